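## Survival machinery --------------------------------------------------------
##
## Thin, contract-checked wrappers around the survival package:
## Kaplan-Meier product-limit curves, two-sided log-rank tests, and Cox
## proportional-hazards models with Efron tie handling. Categorical
## covariates are fit against a declared reference level and all pairwise
## category contrasts are reported (intermediate vs low, high vs
## intermediate, high vs low).

#' Kaplan-Meier dnDSA-free survival curve
#'
#' @param time event/censoring times (years).
#' @param event 0/1 event indicator.
#' @return object of class `survival_curve`: data.frame `time`, `n_risk`,
#'   `n_event`, `surv`, anchored at (0, 1).
#' @export
km_estimate <- function(time, event) {
  stopifnot(length(time) == length(event), length(time) >= 1,
            all(time >= 0))
  sf <- survival::survfit(survival::Surv(time, event) ~ 1)
  out <- data.frame(time = c(0, sf$time),
                    n_risk = c(length(time), sf$n.risk),
                    n_event = c(0, sf$n.event),
                    surv = c(1, sf$surv))
  structure(out, class = c("survival_curve", "data.frame"))
}

#' Two-sided log-rank test
#'
#' @param time,event survival data.
#' @param group group labels (>= 2 levels present).
#' @return list: `chisq`, `df`, `p`.
#' @export
logrank_test <- function(time, event, group) {
  group <- factor(group)
  if (nlevels(droplevels(group)) < 2L) {
    stop("log-rank test needs at least two groups", call. = FALSE)
  }
  sd <- survival::survdiff(survival::Surv(time, event) ~ group)
  df <- length(sd$n) - 1
  list(chisq = sd$chisq, df = df,
       p = stats::pchisq(sd$chisq, df, lower.tail = FALSE))
}

#' Pairwise (unadjusted) log-rank tests over all group pairs
#' @inheritParams logrank_test
#' @return data.frame `group1`, `group2`, `chisq`, `p`.
#' @export
logrank_pairwise <- function(time, event, group) {
  group <- droplevels(factor(group))
  lv <- levels(group)
  combs <- utils::combn(lv, 2)
  rows <- apply(combs, 2, function(pr) {
    sel <- group %in% pr
    lt <- logrank_test(time[sel], event[sel], droplevels(group[sel]))
    data.frame(group1 = pr[1], group2 = pr[2], chisq = lt$chisq, p = lt$p,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Cox proportional-hazards fit (Efron ties)
#'
#' @param formula a survival formula, e.g.
#'   `Surv(time, event) ~ category + cni`.
#' @param data data.frame; character covariates are converted to factors
#'   (set reference levels beforehand with [stats::relevel()] or factor
#'   level order).
#' @return object of class `cox_fit`: `table` (term, coef, hr, ci_lo,
#'   ci_hi, p), `contrasts` (all pairwise level contrasts per factor
#'   covariate), `loglik`, `n`, `n_event`, and the underlying `model`.
#' @export
cox_fit <- function(formula, data) {
  data <- as.data.frame(data)
  for (v in all.vars(formula[[3]])) {
    if (is.character(data[[v]])) data[[v]] <- factor(data[[v]])
    if (is.factor(data[[v]]) && nlevels(droplevels(data[[v]])) < 2L) {
      stop("covariate '", v, "' is constant across subjects", call. = FALSE)
    }
  }
  fit <- survival::coxph(formula, data = data, ties = "efron",
                         model = TRUE)
  if (any(!is.finite(stats::coef(fit))) ||
      any(abs(stats::coef(fit)) > 15)) {
    warning("possible separation: unbounded coefficient estimate(s)")
  }
  s <- summary(fit)
  tab <- data.frame(term = rownames(s$coefficients),
                    coef = s$coefficients[, "coef"],
                    hr = s$coefficients[, "exp(coef)"],
                    ci_lo = s$conf.int[, "lower .95"],
                    ci_hi = s$conf.int[, "upper .95"],
                    p = s$coefficients[, "Pr(>|z|)"],
                    row.names = NULL, stringsAsFactors = FALSE)
  contrasts <- cox_factor_contrasts(fit, data, formula)
  structure(list(table = tab, contrasts = contrasts,
                 loglik = fit$loglik[length(fit$loglik)],
                 n = s$n, n_event = s$nevent, model = fit),
            class = "cox_fit")
}

## all pairwise level contrasts for each factor covariate, from the fitted
## coefficients and their covariance (reference level has coef 0, var 0)
cox_factor_contrasts <- function(fit, data, formula) {
  out <- list()
  V <- stats::vcov(fit)
  cf <- stats::coef(fit)
  for (v in all.vars(formula[[3]])) {
    x <- data[[v]]
    if (!is.factor(x)) next
    lv <- levels(droplevels(x))
    if (length(lv) < 2L) next
    term_of <- function(l) if (l == lv[1]) NA_character_ else paste0(v, l)
    combs <- utils::combn(lv, 2)
    rows <- lapply(seq_len(ncol(combs)), function(k) {
      l1 <- combs[1, k]; l2 <- combs[2, k]   # contrast: l2 vs l1
      t1 <- term_of(l1); t2 <- term_of(l2)
      b <- (if (is.na(t2)) 0 else cf[[t2]]) - (if (is.na(t1)) 0 else cf[[t1]])
      va <- 0
      if (!is.na(t2)) va <- va + V[t2, t2]
      if (!is.na(t1)) va <- va + V[t1, t1]
      if (!is.na(t1) && !is.na(t2)) va <- va - 2 * V[t1, t2]
      se <- sqrt(va)
      z <- b / se
      data.frame(covariate = v, contrast = paste(l2, "vs", l1),
                 coef = b, hr = exp(b),
                 ci_lo = exp(b - 1.96 * se), ci_hi = exp(b + 1.96 * se),
                 p = 2 * stats::pnorm(-abs(z)),
                 stringsAsFactors = FALSE)
    })
    out[[v]] <- do.call(rbind, rows)
  }
  if (!length(out)) return(NULL)
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' @export
print.cox_fit <- function(x, ...) {
  cat("<cox_fit> n =", x$n, ", events =", x$n_event,
      ", loglik =", format(x$loglik), "\n")
  print(x$table, digits = 3)
  if (!is.null(x$contrasts)) {
    cat("pairwise contrasts:\n")
    print(x$contrasts, digits = 3)
  }
  invisible(x)
}
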