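## Alloimmune risk categories ------------------------------------------------
##
## Threshold schemes partition the (dr_max, dq_max) plane into LOW,
## INTERMEDIATE, HIGH. LOW uses strict < on both loci; HIGH uses >= on DQ
## alone or on DR and DQ jointly; everything else is INTERMEDIATE. Schemes
## are data, not code, so cohort-specific thresholds can be expressed
## without edits.

RISK_LEVELS <- c("LOW", "INTERMEDIATE", "HIGH")

#' Define a risk-category scheme
#'
#' @param name scheme label.
#' @param dr_low_lt,dq_low_lt LOW iff `dr_max < dr_low_lt` and
#'   `dq_max < dq_low_lt`.
#' @param dq_ge HIGH rule DQ threshold (`dq_max >= dq_ge`).
#' @param dr_ge optional HIGH rule DR threshold; when given, the HIGH rule
#'   is the conjunction `dr_max >= dr_ge & dq_max >= dq_ge`.
#' @return object of class `risk_scheme`.
#' @export
risk_scheme <- function(name, dr_low_lt, dq_low_lt, dq_ge, dr_ge = NA) {
  sch <- structure(list(name = name,
                        dr_low_lt = as.integer(dr_low_lt),
                        dq_low_lt = as.integer(dq_low_lt),
                        dq_ge = as.integer(dq_ge),
                        dr_ge = if (is.na(dr_ge)) NA_integer_ else
                          as.integer(dr_ge)),
                   class = "risk_scheme")
  ## LOW and HIGH regions must be disjoint
  grid_max <- max(sch$dr_low_lt, sch$dq_low_lt, sch$dq_ge, sch$dr_ge,
                  na.rm = TRUE) + 2L
  g <- expand.grid(dr = 0:grid_max, dq = 0:grid_max)
  low <- g$dr < sch$dr_low_lt & g$dq < sch$dq_low_lt
  high <- scheme_high_rule(sch, g$dr, g$dq)
  if (any(low & high)) {
    stop("scheme '", name, "': LOW and HIGH regions overlap", call. = FALSE)
  }
  sch
}

scheme_high_rule <- function(scheme, dr, dq) {
  if (is.na(scheme$dr_ge)) dq >= scheme$dq_ge
  else dr >= scheme$dr_ge & dq >= scheme$dq_ge
}

#' Published (Wiebe) HLA-DR/DQ alloimmune risk scheme
#'
#' LOW: DR < 7 and DQ < 9; HIGH: DQ >= 15; else INTERMEDIATE.
#' @return a `risk_scheme`.
#' @export
wiebe_scheme <- function() risk_scheme("wiebe", 7, 9, dq_ge = 15)

#' Cohort-specific (NUCOT) HLA-DR/DQ alloimmune risk scheme
#'
#' LOW: DR < 7 and DQ < 9 (retained from the published scheme); HIGH:
#' DR >= 12 and DQ >= 15 (conjunction); else INTERMEDIATE.
#' @return a `risk_scheme`.
#' @export
nucot_scheme <- function() risk_scheme("nucot", 7, 9, dq_ge = 15, dr_ge = 12)

#' Classify single-molecule maxima into risk categories
#'
#' @param dr_max,dq_max non-negative integer vectors (recycled).
#' @param scheme a `risk_scheme`.
#' @return factor with ordered levels `LOW < INTERMEDIATE < HIGH`.
#' @export
classify_risk <- function(dr_max, dq_max, scheme = wiebe_scheme()) {
  stopifnot(inherits(scheme, "risk_scheme"))
  if (any(is.na(dr_max)) || any(is.na(dq_max)) ||
      any(dr_max < 0) || any(dq_max < 0)) {
    stop("dr_max and dq_max must be non-negative", call. = FALSE)
  }
  n <- max(length(dr_max), length(dq_max))
  dr <- rep_len(dr_max, n); dq <- rep_len(dq_max, n)
  low <- dr < scheme$dr_low_lt & dq < scheme$dq_low_lt
  high <- !low & scheme_high_rule(scheme, dr, dq)
  out <- rep("INTERMEDIATE", n)
  out[low] <- "LOW"
  out[high] <- "HIGH"
  factor(out, levels = RISK_LEVELS, ordered = TRUE)
}

#' Category counts and proportions for a set of recipients
#'
#' @param summaries list of `mismatch_summary` objects, or a data.frame
#'   with columns `dr_max`, `dq_max`.
#' @param scheme a `risk_scheme`.
#' @return data.frame with `category`, `n`, `proportion` (sums to 1).
#' @export
category_proportions <- function(summaries, scheme = wiebe_scheme()) {
  df <- summaries_frame(summaries)
  if (!nrow(df)) stop("no recipients to categorize", call. = FALSE)
  cat <- classify_risk(df$dr_max, df$dq_max, scheme)
  n <- table(cat)
  data.frame(category = factor(RISK_LEVELS, levels = RISK_LEVELS,
                               ordered = TRUE),
             n = as.integer(n[RISK_LEVELS]),
             proportion = as.numeric(n[RISK_LEVELS]) / length(cat))
}

## coerce list-of-summaries or data.frame to (pair_id, dr_max, dq_max)
summaries_frame <- function(summaries) {
  if (is.data.frame(summaries)) {
    stopifnot(all(c("dr_max", "dq_max") %in% names(summaries)))
    return(summaries)
  }
  data.frame(
    pair_id = vapply(summaries, `[[`, character(1), "pair_id"),
    dr_max = vapply(summaries, function(s) as.integer(s$dr_max), integer(1)),
    dq_max = vapply(summaries, function(s) as.integer(s$dq_max), integer(1)),
    dr_antigen_mm = vapply(summaries, function(s)
      as.integer(s$dr_antigen_mm %||% NA_integer_), integer(1)),
    dq_antigen_mm = vapply(summaries, function(s)
      as.integer(s$dq_antigen_mm %||% NA_integer_), integer(1)),
    stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
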