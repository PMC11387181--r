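## ROC analysis and cutpoint derivation -------------------------------------
##
## The unit of analysis is the individual donor molecule: score = its eplet
## mismatch count, label = whether dnDSA developed against that molecule.
## AUC is the Mann-Whitney probability (ties counted 1/2); operating
## points are taken at every distinct score with orientation
## "score >= t => positive". The chosen cutpoint maximizes Youden's J,
## ties resolved toward the higher threshold (higher specificity).

#' ROC curve and AUC for integer scores
#'
#' @param scores numeric (typically integer mismatch counts).
#' @param labels 0/1 (or logical) outcome per score.
#' @return object of class `roc_result`: `auc`, `points` (data.frame
#'   `threshold`, `sensitivity`, `specificity`), `n_pos`, `n_neg`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  stopifnot(length(scores) == length(labels), all(labels %in% 0:1))
  n_pos <- sum(labels == 1L); n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L) {
    stop("roc_auc requires both classes present (",
         n_pos, " positive / ", n_neg, " negative)", call. = FALSE)
  }
  r <- rank(scores)                      # midranks handle ties as 1/2
  auc <- (sum(r[labels == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  th <- sort(unique(scores))
  pts <- data.frame(
    threshold = th,
    sensitivity = vapply(th, function(t) mean(scores[labels == 1L] >= t),
                         numeric(1)),
    specificity = vapply(th, function(t) mean(scores[labels == 0L] < t),
                         numeric(1)))
  structure(list(auc = auc, points = pts, n_pos = n_pos, n_neg = n_neg),
            class = "roc_result")
}

#' Youden-optimal cutpoint of a ROC result
#'
#' Maximizes J = sensitivity + specificity - 1 over the operating points;
#' ties are broken toward the higher threshold (favoring specificity).
#'
#' @param roc a `roc_result`.
#' @return the chosen threshold (same type as the scores).
#' @export
optimal_cutpoint <- function(roc) {
  stopifnot(inherits(roc, "roc_result"))
  j <- roc$points$sensitivity + roc$points$specificity - 1
  cand <- which(j >= max(j) - 1e-12)
  max(roc$points$threshold[cand])
}

#' Two-stage derivation of cohort-specific risk thresholds
#'
#' Stage 1 keeps the published LOW definition (it already isolates a
#' near-zero event-rate stratum). Stage 2 removes LOW recipients and
#' re-runs the per-class molecule-level ROC analysis on the remainder;
#' the Youden-optimal cutpoints become the HIGH thresholds of a
#' conjunction rule (DR >= t_DR and DQ >= t_DQ).
#'
#' @param molecule_data data.frame with columns `pair_id`, `locus_class`
#'   (`"DR"`/`"DQ"`), `score`, `label` (0/1 dnDSA against that molecule).
#' @param summaries recipient summaries (list of `mismatch_summary` or
#'   data.frame with `pair_id`, `dr_max`, `dq_max`).
#' @param low_scheme scheme supplying the retained LOW thresholds.
#' @param name name for the derived scheme.
#' @return list of class `threshold_derivation`: `scheme` (a
#'   `risk_scheme`), `roc_dr`, `roc_dq`, `n_excluded_low`.
#' @export
derive_two_stage_thresholds <- function(molecule_data, summaries,
                                        low_scheme = wiebe_scheme(),
                                        name = "derived") {
  stopifnot(all(c("pair_id", "locus_class", "score", "label") %in%
                  names(molecule_data)))
  sm <- summaries_frame(summaries)
  cat <- classify_risk(sm$dr_max, sm$dq_max, low_scheme)
  low_ids <- sm$pair_id[cat == "LOW"]
  keep <- !(molecule_data$pair_id %in% low_ids)
  md <- molecule_data[keep, , drop = FALSE]
  cut_for <- function(cls) {
    d <- md[md$locus_class == cls, , drop = FALSE]
    if (!nrow(d) || length(unique(d$label)) < 2L) {
      stop("threshold derivation failed for ", cls,
           ": no informative molecule-level data after excluding ",
           length(low_ids), " low-risk recipient(s) (",
           sum(d$label == 1), " events / ", nrow(d), " molecules)",
           call. = FALSE)
    }
    roc <- roc_auc(d$score, d$label)
    list(roc = roc, t = optimal_cutpoint(roc))
  }
  dr <- cut_for("DR")
  dq <- cut_for("DQ")
  structure(list(
    scheme = risk_scheme(name, low_scheme$dr_low_lt, low_scheme$dq_low_lt,
                         dq_ge = dq$t, dr_ge = dr$t),
    roc_dr = dr$roc, roc_dq = dq$roc,
    n_excluded_low = length(low_ids)), class = "threshold_derivation")
}
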