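## Molecule-level label simulator -------------------------------------------
##
## Generates labeled per-molecule data for cutpoint-recovery experiments:
## two DR and two DQ donor molecule scores per pair (pair-correlated, so a
## realistic fraction of recipients falls in the LOW stratum), with dnDSA
## labels from a step (change-point) or logistic link in the mismatch
## score.

#' Parameters for the molecule-level label simulator
#'
#' @param n_pairs donor-recipient pairs (two molecules per class each).
#' @param model `"step"`: P(label) = `p_low` below the threshold, `p_high`
#'   at/above; `"logistic"`: plogis(intercept + slope * score).
#' @param t_dr,t_dq change-point thresholds (step model).
#' @param p_low,p_high step-model label probabilities.
#' @param intercept,slope logistic-model parameters.
#' @param dr_mean,dr_sd,dq_mean,dq_sd pair-level score location/spread;
#'   molecule scores add jitter and are clipped to 0..21 (DR) / 0..32 (DQ).
#' @return list of class `molsim_params`.
#' @export
molsim_params <- function(n_pairs = 234, model = c("step", "logistic"),
                          t_dr = 12, t_dq = 15,
                          p_low = 0.001, p_high = 0.25,
                          intercept = -5, slope = 0.25,
                          dr_mean = 7, dr_sd = 5.5,
                          dq_mean = 9, dq_sd = 7) {
  model <- match.arg(model)
  structure(as.list(environment()), class = "molsim_params")
}

#' Simulate a labeled molecule-level dataset
#'
#' @param params a [molsim_params()].
#' @param seed integer seed.
#' @return list: `molecules` (data.frame `pair_id`, `locus_class`,
#'   `score`, `label`), `summaries` (data.frame `pair_id`, `dr_max`,
#'   `dq_max`).
#' @export
simulate_molecule_level_dataset <- function(params = molsim_params(),
                                            seed = 1) {
  stopifnot(inherits(params, "molsim_params"))
  set.seed(seed)
  n <- params$n_pairs
  pair_id <- sprintf("M%04d", seq_len(n))
  clip <- function(x, hi) pmin(hi, pmax(0, round(x)))
  scores_for <- function(mu, sd, hi) {
    base <- stats::rnorm(n, mu, sd)
    cbind(clip(base + stats::rnorm(n, 0, 1.5), hi),
          clip(base + stats::rnorm(n, 0, 1.5), hi))
  }
  dr <- scores_for(params$dr_mean, params$dr_sd, 21)
  dq <- scores_for(params$dq_mean, params$dq_sd, 32)
  prob <- function(score, t) {
    if (params$model == "step") {
      ifelse(score >= t, params$p_high, params$p_low)
    } else {
      stats::plogis(params$intercept + params$slope * score)
    }
  }
  mol <- rbind(
    data.frame(pair_id = rep(pair_id, 2), locus_class = "DR",
               score = c(dr[, 1], dr[, 2]), stringsAsFactors = FALSE),
    data.frame(pair_id = rep(pair_id, 2), locus_class = "DQ",
               score = c(dq[, 1], dq[, 2]), stringsAsFactors = FALSE))
  t_of <- ifelse(mol$locus_class == "DR", params$t_dr, params$t_dq)
  mol$label <- stats::rbinom(nrow(mol), 1, prob(mol$score, t_of))
  list(molecules = mol,
       summaries = data.frame(pair_id = pair_id,
                              dr_max = pmax(dr[, 1], dr[, 2]),
                              dq_max = pmax(dq[, 1], dq[, 2]),
                              stringsAsFactors = FALSE))
}
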