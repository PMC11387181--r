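## Cohort assembly and dnDSA event definition -------------------------------
##
## Cohort records carry exclusion flags set at assembly time; exclusion
## reasons are tallied in a fixed clinical order, each excluded record
## counted once under its first matching reason. A qualifying dnDSA
## detection has MFI >= the cutoff (default 500), falls after the memory
## window (default 14 days; earlier detections indicate pre-sensitization),
## and names a specificity carried by a donor molecule of that locus class.

EXCLUSION_REASONS <- c("primary_non_function", "spk", "abo_incompatible",
                       "pretransplant_dsa", "positive_crossmatch",
                       "inadequate_assessment", "early_dsa_14d")

#' Load a cohort outcomes table
#'
#' @param path CSV with columns `pair_id`, `ethnicity`, `donor_type`,
#'   `cni`, `anti_metabolite`, `induction`, `follow_up_years`, and the
#'   exclusion flag columns (0/1): `primary_non_function`, `spk`,
#'   `abo_incompatible`, `pretransplant_dsa`, `positive_crossmatch`,
#'   `inadequate_assessment` (the early-DSA flag is computed from
#'   detections, see [flag_memory_dsa()]).
#' @return data.frame of cohort records.
#' @export
load_outcomes_table <- function(path) {
  if (!file.exists(path)) stop("outcomes file not found: ", path,
                               call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("pair_id", "follow_up_years")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("outcomes table missing column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  if (any(df$follow_up_years <= 0)) {
    stop("follow_up_years must be positive", call. = FALSE)
  }
  for (fl in setdiff(EXCLUSION_REASONS, "early_dsa_14d")) {
    df[[fl]] <- if (fl %in% names(df)) as.logical(df[[fl]]) else FALSE
  }
  if (!"early_dsa_14d" %in% names(df)) df$early_dsa_14d <- FALSE
  df$pair_id <- as.character(df$pair_id)
  df
}

#' Load a long-format DSA detections table
#' @param path CSV with columns `pair_id`, `day`, `specificity`, `mfi`.
#' @return data.frame.
#' @export
load_detections_table <- function(path) {
  if (!file.exists(path)) stop("detections file not found: ", path,
                               call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("pair_id", "day", "specificity", "mfi")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("detections table missing column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  if (any(df$day < 0, na.rm = TRUE)) stop("detection days must be >= 0",
                                          call. = FALSE)
  df$pair_id <- as.character(df$pair_id)
  df
}

#' Flag memory-response DSA (detection within the early window)
#'
#' @param records cohort records data.frame.
#' @param detections detections data.frame.
#' @param mfi_cutoff qualifying MFI threshold (default 500).
#' @param window_days memory window (default 14 days).
#' @return `records` with `early_dsa_14d` set.
#' @export
flag_memory_dsa <- function(records, detections, mfi_cutoff = 500,
                            window_days = 14) {
  early <- detections$pair_id[detections$day <= window_days &
                                !is.na(detections$mfi) &
                                detections$mfi >= mfi_cutoff]
  records$early_dsa_14d <- records$pair_id %in% early
  records
}

#' Apply cohort exclusion filters
#'
#' @param records cohort records with the flag columns populated.
#' @return list: `retained` (records with no flag), `excluded` (records
#'   with a `reason` column: first matching flag in clinical order),
#'   `tally` (named integer over every reason, zeros included).
#' @export
apply_cohort_filters <- function(records) {
  flags <- sapply(EXCLUSION_REASONS, function(fl) {
    v <- records[[fl]]
    if (is.null(v)) rep(FALSE, nrow(records)) else isTRUE_vec(v)
  })
  if (nrow(records) == 1L) flags <- matrix(flags, nrow = 1,
                                           dimnames = list(NULL,
                                                           EXCLUSION_REASONS))
  any_flag <- rowSums(flags) > 0
  reason <- rep(NA_character_, nrow(records))
  for (fl in rev(EXCLUSION_REASONS)) reason[flags[, fl]] <- fl
  tally <- stats::setNames(integer(length(EXCLUSION_REASONS)),
                           EXCLUSION_REASONS)
  tb <- table(reason[any_flag])
  tally[names(tb)] <- as.integer(tb)
  excluded <- records[any_flag, , drop = FALSE]
  excluded$reason <- reason[any_flag]
  list(retained = records[!any_flag, , drop = FALSE],
       excluded = excluded, tally = tally)
}

isTRUE_vec <- function(v) { v <- as.logical(v); v[is.na(v)] <- FALSE; v }

#' Define per-locus dnDSA event records for one pair
#'
#' @param record one cohort record (one-row data.frame or list with
#'   `pair_id`, `follow_up_years`).
#' @param detections detections data.frame for this pair (or all pairs;
#'   filtered on `pair_id`).
#' @param donor_mols donor [enumerate_molecules()] output for this pair.
#' @param mfi_cutoff qualifying MFI threshold (default 500).
#' @param memory_window_days detections on/before this day are ignored
#'   (memory response; default 14).
#' @param missing_mfi `"screening"` treats a missing MFI as a
#'   screening-only (non-qualifying) row; `"error"` rejects it.
#' @return data.frame with one row per locus (`DR`, `DQ`): `pair_id`,
#'   `locus`, `event` (0/1), `time_years`.
#' @export
define_dndsa_events <- function(record, detections, donor_mols,
                                mfi_cutoff = 500, memory_window_days = 14,
                                missing_mfi = c("screening", "error")) {
  missing_mfi <- match.arg(missing_mfi)
  pid <- as.character(record$pair_id)
  fu <- as.numeric(record$follow_up_years)
  det <- detections[detections$pair_id == pid, , drop = FALSE]
  if (nrow(det) && anyNA(det$mfi)) {
    if (missing_mfi == "error") {
      stop("detection with missing MFI for pair ", pid, call. = FALSE)
    }
    det <- det[!is.na(det$mfi), , drop = FALSE]
  }
  det <- det[det$mfi >= mfi_cutoff & det$day > memory_window_days, ,
             drop = FALSE]
  cls_of <- stats::setNames(donor_mols$locus_class, donor_mols$molecule_id)
  out <- lapply(c("DR", "DQ"), function(cls) {
    t_event <- Inf
    if (nrow(det)) {
      for (i in seq_len(nrow(det))) {
        ids <- suppressWarnings(
          attribute_dsa_to_molecules(det$specificity[i], donor_mols))
        if (any(cls_of[ids] == cls)) {
          t_event <- min(t_event, det$day[i] / 365.25)
        }
      }
    }
    event <- is.finite(t_event) && t_event <= fu
    data.frame(pair_id = pid, locus = cls,
               event = as.integer(event),
               time_years = if (event) t_event else fu,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Assemble the molecule-level ROC dataset for a cohort
#'
#' One row per donor molecule: its eplet mismatch count (score) and
#' whether a qualifying dnDSA was detected against that molecule (label).
#'
#' @param summaries named list (by pair_id) of `mismatch_summary` objects.
#' @param donor_mols_by_pair named list (by pair_id) of donor molecule
#'   data.frames.
#' @param detections detections data.frame.
#' @param mfi_cutoff,memory_window_days qualifying-detection rule.
#' @return data.frame `pair_id`, `molecule_id`, `locus_class`, `score`,
#'   `label`.
#' @export
molecule_roc_data <- function(summaries, donor_mols_by_pair, detections,
                              mfi_cutoff = 500, memory_window_days = 14) {
  det <- detections[!is.na(detections$mfi) &
                      detections$mfi >= mfi_cutoff &
                      detections$day > memory_window_days, , drop = FALSE]
  rows <- lapply(names(summaries), function(pid) {
    sm <- summaries[[pid]]
    mols <- donor_mols_by_pair[[pid]]
    hit_ids <- character()
    d <- det[det$pair_id == pid, , drop = FALSE]
    for (i in seq_len(nrow(d))) {
      hit_ids <- c(hit_ids, suppressWarnings(
        attribute_dsa_to_molecules(d$specificity[i], mols)))
    }
    data.frame(pair_id = pid,
               molecule_id = sm$molecules$molecule_id,
               locus_class = sm$molecules$locus_class,
               score = sm$molecules$count,
               label = as.integer(sm$molecules$molecule_id %in% hit_ids),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
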