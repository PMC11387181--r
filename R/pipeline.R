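## Config-driven pipeline ----------------------------------------------------
##
## typing -> imputation -> molecule mismatch -> categories -> dnDSA events
## -> ROC / threshold derivation -> survival models -> report bundle.
## The config is one declarative JSON file; all defaults mirror the
## analysis settings (MFI cutoff 500, 14-day memory window, published
## LOW/HIGH thresholds, derived conjunction rule).

#' Default pipeline configuration
#'
#' @param registry,typings,frequencies,outcomes,detections input paths.
#' @param output_dir report directory.
#' @param ... overrides of the remaining defaults (`mfi_cutoff`,
#'   `memory_window_days`, `impute`, `derive_thresholds`, `schemes`,
#'   `serologic`, `seed`).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(registry, typings, outcomes, detections,
                            frequencies = NULL, output_dir = "epletmm-out",
                            ...) {
  cfg <- list(registry = registry, typings = typings,
              frequencies = frequencies, outcomes = outcomes,
              detections = detections, output_dir = output_dir,
              mfi_cutoff = 500, memory_window_days = 14,
              impute = TRUE, derive_thresholds = TRUE,
              serologic = "prefix", seed = 1,
              schemes = list(
                wiebe = list(dr_low_lt = 7, dq_low_lt = 9, dq_ge = 15),
                nucot = list(dr_low_lt = 7, dq_low_lt = 9, dq_ge = 15,
                             dr_ge = 12)))
  dots <- list(...)
  cfg[names(dots)] <- dots
  if (cfg$mfi_cutoff <= 0) stop("mfi_cutoff must be > 0", call. = FALSE)
  if (cfg$memory_window_days < 0) stop("memory_window_days must be >= 0",
                                       call. = FALSE)
  structure(cfg, class = "pipeline_config")
}

#' Load a pipeline configuration from JSON
#' @param path JSON file; relative input paths are resolved against the
#'   config file's directory.
#' @return a `pipeline_config`.
#' @export
load_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  base <- dirname(normalizePath(path))
  resolve <- function(p) {
    if (is.null(p) || is.na(p) || !nzchar(p)) return(NULL)
    if (file.exists(p)) p else file.path(base, p)
  }
  for (f in c("registry", "typings", "frequencies", "outcomes",
              "detections")) {
    raw[[f]] <- resolve(raw[[f]])
  }
  args <- raw[intersect(names(raw),
                        c("registry", "typings", "frequencies", "outcomes",
                          "detections", "output_dir"))]
  extra <- raw[setdiff(names(raw), names(args))]
  do.call(pipeline_config, c(args, extra))
}

scheme_from_config <- function(name, s) {
  risk_scheme(name, s$dr_low_lt, s$dq_low_lt, dq_ge = s$dq_ge,
              dr_ge = if (is.null(s$dr_ge)) NA else s$dr_ge)
}

#' Run the end-to-end analysis pipeline
#'
#' @param config a `pipeline_config` or path to a config JSON.
#' @return the report (list), invisibly; writes `summary.csv`,
#'   `exclusions.csv`, `events.csv`, `km_tables.csv`, `cox.csv` and
#'   `report.json` into `output_dir`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- load_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  registry <- load_eplet_registry(config$registry)
  typings <- parse_typing_table(config$typings)
  freq <- if (!is.null(config$frequencies))
    load_frequency_table(config$frequencies) else NULL
  records <- load_outcomes_table(config$outcomes)
  detections <- load_detections_table(config$detections)

  ## imputation
  if (config$impute) {
    typings <- lapply(typings, function(st) {
      if (is_two_field(st)) st else {
        if (is.null(freq)) stop("low-resolution typing present but no ",
                                "frequency table configured", call. = FALSE)
        impute_two_field(st, freq)
      }
    })
  }
  roles <- vapply(typings, `[[`, character(1), "role")
  pids <- vapply(typings, `[[`, character(1), "pair_id")
  donors <- stats::setNames(typings[roles == "donor"], pids[roles == "donor"])
  recips <- stats::setNames(typings[roles == "recipient"],
                            pids[roles == "recipient"])
  shared <- intersect(names(donors), names(recips))
  if (!length(shared)) stop("no complete donor-recipient pairs in typing",
                            call. = FALSE)

  summaries <- lapply(shared, function(pid)
    recipient_mismatch_summary(donors[[pid]], recips[[pid]], registry))
  names(summaries) <- shared
  donor_mols <- lapply(shared, function(pid)
    enumerate_molecules(donors[[pid]], registry))
  names(donor_mols) <- shared

  sm <- summaries_frame(summaries)
  schemes <- lapply(names(config$schemes), function(nm)
    scheme_from_config(nm, config$schemes[[nm]]))
  names(schemes) <- names(config$schemes)
  for (nm in names(schemes)) {
    sm[[paste0("category_", nm)]] <-
      as.character(classify_risk(sm$dr_max, sm$dq_max, schemes[[nm]]))
  }

  ## cohort filters
  records <- flag_memory_dsa(records, detections, config$mfi_cutoff,
                             config$memory_window_days)
  filt <- apply_cohort_filters(records)
  retained <- filt$retained[filt$retained$pair_id %in% shared, ,
                            drop = FALSE]

  ## per-locus events, combined HLA-DR/DQ dnDSA-free survival
  events <- do.call(rbind, lapply(seq_len(nrow(retained)), function(i)
    define_dndsa_events(retained[i, ], detections,
                        donor_mols[[retained$pair_id[i]]],
                        config$mfi_cutoff, config$memory_window_days)))
  first_ev <- do.call(rbind, lapply(split(events, events$pair_id),
                                    function(d) {
    ev <- d[d$event == 1, , drop = FALSE]
    t <- if (nrow(ev)) min(ev$time_years) else min(d$time_years)
    data.frame(pair_id = d$pair_id[1], event = as.integer(nrow(ev) > 0),
               time_years = t, stringsAsFactors = FALSE)
  }))
  rownames(first_ev) <- NULL

  analysis <- merge(merge(retained, sm, by = "pair_id"), first_ev,
                    by = "pair_id")

  ## molecule-level ROC per class
  mol_data <- molecule_roc_data(summaries[analysis$pair_id],
                                donor_mols[analysis$pair_id], detections,
                                config$mfi_cutoff,
                                config$memory_window_days)
  roc_report <- lapply(c("DR", "DQ"), function(cls) {
    d <- mol_data[mol_data$locus_class == cls, ]
    if (length(unique(d$label)) < 2) return(NULL)
    roc <- roc_auc(d$score, d$label)
    list(locus_class = cls, auc = roc$auc,
         cutpoint = optimal_cutpoint(roc),
         n_molecules = nrow(d), n_events = sum(d$label))
  })
  names(roc_report) <- c("DR", "DQ")

  derived <- NULL
  if (isTRUE(config$derive_thresholds)) {
    derived <- tryCatch(
      derive_two_stage_thresholds(mol_data, analysis,
                                  low_scheme = schemes[[1]]),
      error = function(e) {
        warning("threshold derivation skipped: ", conditionMessage(e))
        NULL
      })
    if (!is.null(derived)) {
      schemes$derived <- derived$scheme
      analysis$category_derived <-
        as.character(classify_risk(analysis$dr_max, analysis$dq_max,
                                   derived$scheme))
    }
  }

  ## survival by category, per scheme
  surv_report <- list()
  for (nm in names(schemes)) {
    cat_col <- analysis[[paste0("category_", nm)]]
    props <- category_proportions(analysis, schemes[[nm]])
    km <- lapply(split(seq_len(nrow(analysis)), cat_col), function(idx)
      as.data.frame(km_estimate(analysis$time_years[idx],
                                analysis$event[idx])))
    lr <- if (length(unique(cat_col[!is.na(cat_col)])) >= 2)
      logrank_pairwise(analysis$time_years, analysis$event, cat_col)
    else NULL
    surv_report[[nm]] <- list(proportions = props, km = km,
                              logrank_pairwise = lr)
  }

  ## adjusted Cox model: categories + maintenance immunosuppression
  cox_scheme <- if (!is.null(derived)) "derived" else names(schemes)[length(schemes)]
  cox <- tryCatch({
    d <- analysis
    d$category <- factor(d[[paste0("category_", cox_scheme)]],
                         levels = RISK_LEVELS)
    d$category <- droplevels(d$category)
    d$cni <- stats::relevel(factor(d$cni), ref = "tacrolimus")
    d$anti_metabolite <- stats::relevel(factor(d$anti_metabolite),
                                        ref = "azathioprine")
    cox_fit(survival::Surv(time_years, event) ~ category + cni +
              anti_metabolite, d)
  }, error = function(e) {
    warning("adjusted Cox model skipped: ", conditionMessage(e))
    NULL
  })

  report <- list(
    software = list(package = "epletmm",
                    version = as.character(utils::packageVersion("epletmm")),
                    seed = config$seed,
                    config_hash = config_hash(config)),
    n_input = nrow(records),
    exclusions = as.list(filt$tally),
    n_retained = nrow(analysis),
    roc = roc_report[!vapply(roc_report, is.null, logical(1))],
    derived_scheme = if (!is.null(derived)) list(
      dr_low_lt = derived$scheme$dr_low_lt,
      dq_low_lt = derived$scheme$dq_low_lt,
      dr_ge = derived$scheme$dr_ge, dq_ge = derived$scheme$dq_ge,
      n_excluded_low = derived$n_excluded_low) else NULL,
    survival = lapply(surv_report, function(s)
      list(proportions = s$proportions, logrank_pairwise = s$logrank_pairwise)),
    cox = if (!is.null(cox)) list(scheme = cox_scheme, table = cox$table,
                                  contrasts = cox$contrasts,
                                  n = cox$n, n_event = cox$n_event)
    else NULL)

  out <- config$output_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(sm, file.path(out, "summary.csv"), row.names = FALSE)
  utils::write.csv(filt$excluded, file.path(out, "exclusions.csv"),
                   row.names = FALSE)
  utils::write.csv(events, file.path(out, "events.csv"), row.names = FALSE)
  km_rows <- do.call(rbind, unlist(lapply(names(surv_report), function(nm)
    lapply(names(surv_report[[nm]]$km), function(cat) {
      d <- surv_report[[nm]]$km[[cat]]
      if (!nrow(d)) return(NULL)
      cbind(scheme = nm, category = cat, d)
    })), recursive = FALSE))
  utils::write.csv(km_rows, file.path(out, "km_tables.csv"),
                   row.names = FALSE)
  if (!is.null(cox)) {
    utils::write.csv(rbind(
      cbind(kind = "term", cox$table[, c("term", "coef", "hr", "ci_lo",
                                         "ci_hi", "p")]),
      if (!is.null(cox$contrasts)) cbind(
        kind = "contrast",
        data.frame(term = paste(cox$contrasts$covariate,
                                cox$contrasts$contrast),
                   cox$contrasts[, c("coef", "hr", "ci_lo", "ci_hi", "p")]))),
      file.path(out, "cox.csv"), row.names = FALSE)
  }
  jsonlite::write_json(report, file.path(out, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null", dataframe = "rows")
  invisible(report)
}

config_hash <- function(config) {
  cfg <- unclass(config)
  cfg$output_dir <- NULL          # hash analysis inputs/options only
  s <- jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA,
                        null = "null")
  ## tiny stable fingerprint (polynomial rolling hash of the serialized
  ## config; doubles stay exact below 2^53 so this is platform-stable)
  h <- 0
  for (b in utf8ToInt(as.character(s))) {
    h <- (h * 131 + b) %% 2147483647
  }
  sprintf("%08x", h)
}

#' Write a simulated dataset as a runnable pipeline input directory
#'
#' @param sim a `sim_cohort` from [simulate_cohort()].
#' @param registry the `eplet_registry` used.
#' @param freq_table the `haplotype_freq_table` used.
#' @param dir output directory.
#' @return the path of the written config JSON, invisibly.
#' @export
write_simulated_dataset <- function(sim, registry, freq_table, dir) {
  stopifnot(inherits(sim, "sim_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_eplet_registry(registry, file.path(dir, "registry.tsv"))
  write_frequency_table(freq_table, file.path(dir, "frequencies.csv"))
  utils::write.csv(sim$typing, file.path(dir, "typings.csv"),
                   row.names = FALSE, quote = FALSE)
  rec <- sim$records
  for (fl in EXCLUSION_REASONS) rec[[fl]] <- as.integer(rec[[fl]])
  utils::write.csv(rec, file.path(dir, "outcomes.csv"), row.names = FALSE,
                   quote = FALSE)
  utils::write.csv(sim$detections, file.path(dir, "detections.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(sim$truth, file.path(dir, "ground_truth.csv"),
                   row.names = FALSE, quote = FALSE)
  cfg <- list(registry = "registry.tsv", typings = "typings.csv",
              frequencies = "frequencies.csv", outcomes = "outcomes.csv",
              detections = "detections.csv",
              output_dir = file.path(dir, "report"),
              seed = sim$params$seed)
  path <- file.path(dir, "config.json")
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, null = "null")
  invisible(path)
}
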