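#' Read / write a long-format panel CSV
#'
#' The panel CSV has one row per child per measurement: `child_id`,
#' `age_years`, at least one of `bmi` / `zscore` / `state`, plus `weight`,
#' `stratum`, `psu` and coded covariate columns. States absent from the file
#' are derived downstream (see [classify_panel()]).
#'
#' @param path CSV path.
#' @return Data frame (not yet validated as [as_panel_data()], since `state`
#'   may still need deriving).
#' @export
read_panel <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if ("age_years" %in% names(df) && !"age" %in% names(df)) {
    names(df)[names(df) == "age_years"] <- "age"
  }
  if (!"child_id" %in% names(df)) {
    stop("panel CSV must have a child_id column", call. = FALSE)
  }
  if (!any(c("bmi", "zscore", "state") %in% names(df))) {
    stop("panel CSV needs at least one of bmi, zscore, state", call. = FALSE)
  }
  df
}

#' @rdname read_panel
#' @param panel Panel data frame to write.
#' @export
write_panel <- function(panel, path) {
  df <- as.data.frame(panel)
  names(df)[names(df) == "age"] <- "age_years"
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Derive z-scores and weight states for a panel
#'
#' Fills in `zscore` (from `bmi` via [lms_zscore()], if absent) and `state`
#' (from `zscore` via the chosen cut-off scheme, if absent). Ages are
#' converted to months for the growth reference; the `sex` column (coded 1 =
#' male, 0 = female, or "M"/"F") selects the reference sex.
#'
#' @param panel Panel data frame.
#' @param cutoffs `"uk90_population"` (centile cut-offs) or `"who"`
#'   (age-dependent z-score cut-offs).
#' @param ref A [growth_reference()] (needed only when `bmi` must be
#'   converted).
#' @param implausible_threshold Absolute z-score beyond which a record is
#'   flagged implausible (kept, flagged in column `implausible`; excluded by
#'   [apply_exclusions()]).
#' @return The panel with `zscore`, `state` and `implausible` columns.
#' @export
classify_panel <- function(panel, cutoffs = c("uk90_population", "who"),
                           ref = NULL, implausible_threshold = 5) {
  cutoffs <- match.arg(cutoffs)
  if (is.null(panel$zscore) && !is.null(panel$bmi)) {
    if (is.null(ref)) {
      stop("a growth reference is needed to convert bmi to z-scores",
           call. = FALSE)
    }
    sex_chr <- if (is.numeric(panel$sex)) {
      ifelse(panel$sex == 1, "M", "F")
    } else as.character(panel$sex)
    panel$zscore <- lms_zscore(panel$bmi, panel$age * 12, sex_chr, ref)
  }
  if (!is.null(panel$zscore)) {
    panel$implausible <- flag_implausible(panel$zscore,
                                          implausible_threshold)
  } else {
    panel$implausible <- FALSE
  }
  if (is.null(panel$state)) {
    z <- panel$zscore
    zsafe <- ifelse(is.finite(z), z, 0)  # flagged rows are excluded later
    panel$state <- if (cutoffs == "uk90_population") {
      classify_uk90(zsafe)
    } else {
      classify_who(zsafe, panel$age * 12)
    }
  }
  panel
}

#' Apply the study exclusion rules
#'
#' Drops, in order: flagged multiple births (column `multiple` if present),
#' records flagged implausible, children left with fewer than two
#' observations, and (under complete-case analysis) children missing any
#' configured covariate. Returns the retained panel and an exclusion ledger
#' whose counts reconcile: input children = retained + sum of per-rule
#' exclusions.
#'
#' @param panel Panel data frame (after [classify_panel()] if states needed
#'   deriving).
#' @param covariates Covariate columns checked under complete-case analysis.
#' @param complete_case Apply the complete-case rule?
#' @return List: `panel` (a [as_panel_data()]), `ledger` (data frame of
#'   `rule`, `n_children_excluded`).
#' @export
apply_exclusions <- function(panel, covariates = character(),
                             complete_case = TRUE) {
  n0 <- length(unique(panel$child_id))
  ledger <- list()

  if (!is.null(panel$multiple)) {
    bad <- unique(panel$child_id[panel$multiple %in% c(1, TRUE)])
    ledger$multiple_births <- length(bad)
    panel <- panel[!panel$child_id %in% bad, , drop = FALSE]
  } else ledger$multiple_births <- 0L

  if (!is.null(panel$implausible)) {
    before <- unique(panel$child_id)
    panel <- panel[!panel$implausible, , drop = FALSE]
    # implausible-record exclusion removes records; children disappearing
    # entirely are counted here, the rest fall to the two-measurement rule
    ledger$implausible_records <- length(setdiff(before,
                                                 unique(panel$child_id)))
  } else ledger$implausible_records <- 0L

  nobs <- table(panel$child_id)
  few <- names(nobs)[nobs < 2]
  ledger$fewer_than_two_measurements <- length(few)
  panel <- panel[!panel$child_id %in% few, , drop = FALSE]

  if (complete_case && length(covariates)) {
    has_na <- rep(FALSE, nrow(panel))
    for (cc in intersect(covariates, names(panel))) {
      has_na <- has_na | is.na(panel[[cc]])
    }
    bad <- unique(panel$child_id[has_na])
    ledger$incomplete_covariates <- length(bad)
    panel <- panel[!panel$child_id %in% bad, , drop = FALSE]
  } else ledger$incomplete_covariates <- 0L

  if (!nrow(panel)) stop("all children excluded", call. = FALSE)
  out <- as_panel_data(panel)
  ledger_df <- data.frame(rule = names(ledger),
                          n_children_excluded = unlist(ledger, use.names = FALSE))
  attr(out, "n_input_children") <- n0
  list(panel = out, ledger = ledger_df)
}

.assign_waves <- function(panel, wave_ages) {
  vapply(panel$age, function(a) which.min(abs(wave_ages - a)), integer(1))
}

#' Extract adjacent-wave pairwise datasets (base case)
#'
#' For each adjacent pair of waves, children with a valid state at both
#' waves contribute exactly their two observations, giving five
#' independently fit-ready datasets in which a time-homogeneous process is
#' assumed only within the pair (piecewise linkage across pairs).
#'
#' @param panel A [as_panel_data()].
#' @param wave_ages Nominal wave ages; observations are assigned to the
#'   nearest wave.
#' @return Named list of panel datasets, one per adjacent pair
#'   (`"3-5"`, `"5-7"`, ...).
#' @export
extract_pairwise_datasets <- function(panel,
                                      wave_ages = c(3, 5, 7, 11, 14, 17)) {
  panel <- as_panel_data(panel)
  wave <- .assign_waves(panel, wave_ages)
  out <- list()
  for (i in seq_len(length(wave_ages) - 1)) {
    in_pair <- wave %in% c(i, i + 1L)
    sub <- panel[in_pair, , drop = FALSE]
    wsub <- wave[in_pair]
    # children present at both endpoints, one observation per endpoint
    first_at <- !duplicated(paste(sub$child_id, wsub))
    sub <- sub[first_at, , drop = FALSE]; wsub <- wsub[first_at]
    both <- intersect(sub$child_id[wsub == i], sub$child_id[wsub == i + 1L])
    sub <- sub[sub$child_id %in% both, , drop = FALSE]
    label <- paste0(wave_ages[i], "-", wave_ages[i + 1L])
    if (length(both) < 2) {
      stop("pairwise dataset ", label, " has fewer than two children",
           call. = FALSE)
    }
    out[[label]] <- as_panel_data(sub)
  }
  out
}

#' Extract a time-homogeneous scenario dataset
#'
#' Scenario 1 keeps, for every child observed at the first wave with at
#' least one later observation, all of their observations, fit as a single
#' time-homogeneous dataset (gaps spanned as single long intervals).
#' Scenario 2 keeps only the first adjacent pair, assuming its transition
#' rates hold throughout childhood; it is by construction identical to the
#' first pairwise dataset.
#'
#' @inheritParams extract_pairwise_datasets
#' @param mode `"scenario1"` or `"scenario2"`.
#' @return A panel dataset.
#' @export
extract_scenario_dataset <- function(panel, mode = c("scenario1", "scenario2"),
                                     wave_ages = c(3, 5, 7, 11, 14, 17)) {
  mode <- match.arg(mode)
  panel <- as_panel_data(panel)
  if (mode == "scenario2") {
    return(extract_pairwise_datasets(panel, wave_ages)[[1]])
  }
  wave <- .assign_waves(panel, wave_ages)
  at_w1 <- unique(panel$child_id[wave == 1L])
  later <- unique(panel$child_id[wave > 1L])
  keep <- intersect(at_w1, later)
  if (length(keep) < 2) stop("scenario dataset has fewer than two children",
                             call. = FALSE)
  as_panel_data(panel[panel$child_id %in% keep, , drop = FALSE])
}

.config_hash <- function(config) {
  # hash only analysis-relevant keys, not run plumbing
  config <- config[setdiff(names(config), c("out_dir", "workers"))]
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(config, auto_unbox = TRUE, force = TRUE,
                              digits = NA), tmp)
  unname(tools::md5sum(tmp))
}

#' Read a pipeline configuration file
#'
#' @param path YAML or JSON configuration file.
#' @return Named list.
#' @export
read_config <- function(path) {
  if (grepl("\\.json$", path)) {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
}

#' Run the full analysis pipeline
#'
#' Orchestrates the end-to-end analysis: obtain a panel (simulate a
#' synthetic cohort, or read a panel CSV), derive states, apply exclusions,
#' extract the base-case pairwise datasets and/or scenario dataset, fit the
#' survey-weighted multistate model per dataset, optionally run JKn
#' replicate inference, build traces, and score predicted against observed
#' prevalence. Everything is deterministic given the configuration and
#' seed, and all result tables are written as CSV under `out_dir` alongside
#' run metadata (seed, configuration hash, exclusion ledger).
#'
#' Configuration keys (all optional unless noted): `seed`; `out_dir`;
#' `simulate` (list passed to [sim_config()]) or `panel_csv`; `cutoffs`
#' (`"uk90_population"` or `"who"`); `mode` (`"pairwise"`, `"scenario1"`,
#' `"scenario2"`); `wave_ages`; `covariates`; `complete_case` (default
#' `TRUE`); `robustness` (also fit unadjusted before complete-case
#' exclusion); `replicates` (logical: JKn intervals for each fit);
#' `workers`.
#'
#' @param config Named list or path to a YAML/JSON file.
#' @return A `results_bundle` list: `fits`, `tables` (per-fit intensity /
#'   probability / HR tables), `trace`, `observed`, `validation`,
#'   `exclusions`, `metadata`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_config(config)
  seed <- as.integer(config$seed %||% 1L)
  mode <- config$mode %||% "pairwise"
  wave_ages <- config$wave_ages %||% c(3, 5, 7, 11, 14, 17)
  covariates <- config$covariates %||% character()
  complete_case <- isTRUE(config$complete_case %||% TRUE)
  out_dir <- config$out_dir %||% tempfile("weightmsm_run_")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  # -- input panel
  if (!is.null(config$simulate)) {
    sim_args <- config$simulate
    sim_args$seed <- sim_args$seed %||% seed
    cfg <- do.call(sim_config, sim_args)
    panel <- simulate_cohort(cfg)
  } else if (!is.null(config$panel_csv)) {
    panel <- read_panel(config$panel_csv)
  } else {
    stop("config needs either a simulate block or panel_csv", call. = FALSE)
  }
  ref <- if (!is.null(config$growth_reference)) {
    read_growth_reference(config$growth_reference)
  } else if (is.null(panel$state)) synthetic_growth_reference() else NULL
  panel <- classify_panel(panel, config$cutoffs %||% "uk90_population", ref)

  # -- exclusions (robustness mode also keeps the pre-exclusion fit)
  excl <- apply_exclusions(panel, covariates, complete_case)

  fit_one <- function(p, label, covs) {
    fit_msm(p, covariates = covs, band_label = label)
  }
  datasets <- switch(mode,
    pairwise = extract_pairwise_datasets(excl$panel, wave_ages),
    scenario1 = list(scenario1 = extract_scenario_dataset(
      excl$panel, "scenario1", wave_ages)),
    scenario2 = list(scenario2 = extract_scenario_dataset(
      excl$panel, "scenario2", wave_ages)),
    stop("unknown mode ", mode, call. = FALSE))
  fits <- lapply(names(datasets), function(nm) {
    fit_one(datasets[[nm]], nm, covariates)
  })
  names(fits) <- names(datasets)

  robustness <- NULL
  if (isTRUE(config$robustness)) {
    excl0 <- apply_exclusions(panel, covariates, complete_case = FALSE)
    ds0 <- switch(mode,
      pairwise = extract_pairwise_datasets(excl0$panel, wave_ages),
      list(all = extract_scenario_dataset(excl0$panel, mode, wave_ages)))
    robustness <- lapply(names(ds0), function(nm) {
      fit_one(ds0[[nm]], nm, character())
    })
    names(robustness) <- names(ds0)
  }

  # -- tables (with replicate intervals if requested)
  tables <- list()
  for (nm in names(fits)) {
    f <- fits[[nm]]
    if (!f$converged) next
    tab <- data.frame(dataset = nm,
                      transition = names(f$log_q),
                      intensity = exp(f$log_q))
    if (isTRUE(config$replicates)) {
      rw <- jackknife_replicates(panel_design(datasets[[nm]]))
      reps <- msm_replicate_fits(f, datasets[[nm]], rw,
                                 workers = config$workers %||% 1L)
      ints <- msm_intervals(reps)
      tab$ci_low <- ints$intensities$ci_low
      tab$ci_high <- ints$intensities$ci_high
      utils::write.csv(ints$annual_probabilities,
                       file.path(out_dir, paste0("probabilities_", nm,
                                                 ".csv")),
                       row.names = FALSE)
      if (!is.null(ints$hazard_ratios)) {
        utils::write.csv(ints$hazard_ratios,
                         file.path(out_dir, paste0("hazard_ratios_", nm,
                                                   ".csv")),
                         row.names = FALSE)
      }
    } else {
      p1 <- annual_probabilities(f)
      utils::write.csv(data.frame(from = rep(rownames(p1), 4),
                                  to = rep(colnames(p1), each = 4),
                                  probability = as.numeric(p1)),
                       file.path(out_dir, paste0("probabilities_", nm,
                                                 ".csv")),
                       row.names = FALSE)
      if (length(covariates)) {
        utils::write.csv(hazard_ratios(f),
                         file.path(out_dir, paste0("hazard_ratios_", nm,
                                                   ".csv")),
                         row.names = FALSE)
      }
    }
    tables[[nm]] <- tab
  }

  # -- trace + validation against observed prevalence
  obs <- observed_prevalence(excl$panel, wave_ages)
  schedule <- if (mode == "pairwise") {
    bands <- lapply(seq_len(length(wave_ages) - 1),
                    function(i) wave_ages[i + 0:1])
    ok <- vapply(fits, function(f) isTRUE(f$converged), logical(1))
    if (all(ok)) schedule_from_fits(fits, bands) else NULL
  } else if (isTRUE(fits[[1]]$converged)) {
    matrix_schedule(list(list(age_from = min(wave_ages),
                              age_to = max(wave_ages),
                              P = annual_probabilities(fits[[1]]))))
  } else NULL
  trace <- validation <- NULL
  if (!is.null(schedule)) {
    baseline <- obs[1, ]
    trace <- suppressMessages(
      markov_trace(baseline, schedule, min(wave_ages), max(wave_ages)))
    validation <- predicted_vs_observed(trace, obs)
    write_trace(trace, file.path(out_dir, "trace.csv"))
    utils::write.csv(validation, file.path(out_dir, "validation.csv"),
                     row.names = FALSE)
  }

  utils::write.csv(excl$ledger, file.path(out_dir, "exclusions.csv"),
                   row.names = FALSE)
  if (length(tables)) {
    utils::write.csv(do.call(rbind, tables),
                     file.path(out_dir, "intensities.csv"),
                     row.names = FALSE)
  }
  metadata <- list(seed = seed, mode = mode,
                   config_hash = .config_hash(config),
                   n_input_children = attr(excl$panel, "n_input_children"),
                   n_retained_children = length(unique(
                     excl$panel$child_id)),
                   converged = vapply(fits, function(f) f$converged,
                                      logical(1)))
  jsonlite::write_json(metadata, file.path(out_dir, "run_metadata.json"),
                       auto_unbox = TRUE, digits = NA)

  structure(list(fits = fits, tables = tables, trace = trace,
                 observed = obs, validation = validation,
                 exclusions = excl$ledger, robustness = robustness,
                 datasets = datasets, metadata = metadata,
                 out_dir = out_dir),
            class = "results_bundle")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.results_bundle <- function(x, ...) {
  cat("weightmsm results bundle\n")
  cat("  datasets:", paste(names(x$fits), collapse = ", "), "\n")
  cat("  converged:", paste(vapply(x$fits, function(f) f$converged,
                                   logical(1)), collapse = ", "), "\n")
  cat("  outputs in:", x$out_dir, "\n")
  invisible(x)
}
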