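#' Default run configuration
#'
#' All tunables of the pipeline in one validated list: file paths, frequency
#' bands, taper settings, cleaning thresholds, MCMC settings, alpha levels
#' and the master seed. Values can be overridden from a YAML file
#' ([read_config()]) or by named arguments here.
#'
#' @param ... Named overrides of top-level keys (nested lists replace
#'   wholesale).
#' @return A validated configuration list (class `run_config`).
#' @export
default_config <- function(...) {
  cfg <- list(
    paths = list(out_dir = "results", manifest = NULL),
    cohort = list(n_dyads = 28L, duration_s = 300,
                  task_labels = c("conflict", "positive_event"),
                  regime_mix = c(positive = 0.25, negative = 0.25, null = 0.5),
                  crosslag_effect = 0.3,
                  artifacts = list(ectopic_rate = 1,
                                   run_length_probs = c(0.6, 0.3, 0.1),
                                   dropout_prob = 0.2,
                                   dropout_range_s = c(10, 18))),
    band = list(adult = list(low = 0.12, high = 0.40),
                child = list(`6-11` = list(low = 0.15, high = 0.66))),
    taper = list(family = "dpss", n_tapers = 3L, nw = 2),
    power_floor = 1e-6,
    cleaning = list(physio_bounds = c(300, 1500), jump_fraction = 0.25,
                    max_bridge_s = 10),
    mcmc = list(n_chains = 2L, max_iterations = 100000L,
                psr_threshold = 1.05, check_interval = 500L,
                min_iterations = 1000L, burn_in_fraction = 0.5),
    alpha = list(adf = 0.05),
    seed = 1L)
  over <- list(...)
  for (k in names(over)) cfg[[k]] <- over[[k]]
  validate_config(cfg)
}

#' Validate a run configuration
#'
#' Checks key presence, types and ranges; errors name the offending key.
#'
#' @param cfg A configuration list.
#' @return The validated configuration, invisibly classed `run_config`.
#' @export
validate_config <- function(cfg) {
  need <- function(cond, key)
    if (!isTRUE(cond)) stop(sprintf("invalid configuration key: %s", key),
                            call. = FALSE)
  need(is.list(cfg$paths) && !is.null(cfg$paths$out_dir), "paths.out_dir")
  need(is.numeric(cfg$cohort$n_dyads) && cfg$cohort$n_dyads >= 1,
       "cohort.n_dyads")
  need(is.numeric(cfg$cohort$duration_s) && cfg$cohort$duration_s > 64,
       "cohort.duration_s")
  need(abs(sum(cfg$cohort$regime_mix) - 1) < 1e-9, "cohort.regime_mix")
  need(is.list(cfg$cohort$artifacts) &&
         is.numeric(cfg$cohort$artifacts$ectopic_rate) &&
         cfg$cohort$artifacts$ectopic_rate >= 0 &&
         cfg$cohort$artifacts$dropout_prob >= 0 &&
         cfg$cohort$artifacts$dropout_prob <= 1, "cohort.artifacts")
  need(is.numeric(cfg$band$adult$low) && is.numeric(cfg$band$adult$high) &&
         cfg$band$adult$low > 0 && cfg$band$adult$high > cfg$band$adult$low &&
         cfg$band$adult$high < 2, "band.adult")
  need(cfg$taper$family %in% c("dpss", "sine"), "taper.family")
  need(is.numeric(cfg$taper$n_tapers) && cfg$taper$n_tapers >= 1,
       "taper.n_tapers")
  need(is.numeric(cfg$power_floor) && cfg$power_floor > 0, "power_floor")
  need(length(cfg$cleaning$physio_bounds) == 2L &&
         cfg$cleaning$physio_bounds[1L] < cfg$cleaning$physio_bounds[2L],
       "cleaning.physio_bounds")
  need(is.numeric(cfg$mcmc$psr_threshold) && cfg$mcmc$psr_threshold > 1,
       "mcmc.psr_threshold")
  need(is.numeric(cfg$alpha$adf) && cfg$alpha$adf > 0 && cfg$alpha$adf < 1,
       "alpha.adf")
  need(is.numeric(cfg$seed), "seed")
  class(cfg) <- "run_config"
  invisible(cfg)
}

#' Read a YAML run configuration
#'
#' Missing keys fall back to [default_config()] values.
#' @param path YAML file path.
#' @return A validated `run_config`.
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- unclass(default_config())
  merge_in <- function(base, over) {
    for (k in names(over)) {
      base[[k]] <- if (is.list(base[[k]]) && is.list(over[[k]]))
        merge_in(base[[k]], over[[k]]) else over[[k]]
    }
    base
  }
  validate_config(merge_in(cfg, user))
}

child_band_table <- function(cfg) {
  rows <- lapply(names(cfg$band$child), function(rng) {
    ages <- as.numeric(strsplit(rng, "-", fixed = TRUE)[[1L]])
    data.frame(age_min = ages[1L], age_max = ages[2L],
               low = cfg$band$child[[rng]]$low,
               high = cfg$band$child[[rng]]$high)
  })
  do.call(rbind, rows)
}

config_hash <- function(cfg) {
  s <- jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA)
  # small stable rolling hash; enough to stamp outputs with their provenance
  h <- 0
  for (b in utf8ToInt(as.character(s))) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Write / read a beat CSV (`t_sec` column, one participant-task per file)
#' @param beats A [beat_series()].
#' @param path Output file.
#' @return `path`, invisibly ([write_beats()]); a [beat_series()]
#'   ([read_beats()]).
#' @export
write_beats <- function(beats, path) {
  utils::write.csv(data.frame(t_sec = beats$times), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_beats
#' @export
read_beats <- function(path) {
  df <- utils::read.csv(path)
  if (!"t_sec" %in% names(df)) stop("beat CSV must have a t_sec column")
  beat_series(df$t_sec)
}

#' Write / read an IBI CSV (`t_sec`, `ibi_ms`, `missing`); round-trips
#' losslessly including missing segments (stored as an attribute line-free
#' companion: segments are re-derivable from the `missing` flag runs).
#' @param ibi An [ibi_series()].
#' @param path File path.
#' @return `path` invisibly, or an [ibi_series()].
#' @export
write_ibi <- function(ibi, path) {
  in_seg <- rep(0L, length(ibi$times))
  for (seg in ibi$missing_segments)
    in_seg[ibi$times >= seg[1L] & ibi$times < seg[2L]] <- 1L
  utils::write.csv(data.frame(t_sec = ibi$times, ibi_ms = ibi$ibi,
                              missing = in_seg), path, row.names = FALSE)
  seg_df <- if (length(ibi$missing_segments))
    do.call(rbind, lapply(ibi$missing_segments, function(s)
      data.frame(start_s = s[1L], end_s = s[2L])))
  else data.frame(start_s = numeric(0), end_s = numeric(0))
  utils::write.csv(seg_df, sub("\\.csv$", "_segments.csv", path),
                   row.names = FALSE)
  invisible(path)
}

#' @rdname write_ibi
#' @export
read_ibi <- function(path) {
  df <- utils::read.csv(path)
  seg_path <- sub("\\.csv$", "_segments.csv", path)
  segs <- list()
  if (file.exists(seg_path)) {
    sdf <- utils::read.csv(seg_path)
    segs <- lapply(seq_len(nrow(sdf)), function(i)
      c(sdf$start_s[i], sdf$end_s[i]))
  }
  ibi_series(df$t_sec, df$ibi_ms, segs)
}

#' Write an RSA CSV (`dyad_id, task, role, t_sec, rsa_ln_ms2, valid`)
#' @param rsa An `rsa_series`.
#' @param dyad_id,task,role Identifiers for the record.
#' @param path File path.
#' @return `path` invisibly, or on read a list with identifiers and the
#'   `rsa_series`.
#' @export
write_rsa <- function(rsa, dyad_id, task, role, path) {
  utils::write.csv(data.frame(dyad_id = dyad_id, task = task, role = role,
                              t_sec = rsa$second, rsa_ln_ms2 = rsa$rsa,
                              valid = as.integer(rsa$valid)),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_rsa
#' @export
read_rsa <- function(path) {
  df <- utils::read.csv(path)
  rsa <- data.frame(second = df$t_sec, rsa = df$rsa_ln_ms2,
                    valid = df$valid == 1L)
  class(rsa) <- c("rsa_series", "data.frame")
  list(dyad_id = df$dyad_id[1L], task = df$task[1L], role = df$role[1L],
       rsa = rsa)
}

#' Simulate a cohort to disk
#'
#' Writes per-participant beat CSVs, a cohort manifest JSON (dyad, task,
#' role, file, child age, usability, ground-truth parameters and regimes)
#' and stamps every output with the configuration hash and seed.
#' Deterministic: identical config and seed give byte-identical files.
#'
#' @param config A `run_config` (see [default_config()]).
#' @param unusable Optional list of `list(dyad =, task =)` exclusions
#'   emulating unusable or absent records.
#' @return The manifest as a data.frame, invisibly; files under
#'   `config$paths$out_dir`.
#' @export
run_simulate <- function(config = default_config(), unusable = list()) {
  config <- validate_config(unclass(config))
  out <- config$paths$out_dir
  dir.create(file.path(out, "beats"), recursive = TRUE, showWarnings = FALSE)
  spec <- cohort_spec(config$cohort$n_dyads,
                      regime_mix = config$cohort$regime_mix,
                      task_labels = config$cohort$task_labels,
                      duration_s = config$cohort$duration_s,
                      seed = config$seed,
                      crosslag_effect = config$cohort$crosslag_effect,
                      unusable = unusable,
                      artifacts = config$cohort$artifacts)
  records <- make_cohort(spec)
  manifest <- list()
  truth <- list()
  for (rec in records) {
    for (role in c("parent", "child")) {
      fn <- sprintf("%s_%s_%s.csv", rec$dyad_id, rec$task, role)
      if (rec$usable)
        write_beats(rec$beats[[role]], file.path(out, "beats", fn))
      manifest[[length(manifest) + 1L]] <- data.frame(
        dyad_id = rec$dyad_id, task = rec$task, role = role,
        file = file.path("beats", fn),
        child_age = if (role == "child") rec$child_age else NA_integer_,
        usable = rec$usable)
    }
    truth[[length(truth) + 1L]] <- list(
      dyad_id = rec$dyad_id, task = rec$task,
      regimes = as.list(rec$regimes),
      params = list(mu_parent = rec$params$mu_parent,
                    mu_child = rec$params$mu_child,
                    phi_parent = rec$params$phi_parent,
                    phi_child = rec$params$phi_child,
                    beta_parent_to_child = rec$params$beta_parent_to_child,
                    beta_child_to_parent = rec$params$beta_child_to_parent,
                    innovation_cov = rec$params$innovation_cov))
  }
  manifest <- do.call(rbind, manifest)
  meta <- list(config_hash = config_hash(config), seed = config$seed)
  jsonlite::write_json(list(meta = meta, records = manifest),
                       file.path(out, "manifest.json"), dataframe = "rows",
                       auto_unbox = TRUE, digits = 10, pretty = TRUE)
  jsonlite::write_json(list(meta = meta, truth = truth),
                       file.path(out, "ground_truth.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE)
  invisible(manifest)
}

#' Estimate RSA for every usable record of a simulated or ingested cohort
#'
#' Runs the beat-to-IBI, cleaning, 4 Hz interpolation and spectral stages
#' per participant. Unusable or failing records are logged with a reason and
#' skipped, never silently dropped: every manifest row appears in the
#' processing log.
#'
#' @param config A `run_config`; `config$paths$out_dir` must hold
#'   `manifest.json` and the beat CSVs (as written by [run_simulate()]).
#' @return Data.frame log (`dyad_id`, `task`, `role`, `status`,
#'   `pct_missing`), invisibly; RSA CSVs under `<out_dir>/rsa/`.
#' @export
run_estimate_rsa <- function(config = default_config()) {
  config <- validate_config(unclass(config))
  out <- config$paths$out_dir
  man <- jsonlite::read_json(file.path(out, "manifest.json"),
                             simplifyVector = TRUE)$records
  dir.create(file.path(out, "rsa"), showWarnings = FALSE)
  bank <- build_taper_bank(128L, config$taper$n_tapers, config$taper$family,
                           nw = config$taper$nw)
  cb <- child_band_table(config)
  ab <- band_spec(config$band$adult$low, config$band$adult$high, "adult")
  log <- list()
  for (i in seq_len(nrow(man))) {
    row <- man[i, ]
    status <- "ok"; pct_missing <- NA_real_
    if (!row$usable) {
      status <- "skipped: unusable record"
    } else {
      res <- tryCatch({
        beats <- read_beats(file.path(out, row$file))
        ibi <- flag_and_correct(beats_to_ibi(beats),
                                config$cleaning$physio_bounds,
                                config$cleaning$jump_fraction)
        u <- interpolate_4hz(ibi, config$cohort$duration_s,
                             max_bridge_s = config$cleaning$max_bridge_s)
        rsa <- estimate_rsa(u, row$role,
                            child_age = if (row$role == "child")
                              row$child_age else NULL,
                            adult_band = ab, child_bands = cb, bank = bank,
                            power_floor = config$power_floor)
        pct_missing <- 100 * mean(!rsa$valid)
        fn <- sprintf("%s_%s_%s_rsa.csv", row$dyad_id, row$task, row$role)
        write_rsa(rsa, row$dyad_id, row$task, row$role,
                  file.path(out, "rsa", fn))
        NULL
      }, error = function(e) conditionMessage(e))
      if (!is.null(res)) status <- paste("skipped:", res)
    }
    log[[i]] <- data.frame(dyad_id = row$dyad_id, task = row$task,
                           role = row$role, status = status,
                           pct_missing = pct_missing)
  }
  log <- do.call(rbind, log)
  utils::write.csv(cbind(log, config_hash = config_hash(config),
                         seed = config$seed),
                   file.path(out, "rsa_log.csv"), row.names = FALSE)
  invisible(log)
}

#' Fit the dyadic models and build the cohort summary
#'
#' Stationarity-screens each analyzable dyad-task record, fits the Bayesian
#' bivariate lag-1 model, classifies synchrony, and writes: the screening
#' report, the posterior CSV (one row per dyad x task x parameter), the
#' synchrony calls, and the cross-task agreement table. Non-converged dyads
#' are flagged in the outputs, never dropped.
#'
#' @param config A `run_config`; expects RSA CSVs from [run_estimate_rsa()].
#' @return A list with `screening`, `posteriors`, `calls`, `counts`,
#'   `agreement`, invisibly; CSV/JSON outputs under `config$paths$out_dir`.
#' @export
run_fit_and_summarize <- function(config = default_config()) {
  config <- validate_config(unclass(config))
  out <- config$paths$out_dir
  files <- list.files(file.path(out, "rsa"), pattern = "_rsa\\.csv$",
                      full.names = TRUE)
  if (!length(files)) stop("empty input: no RSA records found under ", out)
  recs <- lapply(files, read_rsa)
  key <- vapply(recs, function(r) paste(r$dyad_id, r$task), character(1L))
  screening <- list(); posteriors <- list(); calls <- list()
  mcfg <- mcmc_config(config$mcmc$n_chains, config$mcmc$max_iterations,
                      config$mcmc$psr_threshold, config$mcmc$check_interval,
                      config$mcmc$min_iterations,
                      config$mcmc$burn_in_fraction, seed = config$seed)
  for (k in unique(key)) {
    grp <- recs[key == k]
    roles <- vapply(grp, `[[`, character(1L), "role")
    if (!all(c("parent", "child") %in% roles)) next
    pr <- grp[[which(roles == "parent")[1L]]]
    cr <- grp[[which(roles == "child")[1L]]]
    scr <- tryCatch(screen_dyad(pr$rsa, cr$rsa, alpha = config$alpha$adf),
                    error = function(e) NULL)
    screening[[k]] <- data.frame(
      dyad_id = pr$dyad_id, task = pr$task,
      if (is.null(scr)) data.frame(role = NA, adf_stat_mean = NA,
                                   p_mean = NA, adf_stat_trend = NA,
                                   p_trend = NA, meets_stationarity = NA)
      else scr)
    rec <- tryCatch(dyad_task_record(pr$dyad_id, pr$task, pr$rsa, cr$rsa),
                    error = function(e) NULL)
    if (is.null(rec)) next
    post <- fit_dyad_var(rec, mcfg)
    posteriors[[k]] <- cbind(data.frame(dyad_id = pr$dyad_id,
                                        task = pr$task),
                             as.data.frame(post),
                             converged = attr(post, "converged"),
                             discarded_fraction =
                               attr(post, "discarded_fraction"))
    calls[[k]] <- classify_synchrony(post)
  }
  screening <- do.call(rbind, c(screening, list(make.row.names = FALSE)))
  posteriors <- do.call(rbind, c(posteriors, list(make.row.names = FALSE)))
  calls <- do.call(rbind, c(calls, list(make.row.names = FALSE)))

  man <- jsonlite::read_json(file.path(out, "manifest.json"),
                             simplifyVector = TRUE)$records
  man_d <- unique(man[, c("dyad_id", "task", "usable")])
  fitted <- paste(calls$dyad_id, calls$task)
  man_d$usable <- man_d$usable & paste(man_d$dyad_id, man_d$task) %in% fitted
  tasks <- config$cohort$task_labels
  counts <- analyzable_counts(man_d, tasks)
  agreement <- build_agreement_table(calls[calls$task == tasks[1L], ],
                                     calls[calls$task == tasks[2L], ],
                                     counts)
  utils::write.csv(screening, file.path(out, "screening.csv"),
                   row.names = FALSE)
  utils::write.csv(posteriors, file.path(out, "posteriors.csv"),
                   row.names = FALSE)
  utils::write.csv(calls, file.path(out, "synchrony_calls.csv"),
                   row.names = FALSE)
  utils::write.csv(agreement, file.path(out, "agreement_table.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(meta = list(config_hash = config_hash(config), seed = config$seed),
         counts = counts,
         agreement = agreement,
         n_nonconverged = sum(!posteriors$converged) / 9,
         mean_discarded_fraction =
           mean(posteriors$discarded_fraction)),
    file.path(out, "summary.json"), auto_unbox = TRUE, digits = 10,
    pretty = TRUE, dataframe = "rows")
  invisible(list(screening = screening, posteriors = posteriors,
                 calls = calls, counts = counts, agreement = agreement))
}
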