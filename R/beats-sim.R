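#' Beat (R-peak) time series
#'
#' Ordered event times of detected heartbeats, the raw input to the pipeline.
#' Annotations are optional per-beat artifact labels standing in for manual
#' R-spike coding.
#'
#' @param times Strictly increasing beat times in seconds, all >= 0.
#' @param annotations Optional character vector of per-beat labels.
#' @return An object of class `beat_series`.
#' @export
beat_series <- function(times, annotations = NULL) {
  times <- as.numeric(times)
  if (length(times) && (any(times < 0) || any(diff(times) <= 0)))
    stop("beat times must be non-negative and strictly increasing")
  if (!is.null(annotations) && length(annotations) != length(times))
    stop("annotations must match beat count")
  structure(list(times = times, annotations = annotations),
            class = "beat_series")
}

#' @export
print.beat_series <- function(x, ...) {
  cat(sprintf("<beat_series: %d beats over %.1f s>\n",
              length(x$times), if (length(x$times)) max(x$times) else 0))
  invisible(x)
}

#' Synthesise beat times encoding a target RSA trajectory
#'
#' Forward model for validating the spectral stage: builds a continuous
#' heart-period signal `base_ibi + A(t) sin(2 pi f t)` whose modulation
#' amplitude is tied to the target log band power by `A(t) = sqrt(2 exp(rsa))`
#' — the power of a sinusoid of amplitude A is A^2/2, so the local
#' respiratory-band power of the signal equals `exp(rsa_target)` ms^2 —
#' then emits beats by stepping through the instantaneous heart period.
#'
#' @param rsa_target Per-second RSA values (ln ms^2); recycled across each
#'   second, linearly interpolated between seconds. A single value gives a
#'   constant target. Use `-Inf` for zero modulation.
#' @param duration_s Task duration covered by the beats (s).
#' @param resp_freq Respiratory modulation frequency (Hz).
#' @param base_ibi Baseline interbeat interval (ms), in [300, 1500].
#' @param seed Integer seed (reserved for jitter; the deterministic forward
#'   model itself uses no randomness unless `ibi_jitter_ms > 0`).
#' @param ibi_jitter_ms Optional white Gaussian jitter added to each emitted
#'   interval (ms), emulating beat-to-beat variability outside the band.
#' @return A [beat_series()].
#' @export
simulate_beats_from_rsa <- function(rsa_target, duration_s, resp_freq,
                                    base_ibi = 800, seed = 1L,
                                    ibi_jitter_ms = 0) {
  stopifnot(base_ibi >= 300, base_ibi <= 1500, duration_s > 0, resp_freq > 0)
  secs <- seq_len(max(length(rsa_target), 1L)) - 1
  amp_fun <- if (length(rsa_target) == 1L) {
    A <- sqrt(2 * exp(rsa_target))
    function(t) rep(A, length(t))
  } else {
    A <- sqrt(2 * exp(rsa_target))
    stats::approxfun(secs, A, rule = 2)
  }
  if (max(amp_fun(seq(0, duration_s, by = 1))) >= base_ibi)
    stop("rsa_target implies modulation amplitude >= base_ibi (negative IBI)")
  set.seed(as.integer(seed))
  times <- numeric(ceiling(duration_s / (base_ibi / 1000)) + 16L)
  times[1L] <- 0
  k <- 1L
  repeat {
    t <- times[k]
    ibi_ms <- base_ibi + amp_fun(t) * sin(2 * pi * resp_freq * t)
    if (ibi_jitter_ms > 0) ibi_ms <- ibi_ms + stats::rnorm(1L, 0, ibi_jitter_ms)
    nxt <- t + ibi_ms / 1000
    if (nxt > duration_s) break
    k <- k + 1L
    if (k > length(times)) times <- c(times, numeric(64L))
    times[k] <- nxt
  }
  beat_series(times[seq_len(k)])
}

#' Artifact specification for beat-series corruption
#'
#' Describes ectopic-like beat corruption (mis-detected beats at a Poisson
#' rate, in runs of configurable length) and dropout segments with no beats,
#' emulating movement artifact and equipment loss.
#'
#' @param ectopic_rate Expected mis-detected beats per minute (>= 0).
#' @param run_length_probs Probability vector over run lengths 1, 2, 3, ...
#'   of consecutive corrupted beats.
#' @param dropout_segments List of `c(start_s, duration_s)` intervals with no
#'   beats; durations must be positive.
#' @return An object of class `artifact_spec`.
#' @export
artifact_spec <- function(ectopic_rate = 0, run_length_probs = 1,
                          dropout_segments = list()) {
  stopifnot(ectopic_rate >= 0, all(run_length_probs >= 0),
            sum(run_length_probs) > 0 || ectopic_rate == 0)
  for (seg in dropout_segments) {
    if (length(seg) != 2L || seg[2L] <= 0)
      stop("dropout segments must be c(start_s, duration_s) with duration > 0")
  }
  structure(list(ectopic_rate = ectopic_rate,
                 run_length_probs = run_length_probs / max(sum(run_length_probs), 1e-12),
                 dropout_segments = dropout_segments),
            class = "artifact_spec")
}

#' Corrupt a beat series according to an artifact specification
#'
#' Ectopic events arrive at `ectopic_rate` per minute; each event corrupts a
#' run of consecutive beats (run length drawn from `run_length_probs`) by
#' displacing every beat in the run a substantial fraction of its interval —
#' enough to trip interval-based artifact flagging. Dropout segments delete
#' all beats they cover. The ground truth (corrupted beat indices in the
#' output series, and the dropout intervals) is returned alongside.
#'
#' @param beats A [beat_series()].
#' @param spec An [artifact_spec()].
#' @param seed Integer seed.
#' @return A list with elements `beats` (corrupted [beat_series()]) and
#'   `truth` (list with `corrupted_idx`, integer indices into the output
#'   series, and `dropout_segments`).
#' @export
corrupt_beats <- function(beats, spec, seed = 1L) {
  stopifnot(inherits(beats, "beat_series"), inherits(spec, "artifact_spec"))
  set.seed(as.integer(seed))
  times <- beats$times
  n <- length(times)
  corrupted <- logical(n)
  if (spec$ectopic_rate > 0 && n > 3L) {
    dur_min <- (max(times) - min(times)) / 60
    n_events <- stats::rpois(1L, spec$ectopic_rate * dur_min)
    if (n_events > 0L) {
      starts <- sample(2:(n - 1L), min(n_events, n - 2L))
      lens <- sample(seq_along(spec$run_length_probs), length(starts),
                     replace = TRUE, prob = spec$run_length_probs)
      for (j in seq_along(starts)) {
        idx <- starts[j]:min(starts[j] + lens[j] - 1L, n - 1L)
        corrupted[idx] <- TRUE
      }
    }
  }
  if (any(corrupted)) {
    # displace each corrupted beat by 40-60% of its preceding interval:
    # large enough to violate any physiologic jump threshold
    idx <- which(corrupted)
    ibi_prev <- times[idx] - times[idx - 1L]
    shift <- stats::runif(length(idx), 0.4, 0.6) * ibi_prev *
      sample(c(-1, 1), length(idx), replace = TRUE)
    times[idx] <- times[idx] + shift
  }
  keep <- rep(TRUE, n)
  for (seg in spec$dropout_segments)
    keep <- keep & !(times >= seg[1L] & times < seg[1L] + seg[2L])
  times <- times[keep]
  corrupted <- corrupted[keep]
  ord <- order(times)
  times <- times[ord]; corrupted <- corrupted[ord]
  dup <- c(FALSE, diff(times) <= 1e-6)
  times <- times[!dup]; corrupted <- corrupted[!dup]
  list(beats = beat_series(times),
       truth = list(corrupted_idx = which(corrupted),
                    dropout_segments = lapply(spec$dropout_segments,
                                              function(s) c(s[1L], s[1L] + s[2L]))))
}

#' Cohort specification for the synthetic dyad generator
#'
#' @param n_dyads Number of enrolled dyads (>= 1).
#' @param regime_mix Named proportions over synchrony regimes applied
#'   independently to each direction (parent-driven, child-driven):
#'   `c(positive = , negative = , null = )`, summing to 1.
#' @param task_labels Ordered task names.
#' @param duration_s Task length in seconds.
#' @param seed Integer seed.
#' @param crosslag_effect Magnitude given to non-null cross-lags; chosen for
#'   detectability at ~300 s of 1 Hz data.
#' @param unusable Optional list of `list(dyad = , task = )` records marked
#'   unusable (or absent) to exercise the exclusion arithmetic.
#' @param artifacts Beat-corruption settings applied per participant record:
#'   `ectopic_rate` (mis-detected beats per minute), `run_length_probs`,
#'   `dropout_prob` (probability a record contains one dropout segment) and
#'   `dropout_range_s` (its duration range). Defaults produce a few percent
#'   of masked RSA on affected records; set rates to 0 for clean data.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_dyads,
                        regime_mix = c(positive = 0.25, negative = 0.25, null = 0.5),
                        task_labels = c("conflict", "positive_event"),
                        duration_s = 300, seed = 1L,
                        crosslag_effect = 0.3,
                        unusable = list(),
                        artifacts = list(ectopic_rate = 1,
                                         run_length_probs = c(0.6, 0.3, 0.1),
                                         dropout_prob = 0.2,
                                         dropout_range_s = c(10, 18))) {
  stopifnot(n_dyads >= 1,
            all(names(regime_mix) %in% c("positive", "negative", "null")),
            all(regime_mix >= 0), all(regime_mix <= 1),
            abs(sum(regime_mix) - 1) < 1e-9,
            length(task_labels) >= 1, duration_s > 64)
  structure(list(n_dyads = as.integer(n_dyads), regime_mix = regime_mix,
                 task_labels = task_labels, duration_s = duration_s,
                 seed = as.integer(seed), crosslag_effect = crosslag_effect,
                 unusable = unusable, artifacts = artifacts),
            class = "cohort_spec")
}

regime_to_beta <- function(regime, effect) {
  switch(regime, positive = effect, negative = -effect, null = 0)
}

#' Assemble a synthetic cohort of dyads with known ground truth
#'
#' For each dyad and task, draws a synchrony regime per direction from the
#' cohort's regime mix, builds the ground-truth lag-1 parameters, simulates
#' the paired RSA trajectories, and renders each participant's trajectory as
#' a beat series with respiratory-band modulation. Records marked unusable
#' keep their flag so exclusion arithmetic can be exercised downstream.
#'
#' Dyad-level heterogeneity: RSA levels, autoregression and respiratory
#' frequencies vary across dyads within physiologically plausible ranges
#' (adult respiration 0.2-0.3 Hz; child respiration faster, 0.3-0.4 Hz;
#' child heart period shorter than the parent's).
#'
#' @param spec A [cohort_spec()].
#' @return A list of records, one per dyad x task, each with `dyad_id`,
#'   `task`, `usable`, ground-truth `params` ([var_params()]), `regimes`
#'   (per-direction labels), per-role `beats`, `resp_freq`, `base_ibi`,
#'   `child_age`, and the simulated ground-truth `rsa` data.frame.
#' @export
make_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  regimes <- names(spec$regime_mix)
  records <- list()
  for (d in seq_len(spec$n_dyads)) {
    dyad_id <- sprintf("dyad%02d", d)
    child_age <- sample(6:11, 1L)
    base_p <- stats::runif(1L, 750, 950)
    base_c <- stats::runif(1L, 550, 750)
    f_p <- stats::runif(1L, 0.20, 0.30)
    f_c <- stats::runif(1L, 0.30, 0.40)
    for (task in spec$task_labels) {
      reg_pd <- sample(regimes, 1L, prob = spec$regime_mix)
      reg_cd <- sample(regimes, 1L, prob = spec$regime_mix)
      params <- var_params(
        mu_parent = stats::runif(1L, 6.0, 7.0),
        mu_child = stats::runif(1L, 5.5, 6.5),
        phi_parent = stats::runif(1L, 0.3, 0.5),
        phi_child = stats::runif(1L, 0.3, 0.5),
        beta_parent_to_child = regime_to_beta(reg_pd, spec$crosslag_effect),
        beta_child_to_parent = regime_to_beta(reg_cd, spec$crosslag_effect),
        innovation_cov = matrix(c(0.09, 0.018, 0.018, 0.09), 2L))
      sim_seed <- spec$seed + 1000L * d + 17L * match(task, spec$task_labels)
      rsa <- simulate_var_series(params, ceiling(spec$duration_s), sim_seed)
      beats_p <- simulate_beats_from_rsa(rsa$parent, spec$duration_s, f_p,
                                         base_p, seed = sim_seed + 1L)
      beats_c <- simulate_beats_from_rsa(rsa$child, spec$duration_s, f_c,
                                         base_c, seed = sim_seed + 2L)
      art <- spec$artifacts
      truth_art <- list()
      if (!is.null(art) &&
          (art$ectopic_rate > 0 || art$dropout_prob > 0)) {
        for (role_i in 1:2) {
          set.seed(sim_seed + 2L + role_i)
          segs <- if (stats::runif(1L) < art$dropout_prob) {
            start <- stats::runif(1L, 32, spec$duration_s - 50)
            list(c(start, stats::runif(1L, art$dropout_range_s[1L],
                                       art$dropout_range_s[2L])))
          } else list()
          aspec <- artifact_spec(art$ectopic_rate, art$run_length_probs,
                                 segs)
          cor <- corrupt_beats(if (role_i == 1L) beats_p else beats_c,
                               aspec, seed = sim_seed + 6L + role_i)
          if (role_i == 1L) beats_p <- cor$beats else beats_c <- cor$beats
          truth_art[[c("parent", "child")[role_i]]] <- cor$truth
        }
      }
      usable <- !any(vapply(spec$unusable, function(u)
        u$dyad == d && u$task == task, logical(1L)))
      records[[length(records) + 1L]] <- list(
        dyad_id = dyad_id, task = task, usable = usable,
        params = params,
        regimes = c(parent_driven = reg_pd, child_driven = reg_cd),
        beats = list(parent = beats_p, child = beats_c),
        resp_freq = c(parent = f_p, child = f_c),
        base_ibi = c(parent = base_p, child = base_c),
        child_age = child_age, rsa = rsa, artifact_truth = truth_art)
    }
  }
  records
}
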