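small_config <- function(out_dir, seed = 5L, n_dyads = 2L) {
  cfg <- unclass(default_config())
  cfg$paths$out_dir <- out_dir
  cfg$seed <- seed
  cfg$cohort$n_dyads <- n_dyads
  cfg$cohort$duration_s <- 120
  cfg$cohort$artifacts$ectopic_rate <- 0     # plumbing test: clean beats
  cfg$cohort$artifacts$dropout_prob <- 0
  cfg$mcmc$min_iterations <- 400L
  cfg$mcmc$check_interval <- 400L
  validate_config(cfg)
}

test_that("configuration validation names the offending key", {
  cfg <- unclass(default_config())
  cfg$taper$family <- "hamming"
  expect_error(validate_config(cfg), "taper.family")
  cfg2 <- unclass(default_config())
  cfg2$mcmc$psr_threshold <- 0.9
  expect_error(validate_config(cfg2), "mcmc.psr_threshold")
  cfg3 <- unclass(default_config())
  cfg3$cohort$regime_mix <- c(positive = 0.5, negative = 0.5, null = 0.5)
  expect_error(validate_config(cfg3), "regime_mix")
})

test_that("YAML round trip overrides defaults and re-validates", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("seed: 99", "band:", "  adult:", "    low: 0.1",
               "    high: 0.5"), path)
  cfg <- read_config(path)
  expect_equal(cfg$seed, 99)
  expect_equal(cfg$band$adult$low, 0.1)
  expect_equal(cfg$taper$family, "dpss")   # untouched default
})

test_that("beat / IBI / RSA CSV schemas round-trip", {
  td <- withr::local_tempdir()
  b <- simulate_beats_from_rsa(log(600), 60, 0.25, 800, seed = 2L)
  f <- file.path(td, "beats.csv")
  write_beats(b, f)
  expect_equal(read_beats(f)$times, b$times)

  ibi <- ibi_series(c(1, 2, 3, 4), c(900, 910, 920, 930),
                    list(c(1.5, 2.5)))
  f2 <- file.path(td, "ibi.csv")
  write_ibi(ibi, f2)
  back <- read_ibi(f2)
  expect_equal(back$ibi, ibi$ibi)
  expect_equal(back$missing_segments, ibi$missing_segments)

  rsa <- const_rsa_df(40L, 6.5)
  class(rsa) <- c("rsa_series", "data.frame")
  f3 <- file.path(td, "rsa.csv")
  write_rsa(rsa, "d1", "t1", "parent", f3)
  back3 <- read_rsa(f3)
  expect_equal(back3$rsa$rsa, rsa$rsa)
  expect_equal(back3$role, "parent")
})

test_that("simulation to disk is deterministic and complete", {
  td1 <- withr::local_tempdir(); td2 <- withr::local_tempdir()
  man1 <- run_simulate(small_config(td1))
  man2 <- run_simulate(small_config(td2))
  expect_equal(man1$dyad_id, man2$dyad_id)
  f1 <- list.files(file.path(td1, "beats"), full.names = TRUE)
  f2 <- list.files(file.path(td2, "beats"), full.names = TRUE)
  expect_equal(basename(f1), basename(f2))
  expect_true(all(mapply(function(a, b)
    identical(readLines(a), readLines(b)), f1, f2)))
  expect_true(file.exists(file.path(td1, "manifest.json")))
  expect_true(file.exists(file.path(td1, "ground_truth.json")))
})

test_that("the pipeline runs end to end and logs skipped records", {
  td <- withr::local_tempdir()
  cfg <- small_config(td, seed = 8L, n_dyads = 3L)
  run_simulate(cfg, unusable = list(list(dyad = 2L, task = "conflict")))
  log <- run_estimate_rsa(cfg)
  expect_equal(nrow(log), 3L * 2L * 2L)      # every manifest row appears
  skipped <- grepl("skipped", log$status)
  expect_equal(sum(skipped), 2L)             # both roles of the unusable record
  expect_true(all(is.finite(log$pct_missing[!skipped])))

  res <- run_fit_and_summarize(cfg)
  expect_equal(res$counts$n_task1, 2L)
  expect_equal(res$counts$n_task2, 3L)
  expect_equal(res$counts$n_both, 2L)
  expect_s3_class(res$agreement, "agreement_table")
  expect_true(all(file.exists(file.path(td,
    c("screening.csv", "posteriors.csv", "synchrony_calls.csv",
      "agreement_table.csv", "summary.json")))))

  # rerunning on the same inputs reproduces the outputs
  calls1 <- read.csv(file.path(td, "synchrony_calls.csv"))
  run_fit_and_summarize(cfg)
  calls2 <- read.csv(file.path(td, "synchrony_calls.csv"))
  expect_identical(calls1, calls2)

  # empty manifest is an explicit error
  td_empty <- withr::local_tempdir()
  cfg_e <- small_config(td_empty)
  dir.create(file.path(td_empty, "rsa"))
  expect_error(run_fit_and_summarize(cfg_e), "empty input")
})
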