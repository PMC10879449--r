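make_manifest <- function(n = 28L, unusable_t1 = integer(0),
                          absent_t2 = integer(0)) {
  rows <- list()
  for (d in seq_len(n)) {
    rows[[length(rows) + 1L]] <- data.frame(
      dyad_id = d, task = "conflict", usable = !(d %in% unusable_t1))
    if (!(d %in% absent_t2))
      rows[[length(rows) + 1L]] <- data.frame(
        dyad_id = d, task = "positive_event", usable = TRUE)
  }
  do.call(rbind, rows)
}

test_that("exclusion arithmetic reproduces usable-dyad counts", {
  # 28 enrolled, 2 unusable in task 1, 1 task-1-usable dyad absent in task 2
  man <- make_manifest(28L, unusable_t1 = c(3L, 9L), absent_t2 = 15L)
  counts <- analyzable_counts(man, c("conflict", "positive_event"))
  expect_equal(counts$n_task1, 26L)
  expect_equal(counts$n_task2, 27L)
  expect_equal(counts$n_both, 25L)

  all_ok <- make_manifest(10L)
  expect_equal(unlist(analyzable_counts(all_ok)[1:3]),
               c(n_task1 = 10L, n_task2 = 10L, n_both = 10L))

  # disjoint unusable sets of sizes a and b: n_both = n - a - b
  man2 <- make_manifest(20L, unusable_t1 = 1:3, absent_t2 = 4:5)
  expect_equal(analyzable_counts(man2)$n_both, 20L - 3L - 2L)
})

test_that("percentages follow the half-away-from-zero one-decimal rule", {
  calls <- data.frame(
    parent_driven = c(rep("positive", 5), rep("negative", 10),
                      rep("null", 11)),
    child_driven = c(rep("positive", 9), rep("negative", 6),
                     rep("null", 11)))
  pc <- synchrony_percentages(calls, 26L)
  get <- function(dir, sg) pc$percent[pc$direction == dir & pc$sign == sg]
  expect_equal(get("child_driven", "positive"), 34.6)   # 9/26
  expect_equal(get("child_driven", "negative"), 23.1)   # 6/26
  expect_equal(get("parent_driven", "positive"), 19.2)  # 5/26
  expect_equal(get("parent_driven", "negative"), 38.5)  # 10/26
  # per direction the three categories account for every call
  expect_equal(sum(pc$count[pc$direction == "child_driven"]), 26L)
  expect_error(synchrony_percentages(calls, 0L), "positive")
  expect_error(synchrony_percentages(calls, 10L), "denominator")
})

test_that("Cohen's kappa matches hand-computed values", {
  # identical vectors with both categories present
  x <- c(TRUE, TRUE, FALSE, FALSE, TRUE)
  expect_equal(cohens_kappa(x, x)$kappa, 1)
  # complete disagreement with symmetric 50/50 marginals
  y <- rep(c(TRUE, FALSE), 10L)
  expect_equal(cohens_kappa(y, !y)$kappa, -1)
  # 2x2 table: both-yes 5, x-only 5, y-only 5, both-no 10
  x2 <- rep(c(TRUE, TRUE, FALSE, FALSE), c(5L, 5L, 5L, 10L))
  y2 <- rep(c(TRUE, FALSE, TRUE, FALSE), c(5L, 5L, 5L, 10L))
  kp <- cohens_kappa(x2, y2)
  expect_equal(kp$p_observed, 0.6)
  expect_equal(kp$p_expected, 0.52)
  expect_equal(kp$kappa, 1 / 6, tolerance = 1e-12)
  # label swap invariance
  expect_equal(cohens_kappa(!x2, !y2)$kappa, kp$kappa)
  # degenerate equal margins
  expect_error(cohens_kappa(rep(TRUE, 5L), rep(TRUE, 5L)), "undefined")
})

test_that("kappa is centred at zero under independence", {
  set.seed(17)
  ks <- replicate(500, {
    x <- runif(40) < 0.4
    y <- runif(40) < 0.4
    tryCatch(cohens_kappa(x, y)$kappa, error = function(e) NA_real_)
  })
  expect_lt(abs(mean(ks, na.rm = TRUE)), 0.02)
})

test_that("the agreement table combines per-task percentages with kappa", {
  calls <- function(task, pd, cd, ids = seq_along(pd))
    data.frame(dyad_id = ids, task = task, parent_driven = pd,
               child_driven = cd)
  pd <- rep(c("positive", "negative", "null"), c(4L, 6L, 10L))
  cd <- rep(c("positive", "negative", "null"), c(8L, 5L, 7L))
  c1 <- calls("t1", pd, cd)
  c2 <- calls("t2", pd, cd)
  man <- data.frame(dyad_id = rep(1:20, 2L),
                    task = rep(c("t1", "t2"), each = 20L), usable = TRUE)
  counts <- analyzable_counts(man, c("t1", "t2"))
  tab <- build_agreement_table(c1, c2, counts)
  expect_equal(nrow(tab), 4L)
  expect_true(all(tab$kappa == 1))           # identical calls across tasks
  expect_equal(tab$percent_task1, tab$percent_task2)
  expect_equal(attr(tab, "n_both"), 20L)

  # independent calls across tasks: kappa near zero on average
  set.seed(29)
  ks <- replicate(200, {
    shuffle <- function() rep(c("positive", "null"), c(8L, 12L))[sample(20L)]
    t1 <- calls("t1", shuffle(), shuffle())
    t2 <- calls("t2", shuffle(), shuffle())
    build_agreement_table(t1, t2, counts)$kappa
  })
  expect_lt(abs(mean(ks, na.rm = TRUE)), 0.03)
})
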