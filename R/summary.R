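#' Round half away from zero
#'
#' Percentage rounding convention of the reported tables (9/26 -> 34.6,
#' 10/26 -> 38.5); base R's `round()` rounds half to even and would disagree
#' on exact halves.
#'
#' @param x Numeric.
#' @param digits Decimal places.
#' @return Rounded values.
#' @export
round_half_away <- function(x, digits = 1L) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Analyzable dyad counts from a cohort manifest
#'
#' @param manifest Data.frame with one row per dyad x task: columns
#'   `dyad_id`, `task`, `usable` (logical; absent records count as unusable).
#'   Every enrolled dyad must appear for at least one task.
#' @param tasks The two task labels, in order; defaults to the alphabetical
#'   unique tasks of the manifest.
#' @return A list with `n_task1`, `n_task2`, `n_both`, `n_enrolled`.
#' @export
analyzable_counts <- function(manifest, tasks = NULL) {
  stopifnot(all(c("dyad_id", "task", "usable") %in% names(manifest)))
  if (is.null(tasks)) tasks <- sort(unique(manifest$task))
  stopifnot(length(tasks) == 2L)
  dyads <- unique(manifest$dyad_id)
  usable_in <- function(task) {
    ok <- manifest$task == task & manifest$usable
    dyads %in% manifest$dyad_id[ok]
  }
  u1 <- usable_in(tasks[1L]); u2 <- usable_in(tasks[2L])
  list(n_task1 = sum(u1), n_task2 = sum(u2), n_both = sum(u1 & u2),
       n_enrolled = length(dyads))
}

#' Per-category synchrony counts and percentages
#'
#' @param calls Data.frame of synchrony calls (`parent_driven`,
#'   `child_driven` columns) for one task.
#' @param denominator Number of analyzable dyads for the task (>= number of
#'   calls).
#' @return A data.frame with one row per direction x sign category:
#'   `direction`, `sign`, `count`, `percent` (one decimal, half away from
#'   zero).
#' @export
synchrony_percentages <- function(calls, denominator) {
  if (denominator <= 0) stop("denominator must be positive")
  if (nrow(calls) > denominator)
    stop("denominator smaller than the number of calls")
  grid <- expand.grid(sign = c("positive", "negative", "null"),
                      direction = c("child_driven", "parent_driven"),
                      stringsAsFactors = FALSE)[, 2:1]
  grid$count <- mapply(function(dir, sg) sum(calls[[dir]] == sg),
                       grid$direction, grid$sign)
  grid$percent <- round_half_away(100 * grid$count / denominator, 1L)
  grid
}

#' Cohen's kappa for two paired binary classifications
#'
#' Chance-corrected agreement `kappa = (p_o - p_e) / (1 - p_e)` with observed
#' agreement `p_o` and chance agreement `p_e` from the marginals. The
#' approximate p-value tests `kappa = 0` with the large-sample standard
#' error under independence (Fleiss, Cohen & Everitt):
#' `var_0 = [p_e + p_e^2 - sum_i p_i. p_.i (p_i. + p_.i)] / (n (1 - p_e)^2)`.
#'
#' @param x,y Logical (or 0/1) vectors of equal length >= 2, paired over
#'   dyads observed in both tasks.
#' @return A list with `kappa`, `p_value`, `p_observed`, `p_expected`, `n`.
#' @export
cohens_kappa <- function(x, y) {
  x <- as.logical(x); y <- as.logical(y)
  stopifnot(length(x) == length(y), length(x) >= 2L,
            !anyNA(x), !anyNA(y))
  n <- length(x)
  p_o <- mean(x == y)
  px <- c(mean(x), 1 - mean(x))
  py <- c(mean(y), 1 - mean(y))
  p_e <- sum(px * py)
  if (1 - p_e < 1e-12)
    stop("undefined kappa: chance agreement is 1 (both margins degenerate)")
  kappa <- (p_o - p_e) / (1 - p_e)
  var0 <- (p_e + p_e^2 - sum(px * py * (px + py))) / (n * (1 - p_e)^2)
  z <- if (var0 > 0) kappa / sqrt(var0) else Inf * sign(kappa)
  list(kappa = kappa, p_value = 2 * stats::pnorm(-abs(z)),
       p_observed = p_o, p_expected = p_e, n = n)
}

#' Cross-task agreement table of synchrony categories
#'
#' Builds the cohort table: for each of the four direction x sign categories
#' (child-driven positive/negative, parent-driven positive/negative), the
#' percentage of analyzable dyads showing the category in each task (per-task
#' denominators) and Cohen's kappa for the category's presence/absence across
#' tasks among dyads analyzable in both. An undefined kappa is reported as
#' `NA` with a note, not an error.
#'
#' @param calls_task1,calls_task2 Synchrony-call data.frames (with `dyad_id`)
#'   for the two tasks, covering all analyzable dyads.
#' @param counts Output of [analyzable_counts()] for the same cohort.
#' @return A data.frame (class `agreement_table`): `direction`, `sign`,
#'   `percent_task1`, `percent_task2`, `kappa`, `p_value`, `note`; attribute
#'   `"n_both"`.
#' @export
build_agreement_table <- function(calls_task1, calls_task2, counts) {
  pc1 <- synchrony_percentages(calls_task1, counts$n_task1)
  pc2 <- synchrony_percentages(calls_task2, counts$n_task2)
  both_ids <- intersect(calls_task1$dyad_id, calls_task2$dyad_id)
  c1 <- calls_task1[match(both_ids, calls_task1$dyad_id), ]
  c2 <- calls_task2[match(both_ids, calls_task2$dyad_id), ]
  grid <- expand.grid(sign = c("positive", "negative"),
                      direction = c("child_driven", "parent_driven"),
                      stringsAsFactors = FALSE)[, 2:1]
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    dir <- grid$direction[i]; sg <- grid$sign[i]
    kp <- tryCatch(cohens_kappa(c1[[dir]] == sg, c2[[dir]] == sg),
                   error = function(e) NULL)
    data.frame(
      direction = dir, sign = sg,
      percent_task1 = pc1$percent[pc1$direction == dir & pc1$sign == sg],
      percent_task2 = pc2$percent[pc2$direction == dir & pc2$sign == sg],
      kappa = if (is.null(kp)) NA_real_ else kp$kappa,
      p_value = if (is.null(kp)) NA_real_ else kp$p_value,
      note = if (is.null(kp)) "kappa undefined (degenerate margins)" else "")
  })
  out <- do.call(rbind, rows)
  attr(out, "n_both") <- length(both_ids)
  class(out) <- c("agreement_table", "data.frame")
  out
}
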