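# Per-recording percentages, group summaries, bootstrap benchmark
# comparisons, condition contrasts and empirical CDFs.

#' Percentage of flagged channels or epochs
#'
#' `100 * flagged / total` from a `channel_qc` or `epoch_qc` result. With 16
#' channels a single bad channel is 6.25%; with 64 channels it is 1.5625%
#' (1.6% at one decimal).
#'
#' @param result A QC result tibble with a logical `bad` column.
#' @return Percentage in `[0, 100]`.
#' @export
percent_bad <- function(result) {
  if (!is.data.frame(result) || !"bad" %in% names(result))
    stop("`result` must be a QC result with a `bad` column", call. = FALSE)
  if (nrow(result) == 0L) stop("empty QC result", call. = FALSE)
  100 * sum(result$bad) / nrow(result)
}

#' Mean, standard deviation and standard error
#'
#' @param values Numeric vector, length >= 2.
#' @return A one-row tibble with `mean`, `sd`, `sem`, `n`.
#' @export
#' @examples
#' group_summary(c(0, 10))  # mean 5, sem 5
group_summary <- function(values) {
  n <- length(values)
  if (n < 2L) stop("group_summary needs at least 2 values", call. = FALSE)
  s <- sd(values)
  tibble(mean = mean(values), sd = s, sem = s / sqrt(n), n = n)
}

#' Bootstrap comparison of a large field sample against a benchmark
#'
#' The field datasets are far larger than the lab benchmarks, so a direct
#' test would be dominated by the field sample size. Instead, on each of
#' `iters` iterations a subsample of the benchmark's size is drawn without
#' replacement from the field values and compared with the benchmark by a
#' two-sided Welch t test; the reported significance is the average p value
#' over iterations. With `iters = 1` and equally sized samples this
#' degenerates to a single plain t test.
#'
#' @param field Numeric vector (the large field sample).
#' @param benchmark Numeric vector, `length(benchmark) <= length(field)`,
#'   at least 2 values.
#' @param iters Number of subsampling iterations (default 50).
#' @param seed Optional integer seed; the RNG state is restored afterwards.
#' @return An object of class `qc_bootstrap`; see [tidy()] / [glance()].
#' @export
bootstrap_compare <- function(field, benchmark, iters = 50, seed = NULL) {
  nb <- length(benchmark)
  if (nb < 2L) stop("`benchmark` needs at least 2 values", call. = FALSE)
  if (length(field) < nb)
    stop("cannot subsample: `field` (", length(field),
         ") is smaller than `benchmark` (", nb, ")", call. = FALSE)
  if (iters < 1L) stop("`iters` must be >= 1", call. = FALSE)
  run <- function() {
    vapply(seq_len(iters), function(i) {
      sub <- sample(field, nb, replace = FALSE)
      stats::t.test(sub, benchmark)$p.value
    }, numeric(1))
  }
  ps <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  structure(
    list(p_value = mean(ps), p_values = ps,
         group_a = group_summary(field), group_b = group_summary(benchmark),
         n_iterations = iters, test = "bootstrap_t", seed = seed),
    class = "qc_bootstrap"
  )
}

#' @export
print.qc_bootstrap <- function(x, ...) {
  cat("<qc_bootstrap> mean p = ", signif(x$p_value, 3), " over ",
      x$n_iterations, " subsampled Welch t tests\n", sep = "")
  cat("  field:     mean ", signif(x$group_a$mean, 4), " +/- ",
      signif(x$group_a$sem, 3), " sem (n = ", x$group_a$n, ")\n", sep = "")
  cat("  benchmark: mean ", signif(x$group_b$mean, 4), " +/- ",
      signif(x$group_b$sem, 3), " sem (n = ", x$group_b$n, ")\n", sep = "")
  invisible(x)
}

#' @export
tidy.qc_bootstrap <- function(x, ...) {
  tibble(group_a_mean = x$group_a$mean, group_a_sem = x$group_a$sem,
         group_a_n = x$group_a$n,
         group_b_mean = x$group_b$mean, group_b_sem = x$group_b$sem,
         group_b_n = x$group_b$n,
         p_value = x$p_value, n_iterations = x$n_iterations, test = x$test)
}

#' @export
glance.qc_bootstrap <- function(x, ...) {
  tibble(p_value = x$p_value, n_iterations = x$n_iterations,
         p_min = min(x$p_values), p_max = max(x$p_values), test = x$test)
}

#' Pairwise group contrasts of a quality measure
#'
#' Two-sided Welch t test for every unordered pair of levels of a grouping
#' column (e.g. sex, indoor/outdoor, team), reporting mean and standard error
#' per level. Levels with fewer than 2 observations are skipped with a
#' warning.
#'
#' @param data A data frame (typically pooled QC summaries).
#' @param value Unquoted column holding the measure (e.g.
#'   `pct_bad_channels`).
#' @param group Unquoted grouping column.
#' @return A tibble with one row per level pair.
#' @export
#' @examples
#' df <- data.frame(g = rep(c("a", "b"), each = 5), v = c(1:5, 6:10))
#' contrast_groups(df, v, g)
contrast_groups <- function(data, value, group) {
  v <- dplyr::pull(data, {{ value }})
  g <- as.character(dplyr::pull(data, {{ group }}))
  keep <- !is.na(v) & !is.na(g)
  v <- v[keep]; g <- g[keep]
  levels <- sort(unique(g))
  sizes <- table(g)
  small <- names(sizes)[sizes < 2]
  if (length(small) > 0) {
    warning("skipping level(s) with fewer than 2 observations: ",
            paste(small, collapse = ", "))
    levels <- setdiff(levels, small)
  }
  if (length(levels) < 2)
    stop("need at least 2 levels with n >= 2", call. = FALSE)
  pairs <- utils::combn(levels, 2)
  out <- lapply(seq_len(ncol(pairs)), function(k) {
    a <- pairs[1, k]; b <- pairs[2, k]
    va <- v[g == a]; vb <- v[g == b]
    tt <- if (sd(va) == 0 && sd(vb) == 0 && mean(va) == mean(vb)) {
      list(p.value = 1)  # identical degenerate groups: no evidence at all
    } else stats::t.test(va, vb)
    tibble(group_a = a, group_b = b,
           mean_a = mean(va), sem_a = sd(va) / sqrt(length(va)), n_a = length(va),
           mean_b = mean(vb), sem_b = sd(vb) / sqrt(length(vb)), n_b = length(vb),
           p_value = tt$p.value, test = "welch_t")
  })
  dplyr::bind_rows(out)
}

#' Empirical cumulative distribution function
#'
#' Right-continuous ECDF as a step-function table: the sorted unique values
#' and the cumulative fraction at each, reaching exactly 1 at the maximum.
#' Invariant under permutation of the input.
#'
#' @param values Numeric vector, length >= 1.
#' @return A tibble of class `qc_ecdf` with columns `value`, `frac`.
#' @export
empirical_cdf <- function(values) {
  if (length(values) == 0L) stop("empty input", call. = FALSE)
  if (anyNA(values)) stop("NA values in ECDF input", call. = FALSE)
  x <- sort(unique(values))
  fn <- stats::ecdf(values)
  out <- tibble(value = x, frac = fn(x))
  class(out) <- c("qc_ecdf", class(out))
  out
}
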