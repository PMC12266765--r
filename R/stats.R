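#' Tukey-Kramer all-pairs comparison after one-way ANOVA
#'
#' Pools the within-group variance into the ANOVA error mean square
#' (df = N - k), forms for each pair the studentized-range statistic
#' `q = |m_i - m_j| / sqrt((MSE/2) (1/n_i + 1/n_j))` (the Kramer
#' adjustment admits unequal group sizes), and converts it to a p-value
#' with the studentized-range distribution with `k` groups and `N - k`
#' error degrees of freedom. Stars mark p < 0.05 (`*`) and p < 0.01
#' (`**`).
#'
#' @param groups Named list of numeric vectors, one per group; at least
#'   two groups of at least two values each.
#' @param alpha Two significance thresholds for the star annotation.
#' @return A `tukey_kramer` object: `groups` (label, n, mean, sd),
#'   `mse`, `df_error`, and `pairs` (group1, group2, mean_diff,
#'   q_statistic, p_value, stars).
#' @export
tukey_kramer <- function(groups, alpha = c(0.05, 0.01)) {
  if (!is.list(groups) || length(groups) < 2L)
    stop("need a named list of at least two groups", call. = FALSE)
  if (is.null(names(groups)) || any(!nzchar(names(groups))))
    stop("groups must be named", call. = FALSE)
  n <- vapply(groups, length, 0L)
  if (any(n < 2L))
    stop("every group needs at least 2 values", call. = FALSE)
  k <- length(groups)
  N <- sum(n)
  means <- vapply(groups, mean, 0)
  sds <- vapply(groups, stats::sd, 0)
  mse <- sum((n - 1) * sds^2) / (N - k)
  df_error <- N - k
  idx <- utils::combn(k, 2)
  pairs <- data.frame(
    group1 = names(groups)[idx[1, ]], group2 = names(groups)[idx[2, ]])
  pairs$mean_diff <- means[idx[2, ]] - means[idx[1, ]]
  if (mse > 0) {
    se <- sqrt((mse / 2) * (1 / n[idx[1, ]] + 1 / n[idx[2, ]]))
    pairs$q_statistic <- abs(pairs$mean_diff) / se
    # for two groups the studentized range is exactly sqrt(2)|t|, so the
    # t distribution gives the same p-value at full numerical accuracy
    pairs$p_value <- if (k == 2L) {
      2 * stats::pt(pairs$q_statistic / sqrt(2), df_error,
                    lower.tail = FALSE)
    } else {
      stats::ptukey(pairs$q_statistic, nmeans = k, df = df_error,
                    lower.tail = FALSE)
    }
  } else {
    # all groups constant: identical means are indistinguishable (p = 1),
    # any nonzero difference is seen without error (p = 0)
    pairs$q_statistic <- ifelse(pairs$mean_diff == 0, 0, Inf)
    pairs$p_value <- ifelse(pairs$mean_diff == 0, 1, 0)
  }
  pairs$stars <- ifelse(pairs$p_value < min(alpha), "**",
                        ifelse(pairs$p_value < max(alpha), "*", ""))
  rownames(pairs) <- NULL
  structure(list(
    groups = data.frame(label = names(groups), n = n, mean = means, sd = sds,
                        row.names = NULL),
    mse = mse, df_error = df_error, pairs = pairs),
    class = "tukey_kramer")
}

#' @export
print.tukey_kramer <- function(x, ...) {
  cat(sprintf("<tukey_kramer> %d groups, error df = %d, MSE = %.6g\n",
              nrow(x$groups), x$df_error, x$mse))
  print(x$pairs, digits = 4)
  invisible(x)
}

#' Expected bulk mutation frequency of a clonally expanded variant
#'
#' If a fraction of cells in a tissue (e.g. the COX-negative/SDH-positive
#' fraction seen by histochemistry) carries a variant at a given
#' within-cell heteroplasmy, bulk sequencing of the tissue is expected to
#' report the product: `100 x cell_fraction x within_cell_heteroplasmy`
#' percent.
#'
#' @param cell_fraction Fraction of affected cells, in \[0,1\].
#' @param within_cell_heteroplasmy Heteroplasmy within affected cells, in
#'   \[0,1\].
#' @return Expected bulk frequency in percent.
#' @export
expected_bulk_frequency <- function(cell_fraction, within_cell_heteroplasmy) {
  if (any(cell_fraction < 0 | cell_fraction > 1) ||
      any(within_cell_heteroplasmy < 0 | within_cell_heteroplasmy > 1))
    stop("both arguments must lie in [0, 1]", call. = FALSE)
  100 * cell_fraction * within_cell_heteroplasmy
}

#' Within-cell heteroplasmy implied by a bulk frequency
#'
#' Inverts [expected_bulk_frequency()]: given the affected-cell fraction
#' and an observed bulk frequency, returns the within-cell heteroplasmy
#' that would produce it. Values above 1 are infeasible (no heteroplasmy
#' in that cell fraction can explain the bulk signal) and are reported
#' capped at 1 with `feasible = FALSE`.
#'
#' @param cell_fraction Fraction of affected cells, in (0,1\].
#' @param bulk_frequency Observed bulk frequency in percent.
#' @return List with `heteroplasmy` (capped at 1), `raw` (uncapped), and
#'   `feasible`.
#' @export
detectable_heteroplasmy <- function(cell_fraction, bulk_frequency) {
  if (any(cell_fraction <= 0 | cell_fraction > 1))
    stop("cell_fraction must lie in (0, 1]", call. = FALSE)
  h <- bulk_frequency / (100 * cell_fraction)
  list(heteroplasmy = pmin(h, 1), raw = h, feasible = h <= 1)
}

#' Cohort-level group report
#'
#' Collects per-sample summaries into per-organ, per-metric group tables
#' (mean +/- SD) and runs the Tukey-Kramer comparison for each organ and
#' metric. Ordering of organs, metrics, and groups is deterministic
#' (alphabetical), so permuting the input leaves the report unchanged.
#'
#' @param summaries List of `sample_summary` objects (see
#'   [sample_summary()] / [read_summary()]).
#' @param group_by Metadata fields forming the group label; any subset of
#'   `c("polg_genotype", "generation")`.
#' @param metrics Summary fields to report.
#' @return A `cohort_report`: list with `means` (organ, metric, group, n,
#'   mean, sd) and `tests` (organ, metric + Tukey-Kramer pair rows).
#' @export
cohort_report <- function(summaries,
                          group_by = "polg_genotype",
                          metrics = c("total_mut_freq", "n_nonsyn_gt1",
                                      "n_pathogenic_gt1", "insertion_freq",
                                      "deletion_freq")) {
  stopifnot(length(summaries) >= 1L)
  bad <- setdiff(group_by, c("polg_genotype", "generation"))
  if (length(bad)) stop("unknown grouping field: ", bad[1], call. = FALSE)
  df <- do.call(rbind, lapply(summaries, function(s) {
    row <- data.frame(mouse_id = s$meta$mouse_id, organ = s$meta$organ,
                      polg_genotype = s$meta$polg_genotype,
                      generation = s$meta$generation)
    for (m in metrics) row[[m]] <- as.numeric(s[[m]])
    row
  }))
  df$group <- do.call(paste, c(df[group_by], sep = " "))
  means <- list(); tests <- list()
  for (org in sort(unique(df$organ))) {
    sub <- df[df$organ == org, , drop = FALSE]
    for (m in sort(metrics)) {
      vals <- split(sub[[m]], sub$group)
      vals <- vals[sort(names(vals))]
      if (any(vapply(vals, function(v) all(is.na(v)), TRUE))) next
      means[[length(means) + 1L]] <- data.frame(
        organ = org, metric = m, group = names(vals),
        n = vapply(vals, length, 0L),
        mean = vapply(vals, mean, 0), sd = vapply(vals, stats::sd, 0),
        row.names = NULL)
      if (length(vals) >= 2L && all(vapply(vals, length, 0L) >= 2L)) {
        tk <- tukey_kramer(vals)
        tests[[length(tests) + 1L]] <-
          cbind(organ = org, metric = m, tk$pairs)
      }
    }
  }
  structure(list(means = do.call(rbind, means),
                 tests = if (length(tests)) do.call(rbind, tests) else NULL),
            class = "cohort_report")
}

#' @export
print.cohort_report <- function(x, ...) {
  cat("<cohort_report> group means (mean +/- SD):\n")
  print(x$means, digits = 4)
  if (!is.null(x$tests)) {
    cat("\nTukey-Kramer pairwise tests:\n")
    print(x$tests, digits = 4)
  }
  invisible(x)
}
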