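# Demographic/behavioural statistics and brain-behaviour correlations.

#' Pooled-variance two-sample t-test from group summaries
#'
#' Recomputes a two-sample t from published group means and SDs under the
#' pooled-variance convention, `df = n1 + n2 - 2` (the convention implied
#' whenever a report prints df equal to the summed group sizes minus two).
#'
#' @param n1,m1,s1 size, mean and SD of group 1.
#' @param n2,m2,s2 size, mean and SD of group 2.
#' @return list with `t`, `df` and the two-sided `p`.
#' @export
pooled_t_from_summary <- function(n1, m1, s1, n2, m2, s2) {
  if (n1 < 2 || n2 < 2) stop("both groups need n >= 2")
  if (s1 < 0 || s2 < 0) stop("SDs must be non-negative")
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / df
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  t <- (m1 - m2) / se
  if (!is.finite(t)) {
    if (m1 == m2) t <- 0
    else warning("zero pooled variance with unequal means: t is infinite")
  }
  p <- if (is.finite(t)) 2 * pt(-abs(t), df) else 0
  list(t = t, df = df, p = p)
}

#' Pooled-variance two-sample t-test from raw data
#'
#' Cross-check companion to [pooled_t_from_summary()]: computes the same
#' statistic from raw vectors.
#'
#' @param x,y raw observations for the two groups.
#' @return list with `t`, `df`, `p`.
#' @export
pooled_t <- function(x, y) {
  pooled_t_from_summary(length(x), mean(x), sd(x),
                        length(y), mean(y), sd(y))
}

#' Pearson chi-square test of a contingency table
#'
#' Pearson chi-square without continuity correction,
#' `df = (r - 1)(c - 1)`.
#'
#' @param table a matrix of counts with r rows and c columns.
#' @return list with `chi_sq`, `df`, `p`.
#' @export
chi_square <- function(table) {
  table <- as.matrix(table)
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("contingency table has a zero marginal")
  res <- suppressWarnings(chisq.test(table, correct = FALSE))
  if (any(res$expected <= 0)) stop("all expected counts must be positive")
  list(chi_sq = unname(res$statistic), df = unname(res$parameter),
       p = unname(res$p.value))
}

#' Pearson correlation with two-sided p
#'
#' @param x,y finite numeric vectors, length >= 3.
#' @return list with `r`, `p`, `n`.
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("need at least 3 observations")
  stopifnot_finite(c(x, y), "correlation input")
  res <- cor.test(x, y, method = "pearson")
  list(r = unname(res$estimate), p = res$p.value, n = length(x))
}

#' Brain-behaviour association per group
#'
#' For each subject, the whole-brain mean of the window-averaged,
#' baseline-normalized connectivity (correct trials only); within each
#' group, the Pearson correlation of this value with task accuracy.
#'
#' @param conns named list of normalized `conn_ts` (correct-trial
#'   connectivity), names = subject ids.
#' @param behaviour behaviour table with `subject_id`, `group`, `accuracy`.
#' @param window ms pair, default the retention interval.
#' @return data frame with one row per group: `group`, `n`, `r`, `p`.
#' @export
brain_behaviour <- function(conns, behaviour, window = c(250, 1250)) {
  ids <- names(conns)
  if (is.null(ids)) ids <- vapply(conns, `[[`, "", "subject_id")
  conn_value <- vapply(conns, function(cn)
    window_average(mean_whole_brain(cn), window), numeric(1))
  rows <- lapply(unique(behaviour$group), function(g) {
    sub <- behaviour[behaviour$group == g & behaviour$subject_id %in% ids, ]
    if (nrow(sub) < 3)
      stop(sprintf("group '%s' has fewer than 3 subjects with connectivity",
                   g))
    ct <- pearson_correlation(conn_value[sub$subject_id], sub$accuracy)
    data.frame(group = g, n = ct$n, r = ct$r, p = ct$p,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
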