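# Two-group nonparametric statistics: Mann-Whitney U, summaries,
# significance stars.

#' Mann-Whitney U test (two-sided)
#'
#' Rank-based two-sample test. U is computed from midrank sums and
#' reported as `min(U1, U2)`. For tie-free samples with a combined size
#' of at most `exact_max` the two-sided p-value is exact, by full
#' enumeration of the null distribution of U over all group labelings;
#' otherwise the normal approximation with tie correction and a
#' continuity correction is used.
#'
#' @param a,b numeric samples (non-empty).
#' @param exact_max combined-size threshold for the exact branch.
#' @return a list: `u_statistic`, `p_value`, `u1`, `u2`, `method`.
#' @export
mann_whitney <- function(a, b, exact_max = 12L) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  n1 <- length(a); n2 <- length(b)
  if (!n1 || !n2) cmq_stop("both samples must be non-empty", "cmq_invalid_argument")
  pooled <- c(a, b)
  r <- rank(pooled)
  u1 <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  u2 <- n1 * n2 - u1
  u <- min(u1, u2)
  ties <- anyDuplicated(pooled) > 0L

  if (!ties && n1 + n2 <= exact_max) {
    # exact: enumerate U1 over all C(n, n1) assignments of the pooled ranks
    combs <- utils::combn(n1 + n2, n1)
    all_r <- seq_len(n1 + n2)
    u1_null <- colSums(matrix(all_r[combs], nrow = n1)) - n1 * (n1 + 1) / 2
    p <- min(1, 2 * min(mean(u1_null <= u1), mean(u1_null >= u1)))
    method <- "exact enumeration"
  } else {
    n <- n1 + n2
    tt <- table(pooled)
    tie_term <- sum(tt^3 - tt) / (n * (n - 1))
    sigma <- sqrt(n1 * n2 / 12 * ((n + 1) - tie_term))
    mu <- n1 * n2 / 2
    if (sigma == 0) { p <- 1 }
    else {
      z <- (u - mu + 0.5) / sigma              # u <= mu, continuity-corrected
      p <- min(1, 2 * stats::pnorm(z))
    }
    method <- "normal approximation"
  }
  list(u_statistic = u, p_value = p, u1 = u1, u2 = u2, method = method)
}

#' Per-group descriptive summary
#'
#' Mean with both dispersion conventions used in figure reporting: the
#' sample standard deviation (n - 1 denominator) and the standard error
#' of the mean.
#'
#' @param values numeric sample (NAs dropped).
#' @return a list: `n`, `mean`, `sd`, `sem` (`sd`/`sem` are `NA` for
#'   n = 1).
#' @export
summarize_values <- function(values) {
  values <- values[is.finite(values)]
  n <- length(values)
  if (!n) cmq_stop("empty sample", "cmq_invalid_argument")
  s <- if (n > 1L) stats::sd(values) else NA_real_
  list(n = n, mean = mean(values), sd = s,
       sem = if (n > 1L) s / sqrt(n) else NA_real_)
}

#' Significance star annotation
#'
#' Half-open bins: `p < 0.0001` gives `****`, `< 0.001` `***`, `< 0.01`
#' `**`, `< 0.05` `*`, and `p >= 0.05` `ns`.
#'
#' @param p p-value(s) in \[0, 1\].
#' @return character vector of star categories.
#' @export
star_annotation <- function(p) {
  if (any(!is.finite(p) | p < 0 | p > 1))
    cmq_stop("p-values must lie in [0, 1]", "cmq_invalid_argument")
  cut(p, breaks = c(-Inf, 1e-4, 1e-3, 1e-2, 0.05, Inf),
      labels = c("****", "***", "**", "*", "ns"), right = FALSE) |>
    as.character()
}

#' Compare two groups across a table of parameters
#'
#' For each parameter, drops missing values, summarizes both groups and
#' runs the two-sided Mann-Whitney test at alpha 0.05. No
#' multiple-testing correction is applied by default (`holm = TRUE`
#' adjusts the p-values with Holm's method across the parameter list).
#'
#' @param results long- or wide-format data.frame. Long format needs
#'   columns `group`, `parameter`, `value`; wide format needs `group`
#'   plus one numeric column per parameter.
#' @param parameters character vector of parameters to compare; default:
#'   all available.
#' @param groups optional length-2 character vector fixing group order
#'   (group 1 vs group 2).
#' @param holm apply Holm correction across parameters.
#' @return a data.frame, one row per parameter: `parameter`, `n1`, `n2`,
#'   `mean1`, `mean2`, `sd1`, `sd2`, `sem1`, `sem2`, `u_statistic`,
#'   `p_value`, `stars`.
#' @export
compare_groups <- function(results, parameters = NULL, groups = NULL,
                           holm = FALSE) {
  stopifnot(is.data.frame(results), "group" %in% names(results))
  if (!all(c("parameter", "value") %in% names(results))) {
    # wide -> long
    num <- names(results)[vapply(results, is.numeric, logical(1L))]
    num <- setdiff(num, c("cell", "n_beats_averaged", "n_periods_used"))
    results <- do.call(rbind, lapply(num, function(p)
      data.frame(group = results$group, parameter = p, value = results[[p]])))
  }
  gl <- groups %||% unique(as.character(results$group))
  if (length(gl) != 2L)
    cmq_stop("exactly two group labels are required", "cmq_invalid_argument")
  parameters <- parameters %||% unique(as.character(results$parameter))

  rows <- lapply(parameters, function(p) {
    sub <- results[results$parameter == p, ]
    x1 <- sub$value[sub$group == gl[1L]]; x1 <- x1[is.finite(x1)]
    x2 <- sub$value[sub$group == gl[2L]]; x2 <- x2[is.finite(x2)]
    s1 <- summarize_values(x1); s2 <- summarize_values(x2)
    mw <- mann_whitney(x1, x2)
    data.frame(parameter = p, n1 = s1$n, n2 = s2$n,
               mean1 = s1$mean, mean2 = s2$mean,
               sd1 = s1$sd, sd2 = s2$sd, sem1 = s1$sem, sem2 = s2$sem,
               u_statistic = mw$u_statistic, p_value = mw$p_value)
  })
  out <- do.call(rbind, rows)
  if (holm) out$p_value <- stats::p.adjust(out$p_value, method = "holm")
  out$stars <- star_annotation(out$p_value)
  out
}
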