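# Rank-based and regression statistics applied to fold-changes.

#' Kruskal-Wallis rank sum statistic
#'
#' Textbook Kruskal-Wallis H with the tie correction
#' \eqn{D = 1 - \sum (t^3 - t) / (N^3 - N)}; mid-ranks are used for ties
#' and the corrected statistic is referred to a chi-square distribution
#' with \eqn{k - 1} degrees of freedom.
#'
#' @param values numeric vector of observations (no `NA`).
#' @param labels group labels, coerced to factor; at least two non-empty
#'   groups are required.
#' @return a list with elements `H`, `df` and `p`.
#' @examples
#' kruskal_wallis(c(1, 2, 3, 10, 11, 12), rep(c("a", "b"), each = 3))
#' @export
kruskal_wallis <- function(values, labels) {
  values <- as.numeric(values)
  if (anyNA(values)) stopf("'values' must not contain NA")
  g <- factor(labels)
  g <- droplevels(g)
  if (nlevels(g) < 2L) stopf("kruskal_wallis needs at least two groups")
  if (length(values) != length(g)) stopf("'values' and 'labels' lengths differ")
  n <- length(values)
  r <- rank(values)
  rs <- tapply(r, g, sum)
  ns <- tabulate(g)
  h_raw <- 12 / (n * (n + 1)) * sum(rs^2 / ns) - 3 * (n + 1)
  ties <- table(values)
  d <- 1 - sum(ties^3 - ties) / (n^3 - n)
  if (d <= 0) {
    # every observation tied: no information, H defined as 0
    return(list(H = 0, df = nlevels(g) - 1L, p = 1))
  }
  h <- h_raw / d
  df <- nlevels(g) - 1L
  list(H = max(0, h), df = df, p = pchisq(max(0, h), df, lower.tail = FALSE))
}

#' Scheirer-Ray-Hare test: two-way ANOVA on ranks
#'
#' Nonparametric factorial test for a response classified by two factors
#' (here: evolutionary age of a microRNA and its chromosomal context).
#' All values are jointly mid-ranked, sums of squares are computed on the
#' ranks (type II via model comparisons, so unbalanced tables are handled),
#' and each effect's statistic is \eqn{H = SS_{effect} / MS_{total}} with
#' \eqn{MS_{total} = SS_{total}/(N-1)} referred to a chi-square
#' distribution. Because the ranks carry the ties, computing
#' \eqn{MS_{total}} from the realized rank variance makes the tie
#' correction implicit.
#'
#' @param values numeric response (e.g. log2 fold-changes), no `NA`.
#' @param factor_a,factor_b classification labels; each must have at least
#'   two observed levels. A *constant* factor is an error pointing to
#'   [kruskal_wallis()]; passing `factor_b = NULL` runs the one-way
#'   ANOVA-on-ranks limit, whose H equals the tie-corrected
#'   Kruskal-Wallis statistic exactly.
#' @param interaction include the interaction term? If any cell of the
#'   two-way table is empty the interaction is dropped with a warning.
#' @return an object of class `srh_result`: a data.frame with one row per
#'   term (`df`, `H`, `p`) and attributes `N`, `ms_total` and
#'   `tie_correction`.
#' @details With every value identical the total rank variance is zero;
#'   all H statistics are then defined as 0 with p = 1.
#' @examples
#' set.seed(1)
#' v <- rnorm(24) + rep(c(0, 1), each = 12)
#' a <- rep(c("novel", "conserved"), each = 12)
#' b <- rep(c("X", "autosome"), times = 12)
#' scheirer_ray_hare(v, a, b)
#' @export
scheirer_ray_hare <- function(values, factor_a, factor_b = NULL,
                              interaction = TRUE) {
  values <- as.numeric(values)
  if (anyNA(values)) stopf("'values' must not contain NA")
  a <- droplevels(factor(factor_a))
  n <- length(values)
  if (length(a) != n)
    stopf("'values' and factor labels must have equal length")
  if (nlevels(a) < 2L)
    stopf("factor A is constant; use kruskal_wallis() on factor B alone")
  if (is.null(factor_b)) return(.srh_one_way(values, a))
  b <- droplevels(factor(factor_b))
  if (length(b) != n)
    stopf("'values' and factor labels must have equal length")
  if (nlevels(b) < 2L)
    stopf("factor B is constant; use kruskal_wallis() on factor A alone")
  n_cells <- nlevels(a) * nlevels(b)
  if (n < n_cells + 1L)
    stopf("need at least %d observations for a %dx%d design, got %d",
          n_cells + 1L, nlevels(a), nlevels(b), n)
  if (interaction && any(table(a, b) == 0L)) {
    warnf("empty cells in the two-way table; interaction term dropped")
    interaction <- FALSE
  }

  r <- rank(values)
  ss_total <- sum((r - mean(r))^2)
  ties <- table(values)
  tie_corr <- 1 - sum(ties^3 - ties) / (n^3 - n)

  df_a <- nlevels(a) - 1L
  df_b <- nlevels(b) - 1L
  df_ab <- df_a * df_b
  terms <- c("A", "B", if (interaction) "A:B")

  if (ss_total <= 0) {
    out <- data.frame(
      term = terms,
      df = c(df_a, df_b, if (interaction) df_ab),
      H = 0, p = 1, stringsAsFactors = FALSE)
  } else {
    ms_total <- ss_total / (n - 1)
    rss <- function(X) {
      fit <- lm.fit(X, r)
      sum(fit$residuals^2)
    }
    rss_a <- rss(stats::model.matrix(~a))
    rss_b <- rss(stats::model.matrix(~b))
    rss_ab <- rss(stats::model.matrix(~ a + b))
    ss_a <- max(0, rss_b - rss_ab)   # type II: A after B
    ss_b <- max(0, rss_a - rss_ab)
    h <- c(ss_a, ss_b) / ms_total
    df <- c(df_a, df_b)
    if (interaction) {
      rss_full <- rss(stats::model.matrix(~ a * b))
      ss_int <- max(0, rss_ab - rss_full)
      h <- c(h, ss_int / ms_total)
      df <- c(df, df_ab)
    }
    out <- data.frame(term = terms, df = df, H = h,
                      p = pchisq(h, df, lower.tail = FALSE),
                      stringsAsFactors = FALSE)
  }
  attr(out, "N") <- n
  attr(out, "ms_total") <- if (ss_total > 0) ss_total / (n - 1) else 0
  attr(out, "tie_correction") <- tie_corr
  class(out) <- c("srh_result", "data.frame")
  out
}

# one-way ANOVA-on-ranks limit: identical to tie-corrected Kruskal-Wallis
.srh_one_way <- function(values, a) {
  n <- length(values)
  r <- rank(values)
  ss_total <- sum((r - mean(r))^2)
  ties <- table(values)
  tie_corr <- 1 - sum(ties^3 - ties) / (n^3 - n)
  df_a <- nlevels(a) - 1L
  if (ss_total <= 0) {
    out <- data.frame(term = "A", df = df_a, H = 0, p = 1,
                      stringsAsFactors = FALSE)
  } else {
    ms_total <- ss_total / (n - 1)
    fit <- lm.fit(stats::model.matrix(~a), r)
    ss_a <- max(0, ss_total - sum(fit$residuals^2))
    out <- data.frame(term = "A", df = df_a, H = ss_a / ms_total,
                      p = pchisq(ss_a / ms_total, df_a, lower.tail = FALSE),
                      stringsAsFactors = FALSE)
  }
  attr(out, "N") <- n
  attr(out, "ms_total") <- if (ss_total > 0) ss_total / (n - 1) else 0
  attr(out, "tie_correction") <- tie_corr
  class(out) <- c("srh_result", "data.frame")
  out
}

#' @export
print.srh_result <- function(x, ...) {
  cat("Scheirer-Ray-Hare test (ANOVA on ranks, type II SS)\n")
  cat(sprintf("N = %d, MS_total = %.4f, tie correction = %.4f\n",
              attr(x, "N"), attr(x, "ms_total"), attr(x, "tie_correction")))
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Ordinary least-squares line fit
#'
#' Simple linear regression `y ~ x` with the usual t test on the slope,
#' used for the cross-species fold-change conservation fits.
#'
#' @param x,y numeric vectors of equal length, `n >= 3`; `x` must not be
#'   constant.
#' @return a list of class `linear_fit`: `slope`, `intercept`,
#'   `r_squared`, `p` (two-sided, slope), `n`.
#' @export
linear_fit <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3L) stopf("linear_fit needs at least 3 complete observations")
  if (stats::sd(x) == 0) stopf("'x' is constant; slope is not identifiable")
  if (stats::sd(y) == 0) {
    out <- list(slope = 0, intercept = y[1], r_squared = 0, p = 1, n = n)
    class(out) <- "linear_fit"
    return(out)
  }
  fit <- stats::lm(y ~ x)
  sm <- suppressWarnings(summary(fit))  # exact lines are legitimate input
  out <- list(slope = unname(stats::coef(fit)[2]),
              intercept = unname(stats::coef(fit)[1]),
              r_squared = sm$r.squared,
              p = sm$coefficients[2, 4],
              n = n)
  class(out) <- "linear_fit"
  out
}

#' @export
print.linear_fit <- function(x, ...) {
  cat(sprintf("linear fit: slope = %.4g, intercept = %.4g, R2 = %.3f, P = %.4g, n = %d\n",
              x$slope, x$intercept, x$r_squared, x$p, x$n))
  invisible(x)
}
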