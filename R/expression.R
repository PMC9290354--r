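# Sex-bias differential expression from small-RNA count tables.
#
# The model is a transparent stand-in for the NB/voom machinery usually
# applied to such data: ordinary least squares on log2(normalized count +
# 0.5) under expression ~ batch + sex, followed by empirical-Bayes
# moderation of the residual variances and a moderated t test.

#' Container for a microRNA count experiment
#'
#' Bundles an integer count matrix (loci x samples) with per-sample
#' metadata, in the spirit of edgeR's `DGEList`.
#'
#' @param counts numeric matrix of non-negative integers; rownames are
#'   locus IDs, colnames are sample IDs.
#' @param samples data.frame with columns `sample`, `sex`
#'   (male/female), `batch`, and optionally `tissue`
#'   (whole/testis/ovary; default "whole").
#' @return an object of class `CountExperiment`: a list with elements
#'   `counts` and `samples` (rows ordered as the matrix columns).
#' @export
count_experiment <- function(counts, samples) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stopf("'counts' must have locus rownames and sample colnames")
  if (anyNA(counts) || any(counts < 0) || any(counts != round(counts)))
    stopf("'counts' must be non-negative integers")
  storage.mode(counts) <- "integer"
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  req <- c("sample", "sex", "batch")
  miss <- setdiff(req, names(samples))
  if (length(miss)) stopf("sample metadata lacks column(s): %s",
                          paste(miss, collapse = ", "))
  if (is.null(samples$tissue)) samples$tissue <- "whole"
  extra <- setdiff(colnames(counts), samples$sample)
  lost <- setdiff(samples$sample, colnames(counts))
  if (length(extra) || length(lost))
    stopf("sample IDs disagree between counts and metadata: %s",
          paste(c(extra, lost), collapse = ", "))
  samples <- samples[match(colnames(counts), samples$sample), , drop = FALSE]
  rownames(samples) <- NULL
  if (!all(samples$sex %in% c("male", "female")))
    stopf("'sex' must be 'male' or 'female'")
  if (anyNA(samples$batch)) stopf("every sample needs a batch label")
  structure(list(counts = counts, samples = samples),
            class = "CountExperiment")
}

#' @export
print.CountExperiment <- function(x, ...) {
  cat(sprintf("CountExperiment: %d loci x %d samples (%d male, %d female)\n",
              nrow(x$counts), ncol(x$counts),
              sum(x$samples$sex == "male"), sum(x$samples$sex == "female")))
  invisible(x)
}

#' @export
dim.CountExperiment <- function(x) dim(x$counts)

.get_counts <- function(x) {
  if (inherits(x, "CountExperiment")) x$counts else as.matrix(x)
}

#' Median-of-ratios size factors
#'
#' The classic count-normalization estimator: each sample's factor is the
#' median, over reference loci, of its counts divided by the locus
#' geometric mean across samples. Factors are rescaled to geometric mean
#' one, so normalized counts stay on the raw-count scale.
#'
#' @param counts count matrix or `CountExperiment`.
#' @param pseudo_reference if no locus has all-positive counts, fall back
#'   to a reference built from positive counts only (off by default; the
#'   strict estimator errors instead, pointing here).
#' @return named numeric vector of positive per-sample size factors with
#'   geometric mean 1.
#' @export
median_of_ratios <- function(counts, pseudo_reference = FALSE) {
  m <- .get_counts(counts)
  if (ncol(m) < 2L) return(structure(rep(1, ncol(m)), names = colnames(m)))
  allpos <- rowSums(m > 0) == ncol(m)
  if (!any(allpos)) {
    if (!pseudo_reference)
      stopf(paste("no locus has positive counts in every sample;",
                  "consider pseudo_reference = TRUE"))
    somepos <- rowSums(m > 0) > 0
    lm_ <- log(m[somepos, , drop = FALSE])
    lm_[!is.finite(lm_)] <- NA
    ref <- exp(rowMeans(lm_, na.rm = TRUE))
    ratios <- m[somepos, , drop = FALSE] / ref
    s <- apply(ratios, 2, function(col) median(col[col > 0]))
  } else {
    sub <- m[allpos, , drop = FALSE]
    ref <- exp(rowMeans(log(sub)))
    s <- apply(sub / ref, 2, median)
  }
  s <- s / exp(mean(log(s)))
  names(s) <- colnames(m)
  s
}

#' TMM size factors
#'
#' Trimmed mean of M-values normalization (default trims: 30% on M, 5% on
#' A, precision weighting), computed with edgeR and converted to
#' per-sample size factors (effective library sizes rescaled to geometric
#' mean one), so they are interchangeable with [median_of_ratios()]
#' output.
#'
#' @param counts count matrix or `CountExperiment`.
#' @param ref optional reference column (index or name) passed to edgeR.
#' @return named numeric vector of size factors, geometric mean 1.
#' @export
tmm_factors <- function(counts, ref = NULL) {
  m <- .get_counts(counts)
  if (any(colSums(m) == 0)) stopf("a sample has zero total counts")
  if (is.character(ref)) ref <- match(ref, colnames(m))
  nf <- edgeR::calcNormFactors(m, method = "TMM", refColumn = ref)
  s <- colSums(m) * nf
  s <- s / exp(mean(log(s)))
  names(s) <- colnames(m)
  s
}

#' Expression filter for the fold-change analyses
#'
#' Keeps a locus only if it has at least one raw read in at least one
#' sample of each sex and a base mean (mean normalized count, using
#' median-of-ratios factors) of at least one.
#'
#' @param ce a `CountExperiment`.
#' @param size_factors optional precomputed size factors used for the
#'   base mean; defaults to [median_of_ratios()] on the counts.
#' @return named logical vector (`TRUE` = kept), with the per-locus base
#'   means attached as attribute `base_mean`.
#' @export
filter_expressed <- function(ce, size_factors = NULL) {
  stopifnot(inherits(ce, "CountExperiment"))
  sex <- ce$samples$sex
  if (!all(c("male", "female") %in% sex))
    stopf("both sexes must be present")
  if (is.null(size_factors))
    size_factors <- median_of_ratios(ce$counts, pseudo_reference = TRUE)
  norm <- sweep(ce$counts, 2, size_factors, "/")
  base_mean <- rowMeans(norm)
  keep <- rowSums(ce$counts[, sex == "male", drop = FALSE] > 0) > 0 &
    rowSums(ce$counts[, sex == "female", drop = FALSE] > 0) > 0 &
    base_mean >= 1
  names(keep) <- rownames(ce$counts)
  attr(keep, "base_mean") <- base_mean
  keep
}

#' Per-locus sex-effect fit under the batch + sex design
#'
#' Fits ordinary least squares to `y = log2(count / size_factor + 0.5)`
#' with an intercept, batch indicators (paired design only) and a sex
#' indicator. The reported `log2fc` is the sex coefficient, male minus
#' female, so positive values are male-biased.
#'
#' @param ce a `CountExperiment`.
#' @param size_factors per-sample size factors.
#' @param design `"paired"` (includes batch indicators) or `"unpaired"`.
#' @return data.frame with one row per locus: `locus`, `log2fc`, `se`,
#'   `sigma2` (residual variance), `df` (residual df); attribute
#'   `v_unscaled` holds the design-dependent unscaled coefficient
#'   variance.
#' @export
fit_sex_model <- function(ce, size_factors,
                          design = c("paired", "unpaired")) {
  stopifnot(inherits(ce, "CountExperiment"))
  design <- match.arg(design)
  sex <- factor(ce$samples$sex, levels = c("female", "male"))
  if (nlevels(droplevels(sex)) < 2L) stopf("both sexes required")
  if (design == "paired") {
    batch <- factor(ce$samples$batch)
    X <- stats::model.matrix(~ batch + sex)
  } else {
    X <- stats::model.matrix(~sex)
  }
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    if (design == "paired" &&
        !any(rowSums(table(ce$samples$batch, sex) > 0) == 2))
      stopf("sex is confounded with batch: no batch contains both sexes")
    stopf("rank-deficient design matrix")
  }
  n <- nrow(X)
  dfres <- n - qx$rank
  if (dfres < 1L)
    stopf("no residual degrees of freedom (n = %d, parameters = %d)",
          n, qx$rank)
  y <- log2(sweep(ce$counts, 2, size_factors, "/") + 0.5)
  fit <- lm.fit(X, t(y))
  co <- if (is.matrix(fit$coefficients)) fit$coefficients else
    matrix(fit$coefficients, ncol = 1,
           dimnames = list(names(fit$coefficients), rownames(y)))
  log2fc <- co["sexmale", ]
  res <- fit$residuals
  if (!is.matrix(res)) res <- matrix(res, ncol = nrow(y))
  sigma2 <- colSums(res^2) / dfres
  xtxinv <- chol2inv(qr.R(qx))
  v <- xtxinv[ncol(X), ncol(X)]   # sex is the last column
  out <- data.frame(locus = rownames(y), log2fc = unname(log2fc),
                    se = sqrt(sigma2 * v), sigma2 = unname(sigma2),
                    df = dfres, stringsAsFactors = FALSE)
  attr(out, "v_unscaled") <- v
  attr(out, "design") <- design
  out
}

# Newton inversion of the trigamma function (for the prior-df moment fit)
trigamma_inverse <- function(y) {
  if (!is.finite(y) || y <= 0) return(Inf)
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in 1:50) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, 2)
    x <- x + dif
    if (abs(dif / x) < 1e-10) break
  }
  x
}

#' Empirical-Bayes moderated t test
#'
#' Pools the per-locus residual variances: a scaled inverse chi-square
#' prior (d0, s0^2) is estimated by method of moments on the log
#' variances, each posterior variance is
#' `(d0 * s0^2 + df * s2) / (d0 + df)`, and the moderated t statistic
#' `log2fc / sqrt(s2_post * v)` is referred to a t distribution with
#' `d0 + df` degrees of freedom.
#'
#' @param fit output of [fit_sex_model()].
#' @param prior_df optional fixed prior df `d0` (overrides estimation);
#'   `0` reproduces the ordinary t test, `Inf` uses the pooled variance
#'   for every locus.
#' @param var_floor minimum residual variance (guards the all-zero
#'   variance corner), default `1e-8`.
#' @return `fit` with columns `t` and `p` added and attributes `d0`,
#'   `s02`.
#' @export
moderated_test <- function(fit, prior_df = NULL, var_floor = 1e-8) {
  d <- fit$df[1]
  s2 <- pmax(fit$sigma2, var_floor)
  v <- attr(fit, "v_unscaled")
  z <- log(s2)
  e <- z - digamma(d / 2) + log(d / 2)
  emean <- mean(e)
  if (is.null(prior_df)) {
    target <- var(e) - trigamma(d / 2)
    d0 <- if (is.na(target) || target <= 0) Inf else 2 * trigamma_inverse(target)
  } else {
    d0 <- prior_df
  }
  s02 <- if (is.finite(d0) && d0 > 0)
    exp(emean + digamma(d0 / 2) - log(d0 / 2)) else exp(emean)
  s2post <- if (is.infinite(d0)) rep(s02, length(s2)) else
    (d0 * s02 + d * s2) / (d0 + d)
  s2post <- pmax(s2post, var_floor)
  tt <- fit$log2fc / sqrt(s2post * v)
  dft <- d0 + d
  fit$t <- tt
  fit$p <- 2 * pt(-abs(tt), df = dft)
  attr(fit, "d0") <- d0
  attr(fit, "s02") <- s02
  fit
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment: `q_i = min over p_j >= p_i of m * p_j /
#' rank_j`, clipped at 1. `NA` p-values propagate as `NA` and do not
#' count toward `m`.
#'
#' @param p numeric vector of p-values in `[0, 1]` (NA allowed).
#' @return numeric vector of q-values, same length and order.
#' @export
bh_adjust <- function(p) {
  q <- rep(NA_real_, length(p))
  ok <- which(!is.na(p))
  if (!length(ok)) return(q)
  pv <- p[ok]
  if (any(pv < 0 | pv > 1)) stopf("p-values must lie in [0, 1]")
  m <- length(pv)
  o <- order(pv, decreasing = TRUE)
  q[ok[o]] <- pmin(1, cummin(m / (m:1) * pv[o]))
  q
}

#' Call sex-biased loci
#'
#' A locus is male-biased when `q < fdr` and `log2fc >= log2(min_fc)`,
#' female-biased when `q < fdr` and `log2fc <= -log2(min_fc)`, otherwise
#' unbiased. The defaults implement an FDR of 10% with an expression
#' difference of at least 25% (fold-change 1.25, boundary inclusive).
#'
#' @param res data.frame with columns `q` and `log2fc`.
#' @param fdr FDR threshold, default 0.10.
#' @param min_fc minimal fold-change on the natural scale, default 1.25.
#' @return `res` with a `biased` column (`"none"`, `"male"`, `"female"`).
#' @export
call_sex_biased <- function(res, fdr = 0.10, min_fc = 1.25) {
  stopifnot(all(c("q", "log2fc") %in% names(res)))
  lfc <- log2(min_fc)
  biased <- rep("none", nrow(res))
  sig <- !is.na(res$q) & res$q < fdr
  biased[sig & res$log2fc >= lfc] <- "male"
  biased[sig & res$log2fc <= -lfc] <- "female"
  res$biased <- biased
  res
}

#' Full differential-expression analysis for one species
#'
#' Normalizes, filters, fits the batch + sex model, moderates, adjusts
#' and calls sex bias in one step.
#'
#' @param ce a `CountExperiment`.
#' @param design `"paired"` or `"unpaired"` (see [fit_sex_model()]).
#' @param norm `"mor"` (median of ratios) or `"tmm"`; the base-mean
#'   filter always uses median-of-ratios factors.
#' @param fdr,min_fc thresholds for [call_sex_biased()].
#' @param var_floor see [moderated_test()].
#' @return data.frame of class `dge_result` with columns `locus`,
#'   `base_mean`, `log2fc`, `se`, `p`, `q`, `biased` for the loci passing
#'   [filter_expressed()]; the number filtered out is attached as
#'   attribute `n_filtered`.
#' @export
run_dge <- function(ce, design = c("paired", "unpaired"),
                    norm = c("mor", "tmm"), fdr = 0.10, min_fc = 1.25,
                    var_floor = 1e-8) {
  design <- match.arg(design)
  norm <- match.arg(norm)
  sf_mor <- median_of_ratios(ce$counts, pseudo_reference = TRUE)
  sf <- if (norm == "mor") sf_mor else tmm_factors(ce$counts)
  keep <- filter_expressed(ce, size_factors = sf_mor)
  base_mean <- attr(keep, "base_mean")
  sub <- count_experiment(ce$counts[keep, , drop = FALSE], ce$samples)
  fit <- fit_sex_model(sub, sf, design = design)
  fit <- moderated_test(fit, var_floor = var_floor)
  fit$q <- bh_adjust(fit$p)
  fit <- call_sex_biased(fit, fdr = fdr, min_fc = min_fc)
  out <- data.frame(locus = fit$locus, base_mean = base_mean[keep],
                    log2fc = fit$log2fc, se = fit$se, p = fit$p, q = fit$q,
                    biased = fit$biased, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "n_filtered") <- sum(!keep)
  attr(out, "d0") <- attr(fit, "d0")
  class(out) <- c("dge_result", "data.frame")
  out
}
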