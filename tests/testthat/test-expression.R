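# Normalization, the batch+sex model, moderation, BH, bias calling.

toy_ce <- function(counts, sex = NULL, batch = NULL) {
  ns <- ncol(counts)
  if (is.null(sex)) sex <- rep(c("male", "female"), length.out = ns)
  if (is.null(batch)) batch <- rep(1, ns)
  if (is.null(rownames(counts)))
    rownames(counts) <- sprintf("L%03d", seq_len(nrow(counts)))
  if (is.null(colnames(counts)))
    colnames(counts) <- sprintf("s%d", seq_len(ns))
  count_experiment(counts,
                   data.frame(sample = colnames(counts), sex = sex,
                              batch = batch))
}

test_that("median-of-ratios factors follow the definition", {
  m <- matrix(c(10, 20, 30, 10, 20, 30), ncol = 2,
              dimnames = list(letters[1:3], c("s1", "s2")))
  expect_equal(unname(median_of_ratios(m)), c(1, 1))

  m2 <- cbind(s1 = c(10, 20, 30), s2 = c(20, 40, 60))
  rownames(m2) <- letters[1:3]
  expect_equal(unname(median_of_ratios(m2)), c(1 / sqrt(2), sqrt(2)),
               tolerance = 1e-12)

  # loci with any zero are excluded from the reference set: the zero row
  # would otherwise drag s2's median down
  m3 <- rbind(m2, d = c(1000, 0))
  expect_equal(unname(median_of_ratios(m3)), c(1 / sqrt(2), sqrt(2)),
               tolerance = 1e-12)

  # no all-positive locus: error mentioning the fallback
  m4 <- cbind(s1 = c(1, 0), s2 = c(0, 1))
  rownames(m4) <- c("a", "b")
  expect_error(median_of_ratios(m4), "pseudo_reference")
  expect_silent(median_of_ratios(m4, pseudo_reference = TRUE))
})

test_that("median-of-ratios agrees with the DESeq2 estimator", {
  skip_if_not_installed("DESeq2")
  set.seed(5)
  m <- matrix(rnbinom(600, mu = 100, size = 5), ncol = 6)
  rownames(m) <- sprintf("g%d", 1:100)
  colnames(m) <- sprintf("s%d", 1:6)
  ours <- median_of_ratios(m)
  ref <- DESeq2::estimateSizeFactorsForMatrix(m)
  ref <- ref / exp(mean(log(ref)))
  # DESeq2 takes the median on the log scale; with an even reference set
  # the two medians differ by the arithmetic/geometric mean of the two
  # middle ratios, hence the loose-ish tolerance
  expect_equal(unname(ours), unname(ref), tolerance = 1e-3)
})

test_that("size factors are scale-equivariant and TMM tracks a trimmed-mean oracle", {
  set.seed(9)
  m <- matrix(rnbinom(1200, mu = 50, size = 2) + 1, ncol = 4)
  rownames(m) <- sprintf("g%d", 1:300); colnames(m) <- sprintf("s%d", 1:4)
  m2 <- m; m2[, 2] <- m2[, 2] * 4
  gain <- function(fun) {
    s0 <- fun(m); s1 <- fun(m2)
    unname((s1[2] / s0[2]) / (s1[1] / s0[1]))
  }
  # median of ratios: exactly equivariant (up to geometric-mean-1 rescale)
  expect_equal(gain(median_of_ratios), 4, tolerance = 1e-6)
  # TMM: near-equivariant only, because the inverse-variance weights
  # depend on absolute counts
  expect_equal(gain(function(x) tmm_factors(x, ref = 1)), 4,
               tolerance = 0.05)
  expect_equal(unname(tmm_factors(cbind(m[, 1], m[, 1]))), c(1, 1),
               tolerance = 1e-12)

  # unweighted 30% trimmed mean of M-values as a simplified oracle
  tmm <- tmm_factors(m, ref = 1)
  for (j in 2:4) {
    M <- log2((m[, j] / sum(m[, j])) / (m[, 1] / sum(m[, 1])))
    M <- M[is.finite(M)]
    keep <- M >= quantile(M, 0.3) & M <= quantile(M, 0.7)
    naive <- 2^mean(M[keep]) * sum(m[, j]) / sum(m[, 1])
    expect_equal(unname(tmm[j] / tmm[1]), naive, tolerance = 0.1)
  }
})

test_that("expression filter implements the per-sex presence and base-mean rules", {
  counts <- rbind(
    both      = c(5, 5, 5, 5),
    male_only = c(9, 9, 0, 0),
    low       = c(1, 1, 1, 1))
  ce <- toy_ce(counts, sex = c("male", "male", "female", "female"))
  sf <- rep(1, 4); names(sf) <- colnames(ce$counts)
  keep <- filter_expressed(ce, size_factors = sf)
  expect_true(keep[["both"]])
  expect_false(keep[["male_only"]])   # all-zero in females
  expect_true(keep[["low"]])          # base mean exactly 1 is kept

  counts2 <- rbind(boundary = c(1, 1, 1, 0), rich = c(50, 60, 70, 80))
  ce2 <- toy_ce(counts2, sex = c("male", "male", "female", "female"))
  keep2 <- filter_expressed(ce2, size_factors = sf)
  expect_false(keep2[["boundary"]])   # base mean 0.75 < 1
  expect_true(all(filter_expressed(
    toy_ce(matrix(1, 3, 4), sex = c("male", "male", "female", "female")),
    size_factors = sf)))
})

test_that("the sex model recovers planted fold-changes and has the stated symmetries", {
  # noise-free: female 512, male 1024 -> log2fc 1 up to pseudocount bias
  counts <- matrix(rep(c(1024, 1024, 512, 512), each = 5), nrow = 5)
  ce <- toy_ce(counts, sex = c("male", "male", "female", "female"),
               batch = c(1, 2, 1, 2))
  sf <- rep(1, 4); names(sf) <- colnames(ce$counts)
  fit <- fit_sex_model(ce, sf, design = "paired")
  expect_true(all(abs(fit$log2fc - 1) < 0.05))

  # label swap negates log2fc exactly
  ce_sw <- toy_ce(counts, sex = c("female", "female", "male", "male"),
                  batch = c(1, 2, 1, 2))
  fit_sw <- fit_sex_model(ce_sw, sf, design = "paired")
  expect_equal(fit_sw$log2fc, -fit$log2fc, tolerance = 1e-12)

  # a multiplicative batch shift leaves the paired log2fc unchanged
  counts_b <- counts
  counts_b[, c(2, 4)] <- counts_b[, c(2, 4)] * 4   # batch 2 shifted
  fit_b <- fit_sex_model(toy_ce(counts_b,
                                sex = c("male", "male", "female", "female"),
                                batch = c(1, 2, 1, 2)), sf, "paired")
  # exact up to the 0.5 pseudocount, which the shift dilutes slightly
  expect_equal(fit_b$log2fc, fit$log2fc, tolerance = 1e-3)

  # sex confounded with batch is rejected with a named cause
  expect_error(
    fit_sex_model(toy_ce(counts, sex = c("male", "male", "female", "female"),
                         batch = c(1, 1, 2, 2)), sf, "paired"),
    "confounded")
})

test_that("moderated t has the right limits and matches limma", {
  set.seed(21)
  counts <- matrix(rnbinom(200 * 6, mu = 200, size = 10), ncol = 6)
  ce <- toy_ce(counts, sex = rep(c("male", "female"), 3))
  sf <- median_of_ratios(ce$counts)
  fit <- fit_sex_model(ce, sf, design = "unpaired")

  # d0 = 0: ordinary t-test p-values
  f0 <- moderated_test(fit, prior_df = 0)
  t_ord <- fit$log2fc / fit$se
  expect_equal(f0$p, 2 * pt(-abs(t_ord), df = fit$df[1]), tolerance = 1e-12)

  # d0 = Inf: every locus uses the pooled prior variance s0^2
  finf <- moderated_test(fit, prior_df = Inf)
  t_pool <- fit$log2fc / sqrt(attr(finf, "s02") * attr(fit, "v_unscaled"))
  expect_equal(finf$t, t_pool, tolerance = 1e-12)

  skip_if_not_installed("limma")
  y <- log2(sweep(ce$counts, 2, sf, "/") + 0.5)
  design <- stats::model.matrix(~ factor(ce$samples$sex,
                                         levels = c("female", "male")))
  lf <- limma::eBayes(limma::lmFit(y, design))
  fm <- moderated_test(fit)
  expect_equal(attr(fm, "d0"), lf$df.prior, tolerance = 1e-6)
  expect_equal(fm$p, lf$p.value[, 2], tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("BH adjustment matches the hand example, the step-up formula, and p.adjust", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.42), 0.42)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  set.seed(2)
  p <- runif(100)
  expect_equal(bh_adjust(p), p.adjust(p, "BH"), tolerance = 1e-14)
  # NA propagation: NA excluded from m
  p2 <- c(0.01, NA, 0.04)
  q2 <- bh_adjust(p2)
  expect_true(is.na(q2[2]))
  expect_equal(q2[c(1, 3)], p.adjust(p2, "BH")[c(1, 3)], tolerance = 1e-14)
})

test_that("sex-bias calls apply the FDR and 25% fold-change rule inclusively", {
  res <- data.frame(
    q = c(0.05, 0.05, 0.15, 0.05, 0.05),
    log2fc = c(0.40, 0.25, 2.0, -0.40, log2(1.25)))
  out <- call_sex_biased(res)
  expect_equal(out$biased,
               c("male", "none", "none", "female", "male"))
})

test_that("model fold-changes agree with a naive normalized-mean estimator", {
  set.seed(31)
  cfg <- simulation_config(seed = 77, n_loci = 150)
  ann <- simulate_annotation(cfg)
  ce <- simulate_counts(ann, cfg, "dps")
  sf <- median_of_ratios(ce$counts)
  fit <- fit_sex_model(ce, sf, design = "paired")
  norm <- sweep(ce$counts, 2, sf, "/")
  male <- ce$samples$sex == "male"
  naive <- log2(rowMeans(norm[, male]) + 0.5) -
    log2(rowMeans(norm[, !male]) + 0.5)
  expect_gt(cor(fit$log2fc, naive), 0.95)
})
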