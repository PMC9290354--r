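# The synthetic-data generator: determinism, planted truth, geometry,
# sequence divergence, NB marginals.

test_that("identical configs give identical annotations, sequences and counts", {
  cfg <- simulation_config(seed = 42, translocation_count = 2)
  a1 <- simulate_annotation(cfg)
  a2 <- simulate_annotation(cfg)
  expect_identical(a1, a2)
  s1 <- simulate_sequences(a1, cfg)
  s2 <- simulate_sequences(a2, cfg)
  expect_identical(as.character(s1$species2), as.character(s2$species2))
  c1 <- simulate_counts(a1, cfg, "dps")
  c2 <- simulate_counts(a2, cfg, "dps")
  expect_identical(c1$counts, c2$counts)
  # different seed changes the draw
  c3 <- simulate_counts(a1, simulation_config(seed = 43,
                                              translocation_count = 2), "dps")
  expect_false(identical(c1$counts, c3$counts))
})

test_that("planted translocations are exactly recovered from the truth tables", {
  for (k in c(0L, 3L)) {
    cfg <- simulation_config(seed = 7, translocation_count = k,
                             n_loci = 100)
    ann <- simulate_annotation(cfg)
    expect_equal(sum(ann$truth$orthologs$translocated), k)
    # build the ortholog table from the annotations and re-detect
    m1 <- stats::setNames(ann$species1$muller, ann$species1$id)
    m2 <- stats::setNames(ann$species2$muller, ann$species2$id)
    orth <- data.frame(id1 = ann$truth$orthologs$id1,
                       id2 = ann$truth$orthologs$id2,
                       muller1 = unname(m1[ann$truth$orthologs$id1]),
                       muller2 = unname(m2[ann$truth$orthologs$id2]),
                       stringsAsFactors = FALSE)
    rep_ <- detect_translocations(orth)
    expect_equal(nrow(rep_$discordant), as.integer(k))
    expect_equal(rep_$n_pairs, nrow(orth))
  }
})

test_that("novel loci exist in species 2 only and fractions are honored", {
  cfg <- simulation_config(seed = 9, n_loci = 200, frac_novel = 0.25)
  ann <- simulate_annotation(cfg)
  expect_equal(nrow(ann$species2), 200L)
  expect_equal(sum(ann$species2$age_class == "novel"), 50L)
  expect_equal(nrow(ann$species1), 150L)
  expect_true(all(ann$species1$age_class == "conserved"))
  # every species-2 locus appears exactly once in the truth effects
  eff2 <- ann$truth$effects[ann$truth$effects$species == "dps", ]
  expect_setequal(eff2$id, ann$species2$id)
  expect_equal(anyDuplicated(eff2$id), 0L)
})

test_that("planted clusters obey the 10-kb rule and are exactly re-called", {
  cfg <- simulation_config(seed = 23, n_loci = 80, n_clusters = 10)
  ann <- simulate_annotation(cfg)
  for (sp in c("species1", "species2")) {
    code <- if (sp == "species1") "dme" else "dps"
    called <- call_clusters(ann[[sp]], gap_bp = 10000)
    truth <- ann$truth$clusters[ann$truth$clusters$species == code, ]
    called <- called[order(called$id), ]
    truth <- truth[match(called$id, truth$id), ]
    expect_true(same_partition(called$cluster, truth$cluster))
  }
})

test_that("infeasible cluster geometry is rejected", {
  expect_error(simulate_annotation(simulation_config(n_loci = 10,
                                                     n_clusters = 8)),
               "infeasible")
  expect_error(simulation_config(intercluster_gap_bp = 5000), "10000")
  expect_error(simulation_config(frac_novel = 1.2), "frac_novel")
  expect_error(simulation_config(nb_dispersion = 0), "positive")
})

test_that("ortholog sequences diverge at the planted substitution rate", {
  cfg0 <- simulation_config(seed = 5, substitution_rate = 0)
  ann <- simulate_annotation(cfg0)
  s0 <- simulate_sequences(ann, cfg0)
  orth <- ann$truth$orthologs
  expect_identical(unname(as.character(s0$species1[orth$id1])),
                   unname(as.character(s0$species2[orth$id2])))

  # rate 0.05 per lineage: per-site mismatch probability is
  # 1 - [(1-r)^2 + r^2/3] (two independent lineages; convergent hits
  # cancel a 1/3 of double mutations)
  cfg <- simulation_config(seed = 6, substitution_rate = 0.05,
                           n_loci = 250, frac_novel = 0, n_clusters = 0)
  ann2 <- simulate_annotation(cfg)
  sq <- simulate_sequences(ann2, cfg)
  orth2 <- ann2$truth$orthologs[1:200, ]
  r <- 0.05
  p_mm <- 1 - ((1 - r)^2 + r^2 / 3)
  total_mm <- 0; total_sites <- 0
  for (k in seq_len(nrow(orth2))) {
    a <- strsplit(as.character(sq$species1[[orth2$id1[k]]]), "")[[1]]
    b <- strsplit(as.character(sq$species2[[orth2$id2[k]]]), "")[[1]]
    total_mm <- total_mm + sum(a != b)
    total_sites <- total_sites + length(a)
  }
  bounds <- qbinom(c(0.005, 0.995), total_sites, p_mm)
  expect_gte(total_mm, bounds[1])
  expect_lte(total_mm, bounds[2])

  expect_error(simulate_sequences(ann, simulation_config(
    substitution_rate = 0.5)), "homology signal")
})

test_that("an unpaired locus rarely reaches the pairing hit threshold", {
  set.seed(88)
  hits <- 0L
  for (i in 1:200) {
    s1 <- random_dna(100); s2 <- random_dna(100)
    a <- local_align(s1, s2, mode = "seeded")
    if (a$score > 0 && evalue(a$score, 100, 100) <= 0.1) hits <- hits + 1L
  }
  expect_lte(hits / 200, 0.05)
})

test_that("count marginals match negative-binomial moments", {
  # flat baseline so all loci of a sample share one mu; 10,000 loci give
  # tight Monte-Carlo bounds on mean and variance
  cfg <- simulation_config(seed = 31, n_loci = 10000, n_clusters = 0,
                           frac_novel = 0, conserved_effect_sd = 0,
                           baseline_log2_sd = 0, batch_effect_log2 = 0,
                           nb_dispersion = 0.2, mean_log_expression = 6)
  ann <- simulate_annotation(cfg)
  ce <- simulate_counts(ann, cfg, "dps")
  for (j in seq_len(ncol(ce$counts))) {
    x <- ce$counts[, j]
    mu_hat <- mean(x)
    v_expected <- mu_hat + mu_hat^2 * 0.2
    expect_equal(var(x), v_expected, tolerance = 0.1)
  }
})

test_that("sample metadata carries the paired design and gonad mode", {
  cfg <- simulation_config(seed = 3, n_replicates_per_sex = 3)
  ann <- simulate_annotation(cfg)
  ce <- simulate_counts(ann, cfg, "dps")
  expect_equal(ncol(ce$counts), 6L)
  tab <- table(ce$samples$batch, ce$samples$sex)
  expect_true(all(tab == 1))   # one male and one female per batch
  gon <- simulate_counts(ann, cfg, "dps", tissue = TRUE)
  expect_setequal(unique(gon$samples$tissue), c("testis", "ovary"))
  expect_true(all((gon$samples$tissue == "testis") ==
                    (gon$samples$sex == "male")))
})
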