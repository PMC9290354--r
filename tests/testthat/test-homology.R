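# Local alignment, E-values, similarity graph, distances, neighbor joining.

test_that("local alignment handles the elementary cases", {
  s <- strrep("ACGT", 25)
  a <- local_align(s, s, mode = "exhaustive")
  expect_equal(a$score, 100)
  expect_equal(a$identity, 1)
  expect_equal(c(a$q_start, a$q_end, a$s_start, a$s_end), c(1, 100, 1, 100))

  # disjoint alphabets: no positive-scoring cell
  expect_equal(local_align(strrep("A", 30), strrep("C", 30),
                           mode = "exhaustive")$score, 0)
  # empty sequence: score 0, no hit
  expect_equal(local_align("", "ACGT")$score, 0)
  # N matches nothing, including N
  expect_equal(local_align(strrep("N", 20), strrep("N", 20),
                           mode = "exhaustive")$score, 0)
})

test_that("exhaustive mode reproduces an independent Smith-Waterman oracle", {
  skip_if_not_installed("Biostrings")
  set.seed(101)
  for (i in 1:100) {
    n1 <- sample(20:120, 1); n2 <- sample(20:120, 1)
    s1 <- random_dna(n1)
    s2 <- if (i %% 2 == 0) mutate_dna(s1, 0.15) else random_dna(n2)
    mine <- local_align(s1, s2, mode = "exhaustive")$score
    ref <- biostrings_local_score(s1, s2)
    # Biostrings reports a negative score when no local alignment is
    # positive; ours reports 0
    expect_equal(mine, max(0, ref))
  }
})

test_that("seeded search never exceeds, and with a seed equals, the exhaustive score", {
  set.seed(202)
  for (i in 1:100) {
    s1 <- random_dna(sample(30:120, 1))
    s2 <- if (i %% 3 == 0) mutate_dna(s1, 0.08) else random_dna(sample(30:120, 1))
    seeded <- local_align(s1, s2, mode = "seeded", word_size = 10)
    full <- local_align(s1, s2, mode = "exhaustive")
    expect_lte(seeded$score, full$score)
    if (seeded$score > 0) expect_equal(seeded$score, full$score)
  }
})

test_that("E-value machinery rejects invalid schemes and is roughly calibrated", {
  # non-negative expected score: theory invalid
  expect_error(karlin_altschul(align_scoring(match = 3, mismatch = -1)),
               "non-negative")
  ka <- karlin_altschul()
  expect_gt(ka$lambda, 0)
  expect_gt(ka$K, 0)
  # identical sequences get a minuscule E-value
  expect_lt(evalue(100, 100, 100), 1e-30)
})

test_that("find_hits recovers planted orthologs and filters by length in genome-scan mode", {
  set.seed(303)
  n <- 60
  anc <- vapply(seq_len(n), function(i) random_dna(sample(70:120, 1)),
                character(1))
  q <- vapply(anc, mutate_dna, character(1), rate = 0.05)
  s <- vapply(anc, mutate_dna, character(1), rate = 0.05)
  names(q) <- sprintf("q%02d", seq_len(n))
  names(s) <- sprintf("s%02d", seq_len(n))
  hits <- find_hits(q, s, evalue_max = 0.1)
  planted <- paste0("q", sprintf("%02d", 1:n), "/s", sprintf("%02d", 1:n))
  found <- paste0(hits$query, "/", hits$subject)
  expect_gte(mean(planted %in% found), 0.99)

  # symmetry: reversing query and subject yields the same edge set
  rev <- find_hits(s, q, evalue_max = 0.1)
  expect_setequal(paste0(hits$query, "/", hits$subject),
                  paste0(rev$subject, "/", rev$query))

  # genome-scan mode drops alignments shorter than 60
  short <- c(a = random_dna(59))
  hit_any <- find_hits(short, c(b = unname(short)), genome_scan = TRUE,
                       min_aln_len = 60)
  expect_equal(nrow(hit_any), 0L)
  long <- c(a = random_dna(80))
  expect_gt(nrow(find_hits(long, c(b = unname(long)), genome_scan = TRUE,
                           min_aln_len = 60)), 0L)
})

test_that("random unrelated pairs rarely clear the genome-scan E-value threshold", {
  set.seed(404)
  n_hit <- 0L
  for (i in 1:500) {
    s1 <- random_dna(100); s2 <- random_dna(100)
    a <- local_align(s1, s2, mode = "seeded")
    if (a$score > 0 && evalue(a$score, 100, 100) <= 0.01) n_hit <- n_hit + 1L
  }
  expect_lt(n_hit / 500, 0.05)
})

test_that("similarity groups are connected components with correct classes", {
  ids1 <- c("a1", "a2", "a3")
  ids2 <- c("b1", "b2", "b3")
  no_hits <- data.frame(query = character(), subject = character())
  g0 <- build_groups(no_hits, ids1, ids2)
  expect_true(all(g0$class == "unpaired"))
  expect_equal(length(unique(g0$group)), 6L)

  # chain a1-b1, a2-b1: one one_to_many group
  chain <- data.frame(query = c("a1", "a2"), subject = c("b1", "b1"))
  g1 <- build_groups(chain, ids1, ids2)
  grp <- g1$group[g1$id == "b1"]
  expect_setequal(g1$id[g1$group == grp], c("a1", "a2", "b1"))
  expect_equal(unique(g1$class[g1$group == grp]), "one_to_many")

  # mir-92-like family: 2 copies vs 3 copies, all cross-similar
  f1 <- c("mirA-1", "mirA-2"); f2 <- c("mirB-1", "mirB-2", "mirB-3")
  full <- expand.grid(query = f1, subject = f2, stringsAsFactors = FALSE)
  gf <- build_groups(full, f1, f2)
  expect_equal(unique(gf$class), "many_to_many")
  expect_equal(length(unique(gf$group)), 1L)
  # strip every cross-edge of one species-2 copy: it becomes unpaired
  pruned <- full[full$subject != "mirB-3", ]
  gp <- build_groups(pruned, f1, f2)
  expect_equal(gp$class[gp$id == "mirB-3"], "unpaired")
})

test_that("components equal brute-force transitive closure on random graphs", {
  set.seed(77)
  for (i in 1:100) {
    n1 <- sample(3:8, 1); n2 <- sample(3:8, 1)
    ids1 <- sprintf("x%d", seq_len(n1)); ids2 <- sprintf("y%d", seq_len(n2))
    n_edges <- sample(0:10, 1)
    hits <- data.frame(query = sample(ids1, n_edges, replace = TRUE),
                       subject = sample(ids2, n_edges, replace = TRUE),
                       stringsAsFactors = FALSE)
    got <- build_groups(hits, ids1, ids2)
    ref <- closure_components(c(ids1, ids2),
                              as.matrix(hits[, c("query", "subject")]))
    expect_true(same_partition(got$group[match(c(ids1, ids2), got$id)],
                               ref))
  }
})

test_that("uncorrected distances count mismatches over gap-free columns", {
  expect_equal(uncorrected_distance("ACGTACGT", "ACGTACGT"), 0)
  expect_equal(uncorrected_distance("AAAA", "TTTT"), 1)
  # 3 mismatches planted in 60 positions: d = 0.05
  s <- strrep("ACGTAC", 10)
  v <- strsplit(s, "")[[1]]
  v[c(7, 25, 49)] <- c("T", "G", "C")
  expect_equal(uncorrected_distance(s, paste(v, collapse = "")), 0.05)
  expect_error(uncorrected_distance("AAAA", ""), "aligned")
})

test_that("neighbor joining solves n=3 exactly and recovers additive trees", {
  d3 <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3, 3,
               dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  nwk <- write_newick(neighbor_joining(d3))
  # closed form: la = (3+4-5)/2 = 1, lb = (3+5-4)/2 = 2, lc = (4+5-3)/2 = 3
  expect_equal(nwk, "(a:1,b:2,c:3);")

  # zero matrix: star with zero lengths
  dz <- matrix(0, 3, 3, dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  expect_equal(write_newick(neighbor_joining(dz)), "(a:0,b:0,c:0);")

  # additive 5-taxon matrix: recovered exactly (checked via path lengths)
  skip_if_not_installed("ape")
  ref <- ape::read.tree(text = "((a:1,b:2):1.5,(c:0.5,d:1):2,e:3);")
  dmat <- ape::cophenetic.phylo(ref)
  dmat <- dmat[order(rownames(dmat)), order(colnames(dmat))]
  tr <- neighbor_joining(dmat)
  back <- ape::read.tree(text = write_newick(tr))
  dback <- ape::cophenetic.phylo(back)
  dback <- dback[rownames(dmat), colnames(dmat)]
  expect_equal(dback, dmat, tolerance = 1e-10)

  expect_error(neighbor_joining(matrix(c(0, 1, 2, 0), 2, 2,
                                       dimnames = list(c("a", "b"),
                                                       c("a", "b")))),
               "symmetric")
})

test_that("canonical newick writing is stable and round-trips through ape", {
  skip_if_not_installed("ape")
  expect_equal(write_newick("solo"), "solo;")
  set.seed(55)
  for (i in 1:10) {
    n <- sample(4:8, 1)
    labs <- sort(sprintf("t%d", sample(100, n)))
    # random additive tree -> distances -> NJ -> newick -> ape -> distances
    d <- as.matrix(stats::dist(matrix(runif(n * 3), n)))
    dimnames(d) <- list(labs, labs)
    tr <- neighbor_joining(d)
    nwk <- write_newick(tr)
    parsed <- ape::read.tree(text = nwk)
    expect_setequal(parsed$tip.label, labs)
    # serialization is canonical: writing twice gives identical strings
    expect_identical(write_newick(tr), nwk)
  }
})
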