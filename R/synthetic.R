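# Seeded generator of two-species microRNA study data: annotations with
# Muller elements and clustered loci, divergent hairpin sequences for
# ortholog pairs, and negative-binomial count matrices with sex, batch
# and library-size effects. All randomness flows from the config seed
# (stage-specific seeds are derived from it), so identical configs give
# identical output.

.default_muller <- function() {
  list(
    chromosomes = data.frame(
      element = c("A", "B", "C", "D", "E", "F"),
      species1 = c("X", "2L", "2R", "3L", "3R", "4"),
      species2 = c("XL", "4", "3", "XR", "2", "5"),
      stringsAsFactors = FALSE),
    x_linked = list(species1 = "A", species2 = c("A", "D")))
}

#' Configuration of the synthetic two-species study
#'
#' Defaults emulate a small paired small-RNA study: two replicates per
#' sex sequenced in two batches (one male and one female per batch),
#' ~120 loci of which a quarter are lineage-specific ("novel", species 2
#' only), clustered loci obeying the 10-kb rule, hairpins of 60-150 nt
#' diverged at 5% per site per lineage, and NB counts with a global
#' dispersion of 0.1. `sex_effect_log2` is the planted log2(male/female)
#' effect given to novel loci on X-linked elements of species 2;
#' conserved ortholog pairs share a true effect drawn with spread
#' `conserved_effect_sd`.
#'
#' @param seed integer RNG seed (< 2^31 - 100).
#' @param n_loci number of species-2 loci (species 1 gets the conserved
#'   subset).
#' @param n_clusters number of multi-locus clusters.
#' @param muller_elements list with a `chromosomes` data.frame (columns
#'   `element`, `species1`, `species2`) and `x_linked` element sets per
#'   species; default: six elements A-F with a species-2 neo-X on D.
#' @param frac_novel proportion of species-2 loci that are
#'   lineage-specific.
#' @param frac_x probability that a locus (cluster) sits on an X-linked
#'   element of species 2.
#' @param sex_effect_log2 planted log2(male/female) effect for novel
#'   X-linked loci.
#' @param novel_effect_log2 planted log2(male/female) effect for novel
#'   loci generally (novel X-linked loci use the stronger
#'   `sex_effect_log2` instead), emulating the general male bias of
#'   evolutionarily young microRNAs.
#' @param batch_effect_log2 additive log2 shift applied to batches after
#'   the first.
#' @param nb_dispersion global NB dispersion (`var = mu + mu^2 *
#'   dispersion`), > 0.
#' @param mean_log_expression mean of the per-locus baseline on the log2
#'   scale.
#' @param n_replicates_per_sex samples per sex (= number of batches in
#'   the paired layout).
#' @param translocation_count ortholog pairs planted on discordant
#'   Muller elements.
#' @param substitution_rate per-site, per-lineage substitution
#'   probability; values >= 0.5 are rejected downstream.
#' @param cluster_span_bp upper bound for the gap drawn between
#'   clustered neighbours (kept well under 10 kb).
#' @param intercluster_gap_bp minimal gap between clusters, must exceed
#'   10000.
#' @param conserved_effect_sd spread of the shared true effect of
#'   conserved pairs.
#' @param baseline_log2_sd per-locus baseline spread (dynamic range).
#' @return validated list of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L, n_loci = 120L, n_clusters = 8L,
                              muller_elements = .default_muller(),
                              frac_novel = 0.25, frac_x = 0.3,
                              sex_effect_log2 = 1.5,
                              novel_effect_log2 = 1.0,
                              batch_effect_log2 = 0.5,
                              nb_dispersion = 0.1,
                              mean_log_expression = 6,
                              n_replicates_per_sex = 2L,
                              translocation_count = 0L,
                              substitution_rate = 0.05,
                              cluster_span_bp = 2000L,
                              intercluster_gap_bp = 50000L,
                              conserved_effect_sd = 1.0,
                              baseline_log2_sd = 1.5) {
  seed <- assert_count(seed, "seed", lower = 0L)
  if (seed > 2^31 - 100) stopf("'seed' too large for a 32-bit integer")
  n_loci <- assert_count(n_loci, "n_loci", lower = 1L)
  n_clusters <- assert_count(n_clusters, "n_clusters", lower = 0L)
  assert_number(frac_novel, "frac_novel", 0, 1)
  assert_number(frac_x, "frac_x", 0, 1)
  assert_number(nb_dispersion, "nb_dispersion")
  if (nb_dispersion <= 0) stopf("'nb_dispersion' must be positive")
  assert_number(substitution_rate, "substitution_rate", 0, 1)
  n_replicates_per_sex <- assert_count(n_replicates_per_sex,
                                       "n_replicates_per_sex", lower = 1L)
  translocation_count <- assert_count(translocation_count,
                                      "translocation_count", lower = 0L)
  intercluster_gap_bp <- assert_count(intercluster_gap_bp,
                                      "intercluster_gap_bp")
  if (intercluster_gap_bp <= 10000)
    stopf("'intercluster_gap_bp' must exceed 10000 (the cluster rule)")
  cluster_span_bp <- assert_count(cluster_span_bp, "cluster_span_bp",
                                  lower = 1L)
  stopifnot(is.list(muller_elements),
            is.data.frame(muller_elements$chromosomes))
  structure(list(
    seed = seed, n_loci = n_loci, n_clusters = n_clusters,
    muller_elements = muller_elements, frac_novel = frac_novel,
    frac_x = frac_x, sex_effect_log2 = sex_effect_log2,
    novel_effect_log2 = novel_effect_log2,
    batch_effect_log2 = batch_effect_log2, nb_dispersion = nb_dispersion,
    mean_log_expression = mean_log_expression,
    n_replicates_per_sex = n_replicates_per_sex,
    translocation_count = translocation_count,
    substitution_rate = substitution_rate,
    cluster_span_bp = cluster_span_bp,
    intercluster_gap_bp = intercluster_gap_bp,
    conserved_effect_sd = conserved_effect_sd,
    baseline_log2_sd = baseline_log2_sd),
    class = "simulation_config")
}

#' Simulate the two species' locus annotations and the ground truth
#'
#' Places loci on named chromosomes with Muller labels. Clustered loci
#' are separated by well under 10 kb, clusters and singletons by more
#' than `intercluster_gap_bp`. Conserved loci appear in both species on
#' the same element (synteny), except `translocation_count` pairs whose
#' species-1 copy is moved to a different element. Novel loci exist in
#' species 2 only; novel loci on X-linked elements carry the planted
#' sex effect.
#'
#' @param config a [simulation_config()].
#' @return list with `species1` and `species2` annotation data.frames
#'   (see [read_annotation()] for columns) and `truth`, a list holding
#'   `effects` (species, id, true_log2_sex_effect), `orthologs` (id1,
#'   id2, translocated), `clusters` (species, id, cluster) and
#'   `translocations`.
#' @export
simulate_annotation <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  withr::local_seed(config$seed)
  n <- config$n_loci
  nc <- config$n_clusters
  if (2L * nc > n)
    stopf("infeasible geometry: %d clusters need at least %d loci, have %d",
          nc, 2L * nc, n)
  # cluster sizes 2-4, trimmed to fit
  sizes <- if (nc > 0) pmin(sample(2:4, nc, replace = TRUE),
                            floor(n / max(1, nc))) else integer(0)
  while (sum(sizes) > n) sizes[which.max(sizes)] <- sizes[which.max(sizes)] - 1L
  if (nc > 0 && any(sizes < 2L))
    stopf("infeasible geometry: clusters of size < 2 after trimming")
  n_clustered <- sum(sizes)
  n_single <- n - n_clustered

  mu <- config$muller_elements
  elements <- mu$chromosomes$element
  x2 <- mu$x_linked$species2
  non_x2 <- setdiff(elements, x2)
  n_units <- nc + n_single
  unit_is_x <- runif(n_units) < config$frac_x
  unit_elem <- ifelse(unit_is_x,
                      sample(x2, n_units, replace = TRUE),
                      sample(non_x2, n_units, replace = TRUE))

  # assign loci to units: clusters first, then singletons
  unit_of <- c(rep(seq_len(nc), times = sizes),
               if (n_single > 0) nc + seq_len(n_single))
  elem2 <- unit_elem[unit_of]

  n_conserved <- round(n * (1 - config$frac_novel))
  novel <- rep(TRUE, n)
  if (n_conserved > 0) novel[sample.int(n, n_conserved)] <- FALSE

  id2 <- character(n)
  id2[!novel] <- sprintf("dps-mir-%03d", seq_len(sum(!novel)))
  id2[novel] <- sprintf("dps-nov-%03d", seq_len(sum(novel)))
  id1 <- rep(NA_character_, n)
  id1[!novel] <- sprintf("dme-mir-%03d", seq_len(sum(!novel)))

  # planted translocations: conserved singleton pairs only, so cluster
  # synteny stays intact
  elem1 <- elem2
  trans_idx <- integer(0)
  if (config$translocation_count > 0) {
    cand <- which(!novel & unit_of[seq_len(n)] > nc)
    if (length(cand) < config$translocation_count)
      stopf("infeasible geometry: only %d conserved singleton pairs for %d translocations",
            length(cand), config$translocation_count)
    trans_idx <- sort(sample(cand, config$translocation_count))
    for (i in trans_idx)
      elem1[i] <- sample(setdiff(elements, elem2[i]), 1)
  }

  pair_len <- sample(60:150, n, replace = TRUE)

  chr_of <- function(elem, col) {
    mu$chromosomes[[col]][match(elem, mu$chromosomes$element)]
  }

  place_species <- function(keep, elem, ids, lens, units, col) {
    keep_idx <- which(keep)
    # deterministic layout: iterate elements, then units in index order
    rows <- list()
    for (el in unique(sort(elem[keep_idx]))) {
      sel <- keep_idx[elem[keep_idx] == el]
      cursor <- 10000L
      for (u in unique(units[sel])) {
        us <- sel[units[sel] == u]
        for (i in us) {
          st <- cursor
          en <- st + lens[i] - 1L
          rows[[length(rows) + 1L]] <- data.frame(
            id = ids[i], chromosome = chr_of(el, col), muller = el,
            start = st, end = en, stringsAsFactors = FALSE)
          cursor <- en + 1L + sample(200:config$cluster_span_bp, 1)
        }
        cursor <- cursor + config$intercluster_gap_bp +
          sample.int(5000L, 1)
      }
    }
    do.call(rbind, rows)
  }

  sp2 <- place_species(rep(TRUE, n), elem2, id2, pair_len, unit_of,
                       "species2")
  sp1 <- place_species(!novel, elem1, id1, pair_len, unit_of, "species1")

  finish <- function(df, species, age) {
    df$species <- species
    df$strand <- sample(c("+", "-"), nrow(df), replace = TRUE)
    df$age_class <- age[match(df$id, names(age))]
    df$multimapper <- FALSE
    .validate_annotation(df)
  }
  age2 <- stats::setNames(ifelse(novel, "novel", "conserved"), id2)
  age1 <- stats::setNames(rep("conserved", sum(!novel)), id1[!novel])
  ann2 <- finish(sp2, "dps", age2)
  ann1 <- finish(sp1, "dme", age1)

  # planted true effects
  eff2 <- numeric(n)
  shared <- rnorm(sum(!novel), 0, config$conserved_effect_sd)
  eff2[!novel] <- shared
  eff2[novel] <- config$novel_effect_log2
  eff2[novel & elem2 %in% x2] <- config$sex_effect_log2
  effects <- rbind(
    data.frame(species = "dme", id = id1[!novel],
               true_log2_sex_effect = shared, stringsAsFactors = FALSE),
    data.frame(species = "dps", id = id2,
               true_log2_sex_effect = eff2, stringsAsFactors = FALSE))

  orth <- data.frame(id1 = id1[!novel], id2 = id2[!novel],
                     translocated = (seq_len(n) %in% trans_idx)[!novel],
                     stringsAsFactors = FALSE)
  clusters <- rbind(
    data.frame(species = "dps", id = id2,
               cluster = paste0("u", unit_of), stringsAsFactors = FALSE),
    data.frame(species = "dme", id = id1[!novel],
               cluster = paste0("u", unit_of[!novel]),
               stringsAsFactors = FALSE))
  truth <- list(
    effects = effects,
    orthologs = orth,
    clusters = clusters,
    translocations = orth[orth$translocated, , drop = FALSE],
    pair_length = stats::setNames(pair_len, id2))
  list(species1 = ann1, species2 = ann2, truth = truth)
}

.random_seq <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

.mutate_seq <- function(seq, rate) {
  if (rate <= 0) return(seq)
  bases <- strsplit(seq, "")[[1]]
  hit <- runif(length(bases)) < rate
  if (any(hit)) {
    bases[hit] <- vapply(bases[hit], function(b)
      sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))
  }
  paste(bases, collapse = "")
}

#' Simulate hairpin sequences for both species
#'
#' Each ortholog pair descends from a common random ancestor hairpin
#' (the pair's annotated length, 60-150 nt) mutated independently in
#' each lineage at `substitution_rate` per site; unpaired (novel) loci
#' get unrelated random sequence of their annotated length. Base
#' composition is uniform (GC 0.5).
#'
#' @param annotation output of [simulate_annotation()].
#' @param config the same [simulation_config()].
#' @return list with `species1` and `species2` `DNAStringSet`s named by
#'   locus ID.
#' @export
simulate_sequences <- function(annotation, config) {
  stopifnot(inherits(config, "simulation_config"))
  if (config$substitution_rate >= 0.5)
    stopf("substitution_rate >= 0.5 destroys the homology signal by design")
  withr::local_seed(config$seed + 1L)
  truth <- annotation$truth
  orth <- truth$orthologs
  seqs1 <- character(0); seqs2 <- character(0)
  lens2 <- stats::setNames(annotation$species2$end -
                             annotation$species2$start + 1L,
                           annotation$species2$id)
  for (k in seq_len(nrow(orth))) {
    anc <- .random_seq(lens2[[orth$id2[k]]])
    seqs1[[orth$id1[k]]] <- .mutate_seq(anc, config$substitution_rate)
    seqs2[[orth$id2[k]]] <- .mutate_seq(anc, config$substitution_rate)
  }
  unpaired2 <- setdiff(annotation$species2$id, orth$id2)
  for (id in unpaired2) seqs2[[id]] <- .random_seq(lens2[[id]])
  unpaired1 <- setdiff(annotation$species1$id, orth$id1)
  lens1 <- stats::setNames(annotation$species1$end -
                             annotation$species1$start + 1L,
                           annotation$species1$id)
  for (id in unpaired1) seqs1[[id]] <- .random_seq(lens1[[id]])
  # order as annotated
  seqs1 <- seqs1[annotation$species1$id]
  seqs2 <- seqs2[annotation$species2$id]
  list(species1 = Biostrings::DNAStringSet(seqs1),
       species2 = Biostrings::DNAStringSet(seqs2))
}

#' Simulate a count experiment for one species
#'
#' Counts are drawn `NB(mu, dispersion)` with `log2 mu = baseline +
#' effect * male + batch_shift`, multiplied by a per-sample library-size
#' factor drawn log-uniformly in `[0.5, 2]` (so normalization is
#' exercised). The paired layout puts one male and one female in each
#' batch; batches after the first are shifted by `batch_effect_log2`.
#' In gonad mode the same loci effects apply to testis (male) versus
#' ovary (female) samples and the tissue column is set accordingly.
#'
#' @param annotation output of [simulate_annotation()].
#' @param config the [simulation_config()].
#' @param species `"dme"` (species 1) or `"dps"` (species 2).
#' @param tissue logical: gonad mode (testis/ovary) instead of whole
#'   body.
#' @return a [count_experiment()].
#' @export
simulate_counts <- function(annotation, config, species = c("dps", "dme"),
                            tissue = FALSE) {
  stopifnot(inherits(config, "simulation_config"))
  species <- match.arg(species)
  withr::local_seed(config$seed + 2L + (species == "dme") * 1L +
                      tissue * 4L)
  ann <- if (species == "dps") annotation$species2 else annotation$species1
  eff_tab <- annotation$truth$effects
  eff <- stats::setNames(eff_tab$true_log2_sex_effect, eff_tab$id)[ann$id]
  nrep <- config$n_replicates_per_sex
  sex <- rep(c("male", "female"), times = nrep)
  batch <- rep(seq_len(nrep), each = 2)
  sample_id <- sprintf("%s_%s_b%d", species, sex, batch)
  tis <- if (tissue) ifelse(sex == "male", "testis", "ovary") else "whole"
  nl <- nrow(ann); ns <- length(sex)
  baseline <- rnorm(nl, config$mean_log_expression, config$baseline_log2_sd)
  lib <- 2^runif(ns, -1, 1)
  male <- as.numeric(sex == "male")
  shift <- config$batch_effect_log2 * (batch - 1)
  log2mu <- outer(baseline, rep(0, ns), "+") +
    outer(eff, male) + matrix(shift, nl, ns, byrow = TRUE)
  mu <- sweep(2^log2mu, 2, lib, "*")
  counts <- matrix(rnbinom(nl * ns, mu = mu, size = 1 / config$nb_dispersion),
                   nl, ns, dimnames = list(ann$id, sample_id))
  count_experiment(counts, data.frame(sample = sample_id, sex = sex,
                                      tissue = tis, batch = batch,
                                      stringsAsFactors = FALSE))
}
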