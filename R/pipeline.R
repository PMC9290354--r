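# End-to-end orchestration: simulate -> dge -> homology -> clusters ->
# synteny -> srh -> report, with a single seed and a machine-readable
# run manifest.

#' Pipeline configuration
#'
#' Collects every stage threshold. Defaults are the analysis' standard
#' operating point: FDR 10% (5% as the stringent variant) with a 25%
#' minimal expression difference, word size 10 with pairing E-value 0.1
#' (genome scan: 0.01 and alignment length >= 60), and the 10-kb cluster
#' rule.
#'
#' @param seed integer seed driving all randomness.
#' @param sim optional [simulation_config()]; defaults to
#'   `simulation_config(seed = seed)`.
#' @param stages character vector of stages to run, a subset of
#'   `c("dge", "homology", "clusters", "synteny", "srh")` (simulation
#'   always runs; later stages require their dependencies).
#' @param design `"paired"` or `"unpaired"` (see [fit_sex_model()]).
#' @param norm `"mor"` or `"tmm"`.
#' @param fdr,fdr_strict,min_fc sex-bias call thresholds.
#' @param word_size,evalue_pair,evalue_genome,min_aln_len homology
#'   search parameters.
#' @param cluster_gap cluster merging gap in bp.
#' @param ortholog_overrides optional data.frame (`id1`, `id2`) of
#'   manually curated ortholog pairs added as graph edges.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, sim = NULL,
                            stages = c("dge", "homology", "clusters",
                                       "synteny", "srh"),
                            design = c("paired", "unpaired"),
                            norm = c("mor", "tmm"),
                            fdr = 0.10, fdr_strict = 0.05, min_fc = 1.25,
                            word_size = 10, evalue_pair = 0.1,
                            evalue_genome = 0.01, min_aln_len = 60,
                            cluster_gap = 10000,
                            ortholog_overrides = NULL) {
  for (nm in c("fdr", "fdr_strict", "min_fc", "word_size", "evalue_pair",
               "evalue_genome", "min_aln_len", "cluster_gap")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || v <= 0)
      stopf("'%s' must be a positive number", nm)
  }
  stages <- match.arg(stages, several.ok = TRUE)
  deps <- list(synteny = c("dge", "homology"), srh = "dge",
               clusters = "dge")
  for (st in intersect(names(deps), stages)) {
    missing_dep <- setdiff(deps[[st]], stages)
    if (length(missing_dep))
      stopf("stage '%s' requires stage(s): %s", st,
            paste(missing_dep, collapse = ", "))
  }
  structure(list(
    seed = assert_count(seed, "seed", lower = 0L),
    sim = sim %||% simulation_config(seed = seed),
    stages = stages,
    design = match.arg(design), norm = match.arg(norm),
    fdr = fdr, fdr_strict = fdr_strict, min_fc = min_fc,
    word_size = word_size, evalue_pair = evalue_pair,
    evalue_genome = evalue_genome, min_aln_len = min_aln_len,
    cluster_gap = cluster_gap,
    ortholog_overrides = ortholog_overrides),
    class = "pipeline_config")
}

.x_class <- function(muller, x_elements) {
  ifelse(muller_letter(muller) %in% x_elements, "X", "autosome")
}

#' Run the full synthetic-study pipeline
#'
#' Simulates the two-species study, then runs every requested stage and
#' writes per-stage TSVs, newick trees, a summary table and a JSON
#' manifest of all parameters under `out_dir`. Output is deterministic
#' given the config: rerunning with the same config yields byte-identical
#' files.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list with every intermediate object
#'   (annotations, truth, count experiments, dge tables, hits, groups,
#'   clusters, translocation report, bias pairs, fits, srh, summary).
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  save_tsv <- function(x, name) {
    p <- file.path(out_dir, name)
    write_tsv_table(x, p)
    paths <<- c(paths, name)
  }

  sim <- config$sim
  ann <- simulate_annotation(sim)
  seqs <- simulate_sequences(ann, sim)
  ce1 <- simulate_counts(ann, sim, species = "dme")
  ce2 <- simulate_counts(ann, sim, species = "dps")
  write_annotation(ann$species1, file.path(out_dir, "dme_annotation.gff3"))
  write_annotation(ann$species2, file.path(out_dir, "dps_annotation.gff3"))
  write_fasta(seqs$species1, file.path(out_dir, "dme_hairpins.fa"))
  write_fasta(seqs$species2, file.path(out_dir, "dps_hairpins.fa"))
  write_counts(ce1, file.path(out_dir, "dme_counts.tsv"),
               file.path(out_dir, "dme_samples.tsv"))
  write_counts(ce2, file.path(out_dir, "dps_counts.tsv"),
               file.path(out_dir, "dps_samples.tsv"))
  paths <- c(paths, "dme_annotation.gff3", "dps_annotation.gff3",
             "dme_hairpins.fa", "dps_hairpins.fa", "dme_counts.tsv",
             "dme_samples.tsv", "dps_counts.tsv", "dps_samples.tsv")
  save_tsv(ann$truth$effects, "truth_effects.tsv")
  save_tsv(ann$truth$orthologs, "truth_orthologs.tsv")
  save_tsv(ann$truth$clusters, "truth_clusters.tsv")

  bundle <- list(config = config, annotation = ann, sequences = seqs,
                 counts = list(dme = ce1, dps = ce2))
  st <- config$stages

  if ("dge" %in% st) {
    dge1 <- run_dge(ce1, design = config$design, norm = config$norm,
                    fdr = config$fdr, min_fc = config$min_fc)
    dge2 <- run_dge(ce2, design = config$design, norm = config$norm,
                    fdr = config$fdr, min_fc = config$min_fc)
    save_tsv(dge1, "dme_dge.tsv")
    save_tsv(dge2, "dps_dge.tsv")
    bundle$dge <- list(dme = dge1, dps = dge2)
  }

  if ("homology" %in% st) {
    hits <- find_hits(seqs$species1, seqs$species2,
                      word_size = config$word_size,
                      evalue_max = config$evalue_pair)
    if (!is.null(config$ortholog_overrides)) {
      ov <- config$ortholog_overrides
      extra <- data.frame(query = ov$id1, subject = ov$id2, score = NA_real_,
                          evalue = 0, aln_length = NA_integer_,
                          pident = NA_real_, q_start = NA_integer_,
                          q_end = NA_integer_, s_start = NA_integer_,
                          s_end = NA_integer_, stringsAsFactors = FALSE)
      hits <- rbind(hits, extra)
    }
    groups <- build_groups(hits, ann$species1$id, ann$species2$id)
    save_tsv(hits, "similarity_hits.tsv")
    save_tsv(groups, "homology_groups.tsv")
    # NJ trees on uncorrected distances for multi-member groups
    tree_dir <- file.path(out_dir, "trees")
    dir.create(tree_dir, showWarnings = FALSE)
    allseq <- c(as.character(seqs$species1), as.character(seqs$species2))
    trees <- list()
    for (g in unique(groups$group[groups$class != "unpaired"])) {
      ids <- groups$id[groups$group == g]
      if (length(ids) < 2L) next
      d <- distance_matrix(allseq[ids])
      tr <- neighbor_joining(d)
      nwk <- write_newick(tr, file.path(tree_dir, sprintf("group_%03d.nwk", g)))
      trees[[as.character(g)]] <- nwk
      paths <- c(paths, sprintf("trees/group_%03d.nwk", g))
    }
    bundle$hits <- hits
    bundle$groups <- groups
    bundle$trees <- trees
  }

  if ("clusters" %in% st) {
    cl1 <- call_clusters(ann$species1, gap_bp = config$cluster_gap)
    cl2 <- call_clusters(ann$species2, gap_bp = config$cluster_gap)
    bm1 <- stats::setNames(bundle$dge$dme$base_mean, bundle$dge$dme$locus)
    bm2 <- stats::setNames(bundle$dge$dps$base_mean, bundle$dge$dps$locus)
    reps1 <- collapse_clusters(
      cl1[cl1$id %in% names(bm1), , drop = FALSE], bm1)
    reps2 <- collapse_clusters(
      cl2[cl2$id %in% names(bm2), , drop = FALSE], bm2)
    save_tsv(cl1, "dme_clusters.tsv")
    save_tsv(cl2, "dps_clusters.tsv")
    save_tsv(reps1, "dme_cluster_representatives.tsv")
    save_tsv(reps2, "dps_cluster_representatives.tsv")
    bundle$clusters <- list(dme = cl1, dps = cl2,
                            representatives = list(dme = reps1, dps = reps2))
  }

  x2 <- config$sim$muller_elements$x_linked$species2
  neo_x <- setdiff(x2, config$sim$muller_elements$x_linked$species1)
  anc_x <- intersect(x2, config$sim$muller_elements$x_linked$species1)

  if ("synteny" %in% st) {
    g11 <- bundle$groups[bundle$groups$class == "one_to_one", , drop = FALSE]
    p1 <- g11[g11$species == 1L, c("group", "id")]
    p2 <- g11[g11$species == 2L, c("group", "id")]
    op <- merge(p1, p2, by = "group", suffixes = c("1", "2"))
    m1 <- stats::setNames(ann$species1$muller, ann$species1$id)
    m2 <- stats::setNames(ann$species2$muller, ann$species2$id)
    orth <- data.frame(id1 = op$id1, id2 = op$id2,
                       muller1 = unname(m1[op$id1]),
                       muller2 = unname(m2[op$id2]),
                       stringsAsFactors = FALSE)
    orth <- orth[order(orth$id1), , drop = FALSE]
    save_tsv(orth, "ortholog_pairs.tsv")
    rep_ <- detect_translocations(orth)
    save_tsv(data.frame(n_pairs = rep_$n_pairs,
                        n_concordant = rep_$n_concordant,
                        n_discordant = nrow(rep_$discordant),
                        n_excluded_unknown = rep_$n_excluded_unknown),
             "translocation_report.tsv")
    if (nrow(rep_$discordant))
      save_tsv(rep_$discordant, "translocation_discordant_pairs.tsv")
    bundle$ortholog_table <- orth
    bundle$translocations <- rep_

    pairs <- pair_ortholog_bias(bundle$groups, bundle$dge$dme,
                                bundle$dge$dps, ann$species2,
                                x_elements = anc_x,
                                neo_x_elements = neo_x)
    save_tsv(pairs, "ortholog_bias_pairs.tsv")
    fits <- list()
    for (grp in c("neo-X", "autosome")) {
      sub <- pairs[if (grp == "neo-X") pairs$chrom_class == "neo-X" else
        pairs$chrom_class != "neo-X", , drop = FALSE]
      fits[[grp]] <- tryCatch(
        linear_fit(sub$log2fc1, sub$log2fc2), error = function(e) NULL)
    }
    fit_rows <- do.call(rbind, lapply(names(fits), function(nm) {
      f <- fits[[nm]]
      if (is.null(f)) return(NULL)
      data.frame(stratum = nm, slope = f$slope, intercept = f$intercept,
                 r_squared = f$r_squared, p = f$p, n = f$n,
                 stringsAsFactors = FALSE)
    }))
    if (!is.null(fit_rows)) save_tsv(fit_rows, "conservation_fits.tsv")
    bundle$bias_pairs <- pairs
    bundle$conservation_fits <- fits
  }

  if ("srh" %in% st) {
    d2 <- bundle$dge$dps
    a2 <- ann$species2
    idx <- match(d2$locus, a2$id)
    age <- a2$age_class[idx]
    chrom <- .x_class(a2$muller[idx], x2)
    srh <- tryCatch(
      scheirer_ray_hare(d2$log2fc, age, chrom),
      error = function(e) {
        warnf("SRH stage skipped: %s", conditionMessage(e))
        NULL
      })
    if (!is.null(srh)) {
      srh_df <- as.data.frame(srh)
      srh_df$factor <- c("age_class", "chromosome",
                         "age_class:chromosome")[seq_len(nrow(srh_df))]
      save_tsv(srh_df[, c("factor", "df", "H", "p")], "srh.tsv")
    }
    bundle$srh <- srh
  }

  # summary of biased calls at both FDR thresholds, by stratum
  if ("dge" %in% st) {
    summarize <- function(dge, annot, label) {
      strict <- call_sex_biased(dge, fdr = config$fdr_strict,
                                min_fc = config$min_fc)
      idx <- match(dge$locus, annot$id)
      strat <- paste(annot$age_class[idx],
                     .x_class(annot$muller[idx], x2), sep = "/")
      data.frame(species = label,
                 stratum = c("all", sort(unique(strat))),
                 n_tested = c(nrow(dge), as.vector(table(strat)[sort(unique(strat))])),
                 male_biased = c(sum(dge$biased == "male"),
                                 vapply(sort(unique(strat)), function(s)
                                   sum(dge$biased == "male" & strat == s),
                                   numeric(1))),
                 female_biased = c(sum(dge$biased == "female"),
                                   vapply(sort(unique(strat)), function(s)
                                     sum(dge$biased == "female" & strat == s),
                                     numeric(1))),
                 biased_fdr_strict = c(sum(strict$biased != "none"),
                                       vapply(sort(unique(strat)), function(s)
                                         sum(strict$biased != "none" & strat == s),
                                         numeric(1))),
                 stringsAsFactors = FALSE)
    }
    summary_df <- rbind(summarize(bundle$dge$dme, ann$species1, "dme"),
                        summarize(bundle$dge$dps, ann$species2, "dps"))
    save_tsv(summary_df, "summary.tsv")
    bundle$summary <- summary_df
  }

  manifest <- list(
    parameters = list(
      seed = config$seed, design = config$design, norm = config$norm,
      fdr = config$fdr, fdr_strict = config$fdr_strict,
      min_fc = config$min_fc, word_size = config$word_size,
      evalue_pair = config$evalue_pair,
      evalue_genome = config$evalue_genome,
      min_aln_len = config$min_aln_len,
      cluster_gap = config$cluster_gap,
      stages = config$stages,
      simulation = config$sim[setdiff(names(config$sim), "muller_elements")]),
    files = sort(paths))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(bundle)
}
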