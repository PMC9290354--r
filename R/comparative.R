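# Genomic clustering of microRNA loci, cluster representatives,
# interchromosomal movement detection, and ortholog fold-change pairing.

#' Call microRNA clusters by the 10-kb rule
#'
#' Single-linkage clustering of loci along each chromosome: two loci
#' belong to the same cluster when a chain of loci connects them with
#' boundary gaps of at most `gap_bp`. The gap between two intervals is
#' `max(0, next_start - prev_end - 1)` (number of separating bases), and
#' a gap of exactly `gap_bp` still merges (inclusive reading of
#' "within").
#'
#' @param loci annotation data.frame of one species (see
#'   [read_annotation()]); must contain `id`, `chromosome`, `start`,
#'   `end`.
#' @param gap_bp maximal merging gap in bases, default 10000.
#' @return data.frame with the input loci (sorted by chromosome and
#'   start) plus a `cluster` column (`<chromosome>:<k>`).
#' @export
call_clusters <- function(loci, gap_bp = 10000) {
  stopifnot(all(c("id", "chromosome", "start", "end") %in% names(loci)))
  if (!is.null(loci$species) &&
      length(unique(stats::na.omit(loci$species))) > 1L)
    stopf("call_clusters expects loci of a single species")
  loci <- loci[order(loci$chromosome, loci$start, loci$end), , drop = FALSE]
  cluster <- character(nrow(loci))
  for (chr in unique(loci$chromosome)) {
    sel <- which(loci$chromosome == chr)
    k <- 1L
    run_end <- loci$end[sel[1]]
    cl <- integer(length(sel))
    cl[1] <- k
    for (ii in seq_along(sel)[-1]) {
      gap <- max(0, loci$start[sel[ii]] - run_end - 1)
      if (gap > gap_bp) k <- k + 1L
      cl[ii] <- k
      run_end <- max(run_end, loci$end[sel[ii]])
    }
    cluster[sel] <- paste0(chr, ":", cl)
  }
  loci$cluster <- cluster
  rownames(loci) <- NULL
  loci
}

#' Pick the representative locus of a cluster
#'
#' The highest expressed member (largest base mean); ties go to the
#' lexicographically smallest locus ID so the choice is deterministic.
#'
#' @param members character vector of member locus IDs.
#' @param base_mean named numeric vector of base means covering the
#'   members.
#' @return the representative locus ID.
#' @export
select_representative <- function(members, base_mean) {
  members <- as.character(members)
  bm <- base_mean[members]
  if (all(is.na(bm)))
    stopf("no expression value for any cluster member")
  bm[is.na(bm)] <- -Inf
  best <- bm == max(bm)
  sort(members[best])[1]
}

#' Collapse clustered loci to representatives
#'
#' Applies [select_representative()] to every cluster of a
#' [call_clusters()] table.
#'
#' @param clustered output of [call_clusters()].
#' @param base_mean named numeric vector (e.g. from a `dge_result`'s
#'   `base_mean` column named by locus).
#' @return data.frame with one row per cluster: `cluster`,
#'   `representative`, `n_members`.
#' @export
collapse_clusters <- function(clustered, base_mean) {
  stopifnot("cluster" %in% names(clustered))
  sp <- split(clustered$id, clustered$cluster)
  reps <- vapply(sp, select_representative, character(1),
                 base_mean = base_mean)
  out <- data.frame(cluster = names(sp),
                    representative = unname(reps),
                    n_members = lengths(sp),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out[order(out$cluster), , drop = FALSE]
}

#' Detect interchromosomal movement between species
#'
#' An ortholog pair is discordant when the Muller element letters of the
#' two species differ (element letters are extracted from labels such as
#' `"A (XL)"`, so arm renaming does not matter). Pairs with an unknown
#' element on either side are excluded and counted separately. The
#' report is symmetric in species order.
#'
#' @param orth ortholog table with columns `id1`, `id2`, `muller1`,
#'   `muller2` (see [read_orthologs()]).
#' @return object of class `translocation_report`: a list with
#'   `n_pairs` (examined), `n_concordant`, `discordant` (data.frame of
#'   offending pairs with both labels), `n_excluded_unknown`.
#' @export
detect_translocations <- function(orth) {
  stopifnot(all(c("id1", "id2", "muller1", "muller2") %in% names(orth)))
  m1 <- muller_letter(orth$muller1)
  m2 <- muller_letter(orth$muller2)
  known <- m1 != "unknown" & m2 != "unknown"
  disc <- known & (m1 != m2)
  out <- list(
    n_pairs = sum(known),
    n_concordant = sum(known & !disc),
    discordant = data.frame(id1 = orth$id1[disc], id2 = orth$id2[disc],
                            muller1 = m1[disc], muller2 = m2[disc],
                            stringsAsFactors = FALSE),
    n_excluded_unknown = sum(!known))
  class(out) <- "translocation_report"
  out
}

#' @export
print.translocation_report <- function(x, ...) {
  cat(sprintf("translocation report: %d pairs examined, %d concordant, %d discordant",
              x$n_pairs, x$n_concordant, nrow(x$discordant)))
  if (x$n_excluded_unknown > 0)
    cat(sprintf(" (%d excluded, unknown element)", x$n_excluded_unknown))
  cat("\n")
  if (nrow(x$discordant)) print.data.frame(x$discordant, row.names = FALSE)
  invisible(x)
}

#' Pair ortholog fold-changes across species
#'
#' Joins the log2 fold-changes of one-to-one homology groups whose
#' members pass the expression filter in both species, and stratifies
#' them by the species-2 chromosomal context (X, neo-X, or autosome,
#' from the Muller element) and evolutionary age class.
#'
#' @param groups output of [build_groups()].
#' @param dge1,dge2 `dge_result` tables for species 1 and 2 (they only
#'   contain loci passing the filter, so membership doubles as the
#'   filter).
#' @param annot2 annotation of species 2 (`id`, `muller`, `age_class`).
#' @param x_elements Muller elements forming the ancestral X in species
#'   2, default `"A"`.
#' @param neo_x_elements Muller elements forming the neo-X, default
#'   `"D"`.
#' @return data.frame with columns `group`, `id1`, `id2`, `log2fc1`,
#'   `log2fc2`, `chrom_class` (`X`/`neo-X`/`autosome`), `age_class`.
#' @export
pair_ortholog_bias <- function(groups, dge1, dge2, annot2,
                               x_elements = "A", neo_x_elements = "D") {
  g11 <- groups[groups$class == "one_to_one", , drop = FALSE]
  if (!nrow(g11))
    return(data.frame(group = integer(), id1 = character(),
                      id2 = character(), log2fc1 = numeric(),
                      log2fc2 = numeric(), chrom_class = character(),
                      age_class = character(), stringsAsFactors = FALSE))
  sp1 <- g11[g11$species == 1L, c("group", "id")]
  sp2 <- g11[g11$species == 2L, c("group", "id")]
  pairs <- merge(sp1, sp2, by = "group", suffixes = c("1", "2"))
  fc1 <- stats::setNames(dge1$log2fc, dge1$locus)
  fc2 <- stats::setNames(dge2$log2fc, dge2$locus)
  keep <- pairs$id1 %in% names(fc1) & pairs$id2 %in% names(fc2)
  pairs <- pairs[keep, , drop = FALSE]
  mul <- stats::setNames(muller_letter(annot2$muller), annot2$id)
  age <- stats::setNames(as.character(annot2$age_class), annot2$id)
  chrom_class <- ifelse(mul[pairs$id2] %in% neo_x_elements, "neo-X",
                        ifelse(mul[pairs$id2] %in% x_elements, "X",
                               "autosome"))
  out <- data.frame(group = pairs$group, id1 = pairs$id1, id2 = pairs$id2,
                    log2fc1 = unname(fc1[pairs$id1]),
                    log2fc2 = unname(fc2[pairs$id2]),
                    chrom_class = unname(chrom_class),
                    age_class = unname(age[pairs$id2]),
                    stringsAsFactors = FALSE)
  out[order(out$group), , drop = FALSE]
}
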