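# Cross-species microRNA homology: seeded local alignment, similarity
# graph components, uncorrected distances and neighbor-joining trees.

#' Alignment scoring scheme
#'
#' Defaults are conservative BLASTN-like values. A gap of length L costs
#' `gap_open + L * gap_extend` (both negative). The expected per-site
#' score under uniform base composition must be negative for the E-value
#' theory to apply.
#'
#' @param match,mismatch,gap_open,gap_extend numeric scores; `match > 0`,
#'   the others `<= 0`.
#' @return list of class `align_scoring`.
#' @export
align_scoring <- function(match = 1, mismatch = -2, gap_open = -5,
                          gap_extend = -2) {
  if (match <= 0) stopf("'match' must be positive")
  if (mismatch > 0 || gap_open > 0 || gap_extend > 0)
    stopf("penalties must be <= 0")
  structure(list(match = match, mismatch = mismatch,
                 gap_open = gap_open, gap_extend = gap_extend),
            class = "align_scoring")
}

.as_seq <- function(x) {
  x <- toupper(as.character(x))
  if (length(x) != 1L) stopf("expected a single sequence")
  if (nchar(x) && !grepl("^[ACGTN]*$", x))
    stopf("sequence must be over the alphabet {A,C,G,T,N}")
  x
}

# exact shared k-mer test (k-mers containing N never seed)
.has_seed <- function(s1, s2, word_size) {
  n1 <- nchar(s1); n2 <- nchar(s2)
  if (n1 < word_size || n2 < word_size) return(FALSE)
  k1 <- unique(substring(s1, seq_len(n1 - word_size + 1),
                         seq_len(n1 - word_size + 1) + word_size - 1))
  k1 <- k1[!grepl("N", k1, fixed = TRUE)]
  k2 <- unique(substring(s2, seq_len(n2 - word_size + 1),
                         seq_len(n2 - word_size + 1) + word_size - 1))
  any(k1 %in% k2)
}

#' Local alignment of two nucleotide sequences
#'
#' Smith-Waterman with affine gaps. In `"exhaustive"` mode the optimal
#' local alignment for the scoring scheme is returned. In `"seeded"` mode
#' (the default, mirroring a word-size-10 blastn search) the pair is
#' first screened for a shared exact word of length `word_size`; pairs
#' without one score 0, pairs with one get the exact DP. The seeded score
#' therefore never exceeds the exhaustive score, and equals it whenever a
#' seed of at least `word_size` exists.
#'
#' @param seq1,seq2 character strings over `{A,C,G,T,N}`; `N` matches
#'   nothing (scores as a mismatch against everything, including `N`).
#' @param scoring an [align_scoring()] scheme.
#' @param mode `"seeded"` or `"exhaustive"`.
#' @param word_size seed word length for seeded mode, default 10.
#' @return list with `score`, 1-based `q_start`, `q_end`, `s_start`,
#'   `s_end` (0 when there is no hit), alignment `length`, `n_ident`,
#'   `n_gap`, and `identity` (`n_ident / length`, `NA` when empty).
#' @export
local_align <- function(seq1, seq2, scoring = align_scoring(),
                        mode = c("seeded", "exhaustive"), word_size = 10) {
  mode <- match.arg(mode)
  s1 <- .as_seq(seq1); s2 <- .as_seq(seq2)
  empty <- list(score = 0, q_start = 0L, q_end = 0L, s_start = 0L,
                s_end = 0L, length = 0L, n_ident = 0L, n_gap = 0L,
                identity = NA_real_)
  if (!nchar(s1) || !nchar(s2)) return(empty)
  if (mode == "seeded" && !.has_seed(s1, s2, word_size)) return(empty)
  a <- .sw_align(s1, s2, scoring$match, scoring$mismatch,
                 scoring$gap_open, scoring$gap_extend)
  a$identity <- if (a$length > 0) a$n_ident / a$length else NA_real_
  a
}

# --- Karlin-Altschul parameters ------------------------------------------

.ka_cache <- new.env(parent = emptyenv())

#' Karlin-Altschul parameters for a scoring scheme
#'
#' `lambda` solves `sum_ij p_i p_j exp(lambda * s_ij) = 1` under uniform
#' base composition (solved numerically). The prefactor `K` has no
#' closed form for gapped scores; it is calibrated once per scheme by
#' fitting the Gumbel location of optimal local-alignment scores of
#' random sequence pairs (deterministic internal seed, cached), via
#' `E[max] = (log(K m n) + gamma) / lambda`.
#'
#' @param scoring an [align_scoring()] scheme.
#' @return list with `lambda` and `K`.
#' @export
karlin_altschul <- function(scoring = align_scoring()) {
  key <- paste(unlist(scoring), collapse = "/")
  if (!is.null(.ka_cache[[key]])) return(.ka_cache[[key]])
  p_match <- 0.25; p_mis <- 0.75
  expected <- p_match * scoring$match + p_mis * scoring$mismatch
  if (expected >= 0)
    stopf("expected per-site score is non-negative; E-values undefined")
  f <- function(l) p_match * exp(l * scoring$match) +
    p_mis * exp(l * scoring$mismatch) - 1
  lambda <- stats::uniroot(f, c(1e-6, 10), tol = 1e-12)$root
  # deterministic Gumbel-mean calibration of K on gapped scores
  len <- 150L; nrep <- 300L
  scores <- withr::with_seed(190657L, {
    vapply(seq_len(nrep), function(i) {
      s1 <- paste(sample(c("A", "C", "G", "T"), len, TRUE), collapse = "")
      s2 <- paste(sample(c("A", "C", "G", "T"), len, TRUE), collapse = "")
      .sw_score(s1, s2, scoring$match, scoring$mismatch,
                scoring$gap_open, scoring$gap_extend)
    }, numeric(1))
  })
  gamma_const <- 0.5772156649015329
  K <- exp(lambda * mean(scores) - gamma_const) / (len * len)
  out <- list(lambda = lambda, K = K)
  .ka_cache[[key]] <- out
  out
}

#' E-value of a local alignment score
#'
#' Ungapped Karlin-Altschul approximation `E = K m n exp(-lambda S)`
#' applied to (gapped) local scores, with the per-pair search space
#' `m * n`.
#'
#' @param score alignment score(s).
#' @param m,n sequence lengths.
#' @param scoring an [align_scoring()] scheme.
#' @return numeric E-value(s).
#' @export
evalue <- function(score, m, n, scoring = align_scoring()) {
  ka <- karlin_altschul(scoring)
  ka$K * m * n * exp(-ka$lambda * score)
}

#' All-vs-all similarity hits between two sequence sets
#'
#' Compares every query against every subject with seeded local
#' alignment and keeps hits with `E <= evalue_max` (default 0.1, as used
#' for ortholog pairing). Genome-scan mode uses the stricter default
#' `E <= 0.01` and additionally requires alignment length `>=
#' min_aln_len` (default 60).
#'
#' @param query,subject named character vectors or
#'   `Biostrings::DNAStringSet` objects (names are locus IDs).
#' @param word_size seed word length, default 10.
#' @param evalue_max E-value threshold; default 0.1, or 0.01 in
#'   genome-scan mode.
#' @param scoring an [align_scoring()] scheme.
#' @param genome_scan logical; enforce the alignment-length filter.
#' @param min_aln_len minimal alignment length in genome-scan mode.
#' @param mode alignment mode, see [local_align()].
#' @return data.frame of hits: `query`, `subject`, `score`, `evalue`,
#'   `aln_length`, `pident`, `q_start`, `q_end`, `s_start`, `s_end`.
#' @export
find_hits <- function(query, subject, word_size = 10,
                      evalue_max = if (genome_scan) 0.01 else 0.1,
                      scoring = align_scoring(), genome_scan = FALSE,
                      min_aln_len = 60, mode = "seeded") {
  qs <- .seq_set(query); ss <- .seq_set(subject)
  rows <- vector("list", length(qs) * length(ss))
  k <- 0L
  for (qi in seq_along(qs)) {
    for (si in seq_along(ss)) {
      a <- local_align(qs[[qi]], ss[[si]], scoring = scoring,
                       mode = mode, word_size = word_size)
      if (a$score <= 0) next
      ev <- evalue(a$score, nchar(qs[[qi]]), nchar(ss[[si]]), scoring)
      if (ev > evalue_max) next
      if (genome_scan && a$length < min_aln_len) next
      k <- k + 1L
      rows[[k]] <- data.frame(
        query = names(qs)[qi], subject = names(ss)[si], score = a$score,
        evalue = ev, aln_length = a$length, pident = 100 * a$identity,
        q_start = a$q_start, q_end = a$q_end,
        s_start = a$s_start, s_end = a$s_end, stringsAsFactors = FALSE)
    }
  }
  if (k == 0L)
    return(data.frame(query = character(), subject = character(),
                      score = numeric(), evalue = numeric(),
                      aln_length = integer(), pident = numeric(),
                      q_start = integer(), q_end = integer(),
                      s_start = integer(), s_end = integer(),
                      stringsAsFactors = FALSE))
  do.call(rbind, rows[seq_len(k)])
}

.seq_set <- function(x) {
  if (inherits(x, "DNAStringSet")) x <- as.character(x)
  x <- toupper(x)
  if (is.null(names(x)) || anyDuplicated(names(x)))
    stopf("sequence sets need unique names")
  as.list(x)
}

#' Build homology groups from similarity hits
#'
#' Loci of both species become vertices of an undirected graph with one
#' edge per hit pair; connected components are the (potential) homology
#' groups. Loci without any edge become singleton unpaired groups. Each
#' group is classified from its per-species member counts:
#' `one_to_one`, `one_to_many`, `many_to_many`, or `unpaired`.
#'
#' @param hits data.frame from [find_hits()] (columns `query`,
#'   `subject`), with query IDs from species 1 and subject IDs from
#'   species 2.
#' @param ids1,ids2 all locus IDs of species 1 and 2 (supersets of the
#'   hit IDs).
#' @return data.frame with one row per locus: `group` (integer id), `id`,
#'   `species` (1 or 2), `class`.
#' @export
build_groups <- function(hits, ids1, ids2) {
  ids1 <- as.character(ids1); ids2 <- as.character(ids2)
  if (anyDuplicated(c(ids1, ids2)))
    stopf("locus IDs must be unique across both species")
  bad <- setdiff(c(hits$query, hits$subject), c(ids1, ids2))
  if (length(bad)) stopf("hits reference unknown loci: %s",
                         paste(unique(bad), collapse = ", "))
  g <- igraph::graph_from_data_frame(
    hits[, c("query", "subject"), drop = FALSE], directed = FALSE,
    vertices = data.frame(name = c(ids1, ids2)))
  comp <- igraph::components(g)
  member <- comp$membership
  out <- data.frame(group = unname(member[c(ids1, ids2)]),
                    id = c(ids1, ids2),
                    species = rep(c(1L, 2L), c(length(ids1), length(ids2))),
                    stringsAsFactors = FALSE)
  n1 <- tapply(out$species == 1L, out$group, sum)
  n2 <- tapply(out$species == 2L, out$group, sum)
  cls <- ifelse(n1 == 0 | n2 == 0, "unpaired",
                ifelse(n1 == 1 & n2 == 1, "one_to_one",
                       ifelse(n1 > 1 & n2 > 1, "many_to_many",
                              "one_to_many")))
  out$class <- as.vector(cls[as.character(out$group)])
  out <- out[order(out$group, out$species, out$id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Uncorrected (p-) distance between two sequences
#'
#' Globally aligns the pair (Needleman-Wunsch, same affine scoring
#' family) and returns mismatches divided by aligned positions; columns
#' with a gap in either sequence are excluded pairwise.
#'
#' @param seq1,seq2 character strings over `{A,C,G,T,N}`.
#' @param scoring an [align_scoring()] scheme.
#' @return distance in `[0, 1]`.
#' @export
uncorrected_distance <- function(seq1, seq2, scoring = align_scoring()) {
  s1 <- .as_seq(seq1); s2 <- .as_seq(seq2)
  a <- .nw_align(s1, s2, scoring$match, scoring$mismatch,
                 scoring$gap_open, scoring$gap_extend)
  if (a$aligned == 0)
    stopf("no aligned positions; uncorrected distance undefined")
  a$mismatches / a$aligned
}

#' Pairwise uncorrected distance matrix
#'
#' @param seqs named character vector or `DNAStringSet` (>= 2 sequences).
#' @param scoring an [align_scoring()] scheme.
#' @return symmetric labeled matrix with zero diagonal.
#' @export
distance_matrix <- function(seqs, scoring = align_scoring()) {
  s <- .seq_set(seqs)
  n <- length(s)
  d <- matrix(0, n, n, dimnames = list(names(s), names(s)))
  if (n >= 2) {
    for (i in seq_len(n - 1)) {
      for (j in seq(i + 1, n)) {
        d[i, j] <- d[j, i] <- uncorrected_distance(s[[i]], s[[j]], scoring)
      }
    }
  }
  d
}

# --- neighbor joining ----------------------------------------------------

.leaf <- function(label) list(label = label, children = NULL, length = NA)

.min_leaf <- function(node) {
  if (is.null(node$children)) return(node$label)
  min(vapply(node$children, .min_leaf, character(1)))
}

#' Neighbor-joining tree from a distance matrix
#'
#' Classic agglomerative neighbor joining: at each step the pair
#' minimizing `Q(i,j) = (n-2) d(i,j) - sum_k d(i,k) - sum_k d(j,k)` is
#' joined, branch lengths follow the standard split formula, and the last
#' three nodes are resolved exactly, yielding an unrooted tree. Negative
#' branch lengths are clamped to zero and flagged. Ties in the Q minimum
#' are broken by node label order, so the result is deterministic.
#'
#' @param d symmetric distance matrix with labels (`n >= 2`).
#' @return object of class `nj_tree`: nested node list with attribute
#'   `negative_clamped` (logical).
#' @seealso [write_newick()] for the canonical serialization.
#' @export
neighbor_joining <- function(d) {
  d <- as.matrix(d)
  if (is.null(rownames(d))) stopf("distance matrix needs labels")
  if (nrow(d) < 2L) stopf("need at least 2 labels")
  if (max(abs(d - t(d))) > 1e-8) stopf("distance matrix is not symmetric")
  if (any(d < 0)) stopf("distances must be non-negative")
  labs <- rownames(d)
  nodes <- lapply(labs, .leaf)
  names(nodes) <- labs
  clamped <- FALSE
  clamp <- function(x) {
    if (x < 0) clamped <<- TRUE
    max(0, x)
  }
  while (nrow(d) > 3L) {
    n <- nrow(d)
    r <- rowSums(d)
    q <- (n - 2) * d - outer(r, r, "+")
    diag(q) <- Inf
    # deterministic argmin: smallest (row, col) index pair
    idx <- which(q == min(q), arr.ind = TRUE)
    idx <- idx[idx[, 1] < idx[, 2], , drop = FALSE]
    i <- idx[1, 1]; j <- idx[1, 2]
    li <- clamp(d[i, j] / 2 + (r[i] - r[j]) / (2 * (n - 2)))
    lj <- clamp(d[i, j] - (d[i, j] / 2 + (r[i] - r[j]) / (2 * (n - 2))))
    ni <- nodes[[i]]; nj_ <- nodes[[j]]
    ni$length <- li; nj_$length <- lj
    new_node <- list(label = NA, children = list(ni, nj_), length = NA)
    dnew <- (d[i, ] + d[j, ] - d[i, j]) / 2
    dnew <- pmax(dnew, 0)
    keep <- setdiff(seq_len(n), c(i, j))
    d2 <- rbind(cbind(d[keep, keep, drop = FALSE], dnew[keep]),
                c(dnew[keep], 0))
    newlab <- paste0("__int", length(nodes))
    rownames(d2) <- colnames(d2) <- c(rownames(d)[keep], newlab)
    nodes <- c(nodes[keep], stats::setNames(list(new_node), newlab))
    d <- d2
  }
  if (nrow(d) == 3L) {
    l1 <- clamp((d[1, 2] + d[1, 3] - d[2, 3]) / 2)
    l2 <- clamp((d[1, 2] + d[2, 3] - d[1, 3]) / 2)
    l3 <- clamp((d[1, 3] + d[2, 3] - d[1, 2]) / 2)
    ch <- nodes
    ch[[1]]$length <- l1; ch[[2]]$length <- l2; ch[[3]]$length <- l3
    root <- list(label = NA, children = unname(ch), length = NA)
  } else {  # exactly 2
    half <- d[1, 2] / 2
    ch <- nodes
    ch[[1]]$length <- half; ch[[2]]$length <- half
    root <- list(label = NA, children = unname(ch), length = NA)
  }
  structure(root, class = "nj_tree", negative_clamped = clamped)
}

#' @export
print.nj_tree <- function(x, ...) {
  cat("neighbor-joining tree:", write_newick(x), "\n")
  invisible(x)
}
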