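# Shared test helpers: random inputs and brute-force oracles that stay
# independent of the implementation paths they check.

random_dna <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# mutate a sequence at a per-site rate (independent of the package's
# generator internals)
mutate_dna <- function(seq, rate) {
  b <- strsplit(seq, "")[[1]]
  hit <- runif(length(b)) < rate
  b[hit] <- vapply(b[hit], function(x)
    sample(setdiff(c("A", "C", "G", "T"), x), 1), character(1))
  paste(b, collapse = "")
}

# brute-force connected components by boolean transitive closure
closure_components <- function(vertices, edges) {
  n <- length(vertices)
  adj <- diag(TRUE, n)
  dimnames(adj) <- list(vertices, vertices)
  if (nrow(edges)) {
    for (k in seq_len(nrow(edges))) {
      i <- match(edges[k, 1], vertices)
      j <- match(edges[k, 2], vertices)
      adj[i, j] <- adj[j, i] <- TRUE
    }
  }
  repeat {
    nxt <- (adj %*% adj) > 0
    if (identical(nxt, adj > 0)) break
    adj <- nxt
  }
  # canonical component labels: smallest member vertex
  apply(adj, 1, function(row) vertices[which(row)[1]])
}

# brute-force single-linkage interval clustering over all pairs
bruteforce_clusters <- function(start, end, gap_bp) {
  n <- length(start)
  edges <- matrix(character(0), ncol = 2)
  ids <- as.character(seq_len(n))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i >= j) next
      gap <- max(0, max(start[i], start[j]) - min(end[i], end[j]) - 1)
      if (gap <= gap_bp) edges <- rbind(edges, c(ids[i], ids[j]))
    }
  }
  closure_components(ids, edges)
}

# Biostrings local alignment with the package's default scoring, as an
# independent full Smith-Waterman oracle (N-free sequences only)
biostrings_local_score <- function(s1, s2, match = 1, mismatch = -2,
                                   gap_open = -5, gap_extend = -2) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(
    match = match, mismatch = mismatch, baseOnly = TRUE)
  Biostrings::pairwiseAlignment(
    s1, s2, type = "local", substitutionMatrix = mat,
    gapOpening = -gap_open, gapExtension = -gap_extend,
    scoreOnly = TRUE)
}

# partition equality up to label renaming
same_partition <- function(a, b) {
  identical(as.vector(unclass(factor(a, levels = unique(a)))),
            as.vector(unclass(factor(b, levels = unique(b)))))
}
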