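# Readers and writers for every external format the pipeline touches.
# Coordinates are 1-based and inclusive everywhere (NCBI convention).

.MULLER_LEVELS <- c("A", "B", "C", "D", "E", "F")

# Normalize a Muller annotation like "A (XL)" or "d" to the element letter;
# anything unrecognized becomes "unknown".
muller_letter <- function(x) {
  out <- toupper(sub("^\\s*([A-Fa-f]).*$", "\\1", as.character(x)))
  out[!(out %in% .MULLER_LEVELS)] <- "unknown"
  out[is.na(x) | x == ""] <- "unknown"
  out
}

.validate_annotation <- function(df, where = "annotation") {
  req <- c("id", "chromosome", "start", "end")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stopf("%s lacks column(s): %s", where, paste(miss, collapse = ", "))
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  bad <- which(is.na(df$start) | is.na(df$end) | df$start < 1 |
                 df$end < df$start)
  if (length(bad))
    stopf("%s: malformed coordinates (end < start or start < 1) in row(s) %s",
          where, paste(bad, collapse = ", "))
  if (is.null(df$species))
    df$species <- rep(NA_character_, nrow(df))
  key <- paste(df$species, df$id)
  if (anyDuplicated(key))
    stopf("%s: duplicated locus id(s): %s", where,
          paste(unique(df$id[duplicated(key)]), collapse = ", "))
  if (is.null(df$strand)) df$strand <- rep("unknown", nrow(df))
  df$strand[!(df$strand %in% c("+", "-"))] <- "unknown"
  if (is.null(df$muller)) df$muller <- rep("unknown", nrow(df))
  raw <- as.character(df$muller)
  df$muller <- muller_letter(raw)
  odd <- raw[df$muller == "unknown" & !is.na(raw) & raw != "" &
               raw != "unknown"]
  if (length(odd))
    warnf("unknown Muller label(s) recorded as 'unknown': %s",
          paste(unique(odd), collapse = ", "))
  if (is.null(df$age_class))
    df$age_class <- rep(NA_character_, nrow(df))
  if (is.null(df$multimapper))
    df$multimapper <- rep(FALSE, nrow(df))
  df$multimapper <- as.logical(df$multimapper)
  df$multimapper[is.na(df$multimapper)] <- FALSE
  cols <- c("id", "species", "chromosome", "muller", "start", "end",
            "strand", "age_class", "multimapper")
  df <- df[, cols, drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Read a microRNA locus annotation
#'
#' Supported dialects: GFF3 (attributes `ID`, `muller`, `age_class`,
#' `species`, `multimapper`) and plain TSV with the same fields as
#' columns. Records are validated: coordinates must satisfy
#' `1 <= start <= end` (hard error naming the offending line), locus IDs
#' must be unique within a species, and unrecognized Muller labels are
#' recorded as `"unknown"` with a warning. Loci flagged as multimappers
#' are kept but marked, so callers can exclude them.
#'
#' @param path input file.
#' @param dialect `"gff3"` or `"tsv"`.
#' @return data.frame with columns `id`, `species`, `chromosome`,
#'   `muller`, `start`, `end`, `strand`, `age_class`, `multimapper`.
#' @export
read_annotation <- function(path, dialect = c("gff3", "tsv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stopf("file not found: %s", path)
  if (dialect == "tsv") {
    df <- tryCatch(read_tsv_table(path), error = function(e) NULL)
    if (is.null(df) || nrow(df) == 0L) {
      warnf("empty annotation file: %s", path)
      return(.validate_annotation(
        data.frame(id = character(), chromosome = character(),
                   start = integer(), end = integer())))
    }
    return(.validate_annotation(df, where = path))
  }
  # GFF3: pre-scan coordinates so errors can name the line
  lines <- readLines(path, warn = FALSE)
  body <- which(!grepl("^#", lines) & nzchar(trimws(lines)))
  if (!length(body)) {
    warnf("empty annotation file: %s", path)
    return(.validate_annotation(
      data.frame(id = character(), chromosome = character(),
                 start = integer(), end = integer())))
  }
  for (ln in body) {
    f <- strsplit(lines[ln], "\t", fixed = TRUE)[[1]]
    if (length(f) < 9L)
      stopf("%s line %d: expected 9 GFF3 columns", path, ln)
    st <- suppressWarnings(as.integer(f[4]))
    en <- suppressWarnings(as.integer(f[5]))
    if (is.na(st) || is.na(en) || st < 1 || en < st)
      stopf("%s line %d: malformed coordinates (start=%s, end=%s)",
            path, ln, f[4], f[5])
  }
  gr <- rtracklayer::import(path, format = "gff3")
  mc <- S4Vectors::mcols(gr)
  getc <- function(nm, default = NA_character_) {
    if (nm %in% names(mc)) as.character(mc[[nm]]) else
      rep(default, length(gr))
  }
  strand <- as.character(BiocGenerics::strand(gr))
  strand[strand == "*"] <- "unknown"
  df <- data.frame(
    id = getc("ID"),
    species = getc("species"),
    chromosome = as.character(GenomicRanges::seqnames(gr)),
    muller = getc("muller"),
    start = BiocGenerics::start(gr),
    end = BiocGenerics::end(gr),
    strand = strand,
    age_class = getc("age_class"),
    multimapper = getc("multimapper", "FALSE"),
    stringsAsFactors = FALSE)
  .validate_annotation(df, where = path)
}

#' Write a microRNA locus annotation
#'
#' Inverse of [read_annotation()]; `write_annotation` followed by
#' `read_annotation` reproduces the table.
#'
#' @param loci annotation data.frame (see [read_annotation()]).
#' @param path output file.
#' @param dialect `"gff3"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(loci, path, dialect = c("gff3", "tsv")) {
  dialect <- match.arg(dialect)
  loci <- .validate_annotation(loci)
  if (dialect == "tsv") return(write_tsv_table(loci, path))
  strand <- loci$strand
  strand[strand == "unknown"] <- "*"
  gr <- GenomicRanges::GRanges(
    seqnames = loci$chromosome,
    ranges = IRanges::IRanges(start = loci$start, end = loci$end),
    strand = strand)
  S4Vectors::mcols(gr)$source <- "mirsexbias"
  S4Vectors::mcols(gr)$type <- "pre_miRNA"
  S4Vectors::mcols(gr)$ID <- loci$id
  S4Vectors::mcols(gr)$species <- loci$species
  S4Vectors::mcols(gr)$muller <- loci$muller
  S4Vectors::mcols(gr)$age_class <- loci$age_class
  S4Vectors::mcols(gr)$multimapper <- as.character(loci$multimapper)
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read a count matrix with its sample metadata
#'
#' @param path TSV with locus IDs in the first column and one column per
#'   sample.
#' @param meta_path TSV with columns `sample`, `sex`, `batch` and
#'   optionally `tissue`.
#' @return a [count_experiment()] object. Mismatched sample IDs or
#'   negative/non-integer entries are errors naming the offenders.
#' @export
read_counts <- function(path, meta_path) {
  tab <- read.delim(path, sep = "\t", quote = "", comment.char = "#",
                    check.names = FALSE, row.names = 1)
  m <- as.matrix(tab)
  if (!is.numeric(m)) stopf("count table contains non-numeric entries")
  bad <- rownames(m)[rowSums(m < 0 | m != round(m)) > 0]
  if (length(bad))
    stopf("negative or non-integer counts at: %s",
          paste(utils::head(bad, 5), collapse = ", "))
  meta <- read_tsv_table(meta_path)
  count_experiment(m, meta)
}

#' Write a count experiment as TSV pair
#'
#' @param ce a `CountExperiment`.
#' @param path counts TSV path (first column `locus`).
#' @param meta_path sample metadata TSV path.
#' @return `path`, invisibly.
#' @export
write_counts <- function(ce, path, meta_path) {
  stopifnot(inherits(ce, "CountExperiment"))
  df <- data.frame(locus = rownames(ce$counts), ce$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv_table(df, path)
  write_tsv_table(ce$samples, meta_path)
  invisible(path)
}

#' Read / write an ortholog-pair table
#'
#' TSV with columns `id1`, `id2`, `muller1`, `muller2` and optional
#' coordinate columns; one-to-many relations are extra rows. Duplicated
#' `(id1, id2)` pairs are rejected.
#'
#' @param path TSV file.
#' @return data.frame.
#' @export
read_orthologs <- function(path) {
  df <- read_tsv_table(path)
  req <- c("id1", "id2", "muller1", "muller2")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stopf("ortholog table lacks column(s): %s", paste(miss, collapse = ", "))
  if (anyDuplicated(df[, c("id1", "id2")]))
    stopf("duplicated (id1, id2) pair in ortholog table")
  df
}

#' @rdname read_orthologs
#' @param orth ortholog data.frame.
#' @export
write_orthologs <- function(orth, path) {
  if (anyDuplicated(orth[, c("id1", "id2")]))
    stopf("duplicated (id1, id2) pair in ortholog table")
  write_tsv_table(orth, path)
}

#' Read / write FASTA sequence sets
#'
#' Thin wrappers around Biostrings.
#'
#' @param path FASTA file.
#' @return `read_fasta`: a `DNAStringSet`.
#' @export
read_fasta <- function(path) Biostrings::readDNAStringSet(path)

#' @rdname read_fasta
#' @param seqs named character vector or `DNAStringSet`.
#' @export
write_fasta <- function(seqs, path) {
  if (!inherits(seqs, "DNAStringSet"))
    seqs <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Bundled predicted ortholog tables
#'
#' The package ships two curated tables of predicted, newly discovered
#' D. pseudoobscura microRNA orthologs (genome-scan hits of annotated
#' D. melanogaster precursors, with the Muller element of each species'
#' copy): a one-to-one set of 26 pairs and a one-to-many set of two
#' microRNAs with two D. pseudoobscura copies each. Returned in
#' [read_orthologs()] layout, ready for [detect_translocations()]; the
#' species-2 ID is synthesized from the genomic location.
#'
#' @param which `"one_to_one"` or `"two_copy"`.
#' @return ortholog data.frame (`id1`, `id2`, `muller1`, `muller2`,
#'   plus `chromosome`, `start`, `end` of the species-2 copy).
#' @export
bundled_ortholog_table <- function(which = c("one_to_one", "two_copy")) {
  which <- match.arg(which)
  f <- if (which == "one_to_one") "predicted_dpse_orthologs.tsv" else
    "predicted_dpse_two_copy_orthologs.tsv"
  path <- system.file("extdata", f, package = "mirsexbias")
  raw <- read_tsv_table(path)
  data.frame(id1 = raw$mirna,
             id2 = sprintf("dps:%s:%d", raw$chromosome, raw$start),
             muller1 = raw$muller_dmel, muller2 = raw$muller_dpse,
             chromosome = raw$chromosome, start = raw$start,
             end = raw$end, stringsAsFactors = FALSE)
}

#' Serialize a tree as canonical newick
#'
#' Children are ordered by their lexicographically smallest leaf label,
#' so equal trees always serialize identically (diffable output). Branch
#' lengths are written at full double precision.
#'
#' @param tree an `nj_tree` (see [neighbor_joining()]) or a bare leaf
#'   label (a single character string), which serializes as `"label;"`.
#' @param path optional file to write to.
#' @return the newick string, invisibly if `path` is given.
#' @export
write_newick <- function(tree, path = NULL) {
  fmt_len <- function(x) {
    if (is.na(x)) "" else paste0(":", sprintf("%.15g", x))
  }
  rec <- function(node) {
    if (is.character(node)) return(node)   # bare leaf label
    if (is.null(node$children)) return(paste0(node$label, fmt_len(node$length)))
    keys <- vapply(node$children, .min_leaf, character(1))
    kids <- node$children[order(keys)]
    inner <- paste(vapply(kids, rec, character(1)), collapse = ",")
    paste0("(", inner, ")", fmt_len(node$length))
  }
  if (is.character(tree) && length(tree) == 1L) {
    s <- paste0(tree, ";")
  } else if (is.null(tree$children)) {
    s <- paste0(tree$label, ";")
  } else {
    root <- tree
    root$length <- NA
    s <- paste0(rec(root), ";")
  }
  if (!is.null(path)) {
    writeLines(s, path)
    return(invisible(s))
  }
  s
}

#' Write a generic results table
#'
#' Convenience alias for the package's TSV dialect (tab separated, no
#' quoting, `.` decimal).
#'
#' @param results data.frame.
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
write_report <- function(results, path) write_tsv_table(results, path)
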