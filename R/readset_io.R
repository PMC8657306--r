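#' Paired-end read set
#'
#' @param read1,read2 character vectors of mate sequences (uppercase ACGTN).
#' @param pair_id pair identifiers (defaults to `pair_1..n`).
#' @param truth optional per-pair truth label (source feature) when
#'   simulator-produced; `NA` otherwise.
#' @return data.frame of class `read_set` with columns `pair_id`, `read1`,
#'   `read2`, `truth`.
#' @export
read_set <- function(read1, read2, pair_id = NULL, truth = NULL) {
  read1 <- as.character(read1); read2 <- as.character(read2)
  if (length(read1) != length(read2))
    stop("read1 and read2 must have equal length")
  if (any(!nzchar(read1)) || any(!nzchar(read2)))
    stop("read sequences must be non-empty")
  bad <- grepl("[^ACGTN]", c(read1, read2))
  if (any(bad)) stop("read sequences must be uppercase over {A,C,G,T,N}")
  n <- length(read1)
  if (is.null(pair_id)) pair_id <- sprintf("pair_%d", seq_len(n))
  if (is.null(truth)) truth <- rep(NA_character_, n)
  structure(data.frame(pair_id = as.character(pair_id), read1 = read1,
                       read2 = read2, truth = as.character(truth),
                       stringsAsFactors = FALSE),
            class = c("read_set", "data.frame"))
}

as_read_frame <- function(reads) {
  if (is.data.frame(reads)) {
    if (!all(c("read1", "read2") %in% names(reads)))
      stop("reads need columns read1 and read2")
    return(reads)
  }
  stop("reads must be a read_set or data.frame with read1/read2 columns")
}

#' Write / read paired FASTQ
#'
#' Mate order is preserved between the two files; quality is a fixed 'I'
#' string (no quality-dependent step exists downstream). Reading is
#' gzip-transparent.
#'
#' @param reads a [read_set()].
#' @param r1_path,r2_path FASTQ paths for mate 1 / mate 2.
#' @return the paths invisibly (writer); a `read_set` (reader, `truth` NA).
#' @export
write_fastq_pair <- function(reads, r1_path, r2_path) {
  reads <- as_read_frame(reads)
  ids <- if ("pair_id" %in% names(reads)) reads$pair_id
         else sprintf("pair_%d", seq_len(nrow(reads)))
  s1 <- Biostrings::DNAStringSet(reads$read1); names(s1) <- ids
  s2 <- Biostrings::DNAStringSet(reads$read2); names(s2) <- ids
  q1 <- Biostrings::BStringSet(strrep("I", nchar(reads$read1)))
  q2 <- Biostrings::BStringSet(strrep("I", nchar(reads$read2)))
  Biostrings::writeXStringSet(s1, r1_path, format = "fastq", qualities = q1)
  Biostrings::writeXStringSet(s2, r2_path, format = "fastq", qualities = q2)
  invisible(c(r1_path, r2_path))
}

#' @rdname write_fastq_pair
#' @export
read_fastq_pair <- function(r1_path, r2_path) {
  s1 <- Biostrings::readDNAStringSet(r1_path, format = "fastq")
  s2 <- Biostrings::readDNAStringSet(r2_path, format = "fastq")
  if (length(s1) != length(s2))
    stop("FASTQ mate files differ in read count")
  read_set(as.character(s1), as.character(s2),
           pair_id = sub(" .*$", "", names(s1)))
}

#' Write / read a counts or RPKM table as TSV with sample-metadata JSON
#'
#' Features x samples with a `feature_id` first column; sample metadata goes
#' to a sidecar JSON holding `sample_id`, `shrna`, `dox`, `timepoint_h` and
#' per-sample assigned totals.
#'
#' @param expr an [expression_matrix()].
#' @param tsv_path table path; the RPKM table is written next to it with an
#'   `.rpkm.tsv` suffix.
#' @param meta_path sidecar JSON path.
#' @return `tsv_path` invisibly (writer); an `expression_matrix` (reader).
#' @export
write_expression_tsv <- function(expr, tsv_path, meta_path) {
  stopifnot(inherits(expr, "expression_matrix"))
  dt <- data.table::data.table(feature_id = rownames(expr$counts),
                               length = expr$lengths)
  for (s in colnames(expr$counts)) dt[[s]] <- expr$counts[, s]
  data.table::fwrite(dt, tsv_path, sep = "\t")
  jsonlite::write_json(list(samples = expr$samples,
                            assigned_totals = as.list(expr$assigned_totals)),
                       meta_path, auto_unbox = TRUE, digits = NA)
  invisible(tsv_path)
}

#' @rdname write_expression_tsv
#' @export
read_expression_tsv <- function(tsv_path, meta_path) {
  dt <- data.table::fread(tsv_path, sep = "\t")
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  samples <- as.data.frame(meta$samples)
  m <- as.matrix(dt[, samples$sample_id, with = FALSE])
  rownames(m) <- dt$feature_id
  expression_matrix(m, stats::setNames(dt$length, dt$feature_id), samples,
                    assigned_totals = unlist(meta$assigned_totals)[samples$sample_id])
}

#' Read an RPKM table directly (genes x samples TSV + metadata JSON)
#'
#' For tables that carry RPKM values rather than raw counts (the target
#' caller's native input). Columns: `feature_id` then one column per sample.
#'
#' @param tsv_path RPKM TSV.
#' @param meta_path sample-metadata JSON (`samples` data.frame as in
#'   [write_expression_tsv()]).
#' @return list with `rpkm` matrix and `samples` data.frame, usable by
#'   [call_targets()].
#' @export
read_rpkm_tsv <- function(tsv_path, meta_path) {
  dt <- data.table::fread(tsv_path, sep = "\t")
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  samples <- as.data.frame(meta$samples)
  m <- as.matrix(dt[, samples$sample_id, with = FALSE])
  rownames(m) <- dt$feature_id
  structure(list(rpkm = m, samples = samples), class = "rpkm_table")
}

#' Read a gene list (one symbol per line)
#' @param path text file, one gene symbol per line; blank lines ignored.
#' @param name set name (defaults to the file name).
#' @return a [gene_set()].
#' @export
read_gene_list <- function(path, name = basename(path)) {
  x <- readLines(path, warn = FALSE)
  gene_set(name, x[nzchar(trimws(x))], provenance = path)
}
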