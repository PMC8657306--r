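#' Transcript gene model
#'
#' A `gene_model` holds the ordered exon structure of one transcript,
#' transcript-oriented (5' to 3'): strand and genomic coordinates are resolved
#' upstream by the annotation reader, so all downstream logic reasons in
#' 1-based exon indices only, the way breakpoints are reported in the fusion
#' literature ("exon 7 fused to exon 8").
#'
#' @param gene_id gene symbol / identifier.
#' @param exons character vector of exon sequences in transcript order,
#'   uppercase ACGT, all non-empty. Exon `i` of the model is `exons[i]`.
#' @param transcript_id transcript identifier (defaults to `<gene_id>_T1`).
#' @return An object of class `gene_model` with fields `gene_id`,
#'   `transcript_id`, `exons`.
#' @examples
#' g <- gene_model("TOY", c("AAA", "CCC"))
#' gene_sequence(g)
#' @export
gene_model <- function(gene_id, exons, transcript_id = paste0(gene_id, "_T1")) {
  if (!is.character(gene_id) || length(gene_id) != 1L || !nzchar(gene_id))
    stop("gene_id must be a single non-empty string")
  exons <- as.character(exons)
  if (length(exons) == 0L)
    stop("malformed annotation: gene '", gene_id, "' has an empty exon list")
  if (any(!nzchar(exons)))
    stop("malformed annotation: gene '", gene_id, "' has an empty exon sequence")
  if (any(grepl("[^ACGT]", exons)))
    stop("malformed annotation: gene '", gene_id,
         "' has exon sequence with characters outside {A,C,G,T}")
  structure(list(gene_id = gene_id, transcript_id = transcript_id,
                 exons = unname(exons)),
            class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("gene_model %s (%s): %d exons, %d nt\n", x$gene_id,
              x$transcript_id, length(x$exons), sum(nchar(x$exons))))
  invisible(x)
}

#' Full transcript sequence of a gene model
#'
#' @param gene a [gene_model()].
#' @return Single string: concatenation of the exon sequences in index order.
#' @export
gene_sequence <- function(gene) {
  stopifnot(inherits(gene, "gene_model"))
  paste(gene$exons, collapse = "")
}

#' Number of exons in a gene model
#' @param gene a [gene_model()].
#' @return integer exon count.
#' @export
n_exons <- function(gene) length(gene$exons)

#' Fusion specification
#'
#' Describes a two-partner gene fusion and the optional in-frame isoform
#' insertion (the +KTS/-KTS distinction of WT1-type partners, a three-codon
#' insertion at an internal junction of the 3' partner). The insertion is a
#' configurable sequence, not hard-coded biology: the default is a 9-nt
#' Lys-Thr-Ser codon run.
#'
#' @param five_prime_gene gene_id of the 5' partner.
#' @param last_5p_exon last 5'-partner exon retained in the fusion (k).
#' @param three_prime_gene gene_id of the 3' partner.
#' @param first_3p_exon first 3'-partner exon in the fusion (m).
#' @param kts_insertion nucleotide string inserted in the +KTS isoform;
#'   length must be a multiple of 3 (in-frame).
#' @param kts_junction_after_exon 1-based exon index of the 3' partner after
#'   which the insertion sits.
#' @return object of class `fusion_spec`.
#' @export
fusion_spec <- function(five_prime_gene, last_5p_exon, three_prime_gene,
                        first_3p_exon, kts_insertion = "AAGACGTCT",
                        kts_junction_after_exon = first_3p_exon) {
  last_5p_exon <- as.integer(last_5p_exon)
  first_3p_exon <- as.integer(first_3p_exon)
  kts_junction_after_exon <- as.integer(kts_junction_after_exon)
  if (nchar(kts_insertion) %% 3L != 0L)
    stop("kts_insertion length must be a multiple of 3 (in-frame insertion)")
  if (grepl("[^ACGT]", kts_insertion))
    stop("kts_insertion must be uppercase ACGT")
  structure(list(five_prime_gene = five_prime_gene,
                 last_5p_exon = last_5p_exon,
                 three_prime_gene = three_prime_gene,
                 first_3p_exon = first_3p_exon,
                 kts_insertion = kts_insertion,
                 kts_junction_after_exon = kts_junction_after_exon),
            class = "fusion_spec")
}

#' @export
print.fusion_spec <- function(x, ...) {
  cat(sprintf("fusion_spec: %s exon 1-%d | %s exon %d-end (+KTS: %d nt after 3' exon %d)\n",
              x$five_prime_gene, x$last_5p_exon, x$three_prime_gene,
              x$first_3p_exon, nchar(x$kts_insertion), x$kts_junction_after_exon))
  invisible(x)
}

validate_fusion_spec <- function(spec, g5, g3) {
  k <- spec$last_5p_exon; m <- spec$first_3p_exon
  if (k < 1L || k >= n_exons(g5))
    stop("fusion spec: last_5p_exon ", k, " outside [1, ", n_exons(g5) - 1L,
         "] for gene '", g5$gene_id, "'")
  if (m <= 1L || m > n_exons(g3))
    stop("fusion spec: first_3p_exon ", m, " outside (1, ", n_exons(g3),
         "] for gene '", g3$gene_id, "'")
  invisible(TRUE)
}

#' Split a transcript into 5' and 3' half-features
#'
#' The core edit of the split-reference strategy: the full-length transcript
#' is replaced by two half-transcripts cut after exon `k`, so that reads from
#' a fusion transcript and reads from the wild-type gene become
#' distinguishable by which half they hit.
#'
#' @param gene a [gene_model()].
#' @param last_5p_exon split point k: the 5' half covers exons `1..k`, the 3'
#'   half exons `k+1..n`.
#' @return list of two half-feature records, each a list with `feature_id`
#'   (`<gene>_5p` / `<gene>_3p`), `source_gene`, `exon_range` (inclusive
#'   1-based pair) and `sequence`.
#' @examples
#' g <- gene_model("TOY", c("AAA", "CCC"))
#' halves <- split_transcript(g, 1)
#' halves[[1]]$sequence  # "AAA"
#' @export
split_transcript <- function(gene, last_5p_exon) {
  stopifnot(inherits(gene, "gene_model"))
  n <- n_exons(gene)
  k <- as.integer(last_5p_exon)
  if (is.na(k) || k < 1L || k >= n)
    stop("split point k=", last_5p_exon, " outside [1, ", n - 1L,
         "] for gene '", gene$gene_id, "' (", n, " exons)")
  list(
    list(feature_id = paste0(gene$gene_id, "_5p"), source_gene = gene$gene_id,
         exon_range = c(1L, k),
         sequence = paste(gene$exons[seq_len(k)], collapse = "")),
    list(feature_id = paste0(gene$gene_id, "_3p"), source_gene = gene$gene_id,
         exon_range = c(k + 1L, n),
         sequence = paste(gene$exons[(k + 1L):n], collapse = ""))
  )
}

#' Construct a fusion transcript sequence
#'
#' Joins exons `1..k` of the 5' partner to exons `m..n` of the 3' partner.
#' For the `plusKTS` isoform the spec's insertion sequence is additionally
#' placed immediately after the 3' partner exon named by
#' `kts_junction_after_exon`.
#'
#' @param g5,g3 [gene_model()]s of the 5' and 3' partners.
#' @param spec a [fusion_spec()] referencing `g5`/`g3` by gene_id.
#' @param isoform `"plusKTS"` or `"minusKTS"`.
#' @return fusion transcript nucleotide sequence (single string).
#' @export
build_fusion_sequence <- function(g5, g3, spec, isoform = c("minusKTS", "plusKTS")) {
  stopifnot(inherits(spec, "fusion_spec"))
  if (length(isoform) != 1L || !isoform %in% c("plusKTS", "minusKTS"))
    isoform <- match.arg(isoform)
  if (spec$five_prime_gene != g5$gene_id || spec$three_prime_gene != g3$gene_id)
    stop("fusion spec names genes '", spec$five_prime_gene, "'/'",
         spec$three_prime_gene, "' but got '", g5$gene_id, "'/'", g3$gene_id, "'")
  validate_fusion_spec(spec, g5, g3)
  k <- spec$last_5p_exon; m <- spec$first_3p_exon; n3 <- n_exons(g3)
  five <- paste(g5$exons[seq_len(k)], collapse = "")
  three_exons <- g3$exons[m:n3]
  if (isoform == "plusKTS") {
    j <- spec$kts_junction_after_exon
    if (j < m || j >= n3)
      stop("kts_junction_after_exon ", j,
           " is not an internal junction of the fused 3' portion (exons ",
           m, "-", n3, ")")
    pos <- j - m + 1L  # insertion goes after this element of three_exons
    three <- paste(c(three_exons[seq_len(pos)], spec$kts_insertion,
                     three_exons[(pos + 1L):length(three_exons)]),
                   collapse = "")
  } else {
    three <- paste(three_exons, collapse = "")
  }
  paste0(five, three)
}

#' Read an exon annotation table
#'
#' Tab-separated with columns `gene_id`, `transcript_id`, `exon_index`,
#' `exon_sequence`. Exon indices must be 1..n consecutive per gene.
#'
#' @param path TSV file path.
#' @return named list of [gene_model()]s.
#' @export
read_annotation_tsv <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          colClasses = list(character = c("gene_id", "transcript_id", "exon_sequence")))
  need <- c("gene_id", "transcript_id", "exon_index", "exon_sequence")
  if (!all(need %in% names(dt)))
    stop("malformed annotation: need columns ", paste(need, collapse = ", "))
  models <- lapply(split(dt, by = "gene_id", sorted = FALSE), function(g) {
    g <- g[order(exon_index)]
    if (!identical(as.integer(g$exon_index), seq_len(nrow(g))))
      stop("malformed annotation: gene '", g$gene_id[1],
           "' exon indices are not 1..n consecutive")
    gene_model(g$gene_id[1], g$exon_sequence, g$transcript_id[1])
  })
  names(models) <- vapply(models, `[[`, "", "gene_id")
  models
}

#' Write an exon annotation table
#' @param models list of [gene_model()]s.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_annotation_tsv <- function(models, path) {
  dt <- data.table::rbindlist(lapply(models, function(g)
    data.table::data.table(gene_id = g$gene_id, transcript_id = g$transcript_id,
                           exon_index = seq_along(g$exons),
                           exon_sequence = g$exons)))
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}

#' Read a fusion spec from JSON
#' @param path JSON file with the [fusion_spec()] fields.
#' @return a [fusion_spec()].
#' @export
read_fusion_spec <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("five_prime_gene", "last_5p_exon", "three_prime_gene", "first_3p_exon")
  missing <- setdiff(need, names(x))
  if (length(missing))
    stop("fusion spec JSON missing field(s): ", paste(missing, collapse = ", "))
  fusion_spec(x$five_prime_gene, x$last_5p_exon, x$three_prime_gene,
              x$first_3p_exon,
              kts_insertion = x$kts_insertion %||% "AAGACGTCT",
              kts_junction_after_exon = x$kts_junction_after_exon %||% x$first_3p_exon)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
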