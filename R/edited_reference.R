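#' Build the edited (split) reference transcriptome
#'
#' Replaces each fusion partner gene by its 5' and 3' half-transcripts, passes
#' every other gene through unchanged as a background feature, and constructs
#' a junction panel: the fusion breakpoint contig plus one diagnostic contig
#' per isoform (+KTS and -KTS), each carrying `flank_w` bases on both sides of
#' its junction point. Quantification runs against half + background features;
#' the full fusion sequence appears only in the junction panel (and in the
#' read simulator).
#'
#' @param annotation named list of [gene_model()]s.
#' @param specs list of [fusion_spec()]s (may be empty).
#' @param flank_w flank width in nt on each side of a junction point; must be
#'   at least the k-mer seed length used downstream (default 30).
#' @return object of class `edited_reference`: lists `half_features`,
#'   `background_features`, `junction_panel` (each element carries
#'   `feature_id`/`junction_id` and `sequence`; junction entries carry a
#'   `diagnostic` flag and an `isoform` tag), plus `flank_w`.
#' @export
build_edited_reference <- function(annotation, specs = list(), flank_w = 30L) {
  if (inherits(specs, "fusion_spec")) specs <- list(specs)
  ids <- vapply(annotation, `[[`, "", "gene_id")
  if (anyDuplicated(ids))
    stop("malformed annotation: duplicate gene ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  names(annotation) <- ids
  flank_w <- as.integer(flank_w)

  split_ids <- character(0)
  half_features <- list()
  junction_panel <- list()
  for (spec in specs) {
    for (g in c(spec$five_prime_gene, spec$three_prime_gene))
      if (!g %in% ids) stop("fusion spec names unknown gene '", g, "'")
    g5 <- annotation[[spec$five_prime_gene]]
    g3 <- annotation[[spec$three_prime_gene]]
    validate_fusion_spec(spec, g5, g3)
    half_features <- c(half_features,
                       split_transcript(g5, spec$last_5p_exon),
                       split_transcript(g3, spec$first_3p_exon - 1L))
    junction_panel <- c(junction_panel, build_junction_panel(g5, g3, spec, flank_w))
    split_ids <- c(split_ids, spec$five_prime_gene, spec$three_prime_gene)
  }

  background_features <- lapply(annotation[setdiff(ids, split_ids)], function(g)
    list(feature_id = g$gene_id, sequence = gene_sequence(g)))
  names(background_features) <- NULL
  names(half_features) <- NULL

  hf_ids <- vapply(half_features, `[[`, "", "feature_id")
  if (anyDuplicated(hf_ids))
    stop("duplicate half-feature ids (a gene named by two specs?): ",
         paste(unique(hf_ids[duplicated(hf_ids)]), collapse = ", "))

  structure(list(half_features = half_features,
                 background_features = background_features,
                 junction_panel = junction_panel,
                 flank_w = flank_w),
            class = "edited_reference")
}

# clipped flank helpers: take at most w bases, warn when fewer exist
take_tail <- function(s, w, what) {
  if (nchar(s) < w) {
    warning("junction contig: only ", nchar(s), " nt available for ", what,
            " (flank_w = ", w, ")")
    return(s)
  }
  substr(s, nchar(s) - w + 1L, nchar(s))
}
take_head <- function(s, w, what) {
  if (nchar(s) < w) {
    warning("junction contig: only ", nchar(s), " nt available for ", what,
            " (flank_w = ", w, ")")
    return(s)
  }
  substr(s, 1L, w)
}

build_junction_panel <- function(g5, g3, spec, flank_w) {
  k <- spec$last_5p_exon; m <- spec$first_3p_exon; n3 <- n_exons(g3)
  five_ctx <- paste(g5$exons[seq_len(k)], collapse = "")
  fused3_minus <- paste(g3$exons[m:n3], collapse = "")
  bp <- paste0(take_tail(five_ctx, flank_w, "5' breakpoint flank"),
               take_head(fused3_minus, flank_w, "3' breakpoint flank"))

  # KTS junction: between 3'-partner exon j and exon j+1, with (plus) or
  # without (minus) the insertion. Contigs are centred on that junction.
  j <- spec$kts_junction_after_exon
  up <- paste(g3$exons[m:j], collapse = "")
  down <- paste(g3$exons[(j + 1L):n3], collapse = "")
  up_fl <- take_tail(up, flank_w, "KTS upstream flank")
  down_fl <- take_head(down, flank_w, "KTS downstream flank")
  plus_core <- paste0(up_fl, spec$kts_insertion, down_fl)
  minus_core <- paste0(up_fl, down_fl)

  fid <- paste0(spec$five_prime_gene, "-", spec$three_prime_gene)
  list(
    list(junction_id = paste0(fid, "_breakpoint"), sequence = bp,
         diagnostic = FALSE, isoform = NA_character_),
    list(junction_id = paste0(fid, "_plusKTS"), sequence = plus_core,
         diagnostic = TRUE, isoform = "plusKTS"),
    list(junction_id = paste0(fid, "_minusKTS"), sequence = minus_core,
         diagnostic = TRUE, isoform = "minusKTS")
  )
}

#' @export
print.edited_reference <- function(x, ...) {
  cat(sprintf("edited_reference: %d half-features, %d background features, %d junction contigs (flank_w = %d)\n",
              length(x$half_features), length(x$background_features),
              length(x$junction_panel), x$flank_w))
  invisible(x)
}

#' All countable features of an edited reference
#'
#' Half-features then background features, as a named character vector of
#' sequences (names are feature ids). Junction contigs are excluded: they are
#' consumed only by [count_isoform_junctions()].
#'
#' @param ref an [build_edited_reference()] result.
#' @return named character vector of feature sequences.
#' @export
reference_features <- function(ref) {
  stopifnot(inherits(ref, "edited_reference"))
  feats <- c(ref$half_features, ref$background_features)
  stats::setNames(vapply(feats, `[[`, "", "sequence"),
                  vapply(feats, `[[`, "", "feature_id"))
}

#' Write / read an edited reference as FASTA
#'
#' One record per feature, record id = feature id. Junction contigs are
#' written with their `junction_id` and a `| junction diagnostic=` suffix in
#' the description so a round-trip restores the panel.
#'
#' @param ref an `edited_reference`.
#' @param path FASTA path.
#' @return `path` invisibly for the writer; an `edited_reference` for the reader.
#' @export
write_reference_fasta <- function(ref, path) {
  stopifnot(inherits(ref, "edited_reference"))
  feats <- reference_features(ref)
  jseq <- vapply(ref$junction_panel, `[[`, "", "sequence")
  jid <- vapply(ref$junction_panel, `[[`, "", "junction_id")
  jdiag <- vapply(ref$junction_panel, `[[`, TRUE, "diagnostic")
  jiso <- vapply(ref$junction_panel, function(x) x$isoform %||% NA_character_, "")
  jnames <- sprintf("%s junction diagnostic=%s isoform=%s", jid,
                    ifelse(jdiag, "yes", "no"), ifelse(is.na(jiso), ".", jiso))
  seqs <- Biostrings::DNAStringSet(c(feats, stats::setNames(jseq, jnames)))
  Biostrings::writeXStringSet(seqs, path, width = 80L)
  invisible(path)
}

#' @rdname write_reference_fasta
#' @export
read_reference_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  nm <- names(seqs)
  is_j <- grepl(" junction ", nm, fixed = TRUE)
  feats <- lapply(which(!is_j), function(i)
    list(feature_id = nm[i], sequence = as.character(seqs[[i]])))
  panel <- lapply(which(is_j), function(i) {
    parts <- strsplit(nm[i], " ", fixed = TRUE)[[1]]
    iso <- sub("^isoform=", "", grep("^isoform=", parts, value = TRUE))
    list(junction_id = parts[1], sequence = as.character(seqs[[i]]),
         diagnostic = any(parts == "diagnostic=yes"),
         isoform = if (iso == ".") NA_character_ else iso)
  })
  is_half <- grepl("_(5|3)p$", vapply(feats, `[[`, "", "feature_id"))
  halves <- lapply(feats[is_half], function(f) {
    f$source_gene <- sub("_(5|3)p$", "", f$feature_id)
    f
  })
  structure(list(half_features = halves,
                 background_features = feats[!is_half],
                 junction_panel = panel,
                 flank_w = NA_integer_),
            class = "edited_reference")
}

#' Detect a fusion breakpoint from junction-spanning reads
#'
#' Scans all candidate exon pairs (k, m) and, for each, counts reads that can
#' be written as (suffix of 5'-partner exons 1..k) + (prefix of 3'-partner
#' sequence starting at exon m) with at least `min_anchor` exactly matching
#' bases on each side of the junction. Returns the pair with maximal support;
#' ties are broken by smaller k, then smaller m. When no read supports any
#' junction the result carries `support = 0` and NA exon indices (not an
#' error).
#'
#' @param junction_reads character vector of transcript-oriented read
#'   sequences (forward orientation over the fusion).
#' @param g5,g3 [gene_model()]s of the candidate partners.
#' @param min_anchor minimum exact-match anchor on each side (>= 10).
#' @return list with `five_prime_exon` (k), `three_prime_exon` (m), `support`.
#' @export
detect_breakpoint <- function(junction_reads, g5, g3, min_anchor = 20L) {
  min_anchor <- as.integer(min_anchor)
  if (min_anchor < 10L) stop("min_anchor must be >= 10")
  reads <- as.character(junction_reads)
  n5 <- n_exons(g5); n3 <- n_exons(g3)
  cum5 <- vapply(seq_len(n5 - 1L), function(k)
    paste(g5$exons[seq_len(k)], collapse = ""), "")
  ctx3 <- vapply(2L:n3, function(m)
    paste(g3$exons[m:n3], collapse = ""), "")
  support <- matrix(0L, nrow = n5 - 1L, ncol = n3 - 1L)  # [k, m-1]

  for (r in reads) {
    L <- nchar(r)
    if (L < 2L * min_anchor) next
    hit <- matrix(FALSE, nrow = n5 - 1L, ncol = n3 - 1L)
    for (p in min_anchor:(L - min_anchor)) {
      pre <- substr(r, 1L, p)
      suf <- substr(r, p + 1L, L)
      kk <- which(endsWith(cum5, pre))
      if (!length(kk)) next
      mm <- which(startsWith(ctx3, suf))
      if (!length(mm)) next
      hit[kk, mm] <- TRUE
    }
    support <- support + hit
  }

  if (all(support == 0L))
    return(list(five_prime_exon = NA_integer_, three_prime_exon = NA_integer_,
                support = 0L))
  best <- max(support)
  idx <- which(support == best, arr.ind = TRUE)
  idx <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]  # smallest k then m
  list(five_prime_exon = as.integer(idx[1L, 1L]),
       three_prime_exon = as.integer(idx[1L, 2L] + 1L),
       support = as.integer(best))
}
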