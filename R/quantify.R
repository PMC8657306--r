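#' Exact k-mer index over reference features
#'
#' Maps every k-mer occurring in any countable feature (half + background) to
#' the set of feature ids containing it. This is the seed table of the
#' package's deterministic read assigner, the self-contained substitute for an
#' external aligner: reads are placed by intersecting the feature sets of
#' their k-mers, so k-mers straddling a split boundary (present in neither
#' half) simply drop out.
#'
#' @param ref an `edited_reference`, or a named character vector of feature
#'   sequences.
#' @param k_mer k-mer length, in `[15, 31]` (default 21).
#' @return object of class `kmer_index`: environment `map` (k-mer ->
#'   character vector of feature ids), `k`, `feature_ids`, `lengths`.
#' @export
index_reference <- function(ref, k_mer = 21L) {
  k <- as.integer(k_mer)
  if (k < 15L || k > 31L) stop("k_mer must be in [15, 31]")
  feats <- if (inherits(ref, "edited_reference")) reference_features(ref)
           else ref
  if (is.null(names(feats)) || any(!nzchar(names(feats))))
    stop("feature sequences must be named by feature id")
  too_short <- nchar(feats) < k
  if (any(too_short)) {
    warning("excluding ", sum(too_short), " feature(s) shorter than k = ", k,
            " from the index: ", paste(names(feats)[too_short], collapse = ", "))
  }
  lens <- nchar(feats)
  feats_idx <- feats[!too_short]
  pieces <- lapply(names(feats_idx), function(fid) {
    s <- feats_idx[[fid]]
    n <- nchar(s) - k + 1L
    data.table::data.table(kmer = unique(substring(s, 1:n, k:(n + k - 1L))),
                           fid = fid)
  })
  dt <- data.table::rbindlist(pieces)
  # k-mers containing N (none in valid references, but guard) never match reads
  dt <- dt[!grepl("N", kmer, fixed = TRUE)]
  map <- new.env(parent = emptyenv(), size = nrow(dt))
  sets <- split(dt$fid, dt$kmer)
  list2env(sets, map)
  structure(list(map = map, k = k, feature_ids = names(feats),
                 lengths = stats::setNames(as.integer(lens), names(feats))),
            class = "kmer_index")
}

#' @export
print.kmer_index <- function(x, ...) {
  cat(sprintf("kmer_index: k = %d, %d features, %d distinct k-mers\n",
              x$k, length(x$feature_ids), length(x$map)))
  invisible(x)
}

read_kmers <- function(seq, k) {
  n <- nchar(seq) - k + 1L
  if (n < 1L) return(character(0))
  substring(seq, 1:n, k:(n + k - 1L))
}

# vectorized reverse complement (FR mate-2 handling)
revcomp_vec <- function(x) {
  if (!length(x)) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Assign read pairs to reference features
#'
#' For each pair, the candidate feature set is the intersection of the index
#' feature sets over all k-mers present (in the index) in either mate. Pairs
#' are assumed FR-oriented (standard paired-end): mate 2 is
#' reverse-complemented before k-mer lookup, since the index holds the
#' transcript strand only. K-mers absent from the index — junction-spanning,
#' error-bearing, or N-containing — are skipped; a pair with no indexed k-mer
#' is unassigned, as is a pair whose candidate intersection is empty (e.g. a
#' chimeric artifact with mates in two features, or a mate straddling a split
#' boundary with a full k-mer on each side). Under `unique_only` a pair is
#' counted iff its candidate set is a singleton; under `fractional` it
#' contributes `1/|candidates|` to each candidate.
#'
#' @param reads a `read_set` (see [read_set()]) or a data.frame with columns
#'   `read1`, `read2`.
#' @param index a [index_reference()] result built with the run's k-mer size.
#' @param policy `"unique_only"` (default) or `"fractional"`.
#' @return list with `counts` (named numeric vector over all features,
#'   integer-valued under `unique_only`), `assigned_total` (number of fully or
#'   fractionally assigned pairs), `unassigned` (pair count).
#' @export
assign_reads <- function(reads, index, policy = c("unique_only", "fractional")) {
  policy <- match.arg(policy)
  stopifnot(inherits(index, "kmer_index"))
  reads <- as_read_frame(reads)
  counts <- stats::setNames(numeric(length(index$feature_ids)), index$feature_ids)
  assigned <- 0
  unassigned <- 0L
  k <- index$k
  map <- index$map
  rc2 <- revcomp_vec(reads$read2)
  for (i in seq_len(nrow(reads))) {
    kms <- c(read_kmers(reads$read1[i], k), read_kmers(rc2[i], k))
    sets <- mget(kms, envir = map, ifnotfound = list(NULL))
    sets <- sets[!vapply(sets, is.null, TRUE)]
    if (!length(sets)) { unassigned <- unassigned + 1L; next }
    tab <- table(unlist(sets, use.names = FALSE))
    cand <- names(tab)[tab == length(sets)]
    if (!length(cand)) { unassigned <- unassigned + 1L; next }
    if (policy == "unique_only") {
      if (length(cand) == 1L) {
        counts[cand] <- counts[cand] + 1
        assigned <- assigned + 1
      } else unassigned <- unassigned + 1L
    } else {
      counts[cand] <- counts[cand] + 1 / length(cand)
      assigned <- assigned + 1
    }
  }
  list(counts = counts, assigned_total = assigned, unassigned = unassigned)
}

#' RPKM normalization
#'
#' `rpkm[i, s] = counts[i, s] * 1e9 / (N_s * L_i)` — reads per kilobase of
#' feature per million assigned read pairs. `N_s` is the per-sample assigned
#' total, not the raw pair count, which makes the conservation identity
#' `sum_i rpkm[i, s] * L_i = 1e9` exact whenever the column sums to `N_s`.
#'
#' @param counts feature x sample numeric matrix.
#' @param lengths feature lengths in nt (recycled along rows), all > 0.
#' @param assigned_totals per-sample assigned pair counts (length = ncol).
#' @return RPKM matrix with the dimensions and dimnames of `counts`.
#' @export
compute_rpkm <- function(counts, lengths, assigned_totals) {
  counts <- as.matrix(counts)
  if (length(lengths) != nrow(counts))
    stop("lengths (", length(lengths), ") do not match features (", nrow(counts), ")")
  if (length(assigned_totals) != ncol(counts))
    stop("assigned_totals (", length(assigned_totals),
         ") do not match samples (", ncol(counts), ")")
  if (any(lengths <= 0)) stop("feature lengths must be > 0")
  if (any(assigned_totals < 0)) stop("assigned_totals must be >= 0")
  zero <- assigned_totals == 0
  if (any(zero))
    warning("sample(s) with zero assigned reads yield all-zero RPKM columns: ",
            paste(colnames(counts)[zero] %||% which(zero), collapse = ", "))
  denom <- outer(as.numeric(lengths), as.numeric(assigned_totals))
  rpkm <- counts * 1e9 / denom
  rpkm[, zero] <- 0
  rpkm
}

#' Expression matrix with sample metadata
#'
#' The pipeline's container for quantified samples: raw counts, the matching
#' RPKM matrix, feature lengths, and per-sample metadata (shRNA identity, DOX
#' status, timepoint).
#'
#' @param counts feature x sample matrix (dimnames required).
#' @param lengths named feature lengths (nt).
#' @param samples data.frame with columns `sample_id`, `shrna` (one of
#'   `"sh2"`, `"sh3"`, `"NT"`, `"none"`), `dox` (logical), `timepoint_h`.
#' @param assigned_totals per-sample assigned totals; defaults to column sums.
#' @return object of class `expression_matrix` with elements `counts`,
#'   `rpkm`, `lengths`, `samples`, `assigned_totals`.
#' @export
expression_matrix <- function(counts, lengths, samples,
                              assigned_totals = colSums(counts)) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have feature rownames and sample colnames")
  if (!all(rownames(counts) %in% names(lengths)))
    stop("lengths missing for feature(s): ",
         paste(setdiff(rownames(counts), names(lengths)), collapse = ", "))
  lengths <- lengths[rownames(counts)]
  need <- c("sample_id", "shrna", "dox", "timepoint_h")
  if (!all(need %in% names(samples)))
    stop("samples metadata needs columns ", paste(need, collapse = ", "))
  samples <- as.data.frame(samples)
  if (!identical(as.character(samples$sample_id), colnames(counts)))
    stop("samples$sample_id must match counts colnames in order")
  rpkm <- compute_rpkm(counts, lengths, assigned_totals)
  structure(list(counts = counts, rpkm = rpkm,
                 lengths = stats::setNames(as.numeric(lengths), rownames(counts)),
                 samples = samples,
                 assigned_totals = stats::setNames(as.numeric(assigned_totals),
                                                   colnames(counts))),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d features x %d samples (shRNA: %s)\n",
              nrow(x$counts), ncol(x$counts),
              paste(unique(x$samples$shrna), collapse = ", ")))
  invisible(x)
}

#' Count +KTS / -KTS isoform reads against the junction panel
#'
#' A read (either mate; mate 2 is reverse-complemented, FR orientation) is
#' classified `+KTS` when it contains a `flank_w`-mer that occurs in the +KTS
#' diagnostic junction contig and not in the -KTS contig; `-KTS`
#' symmetrically. Reads that touch the panel (share a w-mer
#' with any junction contig) but match no diagnostic w-mer — error-bearing or
#' too short an overlap — are counted `unclassified_junction` (a read whose
#' every panel w-mer is destroyed by errors is invisible and counted
#' nowhere). The partition
#' is disjoint: a read matching diagnostic w-mers of both isoforms (not
#' possible with error-free data) is unclassified.
#'
#' @param reads a `read_set` or data.frame with `read1`, `read2`.
#' @param junction_panel the `junction_panel` element of an
#'   `edited_reference` (must contain exactly one diagnostic contig per
#'   isoform).
#' @param flank_w diagnostic word length; defaults to the reference's flank.
#' @return list of class `isoform_counts`: `plus_kts`, `minus_kts`,
#'   `unclassified_junction`.
#' @export
count_isoform_junctions <- function(reads, junction_panel, flank_w = 30L) {
  w <- as.integer(flank_w)
  iso <- vapply(junction_panel, function(x) x$isoform %||% NA_character_, "")
  diag <- vapply(junction_panel, `[[`, TRUE, "diagnostic")
  i_plus <- which(diag & iso == "plusKTS")
  i_minus <- which(diag & iso == "minusKTS")
  if (length(i_plus) != 1L || length(i_minus) != 1L)
    stop("junction panel must contain exactly one diagnostic contig per isoform")
  plus_w <- read_kmers(junction_panel[[i_plus]]$sequence, w)
  minus_w <- read_kmers(junction_panel[[i_minus]]$sequence, w)
  plus_only <- setdiff(plus_w, minus_w)
  minus_only <- setdiff(minus_w, plus_w)
  any_w <- unique(c(plus_w, minus_w,
                    unlist(lapply(junction_panel, function(x)
                      read_kmers(x$sequence, w)))))

  reads <- as_read_frame(reads)
  plus <- 0L; minus <- 0L; uncl <- 0L
  rc2 <- revcomp_vec(reads$read2)
  for (i in seq_len(nrow(reads))) {
    kms <- c(read_kmers(reads$read1[i], w), read_kmers(rc2[i], w))
    hit_plus <- any(kms %in% plus_only)
    hit_minus <- any(kms %in% minus_only)
    if (hit_plus && !hit_minus) plus <- plus + 1L
    else if (hit_minus && !hit_plus) minus <- minus + 1L
    else if (hit_plus && hit_minus) uncl <- uncl + 1L
    else if (any(kms %in% any_w)) uncl <- uncl + 1L
  }
  structure(list(plus_kts = plus, minus_kts = minus,
                 unclassified_junction = uncl),
            class = "isoform_counts")
}

#' @export
print.isoform_counts <- function(x, ...) {
  cat(sprintf("isoform_counts: +KTS %d, -KTS %d, unclassified %d\n",
              x$plus_kts, x$minus_kts, x$unclassified_junction))
  invisible(x)
}

#' Knockdown time-course summary
#'
#' Orders per-feature RPKM over (shRNA, DOX, timepoint) and flags features
#' whose DOX series decreases: each step may rise by at most a tolerance
#' fraction (noise allowance) and the final value must fall below
#' `(1 - tolerance)` of the initial one — so a flat control series is not
#' flagged. Fusion expression is read out on the 3'-partner half-feature
#' (3' partner reads represent fusion expression when the wild-type 3'
#' partner is silent).
#'
#' @param expr an [expression_matrix()] with timepoint metadata and at least
#'   two DOX timepoints.
#' @param features feature ids to summarize.
#' @param tolerance per-step noise allowance as a fraction (default 0.1).
#' @return list with `series` (data.frame: feature, shrna, dox, timepoint_h,
#'   rpkm, ordered by feature/shrna/timepoint) and `decreasing` (data.frame:
#'   feature, shrna, decreasing flag over that shRNA's DOX timepoints).
#' @export
knockdown_timecourse <- function(expr, features, tolerance = 0.1) {
  stopifnot(inherits(expr, "expression_matrix"))
  unknown <- setdiff(features, rownames(expr$rpkm))
  if (length(unknown))
    stop("unknown feature id(s): ", paste(unknown, collapse = ", "))
  md <- expr$samples
  if (sum(md$dox) > 0 && length(unique(md$timepoint_h[md$dox])) < 2L)
    stop("need at least two DOX timepoints")
  ord <- order(md$shrna, md$timepoint_h)
  series <- do.call(rbind, lapply(features, function(f)
    data.frame(feature = f, shrna = md$shrna[ord], dox = md$dox[ord],
               timepoint_h = md$timepoint_h[ord],
               rpkm = as.numeric(expr$rpkm[f, ord]),
               stringsAsFactors = FALSE)))
  dec <- do.call(rbind, lapply(features, function(f) {
    per <- lapply(split(seq_len(nrow(md)), md$shrna), function(ix) {
      ix <- ix[md$dox[ix]]
      if (length(ix) < 2L) return(NA)
      v <- as.numeric(expr$rpkm[f, ix[order(md$timepoint_h[ix])]])
      steps_ok <- all(v[-1] <= v[-length(v)] * (1 + tolerance))
      net_drop <- v[length(v)] < v[1] * (1 - tolerance)
      steps_ok && net_drop
    })
    data.frame(feature = f, shrna = names(per),
               decreasing = unlist(per), row.names = NULL,
               stringsAsFactors = FALSE)
  }))
  dec <- dec[!is.na(dec$decreasing), , drop = FALSE]
  list(series = series, decreasing = dec)
}
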