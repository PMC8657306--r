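#' Target-calling configuration
#'
#' Parameters of the two-shRNA intersection rule: a gene is a fusion target
#' when it moves at least a fraction `fc_threshold` up or down versus the
#' non-targeting control under BOTH knockdown hairpins, and the compared pair
#' passes an expression gate that extracts truly expressed genes.
#'
#' @param fc_threshold fold-change fraction theta in (0, 1); down means
#'   `fc <= 1 - theta`, up means `fc >= 1 + theta` (default 0.25).
#' @param expr_cutoff RPKM gate c > 0: `max(rpkm_NT, rpkm_shX)` must exceed
#'   `c` for each required comparison (default 5).
#' @param timepoint_h calling timepoint in hours post-induction (default 32);
#'   if a hairpin lacks that timepoint its nearest available DOX timepoint is
#'   used, with a message.
#' @param require_both_shrnas require agreement of sh2 and sh3 (default TRUE).
#' @return object of class `target_call_config`.
#' @export
target_call_config <- function(fc_threshold = 0.25, expr_cutoff = 5,
                               timepoint_h = 32, require_both_shrnas = TRUE) {
  if (!(fc_threshold > 0 && fc_threshold < 1))
    stop("fc_threshold must be in (0, 1)")
  if (!(expr_cutoff > 0)) stop("expr_cutoff must be > 0")
  structure(list(fc_threshold = fc_threshold, expr_cutoff = expr_cutoff,
                 timepoint_h = timepoint_h,
                 require_both_shrnas = isTRUE(require_both_shrnas)),
            class = "target_call_config")
}

# per-shRNA mean RPKM column at the calling timepoint (nearest DOX fallback,
# replicates averaged)
shrna_column <- function(rpkm, samples, shrna, timepoint_h) {
  sel <- samples$shrna == shrna & samples$dox
  if (!any(sel))
    stop("configuration error: no DOX sample for shRNA '", shrna, "'")
  tps <- samples$timepoint_h[sel]
  if (!any(tps == timepoint_h)) {
    tp <- tps[which.min(abs(tps - timepoint_h))]
    message("shRNA '", shrna, "' has no ", timepoint_h,
            " h sample; using nearest DOX timepoint ", tp, " h")
  } else tp <- timepoint_h
  idx <- which(sel & samples$timepoint_h == tp)
  if (length(idx) == 1L) as.numeric(rpkm[, idx])
  else rowMeans(rpkm[, idx, drop = FALSE])
}

#' Call fusion target genes with the two-shRNA intersection rule
#'
#' Per gene and hairpin, the fold change is `fc_shX = rpkm_shX / rpkm_NT` at
#' the calling timepoint. A comparison votes "down" when `fc <= 1 - theta`,
#' "up" when `fc >= 1 + theta`, and only counts when
#' `max(rpkm_NT, rpkm_shX) > c` (the truly-expressed gate). With
#' `require_both_shrnas` a gene is called only when sh2 and sh3 agree in
#' direction and both pass the gate; genes with conflicting directions are
#' excluded. Zero denominators follow explicit rules: `rpkm_NT = 0` with
#' `rpkm_shX > c` is an up vote (infinite fold change); `rpkm_shX = 0` with
#' `rpkm_NT > c` is a down vote. No pseudocount and no multiple-testing step:
#' the rule is a deterministic filter.
#'
#' @param expr an [expression_matrix()], `rpkm_table` (see [read_rpkm_tsv()]),
#'   or a list with `rpkm` matrix and `samples` metadata containing DOX sh2,
#'   sh3 and NT samples.
#' @param cfg a [target_call_config()].
#' @return object of class `target_call_result`: `up` / `down` gene-id
#'   vectors, `table` (per-gene rpkm_NT, rpkm_sh2, rpkm_sh3, fc_sh2, fc_sh3,
#'   direction), and `config`.
#' @export
call_targets <- function(expr, cfg = target_call_config()) {
  stopifnot(inherits(cfg, "target_call_config"))
  rpkm <- expr$rpkm
  samples <- expr$samples
  if (is.null(rpkm) || is.null(samples))
    stop("expr must carry an rpkm matrix and samples metadata")
  need <- c("NT", "sh2", "sh3")
  have <- unique(samples$shrna[samples$dox])
  if (!all(need %in% have))
    stop("configuration error: missing DOX sample(s) for ",
         paste(setdiff(need, have), collapse = ", "),
         " at timepoint ", cfg$timepoint_h, " h")
  nt <- shrna_column(rpkm, samples, "NT", cfg$timepoint_h)
  sh2 <- shrna_column(rpkm, samples, "sh2", cfg$timepoint_h)
  sh3 <- shrna_column(rpkm, samples, "sh3", cfg$timepoint_h)

  theta <- cfg$fc_threshold; c0 <- cfg$expr_cutoff

  vote <- function(sh) {
    fc <- ifelse(nt > 0, sh / nt, ifelse(sh > 0, Inf, NA_real_))
    gate <- pmax(nt, sh) > c0
    dir <- rep(NA_character_, length(sh))
    dir[gate & !is.na(fc) & fc <= 1 - theta] <- "down"
    dir[gate & !is.na(fc) & fc >= 1 + theta] <- "up"
    list(fc = fc, dir = dir)
  }
  v2 <- vote(sh2); v3 <- vote(sh3)

  if (cfg$require_both_shrnas) {
    dir <- ifelse(!is.na(v2$dir) & !is.na(v3$dir) & v2$dir == v3$dir,
                  v2$dir, NA_character_)
  } else {
    agree <- !is.na(v2$dir) & !is.na(v3$dir) & v2$dir != v3$dir  # conflict
    dir <- ifelse(!is.na(v2$dir), v2$dir, v3$dir)
    dir[agree] <- NA_character_
  }

  genes <- rownames(rpkm)
  tab <- data.frame(gene = genes, rpkm_NT = nt, rpkm_sh2 = sh2, rpkm_sh3 = sh3,
                    fc_sh2 = v2$fc, fc_sh3 = v3$fc, direction = dir,
                    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(up = genes[!is.na(dir) & dir == "up"],
                 down = genes[!is.na(dir) & dir == "down"],
                 table = tab, config = cfg),
            class = "target_call_result")
}

#' @export
print.target_call_result <- function(x, ...) {
  cat(sprintf("target_call_result: %d up, %d down (theta = %g, cutoff = %g RPKM, %g h)\n",
              length(x$up), length(x$down), x$config$fc_threshold,
              x$config$expr_cutoff, x$config$timepoint_h))
  invisible(x)
}

#' Gene set
#'
#' @param name set name.
#' @param genes character vector of gene symbols; case-normalized to upper
#'   and deduplicated.
#' @param provenance free-text origin note.
#' @return object of class `gene_set`.
#' @export
gene_set <- function(name, genes, provenance = "") {
  structure(list(name = name, genes = unique(toupper(trimws(as.character(genes)))),
                 provenance = provenance),
            class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("gene_set '%s': %d genes\n", x$name, length(x$genes)))
  invisible(x)
}

#' Overlap report between two or three gene sets
#'
#' Intersections on case-normalized symbols; the headline fraction is the
#' share of set `a` present in all compared sets (the Venn-diagram number:
#' "x% of a's genes replicate in the other lines").
#'
#' @param a,b [gene_set()]s; `c` optional third set.
#' @return list with `ab`, `ac`, `bc`, `abc` intersection vectors (pairwise
#'   involving `c` only when supplied), `sizes`, `fraction_of_a` (raw) and
#'   `percent_of_a` (rounded to integer percent).
#' @export
overlap_sets <- function(a, b, c = NULL) {
  stopifnot(inherits(a, "gene_set"), inherits(b, "gene_set"))
  ab <- intersect(a$genes, b$genes)
  out <- list(ab = ab)
  if (!is.null(c)) {
    stopifnot(inherits(c, "gene_set"))
    out$ac <- intersect(a$genes, c$genes)
    out$bc <- intersect(b$genes, c$genes)
    out$abc <- intersect(ab, c$genes)
    shared <- out$abc
  } else shared <- ab
  frac <- if (length(a$genes)) length(shared) / length(a$genes) else 0
  out$sizes <- vapply(out[setdiff(names(out), "sizes")], length, 0L)
  out$fraction_of_a <- frac
  out$percent_of_a <- as.integer(round(100 * frac))
  out
}

#' Z-score gene sets from a per-gene expression vector
#'
#' Standardizes `x` over genes with the sample (n-1) standard deviation and
#' returns the high set (`Z > z_hi`) and low set (`Z < z_lo`). A
#' zero-variance vector yields two empty sets with a warning.
#'
#' @param expression named numeric vector of per-gene expression values
#'   (>= 3 genes, finite).
#' @param z_hi,z_lo thresholds (defaults +1 / -1).
#' @param name_prefix prefix for the returned set names.
#' @return list with `high` and `low` [gene_set()]s and the `z` vector.
#' @export
zscore_gene_sets <- function(expression, z_hi = 1, z_lo = -1,
                             name_prefix = "expr") {
  if (length(expression) < 3L)
    stop("need at least 3 genes to build Z-score sets")
  if (any(!is.finite(expression))) stop("expression values must be finite")
  if (is.null(names(expression)))
    names(expression) <- sprintf("G%d", seq_along(expression))
  s <- stats::sd(expression)
  if (s == 0) {
    warning("zero variance across genes; returning empty gene sets")
    z <- rep(0, length(expression)); names(z) <- names(expression)
  } else z <- (expression - mean(expression)) / s
  list(high = gene_set(paste0(name_prefix, "_high"), names(z)[z > z_hi],
                       provenance = sprintf("Z > %g", z_hi)),
       low = gene_set(paste0(name_prefix, "_low"), names(z)[z < z_lo],
                      provenance = sprintf("Z < %g", z_lo)),
       z = z)
}

#' Mean expression of gene sets per sample group
#'
#' For each (set, group) pair: the mean over the set's genes of each gene's
#' mean reads-per-million within the group. Genes absent from the matrix are
#' skipped and reported; a set with no genes present gets `NA` (missing, not
#' zero).
#'
#' @param rpm gene x sample matrix in reads-per-million (rownames = symbols).
#' @param sets list of [gene_set()]s.
#' @param groups factor or character vector of sample groups (length =
#'   ncol(rpm)).
#' @return list with `means` (set x group matrix) and `missing` (named list
#'   of symbols absent from the matrix per set).
#' @export
geneset_mean_expression <- function(rpm, sets, groups) {
  rpm <- as.matrix(rpm)
  if (length(groups) != ncol(rpm))
    stop("groups must have one entry per sample column")
  groups <- as.factor(groups)
  rn <- toupper(rownames(rpm))
  means <- matrix(NA_real_, nrow = length(sets), ncol = nlevels(groups),
                  dimnames = list(vapply(sets, `[[`, "", "name"),
                                  levels(groups)))
  missing <- stats::setNames(vector("list", length(sets)),
                             vapply(sets, `[[`, "", "name"))
  for (i in seq_along(sets)) {
    present <- sets[[i]]$genes[sets[[i]]$genes %in% rn]
    missing[[i]] <- setdiff(sets[[i]]$genes, rn)
    if (!length(present)) next
    sub <- rpm[match(present, rn), , drop = FALSE]
    for (g in levels(groups)) {
      cols <- which(groups == g)
      means[i, g] <- mean(rowMeans(sub[, cols, drop = FALSE]))
    }
  }
  list(means = means, missing = missing)
}
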