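# shared fixtures, built in code

# deterministic random gene model
rand_gene <- function(id, n_exons, exon_len = 150L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  gene_model(id, replicate(n_exons, paste(
    sample(c("A", "C", "G", "T"), exon_len, replace = TRUE), collapse = "")))
}

# small simulated world used across quantify tests
small_world <- function(seed = 11L, n_bg = 10L, ...) {
  cfg <- sim_config(seed = seed, n_background_genes = n_bg,
                    n_up = 2L, n_down = 2L, error_rate = 0, ...)
  tx <- simulate_transcriptome(cfg)
  list(cfg = cfg, tx = tx,
       ref = build_edited_reference(tx$annotation, list(tx$fusion)))
}

# background-only abundance vector for exactness tests
bg_abundance <- function(tx, seed = 1L) {
  set.seed(seed)
  bg <- setdiff(names(tx$annotation), c("PARTNER5", "PARTNER3"))
  ab <- stats::setNames(rep(0, length(bg) + 3L),
                        c("PARTNER5_wt", "fusion_plusKTS", "fusion_minusKTS", bg))
  ab[bg] <- stats::runif(length(bg), 5, 50)
  ab
}

# reverse complement (building FR-oriented mate-2 sequences by hand)
rc <- function(s)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))

# noise-free 4PL curve on a dose grid
fourpl_curve <- function(doses, top = 1, bottom = 0, ic50 = 0.1, hill = 1.5) {
  bottom + (top - bottom) / (1 + (doses / ic50)^hill)
}

expect_frozen <- function(object, expected, tol = 1e-12) {
  expect_equal(object, expected, tolerance = tol)
}
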