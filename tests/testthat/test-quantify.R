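test_that("index_reference enumerates k-mers and excludes short features", {
  set.seed(3)
  s <- paste(sample(c("A", "C", "G", "T"), 1000, replace = TRUE), collapse = "")
  idx <- index_reference(c(F1 = s), k_mer = 21)
  expect_lte(length(idx$map), 1000 - 21 + 1)
  expect_error(index_reference(c(F1 = s), k_mer = 10), "\\[15, 31\\]")
  expect_warning(idx2 <- index_reference(c(F1 = s, SHORT = "ACGTACGT"), 21),
                 "shorter than k")
  expect_false("SHORT" %in% unlist(as.list(idx2$map)))

  # split halves: boundary-straddling k-mers are in neither half
  g <- rand_gene("G", 2, exon_len = 100, seed = 4)
  h <- split_transcript(g, 1)
  feats <- stats::setNames(c(h[[1]]$sequence, h[[2]]$sequence),
                           c("G_5p", "G_3p"))
  idx3 <- index_reference(feats, 21)
  straddle <- substr(gene_sequence(g), 90, 110)  # spans the split
  expect_false(exists(straddle, envir = idx3$map, inherits = FALSE))
})

test_that("assign_reads reproduces simulator truth exactly on contained reads", {
  w <- small_world(seed = 11)
  idx <- index_reference(w$ref, 21)
  sim <- simulate_reads(w$cfg, w$tx, bg_abundance(w$tx), 1500)
  res <- assign_reads(sim$reads, idx, policy = "unique_only")
  tc <- sim$truth_counts
  expect_identical(unname(res$counts[names(tc)]), as.numeric(tc))
  expect_equal(res$assigned_total + res$unassigned, 1500)
  expect_equal(sum(res$counts), res$assigned_total)
})

test_that("chimeric pairs and junction-only pairs are unassigned", {
  g1 <- rand_gene("C1", 2, exon_len = 200, seed = 7)
  g2 <- rand_gene("C2", 2, exon_len = 200, seed = 8)
  feats <- stats::setNames(c(gene_sequence(g1), gene_sequence(g2)),
                           c("C1", "C2"))
  idx <- index_reference(feats, 21)
  # mate 1 from C1, mate 2 (FR) from C2: empty intersection
  chim <- read_set(substr(feats["C1"], 1, 100),
                   rc(substr(feats["C2"], 1, 100)))
  res <- assign_reads(chim, idx)
  expect_equal(res$assigned_total, 0)
  expect_equal(res$unassigned, 1L)
  # all-N read has no indexed k-mer
  nn <- read_set(strrep("N", 50), strrep("N", 50))
  expect_equal(assign_reads(nn, idx)$unassigned, 1L)
})

test_that("fusion pairs within the 5'-partner portion count toward the 5' half", {
  w <- small_world(seed = 12)
  idx <- index_reference(w$ref, 21)
  ab <- stats::setNames(rep(0, 13),
                        c("PARTNER5_wt", "fusion_plusKTS", "fusion_minusKTS",
                          sprintf("BG%03d", 1:10)))
  ab[c("fusion_plusKTS", "fusion_minusKTS")] <- c(5, 5)
  sim <- simulate_reads(w$cfg, w$tx, ab, 800)
  res <- assign_reads(sim$reads, idx)
  tc <- sim$truth_counts
  expect_equal(unname(res$counts["PARTNER5_5p"]),
               as.numeric(tc["PARTNER5_5p"]))
  expect_equal(unname(res$counts["PARTNER3_3p"]),
               as.numeric(tc["PARTNER3_3p"]))
  # junction-spanning and discordant pairs never land in half-features
  expect_equal(sum(res$counts), res$assigned_total)
  expect_equal(res$unassigned,
               sum(tc[c("junction", "discordant")], na.rm = TRUE))
})

test_that("fractional policy conserves mass and splits ambiguous pairs", {
  # two features sharing a 150 nt block: reads inside the block are ambiguous
  set.seed(15)
  shared <- paste(sample(c("A", "C", "G", "T"), 150, replace = TRUE),
                  collapse = "")
  u1 <- paste(sample(c("A", "C", "G", "T"), 150, replace = TRUE), collapse = "")
  u2 <- paste(sample(c("A", "C", "G", "T"), 150, replace = TRUE), collapse = "")
  feats <- c(FA = paste0(u1, shared), FB = paste0(u2, shared))
  idx <- index_reference(feats, 21)
  amb <- read_set(substr(shared, 1, 60), rc(substr(shared, 61, 120)))
  resU <- assign_reads(amb, idx, "unique_only")
  expect_equal(resU$assigned_total, 0)
  resF <- assign_reads(amb, idx, "fractional")
  expect_equal(unname(resF$counts[c("FA", "FB")]), c(0.5, 0.5))
  expect_equal(sum(resF$counts), resF$assigned_total)
})

test_that("compute_rpkm matches the formula and conserves mass", {
  expect_equal(compute_rpkm(matrix(10), 1000, 1e6)[1, 1], 10)
  expect_equal(compute_rpkm(matrix(0), 1000, 1e6)[1, 1], 0)
  set.seed(16)
  counts <- matrix(rpois(40, 50), nrow = 10,
                   dimnames = list(paste0("f", 1:10), paste0("s", 1:4)))
  lens <- sample(200:2000, 10)
  totals <- colSums(counts)
  rpkm <- compute_rpkm(counts, lens, totals)
  expect_equal(rpkm[3, 2], counts[3, 2] * 1e9 / (totals[2] * lens[3]),
               ignore_attr = TRUE)
  expect_equal(unname(colSums(rpkm * lens) / 1e9), rep(1, 4), tolerance = 1e-6)
  expect_warning(compute_rpkm(matrix(0), 10, 0), "zero assigned")
  expect_error(compute_rpkm(counts, lens[-1], totals), "do not match")
})

test_that("isoform junction counting recovers the planted +KTS fraction", {
  w <- small_world(seed = 13, kts_fraction = 0.7)
  kr <- simulate_junction_reads(w$cfg, w$tx, 1000, "kts")
  ic <- count_isoform_junctions(kr$reads, w$ref$junction_panel, 30)
  # error-free reads built to overlap by >= w: classification is exact
  expect_equal(ic$plus_kts, kr$truth_plus)
  expect_equal(ic$minus_kts, 1000L - kr$truth_plus)
  expect_equal(ic$unclassified_junction, 0L)
  # disjoint partition
  expect_equal(ic$plus_kts + ic$minus_kts + ic$unclassified_junction, 1000L)
  # binomial sanity: estimate within 3 sd of 0.7
  expect_lt(abs(ic$plus_kts / 1000 - 0.7), 3 * sqrt(0.7 * 0.3 / 1000))
})

test_that("isoform counts are zero for the absent isoform and panel is validated", {
  w <- small_world(seed = 14, kts_fraction = 0)
  kr <- simulate_junction_reads(w$cfg, w$tx, 200, "kts")
  ic <- count_isoform_junctions(kr$reads, w$ref$junction_panel, 30)
  expect_equal(ic$plus_kts, 0L)
  expect_equal(ic$minus_kts, 200L)
  no_plus <- w$ref$junction_panel[
    vapply(w$ref$junction_panel, function(x) !identical(x$isoform, "plusKTS"),
           TRUE)]
  expect_error(count_isoform_junctions(kr$reads, no_plus, 30),
               "exactly one diagnostic contig")
})

test_that("knockdown under one hairpin preserves the isoform ratio", {
  w <- small_world(seed = 17, kts_fraction = 0.6)
  pre <- simulate_junction_reads(w$cfg, w$tx, 1000, "kts", seed_offset = 50)
  post <- simulate_junction_reads(w$cfg, w$tx, 250, "kts", seed_offset = 51)
  ic_pre <- count_isoform_junctions(pre$reads, w$ref$junction_panel, 30)
  ic_post <- count_isoform_junctions(post$reads, w$ref$junction_panel, 30)
  expect_lt(ic_post$plus_kts + ic_post$minus_kts,
            ic_pre$plus_kts + ic_pre$minus_kts)
  f_pre <- ic_pre$plus_kts / 1000
  f_post <- ic_post$plus_kts / 250
  expect_lt(abs(f_post - f_pre),
            3 * sqrt(0.6 * 0.4) * sqrt(1 / 1000 + 1 / 250))
})

test_that("knockdown_timecourse flags DOX decay, not flat controls", {
  # construct RPKM directly: 3'-partner half decays, NT flat, 5' half of the
  # 3' partner identically zero
  feats <- c("PARTNER5_5p", "PARTNER3_3p", "PARTNER3_5p", "BG001")
  samples <- data.frame(
    sample_id = c("NT_8h", "NT_24h", "NT_32h", "sh3_8h", "sh3_24h", "sh3_32h"),
    shrna = rep(c("NT", "sh3"), each = 3), dox = TRUE,
    timepoint_h = rep(c(8, 24, 32), 2))
  rpkm <- rbind(
    PARTNER5_5p = c(100, 100, 100, 80, 45, 30),
    PARTNER3_3p = c(90, 92, 89, 70, 40, 27),
    PARTNER3_5p = rep(0, 6),
    BG001 = c(50, 51, 49, 50, 52, 50))
  counts <- round(rpkm * 10)
  colnames(counts) <- samples$sample_id
  expr <- expression_matrix(counts, stats::setNames(rep(1000, 4), feats),
                            samples, assigned_totals = rep(1e6, 6))
  expr$rpkm <- rpkm; colnames(expr$rpkm) <- samples$sample_id
  tc <- knockdown_timecourse(expr, feats)
  dec <- tc$decreasing
  get_flag <- function(f, sh) dec$decreasing[dec$feature == f & dec$shrna == sh]
  expect_true(get_flag("PARTNER5_5p", "sh3"))
  expect_true(get_flag("PARTNER3_3p", "sh3"))
  expect_false(get_flag("PARTNER5_5p", "NT"))
  expect_false(get_flag("BG001", "sh3"))
  expect_false(get_flag("PARTNER3_5p", "sh3"))  # all-zero series
  expect_true(all(tc$series$rpkm[tc$series$feature == "PARTNER3_5p"] == 0))
  expect_error(knockdown_timecourse(expr, "NOPE"), "unknown feature")
})

test_that("expression TSV + metadata round-trips through the writers", {
  samples <- data.frame(sample_id = c("a", "b"), shrna = c("NT", "sh3"),
                        dox = TRUE, timepoint_h = 32)
  counts <- matrix(c(10, 20, 30, 40), 2,
                   dimnames = list(c("f1", "f2"), c("a", "b")))
  expr <- expression_matrix(counts, c(f1 = 500, f2 = 1500), samples)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  meta <- withr::local_tempfile(fileext = ".json")
  write_expression_tsv(expr, tsv, meta)
  back <- read_expression_tsv(tsv, meta)
  expect_equal(back$counts, expr$counts)
  expect_equal(back$rpkm, expr$rpkm)
  expect_equal(back$samples$shrna, expr$samples$shrna)
})

test_that("FASTQ pair round-trip preserves order and sequence", {
  w <- small_world(seed = 18, n_bg = 3)
  sim <- simulate_reads(w$cfg, w$tx, bg_abundance(w$tx), 50)
  r1 <- withr::local_tempfile(fileext = ".fastq")
  r2 <- withr::local_tempfile(fileext = ".fastq")
  write_fastq_pair(sim$reads, r1, r2)
  back <- read_fastq_pair(r1, r2)
  expect_identical(back$read1, sim$reads$read1)
  expect_identical(back$read2, sim$reads$read2)
  expect_identical(back$pair_id, sim$reads$pair_id)
})
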