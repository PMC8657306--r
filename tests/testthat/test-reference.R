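test_that("split_transcript produces the documented half-features", {
  g17 <- rand_gene("EW", 17, seed = 1)
  halves <- split_transcript(g17, 7)
  expect_equal(halves[[1]]$feature_id, "EW_5p")
  expect_equal(halves[[2]]$feature_id, "EW_3p")
  expect_equal(halves[[1]]$exon_range, c(1L, 7L))
  expect_equal(halves[[2]]$exon_range, c(8L, 17L))

  g10 <- rand_gene("WT", 10, seed = 2)
  halves10 <- split_transcript(g10, 7)
  expect_equal(halves10[[1]]$exon_range, c(1L, 7L))
  expect_equal(halves10[[2]]$exon_range, c(8L, 10L))

  toy <- gene_model("TOY", c("AAA", "CCC"))
  h <- split_transcript(toy, 1)
  expect_equal(h[[1]]$sequence, "AAA")
  expect_equal(h[[2]]$sequence, "CCC")
  expect_equal(paste0(h[[1]]$sequence, h[[2]]$sequence), gene_sequence(toy))
})

test_that("split/rejoin identity holds for random genes and all valid k", {
  set.seed(42)
  for (i in 1:10) {
    n <- sample(2:12, 1)
    g <- gene_model(paste0("G", i),
                    replicate(n, paste(sample(c("A", "C", "G", "T"),
                                              sample(20:200, 1), replace = TRUE),
                                       collapse = "")))
    for (k in seq_len(n - 1)) {
      h <- split_transcript(g, k)
      expect_identical(paste0(h[[1]]$sequence, h[[2]]$sequence),
                       gene_sequence(g))
    }
  }
})

test_that("split_transcript rejects invalid split points and empty genes", {
  g <- rand_gene("G", 5, seed = 3)
  expect_error(split_transcript(g, 0), "outside")
  expect_error(split_transcript(g, 5), "outside")
  expect_error(gene_model("E", character(0)), "empty exon list")
  expect_error(gene_model("E", c("ACGT", "")), "empty exon sequence")
  expect_error(gene_model("E", "ACGU"), "outside \\{A,C,G,T\\}")
})

test_that("build_fusion_sequence joins exons and inserts the isoform sequence", {
  g5 <- gene_model("A", c("AT", "GC"))
  g3 <- gene_model("B", c("TT", "AA", "GG"))
  spec <- fusion_spec("A", 1, "B", 2, kts_insertion = "AAGACGTCT",
                      kts_junction_after_exon = 2)
  expect_identical(build_fusion_sequence(g5, g3, spec, "minusKTS"), "ATAAGG")
  expect_identical(build_fusion_sequence(g5, g3, spec, "plusKTS"),
                   "ATAAAAGACGTCTGG")
  expect_equal(nchar(build_fusion_sequence(g5, g3, spec, "plusKTS")) -
               nchar(build_fusion_sequence(g5, g3, spec, "minusKTS")), 9L)
  expect_error(build_fusion_sequence(g5, g3, spec, "noKTS"))
  bad <- fusion_spec("A", 1, "B", 3, kts_junction_after_exon = 3)
  expect_error(build_fusion_sequence(g5, g3, bad, "plusKTS"),
               "internal junction")
})

test_that("fusion length arithmetic holds for random partner shapes", {
  set.seed(7)
  for (i in 1:5) {
    g5 <- rand_gene("P5", sample(3:17, 1), exon_len = sample(50:200, 1))
    g3 <- rand_gene("P3", sample(3:10, 1), exon_len = sample(50:200, 1))
    k <- sample(seq_len(n_exons(g5) - 1), 1)
    m <- sample(2:n_exons(g3), 1)
    j <- if (m < n_exons(g3)) sample(m:(n_exons(g3) - 1), 1) else NA
    spec <- fusion_spec("P5", k, "P3", m,
                        kts_junction_after_exon = if (is.na(j)) m else j)
    len5 <- sum(nchar(g5$exons[1:k]))
    len3 <- sum(nchar(g3$exons[m:n_exons(g3)]))
    expect_equal(nchar(build_fusion_sequence(g5, g3, spec, "minusKTS")),
                 len5 + len3)
    if (!is.na(j))
      expect_equal(nchar(build_fusion_sequence(g5, g3, spec, "plusKTS")),
                   len5 + len3 + nchar(spec$kts_insertion))
  }
})

test_that("fusion_spec enforces an in-frame insertion", {
  expect_error(fusion_spec("A", 1, "B", 2, kts_insertion = "AAGA"),
               "multiple of 3")
})

test_that("build_edited_reference splits partners, passes background, builds the panel", {
  set.seed(9)
  bg <- lapply(1:50, function(i) rand_gene(sprintf("BG%02d", i), sample(2:6, 1),
                                           exon_len = 80))
  g5 <- rand_gene("P5", 17); g3 <- rand_gene("P3", 10)
  ann <- c(list(g5, g3), bg)
  spec <- fusion_spec("P5", 7, "P3", 8)
  ref <- build_edited_reference(ann, list(spec), flank_w = 30)
  expect_length(ref$half_features, 4)
  expect_length(ref$background_features, 50)
  expect_gte(length(ref$junction_panel), 3)
  # half ids unique, ranges per spec
  ids <- vapply(ref$half_features, `[[`, "", "feature_id")
  expect_setequal(ids, c("P5_5p", "P5_3p", "P3_5p", "P3_3p"))
  # concatenating halves reproduces originals
  seqs <- stats::setNames(vapply(ref$half_features, `[[`, "", "sequence"), ids)
  expect_identical(paste0(seqs["P5_5p"], seqs["P5_3p"]), gene_sequence(g5))
  expect_identical(paste0(seqs["P3_5p"], seqs["P3_3p"]), gene_sequence(g3))
  # junction contigs carry w bases each side
  bp <- ref$junction_panel[[1]]
  expect_equal(nchar(bp$sequence), 60)
  expect_true(endsWith(paste(g5$exons[1:7], collapse = ""),
                       substr(bp$sequence, 1, 30)))
  expect_true(startsWith(paste(g3$exons[8:10], collapse = ""),
                         substr(bp$sequence, 31, 60)))

  # empty spec list: pure pass-through
  ref0 <- build_edited_reference(ann, list())
  expect_length(ref0$half_features, 0)
  expect_length(ref0$background_features, 52)
  expect_length(ref0$junction_panel, 0)

  # duplicate gene ids rejected
  expect_error(build_edited_reference(c(ann, list(g5)), list(spec)),
               "duplicate gene ids")
})

test_that("short exons clip junction flanks with a warning", {
  g5 <- gene_model("S5", c("ACGTACGTAC", "GGGTTTCCCA"))
  g3 <- gene_model("S3", c("TTTTAAAACC", "CCCCGGGGAA", "ATATATCGCG"))
  spec <- fusion_spec("S5", 1, "S3", 2)
  ws <- testthat::capture_warnings(
    ref <- build_edited_reference(list(g5, g3), list(spec), flank_w = 30))
  expect_true(all(grepl("only \\d+ nt available", ws)))
  expect_gte(length(ws), 1)
  expect_true(all(nchar(vapply(ref$junction_panel, `[[`, "", "sequence")) > 0))
})

test_that("edited reference FASTA round-trips ids, sequences and panel", {
  w <- small_world(seed = 21, n_bg = 5)
  path <- withr::local_tempfile(fileext = ".fasta")
  write_reference_fasta(w$ref, path)
  back <- read_reference_fasta(path)
  expect_identical(reference_features(back), reference_features(w$ref))
  expect_identical(
    vapply(back$junction_panel, `[[`, "", "junction_id"),
    vapply(w$ref$junction_panel, `[[`, "", "junction_id"))
  expect_identical(
    vapply(back$junction_panel, `[[`, "", "sequence"),
    vapply(w$ref$junction_panel, `[[`, "", "sequence"))
  expect_identical(
    vapply(back$junction_panel, `[[`, TRUE, "diagnostic"),
    vapply(w$ref$junction_panel, `[[`, TRUE, "diagnostic"))
})

test_that("detect_breakpoint recovers the planted junction", {
  w <- small_world(seed = 31, n_bg = 3)
  jr <- simulate_junction_reads(w$cfg, w$tx, 100, "breakpoint")
  bp <- detect_breakpoint(jr$reads$read1, w$tx$annotation$PARTNER5,
                          w$tx$annotation$PARTNER3, min_anchor = 20)
  expect_equal(bp$five_prime_exon, 7L)
  expect_equal(bp$three_prime_exon, 8L)
  expect_equal(bp$support, 100L)
})

test_that("detect_breakpoint returns support 0 on wild-type reads, not an error", {
  g5 <- rand_gene("W5", 17, seed = 5)
  g3 <- rand_gene("W3", 10, seed = 6)
  s <- gene_sequence(g5)
  set.seed(8)
  starts <- sample(seq_len(nchar(s) - 99), 50)
  reads <- substring(s, starts, starts + 99)
  bp <- detect_breakpoint(reads, g5, g3, 20)
  expect_equal(bp$support, 0L)
  expect_true(is.na(bp$five_prime_exon))
  expect_error(detect_breakpoint(reads, g5, g3, min_anchor = 5), ">= 10")
})

test_that("detect_breakpoint recovers arbitrary (k, m) over a property sweep", {
  set.seed(13)
  g5 <- rand_gene("K5", 8, exon_len = 120)
  g3 <- rand_gene("K3", 6, exon_len = 120)
  for (k in c(1, 3, 7)) for (m in c(2, 4, 6)) {
    spec <- fusion_spec("K5", k, "K3", m, kts_junction_after_exon = m)
    fus <- build_fusion_sequence(g5, g3, spec, "minusKTS")
    bp5 <- 120 * k
    over <- sample(25:75, 25, replace = TRUE)
    reads <- substring(fus, bp5 - over + 1, bp5 - over + 100)
    bp <- detect_breakpoint(reads, g5, g3, 20)
    expect_equal(c(bp$five_prime_exon, bp$three_prime_exon), c(k, m),
                 info = sprintf("k=%d m=%d", k, m))
    expect_equal(bp$support, 25L)
  }
})

test_that("annotation TSV and fusion spec JSON round-trip", {
  w <- small_world(seed = 41, n_bg = 3)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_annotation_tsv(w$tx$annotation, tsv)
  back <- read_annotation_tsv(tsv)
  expect_setequal(names(back), names(w$tx$annotation))
  expect_identical(gene_sequence(back$PARTNER5),
                   gene_sequence(w$tx$annotation$PARTNER5))

  js <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(unclass(w$tx$fusion), js, auto_unbox = TRUE)
  spec <- read_fusion_spec(js)
  expect_equal(spec$last_5p_exon, 7L)
  expect_equal(spec$first_3p_exon, 8L)
  bad <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(five_prime_gene = "X"), bad, auto_unbox = TRUE)
  expect_error(read_fusion_spec(bad), "missing field")
})
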