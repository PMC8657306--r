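#' Simulation configuration
#'
#' One object holds every knob of the synthetic world: transcriptome shape,
#' fusion geometry, knockdown kinetics, read model, planted targets, and the
#' drug screen. Defaults state the emulated study design: a 17-exon 5'
#' partner and 10-exon 3' partner fused exon 7 to exon 8 with a 9-nt in-frame
#' isoform insertion, a doxycycline time-course with monotone decay of fusion
#' expression, no wild-type 3' partner expression, negative-binomial count
#' noise, and a 201-compound screen on three cell models with a planted
#' subset sensitive in model 1.
#'
#' @param seed integer seed; the same seed yields byte-identical outputs.
#' @param n_background_genes background transcript count (default 50).
#' @param exon_count_range,exon_length_range uniform integer ranges for
#'   background gene shapes.
#' @param partner5_exons,partner3_exons exon counts of the fusion partners
#'   (defaults 17 and 10).
#' @param partner_exon_length exon length used for both partner genes.
#' @param fusion_k,fusion_m breakpoint exons: last 5'-partner exon and first
#'   3'-partner exon in the fusion (defaults 7 and 8).
#' @param kts_insertion 9-nt default in-frame isoform insertion.
#' @param kts_fraction fraction of fusion transcripts carrying the insertion
#'   (default 0.5).
#' @param knockdown_schedule named numeric vector: residual fusion fraction
#'   by timepoint (h) under an active hairpin with DOX.
#' @param timepoints_h sequenced timepoints (default 8, 24, 32).
#' @param n_up,n_down planted target gene counts (defaults 200 each).
#' @param fc_up,fc_down planted fold changes at full knockdown (2 and 0.5).
#' @param nb_dispersion excess-Poisson overdispersion phi of the count noise
#'   (`variance = mu * (1 + phi)`); 0 gives exact expectations.
#' @param read_length,fragment_mean,fragment_sd,error_rate read model
#'   (defaults 100 nt, 250 +/- 30 nt, 0.5% substitutions).
#' @param n_compounds,n_models,n_doses,n_sensitive,sensitivity_factor,screen_noise_sd
#'   screen shape: 201 compounds, 3 models, 8 log-spaced doses, 10 compounds
#'   whose model-1 IC50 is divided by `sensitivity_factor` (10), 2%
#'   multiplicative noise.
#' @param dose_range dose window in uM (default 1e-3 to 10).
#' @return object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_background_genes = 50L,
                       exon_count_range = c(3L, 12L),
                       exon_length_range = c(120L, 400L),
                       partner5_exons = 17L,
                       partner3_exons = 10L,
                       partner_exon_length = 150L,
                       fusion_k = 7L,
                       fusion_m = 8L,
                       kts_insertion = "AAGACGTCT",
                       kts_fraction = 0.5,
                       knockdown_schedule = c("8" = 0.8, "16" = 0.6,
                                              "24" = 0.45, "32" = 0.3,
                                              "40" = 0.25),
                       timepoints_h = c(8, 24, 32),
                       n_up = 200L, n_down = 200L,
                       fc_up = 2, fc_down = 0.5,
                       nb_dispersion = 0.05,
                       read_length = 100L,
                       fragment_mean = 250, fragment_sd = 30,
                       error_rate = 0.005,
                       n_compounds = 201L, n_models = 3L, n_doses = 8L,
                       n_sensitive = 10L, sensitivity_factor = 10,
                       screen_noise_sd = 0.02,
                       dose_range = c(1e-3, 10)) {
  stopifnot(kts_fraction >= 0, kts_fraction <= 1,
            all(knockdown_schedule >= 0), all(knockdown_schedule <= 1),
            error_rate >= 0, error_rate <= 0.05,
            nb_dispersion >= 0, n_background_genes >= 0)
  if (exon_length_range[1] < 1 || exon_length_range[1] > exon_length_range[2])
    stop("configuration error: infeasible exon length bounds")
  structure(as.list(environment()), class = "sim_config")
}

rand_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")

#' Simulate a toy transcriptome with two fusion partner genes
#'
#' Random exon structures and sequences for `n_background_genes` background
#' genes (ids `BG001..`), plus the two partner genes (`PARTNER5`, 17 exons by
#' default; `PARTNER3`, 10 exons) shaped per the config, and the matching
#' [fusion_spec()] (exon 7 fused to exon 8 by default).
#'
#' @param cfg a [sim_config()].
#' @return list with `annotation` (named list of [gene_model()]s) and
#'   `fusion` (a [fusion_spec()]).
#' @export
simulate_transcriptome <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  g5 <- gene_model("PARTNER5",
                   replicate(cfg$partner5_exons, rand_seq(cfg$partner_exon_length)))
  g3 <- gene_model("PARTNER3",
                   replicate(cfg$partner3_exons, rand_seq(cfg$partner_exon_length)))
  bg <- list()
  if (cfg$n_background_genes > 0) {
    bg <- lapply(seq_len(cfg$n_background_genes), function(i) {
      ne <- sample(cfg$exon_count_range[1]:cfg$exon_count_range[2], 1)
      lens <- sample(cfg$exon_length_range[1]:cfg$exon_length_range[2], ne,
                     replace = TRUE)
      gene_model(sprintf("BG%03d", i), vapply(lens, rand_seq, ""))
    })
  }
  annotation <- c(list(g5, g3), bg)
  names(annotation) <- vapply(annotation, `[[`, "", "gene_id")
  list(annotation = annotation,
       fusion = fusion_spec("PARTNER5", cfg$fusion_k, "PARTNER3", cfg$fusion_m,
                            kts_insertion = cfg$kts_insertion,
                            kts_junction_after_exon = cfg$fusion_m))
}

#' Simulate per-sample transcript abundances across the knockdown design
#'
#' Samples: hairpins sh2, sh3 and the non-targeting control NT, all
#' DOX-induced, at the configured timepoints. Fusion transcript abundance
#' (split `kts_fraction` : `1 - kts_fraction` between +KTS and -KTS isoforms)
#' follows the knockdown schedule under sh2/sh3 and is flat under NT.
#' Wild-type 3'-partner abundance is fixed at zero (the emulated cells do not
#' express it); the wild-type 5' partner is expressed and untouched. Planted
#' up/down target genes scale with the knocked-down fraction: at residual
#' fusion fraction `r` the multiplier is
#' `1 + (fc - 1) * (1 - r)/(1 - r_min)`, so the planted fold change is
#' realized exactly at full knockdown (`r = r_min`).
#'
#' @param cfg a [sim_config()].
#' @param transcriptome a [simulate_transcriptome()] result.
#' @return list with `abundance` (transcript x sample relative-abundance
#'   matrix over transcripts `PARTNER5_wt`, `fusion_plusKTS`,
#'   `fusion_minusKTS`, and background gene ids), `samples` metadata
#'   data.frame, and `truth` (breakpoint, kts_fraction, planted up/down gene
#'   sets with fold changes, schedule).
#' @export
simulate_expression <- function(cfg, transcriptome) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 1L)
  ann <- transcriptome$annotation
  bg_ids <- setdiff(names(ann), c("PARTNER5", "PARTNER3"))
  if (cfg$n_up + cfg$n_down > length(bg_ids))
    stop("configuration error: planted target count (", cfg$n_up + cfg$n_down,
         ") exceeds background gene count (", length(bg_ids), ")")
  planted <- sample(bg_ids, cfg$n_up + cfg$n_down)
  up_genes <- planted[seq_len(cfg$n_up)]
  down_genes <- setdiff(planted, up_genes)

  samples <- expand.grid(shrna = c("NT", "sh2", "sh3"),
                         timepoint_h = cfg$timepoints_h,
                         stringsAsFactors = FALSE)
  samples$dox <- TRUE
  samples$sample_id <- sprintf("%s_%gh", samples$shrna, samples$timepoint_h)
  samples <- samples[order(samples$shrna, samples$timepoint_h),
                     c("sample_id", "shrna", "dox", "timepoint_h")]
  rownames(samples) <- NULL

  base_bg <- stats::setNames(exp(stats::runif(length(bg_ids), log(1), log(100))),
                             bg_ids)
  fusion_base <- 50  # abundant driver transcript
  wt5_base <- 20
  r_min <- min(cfg$knockdown_schedule)
  sched <- function(tp) {
    nm <- as.character(tp)
    if (!nm %in% names(cfg$knockdown_schedule))
      stop("no knockdown schedule entry for timepoint ", tp, " h")
    cfg$knockdown_schedule[[nm]]
  }

  transcripts <- c("PARTNER5_wt", "fusion_plusKTS", "fusion_minusKTS", bg_ids)
  ab <- matrix(0, nrow = length(transcripts), ncol = nrow(samples),
               dimnames = list(transcripts, samples$sample_id))
  for (j in seq_len(nrow(samples))) {
    r <- if (samples$shrna[j] == "NT") 1.0 else sched(samples$timepoint_h[j])
    mult <- stats::setNames(rep(1, length(bg_ids)), bg_ids)
    scale_eff <- (1 - r) / (1 - r_min)
    mult[up_genes] <- 1 + (cfg$fc_up - 1) * scale_eff
    mult[down_genes] <- 1 + (cfg$fc_down - 1) * scale_eff
    ab["PARTNER5_wt", j] <- wt5_base
    ab["fusion_plusKTS", j] <- fusion_base * r * cfg$kts_fraction
    ab["fusion_minusKTS", j] <- fusion_base * r * (1 - cfg$kts_fraction)
    ab[bg_ids, j] <- base_bg * mult
  }
  list(abundance = ab, samples = samples,
       truth = list(breakpoint = c(k = cfg$fusion_k, m = cfg$fusion_m),
                    kts_fraction = cfg$kts_fraction,
                    up_genes = up_genes, down_genes = down_genes,
                    fc_up = cfg$fc_up, fc_down = cfg$fc_down,
                    schedule = cfg$knockdown_schedule))
}

revcomp <- function(s) as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))

add_errors <- function(seqs, rate) {
  if (rate <= 0) return(seqs)
  vapply(seqs, function(s) {
    n <- nchar(s)
    hits <- which(stats::runif(n) < rate)
    if (!length(hits)) return(s)
    ch <- strsplit(s, "")[[1]]
    for (i in hits) ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1)
    paste(ch, collapse = "")
  }, "", USE.NAMES = FALSE)
}

#' Simulate paired-end reads from transcript abundances
#'
#' Fragments are drawn per transcript proportionally to abundance x length;
#' fragment start positions are uniform; fragment lengths are normal
#' (truncated to `[read_length, transcript length]`); mate 1 is the fragment
#' 5' prefix and mate 2 the reverse complement of its 3' suffix; substitution
#' errors are planted at the configured rate. Truth labels state what the
#' exact k-mer assigner must do with each pair under error-free reads:
#' background ids and half-feature ids (`PARTNER5_5p`, `PARTNER3_3p`, ...)
#' for assignable pairs, `junction` / `discordant` (or the
#' `PARTNER5_wt_`-prefixed variants for the wild-type 5' partner split
#' boundary) for pairs whose k-mer candidate intersection is empty by
#' construction.
#'
#' @param cfg a [sim_config()].
#' @param transcriptome a [simulate_transcriptome()] result.
#' @param abundance named non-negative vector over the transcript ids of
#'   [simulate_expression()] (one sample's column).
#' @param n_pairs number of read pairs.
#' @param seed_offset added to `cfg$seed` so per-sample read sets differ.
#' @return list with `reads` (a [read_set()]; `truth` column as above) and
#'   `truth_counts` (named expected-count vector by truth label).
#' @export
simulate_reads <- function(cfg, transcriptome, abundance, n_pairs,
                           seed_offset = 2L) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed + seed_offset)
  ann <- transcriptome$annotation
  spec <- transcriptome$fusion
  g5 <- ann[["PARTNER5"]]; g3 <- ann[["PARTNER3"]]
  seqs <- c(
    PARTNER5_wt = gene_sequence(g5),
    fusion_plusKTS = build_fusion_sequence(g5, g3, spec, "plusKTS"),
    fusion_minusKTS = build_fusion_sequence(g5, g3, spec, "minusKTS"))
  bg_ids <- setdiff(names(ann), c("PARTNER5", "PARTNER3"))
  seqs <- c(seqs, vapply(ann[bg_ids], gene_sequence, ""))
  abundance <- abundance[names(seqs)]
  abundance[is.na(abundance)] <- 0
  lens <- nchar(seqs)
  w <- abundance * lens
  if (sum(w) == 0 || n_pairs == 0) {
    warning("zero total abundance: returning empty read set")
    return(list(reads = read_set(character(0), character(0)),
                truth_counts = numeric(0)))
  }
  src <- sample(names(seqs), n_pairs, replace = TRUE, prob = w / sum(w))
  rl <- cfg$read_length
  frag_len <- pmax(rl, pmin(round(stats::rnorm(n_pairs, cfg$fragment_mean,
                                               cfg$fragment_sd)),
                            lens[src]))
  start <- floor(stats::runif(n_pairs, 1, lens[src] - frag_len + 1 + 1))
  end <- start + frag_len - 1L

  # Truth labels mirror the k-mer assigner exactly (error-free case): a mate
  # contributes a k-mer to the 5' side of a boundary iff it covers >= label_k
  # contiguous bases there, likewise 3'. A pair with k-mer support on both
  # sides has an empty candidate intersection -> "junction" (a mate crosses)
  # or "discordant" (mates on opposite sides); support on one side only means
  # the pair counts toward that half-feature, even if a mate grazes the
  # boundary by < label_k bases.
  label_k <- 21L
  bp5 <- sum(nchar(g5$exons[seq_len(spec$last_5p_exon)]))
  r1_a <- start; r1_b <- pmin(start + rl - 1L, end)
  r2_a <- pmax(end - rl + 1L, start); r2_b <- end
  pair_label <- function(boundary, id5, id3) {
    side5 <- function(a, b) pmin(b, boundary) - a + 1L >= label_k
    side3 <- function(a, b) b - pmax(a, boundary + 1L) + 1L >= label_k
    s5 <- side5(r1_a, r1_b) | side5(r2_a, r2_b)
    s3 <- side3(r1_a, r1_b) | side3(r2_a, r2_b)
    crosses <- (r1_a <= boundary & r1_b > boundary) |
               (r2_a <= boundary & r2_b > boundary)
    ifelse(s5 & s3, ifelse(crosses, "junction", "discordant"),
           ifelse(s3, id3, id5))
  }
  truth <- src
  fus <- src %in% c("fusion_plusKTS", "fusion_minusKTS")
  truth[fus] <- pair_label(bp5, "PARTNER5_5p", "PARTNER3_3p")[fus]
  wt5 <- src == "PARTNER5_wt"
  lab5 <- pair_label(bp5, "PARTNER5_5p", "PARTNER5_3p")
  amb <- lab5 %in% c("junction", "discordant")
  lab5[amb] <- paste0("PARTNER5_wt_", lab5[amb])
  truth[wt5] <- lab5[wt5]

  frag <- substring(seqs[src], start, end)
  r1 <- substr(frag, 1L, rl)
  r2 <- vapply(substring(frag, pmax(1L, frag_len - rl + 1L)), revcomp, "",
               USE.NAMES = FALSE)
  r1 <- add_errors(r1, cfg$error_rate)
  r2 <- add_errors(r2, cfg$error_rate)
  reads <- read_set(r1, r2, truth = truth)
  list(reads = reads, truth_counts = c(table(truth)))
}

#' Simulate junction-spanning read pairs
#'
#' Draws read pairs whose mate 1 crosses a named junction of the fusion
#' transcript — the partner breakpoint or the KTS isoform junction — with at
#' least `min_overhang` bases on each side. Isoform identity is Bernoulli
#' with `cfg$kts_fraction`; mate 2 is the reverse complement of the fragment
#' tail. Truth carries the isoform per pair.
#'
#' @param cfg a [sim_config()].
#' @param transcriptome a [simulate_transcriptome()] result.
#' @param n_pairs number of junction read pairs.
#' @param junction `"breakpoint"` (partner fusion point) or `"kts"` (the
#'   isoform junction).
#' @param min_overhang minimum bases on each side of the junction within
#'   mate 1 (default 30, the flank/diagnostic width).
#' @param seed_offset added to `cfg$seed`.
#' @return list with `reads` (a [read_set()], `truth` = isoform) and
#'   `truth_plus` (count of +KTS pairs).
#' @export
simulate_junction_reads <- function(cfg, transcriptome, n_pairs,
                                    junction = c("breakpoint", "kts"),
                                    min_overhang = 30L, seed_offset = 5L) {
  stopifnot(inherits(cfg, "sim_config"))
  junction <- match.arg(junction)
  set.seed(cfg$seed + seed_offset)
  ann <- transcriptome$annotation
  spec <- transcriptome$fusion
  g5 <- ann[[spec$five_prime_gene]]; g3 <- ann[[spec$three_prime_gene]]
  seqs <- c(plusKTS = build_fusion_sequence(g5, g3, spec, "plusKTS"),
            minusKTS = build_fusion_sequence(g5, g3, spec, "minusKTS"))
  bp5 <- sum(nchar(g5$exons[seq_len(spec$last_5p_exon)]))
  # junction point (last base before the joint) per isoform
  kts_up_len <- sum(nchar(g3$exons[spec$first_3p_exon:spec$kts_junction_after_exon]))
  jpos <- switch(junction,
    breakpoint = c(plusKTS = bp5, minusKTS = bp5),
    kts = c(plusKTS = bp5 + kts_up_len + nchar(spec$kts_insertion),
            minusKTS = bp5 + kts_up_len))
  # for the +KTS isoform the diagnostic junction is the insertion itself; a
  # read crossing the downstream edge with >= w overhang covers insertion+exon
  rl <- cfg$read_length
  if (rl < 2L * min_overhang)
    stop("read_length must be >= 2 * min_overhang")
  iso <- ifelse(stats::runif(n_pairs) < cfg$kts_fraction, "plusKTS", "minusKTS")
  over5 <- sample(min_overhang:(rl - min_overhang), n_pairs, replace = TRUE)
  start <- jpos[iso] - over5 + 1L
  frag_len <- pmax(rl, pmin(round(stats::rnorm(n_pairs, cfg$fragment_mean,
                                               cfg$fragment_sd)),
                            nchar(seqs[iso]) - start + 1L))
  end <- start + frag_len - 1L
  frag <- substring(seqs[iso], start, end)
  r1 <- substr(frag, 1L, rl)
  r2 <- vapply(substring(frag, pmax(1L, frag_len - rl + 1L)), revcomp, "",
               USE.NAMES = FALSE)
  r1 <- add_errors(r1, cfg$error_rate)
  r2 <- add_errors(r2, cfg$error_rate)
  list(reads = read_set(r1, r2, truth = iso),
       truth_plus = sum(iso == "plusKTS"))
}

#' Shortcut RPKM-table generator with planted targets (no reads)
#'
#' Draws negative-binomial counts around expected per-gene abundances for the
#' full (shRNA x timepoint) design and converts them to RPKM-like values by a
#' fixed depth factor (100 counts per RPKM unit, the scale of a deep
#' short-read library for a ~2 kb transcript), so planted fold changes are
#' realized in expectation (exactly, at dispersion 0). `nb_dispersion` is the
#' excess-Poisson overdispersion phi: counts are NB with `mu` and
#' `size = mu/phi`, giving `variance = mu * (1 + phi)` — shot-noise-dominated
#' counts whose relative error shrinks with expression, the regime in which a
#' deterministic 25% fold-change filter is a meaningful caller. Planted
#' target genes are drawn from baselines comfortably above the expression
#' gate so the rule, not the gate, decides.
#'
#' @param cfg a [sim_config()]; relevant fields: `n_background_genes`
#'   (table size; genes `G00001..`), `n_up`, `n_down`, `fc_up`, `fc_down`,
#'   `nb_dispersion`, `knockdown_schedule`, `timepoints_h`, `seed`.
#' @param n_genes table size override (default `max(2000,
#'   cfg$n_background_genes)` so defaults hold 200+200 planted among 2000).
#' @return list with `expr` (list of `rpkm` matrix + `samples`, accepted by
#'   [call_targets()]) and `truth` (up/down planted gene ids, baselines).
#' @export
simulate_rpkm_table <- function(cfg = sim_config(), n_genes = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 3L)
  if (is.null(n_genes)) n_genes <- max(2000L, cfg$n_background_genes)
  if (cfg$n_up + cfg$n_down > n_genes)
    stop("configuration error: planted targets exceed gene count")
  genes <- sprintf("G%05d", seq_len(n_genes))
  baseline <- exp(stats::runif(n_genes, log(0.5), log(500)))
  names(baseline) <- genes
  eligible <- genes[baseline > 2 * 5]  # planted targets clearly above the gate
  planted <- sample(eligible, cfg$n_up + cfg$n_down)
  up_genes <- planted[seq_len(cfg$n_up)]
  down_genes <- setdiff(planted, up_genes)

  samples <- expand.grid(shrna = c("NT", "sh2", "sh3"),
                         timepoint_h = cfg$timepoints_h,
                         stringsAsFactors = FALSE)
  samples$dox <- TRUE
  samples$sample_id <- sprintf("%s_%gh", samples$shrna, samples$timepoint_h)
  samples <- samples[order(samples$shrna, samples$timepoint_h),
                     c("sample_id", "shrna", "dox", "timepoint_h")]
  rownames(samples) <- NULL

  r_min <- min(cfg$knockdown_schedule)
  depth <- 100  # counts per RPKM unit (deep library, ~2 kb transcript)
  rpkm <- matrix(0, n_genes, nrow(samples),
                 dimnames = list(genes, samples$sample_id))
  for (j in seq_len(nrow(samples))) {
    r <- if (samples$shrna[j] == "NT") 1.0
         else cfg$knockdown_schedule[[as.character(samples$timepoint_h[j])]]
    scale_eff <- (1 - r) / (1 - r_min)
    mult <- stats::setNames(rep(1, n_genes), genes)
    mult[up_genes] <- 1 + (cfg$fc_up - 1) * scale_eff
    mult[down_genes] <- 1 + (cfg$fc_down - 1) * scale_eff
    mu <- baseline * mult * depth
    counts <- if (cfg$nb_dispersion == 0) mu
              else stats::rnbinom(n_genes, mu = mu, size = mu / cfg$nb_dispersion)
    rpkm[, j] <- counts / depth
  }
  list(expr = structure(list(rpkm = rpkm, samples = samples),
                        class = "rpkm_table"),
       truth = list(up_genes = up_genes, down_genes = down_genes,
                    baseline = baseline))
}

#' Simulate a drug-screen plate table with planted sensitive compounds
#'
#' Each (compound, model) pair gets a ground-truth 4PL curve (top 1, bottom
#' drawn low, hill and IC50 drawn per compound with small cross-model
#' jitter); `n_sensitive` compounds have their model-1 IC50 divided by
#' `sensitivity_factor`. Wells carry luminescence = plate base x true
#' viability x multiplicative lognormal noise; each (plate, model) has 16
#' DMSO wells. One plate per model.
#'
#' @param cfg a [sim_config()].
#' @return list with `plate` (well-level data.frame consumed by
#'   [normalize_viability()] / [analyze_screen()]) and `truth` (sensitive
#'   compound ids, 4PL parameter table, models, doses).
#' @export
simulate_screen <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$n_doses < 4L) stop("need >= 4 doses per compound")
  set.seed(cfg$seed + 4L)
  compounds <- sprintf("C%03d", seq_len(cfg$n_compounds))
  models <- sprintf("M%d", seq_len(cfg$n_models))
  doses <- 10^seq(log10(cfg$dose_range[1]), log10(cfg$dose_range[2]),
                  length.out = cfg$n_doses)
  sensitive <- if (cfg$n_sensitive > 0) sample(compounds, cfg$n_sensitive)
               else character(0)

  params <- expand.grid(compound_id = compounds, model_id = models,
                        stringsAsFactors = FALSE)
  base_ic50 <- stats::setNames(
    exp(stats::runif(length(compounds), log(0.03), log(3))), compounds)
  base_hill <- stats::setNames(stats::runif(length(compounds), 0.8, 3), compounds)
  base_bottom <- stats::setNames(stats::runif(length(compounds), 0, 0.2), compounds)
  params$top <- 1
  params$bottom <- base_bottom[params$compound_id]
  params$hill <- base_hill[params$compound_id]
  jitter <- exp(stats::rnorm(nrow(params), 0, 0.05))
  params$ic50 <- base_ic50[params$compound_id] * jitter
  sens_rows <- params$compound_id %in% sensitive & params$model_id == models[1]
  params$ic50[sens_rows] <- params$ic50[sens_rows] / cfg$sensitivity_factor

  rows <- vector("list", nrow(params))
  for (i in seq_len(nrow(params))) {
    v <- fourpl(doses, params$top[i], params$bottom[i], params$ic50[i],
                params$hill[i])
    rows[[i]] <- data.frame(plate_id = paste0("P_", params$model_id[i]),
                            compound_id = params$compound_id[i],
                            model_id = params$model_id[i],
                            concentration = doses, true_viability = v,
                            stringsAsFactors = FALSE)
  }
  wells <- do.call(rbind, rows)
  dmso <- do.call(rbind, lapply(models, function(m)
    data.frame(plate_id = paste0("P_", m), compound_id = "DMSO",
               model_id = m, concentration = 0, true_viability = 1,
               stringsAsFactors = FALSE)[rep(1, 16), ]))
  wells <- rbind(wells, dmso)
  base_sig <- 2e5
  noise <- if (cfg$screen_noise_sd > 0)
    exp(stats::rnorm(nrow(wells), 0, cfg$screen_noise_sd)) else 1
  wells$luminescence <- base_sig * wells$true_viability * noise
  wells$well <- sprintf("W%04d", seq_len(nrow(wells)))
  wells$unit <- "uM"
  plate <- wells[, c("plate_id", "well", "compound_id", "concentration",
                     "unit", "model_id", "luminescence")]
  rownames(plate) <- NULL
  list(plate = plate,
       truth = list(sensitive = sensitive, params = params, models = models,
                    doses = doses,
                    true_viability = wells$true_viability))
}
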