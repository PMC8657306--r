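# fusionkd

Fusion-aware knockdown transcriptomics and drug-screen analytics for
fusion-driven sarcomas, built around the analysis design used for
desmoplastic small round cell tumor (DSRCT) models.

## The problem

DSRCT is driven by a single chimeric transcript: the 5′ end of *EWSR1*
(exons 1–7) fused to the 3′ end of *WT1* (exons 8–10), expressed as two
splice isoforms that differ by a 9-nt in-frame insertion (±KTS). Ordinary
RNA-seq quantification cannot separate reads of the fusion from reads of the
wild-type partner genes, and a doxycycline-inducible shRNA knockdown of the
fusion needs exactly that separation to be read out. `fusionkd` packages the
whole computational path:

1. **Edited (split) reference** — each fusion partner transcript is replaced
   by two half-transcripts cut at the breakpoint exon (`EWSR1_5p` = exons
   1–7, `EWSR1_3p` = exons 8–17, likewise for the 3′ partner), so read
   counts on the halves disambiguate fusion vs wild-type origin. A junction
   panel (breakpoint contig + one diagnostic contig per ±KTS isoform) serves
   junction-spanning reads.
2. **Quantification** — a deterministic exact k-mer assigner (default
   k = 21, unique-intersection policy, FR paired-end) replaces an external
   aligner; RPKM = `counts × 1e9 / (N_assigned × length)`.
3. **Breakpoint detection** — exact-anchor scan over candidate exon pairs
   (k, m), maximizing junction-spanning read support.
4. **Target calling** — the two-hairpin intersection rule: a gene is a
   fusion target when `fc = rpkm_sh / rpkm_NT` is ≤ 0.75 (down) or ≥ 1.25
   (up) under **both** shRNA 2 and shRNA 3 at the calling timepoint, with a
   5-RPKM "truly expressed" gate on each compared pair. Gene-set Z-score
   construction (|Z| > 1) and overlap reports against external study lists.
5. **Drug screen** — DMSO normalization per plate/model, range-normalized
   trapezoidal AUC over log10 dose, per-compound AUC Z-scores across cell
   models (`z = (AUC − mean)/sd`, sample sd), 4PL dose-response fits
   `v(c) = bottom + (top − bottom)/(1 + (c/IC50)^hill)` with IC50, and hit
   selection by sensitivity Z plus clinical plasma-concentration criterion.
6. **Synthetic data** — seeded generators for every input (transcriptome,
   knockdown expression schedules, paired FASTQ, RPKM tables with planted
   targets, screen plates with planted sensitive compounds), each emitting a
   truth table for recovery testing.

## Worked example

```r
library(fusionkd)

cfg <- sim_config(seed = 42, n_background_genes = 20, n_up = 4, n_down = 4,
                  error_rate = 0, kts_fraction = 0.7)
tx  <- simulate_transcriptome(cfg)
ref <- build_edited_reference(tx$annotation, list(tx$fusion), flank_w = 30)
ref
#> edited_reference: 4 half-features, 20 background features, 3 junction contigs (flank_w = 30)

jr <- simulate_junction_reads(cfg, tx, 200, "breakpoint")
detect_breakpoint(jr$reads$read1, tx$annotation$PARTNER5,
                  tx$annotation$PARTNER3, min_anchor = 20)
#> breakpoint: exon 7 -> exon 8 (200 supporting reads)

kr <- simulate_junction_reads(cfg, tx, 1000, "kts")
count_isoform_junctions(kr$reads, ref$junction_panel, 30)
#> isoform_counts: +KTS 681, -KTS 319, unclassified 0

sim <- simulate_rpkm_table(sim_config(seed = 42))   # 2000 genes, 200+200 planted
call_targets(sim$expr)
#> target_call_result: 200 up, 200 down (theta = 0.25, cutoff = 5 RPKM, 32 h)

scr <- simulate_screen(sim_config(seed = 42))       # 201 compounds, 3 models
analyze_screen(scr$plate, focus_model = "M1", fit_curves = FALSE)
#> screen_result: 201 compounds x 3 models (focus: M1)

doses <- c(25, 50, 100, 200, 400) / 1000            # uM
v <- 1 / (1 + (doses / 0.104)^1.5)
fit_dose_response(c(0, doses), c(1, v))
#> 4PL fit: top 1.000, bottom 0.000, IC50 0.104 uM, hill 1.50 (rss 1.89e-27)
```

Reading the output: the breakpoint call returns the exon pair joined by the
fusion with its supporting-read count; the isoform counter recovers the
planted 70/30 +KTS/−KTS mix (681/1000 classified +KTS); the target caller
recovers all 400 planted targets at the default thresholds; the 4PL fit
recovers a 104 nM IC50 exactly from a noise-free curve on a 25–400 nM dose
grid.

## Command line

```sh
fusionkd simulate transcriptome --seed 7 --outdir sim/
fusionkd build-ref --annotation sim/annotation.tsv --fusion sim/fusion.json --flank 30 --out ref.fasta
fusionkd quantify --ref ref.fasta --r1 r1.fastq --r2 r2.fastq --k 21 --policy unique_only --out counts.tsv
fusionkd call-targets --rpkm rpkm.tsv --meta meta.json --fc 0.25 --cutoff 5 --time 32 --out targets.json
fusionkd screen --plates plates.csv --plasma plasma.csv --focus-model M1 --out screen.json
```

(`fusionkd` is `inst/exec/fusionkd`; the same dispatcher is exported as
`fusionkd_cli()`.)

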