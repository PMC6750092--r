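test_that("generation is byte-identical under a fixed seed", {
  cfg <- sim_config(n_transcripts = 5L, seed = 42)
  a <- generate_transcriptome(cfg)
  b <- generate_transcriptome(cfg)
  expect_identical(a$transcripts$sequence, b$transcripts$sequence)
  expect_false(identical(
    a$transcripts$sequence,
    generate_transcriptome(sim_config(n_transcripts = 5L,
                                      seed = 43))$transcripts$sequence))
  # simulated reads are equally deterministic
  ra <- simulate_reads(a$transcripts, cfg)
  rb <- simulate_reads(b$transcripts, cfg)
  expect_identical(ra, rb)
})

test_that("generated CDSs are well-formed", {
  cfg <- sim_config(n_transcripts = 8L, seed = 1)
  g <- generate_transcriptome(cfg)
  for (i in seq_len(nrow(g$transcripts))) {
    cv <- riboframe:::cds_codons(g$transcripts[i, ])
    expect_equal(cv[1], "ATG")
    expect_true(cv[length(cv)] %in% STOP_CODONS)
    expect_false(any(cv[-length(cv)] %in% STOP_CODONS))  # no internal stops
  }
})

test_that("uniform usage weights yield near-uniform realized frequencies", {
  cfg <- sim_config(n_transcripts = 40L, cds_codons_range = c(150L, 200L),
                    seed = 2)
  g <- generate_transcriptome(cfg)
  counts <- g$truth$frame_composition$count0
  expect_equal(length(counts), 61L)
  p <- counts / sum(counts)
  # every codon within 5 binomial SEs of 1/61 (start/stop handling aside,
  # ATG is inflated by the forced initiator so gets extra slack)
  se <- sqrt((1 / 61) * (60 / 61) / sum(counts))
  extra <- ifelse(g$truth$frame_composition$codon == "ATG", 40 / sum(counts), 0)
  expect_true(all(abs(p - 1 / 61) <= 5 * se + extra))
})

test_that("the frame-2 ATG suppression knob depletes junctions ~5-fold", {
  base <- sim_config(n_transcripts = 40L, cds_codons_range = c(150L, 200L),
                     seed = 3)
  dep <- sim_config(n_transcripts = 40L, cds_codons_range = c(150L, 200L),
                    frame2_atg_keep = 0.2, seed = 3)
  f2 <- function(g) {
    ft <- g$truth$frame_composition
    sum(ft$count2[ft$codon == "ATG"]) / sum(ft$count0[ft$codon == "ATG"] +
      ft$count1[ft$codon == "ATG"] + ft$count2[ft$codon == "ATG"])
  }
  r_base <- f2(generate_transcriptome(base))
  r_dep <- f2(generate_transcriptome(dep))
  expect_lt(r_dep, 0.45 * r_base)
  expect_gt(r_dep, 0.05 * r_base)
})

test_that("read truth fields are consistent with placement", {
  cfg <- sim_config(n_transcripts = 4L, reads_per_transcript = 500L,
                    seed = 4)
  g <- generate_transcriptome(cfg)
  aln <- simulate_reads(g$transcripts, cfg)
  expect_true(all(aln$true_frame %in% 0:2))
  # frame-0 reads start exactly at their anchor codon's first nucleotide
  f0 <- aln[aln$true_frame == 0L & aln$ribo_frame == 0L, ]
  tr <- g$transcripts
  for (r in sample(nrow(f0), 25)) {
    row <- f0[r, ]
    s <- tr[tr$transcript_id == row$transcript_id, "sequence"]
    expect_equal(substring(s, row$five_prime_pos + 1,
                           row$five_prime_pos + 3), row$true_codon)
  }
  # realized frame composition of 5' ends approximates (q0, q1, q2)
  fr <- table(factor(aln$true_frame, 0:2)) / nrow(aln)
  expect_true(all(abs(as.numeric(fr) - c(0.7, 0.15, 0.15)) < 0.03))
})

test_that("ligation bias skews 5' nucleotides but not frame fidelity", {
  cfg0 <- sim_config(n_transcripts = 10L, reads_per_transcript = 3000L,
                     dwell_multipliers = setNames(rep(1, 61), SENSE_CODONS),
                     seed = 5)
  cfgA <- sim_config(n_transcripts = 10L, reads_per_transcript = 8000L,
                     dwell_multipliers = setNames(rep(1, 61), SENSE_CODONS),
                     ligation_bias = c(A = 10, C = 1, G = 1, T = 1),
                     seed = 5)
  g <- generate_transcriptome(cfg0)
  frac_a <- function(aln) {
    s <- setNames(g$transcripts$sequence, g$transcripts$transcript_id)
    nt <- substring(s[aln$transcript_id], aln$five_prime_pos + 1,
                    aln$five_prime_pos + 1)
    mean(nt == "A")
  }
  aln0 <- simulate_reads(g$transcripts, cfg0)
  alnA <- simulate_reads(g$transcripts, cfgA)
  expect_gt(frac_a(alnA), frac_a(aln0) + 0.2)
  # per-codon IFR is untouched by the within-position bias
  ifr0 <- global_ifr(build_profiles(aln0, g$transcripts), g$transcripts)
  ifrA <- global_ifr(build_profiles(alnA, g$transcripts), g$transcripts)
  # bias thins non-A codon classes ~10-fold, so compare only codons still
  # estimated from several genes, at a binomial-scale tolerance
  ok <- is.finite(ifr0$ifr_global) & is.finite(ifrA$ifr_global) &
    ifrA$n_genes >= 5L
  expect_gt(sum(ok), 30)
  expect_lt(abs(mean(ifrA$ifr_global[ok]) - mean(ifr0$ifr_global[ok])), 0.02)
})

test_that("ground-truth expectations hit the degenerate limits", {
  cfg1 <- sim_config(n_transcripts = 3L, frame_probs = c(1, 0, 0), seed = 6)
  g1 <- generate_transcriptome(cfg1)
  gt1 <- ground_truth_summary(cfg1, g1$transcripts)
  expect_equal(unname(gt1$expected_ifr), rep(1, 61))
  cfg2 <- sim_config(n_transcripts = 3L,
                     dwell_multipliers = setNames(rep(1, 61), SENSE_CODONS),
                     frame_probs = c(1, 1, 1) / 3, seed = 6)
  g2 <- generate_transcriptome(cfg2)
  gt2 <- ground_truth_summary(cfg2, g2$transcripts)
  expect_equal(unname(gt2$expected_acc), rep(1, 61))
})

test_that("expected ACC matches brute-force estimates on a small cohort", {
  cfg <- sim_config(n_transcripts = 10L, reads_per_transcript = 5000L,
                    seed = 7)
  g <- generate_transcriptome(cfg)
  aln <- simulate_reads(g$transcripts, cfg)
  ps <- normalize_profiles(build_profiles(aln, g$transcripts), g$transcripts)
  acc <- global_acc(ps, g$transcripts)
  gt <- ground_truth_summary(cfg, g$transcripts)
  ok <- is.finite(acc$acc_global)
  rel <- acc$acc_global[ok] / gt$expected_acc[acc$codon[ok]]
  expect_lt(median(abs(rel - 1)), 0.1)
  expect_gt(cor(acc$acc_global[ok], gt$expected_acc[acc$codon[ok]]), 0.97)
})

test_that("simulation files round-trip through the standard readers", {
  cfg <- sim_config(n_transcripts = 3L, reads_per_transcript = 200L,
                    seed = 8)
  g <- generate_transcriptome(cfg)
  aln <- simulate_reads(g$transcripts, cfg)
  d <- tempfile()
  paths <- write_simulation(g$transcripts, aln, d)
  ts <- read_transcripts(paths["fasta"], paths["cds"])
  expect_equal(ts$sequence, g$transcripts$sequence)
  expect_equal(ts$cds_start, g$transcripts$cds_start)
  aln2 <- read_alignments_tsv(paths["alignments"])
  expect_equal(aln2$five_prime_pos, aln$five_prime_pos)
})
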