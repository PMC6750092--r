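# A transcript whose CDS places a chosen codon at known positions lets the
# IFR/ACC formulas be evaluated by hand.
two_occurrence_fixture <- function(counts_by_occurrence) {
  # CDS: ATG GCC [TGC] AAA [TGC] CCC TAA -- TGC at codon indices 3 and 5
  seq <- paste0("GG", "ATGGCCTGCAAATGCCCCTAA", "GG")
  tr <- toy_transcript(seq, cds_start = 2L, cds_end = 23L)
  counts <- numeric(nchar(seq))
  pos <- c(8L, 14L)   # 0-based first nucleotides of the two TGC codons
  for (i in 1:2) counts[pos[i] + 1:3] <- counts_by_occurrence[[i]]
  list(tr = tr, profile = toy_profile(tr, counts))
}

test_that("gene IFR evaluates the frame-count ratio over occurrences", {
  fx <- two_occurrence_fixture(list(c(8, 1, 1), c(6, 2, 2)))
  expect_equal(gene_ifr(fx$profile, fx$tr, "TGC"), 14 / 20)
  # all frame-0 reads -> upper bound 1
  fx1 <- two_occurrence_fixture(list(c(7, 0, 0), c(5, 0, 0)))
  expect_equal(gene_ifr(fx1$profile, fx1$tr, "TGC"), 1)
})

test_that("genes below 10 reads for a codon are disregarded, not zeroed", {
  fx <- two_occurrence_fixture(list(c(5, 1, 1), c(2, 0, 0)))   # 9 reads
  r <- gene_ifr(fx$profile, fx$tr, "TGC")
  expect_true(is.na(r))
  expect_equal(attr(r, "reason"), "below_threshold")
  absent <- gene_ifr(fx$profile, fx$tr, "CGT")
  expect_equal(attr(absent, "reason"), "absent")
})

test_that("gene IFR is invariant under uniform count scaling", {
  set.seed(6)
  for (k in c(2L, 7L)) {
    base <- list(c(4, 3, 5), c(9, 1, 2))
    fx <- two_occurrence_fixture(base)
    fxk <- two_occurrence_fixture(lapply(base, `*`, k))
    expect_equal(gene_ifr(fxk$profile, fxk$tr, "TGC"),
                 gene_ifr(fx$profile, fx$tr, "TGC"))
  }
})

test_that("frame counts cover the full profile mass on each codon span", {
  set.seed(7)
  tr <- toy_transcript(random_cds(50))
  aln <- random_alignments(tr, 400)
  ps <- build_profiles(aln, tr)
  cc <- codon_frame_counts(ps, tr)
  p <- ps[["tx1"]]
  for (r in sample(nrow(cc), 10)) {
    occ <- cc[r, ]
    # locate this occurrence's span via its row structure: sum of F equals
    # profile mass on the 3-nt span starting at the codon's first nt
    starts <- seq(0, 147, by = 3)
    trips <- substring(tr$sequence, starts + 1, starts + 3)
    pos <- starts[trips == occ$codon]
    spans <- vapply(pos, function(s) sum(p$counts[s + 1:3]), numeric(1))
    expect_true((occ$F0 + occ$F1 + occ$F2) %in% spans)
  }
})

test_that("global IFR is the unweighted mean over qualified genes", {
  # two genes engineered to IFR 0.6 and 0.8 for the same codon
  seq <- paste0("GG", "ATGTGCTAA", "GG")
  mk <- function(id, gene, f0, rest) {
    tr <- suppressWarnings(transcript_set(id, gene, seq, 2L, 11L))
    counts <- numeric(13); counts[5 + 1:3] <- c(f0, rest / 2, rest / 2)
    list(tr = tr, p = toy_profile(tr, counts))
  }
  a <- mk("t1", "g1", 12, 8)    # 12/20 = 0.6
  b <- mk("t2", "g2", 16, 4)    # 16/20 = 0.8
  ts <- suppressWarnings(transcript_set(c("t1", "t2"), c("g1", "g2"),
                                        c(seq, seq), c(2, 2), c(11, 11)))
  ps <- profile_set_of(a$p, b$p)
  g <- global_ifr(ps, ts)
  expect_equal(g$ifr_global[g$codon == "TGC"], 0.7)
  expect_equal(g$n_genes[g$codon == "TGC"], 2L)
  # single qualified gene -> identity; unqualified codons reported NA
  expect_true(is.na(g$ifr_global[g$codon == "AAA"]))
})

test_that("gene ACC is the mean normalized density at codon starts", {
  fx <- two_occurrence_fixture(list(c(0, 0, 0), c(0, 0, 0)))
  # uniform coverage: every codon present scores exactly 1
  p <- toy_profile(fx$tr, c(0, 0, rep(3, 21), 0, 0))
  n <- normalize_profile(p, fx$tr)
  for (cod in c("ATG", "GCC", "TGC", "AAA")) {
    expect_equal(gene_acc(n, fx$tr, cod), 1)
  }
  # two occurrences with normalized values 2 and 0 average to 1
  counts <- numeric(25)
  cds_pos <- 2:22
  counts[cds_pos + 1] <- 1            # baseline 1/nt
  counts[9] <- 2; counts[15] <- 0     # first nts of the two TGCs
  tr <- fx$tr
  n2 <- normalize_profile(toy_profile(tr, counts), tr)
  expect_equal(n2$cds_mean, 1)
  expect_equal(gene_acc(n2, tr, "TGC"), 1)
  expect_equal(attr(gene_acc(n2, tr, "CGT"), "reason"), "absent")
})

test_that("abundance-fidelity correlation is Spearman with NA handling", {
  st <- data.frame(ifr_global = (1:61) / 62, acc_global = exp((1:61) / 10))
  expect_equal(abundance_fidelity_correlation(st), 1)
  st$acc_global <- rev(st$acc_global)
  expect_equal(abundance_fidelity_correlation(st), -1)
  few <- data.frame(ifr_global = c(0.5, NA, 0.7, NA),
                    acc_global = c(1, 2, NA, NA))
  expect_true(is.na(abundance_fidelity_correlation(few)))
})

test_that("global IFR recovers the programmed frame-0 probability", {
  for (q0 in c(0.5, 0.7, 0.9)) {
    cfg <- sim_config(n_transcripts = 12L, cds_codons_range = c(80L, 120L),
                      dwell_multipliers = setNames(rep(1, 61), SENSE_CODONS),
                      frame_probs = c(q0, (1 - q0) / 2, (1 - q0) / 2),
                      reads_per_transcript = 4000L, seed = 900 + q0 * 10)
    g <- generate_transcriptome(cfg)
    aln <- simulate_reads(g$transcripts, cfg)
    ps <- build_profiles(aln, g$transcripts)
    ifr <- global_ifr(ps, g$transcripts)
    gt <- ground_truth_summary(cfg, g$transcripts)
    ok <- is.finite(ifr$ifr_global)
    expect_gt(sum(ok), 55)
    dev <- abs(ifr$ifr_global[ok] - q0)
    # per-codon bound at 4.5 SE (the 3-SE band is crossed by chance when 61
    # codons x 3 settings are compared), plus a tight cohort-mean check
    expect_true(all(dev < 1.5 * pmax(gt$ifr_tolerance[ifr$codon[ok]], 0.02)))
    expect_lt(abs(mean(ifr$ifr_global[ok]) - q0), 0.01)
  }
})

test_that("excluding the first 30 nt leaves downstream codon IFR unchanged", {
  # TGC occurs only beyond the first 30 nt of the CDS
  set.seed(8)
  body <- paste(rep(c("GCA", "AAA", "CCC"), 5), collapse = "")  # 45 nt, no TGC
  seqcds <- paste0("ATG", body, "TGCTGC", "TAA")
  tr <- toy_transcript(seqcds)
  counts <- numeric(nchar(seqcds))
  counts[48 + 1:6] <- c(9, 2, 1, 7, 1, 0)   # the two TGC spans (pos 48-53)
  p <- toy_profile(tr, counts)
  expect_equal(gene_ifr(p, tr, "TGC", exclude_first_nt = 30L),
               gene_ifr(p, tr, "TGC"))
  # while codons inside the excluded region disappear
  counts2 <- counts; counts2[1:3] <- c(20, 1, 1)
  p2 <- toy_profile(tr, counts2)
  r <- gene_ifr(p2, tr, "ATG", exclude_first_nt = 30L)
  expect_equal(attr(r, "reason"), "absent")
})
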