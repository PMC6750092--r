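test_that("longest-isoform selection orders by CDS, then 5'UTR, then 3'UTR", {
  # gene gA: CDS 300 vs 900 -> 900 wins; gene gB: equal CDS, 5'UTR decides;
  # gene gC: equal CDS and 5'UTR, 3'UTR decides; gene gD: single isoform.
  mk <- function(utr5, cds_codons, utr3) {
    paste0(strrep("C", utr5), random_cds(cds_codons), strrep("G", utr3))
  }
  set.seed(11)
  seqs <- c(mk(10, 100, 10), mk(10, 300, 10),
            mk(100, 50, 10), mk(50, 50, 10),
            mk(20, 50, 80), mk(20, 50, 30),
            mk(5, 40, 5))
  starts <- c(10, 10, 100, 50, 20, 20, 5)
  ends <- starts + c(300, 900, 150, 150, 150, 150, 120)
  ts <- transcript_set(paste0("t", 1:7),
                       c("gA", "gA", "gB", "gB", "gC", "gC", "gD"),
                       seqs, starts, ends)
  sel <- select_longest_isoforms(ts)
  expect_equal(nrow(sel), 4L)
  expect_setequal(sel$transcript_id, c("t2", "t3", "t5", "t7"))
})

test_that("isoform ties on all lengths break deterministically by id", {
  seq <- paste0(strrep("A", 9), random_cds(30), strrep("A", 9))
  ts <- transcript_set(c("tB", "tA"), c("g1", "g1"), c(seq, seq),
                       c(9, 9), c(99, 99))
  expect_equal(select_longest_isoforms(ts)$transcript_id, "tA")
})

test_that("codon enumeration tiles each frame and drops partial triplets", {
  tr <- toy_transcript("ATGGCATGC")
  expect_equal(enumerate_codons(tr, 0L)$triplet, c("ATG", "GCA", "TGC"))
  expect_equal(enumerate_codons(tr, 1L)$triplet, c("TGG", "CAT"))
  f2 <- enumerate_codons(tr, 2L)
  expect_equal(f2$triplet, c("GGC", "ATG"))
  expect_equal(f2$nt_position, c(2L, 5L))
  # degenerate: frame offset leaves no complete triplet
  tr3 <- toy_transcript("ATG")
  expect_equal(nrow(enumerate_codons(tr3, 1L)), 0L)
})

test_that("frame-wise codon list lengths are L, L-1, L-1", {
  set.seed(21)
  for (rep in 1:5) {
    L <- sample(2:60, 1)
    tr <- toy_transcript(random_cds(L))
    lens <- vapply(0:2, function(f) nrow(enumerate_codons(tr, f)), integer(1))
    expect_equal(lens, c(L, L - 1L, L - 1L))
  }
})

test_that("N-containing triplets are flagged", {
  tr <- toy_transcript("ATGGNATGCTAA")
  occ <- enumerate_codons(tr, 0L)
  expect_equal(occ$has_n, c(FALSE, TRUE, FALSE, FALSE))
})

test_that("sticky classification matches AUG-likeness under the CAU tail", {
  m <- sticky_model("CAU")
  expect_equal(m$center_codon, "ATG")
  expect_true(classify_sticky("AUC", m)$sticky)    # single mismatch
  expect_false(classify_sticky("GUC", m)$sticky)   # two mismatches
  expect_equal(classify_sticky("AUG", m)$mismatch, 0L)
  n <- classify_sticky("ANG", m)
  expect_false(n$sticky)
  expect_true(n$has_n)
})

test_that("the GCC-tail mutant makes GGC the zero-mismatch center", {
  m <- sticky_model("GCC")
  cl <- classify_sticky("GGC", m)
  expect_true(cl$sticky)
  expect_equal(cl$mismatch, 0L)
  expect_false(classify_sticky("ATG", m)$sticky)
})

test_that("exactly 10 sticky codons exist under the wild-type model", {
  s <- sticky_codons(sticky_model("CAU"))
  expect_length(s, 10L)
  expect_true("ATG" %in% s)
  # exhaustive: every member within Hamming 1 of ATG, every non-member not
  b <- c("A", "C", "G", "T")
  all64 <- as.vector(outer(outer(b, b, paste0), b, paste0))
  hd <- vapply(all64, function(x) {
    sum(strsplit(x, "")[[1]] != c("A", "T", "G"))
  }, numeric(1))
  expect_setequal(s, setdiff(all64[hd <= 1], STOP_CODONS))
})

test_that("tail and center codon pair base-by-base antiparallel for all 64 tails", {
  b <- c("A", "C", "G", "T")
  pairs <- c(A = "T", C = "G", G = "C", T = "A")
  for (tail in as.vector(outer(outer(b, b, paste0), b, paste0))) {
    center <- sticky_model(tail)$center_codon
    tl <- strsplit(tail, "")[[1]]
    ct <- strsplit(center, "")[[1]]
    # antiparallel: position i of the tail pairs position 4-i of the codon
    expect_equal(unname(pairs[tl]), rev(ct))
  }
})

# Independent brute-force window oracle: enumerate every stop triplet in the
# relevant frames and apply the window definition directly.
fs_window_oracle <- function(seq, ins_pos, shift) {
  n <- nchar(seq)
  sf <- if (shift == 1L) 1L else 2L
  stops_in <- function(frame) {
    s <- seq(frame, n - 3, by = 3)
    s[substring(seq, s + 1, s + 3) %in% c("TAA", "TAG", "TGA")]
  }
  up <- stops_in(sf); up <- up[up + 3 <= ins_pos]
  start <- if (length(up) == 0) 0L else 3L * ceiling((max(up) + 3) / 3)
  dn <- stops_in(0L); dn <- dn[dn >= ins_pos]
  end <- if (length(dn) == 0) n else min(dn)
  c(start = as.integer(start), end = as.integer(end))
}

test_that("frameshift window matches the brute-force stop-scan oracle", {
  set.seed(33)
  for (rep in 1:40) {
    seq <- paste(sample(c("A", "C", "G", "T"), 60, TRUE), collapse = "")
    ins <- sample(3:56, 1)
    shift <- sample(c(1L, -1L), 1)
    w <- find_fs_window(seq, ins, shift)
    o <- fs_window_oracle(seq, ins, shift)
    expect_equal(c(w$start, w$end), unname(o))
    expect_equal(w$length_codons, (o[["end"]] - o[["start"]]) %/% 3L)
  }
})

test_that("window falls back to the full span when no flanking stops exist", {
  seq <- strrep("GCA", 10)   # no stops in any frame
  w <- find_fs_window(seq, 15, 1L)
  expect_equal(w$start, 0L)
  expect_equal(w$end, 30L)
  expect_true(w$upstream_fallback && w$downstream_fallback)
  expect_error(find_fs_window(seq, 30, 1L), "outside")
})

test_that("per-codon rate divides the reporter rate by window size", {
  expect_equal(per_codon_rate(0.0052, 13), 0.0004)
  expect_equal(per_codon_rate(0.37, 1), 0.37)
  expect_equal(per_codon_rate(0, 7), 0)
  expect_error(per_codon_rate(0.01, 0))
})

test_that("CDS not divisible by 3 is rejected at load, not truncated", {
  expect_warning(ts <- transcript_set(c("a", "b"), c("gA", "gB"),
                                      c("ATGAAATAA", "ATGAAAT"),
                                      c(0, 0), c(9, 7)),
                 "divisible by 3")
  expect_equal(ts$transcript_id, "a")
})

test_that("FASTA + CDS TSV round-trip through the readers", {
  set.seed(44)
  seqs <- c(tx1 = paste0("CCCC", random_cds(20), "GGGG"),
            tx2 = paste0("AA", random_cds(10), "TT"))
  fa <- tempfile(fileext = ".fa")
  writeLines(c(">tx1 extra description", seqs[1], ">tx2", seqs[2]), fa)
  tsv <- tempfile(fileext = ".tsv")
  write.table(data.frame(transcript_id = c("tx1", "tx2"),
                         gene_id = c("g1", "g2"),
                         cds_start_1based = c(5L, 3L),
                         cds_end_1based = c(64L, 32L)),
              tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  ts <- read_transcripts(fa, tsv)
  expect_equal(ts["tx1", "cds_start"], 4L)
  expect_equal(ts["tx1", "cds_end"], 64L)
  expect_equal(substring(ts["tx1", "sequence"], 5, 7), "ATG")
  expect_equal(ts["tx2", "utr3_len"], 2L)
})
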