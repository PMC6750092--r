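# Frame-specific codon composition across a CDS set, shuffling null
# models (synonymous-codon, dinucleotide, unconstrained), the depletion
# randomization test, and sticky-codon position tracks.

# Frame-0 codon vector of one transcript's CDS (complete triplets).
cds_codons <- function(transcript) {
  triplets_at(transcript$sequence,
              triplet_starts(transcript$cds_start, transcript$cds_end, 0L))
}

# Per-frame occurrence counts of `codon` given a frame-0 codon vector.
# Frame-1 triplets join the last 2 nt of codon j with the first nt of
# codon j+1; frame-2 triplets the last nt of codon j with the first 2 nt
# of codon j+1.
count_codon_frames <- function(codons, codon) {
  k <- length(codons)
  if (k < 2L) {
    return(c(f0 = sum(codons == codon), f1 = 0L, f2 = 0L))
  }
  a <- codons[-k]; b <- codons[-1L]
  f1 <- paste0(substr(a, 2L, 3L), substr(b, 1L, 1L))
  f2 <- paste0(substr(a, 3L, 3L), substr(b, 1L, 2L))
  c(f0 = sum(codons == codon), f1 = sum(f1 == codon), f2 = sum(f2 == codon))
}

# All-codon frame counts for one codon vector: 64-row matrix of tallies.
all_codon_frame_counts <- function(codons) {
  k <- length(codons)
  lv <- c(SENSE_CODONS, STOP_CODONS)
  m <- matrix(0L, nrow = length(lv), ncol = 3L,
              dimnames = list(lv, c("f0", "f1", "f2")))
  m[, 1L] <- as.integer(table(factor(codons, levels = lv)))
  if (k >= 2L) {
    a <- codons[-k]; b <- codons[-1L]
    m[, 2L] <- as.integer(table(factor(
      paste0(substr(a, 2L, 3L), substr(b, 1L, 1L)), levels = lv)))
    m[, 3L] <- as.integer(table(factor(
      paste0(substr(a, 3L, 3L), substr(b, 1L, 2L)), levels = lv)))
  }
  m
}

#' Frame-specific codon fractions over a CDS set
#'
#' For each transcript, every sense codon is counted in the three reading
#' frames of its CDS (frames 1 and 2 tile from `cds_start + 1` / `+ 2`,
#' UTRs excluded, trailing partial triplets dropped). The codon's fraction
#' in frame f is its frame-f count divided by the sum of its counts over
#' the three frames. Per-gene fractions are computed first and then
#' averaged unweighted over the genes in which the codon occurs at all
#' (`pooled = TRUE` instead divides the pooled tallies).
#'
#' @param transcripts a [transcript_set] (typically the longest-isoform
#'   set).
#' @param pooled pool counts across genes instead of averaging per-gene
#'   fractions (default FALSE).
#' @return `data.frame` with 61 rows: `codon`, `frac0`, `frac1`, `frac2`,
#'   pooled tallies `count0..count2`, and `n_genes` (genes contributing to
#'   the average).
#' @export
frame_codon_fractions <- function(transcripts, pooled = FALSE) {
  lv <- c(SENSE_CODONS, STOP_CODONS)
  tot_counts <- matrix(0L, nrow = length(lv), ncol = 3L,
                       dimnames = list(lv, NULL))
  frac_sum <- matrix(0, nrow = length(lv), ncol = 3L,
                     dimnames = list(lv, NULL))
  n_genes <- setNames(integer(length(lv)), lv)
  for (i in seq_len(nrow(transcripts))) {
    m <- all_codon_frame_counts(cds_codons(transcripts[i, ]))
    tot_counts <- tot_counts + m
    rs <- rowSums(m)
    has <- rs > 0L
    frac_sum[has, ] <- frac_sum[has, ] + m[has, , drop = FALSE] / rs[has]
    n_genes[has] <- n_genes[has] + 1L
  }
  sense <- SENSE_CODONS
  if (pooled) {
    rs <- rowSums(tot_counts[sense, , drop = FALSE])
    fr <- tot_counts[sense, , drop = FALSE] / ifelse(rs > 0L, rs, NA_real_)
  } else {
    fr <- frac_sum[sense, , drop = FALSE] /
      ifelse(n_genes[sense] > 0L, n_genes[sense], NA_real_)
  }
  data.frame(codon = sense,
             frac0 = fr[, 1L], frac1 = fr[, 2L], frac2 = fr[, 3L],
             count0 = tot_counts[sense, 1L],
             count1 = tot_counts[sense, 2L],
             count2 = tot_counts[sense, 3L],
             n_genes = as.integer(n_genes[sense]),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Shuffle a CDS under a composition null model
#'
#' Three nulls that preserve different aspects of frame-0 codon usage
#' while randomizing the triplets read in frames 1 and 2:
#' * `"synonymous_codon"`: codon occurrences are permuted uniformly at
#'   random within synonymous families, so the protein sequence, the codon
#'   multiset, GC content and all frame-0 codon fractions are preserved
#'   exactly;
#' * `"dinucleotide"`: the leading dinucleotides of all shuffled codons
#'   are permuted across positions with third positions fixed in place;
#' * `"codon_free"`: whole codons are permuted without constraint.
#'
#' The terminal stop codon is never moved (relocating a stop into the
#' interior would truncate the frame-0 reading). Randomness comes from R's
#' RNG; seed with [set.seed()] (or via [randomization_test()]).
#'
#' @param cds CDS nucleotide string, length divisible by 3.
#' @param mode one of `"synonymous_codon"`, `"dinucleotide"`,
#'   `"codon_free"`.
#' @return the shuffled CDS string.
#' @export
shuffle_cds <- function(cds, mode = c("synonymous_codon", "dinucleotide",
                                      "codon_free")) {
  mode <- match.arg(mode)
  cds <- normalize_seq(cds)
  if (nchar(cds) %% 3L != 0L) stop("CDS length must be divisible by 3")
  codons <- triplets_at(cds, triplet_starts(0L, nchar(cds), 0L))
  paste(shuffle_codons(codons, mode), collapse = "")
}

# Codon-vector version used by shuffle_cds and the randomization test.
shuffle_codons <- function(codons, mode) {
  k <- length(codons)
  if (k <= 1L) return(codons)
  movable <- seq_len(k)
  if (codons[k] %in% STOP_CODONS) movable <- movable[-k]
  if (length(movable) <= 1L) return(codons)
  if (mode == "synonymous_codon") {
    aa <- translate_codons(codons[movable])
    for (fam in unique(aa)) {
      idx <- movable[aa == fam]
      if (length(idx) > 1L) codons[idx] <- codons[sample(idx)]
    }
  } else if (mode == "dinucleotide") {
    lead <- substr(codons[movable], 1L, 2L)
    third <- substr(codons[movable], 3L, 3L)
    codons[movable] <- paste0(lead[sample(length(lead))], third)
  } else {
    codons[movable] <- codons[sample(movable)]
  }
  codons
}

#' Shuffling randomization test of a frame-specific codon fraction
#'
#' Compares the observed gene-averaged fraction of `codon` in `frame`
#' (per [frame_codon_fractions()]) against its distribution over `n_reps`
#' CDS sets in which every transcript's frame-0 codons were shuffled under
#' `mode`. Reports the z-score `(obs - null mean) / null SD` and the
#' one-sided empirical p-value for depletion,
#' `(1 + #\{null <= obs\}) / (n_reps + 1)` (use
#' `alternative = "greater"` for enrichment).
#'
#' All randomness derives from `seed`; a fixed seed gives bit-identical
#' null fractions.
#'
#' @param transcripts a [transcript_set].
#' @param codon triplet under test (U accepted).
#' @param frame 0, 1 or 2.
#' @param n_reps number of shuffled CDS sets (default 100).
#' @param mode shuffle mode, see [shuffle_cds()].
#' @param seed RNG seed (mandatory).
#' @param alternative `"less"` (depletion, default), `"greater"`, or
#'   `"two.sided"`.
#' @return object of class `shuffle_null`: list with `codon`, `frame`,
#'   `mode`, `observed_fraction`, `null_fractions`, `z` (NA when the null
#'   SD is 0), `p_empirical`, `seed`.
#' @export
randomization_test <- function(transcripts, codon = "ATG", frame = 2L,
                               n_reps = 100L, mode = "synonymous_codon",
                               seed, alternative = c("less", "greater",
                                                     "two.sided")) {
  if (missing(seed)) stop("seed is mandatory")
  alternative <- match.arg(alternative)
  stopifnot(is_count(n_reps), n_reps >= 2L, frame %in% 0:2)
  codon <- normalize_seq(codon)
  codon_vecs <- lapply(seq_len(nrow(transcripts)),
                       function(i) cds_codons(transcripts[i, ]))

  gene_avg_fraction <- function(vecs) {
    fr <- vapply(vecs, function(cv) {
      cnt <- count_codon_frames(cv, codon)
      tot <- sum(cnt)
      if (tot == 0L) NA_real_ else cnt[[frame + 1L]] / tot
    }, numeric(1))
    mean(fr, na.rm = TRUE)
  }

  observed <- gene_avg_fraction(codon_vecs)
  set.seed(as.integer(seed))
  null_fr <- vapply(seq_len(n_reps), function(r) {
    gene_avg_fraction(lapply(codon_vecs, shuffle_codons, mode = mode))
  }, numeric(1))

  mu <- mean(null_fr); s <- sd(null_fr)
  z <- if (s > 0) (observed - mu) / s else NA_real_
  p <- switch(alternative,
    less = (1 + sum(null_fr <= observed)) / (n_reps + 1),
    greater = (1 + sum(null_fr >= observed)) / (n_reps + 1),
    two.sided = min(1, 2 * min(
      (1 + sum(null_fr <= observed)) / (n_reps + 1),
      (1 + sum(null_fr >= observed)) / (n_reps + 1))))
  structure(list(codon = codon, frame = as.integer(frame), mode = mode,
                 observed_fraction = observed, null_fractions = null_fr,
                 z = z, p_empirical = p, seed = as.integer(seed),
                 alternative = alternative),
            class = "shuffle_null")
}

#' @export
print.shuffle_null <- function(x, ...) {
  cat(sprintf(
    "shuffle null (%s, %d reps): %s frame %d fraction %.4g vs null %.4g +/- %.2g\n  z = %.3g, empirical p (%s) = %.4g\n",
    x$mode, length(x$null_fractions), as_rna(x$codon), x$frame,
    x$observed_fraction, mean(x$null_fractions), sd(x$null_fractions),
    x$z, x$alternative, x$p_empirical))
  invisible(x)
}

#' Sticky-codon positions in the three reading frames
#'
#' For track plots and density summaries: the ordered transcript
#' coordinates of sticky-classified codons in each frame of the CDS,
#' optionally with per-kb densities on either side of a breakpoint (e.g. a
#' programmed frameshift site).
#'
#' @param transcript one transcript row.
#' @param model a [sticky_model].
#' @param breakpoint optional 0-based transcript coordinate splitting the
#'   CDS for the density summary.
#' @return list with `positions` (list of three integer vectors, frames
#'   0-2) and, when `breakpoint` is given, `density_per_kb` (a 3 x 2
#'   matrix of sticky codons per kb before/after the breakpoint, rows =
#'   frames).
#' @export
sticky_track <- function(transcript, model = sticky_model(),
                         breakpoint = NULL) {
  pos <- lapply(0:2, function(f) {
    occ <- enumerate_codons(transcript, f)
    occ <- occ[!occ$has_n, , drop = FALSE]
    occ$nt_position[classify_sticky(occ$triplet, model)$sticky]
  })
  names(pos) <- paste0("frame", 0:2)
  out <- list(positions = pos)
  if (!is.null(breakpoint)) {
    span <- c(transcript$cds_start, transcript$cds_end)
    stopifnot(breakpoint > span[1], breakpoint < span[2])
    len_before <- breakpoint - span[1]
    len_after <- span[2] - breakpoint
    d <- t(vapply(pos, function(p) {
      c(before = 1000 * sum(p < breakpoint) / len_before,
        after = 1000 * sum(p >= breakpoint) / len_after)
    }, numeric(2)))
    out$density_per_kb <- d
    out$breakpoint <- breakpoint
  }
  out
}

#' Write a sticky-codon track as a BED-like TSV
#'
#' @param transcript one transcript row.
#' @param model a [sticky_model].
#' @param path output file; columns transcript_id, start, end, triplet,
#'   frame.
#' @export
write_sticky_track <- function(transcript, path, model = sticky_model()) {
  rows <- do.call(rbind, lapply(0:2, function(f) {
    occ <- enumerate_codons(transcript, f)
    occ <- occ[!occ$has_n, , drop = FALSE]
    occ <- occ[classify_sticky(occ$triplet, model)$sticky, , drop = FALSE]
    if (nrow(occ) == 0L) return(NULL)
    data.frame(transcript_id = occ$transcript_id, start = occ$nt_position,
               end = occ$nt_position + 3L, triplet = occ$triplet,
               frame = occ$frame, stringsAsFactors = FALSE)
  }))
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(rows)
}
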