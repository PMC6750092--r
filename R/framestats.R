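# Codon-stratified fidelity statistics: the in-frame rate (IFR) and the
# average codon coverage score (ACCscore), per gene and averaged over
# genes, plus the rank correlation coupling abundance and fidelity.
#
# For a frame-0 occurrence m of a codon, F_m0 is the count at the codon's
# first nucleotide of the profiled site and F_m1/F_m2 the counts at +1 and
# +2 nt. IFR(codon, gene) = sum_m F_m0 / sum_m (F_m0 + F_m1 + F_m2);
# ACC(codon, gene) = mean over occurrences of the CDS-normalized count at
# the codon's first nucleotide.

# Per-(transcript, codon) frame-wise count sums for one profile.
# exclude_first_nt drops codon occurrences starting within that many nt of
# the CDS start.
codon_frame_counts_one <- function(profile, transcript,
                                   exclude_first_nt = 0L) {
  starts <- triplet_starts(transcript$cds_start, transcript$cds_end, 0L)
  if (exclude_first_nt > 0L) {
    starts <- starts[starts >= transcript$cds_start + exclude_first_nt]
  }
  if (length(starts) == 0L) return(NULL)
  trips <- triplets_at(transcript$sequence, starts)
  ok <- !grepl("N", trips, fixed = TRUE)
  starts <- starts[ok]; trips <- trips[ok]
  if (length(starts) == 0L) return(NULL)
  data.frame(transcript_id = transcript$transcript_id,
             codon = trips,
             F0 = profile$counts[starts + 1L],
             F1 = profile$counts[starts + 2L],
             F2 = profile$counts[starts + 3L],
             stringsAsFactors = FALSE)
}

#' Frame-wise footprint counts per codon occurrence
#'
#' For every frame-0 codon occurrence of every transcript, the profile
#' counts at the occurrence's three frame positions (first nucleotide, +1,
#' +2). Occurrences are complete triplets inside the CDS, so no occurrence
#' ever leaves the CDS span; triplets containing N are excluded.
#'
#' @param profiles a `profile_set` (raw counts for IFR, normalized for ACC).
#' @param transcripts the matching [transcript_set].
#' @param exclude_first_nt drop codon occurrences starting within this many
#'   nt of the CDS start (default 0; 30 reproduces the
#'   first-30-nt-excluded sensitivity analysis).
#' @return `data.frame` with columns `transcript_id`, `codon`, `F0`, `F1`,
#'   `F2`, one row per occurrence.
#' @export
codon_frame_counts <- function(profiles, transcripts, exclude_first_nt = 0L) {
  out <- do.call(rbind, lapply(seq_len(nrow(transcripts)), function(i) {
    codon_frame_counts_one(profiles[[transcripts$transcript_id[i]]],
                           transcripts[i, ], exclude_first_nt)
  }))
  if (is.null(out)) {
    out <- data.frame(transcript_id = character(0), codon = character(0),
                      F0 = numeric(0), F1 = numeric(0), F2 = numeric(0))
  }
  out
}

#' Per-gene in-frame rate of one codon
#'
#' @param profile raw-count `positional_profile` for the gene's transcript.
#' @param transcript the matching transcript row.
#' @param codon a sense triplet (U accepted).
#' @param min_reads minimum summed reads across the codon's three frame
#'   positions for the gene to qualify (default 10).
#' @param exclude_first_nt see [codon_frame_counts()].
#' @return the IFR in `[0, 1]`, or `NA` with attribute `reason` equal to
#'   `"absent"` (codon not in the CDS) or `"below_threshold"`.
#' @export
gene_ifr <- function(profile, transcript, codon, min_reads = 10,
                     exclude_first_nt = 0L) {
  stopifnot(!profile$normalized)
  codon <- normalize_seq(codon)
  cc <- codon_frame_counts_one(profile, transcript, exclude_first_nt)
  cc <- cc[cc$codon == codon, , drop = FALSE]
  if (is.null(cc) || nrow(cc) == 0L) {
    return(structure(NA_real_, reason = "absent"))
  }
  tot <- sum(cc$F0 + cc$F1 + cc$F2)
  if (tot < min_reads) {
    return(structure(NA_real_, reason = "below_threshold"))
  }
  sum(cc$F0) / tot
}

#' Per-gene average codon coverage score of one codon
#'
#' @param profile_normalized CDS-normalized `positional_profile`.
#' @param transcript the matching transcript row.
#' @param codon sense triplet.
#' @param exclude_first_nt see [codon_frame_counts()].
#' @return the ACC score (>= 0), or `NA` (attribute `reason`) when the
#'   codon is absent or the profile is excluded for zero CDS coverage.
#' @export
gene_acc <- function(profile_normalized, transcript, codon,
                     exclude_first_nt = 0L) {
  stopifnot(profile_normalized$normalized || profile_normalized$excluded)
  if (profile_normalized$excluded) {
    return(structure(NA_real_, reason = "excluded_profile"))
  }
  codon <- normalize_seq(codon)
  cc <- codon_frame_counts_one(profile_normalized, transcript,
                               exclude_first_nt)
  cc <- cc[cc$codon == codon, , drop = FALSE]
  if (is.null(cc) || nrow(cc) == 0L) {
    return(structure(NA_real_, reason = "absent"))
  }
  mean(cc$F0)
}

# Gene-level IFR table: one row per (transcript, codon) that passes the
# read threshold.
gene_ifr_table <- function(profiles, transcripts, min_reads = 10,
                           exclude_first_nt = 0L) {
  cc <- codon_frame_counts(profiles, transcripts, exclude_first_nt)
  if (nrow(cc) == 0L) return(cc)
  key <- paste(cc$transcript_id, cc$codon, sep = "\r")
  f0 <- rowsum(cc$F0, key)
  tot <- rowsum(cc$F0 + cc$F1 + cc$F2, key)
  parts <- strsplit(rownames(f0), "\r", fixed = TRUE)
  out <- data.frame(
    transcript_id = vapply(parts, `[`, "", 1L),
    codon = vapply(parts, `[`, "", 2L),
    reads = as.numeric(tot),
    ifr = as.numeric(f0) / as.numeric(tot),
    stringsAsFactors = FALSE
  )
  out[out$reads >= min_reads & is.finite(out$ifr), , drop = FALSE]
}

# Gene-level ACC table (normalized profiles; excluded profiles dropped).
gene_acc_table <- function(profiles_normalized, transcripts,
                           exclude_first_nt = 0L) {
  usable <- vapply(profiles_normalized, function(p) !p$excluded, logical(1))
  keep <- transcripts$transcript_id %in%
    names(profiles_normalized)[usable]
  cc <- codon_frame_counts(profiles_normalized,
                           transcripts[keep, , drop = FALSE],
                           exclude_first_nt)
  if (nrow(cc) == 0L) {
    return(data.frame(transcript_id = character(0), codon = character(0),
                      k = numeric(0), acc = numeric(0)))
  }
  key <- paste(cc$transcript_id, cc$codon, sep = "\r")
  s <- rowsum(cc$F0, key)
  k <- rowsum(rep(1, nrow(cc)), key)
  parts <- strsplit(rownames(s), "\r", fixed = TRUE)
  data.frame(
    transcript_id = vapply(parts, `[`, "", 1L),
    codon = vapply(parts, `[`, "", 2L),
    k = as.numeric(k),
    acc = as.numeric(s) / as.numeric(k),
    stringsAsFactors = FALSE
  )
}

#' Global per-codon in-frame rate
#'
#' Per-gene IFRs (genes below the read threshold disregarded) averaged
#' unweighted over qualifying genes, one row per sense codon. Codons with
#' zero qualifying genes are reported as `NA`, never as 0.
#'
#' @inheritParams gene_ifr
#' @param profiles raw-count `profile_set`.
#' @param transcripts the matching [transcript_set].
#' @param weight_by_reads weight gene IFRs by their read totals instead of
#'   averaging unweighted (default FALSE).
#' @return `data.frame` with 61 rows: `codon`, `n_genes`, `ifr_global`.
#' @export
global_ifr <- function(profiles, transcripts, min_reads = 10,
                       exclude_first_nt = 0L, weight_by_reads = FALSE) {
  g <- gene_ifr_table(profiles, transcripts, min_reads, exclude_first_nt)
  g <- g[g$codon %in% SENSE_CODONS, , drop = FALSE]
  out <- data.frame(codon = SENSE_CODONS, n_genes = 0L,
                    ifr_global = NA_real_, stringsAsFactors = FALSE)
  if (nrow(g) > 0L) {
    w <- if (weight_by_reads) g$reads else rep(1, nrow(g))
    num <- rowsum(g$ifr * w, g$codon)
    den <- rowsum(w, g$codon)
    n <- table(g$codon)
    idx <- match(rownames(num), out$codon)
    out$ifr_global[idx] <- as.numeric(num) / as.numeric(den)
    out$n_genes[idx] <- as.integer(n[rownames(num)])
  }
  out
}

#' Global per-codon average codon coverage score
#'
#' Per-gene ACC scores averaged unweighted over genes with usable
#' (nonzero-coverage) profiles.
#'
#' @param profiles_normalized normalized `profile_set`.
#' @param transcripts the matching [transcript_set].
#' @param exclude_first_nt see [codon_frame_counts()].
#' @return `data.frame` with 61 rows: `codon`, `n_genes`, `acc_global`.
#' @export
global_acc <- function(profiles_normalized, transcripts,
                       exclude_first_nt = 0L) {
  g <- gene_acc_table(profiles_normalized, transcripts, exclude_first_nt)
  g <- g[g$codon %in% SENSE_CODONS, , drop = FALSE]
  out <- data.frame(codon = SENSE_CODONS, n_genes = 0L,
                    acc_global = NA_real_, stringsAsFactors = FALSE)
  if (nrow(g) > 0L) {
    m <- rowsum(g$acc, g$codon)
    n <- table(g$codon)
    idx <- match(rownames(m), out$codon)
    out$acc_global[idx] <- as.numeric(m) / as.numeric(n[rownames(m)])
    out$n_genes[idx] <- as.integer(n[rownames(m)])
  }
  out
}

#' Joint per-codon IFR/ACC table for one profiled site
#'
#' Builds raw and normalized profiles at the given site offset and returns
#' the 61-row codon table combining [global_ifr()] and [global_acc()].
#'
#' @param alignments alignment `data.frame`.
#' @param transcripts a [transcript_set].
#' @param site `"fiveprime"` (offset 0), `"P"` (12), `"A"` (15), or a
#'   numeric offset.
#' @param min_reads per-(gene, codon) read threshold for IFR (default 10).
#' @param length_range read-length window, default `c(25, 35)`.
#' @param exclude_first_nt see [codon_frame_counts()].
#' @return `data.frame`: `codon`, `site`, `n_genes`, `ifr_global`,
#'   `acc_global`.
#' @export
codon_stats <- function(alignments, transcripts,
                        site = c("fiveprime", "P", "A"),
                        min_reads = 10, length_range = c(25L, 35L),
                        exclude_first_nt = 0L) {
  offset <- if (is.numeric(site)) as.integer(site) else
    switch(match.arg(site), fiveprime = 0L, P = 12L, A = 15L)
  raw <- build_profiles(alignments, transcripts, site_offset = offset,
                        length_range = length_range)
  norm <- normalize_profiles(raw, transcripts)
  ifr <- global_ifr(raw, transcripts, min_reads, exclude_first_nt)
  acc <- global_acc(norm, transcripts, exclude_first_nt)
  data.frame(codon = ifr$codon,
             site = if (is.numeric(site)) paste0("offset", offset) else
               match.arg(site),
             n_genes = ifr$n_genes,
             ifr_global = ifr$ifr_global,
             acc_global = acc$acc_global,
             stringsAsFactors = FALSE)
}

#' Rank correlation between footprint abundance and frame fidelity
#'
#' Spearman correlation (average ranks for ties) between the global ACC
#' score and the global IFR across sense codons, the coupling statistic
#' relating ribosome dwell to reading-frame maintenance.
#'
#' @param stats a [codon_stats()] table (or any `data.frame` with
#'   `ifr_global` and `acc_global`).
#' @return Spearman's rho, or `NA` when fewer than 3 codons carry both
#'   statistics.
#' @export
abundance_fidelity_correlation <- function(stats) {
  ok <- is.finite(stats$ifr_global) & is.finite(stats$acc_global)
  if (sum(ok) < 3L) return(NA_real_)
  cor(stats$acc_global[ok], stats$ifr_global[ok], method = "spearman")
}

#' Write a codon-stats table to TSV
#' @param stats a [codon_stats()] table.
#' @param path output file.
#' @param rna report codons with U instead of T.
#' @export
write_codon_stats <- function(stats, path, rna = FALSE) {
  if (rna) stats$codon <- as_rna(stats$codon)
  write.table(stats, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
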