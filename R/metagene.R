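# Frame-stratified metagene aggregation around selected codon occurrences,
# +12 nt pause classification, and regional frame-ratio summaries.

#' Locate an anchor codon on a transcript
#'
#' Anchor rules select one frame-0 occurrence of a triplet per transcript:
#' * `"start"` -- the annotated start codon (position `cds_start`,
#'   whatever its triplet);
#' * `"first_internal"` -- the first occurrence at codon index >= 2;
#' * `"nth_internal"` -- the `n`-th occurrence at codon index >= 2;
#' * `"nth"` -- the `n`-th occurrence counting from the start codon;
#' * `"last"` -- the last internal occurrence (equal to `first_internal`
#'   when there is exactly one).
#'
#' @param transcript one transcript row.
#' @param triplet anchor codon (U accepted), ignored for rule `"start"`.
#' @param rule see above.
#' @param n occurrence number for the `nth*` rules.
#' @return 0-based transcript coordinate of the anchor's first nucleotide,
#'   or `NA` when the transcript has no such occurrence.
#' @export
anchor_position <- function(transcript, triplet = "ATG",
                            rule = c("first_internal", "start",
                                     "nth_internal", "nth", "last"),
                            n = 1L) {
  rule <- match.arg(rule)
  if (rule == "start") return(transcript$cds_start)
  triplet <- normalize_seq(triplet)
  occ <- enumerate_codons(transcript, 0L)
  hits <- occ$nt_position[occ$triplet == triplet & !occ$has_n]
  internal <- occ$nt_position[occ$triplet == triplet & !occ$has_n &
                                occ$codon_index >= 2L]
  pos <- switch(rule,
    first_internal = if (length(internal) >= 1L) internal[1L] else NA,
    nth_internal = if (length(internal) >= n) internal[n] else NA,
    nth = if (length(hits) >= n) hits[n] else NA,
    last = if (length(internal) >= 1L) internal[length(internal)] else NA)
  if (is.na(pos)) NA_integer_ else as.integer(pos)
}

#' Frame-stratified metagene profile aligned at a codon
#'
#' Normalized profiles are aligned at the anchor's first nucleotide and
#' averaged position-wise (unweighted across transcripts) over a window of
#' `window[2] - window[1]` nucleotides, default `[-30, +60)` (90 nt).
#' Each window position belongs to one frame series: frames are labelled
#' relative to the annotated CDS frame, and because anchors sit at frame-0
#' codon starts the frame of relative position `r` is `r mod 3`.
#' Transcripts are skipped when the anchor is missing, the window leaves
#' the transcript, or the profile is excluded for zero CDS coverage.
#'
#' @param profiles_normalized normalized `profile_set`.
#' @param transcripts the matching [transcript_set].
#' @param triplet,rule,n anchor selection, see [anchor_position()].
#' @param window integer pair, half-open relative window (default
#'   `c(-30, 60)`).
#' @return object of class `metagene_profile`: a `data.frame` with columns
#'   `rel_pos`, `frame`, `mean_density`, `n`, plus attribute
#'   `n_transcripts`.
#' @export
metagene_profile <- function(profiles_normalized, transcripts,
                             triplet = "ATG", rule = "first_internal",
                             n = 1L, window = c(-30L, 60L)) {
  rel <- seq.int(window[1], window[2] - 1L)
  acc <- numeric(length(rel))
  used <- 0L
  for (i in seq_len(nrow(transcripts))) {
    tr <- transcripts[i, ]
    p <- profiles_normalized[[tr$transcript_id]]
    if (is.null(p) || p$excluded) next
    a <- anchor_position(tr, triplet, rule, n)
    if (is.na(a)) next
    lo <- a + window[1]; hi <- a + window[2] - 1L
    if (lo < 0L || hi >= length(p$counts)) next
    acc <- acc + p$counts[(lo + 1L):(hi + 1L)]
    used <- used + 1L
  }
  if (used == 0L) {
    warning("no transcript contributed to the metagene window")
    md <- rep(NA_real_, length(rel))
  } else {
    md <- acc / used
  }
  out <- data.frame(rel_pos = rel,
                    frame = ((rel %% 3L) + 3L) %% 3L,
                    mean_density = md,
                    n = used)
  attr(out, "n_transcripts") <- used
  class(out) <- c("metagene_profile", "data.frame")
  out
}

#' Classify a transcript as pausing or non-pausing at anchor +12 nt
#'
#' A transcript pauses at the anchor when the normalized density 12 nt
#' downstream of the anchor's first nucleotide is strictly greater than
#' 1.0, the CDS average after normalization (a value of exactly 1.0 is
#' non-pausing).
#'
#' @param profile_normalized normalized `positional_profile`.
#' @param transcript the matching transcript row.
#' @param triplet,rule,n anchor selection, see [anchor_position()].
#' @param peak_offset nt downstream of the anchor to inspect (default 12).
#' @return `"pausing"`, `"non_pausing"`, or `"unclassified"` (anchor
#'   missing, out of range, or excluded profile).
#' @export
classify_pause <- function(profile_normalized, transcript, triplet = "ATG",
                           rule = "first_internal", n = 1L,
                           peak_offset = 12L) {
  if (profile_normalized$excluded) return("unclassified")
  a <- anchor_position(transcript, triplet, rule, n)
  if (is.na(a)) return("unclassified")
  pos <- a + peak_offset
  if (pos < 0L || pos >= length(profile_normalized$counts)) {
    return("unclassified")
  }
  if (profile_normalized$counts[pos + 1L] > 1.0) "pausing" else "non_pausing"
}

#' Frame composition of footprint counts in regions around an anchor
#'
#' Pools raw site-anchored counts across transcripts within each region
#' (nt intervals relative to the anchor's first nucleotide, closed on both
#' ends) and reports the fraction falling in each CDS frame. The default
#' regions compare 30 nt upstream against 60 nt downstream of the anchor,
#' excluding the anchor's own first nucleotide.
#'
#' @param profiles_raw raw-count `profile_set`.
#' @param transcripts the matching [transcript_set].
#' @param triplet,rule,n anchor selection, see [anchor_position()].
#' @param regions named list of closed nt intervals relative to the
#'   anchor, restricted per transcript to the CDS.
#' @return `data.frame` with one row per region: `region`, `f0`, `f1`,
#'   `f2` (NA when the region has no reads), `reads`, `n_transcripts`.
#' @export
region_frame_ratio <- function(profiles_raw, transcripts, triplet = "ATG",
                               rule = "first_internal", n = 1L,
                               regions = list(upstream = c(-30L, -1L),
                                              downstream = c(1L, 60L))) {
  res <- lapply(names(regions), function(rn) {
    iv <- regions[[rn]]
    fcount <- c(0, 0, 0)
    used <- 0L
    for (i in seq_len(nrow(transcripts))) {
      tr <- transcripts[i, ]
      p <- profiles_raw[[tr$transcript_id]]
      if (is.null(p)) next
      a <- anchor_position(tr, triplet, rule, n)
      if (is.na(a)) next
      lo <- max(a + iv[1], tr$cds_start)
      hi <- min(a + iv[2], tr$cds_end - 1L)
      if (lo > hi) next
      pos <- lo:hi
      fr <- (pos - tr$cds_start) %% 3L
      cnt <- p$counts[pos + 1L]
      fcount <- fcount + c(sum(cnt[fr == 0L]), sum(cnt[fr == 1L]),
                           sum(cnt[fr == 2L]))
      used <- used + 1L
    }
    tot <- sum(fcount)
    data.frame(region = rn,
               f0 = if (tot > 0) fcount[1] / tot else NA_real_,
               f1 = if (tot > 0) fcount[2] / tot else NA_real_,
               f2 = if (tot > 0) fcount[3] / tot else NA_real_,
               reads = tot, n_transcripts = used,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
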