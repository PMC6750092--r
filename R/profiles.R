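# Position-specific footprint profiles: alignment readers (TSV and
# SAM/BAM), per-nucleotide count vectors anchored at a chosen in-read site,
# CDS-mean normalization, and fixed-offset shifting.

#' Read footprint alignments from a plain TSV
#'
#' Columns: `transcript_id`, `five_prime_pos` (0-based transcript
#' coordinate of the read 5' end), `read_length`, and optionally `unique`
#' (logical/0-1, defaults to TRUE).
#'
#' @param path TSV file with header.
#' @return `data.frame` of alignments.
#' @export
read_alignments_tsv <- function(path) {
  aln <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  need <- c("transcript_id", "five_prime_pos", "read_length")
  if (!all(need %in% names(aln))) {
    stop("alignment TSV must have columns: ", paste(need, collapse = ", "))
  }
  if (is.null(aln$unique)) aln$unique <- TRUE
  aln$unique <- as.logical(aln$unique)
  aln[, c("transcript_id", "five_prime_pos", "read_length", "unique")]
}

#' Read footprint alignments from SAM/BAM (transcriptome coordinates)
#'
#' Uses Rsamtools; SAM input is converted to BAM on the fly. Only
#' forward-strand, mapped reads are kept (footprints are sequenced from the
#' sense strand of the transcript). Reads whose CIGAR contains indels or
#' skips are dropped and tallied: ribosome footprints are ungapped in
#' transcript space, so a gapped alignment is an artifact. Soft-clipped
#' bases are excluded from the 5'-end definition -- the aligned 5' terminus
#' is used, which is what `pos` already reports. Uniqueness is taken from
#' the NH tag when present (NH == 1), otherwise from MAPQ > 3.
#'
#' @param path SAM or BAM file of alignments against transcript sequences.
#' @return `data.frame` of alignments as in [read_alignments_tsv()], with
#'   attribute `n_gapped` counting dropped gapped reads.
#' @export
read_alignments_sam <- function(path) {
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    path <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                             indexDestination = FALSE)
  }
  p <- Rsamtools::ScanBamParam(
    what = c("rname", "pos", "cigar", "strand", "mapq", "flag"),
    tag = "NH",
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isMinusStrand = FALSE))
  b <- Rsamtools::scanBam(path, param = p)[[1L]]
  gapped <- grepl("[IDNHP]", b$cigar)
  qlen <- vapply(strsplit(gsub("([0-9]+)([MIDNSHP=X])", "\\1.\\2 ", b$cigar),
                          " ", fixed = TRUE),
                 function(ops) {
                   ops <- ops[nzchar(ops)]
                   n <- as.integer(sub("\\..*$", "", ops))
                   type <- sub("^.*\\.", "", ops)
                   sum(n[type %in% c("M", "=", "X")])
                 }, integer(1))
  nh <- b$tag$NH
  uniq <- if (!is.null(nh) && !all(is.na(nh))) {
    ifelse(is.na(nh), b$mapq > 3L, nh == 1L)
  } else b$mapq > 3L
  out <- data.frame(
    transcript_id = as.character(b$rname),
    five_prime_pos = b$pos - 1L,          # SAM 1-based -> 0-based
    read_length = qlen,
    unique = uniq,
    stringsAsFactors = FALSE
  )[!gapped, , drop = FALSE]
  attr(out, "n_gapped") <- sum(gapped)
  out
}

new_profile <- function(transcript_id, counts, site_offset, length_range,
                        normalized = FALSE, cds_mean = NA_real_,
                        excluded = FALSE) {
  structure(list(transcript_id = transcript_id, counts = counts,
                 site_offset = site_offset, length_range = length_range,
                 normalized = normalized, cds_mean = cds_mean,
                 excluded = excluded),
            class = "positional_profile")
}

#' @export
print.positional_profile <- function(x, ...) {
  cat(sprintf(
    "positional profile for %s: %d nt, offset +%d, lengths [%d,%d], %s%s\n",
    x$transcript_id, length(x$counts), x$site_offset,
    x$length_range[1], x$length_range[2],
    if (x$normalized) sprintf("normalized (CDS mean %.3g)", x$cds_mean)
    else "raw counts",
    if (x$excluded) ", EXCLUDED (zero CDS coverage)" else ""))
  invisible(x)
}

#' Build position-specific profiles from footprint alignments
#'
#' Each qualifying read increments the count at
#' `five_prime_pos + site_offset` on its transcript. Offset 0 profiles the
#' 5'-end codon; 12 the P-site; 15 the A-site (P-site plus one codon).
#' Reads are skipped (and tallied) when multimapped (`unique == FALSE`,
#' unless `include_multi`), outside `length_range`, mapped to an unknown
#' transcript, or when the anchored position falls off the transcript.
#'
#' @param alignments `data.frame` from [read_alignments_tsv()] /
#'   [read_alignments_sam()] / [simulate_reads()].
#' @param transcripts a [transcript_set].
#' @param site_offset nucleotides added to the 5' end to define the
#'   profiled site (default 0).
#' @param length_range inclusive read-length window, default `c(25, 35)`.
#' @param include_multi include multimapped reads with weight divided
#'   evenly (weight `1/NH` is not available from the TSV path, so each
#'   multimapped record gets weight 1; default FALSE, i.e. excluded).
#' @return a named list of [positional_profile][build_profiles] objects
#'   (class `profile_set`) with attribute `skipped`, a named count vector.
#' @export
build_profiles <- function(alignments, transcripts, site_offset = 0L,
                           length_range = c(25L, 35L),
                           include_multi = FALSE) {
  stopifnot(inherits(transcripts, "transcript_set"))
  site_offset <- as.integer(site_offset)
  known <- alignments$transcript_id %in% transcripts$transcript_id
  in_len <- alignments$read_length >= length_range[1] &
    alignments$read_length <= length_range[2]
  uniq_ok <- if (include_multi) rep(TRUE, nrow(alignments)) else
    alignments$unique
  keep <- known & in_len & uniq_ok
  aln <- alignments[keep, , drop = FALSE]

  tlen <- setNames(nchar(transcripts$sequence), transcripts$transcript_id)
  pos <- aln$five_prime_pos + site_offset
  in_bounds <- pos >= 0L & pos < tlen[aln$transcript_id] &
    aln$five_prime_pos + aln$read_length <= tlen[aln$transcript_id]
  skipped <- c(unknown_transcript = sum(!known),
               length_filtered = sum(known & !in_len),
               multimapped = sum(known & in_len & !uniq_ok),
               out_of_bounds = sum(!in_bounds))
  aln <- aln[in_bounds, , drop = FALSE]
  pos <- pos[in_bounds]

  idx <- split(pos, aln$transcript_id)
  profiles <- lapply(seq_len(nrow(transcripts)), function(i) {
    id <- transcripts$transcript_id[i]
    p <- idx[[id]]
    counts <- if (is.null(p)) numeric(tlen[[id]]) else
      as.numeric(tabulate(p + 1L, nbins = tlen[[id]]))
    new_profile(id, counts, site_offset, as.integer(length_range))
  })
  names(profiles) <- transcripts$transcript_id
  structure(profiles, class = "profile_set", skipped = skipped,
            site_offset = site_offset)
}

#' Normalize a profile by its mean CDS density
#'
#' Divides every cell by `cds_mean`, the total CDS count divided by the CDS
#' length in nucleotides, so that the mean over CDS positions becomes 1.
#' Transcripts with zero CDS coverage are flagged `excluded` and left
#' undivided. Normalization is idempotent: renormalizing recomputes a CDS
#' mean of 1.
#'
#' @param profile a `positional_profile`.
#' @param transcript the matching transcript row.
#' @return the normalized profile (with `cds_mean` recorded).
#' @export
normalize_profile <- function(profile, transcript) {
  stopifnot(profile$transcript_id == transcript$transcript_id)
  cds <- (transcript$cds_start + 1L):transcript$cds_end
  m <- sum(profile$counts[cds]) / length(cds)
  if (m == 0) {
    profile$excluded <- TRUE
    profile$cds_mean <- 0
    return(profile)
  }
  profile$counts <- profile$counts / m
  profile$cds_mean <- m
  profile$normalized <- TRUE
  profile
}

#' Normalize every profile in a set
#'
#' @param profiles a `profile_set`.
#' @param transcripts the matching [transcript_set].
#' @return normalized `profile_set`.
#' @export
normalize_profiles <- function(profiles, transcripts) {
  out <- lapply(names(profiles), function(id) {
    normalize_profile(profiles[[id]],
                      transcripts[transcripts$transcript_id == id, ])
  })
  names(out) <- names(profiles)
  attributes(out) <- attributes(profiles)
  out
}

#' Shift a profile by a fixed offset
#'
#' Translates counts by `delta` nucleotides (positive = towards 3').
#' Cells shifted past either end are dropped and tallied in the
#' `n_dropped` attribute of the counts. Used e.g. to apply the 4-nt
#' adjustment that aligns 5P-seq 5' ends with Ribo-seq footprint 5' ends.
#'
#' @param profile a `positional_profile`.
#' @param delta signed shift in nt, `abs(delta)` < profile length.
#' @return shifted profile.
#' @export
shift_profile <- function(profile, delta) {
  delta <- as.integer(delta)
  n <- length(profile$counts)
  stopifnot(abs(delta) < n)
  out <- numeric(n)
  if (delta == 0L) {
    out <- profile$counts
    dropped <- 0
  } else if (delta > 0L) {
    out[(1L + delta):n] <- profile$counts[1L:(n - delta)]
    dropped <- sum(profile$counts[(n - delta + 1L):n])
  } else {
    out[1L:(n + delta)] <- profile$counts[(1L - delta):n]
    dropped <- sum(profile$counts[1L:(-delta)])
  }
  profile$counts <- out
  attr(profile$counts, "n_dropped") <- dropped
  profile
}

#' Write / read a profile set as a long TSV
#'
#' Columns `transcript_id`, `position` (0-based), `count`; zero cells are
#' omitted on write and restored on read.
#'
#' @param profiles a `profile_set`.
#' @param path file path.
#' @export
write_profiles_tsv <- function(profiles, path) {
  rows <- do.call(rbind, lapply(profiles, function(p) {
    nz <- which(p$counts != 0)
    if (length(nz) == 0L) return(NULL)
    data.frame(transcript_id = p$transcript_id, position = nz - 1L,
               count = p$counts[nz], stringsAsFactors = FALSE)
  }))
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_profiles_tsv
#' @param transcripts the [transcript_set] the profiles belong to.
#' @param site_offset,length_range metadata to record on the restored set.
#' @export
read_profiles_tsv <- function(path, transcripts, site_offset = 0L,
                              length_range = c(25L, 35L)) {
  long <- read.table(path, header = TRUE, sep = "\t",
                     stringsAsFactors = FALSE)
  tlen <- setNames(nchar(transcripts$sequence), transcripts$transcript_id)
  profiles <- lapply(transcripts$transcript_id, function(id) {
    counts <- numeric(tlen[[id]])
    rows <- long[long$transcript_id == id, , drop = FALSE]
    counts[rows$position + 1L] <- rows$count
    new_profile(id, counts, as.integer(site_offset),
                as.integer(length_range))
  })
  names(profiles) <- transcripts$transcript_id
  structure(profiles, class = "profile_set",
            site_offset = as.integer(site_offset))
}
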