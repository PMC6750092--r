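# Transcript sequences + CDS annotations: loading, longest-isoform
# selection, codon enumeration in the three frames, sticky-codon
# classification against the 18S rRNA tail, and frameshift-window location.

#' Construct a validated transcript set
#'
#' A transcript set is a `data.frame` with one row per transcript carrying
#' its sequence and CDS interval; it is the coordinate substrate for every
#' other module. Coordinates are 0-based and half-open: `cds_start` is the
#' first nucleotide of the start codon, `cds_end` one past the last
#' nucleotide of the stop codon.
#'
#' Validation enforces: CDS length divisible by 3 (violating transcripts are
#' dropped with a warning, never silently truncated), `cds_end` within the
#' sequence, and an A/C/G/T/N alphabet (U is converted to T on input).
#'
#' @param transcript_id,gene_id character vectors.
#' @param sequence character vector of nucleotide sequences (5'->3', U
#'   accepted).
#' @param cds_start,cds_end integer vectors, 0-based half-open CDS interval
#'   on the transcript.
#' @return a `data.frame` of class `transcript_set` with columns
#'   `transcript_id`, `gene_id`, `sequence`, `cds_start`, `cds_end`,
#'   `utr5_len`, `utr3_len`.
#' @export
transcript_set <- function(transcript_id, gene_id, sequence,
                           cds_start, cds_end) {
  sequence <- normalize_seq(sequence)
  check_alphabet(sequence)
  len <- nchar(sequence)
  cds_start <- as.integer(cds_start)
  cds_end <- as.integer(cds_end)
  ok <- !is.na(cds_start) & !is.na(cds_end) &
    cds_start >= 0L & cds_end <= len & cds_end > cds_start
  if (any(!ok)) {
    warning(sprintf("dropping %d transcript(s) with invalid CDS interval",
                    sum(!ok)))
  }
  inframe <- ok & ((cds_end - cds_start) %% 3L == 0L)
  if (any(ok & !inframe)) {
    warning(sprintf(
      "dropping %d transcript(s) whose CDS length is not divisible by 3: %s",
      sum(ok & !inframe),
      paste(head(transcript_id[ok & !inframe], 5L), collapse = ", ")))
  }
  keep <- inframe
  out <- data.frame(
    transcript_id = as.character(transcript_id)[keep],
    gene_id = as.character(gene_id)[keep],
    sequence = sequence[keep],
    cds_start = cds_start[keep],
    cds_end = cds_end[keep],
    utr5_len = cds_start[keep],
    utr3_len = (len - cds_end)[keep],
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(out$transcript_id)) {
    stop("duplicated transcript_id in transcript set")
  }
  rownames(out) <- out$transcript_id
  class(out) <- c("transcript_set", "data.frame")
  out
}

#' Read transcripts from FASTA plus a CDS annotation table
#'
#' Sequences are read with [Biostrings::readDNAStringSet()]. CDS intervals
#' come either from a TSV with columns
#' `transcript_id, gene_id, cds_start_1based, cds_end_1based` (1-based,
#' closed, converted at this boundary) or from a 6-column BED whose
#' `thickStart`/`thickEnd` carry the CDS (already 0-based half-open; the
#' BED `name` field is the transcript id and gene ids default to it).
#'
#' @param fasta path to a FASTA of transcript sequences.
#' @param cds path to the CDS annotation (TSV or BED, see above).
#' @param format `"tsv"` or `"bed"`.
#' @return a [transcript_set].
#' @export
read_transcripts <- function(fasta, cds, format = c("tsv", "bed")) {
  format <- match.arg(format)
  seqs <- Biostrings::readDNAStringSet(fasta)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  if (format == "tsv") {
    ann <- read.table(cds, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE)
    need <- c("transcript_id", "gene_id", "cds_start_1based", "cds_end_1based")
    if (!all(need %in% names(ann))) {
      stop("CDS TSV must have columns: ", paste(need, collapse = ", "))
    }
    ids <- ann$transcript_id
    gene <- ann$gene_id
    start0 <- ann$cds_start_1based - 1L   # 1-based closed -> 0-based half-open
    end0 <- ann$cds_end_1based
  } else {
    ann <- read.table(cds, header = FALSE, sep = "\t",
                      stringsAsFactors = FALSE)
    if (ncol(ann) < 8L) stop("BED input needs >= 8 columns (thickStart/End)")
    ids <- ann[[4L]]
    gene <- ids
    start0 <- as.integer(ann[[7L]])
    end0 <- as.integer(ann[[8L]])
  }
  missing <- setdiff(ids, names(seqs))
  if (length(missing) > 0L) {
    warning(sprintf("%d annotated transcript(s) missing from FASTA, dropped",
                    length(missing)))
    keep <- ids %in% names(seqs)
    ids <- ids[keep]; gene <- gene[keep]
    start0 <- start0[keep]; end0 <- end0[keep]
  }
  transcript_set(ids, gene, as.character(seqs[ids]), start0, end0)
}

#' Select the longest isoform per gene
#'
#' One transcript per gene is retained: the isoform with the largest CDS;
#' ties broken by longer 5' UTR, then longer 3' UTR, then lexicographically
#' smallest transcript id (fully deterministic).
#'
#' @param transcripts a [transcript_set].
#' @return a [transcript_set] with exactly one row per `gene_id`.
#' @export
select_longest_isoforms <- function(transcripts) {
  stopifnot(inherits(transcripts, "transcript_set"))
  cds_len <- transcripts$cds_end - transcripts$cds_start
  ord <- order(transcripts$gene_id,
               -cds_len,
               -transcripts$utr5_len,
               -transcripts$utr3_len,
               transcripts$transcript_id)
  sorted <- transcripts[ord, , drop = FALSE]
  keep <- !duplicated(sorted$gene_id)
  out <- sorted[keep, , drop = FALSE]
  rownames(out) <- out$transcript_id
  class(out) <- c("transcript_set", "data.frame")
  out
}

#' Enumerate codons of a transcript in one frame
#'
#' Tiles `[cds_start + frame, cds_end)` in steps of 3; a trailing partial
#' triplet is excluded. Frames are offsets from the annotated CDS start
#' (frame 0 = the coding frame). Triplets containing N are flagged
#' (`has_n`) and meant to be excluded from counting.
#'
#' @param transcript one row of a [transcript_set] (or any list with
#'   `transcript_id`, `sequence`, `cds_start`, `cds_end`).
#' @param frame 0, 1 or 2.
#' @return `data.frame` with columns `transcript_id`, `frame`,
#'   `codon_index` (1-based ordinal within the frame), `nt_position`
#'   (0-based transcript coordinate of the codon's first nucleotide),
#'   `triplet`, `has_n`.
#' @export
enumerate_codons <- function(transcript, frame = 0L) {
  stopifnot(frame %in% 0:2)
  starts <- triplet_starts(transcript$cds_start, transcript$cds_end, frame)
  trips <- triplets_at(transcript$sequence, starts)
  data.frame(
    transcript_id = rep(transcript$transcript_id, length(starts)),
    frame = rep(as.integer(frame), length(starts)),
    codon_index = seq_along(starts),
    nt_position = starts,
    triplet = trips,
    has_n = grepl("N", trips, fixed = TRUE),
    stringsAsFactors = FALSE
  )
}

#' Write per-transcript codon occurrences to TSV
#'
#' @param transcripts a [transcript_set].
#' @param path output file.
#' @param frames frames to enumerate (default all three).
#' @param rna report triplets with U instead of T.
#' @export
write_codon_occurrences <- function(transcripts, path, frames = 0:2,
                                    rna = FALSE) {
  rows <- do.call(rbind, unlist(lapply(seq_len(nrow(transcripts)), function(i) {
    lapply(frames, function(f) enumerate_codons(transcripts[i, ], f))
  }), recursive = FALSE))
  if (rna) rows$triplet <- as_rna(rows$triplet)
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(rows)
}

#' Define a sticky-codon model from an 18S rRNA tail triplet
#'
#' The 3'-proximal triplet of 18S rRNA (written 5'->3'; wild type CAU) is
#' proposed to base-pair antiparallel with mRNA codons at the exit site of
#' the mRNA channel. Its perfect pairing partner -- the "center" codon --
#' is the reverse complement of the tail (CAU -> AUG; GCC -> GGC). Codons
#' within `max_mismatch` Hamming distance of the center are classified
#' sticky.
#'
#' @param rrna_tail 3-letter tail triplet, 5'->3' (U accepted).
#' @param max_mismatch maximum Hamming distance for stickiness (default 1,
#'   i.e. AUG-like codons under the wild-type tail).
#' @return object of class `sticky_model` with elements `rrna_tail`,
#'   `center_codon`, `max_mismatch`.
#' @export
sticky_model <- function(rrna_tail = "CAU", max_mismatch = 1L) {
  tail <- normalize_seq(rrna_tail)
  stopifnot(nchar(tail) == 3L, !grepl("[^ACGT]", tail),
            is_count(max_mismatch), max_mismatch <= 3)
  structure(list(rrna_tail = tail,
                 center_codon = revcomp(tail),
                 max_mismatch = as.integer(max_mismatch)),
            class = "sticky_model")
}

#' @export
print.sticky_model <- function(x, ...) {
  cat(sprintf("sticky model: 18S tail 5'-%s-3' -> center codon %s (<= %d mismatch)\n",
              as_rna(x$rrna_tail), as_rna(x$center_codon), x$max_mismatch))
  invisible(x)
}

hamming3 <- function(a, b) {
  (substr(a, 1L, 1L) != substr(b, 1L, 1L)) +
    (substr(a, 2L, 2L) != substr(b, 2L, 2L)) +
    (substr(a, 3L, 3L) != substr(b, 3L, 3L))
}

#' Classify codons as sticky or non-sticky
#'
#' A triplet is sticky iff its Hamming distance to the model's center codon
#' is at most `max_mismatch`. AUG itself has distance 0 under the wild-type
#' (CAU-tail) model. Triplets containing N are never sticky and are flagged.
#'
#' @param triplet character vector of 3-letter codons (U accepted).
#' @param model a [sticky_model].
#' @return `data.frame` with columns `triplet` (normalized to DNA),
#'   `mismatch` (NA where N present), `sticky` (logical), `has_n`.
#' @export
classify_sticky <- function(triplet, model = sticky_model()) {
  trip <- normalize_seq(triplet)
  stopifnot(all(nchar(trip) == 3L))
  has_n <- grepl("N", trip, fixed = TRUE)
  mm <- ifelse(has_n, NA_integer_, hamming3(trip, model$center_codon))
  data.frame(triplet = trip,
             mismatch = mm,
             sticky = !has_n & !is.na(mm) & mm <= model$max_mismatch,
             has_n = has_n,
             stringsAsFactors = FALSE)
}

#' All sticky codons under a model
#'
#' Exhaustive enumeration over the 64 triplets; under the wild-type CAU
#' model this is AUG plus its nine single-mismatch neighbours (10 codons).
#'
#' @param model a [sticky_model].
#' @param include_stops keep stop triplets in the output (default FALSE).
#' @return character vector of sticky codons (DNA alphabet).
#' @export
sticky_codons <- function(model = sticky_model(), include_stops = FALSE) {
  b <- c("A", "C", "G", "T")
  all64 <- as.vector(outer(outer(b, b, paste0), b, paste0))
  cl <- classify_sticky(all64, model)
  out <- cl$triplet[cl$sticky]
  if (!include_stops) out <- setdiff(out, STOP_CODONS)
  sort(out)
}

#' Locate the frameshift window around an insertion site
#'
#' For a frameshift reporter, only shifts occurring inside a window
#' delimited by the nearest flanking stop codons can deliver the ribosome
#' to the downstream reporter frame: a ribosome that shifts upstream of the
#' last shifted-frame stop terminates before reaching the reporter, and one
#' that has not shifted by the first source-frame stop downstream of the
#' insertion terminates there.
#'
#' `seq` is the post-insertion (reporter) sequence anchored so that the
#' start codon begins at position 0 and frame 0 is the pre-shift reading
#' frame along the whole span. For `shift = +1` the shifted frame is
#' frame 1 of `seq`; for `shift = -1` it is frame 2 (a 2-nt insertion).
#' The window start is the first frame-0 codon boundary after the nearest
#' shifted-frame stop upstream of `ins_pos` (falling back to the start
#' codon, flagged); the end is the first nucleotide of the nearest frame-0
#' stop at or downstream of `ins_pos` (falling back to the span end,
#' flagged).
#'
#' @param seq nucleotide string (coding span, frame 0 from position 0).
#' @param ins_pos 0-based coordinate of the insertion within the span.
#' @param shift `+1` or `-1`.
#' @return list with `start`, `end` (0-based half-open nt interval),
#'   `length_codons` = `floor((end - start)/3)`, and logical flags
#'   `upstream_fallback`, `downstream_fallback`.
#' @export
find_fs_window <- function(seq, ins_pos, shift = c(1L, -1L)) {
  seq <- normalize_seq(seq)
  shift <- as.integer(shift[1L])
  stopifnot(shift %in% c(1L, -1L))
  n <- nchar(seq)
  if (ins_pos < 0L || ins_pos >= n) stop("ins_pos outside the coding span")
  shifted_frame <- if (shift == 1L) 1L else 2L

  stop_starts <- function(frame) {
    s <- triplet_starts(0L, n, frame)
    s[triplets_at(seq, s) %in% STOP_CODONS]
  }
  up_stops <- stop_starts(shifted_frame)
  up_stops <- up_stops[up_stops + 3L <= ins_pos]    # fully upstream of the site
  upstream_fallback <- length(up_stops) == 0L
  start <- if (upstream_fallback) 0L else {
    after <- max(up_stops) + 3L
    # first frame-0 codon boundary at or after the shifted-frame stop's end
    as.integer(3L * ceiling(after / 3))
  }
  down_stops <- stop_starts(0L)
  down_stops <- down_stops[down_stops >= ins_pos]
  downstream_fallback <- length(down_stops) == 0L
  end <- if (downstream_fallback) n else min(down_stops)

  list(start = start, end = as.integer(end),
       length_codons = as.integer((end - start) %/% 3L),
       upstream_fallback = upstream_fallback,
       downstream_fallback = downstream_fallback)
}

#' Convert a reporter frameshift rate to a per-codon rate
#'
#' Divides the rate observed for a whole reporter by the length (in codons)
#' of its frameshift window, e.g. a 0.52% reporter rate over a 13-codon
#' window gives 0.04% per codon.
#'
#' @param reporter_rate frameshift rate of the reporter (fraction or percent;
#'   returned on the same scale).
#' @param window_codons window length in codons (>= 1).
#' @return per-codon rate, `reporter_rate / window_codons`.
#' @export
per_codon_rate <- function(reporter_rate, window_codons) {
  if (!is_count(window_codons) || window_codons < 1) {
    stop("window_codons must be a positive integer")
  }
  reporter_rate / window_codons
}
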