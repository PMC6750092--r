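# In-code fixtures shared across the suite.

# One-transcript set from a raw sequence (whole sequence = CDS by default).
toy_transcript <- function(seq, cds_start = 0L, cds_end = nchar(seq),
                           id = "tx1", gene = "g1") {
  suppressWarnings(transcript_set(id, gene, seq, cds_start, cds_end))
}

# Profile with prescribed counts for a transcript (raw by default).
toy_profile <- function(transcript, counts, site_offset = 0L) {
  stopifnot(length(counts) == nchar(transcript$sequence))
  p <- structure(list(transcript_id = transcript$transcript_id,
                      counts = as.numeric(counts),
                      site_offset = as.integer(site_offset),
                      length_range = c(25L, 35L),
                      normalized = FALSE, cds_mean = NA_real_,
                      excluded = FALSE),
                 class = "positional_profile")
  p
}

profile_set_of <- function(...) {
  ps <- list(...)
  names(ps) <- vapply(ps, `[[`, "", "transcript_id")
  structure(ps, class = "profile_set", site_offset = ps[[1]]$site_offset)
}

# Random sense-codon CDS (ATG ... stop), length in codons.
random_cds <- function(n_codons, stop_codon = "TAA") {
  paste(c("ATG", sample(SENSE_CODONS, n_codons - 2L, replace = TRUE),
          stop_codon), collapse = "")
}

# Random alignments fully inside a transcript, all unique, length 28.
random_alignments <- function(transcript, n, read_length = 28L) {
  maxpos <- nchar(transcript$sequence) - read_length
  data.frame(transcript_id = transcript$transcript_id,
             five_prime_pos = sample.int(maxpos + 1L, n, TRUE) - 1L,
             read_length = read_length,
             unique = TRUE, stringsAsFactors = FALSE)
}
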