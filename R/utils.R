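# Shared codon-level helpers. Coordinates are 0-based, half-open,
# transcript-relative throughout; the +1 shift to R's 1-based string/vector
# indexing happens only inside these helpers.

#' Stop codons of the standard genetic code
#' @export
STOP_CODONS <- c("TAA", "TAG", "TGA")

#' The 61 sense codons of the standard genetic code
#'
#' All 64 triplets minus [STOP_CODONS], in lexicographic order. Every
#' per-codon table in the package has exactly these rows.
#' @export
SENSE_CODONS <- {
  b <- c("A", "C", "G", "T")
  all64 <- as.vector(outer(outer(b, b, paste0), b, paste0))
  sort(setdiff(all64, c("TAA", "TAG", "TGA")))
}

# U -> T normalization; internal alphabet is DNA.
normalize_seq <- function(x) {
  x <- toupper(x)
  chartr("U", "T", x)
}

# Render internal DNA triplets with U for user-facing output.
as_rna <- function(x) chartr("T", "U", x)

check_alphabet <- function(x, what = "sequence") {
  bad <- grepl("[^ACGTN]", x)
  if (any(bad)) {
    stop(sprintf("%s contains characters outside A/C/G/T/N (after U->T): %s",
                 what, paste(head(which(bad)), collapse = ", ")))
  }
  invisible(x)
}

#' Reverse complement of a DNA string
#'
#' Thin wrapper over [Biostrings::reverseComplement()] operating on plain
#' character vectors (U accepted on input, DNA returned).
#'
#' @param x character vector of nucleotide strings.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  x <- normalize_seq(x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# 0-based start positions of complete triplets tiling [from, to) in steps
# of 3 (trailing partial triplet excluded).
triplet_starts <- function(from, to, frame = 0L) {
  s <- from + frame
  n <- (to - s) %/% 3L
  if (is.na(n) || n <= 0L) return(integer(0))
  seq.int(s, by = 3L, length.out = n)
}

# Extract triplets at 0-based starts from a single sequence string.
triplets_at <- function(seq, starts) {
  if (length(starts) == 0L) return(character(0))
  substring(seq, starts + 1L, starts + 3L)
}

# Translate a vector of DNA codons to one-letter amino acids ("*" = stop).
translate_codons <- function(codons) {
  unname(Biostrings::GENETIC_CODE[codons])
}

is_count <- function(x) length(x) == 1L && is.numeric(x) && !is.na(x) &&
  x >= 0 && x == floor(x)
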