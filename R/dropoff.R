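# Ribosome drop-off through spontaneous frameshifting: the remaining-
# ribosome recursion with stop-codon absorption in the shifted frames, a
# Monte-Carlo per-ribosome simulator sharing the same movement geometry,
# predicted occupancy curves, and the half-CDS density-ratio screen.
#
# Movement geometry per codon step: staying in frame is a 3-nt step; a -1
# frameshift is a 2-nt step; a +1 frameshift is a 4-nt step. Hence frame 0
# of codon i receives +1-shifted ribosomes from frame 2 of codon i-2, and
# frame 2 of codon i receives -1-shifted ribosomes from frame 0 of the
# same codon i. The recursion is implemented exactly in this form; the
# index asymmetry is the geometry, not an error.

#' Frameshift probability parameters
#'
#' Per-codon probabilities of staying in frame (`p0`), shifting +1
#' (`p_plus1`) and shifting -1 (`p_minus1`); they must sum to 1.
#'
#' @param p0,p_plus1,p_minus1 probabilities in `[0, 1]`.
#' @return object of class `frameshift_params`.
#' @export
frameshift_params <- function(p0, p_plus1, p_minus1) {
  v <- c(p0, p_plus1, p_minus1)
  stopifnot(length(v) == 3L, all(is.finite(v)), all(v >= 0), all(v <= 1))
  if (abs(sum(v) - 1) > 1e-8) {
    stop("p0 + p_plus1 + p_minus1 must equal 1")
  }
  structure(list(p0 = p0, p_plus1 = p_plus1, p_minus1 = p_minus1),
            class = "frameshift_params")
}

#' Named frameshift-rate presets
#'
#' Two reported parameterizations of the spontaneous per-codon frameshift
#' rates measured by dual-luciferase reporter assays disagree; both ship
#' and callers must choose explicitly:
#' * `"minus1-dominant"`: p-1 = 0.1%, p+1 = 0.02% (p0 = 99.88%);
#' * `"plus1-dominant"`: p+1 = 0.03%, p-1 = 0.02% (p0 = 99.95%).
#'
#' @param name preset name.
#' @return a [frameshift_params].
#' @export
fs_preset <- function(name = c("minus1-dominant", "plus1-dominant")) {
  switch(match.arg(name),
         "minus1-dominant" = frameshift_params(0.9988, 0.0002, 0.0010),
         "plus1-dominant" = frameshift_params(0.9995, 0.0003, 0.0002))
}

# Stop masks for the shifted frames: stop_mask[i, f+1] is TRUE when the
# complete triplet read in frame f at codon i of the CDS is a stop.
# Trailing partial triplets are non-stops; triplets containing N are
# treated as non-stop with a warning.
shifted_stop_mask <- function(seq_cds) {
  n <- nchar(seq_cds)
  L <- n %/% 3L
  if (grepl("N", seq_cds, fixed = TRUE)) {
    warning("sequence contains N; N-containing triplets treated as non-stop")
  }
  mask <- matrix(FALSE, nrow = L, ncol = 3L)
  for (f in 1:2) {
    starts <- triplet_starts(0L, n, f)            # 0-based within the CDS
    codon_i <- (starts - f) %/% 3L + 1L
    mask[codon_i[triplets_at(seq_cds, starts) %in% STOP_CODONS], f + 1L] <- TRUE
  }
  mask
}

#' Remaining-ribosome recursion along a CDS
#'
#' Starting with 100% of ribosomes at the start codon in frame 0, computes
#' the fraction `R(i, f)` of ribosomes present at codon `i` in frame `f`,
#' where frameshifted ribosomes translocate with 2-nt (-1 shift) or 4-nt
#' (+1 shift) steps and are absorbed at the first stop codon of their new
#' frame:
#' \deqn{R(i,0) = p_0 R(i-1,0) + p_{-1} R(i-1,1) + p_{+1} R(i-2,2)}
#' \deqn{R(i,1) = p_0 R(i-1,1) + p_{+1} R(i-1,0) + p_{-1} R(i-1,2)}
#' \deqn{R(i,2) = p_0 R(i-1,2) + p_{-1} R(i,0) + p_{+1} R(i-1,1)}
#' with `R(1,0) = 1`, `R(1,1) = R(1,2) = 0`, `R(2,0) = p0 R(1,0)`, and
#' `R(i,1)`/`R(i,2)` zeroed wherever the frame-1/frame-2 triplet at codon
#' `i` is a stop. Frame-0 stops do not absorb: the walk ends normally at
#' the annotated stop.
#'
#' @param seq_cds CDS nucleotide string (length divisible by 3, frame 0
#'   from its first base; U accepted).
#' @param params a [frameshift_params].
#' @return list with `R` (L x 3 matrix), `stop_mask` (L x 3 logical), and
#'   `L` (CDS length in codons).
#' @export
remaining_ribosomes <- function(seq_cds, params) {
  seq_cds <- normalize_seq(seq_cds)
  n <- nchar(seq_cds)
  if (n %% 3L != 0L) stop("CDS length must be divisible by 3")
  L <- n %/% 3L
  stopifnot(inherits(params, "frameshift_params"), L >= 1L)
  mask <- shifted_stop_mask(seq_cds)
  p0 <- params$p0; pp <- params$p_plus1; pm <- params$p_minus1

  R <- matrix(0, nrow = L, ncol = 3L)
  R[1L, 1L] <- 1
  for (i in seq_len(L)[-1L]) {
    R[i, 1L] <- if (i == 2L) p0 * R[1L, 1L] else
      p0 * R[i - 1L, 1L] + pm * R[i - 1L, 2L] + pp * R[i - 2L, 3L]
    R[i, 2L] <- if (mask[i, 2L]) 0 else
      p0 * R[i - 1L, 2L] + pp * R[i - 1L, 1L] + pm * R[i - 1L, 3L]
    R[i, 3L] <- if (mask[i, 3L]) 0 else
      p0 * R[i - 1L, 3L] + pm * R[i, 1L] + pp * R[i - 1L, 2L]
  }
  colnames(R) <- c("R0", "R1", "R2")
  list(R = R, stop_mask = mask, L = L)
}

#' Monte-Carlo simulation of per-ribosome frameshift walks
#'
#' Independent ribosomes start at codon 1 in frame 0 and step codon by
#' codon, shifting with probabilities `p_plus1` / `p_minus1` under the
#' same movement geometry as [remaining_ribosomes()] (+1 = 4-nt step into
#' frame 1 of the next codon from frame 0, etc.). A ribosome entering a
#' stop codon of frame 1 or 2 is absorbed there; a -1 shift at the start
#' codon leaves the tracked region (the recursion's `R(1,2) = 0` boundary)
#' and is likewise dropped. The empirical occupancy is the fraction of
#' ribosomes that ever visit each (codon, frame) state, with binomial
#' standard errors.
#'
#' @param seq_cds CDS nucleotide string.
#' @param params a [frameshift_params].
#' @param n_ribosomes number of simulated ribosomes (>= 1).
#' @param seed RNG seed (mandatory, for exact reproducibility).
#' @return list with `R` (empirical L x 3 occupancy), `se` (binomial
#'   standard errors), `n_ribosomes`, and `derail` = 1 - total occupancy
#'   at the final codon.
#' @export
simulate_fs <- function(seq_cds, params, n_ribosomes = 1e5, seed) {
  if (missing(seed)) stop("seed is mandatory")
  seq_cds <- normalize_seq(seq_cds)
  n <- nchar(seq_cds)
  if (n %% 3L != 0L) stop("CDS length must be divisible by 3")
  L <- n %/% 3L
  stopifnot(is_count(n_ribosomes), n_ribosomes >= 1)
  mask <- shifted_stop_mask(seq_cds)
  set.seed(as.integer(seed))

  visits <- matrix(0, nrow = L, ncol = 3L)
  ci <- rep(1L, n_ribosomes)   # current codon
  cf <- rep(0L, n_ribosomes)   # current frame
  visits[1L, 1L] <- n_ribosomes
  p0 <- params$p0; pp <- params$p_plus1; pm <- params$p_minus1

  while (length(ci) > 0L) {
    u <- runif(length(ci))
    shift_plus <- u < pp
    shift_minus <- u >= pp & u < pp + pm
    ni <- ci; nf <- cf
    # stay in frame: one codon forward, frame unchanged
    stay <- !shift_plus & !shift_minus
    ni[stay] <- ci[stay] + 1L
    # +1 shift: 4-nt step
    s <- shift_plus
    ni[s] <- ci[s] + ifelse(cf[s] == 2L, 2L, 1L)
    nf[s] <- ifelse(cf[s] == 2L, 0L, cf[s] + 1L)
    # -1 shift: 2-nt step
    s <- shift_minus
    ni[s] <- ci[s] + ifelse(cf[s] == 0L, 0L, 1L)
    nf[s] <- ifelse(cf[s] == 0L, 2L, cf[s] - 1L)

    # drop: walked past the last codon, -1 shift at the start codon
    alive <- ni <= L & !(ni == 1L & nf > 0L)
    ni <- ni[alive]; nf <- nf[alive]
    # absorb unrecorded at shifted-frame stops
    absorbed <- nf > 0L & mask[cbind(ni, nf + 1L)]
    ni <- ni[!absorbed]; nf <- nf[!absorbed]
    if (length(ni) > 0L) {
      visits <- visits + tabulate((nf * L) + ni, nbins = 3L * L)
    }
    ci <- ni; cf <- nf
  }
  R <- visits / n_ribosomes
  colnames(R) <- c("R0", "R1", "R2")
  se <- sqrt(R * (1 - R) / n_ribosomes)
  list(R = R, se = se, n_ribosomes = n_ribosomes,
       derail = 1 - sum(R[L, ]))
}

#' Predicted ribosome occupancy along a CDS
#'
#' Per-codon total remaining fraction `R(i,0) + R(i,1) + R(i,2)` from
#' [remaining_ribosomes()]; the derail fraction at codon `i` is one minus
#' this total.
#'
#' @param x a transcript row (CDS extracted from its annotation) or a CDS
#'   nucleotide string.
#' @param params a [frameshift_params].
#' @return `data.frame` with columns `i`, `R0`, `R1`, `R2`, `total`,
#'   `derail`.
#' @export
predicted_occupancy <- function(x, params) {
  seq_cds <- if (is.character(x)) x else
    substring(x$sequence, x$cds_start + 1L, x$cds_end)
  rr <- remaining_ribosomes(seq_cds, params)
  tot <- rowSums(rr$R)
  data.frame(i = seq_len(rr$L), R0 = rr$R[, 1L], R1 = rr$R[, 2L],
             R2 = rr$R[, 3L], total = tot, derail = 1 - tot)
}

#' Half-CDS footprint density ratio
#'
#' Mean raw density over the first half of the CDS divided by the mean
#' over the second half, the screen used to flag large ribosome drop-off
#' (e.g. programmed frameshifting). The CDS is split at the codon level,
#' odd codon counts assigning the middle codon to the first half. A
#' transcript qualifies when at least one half carries `min_reads` reads.
#'
#' @param profile_raw raw-count `positional_profile`.
#' @param transcript the matching transcript row.
#' @param min_reads qualification threshold (default 50).
#' @return list with `ratio` (NA when unqualified, `Inf` when the second
#'   half is empty), `n_first`, `n_second`, `qualified`.
#' @export
half_cds_ratio <- function(profile_raw, transcript, min_reads = 50) {
  L <- (transcript$cds_end - transcript$cds_start) %/% 3L
  k1 <- ceiling(L / 2)
  cut <- transcript$cds_start + 3L * k1      # first nt after the first half
  first <- (transcript$cds_start + 1L):cut
  second <- if (cut < transcript$cds_end) (cut + 1L):transcript$cds_end
            else integer(0)
  n1 <- sum(profile_raw$counts[first])
  n2 <- sum(profile_raw$counts[second])
  qualified <- n1 >= min_reads || n2 >= min_reads
  d1 <- n1 / length(first)
  d2 <- if (length(second) > 0L) n2 / length(second) else NA_real_
  ratio <- if (!qualified) NA_real_
           else if (is.na(d2) || d2 == 0) Inf
           else d1 / d2
  list(ratio = ratio, n_first = n1, n_second = n2, qualified = qualified)
}

#' Half-CDS ratio table over a cohort
#'
#' @param profiles_raw raw `profile_set`.
#' @param transcripts a [transcript_set].
#' @param min_reads see [half_cds_ratio()].
#' @return `data.frame` with `transcript_id`, `ratio`, `n_first`,
#'   `n_second`, `qualified`.
#' @export
half_cds_ratio_table <- function(profiles_raw, transcripts, min_reads = 50) {
  rows <- lapply(seq_len(nrow(transcripts)), function(i) {
    tr <- transcripts[i, ]
    h <- half_cds_ratio(profiles_raw[[tr$transcript_id]], tr, min_reads)
    data.frame(transcript_id = tr$transcript_id, ratio = h$ratio,
               n_first = h$n_first, n_second = h$n_second,
               qualified = h$qualified, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
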