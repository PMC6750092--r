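---
title: "Reading-frame fidelity statistics for ribosome profiling: models and methods"
author: "riboframe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reading-frame fidelity statistics for ribosome profiling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(riboframe)
```

## The problem

A translating ribosome must hold one reading frame over hundreds of codons;
a single uncorrected ±1 nt slip usually runs the ribosome into a premature
stop in the shifted frame and destroys the protein. Ribosome profiling
(Ribo-seq) footprints carry frame information at sub-codon resolution: the
5′ ends of 25–35 nt ribosome-protected fragments phase with the coding
frame, with roughly 70% of ends falling in frame 0 in good libraries.
`riboframe` turns that phasing into codon-level fidelity statistics, models
the cumulative consequence of per-codon frameshift rates, classifies
"sticky" AUG-like codons that can base-pair with the 3′ tail of 18S rRNA at
the mRNA exit site, and tests whether genomes deplete such codons from
frame 2 — all validated against a synthetic footprint generator with known
ground truth.

## Coordinates and data model

Everything is transcript-space: a `transcript_set` row holds the spliced
sequence and a 0-based, half-open CDS interval beginning at the start
codon. Annotation readers convert 1-based inputs at the boundary; U is
converted to T on input and can be restored on output. CDS lengths not
divisible by 3 are rejected at load time with a warning — silent truncation
would corrupt every downstream frame assignment. Frames 0/1/2 are offsets
from `cds_start`, and frame-1/2 codon enumerations tile from
`cds_start + 1`/`+ 2` within the CDS only, dropping trailing partial
triplets, so the three frame-wise codon lists have lengths `L, L-1, L-1`.

A `positional_profile` is a per-nucleotide count vector for one transcript,
anchored at a configurable in-read site: offset 0 profiles the footprint
5′-end codon, offset 12 the P-site, offset 15 the A-site (P-site plus one
codon; the A-site offset is a convention exposed as a knob, not a fitted
quantity — offset calibration from periodicity is deliberately out of
scope). Multimapped reads are excluded by default; gapped alignments are
rejected outright because a footprint is ungapped in transcript space; the
aligned 5′ terminus (soft clips excluded) defines the read position. For
5′-monophosphate (5P-seq) style data whose virtual 5′ ends sit 4 nt away
from Ribo-seq ends, `shift_profile()` applies the fixed adjustment.

## The two codon statistics

For each frame-0 occurrence *m* of a codon in a gene, let
\(F_{m0}, F_{m1}, F_{m2}\) be profile counts at the codon's first
nucleotide and the next two positions. The per-gene in-frame rate is

\[
\mathrm{IFR}_{x,i} \;=\; \frac{\sum_m F_{m0}}{\sum_m (F_{m0}+F_{m1}+F_{m2})},
\]

with genes contributing fewer than 10 reads across the codon's positions
disregarded (never reported as zero — an absent codon and an
under-covered codon are distinct conditions, both flagged). The global IFR
of a codon is the unweighted mean over qualifying genes; a read-weighted
variant exists behind a flag but is off by default, matching the
equal-gene-weight convention. The threshold applies per (gene, codon) pair
at the profiled site, not per occurrence.

The average codon coverage (ACC) score divides each profile by its mean
CDS density (reads per nucleotide), then averages the normalized value at
the codon's first nucleotide over its occurrences:
\(\mathrm{ACC}_{x,i} = \sum_m N_m / K\). A uniform profile scores exactly 1
for every codon present, making 1.0 the natural reference for "pausing".
The coupling between abundance and fidelity across the 61 sense codons is
summarized by Spearman rank correlation (average ranks on ties), computed
by `stats::cor`.

"Reads of a codon in frames 0/1/2" is interpreted as counts at the codon's
first nucleotide and the two following positions of the chosen site
profile; this is the only reading under which the per-codon statistic and
the metagene frame series use the same bookkeeping, and nothing finer is
defined by the data.

## Metagene aggregation and pause calls

`metagene_profile()` aligns CDS-normalized profiles at a selected codon
occurrence — the annotated start, the *n*-th or first internal occurrence,
or the last — and averages position-wise over transcripts in a 90 nt
window, by default \([-30, +60)\) around the anchor's first nucleotide.
Anchors closer than 30 nt to the transcript 5′ end or 60 nt to the 3′ end
are skipped. Window positions are labelled by CDS frame (not by distance to
the anchor); since anchors sit at frame-0 codon starts the frame of
relative position \(r\) is \(r \bmod 3\). Transcripts are equally weighted:
normalization has already removed depth differences, so a read-weighted
aggregate would just reintroduce them.

A transcript "pauses" at an anchor when its normalized density 12 nt
downstream exceeds 1.0 — the CDS mean — strictly; a value of exactly 1.0 is
non-pausing. The threshold is the definition of the classification, not a
fitted cutoff, and no significance test is attached by design. The +12 nt
position is where a codon sits when it reaches the mRNA exit site of a
ribosome whose P-site is mapped 12 nt from the footprint 5′ end, which is
why sticky-codon pausing appears there.

Regional frame ratios (`region_frame_ratio()`) pool raw site-anchored
counts over intervals relative to the anchor, by default
\([-30, -1]\) and \([+1, +60]\), excluding the anchor's own first
nucleotide; region boundaries are configurable because published regional
comparisons mark regions only graphically.

## Sticky codons

The 18S rRNA 3′-proximal triplet (wild type CAU, written 5′→3′) pairs
antiparallel with mRNA; its perfect partner is the reverse complement
(CAU → AUG, GCC → GGC), computed with `Biostrings::reverseComplement`. A
codon is sticky when its Hamming distance to that center codon is at most
1, giving exactly 10 sticky codons under the wild-type model (AUG plus nine
single-mismatch neighbours). Triplets containing N are never sticky and are
flagged. The mutant-tail model (GCC) is just another parameterization, so
the same classifier covers tail-swap experiments.

## The drop-off model

With per-codon probabilities \(p_0, p_{+1}, p_{-1}\) of staying in frame or
shifting, the fraction of ribosomes remaining at codon *i* in frame *f*
follows a recursion with stop-codon absorption in the shifted frames.
Frameshifted ribosomes translocate with a 2 nt (−1) or 4 nt (+1) step, so
frame 0 of codon *i* receives +1-shifted ribosomes from frame 2 of codon
*i−2*, and frame 2 of codon *i* receives −1-shifted ribosomes from frame 0
of the *same* codon. That index asymmetry is the movement geometry and is
implemented exactly as printed — no "correction" is applied. Frame-1/2
stop codons zero their cell (the ribosome terminates); frame-0 stops do
not absorb, the walk simply ends at the annotated stop. The derail
fraction at codon *i* is \(1 - \sum_f R(i,f)\).

Reported parameterizations of these measured rates disagree —
\(p_{-1} = 0.1\%\) with \(p_{+1} = 0.02\%\) in one account, versus
\(p_{+1} = 0.03\%\) with \(p_{-1} = 0.02\%\) in another — so both ship as
named presets (`"minus1-dominant"`, `"plus1-dominant"`) and callers must
choose explicitly. On a 312-codon ORF (the scale of Renilla luciferase;
the bundled `rluc_synthetic.fa` is a synthetic stand-in of that length,
since the reporter plasmid sequence is not distributed) the presets
predict 29.0% and 12.8% derailment at the stop codon, bracketing the
~20% loss such rates are usually quoted to imply.

`simulate_fs()` is an independent Monte-Carlo oracle: per-ribosome walks
under the same movement geometry, vectorized across ribosomes, with
binomial standard errors. Two boundary conventions make oracle and
recursion agree cell-for-cell: a −1 shift at the start codon leaves the
tracked region (the recursion's \(R(1,2)=0\)), and ribosomes entering a
shifted-frame stop are absorbed without being recorded. Note one subtlety
verified by the oracle: the total \(\sum_f R(i,f)\) is *not* strictly
non-increasing — the same-codon \(p_{-1}R(i,0)\) inflow can repopulate
frame 2 immediately after a stop zeroed it, so the total can tick up by at
most \(p_{+1}+p_{-1}\) at such codons while decaying overall.

When comparing the recursion against the simulator, each (codon, frame)
cell is exactly Binomial(\(N\), \(R\)), so with thousands of cells the
maximum standardized deviation of a *correct* simulator concentrates
around \(\sqrt{2\ln K}\approx 3.5\)–4; equivalence tests therefore use a
Bonferroni-level maximum bound together with mean \(|z|\) (≈ 0.8 for a
standard normal) and ~99.7% coverage at 3 SE, rather than demanding every
cell fall inside 3 SE, which no correct implementation can satisfy.

The half-CDS screen (`half_cds_ratio()`) divides mean raw density over the
first half of the CDS by the second half, splitting at the codon level
with the middle codon assigned to the first half; transcripts qualify with
at least 50 reads in either half, and an empty second half is reported as
an infinite ratio rather than an error, since that is precisely the
drop-off signal the screen looks for.

## Composition nulls

`frame_codon_fractions()` counts each sense codon in the three frames of
each CDS and reports, per codon, the fraction of its occurrences in each
frame — per-gene fractions first, then an unweighted gene average (a
pooled-count variant is available; the gene-averaged form is the default
because the per-gene formulation is the stated convention). Frames 1/2 may
read stop triplets; those are simply not reported, but they do not enter
any sense codon's denominator, so each reported codon's three fractions
sum to 1 wherever the codon occurs.

`shuffle_cds()` provides three nulls: `synonymous_codon` permutes codon
occurrences within synonymous families, preserving the protein sequence,
codon multiset, GC content and all frame-0 codon fractions exactly;
`dinucleotide` permutes the leading dinucleotides of codons with third
positions fixed; `codon_free` permutes whole codons without constraint.
The synonymous form is the default codon-mode because the amino acid
sequence is explicitly to be maintained; the unconstrained form exists for
sensitivity analysis where the looser phrasing of a whole-codon shuffle is
wanted. The terminal stop codon never moves in any mode — relocating a
stop into the interior would truncate the frame-0 reading and change the
question being asked.

`randomization_test()` compares the observed gene-averaged fraction of a
codon in a frame against 100 shuffled CDS sets (configurable), reporting
\(z = (\mathrm{obs}-\mu_0)/\sigma_0\) and a one-sided empirical p-value
for depletion with the standard \((1+k)/(n+1)\) correction. All randomness
flows from a single mandatory seed, so null distributions are bit-identical
across runs.

## The synthetic generator

`generate_transcriptome()` samples CDSs codon-by-codon from frame-0 usage
weights (uniform by default), always starting ATG and ending with a single
terminal stop; internal frame-0 stops cannot occur because sampling is
restricted to sense codons. UTRs (default 40 nt each) are uniform-random.
The `frame2_atg_keep` knob rejection-samples codons whose junction with
their predecessor spells ATG in frame 2 (a frame-2 triplet straddles two
adjacent frame-0 codons, so frame-2 content is only controllable through
junctions); the achieved, not target, composition is recorded as truth.
Each transcript derives its own RNG substream from the master seed, so
generation is order-independent.

`simulate_reads()` places read 5′ ends at sense-codon starts with
probability proportional to the codon's dwell multiplier, then jitters
them +1/+2 nt with probabilities \((q_1, q_2)\) — out-of-frame footprints
model nuclease over-/under-digestion at the read boundary, so sequences
are never mutated. Defaults: frame probabilities \((0.7, 0.15, 0.15)\),
matching the ~70% frame-0 phasing of good mammalian libraries; read
lengths 25–35 nt peaked at 28. Dwell multipliers default to sticky codons
at ~3× with a deterministic within-group spread (sticky 2.7–3.3,
non-sticky 0.85–1.15): real per-codon dwell varies continuously, and an
all-ties two-level program would make rank-recovery of the multipliers
mathematically ill-posed (with 10 of 61 codons tied at one value the
maximum achievable Spearman correlation is about 0.64). Optional knobs:
per-codon frame-0 probabilities (`codon_q0`) to couple fidelity to dwell;
a post-sticky fidelity boost downstream of the first internal AUG;
ligation bias applied by rejection to the anchored codon's first
nucleotide — uniformly across the three frame offsets of that codon, so
read composition skews while per-codon IFR does not, reproducing the
observed dissociation between 5′-end sequence bias and frame fidelity;
and `fs_params`, which draws anchors and ribosome frames from the
analytic occupancy so drop-off detection can be tested end-to-end.

`ground_truth_summary()` returns the closed-form expectations: IFR equals
the programmed \(q_0\) per codon; ACC equals \(3\,q_0 w_c/\bar w\) (the
factor 3 because a codon's anchor mass concentrates on one of its three
nucleotides while normalization spreads the CDS mean over all positions);
the metagene peak sits at +12 for P-site profiles; binomial tolerance
bands follow from the per-class expected depth.

### What the generator does and does not emulate

It reproduces the features the statistics consume: 3-nt periodicity,
codon-identity-dependent 5′-end dwell, +12 pausing, ligation bias,
frame-2 junction depletion, and frameshift-driven density decay. It does
not model UMI duplication, rRNA contamination, mRNA secondary structure,
ribosome collisions or re-initiation, codon-usage covariation with
expression, or real library chemistry beyond the single bias knob. Passing
recovery tests therefore demonstrates estimator correctness under the
stated sampling model, not robustness to every artifact of real libraries.

## Problem sizes and numerical choices

Recovery suites run on cohorts of 40–60 transcripts of 100–200 codons at
3,000–11,000 reads per transcript (≥ 10⁴ anchored reads per codon class
for IFR/ACC recovery, giving ~0.004 binomial SE against a 0.02 tolerance);
the Monte-Carlo oracle uses 10⁵ ribosomes on 100-codon sequences with
frameshift rates of 0.2–0.5% per codon so that every reachable cell
carries ≥ ~200 expected visits and normal-approximation error bars are
trustworthy. Ties in Spearman correlations use average ranks; IFR of an
uncovered (gene, codon) is `NA` with a reason attribute, never 0;
normalization of a zero-coverage CDS flags the profile excluded rather
than dividing by zero; and all empirical p-values use the add-one
correction so they are never exactly 0.

## Known limitations

The P-/A-site offsets are fixed conventions, not calibrated per library.
The 3′-end codon grouping of footprints is only approximable from 5′ data
(offset `read_length − 3` per read) and is omitted from default outputs.
The frameshift-window locator assumes the standard stop set and falls back
to the start codon/span end (flagged) when no flanking stop exists, a
convention for insertions near the start codon that published reporters do
not constrain. Genome-to-transcriptome projection is out of scope: inputs
are already transcript-space alignments.
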