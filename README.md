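# riboframe

Codon-level analysis of translational reading-frame fidelity from ribosome
profiling data.

A translating ribosome must keep one reading frame for hundreds of codons;
spontaneous ±1 frameshifts usually run it into a premature stop in the
shifted frame. Ribo-seq footprints phase with the coding frame at their 5′
ends, which makes frame maintenance measurable codon by codon. `riboframe`
is for computational biologists who want to quantify that phasing and its
sequence determinants — in particular the AUG-like "sticky" codons that can
base-pair with the 3′-terminal triplet of 18S rRNA at the mRNA exit site,
pausing the ribosome and gripping the message in frame.

## What it computes

For footprints profiled at a chosen in-read site (5′-end codon, P-site at
+12 nt, A-site at +15 nt):

* **In-frame rate (IFR)** per codon *x* and gene *i*, over that codon's
  frame-0 occurrences *m*:

      IFR(x, i) = Σ_m F_m0 / Σ_m (F_m0 + F_m1 + F_m2)

  with genes under 10 reads for the codon disregarded, then an unweighted
  average over qualifying genes.

* **Average codon coverage (ACC) score**: profiles are normalized by mean
  CDS density, then ACC(x, i) = Σ_m N_m / K over the codon's occurrences —
  1.0 means "average density", larger means pausing. The IFR–ACC Spearman
  correlation summarizes whether dwelling and fidelity move together.

* **Frame-stratified metagene profiles** in a 90 nt window ([−30, +60))
  around the start codon, internal AUGs or any other anchor, plus a
  per-transcript **+12 nt pause classification** (above/below the CDS mean)
  and regional frame-ratio comparisons.

* **Ribosome drop-off**: with per-codon frameshift probabilities
  (p0, p+1, p−1), the remaining-ribosome recursion

      R(i,0) = p0·R(i−1,0) + p−1·R(i−1,1) + p+1·R(i−2,2)
      R(i,1) = p0·R(i−1,1) + p+1·R(i−1,0) + p−1·R(i−1,2)   (0 at stops)
      R(i,2) = p0·R(i−1,2) + p−1·R(i,0)   + p+1·R(i−1,1)   (0 at stops)

  with shifted-frame stop absorption (−1 shifts step 2 nt, +1 shifts step
  4 nt — hence the index asymmetry), an independent Monte-Carlo simulator
  with binomial error bars, predicted occupancy/derailment curves, and the
  half-CDS density-ratio screen for frameshift-like drop-off.

* **Sticky codons and composition**: Hamming-distance classification
  against the reverse complement of the 18S tail (CAU → AUG-like; the GCC
  mutant tail → GGC-like), per-frame codon fraction tables across a CDS
  set, and randomization tests against synonymous-codon or dinucleotide
  shuffling nulls for frame-2 depletion.

* **A synthetic Ribo-seq generator** with programmable frame accuracy,
  per-codon dwell, dwell–fidelity coupling, ligation bias, frame-2
  junction depletion and frameshift-driven decay, plus closed-form
  expected values — every statistic above has a recovery test against
  known ground truth.

## Worked example

```r
library(riboframe)

# a synthetic cohort with sticky codons dwelling ~3x and fidelity coupled
# to dwell, 30 genes x 6000 reads
w   <- default_dwell_multipliers()
q0  <- setNames(0.55 + 0.3 * (rank(w) - 1) / 60, names(w))
cfg <- sim_config(n_transcripts = 30, cds_codons_range = c(100L, 150L),
                  dwell_multipliers = w, codon_q0 = q0,
                  reads_per_transcript = 6000, seed = 42)
g   <- generate_transcriptome(cfg)
aln <- simulate_reads(g$transcripts, cfg)

st <- codon_stats(aln, g$transcripts, site = "fiveprime")
st$sticky <- st$codon %in% sticky_codons()
head(st[order(-st$ifr_global), ], 8)
#>    codon n_genes ifr_global acc_global sticky
#> 60   TTG      27      0.851       6.32   TRUE
#> 47   GTG      27      0.847       6.20   TRUE
#> 31   CTG      27      0.845       6.02   TRUE
#> 16   ATT      26      0.839       5.81   TRUE
#> 15   ATG      30      0.826       5.78   TRUE
#> 13   ATA      25      0.826       5.49   TRUE
#> 11   AGG      27      0.821       5.26   TRUE
#> 14   ATC      30      0.819       5.36   TRUE
abundance_fidelity_correlation(st)
#> [1] 0.994
```

The eight most in-frame 5′-end codons are all sticky (AUG-like), they
carry 5–6× the average footprint density, and abundance and fidelity are
rank-correlated at 0.99 — the package recovers the coupling exactly as
programmed into the generator.

Drop-off from measured spontaneous frameshift rates over a 312-codon ORF:

```r
occ <- predicted_occupancy(my_cds, fs_preset("plus1-dominant"))
tail(occ$derail, 1)   # ~0.12: ~12% of ribosomes lost before the stop codon
```

Frame-2 composition against the synonymous shuffling null (an unsuppressed
genome, so the observed fraction sits inside the null):

```r
randomization_test(g$transcripts, "ATG", frame = 2, n_reps = 100, seed = 1)
#> shuffle null (synonymous_codon, 100 reps): AUG frame 2 fraction 0.1868
#>   vs null 0.1831 +/- 0.021
#>   z = 0.175, empirical p (less) = 0.5644
```

On a genome generated with 5-fold frame-2 AUG suppression the same test
returns z < −2 (see the acceptance suite).

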