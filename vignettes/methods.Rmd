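---
title: "Modeling and inference of the somatic mtDNA bottleneck"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling and inference of the somatic mtDNA bottleneck}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitobottleneck)
library(tibble)
```

## The problem

Each human cell carries hundreds of mitochondrial DNA (mtDNA) copies, and a
somatic mutation is typically present in only a fraction of them
(*heteroplasmy*). Single-cell ATAC- and RNA-seq libraries retain enough
mitochondrial fragments to genotype mtDNA per cell, and in such data mature
B, T and NK lymphocytes show a striking pattern: fewer somatic variants per
cell than progenitor or myeloid populations, yet a large excess of
*homoplasmic* variants (within-cell allele frequency near 1). That combination
is the classic fingerprint of a genetic bottleneck — a transient crash in the
number of transmitted mtDNA copies, which amplifies random drift and pushes
variants rapidly toward loss or fixation.

`mitobottleneck` provides the full quantitative machinery for this analysis:

1. a **synthetic cohort generator** that emits per-cell, per-site,
   strand-resolved allele-count tables with planted ground truth;
2. the **somatic-variant filter cascade** used on such count tables;
3. **spectrum statistics** (the 19-bin variant-allele-frequency spectrum,
   per-cell burden, homoplasmic/dominant fractions, a copy-number proxy);
4. a **Wright-Fisher dilution-bottleneck simulator** (compiled core);
5. **rejection ABC** to infer the bottleneck parameters from an observed
   spectrum, with mutation-rate model selection; and
6. **dN/dS** statistics under the vertebrate mitochondrial genetic code.

## The dilution-bottleneck model

A cell lineage is followed from the lymphoid-primed multipotent progenitor
(LMPP) through `Ta` cell divisions to a mature lymphocyte. The mtDNA
population within the lineage evolves as a Wright-Fisher process with
discrete generations: each division, the new population of \(N_{t+1}\)
copies is sampled binomially (with replacement) from the allele frequencies
of the current one, and the number of new mutations entering is Poisson with
mean \(u \cdot N_{t+1}\), where \(u = \mu L\) is the genome-wide mutation
rate (\(\mu\) per site per division, \(L = 16{,}569\) bp). Each new mutation
starts at one copy and is tracked under the infinite-sites approximation
(recurrent mutation is negligible because \(uN \ll L\)).

The bottleneck is generated by *dilution*: during the first `Td` divisions
only a fraction \(\alpha\) of molecules replicates, so the copy number
shrinks as \(N_{t+1} = \mathrm{round}(\alpha N_t)\) and reaches the minimum

\[ N_b = N_0 \, \alpha^{T_d}. \]

`bottleneck_size(500, 0.9, 10)` returns 174.34; the integer trajectory of
`copy_number_trajectory()` matches this within per-generation rounding
(at most `Td/2` copies).

**Timing of the recovery.** After the diluting divisions the model holds the
copy number at \(N_b\) while the cell completes its remaining divisions, and
restores the baseline \(N_0\) in a single resampling step at the final
(maturation) division. This was a genuinely open design point — "rapid
recovery" could equally have been placed immediately after division `Td` —
and we resolved it on two grounds. Biologically, the copy-number proxy in
real data shows that late, lineage-committed progenitors (pro-B/pre-B, CLP)
still have depleted mtDNA while mature lymphocytes have recovered, i.e. the
low-copy state spans development. Numerically, drift needs residence time at
small \(N\) to act: if the population is restored to \(N_0 = 500\) right
after dilution, the cumulative drift \(\sum_t 1/N_t\) stays far below one
coalescent unit, essentially no mutation can fix, and the model cannot
reproduce the homoplasmic excess it exists to explain. With the sustained
low-copy phase, the simulator reproduces both halves of the signature:
`replicate_spectra()` at \(N_b \approx 14\) gives a top-bin (VAF ≥ 0.95)
count exceeding the mid-frequency bins, while an \(\alpha = 1\) control of
matched `Ta` declines monotonically from the first bin and carries the higher
total detectable burden. Both checks run in the test suite.

### Parameters

| Parameter | Meaning | Default |
|---|---|---|
| `N0` | baseline mtDNA copies per cell | 500 (B/T); 300 for NK (`baseline_copy_number("NK")` = 500 × 0.6) |
| `alpha` | fraction of molecules replicating per division | inferred; (0, 1] |
| `Td` | diluting divisions | inferred; integer |
| `Ta` | total divisions LMPP → mature cell | inferred; integer ≥ `Td` |
| `mu` | mutation rate per site per division | 1e-7 (1e-8 as alternative for model selection) |
| `L` | genome length | 16,569 bp |
| `detection_floor` | smallest simulated VAF treated as detectable | 0.05 |

The detection floor equals the first spectrum edge: per-cell sequencing depth
in the tens cannot support heteroplasmy calls below ~5%.

## The 19-bin VAF spectrum

All inference is channelled through one summary statistic: counts of variant
allele frequencies in 19 bins of width 0.05 spanning 0.05–1.00. Bins are
left-closed/right-open except the last, `[0.95, 1.00]`, which is closed so
that fully fixed (VAF = 1) mutations — the key signal — cannot fall off the
edge. VAFs below 0.05 are excluded. `vaf_spectrum()` supports raw counts and
the `per_cell_mean` scale (counts divided by the number of cells); the latter
is the default for ABC because it makes the distance insensitive to cohort
size, which in turn lets the simulated cohorts be much smaller than the
observed one.

## Rejection ABC

`abc_reject()` implements plain rejection sampling: draw
\(\theta' = (\alpha, T_d, T_a)\) from the prior, simulate a cohort, summarize
it as the spectrum \(S'\), and score it by the Euclidean distance
\(d(S', S)\) to the observed spectrum. Rather than a fixed tolerance
\(\varepsilon\), all `K` distances are sorted and the smallest
\(\lfloor K\eta \rfloor\) draws are retained (defaults `K = 1e6`,
`eta = 0.001`, i.e. 1,000 accepted draws). Ties at the cutoff are broken by
draw order; with continuous distances they have measure zero.

Priors: \(T_d \sim U\{0..30\}\), \(T_a \sim U\{10..40\}\) (integers — cell
divisions are discrete), \(\alpha \sim U(0,1)\), subject to \(T_a \ge T_d\)
and the retention rule \(N_b > 10\), which discards parameter draws whose
mtDNA population would effectively go extinct. The continuous range for
\(\alpha\) is the least-informative choice; the retention rule prunes the
infeasible corner (e.g. \(\alpha = 0.7, T_d = 20\) gives
\(N_b \approx 0.4\) and is always resampled).

`posterior_summary()` reports the mean and the 2.5/97.5 percentile interval
per parameter, including the derived \(N_b\). `model_select_mu()` repeats
the inference per candidate mutation rate and prefers the rate with the
smaller mean accepted distance — the selection criterion itself is our
choice, since "fits better" admits several formalizations.

### Problem sizes

Because the distance is computed on the per-cell-mean scale, the per-draw
simulated cohort defaults to 25 lineages (`abc_config(n_cells_sim = 25)`)
even when the observed cohort has hundreds of cells; this is the standard
noisy-summary trade-off of rejection ABC, and the parameter-recovery test
(truth \(\alpha = 0.85, T_d = 15, T_a = 25\), hence \(N_b \approx 43.7\);
`K = 5 \times 10^4`, `eta = 0.002`, 500 observed cells) verifies that the
95% credible interval covers the truth in at least 8 of 10 seeded
repetitions. For mutation-rate model selection the per-draw cohort should be
larger (~100 cells): per-cell-mean counts are quantized at `1/n_cells_sim`,
and that granularity must sit below the burden difference the two rates
produce. The bookkeeping test runs the full `K = 1e6` with single-cell
cohorts, where only the accepted-count contract, not posterior quality, is
at stake.

## The variant filter cascade

`call_somatic_variants()` reproduces the five-step cascade over strand-
resolved per-cell counts. Candidates require, in at least one cell, depth
≥ 8, alt reads ≥ 2 and alt fraction ≥ 0.01. Then, in order:

1. **Germline removal** — variants with pooled (all-cell) VAF > 0.90, or
   per-cell VAF > 0.90 in more than 90% of covered cells (cells with ≥ 8×
   at the site; cells with undefined VAF cannot vote).
2. **Site blacklist** — 13 positions around the two homopolymer tracts
   (302–316, 514–524) and the reference `N` at 3107, where misalignment
   creates recurrent artifacts; any substitution at these positions is
   removed. (Matching is positional: the artifact mechanism is misalignment
   at the position, whatever the apparent substitution.)
3. **Damage substitutions** — all G>T and C>A calls are removed as oxidative
   damage artifacts.
4. **Confidence filters** — depth ≥ 20, alt reads ≥ 2 and a forward-strand
   fraction of alt reads strictly between 0.30 and 0.70 in at least one
   cell; boundary values fail ("above … but below").
5. **Recount and cell filter** — each confident variant's VAF is recounted
   as alt/(alt+ref) in every cell of the same cell type wherever depth ≥ 8
   (missing otherwise), and cells with mean mtDNA depth ≤ 10× are dropped.

"More than 20 reads" is read as ≥ 20 and "more than two reads" as ≥ 2, for
internal consistency with the explicit candidate thresholds (`min-reads2 2`).
The final somatic set is asserted disjoint from the germline set and both
blacklists on every run. Raising `min_site_depth` can only shrink the final
set (monotonicity, tested).

## What the synthetic cohorts emulate — and what they do not

`generate_cohort()` reproduces the *structure* of single-cell mtDNA count
data: germline variants at VAF ≈ 1 in every cell; somatic variants either
from an explicit per-variant VAF/carrier plan or simulated per cell by the
Wright-Fisher model; spurious alt reads at the blacklisted homopolymer
positions; strand-asymmetric G>T/C>A damage reads (alt reads ~95% on one
strand, giving the strand-balance filter real work); negative-binomial
per-site depth with a per-cell gamma factor for coverage variation; and a
binomial strand split for genuine alleles. Somatic plants deliberately avoid
G>T/C>A substitution types, since the cascade removes those categorically —
a known blind spot of the filter, not of the generator.

The generator does **not** model read-level errors (FASTQ), alignment
artifacts beyond the listed positions, doublets, multi-allelic sites, or the
platform-specific error catalogue of any particular sequencer. Passing the
planted-truth test therefore shows the cascade implements its thresholds
correctly, not that those thresholds are sufficient for any given real
dataset.

The bundled reference deserves emphasis: gene/region coordinates are the
standard rCRS map (including the ATP8/ATP6 and ND4L/ND4 overlaps), but the
nucleotide sequence is **synthetic** — deterministic uniform-random bases
from `synthetic_mt_genome()`. Every synthetic cohort draws its reference
alleles from it, so the package is internally consistent; analyses of real
data must supply the true rCRS sequence through the `genome` arguments.

## dN/dS under the vertebrate mitochondrial code

Potential sites are counted by substitution enumeration: for every codon of
every CDS, all 9 single-nucleotide changes are classified as synonymous or
nonsynonymous under the vertebrate mitochondrial code (TGA = Trp, AGA/AGG =
stop, ATA = Met), giving genome totals `N` and `S` with
`N + S = 9 × (#codons)`. Observed variants are classified in codon context
(minus-strand ND6 on the reverse complement); then `dN = n/N`, `dS = s/S`,
and the ratio is reported per heteroplasmy stratum, as `NA` (not infinity)
when `s = 0`. Stop gain/loss counts as nonsynonymous. Positions in a
trimmed trailing partial codon are excluded from both observed and potential
counts. Sites inside overlapping genes are classified once per gene context
and flagged; the same convention is used for potential-site totals, keeping
numerator and denominator consistent. Under uniform random coding
substitutions the ratio is ~1 within binomial sampling error (tested); a
fractional Nei–Gojobori site-counting scheme or maximum-likelihood dN/dS is
out of scope.

## Numerical choices

- Spectrum edges are `(1:20) * 0.05` in double precision in both the R and
  compiled binning paths, so boundary behavior is identical everywhere.
- The Wright-Fisher core uses R's RNG (`R::rbinom`, `R::rpois`) so a single
  `set.seed()` governs every stage; cohorts, ABC runs and pipelines are
  byte-reproducible for a fixed seed.
- `run_pipeline()` derives per-stage seeds deterministically from the global
  seed, so a stage can be rerun in isolation with identical results.
- Copy numbers are integers; dilution rounds half away from zero per
  generation, and extinction (N < 1) raises an error rather than silently
  clamping — the ABC retention rule `Nb > 10` keeps the sampler away from
  that region.
- `sample_prior()` rejection-samples in vectorized rounds and errors out
  after a bounded number of rounds if the constrained prior is infeasible.

## Limitations

- The model is neutral: no selection coefficients on mtDNA variants, no
  organelle-level population structure, no mitophagy. Quantities estimated
  from data with strong selection will be correspondingly biased.
- The bottleneck-size estimates published for real cohorts depend on
  external sequencing datasets; this package reproduces the machinery and
  verifies it on synthetic data, but does not ship those datasets.
- The mutation-rate grid for model selection is coarse (1e-8 vs 1e-7), and
  the low-frequency end of the spectrum is sensitive to the detection floor.
- Rejection ABC with a fixed acceptance fraction is simple and auditable but
  statistically inefficient compared to SMC or regression-adjusted variants,
  which are out of scope.
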