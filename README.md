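# mitobottleneck

Inference of the somatic mitochondrial DNA (mtDNA) genetic bottleneck in
lymphocyte development, from per-cell strand-resolved allele-count tables.

## The problem

Every cell carries hundreds of mtDNA copies; a somatic mutation occupies
only a fraction of them (its per-cell variant allele frequency, VAF).
Single-cell ATAC/RNA-seq data show that mature B, T and NK lymphocytes carry
*fewer* somatic mtDNA variants per cell than progenitors, yet far *more*
homoplasmic ones (VAF ≈ 1). That pattern is the signature of a genetic
bottleneck: a transient crash in mtDNA copy number that amplifies random
drift and forces variants to loss or fixation.

The package models the bottleneck as a Wright–Fisher dilution process. A
lineage runs for `Ta` cell divisions from the lymphoid-primed progenitor
(LMPP) to the mature cell. During the first `Td` divisions only a fraction
`α` of molecules replicates, so the copy number falls from `N0` (≈ 500; 300
in NK cells) to the bottleneck minimum

```
Nb = N0 · α^Td
```

then stays low while the cell completes development and recovers to `N0` at
the final maturation division. Mutations enter as a Poisson process with
genome-wide rate `u = μ·L` (`μ` = 1e-7 per site per division,
`L` = 16,569 bp) and drift neutrally. The parameters `(α, Td, Ta)` are
inferred by rejection ABC: simulate cohorts under prior draws, summarize each
as the 19-bin VAF spectrum (edges 0.05…1.00), and keep the `⌊K·η⌋` draws
closest to the observed spectrum in Euclidean distance (defaults `K = 1e6`,
`η = 0.001` → 1,000 accepted draws), subject to the priors
`Td ~ U{0..30}`, `Ta ~ U{10..40}`, `α ~ U(0,1)` and the retention rule
`Nb > 10`.

Around that core the package provides the somatic-variant filter cascade for
single-cell mtDNA count tables (germline removal → homopolymer-site and
G>T/C>A damage blacklists → depth/alt-read/strand-balance confidence filters
→ per-cell VAF recounting → cell-depth filter), a synthetic-cohort generator
with planted ground truth, spectrum/burden/copy-number statistics, and dN/dS
under the vertebrate mitochondrial genetic code.

## Worked example

Simulate an observed cohort at a known bottleneck and re-infer its size:

```r
library(mitobottleneck)

params <- sim_params(alpha = 0.8, Td = 12, Ta = 28, N0 = 500,
                     n_cells = 400, seed = 42)
params
#> Wright-Fisher dilution model: N0 = 500, alpha = 0.800, Td = 12, Ta = 28
#>   Nb = N0 * alpha^Td = 34.36; u = mu * L = 0.00166 (mu = 1e-07)
#>   cohort: 400 cells, detection floor 0.05

obs <- cellset_spectrum(simulate_cellset(params))
obs
#> VAF spectrum (per_cell_mean): 19 bins, edges 0.05..1.00
#> [0.05,0.10) [0.10,0.15) [0.15,0.20) [0.20,0.25) [0.25,0.30) [0.30,0.35)
#>      0.0800      0.0400      0.0125      0.0125      0.0150      0.0050
#> ...

post <- abc_reject(obs, abc_config(K = 20000, eta = 0.005,
                                   n_cells_sim = 25, seed = 43),
                   prior_spec())
posterior_summary(post)
#> # A tibble: 4 × 4
#>   parameter    mean ci_low ci_high
#>   <chr>       <dbl>  <dbl>   <dbl>
#> 1 alpha       0.713  0.227   0.980
#> 2 Td          6.11   0      19
#> 3 Ta         24.3   10.5    37.0
#> 4 Nb        219.    16.5   500
```

The spectrum of ~0.21 detectable mutations per cell concentrates at low
frequency with the counts decaying toward fixation. At this reduced `K` the
posterior is wide, but the 95% interval for the bottleneck size `Nb`
(16.5–500) covers the generating truth `Nb = 34.4`; the parameter-recovery
test in the suite repeats this experiment ten times at `K = 5e4` and
requires coverage in at least 8 of them. Individual marginals (`alpha`,
`Td`) are only weakly identified — many dilution schedules produce the same
minimum copy number, which is why `Nb` is the quantity reported.

An end-to-end synthetic run (cohort → filter cascade → spectrum → ABC →
dN/dS, with per-stage outputs and a checksummed manifest):

```r
run_pipeline(NULL, out_dir = "demo_run", seed = 1)
```

A thin command-line wrapper lives at `inst/cli/mitobottleneck.R`
(`run` / `synth` / `simulate` subcommands).

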