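# digestor

Analysis toolkit for **chemically stressed anaerobic-digester
microbiomes**.  It is aimed at process engineers and microbial
ecologists who run perturbation experiments on lab-scale digesters and
want one reproducible path from reactor book-keeping and 16S amplicon
profiles to an ecological reading of who is helping or hurting whom.

The package has five layers:

1. **Process chemistry** — stoichiometric accounting of the digestion
   experiment.  The core is the Buswell–Boyle prediction of specific
   methane potential for a substrate CcHhOoNn under complete anaerobic
   degradation:

   CH4 (mol/mol) = c/2 + h/8 − o/4 − 3n/8,
   yield (L/g) = CH4 × 22.414 / M

   plus organic loading rate (Σ weekly VS / 7), hydraulic retention
   time (V / throughput), digestion efficiency, ideal-gas normalisation
   to 273 K / 1013 hPa, and stressor molarity.
2. **Amplicon profiles** — FASTQ length/quality gating (≥ 400 bp, mean
   PHRED ≥ 7), OTU-table containers with QIIME-style lineages, rank
   aggregation, top-N taxon selection, Bray–Curtis dissimilarity
   BC(x, y) = Σ|xᵢ − yᵢ| / Σ(xᵢ + yᵢ) and principal-coordinates
   ordination.
3. **Differential shifts** — Benjamini–Hochberg adjustment, strict
   `padj < α` significance filtering, and a three-stressor Venn
   classification of taxa into increase / decrease / conflict regions
   versus the control.
4. **gLV core** — simulation of the generalized Lotka–Volterra system
   dxᵢ/dt = xᵢ (rᵢ + Σⱼ αᵢⱼ xⱼ) with an adaptive Runge–Kutta scheme,
   gradient-matching inference of r and α by ridge regression of
   d(ln xᵢ)/dt on [1, x₁ … xₙ], and sign-based comparison of
   interaction structures (counts, shared, unique).
5. **Synthetic data + pipeline** — a seeded generator that emulates a
   4-condition × 4-timepoint × 3-replicate stress experiment (gLV
   ground truth, lognormal observation noise, multinomial sequencing
   depth, feeding schedules), and `run_pipeline()` to wire everything
   into one manifest-tracked run.

## Worked example

```r
library(digestor)
db <- species_db()
sprintf("nalidixic acid yield: %.2f L/g", buswell_yield(db$nalidixic_acid))
sprintf("digestion efficiency: %.2f %%", digestion_efficiency(16.66, 28.96))
```

```
nalidixic acid yield: 0.58 L/g
GABA yield:           0.49 L/g
added potential:      12.24 / 10.34 L
digestion efficiency: 57.53 %
expected surplus:     7.04 / 5.95 L
```

Reading: complete degradation of nalidixic acid would release 0.58 L
CH4 per gram; the 21.11 g/L applied over the experiment therefore
carries 12.24 L of extra theoretical potential, of which 7.04 L would
be expected at the observed 57.53% digestion efficiency.  A reactor
producing no such surplus is telling you the stressor was not degraded
(or inhibited the community).

A full synthetic study plus pipeline run:

```r
fx  <- generate_study("study", seed = 1)      # counts, metadata, truth, schedule
out <- run_pipeline(list(
  inputs  = list(otu_table = fx$otu_table, metadata = fx$metadata,
                 schedule  = fx$schedule),
  params  = list(epsilon = 0.05),
  out_dir = "run1"))
jsonlite::read_json("run1/glv_interactions.json", simplifyVector = TRUE)$counts
```

```
  condition positive negative neutral
1   control       22       23       4
2 nalidixic       25       23       1
3      GABA       22       24       3
4 phosphate       24       24       1
```

Counts run over all n² = 49 ordered pairs of the 7 modelled taxa
(diagonal included); `shared_interactions()` and
`unique_interactions()` compare the per-condition sign matrices against
the control.

A command-line wrapper is installed at
`system.file("cli/digestor", package = "digestor")` with subcommands
`chem | profile | diff | glv | simulate | run`.

## Further reading

The methods vignette (`vignettes/digestor-methods.Rmd`) documents the
model assumptions, the identifiability analysis behind the gLV test
design, all numerical choices, and what the synthetic generator does
and does not emulate.
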