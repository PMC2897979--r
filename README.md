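# riftkin

Genome-wide RNA decay kinetics from rifampicin chase time courses.

After rifampicin blocks transcription initiation, the decline of every
transcript's signal over a sampled chase (here 0, 2.5, 5, 10, 20, 40, 60
minutes, in triplicate) measures RNA degradation alone. riftkin turns such
expression time courses — from microarrays, qPCR, or any per-gene intensity
series — into per-gene stability estimates and the downstream analyses that
make them interpretable. It was built around the chase experiment in the
slow-growing marine cyanobacterium *Prochlorococcus* MED4, and is aimed at
anyone estimating bacterial RNA half-lives from transcription-arrest data.

## What it computes

* **Half-life, twofold decay-step method.** The earliest sampled timepoint
  t_j with E(t_j) ≤ E(t_0)/2 defines a two-point exponential fit;
  t½ = (t_j − t_0) / log2(E_0/E_j). Series that never halve fall back to an
  all-timepoint fit and are flagged stable.
* **Decay rate, relative two-phase model.** Two successive exponentials on
  the log2 scale, fitted from the last timepoint of maximal expression
  (the onset); the breakpoint x is chosen from the sampled timepoints by
  minimal pooled MSE of the logged data, ties to the earliest x. The decay
  rate is the first segment's time per twofold change — measured relative
  to maximal expression, so delayed-onset genes get a short decay rate and
  a long half-life, as they should.
* **Operon analyses.** Strand-aware distances to the operon's first start
  codon; Spearman correlation of position with stability; validation of
  predicted operons against expression (weak expression / inconsistent
  member profiles); typing of decay profiles into plateau-before-decline
  (type I) versus transient-rise (type II) operons.
* **Probe-level kinetics.** Sub-gene decay fits for tiled probes of genes
  ≥ 2 kb, and the RNA polymerase elongation rate v = s/(60·t) nt/s from
  probe-pair distances s and half-life differences t.
* **Clustering and enrichment.** Fuzzy c-means (m = 2) on standardized
  log2 profiles, hypergeometric category enrichment with Bonferroni
  adjustment, and enrichment-guided choice of the cluster number.
* **qPCR support.** 2^-ddCt relative quantification and array-versus-qPCR
  concordance scoring used to rank normalization schemes (none,
  all-genes-median, spike-median, RNA-gene-median).
* **Synthetic chase generator.** Seeded fixtures — genes, operons, tiled
  probes, whole genomes — with known kinetic ground truth (two-phase decay,
  onset delays growing with distance from the transcription start,
  transient type II rises, multiplicative noise, saturation clipping), so
  the whole pipeline is testable without external data.

## Worked example

```r
library(riftkin)

design <- chase_design(noise_sigma = 0.1, seed = 1)
sim    <- simulate_genome(n_genes = 1000, n_operons = 50, design = design)
paths  <- write_fixture(sim, "fixture")

cfg <- pipeline_config(expression_threshold = 100, seed = 1)
run_pipeline(paths["expression"], "results",
             annotation = paths["annotation"], config = cfg)
make_report("results", config = cfg)
```

prints

```
genes fitted: 929
median half-life: 3.14 min (80% of genes in 0.99-8.72 min)
median decay rate: 3.07 min
stable transcripts (> 60 min or never declining): 1.8%
operons: 43 retained (32 type I, 11 type II), 0 weak expression, 7 inconsistent
```

929 of 1000 simulated genes clear the t = 0 expression threshold. The
median fitted half-life and decay rate land a few tenths of a minute above
the generator's 2.4-minute median because operon members decay late
(delayed onset inflates the twofold half-life) and noise widens the fitted
distribution; the per-gene table in `results/decay.tsv` carries both
estimates with standard errors, onset, breakpoint and stability flags, and
`results/manifest.json` records input/output digests so a rerun with the
same seed is verifiably identical. At this noise level a few plateau
(type I) operons show spurious rises past the 1.2× typing threshold, which
is why the report counts 11 type II calls against 9 planted.

The same `run_pipeline()` call accepts a GEO-style series matrix in place
of the wide TSV, and `inst/scripts/riftkin.R` wraps simulation and the
pipeline for shell use.

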