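# csdtools

Extraction and statistical analysis of peptide **charge state
distributions (CSDs)** from positive-mode electrospray MS1 data, with a
fully synthetic, ground-truth-known test bed.

When a peptide is electrosprayed it appears as several protonation
states; its CSD is the normalized intensity vector
*p* = (*p*<sub>1+</sub>, …, *p*<sub>5+</sub>). CSDs are reproducible,
sequence-dependent, and informative: a peptide's **basic sites**
(R, K, H, plus an unmodified N-terminus) set a reference charge *b*, and
peptides are *undercharged* (mean charge Σ*k·p*<sub>k+</sub> < *b*) or
*overcharged* (> *b*) depending mostly on mass, with residue-level
fine-tuning. This package is aimed at proteomics researchers who want to
extract high-confidence CSDs from identified MS1 data and analyze what
drives them.

The core pieces:

* **Extraction** (`extract_run`): per-scan matching of theoretical
  isotope envelopes (exact elemental composition, convolved isotope
  distributions) for charges 1+–5+, with ppm-tolerance offsets, a
  cosine ≥ 0.98 shape filter, chimeric-peak rejection and
  confident-absence calls; a reading is kept only when all five charge
  states are confidently estimated, then per-scan CSDs are combined by
  intensity-weighted averaging.
* **Error & batch correction** (`total_variation`, `fit_gamma`): error
  between readings is total variation
  TV(*p*, *q*) = ½ Σ |*p*<sub>k+</sub> − *q*<sub>k+</sub>|; between-run
  batch effects are modeled by one scalar γ > 0 acting as
  *p*<sub>k+</sub> ∝ *p*<sub>k+</sub> γ<sup>k</sup> (a uniform
  log γ shift of all consecutive log-odds), fitted by minimizing the
  summed TV over shared peptides.
* **Regimes** (`summarize_regimes`, `mass_trend`): under/exact/over
  classification against basic sites and monotone mean-charge-vs-mass
  trend curves.
* **Effective basicity** (`fit_effective_basicity`, `mass_adjust`):
  within a charging region (#2O, #3O, #3U, #4U — a basic-site count and
  a consecutive charge pair *k*, *k*+1), logistic regression of
  *y* = *p*<sub>(k+1)+</sub>/(*p*<sub>k+</sub> + *p*<sub>(k+1)+</sub>)
  on 20 amino acid counts + 20 N-terminal indicators (binary cross
  entropy, L2 λ = 0.01). Each coefficient is a residue's *effective
  basicity score* — its log-odds contribution to higher charging — with
  a Huber (δ = 0.01) regression on residue mass providing mass-adjusted
  scores.
* **Synthetic data** (`sample_peptides`, `ground_truth_model`,
  `simulate_run`): tryptic-like peptides (700–4600 Da) with CSDs planted
  by a sequential log-odds model, rendered as MS1 scans with isotope
  envelopes, log-normal noise, chimeric interference, an intensity
  threshold, a 300–1800 m/z window and run-level γ batch effects.

See `vignettes/csd-methods.Rmd` for the model details and design
decisions.

## Worked example

The numbered scripts under `analysis/` run the full study on synthetic
data and write tables under `results/`:

```sh
Rscript analysis/01_simulate.R       # population + reference MS1 run
Rscript analysis/02_extract.R        # CSD extraction vs ground truth
Rscript analysis/03_batch_effects.R  # paired-run gamma fit
Rscript analysis/04_regimes.R        # regime summary + mass trends
Rscript analysis/05_basicity.R       # effective basicity scores
```

Output of a full run:

```
peptides: 500, mass 911-4508 Da, basic sites 1-6
rendered 733251 MS1 peaks in 20000 scans -> results/scans_synthA.tsv
readings: 500/500 peptides
extraction error vs ground truth: median TV 0.0025, 95th pct 0.0163, 97.4% under 2%
fitted log gamma 0.2963 (planted 0.3); mean TV 0.0388 -> 0.0094 after correction (n = 200 shared)
regimes over 500 unique peptides: 33% under, 0% exact, 67% over (pure 0.0%)
b = 3: crosses mean charge 3 near 1900 Da
fitted 12 region-run score sets
within-regime mean r = 0.997, between-regime mean r = 0.418 (two clusters)
region #2O run1, mass-adjusted extremes: high = Q,V,L low = N,E,D
```

Reading this: extraction recovers planted CSDs to a median total
variation of 0.25% despite 20% multiplicative noise, an intensity
threshold and injected chimeras; the one-parameter batch fit recovers
the planted log γ = 0.3 and cuts the between-run error four-fold; each
basic-site group transitions from under- to overcharging as mass grows;
and the under/over charging regions split into two clusters of
effective-basicity scores, with glutamine and the aliphatic residues
scoring high and the short acidic/amide residues low in the overcharging
region — exactly the structure planted in the generator.

In-memory, the same pipeline is one call:

```r
library(csdtools)
res <- pipeline_run(n_peptides = 200, seed = 1)
res$regimes$fractions
res$counts
```

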