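# ionextract

Selected ion extraction of peptide delta-mass peaks for plasma proteomics.

Peptides ionised from natural samples spread over a range of precursor
masses: heavy isotopes of C, H, N, O and S populate +1 … +5 Da above the
monoisotopic mass, and hydrogen loss populates −1, −2 and −3 Da. A
wide-window MS/MS search (precursor delta mass Δm = MH_obs − MH_theor from
−3 to +5 Da) therefore shows nine Gaussian peaks at integer Δm. Keeping only
the monoisotopic peak controls the type I error no better than keeping all
nine — but it discards most true observations, inflating the type II
(false-negative) error. `ionextract` is a toolkit for quantifying that
trade-off, aimed at researchers analysing wide-window search results (or
benchmarking extraction strategies on synthetic ground truth):

* **chemistry** — residue-level composition and mass arithmetic, tryptic
  digestion (`[RK]` cleavage, missed cleavages), modifications, and
  isotope-envelope computation by per-element convolution; the +1/monoisotopic
  crossover mass under an averagine-like model,
* **synthetic data** — a plasma-like sample generator (dominant albumin-like
  protein, Zipf abundance decay) and an LC-MS/MS run simulator with
  isotope/hydrogen-loss precursor sampling and a planted truth table, plus
  blank (noise) runs,
* **random control** — a Monte-Carlo spectrum generator calibrated to a
  run's precursor mass, fragment-count and fragment-m/z distributions,
* **psm engine** — a defined, simplified goodness-of-fit matcher (greedy b/y
  fragment matching, binomial-tail p-value) with the standard precursor
  filters and best-fit-per-spectrum (BFPS) non-redundancy; external PSM
  tables can be ingested instead,
* **ion extraction** — Gaussian kernel densities of Δm, topographic
  integer-peak detection, and window extraction
  (e.g. monoisotopic-only vs all nine integers, ±tolerance),
* **error stats** — chi-square correction of peptide observation
  frequencies against blank/random controls (χ² ≥ 9), gene-symbol
  aggregation with the n ≥ 3 rule, Benjamini–Hochberg q-values, cumulative
  p-values (geometric-mean form `mean_p^n` in log space) and type II error
  `round(100·(1 − detected/benchmark))` per extraction treatment.

## Worked example

Simulate a small plasma-like experiment, run the full pipeline (search,
BFPS, control correction, treatment sweep) and inspect the delta-mass
structure:

```r
library(ionextract)

cfg <- pipeline_config(seed = 42, n_proteins = 60, n_true = 20,
                       n_spectra = 4000, n_blank = 1000, n_random = 4000)
res <- run_pipeline(cfg)
res$sweep
#>                       treatment proteins_n3        fdr_q msms_count type2_percent
#> 1          Monoisotopic ±0.1 Da          19 2.703358e-72       1084            10
#> 2 Hydrogen and Isotopes ±0.1 Da          21 7.739012e-38       3224             0
#> 3           All MS/MS corrected          21 7.739012e-38       3224             0
#> 4       All MS/MS not corrected          33 8.562312e-38       3544            NA
```

Reading the sweep: after correction against the blank and random controls,
21 proteins reach n ≥ 3 peptide observations at q ≤ 0.01 when all nine
integer windows are kept at ±0.1 Da — identical to the uncut corrected
benchmark, whose type II error is 0% by construction. Restricting to the
monoisotopic window keeps only 1,084 of 3,224 corrected PSMs and drops the
protein count to 19 (type II error 10%); the uncorrected row shows what the
controls removed. The planted truth confirms the recovery
(`res$recovery`: 20 of 20 planted-true proteins at q ≤ 0.01), and the
delta-mass density shows the integer peak series:

```r
detect_integer_peaks(density_profile(res$psm_experimental$delta_mass))
#>   center position      height
#> 1     -3   -2.980 0.009761282
#> 2     -2   -1.995 0.036303399
#> 3     -1   -1.000 0.092439047
#> 4      0    0.000 0.580729868
#> 5      1    1.000 0.514186512
#> 6      2    2.000 0.287315374
#> 7      3    3.000 0.142999553
#> 8      4    4.000 0.056773875
```

The error arithmetic is available directly; for a peptide observed 21 times
at a geometric-mean p of 0.001848, and for a treatment detecting 382 of a
2,784-protein benchmark:

```r
cumulative_p(0.001848, 21)
#> [1] 3.987873e-58
type2_protein(382, 2784)
#> [1] 86
```

A command-line wrapper is installed at `exec/ionextract` inside the package
(subcommands `simulate`, `randomgen`, `search`, `extract`, `report`,
`pipeline`), driven by YAML configs and producing MGF/TSV/JSON outputs with
provenance headers.

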