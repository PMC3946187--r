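# gambi

Tools for assessing whether a DNA-barcoding ("genetics based") route to the
AZTI Marine Biotic Index is feasible with a given barcode reference library.

Benthic macroinvertebrate communities are a standard indicator of coastal
ecosystem health. The AMBI summarizes a sample as the abundance-weighted mean
pollution tolerance of its species, each species carrying one of five
ecological groups (GI sensitive … GV first-order opportunist):

    AMBI = (0·%GI + 1.5·%GII + 3·%GIII + 4.5·%GIV + 6·%GV) / 100

where the percentages count individuals (AMBI) or species present (p/a AMBI).
Values in [0, 6] bin into five pollution classes (unpolluted ≤ 1.2 < slightly
≤ 3.3 < moderately ≤ 5 < heavily ≤ 6 < extremely); azoic samples get 7.
Metabarcoding yields presence/absence, not abundances, and only for species
with reference barcodes — so the operational questions are: how well does the
p/a AMBI classification agree with the abundance-based one, and how well does
a classification computed from a *subset* of species (the sequenced ones, or
the most frequent ones) agree with the full one? Agreement is measured with
unweighted Cohen's kappa, interpreted on the Monserud–Leemans scale, and the
frequent-subset kappa is tested against a null of equally many randomly chosen
species (100 replicates; parametric one-sided p from the fitted normal, plus
an empirical companion p).

The package provides:

- `ambi()` / `compute_index()` — AMBI and p/a AMBI with quality classes,
  azoic and unassigned-species handling;
- `confusion_matrix()`, `cohens_kappa()`, `interpret_kappa()`,
  `per_class_agreement()` — agreement between two classifications;
- `species_frequency_ranking()`, `subset_agreement()`,
  `random_subset_null()`, `subset_pvalue()`, `frequent_subset_report()` —
  species-subset analyses with the resampling null;
- `read_fasta()`, `dedup_cluster()`, `coverage_report()`,
  `sequenced_species_filter()` — barcode reference-library auditing
  (greedy per-species clustering at 0.9 identity, longest representative);
- `primer_pair()`, `locate_primer_region()`, `testable_sequences()`,
  `predict_amplification()`, `species_amplification_summary()` — in-silico
  evaluation of degenerate primer pairs with a position-weighted mismatch
  score (3'-terminal mismatches effectively kill amplification);
- `generate_eg_map()`, `generate_gradient_communities()`,
  `generate_barcode_library()`, `simulate_dataset()` — a community and
  library simulator so every stage runs without external data;
- a CLI: `inst/exec/gambi` with subcommands `ambi`, `agreement`, `subsets`,
  `coverage`, `primers`, `simulate`.

## Worked example

```r
library(gambi)

eg  <- generate_eg_map(300, seed = 1)                      # species list
com <- generate_gradient_communities(eg, n_stations = 200, seed = 2)

res <- ambi(com$matrix, eg, mode = "presence")
head(res, 3)
#>    station_id     mode    value     quality_class azoic unassigned_fraction n_taxa_used
#> 1 station_001 presence 1.662162 slightly polluted FALSE          0.00000000          37
#> 2 station_002 presence 1.363636 slightly polluted FALSE          0.02941176          33
#> 3 station_003 presence 1.714286 slightly polluted FALSE          0.05405405          35

frequent_subset_report(com$matrix, eg, n_replicates = 100, seed = 7)
#>   fraction subset_size     kappa interpretation null_mean    null_sd p_parametric p_empirical
#> 1     0.10          30 0.3212670           poor 0.1532223 0.09365293 3.637993e-02  0.05940594
#> 2     0.25          75 0.7346072      very good 0.3371478 0.10444058 7.072947e-05  0.00990099
#> 3     0.50         150 0.7808391      very good 0.5579172 0.11904881 3.056702e-02  0.01980198
```

Reading the report: restricting the p/a AMBI to the 25% most frequent species
still reproduces the full classification very well (kappa 0.73), and far
better than 100 random subsets of the same size (null mean 0.34, parametric
p ≈ 7e-5). Agreement grows with the fraction kept.

In-silico primer evaluation on a simulated library:

```r
pair <- example_primer_pairs()[[2]]        # dgLCO1490 x dgHCO2198
lib  <- generate_barcode_library(eg, coverage_fraction = 0.15, pair = pair,
                                 mutation_rate = 0.02, seed = 3)
pair <- locate_primer_region(lib$reference, pair)
ok   <- testable_sequences(lib$records, pair, lib$reference)
species_amplification_summary(amplification_calls(pair, ok))$by_phylum
```

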