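# sigbenefit

Predicting durable benefit from immunotherapy in advanced non-small
cell lung cancer (NSCLC) from somatic mutational signatures. Tumor
mutational burden (TMB) pools all amino-acid-changing mutations; this
pipeline instead decomposes each tumor's SBS-96 mutation spectrum
`X` against a fixed signature catalog `H` by non-negative least
squares, `X ≈ W H`, and uses the per-Mb activities of two signatures —
tobacco smoking (SBS4) and thiopurine exposure (SBS87) — in a naive
Bayes classifier with zero-inflated-exponential features to predict
durable benefit (progression-free survival ≥ 26 weeks). Predictions
are evaluated with leave-one-out cross-validation, bootstrap
confidence intervals, permutation tests, Kaplan–Meier/Cox survival
comparison and decision-curve (net benefit) analysis. Because the
study cohorts are access-restricted, the package ships a synthetic
cohort generator with the generative structure the analysis assumes,
so every stage is testable end to end.

Intended users: bioinformaticians and biostatisticians working on
immunotherapy biomarkers who want a tested, self-contained
implementation of the full chain from VCF + FASTA to clinical-utility
curves.

## Core model

* **Refit:** per sample, `min ‖x − wH‖² s.t. w ≥ 0`, solved by cyclic
  coordinate descent (tolerance 1e-6, ≤ 1e4 sweeps); activities
  normalised per Mb (47.9 Mb exome by default) and rounded half away
  from zero to 2 decimals; TMB likewise.
* **Classifier:** per class `c` and feature `j`,
  `P(x | c) = π` at `x = 0` and `(1−π) λ e^{−λx}` for `x > 0`,
  multiplied across features, combined with empirical class priors;
  predict durable benefit when `P(DB | x) ≥ 0.438`.
* **Screening:** two-sided Kolmogorov–Smirnov per signature between
  benefit strata, Benjamini–Hochberg across the catalog; Kendall τ-b
  for gene correlations; Fisher exact for enrichment.
* **Survival/utility:** Cox hazard ratio of predicted groups (Breslow
  ties), cross-cohort comparison via
  `z = (β₁−β₂)/√(SE₁²+SE₂²)`, and net benefit
  `TP/n − FP/n · p_t/(1−p_t)` over a threshold grid.

## Worked example

The `analysis/` directory is a numbered workflow over the package;
each script prints what it found and writes its tables under
`results/sim/`:

```sh
Rscript analysis/01_simulate.R        # synthetic discovery cohort (m = 101)
Rscript analysis/02_spectrum.R        # VCF+FASTA -> SBS-96 spectra
Rscript analysis/03_refit.R           # NNLS refit, TMB, responsibilities
Rscript analysis/04_screen_classify.R # K-S/B-H screen + ZIENB LOOCV
Rscript analysis/05_survival_dca.R    # KM, Cox, decision curves
```

A run prints, among other lines:

```
simulated 101 patients, 20 signatures (SIG04, SIG17 informative)
extracted spectra for 5 patients (2631 variants): identical to the simulated counts
refit 101 patients x 20 signatures; 0 signature(s) excluded; relative L1 error vs planted activities: 0.257
per-variant responsibilities for 2631 variants; 87% have a dominant (>= 50%) signature
screened 20 signatures on 95 labelled patients; significant at q <= 0.05: none
reference screen on the latent class: significant: SIG04, SIG17
LOOCV on 95 labelled patients: ROC AUC 0.50 (95% CI 0.38-0.63), accuracy 0.57 at threshold 0.438
same posteriors against the latent class: ROC AUC 0.84 — the gap is label noise at the PFS cutoff, not classifier failure
```

Reading this: spectrum extraction is exact by construction (every
emitted variant's trinucleotide context realises its channel); the
refit recovers planted activities up to Poisson noise (~400 mutations
spread over 20 signatures is a noisy regime); and the screen against
the *latent* benefit class recovers exactly the two informative
signatures while the 26-week *derived* label — which keeps only about
half of benefit-class patients above the cutoff under an exponential
PFS model with hazard ratio 0.4 — dilutes the signal at this cohort
size. The methods vignette
(`vignettes/signature-benefit-methods.Rmd`) derives this attenuation
and states what the synthetic results do and do not show about real
cohorts.

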