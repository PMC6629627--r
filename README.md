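# optoflow

Quantitative characterization of light-controlled gene expression circuits
from flow cytometry, for synthetic biologists building and debugging
optogenetic systems (e.g. the green/red photoreversible CcaSR two-component
system ported into *Bacillus subtilis*).

The package implements the complete measurement-to-model workflow:

1. **Event-level processing** — density gating on forward/side scatter
   (retaining a fixed fraction, default 50%, of events by 2-D kernel
   density), conversion of arbitrary instrument units into standardized
   MEFL/MEAP units via multi-peak calibration beads, per-sample median
   summarization, and same-day autofluorescence subtraction.
2. **Replicate statistics** — one-sided one-sample t-test against zero for
   the "not detected" (N.D.) rule, Welch's unequal-variances two-sample
   test, and fold-change (dynamic range) summaries over day replicates.
3. **Steady-state transfer function** — the Hill form

   `y = y0 + Δy · xⁿ / (xⁿ + K½ⁿ)`

   relating input dose x (light intensity in µmol m⁻² s⁻¹, or an inducer
   concentration) to reporter output y (MEFL), fitted to pooled replicates
   by Levenberg–Marquardt on **log residuals**, `log y − log ŷ`, so that
   low and high fluorescence decades weigh equally.
4. **Step-response kinetics** — the delayed three-stage cascade

   `dp/dt = kp·(c − p)`,
   `dg/dt = kg·(p(t−τ) − g)`,
   `dG/dt = kd·(g − G)`

   for production rate p, immature reporter g, and mature observed
   reporter G, with units chosen so the drive c equals the steady-state
   output. Closed-form step solutions, an independent numeric DDE
   integrator, half-time (t½) extraction, and log-residual fitting with the
   rate-exchange symmetry reported explicitly.
5. **5′ structure recoding** — deterministic synonymous recoding of the
   first 15 codons (minimize GC, then maximize A, then T/U), with folding
   free energies of the transcription-start-site→ORF-nt-90 window from a
   built-in nested-pairing model or ViennaRNA's `RNAfold`.
6. **Synthetic data** — seeded generators for every pipeline input
   (event tables, bead samples, dose-response series, step timecourses)
   with known ground truth, so every stage is testable end to end.

## Worked example

Simulate a dose-response experiment from a known transfer function and fit
it back:

```r
library(optoflow)

truth <- hill_params(y0 = 2000, dy = 106700, n = 1.88, K = 4.66)
doses <- 10^seq(log10(0.1), log10(50), length.out = 8)
d <- gen_dose_response(dose_response_design(truth, doses,
                                            n_replicates = 3,
                                            replicate_cv = 0.1, seed = 42))
fit <- fit_hill(data.frame(x = d$dose, y = d$median_fluorescence))
fit
#> <fit_result>
#>   y0   1962.89 (se 142)
#>   dy   103677 (se 5.66e+03)
#>   n    1.71482 (se 0.0964)
#>   K    4.82194 (se 0.455)
#>   residual (sum sq log): 0.270191; converged after 10 iterations
```

The fitted Hill coefficient `n` and half-maximum dose `K` recover the
generating truth (1.88 and 4.66 µmol m⁻² s⁻¹) within the replicate noise;
`y0` and `y0 + dy` are the dark and saturating outputs in MEFL.

Kinetics, from the same boundary values:

```r
kin <- kinetic_params(kp = 0.02, kg = 0.05, kd = 0.03, tau = 15)
half_time(kin, 2000, 108700)
#> [1] 105.2252
```

i.e. after an instantaneous switch to saturating activating light the
mature reporter crosses the midpoint of its transition ~105 min later.

Recoding a GC-rich ORF head:

```r
r <- recode_report(utr = "TTATAAGGAGGAAAAA", orf = "ATGGGCGGCCTGGCCAAGTAA")
r
#> <recoded_orf: 21 nt, 5 substitution(s), window dG -24.00 -> -17.00 kcal/mol>
#>  index from  to
#>      2  GGC GGA
#>      3  GGC GGA
#>      4  CTG TTA
#>      5  GCC GCA
#>      6  AAG AAA
```

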