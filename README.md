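# mixtoxsys

Systems-level assessment of binary chemical mixture toxicity in aquatic
organisms, built for ecotoxicologists who need to go from raw endpoint
tables to an interaction verdict, a health grade and a transcriptomic
comparison in one reproducible workflow. The package grew out of the
classic mussel (*Mytilus galloprovincialis*) study design in which a heavy
metal and an organophosphate pesticide are tested singly and as an
equitoxic mixture across several levels of biological organisation.

## What it computes

**Dose–response and design.** Single-chemical endpoints are fitted with the
log-logistic model

y(c) = θ_min + (θ_max − θ_min) / (1 + (c/EC50)^β),

inverted in closed form to ECx = EC50 · (x/(100−x))^(1/β), and used to lay
out fixed equitoxic mixture designs in toxic units (for a binary mixture,
nominal 1.0 TU pairs the two EC25s, 0.5 TU the two EC12.5s).

**Mixture interaction testing.** Concentration-Addition (CA) and
Independent-Action (IA) reference surfaces are fitted jointly to axis and
mixture data; interaction is encoded by a deviation term G (G = a·z1·z2
for overall synergism/antagonism, with dose-ratio and dose-level
extensions) entering CA as Σ cᵢ/EC_{y,i} = e^G and IA as
y = θ_max (q₁q₂)^{e^{−G}}. Nested fits are compared with the Gaussian
likelihood-ratio statistic χ² = n·ln(SS_reduced/SS_full); a significant
positive â is antagonism, negative synergism.

**Toxicokinetics.** Depuration series are fitted to C_t = C₀·e^{−kt}
(log-linear by default), giving elimination constants and half-lives.

**Biomarker health grading.** Exposed vs control biomarkers are tested with
the exact Mann-Whitney U test, converted to alteration levels (AL0/1/2) by
severity thresholds, and folded into an A–E health status index by an
auditable, overridable rule table driven by the number of altered
biomarkers and the organisation level they span.

**Transcriptomic comparison.** DEG calling by the log-odds criterion B > 0,
exclusive-overlap accounting of three DEG lists with trend agreement,
microarray/qPCR concordance scoring, efficiency-corrected relative
expression with geometric reference normalisation and a reallocation
randomization test, and hypergeometric GO-term over-representation with
ancestor propagation and lowest-node summarisation.

Seeded generators (`gen_*`) emulate every input, so the whole pipeline is
testable without any external data.

## Worked example

```r
library(mixtoxsys)

# interaction testing on a synthetic antagonistic mixture (a = 3),
# 7 x 7 concentration grid, 5% response noise
truth <- surface_params(100, 1, 2, 2, 1.5, deviation_kind = "SA", a = 3)
d <- gen_mixture_grid(truth, "CA", c(0.25, 0.5, 1, 2, 4, 8),
                      c(0.5, 1, 2, 4, 8, 16), noise_sd = 5, seed = 7)
classify_interaction(d, "CA", n_starts = 2)
#> Mixture interaction assessment (CA framework, alpha = 0.05)
#>   Fit of CA:  R2 = 0.92, P = 9.14e-24
#>   CA vs A:    R2 = 0.98, chi2 = 64.8, P = 8.4e-16
#>   A vs DL:    R2 = 0.98, chi2 = 0.0189, P = 0.891
#>   verdict: antagonism (a_hat = 3.18)
```

The reference CA fit leaves structure unexplained (R² = 0.92); adding the
single deviation parameter is overwhelmingly supported (P ≈ 8e-16) with
â = 3.18 > 0 — antagonism, close to the generating a = 3 — and the
dose-level extension adds nothing (P = 0.89).

```r
# microarray / qPCR concordance on the bundled 12-gene comparison
concordance(qpcr_array_comparison())
#> # A tibble: 4 × 4
#>   condition matches total fraction
#>   <chr>       <int> <int>    <dbl>
#> 1 CHP            10    11     0.91
#> 2 Mix             9    11     0.82
#> 3 Ni              8    11     0.73
#> 4 overall        27    33     0.82
```

Per condition, `matches` counts genes where the two platforms agree
(both significant with the same direction, or both quiet); 27 of the 33
comparisons are concordant overall.

Fitted objects support `tidy()`, `glance()` and `autoplot()`; the whole
assessment can be driven from one YAML/list config via `run_assessment()`.

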