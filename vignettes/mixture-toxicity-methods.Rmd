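---
title: "Models and methods behind mixtoxsys"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind mixtoxsys}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mixtoxsys)
```

mixtoxsys implements a complete assessment chain for binary chemical
mixtures in aquatic ecotoxicology: single-chemical dose–response,
equitoxic mixture design, response-surface interaction testing,
toxicokinetics, biomarker integration into a health grade, and a
transcriptomic comparison layer. This vignette records the models, the
assumptions behind them, the tunable parameters, and the design choices
made where the methodology literature leaves the details open.

## Dose–response model and toxic units

Endpoints are modelled with the two-parameter log-logistic curve
$y(c) = \theta_{min} + (\theta_{max}-\theta_{min})/(1+(c/EC_{50})^\beta)$,
with the lower asymptote fixed at 0 by default because the supported
endpoints (lysosomal membrane stability, acetylcholinesterase activity)
are expressed as a percentage of control with a natural floor; a
`theta_min_free` flag frees it, which then requires a fourth distinct
concentration for identifiability. Errors are additive Gaussian on the
response scale, so the least-squares fit is the maximum-likelihood fit and
nested models can later be compared by likelihood ratio. Endpoints that
rise with dose (lipid accumulation, lysosome/cytoplasm ratio) use the
mirrored curve; effect levels are always fractions of the
$\theta_{max}\!\to\!\theta_{min}$ span, so the same ECx machinery serves
both directions.

Optimisation is deliberately boring: eight multi-starts (EC50 seeds spread
log-uniformly over the tested range crossed with slope seeds 0.5/1/2/4),
Nelder–Mead followed by a BFGS polish on $(\theta, \log EC_{50},
\log\beta)$. Exact recovery on noise-free inputs and scale equivariance
(doses scaled by $s$ scale the fitted EC50 by $s$) are enforced by tests.

Toxic units are linear in concentration, $TU = c/EC_{50}$. The *design*
convention, however, follows the classic equitoxic labelling in which a
k-component mixture at nominal level $T$ combines each chemical at its
EC$(50\,T/k)$ — a binary 1.0 TU mixture pairs the EC25s. The two
conventions agree only at 1 TU for a single chemical; we keep both because
the design convention is how such experiments are labelled in practice,
while the linear one is what the response-surface deviation algebra needs.
`design_equitoxic_mixture()` accepts either fitted models or an explicit
ECx lookup table, the table taking precedence so published endpoint tables
can be used verbatim.

## Response surfaces, deviation terms and the testing ladder

The Concentration-Addition (CA) reference treats the components as
dilutions of one another: the predicted response $y$ at doses $(c_1,c_2)$
solves $\sum_i c_i/EC_{y,i} = 1$ with
$EC_{y,i} = EC_{50,i}((\theta_{max}-y)/y)^{1/\beta_i}$. Independent
Action (IA) multiplies unaffected fractions:
$y = \theta_{max}\, q_1(c_1) q_2(c_2)$ with
$q_i = 1/(1+(c_i/EC_{50,i})^{\beta_i})$.

Interaction enters through a deviation function $G$ built from the
toxic-unit shares $z_i = (c_i/EC_{50,i})/TU_{tot}$:

* overall synergism/antagonism (SA): $G = a\,z_1 z_2$;
* dose-ratio dependent (DR): $G = (a + b\,z_1)\,z_1 z_2$;
* dose-level dependent (DL): $G = a\,z_1 z_2 (1 - b\,TU_{tot})$, which
  changes sign at $TU_{tot} = 1/b$.

$G$ deforms CA as $\sum_i c_i/EC_{y,i} = e^G$ and IA as
$y = \theta_{max}(q_1 q_2)^{e^{-G}}$. These closed forms were chosen to
satisfy every property the framework promises — $G=0$ recovers the
reference, both surfaces collapse to the single-chemical curves on the
axes (the shares $z_i$ vanish there), $a>0$ lifts the whole interior
surface (less toxicity, antagonism) and $a<0$ depresses it — while staying
cheap to evaluate; bit-level parity with any particular spreadsheet
implementation of the same ideas is not claimed. The CA root is found by
monotone bisection on $\log(y/(\theta_{max}-y))$, vectorised over points,
with a bracket of $\pm 60$ log-units and 42 halvings (resolution far below
the $10^{-8}\theta_{max}$ documented tolerance); tests compare it against
an exhaustive grid-scan oracle at $10^{-6}$.

Fitting pools axis and mixture rows and estimates
$(\theta_{max}, EC_{50,1}, \beta_1, EC_{50,2}, \beta_2)$ plus the
deviation parameters jointly by least squares. Starting values come from
logit-linearised regressions on the two axes; deviation fits are
warm-started from their parent, which (together with the optimiser never
returning a value worse than its start) guarantees the nesting
$SS_{ref} \ge SS_{SA} \ge SS_{DL}$ that the likelihood-ratio ladder
requires. Each nested comparison uses the Gaussian profiled-variance
statistic $\chi^2 = n\ln(SS_{reduced}/SS_{full})$ on $\Delta k$ degrees of
freedom. The ladder runs reference → SA → DL, mirroring how such results
are reported; the DR form is implemented but not part of the default
ladder. The "fit of reference" p-value is the F-test of the fitted
surface against the grand-mean model — the natural reading of a
regression-significance row, since the null hypothesis behind it is not
otherwise pinned down. The default significance level is $\alpha = 0.05$
everywhere, always overridable.

### Simulation sizes and calibration

The inference tests use a 7×7 factorial grid (n = 49: controls, both
single-chemical axes, 36 interior points), $\theta_{max} = 100$ and
Gaussian noise of 5 units (5% of the control response) — a realistic
histochemical-endpoint noise level. Type-I error of the reference-vs-SA
test is checked over 200 null replicates (observed ≈ 0.065 for a nominal
0.05, the mild liberality expected of the asymptotic statistic at n = 49),
and power against $a = 3$ over 100 replicates (essentially 1). These
problem sizes keep the whole simulation suite to a few minutes while
leaving the binomial bands tight enough to catch calibration regressions.

## Toxicokinetics

Depuration follows first-order elimination $C_t = C_0 e^{-kt}$. The
default fit regresses $\ln C_t$ on $t$ — closed form, exactly
time-unit-equivariant, and maximum likelihood under multiplicative
lognormal noise, which is also the noise model the generator injects
(chemical concentrations are positive and typically heteroscedastic on
the raw scale). A raw-scale nonlinear fit is available since the fitting
scale is a genuine choice; both agree to $10^{-6}$ on clean data.
Constant series return $k = 0$ with an explicit no-elimination flag
rather than an error, and non-positive fitted $k$ is flagged but
returned. Half-life is $\ln 2 / k$, defined only for $k > 0$.

## Biomarker integration and the health status index

Each biomarker is compared with its control by the exact two-sided
Mann-Whitney U test (the exact distribution whenever the data are
tie-free; mid-rank normal approximation with continuity correction
otherwise — at n = 10 per group the two differ by less than 0.01).
Significant changes become alteration levels: AL1, escalating to AL2 when
the median fractional change in the biomarker's harmful direction reaches
its severity threshold. Thresholds are biomarker-specific and
configurable; the defaults are a 50% labilization-time reduction for LMS
(the guide biomarker) and a 100% change elsewhere — deliberately
conservative, since published threshold sets vary between laboratories.

The A–E grade is produced by an ordered rule table over summary features
of the panel (counts of AL1/AL2, organisation levels spanned, the guide
biomarker's level). The default table encodes the two drivers such expert
systems name — how many biomarkers are altered and how high up the
biological organisation they reach — as five first-match rules (see
`default_rule_table()`). Every predicate is monotone in the alteration
levels, so worsening any single biomarker can never improve the grade; a
10,000-panel property test enforces this together with determinism.
Custom tables are validated for parseability and exhaustiveness (the last
rule must be a catch-all). Because replicate-level data behind published
health-grade figures are generally not printed, the package's guarantees
here are rule-consistency guarantees, not reproductions of any particular
study's grades.

One caveat worth stating: with four biomarkers tested at $\alpha = 0.05$,
a fully unstressed panel has probability $(1-0.043)^4 \approx 0.84$ of
grading A (0.043 being the achieved level of the exact test at n = 10), so
occasional B grades under the null are expected behaviour of the
thresholded design, not a bug.

## Transcriptomic comparison layer

DEGs are genes with log-odds $B > 0$; the trend is the sign of the log2
ratio M, and called genes with $M = 0$ are an error by default (droppable
by option) since they carry no usable trend. Overlap accounting of three
lists uses *exclusive* pairwise intersections (shared by exactly two
lists), which is the only convention under which unique + pairwise +
triple partitions each list; trend agreement is tallied within each
exclusive pair, and a focal condition's "unique including opposite" adds
its opposite-trend shared genes to its unique ones — both counted as
functionally original responses. Percentages use the focal list as
denominator for focal rows and the union otherwise.

Microarray/qPCR concordance calls a gene consistent when both platforms
agree positively (array called with $B>0$, qPCR significant, same
direction) or both are quiet ($B \le 0$, qPCR not significant); rows
without array data are excluded from the totals. This reconstructed rule
reproduces all four published match statistics of the bundled comparison
table (8, 10, 9; 27/33), which is the reason it was adopted; it is a
reconstruction, not a quoted formula.

Relative expression is efficiency-corrected,
$R = E_t^{\Delta Ct_t} / \mathrm{geomean}_r(E_r^{\Delta Ct_r})$ with
$\Delta Ct$ = control mean − exposed mean, geometrically normalised over
the reference genes; with all efficiencies 2 it reduces exactly to the
2^(−ΔΔCt) method. Significance uses a fixed-reallocation randomization
test: replicates are reallocated between groups, exhaustively when at
most 10,000 reallocations exist, otherwise by seeded Monte Carlo with the
+1 correction.

GO enrichment is the one-sided hypergeometric tail on ancestor-propagated
annotations (the true-path rule makes parent counts dominate child
counts). Raw p-values against $\alpha$ are the default because that is
how such scans are conventionally reported; Benjamini-Hochberg is
available and recommended when the term list is long.
Under-representation sits behind a flag. Only `is_a` edges are read from
OBO input; `part_of` is ignored. Lowest-node summarisation returns the
significant antichain — terms with no significant descendant.

## Synthetic data: what it does and does not show

The generators emulate the statistical structure each analysis assumes:
log-logistic curves with additive Gaussian noise, fixed-ray or factorial
mixture surfaces with injected deviation parameters, exponential
elimination with multiplicative lognormal noise, Gaussian biomarker
panels with prescribed fractional shifts, DEG triples whose overlap/trend
structure is reproduced as exact set identities, and layered random GO
DAGs with one term spiked at a chosen odds ratio. Every generator draws
from a private seeded stream (the caller's RNG state is untouched) and
records its parameters in a `provenance` attribute, enabling closed-loop
recovery tests.

What passing these tests shows is that the estimators and decision rules
recover the truth under their own assumptions at realistic noise levels.
What they cannot show: robustness to real-data pathologies the generators
do not model — hormesis, non-Gaussian heavy-tailed endpoint noise,
probe-level redundancy in microarrays (several probes per gene, which is
the likely reason published union counts of DEG lists do not always add
up), correlated replicates within exposure vessels, or annotation bias in
GO assignments.

## Numerical choices and degenerate inputs

* CA bisection: bracket ±60 on the log-odds scale, 42 halvings, bracket
  failure raises a classed numerical error with diagnostics.
* Surface optimisation: BFGS with simplex fallback per start, final BFGS
  polish; degenerate parameter regions (non-positive or non-finite EC50/β
  after back-transform) score as +∞ rather than erroring mid-optimisation.
* LR statistics are clipped at zero so optimiser noise on the boundary
  cannot produce negative χ².
* All-equal responses, missing controls, too-few concentrations,
  non-positive concentrations in log-space fits, zero control medians and
  infeasible overlap requests raise classed validation errors early.
* Exact Mann-Whitney switches to the corrected normal approximation when
  ties make the exact distribution inapplicable, with a message.

## Known limitations

Two-component mixtures only; no hormesis or biphasic dose–response; no
uptake-phase toxicokinetics (the model covers depuration only); the rule
table ships with declared defaults rather than any laboratory's exact
thresholds; GO parsing covers the `is_a` subset of OBO; and the
randomization test treats replicates as exchangeable units, which assumes
no vessel-level structure.
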