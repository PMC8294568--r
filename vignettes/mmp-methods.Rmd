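---
title: "Methods: microbial metabolic phenotyping and the SCFA absorption model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: microbial metabolic phenotyping and the SCFA absorption model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mmpkit)
```

# The measurement and its phenotype

An ex vivo fermentation assay measures what a person's gut microbiota
does with a defined fiber input: homogenized stool slurry is spiked with
inulin, pectin or cellulose (or nothing, as control), incubated
anaerobically, and sampled in duplicate wells at 0, 2 and 4 h for GC-FID
quantification of acetate, propionate and butyrate (mM). Production is
linear over this window, so the rate for one donor, fiber and SCFA is a
two-point slope on replicate-averaged concentrations,

$$\hat\varphi = \frac{C(4) - C(2)}{2} - \frac{C_{\mathrm{ctrl}}(4) - C_{\mathrm{ctrl}}(2)}{2} \quad [\mathrm{mM/h}],$$

with the matched no-spike-in control slope subtracted (cellulose behaves
like control: it is essentially unfermented on this timescale). Net rates
may be negative and are kept so; downstream z-scoring assumes the full
real line. A least-squares slope over all window timepoints is available
(`production_rates(..., method = "least_squares")`) for sensitivity
analysis; replicates are averaged before the slope, which for the
balanced two-point case is identical to averaging per-replicate slopes.

The donors × (fiber:SCFA) matrix of net rates, z-scored per column across
the cohort (sample sd, $n-1$), is the donor's **microbial metabolic
phenotype (MMP)**. Z-scores put the six fiber:SCFA combinations — which
live on different natural scales — on one scale, at the cost of making
every statement cohort-relative.

## Typing, binarization, stability

*Types.* Donor profiles are clustered with UPGMA (average linkage). The
default distance is $1 - r$ (Pearson correlation between profile rows)
rather than Euclidean, and this was a deliberate reversal of an initial
Euclidean design: donors vary strongly in overall fermentation magnitude,
and on z-scored rows that magnitude dominates Euclidean distances, so a
$k = 2$ cut tends to isolate the single most active donor instead of
splitting the phenotype types. Correlation distance compares profile
*shape* — which fiber:SCFA combinations a donor is strong in — and
recovers planted types robustly. Euclidean (or any `stats::dist` metric)
remains one argument away. The cluster count is user-chosen (default
`k = 2`, matching a Type I / Type II reading of the phenotype map); no
automatic model selection is attempted.

*High/low.* A donor is a high producer for a column when $z \ge 0$; the
boundary is deliberately inclusive. For a cohort of two the z-scores are
$\pm 1/\sqrt 2$, forcing one high and one low.

*Stability.* Two visits are compared by binarizing both MMPs and pooling
all donor × column cells into a 2×2 contingency table (rows: visit-1
class; columns: visit-2 class), tested with an exact two-tailed Fisher
test using the point-probability rule (sum of probabilities of all
margin-fixed tables no more probable than the observed one). Two caveats
are worth knowing. First, the cells pooled into the table are *not*
independent — a donor's six columns share type and overall activity — so
the exact test is mildly anti-conservative on such data; the package's
calibration tests therefore use homogeneous synthetic cohorts in which
cells really are independent. Second, exact-test p-values are discrete;
on small cohorts the null distribution of $p$ is visibly lumpy.

# Community composition and prediction

OTU tables follow the fixed downstream order **filter → rarefy →
normalize → (collapse) → classify**: samples under 5,000 reads are
dropped (a sample at exactly 5,000 is kept), rarefaction subsamples
without replacement to the lowest remaining depth under a fixed seed
(`vegan::rrarefy`), total-count normalization produces relative
abundances, and features may be collapsed at any of the seven ranks,
pooling OTUs unassigned at that rank into one feature per parent lineage
(an unassigned-genus Lachnospiraceae OTU stays distinct from named
Lachnospiraceae genera). Alpha diversity is Shannon entropy in natural
log; beta diversity is the Jensen–Shannon *distance* (square root of the
base-2 divergence), bounded by 1 — both base conventions are choices, and
are recorded in output metadata. Classification uses total-normalized
(not rarefied) abundances by default, with a flag to switch.

The high/low classifier is a random forest per stratified fold (default
5 folds, 500 trees, $\lfloor\sqrt p\rfloor$ features per split), with the
per-fold ROC of held-out predictions interpolated onto a common 101-point
false-positive-rate grid and vertically averaged; importances are mean
decrease in Gini, normalized to sum to one and averaged over folds. Every
stage is seeded, so reports are byte-identical across reruns. With ~40
samples a fold's test set is small; folds whose test set lacks a class
are dropped with a warning rather than contributing undefined ROCs.

# The in vivo absorption model

Once produced in the colonic lumen, an SCFA is either absorbed by the
epithelium or excreted. The model keeps exactly the two processes the
data constrain: constant microbial production $\varphi$ (mM/h) and
first-order epithelial absorption at an effective rate $k$ (1/h) over one
transit $\tau$ (h),

$$\frac{dC}{dt} = \varphi - kC, \qquad C(0) = c_0,$$

with closed-form solution $C(t) = \varphi/k + (c_0 - \varphi/k)e^{-kt}$.
Over one transit, per litre of colonic volume: produced $= \varphi\tau$,
absorbed $= \int_0^\tau kC\,dt = \varphi\tau - C(\tau) + c_0$, excreted
$= C(\tau)$, and for $c_0 = 0$ the absorbed fraction is

$$f(k\tau) = 1 - \frac{1 - e^{-k\tau}}{k\tau},$$

which is independent of $\varphi$, strictly increasing in $k\tau$, and
spans 0 to 1. The model is linear in $\varphi$, so donor rankings of
absorbed quantity equal rankings of production rate and are invariant to
the choice of absorption constant — the basis for per-donor predictions
from an MMP rate matrix under the assumption that absorption physiology
is identical across donors.

*Units of the absorption constant.* Published constants are printed in
mmol L⁻¹ h⁻¹ cm⁻², which is not dimensionally a first-order rate: the
surface-to-volume factor and unit conversion needed to close the
dimensions are not published alongside. The default `identity_rate` mode
therefore applies the printed numeric value directly as an effective rate
in h⁻¹ — the one simple reading under which the CaCo-monolayer constant
(0.091) at $\tau = 12$ h yields an absorbed fraction of ~0.39 while the
dialysis-bag constant (0.0019) leaves the large majority excreted, i.e.
the two qualitative regimes the constants are known to produce. A
`surface_scaled` mode ($k = \gamma S/V \cdot u$, defaults $V = 2$ L,
$S = 2000$ cm², both implementation defaults, not measured values) is
provided for sensitivity analysis. Because the mmol outputs need a
volume, a 2 L default colonic volume is used throughout; the absorbed
*fraction* does not depend on it.

*Substrate depletion.* `two_phase_outcome()` stops production at a
depletion time $t_1 < \tau$ and lets the remaining pool decay by
absorption only; it reduces exactly to the single-phase model when
$t_1 \ge \tau$. When transit outlasts substrate, excreted concentration
decays in $\tau - t_1$ — stool SCFA content then reflects transit history
more than production capacity, which is the regime in which stool
measurements are least informative.

*Numerics.* All closed forms are evaluated with `expm1` so small $k t$
loses no precision (a series branch would be equivalent; one code path is
simpler), and the constructor enforces the mass balance
produced $+ V c_0 =$ absorbed $+$ excreted to $10^{-9}$ relative on every
outcome. The test suite checks every closed form against an independent
step-halving RK4 integrator; agreement is asserted at $10^{-8}$ relative
to the transited mass, because at $k \sim 10^{-9}$ the absorbed quantity
itself sits at the double-precision cancellation floor.

# The synthetic cohort: what it emulates, and what it does not

The generator (`cohort_config()`, `generate_cohort()`) produces the
complete study inputs under one root seed with named substreams (rates,
noise, otus, depths), so any stage can be regenerated independently and
reruns are byte-identical.

**Rates.** Two fiber-specialist types in equal proportion: each type
ferments its preferred fiber into all three SCFAs well above the cohort
base rates (acetate 1.5, propionate 1.1, butyrate 0.9 mM/h) and the
opposite fiber near zero, with between-donor sd 0.7 mM/h and truncation
at zero — so for a given fiber:SCFA pair roughly half the cohort are
non-producers, matching the strongly bimodal producer/non-producer
contrasts seen in real phenotype maps. Signature-column separation
exceeds 2 between-donor sd. A per-donor lognormal "overall activity"
factor (sdlog 0.5) multiplies all of a donor's rates, emulating
microbial-load heterogeneity between stools. Control rates are small
(0.15 ± 0.08 mM/h, activity-scaled); baseline concentrations 1 ± 0.3 mM.

**Replicate noise.** Duplicate wells are separate cultures, so the
dominant replicate error is modelled as a per-well lognormal scale factor
shared along the well's whole trajectory (all timepoints and SCFAs
measured from that well), with the log-sd solved analytically so that the
expected pair coefficient of variation equals the 23.5% target
(`pair_cv_sigma()`). This structure matters: the same 23.5% applied as
independent noise per measurement would put roughly half a rate-unit of
noise on every two-point slope and no phenotype would be recoverable —
whereas a trajectory-level factor largely cancels in the within-well
slope, which is the only reading consistent with both the observed
replicate scatter and the observed reproducibility of phenotypes. A
well's factor also scales its 0 h sample, so replicate scatter is uniform
across timepoints.

**Under these conditions** (40 donors, duplicate wells at 0/2/4 h, 23.5%
CV), recovered rates correlate with planted truth at $r \approx 0.95$ to
$0.97$ for typical seeds (the across-seed minimum is nearer 0.91 — the
residual well-factor noise on the slope is irreducible at this CV), the
$k = 2$ UPGMA cut recovers type labels at Rand $\ge 0.9$, and visit
persistence $\rho = 0.9$ gives overwhelming stability significance. At
$\rho = 0$ the visit-2 phenotype (type membership included) is redrawn
independently.

**OTU tables.** One baseline community per donor: 150 OTUs with lognormal
mean abundances (sdlog 2), donor-level log-abundance noise (sd 1),
multinomial counts at lognormal depths (~20,000 reads, sdlog 0.5) with a
2.5% shallow-sample fraction (500–4,999 reads) for exercising the depth
filter. Phenotype–composition coupling has three layers, all shifted in
donors whose *true* linked rate is in the high ($z \ge 0$) class: two
abundant lead producer OTUs (a *Prevotella copri*-like OTU for
inulin→propionate and an unassigned-genus Lachnospiraceae OTU for
inulin→butyrate, both +2 donor-sd), two accessory guild members each
(+1 sd), and a broad community signature (4 enriched, 4 depleted taxa at
±0.7 sd) — phenotypes in real cohorts track community-wide structure, and
a forest trained on a single informative OTU among 149 noise features at
$n = 40$ underperforms the signal its importance ranking finds. The shift
is conditioned on the z-class rather than the median so that the planted
between-class effect keeps its stated size under skewed rate
distributions (the two splits disagree for several donors otherwise).

**What passing recovery tests do and do not show.** The generator shares
the real assay's structure but is idealized: linear kinetics by
construction, exactly two types, no pH drift, no compositional
correlation between background OTUs, no batch effects, and labels that
derive from the same draw as the features. Recovery therefore validates
the *pipeline machinery* — that estimators invert the generative process
at realistic noise — not any claim about classifier performance on real
cohorts, which depends on raw-data properties this generator does not
attempt (the study's printed AUCs require its deposited reads and exact
OTU clustering).

# Problem sizes and runtimes

The shipped tests use cohorts of 4–40 donors for unit checks, 100 donors
for the replicate-CV Monte-Carlo (3,600 well pairs), 200 donors for the
persistence concordance check, 400 for the shallow-fraction rate, 200
independent 80-donor homogeneous cohorts for the null calibration of the
stability test (80 donors keep the exact test's discrete p-value support
fine enough for a Kolmogorov–Smirnov comparison with the uniform), 1,000
random parameter draws for the mass-balance property, and full
enumeration of all 135,751 2×2 tables with total ≤ 40 for the Fisher
cross-check. The complete suite runs in under two minutes on one core.

# Known limitations

- Everything phenotype-level is cohort-relative (z-scores, high/low,
  types); absolute comparisons across cohorts need the raw mM/h matrix.
- The absorption model is zero-dimensional: no spatial structure, no
  pH-dependence, no cross-feeding between the acetate pool and
  butyrate/propionate production, and the unit interpretation of
  published absorption constants is a documented convention, so absolute
  mmol predictions are order-of-magnitude; relative donor comparisons
  are exact under the model's linearity.
- The pooled stability contingency treats correlated cells as
  independent; its p-values are meaningful for strong effects but mildly
  anti-conservative near the null.
- Fisher, rarefaction and forest behavior are validated against
  independent oracles (`fisher.test`, hypergeometric expectations,
  `pROC`), but the classifier's hyperparameters (500 trees,
  $\sqrt p$ mtry) are fixed conventions, not tuned values.
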