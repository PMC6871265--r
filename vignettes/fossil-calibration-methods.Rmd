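---
title: "Fossil calibration methods in fossilbracket"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fossil calibration methods in fossilbracket}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fossilbracket)
```

This vignette is the package's own account of the statistics it implements:
the models and their assumptions, the parameters that matter, what the
simulator does and does not emulate, and the numerical and design choices
made where the design was genuinely open. It states no empirical result
that the test suite or `scripts/acceptance.R` does not itself compute.

## The three-part problem

A fossil-based divergence-time bracket has three components. The oldest
fossil reliably assigned to a lineage (its FAD) gives a minimum. The gap
between the FAD and the true origin of the lineage's first fossilizable
apomorphy (ΔT~Gap~) must be estimated statistically from the richness of
the record. Finally, the divergence itself predates the first apomorphy by
a lag (ΔT~Div−1stApo~) that fossils cannot observe directly, since older
members of the lineage are not recognizable; at best it can be bounded by
an average species duration. The package keeps the three strictly
separate: `min_constraint` for minima, the CI/prior/taphonomic/super-taxon
machinery for ΔT~Gap~, and `apomorphy_lag_bound` for the final widening.

Conventions: ages are in Ma before present, increasing into the past;
reporting precision is one decimal Ma.

## Stratigraphic confidence intervals

### Model and assumptions

For an extant lineage known from $n$ distinct fossil horizons, assume
fossilization and recovery are stochastically constant over the lineage's
history, so the $n$ find ages are uniform on $(0, T)$ with $T$ the true
origin. Then $FAD/T$ is the maximum of $n$ uniforms and

$$T_C = FAD\,(1-C)^{-1/n}$$

is an exact one-sided bound: $P(T \le T_C) = C$. For an extinct lineage
one conditions on the last occurrence; the gaps between successive
horizons are then jointly Dirichlet rather than independent exponentials,
and the bound uses the observed range $R = FAD - LAD$ with one fewer
degree of freedom:

$$T_C = R\left[(1-C)^{-1/(n-1)} - 1\right] + FAD.$$

Both coverages are verified by `coverage_experiment` (10,000 replicates at
$C \in \{0.5, 0.8, 0.95\}$ in the acceptance suite). The basis is chosen
automatically from the record's extant flag and can be overridden.

The unbiased point estimate adds the mean gap ($FAD/n$ or $R/(n-1)$); the
finite-sample ML correction $FAD\,(n+1)/n$ coincides with the extant form.

### What counts as $n$

The exponent counts *distinct fossiliferous horizons*. The package counts
distinct `horizon_id` values, falling back to distinct `locality_id` where
horizons are not recorded. Where two nearby collections stop being
"distinct" is a field judgment the data model cannot make; the rule is a
convention, stated here, and duplicated horizon rows never inflate $n$.

### Dating envelopes

Fossil ages arrive as intervals (e.g. a FAD dated somewhere between 6.5
and 7.5 Ma). Point formulas evaluate at the interval midpoint by default;
every record-level operation also reports an *envelope* evaluated at both
dating endpoints, because for poorly dated FADs the dating uncertainty can
rival the statistical one. The hard minimum uses the *younger* endpoint —
a minimum constraint must not overstate itself.

### Transformed axes

Where the rock record has major temporal gaps or condensed intervals, time
is the wrong axis: recovery is closer to uniform per meter of suitable
rock than per Myr. `ci_transformed` computes the interval on a monotone
piecewise-linear age↔axis map (built from dated horizons, or supplied),
and maps the bound back to Ma, extrapolating linearly beyond the mapped
span with the terminal segment's slope. Ages spanned by little axis length
(gaps, condensed sections) therefore stretch the bound in Ma — the
mechanism by which a thickness-based interval can double a time-based soft
maximum. A non-monotone map is an error; the identity map reproduces the
untransformed interval exactly (tested).

### Nonuniform recovery

`ci_nonuniform` generalizes the extant-basis interval to a supplied
piecewise-constant relative recovery curve $r(t)$ with cumulative
potential $G(t) = \int_0^t r$. Transforming ages by $G$ makes find
positions uniform, so the bound solves

$$(G(FAD)/G(T))^n = 1 - C,$$

found by `uniroot` on $[FAD, t_{\max}]$ to 1e-9 Ma (the equation is
monotone, so bracketing on the curve's support suffices; the closed-form
piecewise inverse of $G$ is used only in the simulator's oracle-free
sampling, keeping the check and the implementation on separate routes).
With a constant curve this reduces to the classical bound to 1e-9
(tested). If the curve carries too little potential older than the FAD for
a root to exist below $t_{\max}$, the result is reported as *unbounded at
this confidence* rather than as an error — that is a finding about the
data, not a failure. For extinct lineages the record is first mapped to
the $G$ axis, where recovery is uniform and the range-basis formula
applies; this reduction reproduces the classical bounds in the uniform
limit, which is the only anchor available since no closed form exists for
the general extinct case.

## The lognormal gap prior

Node-dating needs the frequentist statement as a density. The package
parameterizes a lognormal on the gap ΔT~Gap~ (in Ma older than the FAD) by
two conditions: mode $= FAD/n$ (the corrected ML estimate) and 95% point
at $FAD \cdot 0.05^{-1/n}$. Writing $\sigma$ for the lognormal sd-log,
these force

$$\sigma = -\tfrac{z}{2} + \tfrac12\sqrt{z^2 + 4(\ln 20/n + \ln n)},
\qquad \mu = \ln(FAD) - \ln(n) + \sigma^2,$$

with $z = z_{0.95}$. Two deliberate choices:

- **Full-precision constants.** The defining identities (mode to 1e-9
  relative, CDF at the 95% point to 1e-6) only hold with $z =
  $ `qnorm(0.95)` and $\ln 20$ carried at double precision; four-digit
  printed versions of the same constants (0.8224, 2.7055, 2.9957) shift
  $\sigma^2$ in the fourth decimal. The identities are the contract, so
  the constants are exact.
- **The variable is the gap, not an absolute age.** The mode $FAD/n$ is a
  gap; the absolute soft maximum is $FAD + q_{0.95}$. The export states
  this offset convention in the file itself, because the off-by-FAD misuse
  is otherwise easy. A consequence worth knowing: the 95% *gap* equals the
  whole frequentist *bound* $FAD \cdot 0.05^{-1/n}$, so the absolute
  Bayesian bound exceeds the frequentist one — by a factor approaching 2
  at large $n$, under 1.5 for sparse records ($n \lesssim 4$). This is a
  property of the parameterization as defined and is documented rather
  than "fixed".

## Taphonomic controls, outgroup FADs, assembly

`taphonomic_max` requires controls from the focal region by default
(geographic incompleteness is the main failure mode), supports an optional
environment filter and a minimum number of qualifying horizons $k$
(default 1; control co-occurrence is never perfect, so $k$ is policy, not
statistics). It returns two bounds: the base of the *youngest* control
interval older than the FAD (the "reasonable" soft maximum) and the base
of the *oldest* (a stricter, more certain bracket) — the two ends of the
judgment a control-group argument supports. `outgroup_fad_max` is the
informal successive-outgroup rule: pure pass-through with validation.
`assemble_bracket` collects all candidates per node, never averages,
selects the least restrictive by default (overridable, logged), and treats
a minimum above the selected maximum as a hard data-inconsistency error.
No automatic cross-validation across nodes is performed — sequential
single-calibration checks are biased young, so only report-style listings
are produced.

## The super-taxon method

Multiple FADs constrain a clade's root age jointly. With an uncalibrated
ultrametric tree, a fossil on a branch whose subtending node sits at
relative depth $d$ (tips 0, root 1) implies root age $\ge FAD/d$; the $N$
implied positions are treated as $N$ horizons of a single root-to-present
super-lineage, the oldest playing the FAD role, and the extant-basis
interval applied with $n = N$. Choices: fossils attach to the *stem* of
their lineage (subtending node depth) by default — the conservative
reading; crown attachment is available for labeled internal nodes but
undefined for tips. Uniform recovery along the super-taxon axis is
assumed. Only relative depths enter, so the bracket is invariant to tree
rescaling (tested), and on a star tree the method collapses to the plain
interval on the raw FADs (tested). The leave-one-out screen flags a
projection whose implied root age exceeds the 95% bound computed from the
other $N-1$ — a convention (configurable $C$), requiring $N \ge 3$.

## The clade simulator

`simulate_clade` grows a clade by continuous-time budding birth–death
(Gillespie) from one founder, conditioned on survival by rejection (retry
cap 10,000, attempts logged). Time is in species durations: extinction
terminates a morphospecies, so with $\mu = 1$ one unit is one mean
duration. Fossil sampling is per species (one find, uniform within the
duration) or a per-lineage-time Poisson rate; an optional recovery curve
thins finds by relative potential at their age.

The expanding-clade experiment (`martin_experiment`) reproduces the
classic scenario: growth over 16 durations to ~48 extant species (~380
total, ~330 extinct), then a random 3% of *extinct* species sampled. With
time in durations $\mu = 1$ is forced, leaving $\lambda$ the single free
rate; it is calibrated analytically so the survival-conditioned mean
extant count $e^{rt}/(1-p_0(t))$ equals 48 ($\lambda \approx 1.107$), an
explicit logged step. The conditional mean total then lands near 380 with
no further freedom, and both achieved means are checked at ±10% after
simulation (failure is an error reporting the achieved means). The 3%
sample is per extinct species (matching "a sample of the extinct
species"), not per occurrence. Under this stated world the mean gap
between clade base and oldest sampled fossil is several species durations
and the record misses roughly the first third of the clade's range — the
acceptance suite measures both at 500 replicates.

What the simulator does *not* emulate: geographic structure, correlated
(non-independent) preservation between related species, time-varying
rates, and morphospecies-recognition error. A green coverage test
therefore establishes that the formulas are correct *under their own
model*, not that real records are uniform samplers — which is exactly why
`declining_recovery_demo` exists: with a 10-fold recovery drop older than
66 Ma and a true origin at 100 Ma, the nominal 95% bound covers well under
92% of the time, while `ci_nonuniform` with the true curve restores
nominal coverage (exactly, under the model — the $G$ transform
re-uniformizes the finds; unbounded results count as covering).

## Numerical choices and degenerate inputs

- Root-finding tolerance 1e-9 Ma (`uniroot`); ultrametricity tolerance
  1e-9 relative tip-depth spread after normalization; tip depths snapped
  to exactly 0.
- $C = 0$ returns the FAD (zero-confidence identity); $C \ge 1$ is an
  error (unbounded); extinct basis requires $n \ge 2$.
- Equal implied root ages in the super-taxon sort deterministically by
  lineage label.
- Empty occurrence files parse to empty tables; a lineage with no
  apomorphy-documented occurrence yields an explicit no-minimum result,
  never a silent fallback.
- Survivorship conditioning failures (10,000 consecutive extinctions) are
  errors, as is a calibration check outside ±10%.

## Known limitations

- Weibull/flexible-beta endpoint extrapolation and H-bar preservation
  variants of the super-taxon method are out of scope; so are geochronology
  computations (ages arrive as intervals) and any bundled geologic
  timescale (epoch boundary ages are user-supplied).
- The thickness example from the literature cannot be reproduced
  numerically (formation thicknesses unpublished); the transformed-axis
  tests are exact on constructed stacks and directional on realistic ones.
- The lognormal prior's absolute 95% bound deliberately exceeds the
  frequentist bound (see above); users wanting the frequentist gap should
  use `ci_record` directly.
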