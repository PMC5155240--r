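---
title: "A point-scale carbon-nitrogen model with nitrogen saturation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A point-scale carbon-nitrogen model with nitrogen saturation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nsatcn)
```

## Scope and design

`nsatcn` implements a deliberately reduced terrestrial carbon–nitrogen
model whose single scientific focus is the **nitrogen-saturation
mechanism**: what happens to NPP, allocation, decomposition and NEP when
nitrogen deposition persistently exceeds an ecosystem's empirical
critical load. It is a point-scale annual model with five carbon pools
(leaf, wood, root, litter, SOC) and three nitrogen pools (soil mineral,
soil organic, plant). Everything a full land-surface model would add —
sub-daily photosynthesis, canopy physics, soil moisture dynamics,
vegetation competition — is intentionally absent; the package's claims
concern the saturation modifiers, the critical-load machinery, the
three-stage protocol and the factorial scenario design, all of which are
exercised end-to-end on synthetic forcing.

## The nitrogen-control modifiers

Three multiplicative modifiers couple soil mineral nitrogen $N_M$
(g N m$^{-2}$) to the carbon cycle: $K_P$ scales plant biomass
construction, $K_1$ soil nitrogen immobilization, and $K_M$ soil organic
matter mineralization.

In **legacy** mode (nitrogen limitation only) each modifier rises
linearly from `k0` (default 0.1) at $N_M = 0$ to 1 at the 2 g N m$^{-2}$
ceiling and is fixed at 1 above it — additional nitrogen beyond that
point neither helps nor harms.

In **saturation** mode the same rising limb applies, the modifier equals
exactly 1 at the saturation threshold $N_{MS}$, declines linearly beyond
it, and reaches a floor at the maximum available mineral nitrogen
$N_{Mmax}$, staying there for any larger pool:

$$
K(N_M) \;=\;
\begin{cases}
k_0 + (1-k_0)\,N_M/r, & N_M \le r \\
1, & r < N_M \le N_{MS} \\
1 - (1-K_{\min})\dfrac{N_M - N_{MS}}{N_{Mmax}-N_{MS}}, & N_{MS} < N_M < N_{Mmax} \\
K_{\min}, & N_M \ge N_{Mmax}
\end{cases}
\qquad r = \min(2, N_{MS}).
$$

The exact closed forms of the published modifier equations are rendered
as figures in the source material available to us, so the piecewise
linear family above was adopted: it satisfies every stated constraint
(continuity, unit value at onset, parameterized floors, monotone decline,
agreement with the legacy curves below the ceiling whenever
$N_{MS} \ge 2$). The floors carry the empirical parameterization:

| modifier | floor | meaning |
|---|---|---|
| $K_P$ | 0.824 | maximum 17.6 % NPP reduction at full saturation |
| $K_M$ | 0.85  | maximum 15 % reduction of SOC decomposition |
| $K_1$ | 0.85  | immobilization floor, mirroring $K_M$ (the literature parameterizes production and decomposition but not immobilization separately) |

Because realized NPP is `npp_potential * K_P` and every respired
decomposition term is linear in $K_M$, the floors map *exactly* onto the
17.6 % and 15 % reductions — this is asserted by the test suite with
paired single-year runs. For thresholds below the legacy ceiling
($N_{MS} < 2$, which does not occur with default parameters) the rising
limb is compressed so the curve still peaks at onset; the
legacy/saturation agreement property then holds only below $N_{MS}$.

Allocation shifts with the **saturation degree**
$s = \mathrm{clamp}\!\big((N_M - N_{MS})/(N_{Mmax}-N_{MS}),\,0,\,1\big)$:
base fractions are multiplied by $1 + s\,(m_i - 1)$ with endpoint
multipliers $m = (1.10, 1.25, 0.65)$ for leaf, wood, root, then
renormalized so the three fluxes sum to NPP exactly. $N_{Mmax}$ defaults
to $2\,N_{MS}$ (`n_mmax_factor`), a choice the source material leaves
open.

## Deriving the saturation threshold from critical loads

The package ships the empirical critical-load table (15 vegetation types
× USA/China/Europe/rest-of-world, g N m$^{-2}$ yr$^{-1}$) with its fill
rules: the rest-of-world column is the arithmetic mean of the row's
available regional values, rounded to two decimals. Four published
cells deviate from that rule — the shrubland rows print 0.69 where the
mean is 0.695, and the desert/polar rows print 1 where the mean of
(0, 1, 0) is 0.33. The shipped table keeps the published values and
flags them with provenance `"published"`; `fill_other_region()`
implements the pure averaging rule for users who prefer it.
`classify_saturation()` uses strict exceedance: deposition exactly at
the load is *not* saturation (reading "in excess of" literally).

$N_{MS}$ itself is model-internal: deposition is pinned at the site's
critical load, all three modifiers at 1, and the coupled model is run to
equilibrium (relative change of every pool below $10^{-6}$ per year);
the equilibrium mineral pool is the threshold. At such an equilibrium
uptake balances litterfall nitrogen and mineralization balances inputs,
so deposition is balanced by leaching alone and
$N_{MS} \approx CL / k_{leach}$ — with the default leaching rate
0.03 yr$^{-1}$, thresholds of roughly 30–50 g N m$^{-2}$. These pool
magnitudes are larger than field-measured mineral nitrogen; they are
internally consistent model units (the same model generates both the
threshold and the trajectories compared against it), not predictions of
soil chemistry. The derivation is monotone non-decreasing in the load,
and re-simulating from the derived equilibrium holds the pool within 1 %
over 50 years (both tested).

## Carbon core

Potential NPP responds to climate and CO₂ as
$NPP_{pot} = NPP_{ref}\, e^{k_T (T - T_{ref})}\,
\frac{P/(P+P_{1/2})}{P_{ref}/(P_{ref}+P_{1/2})}\,
\big(1 + \beta \ln (C/C_{ref})\big)$, normalized so the reference
climate (15 °C, 1000 mm, 296 ppm) returns `npp_ref`; $\beta = 0.5$ is a
standard beta-factor magnitude. Litterfall is first-order (leaf 1,
root 0.5, wood 0.05 yr$^{-1}$); litter and SOC decay are first-order
with Q10 temperature and saturating moisture scalars; a fraction 0.3 of
decomposed litter is humified into SOC and the rest respired.
Mineralization releases nitrogen in proportion to respired organic
carbon at the organic pool's current N:C ratio (which keeps the organic
nitrogen pool self-consistent instead of drifting against a fixed
stoichiometry); immobilization is the nitrogen demand of humification
(humified C over the SOC C:N of 12) scaled by $K_1$. Plant uptake demand
comes from new-tissue C:N ratios (leaf 30, wood 150, root 60) and is
limited to 95 % of the currently available mineral pool; leaching is
first-order in mineral nitrogen. Carbon is conserved to machine
precision every step ($\Delta C_{tot} = NPP - R_h$), nitrogen changes by
deposition minus leaching exactly (absent clipping, which is logged);
both are property-tested over thousands of random states.

## Numerical scheme

The carbon pools step annually, but the mineral-nitrogen pool is fast
and its controls are steep: stepped annually, the
uptake–modifier–mineral-N loop has gain above one on the rising limb of
$K_P$ and settles into a spurious period-2 oscillation. The mineral
pool, the three modifiers, uptake and leaching are therefore integrated
on a **monthly substep** inside the annual carbon step, holding the
carbon and organic-nitrogen pools at their start-of-year values; the
reported annual modifiers are substep means. This stabilizes the
feedback (per-substep gain well below one) while keeping every respired
term linear in $K_M$.

Spin-up runs under a repeating climatology until $|NEP| < 0.05$
g C m$^{-2}$ yr$^{-1}$ for ten consecutive years *and* pools are
near-stationary (relative change $< 10^{-4}$; NEP alone can dip through
zero far from equilibrium). Because the slow SOC–organic-N modes give
the spin-up multi-millennial tails, `run_to_equilibrium()` uses
semi-analytic acceleration: at a fixed schedule of early years the slow
pools are jumped to the steady state implied by the current fluxes
(pool = input / effective rate), after which ordinary integration
resumes; the jumps leave the fixed point unchanged and convergence is
only declared from ordinary years. Acceleration is disabled for the
strict pools-criterion equilibrium used in threshold derivation, which
converges quickly unaided. Iteration cost is about a millisecond per
model year; the full eight-site, six-scenario protocol (spin-up shared
across scenarios) completes in a few minutes on one CPU, and the test
suite sizes its sweeps accordingly (e.g. eight random starts for the
fixed-point property, 100 seeds for the profile-shape contracts).

## Synthetic forcing and what it does (not) represent

The forcing generator emulates the *structure* of historical gridded
inputs, not their values: monthly temperature built from a sinusoidal
seasonal cycle plus AR(1) interannual anomalies (SD 0.6 °C, lag-1
correlation 0.3) and a +0.02 °C yr$^{-1}$ trend after 1970; lognormal
monthly precipitation around a mild summer maximum; bounded cloud
fraction, wet days, wind and humidity; a CO₂ ramp from a 296 ppm
plateau to ~387 ppm in 2009; and four deposition archetypes — a US
temperate-forest plateau (1.8 g N m$^{-2}$ yr$^{-1}$, always above its
0.9 load), a European hump peaking mid-1980s and ending below the 1.5
load, an accelerating Asian-grassland rise (0.8 to ~4 by 2009, built
from non-negative increments so it is non-decreasing for every seed),
and a flat 0.1 background. One master seed fans out to per-site,
per-variable substreams, so adding sites never perturbs existing ones.
Deposition profiles are annual; the historical inputs they stand in for
are monthly.

The default `paperlike` ensemble (eight sites, two per archetype, equal
areas) was chosen, together with the pool turnover and leaching rates
(wood 0.05 yr$^{-1}$, SOC 0.05 yr$^{-1}$, leaching 0.03 yr$^{-1}$), so
that the saturation regimes the archetypes represent actually emerge
within the 1851–2009 protocol: the US forest reaches the $K_P$ floor by
~1990, the European forest saturates mildly and recovers by 2009, the
Asian grassland crosses its threshold in the 2000s, and the boreal site
stays nitrogen-limited throughout while its mineral nitrogen declines
under rising CO₂. Slower (more realistic) wood and SOC turnover pushes
the saturation transition beyond the simulated period: real
ecosystems integrate deposition over centuries, and a reduced annual
model that must develop, saturate and recover within 160 years needs
compressed successional timescales. Consequently, passing tests
demonstrate internal consistency and correct mechanism signs — not
calibrated magnitudes for any real site. Global-scale quantities (Pg C
totals) are out of scope by construction; ensemble results are
area-weighted means over a handful of synthetic sites.

## The experiment design

`run_protocol()` implements the three stages: (1) spin-up under the
climatological year with deposition at the 0.05 g N m$^{-2}$ yr$^{-1}$
baseline; (2) 1901–1969 with transient climate and CO₂ but deposition
held at its 1970 value; (3) 1970–2009 fully dynamic. The six scenarios
differ only in stage 3 (and, for NNS, in the modifier pinning rule):
NCC is fully dynamic; NNC, CNC, TNC and PNC hold deposition, CO₂,
temperature or precipitation at 1970 — frozen climate drivers repeat the
single 1970 monthly cycle; NNS pins all three modifiers to 1 in exactly
those site-years whose deposition exceeds the critical load, in any
transient stage (stage 2 uses 1970 deposition, so its pinning status is
constant). Because pinning is the only difference, NCC and NNS are
bit-identical at sites that never exceed their load — a tested
guarantee. Contributions are reported as dynamic-minus-frozen
differences (NNS − NCC for saturation) with interannual SDs and
percentages of the dynamic run's 1970–2009 mean.

On the default ensemble the deposition contribution to NPP is slightly
negative: the ensemble is dominated by saturated sites where extra
deposition harms production. A deposition-limited ensemble (e.g. all
`background` sites with loads above deposition) shows the familiar
positive fertilization instead; the sign is a property of the site
composition, not of the mechanism.

## Degenerate inputs, ties, tolerances

* Deposition exactly at the critical load: not saturated (strict `>`).
* A zero critical load (desert rows): the derived threshold is the
  near-zero drained equilibrium; building a `modifier_curve` requires a
  strictly positive threshold, so desert sites are not usable as
  saturation sites (none of the shipped archetypes are deserts).
* Negative pools cannot arise: annual fractional losses are capped at
  0.95, uptake at 95 % of availability, and any residual clip is logged
  on the step result rather than silently absorbed.
* Climatology accepts any non-empty window (its contract mentions ten
  years as the sensible minimum for a climatology, but short windows are
  permitted and used in tests).
* Equilibrium failure is an error carrying the final residual, never a
  silent partial result.

## Known limitations

* No explicit nitrification/denitrification, gaseous losses, fixation,
  or isotopes; leaching is a single first-order term.
* Annual carbon dynamics with monthly climate aggregated to annual
  drivers; no water balance (precipitation acts through a static
  scalar).
* The saturation threshold and mineral-nitrogen trajectories are in
  model-internal units an order of magnitude above field values (see
  above); comparisons are only meaningful within the model.
* The compressed successional timescales trade realism for a saturation
  signal observable within the simulation period.
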