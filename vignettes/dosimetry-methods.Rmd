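---
title: "Methods: mouse dosimetry and therapy planning for a Lu-177 antibody"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mouse dosimetry and therapy planning for a Lu-177 antibody}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Radioimmunotherapy delivers a beta-emitting radionuclide to tumour cells via
an antibody. Before treating animals (or patients), one wants to know the
absorbed dose each organ will receive per unit of administered activity, and
to invert the dose-limiting organ's tolerance into a prescribed activity.
`mousedose` implements that chain for a Lu-177-labelled anti-hK2 antibody in
prostate-cancer (LNCaP) xenografted mice:

1. **Biokinetics** — fit bi-exponential time–activity curves to
   decay-corrected %IA/g data and integrate them to cumulated activities.
2. **Phantom** — build a voxelised mouse whose organ sizes match the
   measured organ masses.
3. **Transport** — estimate S-factors $S(r_T \leftarrow r_S)$ (Gy per
   disintegration) by Monte Carlo.
4. **MIRD** — combine cumulated activities and S-factors into organ mean
   doses, $D(r_T) = \sum_{r_S} \tilde{A}(r_S)\, S(r_T \leftarrow r_S)$.
5. **Planning** — prescribe the administered activity from a red-marrow
   dose limit.
6. **Efficacy** — caliper tumour volumes, humane endpoints, Kaplan–Meier
   survival.

A synthetic-data module generates biodistribution and therapy-cohort inputs
with the statistical structure the analysis assumes, so the whole chain is
testable without animal data.

# Biokinetics

The model for a source region's decay-corrected activity is
$A(t) = A_1 e^{-\lambda_1 t} + A_2 e^{-\lambda_2 t}$ (time in hours,
amplitudes in %IA or %IA/g). Physical decay is *not* refit from the data:
the measured counts are decay-corrected, so the physical factor
$e^{-\lambda_{phys} t}$ enters analytically inside the cumulated-activity
integral,

$$\tilde{A} = \int_0^\infty A(t)\, e^{-\lambda_{phys} t}\, dt
 = \frac{A_1}{\lambda_1 + \lambda_{phys}} + \frac{A_2}{\lambda_2 + \lambda_{phys}}.$$

Design choices that were genuinely open:

* **One negative amplitude is allowed.** An antibody tumour curve rises to a
  late maximum (here: higher uptake at 168 h than at 72 h); a plain
  two-exponential with positive amplitudes can only fall. Non-negativity is
  therefore enforced on the *model value* over $[0, 2 t_{max}]$ (to a
  numerical tolerance of $10^{-4}$ of the curve maximum), not on the
  amplitudes.
* **Deterministic multi-start.** Rate pairs are initialised on a fixed
  log-spaced grid ($10^{-4}$–$1\ h^{-1}$, plus 0); amplitudes are solved by
  linear least squares at each pair; the best eight starts are polished with
  Levenberg–Marquardt. Ties are broken by lowest residual norm, then lowest
  fast rate. If every polished optimum violates the admissibility
  constraints (convergent integral, non-negative model), the raw grid
  candidates are considered, and finally a penalised refit keeps the
  optimiser in the admissible set. This makes the fit a pure function of the
  data.
* **Units are explicit.** Curves carry `per_gram` or `per_organ`; per-gram
  cumulated activities require a region mass before conversion to absolute
  disintegrations ($1\ \mathrm{MBq\,h} = 3.6\times10^9$ decays). The
  red-marrow curve is never measured: it is 0.36 × blood concentration, the
  standard marrow/blood partition for an intact antibody.

Degenerate inputs are errors, not guesses: fewer than four distinct time
points, all-zero curves, a per-organ curve fed to the marrow rule, or rate
combinations that make the integral diverge.

# Decay data

The shipped Lu-177 data (CSV resources, replaceable via file paths) use a
half-life of 6.647 d, a 1-keV-binned beta spectrum assembled from three
allowed-shape branches (endpoints ≈176, 249, 498 keV) with a
non-relativistic Coulomb correction, and six photon lines dominated by
112.95 keV (6.2 %) and 208.37 keV (10.4 %). Sub-5-keV conversion and Auger
electrons are folded into the unit beta yield rather than modelled as
separate lines. Sampling is inverse-CDF with uniform smearing inside a bin,
and demands an explicit seed — an unseeded draw is an error because it
could not be reproduced.

# The voxel phantom

Only three geometric facts about the dosimetry model are fixed by the study
design: organ *sizes* follow the measured masses, the flank tumour is a
1:2:2 ellipsoid with its short axis perpendicular to the skin attached
outside the body contour, and the submandibular gland is a sphere sized
from its mass. The original deformable-anatomy mouse is not redistributable,
so organs are modelled as non-overlapping geometric primitives (spheres,
ellipsoids, a dorsal skeleton rod containing a coaxial red-marrow core)
placed at literature-informed positions inside a prolate-ellipsoid body
(polar/equatorial ratio 3.2, volume set by the body weight at
1.0 g/cm³ water-equivalent density — no tissue densities being available,
water equivalence is the standard simplification).

Voxelisation is deterministic. Each primitive claims only unassigned
body voxels, which guarantees no overlap; its linear scale is calibrated by
a short secant iteration so the achieved voxel mass lands within tolerance
(default 5 %) of the target. The thin skeleton/marrow rods get a dedicated
two-step calibration (radius, then slab count against the actual claimable
voxels) because per-slab voxel counts are integers and the body contour
tapers along the rod. An organ that cannot reach its mass at the requested
resolution raises an error suggesting a finer voxel size.

The production grid is 160 × 160 × 440; the analysis scripts and tests use
80 × 80 × 220 at 0.5 mm voxels, which builds in under a second and keeps
every organ mass within a few percent of target. Coordinates: x right
(tumour side), y ventral→dorsal, z tail→head, 0-based indices in the
export convention (flat int32 binary + JSON sidecar).

# Monte Carlo transport

The S-factor engine is analog (no variance reduction, so the estimator is
unbiased and directly testable), stratified so every source region receives
exactly its quota of histories, with uncertainties from 10 equal batches.
The physics is deliberately simplified relative to a general-purpose code,
and the simplifications are the package's declared modelling choices:

* **Electrons**: energy sampled from the tabulated spectrum, emitted
  isotropically, deposited *linearly along a straight track* of CSDA range
  in water (tabulated range–energy relation, log-log interpolated). The
  justification is scale: Lu-177 beta ranges (≲2 mm) span only one or two
  voxels, so angular scattering detail is second-order for *organ-mean*
  doses. The equilibrium limit (a region much larger than the range must
  absorb the full mean beta energy per decay) is verified in the tests to
  2 %.
* **Photons**: discrete lines, Woodcock (delta) tracking with water
  attenuation, photoelectric absorption and incoherent Compton scattering
  (Klein–Nishina sampled by Kahn's rejection method; the recoil electron is
  absorbed locally). Photons below the 10 keV cutoff (configurable within
  1–100 keV) deposit locally. Coherent scattering and bremsstrahlung are
  neglected — both are percent-level at these energies in water.
* **Materials**: every labelled voxel is water at the configured density;
  label 0 (air outside the animal) neither attenuates photons nor consumes
  electron range.

Consequences to keep in mind: absolute cross-organ photon doses inherit the
accuracy of the embedded water cross-section table, and condensed-history
effects (electron straggling, secondary electrons) are absent. The engine
is therefore validated by physics invariants — energy conservation,
$1/\sqrt{N}$ uncertainty scaling, attenuation bounds, reciprocity
$m_T S(T \leftarrow S) \approx m_S S(S \leftarrow T)$ in uniform media —
rather than by coefficient-level agreement with any external code, which is
not claimed. For analyses that need published coefficients, the S-matrix
CSV import path and the bundled reference coefficient table bypass the
simulation entirely.

The analysis runs 2 × 10⁴ histories per source on the reduced grid (13
sources, a few seconds); the equilibrium check uses 10⁵ histories. These
sizes were chosen so the statistical uncertainty on self-doses is well
below a percent while the full suite stays quick to iterate.

# MIRD doses and planning

Organ dose coefficients are the cumulated-activity-weighted sums of
S-factors; the self-dose keeps only the diagonal term, so self ≤ total
holds for every organ by construction. Absolute doses are linear in
administered activity; reported tables round coefficients to two decimals
and absolute doses to two significant figures (raw doubles are retained).
"Blood" is a source/target compartment with a configurable mass
(default 1.8 g), not a phantom organ; in the simulated route its decays are
assigned to the remainder-tissue vasculature.

Planning inverts the limiting organ's tolerance:
$A_{presc} = D_{limit} / k_{total}$ with the red marrow at 12 Gy as the
default (the commonly adopted murine marrow tolerance; it is a
configuration constant, not a computed quantity). With the reference marrow
coefficient 0.45 Gy/MBq this gives 26.7 MBq, reported as ≈27 MBq; quoting
downstream doses at the rounded integer activity (27 × 4.9 = 132.3 →
132 Gy to the tumour) matches the convention of the emulated study, and the
exact value — at which the marrow receives the limit exactly — is retained
alongside.

# Efficacy

Tumour volume uses the rotated-ellipsoid caliper formula
$V = \tfrac12 w^2 l$. The humane endpoint is *strict*: weight below 80 % of
the day-0 baseline or largest diameter above 15 mm; exact boundary values do
not trigger, following the wording "exceeding". Survival uses the
product-limit estimator (`survival::survfit`; an independent hand-rolled
product-limit oracle cross-checks it in the tests), with the median read
off the curve as the earliest time with $S(t) \le 0.5$ and reported as
undefined when the curve never reaches one half within the 120 d follow-up
— the convention used when too few animals reach the endpoint. Group
volume-change summaries average only animals still on study at each day
(the attrition convention is flagged in the output, since the emulated
study does not state its own).

# The synthetic-data generator

`generate_tacs()` draws per-animal %IA/g values around mean bi-exponential
curves with multiplicative log-normal noise (CV 20 % by default, matching
the reported inter-animal spread; truncated at ±3σ; unit mean, so group
means match the model). The LNCaP tumour curve is solved at run time to
pass exactly through 22 %IA/g at 72 h and 30 %IA/g at 168 h with fixed
uptake/clearance rates (0.01 and 0.002 h⁻¹), peaking after one week; the
hK2-negative and antigen-blocked models scale to 4.9 and 8.3 %IA/g at 72 h.
Organs not quantified ex vivo (heart 6.7, liver 8.9, submandibular
14 %IA/g at one week) follow imaging-ROI estimates. Marrow is 0.36 × blood
per animal, by construction.

`generate_cohort()` is invented plumbing — the emulated study specifies
outcomes, not a generative model — and lives only in this module. Untreated
tumours grow exponentially at 0.06 d⁻¹ (doubling ≈11.6 d) from a 150 mm³
baseline, which places control endpoint crossings (diameter > 15 mm, i.e.
≈1688 mm³ at $w=l$) near day 40, inside the 35–45 d control-median band.
Treated tumours shrink at 0.002 d⁻¹ per Gy of tumour dose for 0.35 d per Gy
(capped at 60 d), then relapse and regrow at the control rate with a
dose-dependent probability: certain below 60 Gy, 40 % between 60 and
150 Gy (the reported mid-dose relapse fraction), never above. Group
activities are drawn around the nominal 10/19/36 MBq (plus labelled-IgG,
saline and cold-antibody controls) and converted to tumour dose through the
4.9 Gy/MBq coefficient. Caliper readings get log-normal noise (CV 10 %)
and width/length are ordered so width ≤ length.

What passing tests on these data do **not** show: real biodistributions are
not exactly bi-exponential, real inter-animal variation is not exactly
log-normal, real tumour regrowth is not a clean exponential with a
Bernoulli relapse, and measurement schedules in practice are irregular.
The generator demonstrates that the *pipeline* recovers what it assumes;
it cannot validate the biological model itself.

# Numerical conventions

* Time is hours in kinetics, days in efficacy; activities MBq; doses Gy;
  energies keV inside the transport engine (1 keV in 1 g = 1.602 × 10⁻¹³ Gy).
* Every stochastic entry point (`generate_*`, `sample_beta_energy`,
  `simulate_s_factors`, `run_pipeline`) requires an explicit integer seed
  and is bit-reproducible given one; seeded helpers save and restore the
  caller's RNG state.
* Closed-form cumulated activity agrees with adaptive quadrature to 10⁻⁶
  relative (tested on 100 random integrable parameter sets).
* Component ordering in fits: fast rate first; a negligible amplitude
  (≤10⁻⁷ of the larger) is zeroed together with its rate.

# Known limitations

* The phantom is anatomically schematic; inter-organ distances (hence
  cross-organ S-factors) are plausible, not animal-specific.
* Homogeneous water: no lung density, no cortical bone, so marrow and bone
  doses lack the spectral hardening a heterogeneous model would show.
* Electron transport ignores scattering detail; do not use the engine for
  voxel-level dose maps (organ means only, as designed).
* The therapy-dynamics module is calibrated to qualitative outcomes and is
  not a tumour-control model; no dose-rate or fractionation effects.
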