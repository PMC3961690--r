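---
title: "Ionization equilibria of the thioredoxin-fold active site: models, fitting, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ionization equilibria of the thioredoxin-fold active site}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trxpka)
```

## The scientific problem

Thioredoxin-fold proteins catalyse thiol–disulfide exchange through a
-CXXC- motif whose N-terminal cysteine attacks as a thiolate. The rate and
direction of catalysis therefore hinge on that cysteine's pK~a~, which
ranges from ~3.5 in the oxidase DsbA to 10.6 in the reductant-transfer
domain cDsbD. This tuning is not a property of the cysteine pair alone: a
buried acidic residue on strand β1 (six positions before the cysteine), an
acid in helix α1, and a distal residue on strand β2 able to stabilize the
buried carboxylate together form an *extended* active-site motif. When the
buried acid is stabilized (hydrogen bond from a glutamine, or a salt bridge
from a lysine), it ionizes early and its negative charge pushes the
cysteine pK~a~ up. When that stabilization is removed, the acid's pK~a~
rises until the two ionizations merge into *microscopic* pK~a~ behaviour:
within the protein population, either residue may ionize first, and each
molecule's second ionization is harder than its first.

`trxpka` implements this analysis chain: closed-form titration models, a
four-microstate coupled-site model, per-resonance least-squares fitting
with aggregation, replicate activity statistics, motif
extraction/classification, and generators for synthetic data with known
ground truth.

## Titration models

In fast exchange an NMR resonance's position is the population-weighted
average over protonation states, so a single ionization gives

$$\delta(\mathrm{pH}) = \frac{\delta_{HA} + \delta_{A}\,10^{\mathrm{pH}-pK_a}}
{1 + 10^{\mathrm{pH}-pK_a}},$$

a sigmoid with midpoint at the pK~a~ and plateaus at the limiting shifts,
and two ionizations give the analogous double sigmoid over
$1 + 10^{\mathrm{pH}-pK_{a1}} + 10^{2\mathrm{pH}-pK_{a1}-pK_{a2}}$. These
are the standard base-10 Henderson–Hasselbalch chemical-shift forms; they
reproduce all the qualitative behaviour titration studies of this family
describe (a ~2.5 ppm downfield ^13^C^β^ shift upon thiolate formation,
double sigmoids with two almost equal steps for coupled sites). pH is
treated as an opaque axis: values are meter readings and no solvent
isotope correction is ever applied, matching how such titrations are
reported.

Numerically, every $10^x$ is evaluated after subtracting the largest
exponent in the sum (and the one-pKa curve through the deprotonated
fraction $1/(1+10^{-x})$), so curves are finite for $|\mathrm{pH}-pK_a|$
of hundreds of units.

## The coupled two-site model

Two interacting titratable groups A and B have four microstates (HH, AH,
HB, AB) and four microscopic constants, constrained by thermodynamic cycle
closure $pK_A + pK_{B|A} = pK_B + pK_{A|B}$ (the constructor accepts three
and derives the fourth, or validates closure to 10^-9^). Populations come
from the partition function

$$Z = 1 + \frac{K_A + K_B}{[\mathrm{H}^+]} +
\frac{K_A K_{B|A}}{[\mathrm{H}^+]^2},$$

and the macroscopic constants are $K_{a1} = K_A + K_B$ and
$K_{a2} = K_A K_{B|A}/(K_A+K_B)$.

A key identity — used as the module's core oracle in the test suite — is
that the marginal deprotonation curve of one site equals the two-pKa
closed form evaluated with the macroscopic constants and an intermediate
plateau of $K_B/(K_A+K_B)$:

```{r}
m <- symmetric_coupled_model(7.6, 10.4)
macroscopic_from_microscopic(m)
```

For a symmetric model the macroscopic values sit exactly $\log_{10} 2$
outside the microscopic pair (the statistical factor: two equivalent
protons can leave first, and two equivalent sites can accept the last
proton), and the site curve shows two steps of exactly equal height.

**Reporting convention for coupled fits.** Fitting an observed double
sigmoid with the two-pKa closed form estimates the *macroscopic*
constants. Titration studies of symmetric coupled sites, however, quote
the shared *microscopic* pair. The package therefore provides
`microscopic_from_macroscopic()`, the exact inverse under the symmetry
assumption, and the coupled-recovery analyses report microscopic values
obtained through it. This is a deliberate design choice: without the
symmetry assumption two macroscopic constants cannot determine four
microscopic ones, and a double sigmoid with two almost equal steps is
precisely the symmetric signature.

## Fitting and aggregation

Per-resonance fits are unweighted nonlinear least squares (no per-point
uncertainties are available for this kind of data) by Levenberg–Marquardt,
with multi-start initialization because double sigmoids have local minima:
pKa starts on the grid 4–12 (all ordered pairs of 4, 6, 8, 10, 12 for the
two-pKa model, separation at least 0.5 at start), limiting shifts from the
first/last observed points, the intermediate plateau from the mid-range
value. The two-pKa model is parameterized as $(pK_{a1}, \Delta)$ with
$\Delta = pK_{a2}-pK_{a1} \ge 0$, which enforces ordering structurally.
The intermediate plateau is fitted freely rather than constrained, since
nothing in the observable fixes it a priori.

Safeguards:

* an amplitude floor (default 0.1 ppm, well above the 0.05 ppm noise
  scale) turns flat series into an explicit "no titration detected" error
  rather than a garbage fit;
* non-convergence from every start is an explicit failure, never a silent
  best-effort value;
* a fitted pKa outside the observed pH window ± 1 unit is flagged
  `extrapolated`;
* two-pKa fits are flagged `nonidentifiable` when a transition collapses
  (separation < 0.25, or a step amplitude not clearly above the residual
  noise level, 3σ̂) or when fixing either pKa 0.5 units off its optimum
  and refitting the rest barely changes the residual sum of squares
  (relative tolerance 1%).

Per-fit uncertainties are asymptotic standard errors from the
Gauss–Newton Hessian at the optimum, but the headline uncertainty is the
cross-resonance sample standard deviation: `aggregate_pka()` averages the
per-resonance pKa values for one residue and reports "mean ± SD (n)",
which is the reporting convention for this kind of study. Aggregation
refuses to mix one- and two-pKa fits under a single transition label, and
pairs transitions across resonances by sorted order (lower with lower).

Model selection between the nested one- and two-pKa fits uses the
extra-sum-of-squares F-test at α = 0.05 by default. The choice of test and
level is a package decision (studies typically choose per curve by fit
quality); both fits are always returned for audit, and the limiting
behaviours (α = 1 always rich, α → 0 always simple) are tested.

## Replicate activity statistics

For gel-densitometry activity assays the package computes, per construct
and dataset: the replicate mean, sample SD (n − 1), and percentage
standard error $100\,(\sigma_{n-1}/\sqrt{n})/\mathrm{mean}$; the variant's
activity as a percentage of wild type; and cross-dataset averages. The
uncertainty on a per-dataset relative activity is propagated in quadrature
from the *relative sample SDs* of the two replicate sets, and the
uncertainty on the average of $n$ datasets is $\sqrt{\sum u_i^2}/n$. Among
the candidate conventions (SEs instead of SDs, SEM of the per-dataset
percentages), this is the only one that reproduces every printed
uncertainty of the reference activity table from its raw readings (±11,
±7, ±7, ±9, ±4 per dataset and ±5, ±5 on the averages), which is why it
was adopted. Internal values are never rounded; display strings round
half-away-from-zero to integers, matching the published formatting. The
raw readings themselves ship with the package (`dsbd_activity_readings()`)
and the whole table is recomputed, never stored.

## Motif analysis

`find_cxxc()` reports every position with cysteines three apart, overlaps
included. `extract_extended_site()` reads the extended-motif slots
relative to the N-terminal cysteine (offset 0): the β1 acid at −6, the XX
residues, the α1 acid at +7 by default (+6 for CcmG-like spacing), and the
distal β2 partner. The partner cannot sit at a fixed offset across
families (+25 in thioredoxin, +27 in cDsbD), so the default is a
first-match scan over offsets +20 to +35 for residues able to stabilize an
anion (Q, N, K, R, H), with an explicit offset override for curated
alignments — a sequence-only tool cannot reproduce a manual
structure-guided alignment, and the window scan is the honest sequence
approximation. Out-of-bounds slots are marked missing and excluded from
conservation denominators (reported separately), never silently dropped.
Burial is accepted only as a user annotation; computing accessibility
requires structures and is out of scope.

Classification is a deterministic cascade over the slots only: a β1 acid
stabilized by Q/N gives the stabilized-acid (elevated cysteine pK~a~)
class; by K/R the coupled-microscopic (bidirectional) class; an
unpartnered β1 acid the unstabilized-acid (helix-dipole-dominated, low
cysteine pK~a~) class; no β1 acid the near-physiological
(reductant-provision-like) class. Prolines or glycines between the
cysteines append a thiolate-stabilizing-XX modifier. Records that fit no
rule (missing −6 slot, histidine partner) return "unclassified" — the
function is total. Conservation percentages are reported as exact
quotients (e.g. 380/494 = 76.9%) rather than rounded headline figures.

## Synthetic data

No raw titration or gel data are deposited with studies of this kind, so
the generators define the study conditions and every quantitative claim
about recovery is made against them:

* **Titrations**: pH ladder 4–13 (step 0.5 for single transitions, 0.25
  for double sigmoids, mirroring the denser sampling such curves need),
  per-resonance amplitudes drawn from stated ranges (0.5–2.5 ppm
  generally; 1.8–3.0 ppm for the large thiolate shifts; 2.7 ppm total for
  the coupled-site observable), Gaussian noise with SD 0.05 ppm — small
  against the ~2.5 ppm amplitudes, as in the real spectra where fitted
  curves pass essentially through the points. Coupled-site observables are
  linear in each site's deprotonation fraction.
* **Densitometry**: lognormal readings (positivity guaranteed) with CV
  0.07 by default, matching the few-percent spreads of the reference
  table; a truncated-normal alternative is available.
* **Sequences**: background-random over the 19 non-cysteine residues with
  the motif and slot residues planted per frequency tables (defaults: D at
  −6, E at +7, partner Q/R/K at 380/72/42 out of 494). The scanned partner
  window is kept clear of partner-class residues upstream of the planted
  one so extraction recovers the layout exactly.

Every generator is a pure function of its spec including the seed, and
echoes its ground truth. What passing recovery tests show is that the
estimation chain is correct and well calibrated *under these conditions*;
they do not exercise real-data pathologies such as resonance overlap,
exchange broadening near the pK~a~, baseline drift, non-Gaussian
densitometry error, or genuinely asymmetric coupled sites.

## Problem sizes and numerical choices

The test suite and acceptance analyses use: 7/5/6 resonances for the three
pKa-recovery cases (matching the resonance counts behind the reference
estimates), 200 noise replicates for Monte-Carlo bias/SD bounds, 100
random coupled models for the microstate oracle (tolerance 10^-9^ over pH
0–14 at step 0.05), 50 random noiseless datasets for identifiability at
10^-5^, and a 494-sequence simulated family with binomial 95% bounds on
slot frequencies. Cycle closure is validated to 10^-9^, microstate
normalization to 10^-12^. Ties in pH are allowed (repeated measurements);
series are sorted on construction.

## Known limitations

* The coupled-to-microscopic conversion assumes site symmetry; genuinely
  asymmetric coupled sites would need both sites' observables fitted
  jointly, which the package does not do (per-resonance fits plus
  aggregation only, by design).
* The F-test assumes i.i.d. Gaussian residuals; with correlated residuals
  its size is approximate. It is a default, not a substitute for
  inspecting both fits.
* The distal-partner window scan is a sequence-only heuristic; curated
  alignment columns should be supplied where available.
* Asymptotic standard errors understate uncertainty for poorly separated
  double sigmoids; the non-identifiability flag, not the standard error,
  is the signal to distrust such fits.
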