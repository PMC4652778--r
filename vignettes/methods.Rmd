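---
title: "Free-energy surfaces for Watson-Crick to Hoogsteen base-pair switching: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the coordinates

A purine in a Watson-Crick (WC) pair can rotate about its glycosidic bond
into the *syn* conformation and pair in the Hoogsteen (HG) geometry. Two
collective variables describe the switch:

* **chi**, the glycosidic dihedral O4'-C1'-N9-C4 of the flipping purine.
  The *anti* (WC) range is [-180, -90) and the *syn* (HG) range [-90, 90];
  the conventional printed *syn* interval is closed at -90, so that boundary
  is classified *syn*. The residual arc (90, 180) is labelled *other*.
* **CPDb**, a pseudodihedral of four centres of mass: the heavy atoms of the
  base pairs flanking the target pair (P1), the two backbone phosphate
  groups bracketing the flipping residue (P2, P3), and the five-membered
  ring of the purine (P4). CPDb measures base flipping; positive values
  point into the major groove, negative into the minor groove.

All angles use one canonical wrapped representation, [-180, 180), with the
antiperiplanar arrangement stored as -180. This avoids a double
representation of the same physical angle in histograms.

Two conventions in the CPDb definition are not fully determined by its
verbal description and are fixed here as package conventions. First, the
membership of P1 is taken as every heavy atom of the two flanking base
pairs (for the A16 target of the A-tract duplex: A17-T8 above and C15-G10
below); `pseudoatom_spec()` makes any other choice configurable. Second,
the sign of a dihedral flips when its middle points are exchanged, so the
groove sign depends on the P2/P3 ordering; the package fixes P2 as the
phosphate of the target residue (5' side) and P3 as that of its 3'
neighbour, and the tests pin the chirality behaviour (mirror-imaging a
frame negates CPDb). Without a deposited duplex structure to calibrate
against, the groove-sign assignment is a documented convention rather than
a verified fact about any particular crystal frame.

## The bias model

Umbrella windows live on a rectangular grid: 13 CPDb centres spanning
[-100, 100] degrees inclusive, and 24 chi centres spaced 360/24 = 15
degrees starting at -180 (the chi axis is periodic, so both endpoints are
one wrapped point and 24 windows cover the circle without duplication) —
312 windows in all. The bias at window (i, j) is the quadratic

U(CPDb, chi) = k_CPDb (CPDb - CPDb0_i)^2 + k_chi (chi - chi0_j)^2

with **no 1/2 prefactor** — the form as conventionally printed — and each
displacement taken as the minimal-image wrapped difference. The force
constants 100 and 50 are stated without a per-angle unit; the package
interprets them as kcal/mol/rad^2, the common bias-engine convention,
which gives window widths (sigma of roughly 3-4 degrees) consistent with
the 15-17 degree grid spacings. Both conventions are switchable
(`half_k`, `k_unit = "deg"`).

## Reweighting

The biased ensembles are combined by the self-consistent weighted-histogram
(WHAM) equations on a shared binning, iterating

p_m = n_m / sum_i N_i exp((f_i - U_i(m)) / kT),
f_i = -kT log sum_m p_m exp(-U_i(m) / kT)

to a fixed point of the window shifts f_i. The published study used the
spline-based vFEP estimator for this stage; WHAM is the standard
consistent estimator for the identical reweighting task and is what this
package implements, behind a module boundary that admits a drop-in
alternative.

Numerical choices:

* bias evaluated at **bin centres**; default bins 5 x 5 degrees;
* bin centres aligned with the multiples-of-5 lattice that carries the
  window centres (edges offset by half a bin, chi edges -182.5 to 177.5).
  This puts basin minima and window centres on bin centres instead of bin
  edges and removes an avoidable half-bin discretisation bias in basin
  free energies;
* convergence: maximum absolute change of the shifts per iteration below
  1e-7 kcal/mol (cap 1e5 iterations, flagged not-converged rather than
  failing); periodic safeguarded Aitken extrapolation accelerates the
  fixed-point iteration; a warm start from a previous fit is available and
  used by the convergence diagnostic;
* per-bin sums are scaled by a per-bin offset in log space, so window
  biases of thousands of kcal/mol at distant bins cannot underflow the
  denominators;
* all samples carry equal weight. No autocorrelation (statistical
  inefficiency) correction is applied; with the synthetic Metropolis
  sampler the thinning makes this mild, and for real data it would bias
  uncertainty estimates, not the surface itself;
* R = 1.9872041e-3 kcal/mol/K, default T = 300 K;
* bins with no reweighted counts are masked, excluded from marginal
  quadrature (P = 0) and from every RMS comparison.

The derived 1D views follow the conventional definitions: the effective
1D profile F(chi) = -RT log integral P(chi, CPDb) dCPDb by bin-width
quadrature over sampled bins; the fixed-CPDb slice (nearest bin row); and
the lowest-free-energy path profile, the pointwise minimum over the other
axis. Each is min-referenced to zero. Min-referencing means pointwise
inequalities between differently-referenced profiles hold for the raw
(commonly referenced) values; the tests compare raw values where that
distinction matters.

## Topography and the six-route taxonomy

Minima are bins strictly below all sampled 8-neighbours (chi periodic),
merged within one bin (lower kept, ties broken lexicographically).
Transition states are **minimax saddles**: the highest bin on the path
minimising its maximum F over the 8-connected sampled grid (bottleneck
Dijkstra, with an accumulated-F tie-break so equal-bottleneck paths
follow valleys). A Hessian-based saddle search would be fragile on a
noisy estimated surface; the minimax construction is robust and its
accuracy is the bin resolution.

Basins are labelled by rule: WC = lowest *anti* minimum with |CPDb| <= 20;
HG = lowest *syn* minimum with |CPDb| <= 20; LS = lowest remaining *syn*
minimum with CPDb <= -40 (the minor-groove intermediate). The six routes
are operationalised as constrained minimax problems, because a published
route taxonomy identified by visual inspection must be made computable:

* rotation sense: clockwise (R) paths rotate chi from WC to HG through
  the +-180 seam (net wrapped chi travel negative), counterclockwise (L)
  paths through -90;
* flipping class: *small* routes are confined to |CPDb| <= 20 throughout;
  *large* routes have their rotation transit forced beyond +-60 into the
  major (2) or minor (3) groove. "Transit" chi bins are those further
  than 25 degrees from both basin chi values; within the basin sectors
  the path may use any |CPDb| <= 20 (small side) so it can leave and
  re-enter the helix. The 20/60 degree cutoffs are the printed ones; the
  25 degree sector half-width is a package choice, set so that the
  rotation crests (near chi = -75 and +85) count as transit rather than
  basin territory.

Minor-groove routes that pass within one bin of the LS minimum report the
two sub-transition-states flanking it (TS1 before, TS2 after). Barriers
are differences of bin free energies and are invariant to the surface's
additive reference.

## The synthetic generator

No deposited trajectories exist for this system, so the pipeline is
exercised end-to-end by a generator that produces exactly the statistical
objects the estimator consumes — biased samples of (CPDb, chi) — rather
than atomic coordinates; the molecular-dynamics engine itself is out of
scope.

**Model surface.** An analytic, chi-periodic surface encodes the reported
landscape as *design targets of the toy surface, not ground truth about
DNA*: a WC minimum at (0, -105); an HG minimum at (0, 55) with
F(HG) - F(WC) = 4.4 kcal/mol; an LS intermediate at (-57.3, 51.2) at 6.0
kcal/mol; forward route barriers inside the 10-14 kcal/mol band with the
small-flipping routes lowest (about 10.4/11.0 for R1/L1 and 12.5-13.4 for
the four large routes on the 5-degree binned truth); saturating
base-opening costs of 8.0 (major) and 8.4 (minor) kcal/mol; and rising
walls beyond |CPDb| of about 100, where free energies become too large to
matter. The construction is: a saturating plateau in CPDb, a periodic
rotation-cost profile in chi (monotone Hermite interpolation through
knots every 15 degrees — monotone segments cannot overshoot, so the
profile has no spurious wells), multiplied by a CPDb gate with a floor
(rotation is cheapest inside the helix at slightly positive CPDb, and
cheaper again when fully flipped), a barrier bump separating LS from HG,
and Gaussian basin wells whose depths are calibrated at construction by a
fixed-point iteration so the designed basin heights are hit exactly (the
global minimum is then shifted to zero on a 1-degree scan). All transition
states land in the *syn* chi range by design.

**Window sampler.** Each window runs independent Metropolis chains (default
4) on F_true + U_bias with Gaussian proposals (5 and 6 degrees), 400
equilibration steps, thinning 2 — 2000 pooled samples per window,
interleaved in time order so any prefix is a cumulative-time prefix. The
per-window seed is a fixed integer hash of (master seed, window id),
platform-stable, so each window is reproducible in isolation. Default
step sizes were tuned once to keep acceptance within (0.2, 0.8) across
the grid (realised: roughly 0.27-0.49).

**Metadynamics walker.** A toy well-tempered walker (hill 1.0 kcal/mol
deposited every stride, widths 12 degrees, bias factor gamma = 15 at 300
K, hill height scaled by exp(-V/kB dT)) verifies that the window grid is
reachable: a 120 000-step run visits over 90% of the 312 window cells.
The history bias is accumulated on a 2-degree lookup grid, and a soft
quadratic wall beyond |CPDb| = 115 confines the walker to the meaningful
flipping range. This component seeds and sanity-checks coverage; it is
not used for free-energy estimates.

**Aggregation generator.** For the equal-K model, cluster sizes are
geometric in u = K_A m1 (the monomer activity solved from m_T = m1 /
(1 - u)^2). Frames of 16 molecules are drawn by placing independent
cluster boundaries between adjacent molecules, whose run lengths are
exactly those geometric sizes; phi is the cluster count over 16,
averaged over frames. Partitioning a finite frame this way has expected
phi of (1 - u) + u/N — the last molecule always closes a cluster — so
the boundary probability uses u' = u N/(N - 1), which removes the
finite-size offset exactly and makes the expected per-frame phi equal
the equal-K model value.
An optional geometric mode realises drawn configurations as coordinates
(chain members 2.8 Angstrom apart, clusters well separated in a periodic
box) so the 3.5 Angstrom centre-of-mass cluster criterion reproduces
them. The designed K_A = 2.0 molal^-1 used in the scripts is a
plausible mid-range nucleoside stacking constant; the concentration sets
0.0450/0.0375/0.0300 and 0.20/0.15/0.10 molal are the conventional ones
for the two nucleosides.

## Convergence diagnostic

Cumulative surfaces are re-estimated from the first ceiling(fraction n)
samples of every window at fractions 0.25/0.5/0.75/1 and compared with
the full-data surface by RMS over bins sampled in both, after aligning
the two surfaces by their mean difference on those bins (free energies
are defined up to a constant). The acceptance criterion mirrors the
conventional one: the RMS of the three-quarter surface must fall below
kB T = 0.596 kcal/mol at 300 K. At the default problem size the realised
sequence is roughly 0.25, 0.15, 0.09 kcal/mol — monotone and an order of
magnitude under threshold at 75%.

## Problem sizes

The standard study conditions used throughout the scripts and the
acceptance checks are 312 windows x 2000 samples (4 chains x 500 retained
states each), 5-degree bins (49 x 72 after covering sample stray), WHAM to
1e-7 kcal/mol, and convergence re-estimates at four fractions. At these
sizes the recovered surface agrees with the truth to about 0.25 kcal/mol
RMS over bins with true F below 12 kcal/mol, and the free-energy
difference and the lowest barrier to within about 0.3 kcal/mol.

## What the synthetic tests do and do not show

The generator emulates per-window Boltzmann sampling under harmonic
biases on a known landscape, equilibrated by construction. Passing the
recovery tests demonstrates that the estimator and the topographic
analysis are correct and well-conditioned at the stated problem sizes. It
does **not** demonstrate anything about real DNA: the synthetic chains
have no slow orthogonal degrees of freedom, no hysteresis between
windows, no force-field error, and their autocorrelation is mild and
controlled. Real trajectory data would add exactly those failure modes,
and the convergence diagnostic — not the recovery tests — is the tool
that would expose them.

## Known limitations

* The minimax transition state sits on the bin lattice; barrier accuracy
  is limited by bin width and by estimation noise near crests.
* Marginal profiles use bin-width quadrature over sampled bins only;
  heavily masked rows bias the marginal upward near the sampling edge.
* The route taxonomy depends on its three cutoffs (20, 60, 25 degrees);
  surfaces with crests inside a basin sector would need the sector
  half-width adjusted.
* `fit_equal_k` propagates no uncertainty; the residual it reports is a
  goodness-of-fit number, not a standard error.
* The PDB reader keeps the first alternate location and heavy atoms only
  by default; exotic atom naming requires an explicit `pseudoatom_spec`.
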