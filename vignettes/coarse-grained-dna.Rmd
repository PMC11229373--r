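---
title: "A one-bead-per-nucleotide model of duplex B-DNA: model, fitting and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A one-bead-per-nucleotide model of duplex B-DNA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`cgdna` simulates double-stranded B-DNA with one bead per nucleotide, anchored
at the C1' sugar carbon. This resolution keeps whole-gene-scale duplexes
tractable while retaining enough geometric information to regress all-heavy-atom
coordinates back out of the bead positions. This vignette explains the energy
model, the dynamics engine, the bottom-up fitting procedure, the synthetic
reference generator used throughout the tests, the back-mapping scheme, and the
analysis estimators — together with the numerical choices and their rationale,
and what the test suite does and does not establish.

## The Hamiltonian

The total energy splits into a sequential (bonded) and a remote (non-bonded)
part,

$$E = E_{seq} + E_{remote}, \qquad
  E_{seq} = E_{seq\text{-}4mer} + E_{seq\text{-}distant}.$$

Each bead interacts inside an 11-bead cross-strand window: with its two
sequence neighbors (stacking), its Watson–Crick partner (pairing), the beads
one to five positions up- and downstream of the partner (fan), and with its
second neighbors through angle terms. Every local interaction is a truncated
polynomial,

$$E(x) = \sum_{a=2}^{4} K_a\,(x - x_0)^a,$$

where the quadratic term sets the basal harmonicity, the cubic modulates its
asymmetry and the quartic confines large distortions ($K_2 > 0$, $K_4 \ge 0$,
so the energy is bounded below). Distances are in Å, angles in radians,
energies in kcal/mol.

The sequence-dependent part is indexed by *tetramers* — four consecutive
Watson-strand bases, reduced by reverse-complement symmetry to the
lexicographically smaller representative. Each tetramer window carries 2
stacking, 2 pairing, 4 angle and 8 fan terms (fan offsets ±1, ±2 at the
tetramer level under the default `"eq5"` accounting scheme). An interaction
shared by two windows takes the arithmetic mean of the two windows'
parameters. The remaining cross-strand offsets (±3, ±4, ±5 under `"eq5"`) form
the sequence-averaged *distant* set.

Two accounting schemes are provided because the per-window bookkeeping is
genuinely ambiguous: carrying fan offsets ±1..±3 at the tetramer level would
give 12 tetramer fan terms per window, not 8, while a distant set of only
±4, ±5 leaves ±3 unhoused. The default `"eq5"` scheme keeps the per-window
count at 8 by routing ±3 into the sequence-averaged distant set; `"fig1"`
instead keeps ±1..±3 tetramer-level with a ±4, ±5 distant set. Both are
selectable in `enumerateInteractions()` and the parameter files record which
one they were fitted under.

Terminal base pairs have truncated tetramer context; their interactions fall
back to the sequence-averaged `"AVG"` parameter class (which the refinement
stage also fits). This is a design choice — end effects are otherwise
unspecified at this resolution.

The remote part is a 12-6 Lennard-Jones term plus Debye–Hückel screened
electrostatics,

$$E_{LJ} = \sum 4\varepsilon\left[\left(\tfrac{\sigma}{r}\right)^{12} -
  \left(\tfrac{\sigma}{r}\right)^{6}\right], \qquad
  E_{ele} = \sum \frac{C\,q^2\,e^{-\kappa r}}{\varepsilon_r\,r},$$

with $q = -1\,e$ per bead, $\sigma = 10$ Å, $\varepsilon = 0.59$ kcal/mol,
and screening for 100 mM 1:1 salt: $\kappa = 0.104$ Å$^{-1}$ from the standard
Debye-length formula with $\varepsilon_r = 78.5$ (all configurable through
`remoteSettings()`). Remote interactions are switched off for bead pairs
within 5 bp of each other on either strand (circularly on minicircles), to
avoid double counting with the sequential window. The cutoff is $2.5\sigma$
with no switching function; a Verlet neighbor list (2 Å skin, rebuilt on a
half-skin displacement criterion) accelerates the evaluation and is tested to
agree exactly with the $O(N^2)$ double loop.

## Langevin dynamics

Sampling uses Langevin velocity-Verlet with the BAOAB splitting, chosen over
the plain impulse scheme for the accuracy of its configurational averages at
the working timestep of $\Delta t = 0.1$ ps. The friction default is
$\gamma = 1\ \mathrm{ps^{-1}}$ (results are robust to this coupling; it is a
settable parameter). Gaussian bath deviates are produced by the Box–Muller
transformation from R's seeded uniform stream, so a run is bit-reproducible
from its seed. Bead masses default to the nucleotide masses
(A 331.2, C 307.2, G 347.2, T 322.2 Da; configurable). Units are Å, ps,
kcal/mol, Da with $k_B = 1.987204\times10^{-3}$ kcal/mol/K and the
force-to-acceleration conversion $418.4$ (Å/ps²) per (kcal/mol/Å)/Da — the
thermochemical-calorie value, exact by definition.

One numerical subtlety is documented here because it affects how temperatures
are read off: at $\Delta t = 0.1$ ps the stiffest collective modes of a fitted
duplex reach $\omega\Delta t \approx 0.9$, where the *on-step* velocities of
any Verlet scheme systematically underestimate the kinetic energy by
$O((\omega\Delta t)^2)$ even though configurational averages remain accurate.
The energy log therefore records kinetic energy at the thermostat (O) step of
the splitting, where the velocities sample the Maxwell distribution without
this bias; with the bath disabled ($\gamma = 0$) the log falls back to on-step
velocities, whose total energy is the conserved quantity of interest.

Stability: the quartic confinement keeps 10^5-step trajectories of fitted
18-mers finite at baths up to (at least) 600 K at the default timestep; the
engine aborts with the offending step index if any force or coordinate turns
non-finite.

## The synthetic reference generator

The fitting stage needs reference bead ensembles with known statistics; the
package generates them rather than shipping data. `synthEnsemble()` builds
frames as ideal B-DNA (rise 3.38 Å/bp, twist 34.3°/bp, C1' radius 9 Å) plus
two fluctuation channels:

* **Smooth bending**: accumulated small random rotations of the base-pair
  frames (a discrete worm-like chain), with per-step standard deviation
  $\sqrt{\mathrm{rise}/PL}$ set by a target persistence length.
* **Local jitter**: per-bead anisotropic Gaussian displacements in a local
  frame aligned with the stacking bond, the (orthogonalized) pairing
  direction, and their normal.

The three jitter amplitudes are solved from the requested standard deviations
of the stacking distance, pairing distance and backbone angle by inverting the
exact first-order variance-propagation matrix of the ideal geometry; the
variance contributed by the bending channel is measured on a seeded pilot
ensemble and subtracted from the targets first. This is what makes the sample
SDs converge to the requested values (the suite checks 5% at 2000 frames).

Defaults: stacking and pairing SD 0.30 Å and backbone-angle SD 0.08 rad
(≈4.6°), typical of the base-pair-level fluctuations of room-temperature
B-DNA. The default bending persistence length is deliberately stiff, 150 nm
rather than the ~50 nm of real DNA: beads sit 9 Å off the helix axis, so
bending at realistic amplitude alone would already exceed a 0.3 Å stacking-SD
budget and leave the SD knobs without room to operate. The choice keeps the
internal-coordinate amplitudes the controlling parameters of the reference.

This is also the honest statement of what the generator does *not* emulate:
real atomistic ensembles have anharmonic, sequence-correlated fluctuations,
realistic bending (and hence end-to-end variance), and backbone fine
structure; the surrogate is Gaussian and mode-based by design, matching what
the fitting stage can consume (means, variances, selected covariances).
Passing the round-trip tests therefore demonstrates the correctness of the
machinery, not force-field-grade accuracy on real DNA. The same applies to the
all-atom companion builder (`idealBDNAAtomistic()`, `synthAtomisticEnsemble()`):
its nucleotide templates are idealized ring geometries with uniform 1.55 Å
bonds, rigid per residue and labeled synthetic — training fixtures for the
back-mapping, with no claim of covalent-geometry accuracy. With the default
antipodal inter-strand phase (chosen so that base-pair midpoints lie exactly
on the helix axis, which makes midpoint-based observables exact), the
Watson–Crick C1'–C1' width is wider than in crystallographic B-DNA; all
fitted equilibrium values inherit the generator's geometry, consistently.

## Bottom-up fitting

`extractObservables()` computes per-instance means and variances (and selected
shared-bead covariances) over a reference ensemble and pools them by
(tetramer class, role) with multiplicity weighting.

`fitBaseline()` produces the sequence-independent starting point: equilibrium
values are the pooled means, and force constants come from the harmonic
inversion $K_2 = k_BT/(2\,\mathrm{Var})$, with $K_3 = 0$ and
$K_4 = 0.1\,K_2$ — small enough (sub-percent at thermal amplitudes) not to
distort the inversion, large enough to confine rare excursions.

`refineTetramers()` then sweeps over the tetramer classes (including the
terminal `"AVG"` fallback); per class, a box-constrained optimizer (L-BFGS-B)
adjusts that class's force constants and equilibrium values against every
instance the class participates in, holding the other classes at their current
values, Gauss–Seidel style. Box constraints guard against over-training
($K_2 \in (10^{-3}, 100]$, equilibrium values within ±50% of the reference
mean, $K_4 \le K_2$). Sweeps repeat until the maximum relative parameter
change drops below $10^{-2}$; on closed-form synthetic references this takes
2–3 sweeps. Because an instance shared by two windows only constrains the
*mean* of the two classes' parameters, the individual split is weakly
identified; a small proximal penalty (scaled to the current misfit) anchors
the degenerate direction so the sweep terminates instead of sliding.

Model-implied observables during refinement default to the harmonic closed
form — fast and deterministic. The alternative `mode = "simulation"` runs a
seeded short simulation each sweep and models each instance's marginal
variance as $k_BT/\{2(K_{net} + K_{2,\mathrm{eff}})\}$, where $K_{net}$ is the
implicit stiffness contributed by the rest of the coupled spring network,
estimated from the simulation. This matters because marginal variances in the
assembled network are systematically below the isolated-term value; the
harmonic mode reproduces reference variances only term-by-term, while the
simulation mode makes the *simulated* ensemble reproduce them (the
parameter-recovery test holds pooled per-class stiffness to 10% and means to
1% through a full fit → simulate → re-measure loop, using about ten sweeps of
3×10^5 steps each — chosen as the point where the recovery error flattens
into the sampling noise).

`refineDistant()` re-adjusts the sequence-averaged distant terms against
target end-to-end statistics: Metropolis annealing over an effective-
temperature ladder (ramped up and back down, repeated over several seeds),
followed by a conjugate-gradient polish of the best candidate. The merit is
the summed squared relative error of the simulated end-to-end mean and
variance (equal weighting — the split is not otherwise determined). Merit
evaluations fix the simulation seed (common random numbers) so the polish
sees a deterministic surface; the annealing proposal stream is kept separate
from the simulation RNG.

## Back-mapping to heavy atoms

Reconstruction is a two-stage window regression. The backbone stage slides a
10-bp window along the duplex; the window's 20 beads are superposed onto a
stored canonical frame (Kabsch, proper rotations only) and a linear
least-squares map — optionally PCA-rank-reduced, and solved by minimum-norm
SVD because near-rigid synthetic training data is rank deficient — predicts
the window's backbone heavy atoms in that frame. Overlapping window
predictions are blended by plain averaging in the global frame (seam
disagreement before blending is reported as a diagnostic). The base stage
then places base atoms per base pair with one map per pair class (A·T/T·A and
G·C/C·G, purine-first orientation), driven by the eight sugar-backbone anchor
atoms of each residue, which exist for every residue regardless of terminal
phosphate handling. Working in locally superposed frames makes the whole
reconstruction rigid-motion equivariant by construction (asserted numerically
to 10^-3 Å). Circular duplexes reconstruct through wraparound windows;
interior trained windows are reused cyclically when the target is longer than
the training duplex.

Residual clashes are removed by steepest descent on a purely repulsive
soft-sphere potential ($\sum k(r_0 - r)^2$ below $r_0 = 1.7$ Å, pairs within
a residue or sequence-adjacent on a strand exempt, per-atom displacement
capped at 1 Å). This is a geometric clean-up step, *not* a molecular-
mechanics minimization — the output provenance and PDB headers say so
explicitly, so downstream users cannot mistake it for a force-field-polished
structure.

## Analysis estimators

All estimators operate on the bead frames or the base-pair C1'-midpoint
centerline and are rigid-motion invariant:

* `superposeRMSD()`: Kabsch superposition per frame with an iterated,
  self-consistent average structure; reflections are never used, so
  mirror-image frames keep a large RMSD (chirality guard).
* `essentialModes()` / `rmsip()`: covariance eigenmodes after superposition;
  the root mean square inner product of two 10-mode sets is 1 for identical
  subspaces and $\sqrt{n/d}$ in expectation for random ones (checked by Monte
  Carlo).
* `endToEnd()`: distance between the terminal bp midpoints (the definition is
  recorded in the output, so a terminal-bead alternative can be distinguished).
* `persistenceLength()`: tangent–tangent correlations of the (optionally
  smoothed) centerline, fitted log-linearly over the initial decay down to
  $\langle\cos\theta\rangle = 0.5$ — inside the exponential regime, before the
  long-separation noise floor. A chain whose correlations never decay returns
  `Inf`. The estimator's oracle is the discrete worm-like-chain sampler
  (`sampleWLC()`), which realizes a known persistence length by construction;
  the round trip is held to 10%.
* `shapeDescriptors()`: radius of gyration from the gyration-tensor trace and
  aspect ratio $\sqrt{\lambda_{max}/\lambda_{min}}$ of its eigenvalues (the
  eigenvalue definition is our choice; no standard formula exists).
* `bendingProfile()`: at each position, the angle between the two chords to
  the midpoints half a window away on either side. On a planar ring of $n$
  points with window $w$ this is analytically $180°\,w/n$ — the inscribed-
  angle closed form the suite asserts.
* `writhe()`: the discretized Gauss double integral (exact per-segment-pair
  solid angles) over the closed centerline polygon.
* `crossRMSDMatrix()`: pairwise superposed RMSD across ensembles with block
  bookkeeping.

## Problem sizes in the checks

The packaged checks run the statistical engine at 10^5–10^6 steps on 2–36
beads, fit on 18-mers with 2000-frame references, back-map 40-mers trained on
150 frames, and estimate persistence length from a few thousand worm-like
chains — sizes chosen so every claim is measured with comfortable sampling
margin relative to its tolerance. The engine itself accepts arbitrarily long
(including multi-kilobase and circular) duplexes; the 339-bp minicircle build
and a short dynamics run on it are part of the suite.

## Known limitations

* Base flipping, melting, kinks and other large deformations are outside the
  model by construction (the quartic terms forbid base opening); Morse-type
  extensions would be needed.
* The synthetic reference is a Gaussian surrogate: fits to it validate the
  pipeline, not agreement with atomistic force fields. Fitting against real
  atomistic bead ensembles is supported (any `TrajectoryEnsemble` works) but
  ships untested for lack of such data here.
* The remote terms use a single screened-Coulomb dielectric; no explicit
  ions, no distance-dependent dielectric.
* The clash relaxer is geometric; reconstructed structures are starting
  points, not minimized conformations.
* Single-threaded; the per-step cost is $O(N)$ bonded plus neighbor-list
  remote work.
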