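---
title: "Coarse-grained analysis of SUMO-coupled RNA-binding domain closure"
author: "rbdsumo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coarse-grained analysis of SUMO-coupled RNA-binding domain closure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific problem

CPEB3 is a prion-like RNA-binding protein that regulates local translation
at synapses. Its C-terminal RNA-binding domain (RBD) carries two tandem RNA
recognition motifs (RRM1, RRM2) and a zinc finger (ZnF). NMR structures of
homologous tandem RRMs show an open conformation when free and a closed
conformation when RNA-bound; closure of the two RRMs around the RNA is part
of the binding reaction. SUMO2 can engage the RBD bivalently — through a
SUMO-interacting motif (SIM) in RRM1 that pairs with SUMO2's beta-2 strand,
and through the ZnF — and this bivalent clamp biases the RBD toward the
closed, binding-competent conformation. Thermodynamically, removing the
open-state conformational entropy of the free protein raises the RNA-binding
affinity; an affinity difference of about 2 kcal/mol converts, through the
Boltzmann factor exp(ddG/RT) at 300 K, into an equilibrium partitioning
ratio of roughly 30 between the two protein forms.

`rbdsumo` implements the complete computational workflow around this
mechanism at one-site-per-residue resolution: structural-similarity
analysis (mutual Q), principal-component order parameters, contact-map and
frustration screening, a calibrated residue-base contact potential, a
structure-based Langevin simulator with umbrella sampling, WHAM free-energy
reconstruction, and the closed-form dissociation-constant thermodynamics.
Because the original force fields (an associative-memory protein model
combined with a three-site nucleic-acid model) and the NMR template
structures are outside the scope of a self-contained package, every
simulation stage runs on a synthetic model system generated in code, with
analytic or constructional ground truth for each operator.

## The mutual-Q similarity metric

For two conformations A and B sharing a topology,

$$Q = \frac{1}{N}\sum_{(i,j)} \exp\!\left(-\frac{(r_{ij}^A - r_{ij}^B)^2}
{2\delta_{ij}^2}\right),$$

where the sum runs over a declared pair scope. For pairs within one chain
the tolerance grows with sequence separation, $\delta_{ij} = |i-j|^{0.15}$
(in Angstrom), and pairs closer than 3 positions in sequence are excluded
as trivially constrained by chain connectivity; for pairs across chains
$\delta_{ij}^2 = 5\,\mathrm{A}^2$. A pair enters the sum when the two sites
are within the 12 A contact threshold in *either* structure (the union
rule; the Methods that define the threshold leave open which structure
defines the contact set, and the union convention is the one that makes
template comparison symmetric in model and template). Q is 1 for identical
internal distances, symmetric, and rigid-motion invariant.

Three scoped variants cover the analysis stages: inter-domain pairs for
clustering predicted structures and for the closure order parameter
$Q_f$ (similarity to the free, open reference); inter-molecular
union-of-contacts pairs for the template screen $Q_c$, where a predicted
complex is kept only when $Q_c > 0.2$ (strict inequality); and all pairs
for general comparison. Clustering uses average-linkage hierarchical
clustering on the distance $1-Q$ (the choice of linkage is ours; the
source analysis names none), with the cluster representative defined as
the member maximizing mean within-cluster Q, ties broken by lowest index.

## Order parameters

PC0 is the leading cartesian principal component of an equilibrium
ensemble. Frames are iteratively superposed on the evolving mean structure
before the covariance eigendecomposition — without this, rigid-body motion
mixes into the hinge mode. The sign of PC0 is anchored so the open
reference projects positive. R, the dissociation coordinate, is the
distance between the geometric center of the annotated binding-pocket
residues and the geometric center of the ligand sites (geometric rather
than mass-weighted centers; the source defines R only verbally). Basins
are axis-aligned rectangles in order-parameter space; the packaged
defaults mirror the printed PC0 mode ranges ([-10, 0] closed, [10, 30]
open) rescaled to the fitted PC0 range of the system at hand. A
dissociation trajectory is classified path I when PC0 enters the open
range at or before the unbinding step (R crossing the unbound threshold),
path II when PC0 stays in the closed range throughout, and mixed
otherwise.

## The residue-base potential and its calibration

Residue-base well depths are built from atomic contact counts in a
reference complex: counts are pooled by (residue type, base type), and the
depth of a type pair is $\lambda$ times its pooled count normalized by the
largest pooled count. Pooling by type (rather than by instance) is what
lets the same table score *new* sequences in the SIM scan; the exact
functional form mapping counts to strengths is our declared choice — the
source states only that the potential was tuned using atomic contact
numbers as a reference. Interactions use a smooth well: full depth up to
the 6.5 A contact range, cosine-tapered to zero over a further 2 A
(differentiable, finite-ranged). Atomic counting uses a 4.5 A heavy-atom
cutoff, site-level counting 8 A; neither value is stated in the source.

The global scale $\lambda$ is calibrated so the umbrella/WHAM binding free
energy of the model receptor-ligand system equals 8 kcal/mol, the value the
original calibration targeted (the NMR titration Kd of 15.8 +/- 6.6 uM
corresponds to 6.4-6.9 kcal/mol at 300 K). The calibration brackets
$\lambda$ and then applies regula falsi on the measured affinity, which is
monotone non-decreasing in $\lambda$; each trial re-runs the full umbrella
series with a seed derived from the master seed.

## Frustration screening

A contact's frustration z-score compares its native pair energy with
decoys in which the two identities are redrawn from the complex's own
composition: $z = (\langle E_{decoy}\rangle - E_{native})/\sigma_{decoy}$,
and a contact is minimally frustrated when $z > 0.78$ with 1000 decoys —
the standard mutational-frustratometer convention, adopted here because
the source cites that methodology without restating parameters. For a
two-type composition the decoy distribution is a three-point discrete law,
which the test suite uses as a closed-form check of the Monte-Carlo
estimate. Candidate complex models are ranked by the number of minimally
frustrated contacts, ties broken by lower energy.

## The simulator

The simulator is a structure-based (Go-like) coarse-grained model, not a
reimplementation of the transferable force fields used in the original
study: harmonic bonds along each chain (equilibrium lengths from the
reference, k = 20 kcal/mol/A^2), Gaussian wells (width 1 A) on native
contacts enumerated from the reference within 8 A, and a soft quadratic
excluded-volume wall at 3.5 A. Residue-base interactions are Gaussian
wells of the same form on the protein-RNA pairs in contact in the
reference complex, with depths taken from the contact potential — the
same epsilon-weighted native-well construction as the protein contacts,
so the bound ligand holds the cleft at its reference geometry. (The
smooth tapered well belongs to the analysis-side binding-energy operator;
using it inside the simulator would leave the bound cleft free to wobble
across the flat bottom, which suppresses exactly the bound-state
rigidity the closure thermodynamics trades on.) Native contacts across
the two domains get a weaker depth (0.3 vs 1.5 kcal/mol) so the hinge
interconverts at 300 K — the ligand-free receptor populates the open
region roughly half the time, mirroring the bimodal free-state ensemble
the closure thermodynamics requires. Dynamics are
BAOAB-discretized Langevin in reduced units (site mass 1,
kB = 0.0019872 kcal/mol/K, step 0.02, friction 0.2 — a light thermostat
coupling chosen because conformational mixing, the slowest process in
the umbrella windows, scales inversely with friction); with zero
friction the integrator reduces to velocity Verlet, which the tests use
for energy-conservation checks. All stochastic operations take explicit
seeds; umbrella windows run sequentially, each starting from the
previous window's last frame, with per-window seeds split from the
master seed.

Three bias potentials mirror the construction stages of the bivalent
complex: harmonic restraints pairing SIM and beta-2 residues in register
(the sheet-formation guide, turned off for relaxation); a harmonic
umbrella bias on R (with an optional moving center for steered
dissociation); and the cross-link tether — harmonic pair restraints,
spread over the inter-domain interface by greedy max-min selection,
pinning the closed geometry the way the bivalently bound partner does. A
tether anchored at fewer, collinear points leaves the hinge free to rotate
about the anchor axis and has no thermodynamic effect; the spread
selection is what makes the clamp effective. The packaged tether
stiffness was set (once, stored in the demonstration configuration) by
measuring the clamp's equilibrium free-energy cost in the bound and the
unbound state — a Bennett-style two-state comparison on long equilibrium
runs, whose difference is exactly the affinity shift the clamp produces
— and choosing the stiffness where that difference plateaus at the
2 kcal/mol the mechanism predicts. An umbrella-based tuning loop
([calibrate_tether()]) is also provided; it estimates the same quantity
but with the sampling noise of two full umbrella series per trial.

## Free-energy reconstruction

WHAM is the standard binned self-consistent estimator. The window free
energies are converged on a fine internal grid (at least 200 bins;
tolerance 1e-7 kcal/mol on the window offsets, at most 1e5 iterations) so
that bias-at-bin-center discretization does not bias the profile; the
output surface is then built from per-sample unbiasing weights, in 1D and,
reusing the same converged window offsets, in 2D over (R, PC0) or
(Q_f, PC0). Unsampled bins are flagged NA and never interpolated.
Uncertainties come from a 50-replicate block bootstrap within windows
(10 blocks per window). Window connectivity is checked before solving;
disconnected groups are reported by window index.

The binding free energy is read off the 1D profile as the mean over the
unbound plateau (by default the last 20 percent of the sampled R range)
minus the bound minimum. No standard-state volume correction is applied —
the quoted 8 kcal/mol is likewise a profile difference, and whether the
original study applied such a correction when comparing with the 6.4-6.9
kcal/mol experimental range is not stated. Affinity differences propagate
errors in quadrature. Shoulder detection fits a smoothing spline and
reports interior local minima of the slope that flatten toward zero
without a sign change; sign changes are reported separately as true
extrema.

## The synthetic model system

The generators produce every input the pipeline needs:

* **Receptor.** Two 40-residue domains built as serpentine lattice walks
  (3.8 A spacing — compact folds with well-defined contact networks),
  joined by a 4-residue linker laid along a bowed arc whose contour
  length matches 3.8 A bonds: the slack is deliberate, because a taut
  straight linker would suppress the hinge entropy that the closure
  thermodynamics depends on. Open and closed conformers differ by a
  hinge rotation (70 and 100 degrees from the stacking axis); the closed
  form presents a cleft 8 A wide whose lining residues carry the `pocket`
  annotation. Pocket residues are assigned basic/polar types against a
  glycine background so the contact-derived potential engages the pocket
  specifically.
* **Ligand.** A 5-nucleotide single-stranded RNA (the length the original
  study used to represent a target message) docked along the cleft.
* **Bimodal ensembles.** Gaussian-noise perturbations of the two
  conformers in stated proportions, with the planted mode labels carried
  as machine-readable ground truth.
* **Umbrella oracle.** Exact Boltzmann samples from a 1D harmonic
  landscape plus window biases — each window's distribution is Gaussian in
  closed form — giving the WHAM machinery an analytic target
  (recovery within 0.1 kcal/mol is asserted in the tests).
* **Reference complex.** The bound closed complex plus a synthetic
  heavy-atom table constructed so atomic contact counting recovers exactly
  a planted (residue, base, count) table, with enough margin that small
  coordinate jitter cannot change any count.
* **Scan sequences.** Random hydrophilic background with planted
  all-isoleucine windows that maximize the packaged hydropathy-based
  pair-strength table, so an exhaustive scan attains its minimum at the
  planted start.

What the synthetic system does *not* emulate: real secondary structure,
transferable energetics, zinc coordination, sequence-specific RNA
recognition beyond the planted contact table, or the true NMR geometries.
Passing tests therefore demonstrate that the *operators* are correct
(formulas, estimators, invariances, screening rules) and that the
qualitative mechanism (clamp removes open-state entropy, raises binding
affinity, switches the dissociation pathway) is reproduced by a minimal
model — not that the quantitative surfaces of the real system are
reproduced.

## Problem sizes and numerical choices

The packaged demonstration protocol uses 14 umbrella windows over R in
[4, 30] A, a 2 kcal/mol/A^2 umbrella spring, 2e5 steps per window at
300 K with samples recorded every 200 steps, and 50 WHAM bins — sizes at
which a full affinity estimate takes about a minute on one CPU and the
entire calibration a few minutes. The tether comparison uses a denser,
stiffer ladder (20 windows, 4 kcal/mol/A^2) because the rigid bound well
makes the exit region steep, a 12-anchor clamp at the calibrated
stiffness, and averages two independently seeded tethered/untethered
umbrella pairs — single-pair affinity differences on this system carry
roughly +/-1 kcal/mol of seed-to-seed scatter from slow receptor
conformational mixing, and replication is the honest way to report them.
The test suite runs reduced versions (fewer windows and steps) of every
simulation-dependent check; the statistical tolerances in the tests are
matched to those problem sizes.
Equilibration discards the first 20 percent of each window. Degenerate
inputs are handled explicitly: identical-frame ensembles give a
zero-variance PCA model with a warning, homogeneous compositions make
frustration z-scores undefined and error, umbrella series without
neighbour overlap abort listing the disconnected window groups, and
a zero umbrella spring warns that all windows sample the same
distribution.

## Known limitations

* The entropy difference driving the affinity shift depends on the
  flexibility of the synthetic linker and the weak inter-domain contacts;
  its magnitude is a property of the model system, which is why the tether
  stiffness is a calibrated, stored quantity rather than a prediction.
* PC0 biasing inside the simulator projects on a fixed direction without
  re-superposition (adequate for gentle restraints near the reference
  frame, inaccurate far from it); the analysis-side PC0 always
  re-superposes.
* The single-site RNA representation leaves the mapping of the
  three-sites-per-nucleotide model onto R undefined; R here uses the one
  representative site per nucleotide.
* WHAM (not MBAR) is the estimator; for the well-overlapped window
  ladders used here the difference is negligible against the bootstrap
  error.
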