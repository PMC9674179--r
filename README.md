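# rbdsumo

Coarse-grained modeling of how bivalent SUMO binding closes a tandem-RRM
RNA-binding domain and amplifies its RNA-binding affinity.

## The problem

The RNA-binding domain (RBD) of the prion-like translational regulator
CPEB3 carries two RNA recognition motifs (RRM1, RRM2) and a zinc finger
(ZnF). Tandem RRMs are open when free and close around their RNA when
bound, so anything that pre-pays the cost of closure binds RNA more
tightly. SUMO2 can clamp the RBD bivalently — via a SUMO-interacting motif
(SIM) in RRM1 that pairs with SUMO2's β2 strand, and via the ZnF — and
thereby confines the domain to the closed, binding-competent conformation.
The package implements the full computational workflow for quantifying
this mechanism at one-site-per-residue resolution, for structural
bioinformaticians who want the analysis operators (not the original
force fields) as tested, reusable code:

* **mutual Q** — structural similarity
  `Q = (1/N) Σ exp(−(r_ij^A − r_ij^B)² / 2δ_ij²)` with
  `δ_ij = |i−j|^0.15` within chains, `δ² = 5 Å²` across chains, a 12 Å
  contact threshold (union rule), plus Q-distance clustering and the
  `Q_c > 0.2` template screen;
* **collective variables** — superposition-corrected cartesian PCA (PC0,
  the open/closed hinge coordinate), the ligand–pocket distance R, basin
  assignment, dissociation-pathway classification (path I: open before
  unbinding; path II: closed throughout);
* **energetics** — residue–base well depths built from atomic contact
  counts in a reference complex (`ε ∝ λ · pooled count`), binding
  energies with a smooth 6.5 Å well, mutational-frustration z-scores
  (minimally frustrated iff `z > 0.78`), and a SIM sequence scan;
* **simulation** — a structure-based Langevin engine (Rcpp) with
  umbrella sampling on R, a sheet-pairing guide, and the bivalent
  cross-link tether;
* **free energies** — self-consistent WHAM in 1D/2D with block-bootstrap
  errors, binding affinities `ΔG = F(plateau) − F(bound)`, `ΔΔG` with
  quadrature errors, and shoulder detection;
* **thermodynamics** — `ΔG = −RT ln(Kd/c⁰)` and the equilibrium shift
  ratio `exp(ΔΔG/RT)`.

Everything simulation-dependent runs on a synthetic two-domain receptor
with a 5-nt RNA ligand, generated in code with analytic or constructional
ground truth (see the methods vignette in `vignettes/methods.Rmd`).

## Worked example

```r
library(rbdsumo)

## NMR titration: Kd = 15.8 ± 6.6 uM at 300 K
kd_to_dg(15.8e-6)                 # 6.590847  kcal/mol
kd_to_dg(c(9.2e-6, 22.4e-6))      # 6.913254 6.382757  (the 6.9-6.4 range)

## a 2 kcal/mol affinity difference shifts the mRNA pool ~29:1
shift_ratio(2)                    # 28.63999

## synthetic system: receptor + ligand with planted contact counts
sys <- demo_system(lambda = demo_config()$lambda)
compute_r(sys$complex)            # 0.9334 A - ligand centered in pocket
sys$potential$residue_base        # well depths from pooled contact counts
#            A        U
# ARG 0.000000 3.092428
# SER 1.124519 0.000000

## umbrella sampling + WHAM binding affinity (about a minute)
est <- estimate_affinity(sys$topology, seed = 1)
est$affinity                      # binding free energy: ~8 kcal/mol
```

The first three numbers are closed forms: the Kd endpoints bracket the
6.4–6.9 kcal/mol experimental affinity range, and `exp(2/RT) ≈ 28.6` is
the "around 30" equilibrium shift between SUMOylated monomers and
deSUMOylated fibers. The last one is measured by simulation: the packaged
λ was calibrated so the model system reproduces the 8 kcal/mol affinity
the residue–base potential was tuned to.

## Command line

A thin CLI wraps the main entry points:

```sh
exec/rbdsumo generate --seed 1 --out fixtures/   # synthetic system + truth
exec/rbdsumo thermo kd2dg --value 15.8e-6        # Kd -> kcal/mol
exec/rbdsumo run-all --seed 1 --out run/         # full pipeline, JSON report
```
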