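---
title: "Hydration-shell water entropy, structure and dynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hydration-shell water entropy, structure and dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hydroshell)
```

## The problem

Antifreeze proteins (AFPs) and ice-nucleating proteins (INPs) present
structurally similar, threonine-rich ice-binding surfaces (IBS) yet do
opposite jobs: AFPs adsorb to nascent ice and arrest its growth, INPs
template ice formation at mild supercooling. A discriminating observable is
the thermodynamic and dynamic state of the individual water molecules in the
first hydration shell of the IBS: a surface that locks nearby waters into
low-entropy, ice-like arrangements lowers the entropic barrier to
nucleation, while a surface whose side chains fluctuate leaves its shell
water bulk-like. `hydroshell` implements the full per-water analysis chain
on molecular-dynamics trajectories: per-water rotational and translational
entropy, hydrogen bonding, tetrahedral order, mobility, shell-exchange
kinetics, and the protein-side geometry (side-chain orientation angles,
ladder spacings, loop contacts) that modulates all of the above.

## Per-water entropy: permutation reduction plus orientational histograms

Bulk water molecules are indistinguishable, so "water number 532" does not
denote a fixed spatial site over a trajectory; exchanging molecules would
smear any per-molecule statistic toward the bulk average. Permutation
reduction fixes this by relabeling the waters of every frame against a
reference configuration, choosing the permutation that minimizes the total
squared (minimum-image) oxygen displacement. The relabeled index then
denotes a localized spatial slot. The minimization is a linear assignment
problem; `relabel_frame()` solves it exactly with an $O(N^3)$ Hungarian
algorithm (implemented in C++; no weighted-assignment solver exists in the
R toolchain this package targets). Exactness matters: the permuted cost is
provably no larger than the identity cost on every frame, and the test
suite verifies agreement with exhaustive search over all permutations for
$N \le 7$.

The orientation of water $k$ relative to a solute reference point (here,
the nearest IBS threonine hydroxyl oxygen, or a reference water's oxygen in
pure water) is reduced to two angles: $\theta$, between the O$\to$solute
vector and the molecular dipole (O to the H–H midpoint), and $\chi$,
between the normal of the (solute vector, dipole) plane and the H–H vector.
The rotational entropy of the binned density $p(\theta, \chi)$ relative to
the uniform orientational distribution is

$$ S_\mathrm{Rot} = -k_B \int p(\theta,\chi)\, c \,
   \ln\{p(\theta,\chi)\, c\}\, \sin\theta \, d\theta \, d\chi $$

with $c = \int \sin\theta \, d\theta \, d\chi = 2\pi$ the total angular
measure, so a uniform density gives exactly zero and any structuring gives
a negative value (results are reported as $T \cdot S$ in kcal/mol,
$k_B = 0.0019872041$ kcal mol$^{-1}$ K$^{-1}$, default $T = 273$ K).

Numerical choices, all verified against closed forms in the tests:

* **Grid.** 30 × 30 uniform bins over $\theta, \chi \in [0, 180]$ degrees.
  Bin measures use the exact integral of $\sin\theta$ over each bin, not a
  midpoint value, so the uniform, half-domain ($-k_BT\ln 2$) and single-bin
  ($-k_BT\ln(c/\Delta\Omega)$) cases are recovered analytically.
* **$\chi$ convention.** The source formulation fixes no sign convention for
  the plane normal. We take the unsigned angle in $[0,180]$ between
  $\widehat{(O\!\to\!\text{solute})} \times \hat{d}$ and H1$\to$H2. Swapping
  the H labels maps $\chi \mapsto 180 - \chi$; because the grid is uniform
  and symmetric about 90, the histogram — and hence the entropy — is
  invariant under the swap.
* **Degenerate samples.** When the dipole is (anti)parallel to the solute
  vector the plane normal is undefined; such samples are flagged, excluded
  and counted rather than silently binned.
* **Bias.** The plug-in estimator is biased downward at finite $n$; on
  uniform data the bias is provably $\le 0$ and shrinks with $n$ (asserted
  at $n = 10^3 \ldots 10^5$). Profiles should therefore be compared at
  matched sample counts, which the ranked-profile workflow guarantees.

The translational analogue (`translational_entropy()`) is the voxel-histogram
entropy of a label's permutation-reduced positions over a local bounding
cell, referenced to the uniform density over that cell (uniform occupancy
$\Rightarrow 0$; an octant confinement $\Rightarrow -k_BT\ln 8$). The exact
construction behind the published translational values is not specified in
the source text, so this package's choice — a cell-referenced voxel density,
tagged `method: voxel-3D` in reports — is a documented convention of this
implementation, not a reproduction.

## Hydrogen bonds, tetrahedral order, kinetics

**H-bonds** use the standard geometric criterion: donor-O to acceptor-O
distance within 3.5 Å and O–H⋯O deviation angle (between O$_d$→H and
O$_d$→O$_a$) within 30°. The deviation-angle reading matches the convention
of the major MD analysis tools; the donor–H–acceptor reading
(angle at H $\ge 150°$) is available via the criterion's `angle_def` tag.
Which partners count (water–water only, or water plus threonine oxygens) is
always an explicit argument, because the pure-water baseline and the IBS
analysis differ in exactly this respect.

**Tetrahedral order** uses the conditional parameter for central waters with
$k \in \{2,3,4\}$ neighbor oxygens within 3.5 Å:

$$ t_h = 1 - \frac{9}{4}\, \frac{1}{n_p} \sum_{\text{pairs}}
   \left(\cos\psi + \tfrac13\right)^2, \qquad n_p = \binom{k}{2}. $$

The per-pair normalization makes $t_h = 1$ for perfect tetrahedral angles
and $\mathbb{E}[t_h] = 0$ for isotropic neighbor directions at every $k$
(since $\mathbb{E}[(\cos\psi + 1/3)^2] = 4/9$ for a uniformly random
$\cos\psi$), so values are comparable across neighbor counts; the $k=4$
case coincides with the Errington–Debenedetti $q$. Whether the original
conditional formulation restricts neighbors to H-bonded partners is not
recoverable from the text we follow; distance-only neighbors are used, with
the central-water set (typically the H-bonded-to-threonine labels) supplied
explicitly.

**Residence times** follow the stable-state picture: a water is a reactant
member when H-bonded to an IBS hydroxyl (3.5 Å / 35°) at a time origin, and
has reacted when it first passes beyond 5.3 Å (0.53 nm) from the IBS — a
cutoff placed at the first solvation minimum of the site–water RDF, which
`site_water_rdf()` reproduces. The survival correlation
$C(t) = 1 - \langle p_R(0)\, p_P(t) \rangle$ uses an absorbing (first
passage) product indicator, which is what makes the stable-state picture
insensitive to transient recrossings; an instantaneous indicator is provided
for comparison. Averaging uses multiple time origins, restricted to origins
with full lag coverage so the averaged $C(t)$ is guaranteed non-increasing.
$C(t)$ is fitted with

$$ C(t) = C_1 e^{-t/\tau_1} + C_2 e^{-t/\tau_2}, \qquad
   \tau = \frac{C_1 \tau_1 + C_2 \tau_2}{C_1 + C_2}, $$

the standard bi-exponential form and amplitude-weighted mean; the source
renders these equations as images, so the explicit forms are adopted here as
the only ones consistent with the stated coefficients and timescales — this
is flagged rather than silent. The fit is unweighted least squares down to
$C = 0.01$, initialized by exponential peeling (tail fit, subtraction, then
the fast mode) and refined by Levenberg–Marquardt with non-negativity
bounds. Two robustness rules guard the mean: timescales are bounded above
by five observation windows (anything slower is unidentifiable from the
data), and a fitted component carrying less than 2% of the total amplitude
is treated as a noise-floor artifact and excluded from the
amplitude-weighted mean — without this, a spurious near-zero-amplitude slow
mode can inflate $\tau$ by orders of magnitude on clean single-exponential
input.

## Protein-side geometry

`theta_S()` / `theta_T()` measure each threonine's C$_\beta \to$ OG1 vector
against the ladder-long axis (C$_\alpha$ pair of the x-residues of the TxT
patches on the first and last strand) and against the neighbor-C$_\alpha$
axis, respectively; sharp distributions mean rotationally locked hydroxyls.
`sidechain_rmsd()` superposes each frame's backbone (CA, C, N) onto a
reference by least squares before computing per-residue side-chain
heavy-atom RMSD. `ladder_spacing()` reports the threonine C$_\alpha$
register both as consecutive same-strand TxT pairs and as position-matched
pairs across two ladders — the published 7.1 Å (TmAFP) vs 6.9 Å wording is
ambiguous between the two readings, so both are implemented behind a `mode`
switch rather than guessing. Ladder membership is user-supplied
configuration; nothing is auto-detected silently.

## The synthetic generators: what they emulate and what they do not

Because the original 200-ns all-atom trajectories are not deposited, every
analysis stage is validated against generators whose ground truth is known
analytically (each generator records it in a `ground_truth()` attribute,
and tests compare pipeline output to that record, never to numbers
duplicated by hand):

* `gen_tetrahedral_lattice()` — diamond-cubic oxygen lattice (default
  $a = 6.35$ Å, i.e. the ice-like 2.75 Å O–O distance) with hydrogens
  donated along neighbor directions under the ice rule, satisfied exactly by
  an Eulerian orientation of the 4-regular O–O bond graph. At zero jitter:
  all O–O–O angles 109.47°, four H-bonds per water, $t_h = 1$. Carries an
  independent brute-force H-bond count (27-image direct search) for
  detector validation. Donated hydrogens necessarily subtend 109.47° rather
  than a free water's 104.52°; the geometric criteria only see O/H
  positions, so this is immaterial.
* `gen_oriented_waters()` — orientation samples from uniform, half-domain,
  single-bin, concentrated ($\propto e^{\kappa\cos\theta}$) and mixture
  laws with analytic or quadrature-evaluated entropies.
* `gen_exchange_trajectory()` — two-state Markov hopping between a bonded
  slot (exactly satisfying the 3.5 Å / 35° criterion) and a region beyond
  the product cutoff; survival $e^{-k_\mathrm{exit} t}$ when there is no
  return.
* `gen_brownian_box()` — independent Gaussian walkers (step variance
  $2D\,dt$ per axis) with the unwrapped truth retained, for the Einstein
  relation and the localization property of permutation reduction.
* `gen_toy_ibs()` — a planar grid of hydroxyl-bearing pseudo-threonines at
  the 7.4 Å TxT register with pinned (orientation-frozen, H-bonded) and
  free (randomly re-oriented) waters.

All generators use the rigid 3-site water geometry (O–H 0.9572 Å, H–O–H
104.52°, lattice excepted as noted); lone-pair sites of 5-site models are
carried through the trajectory model but ignored by every geometric
criterion, which reference O and H atoms only. The generators are geometric
stand-ins: no force field, no thermostat, no proton-disorder statistics, no
hydrogen-bond cooperativity. Passing tests therefore demonstrate estimator
correctness — that the pipeline recovers known entropies, rates, diffusion
constants and counts from trajectories with those properties — not that any
particular protein orders its hydration shell; the latter requires real MD
input, which the package accepts unchanged through the same readers.

## Problem sizes, defaults and reproducibility

The test suite and the acceptance script run the estimator checks at sizes
chosen for tight tolerances on a single CPU: $10^6$ orientation samples for
the closed-form entropy checks, 400 waters × 3000 frames for the Poisson
residence-time recovery, 1000 walkers for the diffusion check, $10^5$
neighbor vectors for the isotropic $t_h$ mean, and 50 random instances for
assignment optimality. Published per-protein numbers (per-water
$TS_\mathrm{Rot}$ profiles, $\tau$ = 62.1/46/70.5 ps for the three proteins,
H-bond and $t_h$ panels) derive from 200-ns simulations of specific systems
and are inputs this package analyzes, not quantities it can regenerate.

Design decisions that were genuinely open, and the choices made:

* Reference configuration for permutation reduction and nearest-water
  ranking: the first frame (user-selectable), recorded in output metadata;
  the source does not state its choice.
* The $k$ nearest waters are selected once at the reference frame (minimum
  over site atoms, oxygen distances, ties by water id) and then tracked by
  label, matching the per-water bookkeeping downstream.
* Occupancy threshold for "remains H-bonded" selection: 0.5 by default,
  explicit everywhere, recorded in the manifest.
* Equal-cost assignments are resolved deterministically by the solver's
  scan order; different solvers may return different optimal permutations,
  all satisfying the optimality invariant.
* The orchestration layer is exposed as R functions
  (`run_entropy_pipeline()`, `run_structure_dynamics_pipeline()`,
  `run_protein_pipeline()`) taking list or YAML configs; a library-first
  interface suits R users better than a shell tool, and every default that
  fills a config gap is recorded in the JSON manifest.

Every generator takes an explicit seed and is byte-deterministic given one;
re-running a pipeline with the same config reproduces its outputs exactly.

## Worked example

```{r example, eval = FALSE}
library(hydroshell)

# a toy ice-binding surface: 2 waters pinned at bonding geometry, 6 free
ibs <- gen_toy_ibs(n_frames = 40, n_pinned = 2, n_free = 6, seed = 1)
report <- run_entropy_pipeline(list(traj = ibs, k = 8, min_samples = 1))
report$profile          # ranked per-water TS_Rot / TS_Trans table
report$hbonded          # the subset persistently H-bonded to the hydroxyls

# shell-exchange kinetics with known mean residence time 1/k = 50 ps
ex <- gen_exchange_trajectory(k_exit = 0.02, n_waters = 400,
                              n_frames = 3000, seed = 1)
gt <- ground_truth(ex)
sc <- survival_curve(gt$bound, !gt$bound, max_lag = 2800, dt = 0.1,
                     origin_stride = 150)
fit_biexponential(sc)   # tau close to 50 ps
```

## Known limitations

* XTC/TRR trajectories are not readable (no R reader exists for the
  compressed GROMACS formats here); convert to DCD, multi-frame GRO or
  multi-model PDB first.
* The entropy estimator needs large per-label sample counts (the headline
  analyses used $2\times10^6$ frames per water); at small $n$ the downward
  bias dominates and only relative comparisons at matched $n$ are
  meaningful.
* Triclinic minimum-image support assumes reduced (GROMACS-convention)
  cells; heavily skewed cells should be reduced first.
* No energetic H-bond definitions, no multi-body entropy terms, no ice-phase
  classification, and no thermal-hysteresis prediction — out of scope by
  design.
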