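---
title: "Methods: nucleosome-ligand binding sites, energetics, hydration and dynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: nucleosome-ligand binding sites, energetics, hydration and dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nucbind)
```

# Scope and model

`nucbind` implements the computational side of a study of a small hydrophobic
ligand (a sterol) binding the nucleosome core particle: identifying candidate
binding sites from ensemble docking, quantifying per-site affinities with the
linear interaction energy (LIE) method, measuring how binding dehydrates the
particle surface, and asking how binding perturbs the particle's internal
dynamics. No docking engine or MD engine is run here: poses, interaction
energies and trajectories are *inputs*, and a synthetic-data layer generates
all of them with known ground truth so every stage is testable at desk scale.

# Binding-site identification from ensemble docking

Ensemble docking produces many ligand poses across receptor snapshots, all
expressed in one common receptor frame. The pose-pose metric is the ligand
RMSD **without re-superposition**:
\[
d(a,b) = \sqrt{\tfrac1m \sum_{i=1}^m \lVert a_i - b_i\rVert^2},
\]
because superposing poses onto each other would erase exactly the spatial
distinction between binding sites. Poses are grouped by average-linkage
agglomerative clustering cut at a distance threshold (default **5 Å**):
no cluster count is fixed a priori, so both a coarse surface map (tens of
groups) and a handful of candidate sites emerge from the same dendrogram at
the same cut. The threshold is a package default, chosen to sit between the
intra-site pose scatter (≈1–3 Å for a converged docking funnel) and
inter-site distances on a nucleosome-sized particle (≥10–15 Å); it is
configurable and recorded in outputs. Ties (equal sizes, equal scores) are
broken deterministically by lowest pose id, so clustering is invariant under
pose relabeling.

A site model is the cluster's **best-scored pose** (ties to lowest id) plus
its contact residues: every residue with a heavy atom within 4.0 Å
(inclusive) of a ligand heavy atom. Which clusters count as biologically
interesting sites is judgment, not an algorithm, so site selection beyond
cluster rank is an explicit caller-supplied subset (`keep =`), never guessed.

Sites to be simulated together must not crowd one another. `partition_sites()`
greedily colors the conflict graph (edge = centers closer than
`min_separation`), visiting sites in id order; every within-group pair is
guaranteed separated by at least the threshold. Greedy coloring is not
minimal in general, but is deterministic and optimal for the small site sets
(≈6) this targets.

# LIE energetics

The linear interaction energy estimate of a standard binding free energy is

\[
\Delta G = \alpha\,(\langle E_{vdW}\rangle_{bound} - \langle E_{vdW}\rangle_{free})
         + \beta\,(\langle E_{el}\rangle_{bound} - \langle E_{el}\rangle_{free})
         + \gamma ,
\]

with the method's canonical empirical coefficients **α = 0.18, β = 0.5,
γ = 0** as defaults (configurable, recorded in output). The parameterization
actually used for any given published table is rarely recoverable, so the
package claims only self-consistency of the ΔG°↔K conversion, not
reproduction of ΔG° from raw energies.

Interaction-energy series from MD are autocorrelated, so naive `sd/sqrt(n)`
errors are too small. Each component mean carries a **block-averaged
standard error**: the series is split into `n_blocks = 10` contiguous equal
blocks (remainder truncated) and SE = sd(block means)/√10. The ΔG error
propagates the four component SEs through the linear formula. With 10 blocks
per series the 2·SE interval behaves as a t-interval with roughly 36 pooled
degrees of freedom, so its coverage sits near `P(|t36| < 2)` ≈ 94.7% rather
than the Gaussian 95.4% — fixed-seed coverage audits must budget for that
gap.

Free energies convert to equilibrium constants under the **1 M standard
state** at **T = 300 K**:
\[
K = \exp(-\Delta G^\circ / RT)\ \mathrm{M^{-1}},\qquad
R = 1.9872\times10^{-3}\ \mathrm{kcal\,mol^{-1}K^{-1}},
\]
reported in mM⁻¹ (÷1000). These two conventions are forced: they are the
unique pair under which a published six-site ΔG°/K table the package's tests
use is self-consistent to all four printed decimals (R's round-half-even
matching the table's formatting). `K_to_delta_g()` is the exact inverse.

`ligand_stoichiometry()` reports the exact concentration ratios of an
in vitro binding experiment (ligands per particle and per subunit) without
rounding; e.g. 100 µM ligand against 60 nM 36-nucleosome fibers gives
1666.67 per fiber and 46.30 per nucleosome, which coarse prose conventions
may render as "~1,600" and "45" — the package leaves formatting to the
caller.

# Hydration and dewetting

A water is its oxygen; hydrogens are ignored. Two counts are distinguished:

* **first shell** (default cutoff 3.5 Å, inclusive): a water counts for a
  residue when its oxygen is within the cutoff of any heavy atom of that
  residue. Waters shared between residues appear in each per-residue count;
  the *net* count deduplicates them. Both are reported, since "number of
  waters bound to residues" is ambiguous on exactly this point.
* **site occupancy** (default cutoff 10 Å): per-frame count of oxygens in a
  sphere anchored at the site's representative-ligand centroid (the natural
  anchor when a published sphere's center is unspecified), averaged over the
  trajectory with a 10-block SE.

**Dewetting** is the apo-minus-holo occupancy at matched sites, with SEs in
quadrature. Distances are unwrapped-coordinate Euclidean (no periodic
boundary handling): the analyses target solute-centered, desk-scale systems.
All boundaries are inclusive (≤), so a count is monotone in the cutoff and
invariant under joint rigid motion of structure and waters.

# Dynamics

`kabsch_superpose()` computes the least-squares rigid transform via SVD with
the determinant sign fix, so reflections are never returned; fewer than 3
atoms or collinear selections are errors. RMSD series optionally superpose
each frame first; the "plateau" summary is the mean ± sd over the final 25%
of frames (configurable), the usual way a converged equilibration level is
quoted. RMSF is \(\sqrt{\langle\lVert r_i - \langle r_i\rangle\rVert^2\rangle}\);
for isotropic per-axis jitter σ both statistics have the closed form σ√3,
which the tests exploit.

The dynamic cross-correlation map is the scalar (dot-product) normalized
covariance
\[
C_{ij} = \frac{\langle \Delta r_i \cdot \Delta r_j\rangle}
              {\sqrt{\langle\lVert\Delta r_i\rVert^2\rangle
                     \langle\lVert\Delta r_j\rVert^2\rangle}},
\]
unweighted over the full trajectory (no windowing, no mass weighting),
matching the style of the classic C-alpha correlation maps. Global motion is
removed by a deterministic two-pass superposition onto the evolving mean
structure; trajectories generated in a common frame can skip it
(`superpose = FALSE`) — for maps over few atoms that is also the unbiased
choice, since removing 6 rigid-body degrees of freedom induces a small
negative correlation bias of order 1/n. A zero-variance atom yields a
flagged zero row/column (diagonal 1) rather than NaNs.

**Correlation changes** between conditions are the pairs with
\(|C^{holo}_{ij} - C^{apo}_{ij}| \ge 0.2\) (default, configurable — published
map-drawing thresholds are rarely stated), classified *enhanced* when
\(|C^{holo}|>|C^{apo}|\) and *weakened* otherwise (the measure-zero tie goes
to *weakened*). Swapping conditions flips every label; raising the threshold
never adds edges.

# The synthetic stated world

The generators emit the world the analyses were designed for, each with a
`ground_truth()` sidecar:

* **Pseudo-nucleosome**: 8 histone-like chains + 2 DNA-like strands, one
  bead per residue (CA/P) on helical arcs, 100 residues per chain,
  3.8 Å spacing (the C-alpha virtual bond), with landmark residues mimicking
  the H4 N-terminal tail (resids 18–23) and the acidic-patch glutamates
  (E91/E92 on the primed H2A copy; relocated to the chain end when chains
  are shorter than 92 residues). Geometry is synthetic: it supports
  selection/contact logic, not structural realism.
* **Energy series**: stationary AR(1),
  \(x_t = \mu + \phi(x_{t-1}-\mu) + \varepsilon_t\), the simplest process
  with a tunable correlation time — exactly what a block-error estimator
  must handle. Defaults: 2000 frames (200 ns at one sample/100 ps),
  σ = 2.5 kcal/mol, φ = 0.8 (per-frame; correlation time ≈0.9 ns, on the
  conservative/slow side for interaction energies). The planted ΔG under
  given LIE parameters follows from the means via `true_delta_g()`.
* **Pose clouds**: rigid ligand copies (8 heavy atoms, no torsions —
  position-only clustering needs nothing more) displaced isotropically
  (σ = 1 Å) around site centers ≥15 Å apart, 20 poses/site, scores
  Gaussian (−5 ± 1 kcal/mol), snapshot indices round-robin. Note the
  displacement tail: a rare multi-sigma pose can land far enough for average
  linkage to isolate it as a singleton at a 5 Å cut, so exact cluster-count
  recovery is typical for these settings but not guaranteed.
* **Water configurations**: exact planted in/out counts around a center with
  a 0.1 Å guard margin on both sides of the cutoff sphere, making counting
  assertions exact.
* **Correlated trajectories**: zero-mean Gaussian displacements with a
  block-structured atom-atom correlation matrix applied i.i.d. per axis
  (expected DCCM = that matrix), σ = 0.5 Å; non-PSD specifications are
  rejected before sampling.

One global seed expands into independent per-stage child seeds by fixed
offsets (`child_seed()`), keeping runs bit-reproducible.

What the generators do **not** emulate: real nucleosome geometry, solvent
structure, force-field energetics, docking score landscapes, or
conformational gating. A green test therefore establishes the *estimators*
(clustering, LIE arithmetic and errors, counting, correlation recovery) —
not agreement with any wet-lab or full-MD quantity.

# Numerical and design choices

* PDB I/O is fixed-column; both ATOM and HETATM parse; alternate locations
  resolve to highest occupancy then first; insertion codes are rejected
  loudly. Chain labels longer than one character (e.g. `H2A'`) are written
  to the segment-id columns (73–76), CHARMM/NAMD style, and preferred on
  read, so primed-copy names round-trip. Coordinates round-trip to the
  format's 10⁻³ Å. Magnitudes ≥10⁵ Å are a field-overflow error; the
  [10⁴, 10⁵) range falls back to two decimals to keep columns fixed.
* Snapshot extraction targets times `start + k·(len/n)` (k = 0…n−1) and
  snaps each to the nearest stored frame in the window, ties to the earlier
  frame — deterministic, and exact when the window length is a multiple of
  the frame spacing (e.g. 120 snapshots from a 6 ns window at 50 ps).
* Selections are 1-based atom index vectors (the R idiom), built by
  named-argument conjunction (`chain =`, `resid =`, `name =`, `element =`);
  residue numbering is 1-based as in the PDB format itself.
* `cutree(h = cutoff)` on `stats::hclust(method = "average")` provides the
  dendrogram cut; all science-side logic (metric, ordering, ties,
  representatives, contacts, partitioning) is implemented here.
* Degenerate inputs fail early with specific messages: empty structures,
  mismatched atom counts, mislabeled bound/free states, K ≤ 0, fewer than
  2×n_blocks points for a block SE, <2 frames for fluctuation statistics.

# Known limitations

* The LIE 2·SE interval undercovers the Gaussian nominal level (t-tails
  from 10-block SEs); short fixed-seed coverage audits therefore carry a
  material false-failure probability against thresholds set near the
  nominal level. Increasing `n_blocks` trades this against block-length
  bias.
* Average-linkage cluster counts are sensitive to single extreme-tail poses
  (singleton splits); a practitioner inspects the dendrogram gap rather
  than trusting one fixed cut.
* No periodic-boundary or minimum-image handling; inputs must be unwrapped
  and solute-centered.
* The hydration layer counts oxygens only; orientation, residence times and
  H-bonding are out of scope.
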