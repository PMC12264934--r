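---
title: "Ranking unbinding kinetics with path-variable ratchet dynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ranking unbinding kinetics with path-variable ratchet dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pathratchet)
```

## The model

Ligand unbinding from a deep binding pocket is a rare event: the
rate-limiting step is typically the translocation over the first free-energy
barrier, out of the orthosteric site into a shallower vestibular site. The
package's premise is that a *gently rectified* dynamics — one that never
pushes the system forward but forbids it from losing progress — preserves
the ordering of barrier heights in its first-passage times. If that holds,
biased escape times measured over replicas rank systems the same way
experimental dissociation rates do, at a tiny fraction of the cost of
unbiased simulation.

Two ingredients define the method.

**Path collective variables.** A frameset of $P$ milestones
$x_1 \dots x_P$ spans the unbinding channel from the bound pose to the
translocated state. For a configuration $x$,

$$S(x) = \frac{\sum_{i=1}^{P} i\, e^{-\lambda d_i^2}}{\sum_{i=1}^{P} e^{-\lambda d_i^2}},
\qquad
Z(x) = -\frac{1}{\lambda}\ln \sum_{i=1}^{P} e^{-\lambda d_i^2},$$

where $d_i^2$ is the mean-square deviation (Å²) of $x$ from milestone $i$,
computed after optimal superposition with per-atom *align* weights and
averaged with per-atom *displace* weights. $S$ runs from 1 (bound) to $P$
(translocated); $Z$ measures how far the system strays from the path.
$\lambda$ controls the smoothness of the interpolation between milestones;
we use the standard spacing rule $\lambda = 2.3 / \overline{\mathrm{MSD}}$
over adjacent milestones, so the exponential weight decays by roughly an
order of magnitude per milestone. With that $\lambda$, $S$ evaluated at the
milestones themselves is strictly increasing, and $Z$ at a milestone is
non-positive (one term of the sum is exactly 1).

**The ratchet.** With $\rho(t) = (\mathrm{CV}(t) - \mathrm{CV}_0)^2$ and
$\rho_m(t) = \min_{\tau \le t} \rho(\tau)$,

$$U_{\text{bias}} = \begin{cases}
\frac{k}{2}\,\big(\rho - \rho_m\big)^2 & \rho > \rho_m\\
0 & \text{otherwise.}
\end{cases}$$

The bias is zero whenever the system is at (or beyond) its best progress:
barriers are still crossed by thermal fluctuations, merely rectified. We
initialise $\rho_m$ to $\rho$ at $t=0$ (no bias at the start) and evaluate
the bias against the *previous* step's $\rho_m$ before updating it, so the
force is never self-referential. A harmonic upper wall
$U_w = k_w (Z - z_0)^2$ (no $\tfrac12$ — the PLUMED convention, so published
force constants carry over numerically) confines the orthogonal excursion.

## The toy systems and what they emulate

Real receptors are replaced by analytic channel potentials: a flat axis with
a Gaussian barrier of amplitude $\Delta E$, harmonic transverse confinement,
and soft end walls. Because the transverse term and the end walls vanish on
the axis where the Gaussian peaks, the saddle height over the bound basin
equals $\Delta E$ *exactly, by construction* — no numerical saddle search. A
"mutant family" is a set of such systems identical except for $\Delta E$
(defaults 3–7 $k_BT$, mirroring the span of effects binding-site mutations
have on a slowly dissociating antagonist).

Defaults: $T = 303$ K, $dt = 0.01$ ps, mass 12 amu, channel length 30 Å
with the barrier (width 2 Å) at 15 Å, transverse constant
2 kcal mol⁻¹ Å⁻², ratchet $k = 0.05$ kcal mol⁻¹ on $S$ with
$\mathrm{CV}_0 = P = 20$, and a $Z$ wall at 10 Å² with
$k_w = 1000$ kcal mol⁻¹ Å⁻⁴.

**Friction.** The Langevin friction default is 0.05 ps⁻¹, and this is a
deliberate design choice. In the overdamped regime the accumulated ratchet
penalty behaves as a quasi-hard wall trailing the system's best progress,
and the crossing time is dominated by the driven climb rather than by
thermal activation — escape times then barely resolve the barrier height,
which defeats the purpose of the ranking experiment. At low friction escape
stays thermally activated and the family's mean first-passage times increase
strictly with $\Delta E$ across every base seed we probed (32/32, smallest
adjacent-gap ≈ 3 SEM at 20 replicas). All of these are `toy_system()`
arguments, not constants.

The integrator is BAOAB; normal deviates come from R's RNG, so a run is
bit-reproducible from `set.seed()` and a zero-force, zero-temperature step
leaves coordinates untouched. With the ratchet constant set to zero the
trajectory is bitwise identical to an unbiased run with the same seed.

What the toys deliberately do **not** emulate: solvent granularity,
multidimensional exit pathways, conformational gating, or any chemistry in
the fingerprints. Passing the ranking property on toys shows the
*protocol* (bias + statistics) is sound; it says nothing about force-field
or sampling adequacy on a real receptor.

## Unbinding criteria

`evaluate_all_criteria()` sweeps the standard criterion/cutoff grid: the
ligand–anchor atom-pair distance at {6, 9, 12} Å (12 Å marks the upper edge
of the bound free-energy basin), ligand RMSD from the starting pose at
{6, 10, 14} Å, ligand-to-site COM distance at {5, 10, 15} Å, and percent
SASA at {10, 20, 30, 40} %. Events are first crossings with a closed
boundary (a single frame at or beyond the cutoff triggers; recrossings are
ignored, since past the translocation threshold the end states are sampled).
Never-crossing series are censored at the last frame, and censoring
propagates into the statistics. The solvation-shell test declares the ligand
unbound when no non-solvent, non-ion atom lies within 6 Å (two shells); the
boundary is closed — an atom at exactly 6.0 Å still counts as a contact.

SASA is Shrake–Rupley with probe 1.4 Å and 960 deterministic
golden-spiral points per atom; the percent-SASA reference is the ligand's
own conformer with the receptor deleted, recomputed each frame, so the
fraction is exactly 100 % for a fully solvated pose. Ligand RMSD is computed
after receptor superposition by default (configurable), since the receptor
frame is the natural reference for pose displacement.

## Interaction fingerprints

A fingerprint is the *set* of (residue, class) contacts — hydrophobic,
aromatic, hydrogen-bond donor/acceptor, ionic, cation–π — plus a companion
set of nonspecific heavy-atom contact residues. Distances: contact 4.5 Å,
hydrophobic 4.0 Å, H-bond 3.5 Å (donor angle ≥ 150° when explicit hydrogens
exist, distance-only otherwise), ionic 4.5 Å, aromatic and cation–π 5.0 Å to
ring centroids. These defaults are this package's own choices in line with
common fingerprint practice; they are fully exposed in `ifp_config()`.
Atom typing comes from a per-atom tag so pseudo-atomic fixtures need no
chemistry perception; a crude element-based typer exists for untyped input.

The fingerprint residence time is the first frame whose Tanimoto (Jaccard)
distance to the frame-1 fingerprint reaches the cutoff (default 0.3, the
value at which this estimator correlates best with experimental rates in
practice — it fires on the *early* loss of native contacts rather than on
full egress). Tanimoto distance on sets is a true metric; the empty-empty
case is defined as 0.

## Clustering and net flow

Analysis frames are taken every 100 ps from the start until the ligand RMSD
first reaches 14 Å, plus a 5 ns margin. Frames are featurised by
fingerprint, ΔCOM (displacement of the ligand COM from its initial
position; drift correction optional and off by default, as the toys have no
receptor drift) and ligand RMSD. Clustering is average-linkage agglomerative
on the Tanimoto distance over specific features *and* nonspecific contacts
(so poses without specific interactions still separate), cut at 0.4, with
clusters relabelled by increasing mean ΔCOM — cluster 1 is the bound state.
The procedure is deterministic. Directed transition counts between
consecutive analysis frames are aggregated across replicas first, then the
net flow between two clusters is |count(i→j) − count(j→i)| — aggregation
before differencing was an open choice; we aggregate first so replicas with
opposite recrossings cancel.

Loop flexibility is profiled over the path progress by binning frames at
S < 4 (orthosteric), 4–16 (transition) and ≥ 16 (vestibule) and reporting
the per-bin spread of the loop atoms about their bin-mean structure; empty
bins are reported with n = 0, not as errors.

## Ranking statistics

Replica summaries are mean ± SEM (sd/√n). Censored replicas are **kept at
their cap value** by default: dropping them biases the mean fast exactly for
the slowest systems, which is the worst place to be biased; `drop` and
`cap2` policies are available and logged. Spearman uses average ranks for
ties; Pearson acts on raw values; both delegate to `stats::cor` and are
verified against textbook formulas in the tests. Regression is ordinary
least squares with an optional removal of the m = 2 largest-residual systems
(refit reported with the excluded ids); predictions outside the fitted
pk_off range are flagged as extrapolations. Classification splits systems at
pk_off = 1.5 (slow vs fast) against the median computed residence time, and
reports accuracy and the Matthews coefficient, with MCC defined as 0 when a
confusion margin vanishes. The bootstrap resamples s replica times per
system with replacement, B times per sample size, and reports the mean and
sd of the resulting Spearman ρ; tie-degenerate resamples (constant means)
are recorded and excluded with a warning rather than silently coerced.

## Numerical choices

* Log-sum-exp evaluation of S and Z; stable to λ·d² ≈ 10⁴. The naive
  direct sum (used as the test oracle) underflows near λ·d² ≈ 700, which
  bounds the domain on which the two are compared.
* Superposition by weighted SVD (Kabsch) with the reflection branch forced
  to a proper rotation; fewer than 3 points is an error, and point-particle
  toy paths set `use_alignment = FALSE` instead.
* Frameset re-spacing by linear interpolation along cumulative root-MSD arc
  length; an optional k-medoids (PAM) reduction on pairwise ligand RMSD
  precedes it for non-monotone guesses. Adjacent-MSD spread beyond 15 %
  relative warns.
* λ from the spacing rule errors on duplicate milestones (zero adjacent
  MSD) rather than returning infinity.
* hclust heights are monotonised (cummax) before cutting to absorb
  floating-point wiggles from tied distances.
* The pocket fixture records its pair-distance, RMSD and COM ground truth
  in closed form from the constructed geometry; the SASA and Tanimoto
  crossing frames are recorded from the corresponding modules at
  construction and serve as self-consistency anchors, and are labelled as
  such.

## Problem sizes

The shipped experiments are sized for interactive use: 5 toy systems × 20
replicas (≈ 10⁴–10⁵ integrator steps each) for the family ranking; 100
random framesets (P ≤ 10, ≤ 30 atoms) for the path-variable oracle; a
~115-atom pocket fixture over 60 frames for the criteria; 100 seeds × 6
systems × 20 exponential replicas for rank recovery; 500 bootstrap
resamples; 50 seeds for planted-cluster recovery. The full test suite runs
in about two minutes on one CPU.

## Limitations

* The engine integrates analytic toy potentials only; it is a protocol test
  bed, not an MD engine for real systems (no force fields, solvent, or
  constraints). Real-system use consumes externally generated trajectories
  through the analysis modules.
* Fingerprint typing is tag-based; aromatic rings are represented by
  centroid pseudo-atoms, and water-mediated contacts are not detected.
* A single reference path is assumed; multiple-pathway detection and
  committor/Markov-state analyses are out of scope.
* Absolute rates are not predicted — only orderings and regressions against
  experimental rates.
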