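---
title: "Supersecondary motif decomposition and novelty scoring: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Supersecondary motif decomposition and novelty scoring: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smotifr)
```

## The model

A protein chain is decomposed into **Smotifs**: pairs of consecutive regular
secondary-structure elements (α-helix or β-strand) joined by a loop. Because
the C-terminal element of one Smotif is the N-terminal element of the next, a
chain with $k$ regular elements reads as a string of $k-1$ overlapping
Smotifs. The decomposition turns the vague question "is this fold new?" into
countable ones: does the structure contain motif geometries never seen
before, and are its motifs rare or common in the known repertoire?

Each Smotif is characterized at two levels:

1. **Class** — the kinds of the two bracing elements: `HH`, `HE`, `EH`, `EE`.
2. **Geometry** — four internal coordinates computed from the principal axes
   $M_1$, $M_2$ of the elements' Cα traces. With $P_1$ the Cα of the last
   residue of SS1, $P_2$ the Cα of the first residue of SS2 and
   $L = P_2 - P_1$:
   * $D = |L|$ — the junction distance (Å);
   * hoist $\delta = \angle(L, M_1) \in [0, 180]$;
   * packing $\theta = \angle(M_1, M_2) \in [0, 180]$;
   * meridian $\rho \in [0, 360)$ — the azimuth of $M_2$ about $M_1$.

### The meridian convention

The azimuth needs a reference plane. We build the orthonormal frame
$e_1 = M_1$, $e_2 = $ the component of $L$ orthogonal to $e_1$ (in the plane
$\Pi$ spanned by $M_1$ and $L$), $e_3 = e_1 \times e_2$ (the normal of
$\Pi$; the plane $\Gamma$ is spanned by $e_1$ and $e_3$), and define

$$\rho = \operatorname{atan2}(M_2 \cdot e_3,\; M_2 \cdot e_2) \bmod 360^\circ.$$

Any fixed convention with a 0–360° span works for classification, because
only bin co-membership matters; we chose this ordering of the two components
because it makes the chirality behaviour exact: a mirror reflection of the
whole motif maps $\rho \mapsto 360^\circ - \rho$ while leaving $D$, $\delta$,
$\theta$ unchanged. The property-based tests assert exactly that. Absolute
$\rho$ values from other implementations with a different zero or sign are
not comparable; their bins are, after a constant relabeling.

When $\delta$ is within 1° of 0° or 180°, $L$ is parallel to $M_1$ and
$\Pi$ is undefined; the Smotif is flagged degenerate, $\rho$ is reported as
0 and the motif is still binned deterministically.

### The principal axis

The element axis is the smallest-moment eigenvector of the Cα inertia tensor
(unit masses), with the sign fixed N→C. One practical detail: on a short
helix with a fractional final turn, the raw inertia axis of the bare Cα
points tilts by several degrees because the helical phase is unbalanced. We
therefore pass the trace through a short moving average (window ≤ 4
residues, about one helical turn) before forming the tensor. The averaging
is linear, so rigid-motion invariance and the mirror property are untouched;
straight and zigzag (strand) traces are unchanged by symmetry, and the
recovered axis of an ideal 10-residue helix is within 2° of its construction
axis instead of ~7°.

## Secondary-structure input

Elements are maximal runs of identical 3-state labels, split at chain breaks
(Cα–Cα > 4.5 Å), with minimum lengths of 4 residues for helices and 3 for
strands (configurable): three Cα positions are the minimum for a stable
axis, and hydrogen-bond-defined helices are at least one turn long anyway.
Shorter runs are demoted to coil and absorbed into the adjacent loop, which
keeps the Smotif string gapless. The labels themselves can come from four
sources, in decreasing order of fidelity to the hydrogen-bond definition:

* a DSSP output file ([read_dssp()]), reduced 8→3 states as H, G, I → `H`;
  E → `E`; B, T, S, blank → `C` (isolated bridges lack the extended geometry
  a strand axis needs; the helix set is configurable);
* deposited HELIX/SHEET header records ([pdb_header_ss()]);
* a Cα-trace assignment ([assign_ss_ca()]) implementing the published P-SEA
  distance/angle criteria, cross-checked against an independent
  implementation of the same criteria;
* generator ground truth for synthetic chains.

The choice matters. Author header records are hand-curated per entry:
two depositions of the same protein can disagree on element termini by a
couple of residues, which shifts anchors and axes and can move a motif
across a bin boundary. The Cα-trace assignment applies identical criteria
everywhere — on the two independently solved lysozyme entries bundled with
bio3d it yields identical decompositions (all bins shared), where the header
records share none. It is, however, conservative: it finds the prominent
elements and misses marginal short ones, so element counts are lower bounds
relative to DSSP. Analyses that compare against published, DSSP-based
element counts should be run with DSSP files.

## Geometry binning

The default ("tailored") scheme uses 4 Å distance bins capped at 40 Å
(larger distances clamp into the last bin), 60° hoist and packing bins from
0°, and 60° meridian bins offset by 30°, so [330°, 30°) is one wrapped bin.
All intervals are half-open; angles exactly at 180° fold into the last bin,
making assignment a total function — fuzz tests assert totality and
boundary stability. That yields $10 \times 3 \times 3 \times 6 = 540$
geometric cells per class; real libraries occupy far fewer, and both the
total and occupied counts are exposed rather than conflated
([n_cells()], the library's entry table). Alternative schemes are named by
their widths (`"2_45_45_45"`, `"8_90_90_180"`, ...) and evaluated by
[evaluate_binning()]: sample same-bin and different-bin pairs, superpose
each pair (Kabsch over the bracing Cα, anchored at the loop junction and
trimmed to the shorter element — loops excluded, since unequal loops are
exactly what the bin definition abstracts away), and compare RMSD
distributions. A good scheme makes same-bin membership predict sub-Å
similarity; on the bundled real chains all same-bin pairs superpose below
1 Å under the default scheme while different-bin pairs of the same class
sit at a median of several Å.

## The frequency library

Fold classifications put many near-identical structures under one fold, so
raw motif counts would measure sequence redundancy. The library instead
draws one structure per fold uniformly at random, tallies bins, repeats for
`n_rounds = 100` rounds, and averages: a fold with several alternative
structures contributes the expected count over its members. With one
structure per fold the result is exact and round-independent; the
enumerable two-structure case is asserted against its analytic expectation.
One seeded generator drives the whole build, so a (seed, n_rounds) pair
reproduces the library bit-for-bit.

Frequencies are normalized **globally** over the occupied bins of all four
classes (a single simplex) because the novelty score multiplies frequencies
of mixed-class motifs in one product; a per-class mode exists for per-class
frequency panels. First-seen dates per bin are taken over *all* structures
(not the sampled representatives), feeding the saturation curve: the
cumulative count of distinct bins per class over deposition time, a
monotone step function whose terminal value is the occupied-bin count.

## Novelty scores

For a structure with motifs in bins $i = 1..N$ with library frequencies
$fr_i$, the score is the length-normalized log-product

$$S = \frac{1}{N} \sum_{i=1}^{N} \ln \max(fr_i, \epsilon),$$

so $S$ is the log of the geometric-mean frequency: independent of $N$ when
all frequencies are equal, strictly monotone in every $fr_i$, and lower for
rare-motif-enriched structures. The floor $\epsilon$ defaults to half the
smallest nonzero library frequency: unseen geometries keep $S$ finite but
rank below everything seen. Scores are standardized over the scored
population with the population (not sample) standard deviation — the
Z-scores then have mean 0 and SD 1 by construction, which the tests assert.
A population of fewer than two distinct scores is refused rather than
silently standardized; this genuinely occurs on tiny libraries where every
occupied bin has the same frequency.

Comparison against a reference set asks two nested questions per query
motif: is its (class, bin) occupied in the reference library at all
("new geometry" if not), and if occupied, does any same-bin reference motif
have bracing elements of comparable length — within 2 residues for strands
and 4 for helices, per element kind, boundary inclusive ("unique flanking
secondary structures" if not). New geometry implies unique FSS, so the
counts nest; an invariant test keeps them that way. Shared-motif counting
between two structures is the multiset intersection of their bin labels.

## Structural features

Internal contacts are heavy-atom pairs (one atom per bracing element)
within 4.5 Å, loops excluded, and for zero-length loops the covalent
junction pair excluded. This symmetric distance criterion replaces
software-specific contact typing (hydrogen bond vs polar vs hydrophobic):
the analyses here use contacts only as a scalar count, and the cutoff is a
parameter for sensitivity checks. The contact *ratio* divides by Smotif
size, which by default counts only the bracing residues (`"braces"`); a
`"total"` mode includes the loop. Solvent accessibility is Shrake–Rupley
with a 1.4 Å probe, 192 deterministic golden-spiral sphere points per atom
and a documented van der Waals radii set (C 1.70, N 1.55, O 1.52, S 1.80,
Se 1.90 Å, default 1.70), computed in the context of all chain atoms and
averaged per Smotif residue with or without the loop; a per-atom ASA vector
(e.g. aggregated from a DSSP ACC column) can be injected instead.

## The synthetic generator

The generator provides ground truth at three levels:

* **Ideal elements** — helix: 1.5 Å rise, 100°/residue twist, 2.3 Å radius;
  strand: 3.3 Å rise with ±1.0 Å zigzag. Canonical textbook values, fixed
  constants, consecutive Cα spacing ~3.8 Å.
* **Inverse placement** — given a target $(D, \delta, \theta, \rho)$, pose
  an ideal second element so the forward computation recovers the target.
  Under our frame convention the solution is closed-form:
  $M_2 = \cos\theta\, e_1 + \sin\theta(\cos\rho\, e_2 + \sin\rho\, e_3)$
  with $P_2 = P_1 + D\,(\cos\delta\, e_1 + \sin\delta\, e_2)$. Placement
  *verifies itself* by forward computation and errors rather than returning
  an approximation; degenerate targets ($\delta$ or $\theta$ at 0°/180°
  with a pinned $\rho$) are rejected as infeasible. Loop Cα are decorative
  — a gently bowed interpolation that no geometry operation reads — but
  must span the junction: `loop_len` must satisfy
  $D/(\mathrm{loop\_len}+1) \le 4.2$ Å or the chain-break detector would
  sever the string.
* **Fold populations** — an abstract bin universe (default 540, matching
  the default scheme's per-class cell count) with Zipf base frequencies
  $p_k \propto k^{-s}$, "known" folds sampling from the base distribution
  and "novel" folds from a mixture placing mass $\lambda$ on the rarest
  quartile. This emulates the statistical signature of a fold census —
  heavy-tailed motif usage, novel folds enriched in rare motifs — and
  nothing else.

What the generator does **not** emulate: real loop conformations, side
chains, hydrogen-bond physics, β-sheet pairing constraints, or the
empirical within-bin clustering of real motif geometries. Passing the
round-trip and planted-novelty tests therefore demonstrates that the
measurement and scoring machinery is correct, not that any biological claim
holds; the real-structure checks on the bundled crystal structures carry
that weight, at the small scale available offline.

## Numerical choices and validation scale

* Round-trip tolerance: (0.5 Å, 3°, 3°, 5°) — the generator verifies each
  placement at this tolerance and the test suite sweeps 100 random feasible
  targets (recovery is ~100%, asserted ≥ 95).
* Rigid-motion invariance asserted at $10^{-6}$ over randomized
  rotations/translations; mirror $\rho$-flip at $10^{-6}$ circular.
* Planted-novelty recovery: $\lambda = 0.8$, Zipf $s = 1.5$, 200 known +
  200 novel folds of 3–12 motifs, 10 seeds; the novel-group mean Z is below
  the known-group mean with a stable sign in every seed (typical gap ≈ −1.9).
* Bin-quality evaluation: all same-bin pairs plus up to a few hundred
  sampled different-bin pairs on the four bundled real chains (two
  lysozyme entries, the two HIV-protease chains; ~16 motifs). These sizes
  keep the whole suite fast while leaving every statistical direction
  detectable; they are deliberate package defaults, not measurement limits.

## Known limitations

* The offline real-structure sample is tiny and includes near-duplicate
  chains, so the >75% same-bin sub-Å fraction it reproduces is a
  consistency check, not a survey; a proper evaluation needs a diverse,
  fold-non-redundant chain set and DSSP assignments.
* Absolute $\rho$ values are convention-bound (see above).
* The Cα-based assignment undercounts marginal elements relative to DSSP,
  shifting decomposition counts; element-count-sensitive comparisons
  should fix the assignment source.
* Historical census quantities (archive-wide motif totals, novel-fold
  fractions over decades of depositions) require dated database snapshots
  and are out of scope; the machinery to compute them on such snapshots
  (dated libraries, saturation curves, reference comparisons) is all here.
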