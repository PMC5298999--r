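---
title: "Voronoi interface models of antibody-antigen complexes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Voronoi interface models of antibody-antigen complexes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(igvor)
```

## The model

`igvor` analyses antibody-antigen (Ig-Ag) complexes through a geometric,
parameter-free definition of their interface. Each heavy atom is a ball with
its van der Waals radius expanded by a water-probe radius $r_w$ (default
1.4 Å): the *solvent-accessible model* (SAM). The power diagram (weighted
Voronoi diagram with weights $r^2$) of the balls partitions the molecular
volume into *Voronoi restrictions* — the intersection of each ball with its
power cell. The restriction volume $\mathrm{Vol}(a)$ measures the packing of
atom $a$; the boundary of the union of balls is the solvent-accessible
surface, charged per atom.

Two atoms are *in contact* when their restrictions share a facet of positive
area. Contacts of type (Ig, Ag) are direct interface pairs; a water whose
restriction touches both partners is a first-shell interfacial water and
contributes water-mediated pairs. The interface atom set $I = I_{Ig} \cup
I_{Ag}$ collects the partner atoms appearing in either pair type. The
*buried surface area* (BSA) of an atom is the accessible area it loses
between the unbound reference (its partner alone, at bound coordinates,
waters removed) and the complex. Each partner's binding patch carries a
*shelling order* $SO(a)$: boundary atoms (still solvent-exposed, or adjacent
to an exposed non-interface atom of the same partner) have $SO = 1$, and
every other patch atom is one more than the minimum over its patch
neighbors — a hop distance to the patch rim that generalizes the core-rim
picture.

From the interface model, four families of descriptors are derived:

* **Average BSA per interface atom**, per side:
  $\overline{bsa}_{Ig} = BSA_{Ig}/|I_{Ig}|$ and
  $\overline{bsa}_{Ag} = BSA_{Ag}/|I_{Ag}|$. These act as curvature proxies:
  a small convex ligand buries much of its surface per atom, a flat
  protein-protein interface much less. They separate chemical, peptide and
  protein ligands.
* **IVW-IPL** (inverse volume-weighted internal path length):
  $\sum_{a \in I} SO(a)/\mathrm{Vol}(a)$. It grows with interface size,
  isotropy (deep patches reach high $SO$) and packing (small restriction
  volumes), blending the enthalpic and entropic signals of the interface.
* **ANSO** (average normalized shelling order): the IVW-IPL of a region's
  interface atoms divided by their count — a size-free packing-depth score
  used to compare CDRs.
* **NIS$^{charged}$**: the fraction of charged residues (default ASP, GLU,
  LYS, ARG, HIS) among solvent-exposed residues that contribute no interface
  atom, an electrostatics/solvent descriptor of the non-interacting surface.

Free energies follow the standard state: $-\Delta G = -RT\ln(K_d/c^\circ)$
with $c^\circ = 1\,\mathrm{M}$ and $R = 1.9872 \times 10^{-3}$
kcal mol$^{-1}$ K$^{-1}$; at 298 K one order of magnitude in $K_d$ is
$RT\ln 10 \approx 1.4$ kcal/mol.

## Geometry engine and numerical choices

The model's contract is geometric (restriction volumes, facet adjacency,
per-atom accessible areas); the engine honoring it is hybrid:

* **Analytic fast path.** A ball clipped by radical planes whose spherical
  caps are pairwise disjoint has closed-form restriction volume and exposed
  area (ball minus caps). This covers every one- and two-ball configuration
  and most atoms of sparse fixtures, and is exact to machine precision.
* **Deterministic quadrature otherwise.** When caps interact, volumes are
  integrated radially over a Fibonacci direction lattice (default 4096
  directions) and areas by Fibonacci surface sampling (default 4096 points
  per ball). Facet areas on radical planes are estimated with a 512-point
  sunflower lattice; two restrictions are neighbors when the facet area
  exceeds $10^{-6}$ Å$^2$.
* **Rigid-motion covariance.** All sampling lattices are expressed in a
  local frame built from each ball's neighbor normals (and each facet's
  nearest third ball), so rotating or translating the complex transforms
  the sample points identically: volumes, areas, contacts and shelling
  orders are invariant to better than $10^{-6}$ relative, as the test suite
  asserts.
* **Degeneracies.** Coincident equal balls are resolved by symbolic
  perturbation (the lexicographically smaller atom id wins; the loser gets
  an empty restriction) with a warning; a ball contained in another has an
  empty restriction by the power-diagram algebra. Per-atom BSA is floored
  at zero against numerical noise. Iteration is ordered by atom id, and all
  stochastic estimators (the Monte-Carlo union-volume oracle, the rare
  rejection-sampling volume fallback) are seeded, so results are bitwise
  reproducible.

The accuracy claims are not taken on faith: restriction volumes must sum to
an independent Monte-Carlo union-volume estimate within 3 standard errors on
random ball clouds, exposed areas must match a Shrake-Rupley-style oracle
within 1%, and two-sphere configurations must match closed forms to
$10^{-6}$ relative.

One typographic point deserves a note: the defining sum of IVW-IPL is
sometimes typeset as $\sum SO(a)\,\mathrm{Vol}(a)$, but the name (*inverse
volume-weighted*), the role of packing in the denominator, and the
ANSO-based CDR comparisons all require $SO(a)/\mathrm{Vol}(a)$. The division
form is the default; the product form is available via `form = "product"`
for audits.

## Reference states and waters

Restrictions, contacts and shelling orders are computed on the full complex
SAM — both partners plus crystallographic waters — so water-mediated
adjacency is genuine power-diagram adjacency. The unbound reference for BSA
is each partner alone at its bound coordinates with waters excluded (rigid
split, the standard BSA convention). Only first-shell waters (restriction
neighbors of both partners) mediate pairs; water-water chains are not
traversed. Interface atoms reachable only through a water count in
$|I_{Ig}|$ and $|I_{Ag}|$, i.e. in the denominators of the average-BSA
descriptors.

Shelling-order boundary seeding defaults to `"exposed"` (a patch atom with
positive bound exposed area, or adjacent to an exposed same-partner atom
outside the patch, has $SO = 1$); the `"rim"` alternative (adjacency
criterion only) is a configuration flag because the underlying definition
admits both readings.

## Structure input and region annotation

Structures are read from PDB or mmCIF (via `bio3d`); hydrogens are dropped
(the geometry is a heavy-atom model — configurable), alternate locations
resolve to the highest-occupancy conformer with alphabetical tie-breaks, and
waters are kept as their own partner class. Radii come from a named table —
default `"bondi"`, with a configurable fallback radius for exotic elements
in hetero ligands; the table name travels with every structure because
absolute volumes and areas depend on it.

CDR/FR regions follow the IMGT unique numbering: FR1 1-26, CDR1 27-38, FR2
39-55, CDR2 56-65, FR3 66-104, CDR3 105-117, FR4 118-128, with positions
beyond 128 labeled constant/outside-V. Numbering is consumed, never
computed: structures must either carry IMGT numbering or ship a sidecar CSV
of residue ranges per region (overlapping ranges and uncovered Ig residues
are errors). A canonical complex has one heavy chain, one light chain, at
least one ligand chain and a single ligand type; `validate_canonical()`
reports violations without throwing.

## Downstream analyses

**Ligand-type classification.** A CART tree (Gini impurity) on
$(\overline{bsa}_{Ag}, \overline{bsa}_{Ig})$ with depth 2 — at most three
axis-aligned splits, i.e. three separating lines — is evaluated by repeated
stratified 5-fold cross-validation (medians over repetitions, lower-median
convention for even counts). Two baselines calibrate it: a count-preserving
label permutation (median over 10,000 permutations; its expected error has
the closed form $1 - \sum_c n_c(n_c-1)/(n(n-1))$, which the implementation
must reproduce), and a *naive* classifier given only the interface atom
count $|I|$. The tree depth and stratification are configuration: the
published protocol pins neither, and stratification stabilizes the smallest
class at these sample sizes.

**Affinity regression.** $-\Delta G$ is predicted by unweighted k-nearest
neighbors in (IVW-IPL, NIS$^{charged}$) space, features z-scored with
training statistics (a flag restores raw scale; the choice is recorded),
Euclidean distances, stable tie-breaks at the k-th neighbor, default
$k = 10$ with a sweep over $k \in 5..25$. Reports include the fractions of
predictions within 1, 2 and 3 orders of magnitude of $K_d$ (boundary
inclusive), the constant null model (training-mean prediction), and the
reliability diagnostics $d_i$ (mean neighbor distance), $\sigma_i$ (neighbor
response spread) and $d_i/\sigma_i$, whose correlation with the absolute
error indicates when predictions can be trusted. With $k$ equal to the
training size the regressor degenerates exactly to the null model — kept
computable (with a warning) because it anchors the null-model comparison.

**CDR statistics.** Per-complex, per-region BSA/IVW-IPL/ANSO feed paired
comparisons of CDR1+CDR2 against CDR3 within each chain. "CDR1+2" means
summed values for BSA and IVW-IPL but the *pooled atom set* for ANSO
($(\mathrm{IVW}_1 + \mathrm{IVW}_2)/(|A_1|+|A_2|)$), because ANSO is a
per-atom average; pairs with an empty atom set are dropped and logged. The
Wilcoxon signed-rank test drops zero differences, uses the exact null for up
to 25 non-tied pairs and the normal approximation with continuity correction
beyond; the small-sample path is verified against exhaustive enumeration of
all sign assignments.

## What the synthetic generators emulate

The package is fully testable without external data through two generator
families:

* **Ball fixtures** (`make_two_ball()`, `make_patch_fixture()`,
  `make_random_ball_fixture()`, `make_random_complex()`) carry analytic
  truths — lens volumes, cap areas, expected contacts, hand-computed
  shelling orders — that the geometry engine must reproduce. Random
  two-sided complexes place two facing ball clusters (Ig atoms labeled with
  CDR regions at representative IMGT positions, an antigen cluster at a gap
  chosen so the patches touch) to exercise the full pipeline.
* **Cohorts** (`make_cohort()`) emulate the statistical shape of the
  curated corpus: $n = 489$ complexes with class proportions
  (0.16, 0.25, 0.59) for chemical/peptide/protein (largest-remainder
  rounding gives 78/122/289), Gaussian class clouds in
  $(\overline{bsa}_{Ag}, \overline{bsa}_{Ig})$ ordered chemical > peptide >
  protein on the Ag side and inversely on the Ig side, class-dependent
  interface sizes, and an affinity table whose $-\Delta G$ is a known
  affine response of (IVW-IPL, NIS$^{charged}$) plus Gaussian noise
  (default SD 0.8 kcal/mol, spanning roughly the 5-19 kcal/mol range of
  measured complexes). Feature centers and spreads are fixed defaults
  chosen once to look like the published scatter; they are study
  conditions, not tuning knobs.

What passing tests show, and what they do not: the geometry contract,
the descriptor algebra (partition additivity, pooling identities), and the
statistical machinery (baselines, protocol reductions, exact small-sample
nulls) are verified. Dataset-specific numbers — the 9.6% cross-validated
ligand-type error, the 0.878 kcal/mol median affinity error, the published
Wilcoxon p-values — depend on curated corpora of real crystal structures
and are out of reach of synthetic fixtures; nothing here claims them.
Synthetic cohorts also ignore real-data pathologies: missing atoms,
alternate conformations beyond simple altlocs, non-spherical solvent
effects, and flexibility upon binding.

## Problem sizes and limitations

The shipped tests run complexes of tens of atoms and cohorts up to
$n = 2000$, sizes at which the quadratic-cost facet enumeration and the
per-ball quadrature are comfortable on one core; real Fv-antigen complexes
(thousands of atoms) are tractable but benefit from lowering `n_surf` and
`n_dir` for screening work, at the documented accuracy cost. Known
limitations: no conformational sampling or flexibility modelling, no
hot-spot energetics, no renumbering (IMGT numbering is an input), water
chains deeper than the first shell are ignored, and the affinity model
inherits the usual kNN caveat that predictions are only as good as the
coverage of the training cloud — which is exactly what the $d_i/\sigma_i$
diagnostics measure.

```{r example, eval = FALSE}
# end-to-end sketch
s <- read_structure("complex.pdb", heavy_chain = "H", light_chain = "L")
s <- annotate_regions(s, "imgt-numbered")
im <- extract_interface(s)
d <- compute_descriptors(s, im, complex_id = "complex")
d$bsa_avg_Ig; d$bsa_avg_Ag; d$ivw_ipl; d$nis_charged
```
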