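# igvor — Voronoi interface models and affinity descriptors for antibody–antigen complexes

`igvor` is an R package for structural immunologists and method developers
who want a quantitative, geometry-first description of antibody–antigen
(Ig–Ag) interfaces. Instead of distance cutoffs, it models each complex as a
union of solvent-expanded atomic balls and reads the interface off the power
(weighted Voronoi) diagram: two atoms interact when their *Voronoi
restrictions* — ball ∩ power cell — share a facet, waters sandwiched between
the partners mediate additional pairs, and every interface atom carries a
buried surface area, a restriction volume (its packing), and a *shelling
order* SO(a), the hop distance to the rim of its binding patch.

From this model the package derives the descriptors that drive three
analyses:

- **Ligand-type classification.** The average buried surface per interface
  atom on each side, `bsa̅_Ig = BSA_Ig/|I_Ig|` and `bsa̅_Ag = BSA_Ag/|I_Ag|`,
  act as curvature proxies that separate chemical, peptide and protein
  ligands. A depth-2 decision tree over this plane is scored by repeated
  stratified 5-fold cross-validation against a count-preserving label
  permutation baseline and a naive interface-size classifier.
- **Binding-affinity regression.** The inverse volume-weighted internal
  path length, `IVW-IPL = Σ_{a∈I} SO(a)/Vol(a)` (size, morphology and
  packing in one number), and `NIS_charged`, the charged fraction of the
  non-interacting surface, span a two-dimensional space in which `-ΔG =
  -RT ln(Kd/c°)` is predicted by k-nearest-neighbor averaging (default
  k = 10), with a constant null model and `d_i/σ_i` reliability
  diagnostics.
- **CDR dissection.** Interfaces decompose exactly into the 14 IMGT CDR/FR
  regions of VH and VL; per-region BSA, IVW-IPL and the average normalized
  shelling order `ANSO = IVW-IPL/|A|` feed paired Wilcoxon signed-rank
  comparisons of CDR1+2 against CDR3 within each chain.

The geometry is exact (closed-form cap algebra) wherever a ball's clipping
caps are disjoint and deterministic Fibonacci-lattice quadrature elsewhere;
restriction volumes are validated against a Monte-Carlo union-volume oracle,
areas against a Shrake–Rupley-style oracle, and everything is invariant
under rigid motions and bitwise reproducible under fixed seeds.

## Worked example

Everything below runs without external data, on a synthetic two-cluster
complex and a synthetic cohort shipped with the package:

```r
library(igvor)

s  <- make_random_complex(n_ig = 12, n_ag = 9, seed = 5)
im <- extract_interface(s)
im
#> Voronoi interface model
#>   interface atoms: |I_Ig| = 8, |I_Ag| = 8
#>   direct pairs: 24; water-mediated pairs: 0
#>   BSA: Ig 103.62 + Ag 123.06 = 226.68 A^2

d <- compute_descriptors(s, im, complex_id = "demo")
#> bsa_avg_Ig = 12.95  bsa_avg_Ag = 15.38 A^2/atom
#> IVW-IPL = 0.510 A^-3   NIS_charged = 0.50

subset(d$per_region, n_atoms > 0)[, c("region", "n_atoms", "bsa", "ivw_ipl", "anso")]
#>     region n_atoms    bsa ivw_ipl   anso
#>    VH-CDR2       1   1.16  0.0113 0.0113
#>    VH-CDR3       3  53.40  0.1006 0.0335
#>    VL-CDR1       2  34.50  0.0321 0.0160
#>    VL-CDR3       2  14.57  0.0312 0.0156
#>    antigen       8 123.06  0.3348 0.0418
```

Eight atoms per side are in Voronoi contact; the antigen buries more area
per atom than the antibody (15.38 vs 12.95 Å²/atom — the convex-ligand
signature), and VH CDR3 dominates the Ig-side contribution both in area and
in packing-weighted depth (IVW-IPL), the pattern the region statistics
quantify across cohorts.

On a 489-complex synthetic cohort with class proportions 0.16/0.25/0.59 the
classifier and regressor behave as designed:

```r
co   <- make_cohort(n = 489, seed = 1)
cv   <- cross_validate(co$classifier, n_reps = 50, seed = 1)
perm <- permutation_test(co$classifier$label, n_perms = 2000, seed = 1)
#> median CV error 0.016 vs permutation 0.562

tr <- co$affinity[1:400, ]; te <- co$affinity[401:489, ]
p  <- predict(fit_knn(tr, k = 10), te)
nm <- null_model(tr, te)
#> knn median |e| = 0.588 kcal/mol (null 1.686); within 1 order: 0.85
```

The tree recovers the class structure almost perfectly (1.6% error against
a 56.2% permutation floor), and the kNN regressor roughly triples the
accuracy of the training-mean null model, with 85% of predictions within
one order of magnitude of Kd (1.4 kcal/mol at 298 K).

A thin command-line interface wraps the same functions
(`inst/cli/igvor.R`): subcommands `fixtures`, `interface`, `descriptors`,
`classify`, `predict-affinity` and `cdr-stats`, each writing CSV/JSON plus a
provenance block (config, seed, package version).

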