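---
title: "Contact-area mean-force potentials: model, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Contact-area mean-force potentials: model, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(contactpot)
```

## The model

`contactpot` scores protein conformations with a residue-level
knowledge-based potential whose interaction variable is not a distance
but a *contact area*. The underlying assumptions are the usual ones for
mean-force potentials — the ensemble of experimentally determined folds
is treated as a Boltzmann sample, so the log-ratio of an observed
contact statistic to its reference-state expectation is read as an
effective free energy — plus one specific to this method: that the
area two residues bury against each other, which depends on side-chain
orientation and not only on centre distance, is the more informative
statistic.

### Contact areas

Every heavy atom carries a Van der Waals *group* radius (hydrogens are
implicit): carbonyl C 1.5 Å, nitrogens 1.55 Å, side-chain/backbone
oxygens 1.4 Å (1.44 Å for wildcard-matched names such as OXT), sulfurs
2.0 Å, aromatic ring carbons 1.75 Å, all other carbons 2.0 Å. Atom
names that occur in both aromatic and aliphatic residues (CG, CD1, CD2,
CZ) are resolved by residue context — 1.75 Å only in PHE/TYR/TRP/HIS —
because a single name-keyed value would assign an aromatic radius to,
say, LEU CD1. The packaged table (`inst/extdata/vdw_radii.tsv`) also
carries element wildcards (`C**`, `O**`, `S**`, `F**`) as fallbacks for
names with no explicit row.

For atom *a*, `n` quasi-uniform directions (a deterministic
golden-spiral lattice; `generate_sphere_points()`) are scaled to the
sphere of radius `Ra + Rp`, the locus of probe-sphere centres touching
*a*. Each point represents the equal area share `4π(Ra+Rp)²/n`. A point
is **in contact** with partner atom *b* when it lies within `Rb + Rp`
of *b*'s centre; consequently two atoms can share any area only when
their centres are within `Ra + Rb + 2Rp` — the criterion used by the
pair prefilter and the spatial grid. A point contacting several atoms
of the partner residue is credited once, to the nearest contacting atom
(ties to the lowest atom index): without this rule, overlapping partner
spheres would double-count area. Occlusion by third atoms is
deliberately **not** modelled — a point counts even if an intervening
atom lies between the spheres — because the statistic is sphere-overlap
contact, not solvent accessibility; `.directed_residue_area()` only
ever sees the two residues involved.

The residue-pair area is the mean of the two directed sums (points of
residue *i* credited to residue *j*, and vice versa). The two directions
sample different sphere radii and so differ slightly; averaging gives
the symmetric quantity the potential needs, bit-exactly equal under
argument swap.

### Numerical behaviour of the sampling

The lattice quadrature converges to the analytic sphere-cap area as `n`
grows; at `n = 10000` the error is below 1% for caps subtending at
least ~10% of the sphere (thin slivers hold too few lattice points for
a relative bound — they are individually tiny in absolute terms). The
default `n = 1024` points per atom keeps single-structure tables cheap
while staying within ~2–3% per atom pair; areas are sums over many
atom pairs, so residue-level totals are tighter. Because the lattice is
fixed in the global frame, translations leave areas exactly unchanged
(points ride with the atom centres) while rotations re-sample every
sphere: pairs and cutoffs are preserved exactly, areas move at the
quadrature resolution (a few percent per pair at `n = 512`, under 1% on
structure totals). Any fixed deterministic lattice behaves this way;
applications that need rotational reproducibility should raise
`n_points`.

### Sequence-separation bins and probe radii

Contacts are stratified by `d = |i − j|` counted on a per-chain
consecutive renumbering of residues (author numbering gaps and
insertion codes therefore do not inflate `d`). Ten separation classes
are used: `d = 1 … 9` individually and `d ≥ 10` pooled. Consecutive
small separations resolve the strong local geometric signal; the pooled
long-range bin keeps every class populated in modest corpora. Only
intra-chain pairs are counted — sequence separation is undefined across
chains. Supported probe radii are 0.25, 0.5, 0.75, 1, 1.5, 2 and 2.5 Å
(`run_config()` enforces the set unless overridden); the package
default is `Rp = 0.25` Å with scoring restricted to `d = 1`, the
configuration with the strongest native/decoy discrimination — contact
area between consecutive neighbours reflects local packing and
side-chain orientation most directly, and larger probes mainly add
computation.

### Training: K and E

Per separation bin, each training structure contributes its total
contact area per residue-type pair once (per-structure means, so large
proteins do not dominate), accumulated in a symmetric 20×20 matrix: an
(a,b) pair with `a ≠ b` adds to both cells, a like-type pair to the
diagonal. With `Ā_ab` that mean matrix, `Ā_a` its row marginal and `Ā`
the grand total, the preference coefficient is

\[
K(a,b,d,r) \;=\; \frac{\bar A_{ab}(d,r)\,\bar A(d,r)}
                      {\bar A_a(d,r)\,\bar A_b(d,r)}
\]

— an observed/expected ratio whose reference state is the
marginal-product corpus. The ordered-pair accumulation makes the
identity exact: a corpus whose pair areas factor as `w_a·w_b` trains to
`K ≡ 1` to machine precision, and `K` is invariant under any global
rescaling of areas. The potential is the Boltzmann inversion
`E = −T·ln K̃` of the pseudocount-smoothed coefficient
`K̃ = (K·n_obs + 1)/(n_obs + 1)`, with `n_obs` the number of training
structures in which the pair was observed; unobserved pairs thus sit
exactly at the reference state (`E = 0`) instead of an infinite
penalty, and well-supported pairs are essentially unsmoothed. The
temperature factor defaults to 1, leaving energies in `RT`-like
arbitrary units — only relative values matter for ranking.

A structure's total score is `Σ area(i,j) · E(aa_i, aa_j, d)` over the
selected bins (`score_structure()`, default `d = 1`); a flag allows
scoring with raw `K` instead of `E` for diagnostic use.

### Training-set curation

`curate_training_set()` retains X-ray structures at resolution
≤ 2.5 Å with complete heavy-atom side chains for every residue (checked
against a per-type expected-atom table; terminal OXT tolerated). NMR
entries and structures with no recorded resolution are excluded — the
resolution criterion cannot be evaluated without a value. The filter is
idempotent. Synthetic structures carry no header metadata, so the
trainer exposes the filter as an option rather than forcing it.

### Evaluation statistics

Fixed conventions, each chosen once and used everywhere:

* **Rank**: `1 +` the number of decoys with *strictly* lower energy —
  ties do not worsen the native's rank.
* **Z-score**: `(E_native − mean) / sd` with the *population* (divide
  by N) standard deviation; at benchmark set sizes the difference from
  the sample convention is negligible, but a single convention must be
  fixed. Zero spread raises an error rather than returning ±Inf.
* **Pe**: `ln(rank / N)` with the natural logarithm; 0 (native last) is
  the worst value, and a native ranked first gives `ln(1/N)` — e.g.
  −8.74 at N = 6256.
* **RMSD**: Cα coordinates after Kabsch superposition (SVD of the
  covariance with determinant correction to a proper rotation).
  Decoys with a different Cα count are kept in the ranking but get
  `NA` RMSD.

## The synthetic generators, and what they do not show

`make_toy_structure()` builds single chains with ideal backbone
geometry (bond lengths/angles from standard peptide values, φ/ψ of
(−57, −47) for helices and (−120, 120) for extended chains, ω = 180°)
and side chains through Cβ placed tetrahedrally. These structures
exercise every geometric code path — radii, sampling, cutoffs, binning
— but they deliberately lack full side chains, so residue types are
geometrically interchangeable apart from glycine. A potential trained
on toy geometry alone is therefore nearly type-free (`K ≈ 1`), which is
the correct behaviour, not a defect.

`make_planted_corpus()` skips geometry entirely and emits contact
tables whose per-pair totals are `w_a·w_b·K*_{ab}` times lognormal
noise of unit mean and chosen coefficient of variation. Training on it
must recover the planted `K*`, which is how the trainer is validated:
with no enrichment and no noise the trained `K` is identically 1; with
one pair enriched 2× over 500 structures at cv 0.2, the recovered
coefficient lands just below 2 (the tests bound it in [1.8, 2.2]) —
slightly under the planted value because the enriched pair also
inflates its two marginals, a property of the observed/expected form
itself, not an estimation error.

`make_decoy_ensemble()` perturbs a native with independent Gaussian
coordinate noise — side chains at full scale, backbone at half scale,
since contact-area scores are most sensitive to side-chain orientation.
This emulates the *statistical* situation of decoy discrimination, not
the physics of real decoys: random perturbation creates steric
clashes, and clashed atoms share large spherical caps, so Gaussian
decoys systematically *gain* contact area, most dramatically at
sequence separations ≥ 2 where an ideal compact helix has little area
to begin with. Physically generated decoy sets keep atoms apart, so on
real data the native wins by *having* favourable contacts, while in
this synthetic setting it wins by *not having* clash-inflated ones.
The end-to-end tests therefore plant the signal accordingly: the
training corpus depletes the native's pair type (L,L enriched 0.5×,
making `E(L,L)` positive in every bin) and scoring sums separations
≥ 2, where the native and decoy areas separate cleanly; the tests
assert that the native ranks first with a negative Z-score.
Passing this shows the full pipeline — areas, training, scoring,
ranking — composes correctly under a known signal; it does not certify
discrimination performance on real decoy sets, which depends on real
side-chain statistics.

## Problem sizes and determinism

The shipped tests run on deliberately small instances: 6–16 residue toy
structures, 256–1024 sample points, corpora of up to 500 planted tables
or 20 toy structures, decoy ensembles of 8–30. All generators are pure
functions of their seed (`with_seed()` restores the caller's RNG
stream), every command-line path takes a `--seed`, and contact tables
and potentials serialize deterministically (fixed row order, `%.17g`
floats), so reruns are byte-identical.

## Known limitations

* No occlusion/SASA semantics: buried pairs still count full
  sphere-overlap area, and severely clashed models are *rewarded* with
  area rather than penalized — a steric term would have to come from
  elsewhere.
* Rotating a structure changes areas at the quadrature resolution
  (lattice fixed in the global frame); only translations are exact.
* Inter-chain contacts are ignored; multi-chain complexes are scored
  chain-by-chain in effect.
* Non-standard residues (MSE and friends) are dropped at parse time
  rather than remapped to their parents.
* Toy structures stop at Cβ, so synthetic benchmarks cannot probe
  rotamer-level orientation sensitivity — the very thing the method is
  designed to exploit on real data.
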