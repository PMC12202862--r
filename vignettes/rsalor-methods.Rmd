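---
title: "Scoring mutational effects from conservation and solvent accessibility"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring mutational effects from conservation and solvent accessibility}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rsalor)
```

## The model

`rsalor` scores every possible single-site mutation of a target protein with
an unsupervised, independent-site model that combines two signals:

**Evolutionary conservation.** From a multiple sequence alignment (MSA) whose
first record is the target, the model estimates the weighted, regularized
frequency $f_i(a)$ of each amino acid $a$ at each target position $i$. The
evolutionary score of a substitution $wt \to mt$ is the log-odd ratio (LOR)
of the two frequencies' odds,

$$\mathrm{LOR}(i, wt, mt) = \log\frac{f_i(wt)}{1 - f_i(wt)} -
  \log\frac{f_i(mt)}{1 - f_i(mt)},$$

with natural logarithms. The LOR is positive when the wild type is better
represented than the mutant — the usual signature of a deleterious change —
and exactly antisymmetric: swapping $wt$ and $mt$ flips the sign.

**Structural burial.** Mutations in the protein core tend to matter more
than mutations at the surface. The per-residue relative solvent
accessibility (RSA, in percent) modulates the evolutionary score through its
complement:

$$\mathrm{RSALOR}(i, wt, mt) = \left(1 - \frac{\mathrm{RSA}_i}{100}\right)
  \cdot \mathrm{LOR}(i, wt, mt).$$

The structural factor lies in $[0, 1]$ once RSA is clipped at 100, so
RSALOR keeps the sign of LOR and never exceeds it in magnitude: a fully
exposed residue scores neutral, a fully buried one keeps the full
evolutionary signal. Because RSA is computed from the wild-type structure
only and shared by both directions of a substitution, the implementation is
exactly antisymmetric as well.

The model has no trainable parameters. The effect of a multi-site mutation
is taken as the sum of its single-site effects — an explicit no-epistasis
approximation; when any site lacks structural coverage the RSALOR sum is
reported missing rather than mixing scales (the LOR sum is always
available).

## MSA curation, weighting and regularization

Three standard preprocessing steps stand between the raw alignment and
$f_i(a)$; each has one tunable parameter.

* **Deduplication and twilight filter** (`twilight`, default 0.35).
  Byte-identical records are removed, then homologs whose identity to the
  target falls below the cutoff. Sequences in the twilight zone of homology
  (roughly 20–35% identity) add noise rather than conservation signal.
  Identity is always computed over the columns where the *target* is
  non-gap, with gap-vs-anything counting as mismatch; a fixed,
  target-anchored denominator keeps identities comparable across record
  pairs.
* **Inverse-cluster-size weighting** (`cluster_threshold`, default 0.80).
  As in direct-coupling-analysis models, each record is weighted by
  $1/|\{s' : \mathrm{id}(s, s') \ge \theta\}|$ (the neighborhood includes
  the record itself), so a clade of near-duplicates contributes like one
  sequence. The weight sum is the effective number of sequences
  $N_\mathrm{eff}$. Both the vectorized implementation and a literal
  double-loop reference are exposed (`msa_weights(method = )`); they count
  column matches as integers and divide by the same denominator, so they
  agree bit for bit — a property the test suite asserts on random
  alignments.
* **Pseudocount regularization** (`pseudocount`, default $\lambda = 5$).
  With weighted counts $n_i(a)$ and coverage $C_i = \sum_a n_i(a)$,
  $f_i(a) = (n_i(a) + \lambda)/(C_i + 20\lambda)$. This bounds every
  frequency inside $(0, 1)$ so the LOR cannot diverge, and dominates only
  when $N_\mathrm{eff}$ is small, which is exactly the regime where the
  empirical frequencies are unreliable. As $\lambda \to 0$ the empirical
  weighted frequencies are recovered; as $\lambda \to \infty$ all
  frequencies tend to $1/20$. Gaps are excluded from the amino-acid
  denominator and reported as a separate weighted gap fraction, matching
  the output schema. Non-standard symbols (X, B, Z, J, U, O) in homologs
  are treated as gaps; in the target they are an error.

## Solvent accessibility

No installed R package computes solvent accessible surface area, and the
calculation is central to the method, so the package implements the
Shrake–Rupley algorithm directly, with one deliberate twist: the point
lattice on each expanded atomic sphere is a deterministic golden-spiral
(Fibonacci) set rather than a random one. The computation therefore
involves no RNG and is bit-reproducible, which in turn makes the
end-to-end CSV output byte-identical across runs and thread counts.

Numerical choices, all configurable:

* probe radius 1.4 Å (water), `n_sphere_points` 100 per atom;
* van-der-Waals radii: C 1.70, N 1.55, O 1.52, S 1.80, default 1.80 Å
  (NACCESS-like values);
* RSA normalization by the theoretical maximum ASA of Tien et al. (2013)
  (e.g. Ala 129.0, Gly 104.0, Trp 285.0 Å²);
* RSA above 100% (possible for residues more exposed than the tripeptide
  reference, e.g. termini) is preserved in the output but clipped to 100
  for scoring, so the structural factor is never negative;
* by default only the selected chain occludes; `occluders = "all-chains"`
  adds the remaining chains, which is the appropriate setting when scoring
  interface residues of a complex.

An isolated atom recovers the closed form $4\pi(r_\mathrm{vdw} +
r_\mathrm{probe})^2$ exactly (every lattice point is exposed), disjoint
spheres are exactly additive, and removing an occluder can only increase
SASA — the suite asserts all three, plus agreement of the default lattice
with a 10,000-point reference and with the spherical-cap closed form for
two overlapping spheres. One caveat worth stating: with a *fixed* lattice,
rotating a molecule changes each atom's exposed-point count by a few
lattice quanta (one quantum at 100 points is ≈1.2 Å² for carbon), so
rigid-motion invariance holds exactly for translations, to within ~1% for
the chain total under rotation, and only to a few quanta per atom. Users
needing tighter per-atom invariance should raise `n_sphere_points`.

## Mapping the structure onto the alignment

The structure rarely covers the target exactly: residues are missing from
density, or the only structure available is a close homolog. The package
aligns the structure-derived sequence to the MSA target with a global
Needleman–Wunsch alignment (BLOSUM62, gap open 10, extend 0.5, via
Biostrings) and converts aligned non-gap pairs into a
position-to-residue map that is injective and order-preserving by
construction. Mismatched aligned pairs are mapped — RSA is robust to point
substitutions — but counted and reported so homolog templates can be
audited; an identity below 0.7 over aligned pairs triggers a warning and
below 0.3 the structure is rejected outright. Unmapped positions simply
lack RSALOR; their LOR is still reported.

A subtlety surfaced by testing: "delete a window of residues and all other
mappings stay put" is *not* a theorem for arbitrary sequences. If the
residue flanking a deleted window repeats the window's first residue, two
gap placements score identically and the optimum is ambiguous. The
round-trip tests therefore use a repeat-free fixture (the 20-letter
alphabet cycled), where the optimal alignment is unique and the property
must hold exactly — it is checked for every possible 5-residue window of a
50-residue structure.

## Synthetic data: what it does and does not emulate

All tests run on generated fixtures with known ground truth:

* `simulate_msa()` writes an aligned FASTA whose target is the per-column
  argmax of specified column distributions; homologs are sampled per column
  independently, and `msa_cluster()` groups create duplicated-then-mutated
  records with *designed* weights (the standard fixture — target, two
  near-copies, one 50%-identity singleton — must yield weights (⅓, ⅓, ⅓, 1)
  and $N_\mathrm{eff} = 2$). Columns are independent: the generator
  emulates per-column conservation strength and redundancy structure, not
  covariation, phylogenetic correlation, or realistic gap geometry.
* `simulate_pdb()` writes legal fixed-width ATOM records in three geometry
  modes with provable RSA outcomes: `isolated` (residues 40 Å apart — RSA
  clips to 100), `buried-core` (a residue enclosed in a golden-spiral shell
  of blocker atoms — RSA < 5 by construction), and `helix` (an idealized
  α-helical trace used for mapping tests). The geometry is idealized; no
  rotamers, no realistic packing.

Passing tests therefore demonstrate correctness of the *computations*
(curation, weighting, regularization, SASA, mapping, scoring and their
invariants), not predictive accuracy on real proteins, which depends on MSA
depth and structure quality. Problem sizes in the suite — alignments up to
a few hundred records, structures up to 50 residues, 100–960 lattice
points — were chosen so each property is exercised well away from trivial
limits while the whole suite stays fast.

## Known limitations

* Independent sites: epistasis is ignored by design; multi-site scores are
  sums of single-site scores.
* A mutation at a fully exposed residue scores exactly 0 regardless of the
  amino acids involved.
* RSA comes from the wild-type structure only.
* The twilight cutoff, weighting threshold and pseudocount are fixed
  conventions (0.35 / 0.80 / 5), not fitted values; all are exposed as
  configuration.
* PDB input only (no mmCIF); first model of multi-model files; no hydrogen
  placement.
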