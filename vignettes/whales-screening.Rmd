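---
title: "Scaffold-hopping virtual screening with WHALES descriptors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scaffold-hopping virtual screening with WHALES descriptors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The method

`whalescreen` implements a ligand-based virtual screen for atypical
inhibitors of the human dopamine transporter (hDAT): molecules that bind
the S3 site in the intracellular vestibule (benztropine, JHW007,
R/S-modafinil) rather than the orthosteric cocaine site, and therefore
inhibit dopamine reuptake without cocaine-like stimulant liability.
Because the goal is *scaffold hopping* — retrieving chemotypes that share
3D shape and charge distribution with the queries but not their 2D
skeleton — the screen uses WHALES (Weighted Holistic Atom Localization
and Entity Shape) descriptors instead of 2D fingerprints.

For a prepared molecule with atom coordinates $x_i$ and partial charges
$\delta_i$, an atom-centered weighted covariance matrix is built for every
atom $j$:

$$S_w(j) = \frac{\sum_i |\delta_i|\,(x_i - x_j)(x_i - x_j)^T}
                {\sum_i |\delta_i|}$$

Each atom pair is then measured in the metric of the *center* atom's
covariance, giving the atom-centered Mahalanobis (ACM) distance matrix

$$\mathrm{ACM}(i,j) = \sqrt{(x_i - x_j)^T\,S_w(j)^{-1}\,(x_i - x_j)},$$

which is unitless, invariant to rigid motion and to overall molecular
size, and *not* symmetric (the metric changes with the center). Three
per-atom indices summarize it: isolation
$\mathrm{Isol}(j) = \min_{i \ne j} \mathrm{ACM}(i,j)$ (local
environment), remoteness
$\mathrm{Rem}(j) = \mathrm{mean}_{i \ne j}\, \mathrm{ACM}(i,j)$ (global
position), and their ratio $\mathrm{IR}(j)$. The percentiles
0, 10, ..., 100 of each index over the atoms, concatenated as
(Isol | Rem | IR), form the 33-value descriptor. Similarity between
molecules is the plain Euclidean distance between descriptors; smaller is
more similar.

### Conventions the equations leave open

* **Row/column convention.** Because ACM is asymmetric, "min over the
  other atoms" and "mean over the other atoms" could be read over rows or
  columns. Both indices here are taken over the *same* vector — the
  column $\mathrm{ACM}(\cdot, j)$, i.e. all other atoms measured in atom
  $j$'s metric. This matches the indices' intent (local vs. global view
  from atom $j$) and guarantees $0 < \mathrm{IR}(j) \le 1$, since a
  minimum cannot exceed the mean of the same set.
* **Percentiles.** Linear interpolation between closest ranks
  (`stats::quantile` type 7), stated so that independent implementations
  agree bit for bit.
* **Block order.** (Isol | Rem | IR), each min-to-max. Any fixed order
  works — Euclidean distance only needs the order to be consistent
  across molecules.
* **No descriptor scaling.** Distances are computed on raw descriptor
  values. All three blocks are already unitless and of comparable
  magnitude, and a standardization step would make every distance depend
  on the library composition; it is deliberately not offered.

### Numerical choices

* **Singular covariances.** Planar, linear and two-atom geometries make
  $S_w(j)$ singular. Before inversion it is ridge-regularized,
  $S_w(j) + \varepsilon I$ with
  $\varepsilon = 10^{-7} \cdot \max(\mathrm{tr}\,S_w(j), 1)$ — a
  continuous perturbation that is negligible for well-conditioned
  matrices, rather than a pseudo-inverse (which is discontinuous at the
  rank change).
* **Evaluation order.** With the ridge floor, $S_w + \varepsilon I$ can
  have condition number up to $\sim 10^7$, where algebraically equivalent
  but differently-ordered evaluations of the quadratic form diverge near
  $10^{-10}$. The covariance accumulation, the trace, and the quadratic
  form are therefore written in plain scalar evaluation order (no
  BLAS-kernel dependence), and the test suite's independent brute-force
  oracle reproduces the pipeline exactly.
* **Degenerate inputs.** All-zero partial charges are an error (the
  weighted covariance is undefined, and silently falling back to uniform
  weights would change similarity semantics). Coincident atoms give zero
  remoteness and raise a degenerate-geometry error. Descriptors require
  at least 3 atoms.

## Molecule preparation

Descriptors are computed from one explicit-hydrogen, energy-minimized,
charge-assigned conformer per molecule:

1. largest connected fragment kept (salts stripped, logged);
2. ETKDG distance-geometry embedding, seeded per molecule as
   `derive(master_seed, id)` so that growing a collection never
   reshuffles existing conformers; `num_confs > 1` embeds several and
   keeps the lowest-energy minimized one (default 1 — cheap and
   deterministic);
3. MMFF94 minimization, 500 steps by default, with UFF fallback when
   MMFF94 lacks parameters for an atom type;
4. Gasteiger–Marsili partial charges (iterative partial equalization of
   orbital electronegativity), on all atoms including hydrogens.

Preparation, like the descriptor, uses explicit hydrogens throughout:
both the charge distribution and the molecular shape depend on them.
Total charge is checked against the formal charge implied by the SMILES
(within 0.01 e). Molecules are screened in the protonation state written
in the input — no pKa engine is applied, a documented limitation (the
ionization handling used by docking workflows belongs to that branch,
not to this descriptor screen).

The embedding/minimization/charging backend is RDKit (driven in one
batched call per collection); SMILES canonicalization, logP/TPSA/MW and
format conversions go through OpenBabel. Identical records and seed give
bitwise-identical coordinates across runs.

## Screening

Every library molecule is scored against every template. The four
per-template distances are aggregated by the **minimum** (nearest-template
rule): a candidate similar to *any* atypical-inhibitor query is
interesting, and the four queries span two distinct chemotypes
(tropane benzhydryl ethers and sulfinylacetamides), so averaging would
penalize molecules that match one chemotype well. `aggregate = "mean"`
is available. Hits are the `top_k = 27` by default — a rank cutoff, not
a distance threshold, mirroring a screen that takes a fixed short-list
forward. Ties break lexicographically by molecule id, making rankings
deterministic and independent of library input order.

## Drug-likeness filter

Five classical topological properties with inclusive windows:
MW 100–400 Da, logP 1–5, H-bond acceptors 2–5 (N + O count), donors 0–2
(N/O bearing at least one H), TPSA 20–90 Å². The windows describe the
oral, CNS-leaning property space of the repurposing candidates.
Deep-learning ADMET predictions (BBB permeability, toxicity endpoints)
are out of scope: they come from a served model that cannot be
reproduced from open definitions, whereas every property here has one.
logP is the Wildman–Crippen atom-contribution estimate and TPSA the Ertl
fragment sum, both computed by OpenBabel; the test suite cross-checks
them against RDKit on a fixture structure (agreement: MW within 0.01 Da,
logP within 0.1, TPSA within 0.1 Å²).

## MM/GBSA bookkeeping

End-point binding free energies decompose as
$\Delta G_{calc} = \Delta E_{ele} + \Delta E_{vdW} + \Delta G_{pol} +
\Delta G_{nonpol}$ (no entropy term). This package does **not** run
simulations; it is the bookkeeping layer a lab applies to exported
component tables: recombine components, and validate claimed totals to a
tolerance of 0.02 kcal/mol — enough to absorb the rounding of components
printed to two decimals (several rows of the shipped six-complex hDAT
table differ from their component sums by exactly 0.01 for this reason).

## The synthetic screening benchmark

Real repurposing collections are proprietary, so the package generates a
statistical stand-in with the two features the screen actually needs: a
large, mostly-dissimilar drug-like background, and a small set of known
true neighbors.

* **Decoys** are assembled from a shipped fragment set (aromatic,
  heteroaromatic, alicyclic and linker scaffolds × common medicinal-
  chemistry substituents), constrained to MW 100–500 and valence-legal,
  sanitizer-accepted graphs, deduplicated by canonical SMILES. Their
  mean 2D fingerprint similarity to the templates is ~0.2 Tanimoto
  (asserted < 0.5 in the tests).
* **Planted analogs** are seeded structural rewrites of the templates:
  substituent swaps (halogen exchange, aromatic F/Cl/methyl) at `light`,
  plus single-atom chain homologation at `medium`, plus aliphatic ring
  contraction/expansion at `heavy`. All candidate edits are enumerated,
  validated, and sampled under the seed.

The benchmark conditions are fixed by `library_spec()` defaults: 2,000
decoys plus 5 light analogs of each of the 4 templates, seed 11 —
emulating, at desk scale, a screen of a few-thousand-compound library
for a 27-hit short-list. Under these conditions the top-27
minimum-aggregate ranking retrieves 80% (16/20) of the planted analogs,
and the mean descriptor distance of light analogs to their template is
well below that of decoys.

What the generator does *not* emulate: the chemical distribution of any
real vendor catalogue, activity cliffs, tautomer/protomer ambiguity, or
experimental conformational ensembles. Passing the retrieval benchmark
shows the pipeline separates geometric/electrostatic near-neighbors from
a diverse background — not that it would reproduce any particular
historical hit list.

## Problem sizes and determinism

The shipped tests run the complete benchmark (2,020 molecules end to
end, about two minutes), a 50-point-cloud brute-force oracle comparison,
20-molecule invariance suites, and per-module unit tests. Every
stochastic step — embedding, decoy assembly, analog sampling, library
shuffling — is driven by explicit integer seeds, and regenerating with
the same spec is byte-identical.

## Known limitations

* Input protonation states are taken at face value; no pKa/tautomer
  enumeration.
* One conformer per molecule by default; flexible molecules are
  represented by a single minimized geometry, not an ensemble.
* Gasteiger charges are fast topological estimates, not quantum-derived.
* The MM/GBSA module validates arithmetic, not physics: component values
  come from upstream simulation pipelines.
* Docking, MD, ADMET model predictions and uptake assays are outside the
  package's scope by design.
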