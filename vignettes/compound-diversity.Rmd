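---
title: "Comparative scaffold and fingerprint diversity analysis of compound libraries"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative scaffold and fingerprint diversity analysis of compound libraries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scaffdiv)
```

## The problem

Screening-library design asks a structural question: which ring systems
(scaffolds) and which substructural fragments does a compound collection
actually contain, how skewed is their recurrence, and how much of that
space is shared with other collections — drugs, human metabolites, natural
products, toxic compounds, commercial lead libraries? scaffdiv implements a
complete comparative pipeline for this question: curation (standardization,
deduplication, clustering to representatives, lipid filtering, seeded
subsets), circular-fingerprint feature diversity, binary and
frequency-weighted Tanimoto similarity between whole datasets, Lipinski
rule-of-five and extended property profiling, and Bemis–Murcko scaffold
analytics.

Every user-facing function takes a collection — a tibble with `id`,
`smiles` and `source` columns — and returns a tibble (or a small S3 object
with `tidy()`/`glance()`/`autoplot()` methods), so analyses compose with
the pipe.

## Models and procedures

### Standardization and deduplication

All chemistry parsing and canonicalization goes through OpenBabel
(ChemmineR/ChemmineOB). `standardize_collection()` applies, in order:
optional removal of stereochemistry annotations (the analyses here are
2D-topological, so stereoisomers are one structure by default); retention
of the largest covalently connected fragment (salt and solvent stripping;
ties broken by the lexicographically smaller canonical fragment string);
charge neutralization wherever a proton can be added or removed without
violating standard valence (a carboxylate gains a proton, an ammonium
loses one; quaternary nitrogens and other non-neutralizable centers keep
their charge, so zwitterions that cannot be fully neutralized survive
as-is); and canonicalization. The sequence is idempotent, and
`dedup_collection()` then keeps the first record per canonical structure.

### Redundancy-reducing clustering

Public collections over-represent some chemotypes. Following common
practice, `cluster_representatives()` reduces a collection by a target
fraction (default 0.3, i.e. a 30% reduction) using k-medoids on an
atom-type count descriptor — counts over a fixed alphabet of element ×
aromaticity × ring-membership types — with Euclidean distance. The number
of clusters is derived from the outcome, `k = round((1 − reduction) · n)`,
because the design target is the reduction, not k. Every representative is
an actual member (the medoid) of its cluster; singletons represent
themselves. Collections no larger than the CLARA subsample size (default
`min(n, 40 + 2k)`) are clustered with exact PAM on the full distance
matrix; larger ones use the sampling-based CLARA scheme (`n_samples`
subsamples, best total-distance solution kept), seeded for
reproducibility.

### The lipid filter

The lipid filter is a stated stand-in: there is no universally accepted
structural definition of "lipid". The default rule removes molecules
containing an acyclic, unbranched chain of at least 12 sp3 carbons
(computed as the diameter of the forest induced on acyclic single-bonded
carbons), which captures fatty acids and acyl chains while sparing sugars
and typical drug-like molecules. SMARTS patterns can be supplied to extend
the rule. The filter is idempotent.

### Circular fingerprints

`fingerprint_features()` generates extended-connectivity circular
fingerprints by iterative neighborhood expansion. Each atom receives an
initial code; at every iteration the code is re-hashed together with the
sorted (bond-order, neighbor-code) pairs of its immediate neighbors, so
the code at iteration r describes the full environment within r bonds.
The fingerprint of order k is the union of features from iterations
0..k/2 (order 4 ≈ the common ECFP_4/FCFP_4 setting).

Two variants differ only in the initial codes. The *connectivity* variant
hashes (element, heavy-atom degree, hydrogen count, formal charge, ring
flag, aromatic flag) — highly specific, the right choice for measuring
diversity. The *functional* variant uses a 6-bit pharmacophoric role code
(H-bond donor, H-bond acceptor, positively ionizable, negatively
ionizable, aromatic, halogen), so for example chlorine and bromine — which
often substitute for each other functionally — share one initial code; it
is the conventional choice for cross-dataset similarity. Role definitions:
donors are N/O bearing a hydrogen; acceptors are N/O except pyrrole-type
nitrogens; positively ionizable covers formally positive atoms and
non-aromatic amine nitrogens not adjacent to a carbonyl; negatively
ionizable covers formally negative atoms and carboxyl hydroxyls.

Feature identifiers are 32-bit FNV-1a hashes of the code strings,
implemented in C++ for stability across platforms and runs. The hashing
scheme is deliberately implementation-defined: only set and frequency
statistics of identifiers matter downstream, and no published fingerprint
implementation is numerically normative (the identifier space of 2^32
makes collisions on library-scale feature sets rare; a collision would
merge two features in every dataset equally). Per-molecule features are
counted, not bit-folded, so dataset frequency vectors are exact.
Duplicate environments — two features covering the identical atom set —
are removed within each molecule, keeping the earlier iteration's feature
(or, within an iteration, the smaller identifier).

### Tanimoto comparison of whole datasets

For molecules, the binary Tanimoto over feature sets is
`T_b = N_AB / (N_A + N_B − N_AB)`. For whole datasets the package follows
the frequency-weighted (nonbinary) form over the dataset feature-frequency
vectors:

`T_nb = Σ x_iA x_iB / (Σ x_iA² + Σ x_iB² − Σ x_iA x_iB)`

with sums over the union of features and `x_iA` the total occurrence count
of feature i in dataset A. `T_nb = 1` exactly when the frequency vectors
are identical. Degenerate both-empty comparisons are 0/0 and are defined
as 0 with a warning rather than an error, so pipelines do not crash on
empty intersections. Accumulation is in double precision (R's long-double
accumulating `sum()`); the symmetry tolerance used in validation is
1e-12. `dataset_similarity_matrix()` defaults to functional fingerprints
of order 4 with frequency weighting, the conventional dataset-comparison
setting; `order_sensitivity_report()` recomputes the matrix across orders
to show how coefficients drift as fragments grow.

### Physicochemical profile

`compute_properties()` yields eight whole-molecule descriptors: molecular
weight (g/mol); an atomic-contribution logP (OpenBabel's
group-contribution model); H-bond donors and acceptors in Lipinski's
original counting convention (N–H/O–H hydrogens; N+O atoms) because the
downstream test is explicitly the rule of five; topological (Ertl) polar
surface area (Å², no 3D geometry); rotatable bonds (acyclic single bonds
between two heavy atoms each with a further heavy neighbor, amide C–N
excluded); an ESOL-style aqueous solubility estimate
`logS = 0.16 − 0.63·alogp − 0.0062·mw + 0.066·rotatable − 0.74·aromatic_proportion`
(log mol/L) — an openly documented surrogate, since published solubility
models inside commercial descriptor packages are not reproducible; and
ring count as the cyclomatic number, equal to the smallest-set-of-
smallest-rings cardinality (fused bicyclics count 2).

`ro5_violations()` counts thresholds exceeded with *strict* inequalities
(MW exactly 500 passes); whether boundary-equal values should violate is
genuinely underdetermined in the rule's common statements, so the strict
convention was chosen and the thresholds are configurable.
`boxplot_summaries()` uses type-7 (linear interpolation) quantiles, the
convention under which the five-point worked example `[1,2,3,4,5] → q1 2,
median 3, q3 4` holds; the type is configurable.

### Scaffold analytics

`murcko_scaffold()` computes the atomic framework: terminal heavy atoms
are pruned iteratively until only ring atoms and the linker atoms
connecting rings remain — side chains removed, linkers kept. Exocyclic
multiple-bond atoms (a carbonyl oxygen on a ring, for instance) are pruned
by default, giving the pure ring+linker framework; because Murcko
implementations differ on this point, `keep_exocyclic = TRUE` re-attaches
atoms multiple-bonded to the framework. Scaffold identity keeps element
and bond-order information — benzene and pyridine are different scaffolds,
as any per-scaffold ranking requires. Aromaticity of a scaffold is
re-perceived on the isolated framework, not inherited from the parent.
Acyclic molecules have no scaffold, so scaffold occurrence totals can be
below the dataset size, and all "relative to dataset size" percentages use
the collection actually analyzed (e.g. a lipid-filtered set).

`scaffold_table()` + `glance()` give the per-dataset summary (scaffold
count and its percentage of dataset size, singletons and aromatic
scaffolds as percentages of scaffolds, and the recurring complement);
`top_scaffolds()` ranks by occurrence with percentages of total scaffold
occurrences; `shared_scaffold_matrix()` intersects canonical scaffold sets
pairwise and reports the shared count, its percentage of the pair's union
(equal to the binary Tanimoto of the two scaffold sets × 100), and each
dataset's contribution. `missing_scaffold_report()` finds scaffolds
present in a source collection, absent from an exclusion collection, with
a best binary-Tanimoto similarity (connectivity fingerprints of the
scaffold structures) of at least 0.9 — configurable — to a reference
collection: the "scaffolds with close drug counterparts that lead
libraries do not cover" analysis.

## The synthetic-data generator

Real public libraries cannot ship with the package, so
`generate_library()` builds libraries with known ground truth for every
pipeline stage. Each molecule is a scaffold sampled from a built-in pool
of 72 common ring systems (single rings, fused bicyclics, linked
assemblies, a steroid-like fused system) plus terminal decorations
(halogens, methyl/ethyl/propyl, hydroxyl, amino, carboxyl, nitrile,
trifluoromethyl, short heteroatom chains) grafted onto ring carbons with
free hydrogens. Decorations are restricted to terminal substituents and
can never form a ring, so the planted scaffold is provably the Murcko
scaffold of the emitted molecule — recovery is exact by construction, and
the tests assert it exactly rather than statistically.

Generator defaults emulate the statistical structure reported for real
collections: Zipf-distributed scaffold recurrence with exponent 1.5 over a
randomly ranked pool (producing the "skewed, many singletons" profile in
which most scaffolds occur once), a controllable aromatic-scaffold
fraction (0.8 reflects the aromatic bias of drug/lead collections),
controllable lipid and rule-of-five-failure fractions (both 0 unless a
study condition asks otherwise; the acceptance checks use 25% planted Ro5
failures on 400 molecules and 30% reduction clustering on 100, the stated
study conditions). Lipid members are C13–C20 fatty acids — their saturated
chains trigger the curation filter by construction. Rule-of-five failures
are planted by iodine-loading small scaffolds past MW 500; when failures
are planted, the remaining molecules are restricted to lightly decorated
"pass-safe" scaffolds (small, low-lipophilicity ring systems) so that
*pass* labels are guaranteed too, making the planted failure fraction an
exact ground truth rather than a statistical target.

What the generator does **not** emulate: real substituent diversity
(decorations come from a 14-fragment pool), stereochemistry, charged
species, tautomerism, very large or macrocyclic ring systems, and the
long-tailed molecular-weight distributions of natural products. Passing
tests therefore demonstrate algorithmic correctness (exact scaffold
recovery, exact set arithmetic, seeded determinism) — not that any
particular real-world library will show a particular diversity profile.

## Numerical and design choices

* Fingerprint hashing: FNV-1a/32 over code strings; stable, documented,
  implementation-defined by design.
* Quantiles: type 7; Ro5 comparisons strict; both configurable.
* Matrix symmetry validated at 1e-12; Tanimoto of two empty inputs
  defined as 0 with a warning.
* Medoid ties: PAM/CLARA (cluster package) resolution; deterministic
  under a fixed seed, which the pipeline records in its manifest.
* Single heavy atoms (methane, water) cannot pass through a V2000
  connection table; their graphs are built directly and their
  partition/PSA models degenerate to 0 — they are outside the domain of
  interest for library profiling.
* Degenerate inputs: empty collections error in analysis functions and
  warn in writers; all-acyclic collections yield an empty scaffold table
  with percentages defined as 0 and a warning.

## Problem sizes used in validation

The test-suite and acceptance checks run at desk scale, chosen so each
property is decisively exercised: 500 decorated molecules for exact
scaffold recovery, 1000 random feature-multiset pairs against naive
summation oracles, 400 molecules for the planted 25% rule-of-five
recovery, 100 molecules for the 30%-reduction clustering contract (with
exhaustive k-medoids verification at n = 8), and a three-dataset pipeline
determinism check at 40 molecules per dataset. The worked-example checks
recompute the published derived percentages from the published integer
scaffold counts and are instantaneous.

## Known limitations

* AlogP here is OpenBabel's atomic-contribution logP, not a re-derivation
  of the Ghose–Crippen parameter table; absolute solubility and logP
  values are model-dependent and should be compared within, not across,
  descriptor packages.
* The nonbinary Tanimoto is the standard frequency-weighted form; where a
  published analysis used a proprietary fingerprint implementation,
  absolute feature counts (and hence similarity values on real data) are
  not numerically reproducible — only the construction properties and the
  derived arithmetic are.
* Aromaticity follows ChemmineR's Hückel-style ring perception; exotic
  aromatic systems (fused polycations, mesoionics) may be perceived
  differently than by other toolkits.
* The lipid rule is a structural stand-in, not a lipidomics
  classification.
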