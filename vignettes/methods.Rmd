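---
title: "Methods: motif scanning and anchor-constrained peptide placement"
author: "phosphoSLiM"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: motif scanning and anchor-constrained peptide placement}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phosphoSLiM)
```

# The problem

PP2A/B55α dephosphorylates CDK sites on substrates such as p107, TAU and
MAP2.  Substrate recruitment is mediated by a short linear motif (SLiM) in
a disordered region: a phosphoacceptor Ser/Thr followed by Pro, a variable
spacer, and a conserved basic anchor plus hydrophobics that dock into the
groove on top of the B55α β-propeller:

```
p[ST]-P-x(4,10)-[RK]-V-x-x-[VI]-R
```

Two computations follow from this model, and this package implements both.
First, a *sequence* problem: find motif instances proteome-wide, measure
phospho-to-anchor spacing, and test whether motif-bearing proteins are
over-represented among experimentally determined interactors.  Second, a
*structure* problem: the phosphosite must sit in the PP2A active site (a
di-Mn²⁺ centre) while the anchor Arg contacts B55α Asp-197 ~27.5 Å away, so
which peptide backbone conformations can bridge the two sites?  The
structural pipeline mines candidate conformations from existing coordinate
files, clusters them by backbone dihedrals, and places them against the
anchor geometry.

# Motif grammar and scanning semantics

Patterns are dash-separated tokens: a residue letter, a class `[RK]`, a
single-position wildcard `x`, or a variable gap `x(4,10)`; a leading `p`
marks the phosphoacceptor (exactly one).  The anchor element is inferred as
the first class after the gap whose letters are all basic (R/K).

Scanning decisions that the published counts leave open, fixed here as
deterministic conventions:

* **Hit identity.**  Variable gaps make several realisations land on the
  same biological site.  A hit is one distinct (phosphoacceptor position,
  anchor position) pair; among realisations the smallest (start, end) is
  reported.  Overlapping hits at different pairs are all kept — this is why
  hit counts can exceed motif-positive protein counts.
* **Ambiguity letters.**  X/B/Z/U never satisfy a fixed residue or class;
  X (unknown residue) satisfies wildcard and gap positions; B/Z/U do not.
  This is the conservative reading: a class asserts identity, a wildcard
  only presence.
* **Coordinates.**  1-based inclusive spans; an `offset` maps local
  positions to author numbering (offset 611 makes the p107 fragment start
  at author residue 612).

The scanner compiles each gap-length assignment to a look-ahead regular
expression (so overlapping matches are found) and deduplicates pairs; the
test suite holds it equal to a character-by-character brute-force
enumeration on 1,000 random sequences.

# Enrichment statistics

A protein is *positive* when it has ≥ 1 hit; hit multiplicity is ignored,
mirroring how positive-sequence counts are usually reported.  Enrichment of
positives in a target set drawn from a background proteome is the one-sided
Fisher exact (hypergeometric tail) test: `phyper` supplies the tail, and
the direction (enriched/depleted/none) is taken from the observed
fractions.  The exact test is conservative by construction; the suite
verifies empirical type-I error ≤ 0.05 at α = 0.05 over 2,000 null draws
generated by the package's own interactor sampler at enrichment factor 1.

# Fragment mining

`extractFragments` slides a gap-free pattern (e.g. `xHPRVx`, `xEPxxxPRx`)
over every chain.  A window becomes a fragment only if every residue has a
complete N/CA/C/O backbone and consecutive CA–CA distances stay ≤ 4.5 Å (a
standard chain-break heuristic; coordinate files are silent about breaks).
Wildcard flanks must exist — a motif at a chain terminus is discarded —
because flank geometry is needed downstream.  Alternate locations keep the
highest occupancy (ties prefer 'A'); selenomethionine reads as Met; any
other nonstandard residue rejects the window.  The *pattern core* is the
contiguous stretch from first to last non-wildcard element; the Glu and Arg
at core positions get their OE1/OE2 and NH1/NH2 side-chain atoms
role-tagged for span measurement and fitting.

# Dihedral metric and clustering

Backbone torsions follow IUPAC: φ(i) over C(i−1)–N(i)–CA(i)–C(i), ψ(i)
over N(i)–CA(i)–C(i)–N(i+1), and ω(i) over the peptide bond *following*
residue i; hence φ is undefined at the first residue and ψ/ω at the last.
The conformer distance is the maximum over compared positions and angle
types of the circular difference wrapped to [0°, 180°] — a max-metric over
circular metrics, so it satisfies the triangle inequality (property-tested).
By default only core residues are compared (`coreOnly = TRUE`): the mined
motif residues are the scientifically relevant ones and this keeps profiles
comparable across flank lengths.  Comparing full fragments is available as
an option.

Clustering is DBSCAN under this metric.  The clustering radius and density
are not derivable from the published description, so the package requires
them in the call and echoes them in its log; the defaults (eps 60°,
minPts 5) merge thermal spread within a backbone class while separating
secondary-structure classes (an extended strand and an α-helix differ by
~180° in ψ).  No CRAN DBSCAN implementation is assumed: the algorithm is
implemented from its definition, with one deliberate determinism choice —
border points join the cluster of their lowest-indexed core neighbour — and
is tested against a definitional brute-force oracle (neighbourhoods, core
points, density-connected components).

The reference conformer is the member of the largest cluster whose source
structure has the lowest resolution; structures without a resolution (NMR)
rank last, and remaining ties fall back to lexicographic fragment id so the
selection is a total order.

# Spans, the metal survey, and the anchor scene

The Glu–Arg end-to-end span is the **minimum** over the ≤ 4 OE×NH atom
pairs, matching the shortest-distance convention used for the Mn–phosphate
survey (per Mn²⁺ ion, the shortest distance to any phosphate oxygen); `max`
and `mean` are available for sensitivity analysis.  Survey spread is
reported as the **population** standard deviation (n denominator) and says
so in its output, because the convention is not recoverable from a printed
mean ± sd.  Fragments bridging the two sites must span ≥ 20 Å (boundary
inclusive).

The placement target — the *anchor scene* — combines four pieces of
geometry: the holoenzyme's Mn²⁺ pair, its anchor-Asp carboxylate
(OD1/OD2), the Glu-phosphomimetic OE1/OE2 reference transplanted from a
donor phosphatase structure, and Arg NH1/NH2 reference positions placed
against the Asp:

* **Active-site alignment** pairs the two metals plus the CA atoms of
  metal-coordinating residues (protein atoms within 2.6 Å of a metal, CAs
  distance-ranked per metal and truncated to the shared count; both metal
  pairings are tried and the lower-RMSD one kept).  Only chains that hold a
  metal contribute coordinating residues, which keeps substrate or tag
  peptides parked in the active site out of the alignment set.
* **Arg placement** replaces a manual step with a deterministic grid
  search: NH1/NH2 are offset bidentately from OD1/OD2 along each direction
  of a 10° angular grid at the contact distance (default 3.0 Å; directions
  that would push the realised minimum NH–OD distance off the target are
  discarded), and the direction minimising heavy-atom clashes (< 2.5 Å)
  wins.  Ties prefer the direction toward the active-site Glu — the side
  the peptide physically spans in from — then the largest clearance.  The
  procedure is seedless and reproducible.
* **Candidate fitting** superposes a fragment's four anchor atoms onto the
  scene references by Kabsch least squares (proper rotations only;
  reflections are rejected, colinear point sets are flagged).  The
  displacement score is the sum of the four residual distances; candidates
  are ranked by it, the top 20 retained, and the final model minimises
  (min OE→Mn) + (min NH→OD) — the printed selection rule is not an explicit
  formula, so this package states one.  Threading preserves the anchor
  atoms bit-for-bit, so scores are identical before and after threading;
  terminal extensions are built in an extended conformation
  (φ −135°, ψ 135°, ω 180°).

# Synthetic data: what it emulates and what it does not

Every generator is a pure function of (parameters, seed) — RNG state is
saved and restored — and emits a ground-truth record alongside its output.

* `genProteome` plants pattern instances (sampled uniformly from the
  pattern language, gap lengths uniform) into i.i.d. background sequences,
  at most one per protein, and records every plant plus the full hit table
  of the emitted proteome so chance background hits are visible.  Residue
  composition is uniform by default with a human-like preset; the surrogate
  proteome used in the acceptance checks uses the human preset with lengths
  uniform on 120–720 (around the human median of ~420 residues) and 6,000
  proteins — large enough that the Monte-Carlo error on a ~1.5% fraction is
  small against a ±20% band.  An i.i.d. background reproduces the *random*
  occurrence rate of a short motif but none of the real proteome's
  correlations (Ser-Pro dipeptide enrichment in disordered regions, length
  skew, paralogy), so agreement with printed proteome fractions is expected
  only to first order.
* `buildPeptide` constructs backbones from φ/ψ/ω by sequential
  internal-coordinate placement with ideal stereochemistry (N–CA 1.458 Å,
  CA–C 1.525 Å, C–N 1.329 Å; N–CA–C 111.2°, CA–C–N 116.2°, C–N–CA 121.7°);
  carbonyl oxygens are placed anti to the next amide.  Glu/Arg receive
  OE/NH pseudo-atoms rigid with the backbone, reaching 4.9/7.0 Å from CA
  along CA→CB to emulate extended side-chain reach — enough for extended
  conformers of the mined heptapeptide core to clear the 20 Å filter while
  helical ones fail, as real ones do.  These are stubs, not rotamers: no
  packing, no torsional freedom, and no claim of side-chain realism.
* `genConformerLibrary` adds wrapped-Gaussian angular noise (mod 360,
  re-centred) to cluster-centre dihedrals — the natural noise model on
  circular data — and stamps synthetic resolutions so reference selection
  is exercised.
* `genAnchorScene` / `genMockComplex` build scenes whose span and contact
  are exact by construction, then apply a seeded random rigid motion.  The
  mock complex adds a di-Mn centre with coordinating residues (distinct CA
  radii, so distance-ranked correspondence is tie-free), a receptor wall
  behind the anchor Asp leaving only the approach cone open, and a donor
  copy of the metal centre carrying the phosphomimetic Glu under a second
  rigid motion that the assembly must recover.  Passing the assembly check
  on the mock shows the *machinery* (alignment, Glu selection, grid
  placement, span measurement) reproduces a designed 27.5 Å geometry to
  within the grid discretisation (≲ 0.3 Å); it does not re-derive the
  published span from the original crystal structures, which are not
  shipped with the package.

# Numerical choices and degenerate inputs

Angles live in (−180°, 180°]; colinear torsion geometry yields NA with a
warning rather than an error.  Kabsch superposition enforces det(R) = +1
within 1e−9 and warns on colinear point sets (axis rotation unresolved).
The dihedral build→measure round-trip is exact to 1e−6° and superposition
recovery to 1e−8 Å RMSD in the test suite.  Problem sizes in the tests and
acceptance script (6,000-protein surrogate proteome, 2,000 null draws,
1,000 oracle sequences, 12-member conformer libraries) are chosen so the
whole suite runs in about a minute while keeping Monte-Carlo error well
inside every asserted band.

# Known limitations

The pipeline stops at pre-refinement placement: no flexible-backbone
refinement, no Rosetta-style energies, and no phosphoserine
parameterisation (the Glu phosphomimetic convention is retained).  The
published proteome counts (309 hits across 302 sequences for the stricter
degenerate pattern; 2831 across 2422 for the looser one) are tied to a
specific Swiss-Prot release and an unstated hit convention, so they are
treated as regime checks, not exact targets.
Fragment mining operates on user-supplied coordinate files; it does not
re-run a live PDB text search.
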