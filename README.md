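# phosphoSLiM

Scanning and structural modeling of the PP2A/B55α substrate-recruitment
short linear motif (SLiM).

PP2A/B55α is a major Ser/Thr phosphatase holoenzyme whose regulatory B55α
subunit recruits substrates through a groove on top of its β-propeller.  In
the retinoblastoma-family protein p107, a disordered spacer region presents
the phosphosite pSer-615 to the PP2A active site while a conserved basic
anchor (Arg-621) contacts B55α Asp-197, giving the consensus recognition
motif

```
p[ST]-P-x(4,10)-[RK]-V-x-x-[VI]-R
```

(phosphoacceptor Ser/Thr, fixed Pro, a variable spacer of 4–10 residues,
then the basic anchor and a short hydrophobic stretch).  The geometry is
demanding: the phosphomimetic Glu in the active site and the anchored Arg
guanidinium lie ~27.5 Å apart, so the connecting peptide must be highly
extended.

`phosphoSLiM` implements both computational halves of that analysis as a
tested, reproducible pipeline:

* **Motif scanning** — a PROSITE-style pattern grammar with variable gaps
  (`parsePattern`), overlap-aware proteome scanning with one hit per
  distinct (phosphoacceptor, anchor) pair (`scanSequence`, `scanProteome`),
  phospho-to-anchor spacing statistics (`spacingDistribution`), and
  one-sided exact hypergeometric enrichment of motif-positive proteins in
  interactor sets (`motifEnrichment`, `enrichmentTest`).
* **Fragment mining and modeling** — extraction of pattern-matched peptide
  fragments from PDB/mmCIF coordinate files (`extractFragments`), backbone
  φ/ψ/ω computation (`backboneDihedrals`), conformer clustering by DBSCAN
  under a max-circular-torsion metric (`dihedralDistance`,
  `clusterFragments`), reference-fragment selection by cluster size and
  resolution (`selectReference`), Glu–Arg end-to-end span filtering at 20 Å
  (`endpointSpan`, `filterBySpan`), Mn–phosphate distance surveys
  (`mnPhosphateSurvey`), Kabsch superposition (`superpose`), programmatic
  assembly of the two-fragment anchor scene (`alignActiveSite`,
  `placeArgAnchor`, `assembleAnchorScene`), candidate fitting and ranking
  by anchor-atom displacement (`fitCandidate`, `rankCandidates`), and
  sequence threading (`threadSequence`).
* **Synthetic data** — deterministic generators with machine-readable
  ground truth for every input class: planted-motif proteomes
  (`genProteome`), interactor sets with controlled enrichment
  (`genInteractorSets`), dihedral-defined conformer libraries built by an
  internal-coordinate peptide builder (`buildPeptide`,
  `genConformerLibrary`), and mock anchor scenes and receptor/donor
  complexes (`genAnchorScene`, `genMockComplex`).

## Worked example

Scan the p107 spacer fragment M612–R626 with the strict consensus:

```r
library(phosphoSLiM)
pat <- parsePattern(slimPatterns()$strict)
scanSequence(pat, "MPMSPLMHPRVKEVR", id = "p107", offset = 611)
#>   protein_id start end phospho_pos anchor_pos gap_len spacing  matched_seq
#> 1       p107   615 626         615        621       4       5 SPLMHPRVKEVR
```

One hit: the phosphoacceptor is Ser-615, the anchor Arg-621, with 5
residues between them (the spacing is 7 in TAU and 11 in MAP2).

Assemble the two-fragment anchor scene on a synthetic complex built at the
published geometry and fit a mined conformer library into it:

```r
mc    <- genMockComplex(span = 27.5, contactDistance = 3.0, seed = 11)
scene <- assembleAnchorScene(mc$holoenzyme, mc$donor)
endpointSpan(scene)
#> [1] 27.50129

lib   <- genConformerLibrary(
           list(cbind(phi = rep(-135, 9), psi = rep(135, 9), omega = rep(180, 9)),
                cbind(phi = rep(-57, 9),  psi = rep(-47, 9), omega = rep(180, 9))),
           membersPerCluster = 6, noiseSd = 5, sequence = "GEPLMHPRG",
           seed = 42)
frags <- extractFragments(lib$structures, "xEPxxxPRx")
keep  <- filterBySpan(frags, 20)          # extended conformers pass, helical fail
fits  <- lapply(keep, fitCandidate, scene = scene)
best  <- rankCandidates(fits, topK = 20)$best
model <- threadSequence(keep[[1]], "EPLMHPR", prefix = "MPM", suffix = "V",
                        offset = 612)
model@sequence
#> [1] "MPMEPLMHPRV"
```

Only the extended conformers span ≥ 20 Å and survive the filter, matching
the conclusion that the bound peptide must be highly extended; threading
rebuilds the p107 peptide `MPMEPLMHPRV` numbered 612–622.

A thin command-line wrapper for the scanner lives in
`inst/scripts/slimtool.R`:

```sh
Rscript inst/scripts/slimtool.R scan \
    --pattern 'p[ST]-P-x(4,10)-[RK]-V-x-x-[VI]-R' \
    --fasta proteome.fasta --out hits.tsv
Rscript inst/scripts/slimtool.R enrich \
    --pattern 'p[ST]-P-x(4,10)-[RK]-V-x-x-[VI]-R' \
    --fasta proteome.fasta --targets interactors.txt
```

## Limitations

The structure-side pipeline stops at the pre-refinement placement: no
FlexPepDock-style refinement, no phosphoserine parameterization (the Glu
phosphomimetic convention is retained), and no disorder/conservation
scoring.  Published proteome counts depend on the specific Swiss-Prot
release and on an unstated hit-counting convention; this package's
one-hit-per-(phosphoacceptor, anchor) rule is a deterministic convention,
stated in `?scanSequence`.
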