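---
title: "Methods: curation, harmonized orthology and ohnolog detection for the connexin family"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: curation, harmonized orthology and ohnolog detection for the connexin family}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`connexo` implements a complete, self-contained workflow for gene-family
evolution analyses of the connexin (gap-junction protein) family across
vertebrates: signature-based curation of candidate coding sequences,
cysteine-anchored alignment of the two conserved extracellular-loop domains,
distance-based tree inference with bootstrap support, harmonization of
orthogroup names by incremental tree building from three starting points,
naming rules for lineage genes without clear orthology (the cyclostome
situation), classification of within-species duplicates into
whole-genome-duplication (WGD) ohnologs versus tandem duplicates, and a
birth-death gene-family simulator that provides ground truth for every one
of these steps.

This vignette explains the models and conventions behind each stage, the
defaults and why they were chosen, and what the simulation-based validation
does and does not demonstrate.

## Curation by conserved-domain signatures

Connexins are four-pass transmembrane proteins whose two extracellular
loops each carry three invariant cysteines with canonical spacings:
`C-x(6)-C-x(3)-C` in loop 1 (E1) and `C-x(4)-C-x(5)-C` in loop 2 (E2).
`locateConservedDomains()` searches the translation for the first E1 match
and the subsequent E2 match, interpreting `x` as any residue (new cysteines
occasionally arise in the spacer positions of real sequences and do not
invalidate the signature). Both motifs are configurable because some family
members — notably the epsilon-like genes — carry deviating loops.

The located motif is widened by `extension_nt/3` residues on each side
(default 15 nucleotides, i.e. five codons) to give the domain span used for
alignment. Two validity layers follow:

* **Motif completeness** — a record missing either signature is excludable
  (`missing_domains`, `single_domain`), matching the practice of excluding
  predictions lacking proper cysteine patterns or retaining only one
  conserved domain.
* **Transmembrane context** — the mean Kyte–Doolittle hydropathy of the
  `tm_window = 19` residues flanking each side of the domain *core* (the
  motif ± 5 residues) must exceed `tm_min_hydropathy = 1.0`. Random
  protein averages about −0.2 on this scale and membrane helices typically
  exceed 1.5, so 1.0 separates the two regimes with margin. The check is
  anchored to the motif core rather than the configurable alignment
  extension because the transmembrane helices physically flank the
  extracellular loop itself, not an arbitrary analysis window.

Near-duplicate removal (same species, full-length nucleotide identity above
`identity_threshold = 99%`, first-listed record kept) reflects the
observation that re-predicted sequences differing by a few nucleotides are
usually individual variation or assembly artifacts rather than genes. The
kept and excluded sets always partition the input, and every exclusion
carries a machine-readable reason.

Coordinates are 0-based half-open internally and printed 1-based inclusive;
minus-strand records are reverse-complemented on ingest so the stored CDS
is always the coding strand.

## The domain alignment

`alignDomains()` builds the concatenated two-domain alignment with the six
motif cysteines constrained to dedicated anchor columns. Each domain is
split at its cysteines into four segments (left flank, two inter-cysteine
segments, right flank); homologous segments are aligned across records with
a deterministic center-star procedure: the longest segment is the center,
every other segment is aligned to it by global pairwise alignment
(BLOSUM62, gap open 10, extend 0.5), and the per-sequence insertions are
merged into shared gap columns. Segments of equal length are placed
positionally, which both avoids spurious gap pairs between diverged but
indel-free segments and is exact for the simulator's indel-free output. The
two domains are aligned independently and concatenated, and a per-row
residue-index map guarantees the round trip: ungapping any row reproduces
that record's extracted domain residues in order.

The codon-position-1-and-2 view (`nt12View()`) emits, for every amino-acid
column, the first two codon positions of the underlying codon (gaps
propagate as double gaps); this is the nucleotide representation commonly
used for tree building when third positions are saturated.

For the analyses in this package the alignment window is widened to
`extension_nt = 60` (20 residues per side, 104 amino-acid columns), which
approximates the roughly 200-position conserved-domain alignments used for
published connexin trees; the curation default remains 15 nt. The spec of
the domain extent past the cysteines is operational, so we report column
counts with and without gap-only columns where relevant.

## Distances, Neighbor-Joining and bootstrap

`pairwiseDistances()` computes, for each pair of rows, the proportion *p*
of differing sites over mutually ungapped columns (pairwise deletion;
complete deletion is available). Three models transform *p* into a
distance:

* `p_distance` — *p* itself;
* `poisson_gamma` — the closed form *d* = α((1 − p)^(−1/α) − 1), the
  Poisson correction under gamma-distributed site rates with shape α. For
  fixed *p* it decreases strictly in α with limit −ln(1 − p);
* `jtt_gamma` — the divergence *t* solving E[p | t, α] = p, where the
  expected difference curve comes from the spectral decomposition of the
  published JTT replacement matrix (normalized to one expected substitution
  per site per unit time) averaged over *k* = 8 equal-probability discrete
  gamma categories, inverted by monotone bisection on t ∈ [0, 20]. This is
  a method-of-moments estimator, chosen for determinism and testability
  against simulation; a maximum-likelihood pairwise estimator could differ
  in the second decimal at high divergence.

Pairs with zero comparable sites are flagged `incomparable`; pairs with *p*
at or beyond 99% of the model's asymptote (1 − Σπ² ≈ 0.94 for JTT) are
flagged `saturated`. Flags give NA distances rather than silently truncated
values; the tree stages replace flagged distances with a model ceiling so
bootstrap replicates near saturation remain defined.

`neighborJoining()` is the standard Saitou–Nei agglomeration with two fixed
conventions: ties in the Q-criterion break to the lexicographically
smallest index pair, and negative branch-length estimates are clamped to
zero with the overflow moved to the sibling edge so the joined pair's path
length is preserved (the unclamped estimates are available with
`clampNegative = FALSE`). On additive matrices the output reproduces the
generating path-length matrix to numerical precision; the test suite
verifies this against brute-force topology enumeration for up to six taxa
and against `ape::nj` as an independent implementation.

`bootstrapSupport()` resamples alignment columns with replacement
(codon-position pairs are resampled as units for nt12 matrices), rebuilds
the NJ tree per replicate, and annotates each internal edge with the
percentage of replicates containing the same bipartition. Replicate *b*
draws from a stream seeded `seed + b`, so results are reproducible and
independent of the replicate count of other runs. The published convention
for display — supports below 30 hidden, 500 replicates — is available via
`writeTreeWithSupports(threshold = 30)` and the `B` parameter; tests and
examples use smaller B for speed.

Zero-information alignments (all sequences identical) still return the NJ
tree of the original data with supports computed as usual; the resolution
of such trees is arbitrary and documented rather than special-cased.

## Orthology harmonization by three build orders

The harmonization protocol builds NJ trees (JTT, α = 1, pairwise deletion,
no bootstrap) from three starting points, adding one vertebrate group set
per step:

* `mammal_down` — seed with mammals (A–C), add the remaining tetrapods,
  the lobe-finned fish, the non-teleost ray-finned fishes and
  Chondrichthyes before teleosts;
* `teleost_out` — seed with teleosts, add the other actinopterygians, then
  Chondrichthyes, then build upwards;
* `chondrichthyes_up` — seed with Chondrichthyes, build upwards, teleosts
  last.

The first order is the naming pass: anchor sequences carry established
names (committee names for mammal sequences, previously established names
for teleost sequences in the reference scenario), and every other sequence
receives the majority label of its smallest enclosing clade that contains
reference-labeled leaves, with ties left unplaced. Distances are computed
once on the full alignment and subset per step — exact under pairwise
deletion — so the step trees cost only the NJ agglomeration.

The remaining orders are consistency checks, mirroring the original
protocol's purpose of ascertaining that sequences are "generally kept
within the same group": each starts from its own seed group carrying the
naming-pass labels, re-derives every induced label at every step, and takes
its final label from the complete tree. A sequence whose induced label
changes between steps is flagged internally inconsistent — this happens,
for example, when a group is added before any reference of its orthogroup
is present, which is precisely the situation where affiliations "change as
more sequences are added". The final flag is `consistent` only when all
three orders agree and none saw a mid-protocol change; conflicts are
surfaced with the candidate labels rather than resolved silently. We chose
final-tree labels over freezing first inductions because freezing lets one
premature error cascade through subsequent steps, turning a flaggable
wobble into a hard error — the step trees are probes, not label sources.

`assignOrthogroupNames()` applies the case convention: orthogroups
containing at least one mammalian sequence take the anchor's committee name
upper-cased; orthogroups without mammalian members take a configured
lower-case name or placeholder. A label whose members carry two different
committee names (e.g. both GJB2 and GJB6 anchors) is flagged for manual
resolution, never auto-merged.

### Lineage genes without clear orthology

For lineages that only partly follow the orthogroup structure (the
cyclostome situation), `nameUnplacedLineageGenes()` clusters the lineage
leaves into maximal lineage-only clades and names each cluster by mean
conserved-domain amino-acid identity to the orthogroups:

1. nearest orthogroup clearly ahead (≥ 3 percentage points over the
   runner-up, motivated by the observed contrast of ~92–93% versus ~83–85%
   identity in such decisions) → that orthogroup's lower-case name;
2. two orthogroups approximately equidistant but jointly standing out →
   a combined name (`gjd1/2` style);
3. no clear affinity → subfamily prefix plus `-genN`, numbered per
   subfamily.

Within a multi-gene cluster, members on the same assembly unit within the
linkage window (default 1 Mb; real tandem pairs typically lie 10–100 kb
apart) receive `.1`, `.2` suffixes (tandem duplication), members on
different units receive `a`, `b` (duplicates whose mechanism cannot be
asserted); missing locations make the distinction undecidable and fall
back to `-genN` with a warning.

## Ohnologs versus tandem duplicates

`detectDuplicatePairs()` pairs same-species leaves within an orthogroup
when they form a cherry or are reciprocal nearest neighbors by patristic
distance (the fallback catches cherries broken by assembly fragmentation;
it can be disabled). Pairs are classified purely from genomic locations:
different assembly units → `ohnolog` (the different-chromosome signature of
genome duplication), same unit within the linkage window → `tandem`, same
unit beyond the window or unknown location → `unresolved`. Same-species
groups larger than two are emitted as all within-group pairs with a
multiplet flag, since such "pairs" may be genetic reality or assembly
error. Note the classifier deliberately equates "different chromosomes"
with ohnology, as is conventional; a dispersed small-scale duplicate is
therefore indistinguishable from an ohnolog by location alone.

Identities are computed by global alignment: full-length nucleotide
identity for duplicate pairs (matches over mutually ungapped columns) and
conserved-domain amino-acid identity where domain annotations are
available. `summarizeIdentities()` reports count, mean, minimum and maximum
per species over ohnolog-class pairs — the summary in which a young genome
duplication (near-identical pairs) separates cleanly from an old one
(pairs around 70–80% identity).

## The simulator

`simulateHistory()` generates a gene-family history with full truth labels:

* a **family radiation** — a coalescent-topology ultrametric tree over the
  root orthogroups spanning `orthogroup_stem = 3` time units above the
  species root, with internal splits floored at `family_min_split = 0.6`
  of the stem so no two orthogroups are nearly identical. This gives the
  family a nested substructure, like the real subfamilies, instead of an
  idealized star;
* **birth–death** gene evolution along the species tree (defaults
  λ = 0.04, μ = 0.02 per gene per time unit) with tandem duplications
  (probability 0.4, offsets 10–100 kb on the same unit) versus dispersed
  duplications (fresh assembly unit);
* **WGD events** on chosen terminal edges: every gene present duplicates
  with the retention probability, the copy landing on a fresh unit. The
  reference scenario places an old event on the teleost-like stem (age
  0.35 of the root age, retention 0.4) and a young event on the
  sturgeon-like stem (age 0.035, retention 0.9), echoing the relative ages
  and retention patterns of the teleost and sturgeon duplications.

Truth bookkeeping: ohnolog partners are the extant descendants of the two
sides of a WGD duplication; tandem partners the two sides of a tandem
duplication. A copy relocated by a later dispersed duplication or WGD drops
the tags that no longer describe its locus, so the structural invariants —
ohnolog partners on different units, tandem partners linked on one unit —
hold for every seed.

`evolveSequences()` evolves the coding sequence along the gene-lineage
forest with a transition-biased (κ = 2) jump process, gamma site rates
(shape 1) multiplied by region factors from the template: conserved domains
0.03, transmembrane helices 0.3, loops and termini 1.6. Three forms of
purifying selection keep every simulated gene a valid family member: motif
cysteine codons, the start codon and the terminal stop are invariant;
substitutions creating internal stops revert; and transmembrane codons only
accept strongly hydrophobic residues (A, F, I, L, M, V — cysteine excluded
so the loop signatures stay unambiguous). The generative model is
deliberately nucleotide-level (not JTT) so that validating the JTT-based
inference against it is not circular.

Rate calibration is anchored to published family statistics: with
substitution scale 1.0 per unit time, old-WGD ohnolog pairs sit near
80–83% full-length nucleotide identity (the teleost range is 72–82%),
young-WGD pairs near 96–97% (the sturgeon value is ~97%, range
88.4–99.2%), within-orthogroup conserved-domain amino-acid identity is
~92–94% and between-orthogroup identity ~65–70% (the published contrasts
are ~92–93% within versus 83–85% for the nearest neighbours and 70–80%
within subfamilies). Because the simulated orthogroups radiate more
independently than real subfamily neighbours, the between-orthogroup
identities sit at the low end of the real range; the within/between
*ordering*, which drives every decision rule, matches.

Optional per-orthogroup rate multipliers emulate the large conservation
differences between real family members (published per-orthogroup gamma
shapes range from below 0.3 to above 1.6). The gamma-sweep validation uses
one fast orthogroup (multiplier 10, applied below the family radiation so
the orthogroup is internally divergent without drifting away from the
family) inside a family with `family_min_split = 0.35` and site-rate shape
0.5 — conditions under which a low inference shape (α = 0.8) sometimes
fragments the fast orthogroup while α ≥ 1 keeps it united.

## Validation scope and problem sizes

The test suite and the acceptance script validate, at desk scale:

* NJ on 200 random additive matrices (4–8 taxa; brute-force topology
  enumeration as the oracle for ≤ 6 taxa);
* the Poisson+Γ closed forms and ordering properties;
* the JTT+Γ estimator against exact continuous-time simulation under the
  JTT generator (true divergences 0.1–1.0, 200 sites, 100 replicates per
  point, mean within 10%);
* end-to-end orthogroup recovery on the reference scenario (14 groups,
  20 orthogroups, both WGDs; F1 ≥ 0.95 and ≥ 95% agreement between build
  orders);
* the young-versus-old WGD identity ordering over 100 simulated seeds of a
  four-lineage scenario (10 orthogroups per seed);
* gamma-sweep fragmentation monotonicity over 12 seeds.

These sizes were chosen so the whole validation runs in minutes on one
CPU while keeping sampling error far from the decision thresholds.

What passing does **not** show: the simulator has no indels inside domains,
no assembly errors or missing data, no pseudogenes, no gene conversion, and
its orthogroups radiate more cleanly than real subfamily neighbours do.
Real-data performance therefore depends on curation and alignment quality
in ways the simulation cannot probe; the consistency flags, exclusion
reasons and conflict flags exist precisely to route those cases to human
review instead of silently absorbing them.

## Numerical conventions

* Distances: bisection to 60 iterations on t ∈ [0, 20]; saturation ceiling
  at 99% of the model asymptote; discrete-gamma category means via the
  incomplete-gamma formula, renormalized to mean 1.
* NJ: Q-criterion ties to the lowest index pair; negative branch clamping
  with sibling overflow; 3-taxon termination by the three-point formulas.
* Trees are serialized as Newick with integer supports as internal node
  labels; the root label of an unrooted tree is empty.
* All randomness flows from explicit integer seeds; bootstrap replicate b
  uses seed + b, and the simulator derives its sequence-evolution stream
  from the history seed by a fixed offset.
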