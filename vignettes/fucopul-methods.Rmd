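---
title: "Methods: genome-resolved profiling of sulfated polysaccharide degraders"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: genome-resolved profiling of sulfated polysaccharide degraders}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fucopul)
```

## The problem

Fucose- and rhamnose-containing sulfated polysaccharides (FCSPs,
fucoidan-like polymers secreted by diatoms and brown algae) are among the
most recalcitrant fractions of marine organic matter. Degrading them
takes an unusual enzymatic toolkit: many alpha-L-fucosidases and
alpha-L-rhamnosidases, sulfatases matched to the sulfation pattern, and a
way to survive the toxic lactaldehyde produced when the liberated methyl
pentoses (fucose, rhamnose) are catabolised -- bacterial microcompartments
(BMCs) that sequester the aldehyde. `fucopul` implements the
genome-resolved workflow used to find such specialist degraders among
metagenome-assembled genomes (MAGs): quality control, dereplication,
abundance time series, enzyme content profiling, gene-neighbourhood
classification of polysaccharide utilization loci (PULs), BMC locus
detection, and mapping of metaproteome evidence back onto MAGs.

Every stage is testable without external data because the package ships a
synthetic mock-community generator that plants known cluster structure,
abundances, gene neighbourhoods and spectral counts, and records them as
ground truth.

## MAG quality control

A bin passes QC when

\[ \%\mathrm{completion} - 5 \times \%\mathrm{contamination} > 50 \]

(strict inequality; percentages on the 0--100 scale). For representative
selection the score adds a contiguity term:

\[ Q = \%\mathrm{completion} - 5 \times \%\mathrm{contamination}
     + \tfrac{1}{2}\log_{10}(N50). \]

The N50 term is intentionally weak -- one order of magnitude of contiguity
is worth half a point -- so it only breaks near-ties between bins of
similar completeness. Because the N50 term is non-negative for any
N50 \(\ge\) 1 bp, every bin passing the filter scores above 50.

## Dereplication

Pairwise ANI records (FastANI-style, directed and typically asymmetric)
are thresholded into an undirected graph: an edge exists when at least
one direction has ANI \(\ge\) the threshold *and* aligned fraction
\(\ge\) 0.65. The either-direction rule is a package choice: directionality
handling is not standardised for asymmetric ANI output, and the
symmetric reading is the most permissive one consistent with a single
undirected graph. Clusters are the connected components (single
linkage), matching the usual graph reading of ANI networks; 95% ANI
approximates the species boundary and 99% the strain boundary, so a
community dereplicated at both thresholds yields nested partitions.

The representative of a cluster is its highest-scoring member, with one
override: when 16S preference is enabled and any member encodes a 16S
rRNA gene, the choice is restricted to 16S-bearing members (a
higher-scoring MAG lacking 16S is not selected over one that has it --
representatives anchor downstream probe design, which needs the 16S).
Ties break to the lexicographically smallest bin id, a deterministic
convention.

## Abundance: TAD / rpoB

Per-sample MAG abundance is the quotient of two coverages:

\[ \mathrm{abundance}(m, s) = \frac{\mathrm{TAD}_{0.8}(m, s)}
      {\mathrm{depth}_{rpoB}(s)} \]

* **TAD** (truncated average depth): per-position (or per-tile) depths
  are sorted and the lowest and highest \((1-c)/2\) count quantiles
  discarded (count-based, rounded down; with `central_fraction` \(c=0.8\)
  this is TAD80, the convention of the methodology this follows). The
  trim removes spikes from conserved regions and dips from assembly
  gaps. A MAG's TAD concatenates all its contigs' depth vectors first, so
  contigs weigh by length and the trim acts genome-wide. With
  \(c = 1\) TAD is the plain mean; TAD is permutation-invariant and
  scale-equivariant, so multiplying a sample's depths by a constant
  leaves relative abundance unchanged.
* **rpoB depth**: the TAD over the pooled depth values of all
  rpoB-tagged regions of the sample's assembly. rpoB is single-copy, so
  its community-wide depth approximates total genome equivalents per
  sample; pooling positions (rather than averaging per-gene TADs) treats
  it as one community-level normaliser.

A MAG absent from a sample (no depth profile) is reported with abundance
0 and a `present = FALSE` flag rather than dropped, keeping time series
rectangular.

## Annotation acceptance and content profiles

Similarity-search annotations (MEROPS peptidases, TCDB transporters) are
accepted at >40% identity and >50% query coverage, both strict, with no
family whitelist. CAZyme calls require dual evidence: the BLASTp match
passes the same gate, the HMM hit has E-value < 1e-15, and both tools
name the same CAZy family. Acceptance rules are pure functions of the
evidence rows, so row order never matters.

Per-MAG profiles count glycoside hydrolases (tags `GH<n>`, subfamilies
included), sulfatases (S1 subfamily tags `S1_<n>`), peptidases
(`MEROPS:` prefixed tags), fucosidases (GH29, GH95, GH141, GH151,
GH139) and rhamnosidases (GH78, GH90, GH106), each also expressed as a
percent of total predicted genes. A MAG is flagged *dual-high* when both
GH and sulfatase contents reach 1.0% (inclusive) -- the signature of a
dedicated polysaccharide degrader. A gene carrying two accepted families
counts once per family in family counts but once in the GH total.
Group summaries retain full precision and additionally carry the rounded
reporting columns (integer percent shares, 1-decimal means): printed
community tables can be reproduced without losing precision internally.

Content comparisons between groups use the two-sided Wilcoxon rank-sum
test: exact enumeration when the combined n is at most 20 without ties,
the normal approximation with tie correction otherwise; degenerate
all-identical input returns p = 1 with a warning instead of failing.

## PUL classification

Neighbourhood windows take up to ten genes on each side of an anchor
fucosidase/rhamnosidase gene (at most 21 genes); a window is *complete*
only when both sides have the full ten, so fragmented contigs are
visibly flagged. Classification applies a rule table in fixed precedence
order, first match wins:

| order | type  | signature |
|-------|-------|-----------|
| 1 | PUL-7 | two contiguous inward-pointing GH29 genes (+ then -) and S1_15; PF03629 recorded as supporting |
| 2 | PUL-3 | S1_17 and S1_25 |
| 3 | PUL-4 | one of S1_7/S1_8/S1_19 and one of GH139/GH141 |
| 4 | PUL-5 | S1_22 and one of GH2/GH31/GH36; S1_17 supporting |
| 5 | PUL-6 | S1_16 and one of GH2/GH31/GH36 |
| 6 | PUL-1 | no sulfatase tag in the window, and PF07859 present |

Precedence is a package decision: the strand-geometry and
dual-sulfatase signatures are the most specific and therefore outrank
the weaker single-feature rules, ending with the sulfatase-free PUL-1.
"Inward pointing" is operationalised as an adjacent (+, -) pair --
converging 3' ends. PUL-2 is kept as a named but disabled rule slot: it
is a recognised arrangement without a discriminating feature set, so it
is never auto-assigned; users may enable it by editing the rule file.
The rule table is data (`inst/extdata/pul_rules.yaml`), not code, and an
alternative file can be passed to `classify_pul()`. Anchors in ortholog
group GH29-a with an adjacent GH43_12 xylosidase gain the annotation
"sulfated fucose/xylose". Whether PUL-5 additionally requires an S1_17
homolog is ambiguous in the source material; S1_17 is treated as
supporting evidence only. Minimum counts for "enriched" sulfatases are
likewise unquantified; presence (\(\ge 1\)) is used.

## BMC locus detection

Contigs are scanned for rank intervals of at most `span` (default 25)
genes holding at least three BMC-H shell genes (Pfam PF00936) and at
least one BMC-P gene (PF03319; the shell-domain accession sometimes
printed as "PF003319" is normalised to PF03319). Qualifying intervals
separated by at most `merge_gap` (default 5) genes merge into one locus,
reflecting shell genes organised as two contiguous sub-loci. The
reported span is trimmed to the outermost shell genes; accessory enzyme
presence (aldolase, aldehyde/alcohol dehydrogenase, phosphotransacylase,
kinase) is read from the whole merged candidate region, because these
enzymes flank the shell core rather than sit inside it. A locus is
*PV-BMC-like* when it carries the AraD-like aldolase that generates the
lactaldehyde the compartment exists to contain. No locus with fewer than
three BMC-H genes is ever emitted. Span and gap defaults are package
choices (the source material says "contiguous" without counts) and are
configurable.

Pathway completeness labels a genome fucose-capable when fucP, fucI,
fucU and the aldolase are all present, and rhamnose-capable when rhaT,
rhamA, rhaM, rhaB and the aldolase are.

## Metaproteome mapping

NSAF for protein \(i\) in one sample-replicate is
\((\mathrm{SpC}_i / L_i) / \sum_j (\mathrm{SpC}_j / L_j)\); values sum
to 1 per run. NSAF is computed per replicate and then averaged --
computing it on summed counts would weight replicates by depth and is
not the same statistic. Averaging divides by the full replicate count
with absent identifications contributing zero: \{0.3, absent, 0.3\}
over three replicates is 0.2. Detected proteins map to MAG proteins at
\(\ge\) 99% identity and \(\ge\) 50% alignment coverage; both bounds are
read as inclusive (the coverage clause is explicitly "equal or greater";
the same reading is adopted for identity and documented here), each
detected protein taking the best-identity surviving match with
lexicographic tie-break. Raising the identity threshold can only remove
assignments.

## The synthetic community generator

The generator emulates the statistical structure of a bloom-associated
community survey: species-level ANI clusters (optionally with nested
strain subclusters), per-sample planted abundances, planted PUL and BMC
neighbourhoods, and replicated spectral counts with dropouts.

Key design choices:

* **No nucleotide simulation.** No in-scope stage consumes sequence, so
  bins carry contig lengths and gene coordinate tables, and the ANI
  table is emitted directly from the planted cluster structure:
  within-strain pairs at or above `within_cluster_ani` (default 99.5%),
  between-cluster pairs at or below `between_cluster_ani` (default
  80%), strain pairs at `strain_ani` (default 96.5%) when substructure
  is enabled. Any threshold strictly between the planted levels
  therefore recovers the planted partition exactly -- this separability
  is a tested property, and dereplication at 99% and 95% recovers
  strains and species respectively.
* **Depth model.** Expected depth of a cluster at fraction \(f\) is
  \(f \times\) `total_depth` (default 500x, placing default fractions at
  25--150x). Noise is Poisson per 100-bp tile by default, with a mean-1
  lognormal multiplier and a noise-free mode as alternatives; both are
  standard coverage noise models and the choice is an artifact decision,
  not a claim about any particular survey.
* **rpoB normaliser.** Each bin carries one rpoB-tagged marker gene, and
  each sample additionally carries one community-wide rpoB pseudo-contig
  whose expected depth is `total_depth` -- the analogue of pooling reads
  against a curated rpoB database over the whole metagenome. With noise
  off, TAD/rpoB then returns the planted fractions exactly (a tested
  closed loop); under Poisson noise at \(\ge\) 20x the median relative
  error stays under 10%.
* **Locus planting is rule-driven.** `plant_pul()` reads the active rule
  table and inserts exactly the features the rule requires (anchor GH29,
  the inward partner where required, every `all_of` tag, one tag per
  `any_of` group) into a cleared 21-gene window, so a planted window
  satisfies its rule by construction and triggers no higher-precedence
  rule. Planted loci round-trip through `classify_pul()` at 100%, by
  test.
* **Spectral counts** are Poisson draws whose expectation scales with
  protein weight and the planted abundance of the origin bin's cluster;
  dropouts replace counts with absence at a configured rate (checked
  against the binomial interval in tests). Protein match evidence links
  each detected protein to its origin at \(\ge\) 99% identity with
  lower-identity cross-bin decoys, so noiseless mapping recovers the
  planted origin for every protein.

What the generator does **not** emulate: real sequence composition and
assembly artefacts, chimeric bins, ANI estimation error near the
thresholds, depth autocorrelation along contigs beyond the tile scale,
protein inference ambiguity, and compositional coupling between taxa.
Passing tests therefore demonstrate the correctness of the
implementation's logic and its statistical behaviour under the stated
models -- not robustness to every artefact of real survey data.

## Numerical conventions and degenerate inputs

* Quantile trimming is by count with floor rounding, ties kept from the
  low end; at least one value is always retained.
* Strict vs inclusive boundaries follow the stated rules: QC filter and
  the 40/50 similarity gate are strict; the 1% dual-high flag and the
  99/50 protein-mapping thresholds are inclusive.
* All deterministic tie-breaks are lexicographic (representatives,
  protein assignment).
* Degenerate inputs fail loudly and early with the offending field or
  record named: empty depth vectors, zero total genes, all-zero spectral
  counts, malformed ANI rows (with row number), missing contig profiles
  (with contig id). All-identical content comparisons return p = 1 with
  a warning. A pipeline run in which no bin passes QC terminates cleanly
  with a classed condition rather than an error.
* Pipeline outputs are written atomically (temp file + rename, all files
  at the end of the run), carry a header with the package version,
  config hash and seed, and are byte-identical on rerun with the same
  config.

## Problem sizes

The shipped test and acceptance workloads use communities of 3--4
clusters with 2--4 bins each (6--12 bins, ~1 800--3 600 genes), 1--20
samples at 100-bp tiles over 300-kb genomes, 20 replicate plantings per
PUL type, and spectral tables of a few hundred proteins over three
replicates -- sizes chosen so the full suite exercises every code path in
well under a minute while keeping all planted signals at realistic
coverage (\(\ge\) 20x) and count levels.

## Known limitations

* ANI, ortholog groups, checkM-style quality metrics and spectral counts
  are *inputs*; the package does not compute them from sequence.
* The PUL rule table encodes presence/absence and one strand-geometry
  signature; it does not model gene order beyond adjacency, nor
  transporter synteny.
* Single-linkage clustering inherits the usual chaining caveat: one
  spurious high-ANI edge can merge clusters, mitigated by the aligned
  fraction gate.
* NSAF is a relative measure; comparisons are valid within a sample, not
  across proteomes of very different depth.
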