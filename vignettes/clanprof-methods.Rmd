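---
title: "Methods: phylogenomic affinity profiling with clanprof"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phylogenomic affinity profiling with clanprof}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clanprof)
```

## The question and the model

`clanprof` asks where a small focal clade — three genomes, modelled on the
sequenced Aquificae — sits phylogenomically relative to named candidate
partner lineages (Archaea R, Epsilonproteobacteria E, Thermotogae T) when
lateral gene transfer (LGT) may have scrambled much of the signal.  It
combines two complementary, deliberately simple instruments:

* **Phyletic profiles** use only presence/absence of homologs across
  genomes.  They are cheap and genome-wide but blind to the *degree* of
  relatedness.
* **Gene trees** use the full relatedness structure but exist only for
  clusters with enough partners, and each tree is noisy.

Both are referenced to the *clan* structure of unrooted trees: a clan is
the leaf set on one side of an edge, the unrooted counterpart of a clade.
No rooting of gene trees is ever assumed; every operation is a function of
splits only, so results are invariant to how an upstream tool happened to
root its output.

### Homolog clusters

Clusters are seeded on the focal genomes.  A strict graph connects focal
proteins with *bidirectional* hits at `e_bidir = 1e-10`; connected
components then recruit every subject hit at `e_member = 1e-5`.  The two
thresholds play different roles: the strict, reciprocal one decides which
focal proteins are the *same* family (orthology-like), the loose one
decides how far the family's homolog neighbourhood reaches.  Each cluster
is `single`- or `multi`-copy according to whether any focal genome
contributes more than one member.

Recruited subjects are restricted to non-focal proteins.  This is a design
choice where the verbal procedure is ambiguous: allowing a cluster to
recruit a focal protein that belongs to another component would let
clusters overlap on the very objects they are meant to partition.  As
implemented, clusters partition the focal proteins exactly, while a
non-focal subject may legitimately be recruited by several clusters (such
subjects are visible as duplicates across the `members` list-column).

### Clean and dirty ranked profiles

For each cluster a focal query *P* is chosen from the highest-priority
focal genome present (priority is the order of the focal group definition;
ties break lexicographically).  All other members are ranked by ascending
e-value of the *P*-to-subject hit.  With *k* other focal proteins, the
vertical expectation is that they occupy ranks 2 … *k* + 1 exactly
(**clean**); any foreign protein interleaved among them marks the cluster
**dirty**.  Numerical conventions:

* a missing hit record ranks last at e-value +Inf rather than erroring —
  similarity search output is routinely truncated;
* ties are broken by descending bit score, then lexicographic protein id,
  so the classification is deterministic and invariant to row order and to
  duplicated records;
* an exact e-value tie between a focal and a foreign protein is resolved by
  that same ordering — a tie can therefore decide clean vs dirty, which is
  unavoidable in a rank-based statistic and is documented rather than
  hidden;
* clusters with no non-focal member are **degenerate** and excluded from
  clean/dirty denominators.

### Clan cohesion, distances, and the balance of support

The focal genomes are *cohesive* in a tree when some split has exactly
their leaves on one side (a homogeneous clan); single-leaf groups are
cohesive by convention.  Distance from the clan to a group is the number
of internal edges strictly between the clan's defining edge and the
group's nearest leaf's pendant edge — 0 when a group leaf attaches at the
clan's outer node.  Nearest-leaf distance is the weakest assumption among
the plausible operationalisations (nearest leaf, nearest homogeneous clan,
all members) and is the one implemented; the choice only matters for
groups that are themselves scattered.

The **balance of support** between partners X and Y over bootstrap
replicates adds +1 per replicate with X strictly closer, −1 with Y
strictly closer, 0 otherwise.  Replicates where the focal genomes are not
cohesive, where either group is absent, or where the distances tie
contribute 0 — absence of evidence is never converted into evidence.  The
score is antisymmetric by construction and bounded by the replicate count;
`|score| > 0.70 · n` flags a strong preference.

**Supported pairings** take the ML tree's own supports: the smallest clan
strictly containing the focal clan whose defining edge reaches
`min_support = 70` defines the partner set; its non-focal leaves'
lineages are credited.  Size ties go to the higher support.  Note that a
well-supported partner clade *excluding* the focal clan also defines a
containing clan on its complement side; this is intended — support for
"E elsewhere" is support for "focal with the rest".

### Functional categories and the VPI

COG categories are assigned by a four-step priority: direct mapping of
member proteins; majority vote over annotated hit subjects at
`e_func = 1e-15`; GO-derived categories restricted to experimentally or
computationally verified evidence codes (IMP, IGI, IPI, IDA, IEP, ISS,
IGC, ICA); otherwise `unknown`.  Ties at any step fall through to the next
rather than being broken at random, keeping assignment deterministic.

The Variable Preference Index for group g is

$$\mathrm{VPI}(g) = \frac{\#\{\text{profiles containing } g\} \setminus \{\text{all-partner profiles}\}}
                         {\#\{\text{profiles}\} \setminus \{\text{focal-only profiles}\}}$$

so for g = E with partners R, E, T: (E + RE + ET) / (RET + RE + RT + ET +
R + E + T + Other).  The denominator keeps single-partner profiles and
"Other" profiles; only focal-restricted profiles are excluded — we follow
the explicit formula rather than the looser verbal gloss, which could be
read as also dropping single-partner profiles.  Consequences asserted as
properties: VPI ∈ [0, 1]; adding focal-only profiles changes nothing;
adding ubiquitous profiles can only lower every VPI; the three VPIs sum to
at most 2.

### Alignment trimming and supermatrices

Confidence-annotated alignments carry one consensus posterior probability
per column; columns strictly below `trim = 0.80` are removed and the
deleted non-gap residue fraction reported.  How upstream aligners'
per-residue confidences combine into one per-column consensus is not
standardised, so the package takes the consensus track as input (a
one-line comma-separated sidecar next to the FASTA) rather than guessing.
Supermatrix assembly requires one sequence per genome per gene (apply
`reduce_inparalogs()`, which keeps the shortest terminal branch, first),
pads missing genomes with gaps, and emits a per-gene partition table.
Genus reduction on a guide tree downsamples any genus with more than two
leaves forming a homogeneous clan to one representative from each side of
the genus's earliest split.

## The synthetic generator: what it emulates

`simulate_dataset()` builds the statistical structure the analysis
assumes, with known truth:

* A fixed backbone phylogeny: focal clade ((A′,H′)S′), sister lineage E′
  attached directly at the focal node, then T′, R′ and an unaffiliated
  "other" pool progressively further along the backbone, each lineage a
  rake.  This makes the nearest-leaf internal-edge distances strictly
  ordered E′ < T′ < R′ < Other in every pruned family, so without noise
  the balance of support for the true sister saturates at +n replicates —
  a designed invariant, used by the acceptance checks.
* Per family, a phyletic pattern category is drawn from `pattern_freqs`
  (defaults approximate a core gene set dominated by widely shared
  profiles: RET 0.43, ET 0.23, Other 0.10, E 0.07, RE 0.05, R 0.04,
  T 0.03, RT 0.03, FocalOnly 0.02); the named lineages contribute a random
  non-empty genome subset (inclusion probability 0.6).  Named patterns are
  generated exclusively (no "other" genomes mixed in), which keeps the
  truth table exact; the inclusive/exclusive query machinery is exercised
  against randomised profiles in the tests instead.
* LGT is a single-leaf regraft: a focal leaf becomes the cherry partner of
  a donor leaf, halving the donor's pendant edge.  This models single-gene
  transfer, matching the per-gene granularity of the analysis; subtree
  transfers are out of scope.
* E-values derive from patristic distances d through
  log₁₀ e = intercept + slope · d + N(0, σ), clipped to [10⁻¹⁸⁰, 10],
  with defaults intercept −130, slope 55, σ 0.25.  The slope is positive
  so that e-values increase with distance, which is the monotonicity the
  ranked classifier relies on; at σ = 0 the rank order equals the
  tree-distance order exactly.
* Bootstrap replicates are NNI perturbations of the true gene tree
  (per-internal-edge move probability `bootstrap_perturb`, default 0.05);
  ML supports are the replicate frequencies of each split.  Replicates
  perturb topology only — the pipeline consumes topologies.

What the generator does **not** emulate: residue-level evolution and
alignment error, realistic BLAST score statistics, unequal taxon sampling
across lineages, gene duplication (all simulated families are
single-copy; multi-copy classification is exercised on constructed
cases), and compositional artefacts.  Passing tests on synthetic data
therefore demonstrate the *logic* of the pipeline — that each statistic
recovers what it is defined to measure — not that real data meet the
model's assumptions.

A known blind spot, visible in the recovery runs: a transfer into a
family whose only non-focal genome is the donor itself is undetectable in
principle — the 4-leaf topology is unchanged and the regrafted leaf ties
with the donor at equal distance — which is why planted-transfer detection
is asserted at ≥ 95 % rather than 100 %.

## Numerical and reporting conventions

* Percentages in summary tables are whole numbers, rounded half up
  (`pct_round_half_up()`); printed reference tables use the same
  convention.
* Duplicate hit records collapse to the smallest e-value, ties to the
  larger bit score, then first occurrence.
* Newick supports are accepted as internal node labels in either the
  0–100 or the 0–1 dialect; 0–1 values are rescaled by 100, but only when
  a value strictly between 0 and 1 occurs (bare 0s and 1s are taken as
  percentages).  On construction each support is re-attached to the edge
  carrying the same bipartition, so unrooting cannot silently shift a
  support to a different split — node labels in rooted Newick are
  notoriously root-dependent.
* All trees are unrooted on entry; replicate trees have their labels
  stripped (only topology is used).
* Degenerate ranked profiles and trees with no non-focal leaf are excluded
  from the clean/dirty and cohesive/non-cohesive denominators
  respectively.

## Problem sizes

The test suite validates each operation against independent brute-force
oracles (edge-deletion split enumeration via igraph, direct sorting,
direct set logic) on at least 1 000 random instances per operation (trees
up to 14 leaves), checks balance antisymmetry and bounds on 500 random
tree sets, and runs ground-truth recovery on 500 simulated families at
zero e-value noise with and without planted LGT (rate 0.2).  The
acceptance script uses 200-family runs with 5 bootstrap replicates for
recovery rates and 20 families with 100 replicates for the
balance-of-support saturation check; these sizes give exact or
near-deterministic expectations while keeping each run in the order of
seconds.
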