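---
title: "Detecting and sub-typing electron-bifurcating [FeFe]-hydrogenase gene clusters"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and sub-typing electron-bifurcating [FeFe]-hydrogenase gene clusters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bfuscan)
```

## Scope and model

Electron-bifurcating group A3 [FeFe]-hydrogenases are heteromeric
complexes (BfuABC, plus optional accessory BfuD and sensory BfuT
subunits) in which the catalytic subunit BfuA produces or consumes H₂ at
the H-cluster while the BfuB/BfuC core splits the electron pair between
NAD⁺ and ferredoxin at an FMN site wired through a chain of iron-sulfur
clusters. `bfuscan` takes *annotated* genomes — protein FASTA, GFF3 gene
coordinates and a declared per-protein domain-architecture table — and
answers four questions per genome:

* which proteins are catalytic subunits (H-cluster motif screen);
* which motif anchors sit in a gene cluster with an intact bifurcating
  core (neighborhood extraction + retention filter);
* which of the five organizational sub-types each retained cluster
  belongs to (pattern classification with variant flags);
* whether the encoded complex is structurally predicted to bifurcate
  (FeS/flavin rule engine), with an alignment-free phylogeny as an
  independent cross-check of the sub-typing.

Domain detection itself (HMM search against Pfam-class databases) is
deliberately upstream of this package: architectures are inputs. That
keeps the rule engine free of any database dependency and makes every
rule testable in isolation.

## Coordinates and gene ranks

Coordinates are 1-based and inclusive at both ends throughout — the GFF3
convention, and the convention of the R/Bioconductor containers this
package interoperates with. Genes are ranked 1, 2, … along each contig in
coordinate order; the neighborhood window counts *ranks* (genes), never
base pairs, and reverse-strand genes keep their coordinate-order ranks.
Genes flagged `partial` in the GFF3 attributes, or whose coordinates
touch a contig terminus (known from `##sequence-region` pragmas), are
treated as truncated gene models. How truncated genes were flagged in
any particular upstream annotation is not standardized; the
attribute-plus-terminus rule is this package's operational definition.

## The motif screen

The three H-cluster binding motifs are degenerate patterns over the
amino-acid alphabet plus the wildcard `x`:

| motif | pattern | length |
|-------|---------------------|---|
| P1 | `xTSCxPxWx` | 9 |
| P2 | `xxMPCxAKK` | 9 |
| P3 | `ExMxCPGGCxxGxGQ` | 15 |

`scan_motif()` reports *every* window whose mismatch count at
non-wildcard positions is within tolerance (overlaps included; `X`
residues never match). The default tolerance is 0: the screen is a
presence test for near-exact signatures, and a sequence that needs
mismatches to "contain" a motif is exactly the kind of borderline case
(sensory-class relatives) users should see separately, not silently. The
`tolerant` mode of `call_bfuA()` reports genes that would only qualify
at one mismatch per motif as near-misses, without ever promoting them to
anchors. An anchor call requires at least one hit of each motif with
leftmost hits ordered P1 < P2 < P3; the leftmost-hit rule is the
tie-break when motifs occur more than once.

Motif positions are numbered 1-based within the pattern, so "P1 position
5" is the fifth pattern character. Conservation profiles use the plain
logo definition Rᵢ = log₂20 − Hᵢ (Shannon entropy in bits over residue
frequencies) and letter height = frequency × Rᵢ, with **no small-sample
correction** — profiles from few instances overstate conservation, and
callers comparing logos across differently-sized instance sets should
keep the instance counts in view.

## Neighborhood, roles, canonical order

`extract_neighborhood()` collects genes within ±5 ranks of the anchor
(clipping at contig ends sets a `truncated_window` flag). Five genes is
the window the organizational patterns are defined over; it is exposed
as a parameter but changing it changes what "in the cluster" means.

Roles come from `assign_role()`, in precedence order A > T > B > C > D:

* **A** — the anchor (motif call) itself; other anchors inside the
  window stay `X` and are flagged, so each anchor seeds exactly one
  cluster;
* **T** — H-cluster (`2Fe`) domain together with a sensory domain
  (`PAS` or `His_kinase_dom`);
* **B** — `FMN` plus at least one B-series FeS label;
* **C** — carries the `C1` label;
* **D** — architecture exactly equal to the declared accessory-subunit
  architecture. The domain vocabulary here has no label specific to
  BfuD, so the package declares it as a lone `Nqo1` (SLBB/β-grasp)
  domain — the one label that plausibly describes a small accessory
  electron-transfer subunit — and exposes it as an argument
  (`d_architecture`) for users whose annotations say otherwise.

Anything else is `X`; decoys inside the window are kept as `X` members
so patterns with interspersed genes remain classifiable. Members on the
strand opposite the anchor are accepted (flagged `antisense_member`):
no same-strand requirement is imposed.

`canonical_order()` reads the cluster in the anchor's transcription
direction, which makes the role string independent of which genomic
strand carries the cluster (the classic display convention that draws
clusters as if on the negative strand is simply the reverse reading,
returned as `display_string`).

## Retention and sub-typing

A cluster is retained iff it has a non-partial B member whose
architecture includes FMN and B1, and a non-partial C member with C1
(`intactness_filter()`; reasons `no_B`, `incomplete_B`, `no_C`,
`incomplete_C`). Retained clusters are matched, X members ignored,
against:

| canonical order | sub-type | flags |
|------|------|------------------------------|
| A B D C | I | `D_present` |
| A B C | II | `D_absent` |
| C A B | III | |
| A B C T | IV | |
| A T B C | IV | `T_downstream_of_A` |
| T A B C | V | `T_upstream_of_A` |

Three decisions here were genuinely open and are resolved as follows.
The sensory-gene-adjacent-to-the-anchor arrangement is treated as a
sub-type IV *variant*, not a sixth sub-type: it is a placement exception
within an otherwise sub-type IV gene complement. Clusters with two T
genes, or with both D and T, match no pattern and are `unclassified`
(flag `double_T` for the former) with a nearest-pattern hint computed by
edit distance — the double-T arrangement is real but rare and is better
surfaced than forced into IV or V. And a D-less A&lt;B&lt;C cluster is
labelled II with flag `D_absent`: without a phylogeny there is no
organizational evidence for "sub-type I that lost D", so the package
reports the pattern it sees and leaves the override to users who have a
tree. A guarded precedence (I > IV > V > III > II) exists for the
impossible-by-construction case of multiple pattern matches.

## The FeS/flavin rule engine

The label→cluster-type map is fixed: A1, A5, B2, B5, C1 are [2Fe-2S];
A2, A3, A4, B1, B3, B4 are [4Fe-4S]; `DPD_II` contributes two [4Fe-4S]
clusters of its own; `FMN` and `FAD` are flavin slots. Duplicate labels
count with multiplicity, so a double B5 is preserved (and noted — its
function is contested, and it never changes a verdict). The catalytic
subunit is `M3c` when the accessory A1/A5 pair is present, else `M3a`.

`bifurcation_call()` applies, in order:

1. `DPD_II` + `FAD` → **dual_center_candidate** — the architecture in
   which the B3/B4 ferredoxin arm is replaced by a DPD_II module with a
   C-terminal FAD/NAD(P) site, i.e. a possible second, canonical
   flavin-only bifurcation center; calling this non-bifurcating because
   B3/B4 are absent would contradict what the architecture suggests;
2. complete B1–B5 + FMN in B, C1 in C → **bifurcating**;
3. B3 or B4 absent and no FAD anywhere → **non_bifurcating** (the
   architecture of complexes shown experimentally to lack bifurcation);
4. otherwise **indeterminate** — notably B5 absent with B1–B4 present,
   where the literature disagrees about B5's role, so the engine
   reports uncertainty rather than taking a side.

Because of rule 4, a complement can have a complete electron path
(`electron_path_check()`: 2Fe → accessory A-series when M3c → B1 → FMN,
and C1 → B2 → B3 → B4; B5 is not a path link) and still be
indeterminate; what the path guarantees is only that the verdict is
never `non_bifurcating`. All verdicts are structural predictions from
declared architectures — no biochemistry is implied, and reports carry
the verdict under a `capability` (predicted) column.

## The phylogeny cross-check

`concat_abc()` joins the A, B and C proteins in that fixed order
regardless of gene order. Distances are 1 − Jaccard similarity of
amino-acid k-mer sets (k = 4: at the sequence divergences of interest,
tetrapeptide sets are sensitive without saturating), and the tree is
standard Saitou–Nei neighbor joining with negative branch lengths
clamped to zero (the usual cosmetic fix; clamping happens after the
topology is fixed, so it never changes joins). This is a deliberate
simplification: the package needs a *clustering cross-check* of the
organizational sub-typing, not a publication-grade phylogeny, and an
alignment-free distance keeps the pipeline free of aligner/ML-tool
dependencies. The concatenated FASTA can be exported for external ML
tools via the bundle files. Sub-type purity is computed over **all**
edges of the unrooted tree (both directions of every bipartition):
purity = sub-type size / smallest containing clade size, monophyletic
iff purity = 1.

## The synthetic-genome generator

`generate_genome_set()` is first-class, tested code, not a fixture. Per
genome it builds one decoy-only contig plus one contig per planted
cluster; each cluster gets a random strand, 0–2 intervening decoy genes,
and sub-type-specific subunit proteins. Proteins derive from fixed,
hand-written role templates (~120–450 residues) mutated once per
sub-type at proportion 0.15 and once per instance at 0.02 — the
between/within divergences are free parameters (no published estimate
of inter-sub-type divergence exists to copy), chosen so that sub-types
separate cleanly in k-mer space while instances within a sub-type stay
nearly identical. Motif windows in the catalytic template are protected
from mutation; sub-type IV templates carry Cys at P1 position 5 where
the others carry Ser. A configurable fraction (default 0.1) of decoys
carries an isolated P1 instance, exercising the requirement that anchor
calls need all three motifs. Omission (`omit_mix`), contig-edge
truncation (`edge_truncate_prob`) and the sensory-gene variants are
available per plant; defaults are clean plants. All randomness flows
from a single seeded generator per run, and runs are byte-identical for
a fixed seed.

What the generator does **not** emulate: nucleotide sequences, realistic
intergenic spacing or operon structure, pseudogenes, homologs of the
subunits outside planted clusters, annotation noise in the domain
tables, and real inter-genome phylogenetic structure. Passing tests on
synthetic data therefore demonstrate the pipeline's logic —
detection, filtering, orientation handling, classification, rule
application, clustering — not its robustness to noisy real-world
annotations, where domain tables and gene calls carry their own error
modes.

## Problem sizes and numerical notes

The test suite and the acceptance script run on 20-genome sets (60
planted clusters, ~900 proteins), which exercises every code path in
seconds; the pipeline itself is linear in gene count per genome and
quadratic in retained-cluster count only in the distance matrix. The
analysis stages contain no randomness at all: identical inputs give
byte-identical reports (report files carry a YAML front-matter block
recording the parameters, so any count is traceable to its
configuration). Degenerate inputs are handled explicitly: empty genomes
and empty report tables are legal, trees require at least three
classifiable clusters, ragged logo instances and asymmetric distance
matrices are errors, and all-equal distance matrices fall back to ape's
deterministic join order.

## Known limitations

* Capability verdicts inherit every limitation of the declared domain
  tables; a missing label in the input becomes a missing FeS cluster in
  the verdict.
* The organizational classifier and the phylogeny can disagree on real
  data (e.g. a D-less sub-type I cluster labelled II); the package
  reports both views and does not adjudicate.
* The k-mer NJ tree is a cross-check, not an evolutionary
  reconstruction; branch lengths are not interpretable as substitution
  rates, and no support values are computed.
* The motif screen at tolerance 0 will miss genuinely divergent
  catalytic subunits; the near-miss channel exists precisely to surface
  them for manual review.
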