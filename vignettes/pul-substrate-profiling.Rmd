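---
title: "From PUL architecture to substrate expression profiles: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From PUL architecture to substrate expression profiles: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pulpredict)
```

`pulpredict` predicts which polysaccharides flavobacterial genomes are
equipped to degrade, and reads temporal substrate use out of
metaproteomes. This vignette explains the underlying models and the
design choices, in the order the pipeline runs.

## Consensus feature annotation

The pipeline never runs HMMer or BLAST itself; it consumes per-gene
domain-evidence tables (source, label, score) and applies decision rules:

* **CAZyme consensus.** A family (GH/PL/CE/CBM/AA) is assigned to a gene
  only when at least two of the three CAZyme sources — Pfam HMM, dbCAN
  HMM, CAZy BLAST — report it at or above the per-source threshold.
  Single-source hits are treated as unreliable and discarded. Families
  vote independently, so a gene can legitimately carry `GH5` and `CBM6`
  at once. Subfamily labels (`GH5_4`) are normalized to the parent
  family for rule matching but kept verbatim for reporting.
* **Roles.** SusC-like TonB-dependent transporters are called from the
  TIGR04056 model, SusD-like lipoproteins from any of PF12741, PF12771,
  PF14322. The two roles are mutually exclusive on one gene; if both
  models hit, the higher score-to-threshold ratio wins and the conflict
  is logged. A generic TBDT hit (default labels PF00593/PF07715) without
  TIGR04056 yields `tbdt_non_susC` — a transporter too dissimilar to
  count as SusC-like. SulfAtlas hits give `sulfatase` (subfamily label
  retained, e.g. `S1_15`), MEROPS hits give `peptidase`.
* **Thresholds.** Defaults are ≥ 25 bits for HMM sources and, for
  BLAST-type sources scored as −log10 E, ≥ 4 (E ≤ 1e−4, the MEROPS
  default). These are pragmatic stand-ins for family-specific cutoffs,
  which differ between databases and are not reproducible from published
  tables; they are exposed in `annotation_config()` so a user with
  calibrated cutoffs can substitute them. The 2-of-3 consensus makes the
  pipeline robust to the exact values: a spurious hit must recur in two
  independent databases to mislead it.
* **susE-like genes.** No public model exists for SusE. Rather than
  invent one, `annotation_config()` ships an empty susE label list and
  PUL detection flags the gene immediately downstream of a paired susD
  that carries no other annotation as *putative* susE. This positional
  heuristic matches how susCDE triplets present in genome diagrams and
  is only used as a rule predicate (branched α-1,4-glucan PULs).

"Degradative CAZymes" in genome summaries are genes with at least one
GH, PL or CE family; CBM-only and AA-only genes bind or assist but do
not cleave, so they are excluded from density and ratio statistics. The
peptidase:CAZyme ratio is reported as missing (not infinite) for
genomes without degradative CAZymes.

## PUL detection

PUL boundaries in the literature come from manual curation; the package
formalizes that practice with two parameters:

* `gap_tolerance` (default **3** non-signature genes): signature genes —
  consensus CAZymes, sulfatases, susC, susD, generic TBDTs — are grouped
  into maximal runs in which consecutive signature genes are separated
  by at most this many unannotated genes. Three reproduces typical
  published PUL diagrams, which include interspersed hypothetical genes;
  it is a calibration, not ground truth, and is surfaced in the
  configuration rather than hard-coded.
* `min_cazymes` (default **2**): a cluster must contain a CAZyme
  *cluster* (≥ 2 CAZyme genes), or one CAZyme gene next to an adjacent
  susC–susD pair. Transporter tandems with no CAZyme at all are not
  PULs.

susC–susD pairing allows at most one intervening gene and ignores
strand. Completeness is `complete` (≥ 1 adjacent pair), `no_susD`
(SusC without a paired SusD), `tbdt_only`, or `no_susCD`; incomplete
clusters remain PULs, mirroring how incomplete subtypes are counted in
comparative PUL surveys. Intervening non-signature genes inside the
span are members, so family multisets and sulfatase counts are computed
over the full locus. Emitted PULs are disjoint, and detection is
invariant under mirroring the contig.

## The substrate rule engine

Rules are declarative: required family minimum counts, any-of clauses
(with minimum total and minimum distinct counts), forbidden families, a
tri-state sulfatase requirement evaluated on PUL-internal sulfatases
only (published figures annotate sulfatases within the locus), and
transporter-architecture predicates (requires susCD, requires susCDE,
forbids susE). Matching rules are ranked by unique priority — variant
rules above class rules above broad fallbacks — with all other matches
reported as ambiguity, so classification is transparent and auditable.

Notable choices in the built-in table:

* **Laminarin variants.** A: one GH3 β-1,3-glucosidase framed by two
  GH16 β-1,3(4)-glucanases (no GH17/GH30); B: ≥ 2 GH17 β-1,3-glucan
  hydrolases plus a GH30 exo-β-1,6-glucanase; C and D: GH16 + GH30
  without GH17 plus a putative GH5 glucan hydrolase. The published
  description does not fully specify what separates C from D, so the
  table splits them on the CBM6 carbohydrate-binding module co-occurring
  with the GH5 (C requires it, D forbids it) — the GH5's binding domain
  is the one discriminating feature named for these variants. This keeps
  exactly four laminarin variants; a user disagreeing with the split can
  override both rules via YAML.
* **α-1,4-glucan.** The branched rule demands the susCDE triplet plus
  GH13, GH65 and GH31; the simple rule (maltodextrin/amylose-type)
  demands GH13 + GH65 and forbids susE. A lone GH13 is deliberately
  insufficient — single-family evidence stays `unclassified`.
* **α-1,1-glucan (trehalose-like).** Only a placeholder signature
  (GH65 without GH13) at low priority: the source material describes
  these loci only qualitatively, and an unvetted confident rule would
  overstate coverage.
* **Xylan subtypes** (sulfated, glucurono via GH67/GH115, arabino via
  GH51) all require the GH10/GH43 core, so every variant match implies
  the class-level match — a property the tests assert.

## SusC/D reference trees

Pairwise percent identity uses end-to-end Needleman–Wunsch alignment
under BLOSUM62 with affine gaps (open 11, extend 1), identity = 100 ×
matches / alignment columns (gaps count in the denominator). A pairwise
definition was chosen over MSA-column identity because the downstream
placement threshold (≥ 40%) is inherently pairwise and the pairwise
form is self-contained; arguments are ordered canonically before
alignment so the function is exactly symmetric. Sequences are validated
to the 20 IUPAC residues plus X.

Trees are built by neighbor joining on `d = 1 − identity/100`
(uncorrected by default; a Poisson correction is selectable). NJ
replaces approximate-ML deliberately: the tree only serves cluster
extraction and visualization, NJ is deterministic and testable against
an exhaustive least-squares topology oracle, and an external Newick
tree can be imported for parity runs. Negative NJ branch lengths are
clamped to zero. Distances are uncorrected because the divergences of
interest stay within the range where `1 − identity` is monotone in
evolutionary distance.

Substrate clusters are maximal clades (after midpoint rooting) with
≥ `min_size` leaves (default 3) whose labelled-leaf majority substrate
reaches `purity_threshold` (default 0.8); unlabelled leaves do not count
against purity. SusC–SusD congruence is, over PULs whose SusC and SusD
both sit in some substrate cluster, the fraction where the two clusters
agree on the majority substrate; with no eligible PUL it is reported as
missing, never 0.

## Expression profiling

Technical replicates are averaged arithmetically per (protein, sample);
missing replicates are simply absent from the mean. %NSAF is computed
within each sample over *all* proteins in the table — not just SusC/D —
so that a %NSAF of 1 means 1% of all length-adjusted spectral counts in
that experiment; per-sample totals are exactly 100 before filtering,
and the measure is invariant to rescaling all counts in a sample.
A sample with all-zero counts is an error (undefined normalizer), not a
silent zero.

Expressed homologs inherit the substrate of their best-identity
reference when the identity, rounded to 0.1, is ≥ 40. Ties inherit only
a unanimous substrate; otherwise the query is marked ambiguous. The
rounding rule makes the threshold comparison well-defined at the
boundary (39.9 fails, 40.0 passes). Profiles retain a protein only if
its maximum %NSAF across samples reaches 0.05 (≥, so exactly 0.05 is
kept), then sum retained %NSAF per substrate × sample, always keeping
SusC-like and SusD-like proteins in separate panels. Because the
literature does not settle whether multiple homologs mapping to one
reference should be pooled, both the summed profile and the per-protein
records are returned.

Bloom phases derive from chlorophyll *a* (µg/L) with two thresholds
(defaults t1 = 2, t2 = 5, typical of coastal spring blooms): before or
at the chlorophyll peak a sample is pre (< t1), early (< t2) or mid
(≥ t2); after the peak it is mid while ≥ t2 and late below. A series
never reaching t1 is entirely pre-bloom. Explicit phase labels in the
metadata always win.

## What the synthetic generator emulates — and what it does not

The generator plants PUL templates mirroring the recurrent architectures
(e.g. `susC, susD, GH16, GH3, GH16` for laminarin A), separated by runs
of unannotated decoy genes, and emits 2-of-3 consensus evidence for
planted families plus optional single-source decoy evidence that the
consensus rule must reject. Three templates lack a complete tandem to
exercise the incomplete subtypes. Defaults — 6 genomes × 7 PULs —
approximate the per-genome PUL density of sequenced flavobacterial
isolates at desk scale. SusC/D sequences are drawn from per-substrate
families: one class root, family ancestors diverged at 0.6
substitutions/site between substrates and members at 0.2 within,
giving within-family identities well above and between-family
identities well below the 40% placement threshold, as observed for
substrate-specific SusC/D clusters. Expected pairwise identity of a
family follows the closed form 100·((1−p)² + p²/19), which the tests
use as an oracle.

Metaproteomes consist of background proteins with time-constant
negative-binomial-like means plus planted SusC/D homologs (at 0.1
divergence from a reference member) whose mean counts follow a Gaussian
bump — baseline 0.5, height 30, width 1 sample — at the substrate's
peak sample, with Poisson replicate noise and a rising-then-falling
chlorophyll series. The sharp peak emulates the strong, short-lived
induction of transporter expression seen at bloom dates; a broad, flat
bump would not constitute a planted peak at all. All draws come from
per-output streams derived from the master seed, so identical
configurations are byte-identical and adding one output never perturbs
another.

The generator deliberately does **not** emulate: nucleotide-level gene
models, genuinely homologous non-SusC/D protein sequences (decoy and
CAZyme sequences are random — only SusC/D sequences are used
downstream), correlated evidence errors between databases, shared
peptides/protein-inference ambiguity in spectral counting, or
multi-year sampling gaps. Passing the synthetic suite therefore shows
the pipeline's rules and statistics are implemented correctly under the
stated data model, not that the biological predictions are correct on
real genomes — on real data the binding constraints are database
quality and the manual-curation judgment the gap rule approximates.

## Numerical and reproducibility choices

Internal coordinates are 0-based half-open (GFF3 I/O converts from and
to 1-based inclusive), which makes adjacency and gap arithmetic exact.
Tables are written with fixed column order, primary-key sorting and
6-significant-digit floats, so reruns are byte-identical. Floating
%NSAF sums are conserved to 1e−9. Problem sizes in the tests and the
acceptance script — planted-locus recovery for 0–10 PULs over 20 seeds,
NJ versus exhaustive least squares on all 4- and 5-taxon shapes,
families of 4–6 members at sequence length 300, 14-sample
metaproteomes — were chosen as the smallest sizes that still exercise
every code path and tie-break.

## Known limitations

* The gap rule and susE heuristic approximate manual curation; loci with
  long runs of unannotated accessory genes can be split.
* Rule priorities resolve overlapping signatures deterministically, but
  a PUL genuinely targeting two substrates is still reported with a
  single top label (the alternatives appear under `ambiguity`).
* Pairwise identity and NJ are substitutes for MSA-based identity and
  ML trees; both hooks (`identity_fun`, Newick import) exist for parity
  with heavier external tools.
* Placement transfers the *reference's* substrate prediction; errors in
  rule-based classification propagate to expression profiles.
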