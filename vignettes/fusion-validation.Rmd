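---
title: "Validating fusion transcripts with matched WGS data"
author: "fuseval"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating fusion transcripts with matched WGS data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fuseval)
```

# The problem

Fusion-transcript callers such as Arriba and STAR-Fusion detect chimeric
junctions in RNA-Seq data. Many of their predictions have no underlying
genomic rearrangement: they arise from template switching during library
preparation, mis-alignment around homologous sequence, or read-through
transcription. When matched whole-genome sequencing (WGS) is available,
a genuine fusion gene should leave two kinds of DNA-level evidence:

* **discordant read pairs** — paired-end fragments straddling the
  rearrangement, with one mate aligned in each partner gene's locus and
  an aberrant pair configuration (different chromosomes, excessive
  template span, or a cleared proper-pair flag);
* **soft-clipped reads** — reads crossing the genomic breakpoint itself,
  aligned up to the break with the remainder (which belongs to the
  partner locus) clipped off by the aligner.

`fuseval` implements this validation as a reusable pipeline, plus the
annotation, summary statistics and drug-screen association analysis that
normally follow it, and a synthetic-data generator that produces fully
self-contained test studies with known truth.

# The validation model

## Search regions

For each fusion call, the RNA-level junction coordinates and the partner
gene models define two strand-aware search regions:

* 5' partner: from the fusion junction to the *transcriptional* gene end
  (the genomic start for a `-` strand gene);
* 3' partner: from the transcriptional gene start to the junction.

This reflects where DNA breakpoints can sit for a spliced fusion
transcript: downstream (in transcription order) of the 5' junction and
upstream of the 3' junction, typically in the adjacent introns. Each
region is widened by `junction_flank` (default 500 bp) on the junction
side and `gene_flank` (default 2000 bp) on the gene-end side, so that
breakpoints just outside the annotated span are not missed.

## Discordant pairs

A read pair validates a call when one mate overlaps the 5' region and
the other the 3' region, and the pair is discordant: mates on different
chromosomes, or the proper-pair flag unset, or template span above
`max_concordant_insert` (default 1000 bp). The three clauses together
capture translocations, deletions and inversions while excluding
ordinary pairs that happen to bridge two nearby genes. Pairs are
deduplicated by read name. Duplicate, secondary and supplementary
alignments are always excluded (evidence should be counted once), and
reads below `min_mapq` (default 20) are ignored. A call with at least
`min_discordant_pairs` (default 1) qualifying pairs is
*discordant-supported* — which the pipeline treats as validated even
when no breakpoint can be called, since spanning-fragment evidence does
not require reads to cross the break itself.

## Breakpoint candidates from soft clips

Breakpoint search runs only when discordant support exists; an isolated
soft clip with no spanning pairs is much more likely to be an alignment
artefact. On each side, reads with a soft clip of at least
`min_clip_len` (default 10 bp) on the *junction-facing end* of the
alignment are collected. The junction-facing end points toward the
transcriptional gene end for the 5' partner and toward the
transcriptional gene start for the 3' partner — concretely, the right
end of the alignment for a `+` strand 5' partner, and mirrored for `-`
strands and for the 3' role. Clips whose bases average below
`min_clip_mean_qual` (default phred 25) are discarded; low-quality tails
are routinely clipped and carry no positional information.

Each surviving clip contains, if genuine, sequence from the *other*
side of the fusion. It is therefore searched, ungapped with at most
`max_clip_mismatch_frac` (default 10%) mismatches, in the reference
within `mate_window` (default 500 bp, insert-size-scale locality) of the
position of some discordant mate on the other side. The orientation of
the probe is decided by the relative strands of the two partners: equal
strands read straight through, opposite strands (inversion-type events)
require the reverse complement. Clips that pass vote for their
clip-boundary coordinate — the alignment end for a right-side clip, the
alignment start for a left-side clip — and the candidate per side is the
modal coordinate, with ties broken toward the smaller coordinate for
determinism. With this convention, the 5' candidate is the last
transcribed reference base of the 5' segment and the 3' candidate the
first transcribed base of the 3' segment, for all four strand
combinations.

A call with at least one breakpoint candidate (on either side; the
pipeline does not require reciprocal candidates on both sides) is
*breakpoint-supported*. The resulting status scale is ordered:
`unsupported < discordant_supported < breakpoint_supported`.

## Parameter defaults

The flank sizes (500 bp / 2 kb) are part of the published procedure the
pipeline implements. The remaining thresholds are this package's own
calibration, chosen once from standard split-read practice: MAPQ 20
excludes multi-mappers while keeping most unique alignments; clip length
10 is the shortest segment that can be located reliably in a mate-sized
window; mean clip quality 25 rejects adapter/quality tails; the 1000 bp
concordance ceiling sits well above typical WGS insert distributions;
10% clip mismatches tolerate sequencing error without allowing spurious
matches; and the ±500 bp mate window matches insert-size locality. All
are exposed through `validationParams()` and logged in every output.

# Filtering before validation

`filterCalls()` applies the pre-validation rules: junctions must lie
inside the genomic span of their named partner genes (flanking sequence
counts as intergenic), events must involve two distinct genes, Arriba
calls must have a predicted transcribed strand for both partners, and
STAR-Fusion calls must not involve an immunoglobulin-superlocus symbol
(pattern `^IG[HKL]@?`, configurable). Each dropped call gets exactly one
primary reason; the IG rule is checked first because IG-superlocus
symbols are generally absent from the gene annotation and would
otherwise be misclassified as intergenic. Arriba's own event-type
strings (translocation, deletion, duplication, inversion) are all
retained — exclusion is by gene identity and region, not by type name.
Whether read-through events between adjacent genes count as two-gene
fusions is genuinely ambiguous; this implementation keeps any record
whose two symbols differ and whose junctions lie inside both partners,
which is one consistent, deterministic reading.

Assembly liftover is represented by a coordinate-map interface
(identity, per-chromosome offset, lookup table) with explicit partiality:
positions without an image are reported and excluded, never errors.
Chain-file parsing is out of scope.

# Annotation layers

All annotation operations are pure functions over the validated call
table:

* **Alternative splicing**: gene pairs reported more than once by the
  same caller in the same cell line with different junction pairs share
  an `alt_splice_id`. Identical duplicates do not qualify.
* **Promoter swap**: the 5' junction strictly precedes the 5' partner's
  coding start in transcription order. A non-coding 5' partner is always
  a candidate — no coding sequence of the 5' gene can be included, which
  is exactly the promoter-swap configuration.
* **Kinases, miRNA hosts, cancer genes**: symbol or interval lookups
  against user-supplied resource tables. Partners transcribed antisense
  to the annotated gene are never annotated (the prediction does not
  correspond to the annotated product). A partner hosts a miRNA when the
  hairpin lies inside the gene body or within 2 kb downstream of the 3'
  end *and* inside the fused portion of the transcript (transcription
  start to junction for the 5' partner; junction to gene end plus the
  downstream window for the 3' partner). Hairpin strand is ignored;
  containment is full-interval.
* **Known-fusion databases**: order-sensitive (5'::3') symbol matching
  per source, with tissue categories resolved through a user-supplied
  tissue map (`exact > related > no_tissue_match`; `unknown_tissue` when
  every matching entry's tissue is unmapped). Fusion directionality is
  biologically meaningful, hence the order sensitivity; no tissue
  ontology is hard-coded. TumorFusions entries additionally flag exact
  junction matches.
* **Twins**: calls from different callers in the same cell line with
  identical junctions *and* identical annotations (canonical serialized
  tuple; absent equals absent) share a `twin_id`. The weaker notion of a
  *shared prediction* — identical junctions only — is used by the
  enrichment tests instead; the two are deliberately distinct.

`collapseGenePairs()` reduces transcripts to unique
(cell line, caller, gene pair) groups, with any-member-true semantics
for boolean flags, the strongest tissue category, and the strongest
validation status, so that multi-isoform fusions are counted once in
summary tables.

# Statistics

`fisherExact()` computes the two-sided Fisher exact p by summing, in log
space, the hypergeometric probabilities of all tables with the observed
margins that are no more probable than the observed table; this is exact
for small tables and numerically stable at the study scale (tens of
thousands of calls). The test suite verifies it against brute-force
enumeration for all totals up to 30 and against `stats::fisher.test` on
larger tables. The reported odds ratio is the sample odds ratio.
`bhAdjust()` is the standard Benjamini-Hochberg step-up, written out
explicitly and verified against its definition and `stats::p.adjust`.
`welchT()` assembles the Welch statistic with Satterthwaite degrees of
freedom; both-groups-zero-variance cases (saturated screen values) are
flagged and resolved by convention (p = 0 when the means differ, 1 when
equal) rather than raised.

The drug-association analysis follows the screen structure: per
treatment (drug × plate), concentrations tested in fewer than 80% of
cell lines are removed, then one concentration is selected — the
arg-min of |c − mean(c)| on the linear scale (the wording of the
procedure implies linear; a log-scale mean would be a defensible
alternative), ties toward the smaller concentration. Genes qualify when
an in-frame or promoter-swap fusion involves them in at least two
screened cell lines. Replicates collapse to one value per cell line by
mean; one BH correction is applied across all performed tests.

# The synthetic-data generator

`simulateDataset()` emulates exactly the inputs the pipeline consumes:
a random genome, multi-exon gene models on both strands with CDS
starting at the second exon, planted fusion events of three geometries
(interchromosomal, deletion, inversion) whose RNA junctions sit at exon
boundaries and whose DNA breakpoints are drawn inside the adjacent
introns, paired-end WGS reads, caller tables in both dialects, and
annotation resource fixtures wired to the planted events (including
hairpins exactly at, and just beyond, the 2 kb downstream boundary).

Reads are written as already-aligned SAM records: the simulator computes
reference placements, flags and CIGARs itself, which removes any
external aligner from the loop and makes the planted truth exact.
Background fragments tile the unrearranged genome at the nominal depth
with normal insert sizes (truncated below at the read length) and
proper-pair flags. For each event, fragments are sampled across a
fusion contig built from the two breakpoint-flanking segments in
transcription orientation; fragments spanning the junction become
discordant pairs, and reads crossing it become soft-clipped exactly at
the planted breakpoint with clipped bases taken from the partner side.
Base errors are independent substitutions at rate `base_error`.

The default study — two 60 kb chromosomes, twelve genes, three true
fusions (one per geometry), two RNA-only false calls, 30× depth, 100 bp
reads, 350 ± 40 bp inserts, 0.1% base error — is chosen to resemble a
small slice of a real WGS experiment around a handful of loci while
keeping a full multi-seed evaluation to a few minutes on one CPU. These
sizes are the package's reference conditions; the test suite runs the
complete pipeline across seeds 1–10 under them and requires exact
breakpoint recovery for every planted event and `unsupported` status for
every RNA-only spike-in.

What the simulation does *not* model — and hence what passing tests do
not show about real data — includes alignment ambiguity around repeats
and homologous sequence, indels near breakpoints, coverage bias,
chimeric artefacts in the WGS library itself, and copy-number or nested
rearrangements. The simulator demonstrates correctness of the decision
logic, not robustness to every real-world error source.

# Numerical and degenerate-input conventions

* Coordinates are 1-based inclusive everywhere at interfaces (SAM and
  caller-table convention); gene boundary positions are inside the gene.
* Breakpoint tie-breaks go toward the smaller coordinate; group and
  identifier assignment iterates over sorted keys, so outputs are
  independent of input order.
* A contingency table with a zero margin yields p = 1 with a warning.
* Zero remaining concentrations drop the treatment with a warning;
  groups with fewer than two values skip the Welch test.
* All generator stages reseed deterministically from the study seed, so
  every output file is bit-reproducible.

# Known limitations

Validation sensitivity depends on WGS depth: at low physical coverage a
genuine fusion may yield no spanning fragment, and the pipeline reports
what the data support, not what is biologically true. Clip matching is
ungapped, so breakpoints with indels immediately at the junction can
fail breakpoint promotion (they usually remain discordant-supported).
The Mitelman/TumorFusions/KinHub/miRBase/CGC contents themselves are not
bundled; users supply resource tables in the documented formats, and the
package's fixtures only stand in for them structurally. Whether database
matching should be order-sensitive is configurable in effect — reversed
pairs can simply be added to the resource table if symmetric matching is
wanted.
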