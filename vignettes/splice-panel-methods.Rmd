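---
title: "Methods: junction quantification, allele-level effects and ACMG combination for a blood RNA panel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: junction quantification, allele-level effects and ACMG combination for a blood RNA panel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(splicepanel)
```

## The problem

Hereditary-cancer gene panels return many variants of uncertain significance
(VUS), a large share of which are predicted to disturb splicing. Sequencing
RNA from patient blood over the same gene panel lets the laboratory observe
the transcripts directly: an aberrant junction quantified against the gene's
natural junctions is direct evidence for or against a splice effect, and that
evidence feeds the ACMG-AMP classification as PVS1 (aberrant transcript,
loss-of-function) or BP7 (demonstrably normal splicing of a silent/intronic
variant). This package implements that analysis chain — junction
quantification, event typing, allele-level conversion, NMD-exclusion logic,
splice-prediction triage and evidence combination — together with a simulator
that generates reads with known ground truth for every scenario the chain
must handle.

## Coordinate model

Every gene is represented in transcript orientation by its exon and intron
lengths only (`transcript_model()`). Computations use two axes:

* **transcript space** — the concatenated exons, 1-based; HGVS-style r./c.
  coordinates are anchored at the CDS start (5'UTR bases negative, no zero);
* **the gene axis** — exons plus introns concatenated; alignments, junctions
  and CIGAR strings live here.

Genomic coordinates and strand are deliberately not modelled: every quantity
in this workflow is expressible in transcript space, and keeping a single
orientation removes the usual strand-convention bugs. The cost is that models
are synthetic stand-ins: `synthetic_transcript()` provides gene models whose
*relevant* exon boundaries sit at the documented transcript coordinates
(e.g. a PTEN-like exon 3 spanning r.165..209, a MLH1-like exon 10 spanning
r.791..884) while all other exons and every intron length are invented.

## Junction quantification

`count_junctions()` turns gapped alignments into a junction count matrix:
every `N` gap contributes exactly one count to its (donor, acceptor) pair, so
junction counts conserve the number of gap operations — a tested invariant.
Intron retention produces no junction; it is evidenced by gapless stretches
crossing an exon–intron boundary with at least 8 matched bases on each side
(the anchor guards against ragged read ends).

The **relative expression** of a junction j is

$$\mathrm{rel}(j) = \frac{c(j)}{c(j) + r(j)}$$

where `r(j)` is the mean count of the natural junction(s) sharing j's donor
or acceptor site — both, averaged, for an exon-skipping junction, which
borrows a natural donor *and* a natural acceptor. For a natural junction,
`r(j)` is the mean of the gene's other natural junctions; for a fully novel
junction the mean over all natural junctions is used. No formula for
"relative expression over natural junctions" is fixed by the upstream tools
this emulates; this concretization was chosen because it yields 0.5 when
skipped and full-length transcripts are equally deep and it supports the
allele-level arithmetic below, which is the behaviour reported in practice.
Ties (a junction sharing sites with two natural junctions) are resolved by
averaging — documented and tested.

`detect_events()` types each non-natural junction by exhaustive comparison
with the natural set: both ends on natural exon boundaries with ≥1 exon
omitted is **exon skipping**; an acceptor at or 5' of its donor in exon
order is a **back-junction**, the chimeric signature of a tandem exon
duplication; exactly one novel end is a **cryptic donor/acceptor**; anything
else is **complex**. For skipping and cryptic events the omitted exonic
interval is converted to an r. deletion (`event_to_rna_change()`), from which
frame and RT-PCR product-size arithmetic follow.

Default thresholds are `min_reads = 10` supporting reads and `min_fraction =
0.05` relative expression. They are small enough to catch a minor isoform in
the 0–25% range on an adequately covered gene, and large enough that
event-free simulations at depths up to 2 × 10⁴ produce no calls (a tested
specificity property). They are configuration, not claims about any upstream
tool's internals.

## Allele-level effects and NMD

Under biallelic transcription where only the variant allele produces the
aberrant product, an event at overall fraction f affects

$$100 \times f / b \;\%$$

of the variant allele's transcripts, where b is the variant allele's share
of transcription (`percent_variant_allele()`). **The default b = 0.5
(balanced expression) is an assumption**, exactly the one implicit in reading
"equal depths of skipped and full-length transcripts" as a total effect and a
21% aberrant fraction as 42% of the variant allele. When a heterozygous
exonic marker variant is available, `allelic_ratio()` measures the balance
directly; both allele classes need ≥10 reads and a minor fraction ≥0.1 for
the marker to count as observed, and a ratio in [0.3, 0.7] counts as
balanced. These bounds are configurable; no numeric criterion for
"heterozygous variant in RNA" is fixed upstream.

Effects are graded **total** at ≥90% of the variant allele — separating
"total skipping" calls from partial ones while tolerating sampling noise —
**partial** above zero, **none** otherwise.

`nmd_status()` answers whether allele dropout by nonsense-mediated decay has
been excluded: a balanced marker proves both alleles are observed
(*excluded*); without one, a normal result — or a partial result whose
product is frameshift, hence an NMD substrate — may reflect a degraded
aberrant allele (*not excluded*); a total effect, or a partial in-frame
product that NMD would not touch, makes the question moot (*not
applicable*).

## The simulator

`simulate_reads()` emulates targeted RNA sequencing of one gene under
biallelic transcription: reads are drawn from the natural or the aberrant
isoform, the aberrant isoform arising only from the variant allele with
probability `per_allele_event_fraction`. Two modelling choices matter:

* **Fragment-proportional sampling.** A transcript yields reads in
  proportion to its spliced length, as fragment-based library preparation
  makes it. Consequently junction counts are proportional to isoform
  *abundance* — the property junction ratios rely on — rather than biased
  toward the shorter, skipped isoform.
* **NMD as uniform survival.** Decay is a single survival probability
  applied to frameshift aberrant transcripts before sequencing (default 0.3
  when enabled; decay is nowhere quantified upstream, so survival is a free
  parameter). With full penetrance and balance 0.5, the expected
  marker-based allelic ratio is s/(1+s) — a closed form the tests recover
  within three binomial standard errors.

A heterozygous marker is modelled as a single-base difference observed on
reads whose matched segments cover its position; all other reads have
unknown allele, as in real data. Low expression (a BRCA2-like gene in blood)
is emulated purely through the depth parameter. Tandem duplications repeat
exons j..k in the isoform block list, so reads spanning the copy boundary
carry a junction from exon k's 3' end back to exon j's 5' start; such
chimeric reads are written to SAM as two soft-clipped lines sharing a QNAME
(primary + supplementary, as spliced aligners emit them) and re-merged on
reading. Internally these back-junctions are carried as a signed gap in an
extended CIGAR — the one place the "gaps are nonnegative" convention is
deliberately relaxed, since a back-junction *is* a negative reference jump.

Sequencing errors, base qualities and capture efficiency are not modelled.
Passing tests therefore show the quantification logic is correct on clean
spliced alignments; they do not show robustness to alignment artefacts,
pseudogene cross-mapping (the reason a PMS2-like case fails RT-PCR in
practice) or tissue-specific splicing differences.

Study conditions used throughout the tests and the acceptance analysis:
read length 100 nt, depth 10⁴ reads/gene for quantification checks
(5 × 10³ for the deliberately thin low-expression replicates, 2 × 10⁴ for
specificity and NMD checks), balance 0.5, events on the variant allele only.
Depth and read length are configuration; nothing upstream states them.

## Prediction triage

SpIP-style predictions carry a percent score and a mechanism phrase;
SpliceAI-style predictions carry four deltas (acceptor/donor gain/loss) whose
maximum, scaled ×100, is the comparable score. `bucket()` applies the panel's
selection thresholds: high > 50, moderate 20–50 (both endpoints inclusive,
since the published wording ">50%" and "<20%" leaves 20 and 50 to the middle
band), negative < 20. In the concordance table (`concordance()`), SpIP rows
whose phrase is "NTR" (nothing to report) land in the negative row
regardless of their small residual percentage — the published performance
table keeps NTR as its own row, and 14 fixture rows reconcile exactly under
this mapping. Two fixture rows carry a positive SpIP v1 annotation beside a
v2.1 NTR; the published marginals (19/17/14/3) are reproduced exactly when
the row whose operative call was the positive v1 one (BRCA2 c.7670C>T) is
encoded with that phrase and score. The fixture does so, keeping the v2.1
value in the phrase text.

`high_confidence_ppv()` scores a predictor among its >50% calls as the
percentage confirmed by a *typed* RNA event (total or partial). Complex
multi-alteration profiles do not count as confirmations — such a profile
cannot be attributed to the predicted splice-site change — which is also the
accounting under which the published 15/19 = 79% for the SpIP-style tool is
reproduced. The published whole-dataset sensitivity/specificity pairs and
the SpliceAI high/low/negative split could not be reconciled with the
per-variant table under any tested definition; they are treated as free-text
annotations and never recomputed.

## ACMG combination

`parse_acmg()` reads criteria strings with strength suffixes: `_S` strong,
`_M` moderate, `_P` supporting, `_NA` not applicable (contributes nothing).
Defaults follow the code families (PVS1 very strong, PS* strong, PM*
moderate, PP*/BP* supporting, BS* strong). The suffix semantics are inferred
from the internally consistent outcomes of the 53-variant fixture (e.g.
PM2 + PVS1_M → 3 but PM2 + PVS1_M + PM3 → 4); no external rule set is
reproduced.

`combine_acmg()` applies the standard combining rules over effective
strengths: pathogenic (5) for VS + {≥1S | ≥2M | 1M+1P | ≥2P}, 2S, or
1S + {≥3M | 2M+≥2P | 1M+≥4P}; likely pathogenic (4) for VS+1M, 1S+1–2M,
1S+≥2P, ≥3M, 2M+≥2P or 1M+≥4P; likely benign (2) for ≥1 strong benign or ≥2
supporting benign. Strong benign evidence overrides isolated
moderate/supporting pathogenic codes (the fixture's BP7_S outranking PM2 and
even PP3 to give class 2) — encoded as an explicit override, not a score
sum. Strong benign alongside very strong pathogenic is a hard conflict and
raises an error; other pathogenic/benign collisions return class 3. Every
classification carries a rationale string so it can be audited against its
fixture row. PM2, PP1/3/4/5, PS3, PM3, PM5 and BP4 are clinical-context
inputs, never derived here.

`derive_rna_codes()` maps an allele-level observation to its RNA code:
normal with NMD excluded → BP7_S; normal otherwise → BP7_NA; total
frameshift → PVS1; total in-frame (or frame unknown) → PVS1_M; partial →
PVS1_NA unless a monoallelic (minigene) assay showed the effect total on the
variant allele, which restores PVS1_S. BP7 is definitionally restricted to
silent/intronic variants, so a `missense` flag caps it at not applicable —
the fixture applies BP7_NA to missense rows even with a balanced marker.
Some fixture rows carry stronger codes than this generic table would derive
(e.g. full PVS1 for an in-frame skip ablating a known functional domain);
such upgrades rest on gene-specific knowledge and remain external inputs.

`classify_duplication()` encodes the duplication rule: without chimeric
back-junction reads the tandem arrangement is unproven and the duplication
stays a VUS (3); with chimeric proof it is pathogenic (5) when the tandem
product is frame-disrupting or otherwise cannot retain function.
`frame_disrupting` is an input: nucleotide-modulo arithmetic decides it for
short duplications (a 200 nt exon repeated in tandem shifts the frame), but
a duplication spanning most of a gene's coding exons is disruptive even when
its length is a multiple of three, so the packaged annotation marks the
45-exon case disruptive on functional grounds.

## Known limitations

* Transcript-space models cannot express genomic phenomena: pseudogene
  disambiguation, genome-build liftover and structural-variant calling are
  out of scope.
* HGVS support is minimal by design — substitutions, del, dup, delins, ins,
  intron offsets, 5'UTR negative bases and the uncertainty forms `r.?`/`r.=`;
  anything else raises a parse error rather than guessing. Ranges crossing
  the UTR/CDS boundary are not length-corrected for the missing zero.
* Protein-level consequences (fs\*N termination positions) require real
  sequence and are not generated.
* The simulator's clean-alignment assumption means thresholds tuned here say
  nothing about aligner-induced artefacts.
* Phasing of the splice variant to the marker is not modelled; simulation
  provides truth tags, and real-data phasing is external evidence.
* Replicate spread in thin-evidence genes (the low-expression replicates
  range from uncalled to ~42% of the variant allele at 5 × 10³ reads) is
  surfaced per replicate, not reconciled into a single estimate.
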