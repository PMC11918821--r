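# splicepanel

Interpretation of splice variants from targeted blood RNA panel sequencing.

Hereditary-cancer gene panels leave many variants of uncertain significance
(VUS), a large share of them with predicted splice effects. Sequencing RNA
from patient blood over the same 48-gene panel lets a laboratory observe the
transcripts directly: an aberrant splice junction, quantified against the
gene's natural junctions, is evidence for or against a splice effect, and
that evidence enters the ACMG-AMP classification as PVS1 (loss-of-function
transcript) or BP7 (demonstrably normal splicing of a silent/intronic
variant). `splicepanel` implements that analysis chain end to end, for
anyone who wants to reproduce, stress-test or extend this style of
RNA-panel interpretation:

* **Transcript models and HGVS arithmetic** — exon/intron structures in
  transcript space; parsing of c./r. descriptions; frame, codon-overlap and
  RT-PCR product-size arithmetic (`transcript_model()`, `parse_hgvs_c()`,
  `parse_hgvs_r()`, `frame_effect()`, `codons_overlapped()`,
  `predict_rtpcr_size()`).
* **Ground-truth read simulation** — biallelic transcription with a
  per-allele aberrant-splicing probability, heterozygous marker variants,
  NMD-driven decay of frameshift products, depth-based low expression, and
  tandem exon duplications producing chimeric back-junction reads
  (`scenario_config()`, `simulate_reads()`), with minimal SAM text I/O
  (`write_sam()`, `read_sam()`).
* **Junction quantification and event typing** — a junction read-count
  matrix from gapped alignments; relative expression
  `rel(j) = c(j) / (c(j) + r(j))` over the natural junctions sharing j's
  splice sites; typed calls for exon skipping, cryptic donors/acceptors,
  intron retention and back-junctions (`count_junctions()`,
  `relative_expression()`, `detect_events()`, `event_to_rna_change()`).
* **Allele-level effects and NMD exclusion** — conversion of a junction
  fraction f into `100·f/b` percent of the variant-carrying allele under
  allele balance b (default 0.5), marker-based allelic ratios, and the
  excluded / not-excluded / not-applicable NMD logic
  (`percent_variant_allele()`, `allelic_ratio()`, `nmd_status()`).
* **Splice-prediction triage** — SpIP- and SpliceAI-style score buckets
  (>50 high, 20–50 moderate, <20 negative), predictor-vs-RNA concordance
  tables and high-confidence positive predictive values (`bucket()`,
  `spliceai_max()`, `concordance()`, `high_confidence_ppv()`).
* **ACMG-AMP combination** — criteria parsing with strength modifiers
  (`_S`, `_M`, `_NA`), the standard combining rules with a strong-benign
  override, RNA-derived codes, and the tandem-duplication rule
  (`parse_acmg()`, `combine_acmg()`, `derive_rna_codes()`,
  `classify_duplication()`).

The 53-variant evidence table, the 48-gene panel and the four
large-duplication records of the underlying study are packaged as checksummed
plain-text fixtures (`load_variant_table()`, `load_panel_genes()`,
`load_duplications()`).

## Worked example

Simulate a PTEN-like gene in which 21% of all transcripts lack exon 3
(balanced biallelic expression, aberrant products from the variant allele
only), quantify the junctions, and interpret:

```r
library(splicepanel)

pten <- synthetic_transcript("PTEN")
cfg <- scenario_config(pten, depth = 10000, allele_balance = 0.5,
                       event = "exon_skip", event_params = list(exons = 3),
                       per_allele_event_fraction = 0.42, seed = 1)
reads <- simulate_reads(cfg)
ev <- detect_events(count_junctions(reads, pten), pten)
ev
#> # A tibble: 1 × 8
#>   gene  event_type donor acceptor supporting_reads relative_expression
#>   <chr> <chr>      <int>    <int>            <int>               <dbl>
#> 1 PTEN  exon_skip   1164     3310              410               0.206
#> # ℹ 2 more variables: exons_affected <chr>, rna_change <chr>

pct <- percent_variant_allele(ev$relative_expression, allele_balance = 0.5)
sprintf("%.1f%% of the variant allele; grade: %s", pct, effect_grade(pct))
#> "41.2% of the variant allele; grade: partial"

rc <- parse_hgvs_r(ev$rna_change)   # r.165_209del
frame_effect(rc)                    # "in_frame"
codons_overlapped(rc$start, rc$end) # 16 amino acids lost
predict_rtpcr_size(370, rc)         # 325 bp product from a 370 bp amplicon

combine_acmg("PM2, PVS1")
#> [1] 4
#> attr(,"rationale")
#> [1] "likely pathogenic combination met"
```

The exon-3 skip is recovered at 20.6% relative expression — 41.2% of the
variant allele under balanced expression — an in-frame deletion of 16
codons whose RT-PCR product runs 45 bp short of the reference amplicon.
With PM2, the PVS1-level RNA evidence combines to class 4 (likely
pathogenic).

## Analysis workflow

The `analysis/` directory is a numbered, narrated pipeline over the package:

1. `01_simulate_scenarios.R` — the four scenario families (total in-frame
   skip at balanced depth; partial frameshift skip with NMD masking; a
   low-expression gene in triplicate; a tandem exon duplication), written as
   SAM under `results/sim/`.
2. `02_quantify_junctions.R` — junction matrices and typed event calls.
3. `03_allele_effects.R` — allele-level percentages, marker ratios and NMD
   status.
4. `04_prediction_triage.R` — concordance tables and high-confidence PPVs
   for both predictors.
5. `05_classify_variants.R` — ACMG combination over all 53 records, the
   duplication rule, and the study-level summary.

Each script reads its predecessors' output from `results/` and prints what
it found.

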