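#!/usr/bin/env Rscript
# Convert junction-level fractions into allele-level effect estimates under
# balanced biallelic expression, assess heterozygous-marker allelic balance
# where a marker was simulated, and derive the NMD-exclusion status.

suppressPackageStartupMessages(library(splicepanel))
dir.create("results", showWarnings = FALSE)

scenarios <- list(
  pten_total_skip = list(model = synthetic_transcript("PTEN"), marker = NA),
  mlh1_partial_skip = list(model = synthetic_transcript("MLH1"), marker = 300),
  brca2_partial_rep1 = list(model = synthetic_transcript("BRCA2"), marker = NA),
  brca2_partial_rep2 = list(model = synthetic_transcript("BRCA2"), marker = NA),
  brca2_partial_rep3 = list(model = synthetic_transcript("BRCA2"), marker = NA),
  msh2_exon7_tandem_dup = list(model = synthetic_transcript("MSH2"), marker = 500)
)

rows <- list()
for (name in names(scenarios)) {
  sc <- scenarios[[name]]
  reads <- read_sam(file.path("results/sim", paste0(name, ".sam")))
  jc <- count_junctions(reads, sc$model, sample_id = name)
  calls <- detect_events(jc, sc$model)
  if (nrow(calls) == 0L) {
    message(sprintf("%-24s no aberrant event above thresholds (depth too low)",
                    name))
    next
  }
  main <- calls[which.max(calls$relative_expression), ]
  pct <- percent_variant_allele(main$relative_expression, 0.5)
  grade <- effect_grade(pct)
  frame <- if (main$rna_change %in% c("r.?", "r.="))
    "unknown" else frame_effect(parse_hgvs_r(main$rna_change))
  marker <- if (!is.na(sc$marker)) allelic_ratio(reads, sc$marker, sc$model)
            else NULL
  nmd <- nmd_status(if (grade == "none") "none" else grade, frame, marker)
  rows[[name]] <- data.frame(
    scenario = name, gene = sc$model$gene, event = main$event_type,
    rna_change = main$rna_change,
    event_fraction = round(main$relative_expression, 4),
    percent_variant_allele = round(pct, 1), grade = grade, frame = frame,
    marker_ratio = if (is.null(marker)) NA else round(marker$allelic_ratio, 3),
    nmd = nmd)
  message(sprintf("%-24s %5.1f%% of the variant allele (%s, %s, NMD %s)",
                  name, pct, grade, frame, nmd))
}
out <- do.call(rbind, rows)
utils::write.table(out, "results/allele_effects.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
message("Balanced expression (0.5) is the working assumption wherever no ",
        "heterozygous marker pins the allele of origin.")
message("Replicate libraries give a per-replicate range for the thin BRCA2 ",
        "evidence; replicates below the calling thresholds stay uncalled.")
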