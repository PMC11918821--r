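#' Allelic balance at a heterozygous exonic marker variant
#'
#' Counts reads whose matched segments cover the marker position, classified
#' by the base they carry (`ref`/`var`). The marker is "present" -- i.e. both
#' alleles are demonstrably transcribed -- when both classes reach
#' `het_min_reads` and the minor allele fraction reaches `het_min_fraction`.
#' A balanced ratio (inside `balance_window`) is what excludes allele dropout
#' by nonsense-mediated decay.
#'
#' @param reads Alignment-record tibble ([simulate_reads()]/[read_sam()]).
#' @param marker_position Transcript-space (spliced) position of the marker;
#'   must fall in an exon of `model`.
#' @param model The gene's [transcript_model()].
#' @param het_min_reads Minimum reads per allele class (default 10).
#' @param het_min_fraction Minimum minor-allele fraction (default 0.1).
#' @param balance_window Allelic-ratio interval regarded as balanced
#'   (default `c(0.3, 0.7)`).
#' @return Object of class `allele_summary`: `marker_present`, `ref_reads`,
#'   `var_reads`, `allelic_ratio` (var / (ref + var), `NA` when no reads),
#'   `balanced`.
#' @export
allelic_ratio <- function(reads, marker_position, model,
                          het_min_reads = 10L, het_min_fraction = 0.1,
                          balance_window = c(0.3, 0.7)) {
  stopifnot(inherits(model, "transcript_model"))
  tx <- exon_tx_intervals(model)
  ge <- exon_gene_intervals(model)
  i <- which(marker_position >= tx$tx_start & marker_position <= tx$tx_end)
  if (!length(i)) stop("marker_position is not exonic in this model")
  gpos <- ge$start[i] + (marker_position - tx$tx_start[i])

  covers <- logical(nrow(reads))
  for (k in seq_len(nrow(reads))) {
    ops <- parse_cigar(reads$cigar[k])
    pos <- reads$start[k]
    for (j in seq_len(nrow(ops))) {
      if (ops$op[j] == "M") {
        if (gpos >= pos && gpos <= pos + ops$len[j] - 1L) { covers[k] <- TRUE; break }
        pos <- pos + ops$len[j]
      } else if (ops$op[j] == "N") {
        pos <- pos + ops$len[j]
      }
    }
  }
  base <- reads$marker_base[covers]
  ref_reads <- sum(!is.na(base) & base == "ref")
  var_reads <- sum(!is.na(base) & base == "var")
  total <- ref_reads + var_reads
  ratio <- if (total > 0L) var_reads / total else NA_real_
  minor <- if (total > 0L) min(ref_reads, var_reads) / total else 0
  present <- ref_reads >= het_min_reads && var_reads >= het_min_reads &&
    minor >= het_min_fraction
  structure(
    list(marker_present = present, ref_reads = ref_reads,
         var_reads = var_reads, allelic_ratio = ratio,
         balanced = present && !is.na(ratio) &&
           ratio >= balance_window[1L] && ratio <= balance_window[2L]),
    class = "allele_summary"
  )
}

#' @export
print.allele_summary <- function(x, ...) {
  cat(sprintf("<allele_summary> ref %d / var %d, ratio %s, marker %s%s\n",
              x$ref_reads, x$var_reads,
              ifelse(is.na(x$allelic_ratio), "NA", sprintf("%.3f", x$allelic_ratio)),
              if (x$marker_present) "present" else "absent",
              if (x$marker_present && !x$balanced) " (skewed)" else ""))
  invisible(x)
}

#' Convert an overall event fraction to percent of the variant-carrying allele
#'
#' Under biallelic transcription where only the variant allele produces the
#' aberrant product, an event seen in fraction f of all junction-informative
#' reads affects `100 * f / allele_balance` percent of the variant allele's
#' transcripts (capped at 100). With balanced expression (the default
#' assumption when no marker is available), f = 0.21 means 42% of the variant
#' allele and f = 0.5 means the effect is total.
#'
#' @param event_fraction Aberrant-junction relative expression in `[0, 1]`.
#' @param allele_balance Fraction of transcripts from the variant allele
#'   (default 0.5).
#' @param aberrant_from_variant_only If `TRUE` (default), an event fraction
#'   materially above `allele_balance` is rejected as inconsistent.
#' @param tolerance Sampling slack allowed above `allele_balance` before the
#'   consistency check fails (default 0.05).
#' @return Percent of the variant-carrying allele, in `[0, 100]`.
#' @examples
#' percent_variant_allele(0.21, 0.5) # 42
#' @export
percent_variant_allele <- function(event_fraction, allele_balance = 0.5,
                                   aberrant_from_variant_only = TRUE,
                                   tolerance = 0.05) {
  stopifnot(is.numeric(event_fraction), event_fraction >= 0, event_fraction <= 1)
  if (allele_balance <= 0)
    stop("percent of variant allele is undefined when allele_balance is 0")
  if (aberrant_from_variant_only && event_fraction > allele_balance + tolerance)
    stop("event fraction ", event_fraction,
         " exceeds the variant-allele share ", allele_balance,
         "; aberrant products cannot all come from the variant allele")
  min(100, 100 * event_fraction / allele_balance)
}

#' Grade an allele-level splicing effect
#'
#' @param percent_of_variant_allele Percent of the variant allele affected.
#' @param total_threshold Percent at or above which the effect is graded
#'   `"total"` (default 90, separating total skipping from partial calls while
#'   tolerating sampling noise).
#' @return `"total"`, `"partial"` or `"none"`.
#' @export
effect_grade <- function(percent_of_variant_allele, total_threshold = 90) {
  stopifnot(percent_of_variant_allele >= 0, percent_of_variant_allele <= 100)
  if (percent_of_variant_allele >= total_threshold) "total"
  else if (percent_of_variant_allele > 0) "partial"
  else "none"
}

#' NMD-exclusion status of an RNA panel observation
#'
#' Decides whether allele dropout by nonsense-mediated decay has been
#' excluded: a balanced heterozygous marker proves both alleles are observed
#' (`excluded`); without one, a normal result -- or a partial result whose
#' product is a frameshift (hence an NMD substrate) -- may simply reflect a
#' degraded aberrant allele (`not_excluded`). When the observed effect is
#' already total, or partial with an in-frame product that NMD would not
#' degrade, the question does not arise (`not_applicable`).
#'
#' @param grade Effect grade (`"total"`, `"partial"`, `"none"`) from
#'   [effect_grade()]; `"none"` means normal splicing.
#' @param frame `"in_frame"`, `"frameshift"` or `"unknown"` for the aberrant
#'   product (ignored for normal splicing).
#' @param marker An [allelic_ratio()] summary, or `NULL` when no heterozygous
#'   exonic variant is available.
#' @return `"excluded"`, `"not_excluded"` or `"not_applicable"`.
#' @export
nmd_status <- function(grade = c("none", "partial", "total"),
                       frame = c("unknown", "in_frame", "frameshift"),
                       marker = NULL) {
  grade <- match.arg(grade)
  frame <- match.arg(frame)
  if (grade == "total") return("not_applicable")
  if (!is.null(marker)) {
    stopifnot(inherits(marker, "allele_summary"))
    if (marker$marker_present && marker$balanced) return("excluded")
  }
  if (grade == "none") return("not_excluded")
  if (frame == "in_frame") "not_applicable" else "not_excluded"
}

#' Export an allele summary row as TSV
#'
#' @param summary An [allelic_ratio()] result.
#' @param sample_id,gene,marker_position Annotation columns.
#' @param path Output TSV path (appends a header on first write).
#' @return `path`, invisibly.
#' @export
write_allele_summary <- function(summary, sample_id, gene, marker_position, path) {
  df <- data.frame(sample = sample_id, gene = gene,
                   marker_pos = marker_position,
                   ref_reads = summary$ref_reads, var_reads = summary$var_reads,
                   ratio = summary$allelic_ratio,
                   marker_present = summary$marker_present,
                   balanced = summary$balanced)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = !file.exists(path), append = file.exists(path))
  invisible(path)
}
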