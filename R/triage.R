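#' Maximum SpliceAI-style delta score
#'
#' @param ag,al,dg,dl Acceptor-gain, acceptor-loss, donor-gain and donor-loss
#'   delta scores in `[0, 1]` (any `NA` means the prediction is unavailable).
#' @return The maximum delta, or `NA` when unavailable.
#' @examples
#' spliceai_max(0.00, 0.77, 0.00, 0.85) # 0.85
#' @export
spliceai_max <- function(ag, al, dg, dl) {
  v <- c(ag, al, dg, dl)
  if (anyNA(v)) return(NA_real_)
  stopifnot(all(v >= 0), all(v <= 1))
  max(v)
}

#' Bucket a splice-prediction score by the panel's selection thresholds
#'
#' Scores live on a 0-100 scale (SpliceAI deltas are multiplied by 100
#' first). High means > 50, moderate 20-50 inclusive, negative < 20 --
#' matching the selection rule "high (>50%)", "moderate (20 to 50%)",
#' "without splice predictions (<20%)".
#'
#' @param score Numeric score; for `tool = "spliceai"` the 0-1 maximum delta.
#' @param tool `"spip"` (0-100 scale) or `"spliceai"` (0-1 scale).
#' @return `"high"`, `"moderate"`, `"negative"` or `"not_available"`.
#' @examples
#' bucket(98.41, "spip")  # high
#' bucket(0.35, "spliceai")  # moderate
#' @export
bucket <- function(score, tool = c("spip", "spliceai")) {
  tool <- match.arg(tool)
  if (is.na(score)) return("not_available")
  if (tool == "spliceai") {
    stopifnot(score >= 0, score <= 1)
    score <- 100 * score
  }
  if (score > 50) "high" else if (score >= 20) "moderate" else "negative"
}

# SpIP rows whose phrase is "NTR" (nothing to report) belong in the negative
# row of the concordance table regardless of their small residual percentage.
spip_is_ntr <- function(phrase) {
  !is.na(phrase) & grepl("^NTR", phrase)
}

# RNA outcome -> concordance column; "complex" transcripts count as a partial
# effect (aberrant products observed, no single clean total event)
outcome_column <- function(rna_outcome) {
  c(normal = "no_effect", total_event = "total_effect",
    partial_event = "partial_effect", complex = "partial_effect",
    unknown = "no_effect")[rna_outcome]
}

#' Predictor-versus-RNA concordance table
#'
#' Cross-tabulates each tool's bucketed predictions against the RNA panel
#' outcome. Rows are `positive_high` (score > 50), `positive_low` (a positive
#' prediction at or below 50, including sub-20 positives), `negative` (for
#' SpIP the "NTR" phrase; for SpliceAI a maximum delta below 0.20) and
#' `not_available`; columns are `total_effect`, `partial_effect`, `no_effect`.
#'
#' @param fixture Variant evidence tibble ([load_variant_table()] or
#'   compatible).
#' @param tool `"spip"` or `"spliceai"`.
#' @return A 4 x 3 integer matrix with row/column names as above.
#' @export
concordance <- function(fixture, tool = c("spip", "spliceai")) {
  tool <- match.arg(tool)
  rows <- c("positive_high", "positive_low", "negative", "not_available")
  cols <- c("total_effect", "partial_effect", "no_effect")
  out <- matrix(0L, nrow = 4L, ncol = 3L, dimnames = list(rows, cols))
  if (!nrow(fixture)) return(out)
  for (k in seq_len(nrow(fixture))) {
    if (tool == "spip") {
      b <- bucket(fixture$spip_percent[k], "spip")
      row <- if (b == "not_available") "not_available"
             else if (spip_is_ntr(fixture$spip_phrase[k])) "negative"
             else if (b == "high") "positive_high"
             else "positive_low"
    } else {
      mx <- spliceai_max(fixture$spliceai_ag[k], fixture$spliceai_al[k],
                         fixture$spliceai_dg[k], fixture$spliceai_dl[k])
      b <- bucket(mx, "spliceai")
      row <- switch(b, not_available = "not_available",
                    high = "positive_high", moderate = "positive_low",
                    negative = "negative")
    }
    col <- outcome_column(fixture$rna_outcome[k])
    out[row, col] <- out[row, col] + 1L
  }
  out
}

#' Positive predictive value of high-confidence predictions
#'
#' Among variants the tool scores above 50 (percent scale), the percentage
#' whose RNA analysis demonstrated a typed splice event (total or partial),
#' rounded half-up to an integer percent. `complex` and `unknown` outcomes do
#' not count as confirmations: a transcript profile of multiple complex
#' alterations cannot be attributed to the predicted splice-site change, so
#' predictor performance is scored against cleanly typed events only.
#'
#' @param fixture Variant evidence tibble.
#' @param tool `"spip"` or `"spliceai"`.
#' @return Integer percent.
#' @export
high_confidence_ppv <- function(fixture, tool = c("spip", "spliceai")) {
  tool <- match.arg(tool)
  score <- if (tool == "spip") fixture$spip_percent
           else mapply(spliceai_max, fixture$spliceai_ag, fixture$spliceai_al,
                       fixture$spliceai_dg, fixture$spliceai_dl)
  high <- vapply(score, function(s) bucket(s, tool) == "high", TRUE)
  if (!any(high)) stop("no high-confidence predictions for ", tool)
  effect <- fixture$rna_outcome %in% c("total_event", "partial_event")
  floor(100 * sum(high & effect) / sum(high) + 0.5)
}

#' Write a concordance table as TSV
#'
#' @param tab Matrix from [concordance()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_concordance <- function(tab, path) {
  df <- data.frame(prediction = rownames(tab), tab, row.names = NULL,
                   check.names = FALSE)
  df$total <- rowSums(tab)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
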