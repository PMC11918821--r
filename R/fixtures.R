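# Packaged evidence tables, transcribed from the published 48-gene panel
# study: the panel gene list, the 53-variant evidence table and the four
# large-duplication records. Loaders verify an md5 checksum so silent fixture
# corruption surfaces as an error, not as a wrong count downstream.

.fixture_md5 <- c(
  panel_genes_table1.tsv = "03101f501915248a77c5d9b0d3d1ab98",
  variant_evidence_table2.tsv = "4cb1b9a9117d374f77e8f32c8a72ce2c",
  duplications_table4.tsv = "d98526e27f9b938958cf66e591dc1211"
)

fixture_path <- function(name, dir = NULL) {
  path <- if (is.null(dir)) system.file("extdata", name, package = "splicepanel")
          else file.path(dir, name)
  if (!nzchar(path) || !file.exists(path)) stop("fixture not found: ", name)
  got <- unname(tools::md5sum(path))
  if (!identical(got, unname(.fixture_md5[[name]])))
    stop("fixture integrity check failed for ", name,
         " (md5 ", got, ", expected ", .fixture_md5[[name]], ")")
  path
}

#' Load the 48-gene panel fixture
#'
#' @return Tibble with `symbol` and `transcript_id`, one row per panel gene
#'   (exactly 48, unique symbols).
#' @export
load_panel_genes <- function() {
  df <- utils::read.delim(fixture_path("panel_genes_table1.tsv"),
                          stringsAsFactors = FALSE)
  tibble::as_tibble(df)
}

#' Load the 53-variant evidence fixture
#'
#' One row per variant studied on the RNA panel: HGVS c./p./r. descriptions,
#' SpIP-style prediction (`spip_phrase`, `spip_percent` on a 0-100 scale),
#' SpliceAI-style delta scores (`spliceai_ag`/`_al`/`_dg`/`_dl` in `[0, 1]`),
#' the RNA panel outcome (`rna_outcome` in `normal`, `total_event`,
#' `partial_event`, `complex`, `unknown`, plus free-text `rna_detail` and
#' `other_evidence`), the NMD-exclusion status (`het_marker_present`,
#' `no_het_marker`, `not_applicable`), the ACMG criteria string and the
#' assigned 1-5 class.
#'
#' Two rows carry a positive SpIP v1 prediction alongside a v2.1 "NTR"; the
#' row whose operative call was the positive v1 one (BRCA2 c.7670C>T) is
#' encoded with that phrase and score, the v2.1 value retained in the phrase
#' text. See the package vignette for the rationale.
#'
#' @return Tibble of 53 variant records.
#' @export
load_variant_table <- function() {
  df <- utils::read.delim(fixture_path("variant_evidence_table2.tsv"),
                          stringsAsFactors = FALSE, na.strings = "NA")
  if (nrow(df) != 53L) stop("variant fixture must have 53 records, got ", nrow(df))
  stopifnot(all(df$assigned_class %in% 1:5))
  ok <- is.na(df$spliceai_ag) |
    (df$spliceai_ag >= 0 & df$spliceai_ag <= 1 &
     df$spliceai_al >= 0 & df$spliceai_al <= 1 &
     df$spliceai_dg >= 0 & df$spliceai_dg <= 1 &
     df$spliceai_dl >= 0 & df$spliceai_dl <= 1)
  stopifnot(all(ok))
  tibble::as_tibble(df)
}

#' Load the large-duplication fixture
#'
#' Four patients with one-or-more-exon duplications found on the DNA panel,
#' tested on the RNA panel for chimeric (back-junction) reads proving the
#' tandem arrangement. `frame_disrupting` is an annotation added to the
#' published columns: nucleotide-modulo for the short duplications, and
#' disruptive for the 45-exon duplication that repeats most of the coding
#' sequence (`NA` where the duplicated extent is unknown).
#'
#' @return Tibble of 4 duplication records with logical `chimeric_reads` and
#'   `frame_disrupting`.
#' @export
load_duplications <- function() {
  df <- utils::read.delim(fixture_path("duplications_table4.tsv"),
                          stringsAsFactors = FALSE, na.strings = "NA")
  if (nrow(df) != 4L) stop("duplication fixture must have 4 records, got ", nrow(df))
  df$chimeric_reads <- df$chimeric_reads == "Yes"
  df$frame_disrupting <- ifelse(is.na(df$frame_disrupting), NA,
                                df$frame_disrupting == "Yes")
  tibble::as_tibble(df)
}
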