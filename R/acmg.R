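# ACMG-AMP evidence combination with the strength-modifier suffixes used on
# the RNA panel (_S strong, _M moderate, _P supporting, _NA contributes
# nothing). Default strengths follow the code families: PVS1 very strong,
# PS* strong, PM* moderate, PP* supporting on the pathogenic side; BS*
# strong, BP* supporting on the benign side -- except that a benign code
# carrying _S is promoted to strong (the panel's BP7_S).

.acmg_bases <- list(
  pathogenic = c(PVS1 = "very_strong", PS1 = "strong", PS2 = "strong",
                 PS3 = "strong", PS4 = "strong", PM1 = "moderate",
                 PM2 = "moderate", PM3 = "moderate", PM4 = "moderate",
                 PM5 = "moderate", PM6 = "moderate", PP1 = "supporting",
                 PP2 = "supporting", PP3 = "supporting", PP4 = "supporting",
                 PP5 = "supporting"),
  benign = c(BA1 = "stand_alone", BS1 = "strong", BS2 = "strong",
             BS3 = "strong", BS4 = "strong", BP1 = "supporting",
             BP2 = "supporting", BP3 = "supporting", BP4 = "supporting",
             BP5 = "supporting", BP6 = "supporting", BP7 = "supporting")
)

#' Parse an ACMG criteria string into evidence codes
#'
#' Accepts comma-separated codes with optional strength suffixes, e.g.
#' `"PM2, PVS1_M, PM3"` or `"PM2, BP7_S"`. `_NA` codes are kept but carry
#' strength `not_applicable` and contribute nothing to combination.
#'
#' @param text Criteria string (or character vector of codes).
#' @return Tibble with `code`, `base`, `direction` (`pathogenic`/`benign`)
#'   and `strength` (`very_strong`, `strong`, `moderate`, `supporting`,
#'   `not_applicable`).
#' @examples
#' parse_acmg("PM2, PVS1_M, PM3")
#' @export
parse_acmg <- function(text) {
  codes <- if (length(text) == 1L) strsplit(text, ",")[[1]] else text
  codes <- trimws(codes)
  codes <- codes[nzchar(codes)]
  parse1 <- function(code) {
    m <- regexec("^([A-Z]+[0-9]*)(?:_(VS|S|M|P|NA))?$", code)
    g <- regmatches(code, m)[[1]]
    if (length(g) == 0L) stop("malformed ACMG code: ", code)
    base <- g[2L]; suffix <- g[3L]
    if (base %in% names(.acmg_bases$pathogenic)) {
      direction <- "pathogenic"
      strength <- .acmg_bases$pathogenic[[base]]
    } else if (base %in% names(.acmg_bases$benign)) {
      direction <- "benign"
      strength <- .acmg_bases$benign[[base]]
    } else stop("unknown ACMG code family: ", base)
    if (nzchar(suffix)) {
      strength <- c(VS = "very_strong", S = "strong", M = "moderate",
                    P = "supporting", "NA" = "not_applicable")[[suffix]]
    }
    tibble::tibble(code = code, base = base, direction = direction,
                   strength = strength)
  }
  dplyr::bind_rows(lapply(codes, parse1))
}

#' Combine ACMG evidence codes into a 1-5 class
#'
#' Standard ACMG-AMP combining rules over the effective (suffix-adjusted)
#' strengths; `not_applicable` codes are ignored. Pathogenic (5) requires
#' e.g. a very strong plus supporting combinations or two strongs; likely
#' pathogenic (4) weaker combinations; likely benign (2) one strong benign or
#' two supporting benign codes. Strong benign evidence overrides isolated
#' moderate/supporting pathogenic codes (the panel's BP7_S outranking
#' PM2/PP3); a strong benign code alongside very strong pathogenic evidence
#' is a hard conflict and raises an error. Other pathogenic/benign conflicts
#' return class 3.
#'
#' @param codes A criteria string or a tibble from [parse_acmg()].
#' @return Integer class 1-5 with attribute `rationale` (text trail of the
#'   fired rule).
#' @examples
#' combine_acmg("PM2, PVS1")         # 4
#' combine_acmg("PM2, PVS1, PS3")    # 5
#' combine_acmg("PM2, BP4, BP7_S")   # 2
#' @export
combine_acmg <- function(codes) {
  if (is.character(codes)) codes <- parse_acmg(codes)
  active <- codes[codes$strength != "not_applicable", , drop = FALSE]
  p <- active[active$direction == "pathogenic", , drop = FALSE]
  b <- active[active$direction == "benign", , drop = FALSE]
  vs <- sum(p$strength == "very_strong"); st <- sum(p$strength == "strong")
  mo <- sum(p$strength == "moderate"); su <- sum(p$strength == "supporting")
  ba <- sum(b$strength == "stand_alone"); bs <- sum(b$strength == "strong")
  bp <- sum(b$strength == "supporting")

  if (bs + ba > 0L && vs > 0L)
    stop("conflicting evidence: very strong pathogenic alongside strong benign")

  path5 <- (vs >= 1L && (st >= 1L || mo >= 2L || (mo >= 1L && su >= 1L) || su >= 2L)) ||
    vs >= 2L ||
    st >= 2L ||
    (st == 1L && (mo >= 3L || (mo >= 2L && su >= 2L) || (mo >= 1L && su >= 4L)))
  path4 <- (vs >= 1L && mo >= 1L) ||
    (st == 1L && mo >= 1L) ||
    (st == 1L && su >= 2L) ||
    mo >= 3L ||
    (mo >= 2L && su >= 2L) ||
    (mo >= 1L && su >= 4L)
  benign1 <- ba >= 1L || bs >= 2L
  benign2 <- bs >= 1L || bp >= 2L

  res <- function(class, why) structure(as.integer(class), rationale = why)
  if ((benign1 || benign2) && (path5 || path4))
    return(res(3L, "conflicting pathogenic and benign combinations"))
  if (path5) return(res(5L, "pathogenic combination met"))
  if (benign1) return(res(1L, "stand-alone or double strong benign evidence"))
  if (path4) return(res(4L, "likely pathogenic combination met"))
  if (benign2) return(res(2L, sprintf(
    "benign evidence (%d strong, %d supporting) outweighs %d moderate / %d supporting pathogenic",
    bs, bp, mo, su)))
  res(3L, "evidence insufficient for any combination")
}

#' Derive RNA-based ACMG codes from an allele-level splicing effect
#'
#' Encodes the panel's decision table: normal splicing with NMD excluded
#' supports benignity at strong weight (BP7_S); normal splicing without NMD
#' exclusion leaves BP7 not applicable; a total aberrant effect yields PVS1
#' at very strong (frameshift) or moderate (in-frame / unknown) weight; a
#' partial effect leaves PVS1 not applicable unless a monoallelic assay
#' (minigene) showed the effect is total on the variant allele, which
#' restores strong weight. BP7 only ever applies to silent or intronic
#' variants, so `missense = TRUE` caps it at not applicable.
#'
#' @param grade `"none"` (normal splicing), `"partial"`, `"total"` or
#'   `"complex"`.
#' @param frame `"in_frame"`, `"frameshift"` or `"unknown"`.
#' @param nmd `"excluded"`, `"not_excluded"` or `"not_applicable"` from
#'   [nmd_status()].
#' @param context `"standard"`, `"monoallelic_assay_total"` (a minigene
#'   proved the effect total on the variant allele) or `"deep_intronic"`.
#' @param missense Is the DNA change a missense variant?
#' @return Tibble of evidence codes as from [parse_acmg()] (possibly empty).
#' @export
derive_rna_codes <- function(grade = c("none", "partial", "total", "complex"),
                             frame = c("unknown", "in_frame", "frameshift"),
                             nmd = c("not_excluded", "excluded", "not_applicable"),
                             context = c("standard", "monoallelic_assay_total",
                                         "deep_intronic"),
                             missense = FALSE) {
  grade <- match.arg(grade); frame <- match.arg(frame)
  nmd <- match.arg(nmd); context <- match.arg(context)
  code <- if (grade == "none") {
    if (nmd == "excluded" && !missense) "BP7_S" else "BP7_NA"
  } else if (grade == "total") {
    if (frame == "frameshift") "PVS1" else "PVS1_M"
  } else if (grade == "partial") {
    if (context == "monoallelic_assay_total") "PVS1_S" else "PVS1_NA"
  } else {
    NULL  # complex observations carry no single RNA code
  }
  if (is.null(code))
    return(tibble::tibble(code = character(), base = character(),
                          direction = character(), strength = character()))
  parse_acmg(code)
}

#' Classify a large exon duplication from RNA evidence
#'
#' Chimeric back-junction reads prove the duplication sits in tandem within
#' the transcript; when the tandem product disrupts the reading frame (or
#' otherwise cannot retain function), the duplication is pathogenic (5).
#' Without chimeric reads the tandem arrangement is unproven -- the extra
#' copy may lie elsewhere in the genome -- and the variant stays a VUS (3),
#' as does a proven tandem duplication whose product might remain functional.
#'
#' @param chimeric_reads Were back-junction (chimeric) reads observed?
#' @param frame_disrupting Does the tandem product disrupt the reading frame
#'   or otherwise abolish function? Ignored when `chimeric_reads` is `FALSE`.
#' @return Integer class 3 or 5.
#' @examples
#' classify_duplication(TRUE, TRUE)   # 5
#' classify_duplication(FALSE, TRUE)  # 3
#' @export
classify_duplication <- function(chimeric_reads, frame_disrupting = TRUE) {
  stopifnot(is.logical(chimeric_reads), length(chimeric_reads) == 1L)
  if (!chimeric_reads) return(3L)
  if (isTRUE(frame_disrupting)) 5L else 3L
}

#' Summarize panel classifications
#'
#' @param classes Integer vector of computed 1-5 classes (one per fixture
#'   row, in fixture order).
#' @param fixture Variant evidence tibble the classes were computed for.
#' @return List with `n_variants`, `n_rna_effect` (partial or total transcript
#'   modification, complex included), `n_no_effect`, `n_class2`,
#'   `n_class45`, `class_histogram`, and `concordant` (do computed classes
#'   match the fixture's recorded ones?).
#' @export
summarize_panel <- function(classes, fixture) {
  stopifnot(length(classes) == nrow(fixture))
  effect <- fixture$rna_outcome %in% c("total_event", "partial_event", "complex")
  hist <- vapply(1:5, function(k) sum(classes == k), 1L)
  names(hist) <- as.character(1:5)
  list(
    n_variants = nrow(fixture),
    n_rna_effect = sum(effect),
    n_no_effect = sum(!effect),
    n_class2 = sum(classes == 2L),
    n_class45 = sum(classes >= 4L),
    class_histogram = hist,
    concordant = all(classes == fixture$assigned_class)
  )
}
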