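#' Build a junction read-count matrix from gapped alignments
#'
#' Every `N` gap in every read contributes exactly one count to its
#' (donor, acceptor) junction, where donor is the gene-axis coordinate of the
#' last matched base before the gap and acceptor that of the first matched
#' base after it. Gapless stretches that cross a natural exon-intron boundary
#' with at least `anchor_min` matched bases on both sides are tallied
#' separately per natural junction (`boundary_unspliced`) -- the evidence used
#' for intron retention, which produces no junction of its own.
#'
#' @param reads Tibble of alignment records ([simulate_reads()]/[read_sam()])
#'   or a path to a SAM file.
#' @param model The gene's [transcript_model()].
#' @param anchor_min Minimum matched bases required on each side of an
#'   exon-intron boundary for an unspliced-boundary count (default 8, guarding
#'   against soft edge artifacts).
#' @param sample_id Free-text sample label carried into the result.
#' @return Object of class `junction_counts`: a list with `counts` (tibble
#'   `gene`, `donor`, `acceptor`, `count`, `natural`), `boundary_unspliced`
#'   (tibble `junction`, `donor`, `acceptor`, `count`), `n_gaps_total`,
#'   `n_skipped` (reads outside the gene axis, dropped with a warning) and
#'   `sample_id`.
#' @export
count_junctions <- function(reads, model, anchor_min = 8L, sample_id = "sample") {
  stopifnot(inherits(model, "transcript_model"))
  if (is.character(reads) && length(reads) == 1L) reads <- read_sam(reads)
  axis_len <- sum(model$exon_lengths) + sum(model$intron_lengths)

  n <- nrow(reads)
  donors <- vector("list", n); acceptors <- vector("list", n)
  blk_s <- vector("list", n); blk_e <- vector("list", n)
  skipped <- 0L
  has_gap <- grepl("N", reads$cigar, fixed = TRUE)
  for (k in seq_len(n)) {
    s <- reads$start[k]
    if (!has_gap[k]) {
      len <- as.integer(sub("M$", "", reads$cigar[k]))
      e <- s + len - 1L
      if (s < 1L || e > axis_len) { skipped <- skipped + 1L; next }
      blk_s[[k]] <- s; blk_e[[k]] <- e
      next
    }
    ops <- parse_cigar(reads$cigar[k])
    ops <- ops[ops$op != "S", , drop = FALSE]
    pos <- s
    bs <- integer(0L); be <- integer(0L); dn <- integer(0L); ac <- integer(0L)
    for (j in seq_len(nrow(ops))) {
      if (ops$op[j] == "M") {
        bs <- c(bs, pos); be <- c(be, pos + ops$len[j] - 1L)
        pos <- pos + ops$len[j]
      } else {
        dn <- c(dn, pos - 1L)
        pos <- pos + ops$len[j]
        ac <- c(ac, pos)
      }
    }
    if (min(bs) < 1L || max(be) > axis_len) { skipped <- skipped + 1L; next }
    donors[[k]] <- dn; acceptors[[k]] <- ac
    blk_s[[k]] <- bs; blk_e[[k]] <- be
  }
  if (skipped > 0L)
    warning(skipped, " read(s) outside the gene axis were skipped")

  dn <- unlist(donors); ac <- unlist(acceptors)
  nat <- natural_junctions(model)
  if (length(dn)) {
    key <- paste(dn, ac, sep = ":")
    tab <- table(key)
    parts <- strsplit(names(tab), ":", fixed = TRUE)
    counts <- tibble::tibble(
      gene = model$gene,
      donor = vapply(parts, function(p) as.integer(p[1L]), 1L),
      acceptor = vapply(parts, function(p) as.integer(p[2L]), 1L),
      count = as.integer(tab)
    )
  } else {
    counts <- tibble::tibble(gene = character(), donor = integer(),
                             acceptor = integer(), count = integer())
  }
  counts$natural <- counts$donor %in% nat$donor &
    counts$acceptor %in% nat$acceptor &
    paste(counts$donor, counts$acceptor) %in% paste(nat$donor, nat$acceptor)
  counts <- counts[order(counts$donor, counts$acceptor), , drop = FALSE]

  read_idx <- rep(seq_len(n), lengths(blk_s))
  all_s <- unlist(blk_s); all_e <- unlist(blk_e)
  a <- as.integer(anchor_min)
  bcount <- integer(nrow(nat))
  for (i in seq_len(nrow(nat))) {
    d <- nat$donor[i]; A <- nat$acceptor[i]
    cross <- (all_s <= d - a + 1L & all_e >= d + a) |
             (all_s <= A - a & all_e >= A + a - 1L)
    bcount[i] <- length(unique(read_idx[cross]))
  }

  structure(
    list(counts = counts,
         boundary_unspliced = tibble::tibble(junction = nat$junction,
                                             donor = nat$donor,
                                             acceptor = nat$acceptor,
                                             count = bcount),
         n_gaps_total = length(dn),
         n_skipped = skipped,
         sample_id = sample_id,
         gene = model$gene),
    class = "junction_counts"
  )
}

#' @export
print.junction_counts <- function(x, ...) {
  cat(sprintf("<junction_counts> %s (%s): %d junctions, %d gap observations, %d skipped reads\n",
              x$gene, x$sample_id, nrow(x$counts), x$n_gaps_total, x$n_skipped))
  invisible(x)
}

# counts of the natural junctions, zero-filled for unobserved ones
natural_counts <- function(jcm, model) {
  nat <- natural_junctions(model)
  key <- paste(jcm$counts$donor, jcm$counts$acceptor)
  idx <- match(paste(nat$donor, nat$acceptor), key)
  cnt <- ifelse(is.na(idx), 0L, jcm$counts$count[idx])
  nat$count <- as.integer(cnt)
  nat
}

#' Relative expression of a junction over its natural neighbours
#'
#' Computes `c(j) / (c(j) + r(j))`, where `r(j)` is the mean count of the
#' natural junction(s) sharing j's donor or acceptor site (both, averaged, for
#' an exon-skipping junction that borrows a natural donor and a natural
#' acceptor). For a natural junction, `r(j)` is the mean of the gene's other
#' natural junctions. When no natural junction shares a site (a fully novel
#' junction), the mean of all natural junctions is used.
#'
#' @param jcm A [count_junctions()] result.
#' @param model The gene's [transcript_model()].
#' @param donor,acceptor Gene-axis junction coordinates.
#' @return A fraction in `[0, 1]`, or `NA` (no coverage) when both the
#'   junction and its reference set are unobserved.
#' @export
relative_expression <- function(jcm, model, donor, acceptor) {
  stopifnot(inherits(jcm, "junction_counts"))
  nat <- natural_counts(jcm, model)
  key <- paste(jcm$counts$donor, jcm$counts$acceptor)
  idx <- match(paste(donor, acceptor), key)
  cj <- if (is.na(idx)) 0 else jcm$counts$count[idx]

  is_natural <- any(nat$donor == donor & nat$acceptor == acceptor)
  if (is_natural) {
    others <- nat$count[!(nat$donor == donor & nat$acceptor == acceptor)]
    rj <- if (length(others)) mean(others) else 0
  } else {
    shared <- c(nat$count[nat$donor == donor], nat$count[nat$acceptor == acceptor])
    rj <- if (length(shared)) mean(shared) else mean(nat$count)
  }
  if (cj == 0 && (is.na(rj) || rj == 0)) return(NA_real_)
  cj / (cj + rj)
}

# classify one observed junction against the natural junction set.
# Returns list(type, exon_from, exon_to): type is "natural", "exon_skip",
# "cryptic_donor", "cryptic_acceptor", "back_junction" or "complex".
classify_junction <- function(donor, acceptor, model) {
  ex <- exon_gene_intervals(model)
  nat <- natural_junctions(model)
  if (any(nat$donor == donor & nat$acceptor == acceptor))
    return(list(type = "natural", exon_from = NA_integer_, exon_to = NA_integer_))
  de <- match(donor, ex$end)      # exon whose 3' end is the donor
  ae <- match(acceptor, ex$start) # exon whose 5' start is the acceptor
  if (!is.na(de) && !is.na(ae)) {
    if (ae <= de)
      return(list(type = "back_junction", exon_from = de, exon_to = ae))
    if (ae > de + 1L)
      return(list(type = "exon_skip", exon_from = de + 1L, exon_to = ae - 1L))
    return(list(type = "complex", exon_from = NA_integer_, exon_to = NA_integer_))
  }
  if (is.na(de) && !is.na(ae))
    return(list(type = "cryptic_donor", exon_from = ae - 1L, exon_to = ae - 1L))
  if (!is.na(de) && is.na(ae))
    return(list(type = "cryptic_acceptor", exon_from = de + 1L, exon_to = de + 1L))
  list(type = "complex", exon_from = NA_integer_, exon_to = NA_integer_)
}

# transcript-space deletion implied by a forward junction: the exonic bases
# strictly between donor and acceptor, expressed in CDS-anchored coordinates
junction_rna_change <- function(donor, acceptor, model) {
  if (acceptor <= donor + 1L) return(parse_hgvs_r("r.?"))
  ex <- exon_gene_intervals(model)
  tx <- exon_tx_intervals(model)
  lo <- donor + 1L; hi <- acceptor - 1L
  om_start <- pmax(ex$start, lo); om_end <- pmin(ex$end, hi)
  keep <- om_start <= om_end
  if (!any(keep)) return(parse_hgvs_r("r.?"))
  tx_pos <- unlist(Map(function(i, s, e) {
    tx$tx_start[i] + (s - ex$start[i]) + seq_len(e - s + 1L) - 1L
  }, which(keep), om_start[keep], om_end[keep]))
  if (max(tx_pos) - min(tx_pos) + 1L != length(tx_pos))
    return(parse_hgvs_r("r.?"))  # omitted bases not contiguous in the mRNA
  c1 <- tx_to_coding(min(tx_pos), model)
  c2 <- tx_to_coding(max(tx_pos), model)
  txt <- if (c1 == c2) sprintf("r.%ddel", c1) else sprintf("r.%d_%ddel", c1, c2)
  parse_hgvs_r(txt)
}

#' RNA-level change implied by a splice event call
#'
#' For exon skipping and cryptic-site events, returns the transcript-space
#' deletion of the omitted bases (CDS-anchored coordinates; 5'UTR bases come
#' out negative). Back-junction, retention and complex events have no simple
#' deletion and are reported as `r.?`.
#'
#' @param call A row of [detect_events()] output (or any list with `donor`,
#'   `acceptor`, `event_type`).
#' @param model The gene's [transcript_model()].
#' @return An `rna_change`.
#' @export
event_to_rna_change <- function(call, model) {
  if (!call$event_type %in% c("exon_skip", "cryptic_donor", "cryptic_acceptor"))
    return(parse_hgvs_r("r.?"))
  junction_rna_change(call$donor, call$acceptor, model)
}

#' Detect and type abnormally expressed junctions
#'
#' Emits one call per non-natural junction passing both thresholds, typed by
#' comparing its ends with the natural junction set: both ends at natural
#' exon boundaries with >= 1 exon omitted is exon skipping; an acceptor at or
#' 5' of its donor in exon order is a tandem-duplication back-junction;
#' exactly one novel end is a cryptic donor/acceptor; anything else is
#' complex. Intron retention is called from unspliced boundary coverage
#' (quantified as `boundary / (boundary + natural junction count)`), not from
#' a junction.
#'
#' @param jcm A [count_junctions()] result.
#' @param model The gene's [transcript_model()].
#' @param min_reads Minimum supporting reads for a call (default 10).
#' @param min_fraction Minimum relative expression for a call (default 0.05).
#' @return Tibble with `gene`, `event_type`, `donor`, `acceptor`,
#'   `supporting_reads`, `relative_expression`, `exons_affected` (string, e.g.
#'   `"3"` or `"7-8"`), `rna_change` (canonical `r.` string).
#' @export
detect_events <- function(jcm, model, min_reads = 10L, min_fraction = 0.05) {
  stopifnot(inherits(jcm, "junction_counts"), min_reads > 0L, min_fraction > 0)
  calls <- list()
  abn <- jcm$counts[!jcm$counts$natural & jcm$counts$count >= min_reads, , drop = FALSE]
  for (k in seq_len(nrow(abn))) {
    d <- abn$donor[k]; a <- abn$acceptor[k]
    rel <- relative_expression(jcm, model, d, a)
    if (is.na(rel) || rel < min_fraction) next
    cls <- classify_junction(d, a, model)
    exons <- if (is.na(cls$exon_from)) NA_character_
             else if (cls$exon_from == cls$exon_to) as.character(cls$exon_from)
             else paste0(cls$exon_from, "-", cls$exon_to)
    rc <- event_to_rna_change(list(event_type = cls$type, donor = d, acceptor = a),
                              model)
    calls[[length(calls) + 1L]] <- tibble::tibble(
      gene = model$gene, event_type = cls$type, donor = d, acceptor = a,
      supporting_reads = abn$count[k], relative_expression = rel,
      exons_affected = exons, rna_change = format_hgvs_r(rc))
  }

  natc <- natural_counts(jcm, model)
  bu <- jcm$boundary_unspliced
  for (i in seq_len(nrow(bu))) {
    b <- bu$count[i]
    if (b < min_reads) next
    frac <- b / (b + natc$count[i])
    if (frac < min_fraction) next
    calls[[length(calls) + 1L]] <- tibble::tibble(
      gene = model$gene, event_type = "intron_retention",
      donor = bu$donor[i], acceptor = bu$acceptor[i],
      supporting_reads = b, relative_expression = frac,
      exons_affected = paste0(i, "-", i + 1L), rna_change = "r.?")
  }

  if (!length(calls))
    return(tibble::tibble(gene = character(), event_type = character(),
                          donor = integer(), acceptor = integer(),
                          supporting_reads = integer(),
                          relative_expression = double(),
                          exons_affected = character(),
                          rna_change = character()))
  dplyr::bind_rows(calls)
}

#' Export a junction count matrix as TSV
#'
#' Writes one row per observed junction with its count, natural flag and
#' relative expression.
#'
#' @param jcm A [count_junctions()] result.
#' @param model The gene's [transcript_model()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
export_junctions <- function(jcm, model, path) {
  df <- jcm$counts
  df$relative_expression <- vapply(seq_len(nrow(df)), function(k)
    relative_expression(jcm, model, df$donor[k], df$acceptor[k]), 1.0)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write splice event calls as TSV or JSON
#'
#' @param calls Tibble from [detect_events()].
#' @param path Output path.
#' @param format `"tsv"` or `"json"` (JSON requires the jsonlite package).
#' @return `path`, invisibly.
#' @export
write_event_calls <- function(calls, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (format == "tsv") {
    utils::write.table(calls, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    if (!requireNamespace("jsonlite", quietly = TRUE))
      stop("jsonlite is required for JSON export")
    jsonlite::write_json(calls, path, auto_unbox = TRUE, digits = NA, na = "null")
  }
  invisible(path)
}
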