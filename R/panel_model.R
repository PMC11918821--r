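#' Transcript model for one panel gene
#'
#' Represents the exon/intron structure of a single reference transcript in
#' transcript orientation (5'->3'). All downstream coordinates live either in
#' *transcript space* (concatenated exons, 1-based) or on the *gene axis*
#' (exons plus introns concatenated, 1-based), never in genomic space, so
#' strand conventions cannot leak in.
#'
#' @param gene Gene symbol.
#' @param exon_lengths Ordered positive integer exon lengths (nt).
#' @param intron_lengths Ordered positive integer intron lengths (nt); one
#'   fewer than exons.
#' @param cds_start_offset 0-based offset of the first coding base within the
#'   concatenated exonic sequence.
#' @param cds_length CDS length in nt; must be a multiple of 3.
#' @param transcript_id Versioned reference transcript identifier.
#' @return An object of class `transcript_model`.
#' @examples
#' tm <- transcript_model("TOY", c(100, 50, 80), c(500, 300), cds_length = 228)
#' natural_junctions(tm)
#' @export
transcript_model <- function(gene, exon_lengths, intron_lengths,
                             cds_start_offset = 0L, cds_length = NULL,
                             transcript_id = NA_character_) {
  stopifnot(is.character(gene), nzchar(gene))
  exon_lengths <- as.integer(exon_lengths)
  intron_lengths <- as.integer(intron_lengths)
  if (length(exon_lengths) < 1L || any(exon_lengths <= 0L))
    stop("exon_lengths must be positive integers")
  if (length(intron_lengths) != length(exon_lengths) - 1L)
    stop("need exactly one fewer intron than exons")
  if (length(intron_lengths) && any(intron_lengths <= 0L))
    stop("intron_lengths must be positive integers")
  if (is.null(cds_length)) {
    cds_length <- sum(exon_lengths) - as.integer(cds_start_offset)
    cds_length <- cds_length - cds_length %% 3L
  }
  cds_start_offset <- as.integer(cds_start_offset)
  cds_length <- as.integer(cds_length)
  if (cds_length %% 3L != 0L) stop("cds_length must be a multiple of 3")
  if (cds_start_offset + cds_length > sum(exon_lengths))
    stop("CDS extends beyond the transcript")
  structure(
    list(gene = gene, transcript_id = transcript_id,
         exon_lengths = exon_lengths, intron_lengths = intron_lengths,
         cds_start_offset = cds_start_offset, cds_length = cds_length),
    class = "transcript_model"
  )
}

#' @export
print.transcript_model <- function(x, ...) {
  cat(sprintf("<transcript_model> %s (%s): %d exons, %d nt mRNA, CDS %d nt @ offset %d\n",
              x$gene, x$transcript_id, length(x$exon_lengths),
              sum(x$exon_lengths), x$cds_length, x$cds_start_offset))
  invisible(x)
}

#' Exon intervals on the unspliced gene axis
#'
#' @param model A [transcript_model()].
#' @return Tibble with `exon`, `start`, `end` (gene-axis, 1-based inclusive).
#' @export
exon_gene_intervals <- function(model) {
  n <- length(model$exon_lengths)
  starts <- integer(n); ends <- integer(n)
  pos <- 1L
  for (i in seq_len(n)) {
    starts[i] <- pos
    ends[i] <- pos + model$exon_lengths[i] - 1L
    pos <- ends[i] + (if (i < n) model$intron_lengths[i] else 0L) + 1L
  }
  tibble::tibble(exon = seq_len(n), start = starts, end = ends)
}

#' Natural splice junctions of a transcript model
#'
#' Junction i joins the 3' end of exon i (donor) to the 5' start of exon i+1
#' (acceptor), both as gene-axis coordinates of the last/first *matched* base.
#'
#' @param model A [transcript_model()].
#' @return Tibble with `junction`, `donor`, `acceptor`.
#' @export
natural_junctions <- function(model) {
  ex <- exon_gene_intervals(model)
  n <- nrow(ex)
  if (n < 2L) return(tibble::tibble(junction = integer(), donor = integer(), acceptor = integer()))
  tibble::tibble(junction = seq_len(n - 1L),
                 donor = ex$end[-n], acceptor = ex$start[-1L])
}

#' Cumulative transcript-space exon boundaries
#'
#' @param model A [transcript_model()].
#' @return Tibble with `exon`, `tx_start`, `tx_end` (1-based positions of each
#'   exon's first and last base within the spliced transcript).
#' @export
exon_tx_intervals <- function(model) {
  ends <- cumsum(model$exon_lengths)
  tibble::tibble(exon = seq_along(ends),
                 tx_start = c(1L, utils::head(ends, -1L) + 1L),
                 tx_end = ends)
}

# transcript-space position -> CDS-anchored (c./r.-style) coordinate:
# bases 5' of the CDS are negative (no zero), coding base 1 is c.1.
tx_to_coding <- function(pos, model) {
  o <- model$cds_start_offset
  ifelse(pos > o, pos - o, pos - o - 1L)
}

coding_to_tx <- function(cpos, model) {
  o <- model$cds_start_offset
  ifelse(cpos > 0L, cpos + o, cpos + o + 1L)
}

# ---------------------------------------------------------------------------
# HGVS parsing (deliberately minimal: substitutions, del, dup, delins, ins,
# intron offsets, 5'UTR negative bases, and the uncertainty forms r.? / r.=)
# ---------------------------------------------------------------------------

#' Parse an HGVS c. position or range
#'
#' Understands point descriptions (`c.206+6T>G`, `c.100A>G`, `c.-113-1G>A`)
#' and range descriptions (`c.791-489_791-20del`). Intron offsets are signed
#' (+n downstream of a donor, -n upstream of an acceptor); 5'UTR bases are
#' negative. The edit suffix (`del`, `dup`, `>`, `delins`, `ins`) is captured
#' verbatim but not interpreted.
#'
#' @param text HGVS string beginning with `"c."`.
#' @return A list of class `hgvs_c` with `start`, `end` (each a list with
#'   `base`, `intron_offset`), `range` (logical) and `edit` (string).
#' @examples
#' parse_hgvs_c("c.206+6T>G")
#' parse_hgvs_c("c.791-489_791-20del")
#' @export
parse_hgvs_c <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  if (!startsWith(text, "c.")) stop("not an HGVS c. description: ", text)
  body <- substr(text, 3L, nchar(text))
  pos_re <- "(-?[0-9]+)([+-][0-9]+)?"
  m <- regexec(paste0("^", pos_re, "(?:_", pos_re, ")?(.*)$"), body)
  g <- regmatches(body, m)[[1]]
  if (length(g) == 0L || !nzchar(g[2L]))
    stop("malformed HGVS c. position in: ", text)
  mk <- function(base, off) {
    base <- as.integer(base)
    if (base == 0L) stop("HGVS base 0 does not exist in: ", text)
    list(base = base,
         intron_offset = if (nzchar(off)) as.integer(off) else 0L)
  }
  start <- mk(g[2L], g[3L])
  range <- nzchar(g[4L])
  end <- if (range) mk(g[4L], g[5L]) else start
  edit <- g[6L]
  if (grepl("[()*\\[]", edit) && !grepl("^ins", edit))
    stop("unsupported HGVS token in: ", text)
  structure(list(start = start, end = end, range = range, edit = edit),
            class = "hgvs_c")
}

#' Format a parsed HGVS c. description back to its canonical string
#'
#' @param x An object returned by [parse_hgvs_c()].
#' @return Canonical HGVS c. string.
#' @export
format_hgvs_c <- function(x) {
  stopifnot(inherits(x, "hgvs_c"))
  fmt1 <- function(p) {
    off <- if (p$intron_offset == 0L) "" else sprintf("%+d", p$intron_offset)
    paste0(p$base, off)
  }
  pos <- if (x$range) paste0(fmt1(x$start), "_", fmt1(x$end)) else fmt1(x$start)
  paste0("c.", pos, x$edit)
}

#' Parse an HGVS r. description
#'
#' @param text HGVS string beginning with `"r."`. `"r.="` (no change) and
#'   `"r.?"` (undetermined) yield kind `"unknown"`.
#' @return A list of class `rna_change` with `kind` (one of `deletion`,
#'   `duplication`, `substitution`, `unknown`), `start`, `end` and the
#'   original `description`.
#' @examples
#' parse_hgvs_r("r.165_209del")
#' parse_hgvs_r("r.=")
#' @export
parse_hgvs_r <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  if (!startsWith(text, "r.")) stop("not an HGVS r. description: ", text)
  body <- substr(text, 3L, nchar(text))
  if (body %in% c("=", "?")) {
    return(structure(list(kind = "unknown", start = NA_integer_,
                          end = NA_integer_, description = text),
                     class = "rna_change"))
  }
  m <- regexec("^(-?[0-9]+)(?:_(-?[0-9]+))?([A-Za-z>].*)$", body)
  g <- regmatches(body, m)[[1]]
  if (length(g) == 0L) stop("malformed HGVS r. description: ", text)
  start <- as.integer(g[2L])
  end <- if (nzchar(g[3L])) as.integer(g[3L]) else start
  edit <- g[4L]
  kind <- if (grepl("^del(?!ins)", edit, perl = TRUE)) "deletion"
          else if (grepl("^dup", edit)) "duplication"
          else if (grepl(">", edit, fixed = TRUE)) "substitution"
          else "unknown"
  if (start > end) stop("inverted HGVS r. range in: ", text)
  structure(list(kind = kind, start = start, end = end, description = text),
            class = "rna_change")
}

#' @export
print.rna_change <- function(x, ...) {
  cat(sprintf("<rna_change> %s [%s %s..%s]\n", x$description, x$kind,
              x$start, x$end))
  invisible(x)
}

#' Format an rna_change back to a canonical HGVS r. deletion/duplication string
#'
#' @param x An `rna_change`.
#' @return Canonical string (`r.?` for unknown kinds).
#' @export
format_hgvs_r <- function(x) {
  stopifnot(inherits(x, "rna_change"))
  switch(x$kind,
    unknown = if (identical(x$description, "r.=")) "r.=" else "r.?",
    deletion = if (x$start == x$end) sprintf("r.%ddel", x$start)
               else sprintf("r.%d_%ddel", x$start, x$end),
    duplication = if (x$start == x$end) sprintf("r.%ddup", x$start)
                  else sprintf("r.%d_%ddup", x$start, x$end),
    substitution = x$description
  )
}

#' Length of the RNA segment deleted or duplicated
#'
#' @param change An `rna_change` of kind deletion or duplication.
#' @return Integer nucleotide count `end - start + 1`.
#' @examples
#' deleted_length(parse_hgvs_r("r.165_209del")) # 45
#' @export
deleted_length <- function(change) {
  stopifnot(inherits(change, "rna_change"))
  if (!change$kind %in% c("deletion", "duplication"))
    stop("deleted_length is defined only for deletions and duplications, got ",
         change$kind)
  change$end - change$start + 1L
}

#' Reading-frame consequence of an RNA deletion/duplication
#'
#' A segment whose length is a multiple of 3 preserves the downstream codon
#' register (`in_frame`); any other length shifts it (`frameshift`).
#'
#' @param change An `rna_change` of kind deletion or duplication.
#' @return `"in_frame"` or `"frameshift"`.
#' @examples
#' frame_effect(parse_hgvs_r("r.6842_6937del")) # in_frame (96 nt)
#' @export
frame_effect <- function(change) {
  if (deleted_length(change) %% 3L == 0L) "in_frame" else "frameshift"
}

#' Number of codons overlapped by a coding interval
#'
#' Codon k covers coding bases 3k-2..3k, so the interval c.start..c.end
#' touches `ceil(end/3) - ceil(start/3) + 1` codons. UTR (non-positive) bases
#' are rejected.
#'
#' @param c_start,c_end Positive coding (c.) coordinates, `c_start <= c_end`.
#' @param cds_length Optional CDS length for an upper-bound check.
#' @return Integer codon (amino-acid) count.
#' @examples
#' codons_overlapped(165, 209) # 16
#' @export
codons_overlapped <- function(c_start, c_end, cds_length = NULL) {
  if (c_start < 1L || c_end < c_start)
    stop("need 1 <= c_start <= c_end within the CDS")
  if (!is.null(cds_length) && c_end > cds_length)
    stop("position ", c_end, " lies beyond the CDS (", cds_length, " nt)")
  as.integer(ceiling(c_end / 3) - ceiling(c_start / 3) + 1)
}

#' Predicted RT-PCR product size after a splice change
#'
#' @param reference_amplicon Reference product size in bp.
#' @param change An `rna_change`; deletions shorten the product, duplications
#'   lengthen it. The change must fit inside the amplified interval.
#' @return Integer product size in bp.
#' @examples
#' predict_rtpcr_size(370, parse_hgvs_r("r.165_209del")) # 325
#' @export
predict_rtpcr_size <- function(reference_amplicon, change) {
  stopifnot(is.numeric(reference_amplicon), reference_amplicon > 0)
  len <- deleted_length(change)
  if (change$kind == "deletion" && len >= reference_amplicon)
    stop("deletion of ", len, " nt does not fit inside a ",
         reference_amplicon, " bp amplicon")
  as.integer(reference_amplicon + if (change$kind == "duplication") len else -len)
}

#' Read transcript models from a TSV file
#'
#' Expected columns: `gene`, `exon_index`, `exon_length`, `intron_length_after`
#' (empty/NA on the last exon), `cds_start_offset`, `cds_length`, and
#' optionally `transcript_id`. One row per exon, ordered.
#'
#' @param path TSV file path.
#' @return Named list of [transcript_model()] objects.
#' @export
read_transcript_models <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  need <- c("gene", "exon_index", "exon_length", "intron_length_after",
            "cds_start_offset", "cds_length")
  if (!all(need %in% names(df)))
    stop("transcript model TSV must have columns: ", paste(need, collapse = ", "))
  out <- lapply(split(df, df$gene), function(d) {
    d <- d[order(d$exon_index), , drop = FALSE]
    introns <- d$intron_length_after[-nrow(d)]
    transcript_model(
      gene = d$gene[1L],
      exon_lengths = d$exon_length,
      intron_lengths = introns,
      cds_start_offset = d$cds_start_offset[1L],
      cds_length = d$cds_length[1L],
      transcript_id = if ("transcript_id" %in% names(d)) d$transcript_id[1L]
                      else NA_character_
    )
  })
  out[unique(df$gene)]
}

#' Write transcript models to the TSV layout read by [read_transcript_models()]
#'
#' @param models Named list of [transcript_model()] objects.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_transcript_models <- function(models, path) {
  rows <- lapply(models, function(m) {
    n <- length(m$exon_lengths)
    data.frame(gene = m$gene, transcript_id = m$transcript_id,
               exon_index = seq_len(n), exon_length = m$exon_lengths,
               intron_length_after = c(m$intron_lengths, NA_integer_),
               cds_start_offset = m$cds_start_offset, cds_length = m$cds_length)
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a transcript model from GTF-like exon features
#'
#' Accepts a minimal GTF: tab-separated `seqname source feature start end
#' score strand frame attributes` lines where `feature == "exon"` and `start`/
#' `end` are gene-axis coordinates (transcript orientation, 1-based). The
#' attribute field must carry `gene_id`; `cds_start_offset`/`cds_length` may be
#' given as attributes on any exon line and default to a CDS covering the
#' transcript.
#'
#' @param path GTF file path.
#' @return Named list of [transcript_model()] objects.
#' @export
read_transcript_gtf <- function(path) {
  ln <- readLines(path)
  ln <- ln[!startsWith(ln, "#") & nzchar(ln)]
  f <- strsplit(ln, "\t", fixed = TRUE)
  bad <- vapply(f, length, 1L) != 9L
  if (any(bad)) stop("malformed GTF line(s): ", which(bad)[1L])
  f <- do.call(rbind, f)
  f <- as.data.frame(f, stringsAsFactors = FALSE)
  names(f) <- c("seqname", "source", "feature", "start", "end", "score",
                "strand", "frame", "attributes")
  f <- f[f$feature == "exon", , drop = FALSE]
  if (nrow(f) == 0L) stop("no exon features in ", path)
  attr1 <- function(a, key) {
    m <- regmatches(a, regexec(paste0(key, '[ =]+"?([^";]+)"?'), a))[[1]]
    if (length(m)) m[2L] else NA_character_
  }
  f$gene <- vapply(f$attributes, attr1, "", key = "gene_id")
  f$start <- as.integer(f$start); f$end <- as.integer(f$end)
  out <- lapply(split(f, f$gene), function(d) {
    d <- d[order(d$start), , drop = FALSE]
    if (any(d$start[-1L] <= d$end[-nrow(d)]))
      stop("overlapping exon features for ", d$gene[1L])
    exl <- d$end - d$start + 1L
    inl <- if (nrow(d) > 1L) d$start[-1L] - d$end[-nrow(d)] - 1L else integer()
    off <- suppressWarnings(as.integer(attr1(d$attributes[1L], "cds_start_offset")))
    len <- suppressWarnings(as.integer(attr1(d$attributes[1L], "cds_length")))
    transcript_model(d$gene[1L], exl, inl,
                     cds_start_offset = if (is.na(off)) 0L else off,
                     cds_length = if (is.na(len)) NULL else len)
  })
  out[unique(f$gene)]
}
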