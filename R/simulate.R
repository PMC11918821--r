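#' Scenario configuration for the spliced-read simulator
#'
#' Describes one sequencing scenario over a single gene: biallelic
#' transcription with a configurable allele balance, an optional aberrant
#' splicing event restricted to the variant allele, optional NMD-driven
#' degradation of frameshift products, and an optional heterozygous exonic
#' marker variant through which reads reveal their allele of origin.
#'
#' @param transcript A [transcript_model()].
#' @param depth Expected read count over the gene (positive integer). Gene
#'   expression differences (e.g. a gene poorly expressed in blood) are
#'   emulated purely through this parameter.
#' @param allele_balance Fraction of transcripts arising from the variant
#'   allele (default 0.5, balanced biallelic expression).
#' @param event One of `"none"`, `"exon_skip"`, `"partial_exon_skip"`,
#'   `"cryptic_donor"`, `"cryptic_acceptor"`, `"intron_retention"`,
#'   `"tandem_duplication"`.
#' @param event_params Named list of event-specific integers:
#'   * `exon_skip` / `tandem_duplication`: `exons` (index or inclusive range);
#'   * `partial_exon_skip`: `exons` plus `extend_into_next` (nt trimmed from
#'     the 5' end of the exon following the skipped range);
#'   * `cryptic_donor`: `exon`, `shift` (nt the donor moves along the gene
#'     axis; negative = into the exon, positive = into the intron);
#'   * `cryptic_acceptor`: `exon`, `shift` (negative = into the upstream
#'     intron, positive = into the exon);
#'   * `intron_retention`: `intron` (index of the retained intron).
#' @param per_allele_event_fraction Probability that a variant-allele
#'   transcript carries the aberrant event.
#' @param nmd_survival Fraction of NMD-targeted (frameshift) aberrant
#'   transcripts that survive decay; 1 disables NMD.
#' @param marker Optional transcript-space (spliced, 1-based) position of a
#'   heterozygous exonic marker variant.
#' @param read_length Read length in nt.
#' @param seed Integer seed; identical seeds give identical read sets.
#' @return An object of class `scenario_config`.
#' @export
scenario_config <- function(transcript, depth = 2000L, allele_balance = 0.5,
                            event = "none", event_params = list(),
                            per_allele_event_fraction = 1.0,
                            nmd_survival = 1.0, marker = NULL,
                            read_length = 100L, seed = 1L) {
  stopifnot(inherits(transcript, "transcript_model"))
  events <- c("none", "exon_skip", "partial_exon_skip", "cryptic_donor",
              "cryptic_acceptor", "intron_retention", "tandem_duplication")
  event <- match.arg(event, events)
  frac_ok <- function(x) is.numeric(x) && length(x) == 1L && x >= 0 && x <= 1
  if (!frac_ok(allele_balance)) stop("allele_balance must be in [0, 1]")
  if (!frac_ok(per_allele_event_fraction))
    stop("per_allele_event_fraction must be in [0, 1]")
  if (!frac_ok(nmd_survival)) stop("nmd_survival must be in [0, 1]")
  depth <- as.integer(depth); read_length <- as.integer(read_length)
  if (depth < 1L) stop("depth must be positive")
  if (read_length < 2L) stop("read_length must be at least 2")
  if (!is.null(marker)) {
    marker <- as.integer(marker)
    if (marker < 1L || marker > sum(transcript$exon_lengths))
      stop("marker must be a transcript-space exonic position")
  }
  # validates event parameters against the transcript structure
  blocks <- isoform_blocks(transcript, event, event_params)
  if (sum(blocks$end - blocks$start + 1L) < read_length)
    stop("read_length exceeds the aberrant isoform length")
  if (sum(transcript$exon_lengths) < read_length)
    stop("read_length exceeds the transcript length")
  structure(
    list(transcript = transcript, depth = depth,
         allele_balance = allele_balance, event = event,
         event_params = event_params,
         per_allele_event_fraction = per_allele_event_fraction,
         nmd_survival = nmd_survival, marker = marker,
         read_length = read_length, seed = as.integer(seed)),
    class = "scenario_config"
  )
}

#' Exonic blocks (gene-axis intervals) of the isoform produced by an event
#'
#' The natural isoform is the ordered exon chain; each event edits that chain.
#' A tandem duplication repeats exons j..k, so its block list revisits earlier
#' coordinates -- the source of the diagnostic back-junction.
#'
#' @param model A [transcript_model()].
#' @param event,params As in [scenario_config()].
#' @return Tibble with `start`, `end` (gene-axis, ordered along the mRNA).
#' @export
isoform_blocks <- function(model, event = "none", params = list()) {
  ex <- exon_gene_intervals(model)
  n <- nrow(ex)
  get_range <- function(key = "exons") {
    r <- params[[key]]
    if (is.null(r)) stop("event_params$", key, " is required for ", event)
    r <- as.integer(r)
    if (any(r < 1L) || any(r > n)) stop("exon index out of range")
    seq.int(min(r), max(r))
  }
  blocks <- switch(event,
    none = ex,
    exon_skip = {
      j <- get_range()
      if (length(j) >= n) stop("cannot skip every exon")
      if (1L %in% j || n %in% j) stop("cannot skip a terminal exon")
      ex[-j, , drop = FALSE]
    },
    partial_exon_skip = {
      j <- get_range()
      if (1L %in% j || n %in% j) stop("cannot skip a terminal exon")
      extend <- as.integer(params$extend_into_next %||% 0L)
      out <- ex[-j, , drop = FALSE]
      nxt <- which(out$exon == max(j) + 1L)
      out$start[nxt] <- out$start[nxt] + extend
      if (out$start[nxt] > out$end[nxt]) stop("extend_into_next swallows the exon")
      out
    },
    cryptic_donor = {
      j <- as.integer(params$exon %||% stop("event_params$exon required"))
      if (j < 1L || j >= n) stop("cryptic donor needs an internal donor exon")
      shift <- as.integer(params$shift %||% stop("event_params$shift required"))
      out <- ex
      out$end[j] <- out$end[j] + shift
      if (out$end[j] < out$start[j]) stop("donor shift swallows the exon")
      if (j < n && out$end[j] >= out$start[j + 1L]) stop("donor shift crosses next exon")
      out
    },
    cryptic_acceptor = {
      j <- as.integer(params$exon %||% stop("event_params$exon required"))
      if (j <= 1L || j > n) stop("cryptic acceptor needs an internal acceptor exon")
      shift <- as.integer(params$shift %||% stop("event_params$shift required"))
      out <- ex
      out$start[j] <- out$start[j] + shift
      if (out$start[j] > out$end[j]) stop("acceptor shift swallows the exon")
      if (out$start[j] <= out$end[j - 1L]) stop("acceptor shift crosses previous exon")
      out
    },
    intron_retention = {
      j <- as.integer(params$intron %||% stop("event_params$intron required"))
      if (j < 1L || j > n - 1L) stop("intron index out of range")
      out <- ex
      out$end[j] <- out$end[j + 1L]
      out[-(j + 1L), , drop = FALSE]
    },
    tandem_duplication = {
      j <- get_range()
      rbind(ex[seq_len(max(j)), , drop = FALSE],
            ex[j, , drop = FALSE],
            if (max(j) < n) ex[seq.int(max(j) + 1L, n), , drop = FALSE])
    }
  )
  tibble::tibble(start = blocks$start, end = blocks$end)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# does the event produce a frameshift product? (length change mod 3)
event_is_frameshift <- function(model, event, params) {
  if (event == "none") return(FALSE)
  nat <- sum(model$exon_lengths)
  iso <- with(isoform_blocks(model, event, params), sum(end - start + 1L))
  (iso - nat) %% 3L != 0L
}

# one read from an isoform: gene-axis start + extended-CIGAR + marker coverage.
# `cum` is cumsum of block lengths, `tstart` the spliced start position.
.read_from_blocks <- function(blocks, cum, tstart, read_length, marker_pos) {
  i <- findInterval(tstart - 1L, cum) + 1L   # block containing tstart
  off <- tstart - (if (i > 1L) cum[i - 1L] else 0L)  # 1-based offset in block
  gpos <- blocks$start[i] + off - 1L
  start <- gpos
  remaining <- read_length
  cigar <- character(0L)
  covers <- FALSE
  repeat {
    avail <- blocks$end[i] - gpos + 1L
    m <- min(avail, remaining)
    if (!is.na(marker_pos) && marker_pos >= gpos && marker_pos <= gpos + m - 1L)
      covers <- TRUE
    cigar <- c(cigar, paste0(m, "M"))
    remaining <- remaining - m
    if (remaining == 0L) break
    gap <- blocks$start[i + 1L] - blocks$end[i] - 1L
    cigar <- c(cigar, paste0(gap, "N"))
    i <- i + 1L
    gpos <- blocks$start[i]
  }
  list(start = start, cigar = paste(cigar, collapse = ""), covers = covers)
}

#' Simulate spliced alignment records for a scenario
#'
#' Reads are sampled uniformly over spliced transcript positions. Each read's
#' allele of origin follows `allele_balance`; variant-allele reads carry the
#' configured aberrant event with probability `per_allele_event_fraction`;
#' when the aberrant product is frameshift and `nmd_survival < 1`, aberrant
#' reads are removed with probability `1 - nmd_survival` (so the realized
#' depth drops, as decayed transcripts are never sequenced). Gapped segments
#' are encoded as an extended CIGAR (`M`/`N`; a tandem-duplication
#' back-junction appears as a negative `N` length, which [write_sam()] emits
#' as a two-line chimeric alignment).
#'
#' @param config A [scenario_config()].
#' @return Tibble with columns `read_id`, `gene`, `start`, `cigar`, `allele`
#'   (simulated truth: `ref`/`var`), `marker_base` (`ref`/`var` when the read
#'   covers the marker position, `NA` otherwise -- the only allele information
#'   available in real data).
#' @examples
#' cfg <- scenario_config(synthetic_transcript("TOY3"), depth = 200,
#'                        event = "exon_skip", event_params = list(exons = 2),
#'                        seed = 7)
#' reads <- simulate_reads(cfg)
#' @export
simulate_reads <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  model <- config$transcript
  set.seed(config$seed)
  n <- config$depth
  rl <- config$read_length

  nat_len <- sum(model$exon_lengths)
  abr_len <- with(isoform_blocks(model, config$event, config$event_params),
                  sum(end - start + 1L))
  # fragment sampling: a transcript yields reads in proportion to its spliced
  # length, so the probability a read originates from the aberrant isoform is
  # the length-weighted transcript fraction. This keeps junction counts
  # proportional to isoform abundance, the property junction ratios rely on.
  q <- if (config$event == "none") 0
       else config$allele_balance * config$per_allele_event_fraction
  w_a <- abr_len - rl + 1L
  w_n <- nat_len - rl + 1L
  p_read_aberrant <- if (q == 0) 0 else q * w_a / (q * w_a + (1 - q) * w_n)
  aberrant <- stats::runif(n) < p_read_aberrant
  p_var_normal <- if (q >= 1) 0 else
    config$allele_balance * (1 - config$per_allele_event_fraction *
                               (config$event != "none")) / (1 - q)
  allele <- ifelse(aberrant, "var",
                   ifelse(stats::runif(n) < p_var_normal, "var", "ref"))

  if (config$nmd_survival < 1 &&
      event_is_frameshift(model, config$event, config$event_params)) {
    decayed <- aberrant & stats::runif(n) >= config$nmd_survival
    keep <- !decayed
    allele <- allele[keep]; aberrant <- aberrant[keep]
    n <- sum(keep)
  }

  nat_blocks <- isoform_blocks(model, "none")
  abr_blocks <- isoform_blocks(model, config$event, config$event_params)
  nat_cum <- cumsum(nat_blocks$end - nat_blocks$start + 1L)
  abr_cum <- cumsum(abr_blocks$end - abr_blocks$start + 1L)

  marker_gene <- NA_integer_
  if (!is.null(config$marker)) {
    tx <- exon_tx_intervals(model)
    ge <- exon_gene_intervals(model)
    i <- which(config$marker >= tx$tx_start & config$marker <= tx$tx_end)
    marker_gene <- ge$start[i] + (config$marker - tx$tx_start[i])
  }

  tstart <- integer(n)
  nat_max <- nat_cum[length(nat_cum)] - rl + 1L
  abr_max <- abr_cum[length(abr_cum)] - rl + 1L
  tstart[!aberrant] <- sample.int(nat_max, sum(!aberrant), replace = TRUE)
  tstart[aberrant] <- sample.int(abr_max, sum(aberrant), replace = TRUE)

  start <- integer(n); cigar <- character(n); covers <- logical(n)
  for (k in seq_len(n)) {
    r <- if (aberrant[k])
      .read_from_blocks(abr_blocks, abr_cum, tstart[k], rl, marker_gene)
    else
      .read_from_blocks(nat_blocks, nat_cum, tstart[k], rl, marker_gene)
    start[k] <- r$start; cigar[k] <- r$cigar; covers[k] <- r$covers
  }

  tibble::tibble(
    read_id = sprintf("%s_read%06d", model$gene, seq_len(n)),
    gene = model$gene,
    start = start,
    cigar = cigar,
    allele = allele,
    marker_base = ifelse(covers, allele, NA_character_)
  )
}

#' Simulate a tandem exon duplication scenario
#'
#' Convenience wrapper around [simulate_reads()] that insists the scenario is
#' a tandem duplication, whose variant-allele aberrant reads include the
#' chimeric back-junction from the 3' end of the last duplicated exon to the
#' 5' start of the first.
#'
#' @param config A [scenario_config()] with `event = "tandem_duplication"`.
#' @return As [simulate_reads()].
#' @export
simulate_tandem_duplication <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  if (config$event != "tandem_duplication")
    stop("config$event must be 'tandem_duplication'")
  simulate_reads(config)
}

# ---------------------------------------------------------------------------
# Minimal SAM text I/O (M/N/S CIGAR only). Chimeric back-junction reads are
# written as two soft-clipped lines sharing a QNAME (primary + supplementary)
# and re-merged on reading, mirroring how spliced aligners report them.
# ---------------------------------------------------------------------------

# parse an extended CIGAR into a data.frame of (len, op); negative len only
# ever accompanies N in internal records
parse_cigar <- function(cig) {
  toks <- regmatches(cig, gregexpr("-?[0-9]+[MNS]", cig))[[1]]
  if (!length(toks) || nchar(paste(toks, collapse = "")) != nchar(cig))
    stop("malformed CIGAR: ", cig)
  data.frame(len = as.integer(sub("[MNS]$", "", toks)),
             op = sub("^-?[0-9]+", "", toks),
             stringsAsFactors = FALSE)
}

#' Write alignment records as SAM text
#'
#' Emits a minimal SAM file: an `@SQ` header line per gene (reference length =
#' gene-axis length) and one alignment line per colinear read (CIGAR `M`/`N`).
#' Reads spanning a tandem-duplication back-junction (negative internal gap)
#' are split at the back-junction into a primary and a supplementary line with
#' soft clips. The simulated allele and observed marker base travel in the
#' local-use tags `al:Z:` and `mk:Z:`.
#'
#' @param reads Tibble from [simulate_reads()].
#' @param models Named list of [transcript_model()] (or a single model) used
#'   for header lengths.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(reads, models, path) {
  if (inherits(models, "transcript_model")) {
    models <- stats::setNames(list(models), models$gene)
  }
  axis_len <- function(m) sum(m$exon_lengths) + sum(m$intron_lengths)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unknown", con)
  for (m in models)
    writeLines(sprintf("@SQ\tSN:%s\tLN:%d", m$gene, axis_len(m)), con)
  mk <- ifelse(is.na(reads$marker_base), ".", reads$marker_base)
  lines <- character(0L)
  for (k in seq_len(nrow(reads))) {
    ops <- parse_cigar(reads$cigar[k])
    tags <- sprintf("al:Z:%s\tmk:Z:%s", reads$allele[k], mk[k])
    neg <- which(ops$op == "N" & ops$len < 0L)
    if (!length(neg)) {
      lines <- c(lines, sprintf("%s\t0\t%s\t%d\t255\t%s\t*\t0\t0\t*\t*\t%s",
                                reads$read_id[k], reads$gene[k],
                                reads$start[k], reads$cigar[k], tags))
    } else {
      b <- neg[1L]                      # split at the first back-junction
      pre <- ops[seq_len(b - 1L), , drop = FALSE]
      post <- ops[seq.int(b + 1L, nrow(ops)), , drop = FALSE]
      mlen <- function(o) sum(o$len[o$op == "M"])
      cig1 <- paste0(paste0(pre$len, pre$op, collapse = ""), mlen(post), "S")
      cig2 <- paste0(mlen(pre), "S", paste0(post$len, post$op, collapse = ""))
      ref_consumed <- sum(pre$len[pre$op %in% c("M", "N")])
      start2 <- reads$start[k] + ref_consumed + ops$len[b]
      lines <- c(lines,
        sprintf("%s\t0\t%s\t%d\t255\t%s\t*\t0\t0\t*\t*\t%s",
                reads$read_id[k], reads$gene[k], reads$start[k], cig1, tags),
        sprintf("%s\t2048\t%s\t%d\t255\t%s\t*\t0\t0\t*\t*\t%s",
                reads$read_id[k], reads$gene[k], start2, cig2, tags))
    }
  }
  writeLines(lines, con)
  invisible(path)
}

#' Read a SAM text file into alignment records
#'
#' Accepts CIGARs with `M`, `N` and `S` operations (`S` is stripped). Pairs of
#' lines sharing a QNAME where the first ends in a soft clip and the second
#' starts with one (chimeric split alignments) are merged back into a single
#' record with a signed internal gap, recovering back-junctions.
#'
#' @param path SAM file path.
#' @return Tibble with `read_id`, `gene`, `start`, `cigar`, `allele`,
#'   `marker_base`.
#' @export
read_sam <- function(path) {
  ln <- readLines(path)
  ln <- ln[!startsWith(ln, "@")]
  if (!length(ln))
    return(tibble::tibble(read_id = character(), gene = character(),
                          start = integer(), cigar = character(),
                          allele = character(), marker_base = character()))
  f <- strsplit(ln, "\t", fixed = TRUE)
  getf <- function(i) vapply(f, `[[`, "", i)
  qname <- getf(1L); rname <- getf(3L)
  pos <- as.integer(getf(4L)); cig <- getf(6L)
  tag <- function(key) {
    vapply(f, function(x) {
      hit <- grep(paste0("^", key, ":Z:"), x, value = TRUE)
      if (length(hit)) sub(paste0("^", key, ":Z:"), "", hit[1L]) else NA_character_
    }, "")
  }
  allele <- tag("al"); marker <- tag("mk")
  allele[is.na(allele)] <- "unknown"
  marker[!is.na(marker) & marker == "."] <- NA_character_

  strip_s <- function(cg) {
    ops <- parse_cigar(cg)
    ops <- ops[ops$op != "S", , drop = FALSE]
    paste0(ops$len, ops$op, collapse = "")
  }
  ref_span <- function(cg) {
    ops <- parse_cigar(cg)
    sum(ops$len[ops$op %in% c("M", "N")])
  }

  idx_by_read <- split(seq_along(qname), factor(qname, levels = unique(qname)))
  out <- vector("list", length(idx_by_read))
  i <- 0L
  for (q in names(idx_by_read)) {
    idx <- idx_by_read[[q]]
    if (length(idx) == 1L) {
      k <- idx
      rec <- list(read_id = q, gene = rname[k], start = pos[k],
                  cigar = strip_s(cig[k]), allele = allele[k],
                  marker_base = marker[k])
    } else if (length(idx) == 2L) {
      a <- idx[1L]; b <- idx[2L]
      # the part ending in a soft clip is the 5' piece of the chimera
      if (!grepl("S$", cig[a])) { tmp <- a; a <- b; b <- tmp }
      end_a <- pos[a] + ref_span(cig[a]) - 1L
      gap <- pos[b] - end_a - 1L
      rec <- list(read_id = q, gene = rname[a], start = pos[a],
                  cigar = paste0(strip_s(cig[a]), gap, "N", strip_s(cig[b])),
                  allele = allele[a], marker_base = marker[a])
    } else {
      stop("more than two alignment lines for read ", q)
    }
    i <- i + 1L
    out[[i]] <- rec
  }
  dplyr::bind_rows(out)
}
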