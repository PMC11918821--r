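# Independent brute-force oracles used to freeze expected values. These stay
# deliberately naive and separate from the package's own code paths.

# --- ACMG combining: literal rule-pattern enumeration ----------------------
# Each pattern is the minimum multiset of effective strengths that satisfies
# one published combination; a code set qualifies if any pattern is covered.
oracle_acmg_class <- function(codes) {
  if (is.character(codes)) codes <- parse_acmg(codes)
  codes <- codes[codes$strength != "not_applicable", , drop = FALSE]
  n_of <- function(dir, str) sum(codes$direction == dir & codes$strength == str)
  vs <- n_of("pathogenic", "very_strong"); s <- n_of("pathogenic", "strong")
  m <- n_of("pathogenic", "moderate"); p <- n_of("pathogenic", "supporting")
  ba <- n_of("benign", "stand_alone"); bs <- n_of("benign", "strong")
  bp <- n_of("benign", "supporting")
  covered <- function(patterns) {
    any(vapply(patterns, function(q)
      vs >= q[1] && s >= q[2] && m >= q[3] && p >= q[4], TRUE))
  }
  pathogenic_patterns <- list(
    c(1, 1, 0, 0), c(1, 0, 2, 0), c(1, 0, 1, 1), c(1, 0, 0, 2), c(2, 0, 0, 0),
    c(0, 2, 0, 0), c(0, 1, 3, 0), c(0, 1, 2, 2), c(0, 1, 1, 4))
  likely_patterns <- list(
    c(1, 0, 1, 0), c(0, 1, 1, 0), c(0, 1, 0, 2), c(0, 0, 3, 0),
    c(0, 0, 2, 2), c(0, 0, 1, 4))
  if (bs + ba > 0 && vs > 0)
    stop("conflicting evidence")
  is_p <- covered(pathogenic_patterns)
  is_lp <- covered(likely_patterns)
  is_b <- ba >= 1 || bs >= 2
  is_lb <- bs >= 1 || bp >= 2
  if ((is_b || is_lb) && (is_p || is_lp)) return(3L)
  if (is_p) return(5L)
  if (is_b) return(1L)
  if (is_lp) return(4L)
  if (is_lb) return(2L)
  3L
}

# --- reading frame: explicit base bookkeeping ------------------------------
# Number every coding base, delete an interval, and ask whether any surviving
# downstream base changes codon phase. No modular arithmetic shortcuts.
oracle_frame <- function(cds_length, del_start, del_end) {
  bases <- seq_len(cds_length)
  phase_before <- (bases - 1L) %% 3L
  kept <- bases[bases < del_start | bases > del_end]
  phase_after <- (seq_along(kept) - 1L) %% 3L
  downstream <- kept > del_end
  if (!any(downstream)) return("in_frame")  # nothing left to shift
  if (all(phase_after[downstream] == phase_before[match(kept[downstream], bases)]))
    "in_frame" else "frameshift"
}

# --- codon overlap: explicit base->codon assignment ------------------------
oracle_codons <- function(c_start, c_end) {
  length(unique(ceiling(seq(c_start, c_end) / 3)))
}

# --- junction extraction & typing: an independent mini-quantifier ----------
# Parses CIGARs with its own tokenizer, tallies junctions with table(), and
# types each one by exhaustive comparison against every natural junction and
# every exon boundary of the model.
oracle_read_junctions <- function(start, cigar) {
  toks <- regmatches(cigar, gregexpr("-?[0-9]+[MNS]", cigar))[[1]]
  lens <- as.integer(gsub("[MNS]", "", toks))
  ops <- gsub("-?[0-9]+", "", toks)
  pos <- start
  dn <- integer(0); ac <- integer(0)
  for (i in seq_along(ops)) {
    if (ops[i] == "M") pos <- pos + lens[i]
    else if (ops[i] == "N") {
      dn <- c(dn, pos - 1L)
      pos <- pos + lens[i]
      ac <- c(ac, pos)
    }
  }
  if (length(dn)) data.frame(donor = dn, acceptor = ac) else NULL
}

oracle_type_junction <- function(d, a, model) {
  nat <- natural_junctions(model)
  ex <- exon_gene_intervals(model)
  for (i in seq_len(nrow(nat)))
    if (nat$donor[i] == d && nat$acceptor[i] == a) return("natural")
  d_exon <- NA_integer_; a_exon <- NA_integer_
  for (i in seq_len(nrow(ex))) {
    if (ex$end[i] == d) d_exon <- i
    if (ex$start[i] == a) a_exon <- i
  }
  if (!is.na(d_exon) && !is.na(a_exon)) {
    if (a_exon <= d_exon) return("back_junction")
    if (a_exon - d_exon >= 2L) return("exon_skip")
    return("complex")
  }
  if (is.na(d_exon) && !is.na(a_exon)) return("cryptic_donor")
  if (!is.na(d_exon) && is.na(a_exon)) return("cryptic_acceptor")
  "complex"
}

oracle_detect <- function(reads, model, min_reads = 10L, min_fraction = 0.05) {
  js <- do.call(rbind, lapply(seq_len(nrow(reads)), function(k)
    oracle_read_junctions(reads$start[k], reads$cigar[k])))
  if (is.null(js)) return(NULL)
  key <- paste(js$donor, js$acceptor)
  tab <- table(key)
  nat <- natural_junctions(model)
  nat_key <- paste(nat$donor, nat$acceptor)
  nat_count <- as.integer(ifelse(nat_key %in% names(tab), tab[nat_key], 0L))
  out <- NULL
  for (k in names(tab)) {
    if (k %in% nat_key) next
    cnt <- as.integer(tab[[k]])
    if (cnt < min_reads) next
    pr <- as.integer(strsplit(k, " ")[[1]])
    d <- pr[1]; a <- pr[2]
    shared <- c(nat_count[nat$donor == d], nat_count[nat$acceptor == a])
    r <- if (length(shared)) mean(shared) else mean(nat_count)
    rel <- cnt / (cnt + r)
    if (rel < min_fraction) next
    out <- rbind(out, data.frame(donor = d, acceptor = a, count = cnt,
                                 type = oracle_type_junction(d, a, model),
                                 rel = rel))
  }
  if (!is.null(out)) out[order(out$donor, out$acceptor), , drop = FALSE] else NULL
}

# --- misc ------------------------------------------------------------------
# three binomial standard errors around an expected proportion
within_3se <- function(observed, expected, n) {
  se <- sqrt(expected * (1 - expected) / n)
  abs(observed - expected) <= 3 * se + 1e-12
}

random_code_set <- function(max_codes = 6L) {
  pool <- c("PVS1", "PVS1_M", "PVS1_S", "PS3", "PM2", "PM3", "PM5", "PP1",
            "PP3", "PP4", "PP5", "BP4", "BP7", "BP7_S", "BS1", "PM2_P")
  paste(sample(pool, sample.int(max_codes, 1L)), collapse = ", ")
}
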