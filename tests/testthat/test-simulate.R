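test_that("identical seeds give byte-identical read sets", {
  m <- synthetic_transcript("TOY4")
  cfg <- scenario_config(m, depth = 500, event = "exon_skip",
                         event_params = list(exons = 2), marker = 60, seed = 77)
  expect_identical(simulate_reads(cfg), simulate_reads(cfg))
  cfg2 <- scenario_config(m, depth = 500, event = "exon_skip",
                          event_params = list(exons = 2), marker = 60, seed = 78)
  expect_false(identical(simulate_reads(cfg), simulate_reads(cfg2)))
})

test_that("scenario configs reject structurally impossible events", {
  m <- synthetic_transcript("TOY3")
  expect_error(scenario_config(m, event = "exon_skip",
                               event_params = list(exons = 1)), "terminal")
  expect_error(scenario_config(m, event = "exon_skip",
                               event_params = list(exons = 9)), "out of range")
  expect_error(scenario_config(m, event = "cryptic_donor",
                               event_params = list(exon = 2, shift = -95)),
               "swallows")
  expect_error(scenario_config(m, event = "intron_retention",
                               event_params = list(intron = 3)), "out of range")
  expect_error(scenario_config(m, allele_balance = 1.5), "allele_balance")
  expect_error(scenario_config(m, marker = 10^6), "exonic")
})

test_that("event-free simulations produce only natural junctions", {
  m <- synthetic_transcript("MLH1")
  reads <- simulate_reads(scenario_config(m, depth = 1000, event = "none", seed = 7))
  nat <- natural_junctions(m)
  js <- do.call(rbind, lapply(seq_len(nrow(reads)), function(k)
    oracle_read_junctions(reads$start[k], reads$cigar[k])))
  expect_gt(nrow(js), 0L)
  expect_true(all(paste(js$donor, js$acceptor) %in% paste(nat$donor, nat$acceptor)))
})

test_that("every simulated gap matches a junction of the configured isoform", {
  # oracle: regenerate the isoform junction list directly from exon intervals
  m <- synthetic_transcript("TOY4")
  scenarios <- list(
    list(event = "exon_skip", params = list(exons = 2)),
    list(event = "exon_skip", params = list(exons = 2:3)),
    list(event = "partial_exon_skip", params = list(exons = 2, extend_into_next = 4)),
    list(event = "cryptic_donor", params = list(exon = 2, shift = -5)),
    list(event = "cryptic_acceptor", params = list(exon = 3, shift = 7)),
    list(event = "intron_retention", params = list(intron = 1)),
    list(event = "tandem_duplication", params = list(exons = 2:3))
  )
  ex <- exon_gene_intervals(m)
  for (sc in scenarios) {
    blocks <- isoform_blocks(m, sc$event, sc$params)
    iso_junc <- paste(blocks$end[-nrow(blocks)], blocks$start[-1L])
    nat_junc <- paste(ex$end[-nrow(ex)], ex$start[-1L])
    legal <- union(iso_junc, nat_junc)
    cfg <- scenario_config(m, depth = 400, event = sc$event, event_params = sc$params,
                           per_allele_event_fraction = 1, seed = 13)
    reads <- simulate_reads(cfg)
    js <- do.call(rbind, lapply(seq_len(nrow(reads)), function(k)
      oracle_read_junctions(reads$start[k], reads$cigar[k])))
    expect_true(all(paste(js$donor, js$acceptor) %in% legal), info = sc$event)
  }
})

test_that("realized aberrant fraction obeys the law of large numbers", {
  m <- synthetic_transcript("PTEN")
  for (p in c(0.25, 0.42, 1.0)) {
    cfg <- scenario_config(m, depth = 10000, allele_balance = 0.5,
                           event = "exon_skip", event_params = list(exons = 3),
                           per_allele_event_fraction = p, seed = 100 + round(100 * p))
    reads <- simulate_reads(cfg)
    has_skip <- grepl("2145N", reads$cigar, fixed = TRUE)  # gap spanning exon 3
    # reads that span the skip junction vs reads spanning the flanking natural
    # junctions: expectation p/2 among junction-spanning reads at that locus
    jc <- count_junctions(reads, m)
    nat <- natural_junctions(m)
    skip <- jc$counts[!jc$counts$natural, , drop = FALSE]
    expect_equal(nrow(skip), 1L)
    flank <- jc$counts$count[jc$counts$natural &
                               (jc$counts$donor == nat$donor[2] |
                                jc$counts$acceptor == nat$acceptor[3])]
    frac <- skip$count / (skip$count + mean(flank))
    expect_true(within_3se(frac, p / 2, skip$count + mean(flank)),
                info = sprintf("p=%.2f frac=%.3f", p, frac))
    expect_true(any(has_skip) == (p > 0))
  }
})

test_that("tandem duplications yield back-junction reads from the variant allele only", {
  m <- synthetic_transcript("MSH2")
  ex <- exon_gene_intervals(m)
  back_of <- function(reads) {
    js <- do.call(rbind, lapply(seq_len(nrow(reads)), function(k)
      oracle_read_junctions(reads$start[k], reads$cigar[k])))
    js[js$acceptor < js$donor, , drop = FALSE]
  }
  # single-exon repeat: exon 7 end back to exon 7 start
  cfg <- scenario_config(m, depth = 2000, event = "tandem_duplication",
                         event_params = list(exons = 7),
                         per_allele_event_fraction = 1, seed = 5)
  bj <- back_of(simulate_tandem_duplication(cfg))
  expect_gt(nrow(bj), 0L)
  expect_true(all(bj$donor == ex$end[7] & bj$acceptor == ex$start[7]))

  # multi-exon repeat: last duplicated exon back to first
  cfg2 <- scenario_config(m, depth = 2000, event = "tandem_duplication",
                          event_params = list(exons = 4:5),
                          per_allele_event_fraction = 1, seed = 6)
  bj2 <- back_of(simulate_reads(cfg2))
  expect_gt(nrow(bj2), 0L)
  expect_true(all(bj2$donor == ex$end[5] & bj2$acceptor == ex$start[4]))

  # fraction zero: no back-junction reads at all
  cfg0 <- scenario_config(m, depth = 2000, event = "tandem_duplication",
                          event_params = list(exons = 7),
                          per_allele_event_fraction = 0, seed = 5)
  expect_equal(nrow(back_of(simulate_reads(cfg0))), 0L)
})

test_that("NMD removes frameshift aberrant reads at rate 1 - survival", {
  m <- synthetic_transcript("MLH1")  # exon 10 skip is frameshift (94 nt)
  cfg <- scenario_config(m, depth = 20000, event = "exon_skip",
                         event_params = list(exons = 10),
                         per_allele_event_fraction = 1, nmd_survival = 0.3,
                         seed = 17)
  reads <- simulate_reads(cfg)
  # surviving pool: all ref reads plus ~30% of var reads. Reads are sampled
  # in proportion to spliced isoform length, so the expected variant-read
  # fraction carries the length weight of the shorter skipped isoform.
  expect_lt(nrow(reads), 20000L)
  w_a <- (sum(m$exon_lengths) - m$exon_lengths[10]) - 100L + 1L
  w_n <- sum(m$exon_lengths) - 100L + 1L
  p_ab <- 0.5 * w_a / (0.5 * w_a + 0.5 * w_n)
  expected <- p_ab * 0.3 / (p_ab * 0.3 + (1 - p_ab))
  var_frac <- mean(reads$allele == "var")
  expect_true(within_3se(var_frac, expected, nrow(reads)))
  # in-frame events are not NMD substrates: nothing is removed
  m2 <- synthetic_transcript("PTEN")  # exon 3 skip is in-frame (45 nt)
  cfg2 <- scenario_config(m2, depth = 5000, event = "exon_skip",
                          event_params = list(exons = 3),
                          per_allele_event_fraction = 1, nmd_survival = 0.3,
                          seed = 18)
  expect_equal(nrow(simulate_reads(cfg2)), 5000L)
})

test_that("marker bases are observed only on reads overlapping the marker", {
  m <- synthetic_transcript("TOY4")
  cfg <- scenario_config(m, depth = 800, event = "none", marker = 200, seed = 3)
  reads <- simulate_reads(cfg)
  expect_true(any(!is.na(reads$marker_base)))
  expect_true(any(is.na(reads$marker_base)))
  seen <- reads[!is.na(reads$marker_base), ]
  expect_true(all(seen$marker_base == seen$allele))
  # marker position is transcript 200 -> exon 2 (tx 151..246)
  ex <- exon_gene_intervals(m)
  gpos <- ex$start[2] + (200L - 151L)
  covers <- vapply(seq_len(nrow(reads)), function(k) {
    js <- oracle_read_junctions(reads$start[k], reads$cigar[k])
    len <- sum(as.integer(gsub("M", "", regmatches(reads$cigar[k],
      gregexpr("[0-9]+M", reads$cigar[k]))[[1]])))
    pos <- reads$start[k]
    ops <- regmatches(reads$cigar[k], gregexpr("-?[0-9]+[MN]", reads$cigar[k]))[[1]]
    hit <- FALSE
    for (o in ops) {
      l <- as.integer(gsub("[MN]", "", o))
      if (grepl("M$", o)) {
        if (gpos >= pos && gpos <= pos + l - 1L) hit <- TRUE
        pos <- pos + l
      } else pos <- pos + l
    }
    hit
  }, TRUE)
  expect_identical(!is.na(reads$marker_base), covers)
})

test_that("SAM round trip preserves records, including chimeric back-junction reads", {
  m <- synthetic_transcript("MSH2")
  cfg <- scenario_config(m, depth = 300, event = "tandem_duplication",
                         event_params = list(exons = 7),
                         per_allele_event_fraction = 0.6, marker = 500, seed = 21)
  reads <- simulate_reads(cfg)
  sam <- withr::local_tempfile(fileext = ".sam")
  write_sam(reads, m, sam)
  back <- read_sam(sam)
  expect_equal(nrow(back), nrow(reads))
  expect_identical(back$start, reads$start)
  expect_identical(back$cigar, reads$cigar)
  expect_identical(back$allele, reads$allele)
  expect_identical(back$marker_base, reads$marker_base)
})

test_that("emitted SAM agrees with an established alignment parser", {
  skip_if_not_installed("Rsamtools")
  skip_if_not_installed("GenomicAlignments")
  m <- synthetic_transcript("MLH1")
  cfg <- scenario_config(m, depth = 400, event = "exon_skip",
                         event_params = list(exons = 10),
                         per_allele_event_fraction = 0.5, seed = 29)
  reads <- simulate_reads(cfg)
  sam <- withr::local_tempfile(fileext = ".sam")
  write_sam(reads, m, sam)
  bam <- Rsamtools::asBam(sam, withr::local_tempfile(), overwrite = TRUE,
                          indexDestination = FALSE)
  ga <- GenomicAlignments::readGAlignments(bam)
  expect_equal(length(ga), nrow(reads))
  ref_j <- GenomicAlignments::junctions(ga)
  ref_tab <- table(paste(unlist(BiocGenerics::start(ref_j)) - 1L,
                         unlist(BiocGenerics::end(ref_j)) + 1L))
  jc <- count_junctions(reads, m)
  our_tab <- table(rep(paste(jc$counts$donor, jc$counts$acceptor),
                       jc$counts$count))
  expect_setequal(names(ref_tab), names(our_tab))
  nm <- sort(names(ref_tab))
  expect_equal(as.vector(ref_tab[nm]), as.vector(our_tab[nm]))
})
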