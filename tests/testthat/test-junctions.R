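make_reads <- function(gene, starts, cigars) {
  tibble::tibble(read_id = sprintf("r%03d", seq_along(starts)), gene = gene,
                 start = starts, cigar = cigars,
                 allele = "unknown", marker_base = NA_character_)
}

test_that("junction counts conserve the number of gap operations", {
  m <- synthetic_transcript("MLH1")
  cfg <- scenario_config(m, depth = 3000, event = "exon_skip",
                         event_params = list(exons = 10),
                         per_allele_event_fraction = 0.7, seed = 41)
  reads <- simulate_reads(cfg)
  n_gaps <- sum(vapply(reads$cigar, function(cg)
    lengths(regmatches(cg, gregexpr("N", cg))), 1L))
  jc <- count_junctions(reads, m)
  expect_equal(sum(jc$counts$count), n_gaps)
  expect_equal(jc$n_gaps_total, n_gaps)
})

test_that("each gap counts once and multi-gap reads increment every junction", {
  m <- synthetic_transcript("TOY3")  # exons 1-120, 421-510, 911-1030
  reads <- make_reads("TOY3",
    starts = c(rep(100L, 100L), 100L, 50L),
    cigars = c(rep("21M300N79M", 100L),          # natural junction 1
               "21M300N90M400N9M",               # spans junctions 1 and 2
               "71M"))                           # gapless
  jc <- count_junctions(reads, m)
  j1 <- jc$counts$count[jc$counts$donor == 120L & jc$counts$acceptor == 421L]
  j2 <- jc$counts$count[jc$counts$donor == 510L & jc$counts$acceptor == 911L]
  expect_equal(j1, 101L)
  expect_equal(j2, 1L)
  expect_equal(sum(jc$counts$count), 102L)
})

test_that("reads outside the gene axis are skipped with a warning", {
  m <- synthetic_transcript("TOY3")
  reads <- make_reads("TOY3", starts = c(10L, 5000L), cigars = c("50M", "50M"))
  expect_warning(jc <- count_junctions(reads, m), "skipped")
  expect_equal(jc$n_skipped, 1L)
})

test_that("relative expression follows c/(c+r) with site-sharing reference counts", {
  m <- synthetic_transcript("TOY4")
  ex <- exon_gene_intervals(m)
  nat <- natural_junctions(m)
  # hand-built matrix: 500 reads on each natural junction flanking exon 2,
  # 500 on the exon-2 skip junction -> equal depths, ratio 0.5
  skip_cigar <- sprintf("10M%dN10M", ex$start[3] - ex$end[1] - 1L)
  j1_cigar <- sprintf("10M%dN10M", ex$start[2] - ex$end[1] - 1L)
  j2_cigar <- sprintf("10M%dN10M", ex$start[3] - ex$end[2] - 1L)
  reads <- make_reads("TOY4",
    starts = rep(c(ex$end[1] - 9L, ex$end[1] - 9L, ex$end[2] - 9L), c(500, 500, 500)),
    cigars = rep(c(skip_cigar, j1_cigar, j2_cigar), c(500, 500, 500)))
  jc <- count_junctions(reads, m)
  expect_equal(relative_expression(jc, m, ex$end[1], ex$start[3]), 0.5)
  # unobserved junction at shared sites -> 0
  expect_equal(relative_expression(jc, m, ex$end[1], ex$start[4]), 0)
  # 210 aberrant vs 790 natural at both shared sites -> 0.21
  reads2 <- make_reads("TOY4",
    starts = rep(c(ex$end[1] - 9L, ex$end[1] - 9L, ex$end[2] - 9L), c(210, 790, 790)),
    cigars = rep(c(skip_cigar, j1_cigar, j2_cigar), c(210, 790, 790)))
  jc2 <- count_junctions(reads2, m)
  expect_equal(relative_expression(jc2, m, ex$end[1], ex$start[3]), 0.21)
  # natural junction against the mean of the other natural junctions
  expect_equal(relative_expression(jc2, m, ex$end[1], ex$start[2]),
               790 / (790 + (790 + 0) / 2))
  # no coverage anywhere -> NA
  empty <- count_junctions(make_reads("TOY4", 1L, "50M"), m)
  expect_true(is.na(relative_expression(empty, m, ex$end[1], ex$start[3])))
})

test_that("no events are called on event-free simulations at default thresholds", {
  for (seed in c(1L, 99L, 4242L)) {
    for (gene in c("PTEN", "MLH1")) {
      m <- synthetic_transcript(gene)
      reads <- simulate_reads(scenario_config(m, depth = 20000, event = "none",
                                              seed = seed))
      expect_equal(nrow(detect_events(count_junctions(reads, m), m)), 0L,
                   info = sprintf("%s seed %d", gene, seed))
    }
  }
})

test_that("called relative expression recovers the simulated skip fraction", {
  m <- synthetic_transcript("MLH1")
  for (f in c(0.1, 0.25, 0.5)) {
    cfg <- scenario_config(m, depth = 10000, allele_balance = 0.5,
                           event = "exon_skip", event_params = list(exons = 10),
                           per_allele_event_fraction = 2 * f,
                           seed = 1000L + round(100 * f))
    jc <- count_junctions(simulate_reads(cfg), m)
    ev <- detect_events(jc, m)
    skip <- ev[ev$event_type == "exon_skip", ]
    expect_equal(nrow(skip), 1L)
    n_inf <- skip$supporting_reads / skip$relative_expression
    expect_true(within_3se(skip$relative_expression, f, n_inf),
                info = sprintf("f=%.2f got %.3f", f, skip$relative_expression))
  }
})

test_that("event typing matches the generating scenario across event types", {
  m <- synthetic_transcript("MLH1")
  cases <- list(
    list(event = "exon_skip", params = list(exons = 10), type = "exon_skip",
         exons = "10", rna = "r.791_884del"),
    list(event = "exon_skip", params = list(exons = 7:8), type = "exon_skip",
         exons = "7-8", rna = "r.547_720del"),
    list(event = "cryptic_donor", params = list(exon = 3, shift = -5),
         type = "cryptic_donor", exons = "3", rna = "r.302_306del"),
    list(event = "cryptic_acceptor", params = list(exon = 10, shift = 3),
         type = "cryptic_acceptor", exons = "10", rna = "r.791_793del")
  )
  for (cs in cases) {
    cfg <- scenario_config(m, depth = 4000, event = cs$event,
                           event_params = cs$params,
                           per_allele_event_fraction = 1, seed = 55)
    ev <- detect_events(count_junctions(simulate_reads(cfg), m), m)
    expect_equal(nrow(ev), 1L, info = cs$event)
    expect_equal(ev$event_type, cs$type)
    expect_equal(ev$exons_affected, cs$exons)
    expect_equal(ev$rna_change, cs$rna)
  }
})

test_that("skipping exon 12 of the BRCA2-like model implies r.6842_6937del", {
  m <- synthetic_transcript("BRCA2")
  cfg <- scenario_config(m, depth = 4000, event = "exon_skip",
                         event_params = list(exons = 12),
                         per_allele_event_fraction = 1, seed = 61)
  ev <- detect_events(count_junctions(simulate_reads(cfg), m), m)
  expect_equal(ev$rna_change, "r.6842_6937del")
  expect_equal(frame_effect(parse_hgvs_r(ev$rna_change)), "in_frame")
})

test_that("intron retention is called from unspliced boundary coverage", {
  m <- synthetic_transcript("MLH1")
  cfg <- scenario_config(m, depth = 8000, event = "intron_retention",
                         event_params = list(intron = 4),
                         per_allele_event_fraction = 1, seed = 71)
  jc <- count_junctions(simulate_reads(cfg), m)
  ev <- detect_events(jc, m)
  ir <- ev[ev$event_type == "intron_retention", ]
  expect_equal(nrow(ir), 1L)
  expect_equal(ir$exons_affected, "4-5")
  expect_equal(ir$rna_change, "r.?")
  # with full penetrance on half the transcripts, roughly half the boundary
  # traffic is unspliced; quantification is boundary/(boundary + natural)
  expect_gt(ir$relative_expression, 0.3)
  nat <- natural_junctions(m)
  nat_count <- jc$counts$count[jc$counts$natural &
                                 jc$counts$donor == nat$donor[4]]
  expect_equal(ir$relative_expression,
               ir$supporting_reads / (ir$supporting_reads + nat_count))
})

test_that("back-junctions are typed for arbitrary duplicated exon ranges", {
  m <- synthetic_transcript("MSH2")
  ex <- exon_gene_intervals(m)
  for (rng in list(7L, 4:5, 2:6)) {
    cfg <- scenario_config(m, depth = 4000, event = "tandem_duplication",
                           event_params = list(exons = rng),
                           per_allele_event_fraction = 1,
                           seed = 300L + max(rng))
    ev <- detect_events(count_junctions(simulate_reads(cfg), m), m)
    bj <- ev[ev$event_type == "back_junction", ]
    expect_equal(nrow(bj), 1L, info = paste(rng, collapse = "-"))
    expect_equal(bj$donor, ex$end[max(rng)])
    expect_equal(bj$acceptor, ex$start[min(rng)])
    expect_equal(bj$rna_change, "r.?")
  }
})

test_that("detect_events matches the brute-force enumerator on small models", {
  for (gene in c("TOY3", "TOY4")) {
    m <- synthetic_transcript(gene)
    scenarios <- list(
      list(event = "none", params = list()),
      list(event = "exon_skip", params = list(exons = 2)),
      list(event = "cryptic_donor", params = list(exon = 1, shift = -7)),
      list(event = "cryptic_acceptor", params = list(exon = 2, shift = 6)),
      list(event = "tandem_duplication", params = list(exons = 2))
    )
    for (i in seq_along(scenarios)) {
      sc <- scenarios[[i]]
      cfg <- scenario_config(m, depth = 200, event = sc$event,
                             event_params = sc$params,
                             per_allele_event_fraction = 0.8,
                             seed = 500L + i)
      reads <- simulate_reads(cfg)
      got <- detect_events(count_junctions(reads, m), m)
      want <- oracle_detect(reads, m)
      if (is.null(want)) {
        expect_equal(nrow(got[got$event_type != "intron_retention", ]), 0L,
                     info = paste(gene, sc$event))
      } else {
        got_j <- got[got$event_type != "intron_retention", ]
        got_j <- got_j[order(got_j$donor, got_j$acceptor), ]
        expect_equal(nrow(got_j), nrow(want), info = paste(gene, sc$event))
        expect_equal(got_j$donor, want$donor)
        expect_equal(got_j$acceptor, want$acceptor)
        expect_equal(got_j$supporting_reads, want$count)
        expect_equal(got_j$event_type, want$type)
        expect_equal(got_j$relative_expression, want$rel)
      }
    }
  }
})

test_that("event calls export to TSV and junction matrices round-trip through TSV", {
  m <- synthetic_transcript("PTEN")
  cfg <- scenario_config(m, depth = 2000, event = "exon_skip",
                         event_params = list(exons = 3),
                         per_allele_event_fraction = 1, seed = 81)
  jc <- count_junctions(simulate_reads(cfg), m)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  export_junctions(jc, m, tsv)
  back <- utils::read.delim(tsv)
  expect_equal(nrow(back), nrow(jc$counts))
  expect_true(all(back$relative_expression >= 0 & back$relative_expression <= 1))
  ev <- detect_events(jc, m)
  out <- withr::local_tempfile(fileext = ".tsv")
  write_event_calls(ev, out)
  expect_equal(utils::read.delim(out)$event_type, ev$event_type)
})
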