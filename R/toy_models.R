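#' Synthetic transcript models emulating panel genes
#'
#' These models are *synthetic*: exon boundaries are chosen so that the splice
#' events of interest fall at the documented transcript coordinates (e.g. a
#' PTEN-like exon 3 spanning r.165..209), while intron lengths and the
#' remaining exons are invented. They are the fixed study conditions for the
#' simulator; none of their sequence content is real.
#'
#' Available models:
#' * `PTEN`-like: 5 exons; exon 3 = r.165..209 (45 nt, in-frame when skipped).
#' * `MLH1`-like: 11 exons; exon 3 ends r.306, exon 10 = r.791..884 (94 nt,
#'   frameshift when skipped).
#' * `BRCA2`-like: 13 exons; exon 3 = r.68..316 (249 nt, in-frame) and exon 12
#'   = r.6842..6937 (96 nt, in-frame).
#' * `MSH2`-like: 9 exons; exon 7 = r.1077..1276 (200 nt, frameshift when
#'   duplicated in tandem).
#' * `TOY3`/`TOY4`: small 3- and 4-exon models for enumeration oracles.
#'
#' @param gene One of `"PTEN"`, `"MLH1"`, `"BRCA2"`, `"MSH2"`, `"TOY3"`,
#'   `"TOY4"`.
#' @return A [transcript_model()].
#' @examples
#' m <- synthetic_transcript("PTEN")
#' exon_tx_intervals(m)
#' @export
synthetic_transcript <- function(gene = c("PTEN", "MLH1", "BRCA2", "MSH2",
                                          "TOY3", "TOY4")) {
  gene <- match.arg(gene)
  switch(gene,
    PTEN = transcript_model(
      "PTEN", exon_lengths = c(79L, 85L, 45L, 169L, 225L),
      intron_lengths = c(1000L, 1200L, 900L, 1100L),
      cds_start_offset = 0L, cds_length = 603L,
      transcript_id = "SYN_PTEN.1"),
    MLH1 = transcript_model(
      "MLH1",
      exon_lengths = c(116L, 90L, 100L, 74L, 74L, 92L, 100L, 74L, 70L, 94L, 151L),
      intron_lengths = c(800L, 600L, 700L, 500L, 900L, 650L, 750L, 550L, 850L, 950L),
      cds_start_offset = 0L, cds_length = 1035L,
      transcript_id = "SYN_MLH1.1"),
    BRCA2 = transcript_model(
      "BRCA2",
      exon_lengths = c(30L, 37L, 249L, 820L, 810L, 800L, 815L, 830L, 810L,
                       825L, 815L, 96L, 152L),
      intron_lengths = c(400L, 600L, 900L, 700L, 800L, 500L, 650L, 750L,
                         550L, 850L, 950L, 450L),
      cds_start_offset = 0L, cds_length = 7089L,
      transcript_id = "SYN_BRCA2.1"),
    MSH2 = transcript_model(
      "MSH2",
      exon_lengths = c(180L, 180L, 180L, 180L, 180L, 176L, 200L, 170L, 159L),
      intron_lengths = c(700L, 500L, 900L, 600L, 800L, 550L, 750L, 650L),
      cds_start_offset = 0L, cds_length = 1605L,
      transcript_id = "SYN_MSH2.1"),
    TOY3 = transcript_model(
      "TOY3", exon_lengths = c(120L, 90L, 120L), intron_lengths = c(300L, 400L),
      cds_start_offset = 0L, cds_length = 330L, transcript_id = "SYN_TOY3.1"),
    TOY4 = transcript_model(
      "TOY4", exon_lengths = c(150L, 96L, 120L, 150L),
      intron_lengths = c(350L, 450L, 250L),
      cds_start_offset = 0L, cds_length = 516L, transcript_id = "SYN_TOY4.1")
  )
}
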