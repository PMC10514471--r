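test_that("printed locus strings parse to spans matching the printed checks", {
  del <- parse_printed_interval("chr 6: 87,060,757-87,060,829")
  expect_equal(interval_length(del), 72)
  expect_equal(del$seq_name, "chr6")

  mg <- parse_printed_interval("chr2: 69,581,290-69,581,564")
  expect_equal(interval_length(mg), 120 + 54 + 100)

  bare <- parse_printed_interval("69,581,290 to 69,581,564")
  expect_equal(interval_length(bare), 274)
  expect_true(is.na(bare$seq_name))

  expect_equal(interval_length(parse_printed_interval("chrX: 100-100")), 0)

  expect_error(parse_printed_interval("chr1: 100-abc"), "token")
  expect_error(parse_printed_interval("chr1: 200-100"), "end before start")
})

test_that("format/parse round-trips interval spans exactly", {
  set.seed(101)
  for (i in 1:50) {
    a <- sample(0:1e7, 1); b <- a + sample(0:1e5, 1)
    iv <- genome_interval(paste0("chr", sample(1:22, 1)), a, b)
    back <- parse_printed_interval(format(iv))
    expect_identical(back$start, iv$start)
    expect_identical(back$end, iv$end)
    expect_identical(interval_length(back), interval_length(iv))
  }
})

test_that("exon length converts to peptide length with frame bookkeeping", {
  expect_equal(exon_peptide_length(54), list(aa = 18, frame_preserving = TRUE))
  expect_equal(exon_peptide_length(48), list(aa = 16, frame_preserving = TRUE))
  expect_equal(exon_peptide_length(0), list(aa = 0, frame_preserving = TRUE))
  expect_equal(exon_peptide_length(55), list(aa = 18, frame_preserving = FALSE))
  for (k in 0:100) expect_equal(exon_peptide_length(3 * k)$aa, k)
  expect_error(exon_peptide_length(-3), "non-negative")
})

test_that("cassette model enforces exon order and intron lengths", {
  expect_error(cassette_exon_model("s", "+", c(0, 10), c(5, 20), c(30, 40)),
               "out of order")
  expect_error(cassette_exon_model("s", "+", c(0, 10), c(10, 20), c(30, 40)),
               "introns")
  m <- cassette_exon_model("s", "-", c(80, 90), c(40, 60), c(0, 20))
  ii <- model_introns(m)
  expect_equal(c(ii$upstream_intron$start, ii$upstream_intron$end), c(60, 80))
  expect_equal(c(ii$downstream_intron$start, ii$downstream_intron$end),
               c(20, 40))
  expect_equal(c(ii$skip_intron$start, ii$skip_intron$end), c(20, 80))
})

test_that("donor context extraction reads the 9-mer off the sense strand", {
  fx <- donor_fixture()
  ctx <- five_prime_ss_context(fx$model, fx$sequence)
  expect_equal(ctx$nine_mer, "GAGGTGGGA")
  expect_equal(ctx$exon_part, "GAG")
  expect_equal(ctx$intron_part, "GTGGGA")

  # toy read-off: exon ending TTT, intron starting GTAAGT
  m <- cassette_exon_model("s", "+", c(0, 10), c(20, 30), c(40, 50))
  sq <- strrep("A", 50)
  substr(sq, 28, 36) <- "TTTGTAAGT"
  expect_equal(five_prime_ss_context(m, sq)$nine_mer, "TTTGTAAGT")

  short_exon <- cassette_exon_model("s", "+", c(0, 5), c(10, 12), c(30, 40))
  expect_error(five_prime_ss_context(short_exon, strrep("A", 40)),
               "shorter than 3")
  expect_error(five_prime_ss_context(m, strrep("A", 33)), "past")
})

test_that("donor context is invariant under reverse-complement + strand flip", {
  revcomp <- function(s) {
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  }
  set.seed(77)
  for (i in 1:100) {
    m <- random_cassette_model()
    L <- m$downstream_exon$end + sample(0:20, 1)
    sq <- random_dna(L)
    ctx_plus <- five_prime_ss_context(m, sq)
    # same gene encoded on the minus strand of the reverse-complemented seq
    flip <- function(iv) c(L - iv$end, L - iv$start)
    m_minus <- cassette_exon_model(m$seq_name, "-",
                                   flip(m$upstream_exon),
                                   flip(m$cassette_exon),
                                   flip(m$downstream_exon))
    ctx_minus <- five_prime_ss_context(m_minus, revcomp(sq))
    expect_identical(ctx_minus$nine_mer, ctx_plus$nine_mer)
  }
})

test_that("cassette models read from BED12 and TSV dialects", {
  bed <- paste(c("chrT", 100, 600, "toy", 0, "+", 100, 600, "0",
                 3, "100,54,100,", "0,200,400,"), collapse = "\t")
  f <- write_lines_tmp(bed, ".bed")
  m <- read_cassette_model(f)
  expect_equal(c(m$cassette_exon$start, m$cassette_exon$end), c(300, 354))
  expect_equal(m$upstream_exon$start, 100)

  tsv <- c("role\tseq_name\tstart\tend\tstrand",
           "upstream\tchrT\t100\t200\t+",
           "cassette\tchrT\t300\t354\t+",
           "downstream\tchrT\t500\t600\t+")
  m2 <- read_cassette_model(write_lines_tmp(tsv, ".tsv"))
  expect_equal(model_introns(m2)$skip_intron$end, 500)

  # minus-strand BED12: blocks in genomic order, transcript order flips
  bed_m <- paste(c("chrT", 100, 600, "toy", 0, "-", 100, 600, "0",
                   3, "100,54,100,", "0,200,400,"), collapse = "\t")
  m3 <- read_cassette_model(write_lines_tmp(bed_m, ".bed"))
  expect_equal(m3$upstream_exon$start, 500)
  expect_equal(m3$downstream_exon$end, 200)
})

test_that("RNA input is normalized to DNA and bad letters are rejected", {
  expect_equal(normalize_dna("ugcaug"), "TGCATG")
  expect_error(normalize_dna("ACGX"), "invalid nucleotide")
})
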