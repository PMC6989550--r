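test_that("primer matching honours IUPAC sets, the mismatch budget and the 3' rule", {
  m <- match_primer("GTGCCAGCAGCCGCGGTAA", "GTGYCAGCMGCCGCGGTAA")
  expect_equal(m$mismatches, 0L)
  expect_null(match_primer("ACGA", "ACGT"))       # 3' T vs A: not allowed
  m <- match_primer("ACGT", "ACGG")               # 3' G vs T wobble
  expect_equal(m$mismatches, 1L)
  expect_equal(match_primer("ACGG", "ACGT")$mismatches, 1L)  # T vs G wobble
  expect_null(match_primer("ATTA", "AAAA"))       # two internal mismatches
  # the wobble still consumes the single-mismatch budget
  expect_null(match_primer("AGGT", "ACGG"))
  expect_error(iupac_primer("ACGTX"), "IUPAC")
})

make_demux_input <- function() {
  set.seed(11)
  mapping <- data.frame(sample_id = c("a", "b"),
                        forward_barcode = c("AAAA", "CCCC"),
                        reverse_barcode = c("AAAA", "CCCC"),
                        stringsAsFactors = FALSE)
  primer_f <- "ACGT"
  primer_r <- "TTGA"
  tpl_f <- vapply(1:3, function(i) rand_dna(80), "")
  tpl_r <- vapply(1:3, function(i) rand_dna(80), "")
  idx <- rep(1:3, times = c(4, 3, 3))
  bc <- rep(c("AAAA", "CCCC"), length.out = 10)
  list(mapping = mapping, primer_f = primer_f, primer_r = primer_r,
       forward = paste0(bc, primer_f, tpl_f[idx]),
       reverse = paste0(bc, primer_r, tpl_r[idx]))
}

test_that("clean pairs are assigned, trimmed to exact length, and conserved", {
  inp <- make_demux_input()
  dm <- demultiplex(inp$forward, inp$reverse, inp$mapping,
                    inp$primer_f, inp$primer_r,
                    for_read_len = 70, rev_read_len = 60)
  expect_equal(sum(vapply(dm$samples, nrow, 0L)), 10L)
  expect_equal(sum(dm$discarded$count), 0L)
  for (s in dm$samples) {
    expect_true(all(nchar(s$forward) == 70))
    expect_true(all(nchar(s$reverse) == 60))
  }
  # conservation with bad reads mixed in
  fwd <- c(inp$forward, "GGGGACGTAAAA", paste0("AAAA", "AGGA", rand_dna(80)))
  rev <- c(inp$reverse, paste0("AAAA", inp$primer_r, rand_dna(80)),
           paste0("AAAA", inp$primer_r, rand_dna(80)))
  dm2 <- demultiplex(fwd, rev, inp$mapping, inp$primer_f, inp$primer_r,
                     for_read_len = 70, rev_read_len = 60)
  expect_equal(sum(vapply(dm2$samples, nrow, 0L)) + sum(dm2$discarded$count),
               12L)
  expect_setequal(dm2$discarded$reason, c("barcode", "primer"))
})

test_that("too-short reads are discarded with reason length", {
  mapping <- data.frame(sample_id = "a", forward_barcode = "AAAA",
                        reverse_barcode = NA_character_,
                        stringsAsFactors = FALSE)
  fwd <- paste0("AAAA", "ACGT", rand_dna(30))
  rev <- paste0("TTGA", rand_dna(30))
  expect_warning(
    dm <- demultiplex(fwd, rev, mapping, "ACGT", "TTGA",
                      for_read_len = 50, rev_read_len = 20),
    "zero surviving reads")
  expect_equal(dm$discarded$reason, "length")
  expect_equal(nrow(dm$samples$a), 0L)  # empty sample retained
})

test_that("demultiplexing already-trimmed output is the identity", {
  inp <- make_demux_input()
  dm <- demultiplex(inp$forward, inp$reverse, inp$mapping,
                    inp$primer_f, inp$primer_r,
                    for_read_len = 70, rev_read_len = 60)
  one <- dm$samples$a
  mapping1 <- data.frame(sample_id = "a", forward_barcode = "AAAA",
                         reverse_barcode = NA_character_,
                         stringsAsFactors = FALSE)
  dm2 <- demultiplex(one$forward, one$reverse, mapping1,
                     inp$primer_f, inp$primer_r, primer_removed = TRUE,
                     for_read_len = 70, rev_read_len = 60,
                     demultiplexed = TRUE)
  expect_equal(dm2$samples$a$forward, one$forward)
  expect_equal(dm2$samples$a$reverse, one$reverse)
  expect_equal(sum(dm2$discarded$count), 0L)
})

test_that("single/merged-read mode drops the reverse side", {
  mapping <- data.frame(sample_id = "a", forward_barcode = "AAAA",
                        reverse_barcode = NA_character_,
                        stringsAsFactors = FALSE)
  fwd <- paste0("AAAA", "ACGT", vapply(1:5, function(i) rand_dna(90), ""))
  dm <- demultiplex(fwd, NULL, mapping, "ACGT",
                    for_read_len = 80, rev_read_len = NULL)
  expect_equal(nrow(dm$samples$a), 5L)
  expect_true(all(is.na(dm$samples$a$reverse)))
})

test_that("duplicate barcodes and bad mapping files are rejected", {
  mapping <- data.frame(sample_id = c("a", "b"),
                        forward_barcode = c("AAAA", "AAAA"),
                        reverse_barcode = NA_character_,
                        stringsAsFactors = FALSE)
  expect_error(demultiplex("AAAAACGT", NULL, mapping, "ACGT",
                           for_read_len = 4, rev_read_len = NULL),
               "duplicate barcodes")
  tf <- withr::local_tempfile(lines = c("SampleID\tBarcodeSequence",
                                        "a\tAAAA"))
  expect_error(read_mapping_file(tf), "#SampleID")
  tf2 <- withr::local_tempfile(lines = c(
    "#SampleID\tBarcodeSequence\tTreatment",
    "a\tACGT\tx", "b\tGGTT\ty"))
  m <- read_mapping_file(tf2)
  expect_equal(m$sample_id, c("a", "b"))
  expect_equal(m$Treatment, c("x", "y"))
})
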