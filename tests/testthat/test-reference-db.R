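FP <- "ACGTACGT"
RP <- "TTGACCAA"  # given 5'->3' on the opposite strand

# Build reference sequences with known primer sites: pad5 + FP + region
# + revcomp(RP) + pad3.
make_ref_seq <- function(region, pad5 = 12, pad3 = 15) {
  paste0(rand_dna(pad5), FP, region, reverse_complement(RP), rand_dna(pad3))
}

ref_df <- function(seqs, lineages, acc = sprintf("R%02d", seq_along(seqs))) {
  data.frame(accession = acc, sequence = seqs, lineage = lineages,
             stringsAsFactors = FALSE)
}

test_that("consensus primer columns: unanimous, early consensus, gapped rows", {
  set.seed(21)
  region <- rand_dna(40)
  rows <- ref_df(rep(paste0("AAA", FP, region, reverse_complement(RP), "CC"),
                     5),
                 rep("Bacteria;P;C;O;F;G", 5))
  cols <- find_consensus_primer_columns(rows, FP, RP)
  expect_equal(cols, c(4L, 11L, 52L, 59L))
  # consensus reached before discordant trailing rows are read
  good <- paste0("AAA", FP, region, reverse_complement(RP), "CC")
  shifted <- paste0("AAAAAAA", FP, region, reverse_complement(RP), "CC")
  rows2 <- ref_df(c(rep(good, 6), shifted),
                  rep("Bacteria;P;C;O;F;G", 7))
  pad <- max(nchar(rows2$sequence)) - nchar(rows2$sequence)
  rows2$sequence <- paste0(rows2$sequence, strrep("A", pad))
  expect_equal(find_consensus_primer_columns(rows2, FP, RP,
                                             consensus_count = 5)[1:2],
               c(4L, 11L))
  # gap columns shift the alignment coordinates but not the located site
  gapped <- ref_df(rep(paste0("AA--A", FP, region, reverse_complement(RP),
                              "C.C"), 3),
                   rep("Bacteria;P;C;O;F;G", 3))
  expect_equal(find_consensus_primer_columns(gapped, FP, RP),
               c(6L, 13L, 54L, 61L))
  expect_error(
    find_consensus_primer_columns(
      ref_df("AAAATTTTCCCC", "Bacteria;P"), FP, RP),
    "primer")
})

test_that("alignment lookup trims, reverse-complements and collapses correctly", {
  set.seed(22)
  region <- rand_dna(30)
  lin1 <- "Bacteria;P1;C1;O1;F1;G1"
  lin2 <- "Bacteria;P2;C2;O2;F2;G2"
  seqs <- rep(paste0("AAAA", FP, region, reverse_complement(RP), "GG"), 3)
  tab <- build_lookup_from_alignment(ref_df(seqs, c(lin1, lin1, lin2)),
                                     FP, RP, 12, 10)
  # same sequence, same lineage collapses; different lineage does not
  expect_equal(nrow(tab), 2L)
  expect_equal(sort(tab$count), c(1L, 2L))
  expect_equal(sum(tab$count), 3L)
  expect_true(all(nchar(tab$forward) == 12))
  expect_true(all(nchar(tab$reverse) == 10))
  expect_equal(unique(tab$forward), substr(region, 1, 12))
  expect_equal(unique(tab$reverse),
               reverse_complement(substr(region, 21, 30)))
})

test_that("unaligned lookup accepts one primer mismatch but not two", {
  set.seed(23)
  region <- rand_dna(30)
  lin <- "Bacteria;P;C;O;F;G"
  clean <- make_ref_seq(region)
  # one internal mismatch in the forward primer site
  fp1 <- paste0(substr(FP, 1, 2),
                setdiff(c("A", "C", "G", "T"), substr(FP, 3, 3))[1],
                substr(FP, 4, 8))
  one_mm <- paste0(rand_dna(10), fp1, region, reverse_complement(RP),
                   rand_dna(10))
  fp2 <- paste0(setdiff(c("A", "C", "G", "T"), substr(FP, 1, 1))[1],
                substr(fp1, 2, 8))
  two_mm <- paste0(rand_dna(10), fp2, region, reverse_complement(RP),
                   rand_dna(10))
  tab <- build_lookup_from_unaligned(
    ref_df(c(clean, one_mm, two_mm), rep(lin, 3)), FP, RP, 12, 10)
  expect_equal(sum(tab$count), 2L)          # two_mm skipped
  expect_equal(attr(tab, "skipped"), 1L)
  expect_equal(tab$forward[[1]], substr(region, 1, 12))
})

test_that("alignment-mode and unaligned-mode lookups agree on the same references", {
  spec <- mock_spec(n_taxa = 6, seed = 31)
  dir <- withr::local_tempdir()
  generate_references(spec, dir = dir)
  ug <- read_reference_fasta(file.path(dir, "refs_unaligned.fasta"))
  al <- read_reference_fasta(file.path(dir, "refs_aligned.fasta"))
  t1 <- build_lookup_from_unaligned(ug, spec$forward_primer,
                                    spec$reverse_primer, 70, 70)
  t2 <- build_lookup_from_alignment(al, spec$forward_primer,
                                    spec$reverse_primer, 70, 70)
  expect_equal(as.data.frame(t1), as.data.frame(t2),
               ignore_attr = TRUE)
  expect_equal(sum(t1$count), spec$n_taxa)
})

test_that("lookup cache hits on identical keys and rebuilds on any change", {
  spec <- mock_spec(n_taxa = 4, seed = 32)
  dir <- withr::local_tempdir()
  generate_references(spec, dir = dir)
  src <- file.path(dir, "refs_unaligned.fasta")
  cache <- file.path(dir, "cache")
  t1 <- load_or_build_lookup(cache, src, spec$forward_primer,
                             spec$reverse_primer, 70, 70)
  files1 <- list.files(cache)
  expect_length(files1, 1L)
  # cache hit: byte-identical reread, no new file
  t2 <- load_or_build_lookup(cache, src, spec$forward_primer,
                             spec$reverse_primer, 70, 70)
  expect_equal(as.data.frame(t1), as.data.frame(t2))
  expect_equal(list.files(cache), files1)
  # parameter change -> new cache entry
  load_or_build_lookup(cache, src, spec$forward_primer,
                       spec$reverse_primer, 60, 70)
  expect_length(list.files(cache), 2L)
  # corrupt cache file -> rebuild with warning
  writeLines("garbage", file.path(cache, files1))
  expect_warning(
    t4 <- load_or_build_lookup(cache, src, spec$forward_primer,
                               spec$reverse_primer, 70, 70),
    "rebuild")
  expect_equal(as.data.frame(t4), as.data.frame(t1))
  # content change under the same filename -> digest miss, new entry
  txt <- readLines(src)
  writeLines(c(txt, ">EXTRA Bacteria;P;C;O;F;G", txt[[2]]), src)
  t3 <- load_or_build_lookup(cache, src, spec$forward_primer,
                             spec$reverse_primer, 70, 70)
  expect_length(list.files(cache), 3L)
  expect_equal(sum(t3$count), sum(t1$count) + 1L)
})

test_that("lookup TSV round-trips through write_lookup/read_lookup", {
  tab <- make_lookup(c("ACGTACGTAC", "TTTTACGTAC"), c("GGGGGTTTTA", "GGGGGTTTTA"),
                     c("Bacteria;P;C;O;F;G1", "Bacteria;P;C;O;F;G2"),
                     c(3L, 1L))
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_lookup(tab, tf)
  back <- read_lookup(tf)
  expect_equal(as.data.frame(back), as.data.frame(tab))
})
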