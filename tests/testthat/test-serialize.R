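test_that("the graph links every ASV to its sample and class by status", {
  run <- run_small_mock(seed = 2, n_taxa = 4, reads = 200)
  g <- run$res$graph
  expect_s3_class(g, "library_graph")
  expect_equal(g$library_id, "testlib")
  s <- g$samples[[1]]
  expect_equal(nrow(s$asvs), 4L)
  expect_true(all(s$asvs$status == "accepted"))
  f <- file.path(run$dir, "g.ttl")
  export_rdf(g, f)
  lines <- readLines(f)
  expect_equal(sum(grepl("a ag:Library \\.$", lines)), 1L)
  expect_equal(sum(grepl("a ag:Sample \\.$", lines)), 1L)
  expect_equal(sum(grepl("a ag:ASVSet \\.$", lines)), 4L)
  expect_equal(sum(grepl("a ag:PCRPrimerSet \\.$", lines)), 1L)
})

test_that("Turtle round-trip is lossless and parseable by an external RDF stack", {
  run <- run_small_mock(seed = 3, n_taxa = 3, reads = 150,
                        sample_ids = c("s1", "s2"))
  g <- run$res$graph
  f <- file.path(run$dir, "roundtrip.ttl")
  export_rdf(g, f)
  expect_equal(read_rdf(f), g)
  # independent conformance check: python rdflib must parse the file
  py <- Sys.which("python")
  if (nzchar(py)) {
    out <- system2(py, c("-c", shQuote(sprintf(
      "import rdflib; g = rdflib.Graph(); g.parse('%s', format='turtle'); print(len(g))",
      f))), stdout = TRUE, stderr = TRUE)
    expect_gt(as.integer(out[[length(out)]]), 0)
  }
})

test_that("chimeric ASVs are typed RejectedAsChimera, not ASVSet", {
  asvs <- make_asvs(c("AAAA", "GGGG", "AAAA"),
                    c("CCCC", "TTTT", "TTTT"), c(25, 30, 10),
                    status = c("accepted", "accepted", NA))
  asvs <- detect_chimeras(asvs)
  expect_equal(asvs$status[[3]], "chimeric")
  g <- build_library_graph("lib", list(x = 1), list(
    list(sample_id = "s1", asvs = asvs)))
  f <- withr::local_tempfile(fileext = ".ttl")
  export_rdf(g, f)
  lines <- readLines(f)
  expect_equal(sum(grepl("a ag:RejectedAsChimera \\.$", lines)), 1L)
  expect_equal(sum(grepl("a ag:ASVSet \\.$", lines)), 2L)
  expect_equal(read_rdf(f), g)
})

test_that("BIOM export validates, is readable by biomformat, and keeps column sums", {
  run <- run_small_mock(seed = 4, n_taxa = 5, reads = 300,
                        sample_ids = c("s1", "s2"))
  g <- run$res$graph
  f <- file.path(run$dir, "table.biom")
  export_biom(g, f, date = "2026-01-01T00:00:00")
  expect_true(validate_biom(f))
  doc <- jsonlite::fromJSON(f, simplifyVector = FALSE)
  # extension attributes present
  expect_true(!is.null(doc$args))
  expect_equal(doc$type, "OTU table")
  expect_true(all(vapply(doc$rows, function(r)
    nzchar(r$metadata$forward_sequence), NA)))
  # stripping the extensions leaves a valid BIOM 1.0 document
  stripped <- doc
  stripped$args <- NULL
  stripped$rows <- lapply(stripped$rows, function(r) {
    r$metadata <- list(taxonomy = r$metadata$taxonomy); r
  })
  expect_true(validate_biom(stripped))
  f2 <- file.path(run$dir, "stripped.biom")
  jsonlite::write_json(stripped, f2, auto_unbox = TRUE, digits = NA,
                       null = "null")
  b <- suppressWarnings(biomformat::read_biom(f2))
  m <- as.matrix(biomformat::biom_data(b))
  # column sums equal per-sample exported read totals
  for (s in g$samples) {
    keep <- s$asvs$status %in% c("accepted", "provisionally_rejected")
    expect_equal(unname(sum(m[, s$sample_id])),
                 sum(s$asvs$read_count[keep]))
  }
  # cell (i, j) equals the ASV's read count in that sample, 0 if absent
  ids <- vapply(doc$rows, function(r) as.character(r$id), "")
  s1 <- g$samples$s1$asvs
  for (i in seq_len(nrow(s1))) {
    rid <- paste0("asv_", substr(digest::digest(
      paste(s1$forward[[i]], s1$reverse[[i]], sep = "\r"),
      algo = "sha1"), 1, 16))
    expect_equal(unname(m[match(rid, ids), "s1"]), s1$read_count[[i]])
  }
  # args block round-trips into an equal run configuration
  cfg2 <- config_from_args(doc$args)
  expect_equal(cfg2, run$cfg)
})

test_that("byte-identical reruns given an injected timestamp", {
  run <- run_small_mock(seed = 5, n_taxa = 3, reads = 120)
  f1 <- file.path(run$dir, "a.biom"); f2 <- file.path(run$dir, "b.biom")
  export_biom(run$res$graph, f1, date = "2026-01-01T00:00:00")
  export_biom(run$res$graph, f2, date = "2026-01-01T00:00:00")
  expect_identical(readLines(f1), readLines(f2))
  t1 <- file.path(run$dir, "a.ttl"); t2 <- file.path(run$dir, "b.ttl")
  export_rdf(run$res$graph, t1); export_rdf(run$res$graph, t2)
  expect_identical(readLines(t1), readLines(t2))
})

graph_with_asvs <- function(sample_asvs, lib = "lib") {
  build_library_graph(lib, list(), lapply(names(sample_asvs), function(s)
    list(sample_id = s, asvs = sample_asvs[[s]])))
}

test_that("shared ASV queries report per-sample presence vectors", {
  a1 <- make_asvs(c("AAAA", "CCCC"), c("GGGG", "TTTT"), c(10, 20),
                  sample_id = "s1", status = "accepted")
  a2 <- make_asvs(c("AAAA", "CAAC"), c("GGGG", "TTAA"), c(5, 8),
                  sample_id = "s2", status = "accepted")
  a3 <- make_asvs("AAAA", "GGGG", 7, sample_id = "s3",
                  status = "accepted")
  g <- graph_with_asvs(list(s1 = a1, s2 = a2, s3 = a3))
  sh <- shared_asvs(g)
  expect_equal(nrow(sh), 3L)
  all3 <- sh[sh$forward == "AAAA" & sh$reverse == "GGGG", ]
  expect_equal(all3$n_samples, 3)
  expect_true(all3$s1 && all3$s2 && all3$s3)
  uniq <- sh[sh$forward == "CCCC", ]
  expect_equal(uniq$n_samples, 1)
  expect_error(shared_asvs(g, c("s1", "nope")), "unknown sample_id")
})

test_that("rejected recurrence counts cross-sample reappearance", {
  rej <- function(s, f, r, n = 5) make_asvs(f, r, n, sample_id = s,
                                            status = "provisionally_rejected")
  # all rejected ASVs sample-unique -> 0
  g0 <- graph_with_asvs(list(s1 = rej("s1", "AAAA", "CCCC"),
                             s2 = rej("s2", "GGGG", "TTTT")))
  expect_equal(rejected_recurrence(g0, 2), 0.0)
  # 1 of 20 rejected pairs shared by two samples -> 0.05
  f19 <- vapply(1:19, function(i) sprintf("AA%02d", i), "")
  g1 <- graph_with_asvs(list(
    s1 = rej("s1", c("TTTT", f19), c(rep("CCCC", 20))),
    s2 = rej("s2", "TTTT", "CCCC")))
  expect_equal(rejected_recurrence(g1, 2), 1 / 20)
  # a rejected pair that is accepted elsewhere still counts as recurrent
  g2 <- graph_with_asvs(list(
    s1 = rej("s1", "AAAA", "CCCC"),
    s2 = make_asvs("AAAA", "CCCC", 50, sample_id = "s2",
                   status = "accepted")))
  expect_equal(rejected_recurrence(g2, 2), 1.0)
  expect_error(rejected_recurrence(g0, 3), "at least")
})

test_that("unserializable sample metadata is rejected with a named error", {
  g <- build_library_graph("lib", list(), list(
    list(sample_id = "s1",
         asvs = make_asvs("AAAA", "CCCC", 5, status = "accepted"),
         metadata = list(ok = "fine", bad = list(1, 2)))))
  expect_error(export_rdf(g, withr::local_tempfile()), "s1.*bad")
})
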