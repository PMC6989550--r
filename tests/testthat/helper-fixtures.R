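rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Unbanded full-matrix Levenshtein oracle.
full_dp <- function(a, b) drop(utils::adist(a, b))

# Brute-force end-tolerant oracle: minimum over all trailing trims of
# either sequence of the full (unbanded) edit distance.
brute_end_distance <- function(a, b) {
  best <- Inf
  for (t in 0:nchar(a))
    best <- min(best, full_dp(substr(a, 1, nchar(a) - t), b))
  for (t in 0:nchar(b))
    best <- min(best, full_dp(a, substr(b, 1, nchar(b) - t)))
  best
}

# Read-pair data frame for one sample: each row of (f, r) repeated n
# times.
make_pairs <- function(f, r, n, sample_id = "s1") {
  fwd <- rep(f, times = n)
  data.frame(sample_id = rep(sample_id, length(fwd)),
             forward = fwd, reverse = rep(r, times = n),
             stringsAsFactors = FALSE)
}

# Minimal ASV table for unit tests of merge/chimera rules.
make_asvs <- function(forward, reverse, read_count, sample_id = "s1",
                      status = NA_character_) {
  data.frame(sample_id = sample_id, forward = forward, reverse = reverse,
             read_count = as.integer(read_count),
             status = rep_len(status, length(forward)),
             rescued_count = 0L,
             merged_from = I(rep(list(NULL), length(forward))),
             stringsAsFactors = FALSE)
}

# Small in-memory lookup table.
make_lookup <- function(forward, reverse, lineage, count,
                        for_read_len = NULL, rev_read_len = NULL) {
  df <- data.frame(forward = forward, reverse = reverse,
                   lineage = lineage, count = as.integer(count),
                   stringsAsFactors = FALSE)
  structure(df,
            build_parameters = list(
              mode = "test",
              for_read_len = for_read_len %||% nchar(forward[[1]]),
              rev_read_len = rev_read_len %||% nchar(reverse[[1]])),
            skipped = 0L,
            class = c("lookup_table", "data.frame"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# One small end-to-end mock run, reused by serialization and pipeline
# tests.
run_small_mock <- function(seed = 2, n_taxa = 4, reads = 200,
                           sample_ids = "s1", ...) {
  dir <- withr::local_tempdir(.local_envir = parent.frame())
  spec <- mock_spec(n_taxa = n_taxa, reads_per_sample = reads,
                    seed = seed, ...)
  refs <- generate_references(spec, dir = dir)
  generate_reads(spec, refs, sample_ids = sample_ids, dir = dir)
  cfg <- run_config(
    fS = paste0(file.path(dir, "reads_R1.fastq"), ",",
                file.path(dir, "reads_R2.fastq")),
    mapFile = file.path(dir, "mapping.tsv"),
    refdb = file.path(dir, "refs_unaligned.fasta"),
    for_p = spec$forward_primer, rev_p = spec$reverse_primer,
    cache_dir = file.path(dir, "cache"), library_id = "testlib")
  res <- suppressMessages(run_pipeline(cfg))
  list(dir = dir, spec = spec, refs = refs, cfg = cfg, res = res)
}
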