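#' Pipeline run configuration
#'
#' Captures every run parameter with its default.  The flag names
#' follow the established command-line convention: `fS` (comma-
#' separated forward,reverse FASTQ pair), `mapFile`, `refdb`, `for_p`,
#' `rev_p`, `t` (Turtle output), `b` (BIOM output), `primerRemoved`,
#' `for_read_len`, `rev_read_len`, `minPerT` (0.1, percent),
#' `identLvl` (100), `errorCorr` (1), `classifyRatio` (0.8).  The full
#' configuration is embedded in both output files under `"args"`.
#'
#' @param fS Comma-separated `forward.fastq,reverse.fastq` (reverse
#'   part optional in single/merged-read mode).
#' @param mapFile Mapping file path (see [read_mapping_file()]).
#' @param refdb Reference FASTA path (aligned or unaligned).
#' @param for_p,rev_p Degenerate primer strings.
#' @param t,b Optional output paths for the Turtle and BIOM files.
#' @param primerRemoved Logical; primers already stripped upstream.
#' @param for_read_len,rev_read_len Trim lengths; `rev_read_len = NULL`
#'   selects single/merged-read mode.
#' @param minPerT Merge threshold in percent (default 0.1).
#' @param identLvl Percent identity for ASV formation; only 100 is
#'   supported.
#' @param errorCorr Cumulative error-correction distance (default 1).
#' @param classifyRatio Per-rank consensus ratio (default 0.8).
#' @param minIdentical Identical pairs forming an initial ASV
#'   (default 3).
#' @param maxClassifyRejected Most-abundant rejected ASVs that also get
#'   classified (default 100).
#' @param cache_dir Lookup-table cache directory (default: a session
#'   temporary directory).
#' @param library_id Library identifier (default: mapping file base
#'   name).
#' @param demultiplexed Reads are already demultiplexed to the single
#'   mapping sample and carry no barcode.
#' @return A `run_config` list.
#' @export
run_config <- function(fS, mapFile, refdb, for_p, rev_p = NULL,
                       t = NULL, b = NULL, primerRemoved = FALSE,
                       for_read_len = 70L, rev_read_len = 70L,
                       minPerT = 0.1, identLvl = 100, errorCorr = 1L,
                       classifyRatio = 0.8, minIdentical = 3L,
                       maxClassifyRejected = 100L, cache_dir = NULL,
                       library_id = NULL, demultiplexed = FALSE) {
  if (missing(fS) || missing(mapFile) || missing(refdb) || missing(for_p))
    stop("fS, mapFile, refdb and for_p are required")
  if (identLvl != 100)
    stop("only identLvl = 100 (exact-match ASV formation) is supported")
  structure(list(
    fS = fS, mapFile = mapFile, refdb = refdb, for_p = for_p,
    rev_p = rev_p, t = t, b = b, primerRemoved = isTRUE(primerRemoved),
    for_read_len = as.integer(for_read_len),
    rev_read_len = if (is.null(rev_read_len)) NULL
                   else as.integer(rev_read_len),
    minPerT = as.numeric(minPerT), identLvl = 100,
    errorCorr = as.integer(errorCorr),
    classifyRatio = as.numeric(classifyRatio),
    minIdentical = as.integer(minIdentical),
    maxClassifyRejected = as.integer(maxClassifyRejected),
    cache_dir = cache_dir %||%
      file.path(tempdir(), "asvgraph-lookup-cache"),
    library_id = library_id %||%
      tools::file_path_sans_ext(basename(mapFile)),
    demultiplexed = isTRUE(demultiplexed)), class = "run_config")
}

config_args <- function(config) {
  args <- unclass(config)
  args$rev_p <- args$rev_p %||% ""
  args$rev_read_len <- args$rev_read_len %||% -1L
  args$t <- args$t %||% ""
  args$b <- args$b %||% ""
  args
}

#' Rebuild a run configuration from a stored args block
#'
#' Inverse of the `"args"` section embedded in exported files.
#'
#' @param args Named list as stored under `"args"`.
#' @return A `run_config`.
#' @export
config_from_args <- function(args) {
  run_config(fS = args$fS, mapFile = args$mapFile, refdb = args$refdb,
             for_p = args$for_p,
             rev_p = if (nzchar(args$rev_p)) args$rev_p else NULL,
             t = if (nzchar(args$t)) args$t else NULL,
             b = if (nzchar(args$b)) args$b else NULL,
             primerRemoved = args$primerRemoved,
             for_read_len = args$for_read_len,
             rev_read_len = if (args$rev_read_len < 0) NULL
                            else args$rev_read_len,
             minPerT = args$minPerT, identLvl = args$identLvl,
             errorCorr = args$errorCorr,
             classifyRatio = args$classifyRatio,
             minIdentical = args$minIdentical,
             maxClassifyRejected = args$maxClassifyRejected,
             cache_dir = args$cache_dir, library_id = args$library_id,
             demultiplexed = args$demultiplexed)
}

#' Run the full analysis pipeline
#'
#' Demultiplexes and trims the reads, denoises each sample
#' independently (initial ASV formation, singleton rescue,
#' low-abundance merging, chimera flagging), classifies the ASVs
#' against the lookup table built (or cached) from the reference
#' database, assembles the provenance-linked library graph, and writes
#' the Turtle and extended BIOM outputs when paths are configured.
#' Samples are processed independently, so results do not depend on
#' processing order.
#'
#' @param config A [run_config()].
#' @param date Optional injectable timestamp for the BIOM output.
#' @return An `asv_analysis` object: list with `config`, `graph`
#'   (`library_graph`), `lookup`, `demux` and `report` (per-sample
#'   denoising summary data frame).
#' @export
run_pipeline <- function(config, date = NULL) {
  stopifnot(inherits(config, "run_config"))
  for (f in c(strsplit(config$fS, ",")[[1]], config$mapFile, config$refdb))
    if (!file.exists(f)) stop("input file not found: ", f)
  files <- strsplit(config$fS, ",")[[1]]
  paired <- !is.null(config$rev_read_len)
  if (paired && length(files) < 2L)
    stop("rev_read_len is set but fS names only one FASTQ file")
  mapping <- read_mapping_file(config$mapFile)
  message("stage demultiplex: ", config$fS)
  dm <- demultiplex(files[[1]],
                    if (paired) files[[2]] else NULL,
                    mapping,
                    forward_primer = config$for_p,
                    reverse_primer = config$rev_p,
                    primer_removed = config$primerRemoved,
                    for_read_len = config$for_read_len,
                    rev_read_len = config$rev_read_len,
                    demultiplexed = config$demultiplexed)
  params <- denoise_params(
    min_identical = config$minIdentical,
    min_percent_threshold = config$minPerT,
    error_correction_distance = config$errorCorr,
    identity_level = config$identLvl,
    max_classified_rejected = config$maxClassifyRejected)
  message("stage lookup table: ", config$refdb)
  if (is.null(config$rev_p))
    stop("rev_p is required to delimit the reference region of interest")
  lookup <- load_or_build_lookup(config$cache_dir, config$refdb,
                                 config$for_p, config$rev_p,
                                 config$for_read_len,
                                 config$rev_read_len %||% 0L)
  sample_results <- list()
  report <- list()
  for (sid in names(dm$samples)) {
    pairs <- dm$samples[[sid]]
    den <- denoise_sample(pairs, params)
    asvs <- classify_sample(den$asvs, lookup, params,
                            classify_ratio = config$classifyRatio)
    midx <- match(sid, mapping$sample_id)
    meta_cols <- setdiff(names(mapping),
                         c("sample_id", "forward_barcode",
                           "reverse_barcode"))
    metadata <- as.list(mapping[midx, meta_cols, drop = FALSE])
    sample_results[[sid]] <- list(
      sample_id = sid, asvs = asvs, metadata = metadata,
      forward_barcode = mapping$forward_barcode[[midx]],
      reverse_barcode = mapping$reverse_barcode[[midx]] %||% "",
      forward_primer = config$for_p,
      reverse_primer = config$rev_p %||% "")
    tab <- table(factor(asvs$status, levels = names(STATUS_CLASS)))
    report[[sid]] <- data.frame(
      sample_id = sid, reads_in = den$n_input,
      asvs_accepted = tab[["accepted"]],
      asvs_rejected = tab[["provisionally_rejected"]],
      asvs_chimeric = tab[["chimeric"]],
      reads_discarded = den$discarded, stringsAsFactors = FALSE)
    message(sprintf(
      "stage denoise+classify %s: %d reads in, %d/%d/%d asvs, %d discarded",
      sid, den$n_input, tab[["accepted"]],
      tab[["provisionally_rejected"]], tab[["chimeric"]], den$discarded))
  }
  graph <- build_library_graph(config$library_id, config_args(config),
                               sample_results)
  if (!is.null(config$t)) export_rdf(graph, config$t)
  if (!is.null(config$b)) export_biom(graph, config$b, date = date)
  structure(list(config = config, graph = graph, lookup = lookup,
                 demux = dm,
                 report = do.call(rbind, c(report,
                                           make.row.names = FALSE))),
            class = "asv_analysis")
}

#' @export
print.asv_analysis <- function(x, ...) {
  cat(sprintf("amplicon ASV analysis '%s'\n", x$config$library_id))
  print(x$report, row.names = FALSE)
  invisible(x)
}

#' @export
summary.asv_analysis <- function(object, ...) {
  cat(sprintf("library '%s': %d sample(s), lookup table of %d entries\n",
              object$config$library_id, length(object$graph$samples),
              nrow(object$lookup)))
  print(object$report, row.names = FALSE)
  disc <- object$demux$discarded
  if (nrow(disc)) {
    cat("demultiplexing discards:\n")
    print(disc, row.names = FALSE)
  }
  invisible(object)
}

#' Predicted composition of an analysed sample
#'
#' Relative abundances of the accepted ASVs of one sample, labelled by
#' their assigned taxonomy.
#'
#' @param analysis An `asv_analysis` (or a `library_graph`).
#' @param sample_id Sample to extract (default: first).
#' @return Data frame with `lineage`, `abundance`, `forward`,
#'   `reverse`, `read_count`.
#' @export
predicted_composition <- function(analysis, sample_id = NULL) {
  graph <- if (inherits(analysis, "asv_analysis")) analysis$graph
           else analysis
  sample_id <- sample_id %||% names(graph$samples)[[1]]
  s <- graph$samples[[sample_id]]
  if (is.null(s)) stop("unknown sample_id: ", sample_id)
  a <- s$asvs[s$asvs$status == "accepted", , drop = FALSE]
  data.frame(lineage = a$taxonomy, abundance = a$read_count /
               sum(a$read_count), forward = a$forward,
             reverse = a$reverse, read_count = a$read_count,
             stringsAsFactors = FALSE)
}
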