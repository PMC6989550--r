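#' Read a SILVA-style reference FASTA
#'
#' Description lines are `accession lineage` with the lineage as a
#' semicolon-separated rank list (domain;phylum;...;genus[;species]).
#' Sequences may be gapped (`-` or `.`) when the file is a multiple
#' alignment; `U` is converted to `T`.
#'
#' @param path FASTA path (plain or gzipped).
#' @return A data frame with columns `accession`, `sequence`, `lineage`.
#' @export
read_reference_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  desc <- names(x)
  accession <- sub("\\s.*$", "", desc)
  lineage <- ifelse(grepl("\\s", desc), sub("^\\S+\\s+", "", desc), "")
  seqs <- toupper(as.character(x))
  seqs <- chartr("U", "T", seqs)
  nr <- vapply(strsplit(lineage, ";"), length, 0L)
  if (any(nr < 1L | nr > 7L))
    stop("reference lineages must have between 1 and 7 ranks")
  data.frame(accession = accession, sequence = unname(seqs),
             lineage = lineage, stringsAsFactors = FALSE)
}

degap <- function(x) gsub("[-.]", "", x)

# Map an ungapped position to its alignment column.
ungapped_to_column <- function(aligned_row, pos) {
  keep <- which(strsplit(aligned_row, "")[[1]] %in%
                  c("A", "C", "G", "T", "U", "M", "R", "W", "S", "Y", "K",
                    "V", "H", "D", "B", "N"))
  keep[pos]
}

# Locate both primer sites in one ungapped sequence.  Returns NULL or a
# list with fwd_start/fwd_stop/rev_start/rev_stop in ungapped 1-based
# coordinates (the reverse primer is given 5'->3' on the opposite
# strand, so its site on the plus strand is its reverse complement,
# searched downstream of the forward site).
locate_primer_sites <- function(seq, forward_primer, reverse_primer) {
  fp <- as_primer(forward_primer)
  fs <- locate_primer(seq, fp)
  if (is.na(fs)) return(NULL)
  fe <- fs + nchar(fp) - 1L
  rp_plus <- iupac_primer(reverse_complement(unclass(as_primer(reverse_primer))))
  rs <- locate_primer(seq, rp_plus, from = fe + 1L)
  if (is.na(rs)) return(NULL)
  list(fwd_start = fs, fwd_stop = fe,
       rev_start = rs, rev_stop = rs + nchar(rp_plus) - 1L)
}

#' Consensus primer columns in a reference alignment
#'
#' Scans alignment rows in file order, locating in each degapped row
#' the forward primer site and (via reverse complement) the reverse
#' primer site, and remapping their start/stop positions to alignment
#' columns.  Returns the first column quadruple observed
#' `consensus_count` times; if the alignment is exhausted first, the
#' modal quadruple.
#'
#' @param alignment Data frame from [read_reference_fasta()] with
#'   gapped rows of equal width.
#' @param forward_primer,reverse_primer Primers ([iupac_primer()] or
#'   strings); the reverse primer is given 5'->3' on the opposite
#'   strand.
#' @param consensus_count Occurrences required for consensus
#'   (default 1000).
#' @return Integer vector `c(fwd_start, fwd_stop, rev_start, rev_stop)`
#'   of 1-based alignment columns.
#' @export
find_consensus_primer_columns <- function(alignment, forward_primer,
                                          reverse_primer,
                                          consensus_count = 1000L) {
  if (length(unique(nchar(alignment$sequence))) != 1L)
    stop("alignment rows must all have equal width")
  tally <- new.env(parent = emptyenv())
  any_fwd <- FALSE
  any_rev <- FALSE
  for (i in seq_len(nrow(alignment))) {
    row <- alignment$sequence[[i]]
    ug <- degap(row)
    sites <- locate_primer_sites(ug, forward_primer, reverse_primer)
    if (!is.na(locate_primer(ug, forward_primer))) any_fwd <- TRUE
    if (is.null(sites)) next
    any_rev <- TRUE
    cols <- vapply(c(sites$fwd_start, sites$fwd_stop,
                     sites$rev_start, sites$rev_stop),
                   function(p) ungapped_to_column(row, p), 0L)
    key <- paste(cols, collapse = ",")
    cnt <- (if (is.null(tally[[key]])) 0L else tally[[key]]) + 1L
    tally[[key]] <- cnt
    if (cnt >= consensus_count)
      return(as.integer(strsplit(key, ",")[[1]]))
  }
  keys <- ls(tally)
  if (!length(keys)) {
    missing <- if (!any_fwd) "forward" else "reverse"
    stop("no alignment row contains both primer sites (", missing,
         " primer never matched)")
  }
  counts <- vapply(keys, function(k) tally[[k]], 0L)
  as.integer(strsplit(keys[[which.max(counts)]], ",")[[1]])
}

new_lookup_table <- function(entries, build_parameters, skipped = 0L) {
  structure(entries, build_parameters = build_parameters,
            skipped = as.integer(skipped),
            class = c("lookup_table", "data.frame"))
}

collapse_regions <- function(fwd, rev, lineage) {
  df <- data.frame(forward = fwd, reverse = rev, lineage = lineage,
                   stringsAsFactors = FALSE)
  agg <- stats::aggregate(list(count = rep(1L, nrow(df))),
                          df[c("forward", "reverse", "lineage")], sum)
  agg <- agg[order(agg$forward, agg$reverse, agg$lineage), , drop = FALSE]
  rownames(agg) <- NULL
  agg
}

trim_regions <- function(regions, lineages, for_read_len, rev_read_len,
                         build_parameters) {
  len <- nchar(regions)
  keep <- len >= for_read_len & len >= rev_read_len
  skipped <- sum(!keep)
  regions <- regions[keep]
  lineages <- lineages[keep]
  if (!length(regions)) stop("no reference region long enough for the ",
                             "configured read lengths")
  fwd <- substr(regions, 1L, for_read_len)
  rev <- reverse_complement(substr(regions, nchar(regions) - rev_read_len + 1L,
                                   nchar(regions)))
  new_lookup_table(collapse_regions(fwd, rev, lineages),
                   build_parameters, skipped)
}

#' Build a lookup table from a gapped reference alignment
#'
#' Finds the consensus primer columns, then for every row slices the
#' columns strictly between the primer regions, removes alignment gaps,
#' takes the first `for_read_len` bases as the forward region and the
#' reverse complement of the last `rev_read_len` bases as the reverse
#' region (read orientation), and collapses identical
#' (forward, reverse, lineage) triples with summed counts — the
#' four-column lookup table the classifier consumes.
#'
#' @inheritParams find_consensus_primer_columns
#' @param for_read_len,rev_read_len Integer trim lengths.
#' @return A `lookup_table`: data frame with columns `forward`,
#'   `reverse`, `lineage`, `count`, plus `build_parameters` and
#'   `skipped` attributes.
#' @export
build_lookup_from_alignment <- function(alignment, forward_primer,
                                        reverse_primer, for_read_len,
                                        rev_read_len,
                                        consensus_count = 1000L) {
  cols <- find_consensus_primer_columns(alignment, forward_primer,
                                        reverse_primer, consensus_count)
  if (cols[[3]] - cols[[2]] < 2L)
    stop("primer regions are adjacent; no region of interest between them")
  regions <- degap(substr(alignment$sequence, cols[[2]] + 1L, cols[[3]] - 1L))
  bp <- list(mode = "alignment",
             forward_primer = as.character(forward_primer),
             reverse_primer = as.character(reverse_primer),
             for_read_len = for_read_len, rev_read_len = rev_read_len,
             primer_columns = cols)
  trim_regions(regions, alignment$lineage, for_read_len, rev_read_len, bp)
}

#' Build a lookup table from unaligned reference sequences
#'
#' Locates in each sequence the forward primer and, downstream, the
#' reverse-complemented reverse primer under the [match_primer()] rules
#' (at most one mismatch; the 3'-most primer base must match perfectly
#' or be a G/T wobble), extracts the region strictly between the
#' primers, and trims/collapses as in
#' [build_lookup_from_alignment()].  Sequences lacking either site are
#' skipped and counted.
#'
#' @param fasta Data frame from [read_reference_fasta()] (ungapped).
#' @inheritParams build_lookup_from_alignment
#' @return A `lookup_table` (see [build_lookup_from_alignment()]).
#' @export
build_lookup_from_unaligned <- function(fasta, forward_primer,
                                        reverse_primer, for_read_len,
                                        rev_read_len) {
  seqs <- degap(fasta$sequence)
  regions <- character(0)
  lineages <- character(0)
  skipped_sites <- 0L
  for (i in seq_along(seqs)) {
    sites <- locate_primer_sites(seqs[[i]], forward_primer, reverse_primer)
    if (is.null(sites)) { skipped_sites <- skipped_sites + 1L; next }
    regions <- c(regions, substr(seqs[[i]], sites$fwd_stop + 1L,
                                 sites$rev_start - 1L))
    lineages <- c(lineages, fasta$lineage[[i]])
  }
  if (!length(regions))
    stop("no reference sequence contained both primer sites")
  bp <- list(mode = "unaligned",
             forward_primer = as.character(forward_primer),
             reverse_primer = as.character(reverse_primer),
             for_read_len = for_read_len, rev_read_len = rev_read_len)
  tab <- trim_regions(regions, lineages, for_read_len, rev_read_len, bp)
  attr(tab, "skipped") <- attr(tab, "skipped") + skipped_sites
  tab
}

#' @export
print.lookup_table <- function(x, ...) {
  bp <- attr(x, "build_parameters")
  cat(sprintf("lookup table: %d entries (%d reference regions), %s mode\n",
              nrow(x), sum(x$count), bp$mode))
  cat(sprintf("  regions: %d nt forward / %d nt reverse\n",
              bp$for_read_len, bp$rev_read_len))
  NextMethod()
}

lookup_cache_key <- function(source, forward_primer, reverse_primer,
                             for_read_len, rev_read_len) {
  digest::digest(list(
    source_sha256 = digest::digest(file = source, algo = "sha256"),
    forward_primer = as.character(forward_primer),
    reverse_primer = as.character(reverse_primer),
    for_read_len = as.integer(for_read_len),
    rev_read_len = as.integer(rev_read_len)), algo = "sha256")
}

#' Write / read a lookup table as annotated TSV
#'
#' Four tab-separated columns mirroring the in-memory table, preceded
#' by a `#`-prefixed JSON header holding the build parameters.
#'
#' @param table A `lookup_table`.
#' @param path Output path.
#' @return `write_lookup` returns `path` invisibly; `read_lookup`
#'   returns the `lookup_table`.
#' @export
write_lookup <- function(table, path) {
  hdr <- paste0("#", jsonlite::toJSON(attr(table, "build_parameters"),
                                      auto_unbox = TRUE))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(as.data.frame(table), con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' @rdname write_lookup
#' @export
read_lookup <- function(path) {
  lines <- readLines(path, n = 1L)
  if (!length(lines) || !startsWith(lines[[1]], "#"))
    stop("not a lookup table file (missing JSON header)")
  bp <- jsonlite::fromJSON(sub("^#", "", lines[[1]]))
  df <- utils::read.table(path, sep = "\t", header = TRUE, skip = 1L,
                          colClasses = c("character", "character",
                                         "character", "integer"),
                          comment.char = "")
  new_lookup_table(df, bp)
}

#' Build a lookup table, reusing a cached copy when parameters match
#'
#' The cache key is the SHA-256 of the reference file content together
#' with both primer strings and both read lengths, so a changed file
#' (even under the same name) or any changed parameter triggers a
#' rebuild.  A corrupt cache file is rebuilt with a warning.
#'
#' @param cache_dir Writable cache directory.
#' @param source Reference FASTA path (aligned or unaligned; alignment
#'   mode is used when any gap character occurs).
#' @inheritParams build_lookup_from_alignment
#' @return A `lookup_table`.
#' @export
load_or_build_lookup <- function(cache_dir, source, forward_primer,
                                 reverse_primer, for_read_len,
                                 rev_read_len, consensus_count = 1000L) {
  dir.create(cache_dir, showWarnings = FALSE, recursive = TRUE)
  key <- lookup_cache_key(source, forward_primer, reverse_primer,
                          for_read_len, rev_read_len)
  path <- file.path(cache_dir, paste0("lookup_", key, ".tsv"))
  if (file.exists(path)) {
    tab <- tryCatch(read_lookup(path), error = function(e) {
      warning("stale or corrupt lookup cache; rebuilding (",
              conditionMessage(e), ")", call. = FALSE)
      NULL
    })
    if (!is.null(tab)) return(tab)
  }
  refs <- read_reference_fasta(source)
  aligned <- any(grepl("[-.]", refs$sequence))
  tab <- if (aligned) {
    build_lookup_from_alignment(refs, forward_primer, reverse_primer,
                                for_read_len, rev_read_len, consensus_count)
  } else {
    build_lookup_from_unaligned(refs, forward_primer, reverse_primer,
                                for_read_len, rev_read_len)
  }
  write_lookup(tab, path)
  tab
}
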