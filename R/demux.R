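#' @useDynLib asvgraph, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"),
  H = c("A", "C", "T"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "T"))

#' Degenerate (IUPAC) primer
#'
#' Validates a primer given with IUPAC nucleotide ambiguity codes
#' (e.g. the 515F primer `"GTGYCAGCMGCCGCGGTAA"`).
#'
#' @param pattern Character scalar over `ACGTRYSWKMBDHVN`.
#' @return An `iupac_primer` object (the validated uppercase pattern).
#' @export
iupac_primer <- function(pattern) {
  stopifnot(is.character(pattern), length(pattern) == 1L, !is.na(pattern),
            nzchar(pattern))
  pattern <- toupper(pattern)
  bad <- setdiff(strsplit(pattern, "")[[1]], names(IUPAC_SETS))
  if (length(bad))
    stop("invalid IUPAC character(s) in primer: ",
         paste(unique(bad), collapse = ", "))
  structure(pattern, class = "iupac_primer")
}

#' @export
print.iupac_primer <- function(x, ...) {
  cat(sprintf("IUPAC primer: %s (%d nt)\n", unclass(x), nchar(x)))
  invisible(x)
}

#' Match a degenerate primer at the start of a read
#'
#' A read position matches when the read base belongs to the IUPAC set
#' of the primer character.  At most one mismatching position is
#' tolerated across the primer, and the 3'-most position must either
#' match perfectly or be the specific wobble pair primer-G/read-T or
#' primer-T/read-G (the G/T pairing that still primes amplification).
#'
#' @param read Character scalar, the read sequence (primer expected at
#'   its 5' start).
#' @param primer An [iupac_primer()] (plain strings are coerced).
#' @return `NULL` when there is no match, else a list with `offset`
#'   (always 1; the match is anchored) and `mismatches` (0 or 1).
#' @export
match_primer <- function(read, primer) {
  primer <- as_primer(primer)
  p <- strsplit(unclass(primer), "")[[1]]
  np <- length(p)
  if (nchar(read) < np) return(NULL)
  r <- strsplit(toupper(substr(read, 1L, np)), "")[[1]]
  ok <- mapply(function(pc, rc) rc %in% IUPAC_SETS[[pc]], p, r)
  mm <- sum(!ok)
  if (mm > 1L) return(NULL)
  if (!ok[np]) {  # 3'-most mismatch: only G/T wobble primes
    gt <- (p[np] == "G" && r[np] == "T") || (p[np] == "T" && r[np] == "G")
    if (!gt) return(NULL)
  }
  list(offset = 1L, mismatches = as.integer(mm))
}

as_primer <- function(x) {
  if (inherits(x, "iupac_primer")) x else iupac_primer(x)
}

# First offset (1-based) in `seq` where the primer matches under the
# match_primer rules, or NA.  `from` restricts the search start.
locate_primer <- function(seq, primer, from = 1L) {
  primer <- as_primer(primer)
  np <- nchar(primer)
  n <- nchar(seq)
  if (n < np) return(NA_integer_)
  subject <- Biostrings::DNAString(seq)
  hits <- Biostrings::matchPattern(Biostrings::DNAString(unclass(primer)),
                                   subject, max.mismatch = 1L,
                                   with.indels = FALSE, fixed = FALSE)
  starts <- sort(BiocGenerics::start(hits))
  starts <- starts[starts >= from & starts + np - 1L <= n]
  for (s in starts) {
    if (!is.null(match_primer(substr(seq, s, s + np - 1L), primer)))
      return(as.integer(s))
  }
  NA_integer_
}

#' Reverse complement
#'
#' Reverse complement of DNA strings, IUPAC-aware (`R` -> `Y` etc.).
#'
#' @param x Character vector of sequences.
#' @return Character vector of the same length.
#' @export
reverse_complement <- function(x) {
  comp <- chartr("ACGTRYSWKMBDHVNacgt.-", "TGCAYRSWMKVHDBNtgca.-", x)
  vapply(strsplit(comp, ""), function(s) paste(rev(s), collapse = ""), "")
}

#' Read a QIIME-classic mapping file
#'
#' Tab-separated, header line starting `#SampleID`, with columns
#' `SampleID`, `BarcodeSequence`, optional `ReverseBarcode`, and free
#' metadata columns.
#'
#' @param path Path to the mapping file.
#' @return A data frame with columns `sample_id`, `forward_barcode`,
#'   `reverse_barcode` (`NA` when absent) and any metadata columns.
#' @export
read_mapping_file <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines) || !startsWith(lines[[1]], "#SampleID"))
    stop("mapping file must start with a '#SampleID' header line")
  header <- strsplit(sub("^#", "", lines[[1]]), "\t")[[1]]
  body <- lines[-1]
  body <- body[!startsWith(body, "#")]
  fields <- strsplit(body, "\t")
  mat <- do.call(rbind, lapply(fields, function(f) {
    length(f) <- length(header)
    f
  }))
  df <- as.data.frame(mat, stringsAsFactors = FALSE)
  names(df) <- header
  out <- data.frame(sample_id = df$SampleID,
                    forward_barcode = toupper(df$BarcodeSequence),
                    reverse_barcode = if ("ReverseBarcode" %in% names(df))
                      toupper(df$ReverseBarcode) else NA_character_,
                    stringsAsFactors = FALSE)
  meta <- df[setdiff(names(df), c("SampleID", "BarcodeSequence",
                                  "ReverseBarcode"))]
  out <- cbind(out, meta)
  validate_mapping(out)
  out
}

validate_mapping <- function(mapping) {
  if (anyDuplicated(mapping$sample_id))
    stop("duplicate sample_id in mapping file")
  key <- paste(mapping$forward_barcode, mapping$reverse_barcode)
  if (anyDuplicated(key))
    stop("duplicate barcodes across samples in mapping file")
  if (any(grepl("[^ACGT]", mapping$forward_barcode)))
    stop("forward barcodes must be over {A,C,G,T}")
  invisible(mapping)
}

read_fastq_seqs <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  as.character(x)
}

#' Demultiplex, primer-strip and trim paired amplicon reads
#'
#' Splits read pairs by exact barcode prefix, verifies and strips the
#' degenerate primers (see [match_primer()]; at most one mismatch, 3'
#' G/T rule), and hard-trims the remainder to the configured fixed
#' lengths.  Pairs failing any step are counted per discard reason
#' (`barcode`, `primer`, `length`); conservation holds exactly:
#' input pairs = assigned + discarded.
#'
#' @param forward Character vector of raw forward reads, or a FASTQ
#'   path.
#' @param reverse Character vector of raw reverse reads or FASTQ path;
#'   `NULL` for single/merged-read mode.
#' @param mapping Mapping data frame from [read_mapping_file()] (or of
#'   the same shape).
#' @param forward_primer,reverse_primer [iupac_primer()] objects or
#'   strings.  `reverse_primer` is ignored in single-read mode when
#'   `reverse` is `NULL`.
#' @param primer_removed Logical; `TRUE` when primers were already
#'   stripped upstream (no primer check, nothing stripped).
#' @param for_read_len,rev_read_len Integer trim lengths.
#'   `rev_read_len = NULL` selects single/merged-read mode.
#' @param demultiplexed Logical; `TRUE` means all reads belong to the
#'   single sample in `mapping` and carry no barcode.
#' @return A `demux_result`: list with `samples` (named list of data
#'   frames with columns `sample_id`, `forward`, `reverse`) and
#'   `discarded` (data frame `sample_id`, `reason`, `count`; barcode
#'   failures are attributed to `"unassigned"`).
#' @export
demultiplex <- function(forward, reverse = NULL, mapping,
                        forward_primer, reverse_primer = NULL,
                        primer_removed = FALSE,
                        for_read_len, rev_read_len = NULL,
                        demultiplexed = FALSE) {
  if (length(forward) == 1L && file.exists(forward))
    forward <- read_fastq_seqs(forward)
  paired <- !is.null(rev_read_len)
  if (paired) {
    if (is.null(reverse)) stop("rev_read_len set but no reverse reads given")
    if (length(reverse) == 1L && file.exists(reverse))
      reverse <- read_fastq_seqs(reverse)
    if (length(reverse) != length(forward))
      stop("forward and reverse read counts differ")
  } else {
    reverse <- NULL
  }
  validate_mapping(mapping)
  forward <- toupper(forward)
  if (paired) reverse <- toupper(reverse)
  n <- length(forward)

  sample_of <- rep(NA_character_, n)
  fwd <- forward
  rev <- reverse
  if (demultiplexed) {
    if (nrow(mapping) != 1L)
      stop("demultiplexed = TRUE requires a single-sample mapping")
    sample_of[] <- mapping$sample_id[[1]]
  } else {
    for (i in seq_len(nrow(mapping))) {
      fb <- mapping$forward_barcode[[i]]
      hit <- startsWith(forward, fb)
      rb <- mapping$reverse_barcode[[i]]
      if (paired && !is.na(rb) && nzchar(rb))
        hit <- hit & startsWith(reverse, rb)
      hit <- hit & is.na(sample_of)
      sample_of[hit] <- mapping$sample_id[[i]]
      fwd[hit] <- substr(forward[hit], nchar(fb) + 1L, nchar(forward[hit]))
      if (paired && !is.na(rb) && nzchar(rb))
        rev[hit] <- substr(reverse[hit], nchar(rb) + 1L, nchar(reverse[hit]))
    }
  }
  reason <- rep(NA_character_, n)
  reason[is.na(sample_of)] <- "barcode"

  if (!primer_removed) {
    fp <- as_primer(forward_primer)
    nf <- nchar(fp)
    ok <- is.na(reason)
    fok <- vapply(fwd, function(s) !is.null(match_primer(s, fp)), NA,
                  USE.NAMES = FALSE)
    if (paired) {
      rp <- as_primer(reverse_primer)
      nr <- nchar(rp)
      rok <- vapply(rev, function(s) !is.null(match_primer(s, rp)), NA,
                    USE.NAMES = FALSE)
    } else {
      rok <- rep(TRUE, n)
    }
    reason[ok & !(fok & rok)] <- "primer"
    keep <- is.na(reason)
    fwd[keep] <- substr(fwd[keep], nf + 1L, nchar(fwd[keep]))
    if (paired) rev[keep] <- substr(rev[keep], nr + 1L, nchar(rev[keep]))
  }

  short <- is.na(reason) & nchar(fwd) < for_read_len
  if (paired)
    short <- short | (is.na(reason) & nchar(rev) < rev_read_len)
  reason[short] <- "length"
  keep <- is.na(reason)
  fwd[keep] <- substr(fwd[keep], 1L, for_read_len)
  if (paired) rev[keep] <- substr(rev[keep], 1L, rev_read_len)

  samples <- stats::setNames(vector("list", nrow(mapping)), mapping$sample_id)
  for (s in mapping$sample_id) {
    idx <- which(keep & sample_of == s)
    samples[[s]] <- data.frame(
      sample_id = rep(s, length(idx)),
      forward = fwd[idx],
      reverse = if (paired) rev[idx] else rep(NA_character_, length(idx)),
      stringsAsFactors = FALSE)
    if (!length(idx))
      warning("sample '", s, "' has zero surviving reads", call. = FALSE)
  }
  disc_sample <- ifelse(is.na(sample_of), "unassigned", sample_of)
  disc <- data.frame(sample_id = disc_sample[!keep],
                     reason = reason[!keep], stringsAsFactors = FALSE)
  discarded <- if (nrow(disc)) {
    agg <- stats::aggregate(list(count = rep(1L, nrow(disc))),
                            disc[c("sample_id", "reason")], sum)
    agg[order(agg$sample_id, agg$reason), , drop = FALSE]
  } else {
    data.frame(sample_id = character(), reason = character(),
               count = integer(), stringsAsFactors = FALSE)
  }
  structure(list(samples = samples, discarded = discarded,
                 n_input = n, paired = paired),
            class = "demux_result")
}

#' @export
print.demux_result <- function(x, ...) {
  cat(sprintf("demultiplexed %d read pairs into %d sample(s); %d discarded\n",
              x$n_input, length(x$samples), sum(x$discarded$count)))
  for (s in names(x$samples))
    cat(sprintf("  %s: %d pairs\n", s, nrow(x$samples[[s]])))
  invisible(x)
}
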