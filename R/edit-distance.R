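#' k-bounded Levenshtein distance
#'
#' Exact Levenshtein (unit-cost edit) distance between two sequences,
#' computed inside a diagonal band of half-width `k`.  When the true
#' distance exceeds `k` the band cannot contain the optimal path and the
#' result is flagged `exceeded` with an undefined value; when it does
#' not, the banded result equals the full dynamic program.  This is the
#' distance primitive used throughout the pipeline: singleton rescue and
#' erroneous-ASV merging run it with a bound of 1, the classifier with a
#' bound of 50.
#'
#' @param a,b Character scalars (sequences; any finite alphabet,
#'   uppercase DNA expected).
#' @param k Non-negative integer bound.
#' @return A `bounded_distance` object: a list with `value` (integer
#'   edit distance, `NA` when exceeded), `exceeded` (logical) and
#'   `bound`.
#' @examples
#' k_bounded_levenshtein("GATTACA", "GACTATA", 7)
#' k_bounded_levenshtein("AAAA", "TTTT", 2)  # exceeded
#' @seealso [end_tolerant_distance()]
#' @export
k_bounded_levenshtein <- function(a, b, k) {
  check_dist_args(a, b, k)
  res <- dist_bounded_cpp(a, b, as.integer(k), FALSE)
  structure(res, class = "bounded_distance")
}

#' End-tolerant bounded edit distance
#'
#' Like [k_bounded_levenshtein()] but gaps confined to the trailing end
#' of either sequence are free.  Fixed-length trimming of reads and
#' reference regions turns an internal indel into a frame-shifted tail:
#' the sequences agree up to the indel and then run out of register,
#' with one of them overhanging the other's end.  Charging that overhang
#' would count a single sequencing indel as many edits; end-gap-free
#' scoring on the tail charges only the indel itself.
#'
#' @inheritParams k_bounded_levenshtein
#' @return A `bounded_distance` object (see [k_bounded_levenshtein()]).
#' @examples
#' end_tolerant_distance("ACGTA", "ACGT", 1)  # trailing overhang is free
#' @export
end_tolerant_distance <- function(a, b, k) {
  check_dist_args(a, b, k)
  res <- dist_bounded_cpp(a, b, as.integer(k), TRUE)
  structure(res, class = "bounded_distance")
}

check_dist_args <- function(a, b, k) {
  stopifnot(is.character(a), length(a) == 1L, !is.na(a),
            is.character(b), length(b) == 1L, !is.na(b),
            is.numeric(k), length(k) == 1L, !is.na(k), k >= 0)
  invisible(NULL)
}

#' @export
print.bounded_distance <- function(x, ...) {
  if (x$exceeded) {
    cat(sprintf("bounded edit distance: > %d (bound exceeded)\n", x$bound))
  } else {
    cat(sprintf("bounded edit distance: %d (bound %d)\n", x$value, x$bound))
  }
  invisible(x)
}

# Cumulative forward+reverse end-tolerant distance of each (fwd, rev)
# read pair against one reference pair; NA where > k.
pair_distances <- function(fwd, rev, ref_fwd, ref_rev, k) {
  if (is.null(rev)) rev <- rep("", length(fwd))
  if (is.null(ref_rev)) ref_rev <- ""
  pair_dist_cpp(as.character(fwd), as.character(rev),
                ref_fwd, ref_rev, as.integer(k), TRUE)
}
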