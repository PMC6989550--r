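#' Confusion counts between predicted and expected compositions
#'
#' Taxa are compared by exact name match at the requested rank (the
#' benchmarking convention is an exact match at genus level);
#' abundances are ignored and duplicate taxa within one table are
#' collapsed before comparison.
#'
#' @param predicted,expected Either character vectors of taxon names at
#'   `rank`, or data frames with a `lineage` column (semicolon-
#'   separated ranks) from which the rank is extracted.
#' @param rank One of domain, phylum, class, order, family, genus,
#'   species (default `"genus"`).
#' @return A `confusion_counts` list with integers `TP`, `FP`, `FN`.
#' @export
confusion_from_compositions <- function(predicted, expected,
                                        rank = "genus") {
  p <- taxa_at_rank(predicted, rank)
  e <- taxa_at_rank(expected, rank)
  structure(list(TP = length(intersect(p, e)),
                 FP = length(setdiff(p, e)),
                 FN = length(setdiff(e, p))),
            class = "confusion_counts")
}

taxa_at_rank <- function(x, rank) {
  rank <- match.arg(rank, TAX_RANKS)
  if (is.data.frame(x)) {
    if (!"lineage" %in% names(x)) stop("data frame input needs a 'lineage' column")
    x <- split_lineage(x$lineage)[, match(rank, TAX_RANKS)]
  }
  x <- unique(as.character(x))
  x[nzchar(x) & !is.na(x)]
}

#' Precision, recall and F-score from confusion counts
#'
#' `recall = TP/(TP+FN)`, `precision = TP/(TP+FP)`,
#' `F = 2PR/(P+R)`.  An undefined metric (zero denominator) is reported
#' as `NA`, not 0; `F` is 0 when precision and recall are both 0.
#'
#' @param counts A `confusion_counts` object (or list with `TP`, `FP`,
#'   `FN`).
#' @return Named numeric vector `precision`, `recall`, `fscore`.
#' @export
precision_recall_fscore <- function(counts) {
  TP <- counts$TP; FP <- counts$FP; FN <- counts$FN
  precision <- if (TP + FP > 0) TP / (TP + FP) else NA_real_
  recall <- if (TP + FN > 0) TP / (TP + FN) else NA_real_
  fscore <- if (is.na(precision) || is.na(recall)) {
    NA_real_
  } else if (precision + recall == 0) {
    0
  } else {
    2 * precision * recall / (precision + recall)
  }
  c(precision = precision, recall = recall, fscore = fscore)
}

#' Modified RV coefficient between two abundance matrices
#'
#' Correlation between the off-diagonal Gram matrices of `X` and `Y`:
#' with `S = XX' - diag(XX')` and `T = YY' - diag(YY')`, returns
#' `<vec S, vec T> / (||vec S|| ||vec T||)`, a value in `[-1, 1]`
#' interpretable like a Pearson correlation, sensitive to relative
#' abundances and not just presence/absence.  Rows are taxa (a single
#' composition is a one-column matrix); when both matrices carry
#' rownames the taxa axes are aligned by their union with zero fill.
#'
#' @param X,Y Numeric matrices (or named vectors, treated as one-column
#'   matrices) with rows = taxa.
#' @return The coefficient, or `NA` when either Gram matrix has zero
#'   off-diagonal norm.
#' @export
modified_rv <- function(X, Y) {
  X <- as_abundance_matrix(X)
  Y <- as_abundance_matrix(Y)
  if (!is.null(rownames(X)) && !is.null(rownames(Y))) {
    taxa <- union(rownames(X), rownames(Y))
    X <- fill_rows(X, taxa)
    Y <- fill_rows(Y, taxa)
  }
  if (nrow(X) != nrow(Y))
    stop("X and Y must have the same number of rows (taxa) after alignment")
  S <- tcrossprod(X); diag(S) <- 0
  T_ <- tcrossprod(Y); diag(T_) <- 0
  den <- sqrt(sum(S^2)) * sqrt(sum(T_^2))
  if (den == 0) return(NA_real_)
  sum(S * T_) / den
}

as_abundance_matrix <- function(x) {
  if (is.matrix(x)) return(x)
  m <- matrix(as.numeric(x), ncol = 1L)
  rownames(m) <- names(x)
  m
}

fill_rows <- function(m, taxa) {
  out <- matrix(0, nrow = length(taxa), ncol = ncol(m),
                dimnames = list(taxa, colnames(m)))
  out[rownames(m), ] <- m
  out
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("confusion counts: TP %d, FP %d, FN %d\n", x$TP, x$FP, x$FN))
  invisible(x)
}

#' Evaluate a predicted composition against a known one
#'
#' Convenience wrapper combining [confusion_from_compositions()],
#' [precision_recall_fscore()] and [modified_rv()] on abundance-labelled
#' tables.
#'
#' @param predicted,expected Data frames with columns `lineage` and
#'   `abundance`.
#' @param rank Rank for the binary-classifier comparison.
#' @return List with `counts`, `metrics` (precision/recall/fscore) and
#'   `modified_rv`.
#' @export
evaluate_composition <- function(predicted, expected, rank = "genus") {
  counts <- confusion_from_compositions(predicted, expected, rank)
  metrics <- precision_recall_fscore(counts)
  pa <- collapse_abundance(predicted, rank)
  ea <- collapse_abundance(expected, rank)
  rv <- modified_rv(pa, ea)
  list(counts = counts, metrics = metrics, modified_rv = rv)
}

collapse_abundance <- function(x, rank) {
  taxa <- split_lineage(x$lineage)[, match(rank, TAX_RANKS)]
  keep <- nzchar(taxa)
  v <- tapply(x$abundance[keep], taxa[keep], sum)
  stats::setNames(as.numeric(v), names(v))
}
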