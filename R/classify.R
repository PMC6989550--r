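TAX_RANKS <- c("domain", "phylum", "class", "order", "family", "genus",
               "species")

# Split a semicolon lineage into the 7 canonical ranks, padding with "".
split_lineage <- function(lineage) {
  parts <- strsplit(lineage, ";")
  t(vapply(parts, function(p) {
    p <- trimws(p)
    p[p == "_"] <- ""
    length(p) <- length(TAX_RANKS)
    p[is.na(p)] <- ""
    p
  }, character(length(TAX_RANKS))))
}

#' Collect reference hits for one ASV
#'
#' Computes the cumulative (forward + reverse) end-tolerant edit
#' distance between the ASV's sequences and every lookup-table entry,
#' bounded at `max_bound`; entries beyond the bound or with a mismatch
#' fraction above `max_mismatch_fraction` of the combined trimmed
#' length are dropped.  Hits are sorted by distance ascending, then by
#' entry count descending, and the full list is retained on the ASV
#' object as provenance.
#'
#' @param forward,reverse ASV sequences (use `""` for `reverse` in
#'   single-read mode).
#' @param table A `lookup_table`.
#' @param max_bound Edit-distance upper bound (default 50).
#' @param max_mismatch_fraction Maximum mismatch fraction (default
#'   0.15).
#' @return Data frame with columns `forward`, `reverse`, `lineage`,
#'   `count`, `distance`, `identity` (possibly zero rows).
#' @export
collect_hits <- function(forward, reverse = "", table, max_bound = 50L,
                         max_mismatch_fraction = 0.15) {
  if (!nrow(table)) stop("empty lookup table")
  if (is.na(reverse)) reverse <- ""
  total_len <- nchar(forward) + nchar(reverse)
  d <- vapply(seq_len(nrow(table)), function(j) {
    pair_distances(forward, reverse, table$forward[[j]],
                   table$reverse[[j]], max_bound)
  }, integer(1))
  keep <- !is.na(d) & d / total_len <= max_mismatch_fraction
  hits <- data.frame(forward = table$forward[keep],
                     reverse = table$reverse[keep],
                     lineage = table$lineage[keep],
                     count = table$count[keep],
                     distance = d[keep],
                     stringsAsFactors = FALSE)
  hits$identity <- 1 - hits$distance / total_len
  hits <- hits[order(hits$distance, -hits$count, hits$lineage), ,
               drop = FALSE]
  rownames(hits) <- NULL
  hits
}

empty_assignment <- function() {
  structure(list(lineage = stats::setNames(rep("", length(TAX_RANKS)),
                                           TAX_RANKS),
                 lowest_rank = "unassigned",
                 confidence = stats::setNames(numeric(0), character(0))),
            class = "taxonomic_assignment")
}

#' Assign taxonomy from a hit list
#'
#' Only hits at the minimal observed distance (the best stratum) vote.
#' The best identity caps the deepest assignable rank: a perfect match
#' allows species, but only when all best-stratum hits name one single
#' species; identity of at least 0.95 caps at genus, at least 0.92 at
#' family, and below 0.92 at order.  Walking from domain down to the
#' cap, each rank is assigned to the taxon whose reference-count weight
#' among best-stratum hits reaches `classify_ratio`, with that weighted
#' fraction as the per-rank confidence; the first rank failing the
#' ratio stops the walk (deeper ranks stay unassigned).
#'
#' @param hits Hit data frame from [collect_hits()].
#' @param classify_ratio Required count-weighted majority fraction per
#'   rank (default 0.8).
#' @return A `taxonomic_assignment`: list with `lineage` (named
#'   7-vector, unassigned ranks empty), `lowest_rank`, and per-rank
#'   `confidence` fractions.
#' @export
assign_taxonomy <- function(hits, classify_ratio = 0.8) {
  if (is.null(hits) || !nrow(hits)) return(empty_assignment())
  dmin <- min(hits$distance)
  best <- hits[hits$distance == dmin, , drop = FALSE]
  identity <- max(best$identity)
  ranks <- split_lineage(best$lineage)
  cap <- if (identity >= 1) {
    sp <- unique(ranks[, 7L])
    sp <- sp[nzchar(sp)]
    if (length(sp) == 1L && all(nzchar(ranks[, 7L]))) 7L else 6L
  } else if (identity >= 0.95) 6L else if (identity >= 0.92) 5L else 4L
  lineage <- stats::setNames(rep("", length(TAX_RANKS)), TAX_RANKS)
  confidence <- numeric(0)
  total_w <- sum(best$count)
  deepest <- 0L
  for (r in seq_len(cap)) {
    names_r <- ranks[, r]
    w <- tapply(best$count, names_r, sum)
    w <- w[nzchar(names(w))]
    if (!length(w)) break
    frac <- max(w) / total_w
    if (frac < classify_ratio) break
    top <- names(w)[[which.max(w)]]
    lineage[[r]] <- top
    confidence[[TAX_RANKS[[r]]]] <- unname(frac)
    deepest <- r
  }
  lowest <- if (deepest == 0L) "unassigned" else TAX_RANKS[[deepest]]
  structure(list(lineage = lineage, lowest_rank = lowest,
                 confidence = confidence),
            class = "taxonomic_assignment")
}

#' @export
print.taxonomic_assignment <- function(x, ...) {
  assigned <- x$lineage[nzchar(x$lineage)]
  if (!length(assigned)) {
    cat("taxonomic assignment: unassigned\n")
  } else {
    cat("taxonomic assignment (lowest rank ", x$lowest_rank, "):\n",
        sep = "")
    for (r in names(assigned))
      cat(sprintf("  %-7s %s (confidence %.3f)\n", r, assigned[[r]],
                  x$confidence[[r]]))
  }
  invisible(x)
}

#' Classify a sample's ASV objects
#'
#' All accepted ASVs are classified; provisionally rejected ASVs only
#' for the `max_classified_rejected` most abundant (ties broken
#' lexicographically); chimeric ASVs are not classified.
#'
#' @param asvs ASV data frame from [denoise_sample()].
#' @param table A `lookup_table`.
#' @param params A [denoise_params()] object (supplies
#'   `max_classified_rejected`).
#' @param classify_ratio Passed to [assign_taxonomy()].
#' @param max_bound,max_mismatch_fraction Passed to [collect_hits()].
#' @return The ASV data frame with list-columns `hits` and
#'   `assignment` added (`NULL` entries where not classified).
#' @export
classify_sample <- function(asvs, table, params = denoise_params(),
                            classify_ratio = 0.8, max_bound = 50L,
                            max_mismatch_fraction = 0.15) {
  asvs$hits <- I(rep(list(NULL), nrow(asvs)))
  asvs$assignment <- I(rep(list(NULL), nrow(asvs)))
  if (!nrow(asvs)) return(asvs)
  eligible <- which(asvs$status == "accepted")
  rej <- which(asvs$status == "provisionally_rejected")
  if (length(rej) > params$max_classified_rejected) {
    ord <- rej[order(-asvs$read_count[rej], asvs$forward[rej],
                     asvs$reverse[rej])]
    rej <- ord[seq_len(params$max_classified_rejected)]
  }
  for (i in c(eligible, rej)) {
    hits <- collect_hits(asvs$forward[[i]], asvs$reverse[[i]], table,
                         max_bound, max_mismatch_fraction)
    asvs$hits[[i]] <- hits
    asvs$assignment[[i]] <- assign_taxonomy(hits, classify_ratio)
  }
  asvs
}
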