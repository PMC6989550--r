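#' Denoising parameters
#'
#' Parameters of the two-step, abundance-based error model.
#'
#' @param min_identical Minimum number of identical forward+reverse
#'   pairs that form an initial ASV object (default 3).
#' @param min_percent_threshold Relative-abundance threshold for the
#'   merge step, in percent of the total reads associated with ASVs
#'   (default 0.1, i.e. 0.1%).
#' @param error_correction_distance Maximum cumulative edit distance
#'   (forward + reverse combined) treated as a sequencing error in
#'   singleton rescue and ASV merging (default 1).
#' @param identity_level Percent identity for ASV formation; only 100
#'   (exact matching) is supported.
#' @param max_classified_rejected How many of the most abundant
#'   provisionally rejected ASVs also receive a taxonomic assignment
#'   (default 100).
#' @return A `denoise_params` list.
#' @export
denoise_params <- function(min_identical = 3L,
                           min_percent_threshold = 0.1,
                           error_correction_distance = 1L,
                           identity_level = 100,
                           max_classified_rejected = 100L) {
  stopifnot(min_identical >= 0, min_percent_threshold >= 0,
            min_percent_threshold < 100,
            error_correction_distance >= 0,
            max_classified_rejected >= 0)
  if (identity_level != 100)
    stop("only identity_level = 100 (exact-match ASV formation) is supported")
  structure(list(min_identical = as.integer(min_identical),
                 min_percent_threshold = min_percent_threshold,
                 error_correction_distance = as.integer(error_correction_distance),
                 identity_level = 100,
                 max_classified_rejected = as.integer(max_classified_rejected)),
            class = "denoise_params")
}

empty_asv_table <- function(sample_id = character(0)) {
  data.frame(sample_id = sample_id[0], forward = character(0),
             reverse = character(0), read_count = integer(0),
             status = character(0), rescued_count = integer(0),
             merged_from = I(list()), stringsAsFactors = FALSE)
}

# Deterministic ASV ordering: read_count descending, then lexicographic
# (forward, reverse).
order_asvs <- function(asvs) {
  order(-asvs$read_count, asvs$forward, asvs$reverse)
}

#' Form initial ASV objects from exact read-pair matches
#'
#' Groups a sample's read pairs by exact (forward, reverse) sequence;
#' groups of at least `min_identical` pairs become ASV objects with the
#' group size as read count, and all pairs from smaller groups are
#' returned individually as residuals for singleton rescue.
#'
#' @param pairs Data frame with columns `sample_id`, `forward`,
#'   `reverse` (the `reverse` column may be `NA` in single-read mode).
#' @param params A [denoise_params()] object.
#' @return List with `asvs` (ASV data frame) and `residuals` (read-pair
#'   data frame).
#' @export
pick_initial_asvs <- function(pairs, params = denoise_params()) {
  if (!nrow(pairs))
    return(list(asvs = empty_asv_table(), residuals = pairs))
  sample_id <- unique(pairs$sample_id)
  stopifnot(length(sample_id) == 1L)
  rev <- if (all(is.na(pairs$reverse))) rep("", nrow(pairs)) else pairs$reverse
  key <- paste(pairs$forward, rev, sep = "\r")
  counts <- table(key)
  big <- names(counts)[counts >= params$min_identical]
  split_big <- strsplit(big, "\r", fixed = TRUE)
  fwd <- vapply(split_big, `[`, "", 1L)
  rvs <- vapply(split_big, function(x) if (length(x) > 1L) x[[2]] else "", "")
  asvs <- data.frame(sample_id = rep(sample_id, length(big)),
                     forward = fwd, reverse = rvs,
                     read_count = as.integer(counts[big]),
                     status = rep(NA_character_, length(big)),
                     rescued_count = integer(length(big)),
                     merged_from = I(rep(list(NULL), length(big))),
                     stringsAsFactors = FALSE)
  asvs <- asvs[order(asvs$forward, asvs$reverse), , drop = FALSE]
  rownames(asvs) <- NULL
  residuals <- pairs[!(key %in% big), , drop = FALSE]
  rownames(residuals) <- NULL
  list(asvs = asvs, residuals = residuals)
}

#' Rescue residual read pairs into existing ASV objects
#'
#' Each residual pair is compared to every ASV by cumulative
#' end-tolerant edit distance (forward + reverse).  A pair within
#' `error_correction_distance` of some ASV is absorbed into the closest
#' one (ties broken toward the more abundant ASV, then
#' lexicographically), incrementing its read count but leaving its
#' sequences unchanged; pairs farther from every ASV are discarded as
#' sample-specific noise.
#'
#' @param asvs ASV data frame from [pick_initial_asvs()].
#' @param residuals Residual read-pair data frame.
#' @inheritParams pick_initial_asvs
#' @return List with updated `asvs` and integer `discarded`.
#' @export
rescue_singletons <- function(asvs, residuals, params = denoise_params()) {
  if (!nrow(residuals) || !nrow(asvs))
    return(list(asvs = asvs, discarded = nrow(residuals)))
  k <- params$error_correction_distance
  rev <- residuals$reverse
  rev[is.na(rev)] <- ""
  # distance matrix: residuals x asvs, NA where > k
  dmat <- vapply(seq_len(nrow(asvs)), function(j) {
    pair_distances(residuals$forward, rev,
                   asvs$forward[[j]], asvs$reverse[[j]], k)
  }, integer(nrow(residuals)))
  dmat <- matrix(dmat, nrow = nrow(residuals))
  pref <- order_asvs(asvs)  # tie-break preference
  discarded <- 0L
  for (i in seq_len(nrow(residuals))) {
    d <- dmat[i, ]
    if (all(is.na(d))) { discarded <- discarded + 1L; next }
    dmin <- min(d, na.rm = TRUE)
    cand <- pref[pref %in% which(!is.na(d) & d == dmin)][[1]]
    asvs$read_count[[cand]] <- asvs$read_count[[cand]] + 1L
    asvs$rescued_count[[cand]] <- asvs$rescued_count[[cand]] + 1L
  }
  list(asvs = asvs, discarded = discarded)
}

#' Merge erroneous low-abundance ASV objects
#'
#' The merge threshold is `min_percent_threshold` percent of the total
#' reads associated with the sample's ASVs.  ASVs are ranked by read
#' count (descending; ties lexicographic); each below-threshold ASV is
#' compared against the above-threshold ASVs in rank order and absorbed
#' by the first one within `error_correction_distance` (cumulative,
#' forward + reverse): counts sum, the abundant ASV keeps its
#' sequences, and the absorbed triple is recorded in `merged_from`.
#' Below-threshold ASVs that merge nowhere are labelled
#' `provisionally_rejected` but retained; above-threshold ASVs become
#' `accepted`.  The threshold and ranking are computed once
#' (single-pass), so absorption does not re-rank.
#'
#' @inheritParams rescue_singletons
#' @return The ASV data frame with statuses set and merged ASVs
#'   absorbed.
#' @export
merge_error_asvs <- function(asvs, params = denoise_params()) {
  if (!nrow(asvs)) return(asvs)
  total <- sum(asvs$read_count)
  threshold <- params$min_percent_threshold / 100 * total
  high <- asvs$read_count >= threshold
  ord <- order_asvs(asvs)
  high_rank <- ord[ord %in% which(high)]
  low_rank <- ord[ord %in% which(!high)]
  k <- params$error_correction_distance
  absorbed <- logical(nrow(asvs))
  asvs$status[high] <- "accepted"
  for (i in low_rank) {
    merged <- FALSE
    for (j in high_rank) {
      d <- pair_distances(asvs$forward[[i]], asvs$reverse[[i]],
                          asvs$forward[[j]], asvs$reverse[[j]], k)
      if (!is.na(d)) {
        asvs$merged_from[[j]] <- c(asvs$merged_from[[j]],
                                   list(list(forward = asvs$forward[[i]],
                                             reverse = asvs$reverse[[i]],
                                             count = asvs$read_count[[i]])))
        asvs$read_count[[j]] <- asvs$read_count[[j]] + asvs$read_count[[i]]
        absorbed[[i]] <- TRUE
        merged <- TRUE
        break
      }
    }
    if (!merged) asvs$status[[i]] <- "provisionally_rejected"
  }
  out <- asvs[!absorbed, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Flag chimeric ASV objects
#'
#' An ASV is chimeric when its forward sequence is identical to one
#' ASV's forward and its reverse sequence to a *different* ASV's
#' reverse, within the same sample, and both of those ASVs have at
#' least twice its read count.  Chimeric ASVs are excluded from
#' classification and abundance tables but retained in serialized
#' output.  Runs on accepted and provisionally rejected ASVs; disabled
#' (no-op) in single-read mode.
#'
#' @inheritParams rescue_singletons
#' @return The ASV data frame with `status` set to `"chimeric"` where
#'   the rule fires.
#' @export
detect_chimeras <- function(asvs) {
  if (!nrow(asvs)) return(asvs)
  if (all(!nzchar(asvs$reverse))) {
    message("single-read mode: chimera detection skipped")
    return(asvs)
  }
  n <- nrow(asvs)
  chim <- logical(n)
  for (i in seq_len(n)) {
    a_idx <- which(asvs$forward == asvs$forward[[i]] &
                     seq_len(n) != i &
                     asvs$read_count >= 2L * asvs$read_count[[i]])
    if (!length(a_idx)) next
    b_idx <- which(asvs$reverse == asvs$reverse[[i]] &
                     seq_len(n) != i &
                     asvs$read_count >= 2L * asvs$read_count[[i]])
    # two *different* parent ASVs must exist
    if (any(outer(a_idx, b_idx, `!=`))) chim[[i]] <- TRUE
  }
  asvs$status[chim] <- "chimeric"
  asvs
}

#' Denoise one sample end to end
#'
#' Runs [pick_initial_asvs()], [rescue_singletons()],
#' [merge_error_asvs()] and [detect_chimeras()] in order.
#'
#' @inheritParams pick_initial_asvs
#' @return List with `asvs`, `discarded` (residual pairs dropped in
#'   rescue) and `n_input` (pairs entering ASV formation).
#' @export
denoise_sample <- function(pairs, params = denoise_params()) {
  picked <- pick_initial_asvs(pairs, params)
  rescued <- rescue_singletons(picked$asvs, picked$residuals, params)
  asvs <- merge_error_asvs(rescued$asvs, params)
  asvs <- detect_chimeras(asvs)
  list(asvs = asvs, discarded = rescued$discarded, n_input = nrow(pairs))
}
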