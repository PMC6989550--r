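ONTOLOGY_IRI <- "http://asvgraph.org/ontology#"
RESOURCE_IRI <- "http://asvgraph.org/resource/"

STATUS_CLASS <- c(accepted = "ASVSet",
                  provisionally_rejected = "RejectedASVSet",
                  chimeric = "RejectedAsChimera")

canon_json <- function(x) {
  as.character(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA,
                                null = "null"))
}

#' Build a provenance-linked library graph
#'
#' Assembles the full analysis of one sequencing library — samples,
#' their denoised and classified ASV objects, primers, barcodes and
#' the complete command arguments — into a single serializable object.
#' Samples are kept sorted by sample id and ASVs by (forward, reverse)
#' sequence so that identical analyses produce identical graphs.
#'
#' @param library_id Library identifier.
#' @param command_args Named list of the run parameters (stored
#'   completely, so the run can be repeated).
#' @param samples Named list; each element a list with `sample_id`,
#'   `asvs` (classified ASV data frame from [classify_sample()]),
#'   optional `metadata` (named character), `forward_barcode`,
#'   `reverse_barcode`, `forward_primer`, `reverse_primer`.
#' @return A `library_graph` object.
#' @export
build_library_graph <- function(library_id, command_args, samples) {
  samples <- lapply(samples, function(s) {
    asvs <- s$asvs
    n <- nrow(asvs)
    flat <- data.frame(
      forward = asvs$forward, reverse = asvs$reverse,
      read_count = as.integer(asvs$read_count),
      status = asvs$status,
      rescued_count = as.integer(asvs$rescued_count),
      merged_from_json = vapply(seq_len(n), function(i)
        canon_json(asvs$merged_from[[i]]), ""),
      taxonomy = vapply(seq_len(n), function(i) {
        a <- if ("assignment" %in% names(asvs)) asvs$assignment[[i]] else NULL
        if (is.null(a)) "" else paste(a$lineage, collapse = ";")
      }, ""),
      lowest_rank = vapply(seq_len(n), function(i) {
        a <- if ("assignment" %in% names(asvs)) asvs$assignment[[i]] else NULL
        if (is.null(a)) "" else a$lowest_rank
      }, ""),
      confidence_json = vapply(seq_len(n), function(i) {
        a <- if ("assignment" %in% names(asvs)) asvs$assignment[[i]] else NULL
        if (is.null(a)) "null" else canon_json(as.list(a$confidence))
      }, ""),
      hits_json = vapply(seq_len(n), function(i) {
        h <- if ("hits" %in% names(asvs)) asvs$hits[[i]] else NULL
        if (is.null(h)) "null" else canon_json(h)
      }, ""),
      stringsAsFactors = FALSE)
    flat <- flat[order(flat$forward, flat$reverse), , drop = FALSE]
    rownames(flat) <- NULL
    meta <- if (is.null(s$metadata)) list() else as.list(s$metadata)
    list(sample_id = s$sample_id,
         metadata_json = canon_json(meta),
         forward_barcode = s$forward_barcode %||% "",
         reverse_barcode = s$reverse_barcode %||% "",
         forward_primer = as.character(s$forward_primer %||% ""),
         reverse_primer = as.character(s$reverse_primer %||% ""),
         asvs = flat)
  })
  ids <- vapply(samples, `[[`, "", "sample_id")
  samples <- samples[order(ids)]
  names(samples) <- sort(ids)
  structure(list(library_id = library_id,
                 command_args_json = canon_json(command_args),
                 samples = samples),
            class = "library_graph")
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1 && is.na(a))) b else a

#' Command arguments stored in a graph
#'
#' @param graph A `library_graph`.
#' @return The parsed command-argument list.
#' @export
command_args <- function(graph) {
  jsonlite::fromJSON(graph$command_args_json, simplifyVector = TRUE)
}

#' @export
print.library_graph <- function(x, ...) {
  cat(sprintf("library graph '%s': %d sample(s)\n", x$library_id,
              length(x$samples)))
  for (s in x$samples) {
    tab <- table(factor(s$asvs$status, levels = names(STATUS_CLASS)))
    cat(sprintf("  %s: %d accepted, %d provisionally rejected, %d chimeric\n",
                s$sample_id, tab[["accepted"]],
                tab[["provisionally_rejected"]], tab[["chimeric"]]))
  }
  invisible(x)
}

iri_safe <- function(x) {
  safe <- gsub("[^A-Za-z0-9_]", "_", x)
  ifelse(safe == x, safe,
         paste0(safe, "_", substr(vapply(x, digest::digest, "",
                                         algo = "sha1"), 1, 8)))
}

ttl_escape <- function(x) {
  x <- gsub("\\", "\\\\", x, fixed = TRUE)
  x <- gsub("\"", "\\\"", x, fixed = TRUE)
  x <- gsub("\n", "\\n", x, fixed = TRUE)
  x <- gsub("\r", "\\r", x, fixed = TRUE)
  x <- gsub("\t", "\\t", x, fixed = TRUE)
  x
}

ttl_unescape <- function(x) {
  out <- character(length(x))
  for (i in seq_along(x)) {
    s <- x[[i]]
    res <- character(0)
    j <- 1L
    n <- nchar(s)
    while (j <= n) {
      ch <- substr(s, j, j)
      if (ch == "\\" && j < n) {
        nxt <- substr(s, j + 1L, j + 1L)
        res <- c(res, switch(nxt, n = "\n", r = "\r", t = "\t",
                             "\\" = "\\", "\"" = "\"", nxt))
        j <- j + 2L
      } else {
        res <- c(res, ch)
        j <- j + 1L
      }
    }
    out[[i]] <- paste(res, collapse = "")
  }
  out
}

asv_node_id <- function(sample_id, forward, reverse) {
  paste0("Asv_", digest::digest(paste(sample_id, forward, reverse,
                                      sep = "\r"), algo = "sha1"))
}

seq_node_id <- function(seq) {
  paste0("Seq_", digest::digest(seq, algo = "sha1"))
}

#' Export a library graph as Turtle (RDF)
#'
#' Emits one triple per line under a single project namespace; class
#' names are UpperCamelCase and properties lowerCamelCase.  Accepted
#' ASVs are typed `ASVSet`, provisionally rejected ones
#' `RejectedASVSet`, chimeric ones `RejectedAsChimera`; forward and
#' reverse sequences are shared `Sequence` nodes, assignments are
#' `ASVAssignment` nodes, and the command arguments travel both on the
#' `Library` node and through the
#' `Provenance`/`ProvenanceClassification` chain.  The output is plain
#' Turtle, loadable into any triple store.
#'
#' @param graph A `library_graph`.
#' @param path Output path (`.ttl`).
#' @return `path`, invisibly.
#' @seealso [read_rdf()] for the lossless inverse.
#' @export
export_rdf <- function(graph, path) {
  L <- paste0("res:Library_", iri_safe(graph$library_id))
  out <- c(sprintf("@prefix ag: <%s> .", ONTOLOGY_IRI),
           sprintf("@prefix res: <%s> .", RESOURCE_IRI),
           "")
  lit <- function(x) sprintf("\"%s\"", ttl_escape(x))
  tr <- function(s, p, o) sprintf("%s %s %s .", s, p, o)
  out <- c(out,
           tr(L, "a", "ag:Library"),
           tr(L, "ag:libraryId", lit(graph$library_id)),
           tr(L, "ag:commandArgs", lit(graph$command_args_json)))
  prov <- paste0("res:Provenance_", iri_safe(graph$library_id))
  provc <- paste0("res:ProvClass_", iri_safe(graph$library_id))
  out <- c(out,
           tr(L, "ag:hasProvenance", prov),
           tr(prov, "a", "ag:Provenance"),
           tr(prov, "ag:hasClassification", provc),
           tr(provc, "a", "ag:ProvenanceClassification"),
           tr(provc, "ag:commandArgs", lit(graph$command_args_json)))
  for (s in graph$samples) {
    meta <- jsonlite::fromJSON(s$metadata_json, simplifyVector = FALSE)
    bad <- vapply(meta, function(v)
      !(is.character(v) || is.numeric(v) || is.logical(v)) ||
        length(v) != 1L, NA)
    if (any(bad))
      stop("unserializable metadata value for sample '", s$sample_id,
           "', key '", names(meta)[bad][[1]], "'")
    S <- paste0("res:Sample_", iri_safe(s$sample_id))
    P <- paste0("res:PrimerSet_", iri_safe(s$sample_id))
    B <- paste0("res:BarcodeSet_", iri_safe(s$sample_id))
    out <- c(out,
             tr(L, "ag:hasSample", S),
             tr(S, "a", "ag:Sample"),
             tr(S, "ag:sampleId", lit(s$sample_id)),
             tr(S, "ag:metadata", lit(s$metadata_json)),
             tr(S, "ag:hasPrimerSet", P),
             tr(P, "a", "ag:PCRPrimerSet"),
             tr(P, "ag:forwardPrimer", lit(s$forward_primer)),
             tr(P, "ag:reversePrimer", lit(s$reverse_primer)),
             tr(S, "ag:hasBarcodeSet", B),
             tr(B, "a", "ag:BarcodeSet"),
             tr(B, "ag:forwardBarcode", lit(s$forward_barcode)),
             tr(B, "ag:reverseBarcode", lit(s$reverse_barcode)))
    a <- s$asvs
    for (i in seq_len(nrow(a))) {
      A <- paste0("res:", asv_node_id(s$sample_id, a$forward[[i]],
                                      a$reverse[[i]]))
      Ff <- paste0("res:", seq_node_id(a$forward[[i]]))
      Rr <- paste0("res:", seq_node_id(a$reverse[[i]]))
      AS <- paste0(A, "_assignment")
      out <- c(out,
               tr(S, "ag:hasAsv", A),
               tr(A, "a", paste0("ag:", STATUS_CLASS[[a$status[[i]]]])),
               tr(A, "ag:forwardSequence", Ff),
               tr(Ff, "a", "ag:Sequence"),
               tr(Ff, "ag:sequence", lit(a$forward[[i]])),
               tr(A, "ag:reverseSequence", Rr),
               tr(Rr, "a", "ag:Sequence"),
               tr(Rr, "ag:sequence", lit(a$reverse[[i]])),
               tr(A, "ag:readCount", a$read_count[[i]]),
               tr(A, "ag:rescuedCount", a$rescued_count[[i]]),
               tr(A, "ag:mergedFrom", lit(a$merged_from_json[[i]])),
               tr(A, "ag:hasAssignment", AS),
               tr(AS, "a", "ag:ASVAssignment"),
               tr(AS, "ag:taxonLineage", lit(a$taxonomy[[i]])),
               tr(AS, "ag:lowestRank", lit(a$lowest_rank[[i]])),
               tr(AS, "ag:confidence", lit(a$confidence_json[[i]])),
               tr(AS, "ag:hitList", lit(a$hits_json[[i]])))
    }
  }
  writeLines(out, path)
  invisible(path)
}

parse_turtle_lines <- function(lines) {
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "@prefix")]
  s <- sub("^(\\S+)\\s.*$", "\\1", lines)
  rest <- sub("^\\S+\\s+", "", lines)
  p <- sub("^(\\S+)\\s.*$", "\\1", rest)
  o <- sub("^\\S+\\s+", "", rest)
  o <- sub("\\s*\\.$", "", o)
  is_lit <- startsWith(o, "\"")
  o[is_lit] <- ttl_unescape(substr(o[is_lit], 2L, nchar(o[is_lit]) - 1L))
  # triples are a set: shared nodes (e.g. Sequence) may be re-emitted
  unique(data.frame(s = s, p = p, o = o, literal = is_lit,
                    stringsAsFactors = FALSE))
}

#' Read a Turtle file written by [export_rdf()]
#'
#' Reconstructs the `library_graph`, losslessly, from the emitted
#' triple subset (one triple per line).
#'
#' @param path Turtle path.
#' @return A `library_graph`.
#' @export
read_rdf <- function(path) {
  tp <- parse_turtle_lines(readLines(path))
  obj_of <- function(s, p) tp$o[tp$s == s & tp$p == p]
  lib <- tp$s[tp$p == "a" & tp$o == "ag:Library"]
  if (length(lib) != 1L) stop("expected exactly one Library node")
  samples <- list()
  for (S in obj_of(lib, "ag:hasSample")) {
    sid <- obj_of(S, "ag:sampleId")
    P <- obj_of(S, "ag:hasPrimerSet")
    B <- obj_of(S, "ag:hasBarcodeSet")
    asv_nodes <- obj_of(S, "ag:hasAsv")
    rows <- lapply(asv_nodes, function(A) {
      cls <- tp$o[tp$s == A & tp$p == "a"]
      AS <- obj_of(A, "ag:hasAssignment")
      data.frame(
        forward = obj_of(obj_of(A, "ag:forwardSequence"), "ag:sequence"),
        reverse = obj_of(obj_of(A, "ag:reverseSequence"), "ag:sequence"),
        read_count = as.integer(obj_of(A, "ag:readCount")),
        status = names(STATUS_CLASS)[[match(sub("^ag:", "", cls),
                                            STATUS_CLASS)]],
        rescued_count = as.integer(obj_of(A, "ag:rescuedCount")),
        merged_from_json = obj_of(A, "ag:mergedFrom"),
        taxonomy = obj_of(AS, "ag:taxonLineage"),
        lowest_rank = obj_of(AS, "ag:lowestRank"),
        confidence_json = obj_of(AS, "ag:confidence"),
        hits_json = obj_of(AS, "ag:hitList"),
        stringsAsFactors = FALSE)
    })
    asvs <- if (length(rows)) do.call(rbind, rows) else
      data.frame(forward = character(0), reverse = character(0),
                 read_count = integer(0), status = character(0),
                 rescued_count = integer(0),
                 merged_from_json = character(0), taxonomy = character(0),
                 lowest_rank = character(0), confidence_json = character(0),
                 hits_json = character(0), stringsAsFactors = FALSE)
    asvs <- asvs[order(asvs$forward, asvs$reverse), , drop = FALSE]
    rownames(asvs) <- NULL
    samples[[sid]] <- list(sample_id = sid,
                           metadata_json = obj_of(S, "ag:metadata"),
                           forward_barcode = obj_of(B, "ag:forwardBarcode"),
                           reverse_barcode = obj_of(B, "ag:reverseBarcode"),
                           forward_primer = obj_of(P, "ag:forwardPrimer"),
                           reverse_primer = obj_of(P, "ag:reversePrimer"),
                           asvs = asvs)
  }
  samples <- samples[order(names(samples))]
  structure(list(library_id = obj_of(lib, "ag:libraryId"),
                 command_args_json = obj_of(lib, "ag:commandArgs"),
                 samples = samples),
            class = "library_graph")
}

#' Export a library graph as extended BIOM 1.0 JSON
#'
#' Writes a sparse BIOM 1.0 "OTU table" (rows = distinct accepted and
#' provisionally rejected ASV sequence pairs, columns = samples, cells
#' = read counts) that standard BIOM readers accept, extended with a
#' top-level `"args"` object holding the complete command arguments
#' and per-row metadata carrying the forward/reverse sequences, the
#' taxonomy list, per-rank confidence scores and the ASV status.
#' Stripping the extensions leaves a plain BIOM 1.0 document.
#'
#' @param graph A `library_graph`.
#' @param path Output path (`.biom`/`.json`).
#' @param date Optional ISO-8601 timestamp; injectable so reruns are
#'   byte-identical.
#' @return `path`, invisibly.
#' @export
export_biom <- function(graph, path, date = NULL) {
  doc <- biom_document(graph, date)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

biom_document <- function(graph, date = NULL) {
  keep_status <- c("accepted", "provisionally_rejected")
  keys <- list()
  for (s in graph$samples) {
    a <- s$asvs[s$asvs$status %in% keep_status, , drop = FALSE]
    for (i in seq_len(nrow(a)))
      keys[[paste(a$forward[[i]], a$reverse[[i]], sep = "\r")]] <- TRUE
  }
  keys <- sort(names(keys))
  nrows <- length(keys)
  sids <- names(graph$samples)
  counts <- matrix(0L, nrow = nrows, ncol = length(sids),
                   dimnames = list(keys, sids))
  best_count <- stats::setNames(rep(-1L, nrows), keys)
  row_meta <- stats::setNames(vector("list", nrows), keys)
  status_any <- stats::setNames(rep("provisionally_rejected", nrows), keys)
  for (s in graph$samples) {
    a <- s$asvs[s$asvs$status %in% keep_status, , drop = FALSE]
    for (i in seq_len(nrow(a))) {
      key <- paste(a$forward[[i]], a$reverse[[i]], sep = "\r")
      counts[key, s$sample_id] <- a$read_count[[i]]
      if (a$status[[i]] == "accepted") status_any[[key]] <- "accepted"
      if (a$read_count[[i]] > best_count[[key]]) {
        best_count[[key]] <- a$read_count[[i]]
        tax <- strsplit(a$taxonomy[[i]], ";", fixed = TRUE)[[1]]
        length(tax) <- length(TAX_RANKS)
        tax[is.na(tax)] <- ""
        conf <- jsonlite::fromJSON(a$confidence_json[[i]],
                                   simplifyVector = TRUE)
        row_meta[[key]] <- list(
          taxonomy = as.list(tax),
          confidence = if (is.null(conf)) list() else as.list(conf),
          forward_sequence = a$forward[[i]],
          reverse_sequence = a$reverse[[i]])
      }
    }
  }
  rows <- lapply(keys, function(k) {
    m <- row_meta[[k]]
    m$status <- status_any[[k]]
    list(id = paste0("asv_", substr(digest::digest(k, algo = "sha1"),
                                    1, 16)),
         metadata = m)
  })
  cols <- lapply(graph$samples, function(s) {
    meta <- jsonlite::fromJSON(s$metadata_json, simplifyVector = TRUE)
    list(id = s$sample_id,
         metadata = if (length(meta)) as.list(meta) else NULL)
  })
  nz <- which(counts != 0, arr.ind = TRUE)
  data <- lapply(seq_len(nrow(nz)), function(i)
    c(nz[i, 1] - 1L, nz[i, 2] - 1L, counts[nz[i, 1], nz[i, 2]]))
  data <- data[order(vapply(data, `[`, 0, 1), vapply(data, `[`, 0, 2))]
  list(id = graph$library_id,
       format = "Biological Observation Matrix 1.0.0",
       format_url = "http://biom-format.org",
       type = "OTU table",
       generated_by = paste0("asvgraph ",
                             as.character(utils::packageVersion("asvgraph"))),
       date = date %||% format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
       matrix_type = "sparse",
       matrix_element_type = "int",
       shape = c(nrows, length(sids)),
       rows = rows,
       columns = unname(cols),
       data = data,
       args = jsonlite::fromJSON(graph$command_args_json,
                                 simplifyVector = TRUE))
}

#' Structural validation of a BIOM 1.0 JSON document
#'
#' Checks the required top-level fields, types, shape consistency and
#' sparse-triple index ranges of the BIOM 1.0 (JSON) format.
#'
#' @param x Path to a BIOM file or an already-parsed list.
#' @return Invisibly `TRUE`; problems raise an error describing the
#'   first violation.
#' @export
validate_biom <- function(x) {
  doc <- if (is.character(x)) jsonlite::fromJSON(x, simplifyVector = FALSE)
         else x
  need <- c("id", "format", "format_url", "type", "generated_by", "date",
            "matrix_type", "matrix_element_type", "shape", "rows",
            "columns", "data")
  miss <- setdiff(need, names(doc))
  if (length(miss)) stop("missing BIOM field(s): ",
                         paste(miss, collapse = ", "))
  if (!grepl("^Biological Observation Matrix 1\\.0", doc$format))
    stop("format is not BIOM 1.0")
  shape <- unlist(doc$shape)
  if (length(shape) != 2L) stop("shape must have two entries")
  if (length(doc$rows) != shape[[1]]) stop("rows length != shape[1]")
  if (length(doc$columns) != shape[[2]]) stop("columns length != shape[2]")
  ids <- vapply(doc$rows, function(r) as.character(r$id), "")
  if (anyDuplicated(ids)) stop("duplicate row ids")
  if (!doc$matrix_type %in% c("sparse", "dense"))
    stop("matrix_type must be sparse or dense")
  if (doc$matrix_type == "sparse") {
    for (trip in doc$data) {
      trip <- unlist(trip)
      if (length(trip) != 3L) stop("sparse data entries must be triples")
      if (trip[[1]] < 0 || trip[[1]] >= shape[[1]] ||
          trip[[2]] < 0 || trip[[2]] >= shape[[2]])
        stop("sparse index out of range")
    }
  }
  invisible(TRUE)
}

collect_asv_keys <- function(graphs, statuses) {
  if (inherits(graphs, "library_graph")) graphs <- list(graphs)
  out <- list()
  for (g in graphs) {
    for (s in g$samples) {
      a <- s$asvs[s$asvs$status %in% statuses, , drop = FALSE]
      if (nrow(a))
        out[[length(out) + 1L]] <- data.frame(
          sample_id = s$sample_id, forward = a$forward,
          reverse = a$reverse, stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(sample_id = character(0), forward = character(0),
                      reverse = character(0), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

graph_sample_ids <- function(graphs) {
  if (inherits(graphs, "library_graph")) graphs <- list(graphs)
  unlist(lapply(graphs, function(g) names(g$samples)))
}

#' Presence of accepted ASV sequence pairs across samples
#'
#' For every accepted ASV (forward, reverse) pair in the given
#' graph(s), reports which of the requested samples contain an ASV
#' with identical forward *and* reverse sequence — the cross-sample
#' tracking query.
#'
#' @param graphs A `library_graph` or list of them.
#' @param sample_ids Samples to query (default: all).
#' @return Data frame with `forward`, `reverse`, one logical column per
#'   requested sample, and `n_samples`.
#' @export
shared_asvs <- function(graphs, sample_ids = NULL) {
  all_ids <- graph_sample_ids(graphs)
  if (is.null(sample_ids)) sample_ids <- all_ids
  unknown <- setdiff(sample_ids, all_ids)
  if (length(unknown))
    stop("unknown sample_id(s): ", paste(unknown, collapse = ", "))
  acc <- collect_asv_keys(graphs, "accepted")
  acc <- acc[acc$sample_id %in% sample_ids, , drop = FALSE]
  key <- paste(acc$forward, acc$reverse, sep = "\r")
  ukey <- sort(unique(key))
  pres <- matrix(FALSE, nrow = length(ukey), ncol = length(sample_ids),
                 dimnames = list(ukey, sample_ids))
  if (nrow(acc)) pres[cbind(key, acc$sample_id)] <- TRUE
  parts <- strsplit(ukey, "\r", fixed = TRUE)
  out <- data.frame(
    forward = vapply(parts, `[`, "", 1L),
    reverse = vapply(parts, function(x) if (length(x) > 1L) x[[2]] else "",
                     ""),
    stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(pres, optional = TRUE))
  out$n_samples <- rowSums(pres)
  rownames(out) <- NULL
  out
}

#' Recurrence rate of provisionally rejected ASVs
#'
#' Fraction of distinct provisionally rejected (forward, reverse)
#' pairs that occur — as rejected or accepted — in at least
#' `min_samples` samples; low values indicate that flagged ASVs are
#' mostly sample-specific noise.
#'
#' @param graphs A `library_graph` or list of them.
#' @param min_samples Minimum number of samples (default 2).
#' @return The fraction, or `NA` when there are no rejected ASVs.
#' @export
rejected_recurrence <- function(graphs, min_samples = 2L) {
  ids <- graph_sample_ids(graphs)
  if (length(ids) < min_samples)
    stop("need at least min_samples samples")
  rej <- collect_asv_keys(graphs, "provisionally_rejected")
  if (!nrow(rej)) return(NA_real_)
  both <- collect_asv_keys(graphs, c("accepted", "provisionally_rejected"))
  key_all <- paste(both$forward, both$reverse, sep = "\r")
  per_pair <- tapply(both$sample_id, key_all,
                     function(s) length(unique(s)))
  rkeys <- unique(paste(rej$forward, rej$reverse, sep = "\r"))
  mean(per_pair[rkeys] >= min_samples)
}
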