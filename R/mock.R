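#' Mock community specification
#'
#' Describes a synthetic mock community in the style of the public
#' Mockrobiota benchmarks: a known set of 16S-like reference templates
#' with either an even or a staggered (log-spaced over three orders of
#' magnitude) abundance profile, sequenced with configurable per-base
#' error and chimera rates.  All randomness flows from the single
#' `seed`; the same spec produces byte-identical outputs.
#'
#' @param n_taxa Number of taxa (default 20).
#' @param distribution `"even"` or `"staggered"`.
#' @param reads_per_sample Read pairs per sample (default 20000, i.e.
#'   1000 per taxon for the default even mock).
#' @param substitution_rate,insertion_rate,deletion_rate Per-base error
#'   probabilities in `[0, 0.1]`.
#' @param chimera_fraction Fraction of read pairs whose forward read is
#'   drawn from one template and reverse read from another.
#' @param multicopy Named list mapping a taxon index (as character) to
#'   a number of near-identical template variants, emulating
#'   multi-copy 16S operons (e.g. `list("3" = 2)`).
#' @param seed Integer seed driving all randomness.
#' @param for_read_len,rev_read_len Trimmed read lengths (default
#'   70/70).
#' @param forward_primer,reverse_primer Degenerate primers (defaults:
#'   515F/806R-style).
#' @param region_len Length of the amplified region between the
#'   primers (default 253).
#' @param template_len Full template length (default 1500).
#' @param barcode_len Sample barcode length (default 8).
#' @return A `mock_spec` list.
#' @export
mock_spec <- function(n_taxa = 20L, distribution = c("even", "staggered"),
                      reads_per_sample = 20000L,
                      substitution_rate = 0, insertion_rate = 0,
                      deletion_rate = 0, chimera_fraction = 0,
                      multicopy = list(), seed = 1L,
                      for_read_len = 70L, rev_read_len = 70L,
                      forward_primer = "GTGYCAGCMGCCGCGGTAA",
                      reverse_primer = "GGACTACNVGGGTWTCTAAT",
                      region_len = 253L, template_len = 1500L,
                      barcode_len = 8L) {
  distribution <- match.arg(distribution)
  rates <- c(substitution_rate, insertion_rate, deletion_rate)
  stopifnot(n_taxa >= 1, reads_per_sample >= 1,
            all(rates >= 0), all(rates <= 0.1),
            chimera_fraction >= 0, chimera_fraction <= 1)
  structure(list(n_taxa = as.integer(n_taxa), distribution = distribution,
                 reads_per_sample = as.integer(reads_per_sample),
                 substitution_rate = substitution_rate,
                 insertion_rate = insertion_rate,
                 deletion_rate = deletion_rate,
                 chimera_fraction = chimera_fraction,
                 multicopy = multicopy, seed = as.integer(seed),
                 for_read_len = as.integer(for_read_len),
                 rev_read_len = as.integer(rev_read_len),
                 forward_primer = forward_primer,
                 reverse_primer = reverse_primer,
                 region_len = as.integer(region_len),
                 template_len = as.integer(template_len),
                 barcode_len = as.integer(barcode_len)),
            class = "mock_spec")
}

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# One concrete realization of a degenerate primer.
realize_primer <- function(primer) {
  p <- strsplit(unclass(as_primer(primer)), "")[[1]]
  paste(vapply(p, function(ch) {
    s <- IUPAC_SETS[[ch]]
    if (length(s) == 1L) s else sample(s, 1L)
  }, ""), collapse = "")
}

mutate_one_base <- function(seq, pos) {
  base <- substr(seq, pos, pos)
  repl <- sample(setdiff(c("A", "C", "G", "T"), base), 1L)
  paste0(substr(seq, 1L, pos - 1L), repl, substr(seq, pos + 1L, nchar(seq)))
}

#' Generate a mock reference set
#'
#' Builds `n_taxa` random templates, each embedding a concrete
#' realization of the forward primer and of the reverse-complemented
#' reverse primer flanking a random amplified region, at identical
#' offsets across templates.  Lineages are 6-rank SILVA-style strings,
#' one genus per taxon.  `multicopy` taxa gain additional template
#' variants differing by one in-region base.  The aligned version
#' inserts shared all-gap column blocks so that degapping recovers the
#' unaligned sequences.
#'
#' @param spec A [mock_spec()].
#' @param dir Optional directory; when given, writes
#'   `refs_unaligned.fasta`, `refs_aligned.fasta` and
#'   `ground_truth_refs.tsv` (TSV with a `#`-prefixed JSON header of
#'   the spec).
#' @return A `mock_references` list: `templates` data frame
#'   (`accession`, `lineage`, `sequence`, `region`, `forward_read`,
#'   `reverse_read`, `abundance_weight`), realized primers, primer
#'   offsets, and the spec.
#' @export
generate_references <- function(spec, dir = NULL) {
  stopifnot(inherits(spec, "mock_spec"))
  with_seed(spec$seed, {
    fwd_site <- realize_primer(spec$forward_primer)
    rev_site_plus <- reverse_complement(realize_primer(spec$reverse_primer))
    pad5_len <- 200L
    fL <- spec$for_read_len
    rL <- spec$rev_read_len
    regions <- character(spec$n_taxa)
    seen_f <- character(0); seen_r <- character(0)
    for (i in seq_len(spec$n_taxa)) {
      repeat {
        reg <- random_dna(spec$region_len)
        f <- substr(reg, 1L, fL)
        r <- substr(reg, spec$region_len - rL + 1L, spec$region_len)
        if (!(f %in% seen_f) && !(r %in% seen_r)) break
      }
      regions[[i]] <- reg
      seen_f <- c(seen_f, f); seen_r <- c(seen_r, r)
    }
    acc <- sprintf("REF_%03d", seq_len(spec$n_taxa))
    lineage <- sprintf(
      "Bacteria;Phylum_%02d;Class_%02d;Order_%02d;Family_%02d;Genus_%02d",
      (seq_len(spec$n_taxa) - 1L) %/% 5L + 1L,
      (seq_len(spec$n_taxa) - 1L) %/% 3L + 1L,
      seq_len(spec$n_taxa), seq_len(spec$n_taxa), seq_len(spec$n_taxa))
    # expand multicopy variants (1-base in-region change, inside the
    # forward read window so variants are distinct ASVs)
    tax_idx <- integer(0); var_no <- integer(0); all_regions <- character(0)
    for (i in seq_len(spec$n_taxa)) {
      nv <- spec$multicopy[[as.character(i)]]
      nv <- if (is.null(nv)) 1L else as.integer(nv)
      tax_idx <- c(tax_idx, rep(i, nv))
      var_no <- c(var_no, seq_len(nv))
      regs <- regions[[i]]
      if (nv > 1L)
        for (v in 2:nv)
          regs <- c(regs, mutate_one_base(regions[[i]],
                                          sample(seq_len(fL), 1L)))
      all_regions <- c(all_regions, regs)
    }
    n_tpl <- length(all_regions)
    pad5 <- vapply(seq_len(n_tpl), function(i) random_dna(pad5_len), "")
    tail_len <- spec$template_len - pad5_len - nchar(fwd_site) -
      spec$region_len - nchar(rev_site_plus)
    pad3 <- vapply(seq_len(n_tpl), function(i) random_dna(tail_len), "")
    seqs <- paste0(pad5, fwd_site, all_regions, rev_site_plus, pad3)
    accession <- ifelse(var_no == 1L, acc[tax_idx],
                        sprintf("%s_v%d", acc[tax_idx], var_no))
    templates <- data.frame(
      accession = accession,
      taxon = tax_idx,
      lineage = lineage[tax_idx],
      sequence = seqs,
      region = all_regions,
      forward_read = substr(all_regions, 1L, fL),
      reverse_read = reverse_complement(
        substr(all_regions, spec$region_len - rL + 1L, spec$region_len)),
      stringsAsFactors = FALSE)
    refs <- list(templates = templates,
                 fwd_site = fwd_site, rev_site_plus = rev_site_plus,
                 fwd_offset = pad5_len + 1L,
                 region_offset = pad5_len + nchar(fwd_site) + 1L,
                 spec = spec)
    class(refs) <- "mock_references"
    if (!is.null(dir)) write_mock_references(refs, dir)
    refs
  })
}

# Insert shared all-gap blocks into equal-length sequences.
gap_align <- function(seqs, block = 120L, gaps = "---") {
  n <- unique(nchar(seqs))
  stopifnot(length(n) == 1L)
  cuts <- seq(block, n - 1L, by = block)
  vapply(seqs, function(s) {
    parts <- substring(s, c(1L, cuts + 1L), c(cuts, n))
    paste(parts, collapse = gaps)
  }, "", USE.NAMES = FALSE)
}

write_mock_references <- function(refs, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tpl <- refs$templates
  hdr <- paste0(">", tpl$accession, " ", tpl$lineage)
  writeLines(as.vector(rbind(hdr, tpl$sequence)),
             file.path(dir, "refs_unaligned.fasta"))
  writeLines(as.vector(rbind(hdr, gap_align(tpl$sequence))),
             file.path(dir, "refs_aligned.fasta"))
  gt <- file.path(dir, "ground_truth_refs.tsv")
  writeLines(paste0("#", jsonlite::toJSON(unclass(refs$spec),
                                          auto_unbox = TRUE)), gt)
  suppressWarnings(utils::write.table(
    tpl[c("accession", "lineage", "region", "forward_read", "reverse_read")],
    gt, sep = "\t", quote = FALSE, row.names = FALSE, append = TRUE))
  invisible(dir)
}

inject_errors <- function(seq, sub_rate, ins_rate, del_rate) {
  if (sub_rate == 0 && ins_rate == 0 && del_rate == 0)
    return(list(seq = seq, n_errors = 0L))
  ch <- strsplit(seq, "")[[1]]
  out <- character(0)
  n_err <- 0L
  for (b in ch) {
    u <- stats::runif(3)
    if (u[[1]] < del_rate) { n_err <- n_err + 1L; next }
    if (u[[2]] < sub_rate) {
      b <- sample(setdiff(c("A", "C", "G", "T"), b), 1L)
      n_err <- n_err + 1L
    }
    out <- c(out, b)
    if (u[[3]] < ins_rate) {
      out <- c(out, sample(c("A", "C", "G", "T"), 1L))
      n_err <- n_err + 1L
    }
  }
  list(seq = paste(out, collapse = ""), n_errors = n_err)
}

# Vectorized per-base substitutions across many reads at once
# (substitution-only fast path).
inject_subs_vec <- function(seqs, rate) {
  n <- length(seqs)
  if (rate == 0 || !n)
    return(list(seq = seqs, n_errors = integer(n)))
  lens <- nchar(seqs)
  ends <- cumsum(lens)
  total <- ends[[n]]
  hits <- which(stats::runif(total) < rate)
  if (!length(hits))
    return(list(seq = seqs, n_errors = integer(n)))
  big <- strsplit(paste(seqs, collapse = ""), "")[[1]]
  for (p in hits)
    big[[p]] <- sample(setdiff(c("A", "C", "G", "T"), big[[p]]), 1L)
  bigs <- paste(big, collapse = "")
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  read_of <- findInterval(hits - 1L, ends) + 1L
  list(seq = substring(bigs, starts, ends),
       n_errors = tabulate(read_of, nbins = n))
}

mock_abundances <- function(spec, templates) {
  base <- switch(spec$distribution,
                 even = rep(1, spec$n_taxa),
                 staggered = 10^seq(0, -3, length.out = spec$n_taxa))
  base <- base / sum(base)
  per_taxon_copies <- table(factor(templates$taxon,
                                   levels = seq_len(spec$n_taxa)))
  w <- base[templates$taxon] / as.integer(per_taxon_copies)[templates$taxon]
  w / sum(w)
}

#' Generate mock multiplexed read pairs
#'
#' Samples read pairs from the mock templates in proportion to the
#' spec's abundance profile (deterministic rounded counts, largest
#' remainder), prepends a per-sample barcode and the realized primer,
#' injects per-base errors at the configured rates into the
#' template-derived portion, and converts the configured
#' `chimera_fraction` of pairs into chimeras whose reverse read comes
#' from a different template.  Every read's source template, error
#' count and chimera status is recorded in the ground truth.
#'
#' @param spec A [mock_spec()].
#' @param references A `mock_references` from [generate_references()]
#'   built from the same spec.
#' @param sample_ids Character vector of sample names (default
#'   `"sample1"`); all samples are emitted multiplexed together.
#' @param dir Optional directory; when given, writes `reads_R1.fastq`,
#'   `reads_R2.fastq`, `mapping.tsv`, `ground_truth_reads.tsv` and
#'   `composition.tsv`.
#' @return A `mock_reads` list: `forward` and `reverse` raw read
#'   vectors, `mapping` data frame, `truth` per-read data frame,
#'   `composition` per-taxon expected data frame (with expected ASV
#'   sequences), and the spec.
#' @export
generate_reads <- function(spec, references, sample_ids = "sample1",
                           dir = NULL) {
  stopifnot(inherits(references, "mock_references"))
  tpl <- references$templates
  n_tpl <- nrow(tpl)
  fL <- spec$for_read_len; rL <- spec$rev_read_len
  slack <- 10L
  fwd_src <- substr(tpl$region, 1L, pmin(fL + slack, nchar(tpl$region)))
  rev_src <- substr(reverse_complement(tpl$region), 1L,
                    pmin(rL + slack, nchar(tpl$region)))
  w <- mock_abundances(spec, tpl)
  # largest-remainder rounding of per-template read counts
  raw <- w * spec$reads_per_sample
  cnt <- floor(raw)
  rem <- spec$reads_per_sample - sum(cnt)
  if (rem > 0) {
    extra <- order(raw - cnt, decreasing = TRUE)[seq_len(rem)]
    cnt[extra] <- cnt[extra] + 1L
  }
  barcodes <- make_barcodes(length(sample_ids), spec$barcode_len, spec$seed)
  fwd_all <- character(0); rev_all <- character(0)
  truth_list <- list()
  for (si in seq_along(sample_ids)) {
    sid <- sample_ids[[si]]
    with_seed(spec$seed * 1009L + si, {
      src <- rep(seq_len(n_tpl), times = cnt)
      n <- length(src)
      rev_partner <- src
      n_chim <- round(spec$chimera_fraction * n)
      if (n_chim > 0 && n_tpl > 1L) {
        idx <- sample(n, n_chim)
        rev_partner[idx] <- vapply(src[idx], function(s)
          sample(setdiff(seq_len(n_tpl), s), 1L), 0L)
      }
      if (spec$insertion_rate == 0 && spec$deletion_rate == 0) {
        fe <- inject_subs_vec(fwd_src[src], spec$substitution_rate)
        re <- inject_subs_vec(rev_src[rev_partner], spec$substitution_rate)
        fseq <- fe$seq; rseq <- re$seq
        nerr <- fe$n_errors + re$n_errors
      } else {
        nerr <- integer(n)
        fseq <- character(n); rseq <- character(n)
        for (i in seq_len(n)) {
          fe <- inject_errors(fwd_src[[src[[i]]]], spec$substitution_rate,
                              spec$insertion_rate, spec$deletion_rate)
          re <- inject_errors(rev_src[[rev_partner[[i]]]],
                              spec$substitution_rate,
                              spec$insertion_rate, spec$deletion_rate)
          fseq[[i]] <- fe$seq; rseq[[i]] <- re$seq
          nerr[[i]] <- fe$n_errors + re$n_errors
        }
      }
      fwd_all <- c(fwd_all, paste0(barcodes[[si]], references$fwd_site,
                                   fseq))
      rev_all <- c(rev_all,
                   paste0(barcodes[[si]],
                          reverse_complement(references$rev_site_plus),
                          rseq))
      truth_list[[si]] <- data.frame(
        sample_id = rep(sid, n),
        template = tpl$accession[src],
        reverse_template = tpl$accession[rev_partner],
        chimeric = src != rev_partner,
        n_errors = nerr, stringsAsFactors = FALSE)
    })
  }
  mapping <- data.frame(sample_id = sample_ids,
                        forward_barcode = barcodes,
                        reverse_barcode = barcodes,
                        Description = paste0("mock ", sample_ids),
                        stringsAsFactors = FALSE)
  composition <- data.frame(
    accession = tpl$accession, lineage = tpl$lineage,
    abundance = cnt / sum(cnt),
    forward_read = tpl$forward_read, reverse_read = tpl$reverse_read,
    stringsAsFactors = FALSE)
  out <- list(forward = fwd_all, reverse = rev_all, mapping = mapping,
              truth = do.call(rbind, truth_list),
              composition = composition, spec = spec)
  class(out) <- "mock_reads"
  if (!is.null(dir)) write_mock_reads(out, dir)
  out
}

make_barcodes <- function(n, len, seed) {
  with_seed(seed * 2003L + 17L, {
    out <- character(0)
    while (length(out) < n) {
      b <- random_dna(len)
      if (!(b %in% out)) out <- c(out, b)
    }
    out
  })
}

write_mock_reads <- function(reads, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ids <- sprintf("read_%06d", seq_along(reads$forward))
  write_fastq(reads$forward, ids, file.path(dir, "reads_R1.fastq"))
  write_fastq(reads$reverse, ids, file.path(dir, "reads_R2.fastq"))
  map <- reads$mapping
  lines <- c(paste("#SampleID", "BarcodeSequence", "ReverseBarcode",
                   "Description", sep = "\t"),
             paste(map$sample_id, map$forward_barcode, map$reverse_barcode,
                   map$Description, sep = "\t"))
  writeLines(lines, file.path(dir, "mapping.tsv"))
  gt <- file.path(dir, "ground_truth_reads.tsv")
  writeLines(paste0("#", jsonlite::toJSON(unclass(reads$spec),
                                          auto_unbox = TRUE)), gt)
  suppressWarnings(utils::write.table(reads$truth, gt, sep = "\t",
                                      quote = FALSE, row.names = FALSE,
                                      append = TRUE))
  utils::write.table(reads$composition, file.path(dir, "composition.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

write_fastq <- function(seqs, ids, path) {
  qual <- vapply(nchar(seqs), function(n)
    paste(rep("I", n), collapse = ""), "")
  writeLines(as.vector(rbind(paste0("@", ids), seqs, "+", qual)), path)
}

#' @export
print.mock_spec <- function(x, ...) {
  cat(sprintf(paste0("mock community spec: %d taxa (%s), %d reads/sample, ",
                     "sub %.4f ins %.4f del %.4f chimera %.3f, seed %d\n"),
              x$n_taxa, x$distribution, x$reads_per_sample,
              x$substitution_rate, x$insertion_rate, x$deletion_rate,
              x$chimera_fraction, x$seed))
  invisible(x)
}
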