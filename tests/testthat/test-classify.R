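# Hit lists over a combined read length of 200 nt (100 + 100) so that
# distances 0/8/14/20 correspond to identities 1.00/0.96/0.93/0.90.
hit_row <- function(distance, lineage, count = 1L, total_len = 200) {
  data.frame(forward = strrep("A", 100), reverse = strrep("C", 100),
             lineage = lineage, count = as.integer(count),
             distance = as.integer(distance),
             identity = 1 - distance / total_len,
             stringsAsFactors = FALSE)
}

LIN7 <- "Bacteria;Pa;Ca;Oa;Fa;Ga;Sa"

test_that("hit collection applies the bound, the 15% cap and the sort order", {
  f <- strrep("A", 50); r <- strrep("C", 50)   # combined length 100
  mut <- function(s, n, to) paste0(strrep(to, n), substr(s, n + 1, nchar(s)))
  tab <- make_lookup(
    forward = c(f, mut(f, 10, "G"), mut(f, 16, "G"), f),
    reverse = c(r, r, r, r),
    lineage = c("Bacteria;P;C;O;F;G1", "Bacteria;P;C;O;F;G2",
                "Bacteria;P;C;O;F;G3", "Bacteria;P;C;O;F;G4"),
    count = c(3L, 5L, 5L, 148L))
  hits <- collect_hits(f, r, tab)
  # 16% mismatch entry excluded
  expect_equal(nrow(hits), 3L)
  expect_false("Bacteria;P;C;O;F;G3" %in% hits$lineage)
  # distance ascending, then count descending
  expect_equal(hits$distance, c(0L, 0L, 10L))
  expect_equal(hits$count[1:2], c(148L, 3L))
  expect_equal(hits$identity[[1]], 1.0)
  expect_error(collect_hits(f, r, tab[0, ]), "empty lookup")
})

test_that("identity caps the deepest assignable rank", {
  # perfect match, single species -> species with confidence 1
  a <- assign_taxonomy(hit_row(0, LIN7))
  expect_equal(a$lowest_rank, "species")
  expect_equal(unname(a$lineage["species"]), "Sa")
  expect_true(all(a$confidence == 1))
  # perfect matches naming two species -> capped at genus
  a2 <- assign_taxonomy(rbind(hit_row(0, LIN7),
                              hit_row(0, "Bacteria;Pa;Ca;Oa;Fa;Ga;Sb")))
  expect_equal(a2$lowest_rank, "genus")
  expect_equal(unname(a2$lineage["species"]), "")
  # 0.96 identity -> genus; 0.93 -> family; 0.90 -> order
  expect_equal(assign_taxonomy(hit_row(8, LIN7))$lowest_rank, "genus")
  expect_equal(assign_taxonomy(hit_row(14, LIN7))$lowest_rank, "family")
  expect_equal(assign_taxonomy(hit_row(20, LIN7))$lowest_rank, "order")
  expect_equal(assign_taxonomy(hit_row(0, LIN7)[0, ])$lowest_rank,
               "unassigned")
})

test_that("the consensus ratio gates each rank by count-weighted majority", {
  # two perfect hits, counts 276 vs 148, disagreeing from phylum down:
  # top fraction 276/424 < 0.8 -> only the unanimous domain assigned
  hits <- rbind(
    hit_row(0, "Bacteria;Proteobacteria;Alpha;Rickettsiales;Anaplasmataceae;Wolbachia;w",
            276),
    hit_row(0, "Bacteria;Bacteroidetes;Flavo;Flavobacteriales;Flavobacteriaceae;Chryseo;c",
            148))
  a <- assign_taxonomy(hits, classify_ratio = 0.8)
  expect_equal(a$lowest_rank, "domain")
  expect_equal(unname(a$confidence["domain"]), 1.0)
  expect_equal(unname(a$lineage["phylum"]), "")
  # lowering the ratio below 276/424 lets the majority through
  a2 <- assign_taxonomy(hits, classify_ratio = 0.6)
  expect_equal(unname(a2$lineage["phylum"]), "Proteobacteria")
  expect_equal(unname(a2$confidence["phylum"]), 276 / 424)
  # only the best-distance stratum votes
  hits2 <- rbind(hit_row(0, LIN7, 1),
                 hit_row(2, "Bacteria;Px;Cx;Ox;Fx;Gx;Sx", 1000))
  expect_equal(unname(assign_taxonomy(hits2)$lineage["genus"]), "Ga")
})

test_that("raising classify_ratio never deepens an assignment", {
  set.seed(51)
  # strictly hierarchical: the name at each rank determines all
  # shallower names (required for the confidence-monotonicity property)
  lineages <- apply(expand.grid(P = c("P1", "P2"), G = c("G1", "G2", "G3")),
                    1, function(x)
                      sprintf("Bacteria;%s;%s_c;%s_o;%s_f;%s_%s;%s_%s_sp",
                              x[1], x[1], x[1], x[1], x[1], x[2],
                              x[1], x[2]))
  depth_of <- function(a) match(a$lowest_rank,
                                c("unassigned", asvgraph:::TAX_RANKS)) - 1
  for (i in 1:40) {
    n <- sample(1:5, 1)
    hits <- do.call(rbind, lapply(seq_len(n), function(j)
      hit_row(sample(c(0, 8), 1), sample(lineages, 1),
              sample(1:300, 1))))
    depths <- vapply(c(0.5, 0.7, 0.9, 1.0), function(r)
      depth_of(assign_taxonomy(hits, r)), 0)
    expect_true(all(diff(depths) <= 0))
    # confidence is non-increasing from domain downward
    conf <- assign_taxonomy(hits, 0.5)$confidence
    if (length(conf) > 1) expect_true(all(diff(conf) <= 1e-12))
  }
})

test_that("exact-copy ASVs recover their reference lineage verbatim", {
  spec <- mock_spec(n_taxa = 8, seed = 52)
  dir <- withr::local_tempdir()
  refs <- generate_references(spec, dir = dir)
  tab <- build_lookup_from_unaligned(
    read_reference_fasta(file.path(dir, "refs_unaligned.fasta")),
    spec$forward_primer, spec$reverse_primer, 70, 70)
  tpl <- refs$templates
  for (i in seq_len(nrow(tpl))) {
    hits <- collect_hits(tpl$forward_read[[i]], tpl$reverse_read[[i]], tab)
    a <- assign_taxonomy(hits)
    expect_equal(paste(a$lineage[nzchar(a$lineage)], collapse = ";"),
                 tpl$lineage[[i]])
    expect_equal(a$lowest_rank, "genus")   # 6-rank reference lineages
  }
})

test_that("only the most abundant rejected ASVs are classified", {
  set.seed(53)
  n <- 12
  asvs <- make_asvs(vapply(seq_len(n), function(i) rand_dna(20), ""),
                    vapply(seq_len(n), function(i) rand_dna(20), ""),
                    seq_len(n) * 10,
                    status = c("accepted",
                               rep("provisionally_rejected", n - 2),
                               "chimeric"))
  tab <- make_lookup(asvs$forward[[1]], asvs$reverse[[1]],
                     "Bacteria;P;C;O;F;G", 1L)
  out <- classify_sample(asvs, tab,
                         denoise_params(max_classified_rejected = 4))
  classified <- !vapply(out$assignment, is.null, NA)
  expect_true(classified[out$status == "accepted"])
  expect_false(any(classified[out$status == "chimeric"]))
  rej <- which(out$status == "provisionally_rejected")
  expect_equal(sum(classified[rej]), 4L)
  # the classified rejected ones are the most abundant
  expect_true(all(out$read_count[rej][classified[rej]] >
                    max(out$read_count[rej][!classified[rej]]) - 1e-9))
  # ASV with no hit within the cap keeps an empty assignment
  far <- classify_sample(
    make_asvs(strrep("T", 20), strrep("G", 20), 50, status = "accepted"),
    tab, denoise_params())
  expect_equal(far$assignment[[1]]$lowest_rank, "unassigned")
  expect_equal(nrow(far$hits[[1]]), 0L)
})
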