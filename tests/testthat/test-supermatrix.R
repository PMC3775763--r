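test_that("progressive alignment handles identity, pairs and width bounds", {
  set.seed(51)
  s <- random_protein(40)
  ident <- progressive_align(c(a = s, b = s, c = s))
  expect_true(all(ident == s))               # gap-free

  # two sequences: score equals the independent global DP oracle
  mat <- blosum()
  for (k in 1:6) {
    a <- random_protein(sample(15:35, 1))
    b <- random_protein(sample(15:35, 1))
    expect_equal(global_align_score(a, b),
                 oracle_global_align(a, b, mat), tolerance = 1e-9)
  }

  set.seed(52)
  seqs <- stats::setNames(vapply(c(30, 34, 28, 31), random_protein,
                                 character(1)), paste0("s", 1:4))
  aln <- progressive_align(seqs)
  expect_length(unique(nchar(aln)), 1L)
  expect_gte(nchar(aln[[1L]]), 34L)          # no column loss
  expect_identical(names(aln), names(seqs))  # input order preserved
  expect_identical(gsub("-", "", aln), seqs) # rows unchanged up to gaps

  single <- progressive_align(c(only = "MKV"))
  expect_identical(single, c(only = "MKV"))
})

test_that("backtranslation expands residues to codons and gaps to ---", {
  aa <- c(T01 = "M-K", T02 = "MQK")
  cds <- c(T01 = "ATGAAA", T02 = "ATGCAAAAG")
  nt <- backtranslate(aa, cds)
  expect_identical(unname(nt["T01"]), "ATG---AAA")
  expect_identical(unname(nt["T02"]), "ATGCAAAAG")
  expect_true(all(nchar(nt) == 3L * nchar(aa)))
  bad <- c(T01 = "ATGAAG")   # translates to MK, row says M-K -> MK ok; force mismatch
  expect_error(backtranslate(c(T01 = "M-W"), bad), "T01")
})

test_that("missing-data filter drops genes by per-taxon missingness", {
  taxa <- c("T01", "T02", "T03")
  mk_ga <- function(id, rows) {
    nt <- vapply(rows, function(r) paste(
      ifelse(strsplit(r, "")[[1L]] == "-", "---", "ATG"), collapse = ""),
      character(1))
    gene_alignment(id, rows, nt)
  }
  complete <- mk_ga("G1", c(T01 = "MMMMMMMMMM", T02 = "MMMMMMMMMM",
                            T03 = "MMMMMMMMMM"))
  gappy <- mk_ga("G2", c(T01 = "MMMM------", T02 = "MMMMMMMMMM",
                         T03 = "MMMMMMMMMM"))       # T01 60% missing
  absent <- mk_ga("G3", c(T01 = "MMMMMMMMMM", T02 = "MMMMMMMMMM"))
  res <- filter_genes_by_missing(list(complete, gappy, absent), taxa)
  expect_equal(vapply(res$retained, `[[`, character(1), "family_id"), "G1")
  expect_setequal(res$dropped$family_id, c("G2", "G3"))
  expect_equal(res$dropped$worst_taxon[res$dropped$family_id == "G2"], "T01")
  # exactly 50% missing is tolerated (inclusive bound)
  half <- mk_ga("G4", c(T01 = "MMMMM-----", T02 = "MMMMMMMMMM",
                        T03 = "MMMMMMMMMM"))
  expect_length(filter_genes_by_missing(list(half), taxa)$retained, 1L)
})

test_that("concatenation tiles partitions, gap-fills and keeps 3:1 widths", {
  taxa <- c("T01", "T02", "T03")
  g1 <- gene_alignment("G1", c(T01 = "MK", T02 = "MK", T03 = "MR"),
                       c(T01 = "ATGAAA", T02 = "ATGAAG", T03 = "ATGCGT"))
  g2 <- gene_alignment("G2", c(T01 = "WWW", T02 = "WWW"),
                       c(T01 = "TGGTGGTGG", T02 = "TGGTGGTGG"))
  sm <- concatenate_alignments(list(g2, g1), taxa)   # order normalised by id
  expect_equal(sm$partitions$family_id, c("G1", "G2"))
  expect_equal(sm$partitions$aa_start, c(1L, 3L))
  expect_equal(sm$partitions$aa_end, c(2L, 5L))
  expect_equal(sm$partitions$nt_start, c(1L, 7L))
  expect_equal(sm$partitions$nt_end, c(6L, 15L))
  expect_equal(nchar(sm$aa[["T01"]]), 5L)
  expect_equal(nchar(sm$nt[["T01"]]), 15L)
  expect_equal(substr(sm$aa[["T03"]], 3, 5), "---")  # absent taxon gap-filled
  expect_equal(substr(sm$nt[["T03"]], 7, 15), strrep("-", 9))
  # tiling: partition widths sum to the total width
  expect_equal(sum(sm$partitions$aa_end - sm$partitions$aa_start + 1L),
               nchar(sm$aa[[1L]]))
  dup <- gene_alignment("G3", c(T01 = "M", T01 = "M"),
                        c(T01 = "ATG", T01 = "ATG"))
  expect_error(concatenate_alignments(list(dup), taxa), "duplicate")

  # PHYLIP + partition writers round-trip basics
  pp <- tempfile(); pf <- tempfile()
  write_phylip(sm$nt, pp)
  write_partitions(sm$partitions[, c("family_id", "nt_start", "nt_end")] |>
                     dplyr::rename(start = "nt_start", end = "nt_end"), pf)
  expect_match(readLines(pp)[1L], "^3 15$")
  expect_equal(readLines(pf), c("G1 = 1-6", "G2 = 7-15"))
})

test_that("translating the nt supermatrix partition-wise gives the aa matrix", {
  fx <- fixture_small_clean()
  sm <- fx$supermatrix
  expect_equal(nchar(sm$nt[[1L]]), 3L * nchar(sm$aa[[1L]]))
  for (tx in sm$taxa[1:3]) {
    nt_row <- sm$nt[[tx]]
    aa_row <- sm$aa[[tx]]
    cods <- substring(nt_row, seq(1, nchar(nt_row), 3), seq(3, nchar(nt_row), 3))
    back <- vapply(cods, function(cd) {
      if (cd == "---") "-" else unname(Biostrings::GENETIC_CODE[cd])
    }, character(1))
    expect_identical(paste0(back, collapse = ""), aa_row)
  }
})

test_that("filter-then-concatenate matches concatenate-then-drop", {
  fx <- fixture_small_clean()
  gas <- fx$gene_alignments
  taxa <- fx$bench$species_tree$tip.label
  # knock one taxon out of two genes to exercise the filter
  gas[[2]]$aa <- gas[[2]]$aa[-1]; gas[[2]]$nt <- gas[[2]]$nt[-1]
  kept <- filter_genes_by_missing(gas, taxa)$retained
  sm_a <- concatenate_alignments(kept, taxa)
  ids_kept <- vapply(kept, `[[`, character(1), "family_id")
  sm_b <- concatenate_alignments(gas[vapply(gas, function(g)
    g$family_id %in% ids_kept, logical(1))], taxa)
  expect_identical(sm_a$nt, sm_b$nt)
  expect_identical(sm_a$partitions, sm_b$partitions)
})
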