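test_that("species tree simulation is ultrametric, seeded and bounded", {
  tr <- simulate_species_tree(15, root_age = 100, seed = 1)
  expect_s3_class(tr, "phylo")
  expect_equal(ape::Ntip(tr), 15)
  depths <- ape::node.depth.edgelength(tr)[1:15]
  expect_true(max(abs(depths - 100)) < 1e-8)
  expect_identical(ape::write.tree(tr),
                   ape::write.tree(simulate_species_tree(15, root_age = 100,
                                                         seed = 1)))
  expect_error(simulate_species_tree(2), "n_taxa")
  # internal ages strictly below the root age across many replicates
  ok <- vapply(seq_len(1000), function(s) {
    t2 <- simulate_species_tree(6, root_age = 50, seed = s)
    ages <- node_ages(t2)
    internal <- ages[(7:11)]
    all(internal[-1] < 50 + 1e-9) && abs(max(ages) - 50) < 1e-9
  }, logical(1))
  expect_true(all(ok))
})

test_that("gene family birth-death honours its rates", {
  sp <- simulate_species_tree(6, root_age = 100, seed = 2)
  none <- simulate_gene_families(sp, 10, dup_rate = 0, loss_rate = 0, seed = 3)
  expect_true(all(none$single_copy))
  expect_true(all(none$n_genes == 6))
  # with no events, gene trees are congruent with the species tree
  for (gt in none$gene_tree) {
    gt$tip.label <- sub("\\|.*$", "", gt$tip.label)
    expect_equal(rf_distance(gt, sp), 0)
  }
  # duplications produce multi-copy taxa at large family counts
  dup <- simulate_gene_families(sp, 500, dup_rate = 2e-3, loss_rate = 0,
                                seed = 4)
  expect_true(any(vapply(dup$counts, function(ct) any(ct >= 2), logical(1))))
  # single-copy fraction non-increasing in dup_rate (Monte-Carlo averages)
  frac <- vapply(c(0, 1e-3, 4e-3), function(d) {
    mean(vapply(1:3, function(s)
      mean(simulate_gene_families(sp, 60, dup_rate = d, loss_rate = 0,
                                  seed = 10 * s)$single_copy), numeric(1)))
  }, numeric(1))
  expect_true(all(diff(frac) <= 0))
})

test_that("codon simulation respects branch lengths, stationarity and seeds", {
  sp <- simulate_species_tree(4, root_age = 10, seed = 5)
  fam <- simulate_gene_families(sp, 1, dup_rate = 0, loss_rate = 0, seed = 6)
  # zero rate = zero branch lengths: all sequences identical
  sim0 <- simulate_codon_sequences(fam$rec[[1]], 50, rate = 0, seed = 7)
  expect_length(unique(unname(sim0$cds)), 1L)
  expect_true(all(nchar(sim0$cds) == 150))
  # determinism
  s1 <- simulate_codon_sequences(fam$rec[[1]], 40, seed = 8)
  s2 <- simulate_codon_sequences(fam$rec[[1]], 40, seed = 8)
  expect_identical(s1$cds, s2$cds)
  # no stop codons ever
  expect_false(any(grepl("\\*", translate_cds(s1$cds))))
  # law of large numbers: one long branch reaches stationarity
  m <- codon_model()
  pair <- list(label = "", age = 10, dup = FALSE, children = list(
    list(label = "x", age = 0, dup = FALSE, children = NULL),
    list(label = "y", age = 0, dup = FALSE, children = NULL)))
  sim <- simulate_codon_sequences(pair, 1e5, m, rate = 1, seed = 9)
  emp <- table(strsplit(sim$cds[["x"]], "")[[1L]]) / (3e5)
  expect_true(max(abs(emp[c("A", "C", "G", "T")] -
                        codon_stationary(m)$overall)) < 0.01)
  expect_error(codon_model(base_freq = c(A = 1, C = 1, G = 0, T = 0)),
               "sum to 1")
})

test_that("whole-genome duplication inserts dated paralog copies", {
  sp <- simulate_species_tree(5, root_age = 80, seed = 11)
  fam <- simulate_gene_families(sp, 1, dup_rate = 0, loss_rate = 0, seed = 12)
  sim <- simulate_codon_sequences(fam$rec[[1]], 30, rate = 0.002,
                                  wgd = list(age = 40, retained_fraction = 1),
                                  seed = 13)
  # retained_fraction 1: every lineage alive at 40 Ma is duplicated
  expect_true(any(grepl("\\.w$", names(sim$cds))))
  base <- sub("\\.w$", "", names(sim$cds))
  expect_true(all(table(base) == 2))
})

test_that("degrade_and_emit truncates, samples 90 bp pairs and logs truth", {
  sp <- simulate_species_tree(4, root_age = 50, seed = 14)
  fam <- simulate_gene_families(sp, 2, dup_rate = 0, loss_rate = 0, seed = 15)
  sim <- simulate_codon_sequences(fam$rec[[1]], 120, seed = 16)
  names(sim$cds) <- sub("\\|", "|F0001|", names(sim$cds))

  id0 <- degrade_and_emit(sim$cds, missing_fraction = 0, seed = 17)
  expect_identical(id0$transcripts, sim$cds)
  expect_true(all(id0$truth$masked_fraction == 0))

  em <- degrade_and_emit(sim$cds, missing_fraction = 0.3, read_pairs = 25,
                         read_length = 90, seed = 18)
  expect_true(all(nchar(em$reads$bases) == 90))
  expect_true(all(lengths(em$reads$qualities) == 90))
  expect_equal(nrow(em$reads), 50)          # 25 pairs, two mates each
  # truth map traces every emitted transcript to (taxon, family, copy)
  expect_setequal(em$truth$gene_id, names(sim$cds))
  expect_false(anyNA(em$truth$taxon))
  expect_false(anyNA(em$truth$copy_index))
  expect_true(all(abs(em$truth$masked_fraction - 0.3) < 0.01))
  expect_error(degrade_and_emit(sim$cds, missing_fraction = 1), "missing_fraction")

  # 60% masking of one taxon's gene downstream fails the 50% filter
  mf <- ifelse(seq_along(sim$cds) == 1L, 0.6, 0)
  em2 <- degrade_and_emit(sim$cds, missing_fraction = mf, seed = 19)
  kept_len <- nchar(em2$transcripts)
  aa <- translate_cds(sim$cds)
  w <- nchar(aa[[1L]])
  rows <- vapply(names(sim$cds), function(g) {
    k <- (kept_len[[g]] %/% 3L)
    paste0(strrep("X", k), strrep("-", w - k))
  }, character(1))
  names(rows) <- sub("\\|.*$", "", names(rows))
  nt_rows <- vapply(rows, function(r)
    paste(ifelse(strsplit(r, "")[[1L]] == "-", "---", "NNN"), collapse = ""),
    character(1))
  ga <- gene_alignment("F0001", rows, nt_rows)
  res <- filter_genes_by_missing(list(ga), sp$tip.label)
  expect_length(res$retained, 0L)
  expect_equal(res$dropped$family_id, "F0001")
})

test_that("FASTA/FASTQ round-trips preserve records", {
  seqs <- c(a = "ACGTACGT", b = "TTTTGGGG")
  fa <- tempfile(fileext = ".fasta")
  write_fasta(seqs, fa)
  expect_identical(read_fasta(fa), seqs)
  reads <- tibble::tibble(id = c("r1", "r2"),
                          bases = c("ACGT", "GGNN"),
                          qualities = list(c(30L, 30L, 2L, 40L),
                                           c(2L, 2L, 2L, 2L)))
  fq <- tempfile(fileext = ".fastq")
  write_fastq(reads, fq, encoding = "phred64")
  back <- read_fastq(fq, encoding = "phred64")
  expect_identical(back$bases, reads$bases)
  expect_identical(back$qualities, reads$qualities)
})
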