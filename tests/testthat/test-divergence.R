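test_that("4-fold degenerate site extraction follows the strict rules", {
  # all-Gly column retained; Gly/Glu mixed column excluded; gap excluded
  aln <- c(T01 = "GGAGGAGGA", T02 = "GGCGAAGGC", T03 = "GGGGGAGG-")
  ff <- fourfold_sites(aln)
  # codon 1: GGx everywhere -> third positions A, C, G
  expect_identical(unname(ff), c("A", "C", "G"))
  expect_error(fourfold_sites(c(a = "ACGT")), "divisible")
  # idempotence at the site level: every retained column is a 4D third
  # position, so re-checking its source codons changes nothing
  expect_equal(nchar(ff[[1L]]), 1L)

  sm <- fixture_small_clean()$supermatrix
  ff2 <- fourfold_sites(sm)
  expect_true(nchar(ff2[[1L]]) > 0)
  expect_true(nchar(ff2[[1L]]) <= nchar(sm$aa[[1L]]))
})

test_that("with no data the posterior reproduces the calibration prior", {
  tr <- simulate_species_tree(6, root_age = 90, seed = 2)
  cal <- tibble::tibble(clade = list("root"), mean = 90.7, sd = 1.0,
                        type = "crown")
  dt <- strict_clock_date(tr, NULL, cal, steps = 60000, burnin = 10000,
                          thin = 5, seed = 3)
  root_col <- paste0("node", ape::Ntip(tr) + 1L)
  s <- dt$samples[[root_col]]
  expect_lt(abs(mean(s) - 90.7), 0.1)
  expect_lt(abs(stats::sd(s) - 1.0) / 1.0, 0.15)
  # node ages always respect parent > child in every sample
  kids_of_root <- dt$samples[, grep("^node", names(dt$samples))[-1L]]
  expect_true(all(s > 0))
})

test_that("dating validates calibrations and topology", {
  tr <- simulate_species_tree(5, root_age = 50, seed = 4)
  expect_error(strict_clock_date(ape::unroot(tr), NULL,
                                 tibble::tibble(clade = list("root"),
                                                mean = 50, sd = 1)),
               "rooted")
  expect_error(strict_clock_date(tr, NULL,
                                 tibble::tibble(clade = list(c("T01", "ZZ")),
                                                mean = 30, sd = 1,
                                                type = "crown")),
               "ZZ")
  expect_error(strict_clock_date(tr, NULL,
                                 tibble::tibble(clade = list("root"),
                                                mean = 50, sd = -1)),
               "sd")
})

test_that("two chains with different seeds agree within Monte-Carlo error", {
  tr <- simulate_species_tree(6, root_age = 90, seed = 6)
  sim <- simulate_codon_sequences(tr, 400, rate = 0.002, seed = 7)
  ff <- fourfold_sites(sim$alignment)
  cal <- tibble::tibble(clade = list("root"),
                        mean = max(node_ages(tr)), sd = 2, type = "crown")
  d1 <- strict_clock_date(tr, ff, cal, steps = 6000, burnin = 1500, seed = 8)
  d2 <- strict_clock_date(tr, ff, cal, steps = 6000, burnin = 1500, seed = 9)
  root_col <- paste0("node", ape::Ntip(tr) + 1L)
  m1 <- mean(d1$samples[[root_col]]); m2 <- mean(d2$samples[[root_col]])
  ess <- function(x) min(length(x), length(x) /
                           (1 + 2 * sum(stats::acf(x, plot = FALSE,
                                                   lag.max = 50)$acf[-1])))
  mcse <- sqrt(stats::var(d1$samples[[root_col]]) / ess(d1$samples[[root_col]]) +
               stats::var(d2$samples[[root_col]]) / ess(d2$samples[[root_col]]))
  expect_lt(abs(m1 - m2), 4 * mcse + 0.5)
})

test_that("Ks of identical sequences is zero; hand-worked Gly case matches", {
  cds <- paste(rep("GGA", 100), collapse = "")
  expect_equal(ks_pair(cds, cds)$ks, 0)
  # 99 GGA + 1 GGG vs 100 GGA: Sd = 1, S = 100, Ks = -3/4 log(1 - 4/300)
  other <- paste(c(rep("GGA", 99), "GGG"), collapse = "")
  kp <- ks_pair(cds, other)
  expect_equal(kp$Sd, 1)
  expect_equal(kp$S, 100)
  expect_equal(kp$N, 200)
  expect_equal(kp$ks, -3 / 4 * log(1 - 4 / 3 * 0.01), tolerance = 1e-12)
  expect_false(kp$saturated)
  expect_error(ks_pair("ACGTA", "ACGTA"), "divisible")
})

test_that("unrelated sequences saturate; unequal lengths are aligned first", {
  set.seed(71)
  sense <- names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE != "*"]
  a <- paste0(sample(sense, 1200, replace = TRUE), collapse = "")
  b <- paste0(sample(sense, 1200, replace = TRUE), collapse = "")
  kp <- ks_pair(a, b)
  expect_true(kp$saturated)
  expect_true(is.na(kp$ks))
  # length-mismatched but homologous pair: aligned through proteins
  a2 <- substr(a, 1, 1080)
  kp2 <- ks_pair(a, a2)
  expect_equal(kp2$ks, 0)
})

test_that("ks_distribution screens within-taxon paralog pairs", {
  none <- ks_distribution(c(`T01|F1|g1` = "ATGGGA"),
                          list(c("T01|F1|g1")))
  expect_equal(nrow(none$pairs), 0L)
  expect_equal(nrow(none$histogram), 0L)

  sp <- simulate_species_tree(4, root_age = 60, seed = 72)
  fam <- simulate_gene_families(sp, 4, dup_rate = 0, loss_rate = 0, seed = 73)
  cds_all <- character(0); members <- list()
  for (i in 1:4) {
    sim <- simulate_codon_sequences(fam$rec[[i]], 150, rate = 0.004,
                                    wgd = list(age = 30, retained_fraction = 1),
                                    seed = 74 + i)
    names(sim$cds) <- sub("\\|", sprintf("|F%d|", i), names(sim$cds))
    cds_all <- c(cds_all, sim$cds); members[[i]] <- names(sim$cds)
  }
  ksd <- ks_distribution(cds_all, members, bin_width = 0.1)
  expect_true(nrow(ksd$pairs) >= 16)
  ok <- ksd$pairs$ks[!is.na(ksd$pairs$ks)]
  expect_true(all(ok >= 0))
  expect_true(all(ksd$histogram$count >= 0))
  # every taxon with a duplicated gene appears
  expect_setequal(unique(ksd$pairs$taxon), sp$tip.label)
})
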