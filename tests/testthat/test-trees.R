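test_that("neighbor joining recovers additive distances exactly", {
  # hand-built 6-taxon tree; additive matrix from its path lengths
  ref <- ape::read.tree(
    text = "(((a:2,b:3):4,c:6):1,(d:2.5,e:3.5):2,f:8);")
  D <- ape::cophenetic.phylo(ref)
  tr <- nj_tree(D)
  expect_equal(rf_distance(tr, ref), 0)
  # branch lengths reproduced (sum preserved, all non-negative)
  expect_equal(sort(ape::cophenetic.phylo(tr)[rownames(D), colnames(D)]),
               sort(D), tolerance = 1e-8)
  expect_true(all(tr$edge.length >= 0))

  perm <- sample(rownames(D))
  tr2 <- nj_tree(D[perm, perm])
  expect_equal(rf_distance(tr2, ref), 0)

  expect_equal(ape::Ntip(nj_tree(D[1:3, 1:3])), 3L)
  bad <- D; bad[1, 2] <- 99
  expect_error(nj_tree(bad), "symmetric")
})

test_that("Fitch counts match trivial cases and the exhaustive oracle", {
  tr <- ape::read.tree(text = "((A1,A2),(B1,B2));")
  expect_equal(fitch_score(tr, c(A1 = "A", A2 = "A", B1 = "A", B2 = "A")), 0)
  expect_equal(fitch_score(tr, c(A1 = "A", A2 = "A", B1 = "C", B2 = "C")), 1)
  expect_error(fitch_score(tr, c(A1 = "A", A2 = "A", B1 = "C", Z9 = "C")),
               "mismatch")
  # gaps act as wildcards
  expect_equal(fitch_score(tr, c(A1 = "A", A2 = "-", B1 = "C", B2 = "C")), 1)

  set.seed(61)
  for (k in 1:25) {
    n <- sample(4:6, 1)
    topo <- ape::rtree(n, tip.label = paste0("t", seq_len(n)))
    aln <- stats::setNames(vapply(seq_len(n), function(i) random_dna(5),
                                  character(1)), topo$tip.label)
    expect_equal(fitch_score(topo, aln), oracle_parsimony(topo, aln),
                 info = paste("case", k))
  }
})

test_that("parsimony search finds constructed signal and is deterministic", {
  fx <- fixture_small_clean()
  sm <- fx$supermatrix
  sub <- substr(sm$nt, 1, 600)
  names(sub) <- names(sm$nt)
  mp1 <- mp_search(sub, n_random_additions = 3, seed = 77)
  mp2 <- mp_search(sub, n_random_additions = 3, seed = 77)
  expect_equal(mp1$score, mp2$score)
  expect_equal(rf_distance(mp1$trees[[1L]], mp2$trees[[1L]]), 0)
  # returned score is the Fitch score of every returned tree
  for (t in mp1$trees) expect_equal(fitch_score(t, sub), mp1$score)
  # strong congruent signal recovers the generating topology
  expect_equal(rf_distance(mp1$trees[[1L]], fx$bench$species_tree), 0)
})

test_that("pruning likelihood matches closed forms and cross-checks", {
  # JC, two taxa: closed-form site probabilities
  t2 <- ape::read.tree(text = "(a:0.07,b:0.03);")
  a2 <- c(a = "ACGTACGTACGGCCTT", b = "ACGTACGTACGGCCTA")
  d <- 0.1
  p_same <- 1 / 4 + 3 / 4 * exp(-4 * d / 3)
  p_diff <- 1 / 4 - 1 / 4 * exp(-4 * d / 3)
  closed <- 15 * log(p_same / 4) + log(p_diff / 4)
  expect_lt(abs(gtr_loglik(t2, a2, gtr_model()) - closed), 1e-8)

  # GTR, two taxa: independent matrix-exponential oracle
  exch <- c(AC = 1.2, AG = 3.1, AT = 0.8, CG = 0.9, CT = 3.6, GT = 1)
  bf <- c(A = 0.31, C = 0.19, G = 0.22, T = 0.28)
  mod <- gtr_model(exch, bf)
  expect_lt(abs(gtr_loglik(t2, a2, mod) -
                oracle_two_taxon_loglik(a2[["a"]], a2[["b"]], 0.1, exch, bf)),
            1e-8)

  # rerooting invariance and site-duplication additivity on a larger tree
  set.seed(62)
  tr <- ape::rtree(6)
  tr$edge.length <- runif(nrow(tr$edge), 0.02, 0.3)
  aln <- phydat_to_chr(phangorn::simSeq(tr, l = 120, type = "DNA"))
  mod2 <- gtr_model(gamma_shape = 0.7)
  base <- gtr_loglik(tr, aln, mod2)
  rerooted <- ape::root(ape::unroot(tr), outgroup = tr$tip.label[3],
                        resolve.root = TRUE)
  expect_lt(abs(gtr_loglik(rerooted, aln, mod2) - base) / abs(base), 1e-8)
  doubled <- stats::setNames(paste0(aln, aln), names(aln))
  expect_equal(gtr_loglik(tr, doubled, mod2), 2 * base, tolerance = 1e-8)

  # cross-check against phangorn's independent implementation
  dat <- phangorn::phyDat(do.call(rbind, strsplit(aln, "")), type = "DNA")
  fitp <- phangorn::pml(tr, dat, k = 4, shape = 0.7)
  expect_equal(gtr_loglik(tr, aln, gtr_model(gamma_shape = 0.7)),
               fitp$logLik, tolerance = 1e-6)

  expect_error(gtr_model(base_freq = c(A = 0.5, C = 0.5, G = 0.2, T = -0.2)),
               "frequencies")
})

test_that("ML search improves monotonically, is seeded, recovers topology", {
  fx <- fixture_small_clean()
  sm <- fx$supermatrix
  truth <- fx$bench$species_tree
  fit <- ml_search(sm$nt)
  expect_equal(rf_distance(fit$tree, truth), 0)
  # starting at the true tree cannot end lower
  t0 <- ape::unroot(truth)
  fit_true <- ml_search(sm$nt, start = t0)
  expect_gte(fit_true$loglik + 1e-6, fit$loglik - 1)
  # deterministic under NNI rearrangement
  fit2 <- ml_search(sm$nt)
  expect_equal(fit$loglik, fit2$loglik)
  g <- glance(fit)
  expect_s3_class(g, "tbl_df")
  expect_equal(g$loglik, fit$loglik)
})

test_that("bootstrap supports live in [0,100], are seeded, saturate on signal", {
  fx <- fixture_small_clean()
  sub <- substr(fx$supermatrix$nt, 1, 900)
  names(sub) <- names(fx$supermatrix$nt)
  bs1 <- bootstrap_support(sub, builder = "nj", n_replicates = 60, seed = 3)
  bs2 <- bootstrap_support(sub, builder = "nj", n_replicates = 60, seed = 3)
  expect_identical(bs1$support, bs2$support)
  expect_true(all(bs1$support$support >= 0 & bs1$support$support <= 100))
  # clean strong signal: full supports with the ML builder on the full matrix
  bs_ml <- bootstrap_support(fx$supermatrix$nt, builder = "ml",
                             n_replicates = 30, seed = 4)
  expect_true(all(bs_ml$support$support == 100))
})

test_that("RF distance counts bipartition differences", {
  q1 <- ape::read.tree(text = "((a,b),(c,d));")
  q2 <- ape::read.tree(text = "((a,c),(b,d));")
  expect_equal(rf_distance(q1, q1), 0)
  expect_equal(rf_distance(q1, q2), 2)
  expect_true(topologies_equal(q1, q1))
  expect_error(rf_distance(q1, ape::read.tree(text = "((a,b),(c,e));")),
               "leaf sets")
  # bound 2(n-3) and agreement with phangorn's implementation
  set.seed(63)
  for (k in 1:20) {
    n <- sample(5:10, 1)
    ta <- ape::rtree(n, tip.label = paste0("t", 1:n))
    tb <- ape::rtree(n, tip.label = paste0("t", 1:n))
    r <- rf_distance(ta, tb)
    expect_lte(r, 2 * (n - 3))
    expect_equal(r, as.integer(phangorn::RF.dist(ape::unroot(ta),
                                                 ape::unroot(tb))))
  }
})

test_that("outgroup rooting is reversible and validates its input", {
  tr <- ape::read.tree(text = "((a:1,b:1):1,(c:1,d:1):1,out:3);")
  r <- root_with_outgroup(tr, "out")
  expect_true(ape::is.rooted(r))
  expect_equal(sum(r$edge[, 1] == ape::Ntip(r) + 1L), 2L)
  expect_equal(rf_distance(ape::unroot(r), tr), 0)
  expect_error(root_with_outgroup(tr, "missing_taxon"), "not in tree")
})
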