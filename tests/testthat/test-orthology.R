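mk_hits <- function(...) {
  rows <- list(...)
  dplyr::bind_rows(lapply(rows, function(r)
    tibble::tibble(query = r[[1]], subject = r[[2]],
                   raw_score = as.numeric(r[[3]]),
                   qalnlen = as.integer(r[[4]]), salnlen = as.integer(r[[5]]),
                   evalue = NA_real_)))
}

test_that("H-score matches its definition, range and error contract", {
  expect_equal(h_score(250, 250, 250), 100)
  expect_equal(h_score(50, 100, 200), 25)
  expect_equal(h_score(0, 100, 100), 0)
  expect_error(h_score(10, 0, 100), "positive")
  expect_error(h_score(-1, 10, 10), ">= 0")
  # clamped into [0, 100] even for over-unity cross scores
  expect_equal(h_score(300, 100, 200), 100)
})

test_that("graph edges require strict mutual coverage and H-score rules", {
  len <- c(`T01|a` = 90L, `T02|b` = 90L)
  selfs <- mk_hits(list("T01|a", "T01|a", 200, 90, 90),
                   list("T02|b", "T02|b", 200, 90, 90))
  # aligned length exactly one third: no edge (strict inequality)
  h_third <- dplyr::bind_rows(selfs, mk_hits(list("T01|a", "T02|b", 100, 30, 40)))
  g <- build_graph(h_third, len)
  expect_equal(nrow(g$edges), 0L)
  # just above one third on both: edge appears
  h_ok <- dplyr::bind_rows(selfs, mk_hits(list("T01|a", "T02|b", 100, 31, 31)))
  g2 <- build_graph(h_ok, len)
  expect_equal(nrow(g2$edges), 1L)
  expect_equal(g2$edges$h, 50)
  # H-score exactly 5 fails; just above passes
  h5 <- dplyr::bind_rows(selfs, mk_hits(list("T01|a", "T02|b", 10, 60, 60)))
  expect_equal(nrow(build_graph(h5, len)$edges), 0L)
  h5p <- dplyr::bind_rows(selfs, mk_hits(list("T01|a", "T02|b", 10.4, 60, 60)))
  expect_equal(nrow(build_graph(h5p, len)$edges), 1L)
  # no cross-hits: isolated nodes
  g0 <- build_graph(selfs, len)
  expect_equal(nrow(g0$nodes), 2L)
  expect_equal(nrow(g0$edges), 0L)
  # missing self-hit is a hard error
  broken <- mk_hits(list("T01|a", "T01|a", 200, 90, 90),
                    list("T01|a", "T02|b", 100, 60, 60))
  expect_error(build_graph(broken, len), "T02\\|b")
})

test_that("directional scores are symmetrised to the maximum", {
  len <- c(`T01|a` = 90L, `T02|b` = 90L)
  h <- mk_hits(list("T01|a", "T01|a", 200, 90, 90),
               list("T02|b", "T02|b", 200, 90, 90),
               list("T01|a", "T02|b", 80, 60, 60),
               list("T02|b", "T01|a", 100, 60, 60))
  g <- build_graph(h, len)
  expect_equal(g$edges$h, 50)   # max(80, 100) * 100 / 200
})

triangle_graph <- function(h = 50) {
  genes <- c("T01|a", "T02|b", "T03|c")
  selfs <- dplyr::bind_rows(lapply(genes, function(g)
    tibble::tibble(query = g, subject = g, raw_score = 100,
                   qalnlen = 50L, salnlen = 50L, evalue = NA_real_)))
  cross <- dplyr::bind_rows(lapply(utils::combn(genes, 2, simplify = FALSE),
    function(p) tibble::tibble(query = p[1], subject = p[2], raw_score = h,
                               qalnlen = 50L, salnlen = 50L,
                               evalue = NA_real_)))
  build_graph(dplyr::bind_rows(selfs, cross),
              stats::setNames(rep(50L, 3), genes))
}

test_that("clustering merges cliques, respects the density and linkage rules", {
  fams <- cluster_families(triangle_graph())
  expect_equal(nrow(fams), 1L)
  expect_equal(fams$size, 3L)
  expect_equal(fams$edge_density, 1)

  # two 4-cliques joined by one weaker edge: the cliques agglomerate first
  # (within-clique linkage stays 50), then the cross linkage 40/16 = 2.5
  # sits below the threshold, so the cliques remain separate families
  genes <- c(paste0("T0", 1:4, "|a"), paste0("T0", 1:4, "|b"))
  selfs <- dplyr::bind_rows(lapply(genes, function(g)
    tibble::tibble(query = g, subject = g, raw_score = 100,
                   qalnlen = 50L, salnlen = 50L, evalue = NA_real_)))
  within <- dplyr::bind_rows(lapply(list(genes[1:4], genes[5:8]), function(cl)
    dplyr::bind_rows(lapply(utils::combn(cl, 2, simplify = FALSE), function(p)
      tibble::tibble(query = p[1], subject = p[2], raw_score = 50,
                     qalnlen = 50L, salnlen = 50L, evalue = NA_real_)))))
  bridge <- tibble::tibble(query = genes[1], subject = genes[5],
                           raw_score = 40, qalnlen = 50L, salnlen = 50L,
                           evalue = NA_real_)
  g <- build_graph(dplyr::bind_rows(selfs, within, bridge),
                   stats::setNames(rep(50L, 8), genes))
  fams2 <- cluster_families(g)
  expect_equal(sort(fams2$size), c(4L, 4L))

  # an isolated gene is its own singleton family
  iso <- build_graph(mk_hits(list("T09|z", "T09|z", 100, 50, 50)),
                     c(`T09|z` = 50L))
  expect_equal(cluster_families(iso)$size, 1L)
})

test_that("families partition the genes and pairs satisfy the density rule", {
  b <- fixture_small_clean()$bench
  sub <- b$proteins[1:24]
  hits <- all_vs_all(sub, min_raw_score = 40)
  g <- build_graph(hits, stats::setNames(nchar(sub), names(sub)))
  fams <- cluster_families(g)
  all_members <- unlist(fams$members)
  expect_setequal(all_members, names(sub))
  expect_equal(length(all_members), length(unique(all_members)))
  for (i in seq_len(nrow(fams)))
    expect_true(fams$size[i] <= 2 || fams$edge_density[i] > 1 / 3)
})

test_that("single-copy selection demands exactly one gene per required taxon", {
  fams <- tibble::tibble(
    family_id = c("F1", "F2", "F3"),
    size = c(3L, 2L, 4L),
    members = list(c("T01|a", "T02|b", "T03|c"),
                   c("T01|d", "T02|e"),
                   c("T01|f", "T01|g", "T02|h", "T03|i")),
    taxa = list(c("T01", "T02", "T03"), c("T01", "T02"),
                c("T01", "T01", "T02", "T03")))
  sel <- select_single_copy(fams, c("T01", "T02", "T03"))
  expect_equal(sel$family_id, "F1")
  expect_true(all(sel$single_copy))
  expect_error(select_single_copy(fams, character(0)), "non-empty")
})
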