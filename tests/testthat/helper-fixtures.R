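# Memoized fixtures shared between test files (built once per test run).
.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, builder(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# small clean benchmark: 8 taxa, 12 single-copy families of 80 codons, on a
# fixed dated tree whose internal edges (>= 15 Ma) are resolvable from a few
# thousand sites -- so tree-inference checks are not hostage to tree shape
fixture_small_clean <- function() fixture("small_clean", function() {
  tr8 <- ape::read.tree(text = paste0(
    "((((T01:10,T02:10):15,T03:25):20,(T04:20,T05:20):25):25,",
    "((T06:30,T07:30):20,T08:50):20);"))
  b <- simulate_benchmark(n_families = 12, n_codons = 80,
                          dup_rate = 0, loss_rate = 0, species_tree = tr8,
                          seed = 21)
  gas <- lapply(seq_len(nrow(b$families)), function(i)
    align_family(b$families$cds[[i]], b$families$family_id[i]))
  sm <- concatenate_alignments(gas, b$species_tree$tip.label)
  list(bench = b, gene_alignments = gas, supermatrix = sm)
})

# 40 single-copy genes of 300 codons on the fixed benchmark tree
fixture_topology_bench <- function() fixture("topology_bench", function() {
  sp <- benchmark_species_tree()
  b <- simulate_benchmark(n_families = 40, n_codons = 300, dup_rate = 0,
                          loss_rate = 0, species_tree = sp, seed = 5)
  gas <- lapply(seq_len(40), function(i)
    align_family(b$families$cds[[i]], b$families$family_id[i]))
  list(tree = sp, bench = b, gene_alignments = gas)
})
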