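#' Simulate an ultrametric species tree
#'
#' Draws a pure-birth (Yule) tree conditioned on the number of extant taxa and
#' rescales it so the root sits at `root_age`.  The result is the dated
#' species tree that gene families are simulated inside: binary, ultrametric,
#' with ages strictly decreasing from the root to the (age-0) tips.
#'
#' @param n_taxa Number of extant taxa (>= 3).
#' @param birth_rate Speciation rate per unit time (> 0).  After rescaling to
#'   `root_age` it only shapes the relative node depths.
#' @param root_age Age of the root, in the time units used throughout (Ma in
#'   the dating module).
#' @param seed Integer seed; same seed, same tree.
#' @return An ultrametric `phylo` with tip labels `T01`, `T02`, ...
#' @examples
#' tr <- simulate_species_tree(15, seed = 1)
#' max(node_ages(tr))  # 100
#' @export
simulate_species_tree <- function(n_taxa, birth_rate = 0.1, root_age = 100,
                                  seed = NULL) {
  if (n_taxa < 3) stop("n_taxa must be >= 3")
  if (birth_rate <= 0 || root_age <= 0) stop("birth_rate and root_age must be > 0")
  local_seed(seed, {
    tr <- ape::rphylo(n_taxa, birth = birth_rate, death = 0)
    depth <- max(ape::node.depth.edgelength(tr))
    tr$edge.length <- tr$edge.length * (root_age / depth)
    tr$tip.label <- sprintf("T%02d", seq_len(n_taxa))
    tr
  })
}

#' Node ages of an ultrametric tree
#'
#' @param tree An ultrametric `phylo`.
#' @return Named numeric vector of ages (time before present) for every node,
#'   indexed `1..Ntip+Nnode` in `ape` numbering; tips have age ~0.
#' @export
node_ages <- function(tree) {
  depth <- ape::node.depth.edgelength(tree)
  age <- max(depth[seq_len(ape::Ntip(tree))]) - depth
  names(age) <- c(tree$tip.label, rep("", tree$Nnode))
  age
}

# --- recursive tree representation used by the simulators ------------------
# node: list(label, age, dup (logical), children = NULL | list of nodes)

phylo_to_rec <- function(tree) {
  ages <- node_ages(tree)
  ntip <- ape::Ntip(tree)
  kids <- split(tree$edge[, 2], tree$edge[, 1])
  build <- function(nd) {
    if (nd <= ntip)
      return(list(label = tree$tip.label[nd], age = unname(ages[nd]),
                  dup = FALSE, children = NULL))
    lab <- if (!is.null(tree$node.label)) tree$node.label[nd - ntip] else ""
    list(label = lab, age = unname(ages[nd]),
         dup = identical(lab, "D"),
         children = lapply(kids[[as.character(nd)]], build))
  }
  build(ntip + 1L)
}

rec_to_phylo <- function(rec) {
  # returns NULL for an empty tree, a degenerate single-tip marker for k = 1
  if (is.null(rec)) return(NULL)
  n_tip <- count_tips(rec)
  if (n_tip == 1L) {
    lab <- collect_tip_labels(rec)
    return(structure(list(single_tip = lab, age = rec$age), class = "rec_single"))
  }
  nwk <- function(nd, parent_age) {
    len <- format(parent_age - nd$age, scientific = FALSE, digits = 12)
    if (is.null(nd$children)) return(paste0(nd$label, ":", len))
    inner <- paste(vapply(nd$children, nwk, character(1),
                          parent_age = nd$age), collapse = ",")
    paste0("(", inner, ")", if (isTRUE(nd$dup)) "D" else "S", ":", len)
  }
  ape::read.tree(text = paste0(nwk(rec, rec$age), ";"))
}

count_tips <- function(rec) {
  if (is.null(rec)) 0L
  else if (is.null(rec$children)) 1L
  else sum(vapply(rec$children, count_tips, integer(1)))
}

collect_tip_labels <- function(rec) {
  if (is.null(rec)) character(0)
  else if (is.null(rec$children)) rec$label
  else unlist(lapply(rec$children, collect_tip_labels))
}

# drop lost lineages and suppress single-child internals
prune_rec <- function(rec) {
  if (is.null(rec)) return(NULL)
  if (is.null(rec$children)) return(rec)
  kids <- Filter(Negate(is.null), lapply(rec$children, prune_rec))
  if (length(kids) == 0L) return(NULL)
  if (length(kids) == 1L) return(kids[[1L]])
  rec$children <- kids
  rec
}

#' Perturb a dated tree by an age-compatible NNI
#'
#' Applies `n_moves` random nearest-neighbor interchanges that preserve
#' ultrametricity: a subtree is exchanged with its "uncle" subtree only when
#' the uncle is younger than the receiving node.  Used to generate gene-tree
#' discordance around a species tree (genes whose topology conflicts with
#' the species tree while remaining dated trees).
#'
#' @param tree Ultrametric `phylo`.
#' @param n_moves Number of successive NNI moves (default 1).
#' @param seed Integer seed.
#' @return An ultrametric `phylo` with the same tips and node ages.
#' @export
perturb_tree_nni <- function(tree, n_moves = 1, seed = NULL) {
  local_seed(seed, {
    rec <- phylo_to_rec(tree)
    for (k in seq_len(n_moves)) rec <- nni_once(rec)
    rec_to_phylo(rec)
  })
}

# one random age-compatible NNI on the rec form (in place via rebuild)
nni_once <- function(rec) {
  # enumerate eligible (path-to-P, child index of C, grandchild index, uncle index)
  moves <- list()
  walk <- function(nd, path) {
    if (is.null(nd$children)) return(invisible())
    for (ci in seq_along(nd$children)) {
      C <- nd$children[[ci]]
      if (is.null(C$children)) next
      for (ui in setdiff(seq_along(nd$children), ci)) {
        U <- nd$children[[ui]]
        if (U$age < C$age) {
          for (gi in seq_along(C$children))
            moves[[length(moves) + 1L]] <<- list(path = path, ci = ci,
                                                 ui = ui, gi = gi)
        }
      }
    }
    for (ci in seq_along(nd$children)) walk(nd$children[[ci]], c(path, ci))
  }
  walk(rec, integer(0))
  if (length(moves) == 0L) return(rec)
  mv <- moves[[sample.int(length(moves), 1L)]]
  get_node <- function(root, path) {
    nd <- root
    for (p in path) nd <- nd$children[[p]]
    nd
  }
  set_node <- function(root, path, value) {
    if (length(path) == 0L) return(value)
    root$children[[path[1L]]] <-
      set_node(root$children[[path[1L]]], path[-1L], value)
    root
  }
  P <- get_node(rec, mv$path)
  C <- P$children[[mv$ci]]
  G <- C$children[[mv$gi]]
  U <- P$children[[mv$ui]]
  C$children[[mv$gi]] <- U
  P$children[[mv$ui]] <- G
  P$children[[mv$ci]] <- C
  set_node(rec, mv$path, P)
}
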