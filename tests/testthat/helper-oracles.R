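# Brute-force oracles, written independently of the package internals:
# distances by climbing parent chains, Faith's PD by path enumeration.

# parent lookup: node -> parent node (0 at root)
bf_parents <- function(tree) {
  p <- integer(max(tree$edge))
  p[tree$edge[, 2L]] <- tree$edge[, 1L]
  p
}

# edge length keyed by child node
bf_edge_len <- function(tree) {
  len <- numeric(max(tree$edge))
  len[tree$edge[, 2L]] <- tree$edge.length
  len
}

# nodes on the path from `node` up to the root (inclusive)
bf_ancestry <- function(tree, node, parents = bf_parents(tree)) {
  path <- node
  while (parents[node] != 0L) {
    node <- parents[node]
    path <- c(path, node)
  }
  path
}

# patristic distance between two tip labels by explicit path sums
bf_patristic <- function(tree, a, b) {
  parents <- bf_parents(tree)
  len <- bf_edge_len(tree)
  ia <- match(a, tree$tip.label)
  ib <- match(b, tree$tip.label)
  pa <- bf_ancestry(tree, ia, parents)
  pb <- bf_ancestry(tree, ib, parents)
  mrca <- intersect(pa, pb)[1L] # ancestry paths list deepest first
  sum(len[pa[seq_len(match(mrca, pa) - 1L)]]) +
    sum(len[pb[seq_len(match(mrca, pb) - 1L)]])
}

bf_dist_matrix <- function(tree) {
  n <- length(tree$tip.label)
  d <- matrix(0, n, n, dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n)) {
    d[i, j] <- d[j, i] <- bf_patristic(tree, tree$tip.label[i], tree$tip.label[j])
  }
  d
}

# unweighted Faith's PD of a tip subset: sum the lengths of every edge lying
# on some tip-to-root path but not on all of them (i.e. strictly below the
# subset's MRCA), by counting path membership per edge
bf_faith_pd <- function(tree, taxa) {
  parents <- bf_parents(tree)
  len <- bf_edge_len(tree)
  counts <- integer(max(tree$edge))
  for (t in taxa) {
    node <- match(t, tree$tip.label)
    repeat {
      counts[node] <- counts[node] + 1L
      if (parents[node] == 0L) break
      node <- parents[node]
    }
  }
  on_path <- counts > 0L & counts < length(taxa)
  sum(len[on_path])
}

# a random community abundance vector over a subset of tips
rand_abund <- function(tree, n_species, seed) {
  set.seed(seed)
  sp <- sample(tree$tip.label, n_species)
  stats::setNames(stats::runif(n_species, 0.05, 1), sp)
}

fixture_tree <- function() ape::read.tree(text = "((A:1,B:1):1,C:2);")
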