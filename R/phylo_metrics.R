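# Abundance-weighted phylogeny-based diversity metrics, one per dimension:
#   richness    - Faith's PD (sum of branch lengths of the subset tree),
#   divergence  - MPD (mean pairwise patristic distance),
#   regularity  - VPD (variance of pairwise patristic distances; lower
#                 variance = higher regularity).
# All three are "type II" metrics: computed on the subset phylogeny (or the
# pairwise distances) of the species actually present in a plot, weighted by
# relative abundance (e.g. percentage cover). With equal abundances they
# reduce exactly to the classical unweighted forms.

# Logical edges-x-tips incidence: desc[e, t] is TRUE when tip t descends from
# edge e (i.e. from the child node of e). Rows follow tree$edge order.
edge_tip_incidence <- function(tree) {
  nt <- length(tree$tip.label)
  nn <- tree$Nnode
  po <- ape::reorder.phylo(tree, "postorder")$edge
  desc <- matrix(FALSE, nt + nn, nt)
  desc[cbind(seq_len(nt), seq_len(nt))] <- TRUE
  for (i in seq_len(nrow(po)))
    desc[po[i, 1L], ] <- desc[po[i, 1L], ] | desc[po[i, 2L], ]
  desc[tree$edge[, 2L], , drop = FALSE]
}

#' Abundance-weighted Faith's phylogenetic diversity
#'
#' Faith's PD of the species with positive abundance, weighted Barker-style:
#' the tree is pruned to those species (stem above their common ancestor
#' discarded); each branch `i` of the pruned tree, with length \eqn{\lambda_i},
#' is weighted by the mean relative abundance \eqn{\bar{A}_i} of the species
#' descending from it, and
#' \deqn{PD_w = B \frac{\sum_i \lambda_i \bar{A}_i}{\sum_i \bar{A}_i}}
#' with `B` the number of branches. With equal abundances this is exactly the
#' unweighted Faith's PD, i.e. the plain sum of branch lengths.
#'
#' @param tree a `phylo` object containing all positive-abundance species.
#' @param abundances named nonnegative numeric vector of raw abundances or
#'   covers; only the relative values matter.
#' @return the weighted PD, or `NA` (with a message) when fewer than two
#'   species have positive abundance.
#' @seealso [weighted_mpd()], [weighted_vpd()], [diversity_table()]
#' @export
#' @examples
#' tr <- ape::read.tree(text = "((A:1,B:3):1,C:2);")
#' weighted_faith_pd(tr, c(B = 0.9, C = 0.1)) # 7.6
#' weighted_faith_pd(tr, c(A = 1, B = 1, C = 1)) # 5, the branch-length sum
weighted_faith_pd <- function(tree, abundances) {
  validate_phylo(tree)
  f <- check_abundances(abundances, tree$tip.label, what = "tree")
  if (length(f) < 2L) {
    message("weighted_faith_pd: fewer than 2 species with positive abundance; returning NA")
    return(NA_real_)
  }
  sub <- if (length(f) == length(tree$tip.label)) {
    tree$root.edge <- NULL
    tree
  } else prune_to_taxa(tree, names(f))
  f <- f[sub$tip.label] / sum(f)
  desc <- edge_tip_incidence(sub)
  abar <- as.numeric(desc %*% f) / rowSums(desc)
  nrow(sub$edge) * sum(sub$edge.length * abar) / sum(abar)
}

#' Abundance-weighted mean pairwise phylogenetic distance (MPD)
#'
#' \deqn{MPD = \sum_{j<k} f_j f_k d_{jk} / \sum_{j<k} f_j f_k} over the
#' species with positive abundance, where `f` are relative abundances and
#' `d` patristic distances. Invariant under rescaling of the abundances;
#' with equal abundances it is the plain mean of the pairwise distances.
#'
#' @param dist symmetric patristic distance matrix (see
#'   [pairwise_distances()]) whose dimnames cover all positive-abundance
#'   species.
#' @param abundances named nonnegative numeric vector.
#' @return the weighted MPD, or `NA` (with a message) when fewer than two
#'   species have positive abundance.
#' @export
#' @examples
#' d <- pairwise_distances(ape::read.tree(text = "((A:1,B:1):1,C:2);"))
#' weighted_mpd(d, c(A = 0.5, B = 0.25, C = 0.25)) # 3.2
weighted_mpd <- function(dist, abundances) {
  pw <- pair_weights(dist, abundances)
  if (is.null(pw)) return(NA_real_)
  sum(pw$w * pw$d) / pw$wtot
}

#' Abundance-weighted variance of pairwise phylogenetic distances (VPD)
#'
#' Weighted population variance of the pairwise patristic distances,
#' \deqn{VPD = \sum_{j<k} w_{jk} d_{jk}^2 / \sum_{j<k} w_{jk} - MPD^2,}
#' with pair weights \eqn{w_{jk} = f_j f_k} over unordered pairs. Lower VPD
#' means higher phylogenetic regularity. With a single pair (two species)
#' the variance is zero.
#'
#' @inheritParams weighted_mpd
#' @return the weighted VPD, or `NA` (with a message) when fewer than two
#'   species have positive abundance.
#' @export
weighted_vpd <- function(dist, abundances) {
  pw <- pair_weights(dist, abundances)
  if (is.null(pw)) return(NA_real_)
  m <- sum(pw$w * pw$d) / pw$wtot
  v <- sum(pw$w * pw$d^2) / pw$wtot - m^2
  max(v, 0) # clamp tiny negative round-off
}

# Shared setup for the pairwise metrics: validate, subset to positive
# abundances, return unordered-pair distances and weights.
pair_weights <- function(dist, abundances) {
  if (!is.matrix(dist) || is.null(rownames(dist)))
    abort_cladiv("`dist` must be a labelled distance matrix")
  f <- check_abundances(abundances, rownames(dist), what = "distance matrix")
  if (length(f) < 2L) {
    message("pairwise metric: fewer than 2 species with positive abundance; returning NA")
    return(NULL)
  }
  d <- dist[names(f), names(f)]
  ut <- upper.tri(d)
  w <- (f %o% f)[ut]
  list(d = d[ut], w = w, wtot = sum(w))
}

check_abundances <- function(abundances, known, what) {
  if (is.null(names(abundances)))
    abort_cladiv("`abundances` must be a named vector")
  if (anyNA(abundances) || any(abundances < 0))
    abort_cladiv("`abundances` must be nonnegative and non-missing")
  f <- abundances[abundances > 0]
  missing <- setdiff(names(f), known)
  if (length(missing))
    abort_cladiv(sprintf("species with positive abundance not in %s: %s",
                         what, paste(missing, collapse = ", ")))
  f
}

#' Per-site table of phylogeny-based diversity metrics
#'
#' Applies [weighted_faith_pd()], [weighted_mpd()] and [weighted_vpd()] to
#' every site of a community matrix, normalizing each site's abundances to
#' proportions. Sites with a single species get `NA` for all three metrics
#' (pairwise quantities are undefined there).
#'
#' @param tree a `phylo` object containing every species with positive
#'   abundance anywhere in `comm` (unless `allow_drop`).
#' @param comm sites x species numeric matrix of raw covers/abundances.
#' @param allow_drop drop (with a message) species absent from the tree
#'   instead of erroring.
#' @return data.frame with columns `site`, `S`, `PD`, `MPD`, `VPD`.
#' @export
#' @examples
#' tr <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
#' comm <- matrix(c(30, 70, 0, 10, 0, 90), 2, byrow = TRUE,
#'                dimnames = list(c("s1", "s2"), c("A", "B", "C")))
#' diversity_table(tr, comm)
diversity_table <- function(tree, comm, allow_drop = FALSE) {
  validate_phylo(tree)
  validate_community(comm)
  comm <- align_community(comm, tree$tip.label, what = "tree",
                          allow_drop = allow_drop)
  present <- colnames(comm)[colSums(comm > 0) > 0]
  pool_tree <- if (length(present) >= 2L && length(present) < length(tree$tip.label))
    prune_to_taxa(tree, present) else tree
  comm <- comm[, intersect(colnames(comm), pool_tree$tip.label), drop = FALSE]

  S <- rowSums(comm > 0)
  res <- data.frame(site = rownames(comm), S = as.integer(S),
                    PD = NA_real_, MPD = NA_real_, VPD = NA_real_,
                    stringsAsFactors = FALSE, row.names = NULL)
  multi <- S >= 2
  if (!any(multi)) return(res)

  f <- comm / rowSums(comm)
  d <- pairwise_distances(pool_tree)[colnames(comm), colnames(comm)]
  # vectorized pair sums: f'Df double-counts ordered pairs, as does the
  # weight total (sum f)^2 - sum f^2, so the ratios are the pair-form values
  num1 <- rowSums((f %*% d) * f)
  num2 <- rowSums((f %*% (d^2)) * f)
  wtot <- 1 - rowSums(f^2)
  res$MPD[multi] <- (num1 / wtot)[multi]
  res$VPD[multi] <- pmax((num2 / wtot - (num1 / wtot)^2)[multi], 0)
  res$PD <- pd_weighted_batch(pool_tree, comm)
  res
}

# Batch Barker-weighted PD over the rows of a community matrix, without
# pruning a tree per site. Edges of the site's implicit subset tree are the
# pool-tree edges whose descendant set intersects the site's species in a
# nonempty proper subset; chains of edges with identical intersections are
# the merged branches (equal descendant counts along a parent chain imply
# equal sets, since the child's set is contained in the parent's).
pd_weighted_batch <- function(tree, comm) {
  stopifnot(all(colnames(comm) %in% tree$tip.label))
  f <- comm / rowSums(comm)
  full <- matrix(0, nrow(comm), length(tree$tip.label),
                 dimnames = list(rownames(comm), tree$tip.label))
  full[, colnames(f)] <- f
  desc <- edge_tip_incidence(tree) * 1
  cnt <- desc %*% t(full > 0)  # edges x sites: positive species under edge
  sf  <- desc %*% t(full)      # edges x sites: summed relative abundance
  S <- colSums(t(full) > 0)
  parent_edge <- match(tree$edge[, 1L], tree$edge[, 2L]) # NA at root children
  len <- tree$edge.length
  out <- rep(NA_real_, nrow(comm))
  for (i in seq_len(nrow(comm))) {
    if (S[i] < 2L) next
    ci <- cnt[, i]
    keep <- ci > 0 & ci < S[i]
    abar <- sf[, i] / ci
    same_as_parent <- !is.na(parent_edge) & keep[pmax(parent_edge, 1L)] &
      ci[pmax(parent_edge, 1L)] == ci
    head <- keep & !same_as_parent
    out[i] <- sum(head) * sum(len[keep] * abar[keep]) / sum(abar[head])
  }
  out
}

#' Write a diversity table as TSV
#' @param div data.frame from [diversity_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_diversity_table <- function(div, path) {
  write_tsv_na(div, path)
  invisible(path)
}
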