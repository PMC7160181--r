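# Data input/output: phylogenies, community matrices, clade maps, and the
# patristic distances everything downstream consumes.
#
# Conventions:
#  * trees are ape "phylo" objects, rooted, branch lengths required,
#    polytomies and zero-length edges allowed (supertree polytomies are
#    commonly encoded as 0-length edges);
#  * community matrices are numeric matrices, sites in rows, species in
#    columns, raw covers/abundances (normalization to proportions happens
#    inside the metric and index functions, never at read time);
#  * clade maps are named character vectors, names = species, values = clade.

#' Validate a phylogeny
#'
#' Checks the invariants assumed throughout the package: a rooted `phylo`
#' object with at least one tip, unique tip labels, and a nonnegative branch
#' length on every edge.
#'
#' @param tree an [ape::read.tree()]-style `phylo` object.
#' @param arg name used in error messages.
#' @return `tree`, invisibly, if valid; otherwise an error.
#' @export
validate_phylo <- function(tree, arg = "tree") {
  if (!inherits(tree, "phylo"))
    abort_cladiv(sprintf("`%s` must be a 'phylo' object", arg))
  if (length(tree$tip.label) < 1L)
    abort_cladiv(sprintf("`%s` has no tips", arg))
  dup <- unique(tree$tip.label[duplicated(tree$tip.label)])
  if (length(dup))
    abort_cladiv(sprintf("duplicate tip labels in `%s`: %s", arg,
                         paste(dup, collapse = ", ")))
  if (is.null(tree$edge.length))
    abort_cladiv(sprintf("`%s` has no branch lengths", arg))
  if (anyNA(tree$edge.length))
    abort_cladiv(sprintf("`%s` has missing branch lengths", arg))
  if (any(tree$edge.length < 0))
    abort_cladiv(sprintf("`%s` has negative branch lengths", arg))
  invisible(tree)
}

#' Read a rooted phylogeny from a Newick file
#'
#' Thin wrapper around [ape::read.tree()] that enforces the package's tree
#' invariants: one tree per file, unique tip labels, a branch length on every
#' edge (zero lengths allowed), polytomies retained.
#'
#' @param path path to a file containing a single Newick string.
#' @return a `phylo` object.
#' @export
#' @examples
#' tf <- tempfile(fileext = ".nwk")
#' writeLines("((A:1,B:1):1,C:2);", tf)
#' tr <- read_newick(tf)
#' tr$tip.label
read_newick <- function(path) {
  if (!file.exists(path)) abort_cladiv(sprintf("file not found: %s", path))
  tree <- tryCatch(ape::read.tree(path),
                   warning = function(w) abort_cladiv(
                     sprintf("malformed Newick in %s: %s", path, conditionMessage(w))),
                   error = function(e) abort_cladiv(
                     sprintf("malformed Newick in %s: %s", path, conditionMessage(e))))
  if (is.null(tree))
    abort_cladiv(sprintf("malformed Newick in %s: no tree could be parsed", path))
  if (inherits(tree, "multiPhylo")) {
    if (length(tree) != 1L)
      abort_cladiv(sprintf("%s contains %d trees; expected exactly one",
                           path, length(tree)))
    tree <- tree[[1L]]
  }
  validate_phylo(tree, arg = path)
  tree
}

#' Write a phylogeny to a Newick file
#'
#' @param tree a `phylo` object.
#' @param path output file path.
#' @param digits significant digits for branch lengths.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path, digits = 12) {
  validate_phylo(tree)
  ape::write.tree(tree, file = path, digits = digits)
  invisible(path)
}

#' Prune a phylogeny to a set of taxa
#'
#' Keeps exactly `taxa`, suppresses the resulting unary nodes (summing branch
#' lengths along collapsed paths), and re-roots at the most recent common
#' ancestor of `taxa`; any stem edge above that ancestor is discarded.
#' Patristic distances among the retained taxa are unchanged.
#'
#' @param tree a `phylo` object.
#' @param taxa character vector of at least two tip labels.
#' @return the pruned `phylo` object.
#' @export
#' @examples
#' tr <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
#' ape::write.tree(prune_to_taxa(tr, c("A", "C")))
prune_to_taxa <- function(tree, taxa) {
  validate_phylo(tree)
  taxa <- unique(as.character(taxa))
  missing <- setdiff(taxa, tree$tip.label)
  if (length(missing))
    abort_cladiv(sprintf("taxa not in tree: %s", paste(missing, collapse = ", ")))
  if (length(taxa) < 2L)
    abort_cladiv("need at least 2 taxa to prune to")
  out <- ape::keep.tip(tree, taxa)
  out$root.edge <- NULL # stem above the MRCA is not part of the subset tree
  out
}

#' Pairwise patristic distances among tips
#'
#' Sum of branch lengths along the tree path between every pair of tips.
#' On an ultrametric (time-calibrated) tree this equals twice the divergence
#' time of the pair.
#'
#' @param tree a `phylo` object with at least two tips.
#' @return a symmetric numeric matrix with rows/columns in `tree$tip.label`
#'   order and zero diagonal.
#' @export
#' @examples
#' tr <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
#' pairwise_distances(tr)
pairwise_distances <- function(tree) {
  validate_phylo(tree)
  if (length(tree$tip.label) < 2L)
    abort_cladiv("pairwise distances need at least 2 tips")
  d <- stats::cophenetic(tree)
  d[tree$tip.label, tree$tip.label, drop = FALSE]
}

#' Read a community matrix from TSV/CSV
#'
#' Sites in rows, species in columns; the first column holds site identifiers.
#' Values are raw percentage covers or abundances; blank and NA cells are read
#' as zero. Rows need not sum to anything in particular - normalization to
#' proportions is done inside the metric/index functions.
#'
#' @param path path to a delimited text file. Field separator is inferred from
#'   the extension (`.csv` = comma, otherwise tab) unless `sep` is given.
#' @param sep optional field separator override.
#' @return numeric matrix, `rownames` = site ids, `colnames` = species.
#' @export
read_community <- function(path, sep = NULL) {
  if (!file.exists(path)) abort_cladiv(sprintf("file not found: %s", path))
  sep <- sep %||% if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE, comment.char = "",
                          quote = "\"")
  if (ncol(df) < 2L)
    abort_cladiv(sprintf("%s: expected a site-id column plus species columns", path))
  sites <- as.character(df[[1L]])
  if (anyDuplicated(sites))
    abort_cladiv(sprintf("%s: duplicated site ids: %s", path,
                         paste(unique(sites[duplicated(sites)]), collapse = ", ")))
  species <- colnames(df)[-1L]
  if (anyDuplicated(species))
    abort_cladiv(sprintf("%s: duplicated species columns: %s", path,
                         paste(unique(species[duplicated(species)]), collapse = ", ")))
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  m[is.na(m)] <- 0
  rownames(m) <- sites
  validate_community(m, arg = path)
  m
}

#' Validate a community matrix
#'
#' @param comm numeric matrix, sites x species.
#' @param arg name used in error messages.
#' @return `comm`, invisibly.
#' @export
validate_community <- function(comm, arg = "comm") {
  if (!is.matrix(comm) || !is.numeric(comm))
    abort_cladiv(sprintf("`%s` must be a numeric matrix (sites x species)", arg))
  if (is.null(rownames(comm)) || is.null(colnames(comm)))
    abort_cladiv(sprintf("`%s` must have site rownames and species colnames", arg))
  if (anyNA(comm))
    abort_cladiv(sprintf("`%s` contains NA values", arg))
  neg <- which(comm < 0, arr.ind = TRUE)
  if (nrow(neg))
    abort_cladiv(sprintf("negative abundance in `%s` at site '%s', species '%s'",
                         arg, rownames(comm)[neg[1L, 1L]], colnames(comm)[neg[1L, 2L]]))
  empty <- rownames(comm)[rowSums(comm > 0) == 0]
  if (length(empty))
    abort_cladiv(sprintf("`%s`: sites with no positive abundance: %s", arg,
                         paste(empty, collapse = ", ")))
  invisible(comm)
}

#' Write a community matrix as TSV
#' @param comm sites x species numeric matrix.
#' @param path output path.
#' @param id_col name of the leading site-id column.
#' @return `path`, invisibly.
#' @export
write_community <- function(comm, path, id_col = "site") {
  df <- data.frame(rownames(comm), comm, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1L] <- id_col
  write_tsv_na(df, path)
  invisible(path)
}

#' Read a species-to-clade map
#'
#' Two-column headered TSV (`species`, `clade`). Duplicated species rows are
#' tolerated when they agree and rejected when they conflict.
#'
#' @param path path to the TSV file.
#' @return named character vector: names = species, values = clade labels.
#' @export
read_clade_map <- function(path) {
  if (!file.exists(path)) abort_cladiv(sprintf("file not found: %s", path))
  df <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE, comment.char = "", quote = "\"")
  if (ncol(df) < 2L)
    abort_cladiv(sprintf("%s: expected two columns (species, clade)", path))
  sp <- as.character(df[[1L]]); cl <- as.character(df[[2L]])
  if (anyNA(sp) || anyNA(cl) || any(sp == "") || any(cl == ""))
    abort_cladiv(sprintf("%s: empty species or clade entries", path))
  if (anyDuplicated(sp)) {
    conf <- vapply(split(cl, sp), function(x) length(unique(x)) > 1L, logical(1))
    if (any(conf))
      abort_cladiv(sprintf("%s: species mapped to conflicting clades: %s", path,
                           paste(names(conf)[conf], collapse = ", ")))
    keep <- !duplicated(sp)
    sp <- sp[keep]; cl <- cl[keep]
  }
  stats::setNames(cl, sp)
}

#' Write a clade map as TSV
#' @param clade_map named character vector (species -> clade).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_clade_map <- function(clade_map, path) {
  write_tsv_na(data.frame(species = names(clade_map),
                          clade = unname(clade_map),
                          stringsAsFactors = FALSE), path)
  invisible(path)
}

# Reconcile a community matrix with the species known to a tree or clade map.
# Unknown species are an error unless allow_drop = TRUE, in which case they
# are removed with a message (no silent dropping).
align_community <- function(comm, known, what = "tree", allow_drop = FALSE) {
  present <- colnames(comm)[colSums(comm > 0) > 0]
  missing <- setdiff(present, known)
  if (length(missing)) {
    if (!allow_drop)
      abort_cladiv(sprintf("species in community but not in %s: %s", what,
                           paste(missing, collapse = ", ")))
    message(sprintf("dropping %d species absent from %s: %s",
                    length(missing), what, paste(missing, collapse = ", ")))
    comm <- comm[, setdiff(colnames(comm), missing), drop = FALSE]
    if (any(rowSums(comm > 0) == 0))
      abort_cladiv("dropping unmatched species left sites with no species")
  }
  comm
}
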