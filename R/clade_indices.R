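# The clade indices: phylogeny-free surrogates for the three dimensions of
# phylogenetic diversity, computed from clade proportions in a plot plus
# species-richness bookkeeping of the reference species pool. No tree needed.
#
# Notation (used throughout):
#   S      species richness of a plot
#   p_i    proportion (relative cover/abundance) of clade i in the plot
#   CR_i   species richness of clade i in the whole species pool
#   CR_SP  number of defined clades in the whole species pool
#   S_SP   species richness of the whole species pool

#' Summarize a species pool by clade
#'
#' Counts species per clade (`CR_i`), the number of clades (`CR_SP`) and the
#' pool richness (`S_SP`) over a reference species pool - by convention all
#' species appearing in the dataset.
#'
#' @param clade_map named character vector (species -> clade), e.g. from
#'   [read_clade_map()] or [clade_map_from_tree()].
#' @param pool_species character vector of pool species; defaults to every
#'   mapped species.
#' @return an object of class `clade_pool`: list with `clade_richness`
#'   (named integer vector `CR_i`), `CR_SP`, and `S_SP`.
#' @export
#' @examples
#' cm <- c(A = "f1", B = "f1", C = "f2")
#' summarize_pool(cm)
summarize_pool <- function(clade_map, pool_species = NULL) {
  if (is.null(names(clade_map)) || !is.character(clade_map))
    abort_cladiv("`clade_map` must be a named character vector (species -> clade)")
  pool_species <- unique(as.character(pool_species %||% names(clade_map)))
  unmapped <- setdiff(pool_species, names(clade_map))
  if (length(unmapped))
    abort_cladiv(sprintf("pool species with no clade assignment: %s",
                         paste(unmapped, collapse = ", ")))
  cr <- table(factor(clade_map[pool_species]))
  cr <- stats::setNames(as.integer(cr), names(cr))
  cr <- cr[order(names(cr))]
  structure(list(clade_richness = cr,
                 CR_SP = length(cr),
                 S_SP = length(pool_species)),
            class = "clade_pool")
}

#' @export
print.clade_pool <- function(x, ...) {
  cat(sprintf("Species pool: %d species in %d clades\n", x$S_SP, x$CR_SP))
  print(x$clade_richness)
  invisible(x)
}

#' Clade proportions of a single plot
#'
#' Relative abundance of every pool clade in the plot: summed abundance of
#' the plot's species in clade `i` divided by the plot total. Clades of the
#' pool absent from the plot get `p_i = 0`; the proportions sum to one.
#'
#' @param site_abundances named nonnegative numeric vector (raw covers).
#' @param clade_map named character vector (species -> clade).
#' @param pool a `clade_pool` from [summarize_pool()].
#' @return named numeric vector over all pool clades, summing to 1.
#' @export
#' @examples
#' cm <- c(A = "f1", B = "f1", C = "f2")
#' pool <- summarize_pool(cm)
#' clade_proportions(c(A = 30, B = 30, C = 40), cm, pool)
clade_proportions <- function(site_abundances, clade_map, pool) {
  stopifnot(inherits(pool, "clade_pool"))
  if (is.null(names(site_abundances)))
    abort_cladiv("`site_abundances` must be a named vector")
  if (anyNA(site_abundances) || any(site_abundances < 0))
    abort_cladiv("`site_abundances` must be nonnegative and non-missing")
  pos <- site_abundances[site_abundances > 0]
  tot <- sum(pos)
  if (tot <= 0) abort_cladiv("site has zero total abundance")
  unmapped <- setdiff(names(pos), names(clade_map))
  if (length(unmapped))
    abort_cladiv(sprintf("species with no clade assignment: %s",
                         paste(unmapped, collapse = ", ")))
  cl <- clade_map[names(pos)]
  alien <- setdiff(unique(cl), names(pool$clade_richness))
  if (length(alien))
    abort_cladiv(sprintf("clades not in the species pool: %s",
                         paste(alien, collapse = ", ")))
  p <- stats::setNames(numeric(pool$CR_SP), names(pool$clade_richness))
  agg <- tapply(pos, cl, sum)
  p[names(agg)] <- agg / tot
  p
}

#' Clade richness index
#'
#' Surrogate for phylogenetic richness (Faith's PD):
#' \deqn{\log(S) + 3 \sum_i p_i / CR_i} (natural log). Species-rich clades
#' are penalized by their pool richness, so shifting cover toward
#' species-poor clades - whose members tend to be relatively distantly
#' related to the rest of the plot - raises the index, as does species
#' richness itself.
#'
#' @param S plot species richness (>= 1).
#' @param p clade proportions from [clade_proportions()].
#' @param pool a `clade_pool`.
#' @return the index value (unitless).
#' @export
clade_richness_index <- function(S, p, pool) {
  stopifnot(inherits(pool, "clade_pool"))
  if (!is.numeric(S) || length(S) != 1L || is.na(S) || S < 1)
    abort_cladiv("`S` must be a single value >= 1")
  p <- check_proportions(p, pool)
  log(S) + 3 * sum(p / pool$clade_richness[names(p)])
}

#' Clade divergence index
#'
#' Surrogate for phylogenetic divergence (MPD):
#' \deqn{1 - \sum_{i=1}^{CR_{SP}} (p_i - 1/CR_{SP})^2,} summing over all pool
#' clades (absent clades enter with \eqn{p_i = 0}). Equals one exactly when
#' every pool clade is present in equal proportion; deviations from those
#' optimal proportions lower the value. Always strictly positive.
#'
#' @param p clade proportions from [clade_proportions()].
#' @param pool a `clade_pool`.
#' @param absent `"include"` (default) sums over all pool clades;
#'   `"exclude"` restricts the sum to clades present in the plot, for
#'   sensitivity checks.
#' @return the index value (unitless).
#' @export
clade_divergence_index <- function(p, pool, absent = c("include", "exclude")) {
  stopifnot(inherits(pool, "clade_pool"))
  absent <- match.arg(absent)
  p <- check_proportions(p, pool)
  if (absent == "exclude") p <- p[p > 0]
  1 - sum((p - 1 / pool$CR_SP)^2)
}

#' Clade regularity index
#'
#' Surrogate for phylogenetic regularity (low VPD):
#' \deqn{1 - \sum_{i=1}^{CR_{SP}} (p_i - CR_i/S_{SP})^2} over all pool
#' clades. Equals one exactly when each clade's proportion matches its
#' relative species richness in the pool. For extreme proportions the value
#' can be negative; it is returned as-is, never clipped, so downstream
#' filters (e.g. restricting to values above 0.2) see the raw index.
#'
#' @inheritParams clade_divergence_index
#' @return the index value (unitless).
#' @export
clade_regularity_index <- function(p, pool, absent = c("include", "exclude")) {
  stopifnot(inherits(pool, "clade_pool"))
  absent <- match.arg(absent)
  p <- check_proportions(p, pool)
  opt <- pool$clade_richness[names(p)] / pool$S_SP
  if (absent == "exclude") { opt <- opt[p > 0]; p <- p[p > 0] }
  1 - sum((p - opt)^2)
}

check_proportions <- function(p, pool) {
  if (is.null(names(p))) abort_cladiv("`p` must be a named vector of clade proportions")
  extra <- setdiff(names(p), names(pool$clade_richness))
  if (length(extra))
    abort_cladiv(sprintf("proportions for clades not in the pool: %s",
                         paste(extra, collapse = ", ")))
  if (anyNA(p) || any(p < 0))
    abort_cladiv("clade proportions must be nonnegative and non-missing")
  if (abs(sum(p) - 1) > 1e-8)
    abort_cladiv("clade proportions must sum to 1")
  # absent pool clades implicitly contribute p = 0
  full <- stats::setNames(numeric(pool$CR_SP), names(pool$clade_richness))
  full[names(p)] <- p
  full
}

#' Per-site table of clade indices
#'
#' Applies the three clade indices to every site of a community matrix. The
#' reference species pool defaults to all species with positive abundance
#' anywhere in the matrix ("all species in the dataset"); pass an explicit
#' `pool` to override, e.g. when plots are a subset of a larger survey.
#' Computing the indices at a finer clade resolution needs nothing but a
#' different `clade_map`.
#'
#' @param comm sites x species numeric matrix of raw covers/abundances.
#' @param clade_map named character vector (species -> clade).
#' @param pool optional `clade_pool`; default built from `comm` and
#'   `clade_map`.
#' @param absent summation domain for the divergence/regularity indices, see
#'   [clade_divergence_index()].
#' @param allow_drop drop (with a message) species absent from the clade map
#'   instead of erroring.
#' @return data.frame with columns `site`, `S`, `clade_richness_index`,
#'   `clade_divergence_index`, `clade_regularity_index`.
#' @export
#' @examples
#' comm <- matrix(c(30, 30, 40, 10, 0, 90), 2, byrow = TRUE,
#'                dimnames = list(c("s1", "s2"), c("A", "B", "C")))
#' clade_index_table(comm, c(A = "f1", B = "f1", C = "f2"))
clade_index_table <- function(comm, clade_map, pool = NULL,
                              absent = c("include", "exclude"),
                              allow_drop = FALSE) {
  validate_community(comm)
  absent <- match.arg(absent)
  comm <- align_community(comm, names(clade_map), what = "clade map",
                          allow_drop = allow_drop)
  if (is.null(pool)) {
    present <- colnames(comm)[colSums(comm > 0) > 0]
    pool <- summarize_pool(clade_map, present)
  }
  stopifnot(inherits(pool, "clade_pool"))
  res <- data.frame(site = rownames(comm),
                    S = as.integer(rowSums(comm > 0)),
                    clade_richness_index = NA_real_,
                    clade_divergence_index = NA_real_,
                    clade_regularity_index = NA_real_,
                    stringsAsFactors = FALSE, row.names = NULL)
  cr <- pool$clade_richness
  used <- colnames(comm)[colSums(comm > 0) > 0]
  unmapped <- setdiff(used, names(clade_map))
  if (length(unmapped))
    abort_cladiv(sprintf("species with no clade assignment: %s",
                         paste(unmapped, collapse = ", ")))
  alien <- setdiff(unique(clade_map[used]), names(cr))
  if (length(alien))
    abort_cladiv(sprintf("clades not in the species pool: %s",
                         paste(alien, collapse = ", ")))
  if (absent == "include") {
    # vectorized: site x clade proportion matrix, then closed-form indices
    z <- outer(clade_map[colnames(comm)], names(cr), `==`) * 1
    z[is.na(z)] <- 0 # all-zero columns may be unmapped; they contribute nothing
    p <- (comm / rowSums(comm)) %*% z
    res$clade_richness_index <- log(res$S) + 3 * as.numeric(p %*% (1 / cr))
    res$clade_divergence_index <- 1 - rowSums((p - 1 / pool$CR_SP)^2)
    opt <- matrix(cr / pool$S_SP, nrow(p), pool$CR_SP, byrow = TRUE)
    res$clade_regularity_index <- 1 - rowSums((p - opt)^2)
  } else {
    for (i in seq_len(nrow(comm))) {
      p <- clade_proportions(comm[i, ], clade_map, pool)
      res$clade_richness_index[i] <- clade_richness_index(res$S[i], p, pool)
      res$clade_divergence_index[i] <- clade_divergence_index(p, pool, absent)
      res$clade_regularity_index[i] <- clade_regularity_index(p, pool, absent)
    }
  }
  res
}

#' Write a clade-index table as TSV
#' @param idx data.frame from [clade_index_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_clade_index_table <- function(idx, path) {
  write_tsv_na(idx, path)
  invisible(path)
}
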