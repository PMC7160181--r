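# Simulation workflow: species pools sampled from a phylogeny, random
# community matrices over species-richness ranges, and the factorial design
# (phylogenetic scale x pool size x richness range x replicate) used to map
# where the clade indices track the phylogeny-based metrics. Self-contained
# generators (Yule trees, depth-cut clade maps) mean nothing has to be
# downloaded; user-supplied trees and clade maps plug into the same design.

#' Simulate an ultrametric Yule (pure-birth) tree
#'
#' @param n_tips number of tips (>= 2).
#' @param seed optional integer seed; the same seed gives an identical tree.
#' @param height optional total tree height; branch lengths are rescaled so
#'   the tip-to-root depth equals `height` (time units are arbitrary).
#' @param birth speciation rate of the pure-birth process.
#' @return an ultrametric `phylo` object with tips `t1..tn`.
#' @export
#' @examples
#' tr <- simulate_yule_tree(10, seed = 1, height = 100)
#' max(ape::node.depth.edgelength(tr))
simulate_yule_tree <- function(n_tips, seed = NULL, height = NULL, birth = 1) {
  if (!is.numeric(n_tips) || length(n_tips) != 1L || is.na(n_tips) || n_tips < 2)
    abort_cladiv("`n_tips` must be a single integer >= 2")
  tree <- with_seed(seed, ape::rphylo(as.integer(n_tips), birth = birth,
                                      death = 0, fossils = FALSE))
  if (!is.null(height)) {
    h <- max(ape::node.depth.edgelength(tree))
    tree$edge.length <- tree$edge.length * (height / h)
  }
  tree
}

#' Sample a species pool from a phylogeny
#'
#' Uniform sample of tips without replacement, returned together with the
#' phylogeny pruned to the sample (for metric computation).
#'
#' @param tree a `phylo` object.
#' @param size pool size, `2 <= size <=` number of tips.
#' @param seed optional integer seed.
#' @param prune set `FALSE` to skip building the pruned tree (cheaper when
#'   only the species list is needed).
#' @return list with `species` (character) and `tree` (pruned `phylo`, or
#'   `NULL` when `prune = FALSE`).
#' @export
sample_species_pool <- function(tree, size, seed = NULL, prune = TRUE) {
  validate_phylo(tree)
  nt <- length(tree$tip.label)
  if (!is.numeric(size) || length(size) != 1L || is.na(size) || size < 2)
    abort_cladiv("`size` must be a single integer >= 2")
  if (size > nt)
    abort_cladiv(sprintf("pool size %d exceeds the %d tips of the tree", size, nt))
  species <- with_seed(seed, sample_from(tree$tip.label, as.integer(size)))
  list(species = species,
       tree = if (prune) {
         if (size == nt) tree else prune_to_taxa(tree, species)
       } else NULL)
}

#' Generate a random community matrix over a species pool
#'
#' Per site: species richness `S` is drawn uniformly from the integer range,
#' `S` pool species are drawn uniformly without replacement, and their
#' proportions are independent uniform draws renormalized to sum to one.
#' `proportions = "dirichlet"` draws from a flat Dirichlet (uniform on the
#' simplex) instead, as a sensitivity alternative with heavier dominance.
#'
#' @param pool character vector of pool species.
#' @param richness_range integer pair `c(min, max)`, `1 <= min <= max <=`
#'   pool size.
#' @param n_sites number of sites (rows).
#' @param seed optional integer seed.
#' @param proportions `"uniform"` (default) or `"dirichlet"`.
#' @return sites x pool-species numeric matrix; rows sum to 1.
#' @export
#' @examples
#' m <- generate_community_matrix(letters, c(3, 5), n_sites = 4, seed = 1)
#' rowSums(m)
generate_community_matrix <- function(pool, richness_range, n_sites = 240,
                                      seed = NULL,
                                      proportions = c("uniform", "dirichlet")) {
  proportions <- match.arg(proportions)
  pool <- as.character(pool)
  np <- length(pool)
  rr <- as.integer(richness_range)
  if (length(rr) != 2L || anyNA(rr) || rr[1L] < 1L || rr[1L] > rr[2L])
    abort_cladiv("`richness_range` must be an integer pair c(min, max) with 1 <= min <= max")
  if (rr[2L] > np)
    abort_cladiv(sprintf("richness range max %d exceeds pool size %d", rr[2L], np))
  if (n_sites < 1L) abort_cladiv("`n_sites` must be >= 1")
  with_seed(seed, {
    S <- if (rr[1L] == rr[2L]) rep.int(rr[1L], n_sites)
         else sample_from(seq.int(rr[1L], rr[2L]), n_sites, replace = TRUE)
    m <- matrix(0, n_sites, np,
                dimnames = list(sprintf("site%04d", seq_len(n_sites)), pool))
    for (i in seq_len(n_sites)) {
      idx <- sample.int(np, S[i])
      w <- if (proportions == "dirichlet") stats::rgamma(S[i], 1) else stats::runif(S[i])
      if (sum(w) <= 0) w <- rep.int(1, S[i]) # guard against all-zero draws
      m[i, idx] <- w / sum(w)
    }
    m
  })
}

#' Rescale the deep part of an ultrametric tree
#'
#' Stretches (or compresses) every branch segment lying above `cut_depth`
#' over the tips by a common factor so the total tree height becomes
#' `target_height`, leaving everything below the cut untouched. Node
#' heights map as `h -> cut_depth + k (h - cut_depth)` for `h > cut_depth`.
#' This is how the synthetic phylogenetic scales are built: scales share
#' the same clade-level (below-cut) structure and differ only in how deep
#' the divergences among clades reach, like nested clades of one
#' phylogeny do. Ultrametry and any depth-cut clade partition at
#' `cut_depth` are preserved.
#'
#' @param tree an ultrametric `phylo` object.
#' @param cut_depth boundary height above the tips; must lie strictly
#'   between 0 and the tree height.
#' @param target_height desired total height; must exceed `cut_depth`.
#' @return the rescaled `phylo` object.
#' @export
stretch_tree_above <- function(tree, cut_depth, target_height) {
  validate_phylo(tree)
  if (!ape::is.ultrametric(tree, tol = 1e-6))
    abort_cladiv("`tree` must be ultrametric")
  depth_root <- ape::node.depth.edgelength(tree)
  height <- max(depth_root[seq_along(tree$tip.label)])
  if (cut_depth <= 0 || cut_depth >= height)
    abort_cladiv(sprintf("`cut_depth` must lie strictly between 0 and the tree height (%g)",
                         height))
  if (target_height <= cut_depth)
    abort_cladiv("`target_height` must exceed `cut_depth`")
  above <- height - depth_root
  k <- (target_height - cut_depth) / (height - cut_depth)
  new_above <- ifelse(above > cut_depth, cut_depth + k * (above - cut_depth),
                      above)
  tree$edge.length <- new_above[tree$edge[, 1L]] - new_above[tree$edge[, 2L]]
  tree
}

#' Clade map from cutting an ultrametric tree at a fixed depth
#'
#' Clades are the tip sets of the lineages crossing the horizontal line
#' `cut_depth` above the tips - a synthetic analogue of assigning species to
#' a fixed taxonomic rank (e.g. family) of a given age. The result is a
#' partition of all tips into monophyletic groups.
#'
#' @param tree an ultrametric `phylo` object.
#' @param cut_depth height above the tips at which to cut, in branch-length
#'   units; must lie strictly between 0 and the tree height.
#' @return named character vector (species -> clade), clades labelled
#'   `c001, c002, ...` in tip order.
#' @export
#' @examples
#' tr <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
#' clade_map_from_tree(tr, 1.5)
clade_map_from_tree <- function(tree, cut_depth) {
  validate_phylo(tree)
  if (!ape::is.ultrametric(tree, tol = 1e-6))
    abort_cladiv("`tree` must be ultrametric to cut at a fixed depth")
  depth_root <- ape::node.depth.edgelength(tree)
  height <- max(depth_root[seq_along(tree$tip.label)])
  if (!is.numeric(cut_depth) || length(cut_depth) != 1L || is.na(cut_depth) ||
      cut_depth <= 0 || cut_depth >= height)
    abort_cladiv(sprintf("`cut_depth` must lie strictly between 0 and the tree height (%g)",
                         height))
  above <- height - depth_root # height of each node above the tips
  # crossing edges: child below the cut, parent at or above it
  cross <- above[tree$edge[, 2L]] < cut_depth & above[tree$edge[, 1L]] >= cut_depth
  desc <- edge_tip_incidence(tree)
  map <- character(length(tree$tip.label))
  k <- 0L
  for (e in which(cross)) {
    k <- k + 1L
    map[desc[e, ]] <- sprintf("c%03d", k)
  }
  if (any(map == ""))
    abort_cladiv("internal error: depth cut did not partition the tips")
  stats::setNames(map, tree$tip.label)
}

#' Build a simulation configuration
#'
#' The defaults follow the reference factorial design: species pool sizes of
#' 2000, 500 and 250; species-richness ranges 10-160, 10-80, 10-40, 10-20,
#' 5-10 and 2-5 species per community; 50 community matrices of 240 sites
#' per design cell. Phylogenetic scales are one tree each: either a Newick
#' file (with an optional clade-map TSV) or a synthetic Yule specification
#' `list(n_tips =, height =)`; synthetic clade maps come from cutting each
#' tree at `clade_cut_depth`.
#'
#' @param scales named list, one entry per phylogenetic scale. Each entry is
#'   either `list(tree = "path.nwk", clade_map = "map.tsv")` (clade map
#'   optional when the tree is ultrametric) or `list(n_tips =, height =)`.
#' @param pool_sizes integer vector of species pool sizes.
#' @param richness_ranges list of integer pairs `c(min, max)`.
#' @param n_matrices_per_cell replicate community matrices per design cell.
#' @param n_sites sites per community matrix.
#' @param clade_cut_depth depth above the tips for synthetic clade maps, in
#'   branch-length units of the scale trees.
#' @param master_seed integer master seed; every cell derives its own seed
#'   from it by stable label hashing.
#' @param proportions see [generate_community_matrix()].
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(scales = sim_scales_synthetic(),
                       pool_sizes = c(2000L, 500L, 250L),
                       richness_ranges = list(c(10L, 160L), c(10L, 80L),
                                              c(10L, 40L), c(10L, 20L),
                                              c(5L, 10L), c(2L, 5L)),
                       n_matrices_per_cell = 50L,
                       n_sites = 240L,
                       clade_cut_depth = 80,
                       master_seed = 1L,
                       proportions = c("uniform", "dirichlet")) {
  proportions <- match.arg(proportions)
  if (is.null(names(scales)) || any(names(scales) == ""))
    abort_cladiv("`scales` must be a named list")
  pool_sizes <- as.integer(pool_sizes)
  if (any(pool_sizes < 2L)) abort_cladiv("pool sizes must be >= 2")
  for (rr in richness_ranges) {
    rr <- as.integer(rr)
    if (length(rr) != 2L || rr[1L] < 1L || rr[1L] > rr[2L])
      abort_cladiv("each richness range must be c(min, max) with 1 <= min <= max")
    if (rr[2L] > min(pool_sizes))
      abort_cladiv(sprintf("richness range max %d exceeds the smallest pool size %d",
                           rr[2L], min(pool_sizes)))
  }
  if (n_matrices_per_cell < 1L || n_sites < 1L)
    abort_cladiv("`n_matrices_per_cell` and `n_sites` must be >= 1")
  structure(list(scales = scales, pool_sizes = pool_sizes,
                 richness_ranges = richness_ranges,
                 n_matrices_per_cell = as.integer(n_matrices_per_cell),
                 n_sites = as.integer(n_sites),
                 clade_cut_depth = clade_cut_depth,
                 master_seed = as.integer(master_seed),
                 proportions = proportions),
            class = "sim_config")
}

#' Synthetic phylogenetic scales
#'
#' Yule-tree stand-ins for nested phylogenetic scales: one tree per scale,
#' rescaled to heights proportional to the crown ages of progressively more
#' inclusive plant clades (superasterids ~120, angiosperms ~180, all
#' vascular plants ~400 time units). A single absolute clade-cut depth then
#' plays the role of a fixed taxonomic rank across scales.
#'
#' @param n_tips tips per scale tree.
#' @param heights named numeric vector of tree heights, one per scale,
#'   broadest first.
#' @return named list of synthetic scale specifications for [sim_config()].
#' @export
sim_scales_synthetic <- function(n_tips = 3000L,
                                 heights = c(vascular = 400, angiosperm = 180,
                                             superasterid = 120)) {
  stats::setNames(lapply(heights, function(h) list(n_tips = as.integer(n_tips),
                                                   height = h)),
                  names(heights))
}

#' Desk-scale simulation configuration
#'
#' A reduced version of the reference factorial that runs in minutes on one
#' CPU: three synthetic scales (3000-tip Yule trees of heights 400/180/120),
#' pool sizes 250/120/60, four species-richness ranges (2-5, 5-10, 10-20,
#' 10-40), 10 replicate matrices of 240 sites per cell (360 matrices in
#' total). Plot count, the smallest pool size and the species-poor richness
#' ranges match the reference design; only the replicate count, the widest
#' ranges and the larger pools are reduced.
#'
#' @param master_seed integer master seed.
#' @param n_matrices_per_cell replicates per cell.
#' @param n_sites sites per matrix.
#' @return a `sim_config`.
#' @export
sim_config_demo <- function(master_seed = 1L, n_matrices_per_cell = 10L,
                            n_sites = 240L) {
  sim_config(scales = sim_scales_synthetic(n_tips = 3000L),
             pool_sizes = c(250L, 120L, 60L),
             richness_ranges = list(c(2L, 5L), c(5L, 10L),
                                    c(10L, 20L), c(10L, 40L)),
             n_matrices_per_cell = n_matrices_per_cell,
             n_sites = n_sites,
             clade_cut_depth = 80,
             master_seed = master_seed)
}

#' Read a simulation configuration from YAML
#'
#' Keys mirror the arguments of [sim_config()]; `richness_ranges` is a list
#' of two-element sequences; scale entries hold either `tree`/`clade_map`
#' paths (resolved relative to the YAML file) or `n_tips`/`height`.
#'
#' @param path YAML file path.
#' @return a `sim_config`.
#' @export
read_sim_config <- function(path) {
  if (!file.exists(path)) abort_cladiv(sprintf("file not found: %s", path))
  y <- yaml::read_yaml(path)
  need <- c("scales", "pool_sizes", "richness_ranges")
  miss <- setdiff(need, names(y))
  if (length(miss))
    abort_cladiv(sprintf("%s: missing config keys: %s", path,
                         paste(miss, collapse = ", ")))
  base_dir <- dirname(normalizePath(path))
  scales <- lapply(y$scales, function(sc) {
    if (!is.null(sc$tree)) {
      sc$tree <- file.path(base_dir, sc$tree)
      if (!is.null(sc$clade_map)) sc$clade_map <- file.path(base_dir, sc$clade_map)
    }
    sc
  })
  sim_config(scales = scales,
             pool_sizes = unlist(y$pool_sizes),
             richness_ranges = lapply(y$richness_ranges, unlist),
             n_matrices_per_cell = y$n_matrices_per_cell %||% 50L,
             n_sites = y$n_sites %||% 240L,
             clade_cut_depth = y$clade_cut_depth %||% 80,
             master_seed = y$master_seed %||% 1L,
             proportions = y$proportions %||% "uniform")
}

# Load or simulate the tree and clade map of one scale.
resolve_scale <- function(name, spec, config) {
  if (!is.null(spec$tree)) {
    tree <- if (inherits(spec$tree, "phylo")) spec$tree else read_newick(spec$tree)
    map <- if (!is.null(spec$clade_map)) {
      if (is.character(spec$clade_map) && length(spec$clade_map) == 1L &&
          is.null(names(spec$clade_map)))
        read_clade_map(spec$clade_map) else spec$clade_map
    } else clade_map_from_tree(tree, config$clade_cut_depth)
  } else {
    if (is.null(spec$n_tips) || is.null(spec$height))
      abort_cladiv(sprintf("scale '%s' needs either a tree or n_tips/height", name))
    # One Yule tree per scale, rescaled to the scale's height; the single
    # absolute cut depth then plays the role of a fixed taxonomic rank age,
    # so smaller (shallower) scales naturally carry fewer, species-richer
    # clades - the same granularity ladder a fixed rank produces on nested
    # clades of a real phylogeny.
    if (spec$height <= config$clade_cut_depth)
      abort_cladiv(sprintf("scale '%s': height must exceed clade_cut_depth", name))
    tree <- simulate_yule_tree(as.integer(spec$n_tips),
                               seed = derive_seed(config$master_seed,
                                                  paste0("scale-tree|", name)),
                               height = spec$height)
    map <- clade_map_from_tree(tree, config$clade_cut_depth)
  }
  if (max(vapply(config$pool_sizes, identity, integer(1))) > length(tree$tip.label))
    abort_cladiv(sprintf("scale '%s': largest pool size exceeds the tree's %d tips",
                         name, length(tree$tip.label)))
  unmapped <- setdiff(tree$tip.label, names(map))
  if (length(unmapped))
    abort_cladiv(sprintf("scale '%s': tips without clade assignment: %s",
                         name, paste(utils::head(unmapped, 5L), collapse = ", ")))
  list(tree = tree, clade_map = map)
}

# Enumerate the design cells of a configuration with their derived seeds.
design_cells <- function(config) {
  rr_lab <- vapply(config$richness_ranges,
                   function(r) paste0(r[1L], "-", r[2L]), character(1))
  cells <- expand.grid(replicate = seq_len(config$n_matrices_per_cell),
                       richness_range = rr_lab,
                       pool_size = config$pool_sizes,
                       scale = names(config$scales),
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  cells <- cells[, c("scale", "pool_size", "richness_range", "replicate")]
  lab <- with(cells, paste(scale, pool_size, richness_range,
                           sprintf("rep%03d", replicate), sep = "|"))
  cells$seed <- vapply(lab, function(l) derive_seed(config$master_seed, l),
                       integer(1), USE.NAMES = FALSE)
  cells
}

#' Run the factorial simulation workflow
#'
#' For every design cell (phylogenetic scale x pool size x richness range x
#' replicate): draw a fresh species pool from the scale's tree, generate a
#' fresh random community matrix, compute the phylogeny-based metrics and
#' the clade indices per site, and fit the three surrogate models -
#' `sqrt(PD) ~ clade richness index`, `MPD ~ clade divergence index`,
#' `log(VPD) ~ clade regularity index` - recording each fit's R-squared.
#' Cells with degenerate fits are recorded as `NA` with a reason. The whole
#' run is reproducible from `config$master_seed`; each cell carries its own
#' derived seed and can be regenerated in isolation.
#'
#' @param config a `sim_config`.
#' @param compute `"fits"` (default) computes metrics, indices and R-squared
#'   values; `"matrices"` only generates pools and community matrices,
#'   recording per-cell summaries (for design checks at scales where keeping
#'   metrics would be wasteful); `"plan"` only enumerates cells and seeds.
#' @param out_dir optional directory; when given, per-matrix site tables and
#'   the master `results_r2.tsv` are written there, plus a run manifest.
#' @param keep_tables keep every per-matrix site table in the returned
#'   object (memory-hungry; only sensible for small designs).
#' @param progress print one line per design cell.
#' @return an object of class `cladiv_sim`: list with `results` (one row per
#'   cell: labels, seed, and - under `compute = "fits"` - `r2_richness`,
#'   `r2_divergence`, `r2_regularity`, `note`), `config`, and optionally
#'   `tables`.
#' @export
run_factorial <- function(config, compute = c("fits", "matrices", "plan"),
                          out_dir = NULL, keep_tables = FALSE,
                          progress = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  compute <- match.arg(compute)
  cells <- design_cells(config)
  if (compute == "plan")
    return(structure(list(results = cells, config = config), class = "cladiv_sim"))

  scales <- lapply(names(config$scales), function(nm)
    resolve_scale(nm, config$scales[[nm]], config))
  names(scales) <- names(config$scales)

  rr_of <- function(lab) as.integer(strsplit(lab, "-", fixed = TRUE)[[1L]])
  n <- nrow(cells)
  if (compute == "fits") {
    cells$r2_richness <- NA_real_
    cells$r2_divergence <- NA_real_
    cells$r2_regularity <- NA_real_
    cells$note <- NA_character_
  } else {
    cells$n_sites <- NA_integer_
    cells$S_min <- NA_integer_
    cells$S_max <- NA_integer_
    cells$max_rowsum_err <- NA_real_
  }
  tables <- if (keep_tables) vector("list", n) else NULL
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  for (i in seq_len(n)) {
    sc <- scales[[cells$scale[i]]]
    pool <- sample_species_pool(sc$tree, cells$pool_size[i],
                                seed = derive_seed(cells$seed[i], "pool"),
                                prune = compute == "fits")
    comm <- generate_community_matrix(pool$species, rr_of(cells$richness_range[i]),
                                      n_sites = config$n_sites,
                                      seed = derive_seed(cells$seed[i], "matrix"),
                                      proportions = config$proportions)
    if (compute == "matrices") {
      S <- rowSums(comm > 0)
      cells$n_sites[i] <- nrow(comm)
      cells$S_min[i] <- min(S)
      cells$S_max[i] <- max(S)
      cells$max_rowsum_err[i] <- max(abs(rowSums(comm) - 1))
    } else {
      div <- diversity_table(pool$tree, comm)
      idx <- clade_index_table(comm, sc$clade_map,
                               pool = summarize_pool(sc$clade_map, pool$species))
      fits <- fit_surrogates(div, idx)
      cells$r2_richness[i] <- fits$richness
      cells$r2_divergence[i] <- fits$divergence
      cells$r2_regularity[i] <- fits$regularity
      cells$note[i] <- fits$note
      if (keep_tables || !is.null(out_dir)) {
        tab <- merge(div, idx[, setdiff(colnames(idx), "S")], by = "site",
                     sort = FALSE)
        if (keep_tables) tables[[i]] <- tab
        if (!is.null(out_dir))
          write_tsv_na(tab, file.path(out_dir, sprintf(
            "matrix_%s_%d_%s_rep%03d.tsv", cells$scale[i], cells$pool_size[i],
            cells$richness_range[i], cells$replicate[i])))
      }
    }
    if (progress)
      message(sprintf("[%d/%d] %s pool=%d range=%s rep=%d", i, n,
                      cells$scale[i], cells$pool_size[i],
                      cells$richness_range[i], cells$replicate[i]))
  }
  out <- structure(list(results = cells, config = config, tables = tables),
                   class = "cladiv_sim")
  if (!is.null(out_dir)) {
    write_tsv_na(cells, file.path(out_dir, "results_r2.tsv"))
    write_manifest(out_dir, command = "run_factorial",
                   config = unclass(config)[setdiff(names(config), "scales")],
                   seeds = list(master_seed = config$master_seed))
  }
  out
}

#' @export
print.cladiv_sim <- function(x, ...) {
  cat(sprintf("cladiv simulation: %d design cells (%d scales x %d pool sizes x %d richness ranges x %d replicates)\n",
              nrow(x$results), length(x$config$scales),
              length(x$config$pool_sizes), length(x$config$richness_ranges),
              x$config$n_matrices_per_cell))
  if ("r2_richness" %in% colnames(x$results)) {
    ok <- stats::complete.cases(x$results[, c("r2_richness", "r2_divergence",
                                              "r2_regularity")])
    cat(sprintf("fits: %d complete cells; median R2 richness %.3f, divergence %.3f, regularity %.3f\n",
                sum(ok),
                stats::median(x$results$r2_richness, na.rm = TRUE),
                stats::median(x$results$r2_divergence, na.rm = TRUE),
                stats::median(x$results$r2_regularity, na.rm = TRUE)))
  }
  invisible(x)
}

# The three surrogate fits of one community matrix; degenerate fits become
# NA with the reason recorded.
fit_surrogates <- function(div, idx) {
  stopifnot(identical(div$site, idx$site))
  one <- function(x, y, transform) {
    tryCatch(fit_linear(x, y, transform = transform)$r_squared,
             cladiv_degenerate_fit = function(e) NA_real_,
             cladiv_error = function(e) NA_real_)
  }
  r <- list(
    richness = one(idx$clade_richness_index, div$PD, "sqrt"),
    divergence = one(idx$clade_divergence_index, div$MPD, "none"),
    regularity = one(idx$clade_regularity_index, div$VPD, "log"))
  r$note <- if (anyNA(unlist(r[1:3]))) {
    paste0("degenerate fit: ",
           paste(names(r)[vapply(r[1:3], is.na, logical(1))], collapse = ","))
  } else NA_character_
  r
}
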