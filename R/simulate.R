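## Gene-tree simulation with known species partitions.
##
## A pure-birth (Yule) species tree supplies population divergence times;
## a backward-time multispecies coalescent then generates an ultrametric
## gene tree whose tips carry known species memberships, giving a ground
## truth against which delimitation accuracy can be scored.
##
## Units.  The Yule tree is generated on its own divergence-time scale:
## with j extant species the waiting time to the next birth is
## exponential(j * birth_rate), so larger birth rates compress the species
## divergences.  The coalescent runs on the standard coalescent scale (one
## unit = 2N generations, pairwise coalescence rate 1).  The two scales are
## linked by `pop_size`, the population coalescent timescale expressed in
## divergence-time units: a species isolated for t divergence units spans
## t / pop_size coalescent units.  The default pop_size of 0.01 makes
## species isolation long relative to within-population coalescence at
## small birth rates (species recoverable) and short at large ones (heavy
## incomplete lineage sorting) — the axis the birth-rate grid sweeps.

#' Simulation configuration
#'
#' Bundles all simulator parameters.  Defaults give the evenly sampled
#' design: 30 species with 10 sampled individuals each.
#'
#' @param n_species Number of species (tips of the species tree).
#' @param birth_rate Scaled Yule birth rate b'; a useful benchmark grid is
#'   \code{c(5, 10, 20, 40, 80, 160)}.  Small values generate large
#'   evolutionary distances between species.
#' @param sampling Either a single integer (individuals sampled per species,
#'   even design) or an integer vector of length \code{n_species} (uneven
#'   design), e.g. \code{sampling_uneven()} for the 2x100 + 4x50 + 8x10 +
#'   16x2 scheme.
#' @param pop_size Population coalescent timescale in divergence-time units
#'   (see the units note in the source header); default 0.01.
#' @param subs_per_coal_unit Expected substitutions per site per coalescent
#'   unit; scales the gene tree from time to substitutions.  Default 0.01,
#'   which puts branch lengths in the range typical of single-locus
#'   phylogenies.
#' @param noise_sd Standard deviation (log scale) of multiplicative
#'   log-normal noise applied to every gene-tree branch length, a crude
#'   stand-in for tree-inference error.  Default 0 (off); the noise factors
#'   have mean 1.
#' @param seed Integer root seed; per-replicate streams are derived from it.
#' @return A list of class \code{"ptp_sim_config"}.
#' @export
sim_config <- function(n_species = 30L, birth_rate = 10,
                       sampling = 10L, pop_size = 0.01,
                       subs_per_coal_unit = 0.01, noise_sd = 0,
                       seed = 1L) {
  n_species <- as.integer(n_species)
  stopifnot(n_species >= 2L, birth_rate > 0, pop_size > 0,
            subs_per_coal_unit > 0, noise_sd >= 0)
  if (length(sampling) == 1L) sampling <- rep(as.integer(sampling), n_species)
  sampling <- as.integer(sampling)
  if (length(sampling) != n_species)
    stop("`sampling` must have length 1 or n_species")
  if (any(sampling < 1L))
    stop("all per-species sample sizes must be >= 1")
  structure(
    list(n_species = n_species, birth_rate = birth_rate,
         sampling = sampling, pop_size = pop_size,
         subs_per_coal_unit = subs_per_coal_unit, noise_sd = noise_sd,
         seed = as.integer(seed)),
    class = "ptp_sim_config"
  )
}

#' The uneven sampling scheme
#'
#' Thirty species sampled as 2 species with 100 individuals, 4 with 50,
#' 8 with 10 and 16 with 2.
#'
#' @return Integer vector of length 30.
#' @export
sampling_uneven <- function() {
  c(rep(100L, 2), rep(50L, 4), rep(10L, 8), rep(2L, 16))
}

#' Simulate a pure-birth (Yule) species tree
#'
#' Starting from two lineages at the root, the waiting time to the next
#' birth with j extant lineages is exponential with rate
#' \code{j * birth_rate}; a uniformly chosen lineage then splits.  After the
#' \code{n_species}-th lineage appears, one final waiting interval with all
#' lineages extant closes the tree, so for two species the expected root
#' age is \code{1 / (2 * birth_rate)}.  The tree is ultrametric in
#' divergence-time units.
#'
#' @param n_species Number of tips (>= 2).
#' @param birth_rate Birth rate per divergence-time unit (> 0).
#' @param seed Optional integer seed.
#' @return A \code{"phylo"} object with tip labels \code{sp1..spN}.
#' @export
yule_species_tree <- function(n_species, birth_rate, seed = NULL) {
  n_species <- as.integer(n_species)
  stopifnot(n_species >= 2L, birth_rate > 0)
  if (!is.null(seed)) set.seed(as.integer(seed) %% .Machine$integer.max)

  n_max <- 2L * n_species - 1L
  parent <- integer(n_max)      # working ids, 1 = root
  t_start <- numeric(n_max)     # time the node's incoming edge begins
  t_end <- numeric(n_max)       # split time (internal) or present (tip)
  parent[1L] <- 0L
  parent[2:3] <- 1L
  t_start[1:3] <- 0
  next_id <- 4L
  active <- c(2L, 3L)
  t_now <- 0
  while (length(active) < n_species) {
    j <- length(active)
    t_now <- t_now + stats::rexp(1, rate = j * birth_rate)
    i <- sample.int(j, 1L)
    node <- active[i]
    t_end[node] <- t_now
    kids <- c(next_id, next_id + 1L)
    next_id <- next_id + 2L
    parent[kids] <- node
    t_start[kids] <- t_now
    active <- c(active[-i], kids)
  }
  t_now <- t_now + stats::rexp(1, rate = n_species * birth_rate)
  t_end[active] <- t_now
  t_end[1L] <- 0

  .build_phylo(parent, t_start, t_end, tips = sort(active),
               tip_labels = paste0("sp", seq_len(n_species)))
}

# assemble a phylo from working arrays: `tips` are the working ids that
# become tips 1..N (in the given order, matching tip_labels)
.build_phylo <- function(parent, t_start, t_end, tips, tip_labels) {
  n_all <- length(parent)
  internals <- setdiff(seq_len(n_all), tips)
  ntip <- length(tips)
  # root (parent 0) must get ape id ntip+1
  root <- internals[parent[internals] == 0L]
  internals <- c(root, setdiff(internals, root))
  newid <- integer(n_all)
  newid[tips] <- seq_len(ntip)
  newid[internals] <- ntip + seq_along(internals)
  nonroot <- seq_len(n_all)[parent > 0L]
  edge <- cbind(newid[parent[nonroot]], newid[nonroot])
  tree <- structure(
    list(edge = edge,
         edge.length = t_end[nonroot] - t_start[nonroot],
         tip.label = tip_labels,
         Nnode = length(internals)),
    class = "phylo"
  )
  ape::reorder.phylo(tree, "cladewise")
}

#' Simulate a multispecies-coalescent gene tree
#'
#' Backward-time coalescent within the populations of an ultrametric
#' species tree: species are treated as populations completely isolated
#' after their divergence.  Within a population with j active gene
#' lineages, coalescences occur at rate \code{j*(j-1)/2} per coalescent
#' unit; at each species divergence (going rootward) the lineage sets of
#' the joining populations merge, and the process ends when a single
#' lineage remains above the species root.  The returned gene tree is
#' binary and ultrametric, with branch lengths in coalescent units.
#'
#' @param species_tree Ultrametric \code{"phylo"} in divergence-time units,
#'   e.g. from [yule_species_tree()].
#' @param sampling Individuals sampled per species: a single integer or a
#'   vector of length \code{Ntip(species_tree)} (ordered as the species
#'   tree's tip labels).
#' @param pop_size Coalescent timescale of every population, in
#'   divergence-time units (default 0.01); divergence times are divided by
#'   it to obtain coalescent units.
#' @param seed Optional integer seed.
#' @return A list of class \code{"gene_tree_sample"}: \code{gene_tree}
#'   (\code{"phylo"}, tip labels \code{<species>_i<k>}),
#'   \code{true_partition} (named vector mapping each gene-tree tip to its
#'   species), \code{species_tree}, \code{pop_size}, and \code{units}
#'   (\code{"coalescent"} or \code{"substitutions"}).
#' @export
msc_gene_tree <- function(species_tree, sampling, pop_size = 0.01,
                          seed = NULL) {
  single_pop <- is.null(species_tree)
  if (!single_pop) validate_tree(species_tree)
  stopifnot(pop_size > 0)
  if (!is.null(seed)) set.seed(as.integer(seed) %% .Machine$integer.max)
  ns <- if (single_pop) 1L else ape::Ntip(species_tree)
  if (length(sampling) == 1L) sampling <- rep(as.integer(sampling), ns)
  sampling <- as.integer(sampling)
  stopifnot(length(sampling) == ns, all(sampling >= 1L), sum(sampling) >= 2L)
  sp_labels <- if (single_pop) "sp1" else species_tree$tip.label
  n_internal <- if (single_pop) 0L else species_tree$Nnode

  # node ages (time before present) in coalescent units
  if (single_pop) {
    age <- 0
    sp_parent <- 0L
    sp_root <- 1L
    sp_kids <- list(integer(0))
  } else {
    depth <- ape::node.depth.edgelength(species_tree)
    age <- (max(depth[seq_len(ns)]) - depth) / pop_size
    age[seq_len(ns)] <- 0
    sp_parent <- .parent_vec(species_tree)
    sp_root <- ns + 1L
    sp_kids <- .children_list(species_tree)
  }

  n_tips_total <- sum(sampling)
  n_max <- 2L * n_tips_total - 1L
  g_age <- numeric(n_max)       # gene-node ages (coalescent units)
  g_parent <- integer(n_max)
  tip_labels <- character(n_tips_total)
  tip_species <- character(n_tips_total)
  next_gid <- n_tips_total + 1L

  # gene lineages entering the population above each species-tree node
  pool <- vector("list", ns + n_internal)
  gid <- 0L
  for (s in seq_len(ns)) {
    ids <- gid + seq_len(sampling[s])
    gid <- gid + sampling[s]
    tip_labels[ids] <- paste0(sp_labels[s], "_i", seq_len(sampling[s]))
    tip_species[ids] <- sp_labels[s]
    pool[[s]] <- ids
  }

  # run each population from its node's age up to its parent's age;
  # species-tree nodes processed in increasing age so children populations
  # finish before their parent collects the surviving lineages
  ord <- order(age[seq_len(ns + n_internal)])
  for (v in ord) {
    lineages <- if (v > ns) unlist(pool[sp_kids[[v]]]) else pool[[v]]
    t_now <- age[v]
    t_stop <- if (v == sp_root) Inf else age[sp_parent[v]]
    while (length(lineages) >= 2L) {
      j <- length(lineages)
      wait <- stats::rexp(1, rate = j * (j - 1) / 2)
      if (t_now + wait > t_stop) break
      t_now <- t_now + wait
      pair <- sample.int(j, 2L)
      anc <- next_gid
      next_gid <- next_gid + 1L
      g_age[anc] <- t_now
      g_parent[lineages[pair]] <- anc
      lineages <- c(lineages[-pair], anc)
    }
    pool[[v]] <- lineages
  }

  # forward-time coordinates (edge length = parent age - own age)
  used <- seq_len(next_gid - 1L)
  t_start <- numeric(length(used))
  has_par <- g_parent[used] > 0L
  t_start[has_par] <- -g_age[g_parent[used][has_par]]
  structure(
    list(
      gene_tree = .build_phylo(
        parent = g_parent[used],
        t_start = t_start,
        t_end = -g_age[used],
        tips = seq_len(n_tips_total),
        tip_labels = tip_labels
      ),
      true_partition = stats::setNames(tip_species, tip_labels),
      species_tree = species_tree,
      pop_size = pop_size,
      units = "coalescent"
    ),
    class = "gene_tree_sample"
  )
}

#' Scale a gene tree from time to substitutions
#'
#' Multiplies every branch length of the gene tree by
#' \code{subs_per_coal_unit} (expected substitutions per site per
#' coalescent unit).  The true partition is unchanged, and so is the
#' maximum-likelihood delimitation: the two-class likelihood is covariant
#' under a common rescaling of all branch lengths.
#'
#' @param sample A \code{"gene_tree_sample"}.
#' @param subs_per_coal_unit Positive scale factor.
#' @return The rescaled \code{"gene_tree_sample"} with
#'   \code{units = "substitutions"}.
#' @export
scale_to_substitutions <- function(sample, subs_per_coal_unit = 0.01) {
  stopifnot(inherits(sample, "gene_tree_sample"), subs_per_coal_unit > 0)
  sample$gene_tree$edge.length <- sample$gene_tree$edge.length *
    subs_per_coal_unit
  sample$units <- "substitutions"
  sample$subs_per_coal_unit <- subs_per_coal_unit
  sample
}

#' Simulate one dataset under a configuration
#'
#' Convenience driver: Yule species tree, multispecies-coalescent gene
#' tree, substitution scaling.  Component seeds are derived from the
#' configuration's root seed (offset by \code{replicate}), so replicate i
#' of a given configuration is always the same dataset.
#'
#' @param config A \code{"ptp_sim_config"} from [sim_config()].
#' @param replicate Replicate index (default 1).
#' @return A \code{"gene_tree_sample"} in substitution units, with a
#'   \code{meta} element recording the configuration and derived seeds.
#' @export
simulate_dataset <- function(config, replicate = 1L) {
  stopifnot(inherits(config, "ptp_sim_config"))
  base <- (config$seed + 7919L * (as.integer(replicate) - 1L)) %%
    .Machine$integer.max
  s_yule <- (base * 2L + 1L) %% .Machine$integer.max
  s_coal <- (base * 2L + 2L) %% .Machine$integer.max
  sp <- yule_species_tree(config$n_species, config$birth_rate, seed = s_yule)
  gs <- msc_gene_tree(sp, config$sampling, pop_size = config$pop_size,
                      seed = s_coal)
  gs <- scale_to_substitutions(gs, config$subs_per_coal_unit)
  if (config$noise_sd > 0) {
    ne <- length(gs$gene_tree$edge.length)
    gs$gene_tree$edge.length <- gs$gene_tree$edge.length *
      stats::rlnorm(ne, meanlog = -config$noise_sd^2 / 2,
                    sdlog = config$noise_sd)
  }
  gs$meta <- list(config = unclass(config), replicate = as.integer(replicate),
                  seed_yule = s_yule, seed_coal = s_coal)
  gs
}

#' @export
print.gene_tree_sample <- function(x, ...) {
  cat("Multispecies-coalescent gene tree sample\n")
  cat("  tips: ", ape::Ntip(x$gene_tree),
      " across ", length(unique(x$true_partition)), " species\n", sep = "")
  cat("  branch-length units: ", x$units, "\n", sep = "")
  invisible(x)
}
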