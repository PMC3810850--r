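## Maximum-likelihood delimitation search.
##
## Degenerate delimitations — the root alone (one species) and all tips
## (every tip its own species) — are part of the enumeration but carry no
## two-class likelihood (one class is empty).  They are represented by the
## single-rate null model instead: a non-significant likelihood-ratio test
## already means "one species or all singletons".

#' Exhaustive maximum-likelihood delimitation
#'
#' Scores every non-degenerate delimitation of the tree with the two-class
#' likelihood and returns the global optimum.  Ties are broken toward fewer
#' species, then toward the lexicographically smallest sorted species-root
#' id vector, so the result is deterministic.
#'
#' @param tree A \code{"phylo"} object.
#' @param fixed_lambda1 Optional fixed speciation rate (see
#'   [log_likelihood()]).
#' @param epsilon Branch-length floor.
#' @param cap Refuse trees with more than this many delimitations.
#' @return A \code{"ptp_result"} object; see [delimit()] for its contents.
#' @export
exhaustive_ml <- function(tree, fixed_lambda1 = NULL, epsilon = 1e-10,
                          cap = 1e5) {
  validate_tree(tree)
  all_d <- enumerate_delimitations(tree, cap = cap)
  ntip <- ape::Ntip(tree)
  root <- ntip + 1L
  best <- NULL
  n_eval <- 0L
  for (d in all_d) {
    if (.is_degenerate(d, ntip, root)) next
    fit <- log_likelihood(tree, d, fixed_lambda1 = fixed_lambda1,
                          epsilon = epsilon)
    n_eval <- n_eval + 1L
    if (.better_fit(fit, best)) best <- fit
  }
  if (is.null(best))
    return(.null_only_result(tree, "exhaustive", n_eval, epsilon))
  .make_result(tree, best, "exhaustive", n_eval, epsilon)
}

#' Greedy delimitation search for large trees
#'
#' Local search over the delimitation lattice when exhaustive enumeration
#' is infeasible, in two phases.  Phase one is a root-to-tip sweep: starting
#' from one species root on each child of the tree root, the sweep
#' repeatedly applies the SPLIT move (replace an internal species root by
#' its children) that yields the highest likelihood — improving or not —
#' until no split remains, and remembers the best delimitation visited.
#' Sweeping through non-improving states matters because the likelihood
#' along the split path is not monotone even when a much better optimum
#' lies below.  Phase two polishes the best visited state by strict
#' hill-climbing with both SPLIT and MERGE moves (MERGE replaces a complete
#' sibling set of species roots by their parent), applying the single best
#' strictly improving move per iteration until none improves.  Candidate
#' likelihoods are evaluated incrementally (a SPLIT/MERGE only moves the
#' child edges of one node between classes), so each evaluation is O(1).
#'
#' The reported delimitation is always at least as good as the initial
#' state, and the best-so-far likelihood is non-decreasing over the search.
#' With \code{restarts > 1}, additional phase-two climbs start from random
#' antichain covers; the \code{seed} only drives those extra starting
#' points, so the default single-restart search is fully deterministic.
#'
#' @inheritParams exhaustive_ml
#' @param restarts Number of hill-climbs (default 1).
#' @param seed Integer seed for restart starting points.
#' @return A \code{"ptp_result"} object.
#' @export
greedy_ml <- function(tree, fixed_lambda1 = NULL, epsilon = 1e-10,
                      restarts = 1L, seed = 1L) {
  validate_tree(tree)
  ntip <- ape::Ntip(tree)
  root <- ntip + 1L
  kids <- .children_list(tree)
  parent <- .parent_vec(tree)
  elen <- pmax(.edge_len_by_child(tree), epsilon)  # NA at the root, unused
  n_edges <- nrow(tree$edge)
  n_eval <- 0L

  # two-class log-likelihood from sufficient statistics (k among edges
  # summing to Sa; n - k within edges summing to Sw)
  ll_stats <- function(k, Sa, Sw) {
    n_eval <<- n_eval + 1L
    nk <- n_edges - k
    if (nk < 1L || (k < 1L && is.null(fixed_lambda1))) return(NA_real_)
    l1 <- if (is.null(fixed_lambda1)) k / Sa else fixed_lambda1
    (if (k > 0L) k * log(l1) - l1 * Sa else 0) + nk * log(nk / Sw) - nk
  }
  exact_stats <- function(roots) {
    cls <- classify_edges(tree, roots)
    list(k = length(cls$among), Sa = sum(pmax(cls$among, epsilon)),
         Sw = sum(pmax(cls$within, epsilon)))
  }

  best <- list(logL = -Inf, roots = NULL)
  consider <- function(logL, roots) {
    if (is.na(logL)) return(invisible())
    if (logL > best$logL + 1e-12 ||
        (abs(logL - best$logL) <= 1e-12 &&
         .smaller_roots(roots, best$roots)))
      best <<- list(logL = logL, roots = roots)
    invisible()
  }

  init0 <- sort(kids[[root]])
  if (.is_degenerate(init0, ntip, root)) {
    # all children of the root are tips: the only covers are the two
    # degenerate ones, so the two-class model has nothing to fit
    return(.null_only_result(tree, "greedy", 0L, epsilon))
  }

  ## phase 1: top-down split sweep, keeping every state visited
  sweep_states <- list()
  sweep_logL <- numeric(0)
  roots <- init0
  st <- exact_stats(roots)
  if (!.is_degenerate(roots, ntip, root)) {
    l0 <- ll_stats(st$k, st$Sa, st$Sw)
    consider(l0, roots)
    if (!is.na(l0)) {
      sweep_states[[length(sweep_states) + 1L]] <- roots
      sweep_logL <- c(sweep_logL, l0)
    }
  }
  repeat {
    internal <- roots[roots > ntip]
    if (!length(internal)) break
    pick <- NULL
    for (s in internal) {
      ch <- kids[[s]]
      sc <- sum(elen[ch])
      cand_roots <- sort(c(setdiff(roots, s), ch))
      if (.is_degenerate(cand_roots, ntip, root)) next
      lcand <- ll_stats(st$k + length(ch), st$Sa + sc, st$Sw - sc)
      if (is.na(lcand)) next
      if (is.null(pick) || lcand > pick$logL + 1e-12 ||
          (abs(lcand - pick$logL) <= 1e-12 &&
           .smaller_roots(cand_roots, pick$roots)))
        pick <- list(logL = lcand, roots = cand_roots, s = s, ch = ch, sc = sc)
    }
    if (is.null(pick)) break
    roots <- pick$roots
    st <- list(k = st$k + length(pick$ch), Sa = st$Sa + pick$sc,
               Sw = st$Sw - pick$sc)
    consider(pick$logL, roots)
    sweep_states[[length(sweep_states) + 1L]] <- roots
    sweep_logL <- c(sweep_logL, pick$logL)
  }

  ## phase 2: strict SPLIT/MERGE hill-climbs seeded by the sweep states,
  ## best first (capped so the cost stays near-linear in tree size), plus
  ## optional random restarts
  max_climbs <- 25L
  ord <- order(-sweep_logL)[seq_len(min(length(sweep_logL), max_climbs))]
  starts <- sweep_states[ord]
  if (!length(starts)) starts <- list(init0)
  if (restarts > 1L) {
    set.seed(as.integer(seed) %% .Machine$integer.max)
    for (i in seq_len(restarts - 1L))
      starts[[i + 1L]] <- .random_start(tree, kids, ntip, root)
  }
  in_state <- logical(ntip + tree$Nnode)
  for (start in starts) {
    roots <- start
    if (.is_degenerate(roots, ntip, root)) next
    st <- exact_stats(roots)
    cur <- ll_stats(st$k, st$Sa, st$Sw)
    if (is.na(cur)) next
    consider(cur, roots)
    repeat {
      pick <- NULL
      in_state[] <- FALSE
      in_state[roots] <- TRUE
      for (s in roots[roots > ntip]) {               # SPLIT
        ch <- kids[[s]]
        sc <- sum(elen[ch])
        cand_roots <- sort(c(setdiff(roots, s), ch))
        if (.is_degenerate(cand_roots, ntip, root)) next
        lcand <- ll_stats(st$k + length(ch), st$Sa + sc, st$Sw - sc)
        if (!is.na(lcand) && lcand > cur + 1e-12 &&
            (is.null(pick) || lcand > pick$logL + 1e-12 ||
             (abs(lcand - pick$logL) <= 1e-12 &&
              .smaller_roots(cand_roots, pick$roots))))
          pick <- list(logL = lcand, roots = cand_roots,
                       k = st$k + length(ch), Sa = st$Sa + sc, Sw = st$Sw - sc)
      }
      for (p in unique(parent[roots[roots != root]])) {  # MERGE
        if (p == 0L) next
        sibs <- kids[[p]]
        if (!all(in_state[sibs])) next
        sc <- sum(elen[sibs])
        cand_roots <- sort(c(setdiff(roots, sibs), p))
        if (.is_degenerate(cand_roots, ntip, root)) next
        lcand <- ll_stats(st$k - length(sibs), st$Sa - sc, st$Sw + sc)
        if (!is.na(lcand) && lcand > cur + 1e-12 &&
            (is.null(pick) || lcand > pick$logL + 1e-12 ||
             (abs(lcand - pick$logL) <= 1e-12 &&
              .smaller_roots(cand_roots, pick$roots))))
          pick <- list(logL = lcand, roots = cand_roots,
                       k = st$k - length(sibs), Sa = st$Sa - sc,
                       Sw = st$Sw + sc)
      }
      if (is.null(pick)) break
      roots <- pick$roots
      st <- list(k = pick$k, Sa = pick$Sa, Sw = pick$Sw)
      cur <- pick$logL
      consider(cur, roots)
    }
  }

  if (is.null(best$roots))
    return(.null_only_result(tree, "greedy", n_eval, epsilon))
  fit <- log_likelihood(tree, best$roots, fixed_lambda1 = fixed_lambda1,
                        epsilon = epsilon)
  .make_result(tree, fit, "greedy", n_eval, epsilon)
}

# tie-break helper: fewer roots, then lexicographically smaller id vector
.smaller_roots <- function(a, b) {
  if (is.null(b)) return(TRUE)
  if (length(a) != length(b)) return(length(a) < length(b))
  cmp <- a - b
  nz <- which(cmp != 0)
  length(nz) > 0L && cmp[nz[1]] < 0
}

# a random antichain cover: cut each root-to-tip path at a random depth
.random_start <- function(tree, kids, ntip, root) {
  state <- integer(0)
  recurse <- function(node) {
    if (node <= ntip || stats::runif(1) < 0.5) {
      state <<- c(state, node)
    } else {
      for (c_ in kids[[node]]) recurse(c_)
    }
  }
  for (c_ in kids[[root]]) recurse(c_)
  sort(unique(state))
}

.is_degenerate <- function(species_roots, ntip, root) {
  identical(as.integer(species_roots), root) ||
    all(species_roots <= ntip) && length(species_roots) == ntip
}

# ML tie-break: higher logL, then fewer species, then smallest id vector
.better_fit <- function(fit, incumbent) {
  if (is.null(incumbent)) return(TRUE)
  if (fit$logL > incumbent$logL + 1e-12) return(TRUE)
  if (fit$logL < incumbent$logL - 1e-12) return(FALSE)
  a <- fit$species_roots; b <- incumbent$species_roots
  if (length(a) != length(b)) return(length(a) < length(b))
  cmp <- a - b
  nz <- which(cmp != 0)
  length(nz) > 0L && cmp[nz[1]] < 0
}

#' Delimit species on a rooted phylogeny
#'
#' The end-user driver: optionally prunes outgroup taxa, chooses the search
#' strategy (exhaustive when the exact delimitation count is within
#' \code{cap}, greedy otherwise), and augments the maximum-likelihood
#' delimitation with the single-rate null model and the likelihood-ratio
#' test with one degree of freedom.
#'
#' @param tree A \code{"phylo"} object, or a Newick string/file path (passed
#'   to [read_newick()]).  The tree must be correctly rooted: the search
#'   starts from the root, and a misrooted tree misplaces the speciation
#'   transition points.
#' @param outgroup Character vector of tip labels pruned before the search.
#' @param fixed_lambda1 Optional speciation rate fixed externally, e.g.
#'   estimated once on a reference phylogeny; only the within-species rate
#'   is then re-estimated per candidate delimitation.
#' @param search \code{"auto"} (default), \code{"exhaustive"} or
#'   \code{"greedy"}.
#' @param epsilon Branch-length floor (default \code{1e-10}).
#' @param cap Exhaustive-search budget in number of delimitations.
#' @param restarts,seed Passed to [greedy_ml()].
#' @return An object of class \code{"ptp_result"}: list with \code{fit} (the
#'   best \code{"ptp_fit"}, or NULL when only degenerate covers exist),
#'   \code{species} (list of tip-label vectors partitioning the tips),
#'   \code{partition} (named group-id vector over tips), \code{null}
#'   (\code{lambda}, \code{logL0}), \code{lrt} (\code{statistic},
#'   \code{p_value}), \code{speciation_nodes}, \code{search_mode},
#'   \code{evaluations} and the input \code{tree}.
#' @examples
#' res <- delimit(ptp_example_tree())
#' res$species
#' res$lrt$p_value
#' @export
delimit <- function(tree, outgroup = NULL, fixed_lambda1 = NULL,
                    search = c("auto", "exhaustive", "greedy"),
                    epsilon = 1e-10, cap = 1e5, restarts = 1L, seed = 1L) {
  search <- match.arg(search)
  if (is.character(tree) && length(tree) == 1L) {
    tree <- if (file.exists(tree)) read_newick(file = tree)
            else read_newick(text = tree)
  }
  validate_tree(tree)
  if (!is.null(outgroup) && length(outgroup))
    tree <- prune_taxa(tree, outgroup)
  if (ape::Ntip(tree) < 2L)
    stop("fewer than 2 tips after pruning")

  if (search == "auto") {
    cnt <- count_delimitations(tree)
    search <- if (nchar(cnt) <= 15L && as.numeric(cnt) <= cap)
      "exhaustive" else "greedy"
  }
  if (search == "exhaustive")
    exhaustive_ml(tree, fixed_lambda1 = fixed_lambda1, epsilon = epsilon,
                  cap = cap)
  else
    greedy_ml(tree, fixed_lambda1 = fixed_lambda1, epsilon = epsilon,
              restarts = restarts, seed = seed)
}

.make_result <- function(tree, fit, mode, n_eval, epsilon) {
  cls <- classify_edges(tree, fit$species_roots)
  map <- .species_map(tree, fit$species_roots)
  species <- split(tree$tip.label, map)
  species <- species[order(as.integer(names(species)))]
  names(species) <- NULL
  partition <- stats::setNames(match(map, sort(unique(map))), tree$tip.label)
  null <- null_log_likelihood(tree, epsilon = epsilon)
  lrt <- lrt_pvalue(fit$logL, null$logL0)
  structure(
    list(fit = fit, species = species, partition = partition,
         speciation_nodes = cls$speciation_nodes,
         null = null, lrt = lrt,
         search_mode = mode, evaluations = n_eval, tree = tree),
    class = "ptp_result"
  )
}

# Trees whose only covers are degenerate (cherries, stars): report the null
# model as the fit-free answer — one species, p = 1.
.null_only_result <- function(tree, mode, n_eval, epsilon) {
  null <- null_log_likelihood(tree, epsilon = epsilon)
  structure(
    list(fit = NULL, species = list(tree$tip.label),
         partition = stats::setNames(rep(1L, ape::Ntip(tree)), tree$tip.label),
         speciation_nodes = ape::Ntip(tree) + 1L,
         null = null,
         lrt = list(statistic = 0, p_value = 1),
         search_mode = mode, evaluations = n_eval, tree = tree),
    class = "ptp_result"
  )
}

#' @export
print.ptp_result <- function(x, ...) {
  cat("PTP species delimitation (", x$search_mode, " search, ",
      x$evaluations, " likelihood evaluations)\n", sep = "")
  cat("  species: ", length(x$species), "\n", sep = "")
  if (!is.null(x$fit)) {
    cat(sprintf("  lambda1 = %.4g%s, lambda2 = %.4g, logL = %.4f\n",
                x$fit$lambda1, if (x$fit$fixed_lambda1) " [fixed]" else "",
                x$fit$lambda2, x$fit$logL))
  } else {
    cat("  no non-degenerate delimitation exists; null model reported\n")
  }
  cat(sprintf("  null: lambda = %.4g, logL0 = %.4f\n",
              x$null$lambda, x$null$logL0))
  cat(sprintf("  LRT (1 df): statistic = %.4f, p = %.4g\n",
              x$lrt$statistic, x$lrt$p_value))
  for (i in seq_along(x$species))
    cat("  [", i, "] ", paste(x$species[[i]], collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Tag delimited species as known or new
#'
#' Given a set of reference tip labels (each representing a named species),
#' a delimited species containing at least one reference tip is tagged
#' \code{"known"} (carrying those reference labels); species containing
#' none are tagged \code{"new"}.  This is the decision rule used when query
#' sequences are delimited together with reference sequences.
#'
#' @param result A \code{"ptp_result"} from [delimit()].
#' @param reference_labels Character vector of reference tip labels (subset
#'   of the tree's tips; may be empty).
#' @return A data frame with one row per species: \code{species_id},
#'   \code{tag} (\code{"known"}/\code{"new"}), \code{reference}
#'   (comma-separated reference labels or \code{NA}), \code{n_tips}; with
#'   attribute \code{counts = c(known = , new = )}.
#' @export
classify_species <- function(result, reference_labels = character(0)) {
  stopifnot(inherits(result, "ptp_result"))
  reference_labels <- as.character(reference_labels)
  unknown <- setdiff(reference_labels, unlist(result$species))
  if (length(unknown))
    stop("reference labels not among the tips: ",
         paste(unknown, collapse = ", "))
  rows <- lapply(seq_along(result$species), function(i) {
    refs <- intersect(result$species[[i]], reference_labels)
    data.frame(
      species_id = i,
      tag = if (length(refs)) "known" else "new",
      reference = if (length(refs)) paste(refs, collapse = ",") else NA_character_,
      n_tips = length(result$species[[i]]),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  attr(out, "counts") <- c(known = sum(out$tag == "known"),
                           new = sum(out$tag == "new"))
  out
}
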