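## PTP likelihood machinery.
##
## A delimitation is a set of "species roots": node ids of the host tree such
## that every tip has exactly one ancestor-or-self in the set (an antichain
## cover of the tips).  Edges on a root-to-species-root path (species root
## included) are among-species edges; all remaining edges are within-species.
## Each class is modelled as i.i.d. exponential branch lengths — the waiting
## times, in substitutions, of two independent Poisson processes: speciation
## (rate lambda1 per substitution) and within-species branching (lambda2).

#' Check a set of species roots against a tree
#'
#' A valid delimitation is an antichain cover: every tip has exactly one
#' ancestor-or-self among the species roots.
#'
#' @param tree A \code{"phylo"} object.
#' @param species_roots Integer vector of node ids (tips are \code{1..Ntip},
#'   internal nodes follow, the root being \code{Ntip + 1}).
#' @return The sorted species-root vector, invisibly; error if invalid.
#' @export
validate_delimitation <- function(tree, species_roots) {
  species_roots <- sort(unique(as.integer(species_roots)))
  n_nodes <- ape::Ntip(tree) + tree$Nnode
  if (length(species_roots) == 0L || any(species_roots < 1L | species_roots > n_nodes))
    stop("species_roots contains node ids outside 1..", n_nodes)
  cover <- .species_map(tree, species_roots, check = TRUE)
  if (anyNA(cover))
    stop("invalid delimitation: some tips are not covered by a species root")
  invisible(species_roots)
}

# For each tip, the species root on its root path (NA if uncovered; error on
# nested roots when check = TRUE).
.species_map <- function(tree, species_roots, check = FALSE) {
  ntip <- ape::Ntip(tree)
  parent <- .parent_vec(tree)
  root <- ntip + 1L
  is_root_set <- logical(ntip + tree$Nnode)
  is_root_set[species_roots] <- TRUE
  map <- rep(NA_integer_, ntip)
  for (tip in seq_len(ntip)) {
    node <- tip
    repeat {
      if (is_root_set[node]) {
        if (check && !is.na(map[tip]))
          stop("invalid delimitation: two species roots on the path to tip ",
               tree$tip.label[tip])
        map[tip] <- node
        if (!check) break
      }
      if (node == root) break
      node <- parent[node]
    }
  }
  map
}

#' Split the edges of a tree into among- and within-species classes
#'
#' An edge (parent to child) is among-species iff the child lies on a path
#' from the root to a species root, species root included; equivalently, iff
#' the child's subtree (self included) contains a species root.  All other
#' edges are within-species.  Every edge falls in exactly one class.
#'
#' @inheritParams validate_delimitation
#' @return A list with numeric vectors \code{among} and \code{within} (edge
#'   lengths), logical \code{is_among} over the rows of \code{tree$edge}, and
#'   \code{speciation_nodes}: the root plus every internal node whose
#'   incoming edge is among-species.
#' @examples
#' tr <- ptp_example_tree()
#' roots <- match(c("C"), tr$tip.label)            # tip C ...
#' roots <- c(roots, which_node(tr, c("D", "E", "F")))  # ... plus D, E, F
#' classify_edges(tr, roots)$among
#' @export
classify_edges <- function(tree, species_roots) {
  species_roots <- validate_delimitation(tree, species_roots)
  n_nodes <- ape::Ntip(tree) + tree$Nnode
  root <- ape::Ntip(tree) + 1L
  kids <- .children_list(tree)
  flag <- logical(n_nodes)          # subtree-or-self contains a species root
  flag[species_roots] <- TRUE
  for (node in .postorder_nodes(tree))
    if (!flag[node] && length(kids[[node]]))
      flag[node] <- any(flag[kids[[node]]])
  is_among <- flag[tree$edge[, 2L]]
  spec_nodes <- c(root, setdiff(tree$edge[is_among, 2L], seq_len(ape::Ntip(tree))))
  list(
    among = tree$edge.length[is_among],
    within = tree$edge.length[!is_among],
    is_among = is_among,
    speciation_nodes = sort(unique(spec_nodes))
  )
}

#' Look up internal nodes by label
#'
#' @param tree A \code{"phylo"} object with node labels.
#' @param labels Character vector of internal-node labels.
#' @return Integer node ids.
#' @export
which_node <- function(tree, labels) {
  if (is.null(tree$node.label))
    stop("tree has no internal node labels")
  idx <- match(labels, tree$node.label)
  if (anyNA(idx))
    stop("unknown node label(s): ", paste(labels[is.na(idx)], collapse = ", "))
  ape::Ntip(tree) + idx
}

#' Rate estimates for the two branch-length classes
#'
#' The maximum-likelihood rate of an exponential sample is the inverse of its
#' mean, so \code{lambda1 = 1/mean(among)} and \code{lambda2 = 1/mean(within)}.
#' Branch lengths are floored at \code{epsilon} first: inferred trees contain
#' zero-length branches, which would otherwise give infinite rates.
#'
#' @param among,within Numeric vectors of edge lengths; both non-empty.
#' @param epsilon Lower floor applied to every length (default \code{1e-10}).
#' @return \code{list(lambda1, lambda2)}.
#' @examples
#' cls <- classify_edges(ptp_example_tree(),
#'                       c(1, which_node(ptp_example_tree(), c("D", "E", "F"))))
#' estimate_rates(cls$among, cls$within)  # 8.33, 55.05
#' @export
estimate_rates <- function(among, within, epsilon = 1e-10) {
  if (length(among) == 0L || length(within) == 0L)
    stop("degenerate delimitation: a branch-length class is empty")
  among <- pmax(among, epsilon)
  within <- pmax(within, epsilon)
  list(lambda1 = 1 / mean(among), lambda2 = 1 / mean(within))
}

#' Two-class PTP log-likelihood of a delimitation
#'
#' With k among-species lengths x_1..x_k and n-k within-species lengths
#' x_{k+1}..x_n, the log-likelihood is
#' \deqn{L = k \log\lambda_1 - \lambda_1 \sum_{i \le k} x_i +
#'       (n-k)\log\lambda_2 - \lambda_2 \sum_{i > k} x_i.}
#' Unless \code{fixed_lambda1} is supplied, both rates are the closed-form
#' maximum-likelihood estimates (inverse class means).  With a fixed
#' \eqn{\lambda_1} — e.g. a speciation rate estimated once on a reference
#' phylogeny — only \eqn{\lambda_2} is estimated, and an empty among class is
#' then tolerated.
#'
#' @inheritParams validate_delimitation
#' @param fixed_lambda1 Optional externally supplied speciation rate (> 0).
#' @param epsilon Branch-length floor, see [estimate_rates()].
#' @return An object of class \code{"ptp_fit"}: list with \code{lambda1},
#'   \code{lambda2}, \code{logL}, \code{k}, \code{n}, \code{species_roots}.
#' @export
log_likelihood <- function(tree, species_roots, fixed_lambda1 = NULL,
                           epsilon = 1e-10) {
  cls <- classify_edges(tree, species_roots)
  .fit_classes(cls$among, cls$within, species_roots, fixed_lambda1, epsilon)
}

# shared by log_likelihood and the search (which classifies once per move)
.fit_classes <- function(among, within, species_roots, fixed_lambda1 = NULL,
                         epsilon = 1e-10) {
  if (length(within) == 0L)
    stop("degenerate delimitation: within-species class is empty")
  within <- pmax(within, epsilon)
  if (is.null(fixed_lambda1)) {
    if (length(among) == 0L)
      stop("degenerate delimitation: among-species class is empty")
    among <- pmax(among, epsilon)
    lambda1 <- 1 / mean(among)
  } else {
    stopifnot(is.numeric(fixed_lambda1), fixed_lambda1 > 0)
    lambda1 <- fixed_lambda1
    among <- pmax(among, epsilon)
  }
  lambda2 <- 1 / mean(within)
  k <- length(among)
  n <- k + length(within)
  logL <- k * log(lambda1) - lambda1 * sum(among) +
    (n - k) * log(lambda2) - lambda2 * sum(within)
  structure(
    list(lambda1 = lambda1, lambda2 = lambda2, logL = logL,
         k = k, n = n, species_roots = sort(unique(as.integer(species_roots))),
         fixed_lambda1 = !is.null(fixed_lambda1)),
    class = "ptp_fit"
  )
}

#' @export
print.ptp_fit <- function(x, ...) {
  cat("PTP two-class exponential fit\n")
  cat(sprintf("  lambda1 (speciation/subst): %.4g%s\n", x$lambda1,
              if (x$fixed_lambda1) " [fixed]" else ""))
  cat(sprintf("  lambda2 (coalescent/subst): %.4g\n", x$lambda2))
  cat(sprintf("  log-likelihood: %.4f  (k = %d among, %d within edges)\n",
              x$logL, x$k, x$n - x$k))
  invisible(x)
}

#' Single-rate null model
#'
#' Fits one exponential to all n edge lengths: \eqn{\lambda = n/\sum x},
#' \eqn{\log L_0 = n\log\lambda - n}.  This is the model under which there is
#' no distinction between speciation and within-species branching.
#'
#' @inheritParams estimate_rates
#' @param tree A \code{"phylo"} object with >= 2 edges.
#' @return \code{list(lambda, logL0, n)}.
#' @export
null_log_likelihood <- function(tree, epsilon = 1e-10) {
  validate_tree(tree)
  x <- pmax(tree$edge.length, epsilon)
  n <- length(x)
  if (n < 2L || sum(x) <= 0)
    stop("null model needs >= 2 edges with positive total length")
  lambda <- n / sum(x)
  list(lambda = lambda, logL0 = n * log(lambda) - n, n = n)
}

#' Likelihood-ratio test of two rate classes against one
#'
#' The two-class model adds one free rate, so 2(logL1 - logL0) is compared
#' with a chi-square distribution with one degree of freedom.  A large
#' p-value means the branch lengths do not support two classes: either all
#' tips are one species, or every tip is its own species.
#'
#' @param logL1 Two-class (alternative) log-likelihood.
#' @param logL0 Single-class (null) log-likelihood.
#' @param tol Absolute tolerance for clamping a slightly negative statistic
#'   caused by floating-point noise (default \code{1e-9}).
#' @return \code{list(statistic, p_value)}.
#' @export
lrt_pvalue <- function(logL1, logL0, tol = 1e-9) {
  stat <- 2 * (logL1 - logL0)
  if (stat < -tol)
    stop("logL1 < logL0 beyond tolerance: the alternative must nest the null")
  stat <- max(stat, 0)
  list(statistic = stat,
       p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}

## ---- counting and enumerating delimitations --------------------------------

#' Count the delimitations of a rooted tree
#'
#' Exact count of antichain covers via the recursion D(leaf) = 1,
#' D(node) = 1 + prod over children of D(child), carried out in
#' arbitrary-precision integer arithmetic so large trees do not overflow.
#' For a caterpillar tree with m tips the count is exactly m (the lower
#' bound over tree shapes); balanced trees maximise it.
#'
#' @param tree A \code{"phylo"} object.
#' @return The exact count as a decimal character string (counts grow
#'   doubly-exponentially with depth, far beyond integer range); use
#'   \code{as.numeric()} when the tree is small.
#' @examples
#' count_delimitations(ptp_example_tree())  # "16"
#' @export
count_delimitations <- function(tree) {
  validate_tree(tree)
  kids <- .children_list(tree)
  n_nodes <- ape::Ntip(tree) + tree$Nnode
  D <- vector("list", n_nodes)
  for (node in .postorder_nodes(tree)) {
    ch <- kids[[node]]
    if (length(ch) == 0L) {
      D[[node]] <- .big(1)
    } else {
      p <- .big(1)
      for (c_ in ch) p <- .big_mul(p, D[[c_]])
      D[[node]] <- .big_add(p, .big(1))
    }
  }
  .big_to_string(D[[ape::Ntip(tree) + 1L]])
}

#' Enumerate every delimitation of a rooted tree
#'
#' Yields each antichain cover exactly once, including the two degenerate
#' covers (the root alone; all tips).  Refuses trees whose exact count
#' exceeds \code{cap}.
#'
#' @param tree A \code{"phylo"} object.
#' @param cap Maximum number of delimitations to materialise (default 1e5).
#' @return A list of sorted integer node-id vectors, of length equal to
#'   \code{count_delimitations(tree)}.
#' @export
enumerate_delimitations <- function(tree, cap = 1e5) {
  validate_tree(tree)
  cnt <- count_delimitations(tree)
  if (nchar(cnt) > 15L || as.numeric(cnt) > cap)
    stop("tree has ", cnt, " delimitations, above the cap of ", format(cap),
         "; use the greedy search instead")
  kids <- .children_list(tree)
  n_nodes <- ape::Ntip(tree) + tree$Nnode
  E <- vector("list", n_nodes)
  for (node in .postorder_nodes(tree)) {
    ch <- kids[[node]]
    if (length(ch) == 0L) {
      E[[node]] <- list(node)
    } else {
      combos <- list(integer(0))
      for (c_ in ch) {
        combos <- unlist(
          lapply(combos, function(pre) lapply(E[[c_]], function(s) c(pre, s))),
          recursive = FALSE
        )
      }
      E[[node]] <- c(list(node), combos)
    }
  }
  lapply(E[[ape::Ntip(tree) + 1L]], function(s) sort(as.integer(s)))
}

## ---- tiny arbitrary-precision integers (base 1e7, little-endian) -----------
## No big-integer package is declared; the counting recursion only needs
## add and multiply on non-negative integers, which fit in a few lines.

.BIG_BASE <- 1e7

.big <- function(x) as.numeric(x)

.big_carry <- function(d) {
  i <- 1L
  while (i <= length(d)) {
    if (d[i] >= .BIG_BASE) {
      carry <- floor(d[i] / .BIG_BASE)
      d[i] <- d[i] - carry * .BIG_BASE
      if (i == length(d)) d <- c(d, 0)
      d[i + 1L] <- d[i + 1L] + carry
    }
    i <- i + 1L
  }
  while (length(d) > 1L && d[length(d)] == 0) d <- d[-length(d)]
  d
}

.big_add <- function(a, b) {
  n <- max(length(a), length(b))
  .big_carry(c(a, rep(0, n - length(a))) + c(b, rep(0, n - length(b))))
}

.big_mul <- function(a, b) {
  out <- rep(0, length(a) + length(b))
  for (i in seq_along(a)) {
    seg <- a[i] * b                  # < 1e14, exact in doubles
    idx <- (i - 1L) + seq_along(b)
    out[idx] <- out[idx] + seg
    out <- .big_carry(out)           # renormalise eagerly to stay exact
  }
  .big_carry(out)
}

.big_to_string <- function(d) {
  n <- length(d)
  parts <- vapply(rev(d), function(x) formatC(x, format = "d", width = 7, flag = "0"),
                  character(1))
  parts[1] <- sub("^0+(?=\\d)", "", parts[1], perl = TRUE)
  paste(parts, collapse = "")
}
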