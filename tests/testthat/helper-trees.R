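# Fixture builders (all trees are generated in code, none stored on disk).

example_tree <- function() ptp_example_tree()

# caterpillar: ((...((t1,t2),t3)...,tm), unit branch lengths
caterpillar_tree <- function(m, len = 1) {
  stopifnot(m >= 2)
  s <- sprintf("(t1:%g,t2:%g)", len, len)
  for (i in seq_len(m - 2) + 2)
    s <- sprintf("(%s:%g,t%d:%g)", s, len, i, len)
  read_newick(paste0(s, ";"))
}

balanced_tree <- function(n_tips, len = 1) {
  stopifnot(log2(n_tips) %% 1 == 0)
  tr <- ape::stree(n_tips, type = "balanced")
  tr$edge.length <- rep(len, nrow(tr$edge))
  tr
}

# random rooted binary tree with exponential branch lengths
random_tree <- function(n_tips, rate = 10) {
  tr <- ape::rtree(n_tips)
  tr$edge.length <- stats::rexp(nrow(tr$edge), rate)
  tr
}

# a random non-degenerate delimitation of a tree (NULL if none exists)
random_nondegenerate_delim <- function(tree) {
  ntip <- ape::Ntip(tree)
  root <- ntip + 1L
  all_d <- enumerate_delimitations(tree)
  keep <- Filter(function(d) {
    !(identical(as.integer(d), root) ||
        (length(d) == ntip && all(d <= ntip)))
  }, all_d)
  if (!length(keep)) return(NULL)
  keep[[sample.int(length(keep), 1L)]]
}

# a two-rate-class instance: random topology, a random true delimitation,
# among edges ~ Exp(rate_among), within edges ~ Exp(rate_within)
two_class_instance <- function(n_tips = 8, rate_among = 10,
                               rate_within = 100) {
  repeat {
    tr <- ape::rtree(n_tips)
    truth <- random_nondegenerate_delim(tr)
    if (!is.null(truth)) break
  }
  cls <- classify_edges(tr, truth)
  len <- numeric(nrow(tr$edge))
  len[cls$is_among] <- stats::rexp(sum(cls$is_among), rate_among)
  len[!cls$is_among] <- stats::rexp(sum(!cls$is_among), rate_within)
  tr$edge.length <- len
  list(tree = tr, truth = truth)
}

# comb of cherries: n_cherries two-tip species on a caterpillar spine, so a
# delimitation at the cherry roots has 2*n_cherries - 2 among-species edges
# and 2*n_cherries within-species edges
cherry_comb <- function(n_cherries, len = 1) {
  cherry <- function(i) sprintf("(c%da:%g,c%db:%g)S%d", i, len, i, len, i)
  s <- sprintf("(%s:%g,%s:%g)", cherry(1), len, cherry(2), len)
  for (i in seq_len(n_cherries - 2) + 2)
    s <- sprintf("(%s:%g,%s:%g)", s, len, cherry(i), len)
  read_newick(paste0(s, ";"))
}

cherry_roots <- function(tree) {
  which_node(tree, grep("^S", tree$node.label, value = TRUE))
}
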