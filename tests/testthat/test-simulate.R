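test_that("yule trees have the right size and are ultrametric", {
  for (n in c(2, 5, 30)) {
    tr <- yule_species_tree(n, birth_rate = 10, seed = n)
    expect_identical(ape::Ntip(tr), as.integer(n))
    expect_identical(tr$Nnode, as.integer(n) - 1L)
    expect_identical(nrow(tr$edge), 2L * as.integer(n) - 2L)
    expect_true(ape::is.ultrametric(tr, tol = 1e-8))
    expect_true(all(tr$edge.length > 0))
  }
  expect_error(yule_species_tree(1, 5), "n_species")
})

test_that("two-species root age matches the exponential waiting time", {
  # single waiting interval with 2 lineages at rate 2b: E[age] = 1/(2b)
  b <- 5
  set.seed(202)
  ages <- replicate(10000, {
    tr <- yule_species_tree(2, b)
    max(ape::node.depth.edgelength(tr))
  })
  expect_equal(mean(ages), 1 / (2 * b), tolerance = 0.05)
})

test_that("larger birth rates compress the species divergences", {
  mean_edge <- function(b, seed) {
    mean(sapply(1:100, function(i) {
      mean(yule_species_tree(30, b, seed = seed + i)$edge.length)
    }))
  }
  expect_gt(mean_edge(5, 500), mean_edge(160, 900))
})

test_that("a single-population coalescent has the classic TMRCA", {
  # two lineages coalesce at rate 1: E[TMRCA] = 1 coalescent unit
  set.seed(303)
  tm <- replicate(10000, {
    g <- msc_gene_tree(NULL, sampling = 2)
    max(ape::node.depth.edgelength(g$gene_tree))
  })
  expect_equal(mean(tm), 1, tolerance = 0.05)
  # n lineages: E[TMRCA] = 2(1 - 1/n)
  set.seed(304)
  tm5 <- replicate(4000, {
    g <- msc_gene_tree(NULL, sampling = 5)
    max(ape::node.depth.edgelength(g$gene_tree))
  })
  expect_equal(mean(tm5), 2 * (1 - 1 / 5), tolerance = 0.05)
})

test_that("gene trees respect the species divergence barrier", {
  # two species diverged at time t: cross-species coalescences must be
  # older than t (in coalescent units), within-species ones may be younger
  pop <- 0.01
  sp <- yule_species_tree(2, birth_rate = 5, seed = 77)
  tau <- max(ape::node.depth.edgelength(sp)) / pop
  g <- msc_gene_tree(sp, sampling = 6, pop_size = pop, seed = 78)
  gt <- g$gene_tree
  depth <- ape::node.depth.edgelength(gt)
  height <- max(depth[seq_len(ape::Ntip(gt))])
  ages <- height - depth
  # age of the MRCA of each cross-species tip pair
  sp_of <- g$true_partition[gt$tip.label]
  cross <- which(outer(sp_of, sp_of, "!=") & upper.tri(diag(length(sp_of))),
                 arr.ind = TRUE)
  for (r in seq_len(nrow(cross))) {
    mrca <- ape::getMRCA(gt, c(cross[r, 1], cross[r, 2]))
    expect_gte(ages[mrca], tau - 1e-9)
  }
  # and the partition is exactly the two sampled species
  expect_identical(sort(unique(g$true_partition)), c("sp1", "sp2"))
})

test_that("sampling schemes control the tip counts per species", {
  sp <- yule_species_tree(30, 10, seed = 9)
  g <- msc_gene_tree(sp, sampling = 10, pop_size = 0.01, seed = 10)
  expect_identical(ape::Ntip(g$gene_tree), 300L)
  expect_identical(unname(table(g$true_partition))[1], 10L)
  expect_true(all(table(g$true_partition) == 10))
  expect_true(ape::is.ultrametric(g$gene_tree, tol = 1e-8))
  expect_setequal(names(g$true_partition), g$gene_tree$tip.label)

  expect_identical(sum(sampling_uneven()), 512L)
  expect_identical(length(sampling_uneven()), 30L)
  g2 <- msc_gene_tree(sp, sampling = sampling_uneven(), pop_size = 0.01,
                      seed = 11)
  expect_identical(ape::Ntip(g2$gene_tree), 512L)
  expect_identical(sort(unname(table(g2$true_partition)), decreasing = TRUE)[1],
                   100L)
})

test_that("substitution scaling is linear and leaves the arg-max unchanged", {
  cfg <- sim_config(n_species = 8, birth_rate = 5, sampling = 3, seed = 21)
  gs <- simulate_dataset(cfg)
  expect_identical(gs$units, "substitutions")

  unscaled <- msc_gene_tree(yule_species_tree(8, 5, seed = 1), 3,
                            seed = 2)
  scaled <- scale_to_substitutions(unscaled, 0.01)
  expect_equal(scaled$gene_tree$edge.length,
               unscaled$gene_tree$edge.length * 0.01)
  expect_identical(scaled$true_partition, unscaled$true_partition)

  identity_scaled <- scale_to_substitutions(unscaled, 1)
  expect_equal(identity_scaled$gene_tree$edge.length,
               unscaled$gene_tree$edge.length)

  r1 <- delimit(unscaled$gene_tree)
  r2 <- delimit(scaled$gene_tree)
  expect_setequal(lapply(r1$species, sort), lapply(r2$species, sort))
})

test_that("log-normal branch noise perturbs lengths but not the partition", {
  cfg0 <- sim_config(n_species = 6, birth_rate = 10, sampling = 4, seed = 5)
  cfgN <- sim_config(n_species = 6, birth_rate = 10, sampling = 4, seed = 5,
                     noise_sd = 0.3)
  a <- simulate_dataset(cfg0)
  b <- simulate_dataset(cfgN)
  expect_identical(a$true_partition, b$true_partition)
  expect_identical(a$gene_tree$edge, b$gene_tree$edge)
  expect_false(any(a$gene_tree$edge.length == b$gene_tree$edge.length))
  # mean-one noise: totals agree roughly
  expect_equal(sum(b$gene_tree$edge.length), sum(a$gene_tree$edge.length),
               tolerance = 0.5)
})

test_that("replicates are reproducible from the root seed", {
  cfg <- sim_config(n_species = 6, birth_rate = 10, sampling = 4, seed = 5)
  a <- simulate_dataset(cfg, replicate = 3)
  b <- simulate_dataset(cfg, replicate = 3)
  expect_identical(write_newick(a$gene_tree), write_newick(b$gene_tree))
  expect_identical(a$true_partition, b$true_partition)
  c_ <- simulate_dataset(cfg, replicate = 4)
  expect_false(identical(write_newick(a$gene_tree),
                         write_newick(c_$gene_tree)))
})

test_that("known two-class rates are recovered from a fixed delimitation", {
  # 251 cherry species on a spine: 500 among edges, 502 within edges
  set.seed(404)
  tr <- cherry_comb(251)
  roots <- cherry_roots(tr)
  cls <- classify_edges(tr, roots)
  len <- numeric(nrow(tr$edge))
  len[cls$is_among] <- rexp(sum(cls$is_among), rate = 10)
  len[!cls$is_among] <- rexp(sum(!cls$is_among), rate = 100)
  tr$edge.length <- len

  fit <- log_likelihood(tr, roots)
  expect_identical(fit$k, 500L)
  expect_equal(fit$lambda1, 10, tolerance = 0.10)
  expect_equal(fit$lambda2, 100, tolerance = 0.10)
  lrt <- lrt_pvalue(fit$logL, null_log_likelihood(tr)$logL0)
  expect_lt(lrt$p_value, 1e-6)
})
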