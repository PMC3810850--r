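test_that("edge classification matches the thick/thin reading of the example", {
  tr <- example_tree()
  roots <- c(match("C", tr$tip.label), which_node(tr, c("D", "E", "F")))

  cls <- classify_edges(tr, roots)
  expect_setequal(cls$among, c(0.15, 0.11, 0.14, 0.10, 0.10, 0.12))
  expect_setequal(cls$within, c(0.01, 0.02, 0.015, 0.014, 0.03, 0.02))
  expect_identical(length(cls$among) + length(cls$within), nrow(tr$edge))
  expect_setequal(tr$node.label[cls$speciation_nodes - ape::Ntip(tr)],
                  c("R", "A", "B", "D", "E", "F"))

  # all-singleton cover: every edge is among-species
  all_tips <- classify_edges(tr, seq_len(7))
  expect_length(all_tips$within, 0)
  expect_length(all_tips$among, 12)

  # two deep species roots
  ab <- classify_edges(tr, which_node(tr, c("A", "B")))
  expect_setequal(ab$among, c(0.15, 0.11))
  expect_length(ab$within, 10)
})

test_that("invalid delimitations are rejected", {
  tr <- example_tree()
  expect_error(classify_edges(tr, which_node(tr, "A")), "not covered")
  expect_error(
    classify_edges(tr, c(which_node(tr, c("A", "D")),
                         match("C", tr$tip.label),
                         which_node(tr, "B"))),
    "two species roots")
  expect_error(classify_edges(tr, 99L), "node ids")
})

test_that("rates are inverse class means", {
  tr <- example_tree()
  cls <- classify_edges(tr, c(1, which_node(tr, c("D", "E", "F"))))
  r <- estimate_rates(cls$among, cls$within)
  expect_equal(round(r$lambda1, 2), 8.33)
  expect_equal(round(r$lambda2, 2), 55.05)

  expect_equal(estimate_rates(1.0, 1.0), list(lambda1 = 1, lambda2 = 1))
  r2 <- estimate_rates(c(0.2, 0.4), 0.05)
  expect_equal(r2$lambda1, 1 / 0.3)
  expect_equal(r2$lambda2, 20)

  expect_error(estimate_rates(numeric(0), 1), "degenerate")
  # zero lengths are floored, not fatal
  expect_gt(estimate_rates(c(0, 0.1), 0.05)$lambda1, 0)
})

test_that("the two-class log-likelihood reproduces the worked example", {
  tr <- example_tree()
  roots <- c(match("C", tr$tip.label), which_node(tr, c("D", "E", "F")))
  fit <- log_likelihood(tr, roots)
  expect_equal(round(fit$logL, 2), 24.77)
  expect_identical(fit$k, 6L)
  expect_identical(fit$n, 12L)

  # with lambda1 fixed at its own MLE the fit is unchanged
  fit_fixed <- log_likelihood(tr, roots, fixed_lambda1 = fit$lambda1)
  expect_equal(fit_fixed$logL, fit$logL, tolerance = 1e-10)
  expect_true(fit_fixed$fixed_lambda1)

  # unit-length classes: lambda1 = lambda2 = 1, each edge contributes
  # log(1) - 1, so logL = -n
  tr3 <- read_newick("((a:1,b:1):1,c:1);")
  f <- log_likelihood(tr3, c(ape::Ntip(tr3) + 2L, match("c", tr3$tip.label)))
  expect_identical(f$k, 2L)
  expect_equal(f$logL, -4)

  expect_error(log_likelihood(tr, seq_len(7)), "degenerate")
})

test_that("closed-form rates are the likelihood maximisers", {
  tr <- example_tree()
  roots <- c(1, which_node(tr, c("D", "E", "F")))
  cls <- classify_edges(tr, roots)
  fit <- log_likelihood(tr, roots)
  eval_at <- function(l1, l2) {
    k <- length(cls$among)
    n <- k + length(cls$within)
    k * log(l1) - l1 * sum(cls$among) +
      (n - k) * log(l2) - l2 * sum(cls$within)
  }
  for (f1 in c(0.9, 1.1)) for (f2 in c(0.9, 1.1))
    if (f1 != 1 || f2 != 1)
      expect_lt(eval_at(fit$lambda1 * f1, fit$lambda2 * f2), fit$logL)
  expect_lt(eval_at(fit$lambda1 * 0.9, fit$lambda2), fit$logL)
  expect_lt(eval_at(fit$lambda1, fit$lambda2 * 1.1), fit$logL)
})

test_that("null model fits one exponential to all edges", {
  tr <- example_tree()
  null <- null_log_likelihood(tr)
  expect_equal(null$lambda, 12 / 0.829, tolerance = 1e-10)
  expect_equal(null$logL0, 12 * log(12 / 0.829) - 12, tolerance = 1e-10)

  two <- read_newick("(a:1,b:1);")
  expect_equal(null_log_likelihood(two)$lambda, 1)
  expect_equal(null_log_likelihood(two)$logL0, -2)

  # rate recovery on simulated exponential edges
  set.seed(99)
  tr_sim <- random_tree(51, rate = 5)   # 100 edges ~ Exp(5)
  expect_equal(null_log_likelihood(tr_sim)$lambda, 5, tolerance = 0.15)
})

test_that("the LRT uses chi-square with one degree of freedom", {
  lrt <- lrt_pvalue(24.77, 20.069)
  expect_equal(lrt$statistic, 9.402, tolerance = 1e-3)
  expect_equal(lrt$p_value, 2.17e-3, tolerance = 0.01)

  expect_identical(lrt_pvalue(5, 5), list(statistic = 0, p_value = 1))
  # chi-square 5% critical value
  expect_equal(lrt_pvalue(10 + 3.841 / 2, 10)$p_value, 0.05, tolerance = 1e-3)
  # float noise below the null is clamped, real inversions are errors
  expect_identical(lrt_pvalue(10 - 1e-12, 10)$statistic, 0)
  expect_error(lrt_pvalue(9, 10), "nest")
})

test_that("delimitation counts follow the 1 + prod recursion", {
  expect_identical(count_delimitations(example_tree()), "16")
  for (m in 3:12)
    expect_identical(count_delimitations(caterpillar_tree(m)),
                     as.character(m))
  expect_identical(count_delimitations(balanced_tree(8)), "26")
  expect_identical(count_delimitations(balanced_tree(16)), "677")
  # big-integer path: balanced 256-leaf count overflows doubles but is exact
  big <- count_delimitations(balanced_tree(256))
  expect_gt(nchar(big), 30)
  expect_true(grepl("^[0-9]+$", big))
  # last digits check against independent modular arithmetic
  mod <- 1e6
  d <- 1
  for (lvl in 1:8) d <- (d * d + 1) %% mod
  expect_identical(substr(big, nchar(big) - 5, nchar(big)),
                   formatC(d, format = "d", width = 6, flag = "0"))
})

test_that("enumeration yields each cover exactly once and matches the count", {
  tr <- example_tree()
  all_d <- enumerate_delimitations(tr)
  expect_length(all_d, 16)
  keys <- vapply(all_d, paste, character(1), collapse = ",")
  expect_identical(anyDuplicated(keys), 0L)
  # the two degenerate covers are included
  expect_true(any(keys == "8"))                       # root alone
  expect_true(any(keys == paste(1:7, collapse = ","))) # all singletons

  cherry <- read_newick("(a:1,b:1);")
  expect_length(enumerate_delimitations(cherry), 2)

  set.seed(123)
  for (i in 1:50) {
    tr <- random_tree(sample(3:8, 1))
    expect_length(enumerate_delimitations(tr),
                  as.numeric(count_delimitations(tr)))
  }

  expect_error(enumerate_delimitations(balanced_tree(8), cap = 10), "26")
})

test_that("every enumerated cover is a valid antichain over the tips", {
  set.seed(5)
  tr <- random_tree(7)
  for (d in enumerate_delimitations(tr)) {
    expect_silent(validate_delimitation(tr, d))
    cls <- classify_edges(tr, d)
    expect_identical(length(cls$among) + length(cls$within), nrow(tr$edge))
  }
})

test_that("likelihood is covariant under rescaling of branch lengths", {
  set.seed(11)
  inst <- two_class_instance(8)
  tr <- inst$tree
  n <- nrow(tr$edge)
  for (c_ in c(0.01, 3, 250)) {
    scaled <- tr
    scaled$edge.length <- tr$edge.length * c_
    f0 <- log_likelihood(tr, inst$truth)
    f1 <- log_likelihood(scaled, inst$truth)
    expect_equal(f1$lambda1, f0$lambda1 / c_, tolerance = 1e-9)
    expect_equal(f1$lambda2, f0$lambda2 / c_, tolerance = 1e-9)
    expect_equal(f1$logL, f0$logL - n * log(c_), tolerance = 1e-8)
    # arg-max unchanged
    expect_identical(exhaustive_ml(scaled)$fit$species_roots,
                     exhaustive_ml(tr)$fit$species_roots)
  }
})
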