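test_that("host-use matrix is the binary establishment pattern", {
  lt <- tiny_links()
  M <- build_host_use_matrix(lt, "species")
  # i1 established on T1, T2 (hsA) and T3 (hsB); i2 on T4 (hsC)
  expect_equal(M["i1", c("hsA", "hsB")], c(hsA = 1, hsB = 1))
  expect_equal(sum(M["i2", ]), 1)
  expect_equal(unname(M["i2", "hsC"]), 1)
  expect_true(all(M %in% c(0, 1)))
  expect_true(all(rowSums(M) > 0))
  # row sums equal diet breadths
  expect_equal(rowSums(M), diet_breadth(lt, "species")[rownames(M)],
               ignore_attr = TRUE)

  empty <- lt
  empty$establishment <- empty$establishment[0, ]
  expect_error(build_host_use_matrix(empty, "species"), "empty")
})

test_that("phylogenetic VCV matches MRCA-depth oracle", {
  tr <- read_newick(text = "((a:1,b:1):1,c:2);")
  V <- phylo_vcv(tr)
  expect_equal(V["a", "b"], 1)
  expect_equal(V["a", "c"], 0)
  expect_equal(V["a", "a"], 2)

  # star tree is diagonal
  star <- read_newick(text = "(a:1,b:1,c:1);")
  expect_equal(unname(phylo_vcv(star)), diag(3))

  set.seed(5)
  for (rep in 1:5) {
    tree <- ape::rtree(10)
    V <- phylo_vcv(tree)
    expect_equal(V, vcv_oracle(tree)[rownames(V), colnames(V)], tolerance = 1e-10)
  }

  unrooted <- ape::unroot(ape::rtree(5))
  expect_error(phylo_vcv(unrooted), "rooted")
})

test_that("checkerboard swaps conserve both marginals on every call", {
  m0 <- matrix(c(1L, 0L, 0L, 1L), 2, 2)
  expect_equal(swap_null(m0, n_swaps = 1, seed = 1),
               matrix(c(0L, 1L, 1L, 0L), 2, 2))

  # a fully nested matrix admits no checkerboard and is returned unchanged
  nested <- matrix(c(1L, 1L, 1L, 0L), 2, 2)
  expect_warning(out <- swap_null(nested, n_swaps = 1), "no checkerboard")
  expect_equal(out, nested)

  set.seed(23)
  for (i in 1:100) {
    M <- matrix(rbinom(8 * 6, 1, 0.4), 8, 6)
    out <- suppressWarnings(swap_null(M, n_swaps = 5 * max(sum(M), 1)))
    expect_identical(rowSums(out), rowSums(M))
    expect_identical(colSums(out), colSums(M))
  }

  # row-shuffle alternative conserves diet breadths
  M <- matrix(rbinom(60, 1, 0.3), 10, 6)
  out <- row_shuffle_null(M, seed = 2)
  expect_identical(rowSums(out), rowSums(M))
})

test_that("threshold-model fits are deterministic and branch-scale invariant", {
  tr <- simulate_insect_tree(30, seed = 14)
  V <- phylo_vcv(tr)
  set.seed(2)
  y <- rbinom(30, 1, 0.4)
  y[1:2] <- c(0, 1)
  mc <- list(nitt = 800, burnin = 200, thin = 2)
  f1 <- fit_signal(y, V, mcmc = mc, seed = 6)
  f2 <- fit_signal(y, V, mcmc = mc, seed = 6)
  expect_identical(f1$h2_samples, f2$h2_samples)
  expect_true(all(f1$h2_samples >= 0 & f1$h2_samples <= 1))
  expect_true(f1$h2_ci[1] <= f1$h2 && f1$h2 <= f1$h2_ci[2])

  # a power-of-two multiplier keeps the rescaling exact in floating point,
  # so the invariance shows up as bitwise-identical chains
  f3 <- fit_signal(y, 8 * V, mcmc = mc, seed = 6)
  expect_equal(f1$h2_samples, f3$h2_samples)

  expect_error(fit_signal(rep(1, 30), V), "constant")
  expect_error(fit_signal(y, V[1:10, 1:10]), "conformable")
})

test_that("Benjamini-Hochberg flags follow the step-up rule", {
  # all four pass: p(4) = .04 <= 4/4 * .05
  expect_equal(p.adjust(c(.01, .02, .03, .04), "BH") <= .05, rep(TRUE, 4))
  # only p = .01 passes: .04 > 2/4 * .05, .30 > 3/4 * .05, .80 > .05
  expect_equal(p.adjust(c(.01, .04, .30, .80), "BH") <= .05,
               c(TRUE, FALSE, FALSE, FALSE))
})

test_that("signal test reports per-taxon Z against the swap null", {
  tr <- simulate_insect_tree(20, seed = 3)
  tax <- simulate_host_taxonomy(3, 1, 2)
  hu <- simulate_host_use(tr, tax, h2 = 0.7, regime = "random",
                          prevalence = 0.35, seed = 4)
  mc <- list(nitt = 600, burnin = 200, thin = 2)
  sg <- signal_test(hu$M, tr, n_null = 15, mcmc = mc, seed = 5)
  res <- sg$results
  expect_true(all(res$h2 >= 0 & res$h2 <= 1))
  expect_true(all(res$p >= 0 & res$p <= 1))
  expect_equal(res$z, (res$h2 - res$null_mean) / res$null_sd)
  # columns with fewer than 2 users or 2 non-users are skipped, not fitted
  n_users <- colSums(hu$M)
  expect_equal(sort(sg$skipped),
               sort(colnames(hu$M)[n_users < 2 | nrow(hu$M) - n_users < 2]))
})
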