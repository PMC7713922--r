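test_that("simulated insect trees are ultrametric with unit depth", {
  for (n in c(2, 5, 40)) {
    tr <- simulate_insect_tree(n, seed = n)
    expect_equal(length(tr$tip.label), n)
    depths <- ape::node.depth.edgelength(tr)[seq_len(n)]
    expect_equal(depths, rep(1, n), tolerance = 1e-9)
  }
  t1 <- simulate_insect_tree(8, seed = 5)
  t2 <- simulate_insect_tree(8, seed = 5)
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))
  t3 <- simulate_insect_tree(8, seed = 6)
  expect_false(identical(ape::write.tree(t1), ape::write.tree(t3)))
})

test_that("host-use simulation honours regimes and repairs empty rows", {
  tr <- simulate_insect_tree(30, seed = 9)
  tax <- simulate_host_taxonomy(5, 2, 2)
  hu <- simulate_host_use(tr, tax, h2 = 0.4, regime = "specialist",
                          prevalence = 0.15, seed = 2)
  fam_per_row <- apply(hu$M, 1, function(r) {
    length(unique(tax$host_family[r == 1]))
  })
  expect_true(all(fam_per_row == 1))  # every specialist touches one family
  expect_true(all(rowSums(hu$M) >= 1))

  hu0 <- simulate_host_use(tr, tax, h2 = 0, regime = "random", seed = 3)
  expect_true(all(rowSums(hu0$M) >= 1))
  expect_equal(dim(hu0$M), c(30, nrow(tax)))
})

test_that("cherry-state concordance matches the bivariate-normal orthant probability", {
  # the tips a, b share 95% of their root-to-tip path.  With h2 = 0 their
  # states are independent Bernoulli(0.5): P(same state) = 0.5.  With h2 = 1
  # the liabilities are bivariate normal with correlation 0.95 and the
  # orthant formula gives P(same state) = 1/2 + asin(0.95)/pi = 0.899.
  tr <- read_newick(text = "((a:0.05,b:0.05):0.95,(c:0.95,d:0.95):0.05);")
  tax <- simulate_host_taxonomy(2, 2, 2)  # 8 host columns: row repair is rare
  set.seed(11)
  match0 <- match1 <- logical(500)
  for (i in 1:500) {
    m0 <- simulate_host_use(tr, tax, h2 = 0, regime = "random", prevalence = 0.5)$M
    m1 <- simulate_host_use(tr, tax, h2 = 1, regime = "random", prevalence = 0.5)$M
    match0[i] <- m0["a", 1] == m0["b", 1]
    match1[i] <- m1["a", 1] == m1["b", 1]
  }
  expect_lt(abs(mean(match0) - 0.5), 0.07)
  expect_lt(abs(mean(match1) - (0.5 + asin(0.95) / pi)), 0.07)
})

test_that("simulated link tables validate and carry establishment evidence", {
  tr <- simulate_insect_tree(20, seed = 12)
  tax <- simulate_host_taxonomy(4, 2, 2)
  hu <- simulate_host_use(tr, tax, h2 = 0.3, regime = "mixed", seed = 13)
  sim <- simulate_link_table(hu$M, tax, seed = 14)
  expect_s3_class(sim$links, "link_table")
  expect_true(all(sim$links$records$count >= 1))
  expect_true(all(sim$links$records$life_stage == "adult_female"))
  expect_true(all(sim$links$records$tree_id %in% sim$census$tree_id))
  expect_equal(nrow(sim$census), nrow(tax) * 3)

  # round trip through the reader: every generated artifact passes validation
  path <- withr::local_tempfile(fileext = ".tsv")
  write_link_table(sim$links, path)
  expect_equal(read_link_table(path)$records, sim$links$records)

  # deterministic given seed
  sim2 <- simulate_link_table(hu$M, tax, seed = 14)
  expect_identical(sim$links$records, sim2$links$records)
})

test_that("gene-tree sets share leaves, stay shallow within species, and round-trip", {
  part <- list(A = paste0("a", 1:4), B = paste0("b", 1:3), C = paste0("c", 1:4))
  g <- simulate_gene_trees(part, concordance = 1, dropout = 0, seed = 8)
  leaves <- lapply(g$trees, function(t) sort(t$tip.label))
  expect_equal(leaves[[1]], leaves[[2]])
  expect_equal(leaves[[2]], leaves[[3]])
  expect_equal(leaves[[1]], sort(unname(unlist(part))))

  # within-species patristic distances are far below between-species ones
  d <- patristic_distances(g$trees[[1]])
  expect_lt(max(d[part$A, part$A]), 0.02)
  expect_gt(min(d[part$A, part$B]), 0.05)

  # sequences mirror the trees: supermatrix p-distances separate species
  pd <- p_distance(g$supermatrix$alignment)
  expect_lt(max(pd[part$A, part$A]), 0.04)
  expect_gt(min(pd[part$A, part$B]), 0.04)

  # newick round trip of generated trees
  path <- withr::local_tempfile(fileext = ".nwk")
  write_newick(g$trees[[1]], path)
  back <- read_newick(path)
  expect_equal(sort(back$tip.label), sort(g$trees[[1]]$tip.label))

  # dropout removes specimens from single loci only
  g2 <- simulate_gene_trees(part, concordance = 1, dropout = 0.5, seed = 9)
  missing_per_specimen <- vapply(unlist(part), function(s) {
    sum(!vapply(g2$trees, function(t) s %in% t$tip.label, logical(1)))
  }, numeric(1))
  expect_true(all(missing_per_specimen <= 1))
})
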