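tree_txt <- function(s) read_newick(text = s)

test_that("clade status distinguishes present, contradicted and uninformative", {
  tr <- tree_txt("((a,b),(c,d));")
  expect_equal(clade_status(c("a", "b"), tr), "present")
  expect_equal(clade_status(c("a", "c"), tr), "contradicted")
  expect_equal(clade_status(c("a", "b", "c", "d"), tr), "uninformative")
  # partial overlap: restriction of size 1 is uninformative
  tr2 <- tree_txt("((a,x),y);")
  expect_equal(clade_status(c("a", "b"), tr2), "uninformative")
})

test_that("independent lineages require presence in two trees and no contradiction", {
  t1 <- tree_txt("((a,b),(c,(d,e)));")
  lin <- independent_lineages(list(t1, t1, t1))
  expect_equal(partition_key(lapply(lin, `[[`, "members")),
               partition_key(list(c("a", "b"), c("d", "e"), c("c", "d", "e"))))

  # {a,b} present in trees 1 and 2 but contradicted in tree 3: excluded
  t3 <- tree_txt("((a,c),(b,(d,e)));")
  lin2 <- independent_lineages(list(t1, t1, t3))
  expect_false("a,b" %in% partition_key(lapply(lin2, `[[`, "members")))

  # {a,b} present in one tree, uninformative (absent leaves) in the others:
  # not shared by two trees, hence excluded
  t4 <- tree_txt("((a,x),(y,z));")
  t5 <- tree_txt("((b,x),(y,z));")
  lin3 <- independent_lineages(list(t1, t4, t5))
  expect_false("a,b" %in% partition_key(lapply(lin3, `[[`, "members")))

  expect_error(independent_lineages(list(t1)), "at least two")
})

test_that("provisional species are the smallest qualifying lineages", {
  mk_lineages <- function(sets) {
    structure(lapply(sets, function(s) {
      list(members = s, status = c("present", "present", "present"))
    }), class = "clade_set")
  }
  # {a,b,c,d,e} contains the more exclusive qualifying {a,b,c}; {d,e} is too small
  sp <- provisional_species(mk_lineages(list(c("a", "b", "c"),
                                             c("a", "b", "c", "d", "e"),
                                             c("d", "e"))))
  expect_equal(partition_key(sp), "a,b,c")

  expect_equal(partition_key(provisional_species(mk_lineages(list(c("a", "b", "c"))))),
               "a,b,c")
  expect_equal(length(provisional_species(mk_lineages(list(c("a", "b"), c("c", "d"))))), 0)
})

test_that("divergence threshold is the minimum cross-species distance", {
  ids <- c("a", "b", "c", "d", "e", "f")
  set.seed(3)
  D <- matrix(runif(36, 0.2, 0.5), 6, 6, dimnames = list(ids, ids))
  D[lower.tri(D)] <- t(D)[lower.tri(D)]
  diag(D) <- 0
  D["c", "d"] <- D["d", "c"] <- 0.07
  species <- list(c("a", "b", "c"), c("d", "e", "f"))
  # brute force over the 9 cross pairs
  brute <- min(outer(species[[1]], species[[2]], Vectorize(function(x, y) D[x, y])))
  expect_equal(divergence_threshold(species, D), 0.07)
  expect_equal(divergence_threshold(species, D), brute)

  # identical duplicate specimens in different species floor the threshold at 0
  D2 <- D; D2["c", "d"] <- D2["d", "c"] <- 0
  expect_equal(divergence_threshold(species, D2), 0)

  expect_true(is.na(divergence_threshold(species[1], D)))
})

test_that("remaining specimens are rescued per the threshold rule", {
  ids <- c("a1", "a2", "a3", "x", "y1", "y2", "y3", "z")
  n <- length(ids)
  D <- matrix(1, n, n, dimnames = list(ids, ids))
  diag(D) <- 0
  D[c("a1", "a2", "a3"), c("a1", "a2", "a3")] <- 0.01
  diag(D) <- 0
  species <- list(c("a1", "a2", "a3"))
  thr <- 0.1

  # x is far (1 = 10x threshold) from everything: its own singleton species
  # y1..y3 are mutually close but far from the species: one new cluster
  D[c("y1", "y2", "y3"), c("y1", "y2", "y3")] <- 0.05
  diag(D) <- 0
  # z sits at distance 0 from a member of the species: joins it
  D["z", "a1"] <- D["a1", "z"] <- 0
  asg <- assign_remaining(ids, species, thr, D)
  expect_equal(partition_key(asg$species),
               partition_key(list(c("a1", "a2", "a3", "z"), "x", c("y1", "y2", "y3"))))
  expect_equal(unname(asg$origin[match("x", names(asg$assignment))]),
               "threshold_singleton")
  expect_equal(unname(asg$origin[match("z", names(asg$assignment))]), "linked")

  # missing distances involving an unplaced specimen are an error
  D_na <- D; D_na["x", "y1"] <- D_na["y1", "x"] <- NA
  expect_error(assign_remaining(ids, species, thr, D_na), "missing distances")
})

test_that("delimitation recovers the generating partition and is label-equivariant", {
  part <- list(A = paste0("a", 1:4), B = paste0("b", 1:4), C = paste0("c", 1:4))
  g <- simulate_gene_trees(part, concordance = 1, dropout = 0, seed = 21)
  D <- p_distance(trim_alignment(g$supermatrix$alignment))
  asg <- delimit(g$trees, D)
  expect_equal(partition_key(asg$species), partition_key(part))
  # output is a partition: every specimen assigned exactly once
  expect_equal(sort(names(asg$assignment)), sort(unname(unlist(part))))
  expect_false(anyDuplicated(unlist(asg$species)) > 0)

  # consistent relabelling of specimens permutes the partition identically
  relabel <- function(x) chartr("abc", "qrs", x)
  g2 <- g
  for (k in 1:3) g2$trees[[k]]$tip.label <- relabel(g2$trees[[k]]$tip.label)
  D2 <- D
  dimnames(D2) <- lapply(dimnames(D), relabel)
  asg2 <- delimit(g2$trees, D2)
  expect_equal(partition_key(asg2$species),
               partition_key(lapply(asg$species, relabel)))
})

test_that("a deep singleton is rescued as its own species", {
  part <- list(A = paste0("a", 1:4), B = paste0("b", 1:4),
               C = paste0("c", 1:4), Z = "z1")
  g <- simulate_gene_trees(part, concordance = 1, dropout = 0, seed = 33)
  D <- p_distance(trim_alignment(g$supermatrix$alignment))
  asg <- delimit(g$trees, D)
  expect_equal(length(asg$species), 4)
  expect_equal(unname(asg$assignment[["z1"]] != ""), TRUE)
  expect_equal(unname(asg$origin[match("z1", names(asg$assignment))]),
               "threshold_singleton")
})

test_that("raising the threshold never increases the number of singleton species", {
  part <- list(A = paste0("a", 1:3), B = paste0("b", 1:3))
  g <- simulate_gene_trees(part, concordance = 1, dropout = 0, seed = 5)
  D <- p_distance(trim_alignment(g$supermatrix$alignment))
  specimens <- sort(unlist(part))
  species <- list(part$A)
  n_singletons <- vapply(c(0.001, 0.01, 0.05, 0.2, 0.8), function(thr) {
    asg <- assign_remaining(specimens, species, thr, D)
    sum(asg$origin == "threshold_singleton")
  }, numeric(1))
  expect_true(all(diff(n_singletons) <= 0))
})
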