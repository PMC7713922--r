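# Shared fixtures and independent oracles, built in code at test time.

# small well-formed link table: 2 insect species on 4 trees, mixed stages
tiny_links <- function() {
  link_table(data.frame(
    site = "p1",
    tree_id = c("T1", "T2", "T3", "T4", "T1"),
    host_species = c("hsA", "hsA", "hsB", "hsC", "hsA"),
    host_genus = c("hgA", "hgA", "hgB", "hgB", "hgA"),
    host_family = c("hfA", "hfA", "hfB", "hfB", "hfA"),
    insect_species = c("i1", "i1", "i1", "i2", "i2"),
    life_stage = c("adult_female", "second_instar", "adult_female",
                   "adult_female", "first_instar"),
    count = c(2, 1, 3, 5, 4),
    stringsAsFactors = FALSE
  ))
}

aln_from_strings <- function(x) {
  m <- matrix(unlist(strsplit(x, "")), nrow = length(x), byrow = TRUE,
              dimnames = list(names(x), NULL))
  alignment(m)
}

# canonical form of a partition (list of member sets) for comparison
partition_key <- function(sets) {
  sort(unname(vapply(sets, function(s) paste(sort(s), collapse = ","), character(1))))
}

# independent oracle: patristic distance by walking root-to-leaf paths
patristic_oracle <- function(tree) {
  n <- length(tree$tip.label)
  el <- numeric(max(tree$edge))
  el[tree$edge[, 2]] <- tree$edge.length
  parent <- integer(max(tree$edge))
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  root <- setdiff(tree$edge[, 1], tree$edge[, 2])[1]
  path_to_root <- function(i) {
    nodes <- i
    while (i != root) {
      i <- parent[i]
      nodes <- c(nodes, i)
    }
    nodes
  }
  d <- matrix(0, n, n, dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(n - 1)) {
    pi <- path_to_root(i)
    for (j in (i + 1):n) {
      pj <- path_to_root(j)
      shared <- intersect(pi, pj)
      dij <- sum(el[setdiff(pi, shared)]) + sum(el[setdiff(pj, shared)])
      d[i, j] <- d[j, i] <- dij
    }
  }
  d
}

# independent oracle: Brownian VCV as depth of the MRCA from the root
vcv_oracle <- function(tree) {
  n <- length(tree$tip.label)
  el <- numeric(max(tree$edge))
  el[tree$edge[, 2]] <- tree$edge.length
  parent <- integer(max(tree$edge))
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  root <- setdiff(tree$edge[, 1], tree$edge[, 2])[1]
  path_to_root <- function(i) {
    nodes <- i
    while (i != root) {
      i <- parent[i]
      nodes <- c(nodes, i)
    }
    nodes
  }
  depth_from_root <- function(i) sum(el[setdiff(path_to_root(i), root)])
  v <- matrix(0, n, n, dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(n)) {
    pi <- path_to_root(i)
    for (j in i:n) {
      mrca_nodes <- intersect(pi, path_to_root(j))
      # the MRCA is the intersection node farthest from the root
      depths <- vapply(mrca_nodes, depth_from_root, numeric(1))
      v[i, j] <- v[j, i] <- max(depths)
    }
  }
  v
}

# independent oracle: GLM coefficients by nested grid search over the
# log-likelihood (no IRLS involved)
glm_grid_oracle <- function(records, family) {
  loglik <- function(b0, b1) {
    if (family == "poisson") {
      eta <- b0 + b1 * records$breadth
      sum(records$response * eta - exp(eta))
    } else {
      eta <- b0 + b1 * records$breadth
      p <- plogis(eta)
      sum(records$trees_colonized * log(p) +
            (records$trees_surveyed - records$trees_colonized) * log1p(-p))
    }
  }
  c0 <- 0; c1 <- 0; half0 <- 6; half1 <- 3
  for (round in 1:9) {
    b0s <- seq(c0 - half0, c0 + half0, length.out = 41)
    b1s <- seq(c1 - half1, c1 + half1, length.out = 41)
    ll <- outer(b0s, b1s, Vectorize(loglik))
    best <- arrayInd(which.max(ll), dim(ll))
    c0 <- b0s[best[1]]; c1 <- b1s[best[2]]
    half0 <- half0 * 0.12; half1 <- half1 * 0.12
  }
  c(intercept = c0, slope = c1)
}

# deterministic sub-seed streams for loops over replicates
seed_stream <- function(master, n) {
  set.seed(master)
  sample.int(2^31 - 2, n)
}
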