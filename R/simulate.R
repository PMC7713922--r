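## Synthetic survey generator.  Produces every input the pipeline consumes —
## insect species trees, host taxonomies, binary host-use matrices with
## tunable phylogenetic signal, per-tree abundance link tables with tunable
## diet-breadth effects, and three-locus gene trees with sequences — with
## the ground truth alongside, so that estimates can be checked against
## known values.

fmt_bl <- function(x) format(x, digits = 10, scientific = FALSE, trim = TRUE)

#' Simulate an ultrametric insect species tree
#'
#' Birth-death tree conditioned on `n` extant species, with depth normalized
#' to 1 (so Brownian covariances have unit diagonal).
#'
#' @param n number of species (>= 2).
#' @param birth,death birth and death rates (defaults 1 and 0).
#' @param seed optional integer seed.
#' @return an ultrametric `ape::phylo` tree with tips `isp001`, `isp002`, ...
#' @export
simulate_insect_tree <- function(n, birth = 1, death = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(n >= 2)
  tr <- ape::rphylo(n, birth = birth, death = death)
  depth <- max(ape::node.depth.edgelength(tr))
  tr$edge.length <- tr$edge.length / depth
  tr$tip.label <- sprintf("isp%03d", seq_len(n))
  tr
}

#' Simulate a hierarchical host taxonomy
#'
#' @param n_families number of host families.
#' @param genera_per_family genera per family.
#' @param species_per_genus species per genus.
#' @param prefix label prefix (handy for per-site host pools).
#' @return data.frame with columns `host_species`, `host_genus`,
#'   `host_family`, one row per host species.
#' @export
simulate_host_taxonomy <- function(n_families = 8, genera_per_family = 2,
                                   species_per_genus = 2, prefix = "") {
  fam <- sprintf("%shfam%02d", prefix, seq_len(n_families))
  gen <- sprintf("%shgen%02d", prefix, seq_len(n_families * genera_per_family))
  n_sp <- n_families * genera_per_family * species_per_genus
  sp <- sprintf("%shsp%03d", prefix, seq_len(n_sp))
  data.frame(
    host_species = sp,
    host_genus = rep(gen, each = species_per_genus),
    host_family = rep(fam, each = genera_per_family * species_per_genus),
    stringsAsFactors = FALSE
  )
}

#' Simulate binary host use with tunable phylogenetic signal
#'
#' For each host species (column), insect liabilities are
#' `sqrt(h2) * Brownian(V) + sqrt(1 - h2) * iid N(0, 1)`; the species uses
#' the host iff its liability exceeds the threshold that yields the target
#' marginal prevalence.  In the `specialist` regime each insect is confined
#' to the host family where its liabilities are highest; `mixed` applies the
#' specialist rule to half the insect species.  All-zero rows are repaired
#' by switching on the most-liable host, so every species uses at least one.
#'
#' @param tree ultrametric insect species tree ([simulate_insect_tree()]).
#' @param taxonomy host taxonomy ([simulate_host_taxonomy()]).
#' @param h2 target proportion of liability variance explained by phylogeny,
#'   in `[0, 1]`.
#' @param regime `"random"`, `"specialist"` or `"mixed"`.
#' @param prevalence target marginal prevalence of use per host taxon
#'   (default 0.15).
#' @param seed optional integer seed.
#' @return list with the binary matrix `M` (insect species x host species)
#'   and `truth` (`h2`, `regime`, `prevalence`, and the liability matrix).
#' @export
simulate_host_use <- function(tree, taxonomy, h2 = 0.5,
                              regime = c("random", "specialist", "mixed"),
                              prevalence = 0.15, seed = NULL) {
  regime <- match.arg(regime)
  if (!is.null(seed)) set.seed(seed)
  stopifnot(h2 >= 0, h2 <= 1)
  n <- length(tree$tip.label)
  n_tax <- nrow(taxonomy)
  V <- phylo_vcv(tree)
  Vs <- V / mean(diag(V))
  liab <- matrix(rnorm(n * n_tax), n, n_tax)
  if (h2 > 0) {
    Ct <- t(chol(Vs + diag(1e-9, n)))
    bm <- Ct %*% matrix(rnorm(n * n_tax), n, n_tax)
    liab <- sqrt(h2) * bm + sqrt(1 - h2) * liab
  }
  dimnames(liab) <- list(tree$tip.label, taxonomy$host_species)
  thr <- qnorm(1 - prevalence)
  M <- matrix(as.integer(liab > thr), n, n_tax, dimnames = dimnames(liab))

  specialist_rows <- switch(regime,
    random = integer(0),
    specialist = seq_len(n),
    mixed = seq_len(floor(n / 2))
  )
  fam <- taxonomy$host_family
  for (i in specialist_rows) {
    fam_mean <- tapply(liab[i, ], fam, mean)
    f_star <- names(fam_mean)[which.max(fam_mean)]
    M[i, fam != f_star] <- 0L
    if (sum(M[i, ]) == 0) {
      in_f <- which(fam == f_star)
      M[i, in_f[which.max(liab[i, in_f])]] <- 1L
    }
  }
  zero <- which(rowSums(M) == 0)
  for (i in zero) M[i, which.max(liab[i, ])] <- 1L

  list(M = M, truth = list(h2 = h2, regime = regime, prevalence = prevalence,
                           liabilities = liab))
}

#' Simulate an occurrence link table from a host-use matrix
#'
#' Each host species receives `trees_per_species` surveyed trees.  An insect
#' species colonizes an individual tree of a usable host (matrix entry 1)
#' with probability `plogis(qlogis(base_occupancy) + beta_occ * bc)` where
#' `bc` is its centred diet breadth; colonized trees carry
#' `1 + Poisson(max(exp(log(lambda) + beta_abund * bc) - 1, 0))` established
#' individuals (counts are at least 1 because only colonized trees are
#' recorded).  All records are adult females.  Insect species that colonize
#' no tree are simply absent from the table, as in a real survey.
#'
#' @param M binary host-use matrix ([simulate_host_use()]).
#' @param taxonomy host taxonomy matching the columns of `M`.
#' @param trees_per_species surveyed trees per host species (default 3).
#' @param lambda baseline expected count per colonized tree (default 3).
#' @param beta_abund log-scale effect of diet breadth on abundance.
#' @param beta_occ logit-scale effect of diet breadth on occupancy.
#' @param base_occupancy colonization probability at average breadth
#'   (default 0.5).
#' @param site site label.
#' @param seed optional integer seed.
#' @return list with `links` (a [link_table()]), `census` (data.frame of all
#'   surveyed trees with taxonomy) and `truth` (`beta_abund`, `beta_occ`,
#'   per-species diet breadth).
#' @export
simulate_link_table <- function(M, taxonomy, trees_per_species = 3,
                                lambda = 3, beta_abund = 0, beta_occ = 0,
                                base_occupancy = 0.5, site = "site1",
                                seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(lambda > 0, identical(colnames(M), taxonomy$host_species))
  n_host <- nrow(taxonomy)
  census <- taxonomy[rep(seq_len(n_host), each = trees_per_species), ]
  census$tree_id <- sprintf("%s_T%04d", site, seq_len(nrow(census)))
  census <- census[, c("tree_id", "host_species", "host_genus", "host_family")]
  rownames(census) <- NULL

  breadth <- rowSums(M)
  bc <- breadth - mean(breadth)
  pairs <- which(M == 1, arr.ind = TRUE)
  ## expand to individual trees of the usable host species
  idx <- rep(seq_len(nrow(pairs)), each = trees_per_species)
  insect <- rownames(M)[pairs[idx, 1]]
  host_row <- (pairs[idx, 2] - 1L) * trees_per_species +
    rep(seq_len(trees_per_species), nrow(pairs))
  p_col <- plogis(qlogis(base_occupancy) + beta_occ * bc[pairs[idx, 1]])
  colonized <- runif(length(idx)) < p_col
  if (!any(colonized)) stop("simulation produced no colonizations; raise base_occupancy")
  mu <- pmax(exp(log(lambda) + beta_abund * bc[pairs[idx, 1]]) - 1, 0)
  counts <- 1L + rpois(length(idx), mu)

  rec <- data.frame(
    site = site,
    tree_id = census$tree_id[host_row[colonized]],
    host_species = census$host_species[host_row[colonized]],
    host_genus = census$host_genus[host_row[colonized]],
    host_family = census$host_family[host_row[colonized]],
    insect_species = insect[colonized],
    life_stage = "adult_female",
    count = counts[colonized],
    stringsAsFactors = FALSE
  )
  list(links = link_table(rec), census = census,
       truth = list(beta_abund = beta_abund, beta_occ = beta_occ,
                    breadth = stats::setNames(breadth, rownames(M))))
}

## internal: newick for a pectinate (ladder) subtree over `labels`, with
## increasing internal-node heights; returns the string without stem length
ladder_newick <- function(labels, heights) {
  if (length(labels) == 1) return(list(newick = labels, height = 0))
  stopifnot(length(heights) == length(labels) - 1, !is.unsorted(heights))
  cur <- labels[1]
  curh <- 0
  for (k in seq_along(heights)) {
    h <- heights[k]
    cur <- paste0("(", cur, ":", fmt_bl(h - curh), ",",
                  labels[k + 1], ":", fmt_bl(h), ")")
    curh <- h
  }
  list(newick = cur, height = curh)
}

## internal: rescale an ultrametric species tree so tips are at height 0,
## the root at `root_h`, and the shallowest split at `min_h`
rescale_species_tree <- function(tr, min_h = 0.03, root_h = 0.1) {
  n_tip <- length(tr$tip.label)
  depth <- ape::node.depth.edgelength(tr)
  total <- max(depth[seq_len(n_tip)])
  height <- total - depth  # height above the tips; ~0 at tips
  internal <- (n_tip + 1):(n_tip + tr$Nnode)
  h_int <- height[internal]
  h_min <- min(h_int)
  h_max <- max(h_int)
  new_h <- numeric(length(height))
  if (h_max - h_min < 1e-12) {
    new_h[internal] <- root_h
  } else {
    new_h[internal] <- min_h + (h_int - h_min) / (h_max - h_min) * (root_h - min_h)
  }
  tr$edge.length <- new_h[tr$edge[, 1]] - new_h[tr$edge[, 2]]
  tr
}

## internal: newick of a gene tree grafting specimen subtrees onto the tips
## of a species tree (no trailing semicolon)
graft_newick <- function(sptree, sub_newick, sub_height) {
  n_tip <- length(sptree$tip.label)
  root <- n_tip + 1L
  el <- numeric(n_tip + sptree$Nnode)
  el[sptree$edge[, 2]] <- sptree$edge.length
  kids <- split(sptree$edge[, 2], sptree$edge[, 1])
  rec <- function(node) {
    if (node <= n_tip) {
      sp <- sptree$tip.label[node]
      paste0(sub_newick[[sp]], ":", fmt_bl(el[node] - sub_height[[sp]]))
    } else {
      inner <- paste(vapply(kids[[as.character(node)]], rec, character(1)),
                     collapse = ",")
      if (node == root) paste0("(", inner, ")")
      else paste0("(", inner, "):", fmt_bl(el[node]))
    }
  }
  rec(root)
}

## internal: Jukes-Cantor-style sequence evolution along a tree
sim_sequences <- function(tree, L) {
  tree <- ape::reorder.phylo(tree, "cladewise")
  n_tip <- length(tree$tip.label)
  root <- n_tip + 1L
  seqs <- vector("list", n_tip + tree$Nnode)
  seqs[[root]] <- sample.int(4L, L, replace = TRUE)
  for (k in seq_len(nrow(tree$edge))) {
    p <- tree$edge[k, 1]; ch <- tree$edge[k, 2]
    pr <- 0.75 * (1 - exp(-4 * tree$edge.length[k] / 3))
    s <- seqs[[p]]
    mut <- which(runif(L) < pr)
    if (length(mut) > 0) {
      s[mut] <- ((s[mut] - 1L + sample.int(3L, length(mut), replace = TRUE)) %% 4L) + 1L
    }
    seqs[[ch]] <- s
  }
  m <- matrix(c("A", "C", "G", "T")[unlist(seqs[seq_len(n_tip)])],
              nrow = n_tip, byrow = TRUE)
  rownames(m) <- tree$tip.label
  alignment(m)
}

#' Simulate three gene trees and sequences around a known species partition
#'
#' Builds an ultrametric species tree over the multi-specimen species
#' (splits between heights 0.03 and 0.1), grafts shallow within-species
#' genealogies (specimen divergence below 0.016) onto its tips, and evolves
#' sequences along each gene tree so that p-distances mirror tree depths.
#' Within-species genealogies are deliberately discordant across the three
#' loci (pectinate resolutions rotated per locus), mimicking incomplete
#' lineage sorting; without this, concordant within-species clades would
#' (correctly, under the concordance rule) split true species.  With
#' probability `1 - concordance` a gene tree receives a species-level
#' perturbation (two species exchange positions).  Singleton species are
#' attached as deep outgroups (height >= 0.5, far beyond any plausible
#' divergence threshold) when `deep_singletons` is `TRUE`.  Locus dropout
#' removes each specimen from at most one locus (specimens always retain at
#' least two loci, matching the usual inclusion rule for multi-locus data).
#'
#' @param partition named list: species id -> character vector of specimen
#'   ids; at least two species with >= 2 specimens.
#' @param concordance probability in `[0, 1]` that a gene tree matches the
#'   species tree at the species level (default 1).
#' @param dropout per-specimen probability of missing one locus
#'   (default 0.2).
#' @param locus_length alignment length per locus (default 600).
#' @param deep_singletons place single-specimen species as deep outgroups
#'   (default TRUE).
#' @param seed optional integer seed.
#' @return list with `trees` (three `ape::phylo` gene trees), `alignments`
#'   (three per-locus [alignment()]s), `supermatrix` (the
#'   [concatenate_supermatrix()] result) and the input `partition`.
#' @export
simulate_gene_trees <- function(partition, concordance = 1, dropout = 0.2,
                                locus_length = 600, deep_singletons = TRUE,
                                seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(is.list(partition), !is.null(names(partition)))
  sizes <- lengths(partition)
  singles <- if (deep_singletons) names(partition)[sizes == 1] else character(0)
  core <- setdiff(names(partition), singles)
  if (length(core) < 2) stop("need at least two multi-specimen species")

  sptree <- ape::rphylo(length(core), birth = 1, death = 0)
  sptree$tip.label <- core
  sptree <- rescale_species_tree(sptree)

  trees <- vector("list", 3)
  alns <- vector("list", 3)
  for (l in 1:3) {
    spt <- sptree
    if (runif(1) > concordance && length(core) >= 3) {
      sw <- sample(length(core), 2)
      spt$tip.label[sw] <- spt$tip.label[rev(sw)]
    }
    sub_newick <- list()
    sub_height <- list()
    for (sp in core) {
      members <- partition[[sp]]
      m <- length(members)
      rot <- ((seq_len(m) - 1 + (l - 1)) %% m) + 1
      heights <- if (m > 1) sort(runif(m - 1, 0.002, 0.008)) else numeric(0)
      lad <- ladder_newick(members[rot], heights)
      sub_newick[[sp]] <- lad$newick
      sub_height[[sp]] <- lad$height
    }
    cur <- graft_newick(spt, sub_newick, sub_height)
    cur_h <- 0.1
    for (j in seq_along(singles)) {
      d <- 0.5 + 0.25 * (j - 1)
      cur <- paste0("(", cur, ":", fmt_bl(d - cur_h), ",",
                    partition[[singles[j]]], ":", fmt_bl(d), ")")
      cur_h <- d
    }
    trees[[l]] <- ape::read.tree(text = paste0(cur, ";"))
    alns[[l]] <- sim_sequences(trees[[l]], locus_length)
  }

  specimens <- unlist(partition, use.names = FALSE)
  if (dropout > 0) {
    drop_locus <- ifelse(runif(length(specimens)) < dropout,
                         sample.int(3, length(specimens), replace = TRUE), 0L)
    for (l in 1:3) {
      victims <- specimens[drop_locus == l]
      victims <- intersect(victims, trees[[l]]$tip.label)
      if (length(victims) > 0 &&
          length(trees[[l]]$tip.label) - length(victims) >= 3) {
        trees[[l]] <- ape::drop.tip(trees[[l]], victims)
        alns[[l]] <- alignment(alns[[l]][setdiff(rownames(alns[[l]]), victims), ,
                                         drop = FALSE])
      }
    }
  }
  names(trees) <- names(alns) <- paste0("locus", 1:3)
  list(trees = trees, alignments = alns,
       supermatrix = concatenate_supermatrix(alns), partition = partition)
}

#' Simulate a complete two-site survey with known ground truth
#'
#' Generates, independently per site: an insect species tree, a host
#' taxonomy, a binary host-use matrix with the requested phylogenetic
#' signal and specialization regime, and an occurrence link table plus tree
#' census with the requested diet-breadth effects.
#'
#' @param n_insect_species insect species per site (default 50).
#' @param n_host_families,genera_per_family,species_per_genus host taxonomy
#'   shape (defaults 8 x 2 x 2 = 32 host species).
#' @param trees_per_species surveyed trees per host species (default 3).
#' @param h2 target phylogenetic signal of host use (default 0.5).
#' @param regime specialization regime (default `"mixed"`).
#' @param prevalence target host-use prevalence (default 0.15).
#' @param lambda baseline abundance per colonized tree (default 3).
#' @param beta_abund diet-breadth effect on abundance (default 0: no
#'   trade-off, the empirical finding).
#' @param beta_occ diet-breadth effect on occupancy (default 0.5: broader
#'   diets occupy more trees, the empirical finding).
#' @param base_occupancy colonization probability at average breadth.
#' @param sites character vector of site labels (default two sites).
#' @param seed optional integer seed.
#' @return named list (one element per site), each with `tree`, `taxonomy`,
#'   `host_use` (matrix + truth), `links`, `census` and `truth`.
#' @export
simulate_survey <- function(n_insect_species = 50, n_host_families = 8,
                            genera_per_family = 2, species_per_genus = 2,
                            trees_per_species = 3, h2 = 0.5, regime = "mixed",
                            prevalence = 0.15, lambda = 3, beta_abund = 0,
                            beta_occ = 0.5, base_occupancy = 0.5,
                            sites = c("site1", "site2"), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  out <- lapply(sites, function(site) {
    tree <- simulate_insect_tree(n_insect_species)
    tree$tip.label <- paste0(site, "_", tree$tip.label)
    taxonomy <- simulate_host_taxonomy(n_host_families, genera_per_family,
                                       species_per_genus,
                                       prefix = paste0(site, "_"))
    hu <- simulate_host_use(tree, taxonomy, h2 = h2, regime = regime,
                            prevalence = prevalence)
    sim <- simulate_link_table(hu$M, taxonomy,
                               trees_per_species = trees_per_species,
                               lambda = lambda, beta_abund = beta_abund,
                               beta_occ = beta_occ,
                               base_occupancy = base_occupancy, site = site)
    list(tree = tree, taxonomy = taxonomy, host_use = hu,
         links = sim$links, census = sim$census,
         truth = c(hu$truth[c("h2", "regime", "prevalence")], sim$truth))
  })
  names(out) <- sites
  out
}
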