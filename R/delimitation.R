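## DNA-based species delimitation by genealogical concordance.  Clades shared
## by at least two of three gene trees, and contradicted by none, are treated
## as evolutionarily independent lineages; provisional species are the
## smallest such lineages with at least three specimens; the minimum
## divergence between provisional species becomes a maximum threshold for
## within-species divergence, used to place the remaining specimens.

## internal: leaf sets of all internal nodes of a rooted tree, as a named
## list keyed by the canonical set key.  Unrooted input is midpoint rooted.
tree_clades <- function(tree) {
  if (!ape::is.rooted(tree)) tree <- phangorn::midpoint(tree)
  n_tip <- length(tree$tip.label)
  if (n_tip < 2) return(list())
  desc <- vector("list", n_tip + tree$Nnode)
  for (i in seq_len(n_tip)) desc[[i]] <- tree$tip.label[i]
  ## postorder: children come before parents
  for (k in rev(seq_len(nrow(tree$edge)))) {
    p <- tree$edge[k, 1]
    ch <- tree$edge[k, 2]
    desc[[p]] <- c(desc[[p]], desc[[ch]])
  }
  clades <- desc[(n_tip + 1):(n_tip + tree$Nnode)]
  names(clades) <- vapply(clades, set_key, character(1))
  clades
}

#' Status of a candidate clade in a gene tree
#'
#' The status is computed on the restriction of the clade to the leaves
#' present in the tree (gene trees differ in leaf sets when loci fail to
#' amplify).  A restriction of size <= 1, or equal to the whole leaf set, is
#' uninformative; otherwise the clade is `present` if the restricted set is
#' exactly the leaf set of some node of the tree and `contradicted` if not.
#'
#' @param clade character vector of specimen ids.
#' @param tree an `ape::phylo` gene tree (midpoint rooted if unrooted).
#' @return one of `"present"`, `"contradicted"`, `"uninformative"`.
#' @export
clade_status <- function(clade, tree) {
  clade_status_keys(clade, tree$tip.label, tree_clades(tree))
}

## internal fast path: same rule against precomputed clade keys
clade_status_keys <- function(clade, leaves, clades) {
  s <- intersect(clade, leaves)
  if (length(s) <= 1 || length(s) == length(leaves)) return("uninformative")
  if (set_key(s) %in% names(clades)) "present" else "contradicted"
}

#' Evolutionarily independent lineages from three gene trees
#'
#' Candidate specimen sets are the union of all clades of the three trees; a
#' candidate is an independent lineage if its status ([clade_status()]) is
#' `present` in at least two trees and `contradicted` in none.
#'
#' @param gene_trees list of exactly three `ape::phylo` trees over
#'   overlapping specimen sets.
#' @return object of class `clade_set`: list of lineages, each a list with
#'   `members` (specimen ids) and `status` (per-tree status vector).
#' @export
independent_lineages <- function(gene_trees) {
  if (!is.list(gene_trees) || length(gene_trees) < 2) {
    stop("need at least two gene trees (three for the full concordance rule)")
  }
  if (length(gene_trees) != 3) stop("concordance delimitation expects exactly 3 gene trees")
  lapply(gene_trees, function(t) stopifnot(inherits(t, "phylo")))
  clades_per_tree <- lapply(gene_trees, tree_clades)
  leaves_per_tree <- lapply(gene_trees, function(t) t$tip.label)

  all_clades <- unlist(unname(clades_per_tree), recursive = FALSE)
  candidates <- all_clades[!duplicated(names(all_clades))]

  lineages <- list()
  for (cand in candidates) {
    status <- vapply(seq_along(gene_trees), function(k) {
      clade_status_keys(cand, leaves_per_tree[[k]], clades_per_tree[[k]])
    }, character(1))
    if (sum(status == "present") >= 2 && !any(status == "contradicted")) {
      lineages[[length(lineages) + 1]] <- list(members = sort(cand), status = status)
    }
  }
  structure(lineages, class = "clade_set")
}

#' Provisional species from independent lineages
#'
#' Provisional species are the independent lineages with at least three
#' specimens that contain no other qualifying (>= 3 member) lineage as a
#' proper subset; nested lineages with fewer than three members do not
#' disqualify their parent.  Lineages that overlap without nesting (possible
#' when gene-tree leaf sets differ) are resolved deterministically before
#' the rule is applied: keep the lineage present in more trees, then the
#' larger, then the lexicographically smallest member set.
#'
#' @param lineages a `clade_set` from [independent_lineages()].
#' @return list of disjoint character vectors of specimen ids.
#' @export
provisional_species <- function(lineages) {
  stopifnot(inherits(lineages, "clade_set"))
  if (length(lineages) == 0) return(list())
  n_present <- vapply(lineages, function(l) sum(l$status == "present"), numeric(1))
  sizes <- vapply(lineages, function(l) length(l$members), numeric(1))
  keys <- vapply(lineages, function(l) set_key(l$members), character(1))
  ord <- order(-n_present, -sizes, keys)

  accepted <- list()
  for (i in ord) {
    m <- lineages[[i]]$members
    ok <- all(vapply(accepted, function(a) {
      common <- length(intersect(a, m))
      common == 0 || common == length(a) || common == length(m)
    }, logical(1)))
    if (ok) accepted[[length(accepted) + 1]] <- m
  }

  big <- accepted[lengths(accepted) >= 3]
  species <- Filter(function(L) {
    !any(vapply(big, function(S) {
      length(S) < length(L) && all(S %in% L)
    }, logical(1)))
  }, big)

  ## minimal laminar sets are disjoint by construction; assert it anyway
  all_members <- unlist(species)
  if (anyDuplicated(all_members)) {
    stop("internal error: overlapping provisional species after conflict resolution")
  }
  species[order(vapply(species, function(s) sort(s)[1], character(1)))]
}

#' Minimum between-species divergence
#'
#' The minimum distance between members of different provisional species,
#' used as the maximum threshold for within-species divergence when placing
#' the remaining specimens.
#'
#' @param species list of >= 2 disjoint specimen sets.
#' @param D symmetric distance matrix covering all listed specimens.
#' @return the minimum cross-species distance; `NA` if fewer than two
#'   species are supplied (the threshold is then undefined).
#' @export
divergence_threshold <- function(species, D) {
  if (length(species) < 2) return(NA_real_)
  best <- Inf
  for (i in seq_len(length(species) - 1)) {
    for (j in (i + 1):length(species)) {
      block <- D[species[[i]], species[[j]], drop = FALSE]
      if (anyNA(block)) stop("missing distances between provisional species")
      best <- min(best, min(block))
    }
  }
  best
}

#' Assign remaining specimens given a divergence threshold
#'
#' Specimens outside provisional species are clustered by single linkage at
#' the threshold: a specimen farther than the threshold from every other
#' specimen becomes its own species; otherwise it joins the nearest cluster
#' within the threshold (chains of close unplaced specimens form new
#' multi-member species).  Provisional species are never merged with each
#' other.
#'
#' @param specimens character vector of all specimen ids.
#' @param species list of provisional species (disjoint subsets of
#'   `specimens`).
#' @param threshold maximum within-species divergence (strictly greater
#'   distances separate species).
#' @param D symmetric distance matrix over `specimens`.
#' @return object of class `species_assignment`; see [delimit()].
#' @export
assign_remaining <- function(specimens, species, threshold, D) {
  if (is.na(threshold)) stop("divergence threshold is undefined")
  stopifnot(all(specimens %in% rownames(D)))
  placed <- unlist(species)
  unplaced <- setdiff(specimens, placed)
  if (length(unplaced) > 0) {
    sub <- D[unplaced, specimens, drop = FALSE]
    bad <- rownames(sub)[apply(sub, 1, anyNA)]
    if (length(bad) > 0) {
      stop("missing distances involving unplaced specimen(s): ",
           paste(bad, collapse = ", "))
    }
  }

  ## clusters: provisional species (locked) then unplaced singletons
  clusters <- c(species, as.list(unplaced))
  locked <- c(rep(TRUE, length(species)), rep(FALSE, length(unplaced)))
  origin <- c(rep("provisional", length(species)), rep(NA_character_, length(unplaced)))

  repeat {
    k <- length(clusters)
    if (k < 2) break
    best <- NULL
    best_d <- Inf
    for (i in seq_len(k - 1)) {
      for (j in (i + 1):k) {
        if (locked[i] && locked[j]) next
        d_ij <- min(D[clusters[[i]], clusters[[j]], drop = FALSE])
        better <- d_ij < best_d - 1e-15 ||
          (abs(d_ij - best_d) <= 1e-15 && !is.null(best) &&
             set_key(c(clusters[[i]], clusters[[j]])) <
               set_key(c(clusters[[best[1]]], clusters[[best[2]]])))
        if (better) {
          best <- c(i, j)
          best_d <- d_ij
        }
      }
    }
    if (is.null(best) || best_d > threshold) break
    i <- best[1]; j <- best[2]
    clusters[[i]] <- c(clusters[[i]], clusters[[j]])
    locked[i] <- locked[i] || locked[j]
    origin[i] <- if (!is.na(origin[i]) && origin[i] == "provisional" ||
                     !is.na(origin[j]) && origin[j] == "provisional") "provisional" else NA_character_
    clusters[[j]] <- NULL
    locked <- locked[-j]
    origin <- origin[-j]
  }

  origin[is.na(origin) & lengths(clusters) == 1] <- "threshold_singleton"
  origin[is.na(origin)] <- "linked"

  ## deterministic species ids, ordered by lexicographically smallest member
  ord <- order(vapply(clusters, function(cl) sort(cl)[1], character(1)))
  clusters <- clusters[ord]
  origin <- origin[ord]
  ids <- sprintf("sp%03d", seq_along(clusters))

  assignment <- character(0)
  specimen_origin <- character(0)
  for (k in seq_along(clusters)) {
    members <- clusters[[k]]
    memb_origin <- rep(origin[k], length(members))
    if (origin[k] == "provisional") {
      prov <- unlist(species)
      memb_origin[!members %in% prov] <- "linked"
    }
    assignment[members] <- ids[k]
    specimen_origin[members] <- memb_origin
  }
  assignment <- assignment[specimens]
  specimen_origin <- specimen_origin[specimens]

  structure(list(
    assignment = assignment,
    origin = specimen_origin,
    species = stats::setNames(clusters, ids),
    provisional = species,
    outliers = clusters[origin != "provisional"],
    threshold = threshold
  ), class = "species_assignment")
}

#' Delimit species from three gene trees and a distance matrix
#'
#' Runs the full concordance workflow: independent lineages shared by at
#' least two gene trees and contradicted by none; provisional species (the
#' smallest lineages with >= 3 specimens); the minimum between-species
#' divergence as a within-species threshold; and single-linkage placement of
#' all remaining specimens, with distant specimens becoming new species.
#' When only one provisional species exists the threshold falls back to that
#' species' maximum within-species divergence; with none, delimitation stops
#' with an error (no defensible threshold exists).
#'
#' @param gene_trees list of exactly three `ape::phylo` gene trees.
#' @param D symmetric divergence matrix over all specimens, typically
#'   [p_distance()] of the trimmed supermatrix or [patristic_distances()] of
#'   a supermatrix tree.
#' @return a `species_assignment`: named specimen -> species id vector
#'   (`$assignment`), per-specimen `$origin` (`provisional`,
#'   `threshold_singleton` or `linked`), the `$species` clusters,
#'   `$provisional` species, and the `$threshold` used.
#' @export
delimit <- function(gene_trees, D) {
  specimens <- sort(unique(unlist(lapply(gene_trees, function(t) t$tip.label))))
  if (!all(specimens %in% rownames(D))) {
    stop("distance matrix does not cover all specimens in the gene trees")
  }
  lineages <- independent_lineages(gene_trees)
  species <- provisional_species(lineages)
  if (length(species) == 0) {
    stop("no provisional species found; the divergence threshold is undefined")
  }
  threshold <- if (length(species) >= 2) {
    divergence_threshold(species, D)
  } else {
    max(D[species[[1]], species[[1]]])
  }
  assign_remaining(specimens, species, threshold, D)
}

#' @export
print.species_assignment <- function(x, ...) {
  cat("Species assignment (genealogical concordance + divergence threshold)\n")
  cat("  specimens:          ", length(x$assignment), "\n")
  cat("  species:            ", length(x$species), "\n")
  cat("  provisional species:", length(x$provisional), "\n")
  cat("  threshold:          ", format(x$threshold, digits = 4), "\n")
  tab <- table(x$origin)
  cat("  origins:            ",
      paste(names(tab), as.integer(tab), sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.species_assignment <- function(object, ...) {
  sizes <- lengths(object$species)
  cat("Species sizes:\n")
  print(table(sizes))
  invisible(object)
}

#' @export
as.data.frame.species_assignment <- function(x, ...) {
  data.frame(specimen_id = names(x$assignment),
             species_id = unname(x$assignment),
             origin = unname(x$origin),
             stringsAsFactors = FALSE)
}

#' Write a species assignment as TSV
#'
#' @param x a `species_assignment`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_assignment <- function(x, path) {
  write.table(as.data.frame(x), path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
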