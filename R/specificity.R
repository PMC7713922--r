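## Diet-specificity test.  For each insect species, host-taxon diversity is
## the Simpson's reciprocal diversity index (1/D) of the individual host
## trees it colonizes, counted per host taxon at a chosen taxonomic level.
## The mean 1/D across insect species is compared against a null in which
## the species-by-tree associations are randomized while every species keeps
## its number of trees and every tree keeps its number of species: species
## are specialized to the extent that their hosts are less diverse than this
## null expects.

#' Simpson's reciprocal diversity index
#'
#' The effective number of equally used taxa, `1 / sum(p_i^2)` with
#' `p_i = count_i / sum(counts)`.  Always between 1 and the number of taxa.
#'
#' @param counts positive numeric vector of per-taxon counts (at least one).
#' @return the reciprocal Simpson index.
#' @examples
#' simpson_rdi(c(A = 2, B = 2))        # 2
#' simpson_rdi(c(A = 2, B = 1, C = 1)) # 2.667
#' @export
simpson_rdi <- function(counts) {
  counts <- counts[!is.na(counts)]
  if (length(counts) == 0) stop("no counts supplied")
  if (any(counts <= 0)) stop("counts must be positive")
  p <- counts / sum(counts)
  1 / sum(p^2)
}

#' Host-tree diversity per insect species
#'
#' For each insect species in the establishment view, counts the distinct
#' colonized trees per host taxon at the requested level and returns the
#' Simpson's reciprocal diversity of those counts.  Species observed on a
#' single tree are included with RDI 1.
#'
#' @param lt a [link_table()].
#' @param level host-taxonomic level: `"species"`, `"genus"` or `"family"`.
#' @return named numeric vector, insect species -> RDI.
#' @export
host_rdi_per_insect <- function(lt, level = c("species", "genus", "family")) {
  level <- match.arg(level)
  links <- establishment_links(lt, level)
  vapply(split(links$taxon, links$insect_species),
         function(tx) simpson_rdi(table(tx)), numeric(1))
}

## curveball trades on a list of per-species tree-index sets: repeatedly
## pick two species and re-deal the trees they do not share.  Samples
## uniformly from the simple bipartite graphs with the observed margins
## (every species keeps its tree count, every tree its species count).
curveball_trades <- function(sets, n_trades) {
  ns <- length(sets)
  if (ns < 2) return(sets)
  for (k in seq_len(n_trades)) {
    ij <- sample.int(ns, 2)
    si <- sets[[ij[1]]]
    sj <- sets[[ij[2]]]
    comm <- intersect(si, sj)
    a <- setdiff(si, comm)
    b <- setdiff(sj, comm)
    if (length(a) == 0 || length(b) == 0) next
    pool <- sample(c(a, b))
    sets[[ij[1]]] <- c(comm, pool[seq_len(length(a))])
    sets[[ij[2]]] <- c(comm, pool[length(a) + seq_len(length(b))])
  }
  sets
}

## internal: mean RDI over species given per-species tree sets and the
## taxon code of every tree
mean_rdi_sets <- function(sets, tree_tax, n_tax) {
  mean(vapply(sets, function(s) {
    tab <- tabulate(tree_tax[s], nbins = n_tax)
    sum(tab)^2 / sum(tab^2)
  }, numeric(1)))
}

#' Randomize species-by-tree associations
#'
#' Produces one draw from the null model of [specificity_test()]: the
#' species-by-tree colonization links are randomized while conserving, for
#' every insect species, its number of colonized trees, and for every tree,
#' its number of insect species (the default `"swap"` method performs
#' curveball trades on the bipartite incidence, sampling uniformly among
#' simple graphs with the observed margins).  `method = "label"` instead
#' permutes the insect-species column across links, which conserves the
#' same margins as row multisets but can place one species twice on a tree
#' (duplicates collapse when the table is rebuilt).
#'
#' Links that stay in place keep their original records (all life stages
#' and counts); relocated links carry the establishment total of one of the
#' species' vacated links as a single adult-female record.
#'
#' @param lt a [link_table()].
#' @param seed optional integer seed for reproducibility.
#' @param method `"swap"` (degree-preserving, default) or `"label"` (plain
#'   column permutation).
#' @return a new `link_table` with randomized associations; the attribute
#'   `"permuted_links"` holds the randomized tree-level colonization list
#'   (columns `tree_id`, `insect_species`).
#' @export
permute_associations <- function(lt, seed = NULL, method = c("swap", "label")) {
  stopifnot(inherits(lt, "link_table"))
  method <- match.arg(method)
  if (!is.null(seed)) set.seed(seed)
  rec <- lt$records
  is_est <- rec$life_stage %in% ESTABLISHED_STAGES & rec$count >= 1
  est <- rec[is_est, , drop = FALSE]
  if (nrow(est) == 0) stop("establishment view is empty")
  key <- paste(est$insect_species, est$tree_id, sep = "\r")
  link_rows <- !duplicated(key)
  link_sp <- est$insect_species[link_rows]
  link_tr <- est$tree_id[link_rows]

  if (method == "label") {
    new_sp <- sample(link_sp)
    perm_links <- data.frame(tree_id = link_tr, insect_species = new_sp,
                             stringsAsFactors = FALSE)
    map <- stats::setNames(new_sp, key[link_rows])
    rec$insect_species[is_est] <- unname(map[key])
    out <- link_table(rec)
    attr(out, "permuted_links") <- perm_links
    return(out)
  }

  species <- sort(unique(link_sp))
  sets <- lapply(species, function(s) link_tr[link_sp == s])
  names(sets) <- species
  new_sets <- curveball_trades(sets, n_trades = 10 * length(species))

  ## establishment totals per original link
  est_tot <- tapply(est$count, key, sum)
  tax <- unique(rec[, c("tree_id", "site", "host_species", "host_genus", "host_family")])
  rownames(tax) <- tax$tree_id

  kept_keys <- character(0)
  new_rows <- list()
  for (s in species) {
    old <- sets[[s]]
    new <- new_sets[[s]]
    kept <- intersect(old, new)
    kept_keys <- c(kept_keys, paste(s, kept, sep = "\r"))
    dropped <- sort(setdiff(old, new))
    added <- sort(setdiff(new, old))
    if (length(added) > 0) {
      cnt <- unname(est_tot[paste(s, dropped, sep = "\r")])
      new_rows[[length(new_rows) + 1]] <- data.frame(
        site = tax[added, "site"], tree_id = added,
        host_species = tax[added, "host_species"],
        host_genus = tax[added, "host_genus"],
        host_family = tax[added, "host_family"],
        insect_species = s, life_stage = "adult_female", count = cnt,
        stringsAsFactors = FALSE)
    }
  }
  keep_rec <- rec[!is_est | (paste(rec$insect_species, rec$tree_id, sep = "\r")
                             %in% kept_keys), , drop = FALSE]
  out <- link_table(do.call(rbind, c(list(keep_rec), new_rows)))
  attr(out, "permuted_links") <- data.frame(
    tree_id = unlist(new_sets, use.names = FALSE),
    insect_species = rep(species, lengths(new_sets)),
    stringsAsFactors = FALSE)
  out
}

#' Permutation test of diet specificity
#'
#' Computes the mean Simpson's reciprocal diversity index of colonized host
#' trees across insect species, then compares it against `n_permutations`
#' draws of the degree-preserving association null (see
#' [permute_associations()]; draws are consecutive thinned states of one
#' curveball chain).  `Z = (empirical - null mean) / null sd` with a
#' two-sided normal p-value; negative Z indicates specialization (hosts
#' less diverse than expected under random host use).
#'
#' @param lt a [link_table()] (typically one site; stratify by site
#'   upstream).
#' @param level host-taxonomic level: `"species"`, `"genus"` or `"family"`.
#' @param n_permutations number of null draws (default 1000).
#' @param seed optional integer seed.
#' @return object of class `specificity_test` with fields `site`, `level`,
#'   `empirical_mean_rdi`, `null_mean`, `null_sd`, `z`, `p`,
#'   `n_permutations` and the vector of `null_values`.
#' @export
specificity_test <- function(lt, level = c("species", "genus", "family"),
                             n_permutations = 1000, seed = NULL) {
  level <- match.arg(level)
  if (!is.null(seed)) set.seed(seed)
  links <- establishment_links(lt, level)
  if (length(unique(links$insect_species)) < 2) {
    stop("specificity test needs at least two insect species")
  }
  sp <- factor(links$insect_species)
  tr <- factor(links$tree_id)
  n_sp <- nlevels(sp)
  tree_tax <- as.integer(factor(host_taxonomy(lt, level)[levels(tr)]))
  n_tax <- max(tree_tax)
  sets <- split(as.integer(tr), sp)

  empirical <- mean_rdi_sets(sets, tree_tax, n_tax)

  ## one curveball chain: burn-in, then one thinned sample per permutation
  burnin <- 10L * n_sp
  thin <- max(1L, n_sp)
  cur <- curveball_trades(sets, burnin)
  null_values <- vapply(seq_len(n_permutations), function(i) {
    cur <<- curveball_trades(cur, thin)
    mean_rdi_sets(cur, tree_tax, n_tax)
  }, numeric(1))

  null_mean <- mean(null_values)
  null_sd <- sd(null_values)
  if (null_sd == 0) {
    warning("degenerate null distribution (sd = 0); p-value undefined")
    z <- NA_real_
    p <- NA_real_
  } else {
    z <- (empirical - null_mean) / null_sd
    p <- z_to_p(z)
  }
  structure(list(
    site = paste(sort(unique(lt$records$site)), collapse = "+"),
    level = level,
    empirical_mean_rdi = empirical,
    null_mean = null_mean,
    null_sd = null_sd,
    z = z,
    p = p,
    n_permutations = n_permutations,
    null_values = null_values
  ), class = "specificity_test")
}

#' @export
print.specificity_test <- function(x, digits = 3, ...) {
  cat("Diet-specificity permutation test (mean Simpson's 1/D of host trees)\n")
  cat(sprintf("  site: %s   host-taxon level: %s   permutations: %d\n",
              x$site, x$level, x$n_permutations))
  cat(sprintf("  empirical 1/D: %.*f   null 1/D: %.*f (sd %.*f)\n",
              digits, x$empirical_mean_rdi, digits, x$null_mean, digits, x$null_sd))
  cat(sprintf("  Z = %.*f,  two-sided p = %s\n", digits, x$z,
              format.pval(x$p, digits = digits, eps = 1e-3)))
  invisible(x)
}
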