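## Diet-breadth performance trade-offs.  If specialization is adaptive,
## more-specialized species should be more abundant on shared hosts and
## occupy more of the trees in their host taxa.  Abundance per colonized
## tree is modelled as Poisson (log link) and patch occupancy as binomial
## (logit link), each with diet breadth (count of host taxa used at a level)
## as predictor; significance comes from refitting after permuting diet
## breadths across species.

#' Diet breadth per insect species
#'
#' The number of distinct host taxa at the requested level on which each
#' insect species has at least one colonized tree; equals the row sums of
#' [build_host_use_matrix()].
#'
#' @inheritParams build_host_use_matrix
#' @return named integer vector, insect species -> host-taxon count.
#' @export
diet_breadth <- function(lt, level = c("species", "genus", "family"),
                         assignment = NULL) {
  level <- match.arg(level)
  M <- build_host_use_matrix(lt, level, assignment)
  stats::setNames(as.integer(rowSums(M)), rownames(M))
}

#' Abundance records: one row per colonized (species, tree) pair
#'
#' The response is the number of established individuals (second instars
#' plus adult females) of the species on that tree; the predictor is the
#' species' diet breadth at the requested level.  Only associations with at
#' least one record enter (uncolonized trees contribute nothing).
#'
#' @inheritParams diet_breadth
#' @return data.frame with columns `insect_species`, `tree_id`, `taxon`,
#'   `response` (count >= 1) and `breadth`.
#' @export
build_abundance_records <- function(lt, level = c("species", "genus", "family"),
                                    assignment = NULL) {
  level <- match.arg(level)
  est <- establishment_view(lt)
  if (nrow(est) == 0) stop("establishment view is empty")
  sp <- est$insect_species
  if (!is.null(assignment)) sp <- unname(assignment[sp])
  key <- paste(sp, est$tree_id, sep = "\r")
  agg <- rowsum(est$count, key, reorder = FALSE)
  first <- !duplicated(key)
  out <- data.frame(
    insect_species = sp[first],
    tree_id = est$tree_id[first],
    stringsAsFactors = FALSE
  )
  out$response <- as.numeric(agg[match(key[first], rownames(agg)), 1])
  tax <- host_taxonomy(lt, level)
  out$taxon <- unname(tax[out$tree_id])
  breadth <- diet_breadth(lt, level, assignment)
  out$breadth <- unname(breadth[out$insect_species])
  rownames(out) <- NULL
  out
}

#' Occupancy records: one row per observed (species, host taxon) pair
#'
#' `trees_colonized` of `trees_surveyed` trees of the taxon carry the
#' species; host taxa with fewer than `min_trees` surveyed trees are
#' excluded, and only pairs with at least one colonized tree enter.
#'
#' @inheritParams diet_breadth
#' @param census data.frame of all surveyed trees with columns `tree_id`,
#'   `host_species`, `host_genus`, `host_family` (the link table alone only
#'   lists colonized trees).
#' @param min_trees minimum surveyed trees per host taxon (default 3).
#' @return data.frame with columns `insect_species`, `taxon`,
#'   `trees_colonized`, `trees_surveyed` and `breadth`.
#' @export
build_occupancy_records <- function(lt, census,
                                    level = c("species", "genus", "family"),
                                    assignment = NULL, min_trees = 3) {
  level <- match.arg(level)
  census <- unique(as.data.frame(census)[, c("tree_id", "host_species",
                                             "host_genus", "host_family")])
  col <- paste0("host_", level)
  surveyed <- table(census[[col]])
  links <- establishment_links(lt, level)
  if (!is.null(assignment)) links$insect_species <- unname(assignment[links$insect_species])
  missing_tax <- setdiff(unique(links$taxon), names(surveyed))
  if (length(missing_tax) > 0) {
    stop("host taxa present in the link table but absent from the census: ",
         paste(missing_tax, collapse = ", "))
  }
  key <- paste(links$insect_species, links$taxon, sep = "\r")
  colonized <- rowsum(rep(1L, nrow(links)), key, reorder = FALSE)
  first <- !duplicated(key)
  out <- data.frame(
    insect_species = links$insect_species[first],
    taxon = links$taxon[first],
    stringsAsFactors = FALSE
  )
  out$trees_colonized <- as.integer(colonized[match(key[first], rownames(colonized)), 1])
  out$trees_surveyed <- as.integer(surveyed[out$taxon])
  breadth <- diet_breadth(lt, level, assignment)
  out$breadth <- unname(breadth[out$insect_species])
  out <- out[out$trees_surveyed >= min_trees, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Fit a Poisson or binomial GLM of performance on diet breadth
#'
#' Iteratively reweighted least squares via `stats::glm.fit`, with a strict
#' convergence tolerance.  For the Poisson family the response is the count
#' per colonized tree (log link); for the binomial family the response is
#' `trees_colonized / trees_surveyed` weighted by `trees_surveyed` (logit
#' link).  With `predictor = FALSE` an intercept-only model is fitted.
#'
#' @param records data.frame from [build_abundance_records()] or
#'   [build_occupancy_records()].
#' @param family `"poisson"` or `"binomial"`.
#' @param predictor include diet breadth as predictor (default TRUE).
#' @return object of class `glm_fit`: `family`, `coef` (intercept, slope),
#'   `converged`, `iterations`, `deviance`.
#' @export
fit_glm <- function(records, family = c("poisson", "binomial"), predictor = TRUE) {
  family <- match.arg(family)
  if (nrow(records) < 2) stop("need at least two records")
  x <- if (predictor) cbind(`(Intercept)` = 1, breadth = records$breadth)
       else cbind(`(Intercept)` = rep(1, nrow(records)))
  ctrl <- list(epsilon = 1e-10, maxit = 50, trace = FALSE)
  if (family == "poisson") {
    fit <- suppressWarnings(
      glm.fit(x, records$response, family = poisson(), control = ctrl))
  } else {
    y <- records$trees_colonized / records$trees_surveyed
    fit <- suppressWarnings(
      glm.fit(x, y, weights = records$trees_surveyed, family = binomial(),
              control = ctrl))
  }
  cf <- fit$coefficients
  structure(list(
    family = if (family == "poisson") "poisson-log" else "binomial-logit",
    coef = c(intercept = unname(cf[1]),
             slope = if (predictor) unname(cf[2]) else NA_real_),
    converged = isTRUE(fit$converged) && !anyNA(cf),
    iterations = fit$iter,
    deviance = fit$deviance
  ), class = "glm_fit")
}

#' @export
print.glm_fit <- function(x, digits = 4, ...) {
  cat(sprintf("GLM (%s): intercept %.*f, slope %s; %sconverged in %d iterations\n",
              x$family, digits, x$coef["intercept"],
              ifelse(is.na(x$coef["slope"]), "NA",
                     sprintf("%.*f", digits, x$coef["slope"])),
              if (x$converged) "" else "NOT ", x$iterations))
  invisible(x)
}

#' Permutation test for a diet-breadth GLM slope
#'
#' Refits the model on `n_perm` null data sets in which diet breadths are
#' permuted across insect species (the species is the exchangeable unit;
#' every record of a species receives its permuted breadth).  Per-record
#' permutation is available as an alternative.  `Z = (empirical slope -
#' null mean) / null sd`, with a two-sided normal p-value.
#'
#' @param records data.frame of abundance or occupancy records.
#' @param family `"poisson"` or `"binomial"`.
#' @param n_perm number of permutations (default 1000).
#' @param permute `"species"` (default) or `"record"`.
#' @param seed optional integer seed.
#' @return object of class `perm_glm` with the empirical `slope`,
#'   `null_mean`, `null_sd`, `z`, `p`, and the vector of `null_slopes`.
#' @export
permutation_significance <- function(records, family = c("poisson", "binomial"),
                                     n_perm = 1000,
                                     permute = c("species", "record"),
                                     seed = NULL) {
  family <- match.arg(family)
  permute <- match.arg(permute)
  if (!is.null(seed)) set.seed(seed)
  emp <- fit_glm(records, family)
  if (!emp$converged) stop("empirical GLM did not converge")

  sp_breadth <- tapply(records$breadth, records$insect_species, function(b) b[1])
  sp_of_record <- records$insect_species
  resp_multiset <- sort(if (family == "poisson") records$response
                        else records$trees_colonized)

  null_slopes <- numeric(n_perm)
  n_fail <- 0L
  for (b in seq_len(n_perm)) {
    perm <- records
    if (permute == "species") {
      newb <- stats::setNames(sample(as.numeric(sp_breadth)), names(sp_breadth))
      perm$breadth <- unname(newb[sp_of_record])
    } else {
      perm$breadth <- sample(perm$breadth)
    }
    ## permutation conserves the response and predictor multisets
    stopifnot(identical(sort(if (family == "poisson") perm$response
                             else perm$trees_colonized), resp_multiset))
    fit <- fit_glm(perm, family)
    if (fit$converged) {
      null_slopes[b] <- fit$coef["slope"]
    } else {
      null_slopes[b] <- NA_real_
      n_fail <- n_fail + 1L
    }
  }
  if (n_fail > 0.1 * n_perm) {
    stop("more than 10% of null fits failed to converge (", n_fail, "/", n_perm, ")")
  }
  ok <- !is.na(null_slopes)
  null_mean <- mean(null_slopes[ok])
  null_sd <- sd(null_slopes[ok])
  z <- (emp$coef["slope"] - null_mean) / null_sd
  structure(list(
    family = emp$family,
    slope = unname(emp$coef["slope"]),
    intercept = unname(emp$coef["intercept"]),
    null_mean = null_mean,
    null_sd = null_sd,
    z = unname(z),
    p = unname(z_to_p(z)),
    n_perm = n_perm,
    n_nonconverged = n_fail,
    null_slopes = null_slopes
  ), class = "perm_glm")
}

#' @export
print.perm_glm <- function(x, digits = 3, ...) {
  cat(sprintf("Permutation GLM test (%s)\n", x$family))
  cat(sprintf("  slope: %.*f   null: %.*f (sd %.*f)\n", digits, x$slope,
              digits, x$null_mean, digits, x$null_sd))
  cat(sprintf("  Z = %.*f,  two-sided p = %s   (%d permutations)\n",
              digits, x$z, format.pval(x$p, digits = digits, eps = 1e-3),
              x$n_perm))
  invisible(x)
}

#' Abundance and occupancy trade-off tests at one host-taxonomic level
#'
#' Convenience wrapper running the Poisson abundance-per-tree and binomial
#' patch-occupancy permutation tests for one link table (typically one
#' site).
#'
#' @inheritParams build_occupancy_records
#' @param n_perm permutations per test.
#' @param seed optional integer seed.
#' @return list with elements `abundance` and `occupancy`, each a
#'   [permutation_significance()] result (class `perm_glm`).
#' @export
tradeoff_test <- function(lt, census, level = c("species", "genus", "family"),
                          assignment = NULL, min_trees = 3, n_perm = 1000,
                          seed = NULL) {
  level <- match.arg(level)
  if (!is.null(seed)) set.seed(seed)
  ab <- build_abundance_records(lt, level, assignment)
  oc <- build_occupancy_records(lt, census, level, assignment, min_trees)
  list(abundance = permutation_significance(ab, "poisson", n_perm),
       occupancy = permutation_significance(oc, "binomial", n_perm))
}
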