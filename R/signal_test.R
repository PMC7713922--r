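## Phylogenetic conservatism of host use.  The binary use/nonuse of each
## host taxon is modelled with the phylogenetic threshold model
## (fit_signal); empirical heritabilities are compared against a null built
## by checkerboard-swapping the species x host-taxon matrix, which preserves
## both the diet breadth of every insect species (row sums) and the number
## of users of every host taxon (column sums).

#' Binary host-use matrix
#'
#' `M[s, t] = 1` iff insect species `s` has at least one colonized tree
#' (establishment view) with host taxon `t` at the requested level.
#'
#' @param lt a [link_table()].
#' @param level host-taxonomic level.
#' @param assignment optional named vector relabelling the table's
#'   `insect_species` values (e.g., a specimen -> species map from
#'   [delimit()] when the table is recorded per specimen).
#' @return binary integer matrix, insect species x host taxa, with no
#'   all-zero rows.
#' @export
build_host_use_matrix <- function(lt, level = c("species", "genus", "family"),
                                  assignment = NULL) {
  level <- match.arg(level)
  links <- establishment_links(lt, level)
  sp <- links$insect_species
  if (!is.null(assignment)) {
    if (!all(sp %in% names(assignment))) {
      stop("assignment does not cover all insect species in the table")
    }
    sp <- unname(assignment[sp])
  }
  m <- table(sp, links$taxon)
  m <- matrix(as.integer(m > 0), nrow = nrow(m), dimnames = dimnames(m))
  names(dimnames(m)) <- NULL
  m
}

## internal: TRUE if some 2x2 checkerboard submatrix exists
has_checkerboard <- function(M) {
  n <- nrow(M)
  if (n < 2 || ncol(M) < 2) return(FALSE)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      a <- M[i, ] == 1 & M[j, ] == 0
      b <- M[i, ] == 0 & M[j, ] == 1
      if (any(a) && any(b)) return(TRUE)
    }
  }
  FALSE
}

#' Degree-preserving checkerboard swap null
#'
#' Randomizes a binary matrix by 2x2 checkerboard swaps
#' (`[[1,0],[0,1]] <-> [[0,1],[1,0]]`), each of which conserves all row and
#' column sums exactly.  Swaps are attempted until `n_swaps` succeed; the
#' default is 10 times the number of associations (1 entries), enough to
#' shuffle the matrix thoroughly.
#'
#' @param M binary matrix.
#' @param n_swaps number of successful swaps to perform.
#' @param seed optional integer seed.
#' @return shuffled binary matrix with identical marginals.  If the matrix
#'   admits no checkerboard at all (fully nested), it is returned unchanged
#'   with a warning.
#' @export
swap_null <- function(M, n_swaps = 10 * sum(M), seed = NULL) {
  if (!all(M %in% c(0L, 1L))) stop("M must be binary")
  if (!is.null(seed)) set.seed(seed)
  rs <- rowSums(M)
  cs <- colSums(M)
  n <- nrow(M); m <- ncol(M)
  if (n < 2 || m < 2 || n_swaps == 0) return(M)
  done <- 0L
  failures <- 0L
  while (done < n_swaps) {
    i <- sample.int(n, 2)
    j <- sample.int(m, 2)
    sub <- M[i, j]
    if (sub[1, 1] == sub[2, 2] && sub[1, 2] == sub[2, 1] &&
        sub[1, 1] != sub[1, 2]) {
      M[i, j] <- 1L - sub
      done <- done + 1L
      failures <- 0L
    } else {
      failures <- failures + 1L
      if (failures >= 2000L) {
        if (!has_checkerboard(M)) {
          warning("matrix admits no checkerboard swap; returned as-is")
          break
        }
        failures <- 0L
      }
    }
  }
  stopifnot(identical(rowSums(M), rs), identical(colSums(M), cs))
  M
}

#' Row-wise shuffle null (alternative to the checkerboard swap)
#'
#' Re-draws each insect species' host set uniformly at random among the
#' available taxa, preserving row sums (diet breadths) but not column sums.
#'
#' @param M binary matrix.
#' @param seed optional integer seed.
#' @return shuffled binary matrix with identical row sums.
#' @export
row_shuffle_null <- function(M, seed = NULL) {
  if (!all(M %in% c(0L, 1L))) stop("M must be binary")
  if (!is.null(seed)) set.seed(seed)
  out <- M
  out[] <- 0L
  for (i in seq_len(nrow(M))) {
    out[i, sample.int(ncol(M), sum(M[i, ]))] <- 1L
  }
  out
}

#' Permutation test of phylogenetic signal in host use
#'
#' For each host taxon with at least two using and two non-using insect
#' species, fits the phylogenetic threshold model to the binary use column
#' and compares the posterior-mean heritability `h2` against its
#' distribution over `n_null` swap-null matrices (each refit with the same
#' model).  Z tests are two-sided; significance is assigned by
#' Benjamini-Hochberg FDR at level `fdr_q` across the taxa of the level.
#'
#' @param M binary host-use matrix ([build_host_use_matrix()]); rownames
#'   must match the tips of `tree`.
#' @param tree rooted, time-scaled `ape::phylo` insect species tree.
#' @param n_null number of null matrices (default 1000; reduce for quick
#'   runs).
#' @param mcmc chain settings for the empirical fits (see [fit_signal()]).
#' @param null_mcmc chain settings for the null refits; defaults to `mcmc`
#'   (shorter chains here trade fidelity for runtime).
#' @param fdr_q false-discovery-rate level (default 0.05).
#' @param null_method `"checkerboard"` (conserves both marginals) or
#'   `"rowshuffle"` (conserves diet breadths only).
#' @param seed optional integer seed.
#' @return object of class `signal_test`: a results data.frame
#'   (`host_taxon`, `h2`, `null_mean`, `null_sd`, `z`, `p`,
#'   `fdr_significant`) plus the skipped columns and settings.
#' @export
signal_test <- function(M, tree, n_null = 1000,
                        mcmc = list(nitt = 13000, burnin = 3000, thin = 10),
                        null_mcmc = mcmc, fdr_q = 0.05,
                        null_method = c("checkerboard", "rowshuffle"),
                        seed = NULL) {
  null_method <- match.arg(null_method)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(rownames(M))) stop("M must have species rownames")
  if (!all(rownames(M) %in% tree$tip.label)) {
    stop("tree is missing species: ",
         paste(setdiff(rownames(M), tree$tip.label), collapse = ", "))
  }
  if (length(tree$tip.label) > nrow(M)) {
    tree <- ape::keep.tip(tree, rownames(M))
  }
  V <- phylo_vcv(tree)[rownames(M), rownames(M)]

  n_users <- colSums(M)
  eligible <- which(n_users >= 2 & (nrow(M) - n_users) >= 2)
  skipped <- colnames(M)[setdiff(seq_len(ncol(M)), eligible)]
  if (length(eligible) == 0) stop("no host taxon has >= 2 users and >= 2 non-users")

  emp_h2 <- vapply(eligible, function(j) {
    fit_signal(M[, j], V, mcmc = mcmc)$h2
  }, numeric(1))

  null_h2 <- matrix(NA_real_, nrow = n_null, ncol = length(eligible))
  for (b in seq_len(n_null)) {
    Mb <- if (null_method == "checkerboard") swap_null(M) else row_shuffle_null(M)
    null_h2[b, ] <- vapply(seq_along(eligible), function(jj) {
      fit_signal(Mb[, eligible[jj]], V, mcmc = null_mcmc)$h2
    }, numeric(1))
  }

  null_mean <- colMeans(null_h2)
  null_sd <- apply(null_h2, 2, sd)
  z <- (emp_h2 - null_mean) / null_sd
  p <- z_to_p(z)
  fdr_significant <- p.adjust(p, method = "BH") <= fdr_q

  results <- data.frame(
    host_taxon = colnames(M)[eligible],
    h2 = emp_h2,
    null_mean = null_mean,
    null_sd = null_sd,
    z = z,
    p = p,
    fdr_significant = fdr_significant,
    stringsAsFactors = FALSE
  )
  rownames(results) <- NULL
  structure(list(results = results, skipped = skipped, n_null = n_null,
                 fdr_q = fdr_q, null_method = null_method,
                 mcmc = mcmc, null_mcmc = null_mcmc),
            class = "signal_test")
}

#' @export
print.signal_test <- function(x, digits = 3, ...) {
  cat("Phylogenetic signal of host use (threshold model vs swap null)\n")
  cat(sprintf("  null: %s, %d matrices; FDR q = %g\n",
              x$null_method, x$n_null, x$fdr_q))
  if (length(x$skipped) > 0) {
    cat("  skipped (constant or near-constant columns):",
        paste(x$skipped, collapse = ", "), "\n")
  }
  print(format(x$results, digits = digits), row.names = FALSE)
  invisible(x)
}
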