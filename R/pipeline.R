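## Orchestration: run every analysis at every host-taxonomic level for every
## site in a link table, and write report tables shaped like the study's
## summary tables (specificity per site x level; abundance and occupancy
## slopes per site x level; per-taxon phylogenetic signal).

#' Run the full host-use specificity analysis
#'
#' Splits the link table by site and runs, per site and host-taxonomic
#' level: the diet-specificity permutation test ([specificity_test()]), the
#' abundance and occupancy trade-off tests ([tradeoff_test()]), and (for
#' the levels in `signal_levels`) the phylogenetic-signal test
#' ([signal_test()]).  Defaults mirror the study design: 1000 permutations,
#' swap count ten times the number of associations, FDR 0.05, minimum three
#' surveyed trees per host taxon.
#'
#' @param links a [link_table()] covering one or more sites.
#' @param census data.frame of all surveyed trees (see
#'   [build_occupancy_records()]).
#' @param species_trees named list of rooted insect species trees, one per
#'   site (tips = insect species ids); `NULL` skips the signal stage.
#' @param levels host-taxonomic levels to analyse.
#' @param signal_levels levels at which to run the (expensive) signal test;
#'   defaults to `levels`.
#' @param n_perm permutations for specificity and trade-off tests.
#' @param n_null null matrices for the signal test.
#' @param mcmc,null_mcmc chain settings for [signal_test()].
#' @param fdr_q FDR level for the signal test.
#' @param min_trees minimum surveyed trees per host taxon (occupancy).
#' @param seed integer seed; every stage draws a child seed from it, so a
#'   rerun with the same seed reproduces every table.
#' @param out_dir optional directory; when given, writes
#'   `specificity.tsv`, `tradeoff.tsv`, `signal.tsv` and `manifest.json`.
#' @return object of class `hostspec_run` with data.frames `specificity`,
#'   `tradeoff`, `signal`, and the run `manifest`.
#' @export
run_all <- function(links, census, species_trees = NULL,
                    levels = c("species", "genus", "family"),
                    signal_levels = levels,
                    n_perm = 1000, n_null = 1000,
                    mcmc = list(nitt = 13000, burnin = 3000, thin = 10),
                    null_mcmc = mcmc, fdr_q = 0.05, min_trees = 3,
                    seed = NULL, out_dir = NULL) {
  stopifnot(inherits(links, "link_table"))
  levels <- match.arg(levels, several.ok = TRUE)
  if (!is.null(seed)) set.seed(seed)
  t0 <- Sys.time()
  sites <- sort(unique(links$records$site))
  if (!is.null(species_trees) && !all(sites %in% names(species_trees))) {
    stop("species_trees must be a named list covering site(s): ",
         paste(sites, collapse = ", "))
  }

  spec_rows <- list()
  trade_rows <- list()
  signal_rows <- list()
  for (site in sites) {
    lt <- link_table(links$records[links$records$site == site, , drop = FALSE])
    site_census <- census[startsWith(census$tree_id, site) |
                            census$tree_id %in% lt$records$tree_id |
                            census$host_species %in% lt$records$host_species, ,
                          drop = FALSE]
    for (level in levels) {
      st <- specificity_test(lt, level, n_permutations = n_perm,
                             seed = child_seed())
      spec_rows[[length(spec_rows) + 1]] <- data.frame(
        location = site, level = level,
        empirical_rdi = st$empirical_mean_rdi, null_rdi = st$null_mean,
        z = st$z, p = st$p, stringsAsFactors = FALSE)

      tt <- tradeoff_test(lt, site_census, level, min_trees = min_trees,
                          n_perm = n_perm, seed = child_seed())
      trade_rows[[length(trade_rows) + 1]] <- data.frame(
        location = site, level = level,
        abundance_slope = tt$abundance$slope, abundance_z = tt$abundance$z,
        abundance_p = tt$abundance$p,
        occupancy_slope = tt$occupancy$slope, occupancy_z = tt$occupancy$z,
        occupancy_p = tt$occupancy$p, stringsAsFactors = FALSE)

      if (!is.null(species_trees) && level %in% signal_levels) {
        M <- build_host_use_matrix(lt, level)
        sg <- signal_test(M, species_trees[[site]], n_null = n_null,
                          mcmc = mcmc, null_mcmc = null_mcmc, fdr_q = fdr_q,
                          seed = child_seed())
        res <- sg$results
        res <- cbind(data.frame(location = site, level = level,
                                stringsAsFactors = FALSE), res)
        signal_rows[[length(signal_rows) + 1]] <- res
      }
    }
  }

  out <- structure(list(
    specificity = do.call(rbind, spec_rows),
    tradeoff = do.call(rbind, trade_rows),
    signal = if (length(signal_rows) > 0) do.call(rbind, signal_rows) else NULL,
    manifest = list(
      package = "hostspec",
      version = as.character(packageVersion("hostspec")),
      seed = seed,
      sites = sites,
      levels = levels,
      n_perm = n_perm,
      n_null = n_null,
      fdr_q = fdr_q,
      min_trees = min_trees,
      n_records = nrow(links$records),
      started = format(t0, "%Y-%m-%dT%H:%M:%S%z"),
      elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))
    )
  ), class = "hostspec_run")

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write.table(out$specificity, file.path(out_dir, "specificity.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(out$tradeoff, file.path(out_dir, "tradeoff.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(out$signal)) {
      write.table(out$signal, file.path(out_dir, "signal.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
    jsonlite::write_json(out$manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  out
}

#' @export
print.hostspec_run <- function(x, digits = 3, ...) {
  cat("hostspec analysis run (seed", x$manifest$seed %||% "unset", ")\n\n")
  cat("Diet specificity (mean Simpson's 1/D vs permutation null):\n")
  print(format(x$specificity, digits = digits), row.names = FALSE)
  cat("\nDiet-breadth trade-offs (GLM slopes vs permutation null):\n")
  print(format(x$tradeoff, digits = digits), row.names = FALSE)
  if (!is.null(x$signal)) {
    cat("\nPhylogenetic signal of host use:\n")
    print(format(x$signal, digits = digits), row.names = FALSE)
  }
  invisible(x)
}

#' Percentage of identifiable specimens that belong to invasive species
#'
#' @param specimens data.frame with columns `morph_species` (label or `NA`
#'   when the specimen could not be identified morphologically) and
#'   `invasive` (logical flag).
#' @return integer percentage, `round(100 * invasive / identifiable)`.
#' @examples
#' df <- data.frame(morph_species = rep(c("a", "b"), c(77, 103)),
#'                  invasive = rep(c(TRUE, FALSE), c(77, 103)))
#' summarize_invasive_fraction(df)  # 43
#' @export
summarize_invasive_fraction <- function(specimens) {
  stopifnot(all(c("morph_species", "invasive") %in% names(specimens)))
  identifiable <- !is.na(specimens$morph_species) & specimens$morph_species != ""
  if (!any(identifiable)) stop("no morphologically identifiable specimens")
  round(100 * sum(specimens$invasive[identifiable]) / sum(identifiable))
}
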