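## Occurrence link table: the central bipartite data structure.  One row per
## (site, tree, insect species, life stage); trees carry a three-level host
## taxonomy (species, genus, family).

LINK_COLS <- c("site", "tree_id", "host_species", "host_genus", "host_family",
               "insect_species", "life_stage", "count")
LIFE_STAGES <- c("first_instar", "second_instar", "adult_female", "other")
ESTABLISHED_STAGES <- c("second_instar", "adult_female")
TAXON_LEVELS <- c("species", "genus", "family")

#' Construct a validated occurrence link table
#'
#' A link table records which insect species occur on which individual host
#' trees, with counts per life stage.  Only second instars and adult females
#' are evidence of successful establishment (a settled diaspidid cannot move,
#' so later life stages prove the tree is a suitable host); the establishment
#' view that all downstream statistics use is restricted to those stages.
#'
#' @param records data.frame with columns `site`, `tree_id`, `host_species`,
#'   `host_genus`, `host_family`, `insect_species`, `life_stage`
#'   (`first_instar`, `second_instar`, `adult_female`, or `other`) and
#'   `count` (nonnegative integer).  Duplicate rows (same site, tree, insect
#'   species and life stage) have their counts summed.
#' @return an object of class `link_table`: a list with elements `records`
#'   (the validated table) and `establishment` (the rows with life stage
#'   `second_instar` or `adult_female` and count >= 1).
#' @seealso [read_link_table()], [establishment_view()]
#' @export
link_table <- function(records) {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  missing_cols <- setdiff(LINK_COLS, names(records))
  if (length(missing_cols) > 0) {
    stop("link table is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  records <- records[, LINK_COLS]
  for (col in setdiff(LINK_COLS, "count")) {
    records[[col]] <- as.character(records[[col]])
  }
  records$count <- suppressWarnings(as.numeric(records$count))

  bad <- which(is.na(records$count) | records$count < 0 |
                 records$count != floor(records$count))
  if (length(bad) > 0) {
    stop("count must be a nonnegative integer; offending ", row_label(records, bad[1]))
  }
  bad <- which(!records$life_stage %in% LIFE_STAGES)
  if (length(bad) > 0) {
    stop("life_stage must be one of ", paste(LIFE_STAGES, collapse = ", "),
         "; offending ", row_label(records, bad[1]))
  }

  ## each tree maps to exactly one host taxonomy triple
  tax <- unique(records[, c("tree_id", "host_species", "host_genus", "host_family")])
  dup_tree <- tax$tree_id[duplicated(tax$tree_id)]
  if (length(dup_tree) > 0) {
    stop("tree_id '", dup_tree[1], "' is recorded with more than one host taxonomy")
  }
  ## host taxonomy is hierarchical
  sp2gen <- unique(tax[, c("host_species", "host_genus")])
  dup_sp <- sp2gen$host_species[duplicated(sp2gen$host_species)]
  if (length(dup_sp) > 0) {
    stop("host_species '", dup_sp[1], "' maps to more than one genus")
  }
  gen2fam <- unique(tax[, c("host_genus", "host_family")])
  dup_gen <- gen2fam$host_genus[duplicated(gen2fam$host_genus)]
  if (length(dup_gen) > 0) {
    stop("host_genus '", dup_gen[1], "' maps to more than one family")
  }

  ## aggregate duplicate (site, tree, insect, stage) rows by summing counts
  key <- do.call(paste, c(records[, c("site", "tree_id", "insect_species",
                                      "life_stage")], sep = "\r"))
  if (anyDuplicated(key)) {
    agg <- rowsum(records$count, key, reorder = FALSE)
    first <- !duplicated(key)
    records <- records[first, , drop = FALSE]
    records$count <- as.numeric(agg[match(key[first], rownames(agg)), 1])
  }
  rownames(records) <- NULL

  est <- records[records$life_stage %in% ESTABLISHED_STAGES & records$count >= 1, ,
                 drop = FALSE]
  rownames(est) <- NULL
  structure(list(records = records, establishment = est), class = "link_table")
}

#' Read an occurrence link table from a tab-delimited file
#'
#' @param path path to a UTF-8, tab-delimited file with a header row naming
#'   the seven link-table columns plus `count` (see [link_table()]).
#' @return a validated `link_table`.
#' @export
read_link_table <- function(path) {
  df <- read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                   colClasses = "character", fileEncoding = "UTF-8")
  link_table(df)
}

#' Write a link table to a tab-delimited file
#'
#' @param lt a `link_table`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_link_table <- function(lt, path) {
  stopifnot(inherits(lt, "link_table"))
  write.table(lt$records, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}

#' Establishment view of a link table
#'
#' Returns the records restricted to life stages that evidence successful
#' establishment (second instars and adult females).
#'
#' @param lt a `link_table`.
#' @return data.frame of establishment records.
#' @export
establishment_view <- function(lt) {
  stopifnot(inherits(lt, "link_table"))
  lt$establishment
}

#' Host taxonomy lookup for the trees of a link table
#'
#' @param lt a `link_table`.
#' @param level one of `"species"`, `"genus"`, `"family"`.
#' @return named character vector mapping `tree_id` to the host taxon label
#'   at the requested level.
#' @export
host_taxonomy <- function(lt, level = c("species", "genus", "family")) {
  stopifnot(inherits(lt, "link_table"))
  level <- match.arg(level)
  tax <- unique(lt$records[, c("tree_id", "host_species", "host_genus", "host_family")])
  out <- tax[[paste0("host_", level)]]
  names(out) <- tax$tree_id
  out
}

#' @export
print.link_table <- function(x, ...) {
  est <- x$establishment
  cat("Occurrence link table\n")
  cat("  records:           ", nrow(x$records), "\n")
  cat("  establishment rows:", nrow(est), "\n")
  cat("  sites:             ", paste(unique(x$records$site), collapse = ", "), "\n")
  cat("  trees:             ", length(unique(x$records$tree_id)), "\n")
  cat("  insect species:    ", length(unique(x$records$insect_species)), "\n")
  invisible(x)
}

## internal: distinct establishment links (one row per insect-species-by-tree
## association), with host taxon attached at the requested level
establishment_links <- function(lt, level) {
  est <- establishment_view(lt)
  if (nrow(est) == 0) stop("establishment view is empty")
  links <- unique(est[, c("insect_species", "tree_id")])
  tax <- host_taxonomy(lt, level)
  links$taxon <- unname(tax[links$tree_id])
  rownames(links) <- NULL
  links
}
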