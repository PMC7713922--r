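## Multiple sequence alignments as character matrices (rows = specimens,
## columns = sites).  Characters are upper-case A/C/G/T, gap "-", missing "N"
## or IUPAC ambiguity codes.  For trimming and distance computation only
## unambiguous A/C/G/T characters are informative; gaps, N and ambiguity
## codes all count as missing (conservative divergence).

INFORMATIVE_BASES <- c("A", "C", "G", "T")

#' Construct an alignment object
#'
#' @param x character matrix of single characters with unique rownames
#'   (specimen ids); all rows must have equal length.  Lower case is folded
#'   to upper case and RNA `U` is mapped to `T`.
#' @return a character matrix of class `c("dna_alignment", "matrix")`.
#' @export
alignment <- function(x) {
  if (!is.matrix(x) || !is.character(x)) stop("alignment must be a character matrix")
  if (is.null(rownames(x)) || anyDuplicated(rownames(x))) {
    stop("alignment rows must have unique specimen ids")
  }
  x[] <- toupper(x)
  x[x == "U"] <- "T"
  x[x == "." | x == "?"] <- "N"
  class(x) <- c("dna_alignment", class(matrix()))
  x
}

#' Read a FASTA alignment
#'
#' Sequences must all have the same length.  Character normalization: case
#' folded to upper, `U` mapped to `T`; IUPAC ambiguity codes are retained.
#'
#' @param path path to an (uncompressed) FASTA file.
#' @return an [alignment()] matrix.
#' @export
read_fasta <- function(path) {
  seqs <- seqinr::read.fasta(path, seqtype = "DNA", forceDNAtolower = FALSE,
                             set.attributes = FALSE)
  if (length(seqs) == 0) stop("no sequences in ", path)
  if (anyDuplicated(names(seqs))) {
    stop("duplicate sequence id in ", path, ": ",
         names(seqs)[duplicated(names(seqs))][1])
  }
  lens <- lengths(seqs)
  if (length(unique(lens)) != 1) {
    stop("sequences in ", path, " are not aligned (unequal lengths)")
  }
  chars <- do.call(rbind, seqs)
  rownames(chars) <- names(seqs)
  alignment(chars)
}

#' Write an alignment to FASTA
#'
#' @param aln an [alignment()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(aln, path) {
  stopifnot(inherits(aln, "dna_alignment"))
  lines <- character(2 * nrow(aln))
  lines[c(TRUE, FALSE)] <- paste0(">", rownames(aln))
  lines[c(FALSE, TRUE)] <- apply(aln, 1, paste, collapse = "")
  writeLines(lines, path)
  invisible(path)
}

#' Trim alignment columns by non-gap occupancy
#'
#' Keeps exactly the columns in which the fraction of specimens with an
#' unambiguous nucleotide (A/C/G/T; gaps, N and ambiguity codes count as
#' missing) is at least `min_nongap_fraction`.  Column order is preserved.
#' The default retains sites with non-gap sequence for at least 80% of
#' specimens, the standard occupancy rule applied before concatenation.
#'
#' @param aln an [alignment()].
#' @param min_nongap_fraction minimum fraction of informative characters per
#'   column, in (0, 1]; the boundary is kept (`>=`).
#' @return the trimmed [alignment()].
#' @export
trim_alignment <- function(aln, min_nongap_fraction = 0.8) {
  stopifnot(inherits(aln, "dna_alignment"))
  if (nrow(aln) == 0 || ncol(aln) == 0) stop("cannot trim an empty alignment")
  if (!(min_nongap_fraction > 0 && min_nongap_fraction <= 1)) {
    stop("min_nongap_fraction must be in (0, 1]")
  }
  frac <- colMeans(matrix(aln %in% INFORMATIVE_BASES, nrow = nrow(aln)))
  keep <- frac >= min_nongap_fraction
  out <- aln[, keep, drop = FALSE]
  alignment(out)
}

#' Concatenate per-locus alignments into a supermatrix
#'
#' The specimen set of the supermatrix is the union of the per-locus specimen
#' sets (in order of first appearance); a specimen missing from a locus gets
#' an all-gap segment for that locus, which is how missing loci are encoded
#' (a specimen absent from a gene tree is simply absent from that locus's
#' alignment).
#'
#' @param alns list of [alignment()] objects, optionally named by locus.
#' @return list with elements `alignment` (the supermatrix) and `partitions`
#'   (data.frame `locus`, `start`, `end` of 1-based inclusive column ranges).
#' @export
concatenate_supermatrix <- function(alns) {
  if (!is.list(alns) || length(alns) < 1) stop("need at least one alignment")
  lapply(alns, function(a) stopifnot(inherits(a, "dna_alignment")))
  loci <- names(alns)
  if (is.null(loci)) loci <- paste0("locus", seq_along(alns))
  ids <- unique(unlist(lapply(alns, rownames)))
  widths <- vapply(alns, ncol, integer(1))
  ends <- cumsum(widths)
  starts <- c(1L, head(ends, -1) + 1L)
  out <- matrix("-", nrow = length(ids), ncol = sum(widths),
                dimnames = list(ids, NULL))
  for (k in seq_along(alns)) {
    out[rownames(alns[[k]]), starts[k]:ends[k]] <- alns[[k]]
  }
  list(alignment = alignment(out),
       partitions = data.frame(locus = loci, start = starts, end = ends,
                               stringsAsFactors = FALSE))
}

#' Uncorrected pairwise distances from an alignment
#'
#' `d(i, j)` is the proportion of mismatches among comparable sites, i.e.
#' columns where both specimens have an unambiguous A/C/G/T.  Pairs with no
#' comparable sites get `NA` (flagged, never silently zero).
#'
#' @param aln an [alignment()] (typically the trimmed supermatrix).
#' @return symmetric numeric matrix with zero diagonal; dimnames are the
#'   specimen ids.  All-missing specimens trigger a warning and yield `NA`
#'   rows.
#' @export
p_distance <- function(aln) {
  stopifnot(inherits(aln, "dna_alignment"))
  n <- nrow(aln)
  informative <- matrix(aln %in% INFORMATIVE_BASES, nrow = n,
                        dimnames = dimnames(aln))
  empty <- rowSums(informative) == 0
  if (any(empty)) {
    warning("specimen(s) with no informative sites: ",
            paste(rownames(aln)[empty], collapse = ", "))
  }
  comparable <- informative %*% t(informative)
  matches <- matrix(0, n, n)
  for (b in INFORMATIVE_BASES) {
    hit <- matrix(aln == b, nrow = n) & informative
    matches <- matches + hit %*% t(hit)
  }
  d <- 1 - matches / comparable  # NaN where comparable == 0
  d[comparable == 0] <- NA_real_
  diag(d) <- ifelse(rowSums(informative) > 0, 0, NA_real_)
  dimnames(d) <- list(rownames(aln), rownames(aln))
  d
}

#' Write a distance matrix as a PHYLIP-style square TSV
#'
#' @param d symmetric numeric matrix with specimen ids as dimnames.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_distance_matrix <- function(d, path) {
  stopifnot(is.matrix(d), !is.null(rownames(d)))
  df <- data.frame(id = rownames(d), d, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
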