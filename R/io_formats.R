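#' Read sequences from a FASTA file into the RNA alphabet
#'
#' Parses a (possibly line-wrapped) FASTA file and returns the records in
#' file order as a named character vector of uppercase RNA-alphabet
#' sequences. DNA input is converted silently (T becomes U); `N` is kept and
#' never matches or pairs downstream. Gap characters are rejected unless
#' `allow_gaps = TRUE` (used for aligned multi-FASTA input).
#'
#' @param path path to a FASTA file.
#' @param allow_gaps logical; permit `-` characters (aligned FASTA).
#' @return named character vector (names are record ids, possibly empty for
#'   an empty file), residues over `A,C,G,U,N` (plus `-` if allowed).
#' @export
read_fasta <- function(path, allow_gaps = FALSE) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  seqs <- toupper(as.character(set))
  seqs <- chartr("T", "U", seqs)
  alphabet <- if (allow_gaps) "ACGUN-" else "ACGUN"
  bad <- regexpr(sprintf("[^%s]", alphabet), seqs)
  if (any(bad > 0)) {
    i <- which(bad > 0)[1]
    stop(sprintf("illegal residue '%s' in record '%s' at position %d",
                 substr(seqs[i], bad[i], bad[i]), ids[i], bad[i]))
  }
  stats::setNames(seqs, ids)
}

#' Write sequences to a FASTA file
#'
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @param width line-wrap width.
#' @export
write_fasta <- function(seqs, path, width = 70) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    cat(">", names(seqs)[i], "\n", sep = "", file = con)
    s <- seqs[[i]]
    if (nchar(s) == 0) next
    starts <- seq(1, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1, nchar(s))), con)
  }
  invisible(path)
}

#' Read a phylogenetic tree from newick text or file
#'
#' The tree must carry branch lengths on every non-root branch; leaf labels
#' must be unique and there must be at least two leaves.
#'
#' @param text newick string, or `NULL` if `path` is given.
#' @param path optional path to a newick file.
#' @return an [ape::read.tree] `phylo` object.
#' @export
read_newick <- function(text = NULL, path = NULL) {
  if (is.null(text)) text <- paste(readLines(path, warn = FALSE), collapse = "")
  if (!grepl(";\\s*$", text)) text <- paste0(text, ";")
  n_open <- lengths(regmatches(text, gregexpr("(", text, fixed = TRUE)))
  n_close <- lengths(regmatches(text, gregexpr(")", text, fixed = TRUE)))
  if (n_open != n_close) stop("unbalanced parentheses in newick input")
  tree <- tryCatch(
    suppressWarnings(ape::read.tree(text = text)),
    error = function(e) NULL)
  if (is.null(tree)) stop("could not parse newick input")
  if (is.null(tree$edge.length) || anyNA(tree$edge.length) ||
      length(tree$edge.length) != nrow(tree$edge)) {
    stop("newick input is missing branch lengths")
  }
  if (any(tree$edge.length < 0)) stop("negative branch length in newick input")
  if (length(tree$tip.label) < 2) stop("tree must have at least 2 leaves")
  if (anyDuplicated(tree$tip.label)) stop("duplicate leaf labels in tree")
  tree
}

#' Write a tree as newick text
#'
#' @param tree a `phylo` object.
#' @param path optional output path; if `NULL` the newick string is returned.
#' @export
write_newick <- function(tree, path = NULL) {
  txt <- ape::write.tree(tree)
  if (!is.null(path)) { writeLines(txt, path); invisible(path) } else txt
}

#' Read an orthologous UTR alignment from aligned multi-FASTA
#'
#' @param path aligned multi-FASTA; all rows must have equal length.
#' @param ref_species name of the reference species (must be a row).
#' @return a `species_alignment`: list with `rows` (named character vector,
#'   gapped RNA) and `ref_species`.
#' @export
read_alignment <- function(path, ref_species) {
  rows <- read_fasta(path, allow_gaps = TRUE)
  species_alignment(rows, ref_species)
}

#' Construct a species alignment object
#'
#' @param rows named character vector of equal-length gapped sequences.
#' @param ref_species reference species name, present in `rows`.
#' @export
species_alignment <- function(rows, ref_species) {
  if (length(rows) == 0) stop("alignment has no rows")
  if (length(unique(nchar(rows))) != 1) stop("alignment rows differ in length")
  if (!ref_species %in% names(rows)) {
    stop("reference species '", ref_species, "' not in alignment")
  }
  structure(list(rows = rows, ref_species = ref_species),
            class = "species_alignment")
}

#' Ungapped reference sequence of an alignment
#' @param aln a `species_alignment`.
#' @export
alignment_ref_seq <- function(aln) {
  gsub("-", "", aln$rows[[aln$ref_species]], fixed = TRUE)
}

#' Write target sites as BED6
#'
#' One line per site in input order: chrom = UTR id, chromStart/chromEnd =
#' 0-based half-open site coordinates on the UTR, name = `miRNA|site_type`,
#' score = percentile scaled to 0-1000 (0 if unset), strand = `+`.
#' Coordinates are UTR-local; no genome liftover is attempted.
#'
#' @param sites data.frame with columns `utr_id, mirna, start, end,
#'   site_type` and optionally `percentile` (0-100).
#' @param path output path.
#' @export
write_bed <- function(sites, path) {
  con <- file(path, "w")
  on.exit(close(con))
  if (nrow(sites) > 0) {
    score <- if ("percentile" %in% names(sites)) {
      as.integer(round(sites$percentile * 10))
    } else rep(0L, nrow(sites))
    lines <- sprintf("%s\t%d\t%d\t%s|%s\t%d\t+",
                     sites$utr_id, sites$start, sites$end,
                     sites$mirna, sites$site_type, score)
    writeLines(lines, con)
  }
  invisible(path)
}

#' Write a feature report as CSV
#'
#' Writes an RFC-4180 CSV (header row, quoted where needed). All rows must
#' share one column set.
#'
#' @param rows data.frame of report rows.
#' @param path output path.
#' @export
write_csv_report <- function(rows, path) {
  utils::write.csv(rows, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

read_tsv_table <- function(path) {
  tryCatch(
    utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE),
    error = function(e) stop("malformed TSV '", path, "': ", conditionMessage(e)))
}
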