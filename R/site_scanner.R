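# Seed-match scanning and site-type classification.
#
# The miRNA binds the UTR antiparallel, so miRNA position 1 (5' end) faces
# the 3'-most residue of the site on the UTR. Site types follow the
# canonical taxonomy: 6mer (match to seed 2-7), 7mer-A1 (6mer + literal A
# opposite position 1), 7mer-m8 (match through position 8), 8mer (both).
# Only exact Watson-Crick seed matches count: no G:U wobble, no mismatch.

SITE_TYPES <- c("6mer", "7mer-A1", "7mer-m8", "8mer")

#' Extract the seed of a miRNA
#'
#' Positions are 1-based from the miRNA 5' end; the seed is positions 2-7
#' (6 nt) or 2-8 (7 nt).
#'
#' @param mirna miRNA sequence, 5' to 3', RNA alphabet, length >= 8.
#' @param span `"2-7"` or `"2-8"`.
#' @return the seed subsequence.
#' @export
seed_of <- function(mirna, span = c("2-7", "2-8")) {
  span <- match.arg(span)
  if (nchar(mirna) < 8) {
    stop("miRNA must be at least 8 nt (got ", nchar(mirna), ")")
  }
  if (grepl("[^ACGU]", mirna)) stop("miRNA must be over the {A,C,G,U} alphabet")
  substr(mirna, 2, if (span == "2-7") 7 else 8)
}

#' The UTR-side match string of a seed
#'
#' Reverse complement of the seed, i.e. the exact subsequence a UTR must
#' contain (read 5' to 3') to pair with it.
#'
#' @inheritParams seed_of
#' @export
seed_match <- function(mirna, span = c("2-7", "2-8")) {
  rna_revcomp(seed_of(mirna, span))
}

# all 0-based start positions of exact (overlapping) occurrences of motif
str_find_all <- function(seq, motif) {
  L <- nchar(seq); k <- nchar(motif)
  if (L < k || k == 0) return(integer(0))
  starts <- 1:(L - k + 1)
  which(substring(seq, starts, starts + k - 1) == motif) - 1L
}

#' Find and classify seed-match sites of a miRNA in a UTR
#'
#' Scans for exact matches of the reverse complement of the seed. A window
#' matching seed 2-8 is a 7mer-m8, upgraded to 8mer when the UTR residue
#' opposite miRNA position 1 (the next residue 3' on the UTR) is a literal
#' A. A window matching only seed 2-7 is a 6mer, upgraded to 7mer-A1 by the
#' same A rule. Each match is reported once with its maximal class;
#' coordinates (0-based, half-open) cover the matched region including the
#' A of the A1 types. Overlapping sites are all reported.
#'
#' @param utr UTR sequence (RNA alphabet, may contain N).
#' @param mirna miRNA sequence, 5' to 3'.
#' @param utr_id,mirna_name identifiers used in the output.
#' @return data.frame with columns `utr_id, mirna, start, end, site_type`,
#'   ordered by `start`.
#' @export
find_sites <- function(utr, mirna, utr_id = "utr", mirna_name = "mirna") {
  m6 <- seed_match(mirna, "2-7")       # pairs miRNA 2-7
  m8c <- rna_comp(substr(mirna, 8, 8)) # UTR residue opposite miRNA position 8
  L <- nchar(utr)
  hits <- str_find_all(utr, m6)
  if (length(hits) == 0) {
    return(empty_sites())
  }
  rows <- lapply(hits, function(s) {
    # s is the 0-based start of the 6-nt match to seed 2-7; the residue
    # opposite position 8 sits immediately 5' (index s-1), the residue
    # opposite position 1 immediately 3' (index s+6).
    has_m8 <- s >= 1 && substr(utr, s, s) == m8c
    has_a1 <- (s + 6) < L && substr(utr, s + 7, s + 7) == "A"
    if (has_m8 && has_a1) {
      list(start = s - 1L, end = s + 7L, site_type = "8mer")
    } else if (has_m8) {
      list(start = s - 1L, end = s + 6L, site_type = "7mer-m8")
    } else if (has_a1) {
      list(start = s, end = s + 7L, site_type = "7mer-A1")
    } else {
      list(start = s, end = s + 6L, site_type = "6mer")
    }
  })
  out <- data.frame(
    utr_id = utr_id, mirna = mirna_name,
    start = vapply(rows, function(r) as.integer(r$start), integer(1)),
    end = vapply(rows, function(r) as.integer(r$end), integer(1)),
    site_type = vapply(rows, function(r) r$site_type, character(1)),
    stringsAsFactors = FALSE)
  out[order(out$start), , drop = FALSE]
}

empty_sites <- function() {
  data.frame(utr_id = character(0), mirna = character(0),
             start = integer(0), end = integer(0),
             site_type = character(0), stringsAsFactors = FALSE)
}

#' Count seed matches of a miRNA in a UTR
#'
#' Overlapping occurrences are all counted. This is the observed count `n`
#' used by the over-representation features.
#'
#' @inheritParams find_sites
#' @param span seed span used for matching, `"2-8"` (default) or `"2-7"`.
#' @export
count_seed_matches <- function(utr, mirna, span = c("2-8", "2-7")) {
  span <- match.arg(span)
  length(str_find_all(utr, seed_match(mirna, span)))
}
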