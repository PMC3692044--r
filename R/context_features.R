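# Sequence-context features of a site: AU content of the flanks, distance
# to the nearest UTR end, and 3' supplementary pairing of the miRNA.
# The weights (1/(i+1) flank decay, the position 13-16 bonus, the 0.5 per
# nt offset penalty) are this package's committed interpretation of the
# context-score lineage and are collected here for easy revision.

CONTEXT_AU_WINDOW <- 30L
CONTEXT_POSITION_CAP <- 1500L
CONTEXT_3P_REGION <- 15L
CONTEXT_3P_BONUS_RANGE <- 13:16
CONTEXT_3P_BONUS <- 1.0
CONTEXT_3P_BASE <- 0.5
CONTEXT_3P_OFFSET_PENALTY <- 0.5
CONTEXT_3P_MAX_OFFSET <- 6L

#' Weighted AU content around a site
#'
#' Over up to `window` nt on each side of the site, the position at
#' distance `i` from the site edge (i = 1 adjacent) carries weight
#' `1/(i+1)`; the value is the weight sum of A/U positions divided by the
#' weight sum of all available positions. Positions beyond the UTR ends are
#' excluded from both sums.
#'
#' @param utr UTR sequence.
#' @param site a site on the UTR.
#' @param window flank width, nt.
#' @return fraction in `[0, 1]`.
#' @export
au_content <- function(utr, site, window = CONTEXT_AU_WINDOW) {
  L <- nchar(utr)
  chars <- strsplit(utr, "", fixed = TRUE)[[1]]
  wsum <- 0; asum <- 0
  for (i in seq_len(window)) {
    w <- 1 / (i + 1)
    up <- site$start - i + 1L      # 1-based index of upstream position i
    if (up >= 1) {
      wsum <- wsum + w
      if (chars[up] %in% c("A", "U")) asum <- asum + w
    }
    dn <- site$end + i             # 1-based index of downstream position i
    if (dn <= L) {
      wsum <- wsum + w
      if (chars[dn] %in% c("A", "U")) asum <- asum + w
    }
  }
  if (wsum == 0) {
    warning("site has no available flank; AU content set to 0")
    return(0)
  }
  asum / wsum
}

#' Distance of a site to the nearest UTR end
#'
#' Minimum of the distances from the site midpoint to the 5' and 3' UTR
#' ends, capped. Sites close to a UTR end tend to be more repressive, so
#' smaller values mean stronger predicted repression.
#'
#' @inheritParams au_content
#' @param cap maximum reported distance, nt.
#' @return distance in nt, in `[0, cap]`.
#' @export
utr_position <- function(utr, site, cap = CONTEXT_POSITION_CAP) {
  L <- nchar(utr)
  mid <- (site$start + site$end) / 2
  min(mid, L - mid, cap)
}

#' 3' supplementary pairing score
#'
#' Searches the 15-nt UTR region immediately 5' of the seed-paired region
#' for the best run of contiguous Watson-Crick pairs with miRNA positions 9
#' to the 3' end, over register offsets up to `max_offset`. Each paired
#' miRNA position in 13-16 scores 1.0, other positions 0.5, minus 0.5 per
#' nt of offset; the best run score is returned, floored at 0.
#'
#' @inheritParams au_content
#' @param mirna miRNA sequence, 5' to 3'.
#' @param max_offset largest register displacement considered.
#' @return score >= 0.
#' @export
three_prime_pairing <- function(mirna, utr, site,
                                max_offset = CONTEXT_3P_MAX_OFFSET) {
  mlen <- nchar(mirna)
  if (mlen <= 8) return(0)
  mir <- strsplit(mirna, "", fixed = TRUE)[[1]]
  uc <- strsplit(utr, "", fixed = TRUE)[[1]]
  # 0-based position opposite miRNA position 8 in the unshifted register
  seed8 <- if (site$site_type %in% c("7mer-m8", "8mer")) site$start
           else site$start - 1L
  wc <- function(a, b) {
    (a == "A" && b == "U") || (a == "U" && b == "A") ||
    (a == "C" && b == "G") || (a == "G" && b == "C")
  }
  n3p <- min(CONTEXT_3P_REGION, mlen - 8L)
  best <- 0
  for (off in -max_offset:max_offset) {
    paired <- logical(n3p)
    for (t in seq_len(n3p)) {              # miRNA position 8 + t
      u <- seed8 - t + off                 # 0-based UTR index
      if (u >= 0 && u < length(uc)) {
        paired[t] <- wc(mir[8 + t], uc[u + 1])
      }
    }
    # score maximal contiguous runs
    r <- rle(paired)
    ends <- cumsum(r$lengths)
    for (ri in seq_along(r$values)) {
      if (!r$values[ri]) next
      ts <- (ends[ri] - r$lengths[ri] + 1):ends[ri]
      sc <- sum(ifelse((8 + ts) %in% CONTEXT_3P_BONUS_RANGE,
                       CONTEXT_3P_BONUS, CONTEXT_3P_BASE)) -
        CONTEXT_3P_OFFSET_PENALTY * abs(off)
      if (sc > best) best <- sc
    }
  }
  max(0, best)
}
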