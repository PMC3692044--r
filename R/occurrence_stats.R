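# Over-representation of seed matches: probability of seeing at least the
# observed number of motif occurrences in a UTR-length sequence under an
# order-1 Markov model of the UTR composition. Occurrences are counted with
# overlaps ("AAA" contains two "AA").

#' Construct an order-1 Markov model
#'
#' @param initial probability vector over A,C,G,U (sums to 1).
#' @param transition 4x4 row-stochastic matrix, rows/cols in A,C,G,U order.
#' @export
markov_model <- function(initial, transition) {
  initial <- as.numeric(initial)
  transition <- as.matrix(transition)
  stopifnot(length(initial) == 4, all(dim(transition) == c(4, 4)))
  if (any(initial < 0) || any(transition < 0)) {
    stop("Markov model entries must be nonnegative")
  }
  if (abs(sum(initial) - 1) > 1e-9) stop("initial must sum to 1")
  if (any(abs(rowSums(transition) - 1) > 1e-9)) {
    stop("transition rows must sum to 1")
  }
  dimnames(transition) <- list(RNA_BASES, RNA_BASES)
  structure(list(initial = stats::setNames(initial, RNA_BASES),
                 transition = transition),
            class = "markov_model")
}

#' Fit an order-1 Markov model to a sequence
#'
#' The transition matrix is the row-normalized dinucleotide count matrix
#' and the initial distribution the mononucleotide frequencies. `N`
#' positions are excised before fitting. A nucleotide never observed as a
#' transition source gets a uniform row.
#'
#' @param seq RNA string (may contain N).
#' @export
fit_markov <- function(seq) {
  v <- seq_to_int(seq)
  v <- v[v > 0L]
  if (length(v) < 2) stop("need at least 2 non-N residues to fit")
  initial <- tabulate(v, 4) / length(v)
  counts <- matrix(0, 4, 4)
  pairs <- cbind(v[-length(v)], v[-1])
  for (r in seq_len(nrow(pairs))) {
    counts[pairs[r, 1], pairs[r, 2]] <- counts[pairs[r, 1], pairs[r, 2]] + 1
  }
  rs <- rowSums(counts)
  trans <- counts / ifelse(rs == 0, 1, rs)
  trans[rs == 0, ] <- 0.25
  markov_model(initial, trans)
}

#' Probability of a motif under a Markov model
#'
#' `initial(m1) * prod(transition(m_i -> m_{i+1}))`: the chance that the
#' chain emits exactly the motif in its first `k` steps.
#'
#' @param model a [markov_model()].
#' @param motif RNA string, no N.
#' @export
motif_prob <- function(model, motif) {
  m <- seq_to_int(motif)
  if (length(m) == 0 || any(m == 0)) stop("motif must be nonempty, N-free")
  p <- model$initial[m[1]]
  if (length(m) > 1) {
    p <- p * prod(model$transition[cbind(m[-length(m)], m[-1])])
  }
  unname(p)
}

#' Binomial over-representation probability
#'
#' P(X >= n) with X ~ Binomial(L - k + 1, motif_prob): the binomial
#' approximation that treats the L - k + 1 windows as independent trials.
#'
#' @param model a [markov_model()].
#' @param motif RNA string of length k.
#' @param L sequence length, nt (>= k).
#' @param n observed occurrence count (>= 0).
#' @export
pover_binomial <- function(model, motif, L, n) {
  if (n < 0) stop("n must be >= 0")
  k <- nchar(motif)
  if (L < k) stop("L must be >= motif length")
  if (n == 0) return(1.0)
  stats::pbinom(n - 1, L - k + 1, motif_prob(model, motif),
                lower.tail = FALSE)
}

# KMP-style matching automaton: delta[(s+1), c] = next state after reading
# character c in state s (s = length of the longest motif prefix that is a
# suffix of the text). Reaching state k is an occurrence; transitions out
# of k continue from its failure state, so overlapping occurrences count.
match_automaton <- function(motif_int) {
  k <- length(motif_int)
  delta <- matrix(0L, k + 1, 4)
  delta[1, motif_int[1]] <- 1L
  X <- 0L
  for (s in 1:k) {
    delta[s + 1, ] <- delta[X + 1, ]
    if (s < k) {
      delta[s + 1, motif_int[s + 1]] <- s + 1L
      X <- delta[X + 1, motif_int[s + 1]]
    }
  }
  delta
}

# Distribution propagation over (automaton state, previous nucleotide,
# occurrence-count bucket). Buckets 0..nmax-1 are exact counts; mass that
# reaches nmax is absorbed in `done` (counts >= nmax). Returns the vector
# P(count = 0), ..., P(count = nmax - 1), P(count >= nmax).
count_distribution <- function(model, motif, L, nmax) {
  m <- seq_to_int(motif)
  if (length(m) == 0 || any(m == 0)) stop("motif must be nonempty, N-free")
  k <- length(m)
  if (nmax == 0) return(1.0)
  delta <- match_automaton(m)
  # states: 1..4 = (prefix 0, last char c); 4+s = prefix s (last char known)
  n_states <- 4L + k
  last_char <- c(1:4, m)
  to <- matrix(0L, n_states, 4)
  hit <- matrix(FALSE, n_states, 4)
  pr <- matrix(0, n_states, 4)
  s_of <- c(rep(0L, 4), 1:k)
  for (st in 1:n_states) {
    for (c in 1:4) {
      s2 <- delta[s_of[st] + 1, c]
      to[st, c] <- if (s2 == 0L) c else 4L + s2
      hit[st, c] <- s2 == k
      pr[st, c] <- model$transition[last_char[st], c]
    }
  }
  # live[st, bucket] for buckets 1..nmax (counts 0..nmax-1); done = P(>= nmax)
  live <- matrix(0, n_states, nmax)
  done <- 0
  for (c in 1:4) {
    s2 <- delta[1, c]
    st <- if (s2 == 0L) c else 4L + s2
    b <- if (s2 == k) 2L else 1L
    if (b > nmax) done <- done + model$initial[c]
    else live[st, b] <- live[st, b] + model$initial[c]
  }
  steps <- L - 1L
  if (steps > 0) {
    for (t in seq_len(steps)) {
      nxt <- matrix(0, n_states, nmax)
      for (st in 1:n_states) {
        for (c in 1:4) {
          w <- pr[st, c]
          if (w == 0) next
          st2 <- to[st, c]
          if (hit[st, c]) {
            if (nmax > 1) {
              nxt[st2, 2:nmax] <- nxt[st2, 2:nmax] + w * live[st, 1:(nmax - 1)]
            }
            done <- done + w * live[st, nmax]
          } else {
            nxt[st2, ] <- nxt[st2, ] + w * live[st, ]
          }
        }
      }
      live <- nxt
    }
  }
  c(colSums(live), done)
}

#' Exact over-representation probability
#'
#' Exact P(at least n overlapping occurrences of the motif in a length-L
#' sequence emitted by the Markov model), computed with a product automaton:
#' the motif-matching automaton (failure-function construction, so
#' self-overlapping motifs are handled exactly) crossed with the occurrence
#' count truncated at n, advanced L steps under the Markov transitions.
#'
#' @inheritParams pover_binomial
#' @export
pover_exact <- function(model, motif, L, n) {
  if (n < 0) stop("n must be >= 0")
  k <- nchar(motif)
  if (L < k) stop("L must be >= motif length")
  if (n == 0) return(1.0)
  if (n > L - k + 1) return(0.0)
  d <- count_distribution(model, motif, L, n)
  min(1, max(0, d[length(d)]))
}

#' Full occurrence-count distribution under the Markov model
#'
#' @inheritParams pover_binomial
#' @param nmax largest exact count tracked; the last entry of the result is
#'   P(count >= nmax).
#' @return numeric vector `P(0), ..., P(nmax - 1), P(>= nmax)`, summing to 1.
#' @export
occurrence_distribution <- function(model, motif, L, nmax) {
  if (nmax < 1) stop("nmax must be >= 1")
  count_distribution(model, motif, L, nmax)
}

#' Over-representation feature of a UTR / miRNA pair
#'
#' Fits the order-1 Markov model to the UTR, counts the observed seed
#' matches for the chosen span (overlaps included) and returns the
#' probability of at least that many occurrences by chance.
#'
#' @param utr UTR sequence.
#' @param mirna miRNA sequence.
#' @param method `"exact"` or `"binomial"`.
#' @param span seed span used for matching, `"2-8"` (default) or `"2-7"`.
#' @return list `observed_n`, `p_over`, `method`.
#' @export
pover_feature <- function(utr, mirna, method = c("exact", "binomial"),
                          span = c("2-8", "2-7")) {
  method <- match.arg(method)
  span <- match.arg(span)
  n <- count_seed_matches(utr, mirna, span)
  if (n == 0) {
    return(list(observed_n = 0L, p_over = 1.0, method = method))
  }
  motif <- seed_match(mirna, span)
  model <- fit_markov(utr)
  p <- if (method == "exact") {
    pover_exact(model, motif, nchar(utr), n)
  } else {
    pover_binomial(model, motif, nchar(utr), n)
  }
  list(observed_n = as.integer(n), p_over = p, method = method)
}
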