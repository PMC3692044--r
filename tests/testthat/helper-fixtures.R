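# Shared fixtures and independent oracles used across the suite.

MIR <- "UGGAAUGUAAAGAAGUAUGUAU"   # 22 nt, seed 2-7 = GGAAUG (match CAUUCC)

TOY_TREE <- "((A:0.1,B:0.2):0.3,C:0.4);"

TREE8 <- paste0("(((s1:0.3,s2:0.3):0.2,(s3:0.3,s4:0.3):0.2):0.15,",
                "((s5:0.3,s6:0.3):0.2,(s7:0.3,s8:0.3):0.2):0.15);")

# random order-1 Markov model (normalized uniform draws)
random_markov <- function(seed) {
  withr::with_seed(seed, {
    ini <- runif(4, 0.2, 1); ini <- ini / sum(ini)
    tr <- matrix(runif(16, 0.2, 1), 4, 4)
    tr <- tr / rowSums(tr)
    markov_model(ini, tr)
  })
}

# Brute-force oracle: P(at least n overlapping occurrences of motif in a
# length-L sequence) by full enumeration of all 4^L sequences weighted by
# the Markov model. Independent of the automaton implementation.
enum_pover <- function(model, motif, L, n) {
  if (n == 0) return(1.0)
  S <- as.matrix(expand.grid(rep(list(1:4), L)))
  w <- model$initial[S[, 1]]
  if (L > 1) {
    for (j in 2:L) w <- w * model$transition[cbind(S[, j - 1], S[, j])]
  }
  m <- match(strsplit(motif, "")[[1]], c("A", "C", "G", "U"))
  k <- length(m)
  if (L < k) return(0.0)
  cnt <- rep(0L, nrow(S))
  for (o in 1:(L - k + 1)) {
    hit <- rep(TRUE, nrow(S))
    for (t in seq_len(k)) hit <- hit & (S[, o + t - 1] == m[t])
    cnt <- cnt + hit
  }
  sum(w[cnt >= n])
}

# hand-summed nearest-neighbor energy of a perfect, fully stacked duplex
# (x paired to its exact reverse complement), read from the shipped table
nn_hand_sum <- function(x, nn = load_nn_table()) {
  comp <- c(A = "U", C = "G", G = "C", U = "A")
  xs <- strsplit(x, "")[[1]]
  pt <- paste0(xs, comp[xs])           # pair types along x, 5' to 3'
  e <- nn$params[["duplex_init"]]
  for (t in seq_len(length(pt) - 1)) e <- e + nn$stacks[pt[t], pt[t + 1]]
  weak <- function(p) p %in% c("AU", "UA", "GU", "UG")
  e + nn$params[["au_end"]] * (weak(pt[1]) + weak(pt[length(pt)]))
}
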