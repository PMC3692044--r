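# Deterministic generators for all test inputs: random UTRs, UTRs with
# planted seed-match sites (scrubbed of spurious matches), simulated
# orthologous alignments on a tree, and synthetic repression datasets.
# Every generator is a pure function of its arguments including the seed.

#' Generate a random UTR sequence
#'
#' @param length sequence length, nt (>= 0).
#' @param base_composition probabilities over A,C,G,U (normalized).
#' @param seed integer RNG seed.
#' @export
gen_utr <- function(length, base_composition = rep(0.25, 4), seed = 1) {
  if (length < 0) stop("length must be >= 0")
  p <- as.numeric(base_composition)
  if (length(p) != 4 || any(p < 0) || sum(p) <= 0) {
    stop("base_composition must be 4 nonnegative values, not all zero")
  }
  if (length == 0) return("")
  withr::with_seed(seed, {
    paste(sample(RNA_BASES, length, replace = TRUE, prob = p / sum(p)),
          collapse = "")
  })
}

site_match_string <- function(mirna, site_type) {
  m6 <- seed_match(mirna, "2-7")
  m8c <- rna_comp(substr(mirna, 8, 8))
  switch(site_type,
         "6mer" = m6,
         "7mer-A1" = paste0(m6, "A"),
         "7mer-m8" = paste0(m8c, m6),
         "8mer" = paste0(m8c, m6, "A"),
         stop("unknown site type: ", site_type))
}

replace_at <- function(seq, pos0, text) {
  # pos0: 0-based start
  paste0(substr(seq, 1, pos0), text, substr(seq, pos0 + nchar(text) + 1,
                                            nchar(seq)))
}

#' Plant seed-match sites into a UTR background
#'
#' Writes the exact match string of each requested site type at each
#' (0-based) position, forces the immediate context so a planted site
#' keeps exactly its requested class (no accidental upgrade), and then
#' iteratively mutates the background until the scanner finds exactly the
#' planted sites and nothing else.
#'
#' @param utr background UTR sequence.
#' @param mirna miRNA whose sites are planted.
#' @param positions 0-based start positions of the full site spans,
#'   non-overlapping.
#' @param site_types character vector, one of `6mer, 7mer-A1, 7mer-m8,
#'   8mer` per position.
#' @param utr_id,mirna_name identifiers for the truth table.
#' @return list with `utr` (modified sequence) and `truth` (data.frame in
#'   [find_sites()] layout).
#' @export
plant_sites <- function(utr, mirna, positions, site_types,
                        utr_id = "utr", mirna_name = "mirna") {
  stopifnot(length(positions) == length(site_types))
  if (length(positions) == 0) {
    return(list(utr = utr, truth = empty_sites()))
  }
  spans <- nchar(vapply(site_types, site_match_string,
                        character(1), mirna = mirna))
  ends <- positions + spans
  o <- order(positions)
  if (any(positions < 0) || any(ends > nchar(utr))) {
    stop("planted site outside UTR bounds")
  }
  if (length(positions) > 1 &&
      any(positions[o][-1] < ends[o][-length(o)] + 2)) {
    stop("planted sites overlap (2 nt of context required between sites)")
  }
  m8c <- rna_comp(substr(mirna, 8, 8))
  not_base <- function(forbidden) setdiff(c("C", "G", "U", "A"), forbidden)[1]
  protected <- logical(nchar(utr))
  for (i in seq_along(positions)) {
    s <- positions[i]; ty <- site_types[i]
    utr <- replace_at(utr, s, site_match_string(mirna, ty))
    protected[(s + 1):(s + spans[i])] <- TRUE
    # context guards: no accidental m8 upgrade (residue 5' of the match)
    # and no accidental A1 upgrade (residue 3' of the match)
    if (ty %in% c("6mer", "7mer-A1") && s >= 1) {
      if (substr(utr, s, s) == m8c) {
        utr <- replace_at(utr, s - 1, not_base(m8c))
      }
      protected[s] <- TRUE
    }
    if (ty %in% c("6mer", "7mer-m8") && ends[i] < nchar(utr)) {
      if (substr(utr, ends[i] + 1, ends[i] + 1) == "A") {
        utr <- replace_at(utr, ends[i], not_base("A"))
      }
      protected[ends[i] + 1] <- TRUE
    }
  }
  truth <- data.frame(utr_id = utr_id, mirna = mirna_name,
                      start = as.integer(positions),
                      end = as.integer(ends),
                      site_type = site_types, stringsAsFactors = FALSE)
  truth <- truth[order(truth$start), , drop = FALSE]
  rownames(truth) <- NULL
  # scrub spurious matches deterministically
  for (iter in 1:200) {
    found <- find_sites(utr, mirna, utr_id, mirna_name)
    key <- function(d) paste(d$start, d$end, d$site_type)
    extra <- found[!key(found) %in% key(truth), , drop = FALSE]
    if (nrow(extra) == 0) {
      if (!identical(key(found), key(truth))) {
        stop("planted site lost during scrubbing")
      }
      return(list(utr = utr, truth = truth))
    }
    ex <- extra[1, ]
    core <- if (ex$site_type %in% c("7mer-m8", "8mer")) {
      (ex$start + 1L):(ex$start + 6L)    # the 6mer core, 0-based
    } else {
      ex$start:(ex$start + 5L)
    }
    mutable <- core[!protected[core + 1]]
    if (length(mutable) == 0) stop("cannot scrub match overlapping a site")
    p <- mutable[1]
    cur <- substr(utr, p + 1, p + 1)
    utr <- replace_at(utr, p, not_base(cur))
  }
  stop("scrubbing did not converge")
}

#' Simulate an orthologous alignment on a tree
#'
#' Evolves the reference sequence over the tree by sampling from the
#' substitution model's transition probabilities, with each branch length
#' multiplied per position by the scale of the window covering it
#' (lambda < 1 emulates purifying selection, 0 freezes the window). The
#' simulation is conditioned on the reference leaf carrying `ref_seq`
#' (states are propagated outward from that leaf, which is equivalent to
#' root sampling for the reversible models used here), so the reference
#' row of the returned alignment reproduces the input sequence exactly.
#' No indels are introduced: the leaf rows form a gap-free alignment.
#'
#' @param tree `phylo` tree with branch lengths.
#' @param ref_seq reference (and effective root) sequence, RNA string,
#'   N-free.
#' @param model a [subst_model()].
#' @param window_scales list of `list(start, end, lambda)` entries
#'   (0-based, half-open) on the reference sequence; positions not covered
#'   evolve with lambda = 1.
#' @param seed integer RNG seed.
#' @param ref_species the leaf that carries `ref_seq` unchanged.
#' @return a [species_alignment()].
#' @export
gen_alignment <- function(tree, ref_seq, model = subst_model("JC69"),
                          window_scales = list(), seed = 1,
                          ref_species = tree$tip.label[1]) {
  L <- nchar(ref_seq)
  lam <- rep(1, L)
  for (w in window_scales) {
    if (w$lambda < 0) stop("lambda must be >= 0")
    if (w$start < 0 || w$end > L) stop("window outside reference sequence")
    if (w$end > w$start) lam[(w$start + 1):w$end] <- w$lambda
  }
  ref_tip <- match(ref_species, tree$tip.label)
  if (is.na(ref_tip)) stop("ref_species not a tree leaf")
  withr::with_seed(seed, {
    n_tip <- length(tree$tip.label)
    n_node <- n_tip + tree$Nnode
    states <- vector("list", n_node)
    states[[ref_tip]] <- seq_to_int(ref_seq)
    if (any(states[[ref_tip]] == 0L)) stop("reference sequence must be N-free")
    groups <- split(seq_len(L), lam)
    # undirected adjacency; propagate states outward from the reference
    # leaf in breadth-first order
    adj <- vector("list", n_node)
    for (e in seq_len(nrow(tree$edge))) {
      a <- tree$edge[e, 1]; b <- tree$edge[e, 2]; t_e <- tree$edge.length[e]
      adj[[a]] <- rbind(adj[[a]], c(b, t_e))
      adj[[b]] <- rbind(adj[[b]], c(a, t_e))
    }
    queue <- ref_tip
    visited <- logical(n_node); visited[ref_tip] <- TRUE
    while (length(queue) > 0) {
      node <- queue[1]; queue <- queue[-1]
      for (r in seq_len(NROW(adj[[node]]))) {
        nb <- adj[[node]][r, 1]; t_e <- adj[[node]][r, 2]
        if (visited[nb]) next
        visited[nb] <- TRUE
        st <- states[[node]]
        out <- integer(L)
        for (g in seq_along(groups)) {
          idx <- groups[[g]]
          lam_g <- lam[idx[1]]
          if (t_e * lam_g == 0) {
            out[idx] <- st[idx]
          } else {
            P <- model$P(t_e * lam_g)
            out[idx] <- vapply(st[idx], function(a) {
              sample.int(4, 1, prob = P[a, ])
            }, integer(1))
          }
        }
        states[[nb]] <- out
        queue <- c(queue, nb)
      }
    }
    rows <- vapply(seq_len(n_tip), function(i) {
      paste(RNA_BASES[states[[i]]], collapse = "")
    }, character(1))
    names(rows) <- tree$tip.label
    species_alignment(rows, ref_species)
  })
}

# documented per-feature sampling ranges for the synthetic repression data
FEATURE_RANGES <- list(
  dg_duplex = c(-30, 0), dg_binding = c(-30, 0),
  dg_seed_duplex = c(-15, 0), dg_seed_binding = c(-15, 0),
  dg_open = c(0, 15), dg_total = c(-30, 5),
  pover_binomial = c(0, 1), pover_exact = c(0, 1),
  au_content = c(0, 1), utr_position = c(0, 1500),
  three_prime_pairing = c(0, 8), bls = c(0, 5),
  phylop_score = c(-3, 5), n_sites = c(1, 5))

#' Generate a synthetic repression dataset
#'
#' Draws feature values uniformly from documented per-feature ranges and
#' computes the response as the model prediction plus Gaussian noise.
#'
#' @param model a `mirmap_model` whose coefficient names select the
#'   features generated.
#' @param n_pairs number of rows (>= 1).
#' @param noise_sd Gaussian noise standard deviation.
#' @param seed integer RNG seed.
#' @return list with `features` (data.frame) and `response` (numeric).
#' @export
gen_repression_dataset <- function(model, n_pairs, noise_sd, seed = 1) {
  if (n_pairs < 1) stop("n_pairs must be >= 1")
  feats <- names(model$coefficients)
  unknown <- setdiff(feats, names(FEATURE_RANGES))
  if (length(unknown) > 0) {
    stop("no sampling range for: ", paste(unknown, collapse = ", "))
  }
  withr::with_seed(seed, {
    X <- as.data.frame(lapply(feats, function(f) {
      r <- FEATURE_RANGES[[f]]
      stats::runif(n_pairs, r[1], r[2])
    }), col.names = feats)
    y <- predict_repression(model, X) + stats::rnorm(n_pairs, 0, noise_sd)
    list(features = X, response = y)
  })
}
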