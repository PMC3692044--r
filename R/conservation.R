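# Evolutionary features: branch-length score of seed-match presence across
# species, and a phyloP-style likelihood-ratio test for negative selection
# (branch-scale lambda < 1) on the site columns.

#' Construct a nucleotide substitution model
#'
#' JC69 (default) or HKY85. Branch lengths are in expected substitutions
#' per site: the rate matrix is normalized to one expected substitution per
#' unit time at equilibrium.
#'
#' @param kind `"JC69"` or `"HKY85"`.
#' @param freqs equilibrium frequencies over A,C,G,U (HKY85; JC69 fixes
#'   them at 1/4).
#' @param kappa transition/transversion rate ratio (HKY85).
#' @return object with a `P(t)` transition-probability function and `freqs`.
#' @export
subst_model <- function(kind = c("JC69", "HKY85"),
                        freqs = rep(0.25, 4), kappa = 2.0) {
  kind <- match.arg(kind)
  if (kind == "JC69") freqs <- rep(0.25, 4)
  freqs <- as.numeric(freqs)
  if (length(freqs) != 4 || any(freqs <= 0) || abs(sum(freqs) - 1) > 1e-9) {
    stop("freqs must be 4 positive values summing to 1")
  }
  if (kind == "JC69") {
    P <- function(t) {
      e <- exp(-4 * t / 3)
      ps <- 0.25 + 0.75 * e
      pd <- 0.25 - 0.25 * e
      M <- matrix(pd, 4, 4)
      diag(M) <- ps
      M
    }
  } else {
    # HKY85: transitions A<->G, C<->U get rate kappa
    Q <- matrix(0, 4, 4)
    is_transition <- function(i, j) (i + j) %in% c(4, 6) && abs(i - j) == 2
    for (i in 1:4) for (j in 1:4) {
      if (i != j) Q[i, j] <- freqs[j] * if (is_transition(i, j)) kappa else 1
    }
    diag(Q) <- -rowSums(Q)
    Q <- Q / sum(freqs * -diag(Q))          # one substitution per unit time
    # symmetrize with pi^1/2 for a stable eigendecomposition
    D <- diag(sqrt(freqs)); Di <- diag(1 / sqrt(freqs))
    eig <- eigen(D %*% Q %*% Di, symmetric = TRUE)
    P <- function(t) {
      M <- Di %*% eig$vectors %*% diag(exp(eig$values * t)) %*%
        t(eig$vectors) %*% D
      M[M < 0] <- 0
      M
    }
  }
  structure(list(kind = kind, freqs = freqs, P = P), class = "subst_model")
}

#' Species in which the seed match is present
#'
#' Maps the site from ungapped reference coordinates to alignment columns
#' via the reference row, extends the column range by `slop` columns on
#' each side to tolerate alignment jitter, and reports the species whose
#' gap-stripped subsequence over those columns contains the seed match
#' exactly.
#'
#' @param aln a [species_alignment()].
#' @param site a site in ungapped reference coordinates.
#' @param seed_match the UTR-side match string (see [seed_match()]).
#' @param slop columns of slack on each side.
#' @return character vector of species names.
#' @export
site_presence <- function(aln, site, seed_match, slop = 2) {
  ref <- aln$rows[[aln$ref_species]]
  if (is.null(ref)) stop("reference species missing from alignment")
  refc <- strsplit(ref, "", fixed = TRUE)[[1]]
  ungapped <- cumsum(refc != "-")
  cols <- which(ungapped >= site$start + 1 & ungapped <= site$end & refc != "-")
  if (length(cols) == 0) stop("site does not map onto the reference row")
  a <- max(1, min(cols) - slop)
  b <- min(length(refc), max(cols) + slop)
  hit <- vapply(aln$rows, function(row) {
    sub <- gsub("-", "", substr(row, a, b), fixed = TRUE)
    grepl(seed_match, sub, fixed = TRUE)
  }, logical(1))
  names(aln$rows)[hit]
}

#' Branch length score
#'
#' Sum of the branch lengths of the minimal spanning subtree connecting the
#' species in which the site is present; 0 when fewer than two species
#' carry it. Optionally normalized by the total tree length.
#'
#' @param tree a `phylo` tree with branch lengths.
#' @param present character vector of species (must be tree leaves).
#' @param normalize divide by the total tree length.
#' @export
bls <- function(tree, present, normalize = FALSE) {
  present <- unique(present)
  bad <- setdiff(present, tree$tip.label)
  if (length(bad) > 0) {
    stop("species not in tree: ", paste(bad, collapse = ", "))
  }
  if (length(present) <= 1) return(0.0)
  sub <- ape::keep.tip(tree, present)
  s <- sum(sub$edge.length)
  if (normalize) s / sum(tree$edge.length) else s
}

# columns: named character vector (species -> ungapped RNA string, equal
# lengths) or a species_alignment plus 0-based half-open ref coordinates.
columns_matrix <- function(columns) {
  lens <- nchar(columns)
  if (length(unique(lens)) != 1) stop("column strings differ in length")
  M <- matrix(0L, length(columns), lens[1],
              dimnames = list(names(columns), NULL))
  for (i in seq_along(columns)) M[i, ] <- seq_to_int(columns[[i]])
  M
}

#' Extract site columns from an alignment
#'
#' Gapped columns of all species over the reference-mapped site range; gaps
#' and N are treated as missing data in the likelihood.
#'
#' @inheritParams site_presence
#' @export
site_columns <- function(aln, site) {
  ref <- aln$rows[[aln$ref_species]]
  refc <- strsplit(ref, "", fixed = TRUE)[[1]]
  ungapped <- cumsum(refc != "-")
  cols <- which(ungapped >= site$start + 1 & ungapped <= site$end & refc != "-")
  if (length(cols) == 0) stop("site does not map onto the reference row")
  vapply(aln$rows, function(row) {
    paste(strsplit(row, "", fixed = TRUE)[[1]][cols], collapse = "")
  }, character(1))
}

#' Felsenstein pruning log-likelihood
#'
#' Log-likelihood of independent alignment columns on the tree under the
#' substitution model, with every branch length multiplied by `scale`.
#' Species present in only one of tree/columns are dropped with a warning;
#' gaps and N are missing data.
#'
#' @param tree `phylo` tree with branch lengths.
#' @param columns named character vector: species -> equal-length string.
#' @param model a [subst_model()].
#' @param scale positive branch-scale multiplier.
#' @export
felsenstein_loglik <- function(tree, columns, model, scale = 1) {
  if (scale <= 0) stop("scale must be positive")
  common <- intersect(tree$tip.label, names(columns))
  if (length(common) < 2) stop("need >= 2 species shared by tree and columns")
  if (length(common) < length(tree$tip.label) ||
      length(common) < length(columns)) {
    warning("dropping species not shared by tree and columns")
    tree <- ape::keep.tip(tree, common)
    columns <- columns[common]
  }
  X <- columns_matrix(columns)            # species x ncol, 0 = missing
  ncol_ <- ncol(X)
  tr <- stats::setNames(seq_len(nrow(X)), rownames(X))
  tree <- ape::reorder.phylo(tree, "postorder")
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  lik <- vector("list", n_node)
  logsc <- 0
  for (i in seq_len(n_tip)) {
    M <- matrix(0, 4, ncol_)
    states <- X[tr[tree$tip.label[i]], ]
    for (cl in seq_len(ncol_)) {
      if (states[cl] == 0L) M[, cl] <- 1 else M[states[cl], cl] <- 1
    }
    lik[[i]] <- M
  }
  for (e in seq_len(nrow(tree$edge))) {
    parent <- tree$edge[e, 1]; child <- tree$edge[e, 2]
    P <- model$P(tree$edge.length[e] * scale)
    contrib <- P %*% lik[[child]]
    if (is.null(lik[[parent]])) lik[[parent]] <- contrib
    else lik[[parent]] <- lik[[parent]] * contrib
    mx <- apply(lik[[parent]], 2, max)
    if (any(mx <= 0)) return(-Inf)
    lik[[parent]] <- sweep(lik[[parent]], 2, mx, "/")
    logsc <- logsc + sum(log(mx))
  }
  root <- tree$edge[nrow(tree$edge), 1]
  sum(log(colSums(model$freqs * lik[[root]]))) + logsc
}

#' phyloP-style conservation test
#'
#' Likelihood-ratio test of a site-specific branch-scale parameter lambda,
#' optimized in `[1e-4, 10]`, against the neutral lambda = 1. The p-value
#' is half the chi-square(1) tail on the side of the estimate (one-sided);
#' `phylop_score = -log10(p)` signed positive for conservation
#' (lambda < 1), negative for acceleration. `phylop_p` is the one-sided
#' conserved-alternative p-value.
#'
#' @inheritParams felsenstein_loglik
#' @param neutral the neutral [subst_model()].
#' @return list `lambda_hat`, `phylop_p`, `phylop_score`.
#' @export
phylop_score <- function(tree, columns, neutral = subst_model("JC69")) {
  ll <- function(lam) felsenstein_loglik(tree, columns, neutral, scale = lam)
  opt <- tryCatch(
    stats::optimize(ll, interval = c(1e-4, 10), maximum = TRUE,
                    tol = 1e-6),
    error = function(e) stop("lambda optimization failed: ",
                             conditionMessage(e)))
  ll1 <- ll(1)
  lam <- opt$maximum
  llhat <- opt$objective
  if (!is.finite(llhat) || llhat <= ll1) {
    lam <- 1; llhat <- ll1
  }
  lr <- max(0, 2 * (llhat - ll1))
  p_two <- stats::pchisq(lr, df = 1, lower.tail = FALSE)
  if (lam == 1) {
    return(list(lambda_hat = 1, phylop_p = 1, phylop_score = 0))
  }
  half <- p_two / 2
  if (lam < 1) {
    list(lambda_hat = lam, phylop_p = half, phylop_score = -log10(half))
  } else {
    list(lambda_hat = lam, phylop_p = 1 - half, phylop_score = log10(half))
  }
}
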