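toy_tree <- function() read_newick(TOY_TREE)

test_that("bls sums the minimal spanning subtree", {
  tr <- toy_tree()
  expect_equal(bls(tr, c("A", "B")), 0.3)
  expect_equal(bls(tr, c("A", "B", "C")), 1.0)
  expect_equal(bls(tr, c("A", "C")), 0.1 + 0.3 + 0.4)
  expect_identical(bls(tr, "A"), 0.0)
  expect_identical(bls(tr, character(0)), 0.0)
  expect_equal(bls(tr, c("A", "B", "C"), normalize = TRUE), 1.0)
  expect_equal(bls(tr, c("A", "B"), normalize = TRUE), 0.3)
  expect_error(bls(tr, c("A", "Z")), "not in tree")
})

test_that("bls is monotone under adding species", {
  tr <- read_newick(TREE8)
  sp <- tr$tip.label
  withr::with_seed(5, {
    for (rep in 1:10) {
      ord <- sample(sp)
      vals <- vapply(seq_along(ord),
                     function(k) bls(tr, ord[1:k]), numeric(1))
      expect_true(all(diff(vals) >= -1e-12))
      expect_equal(vals[length(vals)], sum(tr$edge.length))
    }
  })
})

test_that("site_presence maps sites through the reference row", {
  site <- list(start = 4L, end = 10L)
  match6 <- "CAUUCC"
  ref <- paste0("GGGG", match6, "GGGG")
  aln <- species_alignment(
    c(hs = ref,
      mm = ref,                                     # identical
      rn = paste0("GGGG", "CAUGCC", "GGGG"),        # substitution inside
      gg = paste0("GGGG", "------", "GGGG")),       # all gaps over the site
    "hs")
  pres <- site_presence(aln, site, match6)
  expect_setequal(pres, c("hs", "mm"))

  # gapped reference: ungapped coordinates still locate the site
  aln2 <- species_alignment(
    c(hs = paste0("GG--GG", match6, "GGGG"),
      mm = paste0("GGAAGG", match6, "GGGG")), "hs")
  expect_setequal(site_presence(aln2, site, match6), c("hs", "mm"))

  # jitter within the 2-column slop still counts as present
  aln3 <- species_alignment(
    c(hs = paste0("GGGG", match6, "GGGG--"),
      mm = paste0("GGG-", "-G", match6, "GGGG")), "hs")
  expect_true("mm" %in% site_presence(aln3, site, match6))
})

test_that("felsenstein pruning matches JC69 closed forms on two leaves", {
  tr <- toy_tree()
  jc <- subst_model("JC69")
  t_ab <- 0.1 + 0.2
  p_same <- 0.25 + 0.75 * exp(-4 * t_ab / 3)
  p_diff <- 0.25 - 0.25 * exp(-4 * t_ab / 3)
  expect_equal(suppressWarnings(
    felsenstein_loglik(tr, c(A = "A", B = "A"), jc)),
    log(0.25 * p_same), tolerance = 1e-9)
  expect_equal(suppressWarnings(
    felsenstein_loglik(tr, c(A = "A", B = "G"), jc)),
    log(0.25 * p_diff), tolerance = 1e-9)
  # columns are independent: log-likelihoods add
  expect_equal(suppressWarnings(
    felsenstein_loglik(tr, c(A = "AA", B = "AG"), jc)),
    log(0.25 * p_same) + log(0.25 * p_diff), tolerance = 1e-9)
})

test_that("scale -> 0 collapses identical columns to one sequence", {
  tr <- read_newick(TREE8)
  jc <- subst_model("JC69")
  cols <- stats::setNames(rep("ACGU", 8), tr$tip.label)
  ll <- felsenstein_loglik(tr, cols, jc, scale = 1e-9)
  expect_equal(ll, 4 * log(0.25), tolerance = 1e-4)
})

test_that("branch scaling behaves like multiplied branch lengths", {
  tr <- toy_tree()
  tr2 <- tr; tr2$edge.length <- tr$edge.length * 0.37
  jc <- subst_model("JC69")
  cols <- c(A = "ACGG", B = "AAGG", C = "ACGU")
  expect_equal(felsenstein_loglik(tr, cols, jc, scale = 0.37),
               felsenstein_loglik(tr2, cols, jc, scale = 1),
               tolerance = 1e-9)
})

test_that("HKY85 transition probabilities are valid and reversible", {
  freqs <- c(0.35, 0.15, 0.3, 0.2)
  hk <- subst_model("HKY85", freqs = freqs, kappa = 3)
  for (t in c(0.01, 0.3, 2)) {
    P <- hk$P(t)
    expect_equal(rowSums(P), rep(1, 4), tolerance = 1e-9)
    expect_true(all(P >= 0))
    # detailed balance: pi_i P_ij == pi_j P_ji
    expect_equal(freqs * P, t(freqs * P), tolerance = 1e-9)
  }
})

test_that("phylop_score is positive on conserved and negative on accelerated sites", {
  tr <- read_newick(TREE8)
  cols_cons <- stats::setNames(rep("ACGUACG", 8), tr$tip.label)
  res <- phylop_score(tr, cols_cons)
  expect_lt(res$lambda_hat, 1)
  expect_gt(res$phylop_score, 0)
  expect_lt(res$phylop_p, 0.05)

  aln_acc <- gen_alignment(tr, gen_utr(7, seed = 2),
                           window_scales = list(list(start = 0, end = 7,
                                                     lambda = 6)),
                           seed = 21)
  res_acc <- phylop_score(tr, aln_acc$rows)
  expect_gt(res_acc$lambda_hat, 1)
  expect_lt(res_acc$phylop_score, 0)
  expect_gt(res_acc$phylop_p, 0.5)
})

test_that("phylop degenerates to the null when lambda-hat is 1", {
  tr <- read_newick(TREE8)
  # flat likelihood in lambda is impossible with data, but the clamp path
  # must return the exact null identity when no improvement is found
  aln <- gen_alignment(tr, gen_utr(7, seed = 8), seed = 33)
  res <- phylop_score(tr, aln$rows)
  if (res$lambda_hat == 1) {
    expect_identical(res$phylop_p, 1)
    expect_identical(res$phylop_score, 0)
  } else {
    expect_true(res$phylop_p > 0 && res$phylop_p <= 1)
    expect_identical(res$phylop_score > 0, res$lambda_hat < 1)
  }
})
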