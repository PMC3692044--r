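test_that("gen_utr is seeded, composition-aware and handles edge lengths", {
  expect_identical(gen_utr(0, seed = 1), "")
  expect_identical(gen_utr(20, c(1, 0, 0, 0), seed = 1), strrep("A", 20))
  expect_identical(gen_utr(500, seed = 7), gen_utr(500, seed = 7))
  expect_false(gen_utr(500, seed = 7) == gen_utr(500, seed = 8))
  expect_error(gen_utr(10, c(-1, 1, 0, 0)), "composition")
  expect_error(gen_utr(-1), ">= 0")
  # composition is respected statistically
  u <- gen_utr(20000, c(0.7, 0.1, 0.1, 0.1), seed = 2)
  a_frac <- lengths(regmatches(u, gregexpr("A", u))) / 20000
  expect_lt(abs(a_frac - 0.7), 0.02)
})

test_that("plant_sites round-trips through the scanner for every class", {
  for (ty in c("8mer", "7mer-m8", "7mer-A1", "6mer")) {
    ps <- plant_sites(gen_utr(150, seed = 11), MIR, 70, ty)
    found <- find_sites(ps$utr, MIR)
    expect_identical(found$start, ps$truth$start)
    expect_identical(found$site_type, ty)
  }
  ps2 <- plant_sites(gen_utr(150, seed = 12), MIR, c(30, 100),
                     c("6mer", "7mer-m8"))
  found <- find_sites(ps2$utr, MIR)
  expect_identical(found$site_type, c("6mer", "7mer-m8"))

  ps0 <- plant_sites(gen_utr(50, seed = 1), MIR, integer(0), character(0))
  expect_identical(ps0$utr, gen_utr(50, seed = 1))
  expect_identical(nrow(ps0$truth), 0L)

  expect_error(plant_sites(gen_utr(50, seed = 1), MIR, c(10, 12),
                           c("6mer", "6mer")), "overlap")
  expect_error(plant_sites(gen_utr(50, seed = 1), MIR, 48, "8mer"), "bounds")
})

test_that("scrubbed backgrounds contain no unplanned matches", {
  for (seed in 1:20) {
    # AU-rich background maximizes spurious CAUUCC hits before scrubbing
    bg <- gen_utr(300, c(0.4, 0.1, 0.1, 0.4), seed = seed)
    ps <- plant_sites(bg, MIR, c(50, 200), c("8mer", "7mer-A1"))
    found <- find_sites(ps$utr, MIR)
    expect_identical(found$start, ps$truth$start)
    expect_identical(found$end, ps$truth$end)
    expect_identical(found$site_type, ps$truth$site_type)
  }
})

test_that("gen_alignment freezes lambda = 0 windows and keeps the reference", {
  tr <- read_newick(TREE8)
  ref <- gen_utr(60, seed = 5)
  aln <- gen_alignment(tr, ref,
                       window_scales = list(list(start = 10, end = 20,
                                                 lambda = 0)),
                       seed = 9)
  expect_identical(alignment_ref_seq(aln), ref)
  frozen <- vapply(aln$rows, function(r) substr(r, 11, 20), character(1))
  expect_true(all(frozen == substr(ref, 11, 20)))
  # reproducible by seed
  aln2 <- gen_alignment(tr, ref,
                        window_scales = list(list(start = 10, end = 20,
                                                  lambda = 0)),
                        seed = 9)
  expect_identical(aln$rows, aln2$rows)
  expect_error(gen_alignment(tr, ref,
                             window_scales = list(list(start = 0, end = 5,
                                                       lambda = -1))),
               "lambda")
})

test_that("large lambda drives leaves toward independence from the reference", {
  tr <- read_newick(TREE8)
  ref <- strrep("A", 2000)
  aln <- gen_alignment(tr, ref,
                       window_scales = list(list(start = 0, end = 2000,
                                                 lambda = 50)),
                       seed = 4)
  other <- aln$rows[["s8"]]
  match_frac <- mean(strsplit(other, "")[[1]] == "A")
  expect_lt(abs(match_frac - 0.25), 0.05)
})

test_that("gen_repression_dataset hits its generative R2 and is seeded", {
  model0 <- demo_model()
  d0 <- gen_repression_dataset(model0, 100, 0, seed = 6)
  fit0 <- fit_linear_model(d0$features, d0$response)
  expect_equal(fit0$training_r2, 1, tolerance = 1e-9)
  expect_equal(fit0$coefficients[names(model0$coefficients)],
               model0$coefficients, tolerance = 1e-7)

  big <- gen_repression_dataset(model0, 20000, 0, seed = 1)
  noise_sd <- sqrt(stats::var(big$response) * (1 / 0.15 - 1))
  d <- gen_repression_dataset(model0, 5000, noise_sd, seed = 8)
  fit <- fit_linear_model(d$features, d$response)
  expect_lt(abs(fit$training_r2 - 0.15), 0.05)

  d2 <- gen_repression_dataset(model0, 50, 1, seed = 13)
  d3 <- gen_repression_dataset(model0, 50, 1, seed = 13)
  expect_identical(d2, d3)
})
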