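test_that("aggregate_pair sums site features and counts sites", {
  sf <- data.frame(dg_duplex = c(-8, -6), dg_open = c(1, 2),
                   dg_total = c(-7, -4), au_content = c(0.5, 0.7),
                   bls = c(1.2, NA))
  one <- aggregate_pair(sf[1, ])
  expect_equal(unname(one["dg_duplex"]), -8)
  expect_equal(unname(one["n_sites"]), 1)

  both <- aggregate_pair(sf)
  expect_equal(unname(both["dg_duplex"]), -14)
  expect_equal(unname(both["au_content"]), 1.2)
  expect_equal(unname(both["n_sites"]), 2)
  # missing conservation at one site: available values summed, flagged
  expect_equal(unname(both["bls"]), 1.2)
  expect_identical(attr(both, "missing"), "bls")

  # two identical sites double the energies
  twice <- aggregate_pair(rbind(sf[1, ], sf[1, ]))
  expect_equal(unname(twice["dg_total"]), -14)

  expect_error(aggregate_pair(sf[0, ]), "at least one site")
})

test_that("noise-free responses are interpolated exactly", {
  model0 <- demo_model()
  d <- gen_repression_dataset(model0, n_pairs = 200, noise_sd = 0, seed = 3)
  fit <- fit_linear_model(d$features, d$response)
  expect_equal(fit$intercept, model0$intercept, tolerance = 1e-9)
  expect_equal(fit$coefficients[names(model0$coefficients)],
               model0$coefficients, tolerance = 1e-7)
  expect_equal(fit$training_r2, 1, tolerance = 1e-9)
})

test_that("fit recovers coefficients within their confidence intervals", {
  model0 <- demo_model()
  # noise chosen for a generative R^2 of 0.15
  big <- gen_repression_dataset(model0, 20000, 0, seed = 1)
  sig_var <- stats::var(big$response)
  noise_sd <- sqrt(sig_var * (1 / 0.15 - 1))
  cover <- matrix(NA, 60, length(model0$coefficients))
  for (r in seq_len(60)) {
    d <- gen_repression_dataset(model0, 2000, noise_sd, seed = 100 + r)
    lmfit <- stats::lm(d$response ~ ., data = d$features)
    ci <- stats::confint(lmfit)[names(model0$coefficients), , drop = FALSE]
    cover[r, ] <- model0$coefficients >= ci[, 1] & model0$coefficients <= ci[, 2]
  }
  expect_true(all(colMeans(cover) >= 0.9))
})

test_that("orthogonal responses give near-zero R2 and rank deficiency errors", {
  withr::with_seed(10, {
    X <- data.frame(a = rnorm(500), b = rnorm(500))
    y <- rnorm(500)
  })
  fit <- fit_linear_model(X, y)
  expect_lt(fit$training_r2, 0.03)

  X$c <- X$a + X$b
  expect_error(fit_linear_model(X, y), "collinear features: c")
  X$c <- 1   # constant column aliases the intercept
  expect_error(fit_linear_model(X, y), "collinear")
})

test_that("predict is exactly linear and reproduces training residuals", {
  model0 <- demo_model()
  f <- vapply(mirtarscan:::FEATURE_RANGES[names(model0$coefficients)], mean, numeric(1))
  base <- predict_repression(model0, f)
  for (nm in names(model0$coefficients)) {
    f2 <- f; f2[nm] <- f2[nm] + 1
    expect_equal(predict_repression(model0, f2) - base,
                 unname(model0$coefficients[nm]), tolerance = 1e-12)
  }
  expect_error(predict_repression(model0, f[-1]), "missing features")
  expect_equal(predict_repression(model0, stats::setNames(
    rep(0, length(model0$coefficients)), names(model0$coefficients))),
    model0$intercept)

  d <- gen_repression_dataset(model0, 300, 0.5, seed = 9)
  fit <- fit_linear_model(d$features, d$response)
  pred <- predict_repression(fit, d$features)
  expect_equal(sum((d$response - pred)^2), sum(fit$residuals^2),
               tolerance = 1e-8)
  # OLS normal equations: residuals orthogonal to every feature column
  for (nm in names(d$features)) {
    expect_lt(abs(sum(fit$residuals * d$features[[nm]])) /
                nrow(d$features), 1e-8)
  }
})

test_that("percentile transform orients, bounds and averages ties", {
  bg <- c(-10, -5, -1)
  expect_equal(percentile_transform(-5, bg, "dg_total"), 50)
  expect_equal(percentile_transform(-10, bg, "dg_total"), 100)
  expect_equal(percentile_transform(-1, bg, "dg_total"), 0)
  # higher_is_stronger feature: orientation flips
  expect_equal(percentile_transform(5, c(0, 2, 5), "bls"), 100)
  expect_equal(percentile_transform(0, c(0, 2, 5), "bls"), 0)
  # ties averaged
  expect_equal(percentile_transform(2, c(1, 2, 2, 3), "bls"),
               100 * (1 + (2 + 1) / 2 - 1) / 3)
  # monotone in the repression direction, bounded
  vals <- seq(-12, 2, by = 0.5)
  p <- percentile_transform(vals, bg, "dg_total")
  expect_true(all(diff(p) <= 0))
  expect_true(all(p >= 0 & p <= 100))
  expect_error(percentile_transform(1, bg, "nope"), "direction map")
  expect_error(percentile_transform(1, numeric(0), "dg_total"), "empty")
})

test_that("model serialization round-trips", {
  f <- withr::local_tempfile(fileext = ".model")
  model0 <- demo_model()
  write_model(model0, f)
  m2 <- read_model(f)
  expect_equal(m2$intercept, model0$intercept)
  expect_equal(m2$coefficients, model0$coefficients)
  d <- gen_repression_dataset(model0, 10, 0, seed = 2)
  expect_equal(predict_repression(m2, d$features),
               predict_repression(model0, d$features), tolerance = 1e-12)
})
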