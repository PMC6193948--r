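test_that("weighted SSR reproduces hand arithmetic", {
  d <- velocity_dataset(c0 = c(1, 2, 4), v0 = c(4, 7, 9),
                        sd = c(1, 1, 0.5))
  p <- mm_params(Km = 1, Vmax = 10)
  # residuals: 4-5 = -1; 7-20/3 = 1/3; 9-8 = 1; wssr = 1 + 1/9 + 4
  expect_equal(weighted_ssr(p, d), 1 + 1 / 9 + 4)
  # all SD = 1 equals unweighted SSR
  d1 <- velocity_dataset(c(1, 2, 4), c(4, 7, 9), sd = 1)
  expect_equal(weighted_ssr(p, d1),
               weighted_ssr(p, d1, weights = "uniform"))
  # exact model data -> 0 under any weighting
  dex <- velocity_dataset(c(1, 2, 4), eval_mm(p, c(1, 2, 4)), sd = 0.3)
  expect_equal(weighted_ssr(p, dex), 0)
})

test_that("zero or missing SD under SD weighting is a named error", {
  d <- velocity_dataset(c(1, 2, 4), c(4, 7, 9), sd = c(1, 0, 0.5))
  expect_error(resolve_weights(d), "point\\(s\\) 2")
  d2 <- velocity_dataset(c(1, 2), c(4, 7), sd = NA_real_)
  expect_error(resolve_weights(d2), "missing or zero")
  expect_equal(resolve_weights(d, weights = "uniform"), rep(1, 3))
  expect_equal(resolve_weights(d, weights = "relative", cv = 0.1),
               1 / (0.1 * d$v0)^2)
})

test_that("noiseless data recovery is essentially exact for both models", {
  grid <- make_concentration_grid(1, 1, 12)
  mm <- mm_params(1, 10)
  d <- velocity_dataset(grid, eval_mm(mm, grid))
  f <- fit_kinetics(d, "MM", weights = "uniform", n_starts = 10)
  expect_equal(unname(coef(f)), c(1, 10), tolerance = 1e-6)
  expect_true(all(f$stderr <= 1e-6 * coef(f)))

  p <- wt_like_truth()
  grid2 <- make_concentration_grid(0.015, 4, 16)
  d2 <- velocity_dataset(grid2, eval_interacting_sites(p, grid2))
  f2 <- fit_kinetics(d2, "IS", weights = "uniform", n_starts = 20)
  expect_equal(unname(coef(f2)),
               c(p$Km1, p$Vmax1, p$a, p$b), tolerance = 1e-4)
})

test_that("a coarse grid search agrees with the optimizer's minimum", {
  p <- is_params(Km1 = 0.5, Vmax1 = 5, a = 20, b = 1.2)
  grid <- make_concentration_grid(0.5, 10, 10)
  d <- simulate_velocity_dataset(p, grid, mode = "relative", cv = 0.04,
                                 n_rep = 1, sd = "true", seed = 21)
  fit <- fit_kinetics(d, "IS", n_starts = 10)
  # brute force over a log grid centred on truth, 12 points/axis
  axes <- lapply(unlist(p), function(t)
    exp(seq(log(t / 10), log(t * 10), length.out = 12)))
  best <- Inf; best_par <- NULL
  for (Km1 in axes[[1]]) for (Vmax1 in axes[[2]])
    for (a in axes[[3]]) for (b in axes[[4]]) {
      w <- weighted_ssr(is_params(Km1, Vmax1, a, b), d)
      if (w < best) { best <- w; best_par <- c(Km1, Vmax1, a, b) }
    }
  expect_lte(fit$wssr, best)       # the optimizer beats the coarse grid
  # and sits in the same region (within one grid decade per axis)
  expect_true(all(abs(log10(coef(fit) / best_par)) < 1))
})

test_that("fit is invariant to permuting dataset rows", {
  p <- wt_like_truth()
  grid <- make_concentration_grid(0.015, 4, 16)
  d <- simulate_velocity_dataset(p, grid, mode = "relative", cv = 0.05,
                                 n_rep = 3, seed = 4)
  set.seed(99)
  perm <- sample(nrow(d))
  dp <- velocity_dataset(d$c0[perm], d$v0[perm], d$sd[perm],
                         d$n_rep[perm])
  f1 <- fit_kinetics(d, "IS", n_starts = 8, seed = 1)
  f2 <- fit_kinetics(dp, "IS", n_starts = 8, seed = 1)
  expect_equal(coef(f1), coef(f2), tolerance = 1e-8)
  expect_equal(f1$wssr, f2$wssr, tolerance = 1e-10)
})

test_that("the MM-embedded start enforces nesting of the weighted SSR", {
  set.seed(31)
  for (i in 1:10) {
    truth <- if (i %% 2) mm_params(rlogunif(1, 0.1, 10),
                                   rlogunif(1, 1, 100))
             else is_params(rlogunif(1, 0.01, 1), rlogunif(1, 1, 50),
                            rlogunif(1, 1, 300), rlogunif(1, 0.5, 2))
    Km2 <- if (inherits(truth, "mm_params")) truth$Km
           else derive_secondary_parameters(truth)[["Km2"]]
    Km1 <- if (inherits(truth, "mm_params")) truth$Km else truth$Km1
    grid <- make_concentration_grid(Km1, Km2, 12)
    d <- simulate_velocity_dataset(truth, grid, mode = "relative",
                                   cv = 0.05, n_rep = 3,
                                   seed = sample.int(1e6, 1))
    cmp <- compare_rate_laws(d, n_starts = 5, seed = 2)
    expect_lte(cmp$fit_is$wssr, cmp$fit_mm$wssr * (1 + 1e-8))
  }
})

test_that("standard errors are calibrated against a Monte-Carlo ensemble", {
  mmp <- mm_params(1, 10)
  g <- make_concentration_grid(1, 1, 12)
  fits <- lapply(0:199, function(s)
    fit_kinetics(simulate_velocity_dataset(mmp, g, mode = "relative",
                                           cv = 0.05, n_rep = 3,
                                           sd = "true", seed = s),
                 "MM", n_starts = 5))
  est <- t(vapply(fits, coef, numeric(2)))
  se <- t(vapply(fits, function(f) f$stderr, numeric(2)))
  ratio <- apply(est, 2, sd) / colMeans(se)
  expect_true(all(ratio > 0.5 & ratio < 2))
})

test_that("duplicating every point shrinks standard errors by ~1/sqrt(2)", {
  mmp <- mm_params(1, 10)
  d <- simulate_velocity_dataset(mmp, make_concentration_grid(1, 1, 20),
                                 mode = "relative", cv = 0.05, n_rep = 3,
                                 seed = 7)
  d2 <- velocity_dataset(rep(d$c0, 2), rep(d$v0, 2), rep(d$sd, 2),
                         rep(d$n_rep, 2))
  f1 <- fit_kinetics(d, "MM", n_starts = 5)
  f2 <- fit_kinetics(d2, "MM", n_starts = 5)
  expect_equal(unname(f2$stderr / f1$stderr), rep(1 / sqrt(2), 2),
               tolerance = 0.06)
})

test_that("log-space and replicate-run fits are reproducible and sane", {
  p <- wt_like_truth()
  grid <- make_concentration_grid(0.015, 4, 16)
  d <- simulate_velocity_dataset(p, grid, mode = "relative", cv = 0.05,
                                 n_rep = 3, seed = 17)
  f1 <- fit_kinetics(d, "IS", n_starts = 8, seed = 3)
  f2 <- fit_kinetics(d, "IS", n_starts = 8, seed = 3)
  expect_identical(coef(f1), coef(f2))
  expect_true(all(coef(f1) > 0))
  expect_equal(f1$dof, 12)
  expect_s3_class(f1, "kinfit")
  expect_output(print(f1), "Interacting-sites")
  expect_equal(predict(f1, d$c0), fitted(f1))
  expect_equal(length(residuals(f1)), 16)
  rep <- kinfit_report(f1)
  expect_equal(rep$config$weights, "sd")
  expect_true(is.numeric(rep$derived$Km2))
})

test_that("too few points is an informative error", {
  d <- velocity_dataset(c(1, 2, 3), c(2, 3, 4), sd = 0.1)
  expect_error(fit_kinetics(d, "IS"), "at least 5 points")
})
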