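lphys <- log(2) / (6.647 * 24)

test_that("time-activity curve validates its invariants", {
  expect_error(time_activity_curve("x", c(1, 1, 2, 3), c(1, 2, 3, 4)),
               "strictly increasing")
  expect_error(time_activity_curve("x", c(-1, 2, 3, 4), 1:4), ">= 0")
  expect_error(time_activity_curve("x", 1:4, c(-1, 2, 3, 4)), ">= 0")
  tc <- time_activity_curve("tumor", c(1, 24, 72, 168), c(5, 10, 22, 30))
  expect_s3_class(tc, "tac")
  expect_equal(tc$value_kind, "per_gram")
})

test_that("noiseless curves are recovered to high accuracy", {
  t <- c(1, 24, 72, 168)
  f <- fit_biexponential(time_activity_curve("m", t, 10 * exp(-0.01 * t)), lphys)
  expect_equal(f$A1, 10, tolerance = 1e-6)
  expect_equal(f$lambda1, 0.01, tolerance = 1e-6)
  expect_equal(f$A2, 0)

  # uptake curve with one negative amplitude (rise then fall)
  tt <- c(4, 24, 48, 72, 120, 168)
  y <- -20 * exp(-0.05 * tt) + 30 * exp(-0.004 * tt)
  f2 <- fit_biexponential(time_activity_curve("u", tt, y), lphys)
  expect_equal(f2$A1, -20, tolerance = 1e-4)
  expect_equal(f2$lambda1, 0.05, tolerance = 1e-4)
  expect_equal(f2$A2, 30, tolerance = 1e-4)
  expect_equal(f2$lambda2, 0.004, tolerance = 1e-4)

  # constant curve: zero-rate single component
  f3 <- fit_biexponential(time_activity_curve("c", c(0, 24, 48, 96), rep(5, 4)), lphys)
  expect_equal(f3$A1, 5, tolerance = 1e-8)
  expect_equal(f3$lambda1, 0, tolerance = 1e-8)
  expect_equal(f3$A2, 0)
})

test_that("fit errors on insufficient or degenerate data", {
  expect_error(fit_biexponential(time_activity_curve("x", c(1, 2, 3), c(1, 2, 3)), lphys),
               "insufficient")
  expect_error(fit_biexponential(time_activity_curve("x", 1:4, rep(0, 4)), lphys),
               "degenerate")
})

test_that("fit is scale-equivariant", {
  tt <- c(4, 24, 48, 72, 120, 168)
  y <- 40 * exp(-0.02 * tt) + 10 * exp(-0.002 * tt)
  f1 <- fit_biexponential(time_activity_curve("a", tt, y), lphys)
  f2 <- fit_biexponential(time_activity_curve("a", tt, 3 * y), lphys)
  expect_equal(f2$A1, 3 * f1$A1, tolerance = 1e-6)
  expect_equal(f2$A2, 3 * f1$A2, tolerance = 1e-6)
  expect_equal(f2$lambda1, f1$lambda1, tolerance = 1e-6)
  expect_equal(f2$lambda2, f1$lambda2, tolerance = 1e-6)
})

test_that("closed-form cumulated activity matches quadrature", {
  mk <- function(A1, l1, A2, l2)
    structure(list(A1 = A1, lambda1 = l1, A2 = A2, lambda2 = l2,
                   lambda_phys = lphys), class = "biexp_fit")
  # zero activity
  expect_equal(cumulated_activity(mk(0, 0.1, 0, 0.01)), 0)
  # pure physical decay
  expect_equal(cumulated_activity(mk(100, 0, 0, 0)), 100 / lphys)
  # quadrature oracle on the worked example
  f <- mk(50, 0.01, 25, 0.001)
  q <- stats::integrate(function(t) (50 * exp(-0.01 * t) + 25 * exp(-0.001 * t)) *
                          exp(-lphys * t), 0, Inf, rel.tol = 1e-10)$value
  expect_equal(cumulated_activity(f), q, tolerance = 1e-6)
  # divergence guard
  expect_error(cumulated_activity(mk(10, -0.01, 0, 0)), "divergent")
})

test_that("closed form equals quadrature on 100 random integrable parameter sets", {
  set.seed(101)
  for (i in 1:100) {
    A1 <- stats::runif(1, -50, 100); A2 <- stats::runif(1, 0, 100)
    if (A1 + A2 < 0) A1 <- abs(A1)
    l1 <- stats::runif(1, 1e-4, 0.5); l2 <- stats::runif(1, 1e-4, 0.5)
    f <- structure(list(A1 = A1, lambda1 = l1, A2 = A2, lambda2 = l2,
                        lambda_phys = lphys), class = "biexp_fit")
    q <- stats::integrate(function(t) (A1 * exp(-l1 * t) + A2 * exp(-l2 * t)) *
                            exp(-lphys * t), 0, Inf, rel.tol = 1e-10)$value
    expect_equal(cumulated_activity(f), q, tolerance = 1e-6)
  }
})

test_that("marrow curve is 0.36 x blood, per gram only", {
  bl <- time_activity_curve("blood", c(4, 24, 72), c(10, 5, 2.5), "per_gram")
  mr <- marrow_curve_from_blood(bl)
  expect_equal(mr$values, 0.36 * c(10, 5, 2.5))
  expect_equal(mr$values[2], 1.8)           # blood 5 %IA/g -> marrow 1.8
  expect_equal(mr$times_h, bl$times_h)
  expect_equal(mr$region, "marrow")
  z <- marrow_curve_from_blood(time_activity_curve("blood", 1:3, rep(0, 3), "per_gram"))
  expect_true(all(z$values == 0))
  lin <- marrow_curve_from_blood(time_activity_curve("blood", 1:3, 1:3, "per_gram"))
  expect_equal(lin$values, c(0.36, 0.72, 1.08))
  per_organ <- time_activity_curve("blood", 1:3, 1:3, "per_organ")
  expect_error(marrow_curve_from_blood(per_organ), "unit mismatch")
})

test_that("cumulated activity converts to absolute disintegrations", {
  expect_equal(decays_per_mbq_administered(100, value_kind = "per_organ"),
               1 * 3.6e9)
  expect_equal(decays_per_mbq_administered(100, region_mass_g = 0.5,
                                           value_kind = "per_gram"),
               0.5 * 3.6e9)
  expect_error(decays_per_mbq_administered(100, value_kind = "per_gram"),
               "mass")
})

test_that("TAC CSV round-trips with strict headers", {
  tacs <- list(tumor = time_activity_curve("tumor", c(4, 24, 72), c(5, 12, 22),
                                           "per_gram", 3))
  path <- tempfile(fileext = ".csv")
  write_tac_csv(tacs, path)
  back <- read_tac_csv(path)
  expect_equal(back$tumor$values, tacs$tumor$values)
  expect_equal(back$tumor$value_kind, "per_gram")
  bad <- tempfile(fileext = ".csv")
  utils::write.csv(data.frame(reg = "x", t = 1, v = 2), bad, row.names = FALSE)
  expect_error(read_tac_csv(bad), "columns")
  expect_error(read_tac_csv(tempfile()), "not found")
})
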