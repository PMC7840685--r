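test_that("binned averages reduce to exact values on analytic inputs", {
  rec <- data.frame(D = seq(1, 2, length.out = 60), m = 5)
  b <- binned_average(rec, "m", n_bins = 10)
  expect_equal(b$mean[!b$empty], rep(5, sum(!b$empty)))

  rec$lin <- rec$D
  bl <- binned_average(rec, "lin", n_bins = 10)
  hw <- diff(bl$center[1:2]) / 2
  expect_true(all(abs(bl$mean - bl$center)[!bl$empty] <= hw + 1e-12))

  b1 <- binned_average(rec, "lin", n_bins = 1)
  expect_equal(b1$mean, mean(rec$lin))
  # empty bins are flagged, not interpolated
  rec2 <- data.frame(D = c(1, 1.01, 1.99, 2), v = 1:4)
  b2 <- binned_average(rec2, "v", n_bins = 5)
  expect_true(any(b2$empty))
  expect_true(all(is.na(b2$mean[b2$empty])))
})

test_that("cubic fits recover known polynomials", {
  D <- seq(1, 2.5, length.out = 40)
  y <- 2 - 1.5 * D + 0.7 * D^2 - 0.1 * D^3
  cf <- fit_cubic(data.frame(D = D, y = y), "y")
  expect_equal(cf, c(2, -1.5, 0.7, -0.1), tolerance = 1e-9)

  # linear data: vanishing quadratic and cubic coefficients
  cfl <- fit_cubic(data.frame(D = D, y = 3 + 2 * D), "y")
  expect_equal(cfl[3:4], c(0, 0), tolerance = 1e-8)

  expect_error(fit_cubic(data.frame(D = rep(1.5, 10), y = rnorm(10)), "y"),
               "rank")
  expect_error(fit_cubic(data.frame(D = 1:3, y = 1:3), "y"), "at least 5")

  # Monte Carlo: empirical coefficient RMSE within 1.5x the analytic OLS sd
  set.seed(31)
  D <- seq(1, 2.5, length.out = 200)
  X <- cbind(1, D, D^2, D^3)
  sigma <- 0.05
  cov_an <- sigma^2 * solve(crossprod(X))
  true_cf <- c(1, -0.5, 0.3, -0.05)
  err <- replicate(100, {
    y <- drop(X %*% true_cf) + rnorm(200, 0, sigma)
    fit_cubic(data.frame(D = D, y = y), "y") - true_cf
  })
  rmse <- sqrt(rowMeans(err^2))
  expect_true(all(rmse < 1.5 * sqrt(diag(cov_an))))
})

test_that("derivative ratios and their peaks match closed-form calculus", {
  mk_curves <- function(cfP, cfA, cfV, drange = c(1, 2)) {
    structure(list(coef = list(P_Ab = cfP, As_Ab = cfA, Vm_Vb = cfV),
                   D_range = drange,
                   D_grid = seq(drange[1], drange[2], by = 0.001)),
              class = "optimization_curves")
  }
  # identical cubics: R identically 1
  cv <- mk_curves(c(0, 1, 2, 3), c(0, 1, 2, 3), c(0, 1, 2, 3))
  expect_equal(range(compute_R(cv, "R_PA")), c(1, 1), tolerance = 1e-12)
  # proportional cubics: R identically 2
  cv2 <- mk_curves(c(0, 0, 0, 2), c(0, 0, 0, 1), c(0, 0, 0, 1))
  expect_equal(range(compute_R(cv2, "R_PA")), c(2, 2), tolerance = 1e-12)

  # numerator derivative quadratic with interior peak over a linear
  # denominator derivative: analytic peak from the derivative's roots
  cfP <- c(0, 1, 1.5, -1 / 3)              # d/dD = 1 + 3D - D^2
  cfA <- c(0, 1, 0, 0)                     # d/dD = 1
  cv3 <- mk_curves(cfP, cfA, cfA, c(0, 3))
  R <- compute_R(cv3, "R_PA")
  pk <- find_peak(R, cv3$D_grid)
  expect_true(pk$interior)
  expect_equal(pk$D_peak, 1.5, tolerance = 1e-3) # argmax of 1 + 3D - D^2
  # independent oracle: root of the symbolic derivative of R
  dR <- function(D) 3 - 2 * D
  root <- uniroot(dR, c(0, 3))$root
  expect_equal(pk$D_peak, root, tolerance = 1e-3)

  # monotone ratio: flagged instead of fabricated
  cv4 <- mk_curves(c(0, 0, 1, 0), c(0, 1, 0, 0), c(0, 1, 0, 0), c(1, 2))
  pk4 <- find_peak(compute_R(cv4, "R_PA"), cv4$D_grid)
  expect_true(pk4$no_interior_peak)
  expect_true(is.na(pk4$D_peak))

  # quadratic refinement beats the grid: parabola peak at 1.3
  Dg <- seq(1, 2, by = 0.01)
  pk5 <- find_peak(-(Dg - 1.303)^2 + 2, Dg)
  expect_equal(pk5$D_peak, 1.303, tolerance = 0.001)
})

test_that("the pipeline produces consistent records and is reproducible", {
  cfg <- list(generators = list(list(type = "htree", D_target = 1.4,
                                     levels = 6L, total_length = 1500)),
              boxcount = list(resolution = 2), volume = list(resolution = 4),
              profile = list(viewpoints = 51L, spine_radius = 2,
                             resolution = 1),
              fit = list(fine_limit = 1), seed = 2)
  expect_warning(out <- run_pipeline(cfg, progress = FALSE), "too few records")
  expect_equal(nrow(out$records), 1)
  r <- out$records
  # ratio consistency
  expect_equal(r$P_Ab, r$P_As * r$As_Ab, tolerance = 1e-9)
  expect_true(all(c(r$P_As, r$As_Ab, r$P_Ab, r$Vm_Vb) > 0))
  expect_true(r$D >= 1 && r$D <= 3)

  out2 <- suppressWarnings(run_pipeline(cfg, progress = FALSE))
  expect_identical(out$records, out2$records)

  # YAML configs drive the same pipeline
  yf <- tempfile(fileext = ".yaml")
  yaml::write_yaml(cfg, yf)
  out3 <- suppressWarnings(run_pipeline(yf, progress = FALSE))
  expect_equal(out3$records$D, out$records$D, tolerance = 1e-12)

  # failures are manifested, not fatal
  cfg_bad <- cfg
  cfg_bad$generators[[2]] <- list(type = "htree", D_target = 1.4, levels = 3L,
                                  total_length = 20) # far too small to fit
  out4 <- suppressWarnings(run_pipeline(cfg_bad, progress = FALSE))
  expect_equal(nrow(out4$failures), 1)
  expect_match(out4$failures$error, "scaling range")
})

test_that("the optional population check demands the deposited data", {
  expect_error(check_neuron_population(tempfile("no-such-dir")),
               "reconstruction data not found")
})
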