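test_that("excitatory drive is zero without input, peaks on the stimulus, and is linear in contrast", {
  g <- test_grid()
  comps <- expand_condition(condition("none", 0.1, "right"))
  E <- excitatory_drive(comps, g)
  expect_true(all(E$left == 0))
  peak <- which(E$right == max(E$right), arr.ind = TRUE)[1, ]
  expect_equal(g$x[peak[1]], 0)
  expect_equal(g$theta[peak[2]], 45)
  E2 <- excitatory_drive(transform(comps, contrast = 0.2), g)
  expect_equal(E2$right, 2 * E$right, tolerance = 1e-12)
  expect_true(all(excitatory_drive(NULL, g)$right == 0))
})

test_that("feature and spatial attention profiles match their closed forms", {
  expect_equal(feature_profile(0, k = 3), 0.5)
  expect_equal(feature_profile(90, k = 3), exp(-6) - 0.5, tolerance = 1e-12)
  # profile is circular with period 180
  expect_equal(feature_profile(123 + 180), feature_profile(123))

  expect_equal(spatial_profile(0, 0, sigma_ax = 3, p = 0), 1 / sqrt(2 * pi))
  expect_equal(spatial_profile(0, 0, sigma_ax = 1.5, p = 0.17),
               1.5^(-0.17) / sqrt(2 * pi), tolerance = 1e-12)
  # fixed volume at p = 1: integral independent of the extent
  x <- seq(-200, 200, by = 0.01)
  i1 <- sum(spatial_profile(x, 0, 1.5, 1)) * 0.01
  i2 <- sum(spatial_profile(x, 0, 8, 1)) * 0.01
  expect_equal(i1, i2, tolerance = 1e-6)
  expect_error(spatial_profile(0, 0, sigma_ax = -1, p = 0), "positive")
})

test_that("suppression kernel has unit peak, 6-degree iso-orientation width, and orientation-selective narrowing", {
  expect_equal(suppression_kernel(0, 37), 1)
  expect_equal(suppression_kernel(6, 0), exp(-0.5))
  # sigma(20 deg) = 6 * exp(-1)
  s20 <- 6 * exp(-1)
  expect_equal(suppression_kernel(s20, 20), exp(-0.5), tolerance = 1e-12)
  # wrapped offsets: 170 degrees == 10 degrees away
  expect_equal(suppression_kernel(2, 170), suppression_kernel(2, 10))
})

test_that("stimulus-driven gains at the target neuron reproduce the published worked examples", {
  g <- test_grid()
  fs <- gain_report(params_t2_fs(), "FS", grid = g)
  expect_equal(unname(fs$stimulus_driven["none"]), 1)
  expect_equal(unname(round(fs$stimulus_driven[c("small", "medium")], 2)),
               c(0.13, 0.20))
  # large: the printed rounded parameters give 0.3449 (prints as 0.35)
  expect_equal(unname(fs$stimulus_driven["large"]), 0.34490, tolerance = 1e-4)
  expect_equal(round(fs$goal_driven, 2), 2.00)

  es <- gain_report(params_t2_es(), "ES", grid = g)
  expect_equal(unname(round(es$stimulus_driven[c("small", "medium", "large")], 2)),
               c(0.15, 0.28, 0.50))
  # ES split composes center and surround: weaker reduction than large
  expect_gt(es$stimulus_driven["split"], es$stimulus_driven["large"])

  t3 <- gain_report(params_t3_fs(), "FS", grid = g)
  expect_equal(unname(round(t3$stimulus_driven[c("small", "large", "split")], 2)),
               c(0.20, 0.36, 0.36))

  # goal-driven gain at the orthogonal (competitor) orientation is nearly 0
  Av <- goal_attention(g, w_v = 5.03)
  ij <- normatt:::grid_index(g, 0, 135)
  expect_equal(Av$right[ij[1], ij[2]],
               1 - 5.03 * (0.5 - exp(-6)) / sqrt(2 * pi), tolerance = 1e-6)
})

test_that("attention fields keep baseline 1 away from the attended region and FS split equals large exactly", {
  g <- test_grid()
  comps <- expand_condition(condition("small", 0.1, "right"))
  A <- stimulus_attention(comps, g, w_x = 4.7, p = 0.17, variant = "FS")
  far <- abs(g$x) >= 10   # beyond 5 extents of the 1.5-degree profile
  expect_true(all(abs(A$right[far, ] - 1) < 1e-6))

  Al <- stimulus_attention(expand_condition(condition("large", 0.1)), g,
                           4.24, 0.13, "FS")
  As <- stimulus_attention(expand_condition(condition("split", 0.1)), g,
                           4.24, 0.13, "FS")
  expect_identical(As$left, Al$left)
  expect_identical(As$right, Al$right)

  # no competitor: unit field in both variants
  none <- expand_condition(condition("none", 0.1))
  expect_true(all(stimulus_attention(none, g, 3, 0.2, "ES")$left == 1))

  # constraint violation is rejected
  expect_error(stimulus_attention(comps, g, w_x = 9, p = 0, variant = "FS"),
               "non-negativity")
})

test_that("suppressive drive matches a brute-force convolution and is linear", {
  g <- neuron_grid(dx = 2, dtheta = 10)  # 21 x 18 coarse grid
  set.seed(7)
  M <- matrix(runif(length(g$x) * length(g$theta)), length(g$x))
  S <- suppressive_drive(M, g)
  # independent oracle: direct double-loop sum, zero padding in x,
  # circular in theta, cell-averaged spatial kernel weight
  Sb <- matrix(0, nrow(M), ncol(M))
  h <- g$dx / 2
  for (i in seq_along(g$x)) for (j in seq_along(g$theta)) {
    acc <- 0
    for (ii in seq_along(g$x)) for (jj in seq_along(g$theta)) {
      dth <- (g$theta[j] - g$theta[jj] + 90) %% 180 - 90
      if (dth == -90) dth <- 90
      s <- 6 * exp(-abs(dth) / 20)
      u <- g$x[i] - g$x[ii]
      w <- s * sqrt(2 * pi) *
        (pnorm((u + h) / s) - pnorm((u - h) / s)) / g$dx
      acc <- acc + w * M[ii, jj]
    }
    Sb[i, j] <- acc * g$dx * g$dtheta
  }
  expect_lt(max(abs(S - Sb)) / max(abs(Sb)), 1e-10)
  expect_true(all(suppressive_drive(M * 0, g) == 0))
  expect_equal(suppressive_drive(3 * M, g), 3 * S, tolerance = 1e-12)
  expect_error(suppressive_drive(M[-1, ], g), "matrix matching the grid")
})

test_that("population responses are non-negative, zero without drive, and saturate with contrast", {
  g <- test_grid()
  p <- model_params(n = 2, sigma = 0.05, w_I = 0.8, w_x = 0, w_v = 0,
                    p = 0.2, sigma_n = 0.005)
  r0 <- population_response(condition("none", 0), p, g, "FS")
  expect_true(all(r0$left == 0) && all(r0$right == 0))

  # with w_I = 0 and no attention, a competitor cannot reach the target eye
  alone <- population_response(condition("none", 0.05), p, g, "FS")
  p0 <- model_params(n = 2, sigma = 0.05, w_I = 0, w_x = 0, w_v = 0,
                     p = 0.2, sigma_n = 0.005)
  masked <- population_response(condition("large", 0.05), p0, g, "FS")
  expect_equal(predict_dprime(masked, g, 0.005),
               predict_dprime(alone, g, 0.005), tolerance = 1e-12)

  # saturating contrast-response at the matched neuron
  cc <- c(0.005, 0.02, 0.08, 0.32)
  d <- vapply(cc, function(ct) predict_dprime(
    population_response(condition("none", ct), p, g, "FS"), g, 0.005),
    numeric(1))
  expect_true(all(diff(d) > 0))
  expect_lt(d[4] / d[3], d[2] / d[1])   # decelerating growth
  expect_true(all(population_response(condition("split", 0.1),
                                      reference_params("group"), g,
                                      "FS")$right >= 0))
})

test_that("d-prime readout is proportional to the target neuron response", {
  g <- test_grid()
  p <- reference_params("group")
  r <- population_response(condition("medium", 0.05), p, g, "FS")
  d1 <- predict_dprime(r, g, sigma_n = 0.01)
  expect_equal(predict_dprime(r, g, sigma_n = 0.005), 2 * d1)
  ij <- normatt:::grid_index(g, 0, 45)
  expect_equal(d1, r$right[ij[1], ij[2]] / 0.01)
})

test_that("fast psychometric engine agrees with the full field pipeline", {
  g <- cv_grid()
  p <- reference_params("S2")
  for (nm in c("none", "small", "split")) {
    full <- population_response(condition(nm, 0.07), p, g, "FS")
    d_full <- predict_dprime(full, g, p$sigma_n)
    d_fast <- predict_psychometric(p, "FS", contrasts = 0.07,
                                   conditions = nm, grid = g)$dprime
    expect_equal(d_fast, d_full, tolerance = 1e-12)
  }
})

test_that("mirroring the stimulus eyes and swapping directional weights swaps the responses exactly", {
  g <- cv_grid()
  p <- model_params(n = 2, sigma = 0.04, w_I = 1, w_x = 3, w_v = 4,
                    p = 0.3, sigma_n = 0.005, w_LR = 2.5, w_RL = 0.4)
  p_swap <- model_params(n = 2, sigma = 0.04, w_I = 1, w_x = 3, w_v = 4,
                         p = 0.3, sigma_n = 0.005, w_LR = 0.4, w_RL = 2.5)
  for (nm in c("large", "split")) {
    r <- population_response(condition(nm, 0.06, "right"), p, g, "ES")
    m <- population_response(condition(nm, 0.06, "left"), p_swap, g, "ES")
    expect_identical(r$right, m$left)
    expect_identical(r$left, m$right)
  }
})

test_that("predictions converge under grid refinement", {
  p <- reference_params("group")
  cc <- default_contrast_ladder()
  d1 <- predict_psychometric(p, "FS", cc, grid = neuron_grid(dx = 0.25,
                                                             dtheta = 1))
  d2 <- predict_psychometric(p, "FS", cc, grid = neuron_grid(dx = 0.125,
                                                             dtheta = 1))
  expect_lt(max(abs(d1$dprime - d2$dprime) / pmax(d2$dprime, 0.01)), 0.01)
})

test_that("noise-free model curves show the size-dependent gain regimes", {
  # descriptive refit of the model's own predictions at the group
  # parameters: small/medium cut the asymptote, large/split shift the
  # curve rightward with the asymptote preserved
  pred <- predict_psychometric(reference_params("group"), "FS",
                               grid = test_grid())
  cells <- data.frame(observer = "m", target_eye = "right",
                      condition = pred$condition, contrast = pred$contrast,
                      dprime = pred$dprime)
  f <- normatt:::fit_nr_profiled(cells)
  par <- f$par
  v <- function(cd, pm) par[[pm]][par$condition == cd]
  expect_lt(v("small", "d_m"), 0.7 * v("none", "d_m"))
  expect_lt(v("medium", "d_m"), 0.9 * v("none", "d_m"))
  expect_gt(v("large", "d_m"), 0.95 * v("none", "d_m"))
  expect_gt(v("split", "d_m"), 0.95 * v("none", "d_m"))
  expect_gt(v("large", "c50"), 2 * v("none", "c50"))
  expect_gt(v("split", "c50"), 2 * v("none", "c50"))
})

test_that("the compound attention field degenerates to FS or ES when one magnitude vanishes", {
  g <- cv_grid()
  comps <- expand_condition(condition("split", 0.1, "right"))
  fs <- stimulus_attention(comps, g, 3.2, 0.25, "FS")
  es <- stimulus_attention(comps, g, 1.1, 0.25, "ES")
  both <- stimulus_attention(comps, g, c(3.2, 1.1), 0.25, "compound")
  expect_equal(stimulus_attention(comps, g, c(3.2, 0), 0.25, "compound"),
               fs, tolerance = 1e-12)
  expect_equal(stimulus_attention(comps, g, c(0, 1.1), 0.25, "compound"),
               es, tolerance = 1e-12)
  # deviations add
  expect_equal(both$left - 1, (fs$left - 1) + (es$left - 1),
               tolerance = 1e-12)
})

test_that("monocular competitors lose every pathway to the target when all couplings vanish", {
  # with w_x = w_v = w_I = 0 the small/medium/large competitors cannot
  # affect the target eye at all; the split condition is the exception by
  # design, since its annular surround feeds the target eye's own
  # normalization pool
  g <- cv_grid()
  p <- model_params(n = 2, sigma = 0.05, w_I = 0, w_x = 0, w_v = 0,
                    p = 0.2, sigma_n = 0.005)
  d <- predict_psychometric(p, "FS", contrasts = c(0.01, 0.1),
                            conditions = c("none", "small", "medium",
                                           "large"), grid = g)
  m <- matrix(d$dprime, nrow = 2)
  expect_true(all(abs(m - m[, 1]) < 1e-12))
  dsplit <- predict_psychometric(p, "FS", contrasts = c(0.01, 0.1),
                                 conditions = "split", grid = g)
  expect_true(all(dsplit$dprime < m[, 1]))
})
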