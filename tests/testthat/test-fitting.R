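# Shared fixtures for the fitting tests: one synthetic cohort generated
# from the feature-specific model, fit once per variant on the coarse grid.
fit_grid <- cv_grid()
fs_trials <- generate_trials(group_cohort_design(seed = 31), "FS",
                             grid = fit_grid)
fit_fs <- normatt(fs_trials, "FS", grid = fit_grid, n_starts = 4, seed = 2)
fit_es <- normatt(fs_trials, "ES", grid = fit_grid, n_starts = 4, seed = 2)

test_that("noise-free model curves are refit to near-zero objective with parameters recovered", {
  truth <- reference_params("group")
  pred <- predict_psychometric(truth, "FS", grid = fit_grid)
  cells <- data.frame(target_eye = "right", condition = pred$condition,
                      contrast = pred$contrast, dprime = pred$dprime)
  engines <- normatt:::prepare_engines(cells, fit_grid, 0.23)
  starts <- c(list(normatt:::default_start(
    normatt:::free_param_names("FS", FALSE))),
    normatt:::random_starts(normatt:::free_param_names("FS", FALSE), 5, 4))
  fit <- normatt:::fit_cells_lm(cells, engines, "FS", starts = starts)
  expect_lt(fit$sse, 1e-6)
  est <- fit$coefficients
  for (pm in c("n", "w_x", "w_v", "p", "sigma_n"))
    expect_lt(abs(est[[pm]] / truth[[pm]] - 1), 0.05)
})

test_that("the kept optimum is at least as good as every converged start", {
  expect_lte(fit_fs$sse, min(fit_fs$starts$sse[fit_fs$starts$ok]) + 1e-8)
  expect_true(all(fit_fs$starts$ok))
})

test_that("the mismatched variant cannot reproduce noise-free curves of the generating variant", {
  truth <- reference_params("group")
  pred <- predict_psychometric(truth, "FS", grid = fit_grid)
  cells <- data.frame(target_eye = "right", condition = pred$condition,
                      contrast = pred$contrast, dprime = pred$dprime)
  engines <- normatt:::prepare_engines(cells, fit_grid, 0.23)
  starts <- c(list(normatt:::default_start(
    normatt:::free_param_names("ES", FALSE))),
    normatt:::random_starts(normatt:::free_param_names("ES", FALSE), 5, 4))
  mis <- normatt:::fit_cells_lm(cells, engines, "ES", starts = starts)
  # the FS refit of the same curves reaches sse ~ 0 (previous test);
  # the ES family stays bounded away from them
  expect_gt(mis$sse, 0.05)
  expect_gt(fit_fs$r_squared, 0.9)
  expect_gt(fit_es$r_squared, 0.9)
})

test_that("pinning the stimulus-driven attention parameters barely costs fit quality", {
  pinned <- normatt(fs_trials, "FS", grid = fit_grid, n_starts = 3,
                    seed = 2,
                    fixed = c(w_x = 4.24, p = 0.13))
  expect_false(any(c("w_x", "p") %in% pinned$free))
  expect_equal(unname(coef(pinned)[c("w_x", "p")]), c(4.24, 0.13))
  expect_lt(fit_fs$r_squared - pinned$r_squared, 0.02)
})

test_that("fitted-model methods are coherent", {
  expect_equal(length(fitted(fit_fs)), nrow(fit_fs$cells))
  expect_equal(residuals(fit_fs), fit_fs$cells$dprime - fitted(fit_fs))
  pr <- predict(fit_fs, contrasts = c(0.01, 0.1))
  expect_equal(nrow(pr), 2 * 5)
  expect_true(all(pr$dprime >= 0))
  gains <- gain_report(fit_fs)
  expect_equal(unname(gains$stimulus_driven["none"]), 1)
  expect_output(print(summary(fit_fs)), "stimulus-driven gain")
  sim <- simulate(fit_fs, seed = 7, trials_per_cell = 10)
  expect_equal(nrow(sim), 5 * 9 * 10)
  ll <- logLik(fit_fs)
  expect_equal(attr(ll, "df"), 7)
  expect_true(is.finite(as.numeric(ll)))
})

test_that("bootstrap refits give seed-stable percentile intervals that cover the estimate", {
  bt <- bootstrap_params(fit_fs, B = 12, seed = 5)
  bt2 <- bootstrap_params(fit_fs, B = 12, seed = 5)
  expect_identical(bt$draws, bt2$draws)
  expect_true(all(bt$ci[, "lo95"] <= bt$ci[, "lo68"]))
  expect_true(all(bt$ci[, "hi68"] <= bt$ci[, "hi95"]))
})

test_that("the Hessian is full rank for the full design but p is unconstrained without response-gain conditions", {
  h <- hessian_rank(fit_fs)
  expect_equal(h$rank, 7)
  tr3 <- fs_trials[fs_trials$condition %in% c("none", "large", "split"), ]
  fit3 <- normatt(tr3, "FS", grid = fit_grid, n_starts = 3, seed = 2,
                  maxiter = 300)
  h3 <- hessian_rank(fit3)
  expect_equal(names(which.max(abs(h3$projection))), "p")
  expect_gt(abs(h3$projection[["p"]]), 0.6)
})

test_that("a structurally flat parameter is detected as rank deficiency", {
  # with right-eye targets only, the right-to-left interocular weight
  # never enters the readout, so the directional fit has a flat direction
  tr3 <- fs_trials[fs_trials$condition %in% c("none", "large", "split"), ]
  fitd <- normatt(tr3, "FS", grid = fit_grid, n_starts = 2, seed = 2,
                  directional = TRUE)
  hd <- hessian_rank(fitd)
  expect_lt(hd$rank, length(fitd$free))
  # and a hand-built duplicated parameter shows the same signature
  quad <- function(th) (th[1] + th[2] - 1)^2 + th[3]^2
  hq <- hessian_rank(quad, par = c(a = 0.5, b = 0.5, c = 0))
  expect_equal(hq$rank, 2)
})

test_that("a redundant attention component neither helps the fit nor lowers the BIC", {
  fit_cp <- normatt(fs_trials, "compound", grid = fit_grid, n_starts = 4,
                    seed = 2)
  expect_equal(length(fit_cp$free), 8)
  # the fitted eye-specific magnitude is reported; with noisy synthetic
  # data the two deviation patterns trade off and it need not vanish
  cat("\ncompound fit w_xf =", round(coef(fit_cp)[["w_xf"]], 2),
      " w_xe =", round(coef(fit_cp)[["w_xe"]], 2), "\n")
  bic <- bic_compare(fs_trials, c("FS", "compound"),
                     fits = list(FS = fit_fs, compound = fit_cp),
                     grid = fit_grid)
  expect_gte(bic$BIC[bic$variant == "compound"],
             bic$BIC[bic$variant == "FS"] - 1e-6)
})

test_that("variants with identical predictions get identical likelihoods and BIC", {
  p0 <- model_params(n = 2, sigma = 0.05, w_I = 0.5, w_x = 0, w_v = 4,
                     p = 0.2, sigma_n = 0.005)
  counts <- normatt:::pooled_counts(fs_trials)
  engines <- normatt:::prepare_engines(counts, fit_grid, 0.23)
  ll_fs <- normatt:::binomial_loglik(counts, engines, p0, "FS")
  ll_es <- normatt:::binomial_loglik(counts, engines, p0, "ES")
  expect_equal(ll_fs, ll_es, tolerance = 1e-12)
})

test_that("training fit quality exceeds held-out fit quality on average", {
  cells_obs <- normatt:::aggregate_cells(fs_trials)
  engines <- normatt:::prepare_engines(fit_fs$cells, fit_grid, 0.23)
  warm <- coef(fit_fs)[fit_fs$free]
  n_tr <- round(cells_obs$n_trials / 2)
  set.seed(99)
  gap <- replicate(50, {
    k_tr <- rhyper(nrow(cells_obs), cells_obs$n_correct,
                   cells_obs$n_trials - cells_obs$n_correct, n_tr)
    mk <- function(k, n) {
      cb <- cells_obs
      cb$dprime <- estimate_dprime(k, n)
      stats::aggregate(list(dprime = cb$dprime),
                       by = list(target_eye = cb$target_eye,
                                 condition = cb$condition,
                                 contrast = cb$contrast), FUN = mean)
    }
    train <- mk(k_tr, n_tr)
    test <- mk(cells_obs$n_correct - k_tr, cells_obs$n_trials - n_tr)
    fit <- normatt:::fit_cells_lm(train, engines, "FS",
                                  starts = list(warm), maxiter = 40)
    pr <- normatt:::predict_cells(engines, fit$params, "FS", test)
    r2_test <- 1 - sum((pr$pred - test$dprime)^2) /
      sum((test$dprime - mean(test$dprime))^2)
    fit$r_squared - r2_test
  })
  expect_gt(mean(gap), 0)
})
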