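#' Bootstrap confidence intervals for the model parameters
#'
#' Resamples individual trials with replacement within each
#' (observer, condition, contrast) cell, recomputes the group-averaged
#' d-prime estimates and refits the model, warm-started at the original
#' estimate. Percentile intervals at 68% and 95% are reported per
#' parameter.
#'
#' @param object a fitted [normatt()] model.
#' @param B number of bootstrap resamples (the full procedure uses 2000;
#'   smaller values are fine for exploration).
#' @param seed integer seed.
#' @param n_random extra random starts per resample on top of the warm
#'   start (default 0).
#' @param maxiter Levenberg-Marquardt iteration cap per refit.
#' @return object of class `"normatt_boot"`: draws matrix (B x params)
#'   and a CI table.
#' @export
bootstrap_params <- function(object, B = 2000, seed = 1, n_random = 0,
                             maxiter = 50) {
  stopifnot(inherits(object, "normatt"))
  cells_obs <- object$cells_observer
  set.seed(seed)
  free <- object$free
  draws <- matrix(NA_real_, B, length(free),
                  dimnames = list(NULL, free))
  warm <- object$coefficients[free]
  extra <- if (n_random > 0) random_starts(free, n_random, seed + 1) else NULL
  engines <- prepare_engines(object$cells, object$grid,
                             object$competitor_contrast)
  for (b in seq_len(B)) {
    k_star <- stats::rbinom(nrow(cells_obs), cells_obs$n_trials,
                            cells_obs$n_correct / cells_obs$n_trials)
    cb <- cells_obs
    cb$dprime <- estimate_dprime(k_star, cb$n_trials)
    cells <- order_cells(stats::aggregate(
      list(dprime = cb$dprime),
      by = list(target_eye = cb$target_eye, condition = cb$condition,
                contrast = cb$contrast),
      FUN = mean))
    fit <- fit_cells_lm(cells, engines, object$variant,
                        object$directional, object$fixed,
                        starts = c(list(warm), extra), maxiter = maxiter)
    draws[b, ] <- fit$coefficients[free]
  }
  ci <- t(apply(draws, 2, stats::quantile,
                probs = c(0.16, 0.84, 0.025, 0.975)))
  colnames(ci) <- c("lo68", "hi68", "lo95", "hi95")
  structure(list(draws = draws, ci = ci, estimate = warm, B = B,
                 seed = seed),
            class = "normatt_boot")
}

#' @export
print.normatt_boot <- function(x, digits = 3, ...) {
  cat(sprintf("bootstrap parameter intervals (B = %d)\n", x$B))
  tab <- cbind(estimate = x$estimate, x$ci)
  print(signif(tab, digits))
  invisible(x)
}

#' Cross-validated comparison of attention variants
#'
#' Repeatedly partitions the raw trials at random into a training and a
#' test half (within each observer-condition-contrast cell), fits each
#' attention variant to the group-averaged training estimates, and scores
#' it by the coefficient of determination on the group-averaged test
#' estimates. The distribution of `R2[first] - R2[second]` over
#' repetitions is the comparison index: the first variant is declared
#' better if at least 95% of the distribution is above zero (and the
#' second if at least 95% is below).
#'
#' Refits are warm-started at each variant's full-data estimate (plus
#' `n_random` random starts). Repetitions whose split empties a cell are
#' redrawn and counted.
#'
#' @param trials trial table.
#' @param variants two attention variants to compare.
#' @param B number of random partitions (the full procedure uses 2000; 200
#'   gives a stable exceedance fraction at a fraction of the cost).
#' @param split_fraction fraction of each cell's trials assigned to the
#'   training set.
#' @param seed integer seed.
#' @param grid fitting grid; the default coarse grid (`dx = 1`,
#'   `dtheta = 3`) keeps the repeated refits cheap.
#' @param n_starts starts for the two full-data fits.
#' @param n_random extra random starts per refit.
#' @param competitor_contrast competitor RMS contrast.
#' @return object of class `"normatt_cv"`: the `r2_diff` distribution,
#'   exceedance fraction, per-variant test R2, decision label and the two
#'   full-data fits.
#' @export
crossval_compare <- function(trials, variants = c("FS", "ES"), B = 200,
                             split_fraction = 0.5, seed = 1,
                             grid = neuron_grid(dx = 1, dtheta = 3),
                             n_starts = 5, n_random = 0,
                             competitor_contrast = DEFAULT_COMPETITOR_CONTRAST) {
  stopifnot(length(variants) == 2L, B >= 100,
            split_fraction > 0, split_fraction < 1)
  cells_obs <- aggregate_cells(trials)
  full <- lapply(variants, function(v)
    normatt(trials, v, grid = grid, n_starts = n_starts, seed = seed,
            competitor_contrast = competitor_contrast))
  names(full) <- variants
  group_cells <- function(cb) {
    order_cells(stats::aggregate(list(dprime = cb$dprime),
                                 by = list(target_eye = cb$target_eye,
                                           condition = cb$condition,
                                           contrast = cb$contrast),
                                 FUN = mean))
  }
  engines <- prepare_engines(full[[1]]$cells, grid, competitor_contrast)
  n_tr <- round(split_fraction * cells_obs$n_trials)
  set.seed(seed)
  r2 <- r2_train <- matrix(NA_real_, B, 2, dimnames = list(NULL, variants))
  redraws <- 0L
  for (b in seq_len(B)) {
    repeat {
      ## trial-level random partition within each cell: the number of
      ## correct trials landing in the training half is hypergeometric
      k_tr <- stats::rhyper(nrow(cells_obs), cells_obs$n_correct,
                            cells_obs$n_trials - cells_obs$n_correct, n_tr)
      if (all(n_tr >= 1) && all(cells_obs$n_trials - n_tr >= 1)) break
      redraws <- redraws + 1L
    }
    tr <- cells_obs
    tr$dprime <- estimate_dprime(k_tr, n_tr)
    te <- cells_obs
    te$dprime <- estimate_dprime(cells_obs$n_correct - k_tr,
                                 cells_obs$n_trials - n_tr)
    train <- group_cells(tr)
    test <- group_cells(te)
    sst <- sum((test$dprime - mean(test$dprime))^2)
    for (v in variants) {
      warm <- full[[v]]$coefficients[full[[v]]$free]
      extra <- if (n_random > 0)
        random_starts(full[[v]]$free, n_random, seed + b) else NULL
      fit <- fit_cells_lm(train, engines, v, FALSE, NULL,
                          starts = c(list(warm), extra), maxiter = 50)
      pr <- predict_cells(engines, fit$params, v, test)
      r2[b, v] <- 1 - sum((pr$pred - test$dprime)^2) / sst
      r2_train[b, v] <- fit$r_squared
    }
  }
  diff <- r2[, 1] - r2[, 2]
  exceedance <- mean(diff > 0)
  decision <- if (exceedance >= 0.95) {
    paste(variants[1], "outperforms", variants[2])
  } else if (exceedance <= 0.05) {
    paste(variants[2], "outperforms", variants[1])
  } else "no decision"
  structure(list(r2 = r2, r2_train = r2_train, r2_diff = diff,
                 exceedance = exceedance, decision = decision, fits = full,
                 B = B, seed = seed, redraws = redraws),
            class = "normatt_cv")
}

#' @export
print.normatt_cv <- function(x, ...) {
  v <- colnames(x$r2)
  cat(sprintf("cross-validated model comparison (%s vs %s, B = %d)\n",
              v[1], v[2], x$B))
  cat(sprintf("  mean test R2: %s %.3f, %s %.3f\n",
              v[1], mean(x$r2[, 1]), v[2], mean(x$r2[, 2])))
  cat(sprintf("  fraction of splits with R2_%s > R2_%s: %.3f\n",
              v[1], v[2], x$exceedance))
  cat("  decision:", x$decision, "\n")
  invisible(x)
}

#' BIC comparison of attention variants
#'
#' Likelihood-based complement to [crossval_compare()]: per-cell correct
#' counts (pooled across observers) are modeled as binomial with
#' `P(correct) = pnorm(d'_model / 2)` (probabilities clipped to
#' `[1e-6, 1 - 1e-6]`), the likelihood is maximized over the free
#' parameters starting from the least-squares estimate, and
#' `BIC = k * log(N_cells) - 2 * logLik` is reported per variant (lower is
#' better).
#'
#' @param trials trial table.
#' @param variants attention variants to compare.
#' @param fits optional named list of [normatt()] fits to reuse.
#' @param grid fitting grid.
#' @param seed seed for the least-squares starts.
#' @param n_starts starts for the least-squares fits.
#' @param competitor_contrast competitor RMS contrast.
#' @return data frame with one row per variant: `k` (free parameters),
#'   `logLik`, `BIC`, and `delta_BIC` relative to the best.
#' @export
bic_compare <- function(trials, variants = c("FS", "ES"), fits = NULL,
                        grid = neuron_grid(dx = 1, dtheta = 3), seed = 1,
                        n_starts = 5,
                        competitor_contrast = DEFAULT_COMPETITOR_CONTRAST) {
  counts <- pooled_counts(trials)
  engines <- prepare_engines(counts, grid, competitor_contrast)
  rows <- lapply(variants, function(v) {
    fit <- if (!is.null(fits) && v %in% names(fits)) fits[[v]] else
      normatt(trials, v, grid = grid, n_starts = n_starts, seed = seed,
              competitor_contrast = competitor_contrast)
    free <- fit$free
    bounds <- param_bounds(free)
    negll <- function(theta) {
      v_full <- c(theta, fit$fixed)
      names(v_full) <- c(free, names(fit$fixed))
      pars <- vector_to_params(v_full, fit$variant, fit$directional)
      pr <- predict_cells(engines, pars, fit$variant, counts)
      p <- pmin(pmax(stats::pnorm(pr$pred / 2), 1e-6), 1 - 1e-6)
      -sum(stats::dbinom(counts$n_correct, counts$n_trials, p,
                         log = TRUE)) + 1e3 * max(0, -pr$min_gain)
    }
    ml <- stats::nlminb(fit$coefficients[free], negll,
                        lower = bounds$lower, upper = bounds$upper)
    k <- length(free)
    ll <- -ml$objective
    data.frame(variant = v, k = k, logLik = ll,
               BIC = k * log(nrow(counts)) - 2 * ll)
  })
  out <- do.call(rbind, rows)
  out$delta_BIC <- out$BIC - min(out$BIC)
  out
}

#' Numerical Hessian rank and identifiability report
#'
#' Computes the Hessian of the least-squares objective at the optimum by
#' central differences, its rank from the singular values (tolerance
#' `length(sv) * eps * max(sv)`), and the projection of the eigenvector of
#' the smallest eigenvalue onto each parameter axis. A full-rank Hessian
#' indicates no redundant parameters; a smallest-eigenvalue eigenvector
#' loading heavily on one parameter flags that parameter as weakly
#' constrained by the data.
#'
#' @param object a fitted [normatt()] model, or a scalar objective
#'   function of a parameter vector.
#' @param ... unused (fitted-model method) or passed on.
#' @param par parameter vector at which to differentiate (function
#'   method).
#' @param rel_step relative step for the central differences.
#' The rank and eigen-structure are evaluated on the Hessian with respect
#' to relatively scaled parameters (each coordinate divided by its
#' magnitude), so that parameters of very different units are comparable;
#' the tolerance for a zero singular value is
#' `length(par) * sqrt(eps) * max(sv)`, matched to the accuracy of the
#' finite differences. The raw-coordinate Hessian is returned as well.
#'
#' @return list with `hessian` (raw), `scaled_hessian`, `rank`,
#'   `singular_values`, `tol`, `min_eigenvalue`, and `projection`
#'   (components of the smallest eigenvector per scaled parameter axis).
#' @export
hessian_rank <- function(object, ...) UseMethod("hessian_rank")

#' @rdname hessian_rank
#' @export
hessian_rank.function <- function(object, par, rel_step = 1e-4, ...) {
  fn <- object
  k <- length(par)
  H <- matrix(NA_real_, k, k, dimnames = list(names(par), names(par)))
  scale <- pmax(abs(par), 1e-3)
  step <- rel_step * scale
  f0 <- fn(par)
  for (attempt in 1:4) {
    bad <- FALSE
    for (i in seq_len(k)) {
      for (j in i:k) {
        ei <- ej <- numeric(k)
        ei[i] <- step[i]
        ej[j] <- step[j]
        if (i == j) {
          h <- (fn(par + ei) - 2 * f0 + fn(par - ei)) / step[i]^2
        } else {
          h <- (fn(par + ei + ej) - fn(par + ei - ej) -
                  fn(par - ei + ej) + fn(par - ei - ej)) /
            (4 * step[i] * step[j])
        }
        if (!is.finite(h)) { bad <- TRUE; break }
        H[i, j] <- H[j, i] <- h
      }
      if (bad) break
    }
    if (!bad) break
    step <- step / 10
    if (attempt == 4) stop("non-finite second differences even after ",
                           "shrinking the step")
  }
  Hs <- H * (scale %o% scale)
  sv <- svd(Hs)$d
  tol <- length(sv) * sqrt(.Machine$double.eps) * max(sv)
  eg <- eigen((Hs + t(Hs)) / 2, symmetric = TRUE)
  vmin <- eg$vectors[, k]
  names(vmin) <- names(par)
  list(hessian = H, scaled_hessian = Hs, rank = sum(sv > tol),
       singular_values = sv, tol = tol,
       min_eigenvalue = eg$values[k], projection = vmin)
}

#' @rdname hessian_rank
#' @export
hessian_rank.normatt <- function(object, rel_step = 1e-4, ...) {
  engines <- prepare_engines(object$cells, object$grid,
                             object$competitor_contrast)
  free <- object$free
  obs <- object$cells$dprime
  fn <- function(theta) {
    v <- c(theta, object$fixed)
    names(v) <- c(free, names(object$fixed))
    pr <- predict_cells(engines,
                        vector_to_params(v, object$variant,
                                         object$directional),
                        object$variant, object$cells)
    sum((pr$pred - obs)^2) + (1e3 * max(0, -pr$min_gain))^2
  }
  hessian_rank(fn, par = object$coefficients[free], rel_step = rel_step)
}
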