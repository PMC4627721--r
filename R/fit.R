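## Seven-parameter least-squares fit of the normalization/attention model.

## Optimizer bounds, in the package's drive-unit convention (see vignette).
param_bounds <- function(names) {
  lower <- c(n = 0.5, sigma = 1e-6, w_I = 0, w_LR = 0, w_RL = 0,
             w_x = 0, w_xf = 0, w_xe = 0, w_v = 0, p = 0, sigma_n = 1e-4)
  upper <- c(n = 6, sigma = 0.5, w_I = 5, w_LR = 5, w_RL = 5,
             w_x = 10, w_xf = 10, w_xe = 10, w_v = 10, p = 1, sigma_n = 20)
  list(lower = lower[names], upper = upper[names])
}

free_param_names <- function(variant, directional) {
  nm <- c("n", "sigma",
          if (directional) c("w_LR", "w_RL") else "w_I",
          if (variant == "compound") c("w_xf", "w_xe") else "w_x",
          "w_v", "p", "sigma_n")
  nm
}

vector_to_params <- function(v, variant, directional) {
  ## tolerate tiny bound excursions from finite-difference probing
  v <- pmax(v, c(n = 1e-6, sigma = 1e-12, sigma_n = 1e-12)[names(v)] %|na|% 0)
  if ("p" %in% names(v)) v[["p"]] <- min(v[["p"]], 1)
  w_x <- if (variant == "compound") c(v[["w_xf"]], v[["w_xe"]]) else v[["w_x"]]
  if (directional) {
    model_params(n = v[["n"]], sigma = v[["sigma"]],
                 w_I = (v[["w_LR"]] + v[["w_RL"]]) / 2, w_x = w_x,
                 w_v = v[["w_v"]], p = v[["p"]], sigma_n = v[["sigma_n"]],
                 w_LR = v[["w_LR"]], w_RL = v[["w_RL"]])
  } else {
    model_params(n = v[["n"]], sigma = v[["sigma"]], w_I = v[["w_I"]],
                 w_x = w_x, w_v = v[["w_v"]], p = v[["p"]],
                 sigma_n = v[["sigma_n"]])
  }
}

## Engines for a cell table possibly spanning both target eyes (main +
## eye-swap sessions). Row mappings are recomputed per call in
## predict_cells, so engines can be reused across resampled cell frames
## that share the same condition/contrast support.
prepare_engines <- function(cells, grid, competitor_contrast) {
  lapply(split(cells, cells$target_eye), function(part) {
    conds <- as.character(unique(part$condition))
    contrasts <- sort(unique(part$contrast))
    psychometric_engine(conds, contrasts, grid,
                        target_eye = unique(part$target_eye),
                        competitor_contrast = competitor_contrast)
  })
}

## Model prediction for every cell row, via the fast engines; also returns
## the worst attentional gain so the optimizer can be penalized smoothly
## outside the non-negativity constraint.
predict_cells <- function(engines, params, variant, cells) {
  pred <- numeric(nrow(cells))
  min_gain <- Inf
  for (eye in names(engines)) {
    eng <- engines[[eye]]
    rows <- which(cells$target_eye == eye)
    if (length(rows) == 0L) next
    ci <- match(cells$condition[rows],
                vapply(eng$conditions, `[[`, "", "name"))
    mi <- match(cells$contrast[rows], eng$contrasts)
    if (anyNA(ci) || anyNA(mi))
      stop("cell table contains conditions or contrasts the engine was ",
           "not prepared for")
    d <- engine_dprime(eng, params, variant, negative_gain = "clamp")
    min_gain <- min(min_gain, attr(d, "min_gain"))
    pred[rows] <- d[cbind(ci, mi)]
  }
  list(pred = pred, min_gain = min_gain)
}

lm_residual_fun <- function(cells, engines, variant, directional,
                            fixed, free_names) {
  obs <- cells$dprime
  function(theta) {
    v <- c(theta, fixed)
    names(v) <- c(free_names, names(fixed))
    pr <- predict_cells(engines, vector_to_params(v, variant, directional),
                        variant, cells)
    penalty <- 1e3 * max(0, -pr$min_gain)
    c(pr$pred - obs, penalty)
  }
}

default_start <- function(free_names) {
  st <- c(n = 2, sigma = CALIBRATED_SIGMA, w_I = 1, w_LR = 1, w_RL = 1,
          w_x = 3, w_xf = 3, w_xe = 1, w_v = 4, p = 0.3,
          sigma_n = CALIBRATED_SIGMA_N)
  st[free_names]
}

random_starts <- function(free_names, n, seed) {
  lo <- c(n = 1, sigma = 1e-3, w_I = 0, w_LR = 0, w_RL = 0, w_x = 0.5,
          w_xf = 0.5, w_xe = 0, w_v = 0.5, p = 0, sigma_n = 1e-3)
  hi <- c(n = 3, sigma = 0.1, w_I = 2, w_LR = 2, w_RL = 2, w_x = 6,
          w_xf = 6, w_xe = 2, w_v = 6, p = 0.6, sigma_n = 1)
  set.seed(seed)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    u <- stats::runif(length(free_names))
    loggy <- free_names %in% c("sigma", "sigma_n")
    v <- ifelse(loggy,
                exp(log(lo[free_names]) + u * (log(hi[free_names]) -
                                                 log(lo[free_names]))),
                lo[free_names] + u * (hi[free_names] - lo[free_names]))
    names(v) <- free_names
    out[[i]] <- v
  }
  out
}

## Core multi-start bounded Levenberg-Marquardt driver shared by the
## fitter, the bootstrap and the cross-validation loop.
fit_cells_lm <- function(cells, engines, variant, directional = FALSE,
                         fixed = NULL, starts, maxiter = 100) {
  free_names <- setdiff(free_param_names(variant, directional),
                        names(fixed))
  if (length(free_names) == 0L) stop("no free parameters left to fit")
  bounds <- param_bounds(free_names)
  resid_fn <- lm_residual_fun(cells, engines, variant, directional,
                              fixed, free_names)
  runs <- lapply(starts, function(st) {
    st <- pmin(pmax(st[free_names], bounds$lower), bounds$upper)
    fit <- tryCatch(
      minpack.lm::nls.lm(par = st, fn = resid_fn,
                         lower = bounds$lower, upper = bounds$upper,
                         control = minpack.lm::nls.lm.control(
                           maxiter = maxiter, nprint = 0)),
      error = function(e) e)
    if (inherits(fit, "error")) return(list(ok = FALSE, message = conditionMessage(fit)))
    list(ok = TRUE, par = stats::coef(fit), sse = fit$deviance,
         info = fit$info, message = fit$message, niter = fit$niter)
  })
  ok <- vapply(runs, `[[`, logical(1), "ok")
  if (!any(ok)) {
    msgs <- vapply(runs, function(r) r$message %||% "", "")
    stop("all optimization starts failed:\n",
         paste(sprintf("  start %d: %s", seq_along(msgs), msgs),
               collapse = "\n"))
  }
  sses <- vapply(runs, function(r) if (r$ok) r$sse else Inf, numeric(1))
  best <- runs[[which.min(sses)]]
  v <- c(best$par, fixed)
  names(v) <- c(free_names, names(fixed))
  params <- vector_to_params(v, variant, directional)
  pr <- predict_cells(engines, params, variant, cells)
  sse <- sum((pr$pred - cells$dprime)^2)
  sst <- sum((cells$dprime - mean(cells$dprime))^2)
  list(coefficients = v[c(free_names, names(fixed))], free = free_names,
       params = params, sse = sse, r_squared = 1 - sse / sst,
       fitted = pr$pred, min_gain = pr$min_gain,
       starts = data.frame(sse = sses,
                           ok = ok,
                           niter = vapply(runs, function(r)
                             if (r$ok) r$niter else NA_integer_, 0L)),
       best_message = best$message)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

`%|na|%` <- function(a, b) { a[is.na(a)] <- b; a }

#' Fit the normalization/attention model to trial data
#'
#' Least-squares fit of the population model of interocular suppression to
#' a trial table: d-prime is estimated per (condition, contrast) cell,
#' averaged across observers, and the model's predicted psychometric
#' functions are fit to the estimates by bounded Levenberg-Marquardt from
#' multiple seeded starting points. The seven free parameters are `n`,
#' `sigma`, `w_I`, `w_x`, `w_v`, `p` and `sigma_n` (see [model_params()]);
#' the spatial extent of stimulus-driven attention is not free, being tied
#' to competitor size. `w_x`, `w_v` and `p` are constrained so the
#' attentional gains stay non-negative (enforced by a smooth penalty).
#'
#' @param trials trial table (see [nakarushton()]); may span both target
#'   eyes (e.g. main plus eye-swap sessions).
#' @param variant attention variant: `"FS"` (feature-specific), `"ES"`
#'   (eye-specific) or `"compound"` (both, 8 free parameters).
#' @param grid a [neuron_grid()]; the default fitting grid (`dx = 0.5`,
#'   `dtheta = 2`) predicts d-prime within a fraction of a percent of the
#'   fine grid at a fraction of the cost.
#' @param n_starts number of optimizer starts (a fixed default start plus
#'   seeded random starts).
#' @param seed seed for the random starts.
#' @param fixed named vector of parameters to pin (e.g.
#'   `c(w_x = 4.62, p = 0.26)` for constrained refits).
#' @param directional fit separate interocular weights `w_LR` and `w_RL`
#'   (for designs that manipulate the eye-of-origin).
#' @param competitor_contrast competitor RMS contrast.
#' @param maxiter maximum Levenberg-Marquardt iterations per start.
#' @return an object of class `"normatt"` with `print`, `summary`,
#'   `coef`, `predict`, `fitted`, `residuals`, `plot`, `simulate` and
#'   `logLik` methods.
#' @seealso [bootstrap_params()], [crossval_compare()], [bic_compare()],
#'   [hessian_rank()]
#' @export
normatt <- function(trials, variant = c("FS", "ES", "compound"),
                    grid = neuron_grid(dx = 0.5, dtheta = 2),
                    n_starts = 10, seed = 1, fixed = NULL,
                    directional = FALSE,
                    competitor_contrast = DEFAULT_COMPETITOR_CONTRAST,
                    maxiter = 100) {
  variant <- match.arg(variant)
  cells_obs <- aggregate_cells(trials)
  cells <- order_cells(stats::aggregate(
    list(dprime = cells_obs$dprime),
    by = list(target_eye = cells_obs$target_eye,
              condition = cells_obs$condition,
              contrast = cells_obs$contrast),
    FUN = mean))
  if (length(unique(cells$condition)) < 2)
    stop("model fitting needs at least 2 conditions")
  engines <- prepare_engines(cells, grid, competitor_contrast)
  starts <- c(list(default_start(free_param_names(variant, directional))),
              random_starts(free_param_names(variant, directional),
                            max(0, n_starts - 1), seed))
  fit <- fit_cells_lm(cells, engines, variant, directional, fixed, starts,
                      maxiter)
  structure(c(fit,
              list(cells = cells, cells_observer = cells_obs,
                   trials = trials, variant = variant, grid = grid,
                   directional = directional, fixed = fixed,
                   competitor_contrast = competitor_contrast,
                   n_starts = n_starts, seed = seed,
                   call = match.call())),
            class = "normatt")
}

#' @export
print.normatt <- function(x, digits = 4, ...) {
  cat(sprintf("normalization/attention model fit (%s variant)\n", x$variant))
  cat(sprintf("  %d cells, %d free parameters, R-squared = %.1f%%\n",
              nrow(x$cells), length(x$free), 100 * x$r_squared))
  print(signif(x$coefficients, digits))
  if (!is.null(x$fixed))
    cat("  pinned:", paste(names(x$fixed), collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.normatt <- function(object, ...) {
  gr <- gain_report(object)
  structure(list(fit = object, gains = gr), class = "summary.normatt")
}

#' @export
print.summary.normatt <- function(x, ...) {
  print(x$fit)
  g <- x$gains$stimulus_driven
  cat(sprintf("stimulus-driven gain at the target neuron: (%s)\n",
              paste(sprintf("%s %.2f", names(g), g), collapse = ", ")))
  cat(sprintf("goal-driven gain at the target neuron: %.2f\n",
              x$gains$goal_driven))
  invisible(x)
}

#' @export
coef.normatt <- function(object, ...) object$coefficients

#' @export
fitted.normatt <- function(object, ...) object$fitted

#' @export
residuals.normatt <- function(object, ...) object$cells$dprime - object$fitted

#' @export
predict.normatt <- function(object, contrasts = NULL, conditions = NULL,
                            target_eye = NULL, ...) {
  if (is.null(contrasts)) contrasts <- sort(unique(object$cells$contrast))
  if (is.null(conditions))
    conditions <- as.character(unique(object$cells$condition))
  if (is.null(target_eye)) target_eye <- unique(object$cells$target_eye)[1]
  predict_psychometric(object$params, object$variant, contrasts,
                       conditions, target_eye, object$grid,
                       object$competitor_contrast)
}

#' @export
gain_report.normatt <- function(params, ...) {
  object <- params
  gain_report(object$params, variant = object$variant,
              conditions = as.character(unique(object$cells$condition)),
              target_eye = unique(object$cells$target_eye)[1],
              grid = object$grid)
}

#' @export
plot.normatt <- function(x, ...) {
  cells <- x$cells
  conds <- as.character(unique(cells$condition))
  cols <- grDevices::hcl.colors(length(conds), "Dark 2")
  names(cols) <- conds
  graphics::plot(NA, xlim = range(cells$contrast),
                 ylim = range(0, cells$dprime), log = "x",
                 xlab = "target contrast", ylab = "d'", ...)
  cc <- exp(seq(log(min(cells$contrast)), log(max(cells$contrast)),
                length.out = 80))
  pr <- predict(x, contrasts = cc)
  for (cd in conds) {
    sel <- cells$condition == cd
    graphics::points(cells$contrast[sel], cells$dprime[sel],
                     col = cols[cd], pch = 16)
    ps <- pr$condition == cd
    graphics::lines(pr$contrast[ps], pr$dprime[ps], col = cols[cd])
  }
  graphics::legend("topleft", legend = conds, col = cols, lty = 1,
                   bty = "n")
  invisible(x)
}

#' @export
simulate.normatt <- function(object, nsim = 1, seed = 1,
                             trials_per_cell = 50, ...) {
  design <- study_design(
    observer_params = list(sim = object$params),
    conditions = as.character(unique(object$cells$condition)),
    contrasts = sort(unique(object$cells$contrast)),
    trials_per_cell = trials_per_cell,
    competitor_contrast = object$competitor_contrast,
    target_eye = unique(object$cells$target_eye)[1], seed = seed)
  out <- lapply(seq_len(nsim), function(i) {
    design$seed <- as.integer(seed + i - 1)
    generate_trials(design, object$variant, object$grid)
  })
  if (nsim == 1) out[[1]] else out
}

## Pooled per-cell binomial counts for likelihood-based comparison.
pooled_counts <- function(trials) {
  stats::aggregate(
    cbind(n_correct = trials$correct, n_trials = 1L),
    by = list(target_eye = trials$target_eye,
              condition = trials$condition, contrast = trials$contrast),
    FUN = sum)
}

binomial_loglik <- function(counts, engines, params, variant,
                            clip = 1e-6) {
  pr <- predict_cells(engines, params, variant, counts)
  p <- pmin(pmax(stats::pnorm(pr$pred / 2), clip), 1 - clip)
  sum(stats::dbinom(counts$n_correct, counts$n_trials, p, log = TRUE))
}

#' @export
logLik.normatt <- function(object, ...) {
  counts <- pooled_counts(object$trials)
  engines <- prepare_engines(counts, object$grid,
                             object$competitor_contrast)
  ll <- binomial_loglik(counts, engines, object$params, object$variant)
  structure(ll, df = length(object$free), nobs = nrow(counts),
            class = "logLik")
}
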