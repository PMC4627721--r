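#' Bootstrap tests for contrast-gain versus response-gain changes
#'
#' Resamples individual trials with replacement within each
#' (observer, condition, contrast) cell, recomputes the group-averaged
#' d-prime estimates, refits the descriptive Naka-Rushton model, and
#' builds bootstrap distributions of the differences in `c50` and `d_m`
#' between each competitor condition and the no-competitor baseline (plus
#' large versus split when both are present). A significant `Delta c50`
#' indicates a contrast-gain change; a significant `Delta d_m` a
#' response-gain change.
#'
#' Resampling n trials with replacement from a cell with k correct
#' responses makes the resampled correct count exactly
#' Binomial(n, k/n)-distributed, which is how the resampling is drawn.
#'
#' Two-sided p-values are twice the smaller tail fraction of the bootstrap
#' distribution of the difference relative to zero, floored at `1/B`;
#' confidence intervals are percentile intervals.
#'
#' @param trials trial table (see [nakarushton()]).
#' @param B number of bootstrap resamples (default 2000; at least 100 for
#'   stable p-values).
#' @param seed integer seed making the procedure reproducible.
#' @param baseline name of the reference condition (default `"none"`).
#' @param unit how resampled estimates are aggregated across observers:
#'   `"observer_params"` refits each observer and averages the fitted
#'   `c50` and `d_m` values (the group-averaged parameter values);
#'   `"group_curve"` refits a single Naka-Rushton set to the
#'   group-averaged d-prime estimates.
#' @param levels nominal confidence levels for the percentile intervals.
#' @param ... passed to the descriptive fitter (e.g. `n_range`).
#' @return object of class `"gain_test"`: a data frame `tests` with one
#'   row per (comparison, parameter) holding the point estimate of the
#'   difference, percentile CIs and p-value, plus the bootstrap draws.
#' @export
bootstrap_gain_tests <- function(trials, B = 2000, seed = 1,
                                 baseline = "none",
                                 unit = c("observer_params", "group_curve"),
                                 levels = c(0.68, 0.95), ...) {
  if (B < 100)
    warning("B < 100 bootstrap resamples gives unstable p-values")
  unit <- match.arg(unit)
  cells <- aggregate_cells(trials)
  conds <- as.character(unique(cells$condition))
  obs_rows <- split(seq_len(nrow(cells)), cells$observer)
  fit_draw <- function(cb) {
    if (unit == "group_curve") {
      fit <- fit_nr_profiled(group_average_cells(cb), ...)
      ix <- match(conds, fit$par$condition)
      cbind(d_m = fit$par$d_m[ix], c50 = fit$par$c50[ix])
    } else {
      acc <- matrix(0, length(conds), 2)
      for (rows in obs_rows) {
        fit <- fit_nr_profiled(cb[rows, , drop = FALSE], ...)
        ix <- match(conds, fit$par$condition)
        acc <- acc + cbind(fit$par$d_m[ix], fit$par$c50[ix])
      }
      acc / length(obs_rows)
    }
  }
  point <- fit_draw(cells)
  dimnames(point) <- list(conds, c("d_m", "c50"))
  if (!baseline %in% conds)
    stop("baseline condition '", baseline, "' not present in the data")
  comparisons <- lapply(setdiff(conds, baseline),
                        function(cd) c(cd, baseline))
  if (all(c("large", "split") %in% conds))
    comparisons <- c(comparisons, list(c("large", "split")))
  set.seed(seed)
  draws <- array(NA_real_, c(B, length(conds), 2),
                 dimnames = list(NULL, conds, c("d_m", "c50")))
  for (b in seq_len(B)) {
    k_star <- stats::rbinom(nrow(cells), cells$n_trials,
                            cells$n_correct / cells$n_trials)
    cb <- cells
    cb$dprime <- estimate_dprime(k_star, cb$n_trials)
    draws[b, , ] <- fit_draw(cb)
  }
  one_test <- function(pair, param) {
    dd <- draws[, pair[1], param] - draws[, pair[2], param]
    est <- point[pair, param]
    p <- max(1 / B, 2 * min(mean(dd <= 0), mean(dd >= 0)))
    qs <- lapply(levels, function(lv)
      stats::quantile(dd, c((1 - lv) / 2, 1 - (1 - lv) / 2), names = FALSE))
    data.frame(comparison = paste(pair[1], "vs", pair[2]), param = param,
               delta = est[1] - est[2],
               lo68 = qs[[1]][1], hi68 = qs[[1]][2],
               lo95 = qs[[2]][1], hi95 = qs[[2]][2], p = p)
  }
  tests <- do.call(rbind, unlist(lapply(comparisons, function(pair)
    list(one_test(pair, "d_m"), one_test(pair, "c50"))), recursive = FALSE))
  structure(list(tests = tests, draws = draws, B = B, seed = seed,
                 unit = unit, point = point),
            class = "gain_test")
}

#' @export
print.gain_test <- function(x, digits = 3, ...) {
  cat(sprintf("bootstrap gain tests (B = %d, unit = %s)\n", x$B, x$unit))
  tab <- x$tests
  for (cl in c("delta", "lo68", "hi68", "lo95", "hi95"))
    tab[[cl]] <- signif(tab[[cl]], digits)
  tab$p <- format.pval(tab$p, digits = 2)
  print(tab, row.names = FALSE)
  invisible(x)
}
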