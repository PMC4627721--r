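#' Naka-Rushton psychometric function
#'
#' `d'(c) = d_m * c^n / (c^n + c50^n)`: zero at zero contrast, half the
#' asymptote `d_m` at the semi-saturation contrast `c50`, saturating at
#' `d_m`. A change in `c50` is a contrast-gain change; a change in `d_m`
#' is a response-gain change.
#'
#' @param c target contrast(s), non-negative.
#' @param d_m asymptotic d-prime.
#' @param c50 semi-saturation contrast (> 0).
#' @param n exponent controlling the slope.
#' @return d-prime value(s).
#' @export
naka_rushton <- function(c, d_m, c50, n) {
  stopifnot(all(c >= 0), c50 > 0, n > 0)
  cn <- c^n
  d_m * cn / (cn + c50^n)
}

#' Estimate d-prime from binary trial counts
#'
#' For an unbiased two-choice identification judgment (clockwise versus
#' counterclockwise), `d' = 2 * qnorm(PC)`. The proportion correct is
#' clipped to `[1/(2n), 1 - 1/(2n)]` so that perfect or chance-level cells
#' give finite estimates.
#'
#' @param n_correct number of correct trials (vectorized).
#' @param n_trials number of trials (>= 1).
#' @return estimated d-prime(s).
#' @export
estimate_dprime <- function(n_correct, n_trials) {
  if (any(n_trials < 1)) stop("'n_trials' must be >= 1")
  stopifnot(all(n_correct >= 0), all(n_correct <= n_trials))
  p <- pmin(pmax(n_correct / n_trials, 1 / (2 * n_trials)),
            1 - 1 / (2 * n_trials))
  2 * stats::qnorm(p)
}

## Aggregate a trial table into per-cell counts and d-prime estimates.
## Cells are (observer, target_eye, condition, contrast).
aggregate_cells <- function(trials) {
  need <- c("observer", "condition", "target_eye", "contrast", "correct")
  miss <- setdiff(need, names(trials))
  if (length(miss))
    stop("trial table is missing column(s): ", paste(miss, collapse = ", "))
  ag <- stats::aggregate(
    cbind(n_correct = trials$correct, n_trials = 1L),
    by = list(observer = trials$observer, target_eye = trials$target_eye,
              condition = trials$condition, contrast = trials$contrast),
    FUN = sum)
  ag$dprime <- estimate_dprime(ag$n_correct, ag$n_trials)
  ag[order(ag$observer, match(ag$condition, condition_names(),
                              nomatch = 99L),
           ag$condition, ag$contrast), , drop = FALSE]
}

## Canonical condition order (none, small, medium, large, split, then
## anything else alphabetically).
order_cells <- function(cells) {
  cells[order(match(cells$condition, condition_names(), nomatch = 99L),
              cells$condition, cells$contrast), , drop = FALSE]
}

## Average per-observer d-prime estimates into group cells.
group_average_cells <- function(cells) {
  ag <- stats::aggregate(
    list(dprime = cells$dprime),
    by = list(target_eye = cells$target_eye, condition = cells$condition,
              contrast = cells$contrast),
    FUN = mean)
  ag$observer <- "group"
  order_cells(ag)
}

## Profiled least-squares Naka-Rushton fit for one set of conditions with
## a shared exponent. Given n, d_m is linear in the saturation shape, so
## each condition reduces to a 1-D search over log(c50); the shared
## exponent is then a 1-D outer optimization. Deterministic and free of
## starting values.
fit_nr_profiled <- function(cells, n_range = c(0.3, 8), d_m_max = 10,
                            c50_bounds = NULL) {
  conds <- unique(cells$condition)
  if (is.null(c50_bounds))
    c50_bounds <- c(min(cells$contrast[cells$contrast > 0]) / 10,
                    max(cells$contrast) * 10)
  lb <- log(c50_bounds)
  per_cond <- function(cc, yy, n) {
    cn <- cc^n
    sse_c50 <- function(lc50) {
      f <- cn / (cn + exp(lc50)^n)
      dm <- sum(yy * f) / sum(f^2)
      dm <- min(max(dm, 0), d_m_max)
      sum((yy - dm * f)^2)
    }
    ## coarse bracket then local refinement (robust to multimodality)
    gridl <- seq(lb[1], lb[2], length.out = 41)
    v <- vapply(gridl, sse_c50, numeric(1))
    i <- which.min(v)
    lo <- gridl[max(1, i - 1)]
    hi <- gridl[min(length(gridl), i + 1)]
    op <- stats::optimize(sse_c50, c(lo, hi), tol = 1e-9)
    c50 <- exp(op$minimum)
    f <- cn / (cn + c50^n)
    dm <- min(max(sum(yy * f) / sum(f^2), 0), d_m_max)
    list(c50 = c50, d_m = dm, sse = sum((yy - dm * f)^2))
  }
  sse_n <- function(n) {
    s <- 0
    for (cd in conds) {
      sel <- cells$condition == cd
      s <- s + per_cond(cells$contrast[sel], cells$dprime[sel], n)$sse
    }
    s
  }
  opn <- stats::optimize(sse_n, n_range, tol = 1e-6)
  n_hat <- opn$minimum
  fits <- lapply(conds, function(cd) {
    sel <- cells$condition == cd
    per_cond(cells$contrast[sel], cells$dprime[sel], n_hat)
  })
  d_m <- vapply(fits, `[[`, numeric(1), "d_m")
  c50 <- vapply(fits, `[[`, numeric(1), "c50")
  sse <- sum(vapply(fits, `[[`, numeric(1), "sse"))
  sst <- sum((cells$dprime - mean(cells$dprime))^2)
  tol <- 1e-4
  flags <- (c50 < c50_bounds[1] * (1 + tol)) |
    (c50 > c50_bounds[2] / (1 + tol)) |
    d_m <= 1e-8   # c50 unidentified when the curve is flat at zero
  data.frame(condition = conds, d_m = d_m, c50 = c50, n = n_hat,
             c50_at_bound = flags, row.names = NULL) ->
    par_tab
  list(par = par_tab, sse = sse, r_squared = 1 - sse / sst,
       c50_bounds = c50_bounds)
}

#' Descriptive Naka-Rushton fit of a trial table
#'
#' Estimates d-prime per (condition, contrast) cell and fits Naka-Rushton
#' psychometric functions by unweighted least squares, one (`d_m`, `c50`)
#' pair per competitor condition with the exponent shared across
#' conditions. Fitting is done either on the group-averaged d-prime
#' estimates (per-observer estimates averaged per cell) or separately per
#' observer. With `shared_n = FALSE` the exponent is also free per
#' condition (used to check that sharing the exponent costs little fit
#' quality).
#'
#' @param trials trial table: data frame with columns `observer`,
#'   `condition`, `target_eye`, `contrast`, `correct` (0/1 or logical).
#' @param grouping `"group_average"` or `"per_observer"`.
#' @param shared_n share the exponent across conditions (default TRUE).
#' @param n_range search interval for the exponent.
#' @param d_m_max upper bound for the asymptote.
#' @param c50_bounds search interval for `c50`; defaults to
#'   `[min contrast / 10, max contrast * 10]`. Estimates at a bound are
#'   flagged.
#' @return object of class `"nakarushton"`: a list with `par` (data frame
#'   of per-condition `d_m`, `c50`, `n`, bound flags, plus `observer` for
#'   per-observer fits), `r_squared`, `cells`, and the call arguments.
#' @export
nakarushton <- function(trials, grouping = c("group_average", "per_observer"),
                        shared_n = TRUE, n_range = c(0.3, 8), d_m_max = 10,
                        c50_bounds = NULL) {
  grouping <- match.arg(grouping)
  cells <- aggregate_cells(trials)
  units <- if (grouping == "group_average") {
    list(group = group_average_cells(cells))
  } else {
    split(cells, cells$observer)
  }
  fit_unit <- function(u) {
    if (shared_n) return(fit_nr_profiled(u, n_range, d_m_max, c50_bounds))
    parts <- lapply(split(u, u$condition), fit_nr_profiled,
                    n_range = n_range, d_m_max = d_m_max,
                    c50_bounds = c50_bounds)
    par <- do.call(rbind, lapply(parts, `[[`, "par"))
    sse <- sum(vapply(parts, `[[`, numeric(1), "sse"))
    sst <- sum((u$dprime - mean(u$dprime))^2)
    list(par = par, sse = sse, r_squared = 1 - sse / sst,
         c50_bounds = parts[[1]]$c50_bounds)
  }
  fits <- lapply(units, fit_unit)
  par <- do.call(rbind, lapply(names(fits), function(nm) {
    cbind(observer = nm, fits[[nm]]$par)
  }))
  structure(list(par = par,
                 r_squared = vapply(fits, `[[`, numeric(1), "r_squared"),
                 sse = vapply(fits, `[[`, numeric(1), "sse"),
                 cells = cells, grouping = grouping, shared_n = shared_n,
                 c50_bounds = fits[[1]]$c50_bounds),
            class = "nakarushton")
}

#' @export
print.nakarushton <- function(x, digits = 3, ...) {
  cat(sprintf("Naka-Rushton descriptive fit (%s%s)\n", x$grouping,
              if (x$shared_n) ", shared exponent" else ""))
  tab <- x$par
  tab$d_m <- signif(tab$d_m, digits)
  tab$c50 <- signif(tab$c50, digits)
  tab$n <- signif(tab$n, digits)
  print(tab, row.names = FALSE)
  cat(sprintf("R-squared: %s\n",
              paste(sprintf("%s %.3f", names(x$r_squared), x$r_squared),
                    collapse = ", ")))
  if (any(tab$c50_at_bound))
    cat("note: some c50 estimates hit the search bounds\n")
  invisible(x)
}

#' @export
coef.nakarushton <- function(object, ...) object$par

#' @export
predict.nakarushton <- function(object, contrasts = NULL, ...) {
  if (is.null(contrasts)) contrasts <- sort(unique(object$cells$contrast))
  tab <- object$par
  out <- do.call(rbind, lapply(seq_len(nrow(tab)), function(i) {
    data.frame(observer = tab$observer[i], condition = tab$condition[i],
               contrast = contrasts,
               dprime = naka_rushton(contrasts, tab$d_m[i], tab$c50[i],
                                     tab$n[i]))
  }))
  out
}

#' @export
plot.nakarushton <- function(x, ...) {
  cells <- if (x$grouping == "group_average")
    group_average_cells(x$cells) else x$cells
  conds <- unique(x$par$condition)
  cols <- grDevices::hcl.colors(length(conds), "Dark 2")
  names(cols) <- conds
  graphics::plot(NA, xlim = range(cells$contrast), ylim = range(0, cells$dprime),
                 log = "x", xlab = "target contrast", ylab = "d'", ...)
  cc <- exp(seq(log(min(cells$contrast)), log(max(cells$contrast)),
                length.out = 80))
  pr <- predict(x, cc)
  for (cd in conds) {
    sel <- cells$condition == cd
    graphics::points(cells$contrast[sel], cells$dprime[sel],
                     col = cols[cd], pch = 16)
    for (ob in unique(pr$observer)) {
      ps <- pr$condition == cd & pr$observer == ob
      graphics::lines(pr$contrast[ps], pr$dprime[ps], col = cols[cd])
    }
  }
  graphics::legend("topleft", legend = conds, col = cols, lty = 1, bty = "n")
  invisible(x)
}
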