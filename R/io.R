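#' Read and write trial tables
#'
#' Trial tables travel as plain comma-separated text with a header row
#' (UTF-8, `.` decimal): columns `observer`, `condition`, `target_eye`,
#' `contrast`, `correct` (0/1) and optionally `trial`. `write_trials()`
#' also writes a YAML provenance sidecar (`<path>.yml`) with the study
#' design and seed when the table carries one.
#'
#' @param path file path.
#' @param trials trial table (see [generate_trials()]).
#' @return `read_trials()` returns the trial table; `write_trials()` the
#'   path, invisibly.
#' @export
read_trials <- function(path) {
  trials <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("observer", "condition", "target_eye", "contrast", "correct")
  miss <- setdiff(need, names(trials))
  if (length(miss))
    stop("malformed trial table '", path, "': missing column(s) ",
         paste(miss, collapse = ", "))
  if (!all(trials$correct %in% c(0L, 1L, TRUE, FALSE)))
    stop("malformed trial table '", path,
         "': 'correct' must be 0/1 (first bad row: ",
         which(!trials$correct %in% c(0, 1))[1], ")")
  if (any(trials$contrast < 0) || any(!is.finite(trials$contrast)))
    stop("malformed trial table '", path, "': bad contrast value (row ",
         which(trials$contrast < 0 | !is.finite(trials$contrast))[1], ")")
  trials$correct <- as.integer(trials$correct)
  trials
}

#' @rdname read_trials
#' @export
write_trials <- function(trials, path) {
  utils::write.csv(trials, path, row.names = FALSE, quote = FALSE)
  design <- attr(trials, "design")
  if (!is.null(design)) {
    side <- list(
      observers = names(design$observer_params),
      parameters = lapply(design$observer_params, function(p)
        lapply(p[c("n", "sigma", "w_I", "w_x", "w_v", "p", "sigma_n",
                   "w_LR", "w_RL")], as.numeric)),
      conditions = design$conditions,
      contrasts = as.numeric(design$contrasts),
      trials_per_cell = design$trials_per_cell,
      competitor_contrast = design$competitor_contrast,
      target_eye = design$target_eye,
      lapse_rate = design$lapse_rate,
      seed = design$seed)
    yaml::write_yaml(side, paste0(path, ".yml"))
  }
  invisible(path)
}

#' Write fit results as structured text
#'
#' Serializes a fitted model, descriptive fit, bootstrap result or
#' comparison to human-readable YAML (parameters, R-squared, gain report,
#' intervals, p-values), so results can be archived next to the data.
#'
#' @param x a `normatt`, `nakarushton`, `normatt_boot`, `normatt_cv` or
#'   `gain_test` object.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_results <- function(x, path) {
  as_plain <- function(df) lapply(as.list(df), function(col)
    if (is.numeric(col)) as.numeric(col) else as.character(col))
  out <- if (inherits(x, "normatt")) {
    list(type = "model_fit", variant = x$variant,
         coefficients = as.list(x$coefficients),
         r_squared = x$r_squared,
         gains = lapply(gain_report(x), as.numeric),
         n_cells = nrow(x$cells))
  } else if (inherits(x, "nakarushton")) {
    list(type = "descriptive_fit", grouping = x$grouping,
         parameters = as_plain(x$par),
         r_squared = as.numeric(x$r_squared))
  } else if (inherits(x, "normatt_boot")) {
    list(type = "bootstrap", B = x$B, estimate = as.list(x$estimate),
         ci = apply(x$ci, 1, as.list))
  } else if (inherits(x, "normatt_cv")) {
    list(type = "cross_validation", B = x$B,
         exceedance = x$exceedance, decision = x$decision,
         mean_r2 = as.list(colMeans(x$r2)))
  } else if (inherits(x, "gain_test")) {
    list(type = "gain_tests", B = x$B, tests = as_plain(x$tests))
  } else stop("don't know how to serialize an object of class ",
              class(x)[1])
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Export a field over the neuron grid as delimited text
#'
#' Writes a gain, drive or response matrix as tab-separated text with the
#' receptive-field centers as row names and preferred orientations as
#' column headers, for inspection outside R.
#'
#' @param field matrix over the grid (one eye).
#' @param grid the [neuron_grid()] it lives on.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_field <- function(field, grid, path) {
  stopifnot(nrow(field) == length(grid$x),
            ncol(field) == length(grid$theta))
  dimnames(field) <- list(grid$x, grid$theta)
  utils::write.table(field, path, sep = "\t", quote = FALSE,
                     col.names = NA)
  invisible(path)
}
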