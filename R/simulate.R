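#' Study design for the synthetic-data generator
#'
#' Describes a simulated psychophysics study with the structure the
#' analysis assumes: a cohort of observers, each with their own model
#' parameters, tested on a set of competitor configurations crossed with a
#' target-contrast ladder, with a fixed number of trials per cell. The
#' defaults emulate the acquisition design: 4 observers, 5 competitor
#' configurations, 9 log-spaced contrasts, 50 trials per cell, competitor
#' fixed at 23% RMS contrast, right-eye targets.
#'
#' @param observer_params named list of [model_params()], one per
#'   observer; defaults to the four observer-level reference sets (whose
#'   interocular weights span near-0 to near-4).
#' @param conditions condition names.
#' @param contrasts target-contrast ladder.
#' @param trials_per_cell trials per (observer, condition, contrast) cell.
#' @param competitor_contrast competitor RMS contrast.
#' @param target_eye eye receiving the target.
#' @param lapse_rate probability of a stimulus-independent random guess
#'   (default 0; provided for robustness checks).
#' @param seed master seed; per-cell child seeds are derived from it so
#'   generation is reproducible and independent of cell order.
#' @return object of class `"study_design"`.
#' @export
study_design <- function(observer_params = NULL,
                         conditions = condition_names(),
                         contrasts = default_contrast_ladder(),
                         trials_per_cell = 50,
                         competitor_contrast = DEFAULT_COMPETITOR_CONTRAST,
                         target_eye = "right", lapse_rate = 0, seed = 1) {
  if (is.null(observer_params))
    observer_params <- sapply(c("S1", "S2", "S3", "S4"), reference_params,
                              simplify = FALSE)
  if (inherits(observer_params, "model_params"))
    observer_params <- list(S1 = observer_params)
  if (is.null(names(observer_params)))
    names(observer_params) <- paste0("S", seq_along(observer_params))
  stopifnot(trials_per_cell >= 1, lapse_rate >= 0, lapse_rate < 1,
            all(contrasts >= 0))
  structure(list(observer_params = observer_params, conditions = conditions,
                 contrasts = contrasts, trials_per_cell = trials_per_cell,
                 competitor_contrast = competitor_contrast,
                 target_eye = target_eye, lapse_rate = lapse_rate,
                 seed = as.integer(seed)),
            class = "study_design")
}

## Deterministic per-cell child seed below 2^31, independent of cell order.
cell_seed <- function(master, index) {
  as.integer((as.numeric(master) * 10007 + index * 7919) %% 2147483629)
}

#' Generate a synthetic trial table
#'
#' Simulates trial-level data from the population model: for every
#' (observer, condition, contrast) cell, d-prime is predicted by the
#' model, converted to a probability correct through the unbiased
#' two-choice mapping `P = pnorm(d'/2)` (mixed with a guessing rate if a
#' lapse rate is set), and independent Bernoulli trials are drawn.
#' Generation is deterministic for a fixed design seed: each cell draws
#' from its own reproducibly derived child seed.
#'
#' @param design a [study_design()].
#' @param variant attention variant used for the predictions.
#' @param grid a [neuron_grid()] (the default fine grid).
#' @return trial table: data frame with columns `observer`, `condition`,
#'   `target_eye`, `contrast`, `correct` (integer 0/1) and `trial`, with
#'   the design and seed attached as attributes `design`.
#' @export
generate_trials <- function(design, variant = c("FS", "ES", "compound"),
                            grid = neuron_grid()) {
  variant <- match.arg(variant)
  stopifnot(inherits(design, "study_design"))
  eng <- psychometric_engine(design$conditions, design$contrasts, grid,
                             design$target_eye, design$competitor_contrast)
  nobs <- length(design$observer_params)
  ncell <- length(design$conditions) * length(design$contrasts)
  out <- vector("list", nobs * ncell)
  idx <- 0L
  for (o in seq_len(nobs)) {
    obs <- names(design$observer_params)[o]
    d <- engine_dprime(eng, design$observer_params[[o]], variant)
    pc <- stats::pnorm(d / 2)
    pc <- design$lapse_rate * 0.5 + (1 - design$lapse_rate) * pc
    for (k in seq_along(design$conditions)) {
      for (m in seq_along(design$contrasts)) {
        idx <- idx + 1L
        set.seed(cell_seed(design$seed, (o - 1L) * ncell +
                             (k - 1L) * length(design$contrasts) + m))
        corr <- as.integer(stats::runif(design$trials_per_cell) < pc[k, m])
        out[[idx]] <- data.frame(
          observer = obs, condition = design$conditions[k],
          target_eye = design$target_eye,
          contrast = design$contrasts[m], correct = corr,
          trial = seq_along(corr), stringsAsFactors = FALSE)
      }
    }
  }
  trials <- do.call(rbind, out)
  rownames(trials) <- NULL
  attr(trials, "design") <- design
  trials
}

#' Generate an eye-swap session
#'
#' Simulates the follow-up design probing the eye-of-origin of interocular
#' normalization: only the no-competitor, large and split conditions are
#' run, with the target moved to the other eye. Directional interocular
#' weights (`w_LR` not equal to `w_RL` in [model_params()]) make the more
#' suppressive condition (large versus split) flip between the original
#' and the swapped session.
#'
#' @param design a [study_design()]; its conditions are replaced by
#'   (none, large, split) and its target eye is swapped.
#' @param variant attention variant.
#' @param grid a [neuron_grid()].
#' @return a trial table, as [generate_trials()].
#' @export
generate_eye_swap_session <- function(design, variant = "FS",
                                      grid = neuron_grid()) {
  stopifnot(inherits(design, "study_design"))
  design$conditions <- c("none", "large", "split")
  design$target_eye <- other_eye(design$target_eye)
  design$seed <- design$seed + 1L  # distinct session stream
  generate_trials(design, variant, grid)
}
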