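#' Population response of the monocular neurons
#'
#' Applies the normalization equation to a stimulus configuration: each
#' eye's attention-modulated excitatory drive `A_x A_v E^n` is divided by
#' its suppressive drive plus the interocularly weighted suppressive drive
#' of the other eye plus the semi-saturation term:
#' `R_L = (A_x A_v E_L^n) / (S_L + w_RL * S_R + sigma^n)` and
#' `R_R = (A_x A_v E_R^n) / (S_R + w_LR * S_L + sigma^n)`
#' (with `w_LR = w_RL = w_I` unless directional weights are set). No
#' rectification or thresholding is applied; responses are non-negative by
#' construction whenever the attentional gains are.
#'
#' @param components component data frame from [expand_condition()] (or a
#'   [condition()], which is expanded first).
#' @param params a [model_params()] object.
#' @param grid a [neuron_grid()].
#' @param variant attention variant, see [stimulus_attention()].
#' @param competitor_contrast competitor RMS contrast used if a condition
#'   is supplied.
#' @return list with response matrices `left` and `right`, the drive `E`,
#'   attention fields `Ax`, `Av` and suppressive drives `S`.
#' @export
population_response <- function(components, params, grid = neuron_grid(),
                                variant = c("FS", "ES", "compound"),
                                competitor_contrast = DEFAULT_COMPETITOR_CONTRAST) {
  variant <- match.arg(variant)
  if (inherits(components, "condition"))
    components <- expand_condition(components, competitor_contrast)
  E <- excitatory_drive(components, grid)
  Ax <- stimulus_attention(components, grid, params$w_x, params$p, variant)
  Av <- goal_attention(grid, params$w_v)
  M <- list(left = Ax$left * Av$left * E$left^params$n,
            right = Ax$right * Av$right * E$right^params$n)
  S <- list(left = suppressive_drive(M$left, grid, params$sigma_sx, params$tau),
            right = suppressive_drive(M$right, grid, params$sigma_sx, params$tau))
  sn <- params$sigma^params$n
  R <- list(left = M$left / (S$left + params$w_RL * S$right + sn),
            right = M$right / (S$right + params$w_LR * S$left + sn))
  if (any(!is.finite(R$left)) || any(!is.finite(R$right)))
    stop("non-finite population response; pathological parameter values")
  c(R, list(E = E, Ax = Ax, Av = Av, S = S))
}

#' Behavioral sensitivity from the population response
#'
#' d-prime is proportional to the response of the neuron most responsive
#' to the target: same eye-of-origin, preferred orientation equal to the
#' target orientation, and receptive field at the target center. The
#' proportionality constant is the inverse of the behavioral noise
#' magnitude `sigma_n` (additive IID noise linking neural response to
#' performance).
#'
#' @param response result of [population_response()].
#' @param grid the [neuron_grid()] the response was computed on.
#' @param sigma_n behavioral noise magnitude (> 0).
#' @param target_eye,target_orientation,target_x readout neuron.
#' @return d-prime (scalar).
#' @export
predict_dprime <- function(response, grid, sigma_n,
                           target_eye = "right",
                           target_orientation = TARGET_ORI, target_x = 0) {
  stopifnot(sigma_n > 0)
  ij <- grid_index(grid, target_x, target_orientation)
  response[[target_eye]][ij[1], ij[2]] / sigma_n
}

## ---- fast psychometric engine ------------------------------------------
## Per-condition precomputation that makes repeated d-prime prediction
## cheap during model fitting: unit-contrast target drive, fixed
## competitor drive, and the suppression-kernel readout row at the target
## neuron. For conditions whose target eye holds only the target, the
## suppressive drive at the readout neuron is c^n times a single weighted
## sum, so a whole contrast ladder costs a handful of array reductions.

psychometric_engine <- function(conditions = condition_names(),
                                contrasts, grid,
                                target_eye = "right",
                                competitor_contrast = DEFAULT_COMPETITOR_CONTRAST) {
  W <- readout_weights(grid)
  ij <- grid_index(grid, 0, TARGET_ORI)
  conds <- lapply(conditions, function(nm) {
    comps <- expand_condition(condition(nm, 1, target_eye),
                              competitor_contrast)
    tgt <- comps[comps$role == "target", , drop = FALSE]
    cmp <- comps[comps$role == "competitor", , drop = FALSE]
    list(name = nm, components = comps,
         Bt = excitatory_drive(tgt, grid),        # unit target contrast
         Bc = excitatory_drive(cmp, grid))        # competitor at contrast
  })
  list(conditions = conds, contrasts = contrasts, grid = grid,
       target_eye = target_eye, ce = other_eye(target_eye),
       W = W, ij = ij)
}

## d-prime matrix (condition x contrast) for one parameter set.
engine_dprime <- function(eng, params, variant,
                          negative_gain = c("error", "clamp")) {
  negative_gain <- match.arg(negative_gain)
  check <- negative_gain == "error"
  min_gain <- Inf
  clamp <- function(f) {
    if (check) return(f)
    min_gain <<- min(min_gain, f$left, f$right)
    list(left = pmax(f$left, 0), right = pmax(f$right, 0))
  }
  grid <- eng$grid
  te <- eng$target_eye
  ce <- eng$ce
  ij <- eng$ij
  W <- eng$W
  n <- params$n
  sn <- params$sigma^n
  w_across <- if (te == "right") params$w_LR else params$w_RL
  Av <- clamp(goal_attention(grid, params$w_v, check = check))
  cc <- eng$contrasts
  ccn <- cc^n
  out <- matrix(NA_real_, length(eng$conditions), length(cc),
                dimnames = list(vapply(eng$conditions, `[[`, "", "name"),
                                NULL))
  for (k in seq_along(eng$conditions)) {
    cond <- eng$conditions[[k]]
    Ax <- clamp(stimulus_attention(cond$components, grid, params$w_x,
                                   params$p, variant, check = check))
    G_te <- Ax[[te]] * Av[[te]]
    g0 <- G_te[ij[1], ij[2]]
    ## competitor-eye suppressive drive at the readout neuron (fixed in c)
    s_ce <- if (max(cond$Bc[[ce]]) > 0) {
      G_ce <- Ax[[ce]] * Av[[ce]]
      sum(W * G_ce * cond$Bc[[ce]]^n)
    } else 0
    if (max(cond$Bc[[te]]) == 0) {
      BtN <- cond$Bt[[te]]^n
      s1 <- sum(W * G_te * BtN)
      num <- g0 * BtN[ij[1], ij[2]] * ccn
      den <- s1 * ccn + w_across * s_ce + sn
      out[k, ] <- num / den / params$sigma_n
    } else {
      for (m in seq_along(cc)) {
        En <- (cc[m] * cond$Bt[[te]] + cond$Bc[[te]])^n
        s_t <- sum(W * G_te * En)
        num <- g0 * En[ij[1], ij[2]]
        out[k, m] <- num / (s_t + w_across * s_ce + sn) / params$sigma_n
      }
    }
  }
  if (any(!is.finite(out)))
    stop("non-finite d-prime prediction; pathological parameter values")
  attr(out, "min_gain") <- if (check) 1 else min_gain
  out
}

#' Predicted psychometric functions
#'
#' Deterministic model prediction of d-prime as a function of target
#' contrast for a set of competitor conditions, under a given attention
#' variant. This is the forward model used both by the least-squares
#' fitter and by the synthetic-data generator.
#'
#' @param params a [model_params()] object.
#' @param variant `"FS"`, `"ES"` or `"compound"`.
#' @param contrasts target RMS contrasts.
#' @param conditions condition names (subset of [condition_names()]).
#' @param target_eye eye receiving the target.
#' @param grid a [neuron_grid()].
#' @param competitor_contrast competitor RMS contrast.
#' @return data frame with columns `condition`, `contrast`, `dprime`.
#' @examples
#' p <- reference_params("group")
#' head(predict_psychometric(p, "FS", contrasts = c(0.01, 0.1),
#'                           grid = neuron_grid(dx = 1, dtheta = 3)))
#' @export
predict_psychometric <- function(params, variant = c("FS", "ES", "compound"),
                                 contrasts = default_contrast_ladder(),
                                 conditions = condition_names(),
                                 target_eye = "right",
                                 grid = neuron_grid(),
                                 competitor_contrast = DEFAULT_COMPETITOR_CONTRAST) {
  variant <- match.arg(variant)
  conditions <- match.arg(conditions, condition_names(), several.ok = TRUE)
  eng <- psychometric_engine(conditions, contrasts, grid, target_eye,
                             competitor_contrast)
  d <- engine_dprime(eng, params, variant)
  data.frame(condition = rep(conditions, each = length(contrasts)),
             contrast = rep(contrasts, length(conditions)),
             dprime = as.vector(t(d)))
}

#' Default target-contrast ladder
#'
#' Nine log-spaced RMS contrasts from 0.3% to 35%, bracketing the dynamic
#' range of the psychometric functions in this design.
#' @return numeric vector of length 9.
#' @export
default_contrast_ladder <- function() {
  exp(seq(log(0.003), log(0.35), length.out = 9))
}

#' Attentional gains at the target neuron
#'
#' The worked-example summary reported alongside fitted parameters: the
#' stimulus-driven attentional gain factor of the neuron tuned to the
#' target (target orientation, receptive field at the stimulus center, in
#' the target eye) for each competitor condition, together with the
#' goal-driven gain at the same neuron (identical across conditions).
#'
#' @param params a [model_params()] object (or a fitted model; see
#'   [normatt()]).
#' @param variant attention variant.
#' @param conditions condition names to report.
#' @param target_eye eye receiving the target.
#' @param grid a [neuron_grid()].
#' @param ... unused.
#' @return named list with `stimulus_driven` (named vector per condition)
#'   and `goal_driven` (scalar).
#' @export
gain_report <- function(params, variant = c("FS", "ES", "compound"),
                        conditions = condition_names(),
                        target_eye = "right", grid = neuron_grid(), ...) {
  UseMethod("gain_report")
}

#' @export
gain_report.model_params <- function(params, variant = c("FS", "ES", "compound"),
                                     conditions = condition_names(),
                                     target_eye = "right",
                                     grid = neuron_grid(), ...) {
  variant <- match.arg(variant)
  ij <- grid_index(grid, 0, TARGET_ORI)
  g <- vapply(conditions, function(nm) {
    comps <- expand_condition(condition(nm, 0.1, target_eye))
    Ax <- stimulus_attention(comps, grid, params$w_x, params$p, variant)
    Ax[[target_eye]][ij[1], ij[2]]
  }, numeric(1))
  Av <- goal_attention(grid, params$w_v)
  list(stimulus_driven = g,
       goal_driven = Av[[target_eye]][ij[1], ij[2]])
}
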