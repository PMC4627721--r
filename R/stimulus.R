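#' Dichoptic stimulus conditions
#'
#' The five competitor configurations of the interocular-suppression design:
#' a 1.5 degree target at 45 degrees shown to one eye, and an orthogonal
#' (135 degree) competitor at fixed RMS contrast shown to the other eye
#' (or split between the eyes). Sizes follow the study design: the target
#' and small competitor are 1.5 degrees in diameter, the medium and large
#' competitors 2.5 and 8 degrees. The split competitor has the overall
#' extent of the large one, but its 1.5 degree center goes to the
#' competitor eye while the annular surround goes to the target eye, so the
#' two halves fuse into a single large patch.
#'
#' @param name one of `"none"`, `"small"`, `"medium"`, `"large"`, `"split"`.
#' @param target_contrast RMS contrast of the target, in `[0, 1]`.
#' @param target_eye `"left"` or `"right"`; the eye receiving the target.
#' @return an object of class `"condition"` (a named list).
#' @seealso [expand_condition()]
#' @export
condition <- function(name, target_contrast, target_eye = "right") {
  name <- match.arg(name, condition_names())
  target_eye <- match.arg(target_eye, c("left", "right"))
  stopifnot(is.numeric(target_contrast), length(target_contrast) == 1L,
            target_contrast >= 0, target_contrast <= 1)
  structure(list(name = name, target_contrast = target_contrast,
                 target_eye = target_eye),
            class = "condition")
}

#' @rdname condition
#' @export
condition_names <- function() c("none", "small", "medium", "large", "split")

## Fixed stimulus geometry (degrees of visual angle / orientation).
TARGET_ORI <- 45
COMPETITOR_ORI <- 135
TARGET_WIDTH <- 1.5
COMPETITOR_WIDTHS <- c(small = 1.5, medium = 2.5, large = 8)
DEFAULT_COMPETITOR_CONTRAST <- 0.23

other_eye <- function(eye) ifelse(eye == "left", "right", "left")

new_component <- function(eye, orientation, center_x, width, contrast,
                          inner_width = 0, role = "target") {
  stopifnot(width > 0, contrast >= 0, inner_width >= 0, inner_width < width)
  data.frame(eye = eye, orientation = orientation %% 180,
             center_x = center_x, width = width, inner_width = inner_width,
             contrast = contrast, role = role,
             stringsAsFactors = FALSE)
}

#' Expand a condition into monocular stimulus components
#'
#' Turns a named competitor configuration into the list of monocular
#' patches it is made of. Space is one-dimensional (the receptive-field
#' center axis) and every patch is an interval centered at 0; a width is a
#' diameter. The split condition expands to a 1.5 degree center patch in
#' the competitor eye plus an annular surround (the 8 degree region minus
#' the 1.5 degree center) in the target eye, both at competitor contrast.
#'
#' @param cond a [condition()] object.
#' @param competitor_contrast RMS contrast of the competitor (default 0.23).
#' @return a data frame of components with columns `eye`, `orientation`,
#'   `center_x`, `width`, `inner_width` (0 for a disc, otherwise the inner
#'   diameter of an annulus), `contrast` and `role`
#'   (`"target"`/`"competitor"`).
#' @examples
#' expand_condition(condition("split", 0.1))
#' @export
expand_condition <- function(cond, competitor_contrast = DEFAULT_COMPETITOR_CONTRAST) {
  if (!inherits(cond, "condition"))
    stop("'cond' must be a condition object; got ", class(cond)[1L])
  if (!cond$name %in% condition_names())
    stop("unknown condition name: '", cond$name, "'")
  te <- cond$target_eye
  ce <- other_eye(te)
  target <- new_component(te, TARGET_ORI, 0, TARGET_WIDTH,
                          cond$target_contrast, role = "target")
  comps <- switch(cond$name,
    none = NULL,
    small = ,
    medium = ,
    large = new_component(ce, COMPETITOR_ORI, 0,
                          COMPETITOR_WIDTHS[[cond$name]],
                          competitor_contrast, role = "competitor"),
    split = rbind(
      new_component(ce, COMPETITOR_ORI, 0, COMPETITOR_WIDTHS[["small"]],
                    competitor_contrast, role = "competitor"),
      new_component(te, COMPETITOR_ORI, 0, COMPETITOR_WIDTHS[["large"]],
                    competitor_contrast,
                    inner_width = COMPETITOR_WIDTHS[["small"]],
                    role = "competitor")))
  rbind(target, comps)
}

## Aperture of a component as a set of closed intervals on the x axis.
component_intervals <- function(comp) {
  h <- comp$width / 2
  if (comp$inner_width > 0) {
    hi <- comp$inner_width / 2
    rbind(c(comp$center_x - h, comp$center_x - hi),
          c(comp$center_x + hi, comp$center_x + h))
  } else {
    rbind(c(comp$center_x - h, comp$center_x + h))
  }
}

## Outer extent (diameter) of the union of competitor apertures, ignoring
## eye-of-origin; this is the fused size that scales stimulus-driven
## attention.
fused_competitor_width <- function(components) {
  comp <- components[components$role == "competitor", , drop = FALSE]
  if (nrow(comp) == 0L) return(NA_real_)
  2 * max(abs(comp$center_x) + comp$width / 2)
}
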