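#' Pipeline configuration
#'
#' Assembles the configuration list used by \code{\link{denoise}},
#' \code{\link{boxToSearch}}, \code{\link{locateIris}} and
#' \code{\link{runBenchmark}}. Defaults can be overridden from a YAML file
#' and/or by named arguments (applied in that order; arguments win).
#'
#' Sections and keys:
#' \describe{
#'   \item{denoise}{\code{reflection_threshold} (normalized gray, default
#'     0.90), \code{mask_dilate_px} (2), \code{closing_radius_px} (3, at a
#'     224-px image scale, rescaled proportionally), \code{stages_enabled}
#'     (character subset of \code{c("reflections", "eyelashes")}),
#'     \code{box_only} (TRUE: denoise only inside the padded detector box),
#'     \code{box_pad_frac} (0.1).}
#'   \item{coarse}{\code{center_window_px} (10), \code{r_min_px} (8),
#'     \code{r_max_frac} (0.35).}
#'   \item{operators}{\code{n_inner} (32), \code{n_outer} (256),
#'     \code{delta_r} (1), \code{sigma} (1),
#'     \code{outer_arcs} (two 90-degree arcs centered on the horizontal axis),
#'     \code{outer_center_window_px} (3), \code{gradient_sign}
#'     (\code{"outward_brighter"}), \code{min_valid_frac} (0.5).}
#' }
#'
#' @param path optional path to a YAML file with any subset of the keys.
#' @param ... named overrides, e.g. \code{denoise = list(box_only = FALSE)}.
#' @return nested configuration list.
#' @examples
#' cfg <- irisConfig(operators = list(n_inner = 64))
#' cfg$operators$n_inner
#' @export
irisConfig <- function(path = NULL, ...) {
  cfg <- list(
    denoise = list(
      reflection_threshold = 0.90,
      mask_dilate_px = 2L,
      closing_radius_px = 3L,
      stages_enabled = c("reflections", "eyelashes"),
      box_only = TRUE,
      box_pad_frac = 0.1
    ),
    coarse = list(
      center_window_px = 10L,
      r_min_px = 8L,
      r_max_frac = 0.35
    ),
    operators = list(
      n_inner = 32L,
      n_outer = 256L,
      delta_r = 1,
      sigma = 1,
      outer_arcs = list(c(315, 45), c(135, 225)),
      outer_center_window_px = 3L,
      gradient_sign = "outward_brighter",
      min_valid_frac = 0.5
    )
  )
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    cfg <- .mergeLists(cfg, yaml::read_yaml(path))
  }
  dots <- list(...)
  if (length(dots)) {
    if (is.null(names(dots)) || any(names(dots) == ""))
      stop("configuration overrides must be named")
    cfg <- .mergeLists(cfg, dots)
  }
  cfg
}

# Outer arcs from config -> matrix form for OperatorParams.
.arcsMatrix <- function(arcs) {
  do.call(rbind, lapply(arcs, function(a) matrix(as.numeric(a), ncol = 2L)))
}
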