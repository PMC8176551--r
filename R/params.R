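#' Active contour parameters
#'
#' Bundles the tunable constants of the region-based level-set evolution.
#' Defaults correspond to the fast, re-initialization-free configuration:
#' the length (`mu`) and area (`nu`) penalties are zero and their
#' regularizing role is played by Gaussian smoothing of the level-set field
#' (`sigma`) followed by binarization to \eqn{\pm}`binarize_level`.
#'
#' @param lambda1,lambda2 Nonnegative weights of the inside / outside region
#'   data terms. Defaults 1.
#' @param mu Nonnegative contour-length weight (used only in `mode = "full"`
#'   evolution). Default 0.
#' @param nu Nonnegative area weight (used only in `mode = "full"`).
#'   Default 0.
#' @param epsilon Positive scale of the regularized Heaviside/Dirac pair.
#'   Default 0.1: the field is re-binarized to `{-c, +c}` every iteration,
#'   so `epsilon` must be small relative to `binarize_level` for the region
#'   means to be sharp phase averages rather than blends of both phases.
#' @param dt Positive pseudo-time step. The per-pixel update force is
#'   normalized by its maximum absolute value, so `dt` bounds the
#'   per-iteration change of the field. The field is re-binarized to
#'   `+-binarize_level` every iteration, so a pixel can only change phase
#'   when `dt * |force| > binarize_level`: small `dt` freezes all but the
#'   strongest-force pixels into a boundary-erosion regime, while
#'   `dt >> binarize_level` is sign-dominant — each pixel adopts the sign
#'   of its own force unless vetoed by the Gaussian smoothing — which is
#'   what makes the evolution insensitive to the initial placement and able
#'   to re-capture a distant object within one or two iterations. Default
#'   50 (results are flat across roughly 10-100).
#' @param sigma Positive width (px) of the Gaussian used to regularize the
#'   level-set field between iterations. Default 1.
#' @param binarize_level Positive value `c`: after each regularization the
#'   field is exactly two-valued in `{-c, +c}`. Default 1.
#' @param max_iters Maximum number of evolution iterations in
#'   [acm_segment()]. Default 200.
#' @param stable_iters Number of consecutive iterations with an unchanged
#'   binary mask that triggers early convergence. Default 5.
#' @param orient `"bright"` (default) relabels the phases after each
#'   binarization so that the inside phase has the larger field mean; the
#'   two-phase energy is label-symmetric (when `lambda1 == lambda2`), and
#'   this fixes the labeling to the convention in which the object is the
#'   bright phase, as it is on a back-projected weight map. `"none"`
#'   disables the relabeling.
#'
#' @return An object of class `acm_params` (a named list).
#' @export
#' @examples
#' p <- acm_params(sigma = 1.5)
#' p$lambda1
acm_params <- function(lambda1 = 1, lambda2 = 1, mu = 0, nu = 0,
                       epsilon = 0.1, dt = 50, sigma = 1, binarize_level = 1,
                       max_iters = 200L, stable_iters = 5L,
                       orient = c("bright", "none")) {
  orient <- match.arg(orient)
  stopifnot(lambda1 >= 0, lambda2 >= 0, mu >= 0, nu >= 0,
            epsilon > 0, dt > 0, sigma > 0, binarize_level > 0,
            max_iters >= 0, stable_iters >= 1)
  structure(list(lambda1 = lambda1, lambda2 = lambda2, mu = mu, nu = nu,
                 epsilon = epsilon, dt = dt, sigma = sigma,
                 binarize_level = binarize_level,
                 max_iters = as.integer(max_iters),
                 stable_iters = as.integer(stable_iters),
                 orient = orient),
            class = "acm_params")
}

#' Color quantizer
#'
#' Maps 8-bit color pixels to histogram bins by uniform-width binning,
#' `floor(value * bins / (channel_max + 1))` per channel. The default is the
#' 16-bin color model: 16 bins per RGB channel, i.e. a 16x16x16 joint
#' histogram. `mode = "luminance"` instead bins a single luminance channel
#' into `bins_per_channel` bins (the most literal single-histogram reading
#' of a "16 bin" color model).
#'
#' @param bins_per_channel Positive integer, default 16.
#' @param channel_max Largest representable channel value, default 255.
#' @param mode `"rgb"` (joint histogram) or `"luminance"`.
#' @return An object of class `color_quantizer`.
#' @export
color_quantizer <- function(bins_per_channel = 16L, channel_max = 255L,
                            mode = c("rgb", "luminance")) {
  mode <- match.arg(mode)
  stopifnot(bins_per_channel >= 1, channel_max >= 1)
  nb <- as.integer(bins_per_channel)
  structure(list(bins_per_channel = nb,
                 channel_max = as.integer(channel_max),
                 mode = mode,
                 n_bins = if (mode == "rgb") nb^3L else nb),
            class = "color_quantizer")
}

#' Spatial kernel for histogram weighting
#'
#' Gaussian profile `exp(-||u||^2 / 2)` on coordinates normalized per axis
#' by the window half-extents, `u = ((x - cx)/hx, (y - cy)/hy)`, so the same
#' kernel serves the reference model (implicit bandwidth) and the candidate
#' model (explicit bandwidth `h`).
#'
#' @return An object of class `kernel_spec`.
#' @export
kernel_spec <- function() {
  structure(list(profile = "gaussian"), class = "kernel_spec")
}

#' Bounding window
#'
#' A (possibly sub-pixel) tracking window: real-valued center `(x, y)` and
#' positive half-extents `(hx, hy)` in pixels. Pixel membership is resolved
#' by rounding the window bounds and clipping against the frame explicitly.
#'
#' @param center Numeric length 2, `(x, y)` with x = column, y = row
#'   (1-based).
#' @param half Numeric length 2, positive half-extents `(hx, hy)` px.
#' @return An object of class `bounding_window`.
#' @export
bounding_window <- function(center, half) {
  stopifnot(length(center) == 2, length(half) == 2, all(half > 0),
            all(is.finite(center)), all(is.finite(half)))
  structure(list(center = as.numeric(center), half = as.numeric(half)),
            class = "bounding_window")
}

#' Convert a rectangle to a bounding window
#'
#' @param box Numeric `c(x, y, w, h)`: top-left corner (1-based column/row)
#'   and width/height in pixels.
#' @return A [bounding_window()].
#' @export
window_from_box <- function(box) {
  stopifnot(length(box) == 4, box[3] >= 1, box[4] >= 1)
  bounding_window(center = c(box[1] + (box[3] - 1) / 2,
                             box[2] + (box[4] - 1) / 2),
                  half = pmax(c((box[3] - 1) / 2, (box[4] - 1) / 2), 0.5))
}

#' Tracker configuration
#'
#' @param acm [acm_params()] for the per-frame contour evolution.
#' @param kernel [kernel_spec()].
#' @param quantizer [color_quantizer()].
#' @param iters_per_frame Evolution iterations per frame (default 50; scale
#'   up for large objects). `0` disables evolution entirely, degrading the
#'   tracker to a pure mean-shift box tracker (useful as an ablation
#'   baseline).
#' @param window_update `"from_mask"` (default): after each frame the
#'   window becomes the bounding box of the evolved mask, padded by 10% and
#'   floored at 8x8 px, which lets the window track scale changes;
#'   `"fixed"`: the window keeps its initial half-extents and only its
#'   center moves.
#' @param weight_cap Upper clip for back-projection weights (default 10).
#' @param ms_max_iters,ms_tol Mean-shift iteration cap (default 20) and
#'   convergence tolerance in px (default 0.5).
#' @return An object of class `tracker_config`.
#' @export
tracker_config <- function(acm = acm_params(),
                           kernel = kernel_spec(),
                           quantizer = color_quantizer(),
                           iters_per_frame = 50L,
                           window_update = c("from_mask", "fixed"),
                           weight_cap = 10,
                           ms_max_iters = 20L,
                           ms_tol = 0.5) {
  window_update <- match.arg(window_update)
  stopifnot(inherits(acm, "acm_params"), inherits(quantizer, "color_quantizer"),
            iters_per_frame >= 0, weight_cap > 0, ms_max_iters >= 1, ms_tol > 0)
  structure(list(acm = acm, kernel = kernel, quantizer = quantizer,
                 iters_per_frame = as.integer(iters_per_frame),
                 window_update = window_update,
                 weight_cap = weight_cap,
                 ms_max_iters = as.integer(ms_max_iters),
                 ms_tol = ms_tol),
            class = "tracker_config")
}
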