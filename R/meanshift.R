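#' Quantize a color frame to histogram bin indices
#'
#' Uniform-width binning per channel:
#' `floor(value * bins / (channel_max + 1))`, so the full channel range maps
#' onto `bins_per_channel` equal bins and `channel_max` falls in the last
#' bin. For the `"rgb"` quantizer the three per-channel indices are combined
#' into one joint bin index; for `"luminance"` the frame is first reduced to
#' Rec. 601 luminance.
#'
#' @param frame Numeric `H x W x 3` array with values in
#'   `[0, channel_max]`, or an `H x W` matrix (treated as a gray frame).
#' @param quantizer [color_quantizer()].
#' @return Integer `H x W` matrix of 1-based bin indices in
#'   `[1, quantizer$n_bins]`.
#' @export
quantize_colors <- function(frame, quantizer = color_quantizer()) {
  q <- quantizer
  if (is.matrix(frame)) {
    frame <- array(rep(frame, 3L), dim = c(dim(frame), 3L))
  }
  stopifnot(length(dim(frame)) == 3, dim(frame)[3] == 3)
  if (min(frame) < 0 || max(frame) > q$channel_max)
    stop("channel values outside [0, channel_max]")
  nb <- q$bins_per_channel
  scale <- nb / (q$channel_max + 1)
  if (q$mode == "luminance") {
    lum <- 0.299 * frame[, , 1] + 0.587 * frame[, , 2] + 0.114 * frame[, , 3]
    idx <- pmin(floor(lum * scale), nb - 1)
    return(matrix(as.integer(idx) + 1L, dim(frame)[1], dim(frame)[2]))
  }
  b1 <- pmin(floor(frame[, , 1] * scale), nb - 1)
  b2 <- pmin(floor(frame[, , 2] * scale), nb - 1)
  b3 <- pmin(floor(frame[, , 3] * scale), nb - 1)
  idx <- b1 + nb * b2 + nb * nb * b3
  matrix(as.integer(idx) + 1L, dim(frame)[1], dim(frame)[2])
}

# integer pixel ranges covered by a window, clipped to the frame.
# Returns NULL when the clipped window is empty.
.window_pixels <- function(window, dim) {
  cx <- window$center[1]; cy <- window$center[2]
  hx <- window$half[1]; hy <- window$half[2]
  x0 <- max(1L, as.integer(round(cx - hx)))
  x1 <- min(as.integer(dim[2]), as.integer(round(cx + hx)))
  y0 <- max(1L, as.integer(round(cy - hy)))
  y1 <- min(as.integer(dim[1]), as.integer(round(cy + hy)))
  if (x1 < x0 || y1 < y0) return(NULL)
  list(xs = x0:x1, ys = y0:y1)
}

# kernel weights for the pixel grid of a window: exp(-||u||^2/2) with
# u = ((x - cx)/hx, (y - cy)/hy); matrix of dim (length(ys), length(xs))
.kernel_weights <- function(px, window) {
  ux <- (px$xs - window$center[1]) / window$half[1]
  uy <- (px$ys - window$center[2]) / window$half[2]
  outer(exp(-0.5 * uy^2), exp(-0.5 * ux^2))
}

#' Build a color-histogram appearance model
#'
#' Kernel-weighted normalized color histogram of the pixels of a window:
#' \deqn{p_c = \frac{\sum_i e^{-\|u_i\|^2/2}\,[b(x_i) = c]}
#'                  {\sum_i e^{-\|u_i\|^2/2}},}
#' with `u_i` the pixel offset from the window center normalized by the
#' window half-extents. The same construction yields the reference model
#' `q` (built once on the manually selected object) and the candidate model
#' `p(y)` at any later center `y`.
#'
#' @param frame Numeric `H x W x 3` color array.
#' @param window [bounding_window()].
#' @param kernel [kernel_spec()] (Gaussian profile).
#' @param quantizer [color_quantizer()].
#' @return Numeric vector of length `quantizer$n_bins` summing to 1, class
#'   `histogram_model`.
#' @export
color_model <- function(frame, window, kernel = kernel_spec(),
                        quantizer = color_quantizer()) {
  bins <- quantize_colors(frame, quantizer)
  px <- .window_pixels(window, dim(bins))
  if (is.null(px)) stop("lost target: window does not intersect the frame")
  w <- .kernel_weights(px, window)
  b <- bins[px$ys, px$xs, drop = FALSE]
  probs <- numeric(quantizer$n_bins)
  acc <- vapply(split(as.numeric(w), as.vector(b)), sum, numeric(1))
  probs[as.integer(names(acc))] <- acc
  probs <- probs / sum(probs)
  structure(probs, class = "histogram_model")
}

#' Unweighted color histogram of a whole frame
#'
#' Context model: the normalized histogram of every pixel in the frame,
#' used as the reference denominator when back-projecting a freshly
#' selected object against its surroundings (before a segmented object
#' model exists).
#'
#' @param frame Numeric `H x W x 3` color array.
#' @param quantizer [color_quantizer()].
#' @return Numeric vector of length `quantizer$n_bins` summing to 1, class
#'   `histogram_model`.
#' @export
frame_model <- function(frame, quantizer = color_quantizer()) {
  bins <- quantize_colors(frame, quantizer)
  probs <- numeric(quantizer$n_bins)
  tab <- tabulate(as.vector(bins), nbins = quantizer$n_bins)
  structure(tab / sum(tab), class = "histogram_model")
}

#' Color model restricted to a segmented mask
#'
#' Kernel-weighted histogram as in [color_model()], but summing only over
#' the pixels of `mask` (the extracted object), with the kernel centered
#' on the mask bounding box. Colors absent from the mask get exactly zero
#' probability, which makes the back-projected weight map vanish on the
#' background.
#'
#' @param frame Numeric `H x W x 3` color array.
#' @param mask Logical matrix (nonempty).
#' @param kernel [kernel_spec()].
#' @param quantizer [color_quantizer()].
#' @return Numeric vector of length `quantizer$n_bins` summing to 1, class
#'   `histogram_model`.
#' @export
color_model_from_mask <- function(frame, mask, kernel = kernel_spec(),
                                  quantizer = color_quantizer()) {
  stopifnot(is.logical(mask), any(mask))
  bins <- quantize_colors(frame, quantizer)
  ij <- which(mask, arr.ind = TRUE)
  ys <- range(ij[, 1]); xs <- range(ij[, 2])
  ctr <- c(mean(xs), mean(ys))
  half <- pmax(c((xs[2] - xs[1]) / 2, (ys[2] - ys[1]) / 2), 0.5)
  u2 <- ((ij[, 2] - ctr[1]) / half[1])^2 + ((ij[, 1] - ctr[2]) / half[2])^2
  w <- exp(-0.5 * u2)
  b <- bins[mask]
  probs <- numeric(quantizer$n_bins)
  acc <- vapply(split(w, b), sum, numeric(1))
  probs[as.integer(names(acc))] <- acc
  structure(probs / sum(probs), class = "histogram_model")
}

#' Bhattacharyya coefficient between two histograms
#'
#' \eqn{\rho(q, p) = \sum_c \sqrt{q_c p_c}} in `[0, 1]`; 1 iff the two
#' normalized histograms are equal, 0 iff their supports are disjoint.
#'
#' @param q,p Numeric probability vectors with the same bin layout.
#' @return A number in `[0, 1]`.
#' @export
bhattacharyya <- function(q, p) {
  if (length(q) != length(p))
    stop("histograms have different bin counts")
  sum(sqrt(as.numeric(q) * as.numeric(p)))
}

#' Back-project the target model into a weight map
#'
#' Per-pixel likelihood-ratio score
#' \eqn{W(x) = \sqrt{q_{b(x)} / p_{b(x)}}}: large where the pixel's color
#' bin is characteristic of the reference model `q` relative to the current
#' candidate surroundings `p`, zero where `q` has no mass. `p` is floored
#' at 1e-10 before division and `W` is clipped at `cap` so the field stays
#' finite. The map is computed over the full frame so the contour can
#' recover an object the localizer missed.
#'
#' @param frame Numeric `H x W x 3` color array.
#' @param q Reference [color_model()].
#' @param p Candidate [color_model()] at the current center.
#' @param quantizer [color_quantizer()].
#' @param cap Upper clip for the weights (default 10).
#' @return Numeric `H x W` matrix, `0 <= W <= cap`.
#' @export
weight_map <- function(frame, q, p, quantizer = color_quantizer(), cap = 10) {
  stopifnot(length(q) == quantizer$n_bins, length(p) == quantizer$n_bins,
            cap > 0)
  bins <- quantize_colors(frame, quantizer)
  wb <- sqrt(as.numeric(q) / pmax(as.numeric(p), 1e-10))
  wb[as.numeric(q) == 0] <- 0
  wb <- pmin(wb, cap)
  matrix(wb[bins], nrow(bins), ncol(bins))
}

#' Localize the target by mean-shift iterations
#'
#' Starting from `start`, repeatedly moves the window center to the
#' weighted centroid
#' \eqn{y \leftarrow \sum_i x_i w_i g_i / \sum_i w_i g_i}, where
#' `w_i = sqrt(q_b / p_b)` are the back-projection weights of the window
#' pixels (with the candidate model `p` rebuilt at the current center) and
#' `g_i = exp(-||u_i||^2/2)` the kernel profile weight. Stops when the
#' shift is below `tol` px or after `max_iters` iterations. A window with
#' no model support (all weights zero) stays put and simply reports a low
#' similarity; drifting fully off the frame is an error.
#'
#' @param frame Numeric `H x W x 3` color array.
#' @param q Reference [color_model()].
#' @param start [bounding_window()] to start from.
#' @param kernel [kernel_spec()].
#' @param quantizer [color_quantizer()].
#' @param max_iters Iteration cap (default 20).
#' @param tol Convergence tolerance in px (default 0.5).
#' @param cap Weight clip as in [weight_map()].
#' @return List: `center` (length-2 numeric), `rho` (Bhattacharyya
#'   similarity between `q` and the candidate model at the final center),
#'   `iterations`.
#' @export
meanshift_localize <- function(frame, q, start, kernel = kernel_spec(),
                               quantizer = color_quantizer(),
                               max_iters = 20L, tol = 0.5, cap = 10) {
  bins <- quantize_colors(frame, quantizer)
  qn <- as.numeric(q)
  win <- start
  it <- 0L
  while (it < max_iters) {
    it <- it + 1L
    px <- .window_pixels(win, dim(bins))
    if (is.null(px)) stop("lost target: window drifted outside the frame")
    g <- .kernel_weights(px, win)
    b <- bins[px$ys, px$xs, drop = FALSE]
    # candidate model at the current center, then per-pixel weights
    pw <- numeric(quantizer$n_bins)
    acc <- vapply(split(as.numeric(g), as.vector(b)), sum, numeric(1))
    pw[as.integer(names(acc))] <- acc
    pw <- pw / sum(pw)
    wb <- sqrt(qn / pmax(pw, 1e-10))
    wb[qn == 0] <- 0
    wb <- pmin(wb, cap)
    w <- matrix(wb[b], nrow(b), ncol(b))
    tot <- sum(w * g)
    if (tot == 0) break  # no support under the window; stay put
    # centroid in window-relative coordinates so integer scene shifts
    # translate the iteration exactly
    wg <- w * g
    sx <- sum(rep(px$xs - win$center[1], each = length(px$ys)) * wg) / tot
    sy <- sum(rep(px$ys - win$center[2], times = length(px$xs)) * wg) / tot
    win <- bounding_window(win$center + c(sx, sy), win$half)
    if (sqrt(sx^2 + sy^2) < tol) break
  }
  p_final <- color_model(frame, win, kernel, quantizer)
  list(center = win$center, rho = bhattacharyya(q, p_final), iterations = it)
}
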