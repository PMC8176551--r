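#' Regularized Heaviside and Dirac functions
#'
#' Smooth approximations of the unit step and its derivative used to
#' differentiate the region integrals of the two-phase segmentation energy:
#' \deqn{H_\epsilon(z) = \tfrac12\left(1 + \tfrac{2}{\pi}\arctan(z/\epsilon)\right),
#'       \qquad
#'       \delta_\epsilon(z) = \frac{1}{\pi}\,\frac{\epsilon}{\epsilon^2 + z^2}.}
#' `heaviside_eps` is monotone in `z` with values in (0, 1) and
#' `heaviside_eps(0) = 0.5`; `dirac_eps` is its derivative, nonnegative,
#' integrating to 1 over the real line.
#'
#' @param z Numeric vector/matrix.
#' @param epsilon Positive regularization scale.
#' @return Numeric of the same shape as `z`.
#' @export
#' @examples
#' heaviside_eps(0, 1)          # 0.5
#' heaviside_eps(10, 1)         # ~0.968
heaviside_eps <- function(z, epsilon = 1) {
  if (!is.numeric(epsilon) || length(epsilon) != 1 || epsilon <= 0)
    stop("`epsilon` must be a positive scalar")
  0.5 * (1 + (2 / pi) * atan(z / epsilon))
}

#' @rdname heaviside_eps
#' @export
dirac_eps <- function(z, epsilon = 1) {
  if (!is.numeric(epsilon) || length(epsilon) != 1 || epsilon <= 0)
    stop("`epsilon` must be a positive scalar")
  (epsilon / pi) / (epsilon^2 + z^2)
}

#' Initialize a level-set field from a rectangular window
#'
#' The field is binary-valued rather than a true signed distance function:
#' `+level` inside the rectangle, `-level` outside, so the zero level lies
#' on the rectangle boundary. The fast evolution never needs signed
#' distances (the gradient magnitude appears only in the optional curvature
#' term) and each iteration re-binarizes the field anyway.
#'
#' @param dim Integer `c(height, width)` of the grid.
#' @param box Numeric `c(x, y, w, h)` rectangle (1-based top-left
#'   column/row, width, height). Clipped to the grid; an empty intersection
#'   is an error.
#' @param level Positive value `c` of the binary field.
#' @return A `height x width` matrix with values in `{-level, +level}`.
#' @export
levelset_from_box <- function(dim, box, level = 1) {
  stopifnot(length(dim) == 2, dim[1] >= 1, dim[2] >= 1,
            length(box) == 4, level > 0)
  x0 <- max(1L, as.integer(ceiling(box[1])))
  y0 <- max(1L, as.integer(ceiling(box[2])))
  x1 <- min(as.integer(dim[2]), as.integer(floor(box[1] + box[3] - 1)))
  y1 <- min(as.integer(dim[1]), as.integer(floor(box[2] + box[4] - 1)))
  if (x1 < x0 || y1 < y0)
    stop("invalid initialization window: no intersection with the grid")
  phi <- matrix(-level, dim[1], dim[2])
  phi[y0:y1, x0:x1] <- level
  phi
}

#' Region means inside and outside the contour
#'
#' Heaviside-weighted field averages:
#' \deqn{m_1 = \frac{\int W H_\epsilon(\phi)}{\int H_\epsilon(\phi)}, \qquad
#'       m_2 = \frac{\int W (1 - H_\epsilon(\phi))}{\int (1 - H_\epsilon(\phi))}.}
#' With `epsilon = 0` the hard indicator `phi >= 0` is used (the sharp
#' limit). If one region has (near-)zero total weight, its mean falls back
#' to the global field mean and the result is flagged degenerate (with a
#' warning).
#'
#' @param field Numeric matrix (image or weight map).
#' @param phi Level-set matrix of the same shape.
#' @param epsilon Nonnegative Heaviside scale; `0` = sharp limit.
#' @return List with components `m1`, `m2`, `degenerate` (class
#'   `region_means`).
#' @export
region_means <- function(field, phi, epsilon = 1) {
  stopifnot(is.matrix(field), is.matrix(phi), all(dim(field) == dim(phi)),
            epsilon >= 0)
  H <- if (epsilon == 0) (phi >= 0) * 1 else heaviside_eps(phi, epsilon)
  s_in <- sum(H)
  s_out <- sum(1 - H)
  degenerate <- FALSE
  tiny <- 1e-8
  if (s_in > tiny) {
    m1 <- sum(field * H) / s_in
  } else {
    m1 <- mean(field)
    degenerate <- TRUE
  }
  if (s_out > tiny) {
    m2 <- sum(field * (1 - H)) / s_out
  } else {
    m2 <- mean(field)
    degenerate <- TRUE
  }
  if (degenerate)
    warning("degenerate partition: one region has (near-)zero weight")
  structure(list(m1 = m1, m2 = m2, degenerate = degenerate),
            class = "region_means")
}

# central differences with replicate padding, d/dx = along columns
.grad_x <- function(m) {
  W <- ncol(m)
  (m[, pmin(seq_len(W) + 1L, W), drop = FALSE] -
     m[, pmax(seq_len(W) - 1L, 1L), drop = FALSE]) / 2
}

.grad_y <- function(m) {
  H <- nrow(m)
  (m[pmin(seq_len(H) + 1L, H), , drop = FALSE] -
     m[pmax(seq_len(H) - 1L, 1L), , drop = FALSE]) / 2
}

#' Curvature of the level-set field
#'
#' Euclidean curvature of the level lines,
#' \eqn{\kappa = \mathrm{div}(\nabla\phi / |\nabla\phi|)}, discretized with
#' central differences and replicate padding; the gradient magnitude is
#' floored at 1e-10 to avoid division by zero. Scale invariant:
#' `curvature(a * phi) == curvature(phi)` for `a > 0`.
#'
#' @param phi Level-set matrix, at least 3x3.
#' @return Matrix of the same shape.
#' @export
curvature <- function(phi) {
  stopifnot(is.matrix(phi), nrow(phi) >= 3, ncol(phi) >= 3)
  gx <- .grad_x(phi)
  gy <- .grad_y(phi)
  nrm <- pmax(sqrt(gx^2 + gy^2), 1e-10)
  .grad_x(gx / nrm) + .grad_y(gy / nrm)
}

#' Two-phase segmentation energy
#'
#' The Chan-Vese energy of the current partition: squared residuals about
#' the inside/outside means, weighted by the regularized Heaviside, plus
#' optional length (`mu`) and area (`nu`) penalties:
#' \deqn{E = \lambda_1\!\int (W - m_1)^2 H_\epsilon(\phi)
#'   + \lambda_2\!\int (W - m_2)^2 (1 - H_\epsilon(\phi))
#'   + \mu\!\int \delta_\epsilon(\phi)|\nabla\phi| + \nu\!\int H_\epsilon(\phi).}
#' The means are recomputed from the given `phi`. Used as a descent
#' monitor; the evolution itself never evaluates it.
#'
#' @param field Numeric matrix.
#' @param phi Level-set matrix, same shape.
#' @param params [acm_params()].
#' @return A single nonnegative number.
#' @export
chanvese_energy <- function(field, phi, params = acm_params()) {
  stopifnot(all(dim(field) == dim(phi)))
  H <- heaviside_eps(phi, params$epsilon)
  m <- suppressWarnings(region_means(field, phi, params$epsilon))
  e <- params$lambda1 * sum((field - m$m1)^2 * H) +
    params$lambda2 * sum((field - m$m2)^2 * (1 - H))
  if (params$mu > 0) {
    gx <- .grad_x(phi)
    gy <- .grad_y(phi)
    e <- e + params$mu * sum(dirac_eps(phi, params$epsilon) * sqrt(gx^2 + gy^2))
  }
  if (params$nu != 0) e <- e + params$nu * sum(H)
  e
}

#' One evolution step of the level-set field
#'
#' Gradient-descent update of the segmentation energy. In `"fast"` mode the
#' force is the pure data term
#' \deqn{F = \delta_\epsilon(\phi)\,[-\lambda_1 (W - m_1)^2 + \lambda_2 (W - m_2)^2],}
#' in `"full"` mode the curvature and area terms are added,
#' \eqn{F = \delta_\epsilon(\phi)[\mu\kappa - \nu - \lambda_1(\cdot)^2 + \lambda_2(\cdot)^2]}.
#' The force is normalized by its maximum absolute value (so the update is
#' clipped to `[-dt, dt]` per pixel) and added to `phi`. No regularization
#' is applied here; see [smooth_binarize()].
#'
#' @param field Numeric matrix.
#' @param phi Level-set matrix, same shape.
#' @param means [region_means()] computed from this `field`/`phi` pair.
#' @param params [acm_params()].
#' @param mode `"fast"` (default) or `"full"`.
#' @return The updated level-set matrix.
#' @export
evolve_step <- function(field, phi, means, params = acm_params(),
                        mode = c("fast", "full")) {
  mode <- match.arg(mode)
  stopifnot(all(dim(field) == dim(phi)), inherits(means, "region_means"))
  force <- -params$lambda1 * (field - means$m1)^2 +
    params$lambda2 * (field - means$m2)^2
  if (mode == "full")
    force <- force + params$mu * curvature(phi) - params$nu
  force <- dirac_eps(phi, params$epsilon) * force
  if (!all(is.finite(force)))
    stop("non-finite evolution force; check the input field")
  ma <- max(abs(force))
  # a numerically uniform field produces only rounding-noise forces;
  # normalizing those to unit strength would amplify pure noise
  if (ma <= 1e-12) return(phi)
  phi + params$dt * (force / ma)
}

# normalized 1-D Gaussian taps with radius ceiling(3*sigma)
.gauss_taps <- function(sigma) {
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  list(k = k / sum(k), r = r)
}

# separable Gaussian convolution, replicate padding
.gauss_smooth <- function(m, sigma) {
  g <- .gauss_taps(sigma)
  r <- g$r
  k <- g$k
  H <- nrow(m)
  W <- ncol(m)
  pad <- m[pmin(pmax(seq(1L - r, H + r), 1L), H),
           pmin(pmax(seq(1L - r, W + r), 1L), W), drop = FALSE]
  tmp <- matrix(0, H + 2L * r, W)
  for (j in seq(-r, r))
    tmp <- tmp + k[j + r + 1L] * pad[, (1L + r + j):(W + r + j), drop = FALSE]
  out <- matrix(0, H, W)
  for (j in seq(-r, r))
    out <- out + k[j + r + 1L] * tmp[(1L + r + j):(H + r + j), , drop = FALSE]
  out
}

#' Regularize the level-set field by smoothing and binarization
#'
#' Convolves `phi` with an isotropic Gaussian of width `sigma`
#' (replicate-padded) and maps the result to `+level` where nonnegative and
#' `-level` where negative. This is the step that replaces signed-distance
#' re-initialization: the output is exactly two-valued, the smoothing plays
#' the role of the contour-length penalty, and no distance information ever
#' needs restoring.
#'
#' @param phi Level-set matrix.
#' @param sigma Positive Gaussian width (px).
#' @param level Positive binarization value.
#' @return A matrix with values exactly in `{-level, +level}`.
#' @export
smooth_binarize <- function(phi, sigma = 1, level = 1) {
  stopifnot(is.matrix(phi), sigma > 0, level > 0)
  s <- .gauss_smooth(phi, sigma)
  ifelse(s >= 0, level, -level)
}

# hard relabeling: keep the bright phase inside (no-op when a phase is empty)
.orient_bright <- function(field, phi) {
  mask <- phi > 0
  n_in <- sum(mask)
  if (n_in == 0L || n_in == length(mask)) return(phi)
  if (mean(field[mask]) < mean(field[!mask])) -phi else phi
}

# shared inner loop: {means -> evolve(fast) -> smooth+binarize [-> orient]}
# runs at most `iters` iterations, stopping early when the binary mask is
# unchanged for `stable_iters` consecutive iterations or the partition
# degenerates. Hot path in C++ (src/acm_evolve.cpp); .acm_evolve_r is the
# plain-R reference used to validate it.
.acm_evolve <- function(field, phi, params, iters,
                        stable_iters = params$stable_iters) {
  .acm_evolve_cpp(field, phi, params$lambda1, params$lambda2,
                  params$mu, params$nu, params$epsilon, params$dt,
                  params$sigma, params$binarize_level,
                  as.integer(iters), as.integer(stable_iters),
                  params$orient == "bright")
}

.acm_evolve_r <- function(field, phi, params, iters,
                          stable_iters = params$stable_iters) {
  energy <- numeric(0)
  stable <- 0L
  it <- 0L
  prev_mask <- phi > 0
  while (it < iters) {
    it <- it + 1L
    means <- suppressWarnings(region_means(field, phi, params$epsilon))
    phi_new <- evolve_step(field, phi, means, params, mode = "fast")
    if (identical(phi_new, phi)) {   # zero force: stationary field
      it <- it - 1L
      break
    }
    # binarize before smoothing: the regularizer is then an equal-vote
    # majority filter on the phase labels rather than amplitude-weighted
    lv <- params$binarize_level
    phi <- smooth_binarize(ifelse(phi_new >= 0, lv, -lv),
                           params$sigma, lv)
    if (params$orient == "bright") phi <- .orient_bright(field, phi)
    mask <- phi > 0
    energy[it] <- chanvese_energy(field, phi, params)
    n_in <- sum(mask)
    if (n_in == 0L || n_in == length(mask)) break
    stable <- if (identical(mask, prev_mask)) stable + 1L else 0L
    prev_mask <- mask
    if (stable >= stable_iters) break
  }
  n_fin <- sum(phi > 0)
  list(phi = phi, iterations = it, energy = energy,
       degenerate = n_fin == 0L || n_fin == length(phi))
}

#' Segment a scalar field with the fast active contour
#'
#' Initializes a binary level-set field from `init_box` and repeats
#' \{region means -> fast evolution step -> Gaussian smoothing +
#' binarization\} until the binary mask is unchanged for
#' `params$stable_iters` consecutive iterations, `params$max_iters` is
#' reached, or the partition degenerates (one region vanishes, which is
#' flagged with a warning). The result is insensitive to the placement of
#' the initial window: the data force acts on the whole domain, so the
#' contour settles on the same bright/dark partition from distant
#' initializations.
#'
#' @param field Numeric matrix (a grayscale image in `[0, 1]` or a weight
#'   map).
#' @param init_box Numeric `c(x, y, w, h)` initialization rectangle.
#' @param params [acm_params()].
#' @return A list of class `acm_segmentation`: `mask` (logical matrix),
#'   `phi`, `iterations`, `energy` (per-iteration trace), `degenerate`.
#' @export
#' @examples
#' img <- matrix(0.1, 48, 48)
#' img[15:34, 15:34] <- 0.9
#' seg <- acm_segment(img, c(20, 20, 12, 12), acm_params(max_iters = 60))
#' sum(seg$mask)   # close to 400
acm_segment <- function(field, init_box, params = acm_params()) {
  stopifnot(is.matrix(field))
  phi <- levelset_from_box(dim(field), init_box, params$binarize_level)
  res <- .acm_evolve(field, phi, params, params$max_iters)
  if (res$degenerate)
    warning("segmentation stopped on a degenerate partition")
  structure(list(mask = res$phi > 0, phi = res$phi,
                 iterations = res$iterations, energy = res$energy,
                 degenerate = res$degenerate),
            class = "acm_segmentation")
}
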