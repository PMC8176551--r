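#' Translate a level-set field
#'
#' Shifts the field by an integer pixel displacement; vacated border cells
#' are filled with the outside value `-level`. A shape pushed entirely off
#' the grid yields an all-outside field carrying a `lost` attribute.
#'
#' @param phi Level-set matrix.
#' @param displacement Numeric `c(dx, dy)` (columns, rows); rounded to
#'   integers.
#' @param level Magnitude used for the outside fill (default `max(abs(phi))`).
#' @return The shifted matrix.
#' @export
translate_levelset <- function(phi, displacement, level = max(abs(phi))) {
  d <- as.integer(round(displacement))
  H <- nrow(phi); W <- ncol(phi)
  out <- matrix(-level, H, W)
  if (abs(d[1]) >= W || abs(d[2]) >= H) {
    attr(out, "lost") <- TRUE
    return(out)
  }
  sx <- max(1L, 1L + d[1]):min(W, W + d[1])
  sy <- max(1L, 1L + d[2]):min(H, H + d[2])
  out[sy, sx] <- phi[sy - d[2], sx - d[1], drop = FALSE]
  out
}

#' Evolve the contour on a back-projected weight map
#'
#' Runs the fast active-contour inner loop of [acm_segment()] with the
#' weight map `W` in place of the image: the region means become
#' Heaviside-weighted averages of `W` and the contour settles on the
#' high-weight (target-colored) phase.
#'
#' @param W Nonnegative weight-map matrix.
#' @param phi Level-set matrix (the translated previous contour).
#' @param acm [acm_params()].
#' @param iters Number of evolution iterations.
#' @return List: `phi`, `iterations`, `energy`, `degenerate`.
#' @export
evolve_on_weight_map <- function(W, phi, acm = acm_params(), iters = 50L) {
  stopifnot(is.matrix(W), all(is.finite(W)), min(W) >= 0,
            all(dim(W) == dim(phi)))
  .acm_evolve(W, phi, acm, iters)
}

# binary dilation by k 4-neighbourhood steps
.dilate_mask <- function(mask, k = 1L) {
  H <- nrow(mask); W <- ncol(mask)
  for (i in seq_len(k)) {
    mask <- mask |
      rbind(mask[-1, , drop = FALSE], FALSE) |
      rbind(FALSE, mask[-H, , drop = FALSE]) |
      cbind(mask[, -1, drop = FALSE], FALSE) |
      cbind(FALSE, mask[, -W, drop = FALSE])
  }
  mask
}

# background-weighted histogram correction: shrink each model color by its
# presence in the scene outside the candidate object (beyond a small
# buffer, so boundary mixing does not count). Colors occupying more than
# `tol` of the exterior are background texture, however rare; a reliable
# object color is (nearly) absent outside the object.
.bg_weight_model <- function(q, frame, mask, quantizer,
                             buffer = 5L, tol = 1e-3) {
  ext <- !.dilate_mask(mask, buffer)
  if (!any(ext)) return(q)
  bins <- quantize_colors(frame, quantizer)
  sigma <- tabulate(bins[ext], nbins = quantizer$n_bins) / sum(ext)
  v <- ifelse(sigma > 0, pmin(tol / sigma, 1), 1)
  q2 <- as.numeric(q) * v
  if (sum(q2) <= 0) return(q)
  structure(q2 / sum(q2), class = "histogram_model")
}

# geodesic reconstruction: the connected component(s) of `mask` reachable
# from `seed` by 4-neighbourhood steps
.mask_reconstruct <- function(mask, seed) {
  cur <- seed & mask
  H <- nrow(mask); W <- ncol(mask)
  repeat {
    grown <- cur |
      rbind(cur[-1, , drop = FALSE], FALSE) |
      rbind(FALSE, cur[-H, , drop = FALSE]) |
      cbind(cur[, -1, drop = FALSE], FALSE) |
      cbind(FALSE, cur[, -W, drop = FALSE])
    grown <- grown & mask
    if (identical(grown, cur)) return(cur)
    cur <- grown
  }
}

# binary erosion by k 4-neighbourhood steps (used to strip mixed boundary
# pixels before color sampling)
.erode_mask <- function(mask, k = 2L) {
  for (i in seq_len(k)) {
    eroded <- mask & !.mask_boundary(mask)
    if (!any(eroded)) return(mask)
    mask <- eroded
  }
  mask
}

# window from a mask bounding box: padded 10%, floored at 8x8 px
.window_from_mask <- function(mask) {
  ij <- which(mask, arr.ind = TRUE)
  ys <- range(ij[, 1]); xs <- range(ij[, 2])
  cx <- mean(xs); cy <- mean(ys)
  hx <- max(1.1 * (xs[2] - xs[1]) / 2, 3.5)
  hy <- max(1.1 * (ys[2] - ys[1]) / 2, 3.5)
  bounding_window(c(cx, cy), c(hx, hy))
}

.frame_result <- function(mask, center, rho, ms_iters, acm_iters,
                          lost = FALSE) {
  structure(list(mask = mask, center = as.numeric(center), rho = rho,
                 ms_iters = as.integer(ms_iters),
                 acm_iters = as.integer(acm_iters), lost = lost),
            class = "frame_result")
}

#' Initialize the tracker on the first frame
#'
#' Builds a provisional color model from the manually selected box,
#' back-projects it against the full-frame context histogram (the box model
#' is an object/background mixture, so the candidate model at the same
#' center would cancel it bin-by-bin; the context ratio instead scores how
#' overrepresented each color is inside the box), extracts the frame-1 mask
#' by weight-map evolution, and then builds the reference model `q` from
#' the mask pixels only. `q` is fixed for the rest of the sequence; colors
#' absent from the extracted object have zero reference probability, so
#' later weight maps vanish on the background.
#'
#' @param frame Numeric `H x W x 3` color array (first frame).
#' @param box Numeric `c(x, y, w, h)` object selection.
#' @param config [tracker_config()].
#' @return List: `state` (class `track_state`: `frame_index`, `center`,
#'   `window`, `phi`, `q_ref`) and `result` (class `frame_result`).
#' @export
init_tracker <- function(frame, box, config = tracker_config()) {
  stopifnot(length(dim(frame)) == 3)
  window <- window_from_box(box)
  q_box <- color_model(frame, window, config$kernel, config$quantizer)
  phi <- levelset_from_box(dim(frame)[1:2], box, config$acm$binarize_level)
  p_ctx <- frame_model(frame, config$quantizer)
  q_ref <- q_box
  acm_iters <- 0L
  if (config$iters_per_frame > 0) {
    # two passes: the box model is an object/background mixture, so the
    # first mask can carry background regions; rebuilding the model from
    # the eroded mask interior and re-evolving removes them. Boundary
    # pixels are excluded because they are mixed (rasterization, smoothing
    # bias) and the ratio weights would amplify any leaked color.
    box_mask <- levelset_from_box(dim(frame)[1:2], box, 1) > 0
    for (pass in 1:2) {
      Wm <- weight_map(frame, q_ref, p_ctx, config$quantizer,
                       config$weight_cap)
      ev <- evolve_on_weight_map(Wm, phi, config$acm,
                                 config$iters_per_frame)
      acm_iters <- acm_iters + ev$iterations
      mask <- ev$phi > 0
      # the selection designates one connected object: keep only the
      # component(s) reachable from the box; same-colored regions
      # elsewhere in the frame are not the selected target
      if (any(mask & box_mask))
        mask <- .mask_reconstruct(mask, box_mask)
      phi <- ifelse(mask, config$acm$binarize_level,
                    -config$acm$binarize_level)
      if (!any(mask)) break
      q_ref <- color_model_from_mask(frame, .erode_mask(mask),
                                     config$kernel, config$quantizer)
      q_ref <- .bg_weight_model(q_ref, frame, mask, config$quantizer)
    }
  }
  mask <- phi > 0
  if (config$window_update == "from_mask" && any(mask))
    window <- .window_from_mask(mask)
  state <- structure(list(frame_index = 1L, center = window$center,
                          window = window, phi = phi, q_ref = q_ref),
                     class = "track_state")
  rho <- bhattacharyya(q_ref, color_model(frame, window, config$kernel,
                                          config$quantizer))
  list(state = state,
       result = .frame_result(mask, window$center, rho, 0L, acm_iters,
                              lost = !any(mask)))
}

#' Track the object into the next frame
#'
#' One pass of the hybrid frame loop: (1) mean-shift localization from the
#' previous center using the fixed reference model `q`; (2) translation of
#' the previous contour by the rounded displacement; (3) back-projection of
#' `q` against the candidate model at the new center into a full-frame
#' weight map; (4) contour evolution on the weight map; (5) window update.
#' A lost target (empty mask or off-grid contour) is flagged and the state
#' frozen so the contour can recover on a later frame.
#'
#' @param frame Numeric `H x W x 3` color array.
#' @param state `track_state` from [init_tracker()] or a previous call.
#' @param config [tracker_config()].
#' @return List: updated `state` and `result` (class `frame_result`).
#' @export
track_frame <- function(frame, state, config = tracker_config()) {
  stopifnot(inherits(state, "track_state"), length(dim(frame)) == 3,
            all(dim(frame)[1:2] == dim(state$phi)))
  start <- bounding_window(state$center, state$window$half)
  ms <- meanshift_localize(frame, state$q_ref, start, config$kernel,
                           config$quantizer, config$ms_max_iters,
                           config$ms_tol, config$weight_cap)
  delta <- ms$center - state$center
  phi <- translate_levelset(state$phi, delta, config$acm$binarize_level)
  if (config$iters_per_frame > 0) {
    # denominator = scene context histogram: the ratio then scores how
    # over-represented a color is in the reference model relative to the
    # whole frame. A window-based denominator would send rare contaminant
    # bins to the cap across the full frame.
    p_ctx <- frame_model(frame, config$quantizer)
    Wm <- weight_map(frame, state$q_ref, p_ctx, config$quantizer,
                     config$weight_cap)
    ev <- evolve_on_weight_map(Wm, phi, config$acm, config$iters_per_frame)
    phi <- ev$phi
    acm_iters <- ev$iterations
  } else {
    acm_iters <- 0L
  }
  mask <- phi > 0
  if (!any(mask)) {
    # lost: keep the previous state (frozen) so a later frame can recover
    state$frame_index <- state$frame_index + 1L
    return(list(state = state,
                result = .frame_result(mask, ms$center, ms$rho,
                                       ms$iterations, acm_iters,
                                       lost = TRUE)))
  }
  if (config$window_update == "from_mask") {
    window <- .window_from_mask(mask)
    center <- window$center
  } else {
    window <- bounding_window(ms$center, state$window$half)
    center <- ms$center
  }
  state$frame_index <- state$frame_index + 1L
  state$center <- center
  state$window <- window
  state$phi <- phi
  list(state = state,
       result = .frame_result(mask, center, ms$rho, ms$iterations, acm_iters))
}

#' Track an object through an image sequence
#'
#' Initializes on the first frame from the given box and applies
#' [track_frame()] to every subsequent frame. Deterministic: identical
#' frames, box and configuration yield bit-identical mask sequences.
#'
#' @param frames List of `H x W x 3` color arrays (all the same shape).
#' @param box Numeric `c(x, y, w, h)` selection on frame 1.
#' @param config [tracker_config()].
#' @return List of `frame_result`, one per frame, class `track_result`.
#' @export
#' @examples
#' seq <- generate_sequence(scene_spec(size = c(48, 48), n_frames = 3,
#'                                     radius = 8, clutter_density = 0,
#'                                     speed = 2, seed = 1))
#' res <- track_sequence(seq$frames, c(17, 17, 15, 15),
#'                       tracker_config(iters_per_frame = 20))
#' length(res)
track_sequence <- function(frames, box, config = tracker_config()) {
  stopifnot(length(frames) >= 1)
  d1 <- dim(frames[[1]])
  for (i in seq_along(frames))
    if (!identical(dim(frames[[i]]), d1))
      stop("frame ", i, " has a different shape than frame 1")
  ini <- init_tracker(frames[[1]], box, config)
  results <- vector("list", length(frames))
  results[[1]] <- ini$result
  state <- ini$state
  for (i in seq_along(frames)[-1]) {
    step <- track_frame(frames[[i]], state, config)
    results[[i]] <- step$result
    state <- step$state
  }
  structure(results, class = "track_result")
}
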