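#' Read an ordered frame sequence from a directory
#'
#' Loads all PNG/TIFF images in `path` (non-recursive), sorted by
#' zero-padded filename. Pixels are returned as 8-bit values in
#' `[0, 255]`; grayscale images are promoted to three channels; alpha
#' channels are dropped. Files named `mask_*` are skipped so a directory
#' written by [write_sequence()] reads back as frames only.
#'
#' @param path Directory containing the frames.
#' @param pattern Filename regular expression (default PNG/TIFF
#'   extensions).
#' @return Named list of `H x W x 3` numeric arrays, in filename order.
#' @export
read_frame_sequence <- function(path,
                                pattern = "\\.(png|tif|tiff)$") {
  files <- sort(list.files(path, pattern = pattern, ignore.case = TRUE))
  files <- files[!grepl("^mask_", files)]
  if (length(files) == 0)
    stop("no readable frames found in ", path)
  frames <- vector("list", length(files))
  names(frames) <- files
  for (i in seq_along(files)) {
    f <- file.path(path, files[i])
    img <- if (grepl("\\.png$", files[i], ignore.case = TRUE))
      png::readPNG(f)
    else
      tiff::readTIFF(f)
    if (is.matrix(img)) img <- array(rep(img, 3L), dim = c(dim(img), 3L))
    if (dim(img)[3] > 3) img <- img[, , 1:3, drop = FALSE]
    if (dim(img)[3] == 2) img <- array(rep(img[, , 1], 3L),
                                       dim = c(dim(img)[1:2], 3L))
    frames[[i]] <- round(img * 255)
    if (i > 1 && !identical(dim(frames[[i]]), dim(frames[[1]])))
      stop("frame shape mismatch in file ", files[i])
  }
  frames
}

#' Read a mask sequence from a directory
#'
#' Reads single-channel 0/255 PNG masks (filenames matching `pattern`,
#' sorted) as logical matrices.
#'
#' @param path Directory.
#' @param pattern Filename regular expression, default `"^mask_.*\\.png$"`.
#' @return Named list of logical matrices.
#' @export
read_mask_sequence <- function(path, pattern = "^mask_.*\\.png$") {
  files <- sort(list.files(path, pattern = pattern, ignore.case = TRUE))
  if (length(files) == 0)
    stop("no readable masks found in ", path)
  masks <- vector("list", length(files))
  names(masks) <- files
  for (i in seq_along(files)) {
    img <- png::readPNG(file.path(path, files[i]))
    if (length(dim(img)) == 3) img <- img[, , 1]
    masks[[i]] <- img >= 0.5
  }
  masks
}

#' Reduce a color frame to luminance in [0, 1]
#'
#' Rec. 601 weights; used when the standalone active contour is applied to
#' a color image.
#'
#' @param frame `H x W x 3` array with values in `[0, 255]`, or a matrix
#'   (returned rescaled).
#' @return Numeric matrix in `[0, 1]`.
#' @export
as_luminance <- function(frame) {
  if (is.matrix(frame)) return(frame / 255)
  (0.299 * frame[, , 1] + 0.587 * frame[, , 2] + 0.114 * frame[, , 3]) / 255
}

# mask boundary: inside pixels with at least one outside 4-neighbour
.mask_boundary <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  up <- rbind(mask[1, , drop = FALSE], mask[-H, , drop = FALSE])
  dn <- rbind(mask[-1, , drop = FALSE], mask[H, , drop = FALSE])
  lf <- cbind(mask[, 1, drop = FALSE], mask[, -W, drop = FALSE])
  rt <- cbind(mask[, -1, drop = FALSE], mask[, W, drop = FALSE])
  mask & !(up & dn & lf & rt)
}

#' Write tracking outputs to a directory
#'
#' Writes one 0/255 mask PNG per frame (named after the input frames when
#' names are given), a per-frame CSV
#' (`frame, center_x, center_y, rho, ms_iters, acm_iters, lost`), and
#' optionally overlay PNGs with the contour drawn on the frame in red.
#'
#' @param results `track_result` (list of `frame_result`).
#' @param out_dir Output directory (created if missing).
#' @param frames Optional list of input frames, required for overlays.
#' @param frame_names Optional character vector of frame names.
#' @param overlay Write contour overlays (default `FALSE`).
#' @return Path of the CSV file, invisibly.
#' @export
write_outputs <- function(results, out_dir, frames = NULL,
                          frame_names = NULL, overlay = FALSE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  n <- length(results)
  if (is.null(frame_names))
    frame_names <- sprintf("frame_%03d.png", seq_len(n))
  rows <- data.frame(frame = character(0), center_x = numeric(0),
                     center_y = numeric(0), rho = numeric(0),
                     ms_iters = integer(0), acm_iters = integer(0),
                     lost = logical(0))
  for (i in seq_len(n)) {
    r <- results[[i]]
    base <- sub("\\.(png|tif|tiff)$", "", frame_names[i], ignore.case = TRUE)
    png::writePNG(r$mask * 1.0,
                  file.path(out_dir, paste0("mask_", base, ".png")))
    if (overlay && !is.null(frames)) {
      ov <- frames[[i]] / 255
      bd <- .mask_boundary(r$mask)
      ov1 <- ov[, , 1]; ov2 <- ov[, , 2]; ov3 <- ov[, , 3]
      ov1[bd] <- 1; ov2[bd] <- 0; ov3[bd] <- 0
      png::writePNG(array(c(ov1, ov2, ov3), dim = dim(ov)),
                    file.path(out_dir, paste0("overlay_", base, ".png")))
    }
    rows <- rbind(rows, data.frame(frame = frame_names[i],
                                   center_x = r$center[1],
                                   center_y = r$center[2],
                                   rho = r$rho, ms_iters = r$ms_iters,
                                   acm_iters = r$acm_iters, lost = r$lost))
  }
  csv <- file.path(out_dir, "tracking.csv")
  utils::write.csv(rows, csv, row.names = FALSE)
  invisible(csv)
}
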