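test_that("color quantization bins 8-bit values uniformly", {
  q <- color_quantizer(16)
  px <- function(r, g, b) array(c(r, g, b), dim = c(1, 1, 3))
  idx <- function(r, g, b) quantize_colors(px(r, g, b), q)[1, 1]
  expect_equal(idx(0, 0, 0), 1)                       # bin (0,0,0)
  expect_equal(idx(255, 255, 255), 15 + 16 * 15 + 256 * 15 + 1)
  # floor(130/16), floor(10/16), floor(250/16) = (8, 0, 15)
  expect_equal(idx(130, 10, 250), 8 + 16 * 0 + 256 * 15 + 1)
  expect_error(quantize_colors(px(-3, 0, 0), q), "channel")
  expect_error(quantize_colors(px(0, 0, 300), q), "channel")
  # luminance mode collapses to bins_per_channel bins
  ql <- color_quantizer(16, mode = "luminance")
  expect_equal(ql$n_bins, 16L)
  expect_equal(quantize_colors(px(255, 255, 255), ql)[1, 1], 16L)
})

test_that("window histograms are normalized and match the double-loop oracle", {
  cd <- color_disk_frame(30, 40, n = 64)
  # uniform-color window: all mass in one bin
  w_in <- bounding_window(c(30, 40), c(4, 4))
  q <- color_model(cd$frame, w_in)
  expect_equal(sum(q), 1, tolerance = 1e-12)
  expect_equal(sum(q > 0), 1)
  expect_equal(max(q), 1)
  # two-pixel worked case: weights 1 and exp(-1/2)
  f2 <- array(0, dim = c(1, 2, 3))
  f2[1, 2, ] <- c(255, 255, 255)
  w2 <- bounding_window(c(1, 1), c(1, 1))
  p2 <- color_model(f2, w2)
  expect_equal(p2[1], 1 / (1 + exp(-0.5)), tolerance = 1e-12)
  expect_equal(p2[15 + 16 * 15 + 256 * 15 + 1], exp(-0.5) / (1 + exp(-0.5)),
               tolerance = 1e-12)
  # oracle equivalence over random windows of a random frame
  withr::with_seed(11, {
    frame <- array(sample(0:255, 40 * 40 * 3, replace = TRUE),
                   dim = c(40, 40, 3))
    for (k in 1:10) {
      win <- bounding_window(stats::runif(2, 8, 32), stats::runif(2, 2, 7))
      got <- color_model(frame, win)
      ora <- brute_color_model(frame, win, color_quantizer())
      expect_equal(as.numeric(got), ora, tolerance = 1e-12)
      expect_equal(sum(got), 1, tolerance = 1e-9)
    }
  })
})

test_that("Bhattacharyya coefficient behaves as a similarity in [0, 1]", {
  withr::with_seed(3, {
    q <- stats::runif(32); q <- q / sum(q)
    expect_equal(bhattacharyya(q, q), 1, tolerance = 1e-12)
    p <- stats::runif(32); p <- p / sum(p)
    expect_equal(bhattacharyya(q, p), bhattacharyya(p, q))
    expect_true(bhattacharyya(q, p) >= 0 && bhattacharyya(q, p) <= 1)
  })
  expect_equal(bhattacharyya(c(0.5, 0.5, 0), c(0, 0, 1)), 0)
  expect_equal(bhattacharyya(c(0.5, 0.5), c(1, 0)), sqrt(0.5),
               tolerance = 1e-12)
  expect_error(bhattacharyya(c(1, 0), c(1, 0, 0)), "bin")
})

test_that("back-projection weights are ratio scores over color bins", {
  cd <- color_disk_frame(30, 30, n = 64)
  q <- color_model_from_mask(cd$frame, cd$mask)
  # p = q: weight 1 exactly on the model support, 0 elsewhere
  W <- weight_map(cd$frame, q, q)
  expect_true(all(W[cd$mask] == 1))
  expect_true(all(W[!cd$mask] == 0))      # background bins have q = 0
  # ratio arithmetic: q = 0.4 vs p = 0.1 gives sqrt(4) = 2
  f1 <- array(c(0, 255, 0, 255, 0, 255), dim = c(1, 2, 3))
  quant2 <- color_quantizer(2, channel_max = 255)
  Wr <- weight_map(f1, c(0.4, rep(0, 6), 0.6), c(0.1, rep(0, 6), 0.9),
                   quant2)
  expect_equal(Wr[1, 1], 2)
  # recoloring a pixel within its bin leaves W unchanged
  f_a <- cd$frame
  f_b <- f_a
  f_b[5, 5, ] <- f_b[5, 5, ] + 7   # stays inside the 16-wide bin (40 -> 47)
  expect_equal(weight_map(f_a, q, q), weight_map(f_b, q, q))
  # the cap bounds the map
  qbig <- c(1, rep(0, 4095))
  f0 <- array(0, dim = c(1, 1, 3))
  expect_equal(weight_map(f0, qbig, c(rep(0, 4095), 1))[1, 1], 10)
})

test_that("mean shift localizes a translated object and is equivariant", {
  a <- color_disk_frame(40, 50)
  b <- color_disk_frame(44, 53)
  q <- color_model_from_mask(a$frame, a$mask)
  start <- bounding_window(c(40, 50), c(12, 12))
  # fixed point: same frame, same start
  ms0 <- meanshift_localize(a$frame, q, start)
  expect_equal(ms0$center, c(40, 50))
  # with the reference built from the same window as the candidate, the
  # similarity at the reference position is ~1
  qw <- color_model(a$frame, start)
  msw <- meanshift_localize(a$frame, qw, start)
  expect_gt(msw$rho, 0.99)
  # (+4, +3) translation recovered within 1 px
  ms <- meanshift_localize(b$frame, q, start)
  expect_lt(max(abs(ms$center - c(44, 53))), 1)
  # exact translation equivariance for integer scene shifts
  t <- c(7, 5)
  a2 <- color_disk_frame(40 + t[1], 50 + t[2])
  b2 <- color_disk_frame(44 + t[1], 53 + t[2])
  q2 <- color_model_from_mask(a2$frame, a2$mask)
  ms2 <- meanshift_localize(b2$frame, q2,
                            bounding_window(c(40, 50) + t, c(12, 12)))
  expect_identical(ms2$center - t, ms$center)
  # erased target: the window stays put and reports low similarity
  bg <- color_disk_frame(40, 50, r = 0.1)$frame
  bg[] <- 40
  msl <- meanshift_localize(bg, q, start)
  expect_lt(msl$rho, 0.1)
  # window fully outside the frame is a lost-target error
  expect_error(meanshift_localize(b$frame, q,
                                  bounding_window(c(500, 500), c(5, 5))),
               "lost")
})
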