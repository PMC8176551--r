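test_that("IoU follows set arithmetic and the brute-force oracle", {
  m <- matrix(FALSE, 12, 12); m[3:8, 3:8] <- TRUE
  expect_equal(mask_iou(m, m), 1)
  # two 10x10 squares offset by 5 px: 50 / 150
  a <- matrix(FALSE, 20, 20); a[1:10, 1:10] <- TRUE
  b <- matrix(FALSE, 20, 20); b[1:10, 6:15] <- TRUE
  expect_equal(mask_iou(a, b), 1 / 3)
  # empty-mask conventions
  e <- matrix(FALSE, 5, 5)
  expect_equal(mask_iou(e, e), 1)
  expect_equal(mask_iou(e, m[1:5, 1:5]), 0)
  withr::with_seed(9, {
    for (k in 1:25) {
      a <- matrix(stats::runif(64) < 0.4, 8, 8)
      b <- matrix(stats::runif(64) < 0.4, 8, 8)
      expect_equal(mask_iou(a, b), brute_iou(a, b), tolerance = 1e-12)
      expect_equal(mask_iou(a, b), mask_iou(b, a))
    }
  })
})

test_that("tracking evaluation counts correctly tracked frames", {
  m <- matrix(FALSE, 10, 10); m[3:7, 3:7] <- TRUE
  ident <- evaluate_tracking(list(m, m), list(m, m))
  expect_equal(ident$percent_correct, 100)
  expect_equal(ident$mean_iou, 1)
  # IoUs (0.9, 0.6, 0.4, 0.8) at threshold 0.5: 3 of 4 frames correct
  mk <- function(n_hit) {
    p <- matrix(FALSE, 10, 40); p[1, seq_len(n_hit)] <- TRUE
    p
  }
  truth <- rep(list(mk(10)), 4)
  pred <- list(mk(9), mk(6), mk(4), mk(8))   # IoU = n/10 here
  ev <- evaluate_tracking(pred, truth, iou_threshold = 0.5)
  expect_equal(ev$per_frame$iou, c(0.9, 0.6, 0.4, 0.8))
  expect_equal(ev$percent_correct, 75)
  expect_error(evaluate_tracking(pred[1:2], truth), "length")
})

test_that("sequences roundtrip losslessly through PNG files", {
  spec <- scene_spec(size = c(48, 48), n_frames = 3, radius = 8, seed = 6)
  seqs <- generate_sequence(spec)
  dir <- withr::local_tempdir()
  write_sequence(seqs, dir)
  frames <- read_frame_sequence(dir)
  expect_length(frames, 3)
  expect_identical(names(frames),
                   sprintf("frame_%03d.png", 1:3))   # sorted order
  for (i in 1:3)
    expect_equal(frames[[i]], seqs$frames[[i]], ignore_attr = TRUE)
  masks <- read_mask_sequence(dir)
  for (i in 1:3)
    expect_identical(unname(masks[[i]]), seqs$gt_masks[[i]])
  expect_error(read_frame_sequence(withr::local_tempdir()), "no readable")
})

test_that("tracking outputs write masks and a per-frame record", {
  cd <- color_disk_frame(24, 24, n = 48, r = 8)
  res <- track_sequence(rep(list(cd$frame), 2), c(18, 18, 13, 13),
                        tracker_config(iters_per_frame = 15))
  dir <- withr::local_tempdir()
  write_outputs(res, dir, frames = rep(list(cd$frame), 2), overlay = TRUE)
  csv <- utils::read.csv(file.path(dir, "tracking.csv"))
  expect_equal(nrow(csv), 2)
  expect_true(all(c("center_x", "rho", "lost") %in% names(csv)))
  back <- png::readPNG(file.path(dir, "mask_frame_001.png"))
  expect_identical(back >= 0.5, res[[1]]$mask)
  expect_true(file.exists(file.path(dir, "overlay_frame_001.png")))
  # empty result list: header-only CSV, no masks
  dir2 <- withr::local_tempdir()
  write_outputs(structure(list(), class = "track_result"), dir2)
  expect_equal(nrow(utils::read.csv(file.path(dir2, "tracking.csv"))), 0)
})

test_that("the command-line interface wires synth, track and eval together", {
  dir <- withr::local_tempdir()
  synth_dir <- file.path(dir, "seq")
  expect_output(acmtrack_main(c("synth", "--out", synth_dir, "--seed", "0",
                                "--frames", "6")),
                "wrote 6 frames")
  side <- jsonlite::read_json(file.path(synth_dir, "sequence.json"),
                              simplifyVector = TRUE)
  ctr <- side$centers[1, ]
  box <- sprintf("%d,%d,29,29", round(ctr[1]) - 14, round(ctr[2]) - 14)
  out_dir <- file.path(dir, "out")
  expect_output(acmtrack_main(c("track", "--frames", synth_dir,
                                "--init", box, "--out", out_dir)),
                "tracked 6 frames")
  rep_file <- file.path(dir, "report.json")
  expect_output(acmtrack_main(c("eval", "--pred", out_dir,
                                "--truth", synth_dir,
                                "--report", rep_file)),
                "correctly tracked")
  rep <- jsonlite::read_json(rep_file)
  expect_equal(rep$n_frames, 6)
  expect_gte(rep$percent_correct, 99)
})
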