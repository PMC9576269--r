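test_that("segmentation finds rendered cells and ignores blank frames", {
  acq <- acquisition_config(pixel_size = 0.5)
  det <- data.frame(x_um = c(30, 70, 105), y_um = c(-30, 10, 35),
                    a_um = c(10, 8, 12), b_um = c(6, 8, 5),
                    beta_deg = c(20, 0, -35), velocity_mm_s = 0, ftt_hz = 0)
  stack <- render_frames(det, acq, width_um = 120, n_frames = 1, seed = 4)
  masks <- segment_cells(stack[, , 1])
  expect_length(masks, 3)

  expect_equal(segment_cells(matrix(0.5, 50, 50)), list())
  blank <- matrix(rnorm(2500, 0.5, 0.01), 50, 50)
  expect_length(segment_cells(blank), 0)

  # two barely-overlapping ellipses merge into one concave doublet
  det2 <- data.frame(x_um = c(50, 68), y_um = c(0, 3), a_um = c(10, 10),
                     b_um = c(6, 6), beta_deg = c(0, 0),
                     velocity_mm_s = 0, ftt_hz = 0)
  stack2 <- render_frames(det2, acq, width_um = 100, n_frames = 1, seed = 5)
  masks2 <- segment_cells(stack2[, , 1])
  expect_length(masks2, 1)
  f2 <- fit_ellipse(masks2[[1]], acq$pixel_size)
  f2$y_um <- 50  # place it away from the center line; shape should reject it
  expect_equal(nrow(filter_detections(f2)), 0)
})

test_that("moment ellipse fit recovers rendered parameters", {
  m <- ellipse_mask(64, 64, 32.5, 32.5, a = 10, b = 5, beta_deg = 30)
  f <- fit_ellipse(m, pixel_size = 1)
  expect_lt(abs(f$a_um / 10 - 1), 0.02)
  expect_lt(abs(f$b_um / 5 - 1), 0.02)
  expect_lt(abs(f$beta_deg - 30), 2)
  expect_gt(f$solidity, 0.95)
  expect_lt(abs(f$circumference_um / ellipse_perimeter(10, 5) - 1), 0.1)

  disc <- ellipse_mask(40, 40, 20.5, 20.5, 8, 8, 0)
  fd <- fit_ellipse(disc, 1)
  expect_equal(fd$beta_deg, 0)
  expect_lt(abs(fd$a_um / fd$b_um - 1), 0.01)

  single <- matrix(FALSE, 10, 10); single[5, 5] <- TRUE
  expect_error(fit_ellipse(single), "too small")
})

test_that("render-segment-fit round trip holds over shapes and sizes", {
  acq <- acquisition_config(pixel_size = 0.345)
  set.seed(9)
  for (i in 1:6) {
    a <- runif(1, 6, 14); ratio <- runif(1, 1, 3.5); beta <- runif(1, -80, 80)
    det <- data.frame(x_um = 60, y_um = 0, a_um = a, b_um = a / ratio,
                      beta_deg = beta, velocity_mm_s = 0, ftt_hz = 0)
    stack <- render_frames(det, acq, width_um = 80, n_frames = 1,
                           seed = 100 + i)
    masks <- segment_cells(stack[, , 1])
    expect_length(masks, 1)
    f <- fit_ellipse(masks[[1]], acq$pixel_size)
    expect_lt(abs(f$a_um / a - 1), 0.02)
    expect_lt(abs(f$b_um / (a / ratio) - 1), 0.02)
    if (ratio > 1.15) expect_lt(abs(f$beta_deg - beta), 2)
  }
})

test_that("shape and position filters apply the documented rules", {
  base <- data.frame(y_um = 30, a_um = 9, b_um = 6, solidity = 0.99,
                     circumference_um = ellipse_perimeter(9, 6))
  expect_equal(nrow(filter_detections(base)), 1)

  near <- base; near$y_um <- 0.5 * sqrt(9 * 6)
  expect_equal(nrow(filter_detections(near)), 0)          # center exclusion
  far <- base; far$y_um <- 3 * sqrt(9 * 6)
  expect_equal(nrow(filter_detections(far)), 1)

  blob <- base; blob$solidity <- 0.80
  expect_equal(nrow(filter_detections(blob)), 0)
  ragged <- base; ragged$circumference_um <- 1.2 * ellipse_perimeter(9, 6)
  expect_equal(nrow(filter_detections(ragged)), 0)

  # idempotent
  once <- filter_detections(rbind(base, near, blob))
  twice <- filter_detections(once)
  expect_equal(nrow(once), nrow(twice))
  expect_equal(once$y_um, twice$y_um)
  expect_equal(attr(filter_detections(rbind(base, near, blob)), "rejections"),
               c(solidity = 1L, circumference = 0L, center_exclusion = 1L))
})

test_that("tracking links cells across frames and computes speeds", {
  acq <- acquisition_config(frame_rate = 500, pixel_size = 0.5)
  mk <- function(x, y, frame) data.frame(frame = frame, x_um = x, y_um = y,
                                         a_um = 8, b_um = 6)
  # one cell moving 20 um per frame -> 10 mm/s
  frames <- list(mk(10, 20, 1), mk(30, 20, 2), mk(50, 20, 3))
  tr <- track_cells(frames, acq)
  expect_length(tr, 1)
  expect_equal(tr[[1]]$velocity, 10e-3, tolerance = 1e-9)

  # a cell leaving the field of view ends its track without error
  frames2 <- list(rbind(mk(10, 20, 1), mk(200, -30, 1)),
                  rbind(mk(30, 20, 2)))
  tr2 <- track_cells(frames2, acq)
  lens <- vapply(tr2, function(t) nrow(t$detections), integer(1))
  expect_equal(sort(lens), c(1L, 2L))

  # two cells crossing in x at distinct y stay separate (y-gating)
  fa <- rbind(mk(10, 20, 1), mk(14, 40, 1))
  fb <- rbind(mk(30, 20, 2), mk(44, 40, 2))
  tr3 <- track_cells(list(fa, fb), acq)
  expect_length(tr3, 2)
  ys <- vapply(tr3, function(t) unique(t$detections$y_um), numeric(1))
  expect_setequal(ys, c(20, 40))
})

test_that("detection CSV round trip preserves the column contract", {
  st <- ref_state()
  tab <- suppressWarnings(
    simulate_cytometry(population_params(n_cells = 30, seed = 5), st))
  path <- tempfile(fileext = ".csv")
  write_detections_csv(tab, path)
  header <- readLines(path, n = 1)
  expect_equal(header, paste0("frame,time_s,x_um,y_um,a_um,b_um,beta_deg,",
                              "solidity,circumference_um,velocity_mm_s,ftt_hz"))
  back <- read_detections_csv(path)
  expect_equal(back$a_um, tab$a_um, tolerance = 1e-12)
  expect_error(write_detections_csv(tab[, -4], path), "missing columns")
})
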