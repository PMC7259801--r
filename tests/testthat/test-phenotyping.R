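test_that("track metrics reproduce hand-computed values and edge cases", {
  m <- compute_track_metrics(data.frame(t = 0:2, x = c(0, 3, 6),
                                        y = c(0, 4, 0)))
  expect_equal(m$S, 5)        # two 3-4-5 steps, 10 um over 2 min
  expect_equal(m$V, 3)        # net 6 um over 2 min
  expect_equal(m$W, 5 / 3)
  straight <- data.frame(t = 0:5, x = 2 * (0:5), y = 3 * (0:5))
  expect_equal(compute_track_metrics(straight)$W, 1)
  loop <- data.frame(t = 0:4, x = c(0, 1, 1, 0, 0), y = c(0, 0, 1, 1, 0))
  ml <- compute_track_metrics(loop)
  expect_equal(ml$V, 0)
  expect_true(ml$undefined_wander)
  expect_true(is.na(ml$W))
  expect_gt(ml$S, 0)
  expect_error(compute_track_metrics(data.frame(t = 0, x = 0, y = 0)),
               class = "invalid_track")
  expect_error(compute_track_metrics(data.frame(t = c(0, 0), x = 1:2,
                                                y = 1:2)),
               class = "invalid_track")
})

test_that("track metrics are invariant under rigid motion and rescale
           correctly in time", {
  set.seed(21)
  for (i in 1:20) {
    n <- sample(3:30, 1)
    tr <- data.frame(t = cumsum(stats::runif(n, 0.5, 2)),
                     x = cumsum(rnorm(n)), y = cumsum(rnorm(n)))
    m <- compute_track_metrics(tr)
    expect_gte(m$S, m$V)
    if (!m$undefined_wander) expect_gte(m$W, 1)
    # rotation + translation
    th <- stats::runif(1, 0, 2 * pi)
    rot <- data.frame(t = tr$t,
                      x = cos(th) * tr$x - sin(th) * tr$y + 13,
                      y = sin(th) * tr$x + cos(th) * tr$y - 7)
    mr <- compute_track_metrics(rot)
    expect_equal(mr$S, m$S, tolerance = 1e-9)
    expect_equal(mr$V, m$V, tolerance = 1e-9)
    # time rescaling divides S and V by k, leaves W unchanged
    k <- 3
    mk <- compute_track_metrics(transform(tr, t = k * t))
    expect_equal(mk$S, m$S / k, tolerance = 1e-9)
    expect_equal(mk$V, m$V / k, tolerance = 1e-9)
    if (!m$undefined_wander) expect_equal(mk$W, m$W, tolerance = 1e-9)
  }
})

test_that("chamber counting: co-labelled nuclei are atrial and counts
           conserve", {
  empty <- data.frame(x = numeric(0), y = numeric(0),
                      mef2 = logical(0), s46 = logical(0))
  expect_equal(count_chambers(empty), list(ventricular = 0, atrial = 0,
                                           total = 0))
  f <- data.frame(x = 1:6, y = 1:6,
                  mef2 = c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE),
                  s46 = c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE))
  cc <- count_chambers(f)
  expect_equal(cc$ventricular, 3)
  expect_equal(cc$atrial, 2)      # mef2+s46 counted atrial, never ventricular
  expect_equal(cc$total, 5)       # s46-only point ignored
  expect_equal(cc$ventricular + cc$atrial, cc$total)
})

test_that("labelled fractions are plain conditional proportions", {
  f <- data.frame(mef2 = rep(TRUE, 12), s46 = FALSE,
                  marker = rep(c(TRUE, FALSE), c(3, 9)))
  expect_equal(labeled_fraction(f, "marker"), 0.25)
  f$marker <- FALSE
  expect_equal(labeled_fraction(f, "marker"), 0)
  f$marker <- TRUE
  expect_equal(labeled_fraction(f, "marker"), 1)
  none <- data.frame(mef2 = FALSE, marker = TRUE)
  expect_error(labeled_fraction(none, "marker"),
               class = "undefined_denominator")
})

test_that("M-mode reslice satisfies its shape, static and time-reversal
           contracts", {
  set.seed(31)
  img <- matrix(stats::runif(40 * 50), 40, 50)
  static <- array(rep(img, each = 4), dim = c(4, 40, 50))
  for (f in 2:4) static[f, , ] <- static[1, , ]
  k <- reslice_mmode(static, c(5, 3), c(30, 44))
  expect_true(all(abs(k - k[, 1]) < 1e-12))
  two <- array(stats::runif(2 * 10 * 10), dim = c(2, 10, 10))
  expect_equal(dim(reslice_mmode(two, c(4, 2), c(4, 7))), c(6, 2))
  stack <- array(stats::runif(6 * 20 * 20), dim = c(6, 20, 20))
  kymo <- reslice_mmode(stack, c(2, 2), c(18, 17))
  rev_stack <- stack[6:1, , ]
  expect_equal(reslice_mmode(rev_stack, c(2, 2), c(18, 17)),
               kymo[, 6:1])
  expect_error(reslice_mmode(stack, c(0, 2), c(18, 17)),
               class = "bounds_error")
  expect_error(reslice_mmode(stack[1, , , drop = FALSE], c(2, 2), c(3, 3)),
               class = "insufficient_frames")
})

test_that("kymograph of an oscillating disc carries the beat period", {
  cfg <- sim_config(seed = 8, rate = 2, trace_duration = 4, frame_rate = 25)
  tr <- gen_contraction_trace(cfg, as_stack = TRUE, img_size = 64)
  kymo <- reslice_mmode(tr$stack, c(32.5, 4), c(32.5, 61))
  # width of the disc along the line, per frame
  width <- colSums(kymo > 0.5)
  ac <- acf(width - mean(width), lag.max = 40, plot = FALSE)$acf[, 1, 1]
  # first local acf maximum after lag 3 should sit at the true period
  period_frames <- cfg$frame_rate / cfg$rate   # 12.5 frames
  peak_lag <- which.max(ac[5:30]) + 3          # lags are 0-based
  expect_lt(abs(peak_lag - period_frames), 1.5)
})

test_that("contraction metrics recover FS and heart rate from clean
           traces and flag degenerate ones", {
  fps <- 127
  t <- seq(0, 6, by = 1 / fps)
  d <- 60 + (100 - 60) * (1 + cos(2 * pi * 2 * t)) / 2
  cm <- contraction_metrics(t, d)
  expect_equal(cm$fractional_shortening, 0.4, tolerance = 1e-3)
  expect_equal(cm$heart_rate_bpm, 120, tolerance = 0.5)
  # FS invariant to uniform scaling of the trace
  cm2 <- contraction_metrics(t, 3.7 * d)
  expect_equal(cm2$fractional_shortening, cm$fractional_shortening,
               tolerance = 1e-12)
  expect_error(contraction_metrics(t, rep(80, length(t))),
               class = "insufficient_cycles")
  expect_error(contraction_metrics(t[1:40], d[1:40]),
               class = "insufficient_cycles")
})

test_that("12 peaks spanning 5.5 seconds give 120 beats per minute", {
  fps <- 40
  t <- seq(0, 5.75, by = 1 / fps)
  # peaks at 0.1, 0.6, ..., 5.6: 12 peaks spanning 5.5 s
  d <- 60 + 40 * (1 + cos(2 * pi * 2 * (t - 0.1))) / 2
  cm <- contraction_metrics(t, d)
  expect_equal(cm$n_beats, 12)
  expect_equal(cm$heart_rate_bpm, 120, tolerance = 1e-9)
})

test_that("expression area counts pixels times pixel area and is
           additive over disjoint masks", {
  expect_equal(expression_area(matrix(FALSE, 8, 8)), 0)
  expect_equal(expression_area(matrix(1, 10, 10), pixel_size = 2), 400)
  a <- matrix(FALSE, 10, 10); a[1:3, 1:3] <- TRUE
  b <- matrix(FALSE, 10, 10); b[7:10, 7:9] <- TRUE
  expect_equal(expression_area(a | b, 1.5),
               expression_area(a, 1.5) + expression_area(b, 1.5))
  expect_error(expression_area(matrix(0.5, 2, 2)), class = "invalid_mask")
})
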