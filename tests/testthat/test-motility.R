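mk_track <- function(xy, interval = 30) track_nucleus(xy, interval)

test_that("speed is total path over total time, in um/h", {
  still <- mk_track(matrix(c(3, 3, 3, 5, 5, 5), 3))
  expect_equal(average_speed(still), 0)
  one_step <- mk_track(rbind(c(0, 0), c(10, 0)), interval = 30)
  expect_equal(average_speed(one_step), 20) # 10 um per 30 min = 20 um/h
  # linear scaling with coordinates, inverse with interval
  tr <- mk_track(rbind(c(0, 0), c(3, 4), c(7, 1)), interval = 30)
  tr2 <- mk_track(2 * rbind(c(0, 0), c(3, 4), c(7, 1)), interval = 30)
  tr3 <- mk_track(rbind(c(0, 0), c(3, 4), c(7, 1)), interval = 60)
  expect_equal(average_speed(tr2), 2 * average_speed(tr))
  expect_equal(average_speed(tr3), average_speed(tr) / 2)
})

test_that("directionality ratio matches hand-computed values", {
  straight <- mk_track(cbind(seq(0, 40, 10), 0))
  expect_equal(directionality_ratio(straight), 1)
  loop <- mk_track(rbind(c(0, 0), c(5, 0), c(5, 5), c(0, 5), c(0, 0)))
  expect_equal(directionality_ratio(loop), 0)
  # two steps (3,0) then (0,4): d = 5 (Pythagoras), D = 7
  ltrack <- mk_track(rbind(c(0, 0), c(3, 0), c(3, 4)))
  expect_equal(directionality_ratio(ltrack), 5 / 7)
  expect_true(is.na(directionality_ratio(mk_track(matrix(1, 3, 2)))))
  # d <= D and invariance under rotation/translation
  set.seed(3)
  for (i in 1:10) {
    pos <- matrix(cumsum(rnorm(12)), 6, 2)
    tr <- mk_track(pos)
    expect_lte(directionality_ratio(tr), 1 + 1e-12)
    rot <- normalize_axis(pos, c(cos(0.9), sin(0.9)))
    expect_equal(directionality_ratio(mk_track(rot + 5)),
                 directionality_ratio(tr), tolerance = 1e-9)
  }
})

test_that("direction autocorrelation handles persistence, turns, and noise", {
  straight <- mk_track(cbind(0:6 * 3, 0))
  ac <- direction_autocorrelation(straight)
  expect_equal(ac$autocorrelation, rep(1, nrow(ac)))
  # alternating +90/-90 turns: A(1) = cos(90 deg) = 0
  zig <- mk_track(rbind(c(0, 0), c(1, 0), c(1, 1), c(2, 1), c(2, 2), c(3, 2)))
  ac <- direction_autocorrelation(zig, max_lag = 2)
  expect_equal(ac$autocorrelation[1], 1) # A(0) = 1
  expect_equal(ac$autocorrelation[2], 0, tolerance = 1e-12)
  # isotropic random walk: A(1) ~ 0 within 3/sqrt(n)
  set.seed(17)
  n <- 1e4
  ang <- runif(n, 0, 2 * pi)
  walk <- rbind(c(0, 0), cbind(cumsum(cos(ang)), cumsum(sin(ang))))
  ac <- direction_autocorrelation(mk_track(walk), max_lag = 1)
  expect_lt(abs(ac$autocorrelation[2]), 3 / sqrt(n - 1))
  # zero-length steps are excluded from angle statistics
  paused <- mk_track(rbind(c(0, 0), c(1, 0), c(1, 0), c(2, 0)))
  ac <- direction_autocorrelation(paused, max_lag = 2)
  expect_false(any(is.nan(ac$autocorrelation)))
  expect_equal(ac$autocorrelation[3], 1) # lag 2 pairs the two +x steps
})

test_that("plot_at_origin translates without distorting geometry", {
  set.seed(4)
  tracks <- lapply(1:3, function(i) mk_track(matrix(cumsum(rnorm(10)), 5, 2) + 20))
  moved <- plot_at_origin(tracks)
  for (i in 1:3) {
    expect_equal(moved[[i]]$positions[1, ], c(0, 0))
    expect_equal(as.numeric(dist(moved[[i]]$positions)),
                 as.numeric(dist(tracks[[i]]$positions)))
    expect_equal(directionality_ratio(moved[[i]]),
                 directionality_ratio(tracks[[i]]))
  }
})

test_that("turning detection flags backward x-steps beyond tolerance", {
  fwd <- mk_track(cbind(c(0, 4, 8, 12), 0))
  expect_false(is_turning(fwd, 1))
  back <- mk_track(cbind(c(0, 4, -1, 3), 0)) # one -5 um x-step
  expect_true(is_turning(back, 1))
  set.seed(9)
  jitter <- cbind(cumsum(c(0, rep(2, 8))) + runif(9, -0.3, 0.3), 0)
  expect_false(is_turning(mk_track(jitter), 1)) # jitter below tolerance
})

test_that("gap policy interpolates single gaps and truncates longer ones", {
  pos <- rbind(c(0, 0), c(2, 0), c(NA, NA), c(6, 0), c(8, 0))
  tr <- track_nucleus(pos, 30)
  expect_equal(tr$positions[3, ], c(4, 0)) # linear interpolation
  expect_true(tr$interpolated[3])
  expect_false(tr$truncated)
  pos2 <- rbind(c(0, 0), c(2, 0), c(NA, NA), c(NA, NA), c(8, 0))
  tr2 <- track_nucleus(pos2, 30)
  expect_true(tr2$truncated)
  expect_identical(nrow(tr2$positions), 2L)
  expect_error(track_nucleus(rbind(c(0, 0), c(NA, NA), c(NA, NA)), 30),
               "at least 2")
})
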