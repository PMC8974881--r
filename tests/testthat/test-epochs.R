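fs <- 500

test_that("epoching subtracts the prestimulus mean correctly", {
  # constant trace -> all-zero epoch
  ep <- epoch_and_baseline(rep(3.7, 2000), fs, -2, -0.5, 1.0, c(-0.5, 0))
  expect_equal(ep$x, numeric(length(ep$x)))
  expect_equal(length(ep$x), round(1.5 * fs))

  # linear ramp -> ramp minus its prestimulus mean, pointwise
  t_tr <- seq(-2, 2 - 1 / fs, by = 1 / fs)
  ramp <- 2 * t_tr + 1
  ep2 <- epoch_and_baseline(ramp, fs, -2, -0.5, 1.0, c(-0.5, 0))
  tt <- seq(-0.5, 1.0 - 1 / fs, by = 1 / fs)
  expected <- (2 * tt + 1) - mean(2 * tt[tt < 0] + 1)
  expect_equal(ep2$x, expected, tolerance = 1e-12)

  # already baseline-zero trace is unchanged by correction
  x <- sin(2 * pi * 3 * t_tr)
  ep3 <- epoch_and_baseline(x, fs, -2, -0.5, 1.0, NULL)
  ep4 <- epoch_and_baseline(ep3$x - mean(ep3$x[tt < 0]), fs, -0.5, -0.5, 1.0,
                            c(-0.5, 0))
  expect_equal(ep4$x, ep3$x - mean(ep3$x[tt < 0]), tolerance = 1e-12)
})

test_that("insufficient trace coverage is rejected with the missing span", {
  expect_error(epoch_and_baseline(rnorm(100), fs, 0, -0.5, 1.0),
               "missing")
})

test_that("woody alignment recovers imposed delays to within one sample", {
  tpl <- template_500()
  base <- numeric(round(1.5 * fs))
  t_ep <- seq(-0.5, 1.0 - 1 / fs, by = 1 / fs)
  i0 <- which.min(abs(t_ep - 0.35))
  make_ep <- function(shift_samples) {
    x <- base
    idx <- (i0 + shift_samples):(i0 + shift_samples + length(tpl$waveform) - 1)
    x[idx] <- tpl$waveform
    structure(list(x = x, fs = fs, t_start = -0.5), class = "pain_epoch")
  }
  expect_equal(woody_align(make_ep(0), tpl)$shift_ms, 0)
  for (d_ms in c(-40, 40)) {
    got <- woody_align(make_ep(round(d_ms / 1000 * fs)), tpl)$shift_ms
    expect_lt(abs(got - (-d_ms)), 1000 / fs + 1e-9)
  }
  # a 150 ms delay exceeds the search range: the shift clamps at -100 ms
  got <- woody_align(make_ep(round(0.150 * fs)), tpl)
  expect_equal(got$shift_ms, -100)
})

test_that("template magnitude is an exact linear projection", {
  tpl <- template_500()
  t_ep <- seq(-0.5, 1.0 - 1 / fs, by = 1 / fs)
  embed <- function(scale) {
    x <- numeric(length(t_ep))
    i0 <- which.min(abs(t_ep - 0.35))
    x[i0:(i0 + length(tpl$waveform) - 1)] <- scale * tpl$waveform
    structure(list(x = x, fs = fs, t_start = -0.5), class = "pain_epoch")
  }
  expect_equal(template_magnitude(embed(1), tpl), 1, tolerance = 1e-9)
  expect_equal(template_magnitude(embed(2.5), tpl), 2.5, tolerance = 1e-9)

  # orthogonal input projects to ~0: shift a copy far enough that the
  # projection window sees only zeros
  zero_ep <- structure(list(x = numeric(length(t_ep)), fs = fs,
                            t_start = -0.5), class = "pain_epoch")
  expect_equal(template_magnitude(zero_ep, tpl), 0, tolerance = 1e-9)

  # linearity over random epochs
  set.seed(42)
  for (i in 1:5) {
    xa <- rnorm(length(t_ep))
    xb <- rnorm(length(t_ep))
    a <- runif(1, -2, 2)
    b <- runif(1, -2, 2)
    epv <- function(v) structure(list(x = v, fs = fs, t_start = -0.5),
                                 class = "pain_epoch")
    expect_equal(template_magnitude(epv(a * xa + b * xb), tpl),
                 a * template_magnitude(epv(xa), tpl) +
                   b * template_magnitude(epv(xb), tpl),
                 tolerance = 1e-9)
  }
})

test_that("automated peak-to-peak follows its window definitions", {
  t_ep <- seq(-0.5, 1.0 - 1 / fs, by = 1 / fs)
  x <- numeric(length(t_ep))
  x[which.min(abs(t_ep - 0.400))] <- -5
  x[which.min(abs(t_ep - 0.520))] <- 7
  ep <- structure(list(x = x, fs = fs, t_start = -0.5), class = "pain_epoch")
  expect_equal(auto_peak_to_peak(ep), 12)
  zero <- structure(list(x = numeric(length(t_ep)), fs = fs, t_start = -0.5),
                    class = "pain_epoch")
  expect_equal(auto_peak_to_peak(zero), 0)
})

test_that("template magnitude at 500 and 1000 Hz agree within 2%", {
  amp <- 6
  beta_at <- function(fs2) {
    tpl <- make_template(fs2)
    t_tr <- seq(-2, 2 - 1 / fs2, by = 1 / fs2)
    x <- numeric(length(t_tr))
    i0 <- round((0.35 + 2) * fs2) + 1
    x[i0:(i0 + length(tpl$waveform) - 1)] <- amp * tpl$waveform
    filt <- bandpass_notch_filter(x, fs2, 0.5, 70)
    ep <- epoch_and_baseline(filt, fs2, -2, -0.5, 1.0, c(-0.5, 0))
    al <- woody_align(ep, tpl)
    template_magnitude(al$epoch, tpl)
  }
  b500 <- beta_at(500)
  b1000 <- beta_at(1000)
  expect_equal(b500, amp, tolerance = 0.02)
  expect_equal(b1000 / b500, 1, tolerance = 0.02)
})
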