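mid <- function(x, frac = 0.6) {
  n <- length(x)
  lo <- floor(n * (1 - frac) / 2)
  x[(lo + 1):(n - lo)]
}

test_that("band-pass preserves in-band sinusoids and the notch removes 50 Hz", {
  rec <- sine_recording(10, fs = 512, dur = 10)
  out <- bandpass(rec, 8, 13)
  expect_lt(abs(sd(mid(out$data[1, ])) / sd(mid(rec$data[1, ])) - 1), 0.05)

  rec50 <- sine_recording(50, fs = 512, dur = 10)
  res <- notch(rec50, 50)
  expect_lt(sd(mid(res$data[1, ])) / sd(mid(rec50$data[1, ])), 0.05)
})

test_that("band-passed white noise concentrates spectral mass in the band", {
  set.seed(5)
  m <- two_channel_montage()
  x <- matrix(rnorm(2 * 512 * 20), 2, dimnames = list(m$labels, NULL))
  rec <- recording(x, 512, m)
  out <- bandpass(rec, 13, 20)
  # periodogram oracle computed directly from the FFT
  v <- mid(out$data[1, ], 0.8)
  spec <- Mod(fft(v))^2
  f <- (seq_along(v) - 1) * 512 / length(v)
  half <- f <= 256
  in_band <- half & f >= 12.5 & f <= 20.5
  expect_gte(sum(spec[in_band]) / sum(spec[half]), 0.9)
})

test_that("stop-band attenuation reaches 30 dB one octave beyond the edges", {
  m <- two_channel_montage()
  fs <- 512
  t <- seq(0, 20 - 1 / fs, by = 1 / fs)
  mk <- function(f) recording(rbind(A = cos(2 * pi * f * t),
                                    B = sin(2 * pi * f * t)), fs, m)
  pass <- sd(mid(bandpass(mk(16), 13, 20)$data[1, ]))
  below <- sd(mid(bandpass(mk(6.5), 13, 20)$data[1, ]))   # octave below 13
  above <- sd(mid(bandpass(mk(40), 13, 20)$data[1, ]))    # octave above 20
  expect_lt(20 * log10(below / pass), -30)
  expect_lt(20 * log10(above / pass), -30)
})

test_that("segmentation drops the trailing partial epoch and rejects short input", {
  m <- two_channel_montage()
  mk <- function(dur) recording(matrix(rnorm(2 * round(512 * dur)), 2,
                                       dimnames = list(m$labels, NULL)),
                                512, m)
  expect_equal(dim(segment(mk(61))$epochs), c(2, 1024, 30))
  expect_equal(dim(segment(mk(2))$epochs)[3], 1)
  expect_error(segment(mk(1.9)), "shorter than one epoch")
})

test_that("average reference zeroes the channel mean and is idempotent", {
  m <- chain_montage()
  ep <- array(rnorm(3 * 100 * 4), c(3, 100, 4),
              dimnames = list(m$labels, NULL, NULL))
  es <- epoch_set(ep, 512, m)
  out <- rereference_average(es)
  for (e in 1:4) {
    expect_lt(max(abs(colMeans(out$epochs[, , e]))), 1e-9)
  }
  twice <- rereference_average(out)
  expect_equal(twice$epochs, out$epochs, tolerance = 1e-12)

  # constant offset on every channel is annihilated
  es2 <- epoch_set(array(7, c(3, 50, 1), dimnames = list(m$labels, NULL, NULL)),
                   512, m)
  expect_lt(max(abs(rereference_average(es2)$epochs)), 1e-12)
  expect_error(rereference_average(
    epoch_set(array(0, c(1, 10, 1)), 512, m)), "at least 2 channels")
})

test_that("downsampling halves the sample count and preserves slow sinusoids", {
  m <- two_channel_montage()
  fs <- 1024
  t <- seq(0, 20 - 1 / fs, by = 1 / fs)
  rec <- recording(rbind(A = 10 * cos(2 * pi * 5 * t),
                         B = 10 * sin(2 * pi * 5 * t)), fs, m)
  out <- downsample(rec, 512)
  expect_equal(ncol(out$data), ncol(rec$data) / 2)
  expect_equal(out$fs, 512)
  expect_lt(abs(sd(mid(out$data[1, ])) / sd(mid(rec$data[1, ])) - 1), 0.05)
  expect_identical(downsample(rec, 1024)$data, rec$data)
  expect_error(downsample(rec, 2048), "upsampling")
})

test_that("amplitude rejection removes exactly the epochs exceeding the limit", {
  m <- two_channel_montage()
  ep <- array(0, c(2, 100, 5), dimnames = list(m$labels, NULL, NULL))
  ep[1, 50, 3] <- 81
  es <- epoch_set(ep, 512, m)
  out <- reject_amplitude(es, 80)
  expect_equal(out$kept_mask, c(TRUE, TRUE, FALSE, TRUE, TRUE))
  expect_equal(dim(out$epochs)[3], 4)
  # retained samples untouched
  expect_identical(out$epochs[, , 3], ep[, , 4])
  expect_equal(dim(reject_amplitude(es, Inf)$epochs)[3], 5)
  expect_warning(reject_amplitude(
    epoch_set(array(100, c(2, 10, 2), dimnames = list(m$labels, NULL, NULL)),
              512, m), 80), "all epochs rejected")
})

test_that("the Hjorth Laplacian matches hand evaluation and kills common-mode signal", {
  m <- chain_montage()
  # chain A-B-C with constant values 2, 1, 0
  ep <- array(rep(c(2, 1, 0), 50), c(3, 50, 1),
              dimnames = list(m$labels, NULL, NULL))
  out <- laplacian(epoch_set(ep, 512, m))
  expect_equal(unname(out$epochs[2, 1, 1]), 1 - (2 + 0) / 2)  # = 0
  expect_equal(unname(out$epochs[1, 1, 1]), 2 - 1)    # single neighbor B
  expect_equal(unname(out$epochs[3, 1, 1]), 0 - 1)

  # identical signal on all channels -> all zero
  sig <- rnorm(50)
  ep2 <- array(rep(sig, each = 3), c(3, 50, 1),
               dimnames = list(m$labels, NULL, NULL))
  expect_lt(max(abs(laplacian(epoch_set(ep2, 512, m))$epochs)), 1e-12)

  # channel whose single neighbor carries 0 is unchanged
  ep3 <- array(0, c(3, 50, 1), dimnames = list(m$labels, NULL, NULL))
  ep3[1, , 1] <- sig
  out3 <- laplacian(epoch_set(ep3, 512, m))
  expect_equal(unname(out3$epochs[1, , 1]), sig)

  expect_error(laplacian(epoch_set(ep, 512, m),
                         montage(c("A", "B", "C"),
                                 list(A = "B", B = "A", C = character(0)))),
               "no neighbors")
})

test_that("the preprocessing pipeline runs in the documented order and logs it", {
  set.seed(9)
  cs <- coupling_spec("alpha2", data.frame(i = "FP1", j = "O2",
                                           lag = pi / 3, q = 0.1),
                      base_amplitude = 8, noise_sd = 3)
  rec <- generate_recording(montage_1020(), 1024, 12, cs, seed = 3)
  es <- preprocess(rec, "alpha2", run_config())
  expect_equal(es$fs, 512)
  expect_equal(dim(es$epochs)[2], 1024)  # 2 s at 512 Hz exactly
  steps <- c("bandpass", "segment", "rereference", "downsample",
             "reject_amplitude", "laplacian")
  hits <- vapply(steps, function(s) grep(s, es$log)[1], numeric(1))
  expect_false(anyNA(hits))
  expect_true(!is.unsorted(hits, strictly = TRUE))
})
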