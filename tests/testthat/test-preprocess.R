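test_that("band-pass filter has the specified magnitude and zero phase", {
  fs <- 1200
  n <- 60 * fs
  t <- (0:(n - 1)) / fs
  mid <- (20 * fs):(40 * fs)

  # 10 Hz sits in the passband: amplitude within 5%, zero lag
  x10 <- sin(2 * pi * 10 * t)
  y10 <- serpbci:::apply_filter(x10, filter_spec(0.1, 25), fs)
  expect_equal(max(abs(y10[mid])), 1, tolerance = 0.05)
  cc <- ccf(y10[mid], x10[mid], lag.max = 20, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)

  # 50 Hz is attenuated below half amplitude
  x50 <- sin(2 * pi * 50 * t)
  y50 <- serpbci:::apply_filter(x50, filter_spec(0.1, 25), fs)
  expect_lt(max(abs(y50[mid])), 0.5)

  # band edges must stay below Nyquist
  expect_error(serpbci:::apply_filter(x10, filter_spec(1, 700), fs), "Nyquist")
})

test_that("DC input vanishes after edge transients", {
  fs <- 1200
  n <- 180 * fs
  y <- serpbci:::apply_filter(rep(1, n), filter_spec(0.1, 25), fs)
  mid <- (80 * fs):(100 * fs)
  expect_lt(max(abs(y[mid])), 1e-6)
})

test_that("EEG channels and Fp1 receive their own filter bands", {
  fs <- 1200
  n <- 60 * fs
  t <- (0:(n - 1)) / fs
  mid <- (20 * fs):(40 * fs)
  # 0.5 Hz passes the 0.1-25 EEG band but not the 1-10 Fp1 band
  dat <- matrix(sin(2 * pi * 0.5 * t), n, 6)
  rec <- bandpass_filter(manual_recording(dat, fs))
  expect_gt(max(abs(rec$data[mid, "C3"])), 0.9)
  expect_lt(max(abs(rec$data[mid, "Fp1"])), 0.5)
})

test_that("epoch segmentation keeps in-bounds events and counts the rest", {
  fs <- 1200
  dat <- matrix(0, 10 * fs, 6)
  ev <- data.frame(onset = c(0.05, 1, 2, 9.8), location = "D", attended = "D",
                   block = 1, subblock = 1)
  rec <- manual_recording(dat, fs, ev)
  ep <- segment_epochs(rec)
  expect_equal(dim(ep$data), c(780, 6, 2))  # 0.05 s and 9.8 s do not fit
  expect_equal(ep$n_skipped, 2L)
  expect_equal(ep$events$onset, c(1, 2))

  empty <- segment_epochs(rec, ev[0, ])
  expect_equal(dim(empty$data)[3], 0)
  expect_equal(empty$n_skipped, 0L)
})

test_that("baseline correction shifts only the poststimulus interval", {
  ep <- constant_epoch(3.5)
  out <- baseline_correct(ep)
  expect_equal(out$data[121:780, , 1], matrix(0, 660, 6), ignore_attr = TRUE)
  expect_equal(out$data[1:120, , 1], matrix(3.5, 120, 6), ignore_attr = TRUE)

  # x - m for arbitrary baseline mean m
  ep2 <- constant_epoch(0)
  ep2$data[1:120, 1, 1] <- rnorm(120, mean = 2)
  ep2$data[121:780, 1, 1] <- 7
  m <- mean(ep2$data[1:120, 1, 1])
  out2 <- baseline_correct(ep2)
  expect_equal(as.numeric(out2$data[400, 1, 1]), 7 - m)

  # zero baseline mean leaves the epoch unchanged
  ep3 <- constant_epoch(0)
  ep3$data[121:780, 2, 1] <- 1
  expect_equal(baseline_correct(ep3)$data, ep3$data)
})

test_that("artifact rejection applies 50 uV to EEG and 80 uV to Fp1", {
  base <- constant_epoch(0)
  spike <- function(ch, v) {
    e <- constant_epoch(0)
    e$data[300, ch, 1] <- v
    e
  }
  expect_equal(dim(reject_artifacts(base)$data)[3], 1)      # all-zero: kept
  expect_equal(reject_artifacts(spike(1, 51))$n_rejected, 1L)   # C3 +51: out
  expect_equal(dim(reject_artifacts(spike(1, 50))$data)[3], 1)  # at threshold: kept
  expect_equal(reject_artifacts(spike(6, -81))$n_rejected, 1L)  # Fp1 -81: out
  ok <- spike(6, 79)  # Fp1 79, EEG within 50: kept
  expect_equal(dim(reject_artifacts(ok)$data)[3], 1)
})

test_that("kept + rejected epochs account for all segmented epochs and rejection is idempotent", {
  spec <- protocol_spec(n_blocks = 1, subblocks_per_block = 2)
  rec <- simulate_subject(seed = 77, spec = spec,
                          noise = noise_spec(blink_rate = 20,
                                             gross_artifact_rate = 10))
  rec <- bandpass_filter(rec)
  ep <- baseline_correct(segment_epochs(rec))
  n_total <- dim(ep$data)[3]
  kept <- reject_artifacts(ep)
  expect_gt(kept$n_rejected, 0)
  expect_equal(dim(kept$data)[3] + kept$n_rejected, n_total)
  again <- reject_artifacts(kept)
  expect_equal(again$n_rejected, 0L)
  expect_identical(again$data, kept$data)
})

test_that("trials are the 50-550 ms slice with Fp1 dropped and cluster labels from (attended, location)", {
  fs <- 1200
  dat <- matrix(0, 10 * fs, 6)
  # encode the sample index on C3 so slicing is verifiable
  dat[, 1] <- seq_len(nrow(dat))
  ev <- data.frame(onset = 2, location = "V", attended = "D",
                   block = 1, subblock = 1)
  rec <- manual_recording(dat, fs, ev)
  ep <- segment_epochs(rec)
  tr <- extract_trials(ep)
  expect_equal(dim(tr$data), c(600, 5, 1))
  expect_false("Fp1" %in% dimnames(tr$data)[[2]])
  s0 <- 2 * fs
  expect_equal(tr$data[, 1, 1], as.numeric((s0 + 61):(s0 + 660)))
  expect_equal(as.character(tr$cluster), "ADSV")

  combos <- data.frame(att = c("D", "D", "V", "V"), loc = c("D", "V", "D", "V"),
                       cluster = c("ADSD", "ADSV", "AVSD", "AVSV"))
  for (i in 1:4) {
    ev$location <- combos$loc[i]; ev$attended <- combos$att[i]
    tri <- extract_trials(segment_epochs(manual_recording(dat, fs, ev)))
    expect_equal(as.character(tri$cluster), combos$cluster[i])
  }
})

test_that("noiseless pipeline reproduces the rendered template at machine precision", {
  spec <- protocol_spec(n_blocks = 1, subblocks_per_block = 1)
  proto <- generate_protocol(spec, seed = 41)
  rec <- synthesize_recording(proto, noise = noise_spec(background_sd = 0,
                                                        blink_rate = 0,
                                                        gross_artifact_rate = 0),
                              seed = 42)
  tr <- preprocess_recording(rec, filter = FALSE)  # raw templates, no filtering
  expect_equal(attr(tr, "n_rejected"), 0L)
  comps <- serp_components()
  for (i in c(1, 25, 60)) {
    att <- identical(proto$location[i], proto$attended[i])
    for (ch in c("C3", "P3")) {
      tmpl <- render_serp(comps, proto$location[i],
                          proto$attended[i], ch)
      expect_equal(tr$data[, ch, i], tmpl[61:660], tolerance = 1e-12)
    }
  }
})

test_that("full default protocol yields 1800 epochs of 780 samples", {
  proto <- generate_protocol(protocol_spec(), seed = 51)
  rec <- synthesize_recording(proto, components = serp_components()[0, ],
                              noise = noise_spec(background_sd = 0,
                                                 blink_rate = 0,
                                                 gross_artifact_rate = 0),
                              seed = 52)
  ep <- segment_epochs(rec)
  expect_equal(dim(ep$data), c(780, 6, 1800))
  expect_equal(ep$n_skipped, 0L)
})
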