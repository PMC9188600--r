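# Perturbation measures against hand enumeration, pulse detection on signals
# with known truth, and the harmonicity identities.

test_that("jitter and shimmer match hand-worked examples", {
  pt <- pt_from(c(10, 11, 10, 11) / 1000)
  expect_equal(jitter_abs(pt), 1 / 1000)           # (1+1+1)/3 ms
  expect_equal(jitter_rel(pt), 1 / 10.5)
  expect_equal(jitter_abs(pt_from(c(8, 12) / 1000)), 4 / 1000)
  expect_equal(jitter_abs(pt_from(rep(0.01, 6))), 0)
  expect_equal(jitter_rel(pt_from(rep(0.01, 6))), 0)

  pt_a <- pt_from(rep(0.01, 3), c(1, 2, 1))
  expect_equal(shimmer_db(pt_a), (abs(20 * log10(2)) + abs(20 * log10(0.5))) / 2)
  expect_equal(shimmer_db(pt_a), 6.0206, tolerance = 1e-4)
  expect_equal(shimmer_rel(pt_a), ((1 + 1) / 2) / (4 / 3))
  expect_equal(shimmer_db(pt_from(rep(0.01, 2), c(1, 10))), 20)
  expect_equal(shimmer_rel(pt_from(rep(0.01, 4), c(2, 4, 2, 4))), 2 / 3,
               tolerance = 1e-12)
  expect_equal(shimmer_db(pt_from(rep(0.01, 4), rep(0.3, 4))), 0)

  expect_equal(pitch_sd(pt_from(rep(0.01, 5))), 0)
  expect_equal(pitch_sd(pt_from(c(10, 10, 12.5) / 1000)),
               sd(c(100, 100, 80)))
})

test_that("perturbation operators match an enumeration oracle on small trains", {
  set.seed(7)
  for (rep in 1:25) {
    n <- sample(2:10, 1)
    periods <- runif(n, 0.004, 0.012)
    amps <- runif(n, 0.2, 1.5)
    pt <- pt_from(periods, amps)
    # independent loop-free re-derivation
    jab <- sum(abs(periods[-1] - periods[-n])) / (n - 1)
    expect_equal(jitter_abs(pt), jab)
    expect_equal(jitter_rel(pt), jab / (sum(periods) / n))
    expect_equal(shimmer_db(pt),
                 sum(abs(20 * log10(amps[-1] / amps[-n]))) / (n - 1))
    expect_equal(shimmer_rel(pt),
                 (sum(abs(amps[-1] - amps[-n])) / (n - 1)) / (sum(amps) / n))
    expect_equal(pitch_sd(pt), sqrt(sum((1 / periods - mean(1 / periods))^2) /
                                      (n - 1)))
    # algebraic identity to machine precision
    expect_equal(jitter_rel(pt) * mean(pt$periods), jitter_abs(pt),
                 tolerance = 1e-15)
  }
})

test_that("degenerate pulse trains raise specific conditions", {
  expect_error(jitter_abs(pt_from(0.01)),
               class = "phonemark_insufficient_cycles")
  expect_error(pulse_train(c(0, 0.01, 0.02), c(1, 0)),
               class = "phonemark_invalid_cycle")
  expect_error(pulse_train(c(0.01, 0.01), 1),
               class = "phonemark_invalid_argument")
})

test_that("pulse detection recovers pulse count and period on known vowels", {
  out <- cached_vowel(duration = 1, f0 = 100, jitter_rel_target = 0.002,
                      shimmer_rel_target = 0.02, noise_db = -40,
                      tract_length_cm = 16.75, seed = 1)
  pt <- detect_pulses(bandpass(out$audio))
  expect_gte(length(pt$pulse_times), 97L)
  expect_lte(length(pt$pulse_times), 101L)
  expect_equal(mean(pt$periods), 0.010, tolerance = 0.01)

  out2 <- cached_vowel(duration = 0.8, f0 = 200, jitter_rel_target = 0.005,
                       shimmer_rel_target = 0.04, noise_db = -25,
                       tract_length_cm = 16.75, seed = 2)
  pt2 <- detect_pulses(bandpass(trim_uniform(out2$audio, 0.5)))
  expect_equal(mean(1 / pt2$periods), 200, tolerance = 0.01)

  set.seed(3)
  wn <- audio_segment(rnorm(22050) * 0.3, 44100)
  expect_error(detect_pulses(wn), class = "phonemark_unvoiced")
})

test_that("clean vowels yield high HNR and near-zero perturbation", {
  out <- clean_vowel()
  f <- bandpass(trim_uniform(out$audio, 0.5))
  pt <- detect_pulses(f)
  expect_lt(pitch_sd(pt), 1)
  expect_lt(jitter_rel(pt), 0.002)
  h <- harmonicity(f, pt)
  expect_gt(h$hnr_db, 25)
  expect_equal(h$t0, 0.01, tolerance = 0.02)
})

test_that("HNR and NHR stay exactly consistent with the shared peak", {
  for (seed in 1:3) {
    out <- cached_vowel(duration = 0.7, f0 = 120, jitter_rel_target = 0.012,
                        shimmer_rel_target = 0.05, noise_db = -30,
                        tract_length_cm = 15, seed = seed)
    f <- bandpass(trim_uniform(out$audio, 0.5))
    h <- harmonicity(f, detect_pulses(f))
    expect_equal(h$nhr, 1 / (1 + 10^(h$hnr_db / 10)), tolerance = 1e-12)
    expect_equal(h$nhr, 1 - h$r0, tolerance = 1e-15)
    expect_equal(h$hnr_db, 10 * log10(h$r0 / (1 - h$r0)), tolerance = 1e-12)
  }
})

test_that("extracted HNR decreases as synthesis noise rises", {
  hnr <- vapply(c(-40, -30, -20, -10), function(nd) {
    out <- cached_vowel(duration = 0.8, f0 = 120, jitter_rel_target = 0.005,
                        shimmer_rel_target = 0.04, noise_db = nd,
                        tract_length_cm = 16.75, seed = 2)
    f <- bandpass(trim_uniform(out$audio, 0.5))
    harmonicity(f, detect_pulses(f))$hnr_db
  }, numeric(1))
  expect_true(all(diff(hnr) < 0))
})

test_that("jitter and shimmer recover within a quarter of realized truth", {
  # light 2x2 slice of the recovery grid; the acceptance suite runs it full
  for (tj in c(0.005, 0.02)) for (ts in c(0.02, 0.05)) {
    ex <- tr <- c(0, 0)
    for (seed in 1:2) {
      out <- cached_vowel(duration = 0.8, f0 = 100, jitter_rel_target = tj,
                          shimmer_rel_target = ts, noise_db = -60,
                          tract_length_cm = 16.75, intensity_drift_db = 0,
                          seed = seed)
      f <- bandpass(trim_uniform(out$audio, 0.5))
      pt <- detect_pulses(f)
      ex <- ex + c(jitter_rel(pt), shimmer_rel(pt)) / 2
      tr <- tr + c(out$truth$jitter_rel, out$truth$shimmer_rel) / 2
    }
    expect_lt(max(abs(ex / tr - 1)), 0.25)
  }
})
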