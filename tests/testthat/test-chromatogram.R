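rt_default <- retention_table()
rt_full <- retention_table(include_extra_insp4 = TRUE)

test_that("synthesis produces unit-area Gaussians on a flat baseline", {
  prof <- tibble::tibble(class = "InsP6", amount = 0.8)
  ch <- synthesize_chromatogram(prof, rt_default)
  expect_equal(ch$time_min[which.max(ch$signal)], 37)
  # trapezoid area within +/- 4 sigma recovers the amount (equal response)
  win <- abs(ch$time_min - 37) <= 4 * 0.25
  area <- sum(diff(ch$time_min[win]) *
                (head(ch$signal[win], -1) + tail(ch$signal[win], -1)) / 2)
  expect_equal(area, 0.8, tolerance = 1e-3)

  flat <- synthesize_chromatogram(tibble::tibble(class = character(),
                                                 amount = numeric()),
                                  rt_default, baseline = 0.1)
  expect_true(all(flat$signal == 0.1))

  a <- synthesize_chromatogram(prof, rt_default, noise_sd = 0.01, seed = 5)
  b <- synthesize_chromatogram(prof, rt_default, noise_sd = 0.01, seed = 5)
  d <- synthesize_chromatogram(prof, rt_default, noise_sd = 0.01, seed = 6)
  expect_identical(a$signal, b$signal)
  expect_false(identical(a$signal, d$signal))

  expect_error(
    synthesize_chromatogram(tibble::tibble(class = "no-such-class", amount = 1),
                            rt_default),
    "missing from the retention table")
})

test_that("peak detection finds isolated Gaussians and nothing on baseline", {
  prof <- tibble::tibble(class = "InsP6", amount = 1)
  ch <- synthesize_chromatogram(prof, rt_default)
  pk <- detect_peaks(ch)
  expect_equal(nrow(pk), 1L)
  expect_lt(abs(pk$apex_time - 37), 0.02)

  flat <- synthesize_chromatogram(tibble::tibble(class = character(),
                                                 amount = numeric()), rt_default)
  expect_equal(nrow(detect_peaks(flat)), 0L)

  # two Gaussians 1 min apart at sigma 0.2 resolve into two peaks
  rt2 <- tibble::tibble(class = c("InsP5 [1/3-OH]", "InsP5 [4/6-OH]"),
                        rt_min = c(28, 29), sigma_min = 0.2,
                        anchored = "invented")
  ch2 <- synthesize_chromatogram(
    tibble::tibble(class = c("InsP5 [1/3-OH]", "InsP5 [4/6-OH]"),
                   amount = c(0.5, 0.4)), rt2)
  expect_equal(nrow(detect_peaks(ch2)), 2L)

  expect_error(detect_peaks(ch[1:3, ], smooth_window = 5), "shorter")
})

test_that("detection agrees with an independent peak finder on a ladder", {
  skip_if_not_installed("pracma")
  prof <- tibble::tibble(
    class = c("Pi/InsP1", "InsP5 [1/3-OH]", "InsP6"),
    amount = c(0.3, 0.2, 0.5))
  ch <- synthesize_chromatogram(prof, rt_default)
  ours <- detect_peaks(ch)
  ref <- pracma::findpeaks(ch$signal, minpeakheight = 0.01)
  expect_equal(nrow(ours), nrow(ref))
  expect_equal(sort(ours$apex_time), sort(ch$time_min[ref[, 2]]),
               tolerance = 0.02)
})

test_that("full standards ladders are detected with perfect recall", {
  withr::local_seed(33)
  for (rep in 1:5) {
    n <- sample(3:nrow(rt_full), 1)
    prof <- random_profile(sample(rt_full$class, n), min_fraction = 0.02)
    ch <- synthesize_chromatogram(prof, rt_full)
    pk <- integrate_and_assign(detect_peaks(ch), ch, rt_full)
    active <- prof$class[prof$amount > 0]
    expect_setequal(pk$class, active) # recall and precision both 1
  }
})

test_that("assignment uses retention-time proximity with tolerance", {
  prof <- make_substrate("clean")
  ch <- synthesize_chromatogram(prof, rt_default)
  pk <- integrate_and_assign(detect_peaks(ch), ch, rt_default)
  expect_equal(pk$class[which.min(abs(pk$apex_time - 37))], "InsP6")

  pi_prof <- tibble::tibble(class = "Pi/InsP1", amount = 1)
  chp <- synthesize_chromatogram(pi_prof, rt_default)
  pkp <- integrate_and_assign(detect_peaks(chp), chp, rt_default)
  expect_equal(pkp$class, "Pi/InsP1")

  # a peak far from every table entry stays unassigned
  rt_off <- tibble::tibble(class = "InsP6", rt_min = 33.5, sigma_min = 0.25,
                           anchored = "invented")
  ch_off <- synthesize_chromatogram(tibble::tibble(class = "InsP6", amount = 1),
                                    rt_off)
  pk_off <- integrate_and_assign(detect_peaks(ch_off), ch_off, rt_default)
  expect_true(is.na(pk_off$class))

  # uniform retention jitter below half the tolerance leaves assignment intact
  rt_jit <- rt_default
  rt_jit$rt_min <- rt_jit$rt_min + 0.15
  ch_jit <- synthesize_chromatogram(prof, rt_jit)
  pk_jit <- integrate_and_assign(detect_peaks(ch_jit), ch_jit, rt_default)
  expect_setequal(pk_jit$class, c("InsP6", "InsP5 [1/3-OH]"))
})

test_that("quantification recovers profiles and applies response models", {
  # pipeline self-consistency on random noise-free profiles
  withr::local_seed(12)
  for (rep in 1:20) {
    n_active <- sample(2:10, 1)
    prof <- random_profile(rt_full$class, n_active, min_fraction = 0.02)
    ch <- synthesize_chromatogram(prof, rt_full)
    rec <- requantify(ch, rt_full)
    err <- max(abs(rec$mole_fraction[match(prof$class, rec$class)] -
                     prof$mole_fraction))
    expect_lt(err, 0.01)
  }

  # single class -> recovered fraction 1
  one <- tibble::tibble(class = "InsP6", amount = 0.4)
  ch1 <- synthesize_chromatogram(one, rt_default)
  rec1 <- requantify(ch1, rt_default)
  expect_equal(rec1$mole_fraction[rec1$class == "InsP6"], 1)

  # per-phosphate response: equal areas mean a 1:2 InsP6:InsP3 mole ratio
  pk <- tibble::tibble(apex_time = c(14, 37), height = c(1, 1),
                       index = c(1L, 2L), area = c(0.3, 0.3),
                       class = c("InsP3", "InsP6"))
  qp <- quantify(pk, response = "per_phosphate")
  expect_equal(qp$amount[qp$class == "InsP3"] / qp$amount[qp$class == "InsP6"], 2)

  # unassigned peaks are reported, not dropped silently
  pk_un <- tibble::tibble(apex_time = 33.5, height = 1, index = 1L,
                          area = 0.2, class = NA_character_)
  expect_warning(q_un <- quantify(pk_un), "unassigned")
  expect_equal(nrow(attr(q_un, "unassigned")), 1L)
})

test_that("quantification bias stays below 5% at a signal-to-noise of 20", {
  withr::local_seed(90)
  prof <- random_profile(c("Pi/InsP1", "InsP3", "d/l-Ins(1,2,5,6)P4",
                           "InsP5 [1/3-OH]", "InsP5 [4/6-OH]", "InsP6"),
                         min_fraction = 0.05)
  ch0 <- synthesize_chromatogram(prof, rt_default)
  min_height <- min(prof$amount) / (0.25 * sqrt(2 * pi))
  noise_sd <- min_height / 20
  rec <- matrix(0, 50, nrow(prof))
  for (s in 1:50) {
    ch <- synthesize_chromatogram(prof, rt_default, noise_sd = noise_sd, seed = s)
    q <- requantify(ch, rt_default)
    rec[s, ] <- q$mole_fraction[match(prof$class, q$class)]
  }
  bias <- abs(colMeans(rec) - prof$mole_fraction) / prof$mole_fraction
  expect_lt(max(bias), 0.05)
  # and the noise-free bias is below 1% relative
  q0 <- requantify(ch0, rt_default)
  bias0 <- abs(q0$mole_fraction[match(prof$class, q0$class)] -
                 prof$mole_fraction) / prof$mole_fraction
  expect_lt(max(bias0), 0.01)
})

test_that("chromatogram CSV round-trips and rejects malformed input", {
  prof <- make_substrate("clean")
  ch <- synthesize_chromatogram(prof, rt_default, noise_sd = 0.01, seed = 3)
  path <- withr::local_tempfile(fileext = ".csv")
  write_chromatogram(ch, path)
  back <- read_chromatogram(path)
  expect_equal(back$time_min, ch$time_min, tolerance = 1e-9)
  expect_equal(back$signal, ch$signal, tolerance = 1e-9)

  bad_header <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("minutes,au", "0,0"), bad_header)
  expect_error(read_chromatogram(bad_header), "header")

  bad_row <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("time_min,signal", "0,0.1", "0.01,oops", "0.02,0.3"), bad_row)
  expect_error(read_chromatogram(bad_row), "line 3")

  bad_grid <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("time_min,signal", "0,0", "0.01,0", "0.5,0", "0.51,0"), bad_grid)
  expect_error(read_chromatogram(bad_grid), "non-uniform")
})
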