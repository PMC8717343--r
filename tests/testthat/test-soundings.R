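test_that("block averaging reduces groups of k to their means", {
  s <- ss(1:10, rep(0, 10), 1:10)
  expect_equal(as.data.frame(block_average(s, 1))[c("x", "y", "t", "depth")],
               as.data.frame(s)[c("x", "y", "t", "depth")])
  b <- block_average(s, 10)
  expect_equal(nrow(b), 1)
  expect_equal(b$depth, 5.5)
  expect_equal(b$x, 5.5)
  ## constant depths stay constant
  b2 <- block_average(ss(1:10, rep(0, 10), rep(50, 10)), 10)
  expect_equal(b2$depth, 50)
  ## remainder group of >= k/2 kept, < k/2 dropped
  b3 <- block_average(ss(1:13, rep(0, 13), 1:13), 10)   # remainder 3 < 5
  expect_equal(nrow(b3), 1)
  b4 <- block_average(ss(1:16, rep(0, 16), 1:16), 10)   # remainder 6 >= 5
  expect_equal(nrow(b4), 2)
  expect_equal(b4$depth[2], mean(11:16))
  expect_error(block_average(s, 0))
})

test_that("tide correction applies the interpolated height minus datum offset", {
  tide <- tide_series(data.frame(t = c(0, 100), height = c(1.30, 1.30)),
                      datum_offset = 0.30)
  s <- ss(0, 0, 20, t = 50)
  expect_equal(tide_correct(s, tide)$depth, 19.00)
  ## tide equal to the offset leaves depths unchanged
  tide0 <- tide_series(data.frame(t = c(0, 100), height = c(0.30, 0.30)),
                       datum_offset = 0.30)
  expect_equal(tide_correct(s, tide0)$depth, 20)
  expect_error(tide_correct(ss(0, 0, 20, t = 500), tide), "outside")
})

test_that("tide correction round-trips raw depths to 1e-9", {
  fix <- test_survey(21, test_scenario(21, extent_x = 2000, extent_y = 1500))
  raw <- fix$survey$soundings
  corr <- tide_correct(raw, fix$survey$tide)
  back <- tide_correct(corr, fix$survey$tide, invert = TRUE)
  expect_lt(max(abs(back$depth - raw$depth)), 1e-9)
})

test_that("tide-corrected depths recover the DEM to within the noise level", {
  des <- survey_design(depth_noise_sd = 0.2, spike_rate = 0, tide_amplitude = 1)
  fix <- test_survey(22, test_scenario(22, extent_x = 3000, extent_y = 2000),
                     design = des)
  corr <- tide_correct(fix$survey$soundings, fix$survey$tide)
  resid_sd <- stats::sd(corr$depth - corr$true_depth)
  expect_lt(abs(resid_sd - 0.2), 0.05)
})

test_that("despike removes isolated spikes and nothing from clean data", {
  clean <- ss(1:50, rep(0, 50), rep(50, 50))
  expect_equal(nrow(despike(clean, 5, 6)), 50)
  z <- rep(50, 50); z[25] <- 80
  d <- despike(ss(1:50, rep(0, 50), z), 5, 6)
  expect_equal(nrow(d), 49)
  expect_false(80 %in% d$depth)
  ## non-positive depths removed too
  z2 <- rep(50, 50); z2[10] <- -3
  expect_equal(nrow(despike(ss(1:50, rep(0, 50), z2), 5, 6)), 49)
  expect_error(despike(clean, 4, 6), "odd")
})

test_that("despike is idempotent on its own output", {
  fix <- test_survey(23, test_scenario(23, extent_x = 3000, extent_y = 1500),
                     design = survey_design(spike_rate = 0.01))
  s <- tide_correct(fix$survey$soundings, fix$survey$tide)
  d1 <- despike(s)
  d2 <- despike(d1)
  expect_equal(nrow(d2), nrow(d1))
})

test_that("sounding summary reports the adjusted Fisher-Pearson skewness", {
  sm <- summarize_soundings(ss(1:3, rep(0, 3), c(1, 2, 3)))
  expect_equal(sm$skewness, 0)
  expect_false(sm$transformation_advised)
  ## constant sample: zero variance flagged
  smc <- summarize_soundings(ss(1:5, rep(0, 5), rep(7, 5)))
  expect_equal(smc$skewness, 0)
  expect_true(smc$zero_variance)
  ## strongly right-skewed sample raises the flag
  sms <- summarize_soundings(ss(1:4, rep(0, 4), c(1, 1, 1, 10)))
  expect_gt(sms$skewness, 1)
  expect_true(sms$transformation_advised)
  expect_true(sm$min <= sm$mean && sm$mean <= sm$max)
  expect_error(summarize_soundings(ss(1:2, c(0, 0), c(1, 2))), "n < 3")
})

test_that("QC operations append to the provenance log in order", {
  fix <- test_survey(24, test_scenario(24, extent_x = 2000, extent_y = 1500))
  s <- fix$survey$soundings
  out <- despike(tide_correct(block_average(s, 2), fix$survey$tide))
  prov <- attr(out, "provenance")
  expect_true(any(grepl("block_average", prov)))
  expect_lt(which(grepl("block_average", prov)), which(grepl("tide_correct", prov)))
  expect_lt(which(grepl("tide_correct", prov)), which(grepl("despike", prov)))
})

test_that("sounding and tide CSV files round-trip", {
  s <- ss(1:5, 5:1, c(10, 20, 30, 40, 50))
  f <- tempfile(fileext = ".csv")
  write_soundings_csv(s, f)
  r <- read_soundings_csv(f)
  expect_equal(as.data.frame(r)[c("x", "y", "t", "depth")],
               as.data.frame(s)[c("x", "y", "t", "depth")])
  tide <- tide_series(data.frame(t = c(0, 600), height = c(0.2, 0.4)), 0.3)
  ft <- tempfile(fileext = ".csv")
  write_tide_csv(tide, ft)
  r2 <- read_tide_csv(ft, datum_offset = 0.3)
  expect_equal(r2$samples, tide$samples)
  expect_equal(r2$datum_offset, 0.3)
})
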