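test_that("semitone deviation matches equal-temperament arithmetic", {
  expect_equal(semitone_deviation(631.6, 1263.2), 12)
  expect_equal(semitone_deviation(440, 440), 0)
  expect_equal(semitone_deviation(440, 466.16), 1, tolerance = 3e-4)
  # symmetric under argument swap (absolute form)
  expect_equal(semitone_deviation(200, 350), semitone_deviation(350, 200))
  expect_equal(semitone_deviation(200, 350, signed = TRUE),
               -semitone_deviation(350, 200, signed = TRUE))
  expect_error(semitone_deviation(0, 100), "positive")
})

test_that("a quartic deviation pattern is recovered exactly by the fit", {
  st <- mean_electrode_state()
  # construct centres so the deviation is an exact quartic in angle
  quartic <- function(th) 5 + 0.01 * th + 2e-5 * th^2 - 1e-8 * th^3 + 5e-12 * th^4
  s_true <- quartic(st$angle_deg)
  fmap <- default_frequency_map()
  fmap$centre_hz <- st$place_hz / 2^(s_true / 12)
  pr <- fit_mismatch_profile(st, fmap)
  expect_equal(pr$data$deviation_st, s_true, tolerance = 1e-8)
  expect_equal(mismatch_at_c6(pr), s_true[6], tolerance = 1e-8)
})

test_that("constant deviation yields a constant profile equal to it at C6", {
  st <- mean_electrode_state()
  fmap <- default_frequency_map()
  fmap$centre_hz <- st$place_hz / 2^(3 / 12) # uniform 3-semitone shift
  pr <- fit_mismatch_profile(st, fmap)
  expect_equal(mismatch_at_c6(pr), 3, tolerance = 1e-8)
})

test_that("zero-mismatch construction returns exactly zero", {
  st <- mean_electrode_state()
  fmap <- default_frequency_map()
  fmap$centre_hz <- st$place_hz
  pr <- fit_mismatch_profile(st, fmap)
  expect_equal(mismatch_at_c6(pr), 0, tolerance = 1e-10)
})

test_that("at cohort-mean geometry the C6 place lies in the 1-2 kHz speech band", {
  pr <- fit_mismatch_profile(mean_electrode_state())
  expect_true(pr$c6_in_band)
  expect_true(pr$c6_place_hz > 1000 && pr$c6_place_hz < 2000)
  # under default maps the shallow shift is largest apically: the deviation
  # declines monotonically from C1 to C12
  dev <- pr$data$deviation_st
  expect_true(all(diff(dev) < 0))
})

test_that("the C6 statistic is non-increasing in insertion depth", {
  depths <- seq(20, 27.5, by = 0.25)
  m <- vapply(depths, function(L) {
    mismatch_at_c6(fit_mismatch_profile(locate_contacts(L, 34.0)))
  }, 1.0)
  expect_true(all(diff(m) <= 1e-9))
})

test_that("fewer than five intracochlear contacts falls back to the raw C6 deviation", {
  st <- locate_contacts(23.1 * 3 / 11 + 0.5, 34.0) # 4 contacts inside
  expect_lt(sum(!is.na(st$angle_deg)), 5)
  expect_warning(pr <- fit_mismatch_profile(st), "fewer than 5")
  expect_true(pr$fallback)
  expect_true(is.na(mismatch_at_c6(pr))) # C6 itself is extracochlear here
})

test_that("mismatch profiles tidy to a per-contact tibble", {
  pr <- fit_mismatch_profile(mean_electrode_state())
  td <- tidy(pr)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 12)
  expect_named(td, c("contact", "angle_deg", "centre_hz", "place_hz",
                     "deviation_st"))
})
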