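test_that("measure_spl maps digital RMS to dB SPL via the affine model", {
  cal100 <- calibration_map(offset = 100, volume = 100)  # no attenuation
  square <- audio_buffer(rep(c(1, -1), 500), 16000)      # RMS exactly 1
  expect_equal(measure_spl(square, cal100), 100)
  sine <- sine_buffer(1000, 0.5, 16000)                  # RMS 1/sqrt(2)
  expect_within(measure_spl(sine, cal100), 100 - 3.0103, 1e-3)
  expect_error(measure_spl(audio_buffer(rep(0, 100), 16000), cal100), "silent")
})

test_that("measure_spl is scale-covariant and monotone in volume", {
  withr::local_seed(51)
  x <- generate_fixture("white", 0.2, 16000, seed = 52)
  for (a in c(0.01, 0.3, 2.5)) {
    expect_equal(measure_spl(audio_buffer(x$samples * a, 16000), test_calib) -
                   measure_spl(x, test_calib),
                 20 * log10(a), tolerance = 1e-9)
  }
  vols <- seq(0, 100, by = 10)
  spl <- vapply(vols, function(v)
    measure_spl(x, default_calibration(volume = v)), numeric(1))
  expect_true(all(diff(spl) >= 0))
})

test_that("the conversational fixture sits in the 62-65 dB SPL window", {
  x <- conversational_fixture(6, 32000)
  spl <- measure_spl(x, default_calibration())
  expect_gte(spl, 62)
  expect_lte(spl, 65)
})

test_that("LTASS of white noise rises ~1 dB per third-octave band", {
  x <- generate_fixture("white", 8, 32000, seed = 53)
  rep <- compute_ltass(x, test_calib)
  fit <- stats::lm(ltass_db ~ seq_along(band), data = rep$bands)
  expect_within(unname(stats::coef(fit)[2]), 10 * log10(2^(1 / 3)), 0.3)
})

test_that("LTASS of a pure tone concentrates in its own band", {
  x <- generate_fixture("tone:1000", 6, 32000, seed = 54)
  rep <- compute_ltass(x, test_calib)
  i1k <- which(rep$bands$band == 1000)
  expect_gt(rep$bands$ltass_db[i1k] - rep$bands$ltass_db[i1k - 1], 30)
  expect_gt(rep$bands$ltass_db[i1k] - rep$bands$ltass_db[i1k + 1], 30)
})

test_that("the dynamic speech range brackets the LTASS in every band", {
  x <- conversational_fixture(6, 32000)
  rep <- compute_ltass(x, test_calib)
  expect_true(all(rep$bands$p30_db <= rep$bands$ltass_db + 1e-9))
  expect_true(all(rep$bands$ltass_db <= rep$bands$p99_db + 1e-9))
  expect_error(compute_ltass(conversational_fixture(2, 16000), test_calib),
               "5 s")
})

test_that("third-octave band powers account for the total signal power", {
  x <- conversational_fixture(6, 32000)          # band-limited by its shaping
  bl <- band_levels(x)
  total_band <- sum(10^(bl / 10))
  total_rms <- 10^(measure_spl(x, test_calib) / 10)
  expect_within(total_band / total_rms, 1, 0.05)
})

test_that("chain verification reports the expected Speechmap checks", {
  src <- set_spl(conversational_fixture(6, 32000), 63.5, test_calib)
  ag <- audiogram_preset("sloping_snhl")

  v_norm <- verify_chain(src, ag, "normal")
  expect_true(all(v_norm$checks$pass))

  v_un <- verify_chain(src, ag, "unaided")
  expect_true(all(v_un$checks$pass))
  # 4 kHz band drops by the 4 kHz preset threshold (60 dB HL)
  i4k <- which(v_un$input_ltass$bands$band == 4000)
  drop <- v_un$input_ltass$bands$ltass_db[i4k] -
    v_un$output_ltass$bands$ltass_db[i4k]
  expect_within(drop, 60, 2)

  v_aid <- verify_chain(src, ag, "aided")
  expect_true(all(v_aid$checks$pass))
})

test_that("verification reports round-trip to CSV and JSON", {
  src <- set_spl(conversational_fixture(5, 32000), 63.5, test_calib)
  v <- verify_chain(src, audiogram_preset("normal"), "normal")
  csv <- withr::local_tempfile(fileext = ".csv")
  js <- withr::local_tempfile(fileext = ".json")
  write_verification(v, csv_path = csv, json_path = js)
  tab <- utils::read.csv(csv)
  expect_named(tab, c("band_hz", "ltass_db", "p30_db", "p99_db"))
  expect_equal(nrow(tab), 19)
  expect_true(jsonlite::fromJSON(js)$pass)
})
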