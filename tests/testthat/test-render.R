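test_that("WAV files round-trip", {
  withr::local_seed(61)
  x <- audio_buffer(cbind(runif(3000, -1, 1), runif(3000, -1, 1)), 44100)
  path <- withr::local_tempfile(fileext = ".wav")
  write_wav(x, path)                      # float32
  y <- read_wav(path)
  expect_equal(y$rate, 44100L)
  expect_lt(max(abs(y$samples - x$samples)), 1e-7)
  write_wav(x, path, format = "pcm16")
  y16 <- read_wav(path)
  expect_lt(max(abs(y16$samples - x$samples)), 1 / 32000)
})

test_that("a normal/quiet job is an identity render", {
  job <- render_job(input = "fixture:speech_shaped", sc = scenario("quiet"),
                    mode = "normal", input_spl = NULL, duration = 0.5,
                    rate = 16000, seed = 5)
  res <- render(job)
  src <- generate_fixture("speech_shaped", 0.5, 16000, seed = 5)
  expect_lt(max(abs(res$audio$samples[, 1] - src$samples[, 1])), 1e-6)
  expect_lt(max(abs(res$audio$samples[, 2] - src$samples[, 1])), 1e-6)
  expect_equal(res$meta$clip_count, 0)
})

test_that("seeded renders are byte-identical across runs", {
  job <- render_job(mode = "aided", sc = scenario("noise", snr_db = 5),
                    duration = 0.5, rate = 16000, seed = 9)
  f1 <- withr::local_tempfile(fileext = ".wav")
  f2 <- withr::local_tempfile(fileext = ".wav")
  render(job, out = f1)
  render(job, out = f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("three-mode renders of one fixture obey the audibility ordering", {
  mk <- function(mode) render(render_job(mode = mode, duration = 1,
                                         rate = 32000, seed = 3))
  res <- list(normal = mk("normal"), unaided = mk("unaided"),
              aided = mk("aided"))
  r <- vapply(res, function(x) buffer_rms(x$audio), numeric(1))
  expect_lt(r[["unaided"]], r[["aided"]])
  expect_lt(r[["aided"]], r[["normal"]])

  rep <- compare_report(res)
  expect_equal(rep$summary$delta_db[rep$summary$mode == "normal"], 0)
  expect_lt(rep$summary$delta_db[rep$summary$mode == "unaided"],
            rep$summary$delta_db[rep$summary$mode == "aided"])
})

test_that("compare_report measures analytic deltas between jobs", {
  freqs <- c(250, 500, 1000, 2000, 4000, 8000)
  flat60 <- audiogram(stats::setNames(rep(60, 6), freqs))
  mk <- function(mode, ag = flat60, sc = scenario("quiet"))
    render(render_job(mode = mode, ag = ag, sc = sc, duration = 1,
                      rate = 32000, seed = 4))
  res <- list(normal = mk("normal"), unaided = mk("unaided"))
  rep <- compare_report(res)
  expect_within(rep$summary$delta_db[2], -60, 1)

  far <- list(normal = mk("normal"),
              far = mk("normal", sc = scenario("distance", distance = 12,
                                               distance_unit = "ft")))
  rep2 <- compare_report(far)
  expect_within(rep2$summary$delta_db[2], -11.263, 0.1)

  other <- render(render_job(mode = "normal", duration = 1, rate = 32000,
                             seed = 99))
  expect_error(compare_report(list(normal = res$normal, o = other)),
               "same source")
})

cli_path <- system.file("cli", "hearsim.R", package = "hearsim")

run_cli <- function(...) {
  out <- suppressWarnings(
    system2("Rscript", c(cli_path, ...), stdout = TRUE, stderr = TRUE))
  list(status = attr(out, "status") %||% 0L, output = paste(out, collapse = "\n"))
}

test_that("the CLI renders, lists and fails loudly", {
  skip_if(cli_path == "", "CLI script not installed")
  wav <- withr::local_tempfile(fileext = ".wav")
  ok <- run_cli("render", "--fixture", "speech_shaped", "--mode", "unaided",
                "--duration", "0.5", "--rate", "16000", "--seed", "1",
                "--out", wav)
  expect_equal(ok$status, 0L)
  expect_true(file.exists(wav) && file.exists(paste0(wav, ".json")))
  side <- jsonlite::fromJSON(paste0(wav, ".json"))
  expect_equal(side$mode, "unaided")

  expect_equal(run_cli("presets")$status, 0L)
  expect_equal(run_cli("fixtures")$status, 0L)

  bad_mode <- run_cli("render", "--mode", "loud", "--out", wav)
  expect_equal(bad_mode$status, 1L)
  expect_match(bad_mode$output, "--mode")

  bad_preset <- run_cli("render", "--preset", "flat90", "--out", wav)
  expect_equal(bad_preset$status, 1L)
  expect_match(bad_preset$output, "preset")

  no_out <- run_cli("render")
  expect_equal(no_out$status, 1L)
  expect_match(no_out$output, "--out")
})
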