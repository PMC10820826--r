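# File-in / file-out runs and their failure modes.

test_that("run_itc fits a generated input and reports convergence", {
  dir <- withr::local_tempdir()
  g <- gen_isotherm(16.3e-6, 0.8, -8.8, noise_sd = 0.2, seed = 2)
  csv <- file.path(dir, "iso.csv")
  write_itc_csv(g$isotherm, csv)
  out <- run_itc(csv, file.path(dir, "out"))
  expect_equal(out$status, 0L)
  report <- jsonlite::read_json(out$json, simplifyVector = TRUE)
  expect_true(report$converged)
  expect_equal(report$kd_uM, 16.3, tolerance = 0.05)
  expect_true(file.exists(file.path(dir, "out", "run_config.json")))
  # reruns are byte-identical
  out2 <- run_itc(csv, file.path(dir, "out2"))
  expect_identical(readLines(out$json), readLines(out2$json))
})

test_that("run_itc signals input errors as such", {
  dir <- withr::local_tempdir()
  expect_error(run_itc(file.path(dir, "missing.csv"), dir),
               class = "mintkit_input_error")
  empty <- file.path(dir, "empty.csv")
  writeLines(character(0), empty)
  expect_error(run_itc(empty, dir), class = "mintkit_input_error")
  garbage <- file.path(dir, "garbage.csv")
  writeLines(c("a,b", "1,2"), garbage)
  expect_error(run_itc(garbage, dir), class = "mintkit_input_error")
})

test_that("run_screen triages strong, weak and malformed bundles in one pass", {
  dir <- withr::local_tempdir()
  strong <- gen_prediction_bundle(triage_scenario(seed = 1),
                                  file.path(dir, "strong"), "strong_pair")
  weak <- gen_prediction_bundle(
    triage_scenario(designed_iptm = c(0.1, 0.1, 0.1),
                    interchain_pae_level = 30, seed = 2),
    file.path(dir, "weak"), "weak_pair")
  broken_dir <- file.path(dir, "broken")
  dir.create(broken_dir)
  writeLines("{ not json", file.path(broken_dir, "manifest.json"))
  screen <- file.path(dir, "screen.json")
  jsonlite::write_json(list(pairs = c(strong$manifest, weak$manifest,
                                      file.path(broken_dir, "manifest.json"))),
                       screen)
  out_csv <- file.path(dir, "summary.csv")
  res <- run_screen(screen, out_csv)
  expect_equal(res$summary$verdict,
               c("interactor_candidate", "no_call", "rejected"))
  tab <- read.csv(out_csv)
  expect_equal(nrow(tab), 3)
  # rerun is identical
  res2 <- run_screen(screen, file.path(dir, "summary2.csv"))
  expect_identical(res$summary, res2$summary)
  # empty manifest -> header-only summary
  empty_manifest <- file.path(dir, "none.json")
  jsonlite::write_json(list(pairs = list()), empty_manifest)
  res0 <- run_screen(empty_manifest, file.path(dir, "empty.csv"))
  expect_equal(nrow(res0$summary), 0)
  expect_equal(names(read.csv(file.path(dir, "empty.csv"))),
               names(tab))
  expect_error(run_screen(file.path(dir, "nope.json"), out_csv),
               class = "mintkit_input_error")
})

test_that("run_fusion writes events matching the generator truth", {
  dir <- withr::local_tempdir()
  gm <- gen_small_movie(seed = 51)
  tif <- file.path(dir, "cell.tif")
  write_movie(gm$movie, tif)
  out <- run_fusion(tif, file.path(dir, "out"),
                    config = small_movie_config(),
                    mask = matrix(TRUE, 64, 64))
  ev <- read.csv(out$events_csv)
  expect_equal(sum(ev$completed), nrow(gm$truth))
  series <- read.csv(file.path(dir, "out", "release_series.csv"))
  expect_equal(tail(series$cumulative, 1), nrow(gm$truth))
  summary <- jsonlite::read_json(file.path(dir, "out",
                                           "fusion_summary.json"),
                                 simplifyVector = TRUE)
  expect_equal(summary$n_completed, nrow(gm$truth))
  expect_gt(summary$density_per_um2, 0)
})

test_that("run_fusion without stimulation metadata warns and continues", {
  dir <- withr::local_tempdir()
  gm <- gen_small_movie(seed = 52, stimulation_frame = NULL)
  bin <- file.path(dir, "cell.bin")
  write_movie(gm$movie, bin)
  expect_warning(
    out <- run_fusion(bin, file.path(dir, "out"),
                      config = small_movie_config(),
                      mask = matrix(TRUE, 64, 64)),
    "whole acquisition")
  expect_equal(out$status, 0L)
})

test_that("run_fusion_compare reports U and the exact enumeration p", {
  dir <- withr::local_tempdir()
  a <- c(0.9, 1.4, 1.1, 1.7, 1.3)
  b <- c(0.6, 0.8, 0.5, 1.0)
  write.csv(data.frame(density_per_um2 = a), file.path(dir, "a.csv"),
            row.names = FALSE)
  write.csv(data.frame(density_per_um2 = b), file.path(dir, "b.csv"),
            row.names = FALSE)
  cmp <- run_fusion_compare(file.path(dir, "a.csv"), file.path(dir, "b.csv"),
                            file.path(dir, "cmp.json"))
  got <- jsonlite::read_json(file.path(dir, "cmp.json"),
                             simplifyVector = TRUE)
  expect_equal(got$u_statistic, cmp$u_statistic)
  expect_equal(got$p_value, mw_exact_p_enumeration(a, b), tolerance = 1e-12)
  expect_error(run_fusion_compare(file.path(dir, "a.csv"),
                                  file.path(dir, "zzz.csv"),
                                  file.path(dir, "cmp2.json")),
               class = "mintkit_input_error")
})

test_that("the command-line wrapper runs an ITC simulate-fit cycle", {
  cli <- system.file("cli", "mintkit", package = "mintkit")
  expect_true(nzchar(cli))
  dir <- withr::local_tempdir()
  rscript <- file.path(R.home("bin"), "Rscript")
  s1 <- system2(rscript, c(cli, "itc-simulate", "--kd-um", "5", "--dh",
                           "-10", "--out", file.path(dir, "iso.csv")))
  expect_equal(s1, 0L)
  s2 <- system2(rscript, c(cli, "itc-fit", file.path(dir, "iso.csv"),
                           "--out", file.path(dir, "fit")))
  expect_equal(s2, 0L)
  report <- jsonlite::read_json(file.path(dir, "fit", "itc_fit.json"),
                                simplifyVector = TRUE)
  expect_equal(report$kd_uM, 5, tolerance = 0.01)
  # missing input exits with the input-error code
  s3 <- system2(rscript, c(cli, "itc-fit", file.path(dir, "nope.csv"),
                           "--out", dir), stderr = FALSE)
  expect_equal(s3, 2L)
})
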