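test_that("CSV grids round-trip bit-identically", {
  img <- ct_image(matrix(c(-1000, 0, 40.5, 3071), 2, 2), spacing = c(0.5, 0.5))
  f <- withr::local_tempfile(fileext = ".csv")
  write_ct_image(img, f)
  back <- read_ct_image(f)
  expect_identical(back$pixels, img$pixels)

  zero <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("0,0,0", "0,0,0", "0,0,0"), zero)
  g <- read_ct_image(zero)
  expect_equal(g$pixels, matrix(0, 3, 3))
  expect_equal(g$spacing, c(1, 1))
})

test_that("ragged or non-numeric CSV grids are rejected", {
  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("1,2,3", "4,5"), bad)
  expect_error(read_ct_image(bad), "non-rectangular")
  alpha <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("1,a", "2,3"), alpha)
  expect_error(read_ct_image(alpha), "non-numeric")
})

test_that("16-bit TIFF + sidecar restores HU including negatives", {
  px <- matrix(seq(-1024, 1500, length.out = 64), 8, 8)
  img <- ct_image(px, spacing = c(0.4, 0.4))
  f <- withr::local_tempfile(fileext = ".tiff")
  write_ct_image(img, f)
  expect_true(file.exists(paste0(f, ".json")))
  back <- read_ct_image(f)
  # quantization step is range/65535 ~ 0.039 HU
  expect_lt(max(abs(back$pixels - px)), 2 * diff(range(px)) / 65535)
  expect_equal(back$spacing, c(0.4, 0.4))
})

test_that("ct_image validates pixels and spacing", {
  expect_error(ct_image(matrix(c(1, NA), 1, 2)), "finite")
  expect_error(ct_image(matrix(1, 2, 2), spacing = 0), "positive")
  img <- ct_image(matrix(1:6, 2, 3))
  expect_equal(dim(img), c(2L, 3L))
  expect_equal(as.matrix(img), matrix(as.numeric(1:6), 2, 3))
})

test_that("run configs validate keys and round-trip through YAML and JSON", {
  cfg <- run_config(seed = 7, radial = list(n_angles = 180),
                    phantom = list(preset = "ir_like"))
  for (ext in c(".yaml", ".json")) {
    f <- withr::local_tempfile(fileext = ext)
    write_run_config(cfg, f)
    back <- read_run_config(f)
    expect_equal(back$seed, 7L)
    expect_equal(back$radial$n_angles, 180)
    expect_equal(back$phantom$preset, "ir_like")
  }
  expect_error(run_config(seed = 1, bogus = 2), "unused argument")
  expect_error(effcnr:::validate_run_config(list(seed = 1, bogus = 2)),
               "unknown run-config keys")
  expect_error(run_config(radial = list(rays = 10)), "unknown keys in")
})

test_that("the command-line tool runs its subcommands", {
  skip_on_os("windows")
  cli <- system.file("cli", "effcnr.R", package = "effcnr")
  expect_true(nzchar(cli))
  rscript <- file.path(R.home("bin"), "Rscript")
  # make sure the spawned process sees the library this package is loaded from
  libs <- paste0("R_LIBS=", paste(.libPaths(), collapse = .Platform$path.sep))
  tmp <- withr::local_tempdir()

  # simulate writes a phantom image
  out <- file.path(tmp, "phantom.csv")
  st <- system2(rscript, c(cli, "simulate", "--preset", "dlr_like",
                           "--seed", "4", "--out", out),
                stdout = TRUE, stderr = TRUE, env = libs)
  expect_equal(attr(st, "status"), NULL)
  expect_true(file.exists(out))

  # noise analysis on that phantom's background fails politely on a flat file
  flat <- file.path(tmp, "flat.csv")
  write_ct_image(ct_image(matrix(0, 50, 50)), flat)
  st2 <- suppressWarnings(
    system2(rscript, c(cli, "noise", "--input", flat),
            stdout = TRUE, stderr = TRUE, env = libs))
  expect_equal(attr(st2, "status"), 1)
  expect_match(paste(st2, collapse = "\n"), "flat")

  # noise analysis on a real noise image writes a JSON report
  nz <- file.path(tmp, "noise.csv")
  write_ct_image(ct_image(64 + noise_field(c(64, 64), 10, 0, seed = 2)), nz)
  rep <- file.path(tmp, "noise.json")
  st3 <- system2(rscript, c(cli, "noise", "--input", nz, "--out", rep),
                 stdout = TRUE, stderr = TRUE, env = libs)
  expect_equal(attr(st3, "status"), NULL)
  parsed <- jsonlite::read_json(rep)
  expect_equal(parsed$sigma_apparent, 10, tolerance = 0.2)
})
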