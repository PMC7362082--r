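test_that("default parameter set carries the calibrated constants", {
  p <- fibrin_params()
  expect_identical(
    unclass(p)[c("k1", "k2", "d2", "k3", "d3", "k4", "d4", "k5", "k6", "d5")],
    list(k1 = 1.5, k2 = 3e-4, d2 = 46, k3 = 130, d3 = 10,
         k4 = 13, d4 = 20, k5 = 0.1, k6 = 2e-4, d5 = 11.5))
  # stated interaction hierarchy and binding conventions
  expect_identical(p$k3 / p$k4, 10)
  expect_identical(p$d4 / p$d3, 2)
  expect_identical(p$k5 / p$k6, 500)
  expect_length(validate_parameters(p), 0)
})

test_that("validation names each offending field", {
  p <- fibrin_params()
  p$k1 <- -1
  v <- validate_parameters(p)
  expect_length(v, 1)
  expect_match(v, "^k1")
  p <- fibrin_params()
  p$d4 <- 0
  v <- validate_parameters(p)
  expect_length(v, 1)
  expect_match(v, "^d4")
  expect_error(fibrin_params(d3 = -1), "d3", class = "fibrinet_validation_error")
  expect_error(fiber_geometry(protein_fraction = 1.2), "protein_fraction")
  expect_error(fiber_geometry(fiber_length = 10), "element_rest_length")
  expect_error(clot_params(fiber_density_per_um3 = 0), "fiber_density")
  expect_error(sim_controls(n_steps = 1), "n_steps")
})

test_that("k6 override off the k5/500 convention warns but is accepted", {
  expect_warning(p <- fibrin_params(k6 = 0.01), "k6")
  expect_identical(p$k6, 0.01)
  expect_silent(fibrin_params(k5 = 0, k6 = 0))
})

test_that("empty config yields the full default set", {
  cfg <- read_fibrin_config(NULL)
  expect_identical(cfg$parameters$k3, 130)
  expect_identical(cfg$fiber$fiber_length, 12000)
  expect_identical(cfg$clot$clot_diameter_mm, 2)
  expect_identical(cfg$simulation$n_steps, 500L)

  empty <- withr::local_tempfile(fileext = ".yaml")
  writeLines("", empty)
  cfg2 <- read_fibrin_config(empty)
  expect_identical(cfg2$parameters, cfg$parameters)
})

test_that("config overrides apply and k5 = 0 disables binding", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("parameters:", "  k5: 0.0", "  k6: 0.0"), path)
  cfg <- read_fibrin_config(path)
  expect_identical(cfg$parameters$k5, 0)
  expect_identical(binding_force(c(3, 25, 100), cfg$parameters), c(0, 0, 0))
  # other fields keep defaults
  expect_identical(cfg$parameters$k3, 130)
})

test_that("malformed values and unknown keys are reported", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("parameters:", "  d3: -1.0"), path)
  expect_error(read_fibrin_config(path), "d3")
  writeLines(c("parameters:", "  k1: 2.0", "  frobnicate: 1"), path)
  expect_warning(cfg <- read_fibrin_config(path), "frobnicate")
  expect_identical(cfg$parameters$k1, 2)
  writeLines(c("not_a_section:", "  a: 1"), path)
  expect_warning(read_fibrin_config(path), "not_a_section")
  expect_error(read_fibrin_config("/nonexistent/file.yaml"), "not found")
})

test_that("save/load round-trip reproduces every field bit-exactly", {
  cfg <- list(
    parameters = suppressWarnings(fibrin_params(k1 = 1/3, k6 = 2.0000001e-4)),
    fiber = fiber_geometry(fiber_length = 12345.6789, protein_fraction = 1/7),
    clot = clot_params(fiber_density_per_um3 = pi / 6),
    simulation = sim_controls(force_max = 199.99999999)
  )
  path <- withr::local_tempfile(fileext = ".yaml")
  write_fibrin_config(cfg, path)
  back <- suppressWarnings(read_fibrin_config(path))
  expect_identical(back$parameters, cfg$parameters)
  expect_identical(back$fiber, cfg$fiber)
  expect_identical(back$clot, cfg$clot)
  expect_identical(unclass(back$simulation)[1:4], unclass(cfg$simulation)[1:4])
})

test_that("shipped example config parses to the defaults", {
  path <- system.file("extdata", "default_config.yaml", package = "fibrinet")
  expect_true(nzchar(path))
  cfg <- read_fibrin_config(path)
  expect_identical(cfg$parameters, fibrin_params())
  expect_identical(cfg$fiber, fiber_geometry())
})
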