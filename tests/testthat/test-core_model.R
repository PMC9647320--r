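test_that("drift velocity, K and K0 reproduce worked values", {
  # unit-ratio identity
  expect_equal(drift_velocity(9.8, 9.8), 1000)
  # RIP and ethanol-monomer drift times, frozen from hand arithmetic
  expect_equal(drift_velocity(9.8, 4.889), 2004.5, tolerance = 1e-4)
  expect_equal(drift_velocity(9.8, 5.1628), 1898.2, tolerance = 1e-4)

  expect_equal(mobility_constant(1000, 500), 2)
  expect_equal(mobility_constant(2004.5, 500), 4.009)
  expect_equal(mobility_constant(1898.2, 500), 3.7964)

  # standard conditions leave K unchanged; half pressure halves K0
  expect_equal(normalize_mobility(4.009, 760, 273.15), 4.009)
  expect_equal(normalize_mobility(2.0, 380, 273.15), 1.0)
  # in-range operating conditions, frozen from hand arithmetic
  expect_equal(normalize_mobility(4.009, 758, 299.15), 3.651,
               tolerance = 1e-3)
})

test_that("mobility operations reject non-positive inputs by name", {
  expect_error(drift_velocity(-9.8, 5), "drift_length_cm")
  expect_error(drift_velocity(9.8, 0), "drift_time_ms")
  expect_error(mobility_constant(0, 500), "drift_velocity_cm_s")
  expect_error(normalize_mobility(2, -1, 273.15), "pressure_Torr")
  expect_error(relative_drift_time(5, 0), "rip_drift_time_ms")
})

test_that("mobility invariants hold over random inputs", {
  set.seed(11)
  K <- stats::runif(50, 0.1, 10)
  expect_equal(normalize_mobility(K, 760, 273.15), K)
  # K is strictly decreasing in drift time for fixed L, E
  td <- sort(stats::runif(20, 3, 12))
  Ks <- mobility_constant(drift_velocity(9.8, td), 500)
  expect_true(all(diff(Ks) < 0))
  rips <- stats::runif(20, 3, 7)
  expect_equal(relative_drift_time(rips, rips), rep(1, 20))
})

test_that("relative drift time reproduces library values", {
  expect_equal(relative_drift_time(4.889, 4.889), 1)
  expect_equal(relative_drift_time(5.1628, 4.889), 1.056, tolerance = 1e-5)
  expect_equal(relative_drift_time(6.1308, 4.889), 1.254, tolerance = 1e-5)
})

test_that("ion_mobility chains the three operations", {
  dev <- device_config(pressure_Torr = 760, temperature_K = 273.15)
  m <- ion_mobility(dev, 5.1628)
  expect_equal(m$mobility_K, m$mobility_K0)  # standard conditions
  expect_equal(m$mobility_K,
               drift_velocity(9.8, 5.1628) / 500)
  dev2 <- device_config()  # 758.5 Torr, 299.15 K
  m2 <- ion_mobility(dev2, 5.1628)
  expect_lt(m2$mobility_K0, m2$mobility_K)
})

test_that("device config validates physics and positivity", {
  expect_s3_class(device_config(), "device_config")
  expect_error(device_config(drift_length_cm = -1), "drift_length_cm")
  # 500 V/cm x 9.8 cm = 4.9 kV is within 10% of 5 kV; 6 kV is not
  expect_error(device_config(drift_voltage_kV = 6), "inconsistent")
})

test_that("spectrum constructor enforces its invariants", {
  M <- matrix(0, 3, 4)
  expect_s3_class(ims_spectrum(1:4, 1:3, M), "ims_spectrum")
  expect_error(ims_spectrum(c(1, 1, 2, 3), 1:3, M), "strictly increasing")
  expect_error(ims_spectrum(1:4, c(3, 2, 1), M), "strictly increasing")
  expect_error(ims_spectrum(1:4, 1:3, matrix(NA_real_, 3, 4)), "finite")
  expect_error(ims_spectrum(1:3, 1:3, M), "matrix")
  expect_error(ims_spectrum(numeric(), numeric(),
                            matrix(0, 0, 0)), "non-empty")
})

test_that("spectrum CSV round trip preserves grid and intensities", {
  g <- list(drift_axis_ms = seq(4.8, 5.0, by = 0.01),
            retention_axis_s = seq(10, 20, by = 2))
  set.seed(4)
  M <- matrix(stats::rnorm(length(g$retention_axis_s) *
                             length(g$drift_axis_ms)),
              nrow = length(g$retention_axis_s))
  sp <- ims_spectrum(g$drift_axis_ms, g$retention_axis_s, M)
  f <- withr::local_tempfile(fileext = ".csv")
  write_spectrum_csv(sp, f)
  sp2 <- read_spectrum_csv(f)
  expect_equal(sp2$drift_axis_ms, sp$drift_axis_ms)
  expect_equal(sp2$retention_axis_s, sp$retention_axis_s)
  expect_equal(sp2$intensity, sp$intensity, tolerance = 1e-12)
})

test_that("default grid is RIP-anchored and covers the required window", {
  for (step in c(0.001, 0.002, 0.004, 0.01)) {
    g <- default_grid(step, 1)
    expect_true(any(abs(g$drift_axis_ms - 4.889) < 1e-12))
    expect_lte(min(g$drift_axis_ms), 4)
    expect_gte(max(g$drift_axis_ms), 7)
  }
  g <- default_grid(0.01, 7)
  expect_gte(max(g$retention_axis_s), 300)
})

test_that("packaged library has the published structure", {
  s <- library_summary(lib_fix)
  expect_identical(s$n_entries, 31L)
  expect_identical(s$n_groups, 20L)
  expect_identical(s$n_named, 23L)
  expect_identical(s$n_distinct_compounds, 13L)
  expect_identical(s$n_unidentified, 8L)
  expect_true(all(lib_fix$relative_drift_time > 1.012 - 1e-9 &
                    lib_fix$relative_drift_time < 1.333 + 1e-9))
  # forms only ever monomer/dimer/trimer; retention sorted as printed
  expect_true(!is.unsorted(lib_fix$retention_time_s))
})

test_that("library uniqueness holds where the matcher needs it", {
  # the named (matching) subset is collision-free at default tolerances
  expect_true(check_library_unique(named_fix))
  # no two entries of the full table share both coordinates exactly
  key <- paste(lib_fix$retention_time_s, lib_fix$relative_drift_time)
  expect_identical(anyDuplicated(key), 0L)
  # the full table is NOT collision-free at the matching tolerances: two
  # N.I. signals sit within tolerance of the acetic acid dimer and the
  # acetone trimer respectively, which is exactly why matching is
  # restricted to named entries
  coll <- library_collisions(lib_fix)
  expect_identical(nrow(coll), 2L)
  expect_setequal(lib_fix$retention_time_s[c(coll$i, coll$j)],
                  c(90, 93, 118, 119))
  # every collision pairs one named with one N.I. entry
  expect_true(all(xor(lib_fix$compound_name[coll$i] == "N.I.",
                      lib_fix$compound_name[coll$j] == "N.I.")))
})

test_that("library constructor validates entries", {
  bad <- as.data.frame(lib_fix)
  bad$group_id[1] <- 21L
  expect_error(reference_library(bad), "group_id")
  bad <- as.data.frame(lib_fix)
  bad$relative_drift_time[1] <- 0.9
  expect_error(reference_library(bad), "relative_drift_time")
  bad <- as.data.frame(lib_fix)
  bad$form[1] <- "tetramer"
  expect_error(reference_library(bad), "form")
  expect_error(reference_library(lib_fix[, 1:3]), "missing library columns")
})

test_that("absolute drift times reconstruct from relative ones", {
  dts <- library_drift_times(lib_fix)
  expect_equal(dts, lib_fix$relative_drift_time * 4.889)
  # round trip through relative_drift_time is exact
  expect_equal(relative_drift_time(dts, 4.889),
               lib_fix$relative_drift_time, tolerance = 1e-12)
  # ethanol monomer
  expect_equal(dts[1], 5.162784, tolerance = 1e-9)
})

test_that("propanoic acid CAS transcription is preserved and annotated", {
  pa <- lib_fix[lib_fix$compound_name == "Propanoic Acid", ]
  expect_true(all(pa$cas_number == "123-38-6"))
  expect_true(all(pa$cas_annotation == "printed_as_is"))
})

test_that("library TSV round trips through its reader", {
  f <- withr::local_tempfile(fileext = ".tsv")
  data.table::fwrite(as.data.frame(lib_fix), f, sep = "\t")
  lib2 <- read_reference_library(f)
  expect_equal(as.data.frame(lib2), as.data.frame(lib_fix))
})
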