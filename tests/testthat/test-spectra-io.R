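test_that("MGF blocks parse with field conversion and clear errors", {
  path <- withr::local_tempfile(fileext = ".mgf")
  writeLines(c("BEGIN IONS", "TITLE=feat_1", "PEPMASS=463.2854",
               "RTINSECONDS=1012.2", "CHARGE=1-",
               "419.2956 1000.0", "403.2643 900.0", "301.2172 500.0",
               "END IONS"), path)
  sp <- read_mgf(path)
  expect_length(sp, 1)
  expect_equal(sp[[1]]$feature_id, "feat_1")
  expect_equal(sp[[1]]$precursor_mz, 463.2854)
  expect_equal(sp[[1]]$rt, 1012.2 / 60)   # seconds converted to minutes
  expect_equal(nrow(sp[[1]]$peaks), 3)
  expect_equal(sp[[1]]$peaks[, "mz"], c(301.2172, 403.2643, 419.2956))

  bad <- withr::local_tempfile(fileext = ".mgf")
  writeLines(c("BEGIN IONS", "TITLE=x", "100 1", "END IONS"), bad)
  expect_error(read_mgf(bad), "PEPMASS")
  writeLines(c("BEGIN IONS", "TITLE=x", "PEPMASS=100"), bad)
  expect_error(read_mgf(bad), "unbalanced")
})

test_that("MGF serialization is a stable roundtrip on a synthetic corpus", {
  counts <- c(SC_ACID = 38L, CORE_RAA = 29L, GLYCOSIDE = 24L,
              NITROGENOUS = 19L, CORE_3OH_4COOH = 38L,
              ACETOXY_MOD = 29L, LYSO_PI = 23L)
  corp <- generate_corpus(corpus_config(n_features_per_class = counts,
                                        rng_seed = 1))
  expect_length(corp$spectra, 200)
  ids <- vapply(corp$spectra, function(s) s$feature_id, character(1))
  expect_false(anyDuplicated(ids) > 0)

  p1 <- withr::local_tempfile(fileext = ".mgf")
  p2 <- withr::local_tempfile(fileext = ".mgf")
  write_mgf(corp$spectra, p1)
  back <- read_mgf(p1)
  expect_length(back, 200)
  # a second write of what was read back is byte-identical: the format is
  # the identity at serialization precision
  write_mgf(back, p2)
  expect_identical(readLines(p1), readLines(p2))
  # and values survive at that precision
  expect_equal(back[[7]]$precursor_mz, corp$spectra[[7]]$precursor_mz,
               tolerance = 1e-4)
  expect_equal(back[[7]]$peaks[, "mz"], corp$spectra[[7]]$peaks[, "mz"],
               tolerance = 1e-4, ignore_attr = TRUE)
})

test_that("feature-table CSV parsing enforces shape and non-negativity", {
  t3 <- table3_fixture()
  expect_equal(dim(t3), c(16L, 9L))
  path <- withr::local_tempfile(fileext = ".csv")
  write_feature_table(t3, path)
  back <- read_feature_table(path)
  expect_equal(back$intensities, t3$intensities)

  writeLines("feature_id,mz,rt,s1,s2", path)
  empty <- read_feature_table(path)
  expect_equal(nrow(empty$intensities), 0)
  expect_equal(empty$samples, c("s1", "s2"))

  writeLines(c("feature_id,mz,rt,s1", "f1,300.1,5.0,-5"), path)
  expect_error(read_feature_table(path), "negative")
})

test_that("library matching identifies by RT + exact mass + spectral match", {
  lib_path <- withr::local_tempfile(fileext = ".mgf")
  raa <- raa_like_spectrum("std_RAA", 463.2854, 16.87)
  z17 <- raa_like_spectrum("std_17Z", 463.2854, 17.27)
  make_library_mgf(list(raa, z17), c("RAA", "17Z-RAA"),
                   c("C30H40O4", "C30H40O4"), lib_path)
  lib <- read_spectral_library(lib_path)
  expect_length(lib, 2)

  q1 <- raa_like_spectrum("q1", 463.2857, 16.87)
  hits <- match_library(list(q1), lib)
  expect_equal(hits$library_name, "RAA")
  expect_lt(abs(hits$ppm_error), 10)

  # +5 min retention shift breaks the match
  q_shift <- raa_like_spectrum("q2", 463.2857, 16.87 + 5)
  expect_equal(nrow(match_library(list(q_shift), lib)), 0)

  # isobaric isomer pair separated only by the RT window
  q_raa <- raa_like_spectrum("fA", 463.2857, 16.87)
  q_17z <- raa_like_spectrum("fB", 463.2858, 17.27)
  hits2 <- match_library(list(q_raa, q_17z), lib, rt_tol = 0.2)
  expect_equal(hits2$library_name[hits2$feature_id == "fA"], "RAA")
  expect_equal(hits2$library_name[hits2$feature_id == "fB"], "17Z-RAA")
})

test_that("shrinking any matching tolerance never adds identifications", {
  lib_path <- withr::local_tempfile(fileext = ".mgf")
  raa <- raa_like_spectrum("std_RAA", 463.2854, 16.87)
  z17 <- raa_like_spectrum("std_17Z", 463.2854, 17.27)
  make_library_mgf(list(raa, z17), c("RAA", "17Z-RAA"),
                   c("C30H40O4", "C30H40O4"), lib_path)
  lib <- read_spectral_library(lib_path)
  queries <- list(raa_like_spectrum("fA", 463.2857, 16.87),
                  raa_like_spectrum("fB", 463.2859, 17.10))

  wide <- match_library(queries, lib, ppm_tol = 10, rt_tol = 1e6,
                        cosine_min = 1e-9)
  # with RT unconstrained and no cosine floor this is precursor matching:
  # both isobaric standards match both features
  expect_equal(nrow(wide), 4)
  key <- function(df) paste(df$feature_id, df$library_name)
  configs <- list(list(ppm_tol = 1, rt_tol = 1e6, cosine_min = 1e-9),
                  list(ppm_tol = 10, rt_tol = 0.2, cosine_min = 1e-9),
                  list(ppm_tol = 10, rt_tol = 1e6, cosine_min = 0.9))
  for (cf in configs) {
    narrow <- match_library(queries, lib, ppm_tol = cf$ppm_tol,
                            rt_tol = cf$rt_tol, cosine_min = cf$cosine_min)
    expect_true(all(key(narrow) %in% key(wide)))
    expect_lte(nrow(narrow), nrow(wide))
  }
})
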