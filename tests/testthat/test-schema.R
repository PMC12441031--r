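test_that("the default schema has 22 uniquely named features in fixed order", {
  sc <- mangrove_schema()
  expect_s3_class(sc, "feature_schema")
  expect_identical(sc$L, 22L)
  expect_false(anyDuplicated(sc$feature_names) > 0)
  # bands first, topographic factor last: the window slides in this order
  expect_identical(sc$feature_names[1], "coastal")
  expect_identical(sc$feature_names[22], "TOF")
  expect_error(feature_schema(c("a", "a", "b")), "unique")
})

test_that("schema files define custom feature inventories", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines("feature_names: [b1, b2, b3, NDVI, elev]", path)
  sc <- read_feature_schema(path)
  expect_identical(sc$L, 5L)
  expect_identical(sc$feature_names[4], "NDVI")
  writeLines("other: 1", path)
  expect_error(read_feature_schema(path), "feature_names")
})

test_that("CSV round trip preserves rows, columns and values", {
  tbl <- tiny_table(n = 7, seed = 3)
  path <- withr::local_tempfile(fileext = ".csv")
  write_feature_table(tbl, path)
  back <- read_feature_table(path)
  expect_identical(nrow(back), 7L)
  expect_true(all(mangrove_schema()$feature_names %in% names(back)))
  expect_equal(feature_matrix(back), feature_matrix(tbl), tolerance = 1e-12)
  expect_equal(back$biomass, tbl$biomass, tolerance = 1e-12)
})

test_that("a table without a biomass column reads cleanly", {
  tbl <- tiny_table(n = 4)
  tbl$biomass <- NULL
  path <- withr::local_tempfile(fileext = ".csv")
  write_feature_table(tbl, path)
  back <- read_feature_table(path)
  expect_false("biomass" %in% names(back))
  expect_identical(nrow(back), 4L)
})

test_that("a missing feature column is reported by name", {
  tbl <- tiny_table(n = 3)
  tbl$NDVI <- NULL
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(tbl, path)
  expect_error(read_feature_table(path), "NDVI")
})

test_that("standardization gives zero-mean unit-sd columns and stores stats", {
  tbl <- tiny_table(n = 25, seed = 9)
  std <- standardize_features(tbl)
  x <- feature_matrix(std)
  expect_true(all(abs(colMeans(x)) < 1e-9))
  expect_true(all(abs(apply(x, 2, sd) - 1) < 1e-9))
  expect_s3_class(feature_stats(std), "tbl_df")
  # target is untouched
  expect_identical(std$biomass, tbl$biomass)
})

test_that("a constant feature standardizes to zeros rather than NaN", {
  tbl <- tiny_table(n = 10)
  tbl$TOF <- 7
  std <- standardize_features(tbl)
  expect_identical(std$TOF, rep(0, 10))
  expect_identical(feature_stats(std)$sd[22], 1)
})

test_that("standardization is an affine bijection per feature", {
  tbl <- tiny_table(n = 15, seed = 5)
  std <- standardize_features(tbl)
  back <- unstandardize_features(std)
  expect_equal(feature_matrix(back), feature_matrix(tbl), tolerance = 1e-9)
})

test_that("single-row tables cannot be standardized without supplied stats", {
  tbl <- tiny_table(n = 1)
  expect_error(standardize_features(tbl), "single row")
  stats <- feature_stats(standardize_features(tiny_table(n = 10)))
  expect_silent(standardize_features(tbl, stats = stats))
})

test_that("train-fitted stats apply unchanged to test rows", {
  tbl <- tiny_table(n = 20, seed = 11)
  tr <- tbl[1:14, ]
  te <- tbl[15:20, ]
  stats <- feature_stats(standardize_features(tr))
  ste <- standardize_features(te, stats = stats)
  manual <- (te$NDVI - stats$mean[stats$feature == "NDVI"]) /
    stats$sd[stats$feature == "NDVI"]
  expect_equal(ste$NDVI, manual, tolerance = 1e-12)
})

test_that("allometric biomass follows the printed power law", {
  expect_identical(biomass_from_diameter(0), 0)
  expect_equal(biomass_from_diameter(1), 3.614, tolerance = 1e-12)
  # frozen from direct evaluation of 3.614 * 10^1.446
  expect_equal(biomass_from_diameter(10), 100.92253, tolerance = 1e-6)
  expect_error(biomass_from_diameter(-1), "non-negative")
})

test_that("allometric biomass is strictly monotone in diameter", {
  set.seed(77)
  for (i in 1:200) {
    d <- sort(runif(2, 0.01, 30))
    expect_lt(biomass_from_diameter(d[1]), biomass_from_diameter(d[2]))
  }
})
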