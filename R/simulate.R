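#' Simulate a synthetic mangrove feature table
#'
#' Generates a feature table with the statistical structure the estimator
#' assumes, so the whole pipeline can be exercised without field data.
#' Each plot gets a latent canopy density `c ~ Uniform(0, 1)`; Landsat-like
#' band reflectances are affine in `c` plus Gaussian noise, with the red
#' and short-wave bands decreasing in canopy density and near-infrared
#' increasing — the spectral contrast that vegetation indices exploit. The
#' six vegetation indices are then computed from the synthetic bands with
#' their standard formulas (NDVI as the normalized difference of NIR and
#' red, and so on), texture statistics are smooth nonlinear transforms of
#' `c` plus noise, and the topographic factor is weakly correlated noise.
#' A latent stem diameter affine in `c` is pushed through
#' [biomass_from_diameter()] and rescaled into `biomass_range`, with
#' Gaussian observation noise, to give the target.
#'
#' @param n Number of plots to simulate.
#' @param seed Integer seed; the same seed reproduces the table exactly.
#' @param latent_noise Feature-level noise scale: each band's noise
#'   standard deviation is `latent_noise` times the magnitude of its
#'   canopy slope (default 0.3).
#' @param biomass_noise Standard deviation of the target observation
#'   noise, in biomass units (default 0.5).
#' @param biomass_range Length-2 numeric: the span the noiseless biomass
#'   is mapped onto (default `c(10, 29)`, the scale typical of Kandelia
#'   plot biomass).
#' @param coefficient,exponent Allometric parameters passed to
#'   [biomass_from_diameter()].
#' @param schema Must be the default 22-feature [mangrove_schema()].
#' @return A tibble with `sample_id`, the 22 feature columns and
#'   `biomass`. Latent canopy density and diameter are attached as the
#'   `"latent"` attribute for diagnostics.
#' @export
#' @examples
#' tbl <- simulate_feature_table(n = 58, seed = 1)
#' range(tbl$biomass)
simulate_feature_table <- function(n, seed = 1L,
                                   latent_noise = 0.3,
                                   biomass_noise = 0.5,
                                   biomass_range = c(10, 29),
                                   coefficient = 3.614, exponent = 1.446,
                                   schema = mangrove_schema()) {
  stopifnot(n >= 1, latent_noise >= 0, biomass_noise >= 0,
            length(biomass_range) == 2L, diff(biomass_range) > 0,
            all(biomass_range > 0))
  if (!identical(schema$feature_names, mangrove_schema()$feature_names)) {
    stop("the simulator emulates the default 22-feature mangrove schema",
         call. = FALSE)
  }
  with_seed(seed, {
    cdens <- stats::runif(n)
    band <- function(intercept, slope) {
      pmax(intercept + slope * cdens +
             stats::rnorm(n, 0, latent_noise * abs(slope)), 0.01)
    }
    coastal <- band(0.10, -0.03)
    blue    <- band(0.09, -0.03)
    green   <- band(0.11, -0.02)
    red     <- band(0.10, -0.06)
    nir     <- band(0.15,  0.35)
    swir1   <- band(0.20, -0.10)
    swir2   <- band(0.15, -0.08)

    # standard index formulas on the synthetic bands
    NDVI  <- (nir - red) / (nir + red)
    RVI   <- nir / red
    DVI   <- nir - red
    SAVI  <- 1.5 * (nir - red) / (nir + red + 0.5)
    EVI   <- 2.5 * (nir - red) / (nir + 6 * red - 7.5 * blue + 1)
    GNDVI <- (nir - green) / (nir + green)

    tex <- function(x, scale) x + stats::rnorm(n, 0, latent_noise * scale)
    VAR <- tex(1.5 * (cdens - 0.5)^2 + 0.3, 0.15)
    HOM <- tex(1 / (1 + 2 * cdens), 0.10)
    CON <- tex(0.5 + 1.2 * cdens^1.5, 0.20)
    HET <- tex(sqrt(cdens + 0.05), 0.12)
    ENT <- tex(log1p(3 * cdens), 0.15)
    ASM <- tex(exp(-2 * cdens), 0.10)
    COR <- tex(0.3 + 0.5 * cdens^2, 0.10)
    MEA <- tex(0.2 + 0.6 * cdens, 0.10)
    TOF <- 5 + 0.5 * cdens + stats::rnorm(n, 0, 2)

    # latent diameter and allometric biomass, rescaled to the target span
    D <- 2 + 8 * cdens
    y_raw <- biomass_from_diameter(D, coefficient, exponent)
    y_lo <- biomass_from_diameter(2, coefficient, exponent)
    y_hi <- biomass_from_diameter(10, coefficient, exponent)
    y <- biomass_range[1] +
      (y_raw - y_lo) / (y_hi - y_lo) * diff(biomass_range) +
      stats::rnorm(n, 0, biomass_noise)
    y <- pmax(y, 0.05 * biomass_range[1])

    out <- tibble::tibble(
      sample_id = paste0("plot", seq_len(n)),
      coastal = coastal, blue = blue, green = green, red = red,
      nir = nir, swir1 = swir1, swir2 = swir2,
      NDVI = NDVI, RVI = RVI, DVI = DVI, SAVI = SAVI, EVI = EVI,
      GNDVI = GNDVI,
      VAR = VAR, HOM = HOM, CON = CON, HET = HET, ENT = ENT, ASM = ASM,
      COR = COR, MEA = MEA, TOF = TOF,
      biomass = y
    )
    attr(out, "latent") <- tibble::tibble(
      sample_id = out$sample_id, canopy = cdens, diameter = D
    )
    validate_feature_table(out, schema)
    out
  })
}

#' Simulate a table and split it 70/30
#'
#' Convenience wrapper: simulates one table with
#' [simulate_feature_table()] and applies the holdout split of
#' [make_split()] (training share `floor(0.7 n)`).
#'
#' @inheritParams simulate_feature_table
#' @param ... Passed on to [simulate_feature_table()].
#' @return A list with tibbles `train` and `test`.
#' @export
#' @examples
#' sp <- simulate_split(n = 58, seed = 1)
#' nrow(sp$train); nrow(sp$test) # 40 and 18
simulate_split <- function(n, seed = 1L, ...) {
  stopifnot(n >= 10)
  tbl <- simulate_feature_table(n = n, seed = seed, ...)
  plan <- make_split(n, mode = "holdout", seed = seed)
  list(train = tbl[plan$folds[[1]]$train, ],
       test  = tbl[plan$folds[[1]]$test, ])
}
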