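#' Simulate site coordinates, climate, and must chemistry
#'
#' Places region centers in a Willamette-Valley-like bounding box, scatters
#' sites around their region center, and draws total precipitation and
#' growing degree days per site and vintage from a Gaussian process over the
#' great-circle distances between sites with exponential correlation of range
#' `env_spatial_range` km.  Geographically closer sites therefore experience
#' more similar weather by construction, which is what the Mantel test
#' between geographic and climate distances detects.  Must chemistry (pH,
#' titratable acidity, malic acid, NOPA, NH3) is drawn with site-by-vintage
#' means around field-typical values.
#'
#' @param cfg a [scenario_config()].
#' @param coordinates optional data frame with columns `site`,
#'   `latitude_deg`, `longitude_deg` to use instead of sampled coordinates.
#' @return list with `sites` (site, region, coordinates) and `covariates`
#'   (site x vintage climate and chemistry means).
#' @export
generate_environment <- function(cfg, coordinates = NULL) {
  validate_scenario_config(cfg)
  des <- study_design(cfg)
  set.seed(.substream(cfg$seed, "environment"))
  sites <- des$sites
  n_s <- nrow(sites)
  if (is.null(coordinates)) {
    regions <- unique(sites$region)
    rc_lat <- runif(length(regions), 43.6, 45.8)
    rc_lon <- runif(length(regions), -123.8, -122.2)
    names(rc_lat) <- names(rc_lon) <- regions
    sites$latitude_deg <- rc_lat[sites$region] + rnorm(n_s, 0, 0.12)
    sites$longitude_deg <- rc_lon[sites$region] + rnorm(n_s, 0, 0.12)
  } else {
    sites <- merge(sites, coordinates, by = "site", sort = FALSE)
  }
  if (n_s < 3)
    .warnf("fewer than 3 sites: spatial correlation check skipped")
  constant_field <- is.infinite(cfg$env_spatial_range)
  if (!constant_field) {
    geo <- haversine_matrix(sites[, c("site", "latitude_deg", "longitude_deg")])
    # squared-exponential: regional climate varies smoothly in space
    K <- exp(-(geo$values / cfg$env_spatial_range)^2) + diag(1e-8, n_s)
  }
  draw_field <- function() {
    if (constant_field) rep(rnorm(1), n_s)
    else as.numeric(mvrnorm(1, rep(0, n_s), K))
  }
  # deterministic orographic gradients (precipitation falls off along the
  # west-east axis, heat accumulation follows latitude) plus a persistent
  # site climatology and smaller vintage-specific anomalies
  ztrend <- function(z) {
    s <- sd(z)
    if (is.na(s) || s == 0 || constant_field) rep(0, n_s) else (z - mean(z)) / s
  }
  trend_p <- ztrend(sites$longitude_deg)
  trend_g <- ztrend(sites$latitude_deg)
  w_tr <- if (constant_field) 0 else sqrt(0.6)
  base_p <- draw_field()
  base_g <- draw_field()
  cov_rows <- list()
  for (v in cfg$vintages) {
    g1 <- w_tr * trend_p +
      sqrt(1 - w_tr^2) * (sqrt(0.8) * base_p + sqrt(0.2) * draw_field())
    g2 <- w_tr * trend_g +
      sqrt(1 - w_tr^2) * (sqrt(0.8) * base_g + sqrt(0.2) * draw_field())
    cov_rows[[v]] <- data.frame(
      site = sites$site, vintage = v,
      precipitation_mm = 700 + 180 * g1,
      gdd = 1500 + 120 * g2,
      stringsAsFactors = FALSE
    )
  }
  covariates <- do.call(rbind, cov_rows)
  rownames(covariates) <- NULL
  set.seed(.substream(cfg$seed, "chemistry"))
  n_sv <- nrow(covariates)
  covariates$pH <- rnorm(n_sv, 3.35, 0.08)
  covariates$titratable_acidity <- rnorm(n_sv, 6.5, 0.6)
  covariates$malic_acid <- pmax(0.2, rnorm(n_sv, 2.2, 0.5))
  covariates$NOPA <- pmax(10, rnorm(n_sv, 120, 25))
  covariates$NH3 <- pmax(5, rnorm(n_sv, 55, 12))
  list(sites = sites, covariates = covariates)
}
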