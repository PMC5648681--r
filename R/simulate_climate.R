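#' Specification for a monthly climate-series simulation
#'
#' Monthly values are a fixed 12-month seasonal baseline plus i.i.d.
#' Gaussian noise, emulating the interpolated monthly temperature and
#' rainfall series used for seasonality analysis (a 15-year monthly window
#' by default).
#'
#' @param n_years number of years (>= 1).
#' @param monthly_profile named list of 12-value baseline vectors, one per
#'   variable (default: a sinusoidal `temperature` profile in deg C and a
#'   wet/dry-season `precipitation` profile in mm).
#' @param noise_sd named numeric vector of noise standard deviations, one
#'   per variable (variable units).
#' @param site site label.
#' @param seed integer seed.
#' @return A list of class `climate_sim_spec`.
#' @export
climate_sim_spec <- function(n_years = 15L,
                             monthly_profile = NULL,
                             noise_sd = NULL,
                             site = "Site1", seed = 1L) {
  .assert_scalar_count(n_years, "n_years")
  if (is.null(monthly_profile)) {
    monthly_profile <- list(
      temperature = 23 + 4 * sin(2 * pi * (seq_len(12) - 4) / 12),
      precipitation = pmax(0, 150 + 140 * cos(2 * pi * (seq_len(12) - 1) / 12))
    )
  }
  if (!is.list(monthly_profile) || is.null(names(monthly_profile)))
    stop("'monthly_profile' must be a named list of 12-value vectors")
  if (any(lengths(monthly_profile) != 12L))
    stop("every monthly profile must have length 12")
  if (is.null(noise_sd))
    noise_sd <- setNames(c(0.8, 40)[seq_along(monthly_profile)],
                         names(monthly_profile))
  if (is.null(names(noise_sd)) ||
      !all(names(monthly_profile) %in% names(noise_sd)))
    stop("'noise_sd' must be named for every profile variable")
  if (any(noise_sd < 0)) stop("'noise_sd' must be >= 0")
  structure(list(n_years = as.integer(n_years),
                 monthly_profile = monthly_profile,
                 noise_sd = noise_sd, site = site,
                 seed = as.integer(seed)),
            class = "climate_sim_spec")
}

#' Simulate a monthly climate series
#'
#' @param spec a [climate_sim_spec].
#' @return A data.frame of class `climate_series` with columns `site`,
#'   `year`, `month` and one column per variable; `12 * n_years` rows in
#'   chronological order.  The spec used is attached as attribute
#'   `"sim_spec"`.
#' @export
simulate_climate <- function(spec) {
  stopifnot(inherits(spec, "climate_sim_spec"))
  set.seed(spec$seed)
  ny <- spec$n_years
  out <- data.frame(site = spec$site,
                    year = rep(seq_len(ny), each = 12L),
                    month = rep(1:12, ny))
  for (v in names(spec$monthly_profile)) {
    base <- rep(spec$monthly_profile[[v]], ny)
    out[[v]] <- base + rnorm(12L * ny, 0, spec$noise_sd[v])
  }
  class(out) <- c("climate_series", "data.frame")
  attr(out, "sim_spec") <- spec
  out
}
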