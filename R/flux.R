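#' Porewater profile for one sediment core
#'
#' Depth-indexed porewater analyte concentrations for a single core, with the
#' bay/season/site labels the comparison stages group by. Depths are positive
#' cm below the seafloor (slice midpoints) and must be strictly increasing.
#'
#' @param site Site label.
#' @param bay Bay label, typically `"heated"` or `"control"`.
#' @param season Season label, typically `"summer"` or `"winter"`.
#' @param depths Numeric vector of slice-midpoint depths, cm below seafloor,
#'   strictly increasing and positive.
#' @param analytes Named list of concentration vectors (mM), one per analyte
#'   (e.g. `sulfate`, `methane`), each the same length as `depths`.
#' @param porosity Sediment porosity, fraction in (0, 1).
#' @return An object of class `porewater_profile`.
#' @export
porewater_profile <- function(site, bay, season, depths, analytes,
                              porosity = 0.8) {
  if (length(depths) == 0L) stop("`depths` must be non-empty", call. = FALSE)
  if (any(!is.finite(depths)) || any(depths <= 0))
    stop("`depths` must be finite and positive (cm below seafloor)", call. = FALSE)
  if (is.unsorted(depths, strictly = TRUE))
    stop("`depths` must be strictly increasing", call. = FALSE)
  if (!is.list(analytes) || is.null(names(analytes)) || any(names(analytes) == ""))
    stop("`analytes` must be a named list of concentration vectors", call. = FALSE)
  for (nm in names(analytes)) {
    v <- analytes[[nm]]
    if (length(v) != length(depths))
      stop(sprintf("analyte '%s' has %d values for %d depths", nm,
                   length(v), length(depths)), call. = FALSE)
    if (any(!is.finite(v)) || any(v < 0))
      stop(sprintf("analyte '%s' has negative or non-finite concentrations", nm),
           call. = FALSE)
  }
  check_porosity(porosity)
  structure(list(site = as.character(site), bay = as.character(bay),
                 season = as.character(season), depths = as.numeric(depths),
                 analytes = lapply(analytes, as.numeric), porosity = porosity),
            class = "porewater_profile")
}

#' @export
print.porewater_profile <- function(x, ...) {
  cat(sprintf("<porewater_profile> site %s, %s bay, %s: %d depths (%g-%g cm), analytes: %s\n",
              x$site, x$bay, x$season, length(x$depths), min(x$depths),
              max(x$depths), paste(names(x$analytes), collapse = ", ")))
  invisible(x)
}

#' Fit a linear sulfate gradient to one core
#'
#' Ordinary least squares of sulfate concentration on depth over the window
#' running from the depth of maximum sulfate concentration down to the last
#' strictly positive value. Starting at the concentration maximum (rather than
#' always at the sediment surface) keeps a winter subsurface sulfate peak from
#' biasing the gradient: above the peak the profile violates the steady-state
#' linear-diffusion assumption.
#'
#' @param profile A [porewater_profile()] with a `sulfate` analyte.
#' @return An object of class `sulfate_fit` with elements `slope`
#'   (mM cm^-1), `intercept` (mM at 0 cm), `r_squared`, `n_points` and
#'   `depth_window` (cm). `r_squared` is `NA` for a zero-variance (constant)
#'   profile.
#' @export
fit_sulfate_gradient <- function(profile) {
  stopifnot(inherits(profile, "porewater_profile"))
  s <- profile$analytes$sulfate
  if (is.null(s)) stop("profile has no sulfate series", call. = FALSE)
  if (all(s <= 0)) stop("all sulfate concentrations are zero", call. = FALSE)
  z <- profile$depths
  idx <- which.max(s):max(which(s > 0))
  if (length(idx) < 3L)
    stop(sprintf("only %d usable sulfate points in the regression window (need >= 3)",
                 length(idx)), call. = FALSE)
  zz <- z[idx]; ss <- s[idx]
  fit <- stats::lm(ss ~ zz)
  ss_tot <- sum((ss - mean(ss))^2)
  r2 <- if (ss_tot > 0) 1 - sum(stats::residuals(fit)^2) / ss_tot
        else NA_real_  # constant response
  structure(list(slope = unname(stats::coef(fit)[2L]),
                 intercept = unname(stats::coef(fit)[1L]),
                 r_squared = r2, n_points = length(idx),
                 depth_window = range(zz)),
            class = "sulfate_fit")
}

#' Depth of no sulfate (DNS)
#'
#' The depth below the seafloor at which the fitted linear sulfate profile
#' reaches zero — the x-intercept `-intercept/slope` of the regression line.
#' Only defined when sulfate decreases with depth (negative slope).
#'
#' @param fit A `sulfate_fit` from [fit_sulfate_gradient()].
#' @return DNS in cm below seafloor.
#' @export
depth_of_no_sulfate <- function(fit) {
  stopifnot(inherits(fit, "sulfate_fit"))
  if (!is.finite(fit$slope) || fit$slope >= 0)
    stop("sulfate does not decrease with depth: depth of no sulfate is undefined",
         call. = FALSE)
  dns <- -fit$intercept / fit$slope
  if (dns <= 0)
    stop("non-positive depth of no sulfate (negative surface intercept)",
         call. = FALSE)
  dns
}

#' Free-solution sulfate diffusion coefficient
#'
#' Linear-in-temperature parameterisation `D0 = (m0 + m1 * T) * 1e-6`
#' cm^2 s^-1, with default coefficients from standard seawater diffusion
#' tabulations (m0 = 4.88, m1 = 0.232).
#'
#' @param temperature_c In-situ temperature, degrees C.
#' @param m0,m1 Parameterisation coefficients (units of 1e-6 cm^2 s^-1 and
#'   1e-6 cm^2 s^-1 per degree C).
#' @return D0 in cm^2 s^-1.
#' @export
sulfate_diffusion_coefficient <- function(temperature_c, m0 = 4.88, m1 = 0.232) {
  stop_if_not_scalar_number(temperature_c, "temperature_c")
  if (temperature_c < -2 || temperature_c > 40)
    warning(sprintf("temperature %g C outside the calibrated range [-2, 40]",
                    temperature_c), call. = FALSE)
  (m0 + m1 * temperature_c) * 1e-6
}

#' Sediment diffusivity from the logarithmic tortuosity correction
#'
#' `Ds = D0 / (1 - ln(phi^2))`, i.e. tortuosity `theta^2 = 1 - ln(phi^2)`.
#' Always smaller than D0 for porosity in (0, 1).
#'
#' @param d0 Free-solution diffusion coefficient, cm^2 s^-1.
#' @param porosity Porosity, fraction in (0, 1).
#' @return Ds in cm^2 s^-1.
#' @export
sediment_diffusivity <- function(d0, porosity) {
  stop_if_not_scalar_number(d0, "d0", positive = TRUE)
  check_porosity(porosity)
  d0 / (1 - log(porosity^2))
}

# (mM cm^-1 -> mmol cm^-4) * (s -> d) * (cm^-2 -> m^-2)
flux_unit_factor <- 1e-3 * 86400 * 1e4

#' Diffusive sulfate flux by Fick's first law
#'
#' `J = -phi * Ds * dC/dx`, converted from cm/s/mM units to
#' mmol m^-2 d^-1. A negative sulfate slope (decreasing with depth) gives a
#' positive J: sulfate diffusing downward into the sediment. In an
#' AOM-dominated sulfate reduction zone this magnitude also serves as a proxy
#' for the equivalent upward methane flux. The porosity factor is the standard
#' diagenetic convention; set `include_porosity_factor = FALSE` for the bare
#' `J = -Ds * dC/dx` form.
#'
#' @param fit A `sulfate_fit`, or a bare numeric slope in mM cm^-1.
#' @param ds Sediment diffusivity, cm^2 s^-1.
#' @param porosity Porosity, fraction in (0, 1).
#' @param include_porosity_factor Multiply by porosity (default `TRUE`).
#' @return Flux J in mmol m^-2 d^-1 (positive downward).
#' @examples
#' diffusive_flux(-1, ds = 5e-6, porosity = 0.8)  # 3.456
#' @export
diffusive_flux <- function(fit, ds, porosity, include_porosity_factor = TRUE) {
  slope <- if (inherits(fit, "sulfate_fit")) fit$slope else fit
  stop_if_not_scalar_number(slope, "slope")
  stop_if_not_scalar_number(ds, "ds", positive = TRUE)
  check_porosity(porosity)
  phi <- if (include_porosity_factor) porosity else 1
  -phi * ds * slope * flux_unit_factor
}

#' Linearity-based core exclusion rule
#'
#' Cores whose sulfate profile is clearly non-linear do not satisfy the
#' steady-state diffusion assumption behind the flux calculation and are
#' excluded. Linearity is judged by the regression R^2 against a threshold
#' (default 0.90).
#'
#' @param fit A `sulfate_fit`.
#' @param r2_threshold Minimum R^2 for inclusion.
#' @return A list with `included` (logical) and `exclusion_reason`
#'   (`NA_character_` when included).
#' @export
apply_linearity_exclusion <- function(fit, r2_threshold = 0.90) {
  stopifnot(inherits(fit, "sulfate_fit"))
  stop_if_not_scalar_number(r2_threshold, "r2_threshold")
  if (is.na(fit$r_squared) || fit$r_squared < r2_threshold) {
    list(included = FALSE, exclusion_reason = "non-linear sulfate profile")
  } else {
    list(included = TRUE, exclusion_reason = NA_character_)
  }
}

#' Full flux calculation for one core
#'
#' Chains [fit_sulfate_gradient()], [depth_of_no_sulfate()],
#' [sulfate_diffusion_coefficient()], [sediment_diffusivity()],
#' [diffusive_flux()] and [apply_linearity_exclusion()] for one core. Cores
#' whose sulfate does not decrease with depth get `NA` DNS/flux and are
#' flagged excluded with reason `"no sulfate depletion"`.
#'
#' @param profile A [porewater_profile()].
#' @param temperature_c In-situ temperature used for D0, degrees C (typically
#'   the bay/season mean bottom-water temperature).
#' @param m0,m1 D0 parameterisation, see [sulfate_diffusion_coefficient()].
#' @param r2_threshold Linearity threshold, see [apply_linearity_exclusion()].
#' @param include_porosity_factor See [diffusive_flux()].
#' @return An object of class `flux_result`: site/bay/season labels, the
#'   `sulfate_fit`, `dns` (cm), `d0`, `ds` (cm^2 s^-1), `flux`
#'   (mmol m^-2 d^-1), `included` and `exclusion_reason`.
#' @export
core_flux <- function(profile, temperature_c, m0 = 4.88, m1 = 0.232,
                      r2_threshold = 0.90, include_porosity_factor = TRUE) {
  stopifnot(inherits(profile, "porewater_profile"))
  fit <- tryCatch(fit_sulfate_gradient(profile), error = identity)
  d0 <- sulfate_diffusion_coefficient(temperature_c, m0, m1)
  ds <- sediment_diffusivity(d0, profile$porosity)
  if (inherits(fit, "error")) {
    # e.g. sulfate increasing to the bottom: the max-to-depletion window is
    # degenerate and no gradient can be fitted
    reason <- sprintf("unusable sulfate profile: %s", conditionMessage(fit))
    fit <- structure(list(slope = NA_real_, intercept = NA_real_,
                          r_squared = NA_real_, n_points = NA_integer_,
                          depth_window = c(NA_real_, NA_real_)),
                     class = "sulfate_fit")
    return(structure(list(site = profile$site, bay = profile$bay,
                          season = profile$season, fit = fit, dns = NA_real_,
                          d0 = d0, ds = ds, flux = NA_real_, included = FALSE,
                          exclusion_reason = reason),
                     class = "flux_result"))
  }
  if (is.finite(fit$slope) && fit$slope < 0 && !is.na(fit$r_squared)) {
    dns <- depth_of_no_sulfate(fit)
    flux <- diffusive_flux(fit, ds, profile$porosity, include_porosity_factor)
    excl <- apply_linearity_exclusion(fit, r2_threshold)
  } else {
    dns <- NA_real_
    flux <- NA_real_
    excl <- list(included = FALSE, exclusion_reason = "no sulfate depletion")
  }
  structure(list(site = profile$site, bay = profile$bay, season = profile$season,
                 fit = fit, dns = dns, d0 = d0, ds = ds, flux = flux,
                 included = excl$included,
                 exclusion_reason = excl$exclusion_reason),
            class = "flux_result")
}

#' @export
print.flux_result <- function(x, ...) {
  cat(sprintf("<flux_result> site %s (%s, %s): DNS %.1f cm, J %.3f mmol m-2 d-1, R2 %.3f, %s\n",
              x$site, x$bay, x$season, x$dns, x$flux, x$fit$r_squared,
              if (x$included) "included" else paste("EXCLUDED:", x$exclusion_reason)))
  invisible(x)
}

#' Flux results as a tidy table
#'
#' @param results A list of `flux_result` objects.
#' @return A data.frame with one row per core.
#' @export
flux_results_table <- function(results) {
  stopifnot(length(results) >= 1L,
            all(vapply(results, inherits, logical(1), "flux_result")))
  do.call(rbind, lapply(results, function(r) {
    data.frame(site = r$site, bay = r$bay, season = r$season,
               slope_mM_cm = r$fit$slope, intercept_mM = r$fit$intercept,
               r_squared = r$fit$r_squared, n_points = r$fit$n_points,
               dns_cm = r$dns, d0_cm2_s = r$d0, ds_cm2_s = r$ds,
               flux_mmol_m2_d = r$flux, included = r$included,
               exclusion_reason = r$exclusion_reason,
               stringsAsFactors = FALSE)
  }))
}

#' Mean flux and DNS per bay and season
#'
#' Arithmetic means over included cores only, per (bay, season) group.
#' Groups present in the input but without any included core are reported
#' with `NA` means rather than dropped.
#'
#' @param results A list of `flux_result` objects.
#' @return A data.frame with columns `bay`, `season`, `n_cores`,
#'   `n_included`, `mean_flux_mmol_m2_d`, `mean_dns_cm`.
#' @export
bay_season_flux_summary <- function(results) {
  tab <- flux_results_table(results)
  groups <- unique(tab[, c("bay", "season")])
  out <- lapply(seq_len(nrow(groups)), function(i) {
    g <- tab[tab$bay == groups$bay[i] & tab$season == groups$season[i], ]
    inc <- g[g$included, ]
    data.frame(bay = groups$bay[i], season = groups$season[i],
               n_cores = nrow(g), n_included = nrow(inc),
               mean_flux_mmol_m2_d = if (nrow(inc)) mean(inc$flux_mmol_m2_d) else NA_real_,
               mean_dns_cm = if (nrow(inc)) mean(inc$dns_cm) else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
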