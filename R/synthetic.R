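#' Ground-truth parameters for one synthetic porewater core
#'
#' Defines the shape a generated core is drawn around: sulfate decreasing
#' linearly from `sulfate_surface` at the seafloor to zero at the true depth
#' of no sulfate `dns_true`, and methane absent above a transition depth tied
#' to `dns_true` then rising monotonically to `methane_deep` at the 32 cm
#' reference depth. The default 6 mM surface sulfate reflects brackish Baltic
#' coastal bottom water.
#'
#' @param site,bay,season Labels for the core.
#' @param sulfate_surface Sulfate at the seafloor, mM (> 0).
#' @param dns_true True depth of no sulfate, cm (> 0).
#' @param methane_deep Methane at the 32 cm reference depth, mM.
#' @param noise_sd Additive Gaussian noise standard deviation, mM (>= 0);
#'   concentrations are truncated at 0.
#' @param porosity Porosity, fraction in (0, 1).
#' @param surface_depression Optional winter-style surface sulfate
#'   depression, mM subtracted at 0 cm and tapering linearly to zero at 10 cm
#'   (default 0 = off). Produces a subsurface sulfate peak.
#' @return An object of class `profile_truth`.
#' @export
profile_truth <- function(site, bay, season, sulfate_surface = 6,
                          dns_true = 25, methane_deep = 0.8, noise_sd = 0.3,
                          porosity = 0.8, surface_depression = 0) {
  stop_if_not_scalar_number(sulfate_surface, "sulfate_surface", positive = TRUE)
  stop_if_not_scalar_number(dns_true, "dns_true", positive = TRUE)
  stop_if_not_scalar_number(methane_deep, "methane_deep")
  stop_if_not_scalar_number(noise_sd, "noise_sd")
  if (noise_sd < 0) stop("`noise_sd` must be >= 0", call. = FALSE)
  if (methane_deep < 0) stop("`methane_deep` must be >= 0", call. = FALSE)
  stop_if_not_scalar_number(surface_depression, "surface_depression")
  check_porosity(porosity)
  structure(list(site = as.character(site), bay = as.character(bay),
                 season = as.character(season),
                 sulfate_surface = sulfate_surface, dns_true = dns_true,
                 methane_deep = methane_deep, noise_sd = noise_sd,
                 porosity = porosity, surface_depression = surface_depression),
            class = "profile_truth")
}

# Unclamped linear sulfate trend implied by a truth object; negative below
# the depth of no sulfate. Observed profiles are max(0, linear + noise): the
# truncation applies once, after the noise, so that depths below the DNS read
# zero rather than half-positive.
truth_sulfate_linear <- function(truth, depths) {
  v <- truth$sulfate_surface * (1 - depths / truth$dns_true)
  if (truth$surface_depression > 0)
    v <- v - truth$surface_depression * pmax(0, 1 - depths / 10)
  v
}

truth_sulfate_mean <- function(truth, depths) {
  pmax(0, truth_sulfate_linear(truth, depths))
}

# Noise-free methane shape: zero above the transition depth (5 cm above the
# DNS), rising to methane_deep at the 32 cm reference depth, either linearly
# (default) or along a logistic ramp.

truth_methane_mean <- function(truth, depths, shape = c("linear", "sigmoid"),
                               reference_depth = 32) {
  shape <- match.arg(shape)
  transition <- truth$dns_true - 5
  if (shape == "linear") {
    ramp <- (depths - transition) / max(reference_depth - transition, 1e-9)
    pmax(0, pmin(ramp, 1)) * truth$methane_deep
  } else {
    mid <- (transition + reference_depth) / 2
    val <- truth$methane_deep / (1 + exp(-(depths - mid) / 2))
    val[depths <= transition] <- 0
    val
  }
}

#' Generate synthetic porewater profiles with known ground truth
#'
#' Draws one [porewater_profile()] per truth object at the given slice
#' depths: the noise-free sulfate/methane shapes implied by each
#' [profile_truth()] plus independent Gaussian noise truncated at zero. A
#' fixed seed makes the output byte-identical across calls; the caller's RNG
#' state is left untouched.
#'
#' @param truths A list of [profile_truth()] objects (a single one is
#'   accepted).
#' @param depths Slice-midpoint depths, cm, strictly increasing and positive.
#' @param seed Integer seed.
#' @param methane_shape `"linear"` (default) or `"sigmoid"` ramp below the
#'   transition depth.
#' @return A list with `profiles` (list of [porewater_profile()]) and
#'   `truths` (data.frame echoing the ground-truth parameters per core,
#'   including the implied linear sulfate slope).
#' @export
generate_porewater_profiles <- function(truths, depths, seed,
                                        methane_shape = c("linear", "sigmoid")) {
  methane_shape <- match.arg(methane_shape)
  if (inherits(truths, "profile_truth")) truths <- list(truths)
  stopifnot(length(truths) >= 1L,
            all(vapply(truths, inherits, logical(1), "profile_truth")))
  if (length(depths) == 0L) stop("`depths` must be non-empty", call. = FALSE)
  if (any(depths <= 0) || is.unsorted(depths, strictly = TRUE))
    stop("`depths` must be strictly increasing and positive", call. = FALSE)
  for (tr in truths) {
    if (tr$dns_true <= min(depths))
      stop(sprintf("site %s: dns_true (%g cm) at or above the shallowest depth (%g cm) gives a degenerate profile",
                   tr$site, tr$dns_true, min(depths)), call. = FALSE)
  }
  profiles <- with_seed(seed, lapply(truths, function(tr) {
    so4 <- truth_sulfate_linear(tr, depths)
    ch4 <- truth_methane_mean(tr, depths, methane_shape)
    if (tr$noise_sd > 0) {
      so4 <- so4 + stats::rnorm(length(depths), 0, tr$noise_sd)
      # methane spans a concentration range smaller by ~sulfate/methane scale
      ch4 <- ch4 + stats::rnorm(length(depths), 0, tr$noise_sd *
                                  tr$methane_deep / tr$sulfate_surface)
    }
    so4 <- pmax(0, so4)
    ch4 <- pmax(0, ch4)
    porewater_profile(tr$site, tr$bay, tr$season, depths,
                      list(sulfate = so4, methane = ch4), tr$porosity)
  }))
  truth_df <- do.call(rbind, lapply(truths, function(tr) {
    data.frame(site = tr$site, bay = tr$bay, season = tr$season,
               sulfate_surface_mM = tr$sulfate_surface, dns_true_cm = tr$dns_true,
               slope_true_mM_cm = -tr$sulfate_surface / tr$dns_true,
               methane_deep_mM = tr$methane_deep, noise_sd_mM = tr$noise_sd,
               porosity = tr$porosity, stringsAsFactors = FALSE)
  }))
  list(profiles = profiles, truths = truth_df)
}

#' Temperature scenario for the two-bay logger emulation
#'
#' An annual sinusoid around `annual_mean` with the heated bay offset by
#' `bay_offset` degrees C above the control bay, plus independent Gaussian
#' logger noise. Defaults emulate a Baltic coastal bay pair: 10 degrees C
#' annual mean, 9.5 degrees C amplitude peaking in late July, and the 5.1
#' degrees C long-term heating offset.
#'
#' @param annual_mean Control-bay annual mean, degrees C.
#' @param annual_amplitude Sinusoid amplitude, degrees C (>= 0).
#' @param bay_offset Heated minus control offset, degrees C.
#' @param sample_interval Logger sampling interval, hours (> 0).
#' @param noise_sd Logger noise standard deviation, degrees C.
#' @param peak_doy Day of year at which the sinusoid peaks.
#' @param seed Integer seed.
#' @return An object of class `temperature_scenario`.
#' @export
temperature_scenario <- function(annual_mean = 10, annual_amplitude = 9.5,
                                 bay_offset = 5.1, sample_interval = 1,
                                 noise_sd = 0.5, peak_doy = 205, seed = 1L) {
  stop_if_not_scalar_number(annual_amplitude, "annual_amplitude")
  if (annual_amplitude < 0) stop("`annual_amplitude` must be >= 0", call. = FALSE)
  stop_if_not_scalar_number(sample_interval, "sample_interval", positive = TRUE)
  stop_if_not_scalar_number(noise_sd, "noise_sd")
  if (noise_sd < 0) stop("`noise_sd` must be >= 0", call. = FALSE)
  structure(list(annual_mean = annual_mean, annual_amplitude = annual_amplitude,
                 bay_offset = bay_offset, sample_interval = sample_interval,
                 noise_sd = noise_sd, peak_doy = peak_doy, seed = seed),
            class = "temperature_scenario")
}

#' Generate heated- and control-bay temperature logger series
#'
#' Control bay: `annual_mean + annual_amplitude * sin(annual phase) + noise`;
#' heated bay: the same seasonal signal plus `bay_offset` and independent
#' noise. Reproducible under the scenario seed.
#'
#' @param scenario A [temperature_scenario()].
#' @param start,end Start and end timestamps (coercible to POSIXct, UTC);
#'   `end` must be after `start`.
#' @return A data.frame with columns `timestamp`, `bay`
#'   (`"control"`/`"heated"`) and `temperature_c`, in long format.
#' @export
generate_temperature_series <- function(scenario,
                                        start = "2021-04-01", end = "2022-03-31") {
  stopifnot(inherits(scenario, "temperature_scenario"))
  start <- as.POSIXct(start, tz = "UTC"); end <- as.POSIXct(end, tz = "UTC")
  if (end <= start) stop("`end` must be after `start`", call. = FALSE)
  times <- seq(start, end, by = scenario$sample_interval * 3600)
  doy <- as.numeric(difftime(times, as.POSIXct(paste0(format(times, "%Y"), "-01-01"),
                                               tz = "UTC"), units = "days"))
  seasonal <- scenario$annual_mean + scenario$annual_amplitude *
    sin(2 * pi * (doy - (scenario$peak_doy - 365.25 / 4)) / 365.25)
  with_seed(scenario$seed, {
    control <- seasonal + stats::rnorm(length(times), 0, scenario$noise_sd)
    heated <- seasonal + scenario$bay_offset +
      stats::rnorm(length(times), 0, scenario$noise_sd)
    rbind(data.frame(timestamp = times, bay = "control",
                     temperature_c = control, stringsAsFactors = FALSE),
          data.frame(timestamp = times, bay = "heated",
                     temperature_c = heated, stringsAsFactors = FALSE))
  })
}

#' Generate headspace jar readings from true porewater concentrations
#'
#' Inverse of the headspace equilibration calculation: the ppm reading each
#' jar would produce for a known total porewater methane concentration, so
#' that [total_porewater_methane()] recovers the truth exactly (round-trip
#' identity). Deterministic: GC reading noise, if wanted, should be added by
#' the caller.
#'
#' @param true_mM Vector of true porewater CH4 concentrations, mM (>= 0).
#' @param geometry A [jar_geometry()].
#' @param lab A [lab_conditions()].
#' @param include_dissolved Must match the setting later used for inversion.
#' @return A data.frame with columns `true_mM` and `ppm`.
#' @export
generate_headspace_samples <- function(true_mM, geometry = jar_geometry(),
                                       lab = lab_conditions(),
                                       include_dissolved = TRUE) {
  data.frame(true_mM = true_mM,
             ppm = ppm_for_concentration(true_mM, geometry, lab,
                                         include_dissolved))
}

#' Community scenario for synthetic amplicon count tables
#'
#' Expected family proportions per sample follow a log-linear model,
#' `proportions ~ exp(base + depth_slope * depth + bay_effect * is_heated)`,
#' and counts are drawn Dirichlet-multinomial: overdispersion is controlled
#' by `dirichlet_concentration` (larger = closer to multinomial). Each family
#' is split over `asvs_per_family` ASVs so rank aggregation is exercised.
#' The default family set names the dominant Bathyarchaeia, methane-cycling
#' and sulfate-reducing lineages of warmed Baltic bay sediments, with ANME-1
#' and BA1 favoured in the heated bay and depth gradients of either sign.
#'
#' @param families Character vector of family labels.
#' @param base_log_abundance Per-family baseline log abundance.
#' @param depth_slope Per-family log-abundance change per cm depth.
#' @param bay_effect Per-family log-abundance shift in the heated bay.
#' @param dirichlet_concentration Positive scalar overdispersion control.
#' @param library_size Reads per sample (> 0).
#' @param asvs_per_family ASVs each family is split into.
#' @param seed Integer seed.
#' @return An object of class `community_scenario`.
#' @export
community_scenario <- function(families = NULL, base_log_abundance = NULL,
                               depth_slope = NULL, bay_effect = NULL,
                               dirichlet_concentration = 200,
                               library_size = 20000, asvs_per_family = 3L,
                               seed = 1L) {
  if (is.null(families)) {
    defaults <- study_community_defaults()
    families <- defaults$family
    base_log_abundance <- defaults$base
    depth_slope <- defaults$slope
    bay_effect <- defaults$bay
  }
  if (length(families) == 0L) stop("`families` must be non-empty", call. = FALSE)
  if (anyDuplicated(families)) stop("duplicate family labels", call. = FALSE)
  k <- length(families)
  base_log_abundance <- base_log_abundance %||% rep(0, k)
  depth_slope <- depth_slope %||% rep(0, k)
  bay_effect <- bay_effect %||% rep(0, k)
  stopifnot(length(base_log_abundance) == k, length(depth_slope) == k,
            length(bay_effect) == k)
  stop_if_not_scalar_number(dirichlet_concentration, "dirichlet_concentration",
                            positive = TRUE)
  stop_if_not_scalar_number(library_size, "library_size", positive = TRUE)
  structure(list(families = families, base_log_abundance = base_log_abundance,
                 depth_slope = depth_slope, bay_effect = bay_effect,
                 dirichlet_concentration = dirichlet_concentration,
                 library_size = as.integer(library_size),
                 asvs_per_family = as.integer(asvs_per_family), seed = seed),
            class = "community_scenario")
}

# Family gradients loosely shaped on the depth/bay structure reported for
# warmed Baltic bay sediment communities: Bathyarchaeia dominate, ANME-1 and
# BA1 increase with depth and in the heated bay, Nitrosopumilaceae decline
# with depth, sulfate reducers peak at depth with the UBA11574 family
# favoured in the control bay.
study_community_defaults <- function() {
  data.frame(
    family = c("TCS64", "UBA233", "ANME-1", "DHVEG-1", "BA1",
               "Nitrosopumilaceae", "Methanomethylophilaceae", "HEL-GB-A",
               "UBA11574", "Desulfatiglandaceae", "Desulfocapsaceae",
               "Thiobacillaceae", "34-128", "Anaerolineaceae",
               "Woeseiaceae", "Sandaracinaceae"),
    base  = c(3.2, 3.0, -1.5, 0.8, -1.8, 2.0, -2.0, -1.5,
              0.8, -0.5, 1.0, 0.8, -0.8, 1.5, 1.2, 0.6),
    slope = c(0.04, -0.03, 0.10, 0.06, 0.08, -0.12, 0.0, 0.0,
              0.06, 0.08, -0.10, 0.04, 0.10, 0.0, -0.05, -0.02),
    bay   = c(0.1, -0.3, 1.2, 0.3, 1.0, -0.2, 0.0, 0.8,
              -0.9, 0.3, 0.1, -0.3, 0.9, 0.0, 0.0, 0.0),
    stringsAsFactors = FALSE)
}

#' Generate a synthetic ASV count table
#'
#' Draws Dirichlet-multinomial counts per sample around the log-linear
#' expected family proportions of a [community_scenario()], splits each
#' family over its ASVs, and packages the result as a [count_table()] with a
#' five-rank taxonomy and the sample metadata. Every sample's total count
#' equals the scenario library size.
#'
#' @param scenario A [community_scenario()].
#' @param samples data.frame with columns `bay`, `season`, `depth_cm` and
#'   optionally `site`/`sample_id`; one row per sample, at least 2 rows.
#' @return A [count_table()] (samples x ASVs).
#' @export
generate_count_table <- function(scenario, samples) {
  stopifnot(inherits(scenario, "community_scenario"), is.data.frame(samples))
  if (nrow(samples) < 2L) stop("need at least 2 samples", call. = FALSE)
  if (!all(c("bay", "season", "depth_cm") %in% names(samples)))
    stop("`samples` needs columns bay, season, depth_cm", call. = FALSE)
  if (is.null(samples$sample_id))
    samples$sample_id <- sprintf("S%03d", seq_len(nrow(samples)))
  if (is.null(samples$site)) samples$site <- "syn"
  k <- length(scenario$families)
  m <- scenario$asvs_per_family
  asv_ids <- as.vector(t(outer(gsub("[^A-Za-z0-9]", "", scenario$families),
                               seq_len(m), function(f, i) sprintf("ASV_%s_%d", f, i))))
  counts <- with_seed(scenario$seed, {
    # fixed within-family ASV split, shared across samples
    split_w <- matrix(stats::rgamma(k * m, shape = 2), nrow = k)
    split_w <- split_w / rowSums(split_w)
    t(vapply(seq_len(nrow(samples)), function(i) {
      eta <- scenario$base_log_abundance +
        scenario$depth_slope * samples$depth_cm[i] +
        scenario$bay_effect * (samples$bay[i] == "heated")
      p <- exp(eta - max(eta)); p <- p / sum(p)
      w <- stats::rgamma(k, shape = scenario$dirichlet_concentration * p)
      if (sum(w) == 0) w <- p
      p_asv <- as.vector(t(split_w * (w / sum(w))))
      stats::rmultinom(1L, scenario$library_size, p_asv)[, 1L]
    }, numeric(k * m)))
  })
  dimnames(counts) <- list(samples$sample_id, asv_ids)
  taxonomy <- data.frame(
    asv_id = asv_ids,
    domain = "Synthetic", phylum = "Synthetic", class = "Synthetic",
    order = "Synthetic", family = rep(scenario$families, each = m),
    stringsAsFactors = FALSE)
  count_table(counts, taxonomy,
              metadata = samples[, c("sample_id", "site", "bay", "season",
                                     "depth_cm")])
}

#' Ground-truth core parameters for the default two-bay study scenario
#'
#' Three cores per bay and season. Control-bay depths of no sulfate follow
#' the seasonal pattern of the emulated system (25 cm summer, 37 cm winter);
#' the heated bay is shallower in both seasons (22 and 30 cm), consistent
#' with a warming-thinned sulfate reduction zone. Deep methane reaches 0.8 mM
#' (control) and 0.7 mM (heated); winter cores carry the optional subsurface
#' sulfate peak.
#'
#' @param noise_sd Concentration noise, mM.
#' @return A list of [profile_truth()] objects (12 cores).
#' @export
study_profile_truths <- function(noise_sd = 0.3) {
  cfg <- expand.grid(site_i = 1:3, bay = c("control", "heated"),
                     season = c("summer", "winter"), stringsAsFactors = FALSE)
  sites <- list(control = c("I", "J", "K"), heated = c("C", "F", "H"))
  dns <- list(control = c(summer = 25, winter = 37),
              heated = c(summer = 22, winter = 30))
  ch4 <- c(control = 0.8, heated = 0.7)
  lapply(seq_len(nrow(cfg)), function(i) {
    bay <- cfg$bay[i]; season <- cfg$season[i]
    profile_truth(site = sites[[bay]][cfg$site_i[i]], bay = bay,
                  season = season, sulfate_surface = 6,
                  dns_true = dns[[bay]][[season]],
                  methane_deep = ch4[[bay]], noise_sd = noise_sd,
                  surface_depression = if (season == "winter") 2.5 else 0)
  })
}
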