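#' Read a long-format porewater CSV into profiles
#'
#' Expected columns: `site,bay,season,depth_cm,analyte,concentration_mM`.
#' Rows are grouped into one [porewater_profile()] per (site, bay, season)
#' with depths sorted ascending; row order in the file does not matter.
#' Lines starting with `#` (provenance headers) are ignored.
#'
#' @param path CSV path.
#' @param porosity Porosity assigned to every profile (not stored in the
#'   CSV).
#' @return A list of [porewater_profile()] objects.
#' @export
read_porewater_csv <- function(path, porosity = 0.8) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE,
                         colClasses = "character")
  need <- c("site", "bay", "season", "depth_cm", "analyte", "concentration_mM")
  missing <- setdiff(need, names(raw))
  if (length(missing))
    stop("missing column(s): ", paste(missing, collapse = ", "), call. = FALSE)
  conc <- suppressWarnings(as.numeric(raw$concentration_mM))
  bad <- which(is.na(conc) & !is.na(raw$concentration_mM) &
                 raw$concentration_mM != "NA")
  if (length(bad))
    stop(sprintf("non-numeric concentration_mM at row %d ('%s')",
                 bad[1], raw$concentration_mM[bad[1]]), call. = FALSE)
  raw$concentration_mM <- conc
  raw$depth_cm <- as.numeric(raw$depth_cm)
  key <- paste(raw$site, raw$bay, raw$season, raw$depth_cm, raw$analyte, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (site, depth, analyte) rows, first at row ",
         which(duplicated(key))[1], call. = FALSE)
  groups <- split(raw, paste(raw$site, raw$bay, raw$season, sep = "\r"))
  unname(lapply(groups, function(g) {
    depths <- sort(unique(g$depth_cm))
    analytes <- lapply(split(g, g$analyte), function(a) {
      a <- a[order(a$depth_cm), ]
      if (!identical(a$depth_cm, depths))
        stop(sprintf("site %s: analyte '%s' not measured at every depth",
                     g$site[1], a$analyte[1]), call. = FALSE)
      a$concentration_mM
    })
    porewater_profile(g$site[1], g$bay[1], g$season[1], depths, analytes,
                      porosity)
  }))
}

#' Write profiles to a long-format porewater CSV
#'
#' @param profiles A list of [porewater_profile()] objects.
#' @param path Output path.
#' @param provenance Optional provenance string written as a `#` header line.
#' @return `path`, invisibly.
#' @export
write_porewater_csv <- function(profiles, path, provenance = NULL) {
  if (inherits(profiles, "porewater_profile")) profiles <- list(profiles)
  rows <- do.call(rbind, lapply(profiles, function(p) {
    do.call(rbind, lapply(names(p$analytes), function(a) {
      data.frame(site = p$site, bay = p$bay, season = p$season,
                 depth_cm = p$depths, analyte = a,
                 concentration_mM = p$analytes[[a]], stringsAsFactors = FALSE)
    }))
  }))
  write_table_prov(rows, path, provenance, sep = ",")
}

#' Read a headspace jar CSV
#'
#' Expected columns:
#' `site,bay,season,depth_top_cm,depth_bottom_cm,ppm`.
#'
#' @param path CSV path.
#' @return A data.frame with an added `depth_cm` column (interval midpoint).
#' @export
read_headspace_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("site", "bay", "season", "depth_top_cm", "depth_bottom_cm", "ppm")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("missing column(s): ", paste(missing, collapse = ", "), call. = FALSE)
  if (any(df$depth_bottom_cm <= df$depth_top_cm))
    stop("depth_bottom_cm must exceed depth_top_cm", call. = FALSE)
  if (any(df$ppm < 0)) stop("negative ppm reading", call. = FALSE)
  df$depth_cm <- (df$depth_top_cm + df$depth_bottom_cm) / 2
  df
}

#' Read an ASV count table with taxonomy and metadata
#'
#' Amplicon-pipeline convention: the count TSV has ASVs in rows (first
#' column `asv_id`) and samples in columns; the taxonomy TSV has columns
#' `asv_id` and `lineage` (semicolon-delimited
#' domain;phylum;class;order;family, short lineages padded with
#' `"Unassigned"`); the metadata CSV has `sample_id,site,bay,season,depth_cm`.
#'
#' @param counts_path,taxonomy_path,metadata_path File paths.
#' @return A [count_table()] (samples x ASVs).
#' @export
read_count_table <- function(counts_path, taxonomy_path, metadata_path) {
  for (p in c(counts_path, taxonomy_path, metadata_path))
    if (!file.exists(p)) stop("file not found: ", p, call. = FALSE)
  ctab <- utils::read.delim(counts_path, comment.char = "#",
                            stringsAsFactors = FALSE, check.names = FALSE)
  if (names(ctab)[1] != "asv_id")
    stop("count TSV must have `asv_id` as its first column", call. = FALSE)
  counts <- t(as.matrix(ctab[, -1, drop = FALSE]))
  colnames(counts) <- ctab$asv_id
  tax_raw <- utils::read.delim(taxonomy_path, comment.char = "#",
                               stringsAsFactors = FALSE)
  if (!all(c("asv_id", "lineage") %in% names(tax_raw)))
    stop("taxonomy TSV needs columns `asv_id` and `lineage`", call. = FALSE)
  ranks <- c("domain", "phylum", "class", "order", "family")
  parts <- strsplit(tax_raw$lineage, ";", fixed = TRUE)
  tax <- do.call(rbind, lapply(parts, function(p) {
    p <- trimws(p)
    length(p) <- length(ranks)
    p[is.na(p) | p == ""] <- "Unassigned"
    p
  }))
  taxonomy <- data.frame(asv_id = tax_raw$asv_id,
                         stats::setNames(as.data.frame(tax,
                                                       stringsAsFactors = FALSE),
                                         ranks),
                         stringsAsFactors = FALSE)
  metadata <- utils::read.csv(metadata_path, comment.char = "#",
                              stringsAsFactors = FALSE)
  count_table(counts, taxonomy, metadata)
}

#' Write a count table to count/taxonomy/metadata files
#'
#' Inverse of [read_count_table()]; taxonomy ranks are joined back into a
#' semicolon lineage.
#'
#' @param table A [count_table()].
#' @param counts_path,taxonomy_path,metadata_path Output paths.
#' @param provenance Optional provenance string written as a `#` header.
#' @return Invisibly, the three paths.
#' @export
write_count_table <- function(table, counts_path, taxonomy_path, metadata_path,
                              provenance = NULL) {
  stopifnot(inherits(table, "count_table"))
  ctab <- data.frame(asv_id = colnames(table$counts),
                     t(table$counts), check.names = FALSE,
                     stringsAsFactors = FALSE)
  write_table_prov(ctab, counts_path, provenance, sep = "\t")
  ranks <- setdiff(names(table$taxonomy), "asv_id")
  lineage <- apply(table$taxonomy[, ranks, drop = FALSE], 1, paste,
                   collapse = ";")
  write_table_prov(data.frame(asv_id = table$taxonomy$asv_id, lineage = lineage,
                              stringsAsFactors = FALSE),
                   taxonomy_path, provenance, sep = "\t")
  write_table_prov(table$metadata, metadata_path, provenance, sep = ",")
  invisible(c(counts_path, taxonomy_path, metadata_path))
}

# Shared writer: optional '#'-prefixed provenance line, then a header row and
# the data; readers skip '#' lines via comment.char.
write_table_prov <- function(df, path, provenance = NULL, sep = ",") {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(provenance)) writeLines(paste0("# ", provenance), con)
  utils::write.table(df, con, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Pipeline configuration
#'
#' Collects every tunable constant of the analysis chain in one validated
#' list: jar geometry and lab constants for the methane conversion, the D0
#' parameterisation and linearity threshold for the flux stage, season
#' windows and the detection floor for the comparisons, and permutation
#' settings for the community stage.
#'
#' @param geometry A [jar_geometry()].
#' @param lab A [lab_conditions()].
#' @param m0,m1 Sulfate D0 parameterisation
#'   (see [sulfate_diffusion_coefficient()]).
#' @param porosity Sediment porosity used throughout.
#' @param r2_threshold Linearity-exclusion threshold.
#' @param season_windows List of [season_window()]s.
#' @param detection_floor Fold-change detection floor, mM.
#' @param permutations PERMANOVA permutations.
#' @param seed Integer seed for every stochastic stage.
#' @param include_porosity_factor Porosity factor in Fick's law.
#' @param include_dissolved Dissolved fraction in the headspace conversion.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(geometry = jar_geometry(), lab = lab_conditions(),
                            m0 = 4.88, m1 = 0.232, porosity = 0.8,
                            r2_threshold = 0.90,
                            season_windows = default_season_windows(),
                            detection_floor = 1e-4, permutations = 999,
                            seed = 1L, include_porosity_factor = TRUE,
                            include_dissolved = TRUE) {
  stopifnot(inherits(geometry, "jar_geometry"), inherits(lab, "lab_conditions"),
            all(vapply(season_windows, inherits, logical(1), "season_window")))
  check_porosity(porosity)
  stop_if_not_scalar_number(detection_floor, "detection_floor", positive = TRUE)
  stop_if_not_scalar_number(permutations, "permutations", positive = TRUE)
  structure(list(geometry = geometry, lab = lab, m0 = m0, m1 = m1,
                 porosity = porosity, r2_threshold = r2_threshold,
                 season_windows = season_windows,
                 detection_floor = detection_floor,
                 permutations = as.integer(permutations), seed = as.integer(seed),
                 include_porosity_factor = isTRUE(include_porosity_factor),
                 include_dissolved = isTRUE(include_dissolved)),
            class = "pipeline_config")
}

#' Run the full synthetic-study pipeline
#'
#' Generates the default two-bay study scenario under the configuration seed
#' and runs the requested stages, writing every result table (with a
#' provenance header carrying the config fingerprint, seed and package
#' version) under `out_dir`:
#' \describe{
#'   \item{simulate}{porewater profiles, ground-truth sidecar, temperature
#'     series, headspace jar readings, community count/taxonomy/metadata.}
#'   \item{methane}{headspace readings converted to porewater CH4 (mM).}
#'   \item{flux}{per-core flux results and the bay/season summary.}
#'   \item{compare}{seasonal temperature summaries, Welch tests, fold
#'     changes.}
#'   \item{community}{family-level Bray-Curtis matrix, PCoA coordinates,
#'     PERMANOVA table.}
#' }
#' Later stages read the files earlier stages wrote, so simulated and real
#' data are interchangeable. A stage failure is rethrown with the stage name.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @param stages Character vector of stages to run, in order.
#' @return Invisibly, a named list of the result objects per stage.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir,
                         stages = c("simulate", "methane", "flux", "compare",
                                    "community")) {
  stopifnot(inherits(config, "pipeline_config"))
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  prov <- sprintf("smtz %s | config %s | seed %d",
                  as.character(utils::packageVersion("smtz")),
                  config_fingerprint(config), config$seed)
  log_stage <- function(stage, msg)
    message(sprintf("[%s] %s", stage, msg))
  in_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
           call. = FALSE))
  }
  paths <- function(...) file.path(out_dir, ...)
  results <- list()

  if ("simulate" %in% stages) results$simulate <- in_stage("simulate", {
    truths <- study_profile_truths()
    gen_s <- generate_porewater_profiles(
      Filter(function(t) t$season == "summer", truths),
      depths = seq(1, 31, by = 2), seed = config$seed)
    gen_w <- generate_porewater_profiles(
      Filter(function(t) t$season == "winter", truths),
      depths = seq(2, 38, by = 4), seed = config$seed + 1L)
    profiles <- c(gen_s$profiles, gen_w$profiles)
    write_porewater_csv(profiles, paths("porewater.csv"), prov)
    write_table_prov(rbind(gen_s$truths, gen_w$truths), paths("truth.csv"), prov)

    temps <- generate_temperature_series(
      temperature_scenario(seed = config$seed))
    write_table_prov(temps, paths("temperature.csv"), prov)

    jar_tops <- c(2, 9, 16, 23)
    hs <- do.call(rbind, lapply(profiles, function(p) {
      tr_idx <- which(vapply(truths, function(t)
        t$site == p$site && t$season == p$season, logical(1)))
      tr <- truths[[tr_idx]]
      mids <- jar_tops + 2
      truth_ch4 <- truth_methane_mean(tr, mids)
      data.frame(site = p$site, bay = p$bay, season = p$season,
                 depth_top_cm = jar_tops, depth_bottom_cm = jar_tops + 4,
                 ppm = ppm_for_concentration(truth_ch4, config$geometry,
                                             config$lab,
                                             config$include_dissolved),
                 stringsAsFactors = FALSE)
    }))
    write_table_prov(hs, paths("headspace.csv"), prov)

    depths5 <- c(0.5, 1.5, 8.5, 15.5, 22.5)
    samp <- expand.grid(site = c("I", "J", "K"), depth_cm = depths5,
                        season = c("summer", "winter"),
                        stringsAsFactors = FALSE)
    samp$bay <- "control"
    samp2 <- samp; samp2$bay <- "heated"
    samp2$site <- c(I = "C", J = "F", K = "H")[samp2$site]
    samples <- rbind(samp, samp2)
    samples$sample_id <- sprintf("%s_%s_%s_%04.1f", samples$bay, samples$season,
                                 samples$site, samples$depth_cm)
    ct <- generate_count_table(community_scenario(seed = config$seed), samples)
    write_count_table(ct, paths("counts.tsv"), paths("taxonomy.tsv"),
                      paths("metadata.csv"), prov)
    log_stage("simulate", sprintf("%d cores, %d community samples written to %s",
                                  length(profiles), nrow(samples), out_dir))
    list(profiles = profiles, temperature = temps, count_table = ct)
  })

  if ("methane" %in% stages) results$methane <- in_stage("methane", {
    hs <- read_headspace_csv(paths("headspace.csv"))
    hs$ch4_mM <- total_porewater_methane(hs$ppm, config$geometry, config$lab,
                                         config$include_dissolved)
    write_table_prov(hs[, c("site", "bay", "season", "depth_cm", "ch4_mM")],
                     paths("methane.csv"), prov)
    log_stage("methane", sprintf("%d jar readings converted", nrow(hs)))
    hs
  })

  if ("flux" %in% stages) results$flux <- in_stage("flux", {
    profiles <- read_porewater_csv(paths("porewater.csv"), config$porosity)
    temps <- utils::read.csv(paths("temperature.csv"), comment.char = "#",
                             stringsAsFactors = FALSE)
    temp_of <- function(bay, season) {
      w <- config$season_windows[[season]]
      seasonal_summary(temps[temps$bay == bay, ], w)$mean_c
    }
    fluxes <- lapply(profiles, function(p)
      core_flux(p, temp_of(p$bay, p$season), config$m0, config$m1,
                config$r2_threshold, config$include_porosity_factor))
    write_table_prov(flux_results_table(fluxes), paths("flux_results.csv"), prov)
    summ <- bay_season_flux_summary(fluxes)
    write_table_prov(summ, paths("flux_summary.csv"), prov)
    log_stage("flux", sprintf("%d cores, %d included",
                              length(fluxes),
                              sum(vapply(fluxes, `[[`, logical(1), "included"))))
    list(results = fluxes, summary = summ)
  })

  if ("compare" %in% stages) results$compare <- in_stage("compare", {
    temps <- utils::read.csv(paths("temperature.csv"), comment.char = "#",
                             stringsAsFactors = FALSE)
    summaries <- do.call(rbind, lapply(c("control", "heated"), function(b) {
      do.call(rbind, lapply(config$season_windows, function(w) {
        cbind(bay = b, seasonal_summary(temps[temps$bay == b, ], w))
      }))
    }))
    write_table_prov(summaries, paths("temperature_summary.csv"), prov)
    tt <- welch_t_test(temps$temperature_c[temps$bay == "heated"],
                       temps$temperature_c[temps$bay == "control"])
    methane <- utils::read.csv(paths("methane.csv"), comment.char = "#",
                               stringsAsFactors = FALSE)
    season_fc <- fold_change(methane, "season", depth = 4,
                             floor = config$detection_floor)
    bay_fc <- fold_change(methane, "bay", depth = 4,
                          floor = config$detection_floor)
    write_table_prov(rbind(cbind(contrast = "season", season_fc),
                           cbind(contrast = "bay", bay_fc)),
                     paths("fold_changes.csv"), prov)
    write_table_prov(rbind(cbind(contrast = "season",
                                 fold_change_summary(season_fc)),
                           cbind(contrast = "bay",
                                 fold_change_summary(bay_fc))),
                     paths("fold_change_summary.csv"), prov)
    log_stage("compare", sprintf("bay t-test p = %.3g", tt$p))
    list(temperature = summaries, welch = tt,
         season_fold = season_fc, bay_fold = bay_fc)
  })

  if ("community" %in% stages) results$community <- in_stage("community", {
    ct <- read_count_table(paths("counts.tsv"), paths("taxonomy.tsv"),
                           paths("metadata.csv"))
    fam <- aggregate_to_rank(ct, "family")
    ra <- relative_abundance(fam, top_k = 15)
    write_table_prov(data.frame(sample_id = rownames(ra), ra,
                                check.names = FALSE), paths("family_relabund.csv"),
                     prov)
    d <- bray_curtis(fam)
    write_table_prov(data.frame(sample_id = rownames(as.matrix(d)),
                                as.matrix(d), check.names = FALSE),
                     paths("bray_curtis.tsv"), prov, sep = "\t")
    ord <- pcoa(d)
    write_table_prov(data.frame(sample_id = rownames(ord$points),
                                ord$points[, 1:2], check.names = FALSE),
                     paths("pcoa.csv"), prov)
    perm <- permanova(d, ~ bay * depth_cm + season, fam$metadata,
                      permutations = config$permutations, seed = config$seed)
    write_table_prov(as.data.frame(perm), paths("permanova.csv"), prov)
    log_stage("community", sprintf("PERMANOVA bay: F = %.2f, p = %.3g",
                                   perm$pseudo_f[perm$term == "bay"],
                                   perm$p_value[perm$term == "bay"]))
    list(table = fam, relabund = ra, dist = d, pcoa = ord, permanova = perm)
  })

  invisible(results)
}
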