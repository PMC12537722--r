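#' Season window
#'
#' A labelled date interval used to subset temperature logger series. The
#' defaults returned by [default_season_windows()] are the study seasons:
#' summer 1 June - 22 September 2021 and winter 21 December 2021 - 20 March
#' 2022.
#'
#' @param label Window label, e.g. `"summer"`.
#' @param start,end Dates (or strings coercible to `Date`); `end` must be
#'   after `start`.
#' @return An object of class `season_window`.
#' @export
season_window <- function(label, start, end) {
  start <- as.Date(start); end <- as.Date(end)
  if (is.na(start) || is.na(end)) stop("invalid window dates", call. = FALSE)
  if (end <= start) stop("`end` must be after `start`", call. = FALSE)
  structure(list(label = as.character(label), start = start, end = end),
            class = "season_window")
}

#' @rdname season_window
#' @export
default_season_windows <- function() {
  list(summer = season_window("summer", "2021-06-01", "2021-09-22"),
       winter = season_window("winter", "2021-12-21", "2022-03-20"))
}

#' Seasonal temperature summary
#'
#' Mean, sample standard deviation (n - 1), minimum and maximum of the
#' observations whose timestamp falls inside the window (inclusive of both
#' end dates).
#'
#' @param series A data.frame with columns `timestamp` (POSIXct or Date) and
#'   `temperature_c`.
#' @param window A [season_window()].
#' @return A one-row data.frame: `season`, `n`, `mean_c`, `sd_c`, `min_c`,
#'   `max_c`.
#' @export
seasonal_summary <- function(series, window) {
  stopifnot(is.data.frame(series), inherits(window, "season_window"))
  if (!all(c("timestamp", "temperature_c") %in% names(series)))
    stop("`series` needs columns `timestamp` and `temperature_c`", call. = FALSE)
  d <- as.Date(series$timestamp)
  x <- series$temperature_c[d >= window$start & d <= window$end]
  if (length(x) < 2L)
    stop(sprintf("fewer than 2 observations in the %s window", window$label),
         call. = FALSE)
  data.frame(season = window$label, n = length(x), mean_c = mean(x),
             sd_c = stats::sd(x), min_c = min(x), max_c = max(x),
             stringsAsFactors = FALSE)
}

#' Welch two-sample t-test
#'
#' Unequal-variance t statistic with Welch-Satterthwaite degrees of freedom
#' and a two-sided p-value. Two identical zero-variance samples are handled by
#' convention as no evidence of a difference (`t = 0`, `p = 1`).
#'
#' @param a,b Numeric samples, each of length >= 2.
#' @return A list with `t`, `df` and `p`.
#' @examples
#' welch_t_test(c(1, 2, 3), c(4, 5, 6))
#' @export
welch_t_test <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L)
    stop("each sample needs at least 2 observations", call. = FALSE)
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    if (mean(a) == mean(b))
      return(list(t = 0, df = length(a) + length(b) - 2, p = 1))
    stop("both samples are constant with different means: t is not defined",
         call. = FALSE)
  }
  tt <- stats::t.test(a, b, var.equal = FALSE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = unname(tt$p.value))
}

#' Methane fold changes between matched contexts
#'
#' Ratios of porewater methane concentration between two contexts differing
#' in exactly one dimension (season within a bay/site, or bay within a
#' season), at a requested depth with nearest-depth matching. A detection
#' floor (default 1e-4 mM, below the smallest concentration the method
#' resolves) replaces values below it in both the numerator and denominator
#' so near-zero winter concentrations do not produce infinite or zero
#' ratios; floored records are flagged.
#'
#' For `contrast = "season"` each site is matched with itself across seasons
#' within a bay. For `contrast = "bay"` the sites differ between bays, so
#' each numerator-bay site is compared against the denominator-bay mean at
#' the matched depth and season.
#'
#' @param methane A data.frame with columns `site`, `bay`, `season`,
#'   `depth_cm`, `ch4_mM` (one row per jar/depth).
#' @param contrast `"season"` (default numerator `"summer"`, denominator
#'   `"winter"`) or `"bay"` (default numerator `"heated"`, denominator
#'   `"control"`).
#' @param depth Requested depth, cm.
#' @param numerator,denominator Context labels overriding the defaults.
#' @param floor Detection floor, mM.
#' @param depth_tol Maximum |matched depth - `depth`|, cm (default 1).
#' @return A data.frame of fold-change records: `site`, `context`, `depth_cm`,
#'   `numerator_mM`, `denominator_mM`, `ratio`, `floored`. Contexts missing a
#'   matching depth are skipped with a message.
#' @export
fold_change <- function(methane, contrast = c("season", "bay"), depth,
                        numerator = NULL, denominator = NULL,
                        floor = 1e-4, depth_tol = 1) {
  contrast <- match.arg(contrast)
  stopifnot(is.data.frame(methane))
  need <- c("site", "bay", "season", "depth_cm", "ch4_mM")
  if (!all(need %in% names(methane)))
    stop("`methane` needs columns ", paste(need, collapse = ", "), call. = FALSE)
  stop_if_not_scalar_number(depth, "depth", positive = TRUE)
  stop_if_not_scalar_number(floor, "floor", positive = TRUE)
  if (contrast == "season") {
    num <- numerator %||% "summer"; den <- denominator %||% "winter"
  } else {
    num <- numerator %||% "heated"; den <- denominator %||% "control"
  }

  nearest <- function(df) {
    if (!nrow(df)) return(NULL)
    i <- which.min(abs(df$depth_cm - depth))
    if (abs(df$depth_cm[i] - depth) > depth_tol) return(NULL)
    df[i, , drop = FALSE]
  }

  records <- list()
  if (contrast == "season") {
    combos <- unique(methane[, c("site", "bay")])
    for (i in seq_len(nrow(combos))) {
      si <- combos$site[i]; ba <- combos$bay[i]
      a <- nearest(methane[methane$site == si & methane$bay == ba &
                             methane$season == num, ])
      b <- nearest(methane[methane$site == si & methane$bay == ba &
                             methane$season == den, ])
      if (is.null(a) || is.null(b)) {
        message(sprintf("fold_change: site %s (%s) skipped, no matching depth within %g cm of %g cm",
                        si, ba, depth_tol, depth))
        next
      }
      records[[length(records) + 1L]] <-
        fold_record(si, ba, a$depth_cm, a$ch4_mM, b$ch4_mM, floor)
    }
  } else {
    for (se in unique(methane$season)) {
      den_rows <- methane[methane$bay == den & methane$season == se, ]
      den_match <- do.call(rbind, lapply(split(den_rows, den_rows$site), nearest))
      if (is.null(den_match) || !nrow(den_match)) {
        message(sprintf("fold_change: season %s skipped, no %s-bay value near %g cm",
                        se, den, depth))
        next
      }
      den_mean <- mean(den_match$ch4_mM)
      num_rows <- methane[methane$bay == num & methane$season == se, ]
      for (si in unique(num_rows$site)) {
        a <- nearest(num_rows[num_rows$site == si, ])
        if (is.null(a)) {
          message(sprintf("fold_change: site %s (%s) skipped, no matching depth",
                          si, se))
          next
        }
        records[[length(records) + 1L]] <-
          fold_record(si, se, a$depth_cm, a$ch4_mM, den_mean, floor)
      }
    }
  }
  if (!length(records))
    stop("no fold-change records could be formed", call. = FALSE)
  do.call(rbind, records)
}

fold_record <- function(site, context, depth_cm, num_mM, den_mM, floor) {
  floored <- num_mM < floor || den_mM < floor
  data.frame(site = site, context = context, depth_cm = depth_cm,
             numerator_mM = num_mM, denominator_mM = den_mM,
             ratio = max(num_mM, floor) / max(den_mM, floor),
             floored = floored, stringsAsFactors = FALSE)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Summarise fold-change records
#'
#' Reports the maximum fold ("up to") and two notions of the average fold
#' across records: the mean of the per-site ratios and the ratio of the mean
#' concentrations. Both are printed because an "average fold" can be either.
#'
#' @param records Output of [fold_change()].
#' @return A one-row data.frame: `n`, `max_fold`, `mean_fold`,
#'   `ratio_of_means`, `n_floored`.
#' @export
fold_change_summary <- function(records) {
  stopifnot(is.data.frame(records), nrow(records) >= 1L,
            all(c("ratio", "numerator_mM", "denominator_mM") %in% names(records)))
  data.frame(n = nrow(records), max_fold = max(records$ratio),
             mean_fold = mean(records$ratio),
             ratio_of_means = mean(records$numerator_mM) /
               max(mean(records$denominator_mM), 1e-12),
             n_floored = sum(records$floored), stringsAsFactors = FALSE)
}
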