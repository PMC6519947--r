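# Dose-response viability table, safe-dose logic, and the group-comparison
# statistics (one-way ANOVA + Fisher LSD) used on viability/fluorescence
# replicates.

#' Viability dose-response table
#'
#' Mean MSC viability (% of basal-medium control) with SEM, on a grid of
#' bupivacaine concentrations x exposure durations.
#'
#' @param concentrations Dose grid, mM, strictly increasing, starting at the
#'   0 mM control.
#' @param exposure_times Exposure grid, hours, strictly increasing.
#' @param mean_viability Matrix (`length(exposure_times)` rows x
#'   `length(concentrations)` columns) of mean viability, %.
#' @param sem Matching matrix of standard errors, %.
#' @param n_experiments Replicate count behind the means (used by the
#'   synthetic replicate generator); default 3.
#' @param metadata Optional list (e.g. verbatim source cells, suspect-value
#'   flags).
#' @return An object of class `viability_table`.
#' @export
viability_table <- function(concentrations, exposure_times, mean_viability,
                            sem = NULL, n_experiments = 3, metadata = list()) {
  concentrations <- as.numeric(concentrations)
  exposure_times <- as.numeric(exposure_times)
  mean_viability <- as.matrix(mean_viability)
  if (is.unsorted(concentrations, strictly = TRUE) ||
      is.unsorted(exposure_times, strictly = TRUE)) {
    stop("concentration and exposure grids must be strictly increasing",
         call. = FALSE)
  }
  if (!identical(dim(mean_viability),
                 c(length(exposure_times), length(concentrations)))) {
    stop("`mean_viability` must be exposure x concentration", call. = FALSE)
  }
  if (any(mean_viability < 0)) {
    stop("viability values must be >= 0", call. = FALSE)
  }
  if (concentrations[1] != 0 || any(mean_viability[, 1] != 100)) {
    stop("the first column must be the 0 mM control normalized to 100%",
         call. = FALSE)
  }
  if (!is.null(sem)) {
    sem <- as.matrix(sem)
    if (!identical(dim(sem), dim(mean_viability)) || any(sem < 0)) {
      stop("`sem` must match `mean_viability` in shape and be >= 0",
           call. = FALSE)
    }
  }
  dimnames(mean_viability) <- list(exposure_times, concentrations)
  if (!is.null(sem)) dimnames(sem) <- dimnames(mean_viability)
  structure(
    list(concentrations = concentrations, exposure_times = exposure_times,
         mean_viability = mean_viability, sem = sem,
         n_experiments = n_experiments, metadata = metadata),
    class = "viability_table"
  )
}

#' @export
print.viability_table <- function(x, ...) {
  cat("viability_table:", length(x$concentrations), "doses x",
      length(x$exposure_times), "exposure times (% of control)\n")
  print(x$mean_viability)
  invisible(x)
}

#' Read a viability table from CSV
#'
#' Expected layout: first column `exposure_h`, remaining column names are
#' concentrations in mM, cells are `"mean ± sem%"` (a plain number is
#' accepted as a mean with missing SEM). A cell whose SEM carries no `%` sign
#' is parsed but flagged as suspect in `metadata$suspect_sem`.
#'
#' @param path CSV file path.
#' @param n_experiments Replicate count behind the means; default 3.
#' @return A [viability_table()].
#' @export
read_viability_csv <- function(path, n_experiments = 3) {
  raw <- utils::read.csv(path, check.names = FALSE, colClasses = "character",
                         fileEncoding = "UTF-8")
  if (names(raw)[1] != "exposure_h") {
    stop("first column of a viability CSV must be `exposure_h`", call. = FALSE)
  }
  conc <- as.numeric(names(raw)[-1])
  if (anyNA(conc)) {
    stop("viability CSV column names (after `exposure_h`) must be ",
         "concentrations in mM", call. = FALSE)
  }
  times <- as.numeric(raw$exposure_h)
  cells <- as.matrix(raw[, -1, drop = FALSE])
  pm <- "±"
  parse_cell <- function(s) {
    s0 <- trimws(s)
    parts <- trimws(strsplit(s0, paste0("(", pm, "|\\+/-)"))[[1]])
    mean_v <- suppressWarnings(as.numeric(sub("%$", "", parts[1])))
    if (is.na(mean_v)) stop("unparseable viability cell: '", s, "'", call. = FALSE)
    sem_v <- NA_real_
    suspect <- FALSE
    if (length(parts) > 1) {
      has_pct <- grepl("%$", parts[2])
      sem_v <- suppressWarnings(as.numeric(sub("%$", "", parts[2])))
      suspect <- !has_pct # SEM printed without a % sign: likely a typo
    }
    c(mean = mean_v, sem = sem_v, suspect = as.numeric(suspect))
  }
  parsed <- apply(cells, c(1, 2), function(s) parse_cell(s)["mean"])
  sems <- apply(cells, c(1, 2), function(s) parse_cell(s)["sem"])
  suspect <- apply(cells, c(1, 2), function(s) parse_cell(s)["suspect"] > 0)
  viability_table(
    concentrations = conc, exposure_times = times,
    mean_viability = parsed, sem = sems, n_experiments = n_experiments,
    metadata = list(
      verbatim = cells,
      suspect_sem = which(suspect, arr.ind = TRUE),
      source = path
    )
  )
}

#' Packaged MSC bupivacaine viability table
#'
#' The bundled dose-response measurements: % viable MSCs (relative to basal
#' medium) after 24 h and 48 h exposure to 0-1 mM bupivacaine. The 0.5 mM /
#' 48 h cell is printed in the source data with an ambiguous SEM ("62 ± 35",
#' no % sign, likely 3%); its mean is used as printed and the SEM flagged in
#' `metadata$suspect_sem`.
#'
#' @return A [viability_table()].
#' @export
msc_viability_table <- function() {
  read_viability_csv(
    system.file("extdata", "msc_bupivacaine_viability.csv",
                package = "depotsim", mustWork = TRUE)
  )
}

# nearest grid exposure, warning when off-grid
match_exposure <- function(table, exposure) {
  i <- which(abs(table$exposure_times - exposure) < 1e-9)
  if (length(i) == 1L) return(i)
  i <- which.min(abs(table$exposure_times - exposure))
  warning(sprintf(
    "exposure %g h is not on the table grid; using nearest tabulated %g h",
    exposure, table$exposure_times[i]), call. = FALSE)
  i
}

#' Interpolate viability at an arbitrary dose
#'
#' Exact at grid knots; between positive doses, linear in log10 of the
#' concentration (pharmacological convention); between the 0 mM control and
#' the smallest positive dose, linear in the concentration itself. No
#' extrapolation above the largest tabulated dose. Exposure times between
#' grid values use the nearest tabulated exposure with a warning.
#'
#' @param table A [viability_table()].
#' @param concentration Dose, mM, >= 0.
#' @param exposure Exposure duration, hours.
#' @return Mean viability, %.
#' @export
interpolate_viability <- function(table, concentration, exposure) {
  stopifnot(inherits(table, "viability_table"))
  if (concentration < 0) stop("`concentration` must be >= 0", call. = FALSE)
  cmax <- max(table$concentrations)
  if (concentration > cmax * (1 + 1e-12)) {
    stop(sprintf(
      "concentration %g mM exceeds the largest tabulated dose (%g mM); refusing to extrapolate",
      concentration, cmax), call. = FALSE)
  }
  row <- table$mean_viability[match_exposure(table, exposure), ]
  conc <- table$concentrations
  k <- which(abs(conc - concentration) < 1e-12 * max(1, cmax))
  if (length(k) == 1L) return(unname(row[k]))
  hi <- which(conc > concentration)[1]
  lo <- hi - 1L
  if (conc[lo] == 0) {
    w <- (concentration - conc[lo]) / (conc[hi] - conc[lo])
  } else {
    w <- (log10(concentration) - log10(conc[lo])) /
      (log10(conc[hi]) - log10(conc[lo]))
  }
  unname((1 - w) * row[lo] + w * row[hi])
}

#' Largest tabulated dose meeting a viability floor
#'
#' Scans the table row for the given exposure and returns the largest
#' tabulated concentration whose mean viability is at or above
#' `viability_floor`. The 90% floor at 48 h is the working definition of a
#' "safe" bolus exposure.
#'
#' @param table A [viability_table()].
#' @param viability_floor Required viability, % in (0, 100].
#' @param exposure Exposure duration, hours (on the table grid).
#' @return The concentration in mM, or `NA` if no tabulated dose (including
#'   the control) meets the floor.
#' @export
max_safe_concentration <- function(table, viability_floor = 90, exposure = 48) {
  stopifnot(inherits(table, "viability_table"))
  if (viability_floor <= 0 || viability_floor > 100) {
    stop("`viability_floor` must be in (0, 100]", call. = FALSE)
  }
  row <- table$mean_viability[match_exposure(table, exposure), ]
  ok <- which(row >= viability_floor)
  if (length(ok) == 0) return(NA_real_)
  max(table$concentrations[ok])
}

#' Classify a release profile against a concentration ceiling
#'
#' Flags a release (or cell-apparent concentration) time series as safe when
#' it never exceeds the threshold concentration — by default the 0.1 mM
#' ceiling at which 48 h bolus exposure still leaves 90% of MSCs viable.
#'
#' @param curve A [release_curve()], the data.frame returned by
#'   [cell_apparent_concentration()], or a numeric concentration series with
#'   a parallel `times` argument.
#' @param threshold Ceiling concentration, mM (default 0.1).
#' @param times Sampling times in hours when `curve` is a bare numeric vector.
#' @return An object of class `safety_report`: `threshold_concentration`,
#'   `max_observed_concentration`, `first_exceedance_time` (h, `NA` if never)
#'   and `safe`.
#' @export
classify_release_safety <- function(curve, threshold = 0.1, times = NULL) {
  if (inherits(curve, "release_curve")) {
    conc <- curve$well_concentration_mM
    times <- curve$time_h
  } else if (is.data.frame(curve) && all(c("time_h", "concentration_mM") %in%
                                         names(curve))) {
    conc <- curve$concentration_mM
    times <- curve$time_h
  } else if (is.numeric(curve)) {
    conc <- curve
    if (is.null(times) || length(times) != length(conc)) {
      stop("numeric series needs a matching `times` vector (hours)",
           call. = FALSE)
    }
  } else {
    stop("unsupported input for `classify_release_safety`", call. = FALSE)
  }
  if (length(conc) == 0) stop("empty concentration series", call. = FALSE)
  if (any(conc < 0)) stop("negative concentrations in series", call. = FALSE)
  over <- which(conc > threshold)
  first_t <- if (length(over)) times[over[1]] else NA_real_
  structure(
    list(threshold_concentration = threshold,
         max_observed_concentration = max(conc),
         first_exceedance_time = first_t,
         safe = is.na(first_t)),
    class = "safety_report"
  )
}

#' @export
print.safety_report <- function(x, ...) {
  cat(sprintf(
    "safety_report: max %.4g mM vs ceiling %.4g mM -> %s%s\n",
    x$max_observed_concentration, x$threshold_concentration,
    if (x$safe) "SAFE" else "UNSAFE",
    if (x$safe) "" else sprintf(" (first exceedance at %g h)",
                                x$first_exceedance_time)))
  invisible(x)
}

#' One-way ANOVA with Fisher LSD post hoc comparisons
#'
#' Group comparison as applied to viability/fluorescence replicates: one-way
#' analysis of variance computed from sums of squares, followed by Fisher's
#' least significant difference pairwise t-tests on the pooled mean squared
#' error (no multiplicity adjustment), flagged at `alpha`.
#'
#' @param measurements Named list of numeric replicate vectors (one per
#'   condition), or a data.frame with columns `group` and `value`.
#' @param alpha Significance level for the LSD flags (default 0.05).
#' @return An object of class `group_comparison`: `f_statistic`, `p_value`,
#'   `df` (between, within), `group_means`, and `lsd` — a data.frame of
#'   pairwise comparisons with `t`, `p_value` and `significant`.
#' @export
compare_groups <- function(measurements, alpha = 0.05) {
  if (is.data.frame(measurements)) {
    stopifnot(all(c("group", "value") %in% names(measurements)))
    measurements <- split(measurements$value, measurements$group)
  }
  if (!is.list(measurements) || length(measurements) < 2) {
    stop("need at least 2 groups", call. = FALSE)
  }
  if (is.null(names(measurements)) || any(names(measurements) == "")) {
    names(measurements) <- paste0("group", seq_along(measurements))
  }
  n_i <- lengths(measurements)
  if (any(n_i < 2)) stop("need >= 2 replicates per group", call. = FALSE)

  k <- length(measurements)
  n <- sum(n_i)
  means <- vapply(measurements, mean, numeric(1))
  grand <- sum(unlist(measurements)) / n
  ss_between <- sum(n_i * (means - grand)^2)
  ss_within <- sum(vapply(measurements,
                          function(g) sum((g - mean(g))^2), numeric(1)))
  df_b <- k - 1
  df_w <- n - k
  if (ss_within <= 0) {
    stop("zero within-group variance across all groups; F is degenerate",
         call. = FALSE)
  }
  ms_b <- ss_between / df_b
  mse <- ss_within / df_w
  f_stat <- ms_b / mse
  p_val <- stats::pf(f_stat, df_b, df_w, lower.tail = FALSE)

  pairs <- utils::combn(names(measurements), 2)
  lsd <- data.frame(
    group1 = pairs[1, ], group2 = pairs[2, ],
    diff = means[pairs[1, ]] - means[pairs[2, ]],
    row.names = NULL
  )
  se <- sqrt(mse * (1 / n_i[pairs[1, ]] + 1 / n_i[pairs[2, ]]))
  lsd$t <- lsd$diff / se
  lsd$p_value <- 2 * stats::pt(abs(lsd$t), df_w, lower.tail = FALSE)
  lsd$significant <- lsd$p_value <= alpha

  structure(
    list(f_statistic = f_stat, p_value = p_val, df = c(df_b, df_w),
         mse = mse, group_means = means, lsd = lsd, alpha = alpha),
    class = "group_comparison"
  )
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("group_comparison: F(%d, %d) = %.4g, p = %.4g\n",
              x$df[1], x$df[2], x$f_statistic, x$p_value))
  print(x$lsd, digits = 4)
  invisible(x)
}
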