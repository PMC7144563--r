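#' Franz-cell receptor-concentration time series
#'
#' One replicate of an in vitro permeation experiment in a vertical Franz
#' diffusion cell: receptor-compartment concentrations sampled at increasing
#' times, together with the cell geometry needed to reduce the series to a
#' flux. Default geometry: diffusion area 4.9 cm^2, receptor volume 20 mL,
#' 0.5 mL withdrawn and replaced with fresh medium at each sampling, donor
#' concentration 100 ug/mL.
#'
#' @param times sampling times in hours, strictly increasing, at least 3.
#' @param concentrations receptor concentrations (ug/mL) at each time.
#' @param donor_concentration initial donor concentration C_d (ug/mL).
#' @param area diffusion area A (cm^2).
#' @param receptor_volume receptor compartment volume V_r (mL).
#' @param sample_volume volume V_s withdrawn (and replaced) per sampling
#'   (mL); 0 disables the dilution correction.
#' @param compound,replicate_id labels.
#' @return An object of class `permeation_series`.
#' @export
permeation_series <- function(times, concentrations,
                              donor_concentration = 100,
                              area = 4.9, receptor_volume = 20,
                              sample_volume = 0.5,
                              compound = "compound", replicate_id = "r1") {
  times <- as.numeric(times)
  concentrations <- as.numeric(concentrations)
  if (length(times) < 3L) stop("need at least 3 time points", call. = FALSE)
  if (length(times) != length(concentrations))
    stop("times and concentrations differ in length", call. = FALSE)
  if (any(diff(times) <= 0)) stop("times must be strictly increasing",
                                  call. = FALSE)
  if (any(concentrations < 0)) stop("negative receptor concentration",
                                    call. = FALSE)
  if (area <= 0) stop("diffusion area must be > 0", call. = FALSE)
  if (donor_concentration <= 0) stop("donor concentration must be > 0",
                                     call. = FALSE)
  if (sample_volume < 0 || receptor_volume <= sample_volume)
    stop("need receptor volume > sample volume >= 0", call. = FALSE)
  structure(list(times = times, concentrations = concentrations,
                 donor_concentration = donor_concentration, area = area,
                 receptor_volume = receptor_volume,
                 sample_volume = sample_volume,
                 compound = compound, replicate_id = replicate_id),
            class = "permeation_series")
}

#' Cumulative permeated amount per unit area
#'
#' Converts receptor concentrations to the cumulative amount of compound
#' that has crossed the membrane per cm^2, correcting for the dilution
#' caused by replacing each withdrawn sample with fresh medium:
#' \deqn{Q_n = (C_n V_r + V_s \sum_{i<n} C_i) / A}
#' With `sample_volume = 0` this reduces to \eqn{C_n V_r / A}.
#'
#' @param series a [permeation_series].
#' @return Numeric vector of Q(t) in ug/cm^2, one per time point.
#' @export
cumulative_amounts <- function(series) {
  stopifnot(inherits(series, "permeation_series"))
  C <- series$concentrations
  prior <- c(0, cumsum(C))[seq_along(C)]
  (C * series$receptor_volume + series$sample_volume * prior) / series$area
}

window_r2 <- function(t, q) {
  fit <- stats::lm.fit(cbind(1, t), q)
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((q - mean(q))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else if (ss_res <= 1e-12) 1 else 0
  c(slope = unname(fit$coefficients[2L]), r2 = r2)
}

#' Steady-state flux from the linear section of a permeation profile
#'
#' Scans every contiguous window of at least `min_window` points, and takes
#' the least-squares slope of the longest window with fit r^2 at or above
#' `r2_threshold`; if none qualifies, the window maximizing r^2. Ties prefer
#' later, then longer windows — steady state is terminal in a Franz
#' experiment, so early lag points are excluded by the scan.
#'
#' @param Q cumulative amount per area (ug/cm^2), from [cumulative_amounts()].
#' @param times sampling times (h), aligned with `Q`.
#' @param min_window smallest acceptable window length (default 3).
#' @param r2_threshold linearity criterion for a window (default 0.99).
#' @return A list: `J_ss` (ug cm^-2 h^-1), `linear_window` (integer index
#'   range), `fit_r2`.
#' @export
steady_state_flux <- function(Q, times, min_window = 3L, r2_threshold = 0.99) {
  n <- length(Q)
  if (length(times) != n) stop("Q and times differ in length", call. = FALSE)
  if (n < min_window)
    stop("fewer points than min_window", call. = FALSE)
  best <- NULL
  for (len in min_window:n) {
    for (start in seq_len(n - len + 1L)) {
      idx <- start:(start + len - 1L)
      wr <- window_r2(times[idx], Q[idx])
      cand <- list(slope = wr[["slope"]], r2 = wr[["r2"]],
                   start = start, end = start + len - 1L, len = len)
      if (is.null(best)) { best <- cand; next }
      better <-
        if (cand$r2 >= r2_threshold && best$r2 >= r2_threshold) {
          # among qualifying windows: longer wins, then later end, then later start
          cand$len > best$len ||
            (cand$len == best$len && cand$end > best$end) ||
            (cand$len == best$len && cand$end == best$end &&
               cand$start > best$start)
        } else if (cand$r2 >= r2_threshold) TRUE
        else if (best$r2 >= r2_threshold) FALSE
        else {
          cand$r2 > best$r2 + 1e-12 ||
            (abs(cand$r2 - best$r2) <= 1e-12 &&
               (cand$end > best$end ||
                  (cand$end == best$end && cand$len > best$len)))
        }
      if (better) best <- cand
    }
  }
  list(J_ss = best$slope, linear_window = c(best$start, best$end),
       fit_r2 = best$r2)
}

#' Apparent permeability coefficient from steady-state flux
#'
#' \eqn{P_{app} = J_{ss} / C_d}: flux divided by the initial donor
#' concentration. With J_ss in ug cm^-2 h^-1 and C_d in ug/mL (= ug/cm^3)
#' the result is in cm/h.
#'
#' @param J_ss steady-state flux (ug cm^-2 h^-1).
#' @param C_d initial donor concentration (ug/mL), must be positive.
#' @return P_app in cm/h.
#' @export
apparent_permeability <- function(J_ss, C_d) {
  if (C_d <= 0) stop("donor concentration must be > 0", call. = FALSE)
  J_ss / C_d
}

#' Reduce one permeation series to its summary
#'
#' Runs the full reduction: cumulative amounts, linear-window flux fit, and
#' apparent permeability (both cm/h and cm/s).
#'
#' @param series a [permeation_series].
#' @inheritParams steady_state_flux
#' @return An object of class `permeation_summary`: a list with `compound`,
#'   `replicate_id`, `Q`, `linear_window`, `J_ss`, `fit_r2`, `P_app` (cm/h)
#'   and `P_app_cm_s`.
#' @export
summarize_permeation <- function(series, min_window = 3L,
                                 r2_threshold = 0.99) {
  Q <- cumulative_amounts(series)
  fl <- steady_state_flux(Q, series$times, min_window = min_window,
                          r2_threshold = r2_threshold)
  p <- apparent_permeability(fl$J_ss, series$donor_concentration)
  structure(list(compound = series$compound,
                 replicate_id = series$replicate_id,
                 times = series$times, Q = Q,
                 linear_window = fl$linear_window, J_ss = fl$J_ss,
                 fit_r2 = fl$fit_r2, P_app = p, P_app_cm_s = p / 3600),
            class = "permeation_summary")
}

#' @export
print.permeation_summary <- function(x, ...) {
  cat(sprintf(
    "Permeation summary %s/%s: J_ss = %.4g ug cm^-2 h^-1, P_app = %.4g cm/h (window %d-%d, r2 = %.4f)\n",
    x$compound, x$replicate_id, x$J_ss, x$P_app,
    x$linear_window[1L], x$linear_window[2L], x$fit_r2))
  invisible(x)
}

#' Aggregate replicate permeability determinations
#'
#' Arithmetic mean and sample standard deviation of P_app across replicates
#' of the same compound (experiments are typically run in triplicate). A
#' single replicate reports `sd = NA`.
#'
#' @param summaries list of [summarize_permeation()] results, one compound.
#' @return A list: `compound`, `n`, `mean_P_app`, `sd_P_app`.
#' @export
aggregate_replicates <- function(summaries) {
  if (length(summaries) < 1L) stop("need at least one replicate", call. = FALSE)
  compounds <- vapply(summaries, `[[`, "", "compound")
  if (length(unique(compounds)) != 1L)
    stop("replicates from different compounds: ",
         paste(unique(compounds), collapse = ", "), call. = FALSE)
  p <- vapply(summaries, `[[`, 0, "P_app")
  list(compound = compounds[1L], n = length(p), mean_P_app = mean(p),
       sd_P_app = if (length(p) > 1L) stats::sd(p) else NA_real_)
}

#' Read Franz-cell series from long-format CSV plus a geometry file
#'
#' The CSV has columns `compound, replicate, time_h, concentration_ug_per_ml`;
#' the geometry block (JSON or YAML, by file extension) supplies `area_cm2`,
#' `receptor_volume_ml`, `sample_volume_ml`, `donor_concentration_ug_per_ml`.
#'
#' @param path CSV path.
#' @param geometry path to a JSON/YAML geometry file, or an equivalent named
#'   list.
#' @return List of [permeation_series], one per compound x replicate.
#' @export
read_permeation <- function(path, geometry) {
  if (is.character(geometry)) {
    geometry <- if (grepl("\\.ya?ml$", geometry, ignore.case = TRUE))
      yaml::read_yaml(geometry) else jsonlite::fromJSON(geometry)
  }
  need <- c("area_cm2", "receptor_volume_ml", "sample_volume_ml",
            "donor_concentration_ug_per_ml")
  missing <- setdiff(need, names(geometry))
  if (length(missing))
    stop("geometry lacks: ", paste(missing, collapse = ", "), call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  cols <- c("compound", "replicate", "time_h", "concentration_ug_per_ml")
  if (!all(cols %in% colnames(df)))
    stop("permeation CSV must have columns: ", paste(cols, collapse = ", "),
         call. = FALSE)
  if (nrow(df) == 0L) stop("empty permeation input", call. = FALSE)
  split_df <- split(df, list(df$compound, df$replicate), drop = TRUE)
  lapply(unname(split_df), function(d) {
    d <- d[order(d$time_h), ]
    permeation_series(d$time_h, d$concentration_ug_per_ml,
                      donor_concentration = geometry$donor_concentration_ug_per_ml,
                      area = geometry$area_cm2,
                      receptor_volume = geometry$receptor_volume_ml,
                      sample_volume = geometry$sample_volume_ml,
                      compound = d$compound[1L], replicate_id = d$replicate[1L])
  })
}

#' Tidy table of permeation summaries
#'
#' @param summaries list of [permeation_summary] objects.
#' @return A data.frame with one row per replicate: compound, replicate,
#'   J_ss, fit_r2, window bounds, P_app in cm/h and cm/s.
#' @export
permeation_table <- function(summaries) {
  do.call(rbind, lapply(summaries, function(s) {
    data.frame(compound = s$compound, replicate = s$replicate_id,
               J_ss_ug_cm2_h = s$J_ss, fit_r2 = s$fit_r2,
               window_start = s$linear_window[1L],
               window_end = s$linear_window[2L],
               P_app_cm_h = s$P_app, P_app_cm_s = s$P_app_cm_s,
               stringsAsFactors = FALSE)
  }))
}
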