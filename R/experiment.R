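#' Titration schedule
#'
#' Describes one ITC experiment: the cell volume, the syringe and initial
#' cell concentrations, and the ordered injection volumes. All
#' concentration bookkeeping in the package derives from this object.
#'
#' Units are fixed package-wide: volumes in ml, concentrations in mmol/l,
#' heats in kcal/mol, power in ucal/s.
#'
#' @param V0 cell volume (ml), positive scalar.
#' @param injection_volumes ordered injection volumes V_1..V_T (ml), all
#'   positive. Their sum must stay below `2 * V0` so that the dilution
#'   formulas remain positive.
#' @param c_L syringe ligand concentration (mmol/l).
#' @param c_M initial cell macromolecule concentration (mmol/l).
#' @param temperature_K absolute temperature (K), used only by
#'   [thermo_from_Ka()].
#' @param valency valency s of the binding model associated with this
#'   experiment (1 to 4).
#'
#' @return An object of class `titration_schedule`.
#' @seealso [total_concentrations()], [cona_example()]
#' @export
#' @examples
#' sch <- titration_schedule(V0 = 1.442, injection_volumes = c(0.001, rep(0.01, 13)),
#'                           c_L = 0.7, c_M = 0.071)
#' sch
titration_schedule <- function(V0, injection_volumes, c_L, c_M,
                               temperature_K = 298.15, valency = 1L) {
  stopifnot(is.numeric(V0), length(V0) == 1L, is.numeric(injection_volumes),
            is.numeric(c_L), length(c_L) == 1L,
            is.numeric(c_M), length(c_M) == 1L)
  if (!is.finite(V0) || V0 <= 0) stop("'V0' must be a positive volume (ml)")
  if (length(injection_volumes) < 1L || any(!is.finite(injection_volumes)) ||
      any(injection_volumes <= 0))
    stop("'injection_volumes' must be a non-empty vector of positive volumes (ml)")
  if (sum(injection_volumes) >= 2 * V0)
    stop("cumulative injected volume must stay below 2 * V0 (got ",
         signif(sum(injection_volumes), 4), " ml against 2 * V0 = ",
         signif(2 * V0, 4), " ml)")
  if (c_L <= 0 || c_M <= 0) stop("'c_L' and 'c_M' must be positive (mmol/l)")
  if (temperature_K <= 0) stop("'temperature_K' must be positive")
  valency <- as.integer(valency)
  if (valency < 1L || valency > 4L) stop("'valency' must be between 1 and 4")
  structure(list(V0 = V0, injection_volumes = as.numeric(injection_volumes),
                 c_L = c_L, c_M = c_M, T_inj = length(injection_volumes),
                 temperature_K = temperature_K, valency = valency),
            class = "titration_schedule")
}

#' @export
print.titration_schedule <- function(x, ...) {
  cat("Titration schedule:", x$T_inj, "injections\n")
  cat(sprintf("  cell V0 = %g ml, c_M = %g mmol/l, syringe c_L = %g mmol/l\n",
              x$V0, x$c_M, x$c_L))
  cat(sprintf("  injected volume %g ml total, T = %g K, valency s = %d\n",
              sum(x$injection_volumes), x$temperature_K, x$valency))
  invisible(x)
}

#' Total ligand and macromolecule concentrations per injection
#'
#' Applies the displacement-corrected dilution formulas to a titration
#' schedule. With cumulative injected volume \eqn{v_i = \sum_{k \le i} V_k},
#' \deqn{l_i = c_L v_i (2 V_0 - v_i) / (2 V_0^2), \qquad
#'       m_i = c_M (2 V_0 - v_i) / (2 V_0 + v_i).}
#' `l` is strictly increasing and `m` strictly decreasing for any valid
#' schedule.
#'
#' @param schedule a [titration_schedule()].
#' @return A data frame of class `concentration_series` with columns
#'   `injection`, `l` (total ligand, mmol/l), `m` (total macromolecule,
#'   mmol/l) and `molar_ratio` (`l/m`).
#' @export
#' @examples
#' conc <- total_concentrations(cona_example(2)$schedule)
#' head(conc, 3)
total_concentrations <- function(schedule) {
  stopifnot(inherits(schedule, "titration_schedule"))
  v <- cumsum(schedule$injection_volumes)
  V0 <- schedule$V0
  l <- schedule$c_L * v * (2 * V0 - v) / (2 * V0^2)
  m <- schedule$c_M * (2 * V0 - v) / (2 * V0 + v)
  out <- data.frame(injection = seq_along(v), l = l, m = m, molar_ratio = l / m)
  class(out) <- c("concentration_series", "data.frame")
  out
}

#' Integrated heats per injection
#'
#' Container for the integrated, per-mole-of-injected-ligand heat of each
#' injection (`q_trans`, kcal/mol), plus the set of injections excluded
#' from fitting (outliers, typically the small first injection).
#'
#' @param q numeric vector of integrated heats (kcal/mol of injected ligand).
#' @param excluded integer indices of injections to exclude from fitting.
#' @return An object of class `heat_series`.
#' @export
heat_series <- function(q, excluded = integer()) {
  stopifnot(is.numeric(q), length(q) >= 1L)
  if (any(!is.finite(q))) stop("'q' must contain finite heats (kcal/mol)")
  excluded <- sort(unique(as.integer(excluded)))
  if (length(excluded) && (any(excluded < 1L) || any(excluded > length(q))))
    stop("'excluded' indices out of range 1..", length(q))
  structure(list(q = as.numeric(q), excluded = excluded), class = "heat_series")
}

#' @export
print.heat_series <- function(x, ...) {
  cat("Heat series:", length(x$q), "injections (kcal/mol)\n")
  print(signif(x$q, 5))
  if (length(x$excluded)) cat("excluded from fitting:", x$excluded, "\n")
  invisible(x)
}

#' Deconvolved power trace
#'
#' A sampled compensation-power signal together with the injection onset
#' times. The trace is assumed already deconvolved from the instrument
#' response; [integrate_peaks()] turns it into a [heat_series()].
#'
#' @param time strictly increasing sample times (s).
#' @param power instantaneous power at each sample (ucal/s).
#' @param injection_times strictly increasing injection onset times (s),
#'   all within the sampled range.
#' @return An object of class `power_trace`.
#' @export
power_trace <- function(time, power, injection_times) {
  stopifnot(is.numeric(time), is.numeric(power), is.numeric(injection_times))
  if (length(time) != length(power)) stop("'time' and 'power' lengths differ")
  if (any(diff(time) <= 0)) stop("'time' must be strictly increasing")
  if (any(diff(injection_times) <= 0))
    stop("'injection_times' must be strictly increasing")
  if (min(injection_times) < min(time) || max(injection_times) > max(time))
    stop("'injection_times' must lie within the sampled time range")
  structure(list(time = as.numeric(time), power = as.numeric(power),
                 injection_times = as.numeric(injection_times)),
            class = "power_trace")
}

#' Reference Con A glycomacromolecule titrations
#'
#' Returns the published reference setups for the lectin Concanavalin A
#' binding precision glycomacromolecules: the injection schedule and the
#' reported fitted parameters for the bivalent (s = 2) and trivalent
#' (s = 3) ligand cases. These are convenient fixtures for diagnostics
#' and for simulating realistic synthetic data; the underlying heats are
#' not redistributed here.
#'
#' @param valency 2 (bivalent) or 3 (trivalent).
#' @return A list with elements `schedule` (a [titration_schedule()]),
#'   `wiseman` (reported [wiseman_params()]), `qc` (reported
#'   [qc_params()]) and `weights` (the [weight_spec()] used for that
#'   case: Gaussian weighting centred on molar ratio 0.3 with the first
#'   injection excluded for the trivalent case, unweighted otherwise).
#' @export
#' @examples
#' cona_example(2)$qc
cona_example <- function(valency = 2) {
  valency <- as.integer(valency)
  vols <- c(0.001, rep(0.01, 13))
  if (valency == 2L) {
    list(
      schedule = titration_schedule(V0 = 1.442, injection_volumes = vols,
                                    c_L = 0.7, c_M = 0.071, valency = 2L),
      wiseman = wiseman_params(K_a = 93.3295, n = 0.1998, dH = -132.3069),
      qc = qc_params(micro_rates(k_on = c(136.4185, 33.4088),
                                 k_off = c(2.3716, 18.5925)),
                     n = 0.3208, dH = -73.4629),
      weights = weight_spec(enabled = FALSE)
    )
  } else if (valency == 3L) {
    list(
      schedule = titration_schedule(V0 = 1.442, injection_volumes = vols,
                                    c_L = 0.978, c_M = 0.0918, valency = 3L),
      wiseman = wiseman_params(K_a = 410.2917, n = 0.3586, dH = -127.7664),
      qc = qc_params(micro_rates(k_on = c(559.1484, 489.7665, 1056.7834),
                                 k_off = c(1844.5886, 81.966, 1338.633)),
                     n = 0.3624, dH = -115.1639),
      weights = weight_spec(enabled = TRUE, mu = 0.3, sigma = 0.1758,
                            excluded = 1L)
    )
  } else stop("'valency' must be 2 or 3")
}

#' Read an experiment from a JSON config and a CSV data file
#'
#' The config is a JSON object with fields `V0_ml`, `c_L_mmol_per_l`,
#' `c_M_mmol_per_l`, `temperature_K`, `valency`, `injection_volumes_ml`
#' and, for power traces, `injection_times_s`. The data file is either a
#' heats CSV with header `injection,q_kcal_per_mol` or a power CSV with
#' header `time_s,power_ucal_per_s`.
#'
#' @param config_path path to the JSON configuration.
#' @param data_path path to the CSV data file.
#' @return A list with `schedule` and either `heats` (a [heat_series()])
#'   or `trace` (a [power_trace()]), depending on the CSV header.
#' @export
read_experiment <- function(config_path, data_path) {
  if (!file.exists(config_path)) stop("config file not found: ", config_path)
  if (!file.exists(data_path)) stop("data file not found: ", data_path)
  cfg <- jsonlite::read_json(config_path, simplifyVector = TRUE)
  for (f in c("V0_ml", "c_L_mmol_per_l", "c_M_mmol_per_l", "injection_volumes_ml"))
    if (is.null(cfg[[f]])) stop("config field missing: '", f, "'")
  schedule <- titration_schedule(
    V0 = cfg$V0_ml, injection_volumes = cfg$injection_volumes_ml,
    c_L = cfg$c_L_mmol_per_l, c_M = cfg$c_M_mmol_per_l,
    temperature_K = if (is.null(cfg$temperature_K)) 298.15 else cfg$temperature_K,
    valency = if (is.null(cfg$valency)) 1L else cfg$valency)
  dat <- utils::read.csv(data_path)
  if (all(c("injection", "q_kcal_per_mol") %in% names(dat))) {
    if (nrow(dat) != schedule$T_inj)
      stop("heats CSV has ", nrow(dat), " rows but config declares ",
           schedule$T_inj, " injections")
    excl <- if (is.null(cfg$excluded_injections)) integer() else cfg$excluded_injections
    list(schedule = schedule,
         heats = heat_series(dat$q_kcal_per_mol[order(dat$injection)],
                             excluded = excl))
  } else if (all(c("time_s", "power_ucal_per_s") %in% names(dat))) {
    if (is.null(cfg$injection_times_s))
      stop("config field missing: 'injection_times_s' (required for power traces)")
    list(schedule = schedule,
         trace = power_trace(dat$time_s, dat$power_ucal_per_s,
                             cfg$injection_times_s))
  } else {
    stop("data CSV must have header 'injection,q_kcal_per_mol' or ",
         "'time_s,power_ucal_per_s'; got: ", paste(names(dat), collapse = ","))
  }
}

#' Write an experiment to a JSON config and a CSV data file
#'
#' Inverse of [read_experiment()] for integrated heats.
#'
#' @param schedule a [titration_schedule()].
#' @param heats a [heat_series()].
#' @param config_path,data_path output paths.
#' @return Invisibly, the two paths.
#' @export
write_experiment <- function(schedule, heats, config_path, data_path) {
  stopifnot(inherits(schedule, "titration_schedule"), inherits(heats, "heat_series"))
  cfg <- list(V0_ml = schedule$V0, c_L_mmol_per_l = schedule$c_L,
              c_M_mmol_per_l = schedule$c_M,
              temperature_K = schedule$temperature_K,
              valency = schedule$valency,
              injection_volumes_ml = schedule$injection_volumes)
  if (length(heats$excluded)) cfg$excluded_injections <- heats$excluded
  jsonlite::write_json(cfg, config_path, auto_unbox = TRUE, digits = NA)
  utils::write.csv(data.frame(injection = seq_along(heats$q),
                              q_kcal_per_mol = heats$q),
                   data_path, row.names = FALSE)
  invisible(c(config_path, data_path))
}
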