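#' Potential methane production rate from a two-time-point headspace incubation
#'
#' Converts the change in headspace CH4 mixing ratio of an anaerobically
#' incubated soil slurry into a mass production rate per gram dry soil.
#' The headspace gas content is obtained from the ideal gas law at the
#' incubation temperature, so that
#' \deqn{PMPR = \frac{dc}{dt} \cdot MM \cdot \frac{V_H \cdot P_A}{R \,(T_{ST} + T)} \cdot \frac{1}{W_s}}
#' with the mixing-ratio change \eqn{dc/dt} expressed as a mole fraction per
#' day, yielding ng CH4 g\eqn{^{-1}} (dry weight) day\eqn{^{-1}} after unit
#' conversion.
#'
#' @param records Data frame of incubation records, one row per vial, with
#'   columns `sample_id`, `c_t0`, `c_t1` (headspace CH4 mixing ratio at the
#'   first and second measurement, in the unit given by `units`), `t0`, `t1`
#'   (incubation day numbers), `VH` (headspace volume, L), `PA` (atmospheric
#'   pressure, kPa), `Ws` (soil dry weight, g) and `T` (incubation
#'   temperature, degrees C). Optional columns `MM` (molar mass of CH4,
#'   g mol^-1), `T_ST` (standard temperature, K) and `R` (gas constant,
#'   J mol^-1 K^-1) override the defaults 16.04, 273.15 and 8.314.
#' @param units Mixing-ratio dialect of `c_t0`/`c_t1`: `"mmol_per_mol"`
#'   (mmol CH4 per mol headspace gas) or `"ppm"` (micromol per mol).
#'
#' @return Data frame with one row per input record: `sample_id`, `dc_dt`
#'   (mixing-ratio change per day, input units) and `pmpr`
#'   (ng CH4 g^-1 dry soil day^-1). The sign of `pmpr` equals the sign of
#'   `dc_dt`.
#'
#' @examples
#' rec <- data.frame(sample_id = "a", c_t0 = 0.5, c_t1 = 0.78,
#'                   t0 = 1, t1 = 15, VH = 0.115, PA = 67, Ws = 5, T = 25)
#' compute_pmpr(rec)
#' @export
compute_pmpr <- function(records, units = c("mmol_per_mol", "ppm")) {
  units <- match.arg(units)
  records <- validate_incubation(records)
  uf <- switch(units, mmol_per_mol = 1e-3, ppm = 1e-6)
  dc_dt <- (records$c_t1 - records$c_t0) / (records$t1 - records$t0)
  t_kelvin <- records$T_ST + records$T
  # mol headspace gas = PA[kPa] * VH[L] / (R * T[K]); kPa*L = J, so units cancel
  mol_per_day <- dc_dt * uf * records$PA * records$VH / (records$R * t_kelvin)
  pmpr <- mol_per_day * records$MM * 1e9 / records$Ws
  data.frame(sample_id = records$sample_id, dc_dt = dc_dt, pmpr = pmpr,
             stringsAsFactors = FALSE)
}

#' Per-sample PMPRs from replicated incubations
#'
#' Averages replicate vial fluxes per sample and optionally subtracts the flux
#' of a blank control vial (a vial filled only with N2), the quality-control
#' layout of the incubation assay. Also reports the coefficient of variation
#' of the replicates.
#'
#' @param records Incubation data frame as for [compute_pmpr()], with an
#'   optional `role` column distinguishing `"sample"` vials from `"blank"`
#'   controls (absent `role` means all rows are sample vials). Replicates
#'   share a `sample_id`.
#' @param units Mixing-ratio dialect, see [compute_pmpr()].
#' @param blank_subtract `"auto"` subtracts the mean blank flux of a sample
#'   whenever that sample has a blank; `"on"` requires blanks; `"off"` ignores
#'   them.
#'
#' @return Data frame with `sample_id`, `pmpr` (replicate mean minus blank
#'   where applicable), `n_replicates`, `cv` (sd/mean of replicate fluxes, NA
#'   for a single replicate or zero mean) and `blank` (the subtracted flux,
#'   0 when none).
#' @export
batch_pmpr <- function(records, units = c("mmol_per_mol", "ppm"),
                       blank_subtract = c("auto", "on", "off")) {
  units <- match.arg(units)
  blank_subtract <- match.arg(blank_subtract)
  if (is.null(records$role)) records$role <- "sample"
  flux <- compute_pmpr(records[setdiff(names(records), "role")], units = units)
  flux$role <- records$role

  ids <- unique(records$sample_id)
  out <- lapply(ids, function(id) {
    fx <- flux[flux$sample_id == id, ]
    reps <- fx$pmpr[fx$role != "blank"]
    blanks <- fx$pmpr[fx$role == "blank"]
    if (length(reps) == 0L) {
      message("batch_pmpr: sample '", id, "' has zero replicate vials; excluded")
      return(NULL)
    }
    if (blank_subtract == "on" && length(blanks) == 0L) {
      stop("batch_pmpr: blank_subtract = 'on' but sample '", id, "' has no blank")
    }
    blank <- if (blank_subtract != "off" && length(blanks) > 0L) mean(blanks) else 0
    m <- mean(reps)
    cv <- if (length(reps) > 1L && m != 0) stats::sd(reps) / abs(m) else NA_real_
    data.frame(sample_id = id, pmpr = m - blank, n_replicates = length(reps),
               cv = cv, blank = blank, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

validate_incubation <- function(records) {
  stopifnot(is.data.frame(records))
  needed <- c("sample_id", "c_t0", "c_t1", "t0", "t1", "VH", "PA", "Ws", "T")
  miss <- setdiff(needed, names(records))
  if (length(miss) > 0L) {
    stop("incubation records missing column(s): ", paste(miss, collapse = ", "))
  }
  if (is.null(records$MM)) records$MM <- 16.04
  if (is.null(records$T_ST)) records$T_ST <- 273.15
  if (is.null(records$R)) records$R <- 8.314
  num <- c("c_t0", "c_t1", "t0", "t1", "VH", "PA", "Ws", "T", "MM", "T_ST", "R")
  for (v in num) {
    if (any(!is.finite(records[[v]]))) stop("non-finite value in field '", v, "'")
  }
  checks <- list(
    t1 = records$t1 > records$t0,
    VH = records$VH > 0,
    PA = records$PA > 0,
    Ws = records$Ws > 0,
    T  = records$T > -273.15,
    c_t0 = records$c_t0 >= 0,
    c_t1 = records$c_t1 >= 0
  )
  for (v in names(checks)) {
    if (any(!checks[[v]])) {
      bad <- records$sample_id[!checks[[v]]][1L]
      stop("invalid field '", v, "' in incubation record for sample '", bad, "'")
    }
  }
  records
}
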