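# Quantitative reductions of the wet-lab assays used to characterise PET
# hydrolases: melting temperature from thermal-shift fluorescence curves,
# DSC crystallinity, HPLC calibration/quantification, depolymerization
# extent, and pH-stat titrant accounting.

# molar mass of one PET repeat unit (terephthalate-ethylene glycol ester),
# g/mol: one mole of released aromatic product (TPA or MHET) accounts for
# one repeat unit of the polymer.
PET_REPEAT_UNIT_MASS <- 192.17

#' Melting temperature from a thermal-shift melt curve
#'
#' The fluorescence signal is smoothed by a centred moving average, the
#' first derivative is taken by central differences on the temperature
#' grid, and Tm is the temperature of the derivative maximum (the unfolding
#' transition midpoint), refined to sub-grid resolution by a parabola
#' fitted by least squares through the peak and its `refine_half`
#' neighbours on each side (the parabola's vertex is the refined Tm). The
#' outermost `window %/% 2` grid points are excluded from the peak search.
#'
#' @param curve data frame with strictly increasing `temperature` (deg C)
#'   and finite `signal` columns, length >= 5.
#' @param window odd smoothing width in grid points (default 5).
#' @param refine_half neighbours per side used in the parabolic peak
#'   refinement (default 4; on a 0.5 deg C grid this spans 2 deg C per
#'   side, well inside the derivative peak of a typical unfolding
#'   transition).
#' @return Object of class `tm_estimate`: list with `tm` (deg C),
#'   `derivative_peak_value` (signal per deg C), `window`.
#' @examples
#' mc <- simulate_melt_curve(tm = 66.8, noise_sd = 0, seed = 1)
#' fit_tm(mc)$tm
#' @export
fit_tm <- function(curve, window = 5L, refine_half = 4L) {
  if (!all(c("temperature", "signal") %in% names(curve))) {
    stop("curve must have columns temperature and signal")
  }
  temp <- curve$temperature
  y <- curve$signal
  n <- length(temp)
  if (n < 5L) stop("melt curve must have at least 5 points")
  if (any(diff(temp) <= 0)) stop("temperature grid must be strictly increasing")
  if (any(!is.finite(y))) stop("signal must be finite")
  if (window < 3L || window %% 2L == 0L || window > n) {
    stop("window must be odd, >= 3 and <= curve length")
  }

  ys <- as.numeric(stats::filter(y, rep(1 / window, window), sides = 2L))
  d <- rep(NA_real_, n)
  d[2L:(n - 1L)] <- (ys[3L:n] - ys[1L:(n - 2L)]) / (temp[3L:n] - temp[1L:(n - 2L)])
  half <- window %/% 2L
  search <- seq_len(n)
  search <- search[search > half & search <= n - half & !is.na(d)]
  if (length(search) < 3L) stop("curve too short for the requested window")

  k <- search[which.max(d[search])]
  dmax <- d[k]
  spread <- stats::mad(d[search], na.rm = TRUE)
  med <- stats::median(d[search], na.rm = TRUE)
  if (!is.finite(dmax) || dmax - med <= 5 * spread + 1e-12) {
    stop("ambiguous derivative peak: no transition above the noise floor")
  }

  tm <- temp[k]
  idx <- seq.int(max(2L, k - refine_half), min(n - 1L, k + refine_half))
  idx <- idx[!is.na(d[idx])]
  if (length(idx) >= 3L) {
    tc <- temp[idx] - temp[k]
    co <- stats::coef(stats::lm(d[idx] ~ tc + I(tc^2)))
    if (all(is.finite(co)) && co[3L] < 0) {
      vertex <- unname(-co[2L] / (2 * co[3L]))
      span <- max(abs(tc))
      if (abs(vertex) <= span) tm <- temp[k] + vertex
    }
  }
  if (tm <= temp[1L] || tm >= temp[n]) {
    stop("estimated Tm falls outside the temperature range")
  }
  structure(list(tm = tm, derivative_peak_value = dmax, window = window),
            class = "tm_estimate")
}

#' @export
print.tm_estimate <- function(x, ...) {
  cat(sprintf("<tm_estimate: Tm %.2f degC (derivative peak %.3g, window %d)>\n",
              x$tm, x$derivative_peak_value, x$window))
  invisible(x)
}

#' Percent crystallinity from DSC enthalpies
#'
#' `crystallinity = (dHm - dHc) / dHf * 100`, with `dHm` the heat of fusion,
#' `dHc` the cold-crystallization enthalpy and `dHf` the fusion enthalpy of
#' fully crystalline PET (140.1 J/g). A negative result (dHc > dHm) is
#' returned as-is with a warning.
#'
#' @param dHm,dHc sample enthalpies, J/g, nonnegative.
#' @param dHf fully crystalline reference enthalpy, J/g, positive.
#' @return Percentage.
#' @examples
#' crystallinity(50, 20)  # 21.41
#' @export
crystallinity <- function(dHm, dHc, dHf = 140.1) {
  if (!is.finite(dHf) || dHf <= 0) stop("dHf must be positive")
  if (any(!is.finite(c(dHm, dHc))) || dHm < 0 || dHc < 0) {
    stop("dHm and dHc must be finite and nonnegative")
  }
  x <- (dHm - dHc) / dHf * 100
  if (x < 0) warning("dHc exceeds dHm: negative crystallinity reported as-is")
  x
}

#' Calibrate analyte concentrations from standard curves
#'
#' Fits an ordinary least-squares line (with intercept) of peak area on
#' known concentration per analyte, then inverts it for the sample areas:
#' `conc = (area - intercept) / slope * dilution_factor`. Negative
#' estimates are clipped to 0 with a warning.
#'
#' @param standards data frame with columns `analyte`, `concentration`,
#'   `area`; at least 2 distinct concentrations per analyte.
#' @param samples data frame with columns `analyte`, `area`.
#' @param dilution_factor multiplier applied to the interpolated
#'   concentration (e.g. 2 for twofold-diluted samples).
#' @return `samples` with an added `concentration` column.
#' @export
calibrate_and_quantify <- function(standards, samples, dilution_factor = 1) {
  req_std <- c("analyte", "concentration", "area")
  if (!all(req_std %in% names(standards))) {
    stop("standards must have columns: ", paste(req_std, collapse = ", "))
  }
  if (!all(c("analyte", "area") %in% names(samples))) {
    stop("samples must have columns analyte and area")
  }
  if (!is.finite(dilution_factor) || dilution_factor <= 0) {
    stop("dilution_factor must be positive")
  }
  fits <- lapply(split(standards, standards$analyte), function(s) {
    if (length(unique(s$concentration)) < 2L) {
      stop("need >= 2 distinct standard concentrations for analyte '",
           s$analyte[1L], "'")
    }
    if (stats::sd(s$area) == 0) {
      stop("singular calibration for analyte '", s$analyte[1L],
           "': all standard areas equal")
    }
    fit <- stats::lm(area ~ concentration, data = s)
    co <- stats::coef(fit)
    if (!is.finite(co[2L]) || co[2L] == 0) {
      stop("singular calibration for analyte '", s$analyte[1L], "'")
    }
    co
  })
  unknown <- setdiff(unique(samples$analyte), names(fits))
  if (length(unknown) > 0L) {
    stop("no standards for analyte(s): ", paste(unknown, collapse = ", "))
  }
  conc <- vapply(seq_len(nrow(samples)), function(i) {
    co <- fits[[samples$analyte[i]]]
    (samples$area[i] - co[1L]) / co[2L] * dilution_factor
  }, numeric(1L))
  if (any(conc < 0)) {
    warning("negative concentration estimate(s) clipped to 0")
    conc[conc < 0] <- 0
  }
  samples$concentration <- conc
  samples
}

#' Construct a hydrolysis-product time course
#'
#' @param times sampling times, hours, nondecreasing.
#' @param tpa,mhet,bhet released product amounts at each time, moles,
#'   nonnegative (`bhet` defaults to zero).
#' @param pet_load PET charged into the reaction, grams, positive.
#' @param volume reaction volume, litres.
#' @return Object of class `product_time_course`.
#' @export
product_time_course <- function(times, tpa, mhet, bhet = 0, pet_load,
                                volume = NA_real_) {
  n <- length(times)
  if (length(bhet) == 1L) bhet <- rep(bhet, n)
  if (length(tpa) != n || length(mhet) != n || length(bhet) != n) {
    stop("times and product series must have equal length")
  }
  if (any(diff(times) < 0)) stop("times must be nondecreasing")
  if (any(c(tpa, mhet, bhet) < 0)) stop("product amounts must be nonnegative")
  if (!is.finite(pet_load) || pet_load <= 0) stop("pet_load must be positive")
  structure(list(times = times, tpa = tpa, mhet = mhet, bhet = bhet,
                 pet_load = pet_load, volume = volume),
            class = "product_time_course")
}

#' PET depolymerization extent over time
#'
#' Converts the summed hydrolysis products (TPA + MHET, the released
#' aromatic monomers; BHET optionally included) to the fraction of the PET
#' charge depolymerized: `extent = 100 * mol_products * 192.17 / pet_load`,
#' with 192.17 g/mol the PET repeat-unit mass.
#'
#' @param tc a [product_time_course()].
#' @param include_bhet include BHET in the product sum (default `FALSE`).
#' @return Data frame `time`, `extent` (percent); attribute `capped` is
#'   `TRUE` when any extent exceeds 100.
#' @export
depolymerization_extent <- function(tc, include_bhet = FALSE) {
  stopifnot(inherits(tc, "product_time_course"))
  mol <- tc$tpa + tc$mhet + if (include_bhet) tc$bhet else 0
  extent <- 100 * mol * PET_REPEAT_UNIT_MASS / tc$pet_load
  out <- data.frame(time = tc$times, extent = extent)
  attr(out, "capped") <- any(extent > 100)
  if (any(extent > 100)) {
    warning("computed extent exceeds 100% at some time point(s)")
  }
  out
}

#' Acid equivalents neutralised in a pH-stat titration
#'
#' `equivalents(t) = molarity * cumulative_volume(t)`.
#'
#' @param times sampling times, hours.
#' @param cumulative_volume cumulative titrant volume, litres,
#'   nondecreasing.
#' @param molarity titrant molarity, mol/L, positive.
#' @return Data frame `time`, `equivalents` (mol).
#' @export
base_to_acid_equivalents <- function(times, cumulative_volume, molarity) {
  if (length(times) != length(cumulative_volume)) {
    stop("times and cumulative_volume must have equal length")
  }
  if (any(diff(cumulative_volume) < 0)) {
    stop("cumulative titrant volume must be nondecreasing")
  }
  if (!is.finite(molarity) || molarity <= 0) stop("molarity must be positive")
  data.frame(time = times, equivalents = molarity * cumulative_volume)
}

#' Expected base equivalents from a product mix
#'
#' Carboxyl stoichiometry of the soluble hydrolysis products: TPA carries 2
#' acid equivalents, MHET 1, BHET 0.
#'
#' @param tpa,mhet,bhet product amounts in moles (vectorised).
#' @return Expected acid equivalents, moles.
#' @export
expected_base_equivalents <- function(tpa, mhet, bhet = 0) {
  if (any(c(tpa, mhet, bhet) < 0)) stop("product amounts must be nonnegative")
  2 * tpa + 1 * mhet + 0 * bhet
}

#' Read a melt curve from CSV
#' @param path CSV with columns `temperature`, `signal`.
#' @return Data frame usable by [fit_tm()].
#' @export
read_melt_curve <- function(path) {
  x <- utils::read.csv(path)
  if (!all(c("temperature", "signal") %in% names(x))) {
    stop("melt-curve CSV must have columns temperature and signal")
  }
  x
}
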