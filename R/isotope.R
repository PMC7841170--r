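# Stable-isotope arithmetic: delta notation, linear standard-based
# calibration, grouped summaries and the consumer-fauna trophic offset.
# All deltas are in permil relative to the international reference scale of
# the system (VPDB for d13C, AIR for d15N, VSMOW/VPDB for d18O).

#' Delta value from isotope ratios
#'
#' delta = (R_sample / R_standard - 1) x 1000, in permil.
#'
#' @param R_sample,R_standard Isotope ratios (> 0).
#' @return Delta in permil.
#' @export
delta_from_ratio <- function(R_sample, R_standard) {
  if (any(R_sample <= 0) || any(R_standard <= 0)) {
    stop("isotope ratios must be positive")
  }
  (R_sample / R_standard - 1) * 1000
}

#' Isotope ratio from a delta value
#' @param delta Delta in permil.
#' @param R_standard Standard ratio (> 0).
#' @return Sample ratio.
#' @export
ratio_from_delta <- function(delta, R_standard) {
  if (any(R_standard <= 0)) stop("isotope ratios must be positive")
  (delta / 1000 + 1) * R_standard
}

#' Calibrate measurements against certified standards
#'
#' Per isotope system, fits the ordinary least-squares line mapping measured
#' standard deltas to their certified values and applies it to the samples.
#' When standards are measured exactly at their certified values the
#' transform is the identity. A two-point fit passes exactly through both
#' standards (zero residuals).
#'
#' @param measurements Measurement data.frame ([read_isotope_table()]).
#' @param standards Standards data.frame (`name`, `system`, `certified`,
#'   `measured`); at least two per system present in `measurements`, with
#'   non-zero spread in `measured`.
#' @return List: `measurements` (with `calibrated_delta` added) and `fits`
#'   (per-system data.frame `system`, `slope`, `intercept`, `max_residual`).
#' @export
calibrate <- function(measurements, standards) {
  systems <- unique(measurements$system)
  fits <- list()
  measurements$calibrated_delta <- NA_real_
  for (sys in systems) {
    st <- standards[standards$system == sys, , drop = FALSE]
    if (nrow(st) < 2L) {
      stop(sprintf("need >= 2 standards for system %s (got %d)", sys, nrow(st)))
    }
    if (diff(range(st$measured)) == 0) {
      stop(sprintf("zero spread in measured standards for system %s", sys))
    }
    fit <- stats::lm(certified ~ measured, data = st)
    co <- stats::coef(fit)
    rows <- measurements$system == sys
    measurements$calibrated_delta[rows] <-
      co[1] + co[2] * measurements$raw_delta[rows]
    fits[[sys]] <- data.frame(system = sys, slope = unname(co[2]),
                              intercept = unname(co[1]),
                              max_residual = max(abs(stats::residuals(fit))))
  }
  list(measurements = measurements, fits = do.call(rbind, fits))
}

#' Grouped isotope summary
#'
#' Means (also reported rounded to 1 decimal permil, the conventional
#' reporting precision), SD, n and range per site x taxon x system group.
#'
#' @param measurements Measurement data.frame; uses `calibrated_delta` when
#'   present, otherwise `raw_delta`.
#' @param by Grouping columns (default site, taxon, system).
#' @return data.frame, one row per group: grouping columns plus `n`, `mean`,
#'   `mean_1dp`, `sd` (NA for n = 1), `min`, `max`.
#' @export
group_summary <- function(measurements, by = c("site", "taxon", "system")) {
  val <- if ("calibrated_delta" %in% names(measurements) &&
             !all(is.na(measurements$calibrated_delta))) {
    measurements$calibrated_delta
  } else measurements$raw_delta
  key <- interaction(measurements[, by, drop = FALSE], drop = TRUE, sep = "\r")
  groups <- split(seq_along(val), key)
  out <- lapply(groups, function(i) {
    g <- measurements[i[1], by, drop = FALSE]
    v <- val[i]
    cbind(g, data.frame(n = length(v), mean = mean(v),
                        mean_1dp = round(mean(v), 1),
                        sd = if (length(v) > 1) stats::sd(v) else NA_real_,
                        min = min(v), max = max(v)))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Trophic offset between consumers and fauna
#'
#' Difference of group mean d15N values, flagged when it falls inside the
#' expected trophic-enrichment window (conventionally 3-5 permil per trophic
#' level for bone collagen nitrogen).
#'
#' @param humans,fauna Measurement data.frames restricted to one system each.
#' @param expected_range Numeric length-2 window in permil (default c(3, 5)).
#' @return List: `offset` (permil), `within_range`, `mean_humans`,
#'   `mean_fauna`, `system`.
#' @export
trophic_offset <- function(humans, fauna, expected_range = c(3, 5)) {
  if (nrow(humans) == 0L || nrow(fauna) == 0L) stop("both groups must be non-empty")
  sys <- unique(c(humans$system, fauna$system))
  if (length(sys) != 1L) stop("mixed isotope systems: ", paste(sys, collapse = ", "))
  value_of <- function(m) {
    if ("calibrated_delta" %in% names(m) && !all(is.na(m$calibrated_delta)))
      m$calibrated_delta else m$raw_delta
  }
  mh <- mean(value_of(humans)); mf <- mean(value_of(fauna))
  offset <- mh - mf
  list(offset = offset,
       within_range = offset >= expected_range[1] & offset <= expected_range[2],
       mean_humans = mh, mean_fauna = mf, system = sys)
}
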