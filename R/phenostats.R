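## Derived growth and physiology statistics: classical relative growth rate
## from paired harvest masses, its image-based per-plant variants, the
## diurnal leaf-rolling statistic, water-use efficiency from gravimetric
## watering logs, and the validation regressions linking image-derived to
## directly measured traits.

#' Relative growth rate from two harvest masses
#'
#' The classical two-point estimator
#' `R = (ln W2 - ln W1) / (t2 - t1)` in g per g per day; positive exactly
#' when the plant gained mass.
#'
#' @param W1,W2 dry masses (g) at the first and second harvest; must be
#'   positive.
#' @param t1,t2 harvest times (days), `t2 > t1`.
#' @return RGR in g g-1 d-1.
#' @examples
#' rgr_biomass(1, exp(1), 0, 1)  # 1
#' @export
rgr_biomass <- function(W1, W2, t1, t2) {
  if (any(W1 <= 0) || any(W2 <= 0)) stopf("harvest masses must be positive")
  if (any(t2 <= t1)) stopf("t2 must exceed t1")
  (log(W2) - log(W1)) / (t2 - t1)
}

#' Per-plant image-based RGR variants
#'
#' Two estimators of per-plant RGR from longitudinal projected leaf area.
#' `rgr_leaf_area` mimics the destructive-harvest design: the initial size
#' is the group-mean initial area (harvest cohorts necessarily pool plants)
#' while the final area is the individual plant's. `rgr_individual` uses the
#' plant's own initial and final areas, which removes the between-plant
#' variance injected by the pooled starting point.
#'
#' @param series data.frame with columns `plant_id`, `time`, `value`
#'   (projected leaf area).
#' @param group_initial optional mean initial area; defaults to the mean of
#'   the first observations across plants.
#' @return data.frame with one row per plant: `plant_id`, `rgr_leaf_area`,
#'   `rgr_individual`. Plants lacking two distinct timepoints are skipped
#'   with a warning.
#' @export
rgr_variants <- function(series, group_initial = NULL) {
  sp <- split(series, series$plant_id)
  ends <- lapply(sp, function(s) {
    s <- s[order(s$time), ]
    if (nrow(s) < 2L || s$time[1] == s$time[nrow(s)]) return(NULL)
    list(t0 = s$time[1], t1 = s$time[nrow(s)],
         a0 = s$value[1], a1 = s$value[nrow(s)])
  })
  skipped <- names(ends)[vapply(ends, is.null, logical(1))]
  if (length(skipped) > 0L)
    warnf("skipping plant(s) without two timepoints: %s",
          paste(skipped, collapse = ", "))
  ends <- Filter(Negate(is.null), ends)
  if (length(ends) == 0L) stopf("no plant has two timepoints")
  if (is.null(group_initial))
    group_initial <- mean(vapply(ends, `[[`, numeric(1), "a0"))
  out <- do.call(rbind, lapply(names(ends), function(id) {
    e <- ends[[id]]
    dt <- e$t1 - e$t0
    data.frame(plant_id = id,
               rgr_leaf_area = (log(e$a1) - log(group_initial)) / dt,
               rgr_individual = (log(e$a1) - log(e$a0)) / dt)
  }))
  rownames(out) <- NULL
  out
}

#' Diurnal leaf-rolling statistic
#'
#' Leaf rolling is quantified by imaging the same plants in the late
#' afternoon (rolled) and at pre-dawn (unrolled): per plant, the percentage
#' leaf-area increase `100 * (predawn - afternoon) / afternoon`. The summary
#' is the mean of per-plant percentages with its standard error and a
#' two-sided paired t-test on the area differences.
#'
#' @param pairs data.frame with columns `la_afternoon`, `la_predawn`
#'   (positive areas, any common unit).
#' @return list with `mean_pct_increase`, `se_pct_increase`, `p_value`
#'   (`NA`, with only the point estimate, for fewer than two pairs or a
#'   degenerate zero-difference sample), `n`, and per-plant `pct_increase`.
#' @export
leaf_rolling <- function(pairs) {
  af <- pairs$la_afternoon; pd <- pairs$la_predawn
  if (any(af <= 0) || any(pd <= 0)) stopf("areas must be positive")
  pct <- 100 * (pd - af) / af
  n <- length(pct)
  se <- if (n >= 2L) sd(pct) / sqrt(n) else NA_real_
  p <- if (n >= 2L && sd(pd - af) > 0) {
    t.test(pd, af, paired = TRUE)$p.value
  } else if (n >= 2L) 1 else NA_real_
  list(mean_pct_increase = mean(pct), se_pct_increase = se,
       p_value = p, n = n, pct_increase = pct)
}

#' Water-use efficiency from a gravimetric watering log
#'
#' Above-ground biomass produced per mass of water consumed, where
#' consumption is the cumulative water added to the planted pot over the
#' growth period. The definition includes soil-surface evaporation (the
#' inclusive, gravimetric definition); setting
#' `subtract_evaporation = TRUE` instead subtracts the mean control-pot
#' water use, giving a transpiration-only denominator.
#'
#' @param final_biomass_g above-ground dry biomass (g).
#' @param water_log data.frame from [generate_watering_log()] (or any log
#'   with columns `pot_type` and `water_added_g`).
#' @param subtract_evaporation logical, see above.
#' @return list with `wue_g_per_kg`, `water_used_kg` and
#'   `control_evaporation_kg` (per control pot, for context).
#' @export
wue <- function(final_biomass_g, water_log, subtract_evaporation = FALSE) {
  planted <- water_log[water_log$pot_type == "planted", ]
  control <- water_log[water_log$pot_type == "control", ]
  used_g <- sum(planted$water_added_g)
  evap_g <- if (nrow(control) > 0L)
    sum(control$water_added_g) / length(unique(control$pot_id)) else 0
  if (subtract_evaporation) used_g <- used_g - evap_g
  if (used_g <= 0) stopf("cumulative water use must be positive")
  list(wue_g_per_kg = final_biomass_g / (used_g / 1000),
       water_used_kg = used_g / 1000,
       control_evaporation_kg = evap_g / 1000)
}

#' Validation regression of measured on image-projected traits
#'
#' Ordinary least squares of a directly measured trait on its image-derived
#' projection, the standard check that imaging tracks ground truth (slope
#' near 1 and high R2 indicate a near one-to-one relationship).
#'
#' @param projected,measured paired numeric vectors, `n >= 3`.
#' @return list with `slope`, `intercept`, `r2`, `p_value` (slope t-test)
#'   and the underlying `lm` fit.
#' @export
validate_projection <- function(projected, measured) {
  if (length(projected) != length(measured) || length(projected) < 3L)
    stopf("need >= 3 paired observations")
  if (var(projected) == 0) stopf("projected values have zero variance")
  f <- lm(measured ~ projected)
  s <- summary(f)
  list(slope = unname(coef(f)[2]), intercept = unname(coef(f)[1]),
       r2 = s$r.squared, p_value = s$coefficients[2, 4], fit = f)
}

#' NIR grey value as a function of leaf thickness and moisture
#'
#' Two-predictor ordinary least squares `NIR ~ LMA + moisture`, testing
#' whether near-infrared reflectance is jointly driven by leaf mass per
#' area (leaf thickness) and tissue water content. Collinear predictors are
#' flagged rather than silently dropped.
#'
#' @param nir_grey mean NIR grey value per plant (8-bit scale).
#' @param lma leaf mass per unit area (g m-2).
#' @param moisture_pct tissue moisture content (%).
#' @return list with `coefficients` (intercept, LMA, moisture), `r2`,
#'   `p_value` (overall F), `collinear` flag and the `lm` fit.
#' @export
nir_regression <- function(nir_grey, lma, moisture_pct) {
  n <- length(nir_grey)
  if (n < 4L || length(lma) != n || length(moisture_pct) != n)
    stopf("need >= 4 complete cases")
  collinear <- var(lma) == 0 || var(moisture_pct) == 0 ||
    abs(cor(lma, moisture_pct)) > 1 - 1e-10
  f <- if (collinear && var(moisture_pct) == 0) {
    warnf("moisture is constant: reduced to a simple regression on LMA")
    lm(nir_grey ~ lma)
  } else if (collinear && var(lma) == 0) {
    warnf("LMA is constant: reduced to a simple regression on moisture")
    lm(nir_grey ~ moisture_pct)
  } else {
    if (collinear) warnf("LMA and moisture are collinear; coefficients unstable")
    lm(nir_grey ~ lma + moisture_pct)
  }
  s <- summary(f)
  pf_overall <- if (!is.null(s$fstatistic))
    unname(pf(s$fstatistic[1], s$fstatistic[2], s$fstatistic[3],
              lower.tail = FALSE)) else NA_real_
  list(coefficients = coef(f), r2 = s$r.squared, p_value = pf_overall,
       collinear = collinear, fit = f)
}
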