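## Synthetic plant image and trajectory generator.
##
## Renders grass-architecture plants (a vertical stem carrying strap leaves,
## with optional tillers) as one top view and two side views (0 and 90
## degrees) on a uniform background, exactly as a conveyor-type imaging
## cabinet captures them. Every rendered pixel is book-kept, so each image
## set comes with exact ground truth: per-view foreground counts, senescent
## pixel counts, height to the top and to the first ligule, the assigned
## mean hue and the near-infrared grey level. Downstream stages
## (segmentation, morphometrics, spectral traits) are validated against
## these known answers.

# ---------------------------------------------------------------------------
# specs

#' Specify a synthetic plant
#'
#' Bundles the geometric and spectral parameters of one rendered plant.
#' Geometry (and therefore all ground-truth pixel counts) is a deterministic
#' function of the spec; `seed` only drives pixel-level texture noise.
#'
#' @param n_leaves number of strap leaves.
#' @param leaf_length_px,leaf_width_px leaf ribbon dimensions in pixels.
#' @param stem_height_px stem height in pixels above the soil line.
#' @param ligule_height_px height of the lowest leaf insertion (the first
#'   ligule); must not exceed `stem_height_px`.
#' @param n_tillers number of lateral shoots drawn from the stem base.
#' @param senescent_fraction proportion of foreground pixels rendered in the
#'   senescent (yellow) hue, in `[0, 1]`. Leaf tips senesce first.
#' @param rolled logical; rolled leaves are drawn at half ribbon width, which
#'   realises leaf rolling as a known reduction in projected area.
#' @param green_hue_deg,yellow_hue_deg HSI hue angles of healthy and
#'   senescent tissue, degrees in `[0, 360)`.
#' @param background_rgb background colour, 8-bit RGB triple. The imaging
#'   cabinet background is a free parameter of the cabinet, not a constant.
#' @param nir_wet_grey,nir_dry_grey 8-bit NIR grey levels of fully hydrated
#'   and fully dry tissue; high grey means low water content.
#' @param moisture tissue moisture in `[0, 1]`; the NIR ground-truth grey is
#'   linear between the dry and wet levels.
#' @param texture_cv coefficient of variation of multiplicative brightness
#'   texture on foreground pixels (0 = noise-free rendering). Brightness
#'   scaling preserves hue, so spectral ground truth is unaffected.
#' @param stem_width_px stem thickness in pixels.
#' @param seed integer seed for texture noise.
#' @return an object of class `plant_spec`.
#' @export
plant_spec <- function(n_leaves = 6,
                       leaf_length_px = 60,
                       leaf_width_px = 6,
                       stem_height_px = 120,
                       ligule_height_px = 40,
                       n_tillers = 0,
                       senescent_fraction = 0,
                       rolled = FALSE,
                       green_hue_deg = 115,
                       yellow_hue_deg = 60,
                       background_rgb = c(120, 140, 190),
                       nir_wet_grey = 90,
                       nir_dry_grey = 170,
                       moisture = 0.8,
                       texture_cv = 0,
                       stem_width_px = 3,
                       seed = 1L) {
  spec <- list(n_leaves = n_leaves, leaf_length_px = leaf_length_px,
               leaf_width_px = leaf_width_px, stem_height_px = stem_height_px,
               ligule_height_px = ligule_height_px, n_tillers = n_tillers,
               senescent_fraction = senescent_fraction, rolled = rolled,
               green_hue_deg = green_hue_deg, yellow_hue_deg = yellow_hue_deg,
               background_rgb = as.integer(background_rgb),
               nir_wet_grey = nir_wet_grey, nir_dry_grey = nir_dry_grey,
               moisture = moisture, texture_cv = texture_cv,
               stem_width_px = stem_width_px, seed = as.integer(seed))
  validate_plant_spec(spec)
  structure(spec, class = "plant_spec")
}

validate_plant_spec <- function(spec) {
  if (!is_count(spec$n_leaves) || !is_count(spec$n_tillers))
    stopf("n_leaves and n_tillers must be nonnegative integers")
  if (!is_number(spec$senescent_fraction) ||
      spec$senescent_fraction < 0 || spec$senescent_fraction > 1)
    stopf("senescent_fraction must lie in [0, 1]")
  if (spec$ligule_height_px > spec$stem_height_px)
    stopf("ligule_height_px (%s) exceeds stem_height_px (%s)",
          spec$ligule_height_px, spec$stem_height_px)
  for (h in c(spec$green_hue_deg, spec$yellow_hue_deg))
    if (h < 0 || h >= 360) stopf("hues must lie in [0, 360)")
  if (length(spec$background_rgb) != 3L ||
      any(spec$background_rgb < 0 | spec$background_rgb > 255))
    stopf("background_rgb must be an 8-bit RGB triple")
  for (g in c(spec$nir_wet_grey, spec$nir_dry_grey))
    if (g < 0 || g > 255) stopf("NIR grey levels must lie in [0, 255]")
  if (spec$moisture < 0 || spec$moisture > 1)
    stopf("moisture must lie in [0, 1]")
  if (spec$texture_cv < 0) stopf("texture_cv must be >= 0")
  invisible(spec)
}

# ---------------------------------------------------------------------------
# raster primitives (row-major, origin top-left, y increases downward)

disc_offsets <- function(r) {
  r <- max(0L, as.integer(round(r)))
  g <- expand.grid(dy = -r:r, dx = -r:r)
  g[g$dy^2 + g$dx^2 <= r^2 + 1e-9, , drop = FALSE]
}

## Stamp discs of radius r at integer centres (rows ys, cols xs) onto a
## logical mask; pixels outside [row_min,row_max] x [1,ncol] are clipped.
stamp_disc <- function(mask, ys, xs, r, row_max = nrow(mask), row_min = 1L) {
  off <- disc_offsets(r)
  rows <- outer(round(ys), off$dy, "+")
  cols <- outer(round(xs), off$dx, "+")
  keep <- rows >= row_min & rows <= row_max & cols >= 1 & cols <= ncol(mask)
  mask[cbind(rows[keep], cols[keep])] <- TRUE
  mask
}

## Points along a quadratic Bezier curve, densely sampled.
bezier_xy <- function(p0, p1, p2) {
  chord <- sqrt(sum((p2 - p0)^2)) + sqrt(sum((p1 - p0)^2))
  n <- max(8L, ceiling(3 * chord))
  tt <- seq(0, 1, length.out = n)
  y <- (1 - tt)^2 * p0[1] + 2 * (1 - tt) * tt * p1[1] + tt^2 * p2[1]
  x <- (1 - tt)^2 * p0[2] + 2 * (1 - tt) * tt * p1[2] + tt^2 * p2[2]
  cbind(y, x)
}

GOLDEN_ANGLE <- 137.50776405

leaf_azimuths <- function(n) ((seq_len(n) - 1) * GOLDEN_ANGLE + 20) %% 360

leaf_ribbon_radius <- function(spec) {
  w <- spec$leaf_width_px
  if (spec$rolled) w <- w / 2        # rolling halves the projected ribbon width
  max(1L, as.integer(floor(w / 2)))
}

## Side-view silhouette mask; view_deg in {0, 90}. Returns the mask plus the
## soil-line (baseline) row.
render_side_mask <- function(spec, view_deg) {
  L <- spec$leaf_length_px
  h <- spec$stem_height_px + ceiling(0.6 * L) + 14L
  w <- 2L * (L + spec$leaf_width_px) + 17L
  mask <- matrix(FALSE, h, w)
  b <- h - 5L                              # baseline (soil line) row
  cx <- (w + 1L) %/% 2L
  half_stem <- (spec$stem_width_px - 1L) %/% 2L
  if (spec$stem_height_px > 0) {
    rows <- (b - spec$stem_height_px + 1L):b
    cols <- (cx - half_stem):(cx + half_stem)
    mask[rows, cols] <- TRUE
  }
  if (spec$n_tillers > 0 && spec$stem_height_px > 0) {
    th <- max(4L, round(0.6 * spec$stem_height_px))
    for (k in seq_len(spec$n_tillers)) {
      az <- (55 + 77 * k) %% 360
      proj <- cos((az - view_deg) * pi / 180)
      p0 <- c(b, cx)
      p2 <- c(b - th, cx + 0.45 * th * proj)
      p1 <- c(b - 0.5 * th, cx + 0.15 * th * proj)
      pts <- bezier_xy(p0, p1, p2)
      mask <- stamp_disc(mask, pts[, 1], pts[, 2], 1L, row_max = b)
    }
  }
  if (spec$n_leaves > 0 && spec$stem_height_px > 0) {
    az <- leaf_azimuths(spec$n_leaves)
    attach_h <- if (spec$n_leaves == 1L) spec$ligule_height_px else
      round(seq(spec$ligule_height_px, spec$stem_height_px,
                length.out = spec$n_leaves))
    rr <- leaf_ribbon_radius(spec)
    for (i in seq_len(spec$n_leaves)) {
      proj <- cos((az[i] - view_deg) * pi / 180)
      row0 <- b - attach_h[i] + 1L
      p0 <- c(row0, cx)
      p1 <- c(row0 - 0.45 * L, cx + 0.5 * L * proj)
      p2 <- c(row0 - 0.05 * L, cx + L * proj)
      pts <- bezier_xy(p0, p1, p2)
      mask <- stamp_disc(mask, pts[, 1], pts[, 2], rr, row_max = b)
    }
  }
  list(mask = mask, baseline_row = b)
}

## Top-view silhouette: stem cross-section plus radial leaf ribbons.
render_top_mask <- function(spec) {
  L <- spec$leaf_length_px
  s <- 2L * (L + spec$leaf_width_px + spec$stem_width_px) + 17L
  mask <- matrix(FALSE, s, s)
  c0 <- (s + 1L) %/% 2L
  if (spec$stem_height_px > 0)
    mask <- stamp_disc(mask, c0, c0, max(1L, ceiling(spec$stem_width_px / 2)))
  if (spec$n_tillers > 0 && spec$stem_height_px > 0) {
    for (k in seq_len(spec$n_tillers)) {
      az <- (55 + 77 * k) %% 360
      th <- max(4L, round(0.6 * spec$stem_height_px))
      d <- 0.45 * th
      mask <- stamp_disc(mask, c0 - d * sin(az * pi / 180),
                         c0 + d * cos(az * pi / 180), 1L)
    }
  }
  if (spec$n_leaves > 0 && spec$stem_height_px > 0) {
    az <- leaf_azimuths(spec$n_leaves)
    rr <- leaf_ribbon_radius(spec)
    for (i in seq_len(spec$n_leaves)) {
      a <- az[i] * pi / 180
      amid <- (az[i] + 14) * pi / 180
      p0 <- c(c0, c0)
      p1 <- c(c0 - 0.55 * L * sin(amid), c0 + 0.55 * L * cos(amid))
      p2 <- c(c0 - L * sin(a), c0 + L * cos(a))
      pts <- bezier_xy(p0, p1, p2)
      mask <- stamp_disc(mask, pts[, 1], pts[, 2], rr)
    }
  }
  list(mask = mask, baseline_row = NA_integer_)
}

# ---------------------------------------------------------------------------
# image synthesis

## Deterministic "senesce tips first" ordering: foreground pixels ranked by
## distance from the plant base (side views) or crown centre (top view).
senescence_order <- function(mask, baseline_row) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(idx)
  cx <- mean(range(idx[, 2]))
  ref_row <- if (is.na(baseline_row)) mean(range(idx[, 1])) else baseline_row
  score <- abs(ref_row - idx[, 1]) + abs(idx[, 2] - cx)
  idx[order(-score, idx[, 1], idx[, 2]), , drop = FALSE]
}

paint_view <- function(spec, mask, baseline_row) {
  h <- nrow(mask); w <- ncol(mask)
  img <- array(0L, c(h, w, 3L))
  for (ch in 1:3) img[, , ch] <- spec$background_rgb[ch]
  idx <- senescence_order(mask, baseline_row)
  n <- nrow(idx)
  n_sen <- round(spec$senescent_fraction * n)
  green_rgb <- hsi_to_rgb(spec$green_hue_deg, 0.65, 0.38)
  yellow_rgb <- hsi_to_rgb(spec$yellow_hue_deg, 0.65, 0.38)
  if (n > 0L) {
    fac <- if (spec$texture_cv > 0) {
      pmin(1.12, pmax(0.85, exp(rnorm(n, 0, spec$texture_cv))))
    } else rep(1, n)
    base <- matrix(rep(green_rgb, each = n), n, 3)
    if (n_sen > 0L)
      base[seq_len(n_sen), ] <- matrix(rep(yellow_rgb, each = n_sen), n_sen, 3)
    vals <- matrix(pmax(0L, pmin(255L, as.integer(round(base * fac)))), n, 3)
    for (ch in 1:3) img[cbind(idx, ch)] <- vals[, ch]
  }
  list(img = img, n_senescent = n_sen, n_fg = n,
       palette_fg = list(green_rgb, yellow_rgb))
}

paint_nir <- function(spec, mask, nir_sd = 2) {
  base_fg <- spec$nir_dry_grey +
    (spec$nir_wet_grey - spec$nir_dry_grey) * spec$moisture
  h <- nrow(mask); w <- ncol(mask)
  nir <- matrix(40L, h, w)
  n <- sum(mask)
  if (n > 0L) {
    noise <- if (spec$texture_cv > 0) rnorm(n, 0, nir_sd) else 0
    nir[mask] <- pmax(0L, pmin(255L, as.integer(round(base_fg + noise))))
  }
  nir
}

#' Render a synthetic plant image set with exact ground truth
#'
#' Draws the plant of a [plant_spec()] as three RGB rasters (top view and two
#' side views at 0 and 90 degrees) plus matching single-channel NIR rasters.
#' Leaves are filled quadratic-curve ribbons placed at golden-angle azimuths;
#' side views foreshorten each leaf by the cosine of its azimuth relative to
#' the camera. Geometry is fully deterministic; the seed affects only
#' brightness texture. A degenerate spec (no stem, no leaves) yields an
#' explicit empty image set rather than an error.
#'
#' @param spec a [plant_spec()].
#' @return an object of class `plant_image_set`: a list with elements
#'   `images` (named list of `h x w x 3` integer arrays `top`, `side0`,
#'   `side90`), `nir` (matching grey matrices), `masks` (true foreground
#'   masks), `truth` (ground-truth record, see Details), `palettes`
#'   (foreground/background reference colours for the segmentation
#'   classifier), `baseline_row`, and the spec itself.
#' @details The `truth` element carries `fg_pixels_per_view`,
#'   `senescent_pixels` (total and per view), `max_height_px` (soil line to
#'   topmost foreground row, counted in rows), `ligule_height_px`,
#'   `true_mean_hue_deg` (circular mean of the assigned hues) and
#'   `true_nir_grey` (the moisture-interpolated NIR level).
#' @export
generate_plant_images <- function(spec) {
  stopifnot(inherits(spec, "plant_spec"))
  validate_plant_spec(spec)
  empty <- spec$stem_height_px == 0 && spec$n_leaves == 0
  rendered <- list(
    top = render_top_mask(spec),
    side0 = render_side_mask(spec, 0),
    side90 = render_side_mask(spec, 90))
  out <- with_seed(spec$seed, {
    imgs <- list(); nirs <- list(); masks <- list()
    n_fg <- integer(3); n_sen <- integer(3)
    pal_fg <- NULL
    for (i in seq_along(rendered)) {
      v <- names(rendered)[i]
      pv <- paint_view(spec, rendered[[v]]$mask, rendered[[v]]$baseline_row)
      imgs[[v]] <- pv$img
      nirs[[v]] <- paint_nir(spec, rendered[[v]]$mask)
      masks[[v]] <- rendered[[v]]$mask
      n_fg[i] <- pv$n_fg; n_sen[i] <- pv$n_senescent
      pal_fg <- pv$palette_fg
    }
    list(imgs = imgs, nirs = nirs, masks = masks,
         n_fg = n_fg, n_sen = n_sen, pal_fg = pal_fg)
  })
  side_masks <- out$masks[c("side0", "side90")]
  b <- rendered$side0$baseline_row
  max_h <- 0L
  for (m in side_masks)
    if (any(m)) max_h <- max(max_h, b - min(which(rowSums(m) > 0)) + 1L)
  n_green_total <- sum(out$n_fg) - sum(out$n_sen)
  true_hue <- if (sum(out$n_fg) > 0) {
    circular_mean_deg(c(spec$green_hue_deg, spec$yellow_hue_deg),
                      w = c(n_green_total, sum(out$n_sen)))
  } else NA_real_
  truth <- list(
    fg_pixels_per_view = setNames(out$n_fg, names(rendered)),
    senescent_pixels = sum(out$n_sen),
    senescent_pixels_per_view = setNames(out$n_sen, names(rendered)),
    max_height_px = max_h,
    ligule_height_px = if (spec$n_leaves > 0) spec$ligule_height_px else max_h,
    true_mean_hue_deg = true_hue,
    true_nir_grey = spec$nir_dry_grey +
      (spec$nir_wet_grey - spec$nir_dry_grey) * spec$moisture)
  structure(list(
    images = out$imgs, nir = out$nirs, masks = out$masks, truth = truth,
    palettes = list(fg = out$pal_fg, bg = list(spec$background_rgb)),
    baseline_row = b, empty = empty, spec = spec),
    class = "plant_image_set")
}

#' @export
print.plant_image_set <- function(x, ...) {
  cat("<plant_image_set>\n")
  cat("  views:", paste(names(x$images), collapse = ", "), "\n")
  cat("  foreground px:", paste(sprintf("%s=%d", names(x$truth$fg_pixels_per_view),
                                        x$truth$fg_pixels_per_view), collapse = " "), "\n")
  cat(sprintf("  max height: %d px, ligule: %d px\n",
              x$truth$max_height_px, x$truth$ligule_height_px))
  invisible(x)
}

# ---------------------------------------------------------------------------
# growth trajectories

#' Specify a simulated growth trajectory ensemble
#'
#' @param model_name one of the eight growth models (see
#'   [growth_model_names()]).
#' @param params named list of model parameters, valid for `model_name`.
#' @param times strictly increasing vector of observation times (days after
#'   sowing).
#' @param noise_cv coefficient of variation of the multiplicative lognormal
#'   observation noise (unit mean, so trajectories stay positive and the
#'   ensemble is mean-unbiased).
#' @param n_plants number of plants to simulate.
#' @param seed integer seed.
#' @return an object of class `trajectory_spec`.
#' @export
trajectory_spec <- function(model_name, params, times, noise_cv = 0.05,
                            n_plants = 1L, seed = 1L) {
  model_name <- match.arg(model_name, growth_model_names())
  if (any(diff(times) <= 0)) stopf("times must be strictly increasing")
  if (noise_cv < 0) stopf("noise_cv must be >= 0")
  if (!is_count(n_plants) || n_plants < 1) stopf("n_plants must be >= 1")
  check_growth_params(model_name, params)
  ## fail fast if the curve is undefined anywhere on the grid
  invisible(evaluate_growth(model_name, params, times))
  structure(list(model_name = model_name, params = params, times = times,
                 noise_cv = noise_cv, n_plants = as.integer(n_plants),
                 seed = as.integer(seed)),
            class = "trajectory_spec")
}

#' Simulate longitudinal growth series
#'
#' Draws `n_plants` trajectories from the deterministic model curve with
#' multiplicative lognormal noise parameterised to unit mean: observed value
#' `M(t) * exp(e)` with `e ~ N(-s^2/2, s^2)` and
#' `s^2 = log(1 + noise_cv^2)`, so the sample CV at each time equals
#' `noise_cv` and the ensemble mean equals the model curve.
#'
#' @param tspec a [trajectory_spec()].
#' @return a data.frame with columns `plant_id`, `time`, `value` and
#'   attributes `model_name`, `params`, `noise_cv`.
#' @export
generate_growth_series <- function(tspec) {
  stopifnot(inherits(tspec, "trajectory_spec"))
  mu <- evaluate_growth(tspec$model_name, tspec$params, tspec$times)
  nt <- length(tspec$times)
  out <- with_seed(tspec$seed, {
    s <- sqrt(log(1 + tspec$noise_cv^2))
    fac <- if (tspec$noise_cv > 0) {
      rlnorm(nt * tspec$n_plants, meanlog = -s^2 / 2, sdlog = s)
    } else rep(1, nt * tspec$n_plants)
    data.frame(
      plant_id = rep(sprintf("plant_%03d", seq_len(tspec$n_plants)), each = nt),
      time = rep(tspec$times, tspec$n_plants),
      value = rep(mu, tspec$n_plants) * fac)
  })
  attr(out, "model_name") <- tspec$model_name
  attr(out, "params") <- tspec$params
  attr(out, "noise_cv") <- tspec$noise_cv
  out
}

# ---------------------------------------------------------------------------
# diurnal pairs and watering logs

#' Simulate afternoon/pre-dawn leaf-area pairs under leaf rolling
#'
#' Leaf rolling reduces the projected leaf area seen in the late afternoon;
#' the pre-dawn image shows the unrolled canopy. The afternoon area is
#' `predawn * (1 - rolling_loss)`.
#'
#' @param area_predawn vector of pre-dawn projected leaf areas (mm2).
#' @param rolling_loss scalar or per-plant vector of proportional area loss
#'   in `[0, 1)`.
#' @return data.frame with columns `plant_id`, `la_afternoon`, `la_predawn`.
#' @export
generate_diurnal_pair <- function(area_predawn, rolling_loss) {
  if (any(rolling_loss < 0 | rolling_loss >= 1))
    stopf("rolling_loss must lie in [0, 1)")
  if (any(area_predawn <= 0)) stopf("areas must be positive")
  n <- length(area_predawn)
  loss <- rep_len(rolling_loss, n)
  data.frame(plant_id = sprintf("plant_%03d", seq_len(n)),
             la_afternoon = area_predawn * (1 - loss),
             la_predawn = area_predawn)
}

#' Simulate a gravimetric pot-watering log
#'
#' Pots are weighed before and after each watering; the water added restores
#' the pot to its target weight, so the daily addition equals that day's
#' transpiration plus surface evaporation. Empty control pots lose water by
#' evaporation only.
#'
#' @param daily_transpiration vector of daily transpiration losses (g/day);
#'   recycled to `n_days`.
#' @param evaporation scalar or daily vector of soil-surface evaporation
#'   (g/day).
#' @param n_days number of days logged.
#' @param target_weight_g pot weight immediately after watering.
#' @return data.frame with one row per pot per day: `day`, `pot_id`,
#'   `pot_type` (`planted`/`control`), `weight_before_g`, `weight_after_g`,
#'   `water_added_g`.
#' @export
generate_watering_log <- function(daily_transpiration, evaporation = 0,
                                  n_days = length(daily_transpiration),
                                  target_weight_g = 2500) {
  if (any(daily_transpiration < 0) || any(evaporation < 0))
    stopf("losses must be nonnegative")
  tr <- rep_len(daily_transpiration, n_days)
  ev <- rep_len(evaporation, n_days)
  planted <- data.frame(day = seq_len(n_days), pot_id = "pot_planted",
                        pot_type = "planted",
                        weight_before_g = target_weight_g - (tr + ev),
                        weight_after_g = target_weight_g,
                        water_added_g = tr + ev)
  control <- data.frame(day = seq_len(n_days), pot_id = "pot_control",
                        pot_type = "control",
                        weight_before_g = target_weight_g - ev,
                        weight_after_g = target_weight_g,
                        water_added_g = ev)
  rbind(planted, control)
}

# ---------------------------------------------------------------------------
# PNG I/O

#' Write a plant image set to PNG files
#'
#' @param set a `plant_image_set`.
#' @param dir output directory (created if absent).
#' @param prefix filename prefix.
#' @return invisibly, the written file paths.
#' @export
write_image_set <- function(set, dir, prefix = "plant") {
  stopifnot(inherits(set, "plant_image_set"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  for (v in names(set$images)) {
    p <- file.path(dir, sprintf("%s_%s_rgb.png", prefix, v))
    png::writePNG(set$images[[v]] / 255, p)
    paths <- c(paths, p)
    p <- file.path(dir, sprintf("%s_%s_nir.png", prefix, v))
    png::writePNG(set$nir[[v]] / 255, p)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Read an 8-bit RGB PNG as an integer array
#'
#' @param path PNG file path.
#' @return `h x w x 3` integer array with values in `[0, 255]` (alpha
#'   discarded; grey images are replicated across channels).
#' @export
read_rgb_png <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 2L) a <- array(rep(a, 3L), c(dim(a), 3L))
  if (dim(a)[3] > 3L) a <- a[, , 1:3, drop = FALSE]
  array(as.integer(round(a * 255)), dim(a))
}

#' Read an 8-bit grey PNG as an integer matrix
#'
#' @param path PNG file path.
#' @return integer matrix with values in `[0, 255]`.
#' @export
read_grey_png <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 3L) a <- a[, , 1]
  matrix(as.integer(round(a * 255)), nrow(a), ncol(a))
}
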