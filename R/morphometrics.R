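## Pixel-to-physical calibration and canopy geometry.
##
## Side-view pixel areas convert to mm2 with a fixed factor (0.273 mm2 per
## pixel). The top-view factor depends on plant height, because a taller
## plant sits closer to the overhead camera: K_TV = 9.937e-5 * Y_ax +
## 0.061936, where Y_ax is the mean centre-of-mass row coordinate of the two
## side-view silhouettes (top-origin raster convention, so taller plants
## have a smaller Y_ax and a smaller K_TV). Both constants are area factors;
## linear measures (heights) use the square root of the side factor.
##
## Geometry is computed on foreground pixel centres with 0-based coordinates
## irrelevant to the results; polygon areas use the shoelace formula.

#' Camera calibration constants
#'
#' @param side_area_factor mm2 per side-view pixel.
#' @param tv_slope,tv_intercept coefficients of the height-dependent
#'   top-view area factor `K_TV(Y_ax) = tv_slope * Y_ax + tv_intercept`
#'   (mm2 per pixel per pixel of `Y_ax`, and mm2 per pixel).
#' @param side_linear_factor mm per pixel for linear measures; defaults to
#'   the square root of `side_area_factor`.
#' @return an object of class `camera_calibration`.
#' @export
camera_calibration <- function(side_area_factor = 0.273,
                               tv_slope = 9.937e-5,
                               tv_intercept = 0.061936,
                               side_linear_factor = sqrt(side_area_factor)) {
  vals <- c(side_area_factor, tv_slope, tv_intercept, side_linear_factor)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stopf("all calibration factors must be positive")
  structure(list(side_area_factor = side_area_factor, tv_slope = tv_slope,
                 tv_intercept = tv_intercept,
                 side_linear_factor = side_linear_factor),
            class = "camera_calibration")
}

#' Height-dependent top-view area factor
#'
#' @param y_ax mean centre-of-mass row of the two side-view masks, in pixels
#'   (top-origin).
#' @param calib a [camera_calibration()].
#' @return `K_TV` in mm2 per pixel.
#' @examples
#' topview_constant(0)     # 0.061936
#' topview_constant(1000)  # 0.161306
#' @export
topview_constant <- function(y_ax, calib = camera_calibration()) {
  stopifnot(inherits(calib, "camera_calibration"))
  if (any(y_ax < 0)) stopf("y_ax must be >= 0")
  calib$tv_slope * y_ax + calib$tv_intercept
}

## Mean centre-of-mass row over the nonempty side masks (pixels).
side_yax <- function(side_masks) {
  rows <- vapply(side_masks, function(m) {
    if (m$pixel_count == 0L) NA_real_ else unname(m$centroid_xy["y"])
  }, numeric(1))
  if (all(is.na(rows))) NA_real_ else mean(rows, na.rm = TRUE)
}

#' Projected leaf area from one top and two side views
#'
#' `area = top_px * K_TV(Y_ax) + (side0_px + side90_px) * side_area_factor`,
#' summing all three calibrated silhouettes into the biomass proxy.
#'
#' @param top_mask,side0_mask,side90_mask [plant_mask()]s of one timepoint.
#' @param calib a [camera_calibration()].
#' @return projected leaf area in mm2 (0, with a warning, if every view is
#'   empty).
#' @export
projected_leaf_area <- function(top_mask, side0_mask, side90_mask,
                                calib = camera_calibration()) {
  side_px <- side0_mask$pixel_count + side90_mask$pixel_count
  if (top_mask$pixel_count == 0L && side_px == 0L) {
    warnf("all views empty: projected leaf area is 0")
    return(0)
  }
  top_mm2 <- if (top_mask$pixel_count > 0L) {
    yax <- side_yax(list(side0_mask, side90_mask))
    if (is.na(yax)) yax <- 0
    top_mask$pixel_count * topview_constant(yax, calib)
  } else 0
  top_mm2 + side_px * calib$side_area_factor
}

# ---------------------------------------------------------------------------
# geometry on pixel centres

mask_coords <- function(mask) {
  m <- if (inherits(mask, "plant_mask")) mask$mask else mask
  idx <- which(m, arr.ind = TRUE)
  cbind(x = idx[, 2], y = idx[, 1])
}

shoelace_area <- function(xy) {
  n <- nrow(xy)
  if (n < 3L) return(0)
  x <- xy[, 1]; y <- xy[, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

#' Convex hull of a plant mask
#'
#' Hull of the foreground pixel centres; the smallest convex polygon that
#' envelopes the imaged plant. Area by the shoelace formula (0 for
#' degenerate, collinear masks).
#'
#' @param mask a [plant_mask()] or logical matrix with at least one pixel.
#' @return list with `vertices` (matrix of x, y in counter-clockwise order)
#'   and `area` (px2).
#' @export
convex_hull_mask <- function(mask) {
  xy <- mask_coords(mask)
  if (nrow(xy) == 0L) stopf("empty mask: convex hull undefined")
  if (nrow(xy) == 1L)
    return(list(vertices = xy, area = 0))
  h <- grDevices::chull(xy[, 1], xy[, 2])
  v <- xy[h, , drop = FALSE]
  list(vertices = v, area = shoelace_area(v))
}

circle_from2 <- function(p, q) {
  list(centre = (p + q) / 2, radius = sqrt(sum((p - q)^2)) / 2)
}

circle_from3 <- function(a, b, c) {
  d <- 2 * (a[1] * (b[2] - c[2]) + b[1] * (c[2] - a[2]) + c[1] * (a[2] - b[2]))
  if (abs(d) < 1e-12) return(NULL)           # collinear
  ux <- (sum(a^2) * (b[2] - c[2]) + sum(b^2) * (c[2] - a[2]) +
           sum(c^2) * (a[2] - b[2])) / d
  uy <- (sum(a^2) * (c[1] - b[1]) + sum(b^2) * (a[1] - c[1]) +
           sum(c^2) * (b[1] - a[1])) / d
  ctr <- c(ux, uy)
  list(centre = ctr, radius = sqrt(sum((a - ctr)^2)))
}

#' Minimum enclosing circle of a plant mask
#'
#' Smallest circle containing every foreground pixel centre. Because the
#' minimum enclosing circle of a point set is determined by its convex hull,
#' the search enumerates the two- and three-point support circles over hull
#' vertices and returns the smallest that contains them all (exact up to
#' 1e-9 relative tolerance).
#'
#' @param mask a [plant_mask()] or logical matrix with at least one pixel.
#' @return list with `centre` (x, y) and `radius` (px).
#' @export
min_enclosing_circle <- function(mask) {
  xy <- mask_coords(mask)
  if (nrow(xy) == 0L) stopf("empty mask: enclosing circle undefined")
  v <- unique(convex_hull_mask(mask)$vertices)
  if (nrow(v) == 1L) return(list(centre = as.numeric(v[1, ]), radius = 0))
  tol <- 1e-9
  contains_all <- function(circ) {
    d <- sqrt((v[, 1] - circ$centre[1])^2 + (v[, 2] - circ$centre[2])^2)
    all(d <= circ$radius * (1 + tol) + tol)
  }
  best <- NULL
  n <- nrow(v)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    circ <- circle_from2(v[i, ], v[j, ])
    if ((is.null(best) || circ$radius < best$radius) && contains_all(circ))
      best <- circ
  }
  if (n >= 3L) {
    for (i in seq_len(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
      circ <- circle_from3(v[i, ], v[j, ], v[k, ])
      if (!is.null(circ) && (is.null(best) || circ$radius < best$radius) &&
          contains_all(circ))
        best <- circ
    }
  }
  list(centre = as.numeric(best$centre), radius = best$radius)
}

#' Calliper length of a hull
#'
#' The longest dimension of the canopy: the maximum pairwise distance
#' between convex-hull vertices (the hull diameter). A single-point hull has
#' calliper length 0.
#'
#' @param hull result of [convex_hull_mask()].
#' @return length in pixels.
#' @export
calliper_length <- function(hull) {
  v <- hull$vertices
  if (nrow(v) < 2L) return(0)
  d2 <- outer(v[, 1], v[, 1], "-")^2 + outer(v[, 2], v[, 2], "-")^2
  sqrt(max(d2))
}

#' Compactness and surface coverage
#'
#' Compactness is the ratio of foreground (leaf) area to convex hull area, a
#' canopy-closure measure analogous to LAI; surface coverage is the ratio of
#' foreground area to the area of the minimum enclosing circle, a
#' size-independent canopy trait. Both are computed on the top view.
#'
#' @param mask a nonempty top-view [plant_mask()].
#' @param hull_area hull area in px2 (from [convex_hull_mask()]).
#' @param circle_radius radius in px (from [min_enclosing_circle()]).
#' @return list with `compactness` (`NA`, flagged by a warning, when the
#'   hull is degenerate) and `surface_coverage`.
#' @export
compactness_and_coverage <- function(mask, hull_area, circle_radius) {
  n <- if (inherits(mask, "plant_mask")) mask$pixel_count else sum(mask)
  if (n == 0L) stopf("empty mask")
  comp <- if (hull_area > 0) n / hull_area else {
    warnf("degenerate hull (area 0): compactness undefined")
    NA_real_
  }
  cov <- if (circle_radius > 0) n / (pi * circle_radius^2) else NA_real_
  list(compactness = comp, surface_coverage = cov)
}

#' Eccentricity of a plant mask
#'
#' Departure from radial symmetry, from the second-order central moments of
#' the foreground pixel coordinates: `e = sqrt(1 - l2/l1)` with
#' `l1 >= l2` the eigenvalues of the 2x2 coordinate covariance matrix.
#' 0 for a radially symmetric canopy, approaching 1 for a linear one.
#'
#' @param mask a [plant_mask()] or logical matrix with >= 3 pixels of
#'   non-degenerate scatter.
#' @return eccentricity in `[0, 1)`.
#' @export
mask_eccentricity <- function(mask) {
  xy <- mask_coords(mask)
  if (nrow(xy) < 3L) stopf("eccentricity needs >= 3 pixels")
  cx <- xy[, 1] - mean(xy[, 1]); cy <- xy[, 2] - mean(xy[, 2])
  sxx <- mean(cx^2); syy <- mean(cy^2); sxy <- mean(cx * cy)
  if (sxx + syy < 1e-12) stopf("degenerate mask: zero coordinate variance")
  ## closed-form eigenvalues of the 2x2 covariance matrix
  tr <- sxx + syy
  disc <- sqrt(max(0, (sxx - syy)^2 + 4 * sxy^2))
  l1 <- (tr + disc) / 2; l2 <- (tr - disc) / 2
  if (l1 <= 0) stopf("degenerate mask: zero coordinate variance")
  sqrt(max(0, 1 - l2 / l1))
}

#' Plant heights from the side views
#'
#' Maximum height runs from the baseline (the lowest foreground row, the
#' soil line with the pot excluded by the ROI) to the topmost foreground
#' row, counted in rows and scaled by the linear calibration factor; the
#' larger of the two side views is reported. Ligule height is detected as
#' the lowest row, scanning from the base upward, at which the object's row
#' extent exceeds `width_ratio` times the median stem width (estimated over
#' the lowest object rows); a plant with no such divergence (a leafless
#' stem) reports ligule height equal to maximum height.
#'
#' @param side_masks list of one or two side-view [plant_mask()]s.
#' @param calib a [camera_calibration()].
#' @param width_ratio divergence threshold relative to stem width.
#' @param n_base_rows number of basal rows used to estimate stem width.
#' @return list with `max_height` and `ligule_height`, both in mm, plus the
#'   underlying pixel measures.
#' @export
shoot_heights <- function(side_masks, calib = camera_calibration(),
                          width_ratio = 2.5, n_base_rows = 12) {
  side_masks <- Filter(function(m) m$pixel_count > 0L, side_masks)
  if (length(side_masks) == 0L) stopf("all side masks empty: heights undefined")
  per_view <- lapply(side_masks, function(pm) {
    m <- pm$mask
    occ <- which(rowSums(m) > 0)
    base_row <- max(occ); top_row <- min(occ)
    height_px <- base_row - top_row + 1L
    extent <- vapply(occ, function(r) {
      cols <- which(m[r, ])
      max(cols) - min(cols) + 1L
    }, numeric(1))
    names(extent) <- occ
    list(base_row = base_row, top_row = top_row, height_px = height_px,
         rows = occ, extent = extent)
  })
  best <- per_view[[which.max(vapply(per_view, `[[`, numeric(1), "height_px"))]]
  ## stem width from the basal rows, scanned bottom-up
  rows_up <- rev(best$rows)                     # base first
  ext_up <- best$extent[as.character(rows_up)]
  stem_w <- median(head(ext_up, n_base_rows))
  div <- which(ext_up > width_ratio * stem_w)
  ligule_px <- if (length(div) == 0L) best$height_px else
    best$base_row - rows_up[min(div)] + 1L
  list(max_height = best$height_px * calib$side_linear_factor,
       ligule_height = ligule_px * calib$side_linear_factor,
       max_height_px = best$height_px, ligule_height_px = ligule_px)
}

# ---------------------------------------------------------------------------
# trait record

#' Extract the full per-timepoint trait record from segmented views
#'
#' Combines the calibrated projected leaf area, heights, top-view shape
#' descriptors, colour traits and the pooled side-view NIR grey value into
#' one phenotype record.
#'
#' @param masks named list of [plant_mask()]s (`top`, `side0`, `side90`).
#' @param set the source `plant_image_set` (for colour and NIR rasters).
#' @param calib a [camera_calibration()].
#' @param bands a [hue_bands()] definition.
#' @return a one-row data.frame of traits (class `shoot_traits`).
#' @export
shoot_traits <- function(masks, set, calib = camera_calibration(),
                         bands = hue_bands()) {
  top <- masks$top
  area <- projected_leaf_area(top, masks$side0, masks$side90, calib)
  geom <- if (top$pixel_count >= 3L) {
    hull <- convex_hull_mask(top)
    mec <- min_enclosing_circle(top)
    cc <- compactness_and_coverage(top, hull$area, mec$radius)
    yax <- side_yax(masks[c("side0", "side90")])
    ktv <- topview_constant(if (is.na(yax)) 0 else yax, calib)
    ## top-view linear measures scale with the square root of the local
    ## top-view area factor
    list(hull_area = hull$area * ktv,
         calliper = calliper_length(hull) * sqrt(ktv),
         min_circle_radius = mec$radius * sqrt(ktv),
         compactness = cc$compactness, surface_coverage = cc$surface_coverage,
         eccentricity = mask_eccentricity(top))
  } else list(hull_area = NA_real_, calliper = NA_real_,
              min_circle_radius = NA_real_, compactness = NA_real_,
              surface_coverage = NA_real_, eccentricity = NA_real_)
  hts <- tryCatch(shoot_heights(masks[c("side0", "side90")], calib),
                  error = function(e) list(max_height = NA_real_,
                                           ligule_height = NA_real_))
  hue <- tryCatch(
    mean_hue_views(masks, set$images),
    error = function(e) NA_real_)
  sen <- tryCatch(
    senescence_fraction_views(masks, set$images, bands),
    error = function(e) NA_real_)
  nir <- tryCatch(
    overlay_nir_views(set$nir[c("side0", "side90")],
                      masks[c("side0", "side90")]),
    error = function(e) NA_real_)
  out <- data.frame(
    projected_leaf_area = area,
    max_height = hts$max_height, ligule_height = hts$ligule_height,
    hull_area = geom$hull_area, compactness = geom$compactness,
    calliper_length = geom$calliper,
    min_circle_radius = geom$min_circle_radius,
    surface_coverage = geom$surface_coverage,
    eccentricity = geom$eccentricity,
    mean_hue_deg = hue, senescent_fraction = sen, nir_mean_grey = nir)
  class(out) <- c("shoot_traits", class(out))
  out
}
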