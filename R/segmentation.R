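## Foreground extraction.
##
## Plants are separated from the uniform imaging background by
## nearest-neighbour colour classification against small reference palettes,
## cleaned by erosion/dilation with a disc structuring element, and all
## surviving connected components are composed into a single plant object.
## The RGB-derived object then serves as a mask for the co-registered NIR
## raster.

#' Build a nearest-neighbour colour classifier
#'
#' @param fg_palette,bg_palette lists of reference RGB triples (8-bit) for
#'   foreground (plant) and background. A pixel is labelled foreground iff
#'   its nearest reference sample, by squared Euclidean distance in RGB
#'   space, is a foreground sample; exact ties resolve to background so that
#'   plant area is never inflated by ambiguous pixels.
#' @return an object of class `color_classifier`.
#' @export
color_classifier <- function(fg_palette, bg_palette) {
  as_pal <- function(p) {
    if (is.numeric(p) && length(p) == 3L) p <- list(p)
    if (length(p) == 0L) return(matrix(numeric(0), 0L, 3L))
    do.call(rbind, lapply(p, function(x) {
      if (length(x) != 3L || any(x < 0 | x > 255))
        stopf("palette entries must be 8-bit RGB triples")
      as.numeric(x)
    }))
  }
  fg <- as_pal(fg_palette); bg <- as_pal(bg_palette)
  if (nrow(fg) == 0L || nrow(bg) == 0L) stopf("both palettes must be non-empty")
  key <- function(m) apply(m, 1, paste, collapse = ",")
  if (length(intersect(key(fg), key(bg))) > 0L)
    stopf("foreground and background palettes must be disjoint")
  structure(list(fg = fg, bg = bg), class = "color_classifier")
}

#' Classify pixels as plant or background
#'
#' Nearest-neighbour colour classification within a rectangular region of
#' interest; everything outside the ROI is background (this is how the
#' visible imaging hardware is excluded).
#'
#' @param image `h x w x 3` integer array, 8-bit RGB.
#' @param clf a [color_classifier()].
#' @param roi `c(row_min, row_max, col_min, col_max)`, or `NULL` for the
#'   whole image.
#' @return logical matrix, `TRUE` = foreground.
#' @export
classify_pixels <- function(image, clf, roi = NULL) {
  stopifnot(inherits(clf, "color_classifier"), length(dim(image)) == 3L)
  h <- dim(image)[1]; w <- dim(image)[2]
  if (is.null(roi)) roi <- c(1L, h, 1L, w)
  if (roi[1] > roi[2] || roi[3] > roi[4]) stopf("empty ROI")
  if (roi[1] < 1 || roi[2] > h || roi[3] < 1 || roi[4] > w)
    stopf("ROI exceeds image bounds")
  sub <- image[roi[1]:roi[2], roi[3]:roi[4], , drop = FALSE]
  px <- cbind(as.numeric(sub[, , 1]), as.numeric(sub[, , 2]),
              as.numeric(sub[, , 3]))
  dist2_to <- function(pal) {
    d <- matrix(Inf, nrow(px), nrow(pal))
    for (j in seq_len(nrow(pal)))
      d[, j] <- (px[, 1] - pal[j, 1])^2 + (px[, 2] - pal[j, 2])^2 +
        (px[, 3] - pal[j, 3])^2
    do.call(pmin, as.data.frame(d))
  }
  dfg <- dist2_to(clf$fg)
  dbg <- dist2_to(clf$bg)
  lab <- dfg < dbg                       # ties -> background
  out <- matrix(FALSE, h, w)
  out[roi[1]:roi[2], roi[3]:roi[4]] <- lab
  out
}

#' Morphological cleanup and composition into one plant object
#'
#' Removes classification noise by erosion followed by dilation with disc
#' structuring elements, discards connected components smaller than
#' `min_component_px`, and unites everything that remains into a single
#' plant mask (composition is a union, never a largest-component pick, so
#' tillers separated from the main stem survive).
#'
#' @param binary logical matrix from [classify_pixels()].
#' @param erosion_radius,dilation_radius disc radii in pixels (0 = skip).
#' @param min_component_px minimum connected-component size retained
#'   (8-connectivity).
#' @param view_label one of `"top"`, `"side0"`, `"side90"`.
#' @return an object of class `plant_mask`: list with `mask`, `pixel_count`,
#'   `centroid_xy` (col, row; `NA` when empty), `view_label`, `empty` flag.
#' @export
clean_and_compose <- function(binary, erosion_radius = 1, dilation_radius = 1,
                              min_component_px = 5, view_label = "top") {
  stopifnot(is.matrix(binary), erosion_radius >= 0, dilation_radius >= 0)
  m <- binary * 1
  ## explicit rasterised disc: cell (dy, dx) on iff dy^2 + dx^2 <= r^2
  disc_kernel <- function(r) {
    r <- as.integer(round(r))
    d <- expand.grid(dy = -r:r, dx = -r:r)
    matrix(as.numeric(d$dy^2 + d$dx^2 <= r^2 + 1e-9), 2L * r + 1L)
  }
  if (erosion_radius > 0)
    m <- EBImage::erode(m, disc_kernel(erosion_radius))
  if (dilation_radius > 0)
    m <- EBImage::dilate(m, disc_kernel(dilation_radius))
  if (min_component_px > 0 && any(m > 0)) {
    lab <- EBImage::bwlabel(m)
    sizes <- tabulate(lab[lab > 0])
    keep <- which(sizes >= min_component_px)
    m <- matrix(as.numeric(lab %in% keep), nrow(m), ncol(m))
  }
  plant_mask(m > 0, view_label)
}

#' Construct a plant mask from a logical matrix
#'
#' @param mask logical matrix.
#' @param view_label view identifier.
#' @return a `plant_mask` object.
#' @export
plant_mask <- function(mask, view_label = "top") {
  stopifnot(is.matrix(mask))
  mask <- mask & TRUE
  n <- sum(mask)
  centroid <- if (n > 0L) {
    idx <- which(mask, arr.ind = TRUE)
    c(x = mean(idx[, 2]), y = mean(idx[, 1]))
  } else c(x = NA_real_, y = NA_real_)
  structure(list(mask = mask, pixel_count = as.integer(n),
                 centroid_xy = centroid, view_label = view_label,
                 empty = n == 0L),
            class = "plant_mask")
}

#' @export
print.plant_mask <- function(x, ...) {
  cat(sprintf("<plant_mask %s> %d px%s\n", x$view_label, x$pixel_count,
              if (x$empty) " (empty, flagged)" else ""))
  invisible(x)
}

#' Mean NIR grey value under a plant mask
#'
#' Overlays the RGB-derived plant object onto the co-registered NIR raster
#' and returns the arithmetic mean grey value on the 8-bit scale. High grey
#' values indicate high reflectance and therefore low tissue water content.
#'
#' @param nir integer matrix (8-bit grey).
#' @param mask a [plant_mask()] of the same dimensions.
#' @return mean grey value in `[0, 255]`.
#' @export
overlay_nir <- function(nir, mask) {
  stopifnot(inherits(mask, "plant_mask"))
  if (!all(dim(nir) == dim(mask$mask)))
    stopf("NIR raster and mask dimensions differ")
  if (mask$pixel_count == 0L) stopf("empty mask: mean NIR grey is undefined")
  mean(nir[mask$mask])
}

#' Mean NIR grey pooled over the two side views
#'
#' The NIR trait is measured from both side-view images; the reported value
#' is the mean over the union of the two masked pixel sets (each view's
#' pixels weighted equally, i.e. a pixel-count-weighted mean of the per-view
#' means).
#'
#' @param nirs list of two NIR matrices.
#' @param masks list of two corresponding [plant_mask()]s.
#' @return pooled mean grey value.
#' @export
overlay_nir_views <- function(nirs, masks) {
  stopifnot(length(nirs) == length(masks), length(nirs) >= 1L)
  tot <- 0; n <- 0L
  for (i in seq_along(nirs)) {
    if (masks[[i]]$pixel_count == 0L) next
    tot <- tot + sum(nirs[[i]][masks[[i]]$mask])
    n <- n + masks[[i]]$pixel_count
  }
  if (n == 0L) stopf("all masks empty: mean NIR grey is undefined")
  tot / n
}

#' Segment a full image set
#'
#' Convenience wrapper running [classify_pixels()] and [clean_and_compose()]
#' on each view of a synthetic or loaded image set using its reference
#' palettes.
#'
#' @param set a `plant_image_set`.
#' @param erosion_radius,dilation_radius,min_component_px passed to
#'   [clean_and_compose()].
#' @param roi optional ROI applied to every view.
#' @return named list of [plant_mask()]s (`top`, `side0`, `side90`).
#' @export
segment_image_set <- function(set, erosion_radius = 0, dilation_radius = 0,
                              min_component_px = 0, roi = NULL) {
  stopifnot(inherits(set, "plant_image_set"))
  clf <- color_classifier(set$palettes$fg, set$palettes$bg)
  out <- list()
  for (v in names(set$images)) {
    bin <- classify_pixels(set$images[[v]], clf, roi)
    out[[v]] <- clean_and_compose(bin, erosion_radius, dilation_radius,
                                  min_component_px, view_label = v)
  }
  out
}
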