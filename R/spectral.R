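## Colour-space traits: HSI hue angle as a greenness index and the
## green/yellow senescence fraction. Hue is an angle, so all averaging is
## circular; for vegetation hues far from the 0/360 wrap the circular and
## arithmetic means coincide.

#' Hue band definitions for senescence scoring
#'
#' Half-open intervals `[low, high)` on the hue circle defining healthy
#' (green) and senescent (yellow) tissue. The category boundaries are
#' configurable; the defaults put yellow at `[40, 80)` and green at
#' `[80, 160)` degrees.
#'
#' @param green_band,yellow_band numeric `c(low, high)` in degrees.
#' @return an object of class `hue_bands`.
#' @export
hue_bands <- function(green_band = c(80, 160), yellow_band = c(40, 80)) {
  chk <- function(b, nm) {
    if (length(b) != 2L || any(b < 0 | b > 360) || b[1] >= b[2])
      stopf("%s must be an increasing interval within [0, 360]", nm)
  }
  chk(green_band, "green_band"); chk(yellow_band, "yellow_band")
  if (max(green_band[1], yellow_band[1]) < min(green_band[2], yellow_band[2]))
    stopf("green and yellow bands must be disjoint")
  structure(list(green = green_band, yellow = yellow_band),
            class = "hue_bands")
}

in_band <- function(hue, band) !is.na(hue) & hue >= band[1] & hue < band[2]

masked_hues <- function(mask, image) {
  m <- if (inherits(mask, "plant_mask")) mask$mask else mask
  if (sum(m) == 0L) stopf("empty mask")
  idx <- which(m, arr.ind = TRUE)
  rgb_to_hsi(image[cbind(idx, 1L)], image[cbind(idx, 2L)],
             image[cbind(idx, 3L)])$hue_deg
}

#' Mean hue angle under a mask
#'
#' Circular mean of the hue angles of the masked chromatic pixels;
#' achromatic pixels (undefined hue) are excluded.
#'
#' @param mask a [plant_mask()] or logical matrix.
#' @param image `h x w x 3` 8-bit RGB array.
#' @return mean hue in degrees `[0, 360)`.
#' @export
mean_hue <- function(mask, image) {
  hue <- masked_hues(mask, image)
  if (all(is.na(hue))) stopf("no chromatic pixels under mask")
  circular_mean_deg(hue)
}

#' Senescent leaf-area fraction under a mask
#'
#' Classifies masked pixels into the green and yellow hue bands and returns
#' `yellow / (green + yellow)`. Pixels falling in neither band (stems,
#' specular highlights, achromatic pixels) are excluded from both counts.
#'
#' @inheritParams mean_hue
#' @param bands a [hue_bands()] definition.
#' @return proportion in `[0, 1]`.
#' @export
senescence_fraction <- function(mask, image, bands = hue_bands()) {
  hue <- masked_hues(mask, image)
  ng <- sum(in_band(hue, bands$green))
  ny <- sum(in_band(hue, bands$yellow))
  if (ng + ny == 0L) stopf("no pixels in either hue band")
  ny / (ng + ny)
}

## Multi-view pooled versions: every masked pixel across the supplied views
## contributes equally.
mean_hue_views <- function(masks, images) {
  hues <- unlist(lapply(names(masks), function(v) {
    if (masks[[v]]$pixel_count == 0L) return(numeric(0))
    masked_hues(masks[[v]], images[[v]])
  }))
  if (length(hues) == 0L || all(is.na(hues)))
    stopf("no chromatic pixels under any mask")
  circular_mean_deg(hues)
}

senescence_fraction_views <- function(masks, images, bands = hue_bands()) {
  hues <- unlist(lapply(names(masks), function(v) {
    if (masks[[v]]$pixel_count == 0L) return(numeric(0))
    masked_hues(masks[[v]], images[[v]])
  }))
  ng <- sum(in_band(hues, bands$green))
  ny <- sum(in_band(hues, bands$yellow))
  if (ng + ny == 0L) stopf("no pixels in either hue band")
  ny / (ng + ny)
}
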