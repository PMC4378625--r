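## RGB <-> HSI colour transforms.
##
## The HSI (hue, saturation, intensity) system expresses hue as an angle on
## the colour circle (red 0, yellow 60, green 120 degrees); it is the standard
## space for scoring leaf "greenness" in visible-spectrum plant imaging.

#' Convert RGB values to HSI
#'
#' Applies the classical geometric HSI transform to 8-bit RGB channels.
#' Hue is returned in degrees in `[0, 360)`; saturation and intensity in
#' `[0, 1]`. Achromatic pixels (`R == G == B`) have no defined hue and
#' return `NA` for both hue and (when intensity is zero) saturation.
#'
#' @param r,g,b numeric vectors of equal length, channel values in `[0, 255]`.
#' @return a data.frame with columns `hue_deg`, `saturation`, `intensity`.
#' @examples
#' rgb_to_hsi(0, 255, 0)$hue_deg    # pure green: 120
#' rgb_to_hsi(255, 255, 0)$hue_deg  # pure yellow: 60
#' @export
rgb_to_hsi <- function(r, g, b) {
  if (any(c(r, g, b) < 0 | c(r, g, b) > 255, na.rm = TRUE))
    stopf("RGB channels must lie in [0, 255]")
  r1 <- r / 255; g1 <- g / 255; b1 <- b / 255
  intensity <- (r1 + g1 + b1) / 3
  mn <- pmin(r1, g1, b1)
  saturation <- ifelse(intensity > 0, 1 - mn / intensity, NA_real_)
  num <- ((r1 - g1) + (r1 - b1)) / 2
  den <- sqrt((r1 - g1)^2 + (r1 - b1) * (g1 - b1))
  achromatic <- den < .Machine$double.eps^0.5
  ct <- ifelse(achromatic, NA_real_, pmin(1, pmax(-1, num / den)))
  theta <- acos(ct) * 180 / pi
  hue <- ifelse(b1 <= g1, theta, 360 - theta)
  hue[achromatic] <- NA_real_
  hue[!is.na(hue) & hue >= 360] <- 0
  data.frame(hue_deg = hue, saturation = saturation, intensity = intensity)
}

#' Convert an HSI triple to 8-bit RGB
#'
#' Inverse of [rgb_to_hsi()], used by the synthetic image generator to render
#' foreground colours whose measured hue equals a prescribed angle (up to
#' 8-bit quantization).
#'
#' @param hue_deg hue angle in degrees, `[0, 360)`.
#' @param saturation,intensity values in `[0, 1]`.
#' @return integer vector `c(r, g, b)` in `[0, 255]`.
#' @export
hsi_to_rgb <- function(hue_deg, saturation, intensity) {
  stopifnot(hue_deg >= 0, hue_deg < 360,
            saturation >= 0, saturation <= 1,
            intensity >= 0, intensity <= 1)
  h <- hue_deg %% 360
  sector <- findInterval(h, c(0, 120, 240, 360), rightmost.closed = TRUE)
  h <- h - c(0, 120, 240)[sector]
  hr <- h * pi / 180
  x <- intensity * (1 - saturation)
  y <- intensity * (1 + saturation * cos(hr) / cos(pi / 3 - hr))
  z <- 3 * intensity - (x + y)
  rgb1 <- switch(sector,
    c(y, z, x),   # 0-120: red sector
    c(x, y, z),   # 120-240: green sector
    c(z, x, y))   # 240-360: blue sector
  as.integer(pmax(0, pmin(255, round(rgb1 * 255))))
}

## Circular mean of angles in degrees; NA if no finite input.
circular_mean_deg <- function(deg, w = NULL) {
  deg <- deg[is.finite(deg)]
  if (length(deg) == 0L) return(NA_real_)
  if (is.null(w)) w <- rep(1, length(deg))
  rad <- deg * pi / 180
  ang <- atan2(sum(w * sin(rad)), sum(w * cos(rad))) * 180 / pi
  ang %% 360
}
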