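# Independent brute-force oracles for the geometry operations, plus small
# fixture builders. These deliberately avoid the package's own geometry code
# paths: naive enumeration only.

# random scatter mask: n distinct pixels in a size x size grid
rand_mask <- function(n, size = 40, seed = 1) {
  set.seed(seed)
  idx <- sample(size * size, n)
  m <- matrix(FALSE, size, size)
  m[idx] <- TRUE
  m
}

mask_xy <- function(m) {
  idx <- which(m, arr.ind = TRUE)
  cbind(x = idx[, 2], y = idx[, 1])
}

# is point p inside or on the convex polygon with vertices v (any order
# given; reordered by angle here)? cross-product sign test.
point_in_polygon_convex <- function(p, v, tol = 1e-9) {
  if (nrow(v) == 1L) return(all(abs(p - v[1, ]) < tol))
  ctr <- colMeans(v)
  v <- v[order(atan2(v[, 2] - ctr[2], v[, 1] - ctr[1])), , drop = FALSE]
  n <- nrow(v)
  s <- vapply(seq_len(n), function(i) {
    a <- v[i, ]; b <- v[if (i == n) 1L else i + 1L, ]
    (b[1] - a[1]) * (p[2] - a[2]) - (b[2] - a[2]) * (p[1] - a[1])
  }, numeric(1))
  all(s >= -tol) || all(s <= tol)
}

# boundary-point oracle: p lies on the hull boundary iff some line through p
# and another point has every point on one side
oracle_is_boundary <- function(p_idx, xy, tol = 1e-9) {
  p <- xy[p_idx, ]
  others <- xy[-p_idx, , drop = FALSE]
  for (j in seq_len(nrow(others))) {
    q <- others[j, ]
    s <- (q[1] - p[1]) * (xy[, 2] - p[2]) - (q[2] - p[2]) * (xy[, 1] - p[1])
    if (all(s >= -tol) || all(s <= tol)) return(TRUE)
  }
  FALSE
}

# strict extreme-point oracle (O(n^3) per point): p is a hull vertex iff it
# is not contained in a segment or triangle of the other points
oracle_hull_vertices <- function(xy, tol = 1e-9) {
  n <- nrow(xy)
  in_tri <- function(p, a, b, c) {
    d <- (b[2] - c[2]) * (a[1] - c[1]) + (c[1] - b[1]) * (a[2] - c[2])
    if (abs(d) < tol) return(FALSE)
    l1 <- ((b[2] - c[2]) * (p[1] - c[1]) + (c[1] - b[1]) * (p[2] - c[2])) / d
    l2 <- ((c[2] - a[2]) * (p[1] - c[1]) + (a[1] - c[1]) * (p[2] - c[2])) / d
    l3 <- 1 - l1 - l2
    l1 >= -tol && l2 >= -tol && l3 >= -tol
  }
  on_seg <- function(p, a, b) {
    cr <- (b[1] - a[1]) * (p[2] - a[2]) - (b[2] - a[2]) * (p[1] - a[1])
    if (abs(cr) > tol) return(FALSE)
    dt <- (p[1] - a[1]) * (b[1] - a[1]) + (p[2] - a[2]) * (b[2] - a[2])
    dt >= -tol && dt <= sum((b - a)^2) + tol
  }
  vapply(seq_len(n), function(i) {
    p <- xy[i, ]
    o <- xy[-i, , drop = FALSE]
    m <- nrow(o)
    for (a in seq_len(m)) {
      if (all(abs(o[a, ] - p) < tol)) return(FALSE)
      if (a < m) for (b in (a + 1):m) {
        if (on_seg(p, o[a, ], o[b, ])) return(FALSE)
        if (b < m) for (cc in (b + 1):m)
          if (in_tri(p, o[a, ], o[b, ], o[cc, ])) return(FALSE)
      }
    }
    TRUE
  }, logical(1))
}

# exhaustive minimum enclosing circle: smallest two- or three-point support
# circle (over ALL points, not hull vertices) containing every point
oracle_mec <- function(xy, tol = 1e-9) {
  n <- nrow(xy)
  best_r <- Inf; best_c <- NULL
  contains <- function(ctr, r) {
    all(sqrt((xy[, 1] - ctr[1])^2 + (xy[, 2] - ctr[2])^2) <= r * (1 + tol) + tol)
  }
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    ctr <- (xy[i, ] + xy[j, ]) / 2
    r <- sqrt(sum((xy[i, ] - xy[j, ])^2)) / 2
    if (r < best_r && contains(ctr, r)) { best_r <- r; best_c <- ctr }
  }
  if (n >= 3) for (i in seq_len(n - 2)) for (j in (i + 1):(n - 1))
    for (k in (j + 1):n) {
      a <- xy[i, ]; b <- xy[j, ]; cc <- xy[k, ]
      d <- 2 * (a[1] * (b[2] - cc[2]) + b[1] * (cc[2] - a[2]) +
                  cc[1] * (a[2] - b[2]))
      if (abs(d) < 1e-12) next
      ux <- (sum(a^2) * (b[2] - cc[2]) + sum(b^2) * (cc[2] - a[2]) +
               sum(cc^2) * (a[2] - b[2])) / d
      uy <- (sum(a^2) * (cc[1] - b[1]) + sum(b^2) * (a[1] - cc[1]) +
               sum(cc^2) * (b[1] - a[1])) / d
      r <- sqrt(sum((a - c(ux, uy))^2))
      if (r < best_r && contains(c(ux, uy), r)) { best_r <- r; best_c <- c(ux, uy) }
    }
  list(centre = best_c, radius = best_r)
}

# optimality certificate for an enclosing circle: contains every point, and
# is supported either by two (near-)diametral boundary points or by three
# boundary points whose triangle contains the centre
mec_certificate_ok <- function(xy, mec, tol = 1e-6) {
  d <- sqrt((xy[, 1] - mec$centre[1])^2 + (xy[, 2] - mec$centre[2])^2)
  if (any(d > mec$radius * (1 + tol) + tol)) return(FALSE)
  if (mec$radius == 0) return(TRUE)
  sup <- which(d >= mec$radius * (1 - tol) - tol)
  if (length(sup) < 2L) return(FALSE)
  # two diametrically opposite support points?
  for (i in sup) for (j in sup) if (i < j) {
    if (sqrt(sum((xy[i, ] - xy[j, ])^2)) >= 2 * mec$radius * (1 - tol))
      return(TRUE)
  }
  if (length(sup) < 3L) return(FALSE)
  # centre inside some support triangle?
  for (i in sup) for (j in sup) for (k in sup) if (i < j && j < k) {
    v <- xy[c(i, j, k), , drop = FALSE]
    if (point_in_polygon_convex(mec$centre, v, tol = 1e-7)) return(TRUE)
  }
  FALSE
}

# all-pairs maximum distance over every foreground pixel
oracle_calliper <- function(xy) {
  if (nrow(xy) < 2) return(0)
  d2 <- outer(xy[, 1], xy[, 1], "-")^2 + outer(xy[, 2], xy[, 2], "-")^2
  sqrt(max(d2))
}

# eigen-decomposition oracle for eccentricity
oracle_eccentricity <- function(xy) {
  S <- stats::cov(xy) * (nrow(xy) - 1) / nrow(xy)
  ev <- sort(eigen(S, symmetric = TRUE)$values, decreasing = TRUE)
  sqrt(1 - ev[2] / ev[1])
}

# naive morphology with a disc structuring element (pure R, no EBImage)
naive_morph <- function(m, r, op = c("erode", "dilate")) {
  op <- match.arg(op)
  off <- expand.grid(dy = -r:r, dx = -r:r)
  off <- off[off$dy^2 + off$dx^2 <= r^2 + 1e-9, ]
  h <- nrow(m); w <- ncol(m)
  out <- matrix(FALSE, h, w)
  for (i in seq_len(h)) for (j in seq_len(w)) {
    ys <- i + off$dy; xs <- j + off$dx
    ok <- ys >= 1 & ys <= h & xs >= 1 & xs <= w
    vals <- m[cbind(ys[ok], xs[ok])]
    out[i, j] <- if (op == "erode") {
      all(vals) && sum(ok) == nrow(off)   # border treated as background
    } else any(vals)
  }
  out
}

make_series <- function(model_name, params, times, noise_cv = 0,
                        n_plants = 1, seed = 1) {
  s <- generate_growth_series(trajectory_spec(model_name, params, times,
                                              noise_cv, n_plants, seed))
  data.frame(time = s$time, value = s$value)
}
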