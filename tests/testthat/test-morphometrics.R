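px_mask <- function(coords, size = 40) {
  m <- matrix(FALSE, size, size)
  m[cbind(coords[, 2], coords[, 1])] <- TRUE   # coords given as (x, y)
  m
}

test_that("the top-view calibration constant is affine in Y_ax", {
  expect_identical(topview_constant(0), 0.061936)
  expect_equal(topview_constant(1000), 0.161306)
  y <- seq(0, 2000, 100)
  expect_true(all(diff(topview_constant(y)) > 0))
  expect_error(topview_constant(-1), "y_ax")
})

test_that("projected leaf area sums the calibrated views", {
  m_of_n <- function(n, size = 60, at_row = 30) {
    m <- matrix(FALSE, size, size)
    if (n > 0) {
      k <- seq_len(n) - 1L           # fill row-major starting at at_row
      m[cbind(at_row + k %/% size, k %% size + 1L)] <- TRUE
    }
    plant_mask(m)
  }
  # side views only: 2000 px at 0.273 mm2/px
  a <- projected_leaf_area(m_of_n(0), m_of_n(1000), m_of_n(1000))
  expect_equal(a, 546)
  # top view only with empty sides: Y_ax falls back to 0
  top1000 <- m_of_n(1000)
  expect_equal(projected_leaf_area(top1000, m_of_n(0), m_of_n(0)), 61.936)
  expect_warning(a0 <- projected_leaf_area(m_of_n(0), m_of_n(0), m_of_n(0)),
                 "empty")
  expect_equal(a0, 0)
  # Y_ax is the mean centre-of-mass row of the side masks
  s <- m_of_n(10, at_row = 50)
  expect_equal(projected_leaf_area(top1000, s, s),
               1000 * topview_constant(50) + 20 * 0.273)
})

test_that("convex hull matches examples and the extreme-point oracle", {
  sq <- px_mask(cbind(c(1, 1, 11, 11), c(1, 11, 1, 11)), size = 15)
  h <- convex_hull_mask(sq)
  expect_equal(h$area, 100)
  col3 <- px_mask(cbind(c(2, 5, 8), c(2, 5, 8)), size = 10)
  h3 <- convex_hull_mask(col3)
  expect_equal(h3$area, 0)
  expect_error(convex_hull_mask(matrix(FALSE, 4, 4)), "empty")
  # brute-force extreme-point oracle on random scatters
  for (seed in 1:5) {
    m <- rand_mask(25, size = 25, seed = seed)
    xy <- mask_xy(m)
    got <- convex_hull_mask(m)$vertices
    want <- xy[oracle_hull_vertices(xy), , drop = FALSE]
    key <- function(v) sort(paste(v[, 1], v[, 2]))
    expect_identical(key(got), key(want))
  }
})

test_that("minimum enclosing circle matches closed forms and brute force", {
  two <- px_mask(cbind(c(2, 8), c(3, 3)), size = 12)
  mec <- min_enclosing_circle(two)
  expect_equal(mec$radius, 3)
  expect_equal(mec$centre, c(5, 3))
  # equilateral-ish triangle scaled: circumradius = side / sqrt(3)
  tri <- matrix(c(0, 0, 12, 0, 6, round(12 * sqrt(3) / 2)), ncol = 2,
                byrow = TRUE) + 5
  mtri <- px_mask(tri, size = 25)
  expect_equal(min_enclosing_circle(mtri)$radius,
               oracle_mec(mask_xy(mtri))$radius, tolerance = 1e-9)
  for (seed in 1:5) {
    m <- rand_mask(20, size = 30, seed = 100 + seed)
    got <- min_enclosing_circle(m)
    want <- oracle_mec(mask_xy(m))
    expect_equal(got$radius, want$radius, tolerance = 1e-9)
  }
})

test_that("calliper length is the hull diameter", {
  sq <- px_mask(cbind(c(1, 1, 11, 11), c(1, 11, 1, 11)), size = 15)
  expect_equal(calliper_length(convex_hull_mask(sq)), 10 * sqrt(2))
  seg <- px_mask(cbind(2:9, rep(4, 8)), size = 12)
  expect_equal(calliper_length(convex_hull_mask(seg)), 7)
  one <- px_mask(cbind(3, 3), size = 5)
  expect_equal(calliper_length(convex_hull_mask(one)), 0)
  for (seed in 1:5) {
    m <- rand_mask(40, size = 30, seed = 200 + seed)
    expect_equal(calliper_length(convex_hull_mask(m)),
                 oracle_calliper(mask_xy(m)))
  }
})

test_that("compactness and surface coverage match hand counts", {
  # plus sign: 5 cells of a cross, hull is the 4 arm tips
  plus <- px_mask(cbind(c(5, 3, 7, 5, 5), c(5, 5, 5, 3, 7)), size = 10)
  h <- convex_hull_mask(plus)
  mec <- min_enclosing_circle(plus)
  cc <- compactness_and_coverage(plus, h$area, mec$radius)
  expect_equal(cc$compactness, 5 / 8)        # hull of tips: diamond, area 8
  expect_equal(cc$surface_coverage, 5 / (pi * 4))  # radius 2
  expect_lte(cc$surface_coverage, cc$compactness)
  # filled disc: compactness ~ 1 up to pixelation
  d <- disc_mask <- matrix(FALSE, 41, 41)
  for (i in 1:41) for (j in 1:41)
    if ((i - 21)^2 + (j - 21)^2 <= 15^2) d[i, j] <- TRUE
  hd <- convex_hull_mask(d)
  cd <- compactness_and_coverage(d, hd$area, min_enclosing_circle(d)$radius)
  expect_equal(cd$compactness, 1, tolerance = 0.05)
  # degenerate hull flags compactness as undefined
  seg <- px_mask(cbind(2:6, rep(3, 5)), size = 8)
  expect_warning(
    c2 <- compactness_and_coverage(seg, convex_hull_mask(seg)$area,
                                   min_enclosing_circle(seg)$radius),
    "degenerate")
  expect_true(is.na(c2$compactness))
})

test_that("eccentricity follows the moment eigenvalues", {
  d <- matrix(FALSE, 41, 41)
  for (i in 1:41) for (j in 1:41)
    if ((i - 21)^2 + (j - 21)^2 <= 15^2) d[i, j] <- TRUE
  expect_lt(mask_eccentricity(d), 0.05)
  # 2:1 axis-ratio ellipse: eigenvalue ratio 4:1, e = sqrt(3)/2
  e <- matrix(FALSE, 41, 81)
  for (i in 1:41) for (j in 1:81)
    if (((i - 21) / 15)^2 + ((j - 41) / 30)^2 <= 1) e[i, j] <- TRUE
  expect_equal(mask_eccentricity(e), sqrt(3) / 2, tolerance = 0.01)
  for (seed in 1:5) {
    m <- rand_mask(50, size = 30, seed = 300 + seed)
    expect_equal(mask_eccentricity(m), oracle_eccentricity(mask_xy(m)),
                 tolerance = 1e-12)
  }
  expect_error(mask_eccentricity(px_mask(cbind(1:2, c(1, 1)), 5)), "3 pixels")
})

test_that("heights recover stem and ligule geometry", {
  f <- camera_calibration()$side_linear_factor
  spec <- plant_spec(n_leaves = 0, stem_height_px = 200, ligule_height_px = 0,
                     seed = 1)
  set <- generate_plant_images(spec)
  masks <- segment_image_set(set)
  h <- shoot_heights(masks[c("side0", "side90")])
  expect_equal(h$max_height, 200 * f)
  # leafless stem: no divergence point, ligule falls back to max height
  expect_equal(h$ligule_height, h$max_height)
  # leafy plant: detected ligule within 5% of the drawn insertion height
  spec2 <- plant_spec(n_leaves = 6, stem_height_px = 160,
                      ligule_height_px = 60, leaf_length_px = 70, seed = 2)
  set2 <- generate_plant_images(spec2)
  masks2 <- segment_image_set(set2)
  h2 <- shoot_heights(masks2[c("side0", "side90")])
  expect_lt(abs(h2$ligule_height_px - set2$truth$ligule_height_px),
            0.05 * set2$truth$max_height_px)
  expect_error(shoot_heights(list(plant_mask(matrix(FALSE, 3, 3)))), "empty")
})

test_that("the geometric ordering chain holds on scatter masks", {
  for (seed in 1:20) {
    m <- rand_mask(sample(10:80, 1), size = 35, seed = 400 + seed)
    n <- sum(m)
    h <- convex_hull_mask(m)
    mec <- min_enclosing_circle(m)
    cal <- calliper_length(h)
    expect_lte(h$area, pi * mec$radius^2 + 1e-9)
    expect_lte(cal, 2 * mec$radius + 1e-9)
    # on scatter masks the pixel-count area sits below the hull area
    expect_lte(n, h$area)
  }
})

test_that("projected area tracks drawn ground-truth area across sizes", {
  sizes <- seq(25, 75, length.out = 8)
  proj <- drawn <- numeric(length(sizes))
  calib <- camera_calibration()
  for (i in seq_along(sizes)) {
    L <- round(sizes[i])
    spec <- plant_spec(n_leaves = 5, leaf_length_px = L,
                       stem_height_px = round(1.8 * L),
                       ligule_height_px = round(0.6 * L), seed = i)
    set <- generate_plant_images(spec)
    masks <- segment_image_set(set)
    proj[i] <- projected_leaf_area(masks$top, masks$side0, masks$side90, calib)
    tm <- lapply(names(set$masks), function(v) plant_mask(set$masks[[v]], v))
    names(tm) <- names(set$masks)
    drawn[i] <- projected_leaf_area(tm$top, tm$side0, tm$side90, calib)
  }
  sl <- coef(lm(proj ~ drawn))[2]
  expect_lt(abs(sl - 1), 0.05)
})
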