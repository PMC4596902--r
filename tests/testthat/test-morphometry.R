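test_that("Crofton perimeter matches analytic and oracle values", {
  for (r in c(50, 100)) {
    g <- geom_of_mask(rasterize_disk(r))
    expect_lt(abs(crofton_perimeter(g) - 2 * pi * r) / (2 * pi * r), 0.03)
  }

  # independent rle-based chord counter agrees exactly on arbitrary masks
  withr::with_seed(13, {
    for (k in 1:5) {
      m <- mask_dilate(matrix(runif(900) < 0.2, 30, 30), 1)
      lab <- open_and_label(m, min_area = 1, opening_radius = 0)
      for (id in lab$objects$id) {
        g <- object_geometry(lab, id)
        expect_equal(crofton_perimeter(g), crofton_oracle(g$mask), tolerance = 1e-12)
        expect_equal(crofton_perimeter(g, directions = 2),
          crofton_oracle(g$mask, directions = 2),
          tolerance = 1e-12
        )
      }
    }
  })

  sq <- geom_of_mask(rasterize_rect(100, 100))
  expect_equal(crofton_perimeter(sq), crofton_oracle(rasterize_rect(100, 100)),
    tolerance = 1e-12
  )

  # hand evaluation for a single pixel: one chord per direction
  px <- geom_of_mask(rasterize_rect(1, 1))
  expect_equal(crofton_perimeter(px), (pi / 4) * (2 + sqrt(2)), tolerance = 1e-12)
})

test_that("equivalent-ellipse axes recover disk and ellipse dimensions", {
  g <- geom_of_mask(rasterize_disk(50))
  ax <- equivalent_ellipse_axes(g)
  expect_lt(abs(ax[["l_max"]] - 100) / 100, 0.02)
  expect_lt(abs(ax[["l_min"]] - 100) / 100, 0.02)

  g2 <- geom_of_mask(rasterize_ellipse(60, 20))
  ax2 <- equivalent_ellipse_axes(g2)
  expect_lt(abs(ax2[["l_max"]] - 120) / 120, 0.03)
  expect_lt(abs(ax2[["l_min"]] - 40) / 40, 0.03)

  g3 <- geom_of_mask(rasterize_ellipse(60, 20, angle = pi / 6))
  ax3 <- equivalent_ellipse_axes(g3)
  expect_lt(abs(ax3[["l_max"]] - ax2[["l_max"]]) / ax2[["l_max"]], 0.03)
  expect_lt(abs(ax3[["l_min"]] - ax2[["l_min"]]) / ax2[["l_min"]], 0.03)
})

test_that("convex hull metrics: square, plus-sign, triangle", {
  sq <- geom_of_mask(rasterize_rect(100, 100))
  hm <- convex_hull_metrics(sq)
  expect_equal(hm[["A_conv"]], 100^2, tolerance = 1e-12)
  expect_equal(hm[["CMA"]], pi / 2, tolerance = 1e-9)

  plus <- matrix(FALSE, 60, 60)
  plus[25:35, 10:50] <- TRUE
  plus[10:50, 25:35] <- TRUE
  gp <- geom_of_mask(plus)
  hp <- convex_hull_metrics(gp)
  expect_gt(hp[["A_conv"]], gp$area)
  expect_lt(gp$area / hp[["A_conv"]], 1)

  # equilateral triangle raster, side ~120
  side <- 120
  h <- side * sqrt(3) / 2
  xs <- 1:140
  tri <- outer(seq_len(ceiling(h) + 8), xs, function(y, x) {
    yy <- y - 4
    xx <- x - 70
    yy >= 0 & yy <= h & abs(xx) <= (1 - yy / h) * side / 2
  })
  gt <- geom_of_mask(tri)
  expect_lt(abs(convex_hull_metrics(gt)[["CMA"]] - pi / 3), 0.05)
})

test_that("SMD vanishes for centrally symmetric shapes and matches the oracle", {
  gd <- geom_of_mask(rasterize_disk(40))
  smd <- symmetry_mean_difference(gd)
  expect_lt(smd[["SMD"]], 0.01 * 40)
  expect_equal(smd[["SMD_sum"]], smd[["SMD"]] * 180, tolerance = 1e-9)

  ge <- geom_of_mask(rasterize_ellipse(50, 18))
  expect_lt(symmetry_mean_difference(ge)[["SMD"]], 0.02 * 50)

  # half-disk: strictly positive and equal to the independent pairing oracle
  half <- rasterize_disk(40)
  half[1:44, ] <- FALSE # remove the upper half (centre at row 45)
  gh <- geom_of_mask(half)
  smd_h <- symmetry_mean_difference(gh)[["SMD"]]
  expect_gt(smd_h, 1)
  expect_equal(smd_h, smd_oracle(gh), tolerance = 1e-9)
})

test_that("Feret diameters: disk, rectangle, and grid-vs-calipers agreement", {
  gd <- geom_of_mask(rasterize_disk(50))
  fd <- feret_diameters(gd)
  expect_lt(abs(fd[["FD_max"]] - 100) / 100, 0.02)
  expect_lt(abs(fd[["FD_min"]] - 100) / 100, 0.02)

  gr <- geom_of_mask(rasterize_rect(120, 40))
  fr <- feret_diameters(gr)
  expect_lt(abs(fr[["FD_max"]] - sqrt(120^2 + 40^2)) / sqrt(120^2 + 40^2), 0.02)
  expect_lt(abs(fr[["FD_min"]] - 40) / 40, 0.02)

  # 1-degree grid vs exact calipers on random convex hulls
  withr::with_seed(31, {
    for (k in 1:50) {
      pts <- cbind(runif(40, 0, 80), runif(40, 0, 80))
      fake <- list(hull = pts[grDevices::chull(pts), , drop = FALSE])
      class(fake) <- "object_geometry"
      a <- feret_diameters(fake, method = "calipers")
      b <- feret_diameters(fake, method = "grid", grid_step = 1)
      expect_lt(abs(a[["FD_max"]] - b[["FD_max"]]) / a[["FD_max"]], 0.005)
      expect_lt(abs(a[["FD_min"]] - b[["FD_min"]]) / a[["FD_min"]], 0.005)
    }
  })
})

test_that("shape factors follow their closed forms", {
  # ideal-circle substitutions on a high-resolution raster
  ft <- features_of_mask(rasterize_disk(100))
  expect_lt(ft$SF_elong, 0.01)
  expect_lt(abs(ft$SF_sfer - 1), 0.02)
  expect_lt(abs(ft$SF_comp - 4 / pi) / (4 / pi), 0.03)
  expect_lt(abs(ft$SF_conv - 1), 0.02)

  # 3:1 ellipse: SF_elong = (3 - 1) / (3 + 1) = 0.5
  fe <- features_of_mask(rasterize_ellipse(90, 30))
  expect_lt(abs(fe$SF_elong - 0.5), 0.01)

  expect_error(
    shape_factors(A = 10, p_crof = 5, l_max = 0, l_min = 0, a_conv = 12, fd_max = 4),
    "degenerate"
  )
})

test_that("feature table covers a mixed scene and honours invariants", {
  m <- matrix(FALSE, 220, 220)
  disks <- list(c(40, 40), c(40, 120), c(40, 190))
  for (d in disks) {
    m[outer(1:220, 1:220, function(y, x) (y - d[1])^2 + (x - d[2])^2 <= 15^2)] <- TRUE
  }
  m[120:124, 20:140] <- TRUE # thin bar 1
  m[180:184, 60:200] <- TRUE # thin bar 2
  lab <- open_and_label(m, min_area = 50, opening_radius = 0)
  ft <- compute_feature_table(lab)
  expect_equal(nrow(ft), 5L)
  bars <- ft[ft$SF_elong > 0.7, ]
  disks_ft <- ft[ft$SF_elong < 0.2, ]
  expect_equal(nrow(bars), 2L)
  expect_equal(nrow(disks_ft), 3L)
  expect_true(all(ft$A_conv >= ft$A))
  expect_true(all(ft$FD_max >= ft$FD_min))
  expect_true(all(ft$FD_min > 0))
  expect_true(all(ft$SF_conv > 0 & ft$SF_conv <= 1.02))
  expect_true(all(ft$SF_sfer <= 1.02))
  expect_true(all(ft$SF_elong >= 0 & ft$SF_elong < 1))

  empty <- open_and_label(matrix(FALSE, 20, 20))
  expect_equal(nrow(compute_feature_table(empty)), 0L)
})

test_that("features are rotation invariant (90 deg exactly, 30 deg within 3%)", {
  m <- rasterize_ellipse(45, 18, angle = 0.4)
  rot90 <- t(m)[ncol(m):1, , drop = FALSE]
  f0 <- features_of_mask(m)
  f90 <- features_of_mask(rot90)
  for (col in setdiff(names(f0), c("id"))) {
    expect_equal(f90[[col]], f0[[col]], tolerance = 1e-9, label = paste("90deg", col))
  }

  f30 <- features_of_mask(rasterize_ellipse(45, 18, angle = 0.4 + pi / 6))
  for (col in c(
    "A", "P_crof", "SF_comp", "l_max", "l_min", "SF_elong", "A_conv",
    "P_conv", "SF_conv", "SMD", "FD_max", "FD_min", "SF_sfer"
  )) {
    expect_lt(abs(f30[[col]] - f0[[col]]) / max(abs(f0[[col]]), 1e-6), 0.03,
      label = paste("30deg", col)
    )
  }
})

test_that("doubling the raster resolution scales features as expected", {
  f1 <- features_of_mask(rasterize_ellipse(40, 16, angle = 0.3))
  f2 <- features_of_mask(rasterize_ellipse(80, 32, angle = 0.3))
  for (col in c("SF_comp", "SF_elong", "SF_conv", "SF_sfer")) {
    expect_lt(abs(f2[[col]] - f1[[col]]) / abs(f1[[col]]), 0.02, label = col)
  }
  expect_lt(abs(f2$A / f1$A - 4), 4 * 0.05)
  for (col in c("P_crof", "l_max", "l_min", "P_conv", "FD_max", "FD_min")) {
    expect_lt(abs(f2[[col]] / f1[[col]] - 2), 2 * 0.03, label = col)
  }
})

test_that("mm-per-px calibration rescales dimensional features only", {
  m <- rasterize_ellipse(30, 14)
  f1 <- features_of_mask(m)
  f2 <- features_of_mask(m, mm_per_px = 0.33)
  expect_equal(f2$A, f1$A * 0.33^2)
  expect_equal(f2$P_conv, f1$P_conv * 0.33)
  expect_equal(f2$FD_max, f1$FD_max * 0.33)
  expect_equal(f2$SF_comp, f1$SF_comp)
  expect_equal(f2$CMA, f1$CMA)
})

test_that("feature CSV round-trips with the canonical column order", {
  ft <- features_of_mask(rasterize_disk(20))
  f <- withr::local_tempfile(fileext = ".csv")
  write_feature_csv(ft, f)
  back <- read_feature_csv(f)
  expect_identical(
    names(back)[1:15],
    c(
      "id", "A", "P_crof", "SF_comp", "l_max", "l_min", "SF_elong",
      "A_conv", "P_conv", "SF_conv", "CMA", "SMD", "FD_max", "FD_min", "SF_sfer"
    )
  )
  expect_equal(back$SF_sfer, ft$SF_sfer, tolerance = 1e-9)
})
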