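#' Per-object geometry extracted from a label map
#'
#' Collects everything the shape descriptors need for one labelled object:
#' its pixel set, centroid, boundary pixels and convex hull. Coordinates are
#' (x = column, y = row) in pixels. The convex hull is taken over the corner
#' points of the boundary pixels (each pixel treated as a unit square), so
#' hull area, hull perimeter and Feret diameters measure the actual
#' union-of-squares object; this guarantees `A_conv >= A`.
#'
#' @param objs A `labeled_objects` result from [open_and_label()], or a plain
#'   integer label map.
#' @param id Object id (a positive label present in the map).
#' @return A list of class `object_geometry` with fields `x`, `y` (pixel
#'   centres), `area`, `centroid`, `boundary` (x/y of boundary pixel centres),
#'   `hull` (two-column matrix of hull vertices, corner coordinates), and the
#'   cropped `mask`.
#' @export
object_geometry <- function(objs, id) {
  lab <- if (inherits(objs, "labeled_objects")) objs$label_map else objs
  idx <- which(lab == id, arr.ind = TRUE)
  if (nrow(idx) == 0L) abort(paste0("no object with id ", id, " in label map"))
  y <- idx[, 1]
  x <- idx[, 2]

  # cropped mask with a 1-px pad so boundary tests see background
  y0 <- min(y) - 1L
  x0 <- min(x) - 1L
  m <- matrix(FALSE, max(y) - y0 + 2L, max(x) - x0 + 2L)
  m[cbind(y - y0 + 1L, x - x0 + 1L)] <- TRUE

  inner <- m &
    shift_mat(m, 1L, 0L) & shift_mat(m, -1L, 0L) &
    shift_mat(m, 0L, 1L) & shift_mat(m, 0L, -1L)
  bidx <- which(m & !inner, arr.ind = TRUE)
  by <- bidx[, 1] + y0 - 1L
  bx <- bidx[, 2] + x0 - 1L

  # pixel-corner cloud of the boundary pixels -> convex hull of the object
  cx <- c(bx - 0.5, bx - 0.5, bx + 0.5, bx + 0.5)
  cy <- c(by - 0.5, by + 0.5, by - 0.5, by + 0.5)
  hull <- NULL
  if (length(unique(cx)) > 1L || length(unique(cy)) > 1L) {
    h <- grDevices::chull(cx, cy)
    hull <- cbind(x = cx[h], y = cy[h])
  }
  # pixel-centre hull: used for corner angles, where the half-pixel squares of
  # the corner cloud would blunt every sharp vertex toward 90 degrees
  hull_centers <- NULL
  hc <- grDevices::chull(bx, by)
  if (length(hc) >= 3L) hull_centers <- cbind(x = bx[hc], y = by[hc])

  structure(
    list(
      x = x, y = y, area = length(x),
      centroid = c(x = mean(x), y = mean(y)),
      boundary = list(x = bx, y = by),
      hull = hull,
      hull_centers = hull_centers,
      mask = m, offset = c(y0 = y0, x0 = x0)
    ),
    class = "object_geometry"
  )
}

#' @export
print.object_geometry <- function(x, ...) {
  cat(sprintf(
    "<object_geometry> %d px, centroid (%.1f, %.1f), %s hull vertices\n",
    x$area, x$centroid["x"], x$centroid["y"],
    if (is.null(x$hull)) "no" else nrow(x$hull)
  ))
  invisible(x)
}

#' Crofton perimeter estimate
#'
#' Estimates an object's perimeter from chord counts along 4 directions
#' (0, 45, 90, 135 degrees):
#' `P = (pi/4) * (c0 + c90 + (c45 + c135)/sqrt(2))`,
#' where `c_theta` is the number of object chords along scan lines in
#' direction theta (diagonal lines are spaced `1/sqrt(2)` apart, hence the
#' weight). The estimator is exact in expectation for isotropic convex bodies
#' and unbiased for a disk (`P = 2*pi*r`). A 2-direction variant
#' (`P = (pi/2) * (c0 + c90)`) is available for comparison.
#'
#' @param obj An [object_geometry()].
#' @param directions 4 (default) or 2.
#' @return Perimeter estimate in pixels.
#' @export
crofton_perimeter <- function(obj, directions = 4) {
  m <- obj$mask
  chords <- function(di, dj) sum(m & !shift_mat(m, di, dj, fill = FALSE))
  c0 <- chords(0L, 1L) # horizontal runs
  c90 <- chords(1L, 0L) # vertical runs
  if (directions == 2) {
    return((pi / 2) * (c0 + c90))
  }
  c45 <- chords(1L, 1L)
  c135 <- chords(1L, -1L)
  (pi / 4) * (c0 + c90 + (c45 + c135) / sqrt(2))
}

#' Equivalent-ellipse major and minor axis lengths
#'
#' Full lengths of the axes of the ellipse with the same second central
#' moments as the object's pixel set (each pixel contributes its unit-square
#' moment, + 1/12 per coordinate), the standard rotation-invariant estimator
#' behind the elongation factor. For a solid ellipse with semi-axes a >= b the
#' variance along the major axis is a^2/4, so lengths are `4 * sqrt(eigen)`.
#'
#' @param obj An [object_geometry()].
#' @return Named numeric `c(l_max, l_min)` in pixels, `l_max >= l_min`.
#' @export
equivalent_ellipse_axes <- function(obj) {
  if (obj$area < 2L) abort("object too small for axis estimation (area < 2 px)")
  dx <- obj$x - obj$centroid["x"]
  dy <- obj$y - obj$centroid["y"]
  mxx <- mean(dx^2) + 1 / 12
  myy <- mean(dy^2) + 1 / 12
  mxy <- mean(dx * dy)
  ev <- eigen(matrix(c(mxx, mxy, mxy, myy), 2L), symmetric = TRUE, only.values = TRUE)$values
  lens <- 4 * sqrt(pmax(ev, 0))
  if (lens[2] <= 0) {
    warn("collinear pixel set: minor axis floored at 1 px")
    lens[2] <- 1
  }
  c(l_max = lens[1], l_min = lens[2])
}

#' Convex-hull area, perimeter and minimum angle
#'
#' Hull area by the shoelace formula on the hull vertices, hull perimeter as
#' the vertex-chain length, and CMA — the minimum interior angle over adjacent
#' hull-edge pairs, in radians. CMA is small for objects with a pointed
#' protrusion (cut leaf tips) and close to pi for smooth round blobs. Area and
#' perimeter use the pixel-corner hull (so `A_conv >= A` holds exactly); CMA
#' uses the pixel-centre hull, where sharp vertices keep their true angle.
#'
#' @param obj An [object_geometry()].
#' @return Named numeric `c(A_conv, P_conv, CMA)`.
#' @export
convex_hull_metrics <- function(obj) {
  h <- obj$hull
  if (is.null(h) || nrow(h) < 3L) abort("degenerate hull: fewer than 3 hull vertices")
  x <- h[, 1]
  y <- h[, 2]
  n <- length(x)
  nxt <- c(2:n, 1L)
  a_conv <- abs(sum(x * y[nxt] - x[nxt] * y)) / 2
  p_conv <- sum(sqrt((x[nxt] - x)^2 + (y[nxt] - y)^2))
  hc <- if (!is.null(obj$hull_centers)) obj$hull_centers else h
  cma <- min_interior_angle(hc[, 1], hc[, 2])
  c(A_conv = a_conv, P_conv = p_conv, CMA = cma)
}

min_interior_angle <- function(x, y) {
  n <- length(x)
  nxt <- c(2:n, 1L)
  prv <- c(n, 1:(n - 1L))
  ux <- x[prv] - x
  uy <- y[prv] - y
  vx <- x[nxt] - x
  vy <- y[nxt] - y
  cosang <- (ux * vx + uy * vy) / (sqrt(ux^2 + uy^2) * sqrt(vx^2 + vy^2))
  min(acos(pmin(1, pmax(-1, cosang))))
}

#' Symmetry mean difference
#'
#' The object's boundary is resampled to `n_points` (an even number, default
#' 360) centroid-to-boundary radii at equally spaced polar angles; SMD is the
#' mean absolute difference between diametrically opposite radii,
#' `SMD = (1/N) * sum_i |l_A(i) - l_A'(i)|` with `N = n_points / 2`. It is 0
#' for centrally symmetric shapes (disks, ellipses, rectangles) and positive
#' for asymmetric fragments. The un-normalised sum is returned alongside.
#'
#' @param obj An [object_geometry()].
#' @param n_points Even number of resampled boundary points (2N), default 360.
#' @return Named numeric `c(SMD, SMD_sum)` in pixels.
#' @export
symmetry_mean_difference <- function(obj, n_points = 360L) {
  if (n_points %% 2L != 0L) abort("`n_points` must be even")
  cx <- obj$centroid["x"]
  cy <- obj$centroid["y"]
  # centroid can fall outside non-convex objects (crescents); still computable
  ci <- round(cy) - obj$offset["y0"] + 1L
  cj <- round(cx) - obj$offset["x0"] + 1L
  inside <- ci >= 1 && cj >= 1 && ci <= nrow(obj$mask) && cj <= ncol(obj$mask) &&
    obj$mask[ci, cj]
  if (!inside) warn("centroid lies outside the object; SMD computed anyway")

  bx <- obj$boundary$x - cx
  by <- obj$boundary$y - cy
  r <- sqrt(bx^2 + by^2)
  ang <- atan2(by, bx)
  # average radius over duplicate angles, then interpolate circularly
  o <- order(ang)
  ang <- ang[o]
  r <- r[o]
  agg <- vapply(split(r, ang), mean, numeric(1))
  a <- as.numeric(names(agg))
  rr <- as.numeric(agg)
  if (length(a) < 2L) {
    return(c(SMD = 0, SMD_sum = 0))
  }
  a_ext <- c(a[length(a)] - 2 * pi, a, a[1] + 2 * pi)
  r_ext <- c(rr[length(rr)], rr, rr[1])
  theta <- seq(-pi, pi, length.out = n_points + 1L)[-(n_points + 1L)]
  rs <- approx(a_ext, r_ext, xout = theta, rule = 2)$y
  n_half <- n_points %/% 2L
  d <- abs(rs[seq_len(n_half)] - rs[seq_len(n_half) + n_half])
  c(SMD = mean(d), SMD_sum = sum(d))
}

#' Feret diameters
#'
#' Projection widths of the object over all directions: `FD_max` is the
#' largest caliper opening and `FD_min` the smallest. The exact method runs on
#' the convex hull: `FD_max` is the hull diameter (maximum vertex-pair
#' distance) and `FD_min` the minimal width (minimum over hull edges of the
#' farthest vertex distance from the edge line). A 1-degree direction grid is
#' available as a cross-check.
#'
#' @param obj An [object_geometry()].
#' @param method `"calipers"` (exact, default) or `"grid"`.
#' @param grid_step Grid spacing in degrees for `method = "grid"`.
#' @return Named numeric `c(FD_max, FD_min)` in pixels.
#' @export
feret_diameters <- function(obj, method = c("calipers", "grid"), grid_step = 1) {
  method <- match.arg(method)
  h <- obj$hull
  if (is.null(h)) abort("degenerate hull: cannot compute Feret diameters")
  x <- h[, 1]
  y <- h[, 2]
  if (method == "grid") {
    th <- seq(0, pi, by = grid_step * pi / 180)
    th <- th[th < pi]
    w <- vapply(th, function(t) {
      p <- x * cos(t) + y * sin(t)
      max(p) - min(p)
    }, numeric(1))
    return(c(FD_max = max(w), FD_min = min(w)))
  }
  n <- length(x)
  fd_max <- 0
  for (i in seq_len(n - 1L)) {
    d2 <- (x[(i + 1L):n] - x[i])^2 + (y[(i + 1L):n] - y[i])^2
    fd_max <- max(fd_max, d2)
  }
  fd_max <- sqrt(fd_max)
  # minimal width: for each hull edge, farthest vertex from the edge line
  nxt <- c(2:n, 1L)
  fd_min <- Inf
  for (i in seq_len(n)) {
    ex <- x[nxt[i]] - x[i]
    ey <- y[nxt[i]] - y[i]
    len <- sqrt(ex^2 + ey^2)
    if (len == 0) next
    d <- abs(ex * (y - y[i]) - ey * (x - x[i])) / len
    fd_min <- min(fd_min, max(d))
  }
  if (!is.finite(fd_min)) fd_min <- fd_max
  c(FD_max = fd_max, FD_min = fd_min)
}

#' Dimensionless shape factors
#'
#' Vectorised computation of the four shape factors from their primitive
#' measurements:
#' * compactness `SF_comp = 16 * A / P_crof^2` (1 for a square under an exact
#'   perimeter, 4/pi for a disk);
#' * elongation `SF_elong = |l_max - l_min| / (l_max + l_min)` (0 for a
#'   circle, toward 1 for a long narrow ellipse);
#' * convexity `SF_conv = A / A_conv` (1 for convex objects);
#' * Pentland sphericity `SF_sfer = 4 * A / (pi * FD_max^2)` (1 for a disk).
#'
#' @param A Object area, pixel^2.
#' @param p_crof Crofton perimeter, pixels.
#' @param l_max,l_min Equivalent-ellipse axis lengths, pixels.
#' @param a_conv Convex-hull area, pixel^2.
#' @param fd_max Maximum Feret diameter, pixels.
#' @return A tibble with columns `SF_comp`, `SF_elong`, `SF_conv`, `SF_sfer`.
#' @examples
#' shape_factors(A = pi * 50^2, p_crof = 2 * pi * 50, l_max = 100, l_min = 100,
#'               a_conv = pi * 50^2, fd_max = 100)
#' @export
shape_factors <- function(A, p_crof, l_max, l_min, a_conv, fd_max) {
  if (any(l_max + l_min <= 0) || any(fd_max <= 0) || any(p_crof <= 0) || any(a_conv <= 0)) {
    abort("degenerate geometry: zero axis length, Feret diameter, perimeter or hull area")
  }
  tibble(
    SF_comp = 16 * A / p_crof^2,
    SF_elong = abs(l_max - l_min) / (l_max + l_min),
    SF_conv = A / a_conv,
    SF_sfer = 4 * A / (pi * fd_max^2)
  )
}

#' Compute the morphometric feature table
#'
#' One row per labelled object with the 11 morphometric parameters used to
#' separate shoot tips from leaf fragments and debris: area `A`, Crofton
#' perimeter `P_crof`, compactness `SF_comp`, equivalent-ellipse axes
#' `l_max`/`l_min`, elongation `SF_elong`, convex area `A_conv`, convex
#' perimeter `P_conv`, convexity `SF_conv`, convex minimum angle `CMA`,
#' symmetry mean difference `SMD` (plus its raw sum `SMD_sum`), Feret
#' diameters `FD_max`/`FD_min`, and Pentland sphericity `SF_sfer`. Degenerate
#' objects (too small or with a degenerate hull) are dropped with a warning
#' naming their ids.
#'
#' @param objs A `labeled_objects` result from [open_and_label()].
#' @param mm_per_px Optional calibration; lengths are multiplied by it and
#'   areas by its square (default 1 = report in pixels).
#' @param smd_points Boundary resampling size for [symmetry_mean_difference()].
#' @param feret_method Passed to [feret_diameters()].
#' @return A tibble keyed by `id`.
#' @export
compute_feature_table <- function(objs, mm_per_px = 1, smd_points = 360L,
                                  feret_method = "calipers") {
  ids <- if (inherits(objs, "labeled_objects")) objs$objects$id else sort(unique(objs[objs > 0]))
  rows <- lapply(ids, function(id) {
    tryCatch(
      {
        g <- object_geometry(objs, id)
        p_crof <- crofton_perimeter(g)
        ax <- equivalent_ellipse_axes(g)
        hm <- convex_hull_metrics(g)
        smd <- symmetry_mean_difference(g, n_points = smd_points)
        fd <- feret_diameters(g, method = feret_method)
        sf <- shape_factors(
          A = g$area, p_crof = p_crof, l_max = ax[["l_max"]], l_min = ax[["l_min"]],
          a_conv = hm[["A_conv"]], fd_max = fd[["FD_max"]]
        )
        s <- mm_per_px
        tibble(
          id = id,
          A = g$area * s^2,
          P_crof = p_crof * s,
          SF_comp = sf$SF_comp,
          l_max = ax[["l_max"]] * s,
          l_min = ax[["l_min"]] * s,
          SF_elong = sf$SF_elong,
          A_conv = hm[["A_conv"]] * s^2,
          P_conv = hm[["P_conv"]] * s,
          SF_conv = sf$SF_conv,
          CMA = hm[["CMA"]],
          SMD = smd[["SMD"]] * s,
          FD_max = fd[["FD_max"]] * s,
          FD_min = fd[["FD_min"]] * s,
          SF_sfer = sf$SF_sfer,
          SMD_sum = smd[["SMD_sum"]] * s
        )
      },
      error = function(e) NULL
    )
  })
  dropped <- ids[vapply(rows, is.null, logical(1))]
  if (length(dropped) > 0L) {
    warn(paste0("dropped degenerate objects: ", paste(dropped, collapse = ", ")))
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0L) {
    out <- tibble(
      id = integer(), A = numeric(), P_crof = numeric(), SF_comp = numeric(),
      l_max = numeric(), l_min = numeric(), SF_elong = numeric(),
      A_conv = numeric(), P_conv = numeric(), SF_conv = numeric(),
      CMA = numeric(), SMD = numeric(), FD_max = numeric(), FD_min = numeric(),
      SF_sfer = numeric(), SMD_sum = numeric()
    )
  }
  out
}

#' Names of the 11 morphometric parameters
#'
#' The feature columns offered to the classifier, in their canonical order.
#' @return Character vector of length 11.
#' @export
morphometric_features <- function() {
  c(
    "A", "SF_comp", "SF_elong", "A_conv", "P_conv", "SF_conv",
    "CMA", "SMD", "FD_max", "FD_min", "SF_sfer"
  )
}

#' Write / read a feature table as CSV
#'
#' The CSV schema is exactly `id, A, P_crof, SF_comp, l_max, l_min, SF_elong,
#' A_conv, P_conv, SF_conv, CMA, SMD, FD_max, FD_min, SF_sfer` (one row per
#' object); extra columns such as `SMD_sum` or a `class` label are appended
#' after the canonical block when present.
#'
#' @param feats A feature tibble from [compute_feature_table()].
#' @param path CSV path.
#' @return The path (writer, invisibly) or a tibble (reader).
#' @export
write_feature_csv <- function(feats, path) {
  canon <- c(
    "id", "A", "P_crof", "SF_comp", "l_max", "l_min", "SF_elong",
    "A_conv", "P_conv", "SF_conv", "CMA", "SMD", "FD_max", "FD_min", "SF_sfer"
  )
  extra <- setdiff(names(feats), c(canon, "SMD_sum"))
  write.csv(feats[, c(canon, extra), drop = FALSE], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_csv
#' @export
read_feature_csv <- function(path) {
  as_tibble(read.csv(path, stringsAsFactors = FALSE))
}
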