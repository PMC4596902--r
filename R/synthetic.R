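#' Species profiles for the synthetic generator
#'
#' Painted-tip geometry differs between grass species: perennial ryegrass and
#' meadow fescue have round thin stems (up to 2 mm), timothy and prairie grass
#' round thicker stems, and cocksfoot a flattened stem base. After roller
#' painting the visible tip blob is much wider than the stem itself; defaults
#' use equivalent diameters of 18--30 px (about 6--10 mm at 0.33 mm/px) so
#' every true tip clears the 200-px small-object filter.
#'
#' @param name `"round"` (default; timothy / prairie-grass like),
#'   `"flattened"` (cocksfoot-like) or `"thin"` (ryegrass / fescue like).
#' @return A list with `tip_diameter` (px range) and `axis_ratio` (range).
#' @export
species_profile <- function(name = c("round", "flattened", "thin")) {
  name <- match.arg(name)
  switch(name,
    round = list(name = "round", tip_diameter = c(20, 30), axis_ratio = c(1.0, 1.4)),
    flattened = list(name = "flattened", tip_diameter = c(20, 30), axis_ratio = c(1.8, 3.0)),
    thin = list(name = "thin", tip_diameter = c(18, 24), axis_ratio = c(1.0, 1.2))
  )
}

#' Specify a synthetic bunch scene
#'
#' Describes one synthetic photograph of a cut, tip-painted grass bunch:
#' a soil-like background (correlated noise with near-equal red/green/blue
#' reflectance, plus a linear illumination gradient), `n_tips` near-white
#' elliptical painted tip cross-sections, elongated moderately bright leaf
#' fragments, and small irregular debris blobs mostly below the 200-px filter.
#' All randomness flows from `seed`; rendering is fully deterministic.
#'
#' @param image_size Image side in pixels (default 1500, about a 50 cm field
#'   of view at 0.33 mm/px).
#' @param species Profile name or list from [species_profile()].
#' @param n_tips Number of painted shoot tips (the true count `O`).
#' @param n_leaf_fragments,n_debris Distractor object counts.
#' @param soil_mean,soil_sd Soil base intensity and texture amplitude (8-bit).
#' @param soil_corr_length Soil texture correlation length, px.
#' @param tip_intensity,leaf_intensity,debris_intensity Intensity ranges.
#' @param gradient_amplitude Peak-to-centre illumination gradient, intensity
#'   levels.
#' @param overlap_prob Overlap budget: at most `ceiling(overlap_prob * n_tips)`
#'   tips may violate the separation margin (touching tips can merge into one
#'   object, exercising under-counting).
#' @param mm_per_px Calibration stored with the spec (default 0.33).
#' @param seed Mandatory RNG seed (default 20130913).
#' @return A list of class `scene_spec`.
#' @export
scene_spec <- function(image_size = 1500, species = "round", n_tips = 150,
                       n_leaf_fragments = 20, n_debris = 40,
                       soil_mean = 90, soil_sd = 12, soil_corr_length = 8,
                       tip_intensity = c(235, 255), leaf_intensity = c(190, 225),
                       debris_intensity = c(180, 230), gradient_amplitude = 10,
                       overlap_prob = 0.02, mm_per_px = 0.33,
                       seed = default_seed()) {
  if (is.character(species)) species <- species_profile(species)
  if (n_tips < 0) abort("`n_tips` must be >= 0")
  if (is.null(seed)) abort("`seed` is mandatory")
  # tips must sit clearly above the plausible soil range for the stated
  # amplitudes, otherwise the scene is not segmentable by construction
  soil_top <- soil_mean + 4 * soil_sd + gradient_amplitude
  if (min(tip_intensity) - soil_top < 30) {
    abort("tip intensity range is not separable from the soil range at these amplitudes")
  }
  structure(
    list(
      image_size = as.integer(image_size), species = species,
      n_tips = as.integer(n_tips),
      n_leaf_fragments = as.integer(n_leaf_fragments),
      n_debris = as.integer(n_debris),
      soil_mean = soil_mean, soil_sd = soil_sd,
      soil_corr_length = soil_corr_length,
      tip_intensity = tip_intensity, leaf_intensity = leaf_intensity,
      debris_intensity = debris_intensity,
      gradient_amplitude = gradient_amplitude,
      overlap_prob = overlap_prob, mm_per_px = mm_per_px,
      seed = as.integer(seed)
    ),
    class = "scene_spec"
  )
}

#' @export
print.scene_spec <- function(x, ...) {
  cat(sprintf(
    "<scene_spec> %d x %d px, %s profile, %d tips + %d leaf fragments + %d debris, seed %d\n",
    x$image_size, x$image_size, x$species$name, x$n_tips,
    x$n_leaf_fragments, x$n_debris, x$seed
  ))
  invisible(x)
}

# correlated Gaussian field via bilinear upsampling of a coarse iid grid
smooth_noise <- function(h, w, corr) {
  gh <- max(2L, ceiling(h / corr) + 1L)
  gw <- max(2L, ceiling(w / corr) + 1L)
  g <- matrix(rnorm(gh * gw), gh, gw)
  yi <- seq(1, gh, length.out = h)
  xi <- seq(1, gw, length.out = w)
  y0 <- pmin(floor(yi), gh - 1L)
  fy <- yi - y0
  x0 <- pmin(floor(xi), gw - 1L)
  fx <- xi - x0
  a00 <- g[cbind(rep(y0, w), rep(x0, each = h))]
  a10 <- g[cbind(rep(y0 + 1L, w), rep(x0, each = h))]
  a01 <- g[cbind(rep(y0, w), rep(x0 + 1L, each = h))]
  a11 <- g[cbind(rep(y0 + 1L, w), rep(x0 + 1L, each = h))]
  wy <- rep(fy, w)
  wx <- rep(fx, each = h)
  out <- (a00 * (1 - wy) + a10 * wy) * (1 - wx) + (a01 * (1 - wy) + a11 * wy) * wx
  matrix(out, h, w)
}

# pixel linear indices of a filled ellipse, clipped to the image
ellipse_pixels <- function(cx, cy, a, b, angle, h, w) {
  r <- ceiling(max(a, b))
  xs <- max(1L, floor(cx - r)):min(w, ceiling(cx + r))
  ys <- max(1L, floor(cy - r)):min(h, ceiling(cy + r))
  if (length(xs) == 0L || length(ys) == 0L) return(integer(0))
  dx <- rep(xs - cx, each = length(ys))
  dy <- rep(ys - cy, times = length(xs))
  u <- (dx * cos(angle) + dy * sin(angle)) / a
  v <- (-dx * sin(angle) + dy * cos(angle)) / b
  inside <- u^2 + v^2 <= 1
  ii <- rep(ys, times = length(xs))[inside]
  jj <- rep(xs, each = length(ys))[inside]
  (jj - 1L) * h + ii
}

# stamped-disk pixels along a curved polyline (leaf fragments)
ribbon_pixels <- function(x0, y0, theta, len, width, curvature, h, w) {
  t <- seq(0, len, by = 1)
  ang <- theta + curvature * t
  px <- x0 + cumsum(c(0, cos(ang[-1])))
  py <- y0 + cumsum(c(0, sin(ang[-1])))
  r <- width / 2
  off <- disk_offsets(r)
  ci <- round(rep(py, each = nrow(off)) + rep(off$di, times = length(py)))
  cj <- round(rep(px, each = nrow(off)) + rep(off$dj, times = length(px)))
  ok <- ci >= 1 & ci <= h & cj >= 1 & cj <= w
  unique((cj[ok] - 1L) * h + ci[ok])
}

# irregular small blob: overlapping stamped disks scattered widely enough
# that larger debris stays ragged rather than tip-like
blob_pixels <- function(cx, cy, size, h, w) {
  k <- sample(3:7, 1L)
  acc <- integer(0)
  for (i in seq_len(k)) {
    ox <- cx + rnorm(1, sd = size / 1.5)
    oy <- cy + rnorm(1, sd = size / 1.5)
    acc <- c(acc, ellipse_pixels(ox, oy, size / 3, size / 3, 0, h, w))
  }
  unique(acc)
}

#' Render a synthetic bunch photograph with ground truth
#'
#' Draws the scene described by a [scene_spec()]: correlated soil background
#' with near-equal RGB bands and a linear illumination gradient; painted tips
#' as near-white filled ellipses with species-profile eccentricity placed with
#' a limited overlap budget; leaf fragments as long thin moderately bright
#' ribbons; debris as small irregular blobs. Object intensities carry mild
#' per-pixel noise. Rendering is deterministic given the spec's seed.
#'
#' @param spec A [scene_spec()].
#' @return A list of class `synthetic_scene`:
#'   * `image` — an [rgb_image()];
#'   * `truth` — list with `O` (= `n_tips`), `objects` (tibble: `id`, `class`,
#'     `x`, `y`, `a`, `b`, `angle`, and a `pixels` list-column of linear
#'     indices), and `tip_mask` (logical matrix of all painted-tip pixels);
#'   * `spec` — the input spec.
#' @export
render_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  with_seed(spec$seed, render_scene_impl(spec))
}

render_scene_impl <- function(spec) {
  h <- w <- spec$image_size
  base <- spec$soil_mean + spec$soil_sd * smooth_noise(h, w, spec$soil_corr_length)
  phi <- runif(1, 0, 2 * pi)
  gx <- matrix(rep((seq_len(w) / w - 0.5), each = h), h, w)
  gy <- matrix(rep((seq_len(h) / h - 0.5), times = w), h, w)
  base <- base + spec$gradient_amplitude * 2 * (gx * cos(phi) + gy * sin(phi))

  chan <- list(
    R = base + rnorm(h * w, sd = 2),
    G = base + rnorm(h * w, sd = 2),
    B = base + rnorm(h * w, sd = 2)
  )

  prof <- spec$species
  margin <- ceiling(max(prof$tip_diameter) / 2 * sqrt(max(prof$axis_ratio))) + 2L
  if (2L * margin >= min(h, w)) abort("image too small for the tip size profile")

  objects <- list()
  tip_mask <- matrix(FALSE, h, w)
  placed_x <- numeric(0)
  placed_y <- numeric(0)
  placed_r <- numeric(0)

  add_object <- function(class, x, y, a, b, angle, px) {
    objects[[length(objects) + 1L]] <<- tibble(
      id = length(objects) + 1L, class = class, x = x, y = y,
      a = a, b = b, angle = angle, pixels = list(px)
    )
  }

  # --- painted tips ---------------------------------------------------------
  tries <- 0L
  max_tries <- 400L * max(1L, spec$n_tips)
  overlap_budget <- ceiling(spec$overlap_prob * spec$n_tips)
  overlaps_used <- 0L
  placed <- 0L
  while (placed < spec$n_tips) {
    tries <- tries + 1L
    if (tries > max_tries) {
      abort("cannot place all tips within the overlap budget; use a larger image")
    }
    d <- runif(1, prof$tip_diameter[1], prof$tip_diameter[2])
    ratio <- runif(1, prof$axis_ratio[1], prof$axis_ratio[2])
    a <- d / 2 * sqrt(ratio)
    b <- d / 2 / sqrt(ratio)
    cx <- runif(1, margin, w - margin)
    cy <- runif(1, margin, h - margin)
    if (length(placed_x) > 0L) {
      dd <- sqrt((placed_x - cx)^2 + (placed_y - cy)^2)
      if (any(dd < placed_r + a + 2)) {
        if (overlaps_used >= overlap_budget) next
        overlaps_used <- overlaps_used + 1L
      }
    }
    ang <- runif(1, 0, pi)
    px <- ellipse_pixels(cx, cy, a, b, ang, h, w)
    v <- runif(1, spec$tip_intensity[1], spec$tip_intensity[2])
    noise <- rnorm(length(px), sd = 2)
    chan$B[px] <- pmax(chan$B[px], v + noise)
    chan$G[px] <- pmax(chan$G[px], v - runif(1, 0, 6) + noise)
    chan$R[px] <- pmax(chan$R[px], v - runif(1, 0, 6) + noise)
    tip_mask[px] <- TRUE
    add_object("shoot", cx, cy, a, b, ang, px)
    placed_x <- c(placed_x, cx)
    placed_y <- c(placed_y, cy)
    placed_r <- c(placed_r, a)
    placed <- placed + 1L
  }

  # --- leaf fragments (long thin ribbons) -----------------------------------
  for (k in seq_len(spec$n_leaf_fragments)) {
    for (try in 1:50) {
      x0 <- runif(1, margin, w - margin)
      y0 <- runif(1, margin, h - margin)
      if (length(placed_x) == 0L ||
        all(sqrt((placed_x - x0)^2 + (placed_y - y0)^2) > placed_r + 40)) {
        break
      }
    }
    len <- runif(1, 60, 220)
    width <- runif(1, 3, 7)
    theta <- runif(1, 0, 2 * pi)
    curv <- runif(1, -0.008, 0.008)
    px <- ribbon_pixels(x0, y0, theta, len, width, curv, h, w)
    px <- px[!tip_mask[px]]
    if (length(px) == 0L) next
    v <- runif(1, spec$leaf_intensity[1], spec$leaf_intensity[2])
    noise <- rnorm(length(px), sd = 3)
    chan$B[px] <- pmax(chan$B[px], v + noise)
    chan$G[px] <- pmax(chan$G[px], pmin(255, v + 15) + noise)
    chan$R[px] <- pmax(chan$R[px], v - 10 + noise)
    add_object("leaf", x0, y0, len / 2, width / 2, theta, px)
  }

  # --- debris (small irregular blobs, mostly < 200 px) ----------------------
  for (k in seq_len(spec$n_debris)) {
    cx <- runif(1, 5, w - 5)
    cy <- runif(1, 5, h - 5)
    size <- runif(1, 6, if (runif(1) < 0.2) 18 else 13)
    px <- blob_pixels(cx, cy, size, h, w)
    px <- px[!tip_mask[px]]
    if (length(px) == 0L) next
    v <- runif(1, spec$debris_intensity[1], spec$debris_intensity[2])
    noise <- rnorm(length(px), sd = 3)
    chan$B[px] <- pmax(chan$B[px], v + noise)
    chan$G[px] <- pmax(chan$G[px], v + noise)
    chan$R[px] <- pmax(chan$R[px], v + noise)
    add_object("debris", cx, cy, size / 2, size / 2, 0, px)
  }

  arr <- array(0L, c(h, w, 3L))
  arr[, , 1] <- pmin(255, pmax(0, round(chan$R)))
  arr[, , 2] <- pmin(255, pmax(0, round(chan$G)))
  arr[, , 3] <- pmin(255, pmax(0, round(chan$B)))

  structure(
    list(
      image = rgb_image(arr),
      truth = list(
        O = spec$n_tips,
        objects = if (length(objects) > 0L) dplyr::bind_rows(objects) else
          tibble(id = integer(), class = character(), x = numeric(), y = numeric(),
                 a = numeric(), b = numeric(), angle = numeric(), pixels = list()),
        tip_mask = tip_mask
      ),
      spec = spec
    ),
    class = "synthetic_scene"
  )
}

#' @export
print.synthetic_scene <- function(x, ...) {
  cat(sprintf(
    "<synthetic_scene> %d x %d px; O = %d tips, %d truth objects\n",
    nrow(x$image), ncol(x$image), x$truth$O, nrow(x$truth$objects)
  ))
  invisible(x)
}

#' Match segmented objects to synthetic ground truth
#'
#' Labels every segmented object `shoot` when at least half of its pixels lie
#' inside the ground-truth painted-tip raster, `non-shoot` otherwise — the
#' synthetic stand-in for the manual labelling of the training set.
#'
#' @param objs A `labeled_objects` result from segmentation.
#' @param scene A `synthetic_scene` from [render_scene()].
#' @param min_overlap Minimum fraction of object pixels on painted tips.
#' @return Tibble with columns `id`, `class`.
#' @export
match_objects <- function(objs, scene, min_overlap = 0.5) {
  lab <- objs$label_map
  tips <- scene$truth$tip_mask
  ids <- objs$objects$id
  if (length(ids) == 0L) return(tibble(id = integer(), class = character()))
  pos <- which(lab > 0L)
  frac <- vapply(split(tips[pos], lab[pos]), mean, numeric(1))
  tibble(
    id = as.integer(names(frac)),
    class = ifelse(frac >= min_overlap, "shoot", "non-shoot")
  ) |> dplyr::arrange(.data$id)
}

#' Generate a seeded synthetic dataset with truth and training tables
#'
#' Renders `n_images` bunch scenes whose true counts `O` are drawn uniformly
#' from `o_range` (the span observed across species in breeding bunches),
#' writes each as a PNG, segments it, computes morphometric features, labels
#' the segmented objects against ground truth, and samples about
#' `train_fraction` of the objects per image into a labelled training table
#' (the field protocol labelled roughly 20 % of all objects). Per-image seeds
#' are drawn from `seed`, so reruns are byte-identical.
#'
#' @param out_dir Output directory (created if needed).
#' @param n_images Number of images (>= 1).
#' @param o_range Integer range for the true tip count per image.
#' @param species Species profile name, recycled over images.
#' @param image_size,... Further arguments forwarded to [scene_spec()].
#' @param train_fraction Fraction of segmented objects labelled for training.
#' @param seed Master seed.
#' @param write_images Set `FALSE` to skip PNG output (tables only).
#' @return Invisibly, a list with `truth` (tibble: `image`, `O`, `species`,
#'   `seed`), `training` (feature schema + `class` + `image`), `features`
#'   (the full per-object feature tables of every image, with truth class —
#'   segmentation is deterministic, so classifying these equals re-running
#'   [count_tillers()] on the written PNGs), `specs` (the per-image
#'   [scene_spec()]s), and the file paths written (`truth.csv`,
#'   `training.csv`, images).
#' @export
generate_dataset <- function(out_dir, n_images, o_range = c(15L, 356L),
                             species = "round", image_size = 1500,
                             train_fraction = 0.2, seed = default_seed(),
                             write_images = TRUE, ...) {
  if (n_images < 1L) abort("`n_images` must be >= 1")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  draws <- with_seed(seed, list(
    O = sample(o_range[1]:o_range[2], n_images, replace = TRUE),
    n_leaf = sample(10:35, n_images, replace = TRUE),
    n_debris = sample(20:60, n_images, replace = TRUE),
    seeds = sample.int(2147483646L, n_images),
    train_seeds = sample.int(2147483646L, n_images)
  ))
  species <- rep_len(species, n_images)

  truth_rows <- vector("list", n_images)
  train_rows <- vector("list", n_images)
  feat_rows <- vector("list", n_images)
  specs <- vector("list", n_images)
  img_paths <- character(0)
  for (i in seq_len(n_images)) {
    sp <- scene_spec(
      image_size = image_size, species = species[i], n_tips = draws$O[i],
      n_leaf_fragments = draws$n_leaf[i], n_debris = draws$n_debris[i],
      seed = draws$seeds[i], ...
    )
    specs[[i]] <- sp
    scene <- render_scene(sp)
    img_name <- sprintf("img_%03d.png", i)
    if (write_images) {
      write_image(scene$image, file.path(out_dir, img_name))
      img_paths <- c(img_paths, file.path(out_dir, img_name))
    }
    lab <- segment_image(scene$image)
    feats <- compute_feature_table(lab)
    cls <- match_objects(lab, scene)
    feats <- dplyr::left_join(feats, cls, by = "id")
    feat_rows[[i]] <- dplyr::mutate(feats, image = img_name)
    k <- nrow(feats)
    n_train <- round(train_fraction * k)
    pick <- with_seed(draws$train_seeds[i], sample.int(k, min(n_train, k)))
    train_rows[[i]] <- dplyr::mutate(feats[sort(pick), , drop = FALSE], image = img_name)
    truth_rows[[i]] <- tibble(
      image = img_name, O = draws$O[i], species = species[i], seed = draws$seeds[i]
    )
  }
  truth <- dplyr::bind_rows(truth_rows)
  training <- dplyr::bind_rows(train_rows)
  truth_path <- file.path(out_dir, "truth.csv")
  train_path <- file.path(out_dir, "training.csv")
  write.csv(truth, truth_path, row.names = FALSE)
  write.csv(training[, setdiff(names(training), "SMD_sum")], train_path, row.names = FALSE)
  invisible(list(
    truth = truth, training = training,
    features = dplyr::bind_rows(feat_rows), specs = specs,
    truth_path = truth_path, training_path = train_path, images = img_paths
  ))
}
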