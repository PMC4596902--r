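test_that("VIF matches closed forms", {
  withr::with_seed(5, {
    x <- data.frame(a = rnorm(5000), b = rnorm(5000), c = rnorm(5000))
    v <- compute_vif(x)
    expect_true(all(abs(v$vif - 1) < 0.05))

    n <- 10000
    x1 <- rnorm(n)
    x2 <- 0.9 * x1 + sqrt(1 - 0.81) * rnorm(n)
    x3 <- rnorm(n)
    v2 <- compute_vif(data.frame(x1, x2, x3))
    expect_lt(abs(v2$vif[1] - 1 / (1 - 0.81)) / (1 / (1 - 0.81)), 0.05)
    expect_lt(abs(v2$vif[2] - 1 / (1 - 0.81)) / (1 / (1 - 0.81)), 0.05)

    y1 <- rnorm(n)
    y2 <- rnorm(n)
    v3 <- compute_vif(data.frame(y1, y2, y3 = y1 + y2))
    expect_true(is.infinite(v3$vif[3]))
  })
})

test_that("VIF pruning removes exactly one of a duplicated pair", {
  withr::with_seed(6, {
    x <- data.frame(a = rnorm(500), b = rnorm(500), c = rnorm(500))
    expect_equal(nrow(vif_prune(x)$trace), 0L)

    x$dup <- x$a # exact duplicate, later column
    pr <- vif_prune(x)
    expect_equal(pr$trace$feature, "dup") # tie broken toward the later column
    expect_setequal(pr$survivors, c("a", "b", "c"))
    expect_true(all(pr$vif$vif <= 10))
  })
})

test_that("VIF pruning of a realistic 11-feature block deletes the perimeter/diameter pair first", {
  x <- simulate_collinear_features()
  v0 <- compute_vif(x)
  # the two most collinear dimensional features dominate the initial VIFs
  top2 <- v0$feature[order(-v0$vif)][1:2]
  expect_setequal(top2, c("P_conv", "FD_max"))
  pr <- vif_prune(x, threshold = 10)
  expect_equal(pr$trace$feature[1:2], c("P_conv", "FD_max"))
  expect_true(all(pr$vif$vif <= 10))
  expect_lte(nrow(pr$trace), ncol(x) - 1)
  expect_identical(pr$survivors, intersect(names(x), pr$survivors)) # original order
  # deterministic given the tie rule
  pr2 <- vif_prune(x, threshold = 10)
  expect_identical(pr$trace, pr2$trace)
})

test_that("LDA recovers the population discriminant and the Bayes rate", {
  train <- simulate_two_gaussians(5000, delta = 4, seed = 41)
  test <- simulate_two_gaussians(5000, delta = 4, seed = 42)
  m <- fit_lda(train, features = c("f1", "f2"))
  w <- m$coefficients / sqrt(sum(m$coefficients^2))
  angle <- acos(abs(w[["f1"]])) * 180 / pi
  expect_lt(angle, 5)
  pred <- predict(m, test)
  acc <- mean(pred$.class == test$class)
  expect_lt(abs(acc - pnorm(2)), 0.02)
})

test_that("LDA agrees with an independent implementation (MASS) on held-out labels", {
  skip_if_not_installed("MASS")
  train <- simulate_two_gaussians(800, delta = 2.5, p_noise = 2, seed = 7)
  test <- simulate_two_gaussians(800, delta = 2.5, p_noise = 2, seed = 8)
  feats <- setdiff(names(train), "class")
  m <- fit_lda(train, features = feats)
  ref <- MASS::lda(x = train[, feats], grouping = train$class)
  ours <- predict(m, test)$.class
  theirs <- as.character(predict(ref, test[, feats])$class)
  expect_gt(mean(ours == theirs), 0.999)
})

test_that("LDA degenerate and invariance behaviour", {
  # identical class distributions: no separation
  same <- simulate_two_gaussians(400, delta = 0, seed = 9)
  m0 <- fit_lda(same, features = c("f1", "f2"))
  expect_gt(m0$wilks_lambda, 0.98)
  acc <- mean(predict(m0, simulate_two_gaussians(2000, delta = 0, seed = 10))$.class ==
    simulate_two_gaussians(2000, delta = 0, seed = 10)$class)
  expect_lt(abs(acc - 0.5), 0.05)

  # permutation invariance
  train <- simulate_two_gaussians(300, delta = 3, seed = 11)
  m1 <- fit_lda(train, features = c("f1", "f2"))
  m2 <- fit_lda(withr::with_seed(1, train[sample(nrow(train)), ]),
    features = c("f1", "f2")
  )
  expect_equal(m1$coefficients, m2$coefficients, tolerance = 1e-10)
  expect_equal(m1$cut, m2$cut, tolerance = 1e-10)

  # affine rescaling of one feature leaves predicted labels unchanged
  train_s <- train
  test <- simulate_two_gaussians(500, delta = 3, seed = 12)
  test_s <- test
  train_s$f1 <- 100 * train_s$f1 + 7
  test_s$f1 <- 100 * test_s$f1 + 7
  m3 <- fit_lda(train_s, features = c("f1", "f2"))
  expect_identical(predict(m3, test_s)$.class, predict(m1, test)$.class)

  # singular within-class covariance is reported, not silently inverted
  bad <- train
  bad$f3 <- bad$f1
  expect_error(fit_lda(bad, features = c("f1", "f2", "f3")), "singular|prune")
})

test_that("diagnostics rank variables by discriminative worth", {
  train <- simulate_two_gaussians(2000, delta = 3, p_noise = 3, seed = 14)
  feats <- setdiff(names(train), "class")
  d <- lda_diagnostics(train, feats)

  # the informative variable carries the largest F-to-remove
  expect_equal(d$feature[which.max(d$f_to_remove)], "f1")
  # uninformative variables: F near 0 and removing them leaves lambda unchanged
  lam_full <- fit_lda(train, features = feats)$wilks_lambda
  noise_rows <- d[grepl("noise|f2", d$feature), ]
  expect_true(all(noise_rows$f_to_remove < 3))
  expect_true(all(abs(noise_rows$wilks_lambda - lam_full) / lam_full < 0.01))

  # duplicated variable drives tolerance to zero
  dup <- train
  dup$dup_f1 <- dup$f1 + rnorm(nrow(dup), sd = 1e-4)
  d2 <- lda_diagnostics(dup, c(feats, "dup_f1"))
  expect_lt(d2$tolerance[d2$feature == "dup_f1"], 1e-4)

  # backward stepwise drops weak variables but keeps the informative one
  m <- fit_lda(train, features = feats, select = "backward", f_remove = 1)
  expect_true("f1" %in% m$features)
  expect_lt(length(m$features), length(feats))
})

test_that("coefficient direction converges with sample size", {
  pop_dir <- c(1, 0)
  err <- function(m) {
    w <- m$coefficients / sqrt(sum(m$coefficients^2))
    acos(pmin(1, abs(sum(w * pop_dir))))
  }
  wins <- 0L
  for (k in 1:20) {
    small <- fit_lda(simulate_two_gaussians(50, delta = 4, seed = 100 + k),
      features = c("f1", "f2")
    )
    big <- fit_lda(simulate_two_gaussians(5000, delta = 4, seed = 200 + k),
      features = c("f1", "f2")
    )
    if (err(big) < err(small)) wins <- wins + 1L
  }
  expect_gte(wins, 18L)
})

test_that("classify_objects counts shoots with the documented tie rule", {
  train <- simulate_two_gaussians(300, delta = 4, seed = 15)
  m <- fit_lda(train, features = c("f1", "f2"))

  empty <- tibble::tibble(f1 = numeric(), f2 = numeric())
  out <- classify_objects(empty, m)
  expect_equal(shoot_count(out), 0L)

  expect_error(classify_objects(tibble::tibble(f1 = 1), m), "f2")

  # a point exactly on the boundary goes to shoot
  w <- m$coefficients
  x_on <- c(f1 = 0, f2 = 0)
  x_on["f1"] <- (m$cut - 0 * w[["f2"]]) / w[["f1"]]
  suppressMessages(
    res <- classify_objects(tibble::tibble(f1 = x_on[["f1"]], f2 = 0), m)
  )
  expect_equal(res$.class, "shoot")
  expect_equal(res$.score, 0, tolerance = 1e-12)
})

test_that("models survive a JSON round-trip", {
  train <- simulate_two_gaussians(400, delta = 3, p_noise = 1, seed = 16)
  m <- train_shoot_classifier(train,
    features = setdiff(names(train), "class"),
    species = "round"
  )
  f <- withr::local_tempfile(fileext = ".json")
  write_model(m, f)
  m2 <- read_model(f)
  test <- simulate_two_gaussians(500, delta = 3, p_noise = 1, seed = 17)
  expect_identical(predict(m2, test)$.class, predict(m, test)$.class)
  expect_equal(m2$coefficients, m$coefficients, tolerance = 1e-12)
  expect_equal(m2$species, "round")
  expect_equal(m2$vif$survivors, m$vif$survivors)
})

test_that("count_tillers runs the full pipeline deterministically", {
  ds_dir <- withr::local_tempdir()
  d <- suppressWarnings(generate_dataset(ds_dir,
    n_images = 2, o_range = c(25L, 45L),
    image_size = 700, seed = 77
  ))
  model <- train_shoot_classifier(d$training)

  r1 <- count_tillers(d$images[1], model)
  r2 <- count_tillers(d$images[1], model)
  expect_identical(r1, r2)
  expect_equal(r1$n_objects, sum(d$features$image == "img_001.png"))

  # blank soil-only image: no supra-threshold objects survive
  blank <- render_scene(scene_spec(
    image_size = 400, n_tips = 0,
    n_leaf_fragments = 0, n_debris = 0, seed = 3
  ))
  rb <- count_tillers(blank$image, model)
  expect_equal(rb$e_shoots, 0L)

  # seeded bunch with 150 tips: count within +/- 10 %
  sc <- render_scene(scene_spec(n_tips = 150, seed = 7))
  rc <- count_tillers(sc$image, model, report_path = file.path(ds_dir, "rep.json"))
  expect_lt(abs(rc$e_shoots - 150) / 150, 0.10)
  rep <- jsonlite::read_json(file.path(ds_dir, "rep.json"), simplifyVector = TRUE)
  expect_equal(rep$e_shoots, rc$e_shoots)

  # stage errors carry the stage name
  expect_error(count_tillers("missing.png", model), "stage 'read'")
})
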