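#' Variance inflation factors
#'
#' `VIF_j = 1 / (1 - R^2_j)`, where `R^2_j` comes from regressing feature `j`
#' on all other features (with intercept). Exactly collinear features are
#' reported as `Inf`.
#'
#' @param x A data frame or matrix of numeric features (objects in rows).
#' @return A tibble with columns `feature` and `vif`, in input column order.
#' @examples
#' set.seed(1)
#' x <- data.frame(a = rnorm(100), b = rnorm(100))
#' compute_vif(x) # both close to 1
#' @export
compute_vif <- function(x) {
  x <- as.matrix(as.data.frame(x))
  if (!is.numeric(x)) abort("features must be numeric")
  p <- ncol(x)
  n <- nrow(x)
  if (p < 2L) abort("need at least 2 features to compute VIF")
  if (n <= p) abort("need more observations than features")
  v <- apply(x, 2, var)
  if (any(v == 0)) abort(paste0(
    "zero-variance feature(s): ",
    paste(colnames(x)[v == 0], collapse = ", ")
  ))
  vif <- vapply(seq_len(p), function(j) {
    fit <- stats::lm.fit(cbind(1, x[, -j, drop = FALSE]), x[, j])
    rss <- sum(fit$residuals^2)
    tss <- sum((x[, j] - mean(x[, j]))^2)
    r2 <- 1 - rss / tss
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  tibble(feature = colnames(x), vif = vif)
}

#' Stepwise VIF pruning of collinear features
#'
#' Repeatedly removes the feature with the largest VIF while any VIF exceeds
#' `threshold`, recomputing VIFs after each deletion, until all survivors are
#' at or below the threshold (default 10, the conventional collinearity cut).
#' Ties are broken by deleting the later column.
#'
#' @inheritParams compute_vif
#' @param threshold Maximum tolerated VIF (default 10).
#' @return A list of class `vif_prune`:
#'   * `survivors` — surviving feature names in original order;
#'   * `trace` — tibble of deletions (`step`, `feature`, `vif` at deletion);
#'   * `vif` — final VIF tibble for the survivors.
#' @export
vif_prune <- function(x, threshold = 10) {
  x <- as.data.frame(x)
  orig <- names(x)
  trace <- tibble(step = integer(), feature = character(), vif = numeric())
  step <- 0L
  while (TRUE) {
    vt <- compute_vif(x)
    mx <- max(vt$vif)
    if (mx <= threshold) break
    worst <- dplyr::last(which(vt$vif == mx)) # tie -> later column
    step <- step + 1L
    trace <- dplyr::bind_rows(trace, tibble(
      step = step, feature = vt$feature[worst], vif = mx
    ))
    x <- x[, -worst, drop = FALSE]
    if (ncol(x) < 2L) abort("over-pruned feature set: fewer than 2 survivors")
  }
  structure(
    list(
      survivors = orig[orig %in% names(x)],
      trace = trace,
      vif = compute_vif(x)
    ),
    class = "vif_prune"
  )
}

#' @export
print.vif_prune <- function(x, ...) {
  cat(sprintf(
    "<vif_prune> %d survivors (%s); %d deleted\n",
    length(x$survivors), paste(x$survivors, collapse = ", "), nrow(x$trace)
  ))
  invisible(x)
}

# pooled within-class scatter pieces for two classes
pooled_within <- function(x1, x0) {
  n1 <- nrow(x1)
  n0 <- nrow(x0)
  s1 <- cov(x1) * (n1 - 1)
  s0 <- cov(x0) * (n0 - 1)
  (s1 + s0) / (n1 + n0 - 2)
}

# two-class Wilks' lambda from Mahalanobis distance between class means
wilks_lambda <- function(x1, x0) {
  n1 <- nrow(x1)
  n0 <- nrow(x0)
  n <- n1 + n0
  w <- pooled_within(x1, x0)
  d <- colMeans(x1) - colMeans(x0)
  wi <- tryCatch(solve(w, d), error = function(e) {
    abort("singular within-class covariance: prune collinear features first")
  })
  d2 <- sum(d * wi)
  1 / (1 + d2 * n1 * n0 / (n * (n - 2)))
}

#' Per-variable LDA diagnostics: tolerance, F-to-remove, Wilks' lambda
#'
#' For each variable `j` in the model:
#' * tolerance `T_j = 1 - R^2` of `j` regressed on the other model variables
#'   (computed from the pooled within-class scatter, the discriminant-analysis
#'   convention); near 0 flags collinearity;
#' * `F_j`, the partial F-to-remove: with two classes,
#'   `F_j = (n - p - 1) * (Lambda_without_j / Lambda_full - 1)` on
#'   `(1, n - p - 1)` degrees of freedom — the loss of discrimination when `j`
#'   is dropped;
#' * `Lambda_j`, Wilks' lambda of the model with `j` removed (smaller lambda =
#'   stronger separation, so an important variable leaves a *large* lambda
#'   behind when removed... its own removal raises lambda toward 1).
#'
#' @param data A data frame holding the feature columns and a class column.
#' @param features Character vector of model variables.
#' @param class_col Name of the class column (default `"class"`).
#' @param positive Label of the shoot class (default `"shoot"`).
#' @return A tibble with columns `feature`, `tolerance`, `f_to_remove`,
#'   `wilks_lambda`.
#' @export
lda_diagnostics <- function(data, features, class_col = "class", positive = "shoot") {
  data <- as.data.frame(data)
  cls <- data[[class_col]] == positive
  x1 <- as.matrix(data[cls, features, drop = FALSE])
  x0 <- as.matrix(data[!cls, features, drop = FALSE])
  n <- nrow(x1) + nrow(x0)
  p <- length(features)
  if (n - p - 1 < 1) {
    warn("too few observations for F-to-remove; diagnostics omitted")
    return(tibble(
      feature = features, tolerance = NA_real_,
      f_to_remove = NA_real_, wilks_lambda = NA_real_
    ))
  }
  w <- pooled_within(x1, x0)
  lam_full <- wilks_lambda(x1, x0)
  out <- lapply(seq_along(features), function(j) {
    tol <- if (p == 1L) {
      1
    } else {
      wjj <- w[j, j]
      woth <- w[-j, -j, drop = FALSE]
      wj <- w[-j, j]
      r2 <- tryCatch(sum(wj * solve(woth, wj)) / wjj, error = function(e) 1)
      max(0, min(1, 1 - r2))
    }
    lam_j <- if (p == 1L) 1 else wilks_lambda(x1[, -j, drop = FALSE], x0[, -j, drop = FALSE])
    f_j <- (n - p - 1) * (lam_j / lam_full - 1)
    tibble(
      feature = features[j], tolerance = tol,
      f_to_remove = f_j, wilks_lambda = lam_j
    )
  })
  dplyr::bind_rows(out)
}

#' Fit a two-class shoot / non-shoot linear discriminant
#'
#' Fisher linear discriminant for separating painted shoot tips from leaf
#' fragments and debris in morphometric feature space. The coefficient vector
#' is `w = W^-1 (mu_shoot - mu_nonshoot)` with `W` the pooled within-class
#' covariance; the decision threshold sits at the midpoint of the projected
#' class means, shifted by the log prior ratio. Optional backward stepwise
#' selection repeatedly drops the variable with the smallest F-to-remove while
#' that F is below `f_remove` (classical stepwise discriminant analysis);
#' tolerance / F-to-remove / Wilks' lambda diagnostics are always reported for
#' the final model.
#'
#' @param data Training tibble: feature columns plus a class column. Features
#'   should already be VIF-pruned (see [vif_prune()]).
#' @param features Feature columns to use; default all of
#'   [morphometric_features()] present in `data`.
#' @param class_col,positive Class column name and the shoot label.
#' @param select `"none"` (default) or `"backward"` stepwise selection.
#' @param f_remove F-to-remove threshold for backward selection (default 1).
#' @param priors `"empirical"` (class frequencies, default) or `"equal"`.
#' @param species Optional species key stored with the model (different grass
#'   species need different feature sets).
#' @param vif A [vif_prune()] result to store for provenance.
#' @return An object of class `shoot_lda`.
#' @export
fit_lda <- function(data, features = NULL, class_col = "class", positive = "shoot",
                    select = c("none", "backward"), f_remove = 1,
                    priors = c("empirical", "equal"), species = NULL, vif = NULL) {
  select <- match.arg(select)
  priors <- match.arg(priors)
  data <- as.data.frame(data)
  if (is.null(features)) features <- intersect(morphometric_features(), names(data))
  missing_f <- setdiff(features, names(data))
  if (length(missing_f) > 0L) {
    abort(paste0("missing feature column(s): ", paste(missing_f, collapse = ", ")))
  }
  if (!class_col %in% names(data)) abort(paste0("missing class column: ", class_col))
  cls <- data[[class_col]] == positive
  if (anyNA(data[, features])) abort("training data contains missing values")
  if (sum(cls) == 0L || sum(!cls) == 0L) abort("both classes must be non-empty")
  n <- nrow(data)
  if (n < length(features) + 2L) abort("need n >= p + 2 training objects")

  # backward stepwise elimination on F-to-remove
  if (select == "backward") {
    repeat {
      if (length(features) <= 1L) break
      diag_t <- lda_diagnostics(data, features, class_col, positive)
      jmin <- which.min(diag_t$f_to_remove)
      if (is.na(diag_t$f_to_remove[jmin]) || diag_t$f_to_remove[jmin] >= f_remove) break
      features <- setdiff(features, diag_t$feature[jmin])
    }
  }

  x1 <- as.matrix(data[cls, features, drop = FALSE])
  x0 <- as.matrix(data[!cls, features, drop = FALSE])
  w_mat <- pooled_within(x1, x0)
  mu1 <- colMeans(x1)
  mu0 <- colMeans(x0)
  coefs <- tryCatch(solve(w_mat, mu1 - mu0), error = function(e) {
    abort("singular within-class covariance: prune collinear features more aggressively")
  })
  pr <- if (priors == "empirical") {
    c(shoot = nrow(x1) / n, nonshoot = nrow(x0) / n)
  } else {
    c(shoot = 0.5, nonshoot = 0.5)
  }
  # score(x) = w'x - cut; >= 0 -> shoot
  cut <- sum(coefs * (mu1 + mu0)) / 2 - log(pr[["shoot"]] / pr[["nonshoot"]])

  structure(
    list(
      features = features,
      coefficients = setNames(as.numeric(coefs), features),
      cut = cut,
      means = list(shoot = mu1, nonshoot = mu0),
      priors = pr,
      n = c(shoot = nrow(x1), nonshoot = nrow(x0)),
      wilks_lambda = wilks_lambda(x1, x0),
      diagnostics = lda_diagnostics(data, features, class_col, positive),
      positive = positive,
      species = species,
      vif = vif
    ),
    class = "shoot_lda"
  )
}

#' @export
print.shoot_lda <- function(x, ...) {
  cat(sprintf(
    "<shoot_lda>%s %d features (%s); n = %d shoot / %d non-shoot; Wilks' lambda %.3f\n",
    if (is.null(x$species)) "" else paste0(" [", x$species, "]"),
    length(x$features), paste(x$features, collapse = ", "),
    x$n[["shoot"]], x$n[["nonshoot"]], x$wilks_lambda
  ))
  invisible(x)
}

#' @rdname fit_lda
#' @param x,object A `shoot_lda` model.
#' @param ... Unused.
#' @export
tidy.shoot_lda <- function(x, ...) {
  dplyr::left_join(
    tibble(feature = x$features, coefficient = as.numeric(x$coefficients)),
    x$diagnostics,
    by = "feature"
  )
}

#' @rdname fit_lda
#' @export
glance.shoot_lda <- function(x, ...) {
  tibble(
    n_features = length(x$features),
    n_shoot = x$n[["shoot"]],
    n_nonshoot = x$n[["nonshoot"]],
    wilks_lambda = x$wilks_lambda,
    prior_shoot = x$priors[["shoot"]]
  )
}

#' @export
predict.shoot_lda <- function(object, newdata, ...) {
  miss <- setdiff(object$features, names(newdata))
  if (length(miss) > 0L) {
    abort(paste0("missing feature column(s): ", paste(miss, collapse = ", ")))
  }
  xm <- as.matrix(as.data.frame(newdata)[, object$features, drop = FALSE])
  score <- as.numeric(xm %*% object$coefficients) - object$cut
  # tie (score exactly 0) -> shoot: under-counting is the costlier error
  tibble(
    .score = score,
    .class = ifelse(score >= 0, object$positive, paste0("non-", object$positive))
  )
}

#' Classify segmented objects and count shoots
#'
#' Applies a fitted [fit_lda()] model to a morphometric feature table and
#' returns it with a discriminant score and class per object. The tiller
#' estimate `E` is the number of objects labelled shoot; objects exactly on
#' the decision boundary are assigned to shoot.
#'
#' @param feats Feature tibble (must contain the model's feature columns).
#' @param model A `shoot_lda` model.
#' @return The input tibble with `.score` and `.class` columns and attribute
#'   `shoot_count` (also retrievable with [shoot_count()]).
#' @export
classify_objects <- function(feats, model) {
  if (nrow(feats) == 0L) {
    out <- dplyr::mutate(feats, .score = numeric(0), .class = character(0))
    attr(out, "shoot_count") <- 0L
    return(out)
  }
  pred <- predict(model, feats)
  if (any(pred$.score == 0)) inform("object(s) exactly on the decision boundary assigned to shoot")
  out <- dplyr::bind_cols(feats, pred)
  attr(out, "shoot_count") <- sum(pred$.class == model$positive)
  out
}

#' @rdname classify_objects
#' @param classified A tibble returned by [classify_objects()].
#' @export
shoot_count <- function(classified) {
  cnt <- attr(classified, "shoot_count")
  if (is.null(cnt)) cnt <- sum(classified$.class == "shoot")
  as.integer(cnt)
}

#' Count tillers in one bunch photograph
#'
#' Runs the full pipeline on an image: blue band, maximum-contrast threshold,
#' opening + 200-px filter, morphometric features, LDA classification. Stage
#' failures are re-raised with the stage name attached.
#'
#' @param image A file path or an [rgb_image()].
#' @param model A fitted `shoot_lda` model.
#' @param band,min_area,opening_radius,mm_per_px Pipeline settings (see
#'   [segment_image()] and [compute_feature_table()]).
#' @param report_path Optional path for a JSON count report.
#' @return A one-row tibble (`image`, `threshold`, `n_objects`, `e_shoots`)
#'   with the classified per-object table in attribute `"objects"`.
#' @export
count_tillers <- function(image, model, band = "blue", min_area = 200,
                          opening_radius = 1, mm_per_px = 1, report_path = NULL) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("stage '", name, "': ", conditionMessage(e)))
    })
  }
  name <- if (is.character(image)) image else "<in-memory image>"
  img <- stage("read", if (is.character(image)) read_image(image) else image)
  lab <- stage("segment", segment_image(img,
    band = band, min_area = min_area,
    opening_radius = opening_radius
  ))
  feats <- stage("features", compute_feature_table(lab, mm_per_px = mm_per_px))
  classified <- stage("classify", classify_objects(feats, model))
  e <- shoot_count(classified)
  report <- tibble(
    image = name,
    threshold = lab$threshold,
    n_objects = nrow(feats),
    e_shoots = e
  )
  if (!is.null(report_path)) {
    jsonlite::write_json(as.list(report), report_path, auto_unbox = TRUE, pretty = TRUE)
  }
  attr(report, "objects") <- classified
  report
}

#' Save / load a fitted model as JSON
#'
#' Serialises feature names, coefficients, cut point, priors, diagnostics,
#' the VIF trace and the species key.
#'
#' @param model A `shoot_lda` model.
#' @param path JSON path.
#' @return The path (writer, invisibly) or a `shoot_lda` (reader).
#' @export
write_model <- function(model, path) {
  payload <- list(
    features = model$features,
    coefficients = as.list(model$coefficients),
    cut = model$cut,
    means = lapply(model$means, as.list),
    priors = as.list(model$priors),
    n = as.list(model$n),
    wilks_lambda = model$wilks_lambda,
    diagnostics = model$diagnostics,
    positive = model$positive,
    species = model$species,
    vif_survivors = model$vif$survivors,
    vif_trace = model$vif$trace
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  vif <- NULL
  if (!is.null(p$vif_survivors)) {
    vif <- structure(
      list(
        survivors = p$vif_survivors,
        trace = as_tibble(p$vif_trace),
        vif = NULL
      ),
      class = "vif_prune"
    )
  }
  structure(
    list(
      features = p$features,
      coefficients = unlist(p$coefficients),
      cut = p$cut,
      means = lapply(p$means, unlist),
      priors = unlist(p$priors),
      n = unlist(p$n),
      wilks_lambda = p$wilks_lambda,
      diagnostics = as_tibble(p$diagnostics),
      positive = p$positive,
      species = p$species,
      vif = vif
    ),
    class = "shoot_lda"
  )
}

#' Train a shoot classifier from a labelled feature table
#'
#' Convenience composition used by the command-line `train` step: VIF pruning
#' of the 11 morphometric parameters to the collinearity threshold, then LDA
#' with optional backward stepwise selection, with all diagnostics retained.
#'
#' @inheritParams fit_lda
#' @param vif_threshold Collinearity cut for [vif_prune()] (default 10).
#' @return A `shoot_lda` model (with the VIF trace in `$vif`).
#' @export
train_shoot_classifier <- function(data, features = NULL, class_col = "class",
                                   positive = "shoot", vif_threshold = 10,
                                   select = "backward", f_remove = 1,
                                   priors = "empirical", species = NULL) {
  data <- as.data.frame(data)
  if (is.null(features)) features <- intersect(morphometric_features(), names(data))
  pruned <- vif_prune(data[, features, drop = FALSE], threshold = vif_threshold)
  fit_lda(data,
    features = pruned$survivors, class_col = class_col, positive = positive,
    select = select, f_remove = f_remove, priors = priors,
    species = species, vif = pruned
  )
}
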