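# shift a logical matrix by (di, dj), padding with `fill`
shift_mat <- function(m, di, dj, fill = FALSE) {
  nr <- nrow(m)
  nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  ri <- max(1L, 1L + di):min(nr, nr + di)
  rj <- max(1L, 1L + dj):min(nc, nc + dj)
  if (length(ri) > 0L && length(rj) > 0L) {
    out[ri, rj] <- m[ri - di, rj - dj]
  }
  out
}

disk_offsets <- function(radius) {
  r <- floor(radius)
  g <- expand.grid(di = -r:r, dj = -r:r)
  g[g$di^2 + g$dj^2 <= radius^2, , drop = FALSE]
}

#' Morphological erosion, dilation and opening with a disk
#'
#' Binary morphology with a digital disk structuring element
#' (`di^2 + dj^2 <= radius^2`); pixels outside the image count as background.
#' Opening (erosion then dilation) removes structures thinner than the disk —
#' the pipeline uses it for speckle noise before the explicit area filter.
#'
#' @param mask Logical matrix.
#' @param radius Disk radius in pixels (radius 1 is the 4-neighbour cross).
#' @return A logical matrix of the same extent.
#' @export
mask_open <- function(mask, radius = 1) {
  mask_dilate(mask_erode(mask, radius), radius)
}

#' @rdname mask_open
#' @export
mask_erode <- function(mask, radius = 1) {
  off <- disk_offsets(radius)
  out <- mask
  for (k in seq_len(nrow(off))) {
    if (off$di[k] == 0L && off$dj[k] == 0L) next
    out <- out & shift_mat(mask, off$di[k], off$dj[k], fill = FALSE)
  }
  out
}

#' @rdname mask_open
#' @export
mask_dilate <- function(mask, radius = 1) {
  off <- disk_offsets(radius)
  out <- mask
  for (k in seq_len(nrow(off))) {
    if (off$di[k] == 0L && off$dj[k] == 0L) next
    out <- out | shift_mat(mask, off$di[k], off$dj[k], fill = FALSE)
  }
  out
}

#' Open a mask and label its surviving objects
#'
#' Applies a morphological opening (disk of `opening_radius`; skipped when
#' `opening_radius = 0`), labels 8-connected components, removes every
#' component smaller than `min_area` pixels (the pipeline default of 200 px
#' discards debris well below a painted tip cross-section), and relabels the
#' survivors contiguously 1..K in scan order.
#'
#' @param mask Logical matrix (`TRUE` = candidate object pixel), e.g. from
#'   [max_contrast_threshold()].
#' @param min_area Minimum surviving component area in pixels (default 200).
#' @param opening_radius Disk radius for the opening (default 1).
#' @return A list of class `labeled_objects`:
#'   * `label_map` — integer matrix, 0 background, k in 1..K object id;
#'   * `objects` — tibble with one row per object (`id`, `area`);
#'   * `min_area`, `opening_radius` — the parameters used.
#' @examples
#' mask <- matrix(FALSE, 40, 40)
#' mask[2:31, 2:11] <- TRUE # 300 px
#' mask[35:37, 35:37] <- TRUE # 9 px, removed
#' open_and_label(mask, min_area = 200)$objects
#' @export
open_and_label <- function(mask, min_area = 200, opening_radius = 1) {
  if (!is.logical(mask) || !is.matrix(mask)) abort("`mask` must be a logical matrix")
  if (opening_radius > 0) mask <- mask_open(mask, opening_radius)
  lab <- .label_components_cpp(mask)
  k0 <- max(lab)
  if (k0 == 0L) {
    return(structure(
      list(
        label_map = lab,
        objects = tibble(id = integer(), area = integer()),
        min_area = min_area, opening_radius = opening_radius
      ),
      class = "labeled_objects"
    ))
  }
  areas <- tabulate(lab, nbins = k0)
  keep <- which(areas >= min_area)
  remap <- integer(k0)
  remap[keep] <- seq_along(keep)
  pos <- lab > 0L
  lab[pos] <- remap[lab[pos]]
  structure(
    list(
      label_map = lab,
      objects = tibble(id = seq_along(keep), area = as.integer(areas[keep])),
      min_area = min_area, opening_radius = opening_radius
    ),
    class = "labeled_objects"
  )
}

#' @export
print.labeled_objects <- function(x, ...) {
  cat(sprintf(
    "<labeled_objects> %d objects >= %d px (opening radius %s) in %d x %d map\n",
    nrow(x$objects), x$min_area, format(x$opening_radius),
    nrow(x$label_map), ncol(x$label_map)
  ))
  invisible(x)
}

#' Segment a bunch photograph into candidate objects
#'
#' Convenience composition of the imaging stage: band extraction,
#' maximum-contrast thresholding and labelling with the small-object filter.
#'
#' @inheritParams to_blue_band
#' @inheritParams open_and_label
#' @param report_path Optional path; when given, a JSON segmentation report
#'   (threshold, object count, per-object areas) is written there.
#' @return A `labeled_objects` list as in [open_and_label()], with the chosen
#'   `threshold` added.
#' @export
segment_image <- function(img, band = "blue", min_area = 200, opening_radius = 1,
                          report_path = NULL) {
  g <- to_blue_band(img, band)
  th <- max_contrast_threshold(g)
  lab <- open_and_label(th$mask, min_area = min_area, opening_radius = opening_radius)
  lab$threshold <- th$threshold
  if (!is.null(report_path)) {
    jsonlite::write_json(
      list(
        threshold = th$threshold,
        n_objects = nrow(lab$objects),
        areas = lab$objects$area
      ),
      report_path,
      auto_unbox = TRUE, pretty = TRUE
    )
  }
  lab
}
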