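#' Square ROIs inside the phantom inserts
#'
#' One square ROI centered in each peripheral insert and a background ROI of
#' the same size in the central water insert. The side length defaults to 10
#' pixels but is shrunk when needed so every ROI stays strictly inside its
#' 3 cm insert with a margin of at least 2 pixels.
#'
#' @param phantom a [build_insert_phantom()] result.
#' @param side ROI side length in pixels (default: auto, at most 10).
#' @return List of class `roi_spec`: `rois` (list of 8 linear-index
#'   vectors, insert order matching `phantom$concentrations`), `bg`
#'   (background indices), `side`.
#' @export
insert_rois <- function(phantom, side = NULL) {
  g <- phantom$geometry
  n <- g$n_pixels
  dx <- g$pixel_size_cm
  r_px <- phantom$insert_radius_cm / dx
  max_side <- floor(2 * (r_px - 2) / sqrt(2))
  if (max_side < 2)
    stop("grid too coarse for ROIs inside the inserts")
  if (is.null(side)) side <- min(10L, max_side)
  if (side > max_side)
    stop("requested ROI side does not fit inside the inserts with margin")
  half <- side / 2
  roi_at <- function(cx, cy) {
    jc <- cx / dx + n / 2   # fractional pixel coordinates of the center
    ic <- cy / dx + n / 2
    js <- floor(jc - half) + seq_len(side)
    is <- floor(ic - half) + seq_len(side)
    as.vector(outer(is, (js - 1) * n, "+"))
  }
  centers <- phantom$insert_centers_cm
  rois <- lapply(2:9, function(m) roi_at(centers[m, 1], centers[m, 2]))
  bg <- roi_at(centers[1, 1], centers[1, 2])
  structure(list(rois = rois, bg = bg, side = side), class = "roi_spec")
}

#' Contrast enhancement of an ROI over the background
#'
#' `mean(image[roi]) - mean(image[bg])`, signed; in HU when the image is in
#' HU.
#'
#' @param image image matrix.
#' @param roi,bg linear index vectors.
#' @export
contrast_enhancement <- function(image, roi, bg) {
  if (!length(roi) || !length(bg)) stop("empty ROI")
  mean(image[roi]) - mean(image[bg])
}

#' Contrast-to-noise ratio
#'
#' `2 * (mean_roi - mean_bg) / sqrt(sd_roi^2 + sd_bg^2)`, reported as a
#' magnitude. A zero-variance pair with a nonzero contrast yields `Inf`
#' (flagged detectability with no noise).
#'
#' @param image image matrix.
#' @param roi,bg linear index vectors (at least 4 pixels each).
#' @export
cnr <- function(image, roi, bg) {
  if (length(roi) < 4 || length(bg) < 4)
    stop("ROIs must contain at least 4 pixels")
  num <- mean(image[roi]) - mean(image[bg])
  den <- sqrt(sd(image[roi])^2 + sd(image[bg])^2)
  if (den == 0) {
    if (num == 0) return(0)
    return(Inf)
  }
  abs(2 * num / den)
}

#' Per-insert iodine concentration errors
#'
#' Estimates each insert's concentration as the ROI mean of an iodine map and
#' compares with the phantom ground truth: `|est - truth| / truth`. Inserts
#' with zero true concentration are excluded (with a message).
#'
#' @param estimate_map iodine concentration image (mg/ml), matrix or vector.
#' @param phantom the [build_insert_phantom()] ground truth.
#' @param rois an [insert_rois()] specification.
#' @return data.frame with insert, truth and estimated mg/ml, and relative
#'   error; the mean relative error is attached as attribute
#'   `mean_rel_error`.
#' @export
concentration_error <- function(estimate_map, phantom, rois) {
  est <- vapply(rois$rois, function(idx) mean(estimate_map[idx]), numeric(1))
  truth <- phantom$concentrations * phantom$stock_mg_per_ml
  keep <- truth > 0
  if (any(!keep))
    message(sprintf("excluding %d zero-concentration insert(s)", sum(!keep)))
  out <- data.frame(insert = seq_along(truth)[keep],
                    truth_mg_ml = truth[keep],
                    estimate_mg_ml = est[keep],
                    rel_error = abs(est[keep] - truth[keep]) / truth[keep])
  attr(out, "mean_rel_error") <- mean(out$rel_error)
  out
}

#' Sensitivity of insert CNR to one model hyperparameter
#'
#' Re-runs the joint reconstruction over a grid of values of `beta`,
#' `alpha1` or `alpha2` (the other parameters fixed) and records the CNR of
#' every insert in the 80 kVp channel, plus their mean and maximum. Solver
#' failures at a grid point are recorded, not propagated.
#'
#' @param parameter one of `"beta"`, `"alpha1"`, `"alpha2"`.
#' @param grid numeric vector of parameter values.
#' @param sino the kVp-switching scan to reconstruct.
#' @param phantom,rois phantom truth and ROI layout for the metrics.
#' @param dict,calib dictionary and calibration.
#' @param params base [meer_params()].
#' @param projectors optional precomputed projectors (reused per grid point).
#' @return data.frame: value, one `cnr_insert*` column per insert,
#'   `cnr_mean`, `cnr_max`, `error` (NA unless the solve failed).
#' @export
sensitivity_sweep <- function(parameter = c("beta", "alpha1", "alpha2"),
                              grid, sino, phantom, rois, dict, calib,
                              params = meer_params(), projectors = NULL) {
  parameter <- match.arg(parameter)
  if (!length(grid)) stop("parameter grid must be nonempty")
  res <- vector("list", length(grid))
  for (gidx in seq_along(grid)) {
    p <- params
    p[[parameter]] <- grid[gidx]
    row <- as.list(rep(NA_real_, 8))
    names(row) <- paste0("cnr_insert", 1:8)
    err <- NA_character_
    tryCatch({
      rec <- meer_reconstruct(sino, dict, calib, p, projectors = projectors)
      hu <- mu_to_hu(rec$F[, , 1], calib$mu_water[1])
      for (m in 1:8) row[[m]] <- cnr(hu, rois$rois[[m]], rois$bg)
    }, error = function(e) err <<- conditionMessage(e))
    res[[gidx]] <- data.frame(parameter = parameter, value = grid[gidx],
                              as.data.frame(row),
                              cnr_mean = mean(unlist(row)),
                              cnr_max = suppressWarnings(max(unlist(row))),
                              error = err)
  }
  do.call(rbind, res)
}
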