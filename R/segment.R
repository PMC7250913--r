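# Per-frame segmentation: threshold (Otsu by default), morphological opening
# then closing, 8-connected components, size filter. EBImage's bwlabel is
# 4-connective, so components touching only diagonally are merged afterwards
# with a union-find pass.

merge_diagonal <- function(lab) {
  h <- nrow(lab); w <- ncol(lab)
  nmax <- max(lab)
  if (nmax < 2 || h < 2 || w < 2) return(lab)
  pairs <- rbind(
    cbind(as.vector(lab[-h, -w]), as.vector(lab[-1, -1])),  # down-right
    cbind(as.vector(lab[-h, -1]), as.vector(lab[-1, -w]))   # down-left
  )
  pairs <- pairs[pairs[, 1] > 0 & pairs[, 2] > 0 &
                   pairs[, 1] != pairs[, 2], , drop = FALSE]
  if (nrow(pairs) == 0) return(lab)
  parent <- seq_len(nmax)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (k in seq_len(nrow(pairs))) {
    a <- find(pairs[k, 1]); b <- find(pairs[k, 2])
    if (a != b) parent[max(a, b)] <- min(a, b)
  }
  root <- vapply(seq_len(nmax), find, integer(1))
  newid <- match(root, sort(unique(root)))
  out <- lab
  out[lab > 0] <- newid[lab[lab > 0]]
  out
}

#' Segment neurons in a single frame
#'
#' Smooths the image with a small Gaussian (denoising; Otsu on a raw
#' shot-noise-limited frame with sparse foreground otherwise locks onto the
#' background noise itself), binarizes at a threshold (Otsu on the smoothed
#' frame's own histogram, or a fixed value), applies morphological opening
#' then closing with a disk, labels 8-connected components, and drops
#' components smaller than `min_area`. Centroids are unweighted mask
#' centroids. A constant image yields zero objects (not an error).
#' Fluorescence is later measured on the raw (unsmoothed) pixels by
#' [measure_fluorescence()]; smoothing only shapes the mask.
#'
#' @param image 2-D numeric matrix of intensities (counts), finite and
#'   non-negative.
#' @param threshold `"otsu"` (per-frame) or a fixed numeric threshold
#'   (applied to the smoothed image).
#' @param min_area Minimum component area in pixels.
#' @param morph_radius Disk radius for opening/closing; 0 disables.
#' @param smooth_sigma Gaussian pre-smoothing sigma in pixels; 0 disables.
#' @param split_touching Split touching objects by watershed on the
#'   distance map of the binary mask (recommended; plain connected
#'   components merge adjacent somata into one object).
#' @return A `segmentation`: list with `objects` (data.frame `object_id, x,
#'   y, area, mean_red, mean_green` — intensities unfilled until
#'   [measure_fluorescence()]) and `labels` (the label matrix).
#' @export
segment_frame <- function(image, threshold = "otsu", min_area = 5,
                          morph_radius = 1, smooth_sigma = 1,
                          split_touching = TRUE) {
  if (length(dim(image)) != 2)
    stop("image must be a 2-D matrix")
  if (!all(is.finite(image)) || any(image < 0))
    stop("image must be finite and non-negative")

  empty <- function() {
    structure(list(objects = data.frame(object_id = integer(0),
                                        x = numeric(0), y = numeric(0),
                                        area = integer(0),
                                        mean_red = numeric(0),
                                        mean_green = numeric(0)),
                   labels = matrix(0L, nrow(image), ncol(image))),
              class = "segmentation")
  }

  work <- if (smooth_sigma > 0)
    EBImage::imageData(EBImage::gblur(EBImage::Image(image),
                                      sigma = smooth_sigma))
  else image

  if (identical(threshold, "otsu")) {
    mx <- max(work)
    if (mx == min(work)) return(empty())
    thr <- EBImage::otsu(EBImage::Image(work / mx),
                         range = c(0, 1), levels = 4096) * mx
    # noise floor: on an (almost) empty frame Otsu degenerates to a split
    # inside the background noise; never threshold below median + 5 MAD
    thr <- max(thr, stats::median(work) + 5 * stats::mad(work))
  } else if (is.numeric(threshold) && length(threshold) == 1) {
    thr <- threshold
  } else {
    stop("threshold must be \"otsu\" or a single numeric value")
  }

  mask <- EBImage::Image(work > thr)
  if (morph_radius > 0) {
    brush <- EBImage::makeBrush(2 * morph_radius + 1, shape = "disc")
    mask <- EBImage::closing(EBImage::opening(mask, brush), brush)
  }
  if (split_touching) {
    # watershed on the distance map splits neurons whose masks touch;
    # otherwise two adjacent somata become one object and one track dies
    lab <- EBImage::imageData(EBImage::watershed(EBImage::distmap(mask),
                                                 tolerance = 1, ext = 1))
    storage.mode(lab) <- "integer"
  } else {
    lab <- merge_diagonal(EBImage::imageData(EBImage::bwlabel(mask)))
  }
  if (max(lab) == 0) return(empty())

  px <- which(lab > 0)
  ids <- lab[px]
  rows <- (px - 1L) %% nrow(lab) + 1L
  cols <- (px - 1L) %/% nrow(lab) + 1L
  area <- tabulate(ids)
  keep <- which(area >= min_area)
  if (length(keep) == 0) return(empty())
  newid <- rep(0L, length(area)); newid[keep] <- seq_along(keep)
  lab[px] <- newid[ids]
  sel <- newid[ids] > 0
  ids2 <- newid[ids][sel]
  objects <- data.frame(
    object_id = seq_along(keep),
    x = as.numeric(tapply(cols[sel], ids2, mean)),
    y = as.numeric(tapply(rows[sel], ids2, mean)),
    area = as.integer(area[keep]),
    mean_red = NA_real_, mean_green = NA_real_
  )
  structure(list(objects = objects, labels = lab), class = "segmentation")
}

#' Background-subtracted fluorescence of segmented objects
#'
#' For every object, the red-channel mask is applied to both channels:
#' `mean_red` is the mean red intensity over the mask minus the red
#' background, and `mean_green` likewise on the green channel (the mask
#' always comes from the red-channel segmentation). The background is
#' estimated per image, either as the median of all pixels outside every
#' mask (default, robust and parameter-free) or as the median of four
#' corner patches. Values may be slightly negative after subtraction and
#' are kept as-is.
#'
#' @param seg A `segmentation` from [segment_frame()] (run on the red frame).
#' @param red_image,green_image Matrices of the same shape as the segmented
#'   frame.
#' @param background_method `"median_outside_masks"` or `"corner_patches"`.
#' @param corner_size Patch edge length for `"corner_patches"`.
#' @return The `segmentation` with `mean_red` / `mean_green` filled and the
#'   background estimates stored as attribute `background`.
#' @export
measure_fluorescence <- function(seg, red_image, green_image,
                                 background_method = c("median_outside_masks",
                                                       "corner_patches"),
                                 corner_size = 8) {
  stopifnot(inherits(seg, "segmentation"))
  background_method <- match.arg(background_method)
  if (!identical(dim(red_image), dim(green_image)) ||
      !identical(dim(red_image), dim(seg$labels)))
    stop("red, green and label images must share the same shape")

  bg_of <- function(img) {
    if (background_method == "median_outside_masks") {
      out <- img[seg$labels == 0]
      if (length(out) == 0) stop("no pixels outside masks for background")
      stats::median(out)
    } else {
      k <- min(corner_size, nrow(img), ncol(img))
      h <- nrow(img); w <- ncol(img)
      stats::median(c(img[1:k, 1:k], img[1:k, (w - k + 1):w],
                      img[(h - k + 1):h, 1:k], img[(h - k + 1):h, (w - k + 1):w]))
    }
  }
  bg_r <- bg_of(red_image); bg_g <- bg_of(green_image)
  obj <- seg$objects
  for (i in seq_len(nrow(obj))) {
    m <- seg$labels == obj$object_id[i]
    if (!any(m)) stop("object ", obj$object_id[i], " has an empty mask")
    obj$mean_red[i] <- mean(red_image[m]) - bg_r
    obj$mean_green[i] <- mean(green_image[m]) - bg_g
  }
  seg$objects <- obj
  attr(seg, "background") <- c(red = bg_r, green = bg_g)
  seg
}
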