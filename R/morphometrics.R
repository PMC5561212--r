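#' Single-channel colony image
#'
#' @param intensities numeric matrix of non-negative intensities, at least
#'   64 x 64.
#' @param pixel_size um per pixel.
#' @return object of class \code{colony_image}.
#' @export
colony_image <- function(intensities, pixel_size) {
  abort_if(!is.matrix(intensities) || !is.numeric(intensities),
           "intensities must be a numeric matrix")
  abort_if(any(dim(intensities) < 64), "image must be at least 64 x 64")
  abort_if(any(!is.finite(intensities)) || any(intensities < 0),
           "intensities must be finite and non-negative")
  abort_if(!is_scalar_number(pixel_size) || pixel_size <= 0,
           "pixel_size must be a positive number")
  structure(list(intensities = intensities, pixel_size = pixel_size),
            class = "colony_image")
}

#' @export
print.colony_image <- function(x, ...) {
  cat("<colony_image> ", paste(dim(x$intensities), collapse = " x "),
      " px at ", x$pixel_size, " um/px\n", sep = "")
  invisible(x)
}

.otsu_threshold <- function(values) {
  rng <- range(values)
  abort_if(diff(rng) == 0, "degenerate histogram: constant intensities")
  scaled <- (values - rng[1]) / diff(rng)
  # EBImage's Otsu operates on an Image container; a 1 x n wrapping of the
  # pixel vector gives the threshold of exactly this histogram
  thr01 <- EBImage::otsu(EBImage::Image(scaled, dim = c(length(scaled), 1L)),
                         range = c(0, 1), levels = 256L)
  rng[1] + thr01 * diff(rng)
}

#' Detect the colony in a fluorescence image
#'
#' Foreground is separated from background by a global Otsu threshold of the
#' intensity histogram ("intensity difference from background"), holes are
#' filled, and the largest connected component is kept. The threshold is
#' computed on log-compressed normalized intensities,
#' \code{log(I / max(I) + 0.001)}: fluorescence images span a wide dynamic
#' range (dark exterior, dim colony body, bright T+ ring), and the
#' compression keeps body and ring on the same side of the background split
#' while remaining exactly invariant to rescaling the image by any positive
#' constant. The center is the component centroid and the radius that of the
#' circle with the component's area, both in pixel units (pixel centers at
#' integer row/col coordinates).
#'
#' @param img a \code{\link{colony_image}}.
#' @param min_fraction minimum colony size as a fraction of the image
#'   (default 0.01).
#' @param blur_sigma Gaussian pre-smoothing SD in pixels applied before
#'   thresholding (detection only; features are computed on the raw image).
#'   Suppresses pixel noise that would otherwise speckle the background
#'   split; 0 disables.
#' @return object of class \code{colony_geometry}: list with \code{mask}
#'   (logical matrix), \code{center} (row, col), \code{radius} (px).
#' @export
detect_colony <- function(img, min_fraction = 0.01, blur_sigma = 1) {
  stopifnot(inherits(img, "colony_image"))
  mat <- img$intensities
  abort_if(max(mat) <= 0, "blank image: no signal")
  if (blur_sigma > 0) {
    mat <- as.matrix(EBImage::gblur(EBImage::Image(mat, dim = dim(mat)),
                                    sigma = blur_sigma))
    mat[mat < 0] <- 0
  }
  lv <- log(mat / max(mat) + 1e-3)
  thr <- tryCatch(.otsu_threshold(as.vector(lv)),
                  error = function(e) stop("colony detection failed: ",
                                           conditionMessage(e), call. = FALSE))
  fg <- EBImage::Image(lv > thr, dim = dim(mat))
  fg <- EBImage::fillHull(fg)
  lab <- EBImage::bwlabel(fg)
  counts <- tabulate(as.integer(lab))
  abort_if(length(counts) == 0 || max(counts) < min_fraction * length(mat),
           "no colony component above the minimum size")
  keep <- which.max(counts)
  mask <- matrix(as.integer(lab) == keep, nrow(mat), ncol(mat))
  idx <- which(mask, arr.ind = TRUE)
  structure(list(mask = mask,
                 center = c(mean(idx[, 1]), mean(idx[, 2])),
                 radius = sqrt(sum(mask) / pi)),
            class = "colony_geometry")
}

#' Segment the T-positive region inside the colony
#'
#' Otsu's threshold is computed from the intensity histogram of the pixels
#' \emph{inside} the colony mask only (so the dark exterior cannot bias the
#' split between ring and colony body); T+ pixels are the inside-colony
#' pixels above it.
#'
#' @param img a \code{\link{colony_image}}.
#' @param geom the matching \code{\link{detect_colony}} result.
#' @return logical matrix, \code{TRUE} at T+ pixels.
#' @export
segment_t_positive <- function(img, geom) {
  stopifnot(inherits(img, "colony_image"), inherits(geom, "colony_geometry"))
  vals <- img$intensities[geom$mask]
  thr <- .otsu_threshold(vals)
  geom$mask & img$intensities > thr
}

#' Compute the four radial morphological features
#'
#' For every T+ pixel the normalized radial coordinate is r = distance to
#' the colony center / colony radius. The features are: \code{area}, the T+
#' fraction of the colony area; \code{position}, mean(r); \code{sd}, the
#' standard deviation of r; and \code{cv} = sd / position. Position and sd
#' are dimensionless through the radius normalization, so all four features
#' are invariant to magnification, rotation, and positive intensity
#' rescaling.
#'
#' @param t_mask logical matrix from \code{\link{segment_t_positive}}.
#' @param geom the matching \code{\link{colony_geometry}}.
#' @return one-row data frame with columns \code{area}, \code{position},
#'   \code{sd}, \code{cv}.
#' @export
compute_features <- function(t_mask, geom) {
  stopifnot(inherits(geom, "colony_geometry"),
            is.logical(t_mask), all(dim(t_mask) == dim(geom$mask)))
  abort_if(any(t_mask & !geom$mask), "t_mask must lie inside the colony mask")
  abort_if(!any(t_mask),
           "no T+ pixels: features undefined (total pattern loss)")
  idx <- which(t_mask, arr.ind = TRUE)
  r <- sqrt((idx[, 1] - geom$center[1])^2 +
              (idx[, 2] - geom$center[2])^2) / geom$radius
  pos <- mean(r)
  sdr <- if (length(r) > 1) sd(r) else 0
  data.frame(area = sum(t_mask) / sum(geom$mask),
             position = pos, sd = sdr, cv = sdr / pos)
}

#' Extract features for a dose series of colony images
#'
#' Batch wrapper feeding the LDC caller: detects, segments and measures each
#' colony, labelling rows with compound, dose and replicate. Colonies that
#' fail (no detectable colony, degenerate histogram, or total pattern loss
#' with zero T+ pixels) are dropped with a warning and counted in
#' \code{attr(, "n_excluded")}; a dose group losing \emph{all} its colonies
#' is an error.
#'
#' @param images list (one element per dose) of lists of
#'   \code{\link{colony_image}} objects.
#' @param doses concentrations matching \code{images}.
#' @param compound label for the compound column.
#' @return replicate feature table (see \code{\link{feature_dose_tests}}).
#' @export
features_for_dose_series <- function(images, doses, compound = "synthetic") {
  stopifnot(is.list(images), length(images) == length(doses))
  abort_if(any(lengths(images) == 0), "every dose group needs >= 1 image")
  n_excluded <- 0L
  rows <- lapply(seq_along(doses), function(i) {
    feats <- lapply(seq_along(images[[i]]), function(j) {
      tryCatch({
        img <- images[[i]][[j]]
        geom <- detect_colony(img)
        cbind(data.frame(compound = compound, dose = doses[i], replicate = j,
                         stringsAsFactors = FALSE),
              compute_features(segment_t_positive(img, geom), geom))
      }, error = function(e) {
        warning("dose ", doses[i], ", colony ", j, " excluded: ",
                conditionMessage(e), call. = FALSE)
        NULL
      })
    })
    feats <- feats[!vapply(feats, is.null, TRUE)]
    n_excluded <<- n_excluded + length(images[[i]]) - length(feats)
    abort_if(length(feats) == 0, "all colonies failed at dose ", doses[i])
    do.call(rbind, feats)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "n_excluded") <- n_excluded
  out
}
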