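#' Simulation parameters for a micropatterned colony image
#'
#' Describes a synthetic single-channel fluorescence image of one circular
#' colony: a disk of dim baseline signal (the colony body) carrying a
#' brighter annulus (the T+ mesoendoderm ring), on a dark background, plus
#' Gaussian pixel noise. Defaults emulate the real assay geometry: 1-mm
#' diameter colonies (radius 500 um) imaged at 2.5 um/pixel in a 512 x 512
#' frame, with the ring in the outer half of the radius.
#'
#' @param image_size square image side, pixels.
#' @param pixel_size um per pixel.
#' @param colony_radius colony radius, um (default 500 = 1-mm colony).
#' @param ring_center radial position of the ring center as a fraction of
#'   the colony radius, in \[0, 1\].
#' @param ring_width ring width as a fraction of the radius;
#'   \code{ring_center +/- ring_width/2} must stay within \[0, 1\].
#' @param ring_intensity,background_intensity arbitrary intensity units for
#'   the ring and the colony body (outside the colony is 0).
#' @param noise_sd additive Gaussian pixel noise SD (same units), >= 0.
#' @param seed RNG seed used when the image is rendered.
#' @return list of class \code{colony_sim_params}.
#' @export
colony_sim_params <- function(image_size = 512, pixel_size = 2.5,
                              colony_radius = 500, ring_center = 0.65,
                              ring_width = 0.3, ring_intensity = 200,
                              background_intensity = 40, noise_sd = 5,
                              seed = NULL) {
  abort_if(ring_center - ring_width / 2 < 0 || ring_center + ring_width / 2 > 1,
           "ring_center +/- ring_width/2 must stay within [0, 1]")
  abort_if(noise_sd < 0, "noise_sd must be >= 0")
  abort_if(ring_intensity <= background_intensity,
           "ring_intensity must exceed background_intensity")
  abort_if(2 * colony_radius / pixel_size > image_size,
           "colony does not fit in the image")
  structure(list(image_size = image_size, pixel_size = pixel_size,
                 colony_radius = colony_radius, ring_center = ring_center,
                 ring_width = ring_width, ring_intensity = ring_intensity,
                 background_intensity = background_intensity,
                 noise_sd = noise_sd, seed = seed),
            class = "colony_sim_params")
}

#' Dose-dependent disruption model for the simulator
#'
#' Maps dose to a disruption effect in \[0, 1) through a Hill function
#' \code{dose^hill / (dose^hill + potency^hill)} — smooth, monotone, and
#' parameterized by the concentration of half-maximal disruption and a
#' slope. Five qualitative modes mirror the disruption phenotypes seen in
#' the assay: blocked inward migration pushes the ring outward
#' (\code{migration_block}), accelerated migration pulls it inward
#' (\code{migration_accel}), loss/gain of differentiation dims/brightens the
#' ring (\code{diff_loss}, \code{diff_gain}), and cytotoxic cell loss shrinks
#' and dims the whole colony (\code{cell_loss}).
#'
#' @param mode one of \code{"migration_block"}, \code{"migration_accel"},
#'   \code{"diff_loss"}, \code{"diff_gain"}, \code{"cell_loss"}.
#' @param potency concentration at half-maximal disruption (ug/ml), > 0.
#' @param hill dimensionless slope, > 0.
#' @export
disruption_model <- function(mode = c("migration_block", "migration_accel",
                                      "diff_loss", "diff_gain", "cell_loss"),
                             potency, hill = 2) {
  mode <- match.arg(mode)
  abort_if(!is_scalar_number(potency) || potency <= 0, "potency must be > 0")
  abort_if(!is_scalar_number(hill) || hill <= 0, "hill must be > 0")
  structure(list(mode = mode, potency = potency, hill = hill),
            class = "disruption_model")
}

hill_effect <- function(dose, potency, hill) {
  ifelse(dose == 0, 0, dose^hill / (dose^hill + potency^hill))
}

#' Render a synthetic colony image with known ground truth
#'
#' Draws the colony described by \code{p}, optionally disrupted by model
#' \code{d} at the given dose, and returns both the image and the exact
#' truth used to draw it (colony center/radius, effective ring position, and
#' the noise-free T+ mask) so downstream feature extraction can be validated
#' pixel-for-pixel. The same parameters and seed always produce a
#' bit-identical image.
#'
#' @param p a \code{\link{colony_sim_params}}.
#' @param d a \code{\link{disruption_model}} or NULL for vehicle control.
#' @param dose concentration (ug/ml), >= 0.
#' @return list with \code{image} (a \code{\link{colony_image}}) and
#'   \code{truth}: \code{center} (row, col), \code{radius} (px),
#'   \code{ring_center_effective}, \code{ring_width},
#'   \code{ring_intensity_effective}, \code{t_mask} (logical matrix).
#' @export
simulate_colony_image <- function(p, d = NULL, dose = 0) {
  stopifnot(inherits(p, "colony_sim_params"))
  abort_if(!is_scalar_number(dose) || dose < 0, "dose must be >= 0")
  e <- 0
  if (!is.null(d)) {
    stopifnot(inherits(d, "disruption_model"))
    e <- hill_effect(dose, d$potency, d$hill)
  }

  rc <- p$ring_center
  w <- p$ring_width
  ring_int <- p$ring_intensity
  body_int <- p$background_intensity
  radius_px <- p$colony_radius / p$pixel_size
  if (!is.null(d)) {
    switch(d$mode,
      migration_block = rc <- rc + e * ((1 - w / 2) - rc),
      migration_accel = rc <- rc - e * (rc - w / 2),
      diff_loss = ring_int <- body_int + (1 - e) * (ring_int - body_int),
      diff_gain = ring_int <- ring_int * (1 + e),
      cell_loss = {
        ring_int <- ring_int * (1 - e)
        body_int <- body_int * (1 - e)
        radius_px <- radius_px * (1 - 0.5 * e)
      })
  }

  n <- p$image_size
  ctr <- (n + 1) / 2
  rows <- matrix(seq_len(n), n, n)
  cols <- matrix(seq_len(n), n, n, byrow = TRUE)
  r <- sqrt((rows - ctr)^2 + (cols - ctr)^2) / radius_px
  colony <- r <= 1
  ring <- colony & r >= rc - w / 2 & r <= rc + w / 2

  img <- matrix(0, n, n)
  img[colony] <- body_int
  img[ring] <- ring_int
  if (p$noise_sd > 0) {
    img <- with_seed(p$seed, img + matrix(rnorm(n * n, 0, p$noise_sd), n, n))
    img[img < 0] <- 0
  }

  list(image = colony_image(img, p$pixel_size),
       truth = list(center = c(ctr, ctr), radius = radius_px,
                    ring_center_effective = rc, ring_width = w,
                    ring_intensity_effective = ring_int,
                    t_mask = ring))
}

#' Simulation parameters for a replicate feature cohort
#'
#' Describes the statistical structure the LDC caller assumes: per-dose
#' replicate vectors of the four features, Gaussian around control baselines,
#' with doses at and above a known true LDC shifted by a fixed effect
#' expressed in control-SD units. Setting \code{true_ldc = NA} gives a
#' non-disruptor cohort (no shift anywhere).
#'
#' @param doses ascending concentrations with \code{doses[1] == 0} (vehicle).
#' @param replicates_per_dose colonies per dose group (>= 2; default 12).
#' @param true_ldc element of \code{doses[-1]}, or NA for a non-disruptor.
#' @param effect_sizes named per-feature shift in control-SD units applied at
#'   and above \code{true_ldc}.
#' @param baselines,noise_sd named per-feature control means and SDs;
#'   defaults match a clean annular ring at ring_center 0.65, ring_width 0.3.
#' @param seed RNG seed.
#' @export
cohort_sim_params <- function(doses, replicates_per_dose = 12,
                              true_ldc = NA,
                              effect_sizes = c(area = 0, position = 5,
                                               sd = 0, cv = 0),
                              baselines = c(area = 0.4, position = 0.65,
                                            sd = 0.08, cv = 0.12),
                              noise_sd = c(area = 0.03, position = 0.02,
                                           sd = 0.008, cv = 0.015),
                              seed = NULL) {
  abort_if(length(doses) < 2 || doses[1] != 0 ||
             is.unsorted(doses, strictly = TRUE),
           "doses must be strictly ascending with doses[1] = 0")
  abort_if(replicates_per_dose < 2,
           "replicates_per_dose must be >= 2 (t-tests need 2)")
  abort_if(!is.na(true_ldc) && !true_ldc %in% doses[-1],
           "true_ldc must be one of the non-control doses, or NA")
  for (v in list(effect_sizes, baselines, noise_sd)) {
    abort_if(!all(feature_names() %in% names(v)),
             "effect_sizes, baselines and noise_sd need entries for ",
             paste(feature_names(), collapse = ", "))
  }
  abort_if(any(noise_sd[feature_names()] <= 0), "noise_sd must be > 0")
  structure(list(doses = doses, replicates_per_dose = replicates_per_dose,
                 true_ldc = true_ldc, effect_sizes = effect_sizes,
                 baselines = baselines, noise_sd = noise_sd, seed = seed),
            class = "cohort_sim_params")
}

#' Simulate a replicate feature table with a known true LDC
#'
#' @param c a \code{\link{cohort_sim_params}}.
#' @param compound label for the compound column.
#' @return data frame with columns \code{compound}, \code{dose},
#'   \code{replicate}, \code{area}, \code{position}, \code{sd}, \code{cv};
#'   the true LDC is attached as \code{attr(, "true_ldc")}.
#' @examples
#' p <- cohort_sim_params(doses = c(0, 2.5, 5, 10, 20, 40), true_ldc = 10,
#'                        seed = 7)
#' conc_value(call_ldc_from_table(simulate_feature_table(p))$ldc)  # 10
#' @export
simulate_feature_table <- function(c, compound = "synthetic") {
  stopifnot(inherits(c, "cohort_sim_params"))
  nrep <- c$replicates_per_dose
  with_seed(c$seed, {
    rows <- lapply(c$doses, function(d) {
      shifted <- !is.na(c$true_ldc) && d >= c$true_ldc && d > 0
      vals <- lapply(feature_names(), function(f) {
        mu <- c$baselines[[f]] +
          if (shifted) c$effect_sizes[[f]] * c$noise_sd[[f]] else 0
        rnorm(nrep, mu, c$noise_sd[[f]])
      })
      names(vals) <- feature_names()
      data.frame(compound = compound, dose = d, replicate = seq_len(nrep),
                 vals, stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    attr(out, "true_ldc") <- c$true_ldc
    out
  })
}

#' Simulate a viability dose-response series
#'
#' Mean response follows a four-parameter logistic in dose; observed
#' replicate values carry multiplicative Gaussian noise with coefficient of
#' variation \code{cv_noise}. If \code{doses} is not given, the default
#' design is 8 concentrations in serial 5-fold dilutions down from
#' \code{max_dose}, the standard cytotoxicity plate layout.
#'
#' @param true_top,true_bottom upper/lower viability asymptotes
#'   (\code{true_top > true_bottom >= 0}).
#' @param true_ic50 concentration of half-maximal inhibition, > 0.
#' @param hill slope, > 0.
#' @param doses ascending positive concentrations; default NULL builds the
#'   5-fold series from \code{max_dose}.
#' @param max_dose top tested dose used when \code{doses} is NULL.
#' @param replicates replicate wells per dose (default 3 runs).
#' @param cv_noise multiplicative noise CV, >= 0.
#' @param seed RNG seed.
#' @return a \code{\link{viability_series}} with the true IC25 attached as
#'   \code{attr(, "true_ic25")}.
#' @export
simulate_viability <- function(true_top = 1, true_bottom = 0, true_ic50,
                               hill = 1, doses = NULL, max_dose = NULL,
                               replicates = 3, cv_noise = 0.05, seed = NULL) {
  abort_if(!is_scalar_number(true_ic50) || true_ic50 <= 0, "true_ic50 must be > 0")
  abort_if(!is_scalar_number(hill) || hill <= 0, "hill must be > 0")
  abort_if(true_bottom < 0 || true_top <= true_bottom,
           "need true_top > true_bottom >= 0")
  abort_if(cv_noise < 0, "cv_noise must be >= 0")
  if (is.null(doses)) {
    abort_if(is.null(max_dose), "give either doses or max_dose")
    doses <- max_dose / 5^(7:0)
  }
  abort_if(any(doses <= 0) || is.unsorted(doses, strictly = TRUE),
           "doses must be positive and strictly ascending")

  mu <- .fourpl(doses, true_top, true_bottom, true_ic50, hill)
  out <- with_seed(seed, {
    rows <- expand.grid(replicate = seq_len(replicates), dose = doses)
    noise <- if (cv_noise > 0) rnorm(nrow(rows), 0, cv_noise) else 0
    rows$viability <- pmax(rep(mu, each = replicates) * (1 + noise), 0)
    rows[, c("dose", "replicate", "viability")]
  })
  v <- viability_series(out)
  target <- 0.75 * true_top
  attr(v, "true_ic25") <- if (true_bottom >= target) NA_real_ else
    true_ic50 * ((true_top - target) / (target - true_bottom))^(1 / hill)
  v
}

#' Write a simulated colony to disk (TIFF + JSON truth sidecar)
#'
#' Stores the image as a 16-bit single-channel TIFF, the truth mask as a
#' second TIFF (\code{<path>_mask.tif}), and the scalar truth values plus
#' the intensity scale as a JSON sidecar (\code{<path>.json}).
#'
#' @param sim a \code{\link{simulate_colony_image}} result.
#' @param path output TIFF path (".tif" appended if absent).
#' @return invisibly, the three file paths.
#' @export
write_colony_tiff <- function(sim, path) {
  stopifnot(is.list(sim), inherits(sim$image, "colony_image"))
  if (!grepl("\\.tiff?$", path)) path <- paste0(path, ".tif")
  mat <- sim$image$intensities
  scale <- max(mat, 1e-12)
  tiff::writeTIFF(mat / scale, path, bits.per.sample = 16L)
  mask_path <- sub("\\.tiff?$", "_mask.tif", path)
  tiff::writeTIFF(sim$truth$t_mask * 1, mask_path, bits.per.sample = 8L)
  json_path <- sub("\\.tiff?$", ".json", path)
  truth <- sim$truth
  truth$t_mask <- NULL
  truth$intensity_scale <- scale
  truth$pixel_size <- sim$image$pixel_size
  jsonlite::write_json(truth, json_path, auto_unbox = TRUE, digits = NA)
  invisible(c(image = path, mask = mask_path, truth = json_path))
}

#' Read a single-channel TIFF as a colony image
#'
#' @param path TIFF file (8/16-bit, one channel; the first channel of a
#'   multi-channel file is used).
#' @param pixel_size um per pixel of the acquisition.
#' @export
read_colony_tiff <- function(path, pixel_size) {
  mat <- tiff::readTIFF(path)
  if (length(dim(mat)) == 3L) mat <- mat[, , 1]
  colony_image(mat, pixel_size)
}
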