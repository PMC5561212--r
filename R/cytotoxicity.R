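#' Validate a viability dose-response series
#'
#' A series holds replicate viability fractions (normalized so the vehicle
#' mean is 1) at ascending positive doses. Rows at dose 0 are treated as
#' vehicle controls: if present, all responses are renormalized by the
#' vehicle mean and the control rows dropped before fitting.
#'
#' @param data data frame with columns \code{dose}, \code{replicate},
#'   \code{viability}.
#' @return validated data frame of positive-dose rows, class
#'   \code{viability_series}.
#' @export
viability_series <- function(data) {
  need <- c("dose", "replicate", "viability")
  missing <- setdiff(need, names(data))
  abort_if(length(missing) > 0, "viability table is missing column(s): ",
           paste(missing, collapse = ", "))
  abort_if(any(!is.finite(data$dose) | data$dose < 0),
           "doses must be finite and non-negative")
  abort_if(any(!is.finite(data$viability) | data$viability < 0),
           "viability values must be finite and non-negative")
  if (any(data$dose == 0)) {
    ctrl_mean <- mean(data$viability[data$dose == 0])
    abort_if(ctrl_mean <= 0, "vehicle-control viability mean must be positive")
    data$viability <- data$viability / ctrl_mean
    data <- data[data$dose > 0, , drop = FALSE]
  }
  abort_if(length(unique(data$dose)) < 5,
           "need at least 5 distinct positive doses")
  data <- data[order(data$dose, data$replicate), , drop = FALSE]
  class(data) <- c("viability_series", "data.frame")
  data
}

.fourpl <- function(dose, top, bottom, ic50, hill) {
  bottom + (top - bottom) / (1 + (dose / ic50)^hill)
}

#' Fit a four-parameter logistic dose-response curve
#'
#' Least-squares fit of viability = bottom + (top - bottom) /
#' (1 + (dose / IC50)^hill), the standard sigmoidal dose-response model, on
#' log-dose. The fit is a bounded Levenberg-Marquardt optimization
#' (\code{minpack.lm::nlsLM}) restarted from a grid of hill/IC50 starting
#' points, keeping the best sum of squared errors. Bounds: top in
#' \[0.5, 1.5\], bottom in \[0, 0.5\], hill in \[0.1, 10\]. \code{fix_top} /
#' \code{fix_bottom} pin the corresponding asymptote (e.g. \code{fix_top = 1,
#' fix_bottom = 0} for the constrained two-parameter variant).
#'
#' A series whose mean response \emph{increases} with dose carries no
#' inhibition signal and is flagged \code{non_toxic}.
#'
#' @param v a \code{\link{viability_series}} (or data frame accepted by it).
#' @param fix_top,fix_bottom optional fixed asymptotes.
#' @return object of class \code{four_pl_fit}: list with \code{top},
#'   \code{bottom}, \code{ic50}, \code{hill}, \code{converged},
#'   \code{residual_sse}, \code{non_toxic}, \code{dose_range}.
#' @examples
#' v <- simulate_viability(true_ic50 = 10, hill = 1, max_dose = 1000,
#'                         cv_noise = 0, seed = 1)
#' fit <- fit_dose_response(v)
#' format(ic25_from_fit(fit))   # ~ 10/3
#' @export
fit_dose_response <- function(v, fix_top = NULL, fix_bottom = NULL) {
  if (!inherits(v, "viability_series")) v <- viability_series(v)
  d <- v$dose
  y <- v$viability
  dose_range <- range(d)

  means <- tapply(y, d, mean)
  slope <- coef(lm(means ~ log(sort(unique(d)))))[2]
  non_toxic <- is.finite(slope) && slope >= 0

  hills <- c(0.5, 1, 2, 4, 8)
  ic50s <- exp(seq(log(dose_range[1]), log(dose_range[2]), length.out = 3))
  starts <- expand.grid(hill = hills, ic50 = ic50s)

  lower <- c(top = 0.5, bottom = 0, lic50 = log(dose_range[1] / 100),
             hill = 0.1)
  upper <- c(top = 1.5, bottom = 0.5, lic50 = log(dose_range[2] * 100),
             hill = 10)
  free <- c(top = is.null(fix_top), bottom = is.null(fix_bottom),
            lic50 = TRUE, hill = TRUE)

  best <- NULL
  for (i in seq_len(nrow(starts))) {
    start <- list(top = 1, bottom = 0.05, lic50 = log(starts$ic50[i]),
                  hill = starts$hill[i])
    if (!is.null(fix_top)) start$top <- NULL
    if (!is.null(fix_bottom)) start$bottom <- NULL
    top_expr <- if (is.null(fix_top)) quote(top) else fix_top
    bot_expr <- if (is.null(fix_bottom)) quote(bottom) else fix_bottom
    form <- eval(bquote(
      y ~ .(bot_expr) + (.(top_expr) - .(bot_expr)) /
        (1 + (d / exp(lic50))^hill)))
    fit <- tryCatch(
      suppressWarnings(minpack.lm::nlsLM(
        form, start = start,
        lower = unname(lower[free]), upper = unname(upper[free]),
        control = minpack.lm::nls.lm.control(maxiter = 200))),
      error = function(e) NULL)
    if (is.null(fit)) next
    sse <- sum(residuals(fit)^2)
    if (is.null(best) || sse < best$sse) best <- list(fit = fit, sse = sse)
  }
  abort_if(is.null(best), "dose-response fit failed from every start")

  cf <- coef(best$fit)
  structure(list(top = if (is.null(fix_top)) unname(cf["top"]) else fix_top,
                 bottom = if (is.null(fix_bottom)) unname(cf["bottom"])
                          else fix_bottom,
                 ic50 = unname(exp(cf["lic50"])),
                 hill = unname(cf["hill"]),
                 converged = TRUE,
                 residual_sse = best$sse,
                 non_toxic = non_toxic,
                 dose_range = dose_range),
            class = "four_pl_fit")
}

#' @export
print.four_pl_fit <- function(x, ...) {
  cat(sprintf(
    "4PL fit: top %.3f  bottom %.3f  IC50 %.4g  hill %.3f  (SSE %.4g)%s\n",
    x$top, x$bottom, x$ic50, x$hill, x$residual_sse,
    if (x$non_toxic) "  [flagged non-toxic]" else ""))
  invisible(x)
}

#' @export
predict.four_pl_fit <- function(object, dose, ...) {
  .fourpl(dose, object$top, object$bottom, object$ic50, object$hill)
}

#' Extract the IC25 from a fitted dose-response curve
#'
#' The IC25 is the concentration causing a 25% reduction in viable cell
#' number relative to control, i.e. the dose where the fitted curve crosses
#' 0.75 x top (relative to the fitted upper asymptote, consistent with "25%
#' reduction from control"). The 4PL inverts in closed form:
#' \code{ic50 * ((top - target) / (target - bottom))^(1/hill)}. If the curve
#' never reaches 0.75 x top (\code{bottom > 0.75 * top}) or the solution lies
#' beyond the tested range, the result is right-censored at the highest
#' tested dose, mirroring ">X" entries in screen tables.
#'
#' @param fit a \code{\link{fit_dose_response}} result.
#' @param dose_range tested dose range; defaults to the range stored in the
#'   fit.
#' @return scalar \code{\link{censored_conc}} (ug/ml).
#' @export
ic25_from_fit <- function(fit, dose_range = fit$dose_range) {
  stopifnot(inherits(fit, "four_pl_fit"))
  abort_if(!isTRUE(fit$converged), "fit did not converge")
  max_dose <- max(dose_range)
  target <- 0.75 * fit$top
  if (fit$non_toxic || fit$bottom >= target) {
    return(censored_conc(max_dose, TRUE))
  }
  conc <- fit$ic50 * ((fit$top - target) / (target - fit$bottom))^(1 / fit$hill)
  if (!is.finite(conc) || conc > max_dose) censored_conc(max_dose, TRUE)
  else censored_conc(conc, FALSE)
}

#' Residual-bootstrap confidence interval for the IC25
#'
#' Refits the curve on residual-resampled responses and returns percentile
#' bounds of the IC25 (censored refits are excluded from the percentiles but
#' counted).
#'
#' @param v a \code{\link{viability_series}}.
#' @param n_boot number of resamples (default 200).
#' @param level confidence level.
#' @param seed RNG seed for the resampling.
#' @param ... passed on to \code{\link{fit_dose_response}}.
#' @return list with \code{estimate}, \code{lower}, \code{upper},
#'   \code{n_censored}.
#' @export
ic25_bootstrap_ci <- function(v, n_boot = 200, level = 0.95, seed = 1, ...) {
  if (!inherits(v, "viability_series")) v <- viability_series(v)
  fit <- fit_dose_response(v, ...)
  mu <- predict(fit, v$dose)
  res <- v$viability - mu
  boot <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      vb <- v
      vb$viability <- pmax(mu + sample(res, replace = TRUE), 0)
      fb <- tryCatch(fit_dose_response(vb, ...), error = function(e) NULL)
      if (is.null(fb)) return(NA_real_)
      ic <- ic25_from_fit(fb, fit$dose_range)
      if (is_censored(ic)) NA_real_ else conc_value(ic)
    }, numeric(1))
  })
  alpha <- (1 - level) / 2
  list(estimate = ic25_from_fit(fit),
       lower = quantile(boot, alpha, na.rm = TRUE, names = FALSE),
       upper = quantile(boot, 1 - alpha, na.rm = TRUE, names = FALSE),
       n_censored = sum(is.na(boot)))
}
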