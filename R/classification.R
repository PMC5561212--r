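#' Two-step teratogen decision rule
#'
#' A compound is called a teratogen when (step 1) the morphological
#' disruption it causes arises at non-cytotoxic concentrations — its lowest
#' disruption concentration (LDC) is no higher than both IC25 cytotoxicity
#' thresholds — and (step 2) the disruption is physiologically plausible —
#' the LDC is no higher than \code{k} times its peak plasma concentration
#' Cmax. Both comparisons are boundary-inclusive (\code{<=}). A censored LDC
#' (\code{">X"}, no disruption observed up to the highest tested dose) fails
#' step 1 outright; a censored IC25 acts as an infinite threshold that any
#' measured LDC satisfies.
#'
#' @param tbl a \code{compound_table} (see \code{\link{load_compound_table}}).
#' @param k positive scale factor on Cmax used by step 2 (default 10).
#' @return \code{step1()} and \code{step2()} return logical vectors.
#'   \code{classify_compounds()} returns a data frame with one row per
#'   compound: \code{name}, \code{in_vivo_class}, \code{step1_pass},
#'   \code{step2_pass} (\code{NA} when step 1 fails, i.e. not evaluated),
#'   \code{predicted} (factor NON/TER) and \code{k_used}.
#' @examples
#' out <- classify_compounds(reference_compounds(), k = 10)
#' table(out$predicted, out$in_vivo_class)
#' @export
step1 <- function(tbl) {
  stopifnot(inherits(tbl, "compound_table"))
  ldc <- threshold_value(compound_conc(tbl, "ldc"))
  ok <- ldc <= threshold_value(compound_conc(tbl, "ic25_ahdf")) &
    ldc <= threshold_value(compound_conc(tbl, "ic25_h9"))
  # a censored LDC means no disruption was ever seen: never a teratogen call
  ok & !tbl$ldc_censored
}

#' @rdname step1
#' @export
step2 <- function(tbl, k = 10) {
  stopifnot(inherits(tbl, "compound_table"))
  abort_if(!is_scalar_number(k) || k <= 0, "k must be a positive number")
  threshold_value(compound_conc(tbl, "ldc")) <= k * tbl$cmax
}

#' @rdname step1
#' @export
classify_compounds <- function(tbl, k = 10) {
  s1 <- step1(tbl)
  s2 <- ifelse(s1, step2(tbl, k), NA)
  data.frame(name = tbl$name,
             in_vivo_class = tbl$in_vivo_class,
             step1_pass = s1,
             step2_pass = s2,
             predicted = factor(ifelse(s1 & !is.na(s2) & s2, "TER", "NON"),
                                levels = c("NON", "TER")),
             k_used = k,
             stringsAsFactors = FALSE)
}

#' Screen performance against in vivo labels
#'
#' Applies the two-step rule to every compound and scores predictions against
#' the in vivo teratogenicity labels. Teratogen is the positive class:
#' sensitivity = tp / (tp + fn), specificity = tn / (tn + fp), accuracy =
#' (tp + tn) / n. Percentages are kept at full precision and rounded to the
#' nearest integer for reporting.
#'
#' @inheritParams step1
#' @return a list of class \code{screen_result} with elements
#'   \code{outcomes} (the \code{\link{classify_compounds}} data frame) and
#'   \code{performance}, a \code{performance_summary} holding the confusion
#'   counts and both exact and rounded percentages.
#' @examples
#' screen_compounds(reference_compounds())$performance
#' @export
screen_compounds <- function(tbl, k = 10) {
  abort_if(anyNA(tbl$in_vivo_class), "every compound needs an in vivo label")
  out <- classify_compounds(tbl, k)
  perf <- performance_summary(predicted = out$predicted,
                              truth = out$in_vivo_class)
  structure(list(outcomes = out, performance = perf, k = k),
            class = "screen_result")
}

#' @rdname screen_compounds
#' @param predicted,truth factors with levels \code{NON}, \code{TER}.
#' @export
performance_summary <- function(predicted, truth) {
  stopifnot(length(predicted) == length(truth))
  predicted <- factor(predicted, levels = c("NON", "TER"))
  truth <- factor(truth, levels = c("NON", "TER"))
  tp <- sum(predicted == "TER" & truth == "TER")
  fp <- sum(predicted == "TER" & truth == "NON")
  tn <- sum(predicted == "NON" & truth == "NON")
  fn <- sum(predicted == "NON" & truth == "TER")
  sens <- 100 * tp / (tp + fn)
  spec <- 100 * tn / (tn + fp)
  acc <- 100 * (tp + tn) / length(truth)
  structure(list(tp = tp, fp = fp, tn = tn, fn = fn,
                 sensitivity = sens, specificity = spec, accuracy = acc,
                 sensitivity_pct = round(sens), specificity_pct = round(spec),
                 accuracy_pct = round(acc)),
            class = "performance_summary")
}

#' @export
print.performance_summary <- function(x, ...) {
  cat("Screen performance (teratogen = positive)\n")
  cat(sprintf("  tp %d  fp %d  tn %d  fn %d\n", x$tp, x$fp, x$tn, x$fn))
  cat(sprintf("  sensitivity %d%%  specificity %d%%  accuracy %d%%\n",
              x$sensitivity_pct, x$specificity_pct, x$accuracy_pct))
  invisible(x)
}

#' @export
print.screen_result <- function(x, ...) {
  cat("Two-step teratogen screen, k =", x$k, "\n")
  print(x$performance)
  invisible(x)
}

#' Rank AUC of a score against binary labels
#'
#' Area under the ROC curve computed by the Mann-Whitney rank identity, with
#' tied scores counted 1/2 (the standard concordance convention). By default
#' a \emph{lower} score indicates the positive class, matching the LDC/Cmax
#' exposure-margin score where teratogens sit at small ratios.
#'
#' @param score numeric vector.
#' @param positive logical vector, \code{TRUE} for the positive class.
#' @param direction \code{"low"} if small scores indicate positives,
#'   \code{"high"} otherwise.
#' @return AUC in \[0, 1\].
#' @export
rank_auc <- function(score, positive, direction = c("low", "high")) {
  direction <- match.arg(direction)
  positive <- as.logical(positive)
  stopifnot(length(score) == length(positive), !anyNA(score), !anyNA(positive))
  n_pos <- sum(positive)
  n_neg <- sum(!positive)
  abort_if(n_pos == 0 || n_neg == 0, "need both classes to compute an AUC")
  r <- rank(score, ties.method = "average")
  # pairs where the positive outranks (exceeds) the negative, ties as 1/2
  u_pos_high <- sum(r[positive]) - n_pos * (n_pos + 1) / 2
  auc_high <- u_pos_high / (n_pos * n_neg)
  if (direction == "low") 1 - auc_high else auc_high
}

#' Cmax scale-factor optimization
#'
#' Searches the integer grid of Cmax scale factors for the value(s) that best
#' separate teratogens from non-teratogens among the step-1 passers. For each
#' k the full-data criterion is the number of compounds whose step-2 call
#' (LDC <= k * Cmax) agrees with the in vivo label; \code{best_k_set} is the
#' argmax of that count. A leave-one-out pass repeats the grid evaluation
#' with each compound held out and records every run's optimum set, showing
#' the stability of the chosen factor. The full-data rank AUC of the
#' exposure-margin score LDC / Cmax (lower = more teratogen-like) is also
#' reported.
#'
#' @param tbl a \code{compound_table}; rows failing step 1 are dropped
#'   (they never reach step 2).
#' @param k_grid integer grid of candidate scale factors, default 1..20.
#' @return an object of class \code{scale_factor_search}: list with
#'   \code{k_grid}, \code{n_correct} (full-data correct counts per k),
#'   \code{accuracy} (the same as fractions), \code{best_k_set},
#'   \code{loo_correct} (runs x k matrix), \code{loo_best} (list of per-run
#'   optimum sets), \code{auc_full}, \code{n_passers}.
#' @examples
#' scale_factor_search(reference_compounds())$best_k_set  # 7 8 9 10
#' @export
scale_factor_search <- function(tbl, k_grid = 1:20) {
  stopifnot(inherits(tbl, "compound_table"))
  abort_if(length(k_grid) == 0 || any(k_grid <= 0), "k_grid must be positive")
  passers <- tbl[step1(tbl), , drop = FALSE]
  n_ter <- sum(passers$in_vivo_class == "TER")
  n_non <- sum(passers$in_vivo_class == "NON")
  abort_if(n_ter < 2 || n_non < 2,
           "need at least 2 step-1 passers of each class, got ",
           n_non, " NON and ", n_ter, " TER")

  ldc <- threshold_value(compound_conc(passers, "ldc"))
  is_ter <- passers$in_vivo_class == "TER"
  correct_at_k <- function(idx, k) {
    pred_ter <- ldc[idx] <= k * passers$cmax[idx]
    sum(pred_ter == is_ter[idx])
  }
  n <- nrow(passers)
  full <- vapply(k_grid, function(k) correct_at_k(seq_len(n), k), 0)
  best <- k_grid[full == max(full)]

  loo <- t(vapply(seq_len(n), function(i) {
    vapply(k_grid, function(k) correct_at_k(setdiff(seq_len(n), i), k), 0)
  }, numeric(length(k_grid))))
  dimnames(loo) <- list(passers$name, paste0("k", k_grid))
  loo_best <- apply(loo, 1L, function(row) k_grid[row == max(row)],
                    simplify = FALSE)

  auc <- rank_auc(ldc / passers$cmax, is_ter, direction = "low")
  structure(list(k_grid = k_grid, n_correct = full, accuracy = full / n,
                 best_k_set = best, loo_correct = loo, loo_best = loo_best,
                 auc_full = auc, n_passers = n),
            class = "scale_factor_search")
}

#' @export
print.scale_factor_search <- function(x, ...) {
  cat("Cmax scale-factor search over", length(x$k_grid), "factors,",
      x$n_passers, "step-1 passers\n")
  cat("  best k set:", paste(x$best_k_set, collapse = " "),
      sprintf("(%d/%d correct)\n", max(x$n_correct), x$n_passers))
  cat(sprintf("  full-data rank AUC of LDC/Cmax: %.3f\n", x$auc_full))
  invisible(x)
}

#' Leave-one-out verification classifiers
#'
#' Independent check of the scale-factor rule: binary logistic regression and
#' a linear-kernel support vector machine are trained on log10(LDC) and
#' log10(Cmax) under leave-one-out cross-validation, and the held-out scores
#' are summarized as a rank AUC per model. Rows with a censored LDC carry no
#' usable disruption concentration and are excluded with a warning.
#'
#' @param tbl a \code{compound_table}.
#' @return named numeric vector with elements \code{logistic} and \code{svm}.
#' @export
reference_classifiers_loo <- function(tbl) {
  stopifnot(inherits(tbl, "compound_table"))
  drop <- tbl$ldc_censored
  if (any(drop)) {
    warning("excluding ", sum(drop), " compound(s) with censored LDC: ",
            paste(tbl$name[drop], collapse = ", "), call. = FALSE)
    tbl <- tbl[!drop, , drop = FALSE]
  }
  y <- factor(tbl$in_vivo_class, levels = c("NON", "TER"))
  abort_if(min(table(y)) < 2, "need at least 2 compounds of each class")
  dat <- data.frame(y = y, ldc = log10(tbl$ldc), cmax = log10(tbl$cmax))
  n <- nrow(dat)

  glm_score <- svm_score <- numeric(n)
  for (i in seq_len(n)) {
    train <- dat[-i, , drop = FALSE]
    fit_glm <- suppressWarnings(
      glm(y ~ ldc + cmax, data = train, family = binomial()))
    glm_score[i] <- predict(fit_glm, dat[i, , drop = FALSE], type = "link")

    fit_svm <- suppressWarnings(
      e1071::svm(y ~ ldc + cmax, data = train, kernel = "linear",
                 scale = TRUE))
    dv <- attr(predict(fit_svm, dat[i, , drop = FALSE],
                       decision.values = TRUE), "decision.values")
    # decision value is signed toward the first class of its column label
    svm_score[i] <- if (startsWith(colnames(dv)[1], "TER")) dv[1] else -dv[1]
  }
  c(logistic = rank_auc(glm_score, y == "TER", direction = "high"),
    svm = rank_auc(svm_score, y == "TER", direction = "high"))
}
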