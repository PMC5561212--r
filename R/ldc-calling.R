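.validate_feature_table <- function(tbl) {
  need <- c("dose", "replicate", feature_names())
  missing <- setdiff(need, names(tbl))
  abort_if(length(missing) > 0, "feature table is missing column(s): ",
           paste(missing, collapse = ", "))
  abort_if(!0 %in% tbl$dose, "feature table needs a dose-0 (vehicle) group")
  counts <- table(tbl$dose)
  abort_if(any(counts < 2),
           "every dose group needs at least 2 replicates; offending dose(s): ",
           paste(names(counts)[counts < 2], collapse = ", "))
  invisible(tbl)
}

#' Per-dose t-tests of morphological features against vehicle control
#'
#' For each of the four features (area, position, sd, cv) and each
#' non-control dose group, runs a two-sided unpaired two-sample t-test of
#' that group against the dose-0 vehicle group. Welch's unequal-variance
#' test is the default; set \code{var_equal = TRUE} for the pooled-variance
#' variant. No multiple-testing correction is applied: the downstream LDC
#' rule works on the raw per-test p-values at its own alpha.
#'
#' Degenerate groups are handled explicitly: if both groups have zero
#' within-group variance, p is 1 when the means are equal (no evidence of
#' any difference) and 0 when they differ (the groups are exactly separated).
#'
#' @param tbl data frame with columns \code{dose} (0 = vehicle control),
#'   \code{replicate}, \code{area}, \code{position}, \code{sd}, \code{cv};
#'   every dose needs >= 2 replicates.
#' @param var_equal pool variances? Default \code{FALSE} (Welch).
#' @return numeric matrix of p-values, rows = features, columns = ascending
#'   non-control doses.
#' @export
feature_dose_tests <- function(tbl, var_equal = FALSE) {
  .validate_feature_table(tbl)
  doses <- sort(unique(tbl$dose[tbl$dose > 0]))
  abort_if(length(doses) == 0, "feature table has only the control group")
  p <- matrix(NA_real_, nrow = 4L, ncol = length(doses),
              dimnames = list(feature_names(), doses))
  for (f in feature_names()) {
    ctrl <- tbl[[f]][tbl$dose == 0]
    for (j in seq_along(doses)) {
      grp <- tbl[[f]][tbl$dose == doses[j]]
      if (sd(ctrl) == 0 && sd(grp) == 0) {
        p[f, j] <- if (mean(ctrl) == mean(grp)) 1 else 0
      } else {
        p[f, j] <- t.test(grp, ctrl, var.equal = var_equal)$p.value
      }
    }
  }
  p
}

#' Call the lowest disruption concentration (LDC)
#'
#' Applies the breakpoint rule to a feature-by-dose p-value matrix: for each
#' feature the candidate is the lowest dose significant at \code{alpha}
#' (p < alpha) such that \emph{every} higher dose is also significant — a
#' non-significant higher dose is a "breaking point" that disqualifies all
#' lower candidates. A feature with no valid candidate is right-censored at
#' the highest tested dose. The compound's LDC is the minimum across the
#' four per-feature calls; it is censored only if all four are.
#'
#' @param p_matrix matrix from \code{\link{feature_dose_tests}} (features x
#'   ascending non-control doses).
#' @param doses ascending non-control concentrations matching the columns;
#'   defaults to the column names of \code{p_matrix}.
#' @param alpha significance level, default 0.01.
#' @return an \code{ldc_result}: list with \code{p_matrix},
#'   \code{significant} (logical matrix), \code{per_feature_ldc}
#'   (\code{\link{censored_conc}} of length 4), \code{ldc} (scalar
#'   \code{censored_conc}), \code{alpha}, \code{doses}.
#' @examples
#' p <- matrix(c(0.5, 0.5, 0.001, 0.001, 0.001), nrow = 1)
#' p <- p[rep(1, 4), ]            # same pattern for all four features
#' rownames(p) <- c("area", "position", "sd", "cv")
#' conc_value(call_ldc(p, doses = c(1, 2, 5, 10, 20))$ldc)  # 5
#' @export
call_ldc <- function(p_matrix, doses = NULL, alpha = 0.01) {
  if (is.null(doses)) doses <- as.numeric(colnames(p_matrix))
  abort_if(anyNA(doses) || is.unsorted(doses, strictly = TRUE),
           "doses must be strictly ascending and match p_matrix columns")
  abort_if(length(doses) != ncol(p_matrix),
           "length(doses) must equal ncol(p_matrix)")
  abort_if(anyNA(p_matrix) || any(p_matrix < 0 | p_matrix > 1),
           "p_matrix must be complete with values in [0, 1]")
  abort_if(!is_scalar_number(alpha) || alpha <= 0 || alpha >= 1,
           "alpha must be in (0, 1)")

  sig <- p_matrix < alpha
  n_dose <- length(doses)
  top <- doses[n_dose]
  per_feature <- apply(sig, 1L, function(s) {
    if (!s[n_dose]) return(NA_real_)
    not_sig <- which(!s)
    j <- if (length(not_sig) == 0) 1L else max(not_sig) + 1L
    doses[j]
  })
  pf <- censored_conc(ifelse(is.na(per_feature), top, per_feature),
                      is.na(per_feature))
  names(pf) <- rownames(p_matrix)
  ldc <- if (all(is.na(per_feature))) censored_conc(top, TRUE)
         else censored_conc(min(per_feature, na.rm = TRUE), FALSE)
  structure(list(p_matrix = p_matrix, significant = sig,
                 per_feature_ldc = pf, ldc = ldc, alpha = alpha,
                 doses = doses),
            class = "ldc_result")
}

#' @rdname call_ldc
#' @param tbl replicate feature table (see \code{\link{feature_dose_tests}}).
#' @param var_equal pool variances in the t-tests?
#' @export
call_ldc_from_table <- function(tbl, alpha = 0.01, var_equal = FALSE) {
  p <- feature_dose_tests(tbl, var_equal = var_equal)
  call_ldc(p, alpha = alpha)
}

#' @export
print.ldc_result <- function(x, ...) {
  cat("LDC call at alpha =", x$alpha, "\n")
  cat("  per-feature:",
      paste(names(x$per_feature_ldc), format(x$per_feature_ldc),
            sep = "=", collapse = "  "), "\n")
  cat("  LDC:", format(x$ldc), "ug/ml\n")
  invisible(x)
}

#' Aggregate LDC calls into a summary table
#'
#' @param results named list of \code{ldc_result} objects (names = compounds).
#' @return data frame with one row per compound: the called LDC token plus
#'   the four per-feature calls.
#' @export
ldc_report <- function(results) {
  stopifnot(is.list(results), length(results) > 0,
            !is.null(names(results)))
  rows <- lapply(names(results), function(nm) {
    r <- results[[nm]]
    stopifnot(inherits(r, "ldc_result"))
    pf <- setNames(as.list(format(r$per_feature_ldc)),
                   paste0("ldc_", feature_names()))
    cbind(data.frame(compound = nm, ldc = format(r$ldc),
                     stringsAsFactors = FALSE),
          as.data.frame(pf, stringsAsFactors = FALSE))
  })
  do.call(rbind, rows)
}
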