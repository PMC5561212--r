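#' Censored concentrations
#'
#' Screening tables report some concentrations as lower bounds: an entry
#' \code{">1000"} means no effect was observed up to 1000 ug/ml, so the true
#' quantity exceeds it. \code{censored_conc()} builds a vector of such values;
#' \code{parse_concentration()} parses the text tokens used in compound
#' tables; \code{threshold_value()} converts to plain numbers for ordering
#' comparisons, mapping right-censored values to \code{+Inf} (a ">" bound can
#' never be exceeded by a measured value, and a ">" lowest-disruption
#' concentration compared against any finite threshold fails a \code{<=}
#' test).
#'
#' @param value numeric vector of positive, finite concentrations (ug/ml).
#' @param censored logical vector (recycled); \code{TRUE} marks a ">" bound.
#' @return \code{censored_conc()} and \code{parse_concentration()} return a
#'   \code{censored_conc} vector; \code{threshold_value()} returns a numeric
#'   vector with \code{+Inf} at censored positions.
#' @examples
#' parse_concentration(c(">1000", "0.025"))
#' threshold_value(parse_concentration(">360"))  # +Inf
#' @export
censored_conc <- function(value, censored = FALSE) {
  value <- as.numeric(value)
  censored <- rep_len(as.logical(censored), length(value))
  abort_if(any(!is.finite(value) | value <= 0),
           "concentrations must be finite and positive")
  structure(value, censored = censored, class = "censored_conc")
}

#' @rdname censored_conc
#' @param x object to convert or inspect.
#' @export
parse_concentration <- function(x) {
  x <- trimws(as.character(x))
  censored <- startsWith(x, ">")
  num <- suppressWarnings(as.numeric(ifelse(censored, substring(x, 2L), x)))
  bad <- !is.finite(num) | num <= 0
  abort_if(any(bad), "cannot parse concentration token(s): ",
           paste(sQuote(x[bad]), collapse = ", "))
  censored_conc(num, censored)
}

#' @rdname censored_conc
#' @export
threshold_value <- function(x) UseMethod("threshold_value")

#' @export
threshold_value.censored_conc <- function(x) {
  ifelse(is_censored(x), Inf, as.numeric(unclass(x)))
}

#' @export
threshold_value.numeric <- function(x) x

#' @rdname censored_conc
#' @export
is_censored <- function(x) {
  stopifnot(inherits(x, "censored_conc"))
  attr(x, "censored")
}

#' @rdname censored_conc
#' @export
conc_value <- function(x) {
  stopifnot(inherits(x, "censored_conc"))
  as.numeric(unclass(x))
}

#' @export
format.censored_conc <- function(x, ...) {
  paste0(ifelse(is_censored(x), ">", ""),
         vapply(conc_value(x), format, "", scientific = FALSE))
}

#' @export
print.censored_conc <- function(x, ...) {
  cat("<censored_conc[", length(x), "]> ",
      paste(format(x), collapse = " "), "\n", sep = "")
  invisible(x)
}

#' @export
`[.censored_conc` <- function(x, i) {
  censored_conc(conc_value(x)[i], is_censored(x)[i])
}

#' @export
c.censored_conc <- function(...) {
  parts <- list(...)
  censored_conc(unlist(lapply(parts, conc_value)),
                unlist(lapply(parts, is_censored)))
}

#' @export
as.character.censored_conc <- function(x, ...) format(x)

.conc_cols <- c("ic25_ahdf", "ic25_h9", "ldc")
.table_cols <- c("name", "class", "ic25_ahdf", "ic25_h9", "cmax", "ldc")

#' Load, write and access compound screen tables
#'
#' A compound table has one row per compound with its in vivo teratogenicity
#' label and four concentrations (all ug/ml): the IC25 cytotoxicity
#' thresholds in adult human dermal fibroblasts (general cytotoxicity,
#' \code{ic25_ahdf}) and H9 hPSCs (embryonic cytotoxicity, \code{ic25_h9}),
#' the peak therapeutic plasma concentration \code{cmax}, and the lowest
#' disruption concentration \code{ldc} measured in the colony assay. IC25 and
#' LDC cells may be right-censored (\code{">1000"}); \code{cmax} must be
#' exact. The loaded table keeps each censored column as a numeric value
#' column plus a logical \code{*_censored} companion, and retains the
#' original cell tokens so \code{write_compound_table()} round-trips them
#' exactly.
#'
#' \code{reference_compounds()} returns the packaged 30-compound reference
#' screen (15 non-teratogens, 15 teratogens); \code{compound_labels()}
#' returns its companion metadata (FDA pregnancy letter, chemical class),
#' used for reporting only.
#'
#' @param path CSV file with columns \code{name, class, ic25_ahdf, ic25_h9,
#'   cmax, ldc}; \code{class} is \code{NON} or \code{TER}.
#' @return a \code{compound_table} data frame with columns \code{name},
#'   \code{in_vivo_class} (factor NON/TER), numeric \code{ic25_ahdf},
#'   \code{ic25_h9}, \code{cmax}, \code{ldc} and logical
#'   \code{ic25_ahdf_censored}, \code{ic25_h9_censored}, \code{ldc_censored}.
#' @examples
#' tbl <- reference_compounds()
#' nrow(tbl)                      # 30
#' table(tbl$in_vivo_class)       # 15 NON, 15 TER
#' @export
load_compound_table <- function(path) {
  raw <- read.csv(path, colClasses = "character", check.names = TRUE)
  missing <- setdiff(.table_cols, names(raw))
  abort_if(length(missing) > 0,
           "compound table is missing column(s): ",
           paste(missing, collapse = ", "))
  raw <- raw[, .table_cols]
  if (nrow(raw) == 0L) {
    warning("compound table has a header but no rows", call. = FALSE)
  }
  dup <- raw$name[duplicated(raw$name)]
  abort_if(length(dup) > 0, "duplicate compound name(s): ",
           paste(unique(dup), collapse = ", "))
  bad_class <- !raw$class %in% c("NON", "TER")
  abort_if(any(bad_class), "row(s) ", paste(which(bad_class), collapse = ", "),
           ": class must be NON or TER")

  out <- data.frame(name = raw$name,
                    in_vivo_class = factor(raw$class, levels = c("NON", "TER")),
                    stringsAsFactors = FALSE)
  for (col in .conc_cols) {
    cc <- tryCatch(parse_concentration(raw[[col]]),
                   error = function(e) stop("column ", sQuote(col), ": ",
                                            conditionMessage(e), call. = FALSE))
    out[[col]] <- conc_value(cc)
    out[[paste0(col, "_censored")]] <- is_censored(cc)
  }
  cmax <- tryCatch(parse_concentration(raw$cmax),
                   error = function(e) stop("column 'cmax': ",
                                            conditionMessage(e), call. = FALSE))
  abort_if(any(is_censored(cmax)), "cmax must be exact, found censored cell(s) at row(s) ",
           paste(which(is_censored(cmax)), collapse = ", "))
  out$cmax <- conc_value(cmax)
  out <- out[, c("name", "in_vivo_class", "ic25_ahdf", "ic25_ahdf_censored",
                 "ic25_h9", "ic25_h9_censored", "cmax", "ldc", "ldc_censored")]
  attr(out, "tokens") <- raw
  class(out) <- c("compound_table", "data.frame")
  out
}

#' @rdname load_compound_table
#' @export
reference_compounds <- function() {
  load_compound_table(system.file("extdata", "table2_compounds.csv",
                                  package = "teratoscreen", mustWork = TRUE))
}

#' @rdname load_compound_table
#' @export
compound_labels <- function() {
  read.csv(system.file("extdata", "table1_labels.csv",
                       package = "teratoscreen", mustWork = TRUE),
           colClasses = "character")
}

#' @rdname load_compound_table
#' @param tbl a \code{compound_table}.
#' @export
serialize_compound_table <- function(tbl) {
  stopifnot(inherits(tbl, "compound_table"))
  tokens <- attr(tbl, "tokens")
  if (!is.null(tokens) && nrow(tokens) == nrow(tbl)) return(tokens)
  fmt <- function(col) {
    format(censored_conc(tbl[[col]], tbl[[paste0(col, "_censored")]]))
  }
  data.frame(name = tbl$name, class = as.character(tbl$in_vivo_class),
             ic25_ahdf = fmt("ic25_ahdf"), ic25_h9 = fmt("ic25_h9"),
             cmax = vapply(tbl$cmax, format, "", scientific = FALSE),
             ldc = fmt("ldc"), stringsAsFactors = FALSE)
}

#' @rdname load_compound_table
#' @export
write_compound_table <- function(tbl, path) {
  write.csv(serialize_compound_table(tbl), path, row.names = FALSE,
            quote = FALSE)
  invisible(path)
}

#' Extract one concentration column as a censored_conc vector
#'
#' @param tbl a \code{compound_table}.
#' @param col one of \code{"ic25_ahdf"}, \code{"ic25_h9"}, \code{"ldc"}.
#' @export
compound_conc <- function(tbl, col = c("ic25_ahdf", "ic25_h9", "ldc")) {
  col <- match.arg(col)
  censored_conc(tbl[[col]], tbl[[paste0(col, "_censored")]])
}

#' @export
print.compound_table <- function(x, ...) {
  cat("Compound screen table:", nrow(x), "compounds (",
      sum(x$in_vivo_class == "NON"), "NON /",
      sum(x$in_vivo_class == "TER"), "TER )\n")
  print(as.data.frame(x), ...)
  invisible(x)
}
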