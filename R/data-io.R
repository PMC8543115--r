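#' COVID-19 daily death ratios, Italy, 1 April - 20 July 2020
#'
#' The 111 daily ratios of new deaths to new cases for Italy recorded from
#' 1 April to 20 July 2020 (World Health Organization daily situation
#' data), shipped as a plain-text fixture. These lifetime-like ratios are
#' the package's worked-example dataset: they are well described by a
#' Weibull model with shape near 2.22 and scale near 0.188.
#'
#' @return Numeric vector of 111 non-negative ratios, with a `"label"`
#'   attribute.
#' @examples
#' x <- covid_italy_ratios()
#' length(x); range(x)
#' @export
covid_italy_ratios <- function() {
  path <- system.file("extdata", "covid_italy_ratios.csv",
                      package = "raspweib", mustWork = TRUE)
  read_ratio_data(path, label = "Italy daily death ratios, Apr-Jul 2020")
}

#' Read a one-column ratio/lifetime dataset
#'
#' Parses one-value-per-line text or single-column CSV. A single header
#' line is auto-detected (first line not parseable as a number). Negative
#' and non-numeric rows are rejected with line-numbered errors.
#'
#' @param path file path.
#' @param label optional free-text label attached to the result.
#' @return Numeric vector of non-negative values with attribute `"label"`.
#' @export
read_ratio_data <- function(path, label = NULL) {
  if (!file.exists(path)) {
    stop(sprintf("file not found: '%s'", path), call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  keep <- nzchar(lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) stop(sprintf("empty file: '%s'", path), call. = FALSE)
  vals <- suppressWarnings(as.numeric(lines))
  start <- 1L
  if (is.na(vals[1L]) && length(lines) > 1L) {
    start <- 2L  # header line
  }
  vals <- vals[start:length(vals)]
  lineno <- lineno[start:length(lineno)]
  if (!length(vals)) stop(sprintf("no data rows in '%s'", path), call. = FALSE)
  bad <- which(is.na(vals))
  if (length(bad)) {
    stop(sprintf("non-numeric value at line %d of '%s'", lineno[bad[1L]], path),
         call. = FALSE)
  }
  neg <- which(vals < 0)
  if (length(neg)) {
    stop(sprintf("negative value (%g) at line %d of '%s'",
                 vals[neg[1L]], lineno[neg[1L]], path), call. = FALSE)
  }
  attr(vals, "label") <- if (is.null(label)) basename(path) else label
  vals
}

#' Write a design table to CSV
#'
#' Renders the output of [generate_design_table()] with the conventional
#' formatting: ASN to two decimals and "-" for infeasible cells.
#'
#' @param table a `data.frame` from [generate_design_table()].
#' @param path output file path.
#' @param digits decimal places for the ASN column (default 2).
#' @return (Invisibly) the formatted `data.frame` that was written.
#' @export
write_design_table <- function(table, path, digits = 2) {
  if (!is.data.frame(table) || !nrow(table)) {
    stop("'table' must be a nonempty data.frame", call. = FALSE)
  }
  need <- c("beta_risk", "ratio", "I", "n", "c1", "c2", "ASN")
  if (!all(need %in% names(table))) {
    stop("'table' must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  out <- table[, need]
  fmt <- function(v, f) ifelse(is.na(v), "-", f(v))
  out$n <- fmt(out$n, function(v) sprintf("%d", as.integer(v)))
  out$c1 <- fmt(out$c1, function(v) sprintf("%d", as.integer(v)))
  out$c2 <- fmt(out$c2, function(v) sprintf("%d", as.integer(v)))
  out$ASN <- fmt(out$ASN, function(v) sprintf(paste0("%.", digits, "f"), v))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(out)
}
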