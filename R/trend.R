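#' Log2 expression ratio of cultured versus fresh tissue
#'
#' `log2(cultured) - log2(fresh)` for paired transcript abundances from the
#' same patient. Zero counts are handled with a pseudocount added to both
#' sides, so equal counts always map to 0.
#'
#' @param count_cultured,count_fresh Transcript abundances (vectorised).
#' @param pseudocount Added to both counts when either is zero.
#' @return Log2 fold change.
#' @export
#' @examples
#' log2_ratio(100, 800) # -3
log2_ratio <- function(count_cultured, count_fresh, pseudocount = 0.5) {
  if (any(count_cultured < 0) || any(count_fresh < 0)) {
    abort_domain("counts must be non-negative")
  }
  zero <- count_cultured == 0 | count_fresh == 0
  cc <- count_cultured + ifelse(zero, pseudocount, 0)
  cf <- count_fresh + ifelse(zero, pseudocount, 0)
  log2(cc) - log2(cf)
}

#' Linear time trend of log2 ratios over culture days
#'
#' Ordinary least squares of the log2 expression ratio on culture day. The
#' intercept extrapolates to day 0 and separates the immediate
#' culture-adaptation response from the long-term drift, which is reported
#' as `slope_x35`, the slope scaled to the full 35-day culture window (one
#' unit = one doubling over 35 days).
#'
#' @param days Culture days (default design: 8, 14, 24, 35).
#' @param log2_ratios Matching log2 ratios.
#' @return A tibble with `intercept`, `slope` (per day) and `slope_x35`.
#' @export
#' @examples
#' ols_trend(c(8, 14, 24, 35), c(-3.76, -1.52, -2.64, 0.60)) # MYH7-like
ols_trend <- function(days, log2_ratios) {
  if (length(days) != length(log2_ratios)) {
    abort_domain("`days` and `log2_ratios` must have equal length")
  }
  ok <- !is.na(log2_ratios) & !is.na(days)
  days <- days[ok]; y <- log2_ratios[ok]
  if (length(unique(days)) < 2) {
    abort_domain("need at least two distinct days for a trend")
  }
  if (any(days <= 0)) abort_domain("culture days must be positive")
  # closed-form least squares
  xb <- mean(days); yb <- mean(y)
  slope <- sum((days - xb) * (y - yb)) / sum((days - xb)^2)
  intercept <- yb - slope * xb
  tibble(intercept = intercept, slope = slope, slope_x35 = slope * 35)
}

#' Trend table for a set of genes
#'
#' Computes the day-0 intercept and 35-day trend for every gene of a
#' log2-ratio table, classifies the trend (`positive` / `negative` /
#' `flat`, threshold one doubling over 35 days), and sorts by `slope_x35`.
#'
#' @param data A data frame with one row per gene and log2-ratio columns
#'   named `d<day>` (default `d8`, `d14`, `d24`, `d35`).
#' @param days Culture days corresponding to the ratio columns.
#' @param flat_threshold `|slope_x35|` below which a trend is `flat`.
#' @return The input tibble with (re)computed `intercept`, `slope_x35` and
#'   `trend` columns, sorted by decreasing `slope_x35`.
#' @export
#' @examples
#' tab <- myoslice_gene_table(1)
#' trend_table(tab)
trend_table <- function(data, days = c(8, 14, 24, 35), flat_threshold = 1) {
  cols <- paste0("d", days)
  if (nrow(data) == 0) {
    out <- as_tibble(data)
    out$intercept <- numeric(0)
    out$slope_x35 <- numeric(0)
    out$trend <- character(0)
    return(out)
  }
  if (!all(cols %in% names(data))) {
    abort_format(sprintf("missing ratio columns: %s",
                         paste(setdiff(cols, names(data)), collapse = ", ")))
  }
  fits <- purrr::map(seq_len(nrow(data)), function(i) {
    ols_trend(days, as.numeric(data[i, cols]))
  })
  out <- as_tibble(data)
  out$intercept <- vapply(fits, function(f) f$intercept, numeric(1))
  out$slope_x35 <- vapply(fits, function(f) f$slope_x35, numeric(1))
  out$trend <- dplyr::case_when(
    out$slope_x35 >= flat_threshold ~ "positive",
    out$slope_x35 <= -flat_threshold ~ "negative",
    TRUE ~ "flat"
  )
  dplyr::arrange(out, dplyr::desc(.data$slope_x35))
}

#' Built-in gene time-course tables
#'
#' The two published reference tables of log2 expression ratios (cultured
#' vs. fresh myocardium from the same patient) over 8, 14, 24 and 35 days
#' of culture, with the printed day-0 intercept and slope-times-35 columns:
#' table 1 covers cardiomyocyte contractility, mitochondrial and
#' disease-marker genes; table 2 growth factors, extracellular matrix,
#' hypoxia targets and the strongest positive/negative trends.
#'
#' @param which 1 or 2.
#' @return A tibble with columns `category`, `protein`, `gene`, `d8`,
#'   `d14`, `d24`, `d35`, `intercept`, `slope_x35`.
#' @export
#' @examples
#' myoslice_gene_table(1)
myoslice_gene_table <- function(which = 1) {
  stopifnot(which %in% c(1, 2))
  path <- system.file("extdata",
                      sprintf("gene_trend_table%d.tsv", which),
                      package = "myoslice", mustWork = TRUE)
  read_gene_table(path)
}

#' Read or write a gene time-course table (TSV)
#'
#' @param path TSV path with columns `protein`, `gene`, ratio columns
#'   `d<day>...`, and optionally `category`, `intercept`, `slope_x35`.
#' @return A tibble.
#' @export
read_gene_table <- function(path) {
  d <- read.delim(path, check.names = FALSE)
  if (!all(c("gene") %in% names(d)) || !any(grepl("^d\\d+$", names(d)))) {
    abort_format("gene table needs a `gene` column and `d<day>` ratio columns")
  }
  as_tibble(d)
}

#' @rdname read_gene_table
#' @param data Table to write.
#' @export
write_gene_table <- function(data, path) {
  write.table(data, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
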