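#' Chi-square test of homogeneity on a contingency table
#'
#' Pearson's chi-square comparing category distributions across
#' independent groups (rows): statistic `sum((O - E)^2 / E)` with
#' expected counts from the row/column marginals, degrees of freedom
#' `(r - 1) * (c - 1)`, and the p-value from the upper tail of the
#' chi-square distribution.  No continuity correction is applied.
#'
#' @param counts Non-negative integer matrix with at least 2 rows and
#'   2 columns (e.g. rows = grading methods, columns = injury grades);
#'   dimnames are preserved in the result.
#' @return List with `statistic`, `df`, `p_value`, `expected`.
#' @examples
#' grading <- rbind(arthroscopy = c(19, 34, 7), mri = c(20, 27, 13))
#' chi_square_homogeneity(grading)
#' @export
chi_square_homogeneity <- function(counts) {
  counts <- as.matrix(counts)
  if (nrow(counts) < 2L || ncol(counts) < 2L)
    stop("need at least a 2x2 table", call. = FALSE)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers", call. = FALSE)
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
    stop("degenerate table: zero row or column marginal", call. = FALSE)
  ct <- stats::chisq.test(counts, correct = FALSE)
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p_value = unname(ct$p.value), expected = ct$expected)
}

#' Percentage summary of labeled counts
#'
#' Expresses enumeration data as percentages of the total, rounded
#' half-up to two decimals (the convention used when such tables are
#' reported clinically; note plain `round()` in R rounds half to even,
#' which would print 0.125 as 0.12 rather than 0.13).
#'
#' @param counts Named non-negative integer vector with positive total.
#' @return A `proportion_report` data frame: `category`, `count`,
#'   `percent`, plus a `total` attribute.
#' @examples
#' proportions_report(c(suture = 17, secondary = 39,
#'                      partial = 3, total_resection = 1))
#' @export
proportions_report <- function(counts) {
  if (is.null(names(counts)) || any(!nzchar(names(counts))))
    stop("counts must be a fully named vector", call. = FALSE)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers", call. = FALSE)
  total <- sum(counts)
  if (total <= 0) stop("total count must be positive", call. = FALSE)
  out <- data.frame(category = names(counts),
                    count = as.integer(counts),
                    percent = round_half_up(100 * counts / total, 2),
                    row.names = NULL)
  attr(out, "total") <- total
  class(out) <- c("proportion_report", class(out))
  out
}

#' Round half away from zero
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded vector.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Packaged clinical count tables
#'
#' Small count tables shipped with the package for the worked clinical
#' examples: `meniscus_grading_table()` is the 2x3 grade-I/II/III
#' distribution of 60 meniscus-injury diagnoses under arthroscopy and
#' under MRI reading; `treatment_counts()` is the distribution of the
#' 60 patients over four surgical treatments.
#'
#' @return For `meniscus_grading_table()`, a 2x3 integer matrix with
#'   dimnames; for `treatment_counts()`, a named integer vector.
#' @export
meniscus_grading_table <- function() {
  path <- system.file("extdata", "meniscus_grading.csv", package = "mrisr")
  df <- utils::read.csv(path, row.names = 1)
  as.matrix(df)
}

#' @rdname meniscus_grading_table
#' @export
treatment_counts <- function() {
  path <- system.file("extdata", "treatment_counts.csv", package = "mrisr")
  df <- utils::read.csv(path)
  stats::setNames(as.integer(df$count), df$treatment)
}

#' Read a labeled count table from CSV
#'
#' Accepts either a two-column CSV (`label,count` — returns a named
#' vector for [proportions_report()]) or a CSV with row names and
#' multiple count columns (returns a matrix for
#' [chi_square_homogeneity()]).
#'
#' @param path CSV path.
#' @return Named integer vector or integer matrix.
#' @export
read_counts_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (ncol(df) == 2L && !is.numeric(df[[1]]))
    return(stats::setNames(as.integer(df[[2]]), as.character(df[[1]])))
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  storage.mode(m) <- "integer"
  m
}
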