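#' Knockout-phenotype categories
#'
#' The four male-fertility phenotype categories a knockout-mouse record can
#' carry, in reporting order: the knockout is infertile; hypofertile
#' (reduced fertility versus wild type); fertility affected (reproductive
#' damage with unclear effect on fertility); fertility
#' unaffected / normal phenotype.
#'
#' @export
phenotype_categories <- c(
  "male infertile",
  "male hypofertile",
  "male fertility affected",
  "male fertility unaffected/normal phenotype"
)

#' Cross-tabulate knockout phenotypes by controller class
#'
#' Builds the phenotype-by-class contingency table: rows are the four
#' fertility categories, columns are `hub` and `non-hub`. Only annotated
#' nodes enter the table — nodes without knockout data are the "not
#' studied" mass and are excluded, never treated as a fifth category.
#' Column percentages are rounded half-up to one decimal.
#'
#' @param annotations A data frame `(node, category)`; categories must be
#'   among [phenotype_categories].
#' @param hubs Character vector of hub node identifiers; annotated nodes
#'   not listed are counted as non-hubs.
#' @return An object of class `phenotype_table`: `counts` (4x2 integer
#'   matrix) and `percentages` (per-column, one decimal).
#' @export
build_phenotype_table <- function(annotations, hubs) {
  annotations <- tibble::as_tibble(annotations)
  stopifnot(all(c("node", "category") %in% names(annotations)))
  bad <- setdiff(unique(annotations$category), phenotype_categories)
  if (length(bad)) {
    rlang::abort(sprintf(
      "Unknown phenotype categor%s: %s",
      if (length(bad) == 1) "y" else "ies", paste(bad, collapse = "; ")
    ))
  }
  if (nrow(annotations) == 0L) {
    rlang::warn("No annotated nodes: the phenotype table is all zeros.")
  }
  cls <- factor(
    ifelse(annotations$node %in% hubs, "hub", "non-hub"),
    levels = c("hub", "non-hub")
  )
  cat_f <- factor(annotations$category, levels = phenotype_categories)
  counts <- unclass(table(cat_f, cls))
  dimnames(counts) <- list(category = phenotype_categories,
                           class = c("hub", "non-hub"))
  totals <- colSums(counts)
  pct <- sweep(counts, 2, ifelse(totals == 0, NA, totals), "/") * 100
  pct <- round_half_up(pct, 1)
  structure(
    list(counts = counts, percentages = pct),
    class = "phenotype_table"
  )
}

# round half away from zero (spreadsheet convention), unlike round()'s
# round-half-even
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Build a phenotype table directly from counts
#'
#' For working with printed contingency tables: supply the per-category
#' counts for each class directly.
#'
#' @param hub_counts,nonhub_counts Integer vectors of length 4, in the
#'   order of [phenotype_categories].
#' @return A `phenotype_table`.
#' @examples
#' phenotype_table_from_counts(c(5, 3, 3, 10), c(96, 60, 95, 94))
#' @export
phenotype_table_from_counts <- function(hub_counts, nonhub_counts) {
  stopifnot(length(hub_counts) == 4L, length(nonhub_counts) == 4L)
  counts <- cbind(hub = as.integer(hub_counts),
                  `non-hub` = as.integer(nonhub_counts))
  rownames(counts) <- phenotype_categories
  names(dimnames(counts)) <- c("category", "class")
  totals <- colSums(counts)
  pct <- round_half_up(sweep(counts, 2, ifelse(totals == 0, NA, totals), "/") * 100, 1)
  structure(list(counts = counts, percentages = pct), class = "phenotype_table")
}

#' @export
print.phenotype_table <- function(x, ...) {
  cat("Phenotype x class contingency table (count (%))\n")
  m <- matrix(
    sprintf("%d (%.1f)", x$counts, x$percentages),
    nrow = nrow(x$counts), dimnames = dimnames(x$counts)
  )
  print(m, quote = FALSE)
  tot <- colSums(x$counts)
  cat(sprintf("Total: hub %d, non-hub %d\n", tot[1], tot[2]))
  invisible(x)
}

#' Tidy a phenotype table
#' @param x A `phenotype_table`.
#' @param ... Unused.
#' @return A long tibble `(category, class, count, pct)`.
#' @export
tidy.phenotype_table <- function(x, ...) {
  tibble::tibble(
    category = rep(rownames(x$counts), times = ncol(x$counts)),
    class = rep(colnames(x$counts), each = nrow(x$counts)),
    count = as.integer(x$counts),
    pct = as.numeric(x$percentages)
  )
}

#' Pearson chi-square test on a phenotype table
#'
#' The uncorrected Pearson test of association between phenotype category
#' and controller class: statistic `sum (O - E)^2 / E` with expected
#' counts from the row/column margins, degrees of freedom
#' `(r - 1)(c - 1)`, p-value from the chi-square upper tail. No continuity
#' correction is applied. A warning is raised when the minimum expected
#' count falls below 5 (the classical validity rule of thumb).
#'
#' @param x A `phenotype_table`, or any r x c count matrix / data frame
#'   with `r, c >= 2`.
#' @return An object of class `contingency_result`: `statistic`, `df`,
#'   `p_value`, `expected`, `min_expected`.
#' @export
chi_square_test <- function(x) {
  counts <- if (inherits(x, "phenotype_table")) x$counts else as.matrix(x)
  if (nrow(counts) < 2L || ncol(counts) < 2L) {
    rlang::abort("Need at least a 2 x 2 table.")
  }
  if (any(colSums(counts) == 0) || any(rowSums(counts) == 0)) {
    rlang::abort("Every row and column margin must be positive.")
  }
  ct <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  min_exp <- min(ct$expected)
  if (min_exp < 5) {
    rlang::warn(sprintf(
      "Minimum expected count %.2f < 5: the chi-square approximation may be inaccurate.",
      min_exp
    ))
  }
  structure(
    list(
      statistic = unname(ct$statistic),
      df = unname(ct$parameter),
      p_value = unname(ct$p.value),
      expected = ct$expected,
      min_expected = min_exp,
      observed = counts
    ),
    class = "contingency_result"
  )
}

#' @export
print.contingency_result <- function(x, ...) {
  cat(sprintf(
    "Pearson chi-square (no continuity correction): X^2 = %.5f, df = %d, p = %.5f\n",
    x$statistic, x$df, x$p_value
  ))
  if (x$min_expected < 5) {
    cat(sprintf("  (min expected count %.2f < 5)\n", x$min_expected))
  }
  invisible(x)
}

#' Tidy / glance methods for a chi-square result
#' @param x A `contingency_result`.
#' @param ... Unused.
#' @return A one-row tibble with `statistic`, `df`, `p_value`,
#'   `min_expected`.
#' @export
tidy.contingency_result <- function(x, ...) {
  tibble::tibble(
    statistic = x$statistic, df = x$df, p_value = x$p_value,
    min_expected = x$min_expected
  )
}

#' @rdname tidy.contingency_result
#' @export
glance.contingency_result <- function(x, ...) tidy(x)
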