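#' Read a subject-by-region morphometry table
#'
#' Reads a CSV or TSV export of regional morphometric measures (cortical
#' thickness in mm, subcortical volume in mm^3), validates it against an
#' atlas, and canonicalizes the column order to the atlas order so that
#' downstream matrices are reproducible. `mean_ct` (the unweighted mean of
#' the cortical-thickness columns) is computed when absent; a `tiv` column
#' (total intracranial volume, mm^3) is carried through if present.
#'
#' @param path CSV/TSV file with a header containing `subject_id` and one
#'   column per atlas region.
#' @param atlas a [region_atlas()].
#' @return A `morphometry_table`: data frame with `subject_id`, the region
#'   columns in atlas order, `mean_ct` and (optionally) `tiv`.
#' @export
read_morphometry <- function(path, atlas) {
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  as_morphometry(df, atlas)
}

#' Coerce and validate a data frame as a morphometry table
#' @param df data frame with `subject_id` and atlas region columns.
#' @inheritParams read_morphometry
#' @return A `morphometry_table` data frame.
#' @export
as_morphometry <- function(df, atlas) {
  if (!"subject_id" %in% names(df))
    stop("schema error: missing column 'subject_id'", call. = FALSE)
  missing <- setdiff(atlas$region_id, names(df))
  if (length(missing))
    stop("schema error: missing region column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (anyDuplicated(df$subject_id))
    stop("duplicated subject_id", call. = FALSE)
  meas <- as.matrix(df[, atlas$region_id, drop = FALSE])
  if (!all(is.finite(meas)))
    stop("validation error: non-finite measure at row ",
         which(!apply(is.finite(meas), 1, all))[1], call. = FALSE)
  if (any(meas <= 0))
    stop("validation error: non-positive measure at row ",
         which(apply(meas <= 0, 1, any))[1], call. = FALSE)
  ct <- atlas_regions(atlas, "cortical_thickness")
  out <- data.frame(subject_id = as.character(df$subject_id),
                    stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(meas))
  out$mean_ct <- if ("mean_ct" %in% names(df)) df$mean_ct else
    if (length(ct)) rowMeans(meas[, ct, drop = FALSE]) else NA_real_
  if ("tiv" %in% names(df)) out$tiv <- df$tiv
  class(out) <- c("morphometry_table", "data.frame")
  attr(out, "region_ids") <- atlas$region_id
  out
}

#' Write a morphometry table to CSV
#' @param x a `morphometry_table`.
#' @param path output file (`.csv` or `.tsv`).
#' @return `path`, invisibly.
#' @export
write_morphometry <- function(x, path) {
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  utils::write.table(x, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Extract the region measurement matrix from a morphometry table
#' @param x a `morphometry_table`.
#' @return numeric matrix subjects x regions with dimnames.
#' @export
morphometry_matrix <- function(x) {
  m <- as.matrix(x[, attr(x, "region_ids"), drop = FALSE])
  rownames(m) <- x$subject_id
  m
}

#' Validate a demographics table
#'
#' Requires `subject_id`, `age` (> 0 years), binary `sex`
#' (`"male"`/`"female"`), `site` and `group` (`"reference"`, `"patient"`,
#' `"control"`). Clinical fields (`duration_illness`, `duration_medicine`,
#' `dose`, `seizure_frequency`) may be `NA`; missingness is kept explicit
#' so per-variable complete-case counts can be reported.
#'
#' @param df data frame.
#' @return the validated data frame with class `demographics`.
#' @export
as_demographics <- function(df) {
  need <- c("subject_id", "age", "sex", "site", "group")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("demographics missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (any(df$age <= 0)) stop("age must be positive", call. = FALSE)
  if (!all(df$sex %in% c("male", "female")))
    stop("sex must be 'male' or 'female'", call. = FALSE)
  if (!all(df$group %in% c("reference", "patient", "control")))
    stop("invalid group label", call. = FALSE)
  class(df) <- c("demographics", "data.frame")
  df
}

#' Pearson chi-square test on a contingency table, no continuity correction
#'
#' Continuity correction is deliberately off: the printed two-by-two
#' statistics in the cohort demographics table are uncorrected Pearson
#' chi-squares.
#'
#' @param tab contingency table (matrix of counts).
#' @return list with `statistic`, `df`, `p_value`.
#' @export
chi_square_test <- function(tab) {
  tab <- as.matrix(tab)
  ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p_value = unname(ht$p.value))
}

#' Two-sided Mann-Whitney U test with midranks
#'
#' Uses midranks for ties. For total n <= 8 the p-value comes from exact
#' enumeration of all rank assignments; for larger samples, from the normal
#' approximation with tie correction (no continuity correction). The
#' reported statistic is U for the first sample.
#'
#' @param x,y numeric vectors for the two groups.
#' @return list with `statistic` (U of `x`), `p_value`, `method`.
#' @export
mann_whitney_u <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  n1 <- length(x); n2 <- length(y)
  if (n1 == 0 || n2 == 0) stop("a group is empty", call. = FALSE)
  if (stats::var(c(x, y)) == 0)
    warning("zero-variance variable; U computed with midranks")
  r <- rank(c(x, y))                       # midranks
  u_of <- function(rk) sum(rk[seq_len(n1)]) - n1 * (n1 + 1) / 2
  u <- u_of(r)
  if (n1 + n2 <= 8) {
    combs <- utils::combn(n1 + n2, n1)
    us <- apply(combs, 2, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
    p <- min(1, 2 * min(mean(us <= u), mean(us >= u)))
    method <- "exact enumeration"
  } else {
    n <- n1 + n2
    mu <- n1 * n2 / 2
    ties <- table(r)
    sig2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    if (sig2 <= 0) { p <- 1 } else {
      z <- (u - mu) / sqrt(sig2)
      p <- min(1, 2 * stats::pnorm(-abs(z)))
    }
    method <- "normal approximation, tie-corrected"
  }
  list(statistic = u, p_value = p, method = method)
}

#' Two-group comparison row for a demographics variable
#'
#' Categorical variables are tested by Pearson chi-square without
#' continuity correction; continuous variables by the two-sided
#' Mann-Whitney U test. Missing values are dropped per variable (the
#' complete-case n per group is reported).
#'
#' @param values vector of the variable (factor/character/logical for
#'   categorical, numeric for continuous).
#' @param groups two-level grouping vector aligned with `values`.
#' @param variable variable name for the output row.
#' @return one-row data frame: `variable`, `test`, `statistic`, `p_value`,
#'   `n1`, `n2`.
#' @export
compare_groups <- function(values, groups, variable = "variable") {
  keep <- !is.na(values) & !is.na(groups)
  values <- values[keep]; groups <- as.character(groups)[keep]
  lev <- unique(groups)
  if (length(lev) != 2) stop("exactly two groups required", call. = FALSE)
  n1 <- sum(groups == lev[1]); n2 <- sum(groups == lev[2])
  if (n1 == 0 || n2 == 0) stop("a group is empty", call. = FALSE)
  if (is.numeric(values)) {
    ht <- mann_whitney_u(values[groups == lev[1]], values[groups == lev[2]])
    test <- "mann_whitney_u"
  } else {
    tab <- table(factor(groups, levels = lev), values)
    ht <- chi_square_test(tab)
    test <- "chi_square"
  }
  data.frame(variable = variable, test = test,
             statistic = ht$statistic, p_value = ht$p_value,
             n1 = n1, n2 = n2, stringsAsFactors = FALSE)
}

#' Group-comparison table over several demographics variables
#' @param demo a [as_demographics()] data frame.
#' @param variables character vector of column names in `demo`.
#' @param group_col column holding the two-level grouping (default `group`).
#' @return data frame, one [compare_groups()] row per variable.
#' @export
group_comparison_table <- function(demo, variables, group_col = "group") {
  do.call(rbind, lapply(variables, function(v)
    compare_groups(demo[[v]], demo[[group_col]], variable = v)))
}
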