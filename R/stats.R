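#' Validate a feature table
#'
#' A feature table has one row per subject: `subject_id` (unique),
#' `label`, and one numeric column per feature (any subset of columns
#' other than `subject_id`, `label`, `skip_count` is treated as a
#' feature). All feature values must be finite.
#'
#' @param table A data.frame.
#' @return The table, invisibly, with attribute `features` naming the
#'   feature columns.
#' @export
validate_feature_table <- function(table) {
  if (!is.data.frame(table)) stop_validation("feature table must be a data.frame")
  if (!all(c("subject_id", "label") %in% names(table)))
    stop_validation("feature table needs `subject_id` and `label` columns")
  if (anyDuplicated(table$subject_id))
    stop_validation("duplicate subject_id in feature table")
  feats <- setdiff(names(table), c("subject_id", "label", "skip_count"))
  if (length(feats) == 0) stop_validation("feature table has no feature columns")
  for (f in feats) {
    if (!is.numeric(table[[f]]))
      stop_validation("feature column `%s` is not numeric", f)
    if (any(!is.finite(table[[f]])))
      stop_validation("feature column `%s` contains non-finite values", f)
  }
  attr(table, "features") <- feats
  invisible(table)
}

#' Per-feature Shapiro-Wilk normality screen
#'
#' Advisory only: results are logged into the comparison report but never
#' block the pipeline. Constant columns are flagged untestable.
#'
#' @param table A feature table (see [validate_feature_table()]).
#' @param group Label of the group to screen.
#' @return data.frame with columns `feature`, `W`, `p_value`, `untestable`.
#' @export
normality_check <- function(table, group) {
  table <- validate_feature_table(table)
  feats <- attr(table, "features")
  sub <- table[table$label == group, , drop = FALSE]
  if (nrow(sub) == 0)
    stop_usage("group `%s` not present in the table", group)
  if (nrow(sub) < 3)
    stop_usage("group `%s` has fewer than 3 subjects; normality untestable", group)
  res <- lapply(feats, function(f) {
    x <- sub[[f]]
    if (stats::sd(x) == 0)
      return(data.frame(feature = f, W = NA_real_, p_value = NA_real_,
                        untestable = TRUE))
    sw <- stats::shapiro.test(x)
    data.frame(feature = f, W = unname(sw$statistic),
               p_value = sw$p.value, untestable = FALSE)
  })
  do.call(rbind, c(res, list(make.row.names = FALSE)))
}

#' Two-group feature comparison (t-test)
#'
#' Per-feature two-sided two-sample t-test between the two labels of the
#' table. The default is the pooled-variance Student test (matching an
#' equal-variance assumption); Welch is one flag away. Features whose
#' pooled variance is zero are flagged degenerate with `NA` statistics
#' rather than dropped.
#'
#' @param table A feature table with exactly two labels, each with >= 2
#'   subjects.
#' @param variant `"student"` (pooled variance) or `"welch"`.
#' @param p_adjust Multiple-testing correction passed to
#'   [stats::p.adjust()]; `"none"` (default) mirrors a single-look
#'   analysis, and the choice is recorded in the result's settings.
#' @return A `ComparisonResult`: list with `test`, `groups`,
#'   `n_per_group`, `settings` and `table` (one row per feature: group
#'   means and sample SDs, `statistic`, `df`, `p_value`, `degenerate`).
#' @examples
#' tab <- data.frame(subject_id = paste0("s", 1:6),
#'                   label = rep(c("tumor", "normal"), each = 3),
#'                   f = c(1, 2, 3, 4, 5, 6))
#' compare_two_groups(tab)$table
#' @export
compare_two_groups <- function(table, variant = c("student", "welch"),
                               p_adjust = "none") {
  variant <- match.arg(variant)
  table <- validate_feature_table(table)
  feats <- attr(table, "features")
  labs <- unique(table$label)
  if (length(labs) != 2)
    stop_usage("two-group comparison needs exactly 2 labels, found %d (%s)",
               length(labs), paste(labs, collapse = ", "))
  n1 <- sum(table$label == labs[1]); n2 <- sum(table$label == labs[2])
  if (n1 < 2 || n2 < 2)
    stop_usage("each group needs >= 2 subjects (found %d and %d)", n1, n2)

  rows <- lapply(feats, function(f) {
    x <- table[[f]][table$label == labs[1]]
    y <- table[[f]][table$label == labs[2]]
    base <- data.frame(feature = f,
                       mean_1 = mean(x), sd_1 = stats::sd(x),
                       mean_2 = mean(y), sd_2 = stats::sd(y))
    tt <- tryCatch(
      stats::t.test(x, y, var.equal = (variant == "student"),
                    alternative = "two.sided"),
      error = function(e) NULL)
    if (is.null(tt))
      cbind(base, data.frame(statistic = NA_real_, df = NA_real_,
                             p_value = NA_real_, degenerate = TRUE))
    else
      cbind(base, data.frame(statistic = unname(tt$statistic),
                             df = unname(tt$parameter),
                             p_value = tt$p.value, degenerate = FALSE))
  })
  tab <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  names(tab)[2:5] <- c(paste0("mean_", labs[1]), paste0("sd_", labs[1]),
                       paste0("mean_", labs[2]), paste0("sd_", labs[2]))
  if (p_adjust != "none")
    tab$p_adjusted <- stats::p.adjust(tab$p_value, method = p_adjust)
  structure(list(
    test = paste0(variant, "_t"), groups = labs,
    n_per_group = stats::setNames(c(n1, n2), labs),
    settings = list(alpha = 0.05, sides = "two.sided", variant = variant,
                    p_adjust = p_adjust),
    table = tab), class = "ComparisonResult")
}

#' Multi-group feature comparison (one-way ANOVA)
#'
#' Per-feature one-way fixed-effects ANOVA (equal-variance F test) across
#' grade labels, with per-grade mean and sample SD. Grades with fewer
#' than 2 subjects are dropped with a warning; at least 2 must remain.
#'
#' @param table A feature table whose labels are grades.
#' @param p_adjust As in [compare_two_groups()].
#' @return A `ComparisonResult` whose table has per-grade `mean_*`/`sd_*`
#'   columns plus `statistic` (F), `df1`, `df2`, `p_value`, `degenerate`.
#' @export
compare_grades <- function(table, p_adjust = "none") {
  table <- validate_feature_table(table)
  feats <- attr(table, "features")
  counts <- table(table$label)
  small <- names(counts)[counts < 2]
  if (length(small)) {
    warning(sprintf("dropping grade(s) with < 2 subjects: %s",
                    paste(small, collapse = ", ")))
    table <- table[!table$label %in% small, , drop = FALSE]
    counts <- table(table$label)
  }
  labs <- names(counts)
  if (length(labs) < 2)
    stop_usage("fewer than 2 grades with >= 2 subjects remain")
  g <- factor(table$label, levels = labs)

  rows <- lapply(feats, function(f) {
    x <- table[[f]]
    ms <- tapply(x, g, mean); ss <- tapply(x, g, stats::sd)
    base <- data.frame(feature = f)
    for (l in labs) {
      base[[paste0("mean_", l)]] <- ms[[l]]
      base[[paste0("sd_", l)]] <- ss[[l]]
    }
    ow <- tryCatch(stats::oneway.test(x ~ g, var.equal = TRUE),
                   error = function(e) NULL)
    if (is.null(ow) || !is.finite(ow$statistic))
      cbind(base, data.frame(statistic = NA_real_, df1 = NA_real_,
                             df2 = NA_real_, p_value = NA_real_,
                             degenerate = TRUE))
    else
      cbind(base, data.frame(statistic = unname(ow$statistic),
                             df1 = unname(ow$parameter[1]),
                             df2 = unname(ow$parameter[2]),
                             p_value = ow$p.value, degenerate = FALSE))
  })
  tab <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (p_adjust != "none")
    tab$p_adjusted <- stats::p.adjust(tab$p_value, method = p_adjust)
  structure(list(
    test = "oneway_anova", groups = labs,
    n_per_group = stats::setNames(as.integer(counts[labs]), labs),
    settings = list(alpha = 0.05, p_adjust = p_adjust),
    table = tab), class = "ComparisonResult")
}

#' @export
print.ComparisonResult <- function(x, ...) {
  cat(sprintf("ComparisonResult (%s): %s\n", x$test,
              paste(sprintf("%s n=%d", names(x$n_per_group), x$n_per_group),
                    collapse = ", ")))
  print(x$table, digits = 4)
  invisible(x)
}

#' Write a comparison report CSV
#'
#' Tabular layout mirroring the feature-comparison tables of the
#' analysis: one row per parameter, one `mean+/-SD` column per group, an
#' `F_value` column for ANOVA results, the p-value, and a `significant`
#' marker that is `"*"` strictly below the 0.05 threshold. Numbers are
#' printed to 4 significant digits.
#'
#' @param result A `ComparisonResult`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
render_report <- function(result, path) {
  if (!inherits(result, "ComparisonResult"))
    stop_validation("`result` must be a ComparisonResult")
  tab <- result$table
  out <- data.frame(Parameter = tab$feature, stringsAsFactors = FALSE)
  for (g in result$groups)
    out[[g]] <- sprintf("%.4g±%.4g", tab[[paste0("mean_", g)]],
                        tab[[paste0("sd_", g)]])
  if (result$test == "oneway_anova")
    out$F_value <- sprintf("%.4g", tab$statistic)
  out$P_value <- sprintf("%.4g", tab$p_value)
  out$significant <- ifelse(!is.na(tab$p_value) &
                              tab$p_value < result$settings$alpha, "*", "")
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
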