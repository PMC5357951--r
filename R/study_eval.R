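#' Canonical class labels of the four-way classification task
#' @export
study_classes <- function() c("STEMI", "PVC", "AFib", "Bigeminy")

canonical_class <- function(x) {
  classes <- study_classes()
  idx <- match(tolower(gsub("[. ]", "", x)), tolower(classes))
  ifelse(is.na(idx), as.character(x), classes[idx])
}

#' Build an observer response table
#'
#' One row per (observer, sample) classification task from a blinded
#' forced-choice study: the observer's group, whether they are a trained
#' musician, the sample's true pathology class and the class the observer
#' assigned. Classes come from the closed four-way set STEMI, PVC, AFib,
#' Bigeminy (matching is case/punctuation-insensitive, so "A. Fib." is
#' accepted). Every observer must answer every sample exactly once.
#'
#' @param df data frame with columns `observer_id`, `group` (1, 2 or 3),
#'   `musician` (logical), `sample_id`, `true_class`, `assigned_class`.
#' @return A validated data frame of class `observer_responses`.
#' @export
observer_responses <- function(df) {
  needed <- c("observer_id", "group", "musician", "sample_id",
              "true_class", "assigned_class")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols))
    stop(sprintf("response table lacks column(s): %s",
                 paste(missing_cols, collapse = ", ")))
  if (!nrow(df)) stop("response table is empty")
  df <- df[needed]
  df$true_class <- canonical_class(df$true_class)
  df$assigned_class <- canonical_class(df$assigned_class)
  bad <- setdiff(unique(c(df$true_class, df$assigned_class)), study_classes())
  if (length(bad))
    stop(sprintf("unknown class label(s): %s (allowed: %s)",
                 paste(bad, collapse = ", "),
                 paste(study_classes(), collapse = ", ")))
  if (!all(df$group %in% 1:3))
    stop("`group` must be 1, 2 or 3")
  if (anyDuplicated(df[c("observer_id", "sample_id")]))
    stop("duplicate (observer_id, sample_id) pair in response table")
  n_per <- table(df$observer_id)
  if (length(unique(n_per)) != 1L)
    stop("every observer must answer the same set of samples")
  grp <- unique(df[c("observer_id", "group")])
  if (anyDuplicated(grp$observer_id))
    stop("an observer is assigned to more than one group")
  df$musician <- as.logical(df$musician)
  class(df) <- c("observer_responses", "data.frame")
  df
}

#' Read an observer response sheet from CSV
#'
#' @param path CSV file with a header row. Column names can be remapped
#'   with `columns`, a named character vector mapping the canonical names
#'   (`observer_id`, `group`, `musician`, `sample_id`, `true_class`,
#'   `assigned_class`) to the names used in the file.
#' @return An [observer_responses()] table.
#' @export
read_responses <- function(path, columns = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!nrow(df)) stop(sprintf("empty response sheet: %s", path))
  if (!is.null(columns)) {
    for (canon in names(columns)) {
      if (!columns[[canon]] %in% names(df))
        stop(sprintf("mapped column '%s' not found in %s", columns[[canon]], path))
      names(df)[names(df) == columns[[canon]]] <- canon
    }
  }
  observer_responses(df)
}

#' Per-observer correct classification rate
#'
#' @param table an [observer_responses()] table.
#' @return Named numeric vector: fraction correct in `[0, 1]` per
#'   observer, ordered by observer id.
#' @export
observer_accuracy <- function(table) {
  stopifnot(inherits(table, "observer_responses"))
  correct <- table$true_class == table$assigned_class
  acc <- tapply(correct, table$observer_id, mean)
  acc <- stats::setNames(as.numeric(acc), names(acc))
  acc[order(names(acc))]
}

#' Group-level accuracy summary
#'
#' Mean and sample standard deviation (n - 1 denominator) of the
#' per-observer accuracies within each group, reported in percent. A
#' single-observer group has a defined mean but an undefined sd (`NA`).
#'
#' @param table an [observer_responses()] table.
#' @return Data frame with columns `group`, `n`, `mean_pct`, `sd_pct`.
#' @export
group_summary <- function(table) {
  stopifnot(inherits(table, "observer_responses"))
  acc <- observer_accuracy(table)
  grp <- unique(table[c("observer_id", "group")])
  g <- grp$group[match(names(acc), grp$observer_id)]
  out <- do.call(rbind, lapply(sort(unique(g)), function(gi) {
    a <- acc[g == gi]
    data.frame(group = gi, n = length(a), mean_pct = 100 * mean(a),
               sd_pct = if (length(a) > 1L) 100 * stats::sd(a) else NA_real_)
  }))
  rownames(out) <- NULL
  out
}

#' Confusion matrix of true vs assigned classes
#'
#' @param table an [observer_responses()] table.
#' @return A 4x4 integer matrix of class `confusion_matrix`; rows are the
#'   true class, columns the assigned class, in the fixed order STEMI,
#'   PVC, AFib, Bigeminy. The diagonal holds correct classifications and
#'   the total equals the number of response rows.
#' @export
confusion <- function(table) {
  stopifnot(inherits(table, "observer_responses"))
  cls <- study_classes()
  m <- table(factor(table$true_class, levels = cls),
             factor(table$assigned_class, levels = cls))
  m <- unclass(m)
  dimnames(m) <- list(true = cls, assigned = cls)
  structure(m, class = c("confusion_matrix", class(m)))
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat("Confusion matrix (rows: true class, columns: assigned class)\n")
  print(unclass(x))
  rates <- diag(x) / rowSums(x)
  cat("per-class correct rate:",
      paste(sprintf("%s %.0f%%", names(rates), 100 * rates), collapse = ", "),
      "\n")
  invisible(x)
}

#' Per-class correct classification rates
#'
#' @param cm a [confusion()] matrix.
#' @return Named numeric vector: diagonal over row sum per true class.
#' @export
class_accuracy <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  diag(cm) / rowSums(cm)
}

#' Fraction of observers above an accuracy threshold
#'
#' Strict inequality: with 12 samples, "over 90%" means at least 11 of 12
#' correct.
#'
#' @param table an [observer_responses()] table.
#' @param threshold accuracy threshold as a fraction.
#' @return Fraction of observers with accuracy strictly greater than
#'   `threshold`.
#' @export
fraction_above <- function(table, threshold) {
  acc <- observer_accuracy(table)
  mean(acc > threshold)
}

#' One-tailed two-sample t-test on observer accuracies
#'
#' Classic Student's pooled-variance two-sample t-test of the alternative
#' mean(A) > mean(B), with `df = nA + nB - 2` (Welch's unequal-variance
#' form behind `welch = TRUE`).
#'
#' @param groupA,groupB numeric accuracy vectors (each n >= 2).
#' @param welch use the Welch correction instead of pooling.
#' @return List with `t`, `df`, `p` (one-tailed) and `degenerate` (TRUE
#'   when the pooled variance is zero, in which case `p` is 0 or 1 by the
#'   sign of the mean difference, 0.5 for identical means).
#' @export
one_tailed_t <- function(groupA, groupB, welch = FALSE) {
  if (length(groupA) < 2L || length(groupB) < 2L)
    stop("both groups need at least 2 observations")
  if (stats::sd(groupA) == 0 && stats::sd(groupB) == 0) {
    d <- mean(groupA) - mean(groupB)
    return(list(t = if (d == 0) 0 else sign(d) * Inf,
                df = length(groupA) + length(groupB) - 2L,
                p = if (d == 0) 0.5 else if (d > 0) 0 else 1,
                degenerate = TRUE))
  }
  ht <- stats::t.test(groupA, groupB, alternative = "greater",
                      var.equal = !welch)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, degenerate = FALSE)
}

#' One-tailed pooled t-test from group summary statistics
#'
#' Same test as [one_tailed_t()] but computed from (n, mean, sd)
#' summaries, for comparing published group-level results.
#'
#' @param nA,meanA,sdA size, mean and sample sd of group A.
#' @param nB,meanB,sdB size, mean and sample sd of group B.
#' @return List with `t`, `df` and one-tailed `p` for mean(A) > mean(B).
#' @export
one_tailed_t_summary <- function(nA, meanA, sdA, nB, meanB, sdB) {
  if (nA < 2L || nB < 2L) stop("both groups need n >= 2")
  sp2 <- ((nA - 1) * sdA^2 + (nB - 1) * sdB^2) / (nA + nB - 2)
  if (sp2 == 0) stop("zero pooled variance")
  t <- (meanA - meanB) / sqrt(sp2 * (1 / nA + 1 / nB))
  df <- nA + nB - 2
  list(t = t, df = df, p = stats::pt(t, df, lower.tail = FALSE))
}

#' Full study report
#'
#' Convenience wrapper printing per-observer accuracies, group summaries,
#' the confusion matrix with per-class rates, the fraction of observers
#' above 90%, and pairwise one-tailed group comparisons.
#'
#' @param table an [observer_responses()] table.
#' @return Invisibly, a list with all computed components.
#' @export
study_report <- function(table) {
  acc <- observer_accuracy(table)
  gs <- group_summary(table)
  cm <- confusion(table)
  fa <- fraction_above(table, 0.90)
  grp <- unique(table[c("observer_id", "group")])
  g <- grp$group[match(names(acc), grp$observer_id)]
  cat(sprintf("%d observers, %d tasks, overall accuracy %.0f%%\n",
              length(acc), nrow(table), 100 * mean(acc)))
  cat("\nGroup summaries (accuracy, %):\n")
  print(gs, row.names = FALSE)
  cat("\n")
  print(cm)
  cat(sprintf("\nobservers above 90%%: %d of %d (%.0f%%)\n",
              sum(acc > 0.90), length(acc), 100 * fa))
  tests <- list()
  for (pair in list(c(1, 2), c(1, 3), c(2, 3))) {
    a <- acc[g == pair[1L]]; b <- acc[g == pair[2L]]
    if (length(a) >= 2L && length(b) >= 2L) {
      tt <- one_tailed_t(a, b)
      key <- sprintf("group%d_vs_group%d", pair[1L], pair[2L])
      tests[[key]] <- tt
      cat(sprintf("one-tailed t, group %d > group %d: t = %.3f, df = %d, p = %.3f\n",
                  pair[1L], pair[2L], tt$t, as.integer(tt$df), tt$p))
    }
  }
  invisible(list(accuracy = acc, groups = gs, confusion = cm,
                 fraction_above_90 = fa, tests = tests))
}
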