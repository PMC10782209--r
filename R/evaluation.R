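## Multiclass validation machinery: confusion matrix, one-vs-rest metrics,
## micro/macro aggregation, Cohen's kappa and diagnostic sample-size
## planning. Stored values keep full precision; rounding (half-up, 2 dp)
## happens only at presentation.

#' Build a confusion matrix from paired labels
#'
#' @param reference Character vector of reference (gold) labels.
#' @param predicted Character vector of predicted labels, same length.
#' @param class_labels Class labels fixing row/column order; defaults to
#'   the sorted union of observed labels.
#' @return A `confusion_matrix`: list with `class_labels` and `counts`
#'   (rows = prediction, columns = reference).
#' @export
#' @examples
#' cm <- build_confusion_matrix(c("a", "b", "a"), c("a", "b", "b"),
#'                              c("a", "b"))
#' cm$counts
build_confusion_matrix <- function(reference, predicted,
                                   class_labels = NULL) {
  if (length(reference) != length(predicted)) {
    stop("reference and predicted must have the same length", call. = FALSE)
  }
  if (is.null(class_labels)) {
    class_labels <- sort(unique(c(reference, predicted)))
  }
  bad <- setdiff(unique(c(reference, predicted)), class_labels)
  if (length(bad) > 0L) {
    stop("label(s) not in class_labels: ", paste(bad, collapse = "; "),
         call. = FALSE)
  }
  counts <- table(factor(predicted, levels = class_labels),
                  factor(reference, levels = class_labels))
  counts <- matrix(as.integer(counts), nrow = length(class_labels),
                   dimnames = list(prediction = class_labels,
                                   reference = class_labels))
  new_confusion_matrix(counts, class_labels)
}

#' Construct a confusion matrix from a count matrix
#'
#' @param counts Square non-negative integer matrix, rows = prediction,
#'   columns = reference.
#' @param class_labels Labels for the rows/columns.
#' @return A `confusion_matrix`.
#' @export
new_confusion_matrix <- function(counts, class_labels = rownames(counts)) {
  counts <- as.matrix(counts)
  if (nrow(counts) != ncol(counts) ||
      nrow(counts) != length(class_labels)) {
    stop("counts must be square with one row/column per class",
         call. = FALSE)
  }
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  storage.mode(counts) <- "integer"
  dimnames(counts) <- list(prediction = class_labels,
                           reference = class_labels)
  structure(list(class_labels = class_labels, counts = counts),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat("<confusion_matrix> ", sum(x$counts), " observations, ",
      length(x$class_labels), " classes\n", sep = "")
  short <- abbreviate(x$class_labels, 18)
  m <- x$counts
  dimnames(m) <- list(prediction = short, reference = short)
  print(m)
  invisible(x)
}

#' One-versus-rest metrics per class
#'
#' Each class is evaluated against all others: TP is the diagonal cell,
#' FN the rest of its reference column, FP the rest of its prediction row,
#' TN the remainder. Ratios with a zero denominator are `NA` (excluded
#' later from macro means, never coerced to 0 or 1).
#'
#' @param cm A `confusion_matrix` with at least one observation.
#' @return Data frame with one row per class: `class_label`, `tp`, `fp`,
#'   `fn`, `tn`, `sensitivity`, `specificity`, `ppv`, `npv`, `accuracy`.
#' @export
one_vs_rest_metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  total <- sum(cm$counts)
  if (total == 0L) stop("confusion matrix is empty", call. = FALSE)
  ratio <- function(num, den) ifelse(den > 0, num / den, NA_real_)
  tp <- diag(cm$counts)
  fp <- rowSums(cm$counts) - tp
  fn <- colSums(cm$counts) - tp
  tn <- total - tp - fp - fn
  data.frame(
    class_label = cm$class_labels,
    tp = as.integer(tp), fp = as.integer(fp),
    fn = as.integer(fn), tn = as.integer(tn),
    sensitivity = ratio(tp, tp + fn),
    specificity = ratio(tn, tn + fp),
    ppv = ratio(tp, tp + fp),
    npv = ratio(tn, tn + fn),
    accuracy = (tp + tn) / total,
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Aggregate per-class metrics
#'
#' Micro accuracy pools counts (trace over total of the confusion matrix);
#' macro values are unweighted means of the defined per-class values, with
#' the number of excluded (undefined) classes reported.
#'
#' @param per_class Output of [one_vs_rest_metrics()].
#' @param cm The confusion matrix the per-class metrics came from.
#' @return An `aggregate_metrics` list: `micro_accuracy`,
#'   `macro_sensitivity`, `macro_specificity`, `macro_ppv`, `macro_npv`,
#'   `n_excluded` (per metric), `per_class`.
#' @export
aggregate_metrics <- function(per_class, cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  total <- sum(cm$counts)
  if (total == 0L) stop("confusion matrix is empty", call. = FALSE)
  if (!identical(sort(per_class$class_label), sort(cm$class_labels)) ||
      sum(per_class$tp) != sum(diag(cm$counts))) {
    stop("per-class metrics are inconsistent with the confusion matrix",
         call. = FALSE)
  }
  macro <- function(v) mean(v, na.rm = TRUE)
  structure(
    list(micro_accuracy = sum(diag(cm$counts)) / total,
         macro_sensitivity = macro(per_class$sensitivity),
         macro_specificity = macro(per_class$specificity),
         macro_ppv = macro(per_class$ppv),
         macro_npv = macro(per_class$npv),
         n_excluded = vapply(
           per_class[c("sensitivity", "specificity", "ppv", "npv")],
           function(v) sum(is.na(v)), integer(1)),
         per_class = per_class),
    class = "aggregate_metrics")
}

#' @export
print.aggregate_metrics <- function(x, ...) {
  cat("<aggregate_metrics>\n")
  cat(sprintf("  micro accuracy:    %.2f\n", round_half_up(x$micro_accuracy, 2)))
  cat(sprintf("  macro sensitivity: %.2f\n", round_half_up(x$macro_sensitivity, 2)))
  cat(sprintf("  macro specificity: %.2f\n", round_half_up(x$macro_specificity, 2)))
  cat(sprintf("  macro PPV:         %.2f\n", round_half_up(x$macro_ppv, 2)))
  cat(sprintf("  macro NPV:         %.2f\n", round_half_up(x$macro_npv, 2)))
  cat("  per class sensitivity: ",
      paste(sprintf("%.2f", round_half_up(x$per_class$sensitivity, 2)),
            collapse = " "), "\n", sep = "")
  invisible(x)
}

#' Round half up
#'
#' Presentation rounding (2 dp in reports): exact halves round away from
#' zero, matching printed clinical tables, unlike [round()]'s banker's
#' rounding.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Cohen's kappa
#'
#' Chance-corrected agreement `(po - pe) / (1 - pe)` between two raters.
#' Under the `marginal` chance model `pe` is the sum over categories of
#' the product of the raters' marginal proportions; under `fixed` the
#' caller supplies `pe` directly.
#'
#' @param rater1,rater2 Equal-length label vectors.
#' @param chance_model `"marginal"` or `"fixed"`.
#' @param pe Chance agreement probability in `[0, 1)`, required for the
#'   fixed model.
#' @return Kappa (single numeric).
#' @export
#' @examples
#' cohens_kappa(c("x", "x", "y"), c("x", "x", "y"))
cohens_kappa <- function(rater1, rater2,
                         chance_model = c("marginal", "fixed"), pe = NULL) {
  chance_model <- match.arg(chance_model)
  if (length(rater1) != length(rater2) || length(rater1) == 0L) {
    stop("raters must give equal, non-zero numbers of labels",
         call. = FALSE)
  }
  po <- mean(rater1 == rater2)
  if (chance_model == "marginal") {
    levels_all <- union(rater1, rater2)
    p1 <- table(factor(rater1, levels = levels_all)) / length(rater1)
    p2 <- table(factor(rater2, levels = levels_all)) / length(rater2)
    pe <- sum(as.numeric(p1) * as.numeric(p2))
  } else {
    if (is.null(pe) || pe < 0 || pe >= 1) {
      stop("fixed chance model needs pe in [0, 1)", call. = FALSE)
    }
  }
  if (pe >= 1) stop("chance agreement pe = 1; kappa undefined", call. = FALSE)
  (po - pe) / (1 - pe)
}

#' Diagnostic sensitivity sample size (Buderer)
#'
#' Number of cases needed to estimate a sensitivity `SN` to within
#' `delta` at a given confidence:
#' `n_cases = ceiling(z^2 * SN * (1 - SN) / delta^2)` (at least 1), with
#' `n_total = ceiling(n_cases / prevalence)` and controls making up the
#' rest.
#'
#' @param expected_sensitivity Anticipated sensitivity, in (0, 1).
#' @param confidence_level Two-sided confidence level, in (0, 1)
#'   (0.95 gives z = 1.96).
#' @param precision_delta Desired half-width of the confidence interval,
#'   in (0, 1).
#' @param prevalence Prevalence of cases among screened subjects, in
#'   (0, 1).
#' @param max_total Guard on the planned total (default 1e7).
#' @return List with `n_cases`, `n_controls`, `n_total`.
#' @export
#' @examples
#' sensitivity_sample_size(0.9, 0.95, 0.05, 0.1)
sensitivity_sample_size <- function(expected_sensitivity, confidence_level,
                                    precision_delta, prevalence,
                                    max_total = 1e7) {
  for (v in c(expected_sensitivity, confidence_level, precision_delta,
              prevalence)) {
    if (!is.numeric(v) || length(v) != 1L || v <= 0 || v >= 1) {
      stop("all sample-size inputs must lie strictly inside (0, 1)",
           call. = FALSE)
    }
  }
  z <- stats::qnorm(1 - (1 - confidence_level) / 2)
  n_cases <- max(1L, as.integer(ceiling(
    z^2 * expected_sensitivity * (1 - expected_sensitivity) /
      precision_delta^2)))
  sample_size_from_cases(n_cases, prevalence, max_total = max_total)
}

#' Controls and total from a fixed number of cases
#'
#' Alternate planner entry point: the number of cases is fixed by the
#' caller and the total / control counts follow from the prevalence.
#'
#' @param n_cases Required number of cases (positive integer).
#' @param prevalence Case prevalence, in (0, 1).
#' @param max_total Guard on the planned total.
#' @return List with `n_cases`, `n_controls`, `n_total`.
#' @export
#' @examples
#' sample_size_from_cases(40, 0.05)  # 800 total, 760 controls
sample_size_from_cases <- function(n_cases, prevalence, max_total = 1e7) {
  stopifnot(is.numeric(n_cases), length(n_cases) == 1L, n_cases >= 1,
            n_cases == round(n_cases))
  if (prevalence <= 0 || prevalence >= 1) {
    stop("prevalence must lie strictly inside (0, 1)", call. = FALSE)
  }
  n_total <- as.integer(ceiling(n_cases / prevalence))
  if (n_total > max_total) {
    stop("planned total ", n_total, " exceeds the configured cap (",
         format(max_total, scientific = FALSE), ")", call. = FALSE)
  }
  list(n_cases = as.integer(n_cases),
       n_controls = n_total - as.integer(n_cases),
       n_total = n_total)
}

#' End-to-end evaluation of a prediction run
#'
#' Composes [build_confusion_matrix()], [one_vs_rest_metrics()] and
#' [aggregate_metrics()], optionally writing the confusion-matrix CSV, a
#' full-precision metrics JSON and a human-readable table (2 dp, half-up).
#'
#' @param reference,predicted Equal-length label vectors.
#' @param class_labels Class order for the matrix; defaults to
#'   [recommendation_classes()].
#' @param out_dir Optional directory to write `confusion_matrix.csv`,
#'   `metrics.json` and `metrics.txt` into.
#' @return An `aggregate_metrics` object with the confusion matrix
#'   attached as attribute `"confusion_matrix"`.
#' @export
evaluate_run <- function(reference, predicted,
                         class_labels = recommendation_classes(),
                         out_dir = NULL) {
  cm <- build_confusion_matrix(reference, predicted, class_labels)
  per_class <- one_vs_rest_metrics(cm)
  agg <- aggregate_metrics(per_class, cm)
  attr(agg, "confusion_matrix") <- cm
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_confusion_matrix_csv(cm, file.path(out_dir, "confusion_matrix.csv"))
    jsonlite::write_json(
      list(micro_accuracy = agg$micro_accuracy,
           macro_sensitivity = agg$macro_sensitivity,
           macro_specificity = agg$macro_specificity,
           macro_ppv = agg$macro_ppv,
           macro_npv = agg$macro_npv,
           n_excluded = as.list(agg$n_excluded),
           per_class = per_class),
      file.path(out_dir, "metrics.json"),
      auto_unbox = TRUE, digits = NA, dataframe = "rows")
    pres <- per_class
    for (col in c("sensitivity", "specificity", "ppv", "npv", "accuracy")) {
      pres[[col]] <- sprintf("%.2f", round_half_up(pres[[col]], 2))
    }
    lines <- c(
      sprintf("micro accuracy: %.2f", round_half_up(agg$micro_accuracy, 2)),
      sprintf("macro sensitivity: %.2f",
              round_half_up(agg$macro_sensitivity, 2)),
      sprintf("macro specificity: %.2f",
              round_half_up(agg$macro_specificity, 2)),
      "", utils::capture.output(print(pres, right = FALSE)))
    writeLines(lines, file.path(out_dir, "metrics.txt"))
  }
  agg
}
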