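#' Fit a triage threshold to estimated soft-max scores
#'
#' Empirical counterpart of [optimal_triage()]: applies the same
#' finite-sample refusal cut to the per-row maxima of an estimated score
#' matrix. When the upstream soft-max is a monotone transform of the
#' true conditional probabilities, thresholding it recovers the oracle
#' rule, because monotone transforms preserve the ordering of row
#' maxima.
#'
#' The rule may be fitted on one score set and applied to another for
#' honest out-of-sample evaluation; applying it back to the fitting data
#' reproduces the in-sample refusals (exactly so when no rows tie at the
#' cut value).
#'
#' @param scores a [score_matrix()] (or coercible matrix).
#' @param epsilon refusal budget in `[0, 1]`.
#' @param class_mask optional logical class-inclusion mask, e.g. from
#'   [min_count_filter()].
#' @return A [triage_rule()] with the realised threshold.
#' @export
fit_threshold <- function(scores, epsilon, class_mask = NULL) {
  scores <- .as_scores(scores)
  if (length(epsilon) != 1L || is.na(epsilon) || epsilon < 0 || epsilon > 1) {
    stop("epsilon must be a single value in [0, 1]", call. = FALSE)
  }
  maxq <- apply(scores$values, 1L, max)
  cut <- .refusal_cut(maxq, scores$weights, epsilon)
  rule <- triage_rule(cut$threshold, scores$labels, epsilon = epsilon)
  if (!is.null(class_mask)) rule <- with_class_mask(rule, class_mask)
  rule
}

#' Apply a triage rule to a score matrix
#'
#' An item is refused when its maximum score does not strictly exceed
#' the rule's threshold, or when its arg-max class is masked out;
#' otherwise it receives its lowest-index arg-max label. This is the
#' factorised form of the rule: decided-set indicator times plug-in
#' classifier.
#'
#' @param scores a [score_matrix()] whose labels match the rule's label
#'   set (any column order).
#' @param rule a [triage_rule()].
#' @return A [triage_result()].
#' @export
apply_triage <- function(scores, rule) {
  scores <- .as_scores(scores)
  stopifnot(inherits(rule, "triage_rule"))
  missing <- setdiff(rule$labels, scores$labels)
  extra <- setdiff(scores$labels, rule$labels)
  if (length(missing) || length(extra)) {
    stop("score labels do not match the rule's labels",
         if (length(missing)) paste0("; missing: ", paste(missing, collapse = ", ")),
         if (length(extra)) paste0("; unexpected: ", paste(extra, collapse = ", ")),
         call. = FALSE)
  }
  if (!identical(scores$labels, rule$labels)) {
    scores$values <- scores$values[, rule$labels, drop = FALSE]
    scores$labels <- rule$labels
  }
  maxq <- apply(scores$values, 1L, max)
  arg_idx <- max.col(scores$values, ties.method = "first")
  decided <- maxq > rule$threshold_b & rule$class_mask[arg_idx]
  .build_result(scores, decided)
}

#' Precision-coverage curve
#'
#' Sweeps the refusal threshold over every distinct observed row
#' maximum (plus a zero endpoint realising full coverage) and reports,
#' at each threshold, the fraction of items classified, the precision on
#' the classified subset, and the joint loss. Coverage is strictly
#' decreasing and joint loss non-increasing along the sweep: refusing
#' more items can only remove potential errors. Inverting this curve
#' tells you how many items must be routed to human review to reach a
#' desired precision.
#'
#' @param scores a [score_matrix()].
#' @param truth character vector of true labels.
#' @param weights optional per-item mass.
#' @return A data frame of class `precision_coverage_curve` with columns
#'   `threshold`, `coverage`, `precision`, `joint_loss`, ordered by
#'   decreasing coverage. The zero-coverage endpoint has `NA` precision.
#' @export
precision_coverage_curve <- function(scores, truth, weights = NULL) {
  scores <- .as_scores(scores)
  n <- nrow(scores$values)
  if (length(truth) != n) {
    stop("truth must have length ", n, ", got ", length(truth), call. = FALSE)
  }
  truth <- as.character(truth)
  weights <- .check_weights(weights, n)
  maxq <- apply(scores$values, 1L, max)
  argmax <- scores$labels[max.col(scores$values, ties.method = "first")]
  wrong <- argmax != truth
  thresholds <- c(0, sort(unique(maxq)))
  rows <- lapply(thresholds, function(b) {
    decided <- maxq > b
    coverage <- sum(weights[decided])
    joint_loss <- sum(weights[decided & wrong])
    data.frame(threshold = b, coverage = coverage,
               precision = if (coverage > 0) 1 - joint_loss / coverage else NA_real_,
               joint_loss = joint_loss)
  })
  curve <- do.call(rbind, rows)
  curve <- curve[order(-curve$coverage, curve$threshold), , drop = FALSE]
  rownames(curve) <- NULL
  class(curve) <- c("precision_coverage_curve", "data.frame")
  curve
}

#' Largest-coverage rule achieving a target precision
#'
#' Inverts the precision-coverage curve: among all threshold placements
#' whose in-sample precision reaches the target, returns the one that
#' classifies the most items (minimising the manual-review workload).
#' When no placement reaches the target the result is flagged
#' unattainable rather than raising an error, so callers can report the
#' best achievable precision instead.
#'
#' @param scores a [score_matrix()].
#' @param truth character vector of true labels.
#' @param target_precision desired precision in `[0, 1]`.
#' @param weights optional per-item mass.
#' @return An object of class `precision_target`: list with `attainable`
#'   (logical), `rule` (a [triage_rule()] or `NULL`), `coverage`,
#'   `precision`, `target_precision`, and `best_precision` (the maximum
#'   precision on the curve, for diagnostics when unattainable).
#' @export
threshold_for_precision <- function(scores, truth, target_precision,
                                    weights = NULL) {
  scores <- .as_scores(scores)
  if (length(target_precision) != 1L || is.na(target_precision) ||
      target_precision < 0 || target_precision > 1) {
    stop("target_precision must be a single value in [0, 1]", call. = FALSE)
  }
  curve <- precision_coverage_curve(scores, truth, weights)
  defined <- !is.na(curve$precision)
  ok <- defined & curve$precision >= target_precision
  best <- if (any(defined)) max(curve$precision[defined]) else NA_real_
  if (!any(ok)) {
    out <- list(attainable = FALSE, rule = NULL, coverage = NA_real_,
                precision = NA_real_, target_precision = target_precision,
                best_precision = best)
    class(out) <- "precision_target"
    return(out)
  }
  # curve rows are ordered by decreasing coverage, so the first
  # qualifying row has maximal coverage
  pick <- which(ok)[1L]
  rule <- triage_rule(curve$threshold[pick], scores$labels,
                      epsilon = 1 - curve$coverage[pick])
  out <- list(attainable = TRUE, rule = rule,
              coverage = curve$coverage[pick],
              precision = curve$precision[pick],
              target_precision = target_precision, best_precision = best)
  class(out) <- "precision_target"
  out
}

#' @export
print.precision_target <- function(x, ...) {
  if (x$attainable) {
    cat(sprintf("Precision target %.4g attained: threshold %.6g, coverage %.4g, precision %.4g\n",
                x$target_precision, x$rule$threshold_b, x$coverage, x$precision))
  } else {
    cat(sprintf("Precision target %.4g unattainable; best achievable precision %.4g\n",
                x$target_precision, x$best_precision))
  }
  invisible(x)
}

#' Per-class error rates against training-set class frequency
#'
#' For each true class, reports its training example count and the
#' misclassification rate among the items of that class that the rule
#' decided. Rare classes tend to be classified less reliably, which is
#' what motivates the minimum-count filter. Classes with no decided
#' items get an `NA` error rate.
#'
#' @param result a [triage_result()] (use a threshold-0 rule for the
#'   full, untriaged classifier).
#' @param truth character vector of true labels.
#' @param counts named non-negative integer vector of per-class training
#'   counts; every truth label must be present.
#' @return Data frame with columns `label`, `count`, `n_items`,
#'   `n_decided`, `n_errors`, `error_rate`, ordered by decreasing count.
#' @export
class_error_by_count <- function(result, truth, counts) {
  stopifnot(inherits(result, "triage_result"))
  truth <- as.character(truth)
  if (length(truth) != length(result$decisions)) {
    stop("truth must match the result's length", call. = FALSE)
  }
  counts <- .check_counts(counts)
  missing <- setdiff(unique(truth), names(counts))
  if (length(missing)) {
    stop("counts is missing an entry for class(es): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  labels <- names(counts)
  rows <- lapply(labels, function(lab) {
    in_class <- truth == lab
    dec <- in_class & result$decided
    n_dec <- sum(dec)
    n_err <- sum(dec & result$decisions != truth)
    data.frame(label = lab, count = unname(counts[lab]),
               n_items = sum(in_class), n_decided = n_dec,
               n_errors = n_err,
               error_rate = if (n_dec > 0) n_err / n_dec else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$count, out$label), , drop = FALSE]
  rownames(out) <- NULL
  out
}

.check_counts <- function(counts) {
  if (is.null(names(counts)) || any(!nzchar(names(counts)))) {
    stop("counts must be a named vector of per-class training counts",
         call. = FALSE)
  }
  vals <- as.numeric(counts)
  if (anyNA(vals) || any(vals < 0) || any(vals != floor(vals))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  stats::setNames(vals, names(counts))
}

#' Minimum-count class filter
#'
#' Declines to classify any class with fewer than `min_count` training
#' examples, on the grounds that under-represented classes are not well
#' enough characterised to be classified reliably. The returned mask is
#' composed into a rule with [with_class_mask()] or the `class_mask`
#' argument of [fit_threshold()]; typical operating points are cutoffs
#' of 100, 500, and 1000 examples.
#'
#' @param counts named non-negative integer vector of per-class counts.
#' @param min_count integer cutoff, `>= 0`.
#' @return Named logical vector, `TRUE` for classes that may be emitted.
#' @examples
#' min_count_filter(c(a1 = 1500, a2 = 600, a3 = 50), 500)
#' @export
min_count_filter <- function(counts, min_count) {
  counts <- .check_counts(counts)
  if (length(min_count) != 1L || is.na(min_count) || min_count < 0) {
    stop("min_count must be a single non-negative integer", call. = FALSE)
  }
  stats::setNames(as.numeric(counts) >= min_count, names(counts))
}
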