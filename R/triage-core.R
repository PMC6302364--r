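#' Bayes classifier on conditional class probabilities
#'
#' Assigns every item to the class with the largest conditional
#' probability. Ties go to the tied class with the lowest column index,
#' the standard convention that makes the induced decision regions a
#' partition of feature space.
#'
#' @param probs a [cond_prob_matrix()], [score_matrix()], or numeric
#'   row-stochastic matrix.
#' @return Character vector of class labels, one per row.
#' @examples
#' bayes_classify(rbind(c(0.2, 0.5, 0.3), c(0.5, 0.5, 0)))
#' @export
bayes_classify <- function(probs) {
  probs <- .as_scores(probs, "probs")
  probs$labels[max.col(probs$values, ties.method = "first")]
}

#' Triage rule
#'
#' A fitted refusal rule: a scalar threshold on the per-item maximum
#' score, a class-inclusion mask (for the minimum-count filter), and the
#' refusal budget epsilon the rule was fitted for. Applying the rule
#' labels an item with its arg-max class when the maximum score strictly
#' exceeds `threshold_b` and the arg-max class is unmasked; otherwise the
#' item is refused.
#'
#' @param threshold_b scalar in `[0, 1]`; items with maximum score `<=`
#'   this value are refused.
#' @param labels ordered class labels the rule applies to.
#' @param class_mask logical vector, `TRUE` for classes the rule may
#'   emit; defaults to all classes.
#' @param epsilon the refusal budget the rule was fitted for (`NA` when
#'   the rule was built directly from a threshold).
#' @return An object of class `triage_rule`.
#' @export
triage_rule <- function(threshold_b, labels, class_mask = NULL, epsilon = NA_real_) {
  labels <- .check_labels(labels, length(labels))
  threshold_b <- as.numeric(threshold_b)
  if (length(threshold_b) != 1L || !is.finite(threshold_b) ||
      threshold_b < 0 || threshold_b > 1) {
    stop("threshold_b must be a single number in [0, 1]", call. = FALSE)
  }
  if (is.null(class_mask)) class_mask <- rep(TRUE, length(labels))
  class_mask <- as.logical(class_mask)
  if (length(class_mask) != length(labels) || anyNA(class_mask)) {
    stop("class_mask must be a logical vector matching the labels",
         call. = FALSE)
  }
  if (!any(class_mask)) {
    stop("class_mask must leave at least one class unmasked", call. = FALSE)
  }
  if (!is.na(epsilon) && (epsilon < 0 || epsilon > 1)) {
    stop("epsilon must lie in [0, 1]", call. = FALSE)
  }
  structure(list(threshold_b = threshold_b, labels = labels,
                 class_mask = class_mask, epsilon = as.numeric(epsilon),
                 tie_break = "lowest_index"),
            class = "triage_rule")
}

#' @export
print.triage_rule <- function(x, ...) {
  cat("Triage rule: refuse when max score <= ",
      format(x$threshold_b, digits = 6), "\n", sep = "")
  if (!is.na(x$epsilon)) {
    cat("Fitted for refusal budget epsilon =", format(x$epsilon), "\n")
  }
  masked <- x$labels[!x$class_mask]
  if (length(masked)) cat("Masked classes:", paste(masked, collapse = ", "), "\n")
  invisible(x)
}

#' Replace the class mask of a triage rule
#'
#' Composes a per-class inclusion mask (for example from
#' [min_count_filter()]) into an existing rule. Masking classes can push
#' realised coverage below `1 - epsilon`; the realised coverage is always
#' reported by [triage_loss()] rather than silently re-normalising the
#' budget.
#'
#' @param rule a [triage_rule()].
#' @param class_mask logical vector or named logical vector over the
#'   rule's labels.
#' @return The rule with the new mask.
#' @export
with_class_mask <- function(rule, class_mask) {
  stopifnot(inherits(rule, "triage_rule"))
  if (!is.null(names(class_mask))) {
    missing <- setdiff(rule$labels, names(class_mask))
    if (length(missing)) {
      stop("class_mask is missing labels: ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
    class_mask <- class_mask[rule$labels]
  }
  triage_rule(rule$threshold_b, rule$labels, class_mask, rule$epsilon)
}

#' Triage decision vector
#'
#' Per-item decisions of a triage rule together with the decided-set
#' indicator and the underlying arg-max (plug-in Bayes) label. The
#' factorisation invariant is enforced: an item's decision equals its
#' arg-max label exactly when it is decided, and equals the refusal
#' token otherwise.
#'
#' @param decisions character vector over the labels plus
#'   [refuse_token()].
#' @param decided logical vector; `TRUE` where a label was emitted.
#' @param argmax_label the plug-in classification of every item,
#'   refused or not.
#' @return An object of class `triage_result`.
#' @export
triage_result <- function(decisions, decided, argmax_label) {
  n <- length(decisions)
  if (length(decided) != n || length(argmax_label) != n) {
    stop("decisions, decided and argmax_label must have equal length",
         call. = FALSE)
  }
  decided <- as.logical(decided)
  if (anyNA(decided)) stop("decided must not contain NA", call. = FALSE)
  if (!all((decisions == refuse_token()) == !decided)) {
    stop("decisions must equal the refusal token exactly on refused items",
         call. = FALSE)
  }
  if (!all(decisions[decided] == argmax_label[decided])) {
    stop("decided items must carry their arg-max label", call. = FALSE)
  }
  structure(list(decisions = as.character(decisions), decided = decided,
                 argmax_label = as.character(argmax_label)),
            class = "triage_result")
}

#' @export
print.triage_result <- function(x, ...) {
  n <- length(x$decisions)
  cat("Triage result:", n, "items,", sum(!x$decided), "refused",
      sprintf("(coverage %.3f)\n", mean(x$decided)))
  invisible(x)
}

# Finite-sample refusal cut: refuse the items of smallest maximum score,
# in stable (score, row index) order, while the refused mass stays within
# epsilon. The 1e-12 guard absorbs cumsum round-off on weights like 1/n.
.refusal_cut <- function(maxp, weights, epsilon) {
  n <- length(maxp)
  ord <- order(maxp, seq_len(n))
  cw <- cumsum(weights[ord])
  k <- sum(cw <= epsilon + 1e-12)
  refused <- ord[seq_len(k)]
  list(refused = refused,
       threshold = if (k > 0L) maxp[ord[k]] else 0,
       n_refused = k)
}

.build_result <- function(scores, decided) {
  argmax <- scores$labels[max.col(scores$values, ties.method = "first")]
  decisions <- ifelse(decided, argmax, refuse_token())
  triage_result(decisions, decided, argmax)
}

#' Optimal epsilon-triage rule for known conditional probabilities
#'
#' The oracle rule: refuse the items whose maximum conditional
#' probability is smallest, spending as much of the refusal budget
#' `epsilon` as the one-sided coverage constraint allows, and classify
#' the rest with the Bayes rule. On uniform weights this refuses exactly
#' `floor(epsilon * n)` items; ties at the cut value are broken by
#' original row index, keeping coverage at or above `1 - epsilon`. The
#' realised threshold (the largest refused maximum, or 0 when nothing is
#' refused) is recorded on the returned rule.
#'
#' @param probs a [cond_prob_matrix()] of true conditionals.
#' @param epsilon refusal budget in `[0, 1]`.
#' @return A list with components `rule` (a [triage_rule()]) and
#'   `result` (a [triage_result()]).
#' @examples
#' p <- cond_prob_matrix(rbind(c(0.90, 0.05, 0.05), c(0.10, 0.80, 0.10),
#'                             c(0.60, 0.20, 0.20), c(0.40, 0.35, 0.25)))
#' tr <- optimal_triage(p, epsilon = 0.25)  # refuses the 0.40-max item
#' tr$result$decisions
#' @export
optimal_triage <- function(probs, epsilon) {
  probs <- .as_probs(probs)
  if (length(epsilon) != 1L || is.na(epsilon) || epsilon < 0 || epsilon > 1) {
    stop("epsilon must be a single value in [0, 1]", call. = FALSE)
  }
  maxp <- apply(probs$values, 1L, max)
  cut <- .refusal_cut(maxp, probs$weights, epsilon)
  decided <- rep(TRUE, nrow(probs$values))
  decided[cut$refused] <- FALSE
  rule <- triage_rule(cut$threshold, probs$labels, epsilon = epsilon)
  list(rule = rule, result = .build_result(probs, decided))
}

#' Joint triage loss, coverage, and precision
#'
#' The joint loss is the mass of items that are both decided and
#' mislabeled, normalised by total mass, so refusals are never
#' penalised. Coverage is the decided mass, and precision is the
#' conditional accuracy on the decided set, `1 - joint_loss / coverage`
#' -- the quantity plotted against fraction classified on a
#' precision-coverage curve. Precision is reported as `NA` (undefined)
#' when nothing is decided, never as 0 or 1.
#'
#' @param result a [triage_result()].
#' @param truth character vector of true labels, one per item.
#' @param weights optional per-item mass, defaults to uniform.
#' @return List with `joint_loss`, `coverage`, `precision`.
#' @export
triage_loss <- function(result, truth, weights = NULL) {
  stopifnot(inherits(result, "triage_result"))
  n <- length(result$decisions)
  if (length(truth) != n) {
    stop("truth must have length ", n, ", got ", length(truth), call. = FALSE)
  }
  weights <- .check_weights(weights, n)
  truth <- as.character(truth)
  joint_loss <- sum(weights[result$decided & result$decisions != truth])
  coverage <- sum(weights[result$decided])
  precision <- if (coverage > 0) 1 - joint_loss / coverage else NA_real_
  list(joint_loss = joint_loss, coverage = coverage, precision = precision)
}

#' Binary likelihood-ratio indecision band
#'
#' For two classes, thresholding the maximum conditional probability at
#' `b` is equivalent to refusing whenever the class-probability ratio
#' `p(1|x) / p(0|x)` falls inside the band `[1/b', b']` with
#' `b' = b / (1 - b)`. The band is empty (measure zero, `b' = 1`)
#' exactly at `b = 1/2`, the smallest possible two-class maximum.
#'
#' @param threshold_b maximum-probability threshold in `[1/2, 1)`.
#' @return An object of class `binary_band` with elements
#'   `ratio_bound_bprime` and `threshold_b`.
#' @examples
#' binary_ratio_band(0.8)$ratio_bound_bprime  # 4
#' @export
binary_ratio_band <- function(threshold_b) {
  if (length(threshold_b) != 1L || is.na(threshold_b) ||
      threshold_b < 0.5 || threshold_b >= 1) {
    stop("threshold_b must lie in [1/2, 1) for a two-class rule",
         call. = FALSE)
  }
  structure(list(ratio_bound_bprime = threshold_b / (1 - threshold_b),
                 threshold_b = threshold_b),
            class = "binary_band")
}

#' @export
print.binary_band <- function(x, ...) {
  cat(sprintf("Binary indecision band: refuse iff 1/%.6g <= p(1|x)/p(0|x) <= %.6g\n",
              x$ratio_bound_bprime, x$ratio_bound_bprime))
  invisible(x)
}

#' Which two-class items does the band refuse?
#'
#' Evaluates the ratio-band refusal region on a two-column probability
#' matrix: item i is refused iff `1/b' <= p(i,2)/p(i,1) <= b'`.
#'
#' @param band a [binary_ratio_band()].
#' @param probs two-class probability or score matrix; column 1 is class
#'   0, column 2 is class 1.
#' @return Logical vector, `TRUE` where the item is refused.
#' @export
band_refuses <- function(band, probs) {
  stopifnot(inherits(band, "binary_band"))
  probs <- .as_scores(probs, "probs")
  if (ncol(probs$values) != 2L) {
    stop("the ratio band applies to two-class matrices only", call. = FALSE)
  }
  p0 <- probs$values[, 1L]
  p1 <- probs$values[, 2L]
  ratio <- ifelse(p0 > 0, p1 / p0, Inf)
  bp <- band$ratio_bound_bprime
  ratio >= 1 / bp & ratio <= bp
}
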