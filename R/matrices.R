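#' Reserved refusal token
#'
#' The literal label used for items a triage rule declines to classify
#' (the "no classification" category). Class labels are validated against
#' it so a refusal can never be confused with a real class.
#'
#' @return The character scalar `"REFUSE"`.
#' @export
refuse_token <- function() "REFUSE"

.check_labels <- function(labels, m) {
  if (is.null(labels)) labels <- paste0("a", seq_len(m))
  labels <- as.character(labels)
  if (length(labels) != m) {
    stop("expected ", m, " class labels, got ", length(labels), call. = FALSE)
  }
  if (anyDuplicated(labels)) {
    stop("duplicate class labels: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "),
         call. = FALSE)
  }
  if (refuse_token() %in% labels) {
    stop("class label collides with the reserved refusal token '",
         refuse_token(), "'", call. = FALSE)
  }
  labels
}

.check_weights <- function(weights, n) {
  if (is.null(weights)) return(rep(1 / n, n))
  weights <- as.numeric(weights)
  if (length(weights) != n) {
    stop("weights must have length ", n, ", got ", length(weights),
         call. = FALSE)
  }
  if (any(weights < 0)) stop("weights must be non-negative", call. = FALSE)
  s <- sum(weights)
  if (s <= 0) stop("weights must have positive total mass", call. = FALSE)
  if (abs(s - 1) > 1e-9) weights <- weights / s
  weights
}

.check_rows <- function(values, tol, what) {
  if (!is.matrix(values)) values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (nrow(values) < 1L || ncol(values) < 1L) {
    stop(what, " must have at least one row and one column", call. = FALSE)
  }
  if (anyNA(values) || any(!is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)[1L, ]
    stop(what, " has a non-finite entry at row ", bad[1L], ", column ",
         bad[2L], call. = FALSE)
  }
  if (any(values < 0) || any(values > 1)) {
    bad <- which(values < 0 | values > 1, arr.ind = TRUE)[1L, ]
    stop(what, " entries must lie in [0, 1]; offending row ", bad[1L],
         ", column ", bad[2L], call. = FALSE)
  }
  sums <- rowSums(values)
  off <- which(abs(sums - 1) > tol)
  if (length(off)) {
    stop(what, " row ", off[1L], " sums to ",
         format(sums[off[1L]], digits = 10), ", not 1 (tolerance ",
         format(tol), ")", call. = FALSE)
  }
  values
}

#' Conditional class probability matrix
#'
#' Container for an n x m matrix whose row i holds the true conditional
#' class probabilities p(a_k | x_i) of item i. Rows must be row-stochastic
#' to within `1e-9`. Optional per-item weights play the role of the
#' feature density on a finite sample and default to uniform `1/n`.
#'
#' @param values numeric matrix, items in rows, classes in columns.
#' @param labels ordered class labels; defaults to column names, then
#'   `a1..am`.
#' @param weights optional non-negative per-item mass, normalised to sum
#'   to 1.
#' @return An object of class `cond_prob_matrix` with elements `values`,
#'   `labels`, `weights`.
#' @seealso [score_matrix()] for estimated (soft-max) scores.
#' @examples
#' p <- cond_prob_matrix(rbind(c(0.2, 0.5, 0.3), c(0.6, 0.2, 0.2)))
#' bayes_classify(p)
#' @export
cond_prob_matrix <- function(values, labels = NULL, weights = NULL) {
  if (is.null(labels) && !is.null(colnames(values))) labels <- colnames(values)
  values <- .check_rows(values, tol = 1e-9, what = "conditional probability matrix")
  labels <- .check_labels(labels, ncol(values))
  colnames(values) <- labels
  structure(list(values = values, labels = labels,
                 weights = .check_weights(weights, nrow(values))),
            class = "cond_prob_matrix")
}

#' Estimated score matrix (soft-max output)
#'
#' Same shape and invariants as [cond_prob_matrix()] but the entries are
#' estimated scores from an upstream classifier's soft-max layer, not
#' assumed equal to the true conditional probabilities. The row-sum
#' tolerance is the looser `1e-6` typical of exported soft-max values.
#'
#' @inheritParams cond_prob_matrix
#' @return An object of class `score_matrix` with elements `values`,
#'   `labels`, `weights`.
#' @export
score_matrix <- function(values, labels = NULL, weights = NULL) {
  if (is.null(labels) && !is.null(colnames(values))) labels <- colnames(values)
  values <- .check_rows(values, tol = 1e-6, what = "score matrix")
  labels <- .check_labels(labels, ncol(values))
  colnames(values) <- labels
  structure(list(values = values, labels = labels,
                 weights = .check_weights(weights, nrow(values))),
            class = "score_matrix")
}

# Accept a cond_prob_matrix, score_matrix, or bare numeric matrix.
.as_scores <- function(x, what = "scores") {
  if (inherits(x, "cond_prob_matrix") || inherits(x, "score_matrix")) return(x)
  if (is.matrix(x) || is.data.frame(x)) return(score_matrix(as.matrix(x)))
  stop(what, " must be a cond_prob_matrix, score_matrix, or numeric matrix",
       call. = FALSE)
}

.as_probs <- function(x, what = "probs") {
  if (inherits(x, "cond_prob_matrix")) return(x)
  if (inherits(x, "score_matrix")) {
    stop(what, " must carry true conditional probabilities ",
         "(a cond_prob_matrix), not estimated scores", call. = FALSE)
  }
  if (is.matrix(x) || is.data.frame(x)) return(cond_prob_matrix(as.matrix(x)))
  stop(what, " must be a cond_prob_matrix or numeric matrix", call. = FALSE)
}

#' @export
print.cond_prob_matrix <- function(x, ...) {
  cat("Conditional probability matrix:", nrow(x$values), "items x",
      length(x$labels), "classes\n")
  cat("Classes:", paste(x$labels, collapse = ", "), "\n")
  invisible(x)
}

#' @export
print.score_matrix <- function(x, ...) {
  cat("Score matrix:", nrow(x$values), "items x",
      length(x$labels), "classes\n")
  cat("Classes:", paste(x$labels, collapse = ", "), "\n")
  invisible(x)
}
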