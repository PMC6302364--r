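#' @keywords internal
# leveled logging to standard error; computation results only ever go to
# standard output or output files
.et_log <- function(level, ...) {
  message("[", level, "] ", ...)
}

.detect_sep <- function(path) {
  first <- readLines(path, n = 1L, warn = FALSE)
  if (length(first) == 0L) stop("file is empty: ", path, call. = FALSE)
  if (grepl("\t", first, fixed = TRUE)) "\t" else ","
}

#' Read a score table from delimited text
#'
#' Reads a CSV or TSV (delimiter auto-detected from the header line)
#' with one item-id column, one numeric score column per class named by
#' the class label, and an optional `truth` column. Rows whose scores
#' sum to 1 within `1e-3` (admitting rounded soft-max exports) but not
#' within the in-memory tolerance of `1e-6` are renormalised, with a
#' warning naming them; larger deviations are rejected. The id column is the column named `id`
#' (case-insensitive) if present, otherwise the first column.
#'
#' @param path file path.
#' @return List with `scores` (a [score_matrix()]), `ids` (character),
#'   and `truth` (character vector or `NULL`).
#' @export
read_scores <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  sep <- .detect_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          comment.char = "", quote = "\"")
  nm <- names(df)
  numeric_nm <- !is.na(suppressWarnings(as.numeric(nm)))
  if (any(numeric_nm)) {
    stop("header row appears to be missing: numeric column name '",
         nm[numeric_nm][1L], "'", call. = FALSE)
  }
  if (anyDuplicated(nm)) {
    stop("duplicate columns in header: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "), call. = FALSE)
  }
  id_col <- if (any(tolower(nm) == "id")) nm[tolower(nm) == "id"][1L] else nm[1L]
  truth_col <- if (any(tolower(nm) == "truth")) nm[tolower(nm) == "truth"][1L] else NULL
  score_cols <- setdiff(nm, c(id_col, truth_col))
  if (length(score_cols) < 2L) {
    stop("need at least two class score columns, found ",
         length(score_cols), call. = FALSE)
  }
  if (refuse_token() %in% score_cols) {
    stop("score column name collides with the reserved refusal token '",
         refuse_token(), "'", call. = FALSE)
  }
  vals <- as.matrix(df[score_cols])
  if (!is.numeric(vals)) {
    bad <- which(is.na(suppressWarnings(
      matrix(as.numeric(vals), nrow = nrow(vals)))) & !is.na(vals),
      arr.ind = TRUE)
    ctx <- if (nrow(bad)) {
      paste0(" (row ", bad[1L, 1L], ", column '", score_cols[bad[1L, 2L]], "')")
    } else ""
    stop("non-numeric score cell", ctx, call. = FALSE)
  }
  if (anyNA(vals)) {
    bad <- which(is.na(vals), arr.ind = TRUE)
    stop("missing score cell (row ", bad[1L, 1L], ", column '",
         score_cols[bad[1L, 2L]], "')", call. = FALSE)
  }
  sums <- rowSums(vals)
  too_far <- which(abs(sums - 1) > 1e-3)
  if (length(too_far)) {
    stop("row ", too_far[1L], " scores sum to ",
         format(sums[too_far[1L]], digits = 8),
         "; more than 1e-3 from 1", call. = FALSE)
  }
  renorm <- which(abs(sums - 1) > 1e-6)
  if (length(renorm)) {
    vals[renorm, ] <- vals[renorm, , drop = FALSE] / sums[renorm]
    .et_log("WARN", "renormalized ", length(renorm),
            " row(s) whose scores summed outside 1 +/- 1e-6 (first: row ",
            renorm[1L], ")")
    warning("renormalized ", length(renorm),
            " row(s) with score sums outside 1 +/- 1e-6", call. = FALSE)
  }
  truth <- if (!is.null(truth_col)) as.character(df[[truth_col]]) else NULL
  if (!is.null(truth)) {
    if (refuse_token() %in% truth) {
      stop("truth column contains the reserved refusal token '",
           refuse_token(), "'", call. = FALSE)
    }
  }
  list(scores = score_matrix(vals, score_cols),
       ids = as.character(df[[id_col]]), truth = truth)
}

.fmt_num <- function(x) {
  ifelse(is.na(x), "NA", sprintf("%.10g", x))
}

#' Write a score table to delimited text
#'
#' Deterministic inverse of [read_scores()]: numbers are written with
#' `%.10g` formatting so identical inputs yield byte-identical files.
#'
#' @param scores a [score_matrix()] or [cond_prob_matrix()].
#' @param path output path; `.tsv` extension selects tab delimiting.
#' @param ids optional item ids, default `item_1..item_n`.
#' @param truth optional truth labels to include as a `truth` column.
#' @export
write_scores <- function(scores, path, ids = NULL, truth = NULL) {
  scores <- .as_scores(scores)
  n <- nrow(scores$values)
  if (is.null(ids)) ids <- paste0("item_", seq_len(n))
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  header <- c("id", scores$labels, if (!is.null(truth)) "truth")
  body <- cbind(ids, apply(scores$values, 2L, .fmt_num),
                if (!is.null(truth)) as.character(truth))
  lines <- c(paste(header, collapse = sep),
             apply(body, 1L, paste, collapse = sep))
  writeLines(lines, path)
  invisible(path)
}

.rule_format_version <- "1.0"

#' Serialise a triage rule to JSON
#'
#' Writes threshold, budget, label order, class mask, tie-break
#' convention and a format version; [read_rule()] round-trips the rule
#' losslessly and rejects unknown format versions.
#'
#' @param rule a [triage_rule()].
#' @param path output path.
#' @export
write_rule <- function(rule, path) {
  stopifnot(inherits(rule, "triage_rule"))
  payload <- list(format_version = .rule_format_version,
                  threshold_b = rule$threshold_b,
                  epsilon = rule$epsilon,
                  labels = rule$labels,
                  class_mask = rule$class_mask,
                  tie_break = rule$tie_break)
  # I(17) significant digits: the shortest representation that
  # round-trips an IEEE double exactly
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17),
                       null = "null", na = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_rule
#' @return `read_rule` returns the [triage_rule()].
#' @export
read_rule <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(payload$format_version) ||
      !identical(as.character(payload$format_version), .rule_format_version)) {
    stop("unknown rule file format version: ",
         if (is.null(payload$format_version)) "<missing>"
         else payload$format_version, call. = FALSE)
  }
  eps <- payload$epsilon
  if (is.null(eps)) eps <- NA_real_
  triage_rule(payload$threshold_b, payload$labels,
              as.logical(payload$class_mask), as.numeric(eps))
}

#' Write a decisions table
#'
#' One row per input item: id, decision (class label or the refusal
#' token), maximum score, and the decided flag. Deterministic
#' formatting for reproducible files.
#'
#' @param result a [triage_result()].
#' @param scores the [score_matrix()] the result came from.
#' @param path output path.
#' @param ids optional item ids.
#' @export
write_decisions <- function(result, scores, path, ids = NULL) {
  stopifnot(inherits(result, "triage_result"))
  scores <- .as_scores(scores)
  n <- length(result$decisions)
  if (is.null(ids)) ids <- paste0("item_", seq_len(n))
  maxq <- apply(scores$values, 1L, max)
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  lines <- c(paste(c("id", "decision", "max_score", "decided"), collapse = sep),
             paste(ids, result$decisions, .fmt_num(maxq),
                   ifelse(result$decided, "true", "false"), sep = sep))
  writeLines(lines, path)
  invisible(path)
}

#' Write / read a precision-coverage curve table
#'
#' @param curve a [precision_coverage_curve()] data frame.
#' @param path output path.
#' @export
write_curve <- function(curve, path) {
  stopifnot(inherits(curve, "precision_coverage_curve") || is.data.frame(curve))
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  lines <- c(paste(c("threshold", "coverage", "precision", "joint_loss"),
                   collapse = sep),
             paste(.fmt_num(curve$threshold), .fmt_num(curve$coverage),
                   .fmt_num(curve$precision), .fmt_num(curve$joint_loss),
                   sep = sep))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_curve
#' @return `read_curve` returns the curve data frame.
#' @export
read_curve <- function(path) {
  sep <- .detect_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  class(df) <- c("precision_coverage_curve", "data.frame")
  df
}

#' Read a per-class counts table
#'
#' Two columns, `label` and `count`, comma or tab delimited.
#'
#' @param path file path.
#' @return Named numeric vector of counts.
#' @export
read_counts <- function(path) {
  sep <- .detect_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  if (!all(c("label", "count") %in% names(df))) {
    stop("counts file needs 'label' and 'count' columns", call. = FALSE)
  }
  .check_counts(stats::setNames(df$count, df$label))
}
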