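#' Log-activity transform
#'
#' Converts an activity in nM to log10 units. All model-quality statistics in
#' this package default to the log-activity scale, since IC50 values span
#' several orders of magnitude and pharmacophore-model regression operates in
#' log space.
#'
#' @param value Positive activity value(s), nM.
#' @return `log10(value)`.
#' @examples
#' to_log_activity(100)   # 2
#' to_log_activity(2.3)   # 0.3617...
#' @export
to_log_activity <- function(value) {
  if (!is.numeric(value)) {
    abort("activity must be numeric", class = "qsarfuse_domain_error")
  }
  if (any(is.na(value) | value <= 0)) {
    abort("activity must be positive to take log10",
          class = "qsarfuse_domain_error")
  }
  log10(value)
}

#' Pearson correlation with strict input validation
#'
#' The model-quality metric used throughout: the Pearson product-moment
#' correlation between experimental and predicted activities.
#'
#' @param x,y Numeric vectors of equal length (at least 2), each with
#'   nonzero variance.
#' @return The correlation, in \[-1, 1\].
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) {
    abort("x and y must have equal length", class = "qsarfuse_shape_error")
  }
  if (length(x) < 2) {
    abort("need at least 2 pairs", class = "qsarfuse_shape_error")
  }
  if (anyNA(x) || anyNA(y)) {
    abort("missing values are not allowed", class = "qsarfuse_shape_error")
  }
  if (sd(x) == 0 || sd(y) == 0) {
    abort("zero variance input", class = "qsarfuse_degenerate_error")
  }
  cor(x, y, method = "pearson")
}

# shared helper: predicted/true value matrix on the chosen scale,
# checking that every system column covers the table
eval_scale <- function(data, cols, scale = c("log10", "raw")) {
  scale <- match.arg(scale)
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols)) {
    abort(paste0("prediction system(s) not found: ",
                 paste(missing_cols, collapse = ", ")),
          class = "qsarfuse_coverage_error")
  }
  for (s in cols) {
    bad <- which(is.na(data[[s]]))
    if (length(bad)) {
      abort(paste0("system '", s, "' is missing predictions for id(s): ",
                   paste(data$id[bad], collapse = ", ")),
            class = "qsarfuse_coverage_error")
    }
  }
  m <- as.matrix(data[cols])
  if (scale == "log10") m <- to_log_activity(m)
  m
}

#' Evaluate prediction systems against experimental activities
#'
#' Computes, per system, the Pearson correlation between experimental and
#' estimated activities over exactly the compounds of `data`, on the chosen
#' scale. This is the r_train / r_test statistic of QSAR model validation.
#'
#' @param data A wide activity table: `id`, the experimental column, and one
#'   numeric column per prediction system.
#' @param systems Character vector of system columns to evaluate; default all.
#' @param scale `"log10"` (default) or `"raw"`.
#' @param truth Name of the experimental-activity column.
#' @param missing `"strict"` (default) raises a coverage error when a system
#'   lacks a prediction for any compound; `"drop"` drops the incomplete pairs
#'   for that system and reports the reduced `n` (exploratory use only).
#' @return A tibble with one row per system: `label`, `n`, `r`, `scale`,
#'   sorted in the order given.
#' @examples
#' train <- load_fixture("table1")
#' evaluate_systems(train)   # r = 0.955, 0.840, 0.238
#' @export
evaluate_systems <- function(data, systems = NULL,
                             scale = c("log10", "raw"),
                             truth = "ic50_nM",
                             missing = c("strict", "drop")) {
  scale <- match.arg(scale)
  missing <- match.arg(missing)
  if (is.null(systems)) systems <- system_labels(data, truth)
  if (!truth %in% names(data)) {
    abort(paste0("missing experimental column '", truth, "'"),
          class = "qsarfuse_schema_error")
  }
  y <- if (scale == "log10") to_log_activity(data[[truth]]) else data[[truth]]
  rows <- purrr::map(systems, function(s) {
    if (!s %in% names(data)) {
      abort(paste0("prediction system(s) not found: ", s),
            class = "qsarfuse_coverage_error")
    }
    v <- data[[s]]
    keep <- !is.na(v)
    if (missing == "strict" && !all(keep)) {
      abort(paste0("system '", s, "' is missing predictions for id(s): ",
                   paste(data$id[!keep], collapse = ", ")),
            class = "qsarfuse_coverage_error")
    }
    x <- if (scale == "log10") to_log_activity(v[keep]) else v[keep]
    tibble(label = s, n = sum(keep), r = pearson_r(x, y[keep]), scale = scale)
  })
  bind_rows(rows)
}

#' Validate a training/testing split
#'
#' Checks a train/test division of an inhibitor collection against the
#' standard selection rules for pharmacophore training sets: (2) at least
#' `min_n` training inhibitors; (3) the training set contains both the most
#' active (minimum IC50) and least active (maximum IC50) inhibitor of the
#' whole collection; (4) training activities span at least
#' `min_span_orders` orders of magnitude. Overlapping identifiers between the
#' two sets are reported as a rule violation, not an error. (Rule 1 of the
#' convention — clear and complete records — is covered by the strict
#' ingest validation.)
#'
#' @param train,test Activity tables (`id`, `ic50_nM`).
#' @param min_n Minimum training-set size (default 16).
#' @param min_span_orders Minimum activity span, log10 units (default 4).
#' @return A `split_report` object. `tidy()` gives one row per rule with its
#'   observed value and pass flag; `glance()` a one-row summary.
#' @examples
#' rep <- validate_training_split(load_fixture("table1"), load_fixture("table2"))
#' tidy(rep)
#' @export
validate_training_split <- function(train, test, min_n = 16,
                                    min_span_orders = 4) {
  if (nrow(train) == 0 || nrow(test) == 0) {
    abort("train and test tables must be non-empty",
          class = "qsarfuse_argument_error")
  }
  n_train <- nrow(train)
  span <- log10(max(train$ic50_nM) / min(train$ic50_nM))
  all_act <- c(train$ic50_nM, test$ic50_nM)
  has_most <- min(train$ic50_nM) <= min(all_act)
  has_least <- max(train$ic50_nM) >= max(all_act)
  overlap <- intersect(train$id, test$id)
  out <- list(
    n_train = n_train,
    n_test = nrow(test),
    span_orders = span,
    has_most_active = has_most,
    has_least_active = has_least,
    overlap_ids = overlap,
    min_n = min_n,
    min_span_orders = min_span_orders,
    rule_flags = c(
      min_size = n_train >= min_n,
      extremes = has_most && has_least,
      span = span >= min_span_orders,
      disjoint = length(overlap) == 0
    )
  )
  class(out) <- "split_report"
  out
}

#' @export
print.split_report <- function(x, ...) {
  cat("Training/testing split report\n")
  cat(sprintf("  n_train = %d (minimum %d): %s\n", x$n_train, x$min_n,
              ifelse(x$rule_flags[["min_size"]], "pass", "FAIL")))
  cat(sprintf("  activity span = %.3f orders (minimum %g): %s\n",
              x$span_orders, x$min_span_orders,
              ifelse(x$rule_flags[["span"]], "pass", "FAIL")))
  cat(sprintf("  most/least active in training set: %s\n",
              ifelse(x$rule_flags[["extremes"]], "pass", "FAIL")))
  cat(sprintf("  train/test ids disjoint: %s\n",
              ifelse(x$rule_flags[["disjoint"]], "pass", "FAIL")))
  invisible(x)
}

#' @rdname validate_training_split
#' @param x A `split_report`.
#' @param ... Unused.
#' @method tidy split_report
#' @export
tidy.split_report <- function(x, ...) {
  tibble(
    rule = c("min_size", "extremes", "span", "disjoint"),
    value = c(x$n_train,
              as.numeric(x$has_most_active && x$has_least_active),
              x$span_orders,
              as.numeric(length(x$overlap_ids) == 0)),
    threshold = c(x$min_n, 1, x$min_span_orders, 1),
    pass = unname(x$rule_flags[c("min_size", "extremes", "span", "disjoint")])
  )
}

#' @rdname validate_training_split
#' @method glance split_report
#' @export
glance.split_report <- function(x, ...) {
  tibble(
    n_train = x$n_train, n_test = x$n_test,
    span_orders = x$span_orders,
    n_rules_failed = sum(!x$rule_flags),
    valid = all(x$rule_flags)
  )
}
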