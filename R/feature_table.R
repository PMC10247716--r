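#' Construct a feature table
#'
#' The shared container for all omics layers in the pipeline: a features x
#' samples numeric matrix with per-sample group labels. Genus count tables,
#' metabolite intensity matrices and hormone panels all travel in this form.
#'
#' @param values Numeric matrix, features in rows, samples in columns.
#'   Row and column names are used as feature and sample identifiers.
#' @param group Per-sample group labels (character or factor, two levels for
#'   all screening operations), aligned with the columns of `values`.
#' @param kind One of `"counts"` (non-negative integers, e.g. genus counts),
#'   `"intensity"` (non-negative reals, e.g. LC-MS peak intensities) or
#'   `"hormone"` (unconstrained reals).
#' @return An object of class `feature_table` with elements `values`,
#'   `feature_ids`, `sample_ids`, `group` (factor) and `kind`.
#' @export
feature_table <- function(values, group, kind = c("counts", "intensity", "hormone")) {
  kind <- match.arg(kind)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix (features x samples)")
  }
  if (is.null(colnames(values)) || (nrow(values) > 0 && is.null(rownames(values)))) {
    stop("`values` must have row names (feature ids) and column names (sample ids)")
  }
  if (is.null(rownames(values))) rownames(values) <- character(0)
  if (anyDuplicated(rownames(values))) {
    dup <- rownames(values)[duplicated(rownames(values))][1L]
    stop("duplicate feature id: ", dup)
  }
  if (anyDuplicated(colnames(values))) {
    dup <- colnames(values)[duplicated(colnames(values))][1L]
    stop("duplicate sample id: ", dup)
  }
  if (length(group) != ncol(values)) {
    stop("`group` must have one label per sample (", ncol(values), " expected)")
  }
  if (anyNA(group)) stop("every sample needs a group label")
  if (kind == "counts") {
    if (any(values < 0) || any(values != round(values))) {
      stop("counts tables must contain non-negative integers")
    }
  }
  structure(
    list(
      values = values,
      feature_ids = rownames(values),
      sample_ids = colnames(values),
      group = factor(group),
      kind = kind
    ),
    class = "feature_table"
  )
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf(
    "<feature_table [%s]> %d features x %d samples; groups: %s\n",
    x$kind, nrow(x$values), ncol(x$values),
    paste(sprintf("%s (n=%d)", levels(x$group), tabulate(x$group)), collapse = ", ")
  ))
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$values)

#' Subset the features of a feature table
#'
#' @param table A [feature_table()].
#' @param features Character vector of feature ids (or logical/integer index).
#' @return A `feature_table` containing only the requested features.
#' @export
subset_features <- function(table, features) {
  stopifnot(inherits(table, "feature_table"))
  v <- table$values[features, , drop = FALSE]
  feature_table(v, table$group, table$kind)
}

# Internal: two-level group as 0/1 indicator (second level = 1).
group_indicator <- function(table) {
  g <- table$group
  if (nlevels(g) != 2L) stop("a 2-level group factor is required")
  as.integer(g == levels(g)[2L])
}
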