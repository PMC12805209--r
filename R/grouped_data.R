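#' Two-level grouped data
#'
#' Bundle individual-level observations of a predictor and an outcome with a
#' group label into a validated container used by all estimators. Group labels
#' may be any atomic values; they are mapped to a canonical index 1..J in
#' order of first appearance.
#'
#' @param x numeric vector of predictor values, one per individual.
#' @param y numeric vector of outcome values, one per individual.
#' @param group vector of group labels, one per individual.
#' @return An object of class `grouped_data`: a list with elements `x`, `y`,
#'   `group` (canonical integer index), `labels` (original label per index),
#'   `sizes` (group sizes), `J` (number of groups), `n` (common group size
#'   when balanced, otherwise `NA`), and `balanced` (logical).
#' @examples
#' d <- grouped_data(x = rnorm(12), y = rnorm(12), group = rep(letters[1:3], 4))
#' d$balanced
#' @export
grouped_data <- function(x, y, group) {
  x <- as.numeric(x)
  y <- as.numeric(y)
  if (length(x) != length(y) || length(x) != length(group))
    stop("x, y and group must have equal length")
  if (anyNA(x) || anyNA(y) || anyNA(group))
    stop("missing values in x, y or group; drop incomplete rows first")
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stop("non-finite values in x or y")
  labels <- unique(group)
  idx <- match(group, labels)
  sizes <- tabulate(idx, nbins = length(labels))
  balanced <- length(unique(sizes)) == 1L
  structure(
    list(x = x, y = y, group = idx, labels = labels, sizes = sizes,
         J = length(labels), n = if (balanced) sizes[1L] else NA_integer_,
         balanced = balanced),
    class = "grouped_data")
}

#' @export
print.grouped_data <- function(x, ...) {
  cat(sprintf("Two-level data: %d individuals in %d groups (%s)\n",
              length(x$x), x$J,
              if (x$balanced) sprintf("balanced, n = %d", x$n)
              else sprintf("unbalanced, sizes %d-%d", min(x$sizes), max(x$sizes))))
  invisible(x)
}

#' Balance grouped data by seeded random deletion
#'
#' Trims every group down to the minimum group size by deleting randomly
#' chosen individuals from larger groups. The deletion is reproducible: the
#' same `seed` always removes the same individuals. If more than
#' `threshold` of the rows would have to be deleted, the data are returned
#' unchanged with a warning and the report flags the abort.
#'
#' @param data a [grouped_data()] object with at least two groups.
#' @param threshold maximum tolerated fraction of deleted rows (default 0.2).
#' @param seed integer seed controlling which rows are deleted.
#' @return A list with elements `data` (the balanced, or untouched,
#'   `grouped_data`) and `report`, a `balance_report` recording original
#'   sizes, target size, rows removed, fraction removed, threshold, seed and
#'   the `aborted` flag.
#' @examples
#' d <- grouped_data(rnorm(18), rnorm(18), rep(1:3, c(5, 7, 6)))
#' b <- balance_data(d, seed = 1)
#' b$report$removed
#' @export
balance_data <- function(data, threshold = 0.2, seed = 1L) {
  stopifnot(inherits(data, "grouped_data"))
  if (data$J < 2L) stop("at least two groups are required")
  if (any(data$sizes == 0L)) stop("empty groups are not allowed")
  target <- min(data$sizes)
  removed <- sum(data$sizes - target)
  total <- length(data$x)
  fraction <- removed / total
  aborted <- fraction > threshold
  report <- structure(
    list(original_sizes = data$sizes, target = target, removed = removed,
         fraction = fraction, threshold = threshold, seed = seed,
         aborted = aborted),
    class = "balance_report")
  if (aborted) {
    warning(sprintf(
      "balancing aborted: %.1f%% of rows would be deleted (threshold %.1f%%)",
      100 * fraction, 100 * threshold))
    return(list(data = data, report = report))
  }
  if (removed == 0L) return(list(data = data, report = report))
  keep <- logical(total)
  with_seed(seed, {
    for (j in seq_len(data$J)) {
      rows <- which(data$group == j)
      if (length(rows) > target)
        rows <- sort(sample(rows, target))
      keep[rows] <- TRUE
    }
  })
  out <- grouped_data(data$x[keep], data$y[keep],
                      data$labels[data$group[keep]])
  list(data = out, report = report)
}

#' @export
print.balance_report <- function(x, ...) {
  cat(sprintf(
    "Balance report: target size %d, removed %d rows (%.1f%%, threshold %.0f%%)%s\n",
    x$target, x$removed, 100 * x$fraction, 100 * x$threshold,
    if (x$aborted) " -- ABORTED" else ""))
  invisible(x)
}

#' Read two-level data from a CSV file
#'
#' Reads a long-format CSV (header required, one row per individual) and
#' returns a [grouped_data()] object. Rows with missing outcome, predictor or
#' group are dropped with a warning giving the count.
#'
#' @param path path to the CSV file.
#' @param y,x,group names of the outcome, predictor and group columns.
#' @return A [grouped_data()] object.
#' @export
read_grouped_csv <- function(path, y = "y", x = "x", group = "group") {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(c(y, x, group), names(df))
  if (length(missing_cols))
    stop("missing columns in CSV: ", paste(missing_cols, collapse = ", "))
  xv <- suppressWarnings(as.numeric(df[[x]]))
  yv <- suppressWarnings(as.numeric(df[[y]]))
  bad <- which(!is.na(df[[x]]) & is.na(xv) | !is.na(df[[y]]) & is.na(yv))
  if (length(bad))
    stop("non-numeric values in predictor or outcome column")
  keep <- !(is.na(xv) | is.na(yv) | is.na(df[[group]]))
  if (any(!keep))
    warning(sprintf("dropped %d rows with missing values", sum(!keep)))
  grouped_data(xv[keep], yv[keep], df[[group]][keep])
}

#' Write two-level data to a CSV file
#'
#' @param data a [grouped_data()] object.
#' @param path output path.
#' @export
write_grouped_csv <- function(data, path) {
  stopifnot(inherits(data, "grouped_data"))
  utils::write.csv(
    data.frame(y = data$y, x = data$x, group = data$labels[data$group]),
    path, row.names = FALSE)
  invisible(path)
}

# run `code` under a temporary RNG state seeded with `seed`
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
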