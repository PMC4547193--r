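# The table-lens interaction algebra over sweep results: every record is a
# row, parameter columns at the left, measure columns at the right. All
# operations are pure: they take a result_table and return an updated one,
# so any interactive gesture has a deterministic scripted equivalent.

#' Build a result table
#'
#' @param x A [sweep_manifest()] or a data frame containing a `record_id`
#'   column plus the named parameter and measure columns.
#' @param param_columns,measure_columns Column names (taken from the manifest
#'   when `x` is one).
#' @return An object of class `result_table` with fields `records` (the data
#'   frame), `param_columns`, `measure_columns`, `ordering` (permutation of
#'   row indices), `visible` (logical per row), `sort_keys`, `selection`
#'   (ordered row indices).
#' @export
result_table <- function(x, param_columns = NULL, measure_columns = NULL) {
  if (inherits(x, "sweep_manifest")) {
    param_columns <- param_columns %||% param_columns(x)
    measure_columns <- measure_columns %||% measure_columns(x)
    x <- x$records
  }
  stopifnot(is.data.frame(x), "record_id" %in% names(x))
  if (is.null(param_columns) || is.null(measure_columns))
    stop("'param_columns' and 'measure_columns' are required for a data frame")
  miss <- setdiff(c(param_columns, measure_columns), names(x))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  structure(list(records = x,
                 param_columns = param_columns,
                 measure_columns = measure_columns,
                 ordering = seq_len(nrow(x)),
                 visible = rep(TRUE, nrow(x)),
                 sort_keys = character(),
                 selection = integer()),
            class = "result_table")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.result_table <- function(x, ...) {
  cat(sprintf(
    "<result_table> %d records (%d visible, %d selected); sort keys: %s\n",
    nrow(x$records), sum(x$visible), length(x$selection),
    if (length(x$sort_keys)) paste(x$sort_keys, collapse = " > ") else "none"))
  invisible(x)
}

table_columns <- function(table) c(table$param_columns, table$measure_columns)

check_column <- function(table, column) {
  if (!column %in% table_columns(table))
    stop("unknown column: '", column, "'")
  column
}

#' Visible records in display order
#'
#' @param table A [result_table()].
#' @return The visible rows of `table$records`, in the current ordering.
#' @export
visible_records <- function(table) {
  idx <- table$ordering[table$visible[table$ordering]]
  table$records[idx, , drop = FALSE]
}

reorder_by_keys <- function(table) {
  args <- c(unname(as.list(table$records[table$sort_keys])),
            list(table$records$record_id))
  table$ordering <- do.call(order, args)
  table
}

#' Nested multi-column sort
#'
#' Appends `new_key` to the table's sort keys and re-sorts: rows are ordered
#' lexicographically ascending by the keys in the order they were applied
#' (earlier keys outermost), ties broken by `record_id`. All previously
#' applied sortings are maintained — rows with equal values for the earlier
#' keys form contiguous bins and are reordered by `new_key` only within each
#' bin, producing the nested step pattern that exposes parameter/measure
#' relationships.
#'
#' @param table A [result_table()].
#' @param new_key Column name not already among the sort keys.
#' @return The re-sorted table.
#' @export
multi_sort <- function(table, new_key) {
  stopifnot(inherits(table, "result_table"))
  check_column(table, new_key)
  if (new_key %in% table$sort_keys)
    stop("column '", new_key, "' is already a sort key")
  table$sort_keys <- c(table$sort_keys, new_key)
  reorder_by_keys(table)
}

# mean (or variance-weighted mean) of |Pearson r| between one parameter and
# every measure column, on the visible records; r is 0 when either side is
# constant
aggregate_correlation <- function(records, param, measure_columns,
                                  weighting = c("none", "variance")) {
  weighting <- match.arg(weighting)
  p <- records[[param]]
  rs <- vapply(measure_columns, function(m) {
    v <- records[[m]]
    if (stats::sd(p) == 0 || stats::sd(v) == 0) return(0)
    abs(stats::cor(p, v))
  }, numeric(1))
  if (weighting == "none") return(mean(rs))
  w <- vapply(measure_columns, function(m) stats::var(records[[m]]),
              numeric(1))
  if (sum(w) == 0) return(0)
  sum(rs * w) / sum(w)
}

#' Smart sort: order by the most output-correlated parameter
#'
#' Scores every parameter by its aggregate correlation with the output
#' measures — by default the mean over measure columns of the absolute
#' Pearson correlation computed on the visible records (correlation taken as
#' 0 when either column is constant); `weighting = "variance"` weights each
#' measure's |r| by the measure's variance instead. The highest-scoring
#' parameter (ties: leftmost parameter column) becomes the sole sort key and
#' the table is re-sorted on it.
#'
#' @param table A [result_table()] with at least 2 visible records.
#' @param weighting `"none"` (mean of |r|) or `"variance"`.
#' @return List with `parameter` (chosen column name), `scores` (named
#'   numeric) and `table` (re-sorted).
#' @export
smart_sort <- function(table, weighting = c("none", "variance")) {
  stopifnot(inherits(table, "result_table"))
  weighting <- match.arg(weighting)
  vis <- visible_records(table)
  if (nrow(vis) < 2L) stop("smart sort needs at least 2 visible records")
  if (length(table$param_columns) < 1L || length(table$measure_columns) < 1L)
    stop("smart sort needs at least one parameter and one measure column")
  scores <- vapply(table$param_columns, aggregate_correlation,
                   numeric(1), records = vis,
                   measure_columns = table$measure_columns,
                   weighting = weighting)
  chosen <- table$param_columns[which.max(scores)]  # ties: leftmost
  table$sort_keys <- chosen
  table <- reorder_by_keys(table)
  list(parameter = chosen, scores = scores, table = table)
}

#' Context-sensitive selection: the maximal run sharing a value
#'
#' Given a cursor position (a visible record and a column), returns the
#' maximal contiguous run of visible rows — in the current ordering —
#' containing that record in which every record has exactly the cursor
#' record's value in the cursor column. This is the scripted equivalent of
#' hover-and-click selection: adjacent rows with the same value for the
#' column under the cursor receive focus together.
#'
#' @param table A [result_table()].
#' @param row Record row index (position in `table$records`); must be
#'   visible.
#' @param column Column name.
#' @return Integer vector of record row indices, top-to-bottom.
#' @export
context_selection <- function(table, row, column) {
  stopifnot(inherits(table, "result_table"))
  check_column(table, column)
  row <- as.integer(row)
  if (row < 1L || row > nrow(table$records)) stop("invalid row index")
  if (!table$visible[row]) stop("row ", row, " is hidden")
  disp <- table$ordering[table$visible[table$ordering]]
  pos <- match(row, disp)
  vals <- table$records[[column]][disp]
  target <- vals[pos]
  lo <- pos
  while (lo > 1L && vals[lo - 1L] == target) lo <- lo - 1L
  hi <- pos
  while (hi < length(vals) && vals[hi + 1L] == target) hi <- hi + 1L
  disp[lo:hi]
}

#' Set the table selection
#'
#' @param table A [result_table()].
#' @param rows Ordered record row indices (must be visible), e.g. from
#'   [context_selection()].
#' @param add Append to the current selection instead of replacing it
#'   (compound selection).
#' @return The updated table.
#' @export
select_rows <- function(table, rows, add = FALSE) {
  stopifnot(inherits(table, "result_table"))
  rows <- as.integer(rows)
  if (any(rows < 1L | rows > nrow(table$records))) stop("invalid row index")
  if (any(!table$visible[rows])) stop("cannot select hidden rows")
  sel <- if (add) c(table$selection, rows) else rows
  table$selection <- sel[!duplicated(sel)]
  table
}

#' Hide records outside an interval
#'
#' Keeps visible only the records whose value in `column` lies in
#' `[lo, hi]` (inclusive), intersected with the previously visible set —
#' filters on different columns compose by intersection. Ordering is
#' unchanged; the selection is pruned to the remaining visible rows.
#'
#' @param table A [result_table()].
#' @param column Column name.
#' @param lo,hi Interval bounds, `lo <= hi`.
#' @return The filtered table.
#' @export
filter_interval <- function(table, column, lo, hi) {
  stopifnot(inherits(table, "result_table"))
  check_column(table, column)
  if (lo > hi) stop("'lo' must be <= 'hi'")
  v <- table$records[[column]]
  table$visible <- table$visible & v >= lo & v <= hi
  table$selection <- table$selection[table$visible[table$selection]]
  table
}

#' Clear all interval filters
#'
#' @param table A [result_table()].
#' @return The table with every record visible again.
#' @export
reset_filters <- function(table) {
  stopifnot(inherits(table, "result_table"))
  table$visible <- rep(TRUE, nrow(table$records))
  table
}

#' Domain coverage of a set of records
#'
#' For each column, reports which parts of the column's domain (its min/max
#' over all records) the given rows occupy: the union of the display bins
#' hit by the rows' values, merged into maximal sub-intervals. This is the
#' data behind the coverage strips that show which parameter/measure values
#' the currently displayed images correspond to.
#'
#' @param table A [result_table()] (non-empty).
#' @param rows Record row indices (typically the selection); may be empty.
#' @param n_bins Number of display bins per column (point values are widened
#'   to one bin).
#' @return Named list (one entry per column, parameters first) of data frames
#'   with columns `lo`, `hi` — the covered sub-intervals.
#' @export
domain_coverage <- function(table, rows, n_bins = 64L) {
  stopifnot(inherits(table, "result_table"))
  if (nrow(table$records) == 0L) stop("empty table")
  rows <- as.integer(rows)
  cols <- table_columns(table)
  out <- lapply(cols, function(cn) {
    v <- table$records[[cn]]
    dlo <- min(v); dhi <- max(v)
    if (length(rows) == 0L)
      return(data.frame(lo = numeric(), hi = numeric()))
    if (dhi == dlo)
      return(data.frame(lo = dlo, hi = dhi))
    width <- (dhi - dlo) / n_bins
    b <- pmin(pmax(ceiling((v[rows] - dlo) / width), 1L), n_bins)
    b <- sort(unique(b))
    runs <- split(b, cumsum(c(1L, diff(b) != 1L)))
    strips <- do.call(rbind, lapply(runs, function(r)
      data.frame(lo = dlo + (min(r) - 1L) * width,
                 hi = dlo + max(r) * width)))
    rownames(strips) <- NULL
    strips
  })
  names(out) <- cols
  out
}

#' Save / load the interaction state of a result table
#'
#' Persists ordering, visibility, sort keys and selection as JSON so CLI
#' invocations can be chained (sort, filter, select, then render).
#'
#' @param table A [result_table()].
#' @param path JSON file path.
#' @return `path` invisibly; `read_table_state` returns the table with the
#'   state applied.
#' @export
write_table_state <- function(table, path) {
  stopifnot(inherits(table, "result_table"))
  st <- list(ordering = table$ordering,
             visible_rows = which(table$visible),
             sort_keys = table$sort_keys,
             selection = table$selection)
  writeLines(jsonlite::toJSON(st, auto_unbox = FALSE, digits = I(17)), path,
             useBytes = TRUE)
  invisible(path)
}

#' @rdname write_table_state
#' @param manifest The manifest the state belongs to.
#' @export
read_table_state <- function(manifest, path) {
  st <- jsonlite::fromJSON(path)
  table <- result_table(manifest)
  n <- nrow(table$records)
  ordering <- as.integer(st$ordering)
  if (!identical(sort(ordering), seq_len(n)))
    stop("state ordering is not a permutation of the table rows")
  table$ordering <- ordering
  table$visible <- seq_len(n) %in% as.integer(st$visible_rows)
  table$sort_keys <- as.character(st$sort_keys)
  table$selection <- as.integer(st$selection)
  table
}
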