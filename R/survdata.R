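#' Construct a left-truncated right-censored survival dataset
#'
#' An `ltrc_data` object holds, for each of n subjects, the study entry
#' (left-truncation) time `entry`, the observed survival time `time`
#' (measured from the same time origin as `entry`), the event indicator
#' `event` (1 = event observed, 0 = right-censored), and an n x p numeric
#' predictor matrix `x`. A subject appears in an LTRC sample only because it
#' survived past its entry time, so `time > entry` is required row by row;
#' `entry = 0` denotes a subject under observation from the time origin.
#'
#' @param entry numeric vector of nonnegative entry times.
#' @param time numeric vector of positive observed times, `time > entry`.
#' @param event integer/numeric vector in \{0, 1\}.
#' @param x numeric matrix of predictors with n rows (may have 0 columns).
#'   Column names are kept; unnamed columns are labelled `x1, x2, ...`.
#' @param id optional subject labels (length n).
#' @param drop_invalid if `TRUE`, rows violating `time > entry` are dropped
#'   with a message giving the count instead of raising an error. Other
#'   violations (missing values, bad event codes, negative entry) always
#'   raise errors: they indicate malformed data, not zero-length risk
#'   intervals.
#' @return An object of class `ltrc_data`: a list with elements `entry`,
#'   `time`, `event`, `x`, `id`.
#' @examples
#' d <- ltrc_data(entry = c(0, 0, 1), time = c(2, 3, 4),
#'                event = c(1, 0, 1), x = matrix(rnorm(3), ncol = 1))
#' d
#' @export
ltrc_data <- function(entry, time, event, x = NULL, id = NULL,
                      drop_invalid = FALSE) {
  n <- length(time)
  if (is.null(x)) x <- matrix(numeric(0), nrow = n, ncol = 0)
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x)) x <- matrix(as.numeric(x), nrow = n)
  storage.mode(x) <- "double"
  entry <- as.numeric(entry)
  time <- as.numeric(time)
  if (length(entry) != n || nrow(x) != n || length(event) != n)
    stop("entry, time, event and rows of x must all have the same length")
  if (anyNA(entry) || anyNA(time) || anyNA(event) || anyNA(x))
    stop("missing values are not allowed in an ltrc_data object")
  if (!all(event %in% c(0, 1)))
    stop("event must be 0/1")
  event <- as.integer(event)
  if (any(entry < 0))
    stop("entry times must be nonnegative; negative at row(s) ",
         paste(utils::head(which(entry < 0), 5L), collapse = ", "))
  bad <- which(time <= entry)
  if (length(bad)) {
    if (drop_invalid) {
      message("dropping ", length(bad),
              " row(s) with time <= entry (zero at-risk duration)")
      keep <- setdiff(seq_len(n), bad)
      entry <- entry[keep]; time <- time[keep]; event <- event[keep]
      x <- x[keep, , drop = FALSE]
      if (!is.null(id)) id <- id[keep]
      n <- length(time)
    } else {
      stop("time must exceed entry for every subject; violated at row(s) ",
           paste(utils::head(bad, 5L), collapse = ", "),
           if (length(bad) > 5L) sprintf(" (and %d more)", length(bad) - 5L),
           ". Use drop_invalid = TRUE to drop such rows.")
    }
  }
  if (any(time <= 0))
    stop("observed times must be positive")
  if (is.null(colnames(x)) && ncol(x) > 0)
    colnames(x) <- paste0("x", seq_len(ncol(x)))
  structure(list(entry = entry, time = time, event = event, x = x,
                 id = id),
            class = "ltrc_data")
}

#' Validate a columnar table as an LTRC dataset
#'
#' Interprets a data frame with reserved columns `entry`, `time`, `event`
#' (or columns named through `column_map`) and treats every remaining
#' numeric column as a predictor.
#'
#' @param table a data frame.
#' @param column_map optional named character vector/list mapping the roles
#'   `entry`, `time`, `event` (and optionally `id`) to column names in
#'   `table`, e.g. `c(entry = "lt_days", time = "os_days", event = "died")`.
#' @inheritParams ltrc_data
#' @return An `ltrc_data` object.
#' @export
as_ltrc_data <- function(table, column_map = NULL, drop_invalid = FALSE) {
  stopifnot(is.data.frame(table))
  map <- list(entry = "entry", time = "time", event = "event", id = NULL)
  if (!is.null(column_map)) {
    column_map <- as.list(column_map)
    unknown <- setdiff(names(column_map), names(map))
    if (length(unknown))
      stop("column_map has unknown role(s): ", paste(unknown, collapse = ", "))
    map[names(column_map)] <- column_map
  }
  for (role in c("entry", "time", "event")) {
    if (!map[[role]] %in% names(table))
      stop("required column '", map[[role]], "' (role: ", role,
           ") not found in table")
  }
  used <- unlist(map[!vapply(map, is.null, TRUE)])
  pred_cols <- setdiff(names(table), used)
  x <- if (length(pred_cols)) {
    xm <- as.matrix(table[pred_cols])
    if (!is.numeric(xm)) stop("predictor columns must be numeric: ",
                              paste(pred_cols[!vapply(table[pred_cols], is.numeric, TRUE)],
                                    collapse = ", "))
    xm
  } else NULL
  ltrc_data(entry = table[[map$entry]], time = table[[map$time]],
            event = table[[map$event]], x = x,
            id = if (!is.null(map$id)) table[[map$id]] else NULL,
            drop_invalid = drop_invalid)
}

#' @export
print.ltrc_data <- function(x, ...) {
  cat(sprintf("LTRC survival dataset: %d subjects, %d predictor(s)\n",
              nobs(x), ncol(x$x)))
  cat(sprintf("  events: %d (%.1f%%), positive entry times: %d (%.1f%%)\n",
              sum(x$event), 100 * mean(x$event),
              sum(x$entry > 0), 100 * mean(x$entry > 0)))
  invisible(x)
}

#' @export
nobs.ltrc_data <- function(object, ...) length(object$time)

#' @export
as.data.frame.ltrc_data <- function(x, ...) {
  out <- data.frame(entry = x$entry, time = x$time, event = x$event)
  if (!is.null(x$id)) out <- cbind(id = x$id, out)
  if (ncol(x$x)) out <- cbind(out, as.data.frame(x$x))
  out
}

#' Subset rows of an LTRC dataset
#' @param x an `ltrc_data` object.
#' @param i row index vector.
#' @param ... ignored.
#' @export
`[.ltrc_data` <- function(x, i, ...) {
  ltrc_data(entry = x$entry[i], time = x$time[i], event = x$event[i],
            x = x$x[i, , drop = FALSE],
            id = if (!is.null(x$id)) x$id[i] else NULL)
}

## ---- delimited I/O ---------------------------------------------------------

#' Read / write LTRC datasets as delimited text
#'
#' `read_ltrc()` reads a comma- or tab-delimited file with a header row;
#' the delimiter is detected from the header line. `write_ltrc()` writes
#' numbers with 17 significant digits so a write -> read round trip
#' reproduces the dataset to full double precision.
#'
#' @param path file path.
#' @inheritParams as_ltrc_data
#' @return `read_ltrc()` returns an `ltrc_data`; `write_ltrc()` returns
#'   `path` invisibly.
#' @export
read_ltrc <- function(path, column_map = NULL, drop_invalid = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  header <- readLines(path, n = 1L)
  if (!length(header)) stop("cannot parse empty file: ", path)
  sep <- if (grepl("\t", header)) "\t" else ","
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE)
  as_ltrc_data(tab, column_map = column_map, drop_invalid = drop_invalid)
}

#' @param data an `ltrc_data` object.
#' @param sep field delimiter: `","` or `"\t"`.
#' @rdname read_ltrc
#' @export
write_ltrc <- function(data, path, sep = ",") {
  stopifnot(inherits(data, "ltrc_data"), sep %in% c(",", "\t"))
  df <- as.data.frame(data)
  num <- vapply(df, is.double, TRUE)
  df[num] <- lapply(df[num], function(v) sprintf("%.17g", v))
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Deterministic train/test split of an LTRC dataset
#'
#' Partitions the rows into a training and a test set. The split depends
#' only on `(n, train_fraction, seed)`, so identical seeds give identical
#' partitions. The training set size is `round(train_fraction * n)`.
#'
#' @param data an `ltrc_data` object (n >= 2).
#' @param train_fraction fraction of rows assigned to training, in (0, 1).
#' @param seed integer seed.
#' @return A list with elements `train` and `test` (both `ltrc_data`) and
#'   `train_idx`, `test_idx` (the row indices).
#' @export
split_ltrc <- function(data, train_fraction = 0.75, seed) {
  stopifnot(inherits(data, "ltrc_data"))
  n <- nobs(data)
  if (n < 2L) stop("need at least 2 rows to split")
  if (!is.numeric(train_fraction) || train_fraction <= 0 || train_fraction >= 1)
    stop("train_fraction must lie strictly between 0 and 1")
  idx <- split_indices(n, train_fraction, seed)
  list(train = data[idx$train], test = data[idx$test],
       train_idx = idx$train, test_idx = idx$test)
}

## index-level split shared with the cohort method
split_indices <- function(n, train_fraction, seed) {
  n_train <- round(train_fraction * n)
  n_train <- max(1L, min(n - 1L, n_train))
  perm <- with_seed(seed, sample.int(n))
  list(train = sort(perm[seq_len(n_train)]),
       test = sort(perm[(n_train + 1L):n]))
}
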