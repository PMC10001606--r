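#' Annual data sequence
#'
#' A `grey_seq` is a named annual series: one real value per calendar year.
#' It is the atom every degree-of-grey-incidence computation consumes — the
#' reference sequence holds the outcome (e.g. circulatory-disease mortality
#' per 100,000), comparison sequences hold candidate factors (smoking rate,
#' physician density per 1,000, income per capita, ...).
#'
#' Invariants enforced at construction: years are strictly increasing
#' integers with no gaps (unless `allow_gaps = TRUE`), at least three
#' observations (the absolute-degree construction needs interior points),
#' and all values finite.
#'
#' @param values numeric vector of observations.
#' @param years integer vector of calendar years, one per value. Defaults to
#'   `seq_along(values)` for unit-free use.
#' @param name label for the series.
#' @param allow_gaps permit missing years. Values are never interpolated;
#'   downstream lag alignment then pairs observations by year value rather
#'   than by position.
#' @return An object of class `grey_seq`.
#' @examples
#' s <- grey_seq(c(86, 84, 81, 79), years = 2001:2004, name = "mortality")
#' mean_image(s)
#' @export
grey_seq <- function(values, years = seq_along(values), name = "x",
                     allow_gaps = FALSE) {
  values <- as.numeric(values)
  years <- as.integer(years)
  if (length(values) != length(years)) {
    stop("grey_seq: `values` and `years` must have equal length", call. = FALSE)
  }
  if (length(values) < 3L) {
    stop("grey_seq: need at least 3 observations, got ", length(values),
         call. = FALSE)
  }
  if (anyNA(years) || any(diff(years) <= 0L)) {
    stop("grey_seq: years must be strictly increasing integers", call. = FALSE)
  }
  if (!allow_gaps && any(diff(years) != 1L)) {
    stop("grey_seq: years have gaps (", paste(years[which(diff(years) != 1L)],
         collapse = ", "), " ...); use allow_gaps = TRUE to permit",
         call. = FALSE)
  }
  if (any(!is.finite(values))) {
    stop("grey_seq: all values must be finite", call. = FALSE)
  }
  structure(list(name = as.character(name)[1L], years = years,
                 values = values),
            class = "grey_seq")
}

#' @export
print.grey_seq <- function(x, ...) {
  cat("<grey_seq> ", x$name, ": ", length(x$values), " obs, ",
      x$years[1L], "-", x$years[length(x$years)], "\n", sep = "")
  print(stats::setNames(x$values, x$years), ...)
  invisible(x)
}

#' @export
length.grey_seq <- function(x) length(x$values)

# Coerce plain numerics for ergonomic use in examples/tests.
as_grey_seq <- function(x, name = "x") {
  if (inherits(x, "grey_seq")) return(x)
  grey_seq(x, name = name)
}

seq_values <- function(x) if (inherits(x, "grey_seq")) x$values else as.numeric(x)

#' Sequence image operators
#'
#' Normalisations applied to a sequence before computing a degree of grey
#' incidence:
#' * `mean_image()` divides by the arithmetic mean, so the output has mean
#'   exactly 1. This is the unit-removing standardisation applied before
#'   Deng's and the absolute degree.
#' * `initial_image()` divides by the first value, so the output starts at 1
#'   (input to the relative degree; scale-free, rate-of-change geometry).
#' * `zero_start_image()` subtracts the first value, so the output starts at
#'   0 (input to the absolute degree's area construction;
#'   translation-removing).
#'
#' @param s a [grey_seq] or numeric vector.
#' @return A `grey_seq` with transformed values on the same years.
#' @examples
#' mean_image(c(1, 2, 3))        # 0.5, 1.0, 1.5
#' initial_image(c(4, 2, 1))     # 1, 0.5, 0.25
#' zero_start_image(c(3, 1, 4))  # 0, -2, 1
#' @export
mean_image <- function(s) {
  s <- as_grey_seq(s)
  m <- mean(s$values)
  if (m == 0) {
    stop("mean_image: degenerate sequence '", s$name,
         "' has zero mean", call. = FALSE)
  }
  new_image(s, s$values / m)
}

#' @rdname mean_image
#' @export
initial_image <- function(s) {
  s <- as_grey_seq(s)
  if (s$values[1L] == 0) {
    stop("initial_image: degenerate sequence '", s$name,
         "' has zero first value", call. = FALSE)
  }
  new_image(s, s$values / s$values[1L])
}

#' @rdname mean_image
#' @export
zero_start_image <- function(s) {
  s <- as_grey_seq(s)
  new_image(s, s$values - s$values[1L])
}

# Internal: rebuild a grey_seq around transformed values, skipping the
# constructor so zero-mean images (a valid zero_start output) are allowed.
new_image <- function(s, values) {
  structure(list(name = s$name, years = s$years, values = values),
            class = "grey_seq")
}

#' Align comparison sequences to a reference under a lag
#'
#' Pairs the reference value at year *t* with each comparison value at year
#' *t − lag*, so a one-year lag regresses/relates this year's outcome on last
#' year's factor levels. With `lag = 0` and complete years this is the
#' identity. When sequences were loaded with gaps allowed, pairing is by
#' year value, not position, and only years where every comparison has an
#' observation at *t − lag* are kept.
#'
#' The returned comparison sequences are re-indexed on the reference years
#' they are paired with; the years the values were observed in are kept in
#' the `source_years` attribute.
#'
#' @param reference a [grey_seq] (the outcome).
#' @param comparisons a single [grey_seq] or a (named) list of them.
#' @param lag non-negative integer; must satisfy `lag < length - 2` so at
#'   least three paired observations remain.
#' @return list with elements `reference` (trimmed `grey_seq`) and
#'   `comparisons` (named list of aligned `grey_seq`).
#' @examples
#' r <- grey_seq(1:5, years = 2001:2005)
#' x <- grey_seq(c(2, 4, 6, 8, 10), years = 2001:2005)
#' lag_align(r, x, lag = 1)$reference$years  # 2002:2005
#' @export
lag_align <- function(reference, comparisons, lag = 0L) {
  reference <- as_grey_seq(reference, "reference")
  if (inherits(comparisons, "grey_seq")) comparisons <- list(comparisons)
  comparisons <- lapply(comparisons, as_grey_seq)
  names(comparisons) <- vapply(comparisons, `[[`, character(1L), "name")
  lag <- as.integer(lag)
  if (lag < 0L) stop("lag_align: lag must be non-negative", call. = FALSE)
  m <- length(reference$values)
  if (lag >= m - 2L) {
    stop("lag_align: lag ", lag, " too large for ", m,
         " observations (need lag < length - 2)", call. = FALSE)
  }
  # Reference years t usable: every comparison observed at t - lag.
  keep <- reference$years
  for (cmp in comparisons) keep <- keep[(keep - lag) %in% cmp$years]
  if (length(keep) < 3L) {
    stop("lag_align: fewer than 3 aligned observations remain", call. = FALSE)
  }
  ref_out <- structure(list(name = reference$name, years = keep,
                            values = reference$values[match(keep, reference$years)]),
                       class = "grey_seq")
  cmp_out <- lapply(comparisons, function(cmp) {
    v <- cmp$values[match(keep - lag, cmp$years)]
    out <- structure(list(name = cmp$name, years = keep, values = v),
                     class = "grey_seq")
    attr(out, "source_years") <- keep - lag
    out
  })
  list(reference = ref_out, comparisons = cmp_out)
}

#' Load an annual panel from CSV into sequences
#'
#' Reads a comma-separated file with a header row and a `year` column and
#' returns one reference sequence (the outcome) plus one comparison sequence
#' per factor. Two dialects are supported: wide (one column per variable,
#' e.g. `mortality_f`, `smoking_f`) and long (a `group` column; pass its
#' name via `group`, and reference/factor columns are extracted per group
#' level).
#'
#' No interpolation is ever performed; missing years are an error unless
#' `allow_gaps = TRUE`.
#'
#' @param path CSV file path.
#' @param reference column name of the outcome.
#' @param factors character vector of factor column names.
#' @param group optional name of a group column (long dialect).
#' @param allow_gaps permit non-consecutive years.
#' @return For the wide dialect, a list with `reference` (a [grey_seq]) and
#'   `comparisons` (named list of `grey_seq`). For the long dialect, a named
#'   list of such lists, one per group level.
#' @export
load_panel <- function(path, reference, factors, group = NULL,
                       allow_gaps = FALSE) {
  if (!file.exists(path)) {
    stop("load_panel: file not found: ", path, call. = FALSE)
  }
  raw <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  needed <- c("year", reference, factors, group)
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols)) {
    stop("load_panel: missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  for (col in setdiff(needed, group)) {
    v <- raw[[col]]
    if (!is.numeric(v)) {
      suppressWarnings(num <- as.numeric(v))
      bad <- which(is.na(num) & !is.na(v) & trimws(v) != "")
      if (length(bad)) {
        stop("load_panel: non-numeric value in column '", col, "', row ",
             bad[1L], ": '", v[bad[1L]], "'", call. = FALSE)
      }
      raw[[col]] <- num
    }
  }
  build_one <- function(df, label_suffix = "") {
    if (anyDuplicated(df$year)) {
      stop("load_panel: year ", df$year[duplicated(df$year)][1L],
           " repeated", label_suffix, " - years must align uniquely",
           call. = FALSE)
    }
    df <- df[order(df$year), , drop = FALSE]
    if (anyNA(df[c(reference, factors)])) {
      stop("load_panel: missing values in data columns", label_suffix,
           call. = FALSE)
    }
    ref <- grey_seq(df[[reference]], df$year, name = reference,
                    allow_gaps = allow_gaps)
    cmps <- lapply(factors, function(f) {
      grey_seq(df[[f]], df$year, name = f, allow_gaps = allow_gaps)
    })
    names(cmps) <- factors
    list(reference = ref, comparisons = cmps)
  }
  if (is.null(group)) return(build_one(raw))
  levels <- unique(raw[[group]])
  out <- lapply(levels, function(g) {
    build_one(raw[raw[[group]] == g, , drop = FALSE],
              paste0(" in group '", g, "'"))
  })
  names(out) <- levels
  # years must align across groups
  yrs <- lapply(out, function(o) o$reference$years)
  if (length(unique(yrs)) > 1L) {
    stop("load_panel: year coverage differs across groups - misaligned panel",
         call. = FALSE)
  }
  out
}
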