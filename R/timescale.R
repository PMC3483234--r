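#' Construct a geologic time scale
#'
#' A time scale is an ordered set of named, non-overlapping geologic
#' intervals. Ages are in Ma before present and increase into the past, so
#' `age_max` is the older bound of an interval and `age_max > age_min >= 0`.
#' Intervals are stored sorted from oldest to youngest.
#'
#' @param name character vector of interval names (unique).
#' @param age_max numeric vector of older bounds (Ma).
#' @param age_min numeric vector of younger bounds (Ma).
#' @return A `timescale` object: a data frame with columns `name`, `age_max`,
#'   `age_min`, sorted old to young.
#' @examples
#' timescale(c("Deseadan", "Colhuehuapian"), c(29, 20.5), c(24.5, 18))
#' @seealso [salma_timescale()] for the packaged South American Land Mammal
#'   Age scale.
#' @export
timescale <- function(name, age_max, age_min) {
  if (length(name) != length(age_max) || length(name) != length(age_min))
    stop("'name', 'age_max' and 'age_min' must have equal length")
  name <- as.character(name)
  age_max <- as.numeric(age_max)
  age_min <- as.numeric(age_min)
  if (anyDuplicated(name))
    stop("interval names must be unique: ",
         paste(unique(name[duplicated(name)]), collapse = ", "))
  if (any(!is.finite(age_max)) || any(!is.finite(age_min)))
    stop("interval bounds must be finite")
  if (any(age_min < 0))
    stop("interval bounds must be non-negative")
  bad <- age_max <= age_min
  if (any(bad))
    stop("age_max must exceed age_min for interval(s): ",
         paste(name[bad], collapse = ", "))
  o <- order(age_max, decreasing = TRUE)
  ts <- data.frame(name = name[o], age_max = age_max[o], age_min = age_min[o],
                   stringsAsFactors = FALSE)
  if (nrow(ts) > 1) {
    # successive intervals must not overlap (touching bounds are fine)
    older_min <- ts$age_min[-nrow(ts)]
    younger_max <- ts$age_max[-1]
    if (any(younger_max > older_min + 1e-9))
      stop("intervals overlap: ",
           paste(ts$name[c(FALSE, younger_max > older_min + 1e-9)],
                 collapse = ", "))
  }
  class(ts) <- c("timescale", "data.frame")
  ts
}

#' South American Land Mammal Age (SALMA) time scale
#'
#' The named late Oligocene to Pliocene SALMA bins with their radioisotopic
#' age bounds (Ma) used throughout the caviomorph worked example: Deseadan
#' 29--24.5, Colhuehuapian 20.5--18, Santacrucian 16.5--15.7, Colloncuran
#' 15.5--13.8, Laventan 13.5--11.8, Chasicoan 9.07--6.1, Huayquerian
#' 6.1--5.3, Montehermosan 5.3--4, Chapadmalan 4--3.27.
#'
#' @return A [timescale] object with nine intervals, sorted old to young.
#' @examples
#' ts <- salma_timescale()
#' interval_bounds(ts, "Deseadan")
#' @export
salma_timescale <- function() {
  timescale(
    name = c("Deseadan", "Colhuehuapian", "Santacrucian", "Colloncuran",
             "Laventan", "Chasicoan", "Huayquerian", "Montehermosan",
             "Chapadmalan"),
    age_max = c(29, 20.5, 16.5, 15.5, 13.5, 9.07, 6.1, 5.3, 4),
    age_min = c(24.5, 18, 15.7, 13.8, 11.8, 6.1, 5.3, 4, 3.27))
}

#' Look up the age bounds of a named interval
#'
#' @param ts a [timescale].
#' @param name interval name.
#' @return Named numeric vector `c(age_max = , age_min = )` in Ma.
#' @export
interval_bounds <- function(ts, name) {
  stopifnot(inherits(ts, "timescale"))
  i <- match(name, ts$name)
  if (anyNA(i))
    stop("unknown interval name(s): ", paste(name[is.na(i)], collapse = ", "))
  if (length(i) == 1L)
    return(c(age_max = ts$age_max[i], age_min = ts$age_min[i]))
  cbind(age_max = ts$age_max[i], age_min = ts$age_min[i])
}

#' Read a time scale from a TSV file
#'
#' The file must have columns `name`, `age_max`, `age_min` (tab separated,
#' with header).
#'
#' @param path file path.
#' @return A [timescale].
#' @export
read_timescale <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("name", "age_max", "age_min")
  if (!all(need %in% names(d)))
    stop("time scale file must have columns: ", paste(need, collapse = ", "))
  timescale(d$name, d$age_max, d$age_min)
}

#' @export
print.timescale <- function(x, ...) {
  cat("Geologic time scale:", nrow(x), "intervals,",
      max(x$age_max), "-", min(x$age_min), "Ma\n")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' Construct a table of fossil occurrences (first appearance data)
#'
#' Each row records the first appearance datum (FAD) of a terminal taxon as
#' an age interval `[fad_min, fad_max]` in Ma, optionally tagged with the
#' geologic interval it falls in. Extant taxa are conventionally recorded
#' with FAD `[0, 0]`.
#'
#' @param taxon character vector of tip labels (unique).
#' @param fad_max numeric, older bound of the FAD (Ma).
#' @param fad_min numeric, younger bound of the FAD (Ma).
#' @param interval optional character vector of interval names; rows with an
#'   interval name and missing numeric bounds take the interval's bounds from
#'   `ts`. When both are given the FAD must lie within the interval.
#' @param ts a [timescale], required when `interval` names are to be resolved.
#' @return A `fossil_occurrences` data frame with columns `taxon`, `fad_max`,
#'   `fad_min`, `interval`.
#' @examples
#' occurrences(c("A", "B"), fad_max = c(29, 0), fad_min = c(24.5, 0))
#' @export
occurrences <- function(taxon, fad_max = NA_real_, fad_min = NA_real_,
                        interval = NA_character_, ts = NULL) {
  n <- length(taxon)
  taxon <- as.character(taxon)
  fad_max <- rep_len(as.numeric(fad_max), n)
  fad_min <- rep_len(as.numeric(fad_min), n)
  interval <- rep_len(as.character(interval), n)
  interval[!is.na(interval) & interval == ""] <- NA_character_
  if (anyDuplicated(taxon))
    stop("duplicate taxon label(s): ",
         paste(unique(taxon[duplicated(taxon)]), collapse = ", "))
  fill <- is.na(fad_max) | is.na(fad_min)
  if (any(fill)) {
    if (is.null(ts))
      stop("rows without numeric FAD bounds need a 'ts' time scale to ",
           "resolve interval names")
    b <- interval_bounds(ts, interval[fill])
    if (is.null(dim(b))) b <- matrix(b, nrow = 1,
                                     dimnames = list(NULL, names(b)))
    fad_max[fill] <- b[, "age_max"]
    fad_min[fill] <- b[, "age_min"]
  }
  bad <- fad_max < fad_min
  if (any(bad))
    stop("fad_max < fad_min for taxon/taxa: ",
         paste(taxon[bad], collapse = ", "))
  if (any(fad_min < 0))
    stop("FAD bounds must be non-negative")
  if (!is.null(ts)) {
    has <- !is.na(interval)
    if (any(has)) {
      b <- interval_bounds(ts, interval[has])
      if (is.null(dim(b))) b <- matrix(b, nrow = 1,
                                       dimnames = list(NULL, names(b)))
      out <- fad_max[has] > b[, "age_max"] + 1e-9 |
        fad_min[has] < b[, "age_min"] - 1e-9
      if (any(out))
        stop("FAD outside its named interval for taxon/taxa: ",
             paste(taxon[has][out], collapse = ", "))
    }
  }
  occ <- data.frame(taxon = taxon, fad_max = fad_max, fad_min = fad_min,
                    interval = interval, stringsAsFactors = FALSE)
  class(occ) <- c("fossil_occurrences", "data.frame")
  occ
}

#' Read fossil occurrences from a TSV file
#'
#' The file must have a `taxon` column and either numeric `fad_max`/`fad_min`
#' columns, an `interval` column resolvable against `ts`, or a mixture (rows
#' with missing numeric bounds are expanded from their interval name).
#'
#' @param path file path.
#' @param ts optional [timescale] used to resolve interval names.
#' @return A `fossil_occurrences` data frame.
#' @export
read_occurrences <- function(path, ts = NULL) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!"taxon" %in% names(d))
    stop("occurrence file must have a 'taxon' column")
  occurrences(taxon = d$taxon,
              fad_max = if ("fad_max" %in% names(d)) d$fad_max else NA_real_,
              fad_min = if ("fad_min" %in% names(d)) d$fad_min else NA_real_,
              interval = if ("interval" %in% names(d)) d$interval
                         else NA_character_,
              ts = ts)
}

#' @export
print.fossil_occurrences <- function(x, ...) {
  ne <- sum(x$fad_max == 0 & x$fad_min == 0)
  cat("Fossil occurrences:", nrow(x), "taxa (", ne, "extant )\n")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}
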