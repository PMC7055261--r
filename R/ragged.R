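#' Build a ragged array from per-unit vectors
#'
#' Spike times of all units in a session are stored as one flat concatenated
#' vector (`data`) plus a cumulative end-index vector (`index`): `index[i]` is
#' the total number of elements belonging to units `1..i`, so `index[n]` equals
#' `length(data)`. This mirrors the `spike_times` / `spike_times_index` column
#' pair of the NWB units table, where the index value points at the last spike
#' of each neuron.
#'
#' @param per_unit_lists List of numeric vectors, one per unit (may be empty).
#' @return An object of class `ragged_pair`: list with `data` (flat numeric
#'   vector) and `index` (integer vector of cumulative end counts).
#' @seealso [slice_ragged()]
#' @examples
#' r <- build_ragged(list(c(0.1, 0.5), 0.9, c(1.2, 2.0)))
#' r$index          # 2 3 5
#' slice_ragged(r, 3)
#' @export
build_ragged <- function(per_unit_lists) {
  stopifnot(is.list(per_unit_lists))
  lens <- vapply(per_unit_lists, length, integer(1))
  data <- if (length(per_unit_lists)) unlist(per_unit_lists, use.names = FALSE) else numeric(0)
  if (is.null(data)) data <- numeric(0)
  if (any(!is.finite(data))) stop("ragged data must be finite")
  structure(list(data = as.numeric(data), index = as.integer(cumsum(lens))),
            class = "ragged_pair")
}

#' Extract one unit's elements from a ragged array
#'
#' Uses half-open zero-based spans internally: unit `i` (1-based here) owns
#' positions `(index[i-1], index[i]]` of `data`, with `index[0] := 0`. On the
#' same index values, MATLAB's 1-based inclusive idiom
#' `data(index(i-1)+1 : index(i))` selects the identical elements, so index
#' vectors written by this package are interoperable with that convention.
#'
#' @param r A `ragged_pair` from [build_ragged()].
#' @param unit_i Unit number, 1-based, in `1..length(r$index)`.
#' @return Numeric vector (possibly empty) of the unit's elements.
#' @export
slice_ragged <- function(r, unit_i) {
  stopifnot(inherits(r, "ragged_pair"), length(unit_i) == 1)
  n <- length(r$index)
  if (unit_i < 1 || unit_i > n) {
    stop("unit_i out of range: ", unit_i, " (have ", n, " units)")
  }
  lo <- if (unit_i == 1) 0L else r$index[unit_i - 1]
  hi <- r$index[unit_i]
  if (hi == lo) return(r$data[0])
  r$data[(lo + 1):hi]
}

#' @export
print.ragged_pair <- function(x, ...) {
  cat("<ragged_pair> ", length(x$index), " units, ",
      length(x$data), " elements\n", sep = "")
  invisible(x)
}
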