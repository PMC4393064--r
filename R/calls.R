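#' Center of a nucleosome interval
#'
#' Coordinates are 0-based half-open (BED convention) throughout the package;
#' the center of an interval is the floor of its midpoint, so it is always an
#' integer base-pair position and is deterministic for even-length intervals.
#'
#' @param start Integer vector of interval starts (0-based, inclusive).
#' @param end Integer vector of interval ends (exclusive); must satisfy
#'   `end > start` elementwise.
#' @return Integer vector of center positions, `floor((start + end) / 2)`.
#' @examples
#' center_of(0, 146)   # 73
#' center_of(100, 101) # 100
#' @export
center_of <- function(start, end) {
  if (length(start) != length(end)) {
    stop("`start` and `end` must have the same length", call. = FALSE)
  }
  if (any(end <= start)) {
    bad <- which(end <= start)[1]
    stop(sprintf("invalid interval: end <= start (first offence at element %d: [%s, %s))",
                 bad, format(start[bad]), format(end[bad])), call. = FALSE)
  }
  as.integer(floor((start + end) / 2))
}

#' Validate and canonicalise a tibble of nucleosome calls
#'
#' A call set is a plain tibble with one row per predicted nucleosome and
#' columns `chrom`, `start`, `end`, `occupancy` and `voter` (an
#' `occupancy_norm` column appears after [normalize_occupancy()]). This
#' function checks the interval and occupancy invariants, (re)derives the
#' `center` column and sorts calls by chromosome and center, which every
#' downstream operation assumes.
#'
#' @param calls A data frame with at least columns `chrom`, `start`, `end`,
#'   `occupancy`, `voter`.
#' @return A tibble sorted by `(chrom, center, voter)` with a `center` column.
#' @export
as_nuc_calls <- function(calls) {
  required <- c("chrom", "start", "end", "occupancy", "voter")
  missing_cols <- setdiff(required, names(calls))
  if (length(missing_cols) > 0) {
    stop("calls are missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  calls <- tibble::as_tibble(calls)
  if (nrow(calls) == 0) {
    calls$center <- integer(0)
    return(dplyr::relocate(calls, "chrom", "start", "end", "center", "occupancy", "voter"))
  }
  if (any(is.na(calls$start)) || any(is.na(calls$end))) {
    stop("calls contain missing coordinates", call. = FALSE)
  }
  if (any(calls$occupancy < 0, na.rm = TRUE)) {
    stop("`occupancy` must be nonnegative", call. = FALSE)
  }
  calls$start <- as.integer(calls$start)
  calls$end <- as.integer(calls$end)
  calls$center <- center_of(calls$start, calls$end)
  calls <- dplyr::arrange(calls, .data$chrom, .data$center, .data$voter)
  dplyr::relocate(calls, "chrom", "start", "end", "center", "occupancy", "voter")
}

#' Nearest call center to a query position
#'
#' @param calls A call tibble (see [as_nuc_calls()]).
#' @param chrom Chromosome of the query.
#' @param pos Query position (bp).
#' @return The row of `calls` whose center is nearest to `pos` on `chrom`
#'   (ties resolved toward the smaller center), or a zero-row tibble if the
#'   chromosome holds no calls.
#' @export
nearest_call <- function(calls, chrom, pos) {
  calls <- as_nuc_calls(calls)
  on_chrom <- calls[calls$chrom == chrom, , drop = FALSE]
  if (nrow(on_chrom) == 0) return(on_chrom)
  d <- abs(on_chrom$center - pos)
  on_chrom[which.min(d), , drop = FALSE]
}
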