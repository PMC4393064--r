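#' Normalize call occupancies across voters
#'
#' Different callers score occupancy on incommensurable scales, so before
#' voting each voter's occupancies are z-scored (zero mean, unit population
#' standard deviation), and then the single global minimum across
#' *all* voters' z-scores is subtracted from every value. The shift makes all
#' normalized occupancies nonnegative (the global minimum maps to exactly 0)
#' while preserving cross-voter comparability, which consensus selection
#' relies on.
#'
#' @param calls Call tibble holding at least two calls per voter with
#'   nonconstant occupancy.
#' @return The call tibble with an `occupancy_norm` column.
#' @export
normalize_occupancy <- function(calls) {
  calls <- as_nuc_calls(calls)
  if (nrow(calls) == 0) {
    calls$occupancy_norm <- numeric(0)
    return(calls)
  }
  stats_by_voter <- dplyr::summarise(
    dplyr::group_by(calls, .data$voter),
    n = dplyr::n(), mu = mean(.data$occupancy), sd = stats::sd(.data$occupancy),
    .groups = "drop")
  bad <- stats_by_voter$n < 2 | is.na(stats_by_voter$sd) | stats_by_voter$sd == 0
  if (any(bad)) {
    stop("degenerate occupancy scale for voter(s): ",
         paste(stats_by_voter$voter[bad], collapse = ", "),
         " (need >= 2 calls with nonconstant occupancy)", call. = FALSE)
  }
  pop_sd <- function(x) stats::sd(x) * sqrt((length(x) - 1) / length(x))
  out <- dplyr::mutate(dplyr::group_by(calls, .data$voter),
                       occupancy_norm = (.data$occupancy - mean(.data$occupancy)) /
                         pop_sd(.data$occupancy))
  out <- dplyr::ungroup(out)
  out$occupancy_norm <- out$occupancy_norm - min(out$occupancy_norm)
  out
}

#' Mean pairwise distance between call centers
#'
#' The center spread of a consensus area: the mean of all pairwise absolute
#' center distances among its members (one pair for two members, three pairs
#' for three).
#'
#' @param centers Numeric vector of at least two center positions.
#' @return Mean pairwise absolute distance, bp.
#' @export
avg_center_distance <- function(centers) {
  if (length(centers) < 2) {
    stop("an area needs at least two members", call. = FALSE)
  }
  mean(stats::dist(matrix(centers, ncol = 1)))
}

# Cross-voter candidate pairs within `max_dist` bp, with the deterministic
# ordering the greedy construction consumes: ascending distance, then smaller
# left center, then larger center, then lexicographic voter pair, then input
# row order. Distances never change as calls are consumed, so scanning this
# list once with used-flags is equivalent to repeatedly re-finding the global
# minimum among remaining calls.
candidate_pairs <- function(center, voter, max_dist) {
  n <- length(center)
  ord <- order(center)
  ii <- integer(0); jj <- integer(0)
  right <- 1L
  for (a in seq_len(n)) {
    i <- ord[a]
    b <- a + 1L
    while (b <= n && center[ord[b]] - center[i] <= max_dist) {
      j <- ord[b]
      if (voter[i] != voter[j]) {
        ii <- c(ii, i); jj <- c(jj, j)
      }
      b <- b + 1L
    }
  }
  if (length(ii) == 0) {
    return(tibble::tibble(i = integer(0), j = integer(0), dist = numeric(0)))
  }
  d <- abs(center[ii] - center[jj])
  cmin <- pmin(center[ii], center[jj])
  cmax <- pmax(center[ii], center[jj])
  vmin <- pmin(voter[ii], voter[jj])
  vmax <- pmax(voter[ii], voter[jj])
  o <- order(d, cmin, cmax, vmin, vmax, pmin(ii, jj), pmax(ii, jj))
  tibble::tibble(i = ii[o], j = jj[o], dist = d[o])
}

#' Group calls from different voters into consensus areas
#'
#' Greedy construction: among all remaining cross-voter pairs with center
#' distance at most `max_center_dist` (73 bp by default — half the prevalent
#' nucleosome size), the globally nearest pair seeds an area; then each voter
#' not yet represented contributes, if possible, its remaining call that
#' minimizes the sum of pairwise center distances within the area while
#' keeping every pairwise distance within the threshold. Members are retired
#' and the search repeats among the remaining calls until no admissible pair
#' is left. Every call ends up in at most one area; calls supported by no
#' other voter are returned as `unmatched`. Ties resolve toward smaller
#' centers, then lexicographic voter ids.
#'
#' @param calls Call tibble from at least two voters (normalized or not).
#' @param max_center_dist Maximum pairwise center distance within an area, bp.
#' @return An object of class `consensus_areas`: a list with `members` (call
#'   rows plus `area_id`), `areas` (per-area summary: `area_id`, `chrom`,
#'   `n_members`, `n_voters`, `avg_center_distance`) and `unmatched` (call
#'   rows in no area).
#' @export
consensus_areas <- function(calls, max_center_dist = 73) {
  stopifnot(max_center_dist >= 1)
  calls <- dplyr::mutate(as_nuc_calls(calls), .call_id = dplyr::row_number())
  area_of <- rep(NA_integer_, nrow(calls))
  next_area <- 0L
  for (chr in unique(calls$chrom)) {
    idx <- which(calls$chrom == chr)
    center <- calls$center[idx]
    voter <- calls$voter[idx]
    pairs <- candidate_pairs(center, voter, max_center_dist)
    if (nrow(pairs) == 0) next
    used <- logical(length(idx))
    voters_all <- sort(unique(voter))
    for (p in seq_len(nrow(pairs))) {
      i <- pairs$i[p]; j <- pairs$j[p]
      if (used[i] || used[j]) next
      next_area <- next_area + 1L
      members <- c(i, j)
      used[i] <- TRUE; used[j] <- TRUE
      for (w in setdiff(voters_all, voter[members])) {
        cand <- which(!used & voter == w)
        if (length(cand) == 0) next
        ok <- cand[vapply(cand, function(k)
          all(abs(center[k] - center[members]) <= max_center_dist), logical(1))]
        if (length(ok) == 0) next
        extra <- vapply(ok, function(k) sum(abs(center[k] - center[members])),
                        numeric(1))
        best <- ok[order(extra, center[ok], ok)][1]
        members <- c(members, best)
        used[best] <- TRUE
      }
      area_of[idx[members]] <- next_area
    }
  }
  calls$area_id <- area_of
  members <- dplyr::filter(calls, !is.na(.data$area_id))
  members <- dplyr::arrange(members, .data$area_id, .data$voter)
  unmatched <- dplyr::select(dplyr::filter(calls, is.na(.data$area_id)),
                             -"area_id", -".call_id")
  if (nrow(members) == 0) {
    areas <- tibble::tibble(area_id = integer(0), chrom = character(0),
                            n_members = integer(0), n_voters = integer(0),
                            avg_center_distance = numeric(0))
  } else {
    areas <- dplyr::summarise(
      dplyr::group_by(members, .data$area_id),
      chrom = .data$chrom[1],
      n_members = dplyr::n(),
      n_voters = dplyr::n_distinct(.data$voter),
      avg_center_distance = avg_center_distance(.data$center),
      .groups = "drop")
  }
  structure(list(members = dplyr::select(members, -".call_id"),
                 areas = areas, unmatched = unmatched),
            class = "consensus_areas")
}

#' @export
print.consensus_areas <- function(x, ...) {
  cat(sprintf("<consensus_areas> %d areas, %d member calls, %d unmatched\n",
              nrow(x$areas), nrow(x$members), nrow(x$unmatched)))
  invisible(x)
}

#' Rank voters by occupancy / center-spread anti-correlation
#'
#' The working hypothesis of the consensus method: where voters agree tightly
#' (small averaged center distance) a real, well-positioned nucleosome is
#' likely present and should carry high occupancy. A voter whose normalized
#' occupancies correlate most negatively with the areas' averaged center
#' distances — computed over areas where *all* voters are represented — is
#' deemed most accurate and receives rank 1.
#'
#' @param ca A [consensus_areas()] object whose members carry
#'   `occupancy_norm`.
#' @param n_voters Total number of voters in play; defaults to the number of
#'   distinct voters seen across members and unmatched calls.
#' @param min_full_areas Minimum number of full-consensus areas required; with
#'   fewer the correlations are not trustworthy and an error is raised.
#' @param method Correlation flavour, `"pearson"` (default) or `"spearman"`.
#' @return A tibble `voter`, `correlation`, `rank` (1 = highest priority,
#'   most negative correlation; ties and undefined correlations fall back to
#'   lexicographic voter order with a warning).
#' @export
voter_priorities <- function(ca, n_voters = NULL, min_full_areas = 3,
                             method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (!"occupancy_norm" %in% names(ca$members)) {
    stop("members carry no `occupancy_norm`; run normalize_occupancy() before ",
         "building areas", call. = FALSE)
  }
  voters <- sort(unique(c(ca$members$voter, ca$unmatched$voter)))
  if (is.null(n_voters)) n_voters <- length(voters)
  full_ids <- ca$areas$area_id[ca$areas$n_voters == n_voters]
  if (length(full_ids) < min_full_areas) {
    stop(sprintf("priority undefined: only %d full-consensus area(s), need >= %d",
                 length(full_ids), min_full_areas), call. = FALSE)
  }
  full <- dplyr::inner_join(
    ca$members[ca$members$area_id %in% full_ids, ],
    ca$areas[, c("area_id", "avg_center_distance")], by = "area_id")
  corr <- dplyr::summarise(
    dplyr::group_by(full, .data$voter),
    correlation = suppressWarnings(
      stats::cor(.data$occupancy_norm, .data$avg_center_distance,
                 method = method)),
    .groups = "drop")
  corr <- dplyr::right_join(corr, tibble::tibble(voter = voters), by = "voter")
  if (any(is.na(corr$correlation)) ||
      anyDuplicated(corr$correlation[!is.na(corr$correlation)])) {
    warning("tied or undefined voter correlations; falling back to ",
            "lexicographic voter order for the affected ranks", call. = FALSE)
  }
  ord <- order(is.na(corr$correlation), corr$correlation, corr$voter)
  corr$rank <- NA_integer_
  corr$rank[ord] <- seq_len(nrow(corr))
  dplyr::arrange(corr, .data$rank)
}

#' Pick one winning call per consensus area
#'
#' In each area the member whose voter holds the best (lowest) rank among the
#' voters present wins; its interval and normalized occupancy are emitted
#' unchanged under the consensus voter id `"nucvoter"` (the original caller is
#' kept in `source_voter`). Calls supported by a single voter never reach an
#' area and are therefore dropped: a site only one voter annotates is treated
#' as nucleosome-free.
#'
#' @param ca A [consensus_areas()] object.
#' @param priorities Priority tibble from [voter_priorities()] or
#'   [global_priorities()].
#' @return Consensus call tibble sorted by center, one row per area.
#' @export
select_consensus <- function(ca, priorities) {
  if (nrow(ca$areas) == 0) {
    out <- ca$members
    out$source_voter <- character(0)
    return(out)
  }
  joined <- dplyr::left_join(ca$members, priorities[, c("voter", "rank")],
                             by = "voter")
  if (any(is.na(joined$rank))) {
    stop("priorities are missing for voter(s): ",
         paste(unique(joined$voter[is.na(joined$rank)]), collapse = ", "),
         call. = FALSE)
  }
  winners <- dplyr::slice_min(dplyr::group_by(joined, .data$area_id),
                              order_by = .data$rank, n = 1, with_ties = FALSE)
  winners <- dplyr::ungroup(winners)
  winners <- dplyr::mutate(winners, source_voter = .data$voter,
                           voter = "nucvoter")
  winners <- dplyr::select(winners, -"rank")
  dplyr::arrange(winners, .data$chrom, .data$center)
}

#' Run the full consensus vote
#'
#' The complete pipeline: normalize occupancies across voters, build
#' consensus areas, rank voters by their occupancy/center-spread
#' anti-correlation (unless fixed `priorities` are supplied, e.g. global
#' priorities shared across related datasets), and emit the winning call per
#' area. Deterministic given its inputs.
#'
#' @param calls Call tibble from at least two voters, with raw `occupancy`.
#' @param max_center_dist Maximum pairwise center distance within an area, bp.
#' @param method Correlation flavour for priorities.
#' @param min_full_areas Minimum full-consensus areas needed to rank voters.
#' @param priorities Optional fixed priority tibble (`voter`, `rank`); when
#'   given, per-dataset priorities are not computed.
#' @return An object of class `nuc_vote`: list with `consensus` (the output
#'   call set), `priorities`, `areas`, `members`, `unmatched` and `config`.
#'   [generics::tidy()] returns the consensus calls, [generics::glance()] a
#'   one-row summary.
#' @export
nuc_vote <- function(calls, max_center_dist = 73,
                     method = c("pearson", "spearman"),
                     min_full_areas = 3, priorities = NULL) {
  method <- match.arg(method)
  calls <- as_nuc_calls(calls)
  n_voters <- dplyr::n_distinct(calls$voter)
  if (n_voters < 2) {
    stop("consensus voting needs calls from at least two voters", call. = FALSE)
  }
  normed <- normalize_occupancy(calls)
  ca <- consensus_areas(normed, max_center_dist)
  if (is.null(priorities)) {
    priorities <- voter_priorities(ca, n_voters = n_voters,
                                   min_full_areas = min_full_areas,
                                   method = method)
  }
  consensus <- select_consensus(ca, priorities)
  structure(list(consensus = consensus, priorities = priorities,
                 areas = ca$areas, members = ca$members,
                 unmatched = ca$unmatched,
                 config = list(max_center_dist = max_center_dist,
                               method = method, n_voters = n_voters)),
            class = "nuc_vote")
}

#' @export
print.nuc_vote <- function(x, ...) {
  cat(sprintf("<nuc_vote> %d voters -> %d consensus nucleosomes (%d areas, %d unmatched calls)\n",
              x$config$n_voters, nrow(x$consensus), nrow(x$areas),
              nrow(x$unmatched)))
  cat("priorities:\n")
  print(as.data.frame(x$priorities), row.names = FALSE)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname nuc_vote
#' @param x A `nuc_vote` object.
#' @param ... Unused.
#' @method tidy nuc_vote
#' @export
tidy.nuc_vote <- function(x, ...) x$consensus

#' @rdname nuc_vote
#' @method glance nuc_vote
#' @export
glance.nuc_vote <- function(x, ...) {
  tibble::tibble(n_voters = x$config$n_voters,
                 n_areas = nrow(x$areas),
                 n_full_areas = sum(x$areas$n_voters == x$config$n_voters),
                 n_consensus = nrow(x$consensus),
                 n_unmatched = nrow(x$unmatched),
                 top_voter = x$priorities$voter[x$priorities$rank == 1])
}

#' Average voter priorities across datasets
#'
#' When several related datasets must be voted consistently (e.g. two
#' conditions of the same cells), each voter's per-dataset correlations are
#' averaged (unweighted) and a single rank order is derived and reused for
#' selection in every dataset.
#'
#' @param priority_tables List of per-dataset priority tibbles from
#'   [voter_priorities()].
#' @return A tibble `voter`, `correlation` (mean across datasets), `rank`.
#' @export
global_priorities <- function(priority_tables) {
  if (length(priority_tables) == 0) {
    stop("no priority tables supplied", call. = FALSE)
  }
  pooled <- dplyr::bind_rows(priority_tables)
  if (all(is.na(pooled$correlation))) {
    stop("priority undefined: no dataset has a defined correlation", call. = FALSE)
  }
  corr <- dplyr::summarise(dplyr::group_by(pooled, .data$voter),
                           correlation = mean(.data$correlation, na.rm = TRUE),
                           .groups = "drop")
  ord <- order(is.na(corr$correlation), corr$correlation, corr$voter)
  corr$rank <- NA_integer_
  corr$rank[ord] <- seq_len(nrow(corr))
  dplyr::arrange(corr, .data$rank)
}

#' Quantile-normalize occupancy vectors across datasets
#'
#' Standard quantile normalization: within each dataset occupancies are
#' sorted, rank `r` is replaced by the cross-dataset mean of the rank-`r`
#' values, and the original order restored. When datasets differ in length
#' the reference distribution lives on the longest dataset's rank grid and
#' shorter datasets interpolate into it. Ties share the interpolated value of
#' their average rank. A single dataset is returned unchanged.
#'
#' @param x List of numeric vectors (one per dataset, each nonempty).
#' @return List of numeric vectors of the same shapes.
#' @examples
#' quantile_normalize(list(c(1, 2, 3), c(4, 5, 6)))
#' @export
quantile_normalize <- function(x) {
  stopifnot(is.list(x), length(x) >= 1)
  if (any(vapply(x, length, integer(1)) == 0)) {
    stop("every dataset needs at least one value", call. = FALSE)
  }
  if (length(x) == 1) return(x)
  n_max <- max(vapply(x, length, integer(1)))
  grid <- seq(0, 1, length.out = n_max)
  sorted_on_grid <- vapply(x, function(v) {
    sv <- sort(v)
    if (length(sv) == 1) return(rep(sv, n_max))
    stats::approx(seq(0, 1, length.out = length(sv)), sv, xout = grid)$y
  }, numeric(n_max))
  reference <- rowMeans(sorted_on_grid)
  lapply(x, function(v) {
    n_i <- length(v)
    target <- if (n_i == n_max) reference
    else if (n_i == 1) stats::approx(grid, reference, xout = 0.5)$y
    else stats::approx(grid, reference, xout = seq(0, 1, length.out = n_i))$y
    if (n_i == 1) return(target)
    r <- rank(v, ties.method = "average")
    stats::approx(seq_len(n_i), target, xout = r)$y
  })
}

#' Quantile-normalize the occupancy column of several call sets
#'
#' @param call_list List of call tibbles (one per dataset).
#' @param column Which occupancy column to normalize across datasets.
#' @return The list with `column` replaced by its quantile-normalized values.
#' @export
quantile_normalize_calls <- function(call_list, column = "occupancy_norm") {
  vals <- lapply(call_list, function(d) d[[column]])
  if (any(vapply(vals, is.null, logical(1)))) {
    stop("column `", column, "` missing from some call set", call. = FALSE)
  }
  normed <- quantile_normalize(vals)
  purrr::map2(call_list, normed, function(d, v) { d[[column]] <- v; d })
}
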