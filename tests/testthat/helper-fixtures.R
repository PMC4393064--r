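# Small in-code fixtures shared across test files.

# A call tibble from explicit centers: fixed 146 bp calls centered on `centers`.
calls_from_centers <- function(centers, voter, occupancy = NULL, chrom = "chrS") {
  if (is.null(occupancy)) occupancy <- seq_along(centers) + 0.5
  start <- as.integer(centers) - 73L
  as_nuc_calls(tibble::tibble(chrom = chrom, start = start, end = start + 146L,
                              occupancy = occupancy, voter = voter))
}

# Random multi-voter call set for property tests (integer centers, positive
# occupancies, no duplicated (voter, center) pairs).
random_calls <- function(n_per_voter, voters = c("a", "b", "c"), span = 600) {
  dplyr::bind_rows(lapply(voters, function(v) {
    centers <- sample.int(span, n_per_voter)
    calls_from_centers(centers + 100L, v, occupancy = stats::runif(n_per_voter, 1, 10))
  }))
}

# The three-voter topology used to pin down greedy area construction:
# voter a = calls 1, 5, 9; voter b = 2, 6, 8; voter c = 3, 4, 7.
# Globally nearest pair is {6, 7}; then {8, 9}; then {1, 2} which absorbs 3
# (total pairwise distance 80) in preference to 4 (130).
figure_topology_calls <- function() {
  dplyr::bind_rows(
    calls_from_centers(c(100, 498, 908), "a", occupancy = c(5, 6, 7)),
    calls_from_centers(c(110, 510, 900), "b", occupancy = c(4, 8, 6)),
    calls_from_centers(c(140, 165, 505), "c", occupancy = c(3, 2, 9))
  )
}

# Independent step-by-step simulation of the greedy consensus rule, written
# as plain exhaustive loops: repeatedly find the globally nearest remaining
# cross-voter pair (ties: smaller left center, larger center, lexicographic
# voter pair, input order), then let every absent voter contribute its
# remaining call minimizing the total pairwise distance subject to all
# pairwise distances <= d. Returns a list of member index vectors (indices
# into the row order of `calls` after as_nuc_calls()).
brute_force_areas <- function(calls, d = 73) {
  calls <- as_nuc_calls(calls)
  center <- calls$center
  voter <- calls$voter
  n <- nrow(calls)
  used <- logical(n)
  areas <- list()
  repeat {
    best <- NULL
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (i >= j || used[i] || used[j]) next
        if (voter[i] == voter[j]) next
        if (abs(center[i] - center[j]) > d) next
        key <- c(abs(center[i] - center[j]),
                 min(center[i], center[j]), max(center[i], center[j]))
        vkey <- sort(c(voter[i], voter[j]))
        cand <- list(i = i, j = j, key = key, vkey = vkey)
        if (is.null(best)) { best <- cand; next }
        cmp <- 0
        for (k in seq_along(key)) {
          if (cand$key[k] != best$key[k]) { cmp <- sign(cand$key[k] - best$key[k]); break }
        }
        if (cmp == 0) {
          if (!identical(cand$vkey, best$vkey)) {
            cmp <- if (paste(cand$vkey, collapse = "") < paste(best$vkey, collapse = "")) -1 else 1
          } else {
            cmp <- sign(min(cand$i, cand$j) - min(best$i, best$j))
            if (cmp == 0) cmp <- sign(max(cand$i, cand$j) - max(best$i, best$j))
          }
        }
        if (cmp < 0) best <- cand
      }
    }
    if (is.null(best)) break
    members <- c(best$i, best$j)
    used[members] <- TRUE
    for (w in sort(setdiff(unique(voter), voter[members]))) {
      cand_rows <- which(!used & voter == w)
      if (length(cand_rows) == 0) next
      feas <- cand_rows[vapply(cand_rows, function(k)
        all(abs(center[k] - center[members]) <= d), logical(1))]
      if (length(feas) == 0) next
      tot <- vapply(feas, function(k) sum(abs(center[k] - center[members])),
                    numeric(1))
      pick <- feas[order(tot, center[feas], feas)][1]
      members <- c(members, pick)
      used[pick] <- TRUE
    }
    areas[[length(areas) + 1]] <- sort(members)
  }
  areas
}

# Extract the fast implementation's areas in the same index space.
fast_areas_as_indices <- function(calls, d = 73) {
  calls <- as_nuc_calls(calls)
  calls$.row <- seq_len(nrow(calls))
  ca <- consensus_areas(calls, max_center_dist = d)
  unname(lapply(split(ca$members$.row, ca$members$area_id), sort))
}
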