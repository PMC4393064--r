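test_that("occupancy normalization z-scores per voter then shifts by the global minimum", {
  calls <- dplyr::bind_rows(
    calls_from_centers(c(100, 400, 700), "a", occupancy = c(1, 2, 3)),
    calls_from_centers(c(120, 420, 720), "b", occupancy = c(10, 30, 50))
  )
  out <- normalize_occupancy(calls)
  a <- out$occupancy_norm[out$voter == "a"]
  # population z-scores of (1, 2, 3) are (-1.2247, 0, 1.2247) before shifting
  expect_equal(a, c(-1.224745, 0, 1.224745) + 1.224745, tolerance = 1e-6)
  expect_equal(min(out$occupancy_norm), 0)
  expect_true(all(out$occupancy_norm >= 0))
  # identical z-profiles across voters still end with global minimum at 0
  b <- out$occupancy_norm[out$voter == "b"]
  expect_equal(a, b, tolerance = 1e-12)
})

test_that("degenerate occupancy scales are rejected", {
  calls <- dplyr::bind_rows(
    calls_from_centers(c(100, 400), "a", occupancy = c(2, 2)),
    calls_from_centers(c(120, 420), "b", occupancy = c(1, 5))
  )
  expect_error(normalize_occupancy(calls), "degenerate occupancy scale.*a")
  expect_error(normalize_occupancy(calls_from_centers(100, "b", occupancy = 1)),
               "degenerate")
})

test_that("averaged center distance is the mean of pairwise distances", {
  expect_equal(avg_center_distance(c(100, 110)), 10)
  expect_equal(avg_center_distance(c(100, 110, 130)), mean(c(10, 30, 20)))
  expect_equal(avg_center_distance(c(50, 50, 50)), 0)
  expect_error(avg_center_distance(100), "at least two")
})

test_that("a lone far call stays unmatched while a near pair forms an area", {
  calls <- dplyr::bind_rows(
    calls_from_centers(100, "a", occupancy = 1),
    calls_from_centers(110, "b", occupancy = 2),
    calls_from_centers(400, "c", occupancy = 3)
  )
  ca <- consensus_areas(calls)
  expect_identical(nrow(ca$areas), 1L)
  expect_identical(sort(ca$members$center), c(100L, 110L))
  expect_identical(ca$unmatched$center, 400L)
  expect_equal(ca$areas$avg_center_distance, 10)
})

test_that("greedy construction reproduces the pinned three-voter topology", {
  ca <- consensus_areas(figure_topology_calls())
  expect_identical(nrow(ca$areas), 3L)
  groups <- lapply(split(ca$members$center, ca$members$area_id), sort)
  # discovery order: {505,510} + 498; {900,908}; {100,110} + 140
  expect_identical(unname(groups[["1"]]), c(498L, 505L, 510L))
  expect_identical(unname(groups[["2"]]), c(900L, 908L))
  expect_identical(unname(groups[["3"]]), c(100L, 110L, 140L))
  # 140 (total pairwise distance 80) beats 165 (130) as the third member
  expect_false(165L %in% ca$members$center)
  expect_identical(ca$unmatched$center, 165L)
})

test_that("single-voter input yields no areas", {
  ca <- consensus_areas(calls_from_centers(c(100, 300), "a"))
  expect_identical(nrow(ca$areas), 0L)
  expect_identical(nrow(ca$unmatched), 2L)
})

test_that("greedy areas match the brute-force simulation on random instances", {
  withr::with_seed(97, {
    for (rep in 1:120) {
      n_calls <- sample(2:12, 1)
      voters <- sample(c("a", "b", "c"), n_calls, replace = TRUE)
      centers <- sample.int(500, n_calls) + 100L
      calls <- dplyr::bind_rows(purrr::map2(centers, voters, function(cc, v)
        calls_from_centers(cc, v, occupancy = runif(1, 1, 10))))
      expect_identical(fast_areas_as_indices(calls),
                       brute_force_areas(calls))
    }
  })
})

test_that("every call lands in exactly one area or in unmatched, within the distance bound", {
  withr::with_seed(31, {
    for (rep in 1:25) {
      calls <- random_calls(n_per_voter = sample(5:25, 1))
      ca <- consensus_areas(calls)
      expect_identical(nrow(ca$members) + nrow(ca$unmatched), nrow(calls))
      # no duplicated calls across areas
      key <- paste(ca$members$voter, ca$members$center, ca$members$occupancy)
      expect_false(any(duplicated(key)))
      # all-pairs constraint inside each area, and voters distinct
      for (g in split(ca$members, ca$members$area_id)) {
        expect_false(any(duplicated(g$voter)))
        expect_lte(max(dist(g$center)), 73)
      }
    }
  })
})

test_that("a wider distance threshold can absorb a would-be seed call into an area", {
  # the greedy rule is not monotone in the threshold: with d = 73 the c call
  # at 80 seeds a second area with a2, but with d = 85 it is absorbed as the
  # third member of the first area and a2 goes unmatched
  calls <- dplyr::bind_rows(
    calls_from_centers(c(1000, 1150), "a", occupancy = c(1, 2)),
    calls_from_centers(1010, "b", occupancy = 3),
    calls_from_centers(1080, "c", occupancy = 4)
  )
  narrow <- consensus_areas(calls, max_center_dist = 73)
  wide <- consensus_areas(calls, max_center_dist = 85)
  expect_identical(nrow(narrow$areas), 2L)
  expect_identical(nrow(wide$areas), 1L)
  expect_identical(sort(wide$members$center), c(1000L, 1010L, 1080L))
  # the fast construction still agrees with the brute-force rule either way
  expect_identical(fast_areas_as_indices(calls, 73), brute_force_areas(calls, 73))
  expect_identical(fast_areas_as_indices(calls, 85), brute_force_areas(calls, 85))
})

test_that("a perfectly anti-correlated voter earns rank 1", {
  # three full areas with spreads (12, 24, 36) bp — offsets (0, x, 2x) give an
  # average pairwise distance of 4x/3 — so voter a's occupancy (30, 20, 10) is
  # exactly linear in spread (r = -1); voter b reverses it, c is in between
  calls <- dplyr::bind_rows(
    calls_from_centers(c(1000, 2000, 3000), "a", occupancy = c(30, 20, 10)),
    calls_from_centers(c(1009, 2018, 3027), "b", occupancy = c(10, 20, 30)),
    calls_from_centers(c(1018, 2036, 3054), "c", occupancy = c(21, 20, 10))
  )
  ca <- consensus_areas(normalize_occupancy(calls))
  pr <- voter_priorities(ca)
  expect_identical(pr$voter[pr$rank == 1], "a")
  expect_equal(pr$correlation[pr$voter == "a"], -1, tolerance = 1e-9)
  expect_identical(pr$voter[pr$rank == 3], "b")
})

test_that("identical call sets tie and fall back to lexicographic voter order", {
  base <- c(1000, 2000, 3000)
  calls <- dplyr::bind_rows(
    calls_from_centers(base, "b", occupancy = c(1, 2, 3)),
    calls_from_centers(base, "a", occupancy = c(1, 2, 3)),
    calls_from_centers(base, "c", occupancy = c(1, 2, 3))
  )
  ca <- consensus_areas(normalize_occupancy(calls))
  expect_warning(pr <- voter_priorities(ca), "lexicographic")
  expect_identical(pr$voter[order(pr$rank)], c("a", "b", "c"))
})

test_that("too few full-consensus areas is an error", {
  calls <- dplyr::bind_rows(
    calls_from_centers(c(1000, 2000), "a", occupancy = c(1, 2)),
    calls_from_centers(c(1001, 2002), "b", occupancy = c(2, 1))
  )
  ca <- consensus_areas(normalize_occupancy(calls))
  expect_error(voter_priorities(ca, n_voters = 2, min_full_areas = 3),
               "priority undefined")
})

test_that("selection emits the best-ranked member per area and drops unmatched calls", {
  calls <- figure_topology_calls()
  ca <- consensus_areas(normalize_occupancy(calls))
  pr <- tibble::tibble(voter = c("b", "a", "c"), rank = 1:3)
  out <- select_consensus(ca, pr)
  expect_identical(nrow(out), nrow(ca$areas))
  expect_identical(out$center, c(110L, 510L, 900L))  # voter b's calls win
  expect_true(all(out$voter == "nucvoter"))
  expect_true(all(out$source_voter == "b"))
  # the unmatched call (center 165) is nowhere in the output
  expect_false(165L %in% out$center)
})

test_that("the full vote is deterministic and collapses identical call sets to themselves", {
  base <- c(1000, 2000, 3000, 4000)
  occ <- c(4, 3, 2, 1)
  calls <- dplyr::bind_rows(
    calls_from_centers(base, "a", occupancy = occ),
    calls_from_centers(base, "b", occupancy = occ),
    calls_from_centers(base, "c", occupancy = occ)
  )
  suppressWarnings({
    fit1 <- nuc_vote(calls)
    fit2 <- nuc_vote(calls)
  })
  expect_identical(fit1$consensus, fit2$consensus)
  expect_identical(fit1$consensus$center, as.integer(base))
  expect_true(all(fit1$areas$avg_center_distance == 0))
  expect_identical(glance(fit1)$n_full_areas, 4L)
  expect_identical(tidy(fit1), fit1$consensus)
  expect_error(nuc_vote(calls_from_centers(base, "a", occupancy = occ)),
               "at least two voters")
})

test_that("global priorities average correlations across datasets", {
  t1 <- tibble::tibble(voter = c("a", "b"), correlation = c(-0.5, -0.2), rank = 1:2)
  t2 <- tibble::tibble(voter = c("a", "b"), correlation = c(-0.1, -0.6), rank = 2:1)
  gp <- global_priorities(list(t1, t2))
  expect_equal(gp$correlation[gp$voter == "a"], -0.3)
  expect_equal(gp$correlation[gp$voter == "b"], -0.4)
  expect_identical(gp$voter[gp$rank == 1], "b")
  expect_identical(global_priorities(list(t1))$rank,
                   t1$rank[order(t1$rank)])
})

test_that("quantile normalization matches hand-computed references", {
  expect_equal(quantile_normalize(list(c(1, 2, 3), c(4, 5, 6))),
               list(c(2.5, 3.5, 4.5), c(2.5, 3.5, 4.5)))
  # identical sorted inputs are a fixed point
  x <- list(c(3, 1, 2), c(1, 2, 3))
  out <- quantile_normalize(x)
  expect_equal(sort(out[[1]]), sort(out[[2]]))
  expect_equal(out[[1]], c(3, 1, 2))
  # equal-length datasets end with identical sorted values
  withr::with_seed(2, y <- list(runif(20), runif(20), runif(20)))
  qy <- quantile_normalize(y)
  expect_equal(sort(qy[[1]]), sort(qy[[2]]))
  expect_equal(sort(qy[[2]]), sort(qy[[3]]))
  # single dataset is untouched
  expect_identical(quantile_normalize(list(c(5, 1))), list(c(5, 1)))
  # calls wrapper replaces the requested column
  cl <- list(calls_from_centers(c(100, 300), "a", occupancy = c(1, 2)),
             calls_from_centers(c(100, 300), "a", occupancy = c(4, 6)))
  out <- quantile_normalize_calls(cl, column = "occupancy")
  expect_equal(out[[1]]$occupancy, c(2.5, 4))
  expect_equal(out[[2]]$occupancy, c(2.5, 4))
})
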