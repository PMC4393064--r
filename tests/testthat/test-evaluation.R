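truth_at <- function(centers) {
  tibble::tibble(chrom = "chrS", start = as.integer(centers) - 73L,
                 end = as.integer(centers) + 73L, center = as.integer(centers))
}

test_that("center matching classifies hand-computed cases", {
  m <- match_nucleosomes(truth_at(100), truth_at(150), d = 73)
  expect_identical(c(m$tp, m$fp, m$fn), c(1L, 0L, 0L))
  expect_equal(m$matched_distances, 50)

  m <- match_nucleosomes(truth_at(100), truth_at(180), d = 73)
  expect_identical(c(m$tp, m$fp, m$fn), c(0L, 1L, 1L))

  m <- match_nucleosomes(truth_at(c(100, 300, 500)), truth_at(c(100, 300, 500)))
  expect_identical(c(m$tp, m$fp, m$fn), c(3L, 0L, 0L))
  expect_true(all(m$matched_distances == 0))
  expect_identical(glance(m), tibble::tibble(tp = 3L, fp = 0L, fn = 0L))
})

test_that("matching is one-to-one: counts always reconcile", {
  withr::with_seed(61, {
    for (rep in 1:20) {
      tr <- truth_at(sort(sample.int(3000, sample(1:30, 1))) + 100L)
      pr <- truth_at(sort(sample.int(3000, sample(1:30, 1))) + 100L)
      m <- match_nucleosomes(tr, pr, d = sample(c(10, 73, 200), 1))
      expect_identical(m$tp + m$fn, nrow(tr))
      expect_identical(m$tp + m$fp, nrow(pr))
      expect_false(any(duplicated(m$pairs$pred_center)))
      expect_false(any(duplicated(m$pairs$truth_center)))
      expect_true(all(m$pairs$dist <= 200))
    }
  })
})

test_that("greedy matching attains the optimal assignment cardinality on small instances", {
  # oracle: maximum bipartite matching size under threshold d via exhaustive
  # recursion over truth-to-prediction assignments
  max_matching <- function(tc, pc, d) {
    if (length(tc) == 0) return(0L)
    best <- max_matching(tc[-1], pc, d)  # leave first truth unmatched
    for (q in seq_along(pc)) {
      if (abs(tc[1] - pc[q]) <= d) {
        best <- max(best, 1L + max_matching(tc[-1], pc[-q], d))
      }
    }
    best
  }
  withr::with_seed(71, {
    for (rep in 1:40) {
      tc <- sample.int(800, sample(1:5, 1)) + 100L
      pc <- sample.int(800, sample(1:5, 1)) + 100L
      d <- sample(c(30, 73, 150), 1)
      m <- match_nucleosomes(truth_at(tc), truth_at(pc), d)
      expect_identical(m$tp, max_matching(tc, pc, d))
    }
  })
})

test_that("unlimited distance with enough predictions leaves no false negatives", {
  tr <- truth_at(c(200, 500, 900))
  pr <- truth_at(c(150, 600, 1000, 4000))
  m <- match_nucleosomes(tr, pr, d = Inf)
  expect_identical(m$fn, 0L)
})

test_that("the distance CDF reproduces hand-computed quantiles and equal-n extraction", {
  cdf <- distance_cdf(c(0, 0, 5, 10))
  expect_equal(cdf$cum_ratio[cdf$distance == 5], 0.75)
  expect_equal(cdf$cum_ratio[cdf$distance == 10], 1.0)
  # equal-n keeps the smallest distances per dataset before pooling
  cdf2 <- distance_cdf(list(c(0, 1, 50), c(2, 3, 80)), equal_n = 2)
  expect_equal(max(cdf2$distance), 3)
  expect_equal(cdf2$cum_ratio[cdf2$distance == 3], 1.0)
  expect_error(distance_cdf(list(c(1, 2), c(3)), equal_n = 2), "equal_n")
  expect_error(distance_cdf(numeric(0)), "empty")
})

test_that("KS comparison behaves at the identity and under separation", {
  same <- ks_compare(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  withr::with_seed(5, {
    a <- rnorm(1000, 0, 5)
    b <- rnorm(1000, 50, 5)
  })
  sep <- ks_compare(a, b)
  expect_lt(sep$p_value, 0.001)
  expect_true(sep$statistic >= 0 && sep$statistic <= 1)
  expect_error(ks_compare(numeric(0), 1), "nonempty")
})

test_that("per-bp confusion reproduces hand counts and boundary cases", {
  tr <- tibble::tibble(start = 0L, end = 100L)
  pr_all <- tibble::tibble(start = 0L, end = 200L)
  conf <- bp_confusion(tr, pr_all, 200)
  expect_equal(conf$sensitivity, 1)
  expect_equal(conf$specificity, 0)
  expect_equal(conf$accuracy, 0.5)

  perfect <- bp_confusion(tr, tr, 200)
  expect_equal(perfect$sensitivity, 1)
  expect_equal(perfect$specificity, 1)
  expect_equal(perfect$accuracy, 1)

  none <- bp_confusion(tr, tr[0, ], 200)
  expect_equal(none$sensitivity, 0)
  expect_equal(none$specificity, 1)

  # conservation: the four cells tile the genome, with overlapping intervals
  withr::with_seed(13, {
    tr2 <- tibble::tibble(start = sample.int(900, 20), end = 0L)
    tr2$end <- tr2$start + sample.int(150, 20)
    pr2 <- tibble::tibble(start = sample.int(900, 15), end = 0L)
    pr2$end <- pr2$start + sample.int(150, 15)
  })
  conf2 <- bp_confusion(tr2, pr2, 1100)
  expect_identical(conf2$tp_bp + conf2$tn_bp + conf2$fp_bp + conf2$fn_bp, 1100L)
})

test_that("paired accuracy test handles dominance, ties and direction", {
  a <- c(0.9, 0.8, 0.95, 0.7)
  b <- a - c(0.01, 0.03, 0.02, 0.05)
  p_ab <- paired_accuracy_test(a, b)
  expect_lt(p_ab, 0.05)
  # one-sided antisymmetry in the continuous case: p(a,b) + p(b,a) = 1
  expect_equal(p_ab + paired_accuracy_test(b, a), 1, tolerance = 1e-9)
  expect_warning(p_tie <- paired_accuracy_test(a, a), "zero-variance")
  expect_equal(p_tie, 1)
  expect_warning(p_dom <- paired_accuracy_test(a + 1, a), "zero-variance")
  expect_equal(p_dom, 0)
  expect_error(paired_accuracy_test(a, b[-1]), "equal length")
})

test_that("linker lengths are positive gaps between consecutive intervals", {
  iv <- tibble::tibble(start = c(0L, 166L, 352L), end = c(146L, 312L, 498L))
  expect_identical(linker_lengths(iv), c(20L, 40L))
  # overlapping consecutive intervals contribute no linker
  ov <- tibble::tibble(start = c(0L, 100L, 400L), end = c(200L, 300L, 500L))
  expect_identical(linker_lengths(ov), c(100L))
  expect_identical(linker_lengths(iv[1, ]), integer(0))
})

test_that("similarity equals TP/(TP+FP+FN) and grows with the threshold", {
  ref <- truth_at(c(100, 300))
  expect_equal(call_similarity(ref, ref), 1)
  expect_equal(call_similarity(ref, truth_at(100)), 0.5)
  expect_equal(call_similarity(truth_at(100), truth_at(5000)), 0)
  expect_error(call_similarity(truth_at(integer(0))[0, ], truth_at(integer(0))[0, ]),
               "undefined")
  withr::with_seed(29, {
    ref2 <- truth_at(sample.int(5000, 25) + 100L)
    pr2 <- truth_at(sample.int(5000, 25) + 100L)
    sims <- vapply(c(5, 20, 73, 200, 1000), function(d)
      call_similarity(ref2, pr2, d), numeric(1))
    expect_true(all(diff(sims) >= 0))
  })
})
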