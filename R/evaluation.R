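#' Match predicted nucleosomes to true nucleosomes by center distance
#'
#' One-to-one matching under the distance threshold `d`: a first greedy pass
#' pairs candidates in ascending distance order (nearest pairs first), and an
#' augmenting-path pass then repairs the pairing to guarantee maximum
#' cardinality — a pure nearest-first greedy can strand a matchable
#' nucleosome, undercounting true positives. Matched truths are true
#' positives, unmatched truths false negatives, unmatched predictions false
#' positives; each prediction can explain at most one true nucleosome, so
#' `fp = n_predicted - tp` and `tp + fn = n_true` always hold.
#'
#' @param truth Tibble of true nucleosomes with a `center` column (and
#'   optionally `chrom`).
#' @param predicted Call tibble with a `center` column.
#' @param d Maximum center distance for a correct prediction, bp (73 by
#'   default: half the prevalent nucleosome size).
#' @return An object of class `nuc_match`: list with counts `tp`, `fp`, `fn`,
#'   the vector `matched_distances` (one entry per true positive) and a
#'   `pairs` tibble (`truth_center`, `pred_center`, `dist`).
#' @export
match_nucleosomes <- function(truth, predicted, d = 73) {
  stopifnot(d >= 0)
  tc <- truth$center
  pc <- predicted$center
  t_chrom <- if ("chrom" %in% names(truth)) truth$chrom else rep("chrS", length(tc))
  p_chrom <- if ("chrom" %in% names(predicted)) predicted$chrom else rep("chrS", length(pc))

  pairs_t <- integer(0); pairs_p <- integer(0)
  for (chr in unique(t_chrom)) {
    ti <- which(t_chrom == chr)
    pi <- which(p_chrom == chr)
    if (length(ti) == 0 || length(pi) == 0) next
    ord <- pi[order(pc[pi])]
    pcs <- pc[ord]
    # left.open so a prediction exactly at distance d is kept on both sides
    lo <- findInterval(tc[ti] - d, pcs, left.open = TRUE) + 1L
    hi <- findInterval(tc[ti] + d, pcs)
    for (a in seq_along(ti)) {
      if (lo[a] > hi[a]) next
      cand <- ord[lo[a]:hi[a]]
      pairs_t <- c(pairs_t, rep.int(ti[a], length(cand)))
      pairs_p <- c(pairs_p, cand)
    }
  }
  match_of_t <- rep(NA_integer_, length(tc))  # truth index -> pred index
  match_of_p <- rep(NA_integer_, length(pc))
  if (length(pairs_t) > 0) {
    dd <- abs(tc[pairs_t] - pc[pairs_p])
    o <- order(dd, tc[pairs_t], pc[pairs_p])
    for (k in o) {
      ti <- pairs_t[k]; pi <- pairs_p[k]
      if (is.na(match_of_t[ti]) && is.na(match_of_p[pi])) {
        match_of_t[ti] <- pi
        match_of_p[pi] <- ti
      }
    }
    # augmenting pass (Kuhn): each still-unmatched truth tries to claim a
    # candidate prediction, recursively re-homing its current owner; `seen`
    # is reset per root so each pass visits a prediction at most once
    adj <- split(pairs_p, pairs_t)
    seen <- logical(length(pc))
    try_truth <- function(ti) {
      for (pi in adj[[as.character(ti)]]) {
        if (seen[pi]) next
        seen[pi] <<- TRUE
        owner <- match_of_p[pi]
        if (is.na(owner) || try_truth(owner)) {
          match_of_t[ti] <<- pi
          match_of_p[pi] <<- ti
          return(TRUE)
        }
      }
      FALSE
    }
    for (root in sort(unique(pairs_t))) {
      if (is.na(match_of_t[root])) {
        seen <- logical(length(pc))
        try_truth(root)
      }
    }
  }
  tp_idx <- which(!is.na(match_of_t))
  pp_idx <- match_of_t[tp_idx]
  dists <- abs(tc[tp_idx] - pc[pp_idx])
  structure(list(tp = length(tp_idx),
                 fp = length(pc) - length(tp_idx),
                 fn = length(tc) - length(tp_idx),
                 matched_distances = dists,
                 pairs = tibble::tibble(truth_center = tc[tp_idx],
                                        pred_center = pc[pp_idx],
                                        dist = dists)),
            class = "nuc_match")
}

#' @export
print.nuc_match <- function(x, ...) {
  cat(sprintf("<nuc_match> TP %d, FP %d, FN %d (median matched distance %s bp)\n",
              x$tp, x$fp, x$fn,
              if (x$tp > 0) format(stats::median(x$matched_distances)) else "-"))
  invisible(x)
}

#' @rdname match_nucleosomes
#' @param x A `nuc_match` object.
#' @param ... Unused.
#' @method tidy nuc_match
#' @export
tidy.nuc_match <- function(x, ...) x$pairs

#' @rdname match_nucleosomes
#' @method glance nuc_match
#' @export
glance.nuc_match <- function(x, ...) {
  tibble::tibble(tp = x$tp, fp = x$fp, fn = x$fn)
}

#' Cumulative distribution of matched center distances
#'
#' Empirical cumulative frequency ratio of true-positive center distances on
#' an integer bp grid. Because methods differ in how many true positives they
#' produce, curves can optionally be made comparable by keeping only the
#' `equal_n` smallest distances of each dataset before pooling.
#'
#' @param distances Numeric vector of matched distances, or a list of such
#'   vectors (one per dataset).
#' @param equal_n Optional count: keep only this many smallest distances per
#'   dataset; must not exceed any dataset's length.
#' @return Tibble `distance` (0 .. max), `cum_ratio` in (0, 1].
#' @export
distance_cdf <- function(distances, equal_n = NULL) {
  if (!is.list(distances)) distances <- list(distances)
  if (any(vapply(distances, length, integer(1)) == 0)) {
    stop("empty distance vector", call. = FALSE)
  }
  if (!is.null(equal_n)) {
    if (any(vapply(distances, length, integer(1)) < equal_n)) {
      stop("`equal_n` exceeds the number of true positives in some dataset",
           call. = FALSE)
    }
    distances <- lapply(distances, function(v) sort(v)[seq_len(equal_n)])
  }
  pooled <- unlist(distances)
  grid <- 0:ceiling(max(pooled))
  tibble::tibble(distance = grid, cum_ratio = stats::ecdf(pooled)(grid))
}

#' Two-sample Kolmogorov-Smirnov comparison of distance distributions
#'
#' @param a,b Nonempty numeric vectors of matched center distances.
#' @return Tibble `statistic`, `p_value` from the two-sided two-sample test.
#' @export
ks_compare <- function(a, b) {
  if (length(a) == 0 || length(b) == 0) {
    stop("both samples must be nonempty", call. = FALSE)
  }
  res <- suppressWarnings(stats::ks.test(a, b, alternative = "two.sided"))
  tibble::tibble(statistic = unname(res$statistic), p_value = res$p.value)
}

# 0/1 coverage over [0, genome_len) from half-open intervals, via a
# difference vector (no per-interval loop).
coverage_vector <- function(start, end, genome_len) {
  d <- integer(genome_len + 1L)
  if (length(start) > 0) {
    s <- pmax(as.integer(start), 0L)
    e <- pmin(as.integer(end), as.integer(genome_len))
    keep <- e > s
    s <- s[keep]; e <- e[keep]
    agg_s <- rowsum(rep(1L, length(s)), s)
    agg_e <- rowsum(rep(1L, length(e)), e)
    d[as.integer(rownames(agg_s)) + 1L] <- d[as.integer(rownames(agg_s)) + 1L] + agg_s[, 1]
    d[as.integer(rownames(agg_e)) + 1L] <- d[as.integer(rownames(agg_e)) + 1L] - agg_e[, 1]
  }
  cumsum(d[seq_len(genome_len)]) > 0
}

#' Per-base-pair confusion matrix of nucleosomal vs linker positions
#'
#' Every genomic position is labelled nucleosomal (covered by at least one
#' interval) or linker, under the truth and under the prediction. True/false
#' positives/negatives are counts of positions; sensitivity = TP/(TP+FN)
#' measures recovery of nucleosomal positions, specificity = TN/(TN+FP)
#' recovery of linker positions, and accuracy = (TP+TN)/genome length.
#'
#' @param truth,predicted Interval tibbles with `start`, `end` columns
#'   (0-based half-open), all within `[0, genome_len)`.
#' @param genome_len Chromosome length, bp.
#' @return One-row tibble: `tp_bp`, `tn_bp`, `fp_bp`, `fn_bp`, `sensitivity`,
#'   `specificity`, `accuracy`. Ratios with empty denominators are reported
#'   as `NaN`.
#' @export
bp_confusion <- function(truth, predicted, genome_len) {
  truth_cov <- coverage_vector(truth$start, truth$end, genome_len)
  pred_cov <- coverage_vector(predicted$start, predicted$end, genome_len)
  tp <- sum(truth_cov & pred_cov)
  tn <- sum(!truth_cov & !pred_cov)
  fp <- sum(!truth_cov & pred_cov)
  fn <- sum(truth_cov & !pred_cov)
  tibble::tibble(tp_bp = tp, tn_bp = tn, fp_bp = fp, fn_bp = fn,
                 sensitivity = tp / (tp + fn),
                 specificity = tn / (tn + fp),
                 accuracy = (tp + tn) / genome_len)
}

#' One-sided paired t-test on per-dataset accuracies
#'
#' Tests whether method A's per-dataset accuracies exceed method B's
#' (alternative: mean difference > 0), pairing by dataset. Zero-variance
#' differences are degenerate for the t statistic; by convention the p-value
#' is then 0 when A strictly dominates, 1 otherwise, with a warning.
#'
#' @param acc_a,acc_b Equal-length numeric vectors (length >= 2) of
#'   per-dataset accuracies for the two methods.
#' @return The one-sided p-value.
#' @export
paired_accuracy_test <- function(acc_a, acc_b) {
  if (length(acc_a) != length(acc_b)) {
    stop("accuracy vectors must have equal length", call. = FALSE)
  }
  if (length(acc_a) < 2) stop("need at least two paired datasets", call. = FALSE)
  diffs <- acc_a - acc_b
  if (stats::sd(diffs) < 1e-10 * (abs(mean(diffs)) + 1e-100)) {
    warning("zero-variance paired differences; returning the limiting p-value",
            call. = FALSE)
    return(if (mean(diffs) > 0) 0 else 1)
  }
  stats::t.test(acc_a, acc_b, paired = TRUE, alternative = "greater")$p.value
}

#' Linker lengths between consecutive nucleosome intervals
#'
#' Gaps between consecutive intervals sorted by start, per chromosome:
#' `next_start - prev_end` where positive. Overlapping or abutting
#' consecutive intervals contribute no linker.
#'
#' @param intervals Tibble with `start`, `end` (and optionally `chrom`)
#'   columns.
#' @return Integer vector of linker lengths, bp.
#' @export
linker_lengths <- function(intervals) {
  if (nrow(intervals) < 2) return(integer(0))
  chrom <- if ("chrom" %in% names(intervals)) intervals$chrom
           else rep("chrS", nrow(intervals))
  out <- integer(0)
  for (chr in unique(chrom)) {
    sub <- intervals[chrom == chr, , drop = FALSE]
    sub <- sub[order(sub$start, sub$end), , drop = FALSE]
    if (nrow(sub) < 2) next
    gaps <- sub$start[-1] - sub$end[-nrow(sub)]
    out <- c(out, as.integer(gaps[gaps > 0]))
  }
  out
}

#' Similarity of a predicted call set to a reference call set
#'
#' Treats the reference as truth, matches by center distance and returns
#' TP / (TP + FP + FN): the fraction of all involved nucleosomes (reference
#' and predicted) that are mutually explained. Equals 1 exactly when the two
#' sets pair off completely within `d`.
#'
#' @param reference Call tibble treated as truth.
#' @param predicted Call tibble being scored.
#' @param d Maximum center distance for a correct prediction, bp.
#' @return Similarity ratio in `[0, 1]`.
#' @export
call_similarity <- function(reference, predicted, d = 73) {
  if (nrow(reference) == 0 && nrow(predicted) == 0) {
    stop("similarity undefined for two empty call sets", call. = FALSE)
  }
  m <- match_nucleosomes(reference, predicted, d)
  m$tp / (m$tp + m$fp + m$fn)
}
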