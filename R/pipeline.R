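#' Simulate, call, vote and evaluate over a benchmark grid
#'
#' The end-to-end benchmark: for every synthetic dataset in a fuzzy-count x
#' coverage grid, runs the three built-in callers, the consensus vote, and
#' both evaluation layers (center-distance matching and the per-bp confusion
#' matrix) for each individual voter and for the consensus.
#'
#' @param grid A grid tibble from [simulate_nuc_grid()]; by default the full
#'   benchmark grid is simulated with `base_seed`.
#' @param base_seed Master seed used when `grid` is not supplied.
#' @param d Center-distance threshold for matching, bp.
#' @return Tibble with one row per dataset x method: `n_fuzzy`, `coverage`,
#'   `method`, `n_calls`, `tp`, `fp`, `fn`, `sensitivity`, `specificity`,
#'   `accuracy`, and a `distances` list-column of matched center distances.
#' @export
run_benchmark <- function(grid = NULL, base_seed = 1L, d = 73) {
  if (is.null(grid)) grid <- simulate_nuc_grid(base_seed = base_seed)
  purrr::pmap_dfr(grid[, c("n_fuzzy", "coverage", "data")],
                  function(n_fuzzy, coverage, data) {
    calls <- call_all_voters(data$tags, genome_len = data$genome_len)
    fit <- nuc_vote(calls)
    by_method <- c(split(calls, calls$voter), list(nucvoter = fit$consensus))
    purrr::imap_dfr(by_method, function(pred, method) {
      m <- match_nucleosomes(data$truth, pred, d)
      conf <- bp_confusion(data$truth, pred, data$genome_len)
      dplyr::bind_cols(
        tibble::tibble(n_fuzzy = n_fuzzy, coverage = coverage, method = method,
                       n_calls = nrow(pred), tp = m$tp, fp = m$fp, fn = m$fn),
        conf[, c("sensitivity", "specificity", "accuracy")],
        tibble::tibble(distances = list(m$matched_distances)))
    })
  })
}
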