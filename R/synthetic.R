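#' Parameters for the synthetic nucleosome-map simulator
#'
#' The simulator emulates a well-ordered chromatin fibre: a periodic lattice
#' of stable nucleosomes with fixed linkers, from which a fraction is removed
#' at random, plus a number of fuzzy (poorly positioned) nucleosomes dropped
#' uniformly over the chromosome. Sequencing tags are then drawn at nucleosome
#' boundaries and jittered, mimicking imprecise nuclease digestion.
#'
#' Defaults describe the benchmark conditions: 1000 stable nucleosomes of
#' 146 bp separated by 20 bp linkers (chromosome length 166 kb), 50 removed,
#' `n_fuzzy` fuzzy nucleosomes, boundary tag counts uniform on `1..coverage`,
#' stable tags jittered within +/-20 bp and fuzzy tags within +/-50 bp.
#'
#' @param n_stable Number of stable nucleosomes in the periodic lattice.
#' @param nuc_size Nucleosome size in bp.
#' @param linker Linker length between adjacent lattice nucleosomes, bp.
#' @param n_remove Number of stable nucleosomes removed at random.
#' @param n_fuzzy Number of fuzzy nucleosomes added at uniform random starts.
#' @param coverage Maximum tag count per nucleosome boundary; the realised
#'   count is uniform on `{1, ..., coverage}`, drawn independently per strand.
#' @param stable_shift,fuzzy_shift Maximum absolute tag jitter (bp) for tags
#'   of stable and fuzzy nucleosomes respectively.
#' @param seed Integer seed making the whole dataset reproducible.
#' @return A named list of parameters (class `synth_params`).
#' @export
synth_params <- function(n_stable = 1000, nuc_size = 146, linker = 20,
                         n_remove = 50, n_fuzzy = 50, coverage = 50,
                         stable_shift = 20, fuzzy_shift = 50, seed = 1L) {
  stopifnot(n_stable >= 1, nuc_size >= 1, linker >= 0,
            n_remove >= 0, n_remove <= n_stable,
            n_fuzzy >= 0, coverage >= 1,
            stable_shift >= 0, fuzzy_shift >= 0)
  structure(list(n_stable = as.integer(n_stable), nuc_size = as.integer(nuc_size),
                 linker = as.integer(linker), n_remove = as.integer(n_remove),
                 n_fuzzy = as.integer(n_fuzzy), coverage = as.integer(coverage),
                 stable_shift = as.integer(stable_shift),
                 fuzzy_shift = as.integer(fuzzy_shift), seed = as.integer(seed)),
            class = "synth_params")
}

#' Periodic lattice of stable nucleosomes
#'
#' Nucleosome `i` (0-based) occupies `[i * (nuc_size + linker),
#' i * (nuc_size + linker) + nuc_size)`, so adjacent nucleosomes are separated
#' by exactly `linker` bp and the chromosome length is
#' `n_stable * (nuc_size + linker)`.
#'
#' @inheritParams synth_params
#' @return A tibble of true nucleosomes (`chrom`, `start`, `end`, `center`,
#'   `kind = "stable"`) with attribute `genome_len`.
#' @export
lattice_nucleosomes <- function(n_stable = 1000, nuc_size = 146, linker = 20) {
  stopifnot(n_stable >= 1)
  period <- nuc_size + linker
  start <- as.integer((seq_len(n_stable) - 1L) * period)
  truth <- tibble::tibble(chrom = "chrS", start = start,
                          end = start + as.integer(nuc_size),
                          center = center_of(start, start + nuc_size),
                          kind = "stable")
  attr(truth, "genome_len") <- as.integer(n_stable * period)
  truth
}

#' Remove nucleosomes uniformly at random
#'
#' Draws `n_remove` rows without replacement from the current RNG stream and
#' drops them, preserving the order of the survivors.
#'
#' @param truth Tibble of true nucleosomes.
#' @param n_remove Number to remove; must not exceed `nrow(truth)`.
#' @export
remove_nucleosomes <- function(truth, n_remove) {
  if (n_remove > nrow(truth)) {
    stop("`n_remove` exceeds the number of nucleosomes", call. = FALSE)
  }
  if (n_remove == 0) return(truth)
  drop <- sample.int(nrow(truth), n_remove)
  out <- truth[-drop, , drop = FALSE]
  attr(out, "genome_len") <- attr(truth, "genome_len")
  out
}

#' Add fuzzy nucleosomes at uniform random positions
#'
#' Fuzzy nucleosomes model poorly positioned nucleosomes: their starts are
#' uniform on `[0, genome_len - nuc_size]` and they may overlap stable
#' nucleosomes or each other (no rejection), which is what makes them fuzzy.
#'
#' @param truth Tibble of true nucleosomes.
#' @param n_fuzzy Number of fuzzy nucleosomes to add.
#' @param genome_len Chromosome length in bp (defaults to the tibble's
#'   `genome_len` attribute).
#' @param nuc_size Fuzzy nucleosome size, bp.
#' @export
add_fuzzy_nucleosomes <- function(truth, n_fuzzy, genome_len = attr(truth, "genome_len"),
                                  nuc_size = 146) {
  if (is.null(genome_len)) stop("`genome_len` is required", call. = FALSE)
  if (genome_len < nuc_size) {
    stop("`genome_len` is shorter than one nucleosome", call. = FALSE)
  }
  if (n_fuzzy == 0) return(truth)
  start <- as.integer(sample.int(genome_len - nuc_size + 1L, n_fuzzy, replace = TRUE) - 1L)
  fuzzy <- tibble::tibble(chrom = "chrS", start = start,
                          end = start + as.integer(nuc_size),
                          center = center_of(start, start + nuc_size),
                          kind = "fuzzy")
  out <- dplyr::arrange(dplyr::bind_rows(truth, fuzzy), .data$center, .data$start)
  attr(out, "genome_len") <- as.integer(genome_len)
  out
}

#' Sample strand-specific boundary tags for a set of true nucleosomes
#'
#' For each nucleosome, `k_f ~ Uniform{1..coverage}` forward tags are placed at
#' its start and, independently, `k_r ~ Uniform{1..coverage}` reverse tags at
#' its last covered base (`end - 1`). Every tag is then shifted by an
#' independent integer drawn uniformly from `[-s, +s]`, where `s` is
#' `stable_shift` for stable and `fuzzy_shift` for fuzzy nucleosomes, and
#' clipped to `[0, genome_len - 1]`.
#'
#' @inheritParams add_fuzzy_nucleosomes
#' @inheritParams synth_params
#' @return A tag map: tibble with columns `chrom`, `pos`, `strand` (`+`/`-`)
#'   and `count`, aggregated over duplicate positions, with attribute
#'   `genome_len`.
#' @export
sample_tag_map <- function(truth, coverage, stable_shift = 20, fuzzy_shift = 50,
                           genome_len = attr(truth, "genome_len")) {
  stopifnot(coverage >= 1)
  if (is.null(genome_len)) stop("`genome_len` is required", call. = FALSE)
  n <- nrow(truth)
  k_f <- sample.int(coverage, n, replace = TRUE)
  k_r <- sample.int(coverage, n, replace = TRUE)
  s_nuc <- ifelse(truth$kind == "fuzzy", fuzzy_shift, stable_shift)

  jitter_tags <- function(anchor, k, s) {
    pos0 <- rep.int(anchor, k)
    s_tag <- rep.int(s, k)
    shift <- as.integer(floor(stats::runif(length(pos0)) * (2 * s_tag + 1)) - s_tag)
    pmin(pmax(pos0 + shift, 0L), as.integer(genome_len) - 1L)
  }
  fwd <- jitter_tags(truth$start, k_f, s_nuc)
  rev <- jitter_tags(truth$end - 1L, k_r, s_nuc)

  tags <- dplyr::bind_rows(
    tibble::tibble(chrom = "chrS", pos = fwd, strand = "+"),
    tibble::tibble(chrom = "chrS", pos = rev, strand = "-")
  )
  tags <- dplyr::count(tags, .data$chrom, .data$pos, .data$strand, name = "count")
  tags <- dplyr::arrange(tags, .data$chrom, .data$pos, .data$strand)
  attr(tags, "genome_len") <- as.integer(genome_len)
  attr(tags, "n_tags") <- sum(k_f) + sum(k_r)
  tags
}

#' Generate one synthetic nucleosome dataset
#'
#' Composes the full simulation: stable lattice, random removal, fuzzy
#' addition, boundary tag sampling. Fully deterministic given `params$seed`
#' (the global RNG state is left untouched).
#'
#' @param params A [synth_params()] list.
#' @return A list of class `nuc_synth` with elements `params`, `truth`
#'   (tibble of true nucleosomes), `tags` (tag map tibble) and `genome_len`.
#' @examples
#' d <- simulate_nuc_map(synth_params(n_fuzzy = 50, coverage = 50, seed = 7))
#' nrow(d$truth)  # 1000 = 1000 - 50 + 50
#' @export
simulate_nuc_map <- function(params = synth_params()) {
  withr::with_seed(params$seed, {
    truth <- lattice_nucleosomes(params$n_stable, params$nuc_size, params$linker)
    genome_len <- attr(truth, "genome_len")
    truth <- remove_nucleosomes(truth, params$n_remove)
    truth <- add_fuzzy_nucleosomes(truth, params$n_fuzzy, genome_len, params$nuc_size)
    tags <- sample_tag_map(truth, params$coverage, params$stable_shift,
                           params$fuzzy_shift, genome_len)
    structure(list(params = params, truth = truth, tags = tags,
                   genome_len = genome_len),
              class = "nuc_synth")
  })
}

#' @export
print.nuc_synth <- function(x, ...) {
  cat(sprintf("<nuc_synth> %d true nucleosomes (%d fuzzy), %d bp chromosome, %d tags\n",
              nrow(x$truth), sum(x$truth$kind == "fuzzy"), x$genome_len,
              attr(x$tags, "n_tags")))
  invisible(x)
}

#' Generate the fuzzy-count x coverage benchmark grid
#'
#' Crosses fuzzy-nucleosome counts with maximum coverages and simulates one
#' dataset per combination; per-dataset seeds are `base_seed + dataset index`
#' so the whole grid is reproducible from one integer. With the default grids
#' (fuzzy 50..500 step 50, coverage 50..200 step 50) this yields 40 datasets
#' holding 49,000 true nucleosomes in total.
#'
#' @param n_fuzzy_grid,coverage_grid Integer vectors crossed to form the grid.
#' @param base_seed Master seed.
#' @param ... Further arguments passed to [synth_params()] (e.g. `n_stable`).
#' @return A tibble with one row per dataset: `n_fuzzy`, `coverage`, `seed`
#'   and a `data` list-column of `nuc_synth` objects.
#' @export
simulate_nuc_grid <- function(n_fuzzy_grid = seq(50L, 500L, by = 50L),
                              coverage_grid = seq(50L, 200L, by = 50L),
                              base_seed = 1L, ...) {
  grid <- tidyr::expand_grid(n_fuzzy = as.integer(n_fuzzy_grid),
                             coverage = as.integer(coverage_grid))
  grid$seed <- as.integer(base_seed) + seq_len(nrow(grid))
  grid$data <- purrr::pmap(grid, function(n_fuzzy, coverage, seed) {
    simulate_nuc_map(synth_params(n_fuzzy = n_fuzzy, coverage = coverage,
                                  seed = seed, ...))
  })
  grid
}
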