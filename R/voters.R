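# Shared profile machinery for the built-in callers. All profiles are dense
# numeric vectors over a single chromosome; positions are 0-based, so profile
# element i corresponds to genomic position i - 1.

tag_genome_len <- function(tags, genome_len) {
  if (!is.null(genome_len)) return(as.integer(genome_len))
  gl <- attr(tags, "genome_len")
  if (!is.null(gl)) return(as.integer(gl))
  if (nrow(tags) == 0) return(0L)
  as.integer(max(tags$pos) + 1L)
}

# Accumulate counts at (possibly shifted) positions into a dense vector,
# clipping to [0, genome_len).
accumulate_profile <- function(pos, count, genome_len) {
  prof <- numeric(genome_len)
  if (length(pos) == 0) return(prof)
  pos <- pmin(pmax(pos, 0L), genome_len - 1L)
  agg <- rowsum(count, pos)
  prof[as.integer(rownames(agg)) + 1L] <- agg[, 1L]
  prof
}

# Convolve a profile with a normalised kernel, zero-padding the edges so the
# output has the same length as the input.
smooth_profile <- function(x, kernel) {
  h <- (length(kernel) - 1L) %/% 2L
  xp <- c(numeric(h), x, numeric(h))
  y <- stats::filter(xp, kernel, sides = 2)
  as.numeric(y[(h + 1L):(h + length(x))])
}

gaussian_kernel <- function(sigma) {
  h <- max(1L, ceiling(4 * sigma))
  k <- stats::dnorm(seq(-h, h), sd = sigma)
  k / sum(k)
}

triangular_kernel <- function(half_width) {
  k <- pmax(0, 1 - abs(seq(-half_width, half_width)) / (half_width + 1))
  k / sum(k)
}

# Local maxima of a profile: strictly above the left neighbour and at least
# the right neighbour, so the leftmost position of a plateau wins.
local_maxima <- function(y) {
  n <- length(y)
  if (n < 2) return(integer(0))
  left <- c(-Inf, y[-n])
  right <- c(y[-1], -Inf)
  which(y > left & y >= right)
}

# Greedy highest-peak-first selection with a fixed suppression radius:
# a candidate is accepted unless it lies within `radius` bp of an already
# accepted center. Ties in height resolve leftmost-first.
select_peaks <- function(y, min_height, radius) {
  cand <- local_maxima(y)
  cand <- cand[y[cand] >= min_height]
  if (length(cand) == 0) return(integer(0))
  cand <- cand[order(-y[cand], cand)]
  n <- length(y)
  blocked <- logical(n)
  accepted <- integer(0)
  for (i in cand) {
    if (!blocked[i]) {
      accepted <- c(accepted, i)
      lo <- max(1L, i - radius)
      hi <- min(n, i + radius)
      blocked[lo:hi] <- TRUE
    }
  }
  sort(accepted) - 1L  # back to 0-based positions
}

fixed_size_calls <- function(centers, heights, nuc_size, genome_len, voter) {
  half <- nuc_size %/% 2L
  start <- pmax(0L, as.integer(centers) - half)
  end <- pmin(as.integer(genome_len), start + as.integer(nuc_size))
  as_nuc_calls(tibble::tibble(chrom = "chrS", start = start, end = end,
                              occupancy = heights, voter = voter))
}

empty_calls <- function(voter) {
  as_nuc_calls(tibble::tibble(chrom = character(0), start = integer(0),
                              end = integer(0), occupancy = numeric(0),
                              voter = character(0)))
}

#' Gaussian-smoothing peak caller
#'
#' Shifts forward tags downstream and reverse tags upstream by half the
#' nucleosome size, sums both strands into a composite profile, smooths it
#' with a Gaussian kernel and places fixed-size nucleosomes at the smoothed
#' local maxima, highest peak first, suppressing further maxima within one
#' nucleosome size of an accepted center.
#'
#' @param tags Tag map tibble (`chrom`, `pos`, `strand`, `count`).
#' @param nuc_size Nucleosome size, bp; calls span
#'   `[center - nuc_size/2, center + nuc_size/2)`.
#' @param sigma Gaussian kernel standard deviation, bp.
#' @param min_height Minimum smoothed height for a local maximum to become a
#'   call.
#' @param genome_len Chromosome length; defaults to the tag map's attribute.
#' @return A call tibble with `voter = "gaussian"`; `occupancy` is the
#'   smoothed profile height at the call center.
#' @export
call_gaussian <- function(tags, nuc_size = 146, sigma = 20, min_height = 0.1,
                          genome_len = NULL) {
  genome_len <- tag_genome_len(tags, genome_len)
  if (nrow(tags) == 0 || genome_len == 0) return(empty_calls("gaussian"))
  half <- nuc_size %/% 2L
  shifted <- ifelse(tags$strand == "+", tags$pos + half, tags$pos - half)
  prof <- accumulate_profile(shifted, tags$count, genome_len)
  sm <- smooth_profile(prof, gaussian_kernel(sigma))
  centers <- select_peaks(sm, min_height, as.integer(nuc_size))
  if (length(centers) == 0) return(empty_calls("gaussian"))
  fixed_size_calls(centers, sm[centers + 1L], nuc_size, genome_len, "gaussian")
}

#' Triangular center-density caller
#'
#' Each forward tag contributes a triangular kernel peaking half a nucleosome
#' downstream of the tag; each reverse tag, half a nucleosome upstream. Local
#' maxima of the summed center density with mass at least `min_mass` become
#' fixed-size calls, with the same greedy suppression as [call_gaussian()].
#'
#' @inheritParams call_gaussian
#' @param half_width Half-width of the triangular kernel, bp.
#' @param min_mass Minimum density at a local maximum for it to become a call.
#' @return A call tibble with `voter = "density"`; `occupancy` is the density
#'   at the call center.
#' @export
call_center_density <- function(tags, nuc_size = 146, half_width = 20,
                                min_mass = 0.1, genome_len = NULL) {
  genome_len <- tag_genome_len(tags, genome_len)
  if (nrow(tags) == 0 || genome_len == 0) return(empty_calls("density"))
  half <- nuc_size %/% 2L
  shifted <- ifelse(tags$strand == "+", tags$pos + half, tags$pos - half)
  impulses <- accumulate_profile(shifted, tags$count, genome_len)
  dens <- smooth_profile(impulses, triangular_kernel(half_width))
  centers <- select_peaks(dens, min_mass, as.integer(nuc_size))
  if (length(centers) == 0) return(empty_calls("density"))
  fixed_size_calls(centers, dens[centers + 1L], nuc_size, genome_len, "density")
}

# Running Pearson correlation of a symmetric template against a profile,
# evaluated at every position (template centered). Positions where the window
# is constant get NA.
running_template_corr <- function(x, template) {
  L <- length(template)
  ones <- rep(1 / L, L)
  mx <- smooth_profile(x, ones)
  mxx <- smooth_profile(x^2, ones)
  vx <- pmax(mxx - mx^2, 0)
  sxy <- smooth_profile(x, template / L)  # (1/L) * sum t_j x_{i+j}
  mt <- mean(template)
  vt <- mean(template^2) - mt^2
  denom <- sqrt(vx * vt)
  corr <- (sxy - mt * mx) / denom
  corr[denom < 1e-12] <- NA_real_
  corr
}

#' Template boundary caller
#'
#' Slides a normal-shaped template along the forward and the reverse tag
#' profile separately; positions where the windowed Pearson correlation with
#' the template is a local maximum of at least `min_corr` are boundary
#' candidates (forward profile: left boundaries; reverse profile: right
#' boundaries). Each left boundary is paired with the nearest unused right
#' boundary that yields a nucleosome size within `size_range`, so calls have
#' variable size; unpaired boundaries are discarded. Overlapping calls are
#' pruned greedily by occupancy so that no retained call overlaps another by
#' more than half the shorter call's length.
#'
#' @inheritParams call_gaussian
#' @param template_sd Standard deviation of the normal-shaped template, bp.
#' @param min_corr Minimum template correlation for a boundary candidate.
#' @param size_range Length-2 numeric: admissible nucleosome sizes, bp
#'   (inclusive).
#' @return A call tibble with `voter = "template"`; `occupancy` is the mean of
#'   the raw profile heights at the two boundaries.
#' @export
call_template <- function(tags, template_sd = 20, min_corr = 0.2,
                          size_range = c(100, 200), genome_len = NULL) {
  genome_len <- tag_genome_len(tags, genome_len)
  if (nrow(tags) == 0 || genome_len == 0) return(empty_calls("template"))
  fwd <- tags[tags$strand == "+", , drop = FALSE]
  rev <- tags[tags$strand == "-", , drop = FALSE]
  prof_f <- accumulate_profile(fwd$pos, fwd$count, genome_len)
  prof_r <- accumulate_profile(rev$pos, rev$count, genome_len)
  template <- stats::dnorm(seq(-3 * template_sd, 3 * template_sd), sd = template_sd)

  boundary_candidates <- function(prof) {
    corr <- running_template_corr(prof, template)
    corr[is.na(corr)] <- -Inf
    cand <- local_maxima(corr)
    sort(cand[corr[cand] >= min_corr]) - 1L
  }
  lb <- boundary_candidates(prof_f)
  rb <- boundary_candidates(prof_r)
  if (length(lb) == 0 || length(rb) == 0) return(empty_calls("template"))

  # pair each left boundary with the nearest unused right boundary giving an
  # admissible size (size = rb - lb + 1, both boundaries covered)
  used_r <- logical(length(rb))
  starts <- integer(0); ends <- integer(0); occ <- numeric(0)
  for (l in lb) {
    size <- rb - l + 1L
    ok <- which(!used_r & size >= size_range[1] & size <= size_range[2])
    if (length(ok) == 0) next
    j <- ok[which.min(rb[ok] - l)]
    used_r[j] <- TRUE
    starts <- c(starts, l)
    ends <- c(ends, rb[j] + 1L)
    occ <- c(occ, (prof_f[l + 1L] + prof_r[rb[j] + 1L]) / 2)
  }
  if (length(starts) == 0) return(empty_calls("template"))

  # greedy overlap pruning: keep higher-occupancy calls, drop any call that
  # overlaps a kept call by more than half the shorter call's length
  ord <- order(-occ, starts)
  keep <- logical(length(starts))
  for (i in ord) {
    ov <- pmin(ends[keep], ends[i]) - pmax(starts[keep], starts[i])
    lim <- pmin(ends[keep] - starts[keep], ends[i] - starts[i]) / 2
    if (all(ov <= lim)) keep[i] <- TRUE
  }
  as_nuc_calls(tibble::tibble(chrom = "chrS", start = starts[keep],
                              end = ends[keep], occupancy = occ[keep],
                              voter = "template"))
}

#' Run all three built-in callers on one tag map
#'
#' @inheritParams call_gaussian
#' @param ... Passed on to the individual callers is not supported; use the
#'   individual functions to change caller parameters.
#' @return One call tibble binding the three voters' calls.
#' @export
call_all_voters <- function(tags, nuc_size = 146, genome_len = NULL) {
  dplyr::bind_rows(
    call_gaussian(tags, nuc_size = nuc_size, genome_len = genome_len),
    call_center_density(tags, nuc_size = nuc_size, genome_len = genome_len),
    call_template(tags, genome_len = genome_len)
  )
}
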