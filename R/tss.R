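#' Signed distances of call centers from transcription start sites
#'
#' For each gene, call centers on its chromosome within `window` bp of the
#' TSS are reported as signed distances, mirrored for minus-strand genes so
#' that positive distances always point downstream (into the gene body).
#'
#' @param calls Call tibble.
#' @param tss Tibble with columns `gene_id`, `chrom`, `tss`, `strand`
#'   (`+`/`-`).
#' @param window Half-width of the window around each TSS, bp.
#' @return Tibble `gene_id`, `distance`, plus the matched call's columns
#'   (`center`, `occupancy`, `occupancy_norm` when present, `voter`).
#' @export
align_to_tss <- function(calls, tss, window = 1000) {
  stopifnot(window > 0)
  required <- c("gene_id", "chrom", "tss", "strand")
  if (!all(required %in% names(tss))) {
    stop("tss table needs columns: ", paste(required, collapse = ", "),
         call. = FALSE)
  }
  calls <- as_nuc_calls(calls)
  unknown <- setdiff(unique(tss$chrom), unique(calls$chrom))
  if (length(unknown) > 0) {
    stop("tss table references unknown chromosome(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  keep <- intersect(c("chrom", "center", "occupancy", "occupancy_norm", "voter"),
                    names(calls))
  joined <- dplyr::inner_join(tss, calls[, keep], by = "chrom",
                              relationship = "many-to-many")
  joined <- dplyr::mutate(joined,
    distance = ifelse(.data$strand == "-",
                      .data$tss - .data$center,
                      .data$center - .data$tss))
  joined <- dplyr::filter(joined, abs(.data$distance) <= window)
  dplyr::select(joined, "gene_id", "distance",
                dplyr::any_of(c("center", "occupancy", "occupancy_norm", "voter")))
}

#' TSS-aligned frequency or occupancy profile
#'
#' Bins TSS-aligned call distances and reports, per bin, either the average
#' nucleosome frequency (calls per gene) or the mean occupancy, optionally
#' lowess-smoothed.
#'
#' @param aligned Output of [align_to_tss()].
#' @param bin Bin width, bp.
#' @param value `"frequency"` (calls per gene per bin) or `"occupancy"`
#'   (mean occupancy per bin; requires an occupancy column).
#' @param smooth `"none"` or `"lowess"`.
#' @param n_genes Number of genes the profile averages over; defaults to the
#'   number of distinct genes present in `aligned`. Pass the full gene count
#'   when some genes contributed no calls.
#' @param occupancy_column Which occupancy column feeds the occupancy
#'   profile.
#' @return Tibble `distance` (bin midpoint) and `value`.
#' @export
tss_profile <- function(aligned, bin = 10, value = c("frequency", "occupancy"),
                        smooth = c("none", "lowess"), n_genes = NULL,
                        occupancy_column = "occupancy") {
  value <- match.arg(value)
  smooth <- match.arg(smooth)
  if (nrow(aligned) == 0) stop("no aligned calls", call. = FALSE)
  if (is.null(n_genes)) n_genes <- dplyr::n_distinct(aligned$gene_id)
  mid <- floor(aligned$distance / bin) * bin + bin / 2
  df <- tibble::tibble(distance = mid,
                       occ = if (value == "occupancy") aligned[[occupancy_column]]
                             else NA_real_)
  prof <- dplyr::summarise(dplyr::group_by(df, .data$distance),
                           value = if (value == "frequency")
                             dplyr::n() / n_genes else mean(.data$occ),
                           .groups = "drop")
  prof <- dplyr::arrange(prof, .data$distance)
  if (smooth == "lowess") {
    sm <- stats::lowess(prof$distance, prof$value)
    prof$value <- sm$y
  }
  prof
}

#' Detect the nucleosome-free region around a TSS
#'
#' The NFR of a gene is the longest linker (gap between consecutive calls)
#' that intersects the promoter search window, by default from 250 bp
#' upstream to 50 bp downstream of the TSS (mirrored for minus-strand genes).
#' Only calls within `search_span` bp of the TSS take part; a finite linker
#' between two such calls counts with its full length even where it extends
#' beyond the window, while the unbounded stretches before the first and
#' after the last nearby call are clipped to the window — in particular, a
#' promoter with no calls within `search_span` reports the whole window as
#' its NFR. A fully covered window yields a zero-length NFR.
#'
#' @param calls Call tibble.
#' @param tss TSS tibble (`gene_id`, `chrom`, `tss`, `strand`).
#' @param upstream,downstream Window extent upstream/downstream of the TSS,
#'   bp.
#' @param search_span Calls whose interval lies entirely farther than this
#'   from the TSS are ignored, bp.
#' @param clip_to_window If `TRUE`, also clip finite linkers to the search
#'   window (alternative semantics; default counts their full length).
#' @return Tibble `gene_id`, `nfr_start`, `nfr_end`, `length`.
#' @export
detect_nfr <- function(calls, tss, upstream = 250, downstream = 50,
                       search_span = 1000, clip_to_window = FALSE) {
  calls <- as_nuc_calls(calls)
  purrr::pmap_dfr(tss[, c("gene_id", "chrom", "tss", "strand")],
                  function(gene_id, chrom, tss, strand) {
    win <- if (strand == "-") c(tss - downstream, tss + upstream)
           else c(tss - upstream, tss + downstream)  # half-open [lo, hi)
    sub <- calls[calls$chrom == chrom &
                   calls$end > tss - search_span &
                   calls$start < tss + search_span, , drop = FALSE]
    sub <- sub[order(sub$start, sub$end), , drop = FALSE]
    if (nrow(sub) == 0) {
      gap_s <- -Inf; gap_e <- Inf
    } else {
      gap_s <- c(-Inf, sub$end)
      gap_e <- c(sub$start, Inf)
    }
    len0 <- gap_e - gap_s
    ok <- len0 > 0 & gap_s < win[2] & gap_e > win[1]
    gap_s <- gap_s[ok]; gap_e <- gap_e[ok]
    if (length(gap_s) == 0) {
      return(tibble::tibble(gene_id = gene_id, nfr_start = tss, nfr_end = tss,
                            length = 0))
    }
    gs <- if (clip_to_window) pmax(gap_s, win[1]) else ifelse(is.finite(gap_s), gap_s, win[1])
    ge <- if (clip_to_window) pmin(gap_e, win[2]) else ifelse(is.finite(gap_e), gap_e, win[2])
    lens <- ge - gs
    best <- order(-lens, gs)[1]
    tibble::tibble(gene_id = gene_id, nfr_start = gs[best], nfr_end = ge[best],
                   length = lens[best])
  })
}

#' Genes whose NFR shrank between two conditions
#'
#' @param nfr_a,nfr_b [detect_nfr()] outputs for conditions A and B over the
#'   same genes.
#' @param min_delta Minimum shrinkage `length_a - length_b` for a gene to be
#'   reported, bp.
#' @return Tibble `gene_id`, `length_a`, `length_b`, `delta` for genes with
#'   `delta >= min_delta`.
#' @export
nfr_shrunk_genes <- function(nfr_a, nfr_b, min_delta = 150) {
  if (!setequal(nfr_a$gene_id, nfr_b$gene_id)) {
    stop("the two conditions cover different gene sets", call. = FALSE)
  }
  joined <- dplyr::inner_join(
    dplyr::select(nfr_a, "gene_id", length_a = "length"),
    dplyr::select(nfr_b, "gene_id", length_b = "length"),
    by = "gene_id")
  joined <- dplyr::mutate(joined, delta = .data$length_a - .data$length_b)
  dplyr::filter(joined, .data$delta >= min_delta)
}
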