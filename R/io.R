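#' Read and write nucleosome call sets as BED-like files
#'
#' Calls are stored as 5-column tab-delimited BED: `chrom`, `start`, `end`,
#' `name` (the voter id) and `score`. The score column carries occupancy as a
#' floating-point value (a deliberate deviation from the 0-1000 integer BED
#' convention), written with full precision so a write/read round trip
#' reproduces the call set.
#'
#' @param path File path.
#' @param calls Call tibble.
#' @param score Which column to write into the BED score field.
#' @return `read_nuc_calls()` returns a call tibble (score read into
#'   `occupancy`); `write_nuc_calls()` returns `path` invisibly.
#' @export
read_nuc_calls <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          colClasses = c("character", "character", "character",
                                         "character", "character"),
                          col.names = c("chrom", "start", "end", "voter", "score"),
                          blank.lines.skip = FALSE)
  start <- suppressWarnings(as.integer(df$start))
  end <- suppressWarnings(as.integer(df$end))
  score <- suppressWarnings(as.numeric(df$score))
  bad <- which(is.na(start) | is.na(end) | is.na(score) | end <= start)
  if (length(bad) > 0) {
    stop("malformed call row(s) at line(s): ",
         paste(utils::head(bad, 10), collapse = ", "), call. = FALSE)
  }
  as_nuc_calls(tibble::tibble(chrom = df$chrom, start = start, end = end,
                              occupancy = score, voter = df$voter))
}

#' @rdname read_nuc_calls
#' @export
write_nuc_calls <- function(calls, path, score = c("occupancy", "occupancy_norm")) {
  score <- match.arg(score)
  calls <- as_nuc_calls(calls)
  if (!score %in% names(calls)) {
    stop("column `", score, "` not present in calls", call. = FALSE)
  }
  out <- data.frame(chrom = calls$chrom, start = calls$start, end = calls$end,
                    name = calls$voter,
                    score = format(calls[[score]], digits = 15, trim = TRUE,
                                   scientific = FALSE))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read and write tag maps
#'
#' Tag maps are 4-column tab-delimited files: `chrom`, `pos` (0-based),
#' `strand` (`+` or `-`) and `count`. Duplicate rows for the same position
#' and strand are summed on read.
#'
#' @param path File path.
#' @param tags Tag map tibble.
#' @param genome_len Optional chromosome length attached to the returned tag
#'   map.
#' @return `read_tag_map()` returns a tag map tibble; `write_tag_map()`
#'   returns `path` invisibly.
#' @export
read_tag_map <- function(path, genome_len = NULL) {
  if (file.size(path) == 0) {
    out <- tibble::tibble(chrom = character(0), pos = integer(0),
                          strand = character(0), count = integer(0))
    attr(out, "genome_len") <- genome_len
    return(out)
  }
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("chrom", "pos", "strand", "count"),
                          colClasses = c("character", "integer", "character",
                                         "integer"))
  bad <- which(!df$strand %in% c("+", "-"))
  if (length(bad) > 0) {
    stop("unknown strand symbol at line(s): ",
         paste(utils::head(bad, 10), collapse = ", "), call. = FALSE)
  }
  out <- dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(df), .data$chrom, .data$pos, .data$strand),
    count = sum(.data$count), .groups = "drop")
  out <- dplyr::arrange(out, .data$chrom, .data$pos, .data$strand)
  if (!is.null(genome_len)) attr(out, "genome_len") <- as.integer(genome_len)
  out
}

#' @rdname read_tag_map
#' @export
write_tag_map <- function(tags, path) {
  utils::write.table(as.data.frame(tags[, c("chrom", "pos", "strand", "count")]),
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a TSS annotation table
#'
#' Expects 4 tab-delimited columns: `gene_id`, `chrom`, `tss` (bp), `strand`.
#'
#' @param path File path.
#' @return Tibble `gene_id`, `chrom`, `tss`, `strand`.
#' @export
read_tss_table <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("gene_id", "chrom", "tss", "strand"),
                          colClasses = c("character", "character", "integer",
                                         "character"))
  bad <- which(!df$strand %in% c("+", "-"))
  if (length(bad) > 0) {
    stop("unknown strand symbol at line(s): ",
         paste(utils::head(bad, 10), collapse = ", "), call. = FALSE)
  }
  tibble::as_tibble(df)
}
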