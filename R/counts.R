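# Read counting over promoter / background intervals and count-matrix I/O.

#' Count reads over an interval set
#'
#' A read is assigned to the interval containing its strand-aware 5' position
#' (`start` for + reads, `end - 1` for - reads, 0-based), so a read counts at
#' most once per annotation set even where 100-bp windows tile contiguously.
#' Reads on chromosomes absent from the interval set are skipped and tallied.
#'
#' @param reads BED-style tibble of mapped reads (`chrom`, `start`, `end`,
#'   optionally `name`, `score`, `strand`); missing strand is treated as `+`.
#' @param intervals Interval tibble with an id column (`promoter_id` or
#'   `window_id`), `chrom`, `start`, `end`; intervals must not overlap within
#'   the set.
#' @return A tibble with the interval id column and a `count` column (one row
#'   per interval, zero-filled). The number of skipped reads is attached as
#'   attribute `skipped`.
#' @export
count_reads <- function(reads, intervals) {
  id_col <- names(intervals)[1L]
  fp <- five_prime(reads)
  counts <- setNames(integer(nrow(intervals)), intervals[[id_col]])
  skipped <- 0L
  for (ch in unique(intervals$chrom)) {
    ii <- which(intervals$chrom == ch)
    ir <- IRanges::IRanges(start = intervals$start[ii] + 1L,
                           end = intervals$end[ii])
    ri <- which(reads$chrom == ch)
    if (length(ri) == 0L) next
    hits <- IRanges::findOverlaps(
      IRanges::IRanges(start = fp[ri] + 1L, width = 1L), ir
    )
    tab <- tabulate(S4Vectors::subjectHits(hits), nbins = length(ii))
    counts[ii] <- counts[ii] + tab
  }
  n_unknown <- sum(!reads$chrom %in% unique(intervals$chrom))
  if (n_unknown > 0L) {
    inform(sprintf("%d read(s) on chromosomes absent from the interval set were skipped",
                   n_unknown))
  }
  out <- tibble::tibble(!!id_col := intervals[[id_col]], count = unname(counts))
  attr(out, "skipped") <- n_unknown + skipped
  out
}

five_prime <- function(reads) {
  strand <- if ("strand" %in% names(reads)) reads$strand else "+"
  ifelse(strand == "-", reads$end - 1L, reads$start)
}

#' Assemble a count matrix from several samples
#'
#' @param read_sets Named list of read tibbles (or paths to BED files), one
#'   per sample.
#' @param intervals Interval tibble as in [count_reads()].
#' @return A count table: interval id column, then one column per sample.
#' @export
build_count_matrix <- function(read_sets, intervals) {
  if (is.null(names(read_sets)) || any(!nzchar(names(read_sets)))) {
    abort("`read_sets` must be a named list (sample ids)")
  }
  cols <- purrr::map(read_sets, function(r) {
    if (is.character(r)) r <- read_bed(r)
    count_reads(r, intervals)$count
  })
  dplyr::bind_cols(intervals[, 1L], tibble::as_tibble(cols))
}

#' Sum window counts into per-promoter background counts
#'
#' For every promoter in the background annotation, the background count in a
#' sample is the sum of that sample's counts over the promoter's finalized
#' windows. Promoters flagged as having no background windows are absent from
#' the annotation and hence from the output.
#'
#' @param window_counts Count table over windows (`window_id` + samples).
#' @param annotation A `background_annotation` ([finalize_background()]).
#' @return A count table: `promoter_id`, then one column per sample.
#' @export
background_counts_per_promoter <- function(window_counts, annotation) {
  m <- as_count_matrix(window_counts, "window counts")
  miss <- setdiff(annotation$window_id, rownames(m))
  if (length(miss) > 0L) {
    abort(paste0("annotated window(s) missing from window counts: ",
                 paste(head(miss, 5L), collapse = ", ")))
  }
  sub <- m[annotation$window_id, , drop = FALSE]
  agg <- rowsum(sub, group = annotation$promoter_id)
  agg <- agg[unique(annotation$promoter_id), , drop = FALSE]
  matrix_to_tbl(agg, id_col = "promoter_id")
}

#' Median-of-ratios size factors
#'
#' For each sample, the median across features of the ratio of its counts to
#' the geometric-mean pseudo-reference, computed over features with all-
#' positive counts. When no such feature exists, total-count scaling
#' (normalized to geometric mean 1) is used with a warning. The same factors
#' should be applied to the promoter and background tables of a sample.
#'
#' @param counts A count table (id column + sample columns).
#' @return Named numeric vector of positive size factors, one per sample.
#' @export
size_factors <- function(counts) {
  m <- as_count_matrix(counts, "count table")
  pos <- rowSums(m > 0) == ncol(m)
  if (!any(pos)) {
    warn("no feature with all-positive counts; falling back to total-count scaling")
    tot <- colSums(m)
    if (any(tot <= 0)) abort("cannot normalize: a sample has zero total counts")
    sf <- tot / exp(mean(log(tot)))
    return(setNames(sf, colnames(m)))
  }
  lm <- log(m[pos, , drop = FALSE])
  ref <- rowMeans(lm)
  sf <- apply(lm, 2L, function(col) exp(median(col - ref)))
  setNames(sf, colnames(m))
}

#' Write / read count tables as TSV
#'
#' @param counts A count table.
#' @param path File path.
#' @return `read_count_table()` returns a tibble (first column character id,
#'   remaining columns numeric).
#' @export
write_count_table <- function(counts, path) {
  readr::write_tsv(counts, path)
  invisible(path)
}

#' @rdname write_count_table
#' @export
read_count_table <- function(path) {
  tb <- readr::read_tsv(path, progress = FALSE, show_col_types = FALSE)
  tb[[1L]] <- as.character(tb[[1L]])
  tb
}
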