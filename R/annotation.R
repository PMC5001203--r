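# Promoter and background-window annotation.
#
# Coordinates are 0-based half-open throughout ([start, end)), the native BED
# convention; refFlat txStart is already 0-based.

#' Bundle genome layout inputs
#'
#' @param chrom_sizes A data frame with columns `chrom`, `length` (bp), or the
#'   path to a two-column `chrom.sizes` file.
#' @param gaps,cpg_islands Optional BED3 data frames (`chrom`, `start`, `end`)
#'   or paths to BED files: assembly gaps (ambiguous bases) and predicted CpG
#'   islands.
#' @param sequences Optional `Biostrings::DNAStringSet` (or path to a FASTA
#'   file) named by chromosome, used to compute per-window GC content and to
#'   detect ambiguous bases.
#' @return A `genome_layout` list.
#' @export
genome_layout <- function(chrom_sizes, gaps = NULL, cpg_islands = NULL,
                          sequences = NULL) {
  if (is.character(chrom_sizes)) {
    chrom_sizes <- readr::read_tsv(chrom_sizes, col_names = c("chrom", "length"),
                                   col_types = "ci", progress = FALSE)
  }
  stopifnot(all(c("chrom", "length") %in% names(chrom_sizes)))
  if (any(chrom_sizes$length < 0)) abort("negative chromosome length")
  if (is.character(sequences)) sequences <- Biostrings::readDNAStringSet(sequences)
  bed_or_null <- function(x) {
    if (is.null(x)) return(NULL)
    if (is.character(x)) x <- read_bed(x)
    check_intervals(x, chrom_sizes)
    x
  }
  structure(
    list(chrom_sizes = tibble::as_tibble(chrom_sizes[, c("chrom", "length")]),
         gaps = bed_or_null(gaps),
         cpg_islands = bed_or_null(cpg_islands),
         sequences = sequences),
    class = "genome_layout"
  )
}

check_intervals <- function(x, chrom_sizes) {
  stopifnot(all(c("chrom", "start", "end") %in% names(x)))
  if (any(x$start < 0) || any(x$end < x$start)) abort("malformed intervals")
  len <- setNames(chrom_sizes$length, chrom_sizes$chrom)
  known <- x$chrom %in% names(len)
  if (any(x$end[known] > len[x$chrom[known]])) abort("interval beyond chromosome end")
  invisible(TRUE)
}

#' Read a BED3+ file
#'
#' @param path Path to a tab-separated BED file (>= 3 columns, no header).
#' @return A tibble with columns `chrom`, `start`, `end` and, when present,
#'   `name`, `score`, `strand`.
#' @export
read_bed <- function(path) {
  tb <- readr::read_tsv(path, col_names = FALSE, progress = FALSE,
                        col_types = readr::cols(.default = readr::col_character()),
                        comment = "#")
  if (ncol(tb) < 3L) abort("BED file needs at least 3 columns")
  nm <- c("chrom", "start", "end", "name", "score", "strand")
  names(tb)[seq_len(min(ncol(tb), 6L))] <- nm[seq_len(min(ncol(tb), 6L))]
  tb$start <- as.integer(tb$start)
  tb$end <- as.integer(tb$end)
  tibble::as_tibble(tb)
}

#' Load promoters from a refFlat annotation
#'
#' Promoters are TSS +/- 2 kb. The TSS is `txStart` for + strand transcripts
#' and `txEnd - 1` for - strand transcripts (0-based). Transcripts sharing a
#' TSS are collapsed to a single promoter record.
#'
#' @param path Path to an 11-column UCSC refFlat file (geneName, name, chrom,
#'   strand, txStart, txEnd, cdsStart, cdsEnd, exonCount, exonStarts,
#'   exonEnds), tab-separated, no header.
#' @param flank Half-width of the promoter window in bp (default 2000).
#' @param chrom_sizes Optional chromosome sizes (data frame `chrom`, `length`);
#'   when given, promoter intervals are clipped to chromosome bounds and
#'   flagged.
#' @return A tibble with columns `promoter_id`, `gene`, `chrom`, `strand`,
#'   `tss`, `start`, `end`, `clipped`.
#' @export
load_refflat <- function(path, flank = 2000L, chrom_sizes = NULL) {
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ok <- vapply(parts, function(p) {
    length(p) >= 6L && p[4] %in% c("+", "-") &&
      !is.na(suppressWarnings(as.integer(p[5]))) &&
      !is.na(suppressWarnings(as.integer(p[6])))
  }, logical(1))
  if (any(!ok)) {
    warn(paste0("skipping malformed refFlat row(s): ",
                paste(which(!ok), collapse = ", ")))
  }
  parts <- parts[ok]
  if (length(parts) == 0L) abort("no usable rows in refFlat file")
  tb <- tibble::tibble(
    gene = vapply(parts, `[[`, character(1), 1L),
    chrom = vapply(parts, `[[`, character(1), 3L),
    strand = vapply(parts, `[[`, character(1), 4L),
    tx_start = as.integer(vapply(parts, `[[`, character(1), 5L)),
    tx_end = as.integer(vapply(parts, `[[`, character(1), 6L))
  )
  tb$tss <- ifelse(tb$strand == "+", tb$tx_start, tb$tx_end - 1L)
  tb <- dplyr::distinct(tb, .data$chrom, .data$tss, .keep_all = TRUE)
  out <- tb |>
    dplyr::mutate(
      start = pmax(.data$tss - as.integer(flank), 0L),
      end = .data$tss + as.integer(flank),
      promoter_id = make.unique(.data$gene, sep = "_")
    )
  out$clipped <- out$start == 0L & out$tss - flank < 0L
  if (!is.null(chrom_sizes)) {
    len <- setNames(chrom_sizes$length, chrom_sizes$chrom)
    cap <- len[out$chrom]
    over <- !is.na(cap) & out$end > cap
    out$clipped <- out$clipped | over
    out$end[over] <- as.integer(cap[over])
  }
  inform(sprintf("loaded %d promoters from %d refFlat rows", nrow(out), length(ok)))
  dplyr::select(out, "promoter_id", "gene", "chrom", "strand", "tss",
                "start", "end", "clipped")
}

#' Tile the genome into 100-bp windows
#'
#' Non-overlapping windows from position 0 on every chromosome; a trailing
#' partial window is dropped. When the layout carries sequences, per-window GC
#' fraction and ambiguous-base flags are computed from them.
#'
#' @param layout A [genome_layout()].
#' @param width Window width in bp (default 100).
#' @return A tibble with columns `window_id`, `chrom`, `start`, `end`,
#'   `gc_fraction`, `has_ambiguous`.
#' @export
tile_genome <- function(layout, width = 100L) {
  stopifnot(inherits(layout, "genome_layout"))
  per_chrom <- purrr::map2(layout$chrom_sizes$chrom, layout$chrom_sizes$length,
                           function(ch, len) {
    n <- len %/% width
    if (n == 0L) return(NULL)
    start <- (seq_len(n) - 1L) * width
    tibble::tibble(chrom = ch, start = start, end = start + as.integer(width))
  })
  win <- dplyr::bind_rows(per_chrom)
  if (nrow(win) == 0L) abort("no chromosome long enough for a single window")
  win$window_id <- paste0(win$chrom, ":", win$start, "-", win$end)
  win$gc_fraction <- NA_real_
  win$has_ambiguous <- FALSE
  seqs <- layout$sequences
  if (!is.null(seqs)) {
    for (ch in unique(win$chrom)) {
      if (!ch %in% names(seqs)) next
      idx <- which(win$chrom == ch)
      v <- Biostrings::Views(seqs[[ch]], start = win$start[idx] + 1L,
                             end = win$end[idx])
      freq <- Biostrings::letterFrequency(v, c("G", "C", "A", "T"))
      tot <- rowSums(freq)
      win$gc_fraction[idx] <- ifelse(tot > 0, (freq[, "G"] + freq[, "C"]) / width, NA_real_)
      win$has_ambiguous[idx] <- tot < width
    }
  }
  dplyr::select(win, "window_id", "chrom", "start", "end", "gc_fraction",
                "has_ambiguous")
}

# TRUE for intervals in `x` overlapping any interval in `y` by >= 1 bp.
overlaps_any <- function(x, y) {
  if (is.null(y) || nrow(y) == 0L) return(rep(FALSE, nrow(x)))
  out <- rep(FALSE, nrow(x))
  for (ch in unique(x$chrom)) {
    xi <- which(x$chrom == ch)
    yi <- which(y$chrom == ch)
    if (length(yi) == 0L) next
    hits <- IRanges::overlapsAny(
      IRanges::IRanges(start = x$start[xi] + 1L, end = x$end[xi]),
      IRanges::IRanges(start = y$start[yi] + 1L, end = y$end[yi])
    )
    out[xi] <- hits
  }
  out
}

#' Filter tiling windows eligible as background
#'
#' A window is excluded if it overlaps (by at least 1 bp) any promoter or CpG
#' island, overlaps an assembly gap, or contains an ambiguous base. What
#' remains measures non-specific pull-down only.
#'
#' @param windows Tiling windows from [tile_genome()].
#' @param promoters Promoter tibble from [load_refflat()] (or any interval set
#'   with `chrom`, `start`, `end`).
#' @param cpg_islands,gaps Optional BED3 tibbles.
#' @return The eligible subset of `windows`.
#' @export
filter_windows <- function(windows, promoters, cpg_islands = NULL, gaps = NULL) {
  drop <- overlaps_any(windows, promoters) |
    overlaps_any(windows, cpg_islands) |
    overlaps_any(windows, gaps) |
    windows$has_ambiguous
  windows[!drop, , drop = FALSE]
}

#' Select candidate background windows near each promoter
#'
#' For each promoter, among eligible windows on its chromosome with GC
#' fraction below `gc_max`, pick the `n_candidates` windows whose midpoints
#' lie closest to the TSS (ties broken toward the lower coordinate).
#'
#' @param promoters Promoter tibble ([load_refflat()]).
#' @param windows Eligible windows ([filter_windows()]); `gc_fraction` must be
#'   available (from sequence input).
#' @param n_candidates Number of candidate windows per promoter (default 80).
#' @param gc_max Exclusive upper bound on window GC fraction (default 0.40).
#' @return A tibble with columns `promoter_id`, `window_id`, `distance`,
#'   `candidate_rank`, `short` (fewer than `n_candidates` available). Promoters
#'   with zero candidates are absent (flagged downstream as "no background").
#' @export
construct_candidates <- function(promoters, windows, n_candidates = 80L,
                                 gc_max = 0.40) {
  if (all(is.na(windows$gc_fraction))) {
    abort("window GC fractions are all missing; provide sequences in the genome layout")
  }
  low_gc <- windows[!is.na(windows$gc_fraction) & windows$gc_fraction < gc_max, ]
  out <- purrr::map(seq_len(nrow(promoters)), function(i) {
    pr <- promoters[i, ]
    w <- low_gc[low_gc$chrom == pr$chrom, ]
    if (nrow(w) == 0L) return(NULL)
    mid <- (w$start + w$end) / 2
    dist <- abs(mid - pr$tss)
    ord <- order(dist, w$start)
    take <- head(ord, n_candidates)
    tibble::tibble(
      promoter_id = pr$promoter_id,
      window_id = w$window_id[take],
      distance = dist[take],
      candidate_rank = seq_along(take),
      short = length(ord) < n_candidates
    )
  })
  dplyr::bind_rows(out)
}

#' Transcripts-per-million normalization of window counts
#'
#' `TPM_g = r_g * r_l * 1e6 / (fl_g * sum_G r_g * r_l / fl_g)` where `r_g` is
#' the read count in window `g`, `r_l` the read length and `fl_g` the fragment
#' length (100 bp here, the window size). With constant `r_l` and `fl_g` this
#' scales each sample's window counts to sum to one million.
#'
#' @param window_counts Count table: `window_id` column then sample columns.
#' @param read_length Read length in bp (scalar).
#' @param fragment_length Fragment length in bp (default 100).
#' @return A tibble of the same shape with TPM values.
#' @export
compute_tpm <- function(window_counts, read_length = 50, fragment_length = 100) {
  m <- as_count_matrix(window_counts, "window counts")
  if (any(colSums(m) <= 0)) abort("all-zero counts for at least one sample")
  t_g <- m * read_length / fragment_length
  tpm <- sweep(t_g, 2L, colSums(t_g), "/") * 1e6
  matrix_to_tbl(tpm, id_col = names(window_counts)[1L])
}

#' Finalize background windows by TPM
#'
#' Of each promoter's candidates, keep the `n_final` with the lowest mean TPM
#' across the annotation-building samples (ties broken by TSS proximity, then
#' lower coordinate). Promoters with fewer than `n_final` candidates keep all
#' of them and are flagged.
#'
#' @param candidates Candidate table from [construct_candidates()].
#' @param tpm TPM table from [compute_tpm()] covering all candidate windows.
#' @param n_final Number of background windows per promoter (default 40).
#' @return A `background_annotation` tibble: `promoter_id`, `window_id`,
#'   `mean_tpm`, `rank`, `short`.
#' @export
finalize_background <- function(candidates, tpm, n_final = 40L) {
  tm <- as_count_matrix(tpm, "TPM table")
  miss <- setdiff(candidates$window_id, rownames(tm))
  if (length(miss) > 0L) {
    abort(paste0("candidate window(s) missing from TPM table: ",
                 paste(head(miss, 5L), collapse = ", ")))
  }
  mean_tpm <- rowMeans(tm)[candidates$window_id]
  out <- candidates |>
    dplyr::mutate(mean_tpm = unname(mean_tpm)) |>
    dplyr::group_by(.data$promoter_id) |>
    dplyr::arrange(.data$mean_tpm, .data$candidate_rank, .by_group = TRUE) |>
    dplyr::slice_head(n = n_final) |>
    dplyr::mutate(rank = dplyr::row_number(),
                  short = dplyr::n() < n_final) |>
    dplyr::ungroup() |>
    dplyr::select("promoter_id", "window_id", "mean_tpm", "rank", "short")
  class(out) <- c("background_annotation", class(out))
  out
}

#' Build the full background annotation for a promoter set
#'
#' Chains [tile_genome()], [filter_windows()], [construct_candidates()],
#' [compute_tpm()] and [finalize_background()].
#'
#' @param promoters Promoter tibble.
#' @param layout A [genome_layout()] with sequences.
#' @param window_counts Read counts per tiling window used for the TPM ranking
#'   (id column + one column per annotation-building sample).
#' @param read_length Read length for the TPM formula.
#' @inheritParams construct_candidates
#' @inheritParams finalize_background
#' @return A `background_annotation` tibble.
#' @export
build_background_annotation <- function(promoters, layout, window_counts,
                                        read_length = 50, n_candidates = 80L,
                                        n_final = 40L, gc_max = 0.40) {
  win <- tile_genome(layout)
  eligible <- filter_windows(win, promoters, layout$cpg_islands, layout$gaps)
  cand <- construct_candidates(promoters, eligible, n_candidates, gc_max)
  tpm <- compute_tpm(window_counts, read_length)
  finalize_background(cand, tpm, n_final)
}
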