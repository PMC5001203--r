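# Fixtures are generated in code at test time.

# A fastqc_data.txt-dialect file holding the given GC counts (names = GC%).
write_fastqc_fixture <- function(counts, path = tempfile(fileext = ".txt")) {
  gc <- as.integer(names(counts))
  lines <- c(
    "##FastQC\t0.11.2",
    ">>Basic Statistics\tpass",
    "#Measure\tValue",
    "Filename\tfixture.fastq",
    ">>END_MODULE",
    ">>Per sequence GC content\tpass",
    "#GC Content\tCount",
    sprintf("%d\t%s", gc, format(counts, scientific = FALSE, trim = TRUE)),
    ">>END_MODULE"
  )
  writeLines(lines, path)
  path
}

# GC histogram from a two-Gaussian read-level generator (n reads).
sample_gc_histogram <- function(n, p2 = 0.5, mu = c(40, 60), sd = c(5, 5),
                                seed = 1) {
  withr::with_seed(seed, {
    comp <- stats::rbinom(n, 1, p2) + 1
    x <- round(stats::rnorm(n, mu[comp], sd[comp]))
    x <- pmin(pmax(x, 0), 100)
    tibble::tibble(gc_percent = 0:100, density = tabulate(x + 1, 101) / n)
  })
}

# Toy genome: one 6-kb chromosome with known sequence (GC content controlled
# per 100-bp window via the proportion of G vs A).
toy_layout <- function(gc_by_window = NULL, chrom_len = 6000L,
                       gaps = NULL, cpg_islands = NULL, seed = 42) {
  n_win <- chrom_len %/% 100L
  if (is.null(gc_by_window)) gc_by_window <- rep(0.3, n_win)
  stopifnot(length(gc_by_window) == n_win)
  withr::with_seed(seed, {
    seq_chars <- unlist(lapply(gc_by_window, function(g) {
      n_gc <- round(100 * g)
      sample(c(rep("G", n_gc), rep("A", 100 - n_gc)))
    }))
  })
  seqs <- Biostrings::DNAStringSet(paste(seq_chars, collapse = ""))
  names(seqs) <- "chr1"
  genome_layout(
    chrom_sizes = tibble::tibble(chrom = "chr1", length = chrom_len),
    gaps = gaps, cpg_islands = cpg_islands, sequences = seqs
  )
}

write_refflat_fixture <- function(rows, path = tempfile(fileext = ".txt")) {
  writeLines(rows, path)
  path
}

# refFlat row helper (11 columns).
rf_row <- function(gene, chrom, strand, tx_start, tx_end) {
  paste(gene, paste0(gene, "_tx"), chrom, strand, tx_start, tx_end,
        tx_start, tx_end, 1L, paste0(tx_start, ","), paste0(tx_end, ","),
        sep = "\t")
}

# Random read set as a BED6 tibble.
random_reads <- function(n, chrom = "chr1", max_pos = 5900L, read_len = 50L,
                         seed = 1) {
  withr::with_seed(seed, {
    start <- sample.int(max_pos, n, replace = TRUE) - 1L
    strand <- sample(c("+", "-"), n, replace = TRUE)
    tibble::tibble(
      chrom = chrom, start = start, end = start + read_len,
      name = sprintf("r%d", seq_len(n)), score = 0L, strand = strand
    )
  })
}

# Independent brute-force oracle for the moderated Fisher test, built on the
# scalar log pmf only.
fisher_oracle <- function(x, y, fit_a, fit_b) {
  n <- x + y
  pa <- exp(vapply(0:n, mbdcapdm:::ddelap_log_one, numeric(1),
                   alpha = fit_a$alpha, beta = fit_a$beta,
                   lambda = fit_a$lambda))
  pb <- exp(vapply(0:n, mbdcapdm:::ddelap_log_one, numeric(1),
                   alpha = fit_b$alpha, beta = fit_b$beta,
                   lambda = fit_b$lambda))
  pab <- pa * rev(pb)
  pobs <- pa[x + 1] * pb[y + 1]
  sum(pab[pab <= pobs]) / sum(pab)
}
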