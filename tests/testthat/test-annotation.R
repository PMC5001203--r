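test_that("load_refflat applies the strand-aware TSS rule and deduplicates", {
  p <- write_refflat_fixture(c(
    rf_row("GENE1", "chr1", "+", 10000, 15000),
    rf_row("GENE1b", "chr1", "+", 10000, 17000),  # same TSS -> collapsed
    rf_row("GENE2", "chr1", "-", 5000, 10000)
  ))
  pr <- suppressMessages(load_refflat(p))
  expect_equal(nrow(pr), 2L)
  g1 <- pr[pr$gene == "GENE1", ]
  expect_equal(g1$tss, 10000L)
  expect_equal(c(g1$start, g1$end), c(8000L, 12000L))
  g2 <- pr[pr$gene == "GENE2", ]
  expect_equal(g2$tss, 9999L)
  expect_equal(c(g2$start, g2$end), c(7999L, 11999L))
})

test_that("load_refflat skips malformed rows and clips at chromosome edges", {
  p <- write_refflat_fixture(c(
    rf_row("GOOD", "chr1", "+", 1000, 2000),
    "broken\trow",
    rf_row("BAD", "chr1", "*", 1000, 2000)
  ))
  expect_warning(pr <- suppressMessages(load_refflat(p)), "malformed")
  expect_equal(pr$gene, "GOOD")
  expect_true(pr$clipped)          # tss - 2000 < 0
  expect_equal(pr$start, 0L)
})

test_that("tile_genome drops partial windows and computes GC from sequence", {
  lay <- toy_layout(chrom_len = 1000L, gc_by_window = rep(1, 10))
  win <- tile_genome(lay)
  expect_equal(nrow(win), 10L)
  expect_equal(win$gc_fraction, rep(1, 10))

  lay2 <- toy_layout(chrom_len = 1000L, gc_by_window = rep(0.2, 10))
  # length 1050: partial trailing window is dropped
  lay2$chrom_sizes$length <- 1050L
  win2 <- tile_genome(lay2)
  expect_equal(nrow(win2), 10L)
  expect_equal(win2$end[10], 1000L)
})

test_that("filter_windows matches a brute-force overlap oracle", {
  lay <- toy_layout(chrom_len = 3000L, gc_by_window = rep(0.3, 30))
  win <- tile_genome(lay)
  promoters <- tibble::tibble(promoter_id = "P1", chrom = "chr1",
                              start = 500L, end = 840L, tss = 700L)
  cpg <- tibble::tibble(chrom = "chr1", start = 2000L, end = 2050L)
  keep <- filter_windows(win, promoters, cpg_islands = cpg)
  # brute force: any-bp overlap
  brute <- vapply(seq_len(nrow(win)), function(i) {
    s <- win$start[i]; e <- win$end[i]
    !(max(s, 500L) < min(e, 840L)) && !(max(s, 2000L) < min(e, 2050L))
  }, logical(1))
  expect_equal(keep$window_id, win$window_id[brute])
  expect_equal(nrow(keep), 25L)  # windows 6-9 (promoter) and 21 (CpG) excluded
  # no exclusions -> everything eligible
  none <- filter_windows(win, promoters[0, ])
  expect_equal(nrow(none), 30L)
})

test_that("windows containing ambiguous bases are excluded", {
  lay <- toy_layout(chrom_len = 500L, gc_by_window = rep(0.3, 5))
  s <- as.character(lay$sequences[[1]])
  substr(s, 250, 250) <- "N"
  lay$sequences <- Biostrings::DNAStringSet(s)
  names(lay$sequences) <- "chr1"
  win <- tile_genome(lay)
  expect_true(win$has_ambiguous[3])
  keep <- filter_windows(win, tibble::tibble(chrom = character(),
                                             start = integer(), end = integer()))
  expect_equal(nrow(keep), 4L)
})

test_that("construct_candidates picks the nearest low-GC windows", {
  gc <- rep(0.3, 60); gc[31:40] <- 0.6   # 10 high-GC windows are ineligible
  lay <- toy_layout(chrom_len = 6000L, gc_by_window = gc)
  win <- tile_genome(lay)
  pr <- tibble::tibble(promoter_id = "P1", chrom = "chr1", strand = "+",
                       tss = 3000L, start = 1000L, end = 5000L)
  cand <- construct_candidates(pr, win, n_candidates = 20L)
  expect_equal(nrow(cand), 20L)
  # oracle: sort eligible by |mid - tss|, then start
  elig <- win[win$gc_fraction < 0.4, ]
  mid <- (elig$start + elig$end) / 2
  oracle <- elig$window_id[order(abs(mid - 3000), elig$start)][1:20]
  expect_equal(sort(cand$window_id), sort(oracle))
  expect_false(any(cand$short))

  # all windows high-GC -> promoter absent
  lay2 <- toy_layout(chrom_len = 2000L, gc_by_window = rep(0.6, 20))
  cand2 <- construct_candidates(pr, tile_genome(lay2))
  expect_equal(nrow(cand2), 0L)

  # fewer than requested -> all taken, flagged
  cand3 <- construct_candidates(pr, win, n_candidates = 100L)
  expect_true(all(cand3$short))
  expect_equal(nrow(cand3), 50L)
})

test_that("compute_tpm matches the formula and normalizes to one million", {
  wc <- tibble::tibble(window_id = c("w1", "w2"), s1 = c(1, 3))
  tpm <- compute_tpm(wc, read_length = 50)
  expect_equal(tpm$s1, c(2.5e5, 7.5e5))
  expect_equal(sum(tpm$s1), 1e6)

  wc2 <- tibble::tibble(window_id = c("w1", "w2"), s1 = c(5, 5))
  expect_equal(compute_tpm(wc2)$s1, c(5e5, 5e5))

  wc3 <- tibble::tibble(window_id = "w1", s1 = 7)
  expect_equal(compute_tpm(wc3)$s1, 1e6)

  expect_error(compute_tpm(tibble::tibble(window_id = "w1", s1 = 0)), "zero")
})

test_that("finalize_background keeps the lowest-TPM candidates with stated tie-breaks", {
  withr::with_seed(9, {
    cand <- tibble::tibble(
      promoter_id = "P1",
      window_id = sprintf("w%02d", 1:80),
      distance = seq(100, by = 100, length.out = 80),
      candidate_rank = 1:80,
      short = FALSE
    )
    tpm_vals <- sample(seq(10, 800, by = 10), 80)
    tpm <- tibble::tibble(window_id = cand$window_id, s1 = tpm_vals)
    fin <- finalize_background(cand, tpm, n_final = 40L)
    oracle <- cand$window_id[order(tpm_vals)][1:40]
    expect_setequal(fin$window_id, oracle)
    expect_false(any(fin$short))
  })

  # shortfall: all 30 candidates retained and flagged
  cand30 <- tibble::tibble(promoter_id = "P1", window_id = sprintf("v%02d", 1:30),
                           distance = 1:30 * 50, candidate_rank = 1:30,
                           short = TRUE)
  tpm30 <- tibble::tibble(window_id = cand30$window_id, s1 = rep(5, 30))
  fin30 <- finalize_background(cand30, tpm30, n_final = 40L)
  expect_equal(nrow(fin30), 30L)
  expect_true(all(fin30$short))

  # all-zero TPM: proximity decides
  tpm0 <- tibble::tibble(window_id = cand30$window_id, s1 = rep(0, 30))
  fin0 <- finalize_background(cand30, tpm0, n_final = 10L)
  expect_equal(fin0$window_id, cand30$window_id[1:10])
})

test_that("the full background annotation respects every exclusion invariant", {
  n_win <- 80L
  withr::with_seed(11, gc <- runif(n_win, 0.1, 0.6))
  cpg <- tibble::tibble(chrom = "chr1", start = 700L, end = 790L)
  lay <- toy_layout(chrom_len = n_win * 100L, gc_by_window = gc,
                    cpg_islands = cpg)
  p <- write_refflat_fixture(rf_row("G1", "chr1", "+", 4000, 4500))
  pr <- suppressMessages(load_refflat(p))
  win <- tile_genome(lay)
  wc <- tibble::tibble(window_id = win$window_id,
                       s1 = withr::with_seed(12, rpois(n_win, 5)) + 1)
  ann <- build_background_annotation(pr, lay, wc, n_candidates = 20L,
                                     n_final = 10L)
  expect_lte(nrow(ann), 10L)
  sel <- win[match(ann$window_id, win$window_id), ]
  expect_true(all(sel$gc_fraction < 0.40))
  # outside the promoter and the CpG island
  expect_true(all(sel$end <= pr$start | sel$start >= pr$end))
  expect_true(all(sel$end <= 700 | sel$start >= 790))
  # deterministic given identical inputs
  ann2 <- build_background_annotation(pr, lay, wc, n_candidates = 20L,
                                      n_final = 10L)
  expect_identical(ann, ann2)
})
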