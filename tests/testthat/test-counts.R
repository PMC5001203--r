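test_that("count_reads assigns by strand-aware 5' position only", {
  iv <- tibble::tibble(promoter_id = "P1", chrom = "chr1",
                       start = 100L, end = 200L)
  reads <- tibble::tibble(
    chrom = "chr1",
    start = c(120L, 150L, 199L, 250L),
    end = c(170L, 200L, 249L, 300L),
    name = paste0("r", 1:4), score = 0L,
    strand = c("+", "+", "+", "+")
  )
  expect_equal(count_reads(reads, iv)$count, 3L)

  # read straddling a window boundary counts where its 5' end lies
  win <- tibble::tibble(window_id = c("w1", "w2"), chrom = "chr1",
                        start = c(0L, 100L), end = c(100L, 200L))
  straddle <- tibble::tibble(chrom = "chr1", start = 80L, end = 130L,
                             name = "r", score = 0L, strand = "+")
  expect_equal(count_reads(straddle, win)$count, c(1L, 0L))
  # on the minus strand the 5' end is end - 1
  straddle$strand <- "-"
  expect_equal(count_reads(straddle, win)$count, c(0L, 1L))
})

test_that("count_reads equals a quadratic all-pairs oracle and ignores order", {
  win <- tibble::tibble(window_id = sprintf("w%02d", 1:10), chrom = "chr1",
                        start = seq(0L, 900L, by = 100L),
                        end = seq(100L, 1000L, by = 100L))
  reads <- random_reads(100, max_pos = 1100L, seed = 13)
  got <- count_reads(reads, win)$count
  fp <- ifelse(reads$strand == "-", reads$end - 1L, reads$start)
  oracle <- vapply(seq_len(nrow(win)), function(i) {
    sum(fp >= win$start[i] & fp < win$end[i])
  }, integer(1))
  expect_equal(got, oracle)
  expect_lte(sum(got), nrow(reads))

  shuffled <- reads[withr::with_seed(14, sample.int(nrow(reads))), ]
  expect_equal(count_reads(shuffled, win)$count, got)
})

test_that("reads on unknown chromosomes are skipped with a tally", {
  iv <- tibble::tibble(promoter_id = "P1", chrom = "chr1",
                       start = 0L, end = 100L)
  reads <- tibble::tibble(chrom = c("chr1", "chrUn"), start = c(10L, 10L),
                          end = c(60L, 60L), name = c("a", "b"),
                          score = 0L, strand = "+")
  expect_message(out <- count_reads(reads, iv), "skipped")
  expect_equal(out$count, 1L)
  expect_equal(attr(out, "skipped"), 1L)
})

test_that("background_counts_per_promoter sums annotated windows", {
  wc <- tibble::tibble(window_id = c("w1", "w2", "w3", "w4"),
                       s1 = c(1, 2, 3, 10), s2 = c(4, 5, 6, 10))
  ann <- tibble::tibble(promoter_id = c("P1", "P1", "P1", "P2"),
                        window_id = c("w1", "w2", "w3", "w4"))
  out <- background_counts_per_promoter(wc, ann)
  expect_equal(out$s1[out$promoter_id == "P1"], 6)
  expect_equal(out$s2[out$promoter_id == "P1"], 15)

  # promoter with no finalized windows is simply absent
  expect_false("P3" %in% out$promoter_id)

  # missing window id errors by name
  bad <- tibble::tibble(promoter_id = "P9", window_id = "missing_w")
  expect_error(background_counts_per_promoter(wc, bad), "missing_w")

  # random matrix equals an independent per-promoter summation oracle
  withr::with_seed(15, {
    wc2 <- tibble::tibble(window_id = sprintf("w%03d", 1:120),
                          a = rpois(120, 4), b = rpois(120, 8))
    ann2 <- tibble::tibble(promoter_id = rep(sprintf("P%d", 1:3), each = 40),
                           window_id = wc2$window_id)
    out2 <- background_counts_per_promoter(wc2, ann2)
    for (pid in unique(ann2$promoter_id)) {
      rows <- wc2$window_id %in% ann2$window_id[ann2$promoter_id == pid]
      expect_equal(out2$a[out2$promoter_id == pid], sum(wc2$a[rows]))
      expect_equal(out2$b[out2$promoter_id == pid], sum(wc2$b[rows]))
    }
  })
})

test_that("size factors are median-of-ratios with the expected equivariance", {
  tb <- tibble::tibble(id = sprintf("p%d", 1:50),
                       s1 = withr::with_seed(16, rpois(50, 40)) + 1)
  tb$s2 <- tb$s1
  expect_equal(unname(size_factors(tb)), c(1, 1))

  tb$s2 <- tb$s1 * 2
  sf <- size_factors(tb)
  expect_equal(unname(sf[2] / sf[1]), 2)

  # independent cross-check against DESeq2 on a random matrix
  skip_if_not_installed("DESeq2")
  withr::with_seed(17, {
    m <- matrix(rnbinom(300, mu = 100, size = 3) + 1, ncol = 3)
  })
  tb3 <- dplyr::bind_cols(tibble::tibble(id = sprintf("g%d", 1:100)),
                          tibble::as_tibble(as.data.frame(m)))
  expect_equal(unname(size_factors(tb3)),
               unname(DESeq2::estimateSizeFactorsForMatrix(m)),
               tolerance = 1e-12)
})

test_that("size factors fall back to total-count scaling without a positive row", {
  tb <- tibble::tibble(id = c("a", "b"), s1 = c(0, 10), s2 = c(5, 0))
  expect_warning(sf <- size_factors(tb), "total-count")
  expect_equal(unname(sf), c(10, 5) / sqrt(50))
})

test_that("count tables round-trip through TSV", {
  tb <- tibble::tibble(promoter_id = c("P1", "P2"), s1 = c(1, 2), s2 = c(3, 4))
  p <- tempfile(fileext = ".tsv")
  write_count_table(tb, p)
  back <- read_count_table(p)
  expect_equal(as.data.frame(back), as.data.frame(tb))
})
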