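test_that("default window geometry is 401 offsets from -250 to +150", {
  ct <- build_count_table(random_signal(), toy_promoters())
  offs <- setdiff(names(ct), "promoter_id")
  expect_length(offs, 401)
  expect_equal(as.integer(offs), -250:150)
  expect_equal(ct$promoter_id, toy_promoters()$promoter_id)
})

test_that("window cells map anchor+offset on + and anchor-offset on -", {
  pr <- toy_promoters()
  sig <- as_stranded_signal(tibble::tibble(
    chrom = c("chrA", "chrA"), strand = c("+", "-"),
    pos = c(1000L, 2990L), count = c(7L, 4L)))
  ct <- build_count_table(sig, pr)
  expect_equal(ct[["0"]], c(7L, 0L, 0L))     # + promoter, anchor itself
  expect_equal(ct[["10"]], c(0L, 4L, 0L))    # - promoter: anchor - 10 = 2990
  expect_equal(sum(as.matrix(ct[, -1])), 11L)
})

test_that("window construction conserves in-window signal and zero-pads ends", {
  set.seed(21)
  pr <- toy_promoters()
  for (i in 1:10) {
    sig <- random_signal(n_pos = 80, chroms = "chrA", max_pos = 1400)
    ct <- build_count_table(sig, pr)
    expected_pA <- sig |>
      dplyr::filter(chrom == "chrA", strand == "+",
                    pos >= 750, pos <= 1150) |>
      dplyr::pull(count) |> sum()
    expect_equal(sum(as.matrix(ct[1, -1])), expected_pA)
  }
  # promoter near the chromosome start: upstream positions just read 0
  pr_edge <- tibble::tibble(promoter_id = "edge", chrom = "chrA",
                            strand = "+", anchor = 5L, class_label = "x")
  expect_silent(ct <- build_count_table(random_signal(chroms = "chrA"), pr_edge))
  expect_equal(nrow(ct), 1)
})

test_that("mirrored minus-strand data give an identical count table", {
  set.seed(33)
  for (i in 1:5) {
    n <- 40
    offsets <- sample(-250:150, n)
    counts <- sample.int(30, n, replace = TRUE)
    plus <- tibble::tibble(promoter_id = "p", chrom = "chr1", strand = "+",
                           anchor = 5000L, class_label = "x")
    minus <- dplyr::mutate(plus, strand = "-")
    sig_plus <- as_stranded_signal(tibble::tibble(
      chrom = "chr1", strand = "+", pos = 5000L + offsets, count = counts))
    sig_minus <- as_stranded_signal(tibble::tibble(
      chrom = "chr1", strand = "-", pos = 5000L - offsets, count = counts))
    expect_equal(as.data.frame(build_count_table(sig_plus, plus)),
                 as.data.frame(build_count_table(sig_minus, minus)),
                 ignore_attr = TRUE)
  }
})

test_that("expression filter uses the mean over WT libraries, inclusive at 100", {
  pr <- toy_promoters()
  mk <- function(totals) {
    sig <- as_stranded_signal(tibble::tibble(
      chrom = pr$chrom, strand = pr$strand, pos = pr$anchor,
      count = as.integer(totals)))
    build_count_table(sig, pr)
  }
  expect_equal(filter_expressed(list(mk(c(100, 99, 1)))), "pA")
  # means 150/49 -> (150+150)/2 = 150 keep, (49+49)/2 dropped; zero dropped
  expect_equal(filter_expressed(list(mk(c(150, 49, 0)), mk(c(150, 49, 0)))),
               "pA")
  # mean 99.5 just misses
  expect_equal(filter_expressed(list(mk(c(150, 150, 1)), mk(c(49, 150, 1)))),
               "pB")
  expect_error(filter_expressed(list()), ">= 1")
})

test_that("row normalization yields unit-sum rows and flags empty rows", {
  pr <- toy_promoters()
  sig <- as_stranded_signal(tibble::tibble(
    chrom = "chrA", strand = "+",
    pos = c(995L, 1000L, 1005L, 1010L), count = c(1L, 2L, 3L, 4L)))
  ct <- build_count_table(sig, pr)
  nt <- normalize_rows(ct)
  row1 <- as.numeric(nt[1, -1])
  expect_equal(sum(row1), 1, tolerance = 1e-9)
  expect_equal(sort(row1[row1 > 0]), c(.1, .2, .3, .4))
  expect_true(all(is.na(as.numeric(nt[2, -1]))))  # pB saw no signal
})

test_that("difference tables subtract element-wise and rows sum to zero", {
  pr <- toy_promoters()[1, ]
  mk <- function(counts, pos) {
    build_count_table(as_stranded_signal(tibble::tibble(
      chrom = "chrA", strand = "+", pos = pos, count = counts)), pr)
  }
  mut <- normalize_rows(mk(c(5L, 5L), c(1000L, 1001L)))
  wt <- normalize_rows(mk(c(2L, 3L, 5L), c(1000L, 1001L, 1002L)))
  d <- diff_tables(mut, wt)
  vals <- as.numeric(d[1, c("0", "1", "2")])
  expect_equal(vals, c(.3, .2, -.5))
  expect_equal(sum(as.numeric(d[1, -1])), 0, tolerance = 1e-9)
  # identity: x - x = 0
  d0 <- diff_tables(mut, mut)
  expect_true(all(as.numeric(d0[1, -1]) == 0))
  # extreme opposite rows give +1/-1
  m2 <- normalize_rows(mk(1L, 1000L)); w2 <- normalize_rows(mk(1L, 1001L))
  d2 <- diff_tables(m2, w2)
  expect_equal(as.numeric(d2[1, c("0", "1")]), c(1, -1))
})

test_that("WT-expression ordering is a stable descending sort within class", {
  tab <- tibble::tibble(promoter_id = c("a", "b", "c", "d"))
  expect_equal(order_by_wt_expression(tab, c(5, 9, 9, 1)),
               c("b", "c", "a", "d"))
  expect_equal(order_by_wt_expression(tab, c(3, 3, 3, 3)),
               c("a", "b", "c", "d"))
  expect_equal(order_by_wt_expression(tab[1, ], 10), "a")
  # classes kept in first-appearance order, sort within class
  expect_equal(order_by_wt_expression(tab, c(5, 9, 9, 1),
                                      classes = c("x", "y", "x", "y")),
               c("c", "a", "b", "d"))
})

test_that("count tables round-trip through CSV", {
  ct <- build_count_table(random_signal(), toy_promoters())
  tf <- withr::local_tempfile(fileext = ".csv")
  write_count_table(ct, tf)
  header <- strsplit(readLines(tf, n = 1), ",")[[1]]
  expect_equal(header[1], "promoter_id")
  expect_equal(as.integer(header[-1]), -250:150)
  back <- read_count_table(tf)
  expect_equal(as.data.frame(back), as.data.frame(ct), ignore_attr = TRUE)
})

test_that("CDT matrices are read as count tables usable by the metrics", {
  tf <- withr::local_tempfile(fileext = ".cdt")
  writeLines(c("id\tname\t-1\t0\t1",
               "r1\tgeneA\t0\t5\t5",
               "r2\tgeneB\t1\t2\t3"), tf)
  ct <- read_cdt(tf)
  expect_equal(ct$promoter_id, c("r1", "r2"))
  m <- metrics_table(ct)
  # r2 cumsum over offsets -1,0,1 is 1,3,6: 50% of 6 is reached at offset 0
  expect_equal(m$median_pos, c(0L, 0L))
})
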