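test_that("the null table tallies (amplitude, magnitude) pairs exactly", {
  seg <- tibble::tibble(chrom = "chr1", start = 0:12 * 25L,
                        m = 0L, mbar = 0L, a = 0L)
  null <- build_null_table(seg)
  expect_equal(nrow(null), 1L)
  expect_equal(null$n, 13L)
  expect_equal(attr(null, "n_segments"), 13L)

  seg2 <- tibble::tibble(chrom = "chr1", start = 1:3 * 25L,
                         m = c(1L, 1L, 2L), mbar = c(1L, 1L, 0L),
                         a = c(2L, 2L, 2L))
  null2 <- build_null_table(seg2)
  expect_equal(null2$n[null2$m == 1], 2L)
  expect_equal(null2$n[null2$m == 2], 1L)
  expect_equal(null_totals(null2)$total, 3L)

  expect_error(build_null_table(seg[0, ]), "zero segments")
})

test_that("null-table mass equals the number of scanned segments", {
  withr::local_seed(7)
  for (rep in 1:5) {
    seg <- tibble::tibble(
      chrom = "chr1", start = seq_len(500) * 25L,
      m = rpois(500, 3), mbar = rpois(500, 3)) |>
      dplyr::mutate(a = m + mbar)
    null <- build_null_table(seg)
    expect_equal(sum(null$n), 500L)
    # independent tally
    ref <- as.data.frame(table(seg$a, seg$m), stringsAsFactors = FALSE)
    ref <- ref[ref$Freq > 0, ]
    expect_equal(nrow(null), nrow(ref))
  }
})

test_that("an empty upper tail gives the minimal threshold of 1", {
  null <- as_null(tibble::tibble(a = 5L, m = 0L, n = 100L))
  th <- compute_min_magnitude(null, 0.1)
  expect_equal(th$m_min[th$a == 5], 1L)
})

test_that("the boundary upper-tail fraction exactly at phi is significant", {
  # N(4, m) = 10, 20, 40, 20, 10 for m = 0..4: U(4, 4) = 0.10 <= 0.1
  null <- as_null(tibble::tibble(a = 4L, m = 0:4,
                                 n = c(10L, 20L, 40L, 20L, 10L)))
  th <- compute_min_magnitude(null, 0.1)
  expect_equal(th$m_min_raw[th$a == 4], 4L)
})

test_that("monotone enforcement takes the running maximum over amplitude", {
  # raw thresholds 1, 1, 3, 2 for a = 0..3 must become 1, 1, 3, 3
  null <- as_null(dplyr::bind_rows(
    tibble::tibble(a = 0L, m = 0L, n = 50L),                 # raw 1
    tibble::tibble(a = 1L, m = 0:1, n = c(95L, 5L)),         # raw 1
    tibble::tibble(a = 2L, m = 0:2, n = c(40L, 30L, 30L)),   # raw 3
    tibble::tibble(a = 3L, m = 0:3, n = c(50L, 42L, 4L, 4L)) # raw 2
  ))
  th <- compute_min_magnitude(null, 0.1)
  expect_equal(th$m_min_raw, c(1L, 1L, 3L, 2L))
  expect_equal(th$m_min, c(1L, 1L, 3L, 3L))
})

test_that("thresholds match the exhaustive oracle on random sparse tables", {
  withr::local_seed(2024)
  for (rep in 1:200) {
    tbl <- random_null_table()
    th <- compute_min_magnitude(as_null(tbl), 0.1)
    oracle <- oracle_thresholds(tbl, 0.1)
    got_raw <- th$m_min_raw[match(oracle$raw$a, th$a)]
    expect_identical(got_raw, oracle$raw$m_min_raw)
    expect_identical(th$m_min, oracle$enforced)
  }
})

test_that("enforced thresholds are monotone and bounded by a + 1", {
  withr::local_seed(99)
  for (rep in 1:50) {
    tbl <- random_null_table()
    th <- compute_min_magnitude(as_null(tbl), runif(1, 0.02, 0.5))
    expect_true(all(diff(th$m_min) >= 0L))
    expect_true(all(th$m_min >= 1L))
    expect_true(all(th$m_min <= th$a + 1L))
  }
})

test_that("flagging keeps exactly the segments at or above their threshold", {
  th <- compute_min_magnitude(
    as_null(tibble::tibble(a = 5L, m = c(0L, 3L, 4L, 5L),
                           n = c(88L, 4L, 4L, 4L))),
    0.1)
  expect_equal(th$m_min[th$a == 5], 4L)
  seg <- tibble::tibble(chrom = "chr1", start = c(0L, 25L),
                        m = c(5L, 3L), mbar = c(0L, 2L), a = c(5L, 5L))
  kept <- flag_significant(seg, th)
  expect_equal(kept$m, 5L)

  # random fixture vs brute-force filter
  withr::local_seed(5)
  seg2 <- tibble::tibble(chrom = "chr1", start = seq_len(400) * 25L,
                         m = rpois(400, 2), mbar = rpois(400, 2)) |>
    dplyr::mutate(a = m + mbar)
  th2 <- compute_min_magnitude(build_null_table(seg2), 0.15)
  kept2 <- flag_significant(seg2, th2)
  brute <- seg2[seg2$m >= th2$m_min[seg2$a + 1L], ]
  expect_identical(kept2, brute)

  # amplitude beyond the table is a misuse error
  seg3 <- tibble::tibble(chrom = "chr1", start = 0L,
                         m = 50L, mbar = 50L, a = 100L)
  expect_error(flag_significant(seg3, th), "missing")
})

test_that("threshold tables dump as a three-column TSV", {
  null <- as_null(tibble::tibble(a = c(2L, 2L, 4L), m = c(0L, 2L, 4L),
                                 n = c(95L, 5L, 10L)))
  th <- compute_min_magnitude(null, 0.1)
  tf <- withr::local_tempfile()
  write_thresholds_tsv(th, tf)
  dumped <- readr::read_tsv(tf, show_col_types = FALSE)
  expect_equal(names(dumped), c("amplitude", "m_min_raw", "m_min_enforced"))
  expect_equal(nrow(dumped), 5L)  # dense 0..4
  expect_equal(dumped$m_min_enforced, th$m_min)
})
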