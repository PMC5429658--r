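test_that("pattern presets carry the canonical run/loop bounds", {
  qp <- g4_pattern("quadparser")
  expect_equal(qp$min_run_len, 3L)
  expect_true(is.infinite(qp$max_run_len))
  expect_equal(c(qp$min_loop_len, qp$max_loop_len), c(1L, 7L))
  rel <- g4_pattern("relaxed")
  expect_equal(c(rel$min_run_len, rel$max_run_len), c(2L, 7L))
  expect_equal(c(rel$min_loop_len, rel$max_loop_len), c(1L, 15L))
  expect_error(g4_pattern(min_run_len = 1, max_run_len = 3,
                          min_loop_len = 1, max_loop_len = 3))
})

test_that("scan finds the engineered worked-example loci", {
  o <- example_oligos()
  bcl2 <- scan_g4(o$bcl2_like$wt)
  expect_equal(nrow(bcl2), 1L)
  expect_equal(bcl2$width, 22L)
  expect_equal(bcl2$tetrads, 3L)
  cxcl14 <- scan_g4(o$cxcl14_like$wt)
  expect_equal(cxcl14$width, 23L)
  taok2 <- scan_g4(o$taok2_like$wt)
  expect_equal(taok2$width, 27L)
  expect_equal(nrow(scan_g4(strrep("A", 24))), 0L)
})

test_that("invalid characters are rejected with their position", {
  expect_error(scan_g4("GGGAXGGGAGGGAGGG"), "position 5")
  expect_error(scan_g4("GGGRGGG"), "'R'")
  # N sits in loops but never in runs
  withN <- scan_g4("GGGNNGGGANGGGAGGG")
  expect_equal(nrow(withN), 1L)
  expect_equal(withN$tetrads, 3L)
})

test_that("scan candidates always satisfy the pattern and reconstruct the slice", {
  set.seed(11)
  n_found <- 0
  for (i in 1:30) {
    s <- random_seq(200, p_g = 0.45)
    df <- scan_g4(s)
    n_found <- n_found + nrow(df)
    for (k in seq_len(nrow(df))) {
      cand <- df[k, ]
      loops <- c(cand$loop1, cand$loop2, cand$loop3)
      expect_true(all(loops >= 1 & loops <= 7))
      runs <- cand$runs[[1]]
      expect_true(all(runs[, 2] - runs[, 1] + 1 >= 3))
      # run/loop decomposition tiles the candidate span exactly
      expect_equal(sum(runs[, 2] - runs[, 1] + 1) + sum(loops),
                   cand$end - cand$start + 1)
      # runs are really all-G and flanked by non-G inside the slice
      for (r in 1:4) {
        expect_equal(substr(s, runs[r, 1], runs[r, 2]),
                     strrep("G", runs[r, 2] - runs[r, 1] + 1))
      }
    }
  }
  expect_gt(n_found, 0)
})

test_that("scan matches the brute-force enumeration oracle on random sequences", {
  set.seed(101)
  n_found <- 0
  for (i in 1:25) {
    s <- random_seq(200, p_g = 0.45)
    got <- scan_g4(s)
    want <- oracle_scan(s)
    expect_equal(nrow(got), length(want))
    n_found <- n_found + nrow(got)
    for (k in seq_len(nrow(got)))
      expect_equal(span_key(got$runs[[k]]), span_key(want[[k]]))
  }
  expect_gt(n_found, 0)
})

test_that("C-rich mirror loci appear at mirrored coordinates on the reverse complement", {
  g4 <- "GGGAGGGAGGGAGGG"
  flank5 <- "ACUACUACUA"; flank3 <- "UCAUCAUCAUCA"
  s <- paste0(flank5, revcomp_rna(g4), flank3)   # C-rich version planted
  expect_equal(nrow(scan_g4(s)), 0L)
  rc <- revcomp_rna(s)
  hit <- scan_g4(rc)
  expect_equal(nrow(hit), 1L)
  n <- nchar(s)
  a <- nchar(flank5) + 1; b <- nchar(flank5) + nchar(g4)
  expect_equal(c(hit$start, hit$end), c(n - b + 1, n - a + 1))
})

test_that("enumeration returns every decomposition, scored and sorted", {
  df <- enumerate_qgrs("GGGAGGGAGGGAGGG")
  top <- df[1, ]
  expect_equal(top$tetrads, 3L)
  expect_equal(c(top$loop1, top$loop2, top$loop3), c(1L, 1L, 1L))
  expect_equal(top$width, 15L)
  expect_true(all(diff(df$gscore) <= 0))
  # ties broken by start then width
  ties <- df[abs(df$gscore - df$gscore[1]) < 1e-12, ]
  expect_equal(ties$start[1], min(ties$start))

  set.seed(21)
  for (i in 1:10) {
    s <- random_seq(120, p_g = 0.3)
    got <- enumerate_qgrs(s)
    want <- oracle_enumerate(s)
    expect_equal(nrow(got), length(want))
    expect_setequal(vapply(got$runs, span_key, ""),
                    vapply(want, span_key, ""))
  }
})

test_that("enumeration output is a superset of the scan output", {
  set.seed(31)
  n_found <- 0
  for (i in 1:10) {
    s <- random_seq(150, p_g = 0.45)
    sc <- scan_g4(s)
    en <- enumerate_qgrs(s, g4_pattern("quadparser"), max_span = 150)
    n_found <- n_found + nrow(sc)
    if (nrow(sc))
      expect_true(all(vapply(sc$runs, span_key, "") %in%
                      vapply(en$runs, span_key, "")))
  }
  expect_gt(n_found, 0)
})

test_that("worked-example enumeration reproduces the tetrad-count change", {
  o <- example_oligos()
  expect_equal(enumerate_qgrs(o$bcl2_like$wt)$tetrads[1], 3L)
  expect_equal(enumerate_qgrs(o$bcl2_like$mut)$tetrads[1], 2L)
})

test_that("gscore has the documented monotonicities", {
  # more tetrads at equal loops
  expect_gt(g4_score(3, c(1, 1, 1), tmax = 3),
            g4_score(2, c(1, 1, 1), tmax = 3))
  # longer loops at equal tetrads
  expect_gt(g4_score(3, c(1, 1, 1), tmax = 3),
            g4_score(3, c(1, 7, 1), tmax = 3))
  # more unequal loops at equal total
  expect_gt(g4_score(3, c(3, 3, 3), tmax = 3),
            g4_score(3, c(1, 3, 5), tmax = 3))
  # ranking matches an independent restatement of the formula
  set.seed(41)
  for (i in 1:30) {
    s <- random_seq(40, p_g = 0.35)
    df <- enumerate_qgrs(s)
    if (nrow(df) < 2) next
    tmax <- attr(df, "tmax")
    ind <- vapply(seq_len(nrow(df)), function(k)
      oracle_gscore(df$tetrads[k], c(df$loop1[k], df$loop2[k], df$loop3[k]),
                    tmax, 15), 0)
    expect_equal(order(-df$gscore), order(-ind, df$start, df$width))
  }
})

test_that("g-run counting matches a character-walk oracle", {
  expect_equal(count_g_runs("GGGG", 3), 1L)
  o <- example_oligos()
  expect_equal(count_g_runs(o$cxcl14_like$wt, 3), 5L)
  set.seed(51)
  for (i in 1:10) {
    s <- random_seq(500, p_g = 0.3)
    for (ml in 2:4)
      expect_equal(count_g_runs(s, ml), length(oracle_g_runs(s, ml)))
  }
})
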