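test_that("the printed acidic motif yields the expected windows", {
  p <- acidic_scan_params(tail_len = "all")
  hits <- scan_acidic_windows("DEDEEGEEDEE", p)
  ## enumerated by hand: both 10-mers of the 11-mer carry 9 D/E
  expect_equal(nrow(hits), 2L)
  first <- hits[hits$start == 1, ]
  expect_equal(first$end, 10L)
  expect_equal(first$acidic_count, 9L)
  expect_equal(first$fraction, 0.9)
})

test_that("an all-acidic decamer gives exactly one full-fraction hit", {
  hits <- scan_acidic_windows("DDDDDDDDDD", acidic_scan_params(tail_len = "all"))
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$fraction, 1.0)
})

test_that("the repressor-domain endecapeptide contains no acidic window", {
  hits <- scan_acidic_windows("LKFGVNAILSS", acidic_scan_params(tail_len = "all"))
  expect_equal(nrow(hits), 0L)
})

test_that("short sequences return no hits with a warning", {
  expect_warning(cc <- call_cter("MKVLSTAQG"), "shorter than window")
  expect_false(cc$positive)
})

test_that("the tail restriction controls which stretches are visible", {
  seq <- paste0(strrep("A", 50), strrep("D", 10), strrep("K", 200))
  expect_false(call_cter(seq, acidic_scan_params(tail_len = 50))$positive)
  expect_true(call_cter(seq, acidic_scan_params(tail_len = "all"))$positive)
})

test_that("a mostly-acidic terminus is called positive", {
  tail14 <- "DEDEEDEKEDEDKE"  # 12 D/E out of 14
  seq <- paste0(strrep("M", 40), tail14)
  cc <- call_cter(seq)
  expect_true(cc$positive)
  expect_true(cc$best_hit$fraction >= 0.8)
})

test_that("best hit maximizes fraction with rightmost tie-break", {
  seq <- paste0("DDDDDDDDDD", "KK", "EEEEEEEEEE")
  cc <- call_cter(seq, acidic_scan_params(tail_len = "all"))
  best_frac <- max(cc$hits$fraction)
  expect_equal(cc$best_hit$fraction, best_frac)
  expect_equal(cc$best_hit$start,
               max(cc$hits$start[cc$hits$fraction == best_frac]))
})

test_that("family classification counts positives and rejects duplicates", {
  fx <- make_motif_fixtures()
  calls <- classify_family(fx)
  expect_equal(nrow(calls), nrow(fx))
  expect_true(calls$positive[calls$seq_id == "mouse_cter_motif"])
  expect_true(calls$positive[calls$seq_id == "poly_acidic"])
  expect_false(calls$positive[calls$seq_id == "rd1_motif"])
  expect_false(calls$positive[calls$seq_id == "no_acidic_tail"])
  expect_equal(unname(attr(calls, "summary")["positive"]), sum(calls$positive))

  empty <- classify_family(protein_records(character(0), character(0)))
  expect_equal(nrow(empty), 0L)

  dup <- fx[c(1, 1), ]
  expect_error(classify_family(dup), "duplicate")
})

test_that("hits match brute-force window enumeration on random sequences", {
  set.seed(91)
  for (i in 1:60) {
    L <- sample(5:200, 1)
    seq <- random_seq(L, pool = c(AA20, "D", "E", "E"))  # acid-enriched
    tl <- sample(c(20, 50, Inf), 1)
    params <- acidic_scan_params(tail_len = if (is.finite(tl)) tl else "all")
    got <- suppressWarnings(scan_acidic_windows(seq, params))
    want <- brute_scan(seq, tail_len = tl)
    expect_equal(got$start, want$start, info = seq)
    expect_equal(got$acidic_count, want$acidic_count, info = seq)
  }
})

test_that("lowering the threshold only adds hits; calls are monotone", {
  set.seed(17)
  for (i in 1:20) {
    seq <- random_seq(80, pool = c(AA20, rep(c("D", "E"), 6)))
    h_lo <- scan_acidic_windows(seq, acidic_scan_params(min_fraction = 0.5,
                                                        tail_len = "all"))
    h_hi <- scan_acidic_windows(seq, acidic_scan_params(min_fraction = 0.8,
                                                        tail_len = "all"))
    expect_true(all(h_hi$start %in% h_lo$start))
    pos_tail <- call_cter(seq, acidic_scan_params(min_fraction = 0.5))$positive
    pos_all <- call_cter(seq, acidic_scan_params(min_fraction = 0.5,
                                                 tail_len = "all"))$positive
    expect_true(pos_all >= pos_tail)  # widening the region never loses a call
  }
})

test_that("prepending non-acidic residues shifts hits by exactly k", {
  set.seed(5)
  seq <- paste0(random_seq(30), "DEDEEGEEDEE")
  k <- 17
  pre <- paste0(strrep("G", k), seq)
  p <- acidic_scan_params(tail_len = "all")
  h0 <- scan_acidic_windows(seq, p)
  h1 <- scan_acidic_windows(pre, p)
  expect_equal(h1$start, h0$start + k)
  expect_equal(h1$end, h0$end + k)
})

test_that("scan parameter validation enforces the documented constraints", {
  expect_error(acidic_scan_params(window = 20, tail_len = 10), "window")
  expect_error(acidic_scan_params(acidic = c("D", "X")), "X")
  expect_error(acidic_scan_params(min_fraction = 0), "min_fraction")
})
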