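test_that("a minimal constructed domain is found with the expected geometry", {
  seqn <- pac_segment()  # minimal spacers: span 75
  m <- scan_strict(c(toy = seqn))
  expect_equal(nrow(m), 1)
  expect_equal(m$span_len, 75L)
  expect_equal(m$gly_pos, 1L)
  # Cys offsets from the Gly anchor
  expect_equal(unlist(m[, paste0("c", 1:6)]) - m$gly_pos,
               c(c1 = 4L, c2 = 7L, c3 = 18L, c4 = 39L, c5 = 48L, c6 = 74L))
  expect_equal(m$cys_in_span, 6L)
})

test_that("sequences without Cys or with out-of-bounds spacers do not match", {
  expect_equal(nrow(scan_strict(c(a = strrep("A", 200)))), 0)
  # Cys3-Cys4 spacer one below the minimum
  bad <- pac_segment(sp = c(10, 19, 8, 25))
  expect_equal(nrow(scan_strict(c(b = bad))), 0)
  # one above the maximum
  bad2 <- pac_segment(sp = c(31, 20, 8, 25))
  expect_equal(nrow(scan_strict(c(b2 = bad2))), 0)
})

test_that("a PS00925-style N-terminus anchors the match as expected", {
  # consensus instance: anchor G at 2, Cys1 at 6, Cys2 at 9
  seqn <- paste0("EGAVYCDTCR", strrep("A", 9), "C", strrep("A", 20),
                 "C", strrep("A", 8), "C", strrep("A", 25), "C")
  m <- scan_strict(c(ps = seqn))
  expect_equal(nrow(m), 1)
  expect_equal(m$gly_pos, 2L)
  expect_equal(m$c1, 6L)
  expect_equal(m$c2, 9L)
})

test_that("stop codons wall off matches", {
  seqn <- pac_segment()
  broken <- paste0(substr(seqn, 1, 30), "*", substr(seqn, 32, nchar(seqn)))
  expect_equal(nrow(scan_strict(c(s = broken))), 0)
})

test_that("min_max_span matches exhaustive boundary enumeration", {
  expect_equal(unname(min_max_span(pac_rule())), c(75L, 172L))
  collapsed <- pac_rule(gap_c2_c3 = 10, gap_c3_c4 = 20, gap_c4_c5 = 8,
                        gap_c5_c6 = 25)
  mm <- min_max_span(collapsed)
  expect_equal(mm[["min_len"]], mm[["max_len"]])
  expect_equal(min_max_span(pac_rule(gap_c2_c3 = c(10, 10)))[["max_len"]], 152L)
  # independent enumeration: spans realized by boundary spacer combinations
  spans <- outer(c(10, 30), c(20, 50), `+`)
  spans <- outer(spans, c(8, 20), `+`)
  spans <- outer(spans, c(25, 60), `+`)
  realized <- sort(unique(as.vector(spans))) + 7 + 3 + 2
  expect_equal(range(realized), c(75, 172))
})

test_that("scan_strict equals the regex oracle on random sequences", {
  set.seed(101)
  for (i in 1:300) {
    n <- sample(50:400, 1)
    s <- random_protein(n, cys_freq = runif(1, 0.01, 0.10))
    # embed a planted domain in a third of the cases to exercise positives
    if (i %% 3 == 0) {
      sp <- c(sample(10:30, 1), sample(20:50, 1), sample(8:20, 1),
              sample(25:60, 1))
      s <- paste0(substr(s, 1, 20), pac_segment(sp), substr(s, 21, n))
    }
    expect_same_matches(scan_strict(c(x = s)), regex_scan_oracle(s))
  }
})

test_that("scan_strict equals the regex oracle under perturbed rules", {
  set.seed(202)
  for (r in 1:5) {
    rule <- random_rule()
    for (i in 1:40) {
      s <- random_protein(sample(50:400, 1), cys_freq = runif(1, 0.02, 0.10))
      expect_same_matches(scan_strict(c(x = s), rule),
                          regex_scan_oracle(s, rule))
    }
  }
})

test_that("widening gaps never removes strict matches, narrowing never adds", {
  set.seed(33)
  base <- pac_rule()
  wide <- pac_rule(gap_c2_c3 = c(5, 35), gap_c3_c4 = c(15, 55),
                   gap_c4_c5 = c(4, 25), gap_c5_c6 = c(20, 65))
  narrow <- pac_rule(gap_c2_c3 = c(12, 28), gap_c3_c4 = c(22, 48),
                     gap_c4_c5 = c(10, 18), gap_c5_c6 = c(27, 58))
  for (i in 1:40) {
    s <- random_protein(300, cys_freq = 0.08)
    if (i %% 2 == 0) {
      s <- paste0(pac_segment(c(sample(10:30, 1), sample(20:50, 1),
                                sample(8:20, 1), sample(25:60, 1))), s)
    }
    key <- function(m) paste(m$gly_pos, m$c1, m$c6)
    kb <- key(scan_strict(c(x = s), base))
    expect_true(all(kb %in% key(scan_strict(c(x = s), wide))))
    expect_true(all(key(scan_strict(c(x = s), narrow)) %in% kb))
    # every span length within the rule bounds
    mb <- scan_strict(c(x = s), base)
    if (nrow(mb) > 0) {
      mm <- min_max_span(base)
      expect_true(all(mb$span_len >= mm[1] & mb$span_len <= mm[2]))
    }
  }
})

test_that("scanning is deterministic", {
  set.seed(9)
  s <- paste0(random_protein(50), pac_segment(), random_protein(50),
              pac_segment(c(12, 22, 10, 30)))
  m1 <- scan_strict(c(x = s))
  m2 <- scan_strict(c(x = s))
  expect_identical(m1, m2)
  expect_true(all(diff(m1$gly_pos) > 0))  # left-to-right anchor order
})

test_that("relaxed mode reproduces strict matches with empty violations", {
  set.seed(5)
  for (i in 1:10) {
    s <- paste0(random_protein(40), pac_segment(c(sample(10:30, 1), 20, 8, 25)),
                random_protein(40))
    strict <- scan_strict(c(x = s))
    tol0 <- scan_relaxed(c(x = s))
    expect_equal(match_positions(tol0[tol0$violations == "", ]),
                 match_positions(strict))
    expect_true(all(tol0$mode[tol0$violations == ""] == "strict"))
  }
})

test_that("an extra Cys inside a spacer is reported as a 7-Cys variant", {
  g <- generate_pdp(1, seed = 23, corruption = "extra_cys")
  expect_equal(nrow(scan_strict(g$record)), 0)
  r <- scan_relaxed(g$record, tolerances = pac_tolerances(max_extra_cys = 1))
  expect_equal(nrow(r), 1)
  expect_equal(r$cys_in_span, 7L)
  expect_match(r$violations, "extra_cys_in_spacer")
})

test_that("a mutated Gly is admitted only with the missing-Gly tolerance", {
  g <- generate_pdp(1, seed = 31, corruption = "missing_gly")
  expect_equal(nrow(scan_strict(g$record)), 0)
  expect_equal(nrow(scan_relaxed(g$record)), 0)
  r <- scan_relaxed(g$record, tolerances = pac_tolerances(missing_gly = TRUE))
  expect_equal(nrow(r), 1)
  expect_true(is.na(r$gly_pos))
  expect_match(r$violations, "missing_gly")
})

test_that("a missing interior Cys is admitted as a 5-Cys variant", {
  g <- generate_pdp(1, seed = 47, corruption = "missing_cys")
  expect_equal(nrow(scan_strict(g$record)), 0)
  r <- scan_relaxed(g$record, tolerances = pac_tolerances(max_missing_cys = 1))
  expect_equal(nrow(r), 1)
  expect_match(r$violations, "missing_cys")
  expect_equal(sum(is.na(unlist(r[, paste0("c", 1:6)]))), 1)
})

test_that("tolerance bounds are validated", {
  expect_error(pac_tolerances(max_extra_cys = 4), "between 0 and 3")
  expect_error(pac_tolerances(max_missing_cys = 2), "0 or 1")
})
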