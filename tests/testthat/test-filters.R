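test_that("signal-peptide heuristic passes a classic tripartite peptide", {
  recs <- as_protein_records(c(
    sp = paste0("MKKLLLLLLLLAASA", strrep("DNSGQ", 20)),
    polyD = paste0("M", strrep("D", 40)),
    acidic_n = paste0("MDDDD", strrep("L", 10), strrep("G", 40))))
  v <- signal_peptide_gate(recs)
  expect_equal(v$signal_peptide[v$record_id == "sp"], "pass")
  expect_equal(v$signal_peptide[v$record_id == "polyD"], "fail")
  # hydrophobic window present but n-region net charge < 0
  expect_equal(v$signal_peptide[v$record_id == "acidic_n"], "fail")
})

test_that("translated fragments without initial Met are unknown", {
  rec <- tibble::tibble(id = "frag", sequence = strrep("LLLLLAAA", 10),
                        source = "translated_frame", frame = 2L)
  expect_equal(signal_peptide_gate(rec)$signal_peptide, "unknown")
})

test_that("external signal-peptide predictions override the heuristic", {
  recs <- as_protein_records(c(a = paste0("M", strrep("D", 40))))
  tab <- tibble::tibble(record_id = "a", verdict = "pass")
  expect_equal(signal_peptide_gate(recs, tab)$signal_peptide, "pass")
  bad <- tibble::tibble(record_id = "nope", verdict = "pass")
  expect_error(signal_peptide_gate(recs, bad), "unknown record")
})

test_that("ss admissibility counts strands and helix fraction over the span", {
  m <- tibble::tibble(record_id = "r", span_start = 1L, span_end = 80L)
  all_coil <- tibble::tibble(record_id = "r", ss = strrep("C", 80))
  expect_equal(ss_admissible(m, all_coil)$ss_admissible, "fail")
  seven <- tibble::tibble(record_id = "r",
                          ss = paste0(strrep(paste0("EEEE", "CCCC"), 7),
                                      strrep("C", 80 - 56)))
  expect_equal(ss_admissible(m, seven)$n_strands, 7L)
  expect_equal(ss_admissible(m, seven)$ss_admissible, "pass")
  # one 48-residue helix covering 60% of the span
  helix <- tibble::tibble(record_id = "r",
                          ss = paste0(strrep("H", 48), strrep("EEEC", 8)))
  res <- ss_admissible(m, helix)
  expect_equal(res$helix_frac, 0.6)
  expect_equal(res$ss_admissible, "fail")
})

test_that("track length mismatches are errors", {
  m <- tibble::tibble(record_id = "r", span_start = 1L, span_end = 10L)
  tr <- tibble::tibble(record_id = "r", ss = "CCCC")
  expect_error(ss_admissible(m, tr), "cover")
  rec <- as_protein_records(c(r = strrep("A", 10)))
  expect_error(ss_admissible(m, tr, rec), "length")
})

test_that("ss gate is monotone in its parameters", {
  set.seed(12)
  m <- tibble::tibble(record_id = "r", span_start = 1L, span_end = 100L)
  for (i in 1:20) {
    ss <- tibble::tibble(record_id = "r",
                         ss = paste(sample(c("H", "E", "C"), 100, TRUE),
                                    collapse = ""))
    strictv <- ss_admissible(m, ss, min_strands = 3, max_helix_frac = 0.4)
    loose <- ss_admissible(m, ss, min_strands = 2, max_helix_frac = 0.6)
    if (strictv$ss_admissible == "pass") {
      expect_equal(loose$ss_admissible, "pass")
    }
  }
})

test_that("fallback predictor follows residue propensities deterministically", {
  rec <- as_protein_records(c(
    v = paste0(strrep("G", 6), strrep("V", 10), strrep("G", 6)),
    gp = strrep("GP", 12)))
  ss <- predict_ss_fallback(rec)
  expect_equal(nchar(ss$ss), nchar(rec$sequence))
  # poly-Val interior called strand, poly-Gly/Pro called coil
  mid <- substr(ss$ss[1], 9, 14)
  expect_equal(mid, strrep("E", 6))
  expect_equal(ss$ss[2], strrep("C", 24))
  expect_identical(predict_ss_fallback(rec), ss)
})

test_that("foreign-domain gate fails intracellular domains, allows PAC", {
  recs <- as_protein_records(c(a = "MKTA", b = "MKTC", c = "MKCA"))
  hits <- tibble::tibble(
    record_id = c("a", "b", "c", "c"),
    accession = c("PF00171", "PF02373", "PF01190", "PS00925"),
    start = 1L, end = 3L,
    evalue = c(1e-30, 1e-10, 1e-30, 1e-12))
  v <- foreign_domain_gate(recs, hits)
  expect_equal(v$foreign_domain, c("fail", "fail", "pass"))
  # weak hits above the e-value cutoff never exclude
  weak <- tibble::tibble(record_id = "a", accession = "PF00171",
                         start = 1L, end = 3L, evalue = 1e-3)
  expect_equal(foreign_domain_gate(recs, weak)$foreign_domain[1], "pass")
})

test_that("the three bona fide gates commute", {
  sim <- simulate_pdp_set(12, seed = 77)
  recs <- sim$records
  hits <- sim$hits
  ss <- predict_ss_fallback(recs)
  matches <- scan_strict(recs)
  sp <- signal_peptide_gate(recs)
  fd <- foreign_domain_gate(recs, hits)
  ssa <- ss_admissible(matches, ss)
  bona_fide <- function(order_ids) {
    ids <- recs$id
    for (g in order_ids) {
      ids <- switch(g,
        sp = ids[ids %in% sp$record_id[sp$signal_peptide != "fail"]],
        fd = ids[ids %in% fd$record_id[fd$foreign_domain == "pass"]],
        ss = ids[ids %in% ssa$record_id[ssa$ss_admissible == "pass"]])
    }
    sort(ids)
  }
  expect_equal(bona_fide(c("sp", "fd", "ss")), bona_fide(c("ss", "sp", "fd")))
  expect_equal(bona_fide(c("fd", "ss", "sp")), bona_fide(c("sp", "ss", "fd")))
})
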