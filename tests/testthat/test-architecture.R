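test_that("W-W detection anchors at the first Trp-X8-Trp and runs to the end", {
  s1 <- paste0(strrep("A", 20), "W", strrep("G", 8), "W", strrep("A", 10))
  a1 <- detect_ww(c(r = s1))
  expect_equal(nrow(a1), 1)
  expect_equal(a1$start, 21L)
  expect_equal(a1$end, nchar(s1))
  # spacing must be exactly 8
  s2 <- paste0(strrep("A", 20), "W", strrep("G", 7), "W", strrep("A", 10))
  expect_equal(nrow(detect_ww(c(r = s2))), 0)
  # two candidate anchors close together: the earlier wins
  s3 <- paste0("W", strrep("A", 3), "W", strrep("A", 4), "W",
               strrep("A", 4), "W", strrep("A", 20))
  a3 <- detect_ww(c(r = s3))
  expect_equal(nrow(a3), 1)
  expect_equal(a3$start, 1L)
})

test_that("extensin regions need >= 3 Ser-Pro(>=2) motifs within merge range", {
  a <- detect_extensin(c(r = "SPPASPPPASPP"))
  expect_equal(nrow(a), 1)
  expect_equal(a$score, 3)
  expect_equal(nrow(detect_extensin(c(r = "SPASPA"))), 0)
  two <- paste0(strrep("SPPA", 3), strrep("G", 100), strrep("SPPA", 3))
  a2 <- detect_extensin(c(r = two))
  expect_equal(nrow(a2), 2)
  expect_equal(a2$score, c(3, 3))
})

test_that("histidine stretches are window-detected and trimmed to His", {
  a <- detect_his_rich(c(r = "AHHHHA"))
  expect_equal(nrow(a), 1)
  expect_equal(c(a$start, a$end, a$score), c(2, 5, 4))
  # 4 His spread over a 6-residue window still qualifies
  a2 <- detect_his_rich(c(r = paste0("GG", "HAHHAH", "GG")))
  expect_equal(nrow(a2), 1)
  expect_equal(c(a2$start, a2$end), c(3, 8))
  expect_equal(nrow(detect_his_rich(c(r = strrep("AG", 20)))), 0)
  # 3 His in any 6-window does not qualify
  expect_equal(nrow(detect_his_rich(c(r = "HAHAHA"))), 0)
})

test_that("proline-rich windows qualify exactly at the 0.3 threshold", {
  six <- paste0(strrep("P", 6), strrep("A", 14))
  expect_equal(nrow(detect_pro_rich(c(r = six))), 1)
  five <- paste0(strrep("P", 5), strrep("A", 15))
  expect_equal(nrow(detect_pro_rich(c(r = five))), 0)
  poly <- detect_pro_rich(c(r = strrep("P", 30)))
  expect_equal(nrow(poly), 1)
  expect_equal(poly$score, 1.0)
})

test_that("AGP-like windows require 30% dipeptide coverage", {
  a <- detect_agp_like(c(r = strrep("AP", 10)))
  expect_equal(nrow(a), 1)
  expect_gt(a$score, 0.9)
  # detectors are independent: AP repeats are both Pro-rich and AGP-like
  expect_equal(nrow(detect_pro_rich(c(r = strrep("AP", 10)))), 1)
  # random windows almost never qualify
  set.seed(88)
  fp <- sum(vapply(1:500, function(i) {
    nrow(detect_agp_like(c(r = random_protein(20, cys_freq = 0.05)))) > 0
  }, logical(1)))
  expect_lt(fp / 500, 0.01)
})

classify_one <- function(g) {
  matches <- scan_strict(g$record)
  sp <- tibble::tibble(record_id = g$record$id, sp_end = g$truth$sp_end)
  ann <- annotate_domains(g$record, sp_ends = sp)
  classify_pdp(g$record, matches, ann)
}

test_that("the four planted architectures are recovered", {
  for (ty in 1:4) {
    g <- generate_pdp(ty, seed = 100 + ty)
    cl <- classify_one(g)
    expect_equal(cl$type, as.character(ty))
  }
  g2 <- generate_pdp(2, seed = 55)
  cl2 <- classify_one(g2)
  expect_true(cl2$ww_2prime)
  expect_equal(cl2$pac_position, "n_terminal")
  g3 <- generate_pdp(3, seed = 56)
  expect_equal(classify_one(g3)$pac_position, "c_terminal")
  g4 <- generate_pdp(4, seed = 57)
  expect_equal(classify_one(g4)$pac_position, "central")
  g1 <- generate_pdp(1, seed = 58)
  expect_equal(classify_one(g1)$pac_position, "whole")
})

test_that("records without a strict match are unclassified", {
  rec <- as_protein_records(c(r = strrep("A", 100)))
  cl <- classify_pdp(rec, scan_strict(rec), NULL)
  expect_equal(cl$type, "unclassified")
})

test_that("multi-PAC proteins classify on the N-terminal match and are flagged", {
  s <- paste0(pac_segment(), strrep("G", 10), pac_segment(c(12, 22, 10, 30)))
  rec <- as_protein_records(c(two = s))
  m <- scan_strict(rec)
  expect_equal(nrow(m), 2)
  expect_message(cl <- classify_pdp(rec, m, NULL), "most N-terminal")
  expect_true(cl$multi_pac)
})

test_that("Type 3 calls are robust to short ragged C-terminal extensions", {
  g <- generate_pdp(3, seed = 71)
  base <- classify_one(g)
  expect_equal(base$type, "3")
  g$record$sequence <- paste0(g$record$sequence, "GNDSA")
  extended <- classify_one(g)
  expect_equal(extended$type, "3")
})

test_that("annotations never overlap the signal peptide after masking", {
  sim <- simulate_pdp_set(40, seed = 300)
  sp <- dplyr::transmute(sim$truth, record_id = .data$record_id,
                         sp_end = .data$sp_end)
  ann <- annotate_domains(sim$records, sp_ends = sp)
  ann <- ann[ann$kind != "signal_peptide", ]
  spe <- sp$sp_end[match(ann$record_id, sp$record_id)]
  expect_true(all(ann$start > spe))
})

test_that("the 1' flag marks Type 1 domains conserved against a reference set", {
  g <- generate_pdp(1, seed = 81)
  pacseq <- substr(g$record$sequence, g$truth$pac_start, g$truth$pac_end)
  # a reference at ~ 90% identity
  ch <- strsplit(pacseq, "")[[1]]
  idx <- setdiff(seq_along(ch), c(1, which(ch == "C")))
  set.seed(4)
  mut <- sample(idx, round(0.1 * length(ch)))
  ch[mut] <- vapply(ch[mut], function(x) sample(setdiff(AA_LETTERS, c(x, "C")), 1),
                    character(1))
  refs <- tibble::tibble(id = "cladeC_ref", sequence = paste(ch, collapse = ""))
  m <- scan_strict(g$record)
  sp <- tibble::tibble(record_id = g$record$id, sp_end = g$truth$sp_end)
  ann <- annotate_domains(g$record, sp_ends = sp)
  cl <- classify_pdp(g$record, m, ann, clade_c_refs = refs)
  expect_true(cl$conserved_1prime)
  # an unrelated reference does not trigger the flag
  far <- tibble::tibble(id = "far", sequence = strrep("KDERNQ", 20))
  cl2 <- classify_pdp(g$record, m, ann, clade_c_refs = far)
  expect_false(cl2$conserved_1prime)
})

test_that("planted types are recovered perfectly on a mixed set", {
  sim <- simulate_pdp_set(80, seed = 500)
  matches <- scan_strict(sim$records)
  sp <- dplyr::transmute(sim$truth, record_id = .data$record_id,
                         sp_end = .data$sp_end)
  ann <- annotate_domains(sim$records, sp_ends = sp)
  cl <- classify_pdp(sim$records, matches, ann)
  expect_equal(cl$type, as.character(sim$truth$planted_type))
})
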