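test_that("identical sequences align at 100/100 with no gaps", {
  s <- pac_segment()
  a <- global_align(s, s)
  expect_equal(a$identity_pct, 100)
  expect_equal(a$similarity_pct, 100)
  expect_equal(a$gaps, 0L)
  expect_equal(a$length, nchar(s))
})

test_that("a toy substitution + gap pair matches the independent DP oracle", {
  a <- "GCCAATGWKRHE"
  b <- "GCCAVTGWKR"
  got <- global_align(a, b)
  exp <- nw_oracle_canonical(a, b)
  expect_equal(got$identity_pct, exp$identity_pct)
  expect_equal(got$similarity_pct, exp$similarity_pct)
  expect_equal(got$score, exp$score)
  expect_equal(got$length, exp$length)
  expect_equal(got$gaps, exp$gaps)
})

test_that("terminal extension yields the arithmetic identity", {
  a <- strrep("MKWVTFDE", 3)
  b <- paste0(a, "AAAAA")
  r <- global_align(a, b)
  expect_equal(r$gaps, 5L)
  expect_equal(r$identity_pct, 100 * nchar(a) / (nchar(a) + 5))
})

test_that("alignment statistics equal the DP oracle on random pairs", {
  set.seed(61)
  for (i in 1:60) {
    a <- random_protein(sample(5:60, 1))
    b <- random_protein(sample(5:60, 1))
    got <- global_align(a, b)
    exp <- nw_oracle_canonical(a, b)
    expect_equal(got$score, exp$score)
    expect_equal(got$identity_pct, exp$identity_pct)
    expect_equal(got$similarity_pct, exp$similarity_pct)
  }
})

test_that("alignment scores agree with Biostrings pairwiseAlignment", {
  m <- local({
    env <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = env)
    b <- env$BLOSUM62
    b["X", ] <- 0L
    b[, "X"] <- 0L
    b
  })
  set.seed(62)
  for (i in 1:20) {
    a <- random_protein(sample(10:50, 1))
    b <- random_protein(sample(10:50, 1))
    ref <- Biostrings::pairwiseAlignment(
      a, b, type = "global", substitutionMatrix = m,
      gapOpening = 10, gapExtension = 0.5, scoreOnly = TRUE)
    expect_equal(global_align(a, b)$score, ref)
  }
})

test_that("identity and similarity are symmetric", {
  set.seed(63)
  for (i in 1:20) {
    a <- random_protein(sample(10:50, 1))
    b <- random_protein(sample(10:50, 1))
    f <- global_align(a, b)
    r <- global_align(b, a)
    expect_equal(f$identity_pct, r$identity_pct)
    expect_equal(f$similarity_pct, r$similarity_pct)
  }
})

test_that("X columns score zero so self-similarity drops below 100", {
  r <- global_align("ACDXFG", "ACDXFG")
  expect_equal(r$identity_pct, 100)
  expect_lt(r$similarity_pct, 100)
})

test_that("dedupe collapses near-identical domains by single linkage", {
  base <- pac_segment(fill = "A")
  ch <- strsplit(base, "")[[1]]
  mutate_at <- function(pos, to) {
    x <- ch
    x[pos] <- to
    paste(x, collapse = "")
  }
  spots <- which(ch == "A")
  near <- mutate_at(spots[1], "G")  # ~ 99% identical
  recs <- tibble::tibble(id = c("a", "b"), sequence = c(base, near),
                         species = "sp1")
  dd <- dedupe(recs, threshold = 85)
  expect_equal(nrow(dd$representatives), 1)
  # chain x-y ~91, y-z ~91, x-z ~81: single linkage keeps one cluster
  tri <- tibble::tibble(id = c("x", "y", "z"),
                        sequence = c(mutate_at(spots[1:7], "G"), base,
                                     mutate_at(spots[8:14], "V")),
                        species = "sp1")
  pi <- pairwise_identities(tri)
  expect_true(pi$identity[pi$id_a == "x" & pi$id_b == "y"] >= 85)
  expect_true(pi$identity[pi$id_a == "y" & pi$id_b == "z"] >= 85)
  expect_true(pi$identity[pi$id_a == "x" & pi$id_b == "z"] < 85)
  dd2 <- dedupe(tri, threshold = 85)
  expect_equal(length(unique(dd2$clusters$cluster)), 1)
  expect_equal(nrow(dd2$representatives), 1)
})

test_that("dedupe keeps everything below threshold and respects extremes", {
  recs <- tibble::tibble(
    id = c("p", "q", "r"),
    sequence = c(strrep("MKWVTFDE", 6), strrep("GNDSAPQR", 6),
                 strrep("HEILYVCF", 6)),
    species = c("sp1", "sp1", "sp2"))
  dd <- dedupe(recs, threshold = 85)
  expect_equal(nrow(dd$representatives), 3)
  expect_equal(nrow(dedupe(recs, threshold = 101)$representatives), 3)
  # threshold 0: everything within a species collapses to one
  dd0 <- dedupe(recs, threshold = 0)
  expect_equal(nrow(dd0$representatives), 2)
  # representative is the longest member, ties to smallest id
  tie <- tibble::tibble(id = c("bb", "aa"), sequence = rep(strrep("MKWV", 10), 2),
                        species = "sp1")
  expect_equal(dedupe(tie, threshold = 85)$representatives$id, "aa")
})

test_that("distance matrices are symmetric with zero diagonal", {
  set.seed(64)
  recs <- tibble::tibble(id = paste0("r", 1:8),
                         sequence = vapply(1:8, function(i) random_protein(30),
                                           character(1)))
  d <- distance_matrix(recs)
  expect_equal(d, t(d))
  expect_equal(unname(diag(d)), rep(0, 8))
  # spot-check against a direct alignment
  al <- global_align(recs$sequence[2], recs$sequence[5])
  expect_equal(d["r2", "r5"], 100 - al$identity_pct)
  f <- withr::local_tempfile()
  write_phylip_dist(d, f)
  expect_equal(as.integer(trimws(readLines(f)[1])), 8)
})
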