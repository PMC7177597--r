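# Independent oracles and fixture builders used across the suite. These
# deliberately avoid the package's own code paths: the scanner oracle is a
# regular expression, the alignment oracle a separately written dynamic
# program, the PROSITE oracle an expansion-based sliding comparison.

AA_LETTERS <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

random_protein <- function(n, cys_freq = 0.05) {
  p <- rep((1 - cys_freq) / 19, 20)
  p[AA_LETTERS == "C"] <- cys_freq
  paste(sample(AA_LETTERS, n, replace = TRUE, prob = p), collapse = "")
}

# a strict-valid PAC segment with given spacer lengths (defaults minimal)
pac_segment <- function(sp = c(10, 20, 8, 25), fill = "A",
                        g0 = 3, g1 = 2) {
  blk <- function(n) strrep(fill, n)
  paste0("G", blk(g0), "C", blk(g1), "C", blk(sp[1]), "C", blk(sp[2]),
         "C", blk(sp[3]), "C", blk(sp[4]), "C")
}

# brute-force regular-expression scan oracle: anchored evaluation at every
# Gly position; with Cys-free spacers the Cys chain per anchor is forced
regex_scan_oracle <- function(seq, rule = pacfinder::pac_rule()) {
  g <- rule
  pat <- sprintf(
    "^G[^C*]{%d}C[^C*]{%d}C[^C*]{%d,%d}C[^C*]{%d,%d}C[^C*]{%d,%d}C[^C*]{%d,%d}C",
    g$gap_gly_c1, g$gap_c1_c2,
    g$gap_c2_c3[1], g$gap_c2_c3[2], g$gap_c3_c4[1], g$gap_c3_c4[2],
    g$gap_c4_c5[1], g$gap_c4_c5[2], g$gap_c5_c6[1], g$gap_c5_c6[2])
  ch <- strsplit(seq, "")[[1]]
  out <- list()
  for (i in which(ch == "G")) {
    m <- regexpr(pat, substring(seq, i), perl = TRUE)
    if (m[1] == 1) {
      txt <- substr(substring(seq, i), 1, attr(m, "match.length"))
      cys <- i - 1L + which(strsplit(txt, "")[[1]] == "C")
      out[[length(out) + 1L]] <- c(i, cys)
    }
  }
  if (length(out) == 0) {
    return(matrix(integer(), 0, 7,
                  dimnames = list(NULL, c("gly", paste0("c", 1:6)))))
  }
  m <- do.call(rbind, out)
  colnames(m) <- c("gly", paste0("c", 1:6))
  m
}

match_positions <- function(matches) {
  as.matrix(matches[, c("gly_pos", paste0("c", 1:6))])
}

random_rule <- function() {
  rng <- function(lo_max, width_max) {
    lo <- sample(0:lo_max, 1)
    c(lo, lo + sample(0:width_max, 1))
  }
  pacfinder::pac_rule(gap_gly_c1 = sample(0:5, 1), gap_c1_c2 = sample(0:5, 1),
                      gap_c2_c3 = rng(15, 20), gap_c3_c4 = rng(25, 30),
                      gap_c4_c5 = rng(12, 12), gap_c5_c6 = rng(30, 35))
}

# independent affine-gap global alignment oracle (same scoring conventions
# stated in the package docs: gap cost open + L*extend, gap states open
# from M only, traceback prefers diagonal, then up, then left)
nw_oracle <- function(a, b, open = 10, ext = 0.5) {
  sm <- local({
    env <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = env)
    m <- env$BLOSUM62
    m["X", ] <- 0L
    m[, "X"] <- 0L
    m
  })
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  A[!A %in% rownames(sm)] <- "X"
  B[!B %in% rownames(sm)] <- "X"
  n <- length(A)
  m <- length(B)
  INF <- 1e18
  M <- X <- Y <- matrix(-INF, n + 1, m + 1)
  ptrM <- ptrX <- ptrY <- matrix("", n + 1, m + 1)
  M[1, 1] <- 0
  for (i in seq_len(n)) X[i + 1, 1] <- -(open + ext * i)
  for (j in seq_len(m)) Y[1, j + 1] <- -(open + ext * j)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- sm[A[i], B[j]]
      best <- c(M = M[i, j], X = X[i, j], Y = Y[i, j])
      w <- names(best)[which.max(best)]
      M[i + 1, j + 1] <- best[[w]] + s
      ptrM[i + 1, j + 1] <- w
      oX <- M[i, j + 1] - open - ext
      eX <- X[i, j + 1] - ext
      if (oX >= eX) { X[i + 1, j + 1] <- oX; ptrX[i + 1, j + 1] <- "M" }
      else { X[i + 1, j + 1] <- eX; ptrX[i + 1, j + 1] <- "X" }
      oY <- M[i + 1, j] - open - ext
      eY <- Y[i + 1, j] - ext
      if (oY >= eY) { Y[i + 1, j + 1] <- oY; ptrY[i + 1, j + 1] <- "M" }
      else { Y[i + 1, j + 1] <- eY; ptrY[i + 1, j + 1] <- "Y" }
    }
  }
  fin <- c(M = M[n + 1, m + 1], X = X[n + 1, m + 1], Y = Y[n + 1, m + 1])
  st <- names(fin)[which.max(fin)]
  i <- n; j <- m
  cols_id <- 0L
  cols_pos <- 0L
  cols <- 0L
  gaps <- 0L
  while (i > 0 || j > 0) {
    if (i == 0) st <- "Y"
    if (j == 0) st <- "X"
    cols <- cols + 1L
    if (st == "M") {
      if (A[i] == B[j]) cols_id <- cols_id + 1L
      if (sm[A[i], B[j]] > 0) cols_pos <- cols_pos + 1L
      st <- ptrM[i + 1, j + 1]
      i <- i - 1L; j <- j - 1L
    } else if (st == "X") {
      gaps <- gaps + 1L
      nxt <- ptrX[i + 1, j + 1]
      if (nxt == "") nxt <- "X"
      i <- i - 1L
      st <- nxt
    } else {
      gaps <- gaps + 1L
      nxt <- ptrY[i + 1, j + 1]
      if (nxt == "") nxt <- "Y"
      j <- j - 1L
      st <- nxt
    }
  }
  list(score = unname(fin[which.max(fin)]),
       identity_pct = 100 * cols_id / cols,
       similarity_pct = 100 * cols_pos / cols,
       length = cols, gaps = gaps)
}

# brute-force PROSITE oracle: expand variable repeats and compare sets
# position by position at every start
prosite_oracle <- function(seq, pattern) {
  toks <- strsplit(pattern, "-", fixed = TRUE)[[1]]
  parsed <- lapply(toks, function(tok) {
    m <- regmatches(tok, regexec(
      "^(\\[([A-Za-z]+)\\]|[A-Za-z])(\\((\\d+)(,(\\d+))?\\))?$", tok))[[1]]
    lo <- if (nzchar(m[5])) as.integer(m[5]) else 1L
    hi <- if (nzchar(m[7])) as.integer(m[7]) else lo
    set <- if (startsWith(m[2], "[")) strsplit(toupper(m[3]), "")[[1]]
           else if (toupper(m[2]) == "X") AA_LETTERS
           else toupper(m[2])
    list(set = set, lens = lo:hi)
  })
  combos <- expand.grid(lapply(parsed, function(p) p$lens))
  ch <- strsplit(toupper(seq), "")[[1]]
  hits <- list()
  for (r in seq_len(nrow(combos))) {
    lens <- as.integer(combos[r, ])
    total <- sum(lens)
    if (total == 0 || total > length(ch)) next
    for (s in seq_len(length(ch) - total + 1L)) {
      pos <- s
      ok <- TRUE
      for (k in seq_along(parsed)) {
        if (lens[k] == 0) next
        if (!all(ch[pos:(pos + lens[k] - 1L)] %in% parsed[[k]]$set)) {
          ok <- FALSE
          break
        }
        pos <- pos + lens[k]
      }
      if (ok) hits[[length(hits) + 1L]] <- c(s, s + total - 1L)
    }
  }
  if (length(hits) == 0) {
    return(tibble::tibble(start = integer(), end = integer()))
  }
  m <- unique(do.call(rbind, hits))
  dplyr::arrange(tibble::tibble(start = m[, 1], end = m[, 2]),
                 start, end)
}

# random proper rigid-body transform applied to an atom tibble
random_rigid_transform <- function(atoms) {
  q <- qr.Q(qr(matrix(stats::rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  shift <- stats::rnorm(3, 0, 50)
  xyz <- as.matrix(atoms[, c("x", "y", "z")]) %*% q
  atoms$x <- xyz[, 1] + shift[1]
  atoms$y <- xyz[, 2] + shift[2]
  atoms$z <- xyz[, 3] + shift[3]
  atoms
}

expect_same_matches <- function(matches, oracle_matrix) {
  got <- match_positions(matches)
  testthat::expect_equal(nrow(got), nrow(oracle_matrix))
  if (nrow(got) > 0) {
    testthat::expect_equal(unname(got[order(got[, 1]), , drop = FALSE]),
                           unname(oracle_matrix[order(oracle_matrix[, 1]), ,
                                                drop = FALSE]))
  }
}

# a free-standing alanine-like residue with coarse backbone geometry
ala_residue <- function(resno = 1L, shift = c(0, 0, 0)) {
  tibble::tibble(
    residue_index = resno, residue_name = "ALA",
    atom_name = c("N", "CA", "C", "O", "CB"),
    x = c(0, 1.46, 2.0, 1.5, 2.0) + shift[1],
    y = c(0, 0, 1.3, 2.4, -0.8) + shift[2],
    z = c(0, 0, 0, 0, 1.2) + shift[3],
    chain = "A")
}

# oracle wrapper honouring the package's documented canonical input order
# (shorter sequence first; ties broken lexicographically), under which the
# alignment statistics are defined
nw_oracle_canonical <- function(a, b, ...) {
  if (nchar(a) > nchar(b) || (nchar(a) == nchar(b) && a > b)) {
    nw_oracle(b, a, ...)
  } else {
    nw_oracle(a, b, ...)
  }
}
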