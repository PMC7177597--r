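# Global alignment (needle-style), per-species deduplication, and distance
# matrices. The substitution matrix is BLOSUM62 with the X row/column set
# to 0 (X scores 0 against everything, the package-wide convention).

pac_substitution_matrix <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      env <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = env)
      m <- env$BLOSUM62
      m["X", ] <- 0L
      m[, "X"] <- 0L
      cache <<- m
    }
    cache
  }
})

score_lookup <- function(chars_a, chars_b) {
  m <- pac_substitution_matrix()
  a <- chars_a
  b <- chars_b
  a[!a %in% rownames(m)] <- "X"
  b[!b %in% rownames(m)] <- "X"
  m[a, b, drop = FALSE]
}

# Gotoh global alignment. Gap of length L costs open + L * extend; gap
# states extend themselves or open from the match state. Traceback prefers
# diagonal, then up (gap in b), then left (gap in a).
nw_affine <- function(a, b, gap_open, gap_extend) {
  ca <- seq_chars(a)
  cb <- seq_chars(b)
  n <- length(ca)
  m <- length(cb)
  S <- score_lookup(ca, cb)
  NEG <- -1e18
  M <- matrix(NEG, n + 1L, m + 1L)
  Ix <- matrix(NEG, n + 1L, m + 1L)  # gap in b (consume a; "up")
  Iy <- matrix(NEG, n + 1L, m + 1L)  # gap in a (consume b; "left")
  M[1, 1] <- 0
  if (n > 0) Ix[2:(n + 1L), 1] <- -(gap_open + gap_extend * (1:n))
  if (m > 0) Iy[1, 2:(m + 1L)] <- -(gap_open + gap_extend * (1:m))
  og <- gap_open + gap_extend
  # pointers: 1 = from M, 2 = from Ix, 3 = from Iy
  pM <- matrix(0L, n + 1L, m + 1L)
  pX <- matrix(0L, n + 1L, m + 1L)
  pY <- matrix(0L, n + 1L, m + 1L)
  for (i in seq_len(n)) {
    Mi1 <- M[i, ]; Xi1 <- Ix[i, ]; Yi1 <- Iy[i, ]
    Mi <- M[i + 1L, ]; Xi <- Ix[i + 1L, ]; Yi <- Iy[i + 1L, ]
    pMi <- pM[i + 1L, ]; pXi <- pX[i + 1L, ]; pYi <- pY[i + 1L, ]
    for (j in seq_len(m)) {
      # M
      cand <- c(Mi1[j], Xi1[j], Yi1[j])
      k <- which.max(cand)
      Mi[j + 1L] <- cand[k] + S[i, j]
      pMi[j + 1L] <- k
      # Ix: consume a_i
      o <- Mi1[j + 1L] - og
      e <- Xi1[j + 1L] - gap_extend
      if (o >= e) { Xi[j + 1L] <- o; pXi[j + 1L] <- 1L }
      else { Xi[j + 1L] <- e; pXi[j + 1L] <- 2L }
      # Iy: consume b_j
      o <- Mi[j] - og
      e <- Yi[j] - gap_extend
      if (o >= e) { Yi[j + 1L] <- o; pYi[j + 1L] <- 1L }
      else { Yi[j + 1L] <- e; pYi[j + 1L] <- 3L }
    }
    M[i + 1L, ] <- Mi; Ix[i + 1L, ] <- Xi; Iy[i + 1L, ] <- Yi
    pM[i + 1L, ] <- pMi; pX[i + 1L, ] <- pXi; pY[i + 1L, ] <- pYi
  }
  fin <- c(M[n + 1L, m + 1L], Ix[n + 1L, m + 1L], Iy[n + 1L, m + 1L])
  state <- which.max(fin)
  score <- fin[state]
  # traceback
  ra <- character(0)
  rb <- character(0)
  i <- n; j <- m
  while (i > 0 || j > 0) {
    if (i == 0) state <- 3L
    if (j == 0) state <- 2L
    if (state == 1L) {
      prev <- pM[i + 1L, j + 1L]
      ra <- c(ca[i], ra); rb <- c(cb[j], rb)
      i <- i - 1L; j <- j - 1L
      state <- prev
    } else if (state == 2L) {
      prev <- if (i >= 1 && j >= 0 && (i + 1L) <= n + 1L) pX[i + 1L, j + 1L] else 2L
      if (prev == 0L) prev <- 2L
      ra <- c(ca[i], ra); rb <- c("-", rb)
      i <- i - 1L
      state <- prev
    } else {
      prev <- pY[i + 1L, j + 1L]
      if (prev == 0L) prev <- 3L
      ra <- c("-", ra); rb <- c(cb[j], rb)
      j <- j - 1L
      state <- prev
    }
  }
  list(score = score, aligned_a = paste(ra, collapse = ""),
       aligned_b = paste(rb, collapse = ""))
}

#' Global pairwise alignment with EMBOSS-style statistics
#'
#' Needleman-Wunsch global alignment with affine gaps (defaults: open 10,
#' extend 0.5, BLOSUM62 with X scoring 0 against everything). Identity is
#' the fraction of identical columns over the alignment length; similarity
#' the fraction of columns whose substitution score is positive (the
#' EMBOSS definition). Traceback tie-breaks prefer diagonal, then up, then
#' left; inputs are ordered canonically internally so the statistics are
#' symmetric in `a` and `b`.
#'
#' @param a,b Non-empty amino-acid strings.
#' @param gap_open,gap_extend Affine gap parameters; a gap of length L
#'   costs `gap_open + L * gap_extend`.
#' @return A one-row tibble: `identity_pct`, `similarity_pct`, `length`
#'   (alignment columns), `gaps` (gap columns), `score`, `aligned_a`,
#'   `aligned_b`.
#' @examples
#' global_align("GCCAATGGG", "GCCAATGG")
#' @export
global_align <- function(a, b, gap_open = 10, gap_extend = 0.5) {
  assert_that(is.character(a) && length(a) == 1 && nzchar(a),
              "sequence a must be a non-empty string")
  assert_that(is.character(b) && length(b) == 1 && nzchar(b),
              "sequence b must be a non-empty string")
  a <- toupper(a)
  b <- toupper(b)
  swapped <- (nchar(a) > nchar(b)) || (nchar(a) == nchar(b) && a > b)
  al <- if (swapped) nw_affine(b, a, gap_open, gap_extend)
        else nw_affine(a, b, gap_open, gap_extend)
  xa <- if (swapped) al$aligned_b else al$aligned_a
  xb <- if (swapped) al$aligned_a else al$aligned_b
  va <- seq_chars(xa)
  vb <- seq_chars(xb)
  len <- length(va)
  gap <- va == "-" | vb == "-"
  ident <- sum(!gap & va == vb)
  m <- pac_substitution_matrix()
  va2 <- va; vb2 <- vb
  va2[!va2 %in% rownames(m)] <- "X"
  vb2[!vb2 %in% rownames(m)] <- "X"
  pos <- sum(m[cbind(va2[!gap], vb2[!gap])] > 0)
  tibble::tibble(identity_pct = 100 * ident / len,
                 similarity_pct = 100 * pos / len,
                 length = len, gaps = sum(gap), score = al$score,
                 aligned_a = xa, aligned_b = xb)
}

#' All pairwise identities within a record set
#'
#' @param records Protein records.
#' @return A tibble `id_a`, `id_b`, `identity`, `similarity` over all
#'   unordered pairs.
#' @export
pairwise_identities <- function(records) {
  records <- as_protein_records(records)
  n <- nrow(records)
  if (n < 2) {
    return(tibble::tibble(id_a = character(), id_b = character(),
                          identity = numeric(), similarity = numeric()))
  }
  pairs <- utils::combn(n, 2)
  rows <- purrr::map(seq_len(ncol(pairs)), function(k) {
    i <- pairs[1, k]; j <- pairs[2, k]
    al <- global_align(records$sequence[i], records$sequence[j])
    tibble::tibble(id_a = records$id[i], id_b = records$id[j],
                   identity = al$identity_pct, similarity = al$similarity_pct)
  })
  dplyr::bind_rows(rows)
}

# minimal union-find
uf_new <- function(n) seq_len(n)
uf_find <- function(p, i) { while (p[i] != i) i <- p[i]; i }
uf_union <- function(p, i, j) {
  ri <- uf_find(p, i); rj <- uf_find(p, j)
  if (ri != rj) p[max(ri, rj)] <- min(ri, rj)
  p
}

#' Deduplicate near-identical domains within species
#'
#' Single-linkage clustering at `identity >= threshold` within each
#' species; each cluster is represented by its longest member (ties broken
#' by the lexicographically smallest id). Mirrors the published selection
#' rule that only domains under 85% mutual identity within a species are
#' retained.
#'
#' @param records Protein records, optionally with a `species` column (one
#'   species assumed otherwise).
#' @param threshold Identity threshold in percent (default 85).
#' @return A list with `representatives` (record tibble in input order) and
#'   `clusters` (tibble `id`, `species`, `cluster`, `representative`).
#' @export
dedupe <- function(records, threshold = 85) {
  records <- as_protein_records_species(records)
  clusters <- purrr::map(split(seq_len(nrow(records)), records$species),
    function(idx) {
      k <- length(idx)
      p <- uf_new(k)
      if (k >= 2) {
        pr <- utils::combn(k, 2)
        for (c in seq_len(ncol(pr))) {
          i <- pr[1, c]; j <- pr[2, c]
          al <- global_align(records$sequence[idx[i]], records$sequence[idx[j]])
          if (al$identity_pct >= threshold) p <- uf_union(p, i, j)
        }
      }
      roots <- vapply(seq_len(k), function(i) uf_find(p, i), integer(1))
      tibble::tibble(row = idx, root = roots)
    })
  cl <- dplyr::bind_rows(clusters, .id = "species")
  cl$cluster <- paste0(cl$species, ":", cl$root)
  reps <- dplyr::group_map(dplyr::group_by(cl, .data$cluster), function(g, key) {
    rows <- g$row
    len <- nchar(records$sequence[rows])
    cand <- rows[len == max(len)]
    rep_row <- cand[order(records$id[cand])][1]
    tibble::tibble(cluster = key$cluster, representative = records$id[rep_row],
                   row = rows)
  })
  reps <- dplyr::bind_rows(reps)
  cl$representative <- reps$representative[match(cl$cluster, reps$cluster)]
  rep_ids <- unique(cl$representative)
  representatives <- records[records$id %in% rep_ids, ]
  list(representatives = representatives,
       clusters = tibble::tibble(id = records$id[cl$row],
                                 species = records$species[cl$row],
                                 cluster = cl$cluster,
                                 representative = cl$representative))
}

as_protein_records_species <- function(records) {
  has_species <- is.data.frame(records) && "species" %in% names(records)
  sp <- if (has_species) as.character(records$species) else NULL
  out <- as_protein_records(records)
  out$species <- sp %||% rep("species1", nrow(out))
  out
}

#' Pairwise distance matrix (100 - identity)
#'
#' @param records Protein records (>= 2).
#' @return A symmetric numeric matrix with zero diagonal and record ids as
#'   dimnames.
#' @export
distance_matrix <- function(records) {
  records <- as_protein_records(records)
  assert_that(nrow(records) >= 2, "need at least two records")
  ids <- records$id
  d <- matrix(0, nrow(records), nrow(records), dimnames = list(ids, ids))
  pi <- pairwise_identities(records)
  for (k in seq_len(nrow(pi))) {
    d[pi$id_a[k], pi$id_b[k]] <- 100 - pi$identity[k]
    d[pi$id_b[k], pi$id_a[k]] <- 100 - pi$identity[k]
  }
  d
}

#' Write a distance matrix in PHYLIP square format
#'
#' Feeds external tree-building tools; names are truncated/padded to 10
#' characters as the classic format requires.
#'
#' @param d A square distance matrix with dimnames.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_phylip_dist <- function(d, path) {
  assert_that(is.matrix(d) && nrow(d) == ncol(d), "d must be square")
  nm <- formatC(substr(rownames(d), 1, 10), width = -10)
  lines <- c(format(nrow(d), width = 5),
             vapply(seq_len(nrow(d)), function(i) {
               paste0(nm[i], paste(formatC(d[i, ], format = "f", digits = 4),
                                   collapse = "  "))
             }, character(1)))
  writeLines(lines, path)
  invisible(path)
}
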