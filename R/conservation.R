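# Per-column conservation profiles, consensus, PROSITE-subset pattern
# matching, and mapping of conservation onto structural accessibility.

#' Build a conservation profile from a multiple alignment
#'
#' Per-column residue frequencies (20 amino acids + gap; anything else
#' counts as gap), information content, and a consensus string. The
#' information content of a column is `log2(20)` minus the Shannon entropy
#' of its gap-excluded frequency vector, scaled by the non-gap fraction so
#' gappy columns score low. The consensus is the plurality residue among
#' non-gap entries, or `x` when its (gap-excluded) frequency is below 0.5,
#' or `-` for all-gap columns.
#'
#' @param alignment Aligned sequences: a character vector (equal lengths,
#'   gaps as `-`) or a record tibble whose `sequence` column is aligned.
#' @return An object of class `pac_profile`: list with `freqs` (21 x L
#'   matrix), `ic` (length-L numeric, bits), `consensus` (string),
#'   `n_seqs`.
#' @export
build_profile <- function(alignment) {
  if (is.data.frame(alignment)) alignment <- alignment$sequence
  assert_that(is.character(alignment) && length(alignment) >= 2,
              "alignment needs at least two sequences")
  alignment <- toupper(alignment)
  lens <- nchar(alignment)
  assert_that(length(unique(lens)) == 1, "ragged alignment: unequal row lengths")
  L <- lens[1]
  mat <- do.call(rbind, strsplit(alignment, "", fixed = TRUE))
  mat[!mat %in% AA20] <- "-"
  lv <- c(AA20, "-")
  freqs <- apply(mat, 2, function(col) {
    tabulate(factor(col, levels = lv), nbins = 21L) / length(col)
  })
  rownames(freqs) <- lv
  nongap <- 1 - freqs["-", ]
  ic <- vapply(seq_len(L), function(j) {
    p <- freqs[1:20, j]
    if (nongap[j] <= 0) return(0)
    p <- p / nongap[j]
    p <- p[p > 0]
    (log2(20) + sum(p * log2(p))) * nongap[j]
  }, numeric(1))
  consensus <- vapply(seq_len(L), function(j) {
    if (nongap[j] <= 0) return("-")
    p <- freqs[1:20, j] / nongap[j]
    k <- which.max(p)
    if (p[k] >= 0.5) AA20[k] else "x"
  }, character(1))
  structure(list(freqs = freqs, ic = ic,
                 consensus = paste(consensus, collapse = ""),
                 n_seqs = length(alignment)),
            class = "pac_profile")
}

#' @export
print.pac_profile <- function(x, ...) {
  cat("<pac_profile> ", length(x$ic), " columns, ", x$n_seqs, " sequences\n",
      "consensus: ", x$consensus, "\n",
      "mean IC: ", round(mean(x$ic), 3), " bits\n", sep = "")
  invisible(x)
}

#' Most conserved window of a profile
#'
#' @param profile A [build_profile()] object.
#' @param width Window width in columns.
#' @return A one-row tibble `start`, `end`, `mean_ic` (ties resolved to the
#'   leftmost window).
#' @export
top_motif <- function(profile, width) {
  ic <- profile$ic
  assert_that(width >= 1 && width <= length(ic),
              "width must be between 1 and the profile length")
  cs <- cumsum(c(0, ic))
  means <- (cs[(width + 1):(length(ic) + 1)] - cs[1:(length(ic) - width + 1)]) / width
  s <- which(means >= max(means) - 1e-9)[1]  # leftmost on (numerical) ties
  tibble::tibble(start = as.integer(s), end = as.integer(s + width - 1L),
                 mean_ic = means[s])
}

# parse a PROSITE-subset pattern into a list of element matchers
parse_prosite <- function(pattern) {
  toks <- strsplit(pattern, "-", fixed = TRUE)[[1]]
  assert_that(length(toks) > 0 && all(nzchar(toks)),
              "malformed pattern: empty element")
  lapply(seq_along(toks), function(i) {
    tok <- toks[i]
    m <- regmatches(tok, regexec("^(\\[([A-Za-z]+)\\]|[A-Za-z])(\\((\\d+)(,(\\d+))?\\))?$", tok))[[1]]
    assert_that(length(m) > 0,
                paste0("malformed pattern element ", i, ": '", tok, "'"))
    body <- m[2]
    lo <- if (nzchar(m[5])) as.integer(m[5]) else 1L
    hi <- if (nzchar(m[7])) as.integer(m[7]) else lo
    assert_that(lo <= hi, paste0("malformed repeat in element ", i))
    set <- if (startsWith(body, "[")) seq_chars(toupper(m[3]))
           else if (toupper(body) == "X") NULL  # wildcard
           else toupper(body)
    list(set = set, lo = lo, hi = hi)
  })
}

#' Match a PROSITE-style pattern
#'
#' Supports the syntax subset: single residues, `[SET]` alternatives, `x`
#' wildcards, and `(n)` / `(n,m)` repeats on any element. All match
#' locations are returned, including overlapping ones and, for variable
#' repeats, multiple lengths from the same start.
#'
#' @param seq Amino-acid string.
#' @param pattern PROSITE pattern, e.g. `"[EQT]-G-x-V-Y-C-D-[TNP]-C-R"`.
#' @return A tibble `start`, `end` (1-based inclusive).
#' @export
match_prosite <- function(seq, pattern) {
  elems <- parse_prosite(pattern)
  ch <- seq_chars(toupper(seq))
  n <- length(ch)
  hits <- list()
  match_from <- function(pos, k) {
    if (k > length(elems)) {
      hits[[length(hits) + 1L]] <<- c(start = NA_integer_, end = pos - 1L)
      return(invisible())
    }
    el <- elems[[k]]
    for (rep in el$lo:el$hi) {
      if (pos + rep - 1L > n) break
      ok <- if (is.null(el$set)) TRUE else all(ch[pos:(pos + rep - 1L)] %in% el$set)
      if (rep == 0L) ok <- TRUE
      if (ok) match_from(pos + rep, k + 1L)
    }
  }
  out <- list()
  for (s in seq_len(n)) {
    hits <- list()
    match_from(s, 1L)
    for (h in hits) out[[length(out) + 1L]] <- c(s, h["end"])
  }
  if (length(out) == 0) {
    return(tibble::tibble(start = integer(), end = integer()))
  }
  m <- do.call(rbind, out)
  res <- tibble::tibble(start = as.integer(m[, 1]), end = as.integer(m[, 2]))
  dplyr::distinct(dplyr::arrange(res, .data$start, .data$end))
}

#' Map conservation onto solvent accessibility and secondary structure
#'
#' Aligns a profile with per-residue relative solvent accessibility (RSA)
#' and secondary-structure tracks of a representative sequence. Columns
#' that are gaps in the representative carry `NA` tracks. Conserved buried
#' columns are labelled `core`; conserved exposed columns
#' `candidate_functional_site`.
#'
#' @param profile A [build_profile()] object.
#' @param representative The representative's aligned row (string with
#'   gaps) matching the profile columns.
#' @param rsa Numeric RSA per representative residue (ungapped length).
#' @param ss Secondary-structure string (H/E/C) per representative residue.
#' @param rsa_buried RSA below which a residue is buried (default 0.2).
#' @param ic_conserved IC (bits) at or above which a column counts as
#'   conserved (default 2).
#' @return A tibble with one row per column: `column`, `consensus`, `ic`,
#'   `residue`, `rsa`, `ss`, `buried`, `label`.
#' @export
map_accessibility <- function(profile, representative, rsa, ss,
                              rsa_buried = 0.2, ic_conserved = 2) {
  cols <- length(profile$ic)
  rep_ch <- seq_chars(toupper(representative))
  assert_that(length(rep_ch) == cols,
              "representative row length differs from the profile")
  res_idx <- cumsum(rep_ch != "-")
  n_res <- max(res_idx)
  ss_ch <- seq_chars(toupper(ss))
  assert_that(length(rsa) == n_res && length(ss_ch) == n_res,
              "rsa/ss track length differs from the representative sequence")
  is_gap <- rep_ch == "-"
  rsa_col <- ifelse(is_gap, NA_real_, rsa[res_idx])
  ss_col <- ifelse(is_gap, NA_character_, ss_ch[res_idx])
  buried <- !is.na(rsa_col) & rsa_col < rsa_buried
  conserved <- profile$ic >= ic_conserved
  label <- dplyr::case_when(
    is_gap ~ NA_character_,
    conserved & buried ~ "core",
    conserved & !buried ~ "candidate_functional_site",
    TRUE ~ "other"
  )
  tibble::tibble(column = seq_len(cols),
                 consensus = seq_chars(profile$consensus),
                 ic = profile$ic,
                 residue = ifelse(is_gap, NA_character_, rep_ch),
                 rsa = rsa_col, ss = ss_col, buried = buried, label = label)
}

#' Export a logo-ready frequency matrix
#'
#' @param profile A [build_profile()] object.
#' @param path Output TSV path (columns = alignment columns, rows = 20
#'   residues; gap row excluded).
#' @return `path`, invisibly.
#' @export
write_profile_tsv <- function(profile, path) {
  m <- profile$freqs[1:20, , drop = FALSE]
  df <- data.frame(residue = rownames(m), m, check.names = FALSE)
  names(df)[-1] <- paste0("col", seq_len(ncol(m)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
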