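# Bona fide gates: signal peptide, secondary-structure admissibility,
# foreign functional domains. All three accept precomputed external
# prediction tables; built-in heuristics are used otherwise.

# Chou-Fasman conformational propensities (helix, strand, turn); the turn
# column doubles as the coil propensity in the three-state fallback.
chou_fasman <- local({
  m <- matrix(c(
    1.42, 0.83, 0.66,  # A
    0.98, 0.93, 0.95,  # R
    0.67, 0.89, 1.56,  # N
    1.01, 0.54, 1.46,  # D
    0.70, 1.19, 1.19,  # C
    1.11, 1.10, 0.98,  # Q
    1.51, 0.37, 0.74,  # E
    0.57, 0.75, 1.56,  # G
    1.00, 0.87, 0.95,  # H
    1.08, 1.60, 0.47,  # I
    1.21, 1.30, 0.59,  # L
    1.16, 0.74, 1.01,  # K
    1.45, 1.05, 0.60,  # M
    1.13, 1.38, 0.60,  # F
    0.57, 0.55, 1.52,  # P
    0.77, 0.75, 1.43,  # S
    0.83, 1.19, 0.96,  # T
    1.08, 1.37, 0.96,  # W
    0.69, 1.47, 1.14,  # Y
    1.06, 1.70, 0.50   # V
  ), ncol = 3, byrow = TRUE,
  dimnames = list(c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                    "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V"),
                  c("H", "E", "C")))
  m
})

SP_HYDROPHOBIC <- c("A", "I", "L", "F", "V", "M", "W", "C")

#' Signal-peptide gate
#'
#' Uses a supplied prediction table when given; otherwise a built-in
#' heuristic: within residues 1-35 there must be an 8-residue window with at
#' least 6 hydrophobic residues (`A,I,L,F,V,M,W,C`; the h-region), preceded
#' by an n-region of net charge >= 0 (`K,R` = +1, `D,E` = -1). Records from
#' translated frames lacking an initial Met are reported `unknown` (the
#' sequence may be an incomplete fragment), and `unknown` does not exclude a
#' candidate downstream.
#'
#' @param records Protein records.
#' @param table Optional tibble `record_id`, `verdict` from an external
#'   predictor; its verdicts override the heuristic.
#' @return A tibble `record_id`, `signal_peptide` with values
#'   `pass`/`fail`/`unknown`.
#' @export
signal_peptide_gate <- function(records, table = NULL) {
  records <- as_protein_records(records)
  if (!is.null(table)) {
    assert_that(all(c("record_id", "verdict") %in% names(table)),
                "prediction table needs record_id and verdict columns")
    unknown_ids <- setdiff(table$record_id, records$id)
    assert_that(length(unknown_ids) == 0,
                paste0("prediction table references unknown record(s): ",
                       paste(utils::head(unknown_ids, 5), collapse = ", ")))
  }
  heuristic <- function(sq, src) {
    ch <- seq_chars(sq)
    if (src == "translated_frame" && ch[1] != "M") return("unknown")
    lim <- min(length(ch), 35L)
    if (lim < 8L) return("fail")
    hyd <- ch %in% SP_HYDROPHOBIC
    chg <- (ch %in% c("K", "R")) - (ch %in% c("D", "E"))
    for (w in 1:(lim - 7L)) {
      if (sum(hyd[w:(w + 7L)]) >= 6L) {
        net <- if (w == 1L) 0L else sum(chg[1:(w - 1L)])
        if (net >= 0L) return("pass")
      }
    }
    "fail"
  }
  verdict <- purrr::map2_chr(records$sequence, records$source, heuristic)
  if (!is.null(table)) {
    idx <- match(records$id, table$record_id)
    verdict <- ifelse(is.na(idx), verdict, as.character(table$verdict)[idx])
  }
  tibble::tibble(record_id = records$id, signal_peptide = verdict)
}

#' Secondary-structure admissibility of PAC matches
#'
#' A match span is admissible when it contains at least `min_strands`
#' strand segments (runs of `E`) of length >= `min_strand_len` and its
#' helix fraction is at most `max_helix_frac`. This is the package's
#' quantification of the qualitative exclusion rule "no predicted
#' beta-sheets / large predicted alpha-helices".
#'
#' @param matches A match tibble from [scan_strict()]/[scan_relaxed()].
#' @param ss_tracks Tibble `record_id`, `ss` (H/E/C strings), e.g. from
#'   [predict_ss_fallback()] or [read_ss_tracks()].
#' @param records Optional protein records; when given, track lengths are
#'   checked against sequence lengths.
#' @param min_strand_len,min_strands,max_helix_frac Gate parameters.
#' @return `matches` with added columns `n_strands`, `helix_frac`,
#'   `ss_admissible` (`"pass"`/`"fail"`).
#' @export
ss_admissible <- function(matches, ss_tracks, records = NULL,
                          min_strand_len = 3L, min_strands = 3L,
                          max_helix_frac = 0.5) {
  assert_that(all(c("record_id", "ss") %in% names(ss_tracks)),
              "ss_tracks needs record_id and ss columns")
  if (!is.null(records)) {
    records <- as_protein_records(records)
    j <- match(ss_tracks$record_id, records$id)
    bad <- which(!is.na(j) & nchar(ss_tracks$ss) != nchar(records$sequence[j]))
    assert_that(length(bad) == 0,
                paste0("ss track length differs from sequence length for: ",
                       paste(utils::head(ss_tracks$record_id[bad], 5), collapse = ", ")))
  }
  idx <- match(matches$record_id, ss_tracks$record_id)
  assert_that(!anyNA(idx), "every match needs an ss track")
  res <- purrr::pmap(list(idx, matches$span_start, matches$span_end),
    function(i, s, e) {
      ss <- ss_tracks$ss[i]
      assert_that(e <= nchar(ss), "ss track does not cover the match span")
      sub <- seq_chars(substr(ss, s, e))
      r <- rle(sub)
      n_str <- sum(r$values == "E" & r$lengths >= min_strand_len)
      hfrac <- mean(sub == "H")
      list(n_str, hfrac)
    })
  matches$n_strands <- purrr::map_int(res, function(x) as.integer(x[[1]]))
  matches$helix_frac <- purrr::map_dbl(res, function(x) x[[2]])
  matches$ss_admissible <- ifelse(
    matches$n_strands >= min_strands & matches$helix_frac <= max_helix_frac,
    "pass", "fail")
  matches
}

#' Built-in fallback secondary-structure predictor
#'
#' Deterministic three-state prediction from Chou-Fasman propensities: each
#' residue's helix/strand/turn propensities are averaged over a centred
#' window of 5 and the arg-max state is assigned (ties prefer coil, then
#' strand). A stand-in for sequence-only workflows; external predictions
#' should be supplied through [read_ss_tracks()] when available.
#'
#' @param records Protein records.
#' @param window Smoothing window (odd, default 5).
#' @return A tibble `record_id`, `ss`.
#' @export
predict_ss_fallback <- function(records, window = 5L) {
  records <- as_protein_records(records)
  half <- window %/% 2L
  pred1 <- function(sq) {
    ch <- seq_chars(sq)
    n <- length(ch)
    idx <- match(ch, rownames(chou_fasman))
    prop <- matrix(1, n, 3)  # unknown residues (X, *) are neutral
    known <- !is.na(idx)
    prop[known, ] <- chou_fasman[idx[known], ]
    sm <- apply(prop, 2, function(v) {
      cs <- cumsum(c(0, v))
      lo <- pmax(seq_len(n) - half, 1L)
      hi <- pmin(seq_len(n) + half, n)
      (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
    })
    # prefer C, then E, then H on ties
    pick <- max.col(cbind(sm[, 3], sm[, 2], sm[, 1]), ties.method = "first")
    paste(c("C", "E", "H")[pick], collapse = "")
  }
  tibble::tibble(record_id = records$id,
                 ss = vapply(records$sequence, pred1, character(1), USE.NAMES = FALSE))
}

#' Foreign functional-domain gate
#'
#' A record fails when any external domain hit at or below `evalue_max` has
#' an accession outside the allow list. The default allow list contains the
#' PAC/Ole e 1 accessions (PF01190, PS00925) and the package's own
#' associated-domain kinds, so only genuinely foreign functional domains
#' (e.g. PF00171 aldehyde dehydrogenase, PF02373 JmjC) exclude a candidate.
#'
#' @param records Protein records.
#' @param hits Domain-hit tibble (see [read_domain_hits()]).
#' @param allow_list Character vector of permitted accessions.
#' @param evalue_max Maximum e-value for a hit to count (default 1e-5).
#' @return A tibble `record_id`, `foreign_domain` (`"pass"`/`"fail"`).
#' @export
foreign_domain_gate <- function(records, hits,
                                allow_list = pac_allowed_accessions(),
                                evalue_max = 1e-5) {
  records <- as_protein_records(records)
  bad <- hits[hits$evalue <= evalue_max & !hits$accession %in% allow_list, ]
  tibble::tibble(record_id = records$id,
                 foreign_domain = ifelse(records$id %in% bad$record_id,
                                         "fail", "pass"))
}

#' Default allow list for the foreign-domain gate
#' @return Character vector of accessions/kinds that never exclude a record.
#' @export
pac_allowed_accessions <- function() {
  c("PF01190", "PS00925",
    "extensin", "pro_rich", "his_rich", "agp_like", "ww",
    "signal_peptide", "pac")
}
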