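#' Coerce input to a protein record tibble
#'
#' Accepts a (possibly named) character vector of sequences or a data frame
#' with at least `id` and `sequence` columns, and returns the canonical
#' record tibble used throughout the package.
#'
#' @param x Character vector or data frame.
#' @return A tibble with columns `id`, `description`, `sequence`, `source`,
#'   `frame`.
#' @export
as_protein_records <- function(x) {
  if (is.character(x)) {
    ids <- names(x) %||% paste0("seq", seq_along(x))
    if (is.null(names(x)) && length(x) == 1) ids <- "seq1"
    x <- tibble::tibble(id = ids, sequence = unname(x))
  }
  assert_that(is.data.frame(x), "records must be a data frame or character vector")
  if (!"id" %in% names(x) && "record_id" %in% names(x)) {
    x$id <- x$record_id
  }
  assert_that(all(c("id", "sequence") %in% names(x)),
              "records need `id` and `sequence` columns")
  assert_that(!anyDuplicated(x$id), "record ids must be unique")
  assert_that(all(nzchar(x$sequence)), "sequences must be non-empty")
  tibble::tibble(
    id = as.character(x$id),
    description = if ("description" %in% names(x)) as.character(x$description) else "",
    sequence = toupper(as.character(x$sequence)),
    source = if ("source" %in% names(x)) as.character(x$source) else "protein",
    frame = if ("frame" %in% names(x)) as.integer(x$frame) else NA_integer_
  )
}

empty_match_tbl <- function() {
  tibble::tibble(
    record_id = character(), mode = character(), gly_pos = integer(),
    c1 = integer(), c2 = integer(), c3 = integer(),
    c4 = integer(), c5 = integer(), c6 = integer(),
    sp1 = integer(), sp2 = integer(), sp3 = integer(),
    sp4 = integer(), sp5 = integer(),
    span_start = integer(), span_end = integer(), span_len = integer(),
    cys_in_span = integer(), violations = character()
  )
}

match_row <- function(id, mode, gly, cys, sp, span, n_c_in_span, viol) {
  tibble::tibble(
    record_id = id, mode = mode, gly_pos = gly,
    c1 = cys[1], c2 = cys[2], c3 = cys[3], c4 = cys[4], c5 = cys[5], c6 = cys[6],
    sp1 = sp[1], sp2 = sp[2], sp3 = sp[3], sp4 = sp[4], sp5 = sp[5],
    span_start = span[1], span_end = span[2], span_len = span[2] - span[1] + 1L,
    cys_in_span = n_c_in_span, violations = join_violations(viol)
  )
}

# strict scan of one residue vector; returns list of match rows
scan_strict_chars <- function(chars, rule, id) {
  n <- length(chars)
  cpos <- which(chars == "C")
  if (length(cpos) < 6) return(list())
  cumC <- cumsum(chars == "C")
  cumS <- cumsum(chars == "*")
  # no C and no '*' strictly between positions a and b
  free <- function(a, b) {
    if (b - a <= 1L) return(TRUE)
    (cumC[b - 1L] - cumC[a]) == 0L && (cumS[b - 1L] - cumS[a]) == 0L
  }
  ranged <- ranged_gaps(rule)
  out <- list()
  for (g in which(chars == "G")) {
    c1 <- g + rule$gap_gly_c1 + 1L
    if (c1 > n || chars[c1] != "C" || !free(g, c1)) next
    c2 <- c1 + rule$gap_c1_c2 + 1L
    if (c2 > n || chars[c2] != "C" || !free(c1, c2)) next
    cys <- c(c1, c2)
    cur <- c2
    ok <- TRUE
    for (k in seq_along(ranged)) {
      idx <- findInterval(cur, cpos) + 1L  # next Cys strictly after cur
      if (idx > length(cpos)) { ok <- FALSE; break }
      nxt <- cpos[idx]
      sp <- nxt - cur - 1L
      if (sp < ranged[[k]][1] || sp > ranged[[k]][2] ||
          (cumS[nxt - 1L] - cumS[cur]) != 0L) { ok <- FALSE; break }
      cys <- c(cys, nxt)
      cur <- nxt
    }
    if (!ok) next
    out[[length(out) + 1L]] <- match_row(
      id, "strict", g, cys, diff(cys) - 1L, c(g, cys[6]), 6L, character()
    )
  }
  out
}

#' Strict PAC domain scan
#'
#' Finds every bona fide PAC domain match in each record: a Gly anchor, six
#' downstream Cys residues, Cys-free spacers with lengths inside the rule's
#' bounds, and no stop codon (`*`) anywhere in the span. With Cys-free
#' spacers the Cys chain from a given anchor is forced, so matches are
#' enumerated left to right by Gly anchor.
#'
#' @param records Protein records (see [as_protein_records()]).
#' @param rule A [pac_rule()].
#' @return A tibble with one row per match: `record_id`, `mode`, `gly_pos`,
#'   `c1`..`c6` (1-based residue positions), spacer lengths `sp1`..`sp5`,
#'   `span_start`/`span_end`/`span_len` (1-based inclusive, Gly through
#'   Cys6), `cys_in_span`, and an empty `violations` string.
#' @examples
#' seq <- paste0("G", strrep("A", 3), "C", strrep("A", 2), "C",
#'               strrep("A", 10), "C", strrep("A", 20), "C",
#'               strrep("A", 8), "C", strrep("A", 25), "C")
#' scan_strict(c(toy = seq))
#' @export
scan_strict <- function(records, rule = pac_rule()) {
  records <- as_protein_records(records)
  rows <- purrr::map2(records$id, records$sequence, function(id, s) {
    scan_strict_chars(seq_chars(s), rule, id)
  })
  out <- dplyr::bind_rows(empty_match_tbl(), purrr::flatten(rows))
  out
}

#' Tolerances for the relaxed PAC scan
#'
#' @param missing_gly Admit matches whose Gly anchor is absent (the residue
#'   at the expected position is not Gly). Such matches report `gly_pos = NA`
#'   and a `missing_gly` violation.
#' @param max_extra_cys Number of surplus Cys residues admitted inside the
#'   spacers, in total (0-3). Seven-, eight- and nine-Cys variants.
#' @param max_missing_cys Admit up to one absent interior Cys (ordinals 2-5);
#'   the two adjacent spacers merge and the missing ordinal is `NA`.
#' @param gap_slack Per-gap slack: each spacer bound is widened by this many
#'   residues on each side; out-of-bounds gaps are flagged.
#' @return An object of class `pac_tolerances`.
#' @export
pac_tolerances <- function(missing_gly = FALSE, max_extra_cys = 0L,
                           max_missing_cys = 0L, gap_slack = 0L) {
  max_extra_cys <- as.integer(max_extra_cys)
  max_missing_cys <- as.integer(max_missing_cys)
  gap_slack <- as.integer(gap_slack)
  assert_that(max_extra_cys >= 0 && max_extra_cys <= 3,
              "max_extra_cys must be between 0 and 3")
  assert_that(max_missing_cys >= 0 && max_missing_cys <= 1,
              "max_missing_cys must be 0 or 1")
  assert_that(gap_slack >= 0, "gap_slack must be >= 0")
  structure(list(missing_gly = isTRUE(missing_gly),
                 max_extra_cys = max_extra_cys,
                 max_missing_cys = max_missing_cys,
                 gap_slack = gap_slack),
            class = "pac_tolerances")
}

gap_names <- c("c1_c2", "c2_c3", "c3_c4", "c4_c5", "c5_c6")

# relaxed scan of one residue vector; depth-first enumeration of Cys chains
scan_relaxed_chars <- function(chars, rule, tol, id, max_chains = 64L) {
  n <- length(chars)
  cpos <- which(chars == "C")
  if (length(cpos) < 5) return(list())
  cumC <- cumsum(chars == "C")
  cumS <- cumsum(chars == "*")
  count_c <- function(a, b) {
    if (b - a <= 1L) return(0L)
    cumC[b - 1L] - if (a >= 1L) cumC[a] else 0L
  }
  has_star <- function(a, b) if (b - a <= 1L) FALSE else (cumS[b - 1L] - cumS[a]) > 0L
  gaps <- all_gaps(rule)
  s <- tol$gap_slack
  out <- list()
  truncated <- FALSE

  for (c1 in cpos) {
    chains <- 0L
    gp <- c1 - rule$gap_gly_c1 - 1L
    gly_ok <- gp >= 1L && chars[gp] == "G" && count_c(gp, c1) == 0L &&
      !has_star(gp, c1)
    if (!gly_ok && !tol$missing_gly) next
    base_viol <- if (gly_ok) character() else "missing_gly"
    gly <- if (gly_ok) gp else NA_integer_

    # state: current position, next ordinal to place, budgets, accumulators
    stack <- list(list(cur = c1, ord = 2L, extra = tol$max_extra_cys,
                       miss = tol$max_missing_cys,
                       cys = c(c1, rep(NA_integer_, 5L)),
                       viol = base_viol))
    while (length(stack) > 0) {
      st <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      if (st$ord > 6L) {
        chains <- chains + 1L
        if (chains > max_chains) { truncated <- TRUE; break }
        cys <- st$cys
        span <- c(if (!is.na(gly)) gly else c1, cys[6])
        sp <- rep(NA_integer_, 5L)
        for (k in 1:5) {
          if (!is.na(cys[k]) && !is.na(cys[k + 1])) sp[k] <- cys[k + 1] - cys[k] - 1L
        }
        out[[length(out) + 1L]] <- match_row(
          id, if (length(st$viol) == 0) "strict" else "relaxed",
          gly, cys, sp, span, count_c(span[1] - 1L, span[2] + 1L), st$viol)
        next
      }
      k <- st$ord - 1L  # gap index leading into ordinal st$ord
      # normal step to ordinal st$ord
      lo <- max(0L, gaps[[k]][1] - s)
      hi <- gaps[[k]][2] + s
      idx0 <- findInterval(st$cur, cpos)
      for (idx in seq_len(length(cpos) - idx0)) {
        q <- cpos[idx0 + idx]
        spc <- q - st$cur - 1L
        if (spc > hi) break
        if (spc < lo || has_star(st$cur, q)) next
        e <- count_c(st$cur, q)
        if (e > st$extra) next
        viol <- st$viol
        if (e > 0) viol <- c(viol, paste0("extra_cys_in_spacer:", gap_names[k]))
        if (spc < gaps[[k]][1] || spc > gaps[[k]][2]) {
          viol <- c(viol, paste0("gap_out_of_bounds:", gap_names[k]))
        }
        cys <- st$cys; cys[st$ord] <- q
        stack[[length(stack) + 1L]] <- list(cur = q, ord = st$ord + 1L,
                                            extra = st$extra - e, miss = st$miss,
                                            cys = cys, viol = viol)
      }
      # skip ordinal st$ord (missing interior Cys, ordinals 2-5 only)
      if (st$miss > 0 && st$ord >= 2L && st$ord <= 5L) {
        k2 <- st$ord  # the gap after the skipped ordinal
        lo2 <- max(0L, gaps[[k]][1] + gaps[[k2]][1] + 1L - s)
        hi2 <- gaps[[k]][2] + gaps[[k2]][2] + 1L + s
        for (idx in seq_len(length(cpos) - idx0)) {
          q <- cpos[idx0 + idx]
          spc <- q - st$cur - 1L
          if (spc > hi2) break
          if (spc < lo2 || has_star(st$cur, q)) next
          e <- count_c(st$cur, q)
          if (e > st$extra) next
          viol <- c(st$viol, paste0("missing_cys:c", st$ord))
          if (e > 0) viol <- c(viol, paste0("extra_cys_in_spacer:", gap_names[k]))
          cys <- st$cys; cys[st$ord + 1L] <- q
          stack[[length(stack) + 1L]] <- list(cur = q, ord = st$ord + 2L,
                                              extra = st$extra - e,
                                              miss = st$miss - 1L,
                                              cys = cys, viol = viol)
        }
      }
    }
    if (truncated) break
  }
  if (truncated) {
    warning("relaxed scan: chain enumeration truncated at ", max_chains,
            " chains for an anchor in record ", id, call. = FALSE)
  }
  out
}

#' Relaxed PAC domain scan
#'
#' Like [scan_strict()] but admitting named deviations from the bona fide
#' rule: a missing Gly anchor, up to three surplus Cys inside spacers
#' (7-9 Cys variants), one missing interior Cys (5-Cys variants), and
#' per-gap slack. Every admitted deviation is recorded in the `violations`
#' column; matches with no violations are the strict matches and are
#' reported with `mode = "strict"`.
#'
#' Chain enumeration is depth-first and capped at 64 chains per Cys1 anchor
#' (with a warning on truncation). Chains touching the same residue set are
#' one physical site and are reported once, preferring the interpretation
#' with the fewest violations (a 5-Cys hit, for instance, admits two
#' ordinal readings of the same residues).
#'
#' @inheritParams scan_strict
#' @param tolerances A [pac_tolerances()].
#' @return A match tibble as in [scan_strict()], with `gly_pos` or one of
#'   `c2`..`c5` possibly `NA` and `violations` a semicolon-joined string.
#' @export
scan_relaxed <- function(records, rule = pac_rule(),
                         tolerances = pac_tolerances()) {
  assert_that(inherits(tolerances, "pac_tolerances"),
              "tolerances must be built with pac_tolerances()")
  records <- as_protein_records(records)
  rows <- purrr::map2(records$id, records$sequence, function(id, sq) {
    scan_relaxed_chars(seq_chars(sq), rule, tolerances, id)
  })
  out <- dplyr::bind_rows(empty_match_tbl(), purrr::flatten(rows))
  if (nrow(out) == 0) return(out)
  # one physical site = one report: chains that touch the same residue set
  # (e.g. the two ordinal readings of a 5-Cys hit) are collapsed, keeping
  # the interpretation with the fewest violations
  cysmat <- as.matrix(out[, paste0("c", 1:6)])
  key <- paste(out$record_id, out$gly_pos,
               apply(cysmat, 1, function(r) paste(sort(r[!is.na(r)]),
                                                  collapse = ",")))
  nv <- stringr::str_count(out$violations, ";") + as.integer(nzchar(out$violations))
  ord <- order(key, nv, out$violations)
  out <- out[ord, ]
  out <- out[!duplicated(key[ord]), ]
  out <- dplyr::arrange(out, .data$record_id, .data$span_start, .data$c1)
  out
}
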