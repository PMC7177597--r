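# Associated-domain detectors and the Type 1-4 architecture classifier.
# Detector thresholds quantify qualitative domain descriptions (the field
# names the domains; it does not define detection cutoffs) and are exposed
# as arguments with the package defaults.

ann_tbl <- function(record_id = character(), kind = character(),
                    start = integer(), end = integer(), score = numeric()) {
  tibble::tibble(record_id = record_id, kind = kind,
                 start = as.integer(start), end = as.integer(end),
                 score = as.numeric(score))
}

detect_per_record <- function(records, f) {
  records <- as_protein_records(records)
  rows <- purrr::map2(records$id, records$sequence, f)
  out <- dplyr::bind_rows(ann_tbl(), rows)
  dplyr::arrange(out, .data$record_id, .data$start)
}

#' Detect the W-W domain
#'
#' The W-W domain is a conserved C-terminal domain starting with a
#' Trp-X8-Trp motif. The annotation runs from the first motif anchor at or
#' after `search_from` to the end of the sequence; later anchors overlap it
#' and are absorbed (first anchor wins).
#'
#' @param records Protein records.
#' @param search_from 1-based position from which anchors are considered.
#' @return Annotation tibble `record_id`, `kind`, `start`, `end`, `score`
#'   (score = number of candidate anchors absorbed).
#' @export
detect_ww <- function(records, search_from = 1L) {
  detect_per_record(records, function(id, sq) {
    ch <- seq_chars(sq)
    n <- length(ch)
    w <- which(ch == "W")
    w <- w[w >= search_from & w + 9L <= n]
    w <- w[ch[w + 9L] == "W"]
    if (length(w) == 0) return(NULL)
    ann_tbl(id, "ww", w[1], n, length(w))
  })
}

#' Detect extensin regions
#'
#' Extensin motifs are Ser-(Pro)n with n >= 2. Motif instances whose starts
#' lie within `merge_dist` residues of the previous instance's end are
#' merged; a merged region with at least `min_motifs` instances is reported
#' with score = instance count.
#'
#' @param records Protein records.
#' @param merge_dist Merge distance in residues (default 30).
#' @param min_motifs Minimum motif instances per region (default 3).
#' @return Annotation tibble (kind `"extensin"`).
#' @export
detect_extensin <- function(records, merge_dist = 30L, min_motifs = 3L) {
  detect_per_record(records, function(id, sq) {
    m <- gregexpr("SP{2,}", sq, perl = TRUE)[[1]]
    if (m[1] == -1) return(NULL)
    starts <- as.integer(m)
    ends <- starts + attr(m, "match.length") - 1L
    grp <- cumsum(c(1L, (starts[-1] - ends[-length(ends)]) > merge_dist))
    rows <- lapply(split(seq_along(starts), grp), function(i) {
      if (length(i) < min_motifs) return(NULL)
      ann_tbl(id, "extensin", min(starts[i]), max(ends[i]), length(i))
    })
    dplyr::bind_rows(rows)
  })
}

#' Detect histidine-rich stretches
#'
#' Regions where some 6-residue window contains at least `min_his` His;
#' qualifying windows are unioned and each region is trimmed to its first
#' and last His. Score = His count in the region.
#'
#' @param records Protein records.
#' @param window Window length (default 6).
#' @param min_his Minimum His per window (default 4).
#' @return Annotation tibble (kind `"his_rich"`).
#' @export
detect_his_rich <- function(records, window = 6L, min_his = 4L) {
  detect_per_record(records, function(id, sq) {
    ch <- seq_chars(sq)
    n <- length(ch)
    if (n < window) return(NULL)
    ish <- as.integer(ch == "H")
    cs <- cumsum(c(0L, ish))
    wsum <- cs[(window + 1L):(n + 1L)] - cs[1:(n - window + 1L)]
    q <- which(wsum >= min_his)
    if (length(q) == 0) return(NULL)
    covered <- rep(FALSE, n)
    for (i in q) covered[i:(i + window - 1L)] <- TRUE
    r <- rle(covered)
    stops <- cumsum(r$lengths)
    rows <- list()
    for (j in which(r$values)) {
      a <- stops[j] - r$lengths[j] + 1L
      b <- stops[j]
      hs <- which(ish[a:b] == 1L) + a - 1L
      rows[[length(rows) + 1L]] <-
        ann_tbl(id, "his_rich", min(hs), max(hs), length(hs))
    }
    dplyr::bind_rows(rows)
  })
}

# shared sliding-window detector: qualifying windows unioned into regions
window_regions <- function(markval, n, window, min_frac) {
  if (n < window) return(NULL)
  cs <- cumsum(c(0, markval))
  wsum <- cs[(window + 1L):(n + 1L)] - cs[1:(n - window + 1L)]
  q <- which(wsum / window >= min_frac - 1e-12)
  if (length(q) == 0) return(NULL)
  covered <- rep(FALSE, n)
  for (i in q) covered[i:(i + window - 1L)] <- TRUE
  r <- rle(covered)
  stops <- cumsum(r$lengths)
  lapply(which(r$values), function(j) {
    a <- stops[j] - r$lengths[j] + 1L
    c(a, stops[j])
  })
}

#' Detect proline-rich regions
#'
#' Sliding windows of `window` residues with Pro fraction >= `min_frac`;
#' overlapping qualifying windows are merged and the region's score is its
#' Pro fraction.
#'
#' @param records Protein records.
#' @param window Window length (default 20).
#' @param min_frac Minimum Pro fraction (default 0.3).
#' @return Annotation tibble (kind `"pro_rich"`).
#' @export
detect_pro_rich <- function(records, window = 20L, min_frac = 0.3) {
  detect_per_record(records, function(id, sq) {
    ch <- seq_chars(sq)
    regs <- window_regions(as.integer(ch == "P"), length(ch), window, min_frac)
    if (is.null(regs)) return(NULL)
    dplyr::bind_rows(lapply(regs, function(r) {
      ann_tbl(id, "pro_rich", r[1], r[2], mean(ch[r[1]:r[2]] == "P"))
    }))
  })
}

AGP_DIPEPTIDES <- c("AP", "PA", "SP", "TP", "VP")

#' Detect AGP-like regions
#'
#' Windows of `window` residues where positions covered by the classic AGP
#' dipeptides (`AP, PA, SP, TP, VP`) make up at least `min_frac` of the
#' window; qualifying windows are merged and scored by dipeptide coverage.
#'
#' @param records Protein records.
#' @param window Window length (default 20).
#' @param min_frac Minimum dipeptide coverage (default 0.3).
#' @return Annotation tibble (kind `"agp_like"`).
#' @export
detect_agp_like <- function(records, window = 20L, min_frac = 0.3) {
  detect_per_record(records, function(id, sq) {
    ch <- seq_chars(sq)
    n <- length(ch)
    if (n < 2) return(NULL)
    di <- paste0(ch[-n], ch[-1])
    hit <- which(di %in% AGP_DIPEPTIDES)
    covered <- rep(0L, n)
    covered[unique(c(hit, hit + 1L))] <- 1L
    regs <- window_regions(covered, n, window, min_frac)
    if (is.null(regs)) return(NULL)
    dplyr::bind_rows(lapply(regs, function(r) {
      ann_tbl(id, "agp_like", r[1], r[2], mean(covered[r[1]:r[2]]))
    }))
  })
}

#' Run all associated-domain detectors
#'
#' Convenience wrapper running [detect_ww()], [detect_extensin()],
#' [detect_his_rich()], [detect_pro_rich()] and [detect_agp_like()]. When a
#' signal-peptide table is supplied, a `signal_peptide` annotation is added
#' per record and other annotations are masked against it: annotations
#' entirely inside the signal peptide are dropped and overlapping ones are
#' trimmed to start after it.
#'
#' @param records Protein records.
#' @param sp_ends Optional tibble `record_id`, `sp_end` (1-based last
#'   residue of the signal peptide).
#' @return Annotation tibble sorted by record and start.
#' @export
annotate_domains <- function(records, sp_ends = NULL) {
  records <- as_protein_records(records)
  ann <- dplyr::bind_rows(
    detect_ww(records), detect_extensin(records), detect_his_rich(records),
    detect_pro_rich(records), detect_agp_like(records))
  if (!is.null(sp_ends)) {
    assert_that(all(c("record_id", "sp_end") %in% names(sp_ends)),
                "sp_ends needs record_id and sp_end columns")
    spe <- sp_ends$sp_end[match(ann$record_id, sp_ends$record_id)]
    spe[is.na(spe)] <- 0L
    keep <- ann$end > spe
    ann <- ann[keep, ]
    ann$start <- pmax(ann$start, spe[keep] + 1L)
    sp_rows <- ann_tbl(sp_ends$record_id, "signal_peptide", 1L,
                       sp_ends$sp_end, NA_real_)
    sp_rows <- sp_rows[sp_rows$record_id %in% records$id & sp_rows$end >= 1, ]
    ann <- dplyr::bind_rows(ann, sp_rows)
  }
  dplyr::arrange(ann, .data$record_id, .data$start)
}

#' Classify PAC domain proteins into architecture types
#'
#' Type 1: the mature protein is essentially the PAC domain alone.
#' Type 2: N-terminal PAC followed by other domain(s) (subtype 2' when a
#' W-W domain follows). Type 3: C-terminal PAC preceded by His-rich,
#' Pro-rich and/or AGP-like domains. Type 4: central PAC flanked by two
#' extensin domains. Subtype 1' flags Type 1 domains with >= `conserved_min`
#' percent identity to a supplied highly-conserved reference set.
#'
#' The position call uses the mature sequence (signal peptide excluded).
#' Annotations mostly contained in the PAC span are treated as part of the
#' domain and ignored. Records with no strict match are `unclassified`;
#' multi-PAC records are classified on the most N-terminal match and
#' flagged.
#'
#' @param records Protein records.
#' @param matches Strict match tibble from [scan_strict()].
#' @param annotations Annotation tibble from [annotate_domains()].
#' @param clade_c_refs Optional record tibble of conserved Type 1 reference
#'   PAC domains for the 1' flag.
#' @param nc_margin,nc_frac Terminal margin: a PAC is N-/C-terminal when the
#'   flanking mature sequence is at most `max(nc_margin, nc_frac * mature
#'   length)` residues (defaults 30 and 0.1).
#' @param whole_frac Minimum PAC fraction of the mature length for a
#'   "whole" call (default 0.8).
#' @param tail_len Unannotated C-tail longer than this makes an N-terminal
#'   PAC a Type 2 (default 30).
#' @param conserved_min Identity percentage for the 1' flag (default 60).
#' @return A tibble with one row per record: `record_id`, `type`
#'   (`"1"`,`"2"`,`"3"`,`"4"`,`"unclassified"`), `pac_position`,
#'   `ww_2prime`, `conserved_1prime`, `multi_pac`.
#' @export
classify_pdp <- function(records, matches, annotations = NULL,
                         clade_c_refs = NULL,
                         nc_margin = 30L, nc_frac = 0.1,
                         whole_frac = 0.8, tail_len = 30L,
                         conserved_min = 60) {
  records <- as_protein_records(records)
  if (is.null(annotations)) annotations <- ann_tbl()
  out <- purrr::pmap(list(records$id, records$sequence), function(id, sq) {
    n <- nchar(sq)
    mm <- matches[matches$record_id == id & matches$mode == "strict", ]
    row <- tibble::tibble(record_id = id, type = "unclassified",
                          pac_position = NA_character_, ww_2prime = FALSE,
                          conserved_1prime = FALSE,
                          multi_pac = nrow(mm) > 1)
    if (nrow(mm) == 0) return(row)
    if (nrow(mm) > 1) {
      message("record ", id, ": ", nrow(mm),
              " PAC matches; classifying on the most N-terminal")
      mm <- mm[order(mm$span_start), ]
    }
    ps <- mm$span_start[1]
    pe <- mm$span_end[1]
    ann <- annotations[annotations$record_id == id, ]
    sp_end <- if (any(ann$kind == "signal_peptide")) {
      max(ann$end[ann$kind == "signal_peptide"])
    } else 0L
    ann <- ann[ann$kind != "signal_peptide", ]
    # annotations mostly inside the PAC span belong to the domain
    if (nrow(ann) > 0) {
      ov <- pmax(0L, pmin(ann$end, pe) - pmax(ann$start, ps) + 1L)
      ann <- ann[ov / (ann$end - ann$start + 1L) <= 0.5, ]
    }
    mature_start <- sp_end + 1L
    mature_len <- n - sp_end
    up_len <- ps - mature_start
    down_len <- n - pe
    mid <- (ann$start + ann$end) / 2
    up_ann <- ann[mid < ps, ]
    down_ann <- ann[mid > pe, ]
    thresh <- max(nc_margin, nc_frac * mature_len)

    type <- "unclassified"
    pos <- NA_character_
    if (any(up_ann$kind == "extensin") && any(down_ann$kind == "extensin")) {
      type <- "4"; pos <- "central"
    } else if ((pe - ps + 1L) / mature_len >= whole_frac && nrow(ann) == 0) {
      type <- "1"; pos <- "whole"
    } else if (up_len <= thresh && nrow(up_ann) == 0) {
      pos <- "n_terminal"
      type <- if (nrow(down_ann) > 0 || down_len > tail_len) "2" else "1"
    } else if (down_len <= thresh && nrow(down_ann) == 0) {
      pos <- "c_terminal"
      type <- if (any(up_ann$kind %in% c("his_rich", "pro_rich", "agp_like")))
        "3" else "unclassified"
    }
    row$type <- type
    row$pac_position <- pos
    row$ww_2prime <- type == "2" && any(down_ann$kind == "ww")
    if (type == "1" && !is.null(clade_c_refs)) {
      pac_seq <- substr(sq, ps, pe)
      refs <- as_protein_records(clade_c_refs)
      idents <- vapply(refs$sequence, function(r) {
        global_align(pac_seq, r)$identity_pct
      }, numeric(1))
      row$conserved_1prime <- any(idents >= conserved_min)
    }
    row
  })
  dplyr::bind_rows(out)
}
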