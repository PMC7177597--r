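# Diagnostic intron position and tandem gene duplication detection.

# CDS-coordinate junction offsets of a gene model: after CDS nucleotide j
# an intron occurs, for each junction between consecutive CDS segments
# (segments are stored in transcription order).
cds_junctions <- function(cds_segments) {
  if (is.null(cds_segments) || nrow(cds_segments) < 2) return(integer())
  w <- abs(cds_segments[, "end"] - cds_segments[, "start"]) + 1L
  utils::head(cumsum(w), -1L)
}

cds_length <- function(cds_segments) {
  if (is.null(cds_segments) || nrow(cds_segments) == 0) return(0L)
  sum(abs(cds_segments[, "end"] - cds_segments[, "start"]) + 1L)
}

#' Diagnostic intron position of a PAC gene
#'
#' A PAC gene's diagnostic intron lies between the sequences encoding Cys1
#' and Cys2 on one side and Cys3 to Cys6 on the other: in CDS coordinates,
#' strictly between the last nucleotide of the Cys2 codon and the first
#' nucleotide of the Cys3 codon. `none` means the gene has no intron inside
#' the PAC span; any other intron position inside the span is `atypical`.
#'
#' @param gene_model One row of a [read_gff()] tibble (or a list with
#'   `cds_segments`).
#' @param match One row of a strict match tibble (1-based protein
#'   coordinates for `c2`, `c3`, `span_start`, `span_end`).
#' @param protein_length Optional protein length to cross-check the CDS
#'   (errors on mismatch; the CDS may include one trailing stop codon).
#' @return One of `"none"`, `"diagnostic"`, `"atypical"`.
#' @export
intron_position <- function(gene_model, match, protein_length = NULL) {
  cds <- gene_model$cds_segments
  if (is.list(cds) && !is.matrix(cds)) cds <- cds[[1]]
  len <- cds_length(cds)
  if (!is.null(protein_length)) {
    aa <- len / 3
    assert_that(len %% 3 == 0 && (aa == protein_length || aa == protein_length + 1),
                "CDS length does not match the protein length")
  }
  j <- cds_junctions(cds)
  c2 <- match$c2[1]
  c3 <- match$c3[1]
  s <- match$span_start[1]
  e <- match$span_end[1]
  assert_that(!anyNA(c(c2, c3, s, e)), "match must have c2, c3 and a span")
  inside <- j[j >= 3L * s - 2L & j <= 3L * e - 1L]
  if (length(inside) == 0) return("none")
  diagnostic <- any(inside >= 3L * c2 & inside <= 3L * c3 - 3L)
  if (diagnostic) "diagnostic" else "atypical"
}

#' Find tandem-duplicated PAC genes
#'
#' Single-linkage chaining of PAC-carrying genes along each scaffold:
#' consecutive members must have at most `max_intervening` non-PAC genes
#' between them and share a PAC-domain amino-acid identity above
#' `threshold` percent. Genes without an identity entry are ignored with a
#' warning. Groups report member orientation; orientation is not filtered
#' on.
#'
#' @param gene_models Gene model tibble (needs `gene_id`, `seq_id`, and a
#'   genomic position; the first exon start is used for ordering).
#' @param pac_identities Long identity tibble `id_a`, `id_b`, `identity`
#'   keyed by gene id, computed on the PAC amino-acid spans (see
#'   [pairwise_identities()]).
#' @param threshold Identity threshold in percent; pairs must exceed it
#'   (default 85).
#' @param max_intervening Maximum number of non-PAC genes between
#'   consecutive members (default 1).
#' @param pdp_genes Optional character vector of gene ids known to carry a
#'   PAC domain; members without any identity entry are then reported with
#'   a warning and treated as intervening genes.
#' @return A tibble with one row per group member: `group`, `seq_id`,
#'   `gene_id`, `strand`, `position`, `min_pair_identity` (the group's
#'   minimum consecutive-pair identity).
#' @export
find_tandems <- function(gene_models, pac_identities, threshold = 85,
                         max_intervening = 1L, pdp_genes = NULL) {
  gm <- gene_models
  assert_that(all(c("gene_id", "seq_id") %in% names(gm)),
              "gene_models needs gene_id and seq_id")
  if (!is.null(pdp_genes)) {
    no_ident <- setdiff(pdp_genes,
                        unique(c(pac_identities$id_a, pac_identities$id_b)))
    if (length(no_ident) > 0) {
      warning("PAC gene(s) without identity entries ignored: ",
              paste(utils::head(no_ident, 5), collapse = ", "), call. = FALSE)
    }
  }
  pos <- if ("position" %in% names(gm)) gm$position else
    vapply(gm$exons, function(e) min(e[, "start"], e[, "end"]), numeric(1))
  gm$.pos <- pos
  pdp_ids <- unique(c(pac_identities$id_a, pac_identities$id_b))
  gm$.is_pdp <- gm$gene_id %in% pdp_ids
  lookup <- function(a, b) {
    hit <- (pac_identities$id_a == a & pac_identities$id_b == b) |
      (pac_identities$id_a == b & pac_identities$id_b == a)
    if (!any(hit)) return(NA_real_)
    pac_identities$identity[which(hit)[1]]
  }
  groups <- list()
  for (sid in unique(gm$seq_id)) {
    sub <- gm[gm$seq_id == sid, ]
    sub <- sub[order(sub$.pos), ]
    pdp_rows <- which(sub$.is_pdp)
    if (length(pdp_rows) < 2) next
    # chain consecutive PDP genes
    cur <- list(pdp_rows[1])
    idents <- list(numeric())
    for (k in 2:length(pdp_rows)) {
      prev <- pdp_rows[k - 1L]
      this <- pdp_rows[k]
      intervening <- (this - prev - 1L)
      idn <- lookup(sub$gene_id[prev], sub$gene_id[this])
      if (intervening <= max_intervening && !is.na(idn) && idn > threshold) {
        cur[[length(cur)]] <- c(cur[[length(cur)]], this)
        idents[[length(idents)]] <- c(idents[[length(idents)]], idn)
      } else {
        cur[[length(cur) + 1L]] <- this
        idents[[length(idents) + 1L]] <- numeric()
      }
    }
    for (gidx in seq_along(cur)) {
      rows <- cur[[gidx]]
      if (length(rows) < 2) next
      groups[[length(groups) + 1L]] <- tibble::tibble(
        group = paste0(sid, ":", sub$gene_id[rows[1]]),
        seq_id = sid,
        gene_id = sub$gene_id[rows],
        strand = if ("strand" %in% names(sub)) sub$strand[rows] else NA_character_,
        position = sub$.pos[rows],
        min_pair_identity = min(idents[[gidx]])
      )
    }
  }
  out <- dplyr::bind_rows(groups)
  if (nrow(out) == 0) {
    out <- tibble::tibble(group = character(), seq_id = character(),
                          gene_id = character(), strand = character(),
                          position = numeric(), min_pair_identity = numeric())
  }
  out
}
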