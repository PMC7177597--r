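#' Read protein sequences from a FASTA file
#'
#' Sequences are uppercased; `*` (stop) characters are retained so that
#' translated transcriptome frames keep their hard walls.
#'
#' @param path Path to a FASTA file.
#' @return A protein record tibble (`id`, `description`, `sequence`,
#'   `source`, `frame`). The `id` is the first whitespace-delimited token of
#'   the header, the remainder is the `description`.
#' @export
read_fasta <- function(path) {
  assert_that(file.exists(path), paste0("no such file: ", path))
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0) {
    warning("empty FASTA file: ", path, call. = FALSE)
    return(as_protein_records(character())[0, ])
  }
  hdr <- names(set)
  ids <- sub("\\s.*$", "", hdr)
  dup <- unique(ids[duplicated(ids)])
  assert_that(length(dup) == 0,
              paste0("duplicate FASTA id(s): ", paste(dup, collapse = ", ")))
  desc <- ifelse(grepl("\\s", hdr), sub("^\\S+\\s+", "", hdr), "")
  tibble::tibble(id = ids, description = desc,
                 sequence = unname(toupper(as.character(set))),
                 source = "protein", frame = NA_integer_)
}

#' Write protein records to a FASTA file
#'
#' @param records Protein records (see [as_protein_records()]).
#' @param path Output path.
#' @param width Line-wrap width (default 60 columns).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 60L) {
  records <- as_protein_records(records)
  hdr <- ifelse(nzchar(records$description),
                paste(records$id, records$description), records$id)
  lines <- purrr::map2(hdr, records$sequence, function(h, s) {
    starts <- seq(1L, nchar(s), by = width)
    c(paste0(">", h), substring(s, starts, pmin(starts + width - 1L, nchar(s))))
  })
  writeLines(unlist(lines), path)
  invisible(path)
}

#' Translate a nucleotide sequence in selected reading frames
#'
#' Uses the standard genetic code; stop codons become `*` and codons
#' containing `N` become `X`. Frame `-k` translates the reverse complement
#' starting at offset `k`.
#'
#' @param nucleotide_seq A single nucleotide string over `A,C,G,T,N`.
#' @param frames Integer subset of `c(1, 2, 3, -1, -2, -3)`.
#' @param id Base id for the emitted records (default `"seq"`); frame
#'   records are named `<id>_frame<k>`.
#' @return A protein record tibble with `source = "translated_frame"` and
#'   the `frame` column filled.
#' @export
translate_frames <- function(nucleotide_seq, frames = c(1L, 2L, 3L, -1L, -2L, -3L),
                             id = "seq") {
  nucleotide_seq <- toupper(nucleotide_seq)
  bad <- which(!seq_chars(nucleotide_seq) %in% c("A", "C", "G", "T", "N"))
  assert_that(length(bad) == 0,
              paste0("illegal nucleotide character(s) at position(s): ",
                     paste(utils::head(bad, 10), collapse = ", ")))
  frames <- as.integer(frames)
  assert_that(all(frames %in% c(1L, 2L, 3L, -1L, -2L, -3L)),
              "frames must be a subset of {1,2,3,-1,-2,-3}")
  fwd <- Biostrings::DNAString(nucleotide_seq)
  rev <- Biostrings::reverseComplement(fwd)
  pep <- vapply(frames, function(f) {
    s <- if (f > 0) fwd else rev
    k <- abs(f)
    if (length(s) < k + 2) return("")
    sub <- Biostrings::subseq(s, start = k)
    sub <- Biostrings::subseq(sub, start = 1, end = 3 * (length(sub) %/% 3))
    as.character(Biostrings::translate(sub, if.fuzzy.codon = "X"))
  }, character(1))
  keep <- nzchar(pep)
  tibble::tibble(id = paste0(id, "_frame", frames[keep]),
                 description = "",
                 sequence = pep[keep],
                 source = "translated_frame",
                 frame = frames[keep])
}

#' Read gene models from a GFF3 file
#'
#' One gene model per mRNA feature, with exons and CDS segments kept in
#' 1-based inclusive genomic coordinates and ordered in transcription order
#' (ascending on `+`, descending on `-`). CDS/exon features without a
#' resolvable mRNA parent are skipped with a warning.
#'
#' @param path Path to a GFF3 file.
#' @return A tibble with one row per mRNA: `gene_id`, `transcript_id`,
#'   `seq_id`, `strand`, `protein_id`, and list-columns `exons` and
#'   `cds_segments` of two-column matrices (`start`, `end`).
#' @export
read_gff <- function(path) {
  assert_that(file.exists(path), paste0("no such file: ", path))
  raw <- readLines(path)
  body <- which(!grepl("^#", raw) & nzchar(trimws(raw)))
  ncol_bad <- body[lengths(strsplit(raw[body], "\t", fixed = TRUE)) != 9]
  assert_that(length(ncol_bad) == 0,
              paste0("malformed GFF3 (not 9 tab-separated columns) at line(s): ",
                     paste(utils::head(ncol_bad, 5), collapse = ", ")))
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as.data.frame(gr)
  type <- as.character(df$type)
  get_attr <- function(col) if (col %in% names(df)) as.character(df[[col]]) else rep(NA_character_, nrow(df))
  ids <- get_attr("ID")
  parents <- vapply(
    if ("Parent" %in% names(df)) df$Parent else rep(list(character()), nrow(df)),
    function(p) if (length(p)) as.character(p)[1] else NA_character_, character(1))
  mrna <- which(type == "mRNA")
  models <- purrr::map(mrna, function(i) {
    tid <- ids[i]
    kids <- which(parents == tid)
    ex <- kids[type[kids] == "exon"]
    cds <- kids[type[kids] == "CDS"]
    ord <- function(rows) {
      if (length(rows) == 0) return(matrix(integer(), 0, 2, dimnames = list(NULL, c("start", "end"))))
      m <- cbind(start = df$start[rows], end = df$end[rows])
      m <- m[order(m[, 1]), , drop = FALSE]
      if (as.character(df$strand[i]) == "-") m <- m[rev(seq_len(nrow(m))), , drop = FALSE]
      m
    }
    em <- ord(ex)
    if (nrow(em) == 0) em <- ord(cds)
    tibble::tibble(
      gene_id = if (!is.na(parents[i])) parents[i] else tid,
      transcript_id = tid,
      seq_id = as.character(df$seqnames[i]),
      strand = as.character(df$strand[i]),
      protein_id = get_attr("protein_id")[i] %||% NA_character_,
      exons = list(em),
      cds_segments = list(ord(cds))
    )
  })
  orphans <- which(type %in% c("CDS", "exon") &
                     (is.na(parents) | !parents %in% ids))
  if (length(orphans) > 0) {
    warning(length(orphans), " CDS/exon feature(s) without a resolvable mRNA parent were skipped",
            call. = FALSE)
  }
  dplyr::bind_rows(models)
}

#' Read per-residue secondary-structure strings
#'
#' Plain-text format: one record per line, `id<TAB or space>HEC-string`.
#'
#' @param path Path to the track file.
#' @return A tibble `record_id`, `ss`.
#' @export
read_ss_tracks <- function(path) {
  assert_that(file.exists(path), paste0("no such file: ", path))
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- stringr::str_split_fixed(lines, "\\s+", 2)
  ss <- toupper(trimws(parts[, 2]))
  bad <- which(grepl("[^HEC]", ss))
  assert_that(length(bad) == 0,
              paste0("non-H/E/C character in track line(s): ",
                     paste(utils::head(bad, 5), collapse = ", ")))
  tibble::tibble(record_id = parts[, 1], ss = ss)
}

#' Read external domain-annotation hits
#'
#' TSV with columns `protein_id`, `domain_accession`, `ali_start`,
#' `ali_end`, `evalue` (header optional but recommended).
#'
#' @param path Path to the TSV file.
#' @return A tibble `record_id`, `accession`, `start`, `end`, `evalue`.
#' @export
read_domain_hits <- function(path) {
  assert_that(file.exists(path), paste0("no such file: ", path))
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  assert_that(ncol(df) >= 5, "domain-hits file needs 5 columns")
  names(df)[1:5] <- c("record_id", "accession", "start", "end", "evalue")
  tibble::tibble(record_id = as.character(df$record_id),
                 accession = as.character(df$accession),
                 start = as.integer(df$start), end = as.integer(df$end),
                 evalue = as.numeric(df$evalue))
}
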