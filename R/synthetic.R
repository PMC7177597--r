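# Synthetic PAC-domain proteins, gene models, tandem clusters and
# structures with planted ground truth. The generator's defaults define
# the simulated study conditions: spacers drawn uniformly inside the
# canonical bounds, a gate-passing signal peptide, beta-strand blocks
# inside spacers so the built-in secondary-structure gate passes by
# construction, and single-fault corruptions so each gate is tested in
# isolation.

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
    get(".Random.seed", envir = .GlobalEnv) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = .GlobalEnv)
    else suppressWarnings(rm(".Random.seed", envir = .GlobalEnv))
  })
  set.seed(seed)
  force(code)
}

# strong coil/turn formers; Pro is deliberately excluded so that spacer
# background cannot seed Ser-Pro motifs that would merge with planted
# extensin/Pro-rich blocks across the domain boundary
COIL_SET <- c("G", "S", "N", "D")
STRAND_SET <- c("V", "I", "F", "Y", "T")    # strong strand formers
HELIX_SET <- c("A", "E", "L", "M")          # strong helix formers
AA19 <- setdiff(AA20, "C")

PAC_CORRUPTIONS <- c("none", "missing_cys", "extra_cys", "gap_violation",
                     "missing_gly", "helix_decoy", "foreign_domain",
                     "no_signal_peptide")

rand_of <- function(set, n) paste(sample(set, n, replace = TRUE), collapse = "")

# spacer with an interior strand block so the fallback predictor calls
# >= 1 strand of >= 3 residues per long spacer
structured_spacer <- function(len, composition) {
  if (composition == "uniform") return(rand_of(AA19, len))
  if (composition == "helix") return(rand_of(HELIX_SET, len))
  if (len < 8) return(rand_of(COIL_SET, len))
  block <- 6L
  pre <- (len - block) %/% 2L
  paste0(rand_of(COIL_SET, pre), rand_of(STRAND_SET, block),
         rand_of(COIL_SET, len - pre - block))
}

make_signal_peptide <- function() {
  paste0("MKK", rand_of(c("A", "I", "L", "F", "V"), 10L), "ASA")
}

#' Generate a synthetic PAC domain protein with planted truth
#'
#' Builds one protein of the requested architecture type with a planted
#' PAC domain whose spacers are drawn uniformly inside the rule bounds,
#' plus a gate-passing signal peptide and the type's associated domains
#' (Type 2: W-W; Type 3: His-rich + AGP/Pro-rich; Type 4: flanking
#' extensins). A named single-fault corruption can be applied; a
#' corruption-free record passes every bona fide gate by construction.
#'
#' @param type Architecture type, 1-4.
#' @param seed Integer seed; output is reproducible given (seed,
#'   parameters).
#' @param corruption One of `none`, `missing_cys`, `extra_cys`,
#'   `gap_violation`, `missing_gly`, `helix_decoy`, `foreign_domain`,
#'   `no_signal_peptide`.
#' @param rule A [pac_rule()].
#' @param composition Spacer composition: `"structured"` (default;
#'   coil background with strand blocks, so the built-in secondary
#'   structure gate passes) or `"uniform"` (uniform over the 19 non-Cys
#'   residues).
#' @param id Record id (default derived from type/seed).
#' @return A list with `record` (one-row record tibble), `truth` (one-row
#'   truth tibble: planted type, PAC span, Cys positions, `sp_end`,
#'   corruption), and `hits` (external domain-hit rows; non-empty for the
#'   `foreign_domain` corruption).
#' @export
generate_pdp <- function(type, seed, corruption = "none", rule = pac_rule(),
                         composition = "structured",
                         id = sprintf("pdp_t%d_s%d_%s", type, seed, corruption)) {
  assert_that(type %in% 1:4, "type must be 1, 2, 3 or 4")
  assert_that(corruption %in% PAC_CORRUPTIONS,
              paste0("unknown corruption: ", corruption))
  with_seed(seed, {
    comp <- if (corruption == "helix_decoy") "helix" else composition
    gaps <- ranged_gaps(rule)
    sp_len <- vapply(gaps, function(g) sample(g[1]:g[2], 1L), integer(1))
    if (corruption == "extra_cys") {
      # keep Cys4 -> extra-Cys distance out of bounds so the planted chain
      # stays the only feasible relaxed interpretation
      lo <- max(gaps[[3]][1], gaps[[3]][2] - 3L)
      sp_len[3] <- sample(lo:gaps[[3]][2], 1L)
    }
    if (corruption == "gap_violation") {
      k <- sample(1:4, 1L)
      side <- sample(c("low", "high"), 1L)
      sp_len[k] <- if (side == "low" && gaps[[k]][1] > 0) gaps[[k]][1] - 1L
                   else gaps[[k]][2] + 1L
    }
    pac <- paste0("G", structured_spacer(rule$gap_gly_c1, "uniform"),
                  "C", structured_spacer(rule$gap_c1_c2, "uniform"),
                  "C", structured_spacer(sp_len[1], comp),
                  "C", structured_spacer(sp_len[2], comp),
                  "C", structured_spacer(sp_len[3], comp),
                  "C", structured_spacer(sp_len[4], comp),
                  "C")
    sp <- if (corruption == "no_signal_peptide") paste0("M", strrep("D", 15L))
          else make_signal_peptide()
    coil_tail <- function(n) rand_of(setdiff(COIL_SET, "W"), n)
    pre <- ""   # mature sequence before the PAC domain
    post <- ""  # mature sequence after the PAC domain
    if (type == 2) {
      post <- paste0(coil_tail(5L), "W", rand_of(setdiff(AA19, "W"), 8L), "W",
                     coil_tail(30L))
    } else if (type == 3) {
      pre <- paste0(strrep("H", 8L), coil_tail(5L), strrep("AP", 15L),
                    coil_tail(5L))
    } else if (type == 4) {
      ext <- function() strrep("SPPPP", 6L)
      pre <- paste0(ext(), coil_tail(3L))
      post <- paste0(coil_tail(3L), ext())
    }
    seqn <- paste0(sp, pre, pac, post)
    ch <- seq_chars(seqn)
    pac_start <- nchar(sp) + nchar(pre) + 1L
    cys <- which(ch == "C")
    cys <- cys[cys >= pac_start]
    gly_pos <- pac_start
    pac_end <- cys[6]

    if (corruption == "missing_cys") {
      victim <- sample(2:5, 1L)
      ch[cys[victim]] <- "S"
      seqn <- paste(ch, collapse = "")
    } else if (corruption == "extra_cys") {
      ch[cys[5] + 4L] <- "C"
      seqn <- paste(ch, collapse = "")
    } else if (corruption == "missing_gly") {
      ch[gly_pos] <- "A"
      seqn <- paste(ch, collapse = "")
    }

    hits <- tibble::tibble(record_id = character(), accession = character(),
                           start = integer(), end = integer(),
                           evalue = numeric())
    if (corruption == "foreign_domain") {
      hits <- tibble::tibble(record_id = id, accession = "PF00171",
                             start = pac_start, end = pac_start + 50L,
                             evalue = 1e-30)
    }
    record <- tibble::tibble(id = id, description = "synthetic PAC protein",
                             sequence = seqn, source = "protein",
                             frame = NA_integer_)
    truth <- tibble::tibble(
      record_id = id, planted_type = as.integer(type),
      corruption = corruption, sp_end = nchar(sp),
      pac_start = gly_pos, pac_end = pac_end,
      cys_positions = list(cys),
      tandem_group = NA_character_, intron_class = NA_character_)
    list(record = record, truth = truth, hits = hits)
  })
}

#' Generate a set of synthetic PAC domain proteins
#'
#' @param n Number of records.
#' @param types Architecture types to cycle over.
#' @param corruption Corruption applied to every record.
#' @param seed Base seed; record k uses `seed + k`.
#' @param ... Passed to [generate_pdp()].
#' @return A list with `records`, `truth` and `hits` tibbles.
#' @export
simulate_pdp_set <- function(n, types = 1:4, corruption = "none", seed = 42L,
                             ...) {
  types_k <- rep(types, length.out = n)
  out <- purrr::map(seq_len(n), function(k) {
    generate_pdp(types_k[k], seed = seed + k, corruption = corruption, ...)
  })
  list(records = dplyr::bind_rows(purrr::map(out, "record")),
       truth = dplyr::bind_rows(purrr::map(out, "truth")),
       hits = dplyr::bind_rows(purrr::map(out, "hits")))
}

codon_options <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      gc_tab <- Biostrings::GENETIC_CODE
      cache <<- split(names(gc_tab), unname(gc_tab))
    }
    cache
  }
})

back_translate <- function(protein) {
  opts <- codon_options()
  ch <- seq_chars(protein)
  paste(vapply(ch, function(a) {
    o <- opts[[a]]
    if (is.null(o)) stop("cannot back-translate residue ", a, call. = FALSE)
    if (length(o) == 1) o else sample(o, 1L)
  }, character(1)), collapse = "")
}

random_intron <- function(len = 64L) {
  paste0("GT", rand_of(c("A", "C", "G", "T"), len - 4L), "AG")
}

#' Generate a gene model for a synthetic PAC protein
#'
#' Back-translates the protein with random synonymous codons and inserts a
#' GT..AG intron according to the requested class: `diagnostic` (between
#' the Cys2 and Cys3 codons), `atypical` (between the Cys4 and Cys5
#' codons), or `none` (intronless). The CDS always translates exactly back
#' to the protein.
#'
#' @param record One-row record tibble (the protein).
#' @param truth Matching one-row truth tibble from [generate_pdp()].
#' @param intron_class `"none"`, `"diagnostic"` or `"atypical"`.
#' @param seed Integer seed.
#' @param gene_id,seq_id,offset Identifiers and genomic offset of the gene.
#' @return A list with `model` (one-row gene-model tibble as in
#'   [read_gff()]), `genomic_seq` (nucleotide string of the scaffold
#'   region), `cds_seq`, and `truth` (input truth with `intron_class`
#'   filled).
#' @export
generate_gene_model <- function(record, truth, intron_class = "none",
                                seed = 1L, gene_id = record$id[1],
                                seq_id = "scaffold1", offset = 0L) {
  assert_that(intron_class %in% c("none", "diagnostic", "atypical"),
              "intron_class must be none, diagnostic or atypical")
  with_seed(seed, {
    cds <- back_translate(record$sequence[1])
    cys <- truth$cys_positions[[1]]
    junction <- NULL
    if (intron_class == "diagnostic") {
      junction <- sample(seq(3L * cys[2], 3L * cys[3] - 3L), 1L)
    } else if (intron_class == "atypical") {
      junction <- sample(seq(3L * cys[4], 3L * cys[5] - 3L), 1L)
    }
    if (is.null(junction)) {
      genomic <- cds
      segs <- cbind(start = offset + 1L, end = offset + nchar(cds))
    } else {
      intron <- random_intron()
      genomic <- paste0(substr(cds, 1L, junction), intron,
                        substr(cds, junction + 1L, nchar(cds)))
      segs <- cbind(
        start = offset + c(1L, junction + nchar(intron) + 1L),
        end = offset + c(junction, nchar(cds) + nchar(intron)))
    }
    colnames(segs) <- c("start", "end")
    model <- tibble::tibble(
      gene_id = gene_id, transcript_id = paste0(gene_id, ".1"),
      seq_id = seq_id, strand = "+", protein_id = record$id[1],
      exons = list(segs), cds_segments = list(segs))
    truth$intron_class <- intron_class
    list(model = model, genomic_seq = genomic, cds_seq = cds, truth = truth)
  })
}

#' Generate a tandem cluster of near-identical PAC genes
#'
#' Duplicates a seed Type 1 PAC gene `n` times with point mutations inside
#' the PAC spacers, calibrated so the realized pairwise identity over the
#' PAC span is within a few points of `identity_target`; the genes are
#' placed adjacently on one synthetic scaffold.
#'
#' @param n Number of genes (>= 2).
#' @param identity_target Target pairwise PAC identity in percent
#'   (50-100].
#' @param seed Integer seed.
#' @param intergenic Intergenic spacing in nucleotides (default 200).
#' @return A list with `records`, `truth`, `models` (gene-model tibble),
#'   and `pac_identities` (realized pairwise identities over PAC spans).
#' @export
generate_tandem_cluster <- function(n, identity_target, seed = 1L,
                                    intergenic = 200L) {
  assert_that(n >= 2, "n must be >= 2")
  assert_that(identity_target > 50 && identity_target <= 100,
              "identity_target must be in (50, 100]")
  with_seed(seed, {
    base <- generate_pdp(1L, seed = sample.int(1e6, 1L), id = "tandem_seed")
    cys <- base$truth$cys_positions[[1]]
    ps <- base$truth$pac_start
    pe <- base$truth$pac_end
    Lpac <- pe - ps + 1L
    anchors <- c(ps, cys)
    mutable <- setdiff(ps:pe, anchors)
    Lsp <- length(mutable)
    # per-copy mutation count m: two copies mutated independently at
    # q = m/Lsp differ per spacer site w.p. 2q(1-q) + q^2 * 17/18
    D <- (1 - identity_target / 100) * Lpac / Lsp
    a <- 19 / 18
    q <- if (D <= 0) 0 else (2 - sqrt(max(0, 4 - 4 * a * D))) / (2 * a)
    m <- round(q * Lsp)
    ch0 <- seq_chars(base$record$sequence[1])
    records <- list()
    truths <- list()
    models <- list()
    offset <- 0L
    for (k in seq_len(n)) {
      ch <- ch0
      if (m > 0) {
        pos <- sample(mutable, m)
        ch[pos] <- vapply(ch[pos], function(x) sample(setdiff(AA19, x), 1L),
                          character(1))
      }
      rec <- base$record
      rec$id <- sprintf("tandem_g%d", k)
      rec$sequence <- paste(ch, collapse = "")
      tru <- base$truth
      tru$record_id <- rec$id
      tru$tandem_group <- "tandem1"
      gm <- generate_gene_model(rec, tru, "none", seed = sample.int(1e6, 1L),
                                gene_id = rec$id, seq_id = "tandem_scaffold",
                                offset = offset)
      offset <- offset + nchar(gm$genomic_seq) + intergenic
      records[[k]] <- rec
      truths[[k]] <- gm$truth
      models[[k]] <- gm$model
    }
    records <- dplyr::bind_rows(records)
    pac_records <- tibble::tibble(
      id = records$id,
      sequence = substr(records$sequence, ps, pe))
    list(records = records,
         truth = dplyr::bind_rows(truths),
         models = dplyr::bind_rows(models),
         pac_identities = pairwise_identities(pac_records))
  })
}

#' Generate a synthetic 3D model with the PAC disulfide topology
#'
#' Places SG atoms so the expected pairs (1,5), (3,4), (2,6) sit at
#' 2.05 Angstrom while every other SG pair is far apart, plus a coarse CA
#' backbone trace. With `swap = TRUE` the pairing is scrambled to
#' (1,2), (3,4), (5,6), producing a topology-violating fixture.
#'
#' @param cys_positions Integer vector of 6 residue indices (e.g.
#'   `truth$cys_positions[[1]]`).
#' @param seed Integer seed (jitters the backbone trace only).
#' @param swap Scramble the bridge topology (default `FALSE`).
#' @param span Optional `c(start, end)` residue range for the CA trace;
#'   defaults to the Cys range.
#' @return An atom tibble.
#' @export
generate_structure <- function(cys_positions, seed = 1L, swap = FALSE,
                               span = NULL) {
  assert_that(length(cys_positions) == 6, "need 6 Cys positions")
  with_seed(seed, {
    span <- span %||% range(cys_positions)
    resno <- span[1]:span[2]
    nres <- length(resno)
    # loose helical CA trace, ~3.8 A spacing
    t <- seq_len(nres)
    ca <- cbind(x = 8 * cos(t / 2) + stats::rnorm(nres, 0, 0.1),
                y = 8 * sin(t / 2) + stats::rnorm(nres, 0, 0.1),
                z = 2.2 * t + stats::rnorm(nres, 0, 0.1))
    pairing <- if (swap) matrix(c(1L, 2L, 3L, 4L, 5L, 6L), ncol = 2, byrow = TRUE)
               else pac_expected_bridges()
    centers <- matrix(c(0, 0, 0, 60, 0, 0, 0, 60, 0), ncol = 3, byrow = TRUE)
    sg <- matrix(NA_real_, 6, 3)
    for (p in seq_len(nrow(pairing))) {
      sg[pairing[p, 1], ] <- centers[p, ] + c(0, 0, 1.025)
      sg[pairing[p, 2], ] <- centers[p, ] - c(0, 0, 1.025)
    }
    is_cys <- resno %in% cys_positions
    atoms_ca <- tibble::tibble(
      residue_index = resno,
      residue_name = ifelse(is_cys, "CYS", "GLY"),
      atom_name = "CA", x = ca[, 1], y = ca[, 2], z = ca[, 3] + 200,
      chain = "A")
    atoms_sg <- tibble::tibble(
      residue_index = cys_positions, residue_name = "CYS", atom_name = "SG",
      x = sg[, 1], y = sg[, 2], z = sg[, 3], chain = "A")
    dplyr::arrange(dplyr::bind_rows(atoms_ca, atoms_sg),
                   .data$residue_index, .data$atom_name)
  })
}
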