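# Disulfide-topology validation and Shrake-Rupley solvent accessibility on
# 3D coordinate models.

VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, H = 1.20)

# Tien et al. (2013) theoretical maximum ASA (A^2), Gly-X-Gly context
MAX_ASA_TIEN <- c(
  ALA = 129, ARG = 274, ASN = 195, ASP = 193, CYS = 167, GLN = 225,
  GLU = 223, GLY = 104, HIS = 224, ILE = 197, LEU = 201, LYS = 236,
  MET = 224, PHE = 240, PRO = 159, SER = 155, THR = 172, TRP = 285,
  TYR = 263, VAL = 174)

#' Read ATOM records from a PDB file
#'
#' @param path Path to a PDB coordinate file.
#' @return An atom tibble: `residue_index`, `residue_name`, `atom_name`,
#'   `x`, `y`, `z`, `chain`.
#' @export
read_pdb_atoms <- function(path) {
  assert_that(file.exists(path), paste0("no such file: ", path))
  pdb <- bio3d::read.pdb(path)
  a <- pdb$atom[pdb$atom$type == "ATOM", ]
  tibble::tibble(residue_index = as.integer(a$resno),
                 residue_name = a$resid, atom_name = a$elety,
                 x = a$x, y = a$y, z = a$z,
                 chain = ifelse(is.na(a$chain), "A", a$chain))
}

#' Write an atom tibble as a PDB file
#'
#' @param atoms An atom tibble (see [read_pdb_atoms()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pdb_atoms <- function(atoms, path) {
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(as.matrix(atoms[, c("x", "y", "z")]))),
                   resno = atoms$residue_index, resid = atoms$residue_name,
                   eleno = seq_len(nrow(atoms)), elety = atoms$atom_name,
                   chain = atoms$chain %||% "A")
  invisible(path)
}

pac_expected_bridges <- function() {
  matrix(c(1L, 5L, 3L, 4L, 2L, 6L), ncol = 2, byrow = TRUE,
         dimnames = list(NULL, c("a", "b")))
}

#' Check the PAC disulfide topology on a 3D model
#'
#' The bona fide PAC topology pairs Cys1-Cys5, Cys3-Cys4 and Cys2-Cys6 in a
#' closed branched loop. The verdict is `pass` when all three expected
#' SG-SG pairs are within `threshold` and no other Cys-ordinal pair is;
#' any extra bridge within threshold is reported rather than silently
#' accepted.
#'
#' @param atoms An atom tibble.
#' @param cys_ordinals Integer vector of length 6: the residue index of
#'   each PAC Cys ordinal 1-6.
#' @param threshold SG-SG bond distance threshold in Angstrom (default 2.5:
#'   covalent ~2.05 plus model slack).
#' @return An object of class `pac_bridge_report`: list with `observed`
#'   (tibble of all 15 ordinal pairs with distances), `expected_pairs`,
#'   `verdict` (`"pass"`/`"fail"`).
#' @export
check_disulfides <- function(atoms, cys_ordinals, threshold = 2.5) {
  assert_that(length(cys_ordinals) == 6, "cys_ordinals must have length 6")
  sg <- lapply(seq_along(cys_ordinals), function(k) {
    r <- cys_ordinals[k]
    row <- atoms[atoms$residue_index == r & atoms$atom_name == "SG", ]
    assert_that(nrow(row) >= 1,
                paste0("no SG atom for Cys ordinal ", k, " (residue ", r, ")"))
    as.numeric(row[1, c("x", "y", "z")])
  })
  exp <- pac_expected_bridges()
  pairs <- utils::combn(6, 2)
  obs <- purrr::map(seq_len(ncol(pairs)), function(c) {
    i <- pairs[1, c]; j <- pairs[2, c]
    d <- sqrt(sum((sg[[i]] - sg[[j]])^2))
    tibble::tibble(ordinal_a = i, ordinal_b = j, distance = d,
                   expected = any(exp[, 1] == i & exp[, 2] == j),
                   bonded = d <= threshold)
  })
  obs <- dplyr::bind_rows(obs)
  verdict <- if (all(obs$bonded[obs$expected]) && !any(obs$bonded[!obs$expected]))
    "pass" else "fail"
  structure(list(observed = obs, expected_pairs = exp, threshold = threshold,
                 verdict = verdict),
            class = "pac_bridge_report")
}

#' @export
print.pac_bridge_report <- function(x, ...) {
  cat("<pac_bridge_report> verdict:", x$verdict, "\n")
  b <- x$observed[x$observed$bonded | x$observed$expected, ]
  for (i in seq_len(nrow(b))) {
    cat(sprintf("  Cys%d-Cys%d  %.2f A  %s%s\n", b$ordinal_a[i], b$ordinal_b[i],
                b$distance[i], ifelse(b$expected[i], "expected", "EXTRA"),
                ifelse(b$bonded[i], ", bonded", ", not bonded")))
  }
  invisible(x)
}

# deterministic quasi-uniform sphere points (golden-spiral lattice)
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

atom_radii <- function(atom_names) {
  el <- substr(gsub("[0-9']", "", atom_names), 1, 1)
  r <- VDW_RADII[el]
  if (anyNA(r)) {
    warning("unknown element(s) for radius lookup; using 1.7 A: ",
            paste(unique(atom_names[is.na(r)]), collapse = ", "), call. = FALSE)
    r[is.na(r)] <- 1.70
  }
  unname(r)
}

# total solvent-accessible surface per atom (A^2), Shrake-Rupley
sasa_atoms <- function(xyz, radii, n_points, probe) {
  n <- nrow(xyz)
  pts <- sphere_points(n_points)
  R <- radii + probe
  asa <- numeric(n)
  for (i in seq_len(n)) {
    ci <- xyz[i, ]
    d2 <- rowSums((xyz - matrix(ci, n, 3, byrow = TRUE))^2)
    nb <- which(d2 < (R[i] + R)^2 & seq_len(n) != i)
    if (length(nb) == 0) {
      asa[i] <- 4 * pi * R[i]^2
      next
    }
    P <- pts * R[i]
    P <- sweep(P, 2, ci, `+`)
    exposed <- rep(TRUE, n_points)
    for (j in nb) {
      if (!any(exposed)) break
      dj2 <- rowSums((P - matrix(xyz[j, ], n_points, 3, byrow = TRUE))^2)
      exposed <- exposed & dj2 > R[j]^2
    }
    asa[i] <- 4 * pi * R[i]^2 * sum(exposed) / n_points
  }
  asa
}

#' Relative solvent accessibility by the Shrake-Rupley method
#'
#' Accessible surface area is computed with a deterministic golden-spiral
#' point lattice (probe 1.4 A, standard van der Waals radii) and
#' normalised per residue. With `reference = "self"` (default) each
#' residue's ASA is divided by the ASA of the same residue's atoms in
#' isolation, computed by the same algorithm, so an unoccluded residue has
#' RSA exactly 1. With `reference = "tien"` the Tien et al. theoretical
#' Gly-X-Gly maxima are used instead. Values are clipped to [0, 1.2].
#'
#' @param atoms An atom tibble.
#' @param n_points Sphere points per atom (>= 92; default 960).
#' @param probe Probe radius in Angstrom (default 1.4).
#' @param reference `"self"` or `"tien"`.
#' @return A tibble `residue_index`, `residue_name`, `asa`, `ref_asa`,
#'   `rsa`.
#' @export
shrake_rupley_rsa <- function(atoms, n_points = 960L, probe = 1.4,
                              reference = c("self", "tien")) {
  reference <- match.arg(reference)
  assert_that(n_points >= 92, "n_points must be >= 92")
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  assert_that(all(is.finite(xyz)), "coordinates must be finite")
  radii <- atom_radii(atoms$atom_name)
  asa <- sasa_atoms(xyz, radii, n_points, probe)
  res <- tibble::tibble(residue_index = atoms$residue_index,
                        residue_name = atoms$residue_name, asa = asa)
  per <- dplyr::summarise(dplyr::group_by(res, .data$residue_index),
                          residue_name = dplyr::first(.data$residue_name),
                          asa = sum(.data$asa), .groups = "drop")
  ref <- vapply(seq_len(nrow(per)), function(k) {
    if (reference == "tien") {
      v <- MAX_ASA_TIEN[per$residue_name[k]]
      if (!is.na(v)) return(unname(v))
      warning("no reference ASA for residue name ", per$residue_name[k],
              "; using isolated-residue ASA", call. = FALSE)
    }
    sel <- atoms$residue_index == per$residue_index[k]
    sum(sasa_atoms(xyz[sel, , drop = FALSE], radii[sel], n_points, probe))
  }, numeric(1))
  per$ref_asa <- ref
  per$rsa <- pmin(pmax(per$asa / per$ref_asa, 0), 1.2)
  per
}

#' Count beta strands in a span
#'
#' @param ss Secondary-structure string (H/E/C), e.g. a DSSP export mapped
#'   to three states or the built-in fallback prediction.
#' @param span Optional `c(start, end)` (1-based inclusive); whole string
#'   by default.
#' @param min_len Minimum strand length (default 2).
#' @return Integer count of maximal `E` runs of length >= `min_len`.
#' @export
count_strands <- function(ss, span = NULL, min_len = 2L) {
  ch <- seq_chars(toupper(ss))
  if (!is.null(span)) {
    assert_that(span[1] >= 1 && span[2] <= length(ch) && span[1] <= span[2],
                "span out of range")
    ch <- ch[span[1]:span[2]]
  }
  r <- rle(ch)
  sum(r$values == "E" & r$lengths >= min_len)
}
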