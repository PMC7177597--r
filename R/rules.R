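#' PAC domain Cys-spacing rule
#'
#' Construct the spacing rule defining a PAC domain: a Gly anchor followed by
#' six Cys residues with constrained spacer lengths. A spacer length is the
#' number of residues strictly between two consecutive anchor residues. The
#' defaults are the canonical bounds for a bona fide PAC domain:
#' Gly (3) Cys1 (2) Cys2 (10,30) Cys3 (20,50) Cys4 (8,20) Cys5 (25,60) Cys6.
#'
#' @param gap_gly_c1 Exact number of residues between the Gly anchor and Cys1.
#' @param gap_c1_c2 Exact number of residues between Cys1 and Cys2.
#' @param gap_c2_c3,gap_c3_c4,gap_c4_c5,gap_c5_c6 Length-2 integer vectors
#'   `c(min, max)` bounding the remaining spacers.
#' @return An object of class `pac_rule`.
#' @examples
#' rule <- pac_rule()
#' min_max_span(rule)
#' @export
pac_rule <- function(gap_gly_c1 = 3L,
                     gap_c1_c2 = 2L,
                     gap_c2_c3 = c(10L, 30L),
                     gap_c3_c4 = c(20L, 50L),
                     gap_c4_c5 = c(8L, 20L),
                     gap_c5_c6 = c(25L, 60L)) {
  rng <- function(x, nm) {
    x <- as.integer(x)
    if (length(x) == 1) x <- c(x, x)
    assert_that(length(x) == 2 && !anyNA(x), paste0(nm, " must be c(min, max)"))
    assert_that(x[1] >= 0, paste0(nm, ": min must be >= 0"))
    assert_that(x[1] <= x[2], paste0(nm, ": min must be <= max"))
    x
  }
  ex <- function(x, nm) {
    x <- as.integer(x)[1]
    assert_that(!is.na(x) && x >= 0, paste0(nm, " must be a single integer >= 0"))
    x
  }
  structure(
    list(
      gap_gly_c1 = ex(gap_gly_c1, "gap_gly_c1"),
      gap_c1_c2 = ex(gap_c1_c2, "gap_c1_c2"),
      gap_c2_c3 = rng(gap_c2_c3, "gap_c2_c3"),
      gap_c3_c4 = rng(gap_c3_c4, "gap_c3_c4"),
      gap_c4_c5 = rng(gap_c4_c5, "gap_c4_c5"),
      gap_c5_c6 = rng(gap_c5_c6, "gap_c5_c6")
    ),
    class = "pac_rule"
  )
}

#' @export
print.pac_rule <- function(x, ...) {
  fmt <- function(g) if (g[1] == g[2]) as.character(g[1]) else paste0(g[1], ",", g[2])
  cat("<pac_rule> Gly (", x$gap_gly_c1, ") Cys1 (", x$gap_c1_c2, ") Cys2 (",
      fmt(x$gap_c2_c3), ") Cys3 (", fmt(x$gap_c3_c4), ") Cys4 (",
      fmt(x$gap_c4_c5), ") Cys5 (", fmt(x$gap_c5_c6), ") Cys6\n", sep = "")
  invisible(x)
}

# the four ranged spacers as a list of c(min, max)
ranged_gaps <- function(rule) {
  list(rule$gap_c2_c3, rule$gap_c3_c4, rule$gap_c4_c5, rule$gap_c5_c6)
}

# all five spacers as c(min, max), gly gap excluded
all_gaps <- function(rule) {
  c(list(c(rule$gap_c1_c2, rule$gap_c1_c2)), ranged_gaps(rule))
}

#' Minimal and maximal span of a spacing rule
#'
#' The span runs from the Gly anchor to Cys6 inclusive: 7 anchor residues
#' plus the five inter-Cys spacers plus the Gly-Cys1 spacer.
#'
#' @param rule A [pac_rule()].
#' @return A named integer vector `c(min_len, max_len)`.
#' @examples
#' min_max_span(pac_rule())  # 75, 172
#' @export
min_max_span <- function(rule = pac_rule()) {
  gaps <- all_gaps(rule)
  mins <- vapply(gaps, `[`, integer(1), 1)
  maxs <- vapply(gaps, `[`, integer(1), 2)
  c(min_len = 7L + rule$gap_gly_c1 + sum(mins),
    max_len = 7L + rule$gap_gly_c1 + sum(maxs))
}

#' Read a spacing rule from a YAML file
#'
#' The file may set any subset of the [pac_rule()] fields; ranged gaps are
#' two-element sequences, exact gaps single integers.
#'
#' @param path Path to a YAML file.
#' @return A `pac_rule`.
#' @export
read_pac_rule <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(pac_rule))
  bad <- setdiff(names(vals), known)
  assert_that(length(bad) == 0,
              paste0("unknown rule fields: ", paste(bad, collapse = ", ")))
  do.call(pac_rule, vals)
}
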