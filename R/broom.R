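# broom-style accessors for the package's result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a conservation profile
#'
#' @param x A [build_profile()] object.
#' @param ... Ignored.
#' @return A tibble with one row per column: `column`, `ic`, `consensus`,
#'   `gap_frac`.
#' @method tidy pac_profile
#' @export
tidy.pac_profile <- function(x, ...) {
  tibble::tibble(column = seq_along(x$ic), ic = x$ic,
                 consensus = seq_chars(x$consensus),
                 gap_frac = unname(x$freqs["-", ]))
}

#' One-row summary of a conservation profile
#'
#' @param x A [build_profile()] object.
#' @param ... Ignored.
#' @return A one-row tibble: `n_columns`, `n_seqs`, `mean_ic`, `max_ic`,
#'   `consensus`.
#' @method glance pac_profile
#' @export
glance.pac_profile <- function(x, ...) {
  tibble::tibble(n_columns = length(x$ic), n_seqs = x$n_seqs,
                 mean_ic = mean(x$ic), max_ic = max(x$ic),
                 consensus = x$consensus)
}

#' Tidy a disulfide bridge report
#'
#' @param x A [check_disulfides()] report.
#' @param ... Ignored.
#' @return The observed-pairs tibble (ordinal pair, SG-SG distance,
#'   expected/bonded flags).
#' @method tidy pac_bridge_report
#' @export
tidy.pac_bridge_report <- function(x, ...) x$observed

#' One-row summary of a disulfide bridge report
#'
#' @param x A [check_disulfides()] report.
#' @param ... Ignored.
#' @return A one-row tibble: `verdict`, `n_expected_bonded`, `n_extra_bonded`,
#'   `threshold`.
#' @method glance pac_bridge_report
#' @export
glance.pac_bridge_report <- function(x, ...) {
  tibble::tibble(verdict = x$verdict,
                 n_expected_bonded = sum(x$observed$bonded & x$observed$expected),
                 n_extra_bonded = sum(x$observed$bonded & !x$observed$expected),
                 threshold = x$threshold)
}
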