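#' Describe an isotopically labelled N source compound
#'
#' A labelled source is defined by its stoichiometry (C and N atoms per
#' molecule) and the atom% excess enrichment on each element. From these the
#' two quantities that drive all tracer accounting are derived: the molar
#' excess-13C : excess-15N ratio expected in tissue when every atom taken up
#' is retained, and the g C per g N mass ratio of the compound.
#'
#' @param name Compound label.
#' @param n_carbon,n_nitrogen C and N atoms per molecule (>= 1).
#' @param excess_13c,excess_15n Atom% excess enrichment on C and N, in
#'   (0, 100].
#'
#' @return An object of class `labelled_source`: a list with the fields
#'   above plus `c_mass_per_n_mass` (g C per g N, from stoichiometry).
#'
#' @examples
#' gln <- glutamine_source()
#' molar_excess_ratio(gln)   # 2.5 for U-13C5,15N2-gln at equal enrichment
#' gln$c_mass_per_n_mass     # 2.144 g C / g N
#' @export
labelled_source <- function(name, n_carbon, n_nitrogen,
                            excess_13c, excess_15n) {
  stopifnot(
    is.character(name), length(name) == 1L,
    n_carbon >= 1, n_nitrogen >= 1,
    excess_13c > 0, excess_13c <= 100,
    excess_15n > 0, excess_15n <= 100
  )
  out <- list(
    name = name,
    n_carbon = as.numeric(n_carbon),
    n_nitrogen = as.numeric(n_nitrogen),
    excess_13c = as.numeric(excess_13c),
    excess_15n = as.numeric(excess_15n),
    c_mass_per_n_mass = (n_carbon * ATOMIC_MASS_C) / (n_nitrogen * ATOMIC_MASS_N)
  )
  class(out) <- "labelled_source"
  out
}

#' @rdname labelled_source
#' @details `glutamine_source()` is the default tracer of the experiment:
#'   glutamine (C5H10N2O3) universally labelled on all five carbons and both
#'   nitrogens, 10 atom% excess on each element.
#' @export
glutamine_source <- function(excess_13c = 10, excess_15n = 10) {
  labelled_source("U-13C5,15N2-L-glutamine",
                  n_carbon = 5, n_nitrogen = 2,
                  excess_13c = excess_13c, excess_15n = excess_15n)
}

#' Theoretical all-atoms-retained molar excess 13C : 15N ratio
#'
#' The slope that a regression of excess 13C on excess 15N (both molar)
#' would have if tissue were built entirely from the labelled compound with
#' no carbon loss: `(n_carbon * excess_13c) / (n_nitrogen * excess_15n)`.
#' For uniformly labelled glutamine at equal enrichment this is 2.5.
#'
#' @param source A [labelled_source()].
#' @return A single number (dimensionless).
#' @export
molar_excess_ratio <- function(source) {
  stopifnot(inherits(source, "labelled_source"))
  (source$n_carbon * source$excess_13c) /
    (source$n_nitrogen * source$excess_15n)
}

#' @export
print.labelled_source <- function(x, ...) {
  cat(sprintf(
    "<labelled_source> %s\n  C%g N%g; excess 13C %.4g / 15N %.4g atom%%\n  molar excess ratio %.4g; %.4g g C / g N (%.4g g N / g C)\n",
    x$name, x$n_carbon, x$n_nitrogen, x$excess_13c, x$excess_15n,
    molar_excess_ratio(x), x$c_mass_per_n_mass, 1 / x$c_mass_per_n_mass
  ))
  invisible(x)
}
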