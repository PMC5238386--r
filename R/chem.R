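# Mass bookkeeping for dansylation labeling chemistry.

# monoisotopic atomic masses (Da), CODATA/AME values
.element_masses <- c(
  C  = 12.0,
  H  = 1.0078250319,
  N  = 14.0030740052,
  O  = 15.9949146221,
  S  = 31.97207069,
  P  = 30.97376151,
  Na = 22.98976928,
  K  = 38.9637064864,
  Cl = 34.96885271,
  F  = 18.9984031627
)

#' Monoisotopic mass of a molecular formula
#'
#' Computes the neutral monoisotopic mass from a Hill-style formula
#' string such as `"C3H7NO3"`.  Only the elements commonly found in
#' derivatized metabolites are supported (C, H, N, O, S, P, Na, K, Cl,
#' F).
#'
#' @param formula Character vector of molecular formulas.
#' @return Numeric vector of monoisotopic masses in Da.
#' @examples
#' monoisotopic_mass("C3H7NO3") # serine
#' @export
monoisotopic_mass <- function(formula) {
  vapply(formula, function(f) {
    stopifnot(is.character(f), nchar(f) > 0L)
    m <- gregexpr("([A-Z][a-z]?)([0-9]*)", f)[[1]]
    toks <- regmatches(f, list(m))[[1]]
    if (sum(nchar(toks)) != nchar(f)) {
      stop("cannot parse formula: ", f)
    }
    total <- 0
    for (tok in toks) {
      el <- sub("[0-9]*$", "", tok)
      cnt <- sub("^[A-Za-z]+", "", tok)
      cnt <- if (nzchar(cnt)) as.integer(cnt) else 1L
      if (!el %in% names(.element_masses)) {
        stop("unsupported element '", el, "' in formula ", f)
      }
      total <- total + .element_masses[[el]] * cnt
    }
    total
  }, numeric(1), USE.NAMES = FALSE)
}

#' Chemistry constants of the dansylation labeling scheme
#'
#' Each labeled amine/phenol group adds a net dansyl moiety
#' (C12H11NO2S) to the metabolite; the heavy reagent carries two 13C
#' substitutions per tag, so the heavy channel of an n-tag metabolite
#' sits n * 2.00671 Da above the light channel.
#'
#' @return A list with elements `proton_mass`, `dansyl_light_addition`
#'   (mass added per tag by the light reagent, Da),
#'   `c13_c12_spacing` (13C-12C mass difference, Da) and `tag_delta`
#'   (heavy-light spacing per tag, Da).
#' @export
chem_constants <- function() {
  spacing <- 13.0033548378 - 12.0
  list(
    proton_mass = 1.00727646688,
    dansyl_light_addition = monoisotopic_mass("C12H11NO2S"),
    c13_c12_spacing = spacing,
    tag_delta = 2 * spacing
  )
}

#' Theoretical m/z of a labeled, protonated metabolite
#'
#' @param neutral_mass Neutral monoisotopic mass of the unlabeled
#'   metabolite in Da.
#' @param n_tags Number of dansyl tags (labelable amine/phenol
#'   groups), an integer >= 1.
#' @param channel `"light"` (12C reagent) or `"heavy"` (13C2 reagent).
#' @return The m/z of the singly protonated, n-fold labeled ion.
#' @examples
#' labeled_mz(monoisotopic_mass("C3H7NO3"), 1, "light") # dns-serine
#' @export
labeled_mz <- function(neutral_mass, n_tags, channel = c("light", "heavy")) {
  channel <- match.arg(channel)
  if (any(neutral_mass <= 0)) stop("neutral_mass must be positive")
  if (any(n_tags < 1)) stop("n_tags must be >= 1")
  cc <- chem_constants()
  mz <- neutral_mass + n_tags * cc$dansyl_light_addition + cc$proton_mass
  if (channel == "heavy") mz <- mz + n_tags * cc$tag_delta
  mz
}

#' Neutral mass recovered from an observed light-channel m/z
#'
#' Inverse of [labeled_mz()]: strips the proton and the dansyl tags to
#' recover the neutral monoisotopic mass of the unlabeled metabolite.
#'
#' @param light_mz Observed m/z of the light-channel ion.
#' @param n_tags Number of dansyl tags.
#' @return Neutral monoisotopic mass in Da.
#' @export
recovered_neutral_mass <- function(light_mz, n_tags) {
  cc <- chem_constants()
  light_mz - cc$proton_mass - n_tags * cc$dansyl_light_addition
}
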