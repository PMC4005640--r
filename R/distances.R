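# Forster conversion between FRET efficiency and inter-dye distance.
#
# R = R0 * (1/E - 1)^(1/6), E = 1 / (1 + (R/R0)^6). The default Forster
# radius of 60 Angstrom is the standard literature value for the
# AF488/AF594 donor/acceptor pair; it is a parameter, never hard-coded in
# the operations.

#' Inter-dye distance from FRET efficiency
#'
#' Inverts the Forster relation: `R = r0 * (1/E - 1)^(1/6)`.
#'
#' @param E FRET efficiency, strictly inside (0, 1) (vectorized).
#' @param r0 Forster radius in Angstrom (default 60 for AF488/AF594).
#' @return distance(s) in Angstrom.
#' @examples
#' distance_from_E(0.5)          # exactly r0
#' distance_from_E(0.75)         # 50.0 Angstrom at r0 = 60
#' @export
distance_from_E <- function(E, r0 = 60) {
  .assert(.is_number(r0) && r0 > 0, "r0 must be positive")
  .assert(is.numeric(E) && all(is.finite(E)) && all(E > 0 & E < 1),
          "E must lie strictly inside (0, 1)")
  r0 * (1 / E - 1)^(1 / 6)
}

#' FRET efficiency from inter-dye distance
#'
#' `E = 1 / (1 + (R/r0)^6)`; the algebraic inverse of [distance_from_E()].
#'
#' @param R distance(s) in Angstrom, > 0.
#' @param r0 Forster radius in Angstrom.
#' @return efficiency in (0, 1).
#' @export
E_from_distance <- function(R, r0 = 60) {
  .assert(.is_number(r0) && r0 > 0, "r0 must be positive")
  .assert(is.numeric(R) && all(is.finite(R)) && all(R > 0), "R must be positive")
  1 / (1 + (R / r0)^6)
}

#' Distance change between two FRET states
#'
#' `delta_R = distance_from_E(E_a) - distance_from_E(E_b)`; positive when
#' state `a` is the more extended (lower-FRET) conformation.
#'
#' @param E_a,E_b efficiencies in (0, 1).
#' @param r0 Forster radius in Angstrom.
#' @return distance change in Angstrom.
#' @examples
#' delta_distance(0.29, 0.73)  # ~18.8 Angstrom domain opening
#' @export
delta_distance <- function(E_a, E_b, r0 = 60) {
  distance_from_E(E_a, r0) - distance_from_E(E_b, r0)
}
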