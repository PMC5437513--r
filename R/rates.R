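#' Elementary rate laws
#'
#' The three rate-law families of the model, all returning extensive fluxes
#' (mol/day) because every transport reaction crosses compartments of
#' different volume.
#'
#' `ferroportin_rate()` is the saturable export law
#' \deqn{v = \frac{V \cdot Volume \cdot [S]}{(K_m + [S] + [I_c])\,(1 + [Hep]/K_i)}}
#' where the isotopic twin of the substrate acts as a competitive inhibitor
#' (same transporter, symmetric in S and Ic) and hepcidin acts
#' non-competitively, mimicking removal of ferroportin molecules (a lowered
#' apparent limiting rate).
#'
#' @param S substrate concentration (M).
#' @param Ic competitive inhibitor (isotopic twin) concentration (M).
#' @param Hep hepcidin concentration (M).
#' @param V limiting rate (M/day; multiplied by `volume` to give mol/day).
#' @param Km Michaelis constant, shared by all ferroportin reactions (M).
#' @param Ki hepcidin non-competitive inhibition constant (M).
#' @param volume source compartment volume (L).
#' @return flux in mol/day.
#' @examples
#' ferroportin_rate(S = 0.01, Ic = 0, Hep = 0, V = 1, Km = 0.01,
#'                  Ki = 23e-9, volume = 1e-3)  # 5e-4 mol/day
#' @export
ferroportin_rate <- function(S, Ic, Hep, V, Km, Ki, volume) {
  stopifnot(S >= 0, Ic >= 0, Hep >= 0, Km > 0, Ki > 0, V >= 0, volume >= 0)
  V * volume * S / ((Km + S + Ic) * (1 + Hep / Ki))
}

#' @rdname ferroportin_rate
#' @param k first-order rate constant (per day).
#' @param source_volume volume of the substrate's compartment (L).
#' @export
mass_action_flux <- function(k, S, source_volume) {
  stopifnot(k >= 0, S >= 0, source_volume >= 0)
  k * S * source_volume
}

#' @rdname ferroportin_rate
#' @param NTBI_like concentration of NTBI or NTBI* (M).
#' @param Tf_like concentration of the transferrin species being loaded (M).
#' @param plasma_volume plasma volume (L).
#' @details `tf_binding_flux()` is irreversible second-order mass action
#'   (dissociation is negligible at a sub-femtomolar Kd); applying it to all
#'   six label combinations captures NTBI vs NTBI* competition naturally.
#' @export
tf_binding_flux <- function(k, NTBI_like, Tf_like, plasma_volume) {
  stopifnot(k >= 0, NTBI_like >= 0, Tf_like >= 0, plasma_volume >= 0)
  k * NTBI_like * Tf_like * plasma_volume
}
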