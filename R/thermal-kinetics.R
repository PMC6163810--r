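# CODATA 2018 exact values. k_B * N_A = R by construction.
.constants <- list(
  R  = 8.31446261815324,   # gas constant, J mol^-1 K^-1
  kB = 1.380649e-23,       # Boltzmann constant, J K^-1
  h  = 6.62607015e-34,     # Planck constant, J s
  e  = 1.602176634e-19,    # elementary charge, C
  Na = 6.02214076e23       # Avogadro constant, mol^-1
)

#' Physical constants used throughout the package
#'
#' CODATA (2018 exact) values of the gas constant `R` (J mol^-1 K^-1), the
#' Boltzmann constant `kB` (J K^-1), the Planck constant `h` (J s), the
#' elementary charge `e` (C) and the Avogadro constant `Na` (mol^-1).
#'
#' @return Named list of constants.
#' @examples
#' physicalConstants()$R
#' @export
physicalConstants <- function() .constants

#' Convert an Arrhenius activation energy to a Q10
#'
#' For a rate following Arrhenius behaviour, the fold-change over the
#' temperature interval `[t1, t2]` is
#' `exp((Ea/R) * (1/t1 - 1/t2))`. A Q10 uses a 10 K interval; e.g. 40 kJ/mol
#' over 290-300 K gives a Q10 of about 1.7.
#'
#' @param ea activation energy, kJ/mol.
#' @param t1,t2 lower and upper absolute temperatures, K (`t1 < t2`).
#' @return Dimensionless fold-change.
#' @seealso [eaFromQ10()]
#' @examples
#' q10FromEa(40, 290, 300)
#' @export
q10FromEa <- function(ea, t1, t2) {
  if (any(t1 <= 0) || any(t2 <= 0)) stop("temperatures must be positive")
  if (any(t1 >= t2)) stop("t1 must be below t2")
  exp((ea * 1000 / .constants$R) * (1 / t1 - 1 / t2))
}

#' Convert a Q10 to an Arrhenius activation energy
#'
#' Exact inverse of [q10FromEa()]:
#' `Ea = R * ln(Q10) / (1/t1 - 1/t2)`, reported in kJ/mol.
#'
#' @param q10 fold-change over the interval (> 0).
#' @param t1,t2 lower and upper absolute temperatures, K (`t1 < t2`).
#' @return Activation energy, kJ/mol.
#' @examples
#' eaFromQ10(2.2, 273.15, 283.15)  # ~50.7 kJ/mol, decade ending at 10 C
#' @export
eaFromQ10 <- function(q10, t1, t2) {
  if (any(q10 <= 0)) stop("q10 must be positive")
  if (any(t1 <= 0) || any(t2 <= 0)) stop("temperatures must be positive")
  if (any(t1 >= t2)) stop("t1 must be below t2")
  .constants$R * log(q10) / (1 / t1 - 1 / t2) / 1000
}

#' Q10 for the decade ending at a Celsius temperature
#'
#' Convenience wrapper adopting the convention that "Q10 at T degrees C"
#' refers to the interval `[T - 10, T]` degrees C.
#'
#' @param q10 fold-change (for [eaForDecade()]).
#' @param tc Celsius temperature at the top of the decade.
#' @param ea activation energy, kJ/mol (for [q10ForDecade()]).
#' @return Activation energy in kJ/mol, or a Q10.
#' @examples
#' eaForDecade(2.2, 10)  # low-temperature proton-conduction decade
#' eaForDecade(1.3, 40)  # high-temperature decade
#' @export
eaForDecade <- function(q10, tc) {
  eaFromQ10(q10, tc - 10 + 273.15, tc + 273.15)
}

#' @rdname eaForDecade
#' @export
q10ForDecade <- function(ea, tc) {
  q10FromEa(ea, tc - 10 + 273.15, tc + 273.15)
}

#' Express a molar energy in thermal (kBT) units
#'
#' Returns `e * 1000 / (R * t)`, i.e. the energy per mole divided by the
#' molar thermal energy `R*T`. At 300 K, 40 kJ/mol is about 16 kBT and
#' 60 kJ/mol about 24 kBT.
#'
#' @param e energy, kJ/mol.
#' @param t absolute temperature, K.
#' @return Dimensionless multiple of kBT.
#' @examples
#' energyInKbt(40, 300)
#' @export
energyInKbt <- function(e, t = 300) {
  if (any(t <= 0)) stop("temperature must be positive")
  e * 1000 / (.constants$R * t)
}

#' Thermal energy per mole
#'
#' `R * t` in kJ/mol; the inverse companion of [energyInKbt()].
#'
#' @param t absolute temperature, K.
#' @return kJ/mol per kBT.
#' @export
kbtInKj <- function(t = 300) {
  if (any(t <= 0)) stop("temperature must be positive")
  .constants$R * t / 1000
}

#' Thermal mode-cutoff frequency kB*T/h
#'
#' Vibrational modes near this frequency are partially excited at
#' temperature `t`; modes far above it are effectively frozen out. At room
#' temperature (300 K) the cutoff is about 6e12 Hz.
#'
#' @param t absolute temperature, K.
#' @return Frequency, Hz.
#' @examples
#' modeCutoffFrequency(300)
#' @export
modeCutoffFrequency <- function(t = 300) {
  if (any(t < 0)) stop("temperature must be nonnegative")
  .constants$kB * t / .constants$h
}

#' Number of vibrational degrees of freedom
#'
#' `3N - 6` for a nonlinear assembly of `N` atoms, `3N - 5` for a linear
#' one. A 976-atom cluster has 2922 vibrational degrees of freedom.
#'
#' @param nAtoms number of atoms (>= 2).
#' @param linear logical; is the assembly linear?
#' @return Integer count of vibrational modes.
#' @examples
#' vibrationalDof(976)
#' @export
vibrationalDof <- function(nAtoms, linear = FALSE) {
  if (any(nAtoms < 2)) stop("need at least 2 atoms")
  as.integer(3 * nAtoms - ifelse(linear, 5L, 6L))
}

#' Gating-cycle count over a channel lifetime
#'
#' A channel firing at `firingRate` Hz over a lifetime of `lifetime`
#' seconds must open and close `rate * lifetime` times; with `nDomains`
#' voltage-sensor domains the total number of domain gating events is that
#' count times `nDomains` (e.g. 10 Hz x 10 min x 4 domains = 24,000).
#'
#' @param firingRate opening rate, Hz.
#' @param lifetime channel lifetime, s.
#' @param nDomains number of voltage-sensor domains (default 1).
#' @return Number of gating events (numeric; integer-valued for integer
#'   inputs).
#' @examples
#' gatingCycleCount(10, 600)       # per channel
#' gatingCycleCount(10, 600, 4)    # per-domain total
#' @export
gatingCycleCount <- function(firingRate, lifetime, nDomains = 1) {
  if (any(firingRate < 0) || any(lifetime < 0) || any(nDomains < 0))
    stop("arguments must be nonnegative")
  firingRate * lifetime * nDomains
}
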