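# Unit system: lengths in Angstrom, energies in kcal/mol, charges in e,
# masses in amu, entropies in cal/mol/K, temperatures in K.

#' Physical constants used by mmgbsa
#'
#' A named list of the physical constants the package computes with:
#' `ke` Coulomb constant (kcal A mol^-1 e^-2, mainstream molecular-mechanics
#' convention), `R_kcal` / `R_cal` gas constant, `h` Planck constant (J s),
#' `kB` Boltzmann constant (J/K), `c_cm` speed of light (cm/s), `NA_avog`
#' Avogadro number, `amu` atomic mass unit (kg).
#'
#' @export
mm_constants <- list(
  ke      = 332.0637128,
  R_kcal  = 0.0019872,
  R_cal   = 1.9872,
  h       = 6.62607015e-34,
  kB      = 1.380649e-23,
  c_cm    = 2.99792458e10,
  NA_avog = 6.02214076e23,
  amu     = 1.66053906660e-27
)

# sqrt(kcal/mol/A^2/amu) -> cm^-1 for mass-weighted Hessian eigenvalues
.freq_factor <- function() {
  lam_si <- 4184 / mm_constants$NA_avog / 1e-20 / mm_constants$amu # s^-2
  sqrt(lam_si) / (2 * pi * mm_constants$c_cm)
}

# run code with a private, restored RNG stream
.with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

.cross3 <- function(a, b) {
  # row-wise cross product of n x 3 matrices
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

.rownorm <- function(m) sqrt(rowSums(m * m))

.deg2rad <- function(x) x * pi / 180
.rad2deg <- function(x) x * 180 / pi
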