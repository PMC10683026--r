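## Shared constants and small numeric helpers.

## Boltzmann gas constant in kJ mol^-1 K^-1.
.kB <- 0.008314462618

#' Thermal energy RT in kJ/mol
#'
#' The conventional value RT = 2.4789 kJ/mol near room temperature is used
#' throughout as the default thermodynamic constant of the free-energy
#' estimators; pass an explicit temperature to derive RT = kB * T instead.
#'
#' @param temperature Temperature in Kelvin, or `NULL` (default) for the
#'   canonical room-temperature constant.
#' @return RT in kJ/mol.
#' @examples
#' thermalRT()          # 2.4789
#' thermalRT(303.15)    # simulation temperature of a typical membrane system
#' @export
thermalRT <- function(temperature = NULL) {
  if (is.null(temperature)) return(2.4789)
  stopifnot(is.numeric(temperature), temperature > 0)
  .kB * temperature
}

## Row-wise log-sum-exp over blocks of columns; x is a matrix, returns vector
## per row when x has one block.
.logSumExpRows <- function(x) {
  m <- apply(x, 1L, max)
  m + log(rowSums(exp(x - m)))
}

## Angstrom <-> nanometre conversion is centralised so units never drift.
.angToNm <- function(x) x / 10
.nmToAng <- function(x) x * 10

.isWholeNumber <- function(x, tol = 1e-8) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && abs(x - round(x)) < tol
}

## Stable seed handling: every stochastic entry point calls this and restores
## the caller's RNG state on exit.
.withSeed <- function(seed, expr) {
  stopifnot(.isWholeNumber(seed))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}
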