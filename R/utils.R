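# Physical constants used throughout (SI unless noted)
.kB_over_e_mV <- 0.08617333262   # Boltzmann constant / elementary charge, mV per K
.e0_coulomb   <- 1.602176634e-19 # elementary charge, C
.R_gas        <- 8.314462618     # gas constant, J / (mol K)

#' Thermal voltage kT/e in millivolts
#'
#' @param temperature temperature in kelvin.
#' @return kT/e in mV.
#' @export
kT_mV <- function(temperature) {
  stopifnot(is.numeric(temperature), temperature > 0)
  .kB_over_e_mV * temperature
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `code` under a local RNG seed without disturbing the caller's
# RNG stream. Seeds are always explicit arguments in this package.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# 32-bit FNV-1a hash of a character scalar, for artifact provenance.
fnv1a <- function(x) {
  bytes <- as.integer(charToRaw(paste(x, collapse = "\n")))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), b) # keep in integer range
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

stop_if_not_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    stop(sprintf("`%s` must be a single positive finite number", name),
         call. = FALSE)
  invisible(x)
}
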