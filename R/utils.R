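#' Derive a child seed from a master seed
#'
#' All randomness in the package flows from one integer master seed. Each
#' simulation / analysis stage draws its own child seed with this splitting
#' scheme so that stages are individually reproducible and adding a stage
#' never perturbs the streams of earlier stages.
#'
#' @param seed master integer seed.
#' @param stage integer stage index (>= 0).
#' @return an integer in [0, 2^31 - 2] usable with [set.seed()].
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.numeric(stage))
  m <- 2147483647 # 2^31 - 1 (Mersenne prime); keeps seeds in 32-bit range
  s <- (as.numeric(seed) %% m)
  as.integer((s * 48271 + as.numeric(stage) * 16807 + 1) %% m)
}

# clip to [lo, hi]
clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# stable row-wise max of a list of equally sized matrices
pmax_list <- function(lst) Reduce(pmax, lst)

# half-open interval overlap: [s1,e1) vs [s2,e2)
overlaps <- function(s1, e1, s2, e2) s1 < e2 & s2 < e1

# is a position p inside [s, e)?
in_interval <- function(p, s, e) p >= s & p < e

`%||%` <- function(a, b) if (is.null(a)) b else a
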