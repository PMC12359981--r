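#' Counter-based seed derivation
#'
#' Derives a stream of independent 31-bit seeds from a master seed and a
#' counter (e.g. a replicate index) via a splitmix-style integer hash. Unlike
#' drawing seeds sequentially from one RNG stream, the derivation is a pure
#' function of `(master_seed, index)`, so replicates can be re-run, resumed or
#' executed in parallel without seed collisions or order dependence.
#'
#' @param master_seed Integer master seed.
#' @param index Non-negative integer counter (vectorised).
#' @return Integer seed(s) in `[1, 2^31 - 1]`.
#' @export
#' @examples
#' derive_seed(42, 0:3)
derive_seed <- function(master_seed, index) {
  master_seed <- as.integer(master_seed)
  stopifnot(length(master_seed) == 1L, !is.na(master_seed))
  vapply(as.integer(index), function(i) splitmix32(master_seed, i), integer(1))
}

# splitmix32 finalizer on (seed + golden-ratio * (index + 1)) mod 2^32,
# done in double arithmetic (exact below 2^53) then xor-shift mixed in
# 32-bit integer space; mapped into [1, 2^31 - 1] for set.seed().
splitmix32 <- function(seed, index) {
  x <- (as.numeric(seed) %% 2^32 + 2654435769 * (as.numeric(index) + 1)) %% 2^32
  x <- to_i32(x)
  x <- bitwXor(x, bitwShiftR_u(x, 16L))
  x <- u32_mul(x, 2246822519)
  x <- bitwXor(x, bitwShiftR_u(x, 13L))
  x <- u32_mul(x, 3266489917)
  x <- bitwXor(x, bitwShiftR_u(x, 16L))
  out <- (from_i32(x) %% (2^31 - 1)) + 1
  as.integer(out)
}

# helpers treating R's signed 32-bit integers as unsigned words
to_i32 <- function(u) {
  u <- u %% 2^32
  as.integer(u - 2^32 * (u >= 2^31))
}
from_i32 <- function(i) {
  x <- as.numeric(i)
  x + 2^32 * (x < 0)
}
bitwShiftR_u <- function(i, n) to_i32(floor(from_i32(i) / 2^n))
u32_mul <- function(i, k) {
  u <- from_i32(i)
  # split 32x32 multiply into 16-bit halves to stay exact in doubles
  lo <- u %% 2^16
  hi <- floor(u / 2^16)
  to_i32((lo * k + (hi * k %% 2^16) * 2^16) %% 2^32)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}
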