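`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive independent seed streams from a master seed
#'
#' Splits one integer seed into `n` child seeds so that separate stages
#' (placement, marker simulation, each permutation stream, ...) consume
#' independent randomness while the whole pipeline stays reproducible from a
#' single integer.
#'
#' @param seed master seed (integer).
#' @param n number of child seeds.
#' @return integer vector of length `n`, each in `[1, 2^31 - 2]`.
#' @export
derive_seeds <- function(seed, n) {
  stopifnot(is.numeric(seed), length(seed) == 1, n >= 1)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  sample.int(2147483646L, n)
}

abort_if <- function(cond, msg) if (cond) stop(msg, call. = FALSE)

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x)

## modal value of a character vector; ties resolved by `order` of first
## appearance in `levels`
modal_label <- function(x, levels = sort(unique(x))) {
  tab <- table(factor(x, levels = levels))
  names(tab)[which.max(tab)]
}
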