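# small shared helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible sub-seed from a master seed
#'
#' Keeps every derived seed a positive 32-bit integer so it is safe for
#' `set.seed()` and the C++ trainers.
#'
#' @param seed master integer seed
#' @param salt integer distinguishing the consumer (fold index, stage, ...)
#' @return an integer seed
#' @export
derive_seed <- function(seed, salt = 0L) {
  s <- (as.numeric(seed) * 48271 + 7919 * (as.numeric(salt) + 1)) %%
    2147483647
  as.integer(max(1, s))
}

#' Significance stars for a p-value
#'
#' Mapping: p < 0.05 `*`, p < 0.01 `**`, p < 0.001 `***`, p < 0.0001 `****`,
#' otherwise `ns`.
#'
#' @param p p-value
#' @return character star code
#' @export
p_stars <- function(p) {
  stopifnot(is.numeric(p), length(p) == 1L, !is.na(p))
  if (p < 1e-4) "****"
  else if (p < 1e-3) "***"
  else if (p < 1e-2) "**"
  else if (p < 0.05) "*"
  else "ns"
}

# index of the grid channel nearest to a target wavenumber
nearest_channel <- function(grid, wavenumber) {
  which.min(abs(grid$values - wavenumber))
}

assert_scalar_num <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lower || x > upper)
    stop(sprintf("`%s` must be a single number in [%s, %s]", name,
                 format(lower), format(upper)), call. = FALSE)
  invisible(x)
}
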