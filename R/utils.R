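# Internal helpers: error signalling, rounding conventions, seed fan-out.

abort_domain <- function(msg) {
  stop(errorCondition(msg, class = c("plumetox_domain_error", "plumetox_error")))
}

abort_config <- function(msg) {
  stop(errorCondition(msg, class = c("plumetox_config_error", "plumetox_error")))
}

abort_data <- function(msg) {
  stop(errorCondition(msg, class = c("plumetox_data_error", "plumetox_error")))
}

#' Round half away from zero
#'
#' Reporting convention for scenario tables: exact halves round away from
#' zero (so 71.5 becomes 72), unlike base R's round-half-even. LODs are
#' reported at one decimal, concentrations at integer precision.
#'
#' @param x numeric vector.
#' @param digits decimal places to keep (default 0).
#' @return rounded numeric vector.
#' @examples
#' round_half_away(71.5)   # 72
#' round_half_away(0.5714, 1)  # 0.6
#' @export
round_half_away <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

# Deterministic child seed so generators can be re-run independently from
# one global seed. Keeps results < 2^31 - 1.
child_seed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((as.numeric(seed) * 48271 + h * 2654435) %% 2147483629)
}

# Evaluate expr with a local RNG state seeded by `seed`; the caller's RNG
# stream is untouched. NULL seed draws from the current stream.
with_local_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

check_scalar <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    abort_config(sprintf("'%s' must be a finite numeric scalar", name))
  if (positive && x <= 0)
    abort_config(sprintf("'%s' must be > 0 (got %g)", name, x))
  if (nonneg && x < 0)
    abort_config(sprintf("'%s' must be >= 0 (got %g)", name, x))
  invisible(x)
}
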