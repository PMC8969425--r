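# internal helpers shared across modules

#' Round half away from zero
#'
#' Rounds to `digits` decimal places with halves carried away from zero, the
#' convention used when reporting outside-band percentages (so 11.65 prints
#' as 11.7, not banker's-rounded to 11.6).
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector of the same length.
#' @export
#' @examples
#' round_half_away(11.65, 1)
round_half_away <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# log-sum-exp, stable for large negative inputs
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# recycle a possibly-missing parameter vector to length n
rep_par <- function(x, n, default = 0) {
  if (is.null(x)) rep.int(default, n) else rep_len(as.numeric(x), n)
}

# prefix-stable per-replicate seeds: replicate r always receives the same
# seed for a given master seed, whatever the total replicate count K
replicate_seeds <- function(seed, K) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  sample.int(.Machine$integer.max, K)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

abort_pk <- function(msg, ...) stop(sprintf(msg, ...), call. = FALSE)
warn_pk <- function(msg, ...) warning(sprintf(msg, ...), call. = FALSE)
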