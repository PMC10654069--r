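#' Monod growth kinetics
#'
#' The hyperbolic reference model `mu = mu_max * S / (K_S + S)`: growth
#' approaches `mu_max` at substrate saturation and equals `mu_max / 2` at
#' `S = K_S`, the half-saturation constant.
#'
#' @param S substrate concentration, uM (>= 0); vectorized.
#' @param mu_max maximum specific growth rate, d^-1 (> 0).
#' @param K_S half-saturation constant, uM (> 0).
#' @return specific growth rate, d^-1.
#' @export
#' @examples
#' monod_growth(0.5, mu_max = 1.2, K_S = 0.5)  # half of mu_max
monod_growth <- function(S, mu_max, K_S) {
  if (any(is.na(S)) || any(S < 0)) {
    stop("substrate concentration must be non-negative", call. = FALSE)
  }
  if (mu_max <= 0 || K_S <= 0) {
    stop("mu_max and K_S must be positive", call. = FALSE)
  }
  mu_max * S / (K_S + S)
}
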