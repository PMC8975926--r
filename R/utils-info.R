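#' Plug-in Shannon entropy (base 2)
#'
#' Empirical entropy of a discrete vector from observed frequencies, with no
#' bias correction. The plug-in estimator is the one all information-theoretic
#' criteria in this package share, so their outputs stay mutually consistent.
#'
#' @param x a vector treated as categorical (factors, integers, strings).
#' @return entropy in bits.
#' @export
#' @examples
#' entropy_bits(c(0, 0, 1, 1)) # 1 bit
entropy_bits <- function(x) {
  if (length(x) == 0L) stop("entropy_bits(): empty input")
  p <- tabulate(as.integer(factor(x)))
  p <- p / sum(p)
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Plug-in mutual information (base 2)
#'
#' I(X;Y) = H(X) + H(Y) - H(X,Y) from the empirical joint distribution.
#'
#' @param x,y equal-length vectors treated as categorical.
#' @return mutual information in bits (non-negative up to floating error).
#' @export
mutual_information <- function(x, y) {
  if (length(x) != length(y)) stop("mutual_information(): length mismatch")
  if (length(x) == 0L) stop("mutual_information(): empty input")
  ok <- !(is.na(x) | is.na(y))
  x <- x[ok]; y <- y[ok]
  max(0, entropy_bits(x) + entropy_bits(y) - entropy_bits(paste(x, y, sep = "\r")))
}

# Conditional MI I(X;Y|Z) by plug-in decomposition; used by the JMI criterion
# through I(X, Xs; Y) = I(Xs; Y) + I(X; Y | Xs).
conditional_mi <- function(x, y, z) {
  ok <- !(is.na(x) | is.na(y) | is.na(z))
  x <- x[ok]; y <- y[ok]; z <- z[ok]
  hz <- entropy_bits(z)
  hxz <- entropy_bits(paste(x, z, sep = "\r"))
  hyz <- entropy_bits(paste(y, z, sep = "\r"))
  hxyz <- entropy_bits(paste(x, y, z, sep = "\r"))
  max(0, hxz + hyz - hxyz - hz)
}

#' Equal-frequency discretization
#'
#' Bins a continuous vector into approximately equal-count levels using sample
#' quantile cut points. Vectors that are already discrete — integer-valued
#' with at most `max_levels` states — pass through with their level structure
#' intact, so plug-in information quantities on discrete data are exact. This
#' is the single discretization used before every information-theoretic
#' computation (feature selection, rule mining, mutual-information networks)
#' so that all stages see the same item universe.
#'
#' @param x numeric vector.
#' @param bins target number of bins for continuous input (default 4).
#' @param max_levels level count up to which integer-valued input is treated
#'   as already discrete (default 12).
#' @return integer vector of bin codes (1-based); `NA` propagates.
#' @export
discretize_ef <- function(x, bins = 4, max_levels = 12) {
  stopifnot(bins >= 2)
  ux <- unique(x[!is.na(x)])
  discrete <- length(ux) <= bins ||
    (all(ux == round(ux)) && length(ux) <= max_levels)
  if (discrete) {
    return(as.integer(factor(x, levels = sort(ux))))
  }
  qs <- stats::quantile(x, probs = seq(0, 1, length.out = bins + 1),
                        na.rm = TRUE, names = FALSE, type = 7)
  qs <- unique(qs)
  qs[1] <- -Inf; qs[length(qs)] <- Inf
  as.integer(cut(x, breaks = qs, labels = FALSE, include.lowest = TRUE))
}

# Deterministically spawn per-stage child seeds from one master seed so that
# stages can be rerun in isolation. Keeps values well below .Machine$integer.max.
spawn_seeds <- function(seed, n, stage = "") {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  base <- sum(utf8ToInt(paste0("chronoanx", stage))) %% 1000L
  # double arithmetic: exact below 2^53, result always a valid 32-bit seed
  as.integer((as.numeric(seed) * 7919 + base + 104729 * seq_len(n)) %% 2147483587)
}
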