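#' Karlin-Altschul parameters for an ungapped scoring scheme
#'
#' Computes the scale parameter lambda and the search-space constant K of
#' the extreme-value distribution of ungapped local alignment scores, so
#' that raw scores can be converted to bit scores
#' \eqn{S' = (\lambda S - \ln K)/\ln 2} and expect values
#' \eqn{E = K m n e^{-\lambda S}}.
#'
#' Lambda is the positive root of \eqn{\sum_s p_s e^{\lambda s} = 1},
#' found by bisection to 1e-9. K is computed with the standard ungapped
#' lattice approximation: with score span \eqn{d} (the gcd of the score
#' values), relative entropy \eqn{H = \lambda \sum_s s\, p_s e^{\lambda s}}
#' and the renewal correction
#' \eqn{\sigma = \sum_{j\ge1} j^{-1}\big[\sum_{s<0} P_j(s) e^{\lambda s} +
#' \sum_{s\ge0} P_j(s)\big]} (with \eqn{P_j} the j-fold convolution of the
#' score distribution),
#' \deqn{K = d\,\lambda\,e^{-2\sigma} / (H (1 - e^{-\lambda d})).}
#'
#' @param match Positive match score.
#' @param mismatch Negative mismatch score.
#' @param composition Base composition (length-4 probability vector,
#'   default uniform). Match probability is \eqn{\sum_i p_i^2} under the
#'   independence model.
#' @param tol Bisection tolerance for lambda (default 1e-9).
#' @return List with `lambda`, `K`, `H` (relative entropy in nats).
#' @export
#' @examples
#' karlin_altschul_params(1, -2)  # classic blastn-like scheme
karlin_altschul_params <- function(match, mismatch,
                                   composition = rep(0.25, 4),
                                   tol = 1e-9) {
  stopifnot(length(composition) == 4, all(composition >= 0))
  composition <- composition / sum(composition)
  p_match <- sum(composition^2)
  p_mis <- 1 - p_match
  escore <- p_match * match + p_mis * mismatch
  if (escore >= 0)
    stop("expected score per aligned pair must be negative ",
         "(got ", signif(escore, 4), ")", call. = FALSE)
  if (match <= 0) stop("match score must be positive", call. = FALSE)

  f <- function(l) p_match * exp(l * match) + p_mis * exp(l * mismatch) - 1
  lo <- 0; hi <- 1
  while (f(hi) < 0) hi <- hi * 2
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (f(mid) < 0) lo <- mid else hi <- mid
  }
  lambda <- (lo + hi) / 2

  scores <- c(match, mismatch)
  probs <- c(p_match, p_mis)
  d <- gcd2(abs(match), abs(mismatch))
  H <- lambda * sum(scores * probs * exp(lambda * scores))

  # renewal correction sigma via convolution powers of the score
  # distribution on the lattice
  lo_s <- min(scores); hi_s <- max(scores)
  offset <- -lo_s
  p <- numeric(hi_s - lo_s + 1L)
  p[scores + offset + 1L] <- probs
  conv <- p
  sigma <- 0
  for (j in 1:60) {
    vals <- seq_along(conv) - 1L - j * offset  # support of j-fold sum
    neg <- vals < 0
    term <- sum(conv[neg] * exp(lambda * vals[neg])) + sum(conv[!neg])
    sigma <- sigma + term / j
    if (term / j < 1e-12) break
    conv <- convolve_probs(conv, p)
  }
  K <- d * lambda * exp(-2 * sigma) / (H * (1 - exp(-lambda * d)))
  list(lambda = lambda, K = K, H = H)
}

gcd2 <- function(a, b) {
  while (b != 0) { t <- b; b <- a %% b; a <- t }
  a
}

convolve_probs <- function(a, b) {
  out <- numeric(length(a) + length(b) - 1L)
  for (i in seq_along(b)) if (b[i] > 0)
    out[i:(i + length(a) - 1L)] <- out[i:(i + length(a) - 1L)] + a * b[i]
  out
}
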