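#' Negative binomial log-probability (mean/dispersion form)
#'
#' \eqn{f_{NB}(x \mid \mu, \theta) =
#' \frac{\Gamma(x+\theta)}{\Gamma(x+1)\Gamma(\theta)}
#' \left(\frac{\theta}{\theta+\mu}\right)^{\theta}
#' \left(\frac{\mu}{\theta+\mu}\right)^{x}}, evaluated on the log scale via
#' log-gamma so large counts and extreme dispersions stay finite. As
#' \eqn{\theta \to \infty} the distribution approaches Poisson(\eqn{\mu}).
#'
#' @param x non-negative integer counts.
#' @param mu mean, positive.
#' @param theta dispersion, positive.
#' @return log-probabilities, recycled to a common length.
#' @examples
#' exp(nbLogPMF(0, mu = 1, theta = 1))  # 0.5
#' @export
nbLogPMF <- function(x, mu, theta) {
  stopifnot(all(x >= 0), all(mu > 0), all(theta > 0))
  lgamma(x + theta) - lgamma(theta) - lgamma(x + 1) +
    theta * (log(theta) - log(theta + mu)) +
    x * (log(mu) - log(theta + mu))
}

#' Zero-inflated negative binomial log-probability
#'
#' Mixture of a point mass at zero (probability \code{pi}) and a negative
#' binomial: \eqn{f(x) = \pi \delta_0(x) + (1-\pi) f_{NB}(x)}. The
#' \eqn{x = 0} branch is evaluated by log-sum-exp of the two mixture terms;
#' at \code{pi = 0} the function reduces exactly to \code{\link{nbLogPMF}}.
#'
#' @inheritParams nbLogPMF
#' @param pi zero-inflation probability in \eqn{[0, 1]}.
#' @return log-probabilities.
#' @export
zinbLogPMF <- function(x, pi, mu, theta) {
  stopifnot(all(pi >= 0), all(pi <= 1))
  n <- max(length(x), length(pi), length(mu), length(theta))
  x <- rep_len(x, n); pi <- rep_len(pi, n)
  mu <- rep_len(mu, n); theta <- rep_len(theta, n)
  lnb <- nbLogPMF(x, mu, theta)
  out <- log1p(-pi) + lnb
  z <- x == 0
  if (any(z)) {
    # log(pi + (1-pi) * nb0) via log-sum-exp, tolerating pi = 0 or 1
    a <- log(pi[z])
    b <- log1p(-pi[z]) + lnb[z]
    m <- pmax(a, b)
    out[z] <- ifelse(is.infinite(m) & m < 0, -Inf,
                     m + log(exp(a - m) + exp(b - m)))
  }
  out
}

#' ZINB reconstruction loss
#'
#' Negative ZINB log-likelihood of the raw counts under the decoder
#' parameters, plus the ridge penalty \eqn{\lambda \, \overline{\pi^2}}
#' that keeps the zero-inflation probabilities from absorbing all zeros.
#' Aggregation is the mean over entries by default (size-invariant); set
#' \code{reduction = "sum"} for the summed form.
#'
#' @param counts raw (unnormalized) count matrix, spots x genes.
#' @param mu,theta,pi decoder parameter matrices of the same shape.
#' @param lambda_pi weight of the \eqn{\pi^2} regularizer.
#' @param reduction \code{"mean"} or \code{"sum"}.
#' @return a single non-negative-free scalar (finite for valid parameters).
#' @export
zinbLoss <- function(counts, mu, theta, pi, lambda_pi = 1,
                     reduction = c("mean", "sum")) {
  reduction <- match.arg(reduction)
  stopifnot(lambda_pi >= 0)
  ll <- zinbLogPMF(as.vector(counts), as.vector(pi), as.vector(mu),
                   as.vector(theta))
  if (reduction == "mean") -mean(ll) + lambda_pi * mean(pi^2)
  else -sum(ll) + lambda_pi * sum(pi^2)
}
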