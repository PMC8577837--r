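# Scalar count-distribution primitives: Poisson and Conway-Maxwell (CoM)
# Poisson in natural coordinates.
#
# A CoM-Poisson distribution p(n) proportional to (lambda^n / n!)^nu has
# natural parameters (theta_n, theta_star) = (nu * log lambda, -nu) with
# sufficient statistic (n, log n!). theta_star = -1 recovers a Poisson with
# rate exp(theta_n). The log partition has no closed form and is evaluated by
# truncating the series; all series are accumulated in log space.

#' Poisson log probability mass
#'
#' @param n Non-negative integer count(s).
#' @param log_rate Log of the Poisson rate (natural parameter).
#' @return Log-probabilities \code{n * log_rate - exp(log_rate) - log(n!)}.
#' @examples
#' exp(poisson_log_pmf(0, 0))  # e^-1
#' @export
poisson_log_pmf <- function(n, log_rate) {
  check_counts(n)
  n * log_rate - exp(log_rate) - lgamma(n + 1)
}

check_com_params <- function(theta_n, theta_star) {
  if (length(theta_star) == 1L) theta_star <- rep(theta_star, length(theta_n))
  if (length(theta_star) != length(theta_n))
    stop("'theta_n' and 'theta_star' must have matching length", call. = FALSE)
  if (any(!is.finite(theta_n)) || any(!is.finite(theta_star)))
    stop("CoM-Poisson parameters must be finite", call. = FALSE)
  if (any(theta_star >= 0))
    stop("'theta_star' must be strictly negative (the series diverges otherwise)",
         call. = FALSE)
  theta_star
}

#' Default series truncation for CoM-Poisson evaluations
#'
#' The cutoff is at least 128 and at least ten times the CoM location
#' parameter \code{exp(theta_n / -theta_star)}, which bounds the neglected
#' tail mass below roughly 1e-12 in the regimes the models operate in.
#'
#' @param theta_n,theta_star CoM-Poisson natural parameters (vectors allowed).
#' @return A single integer cutoff (maximum count retained in the series).
#' @export
com_max_count <- function(theta_n, theta_star) {
  theta_star <- check_com_params(theta_n, theta_star)
  loc <- exp(theta_n / (-theta_star))
  max(128L, as.integer(ceiling(10 * max(loc))))
}

# Truncated log-partition per parameter pair, vectorized over neurons.
# Returns a vector psi_i = log sum_n exp(n * theta_n[i] + log(n!) * theta_star[i]).
com_log_partition_vec <- function(theta_n, theta_star, max_count = NULL) {
  theta_star <- check_com_params(theta_n, theta_star)
  if (is.null(max_count)) max_count <- com_max_count(theta_n, theta_star)
  ns <- 0:max_count
  m <- outer(ns, theta_n) + outer(lgamma(ns + 1), theta_star)
  mx <- apply(m, 2L, max)
  mx + log(colSums(exp(sweep(m, 2L, mx))))
}

#' Truncated CoM-Poisson log-partition function
#'
#' @param theta_n,theta_star Natural parameters; vectors describe a product of
#'   independent CoM-Poisson distributions (one per neuron).
#' @param max_count Series truncation cutoff; default [com_max_count()].
#' @param per_neuron If \code{TRUE} return the per-neuron log-partition
#'   vector, otherwise their sum (the log partition of the product model).
#' @return Log-partition value(s); monotone non-decreasing in
#'   \code{max_count}.
#' @export
com_log_partition <- function(theta_n, theta_star, max_count = NULL,
                              per_neuron = FALSE) {
  psi <- com_log_partition_vec(theta_n, theta_star, max_count)
  if (per_neuron) psi else sum(psi)
}

# Normalized truncated pmf table, (max_count + 1) x length(theta_n).
com_pmf_table <- function(theta_n, theta_star, max_count = NULL) {
  theta_star <- check_com_params(theta_n, theta_star)
  if (is.null(max_count)) max_count <- com_max_count(theta_n, theta_star)
  ns <- 0:max_count
  m <- outer(ns, theta_n) + outer(lgamma(ns + 1), theta_star)
  mx <- apply(m, 2L, max)
  e <- exp(sweep(m, 2L, mx))
  sweep(e, 2L, colSums(e), "/")
}

#' Truncated moments of CoM-Poisson distributions
#'
#' Means and variances computed from the truncation-normalized pmf. In the
#' regime where neither the location nor the shape parameter is small, the
#' mean is approximately \code{lambda + 1/(2 nu) - 1/2} and the variance
#' approximately \code{lambda / nu}.
#'
#' @inheritParams com_log_partition
#' @return A list with components \code{mean} and \code{variance} (vectors).
#' @export
com_moments <- function(theta_n, theta_star, max_count = NULL) {
  p <- com_pmf_table(theta_n, theta_star, max_count)
  ns <- 0:(nrow(p) - 1L)
  mu <- colSums(p * ns)
  v <- colSums(p * ns^2) - mu^2
  list(mean = mu, variance = v)
}

# Truncated expectation of log(n!), needed for the dual (mean) coordinate of
# the dispersion parameters.
com_mean_lfactorial <- function(theta_n, theta_star, max_count = NULL) {
  p <- com_pmf_table(theta_n, theta_star, max_count)
  ns <- 0:(nrow(p) - 1L)
  colSums(p * lgamma(ns + 1))
}

#' Mode of a CoM-Poisson distribution
#'
#' The mode is the floor of the location parameter
#' \code{lambda = exp(theta_n / -theta_star)}.
#'
#' @inheritParams com_log_partition
#' @return Integer mode(s).
#' @export
com_mode <- function(theta_n, theta_star) {
  theta_star <- check_com_params(theta_n, theta_star)
  # epsilon guards against the location landing a rounding error below an
  # integer (e.g. exp(2 log 5 / 2) < 5)
  floor(exp(theta_n / (-theta_star)) + 1e-9)
}

# Inverse-CDF sampling from the truncated pmf; returns an m x dN matrix.
# Uses the current R RNG stream.
com_sample <- function(m, theta_n, theta_star, max_count = NULL) {
  p <- com_pmf_table(theta_n, theta_star, max_count)
  ns <- 0:(nrow(p) - 1L)
  out <- matrix(0L, m, length(theta_n))
  for (i in seq_along(theta_n))
    out[, i] <- sample(ns, m, replace = TRUE, prob = p[, i])
  out
}
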