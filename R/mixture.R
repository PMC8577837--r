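# Stimulus-independent finite mixtures of independent Poisson (IP) or
# CoM-Poisson-based (CB) components, in exponential-family form.
#
# The joint model over counts n and latent component index k is
#   p(n, k) = exp(theta_n . n [+ theta_star . lf(n)]
#                 + theta_k . d(k) + n . theta_nk . d(k) - psi)
# with d(k) the length-(dK - 1) indicator of components 2..dK (component 1 is
# the baseline, d(1) = 0), lf(n) the vector of log-factorials, and psi the
# log partition. For IP the base measure is 1 / prod(n_i!); for CB the
# log-factorial term carries the shared dispersion parameters theta_star and
# the base measure is 1. theta_star = -1 recovers the IP model exactly.

#' Construct a mixture in natural coordinates
#'
#' @param theta_n Length-dN baseline natural parameters (log rates for IP).
#' @param theta_k Length-(dK - 1) index-bias parameters.
#' @param theta_nk dN x (dK - 1) modulation matrix; component k > 1 has
#'   natural parameters \code{theta_n + theta_nk[, k - 1]}, so each column
#'   acts as a log-gain on the baseline rates.
#' @param theta_star Optional length-dN dispersion parameters (strictly
#'   negative); present for CB mixtures, absent (implicitly -1) for IP.
#' @return An object of class \code{"mixture_natural"}.
#' @export
mixture_natural <- function(theta_n, theta_k = numeric(0),
                            theta_nk = matrix(0, length(theta_n), 0),
                            theta_star = NULL) {
  theta_n <- as.numeric(theta_n)
  theta_k <- as.numeric(theta_k)
  theta_nk <- as.matrix(theta_nk)
  dN <- length(theta_n)
  dK <- length(theta_k) + 1L
  if (!identical(dim(theta_nk), c(dN, dK - 1L)) && !(dK == 1L && ncol(theta_nk) == 0))
    stop("'theta_nk' must be dN x (dK - 1)", call. = FALSE)
  if (any(!is.finite(theta_n)) || any(!is.finite(theta_k)) ||
      (length(theta_nk) && any(!is.finite(theta_nk))))
    stop("mixture natural parameters must be finite", call. = FALSE)
  if (!is.null(theta_star)) check_com_params(theta_n, theta_star)
  structure(list(theta_n = theta_n, theta_k = theta_k,
                 theta_nk = matrix(theta_nk, dN, dK - 1L),
                 theta_star = if (is.null(theta_star)) NULL else as.numeric(theta_star),
                 dN = dN, dK = dK,
                 family = if (is.null(theta_star)) "IP" else "CB"),
            class = "mixture_natural")
}

#' @export
print.mixture_natural <- function(x, ...) {
  cat(sprintf("%s mixture in natural coordinates: %d neurons, %d components\n",
              x$family, x$dN, x$dK))
  invisible(x)
}

#' Natural parameters from mixture weights and component rates
#'
#' Inverse reparameterization of an IP mixture: given weights w and per
#' component rate vectors lambda_k, produces the natural parameters under
#' which the joint density equals \code{w_k * prod_i Poisson(n_i; lambda_ik)}.
#'
#' @param weights Length-dK simplex of strictly positive mixture weights.
#' @param rates dN x dK matrix of strictly positive rates (columns index
#'   components).
#' @return A \code{"mixture_natural"} IP object; exact inverse of
#'   [weights_rates_from_natural()].
#' @export
natural_from_weights_rates <- function(weights, rates) {
  rates <- as.matrix(rates)
  if (any(weights <= 0) || any(rates <= 0))
    stop("weights and rates must be strictly positive", call. = FALSE)
  weights <- weights / sum(weights)
  dK <- length(weights)
  if (ncol(rates) != dK) stop("ncol(rates) must equal length(weights)", call. = FALSE)
  theta_n <- log(rates[, 1L])
  theta_nk <- log(rates[, -1L, drop = FALSE]) - theta_n
  # psi_N(theta) = sum_i exp(theta_i) for an independent Poisson model
  psi1 <- sum(rates[, 1L])
  psik <- colSums(rates[, -1L, drop = FALSE])
  theta_k <- if (dK > 1L) log(weights[-1L] / weights[1L]) + psi1 - psik else numeric(0)
  mixture_natural(theta_n, theta_k, theta_nk)
}

#' Mixture weights and component rates from natural parameters
#'
#' @param m An IP \code{"mixture_natural"} object.
#' @return A list with \code{weights} (length-dK simplex) and \code{rates}
#'   (dN x dK matrix).
#' @export
weights_rates_from_natural <- function(m) {
  stopifnot(inherits(m, "mixture_natural"))
  if (m$family != "CB" && !is.null(m$theta_star))
    stop("expected IP parameters", call. = FALSE)
  comp <- component_log_rates(m)
  rates <- exp(comp)
  a <- c(0, m$theta_k) + colSums(rates)
  list(weights = softmax(a), rates = rates)
}

# dN x dK matrix of component natural parameters theta_n + theta_nk . d(k).
component_log_rates <- function(m) {
  cbind(m$theta_n, m$theta_n + m$theta_nk, deparse.level = 0)
}

#' Natural parameters of one mixture component
#'
#' Component 1 is the baseline \code{(theta_n, theta_star)}; component k > 1
#' adds column k - 1 of the modulation matrix to \code{theta_n}. The
#' dispersion parameters (CB) are shared by every component.
#'
#' @param m A \code{"mixture_natural"} object.
#' @param k Component index in 1..dK.
#' @return A list with \code{theta_n} and \code{theta_star} (NULL for IP).
#' @export
component_params <- function(m, k) {
  stopifnot(inherits(m, "mixture_natural"))
  if (k < 1 || k > m$dK || k != floor(k)) stop("component index out of range", call. = FALSE)
  th <- if (k == 1L) m$theta_n else m$theta_n + m$theta_nk[, k - 1L]
  list(theta_n = th, theta_star = m$theta_star)
}

# Per-component log-partition vector psi_k of the count model given k, plus
# the unnormalized index scores a_k = theta_k . d(k) + psi_k.
component_scores <- function(m, max_count = NULL) {
  comp <- component_log_rates(m)
  if (m$family == "IP") {
    psi <- colSums(exp(comp))
  } else {
    if (is.null(max_count)) max_count <- com_max_count(as.vector(comp), rep(m$theta_star, m$dK))
    psi <- vapply(seq_len(m$dK), function(k)
      sum(com_log_partition_vec(comp[, k], m$theta_star, max_count)), numeric(1))
  }
  list(psi = psi, a = c(0, m$theta_k) + psi)
}

#' Log-partition function of a mixture
#'
#' \code{log sum_k exp(theta_k . d(k) + psi_component(k))}, with the
#' independent-Poisson closed form \code{psi(theta) = sum_i exp(theta_i)} for
#' IP components and truncated series for CB components.
#'
#' @param m A \code{"mixture_natural"} object.
#' @param max_count Optional series truncation cutoff (CB only).
#' @return The scalar log-partition value normalizing the joint density.
#' @export
log_partition <- function(m, max_count = NULL) {
  logsumexp(component_scores(m, max_count)$a)
}

#' Log probabilities of the latent component indices
#'
#' @inheritParams log_partition
#' @return Length-dK vector of log p(k); exponentials sum to 1.
#' @export
index_log_probabilities <- function(m, max_count = NULL) {
  a <- component_scores(m, max_count)$a
  a - logsumexp(a)
}

#' Joint log density of counts and a component index
#'
#' @inheritParams log_partition
#' @param n Count vector (length dN) or dT x dN matrix of count vectors.
#' @param k Component index in 1..dK.
#' @return Log p(n, k), one value per row of \code{n}.
#' @export
joint_log_pmf <- function(m, n, k, max_count = NULL) {
  stopifnot(inherits(m, "mixture_natural"))
  if (k < 1 || k > m$dK || k != floor(k)) stop("component index out of range", call. = FALSE)
  n <- if (is.matrix(n)) n else matrix(n, 1L)
  check_counts(n)
  cp <- component_params(m, k)
  psi <- log_partition(m, max_count)
  lf <- rowSums(lgamma(n + 1))
  base <- if (m$family == "IP") -lf else drop(lgamma(n + 1) %*% m$theta_star)
  tk <- if (k == 1L) 0 else m$theta_k[k - 1L]
  drop(n %*% cp$theta_n) + base + tk - psi
}

#' Marginal (observable) log density of a count vector
#'
#' Log-sum-exp over components of the joint density.
#'
#' @inheritParams joint_log_pmf
#' @return Log p(n), one value per row of \code{n}.
#' @export
observable_log_pmf <- function(m, n, max_count = NULL) {
  stopifnot(inherits(m, "mixture_natural"))
  n <- if (is.matrix(n)) n else matrix(n, 1L)
  check_counts(n)
  sc <- component_scores(m, max_count)
  psi <- logsumexp(sc$a)
  comp <- component_log_rates(m)
  lfm <- lgamma(n + 1)
  base <- if (m$family == "IP") -rowSums(lfm) else drop(lfm %*% m$theta_star)
  # dT x dK matrix of per-component complete log densities
  scores <- n %*% comp + rep(c(0, m$theta_k), each = nrow(n))
  row_logsumexp(scores) + base - psi
}

#' Moments of a mixture
#'
#' Mean, covariance and Fano factors of the marginal count distribution. The
#' mean is the weight-average of component means; the variance adds the
#' between-component spread to the average within-component variance, and
#' the covariance between two neurons is the weighted covariance of their
#' component means. Component moments are exact (rates) for IP and truncated
#' for CB.
#'
#' @inheritParams log_partition
#' @return A list with \code{mean}, \code{covariance} (symmetric PSD) and
#'   \code{fano}.
#' @export
mixture_moments <- function(m, max_count = NULL) {
  stopifnot(inherits(m, "mixture_natural"))
  w <- exp(index_log_probabilities(m, max_count))
  comp <- component_log_rates(m)
  if (m$family == "IP") {
    mu_k <- exp(comp)          # component means = rates
    var_k <- mu_k              # Poisson within-component variances
  } else {
    if (is.null(max_count)) max_count <- com_max_count(as.vector(comp), rep(m$theta_star, m$dK))
    mu_k <- matrix(0, m$dN, m$dK)
    var_k <- matrix(0, m$dN, m$dK)
    for (k in seq_len(m$dK)) {
      mom <- com_moments(comp[, k], m$theta_star, max_count)
      mu_k[, k] <- mom$mean
      var_k[, k] <- mom$variance
    }
  }
  mu <- drop(mu_k %*% w)
  dev <- mu_k - mu
  sigma <- dev %*% (w * t(dev))
  diag(sigma) <- drop(var_k %*% w) + rowSums(sweep(dev^2, 2L, w, "*"))
  sigma <- (sigma + t(sigma)) / 2
  list(mean = mu, covariance = sigma, fano = diag(sigma) / mu)
}

#' Sample count vectors from a mixture
#'
#' Ancestral sampling: a component index is drawn from the index
#' probabilities, then each neuron's count from the component distribution
#' (inverse-CDF on the truncated pmf for CB). Uses the current R RNG stream;
#' seed with [set.seed()] for reproducibility.
#'
#' @inheritParams log_partition
#' @param size Number of draws.
#' @return A list with \code{counts} (size x dN integer matrix) and
#'   \code{component} (latent indices).
#' @export
sample_mixture <- function(m, size, max_count = NULL) {
  stopifnot(inherits(m, "mixture_natural"), size >= 1)
  w <- exp(index_log_probabilities(m, max_count))
  ks <- sample.int(m$dK, size, replace = TRUE, prob = w)
  comp <- component_log_rates(m)
  counts <- matrix(0L, size, m$dN)
  for (k in unique(ks)) {
    idx <- which(ks == k)
    if (m$family == "IP") {
      lam <- exp(comp[, k])
      counts[idx, ] <- matrix(stats::rpois(length(idx) * m$dN, rep(lam, each = length(idx))),
                              length(idx), m$dN)
    } else {
      counts[idx, ] <- com_sample(length(idx), comp[, k], m$theta_star, max_count)
    }
  }
  list(counts = counts, component = ks)
}
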