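# Seeded generators: randomized ground-truth conditional mixtures, sampled
# datasets, and the information-limited population simulation.

#' Recipe for a randomized ground-truth conditional mixture
#'
#' Distributional laws for the randomized parameters: preferred orientations
#' are tiled over the (doubled-angle) circle, log-concentrations are
#' Normal(-0.1, 0.2), log-gains Normal(0.2, 0.1), modulation entries
#' Normal(0.2, 0.1), and CB dispersion parameters Uniform(-1.5, -0.8).
#'
#' @param dN,dK Model dimensions.
#' @param family \code{"IP"} or \code{"CB"}.
#' @param kappa_meanlog,kappa_sdlog Law of the von Mises concentrations.
#' @param gain_meanlog,gain_sdlog Law of the baseline gains.
#' @param mod_mean,mod_sd Law of the modulation-matrix entries.
#' @param star_min,star_max Law of the CB dispersion parameters.
#' @param recenter_weights If \code{TRUE}, re-center the index biases so the
#'   peak index score of every component shares a common ceiling over a
#'   dense stimulus grid (keeps several components active at every
#'   stimulus in large populations).
#' @param discretize Optional vector of condition orientations (degrees); if
#'   given, the von Mises map is evaluated at these conditions and converted
#'   to a discrete lookup model.
#' @return A list of class \code{"cm_recipe"}.
#' @export
random_cm_recipe <- function(dN = 20L, dK = 5L, family = c("CB", "IP"),
                             kappa_meanlog = -0.1, kappa_sdlog = 0.2,
                             gain_meanlog = 0.2, gain_sdlog = 0.1,
                             mod_mean = 0.2, mod_sd = 0.1,
                             star_min = -1.5, star_max = -0.8,
                             recenter_weights = FALSE, discretize = NULL) {
  structure(list(dN = as.integer(dN), dK = as.integer(dK),
                 family = match.arg(family),
                 kappa_meanlog = kappa_meanlog, kappa_sdlog = kappa_sdlog,
                 gain_meanlog = gain_meanlog, gain_sdlog = gain_sdlog,
                 mod_mean = mod_mean, mod_sd = mod_sd,
                 star_min = star_min, star_max = star_max,
                 recenter_weights = recenter_weights, discretize = discretize),
            class = "cm_recipe")
}

#' Generate a randomized ground-truth conditional mixture
#'
#' Draws a von Mises CM per the recipe: neuron i gets preferred (doubled)
#' angle \code{rho_i = i / dN * 360} degrees, tuning row
#' \code{(kappa_i cos rho_i, kappa_i sin rho_i)} and baseline offset
#' \code{log gamma_i - log I0(kappa_i)}, so that the baseline-component
#' tuning curves are von Mises bumps with gain gamma_i. The index biases are
#' zero (optionally re-centered) and the modulations and dispersion
#' parameters follow the recipe laws.
#'
#' @param recipe A [random_cm_recipe()].
#' @param seed Integer seed; the generator is a pure function of
#'   (recipe, seed).
#' @return A \code{"cm"} object.
#' @export
random_ground_truth_cm <- function(recipe, seed = 1L) {
  stopifnot(inherits(recipe, "cm_recipe"))
  set.seed(as.integer(seed))
  dN <- recipe$dN
  dK <- recipe$dK
  rho <- (seq_len(dN) / dN) * 2 * pi              # doubled angle, radians
  kappa <- exp(stats::rnorm(dN, recipe$kappa_meanlog, recipe$kappa_sdlog))
  gain <- exp(stats::rnorm(dN, recipe$gain_meanlog, recipe$gain_sdlog))
  theta_nx <- cbind(kappa * cos(rho), kappa * sin(rho))
  theta_n0 <- log(gain) - log(besselI(kappa, 0))
  theta_k <- rep(0, dK - 1L)
  theta_nk <- matrix(stats::rnorm(dN * (dK - 1L), recipe$mod_mean, recipe$mod_sd),
                     dN, dK - 1L)
  theta_star <- if (recipe$family == "CB")
    stats::runif(dN, recipe$star_min, recipe$star_max) else NULL
  cm <- cm_model("von_mises", recipe$family, theta_n0 = theta_n0,
                 theta_nx = theta_nx, theta_k = theta_k, theta_nk = theta_nk,
                 theta_star = theta_star)
  if (isTRUE(recipe$recenter_weights)) {
    # equalize max_x of the unnormalized index scores over a dense grid
    grid <- seq(0, 180, length.out = 361L)[-361L]
    sc <- vapply(grid, function(x) component_scores(mixture_at(cm, x))$a,
                 numeric(dK))
    peak <- apply(sc, 1L, max)
    adj <- mean(peak) - peak
    cm$theta_k <- theta_k + adj[-1L] - adj[1L]
  }
  if (!is.null(recipe$discretize)) {
    lv <- recipe$discretize
    th <- baseline_params(cm, lv)               # dN x dX
    cm <- cm_model("discrete", recipe$family, theta_n0 = th[, 1L],
                   theta_nx = th[, -1L, drop = FALSE] - th[, 1L],
                   theta_k = cm$theta_k, theta_nk = cm$theta_nk,
                   theta_star = theta_star, stimulus_levels = lv)
  }
  cm
}

#' Sample a stimulus-response dataset from a conditional mixture
#'
#' Ancestral sampling at each point of a stimulus grid.
#'
#' @param cm A \code{"cm"} object.
#' @param orientations Stimulus grid (degrees for von Mises maps, condition
#'   labels otherwise).
#' @param reps Repetitions per stimulus value.
#' @param seed Integer seed.
#' @param max_count Optional truncation cutoff.
#' @return A \code{"trial_table"} with an extra \code{component} column of
#'   latent indices.
#' @export
simulate_cm_dataset <- function(cm, orientations = seq(0, 162, by = 18),
                                reps = 200L, seed = NULL, max_count = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  counts <- NULL
  stim <- rep(orientations, each = reps)
  comp <- integer(0)
  for (x in orientations) {
    s <- sample_mixture(mixture_at(cm, x), reps, max_count)
    counts <- rbind(counts, s$counts)
    comp <- c(comp, s$component)
  }
  trial_table(counts, stim, neuron_ids = cm$neuron_ids, component = comp)
}

# ---- information-limited populations ----------------------------------------

# Von Mises concentration whose circular standard deviation (on the doubled
# orientation circle) matches the requested orientation noise.
kappa_from_sd <- function(sd_deg) {
  sd2 <- 2 * deg2rad(sd_deg)
  # tight noise: the Bessel ratio is 1 - 1/(2k) to leading order
  if (sd2 < 0.02) return(1 / sd2^2)
  r_target <- exp(-sd2^2 / 2)
  stats::uniroot(function(k)
    besselI(k, 1, expon.scaled = TRUE) / besselI(k, 0, expon.scaled = TRUE) -
      r_target,
    c(1e-6, 1e5))$root
}

#' Recipe for an information-limited population
#'
#' A source population of conditionally independent Poisson neurons with
#' homogeneous von Mises tuning (identical gain and concentration, tiled
#' preferred orientations) responds to a noisy orientation s, where
#' p(s | x) is von Mises centred at the true orientation x. Marginalizing
#' over s induces information-limiting correlations: the Fisher information
#' about x cannot exceed the precision of the sensory noise however large
#' the population.
#'
#' @param dN Source population size.
#' @param gain Tuning-curve gain (mean count at baseline).
#' @param concentration Von Mises tuning concentration.
#' @param noise_sd Circular standard deviation of the sensory noise, in
#'   degrees of orientation.
#' @return A list of class \code{"info_limited_recipe"}.
#' @export
info_limited_recipe <- function(dN = 200L, gain = 5, concentration = 1,
                                noise_sd = 10) {
  structure(list(dN = as.integer(dN), gain = gain,
                 concentration = concentration, noise_sd = noise_sd,
                 noise_kappa = kappa_from_sd(noise_sd)),
            class = "info_limited_recipe")
}

# Source tuning means mu_i(s) (dN x length(s)) and their derivative with
# respect to orientation in radians.
source_tuning <- function(recipe, s) {
  rho <- (seq_len(recipe$dN) / recipe$dN) * 2 * pi
  a <- 2 * deg2rad(s)
  z <- recipe$concentration * cos(outer(rho, a, function(r, aa) r - aa))
  mu <- recipe$gain * exp(z) / besselI(recipe$concentration, 0)
  dz <- 2 * recipe$concentration * sin(outer(rho, a, function(r, aa) r - aa))
  list(mu = mu, dmu = mu * dz)
}

#' Sample information-limited population responses
#'
#' For each draw: \code{s ~ VonMises(x, noise_kappa)} on the doubled
#' orientation circle, then independent Poisson counts with rates
#' \code{mu_i(s)}. The marginal responses at fixed x are correlated across
#' neurons.
#'
#' @param recipe An [info_limited_recipe()].
#' @param x True orientation (degrees).
#' @param m Number of draws.
#' @param seed Optional integer seed.
#' @return A list with \code{counts} (m x dN) and the latent orientations
#'   \code{s} (degrees).
#' @export
info_limited_sample <- function(recipe, x, m, seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  s <- rvonmises_angle(m, 2 * deg2rad(x), recipe$noise_kappa) / 2
  s <- (s * 180 / pi) %% 180
  mu <- source_tuning(recipe, s)$mu              # dN x m
  counts <- matrix(stats::rpois(m * recipe$dN, as.vector(mu)),
                   nrow = m, byrow = TRUE)
  list(counts = counts, s = s)
}

#' Sample a full information-limited dataset over an orientation grid
#'
#' @inheritParams info_limited_sample
#' @param orientations Orientation grid (degrees).
#' @param reps Draws per orientation.
#' @return A \code{"trial_table"} (stimulus = true orientation x).
#' @export
info_limited_dataset <- function(recipe, orientations = seq(0, 162, by = 18),
                                 reps = 1000L, seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  counts <- NULL
  for (x in orientations)
    counts <- rbind(counts, info_limited_sample(recipe, x, reps)$counts)
  trial_table(counts, rep(orientations, each = reps))
}

# Best-Fisher von Mises sampler (rejection method of Best & Fisher 1979).
rvonmises_angle <- function(m, mu, kappa) {
  if (kappa < 1e-8) return(stats::runif(m, 0, 2 * pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(m)
  got <- 0L
  while (got < m) {
    k <- m - got
    u1 <- stats::runif(k); u2 <- stats::runif(k); u3 <- stats::runif(k)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    c0 <- kappa * (r - f)
    ok <- (c0 * (2 - c0) - u2 > 0) | (log(c0 / u2) + 1 - c0 >= 0)
    th <- sign(u3[ok] - 0.5) * acos(f[ok])
    n_ok <- sum(ok)
    if (n_ok > 0) {
      out[got + seq_len(n_ok)] <- th
      got <- got + n_ok
    }
  }
  (out + mu) %% (2 * pi)
}

#' Source-population Fisher information across subpopulation sizes
#'
#' The Fisher information about the noisy orientation s under the
#' conditionally independent Poisson source model,
#' \code{sum_i mu_i'(s)^2 / mu_i(s)}, averaged over an orientation grid, for
#' nested randomized subpopulations (starting small and reintroducing
#' missing neurons). Additive over neurons, hence linear in expectation in
#' the subpopulation size — while the information about the true orientation
#' x is bounded by the noise-channel precision regardless of size.
#'
#' @param recipe An [info_limited_recipe()].
#' @param sizes Increasing subpopulation sizes.
#' @param seed Integer seed for the neuron ordering.
#' @param orientations Averaging grid (degrees).
#' @return A data frame with \code{size} and \code{fi}, with the
#'   noise-channel bound in attribute \code{"bound"}.
#' @export
source_fi_curve <- function(recipe, sizes = seq(10L, recipe$dN, by = 10L),
                            seed = 1L, orientations = seq(0, 179, by = 1)) {
  set.seed(as.integer(seed))
  ord <- sample.int(recipe$dN)
  st <- source_tuning(recipe, orientations)
  fi_i <- rowMeans(st$dmu^2 / st$mu)     # per-neuron FI averaged over grid
  fi <- vapply(sizes, function(sz) sum(fi_i[ord[seq_len(sz)]]), numeric(1))
  out <- data.frame(size = sizes, fi = fi)
  attr(out, "bound") <- noise_fi_bound(recipe)
  out
}

#' Fisher information bound of the sensory-noise channel
#'
#' The Fisher information about x carried by the noisy orientation s under
#' \code{p(s | x)}, computed by numerical quadrature over the von Mises
#' density; information about x in the population cannot exceed it. Units
#' match [fisher_information()] (per squared radian of orientation).
#'
#' @param recipe An [info_limited_recipe()].
#' @return Scalar bound.
#' @export
noise_fi_bound <- function(recipe) {
  k <- recipe$noise_kappa
  # doubled-angle deviation u = 2(s - x) in radians; d/dx log p = 2 k sin(u)
  f <- function(u) (2 * k * sin(u))^2 * exp(k * cos(u)) /
    (2 * pi * besselI(k, 0))
  stats::integrate(f, -pi, pi)$value
}
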