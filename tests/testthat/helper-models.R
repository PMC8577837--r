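# Small fixture builders used across the suite.

# A tiny IP mixture with known weights/rates.
tiny_ip_mixture <- function(dN = 2, dK = 2, seed = 1) {
  set.seed(seed)
  w <- softmax_vec(stats::rnorm(dK))
  rates <- matrix(stats::runif(dN * dK, 0.5, 4), dN, dK)
  natural_from_weights_rates(w, rates)
}

softmax_vec <- function(x) {
  e <- exp(x - max(x))
  e / sum(e)
}

# A tiny CB mixture.
tiny_cb_mixture <- function(dN = 2, dK = 2, seed = 1) {
  set.seed(seed)
  mixture_natural(theta_n = stats::runif(dN, -0.5, 1),
                  theta_k = stats::rnorm(dK - 1, 0, 0.5),
                  theta_nk = matrix(stats::rnorm(dN * (dK - 1), 0, 0.3), dN, dK - 1),
                  theta_star = stats::runif(dN, -1.5, -0.8))
}

# Enumerate all count vectors up to a cutoff (dN small).
enumerate_counts <- function(dN, max_n) {
  g <- as.matrix(expand.grid(rep(list(0:max_n), dN)))
  dimnames(g) <- NULL
  g
}

# Small synthetic von Mises dataset plus its generating model.
small_vm_dataset <- function(dN = 4, dK = 2, family = "IP", reps = 30,
                             seed = 7) {
  cm0 <- random_ground_truth_cm(random_cm_recipe(dN = dN, dK = dK,
                                                 family = family), seed = seed)
  dat <- simulate_cm_dataset(cm0, orientations = seq(0, 162, by = 18),
                             reps = reps, seed = seed + 1)
  list(cm = cm0, dat = dat)
}
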