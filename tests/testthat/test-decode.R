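# Bayesian decoding, Fisher information, cross-validation, reference
# decoders.

test_that("estimate_prior returns presentation frequencies", {
  expect_equal(unname(estimate_prior(rep(c("a", "b", "c"), each = 4))),
               rep(1 / 3, 3))
  expect_equal(unname(estimate_prior(rep(c("a", "b"), c(10, 30)))),
               c(0.25, 0.75))
  expect_equal(sum(estimate_prior(sample(letters[1:5], 100, TRUE))), 1)
  expect_warning(estimate_prior(c("a", "a"), levels = c("a", "b")), "zero prior")
})

test_that("bayes_posterior normalizes and matches exhaustive computation", {
  lv <- c(0, 60, 120)
  cm <- random_ground_truth_cm(
    random_cm_recipe(dN = 3, dK = 2, family = "IP", discretize = lv), seed = 2)
  set.seed(3)
  counts <- matrix(stats::rpois(15, 2), 5, 3)
  prior <- c(0.2, 0.3, 0.5); names(prior) <- lv
  lp <- bayes_posterior(cm, counts, prior)
  expect_equal(rowSums(exp(lp)), rep(1, 5))
  # dual oracle through the weights/rates parameterization
  for (r in 1:5) {
    lx <- vapply(lv, function(x) {
      wr <- weights_rates_from_natural(mixture_at(cm, x))
      log(sum(wr$weights * vapply(1:2, function(k)
        prod(stats::dpois(counts[r, ], wr$rates[, k])), numeric(1))))
    }, numeric(1))
    post <- lx + log(prior)
    expect_equal(lp[r, ], post - log(sum(exp(post))), tolerance = 1e-10,
                 ignore_attr = TRUE)
  }
  # one-hot prior forces a one-hot posterior
  lp1 <- bayes_posterior(cm, counts, stats::setNames(c(1, 0, 0), lv))
  expect_equal(unname(exp(lp1[, 1])), rep(1, 5))
  # invariance to a constant shift of the log-likelihoods: equal likelihoods
  # and a uniform prior give a uniform posterior
  cmu <- cm
  cmu$theta_nx[] <- 0
  lpu <- bayes_posterior(cmu, counts[1, , drop = FALSE],
                         stats::setNames(rep(1 / 3, 3), lv))
  expect_equal(unname(exp(lpu[1, ])), rep(1 / 3, 3), tolerance = 1e-12)
})

test_that("mean_log_posterior averages the truth entries with flooring", {
  lp <- log(rbind(c(0.7, 0.2, 0.1), c(0.1, 0.8, 0.1), c(1e-20, 0.5, 0.5)))
  colnames(lp) <- c("a", "b", "c")
  truth <- c("a", "b", "a")
  hand <- mean(c(log(0.7), log(0.8), log(1e-12)))
  expect_equal(mean_log_posterior(lp, truth), hand)
  # ignorant decoder on dX = 9
  lp9 <- matrix(log(1 / 9), 4, 9,
                dimnames = list(NULL, as.character(1:9)))
  expect_equal(mean_log_posterior(lp9, c("1", "5", "9", "3")), log(1 / 9))
})

test_that("Fisher information identities hold", {
  # dK = 1 IP von Mises: closed form sum (d mu)^2 / mu
  cm1 <- cm_model("von_mises", "IP", theta_n0 = c(0.5, 1),
                  theta_nx = matrix(c(0.7, -0.4, 0.3, 0.9), 2, 2))
  x <- 33
  mu <- drop(exp(baseline_params(cm1, x)))
  dth <- drop(cm1$theta_nx %*% t(condmix:::vm_basis_deriv(x)))
  expect_equal(fisher_information(cm1, x), sum(dth^2 * mu), tolerance = 1e-10)
  # flat tuning has zero information
  cm0 <- cm1; cm0$theta_nx[] <- 0
  expect_equal(fisher_information(cm0, 90), 0)
  # covariance form vs LFI form on a mixed model
  cm <- random_ground_truth_cm(random_cm_recipe(dN = 4, dK = 3, family = "IP"),
                               seed = 5)
  for (x in c(20, 100))
    expect_equal(fisher_information(cm, x),
                 fisher_information(cm, x, method = "linear", dx = 0.01),
                 tolerance = 1e-6)
  # definitional FI by enumeration + finite differences, dN = 2
  cm2 <- random_ground_truth_cm(random_cm_recipe(dN = 2, dK = 2, family = "IP"),
                                seed = 7)
  x <- 40; dx <- 1e-3
  grid <- enumerate_counts(2, 40)
  lp <- function(xx) observable_log_pmf(mixture_at(cm2, xx), grid)
  d <- (lp(x + dx) - lp(x - dx)) / (2 * condmix:::deg2rad(dx))
  expect_equal(fisher_information(cm2, x), sum(exp(lp(x)) * d^2),
               tolerance = 1e-6)
})

test_that("stratified folds partition trials and preserve proportions", {
  stim <- rep(c("a", "b", "c"), c(40, 25, 35))
  fold <- crossval_folds(stim, folds = 5, seed = 3)
  expect_setequal(fold, 1:5)
  expect_length(fold, 100)
  tab <- table(fold, stim)
  for (lv in colnames(tab))
    expect_lte(diff(range(tab[, lv])), 1)
  expect_identical(crossval_folds(stim, 5, 3), fold)
})

test_that("information gain of the baseline against itself is zero", {
  sv <- small_vm_dataset(dN = 3, dK = 2, reps = 20)
  ig <- information_gain(sv$dat$counts, sv$dat$stimulus,
                         cm_spec(variant = "von_mises", family = "IP", dK = 1),
                         folds = 5, seed = 2)
  expect_identical(ig$folds, rep(0, 5))
  expect_identical(ig$mean, 0)
})

test_that("correlated data yields positive information gain and CM beats the independent decoder", {
  cm0 <- random_ground_truth_cm(random_cm_recipe(dN = 5, dK = 3, family = "IP"),
                                seed = 9)
  # strengthen modulations so mixing induces solid correlations
  cm0$theta_nk <- cm0$theta_nk * 3
  dat <- simulate_cm_dataset(cm0, seq(0, 162, by = 18), reps = 40, seed = 10)
  cv <- crossval_cm(dat$counts, dat$stimulus,
                    cm_spec(dK = 3, schedule = cm_schedule(em_iters = 15,
                                                           ascent_steps = 40)),
                    folds = 5, seed = 11)
  expect_gt(mean(cv$info_gain), 0)
  sm <- summary(cv)
  expect_identical(sm$metric, c("loglik", "info_gain", "log_posterior"))
  expect_true(all(is.finite(sm$se)))
  # decoding comparison: mixture posterior beats the independent baseline
  base_cv <- crossval_cm(dat$counts, dat$stimulus, cm_spec(dK = 1), folds = 5,
                         seed = 11)
  expect_gt(mean(cv$log_posterior), mean(base_cv$log_posterior))
})

test_that("decoder parameter counts match the stated architectures", {
  expect_identical(decoder_param_count("nonmixed_ip", 43, 9), 387L)
  expect_identical(decoder_param_count("nonmixed_ip", 70, 9), 630L)
  expect_identical(decoder_param_count("linear", 43, 9), 352L)
  expect_identical(decoder_param_count("linear", 70, 9), 568L)
  expect_identical(decoder_param_count("mlp", 43, 9, hidden = 700), 527108L)
  expect_identical(decoder_param_count("mlp", 70, 9, hidden = 600), 408008L)
  # constructed decoders carry the same counts
  set.seed(1)
  counts <- matrix(stats::rpois(200, 3), 50, 4)
  stim <- rep(c("a", "b"), 25)
  lin <- fit_linear_decoder(counts, stim, seed = 1)
  expect_identical(lin$n_params, decoder_param_count("linear", 4, 2))
  mlp <- fit_mlp_decoder(counts, stim, hidden = 7, seed = 1)
  expect_identical(mlp$n_params, decoder_param_count("mlp", 4, 2, 7))
})

test_that("trained decoders solve separable problems", {
  set.seed(13)
  n1 <- matrix(stats::rpois(300, 1), 100, 3)
  n2 <- matrix(stats::rpois(300, 9), 100, 3)
  counts <- rbind(n1, n2)
  stim <- rep(c("lo", "hi"), each = 100)
  lin <- fit_linear_decoder(counts, stim, seed = 2, lr = 0.02, batch = 50L,
                            max_epochs = 400L)
  lp <- decoder_posterior(lin, counts)
  expect_equal(rowSums(exp(lp)), rep(1, 200))
  expect_gt(mean_log_posterior(lp, stim), -0.1)
  mlp <- fit_mlp_decoder(counts, stim, hidden = 5, seed = 2, lr = 0.02,
                         batch = 50L, max_epochs = 400L)
  expect_gt(mean_log_posterior(decoder_posterior(mlp, counts), stim), -0.2)
  # determinism
  lin2 <- fit_linear_decoder(counts, stim, seed = 2, lr = 0.02, batch = 50L,
                             max_epochs = 400L)
  expect_identical(lin$weights, lin2$weights)
})

test_that("predict method decodes via the Bayesian posterior", {
  lv <- c(0, 90)
  cm0 <- random_ground_truth_cm(
    random_cm_recipe(dN = 4, dK = 2, family = "IP", discretize = lv), seed = 15)
  dat <- simulate_cm_dataset(cm0, lv, reps = 30, seed = 16)
  fit <- fit_cm(dat$counts, stimulus = dat$stimulus, variant = "discrete",
                dK = 2, schedule = cm_schedule(em_iters = 8, ascent_steps = 25),
                seed = 17, levels = lv)
  lp <- predict(fit, type = "posterior")
  expect_identical(dim(lp), c(60L, 2L))
  expect_equal(rowSums(exp(lp)), rep(1, 60))
  dec <- predict(fit, type = "decode")
  expect_gt(mean(dec == dat$stimulus), 0.7)
  mu <- predict(fit, type = "mean")
  expect_identical(dim(mu), c(4L, 2L))
})
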