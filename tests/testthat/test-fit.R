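# EM machinery: E-step, mean parameters, gradients, initialization, and the
# full training loop.

test_that("e_step responsibilities equal brute-force Bayes posteriors", {
  sv <- small_vm_dataset(dN = 3, dK = 3, family = "IP")
  cm <- sv$cm
  counts <- sv$dat$counts[1:40, ]
  resp <- e_step(cm, counts)
  x0 <- sv$dat$stimulus[1]
  m <- mixture_at(cm, x0)
  for (r in c(1, 7, 23)) {
    joint <- vapply(1:3, function(k)
      joint_log_pmf(m, counts[r, , drop = FALSE], k), numeric(1))
    post <- exp(joint - max(joint)) / sum(exp(joint - max(joint)))
    expect_equal(resp[r, ], post[-1], tolerance = 1e-10)
  }
  # responsibilities are stimulus-free for minimal CMs
  expect_equal(e_step(cm, counts), e_step(cm, counts, stimulus = NULL))
  # limiting case: a count vector near a remote component's rates
  m2 <- natural_from_weights_rates(c(.5, .5), cbind(c(1, 1), c(30, 30)))
  cm2 <- condmix:::as_single_condition_cm(m2)
  r2 <- e_step(cm2, matrix(c(31, 29), 1))
  expect_gt(r2[1, 1], 0.999)
  expect_identical(ncol(e_step(cm, counts[1:2, ] * 0L)), 2L)
  # dK = 1 gives empty responsibilities
  base <- fit_independent_baseline(counts, sv$dat$stimulus[1:40], "von_mises")
  expect_identical(dim(e_step(base, counts)), c(40L, 0L))
})

test_that("mean parameters match exhaustive enumeration", {
  for (family in c("IP", "CB")) {
    cm <- random_ground_truth_cm(random_cm_recipe(dN = 2, dK = 2,
                                                  family = family), seed = 21)
    x <- 54
    mc <- 100L
    mp <- mean_parameters(cm, x, max_count = mc)
    m <- mixture_at(cm, x)
    grid <- enumerate_counts(2, if (family == "IP") 40 else 30)
    pj <- sapply(1:2, function(k) exp(joint_log_pmf(m, grid, k, mc)))
    expect_equal(sum(pj), 1, tolerance = 1e-6)
    expect_equal(mp$eta_n, colSums(rowSums(pj) * grid), tolerance = 1e-6)
    expect_equal(mp$eta_k, sum(pj[, 2]), tolerance = 1e-6)
    expect_equal(drop(mp$eta_nk),
                 colSums(pj[, 2] * grid), tolerance = 1e-6)
    expect_equal(mp$eta_star, colSums(rowSums(pj) * lgamma(grid + 1)),
                 tolerance = 1e-6)
    # eta_k consistency with index probabilities
    expect_equal(mp$eta_k, exp(index_log_probabilities(m, mc))[-1],
                 tolerance = 1e-8)
  }
  # dK = 1 IP: eta_n is the exponentiated baseline
  base <- cm_model("von_mises", "IP", theta_n0 = c(0, 1),
                   theta_nx = matrix(c(.5, -.2, .1, .3), 2, 2))
  mp1 <- mean_parameters(base, 90)
  expect_equal(mp1$eta_n, drop(exp(baseline_params(base, 90))),
               tolerance = 1e-10)
  expect_length(mp1$eta_k, 0)
})

test_that("M-step gradients match central finite differences for every variant and family", {
  set.seed(5)
  dN <- 3; dK <- 2
  stim <- rep(c(0, 45, 90, 135), each = 6)
  counts <- matrix(stats::rpois(length(stim) * dN, 3), ncol = dN)
  mc <- 64L
  for (variant in c("von_mises", "discrete")) {
    for (family in c("IP", "CB")) {
      lv <- if (variant == "discrete") sort(unique(stim)) else NULL
      cm <- initialize_cm(counts, stim, variant, dK, lv)
      if (family == "CB") {
        cm$family <- "CB"
        cm$theta_star <- stats::runif(dN, -1.3, -0.9)
      }
      v <- condmix:::cm_pack(cm) + stats::rnorm(length(condmix:::cm_pack(cm)), 0, 0.1)
      cm <- condmix:::cm_unpack(cm, v)
      resp <- e_step(cm, counts)
      gv <- condmix:::grad_pack(
        cm, m_step_gradients(cm, counts, stim, resp, max_count = mc))
      f <- function(v) complete_log_likelihood(condmix:::cm_unpack(cm, v),
                                               counts, stim, resp, max_count = mc)
      eps <- 1e-5
      fd <- vapply(seq_along(v), function(j) {
        e <- numeric(length(v)); e[j] <- eps
        (f(v + e) - f(v - e)) / (2 * eps)
      }, numeric(1))
      expect_lt(max(abs(gv - fd) / pmax(abs(fd), 1)), 1e-5)
    }
  }
})

test_that("gradients vanish at the single-component moment-matching solution", {
  set.seed(7)
  counts <- matrix(stats::rpois(60, 4), ncol = 2)
  stim <- rep(c("a", "b", "c"), each = 10)
  base <- fit_independent_baseline(counts, stim, "discrete")
  g <- m_step_gradients(base, counts, stim, e_step(base, counts))
  expect_lt(max(abs(g$theta_n0)), 1e-8)
  expect_lt(max(abs(g$theta_nx)), 1e-8)
})

test_that("independent baselines solve the closed-form and convex ML problems", {
  # single neuron, single condition, counts {2, 4} -> rate 3
  base <- fit_independent_baseline(matrix(c(2L, 4L), 2, 1), c("c", "c"),
                                   "discrete")
  expect_equal(drop(base$theta_n0), log(3), tolerance = 1e-10)
  # discrete fits reproduce per-condition empirical means exactly
  set.seed(9)
  counts <- matrix(stats::rpois(90, 5), ncol = 3)
  stim <- rep(c(0, 60, 120), each = 10)
  based <- fit_independent_baseline(counts, stim, "discrete")
  for (x in unique(stim))
    expect_equal(drop(exp(baseline_params(based, x))),
                 colMeans(counts[stim == x, ]), tolerance = 1e-10)
  # von Mises consistency: recovers generating tuning as trials grow
  true <- cm_model("von_mises", "IP", theta_n0 = c(1, 0.5),
                   theta_nx = matrix(c(0.8, -0.3, 0.2, 0.6), 2, 2))
  dat <- simulate_cm_dataset(true, seq(0, 171, by = 9), reps = 300, seed = 10)
  fit <- fit_independent_baseline(dat$counts, dat$stimulus, "von_mises")
  expect_equal(fit$theta_n0, true$theta_n0, tolerance = 0.05)
  expect_equal(fit$theta_nx, true$theta_nx, tolerance = 0.12)
  # silent neurons get floored finite rates
  z <- fit_independent_baseline(cbind(matrix(2L, 10, 1), 0L),
                                rep(c(0, 90), each = 5), "von_mises")
  expect_true(all(is.finite(condmix:::cm_pack(z))))
})

test_that("initialization is seeded and structured", {
  sv <- small_vm_dataset(dN = 5, dK = 3)
  counts <- sv$dat$counts; stim <- sv$dat$stimulus
  set.seed(1); a <- initialize_cm(counts, stim, "von_mises", 4)
  set.seed(1); b <- initialize_cm(counts, stim, "von_mises", 4)
  expect_identical(condmix:::cm_pack(a), condmix:::cm_pack(b))
  # sinusoidal modulations: bounded by 0.2, distinct phases across components
  expect_true(all(abs(a$theta_nk) <= 0.2 + 1e-12))
  phases <- apply(a$theta_nk, 2, function(col) which.max(col))
  expect_gt(length(unique(phases)), 1)
  set.seed(2); d <- initialize_cm(counts, stim, "discrete", 3,
                                  levels = sort(unique(stim)))
  expect_true(all(abs(d$theta_nk) <= 1e-4))
  set.seed(3)
  expect_identical(initialize_cm(counts, stim, "von_mises", 1)$dK, 1L)
})

test_that("EM does not decrease the data log-likelihood (seeded property)", {
  sv <- small_vm_dataset(dN = 3, dK = 2, family = "IP", reps = 15)
  counts <- sv$dat$counts; stim <- sv$dat$stimulus
  tol <- 1e-6 * nrow(counts)
  for (seed in 1:20) {
    fit <- fit_cm(counts, stimulus = stim, dK = 2,
                  schedule = cm_schedule(em_iters = 6, ascent_steps = 25),
                  seed = seed)
    expect_true(all(diff(fit$fit$trace) > -tol))
  }
})

test_that("single-component fits match the convex baseline", {
  sv <- small_vm_dataset(dN = 3, dK = 2, reps = 20)
  counts <- sv$dat$counts; stim <- sv$dat$stimulus
  fit1 <- fit_cm(counts, stimulus = stim, dK = 1,
                 schedule = cm_schedule(em_iters = 5), seed = 2)
  base <- fit_independent_baseline(counts, stim, "von_mises")
  expect_equal(fit1$fit$logLik, cm_log_likelihood(base, counts, stim),
               tolerance = 1e-10)
})

test_that("CB fits warm start from an unchanged IP density", {
  sv <- small_vm_dataset(dN = 2, dK = 2, reps = 10)
  counts <- sv$dat$counts; stim <- sv$dat$stimulus
  sched <- cm_schedule(em_iters = 5, ascent_steps = 10, cb_warm_fraction = 0.8)
  fit_ip <- fit_cm(counts, stimulus = stim, dK = 2, family = "IP",
                   schedule = cm_schedule(em_iters = 4, ascent_steps = 10),
                   seed = 3)
  # switching on theta_star = -1 leaves the density of the IP stage unchanged
  cb0 <- fit_ip
  cb0$family <- "CB"
  cb0$theta_star <- rep(-1, cb0$dN)
  expect_equal(cm_log_likelihood(cb0, counts, stim, max_count = 512L),
               cm_log_likelihood(fit_ip, counts, stim), tolerance = 1e-8)
  fit_cb <- fit_cm(counts, stimulus = stim, dK = 2, family = "CB",
                   schedule = sched, seed = 3)
  # no likelihood jump across the warm-start boundary (trace stays monotone)
  expect_true(all(diff(fit_cb$fit$trace) > -1e-6 * nrow(counts)))
  expect_identical(fit_cb$family, "CB")
  expect_true(all(fit_cb$theta_star < 0))
})

test_that("fitting is deterministic given the seed and supports formulas", {
  sv <- small_vm_dataset(dN = 2, dK = 2, reps = 10)
  sched <- cm_schedule(em_iters = 3, ascent_steps = 10)
  f1 <- fit_cm(sv$dat$counts, stimulus = sv$dat$stimulus, dK = 2,
               schedule = sched, seed = 11)
  f2 <- fit_cm(sv$dat$counts, stimulus = sv$dat$stimulus, dK = 2,
               schedule = sched, seed = 11)
  expect_identical(condmix:::cm_pack(f1), condmix:::cm_pack(f2))
  df <- data.frame(stim = sv$dat$stimulus)
  df$y <- sv$dat$counts
  f3 <- fit_cm(y ~ stim, data = df, dK = 2, schedule = sched, seed = 11)
  expect_equal(condmix:::cm_pack(f3), condmix:::cm_pack(f1))
})

test_that("maximal fits are independent per-condition mixtures", {
  sv <- small_vm_dataset(dN = 3, dK = 2, reps = 25)
  lv <- sort(unique(sv$dat$stimulus))
  fit <- fit_cm(sv$dat$counts, stimulus = sv$dat$stimulus, variant = "maximal",
                dK = 2, schedule = cm_schedule(em_iters = 4, ascent_steps = 20),
                seed = 4, levels = lv)
  expect_identical(fit$variant, "maximal")
  expect_length(fit$tables, length(lv))
  # per-condition tables behave as stimulus-free mixtures of the condition data
  x <- lv[3]
  rows <- sv$dat$stimulus == x
  expect_equal(cm_log_likelihood(fit, sv$dat$counts[rows, ], sv$dat$stimulus[rows]),
               sum(observable_log_pmf(mixture_at(fit, x), sv$dat$counts[rows, ])))
})

test_that("log-likelihood reductions hold", {
  sv <- small_vm_dataset(dN = 2, dK = 2, reps = 5)
  cm <- sv$cm
  expect_identical(cm_log_likelihood(cm, sv$dat$counts[0, , drop = FALSE],
                                     numeric(0)), 0)
  one <- sv$dat$counts[1, , drop = FALSE]
  expect_equal(cm_log_likelihood(cm, one, sv$dat$stimulus[1]),
               drop(observable_log_pmf(mixture_at(cm, sv$dat$stimulus[1]), one)))
  pt <- cm_log_likelihood(cm, sv$dat$counts, sv$dat$stimulus, per_trial = TRUE)
  expect_length(pt, nrow(sv$dat$counts))
  expect_equal(sum(pt), cm_log_likelihood(cm, sv$dat$counts, sv$dat$stimulus))
})

test_that("IP fits recover the moments of a known generator", {
  cm0 <- random_ground_truth_cm(random_cm_recipe(dN = 4, dK = 3, family = "IP"),
                                seed = 31)
  dat <- simulate_cm_dataset(cm0, seq(0, 162, by = 18), reps = 120, seed = 32)
  fit <- fit_cm(dat$counts, stimulus = dat$stimulus, dK = 3,
                schedule = cm_schedule(em_iters = 40, ascent_steps = 50),
                seed = 33)
  for (x in c(18, 90)) {
    m0 <- mixture_moments(mixture_at(cm0, x))
    m1 <- mixture_moments(mixture_at(fit, x))
    expect_equal(m1$mean, m0$mean, tolerance = 0.15)
    expect_lt(mean(abs(m1$covariance - m0$covariance)), 0.35)
  }
  # index probability curves match up to component relabelling
  xs <- seq(0, 170, by = 10)
  p0 <- index_probability_curves(cm0, xs)
  p1 <- index_probability_curves(fit, xs)
  perms <- rbind(1:3, c(1, 3, 2), c(2, 1, 3), c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  best <- min(apply(perms, 1, function(pp) mean(abs(p1[pp, ] - p0))))
  expect_lt(best, 0.15)
})
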