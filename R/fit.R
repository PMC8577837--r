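# Approximate expectation-maximization for conditional mixtures.
#
# The E-step is exact: responsibilities over components are a softmax of
# theta_k + n . theta_nk (the stimulus-dependent baseline and any shared
# dispersion terms are common to all components and cancel). The M-step
# maximizes the complete log-likelihood -- a convex problem -- by a fixed
# number of Adam gradient-ascent steps; the gradients are differences
# between data-side sufficient statistics and model mean parameters, so the
# data side is accumulated once per EM iteration and only the model side is
# re-evaluated along the ascent.

#' EM training schedule
#'
#' @param em_iters Total EM iterations dI.
#' @param ascent_steps Adam gradient-ascent steps per M-step.
#' @param lr_start,lr_end Initial and final learning rates; the rate at EM
#'   iteration t (0-based) is log-linearly interpolated,
#'   \code{exp(((dI - 1 - t) log lr_start + t log lr_end) / (dI - 1))}.
#' @param cb_warm_fraction Fraction of iterations spent training the IP
#'   model before switching on the CB dispersion parameters (CB fits run a
#'   two-stage warm start; the stage-2 initial CB model has \code{theta_star
#'   = -1} and hence exactly the stage-1 IP density).
#' @param trace_stride Evaluate the data log-likelihood every this many EM
#'   iterations.
#' @return A list of class \code{"cm_schedule"}.
#' @export
cm_schedule <- function(em_iters = 500L, ascent_steps = 100L,
                        lr_start = 2e-3, lr_end = 5e-4,
                        cb_warm_fraction = 0.8, trace_stride = 1L) {
  stopifnot(em_iters >= 1, ascent_steps >= 1, lr_start > 0, lr_end > 0,
            cb_warm_fraction > 0, cb_warm_fraction <= 1)
  structure(list(em_iters = as.integer(em_iters),
                 ascent_steps = as.integer(ascent_steps),
                 lr_start = lr_start, lr_end = lr_end,
                 cb_warm_fraction = cb_warm_fraction,
                 trace_stride = as.integer(trace_stride)),
            class = "cm_schedule")
}

schedule_lr <- function(sched, t, dI) {
  if (dI <= 1) return(sched$lr_start)
  exp(((dI - 1 - t) * log(sched$lr_start) + t * log(sched$lr_end)) / (dI - 1))
}

# ---- responsibilities -------------------------------------------------------

#' E-step responsibilities
#'
#' Posterior probabilities of components 2..dK for every trial. For minimal
#' CMs the stimulus drops out and the responsibilities are
#' \code{softmax(0, theta_k + n . theta_nk)}; for maximal CMs the same
#' formula applies with the parameters of the trial's condition.
#'
#' @param cm A \code{"cm"} object.
#' @param counts dT x dN matrix of spike counts.
#' @param stimulus Per-trial stimulus (required for maximal CMs only).
#' @return A dT x (dK - 1) matrix; each implied full simplex vector is
#'   \code{(1 - rowSums, row)}.
#' @export
e_step <- function(cm, counts, stimulus = NULL) {
  stopifnot(inherits(cm, "cm"))
  counts <- as.matrix(counts)
  if (cm$dK == 1L) return(matrix(0, nrow(counts), 0L))
  if (is_minimal(cm)) {
    a <- counts %*% cm$theta_nk
    a <- sweep(a, 2L, cm$theta_k, "+")
  } else {
    if (is.null(stimulus)) stop("maximal CMs need 'stimulus' in the E-step", call. = FALSE)
    idx <- level_index(cm, stimulus)
    a <- matrix(0, nrow(counts), cm$dK - 1L)
    for (l in unique(idx)) {
      rows <- which(idx == l)
      tab <- cm$tables[[l]]
      a[rows, ] <- sweep(counts[rows, , drop = FALSE] %*% tab$theta_nk,
                         2L, tab$theta_k, "+")
    }
  }
  exp(a - row_logsumexp(cbind(0, a)))
}

# ---- model mean parameters --------------------------------------------------

# Mean parameters of a minimal CM at one stimulus, given the baseline column
# theta_x. Returns index probabilities pk, eta_n, eta_star (CB or on
# request), the column-scaled component means eta_nk, and the log-partition.
minimal_mean_core <- function(theta_x, theta_k, theta_nk, theta_star, family,
                              max_count, want_lf = FALSE) {
  dN <- length(theta_x)
  dK <- length(theta_k) + 1L
  comp <- theta_x + cbind(0, theta_nk)
  if (family == "IP" && !want_lf) {
    mu <- exp(comp)
    a <- c(0, theta_k) + colSums(mu)
    pk <- softmax(a)
    eta_star <- NULL
    lfbar <- NULL
  } else {
    star <- if (family == "IP") rep(-1, dN) else theta_star
    ns <- 0:max_count
    lfns <- lgamma(ns + 1)
    m <- outer(ns, as.vector(comp)) + outer(lfns, rep(star, dK))
    mx <- apply(m, 2L, max)
    e <- exp(sweep(m, 2L, mx))
    z <- colSums(e)
    psi_ik <- matrix(mx + log(z), dN, dK)
    mu <- matrix(colSums(ns * e) / z, dN, dK)
    lfbar <- matrix(colSums(lfns * e) / z, dN, dK)
    a <- c(0, theta_k) + colSums(psi_ik)
    pk <- softmax(a)
    eta_star <- drop(lfbar %*% pk)
  }
  list(pk = pk,
       eta_n = drop(mu %*% pk),
       eta_star = eta_star,
       eta_nk = sweep(mu[, -1L, drop = FALSE], 2L, pk[-1L], "*"),
       mu = mu,
       psi = logsumexp(a))
}

#' Model mean parameters at a stimulus
#'
#' Expectations of the sufficient statistics (n, lf(n), d(k), n x d(k))
#' under p(n, k | x): \code{eta_n} is the marginal mean, \code{eta_k} the
#' index probabilities of components 2..dK, \code{eta_nk} column k the
#' product of p(k + 1 | x) with component k + 1's mean vector, and
#' \code{eta_star} the expected per-neuron log-factorial (computed for IP
#' models too, where it is only needed by CB gradients).
#'
#' @param cm A minimal \code{"cm"} object.
#' @param x A single stimulus value.
#' @param max_count Optional series truncation cutoff.
#' @return A list with \code{eta_n}, \code{eta_star}, \code{eta_k},
#'   \code{eta_nk}.
#' @export
mean_parameters <- function(cm, x, max_count = NULL) {
  stopifnot(inherits(cm, "cm"), is_minimal(cm))
  theta_x <- drop(baseline_params(cm, x))
  star <- if (cm$family == "CB") cm$theta_star else rep(-1, cm$dN)
  if (is.null(max_count))
    max_count <- com_max_count(as.vector(theta_x + cbind(0, cm$theta_nk)),
                               rep(star, cm$dK))
  mp <- minimal_mean_core(theta_x, cm$theta_k, cm$theta_nk, cm$theta_star,
                          cm$family, max_count, want_lf = TRUE)
  list(eta_n = mp$eta_n, eta_star = mp$eta_star,
       eta_k = mp$pk[-1L], eta_nk = mp$eta_nk)
}

# ---- packing ----------------------------------------------------------------

cm_pack <- function(cm) {
  c(cm$theta_n0, as.vector(cm$theta_nx), cm$theta_k, as.vector(cm$theta_nk),
    cm$theta_star)
}

cm_unpack <- function(cm, v) {
  dN <- cm$dN; ncx <- ncol(cm$theta_nx); dK <- cm$dK
  i <- 0L
  take <- function(n) {
    out <- v[(i + 1L):(i + n)]
    i <<- i + n
    out
  }
  cm$theta_n0 <- take(dN)
  cm$theta_nx <- matrix(if (ncx > 0) take(dN * ncx) else numeric(0), dN, ncx)
  cm$theta_k <- if (dK > 1L) take(dK - 1L) else numeric(0)
  cm$theta_nk <- matrix(if (dK > 1L) take(dN * (dK - 1L)) else numeric(0), dN, dK - 1L)
  if (cm$family == "CB") cm$theta_star <- take(dN)
  cm
}

# ---- sufficient statistics and grouped data ---------------------------------

# Group trials by stimulus value/level; returns the per-group trial index,
# the group stimuli, and the data-side statistics that are constant across
# the whole fit.
build_groups <- function(cm, counts, stimulus) {
  if (cm$variant == "von_mises") {
    xs <- sort(unique(as.numeric(stimulus)))
    gidx <- match(as.numeric(stimulus), xs)
  } else {
    xs <- cm$stimulus_levels
    gidx <- level_index(cm, stimulus)
  }
  G <- length(xs)
  ct <- tabulate(gidx, G)
  sn <- matrix(0, ncol(counts), G)
  agg <- rowsum(counts, gidx, reorder = TRUE)
  sn[, as.integer(rownames(agg))] <- t(agg)
  list(xs = xs, gidx = gidx, G = G, ct = ct, Sn = sn,
       Slf = colSums(lgamma(counts + 1)),
       VM = if (cm$variant == "von_mises") vm_basis(xs) else NULL)
}

# Complete log-likelihood of a minimal CM given responsibilities, and its
# gradients with respect to every parameter block, both expressed through
# grouped statistics. SK = colSums(resp), SNK = t(counts) %*% resp.
mstep_eval <- function(cm, grp, SK, SNK, max_count, want_grad = TRUE) {
  dN <- cm$dN; dK <- cm$dK
  Theta <- baseline_params(cm, grp$xs)               # dN x G
  obj <- sum(Theta * grp$Sn) +
    (if (dK > 1L) sum(cm$theta_k * SK) + sum(cm$theta_nk * SNK) else 0) +
    (if (cm$family == "CB") sum(cm$theta_star * grp$Slf) else 0)
  etaN <- matrix(0, dN, grp$G)
  etaK <- matrix(0, dK - 1L, grp$G)
  etaS <- if (cm$family == "CB") matrix(0, dN, grp$G) else NULL
  Hnk <- matrix(0, dN, dK - 1L)
  for (g in seq_len(grp$G)) {
    mp <- minimal_mean_core(Theta[, g], cm$theta_k, cm$theta_nk, cm$theta_star,
                            cm$family, max_count)
    obj <- obj - grp$ct[g] * mp$psi
    if (want_grad) {
      etaN[, g] <- mp$eta_n
      if (dK > 1L) {
        etaK[, g] <- mp$pk[-1L]
        Hnk <- Hnk + grp$ct[g] * mp$eta_nk
      }
      if (cm$family == "CB") etaS[, g] <- mp$eta_star
    }
  }
  if (!want_grad) return(list(objective = obj))
  gN <- grp$Sn - sweep(etaN, 2L, grp$ct, "*")        # dN x G
  grad <- list(theta_n0 = rowSums(gN))
  grad$theta_nx <- switch(cm$variant,
    von_mises = gN %*% grp$VM,
    discrete = gN[, -1L, drop = FALSE],
    stop("minimal variants only"))
  if (dK > 1L) {
    grad$theta_k <- SK - drop(etaK %*% grp$ct)
    grad$theta_nk <- SNK - Hnk
  } else {
    grad$theta_k <- numeric(0)
    grad$theta_nk <- matrix(0, dN, 0L)
  }
  if (cm$family == "CB") grad$theta_star <- grp$Slf - drop(etaS %*% grp$ct)
  list(objective = obj, grad = grad)
}

grad_pack <- function(cm, grad) {
  c(grad$theta_n0, as.vector(grad$theta_nx), grad$theta_k,
    as.vector(grad$theta_nk), if (cm$family == "CB") grad$theta_star)
}

#' Complete log-likelihood given responsibilities
#'
#' The EM surrogate objective: the expected joint log-likelihood of counts
#' and latent indices under fixed responsibilities (up to terms constant in
#' the parameters for IP models, whose base measure does not depend on
#' them).
#'
#' @param cm A minimal \code{"cm"} object.
#' @param counts,stimulus Trial data.
#' @param resp Responsibilities from [e_step()].
#' @param max_count Series truncation cutoff.
#' @return Scalar objective value.
#' @export
complete_log_likelihood <- function(cm, counts, stimulus, resp, max_count = NULL) {
  counts <- as.matrix(counts)
  grp <- build_groups(cm, counts, stimulus)
  if (is.null(max_count)) max_count <- fit_max_count(counts)
  base <- if (cm$family == "IP") -sum(lgamma(counts + 1)) else 0
  mstep_eval(cm, grp, colSums(resp), crossprod(counts, resp), max_count,
             want_grad = FALSE)$objective + base
}

#' M-step gradients of the complete log-likelihood
#'
#' Differences between data-side sufficient statistics and model mean
#' parameters, summed over trials: for the baseline map
#' \code{sum_i n_i - eta_n(x_i)} propagated into the map parameters, for the
#' index biases \code{sum_i resp_i - eta_k(x_i)}, for the modulations
#' \code{sum_i n_i x resp_i - eta_nk(x_i)}, and for CB dispersion
#' \code{sum_i lf(n_i) - eta_star(x_i)}. Maximal CMs route each trial's
#' gradients to its condition's parameter table.
#'
#' @inheritParams complete_log_likelihood
#' @return A list of gradient blocks mirroring the CM parameters.
#' @export
m_step_gradients <- function(cm, counts, stimulus, resp, max_count = NULL) {
  counts <- as.matrix(counts)
  if (nrow(resp) != nrow(counts)) stop("responsibility/count shape mismatch", call. = FALSE)
  if (is.null(max_count)) max_count <- fit_max_count(counts)
  if (is_minimal(cm)) {
    grp <- build_groups(cm, counts, stimulus)
    mstep_eval(cm, grp, colSums(resp), crossprod(counts, resp), max_count)$grad
  } else {
    idx <- level_index(cm, stimulus)
    lapply(seq_along(cm$tables), function(l) {
      rows <- which(idx == l)
      sub <- as_single_condition_cm(cm$tables[[l]])
      g <- m_step_gradients(sub, counts[rows, , drop = FALSE],
                            rep("c1", length(rows)),
                            resp[rows, , drop = FALSE], max_count)
      list(theta_n = g$theta_n0, theta_k = g$theta_k,
           theta_nk = g$theta_nk, theta_star = g$theta_star)
    })
  }
}

# View a stimulus-free mixture as a one-condition discrete CM so that the
# minimal-CM machinery applies.
as_single_condition_cm <- function(m) {
  cm_model("discrete", m$family, theta_n0 = m$theta_n,
           theta_nx = matrix(0, m$dN, 0L), theta_k = m$theta_k,
           theta_nk = m$theta_nk, theta_star = m$theta_star,
           stimulus_levels = "c1")
}

# ---- likelihood -------------------------------------------------------------

#' Data log-likelihood of a conditional mixture
#'
#' Sum over trials of the marginal log density of the observed counts at the
#' observed stimulus.
#'
#' @param cm A \code{"cm"} object.
#' @param counts,stimulus Trial data.
#' @param max_count Optional truncation cutoff.
#' @param per_trial If \code{TRUE} return the vector of per-trial values.
#' @return Total log-likelihood in nats (or per-trial vector).
#' @export
cm_log_likelihood <- function(cm, counts, stimulus, max_count = NULL,
                              per_trial = FALSE) {
  stopifnot(inherits(cm, "cm"))
  counts <- as.matrix(counts)
  if (nrow(counts) == 0L) return(if (per_trial) numeric(0) else 0)
  ll <- numeric(nrow(counts))
  if (cm$variant == "von_mises") {
    xs <- unique(as.numeric(stimulus))
    gidx <- match(as.numeric(stimulus), xs)
  } else {
    xs <- cm$stimulus_levels
    gidx <- level_index(cm, stimulus)
  }
  for (g in unique(gidx)) {
    rows <- which(gidx == g)
    m <- mixture_at(cm, xs[g])
    ll[rows] <- observable_log_pmf(m, counts[rows, , drop = FALSE], max_count)
  }
  if (per_trial) ll else sum(ll)
}

# ---- baseline and initialization --------------------------------------------

rate_floor <- function(dT) 0.1 / dT

#' Fit the independent (single-component) baseline model
#'
#' Maximum-likelihood fit of dN independent Poisson neurons with either von
#' Mises tuning (a Poisson regression on the doubled-angle basis, solved
#' exactly per neuron) or a discrete lookup of per-condition mean rates.
#' Empirical rates of silent neurons are floored at \code{0.1 / dT} so the
#' log-rate parameters stay finite.
#'
#' @param counts,stimulus Trial data.
#' @param variant \code{"von_mises"} or \code{"discrete"}.
#' @param levels Optional ordered condition labels (discrete).
#' @return A dK = 1 \code{"cm"} object of family IP.
#' @export
fit_independent_baseline <- function(counts, stimulus,
                                     variant = c("von_mises", "discrete"),
                                     levels = NULL) {
  variant <- match.arg(variant)
  counts <- as.matrix(counts)
  dT <- nrow(counts)
  dN <- ncol(counts)
  if (variant == "discrete") {
    levels <- levels %||% sort(unique(stimulus))
    idx <- match(as.character(stimulus), as.character(levels))
    if (anyNA(idx)) stop("stimulus outside the provided levels", call. = FALSE)
    lam <- t(vapply(seq_along(levels), function(l) {
      rows <- idx == l
      if (!any(rows)) stop("no trials at condition ", levels[l], call. = FALSE)
      pmax(colMeans(counts[rows, , drop = FALSE]), rate_floor(dT))
    }, numeric(dN)))                                  # dX x dN
    th <- log(t(lam))                                 # dN x dX
    cm_model("discrete", "IP", theta_n0 = th[, 1L],
             theta_nx = th[, -1L, drop = FALSE] - th[, 1L],
             stimulus_levels = levels)
  } else {
    X <- cbind(1, vm_basis(as.numeric(stimulus)))
    coefs <- vapply(seq_len(dN), function(i) {
      y <- counts[, i]
      if (sum(y) == 0) return(c(log(rate_floor(dT)), 0, 0))
      fit <- suppressWarnings(stats::glm.fit(X, y, family = stats::poisson()))
      cf <- fit$coefficients
      if (any(!is.finite(cf))) cf <- c(log(max(mean(y), rate_floor(dT))), 0, 0)
      cf
    }, numeric(3))
    cm_model("von_mises", "IP", theta_n0 = coefs[1L, ],
             theta_nx = t(coefs[2:3, , drop = FALSE]))
  }
}

#' Preferred orientations of a von Mises map
#'
#' \code{rho_i = atan2(b_i, a_i) / 2} (degrees in [0, 180)) where (a, b) is
#' row i of the tuning matrix; the baseline offset shifts only the gain, not
#' the peak.
#'
#' @param cm A von Mises \code{"cm"} object.
#' @return Length-dN vector of preferred orientations in degrees.
#' @export
preferred_stimulus <- function(cm) {
  stopifnot(cm$variant == "von_mises")
  rho <- atan2(cm$theta_nx[, 2L], cm$theta_nx[, 1L]) / 2
  (rho * 180 / pi) %% 180
}

#' Initialize a conditional mixture for EM
#'
#' The baseline map comes from [fit_independent_baseline()]; the index
#' biases from Dirichlet(2) weights; the modulations are uniform-small
#' (discrete/maximal) or sinusoidal in each neuron's preferred orientation
#' with a distinct phase per component (von Mises), so that each modulation
#' peaks at a different part of the stimulus circle. Initialization is
#' always of family IP (CB fits warm-start from an IP fit). Uses the current
#' RNG stream.
#'
#' @param counts,stimulus Trial data.
#' @param variant \code{"von_mises"} or \code{"discrete"}.
#' @param dK Number of mixture components.
#' @param levels Optional ordered condition labels (discrete).
#' @return A \code{"cm"} object of family IP with dK components.
#' @export
initialize_cm <- function(counts, stimulus, variant = c("von_mises", "discrete"),
                          dK = 1L, levels = NULL) {
  variant <- match.arg(variant)
  base <- fit_independent_baseline(counts, stimulus, variant, levels)
  if (dK == 1L) return(base)
  dN <- base$dN
  w <- stats::rgamma(dK, shape = 2)
  w <- w / sum(w)
  theta_k <- log(w[-1L] / w[1L])
  if (variant == "von_mises") {
    rho <- deg2rad(preferred_stimulus(base))
    theta_nk <- vapply(seq_len(dK - 1L),
                       function(k) 0.2 * sin(2 * rho + k * 2 * pi / dK),
                       numeric(dN))
  } else {
    theta_nk <- matrix(stats::runif(dN * (dK - 1L), -1e-4, 1e-4), dN, dK - 1L)
  }
  cm_model(variant, "IP", theta_n0 = base$theta_n0, theta_nx = base$theta_nx,
           theta_k = theta_k, theta_nk = theta_nk,
           stimulus_levels = base$stimulus_levels)
}

# ---- Adam -------------------------------------------------------------------

adam_ascend <- function(v, grad_fn, steps, lr,
                        beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  m1 <- numeric(length(v))
  m2 <- numeric(length(v))
  for (s in seq_len(steps)) {
    g <- grad_fn(v)
    m1 <- beta1 * m1 + (1 - beta1) * g
    m2 <- beta2 * m2 + (1 - beta2) * g^2
    mh <- m1 / (1 - beta1^s)
    vh <- m2 / (1 - beta2^s)
    v <- v + lr * mh / (sqrt(vh) + eps)
  }
  v
}

fit_max_count <- function(counts) {
  min(1024L, max(128L, as.integer(ceiling(10 * max(counts, 1)))))
}

# ---- the fitting function ---------------------------------------------------

#' Fit a conditional mixture by expectation-maximization
#'
#' The user-facing fitting function. Alternates exact E-steps with
#' Adam-ascended M-steps under a log-linearly decaying learning rate, with
#' the Adam state reset at every EM iteration. CB fits first train the IP
#' model for \code{cb_warm_fraction} of the iterations, then switch on the
#' dispersion parameters at \code{theta_star = -1} (leaving the density
#' unchanged) and continue. Maximal CMs are fit as independent per-condition
#' mixtures. A single-component IP fit is the convex baseline problem and is
#' solved exactly.
#'
#' @param x A formula \code{counts ~ stimulus} (with a matrix response, e.g.
#'   \code{cbind(n1, n2) ~ x}), or a dT x dN count matrix.
#' @param data Data frame for the formula interface.
#' @param stimulus Per-trial stimulus vector (default method).
#' @param variant,family Model variant and family; see [cm_model()].
#' @param dK Number of mixture components.
#' @param schedule A [cm_schedule()].
#' @param seed Integer seed; fits are deterministic given the seed.
#' @param max_count Series truncation cutoff; default scales with the
#'   largest observed count.
#' @param levels Optional ordered condition labels (discrete/maximal).
#' @param ... Passed between methods.
#' @return An object of class \code{c("cm_fit", "cm")}: the fitted model
#'   plus \code{fit$trace} (per-iteration data log-likelihood),
#'   \code{fit$logLik}, and the training configuration.
#' @examples
#' cm0 <- random_ground_truth_cm(random_cm_recipe(dN = 4, dK = 2, family = "IP"), seed = 1)
#' dat <- simulate_cm_dataset(cm0, orientations = seq(0, 162, by = 18), reps = 20, seed = 2)
#' fit <- fit_cm(dat$counts, stimulus = dat$stimulus, dK = 2,
#'               schedule = cm_schedule(em_iters = 5, ascent_steps = 10), seed = 3)
#' logLik(fit)
#' @export
fit_cm <- function(x, ...) UseMethod("fit_cm")

#' @rdname fit_cm
#' @export
fit_cm.formula <- function(x, data = environment(x), ...) {
  mf <- stats::model.frame(x, data)
  counts <- stats::model.response(mf)
  stim <- mf[[2L]]
  out <- fit_cm.default(as.matrix(counts), stimulus = stim, ...)
  out$fit$call <- match.call()
  out
}

#' @rdname fit_cm
#' @export
fit_cm.default <- function(x, stimulus,
                           variant = c("von_mises", "discrete", "maximal"),
                           family = c("IP", "CB"), dK = 5L,
                           schedule = cm_schedule(), seed = 1L,
                           max_count = NULL, levels = NULL, ...) {
  variant <- match.arg(variant)
  family <- match.arg(family)
  counts <- as.matrix(x)
  check_counts(counts, "counts")
  stopifnot(nrow(counts) == length(stimulus))
  if (is.null(max_count)) max_count <- fit_max_count(counts)

  if (variant == "maximal") {
    levels <- levels %||% sort(unique(stimulus))
    idx <- match(as.character(stimulus), as.character(levels))
    tables <- lapply(seq_along(levels), function(l) {
      rows <- which(idx == l)
      sub <- fit_cm.default(counts[rows, , drop = FALSE],
                            stimulus = rep("c1", length(rows)),
                            variant = "discrete", family = family, dK = dK,
                            schedule = schedule, seed = seed + l,
                            max_count = max_count, levels = "c1")
      mixture_at(sub, "c1")
    })
    cm <- cm_model("maximal", family, tables = tables, stimulus_levels = levels)
    ll <- cm_log_likelihood(cm, counts, stimulus, max_count)
    cm$fit <- list(trace = ll, logLik = ll, schedule = schedule, seed = seed,
                   max_count = max_count, nobs = nrow(counts),
                   counts = counts, stimulus = stimulus,
                   call = match.call())
    class(cm) <- c("cm_fit", class(cm))
    return(cm)
  }

  set.seed(as.integer(seed))
  if (variant == "discrete") levels <- levels %||% sort(unique(stimulus))
  cm <- initialize_cm(counts, stimulus, variant, dK, levels)
  sched <- schedule
  dI <- sched$em_iters

  if (dK == 1L && family == "IP") {
    # convex exact ML: the baseline fit is the EM fixed point
    ll <- cm_log_likelihood(cm, counts, stimulus, max_count)
    trace <- ll
  } else {
    grp <- build_groups(cm, counts, stimulus)
    stages <- if (family == "CB") {
      ip <- max(1L, as.integer(round(sched$cb_warm_fraction * dI)))
      list(c(0L, min(ip, dI)), c(min(ip, dI), dI))
    } else list(c(0L, dI))
    trace <- numeric(0)
    for (si in seq_along(stages)) {
      rng <- stages[[si]]
      if (family == "CB" && si == 2L) {
        # warm start: switching on theta_star = -1 leaves the density unchanged
        cm$family <- "CB"
        cm$theta_star <- rep(-1, cm$dN)
        if (rng[2L] <= rng[1L]) break
      }
      for (t in rng[1L]:(rng[2L] - 1L)) {
        resp <- e_step(cm, counts)
        SK <- colSums(resp)
        SNK <- crossprod(counts, resp)
        lr <- schedule_lr(sched, t, dI)
        gfn <- function(v)
          grad_pack(cm, mstep_eval(cm_unpack(cm, v), grp, SK, SNK, max_count)$grad)
        cm <- cm_unpack(cm, adam_ascend(cm_pack(cm), gfn, sched$ascent_steps, lr))
        if ((t + 1L) %% sched$trace_stride == 0L || t == dI - 1L)
          trace <- c(trace, cm_log_likelihood(cm, counts, stimulus, max_count))
      }
    }
    if (any(!is.finite(trace)))
      stop("non-finite data log-likelihood during EM; inspect the data scale",
           call. = FALSE)
    ll <- trace[length(trace)]
  }
  cm$fit <- list(trace = trace, logLik = ll, schedule = sched, seed = seed,
                 max_count = max_count, nobs = nrow(counts),
                 counts = counts, stimulus = stimulus, call = match.call())
  class(cm) <- c("cm_fit", class(cm))
  cm
}
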