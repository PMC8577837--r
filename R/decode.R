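# Bayesian decoding, Fisher information, cross-validated model comparison,
# and the linear / multilayer-perceptron reference decoders.

LOG_POSTERIOR_FLOOR <- log(1e-12)

#' Empirical stimulus prior
#'
#' Relative frequency of stimulus presentations over an ordered set of
#' conditions.
#'
#' @param stimulus Per-trial stimulus labels.
#' @param levels Ordered condition labels (default: sorted unique values).
#' @return A named simplex vector. Conditions absent from the data get a
#'   zero entry (with a warning).
#' @export
estimate_prior <- function(stimulus, levels = NULL) {
  levels <- levels %||% sort(unique(stimulus))
  ct <- table(factor(as.character(stimulus), levels = as.character(levels)))
  if (any(ct == 0)) warning("conditions with no presentations have zero prior mass")
  p <- as.numeric(ct) / length(stimulus)
  stats::setNames(p, as.character(levels))
}

#' Bayesian posterior over stimulus conditions
#'
#' Brute-force normalization of p(n | x) p(x) over a discrete set of
#' conditions.
#'
#' @param cm A \code{"cm"} object (the encoding model).
#' @param counts Count vector or dT x dN matrix.
#' @param prior Prior simplex over the conditions.
#' @param levels Conditions to decode over (default: the model's conditions;
#'   von Mises models require an explicit grid or prior names).
#' @param max_count Optional truncation cutoff.
#' @return A dT x dX matrix of log-posteriors; rows exponentiate to 1.
#' @export
bayes_posterior <- function(cm, counts, prior = NULL, levels = NULL,
                            max_count = NULL) {
  stopifnot(inherits(cm, "cm"))
  counts <- if (is.matrix(counts)) counts else matrix(counts, 1L)
  levels <- levels %||% cm$stimulus_levels %||% names(prior)
  if (is.null(levels)) stop("no conditions to decode over", call. = FALSE)
  dX <- length(levels)
  prior <- prior %||% stats::setNames(rep(1 / dX, dX), levels)
  stopifnot(length(prior) == dX, all(prior >= 0))
  prior <- prior / sum(prior)
  ll <- vapply(seq_len(dX), function(j) {
    x <- if (cm$variant == "von_mises") as.numeric(levels[j]) else levels[j]
    observable_log_pmf(mixture_at(cm, x), counts, max_count)
  }, numeric(nrow(counts)))
  ll <- matrix(ll, nrow(counts), dX)
  lp <- sweep(ll, 2L, log(prior), "+")
  lp <- lp - row_logsumexp(lp)
  colnames(lp) <- as.character(levels)
  lp
}

#' Mean log-posterior of the true stimulus
#'
#' Average over trials of the log-posterior probability assigned to the true
#' condition. Values are floored at log(1e-12) before averaging so that a
#' decoder assigning numerically zero probability stays finite (and
#' visible).
#'
#' @param log_posterior dT x dX matrix of log-posteriors (columns named by
#'   condition).
#' @param truth Per-trial true condition labels.
#' @param floor Flooring constant.
#' @return Mean floored log-posterior (nats).
#' @export
mean_log_posterior <- function(log_posterior, truth,
                               floor = LOG_POSTERIOR_FLOOR) {
  idx <- match(as.character(truth), colnames(log_posterior))
  if (anyNA(idx)) stop("truth labels missing from the posterior columns", call. = FALSE)
  v <- log_posterior[cbind(seq_along(idx), idx)]
  mean(pmax(v, floor))
}

# ---- Fisher information -----------------------------------------------------

#' Fisher information of a minimal conditional mixture
#'
#' For minimal CMs the Fisher information about the stimulus has the closed
#' form \code{I(x) = d theta_n(x) . Sigma(x) . d theta_n(x)} with Sigma(x)
#' the count covariance at x, and equals the linear Fisher information
#' \code{d mu(x) . Sigma(x)^-1 . d mu(x)} (\code{method = "linear"}, used as
#' an independent cross-check; requires an invertible covariance). The
#' stimulus derivative is analytic for von Mises maps and a central
#' difference otherwise. Units: nats per squared radian of orientation.
#'
#' @param cm A minimal \code{"cm"} object with a smooth stimulus map.
#' @param x Orientation(s) in degrees.
#' @param method \code{"natural"} (covariance form, default) or
#'   \code{"linear"} (LFI form).
#' @param dx Central-difference step in degrees (non-analytic maps and the
#'   LFI mean derivative).
#' @param max_count Optional truncation cutoff.
#' @return Fisher information value(s), non-negative.
#' @export
fisher_information <- function(cm, x, method = c("natural", "linear"),
                               dx = 0.5, max_count = NULL) {
  stopifnot(inherits(cm, "cm"), is_minimal(cm))
  if (cm$variant != "von_mises")
    stop("Fisher information needs a smooth stimulus map", call. = FALSE)
  method <- match.arg(method)
  vapply(x, function(xi) {
    mom <- mixture_moments(mixture_at(cm, xi), max_count)
    if (method == "natural") {
      dth <- drop(cm$theta_nx %*% t(vm_basis_deriv(xi)))  # per radian
      drop(dth %*% mom$covariance %*% dth)
    } else {
      h <- deg2rad(dx)
      dmu <- (grand_tuning(cm, xi + dx, max_count) -
              grand_tuning(cm, xi - dx, max_count)) / (2 * h)
      drop(t(dmu) %*% solve(mom$covariance, dmu))
    }
  }, numeric(1))
}

# ---- cross-validation -------------------------------------------------------

#' Stratified cross-validation folds
#'
#' Seeded fold assignment, stratified by condition so that every condition
#' appears in every training split.
#'
#' @param stimulus Per-trial condition labels.
#' @param folds Number of folds.
#' @param seed Integer seed.
#' @return Integer fold index per trial.
#' @export
crossval_folds <- function(stimulus, folds = 10L, seed = 1L) {
  stopifnot(length(stimulus) >= folds)
  set.seed(as.integer(seed))
  fold <- integer(length(stimulus))
  for (lv in unique(stimulus)) {
    rows <- which(stimulus == lv)
    fold[rows] <- rep_len(seq_len(folds), length(rows))[sample.int(length(rows))]
  }
  fold
}

#' Model specification for cross-validation
#'
#' @param variant,family,dK,schedule,levels Passed to [fit_cm()].
#' @return A list of class \code{"cm_spec"}.
#' @export
cm_spec <- function(variant = "von_mises", family = "IP", dK = 5L,
                    schedule = cm_schedule(), levels = NULL) {
  structure(list(variant = variant, family = family, dK = dK,
                 schedule = schedule, levels = levels), class = "cm_spec")
}

#' Cross-validated evaluation of a conditional mixture specification
#'
#' For each fold, fits the specified CM and the von Mises independent
#' Poisson baseline on the training split and evaluates, on held-out
#' trials: the per-trial log-likelihood, the information gain (per-trial
#' held-out log-likelihood minus the baseline's), and the mean log-posterior
#' of the true condition under Bayesian decoding.
#'
#' @param counts,stimulus Trial data.
#' @param spec A [cm_spec()] (or a fitted spec-like list).
#' @param folds Number of folds.
#' @param seed Integer seed (fold assignment and fits).
#' @param max_count Optional truncation cutoff.
#' @return A data frame of per-fold metrics with class
#'   \code{"cm_crossval"}; \code{summary} gives mean and standard error.
#' @export
crossval_cm <- function(counts, stimulus, spec = cm_spec(), folds = 10L,
                        seed = 1L, max_count = NULL) {
  counts <- as.matrix(counts)
  fold <- crossval_folds(stimulus, folds, seed)
  levels <- spec$levels %||% sort(unique(stimulus))
  res <- lapply(seq_len(folds), function(f) {
    tr <- fold != f
    te <- !tr
    fit <- fit_cm(counts[tr, , drop = FALSE], stimulus = stimulus[tr],
                  variant = spec$variant, family = spec$family, dK = spec$dK,
                  schedule = spec$schedule, seed = seed + f,
                  max_count = max_count, levels = levels)
    base <- fit_independent_baseline(counts[tr, , drop = FALSE], stimulus[tr],
                                     "von_mises")
    n_te <- sum(te)
    ll <- cm_log_likelihood(fit, counts[te, , drop = FALSE], stimulus[te],
                            max_count) / n_te
    ll0 <- cm_log_likelihood(base, counts[te, , drop = FALSE], stimulus[te],
                             max_count) / n_te
    prior <- estimate_prior(stimulus[tr], levels)
    lp <- bayes_posterior(fit, counts[te, , drop = FALSE], prior, levels,
                          max_count)
    data.frame(fold = f, loglik = ll, info_gain = ll - ll0,
               log_posterior = mean_log_posterior(lp, stimulus[te]))
  })
  out <- do.call(rbind, res)
  class(out) <- c("cm_crossval", class(out))
  out
}

#' @export
summary.cm_crossval <- function(object, ...) {
  metrics <- c("loglik", "info_gain", "log_posterior")
  do.call(rbind, lapply(metrics, function(m) {
    v <- object[[m]]
    data.frame(metric = m, mean = mean(v), se = stats::sd(v) / sqrt(length(v)))
  }))
}

#' Cross-validated information gain
#'
#' The difference, per held-out trial, between the log-likelihood of the
#' specified CM and that of a von Mises-tuned independent Poisson model fit
#' on the same training split, 10-fold cross-validated. A specification
#' identical to the baseline scores exactly zero.
#'
#' @inheritParams crossval_cm
#' @return A list with \code{mean}, \code{se}, and the per-fold values.
#' @export
information_gain <- function(counts, stimulus, spec = cm_spec(), folds = 10L,
                             seed = 1L, max_count = NULL) {
  cv <- crossval_cm(counts, stimulus, spec, folds, seed, max_count)
  list(mean = mean(cv$info_gain),
       se = stats::sd(cv$info_gain) / sqrt(folds),
       folds = cv$info_gain)
}

# ---- reference decoders -----------------------------------------------------

# Shared stochastic-gradient trainer: maximizes the categorical
# log-likelihood of condition labels with Adam (fixed learning rate 3e-4,
# minibatches of 500), early-stopping on a held-out test partition
# (80/10/10 split) when epoch-to-epoch performance declines.
train_decoder <- function(counts, stimulus, levels, init, forward, backward,
                          seed, lr = 3e-4, batch = 500L, max_epochs = 200L) {
  set.seed(as.integer(seed))
  y <- match(as.character(stimulus), as.character(levels))
  dT <- nrow(counts)
  idx <- sample.int(dT)
  n_tr <- floor(0.8 * dT)
  n_te <- floor(0.1 * dT)
  itr <- idx[seq_len(n_tr)]
  ite <- idx[n_tr + seq_len(n_te)]
  w <- init
  m1 <- lapply(w, function(p) p * 0)
  m2 <- m1
  step <- 0L
  best <- -Inf
  best_w <- w
  score <- function(w, rows) {
    th <- forward(w, counts[rows, , drop = FALSE])
    lp <- cbind(0, th)
    mean(lp[cbind(seq_along(rows), y[rows])] - row_logsumexp(lp))
  }
  for (ep in seq_len(max_epochs)) {
    ord <- sample(itr)
    for (b in split(ord, ceiling(seq_along(ord) / batch))) {
      g <- backward(w, counts[b, , drop = FALSE], y[b])
      step <- step + 1L
      for (j in seq_along(w)) {
        m1[[j]] <- 0.9 * m1[[j]] + 0.1 * g[[j]]
        m2[[j]] <- 0.999 * m2[[j]] + 0.001 * g[[j]]^2
        w[[j]] <- w[[j]] + lr * (m1[[j]] / (1 - 0.9^step)) /
          (sqrt(m2[[j]] / (1 - 0.999^step)) + 1e-8)
      }
    }
    sc <- score(w, ite)
    if (!is.finite(sc)) stop("non-finite decoder loss", call. = FALSE)
    if (sc < best) break
    best <- sc
    best_w <- w
  }
  best_w
}

#' Fit a multiclass linear decoder
#'
#' Maximum-likelihood linear map from count vectors to the natural
#' parameters of a categorical distribution over conditions,
#' \code{theta_x(n) = theta_x + theta_xn . n} (dX - 1 outputs; condition 1
#' is the reference), trained by minibatch Adam with early stopping.
#'
#' @param counts,stimulus Trial data.
#' @param levels Ordered condition labels.
#' @param seed Integer seed.
#' @param ... Tuning arguments passed to the internal trainer.
#' @return An object of class \code{"cm_decoder"} supporting
#'   [decoder_posterior()].
#' @export
fit_linear_decoder <- function(counts, stimulus, levels = NULL, seed = 1L, ...) {
  counts <- as.matrix(counts)
  levels <- levels %||% sort(unique(stimulus))
  dX <- length(levels)
  dN <- ncol(counts)
  init <- list(theta_x = numeric(dX - 1L),
               theta_xn = matrix(0, dN, dX - 1L))
  forward <- function(w, n) sweep(n %*% w$theta_xn, 2L, w$theta_x, "+")
  backward <- function(w, n, y) {
    th <- forward(w, n)
    p <- exp(cbind(0, th) - row_logsumexp(cbind(0, th)))[, -1L, drop = FALSE]
    d <- (col(p) + 1L == y) - p   # indicator of the true class minus model prob
    list(theta_x = colSums(d) / nrow(n),
         theta_xn = crossprod(n, d) / nrow(n))
  }
  w <- train_decoder(counts, stimulus, levels, init, forward, backward, seed, ...)
  structure(list(type = "linear", weights = w, levels = levels,
                 forward = forward,
                 n_params = decoder_param_count("linear", dN, dX)),
            class = "cm_decoder")
}

#' Fit a two-hidden-layer multiclass decoder
#'
#' A sigmoid multilayer perceptron dN -> hidden -> hidden -> dX - 1 whose
#' outputs are the natural parameters of a categorical distribution over
#' conditions, trained like [fit_linear_decoder()].
#'
#' @inheritParams fit_linear_decoder
#' @param hidden Hidden layer width.
#' @return An object of class \code{"cm_decoder"}.
#' @export
fit_mlp_decoder <- function(counts, stimulus, hidden = 100L, levels = NULL,
                            seed = 1L, ...) {
  counts <- as.matrix(counts)
  levels <- levels %||% sort(unique(stimulus))
  dX <- length(levels)
  dN <- ncol(counts)
  h <- as.integer(hidden)
  set.seed(as.integer(seed))
  rinit <- function(nr, nc) matrix(stats::rnorm(nr * nc, sd = 1 / sqrt(nr)), nr, nc)
  init <- list(W1 = rinit(dN, h), b1 = numeric(h),
               W2 = rinit(h, h), b2 = numeric(h),
               W3 = rinit(h, dX - 1L), b3 = numeric(dX - 1L))
  sig <- function(z) 1 / (1 + exp(-z))
  fwd_full <- function(w, n) {
    h1 <- sig(sweep(n %*% w$W1, 2L, w$b1, "+"))
    h2 <- sig(sweep(h1 %*% w$W2, 2L, w$b2, "+"))
    list(h1 = h1, h2 = h2, th = sweep(h2 %*% w$W3, 2L, w$b3, "+"))
  }
  forward <- function(w, n) fwd_full(w, n)$th
  backward <- function(w, n, y) {
    f <- fwd_full(w, n)
    p <- exp(cbind(0, f$th) - row_logsumexp(cbind(0, f$th)))[, -1L, drop = FALSE]
    d3 <- (col(p) + 1L == y) - p
    d2 <- (d3 %*% t(w$W3)) * f$h2 * (1 - f$h2)
    d1 <- (d2 %*% t(w$W2)) * f$h1 * (1 - f$h1)
    nb <- nrow(n)
    list(W1 = crossprod(n, d1) / nb, b1 = colSums(d1) / nb,
         W2 = crossprod(f$h1, d2) / nb, b2 = colSums(d2) / nb,
         W3 = crossprod(f$h2, d3) / nb, b3 = colSums(d3) / nb)
  }
  w <- train_decoder(counts, stimulus, levels, init, forward, backward, seed, ...)
  structure(list(type = "mlp", weights = w, levels = levels,
                 forward = forward, hidden = h,
                 n_params = decoder_param_count("mlp", dN, dX, h)),
            class = "cm_decoder")
}

#' Log-posterior matrix of a trained decoder
#'
#' @param decoder A \code{"cm_decoder"}.
#' @param counts Count matrix.
#' @return dT x dX matrix of log-posteriors (columns named by condition).
#' @export
decoder_posterior <- function(decoder, counts) {
  counts <- as.matrix(counts)
  th <- cbind(0, decoder$forward(decoder$weights, counts))
  lp <- th - row_logsumexp(th)
  colnames(lp) <- as.character(decoder$levels)
  lp
}

#' @export
print.cm_decoder <- function(x, ...) {
  cat(sprintf("%s decoder over %d conditions (%d parameters)\n",
              x$type, length(x$levels), x$n_params))
  invisible(x)
}
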