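# Standard modelling methods for "cm" and "cm_fit" objects.

#' @export
print.cm <- function(x, ...) {
  cat(sprintf("Conditional mixture (%s, %s): %d neurons, %d components\n",
              x$variant, x$family, x$dN, x$dK))
  if (!is.null(x$stimulus_levels))
    cat("  conditions:", paste(x$stimulus_levels, collapse = ", "), "\n")
  cat("  parameters:", param_count(x$variant, x$family, x$dN, x$dK,
                                   length(x$stimulus_levels) %||% NULL), "\n")
  invisible(x)
}

#' @export
print.cm_fit <- function(x, ...) {
  NextMethod()
  cat(sprintf("  fitted to %d trials; log-likelihood %.2f (%.3f nats/trial)\n",
              x$fit$nobs, x$fit$logLik, x$fit$logLik / x$fit$nobs))
  invisible(x)
}

#' @export
coef.cm <- function(object, ...) {
  if (object$variant == "maximal") {
    lapply(object$tables, function(m)
      list(theta_n = m$theta_n, theta_k = m$theta_k, theta_nk = m$theta_nk,
           theta_star = m$theta_star))
  } else {
    list(theta_n0 = object$theta_n0, theta_nx = object$theta_nx,
         theta_k = object$theta_k, theta_nk = object$theta_nk,
         theta_star = object$theta_star)
  }
}

#' @export
logLik.cm_fit <- function(object, ...) {
  structure(object$fit$logLik,
            df = param_count(object$variant, object$family, object$dN,
                             object$dK, length(object$stimulus_levels) %||% NULL),
            nobs = object$fit$nobs, class = "logLik")
}

#' @export
summary.cm_fit <- function(object, x_ref = NULL, ...) {
  xr <- x_ref %||% if (is_minimal(object) && object$variant == "von_mises") 90
    else object$stimulus_levels[[1L]]
  mom <- mixture_moments(mixture_at(object, xr))
  out <- list(variant = object$variant, family = object$family,
              dN = object$dN, dK = object$dK,
              n_params = param_count(object$variant, object$family, object$dN,
                                     object$dK, length(object$stimulus_levels) %||% NULL),
              logLik = object$fit$logLik, nobs = object$fit$nobs,
              x_ref = xr, mean = mom$mean, fano = mom$fano,
              mean_abs_corr = {
                s <- stats::cov2cor(mom$covariance)
                mean(abs(s[upper.tri(s)]))
              },
              trace = object$fit$trace)
  class(out) <- "summary.cm_fit"
  out
}

#' @export
print.summary.cm_fit <- function(x, ...) {
  cat(sprintf("Conditional mixture fit (%s, %s)\n", x$variant, x$family))
  cat(sprintf("  %d neurons, %d components, %d parameters\n", x$dN, x$dK, x$n_params))
  cat(sprintf("  log-likelihood %.2f over %d trials (%.3f nats/trial)\n",
              x$logLik, x$nobs, x$logLik / x$nobs))
  cat(sprintf("  at stimulus %s: mean rate %.2f, mean Fano factor %.2f,\n",
              format(x$x_ref), mean(x$mean), mean(x$fano)))
  cat(sprintf("  mean |noise correlation| %.3f\n", x$mean_abs_corr))
  invisible(x)
}

#' Decode stimuli from count vectors
#'
#' \code{predict} on a fitted conditional mixture performs Bayesian decoding
#' over the model's discrete conditions: \code{type = "posterior"} returns
#' the matrix of log-posteriors p(x | n), \code{type = "decode"} the
#' maximum-a-posteriori condition, and \code{type = "mean"} the model's
#' grand tuning mean at given stimuli.
#'
#' @param object A fitted \code{"cm_fit"} (or bare \code{"cm"}) object.
#' @param newdata Count matrix to decode (defaults to the training counts);
#'   for \code{type = "mean"}, a vector of stimuli.
#' @param type See above.
#' @param prior Prior simplex over conditions; defaults to the empirical
#'   stimulus frequencies of the training data (uniform if unavailable).
#' @param levels Conditions to decode over (von Mises models decode over the
#'   training stimulus values by default).
#' @param ... Unused.
#' @return See \code{type}.
#' @export
predict.cm <- function(object, newdata = NULL,
                       type = c("posterior", "decode", "mean"),
                       prior = NULL, levels = NULL, ...) {
  type <- match.arg(type)
  lv <- levels %||% object$stimulus_levels %||%
    sort(unique(object$fit$stimulus))
  if (type == "mean") {
    xs <- newdata %||% lv
    return(grand_tuning(object, xs))
  }
  counts <- newdata %||% object$fit$counts
  if (is.null(counts)) stop("'newdata' counts are required", call. = FALSE)
  if (is.null(prior)) {
    prior <- if (!is.null(object$fit$stimulus))
      estimate_prior(object$fit$stimulus, lv)
    else stats::setNames(rep(1 / length(lv), length(lv)), lv)
  }
  lp <- bayes_posterior(object, counts, prior = prior, levels = lv)
  if (type == "posterior") lp else lv[max.col(lp, ties.method = "first")]
}

#' Simulate trials from a conditional mixture
#'
#' @param object A \code{"cm"} object.
#' @param nsim Repetitions per stimulus value.
#' @param seed Integer seed.
#' @param stimulus Stimulus values to present (defaults to the model's
#'   conditions, or 10 orientations over the half-circle for von Mises
#'   maps).
#' @param ... Unused.
#' @return A \code{"trial_table"}: counts, stimulus, latent component per
#'   trial.
#' @export
simulate.cm <- function(object, nsim = 1, seed = NULL, stimulus = NULL, ...) {
  stim <- stimulus %||% object$stimulus_levels %||% seq(0, 162, by = 18)
  simulate_cm_dataset(object, stim, reps = nsim, seed = seed)
}

#' @export
fitted.cm_fit <- function(object, ...) {
  t(grand_tuning_at(object, object$fit$stimulus))
}

# Grand tuning means evaluated per trial (deduplicated by stimulus value).
grand_tuning_at <- function(cm, stimulus) {
  if (cm$variant == "von_mises") {
    xs <- unique(as.numeric(stimulus))
    idx <- match(as.numeric(stimulus), xs)
  } else {
    xs <- cm$stimulus_levels
    idx <- level_index(cm, stimulus)
  }
  gt <- grand_tuning(cm, xs)
  gt[, idx, drop = FALSE]
}

#' @export
residuals.cm_fit <- function(object, type = c("response", "pearson"), ...) {
  type <- match.arg(type)
  mu <- fitted(object)
  r <- object$fit$counts - mu
  if (type == "pearson") r / sqrt(pmax(mu, .Machine$double.eps)) else r
}

#' Diagnostic plots for a conditional mixture
#'
#' Draws the grand tuning curves of every neuron and, below, the
#' stimulus-dependent index probabilities p(k | x).
#'
#' @param x A \code{"cm"} object.
#' @param xs Stimulus grid (defaults to the conditions, or a dense
#'   orientation grid for von Mises maps).
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.cm <- function(x, xs = NULL, ...) {
  if (is.null(xs))
    xs <- if (x$variant == "von_mises") seq(0, 180, length.out = 91)
      else x$stimulus_levels
  xv <- if (x$variant == "von_mises") xs else seq_along(xs)
  gt <- grand_tuning(x, xs)
  pk <- index_probability_curves(x, xs)
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::matplot(xv, t(gt), type = "l", lty = 1,
                    xlab = "stimulus", ylab = "mean spike count",
                    main = "grand tuning curves", ...)
  graphics::matplot(xv, t(pk), type = "l", lty = 1, ylim = c(0, 1),
                    xlab = "stimulus", ylab = "p(k | x)",
                    main = "index probabilities")
  invisible(x)
}
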