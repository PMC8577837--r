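# Stimulus-dependent conditional mixtures (CMs).
#
# A minimal CM restricts stimulus dependence to the baseline parameters
# theta_n(x); the index biases theta_k, the modulations theta_nk and the
# dispersion parameters theta_star (CB) are shared across stimuli:
#   p(n, k | x) ~ exp(theta_n(x) . n [+ theta_star . lf(n)]
#                     + theta_k . d(k) + n . theta_nk . d(k)).
# Two minimal stimulus maps are supported: von Mises tuning
# theta_n(x) = theta_n0 + theta_nx . (cos 2x, sin 2x) for orientations x in
# degrees (period 180), and a discrete lookup theta_n(x) = theta_n0 +
# theta_nx . d(x) over an ordered set of condition labels (level 1 is the
# baseline). A maximal CM instead stores one full mixture per condition.

cm_variants <- c("von_mises", "discrete", "maximal")

#' Construct a conditional mixture model
#'
#' @param variant One of \code{"von_mises"}, \code{"discrete"},
#'   \code{"maximal"}.
#' @param family \code{"IP"} (independent Poisson) or \code{"CB"}
#'   (CoM-Poisson based).
#' @param theta_n0 Length-dN baseline parameters (minimal variants).
#' @param theta_nx dN x 2 (von Mises) or dN x (dX - 1) (discrete) stimulus
#'   map matrix.
#' @param theta_k,theta_nk Shared mixture parameters (minimal variants); see
#'   [mixture_natural()].
#' @param theta_star Shared dispersion parameters (CB minimal variants).
#' @param stimulus_levels Ordered condition labels (discrete and maximal
#'   variants). The first level is the baseline of the discrete map.
#' @param tables Named list of \code{"mixture_natural"} objects, one per
#'   condition (maximal variant).
#' @param neuron_ids Optional neuron identifiers.
#' @return An object of class \code{"cm"}.
#' @export
cm_model <- function(variant, family = c("IP", "CB"),
                     theta_n0 = NULL, theta_nx = NULL,
                     theta_k = NULL, theta_nk = NULL, theta_star = NULL,
                     stimulus_levels = NULL, tables = NULL,
                     neuron_ids = NULL) {
  variant <- match.arg(variant, cm_variants)
  family <- match.arg(family)
  if (variant == "maximal") {
    stopifnot(is.list(tables), length(tables) >= 1L)
    if (is.null(stimulus_levels)) stimulus_levels <- names(tables)
    stopifnot(length(stimulus_levels) == length(tables))
    names(tables) <- as.character(stimulus_levels)
    dN <- tables[[1L]]$dN
    dK <- tables[[1L]]$dK
    obj <- list(variant = variant, family = family, dN = dN, dK = dK,
                stimulus_levels = stimulus_levels, tables = tables)
  } else {
    theta_n0 <- as.numeric(theta_n0)
    dN <- length(theta_n0)
    theta_nx <- as.matrix(theta_nx)
    if (variant == "von_mises" && ncol(theta_nx) != 2L)
      stop("'theta_nx' must have two columns for a von Mises map", call. = FALSE)
    if (variant == "discrete") {
      if (is.null(stimulus_levels)) stop("discrete maps need 'stimulus_levels'", call. = FALSE)
      if (ncol(theta_nx) != length(stimulus_levels) - 1L)
        stop("'theta_nx' must be dN x (number of levels - 1)", call. = FALSE)
    }
    theta_k <- as.numeric(theta_k %||% numeric(0))
    theta_nk <- as.matrix(theta_nk %||% matrix(0, dN, 0))
    dK <- length(theta_k) + 1L
    if (family == "CB") check_com_params(theta_n0, theta_star) else theta_star <- NULL
    obj <- list(variant = variant, family = family, dN = dN, dK = dK,
                theta_n0 = theta_n0, theta_nx = theta_nx,
                theta_k = theta_k, theta_nk = matrix(theta_nk, dN, dK - 1L),
                theta_star = theta_star,
                stimulus_levels = stimulus_levels)
  }
  obj$neuron_ids <- neuron_ids %||% paste0("neuron_", seq_len(obj$dN))
  structure(obj, class = "cm")
}

is_minimal <- function(cm) cm$variant != "maximal"

# Index of discrete/maximal condition labels, with validation.
level_index <- function(cm, x) {
  idx <- match(as.character(x), as.character(cm$stimulus_levels))
  if (anyNA(idx))
    stop("unknown stimulus level(s): ",
         paste(unique(x[is.na(idx)]), collapse = ", "), call. = FALSE)
  idx
}

#' Stimulus-dependent baseline parameters theta_n(x)
#'
#' @param cm A \code{"cm"} object.
#' @param x Stimulus value(s): orientations in degrees (von Mises) or
#'   condition labels (discrete, maximal).
#' @return A dN x length(x) matrix of baseline natural parameters.
#' @export
baseline_params <- function(cm, x) {
  stopifnot(inherits(cm, "cm"))
  switch(cm$variant,
    von_mises = cm$theta_n0 + cm$theta_nx %*% t(vm_basis(x)),
    discrete = {
      idx <- level_index(cm, x)
      d <- cbind(0, cm$theta_nx)  # level 1 is the baseline
      cm$theta_n0 + d[, idx, drop = FALSE]
    },
    maximal = {
      idx <- level_index(cm, x)
      vapply(idx, function(i) cm$tables[[i]]$theta_n, numeric(cm$dN))
    })
}

#' The full mixture at a stimulus value
#'
#' Assembles the stimulus-conditioned mixture p(n, k | x) as a
#' \code{"mixture_natural"} object, to which all mixture operations apply.
#'
#' @inheritParams baseline_params
#' @param x A single stimulus value.
#' @return A \code{"mixture_natural"} object.
#' @export
mixture_at <- function(cm, x) {
  stopifnot(inherits(cm, "cm"), length(x) == 1L)
  if (cm$variant == "maximal") return(cm$tables[[level_index(cm, x)]])
  mixture_natural(drop(baseline_params(cm, x)), cm$theta_k, cm$theta_nk,
                  cm$theta_star)
}

#' Component tuning curves
#'
#' Mean responses of every neuron under every mixture component across a
#' stimulus grid. For IP components these are gain-modulated copies of the
#' baseline tuning curve: \code{mu_ik(x) = gamma_i(k-1) * mu_i1(x)} with
#' log-gains given by the modulation matrix. CB component means are computed
#' by series truncation.
#'
#' @inheritParams baseline_params
#' @param xs Stimulus grid.
#' @param max_count Optional truncation cutoff (CB).
#' @return A dN x dK x length(xs) array of component means.
#' @export
tuning_curves <- function(cm, xs, max_count = NULL) {
  stopifnot(inherits(cm, "cm"))
  out <- array(0, c(cm$dN, cm$dK, length(xs)))
  for (j in seq_along(xs)) {
    m <- mixture_at(cm, xs[j])
    comp <- component_log_rates(m)
    if (m$family == "IP") {
      out[, , j] <- exp(comp)
    } else {
      if (is.null(max_count)) mc <- com_max_count(as.vector(comp), rep(m$theta_star, m$dK))
      else mc <- max_count
      for (k in seq_len(m$dK))
        out[, k, j] <- com_moments(comp[, k], m$theta_star, mc)$mean
    }
  }
  out
}

#' Grand (marginal) tuning curves
#'
#' The stimulus-dependent marginal mean of each neuron,
#' \code{sum_k p(k | x) mu_ik(x)}.
#'
#' @inheritParams tuning_curves
#' @return A dN x length(xs) matrix.
#' @export
grand_tuning <- function(cm, xs, max_count = NULL) {
  tc <- tuning_curves(cm, xs, max_count)
  pk <- index_probability_curves(cm, xs, max_count)
  out <- matrix(0, cm$dN, length(xs))
  for (j in seq_along(xs)) out[, j] <- tc[, , j] %*% pk[, j]
  out
}

#' Stimulus-dependent index probabilities p(k | x)
#'
#' @inheritParams tuning_curves
#' @return A dK x length(xs) matrix; each column sums to 1.
#' @export
index_probability_curves <- function(cm, xs, max_count = NULL) {
  vapply(xs, function(x) exp(index_log_probabilities(mixture_at(cm, x), max_count)),
         numeric(cm$dK))
}

#' Parameter counts of conditional mixture variants
#'
#' Number of free parameters of each CM variant as a function of the number
#' of stimulus conditions dX, neurons dN, and components dK: maximal
#' \code{dX (dN dK + dK - 1)}, von Mises \code{(dN + 1)(dK - 1) + 3 dN},
#' discrete \code{(dN + 1)(dK - 1) + dX dN}. The CB extension adds
#' \code{dX dN} (maximal) or \code{dN} (minimal) dispersion parameters.
#'
#' @param variant,family See [cm_model()].
#' @param dN,dK,dX Positive model dimensions (dX needed for maximal and
#'   discrete variants).
#' @return Integer parameter count.
#' @export
param_count <- function(variant, family = c("IP", "CB"), dN, dK, dX = NULL) {
  variant <- match.arg(variant, cm_variants)
  family <- match.arg(family)
  stopifnot(dN >= 1, dK >= 1)
  base <- switch(variant,
    maximal = dX * (dN * dK + dK - 1),
    von_mises = (dN + 1) * (dK - 1) + 3 * dN,
    discrete = (dN + 1) * (dK - 1) + dX * dN)
  if (family == "CB")
    base <- base + if (variant == "maximal") dX * dN else dN
  as.integer(base)
}

#' Parameter counts of the reference decoders
#'
#' \code{"linear"}: a multiclass linear decoder with dX - 1 categorical
#' natural-parameter outputs, \code{(dX - 1)(dN + 1)} parameters.
#' \code{"mlp"}: a two-hidden-layer sigmoid network dN -> h -> h -> dX - 1.
#' \code{"nonmixed_ip"}: the discrete-tuned independent Poisson encoder,
#' \code{dX * dN}.
#'
#' @param type Decoder type.
#' @param dN,dX Input and condition counts.
#' @param hidden Hidden layer width (MLP).
#' @return Integer parameter count.
#' @export
decoder_param_count <- function(type = c("linear", "mlp", "nonmixed_ip"),
                                dN, dX, hidden = NULL) {
  type <- match.arg(type)
  as.integer(switch(type,
    linear = (dX - 1) * (dN + 1),
    mlp = (dN + 1) * hidden + (hidden + 1) * hidden + (hidden + 1) * (dX - 1),
    nonmixed_ip = dX * dN))
}
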