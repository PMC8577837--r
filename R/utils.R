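# Internal numerical helpers. All mixture arithmetic is done in log space.

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Row-wise log-sum-exp of a matrix.
row_logsumexp <- function(m) {
  mx <- apply(m, 1L, max)
  mx + log(rowSums(exp(m - mx)))
}

softmax <- function(x) {
  e <- exp(x - max(x))
  e / sum(e)
}

deg2rad <- function(x) x * pi / 180

#' Von Mises basis for orientation stimuli
#'
#' Maps orientations in degrees (period 180) to the doubled-angle circular
#' basis \code{(cos 2x, sin 2x)} used by von Mises tuning maps.
#'
#' @param x Numeric vector of orientations in degrees.
#' @return A \code{length(x)} by 2 matrix with columns \code{cos 2x} and
#'   \code{sin 2x} (angles doubled so that the basis is 180-degree periodic).
#' @export
vm_basis <- function(x) {
  a <- 2 * deg2rad(x)
  cbind(cos(a), sin(a))
}

# Derivative of the von Mises basis with respect to orientation in radians.
vm_basis_deriv <- function(x) {
  a <- 2 * deg2rad(x)
  cbind(-2 * sin(a), 2 * cos(a))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

check_counts <- function(n, arg = "n") {
  if (any(!is.finite(n)) || any(n < 0) || any(n != floor(n)))
    stop(sprintf("'%s' must contain non-negative integers", arg), call. = FALSE)
  invisible(n)
}

# djb2-style rolling hash of a character scalar; used to stamp configuration
# provenance into serialized artifacts without a digest dependency. The
# accumulator stays below 2^31 so double arithmetic is exact.
fnv1a_hash <- function(txt) {
  bytes <- as.integer(charToRaw(paste(txt, collapse = "\n")))
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}
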