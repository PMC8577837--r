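# Trial-table and model I/O. CSV is the canonical interchange format for
# datasets (header: stimulus, neuron_1, ..., neuron_dN); models serialize to
# a JSON document of shape metadata plus flat parameter arrays.

CM_SCHEMA_VERSION <- "1.0"

#' Construct a trial table
#'
#' @param counts dT x dN matrix of non-negative integer spike counts.
#' @param stimulus Length-dT stimulus labels (condition labels or
#'   orientations in degrees).
#' @param neuron_ids Optional column identifiers.
#' @param component Optional latent component indices (simulated data).
#' @return An object of class \code{"trial_table"}.
#' @export
trial_table <- function(counts, stimulus, neuron_ids = NULL, component = NULL) {
  counts <- as.matrix(counts)
  check_counts(counts, "counts")
  stopifnot(nrow(counts) == length(stimulus))
  neuron_ids <- neuron_ids %||% paste0("neuron_", seq_len(ncol(counts)))
  stopifnot(length(neuron_ids) == ncol(counts))
  colnames(counts) <- neuron_ids
  structure(list(counts = counts, stimulus = stimulus,
                 neuron_ids = neuron_ids, component = component),
            class = "trial_table")
}

#' @export
print.trial_table <- function(x, ...) {
  cat(sprintf("Trial table: %d trials x %d neurons, %d stimulus values\n",
              nrow(x$counts), ncol(x$counts), length(unique(x$stimulus))))
  invisible(x)
}

#' @export
as.data.frame.trial_table <- function(x, ...) {
  data.frame(stimulus = x$stimulus, x$counts, check.names = FALSE)
}

#' Read a trial table from CSV
#'
#' Expects a header row \code{stimulus, neuron_1, ...}; counts must be
#' non-negative integers (a fractional or negative cell is a validation
#' error naming its position).
#'
#' @param path File path.
#' @param format Only \code{"csv"} is supported.
#' @return A \code{"trial_table"}.
#' @export
read_trials <- function(path, format = c("csv")) {
  format <- match.arg(format)
  df <- utils::read.csv(path, check.names = FALSE)
  if (names(df)[1L] != "stimulus")
    stop("first column must be 'stimulus'", call. = FALSE)
  counts <- as.matrix(df[, -1L, drop = FALSE])
  bad <- which(!is.finite(counts) | counts < 0 | counts != floor(counts),
               arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("invalid count at row %d, column '%s'",
                 bad[1L, 1L], colnames(counts)[bad[1L, 2L]]), call. = FALSE)
  storage.mode(counts) <- "integer"
  trial_table(counts, df$stimulus, neuron_ids = colnames(counts))
}

#' Write a trial table to CSV
#'
#' @param table A \code{"trial_table"}.
#' @param path File path.
#' @param format Only \code{"csv"} is supported.
#' @return \code{path}, invisibly. Round-trips losslessly through
#'   [read_trials()].
#' @export
write_trials <- function(table, path, format = c("csv")) {
  format <- match.arg(format)
  stopifnot(inherits(table, "trial_table"))
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}

# ---- model JSON -------------------------------------------------------------

mixnat_to_list <- function(m) {
  list(theta_n = m$theta_n, theta_k = m$theta_k,
       theta_nk = as.vector(t(m$theta_nk)),   # row-major
       theta_star = m$theta_star)
}

mixnat_from_list <- function(l, dN, dK) {
  mixture_natural(l$theta_n, l$theta_k %||% numeric(0),
                  t(matrix(l$theta_nk %||% numeric(0), dK - 1L, dN)),
                  l$theta_star)
}

#' Serialize a conditional mixture to JSON
#'
#' Shape metadata plus flat, row-major parameter arrays (with an explicit
#' component-axis marker), the schema version, and optional seed and
#' configuration provenance (the configuration is stored alongside its
#' hash).
#'
#' @param cm A \code{"cm"} object.
#' @param path File path.
#' @param seed Optional seed to record.
#' @param config Optional configuration list to record.
#' @return \code{path}, invisibly.
#' @export
write_cm_json <- function(cm, path, seed = NULL, config = NULL) {
  stopifnot(inherits(cm, "cm"))
  doc <- list(schema_version = CM_SCHEMA_VERSION,
              component_axis = "columns",
              variant = cm$variant, family = cm$family,
              dN = cm$dN, dK = cm$dK,
              stimulus_levels = cm$stimulus_levels,
              neuron_ids = cm$neuron_ids,
              seed = seed)
  if (!is.null(config)) {
    cfg_json <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA)
    doc$config <- config
    doc$config_hash <- fnv1a_hash(as.character(cfg_json))
  }
  if (cm$variant == "maximal") {
    doc$tables <- lapply(cm$tables, mixnat_to_list)
  } else {
    doc$theta_n0 <- cm$theta_n0
    doc$theta_nx <- as.vector(t(cm$theta_nx))
    doc$theta_nx_cols <- ncol(cm$theta_nx)
    doc$theta_k <- cm$theta_k
    doc$theta_nk <- as.vector(t(cm$theta_nk))
    doc$theta_star <- cm$theta_star
  }
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a conditional mixture from JSON
#'
#' @param path File written by [write_cm_json()].
#' @return A \code{"cm"} object.
#' @export
read_cm_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  dN <- doc$dN
  dK <- doc$dK
  if (doc$variant == "maximal") {
    tables <- lapply(doc$tables, mixnat_from_list, dN = dN, dK = dK)
    cm_model("maximal", doc$family, tables = tables,
             stimulus_levels = doc$stimulus_levels,
             neuron_ids = doc$neuron_ids)
  } else {
    ncx <- doc$theta_nx_cols
    cm_model(doc$variant, doc$family,
             theta_n0 = doc$theta_n0,
             theta_nx = t(matrix(doc$theta_nx, ncx, dN)),
             theta_k = doc$theta_k %||% numeric(0),
             theta_nk = if (dK > 1L) t(matrix(doc$theta_nk, dK - 1L, dN))
               else matrix(0, dN, 0L),
             theta_star = doc$theta_star,
             stimulus_levels = doc$stimulus_levels,
             neuron_ids = doc$neuron_ids)
  }
}
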