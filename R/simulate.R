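#' Construct a relative-abundance time series object
#'
#' Container for taxa-by-time relative abundances together with presence
#' calls at a detection threshold. Raw abundances are retained; statistics
#' treat below-threshold entries as absences.
#'
#' @param x \code{N x T} matrix of relative abundances (columns sum to 1 for
#'   simulator output; loaded tables are normalized on read).
#' @param detect Detection threshold on relative abundance.
#' @param taxa_ids Row labels; defaults to \code{taxon_1 ... taxon_N}.
#' @param meta List of provenance metadata (generating parameters or source).
#' @return An object of class \code{"cr_series"}.
#' @export
cr_series <- function(x, detect = 1e-4, taxa_ids = NULL, meta = list()) {
  stopifnot(is.matrix(x), all(is.finite(x)), all(x >= 0))
  if (is.null(taxa_ids)) taxa_ids <- paste0("taxon_", seq_len(nrow(x)))
  stopifnot(length(taxa_ids) == nrow(x))
  rownames(x) <- taxa_ids
  structure(list(x = x, present = x > detect, detect = detect,
                 taxa_ids = taxa_ids, meta = meta),
            class = "cr_series")
}

#' @export
print.cr_series <- function(x, ...) {
  cat(sprintf("Relative-abundance time series: %d taxa x %d sampling times\n",
              nrow(x$x), ncol(x$x)))
  cat(sprintf("  detection threshold %g; %.1f%% of entries present\n",
              x$detect, 100 * mean(x$present)))
  if (!is.null(x$meta$variant))
    cat(sprintf("  model variant: %s\n", x$meta$variant))
  invisible(x)
}

#' @export
dim.cr_series <- function(x) dim(x$x)

# Abundance matrix with below-detection entries zeroed.
thresholded <- function(series) {
  xd <- series$x
  xd[!series$present] <- 0
  xd
}

as_cr_series <- function(series, detect = 1e-4) {
  if (inherits(series, "cr_series")) return(series)
  if (is.matrix(series)) return(cr_series(series, detect = detect))
  stop("expected a 'cr_series' object or a numeric matrix")
}

#' Simulate a relative-abundance time series from the ensemble
#'
#' Draws one random instance (consumption matrix and resource set points)
#' from the ensemble, generates a fluctuating resource-supply trajectory, and
#' runs each sampling time's supply to the approximate ecological steady
#' state under serial dilution. Columns of the result sum to 1.
#'
#' @param params A \code{"cr_params"} object.
#' @param variant Model variant: \code{"linear"} (default), \code{"saturating"}
#'   (Monod kinetics with \code{Ys = mean(ybar) / 3}), or \code{"tradeoff"}
#'   (fixed-capacity consumption rows, see [apply_tradeoff()]).
#' @param seed Optional seed; when \code{NULL} the current RNG state is used.
#' @return A \code{"cr_series"} object. \code{meta} records the parameters,
#'   variant, per-time dilution counts (\code{n_dilutions}) and cumulative
#'   generations per sampling interval (\code{generations}).
#' @export
simulate_timeseries <- function(params,
                                variant = c("linear", "saturating", "tradeoff"),
                                seed = NULL) {
  validate_cr_params(params)
  variant <- match.arg(variant)
  if (!is.null(seed)) set.seed(seed)
  R <- draw_consumption_matrix(params)
  ybar <- draw_setpoints(params)
  if (variant == "tradeoff") R <- apply_tradeoff(R, ybar)
  Ys <- if (variant == "saturating") mean(ybar) / 3 else 0
  supply <- resource_trajectory(params, ybar)
  sim <- .cr_series_cpp(R, supply, params$D, params$steady_frac,
                        params$reservoir, Ys, 1e-8, 1e-10, 1e-7,
                        params$cycles_max, 1e6L)
  cr_series(sim$x, detect = params$detect,
            meta = list(params = params, variant = variant, seed = seed,
                        n_cycles = as.integer(sim$n_cycles),
                        n_dilutions = as.integer(sim$n_cycles) - 1L,
                        generations = as.numeric(sim$generations)))
}

#' Simulate independent replicate instances of the ensemble
#'
#' Each instance draws a fresh consumption matrix, set points and resource
#' noise. Instance seeds are derived deterministically from the master seed,
#' so each replicate is individually reproducible.
#'
#' @inheritParams simulate_timeseries
#' @param n_instances Number of replicate instances; defaults to
#'   \code{params$n_instances}.
#' @param seed Master seed; defaults to \code{params$seed}.
#' @return A list of \code{"cr_series"} objects.
#' @export
simulate_replicates <- function(params,
                                variant = c("linear", "saturating", "tradeoff"),
                                n_instances = NULL, seed = NULL) {
  validate_cr_params(params)
  variant <- match.arg(variant)
  if (is.null(n_instances)) n_instances <- params$n_instances
  if (is.null(seed)) seed <- params$seed
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max - 1L, 1)
  seeds <- split_seed(seed, n_instances)
  lapply(seeds, function(s) simulate_timeseries(params, variant, seed = s))
}
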