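#' Global ensemble parameters for the consumer-resource model
#'
#' Bundles the global parameters that define a statistical ensemble of
#' coarse-grained consumer-resource communities: the reservoir size \code{N},
#' the number of coarse-grained resources \code{M}, the sparsity \code{S} of
#' the consumption matrix (probability that a consumer cannot use a resource),
#' and the resource-fluctuation parameters \code{sigma} (noise magnitude) and
#' \code{k} (restoring force). The remaining fields are simulation constants:
#' maximum consumption rate and resource set point (\code{Rmax}, \code{Ymax};
#' only relative abundances are studied, so their absolute scale is
#' immaterial), the serial-dilution factor \code{D}, the approximate
#' steady-state threshold \code{steady_frac} (as a fraction of \code{D}), the
#' presence detection threshold \code{detect}, the number of sampling times
#' \code{T}, and the replicate instance count \code{n_instances}.
#'
#' @param N Number of consumers in the reservoir (>= 1).
#' @param M Number of coarse-grained resources (>= 1).
#' @param S Sparsity of resource competition, in [0, 1].
#' @param sigma Resource-noise magnitude (>= 0), as a fraction of each
#'   resource's set point.
#' @param k Restoring-force strength of the resource random walk, in [0, 1].
#' @param Rmax Maximum consumption rate (> 0).
#' @param Ymax Maximum resource set point (>= 0).
#' @param D Dilution factor between growth cycles (> 1).
#' @param steady_frac Steady-state threshold: a sampling interval ends when
#'   every consumer's growth ratio changes by less than
#'   \code{steady_frac * D} between successive cycles. In (0, 1).
#' @param detect Detection threshold on relative abundance; taxa below it are
#'   called absent.
#' @param T Number of sampling times in a simulated series.
#' @param n_instances Default number of replicate random instances.
#' @param reservoir Relative size of the reservoir inoculum. The first cycle
#'   of each sampling interval starts from total abundance
#'   \code{reservoir * sum(Y0) / (D - 1)} split equally across consumers; 1
#'   makes the serial-dilution fixed point self-consistent (steady growth
#'   ratio exactly \code{D}).
#' @param cycles_max Hard budget of dilution cycles per sampling interval.
#' @param seed Optional master RNG seed.
#'
#' @return An object of class \code{"cr_params"} (a validated list).
#' @seealso [simulate_timeseries()], [read_cr_config()]
#' @export
cr_params <- function(N, M, S, sigma, k,
                      Rmax = 1, Ymax = 1, D = 200, steady_frac = 0.05,
                      detect = 1e-4, T = 300, n_instances = 20,
                      reservoir = 1, cycles_max = 500, seed = NULL) {
  p <- list(N = as.integer(N), M = as.integer(M), S = S, sigma = sigma, k = k,
            Rmax = Rmax, Ymax = Ymax, D = D, steady_frac = steady_frac,
            detect = detect, T = as.integer(T),
            n_instances = as.integer(n_instances), reservoir = reservoir,
            cycles_max = as.integer(cycles_max), seed = seed)
  class(p) <- "cr_params"
  validate_cr_params(p)
  p
}

validate_cr_params <- function(p) {
  stopifnot(p$N >= 1L, p$M >= 1L, p$T >= 1L, p$n_instances >= 1L)
  if (p$S < 0 || p$S > 1) stop("S must be in [0, 1]")
  if (p$k < 0 || p$k > 1) stop("k must be in [0, 1]")
  if (p$sigma < 0) stop("sigma must be non-negative")
  if (p$Rmax <= 0) stop("Rmax must be positive")
  if (p$Ymax < 0) stop("Ymax must be non-negative")
  if (p$D <= 1) stop("D must be greater than 1")
  if (p$steady_frac <= 0 || p$steady_frac >= 1)
    stop("steady_frac must be in (0, 1)")
  if (p$reservoir <= 0) stop("reservoir must be positive")
  invisible(p)
}

#' @export
print.cr_params <- function(x, ...) {
  cat("Consumer-resource ensemble parameters\n")
  cat(sprintf("  N = %d consumers, M = %d resources\n", x$N, x$M))
  cat(sprintf("  S = %g, sigma = %g, k = %g\n", x$S, x$sigma, x$k))
  cat(sprintf("  D = %g, steady_frac = %g, detect = %g, T = %d\n",
              x$D, x$steady_frac, x$detect, x$T))
  invisible(x)
}

#' Read ensemble parameters from a YAML config file
#'
#' The file is a flat key-value mapping using the field names of
#' [cr_params()]. \code{N}, \code{M}, \code{S}, \code{sigma}, \code{k} and
#' \code{T} are required; everything else falls back to the defaults.
#'
#' @param path Path to a YAML file.
#' @return A \code{"cr_params"} object.
#' @export
read_cr_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  # YAML 1.1 resolves the bare keys N/Y (and sometimes T) as booleans
  names(cfg)[names(cfg) == "FALSE"] <- "N"
  names(cfg)[names(cfg) == "TRUE"] <- "T"
  required <- c("N", "M", "S", "sigma", "k", "T")
  missing <- setdiff(required, names(cfg))
  if (length(missing))
    stop("config is missing required fields: ", paste(missing, collapse = ", "))
  known <- names(formals(cr_params))
  unknown <- setdiff(names(cfg), known)
  if (length(unknown))
    stop("unknown config fields: ", paste(unknown, collapse = ", "))
  do.call(cr_params, cfg)
}

#' Draw a random consumption matrix from the ensemble
#'
#' Each rate is drawn independently from a uniform distribution on
#' \code{[0, Rmax]} and then set to zero with probability \code{S}, the
#' sparsity of resource competition.
#'
#' @param params A \code{"cr_params"} object.
#' @return An \code{N x M} matrix of non-negative consumption rates.
#' @export
draw_consumption_matrix <- function(params) {
  validate_cr_params(params)
  R <- matrix(runif(params$N * params$M, 0, params$Rmax),
              nrow = params$N, ncol = params$M)
  zero <- matrix(runif(params$N * params$M) < params$S,
                 nrow = params$N, ncol = params$M)
  R[zero] <- 0
  R
}

#' Draw random resource set points
#'
#' Each resource's average supply is drawn independently from a uniform
#' distribution on \code{[0, Ymax]}.
#'
#' @param params A \code{"cr_params"} object.
#' @return A length-\code{M} vector of set points.
#' @export
draw_setpoints <- function(params) {
  validate_cr_params(params)
  runif(params$M, 0, params$Ymax)
}

#' Impose a metabolic trade-off on a consumption matrix
#'
#' The uniform-with-sparsity ensemble correlates a consumer's maximum growth
#' rate with the number of resources it consumes. To remove that correlation
#' while preserving fitness variation, each row of the matrix is rescaled so
#' that its sum of consumption rates equals a fixed capacity, where the N
#' capacities are resampled (with replacement) from the original growth rates
#' \code{sum_j R_ij * ybar_j}.
#'
#' @param R Consumption matrix with no all-zero row.
#' @param ybar Resource set points (length \code{ncol(R)}).
#' @return The rescaled consumption matrix.
#' @export
apply_tradeoff <- function(R, ybar) {
  stopifnot(is.matrix(R), length(ybar) == ncol(R))
  row_sums <- rowSums(R)
  if (any(row_sums <= 0))
    stop("apply_tradeoff: consumer with an all-zero row consumes nothing ",
         "and cannot be normalized")
  growth <- as.numeric(R %*% ybar)
  capacity <- sample(growth, nrow(R), replace = TRUE)
  R * (capacity / row_sums)
}
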