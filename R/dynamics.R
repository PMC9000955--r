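#' Integrate one batch-growth cycle to resource depletion
#'
#' Integrates the within-cycle consumer-resource dynamics
#' \deqn{dX_i/dt = X_i \sum_j R_{ij} Y_j, \qquad
#'       dY_j/dt = -Y_j \sum_i R_{ij} X_i}
#' from the given state until every resource is depleted (below
#' \code{ytol_frac * max(Y)} of the starting amounts). Growth and consumption
#' are coupled one-to-one, so \code{sum(X) + sum(Y)} is conserved throughout
#' (to integrator accuracy). With \code{Ys > 0} Monod-type saturation
#' kinetics are used instead: every uptake term is multiplied by
#' \code{Y_j / (Ys + Y_j)}.
#'
#' @param X Initial consumer abundances (length \code{N}, at least one
#'   positive).
#' @param Y Initial resource amounts (length \code{M}, non-negative).
#' @param R Consumption matrix (\code{N x M}).
#' @param Ys Saturation constant; 0 (default) selects linear kinetics.
#' @param rtol,atol Relative and absolute integration tolerances.
#' @param ytol_frac Depletion threshold as a fraction of the largest initial
#'   resource amount.
#' @param max_steps Hard budget of integrator steps.
#' @param strict Raise an "undepletable resource" error when a resource with
#'   positive amount is consumed by no consumer. With \code{strict = FALSE}
#'   (used by the simulation pipeline) such inert resources are stationary
#'   (\code{dY/dt = 0}) and count as settled.
#' @return A list with elements \code{X}, \code{Y} (state at depletion) and
#'   \code{n_steps}.
#' @export
integrate_batch <- function(X, Y, R, Ys = 0, rtol = 1e-8, atol = 1e-10,
                            ytol_frac = 1e-7, max_steps = 1e6,
                            strict = TRUE) {
  stopifnot(is.matrix(R), length(X) == nrow(R), length(Y) == ncol(R),
            all(X >= 0), all(Y >= 0), Ys >= 0)
  if (!any(X > 0)) stop("at least one consumer must have positive abundance")
  ytol <- ytol_frac * max(Y, 1e-12)
  out <- .cr_batch_cpp(X, Y, R, Ys, rtol, atol, ytol, as.integer(max_steps),
                       strict)
  out$X <- as.numeric(out$X)
  out$Y <- as.numeric(out$Y)
  out
}

#' Run serial-dilution cycles to the approximate ecological steady state
#'
#' Each sampling interval starts from a reservoir inoculum (all \code{N}
#' consumers at equal abundance, total \code{reservoir * sum(Y0) / (D - 1)}),
#' then repeats: grow the batch to resource depletion, record per-consumer
#' growth ratios \code{g_i} (final over initial abundance), dilute all
#' consumers by \code{D}, and replenish resources to \code{Y0}. The interval
#' ends when every \code{g_i} changes by less than \code{steady_frac * D}
#' between successive cycles (at least 2 cycles). Consumer abundances are
#' floored at 1e-300 when forming ratios so numerically extinct consumers
#' cannot block convergence.
#'
#' @param R Consumption matrix (\code{N x M}).
#' @param Y0 Resource supply for this sampling interval (positive total).
#' @param params A \code{"cr_params"} object (uses \code{D},
#'   \code{steady_frac}, \code{reservoir}, \code{cycles_max}).
#' @param Ys Saturation constant; 0 for linear kinetics.
#' @inheritParams integrate_batch
#' @return A list with \code{x} (relative abundances at the final
#'   pre-dilution state, summing to 1), \code{n_cycles} (growth cycles
#'   performed, at least 2), \code{n_dilutions} (dilution events between
#'   cycles, \code{n_cycles - 1}), \code{growth_ratios} (final cycle), and
#'   \code{generations} (cumulative log2 community growth over the
#'   dilution-initiated cycles, approximately
#'   \code{n_dilutions * log2(D)}).
#' @export
run_to_steady_state <- function(R, Y0, params, Ys = 0, rtol = 1e-8,
                                atol = 1e-10, ytol_frac = 1e-7,
                                max_steps = 1e6) {
  validate_cr_params(params)
  stopifnot(is.matrix(R), length(Y0) == ncol(R), all(Y0 >= 0))
  if (sum(Y0) <= 0) stop("total resource supply must be positive")
  out <- .cr_steady_cpp(R, Y0, params$D, params$steady_frac,
                        params$reservoir, Ys, rtol, atol, ytol_frac,
                        params$cycles_max, as.integer(max_steps))
  out$x <- as.numeric(out$x)
  out$growth_ratios <- as.numeric(out$growth_ratios)
  out$n_dilutions <- out$n_cycles - 1L
  out
}
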