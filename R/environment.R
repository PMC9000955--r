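#' One step of the biased random walk in resource supply
#'
#' Advances the supplied resource amounts one sampling time according to
#' \deqn{Y_j(T) = | Y_j(T-1) - k (Y_j(T-1) - \bar{Y}_j) + \sigma \bar{Y}_j \xi_j(T) |}
#' with independent standard-normal innovations \eqn{\xi_j}. The absolute
#' value enforces non-negative supplies. With \code{k = 1} the supply
#' fluctuates about its set point with no memory of the previous time; with
#' \code{k = 0} it performs an unbiased random walk.
#'
#' @param prev Supply at the previous sampling time (non-negative,
#'   length \code{M}).
#' @param ybar Resource set points (length \code{M}).
#' @param sigma Noise magnitude (>= 0).
#' @param k Restoring-force strength in [0, 1].
#' @param xi Optional innovation vector (for deterministic evaluation);
#'   drawn from N(0, 1) when \code{NULL}.
#' @return The supply vector at the next sampling time.
#' @export
step_resources <- function(prev, ybar, sigma, k, xi = NULL) {
  stopifnot(length(prev) == length(ybar), all(prev >= 0))
  if (sigma < 0) stop("sigma must be non-negative")
  if (is.null(xi)) xi <- rnorm(length(prev))
  abs(prev - k * (prev - ybar) + sigma * ybar * xi)
}

#' Generate a trajectory of fluctuating resource supplies
#'
#' Runs the biased random walk of [step_resources()] to produce the initial
#' resource amounts at each sampling time. The chain starts at the set points
#' and is burned in for \code{burnin} steps before recording, so recorded
#' columns are drawn from the stationary distribution.
#'
#' @param params A \code{"cr_params"} object (uses \code{sigma}, \code{k},
#'   \code{T}).
#' @param ybar Resource set points.
#' @param burnin Number of unrecorded equilibration steps.
#' @return An \code{M x T} matrix; column \code{t} is the supply at sampling
#'   time \code{t}.
#' @export
resource_trajectory <- function(params, ybar, burnin = 50) {
  validate_cr_params(params)
  if (params$T < 1) stop("T must be at least 1")
  M <- length(ybar)
  y <- ybar
  for (b in seq_len(burnin))
    y <- step_resources(y, ybar, params$sigma, params$k)
  supply <- matrix(0, nrow = M, ncol = params$T)
  supply[, 1] <- y
  if (params$T > 1) {
    for (t in 2:params$T)
      supply[, t] <- step_resources(supply[, t - 1], ybar,
                                    params$sigma, params$k)
  }
  supply
}
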