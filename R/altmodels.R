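# Comparison models: no-competition limits, generalized Lotka-Volterra
# (converted from the consumer-resource ensemble or moment-matched random),
# and a non-interacting null model.

#' Simulate the no-competition limit of the consumer-resource model
#'
#' Consumers are assigned disjoint resource sets, so each resource is
#' consumed by exactly one consumer and there is no competition; dynamics,
#' serial dilution, and the fluctuating environment are otherwise identical
#' to the main model. Two modes: \code{"one_unique"} gives every consumer a
#' single unique resource (requires \code{M >= N}); \code{"equal_sets"}
#' gives every consumer a disjoint set of \code{set_size} resources
#' (requires \code{set_size * N <= M}). Resources assigned to no consumer
#' are inert and excluded from the simulated environment.
#'
#' @param params A \code{"cr_params"} object.
#' @param mode \code{"one_unique"} or \code{"equal_sets"}.
#' @param set_size Resources per consumer in \code{"equal_sets"} mode.
#' @param seed Optional seed.
#' @return A \code{"cr_series"} object.
#' @export
simulate_no_competition <- function(params,
                                    mode = c("one_unique", "equal_sets"),
                                    set_size = 10, seed = NULL) {
  validate_cr_params(params)
  mode <- match.arg(mode)
  if (!is.null(seed)) set.seed(seed)
  N <- params$N
  if (mode == "one_unique") {
    if (params$M < N)
      stop("one_unique mode needs M >= N")
    m_active <- N
    set_size <- 1L
  } else {
    if (set_size * N > params$M)
      stop("equal_sets mode needs set_size * N <= M")
    m_active <- set_size * N
  }
  R <- matrix(0, nrow = N, ncol = m_active)
  for (i in seq_len(N)) {
    cols <- ((i - 1) * set_size + 1):(i * set_size)
    R[i, cols] <- runif(set_size, 0, params$Rmax)
  }
  ybar <- runif(m_active, 0, params$Ymax)
  supply <- resource_trajectory(params, ybar)
  sim <- .cr_series_cpp(R, supply, params$D, params$steady_frac,
                        params$reservoir, 0, 1e-8, 1e-10, 1e-7,
                        params$cycles_max, 1e6L)
  cr_series(sim$x, detect = params$detect,
            meta = list(params = params, variant = "no_competition",
                        mode = mode, set_size = set_size, seed = seed,
                        n_cycles = as.integer(sim$n_cycles),
                        n_dilutions = as.integer(sim$n_cycles) - 1L,
                        generations = as.numeric(sim$generations)))
}

#' Convert a consumer-resource instance to a Lotka-Volterra parametrization
#'
#' When consumption rates are close to their mean, the consumer-resource
#' dynamics reduce to a generalized Lotka-Volterra model with growth rates
#' \code{r_i = 2 sum_j R_ij Y0_j} and interaction coefficients of magnitude
#' \code{(1/Rmax) sum_k R_ik R_jk Y0_k}. The interaction matrix is assigned
#' the negative sign (competition): it is symmetric, and its off-diagonal
#' magnitudes grow with the niche overlap of the pair. Because the supply
#' \code{Y0} enters the mapping, fluctuations in supply across sampling
#' times induce fluctuations in both \code{r} and \code{A}.
#'
#' @param R Consumption matrix (\code{N x M}).
#' @param Y0 Resource supply at one sampling time (length \code{M}).
#' @param Rmax Maximum consumption rate of the ensemble.
#' @return An object of class \code{"glv_params"}: list with \code{r}
#'   (length \code{N}), \code{A} (\code{N x N}, symmetric, non-positive),
#'   and \code{meta}.
#' @export
convert_to_glv <- function(R, Y0, Rmax = 1) {
  stopifnot(is.matrix(R), length(Y0) == ncol(R))
  r <- as.numeric(2 * (R %*% Y0))
  A <- -(R %*% (Y0 * t(R))) / Rmax
  A <- (A + t(A)) / 2  # symmetric by construction; enforce against round-off
  structure(list(r = r, A = A, meta = list(provenance = "converted")),
            class = "glv_params")
}

glv_rhs <- function(t, x, parms) {
  Ax <- as.numeric(parms$A %*% x)
  gamma <- sum(parms$r * x) + sum(x * Ax)
  list(x * (parms$r + Ax - gamma))
}

#' Simulate a normalized Lotka-Volterra model across sampling times
#'
#' Integrates the replicator-form gLV dynamics
#' \deqn{dX_i/dt = X_i (r_i + \sum_j A_{ij} X_j - \Gamma(t))}
#' with \eqn{\Gamma} chosen so relative abundances stay on the simplex. Each
#' sampling time uses its own parameter set (e.g. from [convert_to_glv()]
#' applied to that time's resource supply), starts from equal relative
#' abundances, and integrates for a fixed duration.
#'
#' @param glv_per_time List of \code{"glv_params"}, one per sampling time.
#' @param integrate_time Fixed integration duration per sampling time.
#' @param x0 Initial relative abundances (on the simplex); defaults to equal.
#' @param detect Detection threshold for the output series.
#' @return A \code{"cr_series"} object.
#' @export
simulate_glv <- function(glv_per_time, integrate_time, x0 = NULL,
                         detect = 1e-4) {
  stopifnot(length(glv_per_time) >= 1, integrate_time > 0)
  N <- length(glv_per_time[[1]]$r)
  if (is.null(x0)) x0 <- rep(1 / N, N)
  stopifnot(length(x0) == N, abs(sum(x0) - 1) < 1e-8, all(x0 >= 0))
  x <- matrix(NA_real_, nrow = N, ncol = length(glv_per_time))
  for (t in seq_along(glv_per_time)) {
    g <- glv_per_time[[t]]
    sol <- deSolve::ode(y = x0, times = c(0, integrate_time), func = glv_rhs,
                        parms = g, method = "lsoda",
                        rtol = 1e-10, atol = 1e-14)
    xt <- as.numeric(sol[nrow(sol), -1])
    if (any(!is.finite(xt)))
      stop("gLV integration blew up at sampling time ", t)
    if (abs(sum(xt) - 1) > 1e-8)
      stop("gLV simplex drift exceeded 1e-8 at sampling time ", t)
    # abundances are non-negative analytically; clip integrator round-off
    if (any(xt < -1e-8))
      stop("gLV integration produced negative abundances at time ", t)
    xt[xt < 0] <- 0
    x[, t] <- xt
  }
  cr_series(x, detect = detect,
            meta = list(variant = "glv", integrate_time = integrate_time))
}

#' Calibrate the fixed gLV integration duration
#'
#' The gLV comparison integrates each sampling time for a fixed duration,
#' chosen so that the spread of relative abundances matches the
#' consumer-resource model at its approximate ecological steady state.
#' Calibration minimizes the difference between the 10th-90th percentile
#' spread of log10 abundance of the gLV output and of a reference abundance
#' vector, over a log-spaced grid of candidate durations.
#'
#' @param glv A \code{"glv_params"} calibration instance.
#' @param x_ref Reference relative abundances (e.g. one steady-state column
#'   of a consumer-resource simulation with the same instance).
#' @param times Candidate durations.
#' @return The selected duration.
#' @export
calibrate_glv_time <- function(glv, x_ref,
                               times = 10 ^ seq(-2, 2, length.out = 25)) {
  spread <- function(v) {
    v <- v[v > 0]
    diff(quantile(log10(v), c(0.1, 0.9), names = FALSE))
  }
  target <- spread(as.numeric(x_ref))
  got <- vapply(times, function(tt) {
    s <- simulate_glv(list(glv), tt)
    spread(s$x[, 1])
  }, numeric(1))
  times[which.min(abs(got - target))]
}

#' Random Lotka-Volterra parameters moment-matched to a converted ensemble
#'
#' Draws growth rates and interaction coefficients from independent normal
#' distributions whose means and variances equal those of the
#' consumer-resource-converted gLV ensemble, then forces the interactions to
#' be symmetric (copying the upper triangle) and negative (mapping entries
#' to minus their absolute value). Diagonal entries are matched separately.
#'
#' @param converted_ensemble Non-empty list of converted
#'   \code{"glv_params"}.
#' @return A \code{"glv_params"} object with \code{meta$provenance
#'   = "random"}.
#' @export
random_glv_from_moments <- function(converted_ensemble) {
  stopifnot(length(converted_ensemble) >= 1)
  N <- length(converted_ensemble[[1]]$r)
  r_pool <- unlist(lapply(converted_ensemble, `[[`, "r"))
  off_pool <- unlist(lapply(converted_ensemble, function(g) {
    g$A[upper.tri(g$A)]
  }))
  diag_pool <- unlist(lapply(converted_ensemble, function(g) diag(g$A)))
  r <- rnorm(N, mean(r_pool), sd(r_pool))
  A <- matrix(rnorm(N * N, mean(off_pool), sd(off_pool)), N, N)
  A[lower.tri(A)] <- t(A)[lower.tri(A)]
  A <- -abs(A)
  diag(A) <- -abs(rnorm(N, mean(diag_pool), sd(diag_pool)))
  structure(list(r = r, A = A, meta = list(provenance = "random")),
            class = "glv_params")
}

#' Non-interacting null model of an abundance time series
#'
#' Draws each taxon's abundance at each sampling time from an independent
#' normal distribution whose mean and variance equal that taxon's empirical
#' moments in the input series; negative draws are clipped to 0 (treated as
#' absence). The null reproduces each taxon's marginal mean and variance by
#' construction but carries no interspecies interactions, so its pairwise
#' correlations are sharply peaked about zero.
#'
#' @param data A \code{"cr_series"} object.
#' @param seed Optional seed.
#' @return A \code{"cr_series"} object (columns are not renormalized).
#' @export
null_model <- function(data, seed = NULL) {
  data <- as_cr_series(data)
  if (!is.null(seed)) set.seed(seed)
  N <- nrow(data$x)
  Tn <- ncol(data$x)
  mu <- rowMeans(data$x)
  sdv <- apply(data$x, 1, sd)
  x <- matrix(rnorm(N * Tn, mean = mu, sd = sdv), nrow = N, ncol = Tn)
  x[x < 0] <- 0
  cr_series(x, detect = data$detect, taxa_ids = data$taxa_ids,
            meta = list(variant = "null", source = data$meta))
}

#' Consumer-resource-converted gLV time series
#'
#' Convenience pipeline: draws a consumer-resource instance and a
#' fluctuating supply trajectory, converts each sampling time's supply to a
#' gLV parametrization, calibrates the fixed integration duration against
#' the consumer-resource steady state of the first sampling time (unless
#' given), and simulates the gLV series.
#'
#' @param params A \code{"cr_params"} object.
#' @param integrate_time Fixed duration; calibrated when \code{NULL}.
#' @param source \code{"converted"} uses the converted parameters at every
#'   sampling time; \code{"random"} replaces them with one moment-matched
#'   random instance held fixed while the supply-driven fluctuations are
#'   discarded.
#' @param seed Optional seed.
#' @return A \code{"cr_series"} object.
#' @export
simulate_glv_timeseries <- function(params, integrate_time = NULL,
                                    source = c("converted", "random"),
                                    seed = NULL) {
  validate_cr_params(params)
  source <- match.arg(source)
  if (!is.null(seed)) set.seed(seed)
  R <- draw_consumption_matrix(params)
  ybar <- draw_setpoints(params)
  supply <- resource_trajectory(params, ybar)
  glv_list <- lapply(seq_len(params$T), function(t) {
    convert_to_glv(R, supply[, t], params$Rmax)
  })
  if (is.null(integrate_time)) {
    ref <- run_to_steady_state(R, supply[, 1], params)
    integrate_time <- calibrate_glv_time(glv_list[[1]], ref$x)
  }
  if (source == "random") {
    g <- random_glv_from_moments(glv_list)
    glv_list <- rep(list(g), params$T)
  }
  out <- simulate_glv(glv_list, integrate_time, detect = params$detect)
  out$meta$params <- params
  out$meta$source <- source
  out
}
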