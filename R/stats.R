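#' Richness at each sampling time
#'
#' Richness is the number of taxa whose relative abundance exceeds the
#' detection threshold at a sampling time.
#'
#' @param series A \code{"cr_series"} object.
#' @return List with \code{alpha_t} (per-time richness) and \code{alpha_bar}
#'   (its mean).
#' @export
richness <- function(series) {
  series <- as_cr_series(series)
  alpha_t <- colSums(series$present)
  list(alpha_t = as.integer(alpha_t), alpha_bar = mean(alpha_t))
}

#' Taylor's-law fit of temporal variance against mean abundance
#'
#' Ordinary least squares of \code{log10(var_i)} on \code{log10(mean_i)}
#' across taxa, where mean and variance are taken over sampling times with
#' below-detection abundances counted as 0 (set \code{mask_absent = TRUE} to
#' restrict both moments to times when the taxon is present). Only taxa with
#' positive mean and variance enter the regression.
#'
#' @param series A \code{"cr_series"} object.
#' @param mask_absent Compute moments over presence times only.
#' @return List with \code{beta} (slope), \code{intercept}, \code{mean_x},
#'   \code{var_x}, and \code{n_taxa} used.
#' @export
taylor_fit <- function(series, mask_absent = FALSE) {
  series <- as_cr_series(series)
  xd <- thresholded(series)
  if (mask_absent) {
    mean_x <- var_x <- rep(NA_real_, nrow(xd))
    for (i in seq_len(nrow(xd))) {
      v <- series$x[i, series$present[i, ]]
      if (length(v) >= 2) {
        mean_x[i] <- mean(v)
        var_x[i] <- var(v)
      }
    }
  } else {
    mean_x <- rowMeans(xd)
    var_x <- apply(xd, 1, var)
  }
  ok <- is.finite(mean_x) & is.finite(var_x) & mean_x > 0 & var_x > 0
  if (sum(ok) < 2)
    stop("taylor_fit needs at least 2 taxa with positive mean and variance")
  fit <- lm(log10(var_x[ok]) ~ log10(mean_x[ok]))
  list(beta = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       mean_x = mean_x, var_x = var_x, n_taxa = sum(ok))
}

#' Pooled log10 abundance changes between consecutive sampling times
#'
#' For every taxon and every pair of consecutive sampling times at which the
#' taxon is present at both, computes
#' \code{dl = log10(x(t+1) / x(t))} and pools the values over all taxa and
#' times. \code{sigma_dl} is the sample standard deviation of the pool.
#'
#' @param series A \code{"cr_series"} object.
#' @return List with \code{dl_pool} and \code{sigma_dl}.
#' @export
abundance_changes <- function(series) {
  series <- as_cr_series(series)
  x <- series$x
  p <- series$present
  Tn <- ncol(x)
  if (Tn < 2) stop("abundance_changes needs at least 2 sampling times")
  both <- p[, -Tn, drop = FALSE] & p[, -1, drop = FALSE]
  dl <- log10(x[, -1, drop = FALSE] / x[, -Tn, drop = FALSE])
  pool <- dl[both]
  if (!length(pool)) stop("no consecutive presence pairs; empty pool")
  list(dl_pool = as.numeric(pool), sigma_dl = sd(pool))
}

#' Laplace (two-sided exponential) scale of an abundance-change pool
#'
#' The pooled distribution of log10 abundance changes is compared against a
#' two-sided exponential; the maximum-likelihood scale of a Laplace
#' distribution is the mean absolute deviation from the median.
#'
#' @param dl_pool Numeric vector of pooled changes.
#' @return The fitted scale (numeric scalar).
#' @export
fit_exponential_shape <- function(dl_pool) {
  if (!length(dl_pool)) stop("empty pool")
  mean(abs(dl_pool - median(dl_pool)))
}

#' Per-taxon restoring slopes
#'
#' For each taxon, regresses the log10 abundance change
#' \code{dl(t) = l(t+1) - l(t)} on the log10 abundance \code{l(t)} over all
#' consecutive presence pairs. The slope measures reversion to the mean: with
#' memoryless environments it approaches -1, and in general its negative
#' tracks the environmental restoring force.
#'
#' @param series A \code{"cr_series"} object.
#' @param min_points Minimum number of (l, dl) pairs for a taxon to be fit.
#' @return List with \code{s_i} (per-taxon slopes, NA when ineligible) and
#'   \code{s_bar} (mean over eligible taxa).
#' @export
restoring_slopes <- function(series, min_points = 10) {
  series <- as_cr_series(series)
  x <- series$x
  p <- series$present
  Tn <- ncol(x)
  s_i <- rep(NA_real_, nrow(x))
  for (i in seq_len(nrow(x))) {
    use <- p[i, -Tn] & p[i, -1]
    if (sum(use) < min_points) next
    l <- log10(x[i, -Tn][use])
    dl <- log10(x[i, -1][use]) - l
    if (var(l) == 0) next
    s_i[i] <- unname(coef(lm(dl ~ l))[2])
  }
  if (all(is.na(s_i))) stop("no taxon has enough presence pairs to fit")
  list(s_i = s_i, s_bar = mean(s_i, na.rm = TRUE))
}

#' Residence and return times
#'
#' Residence (return) times are the lengths of maximal runs of consecutive
#' presence (absence) of a taxon. Only completed runs -- bounded by a
#' transition on both sides within the observation window -- are pooled;
#' boundary-censored runs are dropped.
#'
#' @param series A \code{"cr_series"} object.
#' @return List with integer vectors \code{t_res} and \code{t_ret}.
#' @export
residence_return_times <- function(series) {
  series <- as_cr_series(series)
  t_res <- integer(0)
  t_ret <- integer(0)
  for (i in seq_len(nrow(series$present))) {
    r <- rle(series$present[i, ])
    n <- length(r$lengths)
    if (n < 3) next
    interior <- 2:(n - 1)
    t_res <- c(t_res, r$lengths[interior][r$values[interior]])
    t_ret <- c(t_ret, r$lengths[interior][!r$values[interior]])
  }
  list(t_res = as.integer(t_res), t_ret = as.integer(t_ret))
}

#' Fit a discrete power law with exponential cutoff to interval lengths
#'
#' Maximum-likelihood fit of \eqn{P(t) \propto t^{\nu} e^{-t/\tau}} over
#' positive integers to a sample of residence or return intervals. The
#' normalizing sum is truncated where it has converged numerically.
#'
#' @param times Integer vector of interval lengths (need >= \code{min_n}).
#' @param min_n Minimum sample size.
#' @return List with \code{nu}, \code{tau}, \code{degenerate} (TRUE when the
#'   sample has no spread and the fit is pinned at the boundary), and
#'   \code{convergence} from the optimizer.
#' @export
fit_powerlaw_cutoff <- function(times, min_n = 20) {
  times <- as.integer(times)
  if (length(times) < min_n)
    stop("need at least ", min_n, " intervals to fit")
  if (any(times < 1)) stop("interval lengths must be positive integers")
  if (length(unique(times)) == 1L) {
    return(list(nu = NA_real_, tau = NA_real_, degenerate = TRUE,
                convergence = NA_integer_))
  }
  t_cap <- max(1000L, 10L * max(times))
  tt <- seq_len(t_cap)
  nll <- function(par) {
    nu <- par[1]
    tau <- exp(par[2])
    logw <- nu * log(tt) - tt / tau
    logZ <- max(logw) + log(sum(exp(logw - max(logw))))
    -(sum(nu * log(times) - times / tau) - length(times) * logZ)
  }
  fit <- optim(c(-1, log(mean(times))), nll, method = "L-BFGS-B",
               lower = c(-6, log(0.1)), upper = c(3, log(1e5)))
  list(nu = fit$par[1], tau = exp(fit$par[2]), degenerate = FALSE,
       convergence = fit$convergence)
}

#' Prevalence, mean abundance, and the rank-abundance distribution
#'
#' Prevalence is the fraction of sampling times at which a taxon is present.
#' Mean abundance is taken over all sampling times with absences counted as
#' 0; the rank-abundance distribution is the mean abundances sorted in
#' decreasing order.
#'
#' @param series A \code{"cr_series"} object.
#' @return List with \code{p_i}, \code{mean_x}, and \code{rank_abund}.
#' @export
prevalence_and_rank <- function(series) {
  series <- as_cr_series(series)
  xd <- thresholded(series)
  p_i <- rowMeans(series$present)
  mean_x <- rowMeans(xd)
  list(p_i = p_i, mean_x = mean_x,
       rank_abund = sort(mean_x, decreasing = TRUE))
}

#' Pairwise abundance correlations across sampling times
#'
#' Pearson correlation of the abundances of every taxon pair over the
#' sampling times at which both are present; pairs sharing fewer than
#' \code{min_shared} such times are skipped.
#'
#' @param series A \code{"cr_series"} object.
#' @param min_shared Minimum number of shared-presence sampling times.
#' @return Numeric vector of pooled correlations.
#' @export
pairwise_correlations <- function(series, min_shared = 10) {
  series <- as_cr_series(series)
  x <- series$x
  p <- series$present
  N <- nrow(x)
  out <- numeric(0)
  if (N < 2) return(out)
  for (i in seq_len(N - 1)) {
    for (j in (i + 1):N) {
      shared <- p[i, ] & p[j, ]
      if (sum(shared) < min_shared) next
      a <- x[i, shared]
      b <- x[j, shared]
      if (sd(a) == 0 || sd(b) == 0) next
      out <- c(out, cor(a, b))
    }
  }
  out
}

#' Shuffle the sampling times of a series
#'
#' Permutes the columns (sampling times) uniformly at random, destroying
#' temporal correlations while leaving every time-order-free statistic
#' (richness, Taylor's law, prevalence, rank abundance) unchanged.
#'
#' @param series A \code{"cr_series"} object.
#' @param perm Optional permutation of \code{1:T} to apply instead of a
#'   random one (e.g. to undo a recorded shuffle).
#' @return A \code{"cr_series"} with permuted columns; the permutation used
#'   is stored in \code{meta$permutation}.
#' @export
shuffle_times <- function(series, perm = NULL) {
  series <- as_cr_series(series)
  Tn <- ncol(series$x)
  if (is.null(perm)) perm <- sample.int(Tn)
  stopifnot(length(perm) == Tn, all(sort(perm) == seq_len(Tn)))
  meta <- series$meta
  meta$permutation <- perm
  cr_series(series$x[, perm, drop = FALSE], detect = series$detect,
            taxa_ids = series$taxa_ids, meta = meta)
}

#' Compute the full set of macroecological summary statistics
#'
#' Convenience wrapper producing all time-series statistics of a series:
#' richness, the Taylor's-law fit, pooled abundance changes with their
#' standard deviation and Laplace scale, restoring slopes, residence/return
#' intervals with power-law-cutoff fits, prevalence, mean abundance and the
#' rank-abundance distribution, and (optionally) pooled pairwise
#' correlations. Statistics that cannot be computed on a degenerate series
#' are returned as NA rather than failing.
#'
#' @param series A \code{"cr_series"} object.
#' @param pools Keep the pooled vectors (abundance changes, intervals,
#'   correlations) in the result; set \code{FALSE} for scalars only (as used
#'   in parameter scans).
#' @param correlations Also compute pairwise correlations (quadratic in the
#'   number of taxa).
#' @return An object of class \code{"cr_stats"}: a list of named statistics.
#' @export
summary_stats <- function(series, pools = TRUE, correlations = FALSE) {
  series <- as_cr_series(series)
  rich <- richness(series)
  out <- list(alpha_t = rich$alpha_t, alpha_bar = rich$alpha_bar,
              beta = NA_real_, taylor_intercept = NA_real_,
              sigma_dl = NA_real_, laplace_scale = NA_real_,
              s_bar = NA_real_, nu_res = NA_real_, tau_res = NA_real_,
              nu_ret = NA_real_, tau_ret = NA_real_)
  ty <- tryCatch(taylor_fit(series), error = function(e) NULL)
  if (!is.null(ty)) {
    out$beta <- ty$beta
    out$taylor_intercept <- ty$intercept
    out$mean_x <- ty$mean_x
    out$var_x <- ty$var_x
  }
  ch <- tryCatch(abundance_changes(series), error = function(e) NULL)
  if (!is.null(ch)) {
    out$sigma_dl <- ch$sigma_dl
    out$laplace_scale <- fit_exponential_shape(ch$dl_pool)
    if (pools) out$dl_pool <- ch$dl_pool
  }
  rs <- tryCatch(restoring_slopes(series), error = function(e) NULL)
  if (!is.null(rs)) {
    out$s_i <- rs$s_i
    out$s_bar <- rs$s_bar
  }
  iv <- residence_return_times(series)
  if (pools) {
    out$t_res <- iv$t_res
    out$t_ret <- iv$t_ret
  }
  fr <- tryCatch(fit_powerlaw_cutoff(iv$t_res), error = function(e) NULL)
  if (!is.null(fr) && !fr$degenerate) {
    out$nu_res <- fr$nu
    out$tau_res <- fr$tau
  }
  ft <- tryCatch(fit_powerlaw_cutoff(iv$t_ret), error = function(e) NULL)
  if (!is.null(ft) && !ft$degenerate) {
    out$nu_ret <- ft$nu
    out$tau_ret <- ft$tau
  }
  pr <- prevalence_and_rank(series)
  out$p_i <- pr$p_i
  out$mean_abund <- pr$mean_x
  out$rank_abund <- pr$rank_abund
  if (correlations) out$corr_pool <- pairwise_correlations(series)
  if (!pools) out$alpha_t <- NULL
  class(out) <- "cr_stats"
  out
}

#' @export
print.cr_stats <- function(x, ...) {
  cat("Macroecological summary statistics\n")
  cat(sprintf("  mean richness        alpha_bar = %.3g\n", x$alpha_bar))
  cat(sprintf("  Taylor exponent      beta      = %.3g\n", x$beta))
  cat(sprintf("  SD of log10 changes  sigma_dl  = %.3g\n", x$sigma_dl))
  cat(sprintf("  mean restoring slope s_bar     = %.3g\n", x$s_bar))
  invisible(x)
}

#' Export a histogram of pooled values as TSV
#'
#' Writes a two-column (value, count) table, e.g. for a pooled
#' abundance-change or interval distribution.
#'
#' @param values Numeric vector to tabulate.
#' @param path Output path.
#' @param breaks Passed to [graphics::hist()] binning via [cut()]; integer
#'   values are tabulated exactly when \code{breaks = NULL}.
#' @export
write_histogram_tsv <- function(values, path, breaks = NULL) {
  if (is.null(breaks)) {
    tab <- table(values)
    out <- data.frame(value = as.numeric(names(tab)),
                      count = as.integer(tab))
  } else {
    cuts <- cut(values, breaks = breaks)
    tab <- table(cuts)
    mids <- vapply(strsplit(gsub("[][()]", "", names(tab)), ","),
                   function(v) mean(as.numeric(v)), numeric(1))
    out <- data.frame(value = mids, count = as.integer(tab))
  }
  write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Serialize summary statistics to JSON
#'
#' Writes the scalar statistics (and, when present, the pooled vectors) of a
#' \code{"cr_stats"} object as a flat JSON document with stable field names.
#'
#' @param stats A \code{"cr_stats"} object.
#' @param path Output file; when \code{NULL} the JSON string is returned.
#' @param pools Include pooled vectors.
#' @return The JSON string, invisibly when written to a file.
#' @export
write_stats_json <- function(stats, path = NULL, pools = FALSE) {
  keep <- c("alpha_bar", "beta", "taylor_intercept", "sigma_dl",
            "laplace_scale", "s_bar", "nu_res", "tau_res", "nu_ret",
            "tau_ret")
  if (pools) keep <- c(keep, "dl_pool", "t_res", "t_ret", "p_i", "corr_pool")
  doc <- stats[intersect(keep, names(stats))]
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA, na = "null")
  if (is.null(path)) return(json)
  writeLines(json, path)
  invisible(json)
}
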