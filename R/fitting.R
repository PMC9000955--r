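# Grid-search fitting of ensemble parameters to summary statistics, and
# susceptibility analysis of the statistics to the parameters.

FIT_STATS <- c("alpha_bar", "beta", "sigma_dl", "s_bar")
SCAN_AXES <- c("M", "S", "sigma", "k")

#' Scan a grid of ensemble parameters
#'
#' Simulates \code{n_instances} replicate instances at every point of a grid
#' over (a subset of) the ensemble parameters \code{M}, \code{S},
#' \code{sigma} and \code{k}, with all other parameters taken from
#' \code{params}, and records the replicate mean and standard deviation of
#' each summary statistic. Failed grid points are recorded with
#' \code{ok = FALSE} and the scan continues.
#'
#' @param params Base \code{"cr_params"} object (fixes \code{N}, \code{T},
#'   constants, and any axis not scanned).
#' @param axes Named list of grid values, names among \code{M}, \code{S},
#'   \code{sigma}, \code{k}.
#' @param n_instances Replicate instances per grid point; defaults to
#'   \code{params$n_instances}.
#' @param variant Model variant passed to [simulate_timeseries()].
#' @param stats Character vector of scalar statistics to record.
#' @param seed Master seed for the scan.
#' @param checkpoint Optional TSV path; completed rows are appended as the
#'   scan runs, and on restart rows already present are not recomputed.
#' @return A data frame of class \code{"cr_scan"}: one row per grid point
#'   with the parameter values, \code{<stat>_mean} and \code{<stat>_sd}
#'   columns, a validity flag \code{ok}, and \code{note}.
#' @export
scan_grid <- function(params, axes, n_instances = NULL,
                      variant = "linear", stats = FIT_STATS,
                      seed = NULL, checkpoint = NULL) {
  validate_cr_params(params)
  stopifnot(length(axes) >= 1, all(names(axes) %in% SCAN_AXES),
            all(lengths(axes) >= 1))
  if (is.null(n_instances)) n_instances <- params$n_instances
  if (is.null(seed)) seed <- params$seed
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max - 1L, 1)

  grid <- expand.grid(axes, KEEP.OUT.ATTRS = FALSE)
  for (ax in setdiff(SCAN_AXES, names(axes))) grid[[ax]] <- params[[ax]]
  grid <- grid[, SCAN_AXES]
  seeds <- split_seed(seed, nrow(grid))

  stat_cols <- c(rbind(paste0(stats, "_mean"), paste0(stats, "_sd")))
  done <- NULL
  if (!is.null(checkpoint) && file.exists(checkpoint)) {
    done <- read.delim(checkpoint, sep = "\t", check.names = FALSE)
  }
  rows <- vector("list", nrow(grid))
  for (g in seq_len(nrow(grid))) {
    pt <- grid[g, ]
    if (!is.null(done)) {
      hit <- which(abs(done$M - pt$M) < 1e-12 & abs(done$S - pt$S) < 1e-12 &
                   abs(done$sigma - pt$sigma) < 1e-12 &
                   abs(done$k - pt$k) < 1e-12)
      if (length(hit)) {
        rows[[g]] <- done[hit[1], c(SCAN_AXES, stat_cols, "ok", "note")]
        next
      }
    }
    p_g <- params
    p_g$M <- as.integer(pt$M)
    p_g$S <- pt$S
    p_g$sigma <- pt$sigma
    p_g$k <- pt$k
    row <- as.list(pt)
    res <- tryCatch({
      reps <- simulate_replicates(p_g, variant, n_instances, seed = seeds[g])
      vals <- vapply(reps, function(s) {
        st <- summary_stats(s, pools = FALSE)
        vapply(stats, function(z) as.numeric(st[[z]]), numeric(1))
      }, numeric(length(stats)))
      vals <- matrix(vals, nrow = length(stats))
      for (z in seq_along(stats)) {
        row[[paste0(stats[z], "_mean")]] <- mean(vals[z, ], na.rm = TRUE)
        row[[paste0(stats[z], "_sd")]] <- sd(vals[z, ])
      }
      row$ok <- TRUE
      row$note <- ""
      row
    }, error = function(e) {
      for (col in stat_cols) row[[col]] <- NA_real_
      row$ok <- FALSE
      row$note <- conditionMessage(e)
      row
    })
    rows[[g]] <- as.data.frame(res, stringsAsFactors = FALSE)
    if (!is.null(checkpoint)) {
      write.table(rows[[g]], checkpoint, sep = "\t", row.names = FALSE,
                  col.names = !file.exists(checkpoint), append = file.exists(checkpoint),
                  quote = FALSE)
    }
  }
  scan <- do.call(rbind, rows)
  rownames(scan) <- NULL
  attr(scan, "stats") <- stats
  attr(scan, "N") <- params$N
  class(scan) <- c("cr_scan", "data.frame")
  scan
}

#' Write or read a scan table as TSV
#'
#' @param scan A \code{"cr_scan"} data frame.
#' @param path Output path.
#' @return \code{read_scan} returns a \code{"cr_scan"} data frame.
#' @export
write_scan <- function(scan, path) {
  write.table(scan, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_scan
#' @export
read_scan <- function(path) {
  scan <- read.delim(path, sep = "\t", check.names = FALSE)
  mean_cols <- grep("_mean$", names(scan), value = TRUE)
  attr(scan, "stats") <- sub("_mean$", "", mean_cols)
  class(scan) <- c("cr_scan", "data.frame")
  scan
}

stat_value <- function(stats_obj, z) {
  v <- stats_obj[[z]]
  if (is.null(v)) stop("statistic '", z, "' missing from stats object")
  as.numeric(v)
}

#' Scan-wide standard deviations of summary statistics
#'
#' The SD of each statistic's replicate mean across all valid rows of a scan
#' table; the common normalization for [fit_error()] and the
#' susceptibilities.
#'
#' @param scan A \code{"cr_scan"} table.
#' @param stats Statistic names.
#' @return Named numeric vector of SDs.
#' @export
scan_sds <- function(scan, stats = FIT_STATS) {
  ok <- if ("ok" %in% names(scan)) as.logical(scan$ok) else rep(TRUE, nrow(scan))
  sds <- vapply(stats, function(z) {
    v <- scan[[paste0(z, "_mean")]][ok]
    sd(v, na.rm = TRUE)
  }, numeric(1))
  if (any(!is.finite(sds)) || any(sds == 0))
    stop("degenerate scan: zero or undefined SD for some statistic")
  sds
}

#' Model-data error over the four fitted statistics
#'
#' The fitting error between a model's and a dataset's summary statistics is
#' the sum over the fitted statistics (by default mean richness, Taylor
#' exponent, SD of log10 abundance changes, and mean restoring slope) of the
#' absolute difference normalized by the standard deviation of that
#' statistic across the whole scan table, which serves as the common
#' normalization reference.
#'
#' @param model_stats,data_stats \code{"cr_stats"} objects (or named lists)
#'   containing the fitted statistics.
#' @param scan A \code{"cr_scan"} table used for normalization.
#' @param stats Statistics entering the error.
#' @param norm_sds Optional named vector of normalization SDs overriding the
#'   ones computed from \code{scan} (e.g. SDs from a full parameter scan
#'   when fitting along a single axis).
#' @return The scalar error.
#' @export
fit_error <- function(model_stats, data_stats, scan, stats = FIT_STATS,
                      norm_sds = NULL) {
  sds <- if (is.null(norm_sds)) scan_sds(scan, stats) else norm_sds[stats]
  sum(vapply(stats, function(z) {
    abs(stat_value(model_stats, z) - stat_value(data_stats, z)) / sds[[z]]
  }, numeric(1)))
}

#' Best-fit ensemble parameters from a scan
#'
#' Returns the grid point minimizing [fit_error()] against the data, plus
#' per-parameter estimation bounds: along each scanned axis through the best
#' point (other parameters held at their best-fit values), the error profile
#' is interpolated piecewise-linearly and the bound is where the error
#' exceeds the best error by 5 percent of the mean error across the whole
#' scan (clipped at the scanned range).
#'
#' @param scan A \code{"cr_scan"} table.
#' @param data_stats \code{"cr_stats"} (or named list) for the data.
#' @param stats Statistics entering the error.
#' @param bound_frac Error increase defining the bounds, as a fraction of
#'   the scan-mean error.
#' @param norm_sds Optional named vector of normalization SDs (see
#'   [fit_error()]).
#' @return An object of class \code{"cr_fit"}: list with \code{best} (named
#'   parameter vector), \code{error}, \code{bounds} (per-axis c(lo, hi)),
#'   and \code{errors} (per-row errors aligned with the scan).
#' @export
best_fit <- function(scan, data_stats, stats = FIT_STATS, bound_frac = 0.05,
                     norm_sds = NULL) {
  ok <- if ("ok" %in% names(scan)) as.logical(scan$ok) else rep(TRUE, nrow(scan))
  if (!any(ok)) stop("no valid rows in scan")
  sds <- if (is.null(norm_sds)) scan_sds(scan, stats) else norm_sds[stats]
  errs <- rep(NA_real_, nrow(scan))
  for (r in which(ok)) {
    errs[r] <- sum(vapply(stats, function(z) {
      abs(scan[[paste0(z, "_mean")]][r] - stat_value(data_stats, z)) / sds[[z]]
    }, numeric(1)))
  }
  best_row <- which.min(errs)
  best <- unlist(scan[best_row, SCAN_AXES])
  thr <- errs[best_row] + bound_frac * mean(errs, na.rm = TRUE)

  bounds <- list()
  for (ax in SCAN_AXES) {
    others <- setdiff(SCAN_AXES, ax)
    on_axis <- ok
    for (o in others) on_axis <- on_axis & abs(scan[[o]] - best[[o]]) < 1e-12
    w <- scan[[ax]][on_axis]
    e <- errs[on_axis]
    o <- order(w)
    w <- w[o]
    e <- e[o]
    if (length(w) < 2) {
      bounds[[ax]] <- c(best[[ax]], best[[ax]])
      next
    }
    bi <- which.min(abs(w - best[[ax]]))
    lo <- w[1]
    i <- bi
    while (i > 1 && e[i - 1] <= thr) i <- i - 1
    if (i > 1) {
      f <- (thr - e[i]) / (e[i - 1] - e[i])
      lo <- w[i] + f * (w[i - 1] - w[i])
    }
    hi <- w[length(w)]
    i <- bi
    while (i < length(w) && e[i + 1] <= thr) i <- i + 1
    if (i < length(w)) {
      f <- (thr - e[i]) / (e[i + 1] - e[i])
      hi <- w[i] + f * (w[i + 1] - w[i])
    }
    bounds[[ax]] <- c(lo, hi)
  }
  structure(list(best = best, error = errs[best_row], bounds = bounds,
                 errors = errs, threshold = thr),
            class = "cr_fit")
}

#' @export
print.cr_fit <- function(x, ...) {
  cat("Best-fit ensemble parameters\n")
  for (ax in names(x$bounds)) {
    cat(sprintf("  %-6s = %-8g [%g, %g]\n", ax, x$best[[ax]],
                x$bounds[[ax]][1], x$bounds[[ax]][2]))
  }
  cat(sprintf("  error = %g\n", x$error))
  invisible(x)
}

susceptibility_core <- function(scan, z, w, rows_use) {
  zcol <- paste0(z, "_mean")
  if (!zcol %in% names(scan)) zcol <- z
  if (!zcol %in% names(scan)) stop("statistic '", z, "' not in scan")
  flip <- FALSE
  axis <- w
  if (w %in% c("N/M", "N_over_M", "NoverM")) {
    axis <- "M"
    flip <- TRUE  # largest N/M corresponds to smallest M
  }
  if (!axis %in% SCAN_AXES) stop("unknown parameter axis '", w, "'")
  ok <- if ("ok" %in% names(scan)) as.logical(scan$ok) else rep(TRUE, nrow(scan))
  ok <- ok & is.finite(scan[[zcol]])
  sub <- scan[ok & rows_use, , drop = FALSE]
  levels_w <- sort(unique(sub[[axis]]))
  if (length(levels_w) < 2) stop("axis '", w, "' has fewer than 2 levels")
  w_lo <- levels_w[1]
  w_hi <- levels_w[length(levels_w)]
  if (flip) {
    tmp <- w_lo
    w_lo <- w_hi
    w_hi <- tmp
  }
  others <- setdiff(SCAN_AXES, axis)
  key <- interaction(sub[others], drop = TRUE)
  deltas <- tapply(seq_len(nrow(sub)), key, function(idx) {
    zi <- sub[[zcol]][idx]
    wi <- sub[[axis]][idx]
    hi <- which(wi == w_hi)
    lo <- which(wi == w_lo)
    if (!length(hi) || !length(lo)) return(NA_real_)
    mean(zi[hi]) - mean(zi[lo])
  })
  sd_z <- sd(scan[[zcol]][ok], na.rm = TRUE)
  if (!is.finite(sd_z) || sd_z == 0) stop("degenerate SD of statistic '", z, "'")
  C <- mean(deltas, na.rm = TRUE) / sd_z
  structure(list(z = z, w = w, C = C), class = "cr_susceptibility")
}

#' Global susceptibility of a statistic to an ensemble parameter
#'
#' The global susceptibility \code{C(z, w)} is the change in statistic
#' \code{z} as parameter \code{w} goes from its smallest to its largest
#' scanned value, averaged over all combinations of the other parameters and
#' normalized by the standard deviation of \code{z} across the entire scan.
#' By this normalization \code{|C|} is at most about 3; a magnitude above 2
#' means that \code{w} dominates the variance of \code{z}. For the resource
#' axis pass \code{w = "N/M"}: the susceptibility is then reported with
#' respect to the ratio N/M, whose largest value corresponds to the smallest
#' scanned M.
#'
#' @param scan A \code{"cr_scan"} table.
#' @param z Statistic name (e.g. \code{"s_bar"}).
#' @param w Parameter name: \code{"M"}, \code{"S"}, \code{"sigma"},
#'   \code{"k"}, or \code{"N/M"}.
#' @return An object of class \code{"cr_susceptibility"} with fields
#'   \code{z}, \code{w}, \code{C}.
#' @export
global_susceptibility <- function(scan, z, w) {
  susceptibility_core(scan, z, w, rep(TRUE, nrow(scan)))
}

#' Local susceptibility around a best fit
#'
#' Same endpoint-difference formula as [global_susceptibility()], but with
#' all parameters other than \code{w} fixed at their best-fit values; the
#' normalization remains the scan-wide standard deviation of \code{z}.
#'
#' @param scan A \code{"cr_scan"} table.
#' @param best A \code{"cr_fit"} object (or named list with the axis values).
#' @inheritParams global_susceptibility
#' @export
local_susceptibility <- function(scan, best, z, w) {
  bp <- if (inherits(best, "cr_fit")) best$best else unlist(best)
  axis <- if (w %in% c("N/M", "N_over_M", "NoverM")) "M" else w
  rows_use <- rep(TRUE, nrow(scan))
  for (o in setdiff(SCAN_AXES, axis))
    rows_use <- rows_use & abs(scan[[o]] - bp[[o]]) < 1e-12
  susceptibility_core(scan, z, w, rows_use)
}

#' @export
print.cr_susceptibility <- function(x, ...) {
  cat(sprintf("Susceptibility C(%s, %s) = %.3g\n", x$z, x$w, x$C))
  invisible(x)
}
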