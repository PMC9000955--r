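# Helpers to build small synthetic scan tables without simulation.
fake_scan <- function(grid, values) {
  scan <- grid
  for (z in names(values)) {
    scan[[paste0(z, "_mean")]] <- values[[z]]
    scan[[paste0(z, "_sd")]] <- 0
  }
  scan$ok <- TRUE
  scan$note <- ""
  attr(scan, "stats") <- names(values)
  class(scan) <- c("cr_scan", "data.frame")
  scan
}

full_grid <- function(M = 30, S = 0.1, sigma = 0.2, k = 0.8) {
  expand.grid(M = M, S = S, sigma = sigma, k = k, KEEP.OUT.ATTRS = FALSE)
}

test_that("fit error is zero at equality, symmetric, and additive", {
  grid <- full_grid(k = c(0.2, 0.5, 0.8, 1.0))
  scan <- fake_scan(grid, list(alpha_bar = c(10, 12, 14, 16),
                               beta = c(1.2, 1.4, 1.5, 1.6),
                               sigma_dl = c(0.2, 0.3, 0.4, 0.5),
                               s_bar = c(-0.2, -0.5, -0.8, -1.0)))
  a <- list(alpha_bar = 10, beta = 1.2, sigma_dl = 0.2, s_bar = -0.2)
  b <- list(alpha_bar = 12, beta = 1.4, sigma_dl = 0.3, s_bar = -0.5)
  expect_equal(fit_error(a, a, scan), 0)
  expect_equal(fit_error(a, b, scan), fit_error(b, a, scan))

  # hand-computed on a 2-row toy
  grid2 <- full_grid(k = c(0.2, 1.0))
  scan2 <- fake_scan(grid2, list(alpha_bar = c(10, 20), beta = c(1, 2),
                                 sigma_dl = c(0.2, 0.4), s_bar = c(-0.2, -1)))
  m <- list(alpha_bar = 10, beta = 1, sigma_dl = 0.2, s_bar = -0.2)
  d <- list(alpha_bar = 20, beta = 2, sigma_dl = 0.4, s_bar = -1)
  manual <- abs(10 - 20) / sd(c(10, 20)) + abs(1 - 2) / sd(c(1, 2)) +
    abs(0.2 - 0.4) / sd(c(0.2, 0.4)) + abs(-0.2 + 1) / sd(c(-0.2, -1))
  expect_equal(fit_error(m, d, scan2), manual)

  # degenerate normalization
  scan3 <- fake_scan(grid2, list(alpha_bar = c(10, 10), beta = c(1, 2),
                                 sigma_dl = c(0.2, 0.4), s_bar = c(-0.2, -1)))
  expect_error(fit_error(m, d, scan3), "degenerate")
})

test_that("best_fit returns the zero-error row with bounds containing it", {
  grid <- full_grid(S = c(0.1, 0.5, 0.9), k = c(0.2, 0.6, 1.0))
  scan <- fake_scan(grid, list(
    alpha_bar = 10 + 5 * grid$S,
    beta = 2 - grid$S,
    sigma_dl = 0.2 + 0.1 * grid$k,
    s_bar = -grid$k))
  data <- list(alpha_bar = 10 + 5 * 0.5, beta = 1.5, sigma_dl = 0.26,
               s_bar = -0.6)
  fit <- best_fit(scan, data)
  expect_equal(unname(fit$best[["S"]]), 0.5)
  expect_equal(unname(fit$best[["k"]]), 0.6)
  expect_equal(fit$error, 0)
  for (ax in c("S", "k")) {
    expect_lte(fit$bounds[[ax]][1], fit$best[[ax]])
    expect_gte(fit$bounds[[ax]][2], fit$best[[ax]])
    expect_gt(diff(fit$bounds[[ax]]), 0)  # nonzero bounds
  }
  # fixed axes collapse to a point
  expect_equal(fit$bounds$M, c(30, 30))
})

test_that("susceptibility matches the closed form for z = w", {
  k_levels <- c(0.2, 0.4, 0.6, 0.8, 1.0)
  grid <- full_grid(S = c(0.1, 0.9), k = k_levels)
  scan <- fake_scan(grid, list(s_bar = -grid$k, beta = rep(1.5, nrow(grid)),
                               alpha_bar = grid$k, sigma_dl = grid$S))
  # z = k exactly: C = (k_max - k_min) / sd(z over all rows)
  out <- global_susceptibility(scan, "alpha_bar", "k")
  expect_equal(out$C, (1.0 - 0.2) / sd(rep(k_levels, each = 2)))
  # z independent of w
  expect_error(global_susceptibility(scan, "beta", "k"), "degenerate")
  expect_equal(global_susceptibility(scan, "sigma_dl", "k")$C, 0)
  # sign flip under the N/M convention: z increasing in M gives negative C
  grid2 <- full_grid(M = c(10, 50, 250), k = c(0.2, 1))
  scan2 <- fake_scan(grid2, list(alpha_bar = log(grid2$M),
                                 beta = grid2$k, sigma_dl = grid2$M,
                                 s_bar = -grid2$k))
  expect_lt(global_susceptibility(scan2, "alpha_bar", "N/M")$C, 0)
  expect_gt(global_susceptibility(scan2, "alpha_bar", "M")$C, 0)
})

test_that("local susceptibility coincides with global on singleton other axes", {
  k_levels <- c(0.2, 0.6, 1.0)
  grid <- full_grid(k = k_levels)
  scan <- fake_scan(grid, list(s_bar = -grid$k, beta = 1 + grid$k,
                               alpha_bar = 2 * grid$k, sigma_dl = 3 * grid$k))
  best <- list(M = 30, S = 0.1, sigma = 0.2, k = 0.6)
  g <- global_susceptibility(scan, "s_bar", "k")
  l <- local_susceptibility(scan, best, "s_bar", "k")
  expect_equal(l$C, g$C)
})

test_that("scan_grid records replicate statistics and checkpoints rows", {
  p <- tiny_params(T = 25)
  path <- withr::local_tempfile(fileext = ".tsv")
  scan <- scan_grid(p, axes = list(k = c(0.5, 1.0)), n_instances = 2,
                    seed = 71, checkpoint = path)
  expect_s3_class(scan, "cr_scan")
  expect_equal(nrow(scan), 2)
  expect_true(all(scan$ok))
  expect_true(all(is.finite(scan$alpha_bar_mean)))
  expect_equal(scan$M, c(6, 6))

  # resuming from the checkpoint reproduces the table without recomputation
  t0 <- Sys.time()
  again <- scan_grid(p, axes = list(k = c(0.5, 1.0)), n_instances = 2,
                     seed = 71, checkpoint = path)
  expect_lt(as.numeric(Sys.time() - t0, units = "secs"), 1)
  expect_equal(again$alpha_bar_mean, scan$alpha_bar_mean)

  # round trip through TSV
  path2 <- withr::local_tempfile(fileext = ".tsv")
  write_scan(scan, path2)
  back <- read_scan(path2)
  expect_equal(back$s_bar_mean, scan$s_bar_mean)
})
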