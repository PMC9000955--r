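test_that("richness counts taxa above the detection threshold", {
  s <- toy_series()
  out <- richness(s)
  expect_equal(out$alpha_t, c(3L, 3L, 3L, 2L, 2L, 2L))
  expect_equal(out$alpha_bar, 2.5)

  # constructed column with exactly 3 of 5 entries above 1e-4
  x <- matrix(c(0.5, 0.3, 2e-4, 5e-5, 1e-6), ncol = 1)
  expect_equal(richness(cr_series(x))$alpha_bar, 3)
  # empty column
  x0 <- matrix(rep(1e-6, 5), ncol = 1)
  expect_equal(richness(cr_series(x0))$alpha_bar, 0)
})

test_that("Taylor fit recovers hand-computed slopes", {
  # each taxon alternates {0, 2 m_i} over two times: var = 2 m_i^2 -> slope 2
  m <- c(0.05, 0.1, 0.2, 0.4)
  x <- cbind(0 * m, 2 * m)
  out <- taylor_fit(cr_series(x, detect = 1e-9))
  expect_equal(out$beta, 2, tolerance = 1e-10)
  expect_equal(out$intercept, log10(2), tolerance = 1e-10)

  # Poisson-like toy: var proportional to mean -> slope ~ 1
  set.seed(41)
  lambda <- 10 ^ seq(0.7, 2.7, length.out = 30)
  xp <- t(sapply(lambda, function(l) rpois(400, l) / 1000))
  outp <- taylor_fit(cr_series(xp, detect = 1e-9))
  expect_equal(outp$beta, 1, tolerance = 0.1)

  # fewer than 2 usable taxa
  expect_error(taylor_fit(cr_series(matrix(c(1, 1), 1, 2))), "at least 2")
})

test_that("abundance changes pool presence-bounded log10 ratios", {
  x <- rbind(c(1e-3, 1e-2, 1e-2),   # dl = 1 then 0
             c(0.5, 0.5, 5e-5))     # second pair has an absent endpoint
  out <- abundance_changes(cr_series(x))
  expect_equal(sort(out$dl_pool), c(0, 0, 1))
  expect_equal(out$sigma_dl, sd(c(1, 0, 0)))

  const <- cr_series(matrix(0.5, 2, 4))
  outc <- abundance_changes(const)
  expect_true(all(outc$dl_pool == 0))
  expect_equal(outc$sigma_dl, 0)

  # all-absent series has an empty pool
  expect_error(abundance_changes(cr_series(matrix(1e-6, 2, 4))), "empty pool")
})

test_that("Laplace scale is the MAD about the median and is consistent", {
  expect_equal(fit_exponential_shape(c(-0.3, 0.3)), 0.3)
  expect_equal(fit_exponential_shape(rep(0, 10)), 0)
  set.seed(42)
  smp <- rexp(20000, rate = 1 / 0.3) * sample(c(-1, 1), 20000, replace = TRUE)
  expect_equal(fit_exponential_shape(smp), 0.3, tolerance = 0.02)
})

test_that("restoring slopes match two-point algebra and the memoryless limit", {
  # log-abundance alternating between two levels: slope is exactly -2
  x <- matrix(rep(c(1e-3, 1e-2), 11)[1:21], nrow = 1)
  out <- restoring_slopes(cr_series(x))
  expect_equal(out$s_i[1], -2, tolerance = 1e-9)

  # i.i.d. log-abundance: regression-to-the-mean slope -1
  set.seed(43)
  xw <- matrix(10 ^ rnorm(2000, -2, 0.3), nrow = 1)
  outw <- restoring_slopes(cr_series(xw))
  expect_equal(outw$s_i[1], -1, tolerance = 0.1)

  # too few presence pairs
  expect_error(restoring_slopes(cr_series(matrix(0.5, 1, 5))), "enough")
})

test_that("residence and return times keep only interior runs", {
  mk <- function(p) cr_series(matrix(ifelse(p, 0.5, 0), nrow = 1))
  out <- residence_return_times(mk(c(FALSE, TRUE, TRUE, FALSE, TRUE)))
  expect_equal(out$t_res, 2L)
  expect_equal(out$t_ret, 1L)

  # always-present taxon contributes nothing
  out2 <- residence_return_times(mk(rep(TRUE, 6)))
  expect_length(out2$t_res, 0)
  expect_length(out2$t_ret, 0)

  # alternating presence: all interior runs have length 1
  out3 <- residence_return_times(mk(rep(c(TRUE, FALSE), 10)))
  expect_true(all(out3$t_res == 1L))
  expect_true(all(out3$t_ret == 1L))
})

test_that("power-law-with-cutoff MLE recovers generating parameters", {
  set.seed(44)
  tt <- 1:500
  # pure exponential special case (nu = 0, tau = 5)
  s1 <- sample(tt, 5000, replace = TRUE, prob = exp(-tt / 5))
  f1 <- fit_powerlaw_cutoff(s1)
  expect_equal(f1$nu, 0, tolerance = 0.2)
  expect_equal(f1$tau, 5, tolerance = 0.2 * 5)
  # power law with cutoff (nu = -1.5, tau = 20)
  s2 <- sample(tt, 5000, replace = TRUE, prob = tt ^ (-1.5) * exp(-tt / 20))
  f2 <- fit_powerlaw_cutoff(s2)
  expect_equal(f2$nu, -1.5, tolerance = 0.15)
  expect_equal(f2$tau, 20, tolerance = 0.2 * 20)
  # degenerate sample pinned and flagged
  f3 <- fit_powerlaw_cutoff(rep(4L, 30))
  expect_true(f3$degenerate)
  expect_error(fit_powerlaw_cutoff(1:5), "at least")
})

test_that("prevalence and rank abundance follow their definitions", {
  s <- toy_series()
  out <- prevalence_and_rank(s)
  expect_equal(unname(out$p_i), c(1, 1, 0.5))
  expect_equal(unname(out$mean_x[3]), mean(c(0.01, 0.01, 0.01, 0, 0, 0)))
  expect_equal(out$rank_abund, sort(out$mean_x, decreasing = TRUE))

  # a taxon present 50 of 100 times
  x <- matrix(c(rep(0.5, 50), rep(1e-6, 50)), nrow = 1)
  x <- rbind(x, 0.5)
  expect_equal(unname(prevalence_and_rank(cr_series(x))$p_i[1]), 0.5)
})

test_that("pairwise correlations hit the exact limits", {
  base <- runif(30, 0.1, 0.5)
  dup <- rbind(base, base)
  expect_equal(pairwise_correlations(cr_series(dup)), 1)
  anti <- rbind(base, 0.6 - base)
  expect_equal(pairwise_correlations(cr_series(anti)), -1)
  # pairs without enough shared presence are skipped
  sparse <- rbind(c(rep(0.5, 5), rep(1e-6, 25)), rep(0.5, 30))
  expect_length(pairwise_correlations(cr_series(sparse)), 0)
})

test_that("shuffling preserves order-free statistics and is invertible", {
  sim <- cached_bestfit_sim()
  set.seed(45)
  sh <- shuffle_times(sim)
  expect_equal(richness(sh)$alpha_bar, richness(sim)$alpha_bar)
  expect_equal(taylor_fit(sh)$beta, taylor_fit(sim)$beta)
  back <- shuffle_times(sh, perm = order(sh$meta$permutation))
  expect_identical(back$x, sim$x)
})

test_that("shuffled series lose temporal structure in the restoring slope", {
  sim <- cached_bestfit_sim()  # generated at k = 0.8
  s0 <- restoring_slopes(sim)$s_bar
  expect_equal(-s0, 0.8, tolerance = 0.15)
  set.seed(46)
  sh <- shuffle_times(sim)
  expect_equal(restoring_slopes(sh)$s_bar, -1, tolerance = 0.15)
})

test_that("summary_stats aggregates the statistic set and serializes", {
  sim <- cached_bestfit_sim()
  st <- summary_stats(sim, correlations = TRUE)
  expect_s3_class(st, "cr_stats")
  expect_true(all(c("alpha_bar", "beta", "sigma_dl", "s_bar", "nu_res",
                    "tau_ret", "p_i", "corr_pool") %in% names(st)))
  expect_true(all(st$corr_pool >= -1 & st$corr_pool <= 1))
  json <- write_stats_json(st)
  parsed <- jsonlite::fromJSON(json)
  expect_equal(parsed$beta, st$beta)
  expect_equal(parsed$s_bar, st$s_bar)
})
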