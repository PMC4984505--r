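test_that("Nem arithmetic is exact", {
  run0 <- list(theta_mode = c(1, 2), m_mode = matrix(0, 2, 2))
  expect_equal(effective_migrants(run0), matrix(0, 2, 2))

  # unit case: theta = 4, M = 1 -> one effective migrant
  run1 <- list(theta_mode = c(4, 4),
               m_mode = matrix(c(0, 1, 1, 0), 2, 2))
  expect_equal(effective_migrants(run1)[2, 1], 1)

  # inversion of a published-scale entry: M = 19.667 into a deme of
  # theta = 4.2 gives ~20.65 migrants
  run2 <- list(theta_mode = c(1, 4.2),
               m_mode = matrix(c(0, 19.667, 0, 0), 2, 2,
                               byrow = TRUE))
  expect_equal(effective_migrants(run2)[1, 2], 19.667 * 4.2 / 4,
               tolerance = 1e-12)
  expect_equal(effective_migrants(run2)[1, 2], 20.65, tolerance = 1e-3)
})

test_that("ladder transition probabilities match a series expansion", {
  lad <- matriflow:::ladder_setup(c(48, 52), buffer = 4)
  K <- lad$K
  Q <- matrix(0, K, K)
  for (i in seq_len(K - 1)) Q[i, i + 1] <- Q[i + 1, i] <- 0.5
  diag(Q) <- -rowSums(Q)
  t <- 0.7
  # truncated matrix exponential series as the independent oracle
  P <- diag(K); term <- diag(K)
  for (m in 1:40) { term <- term %*% (Q * t) / m; P <- P + term }
  f <- numeric(K); f[5] <- 1
  expect_equal(matriflow:::ladder_message(lad, f, t), as.numeric(P[, 5]),
               tolerance = 1e-10)
})

test_that("prior-only runs recover the uniform priors", {
  # detailed-balance check: with likelihood identically 1 the chain must
  # sample theta and M from their uniform priors (reduced prior ranges
  # keep the simulation desk-scale)
  run <- sample_posterior(NULL,
                          deme_model("panmixia", theta_prior = c(0, 20),
                                     m_prior = c(0, 10)),
                          steps = 250, thin = 50, replicates = 1,
                          seed = 3, n_per_deme = 8, lik_fun = "prior",
                          n_loci = 2, delta_theta = 10)
  x <- run$theta_trace[, 1]
  ks <- suppressWarnings(stats::ks.test(x, "punif", 0, 20))
  expect_gt(ks$p.value, 0.01)
  expect_lt(abs(mean(x) - 10), 1.6)
})

test_that("two-tip posterior matches the quadrature oracle", {
  lad <- matriflow:::ladder_setup(c(40, 60), buffer = 10)
  dobs <- c(0L, 2L, 3L)
  i50 <- match(50, lad$states)
  pd <- function(theta, d) {
    stats::integrate(function(t) {
      (2 / theta) * exp(-2 * t / theta) *
        vapply(t, function(tt) {
          f <- numeric(lad$K); f[i50] <- 1
          matriflow:::ladder_message(lad, f, 2 * tt)[i50 + d]
        }, 0)
    }, 0, Inf, rel.tol = 1e-8)$value
  }
  grid <- seq(0.05, 20, by = 0.05)
  post <- vapply(grid, function(th) prod(vapply(dobs, pd, 0, theta = th)),
                 0)
  post <- post / sum(post * 0.05)
  q_mean <- sum(grid * post * 0.05)
  cdf <- cumsum(post * 0.05)
  q_med <- grid[which.min(abs(cdf - 0.5))]

  tipidx <- lapply(dobs, function(d) c(i50, i50 + d))
  lf <- function(gen, locus) matriflow:::loglik_ladder(
    gen, tipidx[[locus]], lad)
  run <- sample_posterior(NULL,
                          deme_model("panmixia", theta_prior = c(0, 20),
                                     m_prior = c(0, 10)),
                          steps = 300, thin = 25, replicates = 2,
                          seed = 11, n_per_deme = 2, lik_fun = lf,
                          n_loci = 3, delta_theta = 6)
  expect_lt(abs(mean(run$theta_trace) - q_mean), 1.2)
  expect_lt(abs(stats::median(run$theta_trace) - q_med), 1.2)
})

test_that("model comparison of identical runs gives a null Bayes factor", {
  fake <- structure(list(mlog = -100, mlog_truncated = -99),
                    class = "posterior_run")
  cmp <- compare_models(fake, fake)
  expect_equal(cmp$lbf, 0)
  cmp2 <- compare_models(structure(list(mlog = -110,
                                        mlog_truncated = -108),
                                   class = "posterior_run"), fake)
  expect_equal(cmp2$lbf, 10)
  expect_match(cmp2$support, "run2")
})

test_that("no-migration data piles the migration posterior near zero", {
  set.seed(21)
  M_tiny <- matrix(c(0, 0.05, 0.05, 0), 2, 2)
  g <- sim_island_genotypes(theta = c(1.5, 1.5), M = M_tiny,
                            n_loci = 5, n_per_deme = c(8, 8))
  run <- sample_posterior(g, deme_model("island", k = 2,
                                        theta_prior = c(0, 20),
                                        m_prior = c(0, 50)),
                          steps = 150, thin = 15, replicates = 1,
                          seed = 5, delta_theta = 5, delta_m = 15)
  # both immigration rates should sit in the lower part of their prior
  expect_lt(stats::median(run$m_trace[, 1]), 15)
  expect_lt(stats::median(run$m_trace[, 2]), 15)
})
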