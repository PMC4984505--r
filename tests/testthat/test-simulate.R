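small_cfg <- function(seed = 1L, n_per_deme = rbind(`2010` = c(10, 10, 10)),
                      ...) {
  sim_config(seed = seed, cohorts = "2010", n_per_deme = n_per_deme,
             theta = c(A = 1, B = 1, C = 1),
             n_loci = 5L, mt_theta = 1,
             length_mean = c(`2010` = 66.59), kn_shift = c(`2010` = 1),
             ...)
}

test_that("fixtures are deterministic and round-trip through the readers", {
  d1 <- file.path(tempfile(), "f1")
  d2 <- file.path(tempfile(), "f2")
  p1 <- make_fixtures(d1)
  p2 <- make_fixtures(d2)
  for (nm in names(p1)) {
    expect_identical(readLines(p1[[nm]]), readLines(p2[[nm]]),
                     info = nm)
  }
  ct <- read.table(p1["cohorts"], header = TRUE, sep = "\t",
                   colClasses = "character")
  a <- read_alignment(p1["fasta"],
                      cohort_map = setNames(ct$cohort, ct$id))
  expect_equal(a$site_count, 355L)
  expect_equal(length(a$ids), 36L)
  g <- read_genepop(p1["genepop"],
                    deme_names = c("2010A", "2010B", "2010C"))
  expect_equal(length(g$loci), 8L)
  expect_setequal(g$ids, a$ids)
  ph <- read.table(p1["phenotypes"], header = TRUE, sep = "\t")
  expect_true(all(ph$weight > 0 & ph$length > 0))
})

test_that("the generator's mtDNA diversity matches its own theta", {
  # Watterson / pairwise estimates on simulated matriline sequences track
  # mt_theta within wide single-locus confidence bounds
  set.seed(40)
  pis <- replicate(12, {
    gen <- matriflow:::rkingman(25)
    seqs <- matriflow:::seq_mutations(
      gen, matriflow:::random_seq(355), rate_per_seq = 1 / 2, kappa = 8)
    a <- mt_alignment(sprintf("i%02d_1", 1:25), seqs)
    collapse_haplotypes(a)$pi * 355
  })
  # E[pi * L] = theta = 1; single-locus variance is large, so test the mean
  expect_lt(abs(mean(pis) - 1), 0.5)
})

test_that("isolation and panmixia limits behave as expected", {
  sim0 <- simulate_structured(small_cfg(seed = 2,
                                        M = matrix(0, 3, 3)))
  expect_gt(global_fst(sim0$genotypes), 0.2)
  # founders differ: fixed differences between matrilines
  tb <- collapse_haplotypes(sim0$alignment)
  expect_gte(tb$s_sites, 2L)

  simp <- simulate_structured(sim_config(
    seed = 3, cohorts = "2010", matrilines = "A",
    n_per_deme = rbind(`2010` = 30), theta = c(A = 2),
    M = matrix(0, 1, 1), n_loci = 5L,
    length_mean = c(`2010` = 66.59), kn_shift = c(`2010` = 1)))
  g <- simp$genotypes
  # split the single deme in two fake halves: no differentiation
  g$deme <- rep(c("X", "Y"), length.out = length(g$ids))
  expect_lt(abs(global_fst(g)), 0.05)
})

test_that("truth record carries the generating parameters", {
  cfg <- small_cfg(seed = 4)
  sim <- simulate_structured(cfg)
  expect_identical(sim$truth$config$seed, 4L)
  expect_equal(sim$truth$config$theta, cfg$theta)
  expect_equal(sort(unique(unname(sim$truth$matriline))),
               c("A", "B", "C"))
  expect_equal(length(sim$truth$founders), 3L)
  # founders 1-2 steps apart
  expect_equal(bp_divergence(sim$truth$founders[1],
                             sim$truth$founders[2]), 1L)
  expect_equal(bp_divergence(sim$truth$founders[1],
                             sim$truth$founders[3]), 2L)
  expect_error(simulate_structured(small_cfg(
    seed = 1, n_per_deme = rbind(`2010` = c(0, 5, 5)))), "infeasible")
})

test_that("phenotypes follow the configured allometry", {
  # single cohort: the pooled slope estimates the generating slope
  # (across cohorts the condition shifts confound the pooled slope, as
  # they do in real data)
  sim1 <- simulate_structured(small_cfg(
    seed = 11, n_per_deme = rbind(`2010` = c(70, 70, 60))))
  fit1 <- suppressWarnings(allometry_fit(sim1$phenotypes))
  se <- summary(fit1$fit)$coefficients[2, 2]
  expect_lt(abs(fit1$b - 3.397), 4 * se)

  sim <- simulate_structured(sim_config(
    seed = 7, cohorts = c("2010", "2012"),
    n_per_deme = rbind(`2010` = c(40, 10, 10), `2012` = c(40, 10, 10)),
    theta = c(A = 1, B = 1, C = 1), n_loci = 2L,
    length_mean = c(`2010` = 66.59, `2012` = 71.60),
    kn_shift = c(`2010` = 0.944, `2012` = 1.061),
    pheno_sigma = 0.04))
  fit <- allometry_fit(sim$phenotypes)
  kn <- condition_index(sim$phenotypes$weight, sim$phenotypes$length,
                        fit$a, fit$b)
  mu <- tapply(kn, sim$phenotypes$cohort, mean)
  expect_gt(mu[["2012"]], mu[["2010"]])
})
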