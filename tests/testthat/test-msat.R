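make_geno <- function(a1, a2, deme = NULL, loci = NULL) {
  n <- nrow(a1)
  if (is.null(deme)) deme <- rep("D", n)
  genotype_matrix(sprintf("i%02d", seq_len(n)), deme, a1, a2, loci)
}

test_that("expected heterozygosity and allelic richness match closed forms", {
  # two equal-frequency alleles: He -> 0.5 (with the n/(n-1) correction)
  a1 <- matrix(rep(10L, 40), ncol = 1)
  a2 <- matrix(rep(12L, 40), ncol = 1)
  g <- make_geno(a1, a2)
  expect_equal(expected_het(g), 80 / 79 * 0.5, tolerance = 1e-12)

  # rarefaction identity: Ar at g = N equals the raw allele count
  set.seed(2)
  g2 <- sim_panmictic_genotypes(theta = 3, n_loci = 3, n_ind = 10,
                                labels = "D")
  raw <- vapply(1:3, function(li)
    length(unique(c(g2$a1[, li], g2$a2[, li]))), 0L)
  expect_equal(unname(rarefied_ar(g2, "D", g_genes = 20, by_locus = TRUE)),
               as.numeric(raw))
  # monotone in g
  expect_lte(rarefied_ar(g2, "D", g_genes = 10),
             rarefied_ar(g2, "D", g_genes = 16))
  expect_error(rarefied_ar(g2, "D", g_genes = 21), "exceeds")
})

test_that("rarefied Ar equals the exhaustive subsample mean", {
  # N = 6 genes with allele counts 3/2/1, g = 4: enumerate all C(6,4)
  al <- rep(c(10L, 12L, 14L), c(3, 2, 1))
  g <- make_geno(matrix(al[c(1, 3, 5)], ncol = 1),
                 matrix(al[c(2, 4, 6)], ncol = 1))
  combs <- utils::combn(6, 4)
  brute <- mean(apply(combs, 2, function(ix) length(unique(al[ix]))))
  expect_equal(rarefied_ar(g, g_genes = 4), brute, tolerance = 1e-12)

  # random instances against exhaustive enumeration
  set.seed(9)
  for (rep in 1:5) {
    al <- sample(10:13, 8, replace = TRUE)
    g <- make_geno(matrix(al[c(1, 3, 5, 7)], ncol = 1),
                   matrix(al[c(2, 4, 6, 8)], ncol = 1))
    gg <- sample(2:7, 1)
    brute <- mean(apply(utils::combn(8, gg), 2,
                        function(ix) length(unique(al[ix]))))
    expect_equal(rarefied_ar(g, g_genes = gg), brute, tolerance = 1e-12)
  }
})

test_that("F_IS detects homozygote excess and is ~0 under HWE", {
  set.seed(4)
  n <- 400
  p <- c(.4, .3, .2, .1)
  a1 <- matrix(sample(1:4, n, TRUE, p) + 10L, ncol = 1)
  a2 <- matrix(sample(1:4, n, TRUE, p) + 10L, ncol = 1)
  g <- make_geno(a1, a2)
  expect_lt(abs(fis(g)), 0.08)
  g_hom <- make_geno(a1, a1)
  expect_equal(fis(g_hom), 1)
})

test_that("IR and HL match their defining formulas on toys", {
  # deme of 5 individuals, 2 loci; frequencies computed from the data
  a1 <- rbind(c(10L, 20L), c(10L, 20L), c(10L, 22L), c(12L, 22L),
              c(12L, 20L))
  a2 <- rbind(c(10L, 22L), c(12L, 22L), c(12L, 22L), c(12L, 24L),
              c(14L, 22L))
  g <- make_geno(a1, a2)
  ir <- internal_relatedness(g)
  hl <- homozygosity_by_loci(g)
  # manual recomputation for individual 1 (hom at locus 1, het at locus 2)
  f1 <- table(c(a1[, 1], a2[, 1])) / 10
  f2 <- table(c(a1[, 2], a2[, 2])) / 10
  sf <- 2 * f1[["10"]] + f2[["20"]] + f2[["22"]]
  expect_equal(unname(ir[1]), unname((2 * 1 - sf) / (2 * 2 - sf)))
  e1 <- 1 - sum((f1)^2); e2 <- 1 - sum((f2)^2)
  expect_equal(unname(hl[1]), unname(e1 / (e1 + e2)))

  # extremes within a polymorphic deme: fully homozygous -> HL 1, IR 1;
  # fully heterozygous -> HL 0
  ext <- make_geno(rbind(c(10L, 20L), c(10L, 20L), c(12L, 22L)),
                   rbind(c(10L, 20L), c(12L, 22L), c(14L, 24L)))
  expect_equal(unname(homozygosity_by_loci(ext)[1]), 1)
  expect_equal(unname(internal_relatedness(ext)[1]), 1)
  expect_equal(unname(homozygosity_by_loci(ext)[3]), 0)
  expect_lt(unname(internal_relatedness(ext)[3]), 0.5)
})

test_that("deme-specific frequencies matter and HL ranks like homozygosity
          under uniform frequencies", {
  set.seed(6)
  g <- sim_panmictic_genotypes(theta = 3, n_loci = 5, n_ind = 24)
  ir1 <- internal_relatedness(g, by_deme = TRUE)
  g_relab <- g
  g_relab$deme[1L] <- "D2"  # move one individual between demes
  ir2 <- internal_relatedness(g_relab, by_deme = TRUE)
  expect_false(isTRUE(all.equal(ir1, ir2)))

  # uniform allele frequencies: HL orders individuals by homozygote count
  a1 <- matrix(rep(c(10L, 10L, 10L), 4), 3, 4)
  a2 <- matrix(c(10L, 10L, 10L, 10L,   10L, 10L, 12L, 12L,
                 12L, 12L, 12L, 12L), 3, 4, byrow = TRUE)
  gu <- make_geno(a1, a2)
  hl <- homozygosity_by_loci(gu, min_typed = 0)
  hom_count <- rowSums(a1 == a2)
  expect_equal(order(hl), order(hom_count))
})

test_that("Weir-Cockerham F_ST behaves at the limits", {
  n <- 10
  g_fix <- make_geno(matrix(rep(c(10L, 20L), each = n), ncol = 1),
                     matrix(rep(c(10L, 20L), each = n), ncol = 1),
                     deme = rep(c("X", "Y"), each = n))
  r <- pairwise_fst(g_fix, "X", "Y", n_perm = 49, seed = 1)
  expect_equal(r$fst, 1)
  expect_lt(r$p, 0.05)

  set.seed(8)
  g0 <- sim_panmictic_genotypes(theta = 3, n_loci = 5, n_ind = 40,
                                labels = c("X", "Y"))
  r0 <- pairwise_fst(g0, "X", "Y", n_perm = 49, seed = 2)
  expect_lt(abs(r0$fst), 0.05)
  expect_error(pairwise_fst(subset_genotypes(g0, 1:8), "X", "Y", 10),
               "n >= 5")
})

test_that("AMOVA matches a hand variance decomposition on a toy", {
  # 2 groups x 2 demes x 4 individuals, 1 locus, 2 alleles
  set.seed(3)
  deme <- rep(c("G1a", "G1b", "G2a", "G2b"), each = 4)
  p_by_deme <- c(G1a = .8, G1b = .7, G2a = .3, G2b = .2)
  a1 <- matrix(ifelse(runif(16) < p_by_deme[deme], 10L, 12L), ncol = 1)
  a2 <- matrix(ifelse(runif(16) < p_by_deme[deme], 10L, 12L), ncol = 1)
  g <- make_geno(a1, a2, deme = deme)
  grp <- c(G1a = "G1", G1b = "G1", G2a = "G2", G2b = "G2")
  res <- amova(g, grp, n_perm = 49, seed = 4)

  # independent oracle: explicit sums of squares over gene indicators
  genes <- c(a1[, 1], a2[, 1])
  gd <- rep(deme, 2)
  gg <- grp[gd]
  y <- as.numeric(genes == 10L)
  # complement allele doubles every SS, so F-ratios are unchanged
  ss <- function(x, f) sum(tapply(x, f, function(v) sum((v - mean(v))^2)))
  ss_w <- ss(y, gd)
  ybar_d <- tapply(y, gd, mean); nd <- table(gd)
  ybar_g <- tapply(y, gg, mean); ng <- table(gg)
  ss_d <- sum(nd * (ybar_d - ybar_g[grp[names(ybar_d)]])^2)
  ss_g <- sum(ng * (ybar_g - mean(y))^2)
  N <- length(y)
  n1 <- (N - sum(tapply(nd, grp[names(nd)], function(x) sum(x^2) / sum(x)))) / 2
  n2 <- (sum(tapply(nd, grp[names(nd)], function(x) sum(x^2) / sum(x))) -
           sum(nd^2) / N) / 1
  n3 <- (N - sum(ng^2) / N) / 1
  sc <- ss_w / (N - 4)
  sb <- (ss_d / 2 - sc) / n1
  sa <- (ss_g / 1 - sc - n2 * sb) / n3
  expect_equal(res$f_ct, sa / (sa + sb + sc), tolerance = 1e-10)
  expect_equal(res$f_sc, sb / (sb + sc), tolerance = 1e-10)
  expect_equal(res$f_st, (sa + sb) / (sa + sb + sc), tolerance = 1e-10)
})

test_that("AMOVA F_CT is near zero for identical demes", {
  set.seed(12)
  g <- sim_panmictic_genotypes(theta = 3, n_loci = 6, n_ind = 48,
                               labels = c("Xa", "Xb", "Ya", "Yb"))
  grp <- c(Xa = "X", Xb = "X", Ya = "Y", Yb = "Y")
  res <- amova(g, grp, n_perm = 30, seed = 5)
  expect_lt(abs(res$f_ct), 0.05)
  expect_gt(res$p_ct, 0.05)
})

test_that("null-allele EM recovers simulated frequencies", {
  set.seed(11)
  sim_null <- function(p0, n = 200, k = 6) {
    pv <- rep((1 - p0) / k, k)
    pall <- c(pv, p0)
    a1 <- a2 <- integer(n)
    for (i in seq_len(n)) {
      gt <- sample(seq_len(k + 1), 2, TRUE, prob = pall)
      if (all(gt == k + 1)) { a1[i] <- NA; a2[i] <- NA }
      else if (any(gt == k + 1)) { v <- gt[gt != k + 1]; a1[i] <- v; a2[i] <- v }
      else { a1[i] <- gt[1]; a2[i] <- gt[2] }
    }
    make_geno(matrix(a1 + 10L, ncol = 1), matrix(a2 + 10L, ncol = 1))
  }
  g15 <- sim_null(0.15)
  expect_lt(abs(null_allele_em(g15, 1, missing_as_null = TRUE) - 0.15),
            0.05)
  g00 <- sim_null(0)
  expect_lt(null_allele_em(g00, 1), 0.03)
  mono <- make_geno(matrix(rep(10L, 20), ncol = 1),
                    matrix(rep(10L, 20), ncol = 1))
  expect_equal(null_allele_em(mono, 1), 0)
})

test_that("Narum-corrected alpha is exact and monotone", {
  expect_equal(fdr_correct(0.01)$alpha_adj, 0.05)
  fc <- fdr_correct(runif(10), alpha = 0.05)
  expect_equal(fc$alpha_adj, 0.05 / sum(1 / (1:10)), tolerance = 1e-12)
  expect_equal(round(fc$alpha_adj, 5), 0.01707)
  # monotone: significant after correction implies significant before
  p <- c(0.001, 0.02, 0.2, 1)
  fc2 <- fdr_correct(p)
  expect_true(all(p[fc2$significant] <= 0.05))
  expect_false(any(fdr_correct(rep(1, 5))$significant))
})

test_that("Evanno delta-K matches hand-computed second differences", {
  L <- rbind(`1` = c(-100, -101), `2` = c(-90, -89), `3` = c(-88, -87.5),
             `4` = c(-87, -88))
  dk <- evanno_delta_k(L)
  expect_true(all(is.na(dk$delta_k[c(1, 4)])))
  # K=2: |L3 - 2 L2 + L1| per replicate = |(-88) - (-180) + (-100)| etc.
  num2 <- mean(abs(L[3, ] - 2 * L[2, ] + L[1, ]))
  expect_equal(dk$delta_k[2], num2 / sd(L[2, ]))
  # linear L -> 0
  Ll <- rbind(`1` = c(-10, -10.5), `2` = c(-8, -8.5), `3` = c(-6, -6.5))
  expect_equal(evanno_delta_k(Ll)$delta_k[2], 0)
  # zero replicate SD flagged
  Lc <- rbind(`1` = c(-10, -10), `2` = c(-9, -9), `3` = c(-7, -7))
  expect_warning(dkc <- evanno_delta_k(Lc), "infinite")
  expect_true(is.infinite(dkc$delta_k[2]))
})

test_that("Mantel test gives exact p on 3x3 and agrees with vegan", {
  m1 <- as.matrix(dist(c(0, 1, 3)))
  m2 <- as.matrix(dist(c(0, 1.1, 2.8)))
  r <- mantel_test(m1, m2)
  expect_true(r$exact)
  # manual enumeration of all 6 relabelings
  perms <- list(1:3, c(1, 3, 2), c(2, 1, 3), c(2, 3, 1), c(3, 1, 2),
                c(3, 2, 1))
  lt <- lower.tri(m1)
  vals <- sapply(perms, function(p) cor(m1[lt], m2[p, p][lt]))
  expect_equal(r$p, mean(vals >= r$r - 1e-12))

  # identity: r = 1
  expect_equal(mantel_test(m1, m1)$r, 1)

  skip_if_not_installed("vegan")
  set.seed(13)
  x <- as.matrix(dist(runif(10))); y <- as.matrix(dist(runif(10)))
  ours <- mantel_test(x, y, n_perm = 999, seed = 1)
  ref <- vegan::mantel(x, y, permutations = 999)
  expect_equal(ours$r, unname(ref$statistic), tolerance = 1e-10)
  expect_lt(abs(ours$p - ref$signif), 0.12)
})

test_that("LD screen returns valid p-values and flags duplicated loci", {
  set.seed(14)
  g <- sim_panmictic_genotypes(theta = 2, n_loci = 3, n_ind = 30,
                               labels = "D")
  # duplicate locus 1 -> perfect LD
  g2 <- genotype_matrix(g$ids, g$deme, cbind(g$a1, g$a1[, 1]),
                        cbind(g$a2, g$a2[, 1]),
                        c(g$loci, "dup"))
  res <- ld_screen(g2, n_perm = 60, seed = 3)
  expect_true(all(res$p > 0 & res$p <= 1))
  dup_row <- res$locus1 == g$loci[1] & res$locus2 == "dup"
  expect_lt(res$p[dup_row], 0.05)
})
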