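#' Null-allele frequency by Dempster's EM algorithm
#'
#' Maximum-likelihood estimate of the frequency of a non-amplifying (null)
#' allele at one locus. Observed homozygotes are treated as mixtures of
#' true homozygotes and null heterozygotes; optionally, missing genotypes
#' are treated as candidate null homozygotes. Iterates expectation /
#' maximisation until the largest allele-frequency change is below `tol`.
#'
#' @param g a `genotype_matrix`.
#' @param locus locus name or index.
#' @param deme optional deme label(s).
#' @param missing_as_null treat missing genotypes as potential null
#'   homozygotes (default FALSE: missing data are ignored).
#' @param tol convergence tolerance.
#' @param max_iter iteration cap.
#' @return estimated null-allele frequency (0 for a monomorphic locus).
#' @export
null_allele_em <- function(g, locus, deme = NULL, missing_as_null = FALSE,
                           tol = 1e-6, max_iter = 2000L) {
  li <- if (is.character(locus)) match(locus, g$loci) else locus
  keep <- if (is.null(deme)) rep(TRUE, length(g$ids)) else g$deme %in% deme
  a1 <- g$a1[keep, li]; a2 <- g$a2[keep, li]
  typed <- !is.na(a1)
  n_typed <- sum(typed)
  if (n_typed < 10L) stop("need >= 10 typed individuals")
  alleles <- sort(unique(c(a1[typed], a2[typed])))
  k <- length(alleles)
  if (k < 2L) return(0)
  ia1 <- match(a1[typed], alleles); ia2 <- match(a2[typed], alleles)
  het <- ia1 != ia2
  n_hom <- tabulate(ia1[!het], nbins = k)   # observed homozygote counts
  het_cnt <- tabulate(c(ia1[het], ia2[het]), nbins = k)
  n_miss <- if (missing_as_null) sum(!typed) else 0L
  n_ind <- n_typed + n_miss
  p <- c(rep(1 / (k + 1), k + 1))  # visible alleles then null
  for (it in seq_len(max_iter)) {
    pv <- p[seq_len(k)]; p0 <- p[k + 1L]
    # E-step: split observed homozygotes ii into (ii) vs (i0)
    denom <- pv^2 + 2 * pv * p0
    w_ii <- ifelse(denom > 0, pv^2 / denom, 1)
    e_ii <- n_hom * w_ii
    e_i0 <- n_hom * (1 - w_ii)
    # M-step
    new_v <- (2 * e_ii + e_i0 + het_cnt) / (2 * n_ind)
    new_0 <- (sum(e_i0) + 2 * n_miss) / (2 * n_ind)
    new_p <- c(new_v, new_0)
    if (max(abs(new_p - p)) < tol) { p <- new_p; break }
    p <- new_p
  }
  unname(p[k + 1L])
}

# simulate one locus: Kingman coalescent with theta, ladder mutations;
# returns sorted gene copies (allele sizes).
sim_locus_alleles <- function(n_genes, theta, model = "smm", p_smm = 1,
                              var_tpm = 0.1) {
  gen <- rkingman(n_genes)
  ladder_mutations(gen, rate = theta / 2, model = model, p_smm = p_smm,
                   var_tpm = var_tpm)
}

# adaptively find theta such that the expected allele count is close to k,
# then return replicates conditioned (by rejection) on exactly k alleles.
sim_heq_conditional <- function(n_genes, k_target, n_keep, model = "smm",
                                p_smm = 1, var_tpm = 0.1,
                                max_attempts = 50L * n_keep) {
  theta <- max(0.5, (k_target - 1)^2 / 2)  # SMM-flavoured initial guess
  for (round in seq_len(6L)) {
    ks <- replicate(25L, length(unique(
      sim_locus_alleles(n_genes, theta, model, p_smm, var_tpm))))
    adj <- log(k_target / max(mean(ks), 1.01))
    theta <- theta * exp(1.2 * adj)
    theta <- min(max(theta, 1e-3), 1e4)
  }
  he <- numeric(0)
  attempts <- 0L
  while (length(he) < n_keep && attempts < max_attempts) {
    attempts <- attempts + 1L
    al <- sim_locus_alleles(n_genes, theta, model, p_smm, var_tpm)
    if (length(unique(al)) == k_target) {
      p <- table(al) / n_genes
      he <- c(he, n_genes / (n_genes - 1) * (1 - sum(p^2)))
    }
  }
  he
}

#' Heterozygosity-excess bottleneck test
#'
#' For every polymorphic locus in a deme, simulates the expected
#' heterozygosity at mutation-drift equilibrium (`Heq`) conditional on the
#' observed allele count and sample size, under a two-phase / stepwise
#' mutation model, and compares the observed (unbiased) heterozygosity
#' against it. A recent severe reduction in effective size leaves an excess
#' of heterozygosity relative to allele count. Loci are combined with a
#' one-tailed Wilcoxon signed-rank test; an allele-frequency mode-shift
#' check (loss of the L-shaped frequency spectrum) is also reported.
#'
#' @param g a `genotype_matrix`.
#' @param deme deme label(s); default all individuals.
#' @param p_smm fraction of strictly stepwise mutations in the two-phase
#'   model (1 = pure SMM).
#' @param var_tpm variance of the multi-step (geometric) component.
#' @param n_coalsim equilibrium replicates per locus.
#' @param seed optional seed.
#' @return list with per-locus table (`he_obs`, `heq_mean`, `heq_sd`,
#'   `excess`), `p_excess`, `p_deficit` (Wilcoxon), `mode_shift` flag and
#'   the frequency-class spectrum.
#' @export
bottleneck_test <- function(g, deme = NULL, p_smm = 0.10, var_tpm = 0.10,
                            n_coalsim = 1000L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  keep <- if (is.null(deme)) rep(TRUE, length(g$ids)) else g$deme %in% deme
  model <- if (p_smm >= 1) "smm" else "tpm"
  rows <- list()
  for (li in seq_along(g$loci)) {
    al <- c(g$a1[keep, li], g$a2[keep, li])
    al <- al[!is.na(al)]
    k <- length(unique(al))
    if (k < 2L) next  # fixed loci carry no signal
    n_genes <- length(al)
    p <- table(al) / n_genes
    he_obs <- n_genes / (n_genes - 1) * (1 - sum(p^2))
    heq <- sim_heq_conditional(n_genes, k, n_coalsim, model, p_smm,
                               var_tpm)
    if (length(heq) < 20L) {
      warning("locus ", g$loci[li], ": too few conditional replicates")
      next
    }
    rows[[length(rows) + 1L]] <- data.frame(
      locus = g$loci[li], k = k, he_obs = he_obs,
      heq_mean = mean(heq), heq_sd = stats::sd(heq),
      excess = he_obs > mean(heq), stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  if (is.null(tab) || nrow(tab) < 4L) {
    stop("too few polymorphic loci for a bottleneck test")
  }
  d <- tab$he_obs - tab$heq_mean
  p_excess <- stats::wilcox.test(d, alternative = "greater",
                                 exact = FALSE)$p.value
  p_deficit <- stats::wilcox.test(d, alternative = "less",
                                  exact = FALSE)$p.value
  # mode shift: pooled allele-frequency classes of width 0.1
  freqs <- unlist(lapply(seq_along(g$loci), function(li) {
    al <- c(g$a1[keep, li], g$a2[keep, li])
    al <- al[!is.na(al)]
    if (length(unique(al)) < 2L) return(numeric(0))
    as.numeric(table(al) / length(al))
  }))
  cls <- cut(freqs, breaks = seq(0, 1, 0.1), include.lowest = TRUE)
  spectrum <- as.numeric(table(cls))
  mode_shift <- which.max(spectrum) != 1L
  list(table = tab, p_excess = p_excess, p_deficit = p_deficit,
       mode_shift = mode_shift, spectrum = spectrum)
}

#' FDIST-style F_ST outlier scan
#'
#' Simulates neutral loci under a finite island model conditioned on the
#' trimmed mean multilocus F_ST of the data, bins the simulated
#' (heterozygosity, F_ST) pairs by heterozygosity, and flags observed loci
#' outside the chosen quantile envelope.
#'
#' @param g a `genotype_matrix` with >= 2 demes.
#' @param n_sims number of simulated neutral loci.
#' @param n_islands number of demes in the simulated island model (sampling
#'   only as many demes as observed, with matched sample sizes).
#' @param trim trim fraction for the target mean F_ST.
#' @param theta_range range of per-deme theta for the simulated loci
#'   (log-uniform), spanning the heterozygosity axis.
#' @param mutation `"smm"` or `"iam"` (infinite alleles: every mutation
#'   creates a new allele).
#' @param probs envelope quantiles.
#' @param n_bins heterozygosity bins.
#' @param seed optional seed.
#' @return list with per-locus table (`he`, `fst`, `lo`, `hi`, `outlier`),
#'   the simulated cloud, and the target F_ST.
#' @export
fdist_scan <- function(g, n_sims = 2000L, n_islands = 50L, trim = 0.3,
                       theta_range = c(0.2, 20), mutation = c("smm", "iam"),
                       probs = c(0.025, 0.975), n_bins = 12L, seed = NULL) {
  mutation <- match.arg(mutation)
  if (!is.null(seed)) set.seed(seed)
  demes <- sort(unique(g$deme))
  d_obs <- length(demes)
  if (d_obs < 2L) stop("need at least two demes")
  sizes <- vapply(demes, function(d) sum(g$deme == d), 0L)
  per_locus_fst <- vapply(seq_along(g$loci), function(li) {
    g1 <- subset_genotypes(g, loci = li)
    global_fst(g1)
  }, 0)
  he_obs <- vapply(seq_along(g$loci), function(li) {
    mean(vapply(demes, function(d) expected_het(
      subset_genotypes(g, loci = li), d), 0))
  }, 0)
  target <- mean(per_locus_fst, trim = trim, na.rm = TRUE)
  target <- min(max(target, 1e-4), 0.5)
  # island model: FST ~= 1 / (1 + M*theta*(d/(d-1))^2) with d islands
  corr <- (n_islands / (n_islands - 1))^2
  sim_one <- function() {
    theta <- exp(stats::runif(1, log(theta_range[1]), log(theta_range[2])))
    M <- (1 / target - 1) / (theta * corr)
    th <- rep(theta, n_islands)
    Mm <- matrix(M / (n_islands - 1), n_islands, n_islands)
    diag(Mm) <- 0
    npd <- integer(n_islands)
    npd[seq_len(d_obs)] <- 2L * sizes
    gen <- rcoal_structured(npd, th, Mm)
    al <- if (mutation == "iam") iam_mutations(gen, rate = 1) else
      ladder_mutations(gen, rate = 1)
    # build one-locus genotype matrix: pair consecutive genes within demes
    ids <- paste0("s", seq_len(sum(sizes)))
    a1 <- matrix(al[seq(1, length(al), 2)], ncol = 1)
    a2 <- matrix(al[seq(2, length(al), 2)], ncol = 1)
    gm <- genotype_matrix(ids, rep(demes, times = sizes), a1, a2, "SIM")
    c(he = mean(vapply(demes, function(d) expected_het(gm, d), 0)),
      fst = global_fst(gm))
  }
  cloud <- t(replicate(n_sims, sim_one()))
  cloud <- cloud[is.finite(cloud[, "fst"]) & is.finite(cloud[, "he"]), ,
                 drop = FALSE]
  # quantile envelope by heterozygosity bins
  brk <- stats::quantile(cloud[, "he"], probs = seq(0, 1,
                                                    length.out = n_bins + 1))
  brk[1] <- -Inf; brk[length(brk)] <- Inf
  bin <- cut(cloud[, "he"], brk)
  lo_b <- tapply(cloud[, "fst"], bin, stats::quantile, probs = probs[1])
  hi_b <- tapply(cloud[, "fst"], bin, stats::quantile, probs = probs[2])
  obin <- cut(he_obs, brk)
  lo <- as.numeric(lo_b[obin]); hi <- as.numeric(hi_b[obin])
  tab <- data.frame(locus = g$loci, he = he_obs, fst = per_locus_fst,
                    lo = lo, hi = hi,
                    outlier = per_locus_fst < lo | per_locus_fst > hi,
                    stringsAsFactors = FALSE)
  list(table = tab, cloud = as.data.frame(cloud), target_fst = target)
}

#' Genotypic linkage-disequilibrium screen
#'
#' Log-likelihood-ratio (G) test of independence between the genotype
#' distributions of each locus pair, with a permutation null (shuffling one
#' locus's genotypes among individuals). Summary output only.
#'
#' @param g a `genotype_matrix`.
#' @param n_perm permutations per pair.
#' @param seed optional seed.
#' @return data.frame with locus pair, G statistic and permutation p.
#' @export
ld_screen <- function(g, n_perm = 200L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  gt_code <- function(li) {
    paste(g$a1[, li], g$a2[, li], sep = "/")
  }
  gstat <- function(x, y) {
    keep <- !grepl("NA", x) & !grepl("NA", y)
    tab <- table(x[keep], y[keep])
    e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    idx <- tab > 0
    2 * sum(tab[idx] * log(tab[idx] / e[idx]))
  }
  out <- list()
  for (i in seq_len(length(g$loci) - 1L)) {
    xi <- gt_code(i)
    for (j in (i + 1L):length(g$loci)) {
      yj <- gt_code(j)
      obs <- gstat(xi, yj)
      more <- 0L
      for (b in seq_len(n_perm)) {
        if (gstat(xi, sample(yj)) >= obs) more <- more + 1L
      }
      out[[length(out) + 1L]] <- data.frame(
        locus1 = g$loci[i], locus2 = g$loci[j], g_stat = obs,
        p = (more + 1) / (n_perm + 1), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
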