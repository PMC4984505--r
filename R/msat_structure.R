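# Weir & Cockerham (1984) variance components for one locus over r demes.
# Returns per-allele a (among demes), b (among individuals), c (within).
wc_components <- function(a1, a2, pop) {
  keep <- !is.na(a1)
  a1 <- a1[keep]; a2 <- a2[keep]; pop <- pop[keep]
  pops <- unique(pop)
  r <- length(pops)
  if (r < 2L) return(NULL)
  ni <- vapply(pops, function(p) sum(pop == p), 0)
  if (any(ni < 2L)) return(NULL)
  nbar <- mean(ni)
  nc <- (r * nbar - sum(ni^2) / (r * nbar)) / (r - 1)
  alleles <- sort(unique(c(a1, a2)))
  a <- b <- c_ <- numeric(length(alleles))
  for (ai in seq_along(alleles)) {
    al <- alleles[ai]
    p_i <- vapply(pops, function(p) {
      idx <- pop == p
      (sum(a1[idx] == al) + sum(a2[idx] == al)) / (2 * sum(idx))
    }, 0)
    h_i <- vapply(pops, function(p) {
      idx <- pop == p
      mean((a1[idx] == al) != (a2[idx] == al))
    }, 0)
    pbar <- sum(ni * p_i) / (r * nbar)
    s2 <- sum(ni * (p_i - pbar)^2) / ((r - 1) * nbar)
    hbar <- sum(ni * h_i) / (r * nbar)
    a[ai] <- nbar / nc * (s2 - 1 / (nbar - 1) *
                            (pbar * (1 - pbar) - (r - 1) / r * s2 -
                               hbar / 4))
    b[ai] <- nbar / (nbar - 1) *
      (pbar * (1 - pbar) - (r - 1) / r * s2 -
         (2 * nbar - 1) / (4 * nbar) * hbar)
    c_[ai] <- hbar / 2
  }
  list(a = a, b = b, c = c_)
}

wc_theta <- function(g, keep, pop) {
  sa <- sabc <- 0
  for (li in seq_along(g$loci)) {
    comp <- wc_components(g$a1[keep, li], g$a2[keep, li], pop)
    if (is.null(comp)) next
    sa <- sa + sum(comp$a)
    sabc <- sabc + sum(comp$a + comp$b + comp$c)
  }
  if (sabc == 0) return(NA_real_)
  sa / sabc
}

#' Pairwise Weir-Cockerham F_ST with a permutation test
#'
#' Multilocus theta between two demes; the p-value permutes individuals
#' between the demes, `p = (#perm >= obs + 1) / (n_perm + 1)`.
#'
#' @param g a `genotype_matrix`.
#' @param deme_a,deme_b deme labels.
#' @param n_perm number of permutations.
#' @param seed optional seed.
#' @return list with `fst`, `p`, `n_perm`.
#' @export
pairwise_fst <- function(g, deme_a, deme_b, n_perm = 1000L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  keep <- g$deme %in% c(deme_a, deme_b)
  if (sum(g$deme == deme_a) < 5L || sum(g$deme == deme_b) < 5L) {
    stop("both demes need n >= 5")
  }
  pop <- g$deme[keep]
  obs <- wc_theta(g, keep, pop)
  more <- 0L
  for (b in seq_len(n_perm)) {
    if (isTRUE(wc_theta(g, keep, sample(pop)) >= obs)) more <- more + 1L
  }
  list(fst = obs, p = (more + 1) / (n_perm + 1), n_perm = n_perm)
}

#' Multilocus W&C F_ST over all demes
#'
#' @param g a `genotype_matrix`.
#' @param pop optional alternative population labels (default the stored
#'   demes).
#' @return theta estimate.
#' @export
global_fst <- function(g, pop = NULL) {
  if (is.null(pop)) pop <- g$deme
  wc_theta(g, rep(TRUE, length(g$ids)), pop)
}

# Hierarchical AMOVA variance components on allele indicators for one
# locus: genes nested in demes nested in groups.
amova_components <- function(a1, a2, deme, group_of_deme) {
  keep <- !is.na(a1)
  a1 <- a1[keep]; a2 <- a2[keep]; deme <- deme[keep]
  genes <- c(a1, a2)
  gd <- c(deme, deme)
  demes <- unique(deme)
  grp <- group_of_deme[gd]
  groups <- unique(group_of_deme)
  nG <- length(groups); nD <- length(demes); N <- length(genes)
  nd <- vapply(demes, function(d) sum(gd == d), 0)
  names(nd) <- demes
  ng <- vapply(groups, function(x) sum(grp == x), 0)
  names(ng) <- groups
  alleles <- sort(unique(genes))
  ss_w <- ss_d <- ss_g <- 0
  for (al in alleles) {
    y <- as.numeric(genes == al)
    ybar <- mean(y)
    yd <- vapply(demes, function(d) mean(y[gd == d]), 0)
    yg <- vapply(groups, function(x) mean(y[grp == x]), 0)
    names(yd) <- demes; names(yg) <- groups
    ss_w <- ss_w + sum((y - yd[gd])^2)
    ss_d <- ss_d + sum(nd * (yd - yg[group_of_deme[demes]])^2)
    ss_g <- ss_g + sum(ng * (yg - ybar)^2)
  }
  df_g <- nG - 1; df_d <- nD - nG; df_w <- N - nD
  sumd2g <- vapply(groups, function(x) {
    dd <- demes[group_of_deme[demes] == x]
    sum(nd[dd]^2) / ng[x]
  }, 0)
  n1 <- (N - sum(sumd2g)) / df_d
  n2 <- (sum(sumd2g) - sum(nd^2) / N) / df_g
  n3 <- (N - sum(ng^2) / N) / df_g
  ms_w <- ss_w / df_w
  ms_d <- if (df_d > 0) ss_d / df_d else NA_real_
  ms_g <- ss_g / df_g
  sig_c <- ms_w
  sig_b <- if (df_d > 0) (ms_d - ms_w) / n1 else 0
  sig_a <- (ms_g - sig_c - n2 * sig_b) / n3
  c(sig_a = sig_a, sig_b = sig_b, sig_c = sig_c)
}

amova_stats <- function(g, group_of_deme, deme = NULL) {
  if (is.null(deme)) deme <- g$deme
  s <- c(sig_a = 0, sig_b = 0, sig_c = 0)
  for (li in seq_along(g$loci)) {
    s <- s + amova_components(g$a1[, li], g$a2[, li], deme, group_of_deme)
  }
  tot <- sum(s)
  c(f_ct = s[["sig_a"]] / tot,
    f_sc = s[["sig_b"]] / (s[["sig_b"]] + s[["sig_c"]]),
    f_st = (s[["sig_a"]] + s[["sig_b"]]) / tot,
    sig_a = s[["sig_a"]], sig_b = s[["sig_b"]], sig_c = s[["sig_c"]])
}

#' Hierarchical AMOVA (genes in demes in groups)
#'
#' Two-level analysis of molecular variance on allele identity: variance is
#' decomposed among groups (F_CT), among demes within groups (F_SC) and
#' within demes, summing components over loci. Significance: F_CT permutes
#' whole demes among groups; F_SC permutes individuals among demes within
#' their group; F_ST permutes individuals among all demes.
#'
#' @param g a `genotype_matrix` whose demes are nested in groups.
#' @param group_of_deme named character vector mapping each deme label to
#'   its group (e.g. deme "2010A" -> cohort "2010").
#' @param n_perm permutations per test.
#' @param seed optional seed.
#' @return list with the three F-statistics, variance components and
#'   permutation p-values.
#' @export
amova <- function(g, group_of_deme, n_perm = 200L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  demes <- sort(unique(g$deme))
  if (!all(demes %in% names(group_of_deme))) {
    stop("group_of_deme must name every deme")
  }
  obs <- amova_stats(g, group_of_deme)
  p_ct <- p_sc <- p_st <- 1L
  for (b in seq_len(n_perm)) {
    # F_CT: permute deme -> group assignment
    gperm <- stats::setNames(sample(group_of_deme[demes]), demes)
    if (isTRUE(amova_stats(g, gperm)[["f_ct"]] >= obs[["f_ct"]])) {
      p_ct <- p_ct + 1L
    }
    # F_SC: permute individuals among demes within groups
    dperm <- g$deme
    for (grp in unique(group_of_deme)) {
      idx <- which(group_of_deme[g$deme] == grp)
      dperm[idx] <- sample(g$deme[idx])
    }
    if (isTRUE(amova_stats(g, group_of_deme,
                           deme = dperm)[["f_sc"]] >= obs[["f_sc"]])) {
      p_sc <- p_sc + 1L
    }
    # F_ST: permute individuals among all demes
    if (isTRUE(amova_stats(g, group_of_deme,
                           deme = sample(g$deme))[["f_st"]] >=
               obs[["f_st"]])) {
      p_st <- p_st + 1L
    }
  }
  list(f_ct = obs[["f_ct"]], f_sc = obs[["f_sc"]], f_st = obs[["f_st"]],
       sigma = obs[c("sig_a", "sig_b", "sig_c")],
       p_ct = p_ct / (n_perm + 1), p_sc = p_sc / (n_perm + 1),
       p_st = p_st / (n_perm + 1), n_perm = n_perm)
}

#' Mantel test between two distance matrices
#'
#' Pearson correlation of the lower triangles under simultaneous row/column
#' permutation of the second matrix. For `n <= 7` all `n!` permutations are
#' enumerated and the p-value is exact; otherwise `n_perm` random
#' permutations are used. Also reports the classical `z` statistic (sum of
#' cross-products).
#'
#' @param m1,m2 symmetric distance matrices of identical dimension.
#' @param n_perm random permutations when enumeration is infeasible.
#' @param seed optional seed.
#' @return list with `r`, `z`, `p`, `exact`.
#' @export
mantel_test <- function(m1, m2, n_perm = 999L, seed = NULL) {
  m1 <- as.matrix(m1); m2 <- as.matrix(m2)
  n <- nrow(m1)
  if (!all(dim(m1) == dim(m2))) stop("matrices differ in dimension")
  lt <- lower.tri(m1)
  v1 <- m1[lt]
  stat <- function(perm) {
    mp <- m2[perm, perm]
    suppressWarnings(stats::cor(v1, mp[lt]))
  }
  obs <- stat(seq_len(n))
  z <- sum(v1 * m2[lt])
  if (is.na(obs)) stop("degenerate distance matrix (zero variance)")
  perms <- NULL
  exact <- n <= 7L
  if (exact) {
    perms <- all_permutations(n)
    vals <- vapply(perms, stat, 0)
    p <- mean(vals >= obs - 1e-12)
  } else {
    if (!is.null(seed)) set.seed(seed)
    more <- 0L
    for (b in seq_len(n_perm)) {
      if (isTRUE(stat(sample(n)) >= obs - 1e-12)) more <- more + 1L
    }
    p <- (more + 1) / (n_perm + 1)
  }
  list(r = obs, z = z, p = p, exact = exact)
}

all_permutations <- function(n) {
  if (n == 1L) return(list(1L))
  sub <- all_permutations(n - 1L)
  out <- vector("list", n * length(sub))
  k <- 0L
  for (p in sub) {
    for (pos in seq_len(n)) {
      k <- k + 1L
      out[[k]] <- append(p, n, after = pos - 1L)
    }
  }
  out
}

#' False-discovery-rate corrected alpha (Narum)
#'
#' Benjamini-Yekutieli-style corrected significance level,
#' `alpha_adj = alpha / sum_{i=1..k} 1/i`, for `k` simultaneous tests.
#'
#' @param p numeric vector of p-values.
#' @param alpha nominal significance level.
#' @return list with `alpha_adj`, logical `significant`, and `k`.
#' @export
fdr_correct <- function(p, alpha = 0.05) {
  k <- length(p)
  if (k == 0L) stop("no p-values")
  alpha_adj <- alpha / sum(1 / seq_len(k))
  list(alpha_adj = alpha_adj, significant = p <= alpha_adj, k = k)
}

#' Evanno's delta-K from clustering log-likelihood tables
#'
#' `deltaK(K) = mean(|L(K+1) - 2 L(K) + L(K-1)|) / sd(L(K))`, with mean
#' over replicate runs and sd across replicates at K. Defined for interior
#' K only; infinite/undefined values (sd = 0) are returned as `Inf` with a
#' warning.
#'
#' @param L numeric matrix of log-likelihoods, rows = K values (rownames =
#'   K), columns = replicate runs.
#' @return data.frame with K and delta_k (NA at the boundaries).
#' @export
evanno_delta_k <- function(L) {
  L <- as.matrix(L)
  Ks <- as.integer(rownames(L))
  if (any(is.na(Ks))) Ks <- seq_len(nrow(L))
  if (nrow(L) < 3L) stop("need at least three K values")
  dk <- rep(NA_real_, nrow(L))
  for (i in 2L:(nrow(L) - 1L)) {
    sdl <- stats::sd(L[i, ])
    num <- mean(abs(L[i + 1L, ] - 2 * L[i, ] + L[i - 1L, ]))
    if (sdl == 0) {
      warning("sd(L) = 0 at K = ", Ks[i], "; delta-K infinite")
      dk[i] <- if (num == 0) 0 else Inf
    } else {
      dk[i] <- num / sdl
    }
  }
  data.frame(K = Ks, delta_k = dk)
}
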