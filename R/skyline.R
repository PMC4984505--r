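#' Pairwise HKY distances for an alignment
#'
#' Maximum-likelihood-style pairwise distance under the HKY substitution
#' model with a fixed transition:transversion rate ratio `kappa` and
#' empirical base frequencies: for each pair the expected proportion of
#' differing sites under HKY at divergence `d` (in substitutions/site) is
#' matched to the observed p-distance by root finding. With `kappa = 1` and
#' uniform base frequencies this reduces to the Jukes-Cantor correction.
#'
#' @param aln an `mt_alignment` or character vector of equal-length
#'   sequences.
#' @param kappa transition:transversion rate ratio (fixed, e.g. from a
#'   model-selection run done elsewhere).
#' @param base_freq optional length-4 vector (A, C, G, T); default
#'   empirical frequencies of the alignment.
#' @return symmetric matrix of distances in substitutions/site.
#' @export
hky_distance <- function(aln, kappa = 8, base_freq = NULL) {
  seqs <- if (inherits(aln, "mt_alignment")) aln$seq else as.character(aln)
  n <- length(seqs)
  chars <- strsplit(seqs, "")
  L <- length(chars[[1L]])
  bases <- c("A", "C", "G", "T")
  if (is.null(base_freq)) {
    tab <- table(factor(unlist(chars), levels = bases))
    base_freq <- as.numeric(tab) / sum(tab)
  }
  base_freq <- pmax(base_freq, 1e-4)  # guard degenerate compositions
  base_freq <- base_freq / sum(base_freq)
  Q <- hky_rate_matrix(kappa, base_freq)
  eg <- eigen(Q)
  Vi <- solve(eg$vectors)
  ts_partner <- c(A = "G", G = "A", C = "T", T = "C")
  # site-category probabilities (identical / transition / transversion)
  # after divergence d, averaged over the stationary base composition
  cat_probs <- function(d) {
    P <- Re(eg$vectors %*% (exp(eg$values * d) * Vi))
    dimnames(P) <- dimnames(Q)
    p_same <- sum(base_freq * diag(P))
    p_ts <- sum(base_freq * P[cbind(rownames(P), ts_partner[rownames(P)])])
    c(same = p_same, ts = p_ts, tv = 1 - p_same - p_ts)
  }
  pur <- c("A", "G")
  dm <- matrix(0, n, n)
  if (inherits(aln, "mt_alignment")) {
    dimnames(dm) <- list(aln$ids, aln$ids)
  }
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      a <- chars[[i]]; b <- chars[[j]]
      diff <- a != b
      if (!any(diff)) next
      n_ts <- sum(diff & ((a %in% pur) == (b %in% pur)))
      n_tv <- sum(diff) - n_ts
      n_same <- L - n_ts - n_tv
      nll <- function(d) {
        pr <- pmax(cat_probs(d), 1e-12)
        -(n_same * log(pr["same"]) + n_ts * log(pr["ts"]) +
            n_tv * log(pr["tv"]))
      }
      opt <- stats::optimize(nll, c(1e-9, 50), tol = 1e-9)
      if (opt$minimum > 49) warning("saturated pair; distance capped at 50")
      dm[i, j] <- dm[j, i] <- opt$minimum
    }
  }
  dm
}

# HKY generator scaled to one expected substitution per unit time
hky_rate_matrix <- function(kappa, pi_) {
  bases <- c("A", "C", "G", "T")
  Q <- matrix(0, 4, 4, dimnames = list(bases, bases))
  is_ts <- function(a, b) (a %in% c("A", "G")) == (b %in% c("A", "G"))
  for (a in 1:4) {
    for (b in 1:4) {
      if (a == b) next
      Q[a, b] <- pi_[b] * if (is_ts(bases[a], bases[b])) kappa else 1
    }
  }
  diag(Q) <- -rowSums(Q)
  mu <- -sum(pi_ * diag(Q))
  Q / mu
}

#' UPGMA genealogy from a distance matrix
#'
#' Thin wrapper around average-linkage clustering (phangorn's UPGMA)
#' returning a rooted ultrametric `phylo` tree; node heights are in the
#' units of the input distances (halved, as usual for UPGMA).
#'
#' @param d distance matrix or `dist` object.
#' @return an ape `phylo` object.
#' @export
upgma_tree <- function(d) {
  phangorn::upgma(stats::as.dist(d))
}

#' Classic / generalized skyline of effective size through time
#'
#' Classic skyline estimate of Pybus & Rambaut: for the coalescent
#' interval with `i` lineages and length `g_i`, the scaled size estimate is
#' `g_i * i * (i - 1) / 2`. The generalized variant pools short adjacent
#' intervals controlled by `epsilon`; `epsilon = "aicc"` picks the pooling
#' parameter by small-sample AIC. Computed via ape's skyline machinery
#' behind this interface.
#'
#' @param tree rooted ultrametric `phylo` (e.g. from [upgma_tree()]).
#' @param epsilon numeric pooling parameter in tree-time units, `0` for the
#'   classic skyline, or `"aicc"` for AICc selection.
#' @param rate optional substitutions/site/time-unit rate; when given, a
#'   `time_years` column is added (`time / rate`).
#' @param rate_sd optional rate standard deviation, propagated into a
#'   `time_years_lo`/`_hi` band.
#' @return a `skyline_profile` data.frame: interval end `time` (from the
#'   present, substitutions/site), `ne` (scaled size Ne*tau), `epsilon`
#'   attribute, optional calendar columns.
#' @export
classic_skyline <- function(tree, epsilon = 0, rate = NULL,
                            rate_sd = NULL) {
  if (!ape::is.ultrametric(tree, tol = 1e-6)) {
    stop("skyline needs an ultrametric genealogy")
  }
  ci <- ape::coalescent.intervals(tree)
  # collapse zero-length intervals to avoid division blow-ups in ape
  if (identical(epsilon, "aicc")) {
    sk <- ape::find.skyline.epsilon(ci, quiet = TRUE)
    eps_used <- sk
    sky <- ape::skyline(ci, epsilon = sk)
  } else {
    eps_used <- epsilon
    sky <- ape::skyline(ci, epsilon = epsilon)
  }
  out <- data.frame(time = sky$time, ne = sky$population.size)
  if (!is.null(rate)) {
    out$time_years <- out$time / rate
    if (!is.null(rate_sd)) {
      out$time_years_lo <- out$time / (rate + rate_sd)
      out$time_years_hi <- out$time / (rate - rate_sd)
    }
  }
  attr(out, "epsilon") <- eps_used
  attr(out, "logL") <- sky$logL
  class(out) <- c("skyline_profile", "data.frame")
  out
}

#' Matriline skyline from sequences
#'
#' Convenience pipeline: HKY distances -> UPGMA genealogy -> generalized
#' skyline, for the sequences of one matriline.
#'
#' @param aln an `mt_alignment` (already subset to one matriline).
#' @param kappa transition:transversion ratio for [hky_distance()].
#' @param epsilon see [classic_skyline()].
#' @param rate,rate_sd see [classic_skyline()].
#' @return a `skyline_profile` with the tree in `attr(, "tree")`.
#' @export
matriline_skyline <- function(aln, kappa = 8, epsilon = "aicc",
                              rate = NULL, rate_sd = NULL) {
  d <- hky_distance(aln, kappa = kappa)
  tr <- upgma_tree(d)
  prof <- classic_skyline(tr, epsilon = epsilon, rate = rate,
                          rate_sd = rate_sd)
  attr(prof, "tree") <- tr
  prof
}
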