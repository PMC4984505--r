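#' Specify a demographic model for migration inference
#'
#' @param flavor `"island"` (k demes, asymmetric gene flow) or
#'   `"panmixia"` (single deme).
#' @param k number of demes (forced to 1 for panmixia).
#' @param theta_prior uniform prior bounds for the mutation-scaled deme
#'   sizes theta.
#' @param m_prior uniform prior bounds for the mutation-scaled immigration
#'   rates M.
#' @return a `deme_model` list.
#' @export
deme_model <- function(flavor = c("island", "panmixia"), k = 3L,
                       theta_prior = c(0, 200), m_prior = c(0, 1000)) {
  flavor <- match.arg(flavor)
  if (flavor == "panmixia") k <- 1L
  structure(list(flavor = flavor, k = as.integer(k),
                 theta_prior = theta_prior, m_prior = m_prior),
            class = "deme_model")
}

# ladder (strict stepwise) mutation model on a bounded allele range:
# symmetric tridiagonal generator, mutation rate 1, reflecting bounds.
ladder_setup <- function(allele_range, buffer = 10L) {
  states <- seq.int(max(2L, allele_range[1L] - buffer),
                    allele_range[2L] + buffer)
  K <- length(states)
  Q <- matrix(0, K, K)
  for (i in seq_len(K - 1L)) {
    Q[i, i + 1L] <- Q[i + 1L, i] <- 0.5
  }
  diag(Q) <- -rowSums(Q)
  eig <- eigen(Q, symmetric = TRUE)
  list(states = states, K = K, U = eig$vectors, lambda = eig$values)
}

# message along a branch: P(t) %*% f via the eigendecomposition
ladder_message <- function(lad, f, t) {
  as.numeric(lad$U %*% (exp(lad$lambda * t) * crossprod(lad$U, f)))
}

# Felsenstein pruning for one locus on one genealogy; tips = allele state
# indices into lad$states (NA = missing). Uniform root frequencies.
loglik_ladder <- function(gen, tip_idx, lad) {
  n <- gen$n_tips
  n_nodes <- 2L * n - 1L
  part <- vector("list", n_nodes)
  logn <- 0
  for (i in seq_len(n)) {
    f <- numeric(lad$K)
    if (is.na(tip_idx[i])) f[] <- 1 else f[tip_idx[i]] <- 1
    part[[i]] <- f
  }
  # children of node x are rows of edge with parent x; parents are created
  # in increasing id order, so ascending order is postorder-safe
  kids <- split(seq_len(nrow(gen$edge)), gen$edge[, 1L])
  for (x in (n + 1L):n_nodes) {
    rows <- kids[[as.character(x)]]
    f <- 1
    for (r in rows) {
      ch <- gen$edge[r, 2L]
      m <- pmax(ladder_message(lad, part[[ch]], gen$edge_length[r]), 0)
      sm <- sum(m)
      if (sm <= 0 || !is.finite(sm)) return(-Inf)
      logn <- logn + log(sm)
      f <- f * (m / sm)
    }
    s <- sum(f)
    if (s <= 0 || !is.finite(s)) return(-Inf)
    logn <- logn + log(s)
    part[[x]] <- f / s
  }
  logn + log(mean(part[[n_nodes]]))
}

prepare_gene_data <- function(g, demes) {
  # per-locus allele states of gene copies ordered by deme block then
  # individual; two consecutive genes per individual
  lapply(seq_along(g$loci), function(li) {
    unlist(lapply(demes, function(d) {
      idx <- which(g$deme %in% d)
      as.vector(rbind(g$a1[idx, li], g$a2[idx, li]))
    }))
  })
}

#' Structured-coalescent MCMC for theta and migration rates
#'
#' Bayesian inference of per-deme mutation-scaled sizes theta and
#' asymmetric mutation-scaled immigration rates M from microsatellite
#' genotypes, by MCMC over coalescent genealogies with migration events.
#' Genealogy updates are per-locus independence proposals drawn from the
#' structured-coalescent prior at the current parameters (accepted on the
#' data-likelihood ratio); parameter updates are reflected sliding-window
#' moves accepted on the genealogy prior-density ratio. Microsatellites
#' evolve by a strict single-step ladder model on a bounded allele range.
#' The harmonic-mean marginal log-likelihood (Mlog) is recorded per
#' replicate, together with a truncated (stabilised) variant.
#'
#' @param g a `genotype_matrix` (deme labels define the island demes), or
#'   NULL when `lik_fun` supplies the likelihood.
#' @param model a [deme_model()].
#' @param steps recorded posterior steps per replicate.
#' @param thin proposals between recorded steps.
#' @param replicates independent chains whose Mlog values are averaged.
#' @param burnin_frac burn-in fraction of total proposals.
#' @param delta_theta,delta_m sliding-window widths.
#' @param buffer allele-ladder buffer beyond the observed range.
#' @param seed integer seed (replicate r uses `seed + r - 1`).
#' @param n_per_deme sampled gene copies per deme when `g` is NULL.
#' @param lik_fun optional likelihood override: `"prior"` for a prior-only
#'   run (likelihood identically 1), or `function(gen, locus)` returning a
#'   log-likelihood.
#' @param n_loci number of loci when `g` is NULL.
#' @param max_events event cap per simulated genealogy (proposals beyond
#'   it are rejected and counted).
#' @return a `posterior_run`: traces, posterior summaries (`theta_mode`,
#'   `theta_ci`, `m_mode`, `m_ci`), `mlog`, `mlog_truncated`, acceptance
#'   rates and ESS of the log-likelihood trace.
#' @export
sample_posterior <- function(g, model, steps = 5000L, thin = 100L,
                             replicates = 3L, burnin_frac = 0.1,
                             delta_theta = 20, delta_m = 100,
                             buffer = 10L, seed = NULL,
                             n_per_deme = NULL, lik_fun = NULL,
                             n_loci = 1L, max_events = 2e4) {
  k <- model$k
  if (!is.null(g)) {
    demes <- if (k == 1L) list(sort(unique(g$deme))) else
      as.list(sort(unique(g$deme)))
    if (k > 1L && length(demes) != k) {
      stop("data has ", length(demes), " demes but model expects ", k)
    }
    dl <- if (k == 1L) demes[[1L]] else unlist(demes)
    n_per_deme <- vapply(demes, function(d) 2L * sum(g$deme %in% d), 0L)
    gene_data <- prepare_gene_data(g, if (k == 1L) list(dl) else dl)
    n_loci <- length(g$loci)
    rng <- range(unlist(gene_data), na.rm = TRUE)
    lad <- ladder_setup(rng, buffer)
    tip_idx <- lapply(gene_data, function(x) match(x, lad$states))
    if (any(vapply(n_per_deme, function(x) x < 4L, TRUE))) {
      stop("each deme needs at least 4 sampled gene copies (n >= 2)")
    }
    locus_ll <- function(gen, locus) loglik_ladder(gen, tip_idx[[locus]],
                                                   lad)
  } else {
    if (is.null(n_per_deme)) stop("n_per_deme required when g is NULL")
    if (is.null(lik_fun)) stop("lik_fun required when g is NULL")
    locus_ll <- NULL
  }
  prior_only <- identical(lik_fun, "prior")
  if (!is.null(lik_fun) && !prior_only) locus_ll <- lik_fun
  if (prior_only) locus_ll <- function(gen, locus) 0
  tp <- model$theta_prior; mp <- model$m_prior
  n_param <- k + if (k > 1L) k * (k - 1L) else 0L
  total <- steps * thin
  burn <- ceiling(burnin_frac * total)
  reflect <- function(x, lo, hi) {
    while (x < lo || x > hi) {
      if (x < lo) x <- 2 * lo - x
      if (x > hi) x <- 2 * hi - x
    }
    x
  }
  # moment-based starting value: under single-step mutation the expected
  # squared allele-size difference of two genes in a deme equals theta
  theta_start <- NULL
  if (!is.null(g)) {
    msd <- vapply(seq_len(n_loci), function(l) {
      x <- gene_data[[l]]
      x <- x[!is.na(x)]
      if (length(x) < 2L) return(NA_real_)
      mean(stats::dist(x)^2)
    }, 0)
    theta_start <- max(min(mean(msd, na.rm = TRUE), 0.9 * tp[2]), 0.1)
  }
  run_chain <- function(rep_seed) {
    if (!is.null(rep_seed)) set.seed(rep_seed)
    theta <- rep(if (!is.null(theta_start)) theta_start else
      stats::runif(1, tp[1] + 0.05 * diff(tp), tp[1] + 0.5 * diff(tp)), k)
    M <- matrix(stats::runif(1, 1, min(20, 0.1 * mp[2])), k, k)
    diag(M) <- 0
    if (k == 1L) M <- matrix(0, 1, 1)
    gens <- vector("list", n_loci)
    lls <- numeric(n_loci)
    for (l in seq_len(n_loci)) {
      for (tries in seq_len(20L)) {
        gens[[l]] <- tryCatch(
          rcoal_structured(n_per_deme, theta, M, max_events = max_events),
          error = function(e) NULL)
        if (!is.null(gens[[l]])) break
        theta <- pmax(theta / 2, 1e-3)
        M <- M / 2
      }
      if (is.null(gens[[l]])) stop("could not initialise genealogies")
      lls[l] <- locus_ll(gens[[l]], l)
      tries <- 0L
      while (!is.finite(lls[l]) && tries < 50L) {
        tries <- tries + 1L
        theta <- pmax(theta / 1.3, 1e-3)
        g2 <- tryCatch(
          rcoal_structured(n_per_deme, theta, M, max_events = max_events),
          error = function(e) NULL)
        if (!is.null(g2)) {
          gens[[l]] <- g2
          lls[l] <- locus_ll(g2, l)
        }
      }
      if (!is.finite(lls[l])) stop("could not find a finite-likelihood start")
    }
    pri <- vapply(gens, dstructured_log, 0, theta = theta, M = M)
    acc_p <- try_p <- acc_g <- try_g <- 0L
    rec_theta <- matrix(NA_real_, steps, k)
    rec_m <- if (k > 1L) matrix(NA_real_, steps, k * (k - 1L)) else NULL
    rec_ll <- numeric(steps)
    rec_i <- 0L
    offdiag <- which(row(M) != col(M))
    for (it in seq_len(total + burn)) {
      u_move <- stats::runif(1)
      if (u_move >= 0.4 && u_move < 0.7) {
        # time-rescale move: scale one locus genealogy by s; the Jacobian
        # of scaling all E event times is s^E
        try_g <- try_g + 1L
        l <- sample.int(n_loci, 1L)
        s <- exp(stats::runif(1, -0.5, 0.5))
        gen2 <- gens[[l]]
        gen2$edge_length <- gen2$edge_length * s
        gen2$node_time <- gen2$node_time * s
        gen2$stats$A <- gen2$stats$A * s
        gen2$stats$B <- gen2$stats$B * s
        ll2 <- locus_ll(gen2, l)
        pri2 <- dstructured_log(gen2, theta, M)
        n_ev <- gen2$n_tips - 1L + gen2$n_mig
        delta <- (pri2 - pri[l]) + (ll2 - lls[l]) + n_ev * log(s)
        if (!is.finite(ll2)) delta <- -Inf
        if (log(stats::runif(1)) < delta) {
          gens[[l]] <- gen2; lls[l] <- ll2; pri[l] <- pri2
          acc_g <- acc_g + 1L
        }
      } else if (u_move < 0.4) {
        try_p <- try_p + 1L
        pi_ <- sample.int(n_param, 1L)
        if (pi_ <= k) {
          th2 <- theta
          th2[pi_] <- reflect(theta[pi_] +
                                stats::runif(1, -delta_theta / 2,
                                             delta_theta / 2),
                              max(tp[1], 1e-4), tp[2])
          pri2 <- vapply(gens, dstructured_log, 0, theta = th2, M = M)
          if (log(stats::runif(1)) < sum(pri2) - sum(pri)) {
            theta <- th2; pri <- pri2; acc_p <- acc_p + 1L
          }
        } else {
          M2 <- M
          ij <- offdiag[pi_ - k]
          M2[ij] <- reflect(M[ij] + stats::runif(1, -delta_m / 2,
                                                 delta_m / 2),
                            max(mp[1], 1e-6), mp[2])
          pri2 <- vapply(gens, dstructured_log, 0, theta = theta, M = M2)
          if (log(stats::runif(1)) < sum(pri2) - sum(pri)) {
            M <- M2; pri <- pri2; acc_p <- acc_p + 1L
          }
        }
      } else {
        try_g <- try_g + 1L
        l <- sample.int(n_loci, 1L)
        gen2 <- tryCatch(
          rcoal_structured(n_per_deme, theta, M, max_events = max_events),
          error = function(e) NULL)
        if (!is.null(gen2)) {
          ll2 <- locus_ll(gen2, l)
          delta <- if (!is.finite(ll2)) -Inf else
            if (!is.finite(lls[l])) Inf else ll2 - lls[l]
          if (log(stats::runif(1)) < delta) {
            gens[[l]] <- gen2
            lls[l] <- ll2
            pri[l] <- dstructured_log(gen2, theta, M)
            acc_g <- acc_g + 1L
          }
        }
      }
      if (it > burn && (it - burn) %% thin == 0L) {
        rec_i <- rec_i + 1L
        rec_theta[rec_i, ] <- theta
        if (k > 1L) rec_m[rec_i, ] <- M[offdiag]
        rec_ll[rec_i] <- sum(lls)
      }
    }
    acc <- (acc_p + acc_g) / (try_p + try_g)
    if (acc < 0.01) {
      stop("non-mixing chain: overall acceptance ", signif(acc, 2),
           " < 1%; increase data/chain budget or adjust deltas")
    }
    list(theta = rec_theta, m = rec_m, ll = rec_ll,
         acc_param = acc_p / max(try_p, 1L),
         acc_gene = acc_g / max(try_g, 1L))
  }
  seeds <- if (is.null(seed)) rep(list(NULL), replicates) else
    as.list(seed + seq_len(replicates) - 1L)
  chains <- lapply(seeds, run_chain)
  all_theta <- do.call(rbind, lapply(chains, `[[`, "theta"))
  all_m <- if (k > 1L) do.call(rbind, lapply(chains, `[[`, "m")) else NULL
  all_ll <- unlist(lapply(chains, `[[`, "ll"))
  mlogs <- vapply(chains, function(ch) harmonic_mean_mlog(ch$ll), 0)
  mlogs_t <- vapply(chains, function(ch)
    harmonic_mean_mlog(ch$ll, trunc_frac = 0.05), 0)
  mode1 <- function(x) {
    if (stats::sd(x) < 1e-12) return(x[1])
    d <- stats::density(x)
    d$x[which.max(d$y)]
  }
  offdiag <- which(row(matrix(0, k, k)) != col(matrix(0, k, k)))
  m_mode <- matrix(0, k, k)
  m_ci <- NULL
  if (k > 1L) {
    m_mode[offdiag] <- apply(all_m, 2L, mode1)
    m_ci <- apply(all_m, 2L, stats::quantile, probs = c(0.025, 0.975))
    colnames(m_ci) <- paste0("M", offdiag)
  }
  structure(list(
    model = model, k = k,
    theta_trace = all_theta, m_trace = all_m, ll_trace = all_ll,
    theta_mode = apply(all_theta, 2L, mode1),
    theta_ci = apply(all_theta, 2L, stats::quantile,
                     probs = c(0.025, 0.975)),
    m_mode = m_mode, m_ci = m_ci,
    mlog = mean(mlogs), mlog_truncated = mean(mlogs_t),
    mlog_replicates = mlogs,
    acc_param = mean(vapply(chains, `[[`, 0, "acc_param")),
    acc_gene = mean(vapply(chains, `[[`, 0, "acc_gene")),
    ess = ess_simple(all_ll),
    steps = steps, thin = thin, replicates = replicates
  ), class = "posterior_run")
}

#' @export
print.posterior_run <- function(x, ...) {
  cat(sprintf("posterior run (%s, k=%d): %d x %d recorded steps\n",
              x$model$flavor, x$k, x$replicates, x$steps))
  cat("theta modes:", paste(signif(x$theta_mode, 4), collapse = ", "), "\n")
  cat(sprintf("Mlog (harmonic mean): %.3f  [truncated: %.3f]\n",
              x$mlog, x$mlog_truncated))
  cat(sprintf("acceptance: params %.2f, genealogies %.2f; ESS(ll) %.0f\n",
              x$acc_param, x$acc_gene, x$ess))
  invisible(x)
}

# harmonic-mean marginal log-likelihood from a posterior log-likelihood
# trace; trunc_frac discards the lowest-likelihood fraction (stabilised
# variant).
harmonic_mean_mlog <- function(ll, trunc_frac = 0) {
  if (trunc_frac > 0) {
    ll <- ll[ll >= stats::quantile(ll, trunc_frac)]
  }
  x <- -ll
  m <- max(x)
  -(m + log(mean(exp(x - m))))
}

ess_simple <- function(x) {
  n <- length(x)
  if (n < 10L || stats::sd(x) < 1e-12) return(n)
  ac <- stats::acf(x, lag.max = min(100L, n - 1L), plot = FALSE)$acf[-1L]
  pos <- which(ac < 0.05)
  cut <- if (length(pos)) pos[1L] else length(ac)
  n / (1 + 2 * sum(ac[seq_len(cut)]))
}

#' Log Bayes factor between two posterior runs
#'
#' `LBF = Mlog(run2) - Mlog(run2's competitor)` on the harmonic-mean
#' marginal log-likelihoods (replicate-averaged). Positive values support
#' `run2`. Conventionally `run1` is the simpler model (panmixia).
#'
#' @param run1,run2 `posterior_run` objects fitted to the same data.
#' @param truncated use the stabilised truncated harmonic mean.
#' @return list with `lbf`, the two Mlogs, and a qualitative `support`
#'   label.
#' @export
compare_models <- function(run1, run2, truncated = FALSE) {
  m1 <- if (truncated) run1$mlog_truncated else run1$mlog
  m2 <- if (truncated) run2$mlog_truncated else run2$mlog
  lbf <- m2 - m1
  support <- if (lbf > 2) "run2 (strong)" else if (lbf > 0) "run2 (weak)"
  else if (lbf > -2) "run1 (weak)" else "run1 (strong)"
  list(lbf = lbf, mlog1 = m1, mlog2 = m2, support = support)
}

#' Effective number of migrants per generation
#'
#' `Nem[j -> i] = M[j, i] * theta[i] / 4`, computed from posterior modes of
#' an island-model run (or from explicit theta and M).
#'
#' @param run a `posterior_run` with island flavor, or a list with
#'   `theta_mode` and `m_mode`.
#' @return k x k matrix of Nem, zero diagonal; `Nem[j, i]` is gene flow
#'   into deme `i` from deme `j`.
#' @export
effective_migrants <- function(run) {
  if (inherits(run, "posterior_run") && run$model$flavor != "island") {
    stop("Nem is defined for the island model")
  }
  theta <- run$theta_mode
  M <- run$m_mode
  k <- length(theta)
  nem <- M * rep(theta, each = k) / 4
  diag(nem) <- 0
  nem
}
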