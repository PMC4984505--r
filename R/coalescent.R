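# Internal coalescent machinery shared by the synthetic-data generator, the
# bottleneck / FST-outlier validation simulations, and the structured
# coalescent MCMC.
#
# Time scale: mutation-scaled, as in coalescent samplers for microsatellite
# data. In a deme of scaled size theta a specific lineage pair coalesces at
# rate 2/theta; a lineage resident in deme i jumps (backwards in time) to
# deme j at rate M[j, i], where M[j, i] is the mutation-scaled immigration
# rate into i from j; mutations occur at rate 1 per lineage per unit time,
# so branch lengths are expected mutation counts.

#' Simulate a structured-coalescent genealogy with migration
#'
#' @param n_per_deme integer vector of sampled gene copies per deme.
#' @param theta positive vector of per-deme mutation-scaled sizes.
#' @param M k x k matrix of mutation-scaled immigration rates, `M[j, i]` =
#'   rate into deme `i` from deme `j`; diagonal ignored. With one deme pass
#'   a 1 x 1 zero matrix.
#' @param max_events safety cap on total events (coalescences + migrations).
#' @return a `genealogy`: list with `n_tips`, `tip_deme`, `edge` (2-column
#'   parent/child), `edge_length`, `node_time` (tips first, times
#'   increasing into the past), `n_mig` (migration event count) and
#'   `stats`, the sufficient statistics of the structured-coalescent
#'   density: `A[i] = sum dt * k_i (k_i - 1)`, `B[i] = sum dt * k_i`,
#'   `C[i]` = coalescences in deme i, `D[i, j]` = migration events i -> j
#'   (backwards in time), `forced` flag for zero-density join events.
#' @keywords internal
rcoal_structured <- function(n_per_deme, theta, M = NULL,
                             max_events = 2e5) {
  k <- length(n_per_deme)
  if (is.null(M)) M <- matrix(0, k, k)
  n <- sum(n_per_deme)
  if (n < 2L) stop("need at least two sampled genes")
  tip_deme <- rep(seq_len(k), n_per_deme)
  act_id <- seq_len(n)
  act_deme <- tip_deme
  node_time <- numeric(2L * n - 1L)
  edge <- matrix(0L, 2L * (n - 1L), 2L)
  elen <- numeric(2L * (n - 1L))
  e_i <- 0L
  lin_start <- numeric(2L * n - 1L)  # start time by node id
  next_node <- n + 1L
  t_now <- 0
  A <- B <- Cc <- numeric(k)
  D <- matrix(0, k, k)
  forced <- FALSE
  n_mig <- 0L
  n_ev <- 0L
  off <- M; diag(off) <- 0
  mig_in <- colSums(off)  # total backward jump rate per lineage in deme i
  kk <- tabulate(act_deme, nbins = k)
  while (length(act_id) > 1L) {
    r_coal <- kk * (kk - 1L) / theta
    r_mig <- kk * mig_in
    r_tot <- sum(r_coal) + sum(r_mig)
    n_ev <- n_ev + 1L
    if (n_ev > max_events) stop("structured coalescent: event cap exceeded")
    if (r_tot <= 0) {
      # completely isolated demes (all M = 0): join stranded lineages by
      # deep forced coalescences so the isolation limit stays simulable;
      # such genealogies have zero density under any finite-rate model
      dt <- 10 * max(theta)
      forced <- TRUE
      t_now <- t_now + dt
      A <- A + dt * kk * (kk - 1L); B <- B + dt * kk
      pair <- order(act_deme)[c(1L, length(act_id))]
      d <- act_deme[pair[1L]]
      d_other <- act_deme[pair[2L]]
    } else {
      dt <- stats::rexp(1L, r_tot)
      t_now <- t_now + dt
      A <- A + dt * kk * (kk - 1L); B <- B + dt * kk
      u <- stats::runif(1L) * r_tot
      if (u > sum(r_coal)) {
        d <- sample.int(k, 1L, prob = r_mig)
        cand <- which(act_deme == d)
        li <- cand[sample.int(length(cand), 1L)]
        j <- sample.int(k, 1L, prob = off[, d])
        act_deme[li] <- j
        kk[d] <- kk[d] - 1L; kk[j] <- kk[j] + 1L
        n_mig <- n_mig + 1L
        D[d, j] <- D[d, j] + 1
        next
      }
      d <- sample.int(k, 1L, prob = r_coal)
      cand <- which(act_deme == d)
      pair <- cand[sample.int(length(cand), 2L)]
      Cc[d] <- Cc[d] + 1
      d_other <- d
    }
    c1 <- act_id[pair[1L]]; c2 <- act_id[pair[2L]]
    node_time[next_node] <- t_now
    edge[e_i + 1L, ] <- c(next_node, c1)
    edge[e_i + 2L, ] <- c(next_node, c2)
    elen[e_i + 1L] <- t_now - lin_start[c1]
    elen[e_i + 2L] <- t_now - lin_start[c2]
    e_i <- e_i + 2L
    act_id <- c(act_id[-pair], next_node)
    act_deme <- c(act_deme[-pair], d)
    lin_start[next_node] <- t_now
    kk[d] <- kk[d] - 1L
    kk[d_other] <- kk[d_other] - 1L
    kk[d] <- kk[d] + 1L
    next_node <- next_node + 1L
  }
  structure(list(
    n_tips = n, tip_deme = tip_deme, edge = edge, edge_length = elen,
    node_time = node_time,
    stats = list(A = A, B = B, C = Cc, D = D, forced = forced),
    n_mig = n_mig
  ), class = "genealogy")
}

# log density of a structured-coalescent genealogy under (theta, M),
# computed from the genealogy's sufficient statistics:
# sum_i [ -A_i / theta_i - B_i * mig_in_i + C_i log(2 / theta_i) ]
#   + sum_{i != j} D_ij log M[j, i]
dstructured_log <- function(gen, theta, M) {
  s <- gen$stats
  if (s$forced) return(-Inf)
  k <- length(theta)
  off <- M; diag(off) <- 0
  mig_in <- colSums(off)
  ll <- sum(-s$A / theta - s$B * mig_in + s$C * log(2 / theta))
  if (any(s$D > 0)) {
    idx <- which(s$D > 0, arr.ind = TRUE)
    # D[i, j] counts backward jumps i -> j, whose rate is M[j, i]
    ll <- ll + sum(s$D[idx] * log(off[cbind(idx[, 2L], idx[, 1L])]))
  }
  ll
}

# Kingman coalescent (single deme) in coalescent units: returns the same
# genealogy structure with theta = 2 equivalence (pair rate 1).
rkingman <- function(n) {
  g <- rcoal_structured(n, theta = 2, M = matrix(0, 1, 1))
  g
}

# total branch length
tree_length <- function(gen) sum(gen$edge_length)

# drop ladder (stepwise) mutations on a genealogy; rate per unit branch
# length; returns tip allele sizes. Two-phase model: with probability
# `p_multi` complement of p_smm a mutation takes 1 + Geometric extra steps
# tuned to `var_tpm`.
ladder_mutations <- function(gen, rate = 1, root_allele = 50L,
                             model = c("smm", "tpm"), p_smm = 1,
                             var_tpm = 0.1) {
  model <- match.arg(model)
  n_nodes <- 2L * gen$n_tips - 1L
  state <- integer(n_nodes)
  root <- n_nodes  # last created node is the MRCA
  state[root] <- root_allele
  # process edges parent->child in decreasing parent id (root first)
  ord <- order(-gen$edge[, 1L])
  q_geom <- if (var_tpm > 0) {
    (-1 + sqrt(1 + 4 * var_tpm)) / (2 * var_tpm)
  } else 1
  for (r in ord) {
    par <- gen$edge[r, 1L]; ch <- gen$edge[r, 2L]
    nm <- stats::rpois(1L, rate * gen$edge_length[r])
    s <- state[par]
    if (nm > 0L) {
      sgn <- sample(c(-1L, 1L), nm, replace = TRUE)
      sz <- rep(1L, nm)
      if (model == "tpm" && p_smm < 1) {
        multi <- stats::runif(nm) > p_smm
        sz[multi] <- 1L + stats::rgeom(sum(multi), q_geom)
      }
      s <- s + sum(sgn * sz)
    }
    state[ch] <- s
  }
  pmax(state[seq_len(gen$n_tips)], 2L)  # keep sizes positive
}

# infinite-alleles mutations: every mutation creates a brand-new allele;
# a tip's allele is set by the most recent mutation on its root path.
iam_mutations <- function(gen, rate = 1, root_allele = 1L) {
  n_nodes <- 2L * gen$n_tips - 1L
  state <- integer(n_nodes)
  state[n_nodes] <- root_allele
  next_al <- root_allele + 1L
  for (r in order(-gen$edge[, 1L])) {
    par <- gen$edge[r, 1L]; ch <- gen$edge[r, 2L]
    if (stats::rpois(1L, rate * gen$edge_length[r]) > 0L) {
      state[ch] <- next_al
      next_al <- next_al + 1L
    } else {
      state[ch] <- state[par]
    }
  }
  state[seq_len(gen$n_tips)]
}

# drop point mutations on a sequence along a genealogy; kappa is the
# transition:transversion rate ratio. Returns tip sequences.
seq_mutations <- function(gen, root_seq, rate_per_seq = 1, kappa = 8) {
  L <- nchar(root_seq)
  n_nodes <- 2L * gen$n_tips - 1L
  state <- vector("list", n_nodes)
  root <- n_nodes
  state[[root]] <- strsplit(root_seq, "")[[1]]
  pur <- c("A", "G")
  p_ts <- kappa / (kappa + 2)
  ord <- order(-gen$edge[, 1L])
  for (r in ord) {
    par <- gen$edge[r, 1L]; ch <- gen$edge[r, 2L]
    s <- state[[par]]
    nm <- stats::rpois(1L, rate_per_seq * gen$edge_length[r])
    if (nm > 0L) {
      for (site in sample.int(L, nm, replace = TRUE)) {
        base <- s[site]
        if (stats::runif(1L) < p_ts) {
          s[site] <- switch(base, A = "G", G = "A", C = "T", T = "C")
        } else {
          s[site] <- sample(setdiff(c("A", "C", "G", "T"),
                                    c(base, switch(base, A = "G", G = "A",
                                                   C = "T", T = "C"))), 1L)
        }
      }
    }
    state[[ch]] <- s
  }
  vapply(state[seq_len(gen$n_tips)], paste, "", collapse = "")
}

# convert an internal genealogy to an ape phylo (for skylines / export)
genealogy_to_phylo <- function(gen, tip_labels = NULL) {
  n <- gen$n_tips
  if (is.null(tip_labels)) tip_labels <- paste0("t", seq_len(n))
  # ape wants internal nodes numbered n+1 .. 2n-1 with root first; our
  # internal ids already follow creation order (root = 2n-1), so remap
  # internal node x -> n + (2n-1 - x) + ... simplest: root must be n+1.
  int_ids <- (n + 1L):(2L * n - 1L)
  new_int <- stats::setNames(rev(int_ids), int_ids)  # oldest gets n+1
  remap <- function(x) ifelse(x > n, new_int[as.character(x)], x)
  edge <- cbind(remap(gen$edge[, 1L]), remap(gen$edge[, 2L]))
  phy <- list(edge = edge, edge.length = gen$edge_length,
              tip.label = tip_labels, Nnode = n - 1L)
  class(phy) <- "phylo"
  phy <- ape::reorder.phylo(phy, "cladewise")
  phy
}
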