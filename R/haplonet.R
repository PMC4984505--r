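#' Transition/transversion-weighted distance between two haplotypes
#'
#' Site-wise distance in which transitions (A<->G, C<->T) score 1 and
#' transversions score `tv_weight` (default 8, reflecting the strong
#' transition bias of vertebrate mtDNA).
#'
#' @param h1,h2 equal-length DNA strings over A,C,G,T.
#' @param tv_weight transversion:transition weight ratio.
#' @return integer-valued score (0 when identical).
#' @export
weighted_distance <- function(h1, h2, tv_weight = 8) {
  a <- strsplit(h1, "")[[1]]
  b <- strsplit(h2, "")[[1]]
  if (length(a) != length(b)) stop("length mismatch")
  diff <- a != b
  if (!any(diff)) return(0)
  pur <- c("A", "G")
  ts <- (a %in% pur) == (b %in% pur) & diff
  sum(ts) + tv_weight * sum(diff & !ts)
}

hap_dist_matrix <- function(seqs, tv_weight = 8) {
  k <- length(seqs)
  d <- matrix(0, k, k)
  if (k < 2L) return(d)
  chars <- strsplit(seqs, "")
  pur <- c("A", "G")
  for (i in seq_len(k - 1L)) {
    ai <- chars[[i]]
    pi_ <- ai %in% pur
    for (j in (i + 1L):k) {
      bj <- chars[[j]]
      diff <- ai != bj
      ts <- sum(diff & (pi_ == (bj %in% pur)))
      tv <- sum(diff) - ts
      d[i, j] <- d[j, i] <- ts + tv_weight * tv
    }
  }
  d
}

# minimax connection threshold sigma(u,v): the largest edge weight on the
# path joining u and v in any minimum spanning tree (the weight at which the
# two nodes' components merge under Kruskal).
minimax_threshold <- function(d) {
  k <- nrow(d)
  sig <- matrix(0, k, k)
  if (k < 2L) return(sig)
  comp <- as.list(seq_len(k))
  ucomp <- seq_len(k)
  ut <- d[upper.tri(d)]
  for (w in sort(unique(ut))) {
    idx <- which(d == w & upper.tri(d), arr.ind = TRUE)
    merged <- FALSE
    for (r in seq_len(nrow(idx))) {
      ci <- ucomp[idx[r, 1L]]
      cj <- ucomp[idx[r, 2L]]
      if (ci != cj) {
        for (a in comp[[ci]]) for (b in comp[[cj]]) sig[a, b] <- sig[b, a] <- w
        comp[[ci]] <- c(comp[[ci]], comp[[cj]])
        ucomp[comp[[cj]]] <- ci
        comp[[cj]] <- integer()
        merged <- TRUE
      }
    }
    if (merged && all(ucomp == ucomp[1L])) break
  }
  sig
}

# epsilon-relaxed minimum spanning network: link (u,v) iff
# d(u,v) <= sigma(u,v) + epsilon. epsilon = 0 gives the MSN with all ties.
relaxed_msn_edges <- function(d, epsilon = 0) {
  sig <- minimax_threshold(d)
  k <- nrow(d)
  out <- NULL
  for (i in seq_len(k - 1L)) {
    for (j in (i + 1L):k) {
      if (d[i, j] <= sig[i, j] + epsilon) {
        out <- rbind(out, c(i, j, d[i, j]))
      }
    }
  }
  colnames(out) <- c("u", "v", "w")
  as.data.frame(out)
}

site_median <- function(a, b, c_) {
  # per-site majority of three sequences; when all three differ the value of
  # the first argument is kept (deterministic quasi-median simplification)
  out <- a
  bc <- b == c_
  out[bc] <- b[bc]
  out
}

#' Median-joining haplotype network
#'
#' Builds the epsilon-relaxed minimum spanning network over observed
#' haplotypes on the transversion-weighted distance, then iteratively adds
#' median vectors (per-site majority consensus of linked triplets) whose
#' connection cost is within `epsilon` of the best candidate, until no
#' further median improves the network or `max_iter` is reached. Median
#' vectors that end up with fewer than three links are removed.
#'
#' @param haps a `haplotype_table` (see [collapse_haplotypes()]) or a
#'   character vector of distinct haplotype sequences.
#' @param epsilon relaxation parameter of the network (0 = strict minimum
#'   spanning network; larger values admit more alternative links and
#'   medians).
#' @param tv_weight transversion weight, see [weighted_distance()].
#' @param max_iter cap on median-addition sweeps; a message is emitted if it
#'   is reached.
#' @return an object of class `haplotype_network`: `seqs` (observed then
#'   median sequences), `observed` (logical), `freq` (counts, 0 for
#'   medians), `edges` (data.frame u, v, w), `epsilon`, `tv_weight`.
#' @export
median_joining <- function(haps, epsilon = 35, tv_weight = 8,
                           max_iter = 10L) {
  if (inherits(haps, "haplotype_table")) {
    seqs <- haps$seqs
    freq <- haps$total
  } else {
    seqs <- as.character(haps)
    freq <- rep(1L, length(seqs))
  }
  if (anyDuplicated(seqs)) stop("haplotypes must be distinct")
  n_obs <- length(seqs)
  observed <- rep(TRUE, n_obs)
  if (n_obs == 1L) {
    return(structure(list(seqs = seqs, observed = observed, freq = freq,
                          edges = data.frame(u = integer(), v = integer(),
                                             w = numeric()),
                          epsilon = epsilon, tv_weight = tv_weight),
                     class = "haplotype_network"))
  }
  iter <- 0L
  tried <- character()  # medians ever added; never re-added once pruned
  repeat {
    iter <- iter + 1L
    d <- hap_dist_matrix(seqs, tv_weight)
    edges <- relaxed_msn_edges(d, epsilon)
    # drop under-connected medians, repeat until stable
    repeat {
      deg <- tabulate(c(edges$u, edges$v), nbins = length(seqs))
      drop <- which(!observed & deg <= 2L)
      if (!length(drop)) break
      keep <- setdiff(seq_along(seqs), drop)
      seqs <- seqs[keep]
      observed <- observed[keep]
      freq <- freq[keep]
      d <- hap_dist_matrix(seqs, tv_weight)
      edges <- relaxed_msn_edges(d, epsilon)
    }
    if (iter > max_iter) {
      message("median_joining: iteration cap reached before fixation")
      break
    }
    # candidate medians from linked triplets (u-v linked, w linked to u or v)
    adj <- vector("list", length(seqs))
    for (r in seq_len(nrow(edges))) {
      adj[[edges$u[r]]] <- c(adj[[edges$u[r]]], edges$v[r])
      adj[[edges$v[r]]] <- c(adj[[edges$v[r]]], edges$u[r])
    }
    chars <- strsplit(seqs, "")
    cand <- character()
    cost <- numeric()
    for (r in seq_len(nrow(edges))) {
      u <- edges$u[r]; v <- edges$v[r]
      for (w in setdiff(union(adj[[u]], adj[[v]]), c(u, v))) {
        m <- paste(site_median(chars[[u]], chars[[v]], chars[[w]]),
                   collapse = "")
        if (m %in% seqs || m %in% cand || m %in% tried) next
        cc <- weighted_distance(m, seqs[u], tv_weight) +
          weighted_distance(m, seqs[v], tv_weight) +
          weighted_distance(m, seqs[w], tv_weight)
        # only medians that shorten the local star of the triplet
        star <- d[u, v] + min(d[u, w], d[v, w])
        if (cc < star) {
          cand <- c(cand, m)
          cost <- c(cost, cc)
        }
      }
    }
    if (!length(cand)) break
    keep <- cost <= min(cost) + epsilon
    seqs <- c(seqs, cand[keep])
    observed <- c(observed, rep(FALSE, sum(keep)))
    freq <- c(freq, rep(0L, sum(keep)))
    tried <- c(tried, cand[keep])
  }
  structure(list(seqs = seqs, observed = observed, freq = freq,
                 edges = edges, epsilon = epsilon, tv_weight = tv_weight),
            class = "haplotype_network")
}

#' @export
print.haplotype_network <- function(x, ...) {
  cat(sprintf(
    "haplotype network: %d observed + %d median nodes, %d links (epsilon=%g, tv=%g)\n",
    sum(x$observed), sum(!x$observed), nrow(x$edges), x$epsilon,
    x$tv_weight))
  if (!is.null(x$trees)) {
    cat(sprintf("shortest trees: %d%s (length %g)\n", length(x$trees),
                if (isTRUE(x$trees_truncated)) "+ (truncated)" else "",
                x$tree_length))
  }
  invisible(x)
}

graph_components <- function(n, edges) {
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (r in seq_len(nrow(edges))) {
      a <- comp[edges$u[r]]; b <- comp[edges$v[r]]
      if (a != b) {
        comp[comp == max(a, b)] <- min(a, b)
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  match(comp, unique(comp))
}

# enumerate spanning trees of the graph (edges data.frame u,v,w over nodes
# 1..n) with total weight == target, by include/exclude branching with an
# MST completion bound. Returns list of edge-index vectors; capped.
enumerate_min_trees <- function(n, edges, target, cap = 10000L) {
  m <- nrow(edges)
  ord <- order(edges$w, edges$u, edges$v)
  edges <- edges[ord, , drop = FALSE]
  out <- list()
  truncated <- FALSE

  mst_bound <- function(chosen, from) {
    # Kruskal completion using chosen edges plus edges from position `from`
    comp <- seq_len(n)
    find <- function(x) { while (comp[x] != x) x <- comp[x]; x }
    wsum <- 0
    cnt <- 0L
    for (e in chosen) {
      a <- find(edges$u[e]); b <- find(edges$v[e])
      if (a != b) { comp[a] <- b; cnt <- cnt + 1L; wsum <- wsum + edges$w[e] }
      else return(Inf)  # cycle among chosen
    }
    i <- from
    while (cnt < n - 1L && i <= m) {
      a <- find(edges$u[i]); b <- find(edges$v[i])
      if (a != b) { comp[a] <- b; cnt <- cnt + 1L; wsum <- wsum + edges$w[i] }
      i <- i + 1L
    }
    if (cnt < n - 1L) Inf else wsum
  }

  rec <- function(pos, chosen) {
    if (truncated) return()
    if (length(chosen) == n - 1L) {
      w <- sum(edges$w[chosen])
      if (abs(w - target) < 1e-9) {
        out[[length(out) + 1L]] <<- sort(ord[chosen])
        if (length(out) >= cap) truncated <<- TRUE
      }
      return()
    }
    if (pos > m) return()
    # include edges[pos]
    if (mst_bound(c(chosen, pos), pos + 1L) <= target + 1e-9) {
      rec(pos + 1L, c(chosen, pos))
    }
    # exclude edges[pos]
    if (!truncated && mst_bound(chosen, pos + 1L) <= target + 1e-9) {
      rec(pos + 1L, chosen)
    }
  }
  if (n == 1L) return(list(trees = list(integer()), truncated = FALSE))
  rec(1L, integer())
  list(trees = out, truncated = truncated)
}

#' Maximum-parsimony post-processing of a median-joining network
#'
#' Enumerates the minimum-length trees that connect all observed haplotypes
#' inside the network (median vectors are optional Steiner points) and
#' deletes every node and link that appears in none of them. The surviving
#' trees are stored on the network for downstream ambiguity resolution.
#'
#' @param net a `haplotype_network`.
#' @param max_trees cap on enumerated shortest trees (deterministic
#'   lexicographic order; truncation is flagged).
#' @param max_medians cap on the number of median vectors enumerated over as
#'   subsets; above it, only medians retained in the full-graph solution are
#'   considered and the result is flagged approximate.
#' @return the pruned `haplotype_network`, with `trees` (list of edge
#'   data.frames), `tree_length` and `trees_truncated` fields.
#' @export
mp_prune <- function(net, max_trees = 10000L, max_medians = 12L) {
  n_all <- length(net$seqs)
  obs <- which(net$observed)
  med <- which(!net$observed)
  edges <- net$edges
  if (length(obs) < 2L || nrow(edges) == 0L) {
    net$trees <- list(edges)
    net$tree_length <- sum(edges$w)
    net$trees_truncated <- FALSE
    return(net)
  }
  approx <- FALSE
  if (length(med) > max_medians) {
    # keep only medians used by one MST of the whole graph
    full <- enumerate_min_trees(n_all, edges, target = {
      b <- kruskal_weight(n_all, edges); b
    }, cap = 1L)
    used <- unique(unlist(lapply(full$trees, function(t)
      c(edges$u[t], edges$v[t]))))
    med <- intersect(med, used)
    approx <- TRUE
    if (length(med) > max_medians) med <- med[seq_len(max_medians)]
    message("mp_prune: median-subset enumeration truncated (approximate)")
  }
  best_w <- Inf
  best <- list()  # list of (nodes, tree edge-index into subgraph edges, edges df)
  truncated <- FALSE
  subsets <- if (length(med)) {
    lapply(seq_len(2^length(med)) - 1L, function(mask)
      med[bitwAnd(mask, 2^(seq_along(med) - 1L)) > 0])
  } else list(integer())
  for (S in subsets) {
    nodes <- sort(c(obs, S))
    sub <- edges[edges$u %in% nodes & edges$v %in% nodes, , drop = FALSE]
    if (!nrow(sub)) next
    remap <- match(seq_len(n_all), nodes)
    sub2 <- data.frame(u = remap[sub$u], v = remap[sub$v], w = sub$w)
    if (max(graph_components(length(nodes), sub2)) > 1L) next
    w <- kruskal_weight(length(nodes), sub2)
    if (w < best_w - 1e-9) { best_w <- w; best <- list() }
    if (w <= best_w + 1e-9) {
      best[[length(best) + 1L]] <- list(nodes = nodes, edges = sub2,
                                        raw = sub)
    }
  }
  if (!length(best)) stop("network not connected over observed haplotypes")
  trees <- list()
  for (bb in best) {
    en <- enumerate_min_trees(length(bb$nodes), bb$edges, best_w,
                              cap = max_trees - length(trees))
    truncated <- truncated || en$truncated
    for (t in en$trees) {
      df <- bb$raw[t, , drop = FALSE]
      rownames(df) <- NULL
      trees[[length(trees) + 1L]] <- df
    }
    if (length(trees) >= max_trees) { truncated <- TRUE; break }
  }
  keep_nodes <- sort(unique(unlist(lapply(trees, function(t) c(t$u, t$v)))))
  keep_nodes <- union(keep_nodes, obs)
  ekey <- function(e) paste(pmin(e$u, e$v), pmax(e$u, e$v))
  keys <- unique(unlist(lapply(trees, ekey)))
  keep_e <- edges[ekey(edges) %in% keys, , drop = FALSE]
  remap <- match(seq_len(n_all), keep_nodes)
  out <- net
  out$seqs <- net$seqs[keep_nodes]
  out$observed <- net$observed[keep_nodes]
  out$freq <- net$freq[keep_nodes]
  out$edges <- data.frame(u = remap[keep_e$u], v = remap[keep_e$v],
                          w = keep_e$w)
  out$trees <- lapply(trees, function(t)
    data.frame(u = remap[t$u], v = remap[t$v], w = t$w))
  out$tree_length <- best_w
  out$trees_truncated <- truncated
  out$approximate <- approx
  out
}

kruskal_weight <- function(n, edges) {
  comp <- seq_len(n)
  find <- function(x) { while (comp[x] != x) x <- comp[x]; x }
  w <- 0
  cnt <- 0L
  for (r in order(edges$w)) {
    a <- find(edges$u[r]); b <- find(edges$v[r])
    if (a != b) { comp[a] <- b; w <- w + edges$w[r]; cnt <- cnt + 1L }
    if (cnt == n - 1L) break
  }
  if (cnt < n - 1L) Inf else w
}

tree_paths_to <- function(tree_edges, n_nodes, targets) {
  # adjacency of the tree; returns for each node the (first-hit target,
  # path weight) by BFS outward that stops at targets
  adj <- vector("list", n_nodes)
  for (r in seq_len(nrow(tree_edges))) {
    u <- tree_edges$u[r]; v <- tree_edges$v[r]; w <- tree_edges$w[r]
    adj[[u]] <- rbind(adj[[u]], c(v, w))
    adj[[v]] <- rbind(adj[[v]], c(u, w))
  }
  adj
}

#' Assign haplotypes to matrilines around the most frequent haplotypes
#'
#' The `k_main` most frequent observed haplotypes anchor the matrilines
#' (labelled A, B, C, ... in decreasing frequency). Every other observed
#' haplotype is assigned to the anchor it reaches first (without passing
#' another anchor) in each enumerated shortest tree; the anchor chosen in
#' the majority of trees wins, with ties broken by smaller path weight and
#' then by anchor frequency.
#'
#' @param net a pruned `haplotype_network` (see [mp_prune()]); an unpruned
#'   network is pruned first.
#' @param k_main number of anchor haplotypes (default 3).
#' @return an object of class `matriline_assignment`: data.frame `table`
#'   with haplotype sequence, frequency, matriline label; `mains` (anchor
#'   indices); `labels` (named vector seq -> label, NA when unassigned).
#' @export
assign_matrilines <- function(net, k_main = 3L) {
  if (is.null(net$trees)) net <- mp_prune(net)
  obs <- which(net$observed)
  if (length(obs) < k_main) stop("fewer observed haplotypes than k_main")
  ord <- obs[order(-net$freq[obs])]
  mains <- ord[seq_len(k_main)]
  lab <- LETTERS[seq_len(k_main)]
  n_nodes <- length(net$seqs)
  sat <- setdiff(obs, mains)
  votes <- matrix(0, length(sat), k_main,
                  dimnames = list(NULL, lab))
  wsum <- matrix(0, length(sat), k_main)
  unassigned <- logical(length(sat))
  for (tr in net$trees) {
    adj <- tree_paths_to(tr, n_nodes, mains)
    for (si in seq_along(sat)) {
      s <- sat[si]
      # BFS from s; do not expand beyond a main node
      hit <- rep(NA_real_, k_main)
      dist <- rep(Inf, n_nodes)
      dist[s] <- 0
      queue <- s
      while (length(queue)) {
        x <- queue[1L]; queue <- queue[-1L]
        if (x %in% mains && x != s) next
        nb <- adj[[x]]
        if (is.null(nb)) next
        for (r in seq_len(nrow(nb))) {
          y <- nb[r, 1L]; w <- nb[r, 2L]
          if (dist[x] + w < dist[y]) {
            dist[y] <- dist[x] + w
            queue <- c(queue, y)
          }
        }
      }
      reach <- which(is.finite(dist[mains]))
      if (!length(reach)) { unassigned[si] <- TRUE; next }
      dd <- dist[mains[reach]]
      cand <- reach[dd == min(dd)]
      if (length(cand) > 1L) {
        f <- net$freq[mains[cand]]
        cand <- cand[which.max(f)]
      }
      votes[si, cand[1L]] <- votes[si, cand[1L]] + 1
      wsum[si, cand[1L]] <- wsum[si, cand[1L]] + min(dd)
    }
  }
  assign <- character(length(sat))
  for (si in seq_along(sat)) {
    if (all(votes[si, ] == 0)) { assign[si] <- NA_character_; next }
    v <- votes[si, ]
    top <- which(v == max(v))
    if (length(top) > 1L) {
      mw <- wsum[si, top] / v[top]
      top <- top[mw == min(mw)]
      if (length(top) > 1L) top <- top[which.max(net$freq[mains[top]])]
    }
    assign[si] <- lab[top[1L]]
  }
  if (any(is.na(assign))) {
    warning(sum(is.na(assign)),
            " haplotype(s) in components without an anchor left unassigned")
  }
  labels <- setNames(rep(NA_character_, length(obs)), net$seqs[obs])
  labels[net$seqs[mains]] <- lab
  labels[net$seqs[sat]] <- assign
  tab <- data.frame(
    haplotype = net$seqs[obs],
    freq = net$freq[obs],
    matriline = unname(labels[net$seqs[obs]]),
    is_main = obs %in% mains,
    stringsAsFactors = FALSE
  )
  tab <- tab[order(-tab$freq), ]
  rownames(tab) <- NULL
  structure(list(table = tab, mains = mains, labels = labels,
                 main_seqs = net$seqs[mains]),
            class = "matriline_assignment")
}

#' @export
print.matriline_assignment <- function(x, ...) {
  cat("matriline assignment:", nrow(x$table), "haplotypes ->",
      paste(names(table(x$table$matriline)), collapse = "/"), "\n")
  print(table(x$table$matriline))
  invisible(x)
}

#' Per-individual deme labels from a matriline assignment
#'
#' Joins a matriline assignment back onto the individuals of an alignment,
#' producing the matriline x cohort "deme" label used by all downstream
#' nuclear analyses.
#'
#' @param assignment a `matriline_assignment`.
#' @param aln the `mt_alignment` the haplotypes came from.
#' @return data.frame with id, cohort, haplotype, matriline, deme
#'   (`"<cohort><matriline>"`; NA matriline propagates).
#' @export
deme_labels <- function(assignment, aln) {
  m <- unname(assignment$labels[aln$seq])
  data.frame(
    id = aln$ids,
    cohort = aln$cohort,
    haplotype = aln$seq,
    matriline = m,
    deme = ifelse(is.na(m), NA_character_, paste0(aln$cohort, m)),
    stringsAsFactors = FALSE
  )
}

#' Unweighted divergence (base pairs) between two haplotypes
#' @param h1,h2 equal-length DNA strings.
#' @return Hamming distance in base pairs.
#' @export
bp_divergence <- function(h1, h2) {
  a <- strsplit(h1, "")[[1]]; b <- strsplit(h2, "")[[1]]
  if (length(a) != length(b)) stop("length mismatch")
  sum(a != b)
}
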