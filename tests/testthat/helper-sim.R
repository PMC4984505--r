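# shared builders for tests: small genotype datasets with known structure

# one-deme (panmictic) dataset split over fake deme labels
sim_panmictic_genotypes <- function(theta = 3, n_loci = 6, n_ind = 30,
                                    labels = c("D1", "D2", "D3")) {
  a1 <- a2 <- matrix(NA_integer_, n_ind, n_loci)
  for (l in seq_len(n_loci)) {
    gen <- matriflow:::rcoal_structured(2L * n_ind, theta, matrix(0, 1, 1))
    al <- matriflow:::ladder_mutations(gen, rate = 1, root_allele = 50L)
    a1[, l] <- al[seq(1L, length(al), 2L)]
    a2[, l] <- al[seq(2L, length(al), 2L)]
  }
  genotype_matrix(sprintf("i%03d", seq_len(n_ind)),
                  rep(labels, length.out = n_ind), a1, a2)
}

# k-deme island dataset with explicit theta and M
sim_island_genotypes <- function(theta, M, n_loci, n_per_deme) {
  k <- length(theta)
  npd <- 2L * n_per_deme
  n_ind <- sum(n_per_deme)
  a1 <- a2 <- matrix(NA_integer_, n_ind, n_loci)
  for (l in seq_len(n_loci)) {
    gen <- matriflow:::rcoal_structured(npd, theta, M)
    al <- matriflow:::ladder_mutations(gen, rate = 1, root_allele = 50L)
    a1[, l] <- al[seq(1L, length(al), 2L)]
    a2[, l] <- al[seq(2L, length(al), 2L)]
  }
  genotype_matrix(sprintf("i%03d", seq_len(n_ind)),
                  rep(paste0("D", seq_len(k)), n_per_deme), a1, a2)
}

# random alignment of related sequences (mutations on a shared base)
sim_related_seqs <- function(n, L = 30, max_steps = 3) {
  base <- paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
                collapse = "")
  vapply(seq_len(n), function(i) {
    v <- strsplit(base, "")[[1]]
    for (s in seq_len(sample.int(max_steps + 1L, 1L) - 1L)) {
      p <- sample.int(L, 1L)
      v[p] <- sample(setdiff(c("A", "C", "G", "T"), v[p]), 1L)
    }
    paste(v, collapse = "")
  }, "")
}
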