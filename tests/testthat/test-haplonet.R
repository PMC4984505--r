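test_that("weighted distance scores transitions 1 and transversions 8", {
  expect_equal(weighted_distance("AAA", "AAA"), 0)
  expect_equal(weighted_distance("AAA", "AAG"), 1)
  expect_equal(weighted_distance("AAA", "AAT"), 8)
  expect_equal(weighted_distance("ACGT", "GTAC", tv_weight = 8),
               4)  # all four differences are transitions
  expect_equal(weighted_distance("AACC", "CTGG", tv_weight = 8),
               8 + 8 + 8 + 8)
  expect_error(weighted_distance("AA", "AAA"), "length")
})

test_that("median joining handles degenerate and tiny inputs", {
  net1 <- median_joining("ACGT")
  expect_equal(nrow(net1$edges), 0L)
  net2 <- median_joining(c("AAAA", "AAAG"), epsilon = 0)
  expect_equal(nrow(net2$edges), 1L)
  expect_equal(net2$edges$w, 1)
})

test_that("median vectors arise as triplet consensus", {
  net <- median_joining(c("AAG", "AGA", "GAA"), epsilon = 0)
  expect_true("AAA" %in% net$seqs)
  expect_equal(sum(!net$observed), 1L)
  # median has full degree
  mid <- which(net$seqs == "AAA")
  expect_gte(sum(net$edges$u == mid | net$edges$v == mid), 3L)
})

test_that("at epsilon 0 the network contains the minimum spanning network", {
  # containment in the threshold sense: every MSN link (u, v) is realised
  # by a path whose links all weigh <= d(u, v)
  set.seed(7)
  for (rep in 1:12) {
    hs <- unique(sim_related_seqs(sample(4:12, 1), L = 15, max_steps = 4))
    if (length(hs) < 3) next
    net <- median_joining(hs, epsilon = 0)
    d <- matriflow:::hap_dist_matrix(hs)
    msn <- matriflow:::relaxed_msn_edges(d, 0)
    idx <- match(hs, net$seqs)
    nn <- length(net$seqs)
    for (r in seq_len(nrow(msn))) {
      sub <- net$edges[net$edges$w <= msn$w[r] + 1e-9, , drop = FALSE]
      comp <- matriflow:::graph_components(nn, sub)
      expect_equal(comp[idx[msn$u[r]]], comp[idx[msn$v[r]]])
    }
  }
})

test_that("maximum-parsimony pruning removes redundant links only", {
  # chord: three haplotypes on a line; the long direct link is in no
  # shortest tree
  net <- median_joining(c("AAAAA", "AAAAG", "AAAGG"), epsilon = 1)
  expect_equal(nrow(net$edges), 3L)
  p <- mp_prune(net)
  expect_equal(nrow(p$edges), 2L)
  expect_equal(p$tree_length, 2)
  expect_equal(length(p$trees), 1L)

  # tree-shaped input is unchanged
  net2 <- median_joining(c("AAAA", "AAAG", "AAGG", "GAAA"), epsilon = 0)
  p2 <- mp_prune(net2)
  expect_equal(nrow(p2$edges), nrow(net2$edges))

  # observed haplotypes are never removed
  set.seed(21)
  for (rep in 1:6) {
    hs <- unique(sim_related_seqs(sample(4:9, 1), L = 12, max_steps = 3))
    if (length(hs) < 3) next
    net <- median_joining(hs, epsilon = 8)
    p <- mp_prune(net)
    expect_true(all(hs %in% p$seqs[p$observed]))
  }
})

test_that("matriline assignment follows shortest-tree connectivity", {
  # three isolated stars: satellites go to their own center
  centers <- c("AAAAAAAAAA", "AAAAACCCCC", "CCCCCCCCCC")
  sats <- c("GAAAAAAAAA", "AAAAACCCCG", "CCCCCCCCCG")
  tb_seqs <- c(centers, sats)
  freq <- c(10L, 8L, 6L, 1L, 1L, 1L)
  tb <- structure(list(seqs = tb_seqs, total = freq), names = c("seqs",
                                                                "total"))
  class(tb) <- "haplotype_table"
  net <- median_joining(tb, epsilon = 0)
  asn <- assign_matrilines(mp_prune(net))
  expect_equal(unname(asn$labels[centers]), c("A", "B", "C"))
  expect_equal(unname(asn$labels[sats]), c("A", "B", "C"))

  # tie: satellite equidistant from two anchors with equal tree support
  # goes to the more frequent anchor
  h <- c("AAAA", "GGAA", "AGAA")  # d(sat, A) = d(sat, B) = 1
  tb2 <- structure(list(seqs = h, total = c(9L, 5L, 1L)),
                   class = "haplotype_table")
  net2 <- mp_prune(median_joining(tb2, epsilon = 0, tv_weight = 8),
                   max_trees = 100)
  asn2 <- assign_matrilines(net2, k_main = 2)
  expect_equal(unname(asn2$labels["AGAA"]), "A")
})

test_that("assignment is invariant to haplotype input order", {
  set.seed(5)
  hs <- unique(sim_related_seqs(8, L = 12, max_steps = 2))
  freq <- seq_along(hs) + 2L
  tb <- structure(list(seqs = hs, total = freq),
                  class = "haplotype_table")
  asn1 <- assign_matrilines(mp_prune(median_joining(tb, epsilon = 0)))
  perm <- sample(length(hs))
  tb2 <- structure(list(seqs = hs[perm], total = freq[perm]),
                   class = "haplotype_table")
  asn2 <- assign_matrilines(mp_prune(median_joining(tb2, epsilon = 0)))
  expect_equal(asn1$labels[sort(names(asn1$labels))],
               asn2$labels[sort(names(asn2$labels))])
})

test_that("deme labels join matrilines with cohorts", {
  a <- mt_alignment(c("x_2010", "y_2010", "z_2011"),
                    c("AAAA", "AAAA", "AAGG"))
  tb <- collapse_haplotypes(a)
  net <- mp_prune(median_joining(tb, epsilon = 0))
  asn <- assign_matrilines(net, k_main = 2)
  dl <- deme_labels(asn, a)
  expect_equal(dl$deme[dl$id == "x_2010"], "2010A")
  expect_equal(nrow(dl), 3L)
  expect_equal(bp_divergence("AAAA", "AAGG"), 2L)
})
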