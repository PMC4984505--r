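test_that("HKY distance reduces to JC and orders ts/tv correctly", {
  s0 <- paste(rep("A", 50), collapse = "")
  s_ts <- paste(c(rep("A", 45), rep("G", 5)), collapse = "")
  s_tv <- paste(c(rep("A", 45), rep("T", 5)), collapse = "")
  d <- hky_distance(c(s0, s0), kappa = 8)
  expect_equal(d[1, 2], 0)
  jc <- -3 / 4 * log(1 - 4 / 3 * 0.1)
  d1 <- hky_distance(c(s0, s_ts), kappa = 1, base_freq = rep(.25, 4))
  expect_equal(d1[1, 2], jc, tolerance = 1e-5)
  d_ts <- hky_distance(c(s0, s_ts), kappa = 8, base_freq = rep(.25, 4))
  d_tv <- hky_distance(c(s0, s_tv), kappa = 8, base_freq = rep(.25, 4))
  expect_gt(d_tv[1, 2], d_ts[1, 2])
  # distances at least the p-distance
  expect_gte(d_ts[1, 2], 0.1)
})

test_that("UPGMA reproduces the textbook 3-taxon clustering", {
  d <- matrix(c(0, 2, 8, 2, 0, 8, 8, 8, 0), 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- upgma_tree(d)
  expect_s3_class(tr, "phylo")
  expect_true(ape::is.ultrametric(tr))
  # a-b join at height 1, root at height 4
  h <- ape::node.depth.edgelength(tr)
  expect_equal(max(h), 4)
  mrca_ab <- ape::getMRCA(tr, c("a", "b"))
  expect_equal(max(h) - h[mrca_ab], 1)

  d2 <- matrix(c(0, 3, 3, 0), 2, dimnames = list(c("a", "b"),
                                                 c("a", "b")))
  tr2 <- upgma_tree(d2)
  expect_equal(tr2$edge.length, c(1.5, 1.5))
})

test_that("star genealogy shows the explosive-growth signature", {
  # a star tree has all coalescences at the root: the classic skyline's
  # terminal (recent) sizes dwarf the root-interval size
  n <- 12
  txt <- paste0("(", paste(sprintf("t%d:1", 1:n), collapse = ","), ");")
  star <- ape::read.tree(text = txt)
  star <- ape::multi2di(star)
  star$edge.length[star$edge.length == 0] <- 1e-9
  prof <- classic_skyline(star, epsilon = 0)
  expect_gt(prof$ne[1] / prof$ne[nrow(prof)], 10)
})

test_that("skyline recovers constant size and ignores tip labels", {
  set.seed(10)
  est <- replicate(40, {
    g <- matriflow:::rkingman(30)
    phy <- matriflow:::genealogy_to_phylo(g)
    prof <- classic_skyline(phy, epsilon = "aicc")
    widths <- diff(c(0, prof$time))
    sum(prof$ne * widths) / sum(widths)   # time-averaged size
  })
  # rkingman has pairwise rate 1, so the skyline's scaled size is 1
  expect_lt(abs(stats::median(est) - 1), 0.15)

  g <- matriflow:::rkingman(20)
  phy <- matriflow:::genealogy_to_phylo(g)
  p1 <- classic_skyline(phy, epsilon = 0)
  phy2 <- phy
  phy2$tip.label <- sample(phy$tip.label)
  p2 <- classic_skyline(phy2, epsilon = 0)
  expect_equal(p1$ne, p2$ne)
  expect_equal(p1$time, p2$time)
})

test_that("rate conversion adds calendar axes with an uncertainty band", {
  set.seed(2)
  g <- matriflow:::rkingman(10)
  phy <- matriflow:::genealogy_to_phylo(g)
  prof <- classic_skyline(phy, epsilon = 0, rate = 0.946e-5,
                          rate_sd = 0.196e-5)
  expect_true(all(c("time_years", "time_years_lo", "time_years_hi") %in%
                    names(prof)))
  expect_true(all(prof$time_years_lo <= prof$time_years))
  expect_true(all(prof$time_years <= prof$time_years_hi))
})

test_that("matriline skyline runs end to end on synthetic sequences", {
  set.seed(30)
  gen <- matriflow:::rkingman(15)
  seqs <- matriflow:::seq_mutations(
    gen, paste(sample(c("A", "C", "G", "T"), 355, TRUE), collapse = ""),
    rate_per_seq = 1.5, kappa = 8)
  a <- mt_alignment(sprintf("s%02d_1", 1:15), seqs)
  prof <- matriline_skyline(a, kappa = 8, epsilon = "aicc")
  expect_s3_class(prof, "skyline_profile")
  expect_true(all(prof$ne > 0))
  expect_true(all(diff(prof$time) > 0))
})
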