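test_that("wc_fst hits the textbook limits", {
  # opposite fixed alleles, equal n -> theta = 1
  calls <- rbind(matrix(2L, 10, 8), matrix(0L, 10, 8))
  d <- genotype_dataset(calls, rep(c("X", "Y"), each = 10))
  expect_equal(as.numeric(wc_fst(d, "X", "Y")), 1)
  # one panmictic population split at random -> theta ~ 0
  set.seed(71)
  p <- runif(2000, 0.1, 0.9)
  g <- matrix(rbinom(200 * 2000, 2, rep(p, each = 200)), 200, 2000)
  d0 <- genotype_dataset(g, rep(c("X", "Y"), each = 100))
  expect_lt(abs(as.numeric(wc_fst(d0, "X", "Y"))), 0.02)
  # monomorphic-only data -> undefined sentinel
  dm <- genotype_dataset(matrix(2L, 4, 2), rep(c("X", "Y"), each = 2))
  expect_true(is.na(wc_fst(dm, "X", "Y")))
})

test_that("wc_fst equals the ANOVA variance-component oracle on explicit counts", {
  # a handful of explicit one-locus instances, including missing data
  cases <- list(
    list(g1 = c(0L, 1L, 2L, 2L), g2 = c(0L, 0L, 1L, 0L)),
    list(g1 = c(2L, 2L, 1L), g2 = c(0L, 1L, 0L)),
    list(g1 = c(1L, 1L, 1L, 1L, 0L), g2 = c(2L, 1L, 0L, 2L, 2L)))
  for (cs in cases) {
    d <- genotype_dataset(matrix(c(cs$g1, cs$g2), ncol = 1),
                          rep(c("X", "Y"), c(length(cs$g1), length(cs$g2))))
    expect_equal(as.numeric(wc_fst(d, "X", "Y")),
                 wc_anova_oracle(cs$g1, cs$g2)$theta, tolerance = 1e-12)
  }
  # multi-locus aggregation is ratio-of-sums
  g1 <- rbind(c(0L, 2L), c(1L, 2L), c(2L, 1L))
  g2 <- rbind(c(0L, 0L), c(0L, 1L), c(1L, 0L))
  d <- genotype_dataset(rbind(g1, g2), rep(c("X", "Y"), each = 3))
  o1 <- wc_anova_oracle(g1[, 1], g2[, 1])
  o2 <- wc_anova_oracle(g1[, 2], g2[, 2])
  expect_equal(as.numeric(wc_fst(d, "X", "Y")),
               (o1$a + o2$a) / (o1$a + o1$b + o1$c + o2$a + o2$b + o2$c),
               tolerance = 1e-12)
})

test_that("fst and reynolds matrices are symmetric with zero diagonals", {
  sc <- sim_scenario(4, 15, 100, breed_F = c(0.2, 0.3, 0.4, 0.5),
                     missing_rate = 0.02, seed = 29)
  d <- simulate_dataset(sc)
  for (m in list(fst_matrix(d), reynolds_matrix(d))) {
    expect_true(isSymmetric(m$values))
    expect_equal(unname(diag(m$values)), rep(0, 4))
    expect_equal(m$breed_means$mean,
                 unname(vapply(1:4, function(i)
                   mean(m$values[i, -i]), numeric(1))))
  }
  # three identical populations -> all entries ~ 0
  sc0 <- sim_scenario(3, 60, 500, breed_F = 1e-6, seed = 30)
  d0 <- simulate_dataset(sc0)
  f0 <- fst_matrix(d0)
  expect_lt(max(abs(f0$values)), 0.02)
})

test_that("reynolds distance matches hand computations", {
  # identical frequencies -> 0
  calls <- rbind(c(2L, 0L), c(0L, 2L), c(2L, 0L), c(0L, 2L))
  d <- genotype_dataset(calls, rep(c("X", "Y"), each = 2))
  expect_equal(reynolds_matrix(d)$values["X", "Y"], 0)
  # opposite fixed alleles at all loci -> 1
  calls2 <- rbind(matrix(2L, 3, 4), matrix(0L, 3, 4))
  d2 <- genotype_dataset(calls2, rep(c("X", "Y"), each = 3))
  expect_equal(reynolds_matrix(d2)$values["X", "Y"], 1)
  # one locus with p1 = 1, p2 = 0.5: num = 0.25, den = 1 - 0.5 = 0.5
  calls3 <- rbind(2L, 2L, 1L, 1L)
  d3 <- genotype_dataset(matrix(calls3, ncol = 1), rep(c("X", "Y"), each = 2))
  expect_equal(reynolds_matrix(d3)$values["X", "Y"], 0.5)
})

test_that("NJ recovers 3-taxon closed form and additive quartets exactly", {
  # 3 taxa: unique unrooted tree, three-point formulas
  dm <- matrix(c(0, 5, 9, 5, 0, 10, 9, 10, 0), 3,
               dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- nj_tree(dm)
  co <- ape::cophenetic.phylo(tr)[c("a", "b", "c"), c("a", "b", "c")]
  expect_equal(co, dm, tolerance = 1e-9)
  # additive quartets: topology from the brute-force least-squares oracle,
  # branch lengths recover the matrix via path lengths
  set.seed(41)
  for (rep in 1:5) {
    gen <- ape::rtree(4, rooted = FALSE, br = function(n) runif(n, 0.1, 1))
    gen$tip.label <- c("a", "b", "c", "d")[as.integer(sub("t", "", gen$tip.label))]
    dmat <- ape::cophenetic.phylo(gen)[c("a", "b", "c", "d"),
                                       c("a", "b", "c", "d")]
    tr4 <- nj_tree(dmat)
    co4 <- ape::cophenetic.phylo(tr4)[rownames(dmat), rownames(dmat)]
    expect_equal(co4, dmat, tolerance = 1e-9)
    expect_equal(quartet_mate(tr4), best_quartet_topology(dmat))
  }
})

test_that("NJ tie-break is deterministic and negative branches are clamped", {
  # equidistant matrix: reproducible topology under the documented rule
  dm <- matrix(1, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  diag(dm) <- 0
  t1 <- nj_tree(dm)
  t2 <- nj_tree(dm)
  expect_equal(ape::write.tree(t1), ape::write.tree(t2))
  expect_true(all(t1$edge.length >= 0))
  expect_error(nj_tree(dm[1:2, 1:2]), ">= 3 taxa")
  dm_bad <- dm; dm_bad[1, 2] <- Inf; dm_bad[2, 1] <- Inf
  expect_error(nj_tree(dm_bad), "finite")
})

test_that("bootstrap supports a clean clade and is seed-deterministic", {
  sc <- sim_scenario(5, 25, 300,
                     breed_F = c(0.5, 0.5, 0.5, 0.5, 0.5),
                     close_pairs = list(list(members = c(1, 2),
                                             F_pair = 0.05, F_shared = 0.5)),
                     seed = 83)
  d <- simulate_dataset(sc)
  tr <- bootstrap_support(d, NULL, n_reps = 300, seed = 4)
  sup <- attr(tr, "support")
  # bipartition keys are normalized to the side not containing the first
  # alphabetical breed, so the {B01,B02} clade reads as its complement
  clade <- sup$support_pct[sup$bipartition == "B03|B04|B05"]
  expect_gte(clade, 95)
  tr2 <- bootstrap_support(d, NULL, n_reps = 300, seed = 4)
  expect_identical(attr(tr2, "support"), sup)
  expect_true(all(sup$support_pct >= 0 & sup$support_pct <= 100))
  expect_error(bootstrap_support(d, NULL, n_reps = 0), "n_reps")
})

test_that("r2_pair matches the closed form when phase is unambiguous", {
  # individuals built from explicit haplotype pairs, no double
  # heterozygotes: haplotypes AB x12, Ab x4, aB x4, ab x12 (strong coupling)
  hap <- rbind(AB = c(1, 1), Ab = c(1, 0), aB = c(0, 1), ab = c(0, 0))
  pairs <- rbind(matrix(rep(c("AB", "AB"), 6), ncol = 2, byrow = TRUE),
                 matrix(rep(c("Ab", "Ab"), 2), ncol = 2, byrow = TRUE),
                 matrix(rep(c("aB", "aB"), 2), ncol = 2, byrow = TRUE),
                 matrix(rep(c("ab", "ab"), 6), ncol = 2, byrow = TRUE))
  g <- t(apply(pairs, 1, function(pr) hap[pr[1], ] + hap[pr[2], ]))
  d <- genotype_dataset(g, rep("X", nrow(g)))
  res <- r2_pair(d, "X", "L1", "L2")
  counts <- c(AB = 12, Ab = 4, aB = 4, ab = 12)
  expect_equal(res$r_squared, r2_from_haplotypes(counts), tolerance = 1e-10)
  expect_true(res$em_converged)
  # duplicated locus -> r2 = 1; monomorphic locus -> undefined
  g2 <- cbind(c(0L, 1L, 2L, 1L), c(0L, 1L, 2L, 1L), c(2L, 2L, 2L, 2L))
  d2 <- genotype_dataset(g2, rep("X", 4))
  expect_equal(r2_pair(d2, "X", "L1", "L2")$r_squared, 1, tolerance = 1e-9)
  expect_true(is.na(r2_pair(d2, "X", "L1", "L3")$r_squared))
})

test_that("r2 is invariant under allele relabelling at either locus", {
  sc <- sim_scenario(2, 50, 10, breed_F = 0.3, n_ld_pairs = 1,
                     ld_copy_error = 0.3, seed = 49)
  d <- simulate_dataset(sc)
  base <- r2_pair(d, "B01", "L0001", "L0002")$r_squared
  flip <- d
  flip$calls[, "L0001"] <- 2L - flip$calls[, "L0001"]
  expect_equal(r2_pair(flip, "B01", "L0001", "L0002")$r_squared, base,
               tolerance = 1e-9)
})
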