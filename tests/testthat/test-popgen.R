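test_that("allele and carrier frequencies count diploid copies", {
  g <- data.frame(sample_id = c("s1", "s2"), locus = "L",
                  allele1 = c("A", "A"), allele2 = c("A", "B"))
  f <- allele_frequencies(g)
  expect_equal(f$L$frequencies, c(A = 0.75, B = 0.25))
  expect_equal(f$L$n2, 4L)
  cf <- carrier_frequencies(g)
  expect_equal(cf$L, c(A = 1.0, B = 0.5))

  # 174 samples -> 2n = 348
  g174 <- data.frame(sample_id = paste0("s", 1:174), locus = "L",
                     allele1 = "A", allele2 = "B")
  expect_equal(allele_frequencies(g174)$L$n2, 348L)

  expect_error(allele_frequencies(g[0, ]), "empty")
  half <- rbind(g, data.frame(sample_id = "s3", locus = "L",
                              allele1 = "B", allele2 = NA))
  expect_warning(fh <- allele_frequencies(half), "half-missing")
  expect_equal(fh$L$n2, 4L)
})

test_that("frequencies sum to one and carrier >= allele frequency", {
  set.seed(5)
  g <- simulate_population(list(L = c(A = 0.5, B = 0.3, C = 0.2)), 200, seed = 5)
  f <- allele_frequencies(g)$L$frequencies
  cf <- carrier_frequencies(g)$L
  expect_equal(sum(f), 1)
  expect_true(all(cf[names(f)] >= f - 1e-12))
})

test_that("coverage and the cumulative curve follow the stated ordering", {
  f <- c(A = 0.6, B = 0.3, C = 0.1)
  expect_equal(coverage(f, c("A", "B")), 0.9)
  expect_equal(coverage(f, c("A", "B", "C")), 1.0)
  expect_equal(coverage(f, c("A", "ZZ")), 0.6)  # absent allele contributes 0

  curve <- cumulative_coverage_curve(c(A = 0.5, C = 0.2, B = 0.3))
  expect_equal(curve$allele, c("A", "B", "C"))
  expect_equal(curve$cumulative, c(0.5, 0.8, 1.0))
  # ties broken lexicographically
  tie <- cumulative_coverage_curve(c(Z = 0.25, A = 0.25, M = 0.5))
  expect_equal(tie$allele, c("M", "A", "Z"))
})

test_that("HWE Monte-Carlo test matches its analytic extremes", {
  all_het <- data.frame(allele1 = rep("A", 100), allele2 = rep("B", 100))
  expect_lt(hwe_test(all_het, 2000, seed = 1)$p_value, 0.01)

  at_exp <- c("A/A" = 4, "A/B" = 8, "B/B" = 4)
  expect_gte(hwe_test(at_exp, 2000, seed = 1)$p_value, 0.5)

  expect_equal(hwe_test(c("A/A" = 30))$p_value, 1)

  # reproducibility under a fixed seed
  p1 <- hwe_test(all_het, 1000, seed = 99)$p_value
  p2 <- hwe_test(all_het, 1000, seed = 99)$p_value
  expect_identical(p1, p2)
})

test_that("HWE p-values are near-uniform under the null (calibration)", {
  set.seed(2026)
  freqs <- list(L = c(A = 0.5, B = 0.3, C = 0.2))
  pvals <- vapply(1:120, function(i) {
    g <- simulate_population(freqs, 60, seed = 10000 + i)
    hwe_test(g[, c("allele1", "allele2")], 1000, seed = 20000 + i)$p_value
  }, 0)
  # two-moment check within Monte-Carlo error (conservative: MC p-values
  # are discrete and stochastically slightly super-uniform)
  expect_gt(mean(pvals), 0.45)
  expect_lt(mean(pvals < 0.1), 0.2)
  expect_gt(mean(pvals < 0.5), 0.3)
})

test_that("chord distance has the stated closed forms and properties", {
  f1 <- list(L = c(A = 1))
  f2 <- list(L = c(B = 1))
  expect_equal(cavalli_sforza_distance(f1, f2), 2)      # fixed different
  expect_equal(cavalli_sforza_distance(f1, f1), 0)      # identical

  set.seed(8)
  for (i in 1:10) {
    p <- runif(4); p <- p / sum(p); q <- runif(4); q <- q / sum(q)
    fp <- list(L = setNames(p, letters[1:4]))
    fq <- list(L = setNames(q, letters[1:4]))
    expect_equal(cavalli_sforza_distance(fp, fq), cavalli_sforza_distance(fq, fp))
    expect_gte(cavalli_sforza_distance(fp, fq), 0)
  }

  # monotone in decreasing sqrt-frequency overlap (single locus, 2 alleles)
  dist_at <- function(p) cavalli_sforza_distance(
    list(L = c(A = 0.5, B = 0.5)), list(L = c(A = p, B = 1 - p)))
  ds <- vapply(c(0.5, 0.4, 0.3, 0.2, 0.1), dist_at, 0)
  expect_true(all(diff(ds) > 0))

  expect_error(cavalli_sforza_distance(list(L1 = c(A = 1)), list(L2 = c(A = 1))),
               "no shared loci")
})

test_that("NJ recovers the three-taxon closed form and additive trees", {
  d3 <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3, 3,
               dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- nj_tree(d3)
  expect_s3_class(tr, "phylo")
  d_rec <- ape::cophenetic.phylo(tr)[c("a", "b", "c"), c("a", "b", "c")]
  expect_equal(d_rec, d3)

  # additive 4- and 6-taxon matrices are exactly recovered (oracle: the
  # generating tree's path-length matrix)
  set.seed(17)
  for (n in c(4, 6)) {
    gen <- ape::rtree(n, br = function(k) runif(k, 0.2, 1.5))
    gen <- ape::unroot(gen)
    dgen <- ape::cophenetic.phylo(gen)
    rec <- nj_tree(dgen)
    expect_equal(ape::cophenetic.phylo(rec)[rownames(dgen), colnames(dgen)],
                 dgen, tolerance = 1e-8)
    # independent oracle: ape's own NJ gives the same path-length matrix
    anj <- ape::nj(as.dist(dgen))
    expect_equal(ape::cophenetic.phylo(rec)[rownames(dgen), colnames(dgen)],
                 ape::cophenetic.phylo(anj)[rownames(dgen), colnames(dgen)],
                 tolerance = 1e-8)
  }

  # equidistant taxa resolve deterministically (smallest index pair first)
  deq <- matrix(1, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  diag(deq) <- 0
  nwk1 <- ape::write.tree(nj_tree(deq))
  nwk2 <- ape::write.tree(nj_tree(deq))
  expect_identical(nwk1, nwk2)

  expect_error(nj_tree(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
  expect_warning(nj_tree(matrix(c(0, 1, 1, 10, 1, 0, 1, 1, 1, 1, 0, 1,
                                  10, 1, 1, 0), 4, 4,
                                dimnames = list(letters[1:4], letters[1:4]))),
                 "clamped")
})

test_that("PCoA recovers planted configurations", {
  # two points at distance d -> +/- d/2 on axis 1, 100% variance
  d2 <- matrix(c(0, 3, 3, 0), 2, 2, dimnames = list(c("P", "Q"), c("P", "Q")))
  p <- pcoa(d2)
  expect_equal(sort(p$coordinates[, 1]), c(-1.5, 1.5), ignore_attr = TRUE)
  expect_equal(p$variance, 1)

  # collinear points -> single positive eigenvalue
  x <- c(0, 1, 2.5, 4)
  dl <- as.matrix(dist(x)); dimnames(dl) <- list(letters[1:4], letters[1:4])
  pl <- pcoa(dl)
  expect_equal(ncol(pl$coordinates), 1L)

  # planted 2-D configuration recovered up to rotation/reflection:
  # compare via stats::cmdscale oracle and via inter-point distances
  set.seed(23)
  conf <- matrix(rnorm(12), 6, 2)
  dd <- as.matrix(dist(conf)); dimnames(dd) <- list(letters[1:6], letters[1:6])
  pp <- pcoa(dd, n_axes = 2)
  expect_equal(as.matrix(dist(pp$coordinates)), dd, ignore_attr = TRUE,
               tolerance = 1e-8)
  oracle <- stats::cmdscale(dd, k = 2)
  expect_equal(abs(cor(pp$coordinates[, 1], oracle[, 1])), 1, tolerance = 1e-8)
})

test_that("allele aliasing conserves mass and detects cycles", {
  f <- c("Cw*0210" = 0.1, "Cw*0202" = 0.05, "Cw*0602" = 0.85)
  out <- alias_alleles(f)
  expect_equal(out[["Cw*0202"]], 0.15)
  expect_equal(sum(out), sum(f))
  expect_false("Cw*0210" %in% names(out))

  expect_equal(alias_alleles(f, alias_map = character(0)), f[sort(names(f))])
  expect_error(alias_alleles(c(A = 1), alias_map = c(A = "B", B = "A")),
               "alias cycle")

  # list-of-loci shape is preserved
  fl <- alias_alleles(list(L = f))
  expect_equal(fl$L[["Cw*0202"]], 0.15)
})

test_that("Fisher exact 2x2 agrees with enumeration extremes and stats oracle", {
  expect_equal(fisher_exact_2x2(matrix(c(5, 0, 0, 5), 2, 2)), 2 / choose(10, 5))
  expect_equal(fisher_exact_2x2(matrix(c(1, 1, 1, 1), 2, 2)), 1)
  expect_equal(fisher_exact_2x2(matrix(c(0, 0, 3, 4), 2, 2, byrow = TRUE)), 1)
  set.seed(31)
  for (i in 1:10) {
    tab <- matrix(rpois(4, 6), 2, 2)
    expect_equal(fisher_exact_2x2(tab), stats::fisher.test(tab)$p.value,
                 tolerance = 1e-10)
  }
  expect_error(fisher_exact_2x2(matrix(c(-1, 0, 0, 5), 2, 2)), "nonnegative")
})

test_that("Fisher-Freeman-Halton Monte-Carlo is seeded and sane", {
  tab <- matrix(c(8, 1, 1, 1, 8, 1, 1, 1, 8), 3, 3)
  r1 <- fisher_freeman_halton(tab, n_mc = 4000, seed = 2)
  r2 <- fisher_freeman_halton(tab, n_mc = 4000, seed = 2)
  expect_identical(r1$p_value, r2$p_value)
  expect_lt(r1$p_value, 0.05)
  flat <- matrix(2, 3, 3)
  expect_gt(fisher_freeman_halton(flat, n_mc = 2000, seed = 3)$p_value, 0.5)
})
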