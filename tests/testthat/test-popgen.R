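test_that("condense keeps everything when nothing is missing", {
  pm <- matrix(TRUE, 5, 8, dimnames = list(paste0("s", 1:5),
                                           paste0("l", 1:8)))
  cd <- condense(pm)
  expect_setequal(cd$samples, rownames(pm))
  expect_setequal(cd$loci, colnames(pm))
})

test_that("condense removes the heavily missing sample", {
  pm <- rbind(s1 = c(TRUE, TRUE, TRUE, TRUE),
              s2 = c(TRUE, TRUE, TRUE, FALSE),
              s3 = c(FALSE, FALSE, FALSE, TRUE))
  colnames(pm) <- paste0("l", 1:4)
  cd <- condense(pm, condenser_policy(max_missing_per_sample = 0.5))
  expect_false("s3" %in% cd$samples)
  oracle <- condense_oracle(pm, 0.5)
  expect_identical(length(cd$samples), length(oracle$samples))
  expect_identical(length(cd$loci), oracle$n_loci)
})

test_that("condense output always satisfies its constraints", {
  for (seed in 1:8) {
    set.seed(seed + 50)
    pm <- matrix(runif(10 * 16) < runif(1, 0.5, 0.9), 10, 16,
                 dimnames = list(paste0("s", 1:10), paste0("l", 1:16)))
    cd <- tryCatch(condense(pm), error = function(e) NULL)
    if (is.null(cd)) next
    sub <- pm[cd$samples, cd$loci, drop = FALSE]
    expect_true(all(colSums(sub) >= cd$min_samples))
    expect_true(all(1 - rowMeans(sub) <= 0.5 + 1e-12))
  }
})

test_that("dosage encoding maps IUPAC genotypes and drops multiallelic sites", {
  g <- rbind(s1 = c("A", "R", "C", "A"),
             s2 = c("A", "G", "T", "C"),
             s3 = c("N", "A", "Y", "G"))
  enc <- dosage_encode(g)
  expect_identical(enc$n_dropped_multiallelic, 1L)  # col 4 has A, C, G
  expect_identical(ncol(enc$dosage), 3L)
  # col 1: A monomorphic -> dosage 0, NA for N
  expect_equal(unname(enc$dosage[, 1L]), c(0, 0, NA))
  # col 2: alleles A/G, A minor (3 G vs 3 A? counts: R=A+G, G=2G, A=2A ->
  # A:3, G:3, tie -> lexicographic minor A); het = 1
  expect_equal(unname(enc$dosage[, 2L]), c(1, 0, 2))
})

test_that("Weir-Cockerham theta behaves at the degenerate extremes", {
  # no differentiation (two samples from one panmictic pool) -> theta ~ 0
  set.seed(2)
  dos <- matrix(rbinom(100 * 200, 2L, rep(runif(200, 0.2, 0.8),
                                          each = 100L)), 100, 200)
  pop <- rep(c("p1", "p2"), each = 50L)
  f <- wc_fst(dos, pop)
  expect_lte(abs(f$theta), 0.01)
  # literally duplicated tables force the among-population variance to zero,
  # giving the exact finite-sample value -1/(2n - 2) under HWE heterozygosity
  block <- matrix(rbinom(50 * 200, 2L, 0.4), 50, 200)
  f_dup <- wc_fst(rbind(block, block), pop)
  expect_lt(f_dup$theta, 0)
  expect_lte(abs(f_dup$theta + 1 / 98), 0.003)
  # fixed opposite homozygotes -> theta = 1
  dos2 <- rbind(matrix(0, 10, 20), matrix(2, 10, 20))
  f2 <- wc_fst(dos2, rep(c("p1", "p2"), each = 10L))
  expect_equal(f2$theta, 1)
  expect_true(is.na(f2$linearized))
  # all monomorphic -> signalled
  expect_error(wc_fst(matrix(0, 10, 5), rep(c("p1", "p2"), each = 5L)),
               "monomorphic")
})

test_that("theta is invariant to allele relabeling and locus order", {
  set.seed(4)
  dos <- matrix(rbinom(40 * 30, 2L, runif(30, 0.2, 0.8)), 40, 30,
                byrow = TRUE)
  pop <- rep(c("p1", "p2"), each = 20L)
  t0 <- wc_fst(dos, pop)$theta
  expect_equal(wc_fst(2 - dos, pop)$theta, t0, tolerance = 1e-12)
  expect_equal(wc_fst(dos[, sample(30)], pop)$theta, t0, tolerance = 1e-12)
})

test_that("PCA + k-means recovers simulated population structure", {
  cfg <- sim_config(seed = 5, taxa = list(
    list(name = "t", n_populations = 2L, n_individuals_per_pop = 15L,
         fst = 0.3)), n_loci = 150L, locus_length = 12L, theta = 0.15)
  truth <- simulate_genotypes(cfg)
  dos <- truth_dosage(truth, "t")
  pk <- pca_kmeans(dos, k_range = 1:5, seed = 1L)
  expect_identical(pk$k, 2L)
  pop <- truth$taxa$t$individuals$population
  agree <- max(mean((pk$assignments == 1L) == (pop == "pop1")),
               mean((pk$assignments == 2L) == (pop == "pop1")))
  expect_gte(agree, 0.95)
  # a duplicated sample lands in the same cluster
  dos2 <- rbind(dos, dup = dos[1L, ])
  rownames(dos2) <- c(rownames(dos2)[-nrow(dos2)], "dup")
  pk2 <- pca_kmeans(dos2, k_range = 1:5, seed = 1L)
  expect_identical(unname(pk2$assignments[nrow(dos2)]),
                   unname(pk2$assignments[1L]))
})

test_that("k-means selects a single cluster for unstructured data", {
  votes <- 0L
  for (seed in 1:6) {
    set.seed(seed + 300)
    dos <- matrix(rbinom(30 * 120, 2L, rep(runif(120, 0.2, 0.8),
                                           each = 30L)), 30, 120)
    pk <- pca_kmeans(dos, k_range = 1:4, seed = seed)
    if (pk$k == 1L) votes <- votes + 1L
  }
  expect_gte(votes, 4L)
})

test_that("mantel test matches expectations on exact cases", {
  set.seed(6)
  m <- as.matrix(dist(rnorm(9)))
  dimnames(m) <- list(paste0("p", 1:9), paste0("p", 1:9))
  expect_equal(mantel_test(m, m, 99, seed = 1L)$r, 1)
  # affine invariance of the correlation
  m2 <- 2 * m + 3
  diag(m2) <- 0
  expect_equal(mantel_test(m, m2, 99, seed = 1L)$r, 1)
  expect_error(mantel_test(m, matrix(1, 9, 9,
    dimnames = dimnames(m)), 99), "constant")
  # determinism under seed
  mm <- as.matrix(dist(rnorm(9)))
  dimnames(mm) <- dimnames(m)
  r1 <- mantel_test(m, mm, 99, seed = 4L)
  r2 <- mantel_test(m, mm, 99, seed = 4L)
  expect_identical(r1, r2)
})

test_that("great-circle distances follow the haversine closed forms", {
  expect_equal(great_circle_km(10, 20, 10, 20), 0)
  expect_equal(great_circle_km(0, 0, 0, 1), 2 * pi * 6371.0088 / 360,
               tolerance = 1e-6)
  expect_equal(great_circle_km(-12, 30, 40, -55),
               great_circle_km(40, -55, -12, 30))
  expect_error(great_circle_km(95, 0, 0, 0), "out of range")
})

test_that("isolation by distance is detected on a spatial gradient", {
  set.seed(77)
  n_pop <- 6L
  n_ind <- 8L
  n_sites <- 150L
  # allele-frequency gradient along a transect
  p0 <- runif(n_sites, 0.3, 0.7)
  slope <- runif(n_sites, -1, 1) * 0.08
  dos <- NULL
  pop <- character(0)
  for (k in seq_len(n_pop)) {
    pk <- pmin(pmax(p0 + slope * (k - (n_pop + 1) / 2), 0.02), 0.98)
    dos <- rbind(dos, matrix(rbinom(n_ind * n_sites, 2L,
                                    rep(pk, each = n_ind)), n_ind))
    pop <- c(pop, rep(sprintf("pop%d", k), n_ind))
  }
  coords <- data.frame(population = sprintf("pop%d", 1:n_pop),
                       latitude = 0, longitude = seq(0, 5, length.out = n_pop))
  res <- ibd_analysis(dos, pop, coords, n_permutations = 199L, seed = 1L)
  expect_gt(res$r, 0)
  expect_lte(res$p, 0.05)
  expect_identical(res$n_populations, 6L)
})

test_that("subsetting by method drops empty populations and needs >= 3", {
  set.seed(88)
  n_sites <- 60L
  dos <- matrix(rbinom(24 * n_sites, 2L, 0.5), 24, n_sites)
  pop <- rep(sprintf("pop%d", 1:4), each = 6L)
  method <- rep(c("gDNA", "MDA"), 12L)
  method[pop == "pop4"] <- "MDA"  # pop4 has no gDNA library
  coords <- data.frame(population = sprintf("pop%d", 1:4),
                       latitude = c(0, 1, 2, 3), longitude = 0)
  res <- ibd_analysis(dos, pop, coords, method = method, subset = "gDNA",
                      n_permutations = 99L, seed = 1L)
  expect_identical(res$n_populations, 3L)
  method2 <- method
  method2[pop %in% c("pop3", "pop4")] <- "MDA"
  expect_error(ibd_analysis(dos, pop, coords, method = method2,
                            subset = "gDNA"), "at least 3")
})
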