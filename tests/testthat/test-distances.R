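test_that("locus-overlap dissimilarity follows the Jaccard definition", {
  pm <- rbind(a = c(TRUE, TRUE, TRUE, FALSE),
              b = c(FALSE, TRUE, TRUE, TRUE),
              c = c(TRUE, TRUE, TRUE, FALSE),
              d = c(FALSE, FALSE, FALSE, FALSE),
              e = c(FALSE, FALSE, FALSE, FALSE))
  colnames(pm) <- paste0("L", 1:4)
  dm <- locus_overlap_dissimilarity(pm)
  expect_equal(dm$values["a", "c"], 0)            # identical sets
  expect_equal(dm$values["a", "b"], 1 - 2 / 4)    # {1,2,3} vs {2,3,4}
  expect_equal(dm$values["a", "d"], 1)            # one empty set
  expect_true(is.na(dm$values["d", "e"]))         # empty union: undefined
  expect_equal(dm$support["a", "b"], 2)
  # disjoint nonempty sets -> 1
  pm2 <- rbind(a = c(TRUE, FALSE), b = c(FALSE, TRUE))
  colnames(pm2) <- c("L1", "L2")
  expect_equal(locus_overlap_dissimilarity(pm2)$values["a", "b"], 1)
})

test_that("genetic distance scores the four cross-library allele comparisons", {
  pol <- filter_policy(min_samples_per_locus = 1,
                       min_shared_for_distance = 1)
  # identical homozygotes -> 0
  ds <- make_ds(list(c(a = "AATA", b = "AATA")))
  ds$loci$L1$flags <- "-..."  # force a SNP site
  expect_equal(genetic_distance(ds, pol)$values["a", "b"], 0)
  # A/A vs A/G (R) -> 0.5 at the single variable site
  ds <- make_ds(list(c(a = "AAAA", b = "RAAA")))
  expect_equal(genetic_distance(ds, pol)$values["a", "b"], 0.5)
  # R vs R -> 0.5 under cross-comparison
  ds <- make_ds(list(c(a = "RAAA", b = "RAAA", c = "GAAA")))
  expect_equal(genetic_distance(ds, pol)$values["a", "b"], 0.5)
  # no qualifying site -> NA, not 0
  ds <- make_ds(list(c(a = "RAAA", b = "NAAA")))
  expect_true(is.na(genetic_distance(ds, pol)$values["a", "b"]))
  # support below the shared-locus threshold -> NA
  ds <- make_ds(list(c(a = "RAAA", b = "AAAA")))
  pol35 <- filter_policy(min_samples_per_locus = 1,
                         min_shared_for_distance = 35)
  expect_true(is.na(genetic_distance(ds, pol35)$values["a", "b"]))
})

test_that("genetic distance is bounded and invariant to library order", {
  cfg <- small_sim(14, n_loci = 60L)
  ds <- simulate_paired_study(cfg)$datasets[[1L]]
  pol <- filter_policy(min_shared_for_distance = 5)
  gd <- genetic_distance(ds, pol)
  v <- gd$values[upper.tri(gd$values)]
  expect_true(all(v[!is.na(v)] >= 0 & v[!is.na(v)] <= 1))
  ds2 <- ds
  ds2$libraries <- ds2$libraries[rev(seq_len(nrow(ds2$libraries))), ]
  gd2 <- genetic_distance(ds2, pol)
  expect_equal(gd2$values[rownames(gd$values), colnames(gd$values)],
               gd$values)
})

test_that("problematic-sample rule flags on the inclusive boundary", {
  meta <- rbind(
    make_meta(c("x_g", "y_g", "z_g"), sample_id = c("x", "y", "z")),
    make_meta(c("x_m"), sample_id = "x", method = "MDA"))
  m <- matrix(0, 4, 4, dimnames = list(c("x_g", "y_g", "z_g", "x_m"),
                                       c("x_g", "y_g", "z_g", "x_m")))
  m["x_g", "y_g"] <- m["y_g", "x_g"] <- 0.02
  m["x_g", "z_g"] <- m["z_g", "x_g"] <- 0.05
  m["y_g", "z_g"] <- m["z_g", "y_g"] <- 0.04
  m["x_g", "x_m"] <- m["x_m", "x_g"] <- 0.01
  m["y_g", "x_m"] <- m["x_m", "y_g"] <- 0.03
  m["z_g", "x_m"] <- m["x_m", "z_g"] <- 0.06
  gd <- rad_dist(m, support = NULL, kind = "genetic")
  fl <- flag_problematic_samples(gd, meta)
  expect_identical(fl$sample_id, "x")
  expect_false(fl$flagged)          # 0.01 < 0.02
  expect_equal(fl$margin, 0.01)
  # equality flags (margin exactly 0)
  m2 <- m
  m2["x_g", "x_m"] <- m2["x_m", "x_g"] <- 0.02
  fl2 <- flag_problematic_samples(rad_dist(m2, NULL, "genetic"), meta)
  expect_true(fl2$flagged)
  expect_equal(fl2$margin, 0)
})

test_that("co-assembled contamination is flagged, clean pairs are not", {
  cfg <- small_sim(23, two_taxa = TRUE, n_loci = 120L)
  study <- simulate_paired_study(cfg)
  dsl <- study$datasets
  tr <- study$truth
  res <- inject_contamination(dsl, "tA_p1_i2_MDA", "tB", 0.3, tr, cfg,
                              mode = "co_assemble")
  gd <- genetic_distance(res$datasets$tA, cfg$filter)
  fl <- flag_problematic_samples(gd, res$datasets$tA$libraries)
  expect_true(fl$flagged[fl$sample_id == "tA_p1_i2"])
  expect_false(any(fl$flagged[fl$sample_id != "tA_p1_i2"]))
})

test_that("neighbor joining recovers additive trees exactly", {
  # 3 leaves: closed-form branch lengths solve the three-point equations
  m <- matrix(0, 3, 3, dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  m["a", "b"] <- m["b", "a"] <- 0.3
  m["a", "c"] <- m["c", "a"] <- 0.4
  m["b", "c"] <- m["c", "b"] <- 0.5
  tree <- neighbor_joining(rad_dist(m, NULL, "genetic"))
  expect_identical(ape::Ntip(tree), 3L)
  bl <- setNames(tree$edge.length, tree$tip.label[tree$edge[, 2L]])
  expect_equal(unname(bl["a"]), (0.3 + 0.4 - 0.5) / 2)
  expect_equal(unname(bl["b"]), (0.3 + 0.5 - 0.4) / 2)
  expect_equal(unname(bl["c"]), (0.4 + 0.5 - 0.3) / 2)

  # additive 5-leaf matrices from random trees are recovered exactly
  for (seed in 1:5) {
    set.seed(seed)
    ref <- ape::rtree(5L, rooted = FALSE)
    dm <- cophenetic(ref)
    rec <- neighbor_joining(dm)
    expect_equal(ape::dist.topo(ape::unroot(ref), rec), 0,
                 ignore_attr = TRUE)
  }

  # duplicated library -> zero-length terminal branch
  m4 <- rbind(c(0, 0, 0.4, 0.5), c(0, 0, 0.4, 0.5),
              c(0.4, 0.4, 0, 0.3), c(0.5, 0.5, 0.3, 0))
  dimnames(m4) <- list(letters[1:4], letters[1:4])
  tr4 <- neighbor_joining(m4)
  bl4 <- setNames(tr4$edge.length, tr4$tip.label[tr4$edge[, 2L]])
  expect_equal(unname(bl4["a"]), 0)
  expect_error(neighbor_joining(m[1:2, 1:2]), "at least 3")
})

test_that("paired libraries cluster as NJ siblings without contamination", {
  hits <- 0L
  n_rep <- 12L
  for (seed in seq_len(n_rep)) {
    cfg <- small_sim(seed + 700, n_loci = 100L)
    ds <- simulate_paired_study(cfg)$datasets[[1L]]
    gd <- genetic_distance(ds, filter_policy(min_shared_for_distance = 5))
    tree <- tryCatch(suppressWarnings(neighbor_joining(gd)),
                     error = function(e) NULL)
    if (is.null(tree)) next
    meta <- ds$libraries
    sib <- TRUE
    for (s in unique(meta$sample_id)) {
      libs <- meta$library_id[meta$sample_id == s]
      if (length(libs) != 2L || !all(libs %in% tree$tip.label)) next
      i <- match(libs, tree$tip.label)
      anc <- c(tree$edge[tree$edge[, 2L] == i[1L], 1L],
               tree$edge[tree$edge[, 2L] == i[2L], 1L])
      if (anc[1L] != anc[2L]) sib <- FALSE
    }
    if (sib) hits <- hits + 1L
  }
  expect_gte(hits / n_rep, 0.95)
})
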