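test_that("read_loci parses blocks, names, flags and ids", {
  txt <- c(
    "s1    ACGTR",
    "s2    ACGTA",
    "s3    ACGTA",
    "//       -*|7|",    # '-' and '*' under columns 4 and 5
    "s1    TTTT-",
    "s2    TTATN",
    "s3    TTATT",
    "//      *|9|")      # '*' under column 3; trailing spaces trimmed
  path <- withr::local_tempfile(fileext = ".loci")
  writeLines(txt, path)
  meta <- make_meta(c("s1", "s2", "s3"))
  ds <- read_loci(path, meta)
  expect_s3_class(ds, "loci_dataset")
  expect_length(ds$loci, 2L)
  expect_identical(names(ds$loci), c("7", "9"))
  expect_identical(names(ds$loci[["7"]]$seqs), c("s1", "s2", "s3"))
  # one informative column marked in each block
  expect_identical(ds$loci[["7"]]$flags, "...-*")
  expect_identical(ds$loci[["9"]]$flags, "..*..")
})

test_that("read_loci handles the empty file and bad inputs", {
  path <- withr::local_tempfile(fileext = ".loci")
  writeLines(character(0), path)
  ds <- read_loci(path, make_meta("s1"))
  expect_length(ds$loci, 0L)

  writeLines(c("s1  ACGT", "s2  ACG", "//      |0|"), path)
  expect_error(read_loci(path, make_meta(c("s1", "s2"))), "ragged")

  writeLines(c("s1  ACGT", "sX  ACGT", "//      |0|"), path)
  expect_error(read_loci(path, make_meta(c("s1", "s2"))), "sX")
})

test_that("write_loci emits the dialect read_loci accepts (round trip)", {
  # zero-locus dataset -> zero blocks
  meta <- make_meta("s1")
  empty <- loci_dataset("tx", list(), meta)
  path <- withr::local_tempfile(fileext = ".loci")
  write_loci(empty, path)
  expect_identical(length(readLines(path)), 0L)

  # 1 locus, 2 members -> 3 lines
  ds <- make_ds(list(c(s1 = "ACGT", s2 = "ACGA")))
  write_loci(ds, path)
  expect_length(readLines(path), 3L)
  back <- read_loci(path, ds$libraries)
  expect_same_loci(ds, back)
})

test_that("loci round trip is stable over many random simulated datasets", {
  for (seed in 1:100) {
    cfg <- small_sim(seed, n_pop = 1L, n_ind = 2L, n_loci = 15L,
                     locus_length = 40L, reads_per_library = 2000L)
    study <- simulate_paired_study(cfg)
    ds <- study$datasets[[1L]]
    path <- withr::local_tempfile(fileext = ".loci")
    write_loci(ds, path)
    back <- read_loci(path, ds$libraries)
    expect_same_loci(ds, back)
    # second round trip is byte-identical
    path2 <- withr::local_tempfile(fileext = ".loci")
    write_loci(back, path2)
    expect_identical(readLines(path), readLines(path2))
  }
})

test_that("presence_matrix reflects membership and is order-invariant", {
  ds <- make_ds(list(
    c(s1 = "AAAA", s2 = "AAAA", s3 = "AAAA"),
    c(s1 = "CCCC"),
    c(s2 = "GGGG", s3 = "GGGG")))
  pm <- presence_matrix(ds)
  expect_true(all(pm[, "L1"]))
  expect_identical(unname(rowSums(pm)), c(2, 2, 2))
  # reorder loci: row sums invariant
  ds2 <- ds
  ds2$loci <- rev(ds2$loci)
  expect_identical(rowSums(presence_matrix(ds2)), rowSums(pm))
})

test_that("presence_matrix row sums match simulator truth", {
  cfg <- small_sim(101, n_pop = 1L, n_ind = 3L, n_loci = 60L,
                   reads_per_library = 1500L)
  study <- simulate_paired_study(cfg)
  pm <- presence_matrix(study$datasets[[1L]])
  for (lib in sample(rownames(pm), 3L)) {
    meta <- study$metadata[study$metadata$library_id == lib, ]
    sim <- simulate_library(study$truth, meta, cfg)
    expect_identical(as.integer(rowSums(pm)[lib]), sum(sim$assembled))
  }
})

test_that("final_dataset applies the min-samples threshold and is idempotent", {
  ds <- make_ds(list(
    c(s1 = "AAAA", s2 = "AAAA", s3 = "AAAA", s4 = "AAAA"),
    c(s1 = "CCCC", s2 = "CCCC", s3 = "CCCC")))
  # min_samples = 1: identity
  expect_length(final_dataset(ds, filter_policy(min_samples_per_locus = 1))$loci, 2L)
  # 3 members at threshold 4: dropped
  fds <- final_dataset(ds, filter_policy(min_samples_per_locus = 4))
  expect_identical(names(fds$loci), "L1")
  expect_identical(nrow(fds$libraries), nrow(ds$libraries))
  # idempotent
  expect_same_loci(final_dataset(fds, filter_policy(min_samples_per_locus = 4)), fds)
})

test_that("final_dataset depletes separate-mode contaminant loci", {
  cfg <- small_sim(77, two_taxa = TRUE, n_loci = 80L,
                   contamination_fraction = 0.2)
  study <- simulate_paired_study(cfg)
  ds <- study$datasets$tA
  contam_ids <- unique(study$truth$contamination$locus_id[
    study$truth$contamination$donor_taxon == "tB"])
  frac_in <- mean(names(ds$loci) %in% contam_ids)
  fds <- final_dataset(ds, filter_policy())
  frac_out <- mean(names(fds$loci) %in% contam_ids)
  expect_gt(frac_in, 0)
  expect_lt(frac_out, frac_in)
})

test_that("SNP phylip reader and writer round trip and validate", {
  m <- rbind(s1 = c("A", "R"), s2 = c("C", "N"))
  path <- withr::local_tempfile(fileext = ".phy")
  write_snp_phylip(m, path)
  back <- read_snp_phylip(path)
  expect_identical(back, m)

  writeLines(c("2 3", "s1  ACG", "s2  AC"), path)
  expect_error(read_snp_phylip(path), "dimension mismatch")
  writeLines(c("1 3", "s1  AXG"), path)
  expect_error(read_snp_phylip(path), "non-IUPAC")
})
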