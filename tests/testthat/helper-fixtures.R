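# Shared fixture builders: everything is constructed in code at test time.

make_meta <- function(ids, taxon = "tx", population = "pop1", pool = "pool1",
                      method = "gDNA", sample_id = NULL, input = NA_real_,
                      n_reads = 1000L) {
  data.frame(
    library_id = ids,
    sample_id = if (is.null(sample_id)) ids else sample_id,
    taxon = taxon, population = population, pool = pool, method = method,
    input_dna_ng = ifelse(method == "MDA" & is.na(input), 100, input),
    n_reads = n_reads, latitude = NA_real_, longitude = NA_real_,
    stringsAsFactors = FALSE
  )
}

# dataset from a list of named character vectors (one per locus)
make_ds <- function(loci_seqs, meta = NULL, taxon = "tx", depths = NULL) {
  ids <- unique(unlist(lapply(loci_seqs, names)))
  if (is.null(meta)) meta <- make_meta(ids, taxon = taxon)
  loci <- lapply(seq_along(loci_seqs), function(i) {
    locus(paste0("L", i), loci_seqs[[i]],
          depth = if (!is.null(depths)) depths[[i]] else NULL)
  })
  loci_dataset(taxon, loci, meta)
}

# small default simulation configs used across tests
small_sim <- function(seed, n_pop = 2L, n_ind = 4L, n_loci = 120L,
                      fst = 0.1, two_taxa = FALSE, ...) {
  taxa <- list(list(name = "tA", n_populations = n_pop,
                    n_individuals_per_pop = n_ind, fst = fst))
  if (two_taxa)
    taxa <- c(taxa, list(list(name = "tB", n_populations = 1L,
                              n_individuals_per_pop = 2L, fst = fst)))
  sim_config(seed = seed, taxa = taxa, n_loci = n_loci, ...)
}

# compare two datasets on parsed content (depths are not serialized)
expect_same_loci <- function(a, b) {
  expect_identical(names(a$loci), names(b$loci))
  for (id in names(a$loci)) {
    expect_identical(a$loci[[id]]$seqs, b$loci[[id]]$seqs)
    expect_identical(a$loci[[id]]$flags, b$loci[[id]]$flags)
  }
}

# exhaustive condenser oracle for small matrices: searches removal subsets in
# increasing size, so the kept-sample count is provably maximal, then
# maximizes kept loci
condense_oracle <- function(pm, max_missing = 0.5, grid = NULL) {
  if (is.null(grid)) grid <- seq(2L, nrow(pm))
  n <- nrow(pm)
  best <- NULL
  for (m in grid) {
    found_r <- NULL
    for (r in 0:(n - 2L)) {
      if (!is.null(found_r)) break
      sets <- utils::combn(n, r, simplify = FALSE)
      for (rm in sets) {
        keep <- setdiff(seq_len(n), rm)
        sub <- pm[keep, , drop = FALSE]
        loci <- which(colSums(sub) >= m)
        miss <- if (length(loci) == 0L) rep(1, length(keep))
                else 1 - rowMeans(sub[, loci, drop = FALSE])
        if (all(miss <= max_missing)) {
          found_r <- r
          score <- c(length(keep), length(loci))
          if (is.null(best) || score[1L] > best$score[1L] ||
              (score[1L] == best$score[1L] && score[2L] > best$score[2L]))
            best <- list(samples = rownames(pm)[keep],
                         n_loci = length(loci), m = m, score = score)
        }
      }
    }
  }
  best
}

# textbook per-site Weir-Cockerham components, written independently of the
# package internals (straightforward transliteration of the 1984 formulas)
wc_site_oracle <- function(dosage, pop) {
  pop <- factor(pop[!is.na(dosage)])
  dosage <- dosage[!is.na(dosage)]
  r <- nlevels(droplevels(pop))
  pop <- droplevels(pop)
  if (r < 2) return(NULL)
  ni <- as.numeric(table(pop))
  pi <- sapply(split(dosage, pop), function(x) sum(x) / (2 * length(x)))
  hi <- sapply(split(dosage, pop), function(x) mean(x == 1))
  nbar <- mean(ni)
  pbar <- sum(ni * pi) / sum(ni)
  if (pbar <= 0 || pbar >= 1 || nbar <= 1) return(NULL)
  nc <- (sum(ni) - sum(ni^2) / sum(ni)) / (r - 1)
  s2 <- sum(ni * (pi - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(ni * hi) / sum(ni)
  a <- nbar / nc * (s2 - 1 / (nbar - 1) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4))
  b <- nbar / (nbar - 1) * (pbar * (1 - pbar) - (r - 1) / r * s2 -
    (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  c(a = a, b = b, c = cc)
}

# dosage matrix straight from simulated truth (all variable sites, all loci)
truth_dosage <- function(truth, taxon) {
  blocks <- lapply(truth$taxa[[taxon]]$loci, function(l)
    if (nrow(l$sites) > 0L) l$geno else NULL)
  do.call(cbind, blocks[!vapply(blocks, is.null, logical(1))])
}
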