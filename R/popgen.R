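#' Policy for missing-data matrix condensing
#'
#' @param max_missing_per_sample maximum allowed missing-data fraction per
#'   kept sample (default 0.5).
#' @param min_samples_grid integer vector of minimum-samples-per-locus
#'   values to search; defaults to `2:max` at run time.
#' @return object of class `condenser_policy`.
#' @export
condenser_policy <- function(max_missing_per_sample = 0.5,
                             min_samples_grid = NULL) {
  stopifnot(max_missing_per_sample > 0, max_missing_per_sample <= 1)
  structure(list(max_missing_per_sample = max_missing_per_sample,
                 min_samples_grid = min_samples_grid),
            class = "condenser_policy")
}

.condense_for_m <- function(pm, m, max_missing) {
  keep <- rownames(pm)
  repeat {
    sub <- pm[keep, , drop = FALSE]
    loci <- colnames(sub)[colSums(sub) >= m]
    if (length(loci) == 0L) {
      miss <- rep(1, length(keep))
    } else {
      miss <- 1 - rowMeans(sub[, loci, drop = FALSE])
    }
    names(miss) <- keep
    if (all(miss <= max_missing)) {
      return(list(samples = keep, loci = loci))
    }
    if (length(keep) <= 2L) return(NULL)
    # worst missingness; ties -> fewer total loci present, then id
    worst <- max(miss)
    cand <- keep[miss >= worst - 1e-12]
    if (length(cand) > 1L) {
      totals <- rowSums(pm[cand, , drop = FALSE])
      cand <- cand[totals == min(totals)]
      cand <- sort(cand)
    }
    keep <- setdiff(keep, cand[1L])
  }
}

# exact sample selection for one min-samples threshold: enumerate removal
# subsets in increasing size, so the first feasible size maximizes kept
# samples; among those, maximize kept loci
.condense_exact_m <- function(pm, m, max_missing) {
  n <- nrow(pm)
  best <- NULL
  for (r in 0:(n - 2L)) {
    for (rm in utils::combn(n, r, simplify = FALSE)) {
      keep <- setdiff(seq_len(n), rm)
      sub <- pm[keep, , drop = FALSE]
      loci <- colnames(sub)[colSums(sub) >= m]
      miss <- if (length(loci) == 0L) rep(1, length(keep))
              else 1 - rowMeans(sub[, loci, drop = FALSE])
      if (all(miss <= max_missing) &&
          (is.null(best) || length(loci) > length(best$loci)))
        best <- list(samples = rownames(pm)[keep], loci = loci)
    }
    if (!is.null(best)) return(best)
  }
  NULL
}

#' Condense a presence matrix to bound per-sample missing data
#'
#' Searches a grid of minimum-samples-per-locus thresholds; for each
#' candidate the sample subset is chosen so that every kept sample has at
#' most `max_missing_per_sample` missing data over the loci passing the
#' threshold among kept samples.  For small matrices (up to `exact_limit`
#' samples) the subset is found by exhaustive search, which guarantees the
#' objective (keep the most samples, then the most loci); for larger
#' matrices samples are removed greedily, highest missing fraction first
#' (ties broken by fewer total loci, then lexicographic id).  The threshold
#' keeping the most samples (then the most loci) wins.  Removal decisions
#' use missingness only, never metadata.
#'
#' @param pm presence matrix ([presence_matrix()]).
#' @param policy a [condenser_policy()].
#' @param exact_limit largest sample count for which the exhaustive search
#'   is used (default 15).
#' @return list with `samples`, `loci`, `min_samples` (chosen threshold),
#'   and the audited `max_missing` actually attained.
#' @export
condense <- function(pm, policy = condenser_policy(), exact_limit = 15L) {
  if (nrow(pm) == 0L || ncol(pm) == 0L) .stopf("empty presence matrix")
  grid <- policy$min_samples_grid
  if (is.null(grid)) grid <- seq(2L, max(2L, nrow(pm)))
  exact <- nrow(pm) <= exact_limit
  best <- NULL
  for (m in sort(unique(as.integer(grid)))) {
    res <- if (exact) {
      .condense_exact_m(pm, m, policy$max_missing_per_sample)
    } else {
      .condense_for_m(pm, m, policy$max_missing_per_sample)
    }
    if (is.null(res) || length(res$samples) < 2L) next
    score <- c(length(res$samples), length(res$loci))
    if (is.null(best) || score[1L] > best$score[1L] ||
        (score[1L] == best$score[1L] && score[2L] > best$score[2L])) {
      best <- list(samples = res$samples, loci = res$loci,
                   min_samples = m, score = score)
    }
  }
  if (is.null(best))
    .stopf("no feasible condensing keeps at least 2 samples")
  sub <- pm[best$samples, best$loci, drop = FALSE]
  # postcondition audit
  stopifnot(all(colSums(sub) >= best$min_samples),
            all(1 - rowMeans(sub) <= policy$max_missing_per_sample + 1e-12))
  list(samples = best$samples, loci = best$loci,
       min_samples = best$min_samples,
       max_missing = max(1 - rowMeans(sub)))
}

#' Encode IUPAC genotypes as alt-allele dosages
#'
#' Determines the two alleles of each site from the pooled allele counts and
#' encodes genotypes as 0/1/2 copies of the minor allele; heterozygotes are
#' 1.  `N` and gaps become `NA`; sites with more than two alleles across the
#' dataset are dropped and counted.
#'
#' @param geno character matrix (libraries x sites) of IUPAC genotypes.
#' @return list with `dosage` (numeric matrix), `n_dropped_multiallelic`,
#'   and `alleles` (2 x sites kept).
#' @export
dosage_encode <- function(geno) {
  n_sites <- ncol(geno)
  dos <- matrix(NA_real_, nrow = nrow(geno), ncol = n_sites,
                dimnames = dimnames(geno))
  keep <- logical(n_sites)
  alleles <- matrix(NA_character_, nrow = 2L, ncol = n_sites)
  for (j in seq_len(n_sites)) {
    col <- geno[, j]
    counts <- c(A = 0, C = 0, G = 0, T = 0)
    for (b in col) {
      al <- .IUPAC_ALLELES[[b]]
      if (!is.null(al)) counts[al] <- counts[al] + 1
    }
    present <- names(counts)[counts > 0]
    if (length(present) > 2L) next
    keep[j] <- TRUE
    if (length(present) == 0L) next
    if (length(present) == 1L) {
      # monomorphic: zero copies of a (non-existent) alternate allele
      called <- !vapply(col, function(b) is.null(.IUPAC_ALLELES[[b]]),
                        logical(1))
      dos[called, j] <- 0
      alleles[, j] <- c(present, NA_character_)
      next
    }
    # minor allele is the dosage allele; ties lexicographic
    ord <- order(counts[present], present)
    minor <- present[ord[1L]]
    major <- present[ord[2L]]
    alleles[, j] <- c(major, minor)
    for (i in seq_len(nrow(geno))) {
      al <- .IUPAC_ALLELES[[col[i]]]
      if (is.null(al)) next
      dos[i, j] <- sum(al == minor)
    }
  }
  list(dosage = dos[, keep, drop = FALSE],
       n_dropped_multiallelic = sum(!keep),
       alleles = alleles[, keep, drop = FALSE])
}

#' PCA and k-means clustering of SNP genotypes
#'
#' Centered PCA on mean-imputed alt-allele dosages, then k-means on the
#' leading principal components (those explaining at least `var_threshold`
#' of the variance, capped at `max_pcs`).  The number of clusters is chosen
#' by the minimum of `BIC(k) = n log(WSS_k / n) + k log(n)` over `k_range`,
#' with `nstart` seeded restarts per k.
#'
#' @param geno character matrix of IUPAC genotypes (libraries x sites) or a
#'   numeric dosage matrix.
#' @param k_range candidate cluster numbers (default 1:6).
#' @param seed integer seed.
#' @param var_threshold cumulative variance cutoff for retained PCs
#'   (default 0.9).
#' @param max_pcs cap on retained PCs (default 20).
#' @param nstart k-means restarts (default 20).
#' @return list with `assignments` (named integer), `k`, `scores` (retained
#'   PC scores), `bic` (`data.frame` k, bic), `var_explained`.
#' @export
pca_kmeans <- function(geno, k_range = 1:6, seed = 1L, var_threshold = 0.9,
                       max_pcs = 20L, nstart = 20L) {
  dos <- if (is.numeric(geno)) geno else dosage_encode(geno)$dosage
  n <- nrow(dos)
  if (n < max(k_range)) .stopf("fewer samples (%d) than clusters (%d)", n,
                               max(k_range))
  # mean-impute missing dosages per site
  for (j in seq_len(ncol(dos))) {
    mis <- is.na(dos[, j])
    if (any(mis)) dos[mis, j] <- mean(dos[, j], na.rm = TRUE)
  }
  dos[is.na(dos)] <- 0
  keep <- apply(dos, 2L, var) > 0
  dos <- dos[, keep, drop = FALSE]
  pc <- prcomp(dos, center = TRUE, scale. = FALSE)
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  n_pc <- min(max(which(cumsum(ve) >= var_threshold)[1L], 1L), max_pcs,
              ncol(pc$x))
  scores <- pc$x[, seq_len(n_pc), drop = FALSE]
  set.seed(seed)
  bic <- data.frame(k = integer(0), bic = numeric(0))
  fits <- list()
  for (k in sort(unique(k_range))) {
    if (k == 1L) {
      wss <- sum(scale(scores, scale = FALSE)^2)
      fit <- list(cluster = rep(1L, n))
    } else {
      fit <- kmeans(scores, centers = k, nstart = nstart, iter.max = 50L)
      wss <- fit$tot.withinss
    }
    bic <- rbind(bic, data.frame(k = k, bic = n * log(wss / n) + k * log(n)))
    fits[[as.character(k)]] <- fit
  }
  k_best <- bic$k[which.min(bic$bic)]
  assignments <- fits[[as.character(k_best)]]$cluster
  names(assignments) <- rownames(dos)
  list(assignments = assignments, k = k_best, scores = scores, bic = bic,
       var_explained = ve[seq_len(n_pc)])
}

# Weir-Cockerham (1984) per-site variance components for one biallelic site.
# dosage: alt-allele dosage vector (0/1/2, NA = missing); pop: factor.
.wc_site <- function(dosage, pop) {
  ok <- !is.na(dosage)
  dosage <- dosage[ok]
  pop <- droplevels(factor(pop[ok]))
  r <- nlevels(pop)
  if (r < 2L) return(NULL)
  n_i <- tapply(dosage, pop, length)
  if (any(n_i < 1L)) return(NULL)
  p_i <- tapply(dosage, pop, function(x) mean(x) / 2)
  h_i <- tapply(dosage, pop, function(x) mean(x == 1L))
  nbar <- mean(n_i)
  nsum <- sum(n_i)
  nc <- (nsum - sum(n_i^2) / nsum) / (r - 1)
  pbar <- sum(n_i * p_i) / nsum
  if (pbar <= 0 || pbar >= 1) return(NULL)  # monomorphic
  s2 <- sum(n_i * (p_i - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(n_i * h_i) / nsum
  if (nbar <= 1) return(NULL)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar * (2 * nbar - 1) / (4 * nbar))
  cc <- hbar / 2
  c(a = a, b = b, c = cc)
}

#' Weir-Cockerham F_ST combined across loci
#'
#' Per biallelic site, the Weir-Cockerham (1984) variance components `a`
#' (among populations), `b` (among individuals within populations) and `c`
#' (within individuals) are computed from allele frequencies, sample sizes
#' and observed heterozygote counts; the combined estimate is the ratio of
#' sums `theta = sum(a) / sum(a + b + c)` over sites.  Monomorphic sites are
#' skipped.  With more than two populations, pairwise estimates are returned
#' for every population pair.
#'
#' @param dosage numeric matrix of alt-allele dosages (individuals x sites;
#'   see [dosage_encode()]).
#' @param pop factor/character of population labels per individual.
#' @param pairwise if `TRUE` (default) estimate for each population pair,
#'   else one overall estimate.
#' @return `data.frame` with columns `pop1`, `pop2`, `theta`, `linearized`
#'   (`theta / (1 - theta)`), `n_sites`; or a single-row frame with
#'   `pop1 = pop2 = "(all)"` when `pairwise = FALSE`.
#' @export
wc_fst <- function(dosage, pop, pairwise = TRUE) {
  pop <- factor(pop)
  if (nlevels(pop) < 2L) .stopf("need at least 2 populations")
  est <- function(rows_pop) {
    comps <- matrix(0, nrow = 0, ncol = 3)
    n_used <- 0L
    sums <- c(a = 0, b = 0, c = 0)
    for (j in seq_len(ncol(dosage))) {
      w <- .wc_site(dosage[, j], rows_pop)
      if (is.null(w)) next
      sums <- sums + w
      n_used <- n_used + 1L
    }
    if (n_used == 0L)
      .stopf("all sites monomorphic: F_ST undefined")
    theta <- sums[["a"]] / sum(sums)
    list(theta = theta, n = n_used)
  }
  if (!pairwise) {
    e <- est(pop)
    return(data.frame(pop1 = "(all)", pop2 = "(all)", theta = e$theta,
                      linearized = e$theta / (1 - e$theta), n_sites = e$n,
                      stringsAsFactors = FALSE))
  }
  levs <- levels(pop)
  out <- list()
  for (i in seq_len(length(levs) - 1L)) {
    for (j in seq(i + 1L, length(levs))) {
      rows <- pop %in% c(levs[i], levs[j])
      sub <- dosage[rows, , drop = FALSE]
      e <- local({
        subpop <- droplevels(pop[rows])
        sums <- c(a = 0, b = 0, c = 0)
        n_used <- 0L
        for (s in seq_len(ncol(sub))) {
          w <- .wc_site(sub[, s], subpop)
          if (is.null(w)) next
          sums <- sums + w
          n_used <- n_used + 1L
        }
        if (n_used == 0L) return(NULL)
        list(theta = sums[["a"]] / sum(sums), n = n_used)
      })
      if (is.null(e)) next
      out[[length(out) + 1L]] <- data.frame(
        pop1 = levs[i], pop2 = levs[j], theta = e$theta,
        linearized = if (e$theta < 1) e$theta / (1 - e$theta) else NA_real_,
        n_sites = e$n, stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L) .stopf("all sites monomorphic: F_ST undefined")
  do.call(rbind, out)
}

#' Mantel test between two distance matrices
#'
#' Pearson correlation of the off-diagonal elements, with significance from
#' permuting the labels of one matrix (one-tailed by default, testing for
#' positive association; `p = (1 + #(r_perm >= r_obs)) / (1 +
#' n_permutations)`).
#'
#' @param dm1,dm2 `dist` objects or symmetric matrices with matching labels.
#' @param n_permutations number of permutations (default 999).
#' @param seed optional seed.
#' @param two_tailed if `TRUE`, use the two-tailed alternative.
#' @return list with `r` and `p`.
#' @export
mantel_test <- function(dm1, dm2, n_permutations = 999L, seed = NULL,
                        two_tailed = FALSE) {
  m1 <- as.matrix(dm1)
  m2 <- as.matrix(dm2)
  if (!is.null(rownames(m1)) && !is.null(rownames(m2))) {
    if (!setequal(rownames(m1), rownames(m2)))
      .stopf("mantel: matrices have different labels")
    m2 <- m2[rownames(m1), rownames(m1)]
  }
  if (anyNA(m1) || anyNA(m2)) .stopf("mantel needs complete matrices")
  if (sd(m1[lower.tri(m1)]) == 0 || sd(m2[lower.tri(m2)]) == 0)
    .stopf("mantel: constant distance matrix, r undefined")
  if (!is.null(seed)) set.seed(seed)
  res <- vegan::mantel(as.dist(m1), as.dist(m2),
                       permutations = n_permutations)
  r <- unname(res$statistic)
  p <- unname(res$signif)
  if (two_tailed) {
    perms <- res$perm
    p <- (1 + sum(abs(perms) >= abs(r) - 1e-12)) / (1 + length(perms))
  }
  list(r = r, p = p)
}

#' Great-circle distance in kilometres
#'
#' Haversine distance on a sphere of radius 6371.0088 km.
#'
#' @param lat1,lon1,lat2,lon2 coordinates in decimal degrees (vectorized).
#' @return distance(s) in km.
#' @export
great_circle_km <- function(lat1, lon1, lat2, lon2) {
  if (any(abs(c(lat1, lat2)) > 90) || any(abs(c(lon1, lon2)) > 180))
    .stopf("coordinates out of range")
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2),
                           r = 6371.0088)
}

#' Isolation by distance: linearized F_ST against geographic distance
#'
#' Computes pairwise Weir-Cockerham F_ST between populations (optionally on
#' the gDNA-only or MDA-only subset of libraries), linearizes it as
#' `theta / (1 - theta)`, computes great-circle distances between population
#' coordinates, and runs a Mantel test.  Populations with no library in the
#' subset are dropped.
#'
#' @param dosage numeric dosage matrix (libraries x sites).
#' @param pop population label per library.
#' @param coords `data.frame` with columns `population`, `latitude`,
#'   `longitude` (one row per population), or per-library coordinates that
#'   are averaged within populations.
#' @param method optional per-library method labels (needed for subsetting).
#' @param subset `"all"`, `"gDNA"` or `"MDA"`.
#' @param n_permutations,seed passed to [mantel_test()].
#' @return list with `r`, `p`, `n_populations`, `fst` (pairwise table), and
#'   the two distance matrices.
#' @export
ibd_analysis <- function(dosage, pop, coords, method = NULL,
                         subset = c("all", "gDNA", "MDA"),
                         n_permutations = 999L, seed = NULL) {
  subset <- match.arg(subset)
  pop <- as.character(pop)
  keep <- rep(TRUE, nrow(dosage))
  if (subset != "all") {
    if (is.null(method)) .stopf("subsetting needs per-library methods")
    keep <- method == subset
  }
  dosage <- dosage[keep, , drop = FALSE]
  pop <- pop[keep]
  pops <- sort(unique(pop))
  if (length(pops) < 3L)
    .stopf("need at least 3 populations with libraries (got %d)",
           length(pops))
  if (!all(c("population", "latitude", "longitude") %in% names(coords)))
    .stopf("coords needs columns population, latitude, longitude")
  coords <- stats::aggregate(coords[, c("latitude", "longitude")],
                             by = list(population = coords$population),
                             FUN = mean)
  coords <- coords[match(pops, coords$population), ]
  if (anyNA(coords$latitude))
    .stopf("missing coordinates for populations: %s",
           paste(pops[is.na(coords$latitude)], collapse = ", "))
  fst <- wc_fst(dosage, pop, pairwise = TRUE)
  gen <- matrix(0, length(pops), length(pops), dimnames = list(pops, pops))
  for (i in seq_len(nrow(fst)))
    gen[fst$pop1[i], fst$pop2[i]] <- gen[fst$pop2[i], fst$pop1[i]] <-
      fst$linearized[i]
  geo <- matrix(0, length(pops), length(pops), dimnames = list(pops, pops))
  for (i in seq_along(pops)) {
    for (j in seq_along(pops)) {
      geo[i, j] <- great_circle_km(coords$latitude[i], coords$longitude[i],
                                   coords$latitude[j], coords$longitude[j])
    }
  }
  mt <- mantel_test(gen, geo, n_permutations = n_permutations, seed = seed)
  list(r = mt$r, p = mt$p, n_populations = length(pops), fst = fst,
       gen_dist = gen, geo_dist = geo)
}
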