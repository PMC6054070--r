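#' Assembled- and final-locus counts per library
#'
#' A locus counts as assembled for a library when the library is a member
#' and, if depths are available and `policy$min_coverage > 0`, its read
#' depth is at least `min_coverage`.  Final counts are taken over the loci
#' retained by [final_dataset()].
#'
#' @param ds a [loci_dataset()].
#' @param policy a [filter_policy()].
#' @return `data.frame` with columns `library_id`, `n_assembled_loci`,
#'   `n_final_loci`.
#' @export
count_loci <- function(ds, policy = filter_policy()) {
  libs <- ds$libraries$library_id
  has_depth <- all(vapply(ds$loci, function(l) !is.null(l$depth), logical(1)))
  if (policy$min_coverage > 0L && length(ds$loci) > 0L && !has_depth)
    .stopf("count_loci: min_coverage > 0 requested but loci carry no depths")
  member_of <- function(dset) {
    counts <- setNames(integer(length(libs)), libs)
    for (l in dset$loci) {
      m <- names(l$seqs)
      if (policy$min_coverage > 0L)
        m <- m[!is.na(l$depth[m]) & l$depth[m] >= policy$min_coverage]
      counts[m] <- counts[m] + 1L
    }
    counts
  }
  assembled <- member_of(ds)
  final <- member_of(final_dataset(ds, policy))
  data.frame(library_id = libs, n_assembled_loci = as.integer(assembled),
             n_final_loci = as.integer(final), stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Mean and sample SD of read depth across a library's assembled loci
#'
#' @param ds a [loci_dataset()] whose loci carry depths.
#' @param library_id library id.
#' @param policy a [filter_policy()]; only loci with depth >=
#'   `min_coverage` contribute.
#' @return list with `mean` and `sd` (sample SD, n-1 denominator; `sd` is
#'   `NA` with a single locus).
#' @export
depth_stats <- function(ds, library_id, policy = filter_policy()) {
  depths <- numeric(0)
  for (l in ds$loci) {
    if (is.null(l$depth) || !library_id %in% names(l$depth)) next
    d <- l$depth[[library_id]]
    if (!is.na(d) && d >= policy$min_coverage) depths <- c(depths, d)
  }
  if (length(depths) == 0L)
    .stopf("library '%s' has no assembled loci with depth information",
           library_id)
  list(mean = mean(depths), sd = sd(depths))
}

.seq_chars <- function(ds, library_id, loci_ids) {
  out <- character(0)
  for (lid in loci_ids) {
    s <- ds$loci[[lid]]$seqs[[library_id]]
    if (!is.null(s)) out <- c(out, strsplit(s, "", fixed = TRUE)[[1L]])
  }
  out
}

.library_locus_ids <- function(ds, library_id) {
  names(ds$loci)[vapply(ds$loci, function(l) library_id %in% names(l$seqs),
                        logical(1))]
}

#' Observed heterozygosity of one library
#'
#' Proportion of heterozygous genotype calls (IUPAC two-allele codes) among
#' called sites, pooled over the library's sequences in the loci retained in
#' the final dataset.  `N` and gaps are excluded from the denominator.
#'
#' @param ds a [loci_dataset()].
#' @param library_id library id.
#' @param policy a [filter_policy()].
#' @param loci `"final"` (default) or `"assembled"`: which locus set to pool
#'   over.
#' @return proportion in [0,1].
#' @export
observed_heterozygosity <- function(ds, library_id, policy = filter_policy(),
                                    loci = c("final", "assembled")) {
  loci <- match.arg(loci)
  dset <- if (loci == "final") final_dataset(ds, policy) else ds
  chars <- .seq_chars(dset, library_id, .library_locus_ids(dset, library_id))
  called <- chars[!chars %in% c("N", "-")]
  if (length(called) == 0L)
    .stopf("library '%s' has no called sites in the %s dataset",
           library_id, loci)
  sum(called %in% .HET_CODES) / length(called)
}

#' GC content of one library's sequences
#'
#' G, C and S count 1; each of R, Y, K, M counts 0.5 (one of the two alleles
#' is G or C); A, T, W count 0.  The denominator is all called sites
#' (excluding `N` and gaps) over the library's assembled loci.
#'
#' @inheritParams observed_heterozygosity
#' @param loci `"assembled"` (default) or `"final"`.
#' @return proportion in [0,1].
#' @export
gc_content <- function(ds, library_id, policy = filter_policy(),
                       loci = c("assembled", "final")) {
  loci <- match.arg(loci)
  dset <- if (loci == "final") final_dataset(ds, policy) else ds
  chars <- .seq_chars(dset, library_id, .library_locus_ids(dset, library_id))
  called <- chars[!chars %in% c("N", "-")]
  if (length(called) == 0L)
    .stopf("library '%s' has no called sites", library_id)
  weights <- c(G = 1, C = 1, S = 1, R = 0.5, Y = 0.5, K = 0.5, M = 0.5,
               A = 0, T = 0, W = 0)
  sum(weights[called]) / length(called)
}

#' Per-library statistics table
#'
#' Computes, for every library of a dataset, the responses and covariates
#' used by the comparison models: assembled and final locus counts, mean and
#' SD of read depth across assembled loci, observed heterozygosity (final
#' loci) and GC content (assembled loci), merged with the library metadata.
#' Libraries with no assembled loci get `NA` statistics.
#'
#' @param ds a [loci_dataset()].
#' @param policy a [filter_policy()].
#' @return `data.frame`, one row per library.
#' @export
library_stats <- function(ds, policy = filter_policy()) {
  counts <- count_loci(ds, policy)
  stats <- counts
  stats$mean_depth <- NA_real_
  stats$sd_depth <- NA_real_
  stats$heterozygosity <- NA_real_
  stats$gc_content <- NA_real_
  for (i in seq_len(nrow(stats))) {
    lib <- stats$library_id[i]
    if (stats$n_assembled_loci[i] > 0L) {
      has_depth <- all(vapply(ds$loci, function(l) !is.null(l$depth),
                              logical(1)))
      if (has_depth) {
        dsx <- depth_stats(ds, lib, policy)
        stats$mean_depth[i] <- dsx$mean
        stats$sd_depth[i] <- dsx$sd
      }
      stats$gc_content[i] <- gc_content(ds, lib, policy)
    }
    if (stats$n_final_loci[i] > 0L)
      stats$heterozygosity[i] <- observed_heterozygosity(ds, lib, policy)
  }
  merge(stats, ds$libraries, by = "library_id", sort = FALSE)
}
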