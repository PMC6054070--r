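#' Labelled symmetric distance matrix
#'
#' Container for the two inter-library distances: locus-overlap
#' dissimilarity and SNP genetic distance.  Undefined pairs (no shared loci,
#' or fewer shared loci than the support threshold) are `NA`, never 0.
#'
#' @param values symmetric numeric matrix with dimnames.
#' @param support integer matrix of shared-locus counts (same shape).
#' @param kind `"locus_overlap"` or `"genetic"`.
#' @return object of class `rad_dist`.
#' @export
rad_dist <- function(values, support, kind = c("locus_overlap", "genetic")) {
  kind <- match.arg(kind)
  stopifnot(is.matrix(values), nrow(values) == ncol(values),
            identical(rownames(values), colnames(values)))
  ok <- !is.na(values)
  if (any(abs(values[ok & t(ok)] - t(values)[ok & t(ok)]) > 1e-12))
    .stopf("distance matrix is not symmetric")
  diag(values) <- 0
  structure(list(values = values, support = support, kind = kind,
                 labels = rownames(values)), class = "rad_dist")
}

#' @export
print.rad_dist <- function(x, ...) {
  cat(sprintf("<rad_dist> kind '%s', %d libraries, %d undefined pairs\n",
              x$kind, length(x$labels),
              sum(is.na(x$values[upper.tri(x$values)]))))
  invisible(x)
}

#' @export
as.matrix.rad_dist <- function(x, ...) x$values

#' Locus-overlap dissimilarity between libraries
#'
#' For libraries a, b with locus sets A, B the dissimilarity is `1 - p` with
#' `p` the proportion of loci shared by both libraries.  By default `p` is
#' Jaccard, `|A n B| / |A u B|`; `denominator = "min"` uses
#' `|A n B| / min(|A|, |B|)` instead.  Pairs where both sets are empty are
#' `NA`.
#'
#' @param pm presence matrix from [presence_matrix()] (typically of the
#'   final dataset).
#' @param denominator `"union"` (default) or `"min"`.
#' @return a [rad_dist()] of kind `locus_overlap`; `support` holds shared
#'   locus counts.
#' @export
locus_overlap_dissimilarity <- function(pm, denominator = c("union", "min")) {
  denominator <- match.arg(denominator)
  if (nrow(pm) < 2L) .stopf("need at least 2 libraries")
  m <- pm * 1
  shared <- tcrossprod(m)
  sizes <- rowSums(m)
  denom <- if (denominator == "union") {
    outer(sizes, sizes, "+") - shared
  } else {
    outer(sizes, sizes, pmin)
  }
  d <- 1 - shared / denom
  d[denom == 0] <- NA_real_
  diag(d) <- 0
  rad_dist(d, support = shared, kind = "locus_overlap")
}

#' Pairwise genetic distance at SNP sites
#'
#' Average proportion of allele differences between two libraries at the
#' SNP sites of the final dataset.  Each called genotype is expanded to its
#' two alleles (homozygotes contribute two copies) and the site score is the
#' mean of the four cross-library allele comparisons (1 if different), so
#' two identical heterozygotes score 0.5.  Sites where either library is
#' uncalled (`N`) or gapped are ignored.  The distance is the mean site
#' score over qualifying sites; pairs sharing fewer than
#' `policy$min_shared_for_distance` final loci (or with no qualifying site)
#' are `NA`.  The diagonal is 0 by convention even though heterozygous
#' self-comparison scores 0.5 under cross-comparison.
#'
#' @param ds a [loci_dataset()].
#' @param policy a [filter_policy()]; the final-dataset filter and the
#'   shared-locus support threshold are taken from it.
#' @return a [rad_dist()] of kind `genetic`; `support` holds shared final
#'   locus counts.
#' @export
genetic_distance <- function(ds, policy = filter_policy()) {
  fds <- final_dataset(ds, policy)
  libs <- fds$libraries$library_id
  nl <- length(libs)
  if (nl < 2L) .stopf("need at least 2 libraries")
  # enumerate SNP sites and fill allele matrices
  site_locus <- integer(0)
  a1 <- NULL
  a2 <- NULL
  member <- matrix(FALSE, nrow = nl, ncol = length(fds$loci),
                   dimnames = list(libs, names(fds$loci)))
  cols <- list()
  for (li in seq_along(fds$loci)) {
    loc <- fds$loci[[li]]
    member[names(loc$seqs), li] <- TRUE
    pos <- which(strsplit(loc$flags, "", fixed = TRUE)[[1L]] %in% c("-", "*"))
    if (length(pos) == 0L) next
    block1 <- matrix(NA_integer_, nrow = nl, ncol = length(pos))
    block2 <- matrix(NA_integer_, nrow = nl, ncol = length(pos))
    smat <- do.call(rbind, strsplit(loc$seqs, "", fixed = TRUE))
    rows <- match(names(loc$seqs), libs)
    sub <- smat[, pos, drop = FALSE]
    block1[rows, ] <- .ALLELE_CODE[1L, ][sub]
    block2[rows, ] <- .ALLELE_CODE[2L, ][sub]
    cols[[length(cols) + 1L]] <- list(b1 = block1, b2 = block2)
    site_locus <- c(site_locus, rep(li, length(pos)))
  }
  if (length(cols) > 0L) {
    a1 <- do.call(cbind, lapply(cols, `[[`, "b1"))
    a2 <- do.call(cbind, lapply(cols, `[[`, "b2"))
  } else {
    a1 <- matrix(NA_integer_, nrow = nl, ncol = 0L)
    a2 <- a1
  }
  support <- tcrossprod(member * 1)
  d <- matrix(NA_real_, nl, nl, dimnames = list(libs, libs))
  diag(d) <- 0
  for (i in seq_len(nl - 1L)) {
    xi1 <- a1[i, ]; xi2 <- a2[i, ]
    for (j in seq(i + 1L, nl)) {
      ok <- !is.na(xi1) & !is.na(a1[j, ])
      if (support[i, j] < policy$min_shared_for_distance || !any(ok)) next
      s <- ((xi1[ok] != a1[j, ok]) + (xi1[ok] != a2[j, ok]) +
            (xi2[ok] != a1[j, ok]) + (xi2[ok] != a2[j, ok])) / 4
      d[i, j] <- d[j, i] <- mean(s)
    }
  }
  rad_dist(d, support = support, kind = "genetic")
}

#' Flag samples whose MDA library looks contaminated
#'
#' A paired sample is flagged when the genetic distance between its gDNA and
#' MDA libraries is at least as large as the distance from its gDNA library
#' to the most similar conspecific gDNA library from another individual.
#' The per-sample margin is `min_j d(gDNA_i, gDNA_j) - d(gDNA_i, MDA_i)`;
#' margins at or below zero flag the sample.
#'
#' @param gd a genetic [rad_dist()].
#' @param metadata library metadata table.
#' @return `data.frame` with one row per evaluable paired sample:
#'   `sample_id`, `taxon`, `d_pair`, `d_nearest_conspecific`, `margin`,
#'   `flagged`.  Samples without an evaluable comparison are dropped with a
#'   warning.
#' @export
flag_problematic_samples <- function(gd, metadata) {
  metadata <- validate_meta(metadata)
  dm <- gd$values
  out <- list()
  skipped <- character(0)
  samples <- unique(metadata$sample_id[metadata$method == "MDA"])
  for (s in samples) {
    rows <- metadata[metadata$sample_id == s, ]
    g <- rows$library_id[rows$method == "gDNA"]
    m <- rows$library_id[rows$method == "MDA"]
    if (length(g) != 1L || length(m) != 1L ||
        !all(c(g, m) %in% rownames(dm))) {
      skipped <- c(skipped, s)
      next
    }
    taxon <- rows$taxon[1L]
    others <- metadata$library_id[metadata$method == "gDNA" &
                                  metadata$taxon == taxon &
                                  metadata$sample_id != s]
    others <- intersect(others, rownames(dm))
    d_pair <- dm[g, m]
    d_cons <- suppressWarnings(min(dm[g, others], na.rm = TRUE))
    if (is.na(d_pair) || !is.finite(d_cons)) {
      skipped <- c(skipped, s)
      next
    }
    margin <- d_cons - d_pair
    out[[length(out) + 1L]] <- data.frame(
      sample_id = s, taxon = taxon, d_pair = d_pair,
      d_nearest_conspecific = d_cons, margin = margin,
      flagged = margin <= 0, stringsAsFactors = FALSE)
  }
  if (length(skipped) > 0L)
    .warnf("samples without an evaluable comparison were skipped: %s",
           paste(skipped, collapse = ", "))
  if (length(out) == 0L)
    return(data.frame(sample_id = character(0), taxon = character(0),
                      d_pair = numeric(0), d_nearest_conspecific = numeric(0),
                      margin = numeric(0), flagged = logical(0)))
  do.call(rbind, out)
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei neighbor joining (via `ape::nj`) on the largest complete
#' submatrix: libraries are dropped greedily (most undefined pairs first,
#' ties lexicographic) until no `NA` remains, with a warning naming the
#' dropped libraries.
#'
#' @param dm a [rad_dist()] or symmetric numeric matrix.
#' @return an unrooted `phylo` tree with branch lengths.
#' @export
neighbor_joining <- function(dm) {
  m <- if (inherits(dm, "rad_dist")) dm$values else dm
  dropped <- character(0)
  while (anyNA(m)) {
    na_counts <- rowSums(is.na(m))
    worst <- names(sort(na_counts, decreasing = TRUE))[1L]
    dropped <- c(dropped, worst)
    keep <- setdiff(rownames(m), worst)
    m <- m[keep, keep, drop = FALSE]
  }
  if (length(dropped) > 0L)
    .warnf("dropped libraries with undefined distances: %s",
           paste(dropped, collapse = ", "))
  if (nrow(m) < 3L) .stopf("need at least 3 libraries with complete distances")
  ape::nj(as.dist(m))
}

#' Write / read a labelled square distance matrix as CSV
#' @param dm a [rad_dist()].
#' @param path file path.
#' @export
write_dist_csv <- function(dm, path) {
  m <- if (inherits(dm, "rad_dist")) dm$values else dm
  write.csv(m, path, row.names = TRUE, quote = FALSE)
  invisible(path)
}

#' @rdname write_dist_csv
#' @param kind distance kind for the reconstructed object.
#' @export
read_dist_csv <- function(path, kind = "genetic") {
  m <- as.matrix(read.csv(path, row.names = 1, check.names = FALSE))
  rad_dist(m, support = NULL, kind = kind)
}
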