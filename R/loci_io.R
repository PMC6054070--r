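#' Assembly filter policy
#'
#' Bundles the dataset-level filters applied during and after assembly: the
#' minimum read depth for a locus to be considered assembled for a library,
#' the minimum number of libraries sharing a locus for it to enter the final
#' dataset, the minimum number of assembled loci for a library to enter
#' paired comparisons, the minimum number of shared loci for a pairwise
#' genetic distance to be defined, and how many of the lowest-yield MDA
#' libraries to exclude from sensitive comparisons.
#'
#' @param min_coverage minimum per-locus read depth for assembly (default 7).
#' @param min_samples_per_locus minimum number of member libraries for a
#'   locus to be kept in the final dataset (default 4).
#' @param min_final_loci minimum number of assembled loci for a library to be
#'   included in paired model comparisons (default 100).
#' @param min_shared_for_distance minimum number of shared final loci for a
#'   pairwise genetic distance to be reported (default 35).
#' @param n_exclude_lowest number of MDA libraries with the smallest final
#'   locus counts to drop from distance-sensitive analyses (default 0).
#' @return object of class `filter_policy`.
#' @export
filter_policy <- function(min_coverage = 7L, min_samples_per_locus = 4L,
                          min_final_loci = 100L, min_shared_for_distance = 35L,
                          n_exclude_lowest = 0L) {
  vals <- c(min_coverage, min_samples_per_locus, min_final_loci,
            min_shared_for_distance, n_exclude_lowest)
  if (any(vals < 0)) .stopf("filter_policy values must be >= 0")
  structure(list(
    min_coverage = as.integer(min_coverage),
    min_samples_per_locus = as.integer(min_samples_per_locus),
    min_final_loci = as.integer(min_final_loci),
    min_shared_for_distance = as.integer(min_shared_for_distance),
    n_exclude_lowest = as.integer(n_exclude_lowest)
  ), class = "filter_policy")
}

#' Construct a single locus alignment
#'
#' @param locus_id character id.
#' @param seqs named character vector (names are library ids) of equal-length
#'   uppercase sequences over `A C G T R Y S W K M N -`.
#' @param flags optional compact flag string (one character per alignment
#'   column: `.` invariant, `-` variable, `*` parsimony-informative).  If
#'   `NULL` flags are computed from the member sequences.
#' @param depth optional named integer vector of per-library read depths.
#' @return object of class `locus`.
#' @export
locus <- function(locus_id, seqs, flags = NULL, depth = NULL) {
  if (length(seqs) < 1L) .stopf("locus '%s' has no members", locus_id)
  if (is.null(names(seqs)) || anyNA(names(seqs)) || any(names(seqs) == ""))
    .stopf("locus '%s': member sequences must be named by library id", locus_id)
  seqs <- toupper(seqs)
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L)
    .stopf("ragged alignment in locus '%s': lengths %s", locus_id,
           paste(unique(lens), collapse = ","))
  if (is.null(flags)) flags <- compute_snp_flags(seqs)
  if (nchar(flags) != lens[1L])
    .stopf("locus '%s': flag string length %d != alignment length %d",
           locus_id, nchar(flags), lens[1L])
  structure(list(locus_id = as.character(locus_id), seqs = seqs,
                 flags = flags, depth = depth),
            class = "locus")
}

#' Compute SNP column flags from an alignment of genotype sequences
#'
#' A column is variable (`-`) if more than one allele is present among called
#' genotypes, and parsimony-informative (`*`) if at least two distinct
#' alleles are each carried by two or more member libraries.  `N` and gaps
#' are ignored.
#'
#' @param seqs named character vector of aligned genotype sequences.
#' @return compact flag string over `.`, `-`, `*`.
#' @export
compute_snp_flags <- function(seqs) {
  mat <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
  carriers <- vapply(c("A", "C", "G", "T"), function(a) {
    has <- vapply(names(.IUPAC_CARRIES), function(b) a %in% .IUPAC_CARRIES[[b]],
                  logical(1))
    lut <- setNames(has, names(.IUPAC_CARRIES))
    m <- matrix(lut[mat], nrow = nrow(mat))
    m[is.na(m)] <- FALSE
    colSums(m)
  }, numeric(ncol(mat)))
  if (is.null(dim(carriers))) carriers <- matrix(carriers, nrow = 1L)
  n_alleles <- rowSums(carriers > 0L)
  n_shared <- rowSums(carriers >= 2L)
  flags <- ifelse(n_alleles <= 1L, ".", ifelse(n_shared >= 2L, "*", "-"))
  paste(flags, collapse = "")
}

#' Construct a per-taxon loci dataset
#'
#' The unit all statistics are computed on: an ordered collection of locus
#' alignments plus the metadata of the libraries they may contain.
#'
#' @param taxon taxon name.
#' @param loci list of [locus()] objects.
#' @param libraries metadata `data.frame`, see [read_meta()].
#' @return object of class `loci_dataset`.
#' @export
loci_dataset <- function(taxon, loci, libraries) {
  libraries <- validate_meta(libraries)
  ids <- unlist(lapply(loci, function(l) names(l$seqs)), use.names = FALSE)
  unknown <- setdiff(unique(ids), libraries$library_id)
  if (length(unknown) > 0L)
    .stopf("library ids in loci but not in metadata: %s",
           paste(unknown, collapse = ", "))
  lid <- vapply(loci, function(l) l$locus_id, character(1))
  if (anyDuplicated(lid)) .stopf("duplicate locus ids")
  names(loci) <- lid
  structure(list(taxon = taxon, loci = loci, libraries = libraries),
            class = "loci_dataset")
}

#' @export
print.loci_dataset <- function(x, ...) {
  cat(sprintf("<loci_dataset> taxon '%s': %d loci, %d libraries\n",
              x$taxon, length(x$loci), nrow(x$libraries)))
  invisible(x)
}

#' Number of loci in a dataset
#' @param ds a `loci_dataset`.
#' @export
n_loci <- function(ds) length(ds$loci)

.META_COLS <- c("library_id", "sample_id", "taxon", "population", "pool",
                "method", "input_dna_ng", "n_reads", "latitude", "longitude")

#' Validate a library metadata table
#'
#' Checks the invariants of the per-library covariate table: unique library
#' ids, unique (sample, method) pairs, method in `gDNA`/`MDA`, and input DNA
#' amount present for every MDA library.
#'
#' @param meta `data.frame` with columns `library_id`, `sample_id`, `taxon`,
#'   `population`, `pool`, `method`, `input_dna_ng`, `n_reads`, `latitude`,
#'   `longitude` (the last four may be `NA`).
#' @return the validated (and column-completed) `data.frame`.
#' @export
validate_meta <- function(meta) {
  need <- c("library_id", "sample_id", "taxon", "population", "pool", "method")
  miss <- setdiff(need, names(meta))
  if (length(miss) > 0L)
    .stopf("metadata is missing column(s): %s", paste(miss, collapse = ", "))
  for (col in setdiff(.META_COLS, names(meta))) meta[[col]] <- NA
  meta <- meta[, .META_COLS]
  meta$library_id <- as.character(meta$library_id)
  meta$sample_id <- as.character(meta$sample_id)
  meta$method <- as.character(meta$method)
  if (!all(meta$method %in% c("gDNA", "MDA")))
    .stopf("method must be 'gDNA' or 'MDA'")
  if (anyDuplicated(meta$library_id))
    .stopf("duplicate library_id in metadata")
  if (anyDuplicated(meta[, c("sample_id", "method")]))
    .stopf("duplicate (sample_id, method) pair in metadata")
  bad <- meta$method == "MDA" & !is.finite(as.numeric(meta$input_dna_ng))
  if (any(bad))
    .stopf("MDA libraries missing input_dna_ng: %s",
           paste(meta$library_id[bad], collapse = ", "))
  if (any(!is.na(meta$input_dna_ng) & meta$input_dna_ng < 0))
    .stopf("negative input_dna_ng")
  rownames(meta) <- NULL
  meta
}

#' Read / write a library metadata table (CSV)
#'
#' @param path file path.
#' @return validated metadata `data.frame`.
#' @export
read_meta <- function(path) {
  if (!file.exists(path)) .stopf("no such file: %s", path)
  validate_meta(read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname read_meta
#' @param meta metadata table.
#' @export
write_meta <- function(meta, path) {
  write.csv(validate_meta(meta), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an ipyrad-style `.loci` file
#'
#' Each locus is a block of whitespace-separated `name sequence` lines closed
#' by a separator line starting with `//`.  The separator carries per-column
#' SNP flags aligned under the sequences (`-` variable, `*` informative, any
#' other non-space character invariant) and, in recent dialects, a trailing
#' `|N|` token holding the locus id; when absent the 0-based block ordinal is
#' used.  Sequences are uppercased on read.
#'
#' @param path file path.
#' @param metadata library metadata (see [read_meta()]); every sequence name
#'   in the file must appear in `metadata$library_id`.
#' @param taxon taxon label for the dataset; defaults to the single taxon in
#'   `metadata` if unambiguous.
#' @return a [loci_dataset()].
#' @export
read_loci <- function(path, metadata, taxon = NULL) {
  if (!file.exists(path)) .stopf("no such file: %s", path)
  metadata <- validate_meta(metadata)
  if (is.null(taxon)) {
    tx <- unique(metadata$taxon)
    taxon <- if (length(tx) == 1L) tx else NA_character_
  }
  lines <- readLines(path, warn = FALSE)
  loci <- list()
  block <- character(0)
  ordinal <- 0L
  for (line in lines) {
    if (startsWith(line, "//")) {
      loci[[length(loci) + 1L]] <- .parse_locus_block(block, line, ordinal)
      block <- character(0)
      ordinal <- ordinal + 1L
    } else if (nzchar(trimws(line))) {
      block <- c(block, line)
    }
  }
  if (length(block) > 0L)
    .stopf("trailing sequence lines without a '//' separator in %s", path)
  loci_dataset(taxon, loci, metadata)
}

.parse_locus_block <- function(block, sep_line, ordinal) {
  if (length(block) == 0L)
    .stopf("empty locus block before separator '%s'", sep_line)
  parts <- regmatches(block, regexpr("^\\S+", block))
  seqs <- toupper(trimws(sub("^\\S+\\s+", "", block)))
  names(seqs) <- parts
  # locus id from a trailing |N| token if present
  id_match <- regmatches(sep_line, regexpr("\\|[^|]*\\|\\s*$", sep_line))
  if (length(id_match) == 1L) {
    id <- gsub("[|[:space:]]", "", id_match)
    flag_src <- sub("\\|[^|]*\\|\\s*$", "", sep_line)
  } else {
    id <- as.character(ordinal)
    flag_src <- sep_line
  }
  if (!nzchar(id)) id <- as.character(ordinal)
  len <- unique(nchar(seqs))
  if (length(len) != 1L)
    .stopf("ragged alignment within locus '%s'", id)
  # flags sit under the sequence columns: the sequence is the trailing token
  # of each sample line, so its columns are the last `len` characters of the
  # (trailing-whitespace-stripped) sample line; pad the separator in case a
  # writer trimmed trailing spaces over invariant columns
  width <- nchar(sub("\\s+$", "", block[1L]))
  flag_src <- sub("\\s+$", "", flag_src)
  if (nchar(flag_src) < width)
    flag_src <- paste0(flag_src, strrep(" ", width - nchar(flag_src)))
  raw <- substr(flag_src, width - len + 1L, width)
  chars <- strsplit(raw, "", fixed = TRUE)[[1L]]
  flags <- ifelse(chars == "-", "-", ifelse(chars == "*", "*", "."))
  locus(id, seqs, flags = paste(flags, collapse = ""))
}

#' Write a dataset in the `.loci` dialect accepted by [read_loci()]
#'
#' @param ds a [loci_dataset()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_loci <- function(ds, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (loc in ds$loci) {
    width <- max(nchar(names(loc$seqs))) + 4L
    for (nm in names(loc$seqs)) {
      writeLines(paste0(formatC(nm, width = -width), loc$seqs[[nm]]), con)
    }
    flag_line <- chartr(".", " ", loc$flags)
    writeLines(paste0(formatC("//", width = -width), flag_line,
                      "|", loc$locus_id, "|"), con)
  }
  invisible(path)
}

#' Presence/absence matrix of libraries across loci
#'
#' @param ds a [loci_dataset()].
#' @return logical matrix, rows = library ids (all libraries in the
#'   metadata), cols = locus ids; `TRUE` iff the library is a member of the
#'   locus.
#' @export
presence_matrix <- function(ds) {
  libs <- ds$libraries$library_id
  pm <- matrix(FALSE, nrow = length(libs), ncol = length(ds$loci),
               dimnames = list(libs, names(ds$loci)))
  for (loc in ds$loci) pm[names(loc$seqs), loc$locus_id] <- TRUE
  pm
}

#' Apply the minimum-samples-per-locus filter
#'
#' Retains exactly the loci shared by at least
#' `policy$min_samples_per_locus` libraries; the library list is unchanged.
#' Idempotent.
#'
#' @param ds a [loci_dataset()].
#' @param policy a [filter_policy()].
#' @return filtered [loci_dataset()].
#' @export
final_dataset <- function(ds, policy = filter_policy()) {
  keep <- vapply(ds$loci, function(l) length(l$seqs) >= policy$min_samples_per_locus,
                 logical(1))
  ds$loci <- ds$loci[keep]
  ds
}

#' Read / write a relaxed-phylip matrix of unlinked SNP genotypes
#'
#' First line: `n_rows n_cols`; each following line: a label, whitespace, and
#' a genotype string over IUPAC codes plus `N` and `-`.
#'
#' @param path file path.
#' @return character matrix (libraries x SNP sites) with row names.
#' @export
read_snp_phylip <- function(path) {
  if (!file.exists(path)) .stopf("no such file: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- as.integer(strsplit(trimws(lines[1L]), "\\s+")[[1L]])
  if (length(hdr) != 2L || anyNA(hdr)) .stopf("malformed phylip header")
  body <- lines[-1L]
  if (length(body) != hdr[1L])
    .stopf("phylip dimension mismatch: header says %d rows, found %d",
           hdr[1L], length(body))
  labels <- regmatches(body, regexpr("^\\S+", body))
  seqs <- toupper(gsub("\\s", "", sub("^\\S+\\s+", "", body)))
  if (any(nchar(seqs) != hdr[2L]))
    .stopf("phylip dimension mismatch: header says %d cols, found %s",
           hdr[2L], paste(unique(nchar(seqs)), collapse = ","))
  bad <- grepl("[^ACGTRYSWKMN-]", seqs)
  if (any(bad))
    .stopf("non-IUPAC characters in rows: %s", paste(labels[bad], collapse = ", "))
  m <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
  rownames(m) <- labels
  m
}

#' @rdname read_snp_phylip
#' @param m character matrix of genotypes with row names.
#' @export
write_snp_phylip <- function(m, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(sprintf("%d %d", nrow(m), ncol(m)), con)
  width <- max(nchar(rownames(m))) + 4L
  for (i in seq_len(nrow(m))) {
    writeLines(paste0(formatC(rownames(m)[i], width = -width),
                      paste(m[i, ], collapse = "")), con)
  }
  invisible(path)
}

#' Read / write per-library locus depths (long TSV)
#'
#' The `.loci` format does not carry read depths; the simulator and pipeline
#' exchange them through a three-column TSV (`library_id`, `locus_id`,
#' `depth`).
#'
#' @param path file path.
#' @return `data.frame` with columns `library_id`, `locus_id`, `depth`.
#' @export
read_depths <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("library_id", "locus_id", "depth")
  if (!all(need %in% names(d))) .stopf("depth table must have columns %s",
                                       paste(need, collapse = ", "))
  d
}

#' @rdname read_depths
#' @param depths depth table.
#' @export
write_depths <- function(depths, path) {
  write.table(depths, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Attach depths from a long table to a dataset
#' @param ds a [loci_dataset()].
#' @param depths depth table as returned by [read_depths()].
#' @return the dataset with per-locus `depth` vectors filled in.
#' @export
attach_depths <- function(ds, depths) {
  sp <- split(depths, depths$locus_id)
  for (id in names(sp)) {
    if (!id %in% names(ds$loci)) next
    d <- sp[[id]]
    ds$loci[[id]]$depth <- setNames(as.integer(d$depth), d$library_id)
  }
  ds
}
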