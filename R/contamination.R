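#' Extract gDNA sequences from the final dataset of each taxon
#'
#' Reference material for contamination screening: every sequence
#' contributed by a gDNA library to a locus retained in the final dataset,
#' per taxon.  The minimum-samples filter applied first makes contaminant
#' loci unlikely to enter the reference.
#'
#' @param datasets named list of [loci_dataset()].
#' @param policy a [filter_policy()].
#' @return named list (taxon -> character vector of degapped sequences).
#' @export
gdna_final_sequences <- function(datasets, policy = filter_policy()) {
  out <- list()
  for (tx in names(datasets)) {
    ds <- final_dataset(datasets[[tx]], policy)
    gdna <- ds$libraries$library_id[ds$libraries$method == "gDNA"]
    seqs <- character(0)
    for (loc in ds$loci) {
      keep <- intersect(names(loc$seqs), gdna)
      seqs <- c(seqs, unname(loc$seqs[keep]))
    }
    out[[tx]] <- gsub("-", "", seqs, fixed = TRUE)
  }
  out
}

.kmers <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  unique(substring(seq, 1:(n - k + 1L), k:n))
}

.sub_mat <- function() {
  if (is.null(.pkg_cache$sub_mat))
    .pkg_cache$sub_mat <- Biostrings::nucleotideSubstitutionMatrix(
      match = 1, mismatch = -1, baseOnly = FALSE)
  .pkg_cache$sub_mat
}

# alignment length (columns incl. gaps) and aligned query residues
.aln_dims <- function(aln) {
  ap <- as.character(Biostrings::pattern(aln))
  c(len = nchar(ap), q_aligned = nchar(gsub("-", "", ap, fixed = TRUE)))
}

.global_identity <- function(a, b) {
  aln <- Biostrings::pairwiseAlignment(a, b, type = "global",
    substitutionMatrix = .sub_mat(), gapOpening = 5, gapExtension = 2)
  Biostrings::nmatch(aln) / .aln_dims(aln)[["len"]]
}

#' Build a de-replicated classification reference
#'
#' Greedy length-sorted clustering within each taxon: a sequence joins an
#' existing entry when its global identity to the representative is at least
#' `identity` (forward strand only), otherwise it seeds a new entry.  The
#' per-taxon entries are combined, optional human (or other non-self)
#' records are added, and a k-mer index over the entries is built for fast
#' candidate lookup.
#'
#' @param seqs_by_taxon named list (taxon -> character vector of sequences),
#'   e.g. from [gdna_final_sequences()].
#' @param human optional character vector of non-self reference sequences,
#'   registered under source `"human"`.
#' @param identity de-replication identity threshold (default 0.95).
#' @param k k-mer size for the candidate index (default 13, minimum 11).
#' @return object of class `reference_db` with `entries`
#'   (`data.frame`: entry_id, taxon, seq), `k`, and the postings index.
#' @export
build_reference <- function(seqs_by_taxon, human = NULL, identity = 0.95,
                            k = 13L) {
  k <- as.integer(k)
  if (k < 11L) .stopf("k must be >= 11")
  total <- sum(vapply(seqs_by_taxon, length, integer(1)))
  if (total == 0L) .stopf("no input sequences")
  entries <- list()
  for (tx in names(seqs_by_taxon)) {
    seqs <- toupper(gsub("-", "", seqs_by_taxon[[tx]], fixed = TRUE))
    seqs <- unique(seqs[nzchar(seqs)])
    seqs <- seqs[order(nchar(seqs), decreasing = TRUE)]
    # greedy incremental clustering in length order: the longest unassigned
    # sequence seeds a representative, then all unassigned sequences sharing
    # k-mers with it are aligned in one batch and absorbed if identical
    # enough; each sequence therefore joins the earliest representative that
    # accepts it
    seq_kmers <- lapply(seqs, .kmers, k = k)
    assigned <- rep(FALSE, length(seqs))
    reps <- character(0)
    while (any(!assigned)) {
      ri <- which(!assigned)[1L]
      reps <- c(reps, seqs[ri])
      assigned[ri] <- TRUE
      open <- which(!assigned)
      if (length(open) == 0L) break
      rk <- seq_kmers[[ri]]
      cand <- open[vapply(seq_kmers[open],
                          function(km) any(km %in% rk), logical(1))]
      if (length(cand) == 0L) next
      aln <- Biostrings::pairwiseAlignment(seqs[cand], seqs[ri],
        type = "global", substitutionMatrix = .sub_mat(),
        gapOpening = 5, gapExtension = 2)
      alen <- nchar(as.character(Biostrings::pattern(aln)))
      ident <- Biostrings::nmatch(aln) / alen
      assigned[cand[ident >= identity]] <- TRUE
    }
    if (length(reps) > 0L)
      entries[[tx]] <- data.frame(
        entry_id = sprintf("%s_ref%04d", tx, seq_along(reps)),
        taxon = tx, seq = reps, stringsAsFactors = FALSE)
  }
  if (!is.null(human) && length(human) > 0L) {
    human <- toupper(gsub("-", "", human, fixed = TRUE))
    entries[["human"]] <- data.frame(
      entry_id = sprintf("human_ref%04d", seq_along(human)),
      taxon = "human", seq = human, stringsAsFactors = FALSE)
  }
  entries <- do.call(rbind, entries)
  rownames(entries) <- NULL
  index <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(entries))) {
    for (km in .kmers(entries$seq[i], k)) {
      index[[km]] <- c(index[[km]], i)
    }
  }
  structure(list(entries = entries, k = k, index = index),
            class = "reference_db")
}

#' @export
print.reference_db <- function(x, ...) {
  cat(sprintf("<reference_db> %d entries (%s), k = %d\n", nrow(x$entries),
              paste(sprintf("%s: %d", names(table(x$entries$taxon)),
                            table(x$entries$taxon)), collapse = ", "),
              x$k))
  invisible(x)
}

#' Classify sequences against the reference
#'
#' Each query is matched to candidate entries sharing k-mers with it, the
#' candidates are aligned locally (forward strand), and the best-scoring
#' entry with identity >= `min_identity` over at least
#' `min_fraction_aligned` of the query decides the category: `human` if the
#' entry is a human record, `correct` if its taxon equals `truth_taxon`,
#' `incorrect` otherwise; queries with no candidate or only sub-threshold
#' alignments are `no_match`.  Score ties break toward `truth_taxon`, then
#' lexicographic entry id.
#'
#' @param seqs character vector of query sequences.
#' @param truth_taxon the taxon the queries are supposed to come from.
#' @param db a [build_reference()] database.
#' @param min_identity minimum alignment identity (default 0.85).
#' @param min_fraction_aligned minimum aligned fraction of the query
#'   (default 0.5).
#' @param max_candidates number of top k-mer candidates to align (default 8).
#' @return object of class `classification_summary`: counts and proportions
#'   of `correct` / `incorrect` / `human` / `no_match`, plus the per-query
#'   assignment table.
#' @export
classify_sequences <- function(seqs, truth_taxon, db, min_identity = 0.85,
                               min_fraction_aligned = 0.5,
                               max_candidates = 8L) {
  cats <- character(length(seqs))
  hits <- character(length(seqs))
  if (length(seqs) > 0L) {
    for (qi in seq_along(seqs)) {
      q <- toupper(gsub("-", "", seqs[qi], fixed = TRUE))
      km <- .kmers(q, db$k)
      post <- unlist(lapply(km, function(x) db$index[[x]]), use.names = FALSE)
      if (length(post) == 0L) {
        cats[qi] <- "no_match"
        next
      }
      tab <- sort(table(post), decreasing = TRUE)
      # entries sharing far fewer k-mers than the best candidate cannot win
      tab <- tab[tab >= max(2, 0.5 * tab[1L])]
      cand <- as.integer(names(tab))[seq_len(min(length(tab), max_candidates))]
      best <- NULL
      for (ci in cand) {
        aln <- Biostrings::pairwiseAlignment(q, db$entries$seq[ci],
          type = "local", substitutionMatrix = .sub_mat(),
          gapOpening = 5, gapExtension = 2)
        dims <- .aln_dims(aln)
        ident <- Biostrings::nmatch(aln) / dims[["len"]]
        frac <- dims[["q_aligned"]] / nchar(q)
        if (ident < min_identity || frac < min_fraction_aligned) next
        score <- Biostrings::nmatch(aln)
        if (is.null(best) || score > best$score ||
            (score == best$score && .tie_beats(db, ci, best$ci, truth_taxon))) {
          best <- list(ci = ci, score = score)
        }
        # a (near-)perfect full-length hit cannot be beaten
        if (ident >= 0.999 && frac >= 0.999) break
      }
      if (is.null(best)) {
        cats[qi] <- "no_match"
      } else {
        tx <- db$entries$taxon[best$ci]
        cats[qi] <- if (tx == "human") "human"
          else if (tx == truth_taxon) "correct" else "incorrect"
        hits[qi] <- db$entries$entry_id[best$ci]
      }
    }
  }
  counts <- c(correct = sum(cats == "correct"),
              incorrect = sum(cats == "incorrect"),
              human = sum(cats == "human"),
              no_match = sum(cats == "no_match"))
  structure(list(counts = counts, total = length(seqs),
                 proportions = if (length(seqs) > 0L) counts / length(seqs)
                               else counts * NA_real_,
                 assignments = data.frame(category = cats, entry = hits,
                                          stringsAsFactors = FALSE)),
            class = "classification_summary")
}

.tie_beats <- function(db, ci, cj, truth_taxon) {
  ti <- db$entries$taxon[ci] == truth_taxon
  tj <- db$entries$taxon[cj] == truth_taxon
  if (ti != tj) return(ti)
  db$entries$entry_id[ci] < db$entries$entry_id[cj]
}

#' @export
print.classification_summary <- function(x, ...) {
  cat(sprintf("<classification_summary> n = %d: %s\n", x$total,
              paste(sprintf("%s %d", names(x$counts), x$counts),
                    collapse = ", ")))
  invisible(x)
}

#' Per-library classification report across pipeline stages
#'
#' Classifies every library's sequences at the requested stages
#' (`assembled`: all member sequences; `final`: member sequences of final
#' loci; `reads`: user-supplied read sequences for real data) and computes
#' the paired MDA - gDNA difference of incorrect-match proportions per
#' sample.
#'
#' @param datasets named list of [loci_dataset()].
#' @param db a [build_reference()] database.
#' @param policy a [filter_policy()].
#' @param stages subset of `c("reads", "assembled", "final")`.
#' @param reads optional named list (library_id -> character vector of read
#'   sequences) required for the `reads` stage.
#' @param ... passed to [classify_sequences()].
#' @return list with `summary` (`data.frame`: library_id, taxon, method,
#'   stage, counts, total, proportions) and `paired_diff` (`data.frame`:
#'   sample_id, stage, incorrect proportion difference MDA - gDNA).
#' @export
stage_report <- function(datasets, db, policy = filter_policy(),
                         stages = c("assembled", "final"), reads = NULL,
                         ...) {
  stages <- match.arg(stages, c("reads", "assembled", "final"),
                      several.ok = TRUE)
  if ("reads" %in% stages && is.null(reads))
    .stopf("the 'reads' stage needs read sequences (reads = ...)")
  rows <- list()
  for (tx in names(datasets)) {
    ds <- datasets[[tx]]
    fds <- final_dataset(ds, policy)
    for (i in seq_len(nrow(ds$libraries))) {
      lib <- ds$libraries$library_id[i]
      for (stage in stages) {
        seqs <- switch(stage,
          reads = reads[[lib]],
          assembled = {
            ids <- .library_locus_ids(ds, lib)
            vapply(ids, function(x) ds$loci[[x]]$seqs[[lib]], character(1))
          },
          final = {
            ids <- .library_locus_ids(fds, lib)
            vapply(ids, function(x) fds$loci[[x]]$seqs[[lib]], character(1))
          })
        if (is.null(seqs)) seqs <- character(0)
        cs <- classify_sequences(unname(seqs), tx, db, ...)
        rows[[length(rows) + 1L]] <- data.frame(
          library_id = lib, taxon = tx,
          method = ds$libraries$method[i], stage = stage,
          correct = cs$counts[["correct"]],
          incorrect = cs$counts[["incorrect"]],
          human = cs$counts[["human"]],
          no_match = cs$counts[["no_match"]],
          total = cs$total,
          p_incorrect = if (cs$total > 0L)
            cs$counts[["incorrect"]] / cs$total else NA_real_,
          stringsAsFactors = FALSE)
      }
    }
  }
  summary <- do.call(rbind, rows)
  rownames(summary) <- NULL
  meta_all <- do.call(rbind, lapply(datasets, function(d) d$libraries))
  summary$sample_id <- meta_all$sample_id[match(summary$library_id,
                                                meta_all$library_id)]
  pd <- list()
  for (s in unique(summary$sample_id)) {
    for (stage in stages) {
      sub <- summary[summary$sample_id == s & summary$stage == stage, ]
      g <- sub$p_incorrect[sub$method == "gDNA"]
      m <- sub$p_incorrect[sub$method == "MDA"]
      if (length(g) == 1L && length(m) == 1L && !is.na(g) && !is.na(m))
        pd[[length(pd) + 1L]] <- data.frame(
          sample_id = s, stage = stage, diff_incorrect = m - g,
          stringsAsFactors = FALSE)
    }
  }
  list(summary = summary,
       paired_diff = if (length(pd) > 0L) do.call(rbind, pd) else
         data.frame(sample_id = character(0), stage = character(0),
                    diff_incorrect = numeric(0)))
}
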