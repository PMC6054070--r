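#' Assemble a run configuration
#'
#' Exactly one of `sim` (a [sim_config()]) or `inputs` (paths to real data:
#' named list with `loci` = named character vector of per-taxon `.loci`
#' paths, `metadata` = metadata CSV, optional `depths` = depth TSV) must be
#' given.
#'
#' @param sim optional [sim_config()].
#' @param inputs optional list of input paths (see above).
#' @param filter a [filter_policy()].
#' @param condenser a [condenser_policy()].
#' @param n_permutations permutations for MDMR and Mantel tests.
#' @param seed master seed for the analysis stages.
#' @return object of class `run_config`.
#' @export
run_config <- function(sim = NULL, inputs = NULL, filter = filter_policy(),
                       condenser = condenser_policy(),
                       n_permutations = 199L, seed = 1L) {
  if (is.null(sim) == is.null(inputs))
    .stopf("exactly one of 'sim' or 'inputs' must be given")
  structure(list(sim = sim, inputs = inputs, filter = filter,
                 condenser = condenser,
                 n_permutations = as.integer(n_permutations),
                 seed = as.integer(seed)),
            class = "run_config")
}

.load_inputs <- function(inputs) {
  metadata <- read_meta(inputs$metadata)
  datasets <- list()
  for (tx in names(inputs$loci)) {
    meta_tx <- metadata[metadata$taxon == tx, , drop = FALSE]
    datasets[[tx]] <- read_loci(inputs$loci[[tx]], meta_tx, taxon = tx)
  }
  if (!is.null(inputs$depths)) {
    depths <- read_depths(inputs$depths)
    datasets <- lapply(datasets, attach_depths, depths = depths)
  }
  list(datasets = datasets, metadata = metadata, truth = NULL)
}

#' Run the full paired-library QC workflow
#'
#' Orchestrates the analysis end to end: per-library statistics, the two
#' distance matrices with MDMR on each, problematic-sample flagging,
#' neighbor-joining trees, contamination classification (multi-taxon
#' datasets), a paired mixed model for locus counts, matrix condensing and
#' PCA/k-means clustering.  Every stage writes its tables under `out_dir`
#' and failures abort with the stage name (partial outputs are retained).
#'
#' @param config a [run_config()].
#' @param out_dir output directory (created if needed).
#' @param quiet suppress progress messages.
#' @return invisibly, a list of the in-memory stage results; a
#'   `manifest.json` in `out_dir` records seeds, versions and input digests.
#' @export
run_all <- function(config, out_dir, quiet = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(sprintf(...))
  stage <- function(name, expr) {
    say("[%s] running", name)
    tryCatch(expr, error = function(e)
      .stopf("stage '%s' failed: %s", name, conditionMessage(e)))
  }
  results <- list()
  policy <- config$filter

  data <- stage("load", {
    if (!is.null(config$sim)) {
      simulate_paired_study(config$sim, out_dir = file.path(out_dir, "sim"))
    } else {
      .load_inputs(config$inputs)
    }
  })
  datasets <- data$datasets
  metadata <- data$metadata

  results$stats <- stage("stats", {
    stats <- do.call(rbind, lapply(datasets, library_stats, policy = policy))
    rownames(stats) <- NULL
    write.csv(stats, file.path(out_dir, "library_stats.csv"),
              row.names = FALSE)
    stats
  })

  results$overlap <- stage("overlap_mdmr", {
    out <- list()
    for (tx in names(datasets)) {
      fds <- final_dataset(datasets[[tx]], policy)
      if (length(fds$loci) < 2L) next
      pm <- presence_matrix(fds)
      dm <- locus_overlap_dissimilarity(pm)
      write_dist_csv(dm, file.path(out_dir, paste0(tx, "_overlap_dist.csv")))
      st <- results$stats[results$stats$taxon == tx, ]
      pred <- data.frame(
        method = st$method, pool = st$pool, population = st$population,
        log_final_loci = log1p(st$n_final_loci),
        row.names = st$library_id)
      fit <- tryCatch(
        mdmr(dm, pred, n_permutations = config$n_permutations,
             seed = .sub_seed(config$seed, paste0("mdmr-overlap-", tx))),
        error = function(e) NULL)
      out[[tx]] <- list(dist = dm, mdmr = fit)
    }
    eff <- do.call(rbind, lapply(names(out), function(tx)
      if (!is.null(out[[tx]]$mdmr))
        cbind(taxon = tx, out[[tx]]$mdmr$effects)))
    if (!is.null(eff))
      write.csv(eff, file.path(out_dir, "mdmr_overlap.csv"),
                row.names = FALSE)
    out
  })

  results$genetic <- stage("genetic_distances", {
    out <- list()
    for (tx in names(datasets)) {
      gd <- tryCatch(genetic_distance(datasets[[tx]], policy),
                     error = function(e) NULL)
      if (is.null(gd)) next
      write_dist_csv(gd, file.path(out_dir, paste0(tx, "_genetic_dist.csv")))
      flags <- suppressWarnings(
        flag_problematic_samples(gd, datasets[[tx]]$libraries))
      tree <- tryCatch(suppressWarnings(neighbor_joining(gd)),
                       error = function(e) NULL)
      if (!is.null(tree))
        ape::write.tree(tree, file.path(out_dir, paste0(tx, "_nj.nwk")))
      out[[tx]] <- list(dist = gd, flags = flags, tree = tree)
    }
    flags <- do.call(rbind, lapply(out, `[[`, "flags"))
    if (!is.null(flags) && nrow(flags) > 0L)
      write.csv(flags, file.path(out_dir, "problematic_samples.csv"),
                row.names = FALSE)
    out
  })

  results$contamination <- stage("contamination", {
    if (length(datasets) < 2L) {
      say("[contamination] skipped: single-taxon dataset")
      NULL
    } else {
      ref_seqs <- gdna_final_sequences(datasets, policy)
      ref_seqs <- ref_seqs[vapply(ref_seqs, length, integer(1)) > 0L]
      if (length(ref_seqs) == 0L) NULL else {
        db <- build_reference(ref_seqs)
        rep <- stage_report(datasets, db, policy)
        write.csv(rep$summary, file.path(out_dir, "contamination_stages.csv"),
                  row.names = FALSE)
        write.csv(rep$paired_diff,
                  file.path(out_dir, "contamination_paired_diff.csv"),
                  row.names = FALSE)
        rep
      }
    }
  })

  results$models <- stage("mixed_models", {
    st <- results$stats
    st <- st[!is.na(st$n_assembled_loci) & st$n_assembled_loci > 0, ]
    st$log_reads <- log(st$n_reads)
    fits <- list()
    # paired comparison: does MDA yield fewer loci at a given read count?
    if (length(unique(st$method)) == 2L && length(unique(st$taxon)) >= 2L) {
      st$loci_logit <- transform_response(pmin(st$n_assembled_loci, 29999),
                                          "logit_capped")
      fits$loci_vs_method <- tryCatch(
        fit_mixed(loci_logit ~ log_reads * method + (1 | taxon), st),
        error = function(e) NULL)
    }
    # input-DNA effect on MDA library yields
    mda <- st[st$method == "MDA" & !is.na(st$input_dna_ng), ]
    if (nrow(mda) >= 10L && length(unique(mda$pool)) >= 2L) {
      fits$loci_vs_input <- tryCatch(
        fit_mixed(n_assembled_loci ~ log_reads * input_dna_ng + (1 | pool),
                  mda),
        error = function(e) NULL)
    }
    tab <- list()
    for (nm in names(fits)) {
      if (is.null(fits[[nm]])) next
      co <- fits[[nm]]$coefficients
      tab[[nm]] <- data.frame(model = nm, term = names(co),
                              estimate = unname(co),
                              stringsAsFactors = FALSE)
    }
    if (length(tab) > 0L)
      write.csv(do.call(rbind, tab), file.path(out_dir, "mixed_models.csv"),
                row.names = FALSE)
    fits
  })

  results$popgen <- stage("popgen", {
    out <- list()
    for (tx in names(datasets)) {
      fds <- final_dataset(datasets[[tx]], policy)
      if (length(fds$loci) < 5L) next
      pm <- presence_matrix(fds)
      cd <- tryCatch(condense(pm, config$condenser), error = function(e) NULL)
      if (is.null(cd)) next
      geno <- .snp_genotype_matrix(fds, cd$samples, cd$loci)
      if (ncol(geno) < 2L) next
      enc <- dosage_encode(geno)
      k_max <- min(6L, nrow(enc$dosage) - 1L)
      pk <- tryCatch(
        pca_kmeans(enc$dosage, k_range = seq_len(k_max),
                   seed = .sub_seed(config$seed, paste0("kmeans-", tx))),
        error = function(e) NULL)
      out[[tx]] <- list(condense = cd, clusters = pk)
      if (!is.null(pk))
        write.csv(data.frame(library_id = names(pk$assignments),
                             cluster = pk$assignments, taxon = tx),
                  file.path(out_dir, paste0(tx, "_clusters.csv")),
                  row.names = FALSE)
    }
    out
  })

  stage("manifest", {
    cfg_path <- file.path(out_dir, "run_config.yaml")
    yaml::write_yaml(.config_as_list(config), cfg_path)
    manifest <- list(
      package = "radpair",
      version = as.character(utils::packageVersion("radpair")),
      r_version = as.character(getRversion()),
      seed = config$seed,
      config_digest = unname(tools::md5sum(cfg_path)),
      created = "see file mtimes",
      stages = names(results)
    )
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    NULL
  })
  say("run complete: %s", out_dir)
  invisible(results)
}

.config_as_list <- function(config) {
  rapply(unclass(config), f = function(x) x, how = "replace")
}

# per-library SNP genotype matrix over one SNP site per locus (unlinked):
# the first variable column of each kept locus
.snp_genotype_matrix <- function(ds, samples, loci_ids) {
  cols <- list()
  for (lid in loci_ids) {
    loc <- ds$loci[[lid]]
    pos <- which(strsplit(loc$flags, "", fixed = TRUE)[[1L]] %in% c("-", "*"))
    if (length(pos) == 0L) next
    p <- pos[1L]
    col <- setNames(rep("N", length(samples)), samples)
    for (nm in intersect(names(loc$seqs), samples))
      col[nm] <- substr(loc$seqs[[nm]], p, p)
    cols[[lid]] <- col
  }
  if (length(cols) == 0L)
    return(matrix(character(0), nrow = length(samples), ncol = 0L,
                  dimnames = list(samples, NULL)))
  do.call(cbind, cols)
}
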