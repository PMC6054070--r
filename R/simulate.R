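#' Configuration for the paired-library ddRAD simulator
#'
#' Defines a multi-taxon study in which every individual can have a gDNA and
#' an MDA library prepared from the same DNA.  Population structure follows
#' the Balding-Nichols island model (per-taxon `fst`).  Coverage across loci
#' is Dirichlet-multinomial: locus weights are Dirichlet with a scalar
#' concentration that, for MDA libraries, scales linearly with the amount of
#' input DNA in the amplification reaction — small inputs give low
#' concentration, hence overdispersed depth and locus dropout below the
#' assembly depth threshold.  At heterozygous sites the allele split of the
#' reads is beta-binomial for MDA (allelic imbalance) and binomial for gDNA;
#' a heterozygote is called only when the minor allele is seen in at least
#' `min_minor_reads` reads, otherwise the major allele is called homozygous
#' (allelic dropout).
#'
#' @param seed integer master seed (mandatory); per-library substreams are
#'   derived by hashing library ids so results do not depend on call order.
#' @param taxa list of taxa, each a list with `name`, `n_populations`,
#'   `n_individuals_per_pop`, `fst` in (0,1).
#' @param n_loci loci per taxon.
#' @param locus_length alignment length in bp (default 90, the usable length
#'   of a 100-bp single-end read after barcode trimming).
#' @param theta per-site probability that a site is polymorphic.
#' @param reads_per_library mean mapped-read budget per library.
#' @param reads_sd_log lognormal SD of the per-library read budget (read
#'   counts in pooled sequencing are highly variable).
#' @param gdna_concentration Dirichlet concentration for gDNA locus weights
#'   (large = even coverage).
#' @param mda_concentration_at_ref Dirichlet concentration of an MDA library
#'   at `mda_input_ref_ng` of input DNA; actual concentration is
#'   `mda_concentration_at_ref * input_dna_ng / mda_input_ref_ng`, floored at
#'   0.05.
#' @param mda_input_ref_ng reference input DNA amount (ng).
#' @param input_dna_range range (ng) from which per-MDA-library input DNA is
#'   drawn log-uniformly when not supplied explicitly; defaults to 6-360 ng,
#'   the span typical of whole-body extractions of small beetles.
#' @param imbalance_beta beta-binomial shape for the MDA allele split at
#'   heterozygous sites; smaller = stronger allelic imbalance.
#' @param min_minor_reads minimum minor-allele reads to call a heterozygote.
#' @param contamination_fraction fraction of assembled loci per MDA library
#'   replaced by cross-taxon contaminant sequences (0 disables).
#' @param contamination_mode `"separate"` (contaminant slots assemble into
#'   their own loci) or `"co_assemble"` (donor sequence replaces the member
#'   sequence inside the locus alignment); see [inject_contamination()].
#' @param n_pools number of size-selection/PCR pools libraries are assigned
#'   to (round-robin).
#' @param filter a [filter_policy()].
#' @return object of class `sim_config`.
#' @export
sim_config <- function(seed,
                       taxa = list(
                         list(name = "taxonA", n_populations = 2L,
                              n_individuals_per_pop = 6L, fst = 0.1),
                         list(name = "taxonB", n_populations = 2L,
                              n_individuals_per_pop = 6L, fst = 0.1)
                       ),
                       n_loci = 200L, locus_length = 90L, theta = 0.02,
                       reads_per_library = 20000L, reads_sd_log = 0.4,
                       gdna_concentration = 200, mda_concentration_at_ref = 5,
                       mda_input_ref_ng = 100, input_dna_range = c(6, 360),
                       imbalance_beta = 0.5, min_minor_reads = 2L,
                       contamination_fraction = 0,
                       contamination_mode = c("separate", "co_assemble"),
                       n_pools = 2L, filter = filter_policy()) {
  if (missing(seed)) .stopf("sim_config: seed is mandatory")
  for (tx in taxa) {
    if (tx$fst <= 0 || tx$fst >= 1) .stopf("fst must be in (0,1)")
  }
  stopifnot(n_loci >= 1, locus_length >= 1, theta >= 0, theta <= 1,
            reads_per_library >= 1, gdna_concentration > 0,
            mda_concentration_at_ref > 0, mda_input_ref_ng > 0,
            imbalance_beta > 0, min_minor_reads >= 0,
            contamination_fraction >= 0, contamination_fraction < 1)
  structure(list(
    seed = as.integer(seed), taxa = taxa, n_loci = as.integer(n_loci),
    locus_length = as.integer(locus_length), theta = theta,
    reads_per_library = as.integer(reads_per_library),
    reads_sd_log = reads_sd_log,
    gdna_concentration = gdna_concentration,
    mda_concentration_at_ref = mda_concentration_at_ref,
    mda_input_ref_ng = mda_input_ref_ng,
    input_dna_range = input_dna_range,
    imbalance_beta = imbalance_beta,
    min_minor_reads = as.integer(min_minor_reads),
    contamination_fraction = contamination_fraction,
    contamination_mode = match.arg(contamination_mode),
    n_pools = as.integer(n_pools), filter = filter
  ), class = "sim_config")
}

#' Simulate true genotypes under the Balding-Nichols island model
#'
#' For each polymorphic site the ancestral allele frequency is drawn from
#' Uniform(0.05, 0.95) and each population's frequency from
#' Beta(p(1-F)/F, (1-p)(1-F)/F) with F the taxon's `fst`; individuals are
#' diploid with Hardy-Weinberg genotypes within populations.  Polymorphic
#' sites are placed uniformly along each locus (Binomial(locus_length,
#' theta) sites per locus).
#'
#' @param config a [sim_config()].
#' @return object of class `sim_truth`: per taxon, an `individuals` table
#'   (sample_id, population), and per locus the ancestral sequence, a site
#'   table (position, ref, alt, ancestral frequency), the population
#'   frequency matrix, and the individual x site matrix of alt-allele
#'   dosages (0/1/2).  A `contamination` table (empty here) records injected
#'   contaminant loci.
#' @export
simulate_genotypes <- function(config) {
  set.seed(.sub_seed(config$seed, "genotypes"))
  bases <- c("A", "C", "G", "T")
  taxa <- list()
  for (tx in config$taxa) {
    n_pop <- tx$n_populations
    n_ind <- tx$n_individuals_per_pop
    inds <- data.frame(
      sample_id = unlist(lapply(seq_len(n_pop), function(p)
        sprintf("%s_p%d_i%d", tx$name, p, seq_len(n_ind)))),
      population = rep(sprintf("pop%d", seq_len(n_pop)), each = n_ind),
      stringsAsFactors = FALSE
    )
    F <- tx$fst
    loci <- vector("list", config$n_loci)
    for (l in seq_len(config$n_loci)) {
      anc <- sample(bases, config$locus_length, replace = TRUE)
      n_var <- rbinom(1L, config$locus_length, config$theta)
      pos <- sort(sample.int(config$locus_length, n_var))
      ref <- anc[pos]
      alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1L), character(1))
      p_anc <- runif(n_var, 0.05, 0.95)
      if (F < 1e-8) {
        pop_freq <- matrix(rep(p_anc, each = n_pop), nrow = n_pop)
      } else {
        pop_freq <- matrix(
          rbeta(n_pop * n_var,
                shape1 = rep(p_anc * (1 - F) / F, each = n_pop),
                shape2 = rep((1 - p_anc) * (1 - F) / F, each = n_pop)),
          nrow = n_pop)
      }
      geno <- matrix(0L, nrow = nrow(inds), ncol = n_var)
      if (n_var > 0L) {
        for (p in seq_len(n_pop)) {
          rows <- which(inds$population == sprintf("pop%d", p))
          geno[rows, ] <- matrix(
            rbinom(length(rows) * n_var, 2L,
                   rep(pop_freq[p, ], each = length(rows))),
            nrow = length(rows))
        }
      }
      rownames(geno) <- inds$sample_id
      loci[[l]] <- list(
        anc_seq = paste(anc, collapse = ""),
        sites = data.frame(pos = pos, ref = ref, alt = alt, p_anc = p_anc,
                           stringsAsFactors = FALSE, row.names = NULL),
        pop_freq = pop_freq, geno = geno
      )
    }
    names(loci) <- sprintf("%s_L%04d", tx$name, seq_len(config$n_loci))
    taxa[[tx$name]] <- list(individuals = inds, loci = loci, fst = F)
  }
  structure(list(taxa = taxa, weights = list(),
                 contamination = data.frame(
                   library_id = character(0), locus_id = character(0),
                   donor_taxon = character(0), donor_locus = character(0),
                   mode = character(0), stringsAsFactors = FALSE)),
            class = "sim_truth")
}

#' True genotype sequence of one individual at one locus
#'
#' Ancestral sequence with IUPAC genotype codes substituted at polymorphic
#' sites according to the individual's alt-allele dosage.
#'
#' @param truth a `sim_truth`.
#' @param taxon,locus_id,sample_id identifiers.
#' @return character sequence.
#' @export
true_sequence <- function(truth, taxon, locus_id, sample_id) {
  loc <- truth$taxa[[taxon]]$loci[[locus_id]]
  chars <- strsplit(loc$anc_seq, "", fixed = TRUE)[[1L]]
  st <- loc$sites
  if (nrow(st) > 0L) {
    d <- loc$geno[sample_id, ]
    for (k in seq_len(nrow(st))) {
      chars[st$pos[k]] <- switch(as.character(d[k]),
        "0" = st$ref[k], "2" = st$alt[k],
        iupac_code(st$ref[k], st$alt[k]))
    }
  }
  paste(chars, collapse = "")
}

#' Simulate read depths and called sequences for one library
#'
#' Implements the Dirichlet-multinomial coverage model and the depth-aware
#' genotype caller described in [sim_config()].  All randomness comes from a
#' substream derived from the master seed and the library id.
#'
#' @param truth a `sim_truth` from [simulate_genotypes()].
#' @param meta one-row metadata `data.frame` for the library.
#' @param config the [sim_config()].
#' @return list with `library_id`, `depths` (named integer over all loci),
#'   `assembled` (logical, depth >= min_coverage), `seqs` (named character:
#'   called genotype sequences for assembled loci), and `weights` (true
#'   locus weights).
#' @export
simulate_library <- function(truth, meta, config) {
  set.seed(.sub_seed(config$seed, paste0("lib:", meta$library_id)))
  tx <- truth$taxa[[meta$taxon]]
  locus_ids <- names(tx$loci)
  n <- length(locus_ids)
  alpha <- if (meta$method == "MDA") {
    max(config$mda_concentration_at_ref *
          as.numeric(meta$input_dna_ng) / config$mda_input_ref_ng, 0.05)
  } else {
    config$gdna_concentration
  }
  g <- rgamma(n, shape = alpha)
  if (sum(g) <= 0) g <- rep(1, n)
  w <- g / sum(g)
  depths <- as.integer(rmultinom(1L, meta$n_reads, w))
  names(depths) <- locus_ids
  assembled <- depths >= config$filter$min_coverage
  seqs <- character(0)
  for (lid in locus_ids[assembled]) {
    loc <- tx$loci[[lid]]
    chars <- strsplit(loc$anc_seq, "", fixed = TRUE)[[1L]]
    st <- loc$sites
    if (nrow(st) > 0L) {
      d <- loc$geno[meta$sample_id, ]
      D <- depths[[lid]]
      for (k in seq_len(nrow(st))) {
        chars[st$pos[k]] <- if (d[k] == 0L) st$ref[k]
        else if (d[k] == 2L) st$alt[k]
        else {
          # heterozygote: allele split of the read stack
          p_alt <- if (meta$method == "MDA")
            rbeta(1L, config$imbalance_beta, config$imbalance_beta) else 0.5
          x_alt <- rbinom(1L, D, p_alt)
          minor <- min(x_alt, D - x_alt)
          if (minor >= config$min_minor_reads) {
            iupac_code(st$ref[k], st$alt[k])
          } else if (x_alt > D - x_alt) st$alt[k] else st$ref[k]
        }
      }
    }
    seqs[[lid]] <- paste(chars, collapse = "")
  }
  list(library_id = meta$library_id, depths = depths, assembled = assembled,
       seqs = seqs, weights = w)
}

#' Inject cross-taxon contamination into one library
#'
#' Replaces a Binomial(n assembled, fraction) draw of the library's assembled
#' locus slots with sequences from a donor taxon.  In `"separate"` mode the
#' contaminant slots leave their original locus and assemble into their own
#' contaminant loci (keyed by donor locus, so two libraries hit by the same
#' donor locus share it) — this is how non-homologous cross-taxon reads
#' behave, and it is what the minimum-samples filter removes.  In
#' `"co_assemble"` mode the donor sequence replaces the member sequence
#' inside the locus alignment (a mis-assembled stack), which inflates the
#' genetic distance between the library and its pair.
#'
#' @param datasets named list of [loci_dataset()] (one per taxon).
#' @param library_id library to contaminate.
#' @param donor_taxon taxon the contaminant sequences come from (must differ
#'   from the library's taxon).
#' @param fraction expected fraction of assembled loci affected, in [0,1).
#' @param truth the `sim_truth` (labels are appended to
#'   `truth$contamination`).
#' @param config the [sim_config()].
#' @param mode `"separate"` or `"co_assemble"`.
#' @return list with updated `datasets` and `truth`.
#' @export
inject_contamination <- function(datasets, library_id, donor_taxon, fraction,
                                 truth, config,
                                 mode = c("separate", "co_assemble")) {
  mode <- match.arg(mode)
  stopifnot(fraction >= 0, fraction < 1)
  meta_all <- do.call(rbind, lapply(datasets, function(d) d$libraries))
  taxon <- meta_all$taxon[match(library_id, meta_all$library_id)]
  if (is.na(taxon)) .stopf("unknown library '%s'", library_id)
  if (identical(taxon, donor_taxon))
    .stopf("donor taxon must differ from the library's taxon")
  if (fraction == 0) return(list(datasets = datasets, truth = truth))
  set.seed(.sub_seed(config$seed, paste0("contam:", library_id)))
  ds <- datasets[[taxon]]
  member <- vapply(ds$loci, function(l) library_id %in% names(l$seqs), logical(1))
  member_ids <- names(ds$loci)[member]
  k <- rbinom(1L, length(member_ids), fraction)
  if (k == 0L) return(list(datasets = datasets, truth = truth))
  slots <- sample(member_ids, k)
  donor <- truth$taxa[[donor_taxon]]
  donor_inds <- donor$individuals$sample_id
  donor_loci <- sample(names(donor$loci), k, replace = FALSE)
  for (i in seq_len(k)) {
    lid <- slots[i]
    dseq <- true_sequence(truth, donor_taxon, donor_loci[i],
                          sample(donor_inds, 1L))
    len <- nchar(ds$loci[[lid]]$seqs[[1L]])
    dseq <- substr(paste0(dseq, strrep("N", len)), 1L, len)
    if (mode == "co_assemble") {
      ds$loci[[lid]]$seqs[[library_id]] <- dseq
      ds$loci[[lid]]$flags <- compute_snp_flags(ds$loci[[lid]]$seqs)
      label_locus <- lid
    } else {
      # remove from the genuine locus
      keep <- setdiff(names(ds$loci[[lid]]$seqs), library_id)
      if (length(keep) == 0L) {
        ds$loci[[lid]] <- NULL
      } else {
        ds$loci[[lid]]$seqs <- ds$loci[[lid]]$seqs[keep]
        if (!is.null(ds$loci[[lid]]$depth))
          ds$loci[[lid]]$depth <- ds$loci[[lid]]$depth[
            intersect(names(ds$loci[[lid]]$depth), keep)]
        ds$loci[[lid]]$flags <- compute_snp_flags(ds$loci[[lid]]$seqs)
      }
      cid <- paste0("CONTAM_", donor_loci[i])
      if (cid %in% names(ds$loci)) {
        ds$loci[[cid]]$seqs[[library_id]] <- dseq
        ds$loci[[cid]]$flags <- compute_snp_flags(ds$loci[[cid]]$seqs)
      } else {
        ds$loci[[cid]] <- locus(cid, setNames(dseq, library_id))
      }
      label_locus <- cid
    }
    truth$contamination <- rbind(truth$contamination, data.frame(
      library_id = library_id, locus_id = label_locus,
      donor_taxon = donor_taxon, donor_locus = donor_loci[i], mode = mode,
      stringsAsFactors = FALSE))
  }
  datasets[[taxon]] <- ds
  list(datasets = datasets, truth = truth)
}

#' Simulate a complete paired-library study
#'
#' Generates metadata (paired gDNA/MDA libraries for every individual, pool
#' assignment, read budgets, MDA input DNA), true genotypes, per-library
#' depths and called sequences, assembles a [loci_dataset()] per taxon
#' (members are the libraries whose depth passes the assembly threshold),
#' and optionally injects cross-taxon contamination and writes everything to
#' disk in the formats read by the I/O module.
#'
#' @param config a [sim_config()].
#' @param out_dir if not `NULL`, a directory to which per-taxon `.loci`
#'   files, `metadata.csv`, `depths.tsv` and `truth.json` (summary) are
#'   written.
#' @return list with `datasets` (named by taxon), `metadata`, `truth`,
#'   `config`.
#' @export
simulate_paired_study <- function(config, out_dir = NULL) {
  truth <- simulate_genotypes(config)
  metadata <- .sim_metadata(config, truth)
  datasets <- list()
  for (tx in names(truth$taxa)) {
    meta_tx <- metadata[metadata$taxon == tx, , drop = FALSE]
    libs <- vector("list", nrow(meta_tx))
    for (i in seq_len(nrow(meta_tx))) {
      libs[[i]] <- simulate_library(truth, meta_tx[i, ], config)
      truth$weights[[meta_tx$library_id[i]]] <- libs[[i]]$weights
    }
    names(libs) <- meta_tx$library_id
    loci <- list()
    for (lid in names(truth$taxa[[tx]]$loci)) {
      seqs <- character(0)
      depth <- integer(0)
      for (lb in libs) {
        if (lid %in% names(lb$seqs)) {
          seqs[[lb$library_id]] <- lb$seqs[[lid]]
          depth[[lb$library_id]] <- lb$depths[[lid]]
        }
      }
      if (length(seqs) > 0L)
        loci[[lid]] <- locus(lid, seqs, depth = depth)
    }
    datasets[[tx]] <- loci_dataset(tx, loci, meta_tx)
  }
  if (config$contamination_fraction > 0 && length(datasets) >= 2L) {
    taxa_names <- names(datasets)
    set.seed(.sub_seed(config$seed, "contam-donors"))
    mda_libs <- metadata$library_id[metadata$method == "MDA"]
    donors <- vapply(metadata$taxon[match(mda_libs, metadata$library_id)],
                     function(tx) sample(setdiff(taxa_names, tx), 1L),
                     character(1))
    for (i in seq_along(mda_libs)) {
      res <- inject_contamination(datasets, mda_libs[i], donors[i],
                                  config$contamination_fraction, truth,
                                  config, mode = config$contamination_mode)
      datasets <- res$datasets
      truth <- res$truth
    }
  }
  out <- list(datasets = datasets, metadata = metadata, truth = truth,
              config = config)
  if (!is.null(out_dir)) .write_study(out, out_dir)
  out
}

.sim_metadata <- function(config, truth) {
  set.seed(.sub_seed(config$seed, "metadata"))
  rows <- list()
  for (tx in config$taxa) {
    inds <- truth$taxa[[tx$name]]$individuals
    for (i in seq_len(nrow(inds))) {
      for (method in c("gDNA", "MDA")) {
        input <- if (method == "MDA") {
          exp(runif(1, log(config$input_dna_range[1]),
                    log(config$input_dna_range[2])))
        } else NA_real_
        rows[[length(rows) + 1L]] <- data.frame(
          library_id = paste0(inds$sample_id[i], "_", method),
          sample_id = inds$sample_id[i], taxon = tx$name,
          population = inds$population[i],
          pool = sprintf("pool%d", sample.int(config$n_pools, 1L)),
          method = method, input_dna_ng = input,
          n_reads = max(50L, as.integer(round(rlnorm(1,
            log(config$reads_per_library), config$reads_sd_log)))),
          latitude = NA_real_, longitude = NA_real_,
          stringsAsFactors = FALSE)
      }
    }
  }
  validate_meta(do.call(rbind, rows))
}

.write_study <- function(study, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_meta(study$metadata, file.path(out_dir, "metadata.csv"))
  depth_rows <- list()
  for (tx in names(study$datasets)) {
    ds <- study$datasets[[tx]]
    write_loci(ds, file.path(out_dir, paste0(tx, ".loci")))
    for (loc in ds$loci) {
      if (!is.null(loc$depth) && length(loc$depth) > 0L)
        depth_rows[[length(depth_rows) + 1L]] <- data.frame(
          library_id = names(loc$depth), locus_id = loc$locus_id,
          depth = as.integer(loc$depth), stringsAsFactors = FALSE)
    }
  }
  if (length(depth_rows) > 0L)
    write_depths(do.call(rbind, depth_rows), file.path(out_dir, "depths.tsv"))
  summary <- list(
    seed = study$config$seed,
    taxa = lapply(study$config$taxa, function(t)
      t[c("name", "n_populations", "n_individuals_per_pop", "fst")]),
    n_loci = study$config$n_loci,
    contamination = study$truth$contamination
  )
  jsonlite::write_json(summary, file.path(out_dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' True observed heterozygosity implied by the simulated genotypes
#'
#' Proportion of heterozygous genotype calls among an individual's
#' polymorphic-site genotypes across all loci of its taxon, computed from
#' truth (no sequencing); used as the oracle for caller-bias tests.
#'
#' @param truth a `sim_truth`.
#' @param taxon,sample_id identifiers.
#' @param per_site if `TRUE` (default) the denominator is all sites
#'   (monomorphic included), matching the pooled-site definition of observed
#'   heterozygosity.
#' @param locus_length locus length used when `per_site` is `TRUE`.
#' @return proportion in [0,1].
#' @export
true_heterozygosity <- function(truth, taxon, sample_id, per_site = TRUE,
                                locus_length = NULL) {
  tx <- truth$taxa[[taxon]]
  n_het <- 0L
  n_var <- 0L
  for (loc in tx$loci) {
    if (nrow(loc$sites) == 0L) next
    d <- loc$geno[sample_id, ]
    n_het <- n_het + sum(d == 1L)
    n_var <- n_var + length(d)
  }
  if (per_site) {
    if (is.null(locus_length))
      locus_length <- nchar(tx$loci[[1L]]$anc_seq)
    n_total <- length(tx$loci) * locus_length
    n_het / n_total
  } else {
    if (n_var == 0L) return(NaN)
    n_het / n_var
  }
}
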