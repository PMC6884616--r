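#' Configuration for the synthetic study generator
#'
#' Defines the simulated study design: a focal lineage of two
#' white-blooded-like species, a comparator group of two red-blooded-like
#' species, and three temperate outgroup species. Expression sampling
#' mirrors the 5/4/5-per-species replicate regime (five focal replicates,
#' four comparator samples pooled across its two species, five replicates
#' per outgroup species). Copy-number signal is planted as focal-lineage
#' duplications with an OG-level dosage effect; expression signal as
#' planted log2 fold changes in non-duplicated OGs.
#'
#' @param n_ogs Number of ortholog groups (default 2000).
#' @param focal_species,comparator_species,outgroup_species Species names.
#' @param focal_reps Expression replicates for the first focal species
#'   (default 5).
#' @param comparator_reps Total comparator samples, split across the
#'   comparator species (default 4).
#' @param outgroup_reps Replicates per outgroup species (default 5).
#' @param dup_fraction Fraction of OGs with planted focal duplication
#'   (default 0.15).
#' @param bg_multi_fraction Fraction of non-duplicated OGs with a shared
#'   (all-species) copy number above one, so the background class is not
#'   exclusively one-to-one (default 0.2).
#' @param dosage_logfc Expression boost per extra copy, log2 units
#'   (default 1).
#' @param de_fraction Fraction of non-duplicated OGs with planted
#'   differential expression (default 0.1).
#' @param de_logfc_range Range of planted absolute log2 fold changes
#'   (default `c(1, 3)`).
#' @param dispersion Negative-binomial dispersion (default 0.1).
#' @param baseline_meanlog,baseline_sdlog Lognormal parameters of OG
#'   baseline abundance on the count scale (defaults 4 and 1.5).
#' @param library_size_range Per-sample library totals (default
#'   `c(8e5, 1.2e6)`).
#' @param n_tissues Tissues in the expression-breadth panel (default 5).
#' @param tissue_replicates Replicates per tissue (default 2).
#' @param tissue_specific_fraction Fraction of focal genes planted as
#'   tissue specific (default 0.2).
#' @param tissue_dup_or Odds ratio biasing tissue-specific planting
#'   toward duplicated-OG genes (default 6).
#' @param tissue_logfc Log2 boost of a tissue-specific gene in its target
#'   tissue (default 4).
#' @param promoter_length Promoter length in bases (default 5000).
#' @param planted_base_sites Motif occurrences planted in every promoter
#'   (default 1).
#' @param planted_extra_sites Additional occurrences planted in focal
#'   promoters of upregulated genes (default 2).
#' @param mito_set_size,mito_set_or Target size and duplication odds
#'   ratio of the planted mitochondrial-like gene set (defaults 300, 3).
#' @param control_set_size Size of the random control set (default 300).
#' @param seed Master seed; every generated artifact derives its own
#'   stream from it.
#' @return A validated `sim_config` object.
#' @export
sim_config <- function(n_ogs = 2000,
                       focal_species = c("ice_a", "ice_b"),
                       comparator_species = c("red_a", "red_b"),
                       outgroup_species = c("out_a", "out_b", "out_c"),
                       focal_reps = 5,
                       comparator_reps = 4,
                       outgroup_reps = 5,
                       dup_fraction = 0.15,
                       bg_multi_fraction = 0.2,
                       dosage_logfc = 1,
                       de_fraction = 0.1,
                       de_logfc_range = c(1, 3),
                       dispersion = 0.1,
                       baseline_meanlog = 4,
                       baseline_sdlog = 1.5,
                       library_size_range = c(8e5, 1.2e6),
                       n_tissues = 5,
                       tissue_replicates = 2,
                       tissue_specific_fraction = 0.2,
                       tissue_dup_or = 6,
                       tissue_logfc = 4,
                       promoter_length = 5000,
                       planted_base_sites = 1,
                       planted_extra_sites = 2,
                       mito_set_size = 300,
                       mito_set_or = 3,
                       control_set_size = 300,
                       seed = 1) {
  cfg <- as.list(environment())
  chk_frac <- function(field) {
    v <- cfg[[field]]
    if (!is.numeric(v) || length(v) != 1 || v < 0 || v > 1) {
      stop("invalid configuration: '", field, "' must lie in [0, 1]")
    }
  }
  for (f in c("dup_fraction", "bg_multi_fraction", "de_fraction",
              "tissue_specific_fraction")) chk_frac(f)
  chk_pos <- function(field, min = 0) {
    v <- cfg[[field]]
    if (!is.numeric(v) || length(v) != 1 || v < min) {
      stop("invalid configuration: '", field, "' must be >= ", min)
    }
  }
  chk_pos("n_ogs", 1); chk_pos("dispersion", 0)
  chk_pos("focal_reps", 2); chk_pos("comparator_reps", 2)
  chk_pos("outgroup_reps", 2); chk_pos("tissue_replicates", 2)
  chk_pos("promoter_length", 1)
  chk_pos("planted_base_sites", 0); chk_pos("planted_extra_sites", 0)
  if (cfg$n_tissues < 2) {
    stop("invalid configuration: 'n_tissues' must be at least 2 (tau undefined otherwise)")
  }
  if (length(cfg$de_logfc_range) != 2 || diff(cfg$de_logfc_range) < 0) {
    stop("invalid configuration: 'de_logfc_range' must be an increasing interval")
  }
  if (length(cfg$library_size_range) != 2 || any(cfg$library_size_range <= 0)) {
    stop("invalid configuration: 'library_size_range' must be positive")
  }
  sp <- c(cfg$focal_species, cfg$comparator_species, cfg$outgroup_species)
  if (anyDuplicated(sp)) stop("invalid configuration: species names must be unique")
  structure(cfg, class = "sim_config")
}

# One reproducible sub-stream per generated artifact so adding an
# artifact never perturbs the others.
sim_seed <- function(config, artifact) {
  offset <- match(artifact, c("orthology", "counts", "tissue",
                              "promoters", "gene_sets"))
  as.integer((as.numeric(config$seed) * 7919 + offset * 104729) %% 2147483629)
}

#' Generate an orthology table with planted focal duplications
#'
#' All species carry one copy per OG except: a `dup_fraction` of OGs gets
#' 1-3 extra copies in every focal species (the planted duplications),
#' and a `bg_multi_fraction` of the remaining OGs gets a shared copy
#' number above one in all species (ancestral duplicates, mean copy
#' difference zero).
#'
#' @param config A `sim_config`.
#' @return List with `orthology` (an `orthology_table`) and `truth` (the
#'   ground-truth manifest, extended by the later generators).
#' @export
generate_orthology <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(sim_seed(config, "orthology"))
  n <- config$n_ogs
  og_ids <- sprintf("OG%05d", seq_len(n))
  species <- c(config$focal_species, config$comparator_species,
               config$outgroup_species)

  n_dup <- round(config$dup_fraction * n)
  dup_idx <- sort(sample.int(n, n_dup))
  extra <- integer(n)
  extra[dup_idx] <- sample(1:3, n_dup, replace = TRUE, prob = c(0.6, 0.3, 0.1))

  non_dup <- setdiff(seq_len(n), dup_idx)
  n_multi <- round(config$bg_multi_fraction * length(non_dup))
  multi_idx <- sort(sample(non_dup, n_multi))
  base_copies <- rep(1L, n)
  base_copies[multi_idx] <- sample(2:3, n_multi, replace = TRUE, prob = c(0.7, 0.3))

  copies <- matrix(base_copies, n, length(species),
                   dimnames = list(og_ids, species))
  copies[, config$focal_species] <- copies[, config$focal_species] + extra

  genes <- lapply(species, function(sp) {
    lapply(seq_len(n), function(i) {
      paste0(sp, "_", og_ids[i], "_g", seq_len(copies[i, sp]))
    })
  })
  names(genes) <- species
  truth <- list(
    og_ids = og_ids,
    copies = copies,
    duplicated = stats::setNames(extra > 0, og_ids),
    extra_copies = stats::setNames(extra, og_ids),
    config = config
  )
  list(orthology = orthology_table(og_ids, genes), truth = truth)
}

sim_sample_meta <- function(config) {
  rows <- list()
  add <- function(sp, group, n_reps) {
    data.frame(sample = paste0(sp, "_r", seq_len(n_reps)),
               species = sp, group = group, replicate = seq_len(n_reps),
               stringsAsFactors = FALSE)
  }
  rows[[1]] <- add(config$focal_species[1], "focal", config$focal_reps)
  n_cmp_sp <- length(config$comparator_species)
  per <- diff(c(0, round(seq_len(n_cmp_sp) * config$comparator_reps / n_cmp_sp)))
  for (i in seq_along(config$comparator_species)) {
    rows[[length(rows) + 1]] <-
      add(config$comparator_species[i], "comparator", per[i])
  }
  for (sp in config$outgroup_species) {
    rows[[length(rows) + 1]] <- add(sp, "outgroup", config$outgroup_reps)
  }
  do.call(rbind, rows)
}

#' Generate per-species RNA-seq count matrices with planted effects
#'
#' Counts are negative-binomial around per-gene means: an OG-level
#' lognormal baseline, scaled by the sample's library factor and by
#' `2^effect` in focal-group samples. The planted effect is
#' `dosage_logfc * extra copies` for duplicated OGs (total OG expression
#' scales with copy number, divided evenly over the copies) and a random
#' signed log2 fold change in `de_logfc_range` for a `de_fraction` of
#' non-duplicated OGs.
#'
#' @param orthology,truth Output of [generate_orthology()].
#' @param config The same `sim_config`.
#' @return List with `counts` (named list of gene x sample matrices, one
#'   per species), `metadata` (sample data frame), and the extended
#'   `truth` (adds `baseline`, `planted_log2fc`, `de`).
#' @export
generate_counts <- function(orthology, truth, config) {
  if (!setequal(og_species(orthology),
                c(config$focal_species, config$comparator_species,
                  config$outgroup_species))) {
    stop("species in config absent from orthology table")
  }
  set.seed(sim_seed(config, "counts"))
  n <- length(truth$og_ids)
  baseline <- stats::rlnorm(n, config$baseline_meanlog, config$baseline_sdlog)
  names(baseline) <- truth$og_ids

  non_dup <- truth$og_ids[!truth$duplicated]
  n_de <- round(config$de_fraction * length(non_dup))
  de_ogs <- sort(sample(non_dup, n_de))
  de_sign <- sample(c(-1, 1), n_de, replace = TRUE)
  de_mag <- stats::runif(n_de, config$de_logfc_range[1], config$de_logfc_range[2])
  planted <- stats::setNames(numeric(n), truth$og_ids)
  planted[truth$duplicated] <-
    config$dosage_logfc * truth$extra_copies[truth$duplicated]
  planted[de_ogs] <- de_sign * de_mag

  meta <- sim_sample_meta(config)
  counts <- lapply(og_species(orthology), function(sp) {
    idx <- which(meta$species == sp)
    if (length(idx) == 0) return(NULL)
    focal <- sp %in% config$focal_species
    cps <- truth$copies[, sp]
    og_mean <- baseline * if (focal) 2^planted else 1
    gene_mean <- rep(og_mean / cps, cps)
    gene_ids <- unlist(orthology$genes[[sp]], use.names = FALSE)
    libs <- stats::runif(length(idx), config$library_size_range[1],
                         config$library_size_range[2])
    mu <- outer(gene_mean, libs / 1e6)
    m <- if (config$dispersion > 0) {
      matrix(stats::rnbinom(length(mu), mu = mu, size = 1 / config$dispersion),
             nrow(mu), ncol(mu))
    } else {
      matrix(stats::rpois(length(mu), mu), nrow(mu), ncol(mu))
    }
    dimnames(m) <- list(gene_ids, meta$sample[idx])
    m
  })
  names(counts) <- og_species(orthology)
  counts <- Filter(Negate(is.null), counts)

  truth$baseline <- baseline
  truth$planted_log2fc <- planted
  truth$de <- stats::setNames(truth$og_ids %in% de_ogs, truth$og_ids)
  list(counts = counts, metadata = meta, truth = truth)
}

#' Generate a multi-tissue expression panel for the focal species
#'
#' Genes of the first focal species are sampled over `n_tissues` tissues
#' with `tissue_replicates` replicates each. A planted fraction of genes
#' is tissue specific: their mean is multiplied by `2^tissue_logfc` in
#' exactly one tissue. Planting is biased toward genes of duplicated OGs
#' at odds ratio `tissue_dup_or`, so expression breadth divergence tracks
#' copy-number divergence as the downstream comparison assumes.
#'
#' @param orthology,truth Output of [generate_counts()] (needs
#'   `truth$baseline`).
#' @param config The same `sim_config`.
#' @return List with `counts` (gene x sample matrix), `tissues` (sample
#'   tissue labels), and extended `truth` (adds `tissue_specific`,
#'   `target_tissue` per gene).
#' @export
generate_tissue_panel <- function(orthology, truth, config) {
  if (config$n_tissues < 2) stop("'n_tissues' must be at least 2")
  if (is.null(truth$baseline)) stop("run generate_counts() first")
  set.seed(sim_seed(config, "tissue"))
  sp <- config$focal_species[1]
  cps <- truth$copies[, sp]
  gene_ids <- unlist(orthology$genes[[sp]], use.names = FALSE)
  gene_og <- rep(truth$og_ids, cps)
  gene_mean <- rep(truth$baseline / cps, cps)

  in_dup <- truth$duplicated[gene_og]
  p_bg <- solve_biased_rate(config$tissue_specific_fraction,
                            config$tissue_dup_or, mean(in_dup))
  p_dup <- biased_prob(p_bg, config$tissue_dup_or)
  specific <- stats::runif(length(gene_ids)) < ifelse(in_dup, p_dup, p_bg)
  target <- sample.int(config$n_tissues, length(gene_ids), replace = TRUE)
  target[!specific] <- NA_integer_

  tissues <- rep(paste0("tissue", seq_len(config$n_tissues)),
                 each = config$tissue_replicates)
  samples <- paste0(tissues, "_r", rep(seq_len(config$tissue_replicates),
                                       config$n_tissues))
  libs <- stats::runif(length(samples), config$library_size_range[1],
                       config$library_size_range[2])
  tissue_idx <- rep(seq_len(config$n_tissues), each = config$tissue_replicates)
  boost <- matrix(1, length(gene_ids), length(samples))
  has_target <- which(specific)
  for (g in has_target) boost[g, tissue_idx == target[g]] <- 2^config$tissue_logfc
  mu <- (gene_mean * boost) %*% diag(libs / 1e6)
  m <- if (config$dispersion > 0) {
    matrix(stats::rnbinom(length(mu), mu = mu, size = 1 / config$dispersion),
           nrow(mu), ncol(mu))
  } else {
    matrix(stats::rpois(length(mu), mu), nrow(mu), ncol(mu))
  }
  dimnames(m) <- list(gene_ids, samples)

  truth$tissue_specific <- stats::setNames(specific, gene_ids)
  truth$target_tissue <- stats::setNames(target, gene_ids)
  list(counts = m, tissues = tissues, truth = truth)
}

# Background planting rate p_bg such that exposed units (probability
# biased_prob(p_bg, or)) and background units average to `overall`.
solve_biased_rate <- function(overall, or, exposed_fraction) {
  if (overall <= 0) return(0)
  if (overall >= 1) return(1)
  if (exposed_fraction <= 0 || or == 1) return(overall)
  f <- function(p) {
    exposed_fraction * biased_prob(p, or) + (1 - exposed_fraction) * p - overall
  }
  stats::uniroot(f, c(1e-12, 1 - 1e-12), tol = 1e-12)$root
}

biased_prob <- function(p, or) or * p / (1 - p + or * p)

#' Generate promoter sequences with planted motif occurrences
#'
#' For every strict 1-to-1 OG, a promoter of `promoter_length` i.i.d.
#' uniform bases is generated per species (focal, comparator, and
#' outgroup representatives). `planted_base_sites` motif occurrences are
#' inserted into every promoter at non-overlapping positions, sampled
#' column-wise from the PFM; focal promoters of upregulated OGs (planted
#' log2 effect >= 1) receive `planted_extra_sites` additional
#' occurrences.
#'
#' @param orthology,truth Output of [generate_counts()].
#' @param pfm A `pfm` object (defaults to the bundled synthetic
#'   GABPA-like motif).
#' @param config The same `sim_config`.
#' @param species Species to emit promoters for; defaults to the focal
#'   representative, the first comparator, and all outgroup species.
#' @return List with `promoters` (named list species -> named character
#'   vector keyed by OG), and extended `truth` (adds `planted_sites`
#'   matrix OG x species and `site_positions`).
#' @export
generate_promoters <- function(orthology, truth, pfm = default_pfm(),
                               config = truth$config, species = NULL) {
  w <- ncol(pfm$counts)
  if (config$promoter_length < w) {
    stop("invalid configuration: 'promoter_length' must be at least the motif width")
  }
  if (is.null(truth$planted_log2fc)) stop("run generate_counts() first")
  if (is.null(species)) {
    species <- c(config$focal_species[1], config$comparator_species[1],
                 config$outgroup_species)
  }
  set.seed(sim_seed(config, "promoters"))
  copies <- truth$copies
  one_to_one <- rownames(copies)[rowSums(copies == 1) == ncol(copies)]
  up <- truth$planted_log2fc[one_to_one] >= 1
  col_probs <- sweep(pfm$counts, 2, colSums(pfm$counts), "/")
  cum_probs <- apply(col_probs, 2, cumsum)
  l <- config$promoter_length

  planted_counts <- matrix(0L, length(one_to_one), length(species),
                           dimnames = list(one_to_one, species))
  positions <- list()
  base_chr <- c(65L, 67L, 71L, 84L)
  promoters <- lapply(species, function(sp) {
    focal <- sp == config$focal_species[1]
    n_sites <- config$planted_base_sites +
      ifelse(focal & up, config$planted_extra_sites, 0L)
    ng <- length(one_to_one)
    idx_all <- sample.int(4, ng * l, replace = TRUE)
    seqs <- character(ng)
    for (i in seq_len(ng)) {
      idx <- idx_all[((i - 1) * l + 1):(i * l)]
      k <- n_sites[i]
      if (k > 0) {
        pos <- plant_positions(l, w, k)
        for (p in pos) {
          # column-wise draw from the PFM via inverse-CDF lookups
          u <- stats::runif(w)
          site <- 1L + colSums(cum_probs[-4, , drop = FALSE] < rep(u, each = 3))
          idx[p:(p + w - 1)] <- site
        }
        positions[[paste(sp, one_to_one[i], sep = "|")]] <<- pos
      }
      seqs[i] <- intToUtf8(base_chr[idx])
    }
    planted_counts[, sp] <<- as.integer(n_sites)
    stats::setNames(seqs, one_to_one)
  })
  names(promoters) <- species
  truth$planted_sites <- planted_counts
  truth$site_positions <- positions
  list(promoters = promoters, truth = truth)
}

# Non-overlapping insertion starts; bounded rejection sampling.
plant_positions <- function(l, w, k, max_tries = 200) {
  for (try in seq_len(max_tries)) {
    pos <- sort(sample.int(l - w + 1, k))
    if (k == 1 || all(diff(pos) >= w)) return(pos)
  }
  stop("could not place ", k, " non-overlapping motif occurrences")
}

#' Generate gene sets with a duplication-enriched mitochondrial-like set
#'
#' Builds one "mito-like" set in which planted duplicated OGs are
#' over-represented at the configured odds ratio, and one random control
#' set of the same nominal size.
#'
#' @param orthology,truth Output of [generate_orthology()] (or later).
#' @param config The same `sim_config`.
#' @return List with `sets` (named list of OG id vectors) and extended
#'   `truth` (adds `mito_like` membership and `set_enriched` flags).
#' @export
generate_gene_sets <- function(orthology, truth, config = truth$config) {
  if (config$mito_set_size > config$n_ogs ||
      config$control_set_size > config$n_ogs) {
    stop("invalid configuration: requested set size exceeds 'n_ogs'")
  }
  set.seed(sim_seed(config, "gene_sets"))
  dup <- truth$duplicated
  n <- length(dup)
  p_bg <- solve_biased_rate(config$mito_set_size / n, config$mito_set_or,
                            mean(dup))
  p_dup <- biased_prob(p_bg, config$mito_set_or)
  in_mito <- stats::runif(n) < ifelse(dup, p_dup, p_bg)
  mito <- truth$og_ids[in_mito]
  control <- sort(sample(truth$og_ids, config$control_set_size))
  sets <- list(mito_like = mito, control = control)
  truth$mito_like <- stats::setNames(in_mito, truth$og_ids)
  truth$set_enriched <- c(mito_like = config$mito_set_or != 1, control = FALSE)
  list(sets = sets, truth = truth)
}

#' Run every generator and return the full synthetic study
#'
#' @param config A `sim_config`.
#' @param pfm Motif used for promoter planting (default bundled motif).
#' @param with_promoters Generate promoter sequences too (default TRUE;
#'   the slowest artifact).
#' @return List with `orthology`, `counts`, `metadata`, `panel`,
#'   `sets`, `promoters`, `pfm`, and the complete `truth` manifest.
#' @export
simulate_study <- function(config = sim_config(), pfm = default_pfm(),
                           with_promoters = TRUE) {
  orth <- generate_orthology(config)
  cnt <- generate_counts(orth$orthology, orth$truth, config)
  panel <- generate_tissue_panel(orth$orthology, cnt$truth, config)
  sets <- generate_gene_sets(orth$orthology, panel$truth, config)
  truth <- sets$truth
  promoters <- NULL
  if (with_promoters) {
    prom <- generate_promoters(orth$orthology, truth, pfm, config)
    promoters <- prom$promoters
    truth <- prom$truth
  }
  list(orthology = orth$orthology, counts = cnt$counts,
       metadata = cnt$metadata,
       panel = panel[c("counts", "tissues")],
       sets = sets$sets, promoters = promoters, pfm = pfm, truth = truth)
}

#' The bundled synthetic GABPA-like motif
#'
#' An 11-column information-rich PFM (consensus `ACCGGAAGTGG`) shipped
#' with the package as a stand-in for an ETS-family binding profile. It
#' is synthetic: column counts were constructed, not measured.
#'
#' @return A `pfm` object.
#' @export
default_pfm <- function() {
  read_jaspar(system.file("extdata", "synthetic_gabpa_like.jaspar",
                          package = "orthodelta", mustWork = TRUE))
}

#' Write a synthetic study to disk
#'
#' Emits the orthology TSV, per-species count TSVs, sample metadata,
#' tissue panel, gene sets (GMT), promoter FASTAs, and the ground-truth
#' manifest (JSON).
#'
#' @param study Output of [simulate_study()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the directory.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_orthology(study$orthology, file.path(dir, "orthology.tsv"))
  utils::write.table(study$metadata, file.path(dir, "metadata.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  for (sp in names(study$counts)) {
    utils::write.table(data.frame(gene = rownames(study$counts[[sp]]),
                                  study$counts[[sp]], check.names = FALSE),
                       file.path(dir, paste0("counts_", sp, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  utils::write.table(data.frame(gene = rownames(study$panel$counts),
                                study$panel$counts, check.names = FALSE),
                     file.path(dir, "tissue_panel.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_gmt(study$sets, file.path(dir, "gene_sets.gmt"))
  if (!is.null(study$promoters)) {
    map <- gene_og_map(study$orthology)
    for (sp in names(study$promoters)) {
      seqs <- study$promoters[[sp]]
      genes <- vapply(names(seqs), function(og) {
        study$orthology$genes[[sp]][[match(og, study$orthology$og_ids)]][1]
      }, "")
      dna <- Biostrings::DNAStringSet(seqs)
      names(dna) <- paste(sp, genes, names(seqs), sep = "|")
      Biostrings::writeXStringSet(dna, file.path(dir, paste0("promoters_", sp, ".fa")))
    }
  }
  manifest <- list(
    copies = as.data.frame(study$truth$copies),
    duplicated = study$truth$duplicated,
    extra_copies = study$truth$extra_copies,
    planted_log2fc = study$truth$planted_log2fc,
    de = study$truth$de,
    tissue_specific = study$truth$tissue_specific,
    target_tissue = study$truth$target_tissue,
    mito_like = study$truth$mito_like,
    planted_sites = if (!is.null(study$truth$planted_sites))
      as.data.frame(study$truth$planted_sites) else NULL
  )
  jsonlite::write_json(manifest, file.path(dir, "truth_manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
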