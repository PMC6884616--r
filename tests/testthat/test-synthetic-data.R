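test_that("configuration validation names the offending field", {
  expect_error(sim_config(dup_fraction = 1.5), "dup_fraction")
  expect_error(sim_config(n_tissues = 1), "n_tissues")
  expect_error(sim_config(focal_reps = 1), "focal_reps")
  expect_error(sim_config(de_logfc_range = c(3, 1)), "de_logfc_range")
  expect_error(sim_config(library_size_range = c(-1, 2)), "library_size_range")
})

test_that("orthology generation plants the configured number of duplications", {
  cfg <- sim_config(n_ogs = 2000, dup_fraction = 0.15, seed = 5)
  sim <- generate_orthology(cfg)
  expect_equal(sum(sim$truth$duplicated), round(0.15 * 2000))
  copies <- copy_number_matrix(sim$orthology)
  expect_identical(unname(copies), unname(sim$truth$copies))

  none <- generate_orthology(sim_config(n_ogs = 500, dup_fraction = 0,
                                        bg_multi_fraction = 0, seed = 5))
  m <- copy_number_matrix(none$orthology)
  expect_true(all(m == 1))
})

test_that("generators are deterministic given the seed", {
  cfg <- quick_config()
  a <- simulate_study(cfg)
  b <- simulate_study(cfg)
  expect_identical(a$orthology, b$orthology)
  expect_identical(a$counts, b$counts)
  expect_identical(a$panel, b$panel)
  expect_identical(a$promoters, b$promoters)
  expect_identical(a$sets, b$sets)
  c_ <- simulate_study(sim_config(n_ogs = 300, seed = 43))
  expect_false(identical(a$counts, c_$counts))
})

test_that("count model matches its negative-binomial specification", {
  # moment recovery of the dispersion from constant-mean outgroup genes
  cfg <- sim_config(n_ogs = 1500, dispersion = 0.2, seed = 11,
                    library_size_range = c(1e6, 1e6),
                    dup_fraction = 0, de_fraction = 0)
  sim <- generate_orthology(cfg)
  cnt <- generate_counts(sim$orthology, sim$truth, cfg)
  y <- cnt$counts$out_a
  mu <- rowMeans(y); v <- apply(y, 1, var)
  band <- mu > 20 & mu < 2000
  disp_hat <- sum(v[band] - mu[band]) / sum(mu[band]^2)
  expect_gt(disp_hat, 0.2 * 0.8)
  expect_lt(disp_hat, 0.2 * 1.2)

  # Poisson limit: per-gene means sit within 3 SE of the planted baseline
  cfg0 <- sim_config(n_ogs = 1000, dispersion = 0, seed = 12,
                     library_size_range = c(1e6, 1e6),
                     dup_fraction = 0, bg_multi_fraction = 0, de_fraction = 0)
  sim0 <- generate_orthology(cfg0)
  cnt0 <- generate_counts(sim0$orthology, sim0$truth, cfg0)
  y0 <- cnt0$counts$out_a
  base <- cnt0$truth$baseline[as.character(gene_og_map(sim0$orthology, "out_a")[rownames(y0)])]
  se <- sqrt(base / ncol(y0))
  z <- (rowMeans(y0) - base) / pmax(se, 1e-9)
  expect_gt(mean(abs(z) <= 3), 0.99)
})

test_that("planted expression effects appear at the configured magnitude", {
  cfg <- sim_config(n_ogs = 1000, seed = 21, de_logfc_range = c(2, 2),
                    library_size_range = c(1e6, 1e6))
  sim <- generate_orthology(cfg)
  cnt <- generate_counts(sim$orthology, sim$truth, cfg)
  truth <- cnt$truth
  up <- names(truth$planted_log2fc)[truth$de & truth$planted_log2fc > 0]

  og_counts <- function(sp) {
    y <- cnt$counts[[sp]]
    rowsum(y, as.character(gene_og_map(sim$orthology, sp)[rownames(y)]))
  }
  focal <- rowMeans(og_counts(cfg$focal_species[1]))
  out <- rowMeans(cbind(og_counts("out_a"), og_counts("out_b"),
                        og_counts("out_c")))
  ratio <- log2(focal[up] / out[up])
  expect_lt(abs(median(ratio) - 2), 0.3)
})

test_that("tissue panel plants single-tissue expression as specified", {
  # on the log2-cpm scale a planted boost of D gives tau ~= D / (x0 + D)
  # where x0 is the gene's baseline log2 cpm (median ~6 here), so D = 10
  # puts planted genes near 0.6-0.7 and far above the unplanted background
  cfg <- quick_config(tissue_logfc = 10)
  st <- simulate_study(cfg, with_promoters = FALSE)
  tt <- tau_table(st$panel$counts, st$panel$tissues)
  spec_genes <- names(st$truth$tissue_specific)[st$truth$tissue_specific]
  hi <- tt$tau[tt$gene %in% spec_genes]
  lo <- tt$tau[!tt$gene %in% spec_genes]
  expect_gt(median(hi, na.rm = TRUE), 0.55)
  expect_gt(median(hi, na.rm = TRUE), median(lo, na.rm = TRUE) + 0.3)

  flat_cfg <- sim_config(n_ogs = 400, seed = 8, tissue_specific_fraction = 0)
  flat <- simulate_study(flat_cfg, with_promoters = FALSE)
  tf <- tau_table(flat$panel$counts, flat$panel$tissues)
  expect_lt(median(tf$tau, na.rm = TRUE), 0.3)
})

test_that("promoter planting matches the manifest exactly", {
  cfg <- quick_config()
  st <- simulate_study(cfg)
  planted <- st$truth$planted_sites
  # recorded insertion positions agree with the planted counts
  for (sp in colnames(planted)) {
    keys <- paste(sp, rownames(planted), sep = "|")
    n_rec <- vapply(keys, function(k) {
      p <- st$truth$site_positions[[k]]
      if (is.null(p)) 0L else length(p)
    }, integer(1))
    expect_equal(unname(n_rec), unname(planted[, sp]))
  }
  # no extra sites planted => identical counts in focal and comparison
  cfg0 <- quick_config(planted_extra_sites = 0)
  st0 <- simulate_study(cfg0)
  p0 <- st0$truth$planted_sites
  expect_true(all(p0[, 1] == p0[, 2]))
})

test_that("planted motif occurrences are found by the scanner", {
  cfg <- quick_config()
  st <- simulate_study(cfg)
  pwm <- pfm_to_pwm(st$pfm)
  dist <- score_distribution(pwm)
  sp <- cfg$focal_species[1]
  planted <- st$truth$planted_sites[, sp]
  some <- names(planted)[planted > 0][1:20]
  for (og in some) {
    hits <- scan_promoter(pwm, dist, st$promoters[[sp]][[og]],
                          p_threshold = 1e-3)
    expect_gte(nrow(hits), planted[og])
  }
})

test_that("gene-set generation hits the requested duplication odds ratio", {
  cfg <- quick_config()
  sim <- generate_orthology(cfg)
  gs <- generate_gene_sets(sim$orthology, sim$truth, cfg)
  expect_false(gs$truth$set_enriched["control"])
  expect_true(gs$truth$set_enriched["mito_like"])
  expect_error(generate_gene_sets(sim$orthology, sim$truth,
                                  sim_config(n_ogs = 300, seed = 42,
                                             mito_set_size = 1000)),
               "exceeds 'n_ogs'")
  # odds ratio 1: inside and outside duplication fractions agree on average
  frac <- replicate(30, {
    cfg1 <- sim_config(n_ogs = 300, mito_set_or = 1,
                       seed = sample.int(1e6, 1))
    s <- generate_orthology(cfg1)
    g <- generate_gene_sets(s$orthology, s$truth, cfg1)
    dup <- s$truth$duplicated
    inside <- mean(dup[g$sets$mito_like])
    inside - mean(dup)
  })
  expect_lt(abs(mean(frac)), 0.05)
})

test_that("study bundles serialize to the documented plain-text formats", {
  cfg <- sim_config(n_ogs = 60, mito_set_size = 20, control_set_size = 20,
                    seed = 2)
  st <- simulate_study(cfg)
  dir <- withr::local_tempdir()
  write_study(st, dir)
  expect_true(file.exists(file.path(dir, "orthology.tsv")))
  back <- read_orthology(file.path(dir, "orthology.tsv"))
  expect_equal(copy_number_matrix(back), copy_number_matrix(st$orthology))
  sets <- read_gmt(file.path(dir, "gene_sets.gmt"))
  expect_setequal(sets$mito_like, st$sets$mito_like)
  fa <- Biostrings::readDNAStringSet(file.path(dir, "promoters_ice_a.fa"))
  expect_equal(length(fa), length(st$promoters$ice_a))
  manifest <- jsonlite::read_json(file.path(dir, "truth_manifest.json"))
  expect_equal(length(manifest$duplicated), cfg$n_ogs)
})
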