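test_that("cpm normalization identities hold", {
  m <- matrix(c(5, 0, 999995,
                10, 0, 90), nrow = 3, byrow = TRUE,
              dimnames = list(c("g1", "g2", "g3"), c("s1", "s2")))
  m[, 1] <- c(5, 0, 999995)
  m[, 2] <- c(10, 0, 90)
  cpm <- compute_cpm(m)
  expect_equal(cpm["g1", "s1"], 5)        # count 5 in a library of 1e6
  expect_equal(cpm["g2", ], c(s1 = 0, s2 = 0))
  expect_equal(unname(colSums(cpm)), c(1e6, 1e6), tolerance = 1e-9)
  bad <- cbind(m, s3 = c(0, 0, 0))
  expect_error(compute_cpm(bad), "s3")
})

test_that("OG aggregation sums member cpm and conserves mass", {
  cpm <- matrix(c(2.5, 1, 7.5, 2, 4, 8), nrow = 3, byrow = TRUE,
                dimnames = list(c("g1", "g2", "g3"), c("s1", "s2")))
  map <- c(g1 = "OG1", g2 = "OG1", g3 = "OG2")
  og <- aggregate_to_ogs(cpm, map)
  expect_equal(og["OG1", "s1"], 2.5 + 7.5)
  expect_equal(og["OG2", ], cpm["g3", ])  # singleton OG is the identity
  expect_equal(colSums(og), colSums(cpm))
  # unmapped genes are dropped and counted
  og2 <- aggregate_to_ogs(cpm, map[c("g1", "g3")])
  expect_equal(attr(og2, "n_unmapped"), 1L)
  expect_equal(colSums(og2), colSums(cpm[c("g1", "g3"), ]))
})

test_that("low-expression filter applies the per-species majority rule", {
  groups <- c("spA", "spA", "spA", "spB", "spB", "spB")
  m <- rbind(
    kept_one_species = c(5, 6, 7, 0.1, 0.2, 0.1),  # expressed in all of spA
    removed          = c(0.1, 0.2, 0.1, 0.3, 0.2, 0.1),
    boundary         = c(1, 1, 1, 1, 1, 1),         # exactly 1.0: strict <
    mixed            = c(0.5, 2, 2, 0.5, 0.4, 2)
  )
  res <- filter_low_expression(m, groups)
  expect_true("kept_one_species" %in% rownames(res$matrix))
  expect_equal(res$removed, "removed")
  expect_true("boundary" %in% rownames(res$matrix))
  strict <- filter_low_expression(m, groups, mode = "any")
  expect_true("mixed" %in% strict$removed)
})

test_that("TMM factors satisfy their analytic identities", {
  set.seed(14)
  base <- rnbinom(500, mu = 80, size = 5) + 1
  m <- cbind(s1 = base, s2 = base, s3 = base)
  expect_equal(unname(tmm_factors(m)$factors), rep(1, 3))

  # on a fixed nominal library, a uniformly doubled sample gets factor 2
  doubled <- cbind(s1 = base, s2 = base, s3 = 2 * base)
  f <- tmm_factors(doubled, lib_sizes = rep(1e6, 3))$factors
  expect_equal(unname(f["s3"] / f["s1"]), 2, tolerance = 1e-6)

  big <- matrix(rnbinom(400 * 6, mu = rexp(400, 1 / 100), size = 3), 400, 6,
                dimnames = list(NULL, paste0("s", 1:6)))
  f2 <- tmm_factors(big)$factors
  expect_equal(exp(mean(log(f2))), 1, tolerance = 1e-8)
  perm <- c(3, 1, 2, 6, 5, 4)
  expect_equal(unname(tmm_factors(big[, perm])$factors), unname(f2[perm]),
               tolerance = 1e-12)
})

test_that("dispersion estimation shrinks tagwise values onto the common one", {
  set.seed(3)
  y <- matrix(rnbinom(300 * 8, mu = rep(rlnorm(300, 4, 1), 8), size = 8),
              300, 8, dimnames = list(paste0("og", 1:300), NULL))
  g <- rep(c("a", "b"), each = 4)
  d <- estimate_dispersion(y, g, prior_df = 1e8)
  expect_lt(max(abs(d$tagwise - d$common)), 1e-3)
  d10 <- estimate_dispersion(y, g, prior_df = 10)
  expect_gt(sd(d10$tagwise), sd(d$tagwise))  # finite prior spreads estimates
  expect_error(estimate_dispersion(matrix(0, 5, 4), rep(c("a", "b"), 2)),
               "all-zero")
})

test_that("NB LRT is null on identical groups and symmetric under relabeling", {
  y <- matrix(rep(c(10, 20, 30, 40), each = 4), nrow = 4, byrow = TRUE,
              dimnames = list(paste0("og", 1:4), paste0("s", 1:4)))
  g <- c("a", "a", "b", "b")
  res <- fit_nb_glm_lrt(y, g, dispersion = 0.1, offset = rep(log(1e6), 4))
  expect_equal(res$logFC, rep(0, 4))
  expect_equal(res$lrt, rep(0, 4), tolerance = 1e-8)
  expect_equal(res$p_value, rep(1, 4), tolerance = 1e-8)

  set.seed(15)
  y2 <- matrix(rnbinom(200 * 10, mu = rep(rlnorm(200, 4, 1), 10), size = 10),
               200, 10, dimnames = list(paste0("og", 1:200), NULL))
  g2 <- factor(rep(c("a", "b"), each = 5), levels = c("a", "b"))
  off <- log(colSums(y2))
  fwd <- fit_nb_glm_lrt(y2, g2, 0.1, off)
  rev <- fit_nb_glm_lrt(y2, factor(g2, levels = c("b", "a")), 0.1, off)
  expect_equal(fwd$logFC, -rev$logFC, tolerance = 1e-8)
  expect_equal(fwd$p_value, rev$p_value, tolerance = 1e-10)
})

test_that("zero-count groups yield finite, strongly negative fold changes", {
  y <- rbind(gone = c(0, 0, 0, 0, 800, 900, 850, 820),
             ok = c(50, 60, 55, 52, 50, 60, 55, 52))
  g <- rep(c("a", "b"), each = 4)
  res <- fit_nb_glm_lrt(y, g, 0.1, offset = rep(log(1e6), 8))
  expect_true(is.finite(res$logFC[1]))
  expect_lt(res$logFC[1], -10)
  both_zero <- rbind(z = rep(0, 8))
  res0 <- fit_nb_glm_lrt(both_zero, g, 0.1, offset = rep(log(1e6), 8))
  expect_equal(res0$logFC, 0)
  expect_equal(res0$p_value, 1)
})

test_that("DE calling uses inclusive fold-change and FDR bounds", {
  # p-values chosen so the BH-adjusted values are (.05, .05, .2, .05)
  de <- data.frame(og = paste0("og", 1:4),
                   logFC = c(1.0, 0.9, -3, -1.5),
                   lrt = 1, p_value = c(0.0125, 0.025, 0.2, 0.0375),
                   converged = TRUE)
  called <- call_de(de)
  expect_equal(called$fdr, c(0.05, 0.05, 0.2, 0.05))
  expect_equal(called$class, c("up", "ns", "ns", "down"))
  expect_true(all(called$fdr >= called$p_value))
})

test_that("NB fits agree with the established GLM route on a fixture", {
  set.seed(77)
  y <- matrix(rnbinom(150 * 9, mu = rep(rlnorm(150, 4.5, 1), 9), size = 6),
              150, 9, dimnames = list(paste0("og", 1:150), paste0("s", 1:9)))
  y[1:20, 1:4] <- y[1:20, 1:4] * 4L  # strong planted signal
  g <- factor(rep(c("a", "b"), c(4, 5)), levels = c("a", "b"))
  off <- log(colSums(y))
  ours <- fit_nb_glm_lrt(y, g, dispersion = 0.15, offset = off)
  library(edgeR)
  design <- model.matrix(~ relevel(g, "b"))
  fit <- glmFit(y, design, dispersion = 0.15, offset = off, prior.count = 0)
  ref <- glmLRT(fit)$table
  expect_equal(ours$logFC, ref$logFC, tolerance = 1e-4)
  expect_equal(ours$p_value, ref$PValue, tolerance = 1e-4)
})
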