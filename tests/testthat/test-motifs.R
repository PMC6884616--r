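test_that("JASPAR PFMs parse in bracketed and raw layouts", {
  bundled <- default_pfm()
  expect_s3_class(bundled, "pfm")
  expect_equal(dim(bundled$counts), c(4L, 11L))
  expect_equal(unname(colSums(bundled$counts)), rep(100, 11))

  raw <- withr::local_tempfile(fileext = ".pfm")
  writeLines(c(">M1 toy", "10 0", "0 10", "0 0", "0 0"), raw)
  p <- read_jaspar(raw)
  expect_equal(unname(p$counts["A", 1]), 10)
  expect_equal(unname(p$counts["C", 2]), 10)
  expect_error(pfm(matrix(c(1, 1, 1, 1, 0, 0, 0, 0), 4)), "all-zero column")
})

test_that("log-odds transformation matches its closed form", {
  p <- pfm(matrix(c(10, 0, 0, 0), 4))
  w <- pfm_to_pwm(p, pseudocount = 1e-9)
  expect_equal(unname(w$scores["A", 1]), 2, tolerance = 1e-6)  # log2(1 / 0.25)
  uniform <- pfm_to_pwm(pfm(matrix(c(5, 5, 5, 5), 4)))
  expect_equal(unname(uniform$scores[, 1]), rep(0, 4))
  w2 <- pfm_to_pwm(p, pseudocount = 0.1)
  expect_true(all(is.finite(w2$scores)))
})

test_that("exact score distribution equals brute-force word enumeration", {
  # width 1: A scores 2, the rest 0 => P(score >= 2) = 1/4
  pwm1 <- structure(list(scores = matrix(c(2, 0, 0, 0), 4,
                                         dimnames = list(c("A", "C", "G", "T"), NULL)),
                         background = rep(0.25, 4), pseudocount = 0),
                    class = "pwm")
  d1 <- score_distribution(pwm1)
  expect_equal(sum(d1$probs), 1, tolerance = 1e-9)
  expect_equal(pwm_tail_p(d1, 2), 0.25)
  expect_equal(pwm_tail_p(d1, -5), 1)  # below the minimum score

  set.seed(21)
  for (i in 1:5) {
    scores <- matrix(round(runif(8, -4, 3), 2), 4)
    rownames(scores) <- c("A", "C", "G", "T")
    bg <- c(0.3, 0.2, 0.3, 0.2)
    pwm2 <- structure(list(scores = scores, background = bg, pseudocount = 0),
                      class = "pwm")
    d2 <- score_distribution(pwm2)
    expect_equal(sum(d2$probs), 1, tolerance = 1e-9)
    for (t in c(-4, -1, 0, 1.5, 3)) {
      expect_equal(pwm_tail_p(d2, t),
                   brute_tail(d2$int_scores, bg, round(t * 1000)),
                   tolerance = 1e-12)
    }
    tails <- vapply(seq(-8, 6, by = 0.5), function(t) pwm_tail_p(d2, t),
                    numeric(1))
    expect_true(all(diff(tails) <= 1e-15))  # non-increasing in the threshold
  }
})

test_that("scanning equals the all-windows brute force on short sequences", {
  pwm <- pfm_to_pwm(default_pfm())
  dist <- score_distribution(pwm)
  set.seed(12)
  for (i in 1:10) {
    s <- random_dna(sample(50:200, 1))
    hits <- scan_promoter(pwm, dist, s, p_threshold = 0.01)
    cutoff <- orthodelta:::score_cutoff_int(dist, 0.01)
    expect_equal(nrow(hits), brute_scan(dist$int_scores, s, cutoff))
    # reverse-complement symmetry of total hit counts
    rc <- orthodelta:::revcomp_chr(s)
    expect_equal(nrow(scan_promoter(pwm, dist, rc, p_threshold = 0.01)),
                 nrow(hits))
  }
  expect_equal(nrow(scan_promoter(pwm, dist, strrep("N", 60))), 0L)
  expect_error(scan_promoter(pwm, dist, "ACGT"), "shorter than the motif")

  # greedy collapse keeps non-overlapping hits only
  consensus <- paste(c("A", "C", "G", "T")[apply(default_pfm()$counts, 2, which.max)],
                     collapse = "")
  tandem <- paste0(strrep("T", 20), consensus, consensus, strrep("T", 20))
  all_hits <- scan_promoter(pwm, dist, tandem, p_threshold = 1e-4)
  collapsed <- scan_promoter(pwm, dist, tandem, p_threshold = 1e-4,
                             collapse = TRUE)
  expect_lte(nrow(collapsed), nrow(all_hits))
  expect_gte(min(diff(sort(collapsed$position[collapsed$strand == "+"])), Inf),
             ncol(dist$int_scores))
})

test_that("a planted consensus site is found at a stringent threshold", {
  pwm <- pfm_to_pwm(default_pfm())
  dist <- score_distribution(pwm)
  consensus <- paste(c("A", "C", "G", "T")[apply(default_pfm()$counts, 2, which.max)],
                     collapse = "")
  set.seed(3)
  s <- random_dna(500)
  substr(s, 201, 200 + nchar(consensus)) <- consensus
  hits <- scan_promoter(pwm, dist, s, p_threshold = 1e-6)
  expect_true(201 %in% hits$position[hits$strand == "+"])
})

test_that("promoter extraction respects strand, truncation, and missing contigs", {
  genome <- Biostrings::DNAStringSet(c(
    chr1 = paste(rep("ACGTT", 10), collapse = ""),  # 50 bases
    chr2 = "AAAACCCCGGGGTTTT"))
  gff <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\tsrc\tgene\t21\t30\t.\t+\t.\tID=gplus",
    "chr1\tsrc\tgene\t11\t30\t.\t-\t.\tID=gminus",
    "chr1\tsrc\tgene\t4\t40\t.\t+\t.\tID=gtrunc",
    "chr3\tsrc\tgene\t5\t9\t.\t+\t.\tID=gmissing"), gff)
  res <- extract_promoters(genome, gff, length = 10)
  chr1 <- as.character(genome[["chr1"]])
  expect_equal(res$promoters[["gplus"]], substr(chr1, 11, 20))
  # minus strand: reverse complement of the 10 bases following the gene end
  expect_equal(res$promoters[["gminus"]],
               as.character(Biostrings::reverseComplement(
                 Biostrings::DNAString(substr(chr1, 31, 40)))))
  expect_equal(res$promoters[["gtrunc"]], substr(chr1, 1, 3))
  expect_true(res$info$truncated[res$info$gene == "gtrunc"])
  expect_false(res$info$truncated[res$info$gene == "gplus"])
  expect_equal(res$skipped, "gmissing")
})

test_that("base composition summarises pooled sequences", {
  comp <- base_composition(c("AACG", "NNTT"))
  expect_equal(unname(comp), c(2, 1, 1, 2) / 6)
  expect_equal(sum(comp), 1)
  expect_error(base_composition("NNN"), "no A/C/G/T")
})

test_that("binding-site deltas summarise comparison species correctly", {
  counts <- matrix(c(5, 4,
                     2, 4,
                     3, 1,
                     4, 2), nrow = 2,
                   dimnames = list(c("g1", "g2"),
                                   c("ice", "cmp1", "cmp2", "cmp3")))
  d <- tfbs_delta(counts, "ice", c("cmp1", "cmp2", "cmp3"))
  expect_equal(unname(d["g1"]), 5 - 3)
  single <- tfbs_delta(counts, "ice", "cmp1")
  expect_equal(unname(single["g2"]), 4 - 4)
  expect_error(tfbs_delta(counts, "nope", "cmp1"), "focal species")
})

test_that("binding-site/expression association excludes downregulated genes", {
  delta <- setNames(c(2, 2, 0, 0, 0, 2), paste0("g", 1:6))
  de <- data.frame(og = paste0("g", 1:6),
                   logFC = c(2, 1.5, 0.1, -0.2, -2, -2),
                   p_value = c(0.01, 0.02, 0.5, 0.6, 0.001, 0.001))
  res <- tfbs_expression_association(delta, de, k = 1)
  expect_equal(sum(res$table), 4L)  # the two downregulated genes are excluded
  expect_equal(unname(res$table["extra_sites", "up"]), 2)
  expect_error(tfbs_expression_association(setNames(0, "g3"),
                                           de[3, , drop = FALSE], k = 1),
               "empty exposure class")
})

test_that("planted binding-site divergence is recovered from generated promoters", {
  cfg <- sim_config(n_ogs = 400, seed = 23)
  st <- simulate_study(cfg)
  pwm <- pfm_to_pwm(st$pfm)
  dist <- score_distribution(pwm)
  counts <- tfbs_count_table(st$promoters, pwm, dist, p_threshold = 1e-5)
  d <- tfbs_delta(counts, cfg$focal_species[1], cfg$outgroup_species)
  planted_up <- rownames(st$truth$planted_sites)[
    st$truth$planted_log2fc[rownames(st$truth$planted_sites)] >= 1]
  expect_equal(median(d[planted_up]), cfg$planted_extra_sites)
  others <- setdiff(names(d), planted_up)
  expect_equal(median(d[others]), 0)
})
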