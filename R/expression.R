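#' Counts per million
#'
#' @param counts Non-negative gene x sample matrix.
#' @param lib_sizes Library sizes; defaults to column sums. Every library
#'   must be positive.
#' @return Matrix of cpm values, columns summing to 1e6 when `lib_sizes`
#'   are the column sums.
#' @export
compute_cpm <- function(counts, lib_sizes = NULL) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative")
  if (is.null(lib_sizes)) lib_sizes <- colSums(counts)
  if (any(lib_sizes <= 0)) {
    bad <- colnames(counts)[lib_sizes <= 0]
    if (is.null(bad)) bad <- which(lib_sizes <= 0)
    stop("zero library size for sample(s): ", paste(bad, collapse = ", "))
  }
  sweep(counts, 2, lib_sizes, "/") * 1e6
}

#' Aggregate gene-level cpm to ortholog groups
#'
#' OG expression is the sum of the member genes' cpm in each sample, so
#' per-sample mass is conserved over the mapped genes. Genes absent from
#' the map are dropped (their count is reported via the `"n_unmapped"`
#' attribute).
#'
#' @param cpm Gene x sample cpm matrix with gene rownames.
#' @param map Named character vector, gene id -> OG id.
#' @return OG x sample matrix of summed cpm.
#' @export
aggregate_to_ogs <- function(cpm, map) {
  if (is.null(rownames(cpm))) stop("'cpm' must have gene rownames")
  mapped <- rownames(cpm) %in% names(map)
  n_unmapped <- sum(!mapped)
  if (n_unmapped == length(mapped)) stop("no gene of 'cpm' appears in the map")
  sub <- cpm[mapped, , drop = FALSE]
  out <- rowsum(sub, group = as.character(map[rownames(sub)]))
  attr(out, "n_unmapped") <- n_unmapped
  out
}

#' Remove weakly expressed OGs
#'
#' An OG is removed when, within every species (or other grouping), its
#' value falls below `threshold` in strictly more than half of that
#' group's samples. With `mode = "all"` (default) the removal condition
#' must hold in every group, so an OG adequately expressed in a single
#' species is retained; `mode = "any"` removes an OG failing in any group.
#'
#' @param og_mat OG x sample expression matrix.
#' @param groups Factor or character vector (length `ncol(og_mat)`)
#'   giving the per-sample grouping, typically species.
#' @param threshold Expression cutoff; the comparison is a strict `<`, so
#'   values exactly at the threshold count as expressed.
#' @param mode `"all"` or `"any"` (see above).
#' @return List with `matrix` (retained rows) and `removed` (dropped OG ids).
#' @export
filter_low_expression <- function(og_mat, groups, threshold = 1,
                                  mode = c("all", "any")) {
  mode <- match.arg(mode)
  groups <- as.factor(groups)
  if (length(groups) != ncol(og_mat)) {
    stop("'groups' must label every sample column")
  }
  below <- og_mat < threshold
  n_per_group <- table(groups)
  below_per_group <- t(rowsum(t(below) * 1, groups))  # OG x group
  fails <- sweep(below_per_group, 2, as.numeric(n_per_group) / 2, ">")
  remove <- if (mode == "all") rowSums(fails) == nlevels(groups) else rowSums(fails) > 0
  list(matrix = og_mat[!remove, , drop = FALSE],
       removed = rownames(og_mat)[remove])
}

# Quantile of scaled counts used to pick the TMM reference sample.
tmm_sample_quantile <- function(mat, lib_sizes, p = 0.75) {
  q <- apply(mat, 2, stats::quantile, probs = p, names = FALSE)
  q / lib_sizes
}

# Trimmed, precision-weighted mean of log ratios between one sample and
# the reference (the standard TMM recipe: 30% trim on M, 5% on A).
tmm_pair_factor <- function(obs, ref, n_obs, n_ref,
                            logratio_trim = 0.3, sum_trim = 0.05,
                            a_cutoff = -1e10) {
  log_r <- log2((obs / n_obs) / (ref / n_ref))
  abs_e <- (log2(obs / n_obs) + log2(ref / n_ref)) / 2
  v <- (n_obs - obs) / n_obs / obs + (n_ref - ref) / n_ref / ref
  fin <- is.finite(log_r) & is.finite(abs_e) & (abs_e > a_cutoff)
  log_r <- log_r[fin]; abs_e <- abs_e[fin]; v <- v[fin]
  if (length(log_r) == 0) stop("sample shares no expressed rows with the reference")
  if (max(abs(log_r)) < 1e-6) return(1)
  n <- length(log_r)
  lo_l <- floor(n * logratio_trim) + 1
  hi_l <- n + 1 - lo_l
  lo_s <- floor(n * sum_trim) + 1
  hi_s <- n + 1 - lo_s
  keep <- (rank(log_r) >= lo_l & rank(log_r) <= hi_l) &
    (rank(abs_e) >= lo_s & rank(abs_e) <= hi_s)
  f <- sum(log_r[keep] / v[keep], na.rm = TRUE) / sum(1 / v[keep], na.rm = TRUE)
  if (is.na(f)) f <- 0
  2^f
}

#' Trimmed mean of M-values normalization factors
#'
#' Between-sample scaling factors computed by the TMM method: each sample
#' is compared to a reference sample (the one whose scaled upper quartile
#' is closest to the mean upper quartile), the log2 expression ratios (M)
#' are doubly trimmed (30% on M, 5% on average abundance A) and averaged
#' with precision weights, and the resulting factors are rescaled to have
#' geometric mean 1.
#'
#' @param mat OG (or gene) x sample expression matrix.
#' @param lib_sizes Library sizes; defaults to column sums.
#' @param ref Optional reference column (index or name); by default chosen
#'   by the upper-quartile rule.
#' @return List with `factors` (named numeric, geometric mean 1) and
#'   `ref` (reference column index).
#' @export
tmm_factors <- function(mat, lib_sizes = NULL, ref = NULL) {
  mat <- as.matrix(mat)
  if (ncol(mat) < 2) stop("TMM needs at least two samples")
  if (is.null(lib_sizes)) lib_sizes <- colSums(mat)
  if (is.null(ref)) {
    f75 <- tmm_sample_quantile(mat, lib_sizes, 0.75)
    ref <- if (stats::median(f75) < 1e-20) {
      which.max(colSums(sqrt(mat)))
    } else {
      which.min(abs(f75 - mean(f75)))
    }
  } else if (is.character(ref)) {
    ref <- match(ref, colnames(mat))
  }
  f <- vapply(seq_len(ncol(mat)), function(j) {
    tmm_pair_factor(as.numeric(mat[, j]), as.numeric(mat[, ref]),
                    lib_sizes[j], lib_sizes[ref])
  }, numeric(1))
  f <- f / exp(mean(log(f)))
  names(f) <- colnames(mat)
  list(factors = f, ref = ref)
}

# Fit a single NB mean per row over a set of samples by Fisher scoring on
# the log scale: mu_i = exp(beta + offset_i). Vectorized over rows.
# Returns beta (NA / -Inf handled as all-zero rows), mu matrix, loglik,
# CR adjustment weight sum, and a convergence flag.
nb_fit_group <- function(y, offset, dispersion, max_iter = 50, tol = 1e-8) {
  y <- as.matrix(y)
  n <- ncol(y)
  eo <- exp(offset)
  tot <- rowSums(y)
  beta <- log(tot / sum(eo))          # Poisson start; -Inf for all-zero rows
  zero <- tot == 0
  converged <- rep(TRUE, nrow(y))
  active <- which(!zero)
  if (length(active) > 0) {
    conv <- rep(FALSE, length(active))
    b <- beta[active]
    ya <- y[active, , drop = FALSE]
    d <- if (length(dispersion) == 1) rep(dispersion, length(active)) else dispersion[active]
    for (it in seq_len(max_iter)) {
      mu <- exp(outer(b, offset, "+"))
      w <- mu / (1 + d * mu)
      score <- rowSums((ya - mu) / (1 + d * mu))
      info <- rowSums(w)
      step <- score / info
      step <- pmax(pmin(step, 5), -5)  # damp wild early steps
      b <- b + step
      conv <- abs(step) < tol
      if (all(conv)) break
    }
    beta[active] <- b
    converged[active] <- conv
  }
  mu <- exp(outer(beta, offset, "+"))
  mu[zero, ] <- 0
  d_full <- if (length(dispersion) == 1) rep(dispersion, nrow(y)) else dispersion
  ll <- rowSums(stats::dnbinom(y, size = 1 / d_full, mu = pmax(mu, 1e-300),
                               log = TRUE))
  ll[zero] <- 0  # all-zero rows: point mass at zero
  wsum <- rowSums(mu / (1 + d_full * mu))
  list(beta = beta, mu = mu, loglik = ll, wsum = wsum, converged = converged)
}

# Per-row Cox-Reid adjusted profile likelihood for a two-group means model
# at a given dispersion (scalar or per-row vector).
nb_apl <- function(y, offset, groups, dispersion) {
  lev <- levels(groups)
  apl <- numeric(nrow(y))
  for (g in lev) {
    idx <- which(groups == g)
    fit <- nb_fit_group(y[, idx, drop = FALSE], offset[idx], dispersion)
    adj <- ifelse(fit$wsum > 0, 0.5 * log(fit$wsum), 0)
    apl <- apl + fit$loglik - adj
  }
  apl
}

#' Estimate common and tagwise NB dispersions
#'
#' The common dispersion maximizes the Cox-Reid adjusted profile
#' likelihood (APL) summed over all OGs, searched on the log-dispersion
#' scale. Tagwise (per-OG) dispersions are weighted-likelihood empirical
#' Bayes estimates: each OG maximizes its own APL plus `prior_df` residual
#' degrees of freedom worth of the shared APL, evaluated on a grid centred
#' on the common value and refined by quadratic interpolation. As
#' `prior_df` grows the tagwise values shrink onto the common dispersion.
#'
#' @param counts Integer OG x sample matrix (summed cpm rounded to
#'   integers in the standard pipeline).
#' @param groups Two-level factor (or coercible) labelling the samples.
#' @param prior_df Prior degrees of freedom for shrinkage (default 10).
#' @param offset Log effective library sizes (defaults to
#'   `log(colSums(counts))`).
#' @return List with `common`, `tagwise` (named per-OG vector), and
#'   `prior_df`.
#' @export
estimate_dispersion <- function(counts, groups, prior_df = 10, offset = NULL) {
  counts <- as.matrix(counts)
  groups <- droplevels(as.factor(groups))
  if (length(groups) != ncol(counts)) stop("'groups' must label every sample")
  if (all(counts == 0)) stop("all-zero count matrix")
  if (is.null(offset)) offset <- log(colSums(counts))
  use <- rowSums(counts) > 0
  y <- counts[use, , drop = FALSE]

  obj <- function(log_d) sum(nb_apl(y, offset, groups, exp(log_d)))
  opt <- stats::optimize(obj, interval = log(c(1e-6, 4)),
                         maximum = TRUE, tol = 1e-4)
  common <- exp(opt$maximum)

  df_res <- max(ncol(counts) - nlevels(groups), 1)
  prior_n <- prior_df / df_res
  grid_log2 <- seq(-6, 6, length.out = 25)       # includes 0 => the common value
  grid <- common * 2^grid_log2
  apl <- vapply(grid, function(d) nb_apl(y, offset, groups, d),
                numeric(nrow(y)))
  shared <- colMeans(apl)
  objective <- apl + matrix(prior_n * shared, nrow(y), length(grid),
                            byrow = TRUE)
  j <- max.col(objective, ties.method = "first")
  # quadratic refinement of the grid maximum (log2-dispersion coordinates)
  x_star <- grid_log2[j]
  interior <- j > 1 & j < length(grid)
  if (any(interior)) {
    i <- which(interior)
    h <- grid_log2[2] - grid_log2[1]
    f0 <- objective[cbind(i, j[i])]
    fm <- objective[cbind(i, j[i] - 1L)]
    fp <- objective[cbind(i, j[i] + 1L)]
    denom <- fm - 2 * f0 + fp
    shift <- ifelse(denom < 0, 0.5 * h * (fm - fp) / denom, 0)
    x_star[i] <- grid_log2[j[i]] + pmax(pmin(shift, h), -h)
  }
  tagwise_use <- common * 2^x_star
  tagwise <- rep(common, nrow(counts))
  tagwise[use] <- tagwise_use
  names(tagwise) <- rownames(counts)
  list(common = common, tagwise = tagwise, prior_df = prior_df)
}

#' Two-group negative-binomial GLM likelihood-ratio test
#'
#' Per OG, a log-link NB GLM with a two-level group factor is compared to
#' the intercept-only model via the likelihood-ratio statistic (chi-square,
#' 1 df). Group means are fitted by Fisher scoring with the supplied
#' offsets (log effective library sizes, i.e. `log(lib_size * tmm_factor)`).
#' The log2 fold change contrasts offset-adjusted fitted group means; when
#' a group has zero total count for an OG, both group rates receive a
#' 0.125 pseudo-count per observation (scaled by the relative offsets) so
#' the fold change stays finite.
#'
#' @param counts Integer OG x sample matrix.
#' @param groups Two-level factor; the first level is the group of
#'   interest (log fold changes are level-1 over level-2).
#' @param dispersion Scalar or per-OG dispersion(s), e.g. the `tagwise`
#'   component of [estimate_dispersion()].
#' @param offset Log effective library sizes (defaults to
#'   `log(colSums(counts))`).
#' @return Data frame with columns `og`, `logFC`, `lrt`, `p_value`, and
#'   `converged`.
#' @export
fit_nb_glm_lrt <- function(counts, groups, dispersion, offset = NULL) {
  counts <- as.matrix(counts)
  groups <- droplevels(as.factor(groups))
  if (nlevels(groups) != 2) stop("exactly two groups are required")
  if (length(groups) != ncol(counts)) stop("'groups' must label every sample")
  if (is.null(offset)) offset <- log(colSums(counts))
  lev <- levels(groups)
  ia <- which(groups == lev[1]); ib <- which(groups == lev[2])

  fit_a <- nb_fit_group(counts[, ia, drop = FALSE], offset[ia], dispersion)
  fit_b <- nb_fit_group(counts[, ib, drop = FALSE], offset[ib], dispersion)
  fit_0 <- nb_fit_group(counts, offset, dispersion)
  ll_alt <- fit_a$loglik + fit_b$loglik
  lrt <- pmax(2 * (ll_alt - fit_0$loglik), 0)
  p <- stats::pchisq(lrt, df = 1, lower.tail = FALSE)

  rate <- function(fit, idx) {
    tot <- rowSums(counts[, idx, drop = FALSE])
    exp_o <- exp(offset[idx])
    mle <- exp(fit$beta)
    # pseudo-count rule for rows where either group total is zero
    w <- exp_o / mean(exp_o)
    shrunk <- (tot + 0.125 * sum(w)) / sum(exp_o)
    list(mle = mle, shrunk = shrunk, tot = tot)
  }
  ra <- rate(fit_a, ia); rb <- rate(fit_b, ib)
  zero_group <- ra$tot == 0 | rb$tot == 0
  logfc <- ifelse(zero_group,
                  log2(ra$shrunk / rb$shrunk),
                  log2(ra$mle / rb$mle))
  logfc[ra$tot == 0 & rb$tot == 0] <- 0

  converged <- fit_a$converged & fit_b$converged & fit_0$converged
  p[!converged] <- NA_real_
  data.frame(og = rownames(counts), logFC = logfc, lrt = lrt,
             p_value = p, converged = converged,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Attach FDR and significance classes to a DE table
#'
#' Benjamini-Hochberg adjusts the LRT p-values and classifies each OG as
#' `up` (`logFC >= logfc_cut` and `fdr <= fdr_cut`), `down`
#' (`logFC <= -logfc_cut` and `fdr <= fdr_cut`), or `ns`. Both bounds are
#' inclusive.
#'
#' @param de Data frame from [fit_nb_glm_lrt()].
#' @param logfc_cut Absolute log2 fold-change cutoff (default 1).
#' @param fdr_cut FDR cutoff (default 0.05).
#' @return The table with added `fdr` and `class` columns.
#' @export
call_de <- function(de, logfc_cut = 1, fdr_cut = 0.05) {
  de$fdr <- benjamini_hochberg(de$p_value)
  de$class <- ifelse(is.na(de$fdr), "ns",
              ifelse(de$logFC >= logfc_cut & de$fdr <= fdr_cut, "up",
              ifelse(de$logFC <= -logfc_cut & de$fdr <= fdr_cut, "down", "ns")))
  de
}

#' Cross-species OG-level differential expression pipeline
#'
#' Runs the full comparison used for multi-species muscle transcriptome
#' contrasts: per-species gene counts are converted to cpm on the species'
#' own library sizes, summed over OG members, assembled into one
#' OG x sample matrix, filtered for low expression per species, rounded to
#' integer pseudo-counts on a nominal library of 1e6, TMM-normalised, and
#' tested between two sample groups with the NB likelihood-ratio test.
#'
#' @param counts_list Named list (by species) of gene x sample count
#'   matrices with gene rownames and sample colnames.
#' @param metadata Data frame with columns `sample`, `species`, `group`
#'   covering every sample column.
#' @param orthology An `orthology_table` covering the species.
#' @param group_a,group_b Group labels to contrast (`group_a` over
#'   `group_b` in the fold change).
#' @param prior_df,logfc_cut,fdr_cut Passed to the dispersion estimator
#'   and DE caller.
#' @return List with `de` (classified DE table), `og_matrix` (filtered
#'   rounded OG counts for the contrasted samples), `factors`,
#'   `dispersion`, and `removed` (filtered-out OG ids).
#' @export
og_de_pipeline <- function(counts_list, metadata, orthology,
                           group_a, group_b,
                           prior_df = 10, logfc_cut = 1, fdr_cut = 0.05) {
  missing_sp <- setdiff(unique(metadata$species), names(counts_list))
  if (length(missing_sp) > 0) {
    stop("species in metadata without count matrix: ",
         paste(missing_sp, collapse = ", "))
  }
  og_parts <- lapply(names(counts_list), function(sp) {
    cpm <- compute_cpm(counts_list[[sp]])
    aggregate_to_ogs(cpm, gene_og_map(orthology, sp))
  })
  names(og_parts) <- names(counts_list)
  all_ogs <- sort(unique(unlist(lapply(og_parts, rownames))))
  all_samples <- unlist(lapply(og_parts, colnames))
  og_mat <- matrix(0, length(all_ogs), length(all_samples),
                   dimnames = list(all_ogs, all_samples))
  for (part in og_parts) og_mat[rownames(part), colnames(part)] <- part

  meta <- metadata[match(colnames(og_mat), metadata$sample), , drop = FALSE]
  if (anyNA(meta$sample)) stop("metadata must cover every sample column")
  flt <- filter_low_expression(og_mat, meta$species)

  sel <- meta$group %in% c(group_a, group_b)
  y <- round(flt$matrix[, sel, drop = FALSE])
  groups <- factor(meta$group[sel], levels = c(group_a, group_b))
  norm <- tmm_factors(y, lib_sizes = rep(1e6, ncol(y)))
  offset <- log(1e6 * norm$factors)
  disp <- estimate_dispersion(y, groups, prior_df = prior_df, offset = offset)
  de <- fit_nb_glm_lrt(y, groups, disp$tagwise, offset = offset)
  de <- call_de(de, logfc_cut = logfc_cut, fdr_cut = fdr_cut)
  list(de = de, og_matrix = y, factors = norm$factors,
       dispersion = disp, removed = flt$removed)
}
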