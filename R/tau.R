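#' Tau tissue-specificity index
#'
#' For a non-negative expression profile over `N >= 2` tissues, each
#' component is divided by the maximal component and
#' `tau = sum(1 - x_i) / (N - 1)`. A profile expressed in a single tissue
#' gives 1; a perfectly uniform profile gives 0. All-zero profiles are
#' undefined and return `NA`.
#'
#' @param x Numeric vector of per-tissue expression values (negative
#'   values are an error; clip or offset upstream).
#' @return Tau in `[0, 1]`, or `NA` for an all-zero profile.
#' @examples
#' tau(c(8, 0, 0, 0, 0))  # 1: single-tissue
#' tau(c(3, 3, 3, 3, 3))  # 0: ubiquitous
#' @export
tau <- function(x) {
  if (length(x) < 2) stop("tau needs at least two tissues")
  if (anyNA(x)) stop("profile must not contain NA")
  if (any(x < 0)) stop("profile components must be non-negative")
  m <- max(x)
  if (m == 0) return(NA_real_)
  sum(1 - x / m) / (length(x) - 1)
}

#' Per-gene tau over a replicated multi-tissue panel
#'
#' Normalises a gene x sample count panel to TMM-scaled log2 cpm,
#' collapses replicates to per-tissue means, and computes tau per gene.
#' Negative log2 cpm values are clipped to zero by default (tau assumes
#' non-negative components); `log_offset = "plus1"` uses `log2(cpm + 1)`
#' instead.
#'
#' @param panel Gene x sample count matrix.
#' @param tissues Character/factor vector assigning each sample column to
#'   a tissue (at least 2 distinct tissues).
#' @param log_offset `"clip"` (default) or `"plus1"`.
#' @return Data frame with columns `gene` and `tau` (`NA` for genes with
#'   all-zero normalised profiles, reported via the `"undefined"`
#'   attribute).
#' @export
tau_table <- function(panel, tissues, log_offset = c("clip", "plus1")) {
  log_offset <- match.arg(log_offset)
  tissues <- as.factor(tissues)
  if (length(tissues) != ncol(panel)) stop("'tissues' must label every sample")
  if (nlevels(tissues) < 2) stop("tau needs at least two tissues")
  cpm <- compute_cpm(panel)
  norm <- tmm_factors(panel)
  cpm <- sweep(cpm, 2, norm$factors, "/")
  expr <- if (log_offset == "clip") pmax(log2(pmax(cpm, 1e-300)), 0) else log2(cpm + 1)
  by_tissue <- t(rowsum(t(expr), tissues) / as.numeric(table(tissues)))
  tv <- apply(by_tissue, 1, tau)
  out <- data.frame(gene = rownames(panel), tau = as.numeric(tv),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "undefined") <- out$gene[is.na(out$tau)]
  out
}

#' Assign genes to duplication categories
#'
#' Genes of a chosen species are grouped by the copy-number class of
#' their OG: `duplicated` (mean copy difference at or above the
#' duplication threshold), `one_to_one` (exactly one copy in every
#' species of the table), and `not_duplicated` (at or below the
#' background threshold, excluding strict one-to-one OGs). Genes of
#' intermediate OGs fall in no category and are reported separately.
#'
#' @param orthology An `orthology_table`.
#' @param dup Classification from [classify_duplication()].
#' @param species Species whose genes are categorised.
#' @return Data frame with columns `gene`, `og`, `category`; excluded
#'   (intermediate) genes are in the `"excluded"` attribute.
#' @export
categorize_genes <- function(orthology, dup, species) {
  copies <- copy_number_matrix(orthology)
  one_to_one <- rownames(copies)[rowSums(copies == 1) == ncol(copies)]
  cls <- stats::setNames(dup$class, dup$og)
  map <- gene_og_map(orthology, species)
  og <- as.character(map)
  category <- rep(NA_character_, length(og))
  known <- og %in% names(cls)
  category[known & cls[og] == "duplicated"] <- "duplicated"
  bg <- known & cls[og] == "background"
  category[bg & og %in% one_to_one] <- "one_to_one"
  category[bg & !(og %in% one_to_one)] <- "not_duplicated"
  out <- data.frame(gene = names(map), og = og, category = category,
                    stringsAsFactors = FALSE, row.names = NULL)
  excluded <- out$gene[is.na(out$category)]
  out <- out[!is.na(out$category), , drop = FALSE]
  attr(out, "excluded") <- excluded
  out
}

#' Compare tau distributions across gene categories
#'
#' Reports the median tau per category and pairwise two-sided Wilcoxon
#' rank-sum p-values between categories.
#'
#' @param tau_df Data frame with columns `gene` and `tau`
#'   (from [tau_table()]).
#' @param categories Data frame with columns `gene` and `category`
#'   (from [categorize_genes()]).
#' @return List with `medians` (named vector), `n` (genes per category),
#'   and `tests` (data frame of pairwise comparisons).
#' @export
tau_by_category <- function(tau_df, categories) {
  merged <- merge(tau_df, categories[, c("gene", "category")], by = "gene")
  merged <- merged[!is.na(merged$tau), , drop = FALSE]
  lev <- unique(merged$category)
  if (length(lev) < 2) stop("need at least two non-empty categories")
  split_tau <- split(merged$tau, merged$category)
  medians <- vapply(split_tau, stats::median, numeric(1))
  pairs <- utils::combn(lev, 2)
  tests <- data.frame(
    category_a = pairs[1, ], category_b = pairs[2, ],
    p_value = apply(pairs, 2, function(pr) {
      wilcoxon_rank_sum(split_tau[[pr[1]]], split_tau[[pr[2]]])$p_value
    }),
    stringsAsFactors = FALSE
  )
  list(medians = medians, n = lengths(split_tau), tests = tests)
}
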