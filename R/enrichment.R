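#' Ranking scores for preranked enrichment
#'
#' Converts a DE table into the signed confidence score used for
#' preranked enrichment: `1 - p` for OGs with positive log fold change,
#' `-(1 - p)` for negative, and 0 when the fold change is exactly zero.
#' The list is sorted by decreasing score with ties broken by OG
#' identifier so permutation analyses are reproducible.
#'
#' @param de Data frame with columns `og`, `logFC`, `p_value`.
#' @return Data frame with columns `og` and `score`, sorted.
#' @export
rank_scores <- function(de) {
  if (anyNA(de$p_value)) {
    de <- de[!is.na(de$p_value), , drop = FALSE]
  }
  score <- ifelse(de$logFC > 0, 1 - de$p_value,
                  ifelse(de$logFC < 0, -(1 - de$p_value), 0))
  ord <- order(-score, de$og)
  data.frame(og = de$og[ord], score = score[ord],
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Classic (unweighted) enrichment score
#'
#' Walks the ranked list accumulating `1/Nh` at each set member ("hit")
#' and `-1/(N - Nh)` at each non-member, so the running sum returns to
#' zero at the end of the list. The enrichment score is the
#' maximum-magnitude deviation of the running sum from zero.
#'
#' @param ranked Data frame from [rank_scores()] (ordered OG ids).
#' @param set Character vector of member identifiers.
#' @return List with `es`, `running` (full running-sum profile), and
#'   `hits` (positions of set members in the list).
#' @export
enrichment_score <- function(ranked, set) {
  ids <- ranked$og
  n <- length(ids)
  hits <- which(ids %in% set)
  nh <- length(hits)
  if (nh == 0) stop("set has empty intersection with the ranked list")
  if (nh == n) stop("set covers the entire ranked list; ES undefined")
  inc <- rep(-1 / (n - nh), n)
  inc[hits] <- 1 / nh
  running <- cumsum(inc)
  hi <- max(running); lo <- min(running)
  # on an exact tie of magnitudes, the positive extreme is reported
  es <- if (hi >= -lo - 1e-12) hi else lo
  list(es = es, running = running, hits = hits)
}

# ES from sorted hit positions only (no full profile): local maxima of the
# running sum sit right after hits, local minima right before hits.
es_from_positions <- function(pos, n, nh) {
  i <- seq_len(nh)
  v_hi <- i / nh - (pos - i) / (n - nh)
  v_lo <- (i - 1) / nh - (pos - i) / (n - nh)
  hi <- max(v_hi)
  lo <- min(v_lo)
  if (hi >= -lo - 1e-12) hi else lo
}

#' Permutation-normalised enrichment over a gene-set collection
#'
#' For every set, the classic enrichment score is compared against a null
#' built by placing the same number of member labels uniformly at random
#' in the ranked list (`n_perm` draws). Scores are normalised by the mean
#' magnitude of same-sign null scores ("meandiv"), nominal p-values come
#' from the same-sign permutation tail (floored at `1/n_perm`, never 0),
#' and FDR q-values compare each normalised score against the pooled
#' normalised null across all sets, with the usual monotonisation from the
#' most extreme score inward.
#'
#' @param ranked Data frame from [rank_scores()].
#' @param sets Named list of character vectors (e.g. from [read_gmt()]).
#' @param n_perm Number of permutations (at least 100; default 1000).
#' @param seed Integer seed making the permutation null reproducible.
#' @return Data frame with one row per scored set: `set`, `size`, `es`,
#'   `nes`, `p_value`, `fdr_q`, `leading_edge` (comma-separated members).
#'   Sets with no overlap with the list are reported in the
#'   `"skipped"` attribute.
#' @export
permutation_nes <- function(ranked, sets, n_perm = 1000, seed = 1) {
  if (n_perm < 100) stop("'n_perm' must be at least 100")
  n <- nrow(ranked)
  overlap <- lapply(sets, function(s) which(ranked$og %in% s))
  skipped <- names(sets)[lengths(overlap) == 0 | lengths(overlap) == n]
  keep <- setdiff(names(sets), skipped)
  if (length(keep) == 0) stop("no set overlaps the ranked list")

  set.seed(seed)
  res <- lapply(keep, function(nm) {
    hits <- overlap[[nm]]
    nh <- length(hits)
    obs <- enrichment_score(ranked, sets[[nm]])
    null_es <- vapply(seq_len(n_perm), function(b) {
      es_from_positions(sort(sample.int(n, nh)), n, nh)
    }, numeric(1))
    mean_pos <- mean(null_es[null_es > 0])
    mean_neg <- mean(abs(null_es[null_es < 0]))
    normalise <- function(e) {
      ifelse(e >= 0,
             e / ifelse(is.finite(mean_pos) && mean_pos > 0, mean_pos, 1),
             e / ifelse(is.finite(mean_neg) && mean_neg > 0, mean_neg, 1))
    }
    same_sign <- if (obs$es >= 0) null_es[null_es >= 0] else null_es[null_es < 0]
    p <- if (length(same_sign) == 0) 1 / n_perm else
      max(mean(abs(same_sign) >= abs(obs$es)), 1 / n_perm)
    peak <- if (obs$es >= 0) which.max(obs$running) else which.min(obs$running)
    lead <- if (obs$es >= 0) obs$hits[obs$hits <= peak] else obs$hits[obs$hits >= peak]
    list(set = nm, size = nh, es = obs$es, nes = normalise(obs$es),
         p_value = p, null_nes = normalise(null_es),
         leading_edge = paste(ranked$og[lead], collapse = ","))
  })

  nes_obs <- vapply(res, `[[`, numeric(1), "nes")
  pooled <- unlist(lapply(res, `[[`, "null_nes"))
  q <- vapply(nes_obs, function(s) {
    if (s >= 0) {
      num_null <- sum(pooled >= s) / max(sum(pooled >= 0), 1)
      num_obs <- sum(nes_obs >= s) / max(sum(nes_obs >= 0), 1)
    } else {
      num_null <- sum(pooled <= s) / max(sum(pooled < 0), 1)
      num_obs <- sum(nes_obs <= s) / max(sum(nes_obs < 0), 1)
    }
    min(1, num_null / num_obs)
  }, numeric(1))
  # monotone from the most extreme score inward, separately per sign
  for (sgn in c(1, -1)) {
    idx <- if (sgn > 0) which(nes_obs >= 0) else which(nes_obs < 0)
    if (length(idx) > 1) {
      ord <- idx[order(-sgn * nes_obs[idx])]
      q[ord] <- cummin(q[ord])
    }
  }
  q <- pmax(q, 1 / n_perm)

  out <- data.frame(
    set = vapply(res, `[[`, "", "set"),
    size = vapply(res, `[[`, integer(1), "size"),
    es = vapply(res, `[[`, numeric(1), "es"),
    nes = nes_obs,
    p_value = vapply(res, `[[`, numeric(1), "p_value"),
    fdr_q = q,
    leading_edge = vapply(res, `[[`, "", "leading_edge"),
    stringsAsFactors = FALSE, row.names = NULL
  )
  attr(out, "skipped") <- skipped
  attr(out, "n_perm") <- n_perm
  out
}

#' Read / write gene sets in GMT format
#'
#' `read_gmt()` wraps `fgsea::gmtPathways()` when available and falls back
#' to a minimal reader otherwise; `write_gmt()` emits the standard
#' tab-separated layout (name, description, members).
#'
#' @param path File path.
#' @return `read_gmt()`: named list of character vectors.
#' @export
read_gmt <- function(path) {
  if (requireNamespace("fgsea", quietly = TRUE)) {
    return(fgsea::gmtPathways(path))
  }
  lines <- readLines(path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  stats::setNames(lapply(parts, function(p) p[-(1:2)]),
                  vapply(parts, `[[`, "", 1))
}

#' @rdname read_gmt
#' @param sets Named list of character vectors.
#' @param descriptions Optional character vector of set descriptions.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Association between duplication status and gene-set membership
#'
#' Builds the 2x2 table of duplicated vs background OGs (intermediates
#' excluded) against set membership and applies a one-sided Fisher exact
#' test for over-representation of set members among duplicated OGs.
#'
#' @param dup Classification from [classify_duplication()].
#' @param set Character vector of OG identifiers.
#' @param alternative Sidedness of the Fisher test (default `"greater"`).
#' @return List with `table`, `p_value`, `odds_ratio`.
#' @export
duplication_set_enrichment <- function(dup, set, alternative = "greater") {
  d <- dup[dup$class != "intermediate", , drop = FALSE]
  in_set <- d$og %in% set
  is_dup <- d$class == "duplicated"
  tab <- matrix(c(sum(is_dup & in_set), sum(is_dup & !in_set),
                  sum(!is_dup & in_set), sum(!is_dup & !in_set)),
                nrow = 2, byrow = TRUE,
                dimnames = list(c("duplicated", "background"),
                                c("in_set", "out_set")))
  ft <- fisher_exact_2x2(tab, alternative)
  list(table = tab, p_value = ft$p_value, odds_ratio = ft$odds_ratio)
}

#' Association between duplication status and upregulation
#'
#' Tests whether duplicated OGs (mean copy difference at or above the
#' duplication threshold) are upregulated (`logFC >= logfc_cut`) more
#' often than background OGs, by a one-sided Fisher exact test on the 2x2
#' table. Intermediate OGs and OGs absent from the DE table are excluded.
#'
#' @param dup Classification from [classify_duplication()].
#' @param de DE table with columns `og` and `logFC`.
#' @param logfc_cut Upregulation cutoff (default 1, inclusive).
#' @param alternative Sidedness of the Fisher test.
#' @return List with `table`, `p_value`, `odds_ratio`.
#' @export
duplication_expression_association <- function(dup, de, logfc_cut = 1,
                                               alternative = "greater") {
  d <- dup[dup$class != "intermediate" & dup$og %in% de$og, , drop = FALSE]
  if (!any(d$class == "duplicated")) stop("no duplicated OGs in the DE universe")
  lfc <- de$logFC[match(d$og, de$og)]
  up <- lfc >= logfc_cut
  is_dup <- d$class == "duplicated"
  tab <- matrix(c(sum(is_dup & up), sum(is_dup & !up),
                  sum(!is_dup & up), sum(!is_dup & !up)),
                nrow = 2, byrow = TRUE,
                dimnames = list(c("duplicated", "background"),
                                c("up", "not_up")))
  ft <- fisher_exact_2x2(tab, alternative)
  list(table = tab, p_value = ft$p_value, odds_ratio = ft$odds_ratio)
}
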