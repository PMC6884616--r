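# Independent brute-force oracles used to validate the analytic routes.

# One-sided ("greater") Fisher p by direct hypergeometric enumeration
# from binomial coefficients.
brute_fisher_greater <- function(tab) {
  x <- tab[1, 1]; m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  supp <- max(0, k - n):min(k, m)
  probs <- choose(m, supp) * choose(n, k - supp) / choose(m + n, k)
  sum(probs[supp >= x])
}

# Two-sided Fisher p: enumerate every table with the observed margins and
# sum those at most as probable as the observed one.
brute_fisher_two_sided <- function(tab) {
  x <- tab[1, 1]; m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  supp <- max(0, k - n):min(k, m)
  probs <- choose(m, supp) * choose(n, k - supp) / choose(m + n, k)
  obs <- probs[supp == x]
  min(1, sum(probs[probs <= obs * (1 + 1e-7)]))
}

# Null distribution of the Mann-Whitney U statistic by full enumeration
# of all assignments of pooled ranks to the first sample.
brute_wilcox_two_sided <- function(x, y) {
  nx <- length(x); ny <- length(y)
  pooled_ranks <- rank(c(x, y))
  u_obs <- sum(pooled_ranks[seq_len(nx)]) - nx * (nx + 1) / 2
  all_u <- apply(utils::combn(nx + ny, nx), 2, function(idx) {
    sum(pooled_ranks[idx]) - nx * (nx + 1) / 2
  })
  lower <- mean(all_u <= u_obs)
  upper <- mean(all_u >= u_obs)
  if (u_obs > nx * ny / 2) min(1, 2 * upper) else min(1, 2 * lower)
}

# Classic enrichment score by prefix enumeration (ties between the
# positive and negative extreme resolve to the positive one, as in the
# implementation's documented tie-break).
brute_es <- function(og_ids, set) {
  n <- length(og_ids)
  is_hit <- og_ids %in% set
  nh <- sum(is_hit)
  dev <- vapply(seq_len(n), function(i) {
    sum(is_hit[1:i]) / nh - sum(!is_hit[1:i]) / (n - nh)
  }, numeric(1))
  hi <- max(dev); lo <- min(dev)
  if (hi >= -lo - 1e-12) hi else lo
}

# All-windows brute-force PWM scanner on the integer score grid.
brute_scan <- function(int_scores, seq_chr, cutoff_int, both_strands = TRUE) {
  count_strand <- function(s) {
    chars <- strsplit(s, "")[[1]]
    w <- ncol(int_scores)
    n_hit <- 0L
    for (p in seq_len(nchar(s) - w + 1)) {
      win <- chars[p:(p + w - 1)]
      if (any(!win %in% c("A", "C", "G", "T"))) next
      sc <- sum(vapply(seq_len(w), function(j) {
        int_scores[match(win[j], c("A", "C", "G", "T")), j]
      }, numeric(1)))
      if (sc >= cutoff_int) n_hit <- n_hit + 1L
    }
    n_hit
  }
  n <- count_strand(seq_chr)
  if (both_strands) {
    rc <- chartr("ACGT", "TGCA", paste(rev(strsplit(seq_chr, "")[[1]]), collapse = ""))
    n <- n + count_strand(rc)
  }
  n
}

# Exact tail probability of a PWM score by enumerating every word
# (feasible for short motifs).
brute_tail <- function(int_scores, background, t_int) {
  w <- ncol(int_scores)
  words <- as.matrix(expand.grid(rep(list(1:4), w)))
  total <- 0
  for (r in seq_len(nrow(words))) {
    sc <- sum(int_scores[cbind(words[r, ], seq_len(w))])
    if (sc >= t_int) total <- total + prod(background[words[r, ]])
  }
  total
}

# Small random DNA string.
random_dna <- function(l) {
  paste(sample(c("A", "C", "G", "T"), l, replace = TRUE), collapse = "")
}

# A reduced study configuration for fast unit tests.
quick_config <- function(...) {
  sim_config(n_ogs = 300, mito_set_size = 80, control_set_size = 80,
             seed = 42, ...)
}
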