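DNA_BASES <- c("A", "C", "G", "T")

#' Read a JASPAR position frequency matrix
#'
#' Supports both the bracketed JASPAR layout (`A [ 1 2 3 ]` per base) and
#' the raw four-line layout, with a `>id name` header.
#'
#' @param path Path to a JASPAR-format PFM file.
#' @return A `pfm` object: list with `id`, `name`, and `counts`
#'   (4 x W matrix, rows A, C, G, T).
#' @export
read_jaspar <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[lines != ""]
  header <- lines[startsWith(lines, ">")][1]
  body <- lines[!startsWith(lines, ">")]
  if (length(body) < 4) stop("JASPAR file must contain four base rows")
  body <- body[1:4]
  rows <- lapply(body, function(l) {
    l <- gsub("^[ACGTacgt]\\s*", "", l)
    l <- gsub("[][]", " ", l)
    as.numeric(strsplit(trimws(l), "\\s+")[[1]])
  })
  w <- unique(lengths(rows))
  if (length(w) != 1) stop("PFM rows have unequal widths")
  counts <- do.call(rbind, rows)
  rownames(counts) <- DNA_BASES
  id <- name <- NA_character_
  if (!is.na(header)) {
    parts <- strsplit(sub("^>", "", header), "\\s+")[[1]]
    id <- parts[1]
    if (length(parts) > 1) name <- paste(parts[-1], collapse = " ")
  }
  pfm(counts, id = id, name = name)
}

#' Construct a position frequency matrix
#'
#' @param counts 4 x W non-negative matrix (rows A, C, G, T); no column
#'   may be all zero.
#' @param id,name Optional identifiers.
#' @return A `pfm` object.
#' @export
pfm <- function(counts, id = NA_character_, name = NA_character_) {
  counts <- as.matrix(counts)
  if (nrow(counts) != 4) stop("PFM must have four rows (A, C, G, T)")
  if (ncol(counts) < 1) stop("PFM must have at least one column")
  if (any(counts < 0)) stop("PFM counts must be non-negative")
  if (any(colSums(counts) == 0)) stop("PFM has an all-zero column")
  rownames(counts) <- DNA_BASES
  structure(list(id = id, name = name, counts = counts), class = "pfm")
}

#' @export
print.pfm <- function(x, ...) {
  cat("pfm", x$id, x$name, "- width", ncol(x$counts), "\n")
  invisible(x)
}

#' Log-odds position weight matrix from a PFM
#'
#' Column counts plus `pseudocount * background` are converted to
#' probabilities and scored as `log2(p / background)`.
#'
#' @param x A `pfm` object (or bare 4 x W count matrix).
#' @param pseudocount Total pseudocount added per column (default 0.1),
#'   distributed according to the background.
#' @param background Background base frequencies (A, C, G, T), summing
#'   to 1; default uniform.
#' @return A `pwm` object: list with `scores` (4 x W log2 odds),
#'   `background`, `pseudocount`.
#' @export
pfm_to_pwm <- function(x, pseudocount = 0.1, background = rep(0.25, 4)) {
  counts <- if (inherits(x, "pfm")) x$counts else as.matrix(x)
  if (abs(sum(background) - 1) > 1e-8) stop("background must sum to 1")
  if (any(background <= 0)) stop("background frequencies must be positive")
  probs <- sweep(counts + pseudocount * background, 2, colSums(counts) + pseudocount, "/")
  scores <- log2(probs / background)
  rownames(scores) <- DNA_BASES
  structure(list(scores = scores, background = background,
                 pseudocount = pseudocount,
                 id = if (inherits(x, "pfm")) x$id else NA_character_),
            class = "pwm")
}

#' Exact PWM score distribution under the background model
#'
#' Scores are rounded to an integer grid (`round(score * scale)`) and the
#' per-column score distributions are convolved under the background
#' model, giving the exact probability mass of every attainable window
#' score. This is the standard dynamic-programming route to exact
#' p-value thresholds for motif scanning.
#'
#' @param pwm A `pwm` object.
#' @param scale Integer scale for score rounding (default 1000).
#' @return A `score_distribution`: list with `probs`, `min_score`
#'   (integer score of `probs[1]`), `int_scores` (4 x W integer matrix
#'   used for scanning), and `scale`.
#' @export
score_distribution <- function(pwm, scale = 1000) {
  s <- round(pwm$scores * scale)
  bg <- pwm$background
  probs <- 1
  min_score <- 0L
  for (j in seq_len(ncol(s))) {
    cmin <- min(s[, j]); cmax <- max(s[, j])
    new_len <- length(probs) + (cmax - cmin)
    acc <- numeric(new_len)
    for (b in 1:4) {
      sh <- s[b, j] - cmin
      acc[(1 + sh):(length(probs) + sh)] <-
        acc[(1 + sh):(length(probs) + sh)] + bg[b] * probs
    }
    probs <- acc
    min_score <- min_score + cmin
  }
  structure(list(probs = probs, min_score = min_score,
                 int_scores = s, scale = scale),
            class = "score_distribution")
}

#' Tail probability of a PWM score
#'
#' `P(window score >= score)` for a random background window, from the
#' exact distribution.
#'
#' @param dist A `score_distribution`.
#' @param score Score threshold in log2-odds units (rounded onto the
#'   integer grid).
#' @return Tail probability in `[0, 1]`.
#' @export
pwm_tail_p <- function(dist, score) {
  t_int <- round(score * dist$scale)
  tail_int(dist, t_int)
}

tail_int <- function(dist, t_int) {
  idx <- t_int - dist$min_score + 1
  n <- length(dist$probs)
  vapply(idx, function(i) {
    if (i <= 1) 1 else if (i > n) 0 else sum(dist$probs[i:n])
  }, numeric(1))
}

# Smallest integer score whose exact tail probability is <= p_threshold.
score_cutoff_int <- function(dist, p_threshold) {
  tails <- rev(cumsum(rev(dist$probs)))
  ok <- which(tails <= p_threshold)
  if (length(ok) == 0) return(dist$min_score + length(dist$probs))  # unreachable
  dist$min_score + ok[1] - 1
}

seq_to_index <- function(seq) {
  codes <- utf8ToInt(toupper(seq))
  idx <- rep(5L, length(codes))
  idx[codes == 65L] <- 1L  # A
  idx[codes == 67L] <- 2L  # C
  idx[codes == 71L] <- 3L  # G
  idx[codes == 84L] <- 4L  # T
  idx
}

revcomp_chr <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

scan_strand <- function(idx, int_scores, cutoff_int) {
  if (length(idx) < ncol(int_scores)) {
    return(list(pos = integer(0), score = numeric(0)))
  }
  .window_hits(idx, int_scores, cutoff_int)
}

#' Scan a promoter sequence with a PWM at an exact p-value threshold
#'
#' Every window (on one or both strands) whose score has exact background
#' p-value at most `p_threshold` is reported. Windows containing `N` are
#' skipped; overlapping hits are all reported.
#'
#' @param pwm A `pwm` object.
#' @param dist Matching `score_distribution`.
#' @param seq Character string (or `DNAString`) over A, C, G, T, N.
#' @param p_threshold Exact p-value threshold (default 1e-4).
#' @param both_strands Scan the reverse complement too (default TRUE).
#' @param collapse Greedily drop hits overlapping an already accepted
#'   higher-scoring hit (default FALSE: overlapping hits all count).
#' @return Data frame with columns `position` (1-based start of the
#'   window on the forward strand), `strand`, `score` (log2-odds, on the
#'   rounding grid), `p_value`.
#' @export
scan_promoter <- function(pwm, dist, seq, p_threshold = 1e-4,
                          both_strands = TRUE, collapse = FALSE) {
  seq <- as.character(seq)
  w <- ncol(dist$int_scores)
  if (nchar(seq) < w) stop("sequence shorter than the motif")
  cutoff <- score_cutoff_int(dist, p_threshold)
  fwd <- scan_strand(seq_to_index(seq), dist$int_scores, cutoff)
  pos <- fwd$pos; strand <- rep("+", length(fwd$pos)); sc <- fwd$score
  if (both_strands) {
    l <- nchar(seq)
    rev <- scan_strand(seq_to_index(revcomp_chr(seq)), dist$int_scores, cutoff)
    pos <- c(pos, l - rev$pos - w + 2L)
    strand <- c(strand, rep("-", length(rev$pos)))
    sc <- c(sc, rev$score)
  }
  out <- data.frame(position = as.integer(pos), strand = strand,
                    score = sc / dist$scale,
                    p_value = tail_int(dist, sc),
                    stringsAsFactors = FALSE, row.names = NULL)
  if (collapse && nrow(out) > 1) {
    accepted <- integer(0)
    for (i in order(-out$score, out$position)) {
      if (!any(abs(out$position[accepted] - out$position[i]) < w)) {
        accepted <- c(accepted, i)
      }
    }
    out <- out[sort(accepted), , drop = FALSE]
  }
  out
}

#' Zero-order base composition of a set of sequences
#'
#' Frequencies of A, C, G, T over the pooled sequences (N and other
#' symbols ignored), for use as a scanning background model.
#'
#' @param seqs Character vector (or list) of DNA sequences.
#' @return Numeric vector of four frequencies summing to 1.
#' @export
base_composition <- function(seqs) {
  idx <- unlist(lapply(unlist(seqs, use.names = FALSE), seq_to_index))
  counts <- tabulate(idx[idx <= 4], nbins = 4)
  if (sum(counts) == 0) stop("no A/C/G/T bases in the input")
  stats::setNames(counts / sum(counts), DNA_BASES)
}

#' Extract promoter regions upstream of transcription start sites
#'
#' For forward-strand genes the promoter is the `length` bases ending
#' just before the annotated gene start; for reverse-strand genes it is
#' the reverse complement of the `length` bases following the gene end.
#' Promoters running off a contig edge are truncated and flagged; genes
#' on missing contigs (or with no upstream sequence at all) are skipped
#' and reported.
#'
#' @param genome `DNAStringSet` or path to a FASTA file.
#' @param annotation `GRanges` (with a gene identifier in `ID`,
#'   `gene_id`, or `Name`) or path to a GFF3 file; features of type
#'   `"gene"` are used when a `type` column is present.
#' @param length Promoter length in bases (default 5000).
#' @return List with `promoters` (named character vector), `info` (data
#'   frame: gene, seqname, strand, start, end, truncated), and `skipped`.
#' @export
extract_promoters <- function(genome, annotation, length = 5000) {
  if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
  names(genome) <- sub("\\s.*", "", names(genome))
  if (is.character(annotation)) annotation <- rtracklayer::import(annotation)
  meta <- S4Vectors::mcols(annotation)
  if ("type" %in% names(meta) && any(meta$type == "gene")) {
    annotation <- annotation[meta$type == "gene"]
    meta <- S4Vectors::mcols(annotation)
  }
  id_col <- intersect(c("ID", "gene_id", "Name"), names(meta))[1]
  gene_ids <- if (!is.na(id_col)) as.character(meta[[id_col]]) else
    paste0("gene", seq_along(annotation))

  proms <- character(0)
  info <- list()
  skipped <- character(0)
  for (i in seq_along(annotation)) {
    chrom <- as.character(GenomicRanges::seqnames(annotation)[i])
    if (!chrom %in% names(genome)) {
      skipped <- c(skipped, gene_ids[i]); next
    }
    clen <- length(genome[[chrom]])
    strand <- as.character(GenomicRanges::strand(annotation)[i])
    if (strand == "-") {
      tss <- GenomicRanges::end(annotation)[i]
      from <- tss + 1
      to <- min(clen, tss + length)
      truncated <- (tss + length) > clen
      if (from > to) { skipped <- c(skipped, gene_ids[i]); next }
      s <- as.character(Biostrings::reverseComplement(
        Biostrings::subseq(genome[[chrom]], from, to)))
    } else {
      tss <- GenomicRanges::start(annotation)[i]
      from <- max(1, tss - length)
      to <- tss - 1
      truncated <- (tss - length) < 1
      if (to < from) { skipped <- c(skipped, gene_ids[i]); next }
      s <- as.character(Biostrings::subseq(genome[[chrom]], from, to))
    }
    proms[gene_ids[i]] <- s
    info[[gene_ids[i]]] <- data.frame(
      gene = gene_ids[i], seqname = chrom, strand = strand,
      start = from, end = to, truncated = truncated,
      stringsAsFactors = FALSE)
  }
  list(promoters = proms,
       info = if (length(info)) do.call(rbind, c(info, make.row.names = FALSE)) else NULL,
       skipped = skipped)
}

#' Count binding sites per gene and species
#'
#' Scans each promoter of each species at the given exact-p threshold and
#' tabulates hit counts, aligning rows by the promoter names (use OG
#' identifiers for cross-species comparisons of 1-to-1 orthologs).
#'
#' @param promoter_sets Named list (by species) of named character
#'   vectors of promoter sequences.
#' @param pwm A `pwm` object.
#' @param dist Matching `score_distribution`.
#' @param p_threshold Exact p-value threshold per window.
#' @param both_strands Scan both strands (default TRUE).
#' @return Integer matrix (promoter name x species) of hit counts; names
#'   absent from a species give `NA`.
#' @export
tfbs_count_table <- function(promoter_sets, pwm, dist, p_threshold = 1e-4,
                             both_strands = TRUE) {
  all_ids <- sort(unique(unlist(lapply(promoter_sets, names))))
  out <- matrix(NA_integer_, length(all_ids), length(promoter_sets),
                dimnames = list(all_ids, names(promoter_sets)))
  cutoff <- score_cutoff_int(dist, p_threshold)
  w <- ncol(dist$int_scores)
  for (sp in names(promoter_sets)) {
    seqs <- promoter_sets[[sp]]
    comp <- c(4L, 3L, 2L, 1L, 5L)
    counts <- vapply(seqs, function(s) {
      idx <- seq_to_index(s)
      n <- length(scan_strand(idx, dist$int_scores, cutoff)$pos)
      if (both_strands) {
        n <- n + length(scan_strand(rev(comp[idx]), dist$int_scores, cutoff)$pos)
      }
      n
    }, integer(1))
    out[names(seqs), sp] <- counts
  }
  out
}

#' Per-gene binding-site count divergence
#'
#' `delta = focal count - summary(comparison counts)`; with a single
#' comparison species this is a plain difference, with several the
#' summary defaults to the median.
#'
#' @param counts Matrix from [tfbs_count_table()].
#' @param focal Focal species (column name).
#' @param comparison Character vector of comparison species.
#' @param summary Summary function over comparison counts (default
#'   [stats::median]).
#' @return Named numeric vector of per-gene deltas (`NA` dropped).
#' @export
tfbs_delta <- function(counts, focal, comparison, summary = stats::median) {
  if (!focal %in% colnames(counts)) stop("focal species not in count table")
  if (!all(comparison %in% colnames(counts))) stop("comparison species not in count table")
  cmp <- counts[, comparison, drop = FALSE]
  delta <- counts[, focal] - apply(cmp, 1, summary)
  delta[stats::complete.cases(counts[, c(focal, comparison), drop = FALSE])]
}

#' Association between extra binding sites and upregulation
#'
#' Tests, by one-sided Fisher exact test, whether genes with at least `k`
#' extra binding sites in the focal species (`delta >= k`) are more often
#' upregulated (`logFC > 0` and `p <= p_cut`) than not differentially
#' expressed. Significantly downregulated genes are excluded from the
#' table.
#'
#' @param delta Named vector from [tfbs_delta()] (names matching the DE
#'   table's `og` column).
#' @param de DE table with columns `og`, `logFC`, `p_value`.
#' @param k Minimum number of extra sites defining the exposed class.
#' @param p_cut Significance cutoff defining differential expression
#'   (default 0.05).
#' @param alternative Sidedness of the Fisher test.
#' @return List with `table`, `p_value`, `odds_ratio`.
#' @export
tfbs_expression_association <- function(delta, de, k = 1, p_cut = 0.05,
                                        alternative = "greater") {
  shared <- intersect(names(delta), de$og)
  if (length(shared) == 0) stop("no shared genes between delta and DE table")
  d <- delta[shared]
  sub <- de[match(shared, de$og), , drop = FALSE]
  up <- sub$logFC > 0 & sub$p_value <= p_cut
  down <- sub$logFC < 0 & sub$p_value <= p_cut
  keep <- !down & !is.na(sub$p_value)
  d <- d[keep]; up <- up[keep]
  exposed <- d >= k
  if (!any(exposed)) stop("empty exposure class: no gene with delta >= ", k)
  tab <- matrix(c(sum(exposed & up), sum(exposed & !up),
                  sum(!exposed & up), sum(!exposed & !up)),
                nrow = 2, byrow = TRUE,
                dimnames = list(c("extra_sites", "no_extra"),
                                c("up", "not_de")))
  ft <- fisher_exact_2x2(tab, alternative)
  list(table = tab, p_value = ft$p_value, odds_ratio = ft$odds_ratio)
}
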