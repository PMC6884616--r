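#' Construct an orthology table
#'
#' An orthology table maps ortholog-group (OG) identifiers to the member
#' genes of each species. It is the backbone joining copy-number,
#' expression, and promoter analyses: gene identifiers must be globally
#' unique (no gene may belong to two OGs).
#'
#' @param og_ids Character vector of unique OG identifiers.
#' @param genes Named list, one element per species; each element is a list
#'   (parallel to `og_ids`) of character vectors of member genes, possibly
#'   empty.
#' @return An object of class `orthology_table`.
#' @export
orthology_table <- function(og_ids, genes) {
  og_ids <- as.character(og_ids)
  if (anyDuplicated(og_ids)) stop("OG identifiers must be unique")
  if (is.null(names(genes)) || any(names(genes) == "")) {
    stop("'genes' must be a named list (one element per species)")
  }
  genes <- lapply(genes, function(sp) {
    if (length(sp) != length(og_ids)) {
      stop("each species entry must have one gene list per OG")
    }
    lapply(unname(sp), as.character)
  })
  all_genes <- unlist(genes, use.names = FALSE)
  dup <- all_genes[duplicated(all_genes)]
  if (length(dup) > 0) {
    stop("gene(s) assigned to more than one OG: ",
         paste(utils::head(unique(dup), 5), collapse = ", "))
  }
  structure(list(og_ids = og_ids, genes = genes), class = "orthology_table")
}

#' @export
print.orthology_table <- function(x, ...) {
  cat("orthology_table:", length(x$og_ids), "OGs x",
      length(x$genes), "species (",
      paste(names(x$genes), collapse = ", "), ")\n")
  invisible(x)
}

#' Species names of an orthology table
#' @param table An `orthology_table`.
#' @export
og_species <- function(table) names(table$genes)

#' Gene-to-OG lookup
#'
#' @param table An `orthology_table`.
#' @param species Optional character vector restricting to some species.
#' @return Named character vector mapping gene id to OG id.
#' @export
gene_og_map <- function(table, species = NULL) {
  sp <- if (is.null(species)) og_species(table) else species
  missing_sp <- setdiff(sp, og_species(table))
  if (length(missing_sp) > 0) {
    stop("species not in orthology table: ", paste(missing_sp, collapse = ", "))
  }
  maps <- lapply(sp, function(s) {
    lens <- lengths(table$genes[[s]])
    stats::setNames(rep(table$og_ids, lens),
                    unlist(table$genes[[s]], use.names = FALSE))
  })
  do.call(c, maps)
}

#' Read an orthology table from TSV
#'
#' Expects a long-format tab-separated file with a header and columns
#' `og`, `species`, `genes`, where `genes` is a comma-separated list of
#' gene identifiers (empty for species absent from the OG).
#'
#' @param path Path to the TSV file.
#' @return An `orthology_table`.
#' @export
read_orthology <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", quote = "")
  need <- c("og", "species", "genes")
  if (!all(need %in% names(df))) {
    stop("orthology TSV must have columns: ", paste(need, collapse = ", "))
  }
  og_ids <- unique(df$og)
  species <- unique(df$species)
  genes <- lapply(species, function(s) {
    rows <- df[df$species == s, , drop = FALSE]
    per_og <- stats::setNames(rows$genes, rows$og)[og_ids]
    lapply(per_og, function(g) {
      if (is.na(g) || g == "") character(0) else strsplit(g, ",", fixed = TRUE)[[1]]
    })
  })
  names(genes) <- species
  orthology_table(og_ids, genes)
}

#' Write an orthology table to TSV
#'
#' @param table An `orthology_table`.
#' @param path Output path.
#' @export
write_orthology <- function(table, path) {
  rows <- do.call(rbind, lapply(og_species(table), function(s) {
    data.frame(og = table$og_ids,
               species = s,
               genes = vapply(table$genes[[s]], paste, "", collapse = ","),
               stringsAsFactors = FALSE)
  }))
  rows <- rows[order(match(rows$og, table$og_ids)), ]
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Filter orthology members by protein alignment coverage
#'
#' Fragmented genome assemblies inflate copy numbers because partial gene
#' models are counted as extra copies. The standard correction retains only
#' proteins whose alignment covers at least a minimum fraction (default
#' 60%) of the reference-species ortholog. Genes without a coverage record
#' are treated as unalignable and removed, with a warning.
#'
#' @param table An `orthology_table`.
#' @param coverage Data frame with columns `gene` and `coverage`
#'   (fractions in `[0, 1]`), or a named numeric vector.
#' @param min_cov Minimum retained coverage, in `(0, 1]`. Genes with
#'   coverage exactly `min_cov` are retained ("at least").
#' @return List with `table` (filtered; OGs empty in every species are
#'   dropped) and `removed` (data frame of removed genes and reasons).
#' @export
apply_coverage_filter <- function(table, coverage, min_cov = 0.60) {
  if (!is.numeric(min_cov) || length(min_cov) != 1 ||
      min_cov <= 0 || min_cov > 1) {
    stop("'min_cov' must lie in (0, 1]")
  }
  if (is.data.frame(coverage)) {
    if (!all(c("gene", "coverage") %in% names(coverage))) {
      stop("'coverage' needs columns 'gene' and 'coverage'")
    }
    cov <- stats::setNames(coverage$coverage, coverage$gene)
  } else {
    cov <- coverage
  }
  if (anyDuplicated(names(cov))) stop("duplicate genes in coverage table")
  if (any(cov < 0 | cov > 1)) stop("coverage values must lie in [0, 1]")

  removed_gene <- character(0)
  removed_reason <- character(0)
  genes <- lapply(table$genes, function(sp) {
    lapply(sp, function(g) {
      if (length(g) == 0) return(g)
      known <- g %in% names(cov)
      keep <- known & (cov[g] >= min_cov)
      keep[is.na(keep)] <- FALSE
      if (any(!keep)) {
        removed_gene <<- c(removed_gene, g[!keep])
        removed_reason <<- c(removed_reason,
                             ifelse(known[!keep], "low_coverage", "no_record"))
      }
      g[keep]
    })
  })
  if (any(removed_reason == "no_record")) {
    warning(sum(removed_reason == "no_record"),
            " gene(s) without coverage record removed as unalignable")
  }
  keep_og <- Reduce(`+`, lapply(genes, lengths)) > 0
  filtered <- orthology_table(table$og_ids[keep_og],
                              lapply(genes, function(sp) sp[keep_og]))
  list(table = filtered,
       removed = data.frame(gene = removed_gene, reason = removed_reason,
                            stringsAsFactors = FALSE),
       dropped_ogs = table$og_ids[!keep_og])
}

#' Gene copy-number matrix
#'
#' @param table An `orthology_table`.
#' @return Integer matrix OG x species of member-gene counts.
#' @export
copy_number_matrix <- function(table) {
  m <- vapply(table$genes, lengths, integer(length(table$og_ids)))
  if (length(table$og_ids) == 1L) m <- matrix(m, nrow = 1,
                                              dimnames = list(NULL, og_species(table)))
  rownames(m) <- table$og_ids
  m
}

#' Mean copy-number difference between species groups
#'
#' For each OG, the mean copy difference is
#' `mean(copies over group A) - mean(copies over group B)`. Species of a
#' group absent from an OG contribute zero copies, so the mean is always
#' over all group members. The statistic is antisymmetric under swapping
#' the two groups.
#'
#' @param copies Copy-number matrix from [copy_number_matrix()].
#' @param group_a,group_b Disjoint, non-empty character vectors of species
#'   (columns of `copies`).
#' @return Named numeric vector of per-OG mean differences, with the group
#'   definitions attached as attributes.
#' @export
mean_delta <- function(copies, group_a, group_b) {
  if (length(group_a) == 0 || length(group_b) == 0) {
    stop("both groups must be non-empty")
  }
  if (length(intersect(group_a, group_b)) > 0) {
    stop("groups must be disjoint")
  }
  missing_sp <- setdiff(c(group_a, group_b), colnames(copies))
  if (length(missing_sp) > 0) {
    stop("species not in copy matrix: ", paste(missing_sp, collapse = ", "))
  }
  md <- rowMeans(copies[, group_a, drop = FALSE]) -
    rowMeans(copies[, group_b, drop = FALSE])
  attr(md, "group_a") <- group_a
  attr(md, "group_b") <- group_b
  md
}

#' Classify OGs by copy-number divergence
#'
#' OGs with mean copy difference at or above `dup_threshold` (default 1,
#' i.e. at least one extra average copy in the focal group) are classified
#' `duplicated`; those at or below `bg_threshold` (default 0) are
#' `background`; the remainder are `intermediate` and are conventionally
#' excluded from two-class association tests.
#'
#' @param md Mean-difference vector from [mean_delta()].
#' @param dup_threshold,bg_threshold Numeric thresholds,
#'   `dup_threshold > bg_threshold`.
#' @return Data frame with columns `og`, `m_delta`, `class`, plus the
#'   thresholds as attributes.
#' @export
classify_duplication <- function(md, dup_threshold = 1, bg_threshold = 0) {
  if (dup_threshold <= bg_threshold) {
    stop("'dup_threshold' must exceed 'bg_threshold'")
  }
  cls <- ifelse(md >= dup_threshold, "duplicated",
                ifelse(md <= bg_threshold, "background", "intermediate"))
  out <- data.frame(og = names(md), m_delta = as.numeric(md), class = cls,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "dup_threshold") <- dup_threshold
  attr(out, "bg_threshold") <- bg_threshold
  out
}
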