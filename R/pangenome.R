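#' Pan-genome matrix, core genomes and shared-core Venn regions
#'
#' @name pangenome
NULL

#' Build the binary presence/absence matrix
#'
#' @param clusters a `gene_cluster_set`.
#' @param genomes character vector of genome ids (row order), or a list
#'   of `phage_genome` objects.
#' @return binary matrix (genomes x clusters) with cluster ids as
#'   column names; attribute `provenance` holds the cluster set.
#' @export
build_matrix <- function(clusters, genomes) {
  if (is.list(genomes) && !is.character(genomes)) {
    genomes <- vapply(genomes, `[[`, "", "id")
  }
  cl <- clusters$clusters
  mat <- matrix(0L, nrow = length(genomes), ncol = length(cl),
                dimnames = list(genomes, names(cl)))
  for (cid in names(cl)) {
    mat[unique(cl[[cid]]$genome), cid] <- 1L
  }
  pv_assert(all(colSums(mat) >= 1) || ncol(mat) == 0,
            "cluster with no member genome")
  attr(mat, "provenance") <- clusters
  mat
}

#' Core genome of a genome subset
#'
#' @param matrix presence/absence matrix from [build_matrix()].
#' @param subset non-empty character vector of genome ids.
#' @return character vector of cluster ids present in every genome of
#'   the subset.
#' @export
core_genome <- function(matrix, subset) {
  pv_assert(length(subset) > 0, "core_genome: empty subset")
  unknown <- setdiff(subset, rownames(matrix))
  pv_assert(length(unknown) == 0,
            sprintf("unknown genome id(s): %s",
                    paste(unknown, collapse = ", ")),
            "panvirome_validation_error")
  if (ncol(matrix) == 0) return(character())
  sub <- matrix[subset, , drop = FALSE]
  colnames(matrix)[colSums(sub) == length(subset)]
}

#' Shared-core Venn region counts
#'
#' For each non-empty combination of groups, counts clusters that are
#' core in every group of the combination and in none of the excluded
#' groups (standard exclusive Venn regions).
#'
#' @param matrix presence/absence matrix.
#' @param groups named list: group label -> genome ids (>= 2 groups).
#' @return named integer vector; names like "A", "A&B", sorted by
#'   region size (number of groups, then name).
#' @export
shared_core_venn <- function(matrix, groups) {
  pv_assert(is.list(groups) && length(groups) >= 2,
            "shared_core_venn needs >= 2 groups")
  cores <- lapply(groups, function(g) core_genome(matrix, g))
  labs <- names(groups)
  out <- integer(0)
  for (k in seq_along(labs)) {
    for (combo in utils::combn(labs, k, simplify = FALSE)) {
      inside <- Reduce(intersect, cores[combo])
      for (ex in setdiff(labs, combo)) inside <- setdiff(inside, cores[[ex]])
      out[paste(combo, collapse = "&")] <- length(inside)
    }
  }
  out
}

#' Functional-category histogram for a cluster set
#'
#' Categories follow the fixed label set A (transcription),
#' B (translation), C (nucleotide metabolism), D (DNA replication,
#' recombination, repair, packaging, processing), E (virion proteins),
#' F (chaperonins/assembly catalysts) and L (others). Clusters absent
#' from the map are counted as L.
#'
#' @param cluster_ids character vector of cluster ids.
#' @param category_map named character vector cluster id -> category.
#' @return data.frame (category, count, fraction); empty input gives a
#'   zero-row frame.
#' @export
categorize_core <- function(cluster_ids, category_map) {
  valid <- c("A", "B", "C", "D", "E", "F", "L")
  if (length(cluster_ids) == 0) {
    return(data.frame(category = character(), count = integer(),
                      fraction = numeric(), stringsAsFactors = FALSE))
  }
  cats <- category_map[cluster_ids]
  cats[is.na(cats)] <- "L"
  pv_assert(all(cats %in% valid),
            sprintf("invalid categories: %s",
                    paste(setdiff(unique(cats), valid), collapse = ", ")))
  tab <- table(factor(cats, levels = valid))
  tab <- tab[tab > 0]
  data.frame(category = names(tab), count = as.integer(tab),
             fraction = as.numeric(tab) / length(cluster_ids),
             stringsAsFactors = FALSE)
}

#' Write / read a presence-absence matrix as TSV
#' @param matrix binary matrix.
#' @param path output TSV path (genomes in rows).
#' @return invisibly `path`.
#' @export
write_pan_matrix <- function(matrix, path) {
  df <- data.frame(genome_id = rownames(matrix), matrix,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pan_matrix
#' @export
read_pan_matrix <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$genome_id
  storage.mode(m) <- "integer"
  m
}
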