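#' Spot-test host-range encoding and lysotyping
#'
#' Host-range matrices record, for each phage x isolate pair, the
#' highest ten-fold dilution showing lysis in a spot test (exponent
#' 0..7, or none). Scores are exponent + 1 (0 = no lysis), so scores
#' run 0..8; "high" lytic activity means lysis at a dilution of at
#' least 1e-4 (score >= 5). Breadth thresholds mirror the three
#' observed lysotype bands on a 65-isolate panel — narrow < 5,
#' intermediate 10..30, broad > 44 — and scale proportionally for other
#' panel sizes; the gaps map to "unclassified".
#'
#' @name host_range
NULL

#' Build a host-range matrix from raw dilution exponents
#'
#' @param raw matrix or data.frame (phages in rows, isolates in
#'   columns) whose entries are exponents 0..7 or "none"/NA, or a path
#'   to such a TSV (first column = phage id).
#' @param isolate_meta data.frame with columns isolate_id, lifestyle
#'   ("psychrophilic"/"mesophilic"), subspecies; or a TSV path.
#' @param high_score minimum score counted as high activity (default 5).
#' @return object of class `host_range_matrix`: list with `scores`
#'   (integer matrix 0..8), `raw_exponent`, `sensitive` (logical),
#'   `high` (logical), `isolates` metadata.
#' @export
encode_matrix <- function(raw, isolate_meta = NULL, high_score = 5L) {
  if (is.character(raw) && length(raw) == 1 && !is.matrix(raw)) {
    df <- read.delim(raw, check.names = FALSE, stringsAsFactors = FALSE)
    rownames(df) <- df[[1]]
    raw <- as.matrix(df[, -1, drop = FALSE])
  }
  raw <- as.matrix(raw)
  exps <- suppressWarnings(matrix(as.numeric(ifelse(raw %in% c("none", ""),
                                                    NA, raw)),
                                  nrow = nrow(raw), dimnames = dimnames(raw)))
  bad <- !is.na(exps) & (exps < 0 | exps > 7 | exps != floor(exps))
  pv_assert(!any(bad), "dilution exponents must be integers in 0..7 or none",
            "panvirome_validation_error")
  scores <- ifelse(is.na(exps), 0L, as.integer(exps) + 1L)
  dimnames(scores) <- dimnames(raw)
  if (is.character(isolate_meta) && length(isolate_meta) == 1) {
    isolate_meta <- read.delim(isolate_meta, stringsAsFactors = FALSE)
  }
  if (!is.null(isolate_meta)) {
    pv_assert(all(c("isolate_id", "lifestyle") %in% names(isolate_meta)),
              "isolate metadata needs isolate_id and lifestyle")
    pv_assert(all(colnames(scores) %in% isolate_meta$isolate_id),
              "isolates missing from metadata")
    isolate_meta <- isolate_meta[match(colnames(scores),
                                       isolate_meta$isolate_id), ]
    pv_assert(all(isolate_meta$lifestyle %in%
                    c("psychrophilic", "mesophilic")),
              "lifestyle must be psychrophilic or mesophilic")
  }
  structure(list(scores = scores, raw_exponent = exps,
                 sensitive = scores > 0, high = scores >= high_score,
                 isolates = isolate_meta),
            class = "host_range_matrix")
}

#' Decode a host-range matrix back to raw exponents
#' @param m a `host_range_matrix`.
#' @return matrix of exponents with NA for no lysis (round-trip of
#'   [encode_matrix()]).
#' @export
decode_matrix <- function(m) {
  out <- m$scores - 1L
  out[m$scores == 0L] <- NA_integer_
  out
}

#' Host-range breadth of a phage
#' @param m a `host_range_matrix`.
#' @param phage phage id.
#' @return number of sensitive isolates (score > 0).
#' @export
breadth <- function(m, phage) {
  pv_assert(phage %in% rownames(m$scores),
            sprintf("unknown phage: %s", phage))
  sum(m$sensitive[phage, ])
}

#' Lysotype breadth group
#'
#' @param breadth number of sensitive isolates.
#' @param n_isolates panel size; thresholds scale proportionally from
#'   the reference 65-isolate panel.
#' @return "narrow", "intermediate", "broad" or "unclassified".
#' @export
assign_lysotype_group <- function(breadth, n_isolates = 65) {
  pv_assert(breadth >= 0 && breadth <= n_isolates,
            "breadth must lie in [0, n_isolates]")
  f <- n_isolates / 65
  if (breadth < 5 * f) "narrow"
  else if (breadth >= 10 * f && breadth <= 30 * f) "intermediate"
  else if (breadth > 44 * f) "broad"
  else "unclassified"
}

#' Cluster phages and isolates for heatmap rendering
#'
#' Both axes are clustered on binary sensitivity with the package's
#' binary distance and average linkage.
#'
#' @param m a `host_range_matrix` (>= 2 phages and >= 2 isolates).
#' @return list (phage_hclust, isolate_hclust, ordered) where `ordered`
#'   is the score matrix in dendrogram order.
#' @export
cluster_heatmap <- function(m) {
  pv_assert(nrow(m$scores) >= 2 && ncol(m$scores) >= 2,
            "cluster_heatmap needs >= 2 phages and >= 2 isolates",
            "panvirome_validation_error")
  sens <- m$sensitive * 1L
  ph <- pan_hclust(suppressWarnings(binary_distance(sens)), "average")
  ih <- pan_hclust(suppressWarnings(binary_distance(t(sens))), "average")
  list(phage_hclust = ph, isolate_hclust = ih,
       ordered = m$scores[ph$order, ih$order, drop = FALSE])
}

#' Phage pairs jointly covering a target isolate set
#'
#' @param m a `host_range_matrix`.
#' @param targets non-empty isolate ids to cover.
#' @return data.frame (phage_a, phage_b, breadth_sum) of all pairs
#'   whose combined sensitivity covers every target, ranked by
#'   decreasing summed breadth; zero rows when no pair covers (e.g. an
#'   isolate resistant to everything).
#' @export
covering_pairs <- function(m, targets) {
  pv_assert(length(targets) > 0, "covering_pairs: empty target set")
  pv_assert(all(targets %in% colnames(m$scores)), "unknown target isolate")
  phages <- rownames(m$scores)
  out <- list()
  for (pair in utils::combn(phages, 2, simplify = FALSE)) {
    covered <- m$sensitive[pair[1], targets] | m$sensitive[pair[2], targets]
    if (all(covered)) {
      out[[length(out) + 1]] <- data.frame(
        phage_a = pair[1], phage_b = pair[2],
        breadth_sum = breadth(m, pair[1]) + breadth(m, pair[2]),
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0) {
    return(data.frame(phage_a = character(), phage_b = character(),
                      breadth_sum = integer(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res[order(-res$breadth_sum, res$phage_a, res$phage_b), , drop = FALSE]
}

#' Lifestyle split of sensitivity with Fisher exact test
#'
#' Summarizes the fraction of sensitive (phage, isolate) cells per
#' lifestyle, tests the collapsed 2x2 table (lifestyle x
#' any-phage-sensitivity per isolate) with Fisher's exact test, and
#' lists every sensitive mesophilic cell explicitly (the exceptions).
#'
#' @param m a `host_range_matrix` with isolate metadata carrying both
#'   lifestyles.
#' @return list (summary data.frame, fisher_p, table, exceptions
#'   data.frame of phage/isolate/score).
#' @export
lifestyle_split <- function(m) {
  pv_assert(!is.null(m$isolates), "no isolate metadata")
  life <- m$isolates$lifestyle
  pv_assert(length(unique(life)) == 2, "need both lifestyles present")
  sens_frac <- vapply(split(seq_len(ncol(m$scores)), life), function(cols) {
    mean(m$sensitive[, cols])
  }, 0)
  any_sens <- colSums(m$sensitive) > 0
  tab <- table(lifestyle = life, sensitive = factor(any_sens,
                                                    levels = c(FALSE, TRUE)))
  ft <- fisher.test(tab)
  meso <- which(life == "mesophilic")
  exc <- which(m$sensitive[, meso, drop = FALSE], arr.ind = TRUE)
  exceptions <- data.frame(
    phage = rownames(m$scores)[exc[, 1]],
    isolate = colnames(m$scores)[meso][exc[, 2]],
    score = m$scores[cbind(exc[, 1], meso[exc[, 2]])],
    stringsAsFactors = FALSE)
  list(summary = data.frame(lifestyle = names(sens_frac),
                            fraction_sensitive = unname(sens_frac)),
       fisher_p = ft$p.value, table = tab, exceptions = exceptions)
}
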