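#' Codon usage, amino-acid composition and GC-class structure
#'
#' Relative synonymous codon usage (RSCU) is computed on the
#' concatenated CDSs of a genome: for codon c in a synonymous family of
#' size k, RSCU_c = observed_c * k / sum(observed over the family).
#' Single-codon families (ATG/Met, TGG/Trp) and stop codons are
#' excluded, leaving 59 informative components. PCA is run on the
#' covariance of the column-centered profiles (components share a
#' scale, so no rescaling).
#'
#' @name codon_usage
NULL

pv_codon_families <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      code <- pv_genetic_code()
      code <- code[code != "*"]
      fam <- split(names(code), code)
      fam <- fam[vapply(fam, length, 0L) > 1] # drop Met, Trp
      cache <<- fam
    }
    cache
  }
})

pv_count_codons <- function(cds_nt) {
  counts <- setNames(integer(64), names(pv_genetic_code()))
  for (nt in cds_nt) {
    nt <- toupper(nt)
    n <- nchar(nt) %/% 3L
    if (n == 0) next
    codons <- substring(nt, 3L * seq_len(n) - 2L, 3L * seq_len(n))
    codons <- codons[codons %in% names(counts)] # skip ambiguous
    tab <- table(codons)
    counts[names(tab)] <- counts[names(tab)] + as.integer(tab)
  }
  counts
}

#' Relative synonymous codon usage of a CDS set
#'
#' @param cds_nt character vector of CDS nucleotide sequences (lengths
#'   divisible by 3; trailing incomplete codons and ambiguous codons
#'   are skipped).
#' @return named 59-component numeric vector of RSCU values; families
#'   with zero observations are all-zero and listed in the
#'   `empty_families` attribute.
#' @export
rscu <- function(cds_nt) {
  counts <- pv_count_codons(cds_nt)
  pv_assert(sum(counts) > 0, "rscu: no valid codons")
  fams <- pv_codon_families()
  out <- numeric(0)
  empty <- character(0)
  for (aa in names(fams)) {
    codons <- sort(fams[[aa]])
    tot <- sum(counts[codons])
    k <- length(codons)
    vals <- if (tot > 0) counts[codons] * k / tot else {
      empty <- c(empty, aa)
      rep(0, k)
    }
    out[codons] <- vals
  }
  # drop stop codons is implicit (families exclude them)
  structure(out, empty_families = empty)
}

#' Amino-acid composition of a CDS set
#'
#' @param cds_aa character vector of protein sequences.
#' @return named 20-component fraction vector summing to 1.
#' @export
aa_composition <- function(cds_aa) {
  aas <- strsplit(paste(cds_aa, collapse = ""), "", fixed = TRUE)[[1]]
  std <- sort(unique(unname(pv_genetic_code()[pv_genetic_code() != "*"])))
  aas <- aas[aas %in% std]
  pv_assert(length(aas) > 0, "aa_composition: no standard residues")
  tab <- table(factor(aas, levels = std))
  as.numeric(tab) / length(aas) -> fr
  setNames(fr, std)
}

#' Codon profile of a genome
#'
#' @param genome a `phage_genome`.
#' @return list (class `codon_profile`): genome_id, rscu, aa_comp,
#'   gc_percent, has_trna.
#' @export
codon_profile <- function(genome) {
  structure(list(genome_id = genome$id, rscu = rscu(genome$cds$nt_seq),
                 aa_comp = aa_composition(genome$cds$aa_seq),
                 gc_percent = genome$gc_percent,
                 has_trna = genome$trna_count > 0),
            class = "codon_profile")
}

#' PCA of codon profiles
#'
#' Column-centered, unscaled eigendecomposition of the covariance
#' matrix. Scores are ordered by decreasing eigenvalue; each
#' component's sign is fixed so that its largest-magnitude loading is
#' positive.
#'
#' @param profiles list of `codon_profile` objects (>= 3).
#' @param on "rscu" or "aa_comp".
#' @return list with `scores` (genomes x components), `loadings`,
#'   `explained` (fraction of variance per component).
#' @export
codon_pca <- function(profiles, on = c("rscu", "aa_comp")) {
  on <- match.arg(on)
  pv_assert(length(profiles) >= 3, "codon_pca needs >= 3 profiles")
  X <- do.call(rbind, lapply(profiles, function(p) as.numeric(p[[on]])))
  rownames(X) <- vapply(profiles, `[[`, "", "genome_id")
  colnames(X) <- names(profiles[[1]][[on]])
  Xc <- scale(X, center = TRUE, scale = FALSE)
  pv_assert(sum(Xc^2) > 1e-12, "codon_pca: zero total variance")
  sv <- svd(Xc)
  pos <- sv$d > 1e-10
  pv_assert(any(pos), "codon_pca: zero total variance")
  scores <- sv$u[, pos, drop = FALSE] %*% diag(sv$d[pos], sum(pos))
  loadings <- sv$v[, pos, drop = FALSE]
  for (k in seq_len(ncol(loadings))) {
    if (loadings[which.max(abs(loadings[, k])), k] < 0) {
      loadings[, k] <- -loadings[, k]
      scores[, k] <- -scores[, k]
    }
  }
  dimnames(scores) <- list(rownames(X), paste0("PC", seq_len(ncol(scores))))
  dimnames(loadings) <- list(colnames(X), colnames(scores))
  ev <- sv$d[pos]^2
  list(scores = scores, loadings = loadings, explained = ev / sum(ev))
}

#' tRNA presence vs GC% association
#'
#' Point-biserial correlation between the tRNA-presence indicator and
#' GC%, plus a perfect-separation check: TRUE iff the GC ranges of
#' tRNA-bearing and tRNA-free genomes do not overlap.
#'
#' @param cohort cohort data.frame with `trna_count` and `gc_percent`.
#' @return list (r, perfect_separation, threshold, one_class).
#' @export
trna_gc_association <- function(cohort) {
  pv_assert(nrow(cohort) >= 2, "need >= 2 genomes")
  has <- cohort$trna_count > 0
  gc <- cohort$gc_percent
  if (all(has) || all(!has)) {
    return(list(r = NA_real_, perfect_separation = TRUE,
                threshold = NA_real_, one_class = TRUE))
  }
  r <- stats::cor(as.numeric(has), gc)
  hi <- gc[has]; lo <- gc[!has]
  sep <- max(hi) < min(lo) || max(lo) < min(hi)
  thr <- if (max(hi) < min(lo)) (max(hi) + min(lo)) / 2
  else if (max(lo) < min(hi)) (max(lo) + min(hi)) / 2
  else NA_real_
  list(r = r, perfect_separation = sep, threshold = thr, one_class = FALSE)
}

#' Flag PCA outliers within GC classes
#'
#' Robust z-scores (median/MAD) on PC1 and PC2 within each GC class
#' (low/high split at 50%); |z| > 3 flags a genome. When the MAD is 0
#' with distinct values present, any point off the class median is
#' flagged (degenerate-scale fallback).
#'
#' @param profiles list of `codon_profile` (provides GC class).
#' @param scores score matrix from [codon_pca()].
#' @param z_cut robust z threshold (default 3).
#' @return character vector of flagged genome ids.
#' @export
flag_outlier <- function(profiles, scores, z_cut = 3) {
  gc <- vapply(profiles, `[[`, 0, "gc_percent")
  ids <- vapply(profiles, `[[`, "", "genome_id")
  cls <- ifelse(gc >= 50, "high", "low")
  flagged <- character(0)
  for (cl in unique(cls)) {
    in_cl <- ids[cls == cl]
    if (length(in_cl) < 2) next
    for (pc in seq_len(min(2, ncol(scores)))) {
      x <- scores[in_cl, pc]
      med <- median(x); s <- mad(x)
      if (s > 1e-12) {
        flagged <- c(flagged, in_cl[abs(x - med) / s > z_cut])
      } else {
        rng <- diff(range(x))
        if (rng > 1e-12) {
          flagged <- c(flagged, in_cl[abs(x - med) > 1e-8 * max(1, abs(med))])
        }
      }
    }
  }
  sort(unique(flagged))
}
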