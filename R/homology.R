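#' Protein homology search and orthology clustering
#'
#' BLASTP-free orthology engine for small phage cohorts: exact
#' Smith-Waterman (BLOSUM62, affine gaps 11/1) all-vs-all comparison,
#' bidirectional best hits, COG-triangle and Markov (MCL) clustering,
#' their strict intersection, and a BLAST-score identity matrix.
#' An e-value surrogate is computed from the Karlin-Altschul formula
#' with the published gapped BLOSUM62-11-1 parameters
#' (lambda = 0.267, K = 0.041).
#'
#' @name homology
NULL

pv_blosum62 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      m <- e$BLOSUM62
      m["X", ] <- 0; m[, "X"] <- 0 # X scored 0 by contract
      cache <<- m
    }
    cache
  }
})

pv_encode_aa <- function(seq, alphabet) {
  pv_assert(is.character(seq) && length(seq) == 1 && nzchar(seq),
            "empty protein sequence")
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  idx <- match(chars, alphabet)
  pv_assert(!anyNA(idx),
            sprintf("unknown amino-acid letter(s): %s",
                    paste(unique(chars[is.na(idx)]), collapse = "")))
  idx - 1L
}

pv_self_score <- function(seq, sub, alphabet) {
  idx <- pv_encode_aa(seq, alphabet) + 1L
  sum(sub[cbind(idx, idx)])
}

#' Align two protein sequences (local, Smith-Waterman)
#'
#' @param a,b protein strings (20-letter alphabet; X allowed, scored 0).
#' @param gap_open,gap_ext affine gap penalties; a gap of length k costs
#'   `gap_open + k * gap_ext`.
#' @return list with score, identity (matches / aligned columns),
#'   coverage_q, coverage_s (aligned span / sequence length), matches,
#'   aligned_cols, and an `evalue_like` Karlin-Altschul surrogate.
#' @export
align_pair <- function(a, b, gap_open = 11, gap_ext = 1) {
  sub <- pv_blosum62()
  alphabet <- rownames(sub)
  r <- cpp_sw_align(pv_encode_aa(a, alphabet), pv_encode_aa(b, alphabet),
                    sub, gap_open, gap_ext)
  r$evalue_like <- pv_evalue(r$score, nchar(a), nchar(b))
  r
}

# Karlin-Altschul E = K m n exp(-lambda S), gapped BLOSUM62 11/1 constants
pv_evalue <- function(score, m, n, lambda = 0.267, K = 0.041) {
  K * m * n * exp(-lambda * score)
}

#' All-vs-all proteome comparison
#'
#' Smith-Waterman comparison of every protein against every protein of
#' every other genome. Hits are reported when both coverages reach
#' `min_cov` and the Karlin-Altschul e-value surrogate is at most
#' `max_evalue`. Self-hits are excluded from the hit table but self
#' scores are retained for normalization.
#'
#' @param genomes named list of [phage_genome()] objects (>= 2), or any
#'   list with `id` and a `cds` data.frame carrying `locus_id`/`aa_seq`.
#' @param min_cov coverage threshold applied to both sequences
#'   (GET_HOMOLOGUES default 0.75).
#' @param max_evalue e-value surrogate cutoff (default 1e-5).
#' @param gap_open,gap_ext affine gap penalties.
#' @return object of class `pv_hits`: list with `hits` (data.frame
#'   query_genome, query, subject_genome, subject, score, identity,
#'   coverage_q, coverage_s, evalue_like), `self_scores` (named vector
#'   keyed "genome:locus"), and `loci` (universe data.frame).
#' @export
all_vs_all <- function(genomes, min_cov = 0.75, max_evalue = 1e-5,
                       gap_open = 11, gap_ext = 1) {
  pv_assert(length(genomes) >= 2, "all_vs_all needs >= 2 genomes")
  sub <- pv_blosum62()
  alphabet <- rownames(sub)
  prot <- lapply(genomes, function(g) {
    seqs <- g$cds$aa_seq
    names(seqs) <- g$cds$locus_id
    seqs
  })
  names(prot) <- vapply(genomes, `[[`, "", "id")
  enc <- lapply(prot, function(p) lapply(p, pv_encode_aa, alphabet = alphabet))
  lens <- lapply(prot, nchar)
  self <- unlist(lapply(names(prot), function(g) {
    s <- vapply(prot[[g]], pv_self_score, 0, sub = sub, alphabet = alphabet)
    names(s) <- paste0(g, ":", names(prot[[g]]))
    s
  }))
  gids <- names(prot)
  rows <- list()
  for (i in seq_along(gids)) {
    for (j in seq_along(gids)) {
      if (i == j) next
      gi <- gids[i]; gj <- gids[j]
      if (length(enc[[gi]]) == 0 || length(enc[[gj]]) == 0) next
      batch <- cpp_sw_batch(unname(enc[[gi]]), unname(enc[[gj]]), sub,
                            gap_open, gap_ext)
      sc <- batch$score
      ev <- pv_evalue(sc, outer(lens[[gi]], rep(1, length(lens[[gj]]))),
                      outer(rep(1, length(lens[[gi]])), lens[[gj]]))
      keep <- which(batch$coverage_q >= min_cov &
                      batch$coverage_s >= min_cov & ev <= max_evalue,
                    arr.ind = TRUE)
      if (nrow(keep) == 0) next
      rows[[length(rows) + 1]] <- data.frame(
        query_genome = gi, query = names(prot[[gi]])[keep[, 1]],
        subject_genome = gj, subject = names(prot[[gj]])[keep[, 2]],
        score = sc[keep], identity = batch$identity[keep],
        coverage_q = batch$coverage_q[keep],
        coverage_s = batch$coverage_s[keep],
        evalue_like = ev[keep], stringsAsFactors = FALSE)
    }
  }
  hits <- if (length(rows)) do.call(rbind, rows) else
    data.frame(query_genome = character(), query = character(),
               subject_genome = character(), subject = character(),
               score = numeric(), identity = numeric(),
               coverage_q = numeric(), coverage_s = numeric(),
               evalue_like = numeric(), stringsAsFactors = FALSE)
  loci <- do.call(rbind, lapply(gids, function(g) {
    if (length(prot[[g]]) == 0) return(NULL)
    data.frame(genome = g, locus = names(prot[[g]]),
               stringsAsFactors = FALSE)
  }))
  structure(list(hits = hits, self_scores = self, loci = loci),
            class = "pv_hits")
}

pv_locus_key <- function(genome, locus) paste0(genome, ":", locus)

#' Bidirectional best hits
#'
#' Edge (x, y) exists iff y is x's best-scoring hit in y's genome and
#' vice versa. Ties broken by higher identity, then lexicographic
#' locus id.
#'
#' @param hits a `pv_hits` object from [all_vs_all()].
#' @return data.frame of undirected edges (genome_a, locus_a, genome_b,
#'   locus_b), each pair once with key_a < key_b.
#' @export
bbh_graph <- function(hits) {
  h <- hits$hits
  if (nrow(h) == 0) {
    return(data.frame(genome_a = character(), locus_a = character(),
                      genome_b = character(), locus_b = character(),
                      stringsAsFactors = FALSE))
  }
  # best hit per (query locus, subject genome)
  ord <- order(h$query_genome, h$query, h$subject_genome,
               -h$score, -h$identity, h$subject)
  hs <- h[ord, ]
  first <- !duplicated(hs[, c("query_genome", "query", "subject_genome")])
  best <- hs[first, ]
  fwd <- paste(pv_locus_key(best$query_genome, best$query),
               pv_locus_key(best$subject_genome, best$subject), sep = "|")
  rev <- paste(pv_locus_key(best$subject_genome, best$subject),
               pv_locus_key(best$query_genome, best$query), sep = "|")
  mutual <- best[fwd %in% rev, ]
  ka <- pv_locus_key(mutual$query_genome, mutual$query)
  kb <- pv_locus_key(mutual$subject_genome, mutual$subject)
  keep <- ka < kb
  data.frame(genome_a = mutual$query_genome[keep],
             locus_a = mutual$query[keep],
             genome_b = mutual$subject_genome[keep],
             locus_b = mutual$subject[keep], stringsAsFactors = FALSE)
}

# minimal union-find
pv_ufind <- function(parent, i) {
  while (parent[i] != i) {
    parent[i] <- parent[parent[i]]
    i <- parent[i]
  }
  i
}

pv_components <- function(n, edges_i, edges_j) {
  parent <- seq_len(n)
  for (k in seq_along(edges_i)) {
    ri <- pv_ufind(parent, edges_i[k])
    rj <- pv_ufind(parent, edges_j[k])
    if (ri != rj) parent[ri] <- rj
  }
  vapply(seq_len(n), function(i) pv_ufind(parent, i), 0L)
}

pv_cluster_set <- function(members_list, algorithm) {
  # members_list: list of data.frames (genome, locus)
  names(members_list) <- sprintf("%s_%04d", algorithm,
                                 seq_along(members_list))
  structure(list(clusters = members_list, algorithm = algorithm),
            class = "gene_cluster_set")
}

#' @export
print.gene_cluster_set <- function(x, ...) {
  cat(sprintf("<gene_cluster_set [%s]: %d clusters, %d loci>\n",
              x$algorithm, length(x$clusters),
              sum(vapply(x$clusters, nrow, 0L))))
  invisible(x)
}

#' COG-triangle clustering of BBH edges
#'
#' Seed clusters are triangles of BBH edges spanning three distinct
#' genomes; triangles sharing an edge are merged. BBH pairs not in any
#' triangle form two-member clusters (skipped when either endpoint is
#' already clustered); remaining loci become singletons.
#'
#' @param bbh edge data.frame from [bbh_graph()].
#' @param loci universe data.frame (genome, locus), e.g. `hits$loci`.
#' @return a `gene_cluster_set` (algorithm "cog").
#' @export
cog_triangles <- function(bbh, loci) {
  keys <- pv_locus_key(loci$genome, loci$locus)
  n <- length(keys)
  idx <- setNames(seq_len(n), keys)
  ea <- idx[pv_locus_key(bbh$genome_a, bbh$locus_a)]
  eb <- idx[pv_locus_key(bbh$genome_b, bbh$locus_b)]
  adj <- vector("list", n)
  for (k in seq_along(ea)) {
    adj[[ea[k]]] <- c(adj[[ea[k]]], eb[k])
    adj[[eb[k]]] <- c(adj[[eb[k]]], ea[k])
  }
  tri_edge <- logical(length(ea))
  genome_of <- loci$genome
  for (k in seq_along(ea)) {
    common <- intersect(adj[[ea[k]]], adj[[eb[k]]])
    if (length(common)) {
      distinct <- genome_of[common] != genome_of[ea[k]] &
        genome_of[common] != genome_of[eb[k]]
      if (any(distinct)) tri_edge[k] <- TRUE
    }
  }
  comp <- pv_components(n, ea[tri_edge], eb[tri_edge])
  in_tri <- seq_len(n) %in% c(ea[tri_edge], eb[tri_edge])
  clusters <- list()
  for (cc in split(seq_len(n)[in_tri], comp[in_tri])) {
    if (length(cc) < 2) next
    clusters[[length(clusters) + 1]] <-
      data.frame(genome = loci$genome[cc], locus = loci$locus[cc],
                 stringsAsFactors = FALSE)
  }
  clustered <- in_tri
  for (k in seq_along(ea)) {
    if (tri_edge[k]) next
    if (clustered[ea[k]] || clustered[eb[k]]) next
    cc <- c(ea[k], eb[k])
    clusters[[length(clusters) + 1]] <-
      data.frame(genome = loci$genome[cc], locus = loci$locus[cc],
                 stringsAsFactors = FALSE)
    clustered[cc] <- TRUE
  }
  for (i in which(!clustered)) {
    clusters[[length(clusters) + 1]] <-
      data.frame(genome = loci$genome[i], locus = loci$locus[i],
                 stringsAsFactors = FALSE)
  }
  clusters <- clusters[order(vapply(clusters, function(m)
    min(pv_locus_key(m$genome, m$locus)), ""))]
  pv_cluster_set(clusters, "cog")
}

#' Markov clustering (MCL) of the similarity graph
#'
#' Builds the symmetric score matrix over all loci, adds self-loops,
#' column-normalizes, and iterates expansion (matrix square) and
#' inflation (entrywise power + renormalization) with pruning of
#' entries below 1e-6 until the maximum entrywise change is below 1e-8
#' or 200 iterations. Clusters are connected components of the
#' attractor support.
#'
#' @param hits a `pv_hits` object.
#' @param inflation inflation exponent (> 1; default 1.5).
#' @return a `gene_cluster_set` (algorithm "mcl"); attribute
#'   `converged` is FALSE when the iteration cap was reached.
#' @export
mcl_cluster <- function(hits, inflation = 1.5) {
  pv_assert(inflation > 1, "mcl inflation must be > 1")
  loci <- hits$loci
  keys <- pv_locus_key(loci$genome, loci$locus)
  n <- length(keys)
  A <- matrix(0, n, n, dimnames = list(keys, keys))
  h <- hits$hits
  if (nrow(h) > 0) {
    qi <- match(pv_locus_key(h$query_genome, h$query), keys)
    sj <- match(pv_locus_key(h$subject_genome, h$subject), keys)
    for (k in seq_along(qi)) {
      v <- max(A[qi[k], sj[k]], h$score[k])
      A[qi[k], sj[k]] <- v
      A[sj[k], qi[k]] <- v
    }
  }
  diag(A) <- pmax(apply(A, 2, max), 1) # self-loops stabilize attractors
  M <- sweep(A, 2, colSums(A), "/")
  converged <- FALSE
  for (it in seq_len(200)) {
    M2 <- M %*% M
    M2 <- M2^inflation
    M2[M2 < 1e-6] <- 0
    cs <- colSums(M2)
    cs[cs == 0] <- 1
    M2 <- sweep(M2, 2, cs, "/")
    delta <- max(abs(M2 - M))
    M <- M2
    if (delta < 1e-8) { converged <- TRUE; break }
  }
  if (!converged) warning("MCL did not converge within 200 iterations")
  supp <- which(M > 1e-6, arr.ind = TRUE)
  comp <- pv_components(n, supp[, 1], supp[, 2])
  clusters <- lapply(split(seq_len(n), comp), function(cc) {
    data.frame(genome = loci$genome[cc], locus = loci$locus[cc],
               stringsAsFactors = FALSE)
  })
  clusters <- unname(clusters)
  clusters <- clusters[order(vapply(clusters, function(m)
    min(pv_locus_key(m$genome, m$locus)), ""))]
  out <- pv_cluster_set(clusters, "mcl")
  attr(out, "converged") <- converged
  out
}

pv_member_keys <- function(cluster_set) {
  lapply(cluster_set$clusters, function(m)
    sort(pv_locus_key(m$genome, m$locus)))
}

#' Intersection of two clusterings
#'
#' Keeps only clusters whose member sets appear identically in both
#' inputs (the strict reading of using "clusters found by both
#' algorithms").
#'
#' @param a,b `gene_cluster_set` objects over the same locus universe.
#' @return a `gene_cluster_set` (algorithm "intersection").
#' @export
intersect_clusterings <- function(a, b) {
  ka <- vapply(pv_member_keys(a), paste, "", collapse = "|")
  kb <- vapply(pv_member_keys(b), paste, "", collapse = "|")
  keep <- a$clusters[ka %in% kb]
  keep <- keep[order(vapply(keep, function(m)
    min(pv_locus_key(m$genome, m$locus)), ""))]
  pv_cluster_set(unname(keep), "intersection")
}

#' Genome-by-genome identity matrix from best-hit scores
#'
#' Entry (i, j) is the mean over genome i's proteins of the best hit
#' score into genome j normalized by the protein's self score (0 when
#' there is no hit), symmetrized by averaging with (j, i). Diagonal 1.
#'
#' @param hits a `pv_hits` object from [all_vs_all()].
#' @return symmetric matrix with entries in \[0, 1\].
#' @export
identity_matrix <- function(hits) {
  gids <- unique(hits$loci$genome)
  n <- length(gids)
  raw <- matrix(0, n, n, dimnames = list(gids, gids))
  h <- hits$hits
  for (gi in gids) {
    own <- hits$loci[hits$loci$genome == gi, ]
    if (nrow(own) == 0) next
    selfs <- hits$self_scores[pv_locus_key(gi, own$locus)]
    for (gj in setdiff(gids, gi)) {
      sub <- h[h$query_genome == gi & h$subject_genome == gj, ]
      best <- rep(0, nrow(own))
      if (nrow(sub) > 0) {
        agg <- tapply(sub$score, sub$query, max)
        m <- match(own$locus, names(agg))
        best[!is.na(m)] <- agg[m[!is.na(m)]]
      }
      raw[gi, gj] <- mean(pmin(best / selfs, 1))
    }
  }
  out <- (raw + t(raw)) / 2
  diag(out) <- 1
  out
}

#' Screen a proteome against a labeled reference protein set
#'
#' Flags proteome members whose best local hit against the reference
#' set passes identity and reference-coverage thresholds. Coverage in
#' `[low_cov, min_cov)` yields verdict "low_confidence" (e.g. a
#' truncated integrase).
#'
#' @param genome a `phage_genome` (or list with `cds$aa_seq`/`locus_id`).
#' @param reference named character vector of reference proteins, or a
#'   path to a protein FASTA.
#' @param min_identity identity threshold (default 0.3).
#' @param min_cov reference coverage for a confident call (default 0.5).
#' @param low_cov lower coverage bound for a low-confidence call
#'   (default 0.3).
#' @return data.frame (locus, reference, identity, coverage, verdict)
#'   with verdict in present/low_confidence; unflagged loci omitted.
#' @export
screen_reference_set <- function(genome, reference, min_identity = 0.3,
                                 min_cov = 0.5, low_cov = 0.3) {
  if (is.character(reference) && length(reference) == 1 &&
      file.exists(reference)) {
    set <- Biostrings::readAAStringSet(reference)
    reference <- setNames(as.character(set), sub("\\s.*$", "", names(set)))
  }
  pv_assert(length(reference) > 0, "empty reference set")
  sub <- pv_blosum62()
  alphabet <- rownames(sub)
  enc_ref <- lapply(reference, pv_encode_aa, alphabet = alphabet)
  out <- list()
  for (i in seq_len(nrow(genome$cds))) {
    q <- pv_encode_aa(genome$cds$aa_seq[i], alphabet)
    best <- NULL
    for (rn in names(reference)) {
      r <- cpp_sw_align(q, enc_ref[[rn]], sub, 11, 1)
      if (is.null(best) || r$score > best$score) {
        best <- r; best$ref <- rn
      }
    }
    if (is.null(best)) next
    cov <- best$coverage_s # coverage of the reference
    if (best$identity >= min_identity && cov >= low_cov) {
      verdict <- if (cov >= min_cov) "present" else "low_confidence"
      out[[length(out) + 1]] <- data.frame(
        locus = genome$cds$locus_id[i], reference = best$ref,
        identity = best$identity, coverage = cov, verdict = verdict,
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0) {
    return(data.frame(locus = character(), reference = character(),
                      identity = numeric(), coverage = numeric(),
                      verdict = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}
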