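#' Terminase phylogeny, saturation assessment and packaging inference
#'
#' Distance phylogenetics over large-terminase-subunit proteins:
#' uncorrected p-distances, neighbor-joining trees, patristic
#' distances, a p-distance-vs-patristic saturation check, and transfer
#' of DNA-packaging labels (headful, cos, DTR, ...) from labeled
#' reference leaves to query leaves through their smallest enclosing
#' labeled clade.
#'
#' @name phylo_packaging
NULL

#' Uncorrected p-distance between two aligned rows
#'
#' Columns with a gap ("-") in either row are excluded.
#'
#' @param a,b equal-length aligned strings.
#' @return fraction of mismatches among compared columns.
#' @export
p_distance <- function(a, b) {
  pv_assert(nchar(a) == nchar(b), "p_distance: rows differ in length")
  ca <- strsplit(a, "", fixed = TRUE)[[1]]
  cb <- strsplit(b, "", fixed = TRUE)[[1]]
  ok <- ca != "-" & cb != "-"
  pv_assert(any(ok), "p_distance: no comparable columns")
  sum(ca[ok] != cb[ok]) / sum(ok)
}

#' Pairwise p-distance matrix of an alignment
#'
#' @param aln named character vector of aligned rows.
#' @return symmetric matrix.
#' @export
p_distance_matrix <- function(aln) {
  n <- length(aln)
  d <- matrix(0, n, n, dimnames = list(names(aln), names(aln)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d[i, j] <- d[j, i] <- p_distance(aln[[i]], aln[[j]])
    }
  }
  d
}

#' Neighbor-joining tree with negative-branch clamping
#'
#' Canonical NJ (via ape). Negative branch lengths are set to zero and
#' the negative amount is transferred to the sister branch so local
#' path lengths are preserved; the sister is floored at zero.
#'
#' @param d symmetric non-negative distance matrix (>= 3 taxa).
#' @return an `ape::phylo` tree (unrooted).
#' @export
nj_tree <- function(d) {
  d <- as.matrix(d)
  pv_assert(!anyNA(d), "nj_tree: NaN/NA distances",
            "panvirome_validation_error")
  pv_assert(nrow(d) >= 3, "nj_tree needs >= 3 taxa")
  pv_assert(isTRUE(all.equal(d, t(d))), "nj_tree: matrix not symmetric")
  tree <- ape::nj(as.dist(d))
  neg <- which(tree$edge.length < 0)
  for (e in neg) {
    child <- tree$edge[e, 2]
    parent <- tree$edge[e, 1]
    sibs <- which(tree$edge[, 1] == parent & seq_len(nrow(tree$edge)) != e)
    amount <- tree$edge.length[e]
    tree$edge.length[e] <- 0
    if (length(sibs) > 0) {
      s <- sibs[1]
      tree$edge.length[s] <- max(0, tree$edge.length[s] + amount)
    }
  }
  tree
}

#' Patristic distance(s) on a tree
#'
#' @param tree an `ape::phylo`.
#' @param a,b leaf labels; when omitted, the full matrix is returned.
#' @return scalar path length, or the full symmetric matrix.
#' @export
patristic <- function(tree, a = NULL, b = NULL) {
  nt <- length(tree$tip.label)
  D <- ape::dist.nodes(tree)[seq_len(nt), seq_len(nt)]
  dimnames(D) <- list(tree$tip.label, tree$tip.label)
  if (is.null(a) && is.null(b)) return(D)
  pv_assert(all(c(a, b) %in% tree$tip.label),
            sprintf("unknown leaf: %s",
                    paste(setdiff(c(a, b), tree$tip.label), collapse = ", ")))
  D[a, b]
}

#' Substitution-saturation check
#'
#' Regresses p-distance on patristic distance. The signal is called
#' saturated when the linear fit is poor (R^2 < `r2_min`) or when the
#' quadratic term of a two-term fit is significantly negative
#' (one-sided alpha = 0.05), i.e. the plot bends toward a plateau.
#'
#' @param p_dist,patristic_dist paired numeric vectors (n >= 5).
#' @param r2_min linear-fit threshold (default 0.90).
#' @return list (slope, r_squared, quad_coef, quad_p_one_sided,
#'   saturated).
#' @export
saturation_test <- function(p_dist, patristic_dist, r2_min = 0.90) {
  pv_assert(length(p_dist) == length(patristic_dist),
            "saturation_test: length mismatch")
  pv_assert(length(p_dist) >= 5, "saturation_test needs n >= 5",
            "panvirome_validation_error")
  pv_assert(var(patristic_dist) > 0 && var(p_dist) > 0,
            "saturation_test: zero variance")
  lin <- lm(p_dist ~ patristic_dist)
  # noise-free input triggers R's perfect-fit note; harmless here
  r2 <- suppressWarnings(summary(lin))$r.squared
  quad <- lm(p_dist ~ patristic_dist + I(patristic_dist^2))
  qs <- suppressWarnings(summary(quad))$coefficients
  qc <- qs[3, 1]
  # one-sided p for a negative quadratic coefficient
  qp <- stats::pt(qs[3, 3], df = quad$df.residual)
  saturated <- (r2 < r2_min) || (qc < 0 && qp < 0.05)
  list(slope = unname(coef(lin)[2]), r_squared = r2, quad_coef = qc,
       quad_p_one_sided = qp, saturated = saturated)
}

pv_tree_children <- function(tree) {
  split(tree$edge[, 2], tree$edge[, 1])
}

pv_clade_tips <- function(tree, node) {
  nt <- length(tree$tip.label)
  if (node <= nt) return(node)
  kids <- pv_tree_children(tree)
  out <- integer(0)
  stack <- node
  while (length(stack)) {
    v <- stack[length(stack)]; stack <- stack[-length(stack)]
    if (v <= nt) out <- c(out, v)
    else stack <- c(stack, kids[[as.character(v)]])
  }
  out
}

#' Infer DNA-packaging strategy from labeled reference leaves
#'
#' Each query is assigned the majority label among references in its
#' smallest enclosing clade that contains at least one labeled
#' reference; ties go to the nearest labeled leaf by patristic
#' distance. A query whose smallest reference-containing clade is the
#' entire tree has no local signal and is labeled "unknown", never
#' guessed; `max_steps` can additionally cap the ancestor walk.
#'
#' @param tree an `ape::phylo` over references and queries.
#' @param ref_labels named character vector reference leaf -> strategy
#'   (e.g. "headful", "cos_5prime", "short_DTR").
#' @param queries leaf names to classify (default: all unlabeled
#'   leaves).
#' @param max_steps optional cap on ancestor nodes searched (default
#'   unlimited short of the root).
#' @return data.frame (query, strategy, confidence, n_refs_in_clade).
#' @export
infer_packaging <- function(tree, ref_labels, queries = NULL,
                            max_steps = Inf) {
  pv_assert(length(ref_labels) > 0, "no labeled references")
  pv_assert(all(names(ref_labels) %in% tree$tip.label),
            "reference labels name absent leaves")
  if (is.null(queries)) {
    queries <- setdiff(tree$tip.label, names(ref_labels))
  }
  nt <- length(tree$tip.label)
  D <- patristic(tree)
  out <- lapply(sort(queries), function(q) {
    # the rooting of an NJ tree is arbitrary; anchor the walk by
    # rerooting on the labeled reference farthest from the query
    # (deterministic: ties broken lexicographically)
    refs_all <- names(ref_labels)
    far <- refs_all[order(-D[q, refs_all], refs_all)][1]
    tr <- tree
    if (length(setdiff(tree$tip.label, far)) > 1) {
      tr <- tryCatch(ape::root(tree, outgroup = far,
                               resolve.root = TRUE),
                     error = function(e) tree)
    }
    parent <- integer(max(tr$edge))
    parent[tr$edge[, 2]] <- tr$edge[, 1]
    qi <- match(q, tr$tip.label)
    node <- qi
    strategy <- "unknown"; conf <- NA_real_; nref <- 0L
    step <- 0
    while (step < max_steps) {
      step <- step + 1
      if (parent[node] == 0) break
      node <- parent[node]
      tips <- tr$tip.label[pv_clade_tips(tr, node)]
      if (length(tips) == nt) break # whole tree: no local signal
      refs <- intersect(tips, names(ref_labels))
      if (length(refs) > 0) {
        labs <- ref_labels[refs]
        tab <- sort(table(labs), decreasing = TRUE)
        top <- names(tab)[tab == max(tab)]
        if (length(top) == 1) {
          strategy <- top
        } else {
          cand <- refs[labs %in% top]
          nearest <- cand[order(D[q, cand], cand)][1]
          strategy <- unname(ref_labels[nearest])
        }
        conf <- max(tab) / length(refs)
        nref <- length(refs)
        break
      }
    }
    data.frame(query = q, strategy = strategy, confidence = conf,
               n_refs_in_clade = nref, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
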