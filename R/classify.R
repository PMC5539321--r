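#' Gene-repertoire classification with AU supports
#'
#' Hierarchical clustering of the binary presence/absence matrix with
#' multiscale-bootstrap approximately-unbiased (AU) p-values, and an
#' AU-threshold cut assigning genomes to groups. The AU computation
#' follows the multiscale bootstrap: bootstrap proportions BP_r are
#' measured at several resampling scales r, their probit transforms are
#' fitted as z_r = d*sqrt(r) + c/sqrt(r) by weighted least squares, and
#' AU = 1 - Phi(d - c).
#'
#' @name classify
NULL

#' Binary (Jaccard) distance between genome presence/absence rows
#'
#' d(i, j) = (b + c) / (a + b + c), where a counts clusters present in
#' both genomes and b, c those present in exactly one; joint absences
#' are ignored. A pair with a + b + c = 0 gets distance 0 with a
#' warning.
#'
#' @param matrix binary genomes x clusters matrix.
#' @return symmetric distance matrix with zero diagonal.
#' @export
binary_distance <- function(matrix) {
  pv_assert(nrow(matrix) >= 2, "binary_distance needs >= 2 genomes")
  m <- matrix > 0
  a <- tcrossprod(m * 1)
  r <- rowSums(m)
  tot <- outer(r, r, "+") - a # a + b + c
  d <- 1 - a / tot
  if (any(tot == 0)) {
    warning("genome pair(s) with no clusters present in either; distance 0")
    d[tot == 0] <- 0
  }
  diag(d) <- 0
  d
}

# leaf index sets under each merge of an hclust-style merge matrix
pv_merge_leaves <- function(merge) {
  n_m <- nrow(merge)
  sets <- vector("list", n_m)
  for (k in seq_len(n_m)) {
    l <- merge[k, 1]; r <- merge[k, 2]
    lv <- if (l < 0) -l else sets[[l]]
    rv <- if (r < 0) -r else sets[[r]]
    sets[[k]] <- sort(c(lv, rv))
  }
  sets
}

#' Agglomerative clustering with a deterministic tie rule
#'
#' Average (default), complete or single linkage on a distance matrix.
#' When several pairs are at the minimal distance (within 1e-12), the
#' pair whose sorted pair of smallest member labels is lexicographically
#' smallest is merged; within a merge, the child containing the
#' lexicographically smallest label goes left.
#'
#' @param dist symmetric distance matrix with dimnames.
#' @param linkage "average", "complete" or "single".
#' @return an object of class `hclust` (merge, height, order, labels).
#' @export
pan_hclust <- function(dist, linkage = "average") {
  pv_assert(linkage %in% c("average", "complete", "single"),
            "linkage must be average, complete or single")
  labels <- rownames(dist)
  n <- nrow(dist)
  pv_assert(n >= 2, "need >= 2 items")
  D <- as.matrix(dist)
  diag(D) <- Inf
  active <- rep(TRUE, n)
  size <- rep(1L, n)
  minlab <- labels # smallest leaf label of each active cluster
  node_id <- -seq_len(n) # hclust convention
  merge <- matrix(0L, n - 1, 2)
  height <- numeric(n - 1)
  for (step in seq_len(n - 1)) {
    mn <- min(D)
    idx <- which(D <= mn + 1e-12)
    if (length(idx) > 2) { # tied pairs beyond the symmetric duplicate
      ii <- (idx - 1L) %% n + 1L
      jj <- (idx - 1L) %/% n + 1L
      sel <- ii < jj
      ii <- ii[sel]; jj <- jj[sel]
      la <- pmin(minlab[ii], minlab[jj])
      lb <- pmax(minlab[ii], minlab[jj])
      o <- order(la, lb)[1]
      i <- ii[o]; j <- jj[o]
    } else {
      k <- idx[1]
      i <- (k - 1L) %% n + 1L
      j <- (k - 1L) %/% n + 1L
      if (i > j) { tmp <- i; i <- j; j <- tmp }
    }
    left <- if (minlab[i] <= minlab[j]) i else j
    right <- if (left == i) j else i
    merge[step, ] <- c(node_id[left], node_id[right])
    height[step] <- mn
    # Lance-Williams update into slot i
    others <- which(active & seq_len(n) != i & seq_len(n) != j)
    if (length(others)) {
      D[i, others] <- switch(linkage,
        average = (size[i] * D[i, others] + size[j] * D[j, others]) /
          (size[i] + size[j]),
        complete = pmax(D[i, others], D[j, others]),
        single = pmin(D[i, others], D[j, others]))
      D[others, i] <- D[i, others]
    }
    active[j] <- FALSE
    D[j, ] <- Inf
    D[, j] <- Inf
    size[i] <- size[i] + size[j]
    minlab[i] <- min(minlab[i], minlab[j])
    node_id[i] <- step
    node_id[j] <- NA_integer_
  }
  ord <- integer(0)
  walk <- function(node) {
    if (node < 0) {
      ord <<- c(ord, -node)
    } else {
      walk(merge[node, 1]); walk(merge[node, 2])
    }
  }
  walk(n - 1)
  structure(list(merge = merge, height = height, order = ord,
                 labels = labels, method = linkage,
                 call = match.call(), dist.method = "binary"),
            class = "hclust")
}

pv_cluster_keys <- function(hc) {
  sets <- pv_merge_leaves(hc$merge)
  vapply(sets, function(s) paste(sort(hc$labels[s]), collapse = "\r"), "")
}

# leaf-set bitmask per merge node (exact for <= 52 leaves); leaves are
# identified by position in the fixed label vector, so masks are
# comparable across trees over the same labels
pv_merge_masks <- function(merge) {
  n_m <- nrow(merge)
  masks <- numeric(n_m)
  for (k in seq_len(n_m)) {
    l <- merge[k, 1]; r <- merge[k, 2]
    masks[k] <- (if (l < 0) 2^(-l - 1) else masks[l]) +
      (if (r < 0) 2^(-r - 1) else masks[r])
  }
  masks
}

# binary distance without validation/warnings, for the bootstrap loop
# (same tot = 0 -> distance 0 contract as binary_distance)
pv_bin_dist_fast <- function(m) {
  a <- tcrossprod(m)
  r <- rowSums(m)
  tot <- outer(r, r, "+") - a
  zero <- tot == 0
  tot[zero] <- 1
  d <- 1 - a / tot
  d[zero] <- 0
  diag(d) <- 0
  d
}

#' Multiscale-bootstrap AU supports for the pan-genome clustering
#'
#' For each scale r the cluster columns are resampled with replacement
#' at size ceiling(r * n_clusters), the genomes are reclustered, and
#' each original internal edge's recovery frequency BP_r is recorded.
#' The probit-scale fit z_r = d*sqrt(r) + c/sqrt(r) (weighted least
#' squares, pvclust weights B*phi(z)^2 / (BP(1-BP))) gives
#' AU = 1 - Phi(d - c). Edges with BP identically 0 or 1 at every scale
#' get AU 0 or 1 directly; BP values are clamped to
#' [1/(2B), 1 - 1/(2B)] before the probit transform. With a single
#' scale the fit is degenerate and AU falls back to BP (flagged).
#'
#' @param matrix binary presence/absence matrix (genomes x clusters).
#' @param scales resampling scales (default 0.5 to 1.4 by 0.1).
#' @param n_boot bootstrap replicates per scale (default 1000; the
#'   original analysis scale is 10000).
#' @param linkage linkage passed to [pan_hclust()].
#' @param seed integer seed; all resampling flows from it.
#' @return object of class `cluster_tree`: list with `hclust`, `edges`
#'   (data.frame node, au, bp, n_leaves, degenerate), `members` (list of
#'   leaf-label vectors per node), `scales`, `n_boot`.
#' @export
multiscale_bootstrap <- function(matrix, scales = seq(0.5, 1.4, by = 0.1),
                                 n_boot = 1000, linkage = "average",
                                 seed = 1) {
  if (n_boot < 100) warning("n_boot < 100: AU estimates will be unstable")
  nc <- ncol(matrix)
  pv_assert(nc >= 1, "matrix has no clusters")
  hc0 <- pan_hclust(binary_distance(matrix), linkage)
  use_masks <- nrow(matrix) <= 52
  keys0 <- if (use_masks) pv_merge_masks(hc0$merge) else
    pv_cluster_keys(hc0)
  n_edge <- length(keys0)
  bmat <- (matrix > 0) * 1
  bp <- matrix(0, n_edge, length(scales))
  set.seed(seed)
  for (si in seq_along(scales)) {
    m <- max(1L, as.integer(ceiling(scales[si] * nc)))
    counts <- integer(n_edge)
    for (b in seq_len(n_boot)) {
      cols <- sample.int(nc, m, replace = TRUE)
      d <- pv_bin_dist_fast(bmat[, cols, drop = FALSE])
      hb <- pan_hclust(d, linkage)
      keys_b <- if (use_masks) pv_merge_masks(hb$merge) else
        pv_cluster_keys(hb)
      counts <- counts + (keys0 %in% keys_b)
    }
    bp[, si] <- counts / n_boot
  }
  r1 <- which.min(abs(scales - 1))
  au <- numeric(n_edge)
  degen <- logical(n_edge)
  for (e in seq_len(n_edge)) {
    v <- bp[e, ]
    if (all(v == 1)) { au[e] <- 1; next }
    if (all(v == 0)) { au[e] <- 0; next }
    # scales where BP is exactly 0 or 1 carry no probit information and
    # would flatten the fit once clamped; drop them
    inf_sc <- v > 0 & v < 1
    if (sum(inf_sc) < 2) {
      au[e] <- round(mean(v))
      degen[e] <- TRUE
      next
    }
    vcl <- pmin(pmax(v[inf_sc], 1 / (2 * n_boot)), 1 - 1 / (2 * n_boot))
    sc <- scales[inf_sc]
    z <- qnorm(1 - vcl)
    X <- cbind(sqrt(sc), 1 / sqrt(sc))
    w <- n_boot * dnorm(z)^2 / (vcl * (1 - vcl))
    XtWX <- crossprod(X, X * w)
    if (abs(det(XtWX)) < 1e-12) {
      au[e] <- v[r1]
      degen[e] <- TRUE
      next
    }
    beta <- solve(XtWX, crossprod(X, z * w))
    au[e] <- 1 - pnorm(beta[1] - beta[2])
  }
  sets <- pv_merge_leaves(hc0$merge)
  members <- lapply(sets, function(s) hc0$labels[s])
  edges <- data.frame(node = seq_len(n_edge), au = au, bp = bp[, r1],
                      n_leaves = lengths(members), degenerate = degen)
  structure(list(hclust = hc0, edges = edges, members = members,
                 scales = scales, n_boot = n_boot, bp_all = bp),
            class = "cluster_tree")
}

#' @export
print.cluster_tree <- function(x, ...) {
  cat(sprintf("<cluster_tree: %d genomes, %d edges, %d x %d bootstrap>\n",
              length(x$hclust$labels), nrow(x$edges), x$n_boot,
              length(x$scales)))
  invisible(x)
}

#' Cut a supported tree into genome groups
#'
#' Groups are the maximal subtrees whose subtending edge reaches the AU
#' threshold while the parent edge does not; unsupported leaves become
#' singleton groups. The root edge does not exist, so the recursion
#' starts at the root's children. Labels are Roman numerals in
#' left-to-right leaf order.
#'
#' @param tree a `cluster_tree` from [multiscale_bootstrap()].
#' @param au_threshold support threshold in (0, 1); default 0.95.
#' @return named character vector genome id -> group label.
#' @export
cut_groups <- function(tree, au_threshold = 0.95) {
  pv_assert(au_threshold > 0 && au_threshold < 1,
            "au_threshold must be in (0, 1)")
  hc <- tree$hclust
  n_m <- nrow(hc$merge)
  # a tree whose every internal edge is supported is a single group
  if (n_m == 1 || all(tree$edges$au[seq_len(n_m - 1)] >= au_threshold)) {
    return(setNames(rep("I", length(hc$labels)), hc$labels))
  }
  groups <- list()
  descend <- function(node) {
    if (node < 0) {
      groups[[length(groups) + 1]] <<- hc$labels[-node]
    } else if (tree$edges$au[node] >= au_threshold) {
      groups[[length(groups) + 1]] <<- tree$members[[node]]
    } else {
      descend(hc$merge[node, 1])
      descend(hc$merge[node, 2])
    }
  }
  descend(hc$merge[n_m, 1])
  descend(hc$merge[n_m, 2])
  leaf_pos <- match(hc$labels, hc$labels[hc$order])
  first_pos <- vapply(groups, function(g) min(leaf_pos[match(g, hc$labels)]), 0)
  groups <- groups[order(first_pos)]
  out <- character(0)
  for (k in seq_along(groups)) {
    out[groups[[k]]] <- as.character(utils::as.roman(k))
  }
  out[hc$labels]
}

#' Export a cluster tree to Newick with AU/BP node comments
#'
#' @param tree a `cluster_tree`.
#' @param path output file.
#' @return invisibly `path`.
#' @export
write_cluster_tree <- function(tree, path) {
  phy <- ape::as.phylo(tree$hclust)
  # as.phylo numbers internal nodes in merge order after the tips
  phy$node.label <- sprintf("au%.2f_bp%.2f", tree$edges$au, tree$edges$bp)
  ape::write.tree(phy, file = path)
  invisible(path)
}
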