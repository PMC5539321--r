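# Independent oracles used by the test suite. These deliberately do not
# share code with the package implementation beyond the genetic-code
# table itself.

# textbook Gotoh local alignment, score only (small sequences)
ref_sw_score <- function(a, b, gap_open = 11, gap_ext = 1) {
  sub <- panvirome:::pv_blosum62()
  ac <- strsplit(a, "")[[1]]
  bc <- strsplit(b, "")[[1]]
  n <- length(ac); m <- length(bc)
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(-Inf, n + 1, m + 1)
  F <- matrix(-Inf, n + 1, m + 1)
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      E[i, j] <- max(H[i, j - 1] - gap_open - gap_ext,
                     E[i, j - 1] - gap_ext)
      F[i, j] <- max(H[i - 1, j] - gap_open - gap_ext,
                     F[i - 1, j] - gap_ext)
      H[i, j] <- max(0, H[i - 1, j - 1] + sub[ac[i - 1], bc[j - 1]],
                     E[i, j], F[i, j])
      best <- max(best, H[i, j])
    }
  }
  best
}

# Nei-Gojobori by explicit enumeration (recursive pathway walk)
ref_ng86 <- function(a, b) {
  code <- Biostrings::getGeneticCode("11")
  stops <- names(code)[code == "*"]
  bases <- c("A", "C", "G", "T")
  split_codons <- function(x) substring(x, seq(1, nchar(x), 3),
                                        seq(3, nchar(x), 3))
  syn_sites <- function(codon) {
    tot <- 0
    for (pos in 1:3) {
      syn <- 0; cnt <- 0
      for (bb in bases) {
        if (bb == substr(codon, pos, pos)) next
        alt <- codon
        substr(alt, pos, pos) <- bb
        if (alt %in% stops) next
        cnt <- cnt + 1
        if (code[alt] == code[codon]) syn <- syn + 1
      }
      if (cnt > 0) tot <- tot + syn / cnt
    }
    tot
  }
  # recursive pathway enumeration between two codons
  paths_sd_nd <- function(ca, cb) {
    diffs <- which(strsplit(ca, "")[[1]] != strsplit(cb, "")[[1]])
    if (length(diffs) == 0) return(c(0, 0))
    walk <- function(cur, remaining) {
      if (length(remaining) == 0) {
        return(list(list(s = 0, n = 0, blocked = FALSE)))
      }
      out <- list()
      for (pos in remaining) {
        nxt <- cur
        substr(nxt, pos, pos) <- substr(cb, pos, pos)
        step_syn <- code[cur] == code[nxt]
        blocked_here <- (nxt %in% stops) && nxt != cb
        for (tailp in walk(nxt, setdiff(remaining, pos))) {
          out[[length(out) + 1]] <- list(
            s = tailp$s + as.integer(step_syn),
            n = tailp$n + as.integer(!step_syn),
            blocked = tailp$blocked || blocked_here)
        }
      }
      out
    }
    all_paths <- walk(ca, diffs)
    ok <- Filter(function(p) !p$blocked, all_paths)
    use <- if (length(ok)) ok else all_paths
    c(mean(vapply(use, `[[`, 0, "s")), mean(vapply(use, `[[`, 0, "n")))
  }
  ca <- split_codons(a); cb <- split_codons(b)
  S <- N <- Sd <- Nd <- 0
  for (k in seq_along(ca)) {
    if (grepl("[^ACGT]", ca[k]) || grepl("[^ACGT]", cb[k])) next
    if (ca[k] %in% stops || cb[k] %in% stops) next
    s_site <- (syn_sites(ca[k]) + syn_sites(cb[k])) / 2
    S <- S + s_site
    N <- N + 3 - s_site
    sn <- paths_sd_nd(ca[k], cb[k])
    Sd <- Sd + sn[1]; Nd <- Nd + sn[2]
  }
  jc <- function(p) if (p >= 0.75) NA_real_ else -0.75 * log(1 - 4 * p / 3)
  list(S = S, N = N, Sd = Sd, Nd = Nd,
       dS = if (S > 0) jc(Sd / S) else NA_real_,
       dN = if (N > 0) jc(Nd / N) else NA_real_)
}

# two-sided Fisher exact p for a 2x2 table by hypergeometric enumeration
ref_fisher2x2 <- function(tab) {
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 2])
  support <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(tab[1, 2], m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# random in-frame, stop-free codon sequence
random_codons <- function(n_codons, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  code <- Biostrings::getGeneticCode("11")
  sense <- names(code)[code != "*"]
  paste(sample(sense, n_codons, replace = TRUE), collapse = "")
}

random_protein <- function(len) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], len,
               replace = TRUE), collapse = "")
}

adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  ch2 <- function(x) sum(choose(x, 2))
  si <- ch2(rowSums(tab)); sj <- ch2(colSums(tab))
  s <- ch2(c(tab)); n <- ch2(sum(tab))
  if ((si + sj) / 2 - si * sj / n == 0) return(1)
  (s - si * sj / n) / ((si + sj) / 2 - si * sj / n)
}

# small recovery cohort shared by classification tests
make_recovery_cohort <- function(seed, n_groups = NULL) {
  set.seed(seed)
  ngr <- if (is.null(n_groups)) sample(3:6, 1) else n_groups
  sizes <- sample(2:4, ngr, replace = TRUE)
  gcs <- stats::runif(ngr, 0.38, 0.58)
  spec <- cohort_spec(
    n_groups = ngr, genomes_per_group = sizes, gc_targets = gcs,
    core_clusters_per_group = 10, shared_clusters = list(),
    noise_clusters = 15, packaging_per_group = rep("headful", ngr),
    lysotype_per_group = rep("broad", ngr),
    size_targets = rep(12000, ngr), seed = seed)
  generate_cohort(spec)
}

cohort_pan_matrix <- function(co) {
  hits <- all_vs_all(co$genomes)
  ix <- intersect_clusterings(cog_triangles(bbh_graph(hits), hits$loci),
                              mcl_cluster(hits))
  build_matrix(ix, names(co$genomes))
}
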