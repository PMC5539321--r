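#' Positive-selection scan: NG86 dN/dS with a permutation test
#'
#' Counting-method selection analysis for orthologous gene clusters:
#' codon-aware alignment (proteins aligned, codons back-threaded), a
#' sliding-window Robinson-Foulds incongruence scan standing in for a
#' full recombination-detection model, Nei-Gojobori (1986) dN/dS with
#' Jukes-Cantor correction, and a column-resampling permutation test of
#' T = dN - dS. This is a deliberate, documented stand-in for
#' likelihood branch-site methods: p-values are calibrated for the
#' verdict threshold (p < 0.05), not comparable to likelihood p-values.
#'
#' @name selection
NULL

pv_stop_codons <- c("TAA", "TAG", "TGA")

# per-codon synonymous site counts; stop-creating mutations are excluded
# from both numerator and denominator at a position
pv_ng86_sites <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    code <- pv_genetic_code()
    bases <- c("A", "C", "G", "T")
    s <- setNames(numeric(64), names(code))
    for (codon in names(code)) {
      if (code[codon] == "*") { s[codon] <- NA_real_; next }
      tot <- 0
      for (pos in 1:3) {
        alts <- vapply(setdiff(bases, substr(codon, pos, pos)), function(b) {
          alt <- codon
          substr(alt, pos, pos) <- b
          alt
        }, "")
        non_stop <- alts[code[alts] != "*"]
        if (length(non_stop) > 0) {
          tot <- tot + sum(code[non_stop] == code[codon]) / length(non_stop)
        }
      }
      s[codon] <- tot
    }
    cache <<- s
    cache
  }
})

# averaged (sd, nd) over minimal mutational pathways between two codons;
# pathways passing through a stop codon are excluded (all-blocked pairs
# fall back to averaging over every pathway)
pv_ng86_path <- local({
  cache <- new.env(parent = emptyenv())
  function(ca, cb) {
    key <- paste0(ca, cb)
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    code <- pv_genetic_code()
    diff_pos <- which(strsplit(ca, "")[[1]] != strsplit(cb, "")[[1]])
    d <- length(diff_pos)
    if (d == 0) {
      res <- c(sd = 0, nd = 0)
    } else {
      perms <- if (d == 1) list(diff_pos) else {
        idx <- seq_len(d)
        out <- list()
        permute <- function(prefix, rest) {
          if (!length(rest)) out[[length(out) + 1]] <<- diff_pos[prefix]
          else for (r in seq_along(rest))
            permute(c(prefix, rest[r]), rest[-r])
        }
        permute(integer(0), idx)
        out
      }
      paths <- lapply(perms, function(ord) {
        cur <- ca
        steps <- character(0)
        blocked <- FALSE
        for (pos in ord) {
          nxt <- cur
          substr(nxt, pos, pos) <- substr(cb, pos, pos)
          steps <- c(steps, if (code[cur] == code[nxt]) "s" else "n")
          if (nxt %in% pv_stop_codons && nxt != cb) blocked <- TRUE
          cur <- nxt
        }
        list(steps = steps, blocked = blocked)
      })
      ok <- !vapply(paths, `[[`, TRUE, "blocked")
      use <- if (any(ok)) paths[ok] else paths
      sd_mean <- mean(vapply(use, function(p) sum(p$steps == "s"), 0))
      res <- c(sd = sd_mean, nd = d - sd_mean)
    }
    cache[[key]] <- res
    res
  }
})

pv_jc_correct <- function(p) {
  if (is.na(p)) return(NA_real_)
  if (p >= 0.75) return(NA_real_) # saturated
  -0.75 * log(1 - 4 * p / 3)
}

pv_split_codons <- function(nt) {
  nt <- toupper(nt)
  n <- nchar(nt) %/% 3L
  substring(nt, 3L * seq_len(n) - 2L, 3L * seq_len(n))
}

# per-column NG86 statistics for a codon pair vector
# returns matrix with rows s_sites, n_sites, sd, nd (NA where skipped)
pv_ng86_columns <- function(codons_a, codons_b) {
  sites <- pv_ng86_sites()
  ncod <- length(codons_a)
  out <- matrix(NA_real_, 4, ncod,
                dimnames = list(c("s_sites", "n_sites", "sd", "nd"), NULL))
  valid_codon <- function(x) {
    !grepl("[^ACGT]", x) & !(x %in% pv_stop_codons)
  }
  ok <- valid_codon(codons_a) & valid_codon(codons_b)
  for (i in which(ok)) {
    sa <- sites[codons_a[i]]; sb <- sites[codons_b[i]]
    path <- pv_ng86_path(codons_a[i], codons_b[i])
    s_site <- (sa + sb) / 2
    out[, i] <- c(s_site, 3 - s_site, path["sd"], path["nd"])
  }
  out
}

#' Nei-Gojobori (1986) dN and dS for an aligned codon pair
#'
#' Synonymous/nonsynonymous site counts are averaged over the two
#' sequences; observed differences are averaged over all minimal
#' mutational pathways (pathways through stop codons excluded);
#' proportions are Jukes-Cantor corrected, d = -(3/4) log(1 - 4p/3).
#' Gap ("---"), ambiguous and stop codons are excluded pairwise.
#'
#' @param a,b aligned nucleotide strings of equal length divisible
#'   by 3.
#' @return list (dN, dS, pN, pS, N, S, Nd, Sd, saturated); dN/dS are NA
#'   with `saturated = TRUE` when a corrected proportion reaches 3/4.
#' @export
ng86_dnds <- function(a, b) {
  pv_assert(nchar(a) == nchar(b) && nchar(a) %% 3 == 0,
            "ng86_dnds: need equal lengths divisible by 3")
  cols <- pv_ng86_columns(pv_split_codons(a), pv_split_codons(b))
  use <- !is.na(cols[1, ])
  pv_assert(any(use), "ng86_dnds: no comparable codons")
  S <- sum(cols["s_sites", use]); N <- sum(cols["n_sites", use])
  Sd <- sum(cols["sd", use]); Nd <- sum(cols["nd", use])
  pS <- if (S > 0) Sd / S else NA_real_
  pN <- if (N > 0) Nd / N else NA_real_
  dS <- pv_jc_correct(pS); dN <- pv_jc_correct(pN)
  list(dN = dN, dS = dS, pN = pN, pS = pS, N = N, S = S, Nd = Nd, Sd = Sd,
       saturated = (is.na(dS) && !is.na(pS) && pS >= 0.75) ||
         (is.na(dN) && !is.na(pN) && pN >= 0.75))
}

#' Codon-aware alignment of nucleotide sequences
#'
#' Sequences are trimmed to full codons (a terminal stop codon is
#' removed), translated (genetic code 11; an internal stop is an
#' error naming the sequence and codon), aligned at the protein level
#' with [align_proteins()], and the codons are threaded back through
#' the protein alignment (protein gaps become "---").
#'
#' @param nt_seqs named character vector of in-frame nucleotide
#'   sequences (>= 2).
#' @return object of class `codon_alignment`: list with `seqs` (aligned
#'   nucleotide rows), `n_codons`, `boundaries` (NULL until set).
#' @export
codon_align <- function(nt_seqs) {
  pv_assert(length(nt_seqs) >= 2 && !is.null(names(nt_seqs)),
            "codon_align: need >= 2 named sequences")
  codons <- lapply(nt_seqs, pv_split_codons)
  for (nm in names(codons)) {
    cc <- codons[[nm]]
    if (length(cc) > 0 && cc[length(cc)] %in% pv_stop_codons) {
      cc <- cc[-length(cc)]
      codons[[nm]] <- cc
    }
    internal_stop <- which(cc %in% pv_stop_codons)
    pv_assert(length(internal_stop) == 0,
              sprintf("internal stop codon in %s at codon %s", nm,
                      paste(internal_stop, collapse = ",")),
              "panvirome_validation_error")
  }
  prots <- vapply(codons, function(cc) {
    code <- pv_genetic_code()
    aa <- unname(code[cc])
    aa[is.na(aa)] <- "X"
    paste(aa, collapse = "")
  }, character(1))
  paln <- align_proteins(prots)
  aligned <- vapply(names(paln), function(nm) {
    chars <- strsplit(paln[[nm]], "", fixed = TRUE)[[1]]
    cc <- codons[[nm]]
    k <- 0L
    out <- vapply(chars, function(ch) {
      if (ch == "-") "---" else { k <<- k + 1L; cc[k] }
    }, "")
    paste(out, collapse = "")
  }, character(1))
  structure(list(seqs = aligned, n_codons = nchar(aligned[[1]]) %/% 3L,
                 boundaries = NULL),
            class = "codon_alignment")
}

#' Sliding-window recombination breakpoint scan
#'
#' Neighbor-joining topologies are built in sliding windows of the
#' codon alignment; a breakpoint is recorded where adjacent windows'
#' topologies differ (Robinson-Foulds > 0) persistently, i.e. for at
#' least two consecutive window comparisons. A simplified stand-in for
#' likelihood recombination detection; explicit boundaries may be
#' supplied downstream to bypass it.
#'
#' @param aln a `codon_alignment` with >= 4 sequences.
#' @param window,step window size and step in codons (defaults 60/20).
#' @return sorted integer vector of breakpoint codon columns (possibly
#'   empty; empty means a single partition).
#' @export
detect_breakpoints <- function(aln, window = 60, step = 20) {
  pv_assert(length(aln$seqs) >= 4,
            "detect_breakpoints needs >= 4 sequences",
            "panvirome_validation_error")
  n <- aln$n_codons
  if (n < window) return(integer(0))
  starts <- seq(1, n - window + 1, by = step)
  trees <- lapply(starts, function(s) {
    sub <- vapply(aln$seqs, function(x) substr(x, 3 * (s - 1) + 1,
                                               3 * (s + window - 1)), "")
    nj_tree(p_distance_matrix(sub))
  })
  if (length(trees) < 2) return(integer(0))
  rf <- vapply(seq_len(length(trees) - 1), function(k) {
    phangorn::RF.dist(trees[[k]], trees[[k + 1]], check.labels = TRUE)
  }, 0)
  # runs of consecutive windows sharing a topology; only runs of >= 2
  # windows count as confident (single-window flips are noise)
  run_id <- cumsum(c(1, rf > 0))
  run_len <- table(run_id)
  conf <- as.integer(names(run_len)[run_len >= 2])
  if (length(conf) < 2) return(integer(0))
  bps <- integer(0)
  for (k in seq_len(length(conf) - 1)) {
    w1 <- max(which(run_id == conf[k]))       # last window of run k
    w2 <- min(which(run_id == conf[k + 1]))   # first window of next run
    if (phangorn::RF.dist(trees[[w1]], trees[[w2]],
                          check.labels = TRUE) == 0) next
    bps <- c(bps, as.integer(round((starts[w1] + window - 1 +
                                      starts[w2]) / 2)))
  }
  bps <- bps[bps > 1 & bps <= n]
  if (length(bps) > 1) {
    keep <- c(TRUE, diff(bps) >= window)
    bps <- bps[keep]
  }
  sort(unique(bps))
}

#' Cluster-level dN/dS with permutation significance
#'
#' Per partition, the mean pairwise dN and dS (NG86,
#' Jukes-Cantor-corrected) give the statistic T = mean dN - mean dS.
#' Significance comes from resampling codon columns with replacement
#' (jointly across all sequence pairs, which preserves the correlation
#' a single substitution induces across pairs) and testing E[T] > 0:
#' p = (1 + #\{T* <= 0\}) / (B + 1). Columns are the exchangeable unit
#' (substitutions are independent across sites); a reallocation null
#' that scrambles each column's synonymous/nonsynonymous identities
#' per pair is badly anti-conservative because pairs share events.
#'
#' @param aln a `codon_alignment` (>= 2 sequences).
#' @param boundaries optional breakpoint codon columns (from
#'   [detect_breakpoints()] or supplied explicitly).
#' @param B permutation replicates (default 1000).
#' @param seed integer seed.
#' @param alpha verdict threshold (default 0.05).
#' @return data.frame, one row per partition: partition, start, end,
#'   dN, dS, T, p_value, positively_selected, n_pairs_used, saturated.
#' @export
cluster_dnds <- function(aln, boundaries = NULL, B = 1000, seed = 1,
                         alpha = 0.05) {
  seqs <- aln$seqs
  pv_assert(length(seqs) >= 2, "cluster_dnds needs >= 2 sequences")
  n <- aln$n_codons
  if (is.null(boundaries)) boundaries <- aln$boundaries
  cuts <- sort(unique(c(1, boundaries, n + 1)))
  cuts <- cuts[cuts >= 1 & cuts <= n + 1]
  codons <- lapply(seqs, pv_split_codons)
  pairs <- utils::combn(seq_along(seqs), 2, simplify = FALSE)
  pair_cols <- lapply(pairs, function(ij) {
    pv_ng86_columns(codons[[ij[1]]], codons[[ij[2]]])
  })
  set.seed(seed)
  out <- list()
  for (k in seq_len(length(cuts) - 1)) {
    cols <- cuts[k]:(cuts[k + 1] - 1)
    stat_from <- function(idx) {
      dn <- ds <- numeric(0)
      for (pc in pair_cols) {
        sub <- pc[, idx, drop = FALSE]
        use <- !is.na(sub[1, ])
        if (!any(use)) next
        S <- sum(sub["s_sites", use]); N <- sum(sub["n_sites", use])
        Sd <- sum(sub["sd", use]); Nd <- sum(sub["nd", use])
        dS_p <- if (S > 0) pv_jc_correct(Sd / S) else NA_real_
        dN_p <- if (N > 0) pv_jc_correct(Nd / N) else NA_real_
        if (!is.na(dS_p) && !is.na(dN_p)) {
          dn <- c(dn, dN_p); ds <- c(ds, dS_p)
        }
      }
      if (length(dn) == 0) return(NULL)
      list(dN = mean(dn), dS = mean(ds), T = mean(dn) - mean(ds),
           n_pairs = length(dn))
    }
    obs <- stat_from(cols)
    if (is.null(obs)) {
      out[[k]] <- data.frame(partition = k, start = cuts[k],
                             end = cuts[k + 1] - 1, dN = NA_real_,
                             dS = NA_real_, T = NA_real_,
                             p_value = NA_real_,
                             positively_selected = FALSE,
                             n_pairs_used = 0L, saturated = TRUE)
      next
    }
    t_star <- numeric(B)
    for (b in seq_len(B)) {
      idx <- sample(cols, length(cols), replace = TRUE)
      st <- stat_from(idx)
      t_star[b] <- if (is.null(st)) NA_real_ else st$T
    }
    p <- (1 + sum(t_star <= 0, na.rm = TRUE)) / (B + 1)
    out[[k]] <- data.frame(partition = k, start = cuts[k],
                           end = cuts[k + 1] - 1, dN = obs$dN,
                           dS = obs$dS, T = obs$T, p_value = p,
                           positively_selected = p < alpha,
                           n_pairs_used = obs$n_pairs, saturated = FALSE)
  }
  do.call(rbind, out)
}

pv_nt_submat <- function(match = 1, mismatch = -1) {
  b <- c("A", "C", "G", "T", "N")
  m <- matrix(mismatch, 5, 5, dimnames = list(b, b))
  diag(m) <- match
  m["N", ] <- 0; m[, "N"] <- 0
  m
}

pv_encode_nt <- function(seq) {
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  idx <- match(chars, c("A", "C", "G", "T", "N"))
  pv_assert(!anyNA(idx), "non-ACGTN base in sequence")
  idx - 1L
}

pv_complement <- function(base) {
  c(A = "T", C = "G", G = "C", T = "A", N = "N")[[base]]
}

#' Classify SNPs between two near-identical genomes
#'
#' Globally aligns the two genome sequences (match 1, mismatch -1, gap
#' -2, linear) and classifies each substitution by its codon effect
#' under the first genome's CDS annotation; positions outside every CDS
#' are intergenic. Refuses pairs below `min_identity` global identity
#' (use the homology module for diverged pairs). Memory is quadratic in
#' genome length: intended for small or sub-sampled genomes.
#'
#' @param genome_a,genome_b `phage_genome` objects; annotation is taken
#'   from `genome_a`.
#' @param min_identity refusal threshold (default 0.95).
#' @return data.frame (position_a, position_b, ref, alt, locus,
#'   codon_change, aa_change, effect); indel runs are reported in the
#'   `indels` attribute (start_a, length, type).
#' @export
classify_snps <- function(genome_a, genome_b, min_identity = 0.95) {
  sub <- pv_nt_submat()
  a <- cpp_nw_align(pv_encode_nt(genome_a$sequence),
                    pv_encode_nt(genome_b$sequence), sub,
                    gap_open = 0, gap_ext = 2)
  achars <- strsplit(genome_a$sequence, "", fixed = TRUE)[[1]]
  bchars <- strsplit(genome_b$sequence, "", fixed = TRUE)[[1]]
  both <- a$a_idx > 0 & a$b_idx > 0
  matches <- sum(achars[a$a_idx[both]] == bchars[a$b_idx[both]])
  identity <- matches / length(a$a_idx)
  pv_assert(identity >= min_identity,
            sprintf(paste0("global identity %.3f below %.2f: genomes too ",
                           "diverged for SNP calling; use the homology ",
                           "module instead"), identity, min_identity),
            "panvirome_validation_error")
  subs <- which(both & achars[pmax(a$a_idx, 1)] != bchars[pmax(a$b_idx, 1)])
  subs <- subs[achars[a$a_idx[subs]] != "N" & bchars[a$b_idx[subs]] != "N"]
  cds <- genome_a$cds
  rows <- lapply(subs, function(col) {
    pa <- a$a_idx[col]; pb <- a$b_idx[col]
    ref <- achars[pa]; alt <- bchars[pb]
    hit <- which(cds$start <= pa & cds$end >= pa)
    if (length(hit) == 0) {
      return(data.frame(position_a = pa, position_b = pb, ref = ref,
                        alt = alt, locus = NA_character_,
                        codon_change = NA_character_,
                        aa_change = NA_character_, effect = "intergenic",
                        stringsAsFactors = FALSE))
    }
    h <- hit[1]
    offset <- if (cds$strand[h] == "+") pa - cds$start[h]
    else cds$end[h] - pa
    codon_i <- offset %/% 3L
    within <- offset %% 3L
    nt <- cds$nt_seq[h]
    ref_codon <- substr(nt, 3 * codon_i + 1, 3 * codon_i + 3)
    alt_base <- if (cds$strand[h] == "+") alt else pv_complement(alt)
    alt_codon <- ref_codon
    substr(alt_codon, within + 1, within + 1) <- alt_base
    code <- pv_genetic_code()
    aa_ref <- unname(code[ref_codon]); aa_alt <- unname(code[alt_codon])
    effect <- if (identical(aa_ref, aa_alt)) "synonymous" else "nonsynonymous"
    data.frame(position_a = pa, position_b = pb, ref = ref, alt = alt,
               locus = cds$locus_id[h],
               codon_change = paste0(ref_codon, ">", alt_codon),
               aa_change = paste0(aa_ref, ">", aa_alt), effect = effect,
               stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(position_a = integer(), position_b = integer(),
               ref = character(), alt = character(), locus = character(),
               codon_change = character(), aa_change = character(),
               effect = character(), stringsAsFactors = FALSE)
  gap_run <- rle(a$a_idx == 0 | a$b_idx == 0)
  indels <- data.frame(start_a = integer(), length = integer(),
                       type = character(), stringsAsFactors = FALSE)
  if (any(gap_run$values)) {
    ends <- cumsum(gap_run$lengths)
    starts <- ends - gap_run$lengths + 1
    for (k in which(gap_run$values)) {
      col <- starts[k]
      type <- if (a$a_idx[col] == 0) "insertion_in_b" else "deletion_in_b"
      prev_a <- if (col > 1) a$a_idx[col - 1] else 0
      indels <- rbind(indels, data.frame(start_a = prev_a + 1,
                                         length = gap_run$lengths[k],
                                         type = type,
                                         stringsAsFactors = FALSE))
    }
  }
  attr(out, "indels") <- indels
  attr(out, "identity") <- identity
  out
}
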