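#' Progressive (center-star) protein multiple alignment
#'
#' A deterministic center-star aligner built on the package's global
#' Needleman-Wunsch engine (BLOSUM62, affine gaps): the center sequence
#' maximizing the summed pairwise alignment score is chosen, every
#' other sequence is aligned to it, and the pairwise alignments are
#' merged by taking, between consecutive center residues, the maximum
#' insertion length observed in any pairwise alignment (insertions
#' left-justified). Adequate for the closely related within-cluster
#' sequences this pipeline aligns; not a general-purpose MSA.
#'
#' @param seqs named character vector of protein sequences (>= 1).
#' @param gap_open,gap_ext affine gap penalties.
#' @return named character vector of equal-length aligned rows, input
#'   order preserved.
#' @export
align_proteins <- function(seqs, gap_open = 11, gap_ext = 1) {
  pv_assert(length(seqs) >= 1 && !is.null(names(seqs)),
            "align_proteins: need named sequences")
  if (length(seqs) == 1) return(seqs)
  sub <- pv_blosum62()
  alphabet <- rownames(sub)
  enc <- lapply(seqs, pv_encode_aa, alphabet = alphabet)
  n <- length(seqs)
  scores <- matrix(0, n, n)
  alns <- vector("list", n * n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      a <- cpp_nw_align(enc[[i]], enc[[j]], sub, gap_open, gap_ext)
      scores[i, j] <- scores[j, i] <- a$score
      alns[[(i - 1) * n + j]] <- a
    }
  }
  center <- which.max(rowSums(scores))
  clen <- nchar(seqs[center])
  # per-sequence insertion counts in slots 0..clen (before pos 1 .. after pos clen)
  ins <- matrix(0L, n, clen + 1)
  pair <- vector("list", n)
  for (k in seq_len(n)) {
    if (k == center) next
    a <- if (k > center) alns[[(center - 1) * n + k]] else {
      # stored as (k, center): swap roles
      x <- alns[[(k - 1) * n + center]]
      list(score = x$score, a_idx = x$b_idx, b_idx = x$a_idx)
    }
    pair[[k]] <- a
    slot <- 0L
    for (col in seq_along(a$a_idx)) {
      if (a$a_idx[col] == 0) {
        ins[k, slot + 1] <- ins[k, slot + 1] + 1L
      } else {
        slot <- a$a_idx[col]
      }
    }
  }
  cap <- apply(ins, 2, max)
  total_len <- clen + sum(cap)
  # column layout: slot s occupies cap[s] columns; center residue i follows slot i-1
  col_of_pos <- integer(clen)
  cur <- 0L
  for (i in seq_len(clen)) {
    cur <- cur + cap[i] # slot i-1 is cap[i] (1-based shift)
    cur <- cur + 1L
    col_of_pos[i] <- cur
  }
  slot_start <- integer(clen + 1) # first column of each slot (1-based)
  slot_start[1] <- 1L
  for (s in seq_len(clen)) slot_start[s + 1] <- col_of_pos[s] + 1L
  out <- matrix("-", n, total_len)
  cchars <- strsplit(seqs[center], "", fixed = TRUE)[[1]]
  out[center, col_of_pos] <- cchars
  for (k in seq_len(n)) {
    if (k == center) next
    a <- pair[[k]]
    bchars <- strsplit(seqs[k], "", fixed = TRUE)[[1]]
    slot <- 0L; used <- 0L
    for (col in seq_along(a$a_idx)) {
      if (a$a_idx[col] == 0) {
        out[k, slot_start[slot + 1] + used] <- bchars[a$b_idx[col]]
        used <- used + 1L
      } else {
        slot <- a$a_idx[col]
        used <- 0L
        if (a$b_idx[col] != 0) {
          out[k, col_of_pos[slot]] <- bchars[a$b_idx[col]]
        }
      }
    }
  }
  res <- apply(out, 1, paste, collapse = "")
  names(res) <- names(seqs)
  res
}
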