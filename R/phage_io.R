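#' Genome input/output and basic statistics
#'
#' Readers and writers for the plain-text formats the pipeline consumes:
#' multi-record FASTA genomes, a tabular CDS annotation (genome_id,
#' locus_id, start, end, strand, product; 1-based inclusive coordinates),
#' and a cohort metadata table (genome sizes, CDS/tRNA counts, GC%,
#' integrase flag). Coordinates are 1-based inclusive throughout, the
#' GenBank convention; translation uses the bacterial/archaeal genetic
#' code (table 11).
#'
#' @name phage_io
NULL

# genetic code table 11 (codon -> amino acid, "*" = stop)
pv_genetic_code <- function() {
  Biostrings::getGeneticCode("11")
}

pv_revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

pv_translate <- function(nt) {
  code <- pv_genetic_code()
  n <- nchar(nt) %/% 3L
  pv_assert(n > 0, "sequence shorter than one codon")
  codons <- substring(nt, 3L * seq_len(n) - 2L, 3L * seq_len(n))
  aa <- unname(code[codons])
  aa[is.na(aa)] <- "X" # ambiguous codon
  paste(aa, collapse = "")
}

#' Percent G+C of a DNA sequence
#'
#' N bases are excluded from both numerator and denominator, so
#' assembly gaps do not bias the estimate.
#'
#' @param seq a DNA string (A/C/G/T/N, case-insensitive).
#' @return GC content as a percentage in \[0, 100\].
#' @examples
#' gc_content("ATGC") # 50
#' @export
gc_content <- function(seq) {
  pv_assert(is.character(seq) && length(seq) == 1 && nzchar(seq),
            "gc_content: need one non-empty DNA string")
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  gc <- sum(chars %in% c("G", "C"))
  at <- sum(chars %in% c("A", "T"))
  pv_assert(gc + at > 0, "gc_content: sequence has no unambiguous bases")
  100 * gc / (gc + at)
}

#' Construct a phage genome object
#'
#' @param id genome identifier.
#' @param sequence DNA string.
#' @param cds data.frame with columns locus_id, start, end, strand
#'   (and optionally product); coordinates 1-based inclusive.
#' @param trna_count non-negative integer.
#' @param integrase_flag one of "yes", "no", "low_confidence".
#' @param family optional taxonomic family string.
#' @return an object of class `phage_genome` with extracted CDS
#'   nucleotide and protein sequences.
#' @export
phage_genome <- function(id, sequence, cds = NULL, trna_count = 0L,
                         integrase_flag = "no", family = NA_character_) {
  sequence <- toupper(sequence)
  len <- nchar(sequence)
  pv_assert(len > 0, sprintf("genome %s: empty sequence", id))
  pv_assert(integrase_flag %in% c("yes", "no", "low_confidence"),
            "integrase_flag must be yes/no/low_confidence")
  if (is.null(cds) || nrow(cds) == 0) {
    cds <- data.frame(locus_id = character(), start = integer(),
                      end = integer(), strand = character(),
                      product = character(), nt_seq = character(),
                      aa_seq = character(), stringsAsFactors = FALSE)
  } else {
    cds <- as.data.frame(cds, stringsAsFactors = FALSE)
    if (is.null(cds$product)) cds$product <- NA_character_
    bad <- cds$start < 1 | cds$end > len | cds$start > cds$end
    if (any(bad)) {
      pv_stop(sprintf("genome %s: CDS out of bounds (%s)", id,
                      paste(cds$locus_id[bad], collapse = ", ")),
              "panvirome_validation_error")
    }
    pv_assert(all(cds$strand %in% c("+", "-")),
              sprintf("genome %s: strand must be + or -", id))
    nt <- substring(sequence, cds$start, cds$end)
    minus <- cds$strand == "-"
    nt[minus] <- vapply(nt[minus], pv_revcomp, character(1))
    cds$nt_seq <- nt
    cds$aa_seq <- vapply(nt, function(x) {
      aa <- pv_translate(x)
      sub("\\*$", "", aa)
    }, character(1))
  }
  structure(list(id = id, sequence = sequence, cds = cds,
                 trna_count = as.integer(trna_count),
                 gc_percent = gc_content(sequence), length_bp = len,
                 integrase_flag = integrase_flag, family = family),
            class = "phage_genome")
}

#' @export
print.phage_genome <- function(x, ...) {
  cat(sprintf("<phage_genome %s: %s bp, %d CDS, %d tRNA, GC %.1f%%>\n",
              x$id, format(x$length_bp, big.mark = ","), nrow(x$cds),
              x$trna_count, x$gc_percent))
  invisible(x)
}

#' Read phage genomes from FASTA plus annotation table
#'
#' @param fasta path to a (multi-record) genome FASTA file, or a vector
#'   of paths.
#' @param annotation optional path to a TSV with columns genome_id,
#'   locus_id, start, end, strand, product.
#' @param cohort optional path to a cohort metadata TSV (see
#'   [read_cohort_table()]) supplying tRNA counts and integrase flags.
#' @return a named list of [phage_genome()] objects.
#' @export
read_genomes <- function(fasta, annotation = NULL, cohort = NULL) {
  for (f in fasta) pv_assert(file.exists(f), sprintf("no such file: %s", f))
  seqs <- do.call(c, lapply(fasta, Biostrings::readDNAStringSet))
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  ann <- NULL
  if (!is.null(annotation)) {
    ann <- read.delim(annotation, stringsAsFactors = FALSE)
    need <- c("genome_id", "locus_id", "start", "end", "strand")
    pv_assert(all(need %in% names(ann)),
              sprintf("annotation %s: missing columns", annotation))
    unknown <- setdiff(unique(ann$genome_id), names(seqs))
    pv_assert(length(unknown) == 0,
              sprintf("annotation references absent genomes: %s",
                      paste(unknown, collapse = ", ")))
  }
  meta <- if (!is.null(cohort)) read_cohort_table(cohort) else NULL
  out <- lapply(names(seqs), function(id) {
    cds <- if (!is.null(ann)) ann[ann$genome_id == id, , drop = FALSE] else NULL
    trna <- 0L; integ <- "no"; fam <- NA_character_
    if (!is.null(meta) && id %in% meta$genome_id) {
      row <- meta[meta$genome_id == id, ]
      trna <- row$trna_count; integ <- row$integrase
      if ("family" %in% names(row)) fam <- row$family
    }
    phage_genome(id, as.character(seqs[[id]]), cds = cds,
                 trna_count = trna, integrase_flag = integ, family = fam)
  })
  names(out) <- names(seqs)
  out
}

#' Write genomes back to FASTA + annotation table
#'
#' Inverse of [read_genomes()]; FASTA wrapped at 60 columns.
#'
#' @param genomes list of `phage_genome`.
#' @param fasta,annotation output paths.
#' @return invisibly, the two paths.
#' @export
write_genomes <- function(genomes, fasta, annotation) {
  set <- Biostrings::DNAStringSet(vapply(genomes, `[[`, "", "sequence"))
  names(set) <- vapply(genomes, `[[`, "", "id")
  Biostrings::writeXStringSet(set, fasta, width = 60)
  ann <- do.call(rbind, lapply(genomes, function(g) {
    if (nrow(g$cds) == 0) return(NULL)
    data.frame(genome_id = g$id, locus_id = g$cds$locus_id,
               start = g$cds$start, end = g$cds$end, strand = g$cds$strand,
               product = ifelse(is.na(g$cds$product), "", g$cds$product),
               stringsAsFactors = FALSE)
  }))
  if (is.null(ann)) {
    ann <- data.frame(genome_id = character(), locus_id = character(),
                      start = integer(), end = integer(),
                      strand = character(), product = character())
  }
  write.table(ann, annotation, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(fasta, annotation))
}

#' Read a cohort metadata table
#'
#' Expects TSV columns: genome_id, size_bp, cds_count, trna_count,
#' gc_percent, integrase (yes/no/low_confidence); optional family.
#' A size_class column is appended via [size_class()].
#'
#' @param path TSV path.
#' @param bounds size-class thresholds passed to [size_class()].
#' @return data.frame, one row per genome.
#' @export
read_cohort_table <- function(path, bounds = c(1e5, 2e5)) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("genome_id", "size_bp", "cds_count", "trna_count",
            "gc_percent", "integrase")
  pv_assert(all(need %in% names(tab)),
            sprintf("cohort table %s: missing columns %s", path,
                    paste(setdiff(need, names(tab)), collapse = ", ")))
  pv_assert(!anyDuplicated(tab$genome_id), "duplicate genome ids")
  tab$size_class <- vapply(tab$size_bp, size_class, character(1),
                           bounds = bounds)
  tab
}

#' Genome size class
#'
#' Buckets a genome length into small / medium / large. The default
#' bounds (100 kb, 200 kb) separate the three natural size groups of
#' *Aeromonas salmonicida* phage genomes (~41-48 kb, ~160-175 kb,
#' ~222-237 kb).
#'
#' @param length_bp positive genome length.
#' @param bounds two increasing thresholds.
#' @return "small", "medium" or "large".
#' @export
size_class <- function(length_bp, bounds = c(1e5, 2e5)) {
  pv_assert(length(length_bp) == 1 && length_bp > 0,
            "size_class: length must be a positive scalar")
  pv_assert(length(bounds) == 2 && bounds[1] < bounds[2],
            "size_class: bounds must be two increasing thresholds")
  if (length_bp < bounds[1]) "small"
  else if (length_bp < bounds[2]) "medium"
  else "large"
}

#' Per-group mean and SD of a cohort column
#'
#' Computes the printed-scale aggregates (GC% as percent, sizes in bp)
#' for an arbitrary partition of the cohort. SD uses the n-1
#' denominator; a singleton group reports SD as NA (undefined), not 0.
#'
#' @param table cohort data.frame from [read_cohort_table()].
#' @param column one of "gc_percent", "size_bp", "cds_count",
#'   "trna_count".
#' @param grouping either a column name of `table` (e.g. "size_class")
#'   or a named list mapping group label -> vector of genome ids
#'   partitioning the cohort.
#' @return data.frame with columns group, mean, sd, n.
#' @export
summarize_by_class <- function(table, column = "gc_percent",
                               grouping = "size_class") {
  pv_assert(column %in% names(table),
            sprintf("no column %s in cohort table", column))
  if (is.character(grouping) && length(grouping) == 1) {
    pv_assert(grouping %in% names(table),
              sprintf("no grouping column %s", grouping))
    groups <- split(table$genome_id, table[[grouping]])
  } else {
    groups <- grouping
    pv_assert(is.list(groups) && length(groups) > 0 &&
                all(lengths(groups) > 0),
              "grouping groups must be non-empty")
    pv_assert(all(unlist(groups) %in% table$genome_id),
              "grouping references unknown genome ids")
  }
  out <- do.call(rbind, lapply(names(groups), function(gname) {
    vals <- table[[column]][match(groups[[gname]], table$genome_id)]
    data.frame(group = gname, mean = mean(vals),
               sd = if (length(vals) > 1) sd(vals) else NA_real_,
               n = length(vals), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Find open reading frames on both strands
#'
#' Simple ORF caller for running the pipeline on bare FASTA when no
#' annotation is supplied: scans the six frames for ATG/GTG/TTG starts
#' through to the next in-frame stop (genetic code table 11), keeps
#' ORFs of at least `min_aa` amino acids, and resolves overlaps by
#' greedy longest-first selection on genome coordinates.
#'
#' @param seq DNA string.
#' @param min_aa minimum protein length (>= 10).
#' @return data.frame of CDS records (locus_id, start, end, strand,
#'   nt_seq, aa_seq), possibly empty.
#' @export
find_orfs <- function(seq, min_aa = 50L) {
  pv_assert(min_aa >= 10, "find_orfs: min_aa must be >= 10")
  seq <- toupper(seq)
  len <- nchar(seq)
  starts_ok <- c("ATG", "GTG", "TTG")
  stops <- c("TAA", "TAG", "TGA")
  scan_strand <- function(s, strand) {
    out <- list()
    slen <- nchar(s)
    for (frame in 0:2) {
      n_cod <- (slen - frame) %/% 3L
      if (n_cod < min_aa + 1) next
      pos <- frame + 3L * (seq_len(n_cod) - 1L) + 1L
      codons <- substring(s, pos, pos + 2L)
      is_stop <- codons %in% stops
      is_start <- codons %in% starts_ok
      # segment between stops; first start in each segment opens the ORF
      seg <- cumsum(c(TRUE, head(is_stop, -1)))
      for (sg in split(seq_along(codons), seg)) {
        k <- sg[length(sg)]
        if (!is_stop[k]) next # no terminating stop: skip (incomplete)
        body <- sg[-length(sg)]
        st <- body[is_start[body]]
        if (length(st) == 0) next
        i <- st[1]
        aa_len <- k - i # codons before the stop
        if (aa_len < min_aa) next
        out[[length(out) + 1]] <- c(from = pos[i], to = pos[k] + 2L,
                                    strand = strand)
      }
    }
    out
  }
  cand <- scan_strand(seq, "+")
  rc <- pv_revcomp(seq)
  for (o in scan_strand(rc, "-")) {
    # map reverse-strand coords back to the forward genome
    from <- len - as.integer(o[["to"]]) + 1L
    to <- len - as.integer(o[["from"]]) + 1L
    cand[[length(cand) + 1]] <- c(from = from, to = to, strand = "-")
  }
  if (length(cand) == 0) {
    return(data.frame(locus_id = character(), start = integer(),
                      end = integer(), strand = character(),
                      nt_seq = character(), aa_seq = character()))
  }
  cand_df <- data.frame(start = vapply(cand, function(x) as.integer(x[["from"]]), 0L),
                        end = vapply(cand, function(x) as.integer(x[["to"]]), 0L),
                        strand = vapply(cand, function(x) x[["strand"]], ""),
                        stringsAsFactors = FALSE)
  cand_df <- cand_df[order(-(cand_df$end - cand_df$start), cand_df$start), ]
  keep <- logical(0); sel <- cand_df[0, ]
  for (i in seq_len(nrow(cand_df))) {
    r <- cand_df[i, ]
    if (nrow(sel) == 0 ||
        all(r$end < sel$start | r$start > sel$end)) {
      sel <- rbind(sel, r)
    }
  }
  sel <- sel[order(sel$start), ]
  nt <- substring(seq, sel$start, sel$end)
  minus <- sel$strand == "-"
  nt[minus] <- vapply(nt[minus], pv_revcomp, character(1))
  data.frame(locus_id = sprintf("orf_%03d", seq_len(nrow(sel))),
             start = sel$start, end = sel$end, strand = sel$strand,
             nt_seq = nt,
             aa_seq = vapply(nt, function(x) sub("\\*$", "", pv_translate(x)),
                             character(1)),
             stringsAsFactors = FALSE, row.names = NULL)
}
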