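#' Synthetic phage cohorts with planted ground truth
#'
#' Generates cohorts of phage genomes whose every downstream signal is
#' known by construction: planted genome groups with group-core gene
#' clusters (plus configurable cross-group sharing and singletons),
#' per-genome GC% hit by a one-parameter exponential tilt on codon
#' choice, tRNA counts perfectly coupled to GC class, group-linked DNA
#' packaging strategies with labeled terminase references,
#' lysotype-structured host ranges over a mixed psychrophilic /
#' mesophilic isolate panel, and one-step growth curves with known
#' burst size and latent period. Defaults mirror the structure of an
#' 18-genome *Aeromonas salmonicida* phage cohort (six groups of sizes
#' 4/2/1/8/2/1; small genomes high-GC and tRNA-free, medium/large
#' genomes low-GC and tRNA-bearing; 13 headful / 1 short-DTR / 4 cos
#' packaging calls) at a desk-scale cluster count.
#'
#' @name synth_cohort
NULL

#' Build a cohort specification
#'
#' @param n_groups number of planted genome groups.
#' @param genomes_per_group integer vector of group sizes.
#' @param core_clusters_per_group gene clusters core to each group.
#' @param shared_clusters named list "i-j" -> count of clusters core to
#'   both groups i and j (on top of the group cores).
#' @param singleton_rate singletons per genome as a fraction of
#'   `core_clusters_per_group`.
#' @param noise_clusters accessory clusters present in a random subset
#'   of genomes irrespective of group. These emulate the scattered
#'   cross-group gene sharing of real phage pan-genomes; without them
#'   the deep (above-group) edges of the dendrogram are artificially
#'   stable under column resampling and the AU cut cannot delimit
#'   groups.
#' @param gc_targets per-group genomic GC fraction in (0, 1).
#' @param trna_rule list with `low` and `high` tRNA count ranges for
#'   genomes below/above 50% GC (default: low-GC genomes carry 10-25
#'   tRNAs, high-GC genomes none — the perfect association).
#' @param protein_length_distribution c(mean, sd) in amino acids.
#' @param divergence_within_group per-site substitution probability
#'   between a cluster member and its ancestor.
#' @param packaging_per_group packaging strategy per group.
#' @param lysotype_per_group host-range class per group ("narrow",
#'   "intermediate", "broad").
#' @param n_isolates host panel size (default 65: 61 psychrophilic, 4
#'   mesophilic).
#' @param size_targets per-group genome length targets in bp (reached
#'   by intergenic padding); defaults give three size classes under
#'   `size_class_bounds`.
#' @param size_class_bounds size-class thresholds appropriate for the
#'   synthetic scale (passed downstream, e.g. to [size_class()]).
#' @param growth_burst_range,growth_latent_range per-phage burst sizes
#'   and latent periods are drawn uniformly from these ranges.
#' @param seed integer; the single source of randomness.
#' @return list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_groups = 6,
                        genomes_per_group = c(4, 2, 1, 8, 2, 1),
                        core_clusters_per_group = 12,
                        shared_clusters = list("4-5" = 6, "5-6" = 4,
                                               "3-6" = 1),
                        singleton_rate = 0.25,
                        noise_clusters = 15,
                        gc_targets = c(0.57, 0.55, 0.57, 0.43, 0.42, 0.37),
                        trna_rule = list(low = c(10, 25), high = c(0, 0)),
                        protein_length_distribution = c(150, 40),
                        divergence_within_group = 0.05,
                        packaging_per_group = c("cos_5prime", "headful",
                                                "short_DTR", "headful",
                                                "headful", "headful"),
                        lysotype_per_group = c("intermediate", "narrow",
                                               "intermediate", "broad",
                                               "intermediate",
                                               "intermediate"),
                        n_isolates = 65,
                        size_targets = c(9000, 9000, 9000, 25000, 35000,
                                         35000),
                        size_class_bounds = c(15000, 30000),
                        growth_burst_range = c(2, 10),
                        growth_latent_range = c(120, 160),
                        seed = 1) {
  pv_assert(length(genomes_per_group) == n_groups,
            "genomes_per_group length must equal n_groups")
  pv_assert(length(gc_targets) == n_groups, "one gc_target per group")
  pv_assert(all(gc_targets > 0 & gc_targets < 1), "gc_targets in (0,1)")
  pv_assert(all(genomes_per_group >= 1) && core_clusters_per_group >= 1,
            "counts must be positive")
  pv_assert(length(packaging_per_group) == n_groups,
            "one packaging strategy per group")
  pv_assert(length(lysotype_per_group) == n_groups,
            "one lysotype class per group")
  pv_assert(length(size_targets) == n_groups, "one size target per group")
  for (key in names(shared_clusters)) {
    ij <- as.integer(strsplit(key, "-")[[1]])
    pv_assert(length(ij) == 2 && all(ij >= 1 & ij <= n_groups),
              sprintf("bad shared_clusters key: %s", key),
              "panvirome_validation_error")
    pv_assert(shared_clusters[[key]] <= core_clusters_per_group,
              sprintf("shared clusters for %s exceed core size", key),
              "panvirome_validation_error")
  }
  structure(as.list(environment()), class = "cohort_spec")
}

pick_int_global <- function(lo, hi) {
  if (lo >= hi) lo else lo + sample.int(hi - lo + 1L, 1) - 1L
}

pv_aa_letters <- function() {
  sort(unique(unname(pv_genetic_code()[pv_genetic_code() != "*"])))
}

pv_random_protein <- function(len) {
  # proteins open with Met so planted CDSs are genuine ORFs
  paste(c("M", sample(pv_aa_letters(), len - 1, replace = TRUE)),
        collapse = "")
}

pv_mutate_protein <- function(aa, divergence) {
  if (divergence <= 0) return(aa)
  chars <- strsplit(aa, "", fixed = TRUE)[[1]]
  hit <- runif(length(chars)) < divergence
  hit[1] <- FALSE # start residue conserved
  if (any(hit)) {
    letters20 <- pv_aa_letters()
    chars[hit] <- vapply(chars[hit], function(old) {
      sample(setdiff(letters20, old), 1)
    }, "")
  }
  paste(chars, collapse = "")
}

# codon GC count per codon, and synonymous families keyed by aa
pv_codon_gc <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      codons <- names(pv_genetic_code())
      cache <<- vapply(strsplit(codons, ""), function(ch)
        sum(ch %in% c("G", "C")), 0)
      names(cache) <<- codons
    }
    cache
  }
})

# solve the exponential codon tilt so expected coding GC hits the target
pv_solve_gc_beta <- function(aa_freq, target_gc) {
  code <- pv_genetic_code()
  fam_all <- split(names(code)[code != "*"], code[code != "*"])
  gcc <- pv_codon_gc()
  expected <- function(beta) {
    e <- 0
    for (aa in names(aa_freq)) {
      codons <- fam_all[[aa]]
      w <- exp(beta * gcc[codons])
      e <- e + aa_freq[[aa]] * sum(w * gcc[codons]) / sum(w) / 3
    }
    e
  }
  lo <- expected(-15); hi <- expected(15)
  pv_assert(target_gc > lo && target_gc < hi,
            sprintf("GC target %.2f outside achievable range [%.2f, %.2f]",
                    target_gc, lo, hi),
            "panvirome_validation_error")
  stats::uniroot(function(b) expected(b) - target_gc, c(-15, 15),
                 tol = 1e-8)$root
}

# reverse-translate a protein with GC-tilted codon choice; appends a stop
pv_codonize <- function(aa, beta) {
  code <- pv_genetic_code()
  fam_all <- split(names(code)[code != "*"], code[code != "*"])
  stops_w <- exp(beta * pv_codon_gc()[pv_stop_codons])
  gcc <- pv_codon_gc()
  chars <- strsplit(aa, "", fixed = TRUE)[[1]]
  codons <- vapply(chars, function(a) {
    cs <- fam_all[[a]]
    w <- exp(beta * gcc[cs])
    sample(cs, 1, prob = w)
  }, "")
  stop_c <- sample(pv_stop_codons, 1, prob = stops_w)
  paste(c(codons, stop_c), collapse = "")
}

pv_random_spacer <- function(len, gc) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), len, replace = TRUE, prob = p), collapse = "")
}

# stop codons in all three frames of both strands ("TAA" at relative
# positions 1/5/9 covers every frame for any placement; the reverse
# complement tail does the same for the minus strand); placed at the
# head of every intergenic spacer so open reading frames cannot run
# through intergenic DNA
pv_stop_cassette <- "TAAATAAATAATTATTTATTTA"

pv_intergenic <- function(len, gc) {
  tail_len <- max(0L, len - nchar(pv_stop_cassette))
  paste0(pv_stop_cassette, pv_random_spacer(tail_len, gc))
}

#' Generate a synthetic phage cohort
#'
#' All randomness flows from `spec$seed`; the same spec yields
#' byte-identical outputs. When `dir` is given, the cohort is also
#' written to disk (genomes.fasta, annotation.tsv, cohort.tsv,
#' host_range.tsv, isolates.tsv, growth.tsv, terminase.fasta,
#' ground_truth.json).
#'
#' @param spec a [cohort_spec()].
#' @param dir optional output directory (created if missing).
#' @param noise_cv multiplicative noise CV for the growth curves
#'   (default 0.1).
#' @return list with `genomes` (list of `phage_genome`),
#'   `cohort_table`, `host_range` (`host_range_matrix`), `growth`
#'   (list of `growth_curve`), `terminase` (named protein vector),
#'   `terminase_labels` (reference -> strategy), and `truth` (groups,
#'   clusters, packaging, lysotype, breadth, growth parameters,
#'   gc_targets).
#' @export
generate_cohort <- function(spec, dir = NULL, noise_cv = 0.1) {
  pv_assert(inherits(spec, "cohort_spec"), "spec must be a cohort_spec")
  set.seed(spec$seed)
  ng <- spec$n_groups
  sizes <- spec$genomes_per_group
  genome_ids <- unlist(lapply(seq_len(ng), function(g)
    sprintf("G%d_P%d", g, seq_len(sizes[g]))))
  group_of <- rep(seq_len(ng), sizes)
  names(group_of) <- genome_ids

  plen <- spec$protein_length_distribution
  draw_len <- function(n) pmax(50L, as.integer(round(rnorm(n, plen[1],
                                                           plen[2]))))
  # cluster ancestors: per-group cores, cross-group shared, singletons
  clusters <- list() # cluster id -> list(ancestor, members = genome ids)
  for (g in seq_len(ng)) {
    for (k in seq_len(spec$core_clusters_per_group)) {
      cid <- sprintf("core_g%d_%03d", g, k)
      clusters[[cid]] <- list(ancestor = pv_random_protein(draw_len(1)),
                              genomes = genome_ids[group_of == g])
    }
  }
  for (key in names(spec$shared_clusters)) {
    ij <- as.integer(strsplit(key, "-")[[1]])
    for (k in seq_len(spec$shared_clusters[[key]])) {
      cid <- sprintf("shared_g%d_g%d_%03d", ij[1], ij[2], k)
      clusters[[cid]] <- list(ancestor = pv_random_protein(draw_len(1)),
                              genomes = genome_ids[group_of %in% ij])
    }
  }
  n_gen <- length(genome_ids)
  for (k in seq_len(spec$noise_clusters)) {
    cid <- sprintf("acc_%03d", k)
    sz <- pick_int_global(2L, max(2L, n_gen %/% 2L))
    clusters[[cid]] <- list(ancestor = pv_random_protein(draw_len(1)),
                            genomes = sort(sample(genome_ids, sz)))
  }
  n_single <- max(0L, round(spec$singleton_rate *
                              spec$core_clusters_per_group))
  for (gid in genome_ids) {
    for (k in seq_len(n_single)) {
      cid <- sprintf("single_%s_%03d", gid, k)
      clusters[[cid]] <- list(ancestor = pv_random_protein(draw_len(1)),
                              genomes = gid)
    }
  }

  # per-genome protein sets (mutated from cluster ancestors)
  truth_members <- list()
  proteins <- setNames(vector("list", length(genome_ids)), genome_ids)
  for (cid in names(clusters)) {
    cl <- clusters[[cid]]
    for (gid in cl$genomes) {
      locus <- sprintf("%s_%s", gid, cid)
      aa <- pv_mutate_protein(cl$ancestor, spec$divergence_within_group)
      proteins[[gid]][[locus]] <- aa
      truth_members[[cid]] <- rbind(truth_members[[cid]],
                                    data.frame(genome = gid, locus = locus,
                                               stringsAsFactors = FALSE))
    }
  }

  # assemble genomes: GC-tilted codons, spacers, random strand
  genomes <- list()
  trna_counts <- integer(length(genome_ids))
  names(trna_counts) <- genome_ids
  for (gi in seq_along(genome_ids)) {
    gid <- genome_ids[gi]
    gc_t <- spec$gc_targets[group_of[gid]]
    prots <- proteins[[gid]]
    aa_all <- strsplit(paste(unlist(prots), collapse = ""), "")[[1]]
    aa_freq <- table(aa_all) / length(aa_all)
    beta <- pv_solve_gc_beta(as.list(aa_freq), gc_t)
    pieces <- character(0)
    ann <- data.frame(locus_id = character(), start = integer(),
                      end = integer(), strand = character(),
                      product = character(), stringsAsFactors = FALSE)
    pos <- 1L
    for (locus in names(prots)) {
      spacer <- pv_intergenic(sample(40:120, 1), gc_t)
      pieces <- c(pieces, spacer)
      pos <- pos + nchar(spacer)
      nt <- pv_codonize(prots[[locus]], beta)
      strand <- sample(c("+", "-"), 1)
      pieces <- c(pieces, if (strand == "+") nt else pv_revcomp(nt))
      ann <- rbind(ann, data.frame(locus_id = locus, start = pos,
                                   end = pos + nchar(nt) - 1L,
                                   strand = strand, product = "synthetic",
                                   stringsAsFactors = FALSE))
      pos <- pos + nchar(nt)
    }
    pieces <- c(pieces, pv_intergenic(sample(40:120, 1), gc_t))
    seq <- paste(pieces, collapse = "")
    pad <- spec$size_targets[group_of[gid]] - nchar(seq)
    if (pad > 0) {
      # padding GC compensates the AT-rich stop cassettes and codon
      # sampling noise so the whole genome hits the target
      chars <- strsplit(seq, "", fixed = TRUE)[[1]]
      gc_now <- sum(chars %in% c("G", "C"))
      gc_pad <- (gc_t * (nchar(seq) + pad) - gc_now) / pad
      gc_pad <- min(0.95, max(0.05, gc_pad))
      seq <- paste0(seq, pv_random_spacer(pad, gc_pad))
    }
    rule <- if (gc_t < 0.5) spec$trna_rule$low else spec$trna_rule$high
    trna_counts[gid] <- if (rule[1] == rule[2]) rule[1] else
      sample(rule[1]:rule[2], 1)
    genomes[[gid]] <- phage_genome(gid, seq, cds = ann,
                                   trna_count = trna_counts[gid])
  }

  cohort_table <- data.frame(
    genome_id = genome_ids,
    size_bp = vapply(genomes, `[[`, 0L, "length_bp"),
    cds_count = vapply(genomes, function(g) nrow(g$cds), 0L),
    trna_count = trna_counts,
    gc_percent = vapply(genomes, `[[`, 0, "gc_percent"),
    integrase = "no",
    stringsAsFactors = FALSE, row.names = NULL)
  cohort_table$size_class <- vapply(cohort_table$size_bp, size_class, "",
                                    bounds = spec$size_class_bounds)

  # terminase references and queries
  strategies <- unique(spec$packaging_per_group)
  term_anc <- setNames(lapply(strategies, function(s)
    pv_random_protein(400L)), strategies)
  term_refs <- list()
  for (s in strategies) {
    for (k in 1:3) {
      term_refs[[sprintf("ref_%s_%d", s, k)]] <-
        pv_mutate_protein(term_anc[[s]], 0.15)
    }
  }
  term_labels <- setNames(rep(strategies, each = 3), names(term_refs))
  term_queries <- setNames(lapply(genome_ids, function(gid) {
    pv_mutate_protein(term_anc[[spec$packaging_per_group[group_of[gid]]]],
                      0.08)
  }), paste0("terml_", genome_ids))
  terminase <- c(unlist(term_refs), unlist(term_queries))

  # host range: planted lysotype breadths over the psychrophilic panel
  n_iso <- spec$n_isolates
  n_meso <- max(1L, round(4 * n_iso / 65))
  n_psy <- n_iso - n_meso
  iso_ids <- c(sprintf("psy_%02d", seq_len(n_psy)),
               sprintf("meso_%02d", seq_len(n_meso)))
  iso_meta <- data.frame(
    isolate_id = iso_ids,
    lifestyle = c(rep("psychrophilic", n_psy), rep("mesophilic", n_meso)),
    subspecies = c(rep("salmonicida", n_psy),
                   c(rep("indian", max(0, n_meso - 1)), "pectinolytica")),
    stringsAsFactors = FALSE)
  f <- n_iso / 65
  pick_int <- function(lo, hi) {
    if (lo >= hi) lo else lo + sample.int(hi - lo + 1L, 1) - 1L
  }
  breadth_draw <- function(class) {
    rng <- switch(class,
                  narrow = c(1, max(1, floor(4 * f))),
                  intermediate = c(ceiling(10 * f), floor(30 * f)),
                  broad = c(ceiling(45 * f), min(n_psy, floor(60 * f))))
    pick_int(rng[1], rng[2])
  }
  lysotype <- spec$lysotype_per_group[group_of]
  names(lysotype) <- genome_ids
  exps <- matrix(NA_real_, length(genome_ids), n_iso,
                 dimnames = list(genome_ids, iso_ids))
  planted_breadth <- integer(length(genome_ids))
  names(planted_breadth) <- genome_ids
  for (gid in genome_ids) {
    b <- breadth_draw(lysotype[gid])
    sens <- sample(seq_len(n_psy), b)
    exps[gid, sens] <- sample(3:7, b, replace = TRUE)
    planted_breadth[gid] <- b
  }
  # one mesophilic exception: first intermediate-class phage lyses the
  # pectinolytica isolate weakly
  inter <- genome_ids[lysotype == "intermediate"]
  if (length(inter) > 0 && n_meso > 0) {
    exps[inter[1], n_psy + n_meso] <- 2
    planted_breadth[inter[1]] <- planted_breadth[inter[1]] + 1L
  }
  raw <- matrix(ifelse(is.na(exps), "none", as.character(exps)),
                nrow = nrow(exps), dimnames = dimnames(exps))
  host_range <- encode_matrix(raw, iso_meta)

  # growth curves
  gp_burst <- sample(spec$growth_burst_range[1]:spec$growth_burst_range[2],
                     length(genome_ids), replace = TRUE)
  gp_latent <- round(runif(length(genome_ids),
                           spec$growth_latent_range[1],
                           spec$growth_latent_range[2]))
  growth <- list()
  for (gi in seq_along(genome_ids)) {
    growth[[genome_ids[gi]]] <- generate_growth_curve(
      burst = gp_burst[gi], latent_min = gp_latent[gi],
      noise_cv = noise_cv, seed = NULL,
      phage_id = genome_ids[gi])
  }

  truth <- list(
    groups = setNames(group_of, genome_ids),
    clusters = truth_members,
    packaging = setNames(spec$packaging_per_group[group_of], genome_ids),
    lysotype = lysotype,
    breadth = planted_breadth,
    growth = data.frame(phage_id = genome_ids, burst = gp_burst,
                        latent_min = gp_latent, stringsAsFactors = FALSE),
    gc_targets = setNames(spec$gc_targets[group_of], genome_ids))

  out <- list(genomes = genomes, cohort_table = cohort_table,
              host_range = host_range, growth = growth,
              terminase = terminase, terminase_labels = term_labels,
              truth = truth, spec = spec)

  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    write_genomes(genomes, file.path(dir, "genomes.fasta"),
                  file.path(dir, "annotation.tsv"))
    write.table(cohort_table, file.path(dir, "cohort.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    hr <- data.frame(phage_id = rownames(raw), raw, check.names = FALSE,
                     stringsAsFactors = FALSE)
    write.table(hr, file.path(dir, "host_range.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(iso_meta, file.path(dir, "isolates.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    gdf <- do.call(rbind, lapply(growth, function(cv)
      data.frame(phage_id = cv$phage_id, time_min = cv$time_min,
                 pfu_ml = cv$pfu_ml, stringsAsFactors = FALSE)))
    write.table(gdf, file.path(dir, "growth.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    tset <- Biostrings::AAStringSet(terminase)
    names(tset) <- vapply(names(terminase), function(nm) {
      if (nm %in% names(term_labels))
        sprintf("%s strategy=%s role=reference", nm, term_labels[nm])
      else sprintf("%s role=query", nm)
    }, "")
    Biostrings::writeXStringSet(tset, file.path(dir, "terminase.fasta"),
                                width = 60)
    json <- jsonlite::toJSON(list(
      groups = as.list(truth$groups), packaging = as.list(truth$packaging),
      lysotype = as.list(truth$lysotype),
      breadth = as.list(truth$breadth), growth = truth$growth),
      auto_unbox = TRUE, digits = NA)
    writeLines(json, file.path(dir, "ground_truth.json"))
    out$dir <- dir
  }
  out
}

#' Generate a one-step growth curve
#'
#' Step-like log-titer series: a pre-burst plateau, a linear (in log
#' titer) rise of width `rise_min` centered on the latent period, and a
#' post-burst plateau at `burst` times the pre-plateau titer, with
#' multiplicative lognormal noise of coefficient of variation
#' `noise_cv`. Default sampling mirrors the assay protocol: every 30
#' minutes up to 210 minutes.
#'
#' @param burst burst size (>= 1).
#' @param latent_min latent period in minutes.
#' @param sampling_min sampling interval (default 30).
#' @param t_max last sampling time (default 210).
#' @param rise_min width of the rise phase (default 30).
#' @param noise_cv multiplicative noise CV (0 = noise-free).
#' @param titer0 pre-burst titer (PFU/ml).
#' @param seed optional seed (NULL inherits the ambient RNG state).
#' @param phage_id optional label.
#' @return a [growth_curve()].
#' @export
generate_growth_curve <- function(burst, latent_min, sampling_min = 30,
                                  t_max = 210, rise_min = 30,
                                  noise_cv = 0, titer0 = 1e6, seed = NULL,
                                  phage_id = NA_character_) {
  pv_assert(burst >= 1, "burst must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  t <- seq(0, t_max, by = sampling_min)
  a <- log10(titer0); b <- a + log10(burst)
  t0 <- latent_min - rise_min / 2; t1 <- latent_min + rise_min / 2
  y <- ifelse(t <= t0, a, ifelse(t >= t1, b,
                                 a + (b - a) * (t - t0) / (t1 - t0)))
  pfu <- 10^y
  if (noise_cv > 0) {
    sdlog <- sqrt(log(1 + noise_cv^2))
    pfu <- pfu * exp(rnorm(length(pfu), -sdlog^2 / 2, sdlog))
  }
  growth_curve(t, pfu, phage_id)
}

#' Simulate a codon alignment under neutral or positive selection
#'
#' Each sequence evolves independently from a common stop-free ancestor
#' by random single-nucleotide substitutions; a proposed substitution
#' creating a stop codon is discarded, a nonsynonymous one is accepted
#' with probability min(1, omega) and a synonymous one with probability
#' min(1, 1/omega). omega = 1 is neutral; omega = 3 plants a 3x
#' nonsynonymous excess.
#'
#' @param n_seq number of sequences.
#' @param n_codons alignment length in codons.
#' @param divergence expected substitution attempts per nucleotide site
#'   per sequence.
#' @param omega nonsynonymous/synonymous acceptance ratio.
#' @param structured_pairs when TRUE (and `n_seq` is even), sequences
#'   evolve along a balanced pair tree — the ancestor begets n_seq/2
#'   pair ancestors, each begetting two tips — so windows carry a
#'   stable, recoverable topology (needed by the breakpoint scan).
#'   When FALSE every sequence descends independently (a star tree).
#' @param seed integer seed.
#' @return named character vector of equal-length in-frame nucleotide
#'   sequences (already codon-aligned by construction).
#' @export
simulate_codon_alignment <- function(n_seq = 6, n_codons = 100,
                                     divergence = 0.05, omega = 1,
                                     structured_pairs = FALSE, seed = 1) {
  set.seed(seed)
  code <- pv_genetic_code()
  sense <- names(code)[code != "*"]
  anc <- sample(sense, n_codons, replace = TRUE)
  bases <- c("A", "C", "G", "T")
  evolve <- function(codons, rate) {
    n_events <- stats::rpois(1, rate * 3 * n_codons)
    for (e in seq_len(n_events)) {
      pos <- sample.int(3 * n_codons, 1)
      ci <- (pos - 1) %/% 3 + 1
      wi <- (pos - 1) %% 3 + 1
      old_codon <- codons[ci]
      new_base <- sample(setdiff(bases, substr(old_codon, wi, wi)), 1)
      new_codon <- old_codon
      substr(new_codon, wi, wi) <- new_base
      if (code[new_codon] == "*") next
      syn <- code[new_codon] == code[old_codon]
      p_acc <- if (syn) min(1, 1 / omega) else min(1, omega)
      if (runif(1) < p_acc) codons[ci] <- new_codon
    }
    codons
  }
  out <- character(n_seq)
  if (structured_pairs && n_seq %% 2 == 0) {
    for (p in seq_len(n_seq / 2)) {
      pair_anc <- evolve(anc, divergence)
      out[2 * p - 1] <- paste(evolve(pair_anc, divergence / 2),
                              collapse = "")
      out[2 * p] <- paste(evolve(pair_anc, divergence / 2), collapse = "")
    }
  } else {
    for (s in seq_len(n_seq)) {
      out[s] <- paste(evolve(anc, divergence), collapse = "")
    }
  }
  names(out) <- sprintf("seq%02d", seq_len(n_seq))
  out
}
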