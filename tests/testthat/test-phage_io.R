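test_that("gc_content matches direct counts and excludes N", {
  expect_equal(gc_content("ATGC"), 50)
  expect_equal(gc_content("GGCC"), 100)
  expect_equal(gc_content("ATATATGC"), 25) # 2 GC / 8
  expect_equal(gc_content("ATGCNNNN"), 50) # N excluded both sides
  expect_error(gc_content("NNN"), "unambiguous")
  expect_error(gc_content(""), "non-empty")
})

test_that("gc_content is invariant under reverse complement", {
  set.seed(1)
  for (k in 1:20) {
    s <- paste(sample(c("A", "C", "G", "T", "N"), 60, replace = TRUE),
               collapse = "")
    if (grepl("[ACGT]", s)) {
      expect_equal(gc_content(s), gc_content(panvirome:::pv_revcomp(s)))
    }
  }
})

test_that("phage_genome extracts CDS respecting strand and validates", {
  g <- phage_genome("g1", "ATGAAATAA",
                    cds = data.frame(locus_id = "c1", start = 1, end = 9,
                                     strand = "+"))
  expect_equal(g$cds$nt_seq, "ATGAAATAA")
  expect_equal(g$cds$aa_seq, "MK")
  # minus strand of CAT is ATG
  g2 <- phage_genome("g2", "CATCATCAT",
                     cds = data.frame(locus_id = "c1", start = 1, end = 3,
                                      strand = "-"))
  expect_equal(g2$cds$nt_seq[1], "ATG")
  expect_error(
    phage_genome("g3", "ATG",
                 cds = data.frame(locus_id = "c1", start = 1, end = 10,
                                  strand = "+")),
    "out of bounds")
})

test_that("read/write round trip preserves sequences and features", {
  spec <- cohort_spec(n_groups = 2, genomes_per_group = c(2, 2),
                      gc_targets = c(0.55, 0.42),
                      core_clusters_per_group = 4,
                      shared_clusters = list(), noise_clusters = 2,
                      packaging_per_group = c("headful", "cos_5prime"),
                      lysotype_per_group = c("broad", "narrow"),
                      size_targets = c(6000, 9000), seed = 3)
  co <- generate_cohort(spec)
  fa <- tempfile(fileext = ".fasta"); an <- tempfile(fileext = ".tsv")
  write_genomes(co$genomes, fa, an)
  back <- read_genomes(fa, an)
  expect_setequal(names(back), names(co$genomes))
  for (id in names(back)) {
    expect_identical(back[[id]]$sequence, co$genomes[[id]]$sequence)
    expect_equal(back[[id]]$cds[, c("locus_id", "start", "end", "strand",
                                    "nt_seq", "aa_seq")],
                 co$genomes[[id]]$cds[, c("locus_id", "start", "end",
                                          "strand", "nt_seq", "aa_seq")],
                 ignore_attr = TRUE)
  }
})

test_that("find_orfs finds planted ORFs and respects min_aa", {
  set.seed(9)
  expect_equal(nrow(find_orfs("ATGAAATAA", min_aa = 10)), 0) # too short
  orfs <- find_orfs(paste0("CCCCC", "ATG", strrep("AAA", 12), "TAA",
                           "CCCCC"), min_aa = 10)
  expect_equal(nrow(orfs), 1)
  expect_equal(orfs$start, 6)
  expect_equal(orfs$aa_seq, paste0("M", strrep("K", 12)))
  # no start codon anywhere -> none
  expect_equal(nrow(find_orfs(strrep("C", 300), min_aa = 10)), 0)
  # planted ORFs on both strands recovered; the caller may extend a
  # start upstream to an earlier in-frame start codon in the spacer, so
  # matches are anchored at the stop-codon end
  spec <- cohort_spec(n_groups = 1, genomes_per_group = 2,
                      gc_targets = 0.5, core_clusters_per_group = 6,
                      shared_clusters = list(), noise_clusters = 0,
                      packaging_per_group = "headful",
                      lysotype_per_group = "broad", size_targets = 6000,
                      divergence_within_group = 0,
                      protein_length_distribution = c(180, 20), seed = 4)
  co <- generate_cohort(spec)
  g <- co$genomes[[1]]
  orfs <- find_orfs(g$sequence, min_aa = 50)
  for (k in seq_len(nrow(g$cds))) {
    anchor <- if (g$cds$strand[k] == "+") g$cds$end[k] else g$cds$start[k]
    hit <- if (g$cds$strand[k] == "+") {
      orfs$strand == "+" & orfs$end == anchor
    } else {
      orfs$strand == "-" & orfs$start == anchor
    }
    expect_true(any(hit), info = g$cds$locus_id[k])
  }
})

test_that("size_class reproduces the three genome-size groups", {
  expect_equal(size_class(41572), "small")
  expect_equal(size_class(173590), "medium")
  expect_equal(size_class(236567), "large")
  expect_error(size_class(-5), "positive")
})

test_that("summarize_by_class honors SD conventions and partitions", {
  tab <- data.frame(genome_id = c("a", "b", "c"),
                    gc_percent = c(50, 50, 50),
                    size_bp = c(1e4, 2e4, 3e4),
                    size_class = c("small", "small", "small"))
  out <- summarize_by_class(tab, "gc_percent", "size_class")
  expect_equal(out$sd, 0) # identical values, n > 1
  single <- summarize_by_class(tab, "gc_percent",
                               list(x = "a", rest = c("b", "c")))
  expect_true(is.na(single$sd[single$group == "x"]))
  # singleton partition of everything equals global mean/sd
  all_in <- summarize_by_class(tab, "size_bp",
                               list(all = tab$genome_id))
  expect_equal(all_in$mean, mean(tab$size_bp))
  expect_equal(all_in$sd, sd(tab$size_bp))
})
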