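test_that("codon_align threads codons through the protein alignment", {
  nt <- c(a = "ATGAAACCCGGGACGTTTTAA", b = "ATGAAACCCGGGACGTTTTAA")
  ca <- codon_align(nt)
  expect_false(any(grepl("-", ca$seqs)))
  expect_equal(unname(nchar(ca$seqs)), c(18, 18)) # stop trimmed
  # clean 1-codon deletion -> one '---' column
  nt2 <- c(a = "ATGAAACCCGGGACGTTTTAA", b = "ATGAAAGGGACGTTTTAA")
  ca2 <- codon_align(nt2)
  expect_equal(unname(nchar(ca2$seqs[1])), 18)
  expect_true(grepl("---", ca2$seqs[["b"]], fixed = TRUE))
  gaps <- gregexpr("-", ca2$seqs[["b"]], fixed = TRUE)[[1]]
  expect_equal(length(gaps), 3)
  # internal stop is an error naming sequence and codon
  nt3 <- c(a = "ATGTAAAAATAA", b = "ATGAAAAAATAA")
  expect_error(codon_align(nt3), "internal stop.*a.*2",
               class = "panvirome_validation_error")
})

test_that("ng86_dnds handles trivial and synonymous-only cases", {
  r0 <- ng86_dnds("ATGAAACTG", "ATGAAACTG")
  expect_equal(r0$dN, 0)
  expect_equal(r0$dS, 0)
  # GCT->GCC within Ala context: only synonymous change
  a <- paste0("GCT", "ATGAAACTGATTCGT")
  b <- paste0("GCC", "ATGAAACTGATTCGT")
  r1 <- ng86_dnds(a, b)
  expect_equal(r1$dN, 0)
  expect_gt(r1$dS, 0)
  expect_equal(r1$Sd, 1)
  expect_equal(r1$Nd, 0)
  expect_error(ng86_dnds("ATG", "ATGAAA"), "equal")
})

test_that("ng86_dnds matches the pathway-enumeration oracle to 1e-12", {
  set.seed(37)
  for (k in 1:50) {
    a <- random_codons(10)
    b <- strsplit(a, "")[[1]]
    nmut <- sample(1:6, 1)
    pos <- sample(30, nmut)
    for (p in pos) {
      b[p] <- sample(setdiff(c("A", "C", "G", "T"), b[p]), 1)
    }
    b <- paste(b, collapse = "")
    # regenerate if we created a stop codon (excluded by contract)
    cods <- substring(b, seq(1, 28, 3), seq(3, 30, 3))
    if (any(cods %in% c("TAA", "TAG", "TGA"))) next
    got <- ng86_dnds(a, b)
    ref <- ref_ng86(a, b)
    expect_equal(got$S, ref$S, tolerance = 1e-12)
    expect_equal(got$N, ref$N, tolerance = 1e-12)
    expect_equal(got$Sd, ref$Sd, tolerance = 1e-12)
    expect_equal(got$Nd, ref$Nd, tolerance = 1e-12)
    if (!is.na(ref$dS)) expect_equal(got$dS, ref$dS, tolerance = 1e-12)
    if (!is.na(ref$dN)) expect_equal(got$dN, ref$dN, tolerance = 1e-12)
    # symmetry
    rev <- ng86_dnds(b, a)
    expect_equal(got$Sd, rev$Sd, tolerance = 1e-12)
    expect_equal(got$Nd, rev$Nd, tolerance = 1e-12)
  }
})

test_that("dS and dN respond to planted substitution classes", {
  s_neutral <- simulate_codon_alignment(2, 200, divergence = 0.03,
                                        omega = 1, seed = 41)
  s_more <- simulate_codon_alignment(2, 200, divergence = 0.09,
                                     omega = 1, seed = 41)
  r1 <- ng86_dnds(s_neutral[1], s_neutral[2])
  r2 <- ng86_dnds(s_more[1], s_more[2])
  expect_gte(r2$Sd + r2$Nd, r1$Sd + r1$Nd)
})

test_that("detect_breakpoints: preconditions, clean and recombinant data", {
  s3 <- simulate_codon_alignment(3, 100, seed = 1)
  aln3 <- structure(list(seqs = s3, n_codons = 100, boundaries = NULL),
                    class = "codon_alignment")
  expect_error(detect_breakpoints(aln3), ">= 4",
               class = "panvirome_validation_error")
  # shorter than one window -> single partition
  short <- simulate_codon_alignment(4, 30, seed = 2,
                                    structured_pairs = TRUE)
  aln_s <- structure(list(seqs = short, n_codons = 30, boundaries = NULL),
                     class = "codon_alignment")
  expect_equal(detect_breakpoints(aln_s), integer(0))
  # homogeneous structured alignments: no false breakpoints (5 seeds)
  for (sd in 1:5) {
    s <- simulate_codon_alignment(4, 160, divergence = 0.3,
                                  structured_pairs = TRUE, seed = sd)
    al <- structure(list(seqs = s, n_codons = 160, boundaries = NULL),
                    class = "codon_alignment")
    expect_equal(detect_breakpoints(al), integer(0))
  }
  # two concatenated topologies -> one breakpoint within +-1 window
  a <- simulate_codon_alignment(4, 80, divergence = 0.3,
                                structured_pairs = TRUE, seed = 5)
  b <- simulate_codon_alignment(4, 80, divergence = 0.3,
                                structured_pairs = TRUE, seed = 99)
  cat2 <- setNames(paste0(a, b[c(2, 3, 1, 4)]), names(a))
  aln2 <- structure(list(seqs = cat2, n_codons = 160, boundaries = NULL),
                    class = "codon_alignment")
  bp <- detect_breakpoints(aln2)
  expect_equal(length(bp), 1)
  expect_lt(abs(bp - 80), 60)
})

test_that("cluster_dnds: identical sequences give T = 0, p = 1", {
  s <- random_codons(60, seed = 3)
  aln <- structure(list(seqs = c(a = s, b = s), n_codons = 60,
                        boundaries = NULL), class = "codon_alignment")
  r <- cluster_dnds(aln, B = 200, seed = 1)
  expect_equal(r$T, 0)
  expect_equal(r$p_value, 1)
  expect_false(r$positively_selected)
})

test_that("cluster_dnds respects partition boundaries", {
  s <- simulate_codon_alignment(4, 120, divergence = 0.05, seed = 9)
  aln <- structure(list(seqs = s, n_codons = 120, boundaries = NULL),
                   class = "codon_alignment")
  r <- cluster_dnds(aln, boundaries = 61, B = 100, seed = 1)
  expect_equal(nrow(r), 2)
  expect_equal(r$start, c(1, 61))
  expect_equal(r$end, c(60, 120))
})

test_that("classify_snps classifies planted substitutions", {
  set.seed(42)
  spacer <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                     replace = TRUE), collapse = "")
  cds_nt <- "ATGAAACCCGGGACGTTTGATCATAAGCTTGGATCCTAA"
  seqA <- paste0(spacer(300), cds_nt, spacer(300))
  ann <- data.frame(locus_id = "cds1", start = 301,
                    end = 300 + nchar(cds_nt), strand = "+")
  ga <- phage_genome("A", seqA, ann)
  expect_equal(nrow(classify_snps(ga, ga)), 0) # identical genomes
  seqB <- seqA
  substr(seqB, 301, 301) <- "G" # ATG -> GTG, M>V
  substr(seqB, 100, 100) <- if (substr(seqB, 100, 100) == "A") "C" else "A"
  gb <- phage_genome("B", seqB, ann)
  s <- classify_snps(ga, gb)
  expect_equal(nrow(s), 2)
  ns <- s[s$effect == "nonsynonymous", ]
  expect_equal(ns$aa_change, "M>V")
  expect_equal(ns$codon_change, "ATG>GTG")
  expect_equal(s$effect[s$position_a == 100], "intergenic")
  # diverged pair refused with guidance
  gc_seq <- phage_genome("C", spacer(700))
  expect_error(classify_snps(ga, gc_seq), "homology",
               class = "panvirome_validation_error")
})
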