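test_that("align_pair basics: identity, self-maximality, planted substitution", {
  a <- "MKVLAWRTESMKVLAWRTES"
  hit <- align_pair(a, a)
  expect_equal(hit$identity, 1)
  expect_equal(hit$coverage_q, 1)
  expect_equal(hit$coverage_s, 1)
  set.seed(2)
  for (k in 1:5) {
    s <- random_protein(50)
    rev_s <- paste(rev(strsplit(s, "")[[1]]), collapse = "")
    expect_lte(align_pair(s, rev_s)$score, align_pair(s, s)$score)
  }
  # one substitution over 100 aa -> identity 0.99
  s <- random_protein(100)
  s2 <- s
  substr(s2, 50, 50) <- if (substr(s, 50, 50) == "A") "W" else "A"
  expect_equal(align_pair(s, s2)$identity, 0.99)
  expect_error(align_pair("", "MKV"), "empty|non-empty")
})

test_that("Smith-Waterman agrees with the textbook DP oracle", {
  set.seed(7)
  for (k in 1:100) {
    a <- random_protein(sample(3:12, 1))
    b <- random_protein(sample(3:12, 1))
    expect_equal(align_pair(a, b)$score, ref_sw_score(a, b))
  }
})

test_that("all_vs_all reports reciprocal hits and filters noise", {
  shared <- random_protein(120)
  mk_genome <- function(id, extra_seed) {
    set.seed(extra_seed)
    prots <- c(shared = shared, unique = random_protein(100))
    cds <- data.frame(locus_id = names(prots), start = 1, end = 3,
                      strand = "+")
    g <- list(id = id,
              cds = data.frame(locus_id = names(prots),
                               aa_seq = unname(prots),
                               stringsAsFactors = FALSE))
    g
  }
  g1 <- mk_genome("g1", 11); g2 <- mk_genome("g2", 22)
  hits <- all_vs_all(list(g1, g2))
  sh <- hits$hits[hits$hits$query == "shared", ]
  expect_equal(nrow(sh), 2) # both directions
  expect_equal(sort(unique(hits$hits$query)), "shared")
  # unrelated random proteomes: no hits at defaults
  set.seed(5)
  r1 <- list(id = "r1", cds = data.frame(
    locus_id = paste0("a", 1:5),
    aa_seq = vapply(1:5, function(i) random_protein(100), "")))
  r2 <- list(id = "r2", cds = data.frame(
    locus_id = paste0("b", 1:5),
    aa_seq = vapply(1:5, function(i) random_protein(100), "")))
  expect_equal(nrow(all_vs_all(list(r1, r2))$hits), 0)
})

test_that("bbh_graph applies the reciprocal-best definition", {
  hits <- structure(list(
    hits = data.frame(
      query_genome = c("A", "B", "B"),
      query = c("a1", "b1", "b2"),
      subject_genome = c("B", "A", "A"),
      subject = c("b1", "a1", "a1"),
      score = c(100, 100, 90),
      identity = c(1, 1, 0.9),
      coverage_q = 1, coverage_s = 1, evalue_like = 0),
    self_scores = c(), loci = NULL), class = "pv_hits")
  e <- bbh_graph(hits)
  expect_equal(nrow(e), 1)
  expect_equal(e$locus_a, "a1")
  expect_equal(e$locus_b, "b1")
  # x's best is y but y's best is z -> no edge (x,y)
  hits$hits <- data.frame(
    query_genome = c("A", "B"), query = c("a1", "b1"),
    subject_genome = c("B", "A"), subject = c("b1", "a2"),
    score = c(100, 100), identity = 1, coverage_q = 1, coverage_s = 1,
    evalue_like = 0)
  expect_equal(nrow(bbh_graph(hits)), 0)
})

test_that("cog_triangles merges triangles and falls back to pairs", {
  loci3 <- data.frame(genome = c("A", "B", "C"),
                      locus = c("a1", "b1", "c1"))
  tri <- data.frame(genome_a = c("A", "A", "B"),
                    locus_a = c("a1", "a1", "b1"),
                    genome_b = c("B", "C", "C"),
                    locus_b = c("b1", "c1", "c1"))
  out <- cog_triangles(tri, loci3)
  expect_equal(length(out$clusters), 1)
  expect_equal(nrow(out$clusters[[1]]), 3)
  # two genomes only: clusters are BBH pairs
  loci2 <- data.frame(genome = c("A", "B"), locus = c("a1", "b1"))
  pair <- data.frame(genome_a = "A", locus_a = "a1",
                     genome_b = "B", locus_b = "b1")
  out2 <- cog_triangles(pair, loci2)
  expect_equal(lengths(lapply(out2$clusters, function(m) m$locus)), 2,
               ignore_attr = TRUE)
})

test_that("mcl_cluster separates cliques and isolates singletons", {
  mk_hits <- function(edges, loci) {
    structure(list(
      hits = data.frame(
        query_genome = loci$genome[edges[, 1]],
        query = loci$locus[edges[, 1]],
        subject_genome = loci$genome[edges[, 2]],
        subject = loci$locus[edges[, 2]],
        score = 100, identity = 1, coverage_q = 1, coverage_s = 1,
        evalue_like = 0),
      self_scores = c(), loci = loci), class = "pv_hits")
  }
  loci <- data.frame(genome = paste0("G", 1:7),
                     locus = paste0("p", 1:7))
  # two cliques {1,2,3}, {4,5,6} and singleton 7
  edges <- rbind(c(1, 2), c(2, 3), c(1, 3), c(4, 5), c(5, 6), c(4, 6))
  out <- mcl_cluster(mk_hits(edges, loci))
  sizes <- as.integer(sort(vapply(out$clusters, nrow, 0L)))
  expect_equal(sizes, c(1L, 3L, 3L))
  # very high inflation: only exact duplicates stay together
  spec <- cohort_spec(n_groups = 2, genomes_per_group = c(3, 3),
                      gc_targets = c(0.5, 0.45),
                      core_clusters_per_group = 4,
                      shared_clusters = list(), noise_clusters = 0,
                      packaging_per_group = c("headful", "headful"),
                      lysotype_per_group = c("broad", "broad"),
                      size_targets = c(6000, 6000),
                      divergence_within_group = 0.05, seed = 8)
  co <- generate_cohort(spec)
  hits <- all_vs_all(co$genomes)
  lo <- mcl_cluster(hits, inflation = 1.5)
  hi <- mcl_cluster(hits, inflation = 10)
  expect_gte(length(hi$clusters), length(lo$clusters))
})

test_that("noise-free cohort: orthology recovers planted clusters exactly", {
  spec <- cohort_spec(n_groups = 3, genomes_per_group = c(3, 3, 2),
                      gc_targets = c(0.56, 0.44, 0.40),
                      core_clusters_per_group = 5,
                      shared_clusters = list(), noise_clusters = 4,
                      packaging_per_group = rep("headful", 3),
                      lysotype_per_group = rep("broad", 3),
                      size_targets = rep(8000, 3),
                      divergence_within_group = 0, seed = 21)
  co <- generate_cohort(spec)
  # identical proteins within each cluster
  for (cid in names(co$truth$clusters)) {
    m <- co$truth$clusters[[cid]]
    aa <- vapply(seq_len(nrow(m)), function(k) {
      g <- co$genomes[[m$genome[k]]]
      g$cds$aa_seq[g$cds$locus_id == m$locus[k]]
    }, "")
    expect_equal(length(unique(aa)), 1)
  }
  hits <- all_vs_all(co$genomes)
  cog <- cog_triangles(bbh_graph(hits), hits$loci)
  mcl <- mcl_cluster(hits)
  ix <- intersect_clusterings(cog, mcl)
  truth_keys <- sort(vapply(co$truth$clusters, function(m)
    paste(sort(paste0(m$genome, ":", m$locus)), collapse = "|"), ""))
  ix_keys <- sort(vapply(ix$clusters, function(m)
    paste(sort(paste0(m$genome, ":", m$locus)), collapse = "|"), ""))
  expect_equal(unname(ix_keys), unname(truth_keys))
})

test_that("intersect_clusterings equals brute-force member-set intersection", {
  expect_cluster_equal <- function(a, b) {
    ka <- sort(vapply(a, function(m) paste(sort(paste0(m$genome, ":",
                                                       m$locus)),
                                           collapse = "|"), ""))
    kb <- sort(vapply(b, function(m) paste(sort(paste0(m$genome, ":",
                                                       m$locus)),
                                           collapse = "|"), ""))
    expect_equal(unname(ka), unname(kb))
  }
  set.seed(13)
  loci <- data.frame(genome = rep(c("A", "B"), 5),
                     locus = paste0("p", 1:10))
  rand_clustering <- function(alg) {
    memb <- sample(1:4, 10, replace = TRUE)
    cl <- lapply(split(seq_len(10), memb), function(ix) loci[ix, ])
    panvirome:::pv_cluster_set(unname(cl), alg)
  }
  for (k in 1:10) {
    a <- rand_clustering("cog"); b <- rand_clustering("mcl")
    got <- intersect_clusterings(a, b)
    key <- function(m) paste(sort(paste0(m$genome, ":", m$locus)),
                             collapse = "|")
    brute <- a$clusters[vapply(a$clusters, key, "") %in%
                          vapply(b$clusters, key, "")]
    expect_cluster_equal(got$clusters, brute)
    # subset property: output appears in both inputs
    expect_true(all(vapply(got$clusters, key, "") %in%
                      vapply(a$clusters, key, "")))
    expect_true(all(vapply(got$clusters, key, "") %in%
                      vapply(b$clusters, key, "")))
    # count bound
    expect_lte(length(got$clusters),
               min(length(a$clusters), length(b$clusters)))
  }
})

test_that("identity_matrix normalizes best-hit scores into [0,1]", {
  prots <- c(p1 = random_protein(80), p2 = random_protein(90))
  g1 <- list(id = "g1", cds = data.frame(locus_id = names(prots),
                                         aa_seq = unname(prots)))
  g2 <- list(id = "g2", cds = data.frame(locus_id = names(prots),
                                         aa_seq = unname(prots)))
  hits <- all_vs_all(list(g1, g2))
  im <- identity_matrix(hits)
  expect_equal(unname(im["g1", "g2"]), 1)
  expect_equal(unname(diag(im)), c(1, 1))
  # planted cohort: within-group identity exceeds between-group
  co <- make_recovery_cohort(31, n_groups = 3)
  im <- identity_matrix(all_vs_all(co$genomes))
  grp <- co$truth$groups
  same <- outer(grp, grp, "==") & upper.tri(im)
  diff <- outer(grp, grp, "!=") & upper.tri(im)
  expect_gt(min(im[same]), max(im[diff]))
})

test_that("screen_reference_set flags exact, truncated and random queries", {
  set.seed(17)
  integrase <- random_protein(200)
  ref <- c(int1 = integrase)
  mk <- function(aa) list(id = "g",
                          cds = data.frame(locus_id = "x", aa_seq = aa))
  hitrow <- screen_reference_set(mk(integrase), ref)
  expect_equal(hitrow$verdict, "present")
  trunc <- substr(integrase, 1, 90) # 45% of the reference
  low <- screen_reference_set(mk(trunc), ref)
  expect_equal(low$verdict, "low_confidence")
  none <- screen_reference_set(mk(random_protein(200)), ref)
  expect_equal(nrow(none), 0)
})
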