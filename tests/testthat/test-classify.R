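test_that("binary_distance matches hand counts and ignores joint absences", {
  m <- rbind(a = c(1, 1, 0), b = c(1, 0, 1))
  expect_equal(binary_distance(m)["a", "b"], 2 / 3)
  m2 <- rbind(a = c(1, 1, 0, 0), b = c(1, 1, 0, 0))
  expect_equal(binary_distance(m2)["a", "b"], 0)
  m3 <- rbind(a = c(1, 0), b = c(0, 1))
  expect_equal(binary_distance(m3)["a", "b"], 1)
  # joint absence must not dilute: appending zero columns changes nothing
  m4 <- cbind(m, matrix(0, 2, 5))
  expect_equal(binary_distance(m4)["a", "b"], 2 / 3)
  expect_warning(binary_distance(rbind(a = c(0, 0), b = c(0, 0))),
                 "no clusters")
})

test_that("binary_distance satisfies the triangle inequality", {
  set.seed(11)
  for (k in 1:20) {
    m <- matrix(rbinom(60, 1, 0.5), 5, 12,
                dimnames = list(paste0("g", 1:5), NULL))
    m[rowSums(m) == 0, sample(12, 1)] <- 1
    d <- binary_distance(m)
    for (i in 1:5) for (j in 1:5) for (l in 1:5) {
      expect_lte(d[i, j], d[i, l] + d[l, j] + 1e-12)
    }
  }
})

test_that("pan_hclust merges nearest pairs and honors tie-breaking", {
  d <- matrix(c(0, 0.1, 0.9,
                0.1, 0, 0.9,
                0.9, 0.9, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  hc <- pan_hclust(d)
  expect_equal(hc$merge[1, ], c(-1, -2)) # (A,B) first
  expect_equal(hc$height, c(0.1, 0.9))
  # all-equal distances: deterministic ladder by smallest labels
  de <- matrix(0.5, 4, 4,
               dimnames = list(c("d", "b", "a", "c"),
                               c("d", "b", "a", "c")))
  diag(de) <- 0
  hc1 <- pan_hclust(de)
  hc2 <- pan_hclust(de)
  expect_identical(hc1$merge, hc2$merge)
  # first merge joins the two lexicographically smallest labels (a, b)
  first <- sort(hc1$labels[-hc1$merge[1, ]])
  expect_equal(first, c("a", "b"))
})

test_that("pan_hclust reproduces ultrametric heights exactly", {
  # build an ultrametric distance: ((A,B):h1,(C,D):h2):h3
  lab <- c("A", "B", "C", "D")
  d <- matrix(0.8, 4, 4, dimnames = list(lab, lab))
  d["A", "B"] <- d["B", "A"] <- 0.2
  d["C", "D"] <- d["D", "C"] <- 0.4
  diag(d) <- 0
  hc <- pan_hclust(d, "average")
  expect_equal(sort(hc$height), c(0.2, 0.4, 0.8))
  expect_equal(as.matrix(cophenetic(hc))[lab, lab], d)
})

test_that("multiscale_bootstrap degenerate contracts hold", {
  # perfectly structured matrix: every edge recovered always -> AU 1
  m <- rbind(a = c(rep(1, 6), rep(0, 6)),
             b = c(rep(1, 6), rep(0, 6)),
             c = c(rep(0, 6), rep(1, 6)),
             d = c(rep(0, 6), rep(1, 6)))
  colnames(m) <- paste0("c", 1:12)
  tr <- multiscale_bootstrap(m, n_boot = 200, seed = 1)
  expect_true(all(tr$edges$au == 1))
  # single scale: AU collapses to BP at r = 1
  tr1 <- multiscale_bootstrap(m, scales = 1, n_boot = 200, seed = 1)
  expect_equal(tr1$edges$au, tr1$edges$bp)
  expect_warning(multiscale_bootstrap(m, n_boot = 50, seed = 1),
                 "unstable")
})

test_that("cut_groups implements the AU-threshold contract", {
  mk_tree <- function(merge, au, labels, order) {
    sets <- panvirome:::pv_merge_leaves(merge)
    structure(list(
      hclust = structure(list(merge = merge, height = seq_len(nrow(merge)),
                              order = order, labels = labels,
                              method = "average"), class = "hclust"),
      edges = data.frame(node = seq_len(nrow(merge)), au = au,
                         bp = au, n_leaves = lengths(sets),
                         degenerate = FALSE),
      members = lapply(sets, function(s) labels[s]),
      scales = 1, n_boot = 100), class = "cluster_tree")
  }
  # star-like: nothing supported -> singletons
  merge <- rbind(c(-1, -2), c(1, -3), c(2, -4))
  t_star <- mk_tree(merge, c(0.5, 0.5, 0.6), letters[1:4], 1:4)
  expect_equal(length(unique(cut_groups(t_star))), 4)
  # fully supported caterpillar -> one group
  t_full <- mk_tree(merge, c(0.99, 0.99, 0.99), letters[1:4], 1:4)
  expect_equal(length(unique(cut_groups(t_full))), 1)
  # two supported cherries under an unsupported deep edge -> cherries
  # plus a singleton leaf
  merge2 <- rbind(c(-1, -2), c(-3, -4), c(1, 2), c(3, -5))
  t_two <- mk_tree(merge2, c(0.99, 0.99, 0.5, 0.99), letters[1:5], 1:5)
  g <- cut_groups(t_two)
  expect_equal(length(unique(g)), 3)
  expect_equal(unname(g[c("a", "b")]), c("I", "I"))
  expect_equal(unname(g[c("c", "d")]), c("II", "II"))
  expect_false(g[["e"]] %in% c("I", "II"))
})

test_that("planted groups are recovered through the full chain", {
  co <- make_recovery_cohort(1)
  pan <- cohort_pan_matrix(co)
  tr <- multiscale_bootstrap(pan, n_boot = 1000, seed = 1)
  g <- cut_groups(tr)
  expect_equal(adjusted_rand(g, co$truth$groups[names(g)]), 1)
})

test_that("newick export writes a readable tree with supports", {
  m <- rbind(a = c(1, 1, 0, 0), b = c(1, 1, 0, 1),
             c = c(0, 0, 1, 0), d = c(0, 1, 1, 1))
  colnames(m) <- paste0("c", 1:4)
  tr <- multiscale_bootstrap(m, n_boot = 100, seed = 2)
  f <- tempfile(fileext = ".nwk")
  write_cluster_tree(tr, f)
  phy <- ape::read.tree(f)
  expect_setequal(phy$tip.label, rownames(m))
})
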