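mk_raw <- function(mat) {
  ifelse(is.na(mat), "none", as.character(mat))
}

test_that("encode_matrix maps exponents to scores and round-trips", {
  raw <- rbind(p1 = c("none", "0", "7"), p2 = c("2", "none", "4"))
  colnames(raw) <- paste0("i", 1:3)
  m <- encode_matrix(raw)
  expect_equal(unname(m$scores["p1", ]), c(0L, 1L, 8L))
  expect_false(m$sensitive["p1", "i1"])
  expect_true(m$high["p1", "i3"])    # exponent 7 -> score 8, high
  expect_false(m$high["p2", "i1"])   # exponent 2 -> score 3, low activity
  expect_true(m$sensitive["p2", "i1"])
  # decode round-trip
  back <- decode_matrix(m)
  expect_equal(back["p1", "i3"], 7)
  expect_true(is.na(back["p1", "i1"]))
  expect_error(encode_matrix(rbind(p = c("9"))), "0..7",
               class = "panvirome_validation_error")
})

test_that("breadth counts sensitive isolates", {
  raw <- rbind(zero = rep("none", 65), full = rep("3", 65))
  colnames(raw) <- paste0("i", 1:65)
  m <- encode_matrix(raw)
  expect_equal(breadth(m, "zero"), 0)
  expect_equal(breadth(m, "full"), 65)
  expect_error(breadth(m, "nope"), "unknown")
})

test_that("lysotype thresholds reproduce the printed bands and scale", {
  expect_equal(assign_lysotype_group(4, 65), "narrow")
  expect_equal(assign_lysotype_group(20, 65), "intermediate")
  expect_equal(assign_lysotype_group(57, 65), "broad")
  expect_equal(assign_lysotype_group(41, 65), "unclassified") # gap 31-44
  expect_equal(assign_lysotype_group(7, 65), "unclassified")  # gap 5-9
  # proportional scaling at n = 130
  expect_equal(assign_lysotype_group(8, 130), "narrow")
  expect_equal(assign_lysotype_group(40, 130), "intermediate")
  expect_equal(assign_lysotype_group(114, 130), "broad")
  expect_error(assign_lysotype_group(70, 65), "breadth")
})

test_that("cluster_heatmap merges identical phages first", {
  raw <- rbind(a = c("3", "3", "none", "none"),
               b = c("3", "3", "none", "none"),
               c = c("none", "none", "3", "3"))
  colnames(raw) <- paste0("i", 1:4)
  m <- encode_matrix(raw)
  hm <- cluster_heatmap(m)
  first <- sort(hm$phage_hclust$labels[-hm$phage_hclust$merge[1, ]])
  expect_equal(first, c("a", "b"))
  expect_equal(dim(hm$ordered), dim(m$scores))
  one <- encode_matrix(raw[1, , drop = FALSE])
  expect_error(cluster_heatmap(one), ">= 2",
               class = "panvirome_validation_error")
})

test_that("covering_pairs equals brute-force enumeration", {
  set.seed(14)
  for (k in 1:8) {
    n_ph <- 6; n_iso <- 20
    sens <- matrix(rbinom(n_ph * n_iso, 1, 0.4), n_ph, n_iso,
                   dimnames = list(paste0("p", 1:n_ph),
                                   paste0("i", 1:n_iso)))
    raw <- ifelse(sens == 1, "3", "none")
    m <- encode_matrix(raw)
    targets <- sample(colnames(raw), 10)
    got <- covering_pairs(m, targets)
    brute <- list()
    for (pair in combn(rownames(raw), 2, simplify = FALSE)) {
      if (all(sens[pair[1], targets] | sens[pair[2], targets])) {
        brute[[length(brute) + 1]] <- sort(pair)
      }
    }
    expect_equal(nrow(got), length(brute))
    if (nrow(got) > 0) {
      got_keys <- apply(got[, 1:2], 1, function(x)
        paste(sort(x), collapse = "|"))
      brute_keys <- vapply(brute, paste, "", collapse = "|")
      expect_setequal(unname(got_keys), brute_keys)
      expect_true(all(diff(got$breadth_sum) <= 0)) # ranked
    }
  }
  # complementary halves -> exactly that pair
  raw <- rbind(l = c(rep("3", 5), rep("none", 5)),
               r = c(rep("none", 5), rep("3", 5)),
               z = rep("none", 10))
  colnames(raw) <- paste0("i", 1:10)
  m <- encode_matrix(raw)
  cp <- covering_pairs(m, colnames(raw))
  expect_equal(nrow(cp), 1)
  expect_setequal(unlist(cp[, 1:2]), c("l", "r"))
  # uncoverable isolate -> empty
  raw2 <- raw; raw2[, 1] <- "none"
  expect_equal(nrow(covering_pairs(encode_matrix(raw2), colnames(raw2))), 0)
})

test_that("lifestyle_split reports exceptions and matches the exact test", {
  # fixture mirroring the described panel: 61 psychrophilic isolates with
  # mixed sensitivity, 4 mesophilic all resistant except one cell
  set.seed(15)
  n_psy <- 61; n_meso <- 4; n_ph <- 12
  sens <- cbind(matrix(rbinom(n_ph * n_psy, 1, 0.4), n_ph, n_psy),
                matrix(0, n_ph, n_meso))
  sens[3, n_psy + 4] <- 1 # the single mesophilic exception
  rownames(sens) <- paste0("p", 1:n_ph)
  colnames(sens) <- c(paste0("psy", 1:n_psy), paste0("meso", 1:n_meso))
  meta <- data.frame(isolate_id = colnames(sens),
                     lifestyle = c(rep("psychrophilic", n_psy),
                                   rep("mesophilic", n_meso)),
                     subspecies = "salmonicida")
  m <- encode_matrix(ifelse(sens == 1, "2", "none"), meta)
  res <- lifestyle_split(m)
  expect_equal(nrow(res$exceptions), 1)
  expect_equal(res$exceptions$phage, "p3")
  expect_equal(res$exceptions$isolate, "meso4")
  expect_equal(res$fisher_p, ref_fisher2x2(res$table), tolerance = 1e-9)
  # perfectly split matrix: p equals hypergeometric oracle
  sens2 <- cbind(matrix(1, 12, 10), matrix(0, 12, 10))
  rownames(sens2) <- paste0("p", 1:12)
  colnames(sens2) <- paste0("i", 1:20)
  meta2 <- data.frame(isolate_id = colnames(sens2),
                      lifestyle = rep(c("psychrophilic", "mesophilic"),
                                      each = 10),
                      subspecies = "x")
  m2 <- encode_matrix(ifelse(sens2 == 1, "5", "none"), meta2)
  res2 <- lifestyle_split(m2)
  expect_equal(res2$fisher_p, ref_fisher2x2(res2$table), tolerance = 1e-9)
  # all-sensitive matrix: no split, p = 1
  sens3 <- matrix(1, 4, 6, dimnames = list(paste0("p", 1:4),
                                           paste0("i", 1:6)))
  meta3 <- data.frame(isolate_id = colnames(sens3),
                      lifestyle = rep(c("psychrophilic", "mesophilic"), 3),
                      subspecies = "x")
  res3 <- lifestyle_split(encode_matrix(ifelse(sens3 == 1, "4", "none"),
                                        meta3))
  expect_equal(res3$fisher_p, 1)
})

test_that("breadth is monotone under adding sensitive isolates", {
  raw <- rbind(p = c(rep("2", 5), rep("none", 5)))
  colnames(raw) <- paste0("i", 1:10)
  b0 <- breadth(encode_matrix(raw), "p")
  raw[1, 6] <- "3"
  expect_equal(breadth(encode_matrix(raw), "p"), b0 + 1)
})
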