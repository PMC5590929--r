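test_that("superposition RMSD is zero for identical and rigidly moved sets", {
  set.seed(21)
  a <- random_point_set()
  expect_equal(kabsch_rmsd(a, a), 0, tolerance = 1e-9)
  # random proper rotation + translation leaves RMSD at zero
  r <- quat_rotation_matrix(rnorm(4))
  b <- a %*% t(r) + matrix(rep(c(5, -3, 12), each = 8), ncol = 3)
  expect_equal(kabsch_rmsd(a, b), 0, tolerance = 1e-9)
  # symmetric in its arguments
  c2 <- random_point_set()
  expect_equal(kabsch_rmsd(a, c2), kabsch_rmsd(c2, a), tolerance = 1e-12)
})

test_that("superposition never resorts to reflection", {
  set.seed(22)
  a <- random_point_set()
  mirrored <- a %*% diag(c(-1, 1, 1))
  # a mirrored copy of a chiral point set cannot be superimposed to zero
  expect_gt(kabsch_rmsd(a, mirrored), 0.1)
})

test_that("superposition matches the brute-force quaternion oracle", {
  set.seed(23)
  for (i in 1:5) {
    a <- random_point_set()
    b <- random_point_set()
    expect_equal(kabsch_rmsd(a, b), oracle_min_rmsd(a, b),
                 tolerance = 1e-3)
  }
})

test_that("pairwise matrices are symmetric, zero-diagonal and permutable", {
  set.seed(24)
  w <- replicate(5, random_point_set(), simplify = FALSE)
  names(w) <- paste0("w", 1:5)
  m <- pairwise_matrix(w)
  expect_equal(diag(m), setNames(rep(0, 5), names(w)))
  expect_equal(m, t(m))
  # identical windows give an all-zero matrix
  m0 <- pairwise_matrix(list(a = w[[1]], b = w[[1]], c = w[[1]]))
  expect_true(all(m0 < 1e-9))
  # permuting the input permutes rows/columns consistently
  perm <- c(3, 1, 5, 2, 4)
  m2 <- pairwise_matrix(w[perm])
  expect_equal(m2, m[perm, perm])
  # incomplete windows are a hard error
  ch <- chain_from_angles(angles_for("h", 10), unobserved = 5)
  bad <- suppressWarnings(extract_window(ch, 5))
  expect_error(pairwise_matrix(list(a = bad, b = bad)), "backbone-complete")
})

test_that("complete linkage separates blocks and guarantees the diameter", {
  # two tight blocks far apart -> two clusters, no singlets
  n <- 6
  m <- matrix(10, n, n)
  m[1:3, 1:3] <- 0.5; m[4:6, 4:6] <- 0.8
  diag(m) <- 0
  rownames(m) <- colnames(m) <- paste0("w", 1:n)
  cl <- complete_linkage_clusters(m, 3)
  expect_equal(length(cl$clusters), 2)
  expect_equal(length(cl$singlets), 0)
  expect_setequal(cl$clusters[[1]], c("w1", "w2", "w3"))
  # everything farther than the cut -> all singlets
  m2 <- matrix(5, n, n); diag(m2) <- 0
  rownames(m2) <- colnames(m2) <- paste0("w", 1:n)
  cl2 <- complete_linkage_clusters(m2, 3)
  expect_equal(length(cl2$clusters), 0)
  expect_equal(length(cl2$singlets), n)
  # diameter guarantee on random dissimilarity matrices
  set.seed(25)
  for (i in 1:20) {
    k <- sample(5:20, 1)
    x <- matrix(runif(k * 3, 0, 6), ncol = 3)
    md <- as.matrix(stats::dist(x))
    rownames(md) <- colnames(md) <- paste0("p", seq_len(k))
    cl3 <- complete_linkage_clusters(md, 3)
    for (members in cl3$clusters)
      expect_lte(max(md[members, members]), 3)
  }
})

test_that("cluster labels follow descending size with stable tie-breaks", {
  m <- matrix(10, 7, 7)
  m[1:2, 1:2] <- 1; m[3:5, 3:5] <- 1; m[6:7, 6:7] <- 1
  diag(m) <- 0
  rownames(m) <- colnames(m) <- c("z1", "z2", "a1", "a2", "a3", "b1", "b2")
  cl <- complete_linkage_clusters(m, 3)
  expect_equal(names(cl$clusters), c("A", "B", "C"))
  expect_setequal(cl$clusters[["A"]], c("a1", "a2", "a3"))
  # equal-size clusters ordered by smallest member id
  expect_setequal(cl$clusters[["B"]], c("b1", "b2"))
  expect_setequal(cl$clusters[["C"]], c("z1", "z2"))
})

test_that("consensus secondary structure votes by plurality with C ties", {
  expect_equal(consensus_ss(list("CCCHHHH", "CCCHHHH")), "CCCHHHH")
  expect_equal(consensus_ss(list("HHHHHHH", "HHHHHHH", "EEEEEEE")),
               "HHHHHHH")
  expect_equal(consensus_ss(list("HHHHHHH", "EEEEEEE")), "CCCCCCC")
  # abstentions: NA positions do not vote
  expect_equal(consensus_ss(list(c("H", "H", "H", "H", "H", "H", "H"),
                                 c(NA, "E", NA, NA, NA, NA, NA),
                                 c(NA, "E", NA, NA, NA, NA, NA))),
               "HEHHHHH")
})

test_that("bootstrap null is reproducible and tracks planted structure", {
  tm <- motif_templates()
  # degenerate pool from a single motif: every replicate gives one cluster
  pool1 <- lapply(1:10, function(i)
    peptide_window_atoms(generate_ideal_peptide(tm$helix, 0.2, seed = i)))
  names(pool1) <- paste0("w", 1:10)
  b1 <- bootstrap_null(pool1, n = 8, reps = 30, seed = 5)
  expect_true(all(b1$counts == 1))
  # fixed seed reproduces exactly
  b2 <- bootstrap_null(pool1, n = 8, reps = 30, seed = 5)
  expect_identical(b1$counts, b2$counts)
  # pool with 3 well-separated motifs, n >> 3: modal count is 3
  pool3 <- list()
  for (k in 1:3)
    for (i in 1:12)
      pool3[[paste0("t", k, "_", i)]] <- peptide_window_atoms(
        generate_ideal_peptide(tm[[k]], 0.2, seed = k * 100 + i))
  b3 <- bootstrap_null(pool3, n = 30, reps = 40, seed = 6)
  expect_equal(as.integer(names(which.max(table(b3$counts)))), 3)
  # sampling beyond the pool size warns but still works
  expect_warning(bootstrap_null(pool1, n = 20, reps = 5, seed = 1),
                 "pool smaller")
})
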