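toy_matrix <- function(seed = 1, n_genes = 12, n_samples = 6) {
  set.seed(seed)
  m <- matrix(rexp(n_genes * n_samples) + 0.05, n_genes, n_samples,
              dimnames = list(sprintf("g%02d", seq_len(n_genes)),
                              sprintf("s%02d", seq_len(n_samples))))
  m
}

test_that("correspondence analysis validates its input", {
  m <- toy_matrix()
  m[3, ] <- 0
  expect_error(correspondence_analysis(m), "g03")
  m2 <- toy_matrix()
  m2[1, 1] <- -1
  expect_error(correspondence_analysis(m2), "non-negative")
})

test_that("identical samples receive identical scores", {
  m <- toy_matrix(2)
  m[, 2] <- m[, 1]
  res <- correspondence_analysis(m)
  expect_equal(res$sample_scores[1, ], res$sample_scores[2, ], tolerance = 1e-9)
})

test_that("axis 1 separates the blocks of a block-diagonal matrix", {
  m <- rbind(cbind(matrix(5, 6, 3), matrix(0, 6, 3)),
             cbind(matrix(0, 6, 3), matrix(5, 6, 3)))
  dimnames(m) <- list(sprintf("g%02d", 1:12), sprintf("s%d", 1:6))
  res <- correspondence_analysis(m)
  a1 <- res$sample_scores[, 1]
  expect_true(all(sign(a1[1:3]) == sign(a1[1])))
  expect_true(all(sign(a1[4:6]) == -sign(a1[1])))
})

test_that("CA axis 1 matches a reciprocal-averaging power-iteration oracle", {
  m <- matrix(c(3, 0, 1, 2,
                1, 4, 0, 1,
                0, 2, 5, 0,
                2, 1, 1, 3,
                0, 0, 2, 4), 5, 4, byrow = TRUE,
              dimnames = list(paste0("g", 1:5), paste0("s", 1:4)))
  res <- correspondence_analysis(m)
  ## oracle: iterate row scores <- weighted average of column scores and
  ## vice versa, re-standardizing each round (classic reciprocal averaging)
  r <- rowSums(m); cs <- colSums(m); tot <- sum(m)
  x <- seq_len(ncol(m))  # initial column scores
  for (it in 1:2000) {
    x <- x - sum(cs * x) / tot
    x <- x / sqrt(sum(cs * x^2) / tot)
    rowsc <- as.numeric(m %*% x) / r
    x <- as.numeric(t(m) %*% rowsc) / cs
  }
  x <- x - sum(cs * x) / tot
  ## compare direction up to sign and scale
  a1 <- res$sample_scores[, 1]
  corsign <- sign(sum(a1 * x))
  expect_gt(abs(cor(a1, x)), 1 - 1e-6)
  expect_equal(a1 / sqrt(sum(cs / tot * a1^2)),
               corsign * x / sqrt(sum(cs / tot * x^2)), tolerance = 1e-6)
})

test_that("eigenvalues lie in [0, 1] and are non-increasing", {
  res <- correspondence_analysis(toy_matrix(4, 20, 8))
  ev <- res$eigenvalues
  expect_true(all(ev >= -1e-12 & ev <= 1 + 1e-12))
  expect_true(all(diff(ev) <= 1e-12))
})

test_that("detrending reduces the arch and keeps axis 1 unchanged", {
  ## samples along a long gradient with unimodal gene responses produce the
  ## classic arch in CA axis 2
  n_s <- 30; n_g <- 40
  grad <- seq(0, 10, length.out = n_s)
  opt <- seq(0, 10, length.out = n_g)
  m <- outer(opt, grad, function(o, g) exp(-(o - g)^2 / 2)) * 100 + 1e-6
  dimnames(m) <- list(sprintf("g%02d", 1:n_g), sprintf("s%02d", 1:n_s))
  ca <- correspondence_analysis(m)
  dca <- detrended_ca(m, n_segments = 6)
  expect_equal(dca$sample_scores[, 1], ca$sample_scores[, 1], tolerance = 1e-12)
  expect_lt(var(dca$sample_scores[, 2]), var(ca$sample_scores[, 2]))

  one_seg <- detrended_ca(m, n_segments = 1)
  expect_equal(one_seg$sample_scores[, 2],
               ca$sample_scores[, 2] - mean(ca$sample_scores[, 2]),
               tolerance = 1e-12)
})

test_that("detrending fails on a degenerate first axis", {
  m <- toy_matrix(5)
  m[, ] <- m[, 1]  # all samples identical: axis-1 range collapses
  expect_error(detrended_ca(m), "rank|degenerate")
})

test_that("CA sample ordering agrees with vegan's correspondence analysis", {
  m <- toy_matrix(8, 15, 7)
  res <- correspondence_analysis(m)
  dec <- vegan::decorana(t(m), ira = 1)  # plain reciprocal averaging
  v1 <- vegan::scores(dec, display = "sites")[, 1]
  r <- abs(cor(res$sample_scores[, 1], v1))
  expect_gt(r, 0.999)
})

test_that("simulated group structure separates in DCA space", {
  hits <- 0
  for (seed in 1:10) {
    res <- simulate_dataset(sim_config(n_samples_per_group = 8, n_genes = 500,
                                       group_effect = 1.2, seed = seed))
    prof <- detection_profile(res$dataset)
    grp <- sample_groups(res$dataset)
    dca <- detrended_ca(prof$normalized[rowSums(prof$detected) > 0, ])
    sc <- dca$sample_scores[, 1:2]
    cen_h <- colMeans(sc[grp == "H", ]); cen_c <- colMeans(sc[grp == "C", ])
    between <- sqrt(sum((cen_h - cen_c)^2))
    within <- mean(c(apply(sc[grp == "H", ], 1, function(r) sqrt(sum((r - cen_h)^2))),
                     apply(sc[grp == "C", ], 1, function(r) sqrt(sum((r - cen_c)^2)))))
    if (between > within) hits <- hits + 1
  }
  expect_gte(hits, 9)
})

test_that("MRPP detects perfectly tight groups with delta 0", {
  x <- cbind(matrix(c(1, 1), 2, 3), matrix(c(5, 5), 2, 3)) + 0.0
  rownames(x) <- c("g1", "g2"); colnames(x) <- paste0("s", 1:6)
  res <- mrpp_test(x, rep(c("a", "b"), each = 3), metric = "euclidean",
                   n_perm = 199, seed = 1)
  expect_equal(res$delta_observed, 0)
  ## exactly 2 of the 20 distinct 3/3 splits (the observed one and its
  ## mirror) also attain delta 0, so the exact p is 0.1
  expect_lt(abs(res$p_value - 0.1), 3 * sqrt(0.1 * 0.9 / 199) + 1 / 200)
  expect_gt(res$A, 0)
})

test_that("monte-carlo MRPP p is within 3 SE of the exhaustive p", {
  set.seed(55)
  x <- matrix(rnorm(12, mean = rep(c(0, 1.5), each = 6)), 2, 6, byrow = TRUE)
  x <- abs(x)
  dimnames(x) <- list(c("g1", "g2"), paste0("s", 1:6))
  labels <- rep(c("a", "b"), each = 3)
  D <- as.matrix(vegan::vegdist(t(x), "bray"))
  ## exhaustive oracle over all 20 distinct 3/3 splits
  delta_of <- function(lab) {
    d <- 0
    for (g in unique(lab)) {
      i <- which(lab == g)
      d <- d + (length(i) / 6) * mean(D[i, i][upper.tri(diag(3))])
    }
    d
  }
  obs <- delta_of(labels)
  all_deltas <- apply(combn(6, 3), 2, function(i) {
    lab <- rep("b", 6); lab[i] <- "a"; delta_of(lab)
  })
  p_exact <- mean(all_deltas <= obs + 1e-12)
  res <- mrpp_test(x, labels, metric = "bray", n_perm = 4000, seed = 9)
  se <- sqrt(p_exact * (1 - p_exact) / 4000)
  expect_lt(abs(res$p_value - p_exact), 3 * se + 2 / 4000)
})

test_that("MRPP statistics agree with vegan's implementation", {
  set.seed(61)
  x <- matrix(rexp(80), 8, 10,
              dimnames = list(paste0("g", 1:8), paste0("s", 1:10)))
  labels <- rep(c("H", "C"), each = 5)
  mine <- mrpp_test(x, labels, metric = "bray", n_perm = 999, seed = 2)
  ref <- vegan::mrpp(vegan::vegdist(t(x), "bray"), labels, permutations = 999)
  expect_equal(mine$delta_observed, ref$delta, tolerance = 1e-10)
  ## A is defined against the permutation mean; agree loosely
  expect_equal(mine$A, ref$A, tolerance = 0.05)
})

test_that("MRPP rejects malformed groupings", {
  x <- toy_matrix(3, 5, 6)
  expect_error(mrpp_test(x, c("a", "a", "a", "a", "a", "b")), "at least two")
  expect_error(mrpp_test(x, rep("a", 6)), "at least two")
})
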