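test_that("median signatures apply the position coverage rule", {
  trials <- list(c(10, 20, 30), c(10, 20, 30), c(10, 20, 30))
  expect_equal(median_signature(trials), c(10, 20, 30))

  expect_equal(median_signature(list(10, 20, 30))[1], 20)

  # lengths {5,5,2}: positions 3-5 covered by 2 of 3 trials (>= 50%), and
  # their medians use the two long trials only
  tr <- list(c(1, 2, 3, 4, 5), c(2, 3, 5, 6, 7), c(9, 9))
  sig <- median_signature(tr)
  expect_length(sig, 5)
  expect_equal(sig[3], median(c(3, 5)))
  expect_equal(sig[1], median(c(1, 2, 9)))

  # stricter coverage truncates instead
  expect_length(median_signature(tr, coverage = 0.9), 2)
  expect_error(median_signature(list(numeric(0))), "no trial")
})

test_that("Spearman distance matches hand-computed rank correlations", {
  u <- c(3, 1, 4, 1.5, 9)
  expect_equal(spearman_distance(u, u), 0)
  expect_equal(spearman_distance(1:5, 5:1), 2)
  expect_equal(spearman_distance(c(1, 2, 3, 4), c(1, 3, 2, 4)), 0.2)
  # unequal lengths truncate to the common prefix
  expect_equal(spearman_distance(c(1, 2, 3), c(1, 2, 3, 99)), 0)
  expect_error(spearman_distance(1:2, 1:2), "3")
  expect_error(spearman_distance(c(1, 1, 1), 1:3), "variance")
})

brute_complete <- function(D) {
  # exhaustive complete-linkage agglomeration; returns merge heights and
  # the full cophenetic matrix
  n <- nrow(D)
  clusters <- as.list(seq_len(n))
  heights <- numeric(0)
  coph <- matrix(0, n, n)
  while (length(clusters) > 1) {
    bh <- Inf; best <- NULL
    for (j in seq_along(clusters)[-1]) for (i in seq_len(j - 1)) {
      h <- max(D[clusters[[i]], clusters[[j]]])
      if (h < bh - 1e-12) { bh <- h; best <- c(i, j) }
    }
    heights <- c(heights, bh)
    for (a in clusters[[best[1]]]) for (b in clusters[[best[2]]])
      coph[a, b] <- coph[b, a] <- bh
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  list(heights = heights, coph = coph)
}

test_that("clustering agrees with brute-force agglomeration", {
  set.seed(17)
  sigs <- replicate(5, cumsum(runif(8, 0.5, 3)), simplify = FALSE)
  sm <- signature_matrix(sigs, arrangement = rep(c("a", "b"), c(3, 2)),
                         delay = c(0, 20, 40, 0, 20))
  dend <- cluster_signatures(sm)
  D <- as.matrix(signature_distances(sm))
  ref <- brute_complete(D)
  expect_equal(dend$hclust$height, ref$heights, tolerance = 1e-12)
  expect_equal(as.matrix(stats::cophenetic(dend$hclust))[1:5, 1:5],
               ref$coph, ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("identical rows merge first at height zero", {
  sigs <- list(c(1, 2, 3, 5), c(1, 2, 3, 5), c(9, 1, 4, 2))
  sm <- signature_matrix(sigs, rep("x", 3), c(0, 20, 40))
  dend <- cluster_signatures(sm)
  expect_equal(dend$hclust$height[1], 0)
  expect_setequal(dend$hclust$merge[1, ], c(-1, -2))
})

test_that("clustering is invariant to row order up to relabeling", {
  set.seed(23)
  sigs <- replicate(6, runif(10, 5, 30), simplify = FALSE)
  sm <- signature_matrix(sigs, rep(c("a", "b"), 3), rep(c(0, 20, 40), 2))
  d1 <- cluster_signatures(sm)
  perm <- c(4, 2, 6, 1, 3, 5)
  sm2 <- signature_matrix(sigs[perm], sm$arrangement[perm], sm$delay[perm])
  d2 <- cluster_signatures(sm2)
  expect_equal(sort(d1$hclust$height), sort(d2$hclust$height))
  c1 <- as.matrix(stats::cophenetic(d1$hclust))
  c2 <- as.matrix(stats::cophenetic(d2$hclust))
  expect_equal(unname(c1[perm, perm]), unname(c2), tolerance = 1e-12)
})

test_that("complete-linkage heights never invert", {
  set.seed(29)
  for (rep in 1:5) {
    sigs <- replicate(7, runif(9, 1, 50), simplify = FALSE)
    sm <- signature_matrix(sigs, rep("x", 7), seq(0, 120, by = 20))
    expect_true(all(diff(cluster_signatures(sm)$hclust$height) >= -1e-12))
  }
})

test_that("dendrograms export as valid Newick trees", {
  sigs <- replicate(4, runif(8, 1, 30), simplify = FALSE)
  sm <- signature_matrix(sigs, rep(c("a", "b"), 2), c(0, 20, 0, 20))
  dend <- cluster_signatures(sm)
  nwk <- as_newick(dend)
  phy <- ape::read.tree(text = nwk)
  expect_equal(ape::Ntip(phy), 4)
  tmp <- tempfile(fileext = ".nwk")
  as_newick(dend, tmp)
  expect_equal(ape::Ntip(ape::read.tree(tmp)), 4)
})

test_that("new patterns classify to their nearest reference condition", {
  set.seed(41)
  sigs <- list(c(8, 11, 15, 8, 11, 15), c(9, 13, 19, 25, 9, 13),
               c(20, 16, 13, 11, 21, 17), c(22, 17, 12, 10, 23, 18))
  sm <- signature_matrix(sigs,
                         arrangement = c("clustered", "clustered",
                                         "diffused", "diffused"),
                         delay = c(40, 100, 160, 220))
  # a reference row re-presented returns its own labels at distance 0
  hit <- classify_new_pattern(sigs[[2]], sm)
  expect_equal(hit$nearest, "clustered_100")
  expect_equal(hit$arrangement, "clustered")
  expect_equal(hit$delay_range, "short")
  expect_equal(hit$distance, 0)
  long_hit <- classify_new_pattern(sigs[[4]] + 0.01, sm)
  expect_equal(long_hit$delay_range, "long")
  expect_error(classify_new_pattern(rep(3, 6), sm), "variance")
  expect_error(classify_new_pattern(c(1, 2), sm), "3")
})

test_that("ttfs decoding inverts the reference curve linearly", {
  ref <- data.frame(arrangement = "fully_diffused",
                    delay = c(0, 20, 40, 60),
                    ttfs_median = c(3, 23, 43, 63))
  expect_equal(ttfs_decoder(43, "fully_diffused", ref), 40)
  expect_equal(ttfs_decoder(33, "fully_diffused", ref), 30)  # midpoint
  out <- ttfs_decoder(80, "fully_diffused", ref)
  expect_true(is.na(out))
  expect_true(attr(out, "extrapolated"))
  expect_error(ttfs_decoder(10, "nope", ref), "no reference")
})
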