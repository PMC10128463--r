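make_mat <- function(lv, pos = seq_len(nrow(lv)) * 10) {
  sites <- data.frame(chrom = "chr1", pos = pos, context = "CG")
  rownames(lv) <- paste0("chr1:", pos)
  colnames(lv) <- colnames(lv) %||% paste0("S", seq_len(ncol(lv)))
  methage:::new_methyl_matrix(sites, colnames(lv), lv, 1, "CG")
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("PCA rejects degenerate cohorts", {
  lv <- matrix(0.5, 10, 4)
  expect_error(methyl_pca(make_mat(lv)), "zero variance")
  expect_error(methyl_pca(make_mat(matrix(runif(20), 10, 2))),
               "at least 3")
})

test_that("PC1 separates two duplicated sample clusters", {
  set.seed(16)
  a <- runif(60); b <- runif(60)
  lv <- cbind(a, a, a, b, b, b) + matrix(rnorm(360, 0, 1e-4), 60)
  p <- methyl_pca(make_mat(lv), remove_var_fraction = 0)
  expect_gt(p$variance_explained[1], 0.99)
  s <- p$scores[, 1]
  expect_true(all(s[1:3] > 0) != all(s[4:6] > 0))
  expect_true(max(abs(s[1:3] - mean(s[1:3]))) < 1e-2)
})

test_that("scores match a brute-force eigendecomposition", {
  set.seed(17)
  lv <- matrix(runif(900), 100, 9)
  p <- methyl_pca(make_mat(lv), remove_var_fraction = 0.1)
  # brute force on the same filtered site set
  keep <- rownames(lv) <- paste0("chr1:", seq_len(100) * 10)
  x <- t(lv[rownames(lv) %in% p$kept_sites, ])
  xc <- scale(x, center = TRUE, scale = FALSE)
  eig <- eigen(crossprod(xc) / (nrow(xc) - 1), symmetric = TRUE)
  k <- ncol(p$scores)
  for (j in seq_len(k - 1)) {       # last component is numerically null
    v <- eig$vectors[, j]
    if (v[which.max(abs(v))] < 0) v <- -v
    expect_equal(unname(p$loadings[, j]), v, tolerance = 1e-8)
    expect_equal(unname(p$scores[, j]), as.vector(xc %*% v),
                 tolerance = 1e-8)
    expect_equal(p$variance_explained[j],
                 eig$values[j] / sum(eig$values), tolerance = 1e-8)
  }
  # reconstruction from all components reproduces the centered matrix
  expect_equal(p$scores %*% t(p$loadings), xc, tolerance = 1e-8,
               ignore_attr = TRUE)
  # low-variance filter actually dropped the bottom decile
  expect_equal(length(p$kept_sites), 90L)
  v_all <- apply(lv, 1, var)
  expect_true(min(v_all[rownames(lv) %in% p$kept_sites]) >=
                max(v_all[!rownames(lv) %in% p$kept_sites]))
})

test_that("PC-age correlation flags the age-aligned component", {
  ages <- rep(c(1, 5, 9), each = 3)
  scores <- cbind(PC1 = ages * 2 + 1, PC2 = rep(c(1, -1), length.out = 9))
  r2 <- pc_age_correlation(scores, ages)
  expect_equal(unname(r2["PC1"]), 1)
  expect_lt(r2["PC2"], 0.2)
  expect_true(is.na(pc_age_correlation(cbind(rep(1, 9)), ages)))
})

test_that("Spearman clustering is monotone-invariant and orders merges", {
  set.seed(18)
  base <- matrix(runif(300), 100, 3)
  lv <- cbind(base[, 1], base[, 1], base[, 2], base[, 3])
  colnames(lv) <- c("dupA", "dupB", "other1", "other2")
  sc <- sample_correlation_cluster(make_mat(lv))
  expect_equal(sc$correlation["dupA", "dupB"], 1)
  expect_equal(diag(sc$correlation), rep(1, 4), ignore_attr = TRUE)
  # the duplicated pair merges first
  first <- sc$hclust$merge[1, ]
  expect_setequal(sc$hclust$labels[-first], c("dupA", "dupB"))
  # strictly monotone transform of one sample changes nothing
  lv2 <- lv; lv2[, 3] <- qlogis(pmin(pmax(lv2[, 3], 1e-6), 1 - 1e-6))
  sc2 <- sample_correlation_cluster(make_mat(lv2))
  expect_equal(sc$correlation, sc2$correlation, tolerance = 1e-12)
  # anti-correlated pair sits at distance 2, merged last
  lv3 <- cbind(a = base[, 1], b = 1 - base[, 1], c = base[, 2],
               d = base[, 2] + rnorm(100, 0, 0.01))
  sc3 <- sample_correlation_cluster(make_mat(lv3), k = 2)
  expect_equal(max(sc3$hclust$height), 1 - sc3$correlation["a", "b"],
               tolerance = 1e-12)
  expect_equal(unname(sc3$clusters["a"] == sc3$clusters["b"]), FALSE)
  expect_error(sample_correlation_cluster(make_mat(cbind(a = rep(0.5, 100),
                                                         b = base[, 1]))),
               "constant.*a")
})

test_that("complete-linkage heights equal a brute-force agglomeration", {
  set.seed(19)
  lv <- matrix(runif(60), 10, 6)
  colnames(lv) <- paste0("S", 1:6)
  sc <- sample_correlation_cluster(make_mat(lv))
  # naive complete-linkage agglomeration over the same distance matrix
  D <- 1 - cor(lv, method = "spearman")
  clusters <- as.list(1:6)
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- c(Inf, 0, 0)
    for (i in seq_along(clusters)) for (j in seq_len(i - 1)) {
      h <- max(D[clusters[[i]], clusters[[j]]])
      if (h < best[1]) best <- c(h, j, i)
    }
    heights <- c(heights, best[1])
    clusters[[best[2]]] <- c(clusters[[best[2]]], clusters[[best[3]]])
    clusters[[best[3]]] <- NULL
  }
  expect_equal(sc$hclust$height, heights, tolerance = 1e-12)
})

test_that("top-variable selection is a brute-force variance sort", {
  set.seed(20)
  lv <- matrix(runif(200 * 6), 200, 6)
  lv[7, ] <- 0.4                       # constant site
  mat <- make_mat(lv)
  top <- top_variable_sites(mat, 50)
  v <- apply(lv, 1, var)
  keys <- paste0("chr1:", seq_len(200) * 10)
  expect_setequal(rownames(top$levels), keys[order(-v)[1:50]])
  expect_false("chr1:70" %in% rownames(top$levels))
  all_sites <- top_variable_sites(mat, 200)
  expect_equal(rownames(all_sites$levels), keys[order(-v)])
  vv <- apply(all_sites$levels, 1, var)
  expect_true(all(diff(vv) <= 1e-15))
  expect_error(top_variable_sites(mat, 201), class = "methage_input_error")
})

test_that("site clustering recovers planted families and matches hclust", {
  set.seed(22)
  fam1 <- matrix(rep(c(0.9, 0.9, 0.1), each = 20) +
                   rnorm(60, 0, 0.02), 20)
  fam2 <- matrix(rep(c(0.1, 0.5, 0.9), each = 20) +
                   rnorm(60, 0, 0.02), 20)
  lv <- rbind(fam1, fam2)
  mat <- make_mat(lv)
  one <- site_cluster(mat, k = 1)
  expect_true(all(one$labels == 1))
  two <- site_cluster(mat, k = 2, ages = c(1, 5, 9))
  expect_equal(length(unique(two$labels[1:20])), 1L)
  expect_equal(length(unique(two$labels[21:40])), 1L)
  expect_true(two$labels[1] != two$labels[21])
  # age-trend summary separates falling from rising clusters
  tr <- two$summary$mean_age_trend
  expect_lt(tr[two$labels[1]], 0)
  expect_gt(tr[two$labels[21]], 0)
  expect_error(site_cluster(mat, k = 41), class = "methage_input_error")
  # labels equal cutree on the same complete-linkage tree
  set.seed(23)
  lv2 <- matrix(runif(200 * 9), 200, 9)
  mat2 <- make_mat(lv2)
  got <- site_cluster(mat2, k = 5)
  ref <- cutree(hclust(dist(lv2), method = "complete"), k = 5)
  expect_equal(unname(got$labels), unname(ref))
})

test_that("dendrograms export to Newick and reimport with the same topology", {
  set.seed(24)
  lv <- matrix(runif(300), 50, 6)
  colnames(lv) <- paste0("S", 1:6)
  sc <- sample_correlation_cluster(make_mat(lv))
  f <- withr::local_tempfile(fileext = ".nwk")
  write_newick(sc$hclust, f)
  tree <- ape::read.tree(f)
  expect_setequal(tree$tip.label, colnames(lv))
})
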