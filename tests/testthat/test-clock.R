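test_that("alpha = 0 reduces to ordinary least squares", {
  set.seed(6)
  X <- cbind(runif(5), runif(5))
  colnames(X) <- c("a", "b")
  y <- 2 + 3 * X[, 1] - 1.5 * X[, 2] + rnorm(5, 0, 0.1)
  fit <- enet_fit(X, y, alpha = 0, tol = 1e-12)
  ols <- solve(crossprod(cbind(1, X)), crossprod(cbind(1, X), y))
  expect_equal(unname(coef(fit)), as.vector(ols), tolerance = 1e-8)
})

test_that("a huge penalty gives the null model", {
  set.seed(7)
  X <- matrix(runif(50), 10)
  y <- rnorm(10, 5)
  fit <- enet_fit(X, y, alpha = 1e6)
  expect_true(all(fit$weights == 0))
  expect_equal(fit$intercept, mean(y))
  expect_equal(length(fit$nonzero_sites), 0L)
})

test_that("one feature matches the hand-derived soft-threshold solution", {
  set.seed(8)
  x <- runif(12)
  y <- 1 + 2 * x + rnorm(12, 0, 0.2)
  for (alpha in c(0.01, 0.05, 0.5)) {
    for (l1 in c(0, 0.5, 1)) {
      fit <- enet_fit(matrix(x, ncol = 1), y, alpha, l1, tol = 1e-10)
      n <- length(x)
      sxy <- sum((x - mean(x)) * (y - mean(y))) / n
      sxx <- sum((x - mean(x))^2) / n
      g1 <- alpha * l1
      w_hand <- sign(sxy) * max(0, abs(sxy) - g1) /
        (sxx + alpha * (1 - l1))
      expect_equal(unname(fit$weights), w_hand, tolerance = 1e-8)
      expect_equal(fit$intercept, mean(y) - w_hand * mean(x),
                   tolerance = 1e-8)
    }
  }
})

enet_objective <- function(X, y, b, w, alpha, l1) {
  n <- length(y)
  sum((y - b - X %*% w)^2) / (2 * n) + alpha * l1 * sum(abs(w)) +
    0.5 * alpha * (1 - l1) * sum(w^2)
}

test_that("the solution never scores worse than the null model", {
  set.seed(9)
  for (rep in 1:5) {
    X <- matrix(runif(9 * 30), 9)
    y <- rnorm(9, 5, 2)
    alpha <- 10^runif(1, -4, 0)
    fit <- enet_fit(X, y, alpha)
    expect_lte(enet_objective(X, y, fit$intercept, fit$weights, alpha, 0.5),
               enet_objective(X, y, mean(y), rep(0, 30), alpha, 0.5) + 1e-10)
  }
})

test_that("coefficients agree with an independent solver", {
  skip_if_not_installed("glmnet")
  set.seed(10)
  X <- matrix(runif(9 * 40), 9)
  colnames(X) <- paste0("s", 1:40)
  y <- rep(c(1, 5, 9), each = 3) + rnorm(9, 0, 0.3)
  # glmnet standardizes y internally (1/n variance), so the objectives only
  # coincide when y already has unit 1/n-variance: compare on that scale
  ys <- y / sqrt(mean((y - mean(y))^2))
  for (l1 in c(0.5, 1)) {
    fit <- enet_fit(X, ys, alpha = 0.01, l1_ratio = l1, tol = 1e-9)
    g <- glmnet::glmnet(X, ys, alpha = l1, lambda = 0.01,
                        standardize = FALSE, thresh = 1e-14)
    expect_equal(unname(fit$weights), as.vector(g$beta), tolerance = 1e-4)
    expect_equal(fit$intercept, unname(g$a0), tolerance = 1e-4)
  }
})

test_that("predictions ignore zero-weight features", {
  set.seed(11)
  X <- matrix(runif(9 * 20), 9)
  colnames(X) <- paste0("s", 1:20)
  y <- 3 * X[, 1] + rnorm(9, 0, 0.05)
  fit <- enet_fit(X, y, alpha = 0.02, l1_ratio = 1)
  zero <- which(fit$weights == 0)
  skip_if(length(zero) == 0)
  X2 <- X
  X2[, zero[1]] <- X2[, zero[1]] + 100
  expect_equal(predict(fit, X2), predict(fit, X))
})

test_that("LOOCV produces one fold per sample and honest metrics", {
  set.seed(12)
  ages <- rep(c(1, 5, 9), each = 3)
  X <- cbind(feat = (ages - 1) / 10)          # noiseless linear feature
  X <- cbind(X, matrix(runif(9 * 5, 0.4, 0.6), 9))
  colnames(X) <- paste0("s", 1:6)
  ev <- loocv_clock(X, ages, alpha = 1e-4, l1_ratio = 0.5)
  expect_equal(length(ev$fold_models), 9L)
  expect_gt(ev$r2, 0.99)
  expect_lt(ev$mae, 0.2)
  expect_true(all(ev$feature_union$n_folds <= 9))
  expect_gte(nrow(ev$feature_union),
             max(vapply(ev$fold_models,
                        function(m) length(m$nonzero_sites), numeric(1))))
})

test_that("LOOCV with only a constant feature predicts the training mean", {
  ages <- c(2, 4, 6, 8)
  X <- matrix(1, 4, 1)
  ev <- loocv_clock(X, ages, alpha = 0.1)
  expect_equal(ev$predictions$predicted,
               vapply(1:4, function(i) mean(ages[-i]), numeric(1)))
})

test_that("grid search minimizes LOOCV error with sparse tie-breaks", {
  set.seed(13)
  X <- matrix(runif(9 * 10), 9)
  y <- rep(c(1, 5, 9), each = 3)
  one <- grid_search_hyperparams(X, y, alpha_grid = 0.05, l1_grid = 0.5)
  expect_equal(one$alpha, 0.05)
  # degenerate data: every pair ties, the largest alpha and l1 win
  Xc <- matrix(0.5, 9, 3)
  tie <- grid_search_hyperparams(Xc, y, alpha_grid = c(0.01, 0.1),
                                 l1_grid = c(0.2, 0.8))
  expect_equal(tie$alpha, 0.1)
  expect_equal(tie$l1_ratio, 0.8)
  # exhaustive brute force over a 3x3 grid
  ag <- c(0.001, 0.01, 0.1); lg <- c(0.2, 0.5, 0.8)
  gs <- grid_search_hyperparams(X, y, ag, lg)
  brute <- expand.grid(alpha = ag, l1_ratio = lg)
  brute$mse <- mapply(function(a, l) {
    pr <- vapply(1:9, function(i) {
      f <- enet_fit(X[-i, ], y[-i], a, l)
      predict(f, X[i, , drop = FALSE])
    }, numeric(1))
    mean((pr - y)^2)
  }, brute$alpha, brute$l1_ratio)
  expect_equal(gs$grid$cv_mse, brute$mse, tolerance = 1e-10)
  best <- brute[which.min(brute$mse), ]
  expect_equal(gs$alpha, best$alpha)
})

test_that("feature overlap uses half-open region membership", {
  regions <- data.frame(chrom = "chr1", start = c(100, 500),
                        end = c(200, 600), name = c("a", "b"))
  fu <- data.frame(site = c("chr1:150", "chr1:201", "chr1:550", "chr2:150"),
                   n_folds = c(9L, 1L, 3L, 1L))
  # site "chr1:201" has pos0 = 200 = region end -> outside (half-open)
  ov <- feature_overlap(fu, regions)
  expect_equal(ov$n_inside, 2L)
  expect_equal(ov$n_outside, 2L)
  expect_equal(ov$sites$inside_region, c(TRUE, FALSE, TRUE, FALSE))
  all_in <- feature_overlap(data.frame(site = "chr1:150", n_folds = 2L),
                            regions)
  expect_equal(all_in$n_outside, 0L)
  # brute-force membership scan on random sites/regions
  set.seed(14)
  pos <- sample.int(1e4, 200)
  fu2 <- data.frame(site = paste0("chr1:", pos),
                    n_folds = sample(1:9, 200, TRUE))
  st <- sort(sample.int(1e4, 20)); rg <- data.frame(chrom = "chr1",
                                                    start = st,
                                                    end = st + 80,
                                                    name = paste0("r", 1:20))
  ov2 <- feature_overlap(fu2, rg)
  brute <- vapply(pos, function(p)
    any((p - 1) >= rg$start & (p - 1) < rg$end), logical(1))
  expect_equal(ov2$sites$inside_region, brute)
})

test_that("planted drift sites dominate the clock's chosen features", {
  cohort <- small_cohort()
  sheet <- cohort$sim$sample_sheet
  mat <- build_common_matrix(sheet, coverage_floor = 5)
  ev <- loocv_clock(mat, sheet$age_years, alpha = 0.00283693)
  truth <- cohort$sim$truth$sites
  drift_keys <- paste0(truth$chrom, ":", truth$pos)[truth$drift]
  prevalence <- mean(rownames(mat$levels) %in% drift_keys)
  hit_rate <- mean(ev$feature_union$site %in% drift_keys)
  expect_gte(hit_rate / prevalence, 5)
})

test_that("non-convergence raises a numerical error naming the gap", {
  set.seed(15)
  X <- matrix(runif(9 * 50), 9)
  y <- rnorm(9)
  expect_error(enet_fit(X, y, alpha = 1e-9, tol = 1e-14, max_iter = 3L),
               class = "methage_numerical_error")
})
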