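#' Fit an elastic-net methylation clock
#'
#' Penalized linear regression of age on per-site methylation levels,
#' minimizing
#' \deqn{\frac{1}{2n}\lVert y - b - Xw\rVert^2
#'       + \alpha\,\lambda_1 \lVert w\rVert_1
#'       + \tfrac{1}{2}\alpha(1-\lambda_1)\lVert w\rVert^2}
#' with unpenalized intercept \eqn{b} and L1/L2 mix \eqn{\lambda_1} =
#' `l1_ratio`. Note the `1/(2n)` loss scaling: `alpha` is only meaningful
#' relative to a convention, and this is the scikit-learn `ElasticNet`
#' one (glmnet's `lambda` with `standardize = FALSE` coincides). Features
#' are used as raw methylation fractions by default — set
#' `standardize = TRUE` to z-score columns before fitting (coefficients
#' are returned on the original scale).
#'
#' The solver is cyclic coordinate descent with a fixed feature order, so
#' fits are deterministic and bit-reproducible for identical inputs.
#'
#' @param X Samples x sites numeric matrix (no missing values), or a
#'   `methyl_matrix` (transposed internally).
#' @param y Numeric ages in years.
#' @param alpha Overall penalty strength (>= 0).
#' @param l1_ratio L1 share of the penalty, in `[0, 1]` (default 0.5).
#' @param standardize Z-score columns before fitting (default `FALSE`).
#' @param tol Convergence tolerance: the sweep's largest coefficient
#'   update, relative to the largest coefficient magnitude (default 1e-4,
#'   the scikit-learn tolerance scale).
#' @param max_iter Maximum coordinate-descent sweeps (default 100000); an
#'   error reporting the residual update gap is raised if not converged.
#' @return A `methyl_clock` object: list with `intercept`, `weights`
#'   (named), `alpha`, `l1_ratio`, `nonzero_sites`, `training_sample_ids`,
#'   `n_iter`, `standardize`.
#' @examples
#' X <- matrix(runif(45), nrow = 9)
#' colnames(X) <- paste0("s", 1:5)
#' fit <- enet_fit(X, rep(c(1, 5, 9), each = 3), alpha = 0.01)
#' coef(fit)
#' predict(fit, X)
#' @export
enet_fit <- function(X, y, alpha, l1_ratio = 0.5, standardize = FALSE,
                     tol = 1e-4, max_iter = 100000L) {
  if (inherits(X, "methyl_matrix")) X <- t(X$levels)
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("site_", seq_len(ncol(X)))
  if (nrow(X) < 2L) stop_input("need at least 2 samples")
  if (length(y) != nrow(X)) stop_input("length(y) must equal nrow(X)")
  if (anyNA(X) || anyNA(y)) stop_input("missing values are not allowed")
  if (alpha < 0 || l1_ratio < 0 || l1_ratio > 1) {
    stop_validation("alpha must be >= 0 and l1_ratio in [0, 1]")
  }
  ctr <- rep(0, ncol(X)); scl <- rep(1, ncol(X))
  Xf <- X
  if (standardize) {
    ctr <- colMeans(X)
    scl <- apply(X, 2, stats::sd)
    scl[scl == 0] <- 1
    Xf <- sweep(sweep(X, 2, ctr), 2, scl, "/")
  }
  res <- .enet_cd(Xf, as.numeric(y), alpha, l1_ratio, tol,
                  as.integer(max_iter), TRUE)
  if (!res$converged) {
    stop(errorCondition(
      paste0("elastic net did not converge in ", max_iter,
             " sweeps (largest coefficient update ",
             signif(res$max_delta, 3), " > tol ", tol, ")"),
      class = c("methage_numerical_error", "error")))
  }
  w <- res$weights / scl
  b <- res$intercept - sum(w * ctr)
  names(w) <- colnames(X)
  structure(list(intercept = b, weights = w, alpha = alpha,
                 l1_ratio = l1_ratio,
                 nonzero_sites = colnames(X)[w != 0],
                 training_sample_ids = rownames(X) %||%
                   as.character(seq_len(nrow(X))),
                 n_iter = res$n_iter, standardize = standardize),
            class = "methyl_clock")
}

#' @export
print.methyl_clock <- function(x, ...) {
  cat("elastic-net methylation clock\n")
  cat("  alpha = ", x$alpha, ", l1_ratio = ", x$l1_ratio, "\n", sep = "")
  cat("  ", length(x$nonzero_sites), " of ", length(x$weights),
      " sites with nonzero weight; intercept = ",
      round(x$intercept, 4), "\n", sep = "")
  invisible(x)
}

#' @export
coef.methyl_clock <- function(object, ...) {
  c("(Intercept)" = object$intercept, object$weights)
}

#' Predict ages from a fitted clock
#' @param object A `methyl_clock`.
#' @param newdata Samples x sites matrix (columns matched by name when
#'   named), or a `methyl_matrix`.
#' @param ... Unused.
#' @return Numeric predicted ages.
#' @export
predict.methyl_clock <- function(object, newdata, ...) {
  if (inherits(newdata, "methyl_matrix")) newdata <- t(newdata$levels)
  newdata <- as.matrix(newdata)
  if (!is.null(colnames(newdata)) &&
      all(names(object$weights) %in% colnames(newdata))) {
    newdata <- newdata[, names(object$weights), drop = FALSE]
  } else if (ncol(newdata) != length(object$weights)) {
    stop_input("newdata does not carry the clock's sites")
  }
  as.vector(object$intercept + newdata %*% object$weights)
}

#' Leave-one-out cross-validated clock evaluation
#'
#' For each sample, an elastic-net clock is fitted on the other n-1
#' samples and used to predict the held-out sample's age. Reports the
#' squared Pearson correlation between predicted and actual age (`r2`),
#' the coefficient of determination (`r2_cod`), the mean absolute error in
#' years, the n per-fold models, and the feature union — every site with a
#' nonzero weight in at least one fold, with the number of folds that used
#' it.
#'
#' @inheritParams enet_fit
#' @param ages Numeric age per sample.
#' @return A `clock_evaluation` object: list with `predictions` (data
#'   frame `sample`, `age`, `predicted`), `r2`, `r2_cod`, `mae`,
#'   `fold_models`, `feature_union` (data frame `site`, `n_folds`),
#'   `alpha`, `l1_ratio`.
#' @export
loocv_clock <- function(X, ages, alpha, l1_ratio = 0.5, standardize = FALSE) {
  if (inherits(X, "methyl_matrix")) X <- t(X$levels)
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 3L) stop_input("LOOCV needs at least 3 samples")
  ids <- rownames(X) %||% as.character(seq_len(n))
  preds <- numeric(n)
  fold_models <- vector("list", n)
  for (i in seq_len(n)) {
    fit <- tryCatch(
      enet_fit(X[-i, , drop = FALSE], ages[-i], alpha, l1_ratio,
               standardize = standardize),
      error = function(e) stop("fold ", i, " (held-out sample ", ids[i],
                               "): ", conditionMessage(e), call. = FALSE))
    preds[i] <- predict(fit, X[i, , drop = FALSE])
    fold_models[[i]] <- fit
  }
  names(fold_models) <- ids
  union_sites <- table(unlist(lapply(fold_models, `[[`, "nonzero_sites")))
  feature_union <- data.frame(site = as.character(names(union_sites) %||%
                                                    character()),
                              n_folds = as.integer(union_sites),
                              stringsAsFactors = FALSE)
  feature_union <- feature_union[order(-feature_union$n_folds,
                                       feature_union$site), , drop = FALSE]
  rownames(feature_union) <- NULL
  structure(list(
    predictions = data.frame(sample = ids, age = ages, predicted = preds,
                             stringsAsFactors = FALSE),
    r2 = if (stats::sd(preds) > 0) stats::cor(preds, ages)^2 else NA_real_,
    r2_cod = 1 - sum((ages - preds)^2) / sum((ages - mean(ages))^2),
    mae = mean(abs(ages - preds)),
    fold_models = fold_models,
    feature_union = feature_union,
    alpha = alpha, l1_ratio = l1_ratio), class = "clock_evaluation")
}

#' @export
print.clock_evaluation <- function(x, ...) {
  cat("LOOCV clock evaluation (", nrow(x$predictions), " folds)\n", sep = "")
  cat("  R2 (squared Pearson) = ", round(x$r2, 4),
      "; R2 (coefficient of determination) = ", round(x$r2_cod, 4), "\n",
      sep = "")
  cat("  MAE = ", round(x$mae, 4), " years\n", sep = "")
  cat("  feature union: ", nrow(x$feature_union), " distinct sites\n",
      sep = "")
  invisible(x)
}

#' @export
plot.clock_evaluation <- function(x, ...) {
  p <- x$predictions
  plot(p$age, p$predicted, xlab = "actual age (years)",
       ylab = "predicted age (years)",
       main = "LOOCV methylation clock", ...)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}

#' Grid search for elastic-net hyperparameters by LOOCV error
#'
#' Evaluates every (alpha, l1_ratio) pair by leave-one-out mean squared
#' error and returns the minimizer; exact ties are broken toward the
#' larger alpha (the sparser model), then the larger l1_ratio.
#'
#' @inheritParams loocv_clock
#' @param alpha_grid,l1_grid Non-empty numeric grids.
#' @return List with `alpha`, `l1_ratio`, and `grid` (data frame `alpha`,
#'   `l1_ratio`, `cv_mse`).
#' @export
grid_search_hyperparams <- function(X, ages, alpha_grid, l1_grid = 0.5,
                                    standardize = FALSE) {
  if (!length(alpha_grid) || !length(l1_grid)) {
    stop_input("hyperparameter grids must be non-empty")
  }
  grid <- expand.grid(alpha = alpha_grid, l1_ratio = l1_grid)
  grid$cv_mse <- NA_real_
  for (g in seq_len(nrow(grid))) {
    ev <- loocv_clock(X, ages, grid$alpha[g], grid$l1_ratio[g],
                      standardize = standardize)
    grid$cv_mse[g] <- mean((ev$predictions$age - ev$predictions$predicted)^2)
  }
  best <- min(grid$cv_mse)
  cand <- grid[grid$cv_mse <= best + 1e-12, , drop = FALSE]
  cand <- cand[order(-cand$alpha, -cand$l1_ratio), , drop = FALSE]
  list(alpha = cand$alpha[1L], l1_ratio = cand$l1_ratio[1L], grid = grid)
}

#' Overlap of clock features with capture regions
#'
#' Partitions the LOOCV feature-union sites by membership in a capture
#' region (point-in-interval on the 0-based half-open regions, so a site
#' at a region's `end` coordinate is outside) and tabulates how many fold
#' models used each site.
#'
#' @param feature_union Data frame `site` (`"chrom:pos"` keys), `n_folds`.
#' @param regions Region data frame from [collapse_to_regions()].
#' @return List with `n_inside`, `n_outside`, `sites` (data frame `site`,
#'   `n_folds`, `inside_region`), and `fold_count_distribution` (data
#'   frame `n_folds`, `n_sites`).
#' @export
feature_overlap <- function(feature_union, regions) {
  parts <- strsplit(feature_union$site, ":", fixed = TRUE)
  chrom <- vapply(parts, `[[`, "", 1L)
  pos <- as.numeric(vapply(parts, `[[`, "", 2L))
  inside <- rep(FALSE, length(pos))
  if (nrow(regions)) {
    hits <- GenomicRanges::findOverlaps(
      GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, pos)),
      GenomicRanges::GRanges(regions$chrom,
                             IRanges::IRanges(regions$start + 1L,
                                              regions$end)))
    inside[unique(S4Vectors::queryHits(hits))] <- TRUE
  }
  sites <- cbind(feature_union, inside_region = inside)
  tab <- table(feature_union$n_folds)
  list(n_inside = sum(inside), n_outside = sum(!inside), sites = sites,
       fold_count_distribution = data.frame(
         n_folds = as.integer(names(tab)), n_sites = as.integer(tab)))
}
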