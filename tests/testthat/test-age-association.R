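test_that("perfectly linear sites hit r = +/-1; flat sites are excluded", {
  ages <- rep(c(1, 5, 9), each = 3)
  lv <- rbind(0.1 + 0.05 * ages,          # rising
              0.9 - 0.05 * ages,          # falling
              rep(0.5, 9))                # flat
  sites <- data.frame(chrom = "chr1", pos = c(100, 200, 300), context = "CG")
  rownames(lv) <- paste0("chr1:", sites$pos)
  colnames(lv) <- paste0("S", 1:9)
  mat <- methage:::new_methyl_matrix(sites, colnames(lv), lv, 1, "CG")
  expect_message(
    st <- site_age_stats(mat, ages, rep(c("Y", "M", "O"), each = 3)),
    "zero-variance")
  expect_equal(st$pearson_r[1:2], c(1, -1), tolerance = 1e-12)
  expect_lt(st$pearson_p[1], 1e-10)
  expect_true(st$zero_variance[3])
  expect_true(is.na(st$pearson_r[3]))
  st <- rank_and_select(st, 2)
  expect_false(st$selected[3])
})

test_that("vectorized statistics match cor.test and anova(lm) per site", {
  pm <- planted_matrix(n_sites = 400, seed = 8)
  st <- site_age_stats(pm$mat, pm$ages, pm$groups)
  idx <- sample(400, 40)
  for (i in idx) {
    ct <- cor.test(pm$mat$levels[i, ], pm$ages)
    expect_equal(st$pearson_r[i], unname(ct$estimate), tolerance = 1e-10)
    expect_equal(st$pearson_p[i], ct$p.value, tolerance = 1e-10)
    av <- anova(lm(pm$mat$levels[i, ] ~ factor(pm$groups)))
    expect_equal(st$anova_F[i], av$`F value`[1], tolerance = 1e-10)
    expect_equal(st$anova_p[i], av$`Pr(>F)`[1], tolerance = 1e-10)
  }
  expect_error(site_age_stats(pm$mat, rep(5, 9), pm$groups), "constant")
})

test_that("BH adjustment follows the step-up formula", {
  expect_equal(adjust_pvalues(0.03), 0.03)
  expect_equal(adjust_pvalues(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(adjust_pvalues(rep(1, 5)), rep(1, 5))
  set.seed(2)
  p <- runif(200)^2
  got <- adjust_pvalues(p)
  o <- order(p)
  hand <- numeric(200)                 # step-up with monotonicity, by hand
  hand[o] <- rev(cummin(rev(p[o] * 200 / seq_len(200))))
  expect_equal(got, pmin(1, hand), tolerance = 1e-12)
  expect_true(all(got >= p))
})

test_that("rank-sum combines the two criteria deterministically", {
  ages <- rep(c(1, 5, 9), each = 3)
  set.seed(3)
  lv <- matrix(runif(20 * 9), 20)
  lv[1, ] <- 0.1 + 0.08 * ages          # unbeatable on both criteria
  sites <- data.frame(chrom = "chr1", pos = 1:20 * 10, context = "CG")
  rownames(lv) <- paste0("chr1:", sites$pos)
  colnames(lv) <- paste0("S", 1:9)
  mat <- methage:::new_methyl_matrix(sites, colnames(lv), lv, 1, "CG")
  st <- rank_and_select(site_age_stats(mat, ages, rep(c("Y", "M", "O"),
                                                      each = 3)), 5)
  expect_equal(st$combined_rank[1], 2L)
  expect_true(st$selected[1])
  expect_equal(sum(st$selected), 5L)
  # duplicated site statistics break ties by genomic order
  lv2 <- lv[c(1, 1, 2:19), ]
  sites2 <- sites; rownames(lv2) <- rownames(lv)
  mat2 <- methage:::new_methyl_matrix(sites2, colnames(lv2), lv2, 1, "CG")
  st2 <- rank_and_select(site_age_stats(mat2, ages,
                                        rep(c("Y", "M", "O"), each = 3)), 1)
  expect_true(st2$selected[1])
  expect_false(st2$selected[2])
  expect_lt(st2$rank_pearson[1], st2$rank_pearson[2])
})

test_that("top-n selection recovers planted drift sites", {
  pm <- planted_matrix(n_sites = 1000, n_drift = 50, slope_min = 0.02,
                       noise_sd = 0.03, seed = 5)
  st <- rank_and_select(site_age_stats(pm$mat, pm$ages, pm$groups),
                        top_n = 50)
  hits <- intersect(which(st$selected), pm$drift_idx)
  expect_gte(length(hits), 45)
  expect_warning(rank_and_select(st, top_n = 5000), "exceeds")
})

test_that("precision of top-k selection grows with planted effect size", {
  recall <- vapply(c(0.005, 0.02, 0.05), function(s) {
    pm <- planted_matrix(n_sites = 600, n_drift = 30, slope_min = s,
                         noise_sd = 0.03, seed = 19)
    st <- rank_and_select(site_age_stats(pm$mat, pm$ages, pm$groups), 30)
    length(intersect(which(st$selected), pm$drift_idx)) / 30
  }, numeric(1))
  expect_true(all(diff(recall) >= 0))
})

test_that("BH keeps the null false-positive fraction in check", {
  pm <- planted_matrix(n_sites = 800, n_drift = 0, seed = 23)
  st <- site_age_stats(pm$mat, pm$ages, pm$groups)
  frac <- mean(st$adj_p_pearson < 0.05, na.rm = TRUE)
  expect_lte(frac, 0.05 + 3 * sqrt(0.05 * 0.95 / 800))
})

test_that("sites collapse into padded, non-overlapping regions", {
  two <- data.frame(chrom = "chr1", pos = c(1000, 1100))
  r1 <- collapse_to_regions(two, merge_gap_bp = 200, pad_bp = 60)
  expect_equal(nrow(r1), 1L)
  expect_equal(r1$n_sites, 2L)
  expect_equal(r1$start, 1000 - 1 - 60)
  expect_equal(r1$end, 1100 - 1 + 60 + 1)
  far <- data.frame(chrom = "chr1", pos = c(1000, 11000))
  expect_equal(nrow(collapse_to_regions(far)), 2L)
})

test_that("region collapse equals a brute-force interval merge", {
  set.seed(31)
  pos <- sort(c(sample.int(1e6, 300),
                rep(sample.int(1e6, 50), each = 4) +
                  sample(0:150, 200, replace = TRUE)))
  sites <- data.frame(chrom = "chr1", pos = pos,
                      pearson_r = rnorm(length(pos)))
  got <- collapse_to_regions(sites, merge_gap_bp = 200, pad_bp = 60)
  # brute force: single left-to-right sweep over sorted positions
  runs <- split(pos, cumsum(c(1, diff(pos) > 200)))
  expect_equal(nrow(got), length(runs))
  expect_equal(got$start, vapply(runs, function(p)
    max(0, min(p) - 1 - 60), numeric(1)), ignore_attr = TRUE)
  expect_equal(got$end, vapply(runs, function(p) max(p) - 1 + 61,
                               numeric(1)), ignore_attr = TRUE)
  expect_equal(got$n_sites, vapply(runs, length, integer(1)),
               ignore_attr = TRUE)
  # direction summary matches per-run fraction of positive correlations
  expect_equal(got$frac_positive, vapply(runs, function(p)
    mean(sites$pearson_r[sites$pos %in% p] > 0), numeric(1)),
    ignore_attr = TRUE)
  # non-overlapping and stable under a further merge
  expect_true(all(got$start[-1] > head(got$end, -1)))
})

test_that("nearest-element annotation reports all ties and zero inside", {
  els <- rbind(
    data.frame(chrom = "chr1", start = 1000, end = 2000, strand = "+",
               kind = "gene", name = "g1"),
    data.frame(chrom = "chr1", start = 2999, end = 3999, strand = "*",
               kind = "repeat", name = "r1"))
  inside <- annotate_nearest_element(data.frame(chrom = "chr1", pos = 1500),
                                     els)
  expect_equal(inside$annotation$element_name, "g1")
  expect_equal(inside$annotation$distance, 0L)
  # pos0 = 2499 is 500 bp right of g1's last base (1999) and 500 bp left of
  # r1's first base (2999): a tie, both reported
  tie <- annotate_nearest_element(data.frame(chrom = "chr1", pos = 2500), els)
  expect_equal(sort(tie$annotation$element_name), c("g1", "r1"))
  expect_equal(tie$annotation$distance, c(500L, 500L))
  orphan <- annotate_nearest_element(
    data.frame(chrom = c("chr1", "chrX"), pos = c(1500, 10)), els)
  expect_equal(orphan$n_unannotated, 1L)
})

test_that("nearest-element annotation matches a brute-force scan", {
  cohort <- small_cohort()
  els <- rbind(cohort$annotation$genes, cohort$annotation$repeats)
  set.seed(41)
  sites <- data.frame(chrom = sample(paste0("chr", 1:3), 1000, TRUE),
                      pos = sample.int(1490000, 1000))
  got <- annotate_nearest_element(sites, els)
  key <- paste(got$annotation$chrom, got$annotation$pos)
  for (i in sample(1000, 25)) {
    p0 <- sites$pos[i] - 1
    on_chr <- which(els$chrom == sites$chrom[i])
    d <- vapply(on_chr, function(j) {
      if (p0 >= els$start[j] && p0 < els$end[j]) 0
      else min(abs(p0 - els$start[j]), abs(p0 - (els$end[j] - 1)))
    }, numeric(1))
    best <- on_chr[d == min(d)]
    rows <- which(key == paste(sites$chrom[i], sites$pos[i]))
    expect_setequal(got$annotation$element_name[rows], els$name[best])
    expect_true(all(got$annotation$distance[rows] == min(d)))
  }
})
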