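# Fixture builders shared across test files. Everything is generated in
# code; nothing is read from disk except what the tests themselves write.

make_records <- function(chrom, pos, meth, total, context = "CG",
                         dinucleotide = ifelse(context == "CG", "CG", "CT"),
                         base = "C") {
  data.frame(chrom = chrom, base = base, pos = pos, context = context,
             dinucleotide = dinucleotide, level = meth / total,
             meth_count = as.integer(meth), total_count = as.integer(total),
             stringsAsFactors = FALSE)
}

random_records <- function(n, seed = 1, chroms = c("chr1", "chr2")) {
  set.seed(seed)
  total <- sample(1:60, n, replace = TRUE)
  make_records(chrom = sample(chroms, n, replace = TRUE),
               pos = sample.int(5e5, n),
               meth = rbinom(n, total, runif(n)),
               total = total)
}

# A small cohort simulated once per test run and reused read-only.
small_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(n_cg_sites = 1000, n_noncg_sites = 300, seed = 101)
      dir <- file.path(tempdir(), "methage_small_cohort")
      cache <<- list(config = cfg,
                     sim = simulate_cohort(cfg, dir),
                     annotation = simulate_annotation(cfg,
                                                      file.path(dir, "ann")))
    }
    cache
  }
})

# Matrix of raw levels with planted linear age drift, no read sampling —
# for operation-level tests that work on a methyl_matrix directly.
planted_matrix <- function(n_sites = 1000, n_drift = 50, slope_min = 0.02,
                           noise_sd = 0.03, seed = 5,
                           ages = rep(c(1, 5, 9), each = 3)) {
  set.seed(seed)
  n <- length(ages)
  baseline <- runif(n_sites, 0.2, 0.8)
  slope <- numeric(n_sites)
  drift_idx <- sample.int(n_sites, n_drift)
  slope[drift_idx] <- sample(c(-1, 1), n_drift, replace = TRUE,
                             prob = c(0.8, 0.2)) *
    runif(n_drift, slope_min, slope_min + 0.02)
  lv <- outer(baseline, rep(1, n)) + outer(slope, ages) +
    matrix(rnorm(n_sites * n, 0, noise_sd), n_sites)
  lv <- pmin(pmax(lv, 0), 1)
  sites <- data.frame(chrom = "chr1", pos = seq_len(n_sites) * 100,
                      context = "CG", stringsAsFactors = FALSE)
  rownames(lv) <- paste0("chr1:", sites$pos)
  colnames(lv) <- paste0("S", seq_len(n))
  mat <- methage:::new_methyl_matrix(sites, colnames(lv), lv, 1, "CG")
  list(mat = mat, ages = ages,
       groups = rep(c("Y", "M", "O"), each = 3)[seq_len(n)],
       drift_idx = sort(drift_idx), slope = slope)
}
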