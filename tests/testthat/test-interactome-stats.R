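# shared miniature table builder
make_table <- function(values, nrep = 3) {
  intensity_table(
    values,
    condition = rep(c("control", "bait"), each = nrep),
    replicate = rep(seq_len(nrep), 2)
  )
}

test_that("normalize_medians equalizes medians and is idempotent", {
  set.seed(42)
  n <- 1000
  base <- exp(rnorm(n, 16, 2))
  scales <- exp(runif(6, log(0.5), log(2)))
  v <- outer(base, scales)
  rownames(v) <- sprintf("P%04d", seq_len(n))
  tbl <- make_table(v)
  norm <- normalize_medians(tbl)
  med <- apply(norm$values, 2, median)
  expect_lt(max(med) - min(med), 1e-9 * max(med))
  # idempotent
  norm2 <- normalize_medians(norm)
  expect_equal(norm2$values, norm$values, tolerance = 1e-14)
  # identical columns unchanged
  v2 <- matrix(rep(base[1:50], 6), ncol = 6)
  rownames(v2) <- sprintf("Q%02d", 1:50)
  same <- normalize_medians(make_table(v2))
  expect_equal(same$values, make_table(v2)$values)
  # doubling a column is undone
  v3 <- cbind(v2[, 1:5], v2[, 6] * 2)
  rownames(v3) <- rownames(v2)
  halved <- normalize_medians(make_table(v3))
  expect_equal(median(halved$values[, 6]), median(halved$values[, 1]))
})

test_that("normalize_medians errors on an all-missing column", {
  v <- matrix(runif(60, 10, 20), ncol = 6)
  rownames(v) <- sprintf("P%02d", 1:10)
  v[, 3] <- NA
  expect_error(normalize_medians(make_table(v)), "no detected")
})

test_that("impute_missing draws from the bottom decile, deterministically", {
  set.seed(7)
  v <- matrix(exp(rnorm(600, 16, 2)), ncol = 6)
  rownames(v) <- sprintf("P%03d", 1:100)
  miss <- sample(length(v), 60)
  v[miss] <- NA
  tbl <- make_table(v)
  imp <- impute_missing(tbl, seed = 99)
  expect_false(anyNA(imp$values))
  detected <- v[!is.na(v)]
  q10 <- quantile(detected, 0.10)
  filled <- imp$values[miss]
  expect_true(all(filled >= min(detected) & filled <= q10))
  # detected cells untouched
  expect_equal(imp$values[-miss], v[-miss])
  # determinism contract
  expect_identical(impute_missing(tbl, seed = 99)$values, imp$values)
  expect_false(identical(impute_missing(tbl, seed = 100)$values, imp$values))
  # no missing values: identity
  full <- make_table(matrix(runif(60, 5, 9), ncol = 6,
    dimnames = list(sprintf("R%02d", 1:10), NULL)))
  expect_identical(impute_missing(full, seed = 1)$values, full$values)
})

test_that("test_depletion matches the textbook pooled-variance t-test", {
  # frozen oracle: control log2 {10.0,10.2,9.8}, bait {9.0,9.1,8.9}
  # => lfc = -1, t = -7.7459666924, df = 4, p = 0.0014964810559
  v <- rbind(A = 2^c(10.0, 10.2, 9.8, 9.0, 9.1, 8.9))
  res <- test_depletion(make_table(v))
  expect_equal(res$log2_fc, -1, tolerance = 1e-12)
  expect_equal(res$p_value, 0.0014964810559, tolerance = 1e-9)
  # dual route: agree with stats::t.test on random data
  set.seed(5)
  for (i in 1:5) {
    x <- rnorm(4, 15, 1)
    y <- rnorm(4, 14, 1)
    v <- matrix(2^c(x, y), nrow = 1, dimnames = list("Z", NULL))
    got <- test_depletion(make_table(v, nrep = 4))
    ref <- t.test(y, x, var.equal = TRUE)
    expect_equal(got$p_value, ref$p.value, tolerance = 1e-12)
  }
})

test_that("test_depletion zero-variance conventions", {
  v <- rbind(
    same = 2^c(10, 10, 10, 10, 10, 10),
    shift = 2^c(10, 10, 10, 8, 8, 8)
  )
  res <- test_depletion(make_table(v))
  expect_equal(res$p_value[res$prey_id == "same"], 1)
  expect_equal(res$log2_fc[res$prey_id == "shift"], -2)
  expect_equal(res$p_value[res$prey_id == "shift"], .Machine$double.xmin)
  expect_identical(res$flag[res$prey_id == "shift"], "zero-variance")
})

test_that("fit_threshold recovers the generating sigma and scales", {
  set.seed(11)
  x <- rnorm(10000, 0, 0.5)
  curve <- fit_threshold(x)
  expect_equal(curve$x0, 1.0, tolerance = 0.05)
  expect_identical(curve$flag, "gaussian-fit")
  # scale equivariance
  curve2 <- fit_threshold(2 * x)
  expect_equal(curve2$x0 / curve$x0, 2, tolerance = 0.02)
  # narrow distribution -> small x0
  curve3 <- fit_threshold(rnorm(5000, 0, 0.01))
  expect_lt(curve3$x0, 0.05)
  expect_error(fit_threshold(rep(0.3, 100)), "degenerate")
  expect_error(fit_threshold(rnorm(10)), "50")
})

test_that("is_significant implements the hyperbolic boundary, inclusive", {
  curve <- list(y0 = 1.3, c = 1, x0 = 1)
  # exactly on the curve at |x| = 2: threshold = 1.3 + 1/(2-1) = 2.3
  expect_true(is_significant(-2, 10^-2.3, curve, side = "depletion"))
  expect_false(is_significant(-2, 10^-2.2, curve, side = "depletion"))
  # inside the asymptote nothing is significant
  expect_false(is_significant(-1, 1e-300, curve, side = "depletion"))
  expect_false(is_significant(-0.5, 0, curve, side = "both"))
  # |x| = 3: threshold 1.8
  expect_true(is_significant(-3, 10^-1.9, curve, side = "depletion"))
  # side restriction
  expect_false(is_significant(3, 10^-5, curve, side = "depletion"))
  expect_true(is_significant(3, 10^-5, curve, side = "enrichment"))
  expect_true(is_significant(3, 10^-5, curve, side = "both"))
})

test_that("significance is monotone in p and in |fold change|", {
  curve <- list(y0 = 1.3, c = 1, x0 = 0.8)
  set.seed(3)
  for (i in 1:50) {
    x <- -runif(1, 0, 4)
    p <- 10^-runif(1, 0, 6)
    if (is_significant(x, p, curve, "depletion")) {
      expect_true(is_significant(x, p / 10, curve, "depletion"))
      expect_true(is_significant(x - 0.5, p, curve, "depletion"))
    }
  }
})

test_that("pipeline recovers binders and controls the null", {
  # a single 1000-prey draw holds only ~13 sub-10 uM binders, so the 80%
  # property is tested on the pool of five seeded simulations; imputation
  # of a missing replicate is the dominant (and expected) error source
  # for the tightest binders
  ok <- n_sub10 <- 0
  for (seed in 1:5) {
    sim <- simulate_nhu_ms(simulation_spec(seed = seed,
      detection_limit_missing = 0))
    res <- run_nhu_pipeline(sim$table, C_bait = 26, seed = seed)
    expect_s3_class(res, "holdup_result")
    expect_equal(nrow(res), 1000)
    merged <- merge(as.data.frame(res), sim$truth, by = "prey_id",
      suffixes = c("_est", "_true"))
    sub10 <- merged[merged$is_binder & merged$K_app_true <= 10, ]
    ok <- ok + sum(sub10$significant &
      abs(log2(sub10$K_app_est / sub10$K_app_true)) <= 1)
    n_sub10 <- n_sub10 + nrow(sub10)
    # significant calls are depletion-side and above the curve
    curve <- attr(res, "threshold")
    sig <- res[res$significant, ]
    expect_true(all(sig$log2_fc < 0))
    expect_true(all(abs(sig$log2_fc) > curve$x0))
  }
  expect_gte(ok / n_sub10, 0.8)
  # null: false-positive rate at most 1%
  null <- simulate_nhu_ms(simulation_spec(seed = 21, n_binders = 0,
    n_replicates = 3))
  nres <- run_nhu_pipeline(null$table, C_bait = 26, seed = 21)
  expect_lte(mean(nres$significant), 0.01)
})

test_that("pipeline is permutation-equivariant in protein order", {
  sim <- simulate_nhu_ms(simulation_spec(seed = 13, n_proteins = 200,
    n_binders = 5))
  res1 <- run_nhu_pipeline(sim$table, 26, seed = 13)
  perm <- sample(nrow(sim$table$values))
  tbl2 <- sim$table
  tbl2$values <- tbl2$values[perm, , drop = FALSE]
  res2 <- run_nhu_pipeline(tbl2, 26, seed = 13)
  # same proteins, same fold changes (imputation draws may differ per cell,
  # so compare the deterministic columns of proteins with no missing data)
  complete <- rownames(sim$table$values)[!apply(
    is.na(sim$table$values), 1, any
  )]
  a <- res1[match(complete, res1$prey_id), c("log2_fc", "p_value")]
  b <- res2[match(complete, res2$prey_id), c("log2_fc", "p_value")]
  expect_equal(a$log2_fc, b$log2_fc, tolerance = 1e-12)
  expect_equal(a$p_value, b$p_value, tolerance = 1e-12)
})

test_that("single-prey worked conversion flows through the result table", {
  # a prey with I_free/I_tot = 0.78 at 26 uM reports ~92 uM
  theta <- degree_of_binding(0.78, 1)
  est <- kapp_from_theta(theta, 26)
  expect_equal(est$K_app, 92.2, tolerance = 0.005)
})
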