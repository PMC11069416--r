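test_that("pseudo-dyads are all ordered cross-pairings within feature groups", {
  meta2 <- tibble::tibble(
    dyad = c("d02", "d25"), video_order = c("order_AB", "order_AB"),
    participant_a = c("d02A", "d25A"), participant_b = c("d02B", "d25B"),
    is_real = TRUE)
  ps <- build_pseudo_dyads(meta2)
  expect_equal(nrow(ps), 2)
  expect_setequal(paste(ps$participant_a, ps$participant_b),
                  c("d02A d25B", "d25A d02B"))
  expect_true(all(!ps$is_real))

  # groups of sizes {2, 2}: 4 pseudo-dyads, enumerated
  meta4 <- tibble::tibble(
    dyad = sprintf("d%02d", 1:4),
    video_order = c("order_AB", "order_BA", "order_AB", "order_BA"),
    participant_a = sprintf("d%02dA", 1:4), participant_b = sprintf("d%02dB", 1:4),
    is_real = TRUE)
  ps4 <- build_pseudo_dyads(meta4)
  expect_equal(nrow(ps4), 4)
  # no pseudo pair crosses order groups
  ord_a <- meta4$video_order[match(ps4$source_a, meta4$dyad)]
  ord_b <- meta4$video_order[match(ps4$source_b, meta4$dyad)]
  expect_true(all(ord_a == ord_b))

  # a singleton group contributes nothing
  meta1 <- meta4[1, ]
  expect_equal(nrow(build_pseudo_dyads(meta1)), 0)

  # missing feature errors
  metaNA <- meta4; metaNA$video_order[2] <- NA
  expect_error(build_pseudo_dyads(metaNA), "feature")
})

test_that("pseudo-dyad counts equal sum k(k-1) over groups for random groupings", {
  set.seed(51)
  for (rep in 1:10) {
    k <- sample(3:12, 1)
    orders <- sample(c("a", "b", "c"), k, replace = TRUE)
    meta <- tibble::tibble(dyad = sprintf("d%02d", 1:k), video_order = orders,
                           participant_a = sprintf("d%02dA", 1:k),
                           participant_b = sprintf("d%02dB", 1:k), is_real = TRUE)
    expected <- sum(vapply(split(orders, orders), function(g)
      length(g) * (length(g) - 1), numeric(1)))
    expect_equal(nrow(build_pseudo_dyads(meta)), expected)
  }
})

test_that("the permutation test handles degenerate and null inputs", {
  r <- permutation_test(rep(1, 5), rep(1, 7), n_perm = 200, seed = 2)
  expect_equal(r$t, 0)
  expect_equal(r$p, 1)
  expect_true(r$degenerate)
  expect_warning(permutation_test(rnorm(3), rnorm(3), n_perm = 50, seed = 1),
                 "coarse")
  expect_error(permutation_test(1, rnorm(3)), "at least 2")
})

test_that("Monte-Carlo p matches exhaustive relabelling at tiny n", {
  x <- c(0.1, 0.25, 0.4); y <- c(0.5, 0.65, 0.9)
  # exhaustive two-sided p over all C(6,3) label assignments
  z <- c(x, y)
  t_of <- function(idx) {
    a <- z[idx]; b <- z[-idx]
    sp <- ((length(a) - 1) * var(a) + (length(b) - 1) * var(b)) / (length(z) - 2)
    (mean(a) - mean(b)) / sqrt(sp * (1 / length(a) + 1 / length(b)))
  }
  t_obs <- t_of(1:3)
  combs <- utils::combn(6, 3)
  t_all <- apply(combs, 2, t_of)
  p_exact <- mean(abs(t_all) >= abs(t_obs) - 1e-12)
  r <- permutation_test(x, y, n_perm = 4000, seed = 7)
  se <- sqrt(p_exact * (1 - p_exact) / 4000)
  expect_lt(abs(r$p - p_exact), 2 * se + 1 / 4000)
  expect_equal(r$t, t_obs, tolerance = 1e-12)
})

test_that("permutation p is invariant under common affine transforms", {
  set.seed(52)
  x <- rnorm(8); y <- rnorm(12) + 0.5
  p0 <- permutation_test(x, y, n_perm = 500, seed = 3)$p
  p1 <- permutation_test(3.2 * x - 7, 3.2 * y - 7, n_perm = 500, seed = 3)$p
  expect_equal(p0, p1)
})

test_that("the permutation test is reproducible and counts its draws", {
  set.seed(53)
  x <- rnorm(6); y <- rnorm(9)
  a <- permutation_test(x, y, n_perm = 300, seed = 11)
  b <- permutation_test(x, y, n_perm = 300, seed = 11)
  expect_equal(a$p, b$p)
  permutation_draws(reset = TRUE)
  invisible(permutation_test(x, y, n_perm = 300, seed = 11))
  invisible(permutation_test(x, y, n_perm = 450, seed = 12))
  expect_equal(permutation_draws(), 750)
})

test_that("the empirical type-I error of the permutation test is nominal", {
  set.seed(54)
  reps <- 400
  rej <- vapply(seq_len(reps), function(i) {
    x <- rnorm(8); y <- rnorm(12)
    permutation_test(x, y, n_perm = 400, seed = 54000 + i)$p < 0.05
  }, logical(1))
  rate <- mean(rej)
  expect_gt(rate, 0.02)
  expect_lt(rate, 0.08)
})

test_that("effect sizes follow the pooled-SD definition with shrinking CI", {
  # equal group means: d = 0, CI symmetric about 0
  es0 <- effect_size(c(1, 2, 3), c(3, 2, 1))
  expect_equal(es0$d, 0)
  expect_equal(es0$ci_low, -es0$ci_high)

  # two large samples one pooled SD apart: d ~ 1
  set.seed(55)
  a <- rnorm(4000); b <- rnorm(4000)
  a <- (a - mean(a)) / sd(a) + 1
  b <- (b - mean(b)) / sd(b)
  es1 <- effect_size(a, b)
  expect_equal(es1$d, 1, tolerance = 1e-9)

  # quadrupling n halves the CI width approximately (d = 0 case)
  w <- function(n) { set.seed(56); x <- rnorm(n); y <- rnorm(n)
    e <- effect_size(x - mean(x), y - mean(y)); e$ci_high - e$ci_low }
  expect_equal(w(4000) / w(1000), 0.5, tolerance = 0.02)

  # zero pooled SD flags degenerate
  expect_true(effect_size(c(1, 1), c(1, 1))$degenerate)
})

test_that("the within-real paired t matches the textbook formula", {
  # v2 = v1 gives t = 0, p = 1
  v <- c(0.1, 0.2, 0.3)
  r0 <- paired_t_within_real(v, v)
  expect_equal(r0$t, 0)
  expect_equal(r0$p, 1)
  expect_true(r0$degenerate)

  # 27 pairs gives 26 degrees of freedom
  set.seed(57)
  v1 <- rnorm(27); v2 <- v1 + rnorm(27, 0.1, 0.2)
  r <- paired_t_within_real(v1, v2)
  expect_equal(r$df, 26)

  # brute-force formula on small vectors
  a <- c(0.12, 0.34, 0.22, 0.41, 0.18)
  b <- c(0.20, 0.30, 0.35, 0.44, 0.25)
  d <- b - a
  t_manual <- mean(d) / (sd(d) / sqrt(length(d)))
  p_manual <- 2 * stats::pt(-abs(t_manual), length(d) - 1)
  rb <- paired_t_within_real(a, b)
  expect_equal(rb$t, t_manual, tolerance = 1e-12)
  expect_equal(rb$p, p_manual, tolerance = 1e-12)
  expect_equal(rb$mean_diff, mean(d), tolerance = 1e-12)

  expect_error(paired_t_within_real(1:3, 1:4), "paired")
})

test_that("p-value adjustment dispatches correctly", {
  p <- c(0.001, 0.02, 0.04, 0.2, 0.8)
  expect_equal(adjust_pvalues(p, "none"), p)
  expect_equal(adjust_pvalues(p, "bonferroni"), pmin(1, p * 5))
  # Benjamini-Hochberg step-up brute force
  m <- length(p)
  o <- order(p)
  bh_manual <- numeric(m)
  prev <- 1
  for (i in rev(seq_len(m))) {
    prev <- min(prev, p[o[i]] * m / i)
    bh_manual[o[i]] <- prev
  }
  expect_equal(adjust_pvalues(p, "BH"), bh_manual)
  expect_error(adjust_pvalues(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(adjust_pvalues(p, "fdr2"))
})

test_that("the permutation grid reports every cell with the standard layout", {
  set.seed(58)
  cells <- tidyr::expand_grid(roi = roi_table()$roi,
                              band = frequency_bands()$band)
  mk <- function(ids, is_real) {
    tidyr::expand_grid(dyad = ids, cells) |>
      dplyr::mutate(is_real = is_real, cowatch1 = rnorm(dplyr::n()),
                    change = rnorm(dplyr::n()))
  }
  measures <- dplyr::bind_rows(mk(sprintf("r%02d", 1:6), TRUE),
                               mk(sprintf("p%02d", 1:10), FALSE))
  g <- permutation_grid(measures, "cowatch1", n_perm = 200, seed = 4)
  expect_equal(nrow(g), 24)
  expect_equal(attr(g, "draws"), 24 * 200)
  expect_true(all(c("band", "roi", "real_mean", "real_sd", "pseudo_mean",
                    "pseudo_sd", "observed_diff", "t", "p", "effect_size",
                    "ci_low", "ci_high") %in% names(g)))
  expect_true(all(g$n_real == 6 & g$n_pseudo == 10))
  # deterministic under the same seed
  g2 <- permutation_grid(measures, "cowatch1", n_perm = 200, seed = 4)
  expect_equal(tidy(g), tidy(g2))
  # tidiers
  gl <- glance(g)
  expect_equal(gl$n_cells, 24)
  expect_equal(gl$draws, 4800)
})
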