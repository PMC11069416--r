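# permutation-draw execution counter (package-level, see permutation_draws())
ib_state <- new.env(parent = emptyenv())
ib_state$perm_draws <- 0

#' Permutation-draw counter
#'
#' Running count of label permutations executed by [permutation_test()]
#' since the last reset; a full 8-ROI x 3-band grid at 10,000 permutations
#' accounts for 240,000 draws per measure.
#'
#' @param reset Reset the counter to zero after reading.
#' @return The number of permutation draws performed.
#' @export
permutation_draws <- function(reset = FALSE) {
  n <- ib_state$perm_draws
  if (reset) ib_state$perm_draws <- 0
  n
}

pooled_t <- function(m1, m2, ss, n1, n2) {
  sp2 <- ss / (n1 + n2 - 2)
  if (sp2 <= 0) return(0)
  (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
}

#' Real-versus-pseudo permutation test
#'
#' Two-sample pooled-variance t statistic between the real-dyad and
#' pseudo-dyad values, calibrated by label permutation: the real/pseudo
#' labels are shuffled over the concatenated values (preserving group
#' sizes) `n_perm` times and the two-sided p-value is
#' `(1 + #{|t*| >= |t_obs|}) / (1 + n_perm)`, so p is never exactly zero.
#'
#' @param real,pseudo Numeric vectors of per-dyad values (at least 2 each).
#' @param n_perm Number of permutations; default 10000.
#' @param seed Integer seed fixing the shuffle sequence.
#' @param statistic `"pooled"` (default) or `"welch"`.
#' @return A `"permutation_result"`: observed difference of means, observed
#'   t, two-sided `p`, Cohen's `d` with 95% CI, group summaries, `n_perm`
#'   and `seed`. `degenerate` flags zero-variance input (then `p = 1`).
#' @export
permutation_test <- function(real, pseudo, n_perm = 10000, seed = 1L,
                             statistic = c("pooled", "welch")) {
  statistic <- match.arg(statistic)
  real <- as.numeric(real); pseudo <- as.numeric(pseudo)
  if (length(real) < 2 || length(pseudo) < 2)
    abort("need at least 2 values per group")
  if (anyNA(real) || anyNA(pseudo)) abort("missing values in group values")
  if (n_perm < 100) warn("fewer than 100 permutations gives a very coarse p-value")
  n1 <- length(real); n2 <- length(pseudo); n <- n1 + n2
  z <- c(real, pseudo)
  stat_fun <- if (statistic == "pooled") {
    Sz <- sum(z); Sz2 <- sum(z^2)
    function(s1) {
      m1 <- s1 / n1; m2 <- (Sz - s1) / n2
      ss <- Sz2 - n1 * m1^2 - n2 * m2^2
      pooled_t(m1, m2, ss, n1, n2)
    }
  } else NULL
  degenerate <- stats::var(z) <= 0
  if (statistic == "pooled") {
    t_obs <- stat_fun(sum(real))
  } else {
    t_obs <- unname(stats::t.test(real, pseudo)$statistic)
  }
  if (degenerate) {
    t_perm <- rep(0, n_perm)
  } else {
    t_perm <- with_seed(seed, {
      if (statistic == "pooled") {
        vapply(seq_len(n_perm),
               function(b) stat_fun(sum(z[sample.int(n, n1)])), numeric(1))
      } else {
        vapply(seq_len(n_perm), function(b) {
          idx <- sample.int(n, n1)
          unname(stats::t.test(z[idx], z[-idx])$statistic)
        }, numeric(1))
      }
    })
  }
  ib_state$perm_draws <- ib_state$perm_draws + n_perm
  p <- (1 + sum(abs(t_perm) >= abs(t_obs) - 1e-12)) / (1 + n_perm)
  if (degenerate) p <- 1
  es <- effect_size(real, pseudo)
  structure(list(
    observed_diff = mean(real) - mean(pseudo), t = t_obs, p = p,
    d = es$d, ci_low = es$ci_low, ci_high = es$ci_high,
    real_mean = mean(real), real_sd = sd(real),
    pseudo_mean = mean(pseudo), pseudo_sd = sd(pseudo),
    n_real = n1, n_pseudo = n2, n_perm = n_perm, seed = seed,
    statistic = statistic, degenerate = degenerate),
    class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf(
    "<permutation_result> diff = %.4g, t = %.3g, p = %.4g (%d perms), d = %.3g [%.3g, %.3g]\n",
    x$observed_diff, x$t, x$p, x$n_perm, x$d, x$ci_low, x$ci_high))
  if (x$degenerate) cat("  (degenerate zero-variance input)\n")
  invisible(x)
}

#' Cohen's d with a normal-approximation confidence interval
#'
#' `d = (mean(real) - mean(pseudo)) / pooled SD`, with the 95% CI from the
#' large-sample variance `(n1 + n2)/(n1 n2) + d^2 / (2 (n1 + n2))`.
#'
#' @param real,pseudo Numeric vectors (at least 2 values each).
#' @param conf_level Confidence level; default 0.95.
#' @return A one-row tibble: `d`, `ci_low`, `ci_high`, `degenerate`.
#' @export
effect_size <- function(real, pseudo, conf_level = 0.95) {
  n1 <- length(real); n2 <- length(pseudo)
  if (n1 < 2 || n2 < 2) abort("need at least 2 values per group")
  sp2 <- ((n1 - 1) * stats::var(real) + (n2 - 1) * stats::var(pseudo)) /
    (n1 + n2 - 2)
  if (sp2 <= 0)
    return(tibble::tibble(d = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                          degenerate = TRUE))
  d <- (mean(real) - mean(pseudo)) / sqrt(sp2)
  vd <- (n1 + n2) / (n1 * n2) + d^2 / (2 * (n1 + n2))
  zq <- stats::qnorm(1 - (1 - conf_level) / 2)
  tibble::tibble(d = d, ci_low = d - zq * sqrt(vd), ci_high = d + zq * sqrt(vd),
                 degenerate = FALSE)
}

#' Paired t-test of real dyads across the two co-watching phases
#'
#' Classic paired t on the per-dyad differences (second video minus first),
#' quantifying whether the intervening conversation changed co-watching
#' coherence within the real dyads alone.
#'
#' @param v1,v2 Equal-length vectors of per-dyad band coherence for the
#'   first and second video, paired by dyad.
#' @return A one-row tibble: `t`, `df`, `p`, `ci_low`, `ci_high`,
#'   `mean_diff`, `degenerate`.
#' @export
paired_t_within_real <- function(v1, v2) {
  if (length(v1) != length(v2)) abort("`v1` and `v2` must be paired (equal length)")
  if (length(v1) < 2) abort("need at least 2 pairs")
  d <- v2 - v1
  if (stats::var(d) <= 0)
    return(tibble::tibble(t = 0, df = length(d) - 1, p = 1, ci_low = mean(d),
                          ci_high = mean(d), mean_diff = mean(d),
                          degenerate = TRUE))
  tt <- stats::t.test(v2, v1, paired = TRUE)
  tibble::tibble(t = unname(tt$statistic), df = unname(tt$parameter),
                 p = tt$p.value, ci_low = tt$conf.int[1],
                 ci_high = tt$conf.int[2], mean_diff = unname(tt$estimate),
                 degenerate = FALSE)
}

#' Multiple-comparison adjustment of p-values
#'
#' Thin dispatcher over [stats::p.adjust()]: `"none"` (identity),
#' `"bonferroni"` or `"BH"` (Benjamini-Hochberg step-up).
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @param method Adjustment method.
#' @return Adjusted p-values, same length as `p`.
#' @export
adjust_pvalues <- function(p, method = c("none", "bonferroni", "BH")) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) abort("p-values must lie in [0, 1]")
  method <- match.arg(method)
  stats::p.adjust(p, method = method)
}

#' Construct pseudo-dyads matched on experimental features
#'
#' Groups real dyads by their experimental-feature tuple (episode order by
#' default) and, within each group of size k, forms all k(k-1) ordered
#' cross-pairings of one dyad's role-A participant with another dyad's
#' role-B participant. Groups of size 1 contribute no pseudo-dyads.
#'
#' @param meta Real-dyad metadata tibble with columns `dyad`,
#'   `participant_a`, `participant_b` and the feature columns.
#' @param features Character vector of matching columns; default
#'   `"video_order"`.
#' @return A tibble of pseudo-dyad metadata (`dyad`, `participant_a`,
#'   `participant_b`, feature columns, `source_a`, `source_b`,
#'   `is_real = FALSE`).
#' @export
build_pseudo_dyads <- function(meta, features = "video_order") {
  stopifnot(all(c("dyad", "participant_a", "participant_b") %in% names(meta)))
  missing_feat <- setdiff(features, names(meta))
  if (length(missing_feat) > 0)
    abort(sprintf("feature column(s) %s absent from metadata",
                  paste(missing_feat, collapse = ", ")))
  if (any(!stats::complete.cases(meta[, features, drop = FALSE])))
    abort("every real dyad must carry a value for each matching feature")
  key <- do.call(paste, c(meta[, features, drop = FALSE], sep = "\r"))
  out <- list()
  for (g in unique(key)) {
    rows <- which(key == g)
    if (length(rows) < 2) next
    for (i in rows) for (j in rows) {
      if (i == j) next
      out[[length(out) + 1L]] <- tibble::tibble(
        dyad = paste0("p_", meta$dyad[i], "_", meta$dyad[j]),
        participant_a = meta$participant_a[i],
        participant_b = meta$participant_b[j],
        source_a = meta$dyad[i], source_b = meta$dyad[j], is_real = FALSE)
    }
  }
  if (length(out) == 0)
    return(tibble::tibble(dyad = character(), participant_a = character(),
                          participant_b = character(), source_a = character(),
                          source_b = character(), is_real = logical()))
  res <- dplyr::bind_rows(out)
  feats <- meta[match(res$source_a, meta$dyad), features, drop = FALSE]
  dplyr::bind_cols(res[, c("dyad", "participant_a", "participant_b")], feats,
                   res[, c("source_a", "source_b", "is_real")])
}

#' Permutation tests over the full ROI-by-band grid
#'
#' Runs [permutation_test()] for one measure in every (ROI, band) cell and
#' returns the results in the standard reporting layout (band, region, real
#' mean (sd), pseudo mean (sd), observed difference, p, effect size, CI).
#' Cells with missing values (e.g. an ROI left unallocated for some dyad)
#' use the complete values only, with counts reported.
#'
#' @param measures Tibble with columns `dyad`, `is_real`, `roi`, `band` and
#'   the measure columns (`cowatch1`, `change`), as produced by the
#'   pipeline's coherence stage.
#' @param measure Which measure to test: `"cowatch1"` or `"change"` (or
#'   `"mean"`).
#' @param n_perm Permutations per cell; default 10000.
#' @param seed Master seed; each cell uses a seed derived from it.
#' @param statistic Passed to [permutation_test()].
#' @return A `"permutation_grid"` tibble with one row per (band, ROI) and a
#'   `draws` attribute counting the label permutations executed.
#' @export
permutation_grid <- function(measures, measure = c("cowatch1", "change", "mean"),
                             n_perm = 10000, seed = 1L,
                             statistic = c("pooled", "welch")) {
  measure <- match.arg(measure)
  statistic <- match.arg(statistic)
  if (!measure %in% names(measures))
    abort(sprintf("measure column '%s' absent", measure))
  draws0 <- permutation_draws()
  cells <- tidyr::expand_grid(band = band_names(), roi = roi_table()$roi)
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    b <- cells$band[i]; r <- cells$roi[i]
    sub <- measures[measures$band == b & measures$roi == r, ]
    v <- sub[[measure]]
    ok <- !is.na(v)
    real <- v[ok & sub$is_real]; pseudo <- v[ok & !sub$is_real]
    if (length(real) < 2 || length(pseudo) < 2)
      return(tibble::tibble(band = b, roi = r, real_mean = NA_real_,
                            real_sd = NA_real_, pseudo_mean = NA_real_,
                            pseudo_sd = NA_real_, observed_diff = NA_real_,
                            t = NA_real_, p = NA_real_, effect_size = NA_real_,
                            ci_low = NA_real_, ci_high = NA_real_,
                            n_real = length(real), n_pseudo = length(pseudo)))
    pr <- permutation_test(real, pseudo, n_perm = n_perm,
                           seed = derive_seed(seed, 31, i),
                           statistic = statistic)
    tibble::tibble(band = b, roi = r, real_mean = pr$real_mean,
                   real_sd = pr$real_sd, pseudo_mean = pr$pseudo_mean,
                   pseudo_sd = pr$pseudo_sd, observed_diff = pr$observed_diff,
                   t = pr$t, p = pr$p, effect_size = pr$d, ci_low = pr$ci_low,
                   ci_high = pr$ci_high, n_real = pr$n_real,
                   n_pseudo = pr$n_pseudo)
  })
  out <- dplyr::bind_rows(rows)
  out$measure <- measure
  attr(out, "draws") <- permutation_draws() - draws0
  attr(out, "n_perm") <- n_perm
  class(out) <- c("permutation_grid", class(out))
  out
}
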