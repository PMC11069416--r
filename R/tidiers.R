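#' @importFrom generics tidy glance
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a permutation test result
#'
#' @param x A `"permutation_result"` from [permutation_test()].
#' @param ... Unused.
#' @return A one-row tibble of the test's estimates.
#' @export
tidy.permutation_result <- function(x, ...) {
  tibble::tibble(observed_diff = x$observed_diff, t = x$t, p = x$p,
                 effect_size = x$d, ci_low = x$ci_low, ci_high = x$ci_high,
                 real_mean = x$real_mean, real_sd = x$real_sd,
                 pseudo_mean = x$pseudo_mean, pseudo_sd = x$pseudo_sd)
}

#' Glance at a permutation test result
#'
#' @param x A `"permutation_result"`.
#' @param ... Unused.
#' @return A one-row tibble of design facts (group sizes, permutations,
#'   seed, statistic, degeneracy).
#' @export
glance.permutation_result <- function(x, ...) {
  tibble::tibble(n_real = x$n_real, n_pseudo = x$n_pseudo, n_perm = x$n_perm,
                 seed = x$seed, statistic = x$statistic,
                 degenerate = x$degenerate)
}

#' Tidy a permutation grid
#'
#' @param x A `"permutation_grid"` from [permutation_grid()].
#' @param ... Unused.
#' @return The grid as a plain tibble (one row per band x ROI).
#' @export
tidy.permutation_grid <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "permutation_grid")
  tibble::as_tibble(out)
}

#' Glance at a permutation grid
#'
#' @param x A `"permutation_grid"`.
#' @param ... Unused.
#' @return A one-row tibble: number of cells, tested cells, minimum p and
#'   its cell, permutations per cell and total draws.
#' @export
glance.permutation_grid <- function(x, ...) {
  ok <- !is.na(x$p)
  i <- which.min(replace(x$p, !ok, Inf))
  tibble::tibble(measure = x$measure[1], n_cells = nrow(x),
                 n_tested = sum(ok), min_p = x$p[i], min_p_roi = x$roi[i],
                 min_p_band = x$band[i], n_perm = attr(x, "n_perm"),
                 draws = attr(x, "draws"))
}
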