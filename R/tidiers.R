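# broom-style tidiers for the package's result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a cluster permutation test
#'
#' @param x an `rs_cluster_test`.
#' @param ... unused.
#' @return tibble with one row per cluster: `start_ms`, `end_ms`, `sign`,
#'   `t_sum`, `p_value`, `significant`.
#' @export
tidy.rs_cluster_test <- function(x, ...) {
  dplyr::mutate(x$clusters, significant = .data$p_value < x$cluster_alpha)
}

#' One-row summary of a cluster permutation test
#'
#' @param x an `rs_cluster_test`.
#' @param ... unused.
#' @return one-row tibble: unit count, permutations, cluster counts and the
#'   smallest cluster p-value.
#' @export
glance.rs_cluster_test <- function(x, ...) {
  tibble::tibble(
    n_units = x$n_units, n_perm = x$n_perm, alpha_bin = x$alpha_bin,
    cluster_alpha = x$cluster_alpha, n_clusters = nrow(x$clusters),
    n_significant = sum(x$clusters$p_value < x$cluster_alpha),
    min_p = if (nrow(x$clusters) > 0) min(x$clusters$p_value) else NA_real_
  )
}
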