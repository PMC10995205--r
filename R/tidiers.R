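#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a PERMANOVA result
#'
#' @param x A `magniche_permanova` object.
#' @param ... Unused.
#' @return One-row tibble with term, df, sums of squares, pseudo-F, R² and
#'   permutation p.
#' @export
tidy.magniche_permanova <- function(x, ...) {
  tibble(
    term = c("groups", "residual"),
    df = unname(x$df),
    sum_of_squares = unname(x$ss[c("between", "within")]),
    statistic = c(x$statistic, NA_real_),
    R_squared = c(x$R_squared, NA_real_),
    p_value = c(x$p_value, NA_real_)
  )
}

#' @rdname tidy.magniche_permanova
#' @export
glance.magniche_permanova <- function(x, ...) {
  tibble(statistic = x$statistic, R_squared = x$R_squared,
         p_value = x$p_value, n = x$n,
         n_permutations = x$n_permutations, method = x$method)
}

#' Tidy ordination sample scores
#'
#' @param x A `magniche_pcoa` or `magniche_dbrda` object.
#' @param ... Unused.
#' @return Tibble with `sample_id` and one column per retained axis.
#' @export
tidy.magniche_pcoa <- function(x, ...) {
  as_tibble(x$scores, rownames = "sample_id")
}

#' @rdname tidy.magniche_pcoa
#' @export
tidy.magniche_dbrda <- function(x, ...) {
  as_tibble(x$scores, rownames = "sample_id")
}

#' @rdname tidy.magniche_pcoa
#' @export
glance.magniche_pcoa <- function(x, ...) {
  tibble(
    n_axes = ncol(x$scores),
    total_inertia = x$total_inertia,
    prop_first_axis = x$prop_var[1],
    n_negative_eigenvalues = length(x$negative_eigenvalues)
  )
}

#' @rdname tidy.magniche_pcoa
#' @export
glance.magniche_dbrda <- function(x, ...) {
  tibble(
    constrained_inertia = x$constrained_inertia,
    unconstrained_inertia = x$unconstrained_inertia,
    total_inertia = x$total_inertia,
    constrained_proportion = x$constrained_inertia / x$total_inertia,
    n_constrained_axes = x$n_constrained_axes
  )
}
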