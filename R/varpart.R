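#' Signed squared correlation
#'
#' Converts a prediction correlation into explained variance,
#' `R^2 = sign(r) * r^2`. The signed square keeps anti-correlated
#' predictions from masquerading as explained variance.
#'
#' @param r Correlation(s) in `[-1, 1]`.
#' @return Signed R-squared value(s).
#' @export
r2_from_score <- function(r) {
  stopifnot(all(abs(r) <= 1 + 1e-12, na.rm = TRUE))
  sign(r) * r^2
}

#' Two-set variance partition
#'
#' Set-theoretic decomposition of the explained variance of two models A, B
#' and their joint model: `shared = A + B - A_union_B`,
#' `unique_A = A_union_B - B`, `unique_B = A_union_B - A`. Negative terms
#' (possible through overfitting) are allowed here and handled by
#' [bias_correct()].
#'
#' @param r2_a,r2_b,r2_ab Explained variance (R^2) of model A, model B and
#'   the joint model.
#' @return An object of class `var_partition`.
#' @export
partition_two <- function(r2_a, r2_b, r2_ab) {
  stopifnot(is.finite(r2_a), is.finite(r2_b), is.finite(r2_ab))
  new_var_partition(
    n_sets = 2L,
    totals = c(A = r2_a, B = r2_b),
    unions = c(AB = r2_ab),
    bias = 0
  )
}

#' Three-set variance partition
#'
#' Extends the two-set identity to three models using inclusion-exclusion:
#' pairwise intersections `A_int_B = A + B - A_union_B` and the triple
#' intersection
#' `A_int_B_int_C = A_union_B_union_C + A + B + C - A_union_B - B_union_C -
#' A_union_C`; unique terms follow as, e.g.,
#' `unique_A = A - A_int_B - A_int_C + A_int_B_int_C`.
#'
#' @param r2_singles Named numeric of length 3 (`A`, `B`, `C`): single-model
#'   R^2.
#' @param r2_pairs Named numeric of length 3 (`AB`, `AC`, `BC`): pairwise
#'   joint-model R^2.
#' @param r2_full R^2 of the full joint model (A union B union C).
#' @return An object of class `var_partition`.
#' @export
partition_three <- function(r2_singles, r2_pairs, r2_full) {
  r2_singles <- r2_singles[c("A", "B", "C")]
  r2_pairs <- r2_pairs[c("AB", "AC", "BC")]
  stopifnot(all(is.finite(c(r2_singles, r2_pairs, r2_full))))
  new_var_partition(
    n_sets = 3L,
    totals = r2_singles,
    unions = c(r2_pairs, ABC = unname(r2_full)),
    bias = 0
  )
}

#' Three-set partition from printed intersection terms
#'
#' Builds a [partition_three()] object from totals plus intersection terms
#' (the layout of a published variance-partitioning table), by first
#' reconstructing the implied union-model R^2 values through
#' inclusion-exclusion.
#'
#' @param totals Named numeric (`A`, `B`, `C`).
#' @param pairwise Named numeric (`AB`, `AC`, `BC`): pairwise
#'   intersections.
#' @param triple Triple intersection.
#' @export
partition_from_intersections <- function(totals, pairwise, triple) {
  totals <- totals[c("A", "B", "C")]
  pairwise <- pairwise[c("AB", "AC", "BC")]
  unions <- c(
    AB = unname(totals["A"] + totals["B"] - pairwise["AB"]),
    AC = unname(totals["A"] + totals["C"] - pairwise["AC"]),
    BC = unname(totals["B"] + totals["C"] - pairwise["BC"]),
    ABC = unname(sum(totals) - sum(pairwise) + triple)
  )
  partition_three(totals, unions[c("AB", "AC", "BC")], unions[["ABC"]])
}

# Core constructor: derives intersections/uniques from totals and unions.
new_var_partition <- function(n_sets, totals, unions, bias) {
  if (n_sets == 2L) {
    shared <- unname(totals["A"] + totals["B"] - unions["AB"])
    uniques <- c(A = unname(unions[["AB"]] - totals[["B"]]),
                 B = unname(unions[["AB"]] - totals[["A"]]))
    pairwise <- c(AB = shared)
    triple <- NULL
  } else {
    pairwise <- c(
      AB = unname(totals[["A"]] + totals[["B"]] - unions[["AB"]]),
      AC = unname(totals[["A"]] + totals[["C"]] - unions[["AC"]]),
      BC = unname(totals[["B"]] + totals[["C"]] - unions[["BC"]])
    )
    triple <- unname(unions[["ABC"]] + sum(totals) -
                       unions[["AB"]] - unions[["BC"]] - unions[["AC"]])
    uniques <- c(
      A = unname(totals[["A"]] - pairwise[["AB"]] - pairwise[["AC"]] +
                   triple),
      B = unname(totals[["B"]] - pairwise[["AB"]] - pairwise[["BC"]] +
                   triple),
      C = unname(totals[["C"]] - pairwise[["AC"]] - pairwise[["BC"]] +
                   triple)
    )
  }
  structure(list(n_sets = n_sets, totals = totals, unions = unions,
                 uniques = uniques, pairwise = pairwise, triple = triple,
                 bias = bias),
            class = "var_partition")
}

#' @export
print.var_partition <- function(x, ...) {
  cat(sprintf("<var_partition> %d sets, bias = %g\n", x$n_sets, x$bias))
  print(tidy(x))
  invisible(x)
}

#' @rdname partition_two
#' @param x A `var_partition`.
#' @param ... Unused.
#' @method tidy var_partition
#' @export
tidy.var_partition <- function(x, ...) {
  tb <- dplyr::bind_rows(
    tibble::tibble(term = paste0("total_", names(x$totals)),
                   r2 = unname(x$totals)),
    tibble::tibble(term = paste0("union_", names(x$unions)),
                   r2 = unname(x$unions)),
    tibble::tibble(term = paste0("unique_", names(x$uniques)),
                   r2 = unname(x$uniques)),
    tibble::tibble(term = paste0("shared_", names(x$pairwise)),
                   r2 = unname(x$pairwise))
  )
  if (!is.null(x$triple)) {
    tb <- dplyr::bind_rows(tb, tibble::tibble(term = "shared_ABC",
                                              r2 = x$triple))
  }
  tb
}

#' @rdname partition_two
#' @method glance var_partition
#' @export
glance.var_partition <- function(x, ...) {
  tibble::tibble(n_sets = x$n_sets, bias = x$bias,
                 min_term = min(c(x$uniques, x$pairwise, x$triple)))
}

#' Nonnegativity bias correction for a variance partition
#'
#' Set theory requires every unique and shared term to be at least zero,
#' but overfitting inflates joint (union) models and can push terms
#' negative. The correction subtracts the smallest uniform `b >= 0` from
#' every union-model R^2 such that all intersection terms become
#' nonnegative (`b = 0` when the raw partition is already valid). If no
#' such `b` exists -- e.g. a unique term is negative, which a uniform union
#' shift cannot repair -- the binding constraint is reported as an error.
#'
#' @param partition A [partition_two()] / [partition_three()] result.
#' @return A corrected `var_partition` with its `bias` field set.
#' @export
bias_correct <- function(partition) {
  stopifnot(inherits(partition, "var_partition"))
  if (partition$n_sets == 2L) {
    b <- max(0, -partition$pairwise[["AB"]])
  } else {
    b <- max(0, -min(partition$pairwise), -partition$triple / 2)
  }
  adj <- new_var_partition(partition$n_sets, partition$totals,
                           partition$unions - b, bias = b)
  bad <- c(adj$uniques, adj$pairwise, adj$triple) < -1e-12
  if (any(bad)) {
    nm <- names(c(adj$uniques, adj$pairwise,
                  if (!is.null(adj$triple)) c(ABC = adj$triple)))[bad]
    abort(paste0("no feasible bias correction; binding constraint: ",
                 paste(nm, collapse = ", "), " remains negative"))
  }
  adj
}
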