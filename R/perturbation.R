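# Demethylase-overexpression analysis: sample cells, sort by tagged-enzyme
# expression, correlate expression with each modification, call substrates
# and products.

#' Randomly sample cells from a normalized table
#'
#' Uniform sampling without replacement; with `n` equal to the table size
#' the table is returned unchanged (order preserved).
#'
#' @param table Normalized table.
#' @param n Number of cells to sample (default 400).
#' @param seed Optional RNG seed.
#' @return Sub-table with exactly `n` rows.
#' @export
sample_cells <- function(table, n = 400, seed = NULL) {
  stopifnot(is.data.frame(table))
  if (nrow(table) < n)
    stop(sprintf("need >= %d retained cells, have %d", n, nrow(table)),
         call. = FALSE)
  if (nrow(table) == n) return(table)
  with_seed(seed, table[sample.int(nrow(table), n), , drop = FALSE])
}

#' Top expressing cells
#'
#' Rows sorted by descending expression level; the first `n_top` are
#' returned. Ties are broken by `cell_id`, so the result is invariant to
#' the input row order.
#'
#' @param table Normalized table containing the expression channel.
#' @param n_top Number of top cells (default 50).
#' @param channel Expression channel column (default `"HaloTag"`).
#' @return Ordered sub-table with `n_top` rows.
#' @export
top_expressers <- function(table, n_top = 50, channel = "HaloTag") {
  if (!channel %in% names(table))
    stop("missing expression channel: ", channel, call. = FALSE)
  if (n_top > nrow(table))
    stop("n_top exceeds table size", call. = FALSE)
  ord <- order(-table[[channel]], table$cell_id)
  table[ord[seq_len(n_top)], , drop = FALSE]
}

#' Expression-modification correlations across replicates
#'
#' Per replicate, the Pearson correlation between
#' `log2(expression_norm + eps)` and `log2(mark_norm + eps)` over the
#' sampled cells (perturbation data are analysed on the log scale), plus
#' the mean across replicates.
#'
#' @param replicates A sampled normalized table or list of them.
#' @param marks Character vector of mark columns to correlate.
#' @param channel Expression channel column.
#' @param eps Offset guarding `log2` at zero expression.
#' @return Object of class `perturbation_result`: list with `marks`, `r`
#'   (replicates x marks matrix), `mean_r` (named), `n` per replicate, and
#'   `calls` (`NULL` until [call_targets()] is applied).
#' @export
expression_correlations <- function(replicates, marks, channel = "HaloTag",
                                    eps = 1e-6) {
  if (is.data.frame(replicates)) replicates <- list(replicates)
  if (!length(replicates)) stop("need at least one replicate", call. = FALSE)
  r <- vapply(replicates, function(tab) {
    if (!channel %in% names(tab))
      stop("missing expression channel: ", channel, call. = FALSE)
    miss <- setdiff(marks, names(tab))
    if (length(miss))
      stop("missing marks: ", paste(miss, collapse = ", "), call. = FALSE)
    lx <- log2(tab[[channel]] + eps)
    vapply(marks, function(mk) pearson_r(lx, log2(tab[[mk]] + eps)),
           numeric(1))
  }, numeric(length(marks)))
  r <- matrix(r, nrow = length(replicates), byrow = TRUE,
              dimnames = list(NULL, marks))
  structure(list(marks = marks, r = r, mean_r = colMeans(r),
                 n = vapply(replicates, nrow, integer(1)), calls = NULL),
            class = "perturbation_result")
}

#' Call substrate and product modifications
#'
#' A mark is called a `substrate` of the overexpressed enzyme when its mean
#' expression correlation is at or below `substrate_r`, a `product` when at
#' or above `product_r`, and `none` otherwise.
#'
#' @param result A `perturbation_result` from [expression_correlations()].
#' @param substrate_r Substrate-call threshold (default -0.2).
#' @param product_r Product-call threshold (default +0.2).
#' @return The result with a `calls` element (named character vector).
#' @export
call_targets <- function(result, substrate_r = -0.2, product_r = 0.2) {
  stopifnot(inherits(result, "perturbation_result"))
  if (substrate_r >= product_r)
    stop("substrate_r must be below product_r", call. = FALSE)
  calls <- ifelse(result$mean_r <= substrate_r, "substrate",
                  ifelse(result$mean_r >= product_r, "product", "none"))
  result$calls <- stats::setNames(calls, result$marks)
  result
}

#' @export
print.perturbation_result <- function(x, ...) {
  cat(sprintf("<perturbation_result: %d replicate(s), n = %s>\n",
              nrow(x$r), paste(x$n, collapse = ", ")))
  for (mk in x$marks)
    cat(sprintf("  %-10s mean r = %+.3f%s\n", mk, x$mean_r[[mk]],
                if (!is.null(x$calls)) paste0("  [", x$calls[[mk]], "]")
                else ""))
  invisible(x)
}

#' Run the demethylase-target analysis end-to-end
#'
#' For each replicate population: normalize, sample `n` cells, correlate
#' log2 expression with each mark, then call targets.
#'
#' @param populations List of perturbed populations (from
#'   [apply_perturbation()]) or intensity tables with an expression channel.
#' @param marks Mark columns to test.
#' @param n Cells sampled per replicate (default 400).
#' @param n_top Top-expresser view size (recorded for display; correlations
#'   use all `n` cells).
#' @param seed RNG seed for the sampling.
#' @param channel Expression channel name.
#' @param substrate_r,product_r Call thresholds.
#' @return `perturbation_result` with calls and an attached `top` list of
#'   top-expresser sub-tables.
#' @export
perturbation_analysis <- function(populations, marks, n = 400, n_top = 50,
                                  seed = NULL, channel = "HaloTag",
                                  substrate_r = -0.2, product_r = 0.2) {
  if (is.data.frame(populations)) populations <- list(populations)
  subsets <- lapply(seq_along(populations), function(i) {
    tab <- normalize_table(populations[[i]])
    sample_cells(tab, n, seed = derive_seed(seed, i))
  })
  res <- expression_correlations(subsets, marks, channel = channel)
  res <- call_targets(res, substrate_r, product_r)
  res$top <- lapply(subsets, top_expressers, n_top = n_top, channel = channel)
  res
}
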