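# Normalization, replicate correlation profiling, three-group cell-cycle
# classification, phase gating and heatmap matrices.

#' Order-statistic Hoechst normalization
#'
#' Maps per-nucleus Hoechst totals onto an approximately `[1, 2]` scale
#' using robust order statistics: the `k`-th smallest value is set to 1 and
#' the `k`-th largest to 2 (default `k = 5`, since the single lowest and
#' highest nuclei are sometimes outliers). Values outside the anchors map
#' below 1 or above 2 — no clipping:
#' `n(x) = 1 + (x - x_(k)) / (x_(n+1-k) - x_(k))`.
#'
#' @param x Positive numeric vector of raw Hoechst totals (`n >= 2k`).
#' @param k Order-statistic rank of the anchors.
#' @return Normalized values, same length as `x`.
#' @examples
#' normalize_hoechst(rlnorm(100))
#' @export
normalize_hoechst <- function(x, k = 5) {
  stopifnot(is.numeric(x))
  if (length(x) < 2 * k)
    stop("need at least 2k values for order-statistic anchors", call. = FALSE)
  s <- sort(x)
  lo <- s[k]
  hi <- s[length(x) + 1 - k]
  if (hi <= lo) stop("degenerate spread: anchors coincide", call. = FALSE)
  1 + (x - lo) / (hi - lo)
}

#' Normalize an intensity table
#'
#' Drops excluded nuclei, maps the Hoechst channel through
#' [normalize_hoechst()] (column `hoechst_norm`), and scales every other
#' channel to unit population mean (relative intensity).
#'
#' @param table Intensity table (from [quantify_fields()] or a ground-truth
#'   population from [sample_population()]).
#' @param hoechst Name of the Hoechst column.
#' @param k Order-statistic rank for the Hoechst anchors.
#' @return Normalized table: `cell_id`, `hoechst_norm`, and one unit-mean
#'   column per remaining channel (original names kept).
#' @export
normalize_table <- function(table, hoechst = "Hoechst", k = 5) {
  stopifnot(is.data.frame(table))
  if (!hoechst %in% names(table))
    stop("missing Hoechst column: ", hoechst, call. = FALSE)
  if ("excluded" %in% names(table)) table <- table[!table$excluded, ]
  else if ("is_edge" %in% names(table))
    table <- table[!table$is_edge & !table$is_mitotic, ]
  if (!nrow(table)) stop("no retained nuclei", call. = FALSE)
  id <- if ("cell_id" %in% names(table)) table$cell_id
  else if (all(c("field_id", "nucleus_id") %in% names(table)))
    paste(table$field_id, table$nucleus_id, sep = ":")
  else seq_len(nrow(table))
  out <- data.frame(cell_id = id,
                    hoechst_norm = normalize_hoechst(table[[hoechst]], k),
                    stringsAsFactors = FALSE)
  for (ch in setdiff(channel_names(table), hoechst)) {
    m <- mean(table[[ch]])
    if (!is.finite(m) || m <= 0)
      stop("non-positive mean for channel ", ch, call. = FALSE)
    out[[ch]] <- table[[ch]] / m
  }
  out
}

#' Pearson product-moment correlation with validation
#'
#' @param x,y Numeric vectors of equal length `n >= 3` with nonzero
#'   variance.
#' @return Correlation coefficient in `[-1, 1]`.
#' @export
pearson_r <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y))
  if (length(x) != length(y)) stop("length mismatch", call. = FALSE)
  if (length(x) < 3) stop("need at least 3 observations", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance: correlation undefined", call. = FALSE)
  stats::cor(x, y, method = "pearson")
}

#' Replicate correlation profile of a mark
#'
#' Pearson correlation, per replicate, between a mark's normalized
#' intensities and a reference channel (`hoechst_norm` or the S-phase
#' reference mark), on the linear scale over retained nuclei, plus the
#' unweighted arithmetic mean across replicates.
#'
#' @param replicates A normalized table or list of them (one per biological
#'   replicate).
#' @param mark Mark column name.
#' @param reference `"Hoechst"` (uses `hoechst_norm`) or a channel name
#'   such as `"H4K5ac"`.
#' @return Object of class `correlation_profile`: list with `mark`,
#'   `reference`, `r` (per replicate), `mean_r`, `n` (cells per replicate).
#' @export
correlation_profile <- function(replicates, mark, reference = "Hoechst") {
  if (is.data.frame(replicates)) replicates <- list(replicates)
  if (!length(replicates)) stop("need at least one replicate", call. = FALSE)
  r <- vapply(replicates, function(tab) {
    if (!mark %in% names(tab)) stop("missing mark: ", mark, call. = FALSE)
    ref <- if (identical(reference, "Hoechst")) tab$hoechst_norm
    else tab[[reference]]
    if (is.null(ref)) stop("missing reference: ", reference, call. = FALSE)
    pearson_r(tab[[mark]], ref)
  }, numeric(1))
  structure(list(mark = mark, reference = reference, r = r,
                 mean_r = mean(r),
                 n = vapply(replicates, nrow, integer(1))),
            class = "correlation_profile")
}

#' @export
print.correlation_profile <- function(x, ...) {
  cat(sprintf("<correlation_profile %s vs %s: r = %s; mean = %.3f>\n",
              x$mark, x$reference,
              paste(sprintf("%.3f", x$r), collapse = ", "), x$mean_r))
  invisible(x)
}

#' Three-group cell-cycle classification of a mark
#'
#' Classifies a modification by its mean correlation with the S-phase
#' reference mark: group 1 (replication-coupled) for `r > 0.6`, group 3
#' (delayed restoration / little or anti-correlation) for `r <= 0.2`,
#' group 2 (intermediate) otherwise. The rule is contiguous; the printed
#' group-2 band starts at 0.25, so calls in `(0.2, 0.25]` are labelled with
#' rule `"contiguous(0.2,0.25]"` to flag the documented ambiguity.
#'
#' @param mean_r Mean correlation with the S-phase reference, in `[-1, 1]`.
#' @return Object of class `group_label`: list with `group` (1, 2 or 3),
#'   `rule` and `mean_r`.
#' @export
classify_group <- function(mean_r) {
  assert_scalar(mean_r, "mean_r", -1, 1)
  group <- if (mean_r > 0.6) 1L else if (mean_r <= 0.2) 3L else 2L
  rule <- if (group == 2L && mean_r <= 0.25) "contiguous(0.2,0.25]"
  else c("r > 0.6", "0.2 < r <= 0.6", "r <= 0.2")[group]
  structure(list(group = group, rule = rule, mean_r = mean_r),
            class = "group_label")
}

#' @export
print.group_label <- function(x, ...) {
  cat(sprintf("<group %d (%s), mean r = %.3f>\n", x$group, x$rule, x$mean_r))
  invisible(x)
}

#' Gate cells into cell-cycle phases
#'
#' Hard gates on normalized intensities: S if the S-phase marker exceeds its
#' threshold; otherwise G1 below `g1_max` normalized Hoechst, G2 above
#' `g2_min`, and `"mid"` in between.
#'
#' @param table Normalized table.
#' @param gates A [phase_gates].
#' @param s_marker Column name of the S-phase reference mark.
#' @return Character vector of phase labels, one per row.
#' @export
assign_phase <- function(table, gates = phase_gates(), s_marker = "H4K5ac") {
  stopifnot(inherits(gates, "phase_gates"))
  if (!all(c("hoechst_norm", s_marker) %in% names(table)))
    stop("normalized Hoechst and S-marker columns required", call. = FALSE)
  ifelse(table[[s_marker]] > gates$s_marker_threshold, "S",
         ifelse(table$hoechst_norm < gates$g1_max, "G1",
                ifelse(table$hoechst_norm > gates$g2_min, "G2", "mid")))
}

#' Heatmap matrix of single-cell intensities
#'
#' Rows are cells sorted by a channel (ascending by default, as for
#' Hoechst-sorted cell-cycle heatmaps; descending for expression-sorted
#' views), columns are channels, and values are `log2` of the normalized
#' intensity for display. Ties are broken by `cell_id`.
#'
#' @param table Normalized table.
#' @param sort_channel Channel to sort rows by; `"Hoechst"` uses
#'   `hoechst_norm`.
#' @param direction `"ascending"` or `"descending"`.
#' @return List with `matrix` (log2 values, rownames = cell ids) and
#'   `order` (row indices into `table`).
#' @export
heatmap_matrix <- function(table, sort_channel = "Hoechst",
                           direction = c("ascending", "descending")) {
  direction <- match.arg(direction)
  key <- if (identical(sort_channel, "Hoechst")) table$hoechst_norm
  else table[[sort_channel]]
  if (is.null(key)) stop("unknown channel: ", sort_channel, call. = FALSE)
  ord <- order(key, table$cell_id)
  if (direction == "descending") ord <- order(-key, table$cell_id)
  cols <- setdiff(names(table), "cell_id")
  m <- log2(as.matrix(table[ord, cols, drop = FALSE]))
  rownames(m) <- table$cell_id[ord]
  list(matrix = m, order = ord)
}
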