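# Plate-level screening analysis: per-well summaries, normalization to
# untreated controls, hit calling and serial-dilution response profiles.

#' Per-well summary statistic of nuclear intensities
#'
#' Median (robust default; mean optional) of the per-nucleus
#' background-subtracted totals for each mark, per well. Wells with fewer
#' retained nuclei than `min_cells` are flagged and excluded from hit
#' calling.
#'
#' @param plate Per-nucleus data frame with `well`, `compound`, `dose_nM`
#'   metadata (from [simulate_plate()] or quantified well tables bound with
#'   layout columns).
#' @param marks Mark columns to summarize; defaults to all channels.
#' @param stat `"median"` or `"mean"`.
#' @param min_cells Minimum retained nuclei per well.
#' @return Data frame with one row per well: `well`, `compound`, `dose_nM`,
#'   `n`, `flagged`, and one summary column per mark.
#' @export
well_summary <- function(plate, marks = NULL, stat = c("median", "mean"),
                         min_cells = 20) {
  stat <- match.arg(stat)
  stopifnot(is.data.frame(plate), all(c("well", "dose_nM") %in% names(plate)))
  if ("excluded" %in% names(plate)) plate <- plate[!plate$excluded, ]
  if (is.null(marks)) marks <- channel_names(plate)
  fun <- if (stat == "median") stats::median else mean
  wells <- unique(plate$well)
  rows <- lapply(wells, function(w) {
    sub <- plate[plate$well == w, , drop = FALSE]
    out <- data.frame(well = w, compound = sub$compound[1],
                      dose_nM = sub$dose_nM[1], n = nrow(sub),
                      flagged = nrow(sub) < min_cells,
                      stringsAsFactors = FALSE)
    for (mk in marks) out[[mk]] <- fun(sub[[mk]])
    out
  })
  do.call(rbind, rows)
}

#' Normalize well summaries to untreated controls
#'
#' Fold change per mark = well statistic divided by the mean of the
#' statistic over valid (unflagged) untreated control wells
#' (`dose_nM == 0`).
#'
#' @param summaries Data frame from [well_summary()].
#' @param marks Mark columns; defaults to all summary channels.
#' @return `summaries` with per-mark columns replaced by fold changes
#'   (column names suffixed `_fold`).
#' @export
normalize_to_control <- function(summaries, marks = NULL) {
  stopifnot(is.data.frame(summaries), "dose_nM" %in% names(summaries))
  if (is.null(marks))
    marks <- setdiff(names(summaries),
                     c("well", "compound", "dose_nM", "n", "flagged"))
  ctrl <- summaries$dose_nM == 0 & !summaries$flagged
  if (!any(ctrl)) stop("no valid untreated control wells", call. = FALSE)
  out <- summaries
  for (mk in marks) {
    ref <- mean(summaries[[mk]][ctrl])
    if (!is.finite(ref) || ref <= 0)
      stop("non-positive control mean for ", mk, call. = FALSE)
    out[[paste0(mk, "_fold")]] <- summaries[[mk]] / ref
    out[[mk]] <- NULL
  }
  out
}

#' Call screening hits
#'
#' A well is a hit when any target (acetylation) mark shows a fold change at
#' or above `threshold`; flagged wells never hit. Records which marks
#' triggered.
#'
#' @param folds Data frame from [normalize_to_control()].
#' @param threshold Fold-change hit threshold (default 2.0).
#' @param marks Fold columns to consider (without the `_fold` suffix);
#'   defaults to all.
#' @return `folds` with logical `hit` and character `hit_marks` columns.
#' @export
call_hits <- function(folds, threshold = 2.0, marks = NULL) {
  fold_cols <- grep("_fold$", names(folds), value = TRUE)
  if (!is.null(marks)) fold_cols <- paste0(marks, "_fold")
  if (!length(fold_cols) || !all(fold_cols %in% names(folds)))
    stop("fold-change columns missing", call. = FALSE)
  fm <- as.matrix(folds[, fold_cols, drop = FALSE])
  over <- fm >= threshold
  over[folds$flagged, ] <- FALSE
  folds$hit <- rowSums(over) > 0
  folds$hit_marks <- apply(over, 1, function(z)
    paste(sub("_fold$", "", fold_cols[z]), collapse = ","))
  folds
}

#' Serial-dilution response profile per compound
#'
#' Orders fold changes by dose for each compound, reports the minimal
#' effective dose (smallest dose whose fold change reaches `threshold`;
#' `NA` for inert compounds) and counts monotonicity violations (reported,
#' not corrected).
#'
#' @param folds Data frame from [normalize_to_control()] (well ordering is
#'   irrelevant).
#' @param mark Mark to profile (without the `_fold` suffix).
#' @param threshold Effective-dose fold threshold.
#' @return Data frame with one row per compound: `compound`,
#'   `med` (minimal effective dose, nM), `n_violations`, plus one
#'   `fold_<dose>` column per dose.
#' @export
dilution_profile <- function(folds, mark, threshold = 2.0) {
  col <- paste0(mark, "_fold")
  if (!col %in% names(folds)) stop("no fold column for ", mark, call. = FALSE)
  if (!any(folds$dose_nM == 0)) stop("dose-0 wells required", call. = FALSE)
  compounds <- setdiff(unique(folds$compound[folds$dose_nM > 0]), "control")
  doses <- sort(unique(folds$dose_nM))
  if (length(doses) < 3) stop("need >= 3 doses including 0", call. = FALSE)
  rows <- lapply(compounds, function(cp) {
    sel <- folds$compound == cp | folds$dose_nM == 0
    sub <- folds[sel, , drop = FALSE]
    f <- vapply(doses, function(d) mean(sub[[col]][sub$dose_nM == d]),
                numeric(1))
    eff <- doses[!is.na(f) & f >= threshold & doses > 0]
    out <- data.frame(compound = cp,
                      med = if (length(eff)) min(eff) else NA_real_,
                      n_violations = sum(diff(f) < 0, na.rm = TRUE))
    for (i in seq_along(doses)) out[[paste0("fold_", doses[i])]] <- f[i]
    out
  })
  do.call(rbind, rows)
}

#' Run the plate screen end-to-end
#'
#' Summarize wells, normalize to controls, call hits and build dilution
#' profiles for every target mark.
#'
#' @param plate Per-nucleus plate data frame.
#' @param marks Target marks; defaults to channels ending in `"ac"`.
#' @param threshold Hit / effective-dose fold threshold.
#' @param stat Per-well statistic.
#' @param min_cells Minimum nuclei per well.
#' @return List with `wells` (folds + hit flags) and `profiles` (named list
#'   of dilution profiles per mark).
#' @export
screen_plate <- function(plate, marks = NULL, threshold = 2.0,
                         stat = "median", min_cells = 20) {
  if (is.null(marks))
    marks <- grep("ac$", channel_names(plate), value = TRUE)
  summaries <- well_summary(plate, marks = marks, stat = stat,
                            min_cells = min_cells)
  folds <- normalize_to_control(summaries, marks = marks)
  wells <- call_hits(folds, threshold = threshold, marks = marks)
  # dilution profiles need a dose series; single-dose screens skip them
  profiles <- if (length(unique(folds$dose_nM)) >= 3)
    lapply(stats::setNames(marks, marks), function(mk)
      dilution_profile(folds, mk, threshold = threshold))
  list(wells = wells, profiles = profiles)
}
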