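# Nuclear segmentation and per-nucleus multichannel quantification.
# Hoechst drives segmentation; the exclusion rules (border-clipped nuclei,
# small mitotic figures, abnormal shapes) mirror routine practice for
# single-focal-plane interphase quantification.

get_channel <- function(field, name) {
  stopifnot(inherits(field, "field_image"))
  ch <- field$channels[[name]]
  if (is.null(ch)) stop("channel not present: ", name, call. = FALSE)
  ch
}

# Otsu threshold on a lightly smoothed Hoechst channel; returns the binary
# foreground matrix. The threshold is computed on the intensity range of the
# smoothed image.
hoechst_foreground <- function(field, smoothing_sigma = 1.0,
                               hoechst = "Hoechst") {
  img <- get_channel(field, hoechst)
  sm <- if (smoothing_sigma > 0)
    as.matrix(EBImage::gblur(EBImage::Image(img), sigma = smoothing_sigma,
                             boundary = "replicate"))
  else img
  if (diff(range(sm)) <= 0)
    stop("flat Hoechst channel: nothing to segment", call. = FALSE)
  # Otsu on the log scale: nuclear densities span several-fold (DNA content
  # doubles across the cycle) while background is tight, so a linear-scale
  # Otsu can split dim from bright nuclei instead of background from
  # foreground. Log compression restores the background/foreground
  # bimodality; the threshold maps back through exp.
  lg <- log1p(sm)
  th <- expm1(EBImage::otsu(EBImage::Image(lg), range = range(lg),
                            levels = 1024))
  list(mask = sm > th, smoothed = sm, threshold = th)
}

#' Estimate per-channel scalar background
#'
#' Background is taken as the median pixel value over the non-cell region:
#' the complement of the Hoechst foreground mask dilated by 3 px.
#'
#' @param field A `field_image`.
#' @param smoothing_sigma Pre-smoothing sd for the foreground mask.
#' @param hoechst Name of the Hoechst channel.
#' @return Named numeric vector, one background value (ADU) per channel.
#' @export
estimate_background <- function(field, smoothing_sigma = 1.0,
                                hoechst = "Hoechst") {
  fg <- hoechst_foreground(field, smoothing_sigma, hoechst)$mask
  brush <- EBImage::makeBrush(7, shape = "disc")    # radius-3 dilation
  dil <- as.matrix(EBImage::dilate(EBImage::Image(fg * 1), brush)) > 0.5
  if (mean(dil) > 0.9)
    stop("foreground covers >90% of the field: no background region",
         call. = FALSE)
  bg_px <- !dil
  vapply(field$channels, function(ch) stats::median(ch[bg_px]), numeric(1))
}

#' Segment nuclei from the Hoechst channel
#'
#' Otsu threshold on the smoothed Hoechst channel, hole filling, removal of
#' sub-`min_area` debris, and optional doublet splitting by watershed on the
#' distance transform: regional maxima of the smoothed distance map are used
#' as seeds after greedy suppression of maxima closer than
#' `seed_separation_frac` x the median object radius, and labels are grown
#' with [EBImage::propagate()].
#'
#' @param field A `field_image`.
#' @param cfg A [seg_config].
#' @param hoechst Name of the Hoechst channel.
#' @return Integer label matrix (background 0, labels 1..K).
#' @export
segment_nuclei <- function(field, cfg = seg_config(), hoechst = "Hoechst") {
  stopifnot(inherits(cfg, "seg_config"))
  fg <- hoechst_foreground(field, cfg$smoothing_sigma, hoechst)
  bin <- EBImage::fillHull(EBImage::Image(fg$mask * 1))
  lab <- EBImage::bwlabel(bin)
  areas <- tabulate(as.integer(lab))
  if (!length(areas) || all(areas == 0))
    stop("empty foreground: no nuclei found", call. = FALSE)
  med_area <- stats::median(areas[areas > 0])
  keep <- which(areas >= cfg$min_area_frac * med_area)
  labm <- matrix(as.integer(lab), nrow(lab), ncol(lab))
  labm[!(labm %in% keep)] <- 0L
  binm <- labm > 0L

  if (!cfg$split_doublets) return(relabel(labm))

  med_radius <- sqrt(med_area / pi)
  dm <- EBImage::distmap(EBImage::Image(binm * 1))
  dms <- as.matrix(EBImage::gblur(dm, sigma = 1, boundary = "replicate"))
  dms[!binm] <- 0
  # regional maxima: pixels equal to the local max within a radius-3 disc
  brush <- EBImage::makeBrush(7, shape = "disc")
  dil <- as.matrix(EBImage::dilate(EBImage::Image(dms), brush))
  is_max <- binm & (dms >= dil - 1e-9) & (dms > 0.25 * med_radius)
  if (!any(is_max)) return(relabel(labm))
  peaks <- peak_centroids(is_max, dms)
  comp <- labm[cbind(peaks$row, peaks$col)]
  seeds <- suppress_close_peaks(peaks, comp,
                                cfg$seed_separation_frac * med_radius)
  seed_img <- matrix(0L, nrow(labm), ncol(labm))
  seed_img[cbind(seeds$row, seeds$col)] <- seq_len(nrow(seeds))
  out <- EBImage::propagate(EBImage::Image(dms), EBImage::Image(seed_img),
                            mask = EBImage::Image(binm * 1))
  relabel(matrix(as.integer(out), nrow(labm), ncol(labm)))
}

# Connected plateaus of maxima -> one representative pixel each (the
# highest, ties by position).
peak_centroids <- function(is_max, height) {
  plab <- EBImage::bwlabel(EBImage::Image(is_max * 1))
  pl <- as.integer(plab)
  idx <- which(pl > 0)
  grp <- pl[idx]
  h <- height[idx]
  ord <- order(grp, -h, idx)
  idx <- idx[ord]; grp <- grp[ord]
  first <- idx[!duplicated(grp)]
  nr <- nrow(is_max)
  data.frame(row = (first - 1L) %% nr + 1L, col = (first - 1L) %/% nr + 1L,
             height = height[first])
}

# Greedy peak suppression: keep peaks in decreasing height order, dropping
# any peak within min_sep of an already-kept peak in the same component.
suppress_close_peaks <- function(peaks, comp, min_sep) {
  ord <- order(-peaks$height)
  keep <- integer(0)
  for (i in ord) {
    if (length(keep)) {
      same <- comp[keep] == comp[i]
      d2 <- (peaks$row[keep] - peaks$row[i])^2 +
        (peaks$col[keep] - peaks$col[i])^2
      if (any(same & d2 < min_sep^2)) next
    }
    keep <- c(keep, i)
  }
  peaks[sort(keep), , drop = FALSE]
}

# Expand labels outward by `ring` px, partitioning contested pixels by
# nearest label (constant-intensity propagate = spatial Voronoi growth).
expand_labels <- function(mask, ring) {
  brush <- EBImage::makeBrush(2 * ring + 1, shape = "disc")
  dil <- as.matrix(EBImage::dilate(EBImage::Image((mask > 0L) * 1),
                                   brush)) > 0.5
  flat <- EBImage::Image(matrix(0, nrow(mask), ncol(mask)))
  out <- EBImage::propagate(flat, EBImage::Image(mask),
                            mask = EBImage::Image(dil * 1))
  matrix(as.integer(out), nrow(mask), ncol(mask))
}

relabel <- function(labm) {
  ids <- sort(unique(labm[labm > 0L]))
  if (!length(ids)) stop("empty foreground: no nuclei found", call. = FALSE)
  lut <- integer(max(ids)); lut[ids] <- seq_along(ids)
  labm[labm > 0L] <- lut[labm[labm > 0L]]
  labm
}

#' Flag labels for exclusion
#'
#' `edge`: label touches any image border. `mitotic`: area below
#' `mitotic_area_factor` x the median area of non-edge labels.
#' `abnormal_shape`: solidity (area over convex-hull area) below
#' `solidity_min`. `excluded` is the union.
#'
#' @param mask Integer label matrix from [segment_nuclei()].
#' @param cfg A [seg_config].
#' @return Data frame with `label`, `area`, `edge`, `mitotic`,
#'   `abnormal_shape`, `excluded`, `solidity`.
#' @export
filter_labels <- function(mask, cfg = seg_config()) {
  labs <- sort(unique(mask[mask > 0L]))
  if (!length(labs))
    return(data.frame(label = integer(0), area = integer(0),
                      edge = logical(0), mitotic = logical(0),
                      abnormal_shape = logical(0), excluded = logical(0),
                      solidity = numeric(0)))
  areas <- tabulate(mask, nbins = max(labs))[labs]
  border <- unique(c(mask[1, ], mask[nrow(mask), ],
                     mask[, 1], mask[, ncol(mask)]))
  edge <- labs %in% border[border > 0L]
  med_area <- stats::median(areas[!edge])
  if (is.na(med_area)) med_area <- stats::median(areas)
  mitotic <- areas < cfg$mitotic_area_factor * med_area
  solidity <- vapply(labs, function(l) label_solidity(mask, l), numeric(1))
  abnormal <- solidity < cfg$solidity_min
  data.frame(label = labs, area = areas, edge = edge, mitotic = mitotic,
             abnormal_shape = abnormal,
             excluded = edge | mitotic | abnormal, solidity = solidity)
}

# Solidity = pixel area / convex-hull area of the pixel footprint. The hull
# of pixel centers is corrected by half the hull perimeter plus 1 (Pick-style
# boundary term) so a digital disk scores ~1; values are clamped to [0, 1].
label_solidity <- function(mask, label) {
  idx <- which(mask == label)
  if (length(idx) < 4) return(1)
  nr <- nrow(mask)
  pts <- cbind((idx - 1L) %% nr + 1L, (idx - 1L) %/% nr + 1L)
  h <- grDevices::chull(pts)
  hp <- pts[h, , drop = FALSE]
  nh <- nrow(hp)
  if (nh < 3) return(1)
  x <- hp[, 1]; y <- hp[, 2]
  area_hull <- abs(sum(x * y[c(2:nh, 1)] - x[c(2:nh, 1)] * y)) / 2
  per_hull <- sum(sqrt(diff(c(x, x[1]))^2 + diff(c(y, y[1]))^2))
  min(1, length(idx) / (area_hull + per_hull / 2 + 1))
}

#' Measure per-nucleus background-subtracted totals
#'
#' For each label and channel, total = sum over label pixels of
#' `max(pixel - background, 0)`; negative post-subtraction pixels are
#' clipped to zero. The summation aperture extends `ring` px beyond the
#' label boundary (Voronoi-partitioned between neighbouring labels, so
#' labels never share pixels): the point-spread function pushes a small
#' fraction of each nucleus's flux just outside the threshold boundary, and
#' the ring recaptures it. Area and centroid are measured on the unexpanded
#' label; exclusion flags are attached.
#'
#' @param mask Integer label matrix.
#' @param field A `field_image` of the same shape.
#' @param background Named per-channel scalar background (ADU), as from
#'   [estimate_background()]; a single number is recycled.
#' @param flags Optional data frame from [filter_labels()]; computed with
#'   default settings when missing.
#' @param cfg [seg_config] used when `flags` is missing.
#' @param ring Aperture expansion in px (0 sums strictly over label
#'   pixels).
#' @return An intensity table: data frame keyed by
#'   (`field_id`, `nucleus_id`) with `area`, `cx`, `cy`, one total column
#'   per channel, and flags `edge`, `mitotic`, `abnormal_shape`, `excluded`.
#' @export
measure_nuclei <- function(mask, field, background = 0, flags = NULL,
                           cfg = seg_config(), ring = 2) {
  stopifnot(inherits(field, "field_image"))
  if (!identical(dim(mask), dim(field$channels[[1]])))
    stop("mask and field shapes differ", call. = FALSE)
  if (is.null(flags)) flags <- filter_labels(mask, cfg)
  aperture <- if (ring > 0) expand_labels(mask, ring) else mask
  labs <- flags$label
  idx <- which(mask > 0L)
  lab_px <- mask[idx]
  nr <- nrow(mask)
  rows <- (idx - 1L) %% nr + 1L
  cols <- (idx - 1L) %/% nr + 1L
  grp_sum <- function(v) {
    s <- rowsum(as.numeric(v), lab_px)
    s[match(labs, as.integer(rownames(s))), 1]
  }
  area <- grp_sum(rep(1L, length(idx)))
  out <- data.frame(field_id = field$field_id, nucleus_id = labs,
                    area = as.integer(area),
                    cx = grp_sum(cols) / area, cy = grp_sum(rows) / area)
  ap_idx <- which(aperture > 0L)
  ap_px <- aperture[ap_idx]
  ap_sum <- function(v) {
    s <- rowsum(as.numeric(v), ap_px)
    s[match(labs, as.integer(rownames(s))), 1]
  }
  chn <- names(field$channels)
  bg <- if (length(background) == 1L && is.null(names(background)))
    stats::setNames(rep(background, length(chn)), chn) else background
  for (ch in chn)
    out[[ch]] <- ap_sum(pmax(field$channels[[ch]][ap_idx] - bg[[ch]], 0))
  out$edge <- flags$edge
  out$mitotic <- flags$mitotic
  out$abnormal_shape <- flags$abnormal_shape
  out$excluded <- flags$excluded
  out
}

#' Quantify a set of fields end-to-end
#'
#' Per field: background estimation, segmentation, exclusion flagging and
#' measurement; results are concatenated into one intensity table.
#'
#' @param fields List of `field_image` objects (e.g. from
#'   [simulate_scene()] or [read_fields()]).
#' @param cfg A [seg_config].
#' @param hoechst Name of the Hoechst channel.
#' @return Combined intensity table (see [measure_nuclei()]).
#' @export
quantify_fields <- function(fields, cfg = seg_config(), hoechst = "Hoechst") {
  if (inherits(fields, "field_image")) fields <- list(fields)
  tabs <- lapply(fields, function(field) {
    bg <- estimate_background(field, cfg$smoothing_sigma, hoechst)
    mask <- segment_nuclei(field, cfg, hoechst)
    flags <- filter_labels(mask, cfg)
    measure_nuclei(mask, field, bg, flags, cfg)
  })
  do.call(rbind, tabs)
}
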