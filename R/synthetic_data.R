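# Synthetic population, field-rendering, perturbation and plate simulators.
# These embody the statistical structure the downstream analysis assumes
# (DNA doubling across the cycle, S-phase-peaked acetylation, delayed
# restoration of repressive marks, transfected subpopulations, Hill-type
# dose response) so that every stage is testable without external data.

# Evaluate a mark model's noise-free signal for cells at clock t.
# t in [0,1) partitions into G1 [0,f_g1), S [f_g1, f_g1+f_s), G2 [rest,1).
mark_signal <- function(mark, phase, u, c, g1_prog, g2_prog) {
  in_s <- phase == "S"
  switch(mark$kind,
    proportional = c,
    constant = rep(1, length(c)),
    replication_coupled = 0.3 + mark$bump * sin(pi * u) * in_s,
    replication_synchronous = c * (1 + mark$bump * sin(pi * u) * in_s),
    delayed_restoration = {
      m <- numeric(length(c))
      g1 <- phase == "G1"; g2 <- phase == "G2"
      m[g1] <- 0.85 + 0.15 * g1_prog[g1]
      first_half <- in_s & u < 0.5
      second_half <- in_s & u >= 0.5
      m[first_half] <- 1
      m[second_half] <- 1 - 0.4 * (u[second_half] - 0.5)
      m[g2] <- 0.8 + 0.15 * g2_prog[g2]
      m
    },
    stop("unknown mark kind: ", mark$kind, call. = FALSE))
}

#' Sample a synthetic interphase cell population
#'
#' Draws `n` interphase cells with a uniform cell-cycle clock `t` partitioned
#' into G1/S/G2 by the configured fractions, assigns DNA content
#' (1 in G1, `1+u` in S, 2 in G2), and generates noisy true channel totals:
#' Hoechst as `a_hoechst * c * LN(sigma_hoechst)` and each mark according to
#' its [mark_model] kind.
#'
#' @param cycle A [cell_cycle_config].
#' @param marks List of [mark_model] objects (names become channel columns).
#' @param n Number of cells (>= 1).
#' @param seed Optional RNG seed.
#' @return Data frame (one row per cell) with columns `cell_id`, `phase`,
#'   `t`, `dna_content`, `is_edge`, `is_mitotic`, `Hoechst` and one column
#'   per mark holding true totals (ADU).
#' @examples
#' cells <- sample_population(cell_cycle_config(), cellcycle_marks(), 100, seed = 1)
#' @export
sample_population <- function(cycle, marks, n, seed = NULL) {
  stopifnot(inherits(cycle, "cell_cycle_config"))
  if (!is.numeric(n) || n < 1) stop("n must be >= 1", call. = FALSE)
  n <- as.integer(n)
  marks <- as_mark_list(marks)
  with_seed(seed, {
    t <- stats::runif(n)
    phase <- ifelse(t < cycle$f_g1, "G1",
                    ifelse(t < cycle$f_g1 + cycle$f_s, "S", "G2"))
    u <- rep(NA_real_, n)
    in_s <- phase == "S"
    u[in_s] <- (t[in_s] - cycle$f_g1) / cycle$f_s
    g1_prog <- ifelse(phase == "G1", t / cycle$f_g1, NA_real_)
    g2_prog <- ifelse(phase == "G2",
                      (t - cycle$f_g1 - cycle$f_s) / cycle$f_g2, NA_real_)
    c_dna <- ifelse(phase == "G1", 1, ifelse(phase == "S", 1 + u, 2))
    u0 <- ifelse(is.na(u), 0, u)

    out <- data.frame(cell_id = seq_len(n), phase = phase, t = t,
                      dna_content = c_dna, is_edge = FALSE,
                      is_mitotic = FALSE, stringsAsFactors = FALSE)
    out$Hoechst <- cycle$a_hoechst * c_dna * rlnorm_unit(n, cycle$sigma_hoechst)
    for (mk in marks) {
      sig <- mark_signal(mk, phase, u0, c_dna, g1_prog, g2_prog)
      tot <- mk$amplitude * sig * rlnorm_unit(n, mk$sigma)
      if (mk$kind == "delayed_restoration") {
        g1 <- phase == "G1"
        tot[g1] <- tot[g1] * rlnorm_unit(sum(g1), mk$sigma_g1)
      }
      out[[mk$name]] <- tot
    }
    out
  })
}

as_mark_list <- function(marks) {
  if (inherits(marks, "mark_model")) marks <- list(marks)
  if (!length(marks) || !all(vapply(marks, inherits, TRUE, "mark_model")))
    stop("marks must be mark_model objects", call. = FALSE)
  names(marks) <- vapply(marks, `[[`, "", "name")
  if (anyDuplicated(names(marks))) stop("duplicate mark names", call. = FALSE)
  marks
}

# Mitotic figures: condensed chromosomes at the G2 DNA content whose rendered
# single-plane totals sit at `mitotic_intensity_factor` (~0.87) of an
# interphase G2 cell's.
sample_mitotic <- function(cycle, marks, n, factor) {
  if (n == 0) {
    out <- sample_population(cycle, marks, 1)[0, ]
    return(out)
  }
  phase <- rep("M", n)
  c_dna <- rep(2, n)
  out <- data.frame(cell_id = seq_len(n), phase = phase, t = NA_real_,
                    dna_content = c_dna, is_edge = FALSE, is_mitotic = TRUE,
                    stringsAsFactors = FALSE)
  out$Hoechst <- factor * cycle$a_hoechst * c_dna *
    rlnorm_unit(n, cycle$sigma_hoechst)
  for (mk in marks) {
    sig <- mark_signal(mk, phase = rep("G2", n), u = rep(0, n), c = c_dna,
                       g1_prog = rep(NA_real_, n), g2_prog = rep(1, n))
    out[[mk$name]] <- factor * mk$amplitude * sig * rlnorm_unit(n, mk$sigma)
  }
  out
}

#' Simulate a full imaging scene: population plus rendered fields
#'
#' Samples `n_interior + n_edge` interphase cells and `n_mitotic` mitotic
#' figures, flags the edge/mitotic subpopulations, and renders them into
#' multichannel fields with ground-truth label masks.
#'
#' @param cycle A [cell_cycle_config].
#' @param marks List of [mark_model]s.
#' @param scene A [scene_config].
#' @param seed RNG seed (drives sampling and rendering).
#' @return A list of class `scene` with elements `cells` (ground truth,
#'   including field/position assignment), `fields` (list of `field_image`)
#'   and `masks` (list of integer label matrices aligned with `fields`).
#' @export
simulate_scene <- function(cycle = cell_cycle_config(),
                           marks = cellcycle_marks(),
                           scene = scene_config(), seed = NULL) {
  stopifnot(inherits(scene, "scene_config"))
  marks <- as_mark_list(marks)
  with_seed(seed, {
    n_int <- scene$n_interior + 2L * scene$doublets
    cells <- sample_population(cycle, marks, n_int + scene$n_edge)
    if (scene$n_edge > 0)
      cells$is_edge[sample.int(nrow(cells), scene$n_edge)] <- TRUE
    mito <- sample_mitotic(cycle, marks, scene$n_mitotic,
                           scene$mitotic_intensity_factor)
    if (nrow(mito)) mito$cell_id <- nrow(cells) + seq_len(nrow(mito))
    cells <- rbind(cells, mito)
    rendered <- render_fields(cells, scene)
    structure(list(cells = rendered$cells, fields = rendered$fields,
                   masks = rendered$masks, scene = scene, seed = seed),
              class = "scene")
  })
}

#' Render cells into multichannel image fields
#'
#' Nuclei are drawn as filled ellipses with uniform per-pixel density
#' `true_total / area` (so the pixel sum equals the true total exactly
#' before optics), blurred by a Gaussian PSF, offset by a constant
#' background and corrupted with Gaussian read noise. Edge cells are placed
#' so that at least 20% of their area falls outside the field; mitotic
#' figures are small (radius `mitotic_radius_factor` x mean) and dense.
#' Interior nuclei never overlap (minimum center distance 2.2x radius).
#'
#' @param cells Ground-truth data frame from [sample_population()] (with
#'   `is_edge`/`is_mitotic` flags set as desired).
#' @param scene A [scene_config].
#' @param seed Optional RNG seed (placement, noise).
#' @return List with `cells` (input plus `field`, `x`, `y`, `radius_a`,
#'   `radius_b`, `theta`), `fields` (list of `field_image`) and `masks`.
#' @export
render_fields <- function(cells, scene = scene_config(), seed = NULL) {
  stopifnot(is.data.frame(cells), inherits(scene, "scene_config"))
  channels <- channel_names(cells)
  with_seed(seed, {
    n <- nrow(cells)
    n_fields <- max(1L, ceiling(n / scene$nuclei_per_field))
    ord <- sample.int(n)                      # shuffle before round-robin
    field_of <- integer(n)
    field_of[ord] <- rep_len(seq_len(n_fields), n)

    r_mean <- scene$nucleus_radius_mean
    radius <- pmax(2, stats::rnorm(n, r_mean, scene$nucleus_radius_sd))
    radius[cells$is_mitotic] <- scene$mitotic_radius_factor * r_mean
    aspect <- stats::runif(n, 0.9, 1.1)
    theta <- stats::runif(n, 0, pi)
    a <- radius * sqrt(aspect)
    b <- radius / sqrt(aspect)

    fs <- scene$field_size
    cells$field <- field_of
    cells$x <- NA_real_; cells$y <- NA_real_
    cells$radius_a <- a; cells$radius_b <- b; cells$theta <- theta

    for (f in seq_len(n_fields)) {
      idx <- which(field_of == f)
      placed_x <- numeric(0); placed_y <- numeric(0); placed_r <- numeric(0)
      # place edge cells first (border positions), then interior
      idx <- idx[order(!cells$is_edge[idx])]
      for (i in idx) {
        r <- radius[i]
        ok <- FALSE
        for (try in seq_len(400)) {
          if (cells$is_edge[i]) {
            side <- sample.int(4, 1)
            d <- stats::runif(1, 0, 0.4) * r   # => >= ~25% of area clipped
            along <- stats::runif(1, r + 2, fs - r - 2)
            pos <- switch(side,
                          c(d, along), c(fs + 1 - d, along),
                          c(along, d), c(along, fs + 1 - d))
            x <- pos[1]; y <- pos[2]
          } else {
            margin <- r + 5
            x <- stats::runif(1, margin, fs - margin)
            y <- stats::runif(1, margin, fs - margin)
          }
          if (length(placed_x)) {
            dmin <- pmax(2.2 * (placed_r + r) / 2, placed_r + r + 6)
            if (any((placed_x - x)^2 + (placed_y - y)^2 < dmin^2)) next
          }
          ok <- TRUE; break
        }
        if (!ok) stop("field overcrowded: placement failed after retries",
                      call. = FALSE)
        placed_x <- c(placed_x, x); placed_y <- c(placed_y, y)
        placed_r <- c(placed_r, r)
        cells$x[i] <- x; cells$y[i] <- y
      }
    }

    fields <- vector("list", n_fields)
    masks <- vector("list", n_fields)
    for (f in seq_len(n_fields)) {
      idx <- which(field_of == f)
      imgs <- lapply(channels, function(ch) matrix(0, fs, fs))
      names(imgs) <- channels
      mask <- matrix(0L, fs, fs)
      for (i in idx) {
        px <- ellipse_pixels(cells$x[i], cells$y[i], a[i], b[i], theta[i], fs)
        if (!length(px$inside)) next
        dens_area <- px$full_area          # density uses full (unclipped) area
        for (ch in channels)
          imgs[[ch]][px$inside] <- imgs[[ch]][px$inside] +
            cells[[ch]][i] / dens_area
        mask[px$inside] <- cells$cell_id[i]
      }
      for (ch in channels) {
        img <- imgs[[ch]]
        if (scene$psf_sigma > 0)
          img <- as.matrix(EBImage::gblur(EBImage::Image(img),
                                          sigma = scene$psf_sigma,
                                          boundary = "replicate"))
        img <- img + scene$background_level
        if (scene$read_noise > 0)
          img <- img + stats::rnorm(length(img), 0, scene$read_noise)
        imgs[[ch]] <- pmax(img, 0)
      }
      fields[[f]] <- field_image(imgs, pixel_size = scene$pixel_size_um,
                                 field_id = f)
      masks[[f]] <- mask
    }
    list(cells = cells, fields = fields, masks = masks)
  })
}

# Rasterize a (possibly clipped) ellipse. Returns linear indices of in-field
# pixels and the full (unclipped) pixel count used for density.
ellipse_pixels <- function(x, y, a, b, theta, fs) {
  rmax <- max(a, b)
  rows <- floor(y - rmax - 1):ceiling(y + rmax + 1)
  cols <- floor(x - rmax - 1):ceiling(x + rmax + 1)
  ct <- cos(theta); st <- sin(theta)
  dy <- rows - y
  dx <- cols - x
  # full grid over bounding box (row-major pairs)
  DX <- matrix(dx, nrow = length(rows), ncol = length(cols), byrow = TRUE)
  DY <- matrix(dy, nrow = length(rows), ncol = length(cols))
  q <- ((DX * ct + DY * st) / a)^2 + ((-DX * st + DY * ct) / b)^2
  inside_full <- q <= 1
  full_area <- sum(inside_full)
  in_field <- outer(rows >= 1 & rows <= fs, cols >= 1 & cols <= fs, "&")
  keep <- inside_full & in_field
  ridx <- matrix(rows, length(rows), length(cols))
  cidx <- matrix(cols, length(rows), length(cols), byrow = TRUE)
  lin <- (cidx[keep] - 1L) * fs + ridx[keep]
  list(inside = lin, full_area = full_area, in_field_area = sum(keep))
}

#' Construct a multichannel field image
#'
#' @param channels Named list of equal-shaped numeric matrices (ADU);
#'   a `Hoechst` channel is expected by the segmentation stage.
#' @param pixel_size Pixel size (um/px).
#' @param field_id Identifier.
#' @return An object of class `field_image`.
#' @export
field_image <- function(channels, pixel_size = 0.325, field_id = 1) {
  if (!length(channels) || is.null(names(channels)))
    stop("channels must be a named list", call. = FALSE)
  dims <- unique(lapply(channels, dim))
  if (length(dims) != 1) stop("all channels must share a shape", call. = FALSE)
  structure(list(channels = channels, pixel_size = pixel_size,
                 field_id = field_id), class = "field_image")
}

#' @export
print.field_image <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf("<field_image #%s: %dx%d px, channels: %s>\n", x$field_id,
              d[1], d[2], paste(names(x$channels), collapse = ", ")))
  invisible(x)
}

#' Apply a transfection/demethylase perturbation to a population
#'
#' Exactly `round(n * transfected_fraction)` cells receive a positive
#' HaloTag expression level `E = A_E * LN(sigma_expression)`; every mark in
#' the effect map is rescaled by `exp(-k*E/A_E)` (substrate) or
#' `2 - exp(-k*E/A_E)` (product). Untransfected cells keep `E = 0` and unit
#' multipliers.
#'
#' @param cells Population data frame from [sample_population()].
#' @param cfg A [perturbation_config].
#' @param seed Optional RNG seed.
#' @param halo_name Name of the expression channel column added.
#' @return `cells` with a HaloTag column and rescaled mark totals.
#' @export
apply_perturbation <- function(cells, cfg, seed = NULL, halo_name = "HaloTag") {
  stopifnot(is.data.frame(cells), inherits(cfg, "perturbation_config"))
  missing_marks <- setdiff(names(cfg$effect_map), names(cells))
  if (length(missing_marks))
    stop("effect_map names absent from population: ",
         paste(missing_marks, collapse = ", "), call. = FALSE)
  with_seed(seed, {
    n <- nrow(cells)
    n_pos <- round(n * cfg$transfected_fraction)
    e <- numeric(n)
    if (n_pos > 0) {
      pos <- sample.int(n, n_pos)
      e[pos] <- cfg$a_expression *
        stats::rlnorm(n_pos, meanlog = 0, sdlog = cfg$sigma_expression)
    }
    cells[[halo_name]] <- e
    decay <- exp(-cfg$k * e / cfg$a_expression)
    for (mk in names(cfg$effect_map)) {
      mult <- if (cfg$effect_map[[mk]] == "substrate") decay else 2 - decay
      cells[[mk]] <- cells[[mk]] * mult
    }
    cells
  })
}

#' Hill dose-response fold change
#'
#' `fold(D) = 1 + emax * D^h / (D^h + ec50^h)`; `fold(0) = 1` and the
#' response is monotone nondecreasing in dose.
#'
#' @param dose Dose (nM), vectorized.
#' @param ec50 Half-maximal dose (nM).
#' @param emax Maximal fold increase above baseline.
#' @param hill Hill coefficient.
#' @return Numeric fold changes.
#' @export
hill_fold <- function(dose, ec50, emax = 5, hill = 2) {
  ifelse(dose <= 0, 1, 1 + emax * dose^hill / (dose^hill + ec50^hill))
}

#' Simulate an inhibitor-screening plate
#'
#' Generates an independent cell population per well and scales the totals
#' of dose-responsive (acetylation) marks by the Hill fold change for that
#' well's compound and dose. Non-target marks and control wells are left at
#' baseline.
#'
#' @param cfg A [plate_config].
#' @param cycle A [cell_cycle_config].
#' @param marks List of [mark_model]s.
#' @param seed RNG seed.
#' @return Data frame of per-nucleus rows with `well`, `compound`,
#'   `dose_nM` metadata columns prepended to the population columns.
#' @export
simulate_plate <- function(cfg, cycle = cell_cycle_config(),
                           marks = cellcycle_marks(), seed = NULL) {
  stopifnot(inherits(cfg, "plate_config"))
  marks <- as_mark_list(marks)
  targets <- cfg$target_marks
  if (is.null(targets)) targets <- grep("ac$", names(marks), value = TRUE)
  unknown <- setdiff(targets, names(marks))
  if (length(unknown))
    stop("target marks not in panel: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  with_seed(seed, {
    wells <- lapply(seq_len(nrow(cfg$layout)), function(i) {
      row <- cfg$layout[i, ]
      pop <- sample_population(cycle, marks, cfg$cells_per_well)
      if (row$dose_nM > 0) {
        fold <- hill_fold(row$dose_nM, cfg$ec50[[row$compound]],
                          cfg$emax, cfg$hill)
        for (mk in targets) pop[[mk]] <- pop[[mk]] * fold
      }
      cbind(data.frame(well = row$well, compound = row$compound,
                       dose_nM = row$dose_nM, stringsAsFactors = FALSE),
            pop)
    })
    do.call(rbind, wells)
  })
}

# Channel columns of a population/intensity table (everything that is not
# metadata).
channel_names <- function(tab) {
  meta <- c("cell_id", "phase", "t", "dna_content", "is_edge", "is_mitotic",
            "field", "x", "y", "radius_a", "radius_b", "theta",
            "field_id", "nucleus_id", "area", "cx", "cy",
            "edge", "mitotic", "abnormal_shape", "excluded",
            "well", "compound", "dose_nM")
  setdiff(names(tab), meta)
}
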