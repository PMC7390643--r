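# Configuration constructors with validation. All numeric defaults used by
# the simulator and the analysis stages are defined here, in one place.

#' Cell-cycle population configuration
#'
#' Defines the interphase population structure the simulator draws from:
#' phase fractions, the DNA-content model and Hoechst channel noise.
#'
#' DNA content `c` is 1 in G1, `1 + u` in S (where `u` in `[0, 1)` is S-phase
#' progress) and 2 in G2, so the total Hoechst signal
#' `A_hoechst * c * LN(sigma_hoechst)` doubles across the cycle the way a
#' stoichiometric DNA dye does.
#'
#' @param f_g1,f_s,f_g2 Phase fractions; must sum to 1.
#' @param sigma_hoechst Lognormal sd (of log) of the multiplicative noise on
#'   the Hoechst total.
#' @param a_hoechst Hoechst amplitude: expected total intensity (ADU) of a G1
#'   nucleus.
#' @return An object of class `cell_cycle_config`.
#' @examples
#' cfg <- cell_cycle_config()
#' @export
cell_cycle_config <- function(f_g1 = 0.5, f_s = 0.3, f_g2 = 0.2,
                              sigma_hoechst = 0.05, a_hoechst = 5e5) {
  assert_scalar(f_g1, "f_g1", 0, 1)
  assert_scalar(f_s, "f_s", 0, 1)
  assert_scalar(f_g2, "f_g2", 0, 1)
  if (abs(f_g1 + f_s + f_g2 - 1) > 1e-9)
    stop("phase fractions must sum to 1", call. = FALSE)
  assert_scalar(sigma_hoechst, "sigma_hoechst", 0)
  assert_scalar(a_hoechst, "a_hoechst", 1e-12)
  structure(list(f_g1 = f_g1, f_s = f_s, f_g2 = f_g2,
                 sigma_hoechst = sigma_hoechst, a_hoechst = a_hoechst),
            class = "cell_cycle_config")
}

#' Histone-mark dynamics model
#'
#' One mark's total-intensity model across the cell cycle. Five kinds cover
#' the qualitative dynamics seen for H3/H4 modifications:
#'
#' * `proportional`: total `A * c * LN(sigma)` — scales with nucleosome
#'   number (H3K4un-like).
#' * `replication_coupled`: `A * (0.3 + bump * sin(pi*u) * 1_S) * LN(sigma)` —
#'   sharply S-phase-peaked, like H4K5ac on newly deposited histones.
#' * `replication_synchronous`: `A * c * (1 + bump * sin(pi*u) * 1_S) *
#'   LN(sigma)` — proportional to DNA content with a mild S bump
#'   (H3K4me-like).
#' * `delayed_restoration`: `A * m(t) * LN(sigma) * LN(sigma_g1 in G1)` with
#'   piecewise-linear `m(t)`: 0.85 to 1.0 across G1, flat 1.0 over the first
#'   half of S, 1.0 to 0.8 over the second half, 0.8 to 0.95 across G2 —
#'   a repressive mark diluted at replication and restored only in the next
#'   G1, with extra G1 spread.
#' * `constant`: `A * LN(sigma)`.
#'
#' @param name Channel name (e.g. `"H4K5ac"`).
#' @param kind One of the five model kinds above.
#' @param amplitude Intensity scale `A` (ADU).
#' @param bump Unitless S-phase elevation `bump >= 0` (used by the two
#'   replication kinds).
#' @param sigma Lognormal sd of the multiplicative noise.
#' @param sigma_g1 Extra lognormal sd applied only in G1
#'   (`delayed_restoration` only).
#' @return An object of class `mark_model`.
#' @examples
#' mark_model("H4K5ac", "replication_coupled")
#' @export
mark_model <- function(name,
                       kind = c("proportional", "replication_coupled",
                                "replication_synchronous",
                                "delayed_restoration", "constant"),
                       amplitude = 2e5, bump = NULL, sigma = NULL,
                       sigma_g1 = 0.25) {
  kind <- match.arg(kind)
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (is.null(bump))
    bump <- switch(kind, replication_coupled = 1.7,
                   replication_synchronous = 0.25, 0)
  if (is.null(sigma))
    sigma <- switch(kind, proportional = 0.08, replication_coupled = 0.10,
                    replication_synchronous = 0.10,
                    delayed_restoration = 0.15, constant = 0.10)
  assert_scalar(amplitude, "amplitude", 1e-12)
  assert_scalar(bump, "bump", 0)
  assert_scalar(sigma, "sigma", 0)
  assert_scalar(sigma_g1, "sigma_g1", 0)
  structure(list(name = name, kind = kind, amplitude = amplitude,
                 bump = bump, sigma = sigma, sigma_g1 = sigma_g1),
            class = "mark_model")
}

#' Default cell-cycle mark panel
#'
#' A panel mirroring the canonical behaviours: a nucleosome-proportional mark
#' (H3K4un-like), the S-phase reference (H4K5ac), a second replication-coupled
#' acetylation (H4K12ac-like), a replication-synchronous methylation
#' (H3K4me3-like) and a delayed-restoration repressive mark (H3K9me3-like).
#'
#' @return Named list of [mark_model] objects.
#' @export
cellcycle_marks <- function() {
  list(
    H3K4un  = mark_model("H3K4un", "proportional"),
    H4K5ac  = mark_model("H4K5ac", "replication_coupled"),
    H4K12ac = mark_model("H4K12ac", "replication_coupled"),
    H3K4me3 = mark_model("H3K4me3", "replication_synchronous"),
    H3K9me3 = mark_model("H3K9me3", "delayed_restoration")
  )
}

#' Scene (field rendering) configuration
#'
#' @param n_interior Analyzable interphase nuclei fully inside the fields.
#' @param n_edge Border-clipped nuclei (at least 20% of area outside).
#' @param n_mitotic Small bright mitotic figures.
#' @param field_size Field side length in pixels (square fields).
#' @param nuclei_per_field Target object count per field; sets the number of
#'   fields rendered.
#' @param nucleus_radius_mean,nucleus_radius_sd Interphase nucleus radius
#'   (px).
#' @param mitotic_radius_factor Mitotic radius as a fraction of the mean
#'   interphase radius; must stay below the mitotic area-flag threshold of
#'   the segmentation stage so mitotic figures are catchable.
#' @param mitotic_intensity_factor Rendered mitotic total relative to an
#'   interphase G2 cell (single-focal-plane deficit).
#' @param background_level Additive background (ADU).
#' @param read_noise Gaussian read-noise sd (ADU).
#' @param psf_sigma Gaussian PSF sd (px); 0 disables blurring.
#' @param pixel_size_um Physical pixel size recorded in metadata.
#' @param doublets Optionally place this many touching nucleus pairs (center
#'   distance 1.6x radius) to exercise doublet splitting. Off (0) by default.
#' @return An object of class `scene_config`.
#' @export
scene_config <- function(n_interior = 450, n_edge = 12, n_mitotic = 8,
                         field_size = 512, nuclei_per_field = 48,
                         nucleus_radius_mean = 12, nucleus_radius_sd = 1.2,
                         mitotic_radius_factor = 0.4,
                         mitotic_intensity_factor = 0.87,
                         background_level = 100, read_noise = 5,
                         psf_sigma = 1, pixel_size_um = 0.325,
                         doublets = 0) {
  assert_scalar(n_interior, "n_interior", 0)
  assert_scalar(n_edge, "n_edge", 0)
  assert_scalar(n_mitotic, "n_mitotic", 0)
  assert_scalar(field_size, "field_size", 16)
  assert_scalar(nuclei_per_field, "nuclei_per_field", 1)
  assert_scalar(nucleus_radius_mean, "nucleus_radius_mean", 1)
  assert_scalar(nucleus_radius_sd, "nucleus_radius_sd", 0)
  assert_scalar(mitotic_radius_factor, "mitotic_radius_factor", 0.05, 0.7)
  assert_scalar(mitotic_intensity_factor, "mitotic_intensity_factor", 0.01)
  assert_scalar(background_level, "background_level", 0)
  assert_scalar(read_noise, "read_noise", 0)
  assert_scalar(psf_sigma, "psf_sigma", 0)
  assert_scalar(doublets, "doublets", 0)
  if (field_size <= 4 * nucleus_radius_mean)
    stop("field_size must exceed 4x the mean nucleus radius", call. = FALSE)
  structure(list(n_interior = as.integer(n_interior),
                 n_edge = as.integer(n_edge),
                 n_mitotic = as.integer(n_mitotic),
                 field_size = as.integer(field_size),
                 nuclei_per_field = as.integer(nuclei_per_field),
                 nucleus_radius_mean = nucleus_radius_mean,
                 nucleus_radius_sd = nucleus_radius_sd,
                 mitotic_radius_factor = mitotic_radius_factor,
                 mitotic_intensity_factor = mitotic_intensity_factor,
                 background_level = background_level,
                 read_noise = read_noise, psf_sigma = psf_sigma,
                 pixel_size_um = pixel_size_um,
                 doublets = as.integer(doublets)),
            class = "scene_config")
}

#' Transfection / demethylase-overexpression configuration
#'
#' Models transient HaloTag-enzyme overexpression: a fraction of cells
#' expresses the tagged enzyme at a lognormal level `E`, and each modification
#' listed in `effect_map` is rescaled monotonically in `E` —
#' `exp(-k*E/A_E)` for substrates (demethylated away) and
#' `2 - exp(-k*E/A_E)` for reaction products (accumulating).
#'
#' @param effect_map Named character vector mapping mark names to
#'   `"substrate"` or `"product"`.
#' @param transfected_fraction Fraction of cells expressing the enzyme.
#' @param a_expression Expression amplitude `A_E` (ADU).
#' @param sigma_expression Lognormal sd (of log) of expression level.
#' @param k Effect strength in the multiplier exponent.
#' @return An object of class `perturbation_config`.
#' @export
perturbation_config <- function(effect_map, transfected_fraction = 0.3,
                                a_expression = 1e5, sigma_expression = 1.0,
                                k = 1.5) {
  if (length(effect_map) == 0 || is.null(names(effect_map)) ||
      any(!nzchar(names(effect_map))))
    stop("effect_map must be a named vector", call. = FALSE)
  if (!all(effect_map %in% c("substrate", "product")))
    stop("effect_map values must be 'substrate' or 'product'", call. = FALSE)
  assert_scalar(transfected_fraction, "transfected_fraction", 0, 1)
  assert_scalar(a_expression, "a_expression", 1e-12)
  assert_scalar(sigma_expression, "sigma_expression", 0)
  assert_scalar(k, "k", 0)
  structure(list(effect_map = effect_map,
                 transfected_fraction = transfected_fraction,
                 a_expression = a_expression,
                 sigma_expression = sigma_expression, k = k),
            class = "perturbation_config")
}

#' Built-in demethylase effect presets
#'
#' Effect maps for three canonical lysine-demethylase behaviours on a
#' methylation series (`un`/`me1`/`me2`/`me3` suffixes appended to `residue`):
#' `kdm5b` removes me1/me2/me3 (KDM5-family on H3K4); `kdm4d` removes
#' me2/me3 producing me1 (H3K9); `kdm6b` removes me3 producing me1 and the
#' unmodified form (H3K27).
#'
#' @param preset One of `"kdm5b"`, `"kdm4d"`, `"kdm6b"`.
#' @param residue Residue prefix for channel names, e.g. `"H3K9"`.
#' @return Named character vector usable as `effect_map`.
#' @export
kdm_effect_map <- function(preset = c("kdm5b", "kdm4d", "kdm6b"),
                           residue = NULL) {
  preset <- match.arg(preset)
  if (is.null(residue))
    residue <- switch(preset, kdm5b = "H3K4", kdm4d = "H3K9", kdm6b = "H3K27")
  nm <- function(suffix) paste0(residue, suffix)
  switch(preset,
    kdm5b = stats::setNames(c("substrate", "substrate", "substrate"),
                            nm(c("me1", "me2", "me3"))),
    kdm4d = stats::setNames(c("product", "substrate", "substrate"),
                            nm(c("me1", "me2", "me3"))),
    kdm6b = stats::setNames(c("product", "product", "substrate"),
                            nm(c("un", "me1", "me3"))))
}

#' Screening-plate configuration
#'
#' @param layout Data frame with columns `well`, `compound`, `dose_nM`;
#'   untreated control wells have `dose_nM = 0`. See [plate_layout()].
#' @param ec50 Named numeric vector of EC50 (nM) per compound.
#' @param emax Maximal fold increase above baseline in the Hill response.
#' @param hill Hill coefficient.
#' @param cells_per_well Nuclei simulated per well.
#' @param target_marks Mark names whose totals respond to dose; `NULL` means
#'   every mark whose name ends in `"ac"` (acetylation channels).
#' @return An object of class `plate_config`.
#' @export
plate_config <- function(layout, ec50, emax = 5, hill = 2,
                         cells_per_well = 200, target_marks = NULL) {
  req <- c("well", "compound", "dose_nM")
  if (!is.data.frame(layout) || !all(req %in% names(layout)))
    stop("layout needs columns well, compound, dose_nM", call. = FALSE)
  if (!any(layout$dose_nM == 0))
    stop("layout must include untreated (dose 0) control wells", call. = FALSE)
  if (any(layout$dose_nM < 0)) stop("doses must be >= 0", call. = FALSE)
  treated <- unique(layout$compound[layout$dose_nM > 0])
  missing_ec50 <- setdiff(treated, names(ec50))
  if (length(missing_ec50))
    stop("no EC50 for compound(s): ", paste(missing_ec50, collapse = ", "),
         call. = FALSE)
  assert_scalar(emax, "emax", 0)
  assert_scalar(hill, "hill", 1e-6)
  assert_scalar(cells_per_well, "cells_per_well", 1)
  structure(list(layout = layout, ec50 = ec50, emax = emax, hill = hill,
                 cells_per_well = as.integer(cells_per_well),
                 target_marks = target_marks),
            class = "plate_config")
}

#' Build a simple plate layout
#'
#' @param compounds Character vector of compound names (one column each).
#' @param doses Dose series in nM; must include 0 for controls.
#' @param n_control Number of extra untreated control wells.
#' @return Data frame with `well`, `compound`, `dose_nM` columns.
#' @export
plate_layout <- function(compounds, doses = c(0, 1, 10, 100, 1000),
                         n_control = 4) {
  grid <- expand.grid(compound = compounds, dose_nM = doses,
                      stringsAsFactors = FALSE)
  ctrl <- data.frame(compound = "control",
                     dose_nM = rep(0, n_control))
  out <- rbind(grid, ctrl)
  out$well <- sprintf("%s%02d", LETTERS[(seq_len(nrow(out)) - 1) %/% 12 + 1],
                      (seq_len(nrow(out)) - 1) %% 12 + 1)
  out[, c("well", "compound", "dose_nM")]
}

#' Segmentation configuration
#'
#' @param smoothing_sigma Gaussian pre-smoothing sd (px) before thresholding.
#' @param min_area_frac Components smaller than this fraction of the median
#'   component area are dropped as debris.
#' @param mitotic_area_factor Objects smaller than this fraction of the
#'   median non-edge area are flagged mitotic.
#' @param solidity_min Objects with solidity below this are flagged
#'   `abnormal_shape` (apoptotic-like).
#' @param split_doublets Split touching nuclei by distance-transform
#'   watershed.
#' @param seed_separation_frac Minimum watershed-seed separation as a
#'   fraction of the median object radius.
#' @return An object of class `seg_config`.
#' @export
seg_config <- function(smoothing_sigma = 1.0, min_area_frac = 1 / 8,
                       mitotic_area_factor = 0.5, solidity_min = 0.8,
                       split_doublets = TRUE, seed_separation_frac = 0.8) {
  assert_scalar(smoothing_sigma, "smoothing_sigma", 0)
  assert_scalar(min_area_frac, "min_area_frac", 0, 1)
  assert_scalar(mitotic_area_factor, "mitotic_area_factor", 1e-9, 1 - 1e-9)
  assert_scalar(solidity_min, "solidity_min", 1e-9, 1)
  assert_scalar(seed_separation_frac, "seed_separation_frac", 0)
  structure(list(smoothing_sigma = smoothing_sigma,
                 min_area_frac = min_area_frac,
                 mitotic_area_factor = mitotic_area_factor,
                 solidity_min = solidity_min,
                 split_doublets = isTRUE(split_doublets),
                 seed_separation_frac = seed_separation_frac),
            class = "seg_config")
}

#' Cell-cycle phase gates on normalized intensities
#'
#' Hard gates replacing visual rainbow coding: S if the S-phase reference
#' mark exceeds `s_marker_threshold`; otherwise G1/G2 by normalized Hoechst.
#'
#' @param s_marker_threshold Normalized S-marker threshold.
#' @param g1_max,g2_min Normalized-Hoechst bounds for G1 and G2 calls.
#' @return An object of class `phase_gates`.
#' @export
phase_gates <- function(s_marker_threshold = 1.3, g1_max = 1.25,
                        g2_min = 1.75) {
  assert_scalar(s_marker_threshold, "s_marker_threshold", 0)
  assert_scalar(g1_max, "g1_max", 1, 2)
  assert_scalar(g2_min, "g2_min", 1, 2)
  if (!(g1_max < g2_min))
    stop("g1_max must be < g2_min", call. = FALSE)
  structure(list(s_marker_threshold = s_marker_threshold,
                 g1_max = g1_max, g2_min = g2_min),
            class = "phase_gates")
}
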