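#' Specify a study group for the synthetic study generator
#'
#' @param name group name (e.g. "saline", "bleomycin").
#' @param n_slides slides (animals) in the group, >= 1.
#' @param mass_fraction,mass_sd mean and SD of the per-slide fibrotic-mass
#'   fraction (truncated to `[0,1]`).
#' @param collagen_fraction,collagen_sd mean and SD of the per-slide alveolar
#'   collagen fraction.
#' @param timepoint free-text timepoint label (e.g. "D14").
#' @return a list usable in [generate_study()].
#' @export
group_spec <- function(name, n_slides, mass_fraction, mass_sd = 0.02,
                       collagen_fraction = 0.03, collagen_sd = 0.01,
                       timepoint = "D14") {
  if (!is_count(n_slides, 1)) fq_stop("fq_param_error", "n_slides must be >= 1")
  if (!is_fraction(mass_fraction) || !is_fraction(collagen_fraction))
    fq_stop("fq_param_error", "group fractions must lie in [0,1]")
  list(name = name, n_slides = as.integer(n_slides),
       mass_fraction = mass_fraction, mass_sd = mass_sd,
       collagen_fraction = collagen_fraction, collagen_sd = collagen_sd,
       timepoint = timepoint)
}

#' Generate a synthetic multi-group study
#'
#' Emulates a batch of independent animal studies: per-slide disease burden is
#' drawn from the group's distribution, and every slide gets its own stain
#' profile drawn uniformly from the drift range (hue shift -15..+15 degrees,
#' channel gain 0.8..1.2), mimicking staining variation across studies and
#' years.
#'
#' @param group_specs non-empty list of [group_spec()]s.
#' @param seed study seed; each slide derives its own sub-seed.
#' @param base_params template [synthetic_slide_params()] for everything not
#'   varied per slide (size, bronchi, noise).
#' @param dir if non-NULL, each slide's pyramid and ground truth are written
#'   there (`<slide_id>.tiff`, `<slide_id>_gt.tiff`) and dropped from memory.
#' @return list with `slides` (list of `fq_slide`, or of file paths when `dir`
#'   is given), and `metadata` (data.frame: slide_id, animal_id, group,
#'   timepoint, true fractions realized in the ground truth, stain drift).
#' @export
generate_study <- function(group_specs, seed = 1L, base_params = NULL, dir = NULL) {
  if (length(group_specs) == 0)
    fq_stop("fq_param_error", "group_specs must be non-empty")
  base_params <- base_params %||% synthetic_slide_params()
  meta <- list(); slides <- list()
  idx <- 0L
  for (g in group_specs) {
    for (i in seq_len(g$n_slides)) {
      idx <- idx + 1L
      sseed <- derive_seed(seed, idx)
      draws <- with_seed(derive_seed(seed, 10000L + idx), {
        list(mass = clamp(rnorm(1, g$mass_fraction, g$mass_sd), 0, 1),
             coll = clamp(rnorm(1, g$collagen_fraction, g$collagen_sd), 0, 1),
             hue = runif(1, -15, 15), gain = runif(1, 0.8, 1.2))
      })
      sp <- base_params$stain_profile
      params <- synthetic_slide_params(
        width_px = base_params$width_px, height_px = base_params$height_px,
        fibrotic_mass_fraction = draws$mass,
        alveolar_collagen_fraction = draws$coll,
        n_bronchi = base_params$n_bronchi,
        stain_profile = stain_profile(sp$collagen, sp$cytoplasm, sp$background,
                                      hue_shift_deg = draws$hue,
                                      intensity_scale = draws$gain),
        noise_sd = base_params$noise_sd,
        pixel_size_um = base_params$pixel_size_um,
        alveolus_px = base_params$alveolus_px, septum_px = base_params$septum_px,
        seed = sseed)
      slide <- generate_slide(params)
      slide_id <- sprintf("s%d_%s_%02d", seed, g$name, i)
      meta[[idx]] <- data.frame(
        slide_id = slide_id, animal_id = sprintf("animal_%03d", idx),
        group = g$name, timepoint = g$timepoint,
        true_mass_fraction = slide$gt$mass_fraction,
        true_collagen_fraction = slide$gt$collagen_fraction,
        hue_shift_deg = draws$hue, intensity_scale = draws$gain,
        seed = sseed, stringsAsFactors = FALSE)
      if (is.null(dir)) {
        slides[[slide_id]] <- slide
      } else {
        write_slide_tiff(slide$pyramid, file.path(dir, paste0(slide_id, ".tiff")))
        write_ground_truth(slide$gt, file.path(dir, paste0(slide_id, "_gt.tiff")))
        slides[[slide_id]] <- file.path(dir, paste0(slide_id, ".tiff"))
      }
    }
  }
  list(slides = slides, metadata = do.call(rbind, meta))
}
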