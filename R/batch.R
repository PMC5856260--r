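#' Run a batch quantification over a study
#'
#' Processes every slide named in a JSON config with both trained models and
#' writes a study table CSV. A slide that fails to load or quantify becomes a
#' `failed` row (the batch continues); a missing model aborts.
#'
#' Config keys: `slides` (array of TIFF paths, or a directory to scan for
#' `*.tiff` excluding `*_gt.tiff`), `model_low`, `model_high` (classifier
#' JSON paths), `output_dir`, optional `metadata_csv` (joined on `slide_id` =
#' file stem), optional `qc` thresholds and `exclude_slides` (manual override
#' list of slide ids to mark excluded, reproducing a visual QC decision).
#'
#' @param config path to the JSON config, or an equivalent named list.
#' @return the study table (invisibly written to
#'   `<output_dir>/study_table.csv`): one row per slide with the three
#'   readouts, QC flags and failure status.
#' @export
run_batch <- function(config) {
  cfg <- if (is.character(config)) jsonlite::read_json(config, simplifyVector = TRUE)
         else config
  for (key in c("slides", "model_low", "model_high", "output_dir"))
    if (is.null(cfg[[key]]))
      fq_stop("fq_config_error", "batch config lacks '%s'", key)
  if (!file.exists(cfg$model_low) || !file.exists(cfg$model_high))
    fq_stop("fq_config_error", "model file(s) not found")
  clf_low <- load_classifier(cfg$model_low)
  clf_high <- load_classifier(cfg$model_high)
  paths <- cfg$slides
  if (length(paths) == 1 && dir.exists(paths)) {
    paths <- list.files(paths, pattern = "\\.tiff?$", full.names = TRUE)
    paths <- paths[!grepl("_gt\\.tiff?$", paths)]
  }
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  meta <- if (!is.null(cfg$metadata_csv)) read.csv(cfg$metadata_csv) else NULL
  exclude <- cfg$exclude_slides %||% character(0)

  rows <- lapply(paths, function(p) {
    slide_id <- sub("\\.tiff?$", "", basename(p))
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch({
      pyr <- read_slide_tiff(p)
      q <- quantify_slide(pyr, clf_low, clf_high,
                          qc = cfg$qc)
      data.frame(slide_id = slide_id,
                 fibrotic_mass_percent = q$fibrotic_mass_percent,
                 alveolar_collagen_percent = q$alveolar_collagen_percent,
                 total_collagen_percent = q$total_collagen_percent,
                 roi_px = q$roi_px,
                 qc_excluded = q$qc$flagged,
                 qc_reason = paste(q$qc$reasons, collapse = "; "),
                 failed = FALSE, stringsAsFactors = FALSE)
    }, error = function(e) {
      data.frame(slide_id = slide_id, fibrotic_mass_percent = NA_real_,
                 alveolar_collagen_percent = NA_real_,
                 total_collagen_percent = NA_real_, roi_px = NA_integer_,
                 qc_excluded = TRUE, qc_reason = conditionMessage(e),
                 failed = TRUE, stringsAsFactors = FALSE)
    })
    message(sprintf("[fibroquant] %s: %s (%.1fs, models %s/%s)", slide_id,
                    if (res$failed) "FAILED" else "ok",
                    proc.time()[["elapsed"]] - t0,
                    substr(clf_low$training_hash, 1, 8),
                    substr(clf_high$training_hash, 1, 8)))
    res
  })
  tab <- do.call(rbind, rows)
  if (length(exclude) > 0) {
    hit <- tab$slide_id %in% exclude
    tab$qc_excluded[hit] <- TRUE
    tab$qc_reason[hit] <- ifelse(nzchar(tab$qc_reason[hit]),
                                 paste0(tab$qc_reason[hit], "; manual override"),
                                 "manual override")
  }
  if (!is.null(meta)) tab <- merge(meta, tab, by = "slide_id", all.y = TRUE, sort = FALSE)
  # stable column order
  lead <- intersect(c("slide_id", "animal_id", "group", "timepoint"), names(tab))
  tab <- tab[, c(lead, setdiff(names(tab), lead)), drop = FALSE]
  write.csv(tab, file.path(cfg$output_dir, "study_table.csv"), row.names = FALSE)
  invisible(tab)
}
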