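#' Write or read a cohort dataset as CSV tables with a JSON sidecar
#'
#' \code{write_cohort} writes \code{subjects.csv}, \code{cells.csv} and
#' \code{config.json} (the full generator configuration, including the seed)
#' into \code{dir}; \code{read_cohort} restores the dataset losslessly.
#'
#' @param dataset a \code{cohort_dataset}.
#' @param dir directory (created if missing).
#' @return \code{write_cohort} returns \code{dir} invisibly;
#'   \code{read_cohort} returns a \code{cohort_dataset}.
#' @export
write_cohort <- function(dataset, dir) {
  stopifnot(inherits(dataset, "cohort_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(dataset$subjects, file.path(dir, "subjects.csv"),
                   row.names = FALSE)
  utils::write.csv(dataset$cells, file.path(dir, "cells.csv"),
                   row.names = FALSE)
  cfg <- unclass(dataset$config)
  # serialize named numeric vectors as JSON objects so names survive
  cfg$subtype_enrichment <- lapply(cfg$subtype_enrichment, as.list)
  cfg$covariate_effects <- as.list(cfg$covariate_effects)
  jsonlite::write_json(cfg, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  cfg_raw <- jsonlite::read_json(file.path(dir, "config.json"),
                                 simplifyVector = TRUE)
  # subtype enrichment folds round-trip as named lists; restore vectors
  cfg_raw$subtype_enrichment <- lapply(cfg_raw$subtype_enrichment, unlist)
  cfg_raw$covariate_effects <- unlist(cfg_raw$covariate_effects)
  cfg <- do.call(cohort_config, cfg_raw)
  subjects <- utils::read.csv(file.path(dir, "subjects.csv"),
                              stringsAsFactors = FALSE)
  cells <- utils::read.csv(file.path(dir, "cells.csv"),
                           stringsAsFactors = FALSE)
  # all-NA columns (measures absent from the assay) read back as logical
  if ("pv_intensity" %in% names(cells))
    cells$pv_intensity <- as.numeric(cells$pv_intensity)
  for (col in c("pv_grain_count", "vamp1_grain_count"))
    if (col %in% names(cells)) cells[[col]] <- as.integer(cells[[col]])
  new_cohort_dataset(subjects, cells, cfg)
}
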