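## Study-table loading/validation and pipeline configuration.

STUDY_COLUMNS <- c("animal_id", "group", "day", "session", "tracer",
                   "dose_MBq", "t_injection", "t_scan", "weight_g",
                   "half_life_min", "file")

#' Load and validate a study metadata table
#'
#' Reads the CSV written by [generate_cohort()] (or prepared for real
#' data) and validates each record: groups and tracers must be known,
#' PET doses positive, acquisition after injection, weights positive,
#' `(animal, day, tracer)` keys unique, and every referenced volume file
#' present under `root`.
#'
#' @param table_path Path to the metadata CSV.
#' @param root Directory the `file` column is relative to; defaults to
#'   the CSV's directory.
#' @return The validated study table (class `study_table`).
#' @export
load_study <- function(table_path, root = dirname(table_path)) {
  if (!file.exists(table_path)) stop("study table not found: ", table_path)
  study <- read.csv(table_path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(STUDY_COLUMNS, names(study))
  if (length(missing_cols))
    stop("study table lacks required columns: ", paste(missing_cols, collapse = ", "))
  key <- paste(study$animal_id, study$day, study$tracer)
  if (anyDuplicated(key))
    stop("duplicate (animal, day, tracer) keys: ",
         paste(unique(key[duplicated(key)]), collapse = "; "))
  if (!all(study$group %in% STUDY_GROUPS))
    stop("unknown group(s): ",
         paste(setdiff(unique(study$group), STUDY_GROUPS), collapse = ", "))
  pet <- study$tracer != "CT"
  if (any(!study$tracer %in% c(TRACERS, "CT")))
    stop("unknown tracer(s): ",
         paste(setdiff(unique(study$tracer), c(TRACERS, "CT")), collapse = ", "))
  bad_dose <- pet & (!is.finite(study$dose_MBq) | study$dose_MBq <= 0)
  if (any(bad_dose))
    stop("non-positive injected dose for: ",
         paste(key[bad_dose], collapse = "; "))
  if (any(!is.finite(study$weight_g) | study$weight_g <= 0))
    stop("non-positive body weight in study table")
  if (any(pet)) {
    el <- as.numeric(difftime(parse_iso8601(study$t_scan[pet]),
                              parse_iso8601(study$t_injection[pet]),
                              units = "mins"))
    if (any(!is.finite(el) | el < 0))
      stop("acquisition precedes injection for: ",
           paste(key[pet][!is.finite(el) | el < 0], collapse = "; "))
  }
  present <- file.exists(file.path(root, study$file))
  if (!all(present))
    stop("missing volume file(s): ",
         paste(study$file[!present], collapse = ", "))
  class(study) <- c("study_table", class(study))
  study
}

#' Pipeline configuration
#'
#' Bundles the tunables of the quantification chain: segmentation
#' parameters, density bands and the HLV ratio multiplier.
#'
#' @param seg A [seg_params()] list.
#' @param bands Density bands in HU (length 3).
#' @param hlv_multiplier Voxel-to-background ratio defining hypoxic
#'   voxels (1.4).
#' @export
pipeline_config <- function(seg = seg_params(), bands = c(-800, -100, 300),
                            hlv_multiplier = 1.4) {
  list(seg = seg, bands = bands, hlv_multiplier = hlv_multiplier)
}

#' Read a pipeline configuration from YAML or JSON
#'
#' Recognised keys: `lung_threshold_hu`, `min_volume_ml`,
#' `closing_radius`, `keep_components`, `bands`, `hlv_multiplier`.
#' Unknown keys raise an error.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A [pipeline_config()].
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("yaml", "yml")) yaml::read_yaml(path)
         else if (ext == "json") jsonlite::read_json(path, simplifyVector = TRUE)
         else stop("unsupported config format: .", ext)
  seg_keys <- c("lung_threshold_hu", "min_volume_ml", "closing_radius",
                "keep_components")
  known <- c(seg_keys, "bands", "hlv_multiplier")
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) stop("unknown config keys: ", paste(unknown, collapse = ", "))
  seg <- do.call(seg_params, raw[intersect(names(raw), seg_keys)])
  cfg <- pipeline_config(seg = seg)
  if (!is.null(raw$bands)) cfg$bands <- as.numeric(raw$bands)
  if (!is.null(raw$hlv_multiplier)) cfg$hlv_multiplier <- raw$hlv_multiplier
  if (length(cfg$bands) != 3 || is.unsorted(cfg$bands, strictly = TRUE))
    stop("config error: density bands must be three increasing HU values")
  cfg
}
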