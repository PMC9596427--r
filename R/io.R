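# On-disk interchange: single-channel TIFF rasters, CSV tables, YAML
# metadata. Thickness rasters are stored as 32-bit float TIFF in
# millimeters (values fall in [0, 1], the range float TIFF encodes
# portably); the package API works in micrometers throughout. Masks are
# 8-bit {0, 255}.

#' Write and read thickness rasters as TIFF
#'
#' @param map Thickness matrix, um.
#' @param path Output path.
#' @return `write_thickness_tiff()` returns `path` invisibly;
#'   `read_thickness_tiff()` returns the thickness matrix in um.
#' @export
write_thickness_tiff <- function(map, path) {
  tiff::writeTIFF(map / 1000, path, bits.per.sample = 32L,
                  compression = "none", reduce = FALSE)
  invisible(path)
}

#' @rdname write_thickness_tiff
#' @export
read_thickness_tiff <- function(path) {
  as.matrix(tiff::readTIFF(path)) * 1000
}

#' Write and read lesion masks as 8-bit TIFF
#'
#' @param mask Logical or 0/1 matrix.
#' @param path Output path.
#' @return `write_mask_tiff()` returns `path` invisibly;
#'   `read_mask_tiff()` returns a logical matrix.
#' @export
write_mask_tiff <- function(mask, path) {
  tiff::writeTIFF((mask != 0) * 1, path, bits.per.sample = 8L,
                  compression = "none", reduce = FALSE)
  invisible(path)
}

#' @rdname write_mask_tiff
#' @export
read_mask_tiff <- function(path) {
  as.matrix(tiff::readTIFF(path)) > 0.5
}

#' Write a synthetic cohort to a directory
#'
#' Lays out a cohort as portable files: `manifest.csv`, `config.yaml`,
#' per-eye/visit/layer thickness TIFFs under `maps/`, masks under `masks/`,
#' the normative set under `normative/` with `normative/ages.csv`.
#'
#' @param cohort A `ga_cohort`.
#' @param dir Target directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "ga_cohort"))
  for (d in file.path(dir, c("", "maps", "masks", "normative"))) {
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
  }
  utils::write.csv(cohort$manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  write_trial_config(cohort$config, file.path(dir, "config.yaml"))
  for (eid in names(cohort$masks)) {
    for (mo in names(cohort$masks[[eid]])) {
      write_mask_tiff(cohort$masks[[eid]][[mo]],
                      file.path(dir, "masks",
                                sprintf("%s_m%s.tif", eid, mo)))
      if (length(cohort$maps)) {
        for (ly in names(cohort$maps[[eid]][[mo]])) {
          write_thickness_tiff(
            cohort$maps[[eid]][[mo]][[ly]],
            file.path(dir, "maps", sprintf("%s_m%s_%s.tif", eid, mo, ly)))
        }
      }
    }
  }
  if (!is.null(cohort$normative)) {
    ns <- cohort$normative
    for (i in seq_along(ns$maps)) {
      for (ly in names(ns$maps[[i]])) {
        write_thickness_tiff(
          ns$maps[[i]][[ly]],
          file.path(dir, "normative", sprintf("N%03d_%s.tif", i, ly)))
      }
    }
    utils::write.csv(
      data.frame(id = sprintf("N%03d", seq_along(ns$maps)),
                 age = ns$ages, laterality = ns$lateralities),
      file.path(dir, "normative", "ages.csv"), row.names = FALSE)
  }
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir Directory produced by [write_cohort()].
#' @return A `ga_cohort` (generating-truth table `eyes` is not persisted
#'   and comes back `NULL`).
#' @export
read_cohort <- function(dir) {
  manifest <- tibble::as_tibble(utils::read.csv(
    file.path(dir, "manifest.csv"), stringsAsFactors = FALSE))
  config <- read_trial_config(file.path(dir, "config.yaml"))
  masks <- list()
  maps <- list()
  mask_files <- list.files(file.path(dir, "masks"), pattern = "\\.tif$")
  for (f in mask_files) {
    parts <- regmatches(f, regexec("^(.*)_m([0-9]+)\\.tif$", f))[[1]]
    masks[[parts[2]]][[parts[3]]] <- read_mask_tiff(
      file.path(dir, "masks", f))
  }
  map_files <- list.files(file.path(dir, "maps"), pattern = "\\.tif$")
  for (f in map_files) {
    parts <- regmatches(f,
                        regexec("^(.*)_m([0-9]+)_([A-Z]+)\\.tif$", f))[[1]]
    maps[[parts[2]]][[parts[3]]][[parts[4]]] <- read_thickness_tiff(
      file.path(dir, "maps", f))
  }
  normative <- NULL
  ages_path <- file.path(dir, "normative", "ages.csv")
  if (file.exists(ages_path)) {
    ages_df <- utils::read.csv(ages_path, stringsAsFactors = FALSE)
    nmaps <- lapply(ages_df$id, function(id) {
      layer_files <- list.files(file.path(dir, "normative"),
                                pattern = paste0("^", id, "_.*\\.tif$"))
      lys <- sub("\\.tif$", "", sub(paste0("^", id, "_"), "", layer_files))
      m <- lapply(layer_files, function(lf)
        read_thickness_tiff(file.path(dir, "normative", lf)))
      names(m) <- lys
      m[intersect(JZ_LAYERS, lys)]
    })
    normative <- structure(
      list(maps = nmaps, ages = ages_df$age,
           lateralities = ages_df$laterality,
           pixel_pitch_deg = config$pixel_pitch_deg),
      class = "normative_set")
  }
  structure(list(manifest = manifest, maps = maps, masks = masks,
                 normative = normative, eyes = NULL, config = config),
            class = "ga_cohort")
}
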