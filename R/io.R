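#' Write an OCT volume to disk
#'
#' Volumes are stored as multi-page TIFF (one page per B-scan, rows =
#' depth, 16-bit) or NIfTI, chosen by file extension (`.tif`/`.tiff` vs
#' `.nii`/`.nii.gz`).  Either way the intensities are quantized to 16 bit
#' so the two formats round-trip identically.  Geometry travels in a JSON
#' sidecar (`<path>.json`): lateral spacing, axial spacing, fovea index.
#' Missing voxels (from flattened volumes) are stored as 0.
#'
#' @param volume an [oct_volume()].
#' @param path output file path.
#' @param sidecar sidecar path (default `<path>.json`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path, sidecar = paste0(path, ".json")) {
  stopifnot(inherits(volume, "oct_volume"))
  V <- volume$intensity
  V[is.na(V)] <- 0
  V <- round(V * 65535) / 65535
  geom <- volume$geometry
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    pages <- lapply(seq_len(geom$dims[1L]), function(b) t(V[b, , ]))
    tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "LZW")
  } else if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) {
    RNifti::writeNifti(RNifti::asNifti(V), path)
  } else {
    stop("unsupported volume format: ", path)
  }
  jsonlite::write_json(
    list(lateral_spacing_um = geom$lateral_spacing_um,
         axial_spacing_um = geom$axial_spacing_um,
         fovea_index = geom$fovea_index,
         dims = geom$dims),
    sidecar, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' Read an OCT volume and its geometry sidecar
#'
#' @param path a `.tif`/`.tiff` or `.nii`/`.nii.gz` file written by
#'   [write_volume()] (or equivalent).
#' @param sidecar JSON sidecar path (default `<path>.json`).
#' @return an [oct_volume()].
#' @export
read_volume <- function(path, sidecar = paste0(path, ".json")) {
  if (!file.exists(path)) stop("volume file not found: ", path)
  if (!file.exists(sidecar)) {
    stop("geometry sidecar not found: ", sidecar,
         " (required keys: lateral_spacing_um, axial_spacing_um, fovea_index)")
  }
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  required <- c("lateral_spacing_um", "axial_spacing_um", "fovea_index")
  missing_keys <- setdiff(required, names(meta))
  if (length(missing_keys) > 0L) {
    stop("sidecar is missing geometry keys: ",
         paste(missing_keys, collapse = ", "))
  }
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    pages <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    nb <- length(pages)
    na_ <- ncol(pages[[1L]]); nz <- nrow(pages[[1L]])
    V <- array(0, c(nb, na_, nz))
    for (b in seq_len(nb)) V[b, , ] <- t(pages[[b]])
  } else if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) {
    V <- RNifti::readNifti(path)
    V <- array(as.vector(V), dim = dim(V))
  } else {
    stop("unsupported volume format: ", path)
  }
  geom <- voxel_geometry(lateral_spacing_um = meta$lateral_spacing_um,
                         axial_spacing_um = meta$axial_spacing_um,
                         dims = dim(V),
                         fovea_index = meta$fovea_index)
  if (!is.null(meta$dims) && !all(meta$dims == dim(V))) {
    stop("sidecar dims ", paste(meta$dims, collapse = "x"),
         " do not match volume data ", paste(dim(V), collapse = "x"))
  }
  oct_volume(V, geom)
}

#' Write / read boundary surfaces as CSV
#'
#' Long-format table: columns `b_scan`, `a_scan`, then one depth column
#' (micrometres) per surface.
#'
#' @param surfaces a [surface_set()].
#' @param path CSV path.
#' @return `path` invisibly / a `surface_set`.
#' @export
write_surfaces <- function(surfaces, path) {
  stopifnot(inherits(surfaces, "surface_set"))
  nb <- nrow(surfaces[[1L]]); na_ <- ncol(surfaces[[1L]])
  df <- data.frame(b_scan = rep(seq_len(nb), na_),
                   a_scan = rep(seq_len(na_), each = nb))
  for (nm in names(surfaces)) df[[nm]] <- as.vector(surfaces[[nm]])
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_surfaces
#' @export
read_surfaces <- function(path) {
  df <- utils::read.csv(path)
  nb <- max(df$b_scan); na_ <- max(df$a_scan)
  ord <- order(df$a_scan, df$b_scan)
  nms <- setdiff(names(df), c("b_scan", "a_scan"))
  maps <- lapply(nms, function(nm) matrix(df[[nm]][ord], nb, na_))
  names(maps) <- nms
  surface_set(maps)
}

#' Export an en face image as PNG with JSON provenance
#'
#' @param image an [enface_image()].
#' @param path PNG path; provenance goes to `<path>.json` (slab
#'   parameters and geometry).
#' @return `path`, invisibly.
#' @export
write_enface <- function(image, path) {
  stopifnot(inherits(image, "enface_image"))
  px <- image$pixels
  px[is.na(px)] <- 0
  png::writePNG(pmin(pmax(t(px), 0), 1), path)
  jsonlite::write_json(
    list(slab = unclass(image$slab),
         lateral_spacing_um = image$geometry$lateral_spacing_um,
         fovea_index = image$geometry$fovea_index),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Parse an edema type label into its components
#'
#' @param label a taxonomy label such as `"FC/NF"` or `"DF/DF + SF"`.
#' @return list `segment1`, `segment2` (`"NF"`/`"DF"`), `sf` (logical).
#' @export
parse_dme_label <- function(label) {
  if (length(label) != 1L || !label %in% taxonomy_labels()) {
    stop("unknown edema type label: '", label, "'")
  }
  parts <- strsplit(label, "/", fixed = TRUE)[[1L]]
  s2_raw <- parts[2L]
  list(segment1 = parts[1L],
       segment2 = if (s2_raw %in% c("DF", "DF + SF")) "DF" else "NF",
       sf = s2_raw %in% c("SF", "DF + SF"))
}

cohort_columns <- function() {
  c("eye_id", "age", "sex", "hba1c", "bcva_decimal", "dme_type", "cst_um",
    "ez_disrupted", "erm_present", "mdrf_um", "pvd_incomplete")
}

#' Read / write a per-eye cohort table
#'
#' CSV with columns `eye_id`, `age` (years), `sex` (`"F"`/`"M"`), `hba1c`
#' (%), `bcva_decimal` (decimal acuity), `dme_type` (taxonomy label),
#' `cst_um`, `ez_disrupted`, `erm_present` (logical), `mdrf_um` (`NA`
#' unless `erm_present`), `pvd_incomplete` (logical).  Reading validates
#' type labels against the taxonomy and adds the derived columns
#' `bcva_logmar` and `segment2_fluid`.
#'
#' @param path CSV path.
#' @return a `data.frame` (class `cohort_table`).
#' @export
read_cohort <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(cohort_columns(), names(df))
  if (length(missing_cols) > 0L) {
    stop("cohort table is missing columns: ",
         paste(missing_cols, collapse = ", "))
  }
  bad <- setdiff(unique(df$dme_type), taxonomy_labels())
  if (length(bad) > 0L) {
    stop("unknown edema type label(s): ", paste(sQuote(bad), collapse = ", "))
  }
  as_cohort_table(df)
}

#' @rdname read_cohort
#' @param cohort a cohort `data.frame`.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort[, cohort_columns()], path, row.names = FALSE)
  invisible(path)
}

#' Attach derived cohort columns and validate invariants
#'
#' Adds `bcva_logmar` and `segment2_fluid` (present iff the type has
#' diffuse Segment-2 fluid: `PC/DF`, `DF/DF`, `DF/DF + SF`).
#'
#' @param df data frame with the columns of [read_cohort()].
#' @return a `cohort_table` data frame.
#' @export
as_cohort_table <- function(df) {
  for (lab in unique(df$dme_type)) parse_dme_label(lab)  # validates
  df$bcva_logmar <- decimal_to_logmar(df$bcva_decimal)
  df$segment2_fluid <- vapply(df$dme_type,
                              function(l) parse_dme_label(l)$segment2 == "DF",
                              logical(1), USE.NAMES = FALSE)
  if (any(!df$erm_present & !is.na(df$mdrf_um))) {
    stop("mdrf_um must be NA for eyes without an epiretinal membrane")
  }
  class(df) <- c("cohort_table", "data.frame")
  df
}
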