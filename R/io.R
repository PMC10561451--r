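# File formats: 2-page 16-bit TIFF fields (page 1 nuclear, page 2 green),
# CSV truth/layout/results tables with a provenance comment header, JSON
# sidecars for planted-foci lists.

#' Write a field as a 2-page 16-bit TIFF
#'
#' Page 1 is the nuclear channel, page 2 the green channel. The filename
#' convention `<plate>_<well>_<field>.tif` carries the identity.
#'
#' @param field a `field_image`.
#' @param dir output directory.
#' @param path explicit path (overrides the convention).
#' @return the written path, invisibly.
#' @export
write_field_tiff <- function(field, dir = ".", path = NULL) {
  path <- path %||% file.path(dir, sprintf("%s_%s_%s.tif", field$plate,
                                           field$well, field$field))
  maxv <- 2^field$bit_depth - 1
  tiff::writeTIFF(list(field$nuclear / maxv, field$green / maxv),
                  path, bits.per.sample = 16L, compression = "none")
  invisible(path)
}

#' Read a field from a 2-page 16-bit TIFF
#'
#' @param path TIFF path; identity is parsed from the
#'   `<plate>_<well>_<field>.tif` filename convention unless given.
#' @param plate,well,field identity overrides.
#' @param bit_depth camera bit depth of the stored data.
#' @return a `field_image`.
#' @export
read_field_tiff <- function(path, plate = NULL, well = NULL, field = NULL,
                            bit_depth = 16L) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (length(pages) != 2L)
    stop_fs("expected a 2-page TIFF (nuclear, green); got %d page(s) in %s",
            length(pages), path)
  if (is.null(plate)) {
    parts <- strsplit(tools::file_path_sans_ext(basename(path)), "_")[[1]]
    if (length(parts) != 3L)
      stop_fs("cannot parse identity from filename '%s' (expected plate_well_field.tif)",
              basename(path))
    plate <- parts[1]; well <- parts[2]; field <- parts[3]
  }
  nuc <- pages[[1]]; grn <- pages[[2]]
  storage.mode(nuc) <- "integer"; storage.mode(grn) <- "integer"
  structure(list(nuclear = nuc, green = grn, plate = plate, well = well,
                 field = field, bit_depth = as.integer(bit_depth)),
            class = "field_image")
}

#' Write ground truth as CSV plus a JSON foci sidecar
#'
#' @param truth a `ground_truth_field`.
#' @param stem output path stem; writes `<stem>.csv` and `<stem>_foci.json`.
#' @return paths, invisibly.
#' @export
write_truth <- function(truth, stem) {
  csv <- paste0(stem, ".csv"); js <- paste0(stem, "_foci.json")
  utils::write.csv(truth$cells, csv, row.names = FALSE)
  jsonlite::write_json(truth$foci, js, digits = NA)
  invisible(c(csv, js))
}

#' Parse and validate a plate-layout CSV
#'
#' Required columns: `plate, well, role, compound_id, dose_uM, duration_h`
#' (an optional `replicate` column is kept). Roles must be one of
#' `control`, `dox`, `compound`, `reference`; doses may carry a `uM`
#' suffix. Every plate must contain at least one control and one dox well;
#' duplicate wells on a plate are an error.
#'
#' @param path CSV path.
#' @return validated layout data frame.
#' @export
parse_plate_layout <- function(path) {
  lay <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("plate", "well", "role", "compound_id", "dose_uM", "duration_h")
  miss <- setdiff(need, names(lay))
  if (length(miss)) stop_fs("layout missing columns: %s", paste(miss, collapse = ", "))
  bad_role <- setdiff(unique(lay$role), c("control", "dox", "compound", "reference"))
  if (length(bad_role)) stop_fs("unknown roles: %s", paste(bad_role, collapse = ", "))
  if (is.character(lay$dose_uM))
    lay$dose_uM <- as.numeric(gsub("[^0-9.eE+-]", "", lay$dose_uM))
  if (any(is.na(lay$dose_uM))) stop_fs("unparseable dose_uM values")
  key <- if ("replicate" %in% names(lay))
    paste(lay$replicate, lay$plate, lay$well) else paste(lay$plate, lay$well)
  if (anyDuplicated(key))
    stop_fs("duplicate well(s): %s", paste(unique(key[duplicated(key)]), collapse = "; "))
  plates <- split(lay, if ("replicate" %in% names(lay))
    paste(lay$replicate, lay$plate) else lay$plate)
  bad <- names(plates)[vapply(plates, function(p)
    !any(p$role == "control") || !any(p$role == "dox"), TRUE)]
  if (length(bad))
    stop_fs("plate(s) lacking a control or DOX well: %s", paste(bad, collapse = ", "))
  lay
}

fs_version <- function() {
  as.character(utils::packageVersion("fociscreen"))
}

# hash of the scientific configuration; the output location is excluded so
# identical analyses into different directories share a hash
config_hash <- function(config) {
  tf <- tempfile(fileext = ".txt")
  on.exit(unlink(tf))
  writeLines(deparse(config[setdiff(names(config), "outdir")]), tf)
  unname(tools::md5sum(tf))
}

# CSV with a one-line provenance comment header
write_result_csv <- function(df, path, hash) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# fociscreen %s config_hash=%s", fs_version(), hash), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Read a results CSV written by the pipeline
#' @param path CSV path.
#' @return data frame (provenance comment line skipped).
#' @export
read_result_csv <- function(path) {
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}
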