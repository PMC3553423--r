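#' Write a sampled signal to delimited text
#'
#' One channel per column with a header row of channel names.  The sample
#' rate and start time are carried in a JSON sidecar (`<path>.json`), since
#' delimited text has no standard slot for them.
#'
#' @param x A `sampled_signal`.
#' @param path Output file; `.csv` writes comma-separated, anything else
#'   tab-separated.
#' @param digits Significant digits for the text representation
#'   (default 15, near-lossless for doubles).
#' @return `path`, invisibly.
#' @export
write_timeseries <- function(x, path, digits = 15) {
  stopifnot(inherits(x, "sampled_signal"))
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- as.data.frame(signif(x$values, digits))
  colnames(df) <- colnames(x$values)
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  meta <- list(sample_rate_hz = x$fs, start_time_s = x$start_time,
               n_samples = nrow(x$values), channels = colnames(x$values))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a sampled signal from delimited text
#'
#' Requires the JSON sidecar written by [write_timeseries()] (or any JSON
#' file `<path>.json` with a `sample_rate_hz` field): a sample rate is
#' never guessed.
#'
#' @param path Input file (csv or tsv, header row of channel names).
#' @return A `sampled_signal`.
#' @export
read_timeseries <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  meta_path <- paste0(path, ".json")
  if (!file.exists(meta_path))
    stop("missing sample-rate metadata: expected sidecar ", meta_path)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  if (is.null(meta$sample_rate_hz))
    stop("sidecar ", meta_path, " lacks a 'sample_rate_hz' field")
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE)
  if (nrow(df) == 0L) stop("no samples in ", path)
  st <- if (is.null(meta$start_time_s)) 0 else meta$start_time_s
  sampled_signal(as.matrix(df), fs = meta$sample_rate_hz, start_time = st,
                 channel_names = colnames(df))
}

#' Read / write event markers
#'
#' JSON files hold an array of `{label, time}` objects; any other
#' extension is read as two-column delimited text (label, seconds).
#'
#' @param path File path.
#' @return An `event_markers` object.
#' @export
read_markers <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    df <- jsonlite::read_json(path, simplifyVector = TRUE)
    if (!length(df)) return(event_markers(character(0), numeric(0)))
    event_markers(df$label, df$time)
  } else {
    df <- utils::read.table(path, header = FALSE,
                            col.names = c("label", "time"))
    event_markers(df$label, df$time)
  }
}

#' @rdname read_markers
#' @param markers An `event_markers` object.
#' @export
write_markers <- function(markers, path) {
  df <- as.data.frame(unclass(markers), stringsAsFactors = FALSE)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(df, path, auto_unbox = TRUE, digits = NA)
  } else {
    utils::write.table(df, path, sep = "\t", row.names = FALSE,
                       col.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Read / write sensor geometry
#'
#' Delimited text, one sensor per row: name, x, y, z, ox, oy, oz (meters,
#' unit orientation).
#'
#' @param path File path.
#' @return A `sensor_array`.
#' @export
read_sensors <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE)
  need <- c("name", "x", "y", "z", "ox", "oy", "oz")
  if (!all(need %in% names(df)))
    stop("sensor file must have columns: ", paste(need, collapse = ", "))
  sensor_array(as.matrix(df[, c("x", "y", "z")]),
               as.matrix(df[, c("ox", "oy", "oz")]),
               names = as.character(df$name))
}

#' @rdname read_sensors
#' @param sensors A `sensor_array`.
#' @export
write_sensors <- function(sensors, path) {
  stopifnot(inherits(sensors, "sensor_array"))
  df <- data.frame(name = sensors$names, sensors$positions,
                   sensors$orientations)
  colnames(df) <- c("name", "x", "y", "z", "ox", "oy", "oz")
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Assemble per-voxel values into a functional image
#'
#' @param values N-vector (one value per grid voxel) or N x T matrix for a
#'   time-resolved image.
#' @param grid The `voxel_grid` the values were computed on.
#' @param dt Time step in seconds between volumes (4D only).
#' @return Object of class `functional_image`: the dense 3D (or 4D) array
#'   with off-grid lattice points set to `NA`, plus grid metadata.
#' @export
functional_image <- function(values, grid, dt = NULL) {
  stopifnot(inherits(grid, "voxel_grid"))
  values <- if (is.matrix(values)) values else matrix(values, ncol = 1L)
  if (nrow(values) != nrow(grid$coords))
    stop("one value (row) per grid voxel required")
  nt <- ncol(values)
  arr <- array(NA_real_, c(grid$dims, nt))
  nvol <- prod(grid$dims)
  for (j in seq_len(nt)) arr[grid$index + (j - 1L) * nvol] <- values[, j]
  if (nt == 1L) arr <- array(arr, grid$dims)
  structure(list(data = arr, grid = grid, dt = dt),
            class = "functional_image")
}

#' Write a functional image as NIfTI-1
#'
#' Voxel ordering is x-fastest, matching [voxel_grid()]; the affine stores
#' the grid spacing and origin in millimeters.
#'
#' @param image A `functional_image`.
#' @param path Output `.nii` path.
#' @return `path`, invisibly.
#' @export
write_volume <- function(image, path) {
  stopifnot(inherits(image, "functional_image"))
  g <- image$grid
  sp_mm <- g$spacing * 1000
  affine <- diag(c(sp_mm, sp_mm, sp_mm, 1))
  affine[1:3, 4] <- g$origin * 1000
  arr <- image$data
  arr[is.na(arr)] <- 0
  pix <- c(sp_mm, sp_mm, sp_mm)
  if (length(dim(arr)) == 4L)
    pix <- c(pix, if (is.null(image$dt)) 1 else image$dt)
  img <- RNifti::asNifti(arr)
  img <- RNifti::`sform<-`(img, structure(affine, code = 2L))
  img <- RNifti::`pixdim<-`(img, pix)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI volume back as a plain array
#'
#' @param path `.nii` path.
#' @return Numeric array with a `pixdim` attribute (mm / s).
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  attr(arr, "pixdim") <- RNifti::pixdim(img)
  arr
}
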