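## Directory-based hierarchical array container.
##
## Every interchange object (epochs, leadfield, contact record) is written
## as a directory holding `meta.json` (type, dimensions, sampling
## parameters, provenance hash) plus one flat CSV per array, so any
## language can read the stages' outputs.  Arrays of rank > 2 are stored
## flattened column-major with their dimensions recorded in the metadata.

write_array_csv <- function(x, path) {
  dims <- dim(x) %||% length(x)
  data.table::fwrite(data.table::data.table(value = as.vector(x)), path)
  dims
}

read_array_csv <- function(path, dims) {
  v <- data.table::fread(path)$value
  if (length(dims) > 1L) array(v, dims) else v
}

#' Write an interchange object to a container directory
#'
#' @param x a `sensor_epochs`, `leadfield` or `contact_record`.
#' @param dir target directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_container <- function(x, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  meta <- list(package = "freqtag", hash = object_hash(x))
  if (inherits(x, "sensor_epochs")) {
    meta$type <- "sensor_epochs"
    meta$dims <- dim(x$data)
    meta$sfreq <- x$sfreq; meta$t0 <- x$t0; meta$condition <- x$condition
    if (!is.null(x$side)) meta$side <- as.character(x$side)
    write_array_csv(x$data, file.path(dir, "epochs.csv"))
  } else if (inherits(x, "leadfield")) {
    meta$type <- "leadfield"
    meta$dims <- dim(x$gain)
    meta$spacing <- x$grid$spacing; meta$mode <- x$mode
    meta$side <- as.character(x$side)
    write_array_csv(x$gain, file.path(dir, "gain.csv"))
    write_array_csv(x$grid$positions, file.path(dir, "positions.csv"))
    write_array_csv(x$sensor_positions, file.path(dir, "sensor_positions.csv"))
  } else if (inherits(x, "contact_record")) {
    meta$type <- "contact_record"
    meta$dims <- dim(x$trace)
    meta$sfreq <- x$sfreq; meta$t0 <- x$t0
    meta$region <- x$region; meta$subject_id <- x$subject_id
    meta$condition <- x$condition; meta$mni <- x$mni
    meta$trial_mask <- x$trial_mask
    write_array_csv(x$trace, file.path(dir, "trace.csv"))
  } else stopf("unsupported object of class %s", paste(class(x), collapse = "/"))
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' Read an interchange object from a container directory
#'
#' @param dir directory written by [write_container()].
#' @return the reconstructed object.
#' @export
read_container <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"), simplifyVector = TRUE)
  dims <- as.integer(meta$dims)
  switch(meta$type,
    sensor_epochs = {
      side <- if (!is.null(meta$side))
        factor(meta$side, levels = c("left", "midline", "right")) else NULL
      sensor_epochs(read_array_csv(file.path(dir, "epochs.csv"), dims),
                    sfreq = meta$sfreq, t0 = meta$t0,
                    condition = meta$condition, side = side)
    },
    leadfield = {
      pos <- read_array_csv(file.path(dir, "positions.csv"),
                            c(dims[2L] / 3L, 3L))
      dimnames(pos) <- list(NULL, c("x", "y", "z"))
      grid <- structure(list(positions = pos, spacing = meta$spacing,
                             dims = NA), class = "source_grid")
      structure(list(gain = read_array_csv(file.path(dir, "gain.csv"), dims),
                     grid = grid,
                     sensor_positions = read_array_csv(
                       file.path(dir, "sensor_positions.csv"), c(dims[1L], 3L)),
                     side = factor(meta$side,
                                   levels = c("left", "midline", "right")),
                     mode = meta$mode, seed = NA_integer_),
                class = "leadfield")
    },
    contact_record = {
      structure(list(trace = read_array_csv(file.path(dir, "trace.csv"), dims),
                     sfreq = meta$sfreq, t0 = meta$t0, region = meta$region,
                     mni = meta$mni, subject_id = meta$subject_id,
                     condition = meta$condition,
                     trial_mask = as.logical(meta$trial_mask)),
                class = "contact_record")
    },
    stopf("unknown container type '%s'", meta$type))
}
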