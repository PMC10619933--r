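# File formats: NIfTI volumes for maps and echo images, a serialized
# single-file container for multi-coil k-space, CSV for tables, and the
# plain-text sampling tables (see sampling.R).

#' Write a map or echo-image stack as NIfTI
#'
#' 2D matrices are written as single volumes; 3D stacks (phase x slice x
#' echo/coefficient) as 4D volumes with a singleton third dimension so the
#' series dimension is the NIfTI time axis.
#'
#' @param x numeric matrix or 3D array (complex input: magnitude is
#'   written).
#' @param path output `.nii` / `.nii.gz` path.
#' @param affine optional 4x4 affine (default identity with unit voxels).
#' @return invisibly `path`.
#' @export
write_volume_nifti <- function(x, path, affine = NULL) {
  if (is.complex(x)) x <- Mod(x)
  d <- dim(x)
  arr <- if (length(d) == 2L) array(x, c(d, 1L)) else
    array(x, c(d[1L], d[2L], 1L, d[3L]))
  img <- RNifti::asNifti(arr)
  if (!is.null(affine)) RNifti::`sform<-`(img, structure(affine, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI volume written by [write_volume_nifti()]
#'
#' @param path NIfTI file path.
#' @return numeric matrix (single volume) or 3D array (series), with the
#'   singleton third dimension dropped.
#' @export
read_volume_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  attributes(arr) <- list(dim = dim(arr))   # plain array, no NIfTI metadata
  d <- dim(arr)
  if (length(d) == 4L && d[3L] == 1L) {
    arr <- array(arr, c(d[1L], d[2L], d[4L]))
  } else if (length(d) == 3L && d[3L] == 1L) {
    arr <- matrix(arr, d[1L], d[2L])
  }
  arr
}

# container schema: named elements that must be present
.kspace_container_names <- c("data", "mask", "echo_times")

#' Save a k-space dataset to a single-file container
#'
#' Serializes the named datasets (`data`, `mask`, `echo_times`, optionally
#' `coil_maps` and a `config` provenance blob) together with an md5
#' checksum of the payload, which is verified on load.
#'
#' @param kspace a [kspace_data()] object.
#' @param path output file path.
#' @param coil_maps optional [coil_maps()] stored alongside.
#' @param config optional configuration list stored as provenance.
#' @return invisibly `path`.
#' @export
save_kspace <- function(kspace, path, coil_maps = NULL, config = NULL) {
  payload <- list(data = kspace$data, mask = kspace$mask,
                  echo_times = kspace$echo_times)
  if (!is.null(coil_maps)) payload$coil_maps <- coil_maps
  if (!is.null(config)) {
    payload$config <- jsonlite::toJSON(config, auto_unbox = TRUE,
                                       digits = NA, force = TRUE)
  }
  blob <- serialize(payload, NULL, version = 2L)
  container <- list(format = "calipr-kspace-v1",
                    md5 = .blob_md5(blob), payload = blob)
  saveRDS(container, path, version = 2L)
  invisible(path)
}

.blob_md5 <- function(blob) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeBin(blob, tf)
  unname(tools::md5sum(tf))
}

#' Load a k-space dataset from a container file
#'
#' Verifies the payload checksum and the presence of every required
#' dataset.
#'
#' @param path file written by [save_kspace()].
#' @return list with `kspace` (a [kspace_data()]), and `coil_maps`,
#'   `config` when present.
#' @export
load_kspace <- function(path) {
  container <- tryCatch(readRDS(path), error = function(e) {
    stop(sprintf("corrupt or truncated container '%s': %s", path,
                 conditionMessage(e)))
  })
  if (!is.list(container) ||
      !identical(container$format, "calipr-kspace-v1")) {
    stop("not a k-space container file")
  }
  if (!identical(.blob_md5(container$payload), container$md5)) {
    stop("container checksum mismatch: file is corrupt")
  }
  payload <- unserialize(container$payload)
  missing <- setdiff(.kspace_container_names, names(payload))
  if (length(missing) > 0L) {
    stop(sprintf("container missing dataset(s): %s",
                 paste(missing, collapse = ", ")))
  }
  out <- list(kspace = kspace_data(payload$data, payload$mask,
                                   payload$echo_times))
  if (!is.null(payload$coil_maps)) out$coil_maps <- payload$coil_maps
  if (!is.null(payload$config)) {
    out$config <- jsonlite::fromJSON(payload$config)
  }
  out
}

#' Reference MESE myelin-water protocols
#'
#' Acquisition parameters of the three protocols discussed throughout the
#' package: the in vivo brain protocol, the in vivo cervical spinal cord
#' protocol, and the fixed-brain reference acquisition used for
#' retrospective validation.  Times are the fully sampled and accelerated
#' acquisition durations in seconds.
#'
#' @return data frame with one row per protocol.
#' @export
mwi_protocols <- function() {
  data.frame(
    protocol = c("brain", "cord", "fixed_brain_reference"),
    n_phase = c(118L, 152L, 113L),
    n_slice = c(59L, 12L, 59L),
    n_echoes = c(56L, 48L, 56L),
    delta_te = c(6.0, 8.0, 5.6),
    full_seconds = c(2 * 3600 + 57 * 60 + 20,   # 2:57:20
                     45 * 60 + 27,              # 45:27
                     2 * 3600 + 47 * 60 + 25),  # 2:47:25
    accel_seconds = c(7 * 60 + 26,              # 7:26
                      8 * 60 + 23,              # 8:23
                      2 * 3600 + 8 * 60 + 10),  # 2:08:10
    lambda = c(0.004, 0.001, 0.004),
    stringsAsFactors = FALSE
  )
}

#' Acceleration factor implied by acquisition times
#'
#' @param full_seconds fully sampled acquisition duration (s).
#' @param accel_seconds accelerated acquisition duration (s).
#' @return ratio `full_seconds / accel_seconds`.
#' @export
protocol_acceleration <- function(full_seconds, accel_seconds) {
  stopifnot(full_seconds > 0, accel_seconds > 0)
  full_seconds / accel_seconds
}
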