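#' Multi-channel image stack with physical spacing and channel roles
#'
#' The universal input container: a named list of numeric arrays (one per
#' channel), each `[x, y]` for a single optical section or `[x, y, z]` for a
#' stack, together with the voxel spacing in micrometres. Channel names are
#' their biological roles, e.g. `"dna"`, `"tubulin"`, `"cortical"`.
#'
#' Coordinate conventions (used throughout the package): x is lateral, y runs
#' from the apical (ventricular) surface toward the pial side, z is the
#' optical (sectioning) axis. Voxel `(i, j, k)` is centred at
#' `((i - 0.5) * dx, (j - 0.5) * dy, (k - 0.5) * dz)` um.
#'
#' @param channels named list of numeric arrays, all with identical
#'   dimensions (`[x, y]` or `[x, y, z]`).
#' @param spacing numeric vector of voxel spacing in um, `c(x, y)` or
#'   `c(x, y, z)`.
#' @param metadata optional list of free-form metadata (e.g. the apical
#'   surface annotation).
#' @return An object of class `"image_stack"`.
#' @export
image_stack <- function(channels, spacing, metadata = list()) {
  if (!length(channels) || is.null(names(channels)) || any(names(channels) == ""))
    stop("'channels' must be a non-empty named list")
  dims <- lapply(channels, dim)
  if (any(vapply(dims, is.null, logical(1))))
    stop("each channel must be a matrix or array")
  d1 <- dims[[1]]
  if (!all(vapply(dims, function(d) identical(d, d1), logical(1))))
    stop("all channels must share the same dimensions")
  nd <- length(d1)
  if (!nd %in% c(2L, 3L)) stop("channels must be 2D [x, y] or 3D [x, y, z]")
  spacing <- as.numeric(spacing)
  if (length(spacing) != nd || any(spacing <= 0))
    stop("'spacing' must be ", nd, " positive values (um per voxel)")
  names(spacing) <- c("x", "y", "z")[seq_len(nd)]
  structure(list(channels = channels, spacing = spacing, metadata = metadata),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat("<image_stack> ", paste(d, collapse = " x "), " voxels, ",
      length(x$channels), " channel(s): ",
      paste(names(x$channels), collapse = ", "), "\n", sep = "")
  cat("  spacing (um): ", paste(signif(x$spacing, 3), collapse = " x "),
      "\n", sep = "")
  invisible(x)
}

#' Extract one channel of an image stack
#'
#' @param stack an [image_stack()].
#' @param role channel role name.
#' @param z optional section index; for a 3D stack returns that 2D section.
#' @return A numeric matrix (or 3D array when `z` is `NULL` and the stack
#'   is 3D).
#' @export
get_channel <- function(stack, role, z = NULL) {
  stopifnot(inherits(stack, "image_stack"))
  if (!role %in% names(stack$channels))
    stop("channel role '", role, "' not present (have: ",
         paste(names(stack$channels), collapse = ", "), ")")
  ch <- stack$channels[[role]]
  if (is.null(z)) return(ch)
  if (length(dim(ch)) == 2L) {
    if (z != 1L) stop("2D stack has only section 1")
    return(ch)
  }
  ch[, , z]
}

#' Maximum-intensity projection of a channel along z
#'
#' @inheritParams get_channel
#' @return A numeric matrix `[x, y]`.
#' @export
max_project <- function(stack, role) {
  ch <- get_channel(stack, role)
  if (length(dim(ch)) == 2L) return(ch)
  apply(ch, c(1, 2), max)
}

#' Write an image stack as multi-page TIFF plus a JSON sidecar
#'
#' Pages are written channel-major then z (`channel 1 z1, channel 1 z2, ...`),
#' as 32-bit float; the sidecar records channel roles, page order, spacing
#' and metadata so the stack round-trips losslessly.
#'
#' @param stack an [image_stack()].
#' @param path output TIFF path; the sidecar is written at `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  d <- dim(stack$channels[[1]])
  nz <- if (length(d) == 3L) d[3] else 1L
  pages <- list()
  for (ch in names(stack$channels)) {
    for (k in seq_len(nz)) {
      sec <- get_channel(stack, ch, z = if (length(d) == 3L) k else 1L)
      # tiff expects [row = y, col = x]
      pages[[length(pages) + 1L]] <- t(sec)
    }
  }
  mx <- max(vapply(pages, max, numeric(1)), 1e-12)
  tiff::writeTIFF(lapply(pages, function(p) p / mx), path,
                  bits.per.sample = 32L)
  sidecar <- list(
    channels = names(stack$channels), n_z = nz,
    page_order = "channel-major, z within channel",
    spacing_um = as.list(stack$spacing),
    intensity_scale = mx,
    metadata = stack$metadata)
  jsonlite::write_json(sidecar, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read an image stack written by [write_stack()]
#'
#' @param path TIFF path with a `<path>.json` sidecar next to it.
#' @return An [image_stack()].
#' @export
read_stack <- function(path) {
  sidecar <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  nz <- sidecar$n_z
  chans <- list()
  i <- 0L
  for (ch in sidecar$channels) {
    secs <- lapply(seq_len(nz), function(k) t(pages[[i + k]]) * sidecar$intensity_scale)
    i <- i + nz
    chans[[ch]] <- if (nz == 1L) secs[[1]] else
      array(unlist(secs), dim = c(dim(secs[[1]]), nz))
  }
  spacing <- unlist(sidecar$spacing_um)
  md <- sidecar$metadata
  if (is.null(md)) md <- list()
  image_stack(chans, spacing, metadata = as.list(md))
}
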