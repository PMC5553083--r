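# Stack containers and TIFF I/O.
#
# Axis convention throughout the package: a stack's `values` is a 3-D
# array indexed [x, y, z].  A TIFF page is a matrix [row = y, col = x],
# so pages are transposed on the way in and out; pages are stored
# z-ascending, one per slice.

#' Photon-count encoded stack
#'
#' Container for an integer-encoded confocal stack together with its
#' photon scale: `photons_per_code` photons correspond to one intensity
#' unit.  In the standard 8-bit photon-counting convention, code 255
#' corresponds to 4 photons, i.e. `photons_per_code = 4/255`.
#'
#' @param values 3-D array (or matrix for a single slice) of non-negative
#'   integers within the bit-depth range, indexed \[x, y, z\].
#' @param photons_per_code Photons per intensity code unit (> 0).
#' @param bit_depth 8 or 16.
#' @return An object of class `encoded_stack`.
#' @export
encoded_stack <- function(values, photons_per_code, bit_depth = 8L) {
  bit_depth <- as.integer(bit_depth)
  if (!bit_depth %in% c(8L, 16L)) stop("bit_depth must be 8 or 16", call. = FALSE)
  stop_if_not_positive(photons_per_code, "photons_per_code")
  v <- as.array(values)
  if (length(dim(v)) == 2L) dim(v) <- c(dim(v), 1L)
  if (any(v < 0) || any(v != round(v))) {
    stop("encoded values must be non-negative integers", call. = FALSE)
  }
  if (any(v > 2^bit_depth - 1)) {
    stop("encoded values exceed the bit-depth range", call. = FALSE)
  }
  storage.mode(v) <- "integer"
  structure(
    list(values = v, photons_per_code = as.numeric(photons_per_code),
         bit_depth = bit_depth),
    class = "encoded_stack"
  )
}

#' @export
print.encoded_stack <- function(x, ...) {
  d <- dim3(x$values)
  cat(sprintf(
    "%d-bit encoded stack %d x %d x %d, %.6g photons per code (full scale %.6g photons)\n",
    x$bit_depth, d[1], d[2], d[3], x$photons_per_code,
    x$photons_per_code * (2^x$bit_depth - 1)
  ))
  cat(sprintf("  code range %d..%d, total %.6g photons\n",
              min(x$values), max(x$values), sum(x$values) * x$photons_per_code))
  invisible(x)
}

#' Decode an encoded stack to expected photon units
#'
#' @param stack An `encoded_stack`.
#' @return A numeric 3-D array of photon values (`code * photons_per_code`).
#' @export
as_photons <- function(stack) {
  stopifnot(inherits(stack, "encoded_stack"))
  stack$values * stack$photons_per_code
}

# ---- sidecar provenance files ------------------------------------------

sidecar_path <- function(path) paste0(path, ".meta")

write_sidecar <- function(path, fields) {
  lines <- vapply(
    names(fields),
    function(k) paste0(k, ": ", as.character(fields[[k]])),
    character(1)
  )
  writeLines(lines, sidecar_path(path))
  invisible(sidecar_path(path))
}

read_sidecar <- function(path) {
  sp <- sidecar_path(path)
  if (!file.exists(sp)) return(NULL)
  lines <- readLines(sp)
  lines <- lines[nzchar(lines)]
  kv <- regmatches(lines, regexpr(": ", lines), invert = TRUE)
  out <- lapply(kv, `[`, 2)
  names(out) <- vapply(kv, `[`, character(1), 1)
  out
}

# ---- stack TIFF I/O ----------------------------------------------------

#' Read / write photon-count stacks as multi-page TIFF
#'
#' Grayscale single-channel multi-page TIFF, one page per z-slice,
#' z-ascending, uniform 8- or 16-bit depth.  The photon scale is stored
#' in a plain-text sidecar `<path>.meta` (so the TIFF stays openable in
#' any viewer); when the sidecar is missing, `read_stack` falls back to
#' the photon-counting convention for the bit depth: `4/255` photons per code for
#' 8-bit and `4/(255*256)` for 16-bit.
#'
#' Output bytes are deterministic for identical input (fixed tag set, no
#' timestamps), so provenance checksums are meaningful.
#'
#' @param stack An `encoded_stack`.
#' @param path TIFF file path.
#' @param extra Optional named list of extra sidecar fields (provenance).
#' @return `write_stack` returns `path` invisibly; `read_stack` returns
#'   an `encoded_stack`.
#' @export
write_stack <- function(stack, path, extra = NULL) {
  stopifnot(inherits(stack, "encoded_stack"))
  d <- dim3(stack$values)
  maxcode <- 2^stack$bit_depth - 1
  pages <- lapply(seq_len(d[3]), function(iz) t(stack$values[, , iz]) / maxcode)
  tiff::writeTIFF(pages, path, bits.per.sample = stack$bit_depth)
  fields <- c(
    list(kind = "encoded_stack",
         bit_depth = stack$bit_depth,
         photons_per_code = format(stack$photons_per_code, digits = 17)),
    extra
  )
  write_sidecar(path, fields)
  invisible(path)
}

#' @rdname write_stack
#' @export
read_stack <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  info <- tiff::readTIFF(path, payload = FALSE, all = TRUE)
  if (is.data.frame(info)) info <- split(info, seq_len(nrow(info)))
  depths <- vapply(info, function(p) as.integer(p$bits.per.sample[[1]]), integer(1))
  if (length(depths) == 0L) stop("TIFF contains no pages", call. = FALSE)
  if (length(unique(depths)) != 1L) stop("mixed bit depths in TIFF", call. = FALSE)
  bit_depth <- depths[1]
  if (!bit_depth %in% c(8L, 16L)) {
    stop("unsupported bit depth for a photon-count stack: ", bit_depth, call. = FALSE)
  }
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  d <- c(ncol(pages[[1]]), nrow(pages[[1]]), length(pages))
  vol <- array(0L, dim = d)
  for (iz in seq_along(pages)) vol[, , iz] <- as.integer(t(pages[[iz]]))
  meta <- read_sidecar(path)
  ppc <- if (!is.null(meta$photons_per_code)) {
    as.numeric(meta$photons_per_code)
  } else if (bit_depth == 8L) 4 / 255 else 4 / (255 * 256)
  encoded_stack(vol, ppc, bit_depth)
}

#' Promote an 8-bit photon-count stack to scaled 16-bit
#'
#' The format step used before Gaussian blurring of real photon-counting
#' data: every 8-bit code is multiplied by exactly 256 (so the typical
#' 0/1/2-photon codes become 0, 256, 512 at the default scale), leaving
#' integer headroom for the blur's intermediate values.  The photon
#' scale is divided by 256, so the physical photon value of every voxel
#' is unchanged.  The maximum possible value, 255 * 256 = 65280, fits in
#' 16 bits.
#'
#' @param stack An 8-bit `encoded_stack`.
#' @return A 16-bit `encoded_stack`.
#' @export
promote_16bit <- function(stack) {
  stopifnot(inherits(stack, "encoded_stack"))
  if (stack$bit_depth != 8L) stop("input must be 8-bit", call. = FALSE)
  encoded_stack(stack$values * 256L, stack$photons_per_code / 256, 16L)
}
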