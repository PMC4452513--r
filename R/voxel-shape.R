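#' Voxel shape: one timepoint of a root reconstruction
#'
#' A voxel shape is a finite set of unit cubes on an integer grid together
#' with the physical edge length of one voxel (mm) and the acquisition
#' index of the timepoint. Voxel centers sit at `coords * edge_length` in
#' physical space; the z axis points up (gravity is -z).
#'
#' @param coords integer matrix (n x 3) of voxel grid coordinates; duplicate
#'   rows are collapsed and rows are stored in lexicographic order.
#' @param edge_length physical edge of one voxel in mm (> 0).
#' @param time_index integer acquisition index (>= 0).
#' @return an object of class `voxel_shape` with elements `voxels`
#'   (integer matrix, canonical order), `edge_length`, `time_index`.
#' @examples
#' sh <- voxel_shape(rbind(c(0, 0, 0), c(0, 0, 1)), edge_length = 0.5)
#' n_voxels(sh)
#' @export
voxel_shape <- function(coords, edge_length, time_index = 0L) {
  coords <- as.matrix(coords)
  if (nrow(coords) == 0L) stop("empty shape")
  if (ncol(coords) != 3L) stop("coords must have three columns")
  if (!is.numeric(edge_length) || length(edge_length) != 1L ||
      is.na(edge_length) || edge_length <= 0) {
    stop("edge_length must be a single positive number (mm)")
  }
  storage.mode(coords) <- "integer"
  if (anyNA(coords)) stop("coords contain missing values")
  coords <- unique(coords)
  coords <- coords[order(coords[, 1L], coords[, 2L], coords[, 3L]), ,
                   drop = FALSE]
  dimnames(coords) <- list(NULL, c("x", "y", "z"))
  structure(
    list(voxels = coords, edge_length = edge_length,
         time_index = as.integer(time_index)),
    class = "voxel_shape"
  )
}

#' @export
print.voxel_shape <- function(x, ...) {
  cat(sprintf("<voxel_shape> %d voxels, edge %.4g mm, t = %d\n",
              nrow(x$voxels), x$edge_length, x$time_index))
  invisible(x)
}

#' Number of voxels in a shape
#' @param shape a `voxel_shape`.
#' @return integer voxel count.
#' @export
n_voxels <- function(shape) nrow(shape$voxels)

#' Voxel centers in physical coordinates (mm)
#' @param shape a `voxel_shape`.
#' @return numeric matrix (n x 3) of voxel centers in mm.
#' @export
voxel_centers <- function(shape) shape$voxels * shape$edge_length

#' Read a voxel shape from file
#'
#' Two dialects are supported. Dialect A is plain text: one `x y z` integer
#' triple per line, whitespace separated, `#` starts a comment. Dialect B
#' is a dense binary mask in NIfTI format (any standard raster volume
#' viewer can open it); nonzero cells become voxels. The dialect is chosen
#' from the file extension (`.nii` / `.nii.gz` for NIfTI, anything else is
#' text).
#'
#' @param path file to read.
#' @param edge_length voxel edge in mm.
#' @param time_index acquisition index of this shape.
#' @return a [voxel_shape()]; duplicates are collapsed.
#' @export
read_voxel_shape <- function(path, edge_length, time_index = 0L) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) {
    vol <- RNifti::readNifti(path)
    arr <- as.array(vol)
    idx <- which(arr != 0, arr.ind = TRUE)
    if (nrow(idx) == 0L) stop("empty shape")
    # array indices are 1-based; grid coordinates are 0-based
    return(voxel_shape(idx - 1L, edge_length, time_index))
  }
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  keep <- which(!grepl("^\\s*$", lines))
  if (length(keep) == 0L) stop("empty shape")
  parsed <- lapply(keep, function(i) {
    toks <- strsplit(trimws(lines[[i]]), "\\s+")[[1L]]
    vals <- suppressWarnings(as.numeric(toks))
    if (length(vals) != 3L || anyNA(vals) || any(vals != round(vals))) {
      stop(sprintf("malformed voxel line %d: '%s'", i, lines[[i]]))
    }
    vals
  })
  voxel_shape(do.call(rbind, parsed), edge_length, time_index)
}

#' Write a voxel shape to file
#'
#' The inverse of [read_voxel_shape()]; the dialect follows the file
#' extension (`.nii` / `.nii.gz` writes a dense NIfTI mask, anything else
#' the text dialect).
#'
#' @param shape a `voxel_shape`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_voxel_shape <- function(shape, path) {
  v <- shape$voxels
  if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) {
    off <- apply(v, 2L, min)
    rel <- sweep(v, 2L, off) + 1L
    dims <- apply(rel, 2L, max)
    arr <- array(0L, dim = dims)
    arr[rel] <- 1L
    img <- RNifti::asNifti(arr, pixdim = rep(shape$edge_length, 3L))
    RNifti::writeNifti(img, path)
  } else {
    writeLines(sprintf("%d %d %d", v[, 1L], v[, 2L], v[, 3L]), path)
  }
  invisible(path)
}

#' Time-series of voxel shapes
#'
#' @param shapes list of `voxel_shape` objects; their `time_index` values
#'   must be strictly increasing (they are renumbered 0..T in order).
#' @return object of class `time_series` with elements `shapes` and `T`.
#' @export
time_series <- function(shapes) {
  if (length(shapes) == 0L) stop("empty time-series")
  stopifnot(all(vapply(shapes, inherits, logical(1L), "voxel_shape")))
  ti <- vapply(shapes, `[[`, integer(1L), "time_index")
  if (any(diff(ti) <= 0) && length(ti) > 1L) {
    stop("time_index values must be strictly increasing")
  }
  edges <- vapply(shapes, `[[`, numeric(1L), "edge_length")
  if (length(unique(edges)) != 1L) {
    stop("all shapes must share one edge_length")
  }
  for (i in seq_along(shapes)) shapes[[i]]$time_index <- i - 1L
  structure(list(shapes = shapes, T = length(shapes) - 1L),
            class = "time_series")
}

#' @export
print.time_series <- function(x, ...) {
  cat(sprintf("<time_series> T = %d (%d shapes), edge %.4g mm\n", x$T,
              length(x$shapes), x$shapes[[1L]]$edge_length))
  invisible(x)
}

# linear key of voxel coordinates for O(1) membership tests;
# box must contain all query coordinates
vox_key <- function(coords, box) {
  (coords[, 1L] - box$lo[1L]) +
    (coords[, 2L] - box$lo[2L]) * box$n[1L] +
    (coords[, 3L] - box$lo[3L]) * (box$n[1L] * box$n[2L])
}

vox_box <- function(coords, pad = 0L) {
  # numeric so key arithmetic stays in double (no integer overflow)
  lo <- as.numeric(apply(coords, 2L, min)) - pad
  hi <- as.numeric(apply(coords, 2L, max)) + pad
  list(lo = lo, n = hi - lo + 1)
}
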