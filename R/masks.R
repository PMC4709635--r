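# Binary lesion masks on a regular 3-D voxel grid.

#' Construct a lesion mask
#'
#' A lesion mask is a 3-D binary voxel array plus the voxel dimensions in mm
#' and the world-space position of the first voxel. World coordinates of
#' voxel (i, j, k) are \code{origin + (c(i, j, k) - 1) * voxel_size_mm}
#' (axis-aligned affine; no rotation).
#'
#' @param grid 3-D array; nonzero entries mark lesioned voxels.
#' @param voxel_size_mm Voxel edge lengths in mm (length 3, > 0).
#' @param origin World-space mm coordinates of voxel (1, 1, 1).
#' @return An object of class \code{lesion_mask}.
#' @export
lesion_mask <- function(grid, voxel_size_mm = c(1, 1, 1),
                        origin = c(0, 0, 0)) {
  if (!is.array(grid) || length(dim(grid)) != 3L)
    stop("'grid' must be a 3-D array", call. = FALSE)
  if (any(is.na(grid))) stop("'grid' must not contain NA", call. = FALSE)
  if (!is.numeric(voxel_size_mm) || length(voxel_size_mm) != 3L ||
      any(voxel_size_mm <= 0))
    stop("'voxel_size_mm' must be 3 positive reals", call. = FALSE)
  if (!is.numeric(origin) || length(origin) != 3L)
    stop("'origin' must be length 3", call. = FALSE)
  g <- array(as.integer(grid != 0), dim = dim(grid))
  structure(list(grid = g, voxel_size_mm = as.numeric(voxel_size_mm),
                 origin = as.numeric(origin)),
            class = "lesion_mask")
}

#' @export
print.lesion_mask <- function(x, ...) {
  cat(sprintf("<lesion_mask> %s voxels of %s mm, %d lesioned (%.2f cc)\n",
              paste(dim(x$grid), collapse = "x"),
              paste(x$voxel_size_mm, collapse = "x"),
              sum(x$grid), lesion_volume(x)))
  invisible(x)
}

#' Lesion volume in cubic centimetres
#'
#' Voxel count times voxel volume in mm^3, divided by 1000.
#'
#' @param mask A \code{\link{lesion_mask}}.
#' @return Volume in cc.
#' @export
lesion_volume <- function(mask) {
  stopifnot(inherits(mask, "lesion_mask"))
  sum(mask$grid) * prod(mask$voxel_size_mm) / 1000
}

check_mask_list <- function(masks) {
  if (length(masks) == 0L) stop("empty mask list", call. = FALSE)
  if (!all(vapply(masks, inherits, TRUE, "lesion_mask")))
    stop("all elements must be lesion_mask objects", call. = FALSE)
  dims <- vapply(masks, function(m) dim(m$grid), integer(3))
  if (any(dims != dims[, 1L]))
    stop("masks must share one grid shape", call. = FALSE)
  invisible(masks)
}

#' Lesion overlap map
#'
#' Voxelwise count of how many masks lesion each voxel (the quantity shown
#' by lesion-overlap figures: max <= number of patients).
#'
#' @param masks List of \code{\link{lesion_mask}} objects on one grid.
#' @return Integer 3-D array of counts, with attributes \code{voxel_size_mm}
#'   and \code{origin} taken from the first mask.
#' @export
overlap_map <- function(masks) {
  check_mask_list(masks)
  counts <- Reduce(`+`, lapply(masks, `[[`, "grid"))
  attr(counts, "voxel_size_mm") <- masks[[1L]]$voxel_size_mm
  attr(counts, "origin") <- masks[[1L]]$origin
  counts
}

#' Write / read a lesion mask as plain-text sparse coordinates
#'
#' One header line records grid shape, voxel size and origin; the body is a
#' CSV of 1-based voxel indices of lesioned voxels. A text stand-in for
#' binary volume formats so cohorts round-trip through ordinary files.
#'
#' @param mask A \code{\link{lesion_mask}}.
#' @param path File path.
#' @return \code{write_mask_csv} returns \code{path} invisibly;
#'   \code{read_mask_csv} returns the reconstructed \code{lesion_mask}.
#' @export
write_mask_csv <- function(mask, path) {
  stopifnot(inherits(mask, "lesion_mask"))
  hdr <- sprintf("# dims=%s voxel_size_mm=%s origin=%s",
                 paste(dim(mask$grid), collapse = ","),
                 paste(mask$voxel_size_mm, collapse = ","),
                 paste(mask$origin, collapse = ","))
  idx <- which(mask$grid != 0L, arr.ind = TRUE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(hdr, "i,j,k"), con)
  if (nrow(idx))
    writeLines(paste(idx[, 1L], idx[, 2L], idx[, 3L], sep = ","), con)
  invisible(path)
}

#' @rdname write_mask_csv
#' @export
read_mask_csv <- function(path) {
  hdr <- readLines(path, n = 1L)
  fields <- regmatches(hdr, gregexpr("[a-z_]+=[-0-9.,]+", hdr))[[1L]]
  kv <- lapply(strsplit(fields, "="), function(f)
    as.numeric(strsplit(f[2L], ",")[[1L]]))
  names(kv) <- vapply(strsplit(fields, "="), `[[`, "", 1L)
  dims <- as.integer(kv$dims)
  grid <- array(0L, dim = dims)
  body <- utils::read.csv(path, comment.char = "#")
  if (nrow(body))
    grid[cbind(body$i, body$j, body$k)] <- 1L
  lesion_mask(grid, kv$voxel_size_mm, kv$origin)
}

# voxel index matrix (n x 3) -> world mm coordinates
voxel_to_world <- function(idx, voxel_size_mm, origin) {
  idx <- matrix(as.numeric(idx), ncol = 3L)
  sweep(sweep(idx - 1, 2L, voxel_size_mm, `*`), 2L, origin, `+`)
}
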