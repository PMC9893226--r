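#' A 3-D scalar volume on a regular grid
#'
#' Light-weight container for probabilistic network maps and binary lesion
#' masks: a 3-D array plus voxel dimensions (mm) and a 4x4 affine. Probability
#' grids must lie in \[0, 1\]; binary grids in {0, 1}.
#'
#' @param data 3-D numeric array.
#' @param voxel_dims numeric triple of voxel edge lengths in mm (> 0).
#' @param affine 4x4 spatial transform; defaults to `diag(c(voxel_dims, 1))`.
#' @param kind `"probability"` or `"binary"`.
#' @return an object of class `volume_grid`.
#' @export
volume_grid <- function(data, voxel_dims, affine = NULL,
                        kind = c("probability", "binary")) {
  kind <- match.arg(kind)
  if (!is.array(data) || length(dim(data)) != 3L) {
    stop("data must be a 3-D array", call. = FALSE)
  }
  if (length(voxel_dims) != 3L || any(!is.finite(voxel_dims)) ||
      any(voxel_dims <= 0)) {
    stop("voxel_dims must be three positive numbers", call. = FALSE)
  }
  if (is.null(affine)) affine <- diag(c(voxel_dims, 1))
  if (!is.matrix(affine) || !all(dim(affine) == c(4L, 4L))) {
    stop("affine must be a 4x4 matrix", call. = FALSE)
  }
  if (anyNA(data)) stop("data contains NA", call. = FALSE)
  if (kind == "probability" && (min(data) < 0 || max(data) > 1)) {
    stop("probability grid values must lie in [0, 1]", call. = FALSE)
  }
  if (kind == "binary" && !all(data %in% c(0, 1))) {
    stop("binary grid values must be 0 or 1", call. = FALSE)
  }
  structure(list(data = data, voxel_dims = as.numeric(voxel_dims),
                 affine = affine, kind = kind),
            class = "volume_grid")
}

#' @export
print.volume_grid <- function(x, ...) {
  cat("<volume_grid>", x$kind, paste(dim(x$data), collapse = "x"),
      "voxels of", paste(x$voxel_dims, collapse = "x"), "mm\n")
  invisible(x)
}

#' Threshold a probabilistic network map
#'
#' Retains voxels whose activation-overlap proportion is at least the
#' threshold (inclusive comparison: "present for at least 5% of contributing
#' participants"), producing the binary network mask used for lesion-overlap
#' volumes.
#'
#' @param prob_map a probability [volume_grid()].
#' @param threshold retention threshold in (0, 1]; default 0.05.
#' @return a binary `volume_grid` on the same grid.
#' @examples
#' v <- volume_grid(array(runif(8), c(2, 2, 2)), c(1, 1, 1))
#' m <- threshold_map(v, 0.5)
#' @export
threshold_map <- function(prob_map, threshold = 0.05) {
  stopifnot(inherits(prob_map, "volume_grid"))
  if (prob_map$kind != "probability") {
    stop("threshold_map expects a probability grid", call. = FALSE)
  }
  stop_if_not_scalar_finite(threshold, "threshold")
  if (threshold <= 0 || threshold > 1) {
    stop("threshold must lie in (0, 1]", call. = FALSE)
  }
  volume_grid((prob_map$data >= threshold) * 1, prob_map$voxel_dims,
              prob_map$affine, kind = "binary")
}

#' Lesion volume inside a network mask
#'
#' Voxelwise intersection of a binary lesion mask with a binary network mask.
#' Both grids must share shape, voxel dimensions and affine (within 1e-4 mm);
#' no resampling is performed — silent interpolation corrupts volumes, so a
#' mismatch is an error naming the offending attribute. Volumes are reported
#' in cm^3.
#'
#' @param lesion,network binary [volume_grid()]s on an identical grid.
#' @return list with `n_overlap_voxels`, `overlap_volume`, `network_volume`,
#'   `lesion_volume` (cm^3), `proportion_network_damaged`,
#'   `proportion_lesion_in_network`.
#' @export
lesion_overlap <- function(lesion, network) {
  stopifnot(inherits(lesion, "volume_grid"), inherits(network, "volume_grid"))
  if (lesion$kind != "binary" || network$kind != "binary") {
    stop("lesion_overlap expects binary grids", call. = FALSE)
  }
  if (!identical(dim(lesion$data), dim(network$data))) {
    stop("grid mismatch: shape differs between lesion and network",
         call. = FALSE)
  }
  if (max(abs(lesion$voxel_dims - network$voxel_dims)) > 1e-4) {
    stop("grid mismatch: voxel_dims differ between lesion and network",
         call. = FALSE)
  }
  if (max(abs(lesion$affine - network$affine)) > 1e-4) {
    stop("grid mismatch: affine differs between lesion and network",
         call. = FALSE)
  }
  voxel_cm3 <- prod(lesion$voxel_dims) / 1000
  n_overlap <- sum(lesion$data == 1 & network$data == 1)
  n_network <- sum(network$data == 1)
  n_lesion <- sum(lesion$data == 1)
  list(
    n_overlap_voxels = n_overlap,
    overlap_volume = n_overlap * voxel_cm3,
    network_volume = n_network * voxel_cm3,
    lesion_volume = n_lesion * voxel_cm3,
    proportion_network_damaged = if (n_network > 0) n_overlap / n_network else NA_real_,
    proportion_lesion_in_network = if (n_lesion > 0) n_overlap / n_lesion else NA_real_
  )
}

#' Per-participant lesion-overlap table
#'
#' Convenience wrapper: thresholds each probabilistic map and intersects every
#' lesion mask with each resulting network mask.
#'
#' @param lesion_masks named list of binary [volume_grid()]s.
#' @param prob_map_lang,prob_map_md probability grids for the two networks.
#' @param threshold map threshold passed to [threshold_map()].
#' @return data.frame with columns `id`, `lesion_vol_lang`, `lesion_vol_md`,
#'   `lesion_vol_total` (cm^3).
#' @export
lesion_volume_table <- function(lesion_masks, prob_map_lang, prob_map_md,
                                threshold = 0.05) {
  net_lang <- threshold_map(prob_map_lang, threshold)
  net_md <- threshold_map(prob_map_md, threshold)
  rows <- lapply(names(lesion_masks), function(id) {
    ol <- lesion_overlap(lesion_masks[[id]], net_lang)
    om <- lesion_overlap(lesion_masks[[id]], net_md)
    data.frame(id = id,
               lesion_vol_lang = ol$overlap_volume,
               lesion_vol_md = om$overlap_volume,
               lesion_vol_total = ol$lesion_volume,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
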