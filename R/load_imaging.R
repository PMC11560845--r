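#' A 3D fluorescence voxel stack
#'
#' Wraps a non-negative 3D intensity array (dimensions ordered z, y, x)
#' together with the physical voxel size, for quantification of
#' intracellular bacterial load as above-threshold voxel volume.
#'
#' @param intensities 3D numeric array `(z, y, x)` of non-negative
#'   intensities.
#' @param voxel_dims Length-3 positive numeric: physical voxel size in
#'   micrometres along (z, y, x). Typical confocal stacks are anisotropic,
#'   e.g. `c(0.2, 0.1, 0.1)`.
#' @return An object of class `"voxel_stack"`.
#' @export
voxel_stack <- function(intensities, voxel_dims) {
  if (!is.array(intensities) || length(dim(intensities)) != 3L)
    stop("'intensities' must be a 3D array (z, y, x)", call. = FALSE)
  if (any(dim(intensities) < 1L))
    stop("all stack dimensions must be >= 1", call. = FALSE)
  if (anyNA(intensities) || any(intensities < 0))
    stop("intensities must be non-negative and free of NA", call. = FALSE)
  if (!is.numeric(voxel_dims) || length(voxel_dims) != 3L ||
      any(voxel_dims <= 0))
    stop("'voxel_dims' must be 3 strictly positive sizes (z, y, x) in um",
         call. = FALSE)
  structure(list(intensities = intensities, voxel_dims = as.numeric(voxel_dims)),
            class = "voxel_stack")
}

#' @export
print.voxel_stack <- function(x, ...) {
  d <- dim(x$intensities)
  cat(sprintf("Voxel stack %d x %d x %d (z, y, x), voxel %.3g x %.3g x %.3g um\n",
              d[1], d[2], d[3],
              x$voxel_dims[1], x$voxel_dims[2], x$voxel_dims[3]))
  invisible(x)
}

#' Otsu intensity threshold for a stack
#'
#' Histogram-based threshold maximising the between-class variance,
#' providing a reproducible default in place of a threshold gauged by
#' visual inspection of the 3D rendering. Returned is the upper edge of
#' the chosen histogram bin, so that `intensity > threshold` selects the
#' foreground class.
#'
#' @param stack A [voxel_stack()] or 3D array.
#' @param n_bins Number of histogram bins (default 256).
#' @return A single threshold intensity, strictly between the stack
#'   minimum and maximum.
#' @export
otsu_threshold <- function(stack, n_bins = 256) {
  v <- as.vector(if (inherits(stack, "voxel_stack")) stack$intensities
                 else stack)
  rng <- range(v)
  if (rng[1] == rng[2])
    stop("constant stack: no two intensity classes to separate",
         call. = FALSE)
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  h <- tabulate(findInterval(v, breaks, rightmost.closed = TRUE,
                             all.inside = TRUE), nbins = n_bins)
  w <- h / sum(h)
  mids <- (breaks[-1L] + breaks[-(n_bins + 1L)]) / 2
  omega <- cumsum(w)                 # class-0 weight up to bin t
  mu <- cumsum(w * mids)             # cumulative first moment
  mu_t <- mu[n_bins]
  # between-class variance for threshold after bin t (t = 1..n_bins-1)
  t_idx <- seq_len(n_bins - 1L)
  denom <- omega[t_idx] * (1 - omega[t_idx])
  bcv <- ifelse(denom > 0, (mu_t * omega[t_idx] - mu[t_idx])^2 / denom, -Inf)
  best <- which.max(bcv)
  breaks[best + 1L]  # upper edge of the background bin
}

#' Quantify bacterial load from a voxel stack
#'
#' Counts voxels with intensity strictly greater than `threshold`,
#' converts the count to physical volume, and labels 26-connected
#' components of the above-threshold mask (the particle count used to
#' sanity-check single-bacterium diameters).
#'
#' @param stack A [voxel_stack()].
#' @param threshold Finite intensity threshold; voxels equal to the
#'   threshold count as background. Default: [otsu_threshold()].
#' @param connectivity Neighbourhood for components: 26 (default, all
#'   touching voxels), 18 or 6 (faces only).
#' @return A list of class `"load_result"` with `n_voxels`, `volume`
#'   (um^3, `n_voxels * prod(voxel_dims)`), `threshold_used`,
#'   `n_components`.
#' @examples
#' arr <- array(0, c(4, 8, 8)); arr[2, 3:4, 3:6] <- 100
#' quantify_load(voxel_stack(arr, c(0.2, 0.1, 0.1)), threshold = 50)
#' @export
quantify_load <- function(stack, threshold = otsu_threshold(stack),
                          connectivity = 26) {
  stopifnot(inherits(stack, "voxel_stack"))
  if (!is.numeric(threshold) || length(threshold) != 1L || !is.finite(threshold))
    stop("'threshold' must be a single finite number", call. = FALSE)
  if (!connectivity %in% c(6, 18, 26))
    stop("'connectivity' must be 6, 18 or 26", call. = FALSE)
  mask <- stack$intensities > threshold
  n_vox <- sum(mask)
  structure(list(
    n_voxels = n_vox,
    volume = n_vox * prod(stack$voxel_dims),
    threshold_used = threshold,
    n_components = count_components(mask, connectivity)
  ), class = "load_result")
}

#' @export
print.load_result <- function(x, ...) {
  cat(sprintf("Bacterial load: %d voxels, %.4g um^3, %d component(s), threshold %.4g\n",
              x$n_voxels, x$volume, x$n_components, x$threshold_used))
  invisible(x)
}

# Connected-component count on a 3D logical mask via iterative flood fill
# over linear indices. Neighbour offsets are precomputed from the chosen
# connectivity; border safety comes from padding the mask by one voxel.
count_components <- function(mask, connectivity = 26) {
  if (!any(mask)) return(0L)
  d <- dim(mask)
  # pad with FALSE so neighbour arithmetic never wraps across borders
  pd <- d + 2L
  padded <- array(FALSE, pd)
  padded[2:(d[1] + 1L), 2:(d[2] + 1L), 2:(d[3] + 1L)] <- mask
  dz <- rep(-1:1, times = 9L)
  dy <- rep(rep(-1:1, each = 3L), times = 3L)
  dx <- rep(-1:1, each = 9L)
  manh <- abs(dz) + abs(dy) + abs(dx)
  keep <- switch(as.character(connectivity),
                 "6"  = manh == 1L,
                 "18" = manh >= 1L & manh <= 2L,
                 "26" = manh >= 1L)
  offsets <- dz[keep] + dy[keep] * pd[1L] + dx[keep] * pd[1L] * pd[2L]
  todo <- which(padded)
  visited <- logical(length(padded))
  n_comp <- 0L
  for (start in todo) {
    if (visited[start]) next
    n_comp <- n_comp + 1L
    frontier <- start
    visited[start] <- TRUE
    while (length(frontier)) {
      nb <- unique(as.vector(outer(frontier, offsets, `+`)))
      nb <- nb[padded[nb] & !visited[nb]]
      visited[nb] <- TRUE
      frontier <- nb
    }
  }
  n_comp
}

#' Classify spores into intensity gates
#'
#' Deterministic substitute for qualitatively drawn FACS gates: assigns
#' each spore's total fluorescence intensity to one of `n_bins` quantile
#' bins — low, medium, high for the default three — with ties broken by
#' input order (stable).
#'
#' @param total_intensities Numeric vector of per-spore total
#'   intensities, containing at least `n_bins` distinct values.
#' @param n_bins Number of gates (default 3).
#' @return A factor of length `length(total_intensities)` with levels
#'   `low`, `medium`, `high` (or `bin1`..`binK` for `n_bins != 3`).
#' @examples
#' classify_intensity_bins(1:9)  # 3 low, 3 medium, 3 high
#' @export
classify_intensity_bins <- function(total_intensities, n_bins = 3) {
  if (!is.numeric(total_intensities) || anyNA(total_intensities))
    stop("'total_intensities' must be numeric without NA", call. = FALSE)
  if (length(unique(total_intensities)) < n_bins)
    stop(sprintf("need at least %d distinct intensity values", n_bins),
         call. = FALSE)
  n <- length(total_intensities)
  r <- rank(total_intensities, ties.method = "first")
  idx <- ceiling(r * n_bins / n)
  labels <- if (n_bins == 3) c("low", "medium", "high")
            else paste0("bin", seq_len(n_bins))
  factor(labels[idx], levels = labels)
}

#' Write / read a voxel stack as plain text
#'
#' Simple text serialisation for voxel stacks (in place of TIFF, which
#' has no reader in this package's dependency set): a header with the
#' dimensions and voxel size, then one whitespace-separated matrix block
#' per z-slice.
#'
#' @param stack A [voxel_stack()].
#' @param path File path.
#' @return `write_voxel_stack` returns `path` invisibly;
#'   `read_voxel_stack` returns a [voxel_stack()].
#' @export
write_voxel_stack <- function(stack, path) {
  stopifnot(inherits(stack, "voxel_stack"))
  d <- dim(stack$intensities)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste("# voxel_stack v1"),
               paste("dims:", paste(d, collapse = " ")),
               paste("voxel_dims_um:", paste(format(stack$voxel_dims, digits = 15),
                                             collapse = " "))), con)
  for (z in seq_len(d[1L])) {
    slice <- stack$intensities[z, , , drop = TRUE]
    if (is.null(dim(slice))) slice <- matrix(slice, nrow = d[2L])
    utils::write.table(slice, con, row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_voxel_stack
#' @export
read_voxel_stack <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 3L || !startsWith(lines[1L], "# voxel_stack"))
    stop("not a voxel_stack text file: ", path, call. = FALSE)
  d <- as.integer(strsplit(sub("^dims: *", "", lines[2L]), " +")[[1L]])
  vd <- as.numeric(strsplit(sub("^voxel_dims_um: *", "", lines[3L]), " +")[[1L]])
  vals <- scan(text = lines[-(1:3)], quiet = TRUE)
  if (length(vals) != prod(d))
    stop("voxel count does not match declared dims in ", path, call. = FALSE)
  # slices are written (y, x) per z: reassemble in the same order
  arr <- array(NA_real_, d)
  per_slice <- d[2L] * d[3L]
  for (z in seq_len(d[1L]))
    arr[z, , ] <- matrix(vals[((z - 1L) * per_slice + 1L):(z * per_slice)],
                         nrow = d[2L], byrow = TRUE)
  voxel_stack(arr, vd)
}
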