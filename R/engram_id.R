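#' Snapshot image container
#'
#' Single-channel non-negative intensity grid. `scale_note` records any
#' binning applied so downstream coordinate frames are explicit.
#'
#' @param pixels numeric matrix (rows x cols), finite and non-negative.
#' @param scale_note character, e.g. `"full"` or `"binned_x2"`.
#' @return A `snapshot_image` object.
#' @export
snapshot_image <- function(pixels, scale_note = "full") {
  pixels <- as.matrix(pixels)
  storage.mode(pixels) <- "double"
  if (!all(is.finite(pixels))) stop("snapshot has non-finite pixels")
  if (any(pixels < 0)) stop("snapshot has negative intensities")
  structure(list(pixels = pixels, scale_note = scale_note),
            class = "snapshot_image")
}

#' @export
print.snapshot_image <- function(x, ...) {
  cat(sprintf("<snapshot_image> %d x %d px (%s), range [%g, %g]\n",
              nrow(x$pixels), ncol(x$pixels), x$scale_note,
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' Read / write plain-text PGM images
#'
#' ASCII (P2) portable graymap, the text stand-in for single-channel TIFF
#' snapshots. Values are integers in `[0, maxval]`.
#'
#' @param path file path.
#' @return `read_pgm`: a [snapshot_image()].
#' @export
read_pgm <- function(path) {
  txt <- readLines(path, warn = FALSE)
  txt <- txt[!grepl("^#", txt)]
  tok <- scan(text = paste(txt, collapse = " "), what = character(),
              quiet = TRUE)
  if (tok[1] != "P2") stop("not an ASCII PGM (P2) file: ", path)
  dims <- as.integer(tok[2:3])          # width height
  vals <- as.numeric(tok[-(1:4)])
  if (length(vals) != prod(dims)) stop("corrupt PGM: wrong pixel count")
  snapshot_image(matrix(vals, nrow = dims[2], ncol = dims[1], byrow = TRUE))
}

#' @rdname read_pgm
#' @param img a [snapshot_image()] or numeric matrix.
#' @param maxval maximum gray value to declare (default: max pixel).
#' @export
write_pgm <- function(img, path, maxval = NULL) {
  px <- if (inherits(img, "snapshot_image")) img$pixels else as.matrix(img)
  px <- round(px)
  if (is.null(maxval)) maxval <- max(1, max(px))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", paste(ncol(px), nrow(px)), as.character(maxval)), con)
  write(t(px), file = con, ncolumns = min(ncol(px), 20))
  invisible(path)
}

# 2x2 (or f x f) block-mean binning; trailing rows/cols beyond a full block
# are dropped.
bin_image <- function(px, f) {
  nr <- (nrow(px) %/% f) * f
  nc <- (ncol(px) %/% f) * f
  px <- px[seq_len(nr), seq_len(nc), drop = FALSE]
  ri <- (seq_len(nr) - 1L) %/% f
  ci <- (seq_len(nc) - 1L) %/% f
  m <- rowsum(px, ri)
  m <- t(rowsum(t(m), ci))
  m / (f * f)
}

# separable Gaussian blur with edge renormalization (kernel mass inside the
# image is divided out, so a flat image stays flat)
gaussian_blur <- function(px, sigma) {
  half <- max(1L, ceiling(2 * sigma))
  k <- exp(-(seq(-half, half))^2 / (2 * sigma^2))
  blur1 <- function(m) {
    out <- stats::filter(m, k, method = "convolution", sides = 2)
    out <- as.matrix(out)
    # renormalize by the same filter applied to ones (handles NA edges)
    w <- stats::filter(matrix(1, nrow(m), ncol(m)), k, sides = 2)
    w <- as.matrix(w)
    edge <- is.na(out)
    if (any(edge)) {
      # explicit truncated sums at the borders
      for (j in seq_len(ncol(m))) {
        nas <- which(edge[, j])
        for (i in nas) {
          lo <- max(1, i - half); hi <- min(nrow(m), i + half)
          kk <- k[(lo - i + half + 1):(hi - i + half + 1)]
          out[i, j] <- sum(m[lo:hi, j] * kk)
          w[i, j] <- sum(kk)
        }
      }
    }
    out / w
  }
  t(blur1(t(blur1(px))))
}

#' Enhance a reporter snapshot
#'
#' Bins the snapshot by `bin_factor` (block mean, the down-sample-and-smooth
#' step) and divides it pixel-by-pixel by a low-passed version of itself
#' (Gaussian blur, sigma = `lowpass_radius_px / 2`). Flat input maps to ~1
#' everywhere; blob-to-background contrast increases.
#'
#' @param img a [snapshot_image()].
#' @param bin_factor spatial binning factor (default 2).
#' @param lowpass_radius_px low-pass radius in (binned) pixels (default 20).
#' @return Enhanced, binned [snapshot_image()].
#' @export
enhance_snapshot <- function(img, bin_factor = 2, lowpass_radius_px = 20) {
  stopifnot(inherits(img, "snapshot_image"))
  px <- img$pixels
  if (nrow(px) <= 2 * lowpass_radius_px || ncol(px) <= 2 * lowpass_radius_px) {
    stop("image too small for lowpass radius ", lowpass_radius_px)
  }
  b <- bin_image(px, bin_factor)
  lp <- gaussian_blur(b, lowpass_radius_px / 2)
  out <- b / pmax(lp, .Machine$double.eps)
  snapshot_image(out, scale_note = sprintf("binned_x%d", bin_factor))
}

# chamfer (3-4) distance transform of a binary mask, two-pass
chamfer_distance <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  inf <- 1e9
  d <- ifelse(mask, inf, 0)
  for (j in seq_len(nc)) for (i in seq_len(nr)) {
    if (d[i, j] == 0) next
    v <- d[i, j]
    if (i > 1) v <- min(v, d[i - 1, j] + 3)
    if (j > 1) v <- min(v, d[i, j - 1] + 3)
    if (i > 1 && j > 1) v <- min(v, d[i - 1, j - 1] + 4)
    if (i < nr && j > 1) v <- min(v, d[i + 1, j - 1] + 4)
    d[i, j] <- v
  }
  for (j in rev(seq_len(nc))) for (i in rev(seq_len(nr))) {
    if (d[i, j] == 0) next
    v <- d[i, j]
    if (i < nr) v <- min(v, d[i + 1, j] + 3)
    if (j < nc) v <- min(v, d[i, j + 1] + 3)
    if (i < nr && j < nc) v <- min(v, d[i + 1, j + 1] + 4)
    if (i > 1 && j < nc) v <- min(v, d[i - 1, j + 1] + 4)
    d[i, j] <- v
  }
  d / 3
}

# 8-connected component labelling by flood fill
label_components <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  idx <- which(mask)
  for (p in idx) {
    if (lab[p] != 0L) next
    cur <- cur + 1L
    queue <- p
    lab[p] <- cur
    while (length(queue)) {
      q <- queue[[1]]; queue <- queue[-1]
      i <- (q - 1L) %% nr + 1L; j <- (q - 1L) %/% nr + 1L
      for (di in -1:1) for (dj in -1:1) {
        ii <- i + di; jj <- j + dj
        if (ii < 1 || ii > nr || jj < 1 || jj > nc) next
        r <- ii + (jj - 1L) * nr
        if (mask[r] && lab[r] == 0L) { lab[r] <- cur; queue <- c(queue, r) }
      }
    }
  }
  lab
}

# watershed split of a binary mask: flood the chamfer distance transform from
# its regional maxima downwards; pixels reachable from two different maxima
# become watershed lines and are removed from the mask.
watershed_split <- function(mask) {
  if (!any(mask)) return(matrix(0L, nrow(mask), ncol(mask)))
  d <- chamfer_distance(mask)
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  WSHED <- -1L
  ord <- order(d[mask], decreasing = TRUE)
  px <- which(mask)[ord]
  nxt <- 0L
  for (p in px) {
    i <- (p - 1L) %% nr + 1L; j <- (p - 1L) %/% nr + 1L
    seen <- integer(0)
    for (di in -1:1) for (dj in -1:1) {
      if (di == 0L && dj == 0L) next
      ii <- i + di; jj <- j + dj
      if (ii < 1 || ii > nr || jj < 1 || jj > nc) next
      l <- lab[ii, jj]
      if (l > 0L) seen <- c(seen, l)
    }
    seen <- unique(seen)
    if (length(seen) == 0L) {
      nxt <- nxt + 1L
      lab[p] <- nxt
    } else if (length(seen) == 1L) {
      lab[p] <- seen
    } else {
      lab[p] <- WSHED
    }
  }
  lab[lab == WSHED] <- 0L
  # merge label fragments that remained 8-connected (plateau artefacts)
  relabel <- label_components(lab > 0L)
  relabel
}

#' Segment ROIs from an enhanced snapshot
#'
#' Keeps exactly the brightest `keep_top_fraction` of pixels (92%-average
#' cutoff keeping the top 8% by default; ties broken by intensity then raster
#' order), applies a majority cleanup (a set pixel survives if at least 2 of
#' its 8 neighbours are set) and one morphological closing, splits touching
#' particles by watershed, and filters connected components by area.
#'
#' @param img enhanced [snapshot_image()] (see [enhance_snapshot()]).
#' @param keep_top_fraction fraction of pixels kept (default 0.08).
#' @param min_area_px,max_area_px particle-area bounds in (binned) pixels;
#'   defaults pi*2^2 and pi*15^2.
#' @return A `roi_set`: list with `rois` (list of `id`, `mask` indices,
#'   `centroid`, `area`), `labels` (labelled image matrix), `n_kept_pixels`.
#' @export
segment_rois <- function(img, keep_top_fraction = 0.08,
                         min_area_px = pi * 2^2, max_area_px = pi * 15^2) {
  stopifnot(inherits(img, "snapshot_image"))
  px <- img$pixels
  P <- length(px)
  n_keep <- max(1L, round(keep_top_fraction * P))
  ord <- order(px, seq_len(P), decreasing = TRUE)  # intensity, then raster order
  mask <- matrix(FALSE, nrow(px), ncol(px))
  mask[ord[seq_len(n_keep)]] <- TRUE
  n_kept <- sum(mask)

  mask <- majority_clean(mask)
  mask <- binary_close(mask)
  lab <- watershed_split(mask)

  rois <- list()
  nid <- 0L
  if (max(lab) > 0L) {
    for (l in seq_len(max(lab))) {
      pix <- which(lab == l)
      a <- length(pix)
      if (a < min_area_px || a > max_area_px) next
      nid <- nid + 1L
      i <- (pix - 1L) %% nrow(lab) + 1L
      j <- (pix - 1L) %/% nrow(lab) + 1L
      rois[[nid]] <- list(id = sprintf("roi%03d", nid), mask = pix,
                          centroid = c(x = mean(j), y = mean(i)), area = a)
    }
  }
  keep_lab <- matrix(0L, nrow(lab), ncol(lab))
  for (k in seq_along(rois)) keep_lab[rois[[k]]$mask] <- k
  structure(list(rois = rois, labels = keep_lab, n_kept_pixels = n_kept,
                 dim = dim(px)),
            class = "roi_set")
}

#' @export
print.roi_set <- function(x, ...) {
  cat(sprintf("<roi_set> %d ROIs on %d x %d px\n",
              length(x$rois), x$dim[1], x$dim[2]))
  invisible(x)
}

# a set pixel survives iff >= 2 of its 8 neighbours are set
majority_clean <- function(mask) {
  cnt <- neighbour_count(mask)
  mask & (cnt >= 2L)
}

neighbour_count <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  m <- matrix(0L, nr + 2L, nc + 2L)
  m[2:(nr + 1), 2:(nc + 1)] <- mask
  cnt <- matrix(0L, nr, nc)
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0L && dj == 0L) next
    cnt <- cnt + m[(2:(nr + 1)) + di, (2:(nc + 1)) + dj]
  }
  cnt
}

# single morphological closing with a 3x3 structuring element
binary_close <- function(mask) {
  dil <- neighbour_count(mask) > 0L | mask
  ero <- neighbour_count(dil) == 8L & dil
  ero
}

#' Match ROIs to registered cells
#'
#' A cell is flagged engram iff at least one ROI satisfies the geometric match
#' criterion: centroid-to-centroid distance at most `r_match` AND the cell
#' centroid lies inside the ROI mask. ROIs matching no cell are reported
#' separately (the discard pile).
#'
#' @param rois a `roi_set` from [segment_rois()].
#' @param registry a [cell_registry()]; centroids must be in the same (binned)
#'   coordinate frame as `rois` — see `scale` / `translate`.
#' @param r_match match radius in binned px; default = mean ROI equivalent
#'   radius `sqrt(area/pi)`.
#' @param scale divide registry centroids by this factor first (use the
#'   snapshot bin factor when the registry is in full-resolution coordinates).
#' @param translate optional `c(dx, dy)` added to scaled centroids (manual
#'   snapshot-to-movie alignment stand-in).
#' @return The registry with `engram_flag` set, plus attributes
#'   `unmatched_rois` (ids) and `r_match`.
#' @export
match_rois_to_cells <- function(rois, registry, r_match = NULL,
                                scale = 1, translate = c(0, 0)) {
  stopifnot(inherits(rois, "roi_set"), inherits(registry, "cell_registry"))
  cx <- registry$x / scale + translate[1]
  cy <- registry$y / scale + translate[2]
  if (is.null(r_match)) {
    r_match <- if (length(rois$rois)) {
      mean(vapply(rois$rois, function(r) sqrt(r$area / pi), 0))
    } else 0
  }
  nr <- rois$dim[1]
  flag <- logical(nrow(registry))
  matched_roi <- logical(length(rois$rois))
  for (k in seq_along(rois$rois)) {
    r <- rois$rois[[k]]
    d2 <- (cx - r$centroid["x"])^2 + (cy - r$centroid["y"])^2
    cand <- which(d2 <= r_match^2)
    for (ci in cand) {
      pi_ <- round(cy[ci]); pj <- round(cx[ci])
      if (pi_ < 1 || pi_ > nr || pj < 1 || pj > rois$dim[2]) next
      if ((pi_ + (pj - 1L) * nr) %in% r$mask) {
        flag[ci] <- TRUE
        matched_roi[k] <- TRUE
      }
    }
  }
  out <- registry
  out$engram_flag <- flag
  attr(out, "unmatched_rois") <-
    vapply(rois$rois[!matched_roi], `[[`, "", "id")
  attr(out, "r_match") <- r_match
  out
}

#' Identify engram cells from a snapshot (end to end)
#'
#' Convenience wrapper: [enhance_snapshot()] then [segment_rois()] then
#' [match_rois_to_cells()], returning engram/non-engram labels for every
#' registry cell.
#'
#' @param snapshot a [snapshot_image()] in full resolution.
#' @param registry a [cell_registry()] with centroids in full-resolution
#'   snapshot coordinates.
#' @param bin_factor,lowpass_radius_px see [enhance_snapshot()].
#' @param keep_top_fraction,min_area_px,max_area_px see [segment_rois()].
#' @param r_match,translate see [match_rois_to_cells()].
#' @return List with `labels` (named character vector
#'   `"engram"`/`"non_engram"`), `registry`, `rois`.
#' @export
identify_engram_cells <- function(snapshot, registry,
                                  bin_factor = 2, lowpass_radius_px = 20,
                                  keep_top_fraction = 0.08,
                                  min_area_px = pi * 2^2,
                                  max_area_px = pi * 15^2,
                                  r_match = NULL, translate = c(0, 0)) {
  enh <- enhance_snapshot(snapshot, bin_factor, lowpass_radius_px)
  rois <- segment_rois(enh, keep_top_fraction, min_area_px, max_area_px)
  reg <- match_rois_to_cells(rois, registry, r_match = r_match,
                             scale = bin_factor, translate = translate)
  labels <- setNames(ifelse(reg$engram_flag, "engram", "non_engram"),
                     reg$cell_id)
  list(labels = labels, registry = reg, rois = rois)
}
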