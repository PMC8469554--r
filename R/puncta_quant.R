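as_matrix_image <- function(img) {
  if (inherits(img, "Image")) img <- EBImage::imageData(img)
  if (length(dim(img)) > 2) img <- img[, , 1]
  storage.mode(img) <- "double"
  img
}

#' Segment cells from a diffuse cytoplasmic channel
#'
#' Gaussian smoothing, Otsu threshold, hole filling and connected-component
#' labelling; components below `min_area` are discarded and labels are
#' renumbered consecutively. Images with no appreciable foreground contrast
#' yield zero labels with a warning.
#'
#' @param img 2-D single-channel image (matrix or EBImage `Image`).
#' @param sigma Smoothing SD in pixels.
#' @param min_area Minimum component area (pixels).
#' @return Integer label matrix (0 = background).
#' @export
segment_cells <- function(img, sigma = 4, min_area = 400) {
  img <- as_matrix_image(img)
  rng <- range(img)
  if (diff(rng) <= 0) {
    warning("flat image: no cells found")
    return(matrix(0L, nrow(img), ncol(img)))
  }
  norm <- (img - rng[1]) / diff(rng)
  sm <- EBImage::imageData(EBImage::gblur(EBImage::Image(norm), sigma = sigma))
  thr <- EBImage::otsu(EBImage::Image(sm), range = c(0, 1))
  # guard: threshold must clear the background noise floor, else the image
  # is background-only and Otsu is splitting noise
  if (thr - stats::median(sm) < 3 * stats::mad(sm)) {
    warning("no foreground contrast: no cells found")
    return(matrix(0L, nrow(img), ncol(img)))
  }
  mask <- EBImage::fillHull(sm > thr)
  lab <- EBImage::bwlabel(mask)
  tab <- tabulate(lab[lab > 0])
  keep <- which(tab >= min_area)
  out <- matrix(0L, nrow(img), ncol(img))
  for (i in seq_along(keep)) out[lab == keep[i]] <- i
  out
}

# strict-ish local maxima of a matrix over the 8-neighbourhood
local_maxima <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  pad <- matrix(-Inf, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- m
  res <- matrix(TRUE, nr, nc)
  for (dx in -1:1) for (dy in -1:1) {
    if (dx == 0 && dy == 0) next
    res <- res & (m >= pad[2:(nr + 1) + dx, 2:(nc + 1) + dy])
  }
  res
}

disk_offsets <- function(r) {
  g <- expand.grid(dx = -r:r, dy = -r:r)
  g[g$dx^2 + g$dy^2 <= r^2, ]
}

disk_values <- function(img, x, y, off) {
  ix <- x + off$dx; iy <- y + off$dy
  ok <- ix >= 1 & ix <= nrow(img) & iy >= 1 & iy <= ncol(img)
  img[cbind(ix[ok], iy[ok])]
}

#' Detect puncta in the mCherry channel
#'
#' Difference-of-Gaussians blob detection (a Laplacian-of-Gaussian
#' approximation at the expected spot scale) followed by local-maximum
#' extraction inside cell masks. The detection threshold is `k_det` robust
#' SDs of the in-cell DoG response. Detections outside any cell are
#' discarded; maxima closer than `3 * spot_sigma` are merged (brightest
#' kept).
#'
#' @param mcherry 2-D image (matrix or EBImage `Image`).
#' @param labels Integer cell label matrix from [segment_cells()].
#' @param spot_sigma Expected spot SD in pixels (default 2; the assay's
#'   puncta span roughly 1.5-4 px).
#' @param k_det Detection threshold in robust SD units of the DoG response.
#' @return Data frame: `x`, `y` (pixel coordinates, 0-based), `cell_id`,
#'   `mcherry_intensity` (background-subtracted integrated intensity).
#' @export
detect_puncta <- function(mcherry, labels, spot_sigma = 2, k_det = 5) {
  img <- as_matrix_image(mcherry)
  if (!all(dim(img) == dim(labels)))
    stop("channel and labels must have the same shape", call. = FALSE)
  empty <- data.frame(x = numeric(), y = numeric(), cell_id = integer(),
                      mcherry_intensity = numeric())
  if (!any(labels > 0)) return(empty)
  dog <- EBImage::imageData(EBImage::gblur(EBImage::Image(img),
                                           sigma = spot_sigma)) -
    EBImage::imageData(EBImage::gblur(EBImage::Image(img),
                                      sigma = 1.6 * spot_sigma))
  # the cell boundary is a strong intensity step whose DoG response would
  # drown real puncta: search an eroded interior only
  er <- ceiling(4 * spot_sigma)
  interior <- EBImage::imageData(
    EBImage::erode(EBImage::Image(labels > 0),
                   EBImage::makeBrush(2 * er + 1, shape = "disc"))) > 0
  if (!any(interior)) return(empty)
  scale <- stats::mad(dog[interior])
  if (scale <= 0) scale <- stats::sd(dog[interior])
  cand <- local_maxima(dog) & (dog > k_det * scale) & interior & (labels > 0)
  idx <- which(cand, arr.ind = TRUE)
  if (nrow(idx) == 0) return(empty)
  resp <- dog[cand]
  ord <- order(resp, decreasing = TRUE)
  idx <- idx[ord, , drop = FALSE]
  # merge near-duplicate maxima
  keep <- rep(TRUE, nrow(idx))
  min_sep2 <- (3 * spot_sigma)^2
  for (i in seq_len(nrow(idx))) {
    if (!keep[i]) next
    if (i < nrow(idx)) {
      j <- (i + 1):nrow(idx)
      d2 <- (idx[j, 1] - idx[i, 1])^2 + (idx[j, 2] - idx[i, 2])^2
      keep[j[d2 < min_sep2]] <- FALSE
    }
  }
  idx <- idx[keep, , drop = FALSE]
  off <- disk_offsets(ceiling(2 * spot_sigma))
  inten <- numeric(nrow(idx))
  cellid <- integer(nrow(idx))
  for (i in seq_len(nrow(idx))) {
    cellid[i] <- labels[idx[i, 1], idx[i, 2]]
    cellpx <- img[labels == cellid[i]]
    bg <- stats::median(cellpx)
    v <- disk_values(img, idx[i, 1], idx[i, 2], off)
    inten[i] <- sum(v - bg)
  }
  data.frame(x = idx[, 1] - 1, y = idx[, 2] - 1, cell_id = cellid,
             mcherry_intensity = inten)
}

#' Classify detected puncta into AP vs AL by GFP status
#'
#' A punctum is an autophagosome (AP, mCherry+/GFP+) iff its mean GFP signal
#' over a small disk exceeds the local cytoplasmic background by `k`
#' standard errors (z-score of the disk mean against the cell's background
#' pixel distribution, spot neighbourhoods excluded); otherwise it is an
#' autophagolysosome (AL, mCherry+/GFP-, GFP quenched).
#'
#' @param spots Data frame from [detect_puncta()].
#' @param gfp GFP channel image.
#' @param labels Cell label matrix.
#' @param k Positivity threshold in background SE units (default 3).
#' @param spot_sigma Spot scale in pixels (measurement disk radius
#'   `2 * spot_sigma`; exclusion radius `3 * spot_sigma`).
#' @return `spots` with added columns `gfp_intensity`, `gfp_z` and `klass`.
#' @export
classify_puncta <- function(spots, gfp, labels, k = 3, spot_sigma = 2) {
  img <- as_matrix_image(gfp)
  if (!all(dim(img) == dim(labels)))
    stop("channel and labels must have the same shape", call. = FALSE)
  if (nrow(spots) == 0) {
    spots$gfp_intensity <- numeric(0)
    spots$gfp_z <- numeric(0)
    spots$klass <- character(0)
    return(spots)
  }
  meas_off <- disk_offsets(ceiling(2 * spot_sigma))
  excl_off <- disk_offsets(ceiling(3 * spot_sigma))
  excl <- matrix(FALSE, nrow(img), ncol(img))
  for (i in seq_len(nrow(spots))) {
    ix <- spots$x[i] + 1 + excl_off$dx; iy <- spots$y[i] + 1 + excl_off$dy
    ok <- ix >= 1 & ix <= nrow(img) & iy >= 1 & iy <= ncol(img)
    excl[cbind(ix[ok], iy[ok])] <- TRUE
  }
  gfp_mean <- numeric(nrow(spots))
  zs <- numeric(nrow(spots))
  for (ci in unique(spots$cell_id)) {
    sel <- spots$cell_id == ci
    bgpx <- img[labels == ci & !excl]
    if (length(bgpx) < 20) bgpx <- img[labels == ci]
    bg_med <- stats::median(bgpx)
    bg_sd <- stats::mad(bgpx)
    if (bg_sd <= 0) bg_sd <- max(stats::sd(bgpx), .Machine$double.eps)
    for (i in which(sel)) {
      v <- disk_values(img, spots$x[i] + 1, spots$y[i] + 1, meas_off)
      gfp_mean[i] <- mean(v)
      zs[i] <- (gfp_mean[i] - bg_med) / (bg_sd / sqrt(length(v)))
    }
  }
  spots$gfp_intensity <- gfp_mean
  spots$gfp_z <- zs
  spots$klass <- ifelse(zs > k, "AP", "AL")
  spots
}

#' Per-cell puncta table and optional time-course row
#'
#' @param records Classified puncta from [classify_puncta()].
#' @param cell_ids Optional vector of all cell ids to report (cells with no
#'   puncta get zero counts).
#' @param metadata Optional list with `condition_id` and `time_h`; when
#'   given, a one-row time-course data frame (per-cell mean AP and AL counts
#'   with SDs, the dialect consumed by [flux_dataset()]) is attached.
#' @return List with `cells` (cell_id, n_AP, n_AL, ratio; ratio is `NA`
#'   when n_AP = 0), `totals`, and optionally `timecourse`.
#' @export
summarize_puncta <- function(records, cell_ids = NULL, metadata = NULL) {
  ids <- sort(unique(c(records$cell_id, cell_ids)))
  cells <- data.frame(cell_id = ids,
                      n_AP = vapply(ids, function(i)
                        sum(records$cell_id == i & records$klass == "AP"),
                        numeric(1)),
                      n_AL = vapply(ids, function(i)
                        sum(records$cell_id == i & records$klass == "AL"),
                        numeric(1)))
  cells$ratio <- ifelse(cells$n_AP > 0, cells$n_AL / cells$n_AP, NA_real_)
  out <- list(cells = cells,
              totals = c(n_AP = sum(cells$n_AP), n_AL = sum(cells$n_AL)))
  if (!is.null(metadata)) {
    out$timecourse <- data.frame(
      condition_id = metadata$condition_id, time_h = metadata$time_h,
      AP = mean(cells$n_AP), AL = mean(cells$n_AL),
      AP_sd = stats::sd(cells$n_AP), AL_sd = stats::sd(cells$n_AL))
  }
  out
}

#' End-to-end puncta quantification of one two-channel frame
#'
#' Segments cells on the GFP channel (diffuse cytoplasmic LC3-I makes cells
#' visible there), detects puncta on mCherry, classifies them by GFP status
#' and summarises counts.
#'
#' @param gfp,mcherry Channel images.
#' @param k GFP positivity threshold (see [classify_puncta()]).
#' @param k_det Detection threshold (see [detect_puncta()]).
#' @param spot_sigma Spot scale in pixels.
#' @param metadata Passed to [summarize_puncta()].
#' @return List with `records`, `cells`, `totals`, `labels` and optionally
#'   `timecourse`.
#' @export
quantify_images <- function(gfp, mcherry, k = 3, k_det = 5, spot_sigma = 2,
                            metadata = NULL) {
  labels <- segment_cells(gfp)
  spots <- detect_puncta(mcherry, labels, spot_sigma = spot_sigma,
                         k_det = k_det)
  records <- classify_puncta(spots, gfp, labels, k = k,
                             spot_sigma = spot_sigma)
  n_cells <- max(labels)
  summ <- summarize_puncta(records,
                           cell_ids = if (n_cells > 0) seq_len(n_cells),
                           metadata = metadata)
  c(list(records = records, labels = labels), summ)
}
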