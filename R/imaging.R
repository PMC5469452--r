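# Nuclei segmentation and per-cell feature extraction -----------------------
#
# A transparent compartmental-analysis stand-in: global Otsu threshold,
# hole filling, distance-transform watershed to split touching nuclei,
# size/border validity filters, then per-object intensity statistics over
# the nuclear mask and a cytoplasmic ring grown around it.

as_ebimage <- function(img) {
  if (inherits(img, "Image")) img else EBImage::Image(t(img))
}

#' Background-correct a fluorescence image
#'
#' Estimates the background as the median of sub-threshold pixels (Otsu
#' threshold on the intensity histogram) and subtracts it, clipping
#' negative values to zero. A constant image is treated as pure background
#' and maps to all zeros.
#'
#' @param img 2-D numeric matrix of non-negative intensities.
#' @return matrix of the same shape, background-subtracted and clipped at 0.
#' @export
correct_background <- function(img) {
  stopifnot(is.matrix(img), all(img >= 0))
  rng <- range(img)
  if (rng[1] == rng[2]) return(img * 0)
  th <- otsu_threshold(img)
  below <- img[img <= th]
  bg <- if (length(below)) stats::median(below) else rng[1]
  pmax(img - bg, 0)
}

# Otsu threshold on the raw intensity scale
otsu_threshold <- function(img) {
  rng <- range(img)
  scaled <- (img - rng[1]) / (rng[2] - rng[1])
  EBImage::otsu(EBImage::Image(t(scaled)), range = c(0, 1)) *
    (rng[2] - rng[1]) + rng[1]
}

#' Segment nuclei from a nuclear-stain image
#'
#' Global Otsu foreground, hole filling, then a distance-transform
#' watershed to split touching nuclei. Objects are relabelled with
#' consecutive ids; objects outside `[min_area, max_area]` or touching the
#' image border are flagged invalid (but kept in the label map).
#'
#' @param img background-corrected 2-D matrix.
#' @param min_area,max_area valid-object area bounds in pixels.
#' @param watershed split touching objects (default TRUE).
#' @param threshold numeric threshold, `"otsu"`, or `"auto"` (default): the
#'   larger of 10x the background noise MAD and 2% of the image maximum.
#'   The auto floor keeps dim nuclei that a global Otsu threshold discards
#'   when bright and dim nuclei coexist, while staying far above shot
#'   noise.
#' @return a `segmentation_result`: list with `label_map` (integer matrix,
#'   0 = background), `objects` (data.frame: id, x, y, area, valid,
#'   border), `n_valid`.
#' @export
segment_nuclei <- function(img, min_area = 20, max_area = 5000,
                           watershed = TRUE, threshold = "auto") {
  stopifnot(is.matrix(img))
  if (all(img == img[1])) {
    lab <- matrix(0L, nrow(img), ncol(img))
    return(new_segmentation(lab))
  }
  th <- if (identical(threshold, "otsu")) {
    otsu_threshold(img)
  } else if (identical(threshold, "auto")) {
    bg <- img[img <= otsu_threshold(img)]
    max(10 * stats::mad(bg), 0.02 * max(img))
  } else threshold
  mask <- img > th
  if (!any(mask)) return(new_segmentation(matrix(0L, nrow(img), ncol(img))))
  emask <- EBImage::Image(t(mask) * 1)
  emask <- EBImage::fillHull(emask)
  lab_img <- if (watershed) {
    EBImage::watershed(EBImage::distmap(emask), tolerance = 1, ext = 1)
  } else {
    EBImage::bwlabel(emask)
  }
  lab <- t(EBImage::imageData(lab_img))  # back to (row, col)
  storage.mode(lab) <- "integer"
  # consecutive ids
  ids <- sort(unique(lab[lab > 0]))
  if (length(ids) && !identical(ids, seq_along(ids))) {
    remap <- integer(max(ids)); remap[ids] <- seq_along(ids)
    lab[lab > 0] <- remap[lab[lab > 0]]
  }
  new_segmentation(lab, min_area = min_area, max_area = max_area)
}

new_segmentation <- function(label_map, min_area = 20, max_area = 5000) {
  n <- max(label_map)
  if (n == 0) {
    objects <- data.frame(id = integer(0), x = numeric(0), y = numeric(0),
                          area = integer(0), border = logical(0),
                          valid = logical(0))
  } else {
    px <- which(label_map > 0, arr.ind = TRUE)
    id <- label_map[px]
    area <- tabulate(id, n)
    cy <- rowsum(as.numeric(px[, 1]), id)[, 1] / area
    cx <- rowsum(as.numeric(px[, 2]), id)[, 1] / area
    on_border <- px[, 1] == 1 | px[, 1] == nrow(label_map) |
      px[, 2] == 1 | px[, 2] == ncol(label_map)
    border <- rowsum(as.numeric(on_border), id)[, 1] > 0
    objects <- data.frame(id = seq_len(n), x = cx, y = cy, area = area,
                          border = border,
                          valid = !border & area >= min_area & area <= max_area)
  }
  structure(list(label_map = label_map, objects = objects,
                 n_valid = sum(objects$valid)),
            class = "segmentation_result")
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat(sprintf("<segmentation_result> %d objects (%d valid) on %dx%d image\n",
              nrow(x$objects), x$n_valid, nrow(x$label_map),
              ncol(x$label_map)))
  invisible(x)
}

#' Extract per-cell compartmental features
#'
#' For every segmented object: nuclear area, and per channel the total and
#' mean intensity over the nuclear mask and over a cytoplasmic ring (pixels
#' within `ring_width` of the nucleus, assigned to the nearest nucleus so
#' rings never overlap other cells). `dna_content` is the total
#' nuclear-compartment intensity in the `dna` channel when present.
#'
#' @param seg a `segmentation_result` (or an integer label matrix).
#' @param channel_images named list of 2-D matrices, same shape as the
#'   label map.
#' @param ring_width ring thickness in pixels.
#' @return data.frame: cell_id, x, y, nuclear_area, valid, per channel
#'   nuc_total_/nuc_mean_/ring_total_/ring_mean_ columns, and
#'   `dna_content` if a `dna` channel is supplied.
#' @export
extract_cell_features <- function(seg, channel_images, ring_width = 4) {
  if (is.matrix(seg) && !inherits(seg, "segmentation_result"))
    seg <- new_segmentation(seg)
  lab <- seg$label_map
  for (ch in channel_images)
    if (!all(dim(ch) == dim(lab))) stop("channel image shape mismatch")
  n <- max(lab)
  out <- seg$objects
  names(out)[names(out) == "id"] <- "cell_id"
  names(out)[names(out) == "area"] <- "nuclear_area"
  if (n == 0) return(out)

  # grow rings: nearest-nucleus assignment within a dilated footprint
  brush <- EBImage::makeBrush(2 * ring_width + 1, shape = "disc")
  fg <- EBImage::Image(t(lab > 0) * 1)
  dil <- EBImage::dilate(fg, brush)
  elab <- EBImage::Image(t(lab))
  grown <- EBImage::propagate(dil, seeds = elab, mask = dil > 0, lambda = 1e-8)
  ring_lab <- t(EBImage::imageData(grown))
  ring_lab[lab > 0] <- 0L
  storage.mode(ring_lab) <- "integer"

  sum_by <- function(region_lab, img) {
    idx <- which(region_lab > 0)
    id <- region_lab[idx]
    tot <- numeric(n)
    s <- rowsum(img[idx], id)
    tot[as.integer(rownames(s))] <- s[, 1]
    tot
  }
  ring_area <- tabulate(ring_lab[ring_lab > 0], n)
  for (ch in names(channel_images)) {
    img <- channel_images[[ch]]
    nt <- sum_by(lab, img)
    rt <- sum_by(ring_lab, img)
    out[[paste0("nuc_total_", ch)]] <- nt
    out[[paste0("nuc_mean_", ch)]] <- nt / out$nuclear_area
    out[[paste0("ring_total_", ch)]] <- rt
    out[[paste0("ring_mean_", ch)]] <- ifelse(ring_area > 0, rt / ring_area, 0)
  }
  if ("dna" %in% names(channel_images))
    out$dna_content <- out$nuc_total_dna
  out
}

#' Well-level quality control on valid object count
#'
#' A well is analyzable only if it contains at least `min_valid_objects`
#' valid segmented objects (default 500); failing wells are excluded from
#' profiling.
#'
#' @param cell_records data.frame with a logical `valid` column (absent =
#'   all valid).
#' @param min_valid_objects threshold count.
#' @return list: `pass`, `n_valid`, `n_total`, `threshold`.
#' @export
well_qc <- function(cell_records, min_valid_objects = 500) {
  n_total <- nrow(cell_records)
  n_valid <- if ("valid" %in% names(cell_records))
    sum(cell_records$valid) else n_total
  list(pass = n_valid >= min_valid_objects, n_valid = n_valid,
       n_total = n_total, threshold = min_valid_objects)
}
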