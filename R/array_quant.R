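# Fixed-circle quantification of peptide-array images and the
# background-plus-kSD positivity threshold.

#' Construct/validate an array layout
#'
#' Describes where each spot sits on the slide image. Roles are
#' `"peptide"` (with a `peptide` index), `"negative"` (buffer-only spots used
#' for the background mean) or `"control"`.
#'
#' @param spots data.frame with columns `spot_id`, `role`, `peptide`
#'   (NA for non-peptide spots), `row`, `col` (pixel center, 1-based), and
#'   `radius` (pixels).
#' @param require_standard if `TRUE`, enforce the standard slide content:
#'   exactly 79 peptide spots and at least 5 negatives.
#' @return the validated data.frame, classed `"array_layout"`.
#' @export
array_layout <- function(spots, require_standard = TRUE) {
  required <- c("spot_id", "role", "peptide", "row", "col", "radius")
  if (!all(required %in% names(spots))) {
    pz_stop("bad_layout", sprintf("layout needs columns %s",
                                  paste(required, collapse = ", ")))
  }
  if (!all(spots$role %in% c("peptide", "negative", "control"))) {
    pz_stop("bad_layout", "role must be peptide/negative/control")
  }
  if (require_standard) {
    if (sum(spots$role == "peptide") != 79L) {
      pz_stop("bad_layout", "standard slide needs exactly 79 peptide spots")
    }
    if (sum(spots$role == "negative") < 5L) {
      pz_stop("bad_layout", "standard slide needs at least 5 negative spots")
    }
  }
  # pairwise non-overlap
  d2 <- as.matrix(stats::dist(spots[, c("row", "col")]))^2
  rr <- outer(spots$radius, spots$radius, `+`)^2
  diag(d2) <- Inf
  if (any(d2 < rr)) pz_stop("bad_layout", "spot circles overlap")
  class(spots) <- c("array_layout", class(spots))
  spots
}

#' Read an array layout TSV
#' @param path TSV with the [array_layout()] columns.
#' @param ... passed to [array_layout()].
#' @export
read_layout_tsv <- function(path, ...) {
  df <- pz_read_tsv(path)
  df$peptide <- suppressWarnings(as.integer(df$peptide))
  array_layout(df, ...)
}

#' Read a 16-bit grayscale array image
#'
#' Reads PNG or TIFF into an integer intensity matrix on the native 16-bit
#' scale (0..65535). Set `invert = TRUE` for optical-density-style scans
#' where binding darkens the image.
#'
#' @param path image file (`.png`, `.tif`, `.tiff`).
#' @param invert if `TRUE`, return `65535 - pixels`.
#' @return integer matrix (rows x cols).
#' @export
read_array_image <- function(path, invert = FALSE) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    pz_stop("bad_image", sprintf("unsupported image format '%s'", ext))
  )
  if (length(dim(img)) == 3L) img <- img[, , 1L]  # first channel of gray-encoded RGB
  m <- round(img * 65535)
  if (invert) m <- 65535 - m
  storage.mode(m) <- "integer"
  m
}

# integer pixel centers inside a circle (pixel-center-in-circle rule)
circle_mask_idx <- function(nrow_img, ncol_img, row0, col0, radius) {
  r_lo <- max(1L, floor(row0 - radius))
  r_hi <- min(nrow_img, ceiling(row0 + radius))
  c_lo <- max(1L, floor(col0 - radius))
  c_hi <- min(ncol_img, ceiling(col0 + radius))
  if (r_lo > r_hi || c_lo > c_hi) return(integer())
  rows <- r_lo:r_hi
  cols <- c_lo:c_hi
  keep <- outer((rows - row0)^2, (cols - col0)^2, `+`) <= radius^2
  idx_rows <- rep(rows, times = length(cols))
  idx_cols <- rep(cols, each = length(rows))
  (idx_cols[keep] - 1L) * nrow_img + idx_rows[keep]
}

#' Measure integrated optical density by the fixed-circle method
#'
#' For each layout spot, sums the pixel intensities whose centers fall
#' within the fixed circle around the expected spot center. No per-pixel
#' background subtraction is applied here; background is handled once, at
#' the threshold stage.
#'
#' @param image integer intensity matrix (see [read_array_image()]).
#' @param layout an [array_layout()].
#' @return data.frame `spot_id`, `role`, `peptide`, `iod`.
#' @export
measure_iod <- function(image, layout) {
  stopifnot(is.matrix(image))
  if (any(image < 0)) pz_stop("bad_image", "negative intensities")
  nr <- nrow(image); nc <- ncol(image)
  if (any(layout$row - layout$radius < 0.5 | layout$row + layout$radius > nr + 0.5 |
          layout$col - layout$radius < 0.5 | layout$col + layout$radius > nc + 0.5)) {
    pz_stop("circle_out_of_bounds", "a layout circle extends outside the image")
  }
  iod <- vapply(seq_len(nrow(layout)), function(i) {
    idx <- circle_mask_idx(nr, nc, layout$row[i], layout$col[i], layout$radius[i])
    if (!length(idx)) {
      pz_stop("empty_circle", sprintf("spot %s: no pixel center inside radius %g",
                                      layout$spot_id[i], layout$radius[i]))
    }
    sum(as.numeric(image[idx]))
  }, numeric(1))
  data.frame(spot_id = layout$spot_id, role = layout$role,
             peptide = layout$peptide, iod = iod, stringsAsFactors = FALSE)
}

#' Background-plus-kSD positivity threshold
#'
#' Per-slide threshold: mean IOD of the negative (buffer-only) spots plus
#' `k` times the sample standard deviation of `n_random` randomly sampled
#' peptide spots. The sample is seeded and the sampled ids recorded so a
#' slide's call set is exactly reproducible.
#'
#' @param quants per-spot IODs from [measure_iod()].
#' @param n_random number of peptide spots sampled for the SD (default 15);
#'   use `n_random = "all"` to take every peptide spot instead.
#' @param k SD multiplier (default 2).
#' @param seed integer seed for the random sample.
#' @return object of class `"threshold_model"` with fields `neg_mean`,
#'   `rand_sd`, `k`, `threshold`, `sampled_ids`, `seed`.
#' @export
compute_threshold <- function(quants, n_random = 15L, k = 2, seed = 1L) {
  negs <- quants$iod[quants$role == "negative"]
  peps <- quants[quants$role == "peptide", , drop = FALSE]
  if (length(negs) < 5L) {
    pz_stop("insufficient_negatives", "need at least 5 negative spots")
  }
  all_peps <- identical(n_random, "all")
  if (!all_peps) {
    n_random <- as.integer(n_random)
    if (nrow(peps) < n_random) {
      pz_stop("insufficient_peptides",
              sprintf("need at least %d peptide spots", n_random))
    }
  }
  if (all_peps) {
    sampled <- peps
  } else {
    sampled <- pz_with_seed(seed, peps[sample.int(nrow(peps), n_random), , drop = FALSE])
  }
  neg_mean <- mean(negs)
  rand_sd <- stats::sd(sampled$iod)
  structure(list(
    neg_mean = neg_mean,
    rand_sd = rand_sd,
    k = k,
    threshold = neg_mean + k * rand_sd,
    sampled_ids = sort(sampled$spot_id),
    seed = if (all_peps) NA_integer_ else as.integer(seed)
  ), class = "threshold_model")
}

#' @export
print.threshold_model <- function(x, ...) {
  cat(sprintf(
    "<threshold_model> neg_mean=%.3g, rand_sd=%.3g (n=%d spots), k=%g -> threshold=%.4g\n",
    x$neg_mean, x$rand_sd, length(x$sampled_ids), x$k, x$threshold))
  invisible(x)
}

#' Call positive peptides on a slide
#'
#' A peptide spot is positive when its IOD minus the slide threshold is
#' strictly greater than zero.
#'
#' @param quants per-spot IODs from [measure_iod()].
#' @param model a [compute_threshold()] model from the same slide.
#' @return logical vector named by peptide index, in peptide order.
#' @export
call_positive <- function(quants, model) {
  stopifnot(inherits(model, "threshold_model"))
  peps <- quants[quants$role == "peptide", , drop = FALSE]
  peps <- peps[order(peps$peptide), , drop = FALSE]
  stats::setNames(peps$iod - model$threshold > 0, peps$peptide)
}

#' Write per-spot quantifications and calls
#'
#' @param quants from [measure_iod()].
#' @param path output TSV.
#' @param model optional [compute_threshold()] model; when given, a
#'   `positive` column is included and the seed/sampled ids are logged in
#'   the header.
#' @export
write_quants_tsv <- function(quants, path, model = NULL) {
  if (!is.null(model)) {
    quants$positive <- quants$role == "peptide" & quants$iod - model$threshold > 0
    meta <- list(threshold = model$threshold, seed = model$seed,
                 sampled_ids = model$sampled_ids)
    return(pz_write_tsv(quants, path, config = meta))
  }
  pz_write_tsv(quants, path)
}
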