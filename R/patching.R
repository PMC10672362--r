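#' Analysis-patch geometry
#'
#' An analysis patch is the \code{Lt x Nx} window of the noisy image whose
#' contents predict the output at its anchor pixel: \code{Lt} depth (row)
#' samples ending at the anchor row, and \code{Nx} consecutive columns
#' reaching \code{nL} to the left and \code{nR} to the right of the anchor
#' column (\code{nL + nR = Nx - 1}). The per-step output dimension \code{P}
#' is 1 for patch-to-pixel prediction or \code{Nx} for patch-to-patch
#' prediction (used by the averaging / adversarial variants).
#'
#' @param Lt Depth samples per patch (default 15).
#' @param Nx Lateral columns per patch (default 15).
#' @param nL,nR Lateral reach left/right of the anchor column; default
#'   symmetric (\code{(Nx-1)/2} each, requires odd \code{Nx}).
#' @param P Output dimension per recurrence step, 1 or \code{Nx}.
#' @return An object of class \code{analysis_patch_config}.
#' @export
analysis_patch_config <- function(Lt = 15L, Nx = 15L, nL = NULL, nR = NULL,
                                  P = 1L) {
  Lt <- as.integer(Lt); Nx <- as.integer(Nx); P <- as.integer(P)
  if (Lt < 1L || Nx < 1L) stop("Lt and Nx must be >= 1")
  if (is.null(nL) && is.null(nR)) {
    if (Nx %% 2L != 1L) stop("default symmetric reach requires odd Nx; give nL/nR")
    nL <- nR <- (Nx - 1L) %/% 2L
  }
  nL <- as.integer(nL); nR <- as.integer(nR)
  if (nL < 0L || nR < 0L || nL + nR != Nx - 1L) {
    stop("need nL + nR = Nx - 1 with nL, nR >= 0")
  }
  if (!(P == 1L || P == Nx)) stop("P must be 1 (patch-to-pixel) or Nx (patch-to-patch)")
  structure(list(Lt = Lt, Nx = Nx, nL = nL, nR = nR, P = P),
            class = "analysis_patch_config")
}

#' Extract one analysis patch
#'
#' Returns the \code{Lt x Nx} window anchored at pixel \code{(i, j)} (1-based;
#' the anchor is the patch's bottom row and its column sits \code{nL} columns
#' from the patch's left edge). Indices falling outside the image are
#' replicate-padded from the nearest edge, so every image pixel has a
#' full-size patch.
#'
#' @param image A [log_image()] or numeric matrix.
#' @param i,j Anchor row / column (1-based, inside the image).
#' @param cfg An [analysis_patch_config()].
#' @return \code{Lt x Nx} numeric matrix.
#' @export
extract_analysis_patch <- function(image, i, j, cfg) {
  v <- if (inherits(image, "log_image")) image$values else as.matrix(image)
  nr <- nrow(v); nc <- ncol(v)
  i <- as.integer(i); j <- as.integer(j)
  if (i < 1L || i > nr || j < 1L || j > nc) {
    stop(sprintf("anchor (%d, %d) outside the %d x %d image", i, j, nr, nc))
  }
  rows <- pmin(pmax(seq.int(i - cfg$Lt + 1L, i), 1L), nr)
  cols <- pmin(pmax(seq.int(j - cfg$nL, j + cfg$nR), 1L), nc)
  v[rows, cols, drop = FALSE]
}

#' Build a supervised patch dataset from one training pair
#'
#' One training instance per pixel of the chosen region: the input is the
#' analysis patch of the noisy image anchored at that pixel; the target is
#' the clean image's depth segment ending at the anchor (\code{P = 1}) or the
#' clean \code{Lt x Nx} patch at the same anchor (\code{P = Nx}). Inputs and
#' targets are mapped to \code{[0, 1]} by the same affine, taken from the
#' noisy training image's value range; the affine is stored for inference.
#'
#' @param noisy,clean [log_image()]s of identical shape.
#' @param cfg An [analysis_patch_config()].
#' @param region Optional list with integer vectors \code{rows} and/or
#'   \code{cols} selecting the anchor region (defaults to the full image).
#'   E.g. \code{list(cols = 1:100)} trains on the first 100 columns.
#' @return An object of class \code{patch_dataset}: list with \code{inputs}
#'   (array \code{m x Lt x Nx}), \code{targets} (\code{m x Lt} or
#'   \code{m x Lt x Nx}), \code{anchors} (\code{m x 2}), \code{normalization}
#'   (the dB affine), \code{cfg}, and \code{m}.
#' @export
build_dataset <- function(noisy, clean, cfg, region = NULL) {
  stopifnot(inherits(noisy, "log_image"), inherits(clean, "log_image"),
            inherits(cfg, "analysis_patch_config"))
  if (!identical(dim(noisy$values), dim(clean$values))) {
    stop("noisy and clean images must have the same shape")
  }
  nr <- nrow(noisy$values); nc <- ncol(noisy$values)
  rows <- if (!is.null(region$rows)) as.integer(region$rows) else seq_len(nr)
  cols <- if (!is.null(region$cols)) as.integer(region$cols) else seq_len(nc)
  if (any(rows < 1L) || any(rows > nr) || any(cols < 1L) || any(cols > nc)) {
    stop("region outside the image")
  }
  norm <- normalize_db(noisy$values)
  Yn <- norm$values
  Xn <- (clean$values - norm$scale[["lo"]]) /
    (norm$scale[["hi"]] - norm$scale[["lo"]])

  anchors <- as.matrix(expand.grid(i = rows, j = cols))
  m <- nrow(anchors)
  ai <- anchors[, 1L]; aj <- anchors[, 2L]

  inputs <- array(0, c(m, cfg$Lt, cfg$Nx))
  for (t in seq_len(cfg$Lt)) {
    ri <- pmin(pmax(ai - cfg$Lt + t, 1L), nr)
    for (u in seq_len(cfg$Nx)) {
      cu <- pmin(pmax(aj - cfg$nL + u - 1L, 1L), nc)
      inputs[, t, u] <- Yn[ri + (cu - 1L) * nr]
    }
  }
  if (cfg$P == 1L) {
    targets <- matrix(0, m, cfg$Lt)
    for (t in seq_len(cfg$Lt)) {
      ri <- pmin(pmax(ai - cfg$Lt + t, 1L), nr)
      targets[, t] <- Xn[ri + (aj - 1L) * nr]
    }
  } else {
    targets <- array(0, c(m, cfg$Lt, cfg$Nx))
    for (t in seq_len(cfg$Lt)) {
      ri <- pmin(pmax(ai - cfg$Lt + t, 1L), nr)
      for (u in seq_len(cfg$Nx)) {
        cu <- pmin(pmax(aj - cfg$nL + u - 1L, 1L), nc)
        targets[, t, u] <- Xn[ri + (cu - 1L) * nr]
      }
    }
  }
  structure(list(inputs = inputs, targets = targets, anchors = anchors,
                 normalization = norm$scale, cfg = cfg, m = m),
            class = "patch_dataset")
}

#' @export
print.patch_dataset <- function(x, ...) {
  cat(sprintf("<patch_dataset> m = %d instances, patch %d x %d, P = %d\n",
              x$m, x$cfg$Lt, x$cfg$Nx, x$cfg$P))
  invisible(x)
}

#' Reconstruct an image from overlapping patch predictions
#'
#' Every predicted patch entry is mapped back to its image coordinates (via
#' the anchor and the patch geometry) and each output pixel is the arithmetic
#' mean of all patch entries covering it. Coverage counts are accumulated
#' explicitly and returned; pixels no patch covers are left \code{NA}.
#'
#' @param patch_predictions Array \code{m x Lt x Nx} of predicted patches (or
#'   a list of \code{Lt x Nx} matrices).
#' @param anchors \code{m x 2} matrix of 1-based anchor (row, column) pairs.
#' @param shape Output image size \code{c(rows, cols)}.
#' @param cfg The [analysis_patch_config()] the patches were extracted with.
#' @return List with \code{values} (the reconstructed matrix) and
#'   \code{coverage} (per-pixel contribution counts).
#' @export
overlap_average_reconstruct <- function(patch_predictions, anchors, shape, cfg) {
  if (is.list(patch_predictions) && !is.array(patch_predictions)) {
    if (!length(patch_predictions)) stop("empty prediction list")
    arr <- array(0, c(length(patch_predictions), cfg$Lt, cfg$Nx))
    for (k in seq_along(patch_predictions)) arr[k, , ] <- patch_predictions[[k]]
    patch_predictions <- arr
  }
  if (!is.array(patch_predictions) || length(dim(patch_predictions)) != 3L ||
      dim(patch_predictions)[1] == 0L) {
    stop("patch_predictions must be a nonempty m x Lt x Nx array")
  }
  anchors <- as.matrix(anchors)
  nr <- as.integer(shape[1]); nc <- as.integer(shape[2])
  if (any(anchors[, 1] < 1L) || any(anchors[, 1] > nr) ||
      any(anchors[, 2] < 1L) || any(anchors[, 2] > nc)) {
    stop("anchors outside the output shape")
  }
  acc <- matrix(0, nr, nc); cover <- matrix(0L, nr, nc)
  ai <- anchors[, 1L]; aj <- anchors[, 2L]
  for (t in seq_len(cfg$Lt)) {
    ri <- ai - cfg$Lt + t
    ok_r <- ri >= 1L & ri <= nr
    for (u in seq_len(cfg$Nx)) {
      cu <- aj - cfg$nL + u - 1L
      ok <- ok_r & cu >= 1L & cu <= nc
      if (!any(ok)) next
      idx <- ri[ok] + (cu[ok] - 1L) * nr
      acc[idx] <- acc[idx] + patch_predictions[ok, t, u]
      cover[idx] <- cover[idx] + 1L
    }
  }
  vals <- acc / ifelse(cover > 0L, cover, NA_integer_)
  list(values = vals, coverage = cover)
}

#' Save / load a patch dataset
#'
#' Serializes a [build_dataset()] result to an RDS container plus a JSON
#' manifest (shape, patch geometry, normalization affine) for reproducible
#' retraining.
#'
#' @param dataset A \code{patch_dataset}.
#' @param path Output path (\code{.rds}; the manifest gets \code{.json}).
#' @return \code{path}, invisibly (\code{load_patch_dataset} returns the
#'   dataset).
#' @export
save_patch_dataset <- function(dataset, path) {
  stopifnot(inherits(dataset, "patch_dataset"))
  saveRDS(dataset, path)
  manifest <- list(m = dataset$m, Lt = dataset$cfg$Lt, Nx = dataset$cfg$Nx,
                   P = dataset$cfg$P,
                   normalization = as.list(dataset$normalization))
  jsonlite::write_json(manifest, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_patch_dataset
#' @export
load_patch_dataset <- function(path) {
  ds <- readRDS(path)
  if (!inherits(ds, "patch_dataset")) stop("not a patch_dataset file")
  ds
}
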