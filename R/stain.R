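# Optical-density transform and H&E color deconvolution.
#
# Stains mix additively in optical-density (OD) space (Beer-Lambert):
# OD_c = -log10(I_c / I0_c). A 3x3 stain basis M (rows = unit OD vectors of
# hematoxylin, eosin and an orthogonal residual) relates per-pixel stain
# amounts Y (row vector) to observed OD phi by phi = Y %*% M, so deconvolution
# is the linear solve Y = phi %*% solve(M).

#' Construct a stain matrix
#'
#' A stain matrix holds three unit optical-density row vectors over the R, G,
#' B channels: hematoxylin, eosin, and a residual that completes the basis.
#'
#' @param rows numeric 3x3 matrix; rows are stains, columns R, G, B.
#' @param source provenance tag, `"reference"` for the built-in H&E basis or
#'   `"custom"` for user-supplied vectors.
#' @return An object of class `stain_matrix` (a 3x3 matrix with attributes).
#' @export
stain_matrix <- function(rows, source = "custom") {
  rows <- as.matrix(rows)
  if (!all(dim(rows) == c(3L, 3L))) stop("stain matrix must be 3x3")
  norms <- sqrt(rowSums(rows[1:2, , drop = FALSE]^2))
  if (any(abs(norms - 1) > 1e-3)) {
    stop("stain rows must have unit Euclidean norm (within 1e-3); ",
         "use normalize_stain_rows() first")
  }
  if (abs(det(rows)) < 1e-12) stop("stain matrix is singular; deconvolution ill-posed")
  rownames(rows) <- c("hematoxylin", "eosin", "residual")
  colnames(rows) <- c("R", "G", "B")
  structure(rows, source = source, class = c("stain_matrix", "matrix", "array"))
}

#' Reference H&E optical-density stain basis
#'
#' The standard normalized H&E basis with hematoxylin row
#' (0.6442, 0.7166, 0.2668) and eosin row (0.0928, 0.9541, 0.2831). The
#' residual row, left empty in two-stain work, is completed as the normalized
#' cross product of the two stain rows so the basis is invertible without
#' altering the H/E geometry.
#'
#' @return A [stain_matrix()] with `source = "reference"`.
#' @export
he_stain_matrix <- function() {
  h <- c(0.6442, 0.7166, 0.2668)
  e <- c(0.0928, 0.9541, 0.2831)
  r <- cross3(h, e)
  r <- r / sqrt(sum(r^2))
  stain_matrix(rbind(h, e, r), source = "reference")
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Normalize raw stain rows to unit length
#'
#' Each nonzero row is divided by its Euclidean length. An all-zero row is
#' replaced by the orthogonal completion of the remaining two (their
#' normalized cross product). Parallel stain rows leave the deconvolution
#' ill-posed and raise an error.
#'
#' @param raw numeric 3x3 matrix of raw OD values, rows = stains.
#' @inheritParams stain_matrix
#' @return A [stain_matrix()].
#' @export
normalize_stain_rows <- function(raw, source = "custom") {
  raw <- as.matrix(raw)
  if (!all(dim(raw) == c(3L, 3L))) stop("raw stain matrix must be 3x3")
  norms <- sqrt(rowSums(raw^2))
  out <- raw
  for (i in 1:3) if (norms[i] > 0) out[i, ] <- raw[i, ] / norms[i]
  zero <- which(norms == 0)
  if (length(zero) > 1L) stop("at most one all-zero stain row can be completed")
  if (length(zero) == 1L) {
    others <- setdiff(1:3, zero)
    r <- cross3(out[others[1], ], out[others[2], ])
    nr <- sqrt(sum(r^2))
    if (nr < 1e-9) stop("stain rows are parallel; deconvolution ill-posed")
    out[zero, ] <- r / nr
  }
  if (abs(det(out)) < 1e-9) stop("stain rows are parallel; deconvolution ill-posed")
  stain_matrix(out, source = source)
}

#' Convert an RGB raster to optical densities
#'
#' `OD_c = -log10(max(I_c, eps) / I0_c)` per channel, clipped at zero from
#' below. The intensity floor `eps` makes the map total on black pixels; it
#' is set well below one intensity unit so it never binds on 8-bit data
#' (whose smallest positive value is 1) yet leaves the continuous forward
#' model exactly invertible for stain amounts up to ~5 OD units.
#'
#' @param raster numeric H x W x 3 array with channel intensities in
#'   `[0, 255]` (continuous values allowed).
#' @param I0 reference white level per channel (scalar or length 3).
#' @param eps intensity floor, default `1e-6`.
#' @return Object of class `od_image`: H x W x 3 array of ODs with the
#'   reference white stored in attribute `I0`.
#' @export
rgb_to_od <- function(raster, I0 = 255, eps = 1e-6) {
  stopifnot(length(dim(raster)) == 3L, dim(raster)[3] == 3L, all(I0 > 0))
  I0 <- rep_len(I0, 3L)
  od <- raster
  for (k in 1:3) od[, , k] <- -log10(pmax(raster[, , k], eps) / I0[k])
  od[od < 0] <- 0
  structure(od, I0 = I0, class = c("od_image", "array"))
}

#' Deconvolve an OD image into per-pixel stain amounts
#'
#' Solves the per-pixel linear system `phi = Y %*% M` for the stain amounts
#' `Y` (hematoxylin, eosin, residual). Amounts may be negative under noise;
#' they are clipped only where physical non-negativity is consumed (the
#' foreground eosin map).
#'
#' @param od an [rgb_to_od()] result or any H x W x 3 OD array.
#' @param matrix a [stain_matrix()].
#' @return H x W x 3 array of stain amounts (planes: hematoxylin, eosin,
#'   residual), class `stain_amounts`.
#' @export
deconvolve <- function(od, matrix = he_stain_matrix()) {
  if (abs(det(unclass(matrix))) < 1e-12) stop("stain matrix is singular")
  dims <- dim(od)
  phi <- flatten_px(unclass(od))
  amounts <- phi %*% solve(unclass(matrix))
  structure(unflatten_px(amounts, dims), class = c("stain_amounts", "array"))
}

#' Recompose optical densities from stain amounts (forward model)
#'
#' @param amounts H x W x 3 stain-amount array.
#' @param matrix a [stain_matrix()].
#' @return H x W x 3 OD array.
#' @export
compose_od <- function(amounts, matrix = he_stain_matrix()) {
  dims <- dim(amounts)
  unflatten_px(flatten_px(unclass(amounts)) %*% unclass(matrix), dims)
}

#' Render stain amounts to transmitted RGB intensities
#'
#' Beer-Lambert forward model: `I_c = I0_c * 10^(-OD_c)`. Continuous
#' intensities are returned; quantization to 8-bit happens only on file
#' output.
#'
#' @inheritParams compose_od
#' @param I0 reference white per channel.
#' @return H x W x 3 RGB array in `[0, I0]`.
#' @export
render_rgb <- function(amounts, matrix = he_stain_matrix(), I0 = 255) {
  od <- compose_od(amounts, matrix)
  I0 <- rep_len(I0, 3L)
  out <- od
  for (k in 1:3) out[, , k] <- I0[k] * 10^(-od[, , k])
  out
}

#' Extract the eosin channel from stain amounts
#'
#' @param amounts a [deconvolve()] result.
#' @param clip clip negative amounts at zero (used for the foreground map).
#' @return H x W matrix of eosin amounts.
#' @export
eosin_channel <- function(amounts, clip = FALSE) {
  e <- unclass(amounts)[, , 2, drop = FALSE]
  dim(e) <- dim(amounts)[1:2]
  if (clip) e[e < 0] <- 0
  e
}

#' Read / write a stain matrix as 3x3 CSV
#' @param path file path.
#' @inheritParams stain_matrix
#' @return `read_stain_matrix` returns a [stain_matrix()];
#'   `write_stain_matrix` returns `path` invisibly.
#' @export
read_stain_matrix <- function(path, source = "custom") {
  m <- as.matrix(utils::read.csv(path, header = FALSE))
  storage.mode(m) <- "double"
  norms <- sqrt(rowSums(m^2))
  # already-normalized bases (e.g. a written reference matrix) pass through
  # untouched; raw OD vectors are normalized and completed
  if (all(abs(norms - 1) < 1e-3)) stain_matrix(m, source = source)
  else normalize_stain_rows(m, source = source)
}

#' @rdname read_stain_matrix
#' @param matrix a [stain_matrix()].
#' @export
write_stain_matrix <- function(matrix, path) {
  utils::write.table(unclass(matrix), path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}
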