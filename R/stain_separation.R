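# Colour deconvolution of H-DAB brightfield images.
#
# Transmitted-light images mix stains multiplicatively; in optical density
# (OD = log10(incident/transmitted)) co-localised stains add linearly, so a
# pixel's OD 3-vector is a linear combination of unit stain vectors and the
# per-stain amounts are recovered by inverting the stain matrix.

#' Convert an 8-bit RGB image to optical density
#'
#' Applies the Beer-Lambert transform `od = log10(i0 / I)` per channel, with
#' transmitted intensity `I` clamped to at least 1 so fully dark pixels map to
#' a finite maximal absorbance rather than infinity.
#'
#' @param img Numeric array (height x width x 3) or matrix of 8-bit
#'   intensities in `[0, 255]`.
#' @param i0 Reference white intensity (incident light). Default 255, the
#'   maximum of an 8-bit image.
#' @return An array of the same shape holding non-negative base-10 optical
#'   densities. A pixel at `i0` has OD exactly 0.
#' @seealso [od_to_rgb()] for the inverse, [deconvolve()] for stain
#'   separation of the result.
#' @export
#' @examples
#' rgb_to_od(array(128, c(2, 2, 3)))[1, 1, ]   # ~0.2994 per channel
rgb_to_od <- function(img, i0 = 255) {
  if (!is.numeric(i0) || length(i0) != 1L || !is.finite(i0) || i0 <= 0) {
    stop("`i0` must be a single positive, finite number", call. = FALSE)
  }
  if (!is.numeric(img)) stop("`img` must be numeric", call. = FALSE)
  if (any(img < 0 | img > 255)) {
    stop("`img` intensities must lie in [0, 255]", call. = FALSE)
  }
  od <- log10(i0 / pmax(img, 1))
  od[od < 0] <- 0
  od
}

#' Render optical density back to an 8-bit RGB image
#'
#' Inverse of [rgb_to_od()]: `I = round(i0 * 10^(-od))`, clamped to
#' `[0, 255]`. Used as the forward imaging model by the synthetic core
#' generator.
#'
#' @param od Non-negative optical-density array (any shape).
#' @inheritParams rgb_to_od
#' @return Integer-valued array of the same shape with values in `[0, 255]`.
#' @export
od_to_rgb <- function(od, i0 = 255) {
  if (!is.numeric(i0) || length(i0) != 1L || !is.finite(i0) || i0 <= 0) {
    stop("`i0` must be a single positive, finite number", call. = FALSE)
  }
  if (!is.numeric(od) || any(!is.finite(od))) {
    stop("`od` must be finite and numeric", call. = FALSE)
  }
  if (any(od < 0)) stop("`od` must be non-negative", call. = FALSE)
  v <- round(i0 * 10^(-od))
  v[v < 0] <- 0
  v[v > 255] <- 255
  storage.mode(v) <- "integer"
  v
}

#' The H-DAB stain matrix
#'
#' Unit optical-density vectors for hematoxylin and DAB from the
#' Ruifrok-Johnston colour-deconvolution basis, with the residual (third)
#' vector taken as the normalised cross product of the two, so the matrix is
#' always invertible. Rows are stains, columns are the R, G, B channels.
#'
#' @return A 3 x 3 numeric matrix with rows `hematoxylin`, `dab`, `residual`
#'   and columns `R`, `G`, `B`; each row has unit Euclidean norm.
#' @references Ruifrok AC, Johnston DA (2001). Quantification of histochemical
#'   staining by color deconvolution. Anal Quant Cytol Histol 23(4):291-299.
#' @export
hdab_stain_matrix <- function() {
  h <- c(0.650, 0.704, 0.286)
  d <- c(0.269, 0.568, 0.778)
  h <- h / sqrt(sum(h^2))
  d <- d / sqrt(sum(d^2))
  r <- c(
    h[2] * d[3] - h[3] * d[2],
    h[3] * d[1] - h[1] * d[3],
    h[1] * d[2] - h[2] * d[1]
  )
  r <- r / sqrt(sum(r^2))
  m <- rbind(hematoxylin = h, dab = d, residual = r)
  colnames(m) <- c("R", "G", "B")
  m
}

#' Validate a stain matrix
#'
#' Checks that `m` is a numeric 3 x 3 matrix with unit-norm rows and a finite
#' condition number. Used when a user supplies a custom basis through the
#' pipeline configuration.
#'
#' @param m Candidate stain matrix (rows = stains, columns = R, G, B).
#' @param tol Tolerance on the unit-norm check.
#' @return `m`, invisibly, with default dimnames filled in if absent.
#' @export
validate_stain_matrix <- function(m, tol = 1e-6) {
  if (!is.matrix(m) || !is.numeric(m) || !all(dim(m) == c(3L, 3L))) {
    stop("stain matrix must be a numeric 3 x 3 matrix", call. = FALSE)
  }
  norms <- sqrt(rowSums(m^2))
  if (any(abs(norms - 1) > tol)) {
    stop("stain matrix rows must have unit Euclidean norm", call. = FALSE)
  }
  if (!is.finite(rcond(m)) || rcond(m) < 1e-12) {
    stop("stain matrix is singular or ill-conditioned", call. = FALSE)
  }
  if (is.null(rownames(m))) rownames(m) <- c("hematoxylin", "dab", "residual")
  if (is.null(colnames(m))) colnames(m) <- c("R", "G", "B")
  invisible(m)
}

#' Separate stain contributions by matrix inversion
#'
#' Solves the Beer-Lambert mixing model per pixel: the OD 3-vector equals the
#' stain amounts multiplied by the stain matrix, so amounts are recovered with
#' the exact linear inverse. No non-negativity clamp is applied here -- small
#' negative amounts from quantisation noise are preserved so the operation
#' stays exactly linear and invertible; clamping happens only when rendering a
#' single-stain image with [concentration_to_gray8()].
#'
#' @param od Optical-density array (height x width x 3) from [rgb_to_od()],
#'   or an n x 3 matrix of OD vectors.
#' @param m Stain matrix, by default [hdab_stain_matrix()].
#' @return An object of the same shape as `od` holding per-pixel stain
#'   amounts (OD units); the stain dimension is named after the rows of `m`.
#' @export
deconvolve <- function(od, m = hdab_stain_matrix()) {
  validate_stain_matrix(m)
  inv <- solve(m)
  if (is.matrix(od)) {
    if (ncol(od) != 3L) stop("`od` matrix must have 3 columns", call. = FALSE)
    out <- od %*% inv
    colnames(out) <- rownames(m)
    return(out)
  }
  d <- dim(od)
  if (length(d) != 3L || d[3] != 3L) {
    stop("`od` must be a height x width x 3 array or an n x 3 matrix",
      call. = FALSE
    )
  }
  flat <- matrix(od, ncol = 3L) %*% inv
  out <- array(flat, dim = d)
  dimnames(out) <- list(NULL, NULL, rownames(m))
  out
}

#' Render one stain's amounts as an 8-bit grayscale image
#'
#' Converts a stain amount map to the transmitted-intensity convention used
#' for histogram scoring: `gray = round(255 * 10^(-max(c, 0)))`, so 255 means
#' no stain and 0 means maximal stain. Negative amounts (deconvolution noise)
#' are clamped to zero here.
#'
#' @param conc Stain amount array from [deconvolve()] (height x width x 3
#'   with a named stain dimension).
#' @param stain One of `"hematoxylin"`, `"dab"`, `"residual"` (or whatever
#'   names the stain matrix used).
#' @return Integer matrix (height x width) with values in `[0, 255]`.
#' @export
concentration_to_gray8 <- function(conc, stain) {
  d <- dim(conc)
  if (is.null(d) || length(d) != 3L || d[3] != 3L) {
    stop("`conc` must be a height x width x 3 stain amount array",
      call. = FALSE
    )
  }
  stains <- dimnames(conc)[[3]]
  if (is.null(stains)) stains <- c("hematoxylin", "dab", "residual")
  if (!is.character(stain) || length(stain) != 1L || !stain %in% stains) {
    stop(sprintf(
      "unknown stain '%s'; expected one of: %s",
      as.character(stain)[1], paste(stains, collapse = ", ")
    ), call. = FALSE)
  }
  cmap <- conc[, , match(stain, stains)]
  g <- round(255 * 10^(-pmax(cmap, 0)))
  g[g < 0] <- 0L
  g[g > 255] <- 255L
  storage.mode(g) <- "integer"
  g
}
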