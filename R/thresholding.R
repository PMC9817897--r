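# Histogram auto-thresholding: the two ImageJ algorithms used for core
# scoring ("Minimum" for tissue selection, "Default"/legacy IsoData for DAB
# positivity) plus histogram and mask utilities.

# round half-down to an integer, the tie rule used by both threshold
# iterations so several tying levels resolve to the lowest
round_half_down <- function(x) ceiling(x - 0.5)

#' 256-bin histogram of an 8-bit grayscale image
#'
#' @param img Integer-valued matrix with values in `[0, 255]`.
#' @param mask Optional logical matrix of the same dimensions restricting the
#'   histogram to `TRUE` pixels.
#' @return Integer vector of length 256; element `v + 1` counts pixels of
#'   gray level `v`.
#' @export
histogram_256 <- function(img, mask = NULL) {
  if (!is.numeric(img) || any(img < 0 | img > 255) ||
    any(img != floor(img))) {
    stop("`img` must contain integers in [0, 255]", call. = FALSE)
  }
  v <- if (is.null(mask)) {
    as.vector(img)
  } else {
    if (!identical(dim(mask), dim(img))) {
      stop("`mask` dimensions must match `img`", call. = FALSE)
    }
    img[mask]
  }
  if (length(v) == 0L) {
    stop("empty region: mask selects no pixels", call. = FALSE)
  }
  tabulate(as.integer(v) + 1L, nbins = 256L)
}

# one pass of the 3-point moving mean; edge bins average over the neighbours
# that exist (2 values at each end)
smooth_histogram_once <- function(x) {
  n <- length(x)
  s <- x
  s[2:(n - 1)] <- (x[1:(n - 2)] + x[2:(n - 1)] + x[3:n]) / 3
  s[1] <- (x[1] + x[2]) / 2
  s[n] <- (x[n - 1] + x[n]) / 2
  s
}

# local maxima of a histogram, plateau-aware: a maximal run of equal values
# that is higher than both neighbouring runs is one maximum (smoothing
# integer counts produces exact ties, so a strict per-bin test would let a
# real mode vanish for an iteration). Edge runs qualify against their single
# neighbour, so a background spike at gray 255 counts as a mode. Returns the
# first and last bin of each maximal run.
local_maxima_runs <- function(x) {
  r <- rle(x)
  v <- r$values
  k <- length(v)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  above_left <- c(TRUE, v[-1L] > v[-k])
  above_right <- c(v[-k] > v[-1L], TRUE)
  is_max <- above_left & above_right
  list(starts = starts[is_max], ends = ends[is_max])
}

#' "Minimum" auto-threshold
#'
#' The bimodal valley-seeking algorithm behind ImageJ's *Minimum* method
#' (Prewitt & Mendelsohn): the histogram is repeatedly smoothed with a
#' 3-point moving mean until exactly two local maxima remain, and the
#' threshold is the lowest gray level strictly between them at which the
#' smoothed histogram is minimal. Used here to separate tissue (dark) from
#' the white slide background.
#'
#' @param h Integer vector of 256 counts from [histogram_256()].
#' @param max_iter Smoothing iteration cap; a histogram that never becomes
#'   bimodal (single spike, strictly unimodal shape) raises a
#'   bimodality-failure error when the cap is reached.
#' @return A single integer gray level in `[0, 255]`.
#' @references Prewitt JMS, Mendelsohn ML (1966). The analysis of cell
#'   images. Ann N Y Acad Sci 128:1035-1053.
#' @export
threshold_minimum <- function(h, max_iter = 10000L) {
  h <- check_histogram(h)
  x <- as.numeric(h)
  iter <- 0L
  repeat {
    mx <- local_maxima_runs(x)
    if (length(mx$starts) == 2L) break
    if (iter >= max_iter) {
      stop("bimodality failure: histogram did not become bimodal after ",
        max_iter, " smoothing iterations",
        call. = FALSE
      )
    }
    x <- smooth_histogram_once(x)
    iter <- iter + 1L
  }
  inner <- (mx$ends[1] + 1L):(mx$starts[2] - 1L)
  t_bin <- inner[which.min(x[inner])]
  as.integer(t_bin - 1L)
}

#' "Default" (legacy IsoData) auto-threshold
#'
#' The intermeans iteration that ImageJ's *Default* method implements:
#' starting from the midpoint of the occupied gray range, the threshold is
#' replaced by the rounded mean of (mean gray at or below it, mean gray above
#' it) until a fixed point is reached. Arithmetic means are rounded half-down
#' so ties resolve to the lowest qualifying level. Used here to pick
#' DAB-positive pixels on the deconvolved DAB image.
#'
#' @inheritParams threshold_minimum
#' @return A single integer gray level; the fixed point of the intermeans
#'   update. Pixels at or below it are on the dark (stained) side.
#' @references Ridler TW, Calvard S (1978). Picture thresholding using an
#'   iterative selection method. IEEE Trans Syst Man Cybern 8:630-632.
#' @export
threshold_default_isodata <- function(h) {
  h <- check_histogram(h)
  occ <- which(h > 0L) - 1L
  if (length(occ) < 2L) {
    stop("degenerate histogram: fewer than two occupied gray levels",
      call. = FALSE
    )
  }
  lev <- 0:255
  t_cur <- round_half_down((min(occ) + max(occ)) / 2)
  seen <- integer(0)
  repeat {
    below <- lev <= t_cur
    m_low <- sum(h[below] * lev[below]) / sum(h[below])
    m_high <- sum(h[!below] * lev[!below]) / sum(h[!below])
    t_new <- round_half_down((m_low + m_high) / 2)
    if (t_new == t_cur) {
      return(as.integer(t_cur))
    }
    if (t_new %in% seen) {
      # oscillation between candidate levels: take the lowest of the cycle
      return(as.integer(min(t_new, t_cur)))
    }
    seen <- c(seen, t_cur)
    t_cur <- t_new
  }
}

#' Materialise a threshold as a binary mask
#'
#' @param img Integer-valued grayscale matrix in `[0, 255]`.
#' @param t Threshold gray level in `[0, 255]`.
#' @param select `"dark"` marks pixels with value `<= t` (stained side under
#'   the 255-is-unstained convention); `"light"` marks pixels `> t`.
#' @return Logical matrix of the same dimensions.
#' @export
apply_threshold <- function(img, t, select = c("dark", "light")) {
  select <- match.arg(select)
  if (!is.numeric(t) || length(t) != 1L || t < 0 || t > 255) {
    stop("`t` must be a single gray level in [0, 255]", call. = FALSE)
  }
  if (select == "dark") img <= t else img > t
}

check_histogram <- function(h) {
  if (!is.numeric(h) || length(h) != 256L || any(h < 0) ||
    any(!is.finite(h))) {
    stop("`h` must be 256 non-negative counts", call. = FALSE)
  }
  if (sum(h) <= 0) stop("`h` must have a positive total count", call. = FALSE)
  h
}
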