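# Per-core immunoreactive scoring: tissue mask -> stain separation -> DAB
# mask -> percent area and DABwt% -> IRS (their product).

#' Rec.601 luminance of an RGB image, rounded to 8 bits
#'
#' @param img Numeric array (height x width x 3) with values in `[0, 255]`.
#' @return Integer matrix of gray levels, the standard 8-bit conversion used
#'   before tissue thresholding.
#' @export
luminance_8bit <- function(img) {
  d <- dim(img)
  if (is.null(d) || length(d) != 3L || d[3] != 3L) {
    stop("`img` must be a height x width x 3 RGB array", call. = FALSE)
  }
  g <- round(0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3])
  g[g < 0] <- 0L
  g[g > 255] <- 255L
  storage.mode(g) <- "integer"
  g
}

#' Tissue mask of a brightfield core image
#'
#' Converts the image to Rec.601 luminance and applies the "Minimum"
#' auto-threshold; tissue is the dark side (tissue absorbs light, the bare
#' slide is near-white).
#'
#' @param img RGB array (height x width x 3), 8-bit intensities.
#' @return Logical matrix marking tissue pixels.
#' @export
tissue_mask <- function(img) {
  g <- luminance_8bit(img)
  t_tissue <- threshold_minimum(histogram_256(g))
  apply_threshold(g, t_tissue, "dark")
}

#' DAB-positive mask within tissue
#'
#' Thresholds the deconvolved DAB grayscale image with the "Default"
#' (legacy IsoData) method and intersects the dark side with the tissue mask.
#'
#' @param dab_img Integer grayscale matrix from [concentration_to_gray8()]
#'   (255 = unstained).
#' @param tissue Logical tissue mask of the same dimensions.
#' @param region Region over which the threshold histogram is computed:
#'   `"image"` (whole image, the default, mirroring a whole-image threshold)
#'   or `"tissue"` (tissue pixels only).
#' @return Logical matrix; always a subset of `tissue`.
#' @export
dab_mask <- function(dab_img, tissue, region = c("image", "tissue")) {
  region <- match.arg(region)
  if (!identical(dim(dab_img), dim(tissue))) {
    stop("`dab_img` and `tissue` dimensions must match", call. = FALSE)
  }
  h <- if (region == "image") {
    histogram_256(dab_img)
  } else {
    histogram_256(dab_img, tissue)
  }
  t_dab <- threshold_default_isodata(h)
  apply_threshold(dab_img, t_dab, "dark") & tissue
}

#' Percent area of DAB-stained tissue
#'
#' @param dab Logical DAB-positive mask.
#' @param tissue Logical tissue mask of the same dimensions; must select at
#'   least one pixel.
#' @return `100 * |dab & tissue| / |tissue|`, a percentage in `[0, 100]`.
#' @export
area_pct <- function(dab, tissue) {
  if (!identical(dim(dab), dim(tissue))) {
    stop("mask dimensions must match", call. = FALSE)
  }
  n_tissue <- sum(tissue)
  if (n_tissue == 0L) {
    stop("empty region: tissue mask selects no pixels", call. = FALSE)
  }
  100 * sum(dab & tissue) / n_tissue
}

#' DABwt%: histogram-weighted DAB staining intensity
#'
#' The mean inverted intensity of a region of the deconvolved DAB image,
#' expressed as a percentage of maximal staining:
#' `100 * sum(counts[v] * (255 - v)) / (sum(counts) * 255)`.
#' A region that is entirely unstained (all 255) scores 0; entirely black, 100.
#'
#' @param h Integer vector of 256 counts from [histogram_256()], typically
#'   over the DAB-positive region within tissue.
#' @return A percentage in `[0, 100]`.
#' @export
dab_wt_pct <- function(h) {
  h <- check_histogram(h)
  lev <- 0:255
  100 * sum(h * (255 - lev)) / (sum(h) * 255)
}

#' Score a single tissue-microarray core
#'
#' Runs the full per-core pipeline: tissue mask ("Minimum" threshold on
#' luminance), H-DAB colour deconvolution, DAB mask ("Default" threshold on
#' the DAB image intersected with tissue), then the percent DAB-positive area
#' (`area_pct`), staining intensity (`dabwt_pct`) and their product, the
#' immunoreactive score (`irs`, range 0-10000). A core whose DAB image is
#' uniformly unstained (degenerate histogram) or whose DAB mask is empty is a
#' biological zero: it scores 0/0/0 rather than erroring.
#'
#' @param img RGB array (height x width x 3) with 8-bit intensities.
#' @param core_id,marker,gleason_group Metadata carried into the result.
#' @param cfg A [pipeline_config()]; controls the stain matrix, reference
#'   white, the DAB threshold histogram region and the DABwt% region
#'   (`"positive"` = stained tissue only, `"tissue"` = all tissue).
#' @return A one-row data frame with columns `core_id`, `marker`,
#'   `gleason_group`, `area_pct`, `dabwt_pct`, `irs`, `tissue_threshold`,
#'   `dab_threshold`.
#' @export
score_core <- function(img, core_id = "core", marker = NA_character_,
                       gleason_group = NA_character_,
                       cfg = pipeline_config()) {
  res <- tryCatch(
    score_core_impl(img, cfg),
    error = function(e) {
      stop(sprintf("core '%s': %s", core_id, conditionMessage(e)),
        call. = FALSE
      )
    }
  )
  data.frame(
    core_id = core_id, marker = marker, gleason_group = gleason_group,
    area_pct = res$area_pct, dabwt_pct = res$dabwt_pct, irs = res$irs,
    tissue_threshold = res$tissue_threshold, dab_threshold = res$dab_threshold,
    stringsAsFactors = FALSE
  )
}

score_core_impl <- function(img, cfg) {
  g <- luminance_8bit(img)
  t_tissue <- threshold_minimum(histogram_256(g))
  tissue <- apply_threshold(g, t_tissue, "dark")
  if (sum(tissue) == 0L) stop("tissue mask is empty")

  od <- rgb_to_od(img, cfg$i0)
  conc <- deconvolve(od, cfg$stain_matrix)
  dabg <- concentration_to_gray8(conc, "dab")

  zero <- list(
    area_pct = 0, dabwt_pct = 0, irs = 0,
    tissue_threshold = t_tissue, dab_threshold = NA_integer_
  )
  h_dab <- if (cfg$dab_threshold_region == "image") {
    histogram_256(dabg)
  } else {
    histogram_256(dabg, tissue)
  }
  t_dab <- tryCatch(threshold_default_isodata(h_dab), error = function(e) NULL)
  if (is.null(t_dab)) {
    return(zero) # uniform DAB image: nothing stained
  }
  dab <- apply_threshold(dabg, t_dab, "dark") & tissue
  zero$dab_threshold <- t_dab
  if (sum(dab) == 0L) {
    return(zero)
  }

  a <- area_pct(dab, tissue)
  wt_region <- if (cfg$dabwt_region == "positive") dab else tissue
  wt <- dab_wt_pct(histogram_256(dabg, wt_region))
  list(
    area_pct = a, dabwt_pct = wt, irs = a * wt,
    tissue_threshold = t_tissue, dab_threshold = t_dab
  )
}

#' Score a batch of cores from a metadata table
#'
#' Scores each row of a metadata table against images on disk. Per-core
#' failures (unreadable file, thresholding failure) are recorded in the
#' `status` column and do not abort the batch.
#'
#' @param meta Data frame with columns `core_id`, `file`, `marker`,
#'   `gleason_group` (the contract of the scoring CSV input).
#' @param image_dir Directory that the `file` column is relative to.
#' @param cfg A [pipeline_config()].
#' @return Data frame with one row per core, sorted by
#'   (`marker`, `gleason_group`, `core_id`), with scoring columns as in
#'   [score_core()] plus `status` (`"ok"` or the error message).
#' @export
score_batch <- function(meta, image_dir = ".", cfg = pipeline_config()) {
  required <- c("core_id", "file", "marker", "gleason_group")
  missing_cols <- setdiff(required, names(meta))
  if (length(missing_cols) > 0L) {
    stop(
      "metadata is missing required column(s): ",
      paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }
  empty <- data.frame(
    core_id = character(), marker = character(), gleason_group = character(),
    area_pct = numeric(), dabwt_pct = numeric(), irs = numeric(),
    tissue_threshold = integer(), dab_threshold = integer(),
    status = character(), stringsAsFactors = FALSE
  )
  if (nrow(meta) == 0L) {
    return(empty)
  }
  rows <- lapply(seq_len(nrow(meta)), function(i) {
    row <- meta[i, ]
    path <- file.path(image_dir, row$file)
    out <- tryCatch(
      {
        img <- read_rgb_image(path)
        sc <- score_core(img, row$core_id, row$marker, row$gleason_group, cfg)
        sc$status <- "ok"
        sc
      },
      error = function(e) {
        data.frame(
          core_id = row$core_id, marker = row$marker,
          gleason_group = row$gleason_group,
          area_pct = NA_real_, dabwt_pct = NA_real_, irs = NA_real_,
          tissue_threshold = NA_integer_, dab_threshold = NA_integer_,
          status = paste0("failed: ", conditionMessage(e)),
          stringsAsFactors = FALSE
        )
      }
    )
    out
  })
  scores <- do.call(rbind, rows)
  scores <- scores[order(scores$marker, scores$gleason_group, scores$core_id), ,
    drop = FALSE
  ]
  rownames(scores) <- NULL
  scores
}
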