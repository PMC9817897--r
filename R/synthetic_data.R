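# Synthetic inputs with known ground truth: H-DAB core images rendered
# through the forward Beer-Lambert model, plus tabular generators matching
# the distributional assumptions of the downstream statistics
# (heteroscedastic group scores, negative-binomial intensities, date-blocked
# assay tables, correlated manual/digital score pairs).
#
# Every generator is a pure function of its parameters and `seed`.

#' Generate a synthetic H-DAB core image with known ground truth
#'
#' Renders a circular tissue disk on a white background. The disk carries a
#' hematoxylin optical-density field (amplitude plus Gaussian texture,
#' clamped at zero); DAB-positive regions are random disks ("blobs")
#' rejection-placed inside the tissue until they cover the requested fraction
#' of the tissue area to within one percentage point, each carrying a DAB
#' optical-density field built the same way. The concentration fields are
#' mixed through [hdab_stain_matrix()] and rendered to 8-bit RGB with
#' [od_to_rgb()], so scoring the image exercises the exact inverse path.
#'
#' @param fraction Target DAB-positive fraction of the tissue area, in
#'   `[0, 1]`.
#' @param dab_amplitude Mean DAB optical density inside blobs (OD units).
#' @param hematoxylin_amplitude Mean hematoxylin optical density across the
#'   tissue disk (OD units).
#' @param noise_sd Standard deviation of the Gaussian OD texture added to
#'   both stain fields.
#' @param size Image side length in pixels (square image), at least 64.
#' @param seed Integer seed; the same seed reproduces the image bit for bit.
#' @param core_id Identifier carried into the ground-truth record.
#' @return A list with elements `image` (height x width x 3 array of 8-bit
#'   intensities) and `truth`, a one-row data frame recording the requested
#'   and *realised* DAB fraction, the stain amplitudes, `noise_sd` and the
#'   seed.
#' @export
generate_core_image <- function(fraction, dab_amplitude = 1.0,
                                hematoxylin_amplitude = 0.6,
                                noise_sd = 0.05, size = 128L, seed = 1L,
                                core_id = "core") {
  stopifnot(
    is.numeric(fraction), length(fraction) == 1L,
    fraction >= 0, fraction <= 1,
    dab_amplitude >= 0, hematoxylin_amplitude >= 0, noise_sd >= 0
  )
  if (size < 64L) stop("`size` must be at least 64 pixels", call. = FALSE)
  size <- as.integer(size)
  set.seed(as.integer(seed))

  centre <- (size + 1) / 2
  radius <- 0.42 * size
  rr <- matrix(seq_len(size), size, size)
  cc <- t(rr)
  dist2 <- (rr - centre)^2 + (cc - centre)^2
  tissue <- dist2 <= radius^2
  n_tissue <- sum(tissue)

  dab <- matrix(FALSE, size, size)
  realized <- 0
  if (fraction > 0) {
    target_px <- fraction * n_tissue
    tissue_idx <- which(tissue)
    attempts <- 0L
    while (sum(dab) < target_px - 0.005 * n_tissue) {
      attempts <- attempts + 1L
      if (attempts > 20000L) {
        stop("blob placement failed to reach the target DAB fraction",
          call. = FALSE
        )
      }
      ctr <- tissue_idx[sample.int(length(tissue_idx), 1L)]
      cy <- (ctr - 1L) %% size + 1L
      cx <- (ctr - 1L) %/% size + 1L
      remaining_px <- target_px - sum(dab)
      r_blob <- min(
        stats::runif(1, 0.02 * size, 0.07 * size),
        sqrt(remaining_px / pi)
      )
      blob <- (rr - cy)^2 + (cc - cx)^2 <= r_blob^2
      dab <- dab | (blob & tissue)
    }
    realized <- sum(dab) / n_tissue
  }

  ch <- matrix(0, size, size)
  ch[tissue] <- pmax(
    hematoxylin_amplitude + stats::rnorm(n_tissue, 0, noise_sd), 0
  )
  cd <- matrix(0, size, size)
  n_dab <- sum(dab)
  if (n_dab > 0L) {
    cd[dab] <- pmax(dab_amplitude + stats::rnorm(n_dab, 0, noise_sd), 0)
  }

  m <- hdab_stain_matrix()
  flat <- cbind(as.vector(ch), as.vector(cd), 0) %*% m
  od <- array(flat, dim = c(size, size, 3L))
  img <- od_to_rgb(od)

  truth <- data.frame(
    core_id = core_id,
    true_dab_fraction = fraction,
    realized_dab_fraction = realized,
    true_dab_amplitude = dab_amplitude,
    true_hematoxylin_amplitude = hematoxylin_amplitude,
    noise_sd = noise_sd,
    seed = as.integer(seed),
    stringsAsFactors = FALSE
  )
  list(image = img, truth = truth)
}

#' Generate per-group scores with group-specific means and variances
#'
#' Draws Gaussian scores for each group with its own mean and standard
#' deviation (clipped at zero, since immunoreactive scores are non-negative),
#' emulating score-by-histological-group data in which the spread grows with
#' the mean.
#'
#' @param group_means,group_sds,n_per_group Equal-length vectors of group
#'   means, standard deviations (> 0) and sample sizes.
#' @param seed Integer seed.
#' @param group_names Optional group labels; defaults to the Gleason-style
#'   labels `normal`, `1&2`, `3`, `4`, `5` when five groups are given,
#'   otherwise `g1`, `g2`, ...
#' @return Data frame with columns `gleason_group` (factor with groups in
#'   the given order) and `irs`.
#' @export
generate_group_scores <- function(group_means, group_sds, n_per_group,
                                  seed = 1L, group_names = NULL) {
  k <- length(group_means)
  if (length(group_sds) != k || length(n_per_group) != k) {
    stop("`group_means`, `group_sds` and `n_per_group` must have equal length",
      call. = FALSE
    )
  }
  if (any(group_sds <= 0)) stop("`group_sds` must be positive", call. = FALSE)
  if (is.null(group_names)) {
    group_names <- if (k == 5L) {
      c("normal", "1&2", "3", "4", "5")
    } else {
      paste0("g", seq_len(k))
    }
  }
  set.seed(as.integer(seed))
  values <- unlist(lapply(seq_len(k), function(i) {
    pmax(stats::rnorm(n_per_group[i], group_means[i], group_sds[i]), 0)
  }))
  data.frame(
    gleason_group = factor(
      rep(group_names, n_per_group),
      levels = group_names
    ),
    irs = values
  )
}

#' Generate negative-binomially distributed counts from a design matrix
#'
#' Draws `y ~ NegBin(mu, theta)` with log link `mu = exp(X beta)` and
#' variance `mu + mu^2 / theta`, the mean-variance relationship assumed for
#' fluorescence intensity data.
#'
#' @param design Numeric design matrix `X` (rows = observations; include an
#'   intercept column if wanted).
#' @param beta Coefficient vector on the log scale, one per design column.
#' @param theta Dispersion parameter (> 0); larger values approach Poisson.
#' @param seed Integer seed.
#' @return Integer vector of counts, one per design row.
#' @export
generate_nb_counts <- function(design, beta, theta, seed = 1L) {
  design <- as.matrix(design)
  if (ncol(design) != length(beta)) {
    stop("`beta` length must match the number of design columns",
      call. = FALSE
    )
  }
  if (!is.numeric(theta) || length(theta) != 1L || theta <= 0) {
    stop("`theta` must be a single positive number", call. = FALSE)
  }
  mu <- exp(drop(design %*% beta))
  if (any(!is.finite(mu))) {
    stop("non-finite mean: check `design` and `beta`", call. = FALSE)
  }
  set.seed(as.integer(seed))
  stats::rnbinom(length(mu), mu = mu, size = theta)
}

#' Generate a balanced, date-blocked assay table
#'
#' Builds the full treatment x date x replicate layout of a plate assay
#' (absorbance or cell counts) with additive treatment and date effects plus
#' Gaussian residual noise -- the structure assumed by the blocked linear
#' model in [fit_blocked_ols()].
#'
#' @param treatment_effects Named numeric vector of treatment effects.
#' @param date_effects Named numeric vector of date (testing-day) effects;
#'   supply at least two when date blocking is to be fitted.
#' @param resid_sd Residual standard deviation (>= 0).
#' @param n_rep Replicates per treatment x date cell (>= 1).
#' @param seed Integer seed.
#' @param grand_mean Baseline response level.
#' @return Data frame with columns `value`, `treatment`, `date`, `replicate`.
#' @export
generate_assay_table <- function(treatment_effects, date_effects,
                                 resid_sd = 0.05, n_rep = 3L, seed = 1L,
                                 grand_mean = 1.0) {
  if (n_rep < 1L) stop("`n_rep` must be at least 1", call. = FALSE)
  if (resid_sd < 0) stop("`resid_sd` must be non-negative", call. = FALSE)
  trt <- names(treatment_effects)
  if (is.null(trt)) trt <- paste0("t", seq_along(treatment_effects))
  dat <- names(date_effects)
  if (is.null(dat)) dat <- paste0("d", seq_along(date_effects))
  grid <- expand.grid(
    replicate = seq_len(n_rep),
    date = dat,
    treatment = trt,
    stringsAsFactors = FALSE
  )
  set.seed(as.integer(seed))
  grid$value <- grand_mean +
    treatment_effects[match(grid$treatment, trt)] +
    date_effects[match(grid$date, dat)] +
    stats::rnorm(nrow(grid), 0, resid_sd)
  grid$treatment <- factor(grid$treatment, levels = trt)
  grid$date <- factor(grid$date, levels = dat)
  grid[, c("value", "treatment", "date", "replicate")]
}

#' Generate paired manual/digital scores with a target correlation
#'
#' Draws a bivariate Gaussian pair with the requested correlation and maps
#' both margins affinely onto a typical immunoreactive-score scale
#' (mean 2000, sd 800). The map is affine, not clipped, so the sample
#' correlation is unbiased for `target_r`; a small tail of values may fall
#' slightly outside `[0, 10000]`.
#'
#' @param n Number of score pairs.
#' @param target_r Target Pearson correlation in `[-1, 1]`.
#' @param seed Integer seed.
#' @param centre,scale Location and scale of the affine map to the score
#'   scale.
#' @return Data frame with columns `manual` and `digital`.
#' @export
generate_paired_scores <- function(n, target_r, seed = 1L,
                                   centre = 2000, scale = 800) {
  if (!is.numeric(target_r) || length(target_r) != 1L ||
    abs(target_r) > 1) {
    stop("`target_r` must lie in [-1, 1]", call. = FALSE)
  }
  set.seed(as.integer(seed))
  z1 <- stats::rnorm(n)
  z2 <- target_r * z1 + sqrt(1 - target_r^2) * stats::rnorm(n)
  data.frame(
    manual = centre + scale * z1,
    digital = centre + scale * z2
  )
}
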