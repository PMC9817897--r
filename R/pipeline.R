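# Pipeline configuration, image/table IO and the reproducible command-style
# entry points (simulate-cores, simulate-tables, score, stats, validate).
# Every run writes a manifest (configuration echo, package version, seed,
# input hashes) so any artifact can be regenerated bit-identically.

#' Pipeline configuration
#'
#' Collects the tunable choices of the scoring pipeline with validated
#' defaults.
#'
#' @param stain_matrix 3 x 3 stain matrix (rows = hematoxylin, dab,
#'   residual; columns = R, G, B), unit-norm rows; default
#'   [hdab_stain_matrix()].
#' @param i0 Reference white intensity for the optical-density transform.
#' @param dabwt_region Region over which DABwt% is computed: `"positive"`
#'   (DAB-positive tissue, default) or `"tissue"` (all tissue).
#' @param dab_threshold_region Histogram region for the DAB threshold:
#'   `"image"` (default) or `"tissue"`.
#' @param p_adjust Multiplicity adjustment for group contrasts.
#' @param seed Integer seed used by simulation subcommands.
#' @param out_dir Output directory for pipeline artifacts.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(stain_matrix = hdab_stain_matrix(), i0 = 255,
                            dabwt_region = c("positive", "tissue"),
                            dab_threshold_region = c("image", "tissue"),
                            p_adjust = c("holm", "bonferroni", "none"),
                            seed = 1L, out_dir = ".") {
  validate_stain_matrix(stain_matrix)
  if (!is.numeric(i0) || length(i0) != 1L || i0 <= 0) {
    stop("`i0` must be a single positive number", call. = FALSE)
  }
  if (!is.numeric(seed) || length(seed) != 1L || seed != floor(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  structure(
    list(
      stain_matrix = stain_matrix,
      i0 = i0,
      dabwt_region = match.arg(dabwt_region),
      dab_threshold_region = match.arg(dab_threshold_region),
      p_adjust = match.arg(p_adjust),
      seed = as.integer(seed),
      out_dir = out_dir
    ),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from a YAML file
#'
#' Recognised keys mirror the arguments of [pipeline_config()]; a custom
#' stain matrix is given as `stain_matrix:` with nine floats (three rows of
#' three, row per stain in the order hematoxylin, dab, residual; channel
#' order R, G, B). Rows are re-normalised to unit length.
#'
#' @param path Path to the YAML file.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  args <- list()
  if (!is.null(raw$stain_matrix)) {
    v <- as.numeric(unlist(raw$stain_matrix))
    if (length(v) != 9L || any(!is.finite(v))) {
      stop("`stain_matrix` must be nine finite numbers", call. = FALSE)
    }
    m <- matrix(v, nrow = 3L, byrow = TRUE)
    m <- m / sqrt(rowSums(m^2))
    rownames(m) <- c("hematoxylin", "dab", "residual")
    colnames(m) <- c("R", "G", "B")
    args$stain_matrix <- m
  }
  for (key in c(
    "i0", "dabwt_region", "dab_threshold_region", "p_adjust",
    "seed", "out_dir"
  )) {
    if (!is.null(raw[[key]])) args[[key]] <- raw[[key]]
  }
  do.call(pipeline_config, args)
}

#' Read an image file as an 8-bit RGB array
#'
#' Decodes PNG or TIFF to a height x width x 3 array of integers in
#' `[0, 255]`. Grayscale inputs are promoted to three identical channels and
#' 16-bit inputs are rescaled to 8 bits, each with a warning; an alpha
#' channel is dropped.
#'
#' @param path Path to a `.png`, `.tif` or `.tiff` file.
#' @return Integer array (height x width x 3).
#' @export
read_rgb_image <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  x <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format '", ext, "' (expected png/tif/tiff)",
      call. = FALSE
    )
  )
  if (is.matrix(x)) {
    warning("grayscale input promoted to 3 identical channels: ", path)
    x <- array(rep(x, 3L), dim = c(dim(x), 3L))
  }
  if (dim(x)[3] == 4L) x <- x[, , 1:3, drop = FALSE]
  if (dim(x)[3] == 2L) {
    warning("grayscale input promoted to 3 identical channels: ", path)
    x <- array(rep(x[, , 1], 3L), dim = c(dim(x)[1:2], 3L))
  }
  v <- x * 255
  if (any(abs(v - round(v)) > 1e-6)) {
    warning("high-bit-depth input rescaled to 8 bits: ", path)
  }
  img <- round(v)
  storage.mode(img) <- "integer"
  img
}

#' Write an 8-bit RGB array as a PNG file
#'
#' @param img Integer array (height x width x 3) with values in `[0, 255]`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_rgb_image <- function(img, path) {
  png::writePNG(img / 255, target = path)
  invisible(path)
}

#' Read core images listed in a metadata table
#'
#' @param image_dir Directory holding the image files.
#' @param meta A data frame, or the path of a CSV file, with required
#'   columns `core_id`, `file`, `marker`, `gleason_group`.
#' @return A list with one element per metadata row: each is a list with
#'   `meta` (the row), `image` (the decoded array, or `NULL` on failure) and
#'   `error` (`NULL`, or the failure message).
#' @export
read_core_images <- function(image_dir, meta) {
  if (is.character(meta) && length(meta) == 1L) {
    meta <- utils::read.csv(meta, stringsAsFactors = FALSE)
  }
  required <- c("core_id", "file", "marker", "gleason_group")
  missing_cols <- setdiff(required, names(meta))
  if (length(missing_cols) > 0L) {
    stop(
      "metadata is missing required column(s): ",
      paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }
  lapply(seq_len(nrow(meta)), function(i) {
    row <- meta[i, ]
    img <- tryCatch(
      read_rgb_image(file.path(image_dir, row$file)),
      error = function(e) e
    )
    if (inherits(img, "error")) {
      list(meta = row, image = NULL, error = conditionMessage(img))
    } else {
      list(meta = row, image = img, error = NULL)
    }
  })
}

write_manifest <- function(out_dir, cfg, command, inputs = character(),
                           outputs = character()) {
  manifest <- list(
    package = "dabscore",
    version = as.character(utils::packageVersion("dabscore")),
    command = command,
    seed = cfg$seed,
    config = list(
      stain_matrix = as.vector(t(cfg$stain_matrix)),
      i0 = cfg$i0,
      dabwt_region = cfg$dabwt_region,
      dab_threshold_region = cfg$dab_threshold_region,
      p_adjust = cfg$p_adjust
    ),
    input_md5 = as.list(tools::md5sum(inputs)),
    output_files = basename(outputs)
  )
  path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, path,
    auto_unbox = TRUE, pretty = TRUE,
    digits = NA
  )
  path
}

#' Run a pipeline subcommand
#'
#' Programmatic equivalent of the command-line interface. Subcommands:
#' \describe{
#'   \item{`simulate-cores`}{`args`: `n`, `fractions` (recycled over cores),
#'     `dab_amplitude`, `hematoxylin_amplitude`, `noise_sd`, `size`. Writes
#'     one PNG per core plus `truth.csv` and `meta.csv` under `cfg$out_dir`.}
#'   \item{`simulate-tables`}{`args`: `kind` (`"group-scores"`,
#'     `"nb-counts"`, `"assay"` or `"paired"`) plus that generator's
#'     parameters. Writes one CSV.}
#'   \item{`score`}{`args`: `image_dir`, `meta` (CSV path or data frame).
#'     Writes `scores.csv`.}
#'   \item{`stats`}{`args`: `scores` (CSV path or data frame), `by`, `value`.
#'     Writes `group_means.csv` and `group_contrasts.csv`.}
#'   \item{`validate`}{end-to-end smoke run: simulates 20 cores in four
#'     groups with group-dependent DAB fractions, scores them and fits the
#'     heteroscedastic group model. Deterministic for a fixed `cfg$seed`.}
#' }
#' Every subcommand writes `manifest.json` describing the run.
#'
#' @param command One of `"simulate-cores"`, `"simulate-tables"`, `"score"`,
#'   `"stats"`, `"validate"`.
#' @param args Named list of subcommand arguments (see Details).
#' @param cfg A [pipeline_config()]; `cfg$out_dir` receives all artifacts.
#' @return A named list of output file paths, invisibly.
#' @export
run_pipeline <- function(command, args = list(), cfg = pipeline_config()) {
  if (!inherits(cfg, "pipeline_config")) {
    stop("`cfg` must be a pipeline_config object", call. = FALSE)
  }
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  switch(command,
    "simulate-cores" = pipeline_simulate_cores(args, cfg),
    "simulate-tables" = pipeline_simulate_tables(args, cfg),
    "score" = pipeline_score(args, cfg),
    "stats" = pipeline_stats(args, cfg),
    "validate" = pipeline_validate(cfg),
    stop("unknown subcommand '", command, "'", call. = FALSE)
  )
}

pipeline_simulate_cores <- function(args, cfg) {
  n <- args$n %||% 10L
  fractions <- rep_len(args$fractions %||% 0.3, n)
  amp <- args$dab_amplitude %||% 1.0
  hamp <- args$hematoxylin_amplitude %||% 0.6
  noise <- args$noise_sd %||% 0.05
  size <- args$size %||% 128L
  truths <- vector("list", n)
  files <- character(n)
  for (i in seq_len(n)) {
    id <- sprintf("core%03d", i)
    sim <- generate_core_image(
      fraction = fractions[i], dab_amplitude = amp,
      hematoxylin_amplitude = hamp, noise_sd = noise, size = size,
      seed = cfg$seed + i, core_id = id
    )
    files[i] <- paste0(id, ".png")
    write_rgb_image(sim$image, file.path(cfg$out_dir, files[i]))
    truths[[i]] <- sim$truth
  }
  truth <- do.call(rbind, truths)
  truth_csv <- file.path(cfg$out_dir, "truth.csv")
  utils::write.csv(truth, truth_csv, row.names = FALSE)
  meta <- data.frame(
    core_id = truth$core_id, file = files,
    marker = args$marker %||% "synthetic",
    gleason_group = args$gleason_group %||% NA_character_,
    stringsAsFactors = FALSE
  )
  meta_csv <- file.path(cfg$out_dir, "meta.csv")
  utils::write.csv(meta, meta_csv, row.names = FALSE)
  manifest <- write_manifest(cfg$out_dir, cfg, "simulate-cores",
    outputs = c(files, truth_csv, meta_csv)
  )
  invisible(list(truth = truth_csv, meta = meta_csv, manifest = manifest))
}

# tabular generators behind one subcommand; `kind` picks the generator.
# The default group-scores scenario is synthetic: a marker whose mean score
# rises with histological group and one whose mean falls, both with spread
# growing with the mean.
pipeline_simulate_tables <- function(args, cfg) {
  kind <- args$kind %||% "group-scores"
  out <- switch(kind,
    "group-scores" = {
      n_per_group <- args$n_per_group %||% c(15L, 10L, 40L, 45L, 30L)
      rising <- generate_group_scores(
        group_means = args$group_means %||% c(800, 900, 1000, 1600, 2000),
        group_sds = args$group_sds %||% c(300, 340, 400, 700, 900),
        n_per_group = n_per_group, seed = cfg$seed
      )
      rising$marker <- "synthetic_rising"
      falling <- generate_group_scores(
        group_means = c(1500, 1400, 1200, 800, 600),
        group_sds = c(520, 480, 420, 320, 260),
        n_per_group = n_per_group, seed = cfg$seed + 1L
      )
      falling$marker <- "synthetic_falling"
      path <- file.path(cfg$out_dir, "group_scores.csv")
      utils::write.csv(rbind(rising, falling), path, row.names = FALSE)
      path
    },
    "nb-counts" = {
      n <- args$n %||% 300L
      design <- cbind(intercept = 1, group = rep(0:1, length.out = n))
      counts <- generate_nb_counts(
        design,
        beta = args$beta %||% c(log(100), 0.7),
        theta = args$theta %||% 3, seed = cfg$seed
      )
      path <- file.path(cfg$out_dir, "nb_counts.csv")
      utils::write.csv(
        data.frame(count = counts, group = design[, "group"]),
        path,
        row.names = FALSE
      )
      path
    },
    "assay" = {
      tab <- generate_assay_table(
        treatment_effects = args$treatment_effects %||%
          c(empty_vector = 0, inhbb = 0.4, inhbc = -0.2),
        date_effects = args$date_effects %||%
          c(d1 = 0.1, d2 = -0.05, d3 = 0.02),
        resid_sd = args$resid_sd %||% 0.05,
        n_rep = args$n_rep %||% 3L, seed = cfg$seed
      )
      path <- file.path(cfg$out_dir, "assay.csv")
      utils::write.csv(tab, path, row.names = FALSE)
      path
    },
    "paired" = {
      tab <- generate_paired_scores(
        n = args$n %||% 100L,
        target_r = args$target_r %||% 0.85, seed = cfg$seed
      )
      path <- file.path(cfg$out_dir, "paired_scores.csv")
      utils::write.csv(tab, path, row.names = FALSE)
      path
    },
    stop("unknown table kind '", kind, "'", call. = FALSE)
  )
  manifest <- write_manifest(cfg$out_dir, cfg, "simulate-tables",
    outputs = out
  )
  invisible(list(table = out, manifest = manifest))
}

pipeline_score <- function(args, cfg) {
  if (is.null(args$image_dir) || is.null(args$meta)) {
    stop("`score` needs `image_dir` and `meta`", call. = FALSE)
  }
  meta <- args$meta
  meta_paths <- character()
  if (is.character(meta)) {
    meta_paths <- meta
    meta <- utils::read.csv(meta, stringsAsFactors = FALSE)
  }
  scores <- score_batch(meta, args$image_dir, cfg)
  scores_csv <- file.path(cfg$out_dir, "scores.csv")
  utils::write.csv(scores, scores_csv, row.names = FALSE)
  manifest <- write_manifest(cfg$out_dir, cfg, "score",
    inputs = meta_paths, outputs = scores_csv
  )
  n_failed <- sum(scores$status != "ok")
  invisible(list(
    scores = scores_csv, manifest = manifest, n_failed = n_failed
  ))
}

pipeline_stats <- function(args, cfg) {
  scores <- args$scores
  score_paths <- character()
  if (is.character(scores)) {
    score_paths <- scores
    scores <- utils::read.csv(scores, stringsAsFactors = FALSE)
  }
  fit <- fit_hetero_groups(
    scores,
    group = args$by %||% "gleason_group",
    value = args$value %||% "irs",
    reference = args$reference %||% "normal",
    p_adjust = cfg$p_adjust
  )
  means_csv <- file.path(cfg$out_dir, "group_means.csv")
  contrasts_csv <- file.path(cfg$out_dir, "group_contrasts.csv")
  utils::write.csv(fit$groups, means_csv, row.names = FALSE)
  utils::write.csv(fit$contrasts, contrasts_csv, row.names = FALSE)
  manifest <- write_manifest(cfg$out_dir, cfg, "stats",
    inputs = score_paths, outputs = c(means_csv, contrasts_csv)
  )
  invisible(list(
    means = means_csv, contrasts = contrasts_csv, manifest = manifest,
    fit = fit
  ))
}

# end-to-end smoke run: simulate -> score -> group stats, all deterministic
pipeline_validate <- function(cfg) {
  groups <- c("normal", "3", "4", "5")
  fractions <- c(normal = 0.05, "3" = 0.15, "4" = 0.30, "5" = 0.45)
  n_per_group <- 5L
  meta_rows <- vector("list", length(groups) * n_per_group)
  files <- character(length(meta_rows))
  k <- 0L
  for (g in groups) {
    for (i in seq_len(n_per_group)) {
      k <- k + 1L
      id <- sprintf("%s_core%02d", gsub("[^a-z0-9]", "", g), i)
      sim <- generate_core_image(
        fraction = fractions[[g]], dab_amplitude = 1.0,
        hematoxylin_amplitude = 0.6, noise_sd = 0.05, size = 96L,
        seed = cfg$seed * 1000L + k, core_id = id
      )
      files[k] <- paste0(id, ".png")
      write_rgb_image(sim$image, file.path(cfg$out_dir, files[k]))
      meta_rows[[k]] <- data.frame(
        core_id = id, file = files[k], marker = "synthetic",
        gleason_group = g, stringsAsFactors = FALSE
      )
    }
  }
  meta <- do.call(rbind, meta_rows)
  meta_csv <- file.path(cfg$out_dir, "meta.csv")
  utils::write.csv(meta, meta_csv, row.names = FALSE)

  scores <- score_batch(meta, cfg$out_dir, cfg)
  scores_csv <- file.path(cfg$out_dir, "scores.csv")
  utils::write.csv(scores, scores_csv, row.names = FALSE)
  if (any(scores$status != "ok")) {
    stop("validate: ", sum(scores$status != "ok"), " core(s) failed scoring",
      call. = FALSE
    )
  }

  fit <- fit_hetero_groups(scores,
    group = "gleason_group", value = "irs",
    reference = "normal", p_adjust = cfg$p_adjust
  )
  means_csv <- file.path(cfg$out_dir, "group_means.csv")
  contrasts_csv <- file.path(cfg$out_dir, "group_contrasts.csv")
  utils::write.csv(fit$groups, means_csv, row.names = FALSE)
  utils::write.csv(fit$contrasts, contrasts_csv, row.names = FALSE)
  manifest <- write_manifest(cfg$out_dir, cfg, "validate",
    outputs = c(files, meta_csv, scores_csv, means_csv, contrasts_csv)
  )
  invisible(list(
    meta = meta_csv, scores = scores_csv, means = means_csv,
    contrasts = contrasts_csv, manifest = manifest, fit = fit
  ))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
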