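# Configuration, plate-layout I/O, image discovery, and the end-to-end run:
# generate (phantom) -> measure (images -> metrics.csv) -> summarize
# (metrics + absorbance -> endpoint tables), with a JSON run manifest.

#' Load and validate a plate layout
#'
#' @param path CSV with columns `well`, `cell_line_label` (optional),
#'   `dose_uM`, `condition`, `replicate`.
#' @return Validated data.frame keyed by well.
#' @export
load_plate_layout <- function(path) {
  if (!file.exists(path))
    stop_spherotrack(sprintf("layout file not found: '%s'", path),
                     "io_error")
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("well", "dose_uM", "condition", "replicate")
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop_spherotrack(sprintf("layout is missing column(s): %s",
                             paste(miss, collapse = ", ")), "schema_error")
  dup <- df$well[duplicated(df$well)]
  if (length(dup))
    stop_spherotrack(sprintf("duplicate well id(s) in layout: %s",
                             paste(unique(dup), collapse = ", ")),
                     "schema_error")
  dose <- suppressWarnings(as.numeric(df$dose_uM))
  bad <- which(is.na(dose) | dose < 0)
  if (length(bad))
    stop_spherotrack(
      sprintf("invalid dose_uM in layout row(s) %s (well %s)",
              paste(bad, collapse = ", "),
              paste(df$well[bad], collapse = ", ")), "schema_error")
  df$dose_uM <- dose
  if (!"cell_line_label" %in% names(df))
    df$cell_line_label <- NA_character_
  df
}

#' Pipeline configuration
#'
#' @param input_dir Directory of images named `{well}_{day}.tif/.png`.
#' @param layout_path Plate-layout CSV path.
#' @param absorbance_path Absorbance CSV path (optional; viability panels are
#'   skipped without it).
#' @param out_dir Results directory.
#' @param segmentation A [segmentation_settings()].
#' @param terminal_day,baseline_day Days used for RTV/TGI (defaults 7, 1).
#' @param epi_threshold Invasiveness threshold (default 0.5).
#' @param pixel_size_um Fallback pixel size for images without metadata.
#' @param seed Integer seed recorded in the manifest.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(input_dir, layout_path, absorbance_path = NULL,
                            out_dir = "results",
                            segmentation = segmentation_settings(),
                            terminal_day = 7L, baseline_day = 1L,
                            epi_threshold = 0.5, pixel_size_um = NULL,
                            seed = 1L) {
  if (terminal_day < baseline_day)
    stop_spherotrack("`terminal_day` must be >= `baseline_day`",
                     "invalid_argument")
  check_number(epi_threshold, "epi_threshold")
  structure(list(input_dir = input_dir, layout_path = layout_path,
                 absorbance_path = absorbance_path, out_dir = out_dir,
                 segmentation = segmentation,
                 terminal_day = as.integer(terminal_day),
                 baseline_day = as.integer(baseline_day),
                 epi_threshold = epi_threshold,
                 pixel_size_um = pixel_size_um, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Load a pipeline configuration file
#'
#' JSON (always available) or YAML (if the `yaml` package is installed);
#' field names mirror [pipeline_config()] arguments, with segmentation
#' settings in a nested `segmentation` block.
#'
#' @param path Config file path.
#' @param ... Overrides applied after the file (flags win over file).
#' @return A `pipeline_config`.
#' @export
load_pipeline_config <- function(path, ...) {
  ext <- tolower(tools::file_ext(path))
  lst <- if (ext %in% c("yaml", "yml")) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop_spherotrack("YAML config requires the 'yaml' package", "io_error")
    yaml::yaml.load_file(path)
  } else jsonlite::read_json(path, simplifyVector = TRUE)
  lst <- utils::modifyList(lst, list(...))
  if (!is.null(lst$segmentation))
    lst$segmentation <- do.call(segmentation_settings,
                                as.list(lst$segmentation))
  do.call(pipeline_config, lst)
}

discover_images <- function(input_dir) {
  files <- list.files(input_dir, pattern = "^.+_[0-9]+\\.(tif|tiff|png)$",
                      full.names = TRUE)
  if (!length(files))
    stop_spherotrack(sprintf("no images found in '%s'", input_dir),
                     "io_error")
  sort(files)
}

#' Measure every image in a directory
#'
#' Runs [measure_image()] on all discovered images; per-image failures are
#' recorded (well, day, message) and do not abort the run.
#'
#' @param input_dir Image directory.
#' @param settings A [segmentation_settings()].
#' @param pixel_size_um Fallback pixel size.
#' @return List with `metrics` (data.frame) and `errors` (data.frame).
#' @export
measure_directory <- function(input_dir, settings = segmentation_settings(),
                              pixel_size_um = NULL) {
  files <- discover_images(input_dir)
  recs <- list(); errs <- list()
  for (f in files) {
    res <- tryCatch({
      img <- read_spheroid_image(f, pixel_size_um = pixel_size_um)
      measure_image(img, settings)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      errs[[length(errs) + 1L]] <- data.frame(
        file = basename(f), message = conditionMessage(res),
        stringsAsFactors = FALSE)
    } else {
      recs[[length(recs) + 1L]] <- res
    }
  }
  list(metrics = if (length(recs)) do.call(rbind, recs) else NULL,
       errors = if (length(errs)) do.call(rbind, errs) else
         data.frame(file = character(0), message = character(0)))
}

#' Run the full measurement and summarization pipeline
#'
#' Discovers images, measures each well/day, writes `metrics.csv`, then the
#' endpoint tables (`timecourse.csv`, `day7_summary.csv`, `tgi.csv`,
#' `dose_response.csv`) and a run manifest (`manifest.json`) recording the
#' configuration, package version, input files and per-well errors.
#' Identical inputs and configuration reproduce byte-identical CSVs.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, list with the summary tables, the metrics, the error
#'   table and output paths.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  layout <- load_plate_layout(config$layout_path)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  mres <- measure_directory(config$input_dir, config$segmentation,
                            config$pixel_size_um)
  if (is.null(mres$metrics))
    stop_spherotrack("no image could be measured", "io_error")
  for (i in seq_len(nrow(mres$errors)))
    warning(sprintf("measurement failed for %s: %s", mres$errors$file[i],
                    mres$errors$message[i]))

  absorbance <- if (!is.null(config$absorbance_path) &&
                    file.exists(config$absorbance_path))
    utils::read.csv(config$absorbance_path, stringsAsFactors = FALSE)
  else
    data.frame(well = character(0), day = integer(0), A570 = numeric(0),
               A600 = numeric(0))

  summaries <- summarize_plate(mres$metrics, absorbance, layout,
                               terminal_day = config$terminal_day,
                               baseline_day = config$baseline_day,
                               epi_threshold = config$epi_threshold)

  paths <- list(
    metrics = file.path(config$out_dir, "metrics.csv"),
    timecourse = file.path(config$out_dir, "timecourse.csv"),
    day7_summary = file.path(config$out_dir, "day7_summary.csv"),
    tgi = file.path(config$out_dir, "tgi.csv"),
    dose_response = file.path(config$out_dir, "dose_response.csv"),
    manifest = file.path(config$out_dir, "manifest.json"))
  utils::write.csv(mres$metrics, paths$metrics, row.names = FALSE)
  utils::write.csv(summaries$timecourse, paths$timecourse,
                   row.names = FALSE)
  utils::write.csv(summaries$day_terminal, paths$day7_summary,
                   row.names = FALSE)
  utils::write.csv(summaries$tgi, paths$tgi, row.names = FALSE)
  utils::write.csv(summaries$dose_response, paths$dose_response,
                   row.names = FALSE)

  manifest <- list(
    package = "spherotrack",
    version = as.character(utils::packageVersion("spherotrack")),
    config = list(
      input_dir = config$input_dir, layout_path = config$layout_path,
      absorbance_path = config$absorbance_path,
      segmentation = unclass(config$segmentation),
      terminal_day = config$terminal_day,
      baseline_day = config$baseline_day,
      epi_threshold = config$epi_threshold, seed = config$seed),
    inputs = basename(discover_images(config$input_dir)),
    errors = mres$errors)
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(c(summaries, list(metrics = mres$metrics,
                              errors = mres$errors, paths = paths)))
}

#' Command-line interface
#'
#' Verbs: `generate` (phantom plate), `measure` (images to metrics.csv),
#' `summarize` (metrics + absorbance + layout to endpoint tables), `run`
#' (generate a demo phantom plate, then measure and summarize it).
#' Typically invoked through the launcher installed at
#' `system.file("cli", "spherotrack", package = "spherotrack")`.
#'
#' @param args Character vector of command-line arguments.
#' @return Exit status, invisibly (0 on success).
#' @export
spherotrack_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!requireNamespace("optparse", quietly = TRUE))
    stop("the CLI requires the 'optparse' package")
  usage <- "usage: spherotrack <generate|measure|summarize|run> [options]"
  if (!length(args) || !args[1] %in% c("generate", "measure", "summarize",
                                       "run")) {
    message(usage); return(invisible(1L))
  }
  verb <- args[1]; rest <- args[-1]
  ol <- list(
    optparse::make_option("--config", type = "character", default = NULL),
    optparse::make_option("--images", type = "character", default = NULL),
    optparse::make_option("--layout", type = "character", default = NULL),
    optparse::make_option("--absorbance", type = "character",
                          default = NULL),
    optparse::make_option("--metrics", type = "character", default = NULL),
    optparse::make_option("--out", type = "character", default = "results"),
    optparse::make_option("--seed", type = "integer", default = 1L),
    optparse::make_option("--pixel-size", type = "double", default = NULL,
                          dest = "pixel_size"),
    optparse::make_option("--replicates", type = "integer", default = 6L),
    optparse::make_option("--days", type = "character", default = "1:7"))
  opt <- optparse::parse_args(optparse::OptionParser(option_list = ol),
                              args = rest)
  days <- eval(parse(text = opt$days))

  if (verb == "generate") {
    cfg <- if (!is.null(opt$config))
      do.call(phantom_config, jsonlite::read_json(opt$config,
                                                  simplifyVector = TRUE))
    else phantom_config(seed = opt$seed)
    generate_plate(cfg, opt$out, n_replicates = opt$replicates, days = days)
    message("phantom plate written to ", opt$out)
  } else if (verb == "measure") {
    res <- measure_directory(opt$images, pixel_size_um = opt$pixel_size)
    dir.create(opt$out, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(res$metrics, file.path(opt$out, "metrics.csv"),
                     row.names = FALSE)
    message(nrow(res$metrics), " images measured, ", nrow(res$errors),
            " failures")
  } else if (verb == "summarize") {
    cfg <- pipeline_config(input_dir = ".", layout_path = opt$layout,
                           absorbance_path = opt$absorbance,
                           out_dir = opt$out, seed = opt$seed)
    metrics <- utils::read.csv(opt$metrics, stringsAsFactors = FALSE)
    absorbance <- utils::read.csv(opt$absorbance, stringsAsFactors = FALSE)
    layout <- load_plate_layout(opt$layout)
    s <- summarize_plate(metrics, absorbance, layout)
    dir.create(opt$out, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(s$timecourse, file.path(opt$out, "timecourse.csv"),
                     row.names = FALSE)
    utils::write.csv(s$day_terminal, file.path(opt$out, "day7_summary.csv"),
                     row.names = FALSE)
    utils::write.csv(s$tgi, file.path(opt$out, "tgi.csv"),
                     row.names = FALSE)
    utils::write.csv(s$dose_response,
                     file.path(opt$out, "dose_response.csv"),
                     row.names = FALSE)
    message("summaries written to ", opt$out)
  } else if (verb == "run") {
    plate_dir <- file.path(opt$out, "phantom")
    cfg <- phantom_config(seed = opt$seed)
    generate_plate(cfg, plate_dir, n_replicates = opt$replicates,
                   days = days)
    pc <- pipeline_config(
      input_dir = file.path(plate_dir, "images"),
      layout_path = file.path(plate_dir, "layout.csv"),
      absorbance_path = file.path(plate_dir, "absorbance.csv"),
      out_dir = file.path(opt$out, "results"), seed = opt$seed)
    run_pipeline(pc)
    message("end-to-end phantom run complete: ", opt$out)
  }
  invisible(0L)
}
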