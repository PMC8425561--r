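#' Write and read a simulation result directory
#'
#' A result directory holds plain-text, schema-stable files loadable
#' without the engine: `events.csv` (step, pollinator_id, flower_id,
#' accepted, nectar_gained), `flowers.csv` (id, x, y, nectar, scent,
#' time_since_visit, visit_count), `pollinators.csv` (id, x, y,
#' nectar_collected, n_accepted) and `manifest.json` (schema version,
#' package version, timestamp, config + seed, refill total, summary
#' metrics, file inventory). The manifest is sufficient to replay the run
#' exactly: rebuilding the configuration from it and calling
#' [run_simulation()] reproduces the same event log.
#'
#' @param result A `sim_result`.
#' @param out_dir Directory to create/write into.
#' @param dir A directory previously written by `write_result()`.
#' @return `write_result()`: invisibly, the named vector of files written.
#'   `read_result()`: a `sim_result` reconstructed from the files.
#' @export
write_result <- function(result, out_dir) {
  stopifnot(inherits(result, "sim_result"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create directory: ", out_dir, call. = FALSE)
  files <- c(events = file.path(out_dir, "events.csv"),
             flowers = file.path(out_dir, "flowers.csv"),
             pollinators = file.path(out_dir, "pollinators.csv"),
             manifest = file.path(out_dir, "manifest.json"))
  utils::write.csv(result$events, files["events"], row.names = FALSE)
  utils::write.csv(result$per_flower, files["flowers"], row.names = FALSE)
  utils::write.csv(result$per_pollinator, files["pollinators"], row.names = FALSE)
  manifest <- list(
    schema_version = 1L,
    package = "scentmark",
    package_version = as.character(utils::packageVersion("scentmark")),
    written_at = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = unclass(result$config),
    seed = result$seed,
    refill_total = result$refill_total,
    summary = as.list(summarize_run(result)),
    files = as.list(basename(files)))
  jsonlite::write_json(manifest, files["manifest"], auto_unbox = TRUE,
                       digits = NA, na = "null")
  invisible(files)
}

#' @rdname write_result
#' @export
read_result <- function(dir) {
  mf <- file.path(dir, "manifest.json")
  if (!file.exists(mf)) stop("no manifest.json in ", dir, call. = FALSE)
  manifest <- jsonlite::fromJSON(mf)
  cfg_args <- manifest$config
  cfg_args$scent_semantics <- as.character(cfg_args$scent_semantics)
  config <- do.call(sim_config, cfg_args)
  res <- list(
    config = config,
    seed = manifest$seed,
    per_pollinator = utils::read.csv(file.path(dir, "pollinators.csv")),
    per_flower = utils::read.csv(file.path(dir, "flowers.csv")),
    events = utils::read.csv(file.path(dir, "events.csv")),
    refill_total = manifest$refill_total)
  # empty CSVs read back with logical columns; coerce to the run schema
  if (nrow(res$events) == 0)
    res$events <- data.frame(step = integer(), pollinator_id = integer(),
                             flower_id = integer(), accepted = integer(),
                             nectar_gained = numeric())
  class(res) <- "sim_result"
  res
}
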