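# Text-based serialization: delimited tables for time series, JSON sidecars
# for metadata, JSON for trained models.  Diffable by design.

meta_attrs <- c("participant_id", "trial_index", "group_label", "skill",
                "seed")

sidecar_path <- function(path) paste0(path, ".json")

write_sidecar <- function(path, meta) {
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
}

#' Write / read a raw stream as a tab-delimited table with JSON sidecar
#'
#' @param stream a `raw_stream`.
#' @param path output file; a `<path>.json` sidecar carries participant id,
#'   group, skill, seed and any extra metadata.
#' @param extra named list merged into the sidecar (e.g. config hash).
#' @return `write_stream` returns `path` invisibly; `read_stream` the
#'   reconstructed `raw_stream`.
#' @export
write_stream <- function(stream, path, extra = list()) {
  write.table(as.data.frame(stream), path, sep = "\t", row.names = FALSE,
              quote = FALSE)
  meta <- attributes(stream)[meta_attrs]
  names(meta) <- meta_attrs
  write_sidecar(path, c(meta, extra))
  invisible(path)
}

#' @rdname write_stream
#' @export
read_stream <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t")
  df$active_dom <- as.logical(df$active_dom)
  df$active_nd <- as.logical(df$active_nd)
  meta <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  structure(df, class = c("raw_stream", "data.frame"),
            participant_id = meta$participant_id,
            trial_index = meta$trial_index, group_label = meta$group_label,
            skill = meta$skill, seed = meta$seed)
}

#' Write / read a metric series (header = manifest order) with sidecar
#' @param trial a `metric_series`.
#' @param path output file.
#' @param extra named list merged into the sidecar.
#' @return `write_metrics` returns `path` invisibly; `read_metrics` the
#'   reconstructed `metric_series`.
#' @export
write_metrics <- function(trial, path, extra = list()) {
  write.table(as.data.frame(trial), path, sep = "\t", row.names = FALSE,
              quote = FALSE)
  meta <- attributes(trial)[meta_attrs]
  names(meta) <- meta_attrs
  write_sidecar(path, c(meta, list(normalized = attr(trial, "normalized"),
                                   window_s = attr(trial, "window_s"),
                                   raw_dt = attr(trial, "raw_dt"),
                                   manifest = attr(trial, "manifest")), extra))
  invisible(path)
}

#' @rdname write_metrics
#' @export
read_metrics <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t")
  meta <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  structure(df, class = c("metric_series", "data.frame"),
            manifest = as.data.frame(meta$manifest),
            normalized = isTRUE(meta$normalized),
            window_s = meta$window_s, raw_dt = meta$raw_dt,
            participant_id = meta$participant_id,
            trial_index = meta$trial_index, group_label = meta$group_label,
            skill = meta$skill)
}

#' Write a score series as a two-column delimited table
#' @param series a `score_series`.
#' @param path output file.
#' @param extra named list merged into the sidecar.
#' @return `path`, invisibly.
#' @export
write_scores <- function(series, path, extra = list()) {
  write.table(as.data.frame(series), path, sep = "\t", row.names = FALSE,
              quote = FALSE)
  meta <- attributes(series)[c("participant_id", "trial_index",
                               "group_label", "task_average")]
  write_sidecar(path, c(meta, extra))
  invisible(path)
}

relist_weights <- function(w) lapply(w, function(m) {
  m <- as.matrix(m)
  storage.mode(m) <- "double"
  m
})

#' Serialize / restore a trained model (weights + sidecar in one JSON)
#'
#' The model travels with its normalization statistics, metric manifest,
#' schedule and RMSE history; [score_trial()] refuses a trial whose manifest
#' does not match, so a model file is self-contained.
#'
#' @param model a `trained_model` or `feedback_model`.
#' @param path output `.json` file.
#' @return `write_model` returns `path` invisibly; `read_model` the model.
#' @export
write_model <- function(model, path) {
  payload <- unclass(model)
  payload$.class <- class(model)
  payload$spec <- unclass(model$spec)
  payload$schedule <- unclass(model$schedule)
  payload$stats <- list(mean = as.list(model$stats$mean),
                        sd = as.list(model$stats$sd),
                        metric_names = model$stats$metric_names)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = FALSE)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  cls <- p$.class
  p$.class <- NULL
  p$weights <- relist_weights(p$weights)
  p$stats <- structure(list(mean = unlist(p$stats$mean),
                            sd = unlist(p$stats$sd),
                            metric_names = p$stats$metric_names),
                       class = "normalization_stats")
  p$spec <- structure(as.list(p$spec), class = "model_spec")
  p$schedule <- structure(as.list(p$schedule), class = "training_schedule")
  structure(p, class = cls[1])
}

#' Write a validation report as JSON plus a readable text table
#' @param report a `validation_report`.
#' @param path output `.json` file; a `.txt` twin holds the printed table.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  txt <- sub("\\.json$", ".txt", path)
  if (txt == path) txt <- paste0(path, ".txt")
  con <- file(txt, "w")
  sink(con)
  print(report)
  sink()
  close(con)
  invisible(path)
}

#' MD5 hash of an R object via its canonical JSON form
#' @param x any jsonlite-serializable object.
#' @return hex digest string.
#' @export
config_hash <- function(x) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(x, tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}
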