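# Plain-text readers/writers for sweep families and truth manifests.
# Data files are tab-separated with an explicit header; recording
# metadata and the protocol travel in a YAML sidecar next to the data.

sidecar_path <- function(path) paste0(sub("\\.tsv$", "", path), ".meta.yaml")

#' Write a sweep family to disk
#'
#' Writes a tab-separated trace table (`sweep_id`, `time_ms`,
#' `voltage_mV`, `current_pA`) and a YAML sidecar
#' (`<stem>.meta.yaml`) carrying the protocol and recording metadata.
#'
#' @param family A [sweep_family()].
#' @param path Output path for the table (conventionally `.tsv`).
#' @return `path`, invisibly.
#' @export
write_sweep_family <- function(family, path) {
  stopifnot(inherits(family, "sweep_family"))
  p <- family$protocol
  t_ms <- protocol_times(p)
  rows <- lapply(seq_len(ncol(family$traces)), function(s) {
    data.frame(sweep_id = s, time_ms = t_ms,
               voltage_mV = command_voltage(p, s, t_ms),
               current_pA = family$traces[, s])
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  meta <- family$metadata
  side <- list(
    protocol = list(holding_mv = p$holding_mv,
                    step_levels_mv = as.list(p$steps$level_mv),
                    step_durations_ms = as.list(p$steps$duration_ms),
                    sweep_levels_mv = as.list(p$sweep_levels),
                    sampling_interval_ms = p$sampling_interval_ms,
                    pre_ms = p$pre_ms),
    metadata = meta)
  yaml::write_yaml(side, sidecar_path(path))
  invisible(path)
}

#' Read a sweep family from disk
#'
#' Reads the table/sidecar pair written by [write_sweep_family()],
#' validating the header, the numeric content (malformed rows are
#' reported with their line numbers), per-sweep time monotonicity, and
#' agreement between trace lengths and the sidecar protocol.
#'
#' @param path Path to the trace table.
#' @return A [sweep_family()].
#' @export
read_sweep_family <- function(path) {
  if (!file.exists(path)) domain_error(sprintf("no such file: %s", path))
  side_file <- sidecar_path(path)
  if (!file.exists(side_file)) {
    domain_error(sprintf("missing metadata sidecar: %s", side_file))
  }
  raw <- utils::read.table(path, sep = "\t", header = TRUE,
                           colClasses = "character")
  need <- c("sweep_id", "time_ms", "voltage_mV", "current_pA")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols)) {
    stop(errorCondition(
      sprintf("missing column(s): %s", paste(missing_cols, collapse = ", ")),
      class = c("hvchan_format_error", "error")))
  }
  num <- lapply(raw[need], function(x) suppressWarnings(as.numeric(x)))
  bad <- which(Reduce(`|`, lapply(num, is.na)))
  if (length(bad)) {
    stop(errorCondition(
      sprintf("non-numeric value(s) at data line(s): %s (file line(s) %s)",
              paste(utils::head(bad, 5), collapse = ", "),
              paste(utils::head(bad + 1L, 5), collapse = ", ")),
      class = c("hvchan_format_error", "error")))
  }
  df <- as.data.frame(num)
  side <- yaml::read_yaml(side_file)
  pr <- side$protocol
  protocol <- voltage_protocol(
    holding_mv = pr$holding_mv,
    steps = data.frame(level_mv = vapply(pr$step_levels_mv, function(x)
      if (is.null(x)) NA_real_ else as.numeric(x), numeric(1)),
      duration_ms = unlist(pr$step_durations_ms)),
    sweep_levels = if (length(pr$sweep_levels_mv))
      unlist(pr$sweep_levels_mv) else NULL,
    sampling_interval_ms = pr$sampling_interval_ms,
    pre_ms = pr$pre_ms)
  t_ms <- protocol_times(protocol)
  sweeps <- sort(unique(df$sweep_id))
  traces <- matrix(NA_real_, nrow = length(t_ms), ncol = length(sweeps))
  for (i in seq_along(sweeps)) {
    sub <- df[df$sweep_id == sweeps[i], ]
    if (is.unsorted(sub$time_ms, strictly = TRUE)) {
      stop(errorCondition(
        sprintf("non-monotone time in sweep %d", sweeps[i]),
        class = c("hvchan_format_error", "error")))
    }
    if (nrow(sub) != length(t_ms)) {
      stop(errorCondition(
        sprintf("sweep %d has %d samples but the protocol implies %d",
                sweeps[i], nrow(sub), length(t_ms)),
        class = c("hvchan_format_error", "error")))
    }
    traces[, i] <- sub$current_pA
  }
  meta <- side$metadata
  meta$series_resistance_mohm <- unlist(meta$series_resistance_mohm)
  sweep_family(protocol, traces, metadata = meta)
}

#' Write a truth manifest as YAML
#' @param manifest A [truth_manifest()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  stopifnot(inherits(manifest, "truth_manifest"))
  yaml::write_yaml(unclass(manifest), path)
  invisible(path)
}

#' Read a truth manifest written by [write_manifest()]
#' @param path Manifest path.
#' @return A [truth_manifest()].
#' @export
read_manifest <- function(path) {
  raw <- yaml::read_yaml(path)
  structure(raw, class = "truth_manifest")
}
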