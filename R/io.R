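## Readers and writers for every artefact the pipeline touches: multi-page
## TIFF movies with a JSON calibration sidecar, stimulus-protocol JSON,
## delimited synapse tables, and YAML configs.

#' Write a movie as multi-page TIFF with a JSON sidecar
#'
#' Planar movies store one page per frame; volumetric movies store
#' `T * Z` pages in Z-fastest order (page = `t * Z + z`, 0-based), as
#' declared in the sidecar. Values are stored as 16-bit unsigned integers
#' scaled by a recorded factor, so integer-valued data round-trips
#' bit-exactly.
#'
#' @param movie a [MovieStack].
#' @param path output `.tif` path; the sidecar goes to `<path>.json`.
#' @param protocol optional [StimulusProtocol] embedded in the sidecar.
#' @return `path`, invisibly.
#' @export
write_movie <- function(movie, path, protocol = NULL) {
  d <- dim(movie$data)
  mx <- max(movie$data, 1)
  scale <- if (mx <= 65535) 1 else 65535 / mx
  pages <- vector("list", d[4] * d[3])
  k <- 0L
  for (t in seq_len(d[4])) for (z in seq_len(d[3])) {
    k <- k + 1L
    pages[[k]] <- round(movie$data[, , z, t] * scale) / 65535
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none",
                  reduce = FALSE)
  side <- list(pixel_size_um = movie$pixel_size_um,
               frame_rate_hz = movie$frame_rate_hz,
               z_step_um = movie$z_step_um,
               n_z = d[3], n_frames = d[4], scale = scale,
               page_order = "z_fastest")
  if (!is.null(protocol))
    side$protocol <- list(trials = protocol$trials,
                          baseline_frames = protocol$baseline_frames,
                          frame_rate_hz = protocol$frame_rate_hz,
                          randomized = protocol$randomized)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a multi-page TIFF movie
#'
#' Reconstructs the `Y x X x Z x T` array from a TIFF written by
#' [write_movie()] (or any multi-page TIFF plus explicit calibration). The
#' page count must be divisible by the declared number of z-slices.
#'
#' @param path `.tif` path.
#' @param calibration optional list overriding/providing `pixel_size_um`,
#'   `frame_rate_hz`, `z_step_um`, `n_z`, `scale`; defaults come from the
#'   sidecar `<path>.json` when present.
#' @return list `movie` ([MovieStack]) and `protocol` ([StimulusProtocol] or
#'   `NULL`).
#' @export
read_movie <- function(path, calibration = list()) {
  if (!file.exists(path)) stop("read_movie: file not found: ", path)
  side_path <- paste0(path, ".json")
  side <- if (file.exists(side_path)) jsonlite::read_json(side_path) else list()
  get <- function(nm, default = NULL) calibration[[nm]] %||% side[[nm]] %||% default
  n_z <- as.integer(get("n_z", 1L))
  scale <- as.numeric(get("scale", 1))
  pages <- tiff::readTIFF(path, all = TRUE, info = FALSE)
  if (length(pages) %% n_z != 0L)
    stop(sprintf("read_movie: page count %d not divisible by Z = %d",
                 length(pages), n_z))
  n_t <- length(pages) %/% n_z
  d1 <- dim(pages[[1]])
  dat <- array(0, c(d1[1], d1[2], n_z, n_t))
  k <- 0L
  for (t in seq_len(n_t)) for (z in seq_len(n_z)) {
    k <- k + 1L
    dat[, , z, t] <- round(pages[[k]] * 65535) / scale
  }
  movie <- MovieStack(dat, as.numeric(get("pixel_size_um", 1)),
                      as.numeric(get("frame_rate_hz", 1)),
                      as.numeric(get("z_step_um", 1)))
  protocol <- NULL
  if (!is.null(side$protocol)) {
    p <- side$protocol
    tr <- do.call(rbind, lapply(p$trials, as.data.frame))
    protocol <- StimulusProtocol(tr, p$baseline_frames, p$frame_rate_hz,
                                 n_frames = n_t, randomized = isTRUE(p$randomized))
  }
  list(movie = movie, protocol = protocol)
}

#' Read a delimited synapse table
#'
#' Reads a CSV/TSV with header into the canonical synapse schema. Required
#' columns: `pre_id`, `post_id`, `x`, `y`, `z`, `region`; `compartment` is
#' optional. Compartment tags are case-folded; tags outside
#' `bouton/claw/dendrite/other` map to `"unknown"` and the normalization
#' count is attached as attribute `"io_log"` and reported. Coordinates are
#' treated as nanometres when no units column is present (connectome-export
#' convention).
#'
#' @param path file path (delimiter sniffed from the header line).
#' @return synapse data.frame.
#' @export
read_synapse_table <- function(path) {
  if (!file.exists(path)) stop("read_synapse_table: file not found: ", path)
  hdr <- readLines(path, n = 1L)
  sep <- if (grepl("\t", hdr)) "\t" else ","
  tb <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  required <- c("pre_id", "post_id", "x", "y", "z", "region")
  missing_cols <- setdiff(required, names(tb))
  if (length(missing_cols))
    stop("read_synapse_table: missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  if (!"compartment" %in% names(tb)) tb$compartment <- "unknown"
  raw <- tolower(trimws(as.character(tb$compartment)))
  valid <- c("bouton", "claw", "dendrite", "other", "unknown")
  normalized <- ifelse(raw %in% valid, raw, "unknown")
  n_case <- sum(normalized == raw & raw != as.character(tb$compartment))
  n_unknown <- sum(normalized == "unknown" & raw != "unknown")
  tb$compartment <- normalized
  if (n_case + n_unknown > 0)
    message("read_synapse_table: normalized ", n_case,
            " tag(s) by case-folding, mapped ", n_unknown, " to 'unknown'")
  if (any(!is.finite(tb$x) | !is.finite(tb$y) | !is.finite(tb$z)))
    stop("read_synapse_table: non-finite coordinates")
  attr(tb, "io_log") <- c(case_folded = n_case, to_unknown = n_unknown)
  attr(tb, "coordinate_units") <- "nm"
  tb
}

#' Write a synapse table as CSV
#' @param table synapse data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_synapse_table <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write / read a stimulus protocol as JSON
#' @param protocol a [StimulusProtocol].
#' @param path file path.
#' @return `path` invisibly / the [StimulusProtocol].
#' @export
write_protocol <- function(protocol, path) {
  jsonlite::write_json(list(trials = protocol$trials,
                            baseline_frames = protocol$baseline_frames,
                            frame_rate_hz = protocol$frame_rate_hz,
                            n_frames = protocol$n_frames,
                            randomized = protocol$randomized),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_protocol
#' @export
read_protocol <- function(path) {
  p <- jsonlite::read_json(path)
  tr <- do.call(rbind, lapply(p$trials, as.data.frame))
  StimulusProtocol(tr, p$baseline_frames, p$frame_rate_hz,
                   n_frames = p$n_frames, randomized = isTRUE(p$randomized))
}

#' Write / read a simulation or run configuration as YAML
#' @param config named list (e.g. a [sim_config()]).
#' @param path file path.
#' @return `path` invisibly / the configuration list.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (all(c("field_px", "n_mg", "frame_rate_hz") %in% names(cfg)))
    cfg <- do.call(sim_config, cfg)
  cfg
}
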