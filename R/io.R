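#' Load and validate a flat key=value run configuration
#'
#' Configuration files are flat `key = value` text (one pair per line, `#`
#' comments allowed). Every key must belong to the known schema; unknown
#' keys are rejected and numeric values are validated against the module
#' preconditions, with errors naming the offending key. Missing keys take
#' their documented defaults. All physical quantities keep the units in
#' their key names (nm, um, mm, cm, 1/cm).
#'
#' @param path Path to the configuration file.
#' @return A validated named list of class `run_config` with all defaults
#'   filled in.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) abort(paste0("Config file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- lengths(kv) != 2
  if (any(bad)) abort(paste0("Unparseable config line: ", lines[bad][1]))
  keys <- trimws(vapply(kv, `[`, "", 1))
  vals <- trimws(vapply(kv, `[`, "", 2))
  if (anyDuplicated(keys)) {
    abort(paste0("Duplicate config key: ", keys[duplicated(keys)][1]))
  }
  schema <- config_schema()
  unknown <- setdiff(keys, names(schema))
  if (length(unknown)) abort(paste0("Unknown config key: ", unknown[1]))
  cfg <- lapply(schema, function(s) s$default)
  for (i in seq_along(keys)) {
    s <- schema[[keys[i]]]
    v <- if (s$type == "character") vals[i] else {
      num <- suppressWarnings(as.numeric(vals[i]))
      if (is.na(num)) abort(paste0("Non-numeric value for key: ", keys[i]))
      num
    }
    cfg[[keys[i]]] <- v
  }
  for (k in names(schema)) {
    s <- schema[[k]]
    if (!is.null(s$check) && !s$check(cfg[[k]])) {
      abort(paste0("Invalid value for config key: ", k))
    }
  }
  structure(cfg, class = "run_config")
}

config_schema <- function() {
  pos <- function(v) is.numeric(v) && v > 0
  nonneg <- function(v) is.numeric(v) && v >= 0
  list(
    wavelength_nm = list(default = 635, type = "numeric", check = pos),
    host_index = list(default = 1.33, type = "numeric",
                      check = function(v) v >= 1),
    sphere_index = list(default = 1.59, type = "numeric", check = pos),
    diameter_um = list(default = 1.04, type = "numeric", check = pos),
    angle_resolution_deg = list(default = 0.25, type = "numeric",
                                check = function(v) v > 0 && v <= 1),
    incident_state = list(default = "linear_minus45", type = "character",
                          check = function(v) v %in% c(
                            "linear_minus45", "linear_plus45",
                            "circular_right", "circular_left")),
    mus_per_cm = list(default = 25, type = "numeric", check = pos),
    mua_per_cm = list(default = 0, type = "numeric", check = nonneg),
    box_cm = list(default = 2.2, type = "numeric", check = pos),
    beam_mm = list(default = 3, type = "numeric", check = pos),
    nx = list(default = 101, type = "numeric", check = pos),
    ny = list(default = 101, type = "numeric", check = pos),
    field_mm = list(default = 20, type = "numeric", check = pos),
    acceptance_deg = list(default = 15, type = "numeric",
                          check = function(v) v > 0 && v <= 90),
    n_packets = list(default = 1e6, type = "numeric", check = pos),
    seed = list(default = 1, type = "numeric", check = nonneg),
    max_events = list(default = 1e5, type = "numeric", check = pos),
    disc_diameter_mm = list(default = 3, type = "numeric", check = pos),
    rect_width_mm = list(default = 1.5, type = "numeric", check = pos),
    rect_length_mm = list(default = Inf, type = "numeric", check = pos),
    rect_angle_deg = list(default = 90, type = "numeric", check = is.numeric),
    annulus_inner_mm = list(default = 1.5, type = "numeric", check = nonneg),
    annulus_outer_mm = list(default = 6, type = "numeric", check = pos),
    min_photons = list(default = 5, type = "numeric", check = pos))
}

#' @rdname load_config
#' @param config A `run_config` (or plain named list drawn from the schema).
#' @export
save_config <- function(config, path) {
  keys <- intersect(names(config_schema()), names(config))
  writeLines(vapply(keys, function(k) {
    v <- config[[k]]
    sprintf("%s = %s", k,
            if (is.character(v)) v else format(v, digits = 17))
  }, ""), path)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Result container: a directory of full-precision TSV arrays plus a JSON
# metadata sidecar. Lossless for both counts and floats; TIFF export is
# offered separately for interoperability with imaging tools.

container_version <- "polarpath-container-1"

#' Write / read a simulation result container
#'
#' `write_result()` stores a [run_simulation()] result as a directory
#' holding one full-precision TSV file per image plane plus a
#' `metadata.json` sidecar (version stamp, run metadata, config echo);
#' `read_result()` restores it losslessly. Exit records, when present, are
#' stored alongside as `exits.tsv`.
#'
#' @param sim A `polarpath_sim`.
#' @param path Container directory (created if needed).
#' @return `write_result()` returns `path` invisibly; `read_result()`
#'   returns the restored `polarpath_sim`.
#' @export
write_result <- function(sim, path) {
  stopifnot(inherits(sim, "polarpath_sim"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(sim$images)) {
    write_matrix_tsv(sim$images[[nm]], file.path(path, paste0(nm, ".tsv")))
  }
  if (!is.null(sim$exits)) {
    fmt <- as.data.frame(lapply(sim$exits, function(col) sprintf("%.17g", col)))
    names(fmt) <- names(sim$exits)
    utils::write.table(fmt, file.path(path, "exits.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  meta <- sim$meta
  jsonlite::write_json(
    list(version = container_version, channels = names(sim$images),
         meta = meta),
    file.path(path, "metadata.json"), auto_unbox = TRUE, digits = NA,
    null = "null")
  invisible(path)
}

write_matrix_tsv <- function(m, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(apply(m, 2, function(col)
    paste(format(col, digits = 17, scientific = TRUE, trim = TRUE),
          collapse = "\t")), con)
}

read_matrix_tsv <- function(path, nx) {
  v <- scan(path, what = double(), sep = "\t", quiet = TRUE)
  matrix(v, nrow = nx)
}

#' @rdname write_result
#' @export
read_result <- function(path) {
  mf <- file.path(path, "metadata.json")
  if (!file.exists(mf)) abort(paste0("Not a result container (no metadata.json): ", path))
  md <- jsonlite::read_json(mf, simplifyVector = TRUE)
  if (!identical(md$version, container_version)) {
    abort(paste0("Unsupported container version: ", md$version))
  }
  meta <- md$meta
  images <- list()
  for (nm in md$channels) {
    f <- file.path(path, paste0(nm, ".tsv"))
    if (!file.exists(f)) abort(paste0("Container is missing channel: ", nm))
    images[[nm]] <- read_matrix_tsv(f, meta$nx)
  }
  exits <- NULL
  ef <- file.path(path, "exits.tsv")
  if (file.exists(ef)) {
    exits <- tibble::as_tibble(utils::read.table(ef, header = TRUE, sep = "\t"))
  }
  structure(list(images = images, meta = meta, exits = exits),
            class = "polarpath_sim")
}

#' Export a result's channel images as 32-bit float TIFF
#'
#' Convenience export for imaging tools; the TSV container written by
#' [write_result()] remains the lossless format of record.
#'
#' @param sim A `polarpath_sim`.
#' @param path Output directory.
#' @param channels Channels to export.
#' @export
export_tiff <- function(sim, path, channels = c("co_linear", "cross_linear",
                                                "co_circular",
                                                "cross_circular")) {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    abort("The 'tiff' package is required for TIFF export.")
  }
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  for (nm in channels) {
    img <- sim$images[[nm]]
    tiff::writeTIFF(t(img) / max(img, 1e-300),
                    file.path(path, paste0(nm, ".tiff")),
                    bits.per.sample = 32L, reduce = FALSE)
  }
  invisible(path)
}
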