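#' Read landmark configurations from a TPS file
#'
#' Parses the TPS dialect used for curve-landmarked dorsal profiles: each
#' record is an `LM=30` line followed by 30 `x y` coordinate lines (dot
#' decimal separator only) and key lines, of which `ID=` is mandatory and
#' carries the study classifiers (see [parse_id_code()]). `IMAGE=`,
#' `SCALE=` and any unknown keys are preserved and written back by
#' [write_tps()]. `SCALE=` is ignored for shape analysis: Procrustes
#' superimposition removes scale.
#'
#' Coordinates are interpreted with y increasing upward. For files
#' digitized in a y-down image origin, pass `y_down = TRUE` together with
#' `image_height` to flip into analysis space.
#'
#' @param path Path to a TPS file. LF and CRLF line endings are accepted.
#' @param y_down Logical; if `TRUE`, y coordinates are flipped as
#'   `image_height - y`.
#' @param image_height Raster height in pixels, required when
#'   `y_down = TRUE`.
#' @return A [landmark_dataset()].
#' @export
read_tps <- function(path, y_down = FALSE, image_height = NULL) {
  if (!file.exists(path)) stop("TPS file not found: ", path)
  if (y_down && is.null(image_height))
    stop("`image_height` is required when `y_down = TRUE`")
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)
  lm_at <- grep("^[Ll][Mm]=", lines)
  configs <- list()
  for (r in seq_along(lm_at)) {
    start <- lm_at[r]
    end <- if (r < length(lm_at)) lm_at[r + 1L] - 1L else length(lines)
    rec <- lines[start:end]
    n_lm <- suppressWarnings(as.integer(sub("^[Ll][Mm]=", "", rec[1L])))
    if (is.na(n_lm) || n_lm != N_LANDMARKS)
      stop("record ", r, " (line ", start, "): LM=", sub("^[Ll][Mm]=", "", rec[1L]),
           " but this dialect requires LM=", N_LANDMARKS)
    if (length(rec) < 1L + n_lm)
      stop("record ", r, " (line ", start, "): fewer than ", n_lm,
           " coordinate lines")
    coord_lines <- rec[2L:(1L + n_lm)]
    pts <- matrix(NA_real_, n_lm, 2L)
    for (j in seq_len(n_lm)) {
      ln <- trimws(coord_lines[j])
      if (grepl(",", ln, fixed = TRUE))
        stop("record ", r, " (line ", start + j,
             "): comma decimal separator found; this dialect requires dots")
      parts <- strsplit(ln, "[ \t]+")[[1L]]
      vals <- suppressWarnings(as.numeric(parts))
      if (length(vals) != 2L || anyNA(vals))
        stop("record ", r, " (line ", start + j,
             "): expected two numeric coordinates, got '", ln, "'")
      pts[j, ] <- vals
    }
    keys <- rec[-seq_len(1L + n_lm)]
    keys <- keys[nzchar(trimws(keys))]
    if (any(!grepl("=", keys, fixed = TRUE)))
      stop("record ", r, " (line ", start,
           "): unexpected non key=value trailing line")
    key_names <- toupper(sub("=.*$", "", keys))
    key_vals <- sub("^[^=]*=", "", keys)
    names(key_vals) <- key_names
    if (!"ID" %in% key_names)
      stop("record ", r, " (line ", start, "): missing ID key")
    if (y_down) pts[, 2L] <- image_height - pts[, 2L]
    extra <- key_vals[key_names != "ID"]
    configs[[r]] <- landmark_config(pts, id = unname(key_vals[["ID"]]),
                                    extra = extra)
  }
  landmark_dataset(configs)
}

#' Write a landmark dataset to a TPS file
#'
#' Inverse of [read_tps()]: one `LM=30` block per configuration, dot
#' decimal separators, `ID=` encoding the classifiers, preserved extra keys
#' after the ID. Writing then re-reading then re-writing is byte-identical.
#'
#' @param dataset A [landmark_dataset()].
#' @param path Output file path.
#' @param digits Significant digits for coordinates (default 10, enough for
#'   pixel coordinates to round-trip visually losslessly).
#' @return `path`, invisibly.
#' @export
write_tps <- function(dataset, path, digits = 10L) {
  stopifnot(inherits(dataset, "landmark_dataset"))
  n <- n_specimens(dataset)
  out <- character(0)
  for (i in seq_len(n)) {
    pts <- dataset$coords[, , i]
    if (nrow(pts) != N_LANDMARKS)
      stop("configuration ", i, " does not have ", N_LANDMARKS, " points")
    coord_lines <- paste(formatC(pts[, 1L], digits = digits, format = "g"),
                         formatC(pts[, 2L], digits = digits, format = "g"))
    rec <- c(sprintf("LM=%d", N_LANDMARKS), coord_lines,
             sprintf("ID=%s", dataset$meta$specimen_id[i]))
    extra <- dataset$extra[[i]]
    if (length(extra))
      rec <- c(rec, paste0(names(extra), "=", unname(extra)))
    out <- c(out, rec)
  }
  writeLines(out, path, sep = "\n")
  invisible(path)
}
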