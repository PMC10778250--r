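#' Lunging-aid codes
#'
#' The four head/neck-position conditions and their one-letter ID codes:
#' A = FMH (freely moving head), B = CH (chambon), C = RB (rubber band),
#' D = TRs (triangle side reins).
#'
#' @format Named character vector mapping code letter to condition label.
#' @export
LUNGING_AIDS <- c(A = "FMH", B = "CH", C = "RB", D = "TRs")

N_LANDMARKS <- 30L

#' Body region of each dorsal-profile landmark
#'
#' The 30-point dorsal-profile curve is partitioned into three body regions:
#' landmarks 1-8 hindquarter, 9-19 back, 20-30 head/neck (1-based indices).
#'
#' @return Character vector of length 30 with values `"hindquarter"`,
#'   `"back"`, `"head_neck"`.
#' @export
landmark_regions <- function() {
  c(rep("hindquarter", 8L), rep("back", 11L), rep("head_neck", 11L))
}

#' Construct a single landmark configuration
#'
#' A configuration is one specimen's 30 ordered 2-D landmarks (image-pixel
#' units, y increasing upward) together with the study classifiers decoded
#' from its ID code: lunging aid, time (0 before / 1 after lunging), and
#' individual number 1-52.
#'
#' @param points Numeric 30 x 2 matrix of (x, y) landmark coordinates.
#' @param id ID code such as `"A001"` (aid letter, time digit, individual
#'   01-52); parsed with [parse_id_code()]. Either `id` or all three of
#'   `lunging_aid`, `time`, `individual` must be given.
#' @param lunging_aid One of `"FMH"`, `"CH"`, `"RB"`, `"TRs"`.
#' @param time Integer 0 (before lunging) or 1 (after).
#' @param individual Integer 1-52.
#' @param extra Named character vector of extra TPS record keys (e.g.
#'   `IMAGE`, `SCALE`) preserved on round-trip.
#' @return Object of class `landmark_config`.
#' @export
landmark_config <- function(points, id = NULL, lunging_aid = NULL,
                            time = NULL, individual = NULL,
                            extra = character()) {
  points <- as.matrix(points)
  if (!is.numeric(points) || ncol(points) != 2L)
    stop("`points` must be a numeric matrix with two columns (x, y)")
  if (nrow(points) != N_LANDMARKS)
    stop("a configuration must have exactly ", N_LANDMARKS,
         " landmarks, got ", nrow(points))
  if (!all(is.finite(points)))
    stop("all landmark coordinates must be finite")
  if (!is.null(id)) {
    dec <- parse_id_code(id)
    lunging_aid <- dec$lunging_aid
    time <- dec$time
    individual <- dec$individual
  } else {
    if (is.null(lunging_aid) || is.null(time) || is.null(individual))
      stop("give either `id` or all of `lunging_aid`, `time`, `individual`")
    id <- make_id_code(lunging_aid, time, individual)
  }
  dimnames(points) <- list(NULL, c("x", "y"))
  structure(
    list(specimen_id = id, lunging_aid = lunging_aid, time = as.integer(time),
         individual = as.integer(individual), points = points,
         region_of = landmark_regions(), extra = extra),
    class = "landmark_config")
}

#' @export
print.landmark_config <- function(x, ...) {
  cat("<landmark_config> ", x$specimen_id, ": ", x$lunging_aid,
      if (x$time == 0L) ", before lunging" else ", after lunging",
      ", individual ", x$individual, "\n", sep = "")
  cat("  30 landmarks, x range [", format(min(x$points[, 1])), ", ",
      format(max(x$points[, 1])), "], y range [", format(min(x$points[, 2])),
      ", ", format(max(x$points[, 2])), "]\n", sep = "")
  invisible(x)
}

#' Parse a study ID code
#'
#' ID codes are four characters: a lunging-aid letter (A = FMH, B = CH,
#' C = RB, D = TRs), a time digit (0 before, 1 after lunging), and a
#' two-digit individual number 01-52.
#'
#' @param code Character scalar, e.g. `"A001"` or `"D152"`.
#' @return List with `lunging_aid`, `time` (integer 0/1), `individual`
#'   (integer 1-52).
#' @seealso [make_id_code()] for the inverse.
#' @examples
#' parse_id_code("A001")  # FMH, before, individual 1
#' parse_id_code("D152")  # TRs, after,  individual 52
#' @export
parse_id_code <- function(code) {
  if (!is.character(code) || length(code) != 1L)
    stop("`code` must be a single character string")
  if (!grepl("^[A-D][01][0-9]{2}$", code))
    stop("malformed ID code '", code,
         "': expected aid letter A-D, time digit 0/1, individual 01-52")
  ind <- as.integer(substr(code, 3L, 4L))
  if (ind < 1L || ind > 52L)
    stop("individual code in '", code, "' must be between 01 and 52")
  list(lunging_aid = unname(LUNGING_AIDS[substr(code, 1L, 1L)]),
       time = as.integer(substr(code, 2L, 2L)),
       individual = ind)
}

#' Encode classifiers into a study ID code
#'
#' @param lunging_aid One of `"FMH"`, `"CH"`, `"RB"`, `"TRs"` (or the code
#'   letter A-D itself).
#' @param time 0 or 1.
#' @param individual Integer 1-52.
#' @return Four-character ID code.
#' @export
make_id_code <- function(lunging_aid, time, individual) {
  if (lunging_aid %in% names(LUNGING_AIDS)) {
    letter <- lunging_aid
  } else {
    letter <- names(LUNGING_AIDS)[match(lunging_aid, LUNGING_AIDS)]
    if (is.na(letter)) stop("unknown lunging aid '", lunging_aid, "'")
  }
  time <- as.integer(time)
  if (!time %in% c(0L, 1L)) stop("`time` must be 0 (before) or 1 (after)")
  individual <- as.integer(individual)
  if (individual < 1L || individual > 52L)
    stop("`individual` must be in 1..52")
  sprintf("%s%d%02d", letter, time, individual)
}

#' Bundle configurations into a landmark dataset
#'
#' Datasets hold coordinates as a p x 2 x n array (p = 30 landmarks,
#' n specimens) with a classifier table in `$meta`, the layout standard in
#' geometric-morphometric software.
#'
#' @param configs List of [landmark_config()] objects.
#' @return Object of class `landmark_dataset` with elements `coords`
#'   (30 x 2 x n array), `meta` (data.frame: specimen_id, lunging_aid,
#'   time, individual), `extra` (list of per-record extra TPS keys).
#' @export
landmark_dataset <- function(configs) {
  if (length(configs) == 0L) {
    return(structure(list(
      coords = array(numeric(0), dim = c(N_LANDMARKS, 2L, 0L)),
      meta = data.frame(specimen_id = character(), lunging_aid = character(),
                        time = integer(), individual = integer(),
                        stringsAsFactors = FALSE),
      extra = list()), class = "landmark_dataset"))
  }
  stopifnot(all(vapply(configs, inherits, logical(1), "landmark_config")))
  coords <- array(NA_real_, dim = c(N_LANDMARKS, 2L, length(configs)),
                  dimnames = list(NULL, c("x", "y"), NULL))
  for (i in seq_along(configs)) coords[, , i] <- configs[[i]]$points
  meta <- data.frame(
    specimen_id = vapply(configs, `[[`, character(1), "specimen_id"),
    lunging_aid = vapply(configs, `[[`, character(1), "lunging_aid"),
    time = vapply(configs, `[[`, integer(1), "time"),
    individual = vapply(configs, `[[`, integer(1), "individual"),
    stringsAsFactors = FALSE)
  structure(list(coords = coords, meta = meta,
                 extra = lapply(configs, `[[`, "extra")),
            class = "landmark_dataset")
}

#' @export
print.landmark_dataset <- function(x, ...) {
  n <- dim(x$coords)[3]
  cat("<landmark_dataset> ", n, " configurations of ", dim(x$coords)[1],
      " 2-D landmarks\n", sep = "")
  if (n > 0) {
    cat("  lunging aids:", paste(names(table(x$meta$lunging_aid)),
                                 table(x$meta$lunging_aid), collapse = ", "), "\n")
    cat("  time points: before =", sum(x$meta$time == 0L),
        ", after =", sum(x$meta$time == 1L), "\n")
  }
  invisible(x)
}

#' Number of specimens in a landmark dataset
#' @param dataset A `landmark_dataset`.
#' @return Integer count.
#' @export
n_specimens <- function(dataset) dim(dataset$coords)[3]

#' Extract one configuration from a dataset
#' @param dataset A `landmark_dataset`.
#' @param i Specimen index.
#' @return A `landmark_config`.
#' @export
get_config <- function(dataset, i) {
  landmark_config(dataset$coords[, , i], id = dataset$meta$specimen_id[i],
                  extra = dataset$extra[[i]])
}

#' Subset a landmark dataset by specimen
#' @param dataset A `landmark_dataset`.
#' @param idx Integer or logical index over specimens.
#' @return A `landmark_dataset` with the selected specimens.
#' @export
subset_dataset <- function(dataset, idx) {
  if (is.logical(idx)) idx <- which(idx)
  structure(list(coords = dataset$coords[, , idx, drop = FALSE],
                 meta = dataset$meta[idx, , drop = FALSE],
                 extra = dataset$extra[idx]),
            class = "landmark_dataset")
}

#' Flatten a dataset to a long data frame
#'
#' One row per landmark per specimen, with classifier columns and the body
#' region of each landmark; the layout used for CSV export.
#'
#' @param dataset A `landmark_dataset`.
#' @return data.frame with columns specimen_id, la, time, individual,
#'   lm_index, x, y, region.
#' @export
dataset_to_df <- function(dataset) {
  n <- n_specimens(dataset)
  p <- dim(dataset$coords)[1]
  regions <- landmark_regions()
  do.call(rbind, lapply(seq_len(n), function(i) {
    data.frame(specimen_id = dataset$meta$specimen_id[i],
               la = dataset$meta$lunging_aid[i],
               time = dataset$meta$time[i],
               individual = dataset$meta$individual[i],
               lm_index = seq_len(p),
               x = dataset$coords[, 1, i],
               y = dataset$coords[, 2, i],
               region = regions,
               stringsAsFactors = FALSE)
  }))
}
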