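#' @importFrom stats lm coef fitted cor pt quantile rnorm sd setNames t.test var
#' @importFrom utils read.csv write.csv
NULL

# Internal helpers -----------------------------------------------------------

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_conebend <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "conebend_error")))
}

check_finite_xy <- function(x, y, where = "coordinates") {
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    stop_conebend(sprintf("non-finite %s", where), "conebend_parse_error")
  }
}

# Constructors ---------------------------------------------------------------

#' Analysis configuration
#'
#' Bundles the run-level settings shared by the readers and pipeline stages:
#' the pixel-to-millimetre calibration, whether image rows are flipped to a
#' mathematical (y up) orientation at parse time, the candidate polynomial
#' ranks for profile fitting, the random seed, and the two significance
#' thresholds used to classify group comparisons.
#'
#' @param scale_factor Length of one pixel in mm (> 0). Inputs already in mm
#'   use the default 1.
#' @param flip_y Flip the image y axis (y down) to mathematical orientation
#'   (y up) at parse time. Tables already in right-handed coordinates keep
#'   the default `FALSE`.
#' @param poly_ranks Integer polynomial degrees considered when fitting
#'   profiles (default 2 and 3).
#' @param rank_criterion Criterion used to choose among ranks; only
#'   `"adjusted_R2"` is implemented.
#' @param seed Integer random seed recorded in run manifests.
#' @param p_moderate,p_strong Significance thresholds: p below `p_moderate`
#'   but above `p_strong` is classed moderate, p at or below `p_strong`
#'   strong.
#' @return An object of class `analysis_config`.
#' @export
analysis_config <- function(scale_factor = 1, flip_y = FALSE,
                            poly_ranks = c(2L, 3L),
                            rank_criterion = "adjusted_R2",
                            seed = 1L,
                            p_moderate = 0.05, p_strong = 0.01) {
  if (!is.numeric(scale_factor) || scale_factor <= 0) {
    stop_conebend("scale_factor must be > 0", "conebend_config_error")
  }
  poly_ranks <- sort(unique(as.integer(poly_ranks)))
  if (any(poly_ranks < 1)) {
    stop_conebend("polynomial ranks must be >= 1", "conebend_config_error")
  }
  if (!(p_strong > 0 && p_moderate < 1 && p_strong < p_moderate)) {
    stop_conebend("significance thresholds must satisfy 0 < p_strong < p_moderate < 1",
                  "conebend_config_error")
  }
  structure(list(scale_factor = scale_factor, flip_y = isTRUE(flip_y),
                 poly_ranks = poly_ranks, rank_criterion = rank_criterion,
                 seed = as.integer(seed),
                 p_moderate = p_moderate, p_strong = p_strong),
            class = "analysis_config")
}

#' Ordered landmark set of one surface in one hydration state
#'
#' @param specimen_id Specimen identifier.
#' @param surface `"adaxial"` or `"abaxial"`.
#' @param state `"dry"` or `"wet"`.
#' @param landmark_id Character vector of unique landmark labels.
#' @param x,y Numeric coordinates in mm.
#' @param region Lamina region; one of `"proximal"`, `"middle"`, `"distal"`,
#'   `"unspecified"`.
#' @return A `landmark_set`, a data frame of landmarks with metadata
#'   attributes.
#' @export
landmark_set <- function(specimen_id, surface, state, landmark_id, x, y,
                         region = "unspecified") {
  surface <- match.arg(surface, c("adaxial", "abaxial"))
  state <- match.arg(state, c("dry", "wet"))
  region <- match.arg(region, c("proximal", "middle", "distal", "unspecified"))
  landmark_id <- as.character(landmark_id)
  if (anyDuplicated(landmark_id)) {
    stop_conebend("duplicate landmark_id in landmark set", "conebend_schema_error")
  }
  check_finite_xy(x, y, "landmark coordinates")
  df <- data.frame(landmark_id = landmark_id, x = as.numeric(x),
                   y = as.numeric(y), stringsAsFactors = FALSE)
  structure(df, specimen_id = as.character(specimen_id), surface = surface,
            state = state, region = region,
            class = c("landmark_set", "data.frame"))
}

#' Dry/wet landmark correspondence
#'
#' Pairs two landmark sets of the same specimen surface in opposite
#' hydration states by landmark id; the declared reference set defines the
#' reference configuration for strain fitting.
#'
#' @param reference,observed `landmark_set` objects in different states.
#' @return A `landmark_correspondence` with matrices `X` (reference) and
#'   `x` (observed), rows aligned by landmark id.
#' @export
landmark_correspondence <- function(reference, observed) {
  stopifnot(inherits(reference, "landmark_set"), inherits(observed, "landmark_set"))
  if (attr(reference, "specimen_id") != attr(observed, "specimen_id") ||
      attr(reference, "surface") != attr(observed, "surface")) {
    stop_conebend("correspondence requires same specimen and surface",
                  "conebend_pairing_error")
  }
  if (attr(reference, "state") == attr(observed, "state")) {
    stop_conebend("reference and observed must be in different hydration states",
                  "conebend_pairing_error")
  }
  if (!setequal(reference$landmark_id, observed$landmark_id)) {
    stop_conebend("landmark_id sets differ between states", "conebend_pairing_error")
  }
  ord <- match(reference$landmark_id, observed$landmark_id)
  structure(list(
    specimen_id = attr(reference, "specimen_id"),
    surface = attr(reference, "surface"),
    region = attr(reference, "region"),
    reference_state = attr(reference, "state"),
    landmark_id = reference$landmark_id,
    X = cbind(x = reference$x, y = reference$y),
    x = cbind(x = observed$x[ord], y = observed$y[ord])
  ), class = "landmark_correspondence")
}

#' Digitized profile trace
#'
#' An ordered polyline digitized along one side of a lamina square or strip
#' profile. Point order follows the digitization order.
#'
#' @param specimen_id Specimen identifier.
#' @param orientation `"LONGIT"` (parallel to the scale axis) or `"TRANSV"`.
#' @param side `"abaxial"` or `"adaxial"`.
#' @param state `"dry"` or `"wet"`.
#' @param x,y Numeric coordinates in mm.
#' @param treatment Free-text tag, e.g. `"intact"` or `"milled"`.
#' @return A `profile_trace` data frame with metadata attributes.
#' @export
profile_trace <- function(specimen_id, orientation, side, state, x, y,
                          treatment = "intact") {
  orientation <- match.arg(orientation, c("LONGIT", "TRANSV"))
  side <- match.arg(side, c("abaxial", "adaxial"))
  state <- match.arg(state, c("dry", "wet"))
  check_finite_xy(x, y, "profile coordinates")
  df <- data.frame(x = as.numeric(x), y = as.numeric(y))
  structure(df, specimen_id = as.character(specimen_id),
            orientation = orientation, side = side, state = state,
            treatment = as.character(treatment),
            class = c("profile_trace", "data.frame"))
}

#' Paired segment lengths in dry and wet state
#'
#' @param L_dry,L_wet Segment lengths (mm), strictly positive.
#' @param direction `"LONGIT"`, `"TRANSV"` or `"THICKNESS"`.
#' @param label Free-text label (e.g. `"AB-AD"`, `"AB-VB"`).
#' @return A `segment_pair` list.
#' @export
segment_pair <- function(L_dry, L_wet, direction = "LONGIT", label = "") {
  direction <- match.arg(direction, c("LONGIT", "TRANSV", "THICKNESS"))
  if (!is.finite(L_dry) || !is.finite(L_wet) || L_dry <= 0 || L_wet <= 0) {
    stop_conebend("segment lengths must be strictly positive", "conebend_domain_error")
  }
  structure(list(L_dry = L_dry, L_wet = L_wet, direction = direction,
                 label = label),
            class = "segment_pair")
}

# Readers --------------------------------------------------------------------

require_columns <- function(df, cols, path) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop_conebend(sprintf("%s: missing required column(s): %s", path,
                          paste(missing, collapse = ", ")),
                  "conebend_schema_error")
  }
}

numeric_or_die <- function(v, col, path) {
  out <- suppressWarnings(as.numeric(v))
  bad <- which(is.na(out) & !is.na(v))
  if (length(bad)) {
    stop_conebend(sprintf("%s: non-numeric value in column '%s' at data row %d",
                          path, col, bad[1]), "conebend_parse_error")
  }
  out
}

apply_calibration <- function(x, y, config) {
  x <- x * config$scale_factor
  y <- y * config$scale_factor
  if (config$flip_y) y <- -y
  list(x = x, y = y)
}

#' Read a landmark coordinate table
#'
#' Reads a CSV with columns `specimen_id, surface, state, region,
#' landmark_id, x, y` and groups rows into one [landmark_set] per
#' (specimen, surface, state). Coordinates are converted from pixels to mm
#' by the configuration scale factor; if `flip_y` is set the image y axis
#' is flipped to mathematical orientation.
#'
#' @param path CSV file path.
#' @param config An [analysis_config].
#' @return List of `landmark_set` objects (empty, with a warning, for a
#'   header-only file).
#' @export
read_landmark_table <- function(path, config = analysis_config()) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  require_columns(df, c("specimen_id", "surface", "state", "region",
                        "landmark_id", "x", "y"), path)
  if (nrow(df) == 0) {
    warning(sprintf("%s: no landmark records", path))
    return(list())
  }
  df$x <- numeric_or_die(df$x, "x", path)
  df$y <- numeric_or_die(df$y, "y", path)
  xy <- apply_calibration(df$x, df$y, config)
  df$x <- xy$x; df$y <- xy$y
  key <- interaction(df$specimen_id, df$surface, df$state, drop = TRUE)
  out <- lapply(split(df, key), function(g) {
    landmark_set(g$specimen_id[1], g$surface[1], g$state[1],
                 g$landmark_id, g$x, g$y, region = g$region[1])
  })
  message(sprintf("read_landmark_table: %d records -> %d landmark sets",
                  nrow(df), length(out)))
  unname(out)
}

#' Read a profile point table
#'
#' Reads a CSV with columns `specimen_id, orientation, side, state,
#' treatment, point_index, x, y`, orders points within each trace by
#' `point_index` and returns one [profile_trace] per trace. Duplicate
#' point indices within a trace are an integrity error.
#'
#' @inheritParams read_landmark_table
#' @return List of `profile_trace` objects.
#' @export
read_profile_table <- function(path, config = analysis_config()) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  require_columns(df, c("specimen_id", "orientation", "side", "state",
                        "treatment", "point_index", "x", "y"), path)
  if (nrow(df) == 0) {
    warning(sprintf("%s: no profile records", path))
    return(list())
  }
  df$x <- numeric_or_die(df$x, "x", path)
  df$y <- numeric_or_die(df$y, "y", path)
  df$point_index <- numeric_or_die(df$point_index, "point_index", path)
  xy <- apply_calibration(df$x, df$y, config)
  df$x <- xy$x; df$y <- xy$y
  key <- interaction(df$specimen_id, df$orientation, df$side, df$state,
                     df$treatment, drop = TRUE)
  out <- lapply(split(df, key), function(g) {
    if (anyDuplicated(g$point_index)) {
      stop_conebend(sprintf("%s: duplicate point_index within trace %s", path,
                            g$specimen_id[1]), "conebend_integrity_error")
    }
    g <- g[order(g$point_index), ]
    profile_trace(g$specimen_id[1], g$orientation[1], g$side[1], g$state[1],
                  g$x, g$y, treatment = g$treatment[1])
  })
  message(sprintf("read_profile_table: %d records -> %d traces",
                  nrow(df), length(out)))
  unname(out)
}

# Writers --------------------------------------------------------------------

#' Write a result table with a JSON run-manifest sidecar
#'
#' Serializes a data frame (or a list of flat records) as CSV with a stable
#' column order and floats at 6 significant digits, and writes a
#' `<path>.manifest.json` sidecar recording the configuration, seed and
#' package version.
#'
#' @param table Data frame or list of flat records.
#' @param path Output CSV path.
#' @param config Optional [analysis_config] recorded in the sidecar.
#' @return Invisibly, the path written.
#' @export
write_results <- function(table, path, config = NULL) {
  if (!is.data.frame(table)) {
    table <- do.call(rbind, lapply(table, function(r) as.data.frame(r, stringsAsFactors = FALSE)))
    if (is.null(table)) table <- data.frame()
  }
  out <- table
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], function(v) signif(v, 6))
  tryCatch(write.csv(out, path, row.names = FALSE, quote = FALSE),
           error = function(e) stop_conebend(
             sprintf("cannot write results to %s: %s", path, conditionMessage(e)),
             "conebend_io_error"))
  sidecar <- list(
    version = as.character(utils::packageVersion("conebend")),
    written = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
    rows = nrow(out),
    config = if (is.null(config)) NULL else unclass(config)
  )
  jsonlite::write_json(sidecar, paste0(path, ".manifest.json"),
                       auto_unbox = TRUE, null = "null")
  invisible(path)
}
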