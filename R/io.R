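# Fixed CSV schemas (comma, dot decimal, UTF-8, header row).
.schema_nights <- c("experiment_id", "arena_id", "repetition_id", "night_index",
                    "session_id", "n_females", "clusters_treatment",
                    "clusters_control")
.schema_eggs <- c("night_index", "female_id", "cluster_id", "position_cm",
                  "n_eggs")
.schema_tracks <- c("moth_id", "trial_id", "playback_side", "t_s", "x_cm",
                    "y_cm")

.check_cols <- function(df, schema, file) {
  miss <- setdiff(schema, names(df))
  if (length(miss))
    stop("file '", file, "' is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  df[schema]
}

.check_numeric <- function(df, fields, file) {
  for (f in fields) {
    v <- suppressWarnings(as.numeric(df[[f]]))
    bad <- which(is.na(v) & !is.na(df[[f]]))
    if (length(bad))
      stop("file '", file, "', row ", bad[1], ", field '", f,
           "': non-numeric value '", df[[f]][bad[1]], "'", call. = FALSE)
    if (anyNA(v))
      stop("file '", file, "', row ", which(is.na(v))[1], ", field '", f,
           "': missing value", call. = FALSE)
    df[[f]] <- v
  }
  df
}

.row_check <- function(cond, df, field, file, what) {
  bad <- which(!cond)
  if (length(bad))
    stop("file '", file, "', row ", bad[1], ", field '", field, "': ", what,
         " (value ", format(df[[field]][bad[1]]), ")", call. = FALSE)
}

#' Write / read the canonical experiment tables
#'
#' CSV writers with fixed headers and validating readers for the three
#' record types: arena-night cluster counts (\code{nights.csv}), gradient
#' egg clusters (\code{eggs.csv}) and moth tracks (\code{tracks.csv}).
#' Readers check the schema, numeric fields and range invariants and report
#' errors by file, row and field.
#'
#' @param nights,eggs,tracks data frames in the respective schema.
#' @param path file path.
#' @param arena_halflength gradient arena half-length used for the position
#'   bound check, cm.
#' @return readers return the validated data frame; writers return the path
#'   invisibly.
#' @name table_io
NULL

#' @rdname table_io
#' @export
write_nights <- function(nights, path) {
  df <- .check_cols(nights, .schema_nights, path)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname table_io
#' @export
read_nights <- function(path) {
  if (!file.exists(path)) stop("file '", path, "' does not exist", call. = FALSE)
  df <- read.csv(path, stringsAsFactors = FALSE)
  df <- .check_cols(df, .schema_nights, path)
  df <- .check_numeric(df, c("night_index", "n_females", "clusters_treatment",
                             "clusters_control"), path)
  .row_check(df$night_index >= 1, df, "night_index", path, "must be >= 1")
  .row_check(df$clusters_treatment >= 0, df, "clusters_treatment", path,
             "must be >= 0")
  .row_check(df$clusters_control >= 0, df, "clusters_control", path,
             "must be >= 0")
  df$zero_laying <- df$clusters_treatment == 0 & df$clusters_control == 0
  df
}

#' @rdname table_io
#' @export
write_eggs <- function(eggs, path) {
  df <- .check_cols(eggs, .schema_eggs, path)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname table_io
#' @export
read_eggs <- function(path, arena_halflength = 75) {
  if (!file.exists(path)) stop("file '", path, "' does not exist", call. = FALSE)
  df <- read.csv(path, stringsAsFactors = FALSE)
  df <- .check_cols(df, .schema_eggs, path)
  df <- .check_numeric(df, c("night_index", "position_cm", "n_eggs"), path)
  .row_check(abs(df$position_cm) <= arena_halflength, df, "position_cm", path,
             paste0("must lie within the ", arena_halflength, " cm bound"))
  .row_check(df$n_eggs >= 1, df, "n_eggs", path, "must be >= 1")
  .row_check(df$night_index >= 1, df, "night_index", path, "must be >= 1")
  df
}

#' @rdname table_io
#' @export
write_tracks <- function(tracks, path) {
  df <- .check_cols(tracks, .schema_tracks, path)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname table_io
#' @export
read_tracks <- function(path) {
  if (!file.exists(path)) stop("file '", path, "' does not exist", call. = FALSE)
  df <- read.csv(path, stringsAsFactors = FALSE)
  df <- .check_cols(df, .schema_tracks, path)
  df <- .check_numeric(df, c("t_s", "x_cm", "y_cm"), path)
  .row_check(df$playback_side %in% c("left", "right"), df, "playback_side",
             path, "must be 'left' or 'right'")
  df
}

#' Read a simulator or pipeline configuration document
#'
#' JSON (".json") or YAML (".yml"/".yaml") by file extension; every
#' configuration field is addressable by name.
#'
#' @param path configuration file path.
#' @return named list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("file '", path, "' does not exist", call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") jsonlite::read_json(path, simplifyVector = TRUE)
  else if (ext %in% c("yml", "yaml")) yaml::read_yaml(path)
  else stop("unsupported config format '.", ext, "' (use JSON or YAML)",
            call. = FALSE)
}

#' Read any subset of the canonical tables
#'
#' @param paths named list with any of \code{nights}, \code{eggs},
#'   \code{tracks}.
#' @return named list of validated data frames.
#' @export
read_tables <- function(paths) {
  out <- list()
  if (!is.null(paths$nights)) out$nights <- read_nights(paths$nights)
  if (!is.null(paths$eggs)) out$eggs <- read_eggs(paths$eggs)
  if (!is.null(paths$tracks)) out$tracks <- read_tracks(paths$tracks)
  out
}

#' Normalise gradient positions to the speaker-at-minus-75 convention
#'
#' In the physical experiment the speaker and resistor swap ends between
#' nights; analyses use a normalised coordinate in which the speaker end is
#' always -75 cm.  Positions recorded with the speaker on the positive end
#' are sign-flipped (the feeder at 0 is unaffected).
#'
#' @param position signed positions, cm.
#' @param speaker_side physical speaker end per record: "left"/"right",
#'   or -1/+1.
#' @return normalised positions with the speaker at the negative end.
#' @export
normalize_speaker_side <- function(position, speaker_side) {
  if (is.character(speaker_side)) {
    if (!all(speaker_side %in% c("left", "right")))
      stop("speaker_side must be 'left'/'right' or -1/+1", call. = FALSE)
    s <- ifelse(speaker_side == "left", -1, 1)
  } else {
    s <- sign(as.numeric(speaker_side))
    if (any(!s %in% c(-1, 1)))
      stop("speaker_side must be 'left'/'right' or -1/+1", call. = FALSE)
  }
  ifelse(s < 0, position, -position)
}

#' Import a deposited-style gradient egg table
#'
#' Thin adapter for externally deposited tables whose column names differ
#' from the canonical schema: columns are mapped by a user-supplied map and
#' positions are normalised so the speaker end is -75 cm regardless of the
#' physical side on a given night.
#'
#' @param path CSV file.
#' @param column_map named character vector mapping canonical names
#'   (\code{night_index}, \code{female_id}, \code{cluster_id},
#'   \code{position_cm}, \code{n_eggs}, \code{speaker_side}) to the file's
#'   column names.
#' @param arena_halflength arena half-length, cm.
#' @return validated egg data frame in the canonical schema, positions
#'   normalised.
#' @export
read_eggs_deposited <- function(path, column_map, arena_halflength = 75) {
  if (!file.exists(path)) stop("file '", path, "' does not exist", call. = FALSE)
  raw <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("night_index", "female_id", "cluster_id", "position_cm", "n_eggs",
            "speaker_side")
  miss <- setdiff(need, names(column_map))
  if (length(miss))
    stop("column_map is missing: ", paste(miss, collapse = ", "), call. = FALSE)
  absent <- setdiff(unname(column_map[need]), names(raw))
  if (length(absent))
    stop("file '", path, "' has no column(s): ", paste(absent, collapse = ", "),
         call. = FALSE)
  df <- data.frame(night_index = raw[[column_map[["night_index"]]]],
                   female_id = as.character(raw[[column_map[["female_id"]]]]),
                   cluster_id = as.character(raw[[column_map[["cluster_id"]]]]),
                   position_cm = normalize_speaker_side(
                     as.numeric(raw[[column_map[["position_cm"]]]]),
                     raw[[column_map[["speaker_side"]]]]),
                   n_eggs = raw[[column_map[["n_eggs"]]]],
                   stringsAsFactors = FALSE)
  tmp <- tempfile(fileext = ".csv")
  on.exit(unlink(tmp))
  write_eggs(df, tmp)
  read_eggs(tmp, arena_halflength)
}
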