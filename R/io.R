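# Reading and writing gridded fields, colony tables and region
# boundary specifications.
#
# Gridded fields use a self-describing text format: a one-line JSON
# header (variable name, units, dimension sizes, coordinates, calendar
# stamps) followed by one line of space-separated values per
# (member, time) slice, printed at full double precision so that a
# write/read round trip is bit-exact. Missing values are written "NA".

.AEVF_MAGIC <- "#AEVF1"

#' Write gridded fields
#'
#' Writes each field to `<dir>/<name>.aevf` in the package's text field
#' format (JSON header + full-precision values).
#'
#' @param fields a [GriddedField-class] or named list of them
#' @param dir output directory (created if needed)
#' @return invisibly, the paths written
#' @export
writeFields <- function(fields, dir) {
  if (is(fields, "GriddedField")) fields <- stats::setNames(
    list(fields), fields@name)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(names(fields), function(nm) {
    f <- fields[[nm]]
    stopifnot(is(f, "GriddedField"))
    path <- file.path(dir, paste0(nm, ".aevf"))
    d <- dim(f@data)
    hdr <- jsonlite::toJSON(list(
      name = f@name, units = f@units, dims = d,
      years = f@years, months = f@months
    ), auto_unbox = TRUE, digits = NA)
    con <- file(path, "w")
    on.exit(close(con), add = TRUE)
    writeLines(c(.AEVF_MAGIC, as.character(hdr)), con)
    for (m in seq_len(d[1])) for (t in seq_len(d[2])) {
      v <- as.vector(f@data[m, t, , ])
      writeLines(paste(ifelse(is.na(v), "NA", sprintf("%.17g", v)),
                       collapse = " "), con)
    }
    path
  }, "")
  invisible(paths)
}

#' Read gridded fields
#'
#' Reads files written by [writeFields()]. Sea-ice concentration fields
#' whose units declare percent are normalised to fraction with a
#' warning; a missing units entry is an error.
#'
#' @param paths file path(s), or a directory containing `.aevf` files
#' @return named list of [GriddedField-class]
#' @export
readFields <- function(paths) {
  if (length(paths) == 1 && dir.exists(paths))
    paths <- list.files(paths, pattern = "\\.aevf$", full.names = TRUE)
  out <- lapply(paths, .readField)
  stats::setNames(out, vapply(out, function(f) f@name, ""))
}

.readField <- function(path) {
  lines <- readLines(path)
  if (!length(lines) || lines[1] != .AEVF_MAGIC)
    stop("not a gridded-field file: ", path)
  hdr <- jsonlite::fromJSON(lines[2])
  for (need in c("name", "units", "dims", "years", "months"))
    if (is.null(hdr[[need]]))
      stop("field file missing header entry '", need, "': ", path)
  d <- as.integer(hdr$dims)
  if (length(lines) - 2L != d[1] * d[2])
    stop("field file has ", length(lines) - 2L, " data lines, expected ",
         d[1] * d[2], ": ", path)
  arr <- array(NA_real_, dim = d)
  k <- 3L
  for (m in seq_len(d[1])) for (t in seq_len(d[2])) {
    v <- scan(text = lines[k], what = double(), na.strings = "NA",
              quiet = TRUE)
    arr[m, t, , ] <- v
    k <- k + 1L
  }
  units <- hdr$units
  if (hdr$name == "SIC" &&
      grepl("^(%|percent)$", units, ignore.case = TRUE)) {
    warning("SIC units '", units, "' normalised to fraction")
    arr <- arr / 100
    units <- "1"
  }
  new("GriddedField", name = hdr$name, units = units, data = arr,
      years = as.integer(hdr$years), months = as.integer(hdr$months))
}

#' Read or write a penguin colony table
#'
#' Comma-separated tables with columns colony_id, lat, lon, abundance
#' and optionally species and nest-count columns (year, count,
#' count_se).
#'
#' @param path csv path
#' @return data.frame
#' @export
readColonyTable <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("colony_id", "lat", "lon", "abundance")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("colony table missing columns: ", paste(miss, collapse = ", "))
  if (any(tab$abundance < 0)) stop("abundances must be >= 0")
  tab
}

#' @rdname readColonyTable
#' @param colonies data.frame to write
#' @export
writeColonyTable <- function(colonies, path) {
  utils::write.csv(colonies, path, row.names = FALSE)
  invisible(path)
}

#' Read or write region boundary specifications
#'
#' Structured-text (YAML) config mapping each region name to a list of
#' `[lon_start, lon_end]` sectors in degrees east.
#'
#' @param path yaml path
#' @return named list of sectors as used by [regionMasks()]
#' @export
readRegionBoundaries <- function(path) {
  spec <- yaml::read_yaml(path)
  lapply(spec, function(sectors) lapply(sectors, as.numeric))
}

#' @rdname readRegionBoundaries
#' @param boundaries named sector list to write
#' @export
writeRegionBoundaries <- function(boundaries, path) {
  yaml::write_yaml(boundaries, path)
  invisible(path)
}
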