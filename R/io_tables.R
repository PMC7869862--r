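# Long-format per-parameter statistics tables (one record per
# object x parameter x channel, the dialect cell-analysis suites export one
# CSV per parameter in), their concatenation into a single wide summary
# table, and the flow-software-compatible CSV export of that table.

#' Construct a long-format statistics table
#'
#' @param object_id positive integer ids.
#' @param parameter_name parameter name per record (e.g. "volume_um3").
#' @param value numeric values.
#' @param channel optional channel name per record (`NA` for geometric
#'   parameters).
#' @return a `data.table` of class `statistics_long`.
#' @export
statistics_long <- function(object_id, parameter_name, value, channel = NA_character_) {
  dt <- data.table::data.table(
    object_id = as.integer(object_id),
    parameter_name = as.character(parameter_name),
    channel = as.character(channel),
    value = as.numeric(value)
  )
  if (nrow(dt) && any(dt$object_id <= 0L | is.na(dt$object_id))) {
    stopf("object_id must be positive integers")
  }
  if (anyDuplicated(dt, by = c("object_id", "parameter_name", "channel"))) {
    stopf("(object_id, parameter_name, channel) must be unique per table")
  }
  data.table::setattr(dt, "class", c("statistics_long", class(dt)))
  dt[]
}

#' Read a long-format statistics CSV
#'
#' With `lenient = TRUE` the parser skips leading title/unit header lines
#' (as found in instrument exports) until it finds the line carrying the
#' `object_id` column header.
#'
#' @param path CSV path.
#' @param lenient skip non-conforming leading lines.
#' @return a `statistics_long` table.
#' @export
read_statistics_csv <- function(path, lenient = FALSE) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  skip <- 0L
  header_re <- "(^|[,;\t])\\s*\"?object_id\"?\\s*([,;\t]|$)"
  if (lenient) {
    lines <- readLines(path, n = 25L, warn = FALSE)
    hit <- grep(header_re, lines)
    if (!length(hit)) stopf("no 'object_id' header found in %s", path)
    skip <- hit[1L] - 1L
  } else {
    first <- readLines(path, n = 1L, warn = FALSE)
    if (!length(first) || !grepl(header_re, first)) {
      stopf("statistics CSV must have columns object_id, parameter_name, value on line 1 (use lenient = TRUE for instrument exports)")
    }
  }
  dt <- data.table::fread(path, skip = skip, header = TRUE)
  need <- c("object_id", "parameter_name", "value")
  if (!all(need %in% names(dt))) {
    stopf("statistics CSV must have columns %s", paste(need, collapse = ", "))
  }
  if (!"channel" %in% names(dt)) dt[, channel := NA_character_]
  statistics_long(dt$object_id, dt$parameter_name, dt$value, dt$channel)
}

#' Write a long-format statistics CSV
#' @param table a `statistics_long` table.
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
write_statistics_csv <- function(table, path) {
  data.table::fwrite(table, path, na = "")
  invisible(path)
}

#' Concatenate long statistics tables into one wide summary table
#'
#' One row per object id, one column per parameter x channel combination.
#' Column order is deterministic: sorted by parameter name, then channel.
#' Objects missing a parameter get `NA` (exported as an empty CSV cell).
#' The same record may appear in several input tables only with an
#' identical value; conflicting duplicates are an error naming the
#' collision.
#'
#' @param tables list of `statistics_long` tables.
#' @return a wide `data.table`, first column `object_id` (sorted).
#' @export
concat_statistics <- function(tables) {
  if (!length(tables)) stopf("tables must be a non-empty list")
  if (inherits(tables, "data.frame")) tables <- list(tables)
  long <- data.table::rbindlist(tables, use.names = TRUE)
  if (any(long$object_id <= 0L)) stopf("object_id must be positive integers")
  long <- unique(long, by = c("object_id", "parameter_name", "channel", "value"))
  dup <- duplicated(long, by = c("object_id", "parameter_name", "channel"))
  if (any(dup)) {
    d <- long[dup][1L]
    stopf("conflicting duplicate record: object_id=%d parameter='%s' channel='%s'",
          d$object_id, d$parameter_name,
          ifelse(is.na(d$channel), "", d$channel))
  }
  long[, col := ifelse(is.na(channel) | channel == "",
                       parameter_name, paste(parameter_name, channel, sep = "_"))]
  key <- unique(long[, .(parameter_name, channel, col)])
  data.table::setorder(key, parameter_name, channel, na.last = FALSE)
  wide <- data.table::dcast(long, object_id ~ col, value.var = "value")
  data.table::setcolorder(wide, c("object_id", key$col))
  data.table::setorder(wide, object_id)
  wide[]
}

#' Export a wide table as a flow-software-compatible CSV
#'
#' Plain RFC-4180 CSV: one header row, one data row per object, '.' decimal
#' separator, no thousands separators, missing values as empty cells.
#' Re-parsing with [read_flowjo_csv()] yields the same table, and a second
#' export of the re-parsed table is byte-identical.
#'
#' @param wide wide `data.table`/data.frame with numeric columns only.
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
export_flowjo_csv <- function(wide, path) {
  wide <- data.table::as.data.table(wide)
  bad <- names(wide)[!vapply(wide, is.numeric, TRUE)]
  if (length(bad)) {
    stopf("non-numeric column(s) in wide table: %s", paste(bad, collapse = ", "))
  }
  data.table::fwrite(wide, path, na = "", sep = ",", dec = ".",
                     scipen = 999L, eol = "\n")
  invisible(path)
}

#' Read back a CSV written by [export_flowjo_csv()]
#' @param path CSV path.
#' @return a wide `data.table`.
#' @export
read_flowjo_csv <- function(path) {
  dt <- data.table::fread(path, header = TRUE, sep = ",", na.strings = "")
  if ("object_id" %in% names(dt)) dt[, object_id := as.integer(object_id)]
  dt[]
}
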