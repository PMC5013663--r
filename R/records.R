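#' Rearing records
#'
#' A rearing-record table holds one row per collected caterpillar: where and
#' when it was collected (site, spatial block, sampling round or BACI
#' timestep, habitat, transect vs extra sampling), its host taxon, whether it
#' was reared through to moth or parasitoid emergence, and the parasitoid
#' taxon if one emerged. Parasitism is only observable through successful
#' rearing, so a recorded parasitoid implies `reared_ok = TRUE`.
#'
#' Canonical columns: `record_id, dataset, site_id, block_id, round,
#' timestep, habitat, source, host_taxon, reared_ok, parasitoid_taxon`.
#' `habitat` is `"P"` (plantation) or `"N"` (native); `source` is
#' `"transect"` or `"extra"`; `dataset` is `"training"` (carries `round`) or
#' `"validation"` (carries `timestep`, `"before"`/`"after"`). An empty
#' `parasitoid_taxon` means the individual was not (observed) parasitized.
#'
#' @name rearing_records
NULL

REARING_COLS <- c("record_id", "dataset", "site_id", "block_id", "round",
                  "timestep", "habitat", "source", "host_taxon", "reared_ok",
                  "parasitoid_taxon")

#' Read rearing records from CSV
#'
#' Reads a comma-separated, UTF-8, headered file of rearing records and
#' validates every row. Column names can be remapped through `schema`.
#'
#' @param path Path to a CSV file.
#' @param schema Optional named character vector mapping canonical column
#'   names (names) to the column names used in the file (values), e.g.
#'   `c(host_taxon = "species")`. Unmapped canonical names are looked up
#'   directly.
#' @return A validated `rearing_records` data frame.
#' @seealso [as_rearing_records()] for validating an in-memory data frame.
#' @export
read_rearing_records <- function(path, schema = NULL) {
  if (!file.exists(path)) {
    stop_edgeweb("rearing-record file not found: ", path)
  }
  df <- utils::read.csv(path, colClasses = "character",
                        stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  if (!is.null(schema)) {
    if (is.null(names(schema)) || any(names(schema) == "")) {
      stop_edgeweb("schema must be a named character vector (canonical = file)")
    }
    for (canon in names(schema)) {
      file_col <- schema[[canon]]
      if (!file_col %in% names(df)) {
        stop_edgeweb("schema maps '", canon, "' to missing column '",
                     file_col, "'", class = "edgeweb_schema_error")
      }
      names(df)[names(df) == file_col] <- canon
    }
  }
  missing <- setdiff(REARING_COLS, names(df))
  if (length(missing)) {
    stop_edgeweb("missing required column(s): ",
                 paste(missing, collapse = ", "),
                 class = "edgeweb_schema_error")
  }
  if (nrow(df) == 0) {
    warning("rearing-record file has a header but no rows: ", path)
  }
  as_rearing_records(df)
}

#' Validate and type a rearing-record data frame
#'
#' Checks every invariant of the record model and returns a typed
#' `rearing_records` data frame. Rows violating any invariant abort with a
#' row-numbered diagnostic.
#'
#' @param df A data frame with the canonical rearing-record columns.
#' @return A `rearing_records` data frame.
#' @export
as_rearing_records <- function(df) {
  missing <- setdiff(REARING_COLS, names(df))
  if (length(missing)) {
    stop_edgeweb("missing required column(s): ",
                 paste(missing, collapse = ", "),
                 class = "edgeweb_schema_error")
  }
  df <- df[REARING_COLS]
  for (col in c("record_id", "dataset", "site_id", "block_id", "timestep",
                "habitat", "source", "host_taxon", "parasitoid_taxon")) {
    df[[col]] <- as.character(df[[col]])
  }
  df$parasitoid_taxon[is.na(df$parasitoid_taxon) |
                        df$parasitoid_taxon == ""] <- NA_character_
  df$timestep[is.na(df$timestep) | df$timestep == ""] <- NA_character_
  reared_raw <- tolower(as.character(df$reared_ok))
  df$reared_ok <- reared_raw %in% c("true", "t", "1", "yes")
  bad_reared <- !reared_raw %in% c("true", "t", "1", "yes",
                                   "false", "f", "0", "no")
  df$round <- suppressWarnings(as.integer(df$round))

  problems <- character(0)
  flag <- function(bad, msg) {
    if (any(bad)) {
      rows <- which(bad)
      shown <- utils::head(rows, 10)
      problems <<- c(problems, paste0(
        msg, " (row", if (length(rows) > 1) "s" else "", " ",
        paste(shown, collapse = ", "),
        if (length(rows) > length(shown)) ", ..." else "", ")"))
    }
  }
  flag(bad_reared, "reared_ok must be TRUE/FALSE")
  flag(!df$dataset %in% c("training", "validation"),
       "dataset must be 'training' or 'validation'")
  flag(!df$habitat %in% c("P", "N"), "habitat must be 'P' or 'N'")
  flag(!df$source %in% c("transect", "extra"),
       "source must be 'transect' or 'extra'")
  flag(!is.na(df$parasitoid_taxon) & !df$reared_ok,
       "parasitoid_taxon recorded for an individual not reared to emergence")
  flag(df$dataset == "training" & is.na(df$round),
       "training records must carry a sampling round")
  flag(df$dataset == "validation" &
         (is.na(df$timestep) | !df$timestep %in% c("before", "after")),
       "validation records must carry timestep 'before' or 'after'")
  flag(is.na(df$host_taxon) | df$host_taxon == "",
       "host_taxon must be non-empty")
  if (length(problems)) {
    stop_edgeweb("invalid rearing records:\n  ",
                 paste(problems, collapse = "\n  "),
                 class = "edgeweb_validation_error")
  }
  class(df) <- c("rearing_records", "data.frame")
  df
}

#' Write rearing records to CSV
#'
#' @param records A `rearing_records` data frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_rearing_records <- function(records, path) {
  out <- as.data.frame(records)
  out$parasitoid_taxon[is.na(out$parasitoid_taxon)] <- ""
  out$timestep[is.na(out$timestep)] <- ""
  out$round[is.na(out$round)] <- ""
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}
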