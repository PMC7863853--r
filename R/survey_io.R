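#' Read and validate one wave of unit-record survey data
#'
#' Reads a delimited text file (CSV, header row naming codebook items) and
#' validates every cell against the codebook: values outside an item's level
#' set (and not a declared missing code) are set to `NA` and counted in the
#' validation report. Validation is idempotent — re-validating an already
#' validated table produces zero new warnings.
#'
#' @param path CSV file path, or a data frame already in memory.
#' @param codebook a `worry_codebook` (see [default_codebook()]).
#' @param wave integer wave id, 2 or 3.
#' @return A data frame of validated records with columns `respondent_id`,
#'   `wave`, and one column per codebook item present in the file. The
#'   validation report (a data frame of per-item invalid counts) is attached
#'   as attribute `"validation"`; retrieve it with [validation_report()].
#' @export
read_wave <- function(path, codebook = default_codebook(), wave) {
  wave <- as.integer(wave)
  if (!wave %in% c(2L, 3L)) stop("unknown wave id: ", wave, " (must be 2 or 3)")
  dat <- if (is.data.frame(path)) {
    as.data.frame(path, stringsAsFactors = FALSE)
  } else {
    utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character",
                    check.names = FALSE)
  }
  mandatory <- c("respondent_id", "worried", "takes_precautions",
                 "qol_worry", "qol_precautions")
  absent <- setdiff(mandatory, names(dat))
  if (length(absent))
    stop("missing mandatory columns: ", paste(absent, collapse = ", "))
  if (anyDuplicated(dat$respondent_id))
    stop("duplicate respondent_id within wave ", wave)
  validate_wave(dat, codebook, wave)
}

# Cell-level validation against the codebook. Invalid levels -> NA with a
# per-item count in the report; missing codes -> NA silently.
validate_wave <- function(dat, codebook, wave) {
  items <- intersect(codebook$item, names(dat))
  report <- data.frame(item = character(0), n_invalid = integer(0))
  for (item in items) {
    e <- codebook_entry(codebook, item)
    x <- dat[[item]]
    if (e$type == "count") {
      xi <- suppressWarnings(as.integer(as.character(x)))
      was_missing <- is.na(x) | as.character(x) %in% e$missing_codes
      bad <- !was_missing & (is.na(xi) | xi < e$levels[1] | xi > e$levels[2])
      xi[bad | was_missing] <- NA_integer_
      dat[[item]] <- xi
    } else {
      xc <- as.character(x)
      was_missing <- is.na(xc) | xc %in% e$missing_codes
      bad <- !was_missing & !xc %in% e$levels
      xc[bad | was_missing] <- NA_character_
      dat[[item]] <- xc
    }
    if (any(bad))
      report <- rbind(report, data.frame(item = item, n_invalid = sum(bad)))
  }
  dat$wave <- rep(wave, nrow(dat))
  ord <- c("respondent_id", "wave", items)
  dat <- dat[, c(ord, setdiff(names(dat), ord)), drop = FALSE]
  attr(dat, "validation") <- report
  class(dat) <- c("wave_table", "data.frame")
  dat
}

#' @rdname read_wave
#' @param x a validated wave table.
#' @export
validation_report <- function(x) {
  rep <- attr(x, "validation")
  if (is.null(rep)) data.frame(item = character(0), n_invalid = integer(0)) else rep
}

#' Link two wave tables into a panel
#'
#' Matches respondents across waves on `respondent_id`. Respondents present
#' in only one wave are retained and flagged, since attrition between waves
#' is expected in online panels.
#'
#' @param wave2,wave3 validated wave tables (see [read_wave()]).
#' @return An object of class `panel_table`: a list with elements `wave2`,
#'   `wave3` (the input tables) and `linkage`, a data frame with columns
#'   `respondent_id` and `linkage_status`
#'   (`"both_waves"`, `"wave2_only"`, `"wave3_only"`).
#' @export
link_panel <- function(wave2, wave3) {
  if (anyDuplicated(wave2$respondent_id)) stop("duplicate respondent_id in wave 2")
  if (anyDuplicated(wave3$respondent_id)) stop("duplicate respondent_id in wave 3")
  ids2 <- wave2$respondent_id
  ids3 <- wave3$respondent_id
  both <- intersect(ids2, ids3)
  if (!length(both)) warning("no respondents appear in both waves")
  linkage <- rbind(
    data.frame(respondent_id = both,
               linkage_status = rep("both_waves", length(both))),
    data.frame(respondent_id = setdiff(ids2, ids3),
               linkage_status = rep("wave2_only", length(setdiff(ids2, ids3)))),
    data.frame(respondent_id = setdiff(ids3, ids2),
               linkage_status = rep("wave3_only", length(setdiff(ids3, ids2))))
  )
  structure(list(wave2 = wave2, wave3 = wave3, linkage = linkage),
            class = "panel_table")
}

#' @export
print.panel_table <- function(x, ...) {
  tab <- table(x$linkage$linkage_status)
  cat(sprintf("<panel_table> wave2 n=%d, wave3 n=%d\n",
              nrow(x$wave2), nrow(x$wave3)))
  cat(paste(sprintf("  %s: %d", names(tab), as.integer(tab)), collapse = "\n"), "\n")
  invisible(x)
}

#' Write analysis tables as CSV with a stable layout
#'
#' Writes each table in a named list to `<dir>/<name>.csv` with fixed column
#' ordering and no row names, so identical inputs yield byte-identical files.
#'
#' @param tables named list of data frames.
#' @param dir output directory, created if needed.
#' @return Invisibly, the character vector of file paths written.
#' @export
write_outputs <- function(tables, dir) {
  stopifnot(is.list(tables), length(names(tables)) == length(tables))
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok && !dir.exists(dir)) stop("cannot create output directory: ", dir)
  }
  paths <- character(0)
  for (nm in names(tables)) {
    p <- file.path(dir, paste0(nm, ".csv"))
    df <- as.data.frame(tables[[nm]])
    utils::write.csv(df, p, row.names = FALSE, quote = TRUE, fileEncoding = "UTF-8")
    paths <- c(paths, p)
  }
  invisible(paths)
}
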