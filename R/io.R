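#' Read individual-tracked census data in long format
#'
#' Long format has one row per (individual, census) presence: an individual's
#' row at a time unit means it was alive (counted) there. Units are ordered
#' numerically when every label parses as a number, by calendar date when
#' every label parses as an ISO date, or by an explicit `unitOrder`. An
#' optional comment line `#units=<label><sep><label>...` (as written by
#' [writeLongFormat()]) declares the full unit list, preserving units where
#' no individual was recorded and fixing their order.
#'
#' The species of an individual is taken from its first appearance; rows that
#' later relabel the same individual trigger a warning and are overridden
#' (re-identifications across censuses are common in long-running plot data).
#' Duplicate (individual, unit) rows are deduplicated with a warning.
#'
#' @param file path or connection to delimited text.
#' @param sep field delimiter (default `","`).
#' @param columns named character vector mapping the roles `individual`,
#'   `species`, `unit` to column names in the file.
#' @param unitOrder optional character vector giving the complete ordered
#'   unit list (overrides sorting and the `#units=` header).
#'
#' @return A [Census-class] object. Individuals appear in order of first
#'   appearance in the file.
#'
#' @examples
#' tf <- tempfile(fileext = ".csv")
#' writeLines(c("individual_id,species_id,time_unit",
#'              "i1,sp1,1", "i1,sp1,2", "i2,sp1,1"), tf)
#' cen <- readLongFormat(tf)
#' occupancy(cen)
#' @export
readLongFormat <- function(file,
                           sep = ",",
                           columns = c(individual = "individual_id",
                                       species = "species_id",
                                       unit = "time_unit"),
                           unitOrder = NULL) {
  stopifnot(all(c("individual", "species", "unit") %in% names(columns)))
  lines <- readLines(file)
  headerUnits <- NULL
  isUnitLine <- startsWith(lines, "#units=")
  if (any(isUnitLine)) {
    headerUnits <- strsplit(sub("^#units=", "", lines[isUnitLine][1L]),
                            sep, fixed = TRUE)[[1L]]
  }
  lines <- lines[!startsWith(lines, "#")]
  if (length(lines) <= 1L || all(!nzchar(lines[-1L])))
    stop("no records")
  df <- utils::read.table(text = lines, sep = sep, header = TRUE,
                          colClasses = "character", quote = "\"",
                          check.names = FALSE)
  missing <- setdiff(unname(columns[c("individual", "species", "unit")]),
                     colnames(df))
  if (length(missing))
    stop("missing column(s): ", paste(missing, collapse = ", "))
  if (nrow(df) == 0L) stop("no records")
  ind <- df[[columns[["individual"]]]]
  spp <- df[[columns[["species"]]]]
  unit <- df[[columns[["unit"]]]]

  dup <- duplicated(paste0(ind, "\r", unit))
  if (any(dup)) {
    warning(sum(dup), " duplicate (individual, unit) row(s) removed")
    # keep first occurrence; later conflicting species labels are handled below
    ind <- ind[!dup]; spp <- spp[!dup]; unit <- unit[!dup]
  }

  units <- .resolveUnits(unit, headerUnits, unitOrder)
  unitIdx <- match(unit, units)

  # first appearance = earliest unit, ties broken by file order
  ord <- order(unitIdx, seq_along(ind))
  firstRow <- ord[!duplicated(ind[ord])]
  ids <- ind[firstRow][order(match(ind[firstRow], unique(ind)))]
  species <- spp[firstRow][match(ids, ind[firstRow])]
  conflict <- tapply(spp, ind, function(s) length(unique(s)) > 1L)
  if (any(conflict))
    warning("conflicting species labels for individual(s) ",
            paste(names(conflict)[conflict], collapse = ", "),
            "; first appearance wins")

  z <- matrix(0L, nrow = length(ids), ncol = length(units),
              dimnames = list(ids, units))
  z[cbind(match(ind, ids), unitIdx)] <- 1L
  census(z, species = species)
}

# order the distinct unit labels: explicit order > header > numeric > date
.resolveUnits <- function(unit, headerUnits, unitOrder) {
  observed <- unique(unit)
  declared <- if (!is.null(unitOrder)) as.character(unitOrder) else headerUnits
  if (!is.null(declared)) {
    extra <- setdiff(observed, declared)
    if (length(extra))
      stop("unit label(s) not in the declared unit list: ",
           paste(extra, collapse = ", "))
    return(declared)
  }
  num <- suppressWarnings(as.numeric(observed))
  if (!anyNA(num)) return(observed[order(num)])
  dates <- suppressWarnings(as.Date(observed, optional = TRUE))
  if (!anyNA(dates)) return(observed[order(dates)])
  stop("time_unit values are neither numeric nor ISO dates; ",
       "supply unitOrder or a #units= header")
}

#' Write a Census as long-format delimited text
#'
#' Writes a `#units=` comment line declaring the full ordered unit list
#' (so units where no individual was recorded survive a round trip), a
#' header, and one row per (individual, unit) presence. Fields are quoted,
#' so species labels containing the delimiter are preserved.
#' `readLongFormat(writeLongFormat(x))` reproduces `x` exactly.
#'
#' @param x a [Census-class] object.
#' @param file path or connection to write to.
#' @param sep field delimiter (default `","`).
#' @param columns column names to use, as in [readLongFormat()].
#'
#' @return Invisibly, the file path/connection.
#' @export
writeLongFormat <- function(x, file,
                            sep = ",",
                            columns = c(individual = "individual_id",
                                        species = "species_id",
                                        unit = "time_unit")) {
  stopifnot(is(x, "Census"))
  z <- x@occupancy
  pres <- which(z == 1L, arr.ind = TRUE)
  pres <- pres[order(pres[, "row"], pres[, "col"]), , drop = FALSE]
  df <- data.frame(rownames(z)[pres[, "row"]],
                   x@species[pres[, "row"]],
                   colnames(z)[pres[, "col"]],
                   stringsAsFactors = FALSE)
  colnames(df) <- unname(columns[c("individual", "species", "unit")])
  con <- if (is.character(file)) file(file, "w") else file
  if (is.character(file)) on.exit(close(con))
  writeLines(paste0("#units=", paste(colnames(z), collapse = sep)), con)
  utils::write.table(df, con, sep = sep, quote = TRUE,
                     row.names = FALSE, col.names = TRUE)
  invisible(file)
}

#' Write a Census as a wide 0/1 occupancy table
#'
#' One row per individual with its id, species, and a 0/1 column per census
#' unit. Intended for inspection and interchange; [writeLongFormat()] is the
#' round-trip format.
#'
#' @param x a [Census-class] object.
#' @param file path or connection.
#' @param sep field delimiter (default tab).
#'
#' @return Invisibly, the file path/connection.
#' @export
writeWideFormat <- function(x, file, sep = "\t") {
  stopifnot(is(x, "Census"))
  df <- data.frame(individual_id = rownames(x@occupancy),
                   species_id = x@species,
                   x@occupancy, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, file, sep = sep, quote = TRUE, row.names = FALSE)
  invisible(file)
}

#' Read a multi-plot long-format file into a list of Census objects
#'
#' Splits a long-format table by a plot identifier column and reads each
#' plot independently (units are resolved per plot).
#'
#' @param file path to delimited text with a plot column.
#' @param plotCol name of the plot identifier column.
#' @inheritParams readLongFormat
#'
#' @return Named list of [Census-class] objects, one per plot, in order of
#'   first appearance.
#' @export
readCensusBatch <- function(file, plotCol = "plot_id",
                            sep = ",",
                            columns = c(individual = "individual_id",
                                        species = "species_id",
                                        unit = "time_unit"),
                            unitOrder = NULL) {
  df <- utils::read.table(file, sep = sep, header = TRUE,
                          colClasses = "character", quote = "\"",
                          comment.char = "#", check.names = FALSE)
  if (!plotCol %in% colnames(df))
    stop("missing plot column: ", plotCol)
  if (nrow(df) == 0L) stop("no records")
  plots <- unique(df[[plotCol]])
  out <- lapply(plots, function(p) {
    sub <- df[df[[plotCol]] == p, , drop = FALSE]
    tc <- textConnection(paste(
      c(paste(colnames(sub), collapse = sep),
        do.call(paste, c(lapply(sub, .quoteField, sep = sep), sep = sep))),
      collapse = "\n"))
    on.exit(close(tc))
    readLongFormat(tc, sep = sep, columns = columns, unitOrder = unitOrder)
  })
  names(out) <- plots
  out
}

.quoteField <- function(x, sep) {
  needs <- grepl(sep, x, fixed = TRUE) | grepl("\"", x, fixed = TRUE)
  x[needs] <- paste0("\"", gsub("\"", "\"\"", x[needs]), "\"")
  x
}
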