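#' Construct a Census from an occupancy matrix and species labels
#'
#' @param occupancy individuals x units matrix of 0/1 (logical or numeric
#'   accepted, coerced to integer). Rownames are individual ids (generated as
#'   `ind1, ind2, ...` if absent); colnames are the ordered census labels
#'   (generated as `t1, t2, ...` if absent). Column order defines time order.
#' @param species character vector of species ids, one per individual
#'   (recycled if length 1).
#' @param units optional character vector of unit labels overriding the
#'   colnames.
#'
#' @return A [Census-class] object.
#'
#' @examples
#' z <- rbind(i1 = c(1, 1), i2 = c(1, 0), i3 = c(1, 0),
#'            i4 = c(0, 1), i5 = c(0, 1))
#' colnames(z) <- c("1982", "1985")
#' cen <- census(z, species = c("sp1", "sp1", "sp2", "sp1", "sp3"))
#' cen
#' @export
census <- function(occupancy, species, units = NULL) {
  z <- as.matrix(occupancy)
  storage.mode(z) <- "integer"
  if (is.null(rownames(z)) && nrow(z) > 0L)
    rownames(z) <- paste0("ind", seq_len(nrow(z)))
  if (!is.null(units)) colnames(z) <- as.character(units)
  if (is.null(colnames(z))) colnames(z) <- paste0("t", seq_len(ncol(z)))
  if (length(species) == 1L && nrow(z) > 1L)
    species <- rep(species, nrow(z))
  if (nrow(z) == 0L) species <- character(0)
  new("Census", occupancy = z, species = as.character(species))
}

#' Accessors for Census and AbundanceMatrix objects
#'
#' @param x a [Census-class] or [AbundanceMatrix-class] object.
#'
#' @return `occupancy()` the 0/1 individuals x units matrix; `speciesIds()`
#'   the per-individual species labels (named by individual id);
#'   `individualIds()` the individual ids; `censusUnits()` the ordered unit
#'   labels; `nIndividuals()` the number of distinct individuals pooled over
#'   all units; `nUnits()` the number of census units.
#'
#' @name census-accessors
#' @aliases occupancy speciesIds individualIds censusUnits nIndividuals nUnits
NULL

#' @rdname census-accessors
#' @export
setMethod("occupancy", "Census", function(x) x@occupancy)

#' @rdname census-accessors
#' @export
setMethod("speciesIds", "Census",
  function(x) stats::setNames(x@species, rownames(x@occupancy)))

#' @rdname census-accessors
#' @export
setMethod("individualIds", "Census", function(x) rownames(x@occupancy))

#' @rdname census-accessors
#' @export
setMethod("censusUnits", "Census", function(x) colnames(x@occupancy))

#' @rdname census-accessors
#' @export
setMethod("nIndividuals", "Census", function(x) nrow(x@occupancy))

#' @rdname census-accessors
#' @export
setMethod("nUnits", "Census", function(x) ncol(x@occupancy))

setMethod("show", "Census", function(object) {
  z <- object@occupancy
  cat("Census with", nrow(z), "individuals,",
      length(unique(object@species)), "species,", ncol(z), "units\n")
  cat("units:", paste(utils::head(colnames(z), 8L), collapse = ", "),
      if (ncol(z) > 8L) "..." else "", "\n")
  cat("individuals alive per unit:",
      paste(utils::head(colSums(z), 8L), collapse = ", "),
      if (ncol(z) > 8L) "..." else "", "\n")
})

# index of a unit label, with a clear error for unknown labels
.unitIndex <- function(cen, u) {
  u <- as.character(u)
  i <- match(u, colnames(cen@occupancy))
  if (anyNA(i))
    stop("unknown unit label(s): ", paste(u[is.na(i)], collapse = ", "))
  i
}

# rows with an internal 0 between two 1s
.gappedRows <- function(z) {
  first <- max.col(z == 1L, ties.method = "first")
  last <- max.col(z == 1L, ties.method = "last")
  which(rowSums(z) < last - first + 1L)
}

#' Enforce or repair non-contiguous individual occupancy
#'
#' An individual recorded alive, then missed at one census, then recorded
#' alive again has a gap (a 1...0...1 pattern) in its occupancy vector. Gaps
#' corrupt the interval mortality/recruitment flows that the null model
#' preserves, so they must be resolved before [intervalFlows()] or
#' [pSesAll()] can run.
#'
#' @param x a [Census-class] object.
#' @param policy one of:
#'   * `"strict"` (default): error if any individual has a gap, naming the
#'     offending ids;
#'   * `"fill"`: set internal zeros between the first and last presence to 1
#'     (the individual is assumed alive but missed); a message reports how
#'     many cells were filled;
#'   * `"events"`: leave occupancy unchanged. Dissimilarity indices remain
#'     computable, but the census is rejected by the null model.
#'
#' @return A [Census-class] object whose gap policy has been applied. The
#'   applied policy is recorded so downstream flow computations can refuse
#'   `"events"` censuses.
#'
#' @examples
#' z <- rbind(i1 = c(1, 0, 1), i2 = c(1, 1, 0))
#' cen <- census(z, species = c("sp1", "sp2"))
#' filled <- applyGapPolicy(cen, "fill")
#' occupancy(filled)["i1", ]
#' @export
applyGapPolicy <- function(x, policy = c("strict", "fill", "events")) {
  policy <- match.arg(policy)
  stopifnot(is(x, "Census"))
  z <- x@occupancy
  if (nrow(z) == 0L) return(x)
  gapped <- .gappedRows(z)
  if (policy == "strict" && length(gapped))
    stop("non-contiguous occupancy (1...0...1) for individual(s): ",
         paste(rownames(z)[gapped], collapse = ", "),
         ". Use policy = \"fill\" to treat internal gaps as census misses.")
  if (policy == "fill" && length(gapped)) {
    filled <- 0L
    for (i in gapped) {
      r <- z[i, ]
      span <- seq(which.max(r == 1L), max(which(r == 1L)))
      filled <- filled + sum(r[span] == 0L)
      z[i, span] <- 1L
    }
    message("filled ", filled, " internal gap cell(s) in ", length(gapped),
            " individual(s)")
    x@occupancy <- z
  }
  x
}

# TRUE if no individual has an internal gap
.isContiguous <- function(x) length(.gappedRows(x@occupancy)) == 0L
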