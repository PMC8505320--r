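#' Derive the species-by-unit abundance matrix from a Census
#'
#' Counts, for every species and census unit, the number of individuals of
#' that species alive at that unit. Species appear in order of first
#' appearance among the individuals. The pooled number of distinct
#' individuals is carried along, since it cannot be recovered from the
#' counts (one individual contributes to every unit it is alive in).
#'
#' @param x a [Census-class] object.
#' @param ... unused.
#'
#' @return An [AbundanceMatrix-class] object.
#'
#' @examples
#' z <- rbind(i1 = c(1, 1), i2 = c(1, 0), i3 = c(1, 0),
#'            i4 = c(0, 1), i5 = c(0, 1))
#' cen <- census(z, species = c("sp1", "sp1", "sp2", "sp1", "sp3"))
#' counts(abundanceMatrix(cen))
#' @rdname abundanceMatrix
#' @export
setMethod("abundanceMatrix", "Census", function(x, ...) {
  z <- x@occupancy
  spp <- unique(x@species)
  counts <- matrix(0L, nrow = length(spp), ncol = ncol(z),
                   dimnames = list(spp, colnames(z)))
  if (nrow(z) > 0L) {
    agg <- rowsum(z, group = x@species, reorder = FALSE)
    counts[rownames(agg), ] <- agg
    storage.mode(counts) <- "integer"
  }
  new("AbundanceMatrix", counts = counts, nIndividuals = nrow(z))
})

#' Totals of an AbundanceMatrix
#'
#' @param x an [AbundanceMatrix-class] object.
#'
#' @return `counts()` the species x units integer matrix; `speciesRichness()`
#'   the per-unit number of species present (S_j); `pooledRichness()` the
#'   number of species over all units (S_T); `unitAbundance()` the
#'   per-unit number of individuals (I_j, the column sums);
#'   `totalAbundance()` the grand total of the counts (T_AB = sum of I_j);
#'   `nIndividuals()` the pooled number of distinct individuals (I_T).
#'
#' @name abundance-accessors
NULL

#' @rdname abundance-accessors
#' @export
counts <- function(x) {
  stopifnot(is(x, "AbundanceMatrix"))
  x@counts
}

#' @rdname abundance-accessors
#' @export
speciesRichness <- function(x) {
  stopifnot(is(x, "AbundanceMatrix"))
  colSums(x@counts > 0L)
}

#' @rdname abundance-accessors
#' @export
pooledRichness <- function(x) {
  stopifnot(is(x, "AbundanceMatrix"))
  sum(rowSums(x@counts) > 0L)
}

#' @rdname abundance-accessors
#' @export
unitAbundance <- function(x) {
  stopifnot(is(x, "AbundanceMatrix"))
  colSums(x@counts)
}

#' @rdname abundance-accessors
#' @export
totalAbundance <- function(x) {
  stopifnot(is(x, "AbundanceMatrix"))
  sum(x@counts)
}

#' @rdname census-accessors
#' @export
setMethod("nIndividuals", "AbundanceMatrix", function(x) x@nIndividuals)

#' @rdname census-accessors
#' @export
setMethod("censusUnits", "AbundanceMatrix", function(x) colnames(x@counts))

#' @rdname census-accessors
#' @export
setMethod("nUnits", "AbundanceMatrix", function(x) ncol(x@counts))

setMethod("show", "AbundanceMatrix", function(object) {
  cat("AbundanceMatrix:", nrow(object@counts), "species x",
      ncol(object@counts), "units;",
      object@nIndividuals, "distinct individuals, total abundance",
      sum(object@counts), "\n")
})
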