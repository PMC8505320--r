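# ratio that propagates a tagged undefined value instead of NaN on 0/0
.ratio <- function(num, den, reason) {
  if (den == 0) structure(NA_real_, reason = reason) else num / den
}

#' Reason an index value is undefined
#'
#' Indices with a zero denominator (e.g. `v_s` when no individual died or
#' was recruited) are returned as `NA` carrying a `reason` attribute rather
#' than raising an error, so batch runs over many plots stay honest about
#' which entries exist.
#'
#' @param x a value returned by one of the index functions.
#' @return The reason string, or `NA` if the value is defined.
#' @export
indexReason <- function(x) {
  r <- attr(x, "reason")
  if (is.null(r)) NA_character_ else r
}

#' Exact components for one pair of censuses
#'
#' Computes, for the ordered unit pair (j, k), the species components
#' (a, b, c), the abundance components (A, B, C), and the individual
#' components: persistence P (alive at both), mortality M (alive at j only),
#' recruitment R (alive at k only), together with the conspecific-replacement
#' split E_loss = M - B and E_gain = R - C. All are exact integers.
#'
#' @param x a [Census-class] object.
#' @param j,k unit labels (j must precede k in the census order for the
#'   mortality/recruitment reading to hold; any two distinct units are
#'   accepted and M/R swap under exchange of j and k).
#' @param ... unused.
#'
#' @return A [PairwiseComponents-class] object.
#'
#' @examples
#' z <- rbind(i1 = c(1, 1), i2 = c(1, 0), i3 = c(1, 0),
#'            i4 = c(0, 1), i5 = c(0, 1))
#' cen <- census(z, species = c("sp1", "sp1", "sp2", "sp1", "sp3"))
#' pairwiseComponents(cen, 1, 2)
#' @rdname pairwiseComponents
#' @export
setMethod("pairwiseComponents", "Census", function(x, j, k, ...) {
  ji <- .unitIndex(x, j); ki <- .unitIndex(x, k)
  if (ji == ki) stop("j and k must be distinct units")
  ab <- abundanceMatrix(x)
  sc <- .speciesComponents(ab@counts, ji, ki)
  acp <- .abundanceComponents(ab@counts, ji, ki)
  ic <- .individualComponents(x@occupancy, ji, ki)
  # Class= spelled out: a slot named `c` would otherwise partially match it
  new(Class = "PairwiseComponents",
      unitJ = colnames(x@occupancy)[ji], unitK = colnames(x@occupancy)[ki],
      a = sc[["a"]], b = sc[["b"]], c = sc[["c"]],
      A = acp[["A"]], B = acp[["B"]], C = acp[["C"]],
      P = ic[["P"]], M = ic[["M"]], R = ic[["R"]],
      Eloss = ic[["M"]] - acp[["B"]], Egain = ic[["R"]] - acp[["C"]])
})

.speciesComponents <- function(counts, ji, ki) {
  pj <- counts[, ji] > 0L; pk <- counts[, ki] > 0L
  c(a = sum(pj & pk), b = sum(pj & !pk), c = sum(!pj & pk))
}

.abundanceComponents <- function(counts, ji, ki) {
  m <- pmin(counts[, ji], counts[, ki])
  c(A = sum(m), B = sum(counts[, ji]) - sum(m), C = sum(counts[, ki]) - sum(m))
}

.individualComponents <- function(z, ji, ki) {
  P <- sum(z[, ji] == 1L & z[, ki] == 1L)
  c(P = P, M = sum(z[, ji]) - P, R = sum(z[, ki]) - P)
}

#' Species components of a census pair
#'
#' Lower-level entry points on an [AbundanceMatrix-class]:
#' `speciesComponents()` returns the shared/unique species counts (a, b, c)
#' and `abundanceComponents()` the abundance components (A, B, C), where A is
#' the per-species minimum summed over species and B, C the one-sided
#' excesses.
#'
#' @param x an [AbundanceMatrix-class] object.
#' @param j,k unit labels.
#' @return Named integer vector.
#' @export
speciesComponents <- function(x, j, k) {
  stopifnot(is(x, "AbundanceMatrix"))
  ji <- .amUnitIndex(x, j); ki <- .amUnitIndex(x, k)
  .speciesComponents(x@counts, ji, ki)
}

#' @rdname speciesComponents
#' @export
abundanceComponents <- function(x, j, k) {
  stopifnot(is(x, "AbundanceMatrix"))
  ji <- .amUnitIndex(x, j); ki <- .amUnitIndex(x, k)
  .abundanceComponents(x@counts, ji, ki)
}

.amUnitIndex <- function(am, u) {
  i <- match(as.character(u), colnames(am@counts))
  if (anyNA(i)) stop("unknown unit label: ", u)
  i
}

#' Individual components of a census pair
#'
#' Persistence, mortality and recruitment counts for the pair (j, k):
#' P = individuals alive at both censuses, M = alive at j but not k,
#' R = alive at k but not j.
#'
#' @param x a [Census-class] object.
#' @param j,k unit labels.
#' @return Named integer vector with entries P, M, R.
#' @export
individualComponents <- function(x, j, k) {
  stopifnot(is(x, "Census"))
  .individualComponents(x@occupancy, .unitIndex(x, j), .unitIndex(x, k))
}

setMethod("show", "PairwiseComponents", function(object) {
  cat("PairwiseComponents for units (", object@unitJ, ", ", object@unitK,
      ")\n", sep = "")
  cat("  species    a =", object@a, " b =", object@b, " c =", object@c, "\n")
  cat("  abundance  A =", object@A, " B =", object@B, " C =", object@C, "\n")
  cat("  individual P =", object@P, " M =", object@M, " R =", object@R,
      " E =", object@Eloss, "\n")
  cat("  d_sor =", format(dSor(object)), " d_BC =", format(dBC(object)),
      " d_MR =", format(dMR(object)), " v_s =", format(vS(object)), "\n")
})

#' Pairwise dissimilarity indices
#'
#' The four pairwise indices, each a ratio of exact integer components:
#' * `dSor(a, b, c) = (b + c) / (2a + b + c)` - Sorensen dissimilarity on
#'   species presences;
#' * `dBC(A, B, C) = (B + C) / (2A + B + C)` - Bray-Curtis (percentage
#'   difference) dissimilarity on abundances;
#' * `dMR(P, M, R) = (M + R) / (2P + M + R)` - the individual-based
#'   analogue: the rate of individual turnover;
#' * `vS = (B + C) / (M + R) = dBC / dMR` - the fraction of individual
#'   turnover that shifts composition (0 = pure conspecific replacement,
#'   1 = every death/recruitment changes composition).
#'
#' Each generic accepts either a [PairwiseComponents-class] object, a
#' [Census-class] with unit labels `j` and `k`, or the three raw integer
#' components. A zero denominator yields a tagged `NA` (see
#' [indexReason()]): both units empty for `dSor`/`dBC`/`dMR`, no individual
#' turnover for `vS`.
#'
#' @param x a [PairwiseComponents-class], a [Census-class], or the first
#'   component (a, A or P).
#' @param ... for the Census methods, unit labels `j` and `k`; for the
#'   numeric methods, the remaining two components.
#'
#' @return A numeric value in `[0, 1]`, or tagged `NA` when undefined.
#'
#' @examples
#' dBC(2, 1, 1)            # 1/3
#' dMR(1, 2, 2)            # 2/3
#' vS(dBC = 1/3, dMR = 2/3)
#' @name pairwise-indices
NULL

#' @rdname pairwise-indices
#' @export
setMethod("dSor", "numeric", function(x, b, c, ...)
  .ratio(b + c, 2 * x + b + c, "both units empty"))

#' @rdname pairwise-indices
#' @export
setMethod("dSor", "PairwiseComponents", function(x, ...)
  .ratio(x@b + x@c, 2 * x@a + x@b + x@c, "both units empty"))

#' @rdname pairwise-indices
#' @export
setMethod("dBC", "numeric", function(x, B, C, ...)
  .ratio(B + C, 2 * x + B + C, "both units empty"))

#' @rdname pairwise-indices
#' @export
setMethod("dBC", "PairwiseComponents", function(x, ...)
  .ratio(x@B + x@C, 2 * x@A + x@B + x@C, "both units empty"))

#' @rdname pairwise-indices
#' @export
setMethod("dMR", "numeric", function(x, M, R, ...)
  .ratio(M + R, 2 * x + M + R, "both units empty"))

#' @rdname pairwise-indices
#' @export
setMethod("dMR", "PairwiseComponents", function(x, ...)
  .ratio(x@M + x@R, 2 * x@P + x@M + x@R, "both units empty"))

#' @rdname pairwise-indices
#' @export
setMethod("vS", "PairwiseComponents", function(x, ...)
  .ratio(x@B + x@C, x@M + x@R, "no individual turnover"))

#' @rdname pairwise-indices
#' @export
setMethod("vS", "missing", function(x, dBC, dMR, ...) {
  if (is.na(dMR) || dMR == 0) return(structure(NA_real_, reason = "no individual turnover"))
  dBC / dMR
})

#' @rdname pairwise-indices
#' @export
setMethod("dSor", "Census", function(x, j, k, ...) dSor(pairwiseComponents(x, j, k)))

#' @rdname pairwise-indices
#' @export
setMethod("dBC", "Census", function(x, j, k, ...) dBC(pairwiseComponents(x, j, k)))

#' @rdname pairwise-indices
#' @export
setMethod("dMR", "Census", function(x, j, k, ...) dMR(pairwiseComponents(x, j, k)))

#' @rdname pairwise-indices
#' @export
setMethod("vS", "Census", function(x, j, k, ...) vS(pairwiseComponents(x, j, k)))

#' All pairwise index values of a census series
#'
#' Computes one of the pairwise indices for every ordered pair of units
#' j < k (by the declared unit order), together with the mean over the
#' defined pairs. This is the quantity the multiple-unit indices are
#' typically contrasted with: the mean of the pairwise values understates
#' overall temporal variability when individuals or species are shared
#' among three or more censuses.
#'
#' @param x a [Census-class] object.
#' @param which one of `"d_mr"`, `"d_bc"`, `"d_sor"`, `"v_s"`.
#'
#' @return A `data.frame` with columns `unit_j`, `unit_k`, `value`,
#'   `defined` (logical) and `reason` (NA where defined), one row per pair,
#'   with attributes `mean` (mean over defined pairs; `NaN` if none) and
#'   `nUndefined` (number of undefined pairs).
#'
#' @examples
#' z <- rbind(z1 = c(1, 1, 1, 1), z2 = c(0, 1, 0, 0))
#' cen <- census(z, species = "sp1")
#' ap <- allPairs(cen, "d_mr")
#' ap
#' attr(ap, "mean")   # 1/6
#' @export
allPairs <- function(x, which = c("d_mr", "d_bc", "d_sor", "v_s")) {
  which <- match.arg(which)
  stopifnot(is(x, "Census"))
  units <- colnames(x@occupancy)
  T <- length(units)
  pairs <- which(upper.tri(matrix(0, T, T)), arr.ind = TRUE)
  pairs <- pairs[order(pairs[, "row"], pairs[, "col"]), , drop = FALSE]
  vals <- numeric(nrow(pairs)); reasons <- rep(NA_character_, nrow(pairs))
  ab <- abundanceMatrix(x)
  for (r in seq_len(nrow(pairs))) {
    ji <- pairs[r, "row"]; ki <- pairs[r, "col"]
    v <- switch(which,
      d_sor = { s <- .speciesComponents(ab@counts, ji, ki)
                dSor(s[["a"]], s[["b"]], s[["c"]]) },
      d_bc  = { s <- .abundanceComponents(ab@counts, ji, ki)
                dBC(s[["A"]], s[["B"]], s[["C"]]) },
      d_mr  = { s <- .individualComponents(x@occupancy, ji, ki)
                dMR(s[["P"]], s[["M"]], s[["R"]]) },
      v_s   = { a <- .abundanceComponents(ab@counts, ji, ki)
                i <- .individualComponents(x@occupancy, ji, ki)
                .ratio(a[["B"]] + a[["C"]], i[["M"]] + i[["R"]],
                       "no individual turnover") })
    vals[r] <- v
    reasons[r] <- indexReason(v)
  }
  out <- data.frame(unit_j = units[pairs[, "row"]],
                    unit_k = units[pairs[, "col"]],
                    value = vals,
                    defined = is.na(reasons),
                    reason = reasons,
                    stringsAsFactors = FALSE)
  attr(out, "mean") <- mean(vals[is.na(reasons)])
  attr(out, "nUndefined") <- sum(!is.na(reasons))
  out
}

#' @rdname allPairs
#' @export
meanPairwise <- function(x, which = c("d_mr", "d_bc", "d_sor", "v_s")) {
  attr(allPairs(x, which), "mean")
}
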