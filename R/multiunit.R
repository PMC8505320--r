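# one-sided exclusives from a 0/1 incidence matrix (rows x units):
# out[j, k] = number of rows present at j and absent at k
.exclusives <- function(inc) {
  shared <- crossprod(inc)           # units x units co-presence
  pres <- colSums(inc)
  out <- matrix(pres, nrow = length(pres), ncol = length(pres)) - shared
  storage.mode(out) <- "integer"
  dimnames(out) <- list(colnames(inc), colnames(inc))
  out
}

# sum of min (and max) of x[j,k], x[k,j] over pairs j < k
.pairMinMax <- function(m) {
  ut <- upper.tri(m)
  lo <- pmin(m[ut], t(m)[ut]); hi <- pmax(m[ut], t(m)[ut])
  c(lo = sum(lo), hi = sum(hi))
}

#' Species-scale multiple-unit components
#'
#' Closed forms for the multiple-unit (inclusion-exclusion) components on
#' the species scale: `a_mu` = sum of per-unit richness minus pooled
#' richness, and `b_mu`/`c_mu` = sums over unit pairs of the smaller/larger
#' one-sided exclusive species counts p_jk.
#'
#' @param x an [AbundanceMatrix-class] object.
#' @return Named integer vector `(a_mu, b_mu, c_mu)`.
#' @seealso [multiUnitComponents()] for all scales at once,
#'   [bruteForceShared()] for the direct inclusion-exclusion audit.
#' @export
incidenceComponents <- function(x) {
  stopifnot(is(x, "AbundanceMatrix"))
  inc <- (x@counts > 0L) * 1L
  p <- .exclusives(inc)
  mm <- .pairMinMax(p)
  c(a_mu = as.integer(sum(colSums(inc)) - sum(rowSums(inc) > 0L)),
    b_mu = as.integer(mm[["lo"]]), c_mu = as.integer(mm[["hi"]]))
}

#' Abundance-scale multiple-unit components
#'
#' `A_mu` = grand total abundance minus the sum over species of the maximum
#' abundance across units; `B_mu`/`C_mu` = sums over unit pairs of the
#' smaller/larger one-sided pairwise abundance excesses.
#'
#' @param x an [AbundanceMatrix-class] object.
#' @return Named integer vector `(A_mu, B_mu, C_mu)`.
#' @export
abundanceMuComponents <- function(x) {
  stopifnot(is(x, "AbundanceMatrix"))
  cnt <- x@counts
  T <- ncol(cnt)
  B <- matrix(0L, T, T)
  for (j in seq_len(T - 1L)) for (k in (j + 1L):T) {
    m <- sum(pmin(cnt[, j], cnt[, k]))
    B[j, k] <- sum(cnt[, j]) - m   # excess of unit j over the pair minimum
    B[k, j] <- sum(cnt[, k]) - m
  }
  mm <- .pairMinMax(B)
  c(A_mu = as.integer(sum(cnt) - sum(apply(cnt, 1L, max))),
    B_mu = as.integer(mm[["lo"]]), C_mu = as.integer(mm[["hi"]]))
}

#' Individual-scale multiple-unit components
#'
#' `P_mu` = sum of per-unit alive counts minus the pooled number of distinct
#' individuals (the inclusion-exclusion persistence component);
#' `M_mu`/`R_mu` = sums over unit pairs of the smaller/larger one-sided
#' exclusive individual counts q_jk.
#'
#' @param x a [Census-class] object.
#' @return Named integer vector `(P_mu, M_mu, R_mu)`.
#' @export
individualMuComponents <- function(x) {
  stopifnot(is(x, "Census"))
  q <- .exclusives(x@occupancy)
  mm <- .pairMinMax(q)
  c(P_mu = as.integer(sum(colSums(x@occupancy)) - nrow(x@occupancy)),
    M_mu = as.integer(mm[["lo"]]), R_mu = as.integer(mm[["hi"]]))
}

#' All multiple-unit components of a census series
#'
#' Computes the nine multiple-unit components (species, abundance and
#' individual scales) in one pass, retaining the one-sided exclusive
#' matrices p_jk (species) and q_jk (individuals) as intermediates.
#'
#' @param x a [Census-class] object.
#' @param ... unused.
#'
#' @return A [MultiUnitComponents-class] object.
#'
#' @examples
#' z <- rbind(z1 = c(1, 1, 1, 1), z2 = c(0, 1, 0, 0))
#' cen <- census(z, species = "sp1")
#' mu <- multiUnitComponents(cen)
#' mu
#' dMRMu(mu)   # 1/3
#' @rdname multiUnitComponents
#' @export
setMethod("multiUnitComponents", "Census", function(x, ...) {
  ab <- abundanceMatrix(x)
  sp <- incidenceComponents(ab)
  au <- abundanceMuComponents(ab)
  iu <- individualMuComponents(x)
  new("MultiUnitComponents",
      aMu = as.integer(sp[["a_mu"]]), bMu = as.integer(sp[["b_mu"]]),
      cMu = as.integer(sp[["c_mu"]]),
      AMu = as.integer(au[["A_mu"]]), BMu = as.integer(au[["B_mu"]]),
      CMu = as.integer(au[["C_mu"]]),
      PMu = as.integer(iu[["P_mu"]]), MMu = as.integer(iu[["M_mu"]]),
      RMu = as.integer(iu[["R_mu"]]),
      p = .exclusives((ab@counts > 0L) * 1L),
      q = .exclusives(x@occupancy))
})

setMethod("show", "MultiUnitComponents", function(object) {
  cat("MultiUnitComponents over", ncol(object@q), "units\n")
  cat("  species    a_mu =", object@aMu, " b_mu =", object@bMu,
      " c_mu =", object@cMu, "\n")
  cat("  abundance  A_mu =", object@AMu, " B_mu =", object@BMu,
      " C_mu =", object@CMu, "\n")
  cat("  individual P_mu =", object@PMu, " M_mu =", object@MMu,
      " R_mu =", object@RMu, "\n")
  cat("  d_sor.mu =", format(dSorMu(object)),
      " d_BC.mu =", format(dBCMu(object)),
      " d_MR.mu =", format(dMRMu(object)),
      " v_s.mu =", format(vSMu(object)), "\n")
})

#' Multiple-unit dissimilarity indices
#'
#' The multiple-unit extensions of the pairwise indices, each
#' `(loss + gain) / (2 shared + loss + gain)` on its own scale:
#' `dSorMu` on species components, `dBCMu` on abundance components, and
#' `dMRMu` on individual components (the individual-based multiple-unit
#' index). `vSMu = dBCMu / dMRMu` is the compositional variability relative
#' to the individual turnover. Because the shared components are computed by
#' inclusion-exclusion, these indices account for species/individuals shared
#' among three or more censuses, which the mean of pairwise values cannot.
#'
#' Each accepts a [MultiUnitComponents-class] object or a [Census-class]
#' (computed on the fly). Zero denominators give a tagged `NA`
#' (see [indexReason()]).
#'
#' @param x a [MultiUnitComponents-class] or [Census-class] object.
#' @param ... unused.
#'
#' @return Numeric value in `[0, 1]`, or tagged `NA` when undefined.
#'
#' @examples
#' z <- rbind(z1 = c(1, 1, 0, 0), z2 = c(0, 1, 1, 1))
#' dMRMu(census(z, species = "sp1"))   # 7/13
#' @name multiunit-indices
NULL

#' @rdname multiunit-indices
#' @export
setMethod("dSorMu", "MultiUnitComponents", function(x, ...)
  .ratio(x@bMu + x@cMu, 2 * x@aMu + x@bMu + x@cMu, "all units empty"))

#' @rdname multiunit-indices
#' @export
setMethod("dBCMu", "MultiUnitComponents", function(x, ...)
  .ratio(x@BMu + x@CMu, 2 * x@AMu + x@BMu + x@CMu, "all units empty"))

#' @rdname multiunit-indices
#' @export
setMethod("dMRMu", "MultiUnitComponents", function(x, ...)
  .ratio(x@MMu + x@RMu, 2 * x@PMu + x@MMu + x@RMu, "all units empty"))

#' @rdname multiunit-indices
#' @export
setMethod("vSMu", "MultiUnitComponents", function(x, ...) {
  num <- dBCMu(x); den <- dMRMu(x)
  if (is.na(den) || den == 0)
    return(structure(NA_real_, reason = "no individual turnover"))
  num / den
})

#' @rdname multiunit-indices
#' @export
setMethod("dSorMu", "Census", function(x, ...) dSorMu(multiUnitComponents(x)))

#' @rdname multiunit-indices
#' @export
setMethod("dBCMu", "Census", function(x, ...) dBCMu(multiUnitComponents(x)))

#' @rdname multiunit-indices
#' @export
setMethod("dMRMu", "Census", function(x, ...) {
  # fast path: only the individual scale is needed
  iu <- individualMuComponents(x)
  .ratio(iu[["M_mu"]] + iu[["R_mu"]],
         2 * iu[["P_mu"]] + iu[["M_mu"]] + iu[["R_mu"]], "all units empty")
})

#' @rdname multiunit-indices
#' @export
setMethod("vSMu", "Census", function(x, ...) vSMu(multiUnitComponents(x)))
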