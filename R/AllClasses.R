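#' @import methods
NULL

#' Census: individual-tracked multi-census occupancy data
#'
#' A `Census` holds one plot's individual-tracked census series: a 0/1
#' occupancy matrix with one row per marked individual and one ordered column
#' per census (time unit), plus a species label per individual. An entry of 1
#' means the individual was alive (counted) at that census. All
#' individual-based dissimilarity indices in this package are computed from
#' this object.
#'
#' @slot occupancy integer matrix, individuals x units, entries 0/1; rownames
#'   are unique individual ids, colnames are the ordered census labels.
#' @slot species character vector, one species id per individual (aligned
#'   with the rows of `occupancy`).
#'
#' @seealso [census()], [readLongFormat()], [applyGapPolicy()],
#'   [abundanceMatrix()], [multiUnitComponents()]
#' @export
setClass("Census",
  slots = c(occupancy = "matrix", species = "character"))

setValidity("Census", function(object) {
  z <- object@occupancy
  msgs <- character()
  if (ncol(z) < 2L)
    msgs <- c(msgs, "a Census needs at least 2 time units")
  if (is.null(colnames(z)) || anyDuplicated(colnames(z)) || any(is.na(colnames(z))))
    msgs <- c(msgs, "unit labels (colnames) must be present and unique")
  if (nrow(z) > 0L) {
    if (is.null(rownames(z)) || anyDuplicated(rownames(z)))
      msgs <- c(msgs, "individual ids (rownames) must be present and unique")
    if (!all(z %in% c(0L, 1L)))
      msgs <- c(msgs, "occupancy entries must be 0 or 1")
    else if (any(rowSums(z) == 0L))
      msgs <- c(msgs, "every individual must be present in at least one unit")
  }
  if (length(object@species) != nrow(z))
    msgs <- c(msgs, "species must have one entry per individual")
  if (anyNA(object@species))
    msgs <- c(msgs, "species labels must not be NA")
  if (length(msgs)) msgs else TRUE
})

#' AbundanceMatrix: species-by-unit counts derived from a Census
#'
#' Species x census abundance counts `x[i, j]` = number of individuals of
#' species `i` alive at unit `j`, together with the pooled number of distinct
#' individuals (which is not derivable from the counts alone, since one
#' individual contributes to several columns).
#'
#' @slot counts integer matrix, species x units (rownames species ids,
#'   colnames unit labels).
#' @slot nIndividuals integer, number of distinct individuals pooled over all
#'   units (I_T).
#'
#' @seealso [abundanceMatrix()], [speciesRichness()], [unitAbundance()]
#' @export
setClass("AbundanceMatrix",
  slots = c(counts = "matrix", nIndividuals = "integer"))

setValidity("AbundanceMatrix", function(object) {
  x <- object@counts
  msgs <- character()
  if (is.null(colnames(x)) || anyDuplicated(colnames(x)))
    msgs <- c(msgs, "unit labels (colnames) must be present and unique")
  if (nrow(x) > 0L && (is.null(rownames(x)) || anyDuplicated(rownames(x))))
    msgs <- c(msgs, "species ids (rownames) must be present and unique")
  if (anyNA(x) || any(x < 0L) || any(x != as.integer(x)))
    msgs <- c(msgs, "counts must be non-negative integers")
  if (length(object@nIndividuals) != 1L || is.na(object@nIndividuals) ||
      object@nIndividuals < 0L)
    msgs <- c(msgs, "nIndividuals must be a single non-negative integer")
  if (length(msgs)) msgs else TRUE
})

#' PairwiseComponents: exact components for one census pair
#'
#' All similarity/dissimilarity components for a single ordered pair of
#' censuses (j before k), kept as exact integers: species-scale a/b/c,
#' abundance-scale A/B/C, individual-scale P/M/R (persistence, mortality,
#' recruitment), and the conspecific-replacement components E_loss = M - B
#' and E_gain = R - C (equal by construction).
#'
#' @slot unitJ,unitK the two census labels (j precedes k in the unit order).
#' @slot a,b,c species counts: shared, unique-to-j, unique-to-k.
#' @slot A,B,C abundance components: sum of per-species minima and the two
#'   one-sided excesses.
#' @slot P,M,R individual counts: persisting, dying (present at j only),
#'   recruited (present at k only).
#' @slot Eloss,Egain individuals replaced by conspecifics; always equal.
#'
#' @seealso [pairwiseComponents()], [dMR()], [vS()]
#' @export
setClass("PairwiseComponents",
  slots = c(unitJ = "character", unitK = "character",
            a = "integer", b = "integer", c = "integer",
            A = "integer", B = "integer", C = "integer",
            P = "integer", M = "integer", R = "integer",
            Eloss = "integer", Egain = "integer"))

setValidity("PairwiseComponents", function(object) {
  v <- c(a = object@a, b = object@b, c = object@c, A = object@A, B = object@B,
         C = object@C, P = object@P, M = object@M, R = object@R,
         Eloss = object@Eloss, Egain = object@Egain)
  msgs <- character()
  if (anyNA(v) || any(v < 0L))
    msgs <- c(msgs, "all components must be non-negative integers")
  else {
    if (object@Eloss != object@Egain)
      msgs <- c(msgs, "E_loss must equal E_gain")
    if (object@A != object@P + object@Eloss)
      msgs <- c(msgs, "A must equal P + E")
    if (object@B + object@C != object@M + object@R - 2L * object@Eloss)
      msgs <- c(msgs, "B + C must equal M + R - 2E")
  }
  if (length(msgs)) msgs else TRUE
})

#' MultiUnitComponents: multiple-unit components for a whole census series
#'
#' Exact-integer multiple-unit (inclusion-exclusion) components on the three
#' scales: species (a_mu/b_mu/c_mu), abundance (A_mu/B_mu/C_mu) and
#' individual (P_mu/M_mu/R_mu). The shared components use the closed forms
#' (sum of per-unit totals minus the pooled total; grand total minus the sum
#' of per-row maxima); the loss/gain components sum pairwise minima and
#' maxima of the one-sided exclusives p_jk (species) and q_jk (individuals),
#' which are stored as intermediates.
#'
#' @slot aMu,bMu,cMu species-scale components.
#' @slot AMu,BMu,CMu abundance-scale components.
#' @slot PMu,MMu,RMu individual-scale components.
#' @slot p,q integer matrices (units x units); `p[j, k]` = number of species
#'   present at j and absent at k; `q[j, k]` = same count over individuals.
#'
#' @seealso [multiUnitComponents()], [dMRMu()], [vSMu()], [bruteForceShared()]
#' @export
setClass("MultiUnitComponents",
  slots = c(aMu = "integer", bMu = "integer", cMu = "integer",
            AMu = "integer", BMu = "integer", CMu = "integer",
            PMu = "integer", MMu = "integer", RMu = "integer",
            p = "matrix", q = "matrix"))

setValidity("MultiUnitComponents", function(object) {
  v <- c(object@aMu, object@bMu, object@cMu, object@AMu, object@BMu,
         object@CMu, object@PMu, object@MMu, object@RMu)
  msgs <- character()
  if (anyNA(v) || any(v < 0L))
    msgs <- c(msgs, "all components must be non-negative integers")
  else {
    if (object@bMu > object@cMu || object@BMu > object@CMu ||
        object@MMu > object@RMu)
      msgs <- c(msgs, "min/max construction requires b_mu <= c_mu, B_mu <= C_mu, M_mu <= R_mu")
    if (object@AMu < object@PMu)
      msgs <- c(msgs, "A_mu must be >= P_mu")
  }
  if (length(msgs)) msgs else TRUE
})

#' IntervalFlows: per-interval mortality and recruitment counts
#'
#' The demographic flows a census series implies: the number of individuals
#' alive at each unit (I_t), and for each interval (t, t+1) the number that
#' died (D_t) and the number recruited (R_t). These are the quantities the
#' randomization null model preserves.
#'
#' @slot units the ordered census labels.
#' @slot alive integer vector, individuals alive per unit.
#' @slot deaths,recruits integer vectors of length `length(units) - 1`.
#'
#' @seealso [intervalFlows()], [randomizeOnce()], [pSesAll()]
#' @export
setClass("IntervalFlows",
  slots = c(units = "character", alive = "integer",
            deaths = "integer", recruits = "integer"))

setValidity("IntervalFlows", function(object) {
  T <- length(object@units)
  msgs <- character()
  if (T < 2L) msgs <- c(msgs, "need at least 2 units")
  if (length(object@alive) != T)
    msgs <- c(msgs, "alive must have one entry per unit")
  if (length(object@deaths) != T - 1L || length(object@recruits) != T - 1L)
    msgs <- c(msgs, "deaths and recruits must have one entry per interval")
  v <- c(object@alive, object@deaths, object@recruits)
  if (anyNA(v) || any(v < 0L))
    msgs <- c(msgs, "all flow counts must be non-negative integers")
  else if (length(object@alive) == T && length(object@deaths) == T - 1L) {
    if (any(object@deaths > object@alive[-T]))
      msgs <- c(msgs, "deaths cannot exceed the individuals alive")
    if (any(object@alive[-1L] !=
            object@alive[-T] - object@deaths + object@recruits))
      msgs <- c(msgs, "conservation violated: I_{t+1} != I_t - D_t + R_t")
  }
  if (length(msgs)) msgs else TRUE
})

#' SESResult: standardized effect size of individual persistence
#'
#' Result of the persistence null model: the observed multiple-unit
#' individual-based dissimilarity, the null distribution obtained by
#' randomizing which individuals die (holding per-interval death and
#' recruitment counts fixed), its mean and sample standard deviation, and the
#' standardized effect size.
#'
#' @slot observed observed index value for the input census.
#' @slot replicates index values of the null replicates.
#' @slot nullMean,nullSd mean and sample standard deviation (n - 1
#'   denominator) of the replicates.
#' @slot ses standardized effect size; `NA` when the null distribution is
#'   degenerate (`reason` then says why).
#' @slot reason explanation when `ses` is undefined, otherwise `NA`.
#' @slot nRand number of null replicates.
#' @slot seed seed used for the replicate stream (`NA` if none supplied).
#' @slot signConvention `"as_stated"` for (observed - null mean)/null sd,
#'   `"reversed"` for its negative.
#'
#' @seealso [pSesAll()]
#' @export
setClass("SESResult",
  slots = c(observed = "numeric", replicates = "numeric",
            nullMean = "numeric", nullSd = "numeric", ses = "numeric",
            reason = "character", nRand = "integer", seed = "integer",
            signConvention = "character"))

setValidity("SESResult", function(object) {
  msgs <- character()
  if (length(object@replicates) != object@nRand)
    msgs <- c(msgs, "replicates must have length nRand")
  if (!object@signConvention %in% c("as_stated", "reversed"))
    msgs <- c(msgs, "signConvention must be 'as_stated' or 'reversed'")
  if (length(msgs)) msgs else TRUE
})
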