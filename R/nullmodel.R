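#' Per-interval mortality and recruitment flows of a census series
#'
#' Derives the demographic flows between consecutive censuses: the number
#' of individuals alive at each unit, and for each interval the number that
#' died (present at t, absent at t+1) and the number recruited (absent at
#' t, present at t+1). These flows are exactly what the persistence null
#' model holds fixed.
#'
#' Occupancy must be contiguous (no individual recorded, missed, then
#' recorded again); apply [applyGapPolicy()] with `"fill"` first if needed.
#' With gaps, an apparent death followed by a reappearance would inflate
#' both flows and make simulated censuses disagree with the observed number
#' of distinct individuals.
#'
#' @param x a [Census-class] object with contiguous occupancy.
#' @param ... unused.
#'
#' @return An [IntervalFlows-class] object.
#'
#' @examples
#' z <- rbind(z1 = c(1, 1, 1, 1), z2 = c(0, 1, 0, 0))
#' intervalFlows(census(z, species = "sp1"))
#' @rdname intervalFlows
#' @export
setMethod("intervalFlows", "Census", function(x, ...) {
  if (!.isContiguous(x))
    stop("census has non-contiguous occupancy; apply ",
         "applyGapPolicy(x, \"fill\") before deriving interval flows")
  z <- x@occupancy
  T <- ncol(z)
  alive <- as.integer(colSums(z))
  deaths <- recruits <- integer(T - 1L)
  for (t in seq_len(T - 1L)) {
    deaths[t] <- sum(z[, t] == 1L & z[, t + 1L] == 0L)
    recruits[t] <- sum(z[, t] == 0L & z[, t + 1L] == 1L)
  }
  new("IntervalFlows", units = colnames(z), alive = alive,
      deaths = deaths, recruits = recruits)
})

setMethod("show", "IntervalFlows", function(object) {
  cat("IntervalFlows over", length(object@units), "units\n")
  cat("  alive:   ", paste(object@alive, collapse = ", "), "\n")
  cat("  deaths:  ", paste(object@deaths, collapse = ", "), "\n")
  cat("  recruits:", paste(object@recruits, collapse = ", "), "\n")
})

# simulate one set of contiguous lifespans consistent with the flows:
# returns list(birth, last), unit indices of first and last presence
.randomLifespans <- function(flows) {
  T <- length(flows@units)
  n0 <- flows@alive[1L]
  nTotal <- n0 + sum(flows@recruits)
  birth <- integer(nTotal); last <- integer(nTotal)
  birth[seq_len(n0)] <- 1L; last[] <- T
  alive <- seq_len(n0)
  nxt <- n0 + 1L
  for (t in seq_len(T - 1L)) {
    d <- flows@deaths[t]
    if (d > 0L) {
      pick <- sample.int(length(alive), d)
      last[alive[pick]] <- t
      alive <- alive[-pick]
    }
    r <- flows@recruits[t]
    if (r > 0L) {
      ids <- seq.int(nxt, nxt + r - 1L)
      birth[ids] <- t + 1L
      alive <- c(alive, ids)
      nxt <- nxt + r
    }
  }
  list(birth = birth, last = last)
}

# individual-scale multiple-unit components straight from lifespans
.muFromLifespans <- function(birth, last, T) {
  Z <- outer(birth, seq_len(T), "<=") & outer(last, seq_len(T), ">=")
  storage.mode(Z) <- "integer"
  shared <- crossprod(Z)
  cs <- colSums(Z)
  q <- matrix(cs, T, T) - shared
  ut <- upper.tri(q)
  c(P_mu = sum(cs) - length(birth),
    M_mu = sum(pmin(q[ut], t(q)[ut])),
    R_mu = sum(pmax(q[ut], t(q)[ut])))
}

#' Draw one census from the persistence null model
#'
#' Simulates a census series with exactly the given per-interval death and
#' recruitment counts, but with the dying individuals chosen uniformly at
#' random (without replacement) among those currently alive at each
#' interval. Recruits always receive new identities and are themselves at
#' risk in later intervals. The result is species-free (all individuals
#' carry the placeholder label `"unassigned"`): the individual-based index
#' does not use species identity.
#'
#' @param flows an [IntervalFlows-class] object, or a [Census-class] from
#'   which flows are derived.
#' @param seed optional integer seed for reproducibility.
#'
#' @return A [Census-class] object whose per-unit alive counts equal the
#'   input flows' counts exactly.
#'
#' @examples
#' z <- rbind(z1 = c(1, 1, 1, 1), z2 = c(0, 1, 0, 0))
#' fl <- intervalFlows(census(z, species = "sp1"))
#' occupancy(randomizeOnce(fl, seed = 1))
#' @export
randomizeOnce <- function(flows, seed = NULL) {
  if (is(flows, "Census")) flows <- intervalFlows(flows)
  stopifnot(is(flows, "IntervalFlows"))
  if (!is.null(seed)) set.seed(seed)
  T <- length(flows@units)
  ls <- .randomLifespans(flows)
  Z <- outer(ls$birth, seq_len(T), "<=") & outer(ls$last, seq_len(T), ">=")
  storage.mode(Z) <- "integer"
  rownames(Z) <- paste0("sim", seq_len(nrow(Z)))
  colnames(Z) <- flows@units
  census(Z, species = rep("unassigned", nrow(Z)))
}

#' Standardized effect size of individual persistence
#'
#' Compares the observed individual-based multiple-unit dissimilarity
#' ([dMRMu()]) of a census with its distribution under the persistence null
#' model: per-interval death and recruitment counts are held at their
#' observed values while the identity of the dying individuals is
#' randomized (ecological drift in who dies). The standardized effect size
#' is `(observed - null mean) / null sd` with the sample standard deviation
#' (n - 1 denominator) over `nRand` replicates.
#'
#' The persistence component P_mu is fully determined by the flows, so it is
#' identical in every replicate (verified internally); only the
#' cross-interval sharing components M_mu and R_mu vary. Values below 0 mean
#' the observed census shares individuals across censuses more than drift
#' predicts (longer-lived individuals, hence a lower observed index);
#' the `"reversed"` convention negates the value for users who prefer
#' "larger = more persistent".
#'
#' @param x a [Census-class] object with contiguous occupancy and at least
#'   3 units for a non-degenerate null (with 2 units the index is fully
#'   determined by the flows).
#' @param nRand number of null replicates (default 100).
#' @param seed optional integer seed.
#' @param signConvention `"as_stated"` (default) for
#'   (observed - null mean)/null sd, `"reversed"` for its negative.
#'
#' @return An [SESResult-class] object. When the null distribution is
#'   degenerate (sd = 0) the `ses` slot is `NA` and `reason` explains why.
#'
#' @examples
#' z <- rbind(z1 = c(1, 1, 1, 1), z2 = c(0, 1, 0, 0))
#' cen <- census(z, species = "sp1")
#' pSesAll(cen, nRand = 200, seed = 1)
#' @export
pSesAll <- function(x, nRand = 100L, seed = NULL,
                    signConvention = c("as_stated", "reversed")) {
  signConvention <- match.arg(signConvention)
  stopifnot(is(x, "Census"), nRand >= 2L)
  flows <- intervalFlows(x)
  T <- ncol(x@occupancy)
  observed <- dMRMu(x)
  obsP <- individualMuComponents(x)[["P_mu"]]
  if (!is.null(seed)) set.seed(seed)
  reps <- numeric(nRand)
  for (r in seq_len(nRand)) {
    ls <- .randomLifespans(flows)
    mu <- .muFromLifespans(ls$birth, ls$last, T)
    if (mu[["P_mu"]] != obsP)
      stop("internal error: replicate P_mu differs from observed P_mu")
    reps[r] <- .ratio(mu[["M_mu"]] + mu[["R_mu"]],
                      2 * mu[["P_mu"]] + mu[["M_mu"]] + mu[["R_mu"]],
                      "all units empty")
  }
  nullMean <- mean(reps)
  nullSd <- stats::sd(reps)
  if (is.na(observed)) {
    ses <- NA_real_; reason <- "observed index undefined (all units empty)"
  } else if (is.na(nullSd) || nullSd == 0) {
    ses <- NA_real_
    reason <- "degenerate null distribution (sd = 0)"
  } else {
    ses <- (observed - nullMean) / nullSd
    if (signConvention == "reversed") ses <- -ses
    reason <- NA_character_
  }
  new("SESResult", observed = as.numeric(observed), replicates = reps,
      nullMean = nullMean, nullSd = nullSd, ses = ses, reason = reason,
      nRand = as.integer(nRand),
      seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
      signConvention = signConvention)
}

setMethod("show", "SESResult", function(object) {
  cat("Persistence SES (", object@signConvention, ", n_rand = ",
      object@nRand, ")\n", sep = "")
  cat("  observed d_MR.mu =", format(object@observed), "\n")
  cat("  null mean =", format(object@nullMean),
      " null sd =", format(object@nullSd), "\n")
  if (is.na(object@ses))
    cat("  ses = NA (", object@reason, ")\n", sep = "")
  else
    cat("  ses =", format(object@ses), "\n")
})

#' @rdname pSesAll
#' @param x an [SESResult-class] object (for the accessors).
#' @export
sesValue <- function(x) {
  stopifnot(is(x, "SESResult"))
  x@ses
}

#' @rdname pSesAll
#' @export
nullReplicates <- function(x) {
  stopifnot(is(x, "SESResult"))
  x@replicates
}
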