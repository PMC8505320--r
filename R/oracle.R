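#' Brute-force inclusion-exclusion audit of the shared components
#'
#' Computes the multiple-unit shared component (a_mu, A_mu or P_mu) directly
#' from its inclusion-exclusion definition: the alternating sum, over every
#' subset of two or more units, of the per-row minimum across the subset
#' (pairs added, triples subtracted, quadruples added, ...). This
#' enumerates all 2^T unit subsets and is intended as an independent audit
#' of the closed forms used by [incidenceComponents()],
#' [abundanceMuComponents()] and [individualMuComponents()]; the two must
#' agree exactly on any census.
#'
#' @param x a [Census-class] (scales `"individual"` and, via the derived
#'   abundance matrix, `"species"`/`"abundance"`) or an
#'   [AbundanceMatrix-class] (scales `"species"` and `"abundance"`).
#' @param scale which shared component to compute: `"species"` (a_mu, on
#'   species presences), `"abundance"` (A_mu, on counts), or `"individual"`
#'   (P_mu, on the occupancy matrix).
#' @param maxUnits guard against accidental exponential blow-up; the
#'   enumeration refuses more than this many units (default 10).
#'
#' @return A single integer.
#'
#' @examples
#' z <- rbind(z1 = c(1, 1, 1, 1), z2 = c(0, 1, 0, 0))
#' cen <- census(z, species = "sp1")
#' bruteForceShared(cen, "individual")                  # 3
#' individualMuComponents(cen)[["P_mu"]]                # same
#' @export
bruteForceShared <- function(x, scale = c("species", "abundance", "individual"),
                             maxUnits = 10L) {
  scale <- match.arg(scale)
  m <- if (is(x, "Census")) {
    if (scale == "individual") x@occupancy else abundanceMatrix(x)@counts
  } else if (is(x, "AbundanceMatrix")) {
    if (scale == "individual")
      stop("the individual scale needs a Census, not an AbundanceMatrix")
    x@counts
  } else stop("x must be a Census or an AbundanceMatrix")
  if (scale == "species") m <- (m > 0L) * 1L
  T <- ncol(m)
  if (T > maxUnits)
    stop("brute-force enumeration over 2^", T, " subsets refused; ",
         "raise maxUnits if you really mean it")
  if (nrow(m) == 0L) return(0L)
  total <- 0
  for (mask in seq_len(2^T - 1L)) {
    inSet <- which(bitwAnd(mask, 2^(seq_len(T) - 1L)) > 0L)
    r <- length(inSet)
    if (r < 2L) next
    rowMin <- do.call(pmin, lapply(inSet, function(j) m[, j]))
    total <- total + (-1)^r * sum(rowMin)
  }
  as.integer(total)
}
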