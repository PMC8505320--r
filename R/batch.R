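#' Load one or many plots from a long-format census file
#'
#' Reads a long-format file into a named list of [Census-class] objects,
#' optionally split by a plot identifier column, and applies the gap policy
#' to each. A plot that fails to load or validate (for example a plot
#' observed at a single census) does not abort the batch: its entry is a
#' `censusLoadError` character holding the message, and downstream batch
#' functions emit an `NA` row for it. Large monitoring data sets routinely
#' hold a thousand or more quadrats in one file; one malformed quadrat must
#' not cost the run.
#'
#' @param input path to a long-format file ([readLongFormat()] format).
#' @param plotCol optional plot identifier column; `NULL` means the file is
#'   a single plot named `"plot1"`.
#' @param gapPolicy gap policy applied to every plot (see
#'   [applyGapPolicy()]).
#' @inheritParams readLongFormat
#'
#' @return Named list; each element is a [Census-class] or a
#'   `censusLoadError` character.
#' @export
loadCensuses <- function(input, plotCol = NULL,
                         gapPolicy = c("strict", "fill", "events"),
                         sep = ",",
                         columns = c(individual = "individual_id",
                                     species = "species_id",
                                     unit = "time_unit"),
                         unitOrder = NULL) {
  gapPolicy <- match.arg(gapPolicy)
  loadOne <- function(expr) {
    tryCatch(applyGapPolicy(expr, gapPolicy),
             error = function(e) structure(conditionMessage(e),
                                           class = "censusLoadError"))
  }
  if (is.null(plotCol)) {
    out <- list(plot1 = loadOne(readLongFormat(input, sep = sep,
                                               columns = columns,
                                               unitOrder = unitOrder)))
  } else {
    df <- utils::read.table(input, sep = sep, header = TRUE,
                            colClasses = "character", quote = "\"",
                            comment.char = "#", check.names = FALSE)
    if (!plotCol %in% colnames(df)) stop("missing plot column: ", plotCol)
    if (nrow(df) == 0L) stop("no records")
    plots <- unique(df[[plotCol]])
    out <- lapply(plots, function(p) {
      sub <- df[df[[plotCol]] == p, setdiff(colnames(df), plotCol),
                drop = FALSE]
      tc <- textConnection(paste(
        c(paste(colnames(sub), collapse = sep),
          do.call(paste, c(lapply(sub, .quoteField, sep = sep), sep = sep))),
        collapse = "\n"))
      on.exit(close(tc))
      loadOne(readLongFormat(tc, sep = sep, columns = columns,
                             unitOrder = unitOrder))
    })
    names(out) <- plots
  }
  failed <- vapply(out, inherits, logical(1), "censusLoadError")
  for (p in names(out)[failed])
    warning("plot ", p, " skipped: ", out[[p]], call. = FALSE)
  out
}

.fraction <- function(num, den) paste0(num, "/", den)

# one row of multiple-unit components + indices + pairwise means
.indicesRow <- function(cen, fractions = FALSE) {
  mu <- multiUnitComponents(cen)
  apMR <- allPairs(cen, "d_mr"); apVS <- allPairs(cen, "v_s")
  row <- data.frame(
    a_mu = mu@aMu, b_mu = mu@bMu, c_mu = mu@cMu,
    A_mu = mu@AMu, B_mu = mu@BMu, C_mu = mu@CMu,
    P_mu = mu@PMu, M_mu = mu@MMu, R_mu = mu@RMu,
    stringsAsFactors = FALSE)
  if (fractions) {
    row$d_sor_mu <- .fraction(mu@bMu + mu@cMu, 2L * mu@aMu + mu@bMu + mu@cMu)
    row$d_bc_mu <- .fraction(mu@BMu + mu@CMu, 2L * mu@AMu + mu@BMu + mu@CMu)
    row$d_mr_mu <- .fraction(mu@MMu + mu@RMu, 2L * mu@PMu + mu@MMu + mu@RMu)
    row$v_s_mu <- .fraction(
      as.numeric(mu@BMu + mu@CMu) * (2 * mu@PMu + mu@MMu + mu@RMu),
      as.numeric(2 * mu@AMu + mu@BMu + mu@CMu) * (mu@MMu + mu@RMu))
  } else {
    row$d_sor_mu <- as.numeric(dSorMu(mu))
    row$d_bc_mu <- as.numeric(dBCMu(mu))
    row$d_mr_mu <- as.numeric(dMRMu(mu))
    row$v_s_mu <- as.numeric(vSMu(mu))
  }
  row$mean_d_mr <- attr(apMR, "mean")
  row$mean_v_s <- attr(apVS, "mean")
  row$n_undefined_pairs <- attr(apMR, "nUndefined") + attr(apVS, "nUndefined")
  row$note <- NA_character_
  row
}

.naIndicesRow <- function(note, fractions = FALSE) {
  row <- as.data.frame(as.list(stats::setNames(rep(NA_integer_, 9L),
    c("a_mu", "b_mu", "c_mu", "A_mu", "B_mu", "C_mu", "P_mu", "M_mu", "R_mu"))))
  idxNA <- if (fractions) NA_character_ else NA_real_
  row$d_sor_mu <- idxNA; row$d_bc_mu <- idxNA
  row$d_mr_mu <- idxNA; row$v_s_mu <- idxNA
  row$mean_d_mr <- NA_real_; row$mean_v_s <- NA_real_
  row$n_undefined_pairs <- NA_integer_
  row$note <- note
  row
}

#' Per-plot table of multiple-unit components and indices
#'
#' For every plot: the nine multiple-unit components, the four
#' multiple-unit indices, and the mean pairwise `d_MR` and `v_s` for
#' comparison (with the count of undefined pairs). Plots that failed to
#' load yield an `NA` row whose `note` column holds the reason.
#'
#' @param censuses named list as returned by [loadCensuses()] (entries may
#'   be `censusLoadError`), or a single [Census-class].
#' @param fractions if `TRUE`, serialize the four index values as exact
#'   integer fractions (strings `"num/den"`) for bit-exact regression
#'   comparisons; the pairwise means stay numeric.
#'
#' @return A `data.frame` with one row per plot, first column `plot_id`.
#'
#' @examples
#' ex <- persistenceExamples()
#' batchIndices(ex)
#' @export
batchIndices <- function(censuses, fractions = FALSE) {
  if (is(censuses, "Census")) censuses <- list(plot1 = censuses)
  rows <- lapply(names(censuses), function(p) {
    cen <- censuses[[p]]
    row <- if (inherits(cen, "censusLoadError"))
      .naIndicesRow(as.character(cen), fractions)
    else tryCatch(.indicesRow(cen, fractions),
                  error = function(e) .naIndicesRow(conditionMessage(e),
                                                    fractions))
    cbind(plot_id = p, row, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Per-plot persistence null-model table
#'
#' Runs [pSesAll()] on every plot and tabulates the observed index, null
#' mean and standard deviation, the standardized effect size, and the
#' bookkeeping needed to reproduce the run. Each plot gets its own derived
#' seed (`seed`, `seed + 1`, ... in plot order) so a batch is reproducible
#' yet plots are independent.
#'
#' @inheritParams batchIndices
#' @param nRand number of null replicates per plot.
#' @param seed integer seed for the first plot; `NULL` for the current RNG
#'   state (then the seed column is `NA`).
#' @param signConvention see [pSesAll()].
#'
#' @return A `data.frame` with one row per plot: `plot_id`, `observed`,
#'   `null_mean`, `null_sd`, `ses`, `reason`, `n_rand`, `seed`,
#'   `sign_convention`, `note`.
#' @export
batchNullModel <- function(censuses, nRand = 100L, seed = NULL,
                           signConvention = c("as_stated", "reversed")) {
  signConvention <- match.arg(signConvention)
  if (is(censuses, "Census")) censuses <- list(plot1 = censuses)
  rows <- lapply(seq_along(censuses), function(i) {
    p <- names(censuses)[i]
    cen <- censuses[[i]]
    plotSeed <- if (is.null(seed)) NULL else as.integer(seed) + i - 1L
    base <- data.frame(plot_id = p, observed = NA_real_, null_mean = NA_real_,
                       null_sd = NA_real_, ses = NA_real_,
                       reason = NA_character_, n_rand = as.integer(nRand),
                       seed = if (is.null(plotSeed)) NA_integer_ else plotSeed,
                       sign_convention = signConvention,
                       note = NA_character_, stringsAsFactors = FALSE)
    if (inherits(cen, "censusLoadError")) {
      base$note <- as.character(cen)
      return(base)
    }
    tryCatch({
      res <- pSesAll(cen, nRand = nRand, seed = plotSeed,
                     signConvention = signConvention)
      base$observed <- res@observed
      base$null_mean <- res@nullMean
      base$null_sd <- res@nullSd
      base$ses <- res@ses
      base$reason <- res@reason
      base
    }, error = function(e) {
      base$note <- conditionMessage(e)
      base
    })
  })
  out <- do.call(rbind, rows)
  undef <- !is.na(out$reason)
  if (any(undef))
    warning("ses undefined for plot(s) ",
            paste(out$plot_id[undef], collapse = ", "), call. = FALSE)
  out
}

#' Serialize an SESResult as JSON
#'
#' @param x an [SESResult-class] object.
#' @param file path to write to, or `NULL` to return the JSON string.
#' @param keepReplicates include the full null distribution.
#'
#' @return The JSON string, invisibly when written to a file.
#' @export
writeSesJson <- function(x, file = NULL, keepReplicates = FALSE) {
  stopifnot(is(x, "SESResult"))
  obj <- list(observed = x@observed, null_mean = x@nullMean,
              null_sd = x@nullSd, ses = x@ses, reason = x@reason,
              n_rand = x@nRand, seed = x@seed,
              sign_convention = x@signConvention)
  if (keepReplicates) obj$replicates <- x@replicates
  json <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, na = "null")
  if (is.null(file)) return(json)
  writeLines(json, file)
  invisible(json)
}

#' Write a batch table as TSV or JSON
#'
#' @param table a `data.frame` from [batchIndices()] or [batchNullModel()].
#' @param file output path.
#' @param format `"tsv"` or `"json"`.
#' @return Invisibly, the file path.
#' @export
writeBatchTable <- function(table, file, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (format == "tsv")
    utils::write.table(table, file, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "NA")
  else
    writeLines(jsonlite::toJSON(table, dataframe = "rows", auto_unbox = TRUE,
                                digits = NA, na = "null"), file)
  invisible(file)
}
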