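makeBatchFile <- function() {
  ex <- persistenceExamples()
  tf <- tempfile(fileext = ".csv")
  rows <- c("plot_id,individual_id,species_id,time_unit")
  for (p in names(ex)) {
    z <- occupancy(ex[[p]])
    for (i in rownames(z)) for (u in which(z[i, ] == 1))
      rows <- c(rows, paste(p, i, "sp1", u, sep = ","))
  }
  writeLines(rows, tf)
  tf
}

test_that("batch indices tabulate components, indices and pairwise means per plot", {
  ex <- persistenceExamples()
  tab <- batchIndices(ex)
  expect_identical(tab$plot_id, c("longLived", "shortLived"))
  expect_equal(tab$d_mr_mu, c(1 / 3, 7 / 13))
  expect_identical(tab$P_mu, c(3L, 3L))
  expect_equal(tab$mean_d_mr, c(1 / 6, 1 / 2))

  # exact-fraction serialization for regression comparisons
  frac <- batchIndices(ex, fractions = TRUE)
  expect_identical(frac$d_mr_mu, c("3/9", "7/13"))

  # a single Census is accepted directly
  one <- batchIndices(ex$longLived)
  expect_identical(one$plot_id, "plot1")
})

test_that("multi-plot files load per plot and identical plots give identical rows", {
  tf <- makeBatchFile()
  censuses <- loadCensuses(tf, plotCol = "plot_id")
  expect_identical(names(censuses), c("longLived", "shortLived"))
  expect_identical(`colnames<-`(occupancy(censuses$longLived), NULL),
                   `colnames<-`(occupancy(persistenceExamples()$longLived), NULL))

  # two identical plots produce two identical rows
  tf2 <- tempfile(fileext = ".csv")
  writeLines(c("plot_id,individual_id,species_id,time_unit",
               "p1,i1,sp1,1", "p1,i1,sp1,2",
               "p2,i1,sp1,1", "p2,i1,sp1,2"), tf2)
  tab <- batchIndices(loadCensuses(tf2, plotCol = "plot_id"))
  expect_identical(`rownames<-`(tab[1, -1], NULL),
                   `rownames<-`(tab[2, -1], NULL))
})

test_that("a plot observed at a single census is skipped, not fatal", {
  tf <- tempfile(fileext = ".csv")
  writeLines(c("plot_id,individual_id,species_id,time_unit",
               "good,i1,sp1,1", "good,i1,sp1,2",
               "lonely,i9,sp1,1"), tf)
  expect_warning(censuses <- loadCensuses(tf, plotCol = "plot_id"),
                 "lonely")
  tab <- batchIndices(censuses)
  expect_identical(nrow(tab), 2L)
  expect_false(is.na(tab$d_mr_mu[tab$plot_id == "good"]))
  expect_true(is.na(tab$d_mr_mu[tab$plot_id == "lonely"]))
  expect_match(tab$note[tab$plot_id == "lonely"], "time units")
})

test_that("batch null model is deterministic and honest about undefined SES", {
  ex <- persistenceExamples()
  a <- suppressWarnings(batchNullModel(ex, nRand = 50, seed = 42))
  b <- suppressWarnings(batchNullModel(ex, nRand = 50, seed = 42))
  expect_identical(a, b)
  expect_identical(a$seed, c(42L, 43L))

  static <- list(flat = census(rbind(i1 = c(1, 1, 1)), species = "a"))
  expect_warning(tab <- batchNullModel(static, nRand = 20, seed = 1),
                 "undefined")
  expect_true(is.na(tab$ses))
  expect_match(tab$reason, "degenerate")
})

test_that("null-model JSON serialization round-trips through jsonlite", {
  cen <- simulateCensus(nUnits = 5, nInitial = 20, deaths = 4, recruits = 4,
                        seed = 3)
  res <- pSesAll(cen, nRand = 25, seed = 9)
  tf <- tempfile(fileext = ".json")
  writeSesJson(res, tf, keepReplicates = TRUE)
  parsed <- jsonlite::fromJSON(tf)
  expect_equal(parsed$observed, res@observed)
  expect_equal(parsed$ses, res@ses)
  expect_identical(parsed$n_rand, 25L)
  expect_equal(parsed$replicates, res@replicates)
})

test_that("batch tables write as TSV and JSON", {
  tab <- batchIndices(persistenceExamples())
  tsv <- tempfile(fileext = ".tsv"); js <- tempfile(fileext = ".json")
  writeBatchTable(tab, tsv, "tsv")
  writeBatchTable(tab, js, "json")
  back <- read.delim(tsv)
  expect_identical(back$plot_id, tab$plot_id)
  expect_equal(back$d_mr_mu, tab$d_mr_mu)
  jback <- jsonlite::fromJSON(js)
  expect_equal(jback$d_mr_mu, tab$d_mr_mu)
})

test_that("the command-line front end runs end to end", {
  rscript <- file.path(R.home("bin"), "Rscript")
  cli <- system.file("scripts", "indivBeta-cli.R", package = "indivBeta")
  skip_if(cli == "", "CLI script not installed")
  tf <- makeBatchFile()

  out <- tempfile(fileext = ".tsv")
  status <- system2(rscript, c(cli, "indices", "--input", tf,
                               "--plot-col", "plot_id", "--out", out),
                    stdout = TRUE, stderr = TRUE)
  expect_true(file.exists(out))
  tab <- read.delim(out)
  expect_equal(tab$d_mr_mu, c(1 / 3, 7 / 13), tolerance = 1e-12)

  out2 <- tempfile(fileext = ".tsv")
  system2(rscript, c(cli, "nullmodel", "--input", tf, "--plot-col", "plot_id",
                     "--n-rand", "50", "--seed", "5", "--out", out2),
          stdout = TRUE, stderr = TRUE)
  ses <- read.delim(out2)
  expect_identical(ses$plot_id, c("longLived", "shortLived"))
  expect_false(any(is.na(ses$ses)))

  simOut <- tempfile(fileext = ".csv")
  system2(rscript, c(cli, "simulate", "--n-units", "4", "--n-initial", "10",
                     "--deaths", "2", "--recruits", "2", "--seed", "1",
                     "--out", simOut), stdout = TRUE, stderr = TRUE)
  sim <- readLongFormat(simOut)
  expect_identical(nUnits(sim), 4L)

  orOut <- tempfile(fileext = ".tsv")
  system2(rscript, c(cli, "oracle", "--input", tf, "--plot-col", "plot_id",
                     "--scale", "individual", "--out", orOut),
          stdout = TRUE, stderr = TRUE)
  oracle <- read.delim(orOut)
  expect_true(all(oracle$agree))

  # unknown policy and missing input exit nonzero
  bad <- suppressWarnings(
    system2(rscript, c(cli, "indices", "--input", tf, "--gap-policy", "bogus"),
            stdout = TRUE, stderr = TRUE))
  expect_false(is.null(attr(bad, "status")))
  bad2 <- suppressWarnings(
    system2(rscript, c(cli, "indices", "--input", "/nonexistent.csv"),
            stdout = TRUE, stderr = TRUE))
  expect_false(is.null(attr(bad2, "status")))
})
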