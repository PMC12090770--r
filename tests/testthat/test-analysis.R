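# Analysis: cross-feeding graphs, KDE maps, SCFA, shifts, Wilcoxon.

test_that("crossFeedingGraph routes transfers and the environment node", {
  ft <- data.frame(agent = 1:6,
                   species = c("p", "p", "c", "c", "q", "q"),
                   metabolite = "acetate",
                   flux = c(2, 4, -1, -1, 1, 1))
  ## species means: p = +3, q = +1 (producers, P = 4); c = -1 (U = 1)
  g <- crossFeedingGraph(ft, c(acetate = 1))
  e <- edgeTable(g)
  expect_setequal(g@nodes, c("p", "c", "q", "environment"))
  pc <- e[e$from == "p" & e$to == "c", ]
  qc <- e[e$from == "q" & e$to == "c", ]
  expect_equal(pc$weight, 1 * (3 / 4) * (1 / 1))  # proportional share
  expect_equal(qc$weight, 1 * (1 / 4))
  ## surplus P - U = 3 routed to the environment proportionally
  pe <- e[e$from == "p" & e$to == "environment", ]
  expect_equal(pe$weight, 3 * 3 / 4)
  ## total out of producers equals total production
  expect_equal(sum(e$weight[e$from %in% c("p", "q")]), 4)
})

test_that("deficits draw from the environment node", {
  ft <- data.frame(agent = 1:2, species = c("p", "c"),
                   metabolite = "glucose", flux = c(1, -5))
  e <- edgeTable(crossFeedingGraph(ft, c(glucose = 2)))
  expect_equal(e$weight[e$from == "p" & e$to == "c"], 1)
  expect_equal(e$weight[e$from == "environment" & e$to == "c"], 4)
})

test_that("metabolites below the concentration threshold are excluded", {
  ft <- data.frame(agent = c(1, 2, 1, 2), species = c("p", "c", "p", "c"),
                   metabolite = rep(c("acetate", "butyrate"), each = 2),
                   flux = c(2, -1, 2, -1))
  g <- crossFeedingGraph(ft, c(acetate = 0.5, butyrate = 0.05),
                         concThreshold = 0.1)
  expect_setequal(unique(edgeTable(g)$metabolite), "acetate")
  g2 <- crossFeedingGraph(ft, c(acetate = 0.5, butyrate = 0.5),
                          exclude = "acetate")
  expect_setequal(unique(edgeTable(g2)$metabolite), "butyrate")
})

test_that("cross-feeding graphs convert to igraph and write to disk", {
  ft <- data.frame(agent = 1:2, species = c("p", "c"),
                   metabolite = "acetate", flux = c(2, -1))
  g <- crossFeedingGraph(ft, c(acetate = 1))
  ig <- asIgraph(g)
  expect_true(igraph::is_directed(ig))
  expect_setequal(igraph::V(ig)$name, g@nodes)
  f1 <- tempfile(fileext = ".tsv")
  f2 <- tempfile(fileext = ".graphml")
  writeGraph(g, f1)
  writeGraph(g, f2, format = "graphml")
  back <- read.table(f1, header = TRUE, sep = "\t")
  expect_equal(nrow(back), nrow(edgeTable(g)))
  expect_gt(file.size(f2), 0)
})

test_that("kdeMap integrates to one with periodic and reflecting walls", {
  set.seed(12)
  W <- 100; H <- 60
  x <- runif(60, 0, W); y <- runif(60, 0, H)
  k <- kdeMap(x, y, W, H, bandwidth = c(6, 6), gridN = 80)
  mass <- sum(k$z) * (W / 80) * (H / 80)
  expect_equal(mass, 1, tolerance = 0.01)
  ## density is periodic in x: agents near the seam spread to both sides
  k2 <- kdeMap(c(1, 2, 99), c(30, 30, 30), W, H, bandwidth = c(3, 3))
  expect_gt(k2$z[length(k2$x), 30 / (H / 64) + 1],
            0.5 * k2$z[1, 30 / (H / 64) + 1])
  expect_warning(expect_null(kdeMap(1, 1, W, H)), "fewer than 2")
})

test_that("normalizeScfa returns fractions that sum to one", {
  f <- normalizeScfa(c(acetate = 6, butyrate = 3, propionate = 1))
  expect_equal(sum(f), 1)
  expect_equal(unname(f["acetate"]), 0.6)
  expect_error(normalizeScfa(c(a = -1, b = 2)), "nonnegative")
  expect_error(normalizeScfa(c(a = 0, b = 0)), "zero")
})

test_that("shiftAnalysis matches a brute-force recomputation", {
  set.seed(13)
  rxns <- paste0("R", 1:6)
  results <- lapply(1:5, function(i) {
    lo <- round(rnorm(6), 2)
    new("FVAResult",
        intervals = matrix(c(lo, lo + round(runif(6, 0, 3), 2)), 6, 2,
                           dimnames = list(rxns, c("min", "max"))),
        fraction = 0.9)
  })
  st <- shiftTable(shiftAnalysis(results, reportThreshold = 1))
  ## brute force over plain loops
  for (k in seq_along(rxns)) {
    lbs <- sapply(results, function(r) r@intervals[k, 1])
    ubs <- sapply(results, function(r) r@intervals[k, 2])
    expect_equal(st$minLB[k], min(lbs))
    expect_equal(st$maxUB[k], max(ubs))
    expect_equal(st$shift[k],
                 max(max(lbs) - min(lbs), max(ubs) - min(ubs)))
    expect_equal(st$reportable[k], st$shift[k] > 1)
  }
  cut <- quantile(st$shift, 0.95)
  expect_equal(st$significant, st$shift >= cut)
  ## width-based alternative
  stw <- shiftTable(shiftAnalysis(results, definition = "width"))
  for (k in seq_along(rxns)) {
    w <- sapply(results, function(r) diff(r@intervals[k, ]))
    expect_equal(stw$shift[k], max(w) - min(w))
  }
})

test_that("wilcoxonSignedRank matches full sign enumeration", {
  set.seed(14)
  for (n in c(5, 7, 10)) {
    for (rep in 1:5) {
      x <- rnorm(n)
      y <- rnorm(n)
      got <- wilcoxonSignedRank(x, y)
      expect_equal(got$method, "exact")
      expect_equal(got$p.value, bruteForceWilcoxon(x, y), tolerance = 1e-12)
    }
  }
})

test_that("wilcoxonSignedRank matches stats::wilcox.test without ties", {
  set.seed(15)
  for (rep in 1:5) {
    x <- rnorm(9); y <- rnorm(9)
    got <- wilcoxonSignedRank(x, y)
    ref <- stats::wilcox.test(x, y, paired = TRUE, exact = TRUE)
    expect_equal(got$statistic, unname(ref$statistic))
    expect_equal(got$p.value, ref$p.value, tolerance = 1e-12)
  }
})

test_that("ties and zeros are handled (mid-ranks, zero removal)", {
  x <- c(3, 3, 5, 7, 9, 2, 4)
  y <- c(1, 1, 5, 3, 4, 1, 1)  # one zero difference, tied |d|
  got <- wilcoxonSignedRank(x, y)
  expect_equal(got$n, 6L)  # zero removed
  expect_equal(got$p.value, bruteForceWilcoxon(x, y), tolerance = 1e-12)
  ## all-zero input degenerates with a warning
  expect_warning(out <- wilcoxonSignedRank(1:6, 1:6), "zero")
  expect_equal(out$p.value, 1)
  expect_error(wilcoxonSignedRank(1:4, c(2, 3, 1, 7)), "at least 5")
})

test_that("large samples fall back to the normal approximation", {
  set.seed(16)
  x <- rnorm(40); y <- rnorm(40, 0.8)
  got <- wilcoxonSignedRank(x, y)
  expect_equal(got$method, "normal approximation")
  ref <- stats::wilcox.test(x, y, paired = TRUE, exact = FALSE,
                            correct = TRUE)
  expect_equal(got$p.value, ref$p.value, tolerance = 1e-3)
  expect_lt(got$p.value, 0.05)  # a clear shift is detected
})

test_that("fvaPerAgent returns per-agent intervals from the final state", {
  cfg <- makeScenario("pair_crossfeed", maxSteps = 8L, seed = 3L)
  res <- runSimulation(cfg)
  out <- fvaPerAgent(res$state, cfg, "producer", fraction = 0.9)
  expect_gt(length(out), 0)
  ids <- agentData(res$state@agents)
  expect_true(all(names(out) %in%
                    as.character(ids$id[ids$species == "producer"])))
  iv <- fluxIntervals(out[[1]])
  expect_setequal(rownames(iv), reactionIds(makeProducer()))
  expect_true(all(iv[, "min"] <= iv[, "max"] + 1e-9))
  ## two agents' tables feed the shift analysis
  if (length(out) >= 2) {
    st <- shiftAnalysis(out)
    expect_equal(nrow(shiftTable(st)), nrow(iv))
  }
  expect_error(fvaPerAgent(res$state, cfg, "missing_species"), "unknown")
})
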