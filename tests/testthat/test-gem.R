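# Metabolic layer: model construction, FBA/pFBA/FVA, uptake kinetics.

test_that("GEMModel validates structure and reports all problems", {
  expect_error(
    GEMModel("x", reactions = list(
      list(id = "A", stoichiometry = c(m = 1), lb = 2, ub = 1),
      list(id = "B", stoichiometry = c(m = -1), lb = 0, ub = 1)),
      objectiveId = "NOPE"),
    "lower bound exceeds upper bound.*A")
  expect_error(
    GEMModel("x", reactions = list(
      list(id = "A", stoichiometry = c(m = 1), lb = 0, ub = 1)),
      objectiveId = "ZZZ"),
    "objective reaction 'ZZZ'")
  ## exchange reactions must touch exactly one metabolite
  expect_error(
    GEMModel("x", reactions = list(
      list(id = "EX_two", stoichiometry = c(a = -1, b = 1), lb = 0, ub = 1),
      list(id = "BIO", stoichiometry = c(a = 1, b = -1), lb = 0, ub = 1)),
      objectiveId = "BIO", exchangeMap = c(EX_two = "a")),
    "exactly one metabolite")
})

test_that("accessors expose the model components", {
  m <- toyModel()
  expect_equal(reactionIds(m),
               c("EX_glucose", "CONV", "EX_acetate", "BIOMASS"))
  expect_setequal(metaboliteIds(m), c("glc", "ac", "bio"))
  expect_equal(objectiveId(m), "BIOMASS")
  expect_equal(speciesId(m), "toy")
  b <- bounds(m)
  expect_equal(b["EX_glucose", "lb"], -10)
  expect_equal(unname(exchangeMap(m)["EX_acetate"]), "acetate")
  expect_equal(dim(stoichiometry(m)), c(3L, 4L))
})

test_that("FBA reproduces the hand-computed optimum mu* = 5", {
  res <- fba(makeProducer(10, 2, 0.5))
  expect_equal(solverStatus(res), "optimal")
  expect_equal(growthRate(res), 5)
  expect_equal(unname(fluxes(res)["EX_glucose"]), -10)
  expect_equal(unname(fluxes(res)["EX_acetate"]), 20)
})

test_that("FBA matches vertex enumeration on every fixture model", {
  for (m in list(makeProducer(), makeConsumer(), makeAerotolerant(),
                 makeProducer(2, 0.2, 0.01, "slowgrower"))) {
    res <- fba(m)
    obj <- as.numeric(reactionIds(m) == objectiveId(m))
    b <- bounds(m)
    want <- bruteForceLP(obj, as.matrix(stoichiometry(m)),
                         rep(0, length(metaboliteIds(m))),
                         pmax(b[, "lb"], -1e6), pmin(b[, "ub"], 1e6))
    expect_equal(growthRate(res), want$value, tolerance = 1e-8)
  }
})

test_that("optimal solutions satisfy mass balance to 1e-6", {
  for (m in list(makeProducer(), makeConsumer(), makeAerotolerant())) {
    for (res in list(fba(m), pfba(m))) {
      expect_equal(solverStatus(res), "optimal")
      expect_lt(max(abs(stoichiometry(m) %*% fluxes(res))), 1e-6)
    }
  }
})

test_that("an infeasible model yields status infeasible, not an error", {
  ## forced glucose secretion with no source makes S v = 0 impossible
  m <- GEMModel("sick", reactions = list(
    list(id = "EX_glc", stoichiometry = c(glc = -1), lb = 5, ub = 10),
    list(id = "BIO", stoichiometry = c(glc = -1, bio = 1), lb = 0, ub = 10),
    list(id = "SINK", stoichiometry = c(bio = -1), lb = 0, ub = 10)),
    objectiveId = "SINK", exchangeMap = c(EX_glc = "glucose"))
  res <- fba(m)
  expect_equal(solverStatus(res), "infeasible")
  expect_equal(growthRate(res), 0)
  expect_equal(solverStatus(pfba(m)), "infeasible")
})

test_that("pFBA attains the FBA optimum with minimal total flux", {
  m <- makeProducer(10, 2, 0.5)
  p <- pfba(m)
  expect_equal(growthRate(p), 5)
  ## the optimum is unique here; |v|_1 = 10 + 10 + 20 + 5
  expect_equal(sum(abs(fluxes(p))), 45)

  ## a model with a wasteful alternative route: pFBA must avoid the cycle
  m2 <- GEMModel("cycle", reactions = list(
    list(id = "EX_a", stoichiometry = c(a = -1), lb = -10, ub = 1000),
    list(id = "FWD", stoichiometry = c(a = -1, b = 1), lb = -1000, ub = 1000),
    list(id = "BACK", stoichiometry = c(b = -1, a = 1), lb = -1000, ub = 1000),
    list(id = "BIO", stoichiometry = c(b = -1, bio = 0.5), lb = 0, ub = 1000),
    list(id = "BIOMASS", stoichiometry = c(bio = -1), lb = 0, ub = 1000)),
    objectiveId = "BIOMASS", exchangeMap = c(EX_a = "a"))
  p2 <- pfba(m2)
  expect_equal(growthRate(p2), growthRate(fba(m2)))
  ## FWD/BACK net 10; any cycling inflates |FWD| + |BACK| beyond 10
  expect_equal(abs(fluxes(p2)[["FWD"]]) + abs(fluxes(p2)[["BACK"]]), 10)
})

test_that("FVA reproduces the hand-derived intervals at fraction 0.9", {
  m <- makeProducer(10, 2, 0.5)
  iv <- fluxIntervals(fva(m, fraction = 0.9))
  expect_equal(unname(iv["EX_glucose", ]), c(-10, -9))
  expect_equal(unname(iv["BIOMASS", ]), c(4.5, 5))
  expect_equal(unname(iv["EX_acetate", ]), c(18, 20))
})

test_that("FVA intervals are monotone in fraction", {
  m <- makeConsumer()
  lo <- fluxIntervals(fva(m, fraction = 0.5))
  hi <- fluxIntervals(fva(m, fraction = 0.9))
  expect_true(all(hi[, "min"] >= lo[, "min"] - 1e-8))
  expect_true(all(hi[, "max"] <= lo[, "max"] + 1e-8))
})

test_that("FVA validates inputs", {
  m <- toyModel()
  expect_error(fva(m, fraction = 0), "fraction")
  expect_error(fva(m, fraction = 1.2), "fraction")
  expect_error(fva(m, reactionIds = "NOPE"), "unknown reactions")
})

test_that("constrainUptake implements Michaelis-Menten bounds", {
  m <- makeProducer(10, 2, 0.5)
  kin <- uptakeKinetics("producer", "glucose", vmax = 8, km = 0.5)

  ## S = Km gives half saturation
  m1 <- constrainUptake(m, c(glucose = 0.5), kin)
  expect_equal(bounds(m1)["EX_glucose", "lb"], -4)
  ## S = 0 and absent metabolite give zero uptake
  expect_equal(bounds(constrainUptake(m, c(glucose = 0), kin)
                      )["EX_glucose", "lb"], 0)
  expect_equal(bounds(constrainUptake(m, c(other = 3), kin)
                      )["EX_glucose", "lb"], 0)
  ## saturation limit
  m2 <- constrainUptake(m, c(glucose = 1e9), kin)
  expect_equal(bounds(m2)["EX_glucose", "lb"], -8, tolerance = 1e-6)
  ## secretion (upper) bounds untouched
  expect_equal(bounds(m1)["EX_glucose", "ub"], 1000)
  expect_equal(bounds(m1)["EX_acetate", ], bounds(m)["EX_acetate", ])
  ## negative concentrations rejected
  expect_error(constrainUptake(m, c(glucose = -1), kin), "nonnegative")
})

test_that("constrainUptake is monotone in concentration", {
  m <- makeProducer()
  kin <- uptakeKinetics("producer", "glucose", vmax = 10, km = 0.5)
  S <- sort(runif(20, 0, 20))
  lbs <- vapply(S, function(s)
    bounds(constrainUptake(m, c(glucose = s), kin))["EX_glucose", "lb"],
    numeric(1))
  expect_true(all(diff(lbs) <= 1e-12))  # larger S never raises the bound
})

test_that("missing kinetics keep model defaults and can report it", {
  m <- makeConsumer()
  kin <- uptakeKinetics("consumer", "acetate", vmax = 10, km = 0.1)
  out <- constrainUptake(m, c(glucose = 5, acetate = 5), kin)
  expect_equal(bounds(out)["EX_glucose", "lb"], -2)  # model default kept
  withr_old <- options(mucosim.verbose = TRUE)
  on.exit(options(withr_old))
  expect_message(constrainUptake(m, c(glucose = 5, acetate = 5), kin),
                 "no kinetics .*glucose")
})

test_that("zero vmax forbids uptake entirely", {
  m <- makeConsumer()
  kin <- uptakeKinetics("consumer", "glucose", vmax = 0, km = 0.5)
  out <- constrainUptake(m, c(glucose = 50), kin)
  expect_equal(bounds(out)["EX_glucose", "lb"], 0)
})

test_that("exchangeFluxes maps reactions to environment metabolites", {
  m <- makeProducer(10, 2, 0.5)
  ex <- exchangeFluxes(m, fba(m))
  expect_equal(ex[["glucose"]], -10)
  expect_equal(ex[["acetate"]], 20)
})

test_that("uptake kinetics tables are validated", {
  expect_error(uptakeKinetics("a", "x", vmax = -1, km = 1), "nonnegative")
  expect_error(uptakeKinetics("a", "x", vmax = 1, km = 0), "km")
  expect_error(uptakeKinetics(c("a", "a"), c("x", "x"), c(1, 2), c(1, 1)),
               "duplicate")
})
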