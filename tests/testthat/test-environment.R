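# Environment layer: rasterization, sources, the finite-volume solver.

test_that("the FVM solver matches the quadratic sink profile", {
  ## discretization error ~ (k / 2D) h^2 / 2 = 0.016 on the 4 um mesh
  expect_lt(quadraticCase(10), 0.05)
})

test_that("halving the mesh cuts the error about fourfold", {
  ratio <- quadraticCase(10) / quadraticCase(20)
  expect_gt(ratio, 3.5)
  expect_lt(ratio, 4.5)
})

test_that("a source-free field relaxes to the boundary value everywhere", {
  grid <- LatticeGrid(6L, 8L, cellSize = 5)
  f <- metaboliteField("m", grid, Dbulk = 50,
                       boundary = boundarySpec(topValue = 7))
  sol <- solveSteadyState(f, grid)
  expect_equal(sol$field@S, matrix(7, 6, 8), tolerance = 1e-10)
  expect_equal(sol$clamped, 0)
})

test_that("discrete flux balance closes to 1e-8 relative", {
  set.seed(8)
  for (bottom in list(boundarySpec(topValue = 5),
                      boundarySpec(topValue = 5, bottom = "dirichlet",
                                   bottomValue = 1),
                      boundarySpec(topValue = 5, bottom = "sink",
                                   bottomValue = 20))) {
    grid <- LatticeGrid(8L, 10L, cellSize = 10)
    grid@biofilmMask[, 1:3] <- TRUE  # heterogeneous diffusivity
    R <- matrix(rnorm(80, 0, 0.05), 8, 10)
    f <- metaboliteField("m", grid, Dbulk = 1e4, boundary = bottom, R = R)
    sol <- solveSteadyState(f, grid)
    expect_equal(sol$clamped, 0)
    bal <- fluxBalance(sol$field, grid)
    scale <- max(abs(bal$boundaryIn), abs(bal$sourceIn), 1e-12)
    expect_lt(abs(bal$residual) / scale, 1e-8)
  }
})

test_that("bottom Dirichlet and sink boundaries shape the profile", {
  grid <- LatticeGrid(4L, 10L, cellSize = 5)
  fD <- metaboliteField("o2", grid, Dbulk = 100,
                        boundary = boundarySpec(topValue = 0,
                                                bottom = "dirichlet",
                                                bottomValue = 2))
  S <- solveSteadyState(fD, grid)$field@S
  expect_true(all(diff(S[1, ]) < 0))  # decreasing away from the supply
  expect_gt(S[1, 1], S[1, 10])

  ## an absorptive sink depletes the bottom relative to zero-flux
  mkf <- function(bottom) {
    f <- metaboliteField("s", grid, Dbulk = 100,
                         boundary = boundarySpec(topValue = 0,
                                                 bottom = bottom,
                                                 bottomValue =
                                                   if (bottom == "sink") 50
                                                   else 0),
                         R = matrix(0.1, 4, 10))
    solveSteadyState(f, grid)$field@S
  }
  expect_lt(mkf("sink")[1, 1], mkf("neumann")[1, 1])
})

test_that("over-consumption is clamped at zero and counted", {
  grid <- LatticeGrid(4L, 4L, cellSize = 10)
  f <- metaboliteField("m", grid, Dbulk = 10,
                       boundary = boundarySpec(topValue = 0.01),
                       R = matrix(-5, 4, 4))
  sol <- solveSteadyState(f, grid)
  expect_gt(sol$clamped, 0)
  expect_true(all(sol$field@S >= 0))
})

test_that("biofilm cells diffuse at 0.6 times the bulk rate", {
  grid <- LatticeGrid(4L, 6L, cellSize = 5)
  D0 <- diffusionMap(grid, Dbulk = 100)
  expect_true(all(D0 == 100))
  grid@biofilmMask[2, 3] <- TRUE
  D1 <- diffusionMap(grid, Dbulk = 100)
  expect_equal(D1[2, 3], 60)
  expect_equal(sum(D1 == 60), 1)
  ## reduced diffusivity steepens the profile across the biofilm layer
  gAll <- LatticeGrid(4L, 10L, cellSize = 5)
  f0 <- metaboliteField("m", gAll, 100, boundarySpec(topValue = 10),
                        R = matrix(-0.5, 4, 10))
  slow <- gAll; slow@biofilmMask[, 1:5] <- TRUE
  f1 <- metaboliteField("m", slow, 100, boundarySpec(topValue = 10),
                        R = matrix(-0.5, 4, 10))
  S0 <- solveSteadyState(f0, gAll)$field@S
  S1 <- solveSteadyState(f1, slow,
                         Dmap = diffusionMap(slow, 100))$field@S
  expect_lt(S1[1, 1], S0[1, 1])
})

test_that("rasterize assigns dry biomass per species and marks biofilm", {
  a <- newAgents(c("a", "a", "b"), x = c(5, 7, 25), y = c(5, 5, 15),
                 mass = c(10, 20, 30), attached = c(TRUE, TRUE, FALSE))
  grid <- LatticeGrid(4L, 2L, cellSize = 10)
  out <- rasterize(a, grid, dryWeightFraction = 0.3)
  expect_equal(out$biomass$a[1, 1], 30 * 1e-12 * 0.3)
  expect_equal(out$biomass$b[3, 2], 30 * 1e-12 * 0.3)
  expect_equal(sum(out$biomass$a), 30e-12 * 0.3)
  ## only attached biomass defines the biofilm mask
  expect_true(out$grid@biofilmMask[1, 1])
  expect_false(out$grid@biofilmMask[3, 2])
  expect_equal(sum(out$grid@biofilmMask), 1L)
})

test_that("agentCells rejects centers outside the lattice", {
  a <- newAgents("s", x = 5, y = 500, mass = 15)
  expect_error(agentCells(a, LatticeGrid(4L, 4L, 10)), "outside")
})

test_that("accumulateSources converts fluxes to volumetric rates", {
  ## one agent, 20 pg, flux -3 mmol/gDW/h of glucose, cell 10x10x10 um:
  ## R = flux * gDW / V = -3 * (20e-12 * 0.3) / 1e-12 L = -18 mM/h
  a <- newAgents("s", x = 5, y = 5, mass = 20)
  grid <- LatticeGrid(2L, 2L, cellSize = 10)
  ft <- data.frame(agent = 1L, species = "s", metabolite = "glucose",
                   flux = -3)
  R <- accumulateSources(ft, a, grid, dryWeightFraction = 0.3,
                         slabDepth = 10)
  expect_equal(R$glucose[1, 1], -3 * 20e-12 * 0.3 / 1e-12)
  expect_equal(sum(R$glucose != 0), 1L)
  ## two agents in one cell add up
  b <- newAgents("s", x = c(5, 6), y = c(5, 5), mass = 20)
  ft2 <- rbind(ft, data.frame(agent = 2L, species = "s",
                              metabolite = "glucose", flux = -3))
  R2 <- accumulateSources(ft2, b, grid, 0.3, 10)
  expect_equal(R2$glucose[1, 1], 2 * R$glucose[1, 1])
})

test_that("boundary specs validate their types", {
  expect_error(boundarySpec(top = "neumann"), "top boundary")
  expect_error(boundarySpec(bottom = "weird"), "bottom boundary")
  expect_error(boundarySpec(bottom = "sink", bottomValue = -1),
               "nonnegative")
})
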