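# Agent layer: geometry, shoving, movement, growth, division, sloughing.

test_that("massToRadius inverts the sphere mass relation", {
  r <- massToRadius(4 / 3 * pi * 1.1 * 8, rho = 1.1)
  expect_equal(r, 2)
  expect_equal(massToRadius(4 / 3 * pi * 2, rho = 2), 1)
})

test_that("AgentSet validity enforces the radius invariant and y >= 0", {
  a <- newAgents("s", x = c(1, 2), y = c(5, 5), mass = 10)
  expect_true(validObject(a))
  d <- agentData(a)
  d$radius[1] <- d$radius[1] * 2
  expect_error(validObject(mucosim:::replaceAgentData(a, d)),
               "radius inconsistent")
  d <- agentData(a)
  d$y[2] <- -1
  expect_error(validObject(mucosim:::replaceAgentData(a, d)), "y >= 0")
})

test_that("displacementDistance matches the worked examples", {
  mass1 <- 4 / 3 * pi * 1.1  # radius 1 at rho = 1.1
  a <- newAgents("s", x = c(0, 1.5, 5), y = c(10, 10, 10), mass = mass1)
  expect_equal(displacementDistance(a, 1, 2, width = 1000), 0.5)
  expect_equal(displacementDistance(a, 1, 3, width = 1000), -3)
  ## tangency
  b <- newAgents("s", x = c(0, 2), y = c(10, 10), mass = mass1)
  expect_equal(displacementDistance(b, 1, 2, width = 1000), 0)
  ## minimum image across the periodic seam
  c2 <- newAgents("s", x = c(0.25, 99.75), y = c(10, 10), mass = mass1)
  expect_equal(displacementDistance(c2, 1, 2, width = 100), 1.5)
})

test_that("two-body shove resolves symmetrically in one iteration", {
  mass1 <- 4 / 3 * pi * 1.1
  a <- newAgents("s", x = c(10, 11), y = c(50, 50), mass = mass1)
  out <- shoveIteration(a, width = 1000)
  d <- agentData(out$agents)
  expect_equal(out$maxOverlap, 1)
  expect_equal(d$x, c(9.5, 11.5))   # each pushed overlap/2 = 0.5 outward
  expect_equal(d$y, c(50, 50))
  expect_equal(resolveCollisions(a, 1000)$iterations, 1L)
})

test_that("two-body resolution matches the closed form for random radii", {
  set.seed(7)
  for (i in 1:20) {
    m <- runif(2, 5, 60)
    r <- massToRadius(m, 1.1)
    gap <- runif(1, 0.1, 0.9) * sum(r)  # overlapping separation
    a <- newAgents("s", x = c(100, 100 + gap), y = c(50, 50), mass = m)
    out <- resolveCollisions(a, width = 1000, maxIter = 10)
    expect_true(out$converged)
    d <- agentData(out$agents)
    ## symmetric half-displacement: both ends move (sum(r) - gap)/2
    push <- (sum(r) - gap) / 2
    expect_equal(d$x, c(100 - push, 100 + gap + push), tolerance = 1e-12)
  }
})

test_that("non-overlapping configurations are a fixed point", {
  set.seed(3)
  a <- newAgents("s", x = seq(10, 90, by = 10), y = seq(10, 90, by = 10),
                 mass = 15)
  out <- shoveIteration(a, width = 200)
  expect_equal(agentData(out$agents)[c("x", "y")],
               agentData(a)[c("x", "y")])
  rc <- resolveCollisions(a, 200)
  expect_equal(rc$iterations, 0L)
  expect_true(rc$converged)
})

test_that("agents shoved into the bottom wall are clipped at y = radius", {
  mass1 <- 4 / 3 * pi * 1.1
  ## vertical pair: the lower agent rests on the wall and cannot go below
  a <- newAgents("s", x = c(10, 10), y = c(1, 1.8), mass = mass1)
  out <- shoveIteration(a, width = 100)
  d <- agentData(out$agents)
  expect_equal(d$y[1], 1)        # clipped at its radius
  expect_gt(d$y[2], 1.8)         # upper agent takes the push
})

test_that("wall-resting agents keep tangential motion (no deadlock)", {
  mass1 <- 4 / 3 * pi * 1.1
  ## two wall-resting agents overlapping horizontally plus one above:
  ## the diagonal downward push must not freeze the sideways escape
  a <- newAgents("s", x = c(10, 11.2, 10.6), y = c(1, 1, 2.4), mass = mass1)
  rc <- resolveCollisions(a, width = 100, maxIter = 50)
  expect_true(rc$converged)
  expect_lt(maxPairOverlap(rc$agents, 100), 1e-6)
})

test_that("resolveCollisions honors its converged contract", {
  set.seed(11)
  a <- newAgents("s", x = runif(40, 0, 60), y = runif(40, 2, 30), mass = 20)
  rc <- resolveCollisions(a, width = 60, maxIter = 500)
  expect_true(rc$converged)
  d <- agentData(rc$agents)
  ## invariants: no positive overlap beyond tolerance, wall respected
  expect_lt(maxPairOverlap(rc$agents, 60), 1e-6)
  expect_true(all(d$y >= d$radius - 1e-9))
  ## non-convergence is reported, not raised
  rc2 <- resolveCollisions(a, width = 60, maxIter = 1)
  expect_false(rc2$converged)
  expect_equal(rc2$iterations, 1L)
})

test_that("collision resolution changes positions only", {
  set.seed(5)
  a <- newAgents(c("x", "y"), x = runif(30, 0, 50), y = runif(30, 2, 25),
                 mass = runif(30, 10, 40))
  rc <- resolveCollisions(a, width = 50, maxIter = 200)
  d0 <- agentData(a)
  d1 <- agentData(rc$agents)
  expect_identical(d1$id, d0$id)
  expect_identical(d1$species, d0$species)
  expect_identical(d1$mass, d0$mass)
  expect_identical(d1$radius, d0$radius)
  expect_identical(d1$attached, d0$attached)
  expect_equal(totalBiomass(rc$agents), totalBiomass(a))
})

test_that("shoving is translation-equivariant along the periodic axis", {
  set.seed(9)
  W <- 80
  a <- newAgents("s", x = runif(25, 0, W), y = runif(25, 2, 30), mass = 25)
  shift <- 17.3
  d <- agentData(a)
  d$x <- (d$x + shift) %% W
  b <- mucosim:::replaceAgentData(a, d)
  ra <- resolveCollisions(a, W, maxIter = 100)$agents
  rb <- resolveCollisions(b, W, maxIter = 100)$agents
  dx <- (agentData(rb)$x - agentData(ra)$x - shift) %% W
  expect_true(all(pmin(dx, W - dx) < 1e-9))
  expect_equal(agentData(rb)$y, agentData(ra)$y)
})

test_that("coincident centers separate deterministically", {
  a <- newAgents("s", x = c(10, 10), y = c(20, 20), mass = 15)
  r1 <- resolveCollisions(a, 100, maxIter = 10)
  r2 <- resolveCollisions(a, 100, maxIter = 10)
  expect_true(r1$converged)
  expect_identical(agentData(r1$agents), agentData(r2$agents))
  expect_lt(maxPairOverlap(r1$agents, 100), 1e-6)
})

test_that("planktonic agents advance exactly stepLength before wrapping", {
  set.seed(2)
  a <- newAgents("s", x = 50, y = 50, mass = 15, angle = pi / 7)
  b <- planktonicMove(a, width = 100, stepLength = 5)
  d0 <- agentData(a)
  d1 <- agentData(b)
  dx <- mucosim:::wrapDx(d1$x - d0$x, 100)
  expect_equal(sqrt(dx^2 + (d1$y - d0$y)^2), 5)
})

test_that("attached agents do not move on their own", {
  a <- newAgents("s", x = 50, y = 50, mass = 15, attached = TRUE)
  b <- planktonicMove(a, width = 100)
  expect_equal(agentData(b)[c("x", "y")], agentData(a)[c("x", "y")])
})

test_that("agents attach on wall contact and contact with attached agents", {
  mass1 <- 4 / 3 * pi * 1.1
  ## heading straight down from just above the wall: stops at y = radius
  a <- newAgents("s", x = 50, y = 4, mass = mass1, angle = -pi / 2)
  b <- planktonicMove(a, width = 100, stepLength = 5)
  d <- agentData(b)
  expect_equal(d$y, 1)
  expect_true(d$attached)
  ## chain attachment: a free agent touching an attached one attaches too,
  ## and attachment propagates through the contact chain in one call
  c3 <- newAgents("s", x = c(10, 10, 10), y = c(1, 2.9, 4.8), mass = mass1,
                  attached = c(TRUE, FALSE, FALSE))
  out <- mucosim:::updateAttachment(c3, width = 100)
  expect_true(all(agentData(out)$attached))
})

test_that("growth is exponential and division conserves mass", {
  a <- newAgents("s", x = c(10, 20), y = c(10, 10), mass = c(4, 8))
  g <- grow(a, mu = c(1, 0), dt = 0.5)
  expect_equal(agentData(g)$mass, c(4 * exp(0.5), 8))
  expect_error(grow(a, mu = -1, dt = 0.5), "nonnegative")

  big <- newAgents("s", x = 10, y = 10, mass = 40)  # radius > 2
  expect_gt(agentData(big)$radius, 2)
  kids <- divideAgents(big, threshold = 2)
  expect_equal(nAgents(kids), 2L)
  expect_equal(agentData(kids)$mass, c(20, 20))
  expect_equal(totalBiomass(kids), 40)

  small <- newAgents("s", x = 10, y = 10, mass = 4)
  expect_identical(agentData(divideAgents(small, threshold = 2)),
                   agentData(small))
})

test_that("division by mass threshold works too", {
  a <- newAgents("s", x = 10, y = 10, mass = 4)
  out <- divideAgents(a, threshold = 3, on = "mass")
  expect_equal(nAgents(out), 2L)
  expect_equal(agentData(out)$mass, c(2, 2))
})

test_that("division overlaps are removed by the next resolveCollisions", {
  set.seed(4)
  a <- newAgents("s", x = runif(10, 5, 45), y = runif(10, 5, 25), mass = 38)
  a <- resolveCollisions(a, 50, maxIter = 300)$agents
  kids <- divideAgents(a, threshold = 2)
  expect_equal(nAgents(kids), 20L)
  rc <- resolveCollisions(kids, 50, maxIter = 500)
  expect_lt(maxPairOverlap(rc$agents, 50), 1e-6)
  expect_equal(totalBiomass(rc$agents), totalBiomass(a))
})

test_that("sloughing removes exactly the agents above the height limit", {
  set.seed(6)
  a <- newAgents(rep(c("a", "b"), 10), x = runif(20, 0, 100),
                 y = runif(20, 2, 80), mass = 15)
  out <- sloughAgents(a, maxHeight = 40)
  d <- agentData(a)
  gone <- d$y - d$radius > 40
  expect_equal(nAgents(out$agents), sum(!gone))
  expect_equal(sum(out$removed), sum(gone))
  expect_equal(sort(agentData(out$agents)$id), sort(d$id[!gone]))
  expect_error(sloughAgents(a, maxHeight = -1))
})
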