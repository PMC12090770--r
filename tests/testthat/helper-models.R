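# Shared test fixtures and independent oracles.

## internals under test
lpSolveBounded <- mucosim:::lpSolveBounded
overlappingPairs <- mucosim:::overlappingPairs
agentCells <- mucosim:::agentCells
windowFluctuation <- mucosim:::windowFluctuation
hashConfig <- mucosim:::hashConfig
parseCliArgs <- mucosim:::parseCliArgs

## Brute-force LP oracle by vertex enumeration: optimizes obj'x over
## {Aeq x = beq, lb <= x <= ub} by fixing every subset of n - rank(Aeq)
## variables at each bound combination and solving for the rest. Exponential,
## only for toy sizes; completely independent of the package solver.
bruteForceLP <- function(obj, Aeq, beq, lb, ub, maximize = TRUE,
                         tol = 1e-7) {
  A <- as.matrix(Aeq)
  n <- length(obj)
  m <- qr(A)$rank
  best <- NULL
  pickBasic <- utils::combn(n, m)
  for (k in seq_len(ncol(pickBasic))) {
    B <- pickBasic[, k]
    N <- setdiff(seq_len(n), B)
    AB <- A[, B, drop = FALSE]
    if (qr(AB)$rank < m) next
    bounds <- expand.grid(rep(list(c(FALSE, TRUE)), length(N)))
    for (r in seq_len(max(nrow(bounds), 1))) {
      xN <- ifelse(unlist(bounds[r, ]), ub[N], lb[N])
      if (any(!is.finite(xN))) next
      rhs <- beq - if (length(N)) A[, N, drop = FALSE] %*% xN else 0
      xB <- tryCatch(qr.solve(AB, rhs, tol = 1e-12),
                     error = function(e) NULL)
      if (is.null(xB)) next
      x <- numeric(n)
      x[B] <- xB
      x[N] <- xN
      if (max(abs(A %*% x - beq)) > tol) next
      if (any(x < lb - tol) || any(x > ub + tol)) next
      val <- sum(obj * x)
      if (is.null(best) ||
          (maximize && val > best$value + 1e-12) ||
          (!maximize && val < best$value - 1e-12))
        best <- list(x = x, value = val)
    }
  }
  best
}

## exact two-sided signed-rank p-value by enumerating all 2^n sign vectors,
## using the same mid-ranks as the implementation under test
bruteForceWilcoxon <- function(x, y) {
  d <- (x - y)
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  signs <- expand.grid(rep(list(c(FALSE, TRUE)), n))
  Vs <- apply(signs, 1, function(s) sum(r[unlist(s)]))
  pLo <- mean(Vs <= V + 1e-9)
  pHi <- mean(Vs >= V - 1e-9)
  min(1, 2 * min(pLo, pHi))
}

## a tiny deterministic two-metabolite model used across tests
toyModel <- function() makeProducer(10, 2, 0.5, speciesId = "toy")

## dense post-division bed: resolved tangent hex packing, grown one default
## timestep at per-agent rates, then divided -- the state the simulator hands
## to resolveCollisions (used by acceptance criterion 1)
postDivisionBed <- function(seed, n = 480, mass = 35, ncol = 30) {
  set.seed(seed)
  r <- massToRadius(mass, 1.1)
  W <- ncol * 2 * r
  ix <- (seq_len(n) - 1) %% ncol
  iy <- (seq_len(n) - 1) %/% ncol
  a <- newAgents("s",
                 x = (ix * 2 * r + ifelse(iy %% 2 == 1, r, 0)) %% W,
                 y = r + iy * sqrt(3) * r, mass = mass, attached = TRUE)
  a <- grow(a, mu = runif(n, 0, 0.7), dt = 0.1)
  a <- divideAgents(a, threshold = 2)
  list(agents = a, width = W)
}

## FVM oracle: uniform sink R = -k, top Dirichlet S0, bottom zero-flux
## Neumann has the closed form S(y) = S0 - (k / 2D) (H^2 - y^2); returns the
## max absolute error of the solver on an ny-cell mesh
quadraticCase <- function(ny, k = 2, D = 100, S0 = 20, H = 40) {
  grid <- LatticeGrid(nx = 4L, ny = as.integer(ny), cellSize = H / ny)
  f <- metaboliteField("m", grid, Dbulk = D,
                       boundary = boundarySpec(topValue = S0),
                       R = matrix(-k, 4, ny))
  sol <- solveSteadyState(f, grid)
  yc <- (seq_len(ny) - 0.5) * H / ny
  exact <- S0 - k / (2 * D) * (H^2 - yc^2)
  max(abs(sweep(sol$field@S, 2, exact)))
}

## largest pair overlap (displacement distance) in an agent set
maxPairOverlap <- function(agents, width) {
  d <- agentData(agents)
  n <- nrow(d)
  if (n < 2) return(-Inf)
  worst <- -Inf
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    dd <- displacementDistance(agents, i, j, width)
    if (dd > worst) worst <- dd
  }
  worst
}
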