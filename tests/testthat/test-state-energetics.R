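test_that("protonation-state labels parse and validate", {
  ps <- parseProtonationState("Y266:-|R300:+|E183:0")
  expect_identical(residueCharges(ps),
                   c(Y266 = "-", R300 = "+", E183 = "0"))
  expect_error(protonationState(Y266 = "neg"), "charge tags")
  expect_error(parseProtonationState("Y266"), "malformed")
})

test_that("minimum-energy state matches an exhaustive scan", {
  set.seed(13)
  for (rep in 1:10) {
    labs <- sprintf("S%02d", 1:10)
    grid <- c(-70, -35, 0, 35, 70)
    df <- expand.grid(state = labs, voltage = grid,
                      stringsAsFactors = FALSE)
    df$energy <- rnorm(nrow(df), 0, 40)
    tab <- stateEnergyTable(df$state, df$voltage, df$energy)
    v <- sample(grid, 1)
    rows <- df[df$voltage == v, ]
    expect_identical(as.character(minEnergyState(tab, v)),
                     rows$state[which.min(rows$energy)])
    # invariant under adding a constant at that voltage
    df2 <- df
    df2$energy[df2$voltage == v] <- df2$energy[df2$voltage == v] + 500
    tab2 <- stateEnergyTable(df2$state, df2$voltage, df2$energy)
    expect_identical(as.character(minEnergyState(tab2, v)),
                     as.character(minEnergyState(tab, v)))
  }
})

test_that("minimum-energy state handles edge cases", {
  tab <- stateEnergyTable("only", -70, 12)
  expect_identical(as.character(minEnergyState(tab, -70)), "only")
  expect_error(minEnergyState(tab, 0), "no states tabulated")
  tied <- stateEnergyTable(c("a", "b"), c(0, 0), c(5, 5))
  expect_error(minEnergyState(tied, 0), "tied")
})

test_that("planted closed state is the -70 mV minimum, open wins at 0 mV", {
  gen <- genEnergyTable(seed = 4)
  tr <- truths(gen$manifest)
  expect_identical(as.character(minEnergyState(gen$table, -70)),
                   tr$stateClosed)
  expect_identical(as.character(minEnergyState(gen$table, 0)), tr$stateOpen)
  ps <- attr(minEnergyState(gen$table, -70), "protonationState")
  expect_identical(unname(residueCharges(ps)[c("Y266", "R300", "E183")]),
                   c("0", "0", "0"))
})

test_that("crossing point interpolates linearly and flags no-crossing", {
  tab <- stateEnergyTable(
    state = rep(c("A", "B"), each = 3),
    voltage = rep(c(-70, 0, 70), 2),
    energy = c(-70, 0, 70, 70, 0, -70))  # E_A = V, E_B = -V
  cp <- crossingPoint(tab, "A", "B")
  expect_true(cp$crossing)
  expect_equal(cp$voltage, 0)

  mono <- stateEnergyTable(rep(c("A", "B"), each = 2),
                           rep(c(-70, 70), 2), c(0, 10, 20, 40))
  expect_false(crossingPoint(mono, "A", "B")$crossing)

  one <- stateEnergyTable(c("A", "B"), c(0, 0), c(1, 2))
  expect_error(crossingPoint(one, "A", "B"), "insufficient")
})

test_that("crossing voltage is symmetric in the pair; height follows the reference", {
  gen <- genEnergyTable(crossingVoltage = -20, crossingHeight = 60, seed = 8)
  tr <- truths(gen$manifest)
  ab <- crossingPoint(gen$table, tr$stateClosed, tr$stateOpen)
  ba <- crossingPoint(gen$table, tr$stateOpen, tr$stateClosed,
                      reference = tr$stateClosed)
  expect_equal(ab$voltage, ba$voltage)
  expect_equal(ab$height, ba$height)
  expect_equal(ab$voltage, -20)
  expect_equal(ab$height, 60)
})

test_that("crossing location matches a dense-grid numeric scan", {
  set.seed(31)
  for (rep in 1:10) {
    grid <- c(-70, -35, 0, 35, 70)
    eA <- sort(runif(5, -50, 50))                # monotone up
    eB <- sort(runif(5, -50, 50), decreasing = TRUE)  # monotone down
    if ((eA[1] - eB[1]) * (eA[5] - eB[5]) >= 0) next
    tab <- stateEnergyTable(rep(c("A", "B"), each = 5), rep(grid, 2),
                            c(eA, eB))
    cp <- crossingPoint(tab, "A", "B")
    dense <- seq(-70, 70, by = 0.001)
    diffDense <- approx(grid, eA, dense)$y - approx(grid, eB, dense)$y
    vScan <- dense[which.min(abs(diffDense))]
    expect_lt(abs(cp$voltage - vScan), 0.1)
  }
})

test_that("decomposition deltas subtract the named term", {
  tab <- stateEnergyTable(c("closed", "open"), c(0, 0), c(10, 5),
                          xc = c(96.0, 25.2))
  expect_equal(decompositionDelta(tab, "closed", "open", 0), 70.8)
  expect_equal(decompositionDelta(tab, "closed", "closed", 0), 0)
  set.seed(2)
  xc <- rnorm(2, 50, 20)
  tab2 <- stateEnergyTable(c("a", "b"), c(35, 35), c(1, 2), xc = xc)
  expect_equal(decompositionDelta(tab2, "a", "b", 35), xc[1] - xc[2])
  noXc <- stateEnergyTable(c("a", "b"), c(0, 0), c(1, 2))
  expect_error(decompositionDelta(noXc, "a", "b", 0), "absent")
  expect_error(decompositionDelta(tab, "closed", "open", 0, term = "zpe"),
               "unknown decomposition term")
})

test_that("state-energy tables round-trip through delimited text", {
  gen <- genEnergyTable(nStates = 4L, seed = 6)
  tmp <- tempfile(fileext = ".tsv")
  writeStateEnergyTable(gen$table, tmp)
  back <- readStateEnergyTable(tmp)
  expect_equal(energyTable(back)$energy, energyTable(gen$table)$energy)
  expect_identical(stateLabels(back), stateLabels(gen$table))
  expect_equal(voltages(back), voltages(gen$table))
})
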