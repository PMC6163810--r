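# minimal in-code structure builder for profile tests
makeStructure <- function(z, q, x = 0, y = 0) {
  n <- length(z)
  a <- data.frame(serial = seq_len(n), elety = "CB", element = "C",
                  resid = "ALA", resno = seq_len(n), chain = "A",
                  x = rep_len(x, n), y = rep_len(y, n), z = z, charge = q,
                  stringsAsFactors = FALSE)
  new("ChargedStructure", atoms = a,
      frame = list(origin = min(z), note = ""))
}

test_that("slab sums land in the right slabs and conserve charge", {
  s <- makeStructure(z = 10, q = 2)
  prof <- slabProfile(s, slabPartition(3, 11L, 0))
  expect_equal(slabCharges(prof)$charge[4], 2)  # z=10 -> [9,12), index 4
  expect_equal(sum(slabCharges(prof)$charge[-4]), 0)
  expect_equal(totalCharge(prof), 2)

  s2 <- makeStructure(z = c(10, 10.5), q = c(1, -1))
  prof2 <- slabProfile(s2, slabPartition(3, 11L, 0))
  expect_equal(slabCharges(prof2)$charge[4], 0)
  expect_equal(totalCharge(prof2), 0)
})

test_that("slab boundaries are half-open and out-of-range atoms error", {
  s <- makeStructure(z = c(0, 3, 32.999), q = c(1, 1, 1))
  prof <- slabProfile(s, slabPartition(3, 11L, 0))
  expect_equal(slabCharges(prof)$charge[1:2], c(1, 1))  # z=3 goes to slab 2
  expect_error(slabProfile(makeStructure(z = 33, q = 1),
                           slabPartition(3, 11L, 0)),
               "outside the slab partition")
  expect_error(slabProfile(makeStructure(z = -0.001, q = 1),
                           slabPartition(3, 11L, 0)),
               "outside the slab partition")
})

test_that("random profiles equal the brute-force filter-and-sum oracle", {
  set.seed(42)
  for (rep in 1:20) {
    n <- sample(30:100, 1)
    z <- runif(n, 0, 32.9)
    q <- rnorm(n, 0, 0.4)
    prof <- slabProfile(makeStructure(z, q), slabPartition(3, 11L, 0))
    expect_equal(slabCharges(prof)$charge, bruteSlabSums(z, q, 0, 3, 11L))
    expect_equal(totalCharge(prof), sum(q))
  }
})

test_that("center of charge follows the charge-weighted mean of midpoints", {
  # single occupied slab, midpoint 10.5
  prof <- slabProfile(makeStructure(z = 10.2, q = 1.5),
                      slabPartition(3, 11L, 0))
  expect_equal(centerOfCharge(prof), 10.5)
  # +1 at the midpoints of slabs [1.5,4.5) and [7.5,10.5): symmetry -> 6
  prof2 <- slabProfile(makeStructure(z = c(3, 9), q = c(1, 1)),
                       slabPartition(3, 11L, 1.5))
  expect_equal(centerOfCharge(prof2), 6)
  # zero total charge: undefined
  prof0 <- slabProfile(makeStructure(z = c(3, 9), q = c(1, -1)),
                       slabPartition(3, 11L, 0))
  expect_error(centerOfCharge(prof0), "undefined")
})

test_that("slabwise center agrees with the atomwise centroid within bounds", {
  set.seed(7)
  for (rep in 1:25) {
    n <- sample(40:120, 1)
    z <- runif(n, 0, 32.9)
    # same-sign charges: binning error provably within thickness/2
    qPos <- runif(n, 0.05, 0.8)
    prof <- slabProfile(makeStructure(z, qPos), slabPartition(3, 11L, 0))
    atomC <- sum(qPos * z) / sum(qPos)
    expect_equal(centerOfCharge(prof, "atomwise"), atomC)
    expect_lt(abs(centerOfCharge(prof, "slabwise") - atomC), 1.5)
    # signed charges: error within (thickness/2) * sum|q| / |sum q|
    qSgn <- rnorm(n, 0, 0.3)
    if (abs(sum(qSgn)) < 0.2) qSgn[1] <- qSgn[1] + 1
    profS <- slabProfile(makeStructure(z, qSgn), slabPartition(3, 11L, 0))
    bound <- 1.5 * sum(abs(qSgn)) / abs(sum(qSgn))
    expect_lte(abs(centerOfCharge(profS) - centerOfCharge(profS, "atomwise")),
               bound)
  }
})

test_that("refining the slabs converges the binned center to the atomwise one", {
  set.seed(19)
  z <- runif(60, 0, 29.9)
  q <- runif(60, 0.05, 0.6)
  atomC <- sum(q * z) / sum(q)
  for (t in c(3, 1, 0.3, 0.1)) {
    prof <- slabProfile(makeStructure(z, q),
                        slabPartition(t, as.integer(ceiling(30 / t)), 0))
    expect_lte(abs(centerOfCharge(prof) - atomC), t / 2)
  }
})

test_that("rigid translation shifts the center of charge exactly", {
  set.seed(3)
  z <- runif(50, 0, 30)
  q <- rnorm(50, 0.1, 0.3)
  for (dz in c(-7.25, 4.5, 11.3)) {
    a <- slabProfile(makeStructure(z, q), slabPartition(3, 11L, 0))
    b <- slabProfile(makeStructure(z + dz, q), slabPartition(3, 11L, dz))
    expect_equal(centerOfCharge(b) - centerOfCharge(a), dz)
    expect_equal(centerOfCharge(b, "atomwise") - centerOfCharge(a, "atomwise"),
                 dz)
  }
})

test_that("displacement is signed, antisymmetric and partition-checked", {
  expect_equal(displacement(19.6, 8.3), 11.3)
  z <- runif(30, 0, 30); q <- runif(30, 0.1, 0.5)
  p <- slabPartition(3, 11L, 0)
  a <- slabProfile(makeStructure(z, q), p)
  b <- slabProfile(makeStructure(30 - z, q), p)
  expect_equal(displacement(a, b), -displacement(b, a))
  expect_equal(displacement(a, a), 0)
  expect_error(displacement(a, slabProfile(makeStructure(z, q),
                                           slabPartition(3, 11L, -1))),
               "incompatible")
})

test_that("effective gating charge scales displacement by the field drop", {
  expect_equal(effectiveGatingCharge(30, 2, 30), 2)   # full traversal
  expect_equal(effectiveGatingCharge(0, 2, 30), 0)
  expect_equal(effectiveGatingCharge(11.3, 2, 30), 2 * 11.3 / 30)
  expect_error(effectiveGatingCharge(5, 2, 0), "positive")
})
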