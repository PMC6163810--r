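# build a ChargedStructure from a site specification for typing tests
structureFromAtoms <- function(df) {
  a <- data.frame(serial = seq_len(nrow(df)), elety = df$elety,
                  element = df$element, resid = df$resid, resno = df$resno,
                  chain = "A", x = df$x, y = df$y, z = df$z,
                  charge = NA_real_, stringsAsFactors = FALSE)
  new("ChargedStructure", atoms = a, frame = list(origin = min(a$z), note = ""))
}

test_that("site typing follows the residue table and the amphoteric rule", {
  s <- structureFromAtoms(data.frame(
    elety = c("OH", "NE", "NH1", "NH2", "OE1", "OE2"),
    element = c("O", "N", "N", "N", "O", "O"),
    resid = c("TYR", "ARG", "ARG", "ARG", "GLU", "GLU"),
    resno = c(266L, 300L, 300L, 300L, 183L, 183L),
    x = 1:6, y = 0, z = 0, stringsAsFactors = FALSE))

  # default nominal charges: Arg +, Glu -
  sites <- assignSites(s)
  role <- setNames(sites$role, paste(sites$residue, sites$atom))
  expect_identical(role[["Y266 OH"]], "both")
  expect_identical(role[["R300 NE"]], "donor")      # protonated: acid
  expect_identical(role[["R300 NH1"]], "donor")
  expect_identical(role[["R300 NH2"]], "donor")
  expect_identical(role[["E183 OE1"]], "acceptor")
  expect_identical(role[["E183 OE2"]], "acceptor")

  # neutral arginine: NE becomes the base; neutral glutamate carries an OH
  neutral <- assignSites(s, protonationState(R300 = "0", E183 = "0"))
  roleN <- setNames(neutral$role, paste(neutral$residue, neutral$atom))
  expect_identical(roleN[["R300 NE"]], "acceptor")
  expect_identical(roleN[["R300 NH1"]], "donor")    # NH donors always
  expect_identical(roleN[["E183 OE1"]], "both")
  expect_identical(roleN[["E183 OE2"]], "acceptor")
})

test_that("apolar structures yield no sites; unknown residues warn", {
  apolar <- structureFromAtoms(data.frame(
    elety = c("CB", "CD1", "CG"), element = "C",
    resid = c("ALA", "LEU", "ILE"), resno = 1:3,
    x = 1:3, y = 0, z = 0, stringsAsFactors = FALSE))
  expect_identical(nrow(assignSites(apolar)), 0L)

  odd <- structureFromAtoms(data.frame(
    elety = "O1", element = "O", resid = "LIG", resno = 9L,
    x = 0, y = 0, z = 0, stringsAsFactors = FALSE))
  expect_warning(assignSites(odd), "unknown")
})

test_that("graph edges require role compatibility and the distance cutoff", {
  pair <- data.frame(
    residue = c("Y1", "E2"), resid = c("TYR", "GLU"), resno = 1:2,
    chain = "A", atom = c("OH", "OE1"), role = c("both", "acceptor"),
    x = c(0, 2.8), y = 0, z = 0, stringsAsFactors = FALSE)
  expect_identical(nrow(buildGraph(pair, 3.5)@edges), 1L)
  # two pure donors never bond
  donors <- transform(pair, role = c("donor", "donor"))
  expect_identical(nrow(buildGraph(donors, 3.5)@edges), 0L)
  # beyond the cutoff
  far <- transform(pair, x = c(0, 3.6))
  expect_identical(nrow(buildGraph(far, 3.5)@edges), 0L)
  expect_error(buildGraph(pair, cutoff = 0), "positive")
})

test_that("random site clouds match the all-pairs brute-force oracle", {
  set.seed(101)
  for (rep in 1:10) {
    sites <- randomSiteCloud(30)
    g <- buildGraph(sites, cutoff = 3.5)
    adj <- bruteResidueAdjacency(sites, 3.5)
    et <- edgeTable(g)
    gotPairs <- sort(paste(pmin(et$residueA, et$residueB),
                           pmax(et$residueA, et$residueB)))
    wantPairs <- sort(unique(unlist(lapply(names(adj), function(a)
      lapply(adj[[a]], function(b)
        paste(min(a, b), max(a, b)))))))
    expect_identical(gotPairs, wantPairs)
  }
})

test_that("triad detection finds planted YRE and RER motifs within the window", {
  triad <- data.frame(
    elety = c("OH", "NE", "OE1"), element = c("O", "N", "O"),
    resid = c("TYR", "ARG", "GLU"), resno = c(266L, 300L, 183L),
    x = c(0, 5, 2.5), y = c(0, 0, 4.33), z = 0, stringsAsFactors = FALSE)
  s <- structureFromAtoms(triad)
  found <- findTriads(assignSites(s), window = 6)
  expect_identical(nrow(found), 1L)
  expect_identical(found$pattern, "YRE")
  expect_identical(c(found$res1, found$res2, found$res3),
                   c("Y266", "R300", "E183"))
  expect_equal(found$d12, 5)

  # one distance beyond the default window excludes the triple
  triad8 <- transform(triad, x = c(0, 8, 2.5))
  expect_identical(nrow(findTriads(assignSites(structureFromAtoms(triad8)),
                                   window = 6)), 0L)
  # monotone in window: the wide window readmits it
  expect_gte(nrow(findTriads(assignSites(structureFromAtoms(triad8)),
                             window = 10)), 1L)

  rer <- data.frame(
    elety = c("NE", "OE1", "NE"), element = c("N", "O", "N"),
    resid = c("ARG", "GLU", "ARG"), resno = c(300L, 226L, 303L),
    x = c(0, 2.6, 5.2), y = 0, z = 0, stringsAsFactors = FALSE)
  foundRer <- findTriads(assignSites(structureFromAtoms(rer)), window = 6)
  expect_identical(foundRer$pattern, "RER")
  expect_identical(c(foundRer$res1, foundRer$res2, foundRer$res3),
                   c("R300", "E226", "R303"))
})

test_that("the planted two-path topology behaves like the Y266F experiment", {
  g <- buildGraph(assignSites(genStructure(seed = 1)$structure))
  paths <- enumeratePaths(g, "R303", "E183")
  expect_identical(formatPaths(paths),
                   c("R303->E226->R300->E183", "R303->Y266->R300->E183"))
  # deleting the tyrosine leaves the glutamate route only
  paths2 <- enumeratePaths(dropResidues(g, "Y266"), "R303", "E183")
  expect_identical(formatPaths(paths2), "R303->E226->R300->E183")
  expect_error(enumeratePaths(g, "R999", "E183"), "not in graph")
})

test_that("path enumeration equals brute-force DFS on random graphs", {
  set.seed(77)
  for (rep in 1:20) {
    n <- sample(6:12, 1)
    sites <- randomSiteCloud(n, span = 6)
    g <- buildGraph(sites, cutoff = 3.5)
    adj <- bruteResidueAdjacency(sites, 3.5)
    ends <- sample(sites$residue, 2)
    maxHops <- sample(3:6, 1)
    got <- formatPaths(enumeratePaths(g, ends[1], ends[2], maxHops))
    want <- formatPaths(dfsPaths(adj, ends[1], ends[2], maxHops))
    expect_identical(got, want)
  }
})

test_that("paths are order-invariant, edge-consistent and damage-monotone", {
  set.seed(55)
  sites <- randomSiteCloud(10, span = 5)
  g <- buildGraph(sites, cutoff = 3.5)
  ends <- c(sites$residue[1], sites$residue[10])
  ref <- formatPaths(enumeratePaths(g, ends[1], ends[2], 6))

  # invariance to site insertion order
  gPerm <- buildGraph(sites[sample(nrow(sites)), ], cutoff = 3.5)
  expect_identical(formatPaths(enumeratePaths(gPerm, ends[1], ends[2], 6)),
                   ref)
  expect_false(any(duplicated(ref)))

  # consecutive residues on every path share a graph edge
  et <- edgeTable(g)
  ePairs <- paste(pmin(et$residueA, et$residueB),
                  pmax(et$residueA, et$residueB))
  for (p in enumeratePaths(g, ends[1], ends[2], 6))
    for (i in seq_len(length(p) - 1L))
      expect_true(paste(min(p[i], p[i + 1]), max(p[i], p[i + 1])) %in% ePairs)

  # deleting any residue never increases the path count
  for (drop in setdiff(sites$residue, ends)) {
    g2 <- dropResidues(g, drop)
    expect_lte(length(enumeratePaths(g2, ends[1], ends[2], 6)), length(ref))
  }
})
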