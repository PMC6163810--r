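# 3-letter -> 1-letter codes for residue labels (Y266 style)
.aa1 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
          GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
          MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
          TYR = "Y", VAL = "V")
.waterNames <- c("HOH", "WAT", "TIP", "SOL")

# functional-group atoms per residue type, used for sites and triad distances
.functionalAtoms <- list(
  TYR = "OH", ARG = c("NE", "NH1", "NH2"), GLU = c("OE1", "OE2"),
  ASP = c("OD1", "OD2"), HIS = c("ND1", "NE2"), SER = "OG", THR = "OG1",
  CYS = "SG", ASN = c("OD1", "ND2"), GLN = c("OE1", "NE2"),
  LYS = "NZ", TRP = "NE1"
)

.residueLabel <- function(resid, resno) {
  one <- .aa1[resid]
  ifelse(resid %in% .waterNames, paste0("HOH", resno),
         ifelse(is.na(one), paste0(resid, resno), paste0(one, resno)))
}

# default nominal side-chain charges (solution conditions)
.defaultTag <- function(resid) {
  switch(resid, ARG = "+", LYS = "+", GLU = "-", ASP = "-", "0")
}

#' Assign hydrogen-bond donor/acceptor sites to a structure
#'
#' Applies the side-chain typing table to every residue: Tyr OH, Ser/Thr
#' OG, Cys SG, His ring nitrogens and water O are both donor and acceptor;
#' Arg NH1/NH2 are always donors, while the amphoteric NE is a donor when
#' the arginine is protonated (`+`) and an acceptor when neutral (`0`) --
#' the property that lets an arginine relay a proton. Glu/Asp carboxylate
#' oxygens are acceptors when charged (`-`); when neutral one oxygen
#' (carrying the proton) is both. Nominal charges default to solution
#' conditions (Arg/Lys `+`, Glu/Asp `-`, others `0`) and can be overridden
#' per residue with a [ProtonationState-class].
#'
#' Residues with no polar side chain yield no sites; residue names outside
#' the typing table are skipped with a warning.
#'
#' @param x a [ChargedStructure-class] (charges need not be attached).
#' @param protonation optional [ProtonationState-class] overriding the
#'   default nominal charges, keyed by residue label (e.g. `"R300"`).
#' @return data.frame of sites with columns `residue`, `resid`, `resno`,
#'   `chain`, `atom`, `role`, `x`, `y`, `z`.
#' @seealso [buildGraph()]
#' @export
setMethod("assignSites", "ChargedStructure",
  function(x, protonation = NULL, ...) {
    a <- x@atoms
    over <- if (is.null(protonation)) character(0) else protonation@charges
    known <- c(names(.aa1), .waterNames)
    unknown <- setdiff(unique(a$resid), known)
    if (length(unknown))
      warning("skipping residues with unknown type: ",
              paste(unknown, collapse = ", "))

    rows <- vector("list", nrow(a))
    n <- 0L
    for (i in seq_len(nrow(a))) {
      resid <- a$resid[i]; atom <- a$elety[i]
      if (resid %in% .waterNames) {
        if (a$element[i] != "O") next
        role <- "both"
      } else {
        fa <- .functionalAtoms[[resid]]
        if (is.null(fa) || !(atom %in% fa)) next
        lab <- .residueLabel(resid, a$resno[i])
        tag <- if (lab %in% names(over)) over[[lab]] else .defaultTag(resid)
        role <- switch(resid,
          ARG = if (atom == "NE") (if (tag == "+") "donor" else "acceptor")
                else "donor",
          LYS = if (tag == "+") "donor" else "both",
          GLU = , ASP =
            if (tag == "0" && atom %in% c("OE1", "OD1")) "both"
            else "acceptor",
          ASN = , GLN = if (substr(atom, 1, 1) == "O") "acceptor" else "donor",
          TRP = "donor",
          "both")
      }
      n <- n + 1L
      rows[[n]] <- data.frame(
        residue = .residueLabel(resid, a$resno[i]), resid = resid,
        resno = a$resno[i], chain = a$chain[i], atom = atom, role = role,
        x = a$x[i], y = a$y[i], z = a$z[i], stringsAsFactors = FALSE)
    }
    if (n == 0L)
      return(data.frame(residue = character(0), resid = character(0),
                        resno = integer(0), chain = character(0),
                        atom = character(0), role = character(0),
                        x = numeric(0), y = numeric(0), z = numeric(0)))
    out <- do.call(rbind, rows[seq_len(n)])
    rownames(out) <- NULL
    out
  })

#' Build a hydrogen-bond site graph
#'
#' Connects every donor-capable/acceptor-capable pair of sites belonging
#' to different residues whose heavy-atom distance is at most `cutoff`.
#' A `"both"` site counts as donor and acceptor; water oxygens are
#' ordinary nodes, so a water-mediated contact costs one hop per water.
#' No donor-H-acceptor angle term is applied: the criterion is
#' distance-level only.
#'
#' @param x a site data.frame from [assignSites()].
#' @param cutoff heavy-atom distance cutoff, angstrom (default 3.5).
#' @return A [SiteGraph-class].
#' @examples
#' s <- genStructure(seed = 1)$structure
#' g <- buildGraph(assignSites(s))
#' @export
setMethod("buildGraph", "data.frame", function(x, cutoff = 3.5, ...) {
  if (cutoff <= 0) stop("cutoff must be positive")
  need <- c("residue", "atom", "role", "x", "y", "z")
  stopifnot(all(need %in% names(x)))
  n <- nrow(x)
  edges <- data.frame(i = integer(0), j = integer(0), distance = numeric(0))
  if (n >= 2L) {
    xyz <- as.matrix(x[, c("x", "y", "z")])
    donor <- x$role %in% c("donor", "both")
    acceptor <- x$role %in% c("acceptor", "both")
    pairs <- which(upper.tri(matrix(TRUE, n, n)), arr.ind = TRUE)
    i <- pairs[, 1]; j <- pairs[, 2]
    ok <- x$residue[i] != x$residue[j] &
      ((donor[i] & acceptor[j]) | (donor[j] & acceptor[i]))
    d <- sqrt(rowSums((xyz[i, , drop = FALSE] - xyz[j, , drop = FALSE])^2))
    ok <- ok & d <= cutoff
    edges <- data.frame(i = i[ok], j = j[ok], distance = d[ok])
  }
  new("SiteGraph", sites = x, edges = edges, cutoff = cutoff)
})

#' @describeIn SiteGraph-accessors site table
#' @export
siteTable <- function(x) {
  stopifnot(is(x, "SiteGraph"))
  x@sites
}

#' Accessors and helpers for SiteGraph
#'
#' `siteTable()` and `edgeTable()` return the node and edge tables;
#' `dropResidues()` removes residues (with their edges), e.g. to model a
#' Y266F mutation that abolishes the tyrosine hydroxyl.
#'
#' @param x a [SiteGraph-class].
#' @param residues residue labels to remove.
#' @name SiteGraph-accessors
NULL

#' @rdname SiteGraph-accessors
#' @export
edgeTable <- function(x) {
  stopifnot(is(x, "SiteGraph"))
  e <- x@edges
  data.frame(residueA = x@sites$residue[e$i], atomA = x@sites$atom[e$i],
             residueB = x@sites$residue[e$j], atomB = x@sites$atom[e$j],
             distance = e$distance)
}

#' @rdname SiteGraph-accessors
#' @export
dropResidues <- function(x, residues) {
  stopifnot(is(x, "SiteGraph"))
  keep <- !(x@sites$residue %in% residues)
  buildGraph(x@sites[keep, , drop = FALSE], cutoff = x@cutoff)
}

setMethod("show", "SiteGraph", function(object) {
  cat("SiteGraph:", nrow(object@sites), "sites over",
      length(unique(object@sites$residue)), "residues;",
      nrow(object@edges), "edges at cutoff", object@cutoff, "A\n")
})

# min distance between the functional-group atoms of two residue groups
.groupDistance <- function(xyzA, xyzB) {
  d2 <- outer(rowSums(xyzA^2), rowSums(xyzB^2), "+") -
    2 * xyzA %*% t(xyzB)
  sqrt(max(0, min(d2)))
}

#' Detect Y-R-E and R-E-R proton-transfer triads
#'
#' Scans residue triples for the tyrosine-arginine-glutamate (or
#' aspartate) motif and the arginine-glutamate/aspartate-arginine motif,
#' recurring arrangements in proton-conducting proteins. A triple is a
#' triad when all three pairwise functional-group distances (minimum over
#' the side-chain functional atoms: Tyr OH; Arg NE/NH1/NH2; Glu OE1/OE2;
#' Asp OD1/OD2) are within `window`. The default 6 angstrom window admits
#' the 5.1-5.4 angstrom arginine-N-to-carboxylate-O spacings seen in
#' voltage-sensor and bacteriorhodopsin triads. Enlarging the window never
#' removes a triad.
#'
#' @param x a [SiteGraph-class] or a site data.frame from
#'   [assignSites()].
#' @param window maximum pairwise functional-group distance, angstrom.
#' @return data.frame with columns `pattern` (`"YRE"` or `"RER"`), the
#'   three residue labels `res1`, `res2`, `res3` (YRE in Y, R, E/D order;
#'   RER with the two arginines first and last, lexicographically
#'   ordered) and the pairwise distances `d12`, `d13`, `d23`. Zero rows
#'   when no triad is present.
#' @export
setMethod("findTriads", "SiteGraph", function(x, window = 6.0, ...) {
  findTriads(x@sites, window = window)
})

#' @rdname findTriads-SiteGraph-method
#' @export
setMethod("findTriads", "data.frame", function(x, window = 6.0, ...) {
  if (window <= 0) stop("window must be positive")
  fun <- x[x$resid %in% c("TYR", "ARG", "GLU", "ASP") &
             mapply(function(r, a) a %in% .functionalAtoms[[r]],
                    x$resid, x$atom), , drop = FALSE]
  empty <- data.frame(pattern = character(0), res1 = character(0),
                      res2 = character(0), res3 = character(0),
                      d12 = numeric(0), d13 = numeric(0), d23 = numeric(0))
  if (nrow(fun) == 0L) return(empty)
  labs <- unique(fun$residue)
  kind <- vapply(labs, function(l) fun$resid[fun$residue == l][1], character(1))
  xyz <- lapply(labs, function(l)
    as.matrix(fun[fun$residue == l, c("x", "y", "z"), drop = FALSE]))
  names(xyz) <- labs
  dmat <- matrix(Inf, length(labs), length(labs), dimnames = list(labs, labs))
  if (length(labs) >= 2L)
    for (i in seq_len(length(labs) - 1L))
      for (j in seq(i + 1L, length(labs)))
        dmat[i, j] <- dmat[j, i] <-
          .groupDistance(xyz[[i]], xyz[[j]])

  ys <- labs[kind == "TYR"]; rs <- labs[kind == "ARG"]
  es <- labs[kind %in% c("GLU", "ASP")]
  out <- list()
  for (y in ys) for (r in rs) for (e in es) {
    d <- c(dmat[y, r], dmat[y, e], dmat[r, e])
    if (all(d <= window))
      out[[length(out) + 1L]] <- data.frame(
        pattern = "YRE", res1 = y, res2 = r, res3 = e,
        d12 = d[1], d13 = d[2], d23 = d[3], stringsAsFactors = FALSE)
  }
  if (length(rs) >= 2L)
    for (a in seq_len(length(rs) - 1L)) for (b in seq(a + 1L, length(rs)))
      for (e in es) {
        r1 <- sort(c(rs[a], rs[b]))
        d <- c(dmat[r1[1], e], dmat[r1[1], r1[2]], dmat[e, r1[2]])
        if (all(d <= window))
          out[[length(out) + 1L]] <- data.frame(
            pattern = "RER", res1 = r1[1], res2 = e, res3 = r1[2],
            d12 = d[1], d13 = d[2], d23 = d[3], stringsAsFactors = FALSE)
      }
  if (length(out) == 0L) return(empty)
  res <- do.call(rbind, out)
  res <- res[order(res$pattern, res$res1, res$res2, res$res3), , drop = FALSE]
  rownames(res) <- NULL
  res
})

#' Enumerate candidate proton paths between residues
#'
#' Collapses the site graph to residue level (two residues are adjacent
#' when any of their sites share an edge) and enumerates all simple paths
#' -- no residue revisited -- from `from` to `to` with at most `maxHops`
#' edges. Each water molecule is one node, hence one hop. Paths are
#' returned in lexicographic order of their residue sequence, so the
#' result is independent of site insertion order.
#'
#' @param x a [SiteGraph-class].
#' @param from,to residue labels; both must have sites in the graph.
#' @param maxHops maximum number of edges per path.
#' @return List of character vectors, each a residue-level path from
#'   `from` to `to`. Use [formatPaths()] for a printable form.
#' @examples
#' g <- buildGraph(assignSites(genStructure(seed = 1)$structure))
#' enumeratePaths(g, "R303", "E183")
#' @export
setMethod("enumeratePaths", "SiteGraph",
  function(x, from, to, maxHops = 6L, ...) {
    resOf <- x@sites$residue
    labs <- sort(unique(resOf))
    if (!(from %in% labs)) stop("residue not in graph: ", from)
    if (!(to %in% labs)) stop("residue not in graph: ", to)
    eRes <- unique(data.frame(a = pmin(resOf[x@edges$i], resOf[x@edges$j]),
                              b = pmax(resOf[x@edges$i], resOf[x@edges$j])))
    eRes <- eRes[eRes$a != eRes$b, , drop = FALSE]
    g <- igraph::graph_from_data_frame(
      eRes, directed = FALSE,
      vertices = data.frame(name = labs))
    paths <- igraph::all_simple_paths(g, from = from, to = to,
                                      cutoff = maxHops)
    paths <- lapply(paths, function(p) igraph::as_ids(p))
    paths[order(vapply(paths, paste, character(1), collapse = "->"))]
  })

#' Format residue-level paths for display
#'
#' @param paths list of residue paths from [enumeratePaths()].
#' @return Character vector, one `"A->B->C"` string per path.
#' @export
formatPaths <- function(paths) {
  vapply(paths, paste, character(1), collapse = "->")
}
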