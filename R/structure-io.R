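#' Read a structure from a PDB file
#'
#' Parses ATOM and HETATM records into a [ChargedStructure-class] with
#' charges unattached. The membrane frame is set with z as the membrane
#' normal (increasing extracellular) and the origin at the minimum z of
#' the structure. Alternate locations are resolved by keeping the
#' highest-occupancy conformer (ties: first encountered).
#'
#' @param path path to a PDB file.
#' @return A [ChargedStructure-class]; `charge` is `NA` for every atom.
#' @seealso [attachCharges()], [writeStructure()]
#' @export
readStructure <- function(path) {
  if (!file.exists(path)) stop("cannot read PDB file: ", path)
  pdb <- tryCatch(bio3d::read.pdb(path, verbose = FALSE),
                  error = function(e) stop("cannot parse PDB file: ",
                                           conditionMessage(e)))
  at <- pdb$atom
  if (is.null(at) || nrow(at) == 0L)
    stop("empty structure: no ATOM/HETATM records in ", path)

  # altloc: keep highest occupancy per (chain, resno, insert, elety); tie ->
  # first encountered record order
  alt <- at$alt
  alt[is.na(alt)] <- ""
  if (any(alt != "")) {
    key <- paste(at$chain, at$resno, at$insert, at$elety, sep = "|")
    occ <- at$o
    occ[is.na(occ)] <- 1
    keep <- rep(TRUE, nrow(at))
    for (k in unique(key[alt != ""])) {
      idx <- which(key == k)
      if (length(idx) > 1L) {
        best <- idx[which.max(occ[idx])]
        keep[setdiff(idx, best)] <- FALSE
      }
    }
    at <- at[keep, , drop = FALSE]
  }

  elem <- at$elesy
  bad <- is.na(elem) | elem == ""
  if (any(bad)) elem[bad] <- substr(gsub("[^A-Za-z].*", "", at$elety[bad]), 1, 1)

  atomsDf <- data.frame(
    serial  = as.integer(at$eleno),
    elety   = as.character(at$elety),
    element = toupper(as.character(elem)),
    resid   = as.character(at$resid),
    resno   = as.integer(at$resno),
    chain   = as.character(at$chain),
    x = as.numeric(at$x), y = as.numeric(at$y), z = as.numeric(at$z),
    charge = NA_real_,
    stringsAsFactors = FALSE
  )
  atomsDf$chain[is.na(atomsDf$chain)] <- " "
  new("ChargedStructure", atoms = atomsDf,
      frame = list(origin = min(atomsDf$z),
                   note = "z = membrane normal, increasing extracellular"))
}

#' Write a structure to a PDB file
#'
#' Coordinates are written at standard PDB precision (3 decimals), so a
#' read-write-read round trip preserves atom count, names and coordinates.
#'
#' @param x a [ChargedStructure-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeStructure <- function(x, path) {
  stopifnot(is(x, "ChargedStructure"))
  a <- x@atoms
  n <- nrow(a)
  water <- a$resid %in% c("HOH", "WAT", "TIP", "SOL")
  bio3d::write.pdb(
    file = path,
    xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
    type = ifelse(water, "HETATM", "ATOM"),
    eleno = a$serial, elety = a$elety, resid = a$resid,
    chain = ifelse(a$chain == " ", "", a$chain), resno = a$resno,
    o = rep(1, n), b = rep(0, n), elesy = a$element
  )
  invisible(path)
}

#' Read an atomic partial-charge table
#'
#' Two-column delimited text (atom serial, charge in elementary-charge
#' units); serials must match the PDB serials. A header line is detected
#' and skipped automatically.
#'
#' @param path path to a TSV/CSV charge table.
#' @param sep field separator (default: any whitespace).
#' @return data.frame with columns `serial` and `charge`.
#' @seealso [attachCharges()]
#' @export
readChargeTable <- function(path, sep = "") {
  if (!file.exists(path)) stop("cannot read charge table: ", path)
  first <- readLines(path, n = 1L)
  hasHeader <- grepl("[A-Za-z]", first)
  tb <- utils::read.table(path, header = hasHeader, sep = sep,
                          stringsAsFactors = FALSE)
  if (ncol(tb) < 2L) stop("charge table needs two columns (serial, charge)")
  data.frame(serial = as.integer(tb[[1]]), charge = as.numeric(tb[[2]]))
}

#' Attach partial charges to a structure
#'
#' Every atom serial in the structure must appear in the table exactly
#' once; missing serials raise a mapping error naming the serial, and
#' duplicated serials raise an ambiguity error. Attachment is independent
#' of the row order of the table.
#'
#' @param x a [ChargedStructure-class].
#' @param table data.frame with columns `serial` and `charge` (e), a named
#'   numeric vector keyed by serial, or a file path readable by
#'   [readChargeTable()].
#' @return `x` with per-atom charges set; [netCharge()] gives their sum.
#' @examples
#' s <- genStructure(nAtoms = 50, seed = 1)$structure
#' netCharge(s)
#' @export
setMethod("attachCharges", "ChargedStructure", function(x, table, ...) {
  if (is.character(table) && length(table) == 1L)
    table <- readChargeTable(table)
  if (is.numeric(table) && !is.null(names(table)))
    table <- data.frame(serial = as.integer(names(table)), charge = unname(table))
  stopifnot(is.data.frame(table), all(c("serial", "charge") %in% names(table)))
  dup <- table$serial[duplicated(table$serial)]
  if (length(dup))
    stop("ambiguous charge table: duplicated serial(s) ",
         paste(unique(dup), collapse = ", "))
  idx <- match(x@atoms$serial, table$serial)
  if (anyNA(idx))
    stop("no charge for atom serial(s) ",
         paste(x@atoms$serial[is.na(idx)], collapse = ", "))
  x@atoms$charge <- table$charge[idx]
  validObject(x)
  x
})

#' Select a subset of a structure
#'
#' Subsets by chain, residue number and/or residue name, preserving atom
#' order and carrying the membrane frame over unchanged. Selections may
#' also be given as a compact string such as `"chain:A,resi:290-310"`.
#'
#' @param x a [ChargedStructure-class].
#' @param chain chain identifiers to keep (optional).
#' @param resno residue numbers to keep (vector, optional).
#' @param resid residue names to keep (optional).
#' @param selection compact selection string, comma-separated
#'   `chain:`/`resi:`/`resn:` clauses; `resi` accepts `a-b` ranges.
#' @return The selected [ChargedStructure-class]; an empty selection is an
#'   error.
#' @examples
#' s <- genStructure(seed = 1)$structure
#' motif <- selectRegion(s, resno = 183)
#' @export
setMethod("selectRegion", "ChargedStructure",
  function(x, chain = NULL, resno = NULL, resid = NULL, selection = NULL, ...) {
    if (!is.null(selection)) {
      for (clause in strsplit(selection, ",", fixed = TRUE)[[1]]) {
        kv <- strsplit(trimws(clause), ":", fixed = TRUE)[[1]]
        if (length(kv) != 2L) stop("malformed selection clause: ", clause)
        val <- kv[2]
        switch(kv[1],
          chain = { chain <- c(chain, val) },
          resi = {
            if (grepl("-", val, fixed = TRUE)) {
              ab <- as.integer(strsplit(val, "-", fixed = TRUE)[[1]])
              resno <- c(resno, seq(ab[1], ab[2]))
            } else resno <- c(resno, as.integer(val))
          },
          resn = { resid <- c(resid, val) },
          stop("unknown selection key: ", kv[1])
        )
      }
    }
    keep <- rep(TRUE, nrow(x@atoms))
    if (!is.null(chain)) keep <- keep & x@atoms$chain %in% chain
    if (!is.null(resno)) keep <- keep & x@atoms$resno %in% resno
    if (!is.null(resid)) keep <- keep & x@atoms$resid %in% resid
    if (!any(keep)) stop("empty selection")
    x@atoms <- x@atoms[keep, , drop = FALSE]
    rownames(x@atoms) <- NULL
    x
  })

#' @describeIn ChargedStructure-accessors atom table of the structure
#' @export
setMethod("atoms", "ChargedStructure", function(x) x@atoms)

#' @describeIn ChargedStructure-accessors number of atoms
#' @export
setMethod("nAtoms", "ChargedStructure", function(x) nrow(x@atoms))

#' Accessors for ChargedStructure
#'
#' `atoms()` returns the atom table, `nAtoms()` the atom count,
#' `netCharge()` the arithmetic sum of attached partial charges (e), and
#' `membraneFrame()` the frame metadata.
#'
#' @param x a [ChargedStructure-class].
#' @name ChargedStructure-accessors
NULL

#' @describeIn ChargedStructure-accessors net charge (e); errors if charges
#'   are unattached
#' @export
setMethod("netCharge", "ChargedStructure", function(x) {
  ch <- x@atoms$charge
  if (anyNA(ch)) stop("charges not attached; see attachCharges()")
  sum(ch)
})

#' @rdname ChargedStructure-accessors
#' @export
membraneFrame <- function(x) {
  stopifnot(is(x, "ChargedStructure"))
  x@frame
}

setMethod("show", "ChargedStructure", function(object) {
  a <- object@atoms
  cat("ChargedStructure with", nrow(a), "atoms,",
      length(unique(paste(a$chain, a$resno))), "residues\n")
  cat("  z range: [", round(min(a$z), 2), ",", round(max(a$z), 2),
      "] A (origin ", round(object@frame$origin, 2), ")\n", sep = "")
  if (anyNA(a$charge)) cat("  charges: unattached\n")
  else cat("  net charge:", format(sum(a$charge), digits = 6), "e\n")
})
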