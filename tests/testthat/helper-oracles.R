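# Independent brute-force oracles used across the suite. These deliberately
# re-derive results with the simplest possible code paths.

# per-slab charge sums by explicit filter-and-sum
bruteSlabSums <- function(z, q, z0, thickness, nSlabs) {
  vapply(seq_len(nSlabs), function(k) {
    lo <- z0 + (k - 1) * thickness
    hi <- z0 + k * thickness
    sum(q[z >= lo & z < hi])
  }, numeric(1))
}

# all simple paths by recursive depth-first enumeration on an adjacency list
dfsPaths <- function(adj, from, to, maxHops) {
  out <- list()
  walk <- function(node, visited) {
    if (node == to) {
      out[[length(out) + 1L]] <<- visited
      return(invisible())
    }
    if (length(visited) - 1L >= maxHops) return(invisible())
    for (nb in adj[[node]])
      if (!(nb %in% visited)) walk(nb, c(visited, nb))
  }
  walk(from, from)
  out[order(vapply(out, paste, character(1), collapse = "->"))]
}

# random site cloud: one site per pseudo-residue with random role
randomSiteCloud <- function(n, span = 10) {
  data.frame(
    residue = sprintf("X%03d", seq_len(n)),
    resid = "XXX", resno = seq_len(n), chain = "A", atom = "O",
    role = sample(c("donor", "acceptor", "both"), n, replace = TRUE),
    x = runif(n, 0, span), y = runif(n, 0, span), z = runif(n, 0, span),
    stringsAsFactors = FALSE)
}

# residue adjacency of a site cloud by brute-force all-pairs filtering
bruteResidueAdjacency <- function(sites, cutoff) {
  labs <- sort(unique(sites$residue))
  adj <- setNames(lapply(labs, function(...) character(0)), labs)
  n <- nrow(sites)
  for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
    if (sites$residue[i] == sites$residue[j]) next
    di <- sqrt(sum((sites[i, c("x", "y", "z")] - sites[j, c("x", "y", "z")])^2))
    donorI <- sites$role[i] %in% c("donor", "both")
    donorJ <- sites$role[j] %in% c("donor", "both")
    accI <- sites$role[i] %in% c("acceptor", "both")
    accJ <- sites$role[j] %in% c("acceptor", "both")
    if (di <= cutoff && ((donorI && accJ) || (donorJ && accI))) {
      a <- sites$residue[i]; b <- sites$residue[j]
      adj[[a]] <- union(adj[[a]], b)
      adj[[b]] <- union(adj[[b]], a)
    }
  }
  adj
}

# write a small PDB text fixture by hand (fixed-width records)
writeTinyPdb <- function(path, atoms) {
  lines <- character(nrow(atoms))
  for (i in seq_len(nrow(atoms))) {
    a <- atoms[i, ]
    lines[i] <- sprintf(
      "%-6s%5d %-4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      a$type, a$serial, a$elety, "", a$resid, a$chain, a$resno, "",
      a$x, a$y, a$z, 1.0, 0.0, a$element)
  }
  writeLines(c(lines, "END"), path)
  path
}
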