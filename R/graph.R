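# Molecular graphs from canonical SMILES.
#
# Bond topology comes from Open Babel's V2000 MOL/SDF export (kekulized
# orders 1/2/3, atom order identical to the SMILES atom order); atom
# identity, aromatic flags, bracket hydrogens and charges come from the
# SMILES tokens. The SDF text is parsed directly (a batch conversion
# plus fixed-width field extraction), and ring perception is done
# in-package, so the per-molecule cost stays low enough for the
# optimizer's child volumes.

# standard SMILES implicit valences, smallest first
.dg_valences <- list(
  B = 3L, C = 4L, N = c(3L, 5L), O = 2L, P = c(3L, 5L),
  S = c(2L, 4L, 6L), F = 1L, Cl = 1L, Br = 1L, I = 1L
)

std_valence <- function(element, bondsum) {
  v <- .dg_valences[[element]]
  if (is.null(v)) return(NA_integer_)
  fit <- v[v >= bondsum]
  if (length(fit) == 0L) NA_integer_ else fit[1L]
}

# Batch-convert valid canonical SMILES to V2000 blocks and extract
# (element vector, bond matrix) per molecule.
ob_mol_blocks <- function(smiles) {
  noopt <- data.frame(names = character(0), args = character(0))
  txt <- ChemmineOB::convertFormat("SMI", "SDF",
                                   source = paste(smiles, collapse = "\n"),
                                   options = noopt)
  blocks <- strsplit(txt, "\\$\\$\\$\\$\n?")[[1L]]
  blocks <- blocks[nzchar(trimws(blocks))]
  if (length(blocks) != length(smiles)) {
    stop("SDF conversion returned ", length(blocks), " blocks for ",
         length(smiles), " molecules")
  }
  lapply(blocks, function(b) {
    lines <- strsplit(b, "\n", fixed = TRUE)[[1L]]
    # counts line is the first line matching the V2000 header layout
    hdr <- grep("V2000\\s*$", lines)[1L]
    if (is.na(hdr)) stop("no V2000 counts line in SDF block")
    natoms <- as.integer(substr(lines[hdr], 1L, 3L))
    nbonds <- as.integer(substr(lines[hdr], 4L, 6L))
    at_lines <- lines[(hdr + 1L):(hdr + natoms)]
    elem <- trimws(substr(at_lines, 32L, 34L))
    bonds <- if (nbonds > 0L) {
      bd_lines <- lines[(hdr + natoms + 1L):(hdr + natoms + nbonds)]
      cbind(a1 = as.integer(substr(bd_lines, 1L, 3L)),
            a2 = as.integer(substr(bd_lines, 4L, 6L)),
            order = as.integer(substr(bd_lines, 7L, 9L)))
    } else {
      cbind(a1 = integer(0), a2 = integer(0), order = integer(0))
    }
    list(elem = elem, bonds = bonds)
  })
}

build_graph <- function(smiles, block) {
  atoms <- smiles_atoms(smiles)
  n <- nrow(atoms)
  if (n == 0L) stop("SMILES has no atoms: ", smiles)
  if (length(block$elem) != n || !all(block$elem == atoms$element)) {
    stop("atom mismatch between SMILES and MOL block for: ", smiles)
  }
  bonds <- data.frame(a1 = block$bonds[, 1L], a2 = block$bonds[, 2L],
                      order = pmin(block$bonds[, 3L], 3L))
  bondsum <- integer(n); degree <- integer(n)
  if (nrow(bonds) > 0L) {
    ends <- c(bonds$a1, bonds$a2)
    ords <- rep(bonds$order, 2L)
    for (k in seq_along(ends)) {
      bondsum[ends[k]] <- bondsum[ends[k]] + ords[k]
    }
    degree <- tabulate(ends, nbins = n)
  }
  hyd <- integer(n); rad <- integer(n)
  for (k in seq_len(n)) {
    eff <- std_valence(atoms$element[k], bondsum[k])
    eff <- if (is.na(eff)) bondsum[k] else eff
    chg <- atoms$charge[k]
    if (chg != 0L) {
      # cations of N/O/S/P gain a bond, anions lose one; B/C lose either way
      eff <- eff + if (atoms$element[k] %in% c("N", "O", "S", "P")) chg else
        -abs(chg)
    }
    eff <- max(eff, bondsum[k])
    if (atoms$bracket[k]) {
      hyd[k] <- atoms$hcount[k]
      if (is.na(hyd[k])) hyd[k] <- 0L
      rad[k] <- max(0L, eff - hyd[k] - bondsum[k])
    } else {
      hyd[k] <- max(0L, eff - bondsum[k])
    }
  }
  n_comp <- graph_components(n, bonds)
  list(
    smiles = smiles, atoms = atoms, bonds = bonds,
    bondsum = bondsum, degree = degree, hydrogens = hyd,
    radical_electrons = rad, n_components = n_comp
  )
}

graph_components <- function(n, bonds) {
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (nrow(bonds) > 0L) {
    for (k in seq_len(nrow(bonds))) {
      ri <- find(bonds$a1[k]); rj <- find(bonds$a2[k])
      if (ri != rj) parent[ri] <- rj
    }
  }
  length(unique(vapply(seq_len(n), find, integer(1))))
}

# Graphs for a batch of valid canonical SMILES (one SDF conversion).
mol_graphs <- function(smiles) {
  if (length(smiles) == 0L) return(list())
  blocks <- ob_mol_blocks(smiles)
  lapply(seq_along(smiles), function(i) build_graph(smiles[i], blocks[[i]]))
}

# --- ring perception --------------------------------------------------------

# Smallest-rings set, SSSR-style. The cyclic core is isolated by pruning
# degree-1 atoms; for every core bond the shortest cycle through it is
# found by breadth-first search with the bond removed; candidate cycles
# are then accepted smallest-first while they cover new bonds, up to the
# cyclomatic count.
ring_set <- function(graph, max_size = 12L) {
  n_ring <- nrow(graph$bonds) - nrow(graph$atoms) + graph$n_components
  if (n_ring <= 0L) return(list())
  n <- nrow(graph$atoms)
  deg <- graph$degree
  alive <- rep(TRUE, n)
  adj <- vector("list", n)
  for (k in seq_len(nrow(graph$bonds))) {
    i <- graph$bonds$a1[k]; j <- graph$bonds$a2[k]
    adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
  }
  # prune tree branches
  repeat {
    leaves <- which(alive & vapply(seq_len(n), function(i) {
      sum(alive[adj[[i]]]) <= 1L
    }, logical(1)))
    if (length(leaves) == 0L) break
    alive[leaves] <- FALSE
  }
  core_bonds <- which(alive[graph$bonds$a1] & alive[graph$bonds$a2])
  if (length(core_bonds) == 0L) return(list())
  cycles <- list()
  seen <- character(0)
  for (k in core_bonds) {
    u <- graph$bonds$a1[k]; v <- graph$bonds$a2[k]
    # BFS from u to v avoiding bond k, within the core
    prev <- rep(NA_integer_, n)
    dist <- rep(NA_integer_, n)
    dist[u] <- 0L
    queue <- u
    while (length(queue) > 0L && is.na(dist[v])) {
      cur <- queue[1L]; queue <- queue[-1L]
      if (dist[cur] >= max_size - 1L) next
      for (nb in adj[[cur]]) {
        if (!alive[nb] || !is.na(dist[nb])) next
        if ((cur == u && nb == v) || (cur == v && nb == u)) next
        dist[nb] <- dist[cur] + 1L
        prev[nb] <- cur
        queue <- c(queue, nb)
      }
    }
    if (is.na(dist[v])) next
    path <- v
    while (path[1L] != u) path <- c(prev[path[1L]], path)
    key <- paste(sort(path), collapse = "-")
    if (!(key %in% seen)) {
      seen <- c(seen, key)
      cycles[[length(cycles) + 1L]] <- path
    }
  }
  if (length(cycles) == 0L) return(list())
  arom <- graph$atoms$aromatic
  ord <- order(vapply(cycles, length, integer(1)))
  covered <- character(0)
  keep <- list()
  for (i in ord) {
    at <- cycles[[i]]
    cyc <- cbind(at, c(at[-1L], at[1L]))
    keys <- apply(cyc, 1L, function(p) paste(sort(p), collapse = "-"))
    if (any(!(keys %in% covered))) {
      covered <- union(covered, keys)
      keep[[length(keep) + 1L]] <- list(atoms = at,
                                        aromatic = all(arom[at]))
      if (length(keep) == n_ring) break
    }
  }
  keep
}
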