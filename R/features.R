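# Featurization: 17 molecular descriptors, 2048-bit path fingerprint,
# 167 MACCS-key slots, and the 2232-long combined feature vector.
#
# All quantities are memoized per canonical SMILES in a package-local
# cache; the CSA optimizer re-scores many recurring molecules and the
# cache is what keeps that affordable. Cached values are pure functions
# of the canonical SMILES, so memoization never changes a result.

.dg_cache <- new.env(parent = emptyenv())

#' Clear the per-session feature cache
#'
#' Descriptors, fingerprints and QED values are memoized by canonical
#' SMILES. The cache only ever stores pure functions of the structure, so
#' clearing it affects speed, not results.
#' @return invisibly, the number of entries dropped.
#' @export
clear_feature_cache <- function() {
  n <- length(ls(.dg_cache))
  rm(list = ls(.dg_cache), envir = .dg_cache)
  rm(list = ls(.dg_canon_memo), envir = .dg_canon_memo)
  rm(list = ls(.dg_valid_memo), envir = .dg_valid_memo)
  invisible(n)
}

.dg_desc_names <- c(
  "hbd", "hba", "rotatable_bonds", "rings", "radicals", "heteroatoms",
  "heterocycles", "lipinski_hba", "lipinski_hbd", "aromatic_carbocycles",
  "aromatic_heterocycles", "amide_bonds", "aliphatic_carbocycles",
  "aliphatic_heterocycles", "fraction_csp3", "labute_asa", "tpsa"
)

.dg_rotatable_smarts <- "[!$(*#*)&!D1]-!@[!$(*#*)&!D1]"
.dg_amide_smarts <- "C(=O)N"

# Bondi van der Waals radii (Angstrom)
.dg_rvdw <- c(H = 1.20, B = 1.92, C = 1.70, N = 1.55, O = 1.52, F = 1.47,
              P = 1.80, S = 1.80, Cl = 1.75, Br = 1.85, I = 1.98)
# covalent radii (Angstrom)
.dg_rcov <- c(H = 0.31, B = 0.84, C = 0.76, N = 0.71, O = 0.66, F = 0.57,
              P = 1.07, S = 1.05, Cl = 1.02, Br = 1.20, I = 1.39)

vdw_radius <- function(el) ifelse(is.na(.dg_rvdw[el]), 1.70, .dg_rvdw[el])
cov_radius <- function(el) ifelse(is.na(.dg_rcov[el]), 0.77, .dg_rcov[el])

# Labute-style approximate accessible surface area (Angstrom^2):
# van der Waals spheres with spherical caps removed for each bonded
# neighbor (including implicit hydrogens), bond lengths approximated
# from covalent radii shortened per bond order.
labute_asa <- function(graph) {
  el <- graph$atoms$element
  n <- length(el)
  rv <- vdw_radius(el)
  rc <- cov_radius(el)
  area <- 4 * pi * rv^2
  cap <- function(Ri, Rj, d) {
    d <- min(max(d, abs(Ri - Rj) + 1e-6), Ri + Rj)
    max(0, pi * Ri * (2 * Ri - d - (Ri^2 - Rj^2) / d))
  }
  if (nrow(graph$bonds) > 0L) {
    for (k in seq_len(nrow(graph$bonds))) {
      i <- graph$bonds$a1[k]; j <- graph$bonds$a2[k]
      d <- (rc[i] + rc[j]) * (1 - 0.07 * (graph$bonds$order[k] - 1L))
      area[i] <- area[i] - cap(rv[i], rv[j], d)
      area[j] <- area[j] - cap(rv[j], rv[i], d)
    }
  }
  h_area <- 0
  rvH <- .dg_rvdw[["H"]]
  for (k in seq_len(n)) {
    nh <- graph$hydrogens[k]
    if (nh > 0L) {
      d <- rc[k] + .dg_rcov[["H"]]
      area[k] <- area[k] - nh * cap(rv[k], rvH, d)
      h_area <- h_area + nh * max(0, 4 * pi * rvH^2 - cap(rvH, rv[k], d))
    }
  }
  sum(pmax(area, 0)) + h_area
}

# Full property table for a batch of valid canonical SMILES: the 17
# descriptors plus mw, logp and aromatic_rings (needed by QED, the
# Lipinski profile and the pseudo-docking oracle).
property_table <- function(canon) {
  refs <- cached_refs(canon)
  props <- ob_props(refs)
  graphs <- cached_graphs(canon)
  rot <- ob_smarts_count(refs, .dg_rotatable_smarts)
  ami <- ob_smarts_count(refs, .dg_amide_smarts)
  n <- length(canon)
  out <- matrix(0, nrow = n, ncol = 20L,
                dimnames = list(NULL, c(.dg_desc_names, "mw", "logp",
                                        "aromatic_rings")))
  for (i in seq_len(n)) {
    g <- graphs[[i]]
    rs <- ring_set(g)
    el <- g$atoms$element
    arom_atom <- g$atoms$aromatic
    ring_arom <- vapply(rs, function(r) r$aromatic, logical(1))
    ring_het <- vapply(rs, function(r) any(!el[r$atoms] %in% "C"), logical(1))
    is_c <- el == "C"
    sp3_c <- is_c & !arom_atom & g$bondsum == g$degree
    n_o <- el %in% c("N", "O")
    out[i, "hbd"] <- props$HBD[i]
    out[i, "hba"] <- props$HBA2[i]
    out[i, "rotatable_bonds"] <- rot[i]
    out[i, "rings"] <- nrow(g$bonds) - nrow(g$atoms) + g$n_components
    out[i, "radicals"] <- sum(g$radical_electrons > 0L)
    out[i, "heteroatoms"] <- sum(!el %in% c("C", "H"))
    out[i, "heterocycles"] <- sum(ring_het)
    out[i, "lipinski_hba"] <- sum(n_o)
    out[i, "lipinski_hbd"] <- sum(g$hydrogens[n_o])
    out[i, "aromatic_carbocycles"] <- sum(ring_arom & !ring_het)
    out[i, "aromatic_heterocycles"] <- sum(ring_arom & ring_het)
    out[i, "amide_bonds"] <- ami[i]
    out[i, "aliphatic_carbocycles"] <- sum(!ring_arom & !ring_het)
    out[i, "aliphatic_heterocycles"] <- sum(!ring_arom & ring_het)
    out[i, "fraction_csp3"] <- if (sum(is_c) > 0L) sum(sp3_c) / sum(is_c) else 0
    out[i, "labute_asa"] <- labute_asa(g)
    out[i, "tpsa"] <- props$TPSA[i]
    out[i, "mw"] <- props$MW[i]
    out[i, "logp"] <- props$logP[i]
    out[i, "aromatic_rings"] <- sum(ring_arom)
  }
  out
}

# Fetch (and compute as needed) a named field for canonical SMILES, using
# the cache. `compute` is called with the subset of SMILES lacking the
# field and must return a list (or matrix rows) aligned with its input.
cache_fetch <- function(canon, field, compute) {
  missing_idx <- which(!vapply(canon, function(s) {
    e <- get0(s, envir = .dg_cache)
    !is.null(e) && !is.null(e[[field]])
  }, logical(1)))
  if (length(missing_idx) > 0L) {
    todo <- unique(canon[missing_idx])
    vals <- compute(todo)
    for (k in seq_along(todo)) {
      e <- get0(todo[k], envir = .dg_cache)
      if (is.null(e)) e <- list()
      e[[field]] <- vals[[k]]
      assign(todo[k], e, envir = .dg_cache)
    }
  }
  lapply(canon, function(s) get0(s, envir = .dg_cache)[[field]])
}

cached_graphs <- function(canon) {
  cache_fetch(canon, "graph", function(todo) mol_graphs(todo))
}

# parsed OBMol references (kept alive by the cache for the session)
cached_refs <- function(canon) {
  cache_fetch(canon, "ref", function(todo) ob_refs(todo))
}

cached_properties <- function(canon) {
  rows <- cache_fetch(canon, "props", function(todo) {
    tab <- property_table(todo)
    lapply(seq_len(nrow(tab)), function(i) tab[i, ])
  })
  do.call(rbind, rows)
}

cached_pathfp <- function(canon) {
  cache_fetch(canon, "pathfp", function(todo) {
    lapply(cached_graphs(todo), path_fingerprint_bits)
  })
}

cached_maccs <- function(canon) {
  rows <- cache_fetch(canon, "maccs", function(todo) {
    refs <- cached_refs(todo)
    fp <- ChemmineOB::fingerprint_OB(refs, "MACCS")
    if (is.null(dim(fp))) fp <- matrix(fp, nrow = 1L)
    # Open Babel stores MACCS keys 1..166 at 1-based bit positions in a
    # 256-bit block; slot 0 of our 167-slot layout is always zero.
    m <- cbind(0L, fp[, 1:166, drop = FALSE])
    storage.mode(m) <- "integer"
    lapply(seq_len(nrow(m)), function(i) m[i, ])
  })
  mat <- do.call(rbind, rows)
  colnames(mat) <- paste0("maccs_", seq_len(167L) - 1L)
  mat
}

# Atom/bond labels for the path fingerprint: element symbol, lowercased
# when aromatic; bond labels ':' between two aromatic atoms, else the
# bond-order symbol.
path_fingerprint_bits <- function(graph, nbits = 2048L, max_len = 7L) {
  el <- graph$atoms$element
  arom <- graph$atoms$aromatic
  lab <- ifelse(arom, tolower(el), el)
  chg <- graph$atoms$charge
  lab <- paste0(lab, ifelse(chg > 0L, "+", ifelse(chg < 0L, "-", "")))
  nb <- nrow(graph$bonds)
  if (nb == 0L) return(integer(0))
  both_arom <- arom[graph$bonds$a1] & arom[graph$bonds$a2]
  blab <- c("-", "=", "#")[pmin(graph$bonds$order, 3L)]
  blab[both_arom] <- ":"
  sort(pathfp_bits(lab, graph$bonds$a1, graph$bonds$a2, blab,
                   as.integer(nbits), as.integer(max_len)))
}

dense_fp <- function(bits_list, nbits = 2048L, prefix = "fp_") {
  m <- matrix(0L, nrow = length(bits_list), ncol = nbits)
  for (i in seq_along(bits_list)) m[i, bits_list[[i]] + 1L] <- 1L
  colnames(m) <- paste0(prefix, seq_len(nbits) - 1L)
  m
}

# --- public featurize API ---------------------------------------------------

#' Compute the 17 molecular descriptors
#'
#' Descriptor block used in the feature vector, in fixed order: hydrogen
#' bond donors and acceptors, rotatable bonds, ring count, radical
#' centers, heteroatoms, heterocycles, Lipinski acceptors/donors (N+O
#' count and H on N/O), aromatic/aliphatic carbo- and heterocycles, amide
#' bonds, fraction of sp3 carbons, Labute approximate surface area and
#' topological polar surface area (both in square Angstrom).
#'
#' @param x character vector of SMILES, or a [molecule()].
#' @return data.frame with one row per molecule and 17 columns.
#' @examples
#' compute_descriptors("CCO")  # 1 donor, 1 acceptor
#' @export
compute_descriptors <- function(x) {
  canon <- as_canonical(x)
  tab <- cached_properties(canon)
  out <- as.data.frame(tab[, .dg_desc_names, drop = FALSE])
  rownames(out) <- NULL
  cbind(smiles = canon, out, stringsAsFactors = FALSE)
}

#' Compute path and MACCS fingerprints
#'
#' The path fingerprint hashes all linear bond paths of 1--7 bonds into
#' 2048 bits (two bits per path). The MACCS block has 167 slots: slot 0
#' is reserved (always 0) and slots 1--166 hold the 166 MACCS keys as
#' matched by Open Babel.
#'
#' @param x character vector of SMILES, or a [molecule()].
#' @return list with 0/1 integer matrices `path_fp` (n x 2048) and
#'   `maccs` (n x 167).
#' @export
compute_fingerprints <- function(x) {
  canon <- as_canonical(x)
  list(
    path_fp = dense_fp(cached_pathfp(canon)),
    maccs = cached_maccs(canon)
  )
}

#' Build the 2232-long feature vector
#'
#' Layout: positions 1--2048 the path fingerprint bits, 2049--2215 the
#' 167 MACCS slots, 2216--2232 the 17 descriptors in [compute_descriptors()]
#' order. Deterministic: the same canonical SMILES always yields the
#' identical vector.
#'
#' @param x character vector of SMILES, or a [molecule()].
#' @return numeric matrix, one row per molecule, 2232 columns.
#' @examples
#' dim(build_feature_vector("c1ccccc1"))  # 1 x 2232
#' @export
build_feature_vector <- function(x) {
  canon <- as_canonical(x)
  fps <- compute_fingerprints(canon)
  desc <- as.matrix(cached_properties(canon)[, .dg_desc_names, drop = FALSE])
  out <- cbind(fps$path_fp, fps$maccs, desc)
  storage.mode(out) <- "double"
  rownames(out) <- NULL
  out
}

#' Tanimoto similarity between two molecules
#'
#' Computed on the 2048-bit path fingerprint: |A and B| / |A or B|.
#' If both fingerprints are empty (no bonds, e.g. methane) the
#' similarity is defined as 0.
#'
#' @param a,b SMILES strings or [molecule()] objects.
#' @return similarity in \[0, 1\].
#' @examples
#' tanimoto_similarity("CCO", "CCO")  # 1
#' @export
tanimoto_similarity <- function(a, b) {
  ca <- as_canonical(a); cb <- as_canonical(b)
  bits <- cached_pathfp(c(ca, cb))
  tanimoto_bits(bits[[1]], bits[[2]])
}

tanimoto_bits <- function(a, b) {
  u <- length(union(a, b))
  if (u == 0L) return(0)
  length(intersect(a, b)) / u
}

# Similarity of each of `canon_a` against each of `canon_b`
# (dense matrix route; rows a, columns b).
tanimoto_cross <- function(canon_a, canon_b) {
  fa <- dense_fp(cached_pathfp(canon_a))
  fb <- dense_fp(cached_pathfp(canon_b))
  inter <- fa %*% t(fb)
  na <- rowSums(fa); nb <- rowSums(fb)
  un <- outer(na, nb, "+") - inter
  out <- ifelse(un == 0, 0, inter / un)
  out
}

#' Lipinski property profile
#'
#' The seven oral drug-likeness properties: molecular weight (Da), logP,
#' hydrogen-bond donors and acceptors, rotatable bonds, aromatic rings
#' and topological polar surface area (square Angstrom).
#'
#' @param x character vector of SMILES, or a [molecule()].
#' @return data.frame with columns `mw`, `logp`, `hbd`, `hba`,
#'   `rotatable`, `aromatic_rings`, `tpsa`.
#' @export
lipinski_profile <- function(x) {
  canon <- as_canonical(x)
  tab <- cached_properties(canon)
  data.frame(
    smiles = canon,
    mw = tab[, "mw"], logp = tab[, "logp"], hbd = tab[, "hbd"],
    hba = tab[, "hba"], rotatable = tab[, "rotatable_bonds"],
    aromatic_rings = tab[, "aromatic_rings"], tpsa = tab[, "tpsa"],
    stringsAsFactors = FALSE, row.names = NULL
  )
}
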