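.dg_canon_memo <- new.env(parent = emptyenv())

# un-memoized single conversion (also the path the idempotence checks use)
ob_canonicalize_one <- function(s) {
  res <- tryCatch(
    ChemmineOB::convertFormat("SMI", "CAN", source = s),
    error = function(e) ""
  )
  res <- sub("[ \t].*$", "", sub("\n.*$", "", res))
  if (!nzchar(res)) NA_character_ else res
}

#' Canonicalize SMILES strings
#'
#' Parses each SMILES with Open Babel (via ChemmineOB), perceives
#' aromaticity and emits the canonical form. Canonicalization is
#' idempotent: `canonicalize_smiles(canonicalize_smiles(s))` equals
#' `canonicalize_smiles(s)`.
#'
#' @param x character vector of SMILES strings.
#' @param strict if `TRUE`, unparseable input raises an error; otherwise
#'   it yields `NA_character_` (batch mode: log and skip).
#' @return character vector of canonical SMILES, `NA` where invalid.
#' @examples
#' canonicalize_smiles(c("OCC", "CCO"))   # both "CCO"
#' canonicalize_smiles("C1CC")            # NA (unclosed ring)
#' @export
canonicalize_smiles <- function(x, strict = FALSE) {
  stopifnot(is.character(x))
  out <- vapply(x, function(s) {
    if (is.na(s) || !nzchar(s)) return(NA_character_)
    hit <- get0(s, envir = .dg_canon_memo)
    if (!is.null(hit)) return(hit)
    res <- ob_canonicalize_one(s)
    # memoize input -> canonical, and mark the canonical form as a fixed
    # point so repeated passes over canonical strings cost a lookup
    assign(s, res, envir = .dg_canon_memo)
    if (!is.na(res)) assign(res, res, envir = .dg_canon_memo)
    res
  }, character(1), USE.NAMES = FALSE)
  if (strict && anyNA(out)) {
    bad <- x[is.na(out)]
    stop("unparseable SMILES: ", paste(utils::head(bad, 5), collapse = ", "))
  }
  out
}

#' Construct a molecule record
#'
#' Thin value type pairing the input SMILES with its canonical form.
#' Invalid input gives `valid = FALSE` and no canonical form.
#'
#' @param smiles a single SMILES string.
#' @param strict raise an error on unparseable input instead.
#' @return an object of class `dg_molecule` with fields `smiles_input`,
#'   `smiles_canonical` and `valid`.
#' @examples
#' m <- molecule("C1=CC=CC=C1")
#' m$smiles_canonical  # aromatic benzene
#' @export
molecule <- function(smiles, strict = FALSE) {
  stopifnot(is.character(smiles), length(smiles) == 1L)
  can <- canonicalize_smiles(smiles, strict = strict)
  structure(
    list(
      smiles_input = smiles,
      smiles_canonical = if (is.na(can)) NA_character_ else can,
      valid = !is.na(can)
    ),
    class = "dg_molecule"
  )
}

#' @export
print.dg_molecule <- function(x, ...) {
  if (x$valid) {
    cat("<molecule> ", x$smiles_canonical, "\n", sep = "")
  } else {
    cat("<molecule> INVALID input: ", x$smiles_input, "\n", sep = "")
  }
  invisible(x)
}

# Resolve input (character SMILES or dg_molecule) to canonical SMILES,
# erroring on invalid molecules. Most user-facing functions funnel
# through this.
as_canonical <- function(m, what = "molecule") {
  if (inherits(m, "dg_molecule")) {
    if (!m$valid) stop("invalid ", what, ": ", m$smiles_input)
    return(m$smiles_canonical)
  }
  stopifnot(is.character(m))
  can <- canonicalize_smiles(m)
  if (anyNA(can)) {
    stop("invalid ", what, ": ", paste(m[is.na(can)], collapse = ", "))
  }
  can
}

# --- SMILES tokenizer -------------------------------------------------------
#
# Splits a SMILES string into tokens. Token types:
#   atom_bracket  [..] atoms           atom_organic  B C N O P S F Cl Br I
#   atom_aromatic b c n o s p         ring          digit or %nn closure
#   bond          - = # : / \          branch        ( )
#   dot           .
# Supports the organic subset plus bracket atoms; enough for canonical
# Open Babel output and for the string-level CSA operators.
.dg_token_re <- paste0(
  "\\[[^]]*\\]|Cl|Br|%[0-9]{2}|[BCNOPSFI]|[bcnops]|[0-9]|",
  "[()]|[-=#:/\\\\~]|\\."
)

smiles_tokens <- function(s) {
  stopifnot(is.character(s), length(s) == 1L, !is.na(s))
  m <- gregexpr(.dg_token_re, s)[[1L]]
  tok <- regmatches(s, list(m))[[1L]]
  if (sum(attr(m, "match.length")) != nchar(s)) {
    covered <- logical(nchar(s))
    for (k in seq_along(tok)) {
      covered[m[k]:(m[k] + attr(m, "match.length")[k] - 1L)] <- TRUE
    }
    bad <- which(!covered)[1L]
    stop("unrecognized SMILES character '", substr(s, bad, bad),
         "' in: ", s)
  }
  first <- substr(tok, 1L, 1L)
  typ <- character(length(tok))
  typ[first == "["] <- "atom_bracket"
  typ[tok %in% c("Cl", "Br") |
        (nchar(tok) == 1L & first %in% c("B", "C", "N", "O", "P", "S",
                                         "F", "I"))] <- "atom_organic"
  typ[first %in% c("b", "c", "n", "o", "s", "p")] <- "atom_aromatic"
  typ[first == "%" | (nchar(tok) == 1L & grepl("[0-9]", first))] <- "ring"
  typ[first %in% c("(", ")")] <- "branch"
  typ[first == "."] <- "dot"
  typ[typ == ""] <- "bond"
  data.frame(token = tok, type = typ, stringsAsFactors = FALSE)
}

# Parse a bracket atom token "[13CH3+2]" into element, aromatic flag,
# hydrogen count and formal charge.
parse_bracket_atom <- function(tok) {
  body <- sub("^\\[", "", sub("\\]$", "", tok))
  body <- sub("^[0-9]*", "", body)                     # isotope
  m <- regmatches(body, regexpr("^([A-Z][a-z]?|[bcnops]|\\*)", body))
  if (length(m) == 0L) stop("cannot parse bracket atom: ", tok)
  elem <- m
  rest <- substring(body, nchar(elem) + 1L)
  rest <- gsub("@", "", rest)                          # chirality
  hcount <- 0L
  hm <- regmatches(rest, regexpr("H[0-9]*", rest))
  if (length(hm) == 1L) {
    hcount <- if (nchar(hm) == 1L) 1L else as.integer(substring(hm, 2L))
    rest <- sub("H[0-9]*", "", rest)
  }
  charge <- 0L
  cm <- regmatches(rest, regexpr("[+-][0-9]*|\\+\\++|--+", rest))
  if (length(cm) == 1L) {
    sign <- if (substring(cm, 1L, 1L) == "+") 1L else -1L
    digs <- gsub("[+-]", "", cm)
    mag <- if (nzchar(digs)) as.integer(digs) else
      nchar(gsub("[^+-]", "", cm))
    charge <- sign * mag
  }
  aromatic <- elem %in% c("b", "c", "n", "o", "s", "p", "se", "as")
  list(
    element = paste0(toupper(substring(elem, 1L, 1L)), substring(elem, 2L)),
    aromatic = aromatic, hcount = hcount, charge = charge,
    explicit_h = length(hm) == 1L
  )
}

# Atom table for one SMILES: element, aromatic, bracket info, in input order
# (Open Babel preserves SMILES atom order when writing SDF).
smiles_atoms <- function(s) {
  tk <- smiles_tokens(s)
  at <- tk[tk$type %in% c("atom_bracket", "atom_organic", "atom_aromatic"), ,
           drop = FALSE]
  n <- nrow(at)
  element <- character(n); aromatic <- logical(n)
  hcount <- rep(NA_integer_, n); charge <- integer(n)
  bracket <- at$type == "atom_bracket"
  for (k in seq_len(n)) {
    if (bracket[k]) {
      p <- parse_bracket_atom(at$token[k])
      element[k] <- p$element; aromatic[k] <- p$aromatic
      hcount[k] <- p$hcount; charge[k] <- p$charge
    } else {
      element[k] <- paste0(toupper(substring(at$token[k], 1L, 1L)),
                           substring(at$token[k], 2L))
      aromatic[k] <- at$type[k] == "atom_aromatic"
    }
  }
  data.frame(element = element, aromatic = aromatic, bracket = bracket,
             hcount = hcount, charge = charge, stringsAsFactors = FALSE)
}

.dg_valid_memo <- new.env(parent = emptyenv())

# Fast validity check (parse only, no canonical output); memoized.
ob_is_valid_smiles <- function(s) {
  hit <- get0(s, envir = .dg_canon_memo)
  if (!is.null(hit)) return(!is.na(hit))
  hit <- get0(s, envir = .dg_valid_memo)
  if (!is.null(hit)) return(hit)
  ok <- tryCatch({
    ChemmineOB::forEachMol("SMILES", s, identity)
    TRUE
  }, error = function(e) FALSE)
  assign(s, ok, envir = .dg_valid_memo)
  ok
}

# Canonicalize a vector of pre-validated SMILES in one batch conversion
# (the per-call converter setup is ~15x the per-molecule cost). Falls
# back to per-molecule conversion if the batch drops entries.
canonicalize_valid_batch <- function(xs) {
  out <- vapply(xs, function(s) {
    hit <- get0(s, envir = .dg_canon_memo)
    if (is.null(hit)) NA_character_ else hit
  }, character(1), USE.NAMES = FALSE)
  todo <- which(is.na(out))
  if (length(todo) > 0L) {
    src <- paste(xs[todo], collapse = "\n")
    res <- tryCatch(
      ChemmineOB::convertFormat("SMI", "CAN", source = src),
      error = function(e) ""
    )
    lines <- sub("[ \t].*$", "", strsplit(res, "\n", fixed = TRUE)[[1L]])
    lines <- lines[nzchar(lines)]
    if (length(lines) == length(todo)) {
      out[todo] <- lines
    } else {
      out[todo] <- vapply(xs[todo], ob_canonicalize_one, character(1),
                          USE.NAMES = FALSE)
    }
    for (k in todo) {
      if (!is.na(out[k])) {
        assign(xs[k], out[k], envir = .dg_canon_memo)
        assign(out[k], out[k], envir = .dg_canon_memo)
      }
    }
  }
  out[!is.na(out)]
}

# Open Babel molecule references for a vector of *valid canonical* SMILES.
ob_refs <- function(smiles) {
  stopifnot(!anyNA(smiles))
  if (length(smiles) == 0L) return(list())
  ChemmineOB::forEachMol("SMILES", paste(smiles, collapse = "\n"),
                         identity, reduce = NULL)
}

# Molecular properties needed by the pipeline (MW, logP, TPSA, HBD,
# HBA2). Calls Open Babel's descriptor engine directly with descriptor
# handles found once per batch; ChemmineOB::prop_OB computes the same
# values but also InChI/formula strings (slow) and re-finds every
# descriptor per molecule.
.dg_prop_names <- c("MW", "logP", "TPSA", "HBD", "HBA2")

ob_props <- function(smiles_or_refs) {
  refs <- if (is.list(smiles_or_refs)) smiles_or_refs else
    ob_refs(smiles_or_refs)
  find_type <- tryCatch(
    get("OBDescriptor_FindType", envir = asNamespace("ChemmineOB")),
    error = function(e) NULL
  )
  if (!is.null(find_type)) {
    predict_d <- get("OBDescriptor_Predict", envir = asNamespace("ChemmineOB"))
    descs <- lapply(.dg_prop_names, find_type)
    out <- matrix(0, length(refs), length(descs),
                  dimnames = list(NULL, .dg_prop_names))
    for (i in seq_along(refs)) {
      for (j in seq_along(descs)) {
        out[i, j] <- predict_d(descs[[j]], refs[[i]])
      }
    }
    return(as.data.frame(out))
  }
  p <- ChemmineOB::prop_OB(refs)
  if (nrow(p) != length(refs)) {
    stop("property calculation dropped molecules (", nrow(p), "/",
         length(refs), ")")
  }
  p[, .dg_prop_names]
}

# SMARTS matching against OBMol references. Compiled pattern handles
# are cached for the session (complex recursive patterns are expensive
# to parse); `ob_smarts_has` uses the short-circuiting any-match test.
.dg_smarts_memo <- new.env(parent = emptyenv())

ob_smarts_pattern <- function(pattern) {
  sp <- get0(pattern, envir = .dg_smarts_memo)
  if (is.null(sp)) {
    ns <- asNamespace("ChemmineOB")
    sp <- get("OBSmartsPattern", envir = ns)()
    if (!get("OBSmartsPattern_Init", envir = ns)(sp, pattern)) {
      stop("failed to parse SMARTS pattern: ", pattern)
    }
    assign(pattern, sp, envir = .dg_smarts_memo)
  }
  sp
}

ob_smarts_count <- function(smiles_or_refs, pattern, unique_matches = TRUE) {
  refs <- if (is.list(smiles_or_refs)) smiles_or_refs else
    ob_refs(smiles_or_refs)
  if (length(refs) == 0L) return(integer(0))
  ns <- asNamespace("ChemmineOB")
  sp <- ob_smarts_pattern(pattern)
  match_f <- get("OBSmartsPattern_Match", envir = ns)
  umap_f <- get("OBSmartsPattern_GetUMapList", envir = ns)
  nmat_f <- get("OBSmartsPattern_NumMatches", envir = ns)
  vapply(refs, function(mol) {
    match_f(sp, mol)
    if (unique_matches) length(umap_f(sp)) else as.integer(nmat_f(sp))
  }, integer(1))
}

ob_smarts_has <- function(refs, pattern) {
  if (length(refs) == 0L) return(logical(0))
  sp <- ob_smarts_pattern(pattern)
  has_f <- get("OBSmartsPattern_HasMatch", envir = asNamespace("ChemmineOB"))
  vapply(refs, function(mol) isTRUE(has_f(sp, mol)), logical(1))
}
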