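# Synthetic study inputs: a fragment-based SMILES generator standing in
# for a large compound database sample, and a deterministic
# pseudo-docking oracle standing in for a docking engine. Both are
# seedable so every experiment in the package reproduces exactly.

#' Default reference ligand
#'
#' ML216, a known inhibitor of the BLM/WRN RecQ helicases
#' (1-(4-fluoro-3-(trifluoromethyl)phenyl)-3-(5-(pyridin-4-yl)-1,3,4-
#' thiadiazol-2-yl)urea), taken from its public chemical record. Used as
#' the default similarity reference; any valid SMILES can be supplied
#' instead wherever a reference is accepted.
#'
#' @return canonical SMILES of the reference ligand.
#' @export
reference_ligand <- function() {
  canonicalize_smiles("O=C(Nc1ccc(F)c(C(F)(F)F)c1)Nc1nnc(-c2ccncc2)s1")
}

#' Pseudo-docking oracle configuration
#'
#' Defines a deterministic stand-in docking-energy function computed
#' from physicochemical properties: heavier, more aromatic molecules
#' with more hydrogen-bonding capability and a logP near `logp_opt`
#' score better (more negative), saturating in molecular weight at
#' `mw_sat`, with results clipped to the observed docking-energy range
#' \[-16.4, -0.4\] kcal/mol.
#'
#' @param a_mw weight per Da of molecular weight (up to `mw_sat`).
#' @param a_ar weight per aromatic ring.
#' @param a_hbd,a_hba weights per H-bond donor / acceptor.
#' @param a_logp penalty per logP unit away from `logp_opt`.
#' @param logp_opt most favorable logP.
#' @param mw_sat molecular weight saturation (Da).
#' @param clip_min,clip_max energy clip bounds (kcal/mol).
#' @param noise_sd Gaussian noise standard deviation (kcal/mol); 0 gives
#'   a fully deterministic oracle.
#' @return a `dg_oracle_config` list.
#' @export
oracle_config <- function(a_mw = 0.015, a_ar = 0.35, a_hbd = 0.25,
                          a_hba = 0.15, a_logp = 0.4, logp_opt = 2.0,
                          mw_sat = 550, clip_min = -16.4, clip_max = -0.4,
                          noise_sd = 0) {
  stopifnot(clip_min < clip_max, noise_sd >= 0)
  structure(
    list(a_mw = a_mw, a_ar = a_ar, a_hbd = a_hbd, a_hba = a_hba,
         a_logp = a_logp, logp_opt = logp_opt, mw_sat = mw_sat,
         clip_min = clip_min, clip_max = clip_max, noise_sd = noise_sd),
    class = "dg_oracle_config"
  )
}

# The oracle energy formula on raw property values; exposed separately
# so the arithmetic can be checked independently of featurization.
oracle_energy <- function(mw, aromatic_rings, hbd, hba, logp,
                          cfg = oracle_config()) {
  raw <- -(cfg$a_mw * pmin(mw, cfg$mw_sat) + cfg$a_ar * aromatic_rings +
             cfg$a_hbd * hbd + cfg$a_hba * hba -
             cfg$a_logp * abs(logp - cfg$logp_opt))
  pmin(pmax(raw, cfg$clip_min), cfg$clip_max)
}

#' Pseudo-docking score
#'
#' Deterministic (at `noise_sd = 0`) docking-energy stand-in computed
#' from molecular weight, aromatic ring count, H-bond donors/acceptors
#' and logP; see [oracle_config()] for the functional form.
#'
#' @param x SMILES vector or [molecule()].
#' @param cfg an [oracle_config()].
#' @param rng_seed seed for the optional noise term (only used when
#'   `cfg$noise_sd > 0`).
#' @return numeric energies (kcal/mol) within the clip bounds.
#' @export
pseudo_docking_score <- function(x, cfg = oracle_config(), rng_seed = 0L) {
  canon <- as_canonical(x)
  tab <- cached_properties(canon)
  raw <- -(cfg$a_mw * pmin(tab[, "mw"], cfg$mw_sat) +
             cfg$a_ar * tab[, "aromatic_rings"] +
             cfg$a_hbd * tab[, "hbd"] + cfg$a_hba * tab[, "hba"] -
             cfg$a_logp * abs(tab[, "logp"] - cfg$logp_opt))
  if (cfg$noise_sd > 0) {
    raw <- raw + with_seed(rng_seed, rnorm(length(raw), sd = cfg$noise_sd))
  }
  unname(pmin(pmax(raw, cfg$clip_min), cfg$clip_max))
}

#' Scorer factories
#'
#' Convenience wrappers producing `function(smiles) -> energies` closures
#' for [evaluate_objective()] and [run_csa()]: `oracle_scorer` wraps the
#' pseudo-docking oracle, `surrogate_scorer` wraps a trained surrogate
#' model (featurizing its input on the fly).
#'
#' @param cfg an [oracle_config()].
#' @return a scoring function.
#' @export
oracle_scorer <- function(cfg = oracle_config()) {
  force(cfg)
  function(smiles) pseudo_docking_score(smiles, cfg)
}

#' @rdname oracle_scorer
#' @param model a trained [build_surrogate()] model.
#' @export
surrogate_scorer <- function(model) {
  stopifnot(inherits(model, "dg_surrogate"))
  if (!model$trained) stop("surrogate model has not been trained")
  function(smiles) predict_surrogate(model, build_feature_vector(smiles))
}

#' Fragment vocabulary for the synthetic SMILES generator
#'
#' Terminal fragments are complete substituents; linker fragments carry
#' one `{R}` attachment point that the generator fills recursively. The
#' set spans aromatic carbo- and heterocycles, amide/urea/sulfonamide
#' linkers, ethers, amines and halogen/alkyl decorations so that the
#' generated pool covers the property ranges the pseudo-docking oracle
#' responds to.
#'
#' @return data.frame with columns `fragment`, `type`, `weight`.
#' @export
fragment_vocabulary <- function() {
  terminals <- c(
    "c1ccccc1", "c1ccncc1", "c1ccc(F)cc1", "c1ccc(Cl)cc1", "c1ccc(O)cc1",
    "c1ccc(OC)cc1", "c1ccc(C)cc1", "c1ccc(C(F)(F)F)cc1", "c1ccsc1",
    "c1ccoc1", "c1cc[nH]c1", "c1cnc[nH]1", "c1nnc(C)s1", "c1ccc2ccccc2c1",
    "C1CCCCC1", "C1CCNCC1", "C1CCOCC1", "C", "CC", "CCC", "C(C)C",
    "C(F)(F)F", "CO", "C#N", "N", "O"
  )
  linkers <- c(
    "c1ccc({R})cc1", "c1ccc({R})nc1", "c1cnc({R})nc1", "c1nnc({R})s1",
    "C(=O)N{R}", "NC(=O){R}", "NC(=O)N{R}", "S(=O)(=O)N{R}",
    "C(=O)O{R}", "O{R}", "N{R}", "N(C){R}", "C{R}", "CC{R}", "CCC{R}",
    "C(=O){R}", "C1CCN({R})CC1", "c1ccc(N{R})cc1", "c1ccc(O{R})cc1",
    "c1ccc(C{R})cc1"
  )
  data.frame(
    fragment = c(terminals, linkers),
    type = c(rep("terminal", length(terminals)),
             rep("linker", length(linkers))),
    weight = 1,
    stringsAsFactors = FALSE
  )
}

# Shift every ring-closure digit in `s` by `offset` so a fragment can be
# nested inside another without digit collisions ("c1ccc(c1ccccc1)cc1"
# would otherwise close the wrong ring).
shift_ring_digits <- function(s, offset) {
  if (offset == 0L) return(s)
  tk <- smiles_tokens(s)
  tk$token[tk$type == "ring"] <- vapply(
    tk$token[tk$type == "ring"], function(t) {
      v <- if (startsWith(t, "%")) as.integer(substring(t, 2L)) else
        as.integer(t)
      v <- v + offset
      if (v <= 9L) as.character(v) else sprintf("%%%02d", v)
    }, character(1))
  paste(tk$token, collapse = "")
}

max_ring_digit <- function(s) {
  tk <- smiles_tokens(s)
  r <- tk$token[tk$type == "ring"]
  if (length(r) == 0L) return(0L)
  max(vapply(r, function(t) {
    if (startsWith(t, "%")) as.integer(substring(t, 2L)) else as.integer(t)
  }, integer(1)))
}

#' Generate a synthetic pool of drug-like SMILES
#'
#' Assembles molecules from 1 to `k_max` vocabulary fragments (linkers
#' chain through their `{R}` attachment point, closed by a terminal),
#' canonicalizes, and keeps distinct valid structures until `n` are
#' collected. Deterministic for a fixed seed.
#'
#' @param n number of distinct molecules required.
#' @param vocab a [fragment_vocabulary()]-style data.frame.
#' @param k_max maximum fragments per molecule.
#' @param rng_seed integer seed.
#' @param max_attempts attempt cap (default `50 * n`) before erroring.
#' @return character vector of `n` distinct canonical SMILES.
#' @export
generate_pool <- function(n, vocab = fragment_vocabulary(), k_max = 4L,
                          rng_seed = 1L, max_attempts = 50L * n) {
  stopifnot(n >= 0L, nrow(vocab) > 0L)
  if (n == 0L) return(character(0))
  terminals <- vocab$fragment[vocab$type == "terminal"]
  linkers <- vocab$fragment[vocab$type == "linker"]
  wt_t <- vocab$weight[vocab$type == "terminal"]
  wt_l <- vocab$weight[vocab$type == "linker"]
  if (length(terminals) == 0L) stop("vocabulary has no terminal fragments")
  with_seed(rng_seed, {
    seen <- character(0)
    attempts <- 0L
    # favor 2-3 fragment assemblies: single fragments are small and
    # sit near the oracle's clip ceiling
    k_weights <- c(0.15, 0.35, 0.3, 0.2)[seq_len(k_max)]
    while (length(seen) < n) {
      attempts <- attempts + 1L
      if (attempts > max_attempts) {
        stop("pool generation cap exceeded: got ", length(seen), " of ", n,
             " distinct molecules in ", max_attempts, " attempts")
      }
      k <- sample.int(k_max, 1L, prob = k_weights)
      smi <- sample(terminals, 1L, prob = wt_t)
      if (k > 1L && length(linkers) > 0L) {
        for (j in seq_len(k - 1L)) {
          lk <- sample(linkers, 1L, prob = wt_l)
          inner <- shift_ring_digits(
            smi, max_ring_digit(sub("{R}", "", lk, fixed = TRUE)))
          smi <- sub("{R}", inner, lk, fixed = TRUE)
        }
      }
      can <- canonicalize_smiles(smi)
      if (!is.na(can) && !(can %in% seen)) seen <- c(seen, can)
    }
    seen
  })
}

#' Featurize and label a pool with the pseudo-docking oracle
#'
#' @param pool character vector of SMILES.
#' @param cfg an [oracle_config()].
#' @param rng_seed seed for oracle noise (when enabled).
#' @return list with `smiles`, feature matrix `X` (n x 2232) and label
#'   vector `y` (kcal/mol).
#' @export
label_pool <- function(pool, cfg = oracle_config(), rng_seed = 0L) {
  canon <- as_canonical(pool)
  list(
    smiles = canon,
    X = build_feature_vector(canon),
    y = pseudo_docking_score(canon, cfg, rng_seed = rng_seed)
  )
}
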