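# The design objective. For a molecule m with predicted docking energy
# D(m) (kcal/mol), drug-likeness Q(m) (QED) and similarity S(m; ref) to
# a reference molecule:
#
#     R(m) = wD * [D(m) + penalty(m)] - wQ * Q(m) - wS * S(m; ref)
#
# Lower is better: good docking energies are negative, and Q and S enter
# with negative sign. Lipinski violators (MW > 500 Da or logP > 5) have
# a large constant (1000 kcal/mol) added to the docking term, and
# radical-bearing molecules a second 1000, which removes them from
# contention without discarding them outright.

#' Objective configuration
#'
#' @param omega_d weight on the (penalized) docking term. The default
#'   0.03 balances docking energy against drug-likeness and similarity.
#' @param omega_q weight on QED.
#' @param omega_s weight on reference similarity.
#' @param reference reference molecule (SMILES or [molecule()]); the
#'   similarity term is Tanimoto similarity to this structure. Defaults
#'   to [reference_ligand()].
#' @param penalty_constant energy added per violated rule (kcal/mol).
#' @param mw_limit,logp_limit Lipinski bounds triggering the penalty.
#' @return a `dg_objective_config` list.
#' @export
objective_config <- function(omega_d = 0.03, omega_q = 1, omega_s = 1,
                             reference = reference_ligand(),
                             penalty_constant = 1000,
                             mw_limit = 500, logp_limit = 5) {
  stopifnot(omega_d >= 0, omega_q >= 0, omega_s >= 0, penalty_constant > 0)
  ref <- as_canonical(reference, what = "reference molecule")
  structure(
    list(omega_d = omega_d, omega_q = omega_q, omega_s = omega_s,
         reference = ref, penalty_constant = penalty_constant,
         mw_limit = mw_limit, logp_limit = logp_limit),
    class = "dg_objective_config"
  )
}

#' Lipinski / radical penalty
#'
#' `penalty_constant` (default 1000 kcal/mol) if molecular weight exceeds
#' `mw_limit` or logP exceeds `logp_limit`; an additional
#' `penalty_constant` if the molecule carries radical centers.
#'
#' @param x SMILES vector or [molecule()].
#' @param cfg an [objective_config()].
#' @return numeric penalty vector (0, 1000 or 2000 with defaults).
#' @export
penalty_for <- function(x, cfg = objective_config()) {
  canon <- as_canonical(x)
  tab <- cached_properties(canon)
  lipinski <- tab[, "mw"] > cfg$mw_limit | tab[, "logp"] > cfg$logp_limit
  radical <- tab[, "radicals"] > 0
  cfg$penalty_constant * (as.numeric(lipinski) + as.numeric(radical))
}

#' Evaluate the design objective
#'
#' Computes the decomposed objective for each molecule: raw docking term
#' `d_raw` from `scorer`, penalty, QED `q`, reference similarity `s` and
#' the total `r_total = omega_d * (d_raw + penalty) - omega_q * q -
#' omega_s * s`.
#'
#' @param x SMILES vector or [molecule()].
#' @param scorer function mapping a character vector of SMILES to
#'   docking energies (kcal/mol): e.g. [oracle_scorer()] or
#'   [surrogate_scorer()].
#' @param cfg an [objective_config()].
#' @return data.frame with columns `smiles`, `d_raw`, `penalty`,
#'   `d_penalized`, `q`, `s`, `r_total`.
#' @export
evaluate_objective <- function(x, scorer, cfg = objective_config()) {
  if (length(x) == 0L) {
    return(data.frame(smiles = character(0), d_raw = numeric(0),
                      penalty = numeric(0), d_penalized = numeric(0),
                      q = numeric(0), s = numeric(0), r_total = numeric(0),
                      stringsAsFactors = FALSE))
  }
  canon <- as_canonical(x)
  d_raw <- tryCatch(scorer(canon), error = function(e) {
    stop("scorer failed on [", paste(utils::head(canon, 3), collapse = ", "),
         "...]: ", conditionMessage(e))
  })
  if (length(d_raw) != length(canon)) {
    stop("scorer returned ", length(d_raw), " values for ", length(canon),
         " molecules")
  }
  pen <- penalty_for(canon, cfg)
  q <- qed_score(canon)
  bits <- cached_pathfp(c(cfg$reference, canon))
  refbits <- bits[[1L]]
  s <- vapply(bits[-1L], function(b) tanimoto_bits(b, refbits), numeric(1))
  d_pen <- d_raw + pen
  data.frame(
    smiles = canon, d_raw = d_raw, penalty = pen, d_penalized = d_pen,
    q = q, s = s,
    r_total = cfg$omega_d * d_pen - cfg$omega_q * q - cfg$omega_s * s,
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Rank molecules by ascending objective
#'
#' Stable sort on `r_total` (lower is better); ties broken by canonical
#' SMILES lexicographic order so the ranking is deterministic.
#'
#' @inheritParams evaluate_objective
#' @return the [evaluate_objective()] data.frame, sorted.
#' @export
rank_molecules <- function(x, scorer, cfg = objective_config()) {
  obj <- evaluate_objective(x, scorer, cfg)
  if (nrow(obj) == 0L) return(obj)
  obj[order(obj$r_total, obj$smiles, method = "radix"), , drop = FALSE]
}
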