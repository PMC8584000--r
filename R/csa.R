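# Conformational space annealing (CSA) over SMILES strings.
#
# A bank of N_bank molecules is evolved for a fixed number of
# iterations. Each iteration the N_seed best not-yet-used members parent
# children: string-level crossover (prefix of one parent, suffix of the
# other, cut at syntactically safe positions) plus three mutation kinds
# (replace / remove / add one atom token). Children compete for bank
# slots under a Tanimoto-similarity cutoff: a child similar to an
# existing member may only replace that member, a dissimilar child
# competes with the current worst member. Both replacements require
# strict improvement of the objective, so the best objective value is
# monotone non-increasing while the cutoff preserves diversity.

#' CSA optimizer configuration
#'
#' @param n_bank bank size (number of molecules kept).
#' @param n_seed preferred molecules selected per iteration
#'   (`n_seed <= n_bank`).
#' @param n_crossover_children crossover children per seed.
#' @param mutation_kinds mutation operators applied to each crossover
#'   child; with the default three kinds each seed yields
#'   `n_crossover_children * (1 + 3) = 80` children.
#' @param max_iterations CSA iterations.
#' @param max_operator_attempts retry cap per crossover slot / mutation.
#' @param rng_seed integer seed; the full run is deterministic given the
#'   seed.
#' @param cutoff_factor per-iteration multiplier on the similarity
#'   cutoff. The default 1.0 keeps the cutoff fixed at half the initial
#'   average bank similarity; a factor below 1 anneals it toward
#'   `cutoff_floor`.
#' @param cutoff_floor lower bound for the annealed cutoff.
#' @return a `dg_csa_config` list.
#' @export
csa_config <- function(n_bank = 500L, n_seed = 300L,
                       n_crossover_children = 20L,
                       mutation_kinds = c("replace", "remove", "add"),
                       max_iterations = 100L, max_operator_attempts = 50L,
                       rng_seed = 1L, cutoff_factor = 1.0,
                       cutoff_floor = 0.1) {
  stopifnot(n_bank >= 2L, n_seed >= 1L, n_crossover_children >= 1L,
            max_iterations >= 0L, max_operator_attempts >= 0L)
  if (n_seed > n_bank) stop("n_seed must not exceed n_bank")
  if (!all(mutation_kinds %in% c("replace", "remove", "add"))) {
    stop("mutation_kinds must be a subset of replace/remove/add")
  }
  if (cutoff_factor <= 0) stop("cutoff_factor must be positive")
  structure(
    list(n_bank = as.integer(n_bank), n_seed = as.integer(n_seed),
         n_crossover_children = as.integer(n_crossover_children),
         mutation_kinds = mutation_kinds,
         n_children_per_seed =
           as.integer(n_crossover_children * (1L + length(mutation_kinds))),
         max_iterations = as.integer(max_iterations),
         max_operator_attempts = as.integer(max_operator_attempts),
         rng_seed = as.integer(rng_seed), cutoff_factor = cutoff_factor,
         cutoff_floor = cutoff_floor),
    class = "dg_csa_config"
  )
}

# --- string-level operators -------------------------------------------------

# Token positions after which a SMILES string may be cut: branch
# parentheses balanced and every ring-closure digit paired within the
# prefix (equivalently, within the suffix). Bracket atoms are single
# tokens, so cuts never land inside [..].
safe_cut_points <- function(tokens) {
  n <- nrow(tokens)
  if (n < 2L) return(integer(0))
  depth <- 0L
  open_rings <- integer(0)
  ok <- logical(n - 1L)
  for (i in seq_len(n - 1L)) {
    t <- tokens$token[i]; ty <- tokens$type[i]
    if (ty == "branch") depth <- depth + if (t == "(") 1L else -1L
    if (ty == "ring") {
      v <- if (startsWith(t, "%")) as.integer(substring(t, 2L)) else
        as.integer(t)
      if (v %in% open_rings) open_rings <- setdiff(open_rings, v)
      else open_rings <- c(open_rings, v)
    }
    ok[i] <- depth == 0L && length(open_rings) == 0L
  }
  which(ok)
}

# one random prefix/suffix splice; string only, no validity check
crossover_candidate <- function(ta, tb, cuts_a, cuts_b) {
  ia <- cuts_a[sample.int(length(cuts_a), 1L)]
  ib <- cuts_b[sample.int(length(cuts_b), 1L)]
  paste0(
    paste(ta$token[seq_len(ia)], collapse = ""),
    paste(tb$token[(ib + 1L):nrow(tb)], collapse = "")
  )
}

# raw crossover: returns a validity-checked but not-yet-canonicalized
# child string, or NA (the optimizer canonicalizes children in batch)
crossover_raw <- function(a, b, max_attempts) {
  ta <- smiles_tokens(a); tb <- smiles_tokens(b)
  cuts_a <- safe_cut_points(ta)
  cuts_b <- safe_cut_points(tb)
  if (length(cuts_a) == 0L || length(cuts_b) == 0L) return(NA_character_)
  for (k in seq_len(max_attempts)) {
    child <- crossover_candidate(ta, tb, cuts_a, cuts_b)
    if (ob_is_valid_smiles(child)) return(child)
  }
  NA_character_
}

#' SMILES crossover
#'
#' Cuts each parent at a random syntactically safe position and splices
#' a prefix of one onto a suffix of the other; the result must parse and
#' canonicalize, retrying with fresh cut points up to `max_attempts`
#' times.
#'
#' @param parent_a,parent_b SMILES strings or [molecule()] objects.
#' @param max_attempts retry cap.
#' @return canonical SMILES of the child, or `NA_character_`.
#' @export
crossover <- function(parent_a, parent_b, max_attempts = 50L) {
  a <- as_canonical(parent_a); b <- as_canonical(parent_b)
  child <- crossover_raw(a, b, max_attempts)
  if (is.na(child)) return(NA_character_)
  canonicalize_smiles(child)
}

.dg_replace_plain <- c("B", "C", "N", "O", "P", "S", "F", "Cl", "Br", "I")
.dg_replace_arom <- c("b", "c", "n", "o", "s", "p")
.dg_add_atoms <- c("C", "C", "C", "N", "N", "O", "O", "S", "F", "Cl")

#' SMILES point mutation
#'
#' Three kinds: `replace` substitutes one atom symbol with another
#' element (aromatic symbols stay aromatic), `remove` deletes one atom
#' token that carries no ring closures, `add` inserts one atom (inline
#' or as a branch) after an existing atom. The mutant must parse,
#' canonicalize and differ from the parent; each attempt draws fresh
#' random choices, up to `max_attempts`.
#'
#' @param x parent SMILES or [molecule()].
#' @param kind one of `"replace"`, `"remove"`, `"add"`.
#' @param max_attempts retry cap.
#' @return canonical SMILES of the mutant, or `NA_character_`.
#' @export
mutate_smiles <- function(x, kind = c("replace", "remove", "add"),
                          max_attempts = 50L) {
  kind <- match.arg(kind)
  parent <- as_canonical(x)
  for (attempt in seq_len(max_attempts)) {
    cand <- mutate_candidate(parent, kind)
    if (is.null(cand) || !ob_is_valid_smiles(cand)) next
    can <- canonicalize_smiles(cand)
    if (!is.na(can) && can != parent) return(can)
  }
  NA_character_
}

# raw mutation: validity-checked, not canonicalized, or NA
mutate_raw <- function(parent, kind, max_attempts) {
  for (attempt in seq_len(max_attempts)) {
    cand <- mutate_candidate(parent, kind)
    if (!is.null(cand) && ob_is_valid_smiles(cand)) return(cand)
  }
  NA_character_
}

# build one randomly mutated candidate string (NULL when the kind is
# inapplicable, e.g. removing the only atom)
mutate_candidate <- function(parent, kind) {
  tk <- smiles_tokens(parent)
  atom_idx <- which(tk$type %in% c("atom_organic", "atom_aromatic"))
  n <- nrow(tk)
  if (length(atom_idx) == 0L) return(NULL)
  {
    cand <- NULL
    if (kind == "replace") {
      i <- atom_idx[sample.int(length(atom_idx), 1L)]
      pool <- if (tk$type[i] == "atom_aromatic") .dg_replace_arom else
        .dg_replace_plain
      pool <- setdiff(pool, tk$token[i])
      repl <- pool[sample.int(length(pool), 1L)]
      toks <- tk$token; toks[i] <- repl
      cand <- paste(toks, collapse = "")
    } else if (kind == "remove") {
      # atoms with a ring-closure digit attached are ring-critical
      removable <- atom_idx[vapply(atom_idx, function(i) {
        !(i < n && tk$type[i + 1L] == "ring")
      }, logical(1))]
      if (length(removable) == 0L) return(NULL)
      i <- removable[sample.int(length(removable), 1L)]
      drop <- i
      if (i > 1L && tk$type[i - 1L] == "bond") drop <- c(i - 1L, i)
      else if (i == 1L && n > 1L && tk$type[2L] == "bond") drop <- c(1L, 2L)
      # deleting a branch's only atom leaves "()": drop the parens too
      if (i > 1L && i < n && tk$token[i - 1L] == "(" &&
          tk$token[i + 1L] == ")") {
        drop <- c(i - 1L, i, i + 1L)
      }
      toks <- tk$token[-drop]
      if (length(toks) == 0L) return(NULL)
      cand <- paste(toks, collapse = "")
    } else {  # add
      i <- atom_idx[sample.int(length(atom_idx), 1L)]
      # skip past ring closures belonging to this atom
      j <- i
      while (j < n && tk$type[j + 1L] == "ring") j <- j + 1L
      atom <- .dg_add_atoms[sample.int(length(.dg_add_atoms), 1L)]
      ins <- if (runif(1) < 0.5) atom else paste0("(", atom, ")")
      cand <- paste(c(tk$token[seq_len(j)], ins,
                      if (j < n) tk$token[(j + 1L):n]), collapse = "")
    }
    cand
  }
}

#' Generate the children of one seed molecule
#'
#' Crossover of the seed with randomly drawn bank partners fills
#' `n_crossover_children` slots; each of the configured mutation kinds
#' is then applied to every crossover child. With defaults that targets
#' 20 + 60 = 80 children; operator failures and duplicate structures
#' reduce the realized count.
#'
#' @param seed seed SMILES.
#' @param partners character vector of potential crossover partners
#'   (typically the current bank).
#' @param cfg a [csa_config()].
#' @return character vector of distinct canonical child SMILES.
#' @export
generate_children <- function(seed, partners, cfg = csa_config()) {
  raw <- generate_children_raw(seed, partners, cfg)
  unique(canonicalize_valid_batch(raw))
}

# validity-checked raw child strings (canonicalization is batched by the
# caller; the optimizer canonicalizes one batch per iteration)
generate_children_raw <- function(seed, partners, cfg) {
  seed <- as_canonical(seed)
  partners <- setdiff(partners, seed)
  if (length(partners) == 0L) return(character(0))
  cross <- character(0)
  for (slot in seq_len(cfg$n_crossover_children)) {
    partner <- partners[sample.int(length(partners), 1L)]
    swap <- runif(1) < 0.5
    child <- if (swap) {
      crossover_raw(partner, seed, cfg$max_operator_attempts)
    } else {
      crossover_raw(seed, partner, cfg$max_operator_attempts)
    }
    if (!is.na(child)) cross <- c(cross, child)
  }
  mutants <- character(0)
  for (kind in cfg$mutation_kinds) {
    for (ch in cross) {
      m <- mutate_raw(ch, kind, cfg$max_operator_attempts)
      if (!is.na(m)) mutants <- c(mutants, m)
    }
  }
  c(cross, mutants)
}

# --- bank -------------------------------------------------------------------

new_bank <- function(obj, used, avg_sim, cutoff, iteration = 0L) {
  structure(
    list(smiles = obj$smiles, objective = obj, used = used,
         avg_pairwise_similarity = avg_sim, similarity_cutoff = cutoff,
         iteration = iteration),
    class = "dg_bank"
  )
}

#' @export
print.dg_bank <- function(x, ...) {
  cat(sprintf(
    "<CSA bank: %d molecules, best r = %.4f, cutoff = %.4f, iteration %d>\n",
    length(x$smiles), min(x$objective$r_total), x$similarity_cutoff,
    x$iteration))
  invisible(x)
}

#' Average pairwise bank similarity
#'
#' Mean Tanimoto similarity over all unordered pairs of bank members
#' (path fingerprints).
#'
#' @param bank a `dg_bank` or character vector of SMILES (at least 2).
#' @return mean similarity in \[0, 1\].
#' @export
average_bank_similarity <- function(bank) {
  smiles <- if (inherits(bank, "dg_bank")) bank$smiles else
    as_canonical(bank)
  n <- length(smiles)
  if (n < 2L) stop("need at least 2 molecules")
  sims <- tanimoto_cross(smiles, smiles)
  mean(sims[upper.tri(sims)])
}

#' Initialize the CSA bank
#'
#' Deduplicates the pool by canonical SMILES, samples `n_bank` members
#' under the configured seed, scores them and sets the similarity cutoff
#' to half the average pairwise similarity.
#'
#' @param pool character vector of candidate SMILES (>= `n_bank`
#'   distinct valid molecules).
#' @param cfg a [csa_config()].
#' @param scorer docking-energy scorer (see [oracle_scorer()]).
#' @param obj_cfg an [objective_config()].
#' @return a `dg_bank`.
#' @export
init_bank <- function(pool, cfg, scorer, obj_cfg) {
  canon <- canonicalize_smiles(pool)
  canon <- unique(canon[!is.na(canon)])
  if (length(canon) < cfg$n_bank) {
    stop("pool has ", length(canon), " distinct valid molecules; n_bank = ",
         cfg$n_bank, " required")
  }
  members <- with_seed(cfg$rng_seed, sample(canon, cfg$n_bank))
  obj <- evaluate_objective(members, scorer, obj_cfg)
  avg <- average_bank_similarity(members)
  new_bank(obj, used = rep(FALSE, cfg$n_bank), avg_sim = avg,
           cutoff = avg / 2)
}

#' Select seed molecules from the bank
#'
#' The `n_seed` unused members with the lowest objective values; when
#' fewer than `n_seed` unused members remain all usage flags are reset
#' first. Selected members are marked used.
#'
#' @param bank a `dg_bank`.
#' @param cfg a [csa_config()].
#' @return list with the updated `bank` and integer `seed_idx`.
#' @export
select_seeds <- function(bank, cfg) {
  stopifnot(inherits(bank, "dg_bank"))
  if (sum(!bank$used) < cfg$n_seed) bank$used[] <- FALSE
  avail <- which(!bank$used)
  ord <- avail[order(bank$objective$r_total[avail], bank$smiles[avail],
                     method = "radix")]
  seed_idx <- ord[seq_len(min(cfg$n_seed, length(ord)))]
  bank$used[seed_idx] <- TRUE
  list(bank = bank, seed_idx = seed_idx)
}

#' Update the bank with scored children
#'
#' Children are processed in order. A child already in the bank is
#' skipped. Otherwise its most similar bank member is found: if that
#' similarity is at or above the cutoff the child may only replace that
#' member (it occupies the same region of chemical space); if below, the
#' child competes with the worst-objective member. Either replacement
#' requires strictly lower `r_total`; bank size never changes.
#'
#' @param bank a `dg_bank`.
#' @param children character vector of child SMILES.
#' @param scorer docking-energy scorer.
#' @param obj_cfg an [objective_config()].
#' @return the updated `dg_bank` (attribute `n_accepted` reports the
#'   number of replacements).
#' @export
update_bank <- function(bank, children, scorer, obj_cfg) {
  stopifnot(inherits(bank, "dg_bank"))
  children <- unique(children[!is.na(children)])
  children <- children[!(children %in% bank$smiles)]
  if (length(children) == 0L) {
    attr(bank, "n_accepted") <- 0L
    return(bank)
  }
  cobj <- evaluate_objective(children, scorer, obj_cfg)
  bank_fp <- dense_fp(cached_pathfp(bank$smiles))
  bank_n <- rowSums(bank_fp)
  accepted <- 0L
  for (k in seq_len(nrow(cobj))) {
    smi <- cobj$smiles[k]
    if (smi %in% bank$smiles) next
    cb <- cached_pathfp(smi)[[1L]]
    cvec <- integer(2048L); cvec[cb + 1L] <- 1L
    inter <- drop(bank_fp %*% cvec)
    un <- bank_n + length(cb) - inter
    sims <- ifelse(un == 0, 0, inter / un)
    j_sim <- which.max(sims)
    target <- if (sims[j_sim] >= bank$similarity_cutoff) {
      j_sim
    } else {
      which.max(bank$objective$r_total)
    }
    if (cobj$r_total[k] < bank$objective$r_total[target]) {
      bank$objective[target, ] <- cobj[k, ]
      bank$smiles[target] <- smi
      bank$used[target] <- FALSE
      bank_fp[target, ] <- cvec
      bank_n[target] <- length(cb)
      accepted <- accepted + 1L
    }
  }
  attr(bank, "n_accepted") <- accepted
  bank
}

#' Anneal the similarity cutoff
#'
#' Multiplies the cutoff by `cfg$cutoff_factor` (default 1.0: fixed at
#' half the initial average similarity), never dropping below
#' `cfg$cutoff_floor`.
#'
#' @param bank a `dg_bank`.
#' @param cfg a [csa_config()].
#' @return the updated `dg_bank`.
#' @export
anneal_cutoff <- function(bank, cfg) {
  stopifnot(inherits(bank, "dg_bank"))
  if (cfg$cutoff_factor < 1) {
    bank$similarity_cutoff <- max(bank$similarity_cutoff * cfg$cutoff_factor,
                                  cfg$cutoff_floor)
  } else {
    bank$similarity_cutoff <- bank$similarity_cutoff * cfg$cutoff_factor
  }
  bank
}

#' Run the CSA optimization
#'
#' `max_iterations` rounds of seed selection, child generation, bank
#' update and cutoff annealing. Fully deterministic under
#' `cfg$rng_seed`.
#'
#' @param pool initial molecule pool (character SMILES).
#' @param cfg a [csa_config()].
#' @param scorer docking-energy scorer (see [oracle_scorer()] /
#'   [surrogate_scorer()]).
#' @param obj_cfg an [objective_config()].
#' @return a `dg_csa_result`: list with the final `bank` and a
#'   `trajectory` data.frame (per iteration: best/mean objective, mean
#'   docking term, mean QED, mean similarity, cutoff, children counts).
#' @export
run_csa <- function(pool, cfg = csa_config(), scorer = oracle_scorer(),
                    obj_cfg = objective_config()) {
  bank <- init_bank(pool, cfg, scorer, obj_cfg)
  traj <- vector("list", cfg$max_iterations + 1L)
  traj[[1L]] <- data.frame(
    iteration = 0L,
    best_r = min(bank$objective$r_total),
    mean_r = mean(bank$objective$r_total),
    mean_d = mean(bank$objective$d_raw),
    mean_q = mean(bank$objective$q),
    mean_s = mean(bank$objective$s),
    cutoff = bank$similarity_cutoff,
    n_children = 0L,
    n_accepted = 0L
  )
  for (it in seq_len(cfg$max_iterations)) {
    # the code block is evaluated in this function's frame, so the
    # assignments below update run_csa's own `bank`
    children <- with_seed(derive_seed(cfg$rng_seed, it), {
      sel <- select_seeds(bank, cfg)
      bank <- sel$bank
      raw <- character(0)
      for (si in sel$seed_idx) {
        raw <- c(raw, generate_children_raw(bank$smiles[si],
                                            bank$smiles, cfg))
      }
      unique(canonicalize_valid_batch(raw))
    })
    bank <- update_bank(bank, children, scorer, obj_cfg)
    bank <- anneal_cutoff(bank, cfg)
    bank$iteration <- it
    traj[[it + 1L]] <- data.frame(
      iteration = it,
      best_r = min(bank$objective$r_total),
      mean_r = mean(bank$objective$r_total),
      mean_d = mean(bank$objective$d_raw),
      mean_q = mean(bank$objective$q),
      mean_s = mean(bank$objective$s),
      cutoff = bank$similarity_cutoff,
      n_children = length(children),
      n_accepted = attr(bank, "n_accepted")
    )
  }
  structure(
    list(bank = bank, trajectory = do.call(rbind, traj), config = cfg),
    class = "dg_csa_result"
  )
}

#' @export
print.dg_csa_result <- function(x, ...) {
  cat(sprintf("<CSA result: %d iterations, best r = %.4f, mean QED = %.3f>\n",
              max(x$trajectory$iteration), min(x$bank$objective$r_total),
              mean(x$bank$objective$q)))
  invisible(x)
}
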