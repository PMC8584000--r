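# Quantitative estimate of drug-likeness (QED).
#
# Weighted geometric mean of asymmetric-double-sigmoid (ADS) desirability
# functions over eight properties: molecular weight, logP, H-bond
# acceptors and donors, polar surface area, rotatable bonds, aromatic
# rings and structural-alert count. ADS parameters and the default
# (mean) weights are the published fitted constants of the desirability
# framework; the alert set is the 116 published unwanted-substructure
# patterns, matched here with Open Babel SMARTS (the two
# component-disconnected patterns are expressed as match-count rules
# with identical semantics).

.dg_ads <- data.frame(
  prop = c("MW", "ALOGP", "HBA", "HBD", "PSA", "ROTB", "AROM", "ALERTS"),
  a = c(2.817065973, 3.172690585, 2.948620388, 1.618662227, 1.876861559,
        0.010000091, 3.217788970, 0.010000000),
  b = c(392.5754953, 137.8624751, 160.4605972, 1010.051101, 125.2232657,
        272.4121427, 957.7374108, 1199.094025),
  c = c(290.7489764, 2.534937431, 3.615294657, 0.985094388, 62.90773554,
        2.558379970, 2.274627939, -0.09002883),
  d = c(2.419764353, 4.581497897, 4.435986202, 0.000000001, 87.83366614,
        1.565547684, 0.000000001, 0.000000001),
  e = c(49.22325677, 0.822739154, 0.290141953, 0.713820843, 12.01999824,
        1.271567166, 1.317690384, 0.185904477),
  f = c(65.37051707, 0.576295591, 1.300669958, 0.920922555, 28.51324732,
        2.758063707, 0.375760881, 0.875193782),
  dmax = c(104.9805561, 131.3186604, 148.7763046, 258.1632616, 104.5686167,
           105.4420403, 312.3372610, 417.7253140),
  stringsAsFactors = FALSE
)

.dg_qed_weights <- c(MW = 0.66, ALOGP = 0.46, HBA = 0.05, HBD = 0.61,
                     PSA = 0.06, ROTB = 0.65, AROM = 0.48, ALERTS = 0.95)

ads <- function(x, p) {
  (p$a + p$b / (1 + exp(-(x - p$c + p$d / 2) / p$e)) *
     (1 - 1 / (1 + exp(-(x - p$c - p$d / 2) / p$f)))) / p$dmax
}

# Structural alert SMARTS (Open Babel dialect-compatible subset of the
# published set).
.dg_alert_smarts <- c(
  "*1[O,S,N]*1", "[S,C](=[O,S])[F,Br,Cl,I]",
  "[C&X4][Cl,Br,I]", "[#6]S(=O)(=O)O[#6]",
  "[$([C&H1]),$(CC)]#CC(=O)[#6]", "[$([C&H1]),$(CC)]#CC(=O)O[#6]",
  "n[O&H1]", "[$([C&H1]),$(CC)]#CS(=O)(=O)[#6]",
  "C=C(C=O)C=O", "n1c([F,Cl,Br,I])cccc1",
  "[C&H1]=O", "[#8][#8]",
  "[C&!R]=[N&!R]", "[N&!R]=[N&!R]",
  "[#6](=O)[#6]=O", "[#16][#16]",
  "[#7][N&H2]", "C(=O)N[N&H2]",
  "[#6]=S", "[$([C&H2]),$([C&H1][C&X4]),$(C([C&X4])[C&X4])]=[$([C&H2]),$([C&H1][C&X4]),$(C([C&X4])[C&X4])]",
  "C1(=[O,N])C=CC(=[O,N])C=C1", "C1(=[O,N])C(=[O,N])C=CC=C1",
  "a12aa3a(aa1aaaa2)aaaa3", "a12a(a3a(aa1)aaaa3)aaaa2",
  "a1aa2a3a(a1)A=AA=A3=AA=A2", "c1cc([N&H2])ccc1",
  "[#80,#26,#33,#51,#30,#34,se,#52,B,#14,#11,#20,#32,#47,#12,#19,#56,#38,#4,#22,#42,#25,#44,#46,#28,#29,#79,#48,#13,#31,#50,#45,#81,#83,#41,#3,#82,#72,#67]", "I",
  "OS(=O)(=O)[O&-]", "[N&+](=O)[O&-]",
  "C(=O)N[O&H1]", "C1NC(=O)NC1=O",
  "[S&H1]", "[S&-]",
  "c1ccc([Cl,Br,I,F])c([Cl,Br,I,F])c1[Cl,Br,I,F]", "c1cc([Cl,Br,I,F])cc([Cl,Br,I,F])c1[Cl,Br,I,F]",
  "[C&R1]1[C&R1][C&R1][C&R1][C&R1][C&R1][C&R1]1", "[C&R1]1[C&R1][C&R1]cc[C&R1][C&R1]1",
  "[C&R2]1[C&R2][C&R2][C&R2][C&R2][C&R2][C&R2][C&R2]1", "[C&R2]1[C&R2][C&R2]cc[C&R2][C&R2][C&R2]1",
  "[C&H2&R2]1N[C&H2&R2][C&H2&R2][C&H2&R2][C&H2&R2][C&H2&R2]1", "[C&H2&R2]1N[C&H2&R2][C&H2&R2][C&H2&R2][C&H2&R2][C&H2&R2][C&H2&R2]1",
  "C#C", "[O&R2,N&R2]@[C&R2]@[C&R2]@[O&R2,N&R2]@[C&R2]@[C&R2]@[O&R2,N&R2]",
  "[$([N&+&R]),$([n&+&R]),$([N&+]=C)][O&-]", "[#6]=N[O&H1]",
  "[#6]=NOC=O", "[#6](=O)[C&X4,C&R0&X3,O][#6]=O",
  "c1ccc2c(c1)ccc(=O)o2", "[O&+,o&+,S&+,s&+]",
  "N=C=O", "[N&X3,N&X4][F,Cl,Br,I]",
  "c1ccccc1OC(=O)[#6]", "[C&R0]=[C&R0][C&R0]=[C&R0]",
  "[C&+,c&+,C&-,c&-]", "N=[N&+]=[N&-]",
  "C12C(NC(N1)=O)CSC2", "c1c([O&H1])c([O&H1,N&H2,N&H1])ccc1",
  "P", "[N,O,S]C#N",
  "C=C=O", "[#14][F,Cl,Br,I]",
  "[S&X2]O", "[#14&R0,C&R0](c1ccccc1)(c1ccccc1)c1ccccc1",
  "O1CCCCC1OC1CCC2CCCCC2C1", "N=[C&R0][N,n,O,S]",
  "[c&R2]1[c&R2][c&R2]([N&v3&X3,N&v4&X4])[c&R2][c&R2][c&R2]1[c&R2]1[c&R2][c&R2][c&R2]([N&v3&X3,N&v4&X4])[c&R2][c&R2]1", "C=[C&!R]C#N",
  "[c&R2]1[c&R2]c([N&+0&X3&R0,n&X3&R0])c([N&+0&X3&R0,n&X3&R0])[c&R2][c&R2]1", "[c&R2]1[c&R2]c([N&+0&X3&R0,n&X3&R0])[c&R2]c([N&+0&X3&R0,n&X3&R0])[c&R2]1",
  "[c&R2]1[c&R2]c([N&+0&X3&R0,n&X3&R0])[c&R2][c&R2]c1[N&+0&X3&R0,n&X3&R0]", "[O&H1]c1ccc([O&H1,N&H2,N&H1])cc1",
  "c1ccccc1OC(=O)O", "[S&X2&H0]N",
  "c12ccccc1SC(S)=N2", "c12ccccc1SC(=S)N2",
  "c1nnnn1C=O", "s1c(S)nnc1NC=O",
  "S1C=CSC1=S", "C(=O)Onnn",
  "OS(=O)(=O)C(F)(F)F", "N#CC[O&H1]",
  "N#CC=O", "S(=O)(=O)C#N",
  "N[C&H2]C#N", "C1(=O)NCC1",
  "S(=O)(=O)[O&-,O&H1]", "NC[F,Cl,Br,I]",
  "C=[C&!R]O", "[N&X2&+0]=[O&+0]",
  "[O&R0,N&R0][O&R0,N&R0]", "[C&X2&R0][N&X3&R0]",
  "c1ccccc1[C&!R]=[C&!R]c1ccccc1", "[N&X3&R0,N&X4&R0,O&R0,S&X2&R0][C&X4][N&X3&R0,N&X4&R0,O&R0,S&X2&R0]",
  "[s,S,c,C,n,N,o,O]~[n&+,N&+](~[s,S,c,C,n,N,o,O])(~[s,S,c,C,n,N,o,O])~[s,S,c,C,n,N,o,O]", "[s,S,c,C,n,N,o,O]~[n&X3&+,N&X3&+](~[s,S,c,C,n,N])~[s,S,c,C,n,N]",
  "*=[N&+]=*", "[S&X3](=O)[O&-,O&H1]",
  "N#N", "[R0&D2][R0&D2][R0&D2][R0&D2]",
  "[c&R,C&R]~C(=O)NC(=O)~[c&R,C&R]", "C=&!@CC=[O,S]",
  "[#6,#8,#16][#6](=O)O[#6]", "c[C&R0](=[O,S])[#6]",
  "c[S&X2][C&!R]", "C=C=C",
  "c1nc([F,Cl,Br,I,S])ncc1", "c1ncnc([F,Cl,Br,I,S])c1",
  "c1ncc2c(n1)nc(n2)[F,Cl,Br,I]", "[#6]S(=O)(=O)c1ccc(cc1)F",
  "[N&15*]", "[C&13*]",
  "[O&18*]", "[S&34*]"
)

# Multi-occurrence alert rules (component-disconnected patterns of the
# published set, re-expressed as minimum match counts).
.dg_alert_counts <- data.frame(
  smarts = c("C(=O)O[C,H1]", "F"),
  min_count = c(3L, 4L),
  stringsAsFactors = FALSE
)

# Elements a SMARTS pattern demands with certainty: literal atom
# symbols at bracket depth 0 are required for any match (everything
# inside [...] -- classes, recursive SMARTS, disjunctions -- is ignored
# as potentially optional). Used to skip patterns a molecule cannot
# match; a conservative, purely semantic shortcut.
smarts_required_elements <- function(pattern) {
  out <- character(0)
  depth <- 0L
  i <- 1L
  n <- nchar(pattern)
  while (i <= n) {
    ch <- substr(pattern, i, i)
    if (ch == "[") depth <- depth + 1L
    else if (ch == "]") depth <- depth - 1L
    else if (depth == 0L) {
      two <- substr(pattern, i, i + 1L)
      if (two %in% c("Cl", "Br")) {
        out <- c(out, two); i <- i + 1L
      } else if (ch %in% c("N", "O", "S", "P", "F", "I")) {
        out <- c(out, ch)
      } else if (ch %in% c("n", "o", "s", "p")) {
        out <- c(out, toupper(ch))
      }
    }
    i <- i + 1L
  }
  unique(out)
}

.dg_alert_required <- NULL

alert_required_elements <- function() {
  if (is.null(.dg_alert_required)) {
    req <- lapply(.dg_alert_smarts, smarts_required_elements)
    utils::assignInMyNamespace(".dg_alert_required", req)
  }
  .dg_alert_required
}

cached_alerts <- function(canon) {
  vals <- cache_fetch(canon, "alerts", function(todo) {
    refs <- cached_refs(todo)
    graphs <- cached_graphs(todo)
    elems <- lapply(graphs, function(g) unique(g$atoms$element))
    req <- alert_required_elements()
    hits <- integer(length(todo))
    for (p in seq_along(.dg_alert_smarts)) {
      need <- req[[p]]
      idx <- if (length(need) == 0L) seq_along(todo) else
        which(vapply(elems, function(e) all(need %in% e), logical(1)))
      if (length(idx) == 0L) next
      hits[idx] <- hits[idx] +
        as.integer(ob_smarts_has(refs[idx], .dg_alert_smarts[p]))
    }
    for (k in seq_len(nrow(.dg_alert_counts))) {
      cnt <- ob_smarts_count(refs, .dg_alert_counts$smarts[k])
      hits <- hits + as.integer(cnt >= .dg_alert_counts$min_count[k])
    }
    as.list(hits)
  })
  unlist(vals)
}

#' Quantitative estimate of drug-likeness (QED)
#'
#' Weighted geometric mean of desirability values for eight properties:
#' molecular weight, logP, H-bond acceptors, H-bond donors, polar
#' surface area, rotatable bonds, aromatic rings and structural-alert
#' count. Ranges over \[0, 1\]; higher is more drug-like.
#'
#' @param x character vector of SMILES, or a [molecule()].
#' @return numeric vector of QED values in \[0, 1\].
#' @examples
#' \donttest{
#' qed_score("CC(=O)Nc1ccc(O)cc1") > qed_score("c1ccccc1")
#' }
#' @export
qed_score <- function(x) {
  canon <- as_canonical(x)
  vals <- cache_fetch(canon, "qed", function(todo) {
    tab <- cached_properties(todo)
    alerts <- cached_alerts(todo)
    props <- cbind(
      MW = tab[, "mw"], ALOGP = tab[, "logp"], HBA = tab[, "hba"],
      HBD = tab[, "hbd"], PSA = tab[, "tpsa"],
      ROTB = tab[, "rotatable_bonds"], AROM = tab[, "aromatic_rings"],
      ALERTS = alerts
    )
    w <- .dg_qed_weights
    out <- vapply(seq_len(nrow(props)), function(i) {
      d <- vapply(seq_len(8L), function(j) {
        max(ads(props[i, j], .dg_ads[j, ]), 1e-9)
      }, numeric(1))
      exp(sum(w * log(d)) / sum(w))
    }, numeric(1))
    as.list(out)
  })
  unlist(vals)
}
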