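# Quantitative estimate of drug-likeness (QED): the weighted geometric mean of
# eight desirability functions (molecular weight, ALOGP, H-bond acceptors and
# donors, polar surface area, rotatable bonds, aromatic rings, structural
# alerts), each an asymmetric double-sigmoid (ADS) fitted to the property
# distribution of approved oral drugs. The ADS constants and default weights
# below are the published values of the original QED formulation; descriptors
# are computed with OpenBabel, so absolute values can differ slightly from
# other toolkits while remaining deterministic and internally consistent.

QED_ADS <- list(
  MW     = c(a = 2.817065973, b = 392.5754953,  c = 290.7489764,  d = 2.419764353,
             e = 49.22325677, f = 65.37051707,  dmax = 104.9805561),
  ALOGP  = c(a = 3.172690585, b = 137.8624751,  c = 2.534937431,  d = 4.581497897,
             e = 0.822739154, f = 0.576295591,  dmax = 131.3186604),
  HBA    = c(a = 2.948620388, b = 160.4605972,  c = 3.615294657,  d = 4.435986202,
             e = 0.290141953, f = 1.300669958,  dmax = 148.7763046),
  HBD    = c(a = 1.618662227, b = 1010.051101,  c = 0.985094388,  d = 1e-09,
             e = 0.713820843, f = 0.920922555,  dmax = 258.1632616),
  PSA    = c(a = 1.876861559, b = 125.2232657,  c = 62.90773554,  d = 87.83366614,
             e = 12.01999824, f = 28.51324732,  dmax = 104.5686167),
  ROTB   = c(a = 0.01,        b = 272.4121427,  c = 2.55837997,   d = 1.565547684,
             e = 1.271567166, f = 2.758063707,  dmax = 105.4420403),
  AROM   = c(a = 3.21778897,  b = 957.7374108,  c = 2.274627939,  d = 1e-09,
             e = 1.317690384, f = 0.375760881,  dmax = 312.337261),
  ALERTS = c(a = 0.01,        b = 1199.094025,  c = -0.09002883,  d = 1e-09,
             e = 0.185904477, f = 0.875193782,  dmax = 417.725314))

QED_WEIGHTS_MEAN <- c(MW = 0.66, ALOGP = 0.46, HBA = 0.05, HBD = 0.61,
                      PSA = 0.06, ROTB = 0.65, AROM = 0.48, ALERTS = 0.95)

ROTB_SMARTS <- "[!$(*#*)&!D1]-!@[!$(*#*)&!D1]"
AROM_RING_SMARTS <- c("a1aaa1", "a1aaaa1", "a1aaaaa1", "a1aaaaaa1", "a1aaaaaaa1")

# Published structural-alert SMARTS of the QED formulation (component-level
# patterns containing "." are omitted: the SMARTS engine in use rejects them).
QED_ALERT_SMARTS <- c(
  "*1[O,S,N]*1", "[S,C](=[O,S])[F,Br,Cl,I]", "[CX4][Cl,Br,I]", "[#6]S(=O)(=O)O[#6]",
  "[$([CH]),$(CC)]#CC(=O)[#6]", "[$([CH]),$(CC)]#CC(=O)O[#6]", "n[OH]",
  "[$([CH]),$(CC)]#CS(=O)(=O)[#6]", "C=C(C=O)C=O", "n1c([F,Cl,Br,I])cccc1", "[CH1](=O)",
  "[#8][#8]", "[C;!R]=[N;!R]", "[N!R]=[N!R]", "[#6](=O)[#6](=O)", "[#16][#16]", "[#7][NH2]",
  "C(=O)N[NH2]", "[#6]=S",
  "[$([CH2]),$([CH][CX4]),$(C([CX4])[CX4])]=[$([CH2]),$([CH][CX4]),$(C([CX4])[CX4])]",
  "C1(=[O,N])C=CC(=[O,N])C=C1", "C1(=[O,N])C(=[O,N])C=CC=C1", "a21aa3a(aa1aaaa2)aaaa3",
  "a31a(a2a(aa1)aaaa2)aaaa3", "a1aa2a3a(a1)A=AA=A3=AA=A2", "c1cc([NH2])ccc1",
  "[Hg,Fe,As,Sb,Zn,Se,se,Te,B,Si,Na,Ca,Ge,Ag,Mg,K,Ba,Sr,Be,Ti,Mo,Mn,Ru,Pd,Ni,Cu,Au,Cd,Al,Ga,Sn,Rh,Tl,Bi,Nb,Li,Pb,Hf,Ho]",
  "I", "OS(=O)(=O)[O-]", "[N+](=O)[O-]", "C(=O)N[OH]", "C1NC(=O)NC(=O)1", "[SH]", "[S-]",
  "c1ccc([Cl,Br,I,F])c([Cl,Br,I,F])c1[Cl,Br,I,F]",
  "c1cc([Cl,Br,I,F])cc([Cl,Br,I,F])c1[Cl,Br,I,F]", "[CR1]1[CR1][CR1][CR1][CR1][CR1][CR1]1",
  "[CR1]1[CR1][CR1]cc[CR1][CR1]1", "[CR2]1[CR2][CR2][CR2][CR2][CR2][CR2][CR2]1",
  "[CR2]1[CR2][CR2]cc[CR2][CR2][CR2]1", "[CH2R2]1N[CH2R2][CH2R2][CH2R2][CH2R2][CH2R2]1",
  "[CH2R2]1N[CH2R2][CH2R2][CH2R2][CH2R2][CH2R2][CH2R2]1", "C#C",
  "[OR2,NR2]@[CR2]@[CR2]@[OR2,NR2]@[CR2]@[CR2]@[OR2,NR2]",
  "[$([N+R]),$([n+R]),$([N+]=C)][O-]", "[#6]=N[OH]", "[#6]=NOC=O",
  "[#6](=O)[CX4,CR0X3,O][#6](=O)", "c1ccc2c(c1)ccc(=O)o2", "[O+,o+,S+,s+]", "N=C=O",
  "[NX3,NX4][F,Cl,Br,I]", "c1ccccc1OC(=O)[#6]", "[CR0]=[CR0][CR0]=[CR0]", "[C+,c+,C-,c-]",
  "N=[N+]=[N-]", "C12C(NC(N1)=O)CSC2", "c1c([OH])c([OH,NH2,NH])ccc1", "P", "[N,O,S]C#N",
  "C=C=O", "[Si][F,Cl,Br,I]", "[SX2]O", "[SiR0,CR0](c1ccccc1)(c2ccccc2)(c3ccccc3)",
  "O1CCCCC1OC2CCC3CCCCC3C2", "N=[CR0][N,n,O,S]",
  "[cR2]1[cR2][cR2]([Nv3X3,Nv4X4])[cR2][cR2][cR2]1[cR2]2[cR2][cR2][cR2]([Nv3X3,Nv4X4])[cR2][cR2]2",
  "C=[C!r]C#N", "[cR2]1[cR2]c([N+0X3R0,nX3R0])c([N+0X3R0,nX3R0])[cR2][cR2]1",
  "[cR2]1[cR2]c([N+0X3R0,nX3R0])[cR2]c([N+0X3R0,nX3R0])[cR2]1",
  "[cR2]1[cR2]c([N+0X3R0,nX3R0])[cR2][cR2]c1([N+0X3R0,nX3R0])", "[OH]c1ccc([OH,NH2,NH])cc1",
  "c1ccccc1OC(=O)O", "[SX2H0][N]", "c12ccccc1(SC(S)=N2)", "c12ccccc1(SC(=S)N2)", "c1nnnn1C=O",
  "s1c(S)nnc1NC=O", "S1C=CSC1=S", "C(=O)Onnn", "OS(=O)(=O)C(F)(F)F", "N#CC[OH]", "N#CC(=O)",
  "S(=O)(=O)C#N", "N[CH2]C#N", "C1(=O)NCC1", "S(=O)(=O)[O-,OH]", "NC[F,Cl,Br,I]", "C=[C!r]O",
  "[NX2+0]=[O+0]", "[OR0,NR0][OR0,NR0]", "[CX2R0][NX3R0]", "c1ccccc1[C;!R]=[C;!R]c2ccccc2",
  "[NX3R0,NX4R0,OR0,SX2R0][CX4][NX3R0,NX4R0,OR0,SX2R0]",
  "[s,S,c,C,n,N,o,O]~[n+,N+](~[s,S,c,C,n,N,o,O])(~[s,S,c,C,n,N,o,O])~[s,S,c,C,n,N,o,O]",
  "[s,S,c,C,n,N,o,O]~[nX3+,NX3+](~[s,S,c,C,n,N])~[s,S,c,C,n,N]", "[*]=[N+]=[*]",
  "[SX3](=O)[O-,OH]", "N#N", "[R0;D2][R0;D2][R0;D2][R0;D2]", "[cR,CR]~C(=O)NC(=O)~[cR,CR]",
  "C=!@CC=[O,S]", "[#6,#8,#16][#6](=O)O[#6]", "c[C;R0](=[O,S])[#6]", "c[SX2][C;!R]", "C=C=C",
  "c1nc([F,Cl,Br,I,S])ncc1", "c1ncnc([F,Cl,Br,I,S])c1", "c1nc(c2c(n1)nc(n2)[F,Cl,Br,I])",
  "[#6]S(=O)(=O)c1ccc(cc1)F", "[15N]", "[13C]", "[18O]", "[34S]")

ads <- function(x, p) {
  exp1 <- 1 + exp(-(x - p["c"] + p["d"] / 2) / p["e"])
  exp2 <- 1 + exp(-(x - p["c"] - p["d"] / 2) / p["f"])
  unname((p["a"] + p["b"] / exp1 * (1 - 1 / exp2)) / p["dmax"])
}

#' QED property profile
#'
#' Computes the eight QED descriptors per molecule: molecular weight, ALOGP,
#' hydrogen-bond acceptor and donor counts, topological polar surface area,
#' rotatable-bond count, aromatic-ring count, and structural-alert count.
#'
#' @param smiles character vector of valid SMILES.
#' @return data.frame with columns MW, ALOGP, HBA, HBD, PSA, ROTB, AROM,
#'   ALERTS.
#' @export
qed_properties <- function(smiles) {
  syn <- vapply(smiles, smiles_syntax_ok, logical(1), USE.NAMES = FALSE)
  if (!all(syn))
    stop("invalid molecule(s): ",
         paste(utils::head(smiles[!syn], 5), collapse = ", "))
  refs <- ob_mol_refs(smiles)
  pr <- ob_props(refs)
  rotb <- ob_smarts_count(refs, ROTB_SMARTS)
  arom <- Reduce(`+`, lapply(AROM_RING_SMARTS, function(s) ob_smarts_count(refs, s)))
  alerts <- Reduce(`+`, lapply(QED_ALERT_SMARTS,
                               function(s) as.integer(ob_smarts_count(refs, s) > 0L)))
  data.frame(MW = pr$MW, ALOGP = pr$logP, HBA = pr$HBA1, HBD = pr$HBD,
             PSA = pr$TPSA, ROTB = rotb, AROM = arom, ALERTS = alerts)
}

.qed_cache <- new.env(parent = emptyenv())

#' Quantitative estimate of drug-likeness
#'
#' Weighted geometric mean of the eight ADS-mapped QED descriptors; values lie
#' in `[0, 1]`, higher is more drug-like. Deterministic per molecule and
#' invariant to the SMILES spelling (properties are computed on the parsed
#' structure). Results are memoised per SMILES string.
#'
#' @param smiles character vector of valid SMILES.
#' @param weights named weight vector over the eight properties; the default
#'   is the standard mean-weight set.
#' @return numeric vector of QED values in `[0, 1]`.
#' @export
compute_qed <- function(smiles, weights = QED_WEIGHTS_MEAN) {
  stopifnot(is.character(smiles))
  if (length(smiles) == 0L) return(numeric(0))
  out <- rep(NA_real_, length(smiles))
  key <- paste0("q:", smiles)
  cached <- vapply(key, function(k) exists(k, envir = .qed_cache), logical(1))
  default_w <- identical(weights, QED_WEIGHTS_MEAN)
  if (any(cached) && default_w)
    out[cached] <- vapply(key[cached], function(k) get(k, envir = .qed_cache),
                          numeric(1))
  todo <- if (default_w) which(!cached) else seq_along(smiles)
  todo <- todo[!duplicated(smiles[todo])]
  if (length(todo) > 0L) {
    props <- qed_properties(smiles[todo])
    if (anyNA(props$MW))
      stop("invalid molecule(s): ",
           paste(utils::head(smiles[todo][is.na(props$MW)], 5), collapse = ", "))
    d <- vapply(names(QED_ADS), function(nm) {
      pmin(pmax(ads(props[[nm]], QED_ADS[[nm]]), 1e-12), 1)
    }, numeric(nrow(props)))
    d <- matrix(d, nrow = nrow(props))
    w <- weights[names(QED_ADS)]
    q <- exp(as.vector(log(d) %*% w) / sum(w))
    for (i in seq_along(todo)) {
      hit <- smiles == smiles[todo[i]]
      out[hit] <- q[i]
      if (default_w) assign(key[todo[i]][1], q[i], envir = .qed_cache)
    }
  }
  out
}
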