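# SMILES parsing through OpenBabel (ChemmineOB). OpenBabel is the format
# toolkit here: it canonicalizes, perceives aromaticity and generates the 2D
# depiction coordinates. Its V2000/MOL2 text output is decoded by the two
# small readers below (the installed SDF container class rejects molecules
# with zero bonds, which single-heavy-atom inputs legitimately produce).

# Standard element symbols indexed by atomic number 1..118.
.ELEMENTS <- c(
  "H", "He", "Li", "Be", "B", "C", "N", "O", "F", "Ne", "Na", "Mg", "Al",
  "Si", "P", "S", "Cl", "Ar", "K", "Ca", "Sc", "Ti", "V", "Cr", "Mn", "Fe",
  "Co", "Ni", "Cu", "Zn", "Ga", "Ge", "As", "Se", "Br", "Kr", "Rb", "Sr",
  "Y", "Zr", "Nb", "Mo", "Tc", "Ru", "Rh", "Pd", "Ag", "Cd", "In", "Sn",
  "Sb", "Te", "I", "Xe", "Cs", "Ba", "La", "Ce", "Pr", "Nd", "Pm", "Sm",
  "Eu", "Gd", "Tb", "Dy", "Ho", "Er", "Tm", "Yb", "Lu", "Hf", "Ta", "W",
  "Re", "Os", "Ir", "Pt", "Au", "Hg", "Tl", "Pb", "Bi", "Po", "At", "Rn",
  "Fr", "Ra", "Ac", "Th", "Pa", "U", "Np", "Pu", "Am", "Cm", "Bk", "Cf",
  "Es", "Fm", "Md", "No", "Lr", "Rf", "Db", "Sg", "Bh", "Hs", "Mt", "Ds",
  "Rg", "Cn", "Nh", "Fl", "Mc", "Lv", "Ts", "Og")

.atomicNumber <- function(symbol) match(symbol, .ELEMENTS)

.obConvert <- function(from, to, source) {
  out <- tryCatch(
    suppressWarnings(ChemmineOB::convertFormat(from, to, source = source)),
    error = function(e) "")
  if (!is.character(out) || length(out) != 1L) "" else out
}

#' Canonical SMILES of a molecule
#'
#' Canonicalization dialect is the parsing toolkit's (OpenBabel). Returns
#' `NA_character_` for strings the toolkit cannot parse.
#'
#' @param smiles character vector of SMILES strings.
#' @return character vector of canonical SMILES, `NA` where unparseable.
#' @examples
#' canonicalizeSmiles(c("CCO", "OCC"))
#' @export
canonicalizeSmiles <- function(smiles) {
  vapply(smiles, function(s) {
    if (is.na(s) || !nzchar(s)) return(NA_character_)
    out <- .obConvert("SMI", "CAN", s)
    out <- sub("[ \t\r\n].*$", "", out)
    if (!nzchar(out)) NA_character_ else out
  }, character(1), USE.NAMES = FALSE)
}

# Decode a V2000 molblock: atoms (symbol, x, y, charge code, parity) and
# bonds (from, to, order). Old-style charge codes: 1->+3 ... 3->+1, 5->-1,
# 6->-2, 7->-3; 4 is a radical flag, treated as charge 0.
.parseV2000 <- function(text) {
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  counts <- lines[4]
  na <- as.integer(substr(counts, 1, 3))
  nb <- as.integer(substr(counts, 4, 6))
  if (is.na(na)) stop("malformed molblock")
  atoms <- lines[seq_len(na) + 4L]
  symbol <- character(na); x <- numeric(na); y <- numeric(na)
  charge <- integer(na); parity <- integer(na)
  for (i in seq_len(na)) {
    f <- strsplit(trimws(atoms[i]), "[ \t]+")[[1]]
    x[i] <- as.numeric(f[1]); y[i] <- as.numeric(f[2])
    symbol[i] <- f[4]
    code <- as.integer(f[6])
    charge[i] <- if (is.na(code) || code == 0L || code == 4L) 0L else 4L - code
    parity[i] <- if (length(f) >= 7) as.integer(f[7]) else 0L
  }
  from <- integer(nb); to <- integer(nb); order <- integer(nb)
  if (nb > 0) {
    bonds <- lines[seq_len(nb) + 4L + na]
    for (i in seq_len(nb)) {
      from[i] <- as.integer(substr(bonds[i], 1, 3))
      to[i] <- as.integer(substr(bonds[i], 4, 6))
      order[i] <- as.integer(substr(bonds[i], 7, 9))
    }
  }
  # "M  CHG" property lines override old-style codes when present
  chg <- grep("^M  CHG", lines, value = TRUE)
  for (ln in chg) {
    f <- as.integer(strsplit(trimws(sub("^M  CHG", "", ln)), "[ \t]+")[[1]])
    k <- f[1]
    for (j in seq_len(k)) charge[f[2 * j]] <- f[2 * j + 1]
  }
  list(symbol = symbol, x = x, y = y, charge = charge, parity = parity,
       from = from, to = to, order = order)
}

# Decode a MOL2 block: SYBYL atom types and bond types (1/2/3/am/ar/...).
.parseMol2 <- function(text) {
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  ai <- grep("^@<TRIPOS>ATOM", lines)[1]
  bi <- grep("^@<TRIPOS>BOND", lines)[1]
  sections <- grep("^@<TRIPOS>", lines)
  aEnd <- min(c(sections[sections > ai], length(lines) + 1L)) - 1L
  bEnd <- min(c(sections[sections > bi], length(lines) + 1L)) - 1L
  atomLines <- lines[seq(ai + 1L, aEnd)]
  atomLines <- atomLines[nzchar(trimws(atomLines))]
  sybyl <- vapply(atomLines,
                  function(l) strsplit(trimws(l), "[ \t]+")[[1]][6],
                  character(1), USE.NAMES = FALSE)
  bondType <- character(0); bFrom <- integer(0); bTo <- integer(0)
  if (!is.na(bi) && bi + 1L <= bEnd) {
    bondLines <- lines[seq(bi + 1L, bEnd)]
    bondLines <- bondLines[nzchar(trimws(bondLines))]
    if (length(bondLines)) {
      parts <- lapply(bondLines, function(l) strsplit(trimws(l), "[ \t]+")[[1]])
      bFrom <- vapply(parts, function(p) as.integer(p[2]), integer(1))
      bTo <- vapply(parts, function(p) as.integer(p[3]), integer(1))
      bondType <- vapply(parts, function(p) p[4], character(1))
    }
  }
  list(sybyl = sybyl, from = bFrom, to = bTo, type = bondType)
}

# Hybridization from the SYBYL atom type.
.hybridFromSybyl <- function(sybyl) {
  suffix <- sub("^[A-Za-z]+", "", sybyl)
  base <- sub("\\..*$", "", sybyl)
  if (suffix %in% c(".1")) return("sp")
  if (suffix %in% c(".2", ".ar", ".am", ".pl3", ".co2", ".cat")) return("sp2")
  if (suffix %in% c(".3", ".o", ".o2", ".t3", ".th")) return("sp3")
  if (base %in% c("F", "Cl", "Br", "I", "O", "N", "S", "P", "C")) return("sp3")
  "other"
}

# Bond-in-ring: an edge lies on a cycle iff it is not a bridge, i.e. its
# endpoints stay connected after removing it (BFS on the remaining bonds).
.ringBonds <- function(nAtoms, from, to) {
  nb <- length(from)
  if (nb == 0) return(logical(0))
  adj <- vector("list", nAtoms)
  for (b in seq_len(nb)) {
    adj[[from[b]]] <- c(adj[[from[b]]], b)
    adj[[to[b]]] <- c(adj[[to[b]]], b)
  }
  vapply(seq_len(nb), function(b) {
    start <- from[b]; goal <- to[b]
    seen <- rep(FALSE, nAtoms); seen[start] <- TRUE
    queue <- start
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (bb in adj[[v]]) {
        if (bb == b) next
        w <- if (from[bb] == v) to[bb] else from[bb]
        if (!seen[w]) {
          if (w == goal) return(TRUE)
          seen[w] <- TRUE
          queue <- c(queue, w)
        }
      }
    }
    FALSE
  }, logical(1))
}

# Geometry-based cis/trans call for acyclic double bonds carrying SMILES
# directional markers: reference substituents on the same side of the 2D
# double-bond axis -> cis, opposite sides -> trans.
.assignCisTrans <- function(parsed, inRing, neighbours) {
  stereo <- rep("none", length(parsed$from))
  for (b in seq_along(parsed$from)) {
    if (parsed$order[b] != 2L || inRing[b]) next
    a1 <- parsed$from[b]; a2 <- parsed$to[b]
    s1 <- setdiff(neighbours[[a1]], a2)
    s2 <- setdiff(neighbours[[a2]], a1)
    if (!length(s1) || !length(s2)) next
    r1 <- min(s1); r2 <- min(s2)
    v <- c(parsed$x[a2] - parsed$x[a1], parsed$y[a2] - parsed$y[a1])
    w1 <- c(parsed$x[r1] - parsed$x[a1], parsed$y[r1] - parsed$y[a1])
    w2 <- c(parsed$x[r2] - parsed$x[a2], parsed$y[r2] - parsed$y[a2])
    c1 <- v[1] * w1[2] - v[2] * w1[1]
    c2 <- v[1] * w2[2] - v[2] * w2[1]
    if (c1 == 0 || c2 == 0) next
    stereo[b] <- if (sign(c1) == sign(c2)) "cis" else "trans"
  }
  stereo
}

# Full per-molecule parse: elements, charges, chirality tags, hybridization,
# aromatic flags, coordinates and a bond table. Returns NULL if unparseable.
.parseSmiles <- function(smiles) {
  sdfText <- .obConvert("SMI", "SDF", smiles)
  if (!nzchar(sdfText) || !grepl("V2000", sdfText)) return(NULL)
  parsed <- tryCatch(.parseV2000(sdfText), error = function(e) NULL)
  if (is.null(parsed)) return(NULL)
  mol2Text <- .obConvert("SMI", "MOL2", smiles)
  mol2 <- tryCatch(.parseMol2(mol2Text), error = function(e) NULL)
  if (is.null(mol2) || length(mol2$sybyl) != length(parsed$symbol)) return(NULL)
  canonical <- canonicalizeSmiles(smiles)
  if (is.na(canonical)) return(NULL)

  n <- length(parsed$symbol)
  nb <- length(parsed$from)
  neighbours <- vector("list", n)
  for (b in seq_len(nb)) {
    neighbours[[parsed$from[b]]] <- c(neighbours[[parsed$from[b]]], parsed$to[b])
    neighbours[[parsed$to[b]]] <- c(neighbours[[parsed$to[b]]], parsed$from[b])
  }
  inRing <- .ringBonds(n, parsed$from, parsed$to)

  # aromatic bonds: SYBYL "ar" restricted to ring bonds (OpenBabel also tags
  # e.g. carboxylates "ar", which are not aromatic rings)
  key <- function(i, j) paste(pmin(i, j), pmax(i, j))
  arKeys <- character(0)
  if (length(mol2$type))
    arKeys <- key(mol2$from, mol2$to)[mol2$type == "ar"]
  bondAromatic <- inRing & (key(parsed$from, parsed$to) %in% arKeys)

  atomAromatic <- rep(FALSE, n)
  for (b in which(bondAromatic)) {
    atomAromatic[parsed$from[b]] <- TRUE
    atomAromatic[parsed$to[b]] <- TRUE
  }
  atomAromatic <- atomAromatic | grepl("\\.ar$", mol2$sybyl)

  hybrid <- vapply(mol2$sybyl, .hybridFromSybyl, character(1), USE.NAMES = FALSE)
  hybrid[atomAromatic & hybrid == "sp3"] <- "sp2"

  chirality <- rep("unspecified", n)
  chirality[parsed$parity == 1L] <- "R"
  chirality[parsed$parity == 2L] <- "S"
  chirality[parsed$parity == 3L] <- "unrecognized"

  stereo <- if (grepl("[/\\\\]", smiles))
    .assignCisTrans(parsed, inRing, neighbours) else rep("none", nb)

  order <- rep("single", nb)
  order[parsed$order == 2L] <- "double"
  order[parsed$order == 3L] <- "triple"
  order[bondAromatic] <- "aromatic"

  degree <- vapply(neighbours, length, integer(1))

  list(smiles = smiles, canonical = canonical, elements = parsed$symbol,
       charge = parsed$charge, chirality = chirality, hybrid = hybrid,
       aromatic = atomAromatic, degree = degree,
       coords = cbind(x = parsed$x, y = parsed$y),
       bonds = data.frame(from = parsed$from, to = parsed$to,
                          order = order, ring = inRing, stereo = stereo,
                          stringsAsFactors = FALSE))
}
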