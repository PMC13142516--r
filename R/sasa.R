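# Solvent-accessible surface area and interface labeling.
#
# Interface residues are defined operationally: a residue of the focal chain
# is an interface site if its relative solvent accessibility (RSA) drops by
# more than 4 percentage points when the complex is separated into isolated
# chains (strict inequality). SASA is estimated with the Shrake-Rupley
# method: a deterministic quasi-uniform point set on each atom's
# probe-expanded sphere, counting points not buried inside any neighbouring
# expanded sphere.

# van der Waals radii (Angstrom) per element.
ELEMENT_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
                   H = 1.20, SE = 1.90)
DEFAULT_RADIUS <- 1.70

#' Maximum accessible surface areas (theoretical, Angstrom^2)
#'
#' Residue-type maxima used to normalise SASA into relative solvent
#' accessibility. The default is the theoretical (Gly-X-Gly) set of Tien et
#' al.; any named vector over three-letter codes can be substituted.
#'
#' @return Named numeric vector (three-letter residue codes).
#' @export
maxAsaTable <- function() {
  c(ALA = 129.0, ARG = 274.0, ASN = 195.0, ASP = 193.0, CYS = 167.0,
    GLN = 225.0, GLU = 223.0, GLY = 104.0, HIS = 224.0, ILE = 197.0,
    LEU = 201.0, LYS = 236.0, MET = 224.0, PHE = 240.0, PRO = 159.0,
    SER = 155.0, THR = 172.0, TRP = 285.0, TYR = 263.0, VAL = 174.0,
    UNK = 203.0)
}

# Deterministic quasi-uniform unit-sphere points (golden-section spiral).
spherePoints <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' Per-residue absolute SASA of one or more chains considered together. Each
#' atom's sphere of radius `r + probeRadius` is sampled at `nPoints`
#' deterministic spiral points; the exposed fraction times the sphere area is
#' the atom's SASA and residues sum their atoms. Hydrogens are expected to
#' have been excluded upstream (the PDB reader drops them).
#'
#' @param chains A [ChainStructure-class] or list of them; all atoms of all
#'   chains occlude each other.
#' @param probeRadius Solvent probe radius in Angstrom (default 1.4).
#' @param nPoints Sphere sample points per atom (default 960).
#' @return Named list mapping `chainId` to a numeric vector of per-residue
#'   SASA (Angstrom^2) in chain residue order.
#' @export
computeSasa <- function(chains, probeRadius = 1.4, nPoints = 960L) {
  if (is(chains, "ChainStructure")) chains <- list(chains)
  atoms <- do.call(rbind, lapply(chains, function(ch) {
    a <- chainAtoms(ch)
    if (nrow(a)) cbind(a, chain = chainId(ch)) else NULL
  }))
  if (is.null(atoms) || nrow(atoms) == 0L)
    stop("input error: no atoms supplied", call. = FALSE)
  pts <- spherePoints(nPoints)
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  rExp <- atoms$radius + probeRadius
  n <- nrow(atoms)
  atomSasa <- numeric(n)
  for (i in seq_len(n)) {
    ri <- rExp[i]
    # candidate occluders: expanded spheres that can reach sphere i
    dx <- sweep(xyz, 2L, xyz[i, ])
    dist2 <- rowSums(dx^2)
    nb <- which(dist2 < (ri + rExp)^2 & seq_len(n) != i)
    sp <- pts * ri + rep(xyz[i, ], each = nPoints)
    exposed <- rep(TRUE, nPoints)
    for (j in nb) {
      dj <- sweep(sp, 2L, xyz[j, ])
      exposed <- exposed & (rowSums(dj^2) > rExp[j]^2)
      if (!any(exposed)) break
    }
    atomSasa[i] <- sum(exposed) / nPoints * 4 * pi * ri^2
  }
  out <- list()
  for (ch in chains) {
    sel <- atoms$chain == chainId(ch)
    res <- numeric(nResidues(ch))
    if (any(sel)) {
      agg <- tapply(atomSasa[sel], atoms$resIdx[sel], sum)
      res[as.integer(names(agg))] <- agg
    }
    out[[chainId(ch)]] <- res
  }
  out
}

#' Relative solvent accessibility (percent)
#'
#' @param sasa Per-residue absolute SASA (Angstrom^2).
#' @param resNames Three-letter residue codes, same length.
#' @param table Named maxASA vector; see [maxAsaTable()].
#' @param cap Cap RSA at 100 percent (default FALSE).
#' @return Per-residue RSA in percent.
#' @export
residueRsa <- function(sasa, resNames, table = maxAsaTable(), cap = FALSE) {
  maxasa <- table[resNames]
  unknown <- is.na(maxasa)
  if (any(unknown)) {
    warning("unknown residue type(s) ",
            paste(unique(resNames[unknown]), collapse = ","),
            "; using generic UNK maxASA")
    maxasa[unknown] <- table[["UNK"]]
  }
  rsa <- 100 * sasa / unname(maxasa)
  if (cap) rsa <- pmin(rsa, 100)
  rsa
}

#' Interface labels on a focal chain from complex separation
#'
#' Computes per-residue RSA of the focal chain twice — once within the full
#' complex and once with the focal chain isolated — and labels residue i an
#' interface site iff `RSA_isolated(i) - RSA_in_complex(i) > threshold`
#' (strict; a residue at exactly the threshold is not labeled).
#'
#' @param chains List of [ChainStructure-class] forming the complex.
#' @param focalChain `chainId` of the chain to label.
#' @param threshold Delta-RSA threshold in percentage points (default 4.0).
#' @param probeRadius,nPoints Passed to [computeSasa()].
#' @param table maxASA normalisation table.
#' @return List with `labels` (0/1 per focal residue), `deltaRsa`,
#'   `rsaIsolated`, `rsaComplex`.
#' @export
deltaRsaLabels <- function(chains, focalChain, threshold = 4.0,
                           probeRadius = 1.4, nPoints = 960L,
                           table = maxAsaTable()) {
  ids <- vapply(chains, chainId, character(1))
  if (!focalChain %in% ids)
    stop("focal chain ", focalChain, " not present in complex", call. = FALSE)
  focal <- chains[[match(focalChain, ids)]]
  resNames <- chainResidues(focal)$resName
  sasaC <- computeSasa(chains, probeRadius, nPoints)[[focalChain]]
  sasaI <- computeSasa(focal, probeRadius, nPoints)[[focalChain]]
  rsaC <- residueRsa(sasaC, resNames, table)
  rsaI <- residueRsa(sasaI, resNames, table)
  delta <- rsaI - rsaC
  list(labels = as.integer(delta > threshold), deltaRsa = delta,
       rsaIsolated = rsaI, rsaComplex = rsaC)
}
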