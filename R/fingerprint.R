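#' @include AllClasses.R backends.R
NULL

#' Morgan (ECFP) fingerprint of one compound
#'
#' Hashed circular fingerprint: each bit flags an atom-centred substructure
#' environment up to \code{radius} bonds from the central atom (radius 2 is
#' the conventional ECFP4). Environments are enumerated and hashed by the
#' cheminformatics toolkit (OpenBabel via ChemmineOB) into a 4096-bit
#' vector, then folded by OR onto \code{nBits} positions.
#'
#' @param record A \linkS4class{CompoundRecord}, or a SMILES string.
#' @param radius environment radius in bonds (0..5). Default 2.
#' @param nBits fingerprint length after folding. Default 2048.
#' @return Named integer vector of length \code{nBits} over \{0, 1\}, names
#'   \code{fp_0001...}. Deterministic for a fixed input.
#' @export
computeFingerprint <- function(record, radius = 2L, nBits = 2048L) {
  smiles <- if (methods::is(record, "CompoundRecord")) record@smiles else record
  radius <- .assert_count(radius, "radius")
  nBits <- .assert_count(nBits, "nBits", min = 1L)
  if (radius > 5L)
    .validation_error("radius: toolkit supports radii 0..5", field = "radius")
  bits <- .with_mol(smiles, function(mol)
    ChemmineOB::fingerprint_OB(mol, sprintf("ECFP%d", 2L * radius)))
  raw_bits <- which(bits == 1)
  out <- integer(nBits)
  if (length(raw_bits)) out[unique((raw_bits - 1L) %% nBits + 1L)] <- 1L
  names(out) <- .feature_names("fp", nBits)
  out
}
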