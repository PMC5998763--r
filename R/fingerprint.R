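# Hashed path fingerprints (RDKit bridge) and Tanimoto similarity.
# Fingerprints are stored sparsely as sorted 1-based on-bit positions.

#' Compute hashed path fingerprints
#'
#' Deterministic, canonicalization-invariant hashed path fingerprints
#' (CDK-style: bond-order sensitive, hydrogens removed). Two SMILES spellings
#' of the same molecule yield bit-identical fingerprints.
#'
#' @param smiles character vector of SMILES (NAs allowed).
#' @param length fingerprint length in bits (identical across a run).
#' @return list of `fingerprint` objects (or NA for absent/unparsable
#'   structures, the missing-structure signal): each has `on_bits` (sorted
#'   integer positions), `length`, `n_set`.
#' @export
compute_fingerprint <- function(smiles, length = 1024L) {
  length <- as.integer(length)
  stopifnot(length > 0)
  res <- chem_lookup(smiles, fp_length = length)
  lapply(res, function(r) {
    if (is.na(r$canonical)) return(NA)
    structure(list(on_bits = sort(unique(r$bits)), length = length,
                   n_set = base::length(unique(r$bits))),
              class = "fingerprint")
  })
}

#' Construct a fingerprint from explicit bit positions
#'
#' Mostly useful for tests and for Tanimoto on synthetic bit vectors.
#'
#' @param on_bits integer positions of set bits (1-based).
#' @param length total bit-vector length.
#' @return a `fingerprint`.
#' @export
fingerprint <- function(on_bits, length = 1024L) {
  on_bits <- sort(unique(as.integer(on_bits)))
  if (base::length(on_bits) > 0 &&
      (min(on_bits) < 1 || max(on_bits) > length)) {
    stop("on_bits outside [1, length]", call. = FALSE)
  }
  structure(list(on_bits = on_bits, length = as.integer(length),
                 n_set = base::length(on_bits)),
            class = "fingerprint")
}

#' @export
print.fingerprint <- function(x, ...) {
  cat("fingerprint:", x$n_set, "of", x$length, "bits set\n")
  invisible(x)
}

#' Tanimoto similarity of two fingerprints
#'
#' For binary vectors the Tanimoto coefficient
#' \eqn{\sum x_A x_B / (\sum x_A^2 + \sum x_B^2 - \sum x_A x_B)} reduces to
#' \eqn{|A \cap B| / |A \cup B|} over the set-bit positions. Two all-zero
#' fingerprints (the 0/0 case) are defined to have similarity 0: a
#' structureless match carries no evidence.
#'
#' @param fp_a,fp_b `fingerprint`s of equal length.
#' @return similarity in \[0, 1\]; symmetric.
#' @export
tanimoto <- function(fp_a, fp_b) {
  stopifnot(inherits(fp_a, "fingerprint"), inherits(fp_b, "fingerprint"))
  if (fp_a$length != fp_b$length) {
    stop("fingerprint lengths differ (", fp_a$length, " vs ", fp_b$length, ")",
         call. = FALSE)
  }
  n_common <- length(intersect(fp_a$on_bits, fp_b$on_bits))
  n_union <- fp_a$n_set + fp_b$n_set - n_common
  if (n_union == 0) return(0)
  n_common / n_union
}
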