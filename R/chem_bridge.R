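# Subprocess bridge to RDKit for SMILES canonicalization and hashed path
# fingerprints. Calls are batched (one python start-up per unique request
# set) and memoized for the session, keyed by (smiles, fp_length).

.chem_cache <- new.env(parent = emptyenv())

chem_python <- function() {
  Sys.getenv("NPMATCH_PYTHON", unset = "python")
}

chem_bridge_script <- function() {
  path <- system.file("python", "chem_bridge.py", package = "npmatch")
  if (!nzchar(path)) {
    # devtools::load_all() keeps inst/ unflattened
    path <- system.file("inst", "python", "chem_bridge.py", package = "npmatch")
  }
  if (!nzchar(path)) stop("chem_bridge.py not found in installed package", call. = FALSE)
  path
}

run_chem_bridge <- function(smiles, fp_length) {
  infile <- tempfile(fileext = ".tsv")
  outfile <- tempfile(fileext = ".tsv")
  on.exit(unlink(c(infile, outfile)), add = TRUE)
  writeLines(paste(seq_along(smiles), smiles, sep = "\t"), infile)
  status <- system2(chem_python(),
                    c(shQuote(chem_bridge_script()),
                      "--in", shQuote(infile), "--out", shQuote(outfile),
                      "--fp-size", fp_length),
                    stdout = FALSE, stderr = "")
  if (!identical(status, 0L)) {
    stop("RDKit bridge failed (exit status ", status,
         "); is python with rdkit on PATH?", call. = FALSE)
  }
  lines <- readLines(outfile)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  canon <- vapply(parts, function(p) if (length(p) >= 2) p[[2]] else "", "")
  bits <- lapply(parts, function(p) {
    if (length(p) >= 3 && nzchar(p[[3]])) {
      as.integer(strsplit(p[[3]], " ", fixed = TRUE)[[1]])
    } else integer(0)
  })
  list(canonical = canon, bits = bits)
}

# Returns, for each input SMILES, list(canonical = chr or NA, bits = int vec).
# Unparsable SMILES yield canonical NA and empty bits.
chem_lookup <- function(smiles, fp_length = 1024L) {
  keys <- paste0(fp_length, "|", smiles)
  todo <- !vapply(keys, exists, NA, envir = .chem_cache) & !is.na(smiles)
  uniq <- unique(smiles[todo])
  if (length(uniq) > 0) {
    res <- run_chem_bridge(uniq, fp_length)
    for (i in seq_along(uniq)) {
      assign(paste0(fp_length, "|", uniq[i]),
             list(canonical = if (nzchar(res$canonical[i])) res$canonical[i] else NA_character_,
                  bits = res$bits[[i]]),
             envir = .chem_cache)
    }
  }
  lapply(seq_along(smiles), function(i) {
    if (is.na(smiles[i])) {
      list(canonical = NA_character_, bits = integer(0))
    } else {
      get(keys[i], envir = .chem_cache)
    }
  })
}

# SDF -> data.frame(id, smiles) using the bridge's SDF mode.
read_sdf_smiles <- function(path) {
  outfile <- tempfile(fileext = ".tsv")
  on.exit(unlink(outfile), add = TRUE)
  status <- system2(chem_python(),
                    c(shQuote(chem_bridge_script()),
                      "--in", shQuote(path), "--out", shQuote(outfile), "--sdf"),
                    stdout = FALSE, stderr = "")
  if (!identical(status, 0L)) {
    stop("RDKit bridge failed reading SDF ", path, call. = FALSE)
  }
  lines <- readLines(outfile)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  data.frame(
    id = vapply(parts, `[[`, "", 1L),
    smiles = vapply(parts, function(p) {
      s <- if (length(p) >= 2) p[[2]] else ""
      if (nzchar(s)) s else NA_character_
    }, ""),
    stringsAsFactors = FALSE
  )
}
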