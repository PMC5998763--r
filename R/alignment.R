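# Target similarity: Smith-Waterman local alignment under BLOSUM-62,
# normalized by the geometric mean of the self-alignment scores, then a
# global top-5% filter-and-average across all target pairs of a run.

#' Alignment scoring configuration
#'
#' @param gap_open gap opening penalty (> 0, default 10).
#' @param gap_extend gap extension penalty (> 0, default 0.5).
#' @param substitution_matrix name of the substitution matrix (BLOSUM62).
#' @return an `alignment_config`.
#' @export
alignment_config <- function(gap_open = 10, gap_extend = 0.5,
                             substitution_matrix = "BLOSUM62") {
  if (gap_open <= 0 || gap_extend <= 0) {
    stop("gap penalties must be > 0", call. = FALSE)
  }
  structure(list(gap_open = gap_open, gap_extend = gap_extend,
                 substitution_matrix = substitution_matrix),
            class = "alignment_config")
}

get_substitution_matrix <- function(cfg) {
  name <- cfg$substitution_matrix
  env <- new.env()
  utils::data(list = name, package = "Biostrings", envir = env)
  get(name, envir = env)
}

sw_score <- function(a, b, cfg, mat = NULL) {
  if (is.null(mat)) mat <- get_substitution_matrix(cfg)
  Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b), type = "local",
    substitutionMatrix = mat,
    gapOpening = cfg$gap_open, gapExtension = cfg$gap_extend,
    scoreOnly = TRUE
  )
}

#' Normalized Smith-Waterman similarity between two protein sequences
#'
#' `SW(a, b) / sqrt(SW(a, a) * SW(b, b))`: the local alignment score divided
#' by the geometric mean of the self-alignment scores. Symmetric, and exactly
#' 1 for a self-comparison. Under BLOSUM-62 self-alignment scores are always
#' positive; a non-positive one (guarded anyway) yields NA with a warning.
#'
#' @param seq_a,seq_b amino-acid sequence strings.
#' @param cfg an [alignment_config()].
#' @return similarity in (0, 1\], or NA if a self-alignment score is <= 0.
#' @export
normalized_sw <- function(seq_a, seq_b, cfg = alignment_config()) {
  mat <- get_substitution_matrix(cfg)
  saa <- sw_score(seq_a, seq_a, cfg, mat)
  sbb <- sw_score(seq_b, seq_b, cfg, mat)
  if (saa <= 0 || sbb <= 0) {
    warning("self-alignment score <= 0; normalized SW undefined", call. = FALSE)
    return(NA_real_)
  }
  if (identical(seq_a, seq_b)) return(1)
  min(1, sw_score(seq_a, seq_b, cfg, mat) / sqrt(saa * sbb))
}

# All-vs-all normalized SW among a set of sequences, self-score cached,
# one vectorized pairwiseAlignment call per subject sequence.
normalized_sw_matrix <- function(proteome, cfg = alignment_config()) {
  mat <- get_substitution_matrix(cfg)
  n <- length(proteome)
  ids <- names(proteome)
  self <- vapply(seq_len(n), function(i) {
    sw_score(as.character(proteome[[i]]), as.character(proteome[[i]]), cfg, mat)
  }, 0)
  if (any(self <= 0)) {
    warning("self-alignment score <= 0 for: ",
            paste(ids[self <= 0], collapse = ", "), call. = FALSE)
  }
  out <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
  diag(out) <- ifelse(self > 0, 1, NA_real_)
  for (i in seq_len(n - 1)) {
    j <- (i + 1):n
    raw <- Biostrings::pairwiseAlignment(
      proteome[j], proteome[[i]], type = "local",
      substitutionMatrix = mat,
      gapOpening = cfg$gap_open, gapExtension = cfg$gap_extend,
      scoreOnly = TRUE
    )
    val <- pmin(1, raw / sqrt(self[i] * self[j]))
    val[self[i] <= 0 | self[j] <= 0] <- NA_real_
    out[i, j] <- val
    out[j, i] <- val
  }
  out
}

#' All target-vs-target similarity scores for a compound pair
#'
#' One normalized SW score per (target of A) x (target of B) combination.
#' Targets without a sequence in the proteome are skipped with a warning;
#' when nothing remains the pair carries a missing-target signal (NULL).
#'
#' @param compound_a,compound_b rows of a `compound_set` (or lists with
#'   `id` and `targets`).
#' @param proteome named AAStringSet of target sequences.
#' @param cfg an [alignment_config()].
#' @return numeric vector of scores, or NULL when no scorable target pair.
#' @export
target_pair_scores <- function(compound_a, compound_b, proteome,
                               cfg = alignment_config()) {
  ta <- unlist(compound_a$targets, use.names = FALSE)
  tb <- unlist(compound_b$targets, use.names = FALSE)
  known_a <- ta[ta %in% names(proteome)]
  known_b <- tb[tb %in% names(proteome)]
  skipped <- setdiff(c(ta, tb), names(proteome))
  if (length(skipped) > 0) {
    warning("target(s) without sequence skipped: ",
            paste(skipped, collapse = ", "), call. = FALSE)
  }
  if (length(known_a) == 0 || length(known_b) == 0) return(NULL)
  scores <- outer(known_a, known_b, Vectorize(function(ga, gb) {
    normalized_sw(as.character(proteome[[ga]]), as.character(proteome[[gb]]), cfg)
  }))
  as.vector(scores)
}

#' Threshold covering the top fraction of a score distribution
#'
#' The (1 - fraction) quantile of the pooled score distribution, with linear
#' interpolation between order statistics (type-6 quantile, interpolating
#' the empirical distribution function). Computed once per run over all
#' target-pair scores, per the global-threshold reading of the top-5% rule.
#' The type-6 plotting position is used rather than R's type-7 default so
#' that a lone upper outlier is separated from a massed lower mode rather
#' than the threshold collapsing onto the mode.
#'
#' @param all_scores numeric vector of pooled scores (non-empty).
#' @param fraction fraction of the upper tail to keep (default 0.05).
#' @return the threshold value.
#' @export
top_fraction_threshold <- function(all_scores, fraction = 0.05) {
  all_scores <- all_scores[!is.na(all_scores)]
  if (length(all_scores) == 0) {
    stop("cannot compute a threshold from an empty score collection",
         call. = FALSE)
  }
  stopifnot(fraction > 0, fraction < 1)
  unname(quantile(all_scores, probs = 1 - fraction, type = 6))
}

#' Target similarity of one compound pair
#'
#' Mean of the pair's target-vs-target scores at or above the global
#' threshold (boundary inclusive). An empty surviving set gives 0 (evidence
#' of dissimilar target sets), distinct from NA (no target data at all).
#'
#' @param pair_scores output of [target_pair_scores()] (NULL = missing).
#' @param threshold from [top_fraction_threshold()].
#' @return score in \[0, 1\], or NA for a missing signal.
#' @export
target_similarity <- function(pair_scores, threshold) {
  if (is.null(pair_scores)) return(NA_real_)
  pair_scores <- pair_scores[!is.na(pair_scores)]
  if (length(pair_scores) == 0) return(NA_real_)
  surviving <- pair_scores[pair_scores >= threshold]
  if (length(surviving) == 0) return(0)
  mean(surviving)
}
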