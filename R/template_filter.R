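#' Gap-penalized identity and similarity levels
#'
#' Filter statistics for ranking target-template alignments: the percentage
#' of alignment columns holding identical (similar) residue pairs, with an
#' extra charge of `gamma` per opening gap. Larger values mean higher
#' sequence homology with fewer gap runs; heavily gapped, low-identity
#' alignments can go negative.
#'
#' @param aln a `"pairwise_alignment"` from [align_pair()].
#' @param gamma non-negative opening-gap charge (default 1); 0 recovers
#'   plain percent identity/similarity over columns.
#' @param denominator `"n_columns"` (default) or `"min_length"` (shorter
#'   ungapped sequence length).
#' @return Numeric percentage.
#' @export
identity_level <- function(aln, gamma = 1.0,
                           denominator = c("n_columns", "min_length")) {
  level_stat(aln, aln$ident, gamma, match.arg(denominator))
}

#' @rdname identity_level
#' @export
similarity_level <- function(aln, gamma = 1.0,
                             denominator = c("n_columns", "min_length")) {
  level_stat(aln, aln$sim, gamma, match.arg(denominator))
}

level_stat <- function(aln, count, gamma, denominator) {
  stopifnot(gamma >= 0, aln$n_columns > 0)
  den <- if (denominator == "min_length")
    min(nchar(gsub("-", "", aln$t_row)), nchar(gsub("-", "", aln$p_row)))
  else aln$n_columns
  100 * (count - gamma * aln$gap_openings) / den
}

#' Select the candidate alignment set
#'
#' Unions the top-k alignments by identity level with the top-k by
#' similarity level. With a pool of at least 2k alignments the result holds
#' between k and 2k members. Ties within either ranking break by higher raw
#' alignment score, then lexicographic template id, so the selection is
#' deterministic.
#'
#' @param pool non-empty list of `"pairwise_alignment"` (one target against
#'   many templates).
#' @param k positive top-k parameter (default 5).
#' @param gamma opening-gap charge passed to the level statistics.
#' @param denominator see [identity_level()].
#' @return An object of class `"candidate_set"`: list with `k`, `members`
#'   (alignments), and `table` (data.frame with template_id,
#'   identity_level, similarity_level, in_top_il, in_top_sl).
#' @export
select_candidates <- function(pool, k = 5L, gamma = 1.0,
                              denominator = c("n_columns", "min_length")) {
  denominator <- match.arg(denominator)
  stopifnot(length(pool) >= 1L, k >= 1L)
  k <- as.integer(k)
  if (k > length(pool)) {
    warning("k = ", k, " exceeds pool size ", length(pool),
            "; returning the entire pool")
    k <- length(pool)
  }
  il <- vapply(pool, identity_level, 0, gamma = gamma,
               denominator = denominator)
  sl <- vapply(pool, similarity_level, 0, gamma = gamma,
               denominator = denominator)
  score <- vapply(pool, `[[`, 0, "score")
  tid <- vapply(pool, `[[`, "", "template_id")
  rank_by <- function(lvl) order(-lvl, -score, tid)
  top_il <- rank_by(il)[seq_len(k)]
  top_sl <- rank_by(sl)[seq_len(k)]
  sel <- sort(unique(c(top_il, top_sl)))
  # order members by best rank in either list, then identity level
  pos_il <- match(sel, top_il)
  pos_sl <- match(sel, top_sl)
  best <- pmin(pos_il, pos_sl, na.rm = TRUE)
  ord <- order(best, -il[sel], tid[sel])
  sel <- sel[ord]
  structure(
    list(k = k,
         members = pool[sel],
         table = data.frame(
           target_id = vapply(pool[sel], `[[`, "", "target_id"),
           template_id = tid[sel],
           identity_level = il[sel],
           similarity_level = sl[sel],
           in_top_il = sel %in% top_il,
           in_top_sl = sel %in% top_sl,
           stringsAsFactors = FALSE)),
    class = "candidate_set")
}

#' @export
print.candidate_set <- function(x, ...) {
  cat("<candidate_set> k =", x$k, "->", length(x$members), "alignments\n")
  print(x$table)
  invisible(x)
}
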