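#' Enumerate model candidates from a candidate alignment set
#'
#' Builds the candidate simulated-structure set: one candidate per single
#' template plus one per unordered pair of distinct templates, i.e.
#' n + n(n-1)/2 candidates for n filtered alignments. Triples and beyond are
#' excluded (their modeling cost is prohibitive for batch runs). Order is
#' deterministic: singles in filter-ranking order, then pairs (i, j), i < j,
#' in the same order.
#'
#' @param ca a `"candidate_set"` from [select_candidates()], or a plain list
#'   of alignments.
#' @param templates optional named list of [template_record()] used to attach
#'   template metadata (binding positions) to each candidate.
#' @return A list of `"model_candidate"` objects: list with `candidate_id`,
#'   `template_ids`, `alignments`, `templates` (possibly NULL entries),
#'   `origin` ("single"/"double"), `z_score` (NA until scored).
#' @export
enumerate_candidates <- function(ca, templates = NULL) {
  members <- if (inherits(ca, "candidate_set")) ca$members else ca
  stopifnot(length(members) >= 1L)
  tmpl_of <- function(aln) {
    if (is.null(templates)) NULL else templates[[aln$template_id]]
  }
  mk <- function(alns, origin) {
    ids <- vapply(alns, `[[`, "", "template_id")
    structure(
      list(candidate_id = paste(ids, collapse = "+"),
           template_ids = ids, alignments = alns,
           templates = lapply(alns, tmpl_of),
           origin = origin, z_score = NA_real_),
      class = "model_candidate")
  }
  n <- length(members)
  singles <- lapply(members, function(a) mk(list(a), "single"))
  doubles <- list()
  if (n >= 2L) {
    idx <- combn(n, 2L)
    doubles <- lapply(seq_len(ncol(idx)), function(c)
      mk(members[idx[, c]], "double"))
  }
  c(singles, doubles)
}

#' @export
print.model_candidate <- function(x, ...) {
  cat("<model_candidate> ", x$candidate_id, " (", x$origin, ") z = ",
      format(x$z_score), "\n", sep = "")
  invisible(x)
}

#' Deterministic mock structure scorer
#'
#' Stand-in for an external statistical-potential engine so the full
#' pipeline runs offline: per alignment, score = 1 - 2 * (ident / columns)
#' - 0.5 * (fraction of target HARs aligned onto the template's known
#' binding positions), averaged over the candidate's one or two alignments.
#' Lower is better; a perfect self-alignment with every HAR on a binding
#' residue scores -1.5, a no-identity no-coverage alignment scores 1.
#'
#' @param target the target [annotated_seq()].
#' @param candidate a `"model_candidate"` whose `templates` entries are
#'   [template_record()]s (HAR coverage counts 0 for templates without
#'   binding annotations).
#' @return Finite numeric z-like score; identical inputs give identical
#'   values.
#' @export
mock_surface_scorer <- function(target, candidate) {
  per_aln <- vapply(seq_along(candidate$alignments), function(i) {
    aln <- candidate$alignments[[i]]
    tmpl <- candidate$templates[[i]]
    ident_frac <- aln$ident / aln$n_columns
    hars <- which(target$har_flags)
    cov <- 0
    if (length(hars) && !is.null(tmpl) &&
        length(tmpl$known_binding_positions)) {
      both <- aln$t_idx > 0L & aln$p_idx > 0L
      hit <- aln$t_idx[both] %in% hars &
        aln$p_idx[both] %in% tmpl$known_binding_positions
      cov <- sum(hit) / length(hars)
    }
    1 - 2 * ident_frac - 0.5 * cov
  }, 0)
  mean(per_aln)
}

#' Score and rank model candidates
#'
#' Applies a structure scorer (any deterministic function
#' `(target, candidate) -> number`, lower = better) to every candidate and
#' sorts ascending by score. A candidate whose scorer call errors is
#' excluded with a warning; the batch continues. An optional injected table
#' (`candidate_id` -> z) overrides the scorer, mirroring the use of real
#' modeling-engine z scores.
#'
#' @param target the target [annotated_seq()].
#' @param candidates list from [enumerate_candidates()].
#' @param scorer scoring function; default [mock_surface_scorer()].
#' @param z_table optional data.frame with columns `candidate_id`, `z_score`.
#' @param n_runs number of scorer evaluations to average per candidate
#'   (default 1; meaningful only for stochastic scorers).
#' @return The scored candidates sorted by `z_score` ascending (ties: fewer
#'   templates, then candidate id).
#' @export
rank_candidates <- function(target, candidates, scorer = mock_surface_scorer,
                            z_table = NULL, n_runs = 1L) {
  scored <- list()
  for (cand in candidates) {
    z <- if (!is.null(z_table) && cand$candidate_id %in% z_table$candidate_id)
      z_table$z_score[match(cand$candidate_id, z_table$candidate_id)]
    else tryCatch(mean(vapply(seq_len(n_runs),
                              function(i) scorer(target, cand), 0)),
                  error = function(e) {
                    warning("scorer failed for candidate '",
                            cand$candidate_id, "': ", conditionMessage(e),
                            "; candidate skipped")
                    NA_real_
                  })
    if (is.na(z) || !is.finite(z)) next
    cand$z_score <- z
    scored[[length(scored) + 1L]] <- cand
  }
  if (!length(scored)) return(scored)
  z <- vapply(scored, `[[`, 0, "z_score")
  ntm <- vapply(scored, function(c) length(c$template_ids), 0L)
  cid <- vapply(scored, `[[`, "", "candidate_id")
  scored[order(z, ntm, cid)]
}

#' Select the best-scoring candidate
#'
#' @param ranked non-empty list of scored candidates (as from
#'   [rank_candidates()]).
#' @return The candidate with minimal z score; ties favor fewer templates,
#'   then lexicographic candidate id.
#' @export
select_best <- function(ranked) {
  ranked <- Filter(function(c) !is.na(c$z_score), ranked)
  if (!length(ranked))
    stop("no scored candidates to select from")
  z <- vapply(ranked, `[[`, 0, "z_score")
  ntm <- vapply(ranked, function(c) length(c$template_ids), 0L)
  cid <- vapply(ranked, `[[`, "", "candidate_id")
  ranked[[order(z, ntm, cid)[1L]]]
}

#' Tabulate candidates
#'
#' @param candidates list of (scored) `"model_candidate"`.
#' @return data.frame: candidate_id, templates, origin, z_score, rank (NA
#'   for unscored).
#' @export
candidate_table <- function(candidates) {
  df <- do.call(rbind, lapply(candidates, function(c)
    data.frame(candidate_id = c$candidate_id,
               templates = paste(c$template_ids, collapse = "+"),
               origin = c$origin, z_score = c$z_score,
               stringsAsFactors = FALSE)))
  df$rank <- NA_integer_
  scored <- !is.na(df$z_score)
  df$rank[scored] <- rank(df$z_score[scored], ties.method = "first")
  df
}
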