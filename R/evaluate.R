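#' Confusion counts at a score threshold
#'
#' A site is predicted binding when its HAR score is greater than or equal
#' to the threshold (the same >= rule used for HAR calling).
#'
#' @param scores named numeric vector, one score per site; names identify
#'   sites (e.g. "protein:position").
#' @param positives,negatives disjoint character vectors of site names,
#'   both present in `scores`.
#' @param threshold numeric cutoff.
#' @return A one-row data.frame: threshold, tp, fp, tn, fn, tpr, fpr.
#' @export
confusion_at_threshold <- function(scores, positives, negatives, threshold) {
  check_sites(scores, positives, negatives)
  pred_pos <- names(scores)[scores >= threshold]
  tp <- sum(positives %in% pred_pos)
  fp <- sum(negatives %in% pred_pos)
  fn <- length(positives) - tp
  tn <- length(negatives) - fp
  data.frame(threshold = threshold, tp = tp, fp = fp, tn = tn, fn = fn,
             tpr = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
             fpr = if (fp + tn > 0) fp / (fp + tn) else NA_real_)
}

check_sites <- function(scores, positives, negatives) {
  if (is.null(names(scores)) || anyNA(scores))
    stop("scores must be a complete named vector")
  if (length(intersect(positives, negatives)))
    stop("positive and negative site sets overlap")
  miss <- setdiff(c(positives, negatives), names(scores))
  if (length(miss))
    stop("site(s) without a score: ", paste(utils::head(miss, 3),
                                            collapse = ", "))
  invisible(TRUE)
}

#' ROC curve of a score-thresholded binding-residue predictor
#'
#' One point per distinct score value plus sentinel endpoints: a threshold
#' above every score (fpr = tpr = 0) and one at -Inf (fpr = tpr = 1).
#' Points are sorted by threshold; tpr and fpr are non-increasing in the
#' threshold.
#'
#' @inheritParams confusion_at_threshold
#' @return data.frame of class `"roc_curve"` (threshold, tp, fp, tn, fn,
#'   tpr, fpr), with the trapezoid-rule AUC in attribute `"auc"`.
#' @export
roc_curve <- function(scores, positives, negatives) {
  check_sites(scores, positives, negatives)
  if (!length(positives) || !length(negatives))
    stop("ROC needs at least one positive and one negative site")
  used <- scores[c(positives, negatives)]
  thr <- c(-Inf, sort(unique(used)), max(used) + 1)
  rows <- do.call(rbind, lapply(thr, function(t)
    confusion_at_threshold(scores, positives, negatives, t)))
  rows <- rows[order(rows$threshold), ]
  rownames(rows) <- NULL
  ord <- order(rows$fpr, rows$tpr)
  auc <- sum(diff(rows$fpr[ord]) *
             (utils::head(rows$tpr[ord], -1) + utils::tail(rows$tpr[ord], -1)) / 2)
  structure(rows, auc = auc, class = c("roc_curve", "data.frame"))
}

#' Trapezoid-rule area under a ROC curve
#'
#' @param roc a `"roc_curve"`.
#' @return Numeric AUC in \[0, 1\].
#' @export
roc_auc <- function(roc) attr(roc, "auc")

#' Evaluate HAR calling as a binding-residue predictor over templates
#'
#' Builds the positive set (known ligand-binding aromatic positions) and
#' negative set (all other aromatic positions) from a template collection,
#' scores every aromatic with [har_score()], and returns the ROC plus the
#' confusion counts at the calling threshold. Note the negative set mixes
#' true negatives with not-yet-characterized binders, so the false (true)
#' positive rate is an over- (under-) estimate.
#'
#' @param templates list of [template_record()].
#' @param threshold calling cutoff (default 97).
#' @param table weight table.
#' @return list(scores, positives, negatives, roc, at_threshold).
#' @export
evaluate_binding_prediction <- function(templates, threshold = 97L,
                                        table = default_weight_table()) {
  scores <- numeric(0); positives <- character(0); negatives <- character(0)
  for (tmpl in templates) {
    calls <- identify_hars(tmpl$seq, table, threshold)
    if (!nrow(calls)) next
    site <- paste0(tmpl$template_id, ":", calls$position)
    s <- calls$score
    names(s) <- site
    scores <- c(scores, s)
    known <- calls$position %in% tmpl$known_binding_positions
    positives <- c(positives, site[known])
    negatives <- c(negatives, site[!known])
  }
  if (!length(positives) || !length(negatives))
    stop("template collection yields an empty positive or negative set")
  roc <- roc_curve(scores, positives, negatives)
  list(scores = scores, positives = positives, negatives = negatives,
       roc = roc,
       at_threshold = confusion_at_threshold(scores, positives, negatives,
                                             threshold))
}

#' Summary statistics over a batch of alignments
#'
#' Mean and median percent identity and similarity (per alignment, over
#' columns) across a collection of pairwise alignments, plus the count.
#'
#' @param alignments non-empty list of `"pairwise_alignment"`.
#' @return list(n, mean_identity, median_identity, mean_similarity,
#'   median_similarity), percentages.
#' @export
summarize_alignment_stats <- function(alignments) {
  stopifnot(length(alignments) >= 1L)
  pid <- vapply(alignments, function(a) 100 * a$ident / a$n_columns, 0)
  psim <- vapply(alignments, function(a) 100 * a$sim / a$n_columns, 0)
  list(n = length(alignments),
       mean_identity = mean(pid), median_identity = median(pid),
       mean_similarity = mean(psim), median_similarity = median(psim))
}

#' Single- versus double-template usage among top-ranked candidates
#'
#' Across per-target top-5 candidate lists, the share of entries built from
#' double versus single templates.
#'
#' @param ranked_sets non-empty list; each element a list of scored
#'   `"model_candidate"` (at most 5 per target).
#' @return list(n_entries, pct_single, pct_double).
#' @export
summarize_template_usage <- function(ranked_sets) {
  stopifnot(length(ranked_sets) >= 1L)
  origin <- unlist(lapply(ranked_sets, function(set) {
    stopifnot(length(set) <= 5L)
    vapply(set, `[[`, "", "origin")
  }))
  if (!length(origin)) stop("no candidates in any set")
  list(n_entries = length(origin),
       pct_single = 100 * mean(origin == "single"),
       pct_double = 100 * mean(origin == "double"))
}

#' Write a ROC table to TSV
#'
#' @param roc a `"roc_curve"`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_roc_tsv <- function(roc, path) {
  write.table(as.data.frame(roc), path, sep = "\t", row.names = FALSE,
              quote = FALSE)
  invisible(path)
}
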