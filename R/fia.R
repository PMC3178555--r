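#' Feature-incorporated alignment parameters
#'
#' Scoring parameters for the global affine-gap aligner. Substitution scores
#' come from BLOSUM62; on top of it, a column aligning two HAR-flagged
#' residues earns `har_bonus`, and a column whose two residues share a
#' confident helix or strand state earns `ss_bonus` (loop-loop columns earn
#' nothing: loops are low-information). A gap run of length L costs
#' `gap_open + (L - 1) * gap_extend`.
#'
#' @param matrix substitution matrix name; only "BLOSUM62" is shipped.
#' @param gap_open positive opening penalty (default 11).
#' @param gap_extend positive extension penalty (default 1); must not exceed
#'   `gap_open`.
#' @param har_bonus non-negative bonus for HAR-HAR columns (default 5).
#' @param ss_bonus non-negative bonus for matched H/E columns (default 2).
#' @param free_end_gaps logical; when TRUE, leading and trailing gap runs are
#'   unpenalized (for aligning a domain inside a longer protein). Default
#'   FALSE: whole-domain global alignment.
#' @return An object of class `"alignment_params"`.
#' @export
alignment_params <- function(matrix = "BLOSUM62", gap_open = 11,
                             gap_extend = 1, har_bonus = 5, ss_bonus = 2,
                             free_end_gaps = FALSE) {
  stopifnot(gap_open > 0, gap_extend > 0, gap_extend <= gap_open,
            har_bonus >= 0, ss_bonus >= 0)
  if (!identical(matrix, "BLOSUM62"))
    stop("unsupported substitution matrix: ", matrix)
  structure(list(matrix = matrix, gap_open = gap_open,
                 gap_extend = gap_extend, har_bonus = har_bonus,
                 ss_bonus = ss_bonus, free_end_gaps = free_end_gaps),
            class = "alignment_params")
}

# Map residue characters onto substitution-matrix row names; anything not in
# the matrix falls back to the 'X' row.
matrix_codes <- function(chars, mat) {
  idx <- match(chars, rownames(mat))
  idx[is.na(idx)] <- match("X", rownames(mat))
  idx
}

#' Position score of one aligned residue pair
#'
#' Substitution score plus the HAR and secondary-structure bonuses; the
#' column-level scoring unit of the feature-incorporated aligner.
#'
#' @param a,b residue characters (not gaps).
#' @param har_a,har_b logical HAR flags of the two residues.
#' @param state_a,state_b secondary-structure states (H/E/L).
#' @param params an [alignment_params()].
#' @return Numeric score.
#' @examples
#' position_score("W", "W", TRUE, TRUE, "E", "E")  # 11 + 5 + 2
#' @export
position_score <- function(a, b, har_a = FALSE, har_b = FALSE,
                           state_a = "L", state_b = "L",
                           params = alignment_params()) {
  mat <- blosum62()
  s <- mat[matrix_codes(a, mat), matrix_codes(b, mat)]
  if (har_a && har_b) s <- s + params$har_bonus
  if (state_a == state_b && state_a %in% c("H", "E")) s <- s + params$ss_bonus
  as.numeric(s)
}

# Full n x m position-score matrix for a pair of annotated sequences.
position_score_matrix <- function(target, template, params) {
  mat <- blosum62()
  tc <- matrix_codes(seq_chars(target), mat)
  pc <- matrix_codes(seq_chars(template), mat)
  S <- mat[tc, pc, drop = FALSE]
  storage.mode(S) <- "double"
  if (params$har_bonus > 0 && any(target$har_flags) &&
      any(template$har_flags))
    S <- S + params$har_bonus * outer(target$har_flags, template$har_flags)
  if (params$ss_bonus > 0) {
    th <- target$states == "H"; te <- target$states == "E"
    ph <- template$states == "H"; pe <- template$states == "E"
    S <- S + params$ss_bonus * (outer(th, ph) | outer(te, pe))
  }
  S
}

#' Align a target to a template
#'
#' Optimal global alignment under the affine-gap model with
#' feature-incorporated position scores, computed by the Gotoh dynamic
#' program with a deterministic traceback (ties: diagonal, then gap in the
#' template row, then gap in the target row). Derived counts: `ident` =
#' aligned identical residue pairs; `sim` = aligned pairs that are identical
#' or have a positive BLOSUM62 entry (the standard "positives" convention);
#' `gap_openings` = number of maximal gap runs across both rows.
#'
#' @param target an [annotated_seq()] (or residue string).
#' @param template an [annotated_seq()], [template_record()] or residue
#'   string.
#' @param params an [alignment_params()].
#' @return An object of class `"pairwise_alignment"`: list with
#'   `target_id`, `template_id`, `t_row`, `p_row` (gapped rows), `t_idx`,
#'   `p_idx` (per-column 1-based residue indices, 0 = gap), `score`,
#'   `ident`, `sim`, `gap_openings`, `n_columns`.
#' @examples
#' a <- align_pair("GSWNP", "GSWNP")
#' a$ident
#' @export
align_pair <- function(target, template, params = alignment_params()) {
  if (is.character(target)) target <- annotated_seq("target", target)
  if (inherits(template, "template_record")) template <- template$seq
  if (is.character(template)) template <- annotated_seq("template", template)
  if (seq_length(target) < 1L || seq_length(template) < 1L)
    stop("cannot align empty sequences")
  S <- position_score_matrix(target, template, params)
  res <- fia_align_cpp(S, params$gap_open, params$gap_extend,
                       params$free_end_gaps)
  tc <- seq_chars(target); pc <- seq_chars(template)
  mat <- blosum62()
  tcode <- matrix_codes(tc, mat); pcode <- matrix_codes(pc, mat)
  ncol <- length(res$t_idx)
  t_row <- rep("-", ncol); p_row <- rep("-", ncol)
  tg <- res$t_idx > 0L; pg <- res$p_idx > 0L
  t_row[tg] <- tc[res$t_idx[tg]]
  p_row[pg] <- pc[res$p_idx[pg]]
  both <- tg & pg
  ai <- tcode[res$t_idx[both]]; bi <- pcode[res$p_idx[both]]
  same <- t_row[both] == p_row[both]
  ident <- sum(same)
  sim <- ident + sum(mat[cbind(ai[!same], bi[!same])] > 0)
  runs <- function(g) sum(g & !c(FALSE, g[-length(g)]))
  structure(
    list(target_id = target$id, template_id = template$id,
         t_row = paste(t_row, collapse = ""),
         p_row = paste(p_row, collapse = ""),
         t_idx = res$t_idx, p_idx = res$p_idx,
         score = res$score, ident = ident, sim = sim,
         gap_openings = runs(!tg) + runs(!pg),
         n_columns = ncol),
    class = "pairwise_alignment")
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat("<pairwise_alignment> ", x$target_id, " vs ", x$template_id,
      ": score ", format(x$score), ", ident ", x$ident, "/", x$n_columns,
      ", sim ", x$sim, ", gap openings ", x$gap_openings, "\n", sep = "")
  cat(" ", x$t_row, "\n ", x$p_row, "\n", sep = "")
  invisible(x)
}

#' Align a target against every template
#'
#' Produces the preliminary alignment set fed to the template filter: one
#' alignment per template, input order preserved. Per-template failures are
#' rethrown with the template id attached.
#'
#' @param target an [annotated_seq()].
#' @param templates list of [template_record()] (or annotated sequences).
#' @param params an [alignment_params()].
#' @return A list of `"pairwise_alignment"` objects.
#' @export
align_all <- function(target, templates, params = alignment_params()) {
  if (!length(templates)) stop("no templates supplied")
  lapply(templates, function(tmpl) {
    tid <- if (inherits(tmpl, "template_record")) tmpl$template_id
           else if (inherits(tmpl, "annotated_seq")) tmpl$id else "?"
    tryCatch(align_pair(target, tmpl, params),
             error = function(e)
               stop("aligning '", target$id, "' to template '", tid, "': ",
                    conditionMessage(e), call. = FALSE))
  })
}

#' Tabulate alignments
#'
#' @param alignments list of `"pairwise_alignment"`.
#' @return data.frame with one row per alignment: target_id, template_id,
#'   score, ident, sim, gap_openings, n_columns.
#' @export
alignment_table <- function(alignments) {
  do.call(rbind, lapply(alignments, function(a)
    data.frame(target_id = a$target_id, template_id = a$template_id,
               score = a$score, ident = a$ident, sim = a$sim,
               gap_openings = a$gap_openings, n_columns = a$n_columns,
               stringsAsFactors = FALSE)))
}
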