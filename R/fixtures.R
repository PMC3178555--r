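# Synthetic CBM-like benchmark generator. Templates carry planted
# high-scoring aromatic motifs (the ground-truth "binding residues");
# targets are mutated copies at controlled divergence with the motif
# windows optionally preserved, emulating the low-identity regime typical
# of CBM target-template pairs.

# Flank alphabet for planted motifs: the five heaviest residues in the
# default weight table (min weight 33), so any motif center scores at least
# 4 * 33 = 132 >= 97 under the default table.
MOTIF_FLANKS <- c("G", "N", "S", "T", "D")

# BLOSUM62 background amino-acid frequencies (Robinson-Robinson style), for
# the optional non-uniform background.
BG_BLOSUM62 <- c(
  A = 0.074, R = 0.052, N = 0.045, D = 0.054, C = 0.025, Q = 0.034,
  E = 0.054, G = 0.074, H = 0.026, I = 0.068, L = 0.099, K = 0.058,
  M = 0.025, F = 0.047, P = 0.039, S = 0.057, T = 0.051, W = 0.013,
  Y = 0.032, V = 0.073)

sample_residues <- function(n, background = c("uniform", "blosum62")) {
  background <- match.arg(background)
  if (background == "uniform") sample(AA_STANDARD, n, replace = TRUE)
  else sample(names(BG_BLOSUM62), n, replace = TRUE, prob = BG_BLOSUM62)
}

# Secondary-structure track as runs of H/E/L; strand-rich, as in the
# beta-sandwich / beta-trefoil folds that dominate CBMs.
random_track <- function(n) {
  states <- character(0)
  while (length(states) < n) {
    st <- sample(c("E", "L", "H"), 1, prob = c(0.40, 0.45, 0.15))
    states <- c(states, rep(st, sample(3:8, 1)))
  }
  states[seq_len(n)]
}

#' Generate a synthetic template set with planted binding motifs
#'
#' Each template is a random sequence into which `n_binding` non-overlapping
#' 5-residue motifs are planted: an aromatic center (W/Y/F) flanked by
#' heavy-weight residues, guaranteeing a HAR score of at least 132 at the
#' center. Centers are recorded as the template's known binding positions.
#' Output is reproducible per seed.
#'
#' @param n number of templates.
#' @param length residues per template (default 100).
#' @param n_binding planted motifs per template (default 2); requires
#'   `n_binding * 5 <= length`.
#' @param seed integer seed.
#' @param background residue background: "uniform" (default) or "blosum62".
#' @param family family label stamped on the records.
#' @return A named list of [template_record()]; each record's sequence
#'   carries HAR flags (computed at the default threshold) and attribute
#'   `"planted_centers"`.
#' @export
generate_template_set <- function(n, length = 100L, n_binding = 2L,
                                  seed = 1L,
                                  background = c("uniform", "blosum62"),
                                  family = "SYN") {
  background <- match.arg(background)
  stopifnot(n >= 1L, length >= 5L)
  if (n_binding * 5L > length)
    stop("cannot pack ", n_binding, " 5-residue motifs into length ", length)
  with_seed(seed, {
    out <- vector("list", n)
    for (i in seq_len(n)) {
      chars <- sample_residues(length, background)
      centers <- integer(0)
      if (n_binding > 0L) {
        # one motif per equal-width block, random offset, 2-residue margins
        block <- length %/% n_binding
        centers <- vapply(seq_len(n_binding), function(b) {
          lo <- (b - 1L) * block + 3L
          hi <- b * block - 2L
          if (hi < lo) stop("cannot pack motifs: blocks too narrow")
          as.integer(sample(lo:hi, 1))
        }, 0L)
        for (ctr in centers) {
          chars[(ctr - 2L):(ctr + 2L)] <-
            c(sample(MOTIF_FLANKS, 2, replace = TRUE), sample(AROMATIC, 1),
              sample(MOTIF_FLANKS, 2, replace = TRUE))
        }
      }
      id <- sprintf("syn%03d", i)
      s <- annotated_seq(id, paste(chars, collapse = ""),
                         states = random_track(length))
      s <- flag_hars(s)
      attr(s, "planted_centers") <- sort(centers)
      out[[i]] <- template_record(id, family, s, centers)
    }
    names(out) <- vapply(out, `[[`, "", "template_id")
    out
  })
}

#' Mutate a sequence at controlled substitution and indel rates
#'
#' Point substitutions (to a different residue) and short indels
#' (geometric lengths, p = 0.5, capped at 5) are applied per position.
#' With `preserve_motifs`, positions within two residues of a planted motif
#' center are left untouched and never deleted, so the motif windows
#' survive. Reproducible per seed.
#'
#' @param seq an [annotated_seq()]; planted centers are read from its
#'   `"planted_centers"` attribute (or pass `motif_centers`).
#' @param sub_rate,indel_rate per-position rates in \[0, 1).
#' @param seed integer seed.
#' @param preserve_motifs logical (default TRUE).
#' @param motif_centers optional explicit centers.
#' @return A mutated [annotated_seq()] (id suffixed "_mut"); attribute
#'   `"planted_centers"` holds the centers' new coordinates. The
#'   secondary-structure track follows surviving residues; inserted
#'   residues get loop states.
#' @export
mutate_sequence <- function(seq, sub_rate = 0.3, indel_rate = 0.02,
                            seed = 1L, preserve_motifs = TRUE,
                            motif_centers = NULL) {
  stopifnot(sub_rate >= 0, sub_rate < 1, indel_rate >= 0, indel_rate < 1)
  centers <- if (!is.null(motif_centers)) motif_centers
             else attr(seq, "planted_centers")
  if (is.null(centers)) centers <- integer(0)
  n <- seq_length(seq)
  masked <- rep(FALSE, n)
  if (preserve_motifs && length(centers))
    for (ctr in centers)
      masked[max(1L, ctr - 2L):min(n, ctr + 2L)] <- TRUE
  chars <- seq_chars(seq)
  with_seed(seed, {
    out_chars <- character(0)
    out_states <- character(0)
    new_pos <- rep(NA_integer_, n)   # old position -> new position
    for (i in seq_len(n)) {
      if (!masked[i]) {
        r <- runif(3)
        if (r[1] < indel_rate) {
          len <- min(1L + rgeom(1, 0.5), 5L)
          if (r[2] < 0.5) {         # insertion before position i
            out_chars <- c(out_chars, sample_residues(len))
            out_states <- c(out_states, rep("L", len))
          } else {                   # deletion of this residue
            next
          }
        }
        if (r[3] < sub_rate) {
          out_chars <- c(out_chars, sample(setdiff(AA_STANDARD, chars[i]), 1))
          out_states <- c(out_states, seq$states[i])
          new_pos[i] <- length(out_chars)
          next
        }
      }
      out_chars <- c(out_chars, chars[i])
      out_states <- c(out_states, seq$states[i])
      new_pos[i] <- length(out_chars)
    }
    s <- annotated_seq(paste0(seq$id, "_mut"),
                       paste(out_chars, collapse = ""),
                       states = out_states)
    attr(s, "planted_centers") <-
      sort(new_pos[centers[!is.na(new_pos[centers])]])
    attr(s, "source_positions") <- new_pos
    s
  })
}

#' Generate a full synthetic benchmark
#'
#' Builds a template set, then derives targets from each template by
#' mutation at the requested divergence levels (cycled across targets) and
#' perturbs their secondary-structure tracks at a given state-flip rate.
#' Targets get HAR flags at the default threshold. The truth table maps
#' every target to its source template.
#'
#' @param n_templates,n_targets_per_template counts (>= 1).
#' @param divergence vector of substitution rates, recycled over the targets
#'   of each template (default 0.3).
#' @param indel_rate per-position indel rate (default 0.02).
#' @param track_flip_rate per-residue probability of relabeling a track
#'   state to a random different state (default 0.1, roughly matching a
#'   70% accurate 3-state predictor).
#' @param template_length,n_binding passed to [generate_template_set()].
#' @param seed integer seed; all per-target seeds derive from it.
#' @return list(templates, targets, truth) of class
#'   `"synthetic_benchmark"`; `truth` is a data.frame(target_id,
#'   template_id, sub_rate, indel_rate).
#' @export
generate_benchmark <- function(n_templates = 5L, n_targets_per_template = 2L,
                               divergence = 0.3, indel_rate = 0.02,
                               track_flip_rate = 0.1,
                               template_length = 100L, n_binding = 2L,
                               seed = 1L) {
  stopifnot(n_templates >= 1L, n_targets_per_template >= 1L)
  templates <- generate_template_set(n_templates, template_length, n_binding,
                                     seed = seed)
  targets <- list()
  truth <- list()
  k <- 0L
  for (tmpl in templates) {
    for (j in seq_len(n_targets_per_template)) {
      k <- k + 1L
      sub_rate <- divergence[((j - 1L) %% length(divergence)) + 1L]
      tgt <- mutate_sequence(tmpl$seq, sub_rate = sub_rate,
                             indel_rate = indel_rate, seed = seed + 7L * k)
      tgt$id <- sprintf("tgt%04d", k)
      tgt <- with_seed(seed + 7L * k + 3L, {
        flip <- runif(seq_length(tgt)) < track_flip_rate
        st <- tgt$states
        st[flip] <- vapply(st[flip], function(s)
          sample(setdiff(c("H", "E", "L"), s), 1), "")
        tgt$states <- st
        tgt
      })
      tgt <- flag_hars(tgt)
      targets[[tgt$id]] <- tgt
      truth[[k]] <- data.frame(target_id = tgt$id,
                               template_id = tmpl$template_id,
                               sub_rate = sub_rate,
                               indel_rate = indel_rate,
                               stringsAsFactors = FALSE)
    }
  }
  structure(list(templates = templates, targets = targets,
                 truth = do.call(rbind, truth)),
            class = "synthetic_benchmark")
}

#' @export
print.synthetic_benchmark <- function(x, ...) {
  cat("<synthetic_benchmark>", length(x$templates), "templates,",
      length(x$targets), "targets\n")
  invisible(x)
}

#' Write a benchmark to disk as standard files
#'
#' FASTA for targets, per-sequence track files, and a template profile
#' table, so the command-line pipeline can be exercised end-to-end.
#'
#' @param bench a `"synthetic_benchmark"`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_benchmark <- function(bench, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(bench$targets, file.path(dir, "targets.fasta"))
  trackdir <- file.path(dir, "tracks")
  dir.create(trackdir, showWarnings = FALSE)
  for (tgt in bench$targets)
    write_secstruct_track(tgt, file.path(trackdir, paste0(tgt$id, ".track")))
  write_template_table(bench$templates, file.path(dir, "templates.csv"))
  write.table(bench$truth, file.path(dir, "truth.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  invisible(dir)
}
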