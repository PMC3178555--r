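# Independent oracles and small generators shared across the test files.
# These deliberately re-derive results by the dumbest correct route
# (string slicing, exhaustive enumeration, per-threshold recounts) so they
# share no code path with the implementation they check.

AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

random_protein <- function(n) paste(sample(AA20, n, replace = TRUE),
                                    collapse = "")

random_states <- function(n) sample(c("H", "E", "L"), n, replace = TRUE)

# BLOSUM62 lookup used by the oracles, fetched straight from Biostrings.
bl62 <- local({
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
})

# --- HAR oracle: score every aromatic by slicing out the 5-window ---------
naive_har_table <- function(string, table = default_weight_table(),
                            threshold = 97) {
  chars <- strsplit(string, "")[[1]]
  w <- unclass(table)
  rows <- lapply(which(chars %in% c("W", "Y", "F")), function(p) {
    flanks <- chars[intersect(c(p - 2, p - 1, p + 1, p + 2),
                              seq_along(chars))]
    sc <- sum(w[flanks], na.rm = TRUE)
    data.frame(position = p, score = sc, is_har = sc >= threshold)
  })
  if (!length(rows)) return(NULL)
  do.call(rbind, rows)
}

# --- brute-force global affine alignment score ----------------------------
# Exhaustively explores every global alignment (every monotone path), with
# a gap run of length L costing go + (L - 1) * ge; a run is "extended" only
# when the previous move was a gap in the same row. No memoization: this is
# enumeration, not dynamic programming.
brute_force_score <- function(s1, s2, go = 11, ge = 1) {
  c1 <- strsplit(s1, "")[[1]]; c2 <- strsplit(s2, "")[[1]]
  n <- length(c1); m <- length(c2)
  rec <- function(i, j, last) {
    if (i > n && j > m) return(0)
    best <- -Inf
    if (i <= n && j <= m) {
      v <- bl62[c1[i], c2[j]] + rec(i + 1, j + 1, "M")
      if (v > best) best <- v
    }
    if (i <= n) {
      v <- -(if (last == "X") ge else go) + rec(i + 1, j, "X")
      if (v > best) best <- v
    }
    if (j <= m) {
      v <- -(if (last == "Y") ge else go) + rec(i, j + 1, "Y")
      if (v > best) best <- v
    }
    best
  }
  rec(1, 1, "M")
}

# --- naive ROC recount ----------------------------------------------------
naive_confusion <- function(scores, positives, negatives, thr) {
  pred <- names(scores)[scores >= thr]
  c(tp = sum(positives %in% pred), fp = sum(negatives %in% pred),
    fn = sum(!positives %in% pred), tn = sum(!negatives %in% pred))
}

# --- naive top-k union for the template filter ----------------------------
naive_candidate_ids <- function(pool, k, gamma = 1) {
  df <- do.call(rbind, lapply(pool, function(a) data.frame(
    id = a$template_id, score = a$score,
    il = 100 * (a$ident - gamma * a$gap_openings) / a$n_columns,
    sl = 100 * (a$sim - gamma * a$gap_openings) / a$n_columns)))
  top <- function(col) df$id[order(-df[[col]], -df$score, df$id)][seq_len(k)]
  sort(unique(c(top("il"), top("sl"))))
}

# Small annotated pair with controllable HAR flags / states.
toy_seq <- function(id, residues, states = NULL, hars = integer(0)) {
  s <- annotated_seq(id, residues, states = states)
  s$har_flags[hars] <- TRUE
  s
}
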