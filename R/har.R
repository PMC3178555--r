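#' Default flanking-residue weight table
#'
#' Occurrence-derived integer weights for the residues found in the two
#' upstream and two downstream positions flanking known ligand-binding
#' aromatic residues of CBM structure templates. Small residues (G, A) and
#' the polar residues N, S, T, D, Q, E, K carry the largest weights,
#' consistent with their hydrogen-bonding and low-steric roles next to a
#' stacking aromatic.
#'
#' @return A named integer vector over the 20 standard amino acids, class
#'   `"weight_table"`.
#' @examples
#' w <- default_weight_table()
#' w["G"]  # 49
#' @export
default_weight_table <- function() {
  w <- c(G = 49L, N = 43L, S = 34L, T = 34L, D = 33L, A = 30L, Q = 27L,
         I = 22L, E = 22L, K = 20L, V = 16L, L = 13L, Y = 9L, P = 8L,
         C = 6L, M = 6L, F = 6L, H = 4L, R = 3L, W = 3L)
  structure(w, class = "weight_table")
}

#' Read a flanking-residue weight table from a 2-column TSV
#'
#' Columns: residue (one letter), weight (non-negative integer). All 20
#' standard residues must be present exactly once.
#'
#' @param path TSV file.
#' @return A `"weight_table"` as from [default_weight_table()].
#' @export
read_weight_table <- function(path) {
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  stopifnot(ncol(df) >= 2)
  w <- as.integer(df[[2]])
  names(w) <- toupper(trimws(df[[1]]))
  if (!setequal(names(w), AA_STANDARD) || length(w) != 20L)
    stop("weight table must contain each of the 20 standard residues once")
  if (any(w < 0)) stop("weights must be non-negative")
  structure(w[AA_STANDARD], class = "weight_table")
}

# Weight of a single residue character; unknown ('X') and out-of-range
# flanks contribute 0.
flank_weight <- function(chars, pos, table) {
  if (pos < 1L || pos > length(chars)) return(0L)
  w <- unclass(table)[chars[pos]]
  if (is.na(w)) 0L else as.integer(w)
}

#' HAR score of an aromatic residue
#'
#' Sums the weights of the residues at positions pos-2, pos-1, pos+1 and
#' pos+2. Flank positions falling outside the sequence, and unknown ('X')
#' residues, contribute 0.
#'
#' @param seq an [annotated_seq()] or a plain residue string.
#' @param pos 1-based position; the residue there must be W, Y or F.
#' @param table a weight table, default [default_weight_table()].
#' @return Integer score in \[0, 4 * max(table)\].
#' @examples
#' har_score("GSWNP", 3)  # 134: G(49) + S(34) + N(43) + P(8)
#' har_score("PTYKA", 3)  # 92:  P(8) + T(34) + K(20) + A(30)
#' @export
har_score <- function(seq, pos, table = default_weight_table()) {
  if (is.character(seq)) seq <- annotated_seq("seq", seq)
  chars <- seq_chars(seq)
  pos <- as.integer(pos)
  if (pos < 1L || pos > length(chars))
    stop("position ", pos, " outside [1, ", length(chars), "]")
  if (!chars[pos] %in% AROMATIC)
    stop("residue at position ", pos, " is '", chars[pos],
         "', not aromatic (W/Y/F)")
  flank_weight(chars, pos - 2L, table) + flank_weight(chars, pos - 1L, table) +
    flank_weight(chars, pos + 1L, table) + flank_weight(chars, pos + 2L, table)
}

#' Identify hydrophilic aromatic residues (HARs)
#'
#' Scores every aromatic residue (W/Y/F) by [har_score()] and calls it an
#' HAR when the score reaches the cutoff (score >= threshold). In strict
#' mode an aromatic additionally needs at least one polar/small flanking
#' residue on each side (N, S, T, D, Q, E, K, G, A), echoing the original
#' flanked-on-both-sides definition.
#'
#' @param seq an [annotated_seq()] or residue string.
#' @param table weight table.
#' @param threshold integer cutoff, default 97.
#' @param strict logical; off by default.
#' @return A data.frame with columns `position`, `residue`, `window` (up to
#'   5-character context), `score`, `is_har`, one row per aromatic residue
#'   in sequence order (zero rows if none).
#' @examples
#' identify_hars("AAGSWNPAA")
#' @export
identify_hars <- function(seq, table = default_weight_table(),
                          threshold = 97L, strict = FALSE) {
  if (is.character(seq)) seq <- annotated_seq("seq", seq)
  chars <- seq_chars(seq)
  pos <- which(chars %in% AROMATIC)
  n <- length(chars)
  polar_small <- c("N", "S", "T", "D", "Q", "E", "K", "G", "A")
  rows <- lapply(pos, function(p) {
    sc <- har_score(seq, p, table)
    win <- paste(chars[max(1L, p - 2L):min(n, p + 2L)], collapse = "")
    is_har <- sc >= threshold
    if (strict && is_har) {
      up <- chars[max(1L, p - 2L):max(1L, p - 1L)]
      dn <- chars[min(n, p + 1L):min(n, p + 2L)]
      is_har <- p > 1L && p < n &&
        any(up %in% polar_small) && any(dn %in% polar_small)
    }
    data.frame(position = p, residue = chars[p], window = win,
               score = sc, is_har = is_har, stringsAsFactors = FALSE)
  })
  if (!length(rows))
    return(data.frame(position = integer(0), residue = character(0),
                      window = character(0), score = integer(0),
                      is_har = logical(0), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Set HAR flags on a sequence
#'
#' Runs [identify_hars()] and returns the sequence with `har_flags` TRUE at
#' the called positions.
#'
#' @inheritParams identify_hars
#' @return The [annotated_seq()] with updated flags.
#' @export
flag_hars <- function(seq, table = default_weight_table(), threshold = 97L,
                      strict = FALSE) {
  calls <- identify_hars(seq, table, threshold, strict)
  flags <- rep(FALSE, seq_length(seq))
  flags[calls$position[calls$is_har]] <- TRUE
  seq$har_flags <- flags
  seq
}

#' Write HAR calls to TSV
#'
#' @param calls data.frame from [identify_hars()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_har_tsv <- function(calls, path) {
  write.table(calls, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
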