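#' Annotated protein sequence
#'
#' The unit that flows through the pipeline: a one-letter residue string with
#' an optional 3-state secondary-structure track (H = helix, E = strand,
#' L = loop), optional per-residue confidences in \[0, 1\], and per-residue
#' HAR flags. All coordinates are 1-based inclusive.
#'
#' States predicted with confidence below 0.5 are relabeled to loop: only
#' confident helix/strand calls carry information into alignment. 'C' (coil,
#' emitted by many predictors) is accepted as a synonym of 'L'.
#'
#' @param id character scalar identifier.
#' @param residues one-letter amino-acid string (standard 20 letters or 'X');
#'   lowercase is uppercased.
#' @param states optional per-residue states over H/E/L (C accepted as L),
#'   given as a string or character vector; defaults to all-loop.
#' @param confidences optional numeric vector of per-residue confidences in
#'   \[0, 1\]; positions with confidence < 0.5 are relabeled to 'L'.
#' @param har_flags optional logical vector of HAR flags; defaults to all
#'   FALSE. Usually set by [flag_hars()].
#' @param domain_start,domain_end optional 1-based inclusive coordinates of
#'   the domain in its parent protein.
#' @return An object of class `"annotated_seq"`.
#' @examples
#' s <- annotated_seq("t1", "GSWNP", states = "LLEEL")
#' seq_length(s)
#' @export
annotated_seq <- function(id, residues, states = NULL, confidences = NULL,
                          har_flags = NULL, domain_start = NA_integer_,
                          domain_end = NA_integer_) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  residues <- toupper(gsub("[[:space:]*]", "", paste(residues, collapse = "")))
  if (!nzchar(residues)) stop("sequence '", id, "': residues must be non-empty")
  chars <- strsplit(residues, "")[[1]]
  bad <- which(!chars %in% c(AA_STANDARD, "X"))
  if (length(bad)) {
    stop("sequence '", id, "': illegal residue '", chars[bad[1]],
         "' at position ", bad[1])
  }
  n <- length(chars)
  if (is.null(states)) states <- rep("L", n)
  if (is.character(states) && length(states) == 1L && nchar(states) > 1L)
    states <- strsplit(states, "")[[1]]
  states <- toupper(states)
  states[states == "C"] <- "L"
  if (length(states) != n)
    stop("sequence '", id, "': states length ", length(states),
         " != sequence length ", n)
  bad <- which(!states %in% c("H", "E", "L"))
  if (length(bad))
    stop("sequence '", id, "': unknown secondary-structure state '",
         states[bad[1]], "' at position ", bad[1])
  if (!is.null(confidences)) {
    if (length(confidences) != n)
      stop("sequence '", id, "': confidences length ", length(confidences),
           " != sequence length ", n)
    if (any(confidences < 0 | confidences > 1, na.rm = TRUE))
      stop("sequence '", id, "': confidences must lie in [0, 1]")
    states[!is.na(confidences) & confidences < 0.5] <- "L"
  }
  if (is.null(har_flags)) har_flags <- rep(FALSE, n)
  stopifnot(is.logical(har_flags), length(har_flags) == n)
  if (!is.na(domain_start) && !is.na(domain_end) && domain_start > domain_end)
    stop("sequence '", id, "': domain_start > domain_end")
  structure(
    list(id = id, residues = residues, states = states,
         confidences = confidences, har_flags = har_flags,
         domain_start = as.integer(domain_start),
         domain_end = as.integer(domain_end)),
    class = "annotated_seq")
}

#' @export
print.annotated_seq <- function(x, ...) {
  cat("<annotated_seq> ", x$id, " (", seq_length(x), " aa, ",
      sum(x$har_flags), " HAR)\n", sep = "")
  invisible(x)
}

#' Sequence length and residue accessors
#'
#' @param seq an [annotated_seq()].
#' @return `seq_length()`: integer length; `seq_chars()`: character vector of
#'   one-letter residues.
#' @export
seq_length <- function(seq) nchar(seq$residues)

#' @rdname seq_length
#' @export
seq_chars <- function(seq) strsplit(seq$residues, "")[[1]]

#' Template record
#'
#' A non-redundant CBM structure template: an annotated sequence plus the set
#' of residue positions experimentally annotated as ligand-binding. Every
#' known binding position must carry an aromatic residue (W/Y/F).
#'
#' @param template_id structure identifier (e.g. a PDB code).
#' @param family CBM family label (e.g. "CBM20").
#' @param seq an [annotated_seq()].
#' @param known_binding_positions integer vector of 1-based positions of
#'   experimentally known ligand-binding aromatic residues (may be empty).
#' @return An object of class `"template_record"`.
#' @export
template_record <- function(template_id, family, seq,
                            known_binding_positions = integer(0)) {
  stopifnot(inherits(seq, "annotated_seq"))
  pos <- sort(unique(as.integer(known_binding_positions)))
  n <- seq_length(seq)
  if (length(pos)) {
    if (any(pos < 1L | pos > n))
      stop("template '", template_id, "': binding position out of range [1, ",
           n, "]")
    res <- seq_chars(seq)[pos]
    bad <- which(!res %in% AROMATIC)
    if (length(bad))
      stop("template '", template_id, "': binding position ", pos[bad[1]],
           " is '", res[bad[1]], "', not an aromatic residue (W/Y/F)")
  }
  structure(
    list(template_id = template_id, family = family, seq = seq,
         known_binding_positions = pos),
    class = "template_record")
}

#' @export
print.template_record <- function(x, ...) {
  cat("<template_record> ", x$template_id, " [", x$family, "] ",
      seq_length(x$seq), " aa, ", length(x$known_binding_positions),
      " known binding residues\n", sep = "")
  invisible(x)
}
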