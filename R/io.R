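#' Read protein sequences from a FASTA file
#'
#' Parses via Biostrings and normalizes into [annotated_seq()] objects:
#' sequences are uppercased, '*' and whitespace stripped, record order
#' preserved. Headers of the form `id/start-end` set the domain coordinates.
#'
#' @param path FASTA file.
#' @return A named list of [annotated_seq()] in file order.
#' @export
read_fasta <- function(path) {
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("cannot parse FASTA '", path, "': ",
                                           conditionMessage(e)))
  if (length(set) == 0L) stop("FASTA file '", path, "' contains no records")
  ids <- sub("\\s.*$", "", names(set))
  out <- vector("list", length(set))
  for (i in seq_along(set)) {
    id <- ids[i]
    ds <- de <- NA_integer_
    m <- regmatches(id, regexec("^(.+)/(\\d+)-(\\d+)$", id))[[1]]
    if (length(m) == 4L) {
      id <- m[2]; ds <- as.integer(m[3]); de <- as.integer(m[4])
    }
    out[[i]] <- annotated_seq(id, as.character(set[[i]]),
                              domain_start = ds, domain_end = de)
  }
  names(out) <- vapply(out, `[[`, "", "id")
  out
}

#' Write sequences to FASTA
#'
#' @param seqs a list of [annotated_seq()] (or a single one).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  if (inherits(seqs, "annotated_seq")) seqs <- list(seqs)
  set <- Biostrings::AAStringSet(vapply(seqs, `[[`, "", "residues"))
  names(set) <- vapply(seqs, function(s) {
    if (!is.na(s$domain_start) && !is.na(s$domain_end))
      sprintf("%s/%d-%d", s$id, s$domain_start, s$domain_end)
    else s$id
  }, "")
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read a secondary-structure track file
#'
#' Bespoke two-line plain-text format: line 1 is the state string over
#' H/E/L (C accepted as a synonym of L), optional line 2 holds
#' comma-separated per-residue confidences in \[0, 1\]. Blank lines and lines
#' starting with '#' are ignored. States with confidence below 0.5 are
#' relabeled to loop; absent confidences are treated as confident. HAR flags
#' are initialized to all-FALSE.
#'
#' @param path track file.
#' @param seq the [annotated_seq()] the track annotates; its length must
#'   match the state string.
#' @return A new [annotated_seq()] with the track attached.
#' @export
read_secstruct_track <- function(path, seq) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) stop("track file '", path, "' is empty")
  states <- gsub("[[:space:]]", "", lines[1])
  if (nchar(states) != seq_length(seq))
    stop("track file '", path, "': state string length ", nchar(states),
         " != length of sequence '", seq$id, "' (", seq_length(seq), ")")
  conf <- NULL
  if (length(lines) >= 2L) {
    conf <- suppressWarnings(as.numeric(strsplit(lines[2], ",")[[1]]))
    if (anyNA(conf))
      stop("track file '", path, "': malformed confidence line")
  }
  annotated_seq(seq$id, seq$residues, states = states, confidences = conf,
                domain_start = seq$domain_start, domain_end = seq$domain_end)
}

#' Write a secondary-structure track file
#'
#' @param seq an [annotated_seq()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_secstruct_track <- function(seq, path) {
  lines <- paste(seq$states, collapse = "")
  if (!is.null(seq$confidences))
    lines <- c(lines, paste(format(seq$confidences, trim = TRUE),
                            collapse = ","))
  writeLines(lines, path)
  invisible(path)
}

#' Read a template profile table
#'
#' Delimited text (comma or tab, sniffed from the header) with columns
#' `template_id`, `family`, `sequence`, `known_binding_positions`
#' (semicolon-separated 1-based integers, may be empty) and optionally
#' `states`. Records are validated: binding positions must be in range and
#' carry aromatic residues.
#'
#' @param path table file.
#' @return A named list of [template_record()] in file order.
#' @export
read_template_table <- function(path) {
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- read.delim(path, sep = sep, stringsAsFactors = FALSE,
                   colClasses = "character")
  need <- c("template_id", "family", "sequence", "known_binding_positions")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("template table '", path, "': missing column(s) ",
         paste(miss, collapse = ", "))
  out <- vector("list", nrow(df))
  for (i in seq_len(nrow(df))) {
    pos <- trimws(strsplit(df$known_binding_positions[i], ";")[[1]])
    pos <- as.integer(pos[nzchar(pos)])
    states <- if ("states" %in% names(df) && nzchar(df$states[i]))
      df$states[i] else NULL
    s <- annotated_seq(df$template_id[i], df$sequence[i], states = states)
    out[[i]] <- template_record(df$template_id[i], df$family[i], s, pos)
  }
  names(out) <- vapply(out, `[[`, "", "template_id")
  out
}

#' Write a template profile table
#'
#' @param templates list of [template_record()].
#' @param path output file (written as CSV).
#' @return `path`, invisibly.
#' @export
write_template_table <- function(templates, path) {
  df <- data.frame(
    template_id = vapply(templates, `[[`, "", "template_id"),
    family = vapply(templates, `[[`, "", "family"),
    sequence = vapply(templates, function(t) t$seq$residues, ""),
    known_binding_positions = vapply(templates, function(t)
      paste(t$known_binding_positions, collapse = ";"), ""),
    states = vapply(templates, function(t)
      paste(t$seq$states, collapse = ""), ""),
    stringsAsFactors = FALSE)
  write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Merge one or two pairwise alignments sharing a target onto a common column
# space. Returns a list of equal-length rows: target first, then one row per
# template. Template-row insertions (columns where the target row holds a
# gap) are emitted before the shared target column, first alignment first.
project_on_target <- function(alignments) {
  t_idx <- lapply(alignments, `[[`, "t_idx")
  p_idx <- lapply(alignments, `[[`, "p_idx")
  p_chr <- lapply(alignments, function(a) strsplit(a$p_row, "")[[1]])
  t_chr1 <- strsplit(alignments[[1]]$t_row, "")[[1]]
  n_aln <- length(alignments)
  cur <- rep(1L, n_aln)
  len <- vapply(t_idx, length, 0L)
  t_out <- character(0)
  p_out <- rep(list(character(0)), n_aln)
  repeat {
    # flush columns that are insertions relative to the target
    for (a in seq_len(n_aln)) {
      while (cur[a] <= len[a] && t_idx[[a]][cur[a]] == 0L) {
        t_out <- c(t_out, "-")
        for (b in seq_len(n_aln))
          p_out[[b]] <- c(p_out[[b]],
                          if (b == a) p_chr[[b]][cur[b]] else "-")
        cur[a] <- cur[a] + 1L
      }
    }
    if (all(cur > len)) break
    if (any(cur > len))
      stop("alignments disagree on the shared target row")
    # all alignments now sit on the same target residue
    ti <- t_idx[[1]][cur[1]]
    for (a in seq_len(n_aln)) {
      if (cur[a] > len[a] || t_idx[[a]][cur[a]] != ti)
        stop("alignments disagree on the shared target row")
    }
    t_out <- c(t_out, t_chr1[cur[1]])
    for (a in seq_len(n_aln)) {
      p_out[[a]] <- c(p_out[[a]], p_chr[[a]][cur[a]])
      cur[a] <- cur[a] + 1L
    }
  }
  c(list(paste(t_out, collapse = "")),
    lapply(p_out, paste, collapse = ""))
}

#' Write a PIR (Modeller-dialect) alignment file
#'
#' One `>P1;` entry per sequence: templates typed `structureX`, the target
#' typed `sequence`, all rows padded onto a shared column space and
#' terminated by `'*'`. With two alignments the two target rows are
#' re-projected onto common columns via the shared target.
#'
#' @param target the target [annotated_seq()].
#' @param alignments one or two [align_pair()] results sharing that target.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_pir <- function(target, alignments, path) {
  if (inherits(alignments, "pairwise_alignment"))
    alignments <- list(alignments)
  stopifnot(length(alignments) %in% c(1L, 2L))
  for (a in alignments) {
    if (a$target_id != target$id)
      stop("alignment target '", a$target_id, "' does not match '",
           target$id, "'")
    if (gsub("-", "", a$t_row) != target$residues)
      stop("alignment target row is inconsistent with the target sequence")
  }
  rows <- project_on_target(alignments)
  n <- nchar(rows[[1]])
  lines <- character(0)
  wrap <- function(s) substring(s, seq(1, nchar(s), 75),
                                pmin(seq(1, nchar(s), 75) + 74, nchar(s)))
  for (i in seq_along(alignments)) {
    tid <- alignments[[i]]$template_id
    lines <- c(lines, paste0(">P1;", tid),
               paste0("structureX:", tid, ":1::", nchar(gsub("-", "",
                      rows[[i + 1]])), "::::0.00:0.00"),
               wrap(paste0(rows[[i + 1]], "*")))
  }
  lines <- c(lines, paste0(">P1;", target$id),
             paste0("sequence:", target$id, ":1::", seq_length(target),
                    "::::0.00:0.00"),
             wrap(paste0(rows[[1]], "*")))
  writeLines(lines, path)
  invisible(path)
}

#' Read back a PIR alignment file
#'
#' Round-trip parser for files written by [write_pir()]; used to verify the
#' shared-column projection.
#'
#' @param path PIR file.
#' @return A data.frame with columns `id`, `type`, `row` (gapped row without
#'   the terminal `'*'`).
#' @export
read_pir <- function(path) {
  lines <- readLines(path, warn = FALSE)
  starts <- grep("^>P1;", lines)
  if (!length(starts)) stop("'", path, "' contains no PIR entries")
  ends <- c(starts[-1] - 1L, length(lines))
  ids <- sub("^>P1;", "", lines[starts])
  type <- character(length(starts)); row <- character(length(starts))
  for (i in seq_along(starts)) {
    type[i] <- sub(":.*$", "", lines[starts[i] + 1L])
    body <- paste(lines[(starts[i] + 2L):ends[i]], collapse = "")
    if (!grepl("\\*", body)) stop("PIR entry '", ids[i], "' lacks a '*'")
    row[i] <- sub("\\*.*$", "", body)
  }
  data.frame(id = ids, type = type, row = row, stringsAsFactors = FALSE)
}
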