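#' @importFrom utils read.delim write.table head tail
NULL

## Residue alphabet: 20 standard amino acids plus X for ambiguity.
## U/B/Z/J/O occasionally emitted by databases are folded into X with a warning.
AA_STANDARD <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
AA_VALID <- c(AA_STANDARD, "X")
AA_AMBIGUOUS <- c("U", "B", "Z", "J", "O")

#' Normalize and validate a protein sequence
#'
#' Uppercases, strips a single terminal stop (`*`), maps the ambiguity codes
#' U/B/Z/J/O to `X` (with a warning), and rejects any remaining character
#' outside the 20 standard amino acids plus `X`.
#'
#' @param seq character scalar, raw residue string.
#' @param id identifier used in error messages.
#' @param allow_gap logical; permit `-` (for alignment rows).
#' @return normalized residue string.
#' @keywords internal
normalize_residues <- function(seq, id = "<unnamed>", allow_gap = FALSE) {
  stopifnot(is.character(seq), length(seq) == 1L)
  s <- toupper(seq)
  s <- sub("\\*$", "", s)
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  amb <- chars %in% AA_AMBIGUOUS
  if (any(amb)) {
    warning(sprintf("record '%s': %d ambiguity code(s) (%s) mapped to X",
                    id, sum(amb), paste(unique(chars[amb]), collapse = ",")),
            call. = FALSE)
    chars[amb] <- "X"
  }
  ok <- chars %in% AA_VALID | (allow_gap & chars == "-")
  if (!all(ok)) {
    bad <- which(!ok)[1L]
    stop(sprintf("record '%s': illegal residue character '%s' at position %d",
                 id, chars[bad], bad), call. = FALSE)
  }
  paste(chars, collapse = "")
}

#' Construct a collection of protein records
#'
#' A light container for named protein sequences: a `data.frame` with columns
#' `id`, `species`, `seq` and `length`, one row per protein. Sequences are
#' normalized (uppercase, terminal stop stripped, ambiguity codes to `X`) and
#' validated against the 20-standard-residue alphabet.
#'
#' @param id character vector of unique identifiers.
#' @param seq character vector of residue strings.
#' @param species optional character vector of species names.
#' @return a `protein_records` data.frame.
#' @export
#' @examples
#' protein_records(c("a", "b"), c("MKV", "mdel*"))
protein_records <- function(id, seq, species = NA_character_) {
  stopifnot(length(id) == length(seq))
  if (any(!nzchar(id)) || anyNA(id)) stop("empty record id", call. = FALSE)
  if (anyDuplicated(id)) {
    stop(sprintf("duplicate record id(s): %s",
                 paste(unique(id[duplicated(id)]), collapse = ", ")),
         call. = FALSE)
  }
  if (any(!nzchar(seq))) {
    stop(sprintf("record '%s': empty sequence", id[!nzchar(seq)][1L]),
         call. = FALSE)
  }
  seq <- mapply(normalize_residues, seq, id, USE.NAMES = FALSE)
  if (any(!nzchar(seq))) {
    stop(sprintf("record '%s': empty sequence after normalization",
                 id[!nzchar(seq)][1L]), call. = FALSE)
  }
  out <- data.frame(id = as.character(id),
                    species = rep_len(as.character(species), length(id)),
                    seq = seq,
                    length = nchar(seq),
                    stringsAsFactors = FALSE)
  class(out) <- c("protein_records", "data.frame")
  out
}

#' Read protein sequences from a FASTA file
#'
#' Records are returned in file order. Lowercase residues are uppercased, a
#' terminal `*` is stripped, and ambiguity codes are mapped to `X` with a
#' warning. The record id is the first whitespace-delimited token of the
#' header; a bracketed `[Genus species]` tag, if present, becomes the species.
#'
#' @param path FASTA file.
#' @return a [protein_records()] data.frame.
#' @export
read_fasta <- function(path) {
  raw <- parse_fasta_file(path)
  protein_records(raw$id, raw$seq, raw$species)
}

## Minimal FASTA reader shared by read_fasta/read_alignment so that parse
## errors can name the offending record (Biostrings is used for writing and
## for alignment machinery; parsing here stays under our error contract).
parse_fasta_file <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop(sprintf("empty FASTA file: %s", path), call. = FALSE)
  if (!startsWith(lines[1L], ">")) {
    stop(sprintf("malformed FASTA (no '>' header on first line): %s", path),
         call. = FALSE)
  }
  hdr <- grepl("^>", lines)
  grp <- cumsum(hdr)
  ids <- character(0); species <- character(0); seqs <- character(0)
  for (g in seq_len(max(grp))) {
    block <- lines[grp == g]
    header <- sub("^>", "", block[1L])
    id <- strsplit(trimws(header), "\\s+")[[1]][1L]
    if (is.na(id) || !nzchar(id)) {
      stop(sprintf("malformed FASTA header (record %d): empty id", g),
           call. = FALSE)
    }
    sp <- if (grepl("\\[.+\\]", header)) {
      sub(".*\\[(.+)\\].*", "\\1", header)
    } else {
      rest <- trimws(sub("^\\S+\\s*", "", trimws(header)))
      if (nzchar(rest)) rest else NA_character_
    }
    body <- paste(gsub("\\s", "", block[-1L]), collapse = "")
    if (!nzchar(body)) {
      stop(sprintf("record '%s': empty sequence", id), call. = FALSE)
    }
    ids <- c(ids, id); species <- c(species, sp); seqs <- c(seqs, body)
  }
  if (anyDuplicated(ids)) {
    stop(sprintf("duplicate record id(s): %s",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")),
         call. = FALSE)
  }
  list(id = ids, species = species, seq = seqs)
}

#' Write protein records (or alignment rows) to FASTA
#'
#' @param x a `protein_records` data.frame, a `family_alignment`, or a named
#'   character vector of sequences.
#' @param path output file.
#' @param width line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, width = 60L) {
  if (inherits(x, "family_alignment")) {
    seqs <- x$seqs
  } else if (is.data.frame(x)) {
    seqs <- stats::setNames(x$seq, x$id)
  } else {
    seqs <- x
  }
  stopifnot(!is.null(names(seqs)), all(nzchar(names(seqs))))
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Construct a family alignment from gapped sequences
#'
#' @param seqs named character vector of equal-length gapped sequences
#'   (gap character `-`).
#' @return a `family_alignment`: list with `ids`, `seqs` (named character) and
#'   `n_cols`.
#' @export
family_alignment <- function(seqs) {
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  ids <- names(seqs)
  if (anyDuplicated(ids)) {
    stop(sprintf("duplicate alignment row id(s): %s",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")),
         call. = FALSE)
  }
  widths <- nchar(seqs)
  if (length(unique(widths)) != 1L) {
    ragged <- ids[widths != stats::median(widths)]
    if (length(ragged) == 0L) ragged <- ids
    stop(sprintf("alignment rows have unequal length (offending ids: %s)",
                 paste(ragged, collapse = ", ")), call. = FALSE)
  }
  seqs <- vapply(ids, function(i) normalize_residues(seqs[[i]], i, allow_gap = TRUE),
                 character(1))
  if (length(unique(nchar(seqs))) != 1L) {
    stop("alignment rows have unequal length after normalization", call. = FALSE)
  }
  degapped <- gsub("-", "", seqs, fixed = TRUE)
  if (any(!nzchar(degapped))) {
    stop(sprintf("all-gap alignment row(s): %s",
                 paste(ids[!nzchar(degapped)], collapse = ", ")), call. = FALSE)
  }
  out <- list(ids = ids,
              seqs = stats::setNames(unname(seqs), ids),
              n_cols = unname(nchar(seqs[[1L]])))
  class(out) <- "family_alignment"
  out
}

#' Read a gapped FASTA multiple alignment
#'
#' @param path aligned FASTA file with `-` gaps.
#' @return a [family_alignment()].
#' @export
read_alignment <- function(path) {
  raw <- parse_fasta_file(path)
  family_alignment(stats::setNames(raw$seq, raw$id))
}

#' @export
print.family_alignment <- function(x, ...) {
  cat(sprintf("family_alignment: %d rows x %d columns\n",
              length(x$ids), x$n_cols))
  invisible(x)
}

#' Remove gaps from an alignment row
#' @param x character vector of gapped sequences.
#' @return ungapped sequences.
#' @export
degap <- function(x) gsub("-", "", x, fixed = TRUE)

## alignment as a character matrix (rows = taxa, cols = columns)
aln_matrix <- function(aln) {
  m <- do.call(rbind, strsplit(aln$seqs, "", fixed = TRUE))
  rownames(m) <- aln$ids
  m
}

#' Read a single Newick tree
#'
#' Thin wrapper over [ape::read.tree()] adding the validation the pipeline
#' relies on: exactly one tree, at least two leaves, unique leaf labels.
#' Branch lengths are parsed but ignored by all parsimony operations.
#'
#' @param path Newick file.
#' @return an [ape] `phylo` object.
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  tr <- tryCatch(suppressWarnings(ape::read.tree(path)),
                 error = function(e) NULL)
  if (is.null(tr)) stop(sprintf("Newick parse error in %s", path), call. = FALSE)
  if (inherits(tr, "multiPhylo")) {
    if (length(tr) != 1L) {
      stop(sprintf("expected a single Newick tree, found %d", length(tr)),
           call. = FALSE)
    }
    tr <- tr[[1L]]
  }
  validate_tree(tr)
  tr
}

validate_tree <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a phylo tree", call. = FALSE)
  if (ape::Ntip(tree) < 2L) stop("tree must have at least 2 leaves", call. = FALSE)
  if (anyDuplicated(tree$tip.label)) {
    stop(sprintf("duplicate leaf label(s): %s",
                 paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
                       collapse = ", ")), call. = FALSE)
  }
  invisible(tree)
}

#' Write a tree in Newick format
#' @param tree a `phylo` object.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Read a per-residue relative solvent accessibility table
#'
#' The expected layout is a minimal NetSurfP-like tab-separated file: comment
#' lines starting with `#`, a header row, and one row per residue with (at
#' least) columns `pos` (1-based position), `res` (one-letter residue) and
#' `rsa` (relative solvent accessibility in `[0,1]`). Positions must be
#' contiguous from 1; when `record` is supplied the residue column is
#' cross-checked against it.
#'
#' @param path tab-separated file.
#' @param id profile identifier (defaults to the file stem).
#' @param record optional single-row [protein_records()] to validate against.
#' @return an `rsa_profile`: list with `id`, `values`, `residues`.
#' @export
read_rsa_table <- function(path, id = NULL, record = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  tab <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  names(tab) <- tolower(names(tab))
  req <- c("pos", "res", "rsa")
  alias <- c(pos = "position", res = "residue", rsa = "rsa")
  for (k in req) {
    if (!k %in% names(tab) && alias[[k]] %in% names(tab)) {
      names(tab)[names(tab) == alias[[k]]] <- k
    }
  }
  missing_cols <- setdiff(req, names(tab))
  if (length(missing_cols)) {
    stop(sprintf("RSA table %s lacks column(s): %s", path,
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  if (is.null(id)) id <- sub("\\.[^.]*$", "", basename(path))
  rsa_profile(id, tab$rsa, toupper(tab$res), positions = tab$pos,
              record = record)
}

#' Construct an RSA profile
#'
#' @param id profile identifier.
#' @param values numeric accessibilities in `[0,1]`, one per residue.
#' @param residues optional one-letter residues.
#' @param positions optional 1-based positions (must be contiguous from 1).
#' @param record optional matching [protein_records()] row for cross-checking.
#' @return an `rsa_profile` object.
#' @export
rsa_profile <- function(id, values, residues = NULL, positions = NULL,
                        record = NULL) {
  values <- as.numeric(values)
  if (anyNA(values) || any(values < 0 | values > 1)) {
    bad <- which(is.na(values) | values < 0 | values > 1)[1L]
    stop(sprintf("RSA profile '%s': value out of [0,1] at row %d", id, bad),
         call. = FALSE)
  }
  n <- length(values)
  if (!is.null(positions)) {
    if (!identical(as.integer(positions), seq_len(n))) {
      gap_at <- which(as.integer(positions) != seq_len(n))[1L]
      stop(sprintf("RSA profile '%s': positions not contiguous 1..%d (first break at row %d)",
                   id, n, gap_at), call. = FALSE)
    }
  }
  if (!is.null(record)) {
    rec <- if (is.data.frame(record)) record[1L, ] else record
    if (rec$length != n) {
      stop(sprintf("RSA profile '%s' has %d rows but record '%s' has %d residues",
                   id, n, rec$id, rec$length), call. = FALSE)
    }
    if (!is.null(residues)) {
      recres <- strsplit(rec$seq, "", fixed = TRUE)[[1]]
      mismatch <- which(residues != recres & residues != "X" & recres != "X")
      if (length(mismatch)) {
        stop(sprintf("RSA profile '%s': residue mismatch with record '%s' at position %d",
                     id, rec$id, mismatch[1L]), call. = FALSE)
      }
    }
  }
  structure(list(id = id, values = values, residues = residues),
            class = "rsa_profile")
}

#' Write result tables as tab-separated files
#'
#' Each element of `results` (a data.frame) is written as
#' `<dir>/<name>.tsv` with a header row, no quoting and no row names —
#' byte-identical across reruns on identical input.
#'
#' @param results named list of data.frames.
#' @param dir output directory (created if needed).
#' @return character vector of paths written, invisibly.
#' @export
write_report_tables <- function(results, dir) {
  stopifnot(is.list(results), !is.null(names(results)), all(nzchar(names(results))))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (nm in names(results)) {
    p <- file.path(dir, paste0(nm, ".tsv"))
    write.table(results[[nm]], p, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = TRUE)
    paths <- c(paths, p)
  }
  invisible(paths)
}
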