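## ClustalX residue groups (strong and weak), as shipped with ClustalX.
## Hard-coded because published alignments annotate conservation with these
## symbols without restating the group definitions.
CLUSTALX_STRONG <- list(
  c("S", "T", "A"),
  c("N", "E", "Q", "K"),
  c("N", "H", "Q", "K"),
  c("N", "D", "E", "Q"),
  c("Q", "H", "R", "K"),
  c("M", "I", "L", "V"),
  c("M", "I", "L", "F"),
  c("H", "Y"),
  c("F", "Y", "W"))

CLUSTALX_WEAK <- list(
  c("C", "S", "A"),
  c("A", "T", "V"),
  c("S", "A", "G"),
  c("S", "T", "N", "K"),
  c("S", "T", "P", "A"),
  c("S", "G", "N", "D"),
  c("S", "N", "D", "E", "Q", "K"),
  c("N", "D", "E", "Q", "H", "K"),
  c("N", "E", "Q", "H", "R", "K"),
  c("F", "V", "L", "I", "M"),
  c("H", "F", "Y"))

#' ClustalX conservation groups
#'
#' @return list with elements `strong` and `weak`, each a list of residue
#'   sets.
#' @export
clustalx_groups <- function() list(strong = CLUSTALX_STRONG, weak = CLUSTALX_WEAK)

in_one_group <- function(residues, groups) {
  any(vapply(groups, function(g) all(residues %in% g), logical(1)))
}

#' Do two residues share a ClustalX strong group?
#' @param a,b single residue characters.
#' @return logical.
#' @keywords internal
share_strong_group <- function(a, b) {
  if (a == b) return(TRUE)
  any(vapply(CLUSTALX_STRONG, function(g) a %in% g && b %in% g, logical(1)))
}

#' Annotate a domain interval on a reference sequence
#'
#' Coordinates are 1-based inclusive residue positions on the (ungapped)
#' reference, matching the convention of published domain definitions
#' (e.g. RD1 = 36-50, RD2 = 105-127, Cter = 311-335 on mouse Dbx1).
#'
#' @param name domain name.
#' @param ref_id reference sequence id.
#' @param start,end 1-based inclusive positions.
#' @return a `domain_annotation` list.
#' @export
domain_annotation <- function(name, ref_id, start, end) {
  start <- as.integer(start); end <- as.integer(end)
  if (is.na(start) || is.na(end) || start < 1L || end < start) {
    stop(sprintf("domain '%s': invalid interval %s-%s", name, start, end),
         call. = FALSE)
  }
  structure(list(name = name, ref_id = ref_id, start = start, end = end),
            class = "domain_annotation")
}

#' Project reference domain coordinates through a family alignment
#'
#' Walks the reference row counting non-gap residues to find the alignment
#' columns carrying the reference residues `start..end`, then extracts every
#' taxon's slice at exactly those columns. Per taxon it records the slice,
#' the number of non-gap residues, and a similarity to the reference: the
#' fraction of mutually ungapped positions where the taxon residue is
#' identical to, or shares a ClustalX strong group with, the reference
#' residue.
#'
#' @param aln a [family_alignment()].
#' @param domain a [domain_annotation()].
#' @return a `projected_domain`: list with `domain`, `columns`, `slices`,
#'   `n_nongap`, `similarity`.
#' @export
project_domain <- function(aln, domain) {
  stopifnot(inherits(aln, "family_alignment"),
            inherits(domain, "domain_annotation"))
  if (!domain$ref_id %in% aln$ids) {
    stop(sprintf("reference id '%s' not found in alignment", domain$ref_id),
         call. = FALSE)
  }
  m <- aln_matrix(aln)
  refrow <- m[domain$ref_id, ]
  nongap_cols <- which(refrow != "-")
  if (domain$end > length(nongap_cols)) {
    stop(sprintf("domain '%s' end %d exceeds reference length %d",
                 domain$name, domain$end, length(nongap_cols)), call. = FALSE)
  }
  columns <- nongap_cols[domain$start:domain$end]
  refres <- refrow[columns]
  slices <- apply(m[, columns, drop = FALSE], 1L, paste, collapse = "")
  n_nongap <- apply(m[, columns, drop = FALSE], 1L,
                    function(r) sum(r != "-"))
  similarity <- vapply(aln$ids, function(tx) {
    txres <- m[tx, columns]
    both <- txres != "-" & refres != "-"
    if (!any(both)) return(0)
    mean(mapply(share_strong_group, txres[both], refres[both]))
  }, numeric(1))
  structure(list(domain = domain, columns = columns,
                 slices = slices[aln$ids],
                 n_nongap = n_nongap[aln$ids],
                 similarity = similarity[aln$ids]),
            class = "projected_domain")
}

#' ClustalX-style conservation symbols for an alignment
#'
#' Per column: `*` when the column holds a single residue type and no gaps,
#' `:` when all residues fall within one ClustalX strong group, `.` when
#' within one weak group, and space otherwise. A gap anywhere in the column
#' forbids `*` and breaks group membership (yielding space).
#'
#' @param aln a [family_alignment()] with at least two rows.
#' @return a string of length `n_cols` over `* : .` and space.
#' @export
conservation_symbols <- function(aln) {
  stopifnot(inherits(aln, "family_alignment"))
  if (length(aln$ids) < 2L) stop("conservation needs >= 2 rows", call. = FALSE)
  m <- aln_matrix(aln)
  syms <- vapply(seq_len(ncol(m)), function(j) {
    col <- m[, j]
    if (any(col == "-")) return(" ")
    u <- unique(col)
    if (length(u) == 1L) return("*")
    if (in_one_group(u, CLUSTALX_STRONG)) return(":")
    if (in_one_group(u, CLUSTALX_WEAK)) return(".")
    " "
  }, character(1))
  paste(syms, collapse = "")
}

#' Call per-taxon domain presence from a projection
#'
#' A taxon carries the domain when its coverage (non-gap residues over the
#' domain length) reaches `min_coverage` and its similarity to the reference
#' reaches `min_similarity`. The thresholds are artifact choices — published
#' presence/absence is typically read qualitatively from an alignment figure
#' — so they are parameters and are echoed in every call row.
#'
#' @param proj a `projected_domain` from [project_domain()].
#' @param min_coverage,min_similarity thresholds in `[0,1]`.
#' @return data.frame with columns `taxon`, `domain`, `present`, `coverage`,
#'   `similarity`, `min_coverage`, `min_similarity`.
#' @export
call_domain_presence <- function(proj, min_coverage = 0.6,
                                 min_similarity = 0.4) {
  stopifnot(inherits(proj, "projected_domain"))
  dlen <- proj$domain$end - proj$domain$start + 1L
  taxa <- names(proj$slices)
  coverage <- proj$n_nongap / dlen
  similarity <- proj$similarity
  present <- coverage >= min_coverage & similarity >= min_similarity
  data.frame(taxon = taxa,
             domain = proj$domain$name,
             present = unname(present),
             coverage = unname(coverage),
             similarity = unname(similarity),
             min_coverage = min_coverage,
             min_similarity = min_similarity,
             row.names = NULL)
}

#' In-silico construct editing
#'
#' Deterministic sequence edits mirroring deletion-construct cloning:
#' `delete_interval` removes residues `start..end` (1-based inclusive),
#' `truncate_cterm` removes the last `n` residues, and `append_cterm`
#' appends the last `n` residues of a donor protein. Edited records carry a
#' suffix naming the edit; `truncate_cterm(x, 0)` is the identity.
#'
#' @param record a single-row [protein_records()] data.frame.
#' @param start,end interval to delete, 1-based inclusive.
#' @param n number of C-terminal residues.
#' @param donor donor record for `append_cterm`.
#' @return an edited single-row [protein_records()] data.frame.
#' @export
delete_interval <- function(record, start, end) {
  rec <- as_record_row(record)
  start <- as.integer(start); end <- as.integer(end)
  if (start < 1L || end < start || end > rec$length) {
    stop(sprintf("delete_interval: interval %d-%d out of range for '%s' (%d aa)",
                 start, end, rec$id, rec$length), call. = FALSE)
  }
  newseq <- paste0(substr(rec$seq, 1L, start - 1L),
                   substr(rec$seq, end + 1L, rec$length))
  protein_records(paste0(rec$id, "_del", start, "-", end), newseq, rec$species)
}

#' @rdname delete_interval
#' @export
truncate_cterm <- function(record, n) {
  rec <- as_record_row(record)
  n <- as.integer(n)
  if (n < 0L || n > rec$length) {
    stop(sprintf("truncate_cterm: n=%d out of range for '%s' (%d aa)",
                 n, rec$id, rec$length), call. = FALSE)
  }
  if (n == 0L) return(record)
  delete_result <- delete_interval(record, rec$length - n + 1L, rec$length)
  delete_result$id <- paste0(rec$id, "_dC", n)
  delete_result
}

#' @rdname delete_interval
#' @export
append_cterm <- function(record, donor, n) {
  rec <- as_record_row(record)
  don <- as_record_row(donor)
  n <- as.integer(n)
  if (n < 1L || n > don$length) {
    stop(sprintf("append_cterm: n=%d out of range for donor '%s' (%d aa)",
                 n, don$id, don$length), call. = FALSE)
  }
  tail_seq <- substr(don$seq, don$length - n + 1L, don$length)
  protein_records(paste0(rec$id, "_plusC", n),
                  paste0(rec$seq, tail_seq), rec$species)
}

#' @rdname delete_interval
#' @param edit a list describing the edit: `list(type = "delete_interval",
#'   start=, end=)`, `list(type = "truncate_cterm", n=)` or
#'   `list(type = "append_cterm", donor=, n=)`.
#' @export
build_construct <- function(record, edit) {
  stopifnot(is.list(edit), !is.null(edit$type))
  switch(edit$type,
         delete_interval = delete_interval(record, edit$start, edit$end),
         truncate_cterm = truncate_cterm(record, edit$n),
         append_cterm = append_cterm(record, edit$donor, edit$n),
         stop(sprintf("unknown edit type '%s'", edit$type), call. = FALSE))
}

as_record_row <- function(x) {
  if (is.data.frame(x)) {
    stopifnot(nrow(x) == 1L)
    x
  } else {
    stop("expected a single-row protein_records data.frame", call. = FALSE)
  }
}
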