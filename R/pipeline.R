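#' Run the full domain-evolution analysis from one configuration
#'
#' Orchestrates the stages: sequence/alignment input, clustered-acidic
#' C-terminal (Cter) calling, reference-anchored domain projection and
#' presence calls, column conservation, gain/loss scenario comparison on the
#' species tree, RSA summaries, and pairwise identities. Stages whose inputs
#' are absent from the configuration are skipped with a logged message.
#' All tables plus a JSON roll-up (with a provenance block: parameters,
#' package version, input checksums) are written under `out_dir`; reruns on
#' identical inputs produce byte-identical outputs.
#'
#' @param config a named list (or path to a YAML file) with entries:
#'   \describe{
#'     \item{alignment}{path to a gapped FASTA, or a [family_alignment()].}
#'     \item{tree}{path to a Newick file, or a `phylo` tree.}
#'     \item{fasta}{optional unaligned FASTA (or [protein_records()]) for
#'       pairwise identity.}
#'     \item{rsa}{optional named list mapping sequence id to an RSA table
#'       path (or to an `rsa_profile`).}
#'     \item{ref_id}{reference sequence id for domain projection.}
#'     \item{domains}{data.frame with `name`, `start`, `end` (1-based
#'       inclusive on the reference).}
#'     \item{scan}{optional list of [acidic_scan_params()] arguments.}
#'     \item{min_coverage, min_similarity}{presence thresholds.}
#'     \item{alpha}{significance level for RSA comparisons.}
#'     \item{out_dir}{output directory.}
#'   }
#' @return an `analysis_report` list (tables plus provenance), invisibly
#'   when `out_dir` is set.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("reading a YAML config requires the yaml package", call. = FALSE)
    }
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  cfg <- config
  report <- list()
  checksums <- list()

  note <- function(fmt, ...) message(sprintf(paste0("[pipeline] ", fmt), ...))

  load_path <- function(x, reader, what) {
    if (is.character(x) && length(x) == 1L) {
      checksums[[basename(x)]] <<- unname(tools::md5sum(x))
      reader(x)
    } else x
  }

  aln <- if (!is.null(cfg$alignment)) {
    load_path(cfg$alignment, read_alignment, "alignment")
  } else NULL
  tree <- if (!is.null(cfg$tree)) load_path(cfg$tree, read_newick, "tree") else NULL
  fasta <- if (!is.null(cfg$fasta)) load_path(cfg$fasta, read_fasta, "fasta") else NULL

  scan_params <- do.call(acidic_scan_params,
                         if (is.null(cfg$scan)) list() else cfg$scan)
  min_coverage <- if (is.null(cfg$min_coverage)) 0.6 else cfg$min_coverage
  min_similarity <- if (is.null(cfg$min_similarity)) 0.4 else cfg$min_similarity
  alpha <- if (is.null(cfg$alpha)) 0.01 else cfg$alpha

  ## --- Cter calls on the family sequences ---------------------------------
  family_records <- if (!is.null(fasta)) fasta
  else if (!is.null(aln)) protein_records(aln$ids, degap(aln$seqs))
  else NULL
  if (!is.null(family_records)) {
    report$cter_calls <- classify_family(family_records, scan_params)
  } else {
    note("no sequences given; skipping Cter classification")
  }

  ## --- domain projection / conservation -----------------------------------
  presence_mat <- NULL
  if (!is.null(aln) && !is.null(cfg$ref_id) && !is.null(cfg$domains)) {
    doms <- cfg$domains
    calls <- list()
    for (i in seq_len(nrow(doms))) {
      d <- domain_annotation(doms$name[i], cfg$ref_id, doms$start[i], doms$end[i])
      proj <- project_domain(aln, d)
      calls[[d$name]] <- call_domain_presence(proj, min_coverage, min_similarity)
    }
    report$domain_presence <- do.call(rbind, calls)
    rownames(report$domain_presence) <- NULL
    presence_mat <- do.call(cbind, lapply(calls, function(x) {
      stats::setNames(as.integer(x$present), x$taxon)[aln$ids]
    }))
    rownames(presence_mat) <- aln$ids
    report$conservation <- data.frame(symbols = conservation_symbols(aln))
  } else {
    note("alignment, ref_id or domains missing; skipping domain projection")
  }

  ## Cter presence column from the scanner, if both stages ran
  if (!is.null(presence_mat) && !is.null(report$cter_calls)) {
    cc <- report$cter_calls
    shared <- intersect(rownames(presence_mat), cc$seq_id)
    if (length(shared) == length(rownames(presence_mat)) &&
        !"Cter" %in% colnames(presence_mat)) {
      presence_mat <- cbind(presence_mat,
                            Cter = stats::setNames(as.integer(cc$positive),
                                                   cc$seq_id)[rownames(presence_mat)])
    }
  }
  if (!is.null(presence_mat)) {
    report$presence_matrix <- data.frame(taxon = rownames(presence_mat),
                                         presence_mat, row.names = NULL,
                                         check.names = FALSE)
  }

  ## --- scenario comparison on the tree -------------------------------------
  if (!is.null(tree) && !is.null(presence_mat)) {
    report$scenarios <- compare_scenarios(tree, presence_mat)
  } else {
    note("tree or presence matrix missing; skipping scenario comparison")
  }

  ## --- RSA ------------------------------------------------------------------
  if (!is.null(cfg$rsa) && !is.null(cfg$domains)) {
    doms <- cfg$domains
    summaries <- list(); comparisons <- list()
    for (id in names(cfg$rsa)) {
      prof <- if (is.character(cfg$rsa[[id]])) {
        checksums[[basename(cfg$rsa[[id]])]] <- unname(tools::md5sum(cfg$rsa[[id]]))
        read_rsa_table(cfg$rsa[[id]], id = id)
      } else cfg$rsa[[id]]
      sm <- domain_rsa_summary(prof, doms)
      sm$profile <- id
      summaries[[id]] <- sm
      dlist <- as_domain_list(doms)
      if (length(dlist) >= 2L) {
        for (i in seq_len(length(dlist) - 1L)) {
          for (j in seq(i + 1L, length(dlist))) {
            cmp <- compare_domains(rsa_domain_values(prof, dlist[[i]]),
                                   rsa_domain_values(prof, dlist[[j]]),
                                   alpha = alpha,
                                   name_a = dlist[[i]]$name,
                                   name_b = dlist[[j]]$name)
            comparisons[[length(comparisons) + 1L]] <-
              data.frame(profile = id, group_a = cmp$group_a,
                         group_b = cmp$group_b, n_a = cmp$n_a, n_b = cmp$n_b,
                         u = cmp$u_statistic, p_value = cmp$p_value,
                         method = cmp$method, significant = cmp$significant)
          }
        }
      }
    }
    report$rsa_summaries <- do.call(rbind, summaries)
    rownames(report$rsa_summaries) <- NULL
    if (length(comparisons)) {
      report$rsa_comparisons <- do.call(rbind, comparisons)
    }
  } else {
    note("no RSA tables; skipping RSA summaries")
  }

  ## --- pairwise identity ----------------------------------------------------
  if (!is.null(fasta) && nrow(fasta) >= 2L) {
    pairs <- utils::combn(seq_len(nrow(fasta)), 2L)
    rows <- lapply(seq_len(ncol(pairs)), function(k) {
      i <- pairs[1L, k]; j <- pairs[2L, k]
      r <- global_align(fasta[i, ], fasta[j, ])
      data.frame(id_a = r$id_a, id_b = r$id_b, score = r$score,
                 n_identical = r$n_identical, n_scored_cols = r$n_scored_cols,
                 identity_pct = r$identity_pct)
    })
    report$pairwise_identity <- do.call(rbind, rows)
  } else {
    note("fewer than two unaligned sequences; skipping pairwise identity")
  }

  report$provenance <- list(
    package = "acidtrace",
    version = as.character(utils::packageVersion("acidtrace")),
    parameters = list(scan = unclass(scan_params),
                      min_coverage = min_coverage,
                      min_similarity = min_similarity,
                      alpha = alpha,
                      ref_id = cfg$ref_id),
    input_md5 = checksums)
  class(report) <- "analysis_report"

  if (!is.null(cfg$out_dir)) {
    tabs <- report[vapply(report, is.data.frame, logical(1))]
    write_report_tables(tabs, cfg$out_dir)
    jsonlite::write_json(
      list(tables = names(tabs), provenance = report$provenance),
      file.path(cfg$out_dir, "report.json"),
      auto_unbox = TRUE, pretty = TRUE, digits = NA)
    return(invisible(report))
  }
  report
}
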