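#!/usr/bin/env Rscript

## Step 2 — scan every family member for the clustered-acidic C-terminal
## criterion (10-aa window, >= 80 % D/E within the terminal region), project
## the RD1/RD2 reference coordinates through the alignment, and score
## column conservation. Run analysis/01_simulate_family.R first.

suppressPackageStartupMessages(library(acidtrace))

out <- file.path("results", "analysis")
records <- read_fasta(file.path(out, "family.fa"))
aln <- read_alignment(file.path(out, "family.afa"))

## Cter classification
calls <- classify_family(records, acidic_scan_params())
s <- attr(calls, "summary")
cat(sprintf("Cter scan: %d positive, %d negative of %d sequences\n",
            s["positive"], s["negative"], nrow(calls)))

## domain projection from the first taxon as reference
ref_id <- records$id[1]
domains <- data.frame(name = c("RD1", "RD2"),
                      start = c(36L, 105L), end = c(50L, 127L))
presence <- do.call(rbind, lapply(seq_len(nrow(domains)), function(i) {
  d <- domain_annotation(domains$name[i], ref_id, domains$start[i], domains$end[i])
  call_domain_presence(project_domain(aln, d))
}))
cat(sprintf("domain presence (reference %s): RD1 %d/%d, RD2 %d/%d taxa\n",
            ref_id,
            sum(presence$present[presence$domain == "RD1"]), nrow(records),
            sum(presence$present[presence$domain == "RD2"]), nrow(records)))

cons <- conservation_symbols(aln)
cat(sprintf("conservation: %d identical (*), %d strong (:), %d weak (.) of %d columns\n",
            lengths(regmatches(cons, gregexpr("\\*", cons))),
            lengths(regmatches(cons, gregexpr(":", cons))),
            lengths(regmatches(cons, gregexpr("\\.", cons))), nchar(cons)))

## presence matrix joining projected domains with the scanner's Cter call
pm <- data.frame(taxon = records$id,
                 RD1 = as.integer(presence$present[presence$domain == "RD1"]),
                 RD2 = as.integer(presence$present[presence$domain == "RD2"]),
                 Cter = as.integer(calls$positive))
write_report_tables(list(cter_calls = calls,
                         domain_presence = presence,
                         presence_matrix = pm,
                         conservation = data.frame(symbols = cons)), out)
cat(sprintf("wrote cter_calls / domain_presence / presence_matrix / conservation under %s\n",
            out))
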