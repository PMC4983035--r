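mini_aln <- function(...) family_alignment(c(...))

test_that("ungapped projection is the identity on coordinates", {
  aln <- mini_aln(ref = "MKVLS", tx = "MKILT")
  proj <- project_domain(aln, domain_annotation("d", "ref", 2, 4))
  expect_equal(proj$columns, 2:4)
  expect_equal(unname(proj$slices["tx"]), "KIL")
  expect_equal(unname(proj$n_nongap["tx"]), 3L)
})

test_that("gaps in the reference shift projected columns", {
  aln <- mini_aln(ref = "A-CD", tx = "AGCD")
  proj <- project_domain(aln, domain_annotation("d", "ref", 2, 3))
  expect_equal(proj$columns, c(3L, 4L))
  expect_equal(unname(proj$slices["ref"]), "CD")
})

test_that("projection errors on bad reference or coordinates", {
  aln <- mini_aln(ref = "ACDE", tx = "ACDE")
  expect_error(project_domain(aln, domain_annotation("d", "ref", 1, 5)),
               "exceeds reference length")
  expect_error(project_domain(aln, domain_annotation("d", "zz", 1, 2)),
               "not found")
  expect_error(domain_annotation("d", "ref", 3, 2), "invalid interval")
})

test_that("degapping the reference slice recovers the reference substring", {
  set.seed(31)
  for (rep in 1:10) {
    res <- random_seq(40)
    gapped <- strsplit(res, "")[[1]]
    for (g in sort(sample(40, 8))) {
      gapped <- append(gapped, "-", after = g)
    }
    aln <- mini_aln(ref = paste(gapped, collapse = ""),
                    tx = paste(sample(c(AA20, "-"), length(gapped),
                                      replace = TRUE), collapse = ""))
    s <- sample(1:30, 1); e <- s + sample(0:9, 1)
    proj <- project_domain(aln, domain_annotation("d", "ref", s, e))
    expect_equal(degap(unname(proj$slices["ref"])), substr(res, s, e))
  }
})

test_that("conservation symbols follow the ClustalX rules", {
  aln <- mini_aln(a = "AIDCA", b = "ALWSA", c = "AVWAA")
  ## col1 identical A -> '*'; col2 {I,L,V} strong -> ':';
  ## col3 {D,W} no group -> ' '; col4 {C,S,A} weak -> '.'; col5 '*'
  expect_equal(conservation_symbols(aln), "*: .*")
  ## {D,K} share the SNDEQK weak group, so it earns '.' rather than blank
  expect_equal(conservation_symbols(mini_aln(a = "D", b = "K")), ".")
})

test_that("a gap in a column forbids conservation marks", {
  aln <- mini_aln(a = "AA", b = "A-")
  expect_equal(conservation_symbols(aln), "* ")
})

test_that("conservation is invariant to row order and duplicate rows", {
  set.seed(13)
  seqs <- c(a = random_seq(25), b = random_seq(25), c = random_seq(25))
  s1 <- conservation_symbols(family_alignment(seqs))
  s2 <- conservation_symbols(family_alignment(seqs[c(3, 1, 2)]))
  s3 <- conservation_symbols(family_alignment(c(seqs, d = unname(seqs["a"]))))
  expect_equal(s1, s2)
  expect_equal(s1, s3)
})

test_that("presence calls apply coverage and similarity thresholds", {
  aln <- mini_aln(ref = "MKVLSTAQGRIWNPH", tx = "MKVLSTA--------")
  proj <- project_domain(aln, domain_annotation("d", "ref", 1, 15))
  calls <- call_domain_presence(proj)
  ref_row <- calls[calls$taxon == "ref", ]
  expect_true(ref_row$present)
  expect_equal(ref_row$coverage, 1)
  expect_equal(ref_row$similarity, 1)
  tx_row <- calls[calls$taxon == "tx", ]
  expect_equal(tx_row$coverage, 7 / 15)
  expect_false(tx_row$present)  # coverage below 0.6

  ## taxon all-gap across the domain columns (but not across the alignment)
  allgap <- mini_aln(ref = "MKVLSA", tx = "-----A")
  cg <- call_domain_presence(project_domain(allgap,
                                            domain_annotation("d", "ref", 1, 5)))
  expect_equal(cg$coverage[cg$taxon == "tx"], 0)
  expect_false(cg$present[cg$taxon == "tx"])
})

test_that("raising min_similarity never turns absent into present", {
  set.seed(77)
  for (rep in 1:10) {
    aln <- mini_aln(ref = random_seq(20), tx = random_seq(20))
    proj <- project_domain(aln, domain_annotation("d", "ref", 3, 17))
    lo <- call_domain_presence(proj, min_similarity = 0.2)
    hi <- call_domain_presence(proj, min_similarity = 0.6)
    expect_true(all(hi$present <= lo$present))
  }
})

test_that("strong-group matches count toward similarity", {
  ## V vs I share the MILV strong group but are not identical
  aln <- mini_aln(ref = "VVVVV", tx = "IIIII")
  proj <- project_domain(aln, domain_annotation("d", "ref", 1, 5))
  expect_equal(unname(proj$similarity["tx"]), 1)
})

test_that("construct edits do exact interval arithmetic", {
  rec <- protein_records("mDbx1_like", random_seq(335))
  del <- delete_interval(rec, 36, 50)
  expect_equal(del$length, 320L)
  expect_equal(del$id, "mDbx1_like_del36-50")
  expect_equal(substr(del$seq, 1, 35), substr(rec$seq, 1, 35))
  expect_equal(substr(del$seq, 36, 320), substr(rec$seq, 51, 335))

  expect_identical(truncate_cterm(rec, 0), rec)

  tr <- truncate_cterm(rec, 21)
  same <- delete_interval(rec, 335 - 21 + 1, 335)
  expect_equal(tr$seq, same$seq)

  donor <- protein_records("donor", random_seq(335))
  app <- append_cterm(rec, donor, 25)
  expect_equal(app$length, 360L)
  expect_equal(substr(app$seq, 336, 360), substr(donor$seq, 311, 335))

  expect_error(delete_interval(rec, 300, 400), "out of range")
})

test_that("disjoint deletions commute after coordinate shift", {
  rec <- protein_records("r", random_seq(100))
  ## delete 10-19 then (shifted) 40-49, vs 50-59 then 10-19
  a <- delete_interval(delete_interval(rec, 10, 19), 40, 49)
  b <- delete_interval(delete_interval(rec, 50, 59), 10, 19)
  expect_equal(a$seq, b$seq)
})

test_that("build_construct dispatches on edit type", {
  rec <- protein_records("r", random_seq(50))
  expect_equal(build_construct(rec, list(type = "truncate_cterm", n = 5))$length, 45L)
  expect_error(build_construct(rec, list(type = "nope")), "unknown edit")
})
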