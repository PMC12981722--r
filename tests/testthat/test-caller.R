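test_that("depth QC is a strict, exhaustive, disjoint partition", {
  qc <- qc_filter(c(s1 = 150, s2 = 100, s3 = 99), threshold = 100)
  expect_identical(qc$passed, "s1")          # 100x is not >100x
  expect_setequal(qc$failed, c("s2", "s3"))
  expect_identical(qc_filter(numeric()), list(passed = character(),
                                              failed = character()))
  expect_error(qc_filter(c(a = -1)), "negative")

  set.seed(42)
  depths <- setNames(runif(20, 50, 150), paste0("x", 1:20))
  qc <- qc_filter(depths, 100)
  expect_identical(sort(qc$passed), sort(names(depths)[depths > 100]))
  expect_length(c(qc$passed, qc$failed), 20L)
})

test_that("core-set matching assigns the most specific star allele", {
  # the two variants that define *2
  cl <- match_haplotype(rsid_keys(d6, c("rs16947", "rs1135840")), d6)
  expect_identical(cl$allele, "*2")
  expect_length(cl$unexplained, 0L)
  expect_false(cl$is_novel_suballele)
  expect_true(is.na(cl$suballele))

  # a variant-free haplotype is the default allele
  ref <- match_haplotype(character(), d6)
  expect_identical(ref$allele, "*1")
  expect_false(ref$is_novel_suballele)

  # the single-variant uncertain-function allele
  expect_identical(match_haplotype(rsid_keys(d6, "rs118203758"), d6)$allele,
                   "*71")

  # rs76326664 on a *2 background is the catalogued *2.039 suballele
  full <- match_haplotype(rsid_keys(d6, c("rs16947", "rs1135840",
                                          "rs76326664")), d6)
  expect_identical(full$allele, "*2")
  expect_identical(full$suballele, "*2.039")
  expect_false(full$is_novel_suballele)
})

test_that("variants unexplained by the catalogue flag a novel suballele", {
  # with *2.039 absent from the table, the same haplotype is a novel candidate
  rows <- c("CYP2D6\t*1\t.\tnormal\t1\tnone\t.",
            "CYP2D6\t*2\t.\tnormal\t1\tnone\t7870:C>T:rs16947;9200:C>G:rs1135840")
  slim <- tiny_table(rows, gene = "CYP2D6")
  cl <- match_haplotype(c("7870:C>T", "9200:C>G", "6810:A>G"), slim)
  expect_identical(cl$allele, "*2")
  expect_identical(cl$unexplained, "6810:A>G")
  expect_true(cl$is_novel_suballele)
})

test_that("ties are broken deterministically and residual ties error", {
  rows <- c("GX\t*1\t.\tnormal\t1\tnone\t.",
            "GX\t*3\t.\tnormal\t1\tnone\t10:A>G",
            "GX\t*7\t.\tnormal\t1\tnone\t20:C>T")
  tab <- tiny_table(rows)
  # equal core size and equal unexplained count: lower star number wins
  expect_identical(match_haplotype(c("10:A>G", "20:C>T"), tab)$allele, "*3")

  rows_bad <- c("GX\t*1\t.\tnormal\t1\tnone\t.",
                "GX\t*A\t.\tnormal\t1\tnone\t10:A>G",
                "GX\t*B\t.\tnormal\t1\tnone\t20:C>T")
  tab_bad <- tiny_table(rows_bad)
  expect_error(match_haplotype(c("10:A>G", "20:C>T"), tab_bad), "ambiguous")
})

test_that("adding a superset allele's core variant raises specificity", {
  # *10 is defined by rs1065852; *4 by rs1065852 + rs3892097
  expect_identical(match_haplotype(rsid_keys(d6, "rs1065852"), d6)$allele,
                   "*10")
  expect_identical(
    match_haplotype(rsid_keys(d6, c("rs1065852", "rs3892097")), d6)$allele,
    "*4")
})

test_that("matching agrees with the exhaustive-search oracle", {
  pool <- rsid_keys(d6, c("rs1065852", "rs3892097", "rs16947", "rs1135840",
                          "rs769258", "rs28371725", "rs1080985",
                          "rs118203758", "rs377617003", "rs76326664"))
  # every haplotype of up to 6 variants drawn from the pool
  for (k in 0:6) {
    combos <- combn(length(pool), k)
    for (j in seq_len(ncol(combos))) {
      hap <- pool[combos[, j]]
      expect_identical(match_haplotype(hap, d6)$allele, oracle_match(hap, d6))
    }
  }
})

test_that("novel candidates aggregate by variant and host allele", {
  novel <- "9600:A>G"  # reserved position, in no catalogued allele
  calls <- replicate(5, match_haplotype(c(rsid_keys(d6, c("rs1065852",
                                                          "rs3892097")),
                                          novel), d6),
                     simplify = FALSE)
  tab <- collect_novel_candidates(calls)
  expect_equal(tab, data.frame(key = novel, host_allele = "*4",
                               n_observed = 5L))
  expect_equal(nrow(collect_novel_candidates(
    list(match_haplotype(character(), d6)))), 0L)
})

test_that("haplotype TSVs round-trip variant sets", {
  path <- withr::local_tempfile(fileext = ".tsv")
  long <- data.frame(sample_id = c("a", "a", "a", "b", "b"),
                     hap_index = c(1L, 1L, 2L, 1L, 2L),
                     key = c("7870:C>T", "9200:C>G", NA, "5119:C>T", NA))
  write_haplotype_tsv(long, path)
  back <- read_haplotype_tsv(path)
  for (s in c("a", "b")) for (h in 1:2) {
    want <- sort(long$key[long$sample_id == s & long$hap_index == h &
                            !is.na(long$key)])
    got <- sort(back$key[back$sample_id == s & back$hap_index == h &
                           !is.na(back$key)])
    expect_identical(got, want)
  }
})
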