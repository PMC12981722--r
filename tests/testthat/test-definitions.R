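test_that("packaged definition tables contain the catalogued alleles", {
  base <- d6$alleles[is.na(d6$alleles$suballele), ]
  expect_true(all(c("*1", "*2", "*4", "*5", "*6", "*9", "*10", "*33", "*35",
                    "*41", "*59", "*71", "*108") %in% base$name))
  expect_false(anyDuplicated(base$name) > 0)
  subs <- d6$alleles$suballele[!is.na(d6$alleles$suballele)]
  expect_setequal(subs, c("*1.069", "*1.070", "*1.071", "*2.038", "*2.039",
                          "*4.036", "*4.037", "*4.038", "*41.010", "*186.001"))

  c19_base <- c19$alleles[is.na(c19$alleles$suballele), ]
  expect_setequal(c19_base$name, c("*1", "*2", "*3", "*17"))
  expect_identical(allele_function(c19, "*2"), "no_function")

  # *71 is defined by rs118203758 and has uncertain function, no score
  expect_identical(d6$core[["*71"]]$rsid, "rs118203758")
  expect_identical(allele_function(d6, "*71"), "uncertain")
  expect_true(is.na(base$activity[base$name == "*71"]))
})

test_that("activity values follow the published per-allele scores", {
  want <- c("*1" = 1, "*2" = 1, "*4" = 0, "*5" = 0, "*6" = 0, "*9" = 0.5,
            "*10" = 0.25, "*33" = 1, "*35" = 1, "*41" = 0.5, "*59" = 0.5)
  for (al in names(want))
    expect_equal(allele_activity(d6, al), want[[al]], info = al)
  expect_true(is.na(allele_activity(d6, "*108")))
  # a duplication label contributes N times the base value
  expect_equal(allele_activity(d6, "*1x2"), 2)
  expect_equal(allele_activity(d6, "*2x3"), 3)
})

test_that("malformed definition TSVs are rejected with line context", {
  empty <- withr::local_tempfile(fileext = ".tsv")
  writeLines("gene\tallele\tsuballele\tfunction\tactivity_score\tstructural\tvariants",
             empty)
  expect_error(load_definition_table(empty, "GX"), "no allele rows")
  expect_error(load_definition_table(tempfile(), "GX"), "not found")

  expect_error(tiny_table(c("GX\t*1\t.\tnormal\t1\tnone\t.",
                            "GX\t*2\t.\tbogus\t1\tnone\t10:A>G")),
               "line 3")
  # duplicate (name, suballele) rows
  expect_error(tiny_table(c("GX\t*1\t.\tnormal\t1\tnone\t.",
                            "GX\t*1\t.\tnormal\t1\tnone\t.")),
               "duplicate")
  # missing default allele
  expect_error(tiny_table("GX\t*2\t.\tnormal\t1\tnone\t10:A>G"),
               "default allele")
  # deletion alleles cannot carry variants
  expect_error(tiny_table(c("GX\t*1\t.\tnormal\t1\tnone\t.",
                            "GX\t*5\t.\tno_function\t0\tdeletion\t10:A>G")),
               "deletion")
  # uncertain function cannot carry a numeric activity score
  expect_error(tiny_table(c("GX\t*1\t.\tnormal\t1\tnone\t.",
                            "GX\t*7\t.\tuncertain\t1\tnone\t10:A>G")),
               "activity")
})

test_that("variant tokens parse and reject malformed input", {
  v <- parse_variant_tokens("5102:G>A:rs377617003:R28H:42130709;4674:T>C")
  expect_equal(v$gene_pos, c(5102L, 4674L))
  expect_equal(v$key, c("5102:G>A", "4674:T>C"))
  expect_equal(v$rsid, c("rs377617003", NA))
  expect_equal(v$grch38_pos, c(42130709L, NA))
  expect_equal(nrow(parse_variant_tokens(".")), 0L)
  expect_error(parse_variant_tokens("10:A>A"), "identical")
  expect_error(parse_variant_tokens("10:A>N"), "A,C,G,T")
  expect_error(parse_variant_tokens("0:A>G"), "positive")
  expect_error(parse_variant_tokens("10:A>G;10:A>G"), "duplicate")
})

test_that("builtin_table rejects unsupported genes", {
  expect_error(builtin_table("CYP3A5"), "CYP2D6")
})

test_that("dual coordinates satisfy a single reverse-strand sum constant", {
  # brute-force the constant over the ten catalogued dual-coordinate pairs
  sums <- novel_coord_pairs$gene_pos + novel_coord_pairs$grch38_pos
  expect_length(unique(sums), 1L)
  expect_equal(check_coordinate_consistency(d6), sums[1])

  # corrupting one genomic coordinate must be caught and named
  bad <- tiny_table(c("GX\t*1\t.\tnormal\t1\tnone\t.",
                      "GX\t*2\t.\tnormal\t1\tnone\t100:A>G:.:.:9900;200:C>T:.:.:9999"))
  expect_error(check_coordinate_consistency(bad), "200:C>T")
  one <- tiny_table(c("GX\t*1\t.\tnormal\t1\tnone\t.",
                      "GX\t*2\t.\tnormal\t1\tnone\t100:A>G:.:.:9900"))
  expect_error(check_coordinate_consistency(one), "at least two")
})

test_that("definition tables round-trip through the TSV writer", {
  for (tab in list(d6, c19)) {
    path <- withr::local_tempfile(fileext = ".tsv")
    write_definition_table(tab, path)
    back <- load_definition_table(path, tab$gene,
                                  reference_id = tab$reference_id)
    expect_equal(back$alleles, tab$alleles)
    expect_equal(back$core, tab$core)
    expect_equal(back$sub, tab$sub)
    expect_identical(back$default_allele, tab$default_allele)
  }
})

test_that("rsid_keys resolves identifiers and flags unknowns", {
  expect_identical(rsid_keys(d6, c("rs16947", "rs1135840")),
                   c("7870:C>T", "9200:C>G"))
  expect_error(rsid_keys(d6, "rs0"), "rs0")
})
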