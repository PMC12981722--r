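table1_freqs <- function() {
  counts <- study_allele_counts("CYP2D6")
  counts / sum(counts)
}

test_that("simulation configs validate their invariants", {
  expect_error(sim_config("CYP2D6", c("*1" = 0.6, "*2" = 0.3), 10), "sum to 1")
  expect_error(sim_config("CYP2D6", c("*1" = 1), 0), "n_individuals")
  expect_error(sim_config("CYP2D6", c(0.5, 0.5), 10), "named")
  cfg <- sim_config("CYP2D6", c("*1" = 1), 5)
  expect_s3_class(cfg, "pgx_simconfig")
  # alleles absent from the table fail before sampling
  bad <- sim_config("CYP2D6", c("*1" = 0.5, "*999" = 0.5), 5)
  expect_error(simulate_cohort(bad, d6), "not found")
})

test_that("a degenerate frequency vector yields an all-reference cohort", {
  sim <- simulate_cohort(sim_config("CYP2D6", c("*1" = 1), 10, seed = 3L))
  expect_identical(unique(sim$ledger$diplotypes$display), "*1/*1")
  expect_identical(unique(sim$haplotypes$variants), ".")
  expect_length(sim$structural, 0L)
  expect_length(sim$depths, 10L)
})

test_that("identical config and seed reproduce the simulation exactly", {
  cfg <- sim_config("CYP2D6", table1_freqs(), 60,
                    novel_injection_rate = 0.05, suballele_rate = 0.2,
                    seed = 99L)
  a <- simulate_cohort(cfg); b <- simulate_cohort(cfg)
  expect_identical(a, b)
  dir_a <- withr::local_tempdir(); dir_b <- withr::local_tempdir()
  pa <- write_simulation(a, dir_a); pb <- write_simulation(b, dir_b)
  for (f in c("vcf", "structural", "depth"))
    expect_identical(readLines(pa[[f]]), readLines(pb[[f]]))
})

test_that("sampled allele frequencies recover the input vector", {
  freqs <- table1_freqs()
  sim <- simulate_cohort(sim_config("CYP2D6", freqs, 800, seed = 5L))
  drawn <- unlist(sim$ledger$diplotypes[c("hap1", "hap2")])
  for (al in c("*1", "*2", "*4", "*71")) {
    p <- freqs[[al]]
    se <- sqrt(p * (1 - p) / 1600)
    expect_lt(abs(mean(drawn == al) - p), 3 * se + 1e-12)
  }
})

test_that("novel-variant injection follows its rate and is fully logged", {
  cfg <- sim_config("CYP2D6", table1_freqs(), 1000,
                    novel_injection_rate = 0.05, seed = 17L)
  sim <- simulate_cohort(cfg)
  n_inj <- nrow(sim$ledger$injections)
  se <- sqrt(0.05 * 0.95 * 2000)
  expect_lt(abs(n_inj - 0.05 * 2000), 3 * se)
  # every injected key sits in the reserved pool, outside the catalogue
  pos <- as.integer(sub(":.*", "", sim$ledger$injections$key))
  expect_true(all(pos >= 9501 & pos <= 9900))
  expect_false(any(sim$ledger$injections$key %in% all_variants(d6)$key))
})

test_that("phased VCF emission round-trips haplotype variant sets", {
  cfg <- sim_config("CYP2D6", table1_freqs(), 40,
                    novel_injection_rate = 0.1, suballele_rate = 0.3,
                    seed = 21L)
  sim <- simulate_cohort(cfg)
  path <- withr::local_tempfile(fileext = ".vcf")
  emit_phased_vcf(sim, d6, path)
  back <- read_phased_vcf(path)
  for (i in seq_len(nrow(sim$haplotypes))) {
    h <- sim$haplotypes[i, ]
    want <- if (h$variants == ".") character() else
      sort(strsplit(h$variants, ";")[[1]])
    got <- back$key[back$sample_id == h$sample_id &
                      back$hap_index == h$hap_index]
    expect_identical(sort(got[!is.na(got)]), want)
  }
})

test_that("an empty cohort emits a header-only VCF", {
  sim <- list(haplotypes = data.frame(sample_id = character(),
                                      hap_index = integer(),
                                      allele = character(),
                                      suballele = character(),
                                      variants = character()),
              structural = list())
  path <- withr::local_tempfile(fileext = ".vcf")
  emit_phased_vcf(sim, d6, path)
  lines <- readLines(path)
  expect_true(all(grepl("^#", lines)))
  expect_identical(nrow(read_phased_vcf(path)), 0L)
})

test_that("deletion carriers emit missing genotypes plus a sidecar flag", {
  freqs <- c("*2" = 0.4, "*5" = 0.6)  # deletion-rich to guarantee carriers
  sim <- simulate_cohort(sim_config("CYP2D6", freqs, 20, seed = 31L))
  expect_gt(length(sim$structural), 0L)
  dir <- withr::local_tempdir()
  paths <- write_simulation(sim, dir, table = d6)
  carriers <- names(sim$structural)
  vcf <- readLines(paths[["vcf"]])
  stopifnot(any(!grepl("^#", vcf)))
  hdr <- strsplit(vcf[grep("^#CHROM", vcf)], "\t")[[1]]
  for (s in carriers[1:min(3, length(carriers))]) {
    col <- match(s, hdr)
    gts <- vapply(vcf[!grepl("^#", vcf)], function(ln)
      strsplit(ln, "\t")[[1]][col], character(1), USE.NAMES = FALSE)
    hap <- sim$structural[[s]]$carrier_hap
    expect_true(all(vapply(strsplit(gts, "|", fixed = TRUE),
                           function(g) g[hap] == ".", logical(1))))
  }
  flags <- read_structural_tsv(paths[["structural"]])
  expect_setequal(names(flags), carriers)
  expect_true(all(vapply(flags, function(st) st$kind == "deletion",
                         logical(1))))
})
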