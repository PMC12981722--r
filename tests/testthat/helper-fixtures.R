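# Shared fixtures: the packaged tables are loaded once per test run, and a
# tiny in-code definition TSV builder supports degenerate-input tests.

d6 <- builtin_table("CYP2D6")
c19 <- builtin_table("CYP2C19")

# write a definition TSV from row strings and load it
tiny_table <- function(rows, gene = "GX", default_allele = "*1") {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  writeLines(c("gene\tallele\tsuballele\tfunction\tactivity_score\tstructural\tvariants",
               rows), path)
  load_definition_table(path, gene, default_allele = default_allele)
}

# gene-reference / GRCh38 coordinate pairs of the ten catalogued novel
# (sub)allele variants, used to brute-force the reverse-strand sum constant
novel_coord_pairs <- data.frame(
  gene_pos = c(4674, 5102, 5243, 6706, 6810, 7032, 7265, 7373, 8428, 8446),
  grch38_pos = c(42131137, 42130709, 42130568, 42129105, 42129001, 42128779,
                 42128546, 42128438, 42127383, 42127365))

# independent exhaustive-search oracle for star-allele matching: scores every
# non-structural allele by matched-core size with the documented tie-breaks
oracle_match <- function(variants, table) {
  al <- table$alleles
  base <- al[is.na(al$suballele) & al$structural == "none", , drop = FALSE]
  best <- NULL
  for (nm in base$name) {
    core <- table$core[[nm]]$key
    if (!all(core %in% variants)) next
    rest <- setdiff(variants, core)
    # best suballele by brute force
    subs <- al$suballele[!is.na(al$suballele) & al$name == nm]
    explained <- 0L
    for (s in subs) {
      ex <- table$sub[[paste(nm, s, sep = "\r")]]$key
      if (all(ex %in% rest)) explained <- max(explained, length(ex))
    }
    cand <- list(allele = nm, core_n = length(core),
                 unex = length(rest) - explained,
                 num = suppressWarnings(as.numeric(sub("^\\*", "", nm))))
    if (is.null(best) ||
        cand$core_n > best$core_n ||
        (cand$core_n == best$core_n && cand$unex < best$unex) ||
        (cand$core_n == best$core_n && cand$unex == best$unex &&
         cand$num < best$num)) best <- cand
  }
  if (is.null(best)) table$default_allele else best$allele
}

# hand-written Pearson chi-square oracle on a 2x2 table of counts
chisq_oracle <- function(tab) {
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - E)^2 / E)
}
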