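# Cohort-level summaries: allele and phenotype count/frequency tables,
# chi-square comparison against reference population frequencies with the
# conventional significance stars, and table rendering.

#' Summarise a cohort of diplotypes and phenotypes
#'
#' Counts alleles over the 2n observed haplotypes (a deletion allele is one
#' haplotype; a duplicated allele label such as `"*1x2"` is its own allele and
#' also one haplotype, so copy number never changes the denominator) and
#' phenotype classes over the n individuals. Frequencies are kept at full
#' precision; rounding happens only at rendering.
#'
#' @param diplotypes list of `pgx_diplotype` objects (one per individual).
#' @param phenotypes list of `pgx_phenotype` objects for the same samples
#'   (may be `NULL` to summarise alleles only).
#' @param gene gene symbol recorded in the summary.
#' @return a `pgx_cohort`: list with `gene`, `n_individuals`, `n_haplotypes`,
#'   `allele_counts`, `allele_freqs`, `phenotype_counts`, `phenotype_freqs`.
#' @export
summarise_cohort <- function(diplotypes, phenotypes = NULL, gene = NULL) {
  n <- length(diplotypes)
  labels <- unlist(lapply(diplotypes, diplotype_labels))
  n_hap <- count_haplotypes(diplotypes)
  counts <- if (n > 0L) table(labels) else table(character())
  # simple alleles in ascending star order, CNV duplication alleles last
  ord <- order(vapply(names(counts), label_multiplicity, integer(1)) > 1L,
               vapply(names(counts), star_number, numeric(1)))
  allele_counts <- as.integer(counts)[ord]
  names(allele_counts) <- names(counts)[ord]

  ph_counts <- ph_freqs <- NULL
  if (!is.null(phenotypes)) {
    if (length(phenotypes) != n)
      stop("phenotype list does not match the diplotype list (",
           length(phenotypes), " vs ", n, " samples)")
    sid_d <- vapply(diplotypes, function(d)
      if (is.na(d$sample_id)) "" else d$sample_id, character(1))
    sid_p <- vapply(phenotypes, function(p)
      if (is.na(p$sample_id)) "" else p$sample_id, character(1))
    if (!setequal(sid_d, sid_p)) stop("mismatched sample sets")
    cls <- vapply(phenotypes, `[[`, character(1), "phenotype")
    ph_counts <- vapply(PHENOTYPE_CLASSES, function(p) sum(cls == p),
                        integer(1))
    ph_freqs <- if (n > 0L) ph_counts / n else ph_counts * NA_real_
  }
  structure(list(gene = if (is.null(gene)) NA_character_ else gene,
                 n_individuals = n, n_haplotypes = n_hap,
                 allele_counts = allele_counts,
                 allele_freqs = if (n_hap > 0L) allele_counts / n_hap
                                else allele_counts * NA_real_,
                 phenotype_counts = ph_counts,
                 phenotype_freqs = ph_freqs),
            class = "pgx_cohort")
}

#' @export
print.pgx_cohort <- function(x, ...) {
  cat("Cohort summary", if (!is.na(x$gene)) paste0(" for ", x$gene), ": ",
      x$n_individuals, " individuals, ", x$n_haplotypes, " haplotypes\n",
      sep = "")
  writeLines(render_allele_table(x))
  if (!is.null(x$phenotype_counts)) {
    cat("\n")
    writeLines(render_phenotype_table(x))
  }
  invisible(x)
}

round3 <- function(x) formatC(round(x, 3), format = "f", digits = 3)

#' Render cohort tables as text
#'
#' `render_allele_table()` mirrors the published star-allele frequency table
#' layout: one row per observed allele with haplotype count and frequency to
#' 3 decimal places, plus reference-population frequency and significance
#' stars when comparisons are supplied. `render_phenotype_table()` renders
#' phenotype classes, printing empty classes as count 0 and frequency 0.
#'
#' @param summary a `pgx_cohort`.
#' @param comparisons optional named list (by population) of lists of
#'   `pgx_freqcomp` objects, as produced via [compare_to_reference()].
#' @return character vector of TSV-ish table lines.
#' @export
render_allele_table <- function(summary, comparisons = NULL) {
  header <- c("allele", "haplotypes", "freq")
  pops <- names(comparisons)
  header <- c(header, vapply(pops, function(p) paste0("freq_", p), character(1)))
  lines <- paste(header, collapse = "\t")
  for (al in names(summary$allele_counts)) {
    row <- c(al, summary$allele_counts[[al]],
             round3(summary$allele_freqs[[al]]))
    for (p in pops) {
      cmp <- Filter(function(cc) cc$allele == al, comparisons[[p]])
      row <- c(row, if (length(cmp) == 0L || is.na(cmp[[1]]$ref_freq)) "n.d."
                    else paste0(round3(cmp[[1]]$ref_freq), cmp[[1]]$stars))
    }
    lines <- c(lines, paste(row, collapse = "\t"))
  }
  lines
}

#' @rdname render_allele_table
#' @export
render_phenotype_table <- function(summary) {
  if (is.null(summary$phenotype_counts))
    stop("summary has no phenotype counts")
  classes <- PHENOTYPE_CLASSES
  if (identical(summary$gene, "CYP2D6"))
    classes <- setdiff(classes, "rapid")  # rapid class is not defined for CYP2D6
  pretty <- c(ultra_rapid = "Ultra-rapid", rapid = "Rapid", normal = "Normal",
              intermediate = "Intermediate", poor = "Poor",
              uncertain = "Uncertain/unknown")
  lines <- "phenotype\tcount\tfreq"
  for (cl in classes) {
    cnt <- summary$phenotype_counts[[cl]]
    lines <- c(lines, paste(pretty[[cl]], cnt,
                            if (cnt == 0L) "0" else
                              round3(summary$phenotype_freqs[[cl]]),
                            sep = "\t"))
  }
  lines
}

#' Compare a study allele frequency with a reference population
#'
#' Builds the 2x2 haplotype-count contingency table — study carriers vs
#' non-carriers against reference carriers vs non-carriers, where the
#' reference carrier count is `round(ref_freq * 2 * ref_n_individuals)` — and
#' applies Pearson's chi-square test with 1 degree of freedom. Yates'
#' continuity correction is off by default (an option, not a default, since
#' published per-allele stars are conventionally uncorrected). Stars follow
#' the usual convention: `*` p < 0.05, `**` p < 0.01, `***` p < 0.001.
#'
#' @param allele allele label (annotation only).
#' @param study_count haplotypes carrying the allele in the study.
#' @param study_n total study haplotypes.
#' @param ref_freq reference allele frequency in `[0, 1]`, or `NA` when the
#'   reference reports no data (the comparison is then skipped).
#' @param ref_n_individuals number of individuals behind the reference
#'   frequency (haplotype count is twice this).
#' @param yates apply the continuity correction.
#' @return a `pgx_freqcomp`: list with `allele`, `study_count`, `study_n`,
#'   `study_freq`, `ref_freq`, `ref_n_individuals`, `chi2`, `p_value`,
#'   `stars`, `skipped`.
#' @export
compare_to_reference <- function(allele, study_count, study_n, ref_freq,
                                 ref_n_individuals, yates = FALSE) {
  if (study_count > study_n) stop("study_count exceeds study_n")
  if (study_count < 0 || study_n <= 0) stop("invalid study counts")
  out <- list(allele = allele, study_count = as.integer(study_count),
              study_n = as.integer(study_n),
              study_freq = study_count / study_n,
              ref_freq = ref_freq,
              ref_n_individuals = as.integer(ref_n_individuals),
              chi2 = NA_real_, p_value = NA_real_, stars = "",
              skipped = FALSE)
  if (is.na(ref_freq)) {
    out$skipped <- TRUE
    return(structure(out, class = "pgx_freqcomp"))
  }
  if (ref_freq < 0 || ref_freq > 1) stop("ref_freq must lie in [0, 1]")
  if (ref_n_individuals <= 0) stop("ref_n_individuals must be positive")
  ref_n <- 2L * as.integer(ref_n_individuals)
  ref_count <- round(ref_freq * ref_n)
  tab <- matrix(c(study_count, study_n - study_count,
                  ref_count, ref_n - ref_count),
                nrow = 2, byrow = TRUE)
  ht <- suppressWarnings(chisq.test(tab, correct = yates))
  out$chi2 <- unname(ht$statistic)
  out$p_value <- unname(ht$p.value)
  out$stars <- significance_stars(out$p_value)
  structure(out, class = "pgx_freqcomp")
}

significance_stars <- function(p) {
  if (is.na(p)) "" else if (p < 0.001) "***" else if (p < 0.01) "**"
  else if (p < 0.05) "*" else ""
}

#' @export
print.pgx_freqcomp <- function(x, ...) {
  if (x$skipped) {
    cat(x$allele, ": reference frequency not available (n.d.)\n", sep = "")
  } else {
    cat(x$allele, ": study ", x$study_count, "/", x$study_n, " (",
        round3(x$study_freq), ") vs reference ", round3(x$ref_freq),
        "; chi2 = ", signif(x$chi2, 4), ", p = ", signif(x$p_value, 3),
        if (nzchar(x$stars)) paste0(" ", x$stars), "\n", sep = "")
  }
  invisible(x)
}

#' Packaged reference population frequencies
#'
#' Aggregate star-allele frequencies per biogeographic group (with the number
#' of individuals behind each estimate) used as the comparison baseline.
#' Frequencies a source reports as "n.d." are returned as `NA`.
#'
#' @param gene `"CYP2D6"` or `"CYP2C19"`.
#' @param population `"oceanian"` or `"european"`.
#' @return data.frame with columns `allele`, `freq`, `n_individuals`.
#' @export
reference_fixture <- function(gene, population) {
  path <- system.file("extdata", "reference_freqs.tsv", package = "pgxstar",
                      mustWork = TRUE)
  raw <- read.delim(path, colClasses = "character", na.strings = NULL)
  raw <- raw[raw$gene == gene & raw$population == population, , drop = FALSE]
  if (nrow(raw) == 0L)
    stop("no packaged reference frequencies for ", gene, " / ", population)
  data.frame(allele = raw$allele,
             freq = suppressWarnings(as.numeric(ifelse(raw$freq == ".",
                                                       NA, raw$freq))),
             n_individuals = as.integer(raw$n_individuals),
             stringsAsFactors = FALSE)
}

#' Packaged study counts
#'
#' The observed haplotype counts per star allele and phenotype-class counts
#' from the sequenced cohort (135 CYP2D6 / 73 CYP2C19 individuals), packaged
#' for reconstruction and comparison.
#'
#' @param gene `"CYP2D6"` or `"CYP2C19"`.
#' @return `study_allele_counts()`: named integer vector of haplotype counts;
#'   `study_phenotype_counts()`: named integer vector by phenotype class.
#' @export
study_allele_counts <- function(gene) {
  path <- system.file("extdata", "study_counts.tsv", package = "pgxstar",
                      mustWork = TRUE)
  raw <- read.delim(path, colClasses = "character")
  raw <- raw[raw$gene == gene, , drop = FALSE]
  if (nrow(raw) == 0L) stop("no packaged study counts for ", gene)
  structure(as.integer(raw$haplotypes), names = raw$allele)
}

#' @rdname study_allele_counts
#' @export
study_phenotype_counts <- function(gene) {
  path <- system.file("extdata", "study_phenotype_counts.tsv",
                      package = "pgxstar", mustWork = TRUE)
  raw <- read.delim(path, colClasses = "character")
  raw <- raw[raw$gene == gene, , drop = FALSE]
  if (nrow(raw) == 0L) stop("no packaged phenotype counts for ", gene)
  structure(as.integer(raw$count), names = raw$phenotype)
}
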