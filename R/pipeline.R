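# End-to-end orchestration: depth QC -> per-haplotype star calls ->
# diplotypes -> phenotypes -> cohort summary -> reference comparisons ->
# novel-candidate table, with optional what-if function reassignment and
# machine-readable outputs.

#' Run the full per-gene pipeline
#'
#' Consumes phased per-haplotype variant calls (in memory, or as a phased VCF
#' / haplotype TSV path), per-sample structural evidence and per-sample mean
#' depths; emits every intermediate and final artefact of the analysis for
#' one gene.
#'
#' @param gene gene symbol.
#' @param variants long data.frame (`sample_id`, `hap_index`, `key`; `NA` key
#'   for a variant-free haplotype) or a path to a `.vcf` or haplotype `.tsv`.
#' @param structural named list of [structural_status()] by sample (or a path
#'   to a structural TSV); samples not listed have no structural event.
#' @param depths named numeric vector of mean depths by sample (or a path to
#'   a depth TSV). `NULL` skips depth QC (all samples pass).
#' @param table definition-table source; defaults to the packaged table.
#' @param qc_threshold strict depth cutoff in reads.
#' @param populations reference populations to compare against.
#' @param scenario optional named list `allele -> list(function, activity)`
#'   applied via [reassign_function()]; the report then carries both baseline
#'   and scenario phenotype summaries.
#' @param out_dir optional directory for TSV/JSON reports.
#' @return a `pgx_report` list: `gene`, `qc` (passed/failed), `calls`,
#'   `diplotypes`, `phenotypes`, `summary`, `comparisons`, `novel`,
#'   `scenario` (or `NULL`), `manifest`.
#' @export
run_pipeline <- function(gene, variants, structural = list(), depths = NULL,
                         table = builtin_table(gene), qc_threshold = 100,
                         populations = c("oceanian", "european"),
                         scenario = NULL, out_dir = NULL) {
  stopifnot(inherits(table, "pgx_deftab"), qc_threshold > 0)
  if (is.character(variants) && length(variants) == 1L) {
    variants <- if (grepl("\\.vcf$", variants)) read_phased_vcf(variants)
                else read_haplotype_tsv(variants)
  }
  if (is.character(structural)) structural <- read_structural_tsv(structural)
  if (is.character(depths)) depths <- read_depth_tsv(depths)

  samples <- unique(variants$sample_id)
  if (is.null(depths)) {
    qc <- list(passed = samples, failed = character())
  } else {
    qc <- qc_filter(depths[samples], qc_threshold)
  }
  keep <- qc$passed

  calls <- list(); diplotypes <- list()
  by_sample <- split(variants, variants$sample_id)
  for (s in keep) {
    st <- structural[[s]]
    if (is.null(st)) st <- structural_status("none")
    sv <- by_sample[[s]]
    two <- lapply(1:2, function(h) {
      keys <- sv$key[sv$hap_index == h]
      match_haplotype(keys[!is.na(keys)], table, sample_id = s, hap_index = h)
    })
    calls[[length(calls) + 1L]] <- two[[1]]
    calls[[length(calls) + 1L]] <- two[[2]]
    diplotypes[[s]] <- call_diplotype(two[[1]], two[[2]], st)
  }
  diplotypes <- unname(diplotypes)
  phenotypes <- lapply(diplotypes, phenotype_call, table = table)
  summary <- summarise_cohort(diplotypes, phenotypes, gene = gene)
  comparisons <- compare_summary(summary, gene, populations)
  novel <- collect_novel_candidates(calls)

  scen <- NULL
  if (!is.null(scenario)) {
    stab <- table
    for (al in names(scenario))
      stab <- reassign_function(stab, al, scenario[[al]]$`function`,
                                if (is.null(scenario[[al]]$activity))
                                  NA_real_ else scenario[[al]]$activity)
    sphen <- lapply(diplotypes, phenotype_call, table = stab)
    scen <- list(table = stab,
                 phenotypes = sphen,
                 summary = summarise_cohort(diplotypes, sphen, gene = gene))
  }

  report <- structure(
    list(gene = gene, qc = qc, calls = calls, diplotypes = diplotypes,
         phenotypes = phenotypes, summary = summary,
         comparisons = comparisons, novel = novel, scenario = scen,
         manifest = list(gene = gene, qc_threshold = qc_threshold,
                         populations = populations,
                         n_input_samples = length(samples),
                         n_passed = length(keep),
                         scenario = scenario,
                         package_version =
                           as.character(utils::packageVersion("pgxstar")))),
    class = "pgx_report")
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

compare_summary <- function(summary, gene, populations) {
  out <- list()
  for (pop in populations) {
    ref <- reference_fixture(gene, pop)
    out[[pop]] <- lapply(names(summary$allele_counts), function(al) {
      i <- match(al, ref$allele)
      compare_to_reference(al, summary$allele_counts[[al]],
                           summary$n_haplotypes,
                           if (is.na(i)) NA_real_ else ref$freq[i],
                           if (is.na(i)) 0L else ref$n_individuals[i])
    })
  }
  out
}

#' Run the pipeline for several genes and report the sample overlap
#'
#' @param configs named list (by gene) of argument lists for [run_pipeline()].
#' @return list with per-gene `reports`, per-gene passed-sample counts and
#'   `overlap`, the number of samples passing QC in every gene.
#' @export
run_multi_pipeline <- function(configs) {
  reports <- lapply(names(configs), function(g)
    do.call(run_pipeline, c(list(gene = g), configs[[g]])))
  names(reports) <- names(configs)
  passed <- lapply(reports, function(r) r$qc$passed)
  list(reports = reports,
       n_passed = vapply(passed, length, integer(1)),
       overlap = length(Reduce(intersect, passed)))
}

#' @export
print.pgx_report <- function(x, ...) {
  cat("pgxstar pipeline report for ", x$gene, "\n", sep = "")
  cat("  QC: ", length(x$qc$passed), " passed, ", length(x$qc$failed),
      " failed (threshold strict)\n", sep = "")
  print(x$summary)
  if (nrow(x$novel) > 0L) {
    cat("\nNovel-suballele candidates:\n")
    print(x$novel)
  }
  if (!is.null(x$scenario)) {
    cat("\nScenario phenotype summary:\n")
    writeLines(render_phenotype_table(x$scenario$summary))
  }
  invisible(x)
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  pre <- file.path(out_dir, report$gene)
  # per-haplotype calls
  call_df <- do.call(rbind, lapply(report$calls, function(cl)
    data.frame(sample = cl$sample_id, hap = cl$hap_index, allele = cl$allele,
               suballele = ifelse(is.na(cl$suballele), ".", cl$suballele),
               novel = cl$is_novel_suballele,
               unexplained = if (length(cl$unexplained) == 0L) "." else
                 paste(cl$unexplained, collapse = ";"),
               stringsAsFactors = FALSE)))
  write.table(call_df, paste0(pre, ".calls.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  phen_df <- do.call(rbind, lapply(report$phenotypes, function(p)
    data.frame(sample = p$sample_id, gene = p$gene, diplotype = p$diplotype,
               activity_score = p$activity_score, phenotype = p$phenotype,
               stringsAsFactors = FALSE)))
  write.table(phen_df, paste0(pre, ".phenotypes.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  writeLines(render_allele_table(report$summary, report$comparisons),
             paste0(pre, ".allele_table.tsv"))
  writeLines(render_phenotype_table(report$summary),
             paste0(pre, ".phenotype_table.tsv"))
  write.table(report$novel, paste0(pre, ".novel_candidates.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  comp <- lapply(report$comparisons, function(cmps)
    lapply(cmps, function(cc) unclass(cc)))
  jsonlite::write_json(list(manifest = report$manifest, comparisons = comp),
                       paste0(pre, ".report.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(out_dir)
}
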