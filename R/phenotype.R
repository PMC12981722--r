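# Diplotype-to-phenotype translation: additive CYP2D6 activity scores with
# standardised bins, categorical CYP2C19 rules, uncertainty propagation, and
# what-if reassignment of an allele's function class.

#' CYP2D6 diplotype activity score
#'
#' Sum of the two alleles' activity values; a duplicated allele `xN`
#' contributes N times its base value, the deletion allele contributes 0. The
#' score is undefined (`NA`) as soon as either allele's function class is
#' uncertain or unknown — uncertainty propagates, it is never averaged away.
#'
#' @param d a `pgx_diplotype`, or a display string like `"*4/*5"`.
#' @param table a `pgx_deftab`.
#' @return numeric activity score, or `NA` when undefined.
#' @export
diplotype_activity_score <- function(d, table) {
  labels <- diplotype_labels(d)
  funs <- vapply(labels, function(l) allele_function(table, l), character(1))
  if (any(funs %in% c("uncertain", "unknown"))) return(NA_real_)
  vals <- vapply(labels, function(l) allele_activity(table, l), numeric(1))
  if (anyNA(vals))
    stop("allele(s) without an activity value in an activity-scored gene: ",
         paste(labels[is.na(vals)], collapse = ", "))
  sum(vals)
}

diplotype_labels <- function(d) {
  if (inherits(d, "pgx_diplotype")) return(c(d$allele_a, d$allele_b))
  if (is.character(d) && length(d) == 1L) {
    parts <- strsplit(d, "/", fixed = TRUE)[[1]]
    if (length(parts) != 2L) stop("diplotype string must be 'A/B': ", d)
    return(parts)
  }
  stop("expected a pgx_diplotype or an 'A/B' string")
}

#' CYP2D6 metaboliser phenotype from an activity score
#'
#' Standardised activity-score bins: 0 is a poor metaboliser; above 0 and
#' below 1.25 intermediate; 1.25 to 2.25 inclusive normal; above 2.25
#' ultra-rapid. An undefined score (`NA`) maps to the uncertain class.
#'
#' @param score numeric activity score (>= 0) or `NA`.
#' @return one of `"poor"`, `"intermediate"`, `"normal"`, `"ultra_rapid"`,
#'   `"uncertain"`.
#' @export
cyp2d6_phenotype <- function(score) {
  if (length(score) != 1L) stop("one score at a time")
  if (is.na(score)) return("uncertain")
  if (score < 0) stop("activity score cannot be negative")
  if (score == 0) "poor"
  else if (score < 1.25) "intermediate"
  else if (score <= 2.25) "normal"
  else "ultra_rapid"
}

#' CYP2C19 metaboliser phenotype from a diplotype
#'
#' CYP2C19 uses no activity score; phenotype is a rule table on the unordered
#' pair of allele function classes: two no-function alleles are poor; one
#' no-function allele with a normal or increased partner is intermediate; two
#' normal alleles normal; normal with increased is rapid; two increased
#' alleles ultra-rapid. Any uncertain/unknown-function allele yields the
#' uncertain class; other combinations are an error.
#'
#' @param d a `pgx_diplotype` or `"A/B"` string.
#' @param table a `pgx_deftab` for CYP2C19.
#' @return a phenotype class string.
#' @export
cyp2c19_phenotype <- function(d, table) {
  labels <- diplotype_labels(d)
  funs <- sort(vapply(labels, function(l) allele_function(table, l),
                      character(1)))
  if (any(funs %in% c("uncertain", "unknown"))) return("uncertain")
  pair <- paste(funs, collapse = "+")
  rules <- c("no_function+no_function" = "poor",
             "no_function+normal"      = "intermediate",
             "increased+no_function"   = "intermediate",
             "normal+normal"           = "normal",
             "increased+normal"        = "rapid",
             "increased+increased"     = "ultra_rapid")
  if (!pair %in% names(rules))
    stop("no phenotype rule for function pair (", pair, ")")
  unname(rules[[pair]])
}

#' Phenotype call for one sample
#'
#' Dispatches on gene: CYP2D6 goes through the additive activity score and
#' its bins, CYP2C19 through the categorical rule table (and never carries a
#' score).
#'
#' @param d a `pgx_diplotype` or `"A/B"` string.
#' @param table a `pgx_deftab`.
#' @return a `pgx_phenotype`: list with `sample_id`, `gene`, `diplotype`,
#'   `activity_score` (`NA` unless the gene is activity-scored and the score
#'   is defined) and `phenotype`.
#' @export
phenotype_call <- function(d, table) {
  sid <- if (inherits(d, "pgx_diplotype")) d$sample_id else NA_character_
  disp <- paste(diplotype_labels(d), collapse = "/")
  if (identical(table$gene, "CYP2C19")) {
    ph <- cyp2c19_phenotype(d, table); score <- NA_real_
  } else {
    score <- diplotype_activity_score(d, table)
    ph <- cyp2d6_phenotype(score)
  }
  structure(list(sample_id = sid, gene = table$gene, diplotype = disp,
                 activity_score = score, phenotype = ph),
            class = "pgx_phenotype")
}

#' @export
print.pgx_phenotype <- function(x, ...) {
  cat(x$gene, " ", x$diplotype, " -> ",
      if (!is.na(x$activity_score)) paste0("activity ", x$activity_score, ", "),
      x$phenotype, "\n", sep = "")
  invisible(x)
}

#' Reassign an allele's function class (scenario analysis)
#'
#' Returns a modified copy of the definition table in which one allele's
#' function class (and activity value) is replaced; the original table is
#' untouched. Running the phenotype translation under the modified table
#' implements what-if analyses such as treating an uncertain-function allele
#' as nonfunctional.
#'
#' @param table a `pgx_deftab`.
#' @param allele star-allele name to modify.
#' @param new_function a function class.
#' @param new_activity activity value consistent with the class (`NA` required
#'   for uncertain/unknown).
#' @return a new `pgx_deftab`.
#' @export
reassign_function <- function(table, allele, new_function,
                              new_activity = NA_real_) {
  stopifnot(inherits(table, "pgx_deftab"))
  if (!new_function %in% FUNCTION_CLASSES)
    stop("unknown function class '", new_function, "'")
  if (new_function %in% c("uncertain", "unknown") && !is.na(new_activity))
    stop("uncertain/unknown function cannot carry an activity value")
  if (!is.na(new_activity) && new_activity < 0)
    stop("activity value cannot be negative")
  idx <- which(table$alleles$name == allele)
  if (length(idx) == 0L)
    stop("allele ", allele, " not found in ", table$gene, " definition table")
  table$alleles$function_class[idx] <- new_function
  table$alleles$activity[idx] <- new_activity
  validate_definition_table(table)
  table
}
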