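# Diplotype construction: combine two haplotype calls with per-sample
# structural evidence (whole-gene deletion, duplication) into a canonical
# "A/B" diplotype string.

#' Structural status of a sample
#'
#' Evidence for a whole-gene structural allele, as detected by a diagnostic
#' CNV amplicon rather than small variants: either nothing, a deletion of one
#' gene copy, or a duplication with a copy count.
#'
#' @param kind `"none"`, `"deletion"` or `"duplication"`.
#' @param multiplicity total copies on the carrier haplotype (>= 2), required
#'   for duplications and forbidden otherwise.
#' @param carrier_hap which haplotype (1 or 2) carries the event; required
#'   unless `kind = "none"`.
#' @return a `pgx_structural` list.
#' @export
structural_status <- function(kind = "none", multiplicity = NA_integer_,
                              carrier_hap = NA_integer_) {
  if (!kind %in% STRUCTURAL_KINDS)
    stop("structural kind must be one of: ", paste(STRUCTURAL_KINDS, collapse = ", "))
  if (kind == "duplication") {
    if (is.na(multiplicity) || multiplicity < 2L)
      stop("duplication requires multiplicity >= 2")
  } else if (!is.na(multiplicity)) {
    stop("multiplicity only applies to duplications")
  }
  if (kind != "none") {
    if (is.na(carrier_hap) || !carrier_hap %in% c(1L, 2L))
      stop("structural event must be assigned to haplotype 1 or 2")
  }
  structure(list(kind = kind, multiplicity = as.integer(multiplicity),
                 carrier_hap = as.integer(carrier_hap)),
            class = "pgx_structural")
}

# ascending star number; at equal number the higher copy count first ("*1x2/*1")
order_labels <- function(a, b) {
  na <- star_number(a); nb <- star_number(b)
  if (na < nb) return(c(a, b))
  if (nb < na) return(c(b, a))
  if (label_multiplicity(a) >= label_multiplicity(b)) c(a, b) else c(b, a)
}

#' Call a diplotype from two haplotype calls and structural evidence
#'
#' A deletion replaces the carrier haplotype's star call with the deletion
#' allele (the gene is absent from that chromosome, so a call derived from
#' variants would be meaningless — and a deletion carrier haplotype showing
#' variants is rejected as inconsistent). A duplication suffixes the carrier
#' haplotype's label with `xN`. Labels are ordered canonically (ascending
#' star number; at equal number the duplicated label first), so the display
#' string is invariant under swapping the two input calls.
#'
#' @param call_a,call_b `pgx_starcall` objects for haplotypes 1 and 2.
#' @param structural a `pgx_structural` (default: none).
#' @param deletion_allele label used for a deleted gene copy.
#' @return a `pgx_diplotype`: list with `sample_id`, `allele_a`, `allele_b`,
#'   `display`, `suballeles`, `structural`.
#' @export
call_diplotype <- function(call_a, call_b,
                           structural = structural_status("none"),
                           deletion_allele = "*5") {
  stopifnot(inherits(call_a, "pgx_starcall"), inherits(call_b, "pgx_starcall"),
            inherits(structural, "pgx_structural"))
  if (!identical(call_a$gene, call_b$gene))
    stop("haplotype calls are from different genes")
  sid <- call_a$sample_id
  if (!is.na(sid) && !is.na(call_b$sample_id) && !identical(sid, call_b$sample_id))
    stop("haplotype calls are from different samples")
  labels <- c(call_a$allele, call_b$allele)
  if (structural$kind == "deletion") {
    carrier <- list(call_a, call_b)[[structural$carrier_hap]]
    if (length(carrier$hap_variants) > 0L)
      stop("sample ", sid, ": deletion haplotype carries variants (",
           paste(carrier$hap_variants, collapse = ", "),
           "); a deleted gene cannot show variants")
    labels[structural$carrier_hap] <- deletion_allele
  } else if (structural$kind == "duplication") {
    labels[structural$carrier_hap] <-
      paste0(labels[structural$carrier_hap], "x", structural$multiplicity)
  }
  ordered <- order_labels(labels[1], labels[2])
  structure(list(sample_id = sid, allele_a = ordered[1], allele_b = ordered[2],
                 display = paste(ordered, collapse = "/"),
                 suballeles = c(call_a$suballele, call_b$suballele),
                 structural = structural),
            class = "pgx_diplotype")
}

#' Build a diplotype directly from two allele labels
#'
#' Convenience constructor for worked examples and cohort reconstruction when
#' per-haplotype variant data are not in play; labels may carry an `xN`
#' duplication suffix or be the deletion allele.
#'
#' @param label_a,label_b star-allele labels.
#' @param sample_id optional sample identifier.
#' @return a `pgx_diplotype`.
#' @export
diplotype_from_labels <- function(label_a, label_b, sample_id = NA_character_) {
  ordered <- order_labels(label_a, label_b)
  structure(list(sample_id = sample_id, allele_a = ordered[1],
                 allele_b = ordered[2],
                 display = paste(ordered, collapse = "/"),
                 suballeles = c(NA_character_, NA_character_),
                 structural = NULL),
            class = "pgx_diplotype")
}

#' @export
print.pgx_diplotype <- function(x, ...) {
  cat(if (!is.na(x$sample_id)) paste0(x$sample_id, ": "), x$display, "\n",
      sep = "")
  invisible(x)
}

#' Number of haplotypes a diplotype collection represents
#'
#' Exactly two haplotypes per individual: a deletion allele counts as one
#' observed haplotype, and a duplicated allele (`xN`) also counts as one —
#' copy number never inflates or deflates the frequency denominator.
#'
#' @param diplotypes list of `pgx_diplotype` objects.
#' @return integer, `2 * length(diplotypes)`.
#' @export
count_haplotypes <- function(diplotypes) {
  stopifnot(all(vapply(diplotypes, inherits, logical(1), "pgx_diplotype")))
  2L * length(diplotypes)
}

#' Read a structural-evidence TSV
#'
#' Columns `sample`, `kind`, `multiplicity`, `carrier_hap` (`.` for empty).
#' Samples without a structural event may be listed with kind `none` or
#' omitted entirely.
#'
#' @param path file path.
#' @return named list of `pgx_structural`, keyed by sample.
#' @export
read_structural_tsv <- function(path) {
  raw <- read.delim(path, header = TRUE, colClasses = "character",
                    na.strings = NULL)
  if (!all(c("sample", "kind", "multiplicity", "carrier_hap") %in% names(raw)))
    stop("structural TSV needs columns sample, kind, multiplicity, carrier_hap")
  out <- list()
  num <- function(x) if (x %in% c(".", "")) NA_integer_ else as.integer(x)
  for (i in seq_len(nrow(raw))) {
    if (raw$sample[i] %in% names(out))
      stop("duplicate structural row for sample ", raw$sample[i])
    out[[raw$sample[i]]] <- structural_status(raw$kind[i],
                                              num(raw$multiplicity[i]),
                                              num(raw$carrier_hap[i]))
  }
  out
}

write_structural_tsv <- function(structural, path) {
  dot <- function(v) ifelse(is.na(v), ".", as.character(v))
  lines <- vapply(names(structural), function(s) {
    st <- structural[[s]]
    paste(s, st$kind, dot(st$multiplicity), dot(st$carrier_hap), sep = "\t")
  }, character(1))
  writeLines(c("sample\tkind\tmultiplicity\tcarrier_hap", lines), path)
  invisible(path)
}
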