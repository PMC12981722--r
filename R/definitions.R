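# Star-allele definition tables: data model, TSV reader/writer, validators,
# packaged fixtures, and the dual gene-reference / GRCh38 coordinate check.

#' Parse variant tokens
#'
#' A variant token is `gene_pos:ref>alt[:rsid[:aa[:grch38_pos]]]` with `.` for
#' an empty optional field; several tokens are joined with `;`. Coordinates are
#' 1-based on the gene reference sequence. The canonical identity of a variant
#' is `gene_pos:ref>alt`; rsid, amino-acid change and the GRCh38 coordinate are
#' annotations and never used for matching.
#'
#' @param x a single string of `;`-separated tokens, or `"."`/`""` for none.
#' @return data.frame with columns `key`, `gene_pos`, `ref`, `alt`, `rsid`,
#'   `aa_change`, `grch38_pos` (one row per variant).
#' @export
parse_variant_tokens <- function(x) {
  empty <- data.frame(key = character(), gene_pos = integer(),
                      ref = character(), alt = character(),
                      rsid = character(), aa_change = character(),
                      grch38_pos = integer(), stringsAsFactors = FALSE)
  if (length(x) != 1L || is.na(x)) stop("expected a single token string")
  x <- trimws(x)
  if (x == "" || x == ".") return(empty)
  tokens <- strsplit(x, ";", fixed = TRUE)[[1]]
  rows <- lapply(tokens, function(tok) {
    parts <- strsplit(tok, ":", fixed = TRUE)[[1]]
    if (length(parts) < 2L) stop("malformed variant token: ", tok)
    gene_pos <- suppressWarnings(as.integer(parts[1]))
    if (is.na(gene_pos) || gene_pos < 1L)
      stop("variant token needs a positive 1-based gene position: ", tok)
    change <- strsplit(parts[2], ">", fixed = TRUE)[[1]]
    if (length(change) != 2L) stop("malformed ref>alt in token: ", tok)
    ref <- toupper(change[1]); alt <- toupper(change[2])
    if (ref == alt) stop("ref and alt bases identical in token: ", tok)
    if (!grepl("^[ACGT]+$", ref) || !grepl("^[ACGT]+$", alt))
      stop("bases must be drawn from A,C,G,T in token: ", tok)
    opt <- function(i) {
      if (length(parts) >= i && parts[i] != "." && parts[i] != "") parts[i] else NA_character_
    }
    g38 <- opt(5)
    g38 <- if (is.na(g38)) NA_integer_ else as.integer(g38)
    data.frame(key = paste0(gene_pos, ":", ref, ">", alt),
               gene_pos = gene_pos, ref = ref, alt = alt,
               rsid = opt(3), aa_change = opt(4), grch38_pos = g38,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (anyDuplicated(out$key)) stop("duplicate variant in token list: ", x)
  out
}

format_variant_tokens <- function(df) {
  if (nrow(df) == 0L) return(".")
  dot <- function(v) ifelse(is.na(v), ".", as.character(v))
  paste(paste(df$gene_pos, paste0(df$ref, ">", df$alt),
              dot(df$rsid), dot(df$aa_change), dot(df$grch38_pos), sep = ":"),
        collapse = ";")
}

sub_id <- function(name, suballele) paste(name, suballele, sep = "\r")

#' Load a star-allele definition table from TSV
#'
#' Reads the documented TSV dialect: header columns `gene`, `allele`,
#' `suballele`, `function`, `activity_score`, `structural`, `variants`. Rows
#' with an empty `suballele` define a star allele and its core variant set;
#' rows naming a suballele list only the additional variants that distinguish
#' the suballele from its parent star allele. `.` denotes an empty field.
#'
#' @param path path to the TSV file.
#' @param gene gene symbol the table must describe (rows for other genes are
#'   rejected).
#' @param reference_id accession of the gene reference sequence the positions
#'   refer to (annotation only).
#' @param default_allele name assigned to a variant-free haplotype.
#' @return a validated `pgx_deftab` object.
#' @export
load_definition_table <- function(path, gene, reference_id = NA_character_,
                                  default_allele = "*1") {
  if (!file.exists(path)) stop("definition table not found: ", path)
  raw <- tryCatch(
    read.delim(path, header = TRUE, colClasses = "character",
               na.strings = NULL, check.names = FALSE),
    error = function(e) stop("cannot parse definition TSV ", path, ": ",
                             conditionMessage(e)))
  need <- c("gene", "allele", "suballele", "function", "activity_score",
            "structural", "variants")
  if (!all(need %in% names(raw)))
    stop("definition TSV must have columns: ", paste(need, collapse = ", "))
  if (nrow(raw) == 0L) stop("definition TSV has no allele rows: ", path)

  alleles <- list(); core <- list(); sub <- list()
  for (i in seq_len(nrow(raw))) {
    row <- raw[i, ]
    line <- i + 1L  # header is line 1
    if (row$gene != gene)
      stop("line ", line, ": gene ", row$gene, " does not match ", gene)
    fun <- row[["function"]]
    if (!fun %in% FUNCTION_CLASSES)
      stop("line ", line, ": unknown function class '", fun, "'")
    structural <- row$structural
    if (!structural %in% STRUCTURAL_KINDS)
      stop("line ", line, ": unknown structural kind '", structural, "'")
    activity <- if (row$activity_score %in% c(".", "")) NA_real_ else {
      a <- suppressWarnings(as.numeric(row$activity_score))
      if (is.na(a) || a < 0) stop("line ", line, ": bad activity score")
      a
    }
    if (!is.na(activity) && fun %in% c("uncertain", "unknown"))
      stop("line ", line, ": ", row$allele,
           " has uncertain/unknown function but a numeric activity score")
    variants <- tryCatch(parse_variant_tokens(row$variants),
                         error = function(e) stop("line ", line, ": ",
                                                  conditionMessage(e)))
    suballele <- if (row$suballele %in% c(".", "")) NA_character_ else row$suballele
    if (structural == "deletion" && (nrow(variants) > 0L))
      stop("line ", line, ": a deletion allele cannot carry variants")
    id <- sub_id(row$allele, suballele)
    if (!is.null(alleles[[id]]))
      stop("line ", line, ": duplicate allele row (", row$allele,
           if (!is.na(suballele)) paste0(" / ", suballele) else "", ")")
    alleles[[id]] <- data.frame(name = row$allele, suballele = suballele,
                                function_class = fun, activity = activity,
                                structural = structural,
                                stringsAsFactors = FALSE)
    if (is.na(suballele)) core[[row$allele]] <- variants else sub[[id]] <- variants
  }
  tab <- structure(list(gene = gene, reference_id = reference_id,
                        default_allele = default_allele,
                        alleles = do.call(rbind, c(alleles,
                                                   make.row.names = FALSE)),
                        core = core, sub = sub),
                   class = "pgx_deftab")
  validate_definition_table(tab)
  tab
}

#' Validate a definition table
#'
#' Checks the structural invariants: unique (allele, suballele) rows, exactly
#' one default allele with an empty core set, every suballele row attached to a
#' known parent allele, suballele extras disjoint from the parent core, and
#' deletion alleles free of variants.
#'
#' @param table a `pgx_deftab`.
#' @return the table, invisibly; stops on violation.
#' @export
validate_definition_table <- function(table) {
  stopifnot(inherits(table, "pgx_deftab"))
  al <- table$alleles
  base <- al[is.na(al$suballele), , drop = FALSE]
  if (anyDuplicated(base$name)) stop("duplicate star-allele names")
  if (!table$default_allele %in% base$name)
    stop("default allele ", table$default_allele, " missing from table")
  if (nrow(table$core[[table$default_allele]]) != 0L)
    stop("default allele must have an empty core variant set")
  subs <- al[!is.na(al$suballele), , drop = FALSE]
  for (i in seq_len(nrow(subs))) {
    nm <- subs$name[i]; sb <- subs$suballele[i]
    if (!nm %in% base$name)
      stop("suballele ", sb, " has no parent allele row ", nm)
    extras <- table$sub[[sub_id(nm, sb)]]
    if (any(extras$key %in% table$core[[nm]]$key))
      stop("suballele ", sb, " repeats a core variant of ", nm)
  }
  for (nm in base$name[base$structural == "deletion"])
    if (nrow(table$core[[nm]]) > 0L)
      stop("deletion allele ", nm, " cannot carry variants")
  invisible(table)
}

#' Built-in definition tables
#'
#' Packaged fixture tables for CYP2D6 (star alleles *1, *2, *4, *5, *6, *9,
#' *10, *33, *35, *41, *59, *71, *108, *186 plus the suballeles *1.069-*1.071,
#' *2.038, *2.039, *4.036-*4.038, *41.010 and *186.001) and CYP2C19 (*1, *2,
#' *3, *17). Core variant sets are small discriminating subsets sufficient to
#' separate the catalogued alleles, not complete PharmVar definitions.
#'
#' @param gene `"CYP2D6"` or `"CYP2C19"`.
#' @return a `pgx_deftab`.
#' @export
builtin_table <- function(gene) {
  meta <- list(CYP2D6 = list(file = "cyp2d6_alleles.tsv", ref = "NG_008376.4"),
               CYP2C19 = list(file = "cyp2c19_alleles.tsv", ref = "NG_008384.3"))
  if (!gene %in% names(meta))
    stop("unsupported gene '", gene, "'; supported: ",
         paste(names(meta), collapse = ", "))
  path <- system.file("extdata", meta[[gene]]$file, package = "pgxstar",
                      mustWork = TRUE)
  load_definition_table(path, gene, reference_id = meta[[gene]]$ref)
}

#' Write a definition table to TSV
#'
#' Inverse of [load_definition_table()]: the written file reloads to an
#' identical table (round-trip on all fields).
#'
#' @param table a `pgx_deftab`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_definition_table <- function(table, path) {
  al <- table$alleles
  rows <- vapply(seq_len(nrow(al)), function(i) {
    vs <- if (is.na(al$suballele[i])) table$core[[al$name[i]]]
          else table$sub[[sub_id(al$name[i], al$suballele[i])]]
    paste(table$gene, al$name[i],
          ifelse(is.na(al$suballele[i]), ".", al$suballele[i]),
          al$function_class[i],
          ifelse(is.na(al$activity[i]), ".", format(al$activity[i])),
          al$structural[i], format_variant_tokens(vs), sep = "\t")
  }, character(1))
  writeLines(c(paste(c("gene", "allele", "suballele", "function",
                       "activity_score", "structural", "variants"),
                     collapse = "\t"), rows), path)
  invisible(path)
}

#' Check dual-coordinate consistency
#'
#' For a gene on the reverse strand of the genome, a 1-based position on the
#' gene reference and the corresponding 1-based GRCh38 position must sum to a
#' single gene-wide constant. Verifies this over every variant in the table
#' that carries both coordinates and returns the constant.
#'
#' @param table a `pgx_deftab`.
#' @return the integer constant `gene_pos + grch38_pos`.
#' @export
check_coordinate_consistency <- function(table) {
  v <- all_variants(table)
  v <- v[!is.na(v$grch38_pos), , drop = FALSE]
  if (nrow(v) < 2L)
    stop("need at least two variants with both coordinates")
  sums <- v$gene_pos + v$grch38_pos
  if (length(unique(sums)) != 1L) {
    bad <- v$key[sums != sums[1]]
    stop("inconsistent gene/GRCh38 coordinates for variant(s): ",
         paste(bad, collapse = ", "))
  }
  sums[1]
}

#' All distinct variants known to a table
#'
#' @param table a `pgx_deftab`.
#' @return data.frame of distinct variants (core and suballele) with columns
#'   as in [parse_variant_tokens()].
#' @export
all_variants <- function(table) {
  v <- do.call(rbind, c(unname(table$core), unname(table$sub)))
  if (is.null(v) || nrow(v) == 0L) return(parse_variant_tokens("."))
  v[!duplicated(v$key), , drop = FALSE]
}

strip_multiplicity <- function(label) sub("x[0-9]+$", "", label)

label_multiplicity <- function(label) {
  m <- regmatches(label, regexpr("x([0-9]+)$", label))
  if (length(m) == 0L) 1L else as.integer(sub("^x", "", m))
}

star_number <- function(name) {
  n <- suppressWarnings(as.numeric(sub("^\\*", "", strip_multiplicity(name))))
  if (is.na(n)) Inf else n
}

base_allele_row <- function(table, name) {
  al <- table$alleles
  row <- al[al$name == name & is.na(al$suballele), , drop = FALSE]
  if (nrow(row) != 1L)
    stop("allele ", name, " not found in ", table$gene, " definition table")
  row
}

#' Activity value and function class of a single allele label
#'
#' `allele_activity()` resolves a star-allele label, including a duplication
#' label such as `"*1x2"`, to its activity contribution: N copies contribute
#' N times the base allele's activity value. Returns `NA` for alleles whose
#' function is uncertain/unknown or that carry no activity value.
#'
#' @param table a `pgx_deftab`.
#' @param label allele label, optionally suffixed `xN`.
#' @return numeric activity (or `NA`); for `allele_function()`, the function
#'   class string.
#' @export
allele_activity <- function(table, label) {
  row <- base_allele_row(table, strip_multiplicity(label))
  label_multiplicity(label) * row$activity
}

#' @rdname allele_activity
#' @export
allele_function <- function(table, label) {
  base_allele_row(table, strip_multiplicity(label))$function_class
}

#' Variant keys defining an allele (or one of its suballeles)
#'
#' @param table a `pgx_deftab`.
#' @param allele star-allele name.
#' @param suballele optional suballele label; when given, the union of the core
#'   set and the suballele's additional variants is returned.
#' @return character vector of canonical `pos:ref>alt` keys.
#' @export
allele_variant_keys <- function(table, allele, suballele = NULL) {
  base_allele_row(table, allele)  # existence check
  keys <- table$core[[allele]]$key
  if (!is.null(suballele) && !is.na(suballele)) {
    id <- sub_id(allele, suballele)
    if (is.null(table$sub[[id]]))
      stop("suballele ", suballele, " of ", allele, " not in table")
    keys <- c(keys, table$sub[[id]]$key)
  }
  keys
}

#' Map rsIDs to canonical variant keys
#'
#' Convenience lookup against the table's variant catalogue.
#'
#' @param table a `pgx_deftab`.
#' @param rsids character vector of dbSNP identifiers.
#' @return character vector of `pos:ref>alt` keys, in input order.
#' @export
rsid_keys <- function(table, rsids) {
  v <- all_variants(table)
  idx <- match(rsids, v$rsid)
  if (anyNA(idx)) stop("rsID(s) not in table: ",
                       paste(rsids[is.na(idx)], collapse = ", "))
  v$key[idx]
}

#' @export
print.pgx_deftab <- function(x, ...) {
  base <- x$alleles[is.na(x$alleles$suballele), , drop = FALSE]
  cat("Star-allele definition table for ", x$gene,
      " (reference ", x$reference_id, ")\n", sep = "")
  cat("  ", nrow(base), " star alleles, ",
      sum(!is.na(x$alleles$suballele)), " suballeles; default ",
      x$default_allele, "\n", sep = "")
  cat("  alleles: ", paste(base$name, collapse = " "), "\n", sep = "")
  invisible(x)
}
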