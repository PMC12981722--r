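# Synthetic diploid cohorts: Hardy-Weinberg draws from a star-allele
# frequency vector (including deletion and duplication pseudo-alleles),
# expansion to phased variant sets, novel-variant injection, depth
# simulation, and a ground-truth ledger covering every emitted sample.

#' Simulation configuration
#'
#' @param gene gene symbol.
#' @param allele_freqs named numeric vector over star-allele labels summing
#'   to 1 (within 1e-9); may include the deletion allele (`"*5"`) and
#'   duplication pseudo-alleles (`"*1x2"`).
#' @param n_individuals cohort size (>= 1).
#' @param novel_injection_rate per-haplotype probability of injecting one
#'   novel variant at a reserved position unused by any catalogued allele.
#' @param depth_mean,depth_sd normal distribution of per-sample mean amplicon
#'   read depth (reads; truncated at 0).
#' @param suballele_rate probability that a drawn allele with catalogued
#'   suballeles is emitted as a (uniformly chosen) suballele haplotype.
#' @param seed integer seed; the whole simulation is reproducible from it.
#' @return a `pgx_simconfig` list.
#' @export
sim_config <- function(gene, allele_freqs, n_individuals,
                       novel_injection_rate = 0, depth_mean = 500,
                       depth_sd = 120, suballele_rate = 0, seed = 1L) {
  stopifnot(n_individuals >= 1, novel_injection_rate >= 0,
            novel_injection_rate <= 1, suballele_rate >= 0, suballele_rate <= 1)
  if (is.null(names(allele_freqs)) || any(names(allele_freqs) == ""))
    stop("allele_freqs must be named by allele label")
  if (any(allele_freqs < 0)) stop("negative allele frequency")
  if (abs(sum(allele_freqs) - 1) > 1e-9)
    stop("allele frequencies must sum to 1 (got ", sum(allele_freqs), ")")
  structure(list(gene = gene, allele_freqs = allele_freqs,
                 n_individuals = as.integer(n_individuals),
                 novel_injection_rate = novel_injection_rate,
                 depth_mean = depth_mean, depth_sd = depth_sd,
                 suballele_rate = suballele_rate, seed = as.integer(seed)),
            class = "pgx_simconfig")
}

# positions 9501..9900 are reserved for injected novels: no fixture allele
# uses them, so every downstream novel flag is attributable to the injector
NOVEL_POOL_POS <- 9501:9900

#' Simulate a diploid cohort under Hardy-Weinberg equilibrium
#'
#' Each individual draws two allele labels independently from the frequency
#' vector (random mating); at most one structural (deletion/duplication)
#' allele is kept per individual — a second structural draw is redrawn from
#' the non-structural alleles. Each non-deleted haplotype's variant set is
#' the drawn allele's core set (plus a catalogued suballele's extras at
#' `suballele_rate`), plus, at the injection rate, one novel variant from a
#' reserved position pool. Per-sample depths are drawn from the configured
#' normal distribution. Everything emitted is recorded in a ground-truth
#' ledger.
#'
#' @param config a `pgx_simconfig`.
#' @param table a `pgx_deftab` for the same gene; every non-structural allele
#'   in the frequency vector must be present in it (checked before sampling).
#' @return list with elements
#'   `haplotypes` (data.frame: sample_id, hap_index, allele drawn, variant
#'   keys as `;`-joined string), `variants` (long data.frame: sample_id,
#'   hap_index, key), `structural` (named list of `pgx_structural`),
#'   `depths` (named numeric), and `ledger` (true diplotype per sample,
#'   injected variants per haplotype, depths, structural status).
#' @export
simulate_cohort <- function(config, table = builtin_table(config$gene)) {
  stopifnot(inherits(config, "pgx_simconfig"), inherits(table, "pgx_deftab"))
  labels <- names(config$allele_freqs)
  base_names <- vapply(labels, strip_multiplicity, character(1))
  for (nm in base_names) base_allele_row(table, nm)  # errors before sampling
  struct_kind <- function(label) {
    if (label_multiplicity(label) > 1L) return("duplication")
    if (base_allele_row(table, label)$structural == "deletion") return("deletion")
    "none"
  }
  kinds <- vapply(labels, struct_kind, character(1))
  known_pos <- all_variants(table)$gene_pos
  if (any(NOVEL_POOL_POS %in% known_pos))
    stop("reserved novel-variant positions collide with the table")

  set.seed(config$seed)
  n <- config$n_individuals
  ids <- sprintf("S%04d", seq_len(n))
  nonstruct <- labels[kinds == "none"]
  draw <- matrix(sample(labels, 2L * n, replace = TRUE,
                        prob = config$allele_freqs), ncol = 2)
  both_struct <- kinds[draw[, 1]] != "none" & kinds[draw[, 2]] != "none"
  if (any(both_struct)) {
    p_ns <- config$allele_freqs[nonstruct]
    draw[both_struct, 2] <- sample(nonstruct, sum(both_struct),
                                   replace = TRUE, prob = p_ns)
  }

  nhap <- 2L * n
  hap_sample <- rep(ids, each = 2L)
  hap_idx <- rep(1:2, n)
  hap_allele <- as.character(t(draw))
  hap_sub <- rep(NA_character_, nhap)
  key_list <- vector("list", nhap)
  inj_sample <- character(); inj_hap <- integer(); inj_key <- character()
  structural <- list()
  suballeles_of <- function(nm) {
    subs <- table$alleles$suballele[!is.na(table$alleles$suballele) &
                                      table$alleles$name == nm]
    subs[vapply(subs, function(s)
      nrow(table$sub[[sub_id(nm, s)]]) > 0L, logical(1))]
  }
  for (j in seq_len(nhap)) {
    label <- hap_allele[j]
    h <- hap_idx[j]
    kind <- kinds[[label]]
    if (kind != "none")
      structural[[hap_sample[j]]] <- structural_status(
        kind,
        if (kind == "duplication") label_multiplicity(label) else NA_integer_,
        h)
    keys <- character()
    if (kind != "deletion") {
      nm <- strip_multiplicity(label)
      keys <- table$core[[nm]]$key
      subs <- suballeles_of(nm)
      if (length(subs) > 0L && runif(1) < config$suballele_rate) {
        hap_sub[j] <- sample(subs, 1L)
        keys <- c(keys, table$sub[[sub_id(nm, hap_sub[j])]]$key)
      }
      if (runif(1) < config$novel_injection_rate) {
        nk <- paste0(sample(NOVEL_POOL_POS, 1L), ":A>G")
        keys <- c(keys, nk)
        inj_sample <- c(inj_sample, hap_sample[j])
        inj_hap <- c(inj_hap, h)
        inj_key <- c(inj_key, nk)
      }
    }
    key_list[[j]] <- keys
  }
  depths <- pmax(0, rnorm(n, config$depth_mean, config$depth_sd))
  names(depths) <- ids

  lens <- lengths(key_list)
  haplotypes <- data.frame(
    sample_id = hap_sample, hap_index = hap_idx, allele = hap_allele,
    suballele = hap_sub,
    variants = vapply(key_list, function(k)
      if (length(k) == 0L) "." else paste(k, collapse = ";"), character(1)),
    stringsAsFactors = FALSE)
  # variant-free haplotypes keep an NA-key row so every (sample, hap)
  # stays represented downstream
  variants <- data.frame(
    sample_id = rep(hap_sample, pmax(lens, 1L)),
    hap_index = rep(hap_idx, pmax(lens, 1L)),
    key = unlist(lapply(key_list, function(k)
      if (length(k) == 0L) NA_character_ else k), use.names = FALSE),
    stringsAsFactors = FALSE)
  injections <- data.frame(sample_id = inj_sample, hap_index = inj_hap,
                           key = inj_key, stringsAsFactors = FALSE)
  true_diplotypes <- data.frame(
    sample_id = ids,
    display = vapply(seq_len(n), function(i)
      paste(order_labels(draw[i, 1], draw[i, 2]), collapse = "/"),
      character(1)),
    hap1 = draw[, 1], hap2 = draw[, 2], stringsAsFactors = FALSE)

  list(haplotypes = haplotypes, variants = variants, structural = structural,
       depths = depths,
       ledger = list(config = config, diplotypes = true_diplotypes,
                     injections = injections, depths = depths,
                     structural = structural))
}

#' Emit simulated haplotypes as a minimal phased VCF
#'
#' One pseudo-contig named after the gene reference, 1-based gene-reference
#' positions, one sample column per individual with a phased GT (`a|b`). A
#' deleted haplotype is written as the missing allele `.` in the GT; its
#' structural interpretation travels in the sidecar structural TSV, mirroring
#' a CNV call made from a separate diagnostic amplicon.
#'
#' @param sim output of [simulate_cohort()] (elements `haplotypes`,
#'   `structural`), or any object with those elements.
#' @param table the `pgx_deftab` used to simulate (supplies ref/alt bases for
#'   catalogued variants; injected novels are A>G by construction).
#' @param path output VCF path.
#' @return `path`, invisibly.
#' @export
emit_phased_vcf <- function(sim, table, path) {
  haps <- sim$haplotypes
  samples <- unique(haps$sample_id)
  key_split <- function(s) if (s == ".") character() else
    strsplit(s, ";", fixed = TRUE)[[1]]
  hap_keys <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(haps)))
    assign(paste0(haps$sample_id[i], "|", haps$hap_index[i]),
           key_split(haps$variants[i]), envir = hap_keys)
  deleted <- function(s, h) {
    st <- sim$structural[[s]]
    !is.null(st) && st$kind == "deletion" && st$carrier_hap == h
  }
  all_keys <- sort(unique(unlist(lapply(haps$variants, key_split))))
  pos <- as.integer(sub(":.*", "", all_keys))
  all_keys <- all_keys[order(pos)]
  known <- all_variants(table)
  header <- c("##fileformat=VCFv4.2",
              paste0("##contig=<ID=", table$reference_id, ">"),
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Phased genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", samples), collapse = "\t"))
  records <- vapply(all_keys, function(k) {
    p <- sub(":.*", "", k)
    ra <- strsplit(sub("^[0-9]+:", "", k), ">", fixed = TRUE)[[1]]
    id <- known$rsid[match(k, known$key)]
    gts <- vapply(samples, function(s) {
      g <- vapply(1:2, function(h) {
        if (deleted(s, h)) return(".")
        if (k %in% get(paste0(s, "|", h), envir = hap_keys)) "1" else "0"
      }, character(1))
      paste(g, collapse = "|")
    }, character(1))
    paste(c(table$reference_id, p, ifelse(is.na(id), ".", id), ra[1], ra[2],
            ".", "PASS", ".", "GT", gts), collapse = "\t")
  }, character(1))
  writeLines(c(header, records), path)
  invisible(path)
}

#' Read a phased VCF into per-haplotype variant sets
#'
#' Accepts the minimal single-contig phased VCF written by
#' [emit_phased_vcf()] (and any VCF restricted to phased biallelic GTs with
#' `|` separators). A `.` haplotype allele contributes no variants.
#'
#' @param path VCF path.
#' @return data.frame with columns `sample_id`, `hap_index`, `key` (one row
#'   per variant call; samples/haplotypes with no variants appear with
#'   `key = NA` so that every haplotype of every sample is represented).
#' @export
read_phased_vcf <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#CHROM", lines)
  if (length(hdr) != 1L) stop("not a VCF: missing #CHROM header in ", path)
  cols <- strsplit(lines[hdr], "\t", fixed = TRUE)[[1]]
  if (length(cols) < 10L) {
    samples <- character()
  } else samples <- cols[10:length(cols)]
  body <- lines[seq_along(lines) > hdr]
  rows <- list()
  for (ln in body) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    key <- paste0(f[2], ":", toupper(f[4]), ">", toupper(f[5]))
    fmt <- strsplit(f[9], ":", fixed = TRUE)[[1]]
    gti <- match("GT", fmt)
    if (is.na(gti)) stop("VCF record without GT field")
    for (j in seq_along(samples)) {
      gt <- strsplit(f[9 + j], ":", fixed = TRUE)[[1]][gti]
      if (!grepl("|", gt, fixed = TRUE))
        stop("unphased genotype '", gt, "' for sample ", samples[j])
      al <- strsplit(gt, "|", fixed = TRUE)[[1]]
      for (h in 1:2) {
        if (identical(al[h], "1"))
          rows[[length(rows) + 1L]] <-
            data.frame(sample_id = samples[j], hap_index = h, key = key,
                       stringsAsFactors = FALSE)
      }
    }
  }
  calls <- if (length(rows) > 0L) do.call(rbind, rows) else
    data.frame(sample_id = character(), hap_index = integer(),
               key = character(), stringsAsFactors = FALSE)
  # ensure every (sample, hap) is present even when variant-free
  full <- expand.grid(sample_id = samples, hap_index = 1:2,
                      stringsAsFactors = FALSE)
  have <- paste(calls$sample_id, calls$hap_index)
  missing <- full[!paste(full$sample_id, full$hap_index) %in% have, ,
                  drop = FALSE]
  if (nrow(missing) > 0L) {
    missing$key <- NA_character_
    calls <- rbind(calls, missing)
  }
  calls[order(calls$sample_id, calls$hap_index), , drop = FALSE]
}

#' Write simulation sidecar files
#'
#' Writes the structural-evidence TSV, the per-sample depth TSV and the
#' ground-truth ledger JSON next to a VCF, completing the file quartet a
#' pipeline run consumes.
#'
#' @param sim output of [simulate_cohort()].
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @param table the `pgx_deftab` used to simulate.
#' @return named character vector of the written paths.
#' @export
write_simulation <- function(sim, dir, prefix = "cohort",
                             table = builtin_table(sim$ledger$config$gene)) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(vcf = file.path(dir, paste0(prefix, ".vcf")),
             structural = file.path(dir, paste0(prefix, ".structural.tsv")),
             depth = file.path(dir, paste0(prefix, ".depth.tsv")),
             ledger = file.path(dir, paste0(prefix, ".ledger.json")))
  emit_phased_vcf(sim, table, paths[["vcf"]])
  write_structural_tsv(sim$structural, paths[["structural"]])
  writeLines(c("sample\tmean_depth",
               paste(names(sim$depths), format(sim$depths, digits = 10),
                     sep = "\t")), paths[["depth"]])
  led <- sim$ledger
  led$structural <- lapply(led$structural, unclass)
  led$config <- unclass(led$config)
  jsonlite::write_json(led, paths[["ledger"]], auto_unbox = TRUE, digits = NA,
                       na = "null")
  paths
}

read_depth_tsv <- function(path) {
  raw <- read.delim(path, colClasses = "character")
  if (!all(c("sample", "mean_depth") %in% names(raw)))
    stop("depth TSV needs columns sample, mean_depth")
  structure(as.numeric(raw$mean_depth), names = raw$sample)
}
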