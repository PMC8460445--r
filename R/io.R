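# File-format plumbing: weight TSV, dosage CSV/VCF, phenotype CSV,
# incidence-schedule CSV. All formats are plain text.

#' Read a variant weight table (TSV)
#'
#' Expected header: `variant_id chrom pos effect_allele other_allele eaf
#' weight_overall weight_erpos weight_erneg`.
#'
#' @param path TSV path.
#' @return A validated panel data.frame.
#' @export
read_weight_panel <- function(path) {
  panel <- utils::read.delim(path, stringsAsFactors = FALSE,
                             colClasses = c(chrom = "character"))
  validate_panel(panel)
  panel
}

#' @rdname read_weight_panel
#' @param panel Panel data.frame.
#' @export
write_weight_panel <- function(panel, path) {
  validate_panel(panel)
  utils::write.table(panel, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read/write a subject-by-variant dosage matrix (CSV)
#'
#' First column `subject_id`; remaining columns one per variant id.
#'
#' @param path CSV path.
#' @return Numeric matrix with subject ids as rownames.
#' @export
read_dosage_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (names(df)[1] != "subject_id") stop("first column must be subject_id")
  m <- as.matrix(df[-1])
  rownames(m) <- df$subject_id
  storage.mode(m) <- "double"
  m
}

#' @rdname read_dosage_csv
#' @param dosages Matrix as from [generate_families_genotypes()].
#' @export
write_dosage_csv <- function(dosages, path) {
  df <- data.frame(subject_id = rownames(dosages), dosages,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read genotype dosages from a VCF with a per-sample `DS` FORMAT field
#'
#' Returns the dosage matrix together with the variant metadata needed by
#' [align_dosages()] (the VCF ALT allele is taken as the coded allele).
#' Requires the `vcfR` package.
#'
#' @param path VCF path (uncompressed or bgzipped).
#' @return A list `dosages` (subject x variant), `variants` (data.frame
#'   `variant_id`, `chrom`, `pos`, `coded_allele`, `other_allele`, `freq`).
#' @export
read_dosage_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("reading VCF dosages requires the vcfR package")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  ds <- vcfR::extract.gt(v, element = "DS", as.numeric = TRUE)
  fix <- vcfR::getFIX(v)
  ids <- fix[, "ID"]
  ids[is.na(ids) | ids == "."] <- paste0(fix[, "CHROM"], ":", fix[, "POS"])[is.na(ids) | ids == "."]
  dosages <- t(ds)
  colnames(dosages) <- ids
  freq <- colMeans(dosages, na.rm = TRUE) / 2
  list(
    dosages = dosages,
    variants = data.frame(
      variant_id = ids, chrom = as.character(fix[, "CHROM"]),
      pos = as.integer(fix[, "POS"]),
      coded_allele = fix[, "ALT"], other_allele = fix[, "REF"],
      freq = unname(freq), stringsAsFactors = FALSE
    )
  )
}

#' Write a minimal VCF carrying dosages in a `DS` FORMAT field
#'
#' @param dosages Subject x variant matrix.
#' @param panel Panel supplying positions and alleles (effect allele is
#'   written as ALT so the coded allele equals the effect allele).
#' @param path Output path.
#' @export
write_dosage_vcf <- function(dosages, panel, path) {
  validate_panel(panel)
  stopifnot(all(colnames(dosages) %in% panel$variant_id))
  p <- panel[match(colnames(dosages), panel$variant_id), ]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Effect-allele dosage\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", rownames(dosages)), collapse = "\t")
  ), con)
  body <- vapply(seq_len(nrow(p)), function(j) {
    paste(c(p$chrom[j], p$pos[j], p$variant_id[j], p$other_allele[j],
            p$effect_allele[j], ".", "PASS", ".", "DS",
            formatC(dosages[, j], format = "g", digits = 6)),
          collapse = "\t")
  }, "")
  writeLines(body, con)
  invisible(path)
}

#' Read a phenotype table (CSV)
#'
#' One row per woman with the subject-record schema used throughout:
#' identifiers (`subject_id`, `family_id`, `country`), `birth_year`, ages
#' (`age_bc1`, `age_baseline`, `age_cbc`, `age_rrm`, `age_death`,
#' `age_distant_relapse`), event descriptors (`cbc_invasive`,
#' `cbc_er_status`), `metastatic_bc1` and the first-tumor covariates.
#'
#' @param path CSV path.
#' @return data.frame of subject records.
#' @export
read_phenotypes <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "family_id", "country", "age_bc1")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("phenotypes missing columns: ",
                         paste(miss, collapse = ", "))
  if (any(df$family_id == "" | is.na(df$family_id))) {
    stop("family_id must be non-empty")
  }
  df
}

#' Read an external marginal incidence schedule (CSV)
#'
#' Columns `age_group` (`<40`, `40-50`, `>=50`), `t` (years since first BC,
#' uniform step within group) and `rate` (marginal CBC incidence per year).
#'
#' @param path CSV path.
#' @return data.frame, checked per group for a uniform increasing grid and
#'   nonnegative rates.
#' @export
read_incidence_schedule <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("age_group", "t", "rate")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("schedule missing columns: ",
                         paste(miss, collapse = ", "))
  for (g in unique(df$age_group)) {
    validate_schedule(df[df$age_group == g, ])
  }
  df
}
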