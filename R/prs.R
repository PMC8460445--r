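#' Standardization contract for a polygenic risk score
#'
#' The scores are standardized to a cohort mean (affected and unaffected
#' alike) and to an externally supplied reference SD -- the convention that
#' makes hazard ratios per SD directly comparable across studies using the
#' same reference population. The reference SD is a required input: it is
#' a property of the external control series, not of the analysis cohort.
#'
#' @param center Cohort mean of raw scores, or `NULL` to compute it
#'   internally from all subjects supplied to [standardize_prs()].
#' @param scale Reference SD (> 0).
#' @return A `cbc_standardization` list.
#' @export
standardization_spec <- function(center = NULL, scale) {
  if (!is.numeric(scale) || length(scale) != 1 || !is.finite(scale) ||
      scale <= 0) {
    stop("scale must be a single positive number")
  }
  structure(list(center = center, scale = scale),
            class = "cbc_standardization")
}

weight_column <- function(flavor) {
  switch(match.arg(flavor, c("overall", "er_positive", "er_negative")),
         overall = "weight_overall",
         er_positive = "weight_erpos",
         er_negative = "weight_erneg")
}

#' Align source dosages to the panel's effect alleles
#'
#' Matches source variants to the panel by (chromosome, position, allele
#' pair) -- or by variant id when `match_by_id = TRUE` -- and re-expresses
#' each dosage as a count of the panel's effect allele: unchanged when the
#' source's coded allele is the effect allele, `2 - d` when it is the other
#' allele. Variants whose allele pair does not match are dropped with a
#' logged reason. Strand-ambiguous pairs (A/T, C/G) are dropped when the
#' source allele frequency differs from the panel frequency by more than
#' 0.2, since strand cannot then be resolved.
#'
#' @param panel Variant weight panel.
#' @param source A list/data.frame-backed source with elements `dosages`
#'   (subject x variant matrix, columns named by source variant id), and
#'   `variants`: data.frame with `variant_id`, `chrom`, `pos`,
#'   `coded_allele`, `other_allele` and optionally `freq` (coded-allele
#'   frequency; required to keep ambiguous pairs).
#' @param match_by_id Match on variant id instead of position/alleles.
#' @param ambiguous_freq_tol Frequency discrepancy above which a
#'   strand-ambiguous variant is dropped.
#' @return A matrix of aligned dosages (columns = panel variant ids that
#'   matched) with a `"dropped"` attribute logging removed variants.
#' @export
align_dosages <- function(panel, source, match_by_id = FALSE,
                          ambiguous_freq_tol = 0.2) {
  validate_panel(panel)
  v <- source$variants
  if (anyDuplicated(v$variant_id)) stop("duplicate variant ids in source")
  key <- function(chrom, pos) paste(chrom, pos, sep = ":")
  idx <- if (match_by_id) {
    match(v$variant_id, panel$variant_id)
  } else {
    match(key(v$chrom, v$pos), key(panel$chrom, panel$pos))
  }
  dropped <- data.frame(variant_id = character(0), reason = character(0),
                        stringsAsFactors = FALSE)
  drop <- function(ids, reason) {
    rbind(dropped, data.frame(variant_id = ids, reason = reason,
                              stringsAsFactors = FALSE))
  }
  keep <- !is.na(idx)
  if (any(!keep)) dropped <- drop(v$variant_id[!keep], "not_in_panel")
  v <- v[keep, , drop = FALSE]
  idx <- idx[keep]

  same <- v$coded_allele == panel$effect_allele[idx] &
    v$other_allele == panel$other_allele[idx]
  flip <- v$coded_allele == panel$other_allele[idx] &
    v$other_allele == panel$effect_allele[idx]
  mismatch <- !(same | flip)
  if (any(mismatch)) dropped <- drop(v$variant_id[mismatch], "allele_mismatch")

  pair <- function(a, b) paste(pmin(a, b), pmax(a, b))
  ambig <- pair(v$coded_allele, v$other_allele) %in% c("A T", "C G")
  ambig_drop <- ambig & !mismatch
  if (any(ambig_drop)) {
    if (is.null(v$freq)) {
      dropped <- drop(v$variant_id[ambig_drop], "ambiguous_no_freq")
      ok_ambig <- rep(FALSE, nrow(v))
    } else {
      # Compare on the coded-allele scale: the panel frequency refers to the
      # effect allele, so flip it where the coding is flipped.
      pf <- ifelse(flip, 1 - panel$eaf[idx], panel$eaf[idx])
      far <- abs(v$freq - pf) > ambiguous_freq_tol
      bad <- ambig_drop & far
      if (any(bad)) dropped <- drop(v$variant_id[bad], "ambiguous_freq_mismatch")
      ok_ambig <- ambig_drop & !far
    }
  } else {
    ok_ambig <- rep(FALSE, nrow(v))
  }
  keep2 <- (same | flip) & (!ambig_drop | ok_ambig)
  v <- v[keep2, , drop = FALSE]
  idx <- idx[keep2]
  flip <- flip[keep2]

  d <- source$dosages[, v$variant_id, drop = FALSE]
  if (any(flip)) d[, flip] <- 2 - d[, flip, drop = FALSE]
  colnames(d) <- panel$variant_id[idx]
  attr(d, "dropped") <- dropped
  d
}

#' Compute raw polygenic risk scores
#'
#' `raw_i = sum_j w_j g_ij` over the panel variants, using the weight column
#' of the requested flavor. Missing dosages are mean-imputed at twice the
#' effect-allele frequency (the expected count under Hardy-Weinberg), the
#' standard PRS convention; subjects missing more than `max_missing` of the
#' panel are flagged in the `"flagged_subjects"` attribute.
#'
#' Dosage columns absent from the panel are ignored with a warning; panel
#' variants absent from the dosages are mean-imputed for every subject.
#'
#' @param dosages Subject x variant dosage matrix, columns named by variant
#'   id, values in [0, 2] or `NA`.
#' @param panel Variant weight panel.
#' @param flavor `"overall"`, `"er_positive"` or `"er_negative"`.
#' @param max_missing Per-subject missing-variant fraction above which the
#'   subject is flagged.
#' @return A data.frame `subject_id`, `raw` with attributes
#'   `n_imputed_entries` and `flagged_subjects`.
#' @export
compute_prs <- function(dosages, panel, flavor = "overall",
                        max_missing = 0.2) {
  validate_panel(panel)
  extra <- setdiff(colnames(dosages), panel$variant_id)
  if (length(extra)) {
    warning(length(extra), " dosage variants not in panel; ignored")
    dosages <- dosages[, setdiff(colnames(dosages), extra), drop = FALSE]
  }
  rng <- range(dosages, na.rm = TRUE)
  if (rng[1] < 0 || rng[2] > 2) stop("dosages must lie in [0, 2]")
  m <- match(panel$variant_id, colnames(dosages))
  n <- nrow(dosages)
  G <- matrix(NA_real_, n, nrow(panel))
  G[, !is.na(m)] <- dosages[, m[!is.na(m)], drop = FALSE]
  miss <- is.na(G)
  n_imp <- sum(miss)
  if (n_imp) {
    fill <- matrix(rep(2 * panel$eaf, each = n), n)
    G[miss] <- fill[miss]
  }
  w <- panel[[weight_column(flavor)]]
  raw <- drop(G %*% w)
  frac_miss <- rowMeans(miss)
  ids <- rownames(dosages) %||% sprintf("s%06d", seq_len(n))
  out <- data.frame(subject_id = ids, raw = raw, stringsAsFactors = FALSE)
  attr(out, "n_imputed_entries") <- n_imp
  attr(out, "flagged_subjects") <- ids[frac_miss > max_missing]
  out
}

#' Standardize raw PRS to SD units of a reference population
#'
#' `z = (raw - center) / scale`. When the spec's center is `NULL`, the
#' center is the mean of the raw scores over all subjects supplied --
#' affected and unaffected alike.
#'
#' @param raw_scores data.frame from [compute_prs()] (columns `subject_id`,
#'   `raw`).
#' @param spec A [standardization_spec()].
#' @param flavor Flavor label carried in the output.
#' @return data.frame `subject_id`, `raw`, `z`, `flavor`, with the applied
#'   `center`/`scale` recorded as attributes.
#' @export
standardize_prs <- function(raw_scores, spec, flavor = "overall") {
  stopifnot(inherits(spec, "cbc_standardization"))
  center <- spec$center %||% mean(raw_scores$raw)
  z <- (raw_scores$raw - center) / spec$scale
  if (any(!is.finite(z))) stop("standardized scores must be finite")
  out <- data.frame(subject_id = raw_scores$subject_id,
                    raw = raw_scores$raw, z = z,
                    flavor = flavor, stringsAsFactors = FALSE)
  attr(out, "center") <- center
  attr(out, "scale") <- spec$scale
  out
}
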