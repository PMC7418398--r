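#' Variant-trait integration and colocalization
#'
#' Significant pQTL variants are joined to variant-trait catalogs (GWAS
#' Catalog / ClinVar / PharmGKB style exports unified to rsid, trait, source)
#' by rsID. Colocalization of a protein's pQTL signal with an external
#' eQTL/GWAS variant requires (1) pairwise LD r-squared above 0.8 between the
#' external variant and the lead pQTL variant and (2) the lead variant's
#' association p to be no longer significant once the external variant's
#' dosage is added to the model (conditional analysis). LD is computed from
#' this study's genotypes; no external reference panel.
#'
#' @name trait_integration
NULL

#' Join significant pQTLs to a trait catalog by rsID
#'
#' @param records significant-association table with `rsid`, `protein`.
#' @param catalog data.frame with `rsid`, `trait` and optional `source`.
#' @return list with `triples` (deduplicated rsid-protein-trait rows) and
#'   per-trait / per-protein counts.
#' @export
map_traits <- function(records, catalog) {
  records <- as.data.table(records)
  catalog <- as.data.table(catalog)
  if (!nrow(catalog) || !nrow(records)) {
    triples <- data.table(rsid = character(), protein = character(),
                          trait = character(), source = character())
  } else {
    if (!"source" %in% names(catalog)) catalog[, source := "user"]
    triples <- unique(merge(records[, .(rsid, protein)],
                            unique(catalog[, .(rsid, trait, source)]),
                            by = "rsid", allow.cartesian = TRUE))
  }
  list(triples = triples,
       n_variants = uniqueN(triples$rsid),
       n_traits = uniqueN(triples$trait),
       per_trait = triples[, .N, by = trait][order(-N)],
       per_protein = triples[, .N, by = protein][order(-N)])
}

#' Lead variant of a protein
#'
#' The variant with the smallest association p; ties broken by smaller
#' position, then lexicographic rsID.
#'
#' @param records association records of one protein (`rsid`, `pos`, `p`).
#' @return one-row data.table.
#' @export
lead_variant <- function(records) {
  records <- as.data.table(records)
  if (!nrow(records)) stop("no records to pick a lead variant from")
  setorder(records, p, pos, rsid)
  records[1]
}

#' Conditional association test
#'
#' Refits the lead variant's additive model with the candidate variant's
#' dosage added as a covariate and reports the lead's unconditional and
#' conditional p. A column-identical candidate (perfect collinearity) gets
#' conditional p = 1 and a collinear flag.
#'
#' @param y protein trait vector.
#' @param lead_dosage,candidate_dosage dosage vectors.
#' @param covariates numeric covariate matrix (or NULL); retained in the
#'   conditional model unless `keep_covariates = FALSE`.
#' @param keep_covariates drop covariates from the conditional model if FALSE.
#' @return list(p_unconditional, p_conditional, collinear).
#' @export
conditional_test <- function(y, lead_dosage, candidate_dosage,
                             covariates = NULL, keep_covariates = TRUE) {
  f0 <- fit_additive(lead_dosage, y, covariates)
  if (is.null(f0)) stop("unconditional model could not be fitted")
  r2 <- ld_r2(lead_dosage, candidate_dosage)
  if (!is.na(r2) && r2 > 1 - 1e-12)
    return(list(p_unconditional = f0$p, p_conditional = 1, collinear = TRUE))
  cov2 <- cbind(if (keep_covariates) covariates, candidate = candidate_dosage)
  f1 <- fit_additive(lead_dosage, y, cov2)
  list(p_unconditional = f0$p,
       p_conditional = if (is.null(f1)) 1 else f1$p,
       collinear = FALSE)
}

#' Colocalization of a protein's pQTL with external association signals
#'
#' For each external variant in LD (r-squared > `r2_min`) with the protein's
#' lead pQTL variant, runs [conditional_test()]; the pair colocalizes iff the
#' conditional p is no longer significant (>= `threshold`).
#'
#' @param protein protein ID.
#' @param records significant-association table (all proteins).
#' @param external data.frame of external variants (`rsid`; eQTL or GWAS
#'   summaries).
#' @param gm a [genotype_matrix()] holding dosages for LD and conditioning.
#' @param proteins a `protein_matrix` (source of the trait vector).
#' @param covariates numeric covariate design (as used in the scan) or NULL.
#' @param threshold significance threshold declaring the conditional p "no
#'   longer significant" (default: the study's genome-wide threshold is what
#'   the scan used; pass it explicitly or use 0.05 for a nominal rule).
#' @param r2_min LD cutoff, default 0.8 (strict >).
#' @return data.table: protein, lead_rsid, candidate_rsid, r2, p_uncond,
#'   p_cond, collinear, colocalized; external variants absent from the
#'   genotypes are skipped and counted in the `n_skipped` attribute.
#' @export
colocalize <- function(protein, records, external, gm, proteins,
                       covariates = NULL, threshold, r2_min = 0.8) {
  records <- as.data.table(records)
  prec <- records[records$protein == protein]
  if (!nrow(prec)) stop("no significant records for protein ", protein)
  lead <- lead_variant(prec)
  external <- as.data.table(external)
  known <- external$rsid %in% gm$variants$rsid
  n_skipped <- sum(!known)
  if (n_skipped)
    warning(n_skipped, " external variant(s) absent from genotypes; skipped")
  # the lead itself may appear in the external table: that is the clearest
  # shared-causal case and resolves as collinear -> colocalized
  cand <- unique(external$rsid[known])
  empty <- data.table(protein = character(), lead_rsid = character(),
                      candidate_rsid = character(), r2 = numeric(),
                      p_uncond = numeric(), p_cond = numeric(),
                      collinear = logical(), colocalized = logical())
  y <- proteins$conc[protein, gm$samples]
  gl <- gm$dosage[, lead$rsid]
  out <- lapply(cand, function(rs) {
    gc_ <- gm$dosage[, rs]
    r2 <- ld_r2(gl, gc_)
    if (is.na(r2) || r2 <= r2_min) return(NULL)
    ct <- conditional_test(y, gl, gc_, covariates)
    data.table(protein = protein, lead_rsid = lead$rsid, candidate_rsid = rs,
               r2 = r2, p_uncond = ct$p_unconditional,
               p_cond = ct$p_conditional, collinear = ct$collinear,
               colocalized = ct$p_conditional >= threshold)
  })
  res <- rbindlist(c(list(empty), out))
  setattr(res, "n_skipped", n_skipped)
  res
}

#' Colocalization across all proteins with significant pQTLs
#'
#' @inheritParams colocalize
#' @param external data.frame with `rsid` and optionally `trait`/`gene`.
#' @export
colocalize_all <- function(records, external, gm, proteins,
                           covariates = NULL, threshold, r2_min = 0.8) {
  records <- as.data.table(records)
  res <- lapply(unique(records$protein), function(pr)
    suppressWarnings(colocalize(pr, records, external, gm, proteins,
                                covariates, threshold, r2_min)))
  rbindlist(res)
}
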