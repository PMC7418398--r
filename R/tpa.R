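#' Absolute protein quantification by the total protein approach (TPA)
#'
#' Functions converting peptide-level DIA MS2 peak areas into absolute protein
#' concentrations (pmol per mg total input protein). The concentration of
#' protein i is
#'
#'   Protein(i) = MS2signal(i) / (TotalMS2signal * MolecularMass(i)) * 1e9
#'
#' where MS2signal(i) sums the areas of peptides assigned to protein i after
#' the signal of shared peptides has been redistributed among carrier proteins
#' in proportion to their unique-peptide signal totals.
#'
#' @name tpa
NULL

#' Construct and validate a peptide signal table
#'
#' @param x data.frame with columns `peptide_id`, `sequence`, `protein_ids`
#'   (semicolon-separated protein accessions) followed by one numeric MS2
#'   peak-area column per sample. `NA` means the peptide was not detected in
#'   that sample (it contributes nothing; it is not a zero).
#' @return a `peptide_signal_table` (data.table) with a `samples` attribute.
#' @export
peptide_signal_table <- function(x) {
  req <- c("peptide_id", "sequence", "protein_ids")
  miss <- setdiff(req, names(x))
  if (length(miss))
    stop("peptide table lacks required columns: ", paste(miss, collapse = ", "))
  x <- as.data.table(x)
  samples <- setdiff(names(x), req)
  for (s in samples) {
    v <- x[[s]]
    if (!is.numeric(v)) stop("area column '", s, "' is not numeric")
    if (any(v < 0, na.rm = TRUE))
      stop("negative MS2 peak area in sample '", s, "'")
  }
  if (any(!nzchar(x$protein_ids)))
    stop("every peptide must map to at least one protein")
  setattr(x, "samples", samples)
  setattr(x, "class", c("peptide_signal_table", class(x)))
  x[]
}

#' Read a peptide signal table from TSV
#' @param path TSV file (columns as in [peptide_signal_table()]).
#' @export
read_peptide_table <- function(path) {
  peptide_signal_table(fread(path, sep = "\t"))
}

# split the protein_ids column once; returns list of character vectors
protein_groups <- function(table) strsplit(table$protein_ids, ";", fixed = TRUE)

#' Sum unique-peptide MS2 signal per protein
#'
#' A peptide is unique iff its protein group holds exactly one protein. For one
#' sample, returns the per-protein sum of areas of its unique peptides;
#' proteins that appear only in shared groups get 0.
#'
#' @param table a [peptide_signal_table()].
#' @param sample sample (column) name.
#' @return named numeric vector over all proteins occurring in the table.
#' @export
sum_unique_signals <- function(table, sample) {
  groups <- protein_groups(table)
  proteins <- sort(unique(unlist(groups)))
  totals <- setNames(numeric(length(proteins)), proteins)
  if (!length(proteins)) return(totals)
  areas <- table[[sample]]
  if (is.null(areas)) stop("no such sample column: ", sample)
  uni <- lengths(groups) == 1L & !is.na(areas)
  if (any(uni)) {
    agg <- tapply(areas[uni], unlist(groups[uni]), sum)
    totals[names(agg)] <- agg
  }
  totals
}

#' Redistribute shared-peptide signal among carrier proteins
#'
#' Each shared peptide's area is split among exactly its own carrier proteins
#' in proportion to their unique-signal totals in the same sample:
#'
#'   MS2signal(i) = unique(i) + sum_over_shared_peptides unique(i)/sum_G unique * area
#'
#' A shared peptide whose carriers all have zero unique signal is unassignable;
#' its area is excluded and reported.
#'
#' @inheritParams sum_unique_signals
#' @return list with `signal` (named per-protein totals after redistribution),
#'   `unassignable` (total excluded shared area) and `unquantifiable`
#'   (proteins detected only through unassignable shared peptides).
#' @export
redistribute_shared <- function(table, sample) {
  unique_tot <- sum_unique_signals(table, sample)
  signal <- unique_tot
  groups <- protein_groups(table)
  areas <- table[[sample]]
  shared_idx <- which(lengths(groups) > 1L & !is.na(areas) & areas > 0)
  unassignable <- 0
  orphan <- character(0)
  for (k in shared_idx) {
    carriers <- groups[[k]]
    u <- unique_tot[carriers]
    su <- sum(u)
    if (su <= 0) {
      unassignable <- unassignable + areas[k]
      orphan <- c(orphan, carriers)
      next
    }
    signal[carriers] <- signal[carriers] + u / su * areas[k]
  }
  # proteins seen in this sample only via unassignable shared peptides
  unquantifiable <- setdiff(unique(orphan), names(signal)[signal > 0])
  list(signal = signal, unassignable = unassignable,
       unquantifiable = unquantifiable)
}

#' TPA concentration of one protein
#'
#' @param ms2_signal_i protein-level MS2 signal (after redistribution).
#' @param total_ms2 total MS2 signal of the sample (> 0).
#' @param mass_i molecular mass of the protein in g/mol (> 0).
#' @return concentration in pmol per mg total input protein.
#' @export
tpa_concentration <- function(ms2_signal_i, total_ms2, mass_i) {
  if (any(total_ms2 <= 0)) stop("total_ms2 must be > 0")
  if (any(mass_i <= 0)) stop("molecular mass must be > 0")
  ms2_signal_i / (total_ms2 * mass_i) * 1e9
}

#' Protein metadata table
#'
#' @param x data.frame with columns `protein`, `gene`, `chrom`, `start`, `end`
#'   (1-based inclusive gene interval) and `mass` (g/mol).
#' @export
protein_meta <- function(x) {
  req <- c("protein", "gene", "chrom", "start", "end", "mass")
  miss <- setdiff(req, names(x))
  if (length(miss))
    stop("protein metadata lacks columns: ", paste(miss, collapse = ", "))
  if (any(x$mass <= 0)) stop("molecular mass must be > 0")
  if (any(x$start > x$end)) stop("gene start > end")
  if (anyDuplicated(x$protein)) stop("duplicate protein IDs in metadata")
  x <- as.data.table(x)
  setattr(x, "class", c("protein_meta", class(x)))
  x[]
}

#' Quantify a full protein-by-sample concentration matrix
#'
#' Applies unique-signal summation, shared-signal redistribution and the TPA
#' equation per sample. Proteins without any detected peptide in a sample are
#' missing (`NA`), not zero.
#'
#' @param table a [peptide_signal_table()].
#' @param meta a [protein_meta()] covering every protein in the table.
#' @param total_signal `"all"` (default): the TPA denominator is the sum of all
#'   detected peptide areas in the sample, including peptides of proteins that
#'   are later unquantifiable; `"quantified"`: only signal assigned to
#'   quantified proteins.
#' @return a `protein_matrix`: list with `conc` (proteins x samples matrix,
#'   pmol/mg), `meta`, and `log` (per-sample unassignable shared signal).
#' @export
quantify_matrix <- function(table, meta, total_signal = c("all", "quantified")) {
  total_signal <- match.arg(total_signal)
  meta <- if (inherits(meta, "protein_meta")) meta else protein_meta(meta)
  groups <- protein_groups(table)
  proteins <- sort(unique(unlist(groups)))
  absent <- setdiff(proteins, meta$protein)
  if (length(absent))
    stop("proteins present in the peptide table but missing from metadata: ",
         paste(absent, collapse = ", "))
  samples <- attr(table, "samples")
  mass <- setNames(meta$mass, meta$protein)[proteins]
  conc <- matrix(NA_real_, length(proteins), length(samples),
                 dimnames = list(proteins, samples))
  log <- data.table(sample = samples, unassignable = 0,
                    n_unquantifiable = 0L)
  for (j in seq_along(samples)) {
    s <- samples[j]
    areas <- table[[s]]
    detected <- !is.na(areas)
    if (!any(detected)) next
    rd <- redistribute_shared(table, s)
    total <- if (total_signal == "all") sum(areas[detected]) else sum(rd$signal)
    if (total <= 0) next
    # a protein is present iff some detected peptide carries it
    present <- unique(unlist(groups[detected]))
    vals <- tpa_concentration(rd$signal[present], total, mass[present])
    conc[present, j] <- vals
    # zero assigned signal despite detection only via orphan shared peptides
    if (length(rd$unquantifiable)) conc[rd$unquantifiable, j] <- NA_real_
    log$unassignable[j] <- rd$unassignable
    log$n_unquantifiable[j] <- length(rd$unquantifiable)
  }
  structure(list(conc = conc, meta = meta, log = log),
            class = "protein_matrix")
}

#' @export
print.protein_matrix <- function(x, ...) {
  cat(sprintf("protein_matrix: %d proteins x %d samples (%.1f%% missing)\n",
              nrow(x$conc), ncol(x$conc),
              100 * mean(is.na(x$conc))))
  invisible(x)
}

#' Write a protein concentration matrix to TSV
#' @param x a `protein_matrix`.
#' @param path output TSV (rows proteins, columns samples; first column `protein`).
#' @export
write_protein_matrix <- function(x, path) {
  dt <- data.table(protein = rownames(x$conc))
  dt <- cbind(dt, as.data.table(x$conc))
  fwrite(dt, path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}

#' Read a protein concentration matrix from TSV
#' @param path concentration TSV written by [write_protein_matrix()].
#' @param meta a [protein_meta()] table.
#' @export
read_protein_matrix <- function(path, meta) {
  dt <- fread(path, sep = "\t")
  m <- as.matrix(dt[, -1])
  rownames(m) <- dt$protein
  structure(list(conc = m, meta = protein_meta(meta),
                 log = data.table()), class = "protein_matrix")
}
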