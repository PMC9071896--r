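#' Read a gene-by-sample expression table
#'
#' Reads a TSV with gene identifiers in the first column and one column per
#' sample, and returns a validated non-negative matrix on linear scale.
#' Tables that were stored as `log2(x + 1)` can be declared as such with
#' `log2_input`, in which case values are back-transformed to linear scale
#' as `2^v - 1` and clipped at zero. Duplicate gene rows are collapsed by
#' their arithmetic mean (with a warning), which is common in array-derived
#' tables where several probes map to one symbol.
#'
#' @param path path to a tab-separated file; header row holds sample ids.
#' @param log2_input logical; values are `log2(x + 1)` and must be
#'   back-transformed to linear scale.
#' @return numeric matrix (genes x samples) with unique dimnames.
#' @export
read_expression_table <- function(path, log2_input = FALSE) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 3L) stopf("expression table needs >= 2 sample columns: %s", path)
  sample_ids <- colnames(df)[-1L]
  if (anyDuplicated(sample_ids))
    stopf("duplicate sample ids in '%s': %s", path,
          paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  genes <- as.character(df[[1L]])
  values <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(values) <- "double"
  if (anyNA(values) || any(!is.finite(values)))
    stopf("non-finite values in expression table '%s'", path)
  if (log2_input) {
    values <- pmax(2^values - 1, 0)
  } else if (any(values < 0)) {
    bad <- which(values < 0, arr.ind = TRUE)[1L, ]
    stopf("negative linear expression value at gene '%s', sample '%s'",
          genes[bad[1L]], sample_ids[bad[2L]])
  }
  if (anyDuplicated(genes)) {
    dup <- unique(genes[duplicated(genes)])
    warnf("collapsing %d duplicated gene id(s) by mean: %s", length(dup),
          paste(utils::head(dup, 5L), collapse = ", "))
    values <- rowsum(values, group = genes, reorder = FALSE) /
      as.vector(table(factor(genes, levels = unique(genes))))
    genes <- unique(genes)
  }
  rownames(values) <- genes
  colnames(values) <- sample_ids
  validate_expression_table(values)
}

#' Validate an expression matrix
#'
#' Checks the invariants every expression table in the pipeline must hold:
#' unique gene and sample identifiers, finite non-negative values, and at
#' least two samples.
#'
#' @param x numeric matrix with genes in rows, samples in columns.
#' @return `x`, invisibly validated (returned unchanged).
#' @export
validate_expression_table <- function(x) {
  if (!is.matrix(x) || !is.numeric(x)) stopf("expression table must be a numeric matrix")
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stopf("expression table needs gene rownames and sample colnames")
  if (anyDuplicated(rownames(x))) stopf("duplicate gene ids")
  if (anyDuplicated(colnames(x))) stopf("duplicate sample ids")
  if (ncol(x) < 2L) stopf("expression table needs at least 2 samples")
  if (anyNA(x) || any(!is.finite(x)) || any(x < 0))
    stopf("expression values must be finite and >= 0")
  x
}

#' Write an expression table to TSV
#'
#' @param x validated expression matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_expression_table <- function(x, path) {
  validate_expression_table(x)
  df <- data.frame(gene_id = rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a per-sample clinical table
#'
#' Requires columns `sample_id`, `os_time` (days, > 0) and `os_event`
#' (0 = censored, 1 = death). Optional columns (`subtype`, `stage`,
#' `response_score`, `msi_score`, `purity`, `ploidy`) and any unknown
#' columns are carried through unchanged as covariates.
#'
#' @param path path to a tab-separated file.
#' @return data.frame, one row per sample.
#' @export
read_clinical_table <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  validate_clinical_table(df)
}

#' Validate a clinical table
#'
#' @param df data.frame with at least sample_id, os_time, os_event.
#' @return the validated data.frame.
#' @export
validate_clinical_table <- function(df) {
  required <- c("sample_id", "os_time", "os_event")
  missing <- setdiff(required, colnames(df))
  if (length(missing))
    stopf("clinical table missing required column(s): %s", paste(missing, collapse = ", "))
  df$sample_id <- as.character(df$sample_id)
  if (anyDuplicated(df$sample_id))
    stopf("duplicate sample ids in clinical table: %s",
          paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))
  if (anyNA(df$os_time) || any(df$os_time <= 0))
    stopf("os_time must be > 0; offending sample(s): %s",
          paste(df$sample_id[is.na(df$os_time) | df$os_time <= 0], collapse = ", "))
  if (anyNA(df$os_event) || !all(df$os_event %in% c(0, 1)))
    stopf("os_event must be 0 or 1; offending sample(s): %s",
          paste(df$sample_id[is.na(df$os_event) | !df$os_event %in% c(0, 1)], collapse = ", "))
  if ("purity" %in% colnames(df)) {
    p <- df$purity[!is.na(df$purity)]
    if (any(p < 0 | p > 1)) stopf("purity must lie in [0, 1]")
  }
  if ("ploidy" %in% colnames(df)) {
    p <- df$ploidy[!is.na(df$ploidy)]
    if (any(p <= 0)) stopf("ploidy must be > 0")
  }
  df
}

#' Write a clinical table to TSV
#' @param df validated clinical table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_clinical_table <- function(df, path) {
  validate_clinical_table(df)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a cell-type signature matrix
#'
#' LM22-style layout: gene ids in the first column, one column per cell
#' type, non-negative reference expression values.
#'
#' @param path path to a tab-separated file.
#' @return numeric matrix, genes x cell types.
#' @export
read_signature_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  genes <- as.character(df[[1L]])
  values <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(values) <- "double"
  rownames(values) <- genes
  validate_signature_matrix(values)
}

#' Validate a signature matrix
#' @param x numeric matrix, genes x cell types.
#' @return the validated matrix.
#' @export
validate_signature_matrix <- function(x) {
  if (!is.matrix(x) || !is.numeric(x)) stopf("signature matrix must be numeric")
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stopf("signature matrix needs gene rownames and cell-type colnames")
  if (anyDuplicated(rownames(x)) || anyDuplicated(colnames(x)))
    stopf("duplicate labels in signature matrix")
  if (ncol(x) < 2L) stopf("signature matrix needs >= 2 cell types")
  if (anyNA(x) || any(!is.finite(x)) || any(x < 0))
    stopf("signature values must be finite and >= 0")
  x
}

maf_required_cols <- c("Hugo_Symbol", "Tumor_Sample_Barcode", "Chromosome",
                       "Start_Position", "Reference_Allele", "Tumor_Seq_Allele2",
                       "Variant_Classification", "Variant_Type")

#' Read somatic mutations from a MAF file
#'
#' Parses the tab-separated Mutation Annotation Format columns the pipeline
#' consumes and returns a tidy mutation table. When an (optionally indexed)
#' FASTA is supplied, a 3-base reference context centred on each SNP is
#' extracted (1-based, inclusive, `pos-1..pos+1`). SNP records whose
#' reference allele disagrees with the FASTA base are rejected with a
#' warning; the rejection count is stored in `attr(, "n_rejected")`.
#'
#' @param path path to a MAF file (plain tab-separated text, `#` comments).
#' @param fasta optional path to a reference FASTA covering all SNP loci.
#' @return data.frame with columns sample_id, gene_symbol, chromosome,
#'   position, ref_allele, alt_allele, variant_classification,
#'   variant_type, ref_context.
#' @export
read_maf <- function(path, fasta = NULL) {
  # read everything as character: allele columns like "T" must never be
  # type-converted to logicals
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                          comment.char = "#", colClasses = "character")
  missing <- setdiff(maf_required_cols, colnames(df))
  if (length(missing))
    stopf("MAF missing required column(s): %s", paste(missing, collapse = ", "))
  pos <- suppressWarnings(as.numeric(df$Start_Position))
  if (anyNA(pos) || any(pos < 1) || any(pos != floor(pos)))
    stopf("malformed Start_Position in MAF '%s'", path)
  maf <- data.frame(
    sample_id = as.character(df$Tumor_Sample_Barcode),
    gene_symbol = as.character(df$Hugo_Symbol),
    chromosome = as.character(df$Chromosome),
    position = as.integer(pos),
    ref_allele = toupper(as.character(df$Reference_Allele)),
    alt_allele = toupper(as.character(df$Tumor_Seq_Allele2)),
    variant_classification = as.character(df$Variant_Classification),
    variant_type = as.character(df$Variant_Type),
    ref_context = if ("ref_context" %in% colnames(df))
      toupper(as.character(df$ref_context)) else NA_character_,
    stringsAsFactors = FALSE
  )
  maf <- validate_mutation_table(maf)
  n_rejected <- 0L
  if (!is.null(fasta)) {
    seqs <- read_fasta_seqs(fasta)
    need <- maf$variant_type == "SNP" & is.na(maf$ref_context)
    if (any(need)) {
      ctx <- extract_flank_context(seqs, maf$chromosome[need], maf$position[need])
      maf$ref_context[need] <- ctx
    }
    # reject SNPs whose reference allele disagrees with the FASTA base
    is_snp <- maf$variant_type == "SNP" & !is.na(maf$ref_context)
    center <- substr(maf$ref_context[is_snp],
                     (nchar(maf$ref_context[is_snp]) + 1L) %/% 2L,
                     (nchar(maf$ref_context[is_snp]) + 1L) %/% 2L)
    bad <- center != maf$ref_allele[is_snp]
    if (any(bad)) {
      n_rejected <- sum(bad)
      warnf("rejecting %d SNP record(s) whose ref_allele disagrees with the FASTA base",
            n_rejected)
      drop_idx <- which(is_snp)[bad]
      maf <- maf[-drop_idx, , drop = FALSE]
      rownames(maf) <- NULL
    }
  }
  attr(maf, "n_rejected") <- n_rejected
  maf
}

#' Validate a mutation table
#'
#' @param maf data.frame in the layout produced by [read_maf()].
#' @return the validated table.
#' @export
validate_mutation_table <- function(maf) {
  need <- c("sample_id", "gene_symbol", "chromosome", "position", "ref_allele",
            "alt_allele", "variant_classification", "variant_type")
  missing <- setdiff(need, colnames(maf))
  if (length(missing))
    stopf("mutation table missing column(s): %s", paste(missing, collapse = ", "))
  if (any(maf$position < 1)) stopf("MAF positions must be >= 1")
  snp <- maf$variant_type == "SNP"
  if (any(snp)) {
    if (any(nchar(maf$ref_allele[snp]) != 1L | nchar(maf$alt_allele[snp]) != 1L))
      stopf("SNP records must have single-base alleles")
    if (any(maf$ref_allele[snp] == maf$alt_allele[snp]))
      stopf("SNP records must have ref_allele != alt_allele")
    has_ctx <- snp & !is.na(maf$ref_context)
    if (any(has_ctx)) {
      n <- nchar(maf$ref_context[has_ctx])
      if (any(n %% 2L == 0L))
        stopf("ref_context must have odd length")
      center <- substr(maf$ref_context[has_ctx], (n + 1L) %/% 2L, (n + 1L) %/% 2L)
      if (any(center != maf$ref_allele[has_ctx]))
        stopf("ref_context center base must equal ref_allele")
    }
  }
  maf
}

#' Write a mutation table as a minimal MAF
#' @param maf validated mutation table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_maf <- function(maf, path) {
  out <- data.frame(
    Hugo_Symbol = maf$gene_symbol,
    Tumor_Sample_Barcode = maf$sample_id,
    Chromosome = maf$chromosome,
    Start_Position = maf$position,
    Reference_Allele = maf$ref_allele,
    Tumor_Seq_Allele2 = maf$alt_allele,
    Variant_Classification = maf$variant_classification,
    Variant_Type = maf$variant_type,
    ref_context = maf$ref_context,
    stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# read a FASTA into a named character vector of sequences
read_fasta_seqs <- function(fasta) {
  if (requireNamespace("Biostrings", quietly = TRUE)) {
    ss <- Biostrings::readDNAStringSet(fasta)
    seqs <- as.character(ss)
    names(seqs) <- sub("\\s.*$", "", names(ss))
    return(toupper(seqs))
  }
  # minimal fallback parser for plain FASTA
  lines <- readLines(fasta)
  hdr <- grepl("^>", lines)
  id <- sub("\\s.*$", "", sub("^>", "", lines[hdr]))
  grp <- cumsum(hdr)
  seqs <- vapply(split(lines[!hdr], grp[!hdr]), paste0, character(1), collapse = "")
  names(seqs) <- id
  toupper(seqs)
}

extract_flank_context <- function(seqs, chrom, pos, flank = 1L) {
  vapply(seq_along(pos), function(i) {
    s <- seqs[[chrom[i]]]
    if (is.null(s)) stopf("chromosome '%s' not in FASTA", chrom[i])
    lo <- pos[i] - flank
    hi <- pos[i] + flank
    if (lo < 1L || hi > nchar(s))
      stopf("position %d on '%s' too close to the sequence edge for context extraction",
            pos[i], chrom[i])
    substr(s, lo, hi)
  }, character(1))
}
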