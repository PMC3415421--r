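#' Export a simulated cohort to VCF + phenotype TSV
#'
#' Writes \code{<out_prefix>.vcf} (VCFv4.2, biallelic SNV records, GT-only
#' FORMAT; carriage 0/1 encoded as genotypes 0/0 vs 0/1) and
#' \code{<out_prefix>.pheno.tsv} (columns \code{sample_id}, \code{status},
#' \code{covariate}). INFO fields \code{DMG} and \code{SGN} record each
#' site's simulated damage class and effect sign.
#'
#' @param cohort an [simulate_cohort()] object.
#' @param out_prefix output path prefix.
#' @return invisibly, a character vector with the two file paths.
#' @seealso [read_vcf()], [read_pheno()]
#' @export
export_cohort <- function(cohort, out_prefix) {
  stopifnot(inherits(cohort, "rv_cohort"))
  geno <- cohort$genotypes
  n <- nrow(geno); p <- ncol(geno)
  stopifnot(p >= 1)
  vcf_path <- paste0(out_prefix, ".vcf")
  tsv_path <- paste0(out_prefix, ".pheno.tsv")
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=rvth",
    '##INFO=<ID=DMG,Number=1,Type=Integer,Description="Simulated damage class (0-3)">',
    '##INFO=<ID=SGN,Number=1,Type=Integer,Description="Simulated effect sign (+1/-1)">',
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", rownames(geno)), collapse = "\t"))
  gt <- matrix(c("0/0", "0/1")[geno + 1L], n, p)
  records <- vapply(seq_len(p), function(j) {
    paste(c("1", j, colnames(geno)[j], "A", "T", ".", "PASS",
            sprintf("DMG=%d;SGN=%d", cohort$gene$damage_class[j],
                    cohort$gene$sign[j]),
            "GT", gt[, j]), collapse = "\t")
  }, character(1))
  con <- file(vcf_path, "w")
  on.exit(close(con))
  writeLines(c(header, records), con)
  pheno <- data.frame(sample_id = rownames(geno), status = cohort$y,
                      covariate = cohort$covariate)
  utils::write.table(pheno, tsv_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(vcf = vcf_path, pheno = tsv_path))
}

#' Read a VCF into a genotype dataset
#'
#' Parses a biallelic VCF with \pkg{vcfR} and returns per-subject allele
#' dosages (0/1/2) together with carriage indicators and sample minor
#' allele frequencies. Missing genotypes are imputed as homozygous
#' reference (non-carrier) with a message reporting the count, unless
#' \code{missing_drop = TRUE}, in which case samples with any missing call
#' are excluded instead.
#'
#' @param path VCF file path (plain text or gzipped).
#' @param missing_drop drop samples with missing genotypes instead of
#'   imputing 0.
#' @return a list of class \code{genotype_dataset} with \code{sample_ids},
#'   \code{variant_ids}, \code{matrix} (subjects x variants dosage),
#'   \code{carriage_matrix} (dosage >= 1) and \code{mafs}.
#' @export
read_vcf <- function(path, missing_drop = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix)))                 # single-record VCF drops to vector
    fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  if (nrow(v@gt) == 0 || ncol(v@gt) < 2)
    stop("VCF has no genotype columns")
  alt <- fix[, "ALT"]
  multi <- grepl(",", alt, fixed = TRUE)
  if (any(multi))
    stop("multi-allelic records are not supported (variant ",
         paste(fix[multi, "ID"], collapse = ", "), ")")
  gt <- vcfR::extract.gt(v, element = "GT")
  ## count ALT alleles in the GT string; "." (missing) -> NA
  dose <- matrix(NA_integer_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  called <- !is.na(gt) & !grepl("\\.", gt)
  dose[called] <- vapply(strsplit(gt[called], "[/|]"),
                         function(a) sum(a != "0"), integer(1))
  n_missing <- sum(!called)
  if (missing_drop && n_missing > 0) {
    keep <- colSums(!called) == 0
    message(sum(!keep), " sample(s) with missing genotypes dropped")
    dose <- dose[, keep, drop = FALSE]
    called <- called[, keep, drop = FALSE]
  }
  ## MAF from called alleles only (diploid: 2 alleles per called genotype)
  called_n <- rowSums(called)
  alt_count <- rowSums(dose, na.rm = TRUE)
  mafs <- ifelse(called_n > 0, alt_count / (2 * called_n), 0)
  mafs <- pmin(mafs, 1 - mafs)
  if (any(called_n == 0))
    warning(sum(called_n == 0), " record(s) with no called genotypes; MAF set to 0")
  if (!missing_drop && n_missing > 0) {
    message(n_missing, " missing genotype call(s) imputed as non-carrier")
    dose[is.na(dose)] <- 0L
  }
  ids <- fix[, "ID"]
  ids[is.na(ids) | ids == "."] <- paste0(fix[, "CHROM"], ":", fix[, "POS"])[
    is.na(ids) | ids == "."]
  mat <- t(dose)                      # subjects x variants
  ## order-normalise so outputs depend on content, not file order
  ord_v <- order(ids)
  ord_s <- if (is.null(rownames(mat))) integer(0) else order(rownames(mat))
  mat <- mat[ord_s, ord_v, drop = FALSE]
  colnames(mat) <- ids[ord_v]
  structure(list(sample_ids = rownames(mat), variant_ids = ids[ord_v],
                 matrix = mat,
                 carriage_matrix = (mat >= 1L) + 0L,
                 mafs = unname(mafs[ord_v])),
            class = "genotype_dataset")
}

#' Read a phenotype/covariate table aligned to a genotype dataset
#'
#' Reads a tab-separated table with columns \code{sample_id} and
#' \code{status} (0/1); any additional numeric columns become covariates.
#' Rows are aligned to \code{sample_ids} by id, so file row order is
#' irrelevant.
#'
#' @param path TSV path with a header line.
#' @param sample_ids optional character vector giving the required sample
#'   order (e.g. \code{read_vcf(...)$sample_ids}); every id must be present
#'   exactly once.
#' @return list with \code{y} (integer 0/1), \code{covariates} (numeric
#'   matrix or NULL) and \code{sample_ids}.
#' @export
read_pheno <- function(path, sample_ids = NULL) {
  tab <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  if (!all(c("sample_id", "status") %in% names(tab)))
    stop("phenotype table must have 'sample_id' and 'status' columns")
  if (anyDuplicated(tab$sample_id))
    stop("duplicated sample_id: ",
         paste(unique(tab$sample_id[duplicated(tab$sample_id)]), collapse = ", "))
  if (!all(tab$status %in% c(0, 1)))
    stop("status must be binary 0/1; offending values: ",
         paste(unique(setdiff(tab$status, c(0, 1))), collapse = ", "))
  if (is.null(sample_ids)) sample_ids <- sort(tab$sample_id)
  miss <- setdiff(sample_ids, tab$sample_id)
  if (length(miss))
    stop("sample ids missing from phenotype table: ",
         paste(miss, collapse = ", "))
  tab <- tab[match(sample_ids, tab$sample_id), , drop = FALSE]
  covar_cols <- setdiff(names(tab), c("sample_id", "status"))
  covar_cols <- covar_cols[vapply(tab[covar_cols], is.numeric, logical(1))]
  covariates <- if (length(covar_cols))
    as.matrix(tab[covar_cols]) else NULL
  if (!is.null(covariates)) rownames(covariates) <- sample_ids
  list(y = as.integer(tab$status), covariates = covariates,
       sample_ids = sample_ids)
}

#' Read a simulation configuration from a YAML file
#'
#' Flat key-value YAML mirroring the [sim_config()] (and nested
#' [wright_params()]) argument names.
#'
#' @param path YAML file path.
#' @return an \code{rv_sim_config} object.
#' @export
read_sim_config <- function(path) {
  vals <- yaml::read_yaml(path)
  wright_keys <- intersect(names(vals), names(formals(wright_params)))
  cfg_keys <- intersect(names(vals), setdiff(names(formals(sim_config)),
                                             "wright"))
  unknown <- setdiff(names(vals), c(wright_keys, cfg_keys))
  if (length(unknown))
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
  wp <- do.call(wright_params, vals[wright_keys])
  do.call(sim_config, c(vals[cfg_keys], list(wright = wp)))
}
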