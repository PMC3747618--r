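#' Read a case-control genotype dataset
#'
#' Reads a binary genotype matrix plus phenotype from one of three
#' formats and returns a tibble ready for [fslr()]:
#'
#' * `tsv` - tab-separated, header row with SNP identifiers, one row per
#'   individual, the last column named `phenotype` (0 = control,
#'   1 = case), all genotype entries 0/1.
#' * `vcf` - a VCF file (read with the vcfR package); genotypes are
#'   converted to per-site mutant-allele dosages 0/1/2 and recoded to
#'   binary via `diploid_mode`. VCFs carry no phenotype, so supply
#'   `phenotype` as a 0/1 vector (one entry per sample).
#' * `plink_raw` - a PLINK `.raw` additive dosage table (columns FID IID
#'   PAT MAT SEX PHENOTYPE then one 0/1/2 dosage per SNP; phenotype coded
#'   1/2 is recoded to 0/1), recoded via `diploid_mode`.
#'
#' Diploid recoding follows the standard logic-regression convention:
#' `"pair"` expands each site into two binary variables, a dominant bit
#' (`<id>_d`, any mutant allele) and a recessive bit (`<id>_r`, homozygous
#' mutant); `"dominant"` and `"recessive"` keep one thresholded column per
#' site.
#'
#' @param path input file.
#' @param format `"tsv"`, `"vcf"` or `"plink_raw"`.
#' @param diploid_mode `"pair"`, `"dominant"` or `"recessive"`.
#' @param phenotype 0/1 vector for VCF input.
#' @return A tibble of binary SNP columns plus a `phenotype` column;
#'   column order of the source is preserved.
#' @export
read_dataset <- function(path, format = c("tsv", "vcf", "plink_raw"),
                         diploid_mode = c("pair", "dominant", "recessive"),
                         phenotype = NULL) {
  format <- match.arg(format)
  diploid_mode <- match.arg(diploid_mode)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  switch(format,
    tsv = read_tsv_dataset(path),
    vcf = read_vcf_dataset(path, diploid_mode, phenotype),
    plink_raw = read_raw_dataset(path, diploid_mode))
}

read_tsv_dataset <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  if (!"phenotype" %in% names(df)) {
    stop("tsv dataset must contain a 'phenotype' column", call. = FALSE)
  }
  for (nm in names(df)) {
    bad <- which(!df[[nm]] %in% c(0L, 1L))
    if (length(bad) > 0L) {
      stop("non-binary entry in column '", nm, "', row ", bad[1L],
           call. = FALSE)
    }
    df[[nm]] <- as.integer(df[[nm]])
  }
  tibble::as_tibble(df)
}

dosage_to_binary <- function(dos, ids, diploid_mode) {
  dos <- as.matrix(dos)
  if (diploid_mode == "pair") {
    out <- matrix(0L, nrow(dos), 2L * ncol(dos))
    out[, seq(1L, 2L * ncol(dos), by = 2L)] <- (dos >= 1L) * 1L
    out[, seq(2L, 2L * ncol(dos), by = 2L)] <- (dos == 2L) * 1L
    colnames(out) <- as.vector(rbind(paste0(ids, "_d"), paste0(ids, "_r")))
  } else if (diploid_mode == "dominant") {
    out <- (dos >= 1L) * 1L
    colnames(out) <- ids
  } else {
    out <- (dos == 2L) * 1L
    colnames(out) <- ids
  }
  storage.mode(out) <- "integer"
  out
}

read_vcf_dataset <- function(path, diploid_mode, phenotype) {
  if (is.null(phenotype)) {
    stop("VCF input carries no phenotype; supply `phenotype` as a 0/1 vector",
         call. = FALSE)
  }
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(vcf, element = "GT")
  # mutant-allele dosage; tolerate phased separators and missing entries
  dos <- apply(gt, c(1, 2), function(g) {
    if (is.na(g)) return(0L)
    sum(as.integer(strsplit(g, "[/|]")[[1]]) > 0L)
  })
  ids <- rownames(dos)
  if (is.null(ids)) ids <- paste0("snp", seq_len(nrow(dos)))
  dos <- t(dos)  # rows = samples
  if (length(phenotype) != nrow(dos)) {
    stop("phenotype length ", length(phenotype), " does not match ",
         nrow(dos), " VCF samples", call. = FALSE)
  }
  out <- tibble::as_tibble(as.data.frame(dosage_to_binary(dos, ids,
                                                          diploid_mode)))
  out$phenotype <- as.integer(phenotype)
  out
}

read_raw_dataset <- function(path, diploid_mode) {
  df <- utils::read.table(path, header = TRUE, check.names = FALSE)
  meta <- c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE")
  if (!all(meta %in% names(df))) {
    stop("not a PLINK .raw file: missing ",
         paste(setdiff(meta, names(df)), collapse = ", "), call. = FALSE)
  }
  ph <- df$PHENOTYPE
  ph <- if (all(ph %in% c(1L, 2L))) ph - 1L else as.integer(ph)
  if (!all(ph %in% c(0L, 1L))) {
    stop("PLINK phenotype is not case/control coded", call. = FALSE)
  }
  dos <- as.matrix(df[setdiff(names(df), meta)])
  out <- tibble::as_tibble(as.data.frame(dosage_to_binary(dos, colnames(dos),
                                                          diploid_mode)))
  out$phenotype <- ph
  out
}

#' Write a dataset (and its simulation truth) to disk
#'
#' Writes the genotype-plus-phenotype tibble as a TSV in the layout
#' [read_dataset()] reads back (SNP columns, then `phenotype`). For a
#' `sim_dataset`, a companion `<path>.truth.json` records the planted
#' expression, the causal indices, the configuration and the seed.
#'
#' @param x a data frame or `sim_dataset`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(x, path) {
  df <- if (inherits(x, "sim_dataset")) x$data else x
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (inherits(x, "sim_dataset")) {
    truth <- list(expression = format(x$truth_tree),
                  expression_json = jsonlite::fromJSON(
                    tree_to_json(x$truth_tree), simplifyVector = FALSE),
                  causal_indices = x$causal_indices,
                  config = unclass(x$config), seed = x$seed)
    jsonlite::write_json(truth, paste0(path, ".truth.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  invisible(path)
}

#' Write the report files of a fitted swarm
#'
#' Emits, under `dir`:
#' * `report.json` - the global-best model (serialized tree, coefficients,
#'   score), per-agent models, importance values, evaluation metrics (if
#'   given), and the echoed effective configuration and seed;
#' * `snps.tsv` - SNPs ranked by importance (ties broken by index);
#' * `interactions.tsv` - ranked SNP pair/triple co-occurrence counts.
#'
#' @param fit an `fslr_fit`.
#' @param evaluation optional tibble from [evaluate_fit()].
#' @param dir output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_report <- function(fit, evaluation = NULL, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  imp <- dplyr::arrange(fit$importance, dplyr::desc(.data$value), .data$snp)
  imp$snp_id <- fit$snp_ids[imp$snp]
  utils::write.table(imp[c("snp", "snp_id", "value", "prob")],
                     file.path(dir, "snps.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(fit$interactions, file.path(dir, "interactions.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  report <- list(
    best = list(tree = format(fit$best$tree),
                tree_json = jsonlite::fromJSON(tree_to_json(fit$best$tree),
                                               simplifyVector = FALSE),
                beta0 = fit$best$model$beta0, betas = fit$best$model$betas,
                score = fit$best$score, n_obs = fit$n_obs),
    agents = lapply(fit$agents, function(a) {
      list(id = a$id, tree = format(a$tree), score = a$score)
    }),
    selected = fit$selected,
    evaluation = if (!is.null(evaluation)) as.list(evaluation),
    iterations = fit$iterations, converged = fit$converged,
    config = unclass(fit$control),
    seed = if (is.null(fit$seed)) NA else fit$seed)
  jsonlite::write_json(report, file.path(dir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}

#' Structural validation of a written report
#'
#' Lightweight schema check of `report.json`: required fields present with
#' the expected types. Returns `TRUE` invisibly or stops with the first
#' violation.
#'
#' @param path path to a `report.json`.
#' @export
validate_report <- function(path) {
  rep <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  need <- c("best", "agents", "selected", "iterations", "converged",
            "config", "seed")
  miss <- setdiff(need, names(rep))
  if (length(miss)) stop("report missing fields: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  stopifnot(is.character(rep$best$tree), is.numeric(rep$best$score),
            length(rep$agents) >= 1, is.numeric(rep$iterations),
            is.logical(rep$converged), is.list(rep$config))
  invisible(TRUE)
}
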