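#' Assemble a run configuration
#'
#' Collects the file paths and column mappings for an end-to-end run.
#'
#' @param methylation path to the methylation TSV (first column probe id,
#'   optional chrom/pos columns, then one column per sample).
#' @param phenotypes path to the phenotype CSV.
#' @param annotation path to the gene annotation (BED or GFF3).
#' @param blacklist optional path to a probe blacklist (one id per line).
#' @param output_dir directory for result files.
#' @param exposure,outcome phenotype column names.
#' @param family outcome family, `"gaussian"` or `"binomial"`.
#' @param covariates adjustment covariate columns (including the
#'   cell-proportion columns).
#' @param case_column optional binary column defining cases/controls for the
#'   per-CpG differential count; defaults to the outcome when binary, else
#'   the exposure.
#' @param upstream promoter extension in bp.
#' @param fdr_level FDR threshold reported in the run log.
#' @param min_cpgs minimum CpGs per testable gene.
#' @param recal_min_genes minimum genes for empirical-null recalibration.
#' @param seed integer seed recorded with the run.
#' @return a list of class `"run_config"`.
#' @export
run_config <- function(methylation, phenotypes, annotation, blacklist = NULL,
                       output_dir = "results",
                       exposure = "exposure", outcome = "outcome",
                       family = c("gaussian", "binomial"),
                       covariates = c("age", "sex", "bmi", "CD4T", "CD8T",
                                      "Bcell", "NK", "Mono"),
                       case_column = NULL,
                       upstream = 500L, fdr_level = 0.05, min_cpgs = 1L,
                       recal_min_genes = 1000L, seed = 1L) {
  family <- match.arg(family)
  if (fdr_level <= 0 || fdr_level >= 1) stop("'fdr_level' must lie in (0, 1)")
  if (upstream < 0) stop("'upstream' must be >= 0")
  structure(list(methylation = methylation, phenotypes = phenotypes,
                 annotation = annotation, blacklist = blacklist,
                 output_dir = output_dir, exposure = exposure,
                 outcome = outcome, family = family,
                 covariates = covariates, case_column = case_column,
                 upstream = as.integer(upstream), fdr_level = fdr_level,
                 min_cpgs = as.integer(min_cpgs),
                 recal_min_genes = as.integer(recal_min_genes),
                 seed = as.integer(seed)),
            class = "run_config")
}

## Listwise-complete sample filter over the analysis columns, with a log of
## per-variable missingness.
drop_missing_samples <- function(phen, columns) {
  miss <- vapply(columns, function(cl) sum(is.na(phen[[cl]])), 0L)
  keep <- stats::complete.cases(phen[, columns, drop = FALSE])
  if (any(miss > 0))
    message("dropping ", sum(!keep), " sample(s) with missing values (",
            paste(sprintf("%s: %d", names(miss[miss > 0]), miss[miss > 0]),
                  collapse = ", "), ")")
  list(phenotypes = phen[keep, , drop = FALSE], missing = miss,
       dropped = sum(!keep))
}

#' Gene-centric mediation scan over an in-memory study
#'
#' Runs both path tests for every gene in the gene map, composes the
#' genome-wide sub-null weights from the two p-value series, forms the
#' weighted composite-null mediation p-value, recalibrates it against the
#' empirical null when enough genes are available, and attaches
#' Benjamini-Hochberg q-values.  Genes failing any stage carry `NA` and a
#' reason instead of aborting the scan.
#'
#' @param phenotypes per-sample table holding exposure, outcome and
#'   covariates.
#' @param methylation a [methylation_matrix()] on the M-value scale.
#' @param gene_map a [map_cpgs_to_genes()] result (or the `gene_map` of a
#'   [simulate_study()]).
#' @param exposure,outcome,covariates,case_column column names in
#'   `phenotypes`.
#' @param family outcome family.
#' @param min_cpgs minimum member CpGs for a gene to be tested.
#' @param fdr_level FDR threshold used for the per-CpG differential count.
#' @param recal_min_genes minimum genes for recalibration.
#' @param compute_direction set `FALSE` to skip per-CpG direction fits.
#' @return a data.frame, one row per gene (columns `gene`, `chrom`, `lower`,
#'   `upper`, `m`, `m_star`, `direction_alpha`, `p_alpha`,
#'   `direction_beta`, `p_beta`, `p_mediation`, `q_value`, `method_alpha`,
#'   `method_beta`, `reason`), with the composite weights and alignment log
#'   in attributes.
#' @export
mediation_scan <- function(phenotypes, methylation, gene_map,
                           exposure = "exposure", outcome = "outcome",
                           covariates = c("age", "sex", "bmi", "CD4T",
                                          "CD8T", "Bcell", "NK", "Mono"),
                           family = c("gaussian", "binomial"),
                           case_column = NULL,
                           min_cpgs = 1L, fdr_level = 0.05,
                           recal_min_genes = 1000L,
                           compute_direction = TRUE) {
  family <- match.arg(family)
  stopifnot(inherits(methylation, "methylation_matrix"))
  if (identical(methylation$scale, "beta"))
    stop("methylation must be on the M-value scale; apply beta_to_mvalue first")
  if (nrow(gene_map) == 0L)
    stop("zero testable genes after preprocessing")
  cols <- c(exposure, outcome, covariates)
  missing_cols <- setdiff(cols, names(phenotypes))
  if (length(missing_cols))
    stop("phenotype column(s) not found: ", paste(missing_cols, collapse = ", "))

  ## sample alignment by id intersection, phenotype order
  common <- intersect(phenotypes$sample_id, methylation$sample_ids)
  if (length(common) < 10L)
    stop("fewer than 10 samples shared between phenotypes and methylation")
  phen <- phenotypes[match(common, phenotypes$sample_id), , drop = FALSE]
  dm <- drop_missing_samples(phen, cols)
  phen <- dm$phenotypes
  vals <- methylation$values[, match(phen$sample_id, methylation$sample_ids),
                             drop = FALSE]
  align_log <- c(n_phenotypes = nrow(phenotypes),
                 n_methylation = length(methylation$sample_ids),
                 n_common = length(common), n_dropped_missing = dm$dropped,
                 n_analyzed = nrow(phen))

  X <- phen[[exposure]]
  Y <- phen[[outcome]]
  C <- as.matrix(phen[, covariates, drop = FALSE])
  if (!all(X %in% c(0, 1)) || length(unique(X)) < 2L)
    stop("exposure must be binary 0/1 with both classes present")
  is_binary_y <- all(Y %in% c(0, 1))
  if (family == "gaussian" && is_binary_y)
    warning("outcome looks binary but family is gaussian; ",
            "continuing with the configured family")
  if (family == "binomial" && !is_binary_y)
    stop("binomial family requires a 0/1 outcome")

  nf_alpha <- fit_null_model(X, C, "binomial")
  nf_beta <- fit_null_model(Y, cbind(X = X, C), family)

  ## per-CpG differential count between cases and controls
  status <- if (!is.null(case_column)) phen[[case_column]] else
    if (is_binary_y) Y else X
  diff_tab <- cpg_differential_test(vals, status, C)
  sig_probes <- diff_tab$probe_id[!is.na(diff_tab$q) & diff_tab$q < fdr_level]

  G <- nrow(gene_map)
  res <- data.frame(gene = gene_map$gene, chrom = gene_map$chrom,
                    lower = gene_map$start, upper = gene_map$end,
                    m = NA_integer_, m_star = NA_integer_,
                    direction_alpha = NA_character_, p_alpha = NA_real_,
                    direction_beta = NA_character_, p_beta = NA_real_,
                    p_mediation = NA_real_, q_value = NA_real_,
                    method_alpha = NA_character_,
                    method_beta = NA_character_,
                    reason = NA_character_, stringsAsFactors = FALSE)
  for (g in seq_len(G)) {
    probes <- gene_map$probes[[g]]
    idx <- match(probes, rownames(vals))
    idx <- idx[!is.na(idx)]
    res$m[g] <- length(idx)
    res$m_star[g] <- sum(rownames(vals)[idx] %in% sig_probes)
    if (length(idx) < min_cpgs) {
      res$reason[g] <- "fewer member CpGs than min_cpgs"
      next
    }
    M <- t(vals[idx, , drop = FALSE])
    ra <- tryCatch(test_exposure_mediators(X, M, C, null_fit = nf_alpha),
                   error = function(e) conditionMessage(e))
    rb <- tryCatch(test_mediators_outcome(Y, M, X, C, family = family,
                                          null_fit = nf_beta,
                                          compute_direction = compute_direction),
                   error = function(e) conditionMessage(e))
    if (is.character(ra)) { res$reason[g] <- paste("alpha path:", ra); next }
    if (is.character(rb)) { res$reason[g] <- paste("beta path:", rb); next }
    res$p_alpha[g] <- ra$p
    res$p_beta[g] <- rb$p
    res$direction_alpha[g] <- ra$direction
    res$direction_beta[g] <- rb$direction
    res$method_alpha[g] <- ra$method
    res$method_beta[g] <- rb$method
  }

  ok <- !is.na(res$p_alpha) & !is.na(res$p_beta)
  if (!any(ok))
    stop("no gene produced both path p-values")
  pi0_a <- estimate_null_proportion(pvals_to_z(res$p_alpha[ok]))
  pi0_b <- estimate_null_proportion(pvals_to_z(res$p_beta[ok]))
  w <- compose_weights(as.numeric(pi0_a), as.numeric(pi0_b))
  res$p_mediation[ok] <- dact_statistic(res$p_alpha[ok], res$p_beta[ok], w)
  res$p_mediation <- efron_recalibrate(res$p_mediation,
                                       min_genes = recal_min_genes)
  recal_fit <- attr(res$p_mediation, "null_fit")
  res$p_mediation <- as.vector(res$p_mediation)
  res$q_value <- bh_fdr(res$p_mediation)

  attr(res, "weights") <- w
  attr(res, "alignment") <- align_log
  attr(res, "recalibration") <- recal_fit
  attr(res, "n_tested") <- sum(ok)
  res
}

#' Run the full mediation scan from files on disk
#'
#' Reads the configured inputs, transforms beta values to M-values when
#' needed, applies the probe filters, builds the promoter-extended gene
#' map, runs [mediation_scan()] and writes the result files.
#'
#' @param config a [run_config()].
#' @return the gene-level result table, invisibly; files are written to
#'   `config$output_dir` by [write_results()].
#' @export
run_mediation_scan <- function(config) {
  stopifnot(inherits(config, "run_config"))
  meth <- read_methylation(config$methylation)
  if (identical(meth$scale, "beta"))
    meth <- methylation_matrix(beta_to_mvalue(meth$values),
                               chrom = meth$chrom, pos = meth$pos,
                               probe_ids = meth$probe_ids,
                               sample_ids = meth$sample_ids, scale = "M")
  blk <- if (is.null(config$blacklist)) character() else
    read_blacklist(config$blacklist)
  flt <- filter_probes(meth, blk)
  phen <- read_phenotypes(config$phenotypes)
  ann <- read_annotation(config$annotation)
  gene_map <- map_cpgs_to_genes(ann, flt$matrix, upstream = config$upstream)
  if (nrow(gene_map) == 0L)
    stop("zero testable genes; filter report: ",
         paste(sprintf("%s=%d", names(flt$report), flt$report), collapse = ", "))
  res <- mediation_scan(phen, flt$matrix, gene_map,
                        exposure = config$exposure, outcome = config$outcome,
                        covariates = config$covariates,
                        family = config$family,
                        case_column = config$case_column,
                        min_cpgs = config$min_cpgs,
                        fdr_level = config$fdr_level,
                        recal_min_genes = config$recal_min_genes)
  attr(res, "filter_report") <- flt$report
  attr(res, "n_genes_annotation") <- nrow(ann)
  write_results(res, config)
  invisible(res)
}

#' Total-effect tests for each configured outcome
#'
#' One row per outcome with the exposure coefficient, its Wald interval and
#' p-value (log-odds scale for binomial outcomes, with the odds ratio
#' alongside), in the layout of a total-effect summary table.
#'
#' @param phenotypes per-sample table.
#' @param exposure exposure column name.
#' @param outcomes named character vector mapping outcome column names to
#'   families, e.g. `c(bdi = "gaussian", ptsd = "binomial")`.
#' @param covariates covariate column names.
#' @return data.frame with `outcome`, `family`, `estimate`, `se`, `ci_low`,
#'   `ci_high`, `p`, `odds_ratio`.
#' @export
run_total_effects <- function(phenotypes, exposure = "exposure",
                              outcomes = c(outcome = "gaussian"),
                              covariates = c("age", "sex", "bmi", "CD4T",
                                             "CD8T", "Bcell", "NK", "Mono")) {
  missing_cols <- setdiff(c(exposure, names(outcomes), covariates),
                          names(phenotypes))
  if (length(missing_cols))
    stop("phenotype column(s) not found: ", paste(missing_cols, collapse = ", "))
  rows <- lapply(names(outcomes), function(oc) {
    fam <- outcomes[[oc]]
    dm <- drop_missing_samples(phenotypes, c(exposure, oc, covariates))
    ph <- dm$phenotypes
    yv <- ph[[oc]]
    if (fam == "gaussian" && all(yv %in% c(0, 1)))
      warning("outcome '", oc, "' looks binary but family is gaussian; ",
              "continuing with the configured family")
    te <- total_effect(yv, ph[[exposure]],
                       as.matrix(ph[, covariates, drop = FALSE]),
                       family = fam)
    data.frame(outcome = oc, family = fam, estimate = te$estimate,
               se = te$se, ci_low = te$ci_low, ci_high = te$ci_high,
               p = te$p,
               odds_ratio = if (fam == "binomial") te$odds_ratio else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Write scan results, run log and config echo to disk
#'
#' Writes `gene_mediation.tsv` (one row per gene in the documented column
#' order), `run_log.txt` (filter counts, sample alignment, estimated
#' sub-null proportions) and `config_echo.txt`.
#'
#' @param table a [mediation_scan()] result.
#' @param config a [run_config()] (its `output_dir` is used).
#' @return invisibly, the paths written.
#' @export
write_results <- function(table, config) {
  dir <- config$output_dir
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cols <- c("gene", "chrom", "lower", "upper", "m", "m_star",
            "direction_alpha", "p_alpha", "direction_beta", "p_beta",
            "p_mediation", "q_value", "method_alpha", "method_beta",
            "reason")
  tab_path <- file.path(dir, "gene_mediation.tsv")
  data.table::fwrite(data.table::as.data.table(table[, cols, drop = FALSE]),
                     tab_path, sep = "\t", na = "NA")

  w <- attr(table, "weights")
  al <- attr(table, "alignment")
  fr <- attr(table, "filter_report")
  log_lines <- c(
    sprintf("genes_in_output: %d", nrow(table)),
    sprintf("genes_tested: %s", attr(table, "n_tested")),
    if (!is.null(attr(table, "n_genes_annotation")))
      sprintf("genes_in_annotation: %d", attr(table, "n_genes_annotation")),
    if (!is.null(fr)) sprintf("filter_%s: %d", names(fr), fr),
    if (!is.null(al)) sprintf("align_%s: %d", names(al), al),
    if (!is.null(w)) c(sprintf("pi0_alpha: %.6f", w$pi0_alpha),
                       sprintf("pi0_beta: %.6f", w$pi0_beta),
                       sprintf("pi00: %.6f", w$pi00),
                       sprintf("pi01: %.6f", w$pi01),
                       sprintf("pi10: %.6f", w$pi10)))
  log_path <- file.path(dir, "run_log.txt")
  writeLines(log_lines, log_path)

  cfg <- config[setdiff(names(config), NULL)]
  echo <- vapply(names(cfg), function(k)
    sprintf("%s: %s", k, paste(format(cfg[[k]]), collapse = ",")), "")
  cfg_path <- file.path(dir, "config_echo.txt")
  writeLines(echo, cfg_path)
  invisible(c(table = tab_path, log = log_path, config = cfg_path))
}
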