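#' Cohort configuration for the synthetic-data generator
#'
#' Default marginals emulate a trauma-exposed adult cohort profiled on a
#' methylation array: age and BMI are Gaussian, sex is Bernoulli, the five
#' measured blood-cell proportions (CD4T, CD8T, B cell, NK, monocyte) are a
#' Dirichlet draw over six compartments with the granulocyte share dropped,
#' and the binary exposure (dichotomised childhood-maltreatment score) is
#' drawn from a logistic model on the covariates so that the design is
#' confounded by construction.
#'
#' @param age_mean,age_sd,bmi_mean,bmi_sd Gaussian moments for age (years)
#'   and BMI (kg/m^2).
#' @param sex_p_female probability of female sex (`sex = 1`).
#' @param cell_conc named positive Dirichlet concentrations over six blood
#'   cell compartments; the first five are kept as covariates.
#' @param exposure_intercept intercept of the logistic exposure model, on the
#'   log-odds scale; the default targets a 43.7% exposure prevalence.
#' @param exposure_coef named log-odds coefficients on the standardized
#'   covariates (`age`, `sex`, `bmi`) linking them to exposure probability.
#'
#' @return a list consumed by [simulate_cohort()].
#' @export
cohort_config <- function(age_mean = 41.5, age_sd = 13.2,
                          sex_p_female = 0.704,
                          bmi_mean = 32.2, bmi_sd = 8.4,
                          cell_conc = c(CD4T = 7.5, CD8T = 4, Bcell = 2.5,
                                        NK = 2, Mono = 4, Gran = 30),
                          exposure_intercept = stats::qlogis(0.437),
                          exposure_coef = c(age = 0.2, sex = -0.1, bmi = 0.1)) {
  if (any(!is.finite(cell_conc)) || any(cell_conc <= 0))
    stop("Dirichlet concentrations must all be positive")
  if (length(cell_conc) < 6L)
    stop("'cell_conc' needs six compartments (five kept + granulocytes)")
  list(age_mean = age_mean, age_sd = age_sd, sex_p_female = sex_p_female,
       bmi_mean = bmi_mean, bmi_sd = bmi_sd, cell_conc = cell_conc,
       exposure_intercept = exposure_intercept, exposure_coef = exposure_coef)
}

#' Simulate a cohort phenotype table
#'
#' Draws `n` samples of covariates and a binary exposure from the logistic
#' confounding model described in [cohort_config()].
#'
#' @param n number of samples (at least 10).
#' @param config a [cohort_config()] list.
#' @param seed integer RNG seed; identical seeds give identical tables.
#'
#' @return a data.frame with columns `sample_id`, `age`, `sex` (0/1, 1 =
#'   female), `bmi`, the five cell proportions, and `exposure` (0/1).
#' @export
simulate_cohort <- function(n, config = cohort_config(), seed = 1L) {
  if (!is.numeric(n) || length(n) != 1L || n < 10)
    stop("'n' must be a single count >= 10")
  n <- as.integer(n)
  if (any(config$cell_conc <= 0)) stop("Dirichlet concentrations must be positive")
  set.seed(as.integer(seed))
  age <- stats::rnorm(n, config$age_mean, config$age_sd)
  sex <- stats::rbinom(n, 1L, config$sex_p_female)
  bmi <- stats::rnorm(n, config$bmi_mean, config$bmi_sd)
  conc <- config$cell_conc
  g <- matrix(stats::rgamma(n * length(conc), shape = rep(conc, each = n)),
              nrow = n)
  props <- g / rowSums(g)
  colnames(props) <- names(conc)
  cells <- props[, seq_len(5L), drop = FALSE]

  cf <- config$exposure_coef
  eta <- rep(config$exposure_intercept, n)
  eta <- eta + cf[["age"]] * (age - config$age_mean) / config$age_sd
  eta <- eta + cf[["sex"]] * (sex - config$sex_p_female)
  eta <- eta + cf[["bmi"]] * (bmi - config$bmi_mean) / config$bmi_sd
  exposure <- stats::rbinom(n, 1L, stats::plogis(eta))

  out <- data.frame(sample_id = sprintf("S%04d", seq_len(n)),
                    age = age, sex = sex, bmi = bmi,
                    stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(cells))
  out$exposure <- exposure
  out
}

## Default covariate columns of a simulated phenotype table.
default_covariates <- function() {
  c("age", "sex", "bmi", "CD4T", "CD8T", "Bcell", "NK", "Mono")
}

## Column-standardized covariate matrix used by the generator's linear
## predictors (analysis-side adjustment uses the raw columns).
standardized_covariates <- function(phenotypes,
                                    covariates = default_covariates()) {
  m <- as.matrix(phenotypes[, covariates, drop = FALSE])
  sds <- apply(m, 2L, stats::sd)
  sds[sds == 0] <- 1
  sweep(sweep(m, 2L, colMeans(m)), 2L, sds, "/")
}

#' Define a per-gene simulation scenario
#'
#' A scenario fixes one cell of the composite-null layout: `H00` (no path
#' active), `H01` (outcome path only), `H10` (exposure path only), `H11`
#' (both paths active, i.e. mediation).  Per-CpG effects are random-effect
#' draws, \eqn{\alpha_k \sim N(0, \tau_\alpha^2)} and
#' \eqn{\beta_k \sim N(0, \tau_\beta^2)}, matching the mixed-model
#' formulation of the path tests; an optional sparse variant zeroes a
#' fraction of them.
#'
#' @param label one of `"H00"`, `"H01"`, `"H10"`, `"H11"`.
#' @param n sample count.
#' @param K CpGs per gene.
#' @param rho within-gene CpG correlation in `[0, 1)`.
#' @param tau_alpha_sq,tau_beta_sq variances of the per-CpG exposure and
#'   outcome effects; `NULL` picks the label-consistent default (0.25 on an
#'   active path, 0 on an inactive one).  Values inconsistent with `label`
#'   are an error.
#' @param c_prime direct exposure effect on the outcome linear predictor.
#' @param sigma_m_sq,sigma_y_sq CpG and outcome residual variances
#'   (M-value^2 and outcome^2 units).
#' @param outcome_family `"gaussian"` or `"binomial"`.
#' @param corstr residual correlation structure of the CpG block:
#'   exchangeable (default) or AR(1).
#' @param sparsity_alpha,sparsity_beta fraction of CpGs with nonzero effect
#'   on each path (1 = dense default).
#' @param covar_effect_sd standard deviation of the per-CpG loadings on the
#'   standardized covariates (methylation confounding).
#' @param seed integer RNG seed for the gene draw.
#'
#' @return a list of class `"sim_scenario"`.
#' @export
sim_scenario <- function(label = c("H00", "H01", "H10", "H11"),
                         n = 352L, K = 16L, rho = 0.5,
                         tau_alpha_sq = NULL, tau_beta_sq = NULL,
                         c_prime = 0, sigma_m_sq = 1, sigma_y_sq = 1,
                         outcome_family = c("gaussian", "binomial"),
                         corstr = c("exchangeable", "ar1"),
                         sparsity_alpha = 1, sparsity_beta = 1,
                         covar_effect_sd = 0.05, seed = 1L) {
  label <- match.arg(label)
  outcome_family <- match.arg(outcome_family)
  corstr <- match.arg(corstr)
  if (!is.numeric(rho) || rho < 0 || rho >= 1)
    stop("'rho' must lie in [0, 1)")
  alpha_on <- label %in% c("H10", "H11")
  beta_on  <- label %in% c("H01", "H11")
  if (is.null(tau_alpha_sq)) tau_alpha_sq <- if (alpha_on) 0.25 else 0
  if (is.null(tau_beta_sq))  tau_beta_sq  <- if (beta_on)  0.25 else 0
  if (tau_alpha_sq < 0 || tau_beta_sq < 0 || sigma_m_sq < 0 || sigma_y_sq < 0)
    stop("variances must be non-negative")
  if (alpha_on != (tau_alpha_sq > 0) || beta_on != (tau_beta_sq > 0))
    stop(sprintf("label %s is inconsistent with tau_alpha_sq=%g, tau_beta_sq=%g",
                 label, tau_alpha_sq, tau_beta_sq))
  structure(list(label = label, n = as.integer(n), K = as.integer(K),
                 rho = rho, tau_alpha_sq = tau_alpha_sq,
                 tau_beta_sq = tau_beta_sq, c_prime = c_prime,
                 sigma_m_sq = sigma_m_sq, sigma_y_sq = sigma_y_sq,
                 outcome_family = outcome_family, corstr = corstr,
                 sparsity_alpha = sparsity_alpha,
                 sparsity_beta = sparsity_beta,
                 covar_effect_sd = covar_effect_sd,
                 seed = as.integer(seed)),
            class = "sim_scenario")
}

## Re-label a scenario, replacing the path variances by the label-consistent
## pattern while keeping the active-path magnitudes.
relabel_scenario <- function(scenario, label, seed = scenario$seed) {
  ta <- if (label %in% c("H10", "H11"))
    (if (scenario$tau_alpha_sq > 0) scenario$tau_alpha_sq else 0.25) else 0
  tb <- if (label %in% c("H01", "H11"))
    (if (scenario$tau_beta_sq > 0) scenario$tau_beta_sq else 0.25) else 0
  s <- scenario
  s$label <- label; s$tau_alpha_sq <- ta; s$tau_beta_sq <- tb
  s$seed <- as.integer(seed)
  s
}

## Mean-zero residual CpG block with the scenario's correlation structure.
gene_residuals <- function(n, K, rho, sigma_m_sq, corstr) {
  sd_m <- sqrt(sigma_m_sq)
  if (corstr == "exchangeable") {
    shared <- stats::rnorm(n)
    E <- sqrt(rho) * shared %o% rep(1, K) +
      sqrt(1 - rho) * matrix(stats::rnorm(n * K), n, K)
    sd_m * E
  } else {
    R <- rho^abs(outer(seq_len(K), seq_len(K), "-"))
    Z <- matrix(stats::rnorm(n * K), n, K)
    sd_m * Z %*% chol(R)
  }
}

#' Simulate one gene's CpG block and outcome contribution
#'
#' Generates an `n x K` M-value block `M = C Gamma + X alpha' + E` with
#' per-CpG random effects drawn from the scenario and residual rows drawn
#' from the scenario's correlation structure, plus the gene's contribution
#' `M beta` to the outcome linear predictor.
#'
#' @param scenario a [sim_scenario()].
#' @param phenotypes a phenotype table with an `exposure` column, as from
#'   [simulate_cohort()].
#'
#' @return list with `M` (n x K matrix), `y_contrib` (length-n vector on the
#'   linear-predictor scale), `alpha` and `beta` (length-K effect vectors).
#' @export
simulate_gene <- function(scenario, phenotypes) {
  stopifnot(inherits(scenario, "sim_scenario"))
  if (!"exposure" %in% names(phenotypes))
    stop("'phenotypes' must contain an 'exposure' column")
  n <- nrow(phenotypes)
  if (n != scenario$n)
    stop(sprintf("phenotype rows (%d) do not match scenario n (%d)",
                 n, scenario$n))
  K <- scenario$K
  set.seed(scenario$seed)
  alpha <- stats::rnorm(K, 0, sqrt(scenario$tau_alpha_sq))
  beta  <- stats::rnorm(K, 0, sqrt(scenario$tau_beta_sq))
  if (scenario$sparsity_alpha < 1)
    alpha <- alpha * stats::rbinom(K, 1L, scenario$sparsity_alpha)
  if (scenario$sparsity_beta < 1)
    beta <- beta * stats::rbinom(K, 1L, scenario$sparsity_beta)

  Cstd <- standardized_covariates(phenotypes)
  Gamma <- matrix(stats::rnorm(ncol(Cstd) * K, 0, scenario$covar_effect_sd),
                  ncol(Cstd), K)
  E <- gene_residuals(n, K, scenario$rho, scenario$sigma_m_sq, scenario$corstr)
  X <- phenotypes$exposure
  M <- Cstd %*% Gamma + X %o% alpha + E
  list(M = M, y_contrib = drop(M %*% beta), alpha = alpha, beta = beta)
}

## Documented counter scheme: gene g of a study with master seed s draws
## from seed (s*1000003 + g*7919) mod (2^31-1), so any gene is reproducible
## in isolation.  All terms stay inside exact double-precision integers.
derive_gene_seed <- function(master, g) {
  as.integer((as.double(master) %% 2147483647 * 1000003 + g * 7919) %% 2147483647)
}

#' Simulate a full gene-centric mediation study
#'
#' Assigns composite-null labels to `G` genes multinomially, simulates every
#' gene's CpG block from `base_scenario` under its label, lays the genes out
#' on chromosomes 1-22, and assembles the outcome once per sample as
#' covariate effects + `c_prime * X` + the sum of all genes' `M beta`
#' contributions plus noise (Gaussian family) or a Bernoulli draw of the
#' inverse-logit linear predictor (binomial family).  With
#' `isolated = TRUE` each gene additionally receives its own outcome built
#' from its contribution alone, so path tests can be studied without
#' between-gene leakage.
#'
#' @param G gene count (>= 1).
#' @param scenario_mix named proportions over labels, summing to 1.
#' @param base_scenario a [sim_scenario()] providing n, K and the active-path
#'   effect magnitudes.
#' @param seed master seed; per-gene streams are derived by a documented
#'   counter scheme so identical seeds give bit-identical studies.
#' @param covariate_config a [cohort_config()] for the cohort draw.
#' @param isolated also return an `n x G` matrix of per-gene outcomes.
#' @param y_covar_coef named coefficients of the standardized covariates in
#'   the outcome linear predictor (outcome-side confounding).
#'
#' @return a list of class `"sim_study"`: `phenotypes` (with `outcome`
#'   column), `methylation` (a [methylation_matrix()] on the M-value scale),
#'   `gene_map`, `truth` (per-gene label, effect vectors, aggregate effect
#'   sums), and optionally `outcomes_isolated`.
#' @export
simulate_study <- function(G, scenario_mix, base_scenario, seed = 1L,
                           covariate_config = cohort_config(),
                           isolated = FALSE,
                           y_covar_coef = c(age = 0.2, sex = 0.2, bmi = 0.1)) {
  if (!is.numeric(G) || G < 1) stop("'G' must be >= 1")
  G <- as.integer(G)
  labs <- c("H00", "H01", "H10", "H11")
  if (is.null(names(scenario_mix)) || !all(names(scenario_mix) %in% labs))
    stop("'scenario_mix' must be named with labels among H00, H01, H10, H11")
  if (abs(sum(scenario_mix) - 1) > 1e-8)
    stop("'scenario_mix' must sum to 1")
  stopifnot(inherits(base_scenario, "sim_scenario"))
  seed <- as.integer(seed)

  phen <- simulate_cohort(base_scenario$n, covariate_config, seed = seed)
  n <- nrow(phen)
  set.seed(derive_gene_seed(seed, 0L))
  gene_labels <- sample(names(scenario_mix), G, replace = TRUE,
                        prob = scenario_mix)

  K <- base_scenario$K
  M_all <- matrix(NA_real_, n, G * K)
  contrib <- matrix(0, n, G)
  alpha_l <- vector("list", G)
  beta_l <- vector("list", G)
  for (g in seq_len(G)) {
    scen_g <- relabel_scenario(base_scenario, gene_labels[g],
                               seed = derive_gene_seed(seed, g))
    sim <- simulate_gene(scen_g, phen)
    M_all[, (g - 1L) * K + seq_len(K)] <- sim$M
    contrib[, g] <- sim$y_contrib
    alpha_l[[g]] <- sim$alpha
    beta_l[[g]] <- sim$beta
  }

  ## genomic layout: genes tile chromosomes 1-22; probes every 100 bp in the
  ## gene body
  genes <- sprintf("G%05d", seq_len(G))
  chrom_g <- paste0("chr", ((seq_len(G) - 1L) %% 22L) + 1L)
  slot <- (seq_len(G) - 1L) %/% 22L
  start_g <- 100000L + slot * 50000L
  end_g <- start_g + (K - 1L) * 100L
  strand_g <- ifelse(seq_len(G) %% 2L == 1L, "+", "-")
  probe_ids <- sprintf("cg%07d", seq_len(G * K))
  probe_chrom <- rep(chrom_g, each = K)
  probe_pos <- rep(start_g, each = K) + rep(seq_len(K) - 1L, G) * 100L

  meth <- methylation_matrix(t(M_all), chrom = probe_chrom, pos = probe_pos,
                             probe_ids = probe_ids,
                             sample_ids = phen$sample_id, scale = "M")
  gene_map <- data.frame(gene = genes, chrom = chrom_g, strand = strand_g,
                         start = start_g, end = end_g, K = K,
                         stringsAsFactors = FALSE)
  gene_map$probes <- split(probe_ids, rep(seq_len(G), each = K))

  Cstd <- standardized_covariates(phen)
  lp_cov <- drop(Cstd[, names(y_covar_coef), drop = FALSE] %*% y_covar_coef)
  lp_base <- lp_cov + base_scenario$c_prime * phen$exposure
  set.seed(derive_gene_seed(seed, G + 1L))
  noise <- stats::rnorm(n, 0, sqrt(base_scenario$sigma_y_sq))
  lp <- lp_base + rowSums(contrib)
  if (base_scenario$outcome_family == "gaussian") {
    phen$outcome <- lp + noise
  } else {
    phen$outcome <- stats::rbinom(n, 1L, stats::plogis(lp))
  }

  out <- list(phenotypes = phen, methylation = meth, gene_map = gene_map,
              truth = data.frame(gene = genes, label = gene_labels,
                                 c_prime = base_scenario$c_prime,
                                 alpha_sum = vapply(alpha_l, sum, 0),
                                 beta_sum = vapply(beta_l, sum, 0),
                                 stringsAsFactors = FALSE),
              base_scenario = base_scenario, seed = seed)
  out$truth$alpha <- alpha_l
  out$truth$beta <- beta_l
  if (isolated) {
    set.seed(derive_gene_seed(seed, G + 2L))
    if (base_scenario$outcome_family == "gaussian") {
      iso_noise <- matrix(stats::rnorm(n * G, 0, sqrt(base_scenario$sigma_y_sq)),
                          n, G)
      out$outcomes_isolated <- lp_base + contrib + iso_noise
    } else {
      pr <- stats::plogis(lp_base + contrib)
      out$outcomes_isolated <- matrix(stats::rbinom(n * G, 1L, pr), n, G)
    }
  }
  class(out) <- "sim_study"
  out
}

#' Write a simulated study to the pipeline's standard input files
#'
#' Writes `methylation.tsv` (probe id, chromosome, position, then one column
#' per sample), `phenotypes.csv`, `genes.bed` (0-based half-open, as BED
#' requires) and `truth.tsv` into `dir`.
#'
#' @param study a [simulate_study()] result.
#' @param dir output directory, created if absent.
#' @return invisibly, the paths written.
#' @export
write_sim_study <- function(study, dir) {
  stopifnot(inherits(study, "sim_study"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  meth <- study$methylation
  dt <- data.table::data.table(probe_id = meth$probe_ids,
                               chrom = meth$chrom, pos = meth$pos)
  vals <- data.table::as.data.table(meth$values)
  data.table::setnames(vals, meth$sample_ids)
  meth_path <- file.path(dir, "methylation.tsv")
  data.table::fwrite(cbind(dt, vals), meth_path, sep = "\t")

  phen_path <- file.path(dir, "phenotypes.csv")
  data.table::fwrite(data.table::as.data.table(study$phenotypes), phen_path)

  gm <- study$gene_map
  bed <- data.table::data.table(chrom = gm$chrom, start = gm$start - 1L,
                                end = gm$end, name = gm$gene, score = 0L,
                                strand = gm$strand)
  bed_path <- file.path(dir, "genes.bed")
  data.table::fwrite(bed, bed_path, sep = "\t", col.names = FALSE)

  tr <- study$truth
  truth_path <- file.path(dir, "truth.tsv")
  data.table::fwrite(data.table::data.table(
    gene = tr$gene, label = tr$label, c_prime = tr$c_prime,
    alpha_sum = tr$alpha_sum, beta_sum = tr$beta_sum,
    alpha = vapply(tr$alpha, function(v) paste(v, collapse = ","), ""),
    beta = vapply(tr$beta, function(v) paste(v, collapse = ","), "")),
    truth_path, sep = "\t")
  invisible(c(methylation = meth_path, phenotypes = phen_path,
              annotation = bed_path, truth = truth_path))
}
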