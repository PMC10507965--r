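#' The 20-gene ICR panel
#'
#' Gene symbols of the immune-activation panel used by the classifier:
#' Th1 signaling (IFNG, TBX21, CD8A/B, IL12B, STAT1, IRF1), Th1
#' chemoattraction (CXCL9, CXCL10, CCL5), cytotoxic effectors (GNLY, PRF1,
#' GZMA/B/H) and counter-regulatory checkpoints (CD274, PDCD1, IDO1, CTLA4,
#' FOXP3).
#'
#' @return Character vector of the 20 symbols, alphabetical.
#' @export
icr_panel <- function() {
  c("CCL5", "CD274", "CD8A", "CD8B", "CTLA4", "CXCL9", "CXCL10", "FOXP3",
    "GNLY", "GZMA", "GZMB", "GZMH", "IDO1", "IFNG", "IL12B", "IRF1",
    "PDCD1", "PRF1", "STAT1", "TBX21")
}

#' Simulation configuration for the multi-cohort generator
#'
#' The defaults encode the cohort structure the analysis assumes: five
#' cohorts of 44/30/30/28/30 patients (162 total), latent immune classes
#' drawn with probabilities (0.22, 0.30, 0.22, 0.26), durable-clinical-
#' benefit probability 0.09 in class 1 and 0.35 in classes 2-4, a monotone
#' 4-class continuum on the 20 panel genes, companion-signature genes
#' loaded on the same continuum, per-cohort location/scale batch effects,
#' and survival independent of class.
#'
#' @param n_cohorts number of cohorts.
#' @param n_per_cohort integer vector of cohort sizes (length `n_cohorts`),
#'   each >= 4.
#' @param class_probs probabilities of latent classes ICR1..ICR4; sum to 1.
#' @param dcb_probs per-class probability of durable clinical benefit.
#' @param icr_gene_means 4 x 20 matrix of class-wise mean log2 expression of
#'   the panel genes; the row means must strictly increase class 1 -> 4.
#'   Default: gene baselines 4.5..8.3 plus `separation` per class step.
#' @param separation log2 increment between consecutive class means used to
#'   build the default `icr_gene_means` ("strong" preset 1.5; use ~0.5 for a
#'   weak-separation stress preset).
#' @param noise_sd residual SD in log2 units around the class mean.
#' @param batch_shift_sd SD of the per-cohort additive location shift.
#' @param batch_scale_sd SD (log scale) of the per-cohort multiplicative
#'   noise inflation.
#' @param n_extra_genes total non-panel genes. Companion-signature genes
#'   (from `signature_db`) come first; the remainder are neutral fillers.
#' @param loading default continuum loading of companion immune genes
#'   (log2 units per class step); TP53-activation genes get `-loading`,
#'   Th2 genes `0.25 * loading`, fillers 0.
#' @param survival_params list with `event_rate` (exponential events/month)
#'   and `censor_max` (months; censoring ~ Uniform(0, censor_max)).
#' @param signature_db path to the GMT file defining companion gene sets;
#'   default the shipped database.
#' @param seed root integer seed; per-cohort streams are derived from it by
#'   a fixed offset so each cohort is independently reproducible.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_cohorts = 5L,
                       n_per_cohort = c(44L, 30L, 30L, 28L, 30L),
                       class_probs = c(0.22, 0.30, 0.22, 0.26),
                       dcb_probs = c(0.09, 0.35, 0.35, 0.35),
                       icr_gene_means = NULL,
                       separation = 1.5,
                       noise_sd = 0.7,
                       batch_shift_sd = 0.5,
                       batch_scale_sd = 0.15,
                       n_extra_genes = 400L,
                       loading = 0.8,
                       survival_params = list(event_rate = 0.012,
                                              censor_max = 120),
                       signature_db = default_signature_db(),
                       seed = 1L) {
  n_cohorts <- as.integer(n_cohorts)
  n_per_cohort <- as.integer(n_per_cohort)
  if (n_cohorts < 1L) stop("n_cohorts must be >= 1")
  if (length(n_per_cohort) != n_cohorts) {
    stop("n_per_cohort must have length n_cohorts")
  }
  if (any(n_per_cohort < 4L)) stop("n_per_cohort < 4: cannot cluster a cohort")
  if (length(class_probs) != 4L || any(class_probs < 0) ||
      abs(sum(class_probs) - 1) > 1e-8) {
    stop("class_probs must be 4 non-negative probabilities summing to 1")
  }
  if (length(dcb_probs) != 4L || any(dcb_probs < 0 | dcb_probs > 1)) {
    stop("dcb_probs must be 4 probabilities in [0, 1]")
  }
  panel <- icr_panel()
  if (is.null(icr_gene_means)) {
    baseline <- seq(4.5, 8.3, length.out = length(panel))
    icr_gene_means <- outer(separation * (0:3), rep(1, length(panel))) +
      outer(rep(1, 4), baseline)
    colnames(icr_gene_means) <- panel
  }
  icr_gene_means <- as.matrix(icr_gene_means)
  if (!identical(dim(icr_gene_means), c(4L, length(panel)))) {
    stop("icr_gene_means must be 4 x 20")
  }
  if (is.null(colnames(icr_gene_means))) colnames(icr_gene_means) <- panel
  if (any(diff(rowMeans(icr_gene_means)) <= 0)) {
    stop("icr_gene_means row means must strictly increase class 1 -> 4")
  }
  stopifnot(noise_sd >= 0, batch_shift_sd >= 0, batch_scale_sd >= 0,
            n_extra_genes >= 0, is.numeric(survival_params$event_rate),
            survival_params$event_rate > 0, survival_params$censor_max > 0)
  structure(
    list(n_cohorts = n_cohorts, n_per_cohort = n_per_cohort,
         class_probs = class_probs, dcb_probs = dcb_probs,
         icr_gene_means = icr_gene_means, separation = separation,
         noise_sd = noise_sd, batch_shift_sd = batch_shift_sd,
         batch_scale_sd = batch_scale_sd,
         n_extra_genes = as.integer(n_extra_genes), loading = loading,
         survival_params = survival_params, signature_db = signature_db,
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' Path to the shipped signature gene-set database
#' @return Path to the GMT file installed with the package.
#' @export
default_signature_db <- function() {
  system.file("extdata", "signatures.gmt", package = "icrlung",
              mustWork = TRUE)
}

# Companion-gene annotation derived from the signature DB: symbol + loading
# multiplier (in class steps). Panel genes are excluded; conflicts resolved
# with priority TP53 (-1) > Th2 (0.25) > immune (+1).
companion_loadings <- function(config) {
  db <- read_gmt(config$signature_db)
  panel <- icr_panel()
  all_genes <- unique(unlist(lapply(db, `[[`, "genes")))
  all_genes <- setdiff(all_genes, panel)
  mult <- rep(1, length(all_genes))
  names(mult) <- all_genes
  th2 <- db[["BINDEA_TH2"]]$genes
  tp53 <- db[["TP53_ACTIVATION"]]$genes
  mult[names(mult) %in% th2] <- 0.25
  mult[names(mult) %in% tp53] <- -1
  mult * config$loading
}

# One cohort's per-stream seed; offset keeps streams distinct and < 2^31.
cohort_seed <- function(seed, cohort_index) {
  (seed + 7919L * cohort_index) %% .Machine$integer.max
}

#' Generate one synthetic cohort
#'
#' Draws latent class labels, builds log2 expression for the 20 panel genes
#' (class mean + cohort batch shift + Gaussian noise scaled by the cohort
#' batch factor), companion-signature genes loaded on the same class
#' continuum, neutral filler genes, and a clinical table with class-dependent
#' durable clinical benefit and class-independent survival.
#'
#' @param config a [sim_config()].
#' @param cohort_index 1-based cohort index, `<= config$n_cohorts`.
#' @return A list of class `sim_cohort`: `expression`
#'   ([expression_dataset()]), `clinical` (validated data.frame),
#'   `true_class` (integer 1-4 per sample), and the realized `batch_shift`
#'   and `batch_scale`.
#' @export
generate_cohort <- function(config, cohort_index = 1L) {
  stopifnot(inherits(config, "sim_config"))
  cohort_index <- as.integer(cohort_index)
  if (cohort_index < 1L || cohort_index > config$n_cohorts) {
    stop("cohort_index out of range")
  }
  n <- config$n_per_cohort[cohort_index]
  cohort_id <- sprintf("cohort%02d", cohort_index)
  set.seed(cohort_seed(config$seed, cohort_index))

  batch_shift <- stats::rnorm(1, 0, config$batch_shift_sd)
  batch_scale <- exp(stats::rnorm(1, 0, config$batch_scale_sd))

  true_class <- sample.int(4L, n, replace = TRUE, prob = config$class_probs)
  sample_ids <- sprintf("%s_s%03d", cohort_id, seq_len(n))

  panel <- icr_panel()
  sd_eff <- config$noise_sd * batch_scale
  panel_vals <- t(config$icr_gene_means[true_class, , drop = FALSE]) +
    batch_shift +
    matrix(stats::rnorm(length(panel) * n, 0, sd_eff), length(panel), n)
  rownames(panel_vals) <- panel

  loadings <- companion_loadings(config)
  n_comp <- length(loadings)
  if (config$n_extra_genes < n_comp) {
    stop("n_extra_genes (", config$n_extra_genes,
         ") smaller than the companion-signature gene count (", n_comp, ")")
  }
  # Gene baselines are deterministic functions of gene index (not of the
  # seed) so gene identity is stable across cohorts, and spread over a wide
  # dynamic range as in real transcriptomes - this keeps per-cohort
  # quantile normalization close to rank-preserving on the class signal.
  class_step <- true_class - 1L            # 0..3 continuum position
  comp_base <- seq(3, 10, length.out = n_comp)
  comp_vals <- matrix(stats::rnorm(n_comp * n, 0, sd_eff), n_comp, n)
  comp_vals <- comp_vals + outer(loadings, class_step) + comp_base +
    batch_shift
  rownames(comp_vals) <- names(loadings)

  n_fill <- config$n_extra_genes - n_comp
  fill_base <- seq(2, 12, length.out = n_fill)
  fill_vals <- matrix(stats::rnorm(n_fill * n, 0, sd_eff), n_fill, n) +
    fill_base + batch_shift
  rownames(fill_vals) <- sprintf("FILLER%04d", seq_len(n_fill))

  vals <- rbind(panel_vals, comp_vals, fill_vals)
  colnames(vals) <- sample_ids
  expr <- expression_dataset(vals, cohort_id = cohort_id)

  dcb <- stats::rbinom(n, 1, config$dcb_probs[true_class])
  event_time <- stats::rexp(n, config$survival_params$event_rate)
  censor_time <- stats::runif(n, 0, config$survival_params$censor_max)
  clin <- data.frame(
    patient_id = sample_ids,
    cohort = cohort_id,
    age = pmin(pmax(round(stats::rnorm(n, 60, 10)), 26), 86),
    sex = sample(c("male", "female"), n, replace = TRUE, prob = c(0.67, 0.33)),
    smoker = sample(c("current", "former", "non"), n, replace = TRUE,
                    prob = c(0.46, 0.43, 0.11)),
    histology = sample(c("squamous", "non-squamous"), n, replace = TRUE,
                       prob = c(0.35, 0.65)),
    mutation = sample(c("mutated", "wild-type"), n, replace = TRUE,
                      prob = c(0.38, 0.62)),
    dcb = dcb,
    dfs_months = pmin(event_time, censor_time),
    dfs_event = as.integer(event_time <= censor_time),
    stringsAsFactors = FALSE
  )
  validate_clinical(clin)

  structure(list(expression = expr, clinical = clin, true_class = true_class,
                 batch_shift = batch_shift, batch_scale = batch_scale),
            class = "sim_cohort")
}

#' Generate all cohorts of a simulated multi-cohort study
#'
#' @param config a [sim_config()].
#' @return List of [generate_cohort()] results, one per cohort.
#' @export
generate_multi_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  lapply(seq_len(config$n_cohorts), function(i) generate_cohort(config, i))
}

#' Generate a raw nCounter-style probe count table
#'
#' Produces integer counts for a 770-probe panel (716 endogenous, 8 negative
#' controls, 6 positive controls, 40 housekeeping) with known per-sample
#' scale factors and known additive background, recorded as attributes for
#' ground-truth checks of the normalization chain. Endogenous probe
#' abundances follow cohort 1 of the expression model in `config`.
#'
#' @param config a [sim_config()] (needs `n_extra_genes >= 696` to fill the
#'   716 endogenous probes; surplus model genes are dropped, deficit filled
#'   with fillers).
#' @param scale_factors optional per-sample multiplicative factors (default
#'   lognormal around 1); `background` optional per-sample additive count
#'   (default ~ 30). Pass 1 and 0 to make normalization an identity check.
#' @return A `raw_counts` object (see [raw_counts()]) with attributes
#'   `true_scale` and `true_background`.
#' @export
generate_raw_nanostring <- function(config, scale_factors = NULL,
                                    background = NULL) {
  stopifnot(inherits(config, "sim_config"))
  cohort <- generate_cohort(config, 1L)
  n <- ncol(cohort$expression$values)
  set.seed(cohort_seed(config$seed, 977L))

  n_endo <- 716L
  expr <- cohort$expression$values
  if (nrow(expr) >= n_endo) {
    expr <- expr[seq_len(n_endo), , drop = FALSE]
  } else {
    extra <- matrix(stats::rnorm((n_endo - nrow(expr)) * n, 6, 1),
                    n_endo - nrow(expr), n)
    rownames(extra) <- sprintf("PAD%04d", seq_len(nrow(extra)))
    expr <- rbind(expr, extra)
  }
  mu_endo <- 2^expr                       # linear-scale abundance

  if (is.null(scale_factors)) {
    scale_factors <- exp(stats::rnorm(n, 0, 0.3))
  }
  if (is.null(background)) background <- rep(30, n)
  scale_factors <- rep_len(scale_factors, n)
  background <- rep_len(background, n)

  hk_mu <- stats::runif(40, 200, 2000)       # housekeeping, class-independent
  pos_mu <- c(8000, 2000, 500, 125, 32, 8)   # positive-control titration
  neg_mu <- rep(0, 8)                        # negatives see background only

  mu <- rbind(mu_endo,
              matrix(neg_mu, 8, n),
              matrix(pos_mu, 6, n),
              matrix(hk_mu, 40, n))
  mu <- sweep(mu, 2, scale_factors, `*`)
  mu <- sweep(mu, 2, background, `+`)
  counts <- matrix(stats::rpois(length(mu), lambda = mu), nrow(mu), ncol(mu))
  probe_class <- c(rep("endogenous", n_endo), rep("negative", 8),
                   rep("positive", 6), rep("housekeeping", 40))
  probe_id <- c(rownames(expr), sprintf("NEG_%d", 1:8),
                sprintf("POS_%s", LETTERS[1:6]), sprintf("HK_%02d", 1:40))
  gene_symbol <- probe_id
  dimnames(counts) <- list(probe_id, cohort$expression$sample_ids)
  rc <- raw_counts(counts, probe_class, gene_symbol)
  attr(rc, "true_scale") <- scale_factors
  attr(rc, "true_background") <- background
  rc
}

#' Write a simulated cohort to plain-text files
#'
#' Expression as TSV ([write_expression_tsv()]), clinical table and
#' ground-truth class labels as CSV.
#'
#' @param cohort a `sim_cohort`.
#' @param dir output directory (created if needed).
#' @return Named character vector of the three paths, invisibly.
#' @export
write_sim_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "sim_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  id <- cohort$expression$cohort_id
  paths <- c(
    expression = file.path(dir, paste0(id, "_expression.tsv")),
    clinical = file.path(dir, paste0(id, "_clinical.csv")),
    truth = file.path(dir, paste0(id, "_truth.csv"))
  )
  write_expression_tsv(cohort$expression, paths[["expression"]])
  utils::write.csv(cohort$clinical, paths[["clinical"]], row.names = FALSE)
  utils::write.csv(
    data.frame(patient_id = cohort$clinical$patient_id,
               true_class = cohort$true_class),
    paths[["truth"]], row.names = FALSE)
  invisible(paths)
}
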