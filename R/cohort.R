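#' Configuration for a synthetic PME cohort
#'
#' Describes a simulated two-group (normal vs peritumor liver) label-free
#' proteomic cohort with the statistical structure the PME analysis assumes:
#' log-normal protein intensities, planted differential proteins, planted
#' occurrence and progression markers (the latter with proportional-hazards
#' survival effects), latent block-structured subtypes among peritumor
#' samples, detection-limit (left-censored) missingness, and clinical
#' covariates coupled to the planted risk burden through a Gaussian copula.
#'
#' Default group sizes (34 normal / 61 peritumor) mirror the study design
#' this pipeline targets. Planted markers reuse the panel gene symbols
#' HSPA4L, VIL1, TYMP (occurrence) and CMPK2, TYMP, NADSYN1 (progression) so
#' the default model panels resolve on synthetic cohorts; TYMP is shared
#' between arms.
#'
#' @param n_normal,n_peritumor group sizes.
#' @param n_proteins total proteins simulated.
#' @param n_de planted differential proteins, markers included (default 8%
#'   of `n_proteins`, i.e. 400 at the default proteome size).
#' @param fc_range linear fold-change magnitudes for planted differentials,
#'   drawn uniformly; sign random.
#' @param n_occurrence_markers planted strong discriminators (linear fold
#'   change `marker_fc`, residual SD `marker_sd` on log2 scale), categories
#'   cycled over the six functional factors; default `min(12, 0.6 * n_de)`.
#' @param n_progression_markers planted survival-associated proteins;
#'   default `min(6, 0.3 * n_de)`.
#' @param marker_fc,marker_sd occurrence-marker effect size and noise.
#' @param hazard_beta_range per-progression-marker |log-hazard ratio| per SD
#'   of log2 abundance; signs random. Overridden by `hazard_betas`.
#' @param hazard_betas optional explicit signed log-hazard vector (length
#'   `n_progression_markers`).
#' @param n_subtypes latent peritumor subtypes.
#' @param n_subtype_proteins block proteins per subtype (disjoint blocks);
#'   default `min(60, (n_proteins - n_de) / (2 * n_subtypes))`.
#' @param subtype_signal log2 up-shift of a subtype's block in its samples.
#' @param missing_rate target fraction of each sample's values set missing by
#'   stochastic left-censoring at the sample's detection quantile.
#' @param detection_bias relative reduction of the peritumor missing rate
#'   (peritumor tissue yields slightly deeper proteome coverage).
#' @param censor_rate target fraction of censored survival times.
#' @param baseline_hazard exponential baseline hazard (per day); default
#'   log(2)/344 anchors the median survival to 344 days.
#' @param clinical_coupling Gaussian-copula correlation between the planted
#'   risk burden and AFP / cirrhosis stage / CYP2E1 activity.
#' @param seed RNG seed; the whole cohort is a deterministic function of the
#'   config.
#' @return object of class `cohort_config` (a validated list).
#' @export
cohort_config <- function(n_normal = 34, n_peritumor = 61, n_proteins = 5000,
                          n_de = NULL, fc_range = c(1.5, 2.5),
                          n_occurrence_markers = NULL,
                          n_progression_markers = NULL,
                          marker_fc = 3, marker_sd = 0.3,
                          hazard_beta_range = c(0.4, 0.8), hazard_betas = NULL,
                          n_subtypes = 3, n_subtype_proteins = NULL,
                          subtype_signal = 1.2, missing_rate = 0.10,
                          detection_bias = 0.15, censor_rate = 0.3,
                          baseline_hazard = log(2) / 344,
                          clinical_coupling = 0.6, seed = 1) {
  ## size-dependent defaults: 8% of the proteome planted differential (400 at
  ## the default 5000), marker and block counts shrink with small proteomes
  if (is.null(n_de)) n_de <- round(0.08 * n_proteins)
  if (is.null(n_occurrence_markers))
    n_occurrence_markers <- min(12L, floor(0.6 * n_de))
  if (is.null(n_progression_markers))
    n_progression_markers <- min(6L, floor(0.3 * n_de))
  if (is.null(n_subtype_proteins))
    n_subtype_proteins <- min(60L, floor((n_proteins - n_de) /
                                           (2 * n_subtypes)))
  cfg <- list(n_normal = n_normal, n_peritumor = n_peritumor,
              n_proteins = n_proteins, n_de = n_de, fc_range = fc_range,
              n_occurrence_markers = n_occurrence_markers,
              n_progression_markers = n_progression_markers,
              marker_fc = marker_fc, marker_sd = marker_sd,
              hazard_beta_range = hazard_beta_range,
              hazard_betas = hazard_betas, n_subtypes = n_subtypes,
              n_subtype_proteins = n_subtype_proteins,
              subtype_signal = subtype_signal, missing_rate = missing_rate,
              detection_bias = detection_bias,
              censor_rate = censor_rate, baseline_hazard = baseline_hazard,
              clinical_coupling = clinical_coupling, seed = seed)
  validate_cohort_config(cfg)
  structure(cfg, class = "cohort_config")
}

#' A fully null cohort configuration
#'
#' Convenience wrapper: no planted differentials, no markers, zero hazard
#' effects, no subtype blocks, no clinical coupling — every protein and
#' covariate is null, for calibration checks of downstream tests.
#'
#' @param ... overrides passed to [cohort_config()].
#' @export
null_cohort_config <- function(...) {
  args <- list(n_de = 0, n_occurrence_markers = 0, n_progression_markers = 0,
               n_subtype_proteins = 0, subtype_signal = 0,
               clinical_coupling = 0, detection_bias = 0)
  override <- list(...)
  args[names(override)] <- override
  do.call(cohort_config, args)
}

validate_cohort_config <- function(cfg) {
  with(cfg, {
    stopifnot(n_normal >= 1, n_peritumor >= 1, n_proteins >= 1,
              n_de >= 0, n_de <= n_proteins,
              n_occurrence_markers >= 0, n_progression_markers >= 0)
    if (n_occurrence_markers + n_progression_markers > 0 && n_de == 0)
      stop("markers are drawn from planted differential proteins; n_de must be > 0")
    if (n_de > 0 && (any(fc_range <= 1) || fc_range[2] < fc_range[1]))
      stop("fold changes must be > 1")
    if (n_occurrence_markers + n_progression_markers > n_de)
      stop("more markers than planted differential proteins")
    if (missing_rate < 0 || missing_rate >= 1) stop("missing_rate in [0,1)")
    if (detection_bias < 0 || detection_bias >= 1)
      stop("detection_bias in [0,1)")
    if (censor_rate < 0 || censor_rate >= 1) stop("censor_rate in [0,1)")
    if (n_subtypes < 1) stop("n_subtypes >= 1")
    if (n_subtypes * n_subtype_proteins > n_proteins - n_de)
      stop("not enough non-differential proteins for subtype blocks")
    if (abs(clinical_coupling) > 0.99) stop("|clinical_coupling| <= 0.99")
    if (!is.null(hazard_betas) && length(hazard_betas) != n_progression_markers)
      stop("hazard_betas length must equal n_progression_markers")
  })
  invisible(cfg)
}

pme_categories <- c("immunity", "inflammation", "angiogenesis", "metabolism",
                    "proliferation_invasion", "dna_damage_repair")

occ_panel_names <- c("HSPA4L", "VIL1", "TYMP")
prog_panel_names <- c("CMPK2", "TYMP", "NADSYN1")
## panel categories as reported for the six-factor scheme
panel_categories <- c(HSPA4L = "immunity", VIL1 = "inflammation",
                      TYMP = "angiogenesis", CMPK2 = "inflammation",
                      NADSYN1 = "metabolism")

#' Generate a synthetic PME cohort
#'
#' Simulates abundances, clinical covariates, survival, and ground truth per
#' the supplied [cohort_config()]. Log2 intensities are Gaussian per protein
#' with protein-level means ~ N(20, 1.5^2) and variances from a scaled
#' inverse-chi-square meta-distribution (d0 = 8, s0 = 0.45); planted
#' differential proteins are shifted by their signed log2 fold change in
#' peritumor samples; subtype blocks add `subtype_signal` in the samples of
#' their subtype; survival follows an exponential proportional-hazards model
#' on the standardized progression-marker abundances with independent
#' exponential censoring; each sample's lowest `missing_rate` fraction of
#' linear intensities is set missing (left-censoring at the detection
#' limit).
#'
#' @param config a [cohort_config()].
#' @return object of class `pme_cohort`: list with `abundance` (linear-scale
#'   [abundance_matrix()] with missing values), `clinical` (data.frame, see
#'   [read_clinical()]), `truth` (planted ground truth: differential table,
#'   marker tables, subtype labels, generating linear predictor), and
#'   `category_map` (protein to functional category, covering all proteins).
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "cohort_config")) config <- do.call(cohort_config, config)
  validate_cohort_config(config)
  with_seed(config$seed, generate_cohort_impl(config))
}

generate_cohort_impl <- function(cfg) {
  n_n <- cfg$n_normal; n_p <- cfg$n_peritumor
  n <- n_n + n_p; P <- cfg$n_proteins
  samp <- c(sprintf("N%03d", seq_len(n_n)), sprintf("P%03d", seq_len(n_p)))
  group <- rep(c("normal", "peritumor"), c(n_n, n_p))
  prot <- sprintf("PR%05d", seq_len(P))

  ## plant marker gene symbols onto the first protein slots
  n_occ <- cfg$n_occurrence_markers; n_prog <- cfg$n_progression_markers
  occ_ids <- prog_ids <- character(0)
  if (n_occ > 0)
    occ_ids <- c(occ_panel_names, sprintf("OM%03d", seq_len(max(0, n_occ - 3))))[seq_len(n_occ)]
  if (n_prog > 0)
    prog_ids <- c(prog_panel_names, sprintf("PM%03d", seq_len(max(0, n_prog - 3))))[seq_len(n_prog)]
  marker_ids <- union(occ_ids, prog_ids)
  prot[seq_along(marker_ids)] <- marker_ids

  ## protein meta-distribution; planted markers sit comfortably above the
  ## detection limit (the screening operates on the quantifiable proteome)
  mu <- stats::rnorm(P, mean = 20, sd = 1.5)
  sigma <- pmax(sqrt(8 * 0.45^2 / stats::rchisq(P, df = 8)), 0.25)
  if (length(marker_ids))
    mu[match(marker_ids, prot)] <- stats::rnorm(length(marker_ids), 21.5, 0.75)

  ## planted differential set: markers first, then extra DE proteins
  de_idx <- integer(0); lfc <- numeric(P)
  if (cfg$n_de > 0) {
    pool <- setdiff(seq_len(P), seq_along(marker_ids))
    extra <- sample(pool, cfg$n_de - length(marker_ids))
    de_idx <- c(seq_along(marker_ids), extra)
    lfc[de_idx] <- log2(stats::runif(length(de_idx), cfg$fc_range[1], cfg$fc_range[2])) *
      sample(c(-1, 1), length(de_idx), replace = TRUE)
    ## occurrence markers: fixed strong up-shift, tight noise (elevated
    ## peritumor markers, so planted directions replicate across cohorts);
    ## progression markers stay ordinary differential proteins apart from
    ## the hazard link
    oi <- match(occ_ids, prot)
    lfc[oi] <- log2(cfg$marker_fc)
    sigma[oi] <- cfg$marker_sd
  }

  ## subtype structure on peritumor samples
  subtype <- rep(NA_integer_, n)
  block_idx <- vector("list", cfg$n_subtypes)
  if (cfg$n_subtypes > 1) {
    subtype[group == "peritumor"] <-
      sample(rep_len(seq_len(cfg$n_subtypes), n_p))
    if (cfg$n_subtype_proteins > 0) {
      pool <- setdiff(seq_len(P), de_idx)
      picks <- sample(pool, cfg$n_subtypes * cfg$n_subtype_proteins)
      block_idx <- split(picks, rep(seq_len(cfg$n_subtypes),
                                    each = cfg$n_subtype_proteins))
    }
  }

  ## log2 abundance matrix
  x <- matrix(stats::rnorm(P * n), P, n) * sigma + mu
  pt <- group == "peritumor"
  x[, pt] <- x[, pt] + lfc
  if (cfg$n_subtype_proteins > 0 && cfg$n_subtypes > 1) {
    for (s in seq_len(cfg$n_subtypes)) {
      in_s <- which(!is.na(subtype) & subtype == s)
      x[block_idx[[s]], in_s] <- x[block_idx[[s]], in_s] + cfg$subtype_signal
    }
  }
  dimnames(x) <- list(prot, samp)

  ## survival from proportional hazards on standardized progression markers
  betas <- numeric(0)
  lp <- rep(0, n_p)
  if (n_prog > 0) {
    if (is.null(cfg$hazard_betas)) {
      betas <- stats::runif(n_prog, cfg$hazard_beta_range[1], cfg$hazard_beta_range[2]) *
        sample(c(-1, 1), n_prog, replace = TRUE)
    } else betas <- cfg$hazard_betas
    z <- scale(t(x[match(prog_ids, prot), pt, drop = FALSE]))
    lp <- drop(z %*% betas)
  }
  h0 <- cfg$baseline_hazard
  t_event <- stats::rexp(n_p, rate = h0 * exp(lp))
  cens_rate <- if (cfg$censor_rate > 0)
    h0 * cfg$censor_rate / (1 - cfg$censor_rate) else 0
  t_cens <- if (cens_rate > 0) stats::rexp(n_p, rate = cens_rate) else rep(Inf, n_p)
  t_cens <- pmin(t_cens, 1609)  # administrative end of follow-up
  surv_days <- round(pmax(pmin(t_event, t_cens), 1), 1)
  event <- as.integer(t_event <= t_cens)

  ## clinical covariates: Gaussian copula on the standardized risk burden
  rho <- cfg$clinical_coupling
  burden <- if (stats::sd(lp) > 0) drop(scale(lp)) else rep(0, n_p)
  latent <- function() rho * burden + sqrt(1 - rho^2) * stats::rnorm(n_p)
  afp_p <- stats::qlnorm(stats::pnorm(latent()), meanlog = log(60), sdlog = 1.6)
  cirr_p <- findInterval(stats::pnorm(latent()), c(0.15, 0.35, 0.6, 0.85))
  cyp_p <- stats::qnorm(stats::pnorm(latent()), mean = 1350, sd = 260)
  diam_p <- stats::qlnorm(stats::pnorm(0.4 * burden + sqrt(1 - 0.16) * stats::rnorm(n_p)),
                          meanlog = log(4.5), sdlog = 0.45)
  multi_p <- stats::rbinom(n_p, 1, stats::plogis(0.5 * burden - 1))

  clinical <- data.frame(
    sample_id = samp, group = group,
    survival_days = c(rep(NA_real_, n_n), surv_days),
    event = c(rep(NA_integer_, n_n), event),
    afp_ng_ml = round(c(stats::rlnorm(n_n, log(6), 0.8), afp_p), 2),
    cirrhosis_stage = c(stats::rbinom(n_n, 1, 0.15), cirr_p),
    cyp2e1_activity = round(c(stats::rnorm(n_n, 1600, 220), cyp_p), 1),
    tumor_diameter_cm = round(c(rep(NA_real_, n_n), diam_p), 2),
    tumor_multiplicity = c(rep(NA_integer_, n_n), multi_p),
    stringsAsFactors = FALSE)

  ## detection-limit missingness: stochastic left-censoring around each
  ## sample's detection quantile (logistic width 0.25 log2 units); peritumor
  ## detects slightly more (detection_bias), emulating the deeper peritumor
  ## proteome
  lin <- 2^x
  if (cfg$missing_rate > 0) {
    rate_j <- ifelse(pt, cfg$missing_rate * (1 - cfg$detection_bias),
                     cfg$missing_rate)
    for (j in seq_len(n)) {
      thr <- stats::quantile(x[, j], rate_j[j], names = FALSE)
      p_miss <- stats::plogis((thr - x[, j]) / 0.25)
      lin[stats::runif(P) < p_miss, j] <- NA
    }
  }

  ## every protein carries a functional-category annotation
  category_map <- stats::setNames(
    sample(pme_categories, P, replace = TRUE), prot)
  category_map[occ_ids] <- rep_len(pme_categories, length(occ_ids))
  category_map[prog_ids] <- rep_len(pme_categories[c(2:6, 1)], length(prog_ids))
  for (g in intersect(names(panel_categories), prot))
    category_map[g] <- panel_categories[g]

  truth <- list(
    de = data.frame(protein_id = prot[de_idx], log2fc = lfc[de_idx],
                    stringsAsFactors = FALSE),
    occurrence_markers = if (n_occ > 0)
      data.frame(protein_id = occ_ids,
                 category = unname(category_map[occ_ids]),
                 log2fc = lfc[match(occ_ids, prot)],
                 stringsAsFactors = FALSE) else NULL,
    progression_markers = if (n_prog > 0)
      data.frame(protein_id = prog_ids,
                 category = unname(category_map[prog_ids]),
                 beta = betas, stringsAsFactors = FALSE) else NULL,
    subtype = data.frame(sample_id = samp[pt], label = subtype[pt],
                         stringsAsFactors = FALSE),
    linear_predictor = stats::setNames(lp, samp[pt]),
    config = unclass(cfg))

  structure(list(abundance = abundance_matrix(lin, "linear"),
                 clinical = clinical, truth = truth,
                 category_map = category_map),
            class = "pme_cohort")
}

#' @export
print.pme_cohort <- function(x, ...) {
  cat(sprintf("pme_cohort: %d proteins x %d samples (%d normal / %d peritumor)\n",
              nrow(x$abundance), ncol(x$abundance),
              sum(x$clinical$group == "normal"),
              sum(x$clinical$group == "peritumor")))
  cat(sprintf("  planted: %d differential, %d occurrence / %d progression markers, %d subtypes\n",
              nrow(x$truth$de),
              NROW(x$truth$occurrence_markers), NROW(x$truth$progression_markers),
              x$truth$config$n_subtypes))
  invisible(x)
}

#' Write a cohort to disk as plain-text fixtures
#'
#' Emits `abundance.tsv` (see [read_abundance()]), `clinical.csv`
#' (see [read_clinical()]), `category_map.tsv` (protein_id, category) and
#' `ground_truth.json`; the TSV/CSV round-trip through the readers is
#' lossless.
#'
#' @param cohort a `pme_cohort`.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_abundance(cohort$abundance, file.path(dir, "abundance.tsv"))
  write_clinical(cohort$clinical, file.path(dir, "clinical.csv"))
  write_category_map(cohort$category_map, file.path(dir, "category_map.tsv"))
  jsonlite::write_json(cohort$truth, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  invisible(dir)
}

#' Read / write a protein-to-category annotation map
#'
#' Two-column TSV (`protein_id`, `category`); categories come from the fixed
#' six-factor scheme (immunity, inflammation, angiogenesis, metabolism,
#' proliferation_invasion, dna_damage_repair).
#'
#' @param path file path.
#' @return named character vector, protein ID -> category.
#' @export
read_category_map <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  stats::setNames(df$category, df$protein_id)
}

#' @param map named character vector as returned by [read_category_map()].
#' @rdname read_category_map
#' @export
write_category_map <- function(map, path) {
  utils::write.table(data.frame(protein_id = names(map), category = unname(map)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Simulate survival data under a proportional-hazards model
#'
#' Small standalone generator for calibration studies: covariates are
#' standard normal, event times exponential with hazard
#' `baseline * exp(x %*% beta)`, censoring independent exponential tuned to
#' the target censoring fraction.
#'
#' @param n subjects.
#' @param beta log-hazard coefficient vector (length = number of covariates).
#' @param baseline baseline hazard.
#' @param censor_rate target censored fraction.
#' @param seed RNG seed.
#' @return list with `x` (matrix), `time`, `event`, `lp` (true linear
#'   predictor).
#' @export
simulate_ph_data <- function(n, beta, baseline = 0.01, censor_rate = 0.3,
                             seed = 1) {
  with_seed(seed, {
    p <- length(beta)
    x <- matrix(stats::rnorm(n * p), n, p,
                dimnames = list(NULL, paste0("x", seq_len(p))))
    lp <- drop(x %*% beta)
    te <- stats::rexp(n, rate = baseline * exp(lp))
    tc <- if (censor_rate > 0)
      stats::rexp(n, rate = baseline * censor_rate / (1 - censor_rate))
    else rep(Inf, n)
    list(x = x, time = pmax(pmin(te, tc), 1e-6), event = as.integer(te <= tc),
         lp = lp)
  })
}
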