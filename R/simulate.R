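#' Default tissue panel for synthetic atlases
#'
#' Adult testis plus the somatic panel typically used for tissue-bias
#' scoring: accessory glands, brain, head, thoracicoabdominal ganglion,
#' crop, midgut, hindgut, adult and larval malpighian tubules, ovary,
#' salivary glands and carcass.
#'
#' @format Character vector of tissue labels.
#' @export
DEFAULT_TISSUES <- c("testis", "accessory_gland", "brain", "head",
                     "thoracicoabdominal_ganglion", "crop", "midgut",
                     "hindgut", "malpighian_tubule_adult",
                     "malpighian_tubule_larval", "ovary", "salivary_gland",
                     "carcass")

#' Default chromatin-protein panel with role tags
#'
#' Proteins whose binding in embryos and cultured cells is generally
#' associated with gene silencing (histone H1, H3K27me3, LamDm0, D1, Pc,
#' esc, Sce) or with active expression (H3.3A, H3K4me3, DJun, bcd).
#'
#' @format Named character vector: names are proteins, values are roles.
#' @export
DEFAULT_PROTEIN_ROLES <- c(
  H1 = "silencing", H3K27me3 = "silencing", LamDm0 = "silencing",
  D1 = "silencing", Pc = "silencing", esc = "silencing", Sce = "silencing",
  H3.3A = "activation", H3K4me3 = "activation", DJun = "activation",
  bcd = "activation")

default_timepoints <- function() {
  data.frame(day = c(4L, 5L, 6L, 7L, 7L, 10L),
             stage = c("feeding", "feeding", "feeding", "feeding",
                       "wandering", "wandering"),
             stringsAsFactors = FALSE)
}

#' Configuration for the synthetic-data generator
#'
#' The defaults describe the study conditions the generator emulates: a
#' genome-scale catalog on the six major arms with realistic arm shares,
#' log-normal baseline intensities, a cohort of genes planted with
#' multiplicative bias toward single tissues (factors stratified over
#' 2-5x, 5-10x and >=10x), depletion of the >=10x cohort on the X,
#' monotone spermatocyte-activation trajectories over larval testis
#' development, and chromatin-binding scores correlated (positively for
#' silencing-role proteins, negatively for activation-role proteins) with
#' planted testis up-regulation, attenuated on the X.
#'
#' @param n_genes Number of genes.
#' @param arm_proportions Named fractions per arm, summing to 1.
#' @param baseline_log_mean,baseline_log_sd Natural-log mean and sd of the
#'   log-normal baseline intensity.
#' @param bias_fraction_per_tissue Fraction of genes planted as biased
#'   toward each tissue in \code{tissues}.
#' @param bias_strata List with \code{breaks} (stratum edges, default
#'   \code{c(2, 5, 10, 50)}) and \code{weights} (mixture weights over the
#'   three strata); planted factors are log-uniform within a stratum.
#' @param x_highbias_depletion Multiplier in [0, 1] applied to the X
#'   assignment probability of planted high-bias (top-stratum) genes; the
#'   autosomal probabilities are rescaled to absorb the freed mass, so the
#'   expected X fraction of high-bias genes is exactly
#'   \code{x_highbias_depletion} times the X share.
#' @param activation_fraction Fraction of genes with monotone increasing
#'   testis-development trajectories.
#' @param trajectory_slope_range Range (log2 units per day) of activation
#'   slopes, drawn uniformly.
#' @param noise_cv Coefficient of variation of multiplicative measurement
#'   noise.
#' @param n_replicates Hybridization replicates per time-course condition.
#' @param timepoints Data frame with columns \code{day} and \code{stage};
#'   the earliest day is the reference.
#' @param tissues Tissue labels for the atlas.
#' @param proteins Named character vector of protein roles.
#' @param binding_rho_silencing,binding_rho_activation Target Pearson
#'   correlations between planted testis up-regulation and binding score
#'   for the two protein roles.
#' @param x_attenuation Factor in [0, 1] shrinking the planted binding
#'   correlation for X-linked genes.
#' @param binding_threshold_quantile Quantile of generated scores at which
#'   each protein's bound/non-bound threshold is set.
#' @param seed Integer root seed; per-table substreams are derived
#'   deterministically from (seed, table name).
#' @return List of class \code{sim_config}.
#' @export
sim_config <- function(n_genes = 13000,
                       arm_proportions = c(X = 0.17, `2L` = 0.185,
                                           `2R` = 0.21, `3L` = 0.195,
                                           `3R` = 0.22, `4` = 0.02),
                       baseline_log_mean = 5.5,
                       baseline_log_sd = 1.2,
                       bias_fraction_per_tissue = 0.025,
                       bias_strata = list(breaks = c(2, 5, 10, 50),
                                          weights = c(0.35, 0.25, 0.40)),
                       x_highbias_depletion = 0.5,
                       activation_fraction = 0.15,
                       trajectory_slope_range = c(0.3, 1.2),
                       noise_cv = 0.2,
                       n_replicates = 3,
                       timepoints = default_timepoints(),
                       tissues = DEFAULT_TISSUES,
                       proteins = DEFAULT_PROTEIN_ROLES,
                       binding_rho_silencing = 0.4,
                       binding_rho_activation = -0.4,
                       x_attenuation = 0.5,
                       binding_threshold_quantile = 0.75,
                       seed = 1) {
  cfg <- list(n_genes = n_genes, arm_proportions = arm_proportions,
              baseline_log_mean = baseline_log_mean,
              baseline_log_sd = baseline_log_sd,
              bias_fraction_per_tissue = bias_fraction_per_tissue,
              bias_strata = bias_strata,
              x_highbias_depletion = x_highbias_depletion,
              activation_fraction = activation_fraction,
              trajectory_slope_range = trajectory_slope_range,
              noise_cv = noise_cv, n_replicates = n_replicates,
              timepoints = as.data.frame(timepoints),
              tissues = tissues, proteins = proteins,
              binding_rho_silencing = binding_rho_silencing,
              binding_rho_activation = binding_rho_activation,
              x_attenuation = x_attenuation,
              binding_threshold_quantile = binding_threshold_quantile,
              seed = seed)
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$n_genes >= 1)
  if (!setequal(names(cfg$arm_proportions), ARM_LEVELS))
    stop("arm_proportions must name every arm in ARM_LEVELS", call. = FALSE)
  if (abs(sum(cfg$arm_proportions) - 1) > 1e-9)
    stop("arm_proportions must sum to 1", call. = FALSE)
  fr <- c(cfg$bias_fraction_per_tissue, cfg$x_highbias_depletion,
          cfg$activation_fraction, cfg$x_attenuation,
          cfg$binding_threshold_quantile)
  if (any(fr < 0 | fr > 1))
    stop("fractions must lie in [0, 1]", call. = FALSE)
  if (abs(sum(cfg$bias_strata$weights) - 1) > 1e-9)
    stop("bias_strata weights must sum to 1", call. = FALSE)
  if (length(cfg$bias_strata$breaks) != length(cfg$bias_strata$weights) + 1)
    stop("bias_strata needs one more break than weights", call. = FALSE)
  if (abs(cfg$binding_rho_silencing) >= 1 || abs(cfg$binding_rho_activation) >= 1)
    stop("binding correlations must lie in (-1, 1)", call. = FALSE)
  if (cfg$noise_cv < 0) stop("noise_cv must be nonnegative", call. = FALSE)
  if (length(cfg$bias_fraction_per_tissue) == 1 &&
      cfg$bias_fraction_per_tissue * length(cfg$tissues) > 1)
    stop("total planted bias fraction exceeds 1", call. = FALSE)
  if (length(unique(cfg$timepoints$day)) < 2)
    stop("timepoints must span at least two days", call. = FALSE)
  if (!all(cfg$proteins %in% c("silencing", "activation")))
    stop("protein roles must be silencing or activation", call. = FALSE)
  invisible(cfg)
}

lognorm_noise_sdlog <- function(cv) if (cv == 0) 0 else sqrt(log(1 + cv^2))

#' Generate a synthetic gene catalog with planted truth
#'
#' Assigns each gene a chromosome arm (multinomial over the configured arm
#' shares), plants single-tissue expression bias for a configured fraction
#' of genes per tissue with log-uniform factors within strata, plants
#' monotone testis-development activation for a configured fraction, and
#' depletes the X assignment probability of top-stratum (high-bias) genes
#' by \code{x_highbias_depletion}.
#'
#' @param config A \code{\link{sim_config}}.
#' @return List with elements \code{catalog} (a
#'   \code{\link{gene_catalog}}) and \code{truth}, a data frame with one
#'   row per gene recording arm, planted bias tissue and factor, activation
#'   flag and slope, planted final-day up-regulation (log2) and the
#'   X-attenuation applied to its binding correlation.
#' @export
generate_catalog <- function(config) {
  validate_sim_config(config)
  with_seed(substream_seed(config$seed, "catalog"), {
    n <- config$n_genes
    ids <- sprintf("g%06d", seq_len(n))
    brk <- config$bias_strata$breaks
    wts <- config$bias_strata$weights

    bias_tissue <- rep(NA_character_, n)
    bias_factor <- rep(1, n)
    n_per <- round(n * config$bias_fraction_per_tissue)
    n_tis <- length(config$tissues)
    if (n_per * n_tis > 0) {
      picked <- sample.int(n, n_per * n_tis)
      bias_tissue[picked] <- rep(config$tissues, each = n_per)
      stratum <- sample.int(length(wts), length(picked), replace = TRUE,
                            prob = wts)
      lo <- brk[stratum]; hi <- brk[stratum + 1]
      bias_factor[picked] <- exp(stats::runif(length(picked), log(lo), log(hi)))
    }
    high <- bias_factor >= brk[length(brk) - 1]

    p <- config$arm_proportions[ARM_LEVELS]
    arm <- character(n)
    arm[!high] <- sample(ARM_LEVELS, sum(!high), replace = TRUE, prob = p)
    if (any(high)) {
      pX <- p[["X"]] * config$x_highbias_depletion
      p_dep <- c(pX, (1 - pX) / (1 - p[["X"]]) * p[ARM_LEVELS != "X"])
      names(p_dep) <- ARM_LEVELS
      arm[high] <- sample(ARM_LEVELS, sum(high), replace = TRUE, prob = p_dep)
    }

    activated <- stats::runif(n) < config$activation_fraction
    slope <- ifelse(activated,
                    stats::runif(n, config$trajectory_slope_range[1],
                                 config$trajectory_slope_range[2]), 0)
    span <- diff(range(config$timepoints$day))
    truth <- data.frame(
      gene_id = ids, arm = arm, bias_tissue = bias_tissue,
      bias_factor = bias_factor, high_bias = high, activated = activated,
      slope = slope, upregulation = slope * span,
      binding_attenuation = ifelse(arm == "X", config$x_attenuation, 1),
      stringsAsFactors = FALSE)
    list(catalog = gene_catalog(ids, arm), truth = truth)
  })
}

#' Generate a synthetic tissue expression atlas
#'
#' Intensity is a log-normal baseline, multiplied by the planted bias
#' factor in the gene's target tissue only, times multiplicative
#' log-normal noise with the configured coefficient of variation.
#'
#' @param catalog A \code{\link{gene_catalog}} from
#'   \code{\link{generate_catalog}}.
#' @param truth Matching truth table.
#' @param config A \code{\link{sim_config}}.
#' @param tissue_labels Atlas columns; must include every planted target
#'   tissue.
#' @return An \code{\link{expression_atlas}}.
#' @export
generate_atlas <- function(catalog, truth, config,
                           tissue_labels = config$tissues) {
  targets <- unique(stats::na.omit(truth$bias_tissue))
  if (!all(targets %in% tissue_labels))
    stop("tissue_labels must include every planted target tissue",
         call. = FALSE)
  with_seed(substream_seed(config$seed, "atlas"), {
    n <- nrow(catalog)
    base <- stats::rlnorm(n, config$baseline_log_mean, config$baseline_log_sd)
    sdl <- lognorm_noise_sdlog(config$noise_cv)
    noise <- if (sdl == 0) 1 else
      exp(matrix(stats::rnorm(n * length(tissue_labels), 0, sdl), n))
    vals <- base * noise
    if (!is.matrix(vals)) vals <- matrix(vals, n, length(tissue_labels))
    dimnames(vals) <- list(catalog$gene_id, tissue_labels)
    planted <- which(!is.na(truth$bias_tissue))
    if (length(planted)) {
      j <- match(truth$bias_tissue[planted], tissue_labels)
      vals[cbind(planted, j)] <- vals[cbind(planted, j)] *
        truth$bias_factor[planted]
    }
    expression_atlas(vals)
  })
}

#' Generate a synthetic testis-development time course
#'
#' Activated genes follow a monotone increasing expected log2 trajectory
#' (their planted slope per day); all other genes are flat. Replicates are
#' independent multiplicative noise draws around the expected intensity.
#'
#' @param catalog,truth,config As for \code{\link{generate_atlas}}.
#' @param timepoints Data frame with columns \code{day} and \code{stage};
#'   defaults to the configured design. A plain numeric vector of days is
#'   also accepted.
#' @return A \code{\link{time_course}} on the raw intensity scale.
#' @export
generate_timecourse <- function(catalog, truth, config,
                                timepoints = config$timepoints) {
  if (is.numeric(timepoints))
    timepoints <- data.frame(day = as.integer(timepoints), stage = "feeding",
                             stringsAsFactors = FALSE)
  if (length(unique(timepoints$day)) < 2)
    stop("need at least two timepoints", call. = FALSE)
  with_seed(substream_seed(config$seed, "timecourse"), {
    n <- nrow(catalog)
    base_log2 <- log2(stats::rlnorm(n, config$baseline_log_mean,
                                    config$baseline_log_sd))
    d0 <- min(timepoints$day)
    sdl2 <- lognorm_noise_sdlog(config$noise_cv) / log(2)
    reps <- config$n_replicates
    cols <- list(); meta <- list()
    for (i in seq_len(nrow(timepoints))) {
      day <- timepoints$day[i]; stage <- timepoints$stage[i]
      mu <- base_log2 + truth$slope * (day - d0)
      for (r in seq_len(reps)) {
        eps <- if (sdl2 == 0) 0 else stats::rnorm(n, 0, sdl2)
        nm <- sprintf("d%d%s_r%d", day, substr(stage, 1, 1), r)
        cols[[nm]] <- 2^(mu + eps)
        meta[[nm]] <- data.frame(sample = nm, day = day, stage = stage,
                                 replicate = r, stringsAsFactors = FALSE)
      }
    }
    vals <- do.call(cbind, cols)
    rownames(vals) <- catalog$gene_id
    suppressWarnings(time_course(vals, do.call(rbind, meta)))
  })
}

#' Generate a synthetic chromatin-binding profile
#'
#' For each protein, the score is \eqn{\rho_{eff} z + \sqrt{1-\rho_{eff}^2}
#' \epsilon}, where \eqn{z} is the standardized planted testis
#' up-regulation, \eqn{\rho_{eff}} is the role's target correlation
#' (positive for silencing, negative for activation) multiplied by
#' \code{x_attenuation} for X-linked genes, and \eqn{\epsilon} is standard
#' normal noise. Each protein's bound/non-bound threshold is set at the
#' configured quantile of its generated scores.
#'
#' @param catalog,truth,config As for \code{\link{generate_atlas}}.
#' @param proteins Named character vector of roles; defaults to the
#'   configured panel.
#' @return A \code{\link{binding_profile}}.
#' @export
generate_binding <- function(catalog, truth, config,
                             proteins = config$proteins) {
  with_seed(substream_seed(config$seed, "binding"), {
    n <- nrow(catalog)
    up <- truth$upregulation
    z <- if (stats::sd(up) > 0) as.numeric(scale(up)) else rep(0, n)
    att <- ifelse(truth$arm == "X", config$x_attenuation, 1)
    scores <- sapply(names(proteins), function(pr) {
      rho <- if (proteins[[pr]] == "silencing") config$binding_rho_silencing
             else config$binding_rho_activation
      re <- rho * att
      re * z + sqrt(1 - re^2) * stats::rnorm(n)
    })
    rownames(scores) <- catalog$gene_id
    thr <- apply(scores, 2, stats::quantile,
                 probs = config$binding_threshold_quantile, names = FALSE)
    binding_profile(scores, thr, proteins)
  })
}

#' Generate a complete synthetic study
#'
#' Runs all four generators from one configuration; per-table random
#' substreams are derived from (seed, table name), so the same config
#' always produces byte-identical tables.
#'
#' @param config A \code{\link{sim_config}}.
#' @return List with \code{catalog}, \code{truth}, \code{atlas},
#'   \code{timecourse}, \code{binding} and the resolved \code{config}.
#' @export
simulate_study <- function(config = sim_config()) {
  cat_truth <- generate_catalog(config)
  list(catalog = cat_truth$catalog,
       truth = cat_truth$truth,
       atlas = generate_atlas(cat_truth$catalog, cat_truth$truth, config),
       timecourse = generate_timecourse(cat_truth$catalog, cat_truth$truth,
                                        config),
       binding = generate_binding(cat_truth$catalog, cat_truth$truth, config),
       config = config)
}
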