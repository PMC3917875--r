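#' Planted co-expression module specification
#'
#' Describes one module to plant in a synthetic compendium: a group of genes
#' that switch between an "off" and an "on" expression state together. The
#' per-sample on/off state is a latent Bernoulli variable shared by all member
#' genes, which is what makes the genes both bimodal and co-expressed.
#'
#' @param name module name (string).
#' @param size number of member genes, at least 3.
#' @param activation_prob fraction of samples in the "on" state, in (0,1).
#'   Default 0.5, the canonical balanced on/off pattern.
#' @param effect on/off mean shift Delta in log2 units, > 0.
#' @param loading_sd sd of the multiplicative per-gene effect jitter; each
#'   gene's effect is `effect * max(0.2, 1 + N(0, loading_sd^2))` so no member
#'   gene has a vanishing effect.
#' @param extrinsic if `TRUE` the module is microenvironment-driven: in
#'   cell-line-context datasets its genes get independent per-gene latents,
#'   so they stay bimodal but are no longer co-expressed.
#' @return object of class `planted_module`.
#' @export
planted_module <- function(name, size, activation_prob = 0.5, effect = 3,
                           loading_sd = 0.2, extrinsic = FALSE) {
  if (!is_count(size, min = 3L)) stop_("module size must be an integer >= 3")
  if (!is_prob(activation_prob)) stop_("activation_prob must be in (0,1)")
  if (!(length(effect) == 1L && effect > 0)) stop_("effect must be > 0")
  if (loading_sd < 0) stop_("loading_sd must be nonnegative")
  structure(list(name = as.character(name), size = as.integer(size),
                 activation_prob = activation_prob, effect = effect,
                 loading_sd = loading_sd, extrinsic = isTRUE(extrinsic)),
            class = "planted_module")
}

default_modules <- function(n_modules = 5L, size = 40L, ...) {
  lapply(seq_len(n_modules), function(i)
    planted_module(paste0("mod", i), size = size, ...))
}

#' Configuration of a synthetic expression compendium
#'
#' Defines the study conditions for the generator: how many datasets, their
#' biological contexts, the shared gene universe size, the planted modules,
#' the per-array quality confounder and the noise level. The default
#' configuration is six tumor datasets of 120 samples over 3,000 genes with
#' five planted 40-gene modules of effect 3 (log2 units) on unit noise.
#'
#' @param n_datasets number of datasets.
#' @param contexts character vector (length `n_datasets`) of `"tumor"` /
#'   `"cell_line"`.
#' @param n_genes genes in the shared universe; must be at least the total
#'   planted module size.
#' @param n_samples samples per dataset (scalar or per-dataset vector).
#' @param modules list of [planted_module] objects.
#' @param quality_sd sd of the additive per-array quality offset applied to
#'   every gene of a sample (log2 units).
#' @param noise_sd sd of the iid Gaussian measurement noise, > 0.
#' @param latent_coupling symmetric positive semi-definite matrix with unit
#'   diagonal giving the dependence between module latents (a Gaussian copula
#'   correlation); default identity.
#' @param seed integer seed; all generator randomness derives from it.
#' @return object of class `simulation_config`.
#' @export
simulation_config <- function(n_datasets = 6L,
                              contexts = rep("tumor", n_datasets),
                              n_genes = 3000L,
                              n_samples = 120L,
                              modules = default_modules(),
                              quality_sd = 0.6,
                              noise_sd = 1,
                              latent_coupling = diag(length(modules)),
                              seed = 1L) {
  if (!is_count(n_datasets)) stop_("n_datasets must be a positive integer")
  contexts <- match.arg(contexts, c("tumor", "cell_line"), several.ok = TRUE)
  if (length(contexts) != n_datasets)
    stop_("contexts must have one entry per dataset")
  if (!is_count(n_genes)) stop_("n_genes must be a positive integer")
  n_samples <- as.integer(rep(n_samples, length.out = n_datasets))
  if (any(n_samples < 3L)) stop_("each dataset needs at least 3 samples")
  if (!length(modules) || !all(vapply(modules, inherits, logical(1),
                                      "planted_module")))
    stop_("modules must be a list of planted_module objects")
  total <- sum(vapply(modules, function(m) m$size, integer(1)))
  if (total > n_genes)
    stop_("infeasible config: planted module genes (", total,
          ") exceed n_genes (", n_genes, ")")
  if (quality_sd < 0) stop_("quality_sd must be nonnegative")
  if (noise_sd <= 0) stop_("noise_sd must be positive")
  k <- length(modules)
  latent_coupling <- as.matrix(latent_coupling)
  if (!isTRUE(all.equal(dim(latent_coupling), c(k, k))))
    stop_("latent_coupling must be a ", k, "x", k, " matrix")
  if (max(abs(latent_coupling - t(latent_coupling))) > 1e-8)
    stop_("latent_coupling must be symmetric")
  if (max(abs(diag(latent_coupling) - 1)) > 1e-8)
    stop_("latent_coupling must have unit diagonal")
  ev <- eigen(latent_coupling, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8)
    stop_("latent_coupling must be positive semi-definite")
  nm <- vapply(modules, function(m) m$name, character(1))
  if (anyDuplicated(nm)) stop_("duplicate module names")
  structure(list(n_datasets = as.integer(n_datasets), contexts = contexts,
                 n_genes = as.integer(n_genes), n_samples = n_samples,
                 modules = modules, quality_sd = quality_sd,
                 noise_sd = noise_sd, latent_coupling = latent_coupling,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

# correlated binary module states for one dataset: threshold a Gaussian
# copula at the quantile matching each module's activation probability
draw_latent_states <- function(config, n) {
  k <- length(config$modules)
  L <- t(chol(config$latent_coupling + diag(1e-10, k)))
  Z <- L %*% matrix(stats::rnorm(k * n), k, n)
  probs <- vapply(config$modules, function(m) m$activation_prob, numeric(1))
  states <- (Z > stats::qnorm(1 - probs)) * 1L
  rownames(states) <- vapply(config$modules, function(m) m$name, character(1))
  states
}

#' Generate a synthetic expression compendium with planted modules
#'
#' Each dataset is built as `baseline + effect * latent * loading +
#' quality_offset + noise` on the log2 scale: per-gene baselines are
#' N(7, 1.5^2); member genes of a module add their (jittered) effect whenever
#' the module's latent state is "on" in a sample; a per-array quality offset
#' (sd `quality_sd`) shifts all genes of a sample together; iid Gaussian
#' noise (sd `noise_sd`) is added everywhere. Modules flagged `extrinsic`
#' lose their shared latent in cell-line-context datasets (each member gene
#' gets an independent latent there, so bimodality persists but co-expression
#' does not). The same config and seed always reproduce identical output.
#'
#' @param config a [simulation_config].
#' @return list with `compendium` (a [compendium]) and `truth`, a
#'   `simulation_truth` list holding `gene_membership` (named character
#'   vector, `NA` for background genes), `latent_activity` (per dataset, a
#'   modules x samples binary matrix; rows only for modules coherent in that
#'   dataset), `loadings` (per module, the per-gene effect multipliers) and
#'   the `config`.
#' @export
generate_compendium <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  k <- length(config$modules)
  genes <- sprintf("g%05d", seq_len(config$n_genes))
  membership <- stats::setNames(rep(NA_character_, config$n_genes), genes)
  idx <- 1L
  member_idx <- vector("list", k)
  for (j in seq_len(k)) {
    m <- config$modules[[j]]
    member_idx[[j]] <- idx:(idx + m$size - 1L)
    membership[member_idx[[j]]] <- m$name
    idx <- idx + m$size
  }
  # per-gene effect multipliers, shared across datasets so the planted
  # loading direction is a well-defined compendium-level truth
  loadings <- with_seed(derive_seed(config$seed, "loadings"), {
    lapply(seq_len(k), function(j) {
      m <- config$modules[[j]]
      stats::setNames(pmax(0.2, 1 + stats::rnorm(m$size, 0, m$loading_sd)),
                      genes[member_idx[[j]]])
    })
  })
  names(loadings) <- vapply(config$modules, `[[`, character(1), "name")

  datasets <- vector("list", config$n_datasets)
  latent_activity <- vector("list", config$n_datasets)
  for (d in seq_len(config$n_datasets)) {
    ds_id <- sprintf("SIM%02d", d)
    ctx <- config$contexts[d]
    n <- config$n_samples[d]
    dat <- with_seed(derive_seed(config$seed, "dataset", ds_id), {
      baseline <- stats::rnorm(config$n_genes, 7, 1.5)
      X <- matrix(baseline, config$n_genes, n) +
        matrix(stats::rnorm(config$n_genes * n, 0, config$noise_sd),
               config$n_genes, n)
      states <- draw_latent_states(config, n)
      coherent <- rep(TRUE, k)
      for (j in seq_len(k)) {
        m <- config$modules[[j]]
        rows <- member_idx[[j]]
        if (m$extrinsic && ctx == "cell_line") {
          # microenvironment-driven: bimodal per gene, but no shared latent
          coherent[j] <- FALSE
          lat <- matrix(stats::rbinom(length(rows) * n, 1L,
                                      m$activation_prob), length(rows), n)
          X[rows, ] <- X[rows, ] + m$effect * loadings[[j]] * lat
        } else {
          X[rows, ] <- X[rows, ] + (m$effect * loadings[[j]]) %o% states[j, ]
        }
      }
      if (config$quality_sd > 0) {
        q <- stats::rnorm(n, 0, config$quality_sd)
        X <- X + matrix(q, config$n_genes, n, byrow = TRUE)
      }
      list(X = X, states = states[coherent, , drop = FALSE])
    })
    rownames(dat$X) <- genes
    colnames(dat$X) <- sprintf("%s_s%03d", ds_id, seq_len(n))
    colnames(dat$states) <- colnames(dat$X)
    datasets[[d]] <- expression_dataset(dat$X, ds_id, ctx)
    latent_activity[[d]] <- dat$states
  }
  names(latent_activity) <- vapply(datasets, `[[`, character(1), "dataset_id")
  truth <- structure(list(gene_membership = membership,
                          latent_activity = latent_activity,
                          loadings = loadings, config = config),
                     class = "simulation_truth")
  list(compendium = compendium(datasets), truth = truth)
}

#' Generate module-driven clinical annotation for a synthetic compendium
#'
#' Survival times are exponential with log-hazard linear in the binary module
#' latent states (`log h = log h0 + sum(beta_m * state_m)`); censoring is an
#' independent exponential whose rate is `h0 * censoring_rate /
#' (1 - censoring_rate)`, so `censoring_rate = 0` yields no censoring and a
#' baseline ("all off") sample is censored with probability `censoring_rate`.
#' Pathologic complete response is Bernoulli with
#' `logit P(pCR) = qlogis(0.25) + sum(gamma_m * state_m)`. Subtype, receptor
#' status and metastasis site follow documented deterministic/logistic rules
#' on the latent states (see the methods vignette).
#'
#' @param truth `simulation_truth` from [generate_compendium()].
#' @param hazard_coeffs named numeric vector of per-module log-hazard
#'   coefficients (names must be planted module names; missing modules get 0).
#' @param logistic_coeffs named numeric vector of per-module pCR log-odds
#'   coefficients.
#' @param censoring_rate baseline censoring probability in [0, 1).
#' @param base_hazard baseline event rate `h0` (arbitrary inverse-time units).
#' @param seed integer seed.
#' @return data.frame with columns `sample_id`, `dataset_id`, `time`, `event`,
#'   `pcr`, `subtype`, `er_status`, `her2_status`, `met_site`.
#' @export
generate_clinical <- function(truth, hazard_coeffs = NULL,
                              logistic_coeffs = NULL, censoring_rate = 0.3,
                              base_hazard = 0.1, seed = 1L) {
  stopifnot(inherits(truth, "simulation_truth"))
  mod_names <- vapply(truth$config$modules, `[[`, character(1), "name")
  fill <- function(v) {
    out <- stats::setNames(rep(0, length(mod_names)), mod_names)
    if (!is.null(v)) {
      if (is.null(names(v)) || !all(names(v) %in% mod_names))
        stop_("coefficient names must be planted module names (",
              paste(mod_names, collapse = ", "), ")")
      out[names(v)] <- v
    }
    out
  }
  beta <- fill(hazard_coeffs)
  gamma <- fill(logistic_coeffs)
  if (!(is_prob(censoring_rate, open_lo = FALSE, open_hi = TRUE) ||
        censoring_rate == 0))
    stop_("censoring_rate must be in [0, 1)")

  rows <- lapply(names(truth$latent_activity), function(ds_id) {
    states <- truth$latent_activity[[ds_id]]
    n <- ncol(states)
    S <- matrix(0, length(mod_names), n, dimnames = list(mod_names, NULL))
    S[rownames(states), ] <- states
    with_seed(derive_seed(seed, "clinical", ds_id), {
      lp <- drop(beta %*% S)
      rate <- base_hazard * exp(lp)
      t_event <- stats::rexp(n, rate)
      if (censoring_rate > 0) {
        c_rate <- base_hazard * censoring_rate / (1 - censoring_rate)
        t_cens <- stats::rexp(n, c_rate)
      } else t_cens <- rep(Inf, n)
      event <- as.integer(t_event <= t_cens)
      time <- pmin(t_event, t_cens)
      pcr <- stats::rbinom(n, 1L, stats::plogis(stats::qlogis(0.25) +
                                                drop(gamma %*% S)))
      s1 <- if (length(mod_names) >= 1) S[1, ] else rep(0, n)
      s2 <- if (length(mod_names) >= 2) S[2, ] else rep(0, n)
      s3 <- if (length(mod_names) >= 3) S[3, ] else rep(0, n)
      subtype <- ifelse(s1 == 1 & s2 == 1, "LumB",
                 ifelse(s1 == 1, "LumA",
                 ifelse(s3 == 1, "Her2",
                 ifelse(s2 == 1, "Basal", "Normal"))))
      met_site <- ifelse(event == 1,
                         ifelse(stats::runif(n) <
                                  stats::plogis(drop(gamma %*% S)),
                                "bone", "other"), NA_character_)
      data.frame(sample_id = colnames(states), dataset_id = ds_id,
                 time = time, event = event, pcr = pcr, subtype = subtype,
                 er_status = ifelse(s1 == 1, "pos", "neg"),
                 her2_status = ifelse(s3 == 1, "pos", "neg"),
                 met_site = met_site, stringsAsFactors = FALSE)
    })
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
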