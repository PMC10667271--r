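#' Dehydration states of the sampled design
#'
#' The six-level hydration axis used throughout: fully hydrated, ~80% RWC,
#' ~60% RWC, ~40% RWC, <10% RWC (desiccated), and rehydrated (recovery,
#' sampled 24-48 h after rewatering).
#'
#' @export
DEHYDRATION_STATES <- c("hydrated", "RWC80", "RWC60", "RWC40", "RWC10",
                        "rehydrated")

#' Declare a planted co-expression module
#'
#' A module is a block of genes sharing one latent factor (hence mutually
#' correlated) within one tissue, and shifted up or down by the planted
#' effect size in the given dehydration states of that tissue.
#'
#' @param size Number of genes in the module.
#' @param tissue Tissue the module belongs to (`"shoot"` or `"root"`).
#' @param states Character vector of dehydration states in which the module
#'   is differentially expressed.
#' @param direction `"up"` or `"down"`.
#' @return A `module_spec` list.
#' @export
#' @examples
#' module_spec(50, "root", "RWC40", "down")
module_spec <- function(size, tissue, states, direction = c("up", "down")) {
  direction <- match.arg(direction)
  stopifnot(is.numeric(size), size >= 1)
  structure(list(size = as.integer(size), tissue = tissue,
                 states = as.character(states), direction = direction),
            class = "module_spec")
}

#' Simulation configuration
#'
#' Collects every knob of the synthetic-data generators. The defaults
#' emulate the sampled study design: two tissues, six dehydration states,
#' triplicates, log2-scale expression, and four planted modules reproducing
#' the qualitative tissue contrast (a broad shoot response present across
#' all drying states versus a root response concentrated at 40% RWC, with
#' the 40% state carrying more down-regulated genes).
#'
#' @param n_genes Total number of genes (planted module genes included).
#' @param n_metabolites Size of the metabolite panel; the named panel of
#'   sugars, amino acids and organic acids is used first and generic stable
#'   metabolites pad any remainder.
#' @param states Ordered dehydration states; must include `"hydrated"`.
#' @param tissues Tissues sampled.
#' @param replicates Biological replicates per tissue x state (>= 2).
#' @param modules List of [module_spec()] entries; their sizes must sum to
#'   at most `n_genes`.
#' @param noise_sd Residual SD of log2 expression around gene baselines
#'   (default 0.3, a typical replicate-level spread for moderately
#'   expressed genes).
#' @param module_corr Target expected pairwise Pearson correlation within a
#'   module, in (0, 1).
#' @param module_state_frac Fraction of the module factor's unit variance
#'   carried by its state-level component, in \[0, 1\]. The factor is the
#'   sum of a state-level draw (the module's coordinated dehydration
#'   response, constant within a tissue x state cell) and a sample-level
#'   draw (replicate fluctuation); the default 0.75 makes module activity
#'   predominantly state-driven, as a dehydration-response module should
#'   be, while keeping replicate-level co-fluctuation.
#' @param deg_log2fc Planted absolute log2 fold change applied to module
#'   genes in their active (tissue, state) cells. The default 8 (~250-fold)
#'   reflects the scale on which strong desiccation-response genes switch
#'   between the hydrated and dried states, and keeps planted effects
#'   detectable at triplicate sample sizes despite the module factor's
#'   contribution to per-gene variance.
#' @param metab_fold Fold elevation of planted metabolite trajectories.
#' @param metab_sdlog Log-scale SD of the multiplicative metabolite noise.
#' @param hormone_sd Gaussian SD of hormone measurements (pmol/mg).
#' @param seed Root seed; every generator draws from a named substream of
#'   it, so regenerating one table does not perturb the others.
#' @return A validated `sim_config` object.
#' @export
#' @examples
#' cfg <- sim_config(n_genes = 200, seed = 1)
#' cfg
sim_config <- function(n_genes = 2000L,
                       n_metabolites = 20L,
                       states = DEHYDRATION_STATES,
                       tissues = c("shoot", "root"),
                       replicates = 3L,
                       modules = default_modules(),
                       noise_sd = 0.3,
                       module_corr = 0.9,
                       module_state_frac = 0.75,
                       deg_log2fc = 8,
                       metab_fold = 4,
                       metab_sdlog = 0.25,
                       hormone_sd = 1,
                       seed = 1L) {
  cfg <- structure(list(
    n_genes = as.integer(n_genes), n_metabolites = as.integer(n_metabolites),
    states = as.character(states), tissues = as.character(tissues),
    replicates = as.integer(replicates), modules = modules,
    noise_sd = noise_sd, module_corr = module_corr,
    module_state_frac = module_state_frac,
    deg_log2fc = deg_log2fc, metab_fold = metab_fold,
    metab_sdlog = metab_sdlog, hormone_sd = hormone_sd,
    seed = as.integer(seed)), class = "sim_config")
  validate_sim_config(cfg)
  cfg
}

#' Default planted modules of the demo design
#'
#' Two shoot modules (one up-, one down-regulated) active throughout drying
#' and two root modules each tied to a single state, so the root network
#' changes composition across states while the shoot one does not.
#'
#' @param size Genes per module.
#' @return List of [module_spec()] objects.
#' @export
default_modules <- function(size = 50L) {
  drying <- c("RWC60", "RWC40", "RWC10")
  list(module_spec(size, "shoot", drying, "up"),
       module_spec(size, "shoot", drying, "down"),
       module_spec(size, "root", "RWC40", "down"),
       module_spec(size, "root", "RWC10", "up"))
}

validate_sim_config <- function(cfg) {
  fail <- function(msg) stop("invalid simulation config: ", msg, call. = FALSE)
  if (!"hydrated" %in% cfg$states) fail("states must include 'hydrated'")
  if (cfg$replicates < 2L) fail("replicates must be >= 2")
  if (!(cfg$module_corr > 0 && cfg$module_corr < 1))
    fail("module_corr must lie in (0, 1)")
  if (!(cfg$module_state_frac >= 0 && cfg$module_state_frac <= 1))
    fail("module_state_frac must lie in [0, 1]")
  if (cfg$noise_sd < 0) fail("noise_sd must be nonnegative")
  if (cfg$deg_log2fc < 0) fail("deg_log2fc must be nonnegative")
  sizes <- vapply(cfg$modules, function(m) m$size, integer(1))
  if (sum(sizes) > cfg$n_genes)
    fail("module sizes exceed n_genes (module_size x n_modules <= n_genes)")
  for (m in cfg$modules) {
    if (!m$tissue %in% cfg$tissues)
      fail(sprintf("module tissue '%s' not among tissues", m$tissue))
    if (!all(m$states %in% cfg$states))
      fail("module active states must be a subset of states")
  }
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Simulation configuration\n")
  cat(sprintf("  %d genes, %d metabolites; %s x %s, %d replicates\n",
              x$n_genes, x$n_metabolites,
              paste(x$tissues, collapse = "/"),
              paste(x$states, collapse = ","), x$replicates))
  cat(sprintf("  %d planted modules (target r = %.2f, |log2FC| = %g), noise SD %g, seed %d\n",
              length(x$modules), x$module_corr, x$deg_log2fc,
              x$noise_sd, x$seed))
  invisible(x)
}

# Named substreams off the root seed; offsets fixed so each generator is a
# pure function of the root seed alone.
.substream <- function(seed, stream) {
  offset <- c(expression = 101L, metabolites = 202L, hormones = 303L,
              physiology = 404L)[[stream]]
  (as.integer(seed) %% 2000000000L) + offset
}

.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

.make_sample_sheet <- function(cfg) {
  grid <- expand.grid(replicate = seq_len(cfg$replicates),
                      state = cfg$states, tissue = cfg$tissues,
                      stringsAsFactors = FALSE)
  grid <- grid[, c("tissue", "state", "replicate")]
  grid$sample_id <- sprintf("%s_%s_r%d", grid$tissue, grid$state,
                            grid$replicate)
  grid[, c("sample_id", "tissue", "state", "replicate")]
}

#' Generate a synthetic log2 expression matrix with planted structure
#'
#' Background genes are independent Gaussian noise around gene-specific
#' baselines (drawn uniformly on 4-12 log2 units). Each planted module adds
#' one latent standard-Gaussian factor per sample of its tissue with loading
#' `noise_sd * sqrt(rho / (1 - rho))`, so the expected within-module pairwise
#' Pearson correlation is `module_corr`; module genes are additionally
#' shifted by +/- `deg_log2fc` in their active (tissue, state) cells only,
#' so a gene can be down at 40% RWC and unchanged elsewhere.
#'
#' @param config A [sim_config()].
#' @return List with `expression` (genes x samples matrix, log2 scale),
#'   `samples` (sample sheet data frame), and `truth` (a `synthetic_truth`
#'   list with `deg_truth`, `module_truth` and the planted module specs).
#' @export
#' @examples
#' sim <- simulate_expression(sim_config(n_genes = 100, seed = 7))
#' dim(sim$expression)
#' head(sim$truth$deg_truth)
simulate_expression <- function(config) {
  validate_sim_config(config)
  samples <- .make_sample_sheet(config)
  genes <- sprintf("gene%05d", seq_len(config$n_genes))
  .with_seed(.substream(config$seed, "expression"), {
    baseline <- runif(config$n_genes, 4, 12)
    expr <- matrix(rnorm(config$n_genes * nrow(samples), sd = config$noise_sd),
                   nrow = config$n_genes,
                   dimnames = list(genes, samples$sample_id))
    expr <- expr + baseline

    module_truth <- setNames(rep(NA_integer_, config$n_genes), genes)
    deg_truth <- list()
    rho <- config$module_corr
    loading <- config$noise_sd * sqrt(rho / (1 - rho))
    w <- config$module_state_frac
    next_gene <- 1L
    for (mi in seq_along(config$modules)) {
      m <- config$modules[[mi]]
      idx <- next_gene:(next_gene + m$size - 1L)
      next_gene <- next_gene + m$size
      module_truth[idx] <- mi
      in_tissue <- samples$tissue == m$tissue
      # unit-variance factor split between a state-level component (the
      # module's coordinated dehydration response) and a sample-level
      # component (replicate-to-replicate fluctuation); the split leaves
      # the expected within-module correlation at module_corr
      cell <- match(samples$state[in_tissue],
                    unique(samples$state[in_tissue]))
      state_scores <- rnorm(max(cell))
      factor_scores <- sqrt(w) * state_scores[cell] +
        sqrt(1 - w) * rnorm(sum(in_tissue))
      expr[idx, in_tissue] <- expr[idx, in_tissue] +
        rep(loading * factor_scores, each = m$size)
      shift <- if (m$direction == "up") config$deg_log2fc else -config$deg_log2fc
      active <- in_tissue & samples$state %in% m$states
      if (any(active))
        expr[idx, active] <- expr[idx, active] + shift
      dt <- expand.grid(gene = genes[idx], tissue = m$tissue,
                        state = m$states, stringsAsFactors = FALSE)
      dt$direction <- rep(m$direction, nrow(dt))
      deg_truth[[mi]] <- dt
    }
    deg_truth <- if (length(deg_truth)) do.call(rbind, deg_truth) else NULL
    if (is.null(deg_truth) || !nrow(deg_truth))
      deg_truth <- data.frame(gene = character(), tissue = character(),
                              state = character(), direction = character())
    truth <- structure(list(deg_truth = deg_truth,
                            module_truth = module_truth,
                            modules = config$modules),
                       class = "synthetic_truth")
    list(expression = expr, samples = samples, truth = truth)
  })
}

# Named metabolite panel. Early set accumulates in shoots from 60% RWC on;
# late set accumulates in roots only at <10% RWC; the rest stay flat.
.metabolite_panel <- function(n) {
  early <- c("sucrose", "raffinose", "myo-inositol", "proline", "galactitol",
             "D-erythritol", "tyrosine", "isoleucine", "tryptophan",
             "phenylalanine")
  late <- c("lysine", "methionine", "alanine", "valine", "leucine")
  stable <- c("succinate", "fumarate", "malate", "citrate", "pyruvate")
  panel <- data.frame(metabolite = c(early, late, stable),
                      role = rep(c("early_shoot", "late_root", "stable"),
                                 c(length(early), length(late),
                                   length(stable))),
                      stringsAsFactors = FALSE)
  if (n < nrow(panel)) return(panel[seq_len(n), ])
  if (n > nrow(panel)) {
    extra <- sprintf("metab%03d", seq_len(n - nrow(panel)))
    panel <- rbind(panel, data.frame(metabolite = extra, role = "stable"))
  }
  panel
}

#' Generate a synthetic metabolite abundance matrix
#'
#' Raw-scale (positive) abundances with multiplicative lognormal noise.
#' The early-accumulating set (sucrose, raffinose, myo-inositol, proline,
#' aromatic amino acids, ...) is elevated `metab_fold`-fold in shoots from
#' 60% RWC onward through drying; the late set (lysine, methionine,
#' alanine, ...) is elevated only in roots at <10% RWC.
#'
#' @param config A [sim_config()].
#' @return List with `metabolites` (metabolites x samples matrix, raw
#'   scale), `samples`, and `panel` (metabolite roles).
#' @export
simulate_metabolites <- function(config) {
  validate_sim_config(config)
  samples <- .make_sample_sheet(config)
  panel <- .metabolite_panel(config$n_metabolites)
  drying_60_on <- intersect(c("RWC60", "RWC40", "RWC10"), config$states)
  .with_seed(.substream(config$seed, "metabolites"), {
    base <- exp(runif(nrow(panel), log(20), log(500)))
    mean_mat <- matrix(base, nrow = nrow(panel), ncol = nrow(samples),
                       dimnames = list(panel$metabolite, samples$sample_id))
    early <- panel$role == "early_shoot"
    late <- panel$role == "late_root"
    up_early <- samples$tissue == "shoot" & samples$state %in% drying_60_on
    up_late <- samples$tissue == "root" & samples$state == "RWC10"
    mean_mat[early, up_early] <- mean_mat[early, up_early] * config$metab_fold
    mean_mat[late, up_late] <- mean_mat[late, up_late] * config$metab_fold
    noise <- matrix(rnorm(length(mean_mat), sd = config$metab_sdlog),
                    nrow = nrow(mean_mat))
    list(metabolites = mean_mat * exp(noise), samples = samples,
         panel = panel)
  })
}

# State-wise mean trajectories (pmol/mg) for the three measured hormones:
# ABA primed high in hydrated/mildly dehydrated plants and low from 60% RWC;
# SA rising from 60% RWC and continuing through drying; JA-Ile declining
# from 60% RWC. Recovery behaves like a partial return toward hydrated.
.hormone_profiles <- function(states) {
  prof <- list(
    ABA      = c(hydrated = 40, RWC80 = 35, RWC60 = 15, RWC40 = 10,
                 RWC10 = 8,  rehydrated = 14),
    SA       = c(hydrated = 5,  RWC80 = 6,  RWC60 = 15, RWC40 = 25,
                 RWC10 = 35, rehydrated = 28),
    `JA-Ile` = c(hydrated = 20, RWC80 = 18, RWC60 = 10, RWC40 = 5,
                 RWC10 = 4,  rehydrated = 6))
  lapply(prof, function(p) {
    known <- intersect(states, names(p))
    out <- p[known]
    extra <- setdiff(states, names(p))
    if (length(extra)) out <- c(out, setNames(rep(mean(p), length(extra)),
                                              extra))
    out[states]
  })
}

#' Generate synthetic phytohormone measurements
#'
#' Long-format triplicate shoot measurements for ABA, SA and JA-Ile with
#' Gaussian noise around state-wise mean trajectories (ABA highest when
#' hydrated, SA rising from 60% RWC, JA-Ile declining through drying).
#' Concentrations are truncated at zero.
#'
#' @param config A [sim_config()].
#' @return List with `hormones` (data frame: hormone, state, replicate,
#'   conc_pmol_per_mg) and `truth` (state-wise mean vectors per hormone).
#' @export
simulate_hormones <- function(config) {
  validate_sim_config(config)
  profiles <- .hormone_profiles(config$states)
  .with_seed(.substream(config$seed, "hormones"), {
    rows <- lapply(names(profiles), function(h) {
      mu <- profiles[[h]]
      data.frame(hormone = h,
                 state = rep(names(mu), each = config$replicates),
                 replicate = rep(seq_len(config$replicates), length(mu)),
                 conc_pmol_per_mg = pmax(0, rnorm(
                   length(mu) * config$replicates,
                   mean = rep(mu, each = config$replicates),
                   sd = config$hormone_sd)),
                 stringsAsFactors = FALSE)
    })
    list(hormones = do.call(rbind, rows), truth = profiles)
  })
}

# RWC bands of the gradual-then-rapid drying experiment, wettest first.
.rwc_bands <- function() {
  data.frame(rwc_band = c("hydrated", "100-80", "70-60", "50-40", "30-20",
                          "<10"),
             lo = c(95, 80, 60, 40, 20, 2),
             hi = c(100, 100, 70, 50, 30, 10),
             stringsAsFactors = FALSE)
}

#' Generate synthetic physiology records
#'
#' Weight triples (fresh/dry/turgid, grams) consistent with each declared
#' RWC band; Evans Blue A600 readings that are high for plants rapidly
#' dried from >= 80% RWC and low for plants first acclimated to 60% RWC or
#' drier (plus boiled-positive and hydrated-negative controls); and
#' all-or-nothing survival counts out of five plants per band (death above
#' 70-60, full resurrection at 70-60 and drier).
#'
#' @param config A [sim_config()].
#' @return List with `weights`, `viability` and `survival` data frames.
#' @export
simulate_physiology <- function(config) {
  validate_sim_config(config)
  bands <- .rwc_bands()
  .with_seed(.substream(config$seed, "physiology"), {
    n <- config$replicates
    w <- do.call(rbind, lapply(seq_len(nrow(bands)), function(i) {
      rwc <- runif(n, bands$lo[i], bands$hi[i])
      dw <- runif(n, 0.2, 0.5)
      tw <- dw + runif(n, 1, 2)
      data.frame(sample_id = sprintf("%s_w%d", bands$rwc_band[i], seq_len(n)),
                 rwc_band = bands$rwc_band[i],
                 fresh_weight = dw + rwc / 100 * (tw - dw),
                 dry_weight = dw, turgid_weight = tw,
                 stringsAsFactors = FALSE)
    }))
    a600_mean <- c(`boiled-positive` = 1.2, `hydrated-negative` = 0.10,
                   hydrated = 1.05, `100-80` = 1.0, `70-60` = 0.35,
                   `50-40` = 0.30, `30-20` = 0.26, `<10` = 0.25)
    v <- data.frame(
      sample_id = sprintf("%s_v%d", rep(names(a600_mean), each = n),
                          seq_len(n)),
      treatment = rep(names(a600_mean), each = n),
      a600 = pmax(0, rnorm(length(a600_mean) * n,
                           rep(a600_mean, each = n), sd = 0.03)),
      stringsAsFactors = FALSE)
    surv <- data.frame(rwc_band = bands$rwc_band, n_plants = 5L,
                       n_resurrected = ifelse(
                         bands$rwc_band %in% c("hydrated", "100-80"), 0L, 5L),
                       stringsAsFactors = FALSE)
    list(weights = w, viability = v, survival = surv)
  })
}
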